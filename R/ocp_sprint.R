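# Assembly of the sprint data-tracking optimal control problem.
#
# State vector x = [q v]; controls u = [u_act u_res u_vdot u_grf] with the
# torque actuators playing the role of the upper-limb/net-moment drives, one
# bounded reserve per internal DOF, the implicit-dynamics acceleration
# controls, and one planar force pair per contact sphere. The first-order
# dynamics (qdot = v, vdot = u_vdot) are linear; the skeletal equation of
# motion and the contact-consistency conditions enter as nonlinear algebraic
# path constraints at the beginning of every mesh interval.

# control-vector layout for a given model
control_layout <- function(model) {
  nd <- model$ndof
  ni <- length(model$internal_dofs)
  nsph <- nrow(model$spheres)
  list(
    nd = nd, ni = ni, nsph = nsph,
    nu = 2 * ni + nd + 2 * nsph,
    i_act = seq_len(ni),
    i_res = ni + seq_len(ni),
    i_vdot = 2 * ni + seq_len(nd),
    i_grf = 2 * ni + nd + seq_len(2 * nsph) # (fx_1..fx_s, fy_1..fy_s)
  )
}

#' Signal normalizers for the tracking objective
#'
#' Builds the per-signal normalizing divisors: 10% of the experimental range
#' for tracked kinematics, ground reaction forces, net moments and the
#' acceleration controls, a 0.01 m override for the pelvis anterior-posterior
#' translation, and the respective bounds for the reserve actuators.
#' Degenerate (near-constant) signals fall back to a fixed margin.
#'
#' @param exp a preprocessed `sprint_experiment`.
#' @param model the `sprint_model`.
#' @return list with numeric vectors `q`, `grf`, `tau`, `vdot`, `res`.
#' @export
normalization_spec <- function(exp, model) {
  rng <- function(M, fallback) {
    r <- apply(M, 2, function(x) diff(range(x)))
    bad <- r < 1e-6
    if (any(bad)) {
      message("degenerate signal range for ", paste(colnames(M)[bad], collapse = ", "),
              "; using fixed normalizer fallback")
      r[bad] <- fallback
    }
    r
  }
  nq <- 0.1 * rng(exp$q, 0.1)
  nq[1] <- 0.01 # pelvis anterior-posterior translation tracked tightly
  G <- cbind(exp$grf$right, exp$grf$left)
  colnames(G) <- c("r_ap", "r_vertical", "l_ap", "l_vertical")
  a <- if (!is.null(exp$a)) exp$a else exp$q_fun(exp$time, 2)
  colnames(a) <- colnames(exp$q)
  list(q = nq,
       grf = 0.1 * rng(G, 10),
       tau = 0.1 * rng(exp$tau, 1),
       vdot = 0.1 * rng(a, 1),
       res = model$actuators$reserve_bound)
}

#' State and control bounds plus initial guess for tracking
#'
#' Kinematic states and acceleration controls are bounded 25% of the
#' experimental range beyond each extremum (with a fixed fallback margin for
#' degenerate signals); reserves are bounded by the actuator map (10 Nm by
#' default, 40 Nm at MTP DOFs) and GRF controls by +/- 2500 N per component.
#' The guess interpolates the experimental splines; reserves start at zero
#' and GRF controls at the contact model evaluated on the data.
#'
#' @param exp a preprocessed `sprint_experiment`.
#' @param model the `sprint_model`.
#' @return list with `x_lb`, `x_ub`, `u_lb`, `u_ub`, `x_guess(tnorm)`,
#'   `u_guess(tnorm)` (normalized-time closures over the horizon).
#' @export
tracking_bounds_and_guess <- function(exp, model) {
  cl <- control_layout(model)
  tf <- exp$time[length(exp$time)] - exp$time[1]
  range_bounds <- function(M, fallback = 0.25) {
    lo <- apply(M, 2, min); hi <- apply(M, 2, max)
    r <- hi - lo
    r[r < 1e-6] <- fallback
    cbind(lo - 0.25 * r, hi + 0.25 * r)
  }
  v <- if (!is.null(exp$v)) exp$v else exp$q_fun(exp$time, 1)
  a <- if (!is.null(exp$a)) exp$a else exp$q_fun(exp$time, 2)
  bq <- range_bounds(exp$q)
  bv <- range_bounds(v)
  ba <- range_bounds(a)
  act_b <- model$actuators$torque_bound[model$internal_dofs]
  res_b <- model$actuators$reserve_bound[model$internal_dofs]
  u_lb <- c(-act_b, -res_b, ba[, 1], rep(-2500, 2 * cl$nsph))
  u_ub <- c(act_b, res_b, ba[, 2], rep(2500, 2 * cl$nsph))

  grf_guess <- local({
    if (!is.null(exp$grf_sphere)) {
      fxs <- colwise_splines(exp$time, exp$grf_sphere$fx)
      fys <- colwise_splines(exp$time, exp$grf_sphere$fy)
      function(t) c(fxs(t), fys(t))
    } else {
      function(t) {
        cg <- contact_grf(model, exp$q_fun(t), exp$q_fun(t, 1))
        c(cg$per_sphere$fx, cg$per_sphere$fy)
      }
    }
  })
  taus <- exp$tau_fun
  list(
    x_lb = c(bq[, 1], bv[, 1]), x_ub = c(bq[, 2], bv[, 2]),
    u_lb = u_lb, u_ub = u_ub,
    x_guess = function(tnorm) {
      t <- exp$time[1] + tnorm * tf
      c(exp$q_fun(t), exp$q_fun(t, 1))
    },
    u_guess = function(tnorm) {
      t <- exp$time[1] + tnorm * tf
      u <- numeric(cl$nu)
      u[cl$i_act] <- taus(t)
      u[cl$i_vdot] <- exp$q_fun(t, 2)
      u[cl$i_grf] <- grf_guess(t)
      u
    }
  )
}

# path-constraint closure shared by tracking and predictive problems:
# skeletal EoM residual (one row per DOF) followed by per-sphere contact
# consistency rows (fx then fy).
sprint_path_fun <- function(model) {
  cl <- control_layout(model)
  nd <- cl$nd
  function(X, U, t) {
    Q <- X[, seq_len(nd), drop = FALSE]
    V <- X[, nd + seq_len(nd), drop = FALSE]
    TAU <- U[, cl$i_act, drop = FALSE] + U[, cl$i_res, drop = FALSE]
    FX <- U[, cl$i_grf[seq_len(cl$nsph)], drop = FALSE]
    FY <- U[, cl$i_grf[cl$nsph + seq_len(cl$nsph)], drop = FALSE]
    cm <- com_state(model, Q, V)
    drag <- aerodynamic_drag(cm$vx, model$drag)
    eom <- eom_residual_batch(model, Q, V, U[, cl$i_vdot, drop = FALSE],
                              TAU = TAU, FX = FX, FY = FY, drag_fx = drag)
    cg <- contact_grf(model, Q, V)
    cbind(eom,
          cg$per_sphere$fx - FX,
          cg$per_sphere$fy - FY)
  }
}

#' Build the data-tracking optimal control problem
#'
#' @param exp a preprocessed `sprint_experiment` (see [preprocess()]).
#' @param model the `sprint_model`.
#' @param N number of mesh intervals (default 50).
#' @param d collocation order (default 3).
#' @param weights the seven tracking/effort/control weights `w1..w7`.
#' @param control_rep control parameterization.
#' @return an `ocp_def` ready for [solve_ocp()].
#' @export
build_tracking_ocp <- function(exp, model, N = 50, d = 3,
                               weights = c(0.1, 0.05, 0.01, 0.01, 0.001, 1e-4, 0.1),
                               control_rep = "constant") {
  if (is.null(exp$q_fun)) stop("experiment must be preprocessed first (see preprocess())")
  cl <- control_layout(model)
  nd <- cl$nd
  nx <- 2 * nd
  tf <- exp$time[length(exp$time)] - exp$time[1]
  bg <- tracking_bounds_and_guess(exp, model)
  norms <- normalization_spec(exp, model)
  tracked_tau <- setdiff(model$internal_dofs,
                         if (!is.null(model$mtp)) model$mtp$dofs else character(0))
  i_tracked <- match(tracked_tau, model$internal_dofs)

  A <- matrix(0, nx, nx); A[seq_len(nd), nd + seq_len(nd)] <- diag(nd)
  B <- matrix(0, nx, cl$nu); B[nd + seq_len(nd), cl$i_vdot] <- diag(nd)

  w <- weights
  objective <- function(layout) {
    tt <- function(tnorm) exp$time[1] + tnorm * tf
    terms <- list(
      obj_term_states(layout, dofs = seq_len(nd), weight = w[1],
                      target = function(tn) exp$q_fun(tt(tn)),
                      norm = norms$q, name = "track_q"),
      local({
        C <- matrix(0, 4, cl$nu)
        sp <- model$spheres
        for (k in seq_len(cl$nsph)) {
          col_fx <- cl$i_grf[k]; col_fy <- cl$i_grf[cl$nsph + k]
          row <- if (sp$foot[k] == "right") 1 else 3
          C[row, col_fx] <- 1       # anterior-posterior
          C[row + 1, col_fy] <- 1   # vertical
        }
        obj_term_controls(layout, C, weight = w[2],
                          target = function(tn) exp$grf_fun(tt(tn)),
                          norm = norms$grf, name = "track_grf")
      }),
      local({
        C <- matrix(0, length(i_tracked), cl$nu)
        for (r in seq_along(i_tracked)) {
          C[r, cl$i_act[i_tracked[r]]] <- 1
          C[r, cl$i_res[i_tracked[r]]] <- 1
        }
        obj_term_controls(layout, C, weight = w[3],
                          target = function(tn) exp$tau_fun(tt(tn))[, i_tracked, drop = FALSE],
                          norm = norms$tau[i_tracked], name = "track_tau")
      }),
      local({
        C <- matrix(0, cl$ni, cl$nu)
        C[cbind(seq_len(cl$ni), cl$i_res)] <- 1
        obj_term_controls(layout, C, weight = w[5], target = 0,
                          norm = norms$res, name = "control_res")
      }),
      local({
        C <- matrix(0, nd, cl$nu)
        C[cbind(seq_len(nd), cl$i_vdot)] <- 1
        obj_term_controls(layout, C, weight = w[6], target = 0,
                          norm = norms$vdot, name = "control_vdot")
      })
    )
    terms
  }

  define_ocp(
    nx = nx, nu = cl$nu, N = N, d = d, tf = tf,
    linear_dyn = list(A = A, B = B),
    path = sprint_path_fun(model), npath = nd + 2 * cl$nsph,
    path_scale = c(rep(200, 3), rep(100, nd - 3), rep(500, 2 * cl$nsph)),
    x_lb = bg$x_lb, x_ub = bg$x_ub, u_lb = bg$u_lb, u_ub = bg$u_ub,
    x_guess = bg$x_guess, u_guess = bg$u_guess,
    objective = objective, control_rep = control_rep
  )
}

#' Run the data-tracking simulation
#'
#' Preprocesses the experiment (if needed), builds and solves the tracking
#' OCP with the horizon fixed to the experiment duration, and reports
#' root-mean-squared differences between the tracked data and the solution.
#'
#' @param exp a `sprint_experiment`.
#' @param model the `sprint_model` (defaults to the experiment's generator
#'   model or [default_model()]).
#' @param N mesh intervals (default 50).
#' @param cutoff preprocessing low-pass cut-off (Hz); `NA` disables
#'   filtering, `NULL` (default) filters at 20 Hz only when the experiment
#'   records added measurement noise (noise-free data are already
#'   band-limited, and filtering them only perturbs their dynamic
#'   consistency).
#' @param weights tracking weights `w1..w7`.
#' @param control_rep control parameterization: "constant" (piecewise
#'   constant, the default) or "linear" (piecewise-linear refinement, which
#'   represents within-interval control variation at coarse meshes).
#' @param control solver options for [solve_ipnlp()].
#' @return object of class `sprint_tracking`: list with the `ocp_solution`
#'   (`sol`), RMSD summaries (`rmsd`), the preprocessed experiment, model and
#'   the control layout.
#' @export
run_tracking <- function(exp, model = NULL, N = 50, cutoff = NULL,
                         weights = c(0.1, 0.05, 0.01, 0.01, 0.001, 1e-4, 0.1),
                         control_rep = "constant", control = list()) {
  if (is.null(model)) {
    model <- if (!is.null(exp$meta$model)) exp$meta$model else default_model(mass = exp$mass)
  }
  if (!identical(colnames(exp$q), model$dof_names)) {
    stop("experiment and model disagree on DOF naming")
  }
  if (is.null(cutoff)) {
    cutoff <- if (!is.null(exp$meta$noise)) 20 else NA
  }
  pe <- if (is.null(exp$q_fun)) preprocess(exp, cutoff = cutoff) else exp
  ocp <- build_tracking_ocp(pe, model, N = N, weights = weights,
                            control_rep = control_rep)
  # warm-started problem: begin with a small barrier parameter
  control <- utils::modifyList(list(mu_init = 1e-5, kappa_eps = 100), control)
  sol <- solve_ocp(ocp, control = control)
  out <- structure(list(sol = sol, exp = pe, model = model,
                        layout = control_layout(model),
                        weights = weights),
                   class = "sprint_tracking")
  out$rmsd <- tracking_rmsd(out)
  out
}

#' RMSD summary of a tracking solution
#'
#' Per-coordinate RMSD of angles (deg) and translations (cm), and per-foot
#' per-component GRF RMSD in body weights, evaluated on the collocation grid
#' against the tracked experimental splines over the whole horizon.
#'
#' @param tr a `sprint_tracking`.
#' @return list with `q_deg`, `translations_cm`, `grf_bw`, `tau_nm`.
#' @export
tracking_rmsd <- function(tr) {
  sol <- tr$sol; pe <- tr$exp; model <- tr$model
  nd <- model$ndof
  g <- solution_grid(sol)
  tt <- pe$time[1] + g$t
  qexp <- pe$q_fun(tt)
  q_deg <- vapply(3:nd, function(j) rmsd(g$X[, j], qexp[, j]), numeric(1)) * 180 / pi
  names(q_deg) <- model$dof_names[3:nd]
  tr_cm <- vapply(1:2, function(j) rmsd(g$X[, j], qexp[, j]), numeric(1)) * 100
  names(tr_cm) <- model$dof_names[1:2]
  cg <- contact_grf(model, g$X[, seq_len(nd)], g$X[, nd + seq_len(nd)])
  gexp <- pe$grf_fun(tt)
  bw <- tr$exp$mass * model$gravity
  grf_bw <- c(
    r_ap = rmsd(cg$right[, "ap"], gexp[, "r_ap"]),
    r_vertical = rmsd(cg$right[, "vertical"], gexp[, "r_vertical"]),
    l_ap = rmsd(cg$left[, "ap"], gexp[, "l_ap"]),
    l_vertical = rmsd(cg$left[, "vertical"], gexp[, "l_vertical"])
  ) / bw
  # net moments at interval starts (piecewise-constant controls)
  lay <- sol$layout
  cl <- tr$layout
  tau_sim <- sol$U[seq_len(lay$N), cl$i_act, drop = FALSE] +
    sol$U[seq_len(lay$N), cl$i_res, drop = FALSE]
  t0s <- pe$time[1] + (seq_len(lay$N) - 1) / lay$N *
    (pe$time[length(pe$time)] - pe$time[1])
  tau_exp <- pe$tau_fun(t0s)
  tau_nm <- vapply(seq_len(ncol(tau_sim)), function(j) rmsd(tau_sim[, j], tau_exp[, j]),
                   numeric(1))
  names(tau_nm) <- model$internal_dofs
  list(q_deg = q_deg, translations_cm = tr_cm, grf_bw = grf_bw, tau_nm = tau_nm)
}

#' @export
print.sprint_tracking <- function(x, ...) {
  cat("<sprint_tracking> status:", x$sol$status, "objective:",
      format(x$sol$objective), "\n")
  cat("  max angle RMSD:", format(max(x$rmsd$q_deg), digits = 3), "deg;",
      "max translation RMSD:", format(max(x$rmsd$translations_cm), digits = 3), "cm\n")
  cat("  GRF RMSD (BW):", paste(names(x$rmsd$grf_bw),
                                format(x$rmsd$grf_bw, digits = 2), collapse = ", "), "\n")
  invisible(x)
}
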