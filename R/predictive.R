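# Predictive simulations: free chosen net joint moments, track the rest
# against the data-tracking solution, and minimize the time horizon subject
# to the boundary conditions that keep the motion a continuable sprint step.

#' Build a tracked/freed moment mask
#'
#' Returns a binary vector over the model's internal DOFs with ones at the
#' net joint moments that remain tracked and zeros at the moments freed by
#' the named configuration: `A` frees the ankle plantarflexor-dorsiflexor
#' moments, `K` the knee and `H` the hip flexor-extensor moments, always for
#' both legs. Letter orderings are accepted as aliases (`K-H-free` and
#' `H-K-free` are the same configuration); `"none"`/`"all-tracked"` frees
#' nothing.
#'
#' @param config configuration name, e.g. `"K-free"` or `"A-K-H-free"`.
#' @param model a `sprint_model`.
#' @return named integer vector (1 = tracked, 0 = freed) of class
#'   `moment_mask` with the canonical configuration name as attribute.
#' @export
build_mask <- function(config, model) {
  mask <- stats::setNames(rep(1L, length(model$internal_dofs)),
                          model$internal_dofs)
  canon <- toupper(gsub("[- ]?free$", "", config, ignore.case = TRUE))
  letters_free <- sort(strsplit(gsub("-", "", canon), "")[[1]])
  if (config %in% c("none", "all-tracked") || canon == "NONE") {
    letters_free <- character(0)
  } else if (!all(letters_free %in% c("A", "K", "H")) || length(letters_free) == 0) {
    stop("unknown predictive configuration: ", config)
  }
  joint_of <- c(A = "q_foot", K = "q_shank", H = "q_thigh")
  for (l in letters_free) {
    hit <- grep(paste0("^", joint_of[[l]], "_"), names(mask))
    if (length(hit) == 0) stop("model has no DOFs for moment group ", l)
    mask[hit] <- 0L
  }
  canonical <- if (length(letters_free) == 0) "all-tracked" else {
    paste0(paste(sort(letters_free), collapse = "-"), "-free")
  }
  structure(mask, class = "moment_mask", config = canonical)
}

# net-moment series of a tracking solution at interval starts, plus a
# normalized-time interpolant (stretch-to-fit mapping onto the predictive
# horizon)
tracking_moment_reference <- function(tr) {
  cl <- tr$layout
  lay <- tr$sol$layout
  n_nodes <- nrow(tr$sol$U)
  tau <- tr$sol$U[, cl$i_act, drop = FALSE] + tr$sol$U[, cl$i_res, drop = FALSE]
  tnorm <- (seq_len(n_nodes) - 1) / lay$N
  rng <- apply(tau, 2, function(x) max(diff(range(x)), 1e-3))
  fun <- colwise_splines(tnorm, tau)
  list(fun = fun, range = rng, tau = tau, tnorm = tnorm)
}

#' Build a predictive optimal control problem
#'
#' Frees the net joint moments named by `config`, tracks the remaining
#' internal moments against the data-tracking solution (normalized by 2% of
#' each moment's tracking range, mapped onto the predictive horizon in
#' normalized time), minimizes the free time horizon, and enforces the
#' boundary constraints: the initial multibody state equals the tracking
#' solution's, the terminal pelvis anterior-posterior translation equals the
#' tracking value, and the terminal relative joint angles stay within +/- 10
#' degrees of the tracking values. The horizon is bounded in
#' `[0.95, 1] * tf_track` by default, and all other bounds and the initial
#' guess come from the tracking problem and its solution.
#'
#' @param tr a solved `sprint_tracking`.
#' @param config predictive configuration name (see [build_mask()]).
#' @param weights the six predictive weights `W1..W6` (time, moment
#'   tracking, effort, reserves, accelerations, muscle rates).
#' @param tf_bounds horizon bounds as fractions of the tracking horizon.
#' @param terminal_window half-width of the terminal joint-angle window
#'   (rad).
#' @param control_rep control parameterization.
#' @param N mesh intervals (default: the tracking solution's mesh; a smaller
#'   value gives a reduced-mesh predictive problem warm-started by
#'   interpolation).
#' @return an `ocp_def`.
#' @export
build_predictive_ocp <- function(tr, config,
                                 weights = c(50, 0.1, 0.01, 1, 1e-4, 0.1),
                                 tf_bounds = c(0.95, 1),
                                 terminal_window = 10 * pi / 180,
                                 control_rep = "constant", N = NULL) {
  model <- tr$model
  pe <- tr$exp
  cl <- tr$layout
  lay <- tr$sol$layout
  nd <- model$ndof
  nx <- 2 * nd
  if (is.null(N)) N <- lay$N
  d <- lay$d
  tf_track <- tr$sol$tf
  mask <- build_mask(config, model)
  ref <- tracking_moment_reference(tr)
  bg <- tracking_bounds_and_guess(pe, model)
  norms <- normalization_spec(pe, model)

  # guesses from the tracking solution on normalized time
  gsol <- solution_grid(tr$sol)
  xfun <- colwise_splines(gsol$t / tf_track, gsol$X)
  U_tr <- tr$sol$U
  N_tr <- lay$N
  u_guess <- function(tnorm) {
    ci <- min(nrow(U_tr), max(1L, 1L + floor(tnorm * N_tr + 1e-9)))
    U_tr[ci, ]
  }

  A <- matrix(0, nx, nx); A[seq_len(nd), nd + seq_len(nd)] <- diag(nd)
  B <- matrix(0, nx, cl$nu); B[nd + seq_len(nd), cl$i_vdot] <- diag(nd)

  x0 <- gsol$X[1, ]
  x_fix <- lapply(seq_len(nx), function(j) list(i = 1, k = 0, dof = j, value = x0[j]))
  xT <- gsol$X[nrow(gsol$X), ]
  x_fix <- c(x_fix, list(list(i = N, k = d, dof = 1, value = xT[1])))
  x_window <- lapply(3L + seq_len(cl$ni), function(j) {
    list(i = N, k = d, dof = j, lb = xT[j] - terminal_window,
         ub = xT[j] + terminal_window)
  })

  W <- weights
  i_tracked <- which(mask == 1L)
  objective <- function(layout) {
    terms <- list(obj_term_mayer_tf(layout, W[1], name = "time"))
    if (length(i_tracked) > 0) {
      C <- matrix(0, length(i_tracked), cl$nu)
      for (r in seq_along(i_tracked)) {
        C[r, cl$i_act[i_tracked[r]]] <- 1
        C[r, cl$i_res[i_tracked[r]]] <- 1
      }
      terms <- c(terms, list(
        obj_term_controls(layout, C, weight = W[2],
                          target = function(tn) ref$fun(tn)[, i_tracked, drop = FALSE],
                          norm = 0.02 * ref$range[i_tracked],
                          name = "track_tau")))
    }
    C_res <- matrix(0, cl$ni, cl$nu)
    C_res[cbind(seq_len(cl$ni), cl$i_res)] <- 1
    C_vd <- matrix(0, nd, cl$nu)
    C_vd[cbind(seq_len(nd), cl$i_vdot)] <- 1
    c(terms, list(
      obj_term_controls(layout, C_res, weight = W[4], target = 0,
                        norm = norms$res, name = "control_res"),
      obj_term_controls(layout, C_vd, weight = W[5], target = 0,
                        norm = norms$vdot, name = "control_vdot")
    ))
  }

  tf_arg <- if (abs(tf_bounds[2] - tf_bounds[1]) < 1e-12) {
    tf_bounds[1] * tf_track
  } else {
    list(lower = tf_bounds[1] * tf_track, upper = tf_bounds[2] * tf_track,
         guess = tf_bounds[2] * tf_track)
  }
  define_ocp(
    nx = nx, nu = cl$nu, N = N, d = d, tf = tf_arg,
    linear_dyn = list(A = A, B = B),
    path = sprint_path_fun(model), npath = nd + 2 * cl$nsph,
    path_scale = c(rep(200, 3), rep(100, nd - 3), rep(500, 2 * cl$nsph)),
    x_lb = bg$x_lb, x_ub = bg$x_ub, u_lb = bg$u_lb, u_ub = bg$u_ub,
    x_guess = function(tn) xfun(tn), u_guess = u_guess,
    objective = objective, x_fix = x_fix, x_window = x_window,
    control_rep = control_rep
  )
}

# warm-start closures from a previous solution on normalized time
guess_from_solution <- function(sol) {
  g <- solution_grid(sol)
  xfun <- colwise_splines(g$t / sol$tf, g$X)
  U <- sol$U
  N <- sol$layout$N
  list(
    x_guess = function(tn) xfun(tn),
    u_guess = function(tn) U[min(nrow(U), max(1L, 1L + floor(tn * N + 1e-9))), ]
  )
}

#' Run one predictive simulation
#'
#' The free time horizon is handled by parametric continuation: the problem
#' is solved on a descending grid of fixed horizon durations spanning the
#' admissible interval (each solve warm-started from the previous one), the
#' smooth objective-versus-horizon curve is refined with one parabolic step,
#' and the best solution is returned. This keeps every inner problem on the
#' well-conditioned fixed-horizon path while still optimizing the horizon to
#' the solver tolerance.
#'
#' @inheritParams build_predictive_ocp
#' @param n_grid number of horizon grid points spanning `tf_bounds`.
#' @param control solver options.
#' @return object of class `sprint_predictive`: the `ocp_solution` plus the
#'   moment mask, configuration name, the horizon profile (`tf_profile`) and
#'   the source tracking object.
#' @export
run_predictive <- function(tr, config,
                           weights = c(50, 0.1, 0.01, 1, 1e-4, 0.1),
                           tf_bounds = c(0.95, 1),
                           control_rep = "constant", N = NULL,
                           n_grid = 3, control = list()) {
  control <- utils::modifyList(list(mu_init = 1e-5, kappa_eps = 100,
                                    max_iter = 60), control)
  tf_track <- tr$sol$tf
  solve_at <- function(frac, guess) {
    ocp <- build_predictive_ocp(tr, config, weights = weights,
                                tf_bounds = c(frac, frac),
                                control_rep = control_rep, N = N)
    if (!is.null(guess)) {
      ocp$x_guess <- guess$x_guess
      ocp$u_guess <- guess$u_guess
    }
    solve_ocp(ocp, control = control)
  }
  if (abs(tf_bounds[2] - tf_bounds[1]) < 1e-12) {
    sol <- solve_at(tf_bounds[1], NULL)
    profile <- data.frame(frac = tf_bounds[1], objective = sol$objective,
                          status = sol$status)
  } else {
    fracs <- seq(tf_bounds[2], tf_bounds[1], length.out = max(2, n_grid))
    sols <- vector("list", length(fracs))
    guess <- NULL
    for (i in seq_along(fracs)) {
      sols[[i]] <- solve_at(fracs[i], guess)
      if (sols[[i]]$status != "failed") guess <- guess_from_solution(sols[[i]])
    }
    objs <- vapply(sols, function(s) s$objective, numeric(1))
    # parabolic refinement around the best grid point (interior minima only)
    ib <- which.min(objs)
    if (ib > 1 && ib < length(fracs)) {
      xs <- fracs[(ib - 1):(ib + 1)]; ys <- objs[(ib - 1):(ib + 1)]
      den <- (xs[1] - xs[2]) * (xs[1] - xs[3]) * (xs[2] - xs[3])
      aq <- (xs[3] * (ys[2] - ys[1]) + xs[2] * (ys[1] - ys[3]) + xs[1] * (ys[3] - ys[2])) / den
      bq <- (xs[3]^2 * (ys[1] - ys[2]) + xs[2]^2 * (ys[3] - ys[1]) + xs[1]^2 * (ys[2] - ys[3])) / den
      if (aq > 0) {
        fr <- max(tf_bounds[1], min(tf_bounds[2], -bq / (2 * aq)))
        if (min(abs(fr - fracs)) > 1e-4) {
          s2 <- solve_at(fr, guess_from_solution(sols[[ib]]))
          if (s2$status != "failed" && s2$objective < objs[ib]) {
            sols <- c(sols, list(s2)); fracs <- c(fracs, fr)
            objs <- c(objs, s2$objective)
          }
        }
      }
    }
    ib <- which.min(objs)
    sol <- sols[[ib]]
    profile <- data.frame(frac = fracs, objective = objs,
                          status = vapply(sols, function(s) s$status, character(1)))
  }
  structure(list(sol = sol, config = attr(build_mask(config, tr$model), "config"),
                 mask = build_mask(config, tr$model), tracking = tr,
                 model = tr$model, layout = tr$layout, tf_profile = profile),
            class = "sprint_predictive")
}

#' @export
print.sprint_predictive <- function(x, ...) {
  cat("<sprint_predictive>", x$config, " status:", x$sol$status,
      " tf:", format(x$sol$tf), "s  objective:", format(x$sol$objective), "\n")
  invisible(x)
}

#' Run the full suite of predictive simulations
#'
#' The seven free-moment configurations of the study: each of the ankle, knee
#' and hip moment groups freed individually, the three pairs, and all three
#' together. Individual failures are recorded and the suite continues.
#'
#' @param tr a solved `sprint_tracking`.
#' @param configs configuration names (default: all seven).
#' @param ... passed to [run_predictive()].
#' @return list of class `sprint_suite`: `runs` (named list of
#'   `sprint_predictive` or error condition), `tracking`.
#' @export
run_suite <- function(tr, configs = c("A-free", "K-free", "H-free",
                                      "A-K-free", "A-H-free", "K-H-free",
                                      "A-K-H-free"),
                      ...) {
  runs <- list()
  for (cf in configs) {
    runs[[cf]] <- tryCatch(run_predictive(tr, cf, ...), error = function(e) e)
  }
  names(runs) <- configs
  structure(list(runs = runs, tracking = tr), class = "sprint_suite")
}

#' @export
print.sprint_suite <- function(x, ...) {
  cat("<sprint_suite>", length(x$runs), "predictive runs\n")
  for (nm in names(x$runs)) {
    r <- x$runs[[nm]]
    if (inherits(r, "sprint_predictive")) {
      cat(" ", nm, ": status", r$sol$status, " tf", format(r$sol$tf), "\n")
    } else {
      cat(" ", nm, ": ERROR", conditionMessage(r), "\n")
    }
  }
  invisible(x)
}
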