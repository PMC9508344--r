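# Flipped-LGR direct collocation transcription.
#
# States are parameterized within each mesh interval by Lagrange polynomials
# on the interval start plus the d flipped LGR points; first-order dynamics
# are enforced at the LGR points, algebraic path constraints at the beginning
# of each mesh interval, and explicit state continuity constraints join
# consecutive intervals. Controls are piecewise constant, parameterized at
# interval starts (a piecewise-linear refinement is available). A free final
# time is handled by transcribing on normalized time [0, 1] with the horizon
# duration as an extra, bounded decision variable multiplying the dynamics
# and the quadrature. All variables are affinely scaled to [-1, 1] from their
# bounds before the NLP is handed to the interior-point solver.

#' Define an optimal control problem for collocation
#'
#' @param nx,nu state and control dimensions.
#' @param N number of mesh intervals.
#' @param d collocation order (default 3: third-order state polynomials, four
#'   points per interval).
#' @param tf fixed horizon duration, or a list `list(lower, upper, guess)`
#'   for a free final time.
#' @param linear_dyn optional list `list(A, B)` declaring the linear explicit
#'   dynamics `xdot = A x + B u` (used analytically); otherwise supply `dyn`.
#' @param dyn function(X, U, t) returning the explicit right-hand side for a
#'   batch of rows (matrix in, matrix out).
#' @param path optional function(X, U, t) of interval-start states/controls
#'   returning a matrix of path-constraint values (one row per point).
#' @param npath number of path constraint rows per point.
#' @param path_lb,path_ub bounds per path row (equal entries give equality
#'   constraints; otherwise a bounded slack is attached).
#' @param path_scale characteristic magnitude per path row used for
#'   constraint scaling.
#' @param path_terminal also enforce path constraints at the final grid
#'   point (default FALSE: beginnings of mesh intervals only).
#' @param x_lb,x_ub,u_lb,u_ub variable bounds (vectors of length nx / nu).
#' @param x_guess function(t) returning a matrix of state guesses (rows =
#'   time points), or a constant vector.
#' @param u_guess function(t) or constant vector for control guesses.
#' @param objective function(layout) returning a list of objective terms
#'   built with [obj_term_states()] / [obj_term_controls()] /
#'   [obj_term_mayer_tf()], or such a list directly.
#' @param x_fix list of fixes `list(i, k, dof, value)` pinning a state at a
#'   node (used for boundary equality constraints).
#' @param x_window list of overrides `list(i, k, dof, lb, ub)` tightening a
#'   state bound at a node (used for terminal windows).
#' @param control_rep "constant" (default) or "linear" control
#'   parameterization.
#' @return an object of class `ocp_def`.
#' @export
define_ocp <- function(nx, nu, N, d = 3, tf,
                       linear_dyn = NULL, dyn = NULL,
                       path = NULL, npath = 0, path_lb = NULL, path_ub = NULL,
                       path_scale = NULL, path_terminal = FALSE,
                       x_lb, x_ub, u_lb, u_ub,
                       x_guess = NULL, u_guess = NULL,
                       objective = list(),
                       x_fix = list(), x_window = list(),
                       control_rep = c("constant", "linear")) {
  control_rep <- match.arg(control_rep)
  if (any(x_ub < x_lb) || any(u_ub < u_lb)) stop("infeasible bounds (lower > upper)")
  free_tf <- is.list(tf)
  if (free_tf) {
    stopifnot(tf$lower <= tf$upper)
    if (tf$upper - tf$lower < 1e-12) { tf <- tf$lower; free_tf <- FALSE }
  }
  if (npath > 0) {
    if (is.null(path_lb)) path_lb <- rep(0, npath)
    if (is.null(path_ub)) path_ub <- rep(0, npath)
    if (is.null(path_scale)) path_scale <- rep(1, npath)
  }
  structure(list(nx = nx, nu = nu, N = N, d = d, tf = tf, free_tf = free_tf,
                 linear_dyn = linear_dyn, dyn = dyn,
                 path = path, npath = npath, path_lb = path_lb,
                 path_ub = path_ub, path_scale = path_scale,
                 path_terminal = path_terminal,
                 x_lb = x_lb, x_ub = x_ub, u_lb = u_lb, u_ub = u_ub,
                 x_guess = x_guess, u_guess = u_guess, objective = objective,
                 x_fix = x_fix, x_window = x_window,
                 control_rep = control_rep),
            class = "ocp_def")
}

#' Decision-variable layout of a transcribed OCP
#'
#' @param ocp an `ocp_def`.
#' @return list describing the variable layout: index arrays `ix` (N x (d+1)
#'   x nx), `iu` (control nodes x nu), `itf`, node times, quadrature weights
#'   and differentiation matrix.
#' @export
ocp_layout <- function(ocp) {
  N <- ocp$N; d <- ocp$d; nx <- ocp$nx; nu <- ocp$nu
  lg <- lgr_nodes(d)
  nodes <- c(0, lg$nodes)
  D <- lagrange_differentiation(nodes)
  n_state <- N * (d + 1) * nx
  ix <- array(seq_len(n_state), dim = c(nx, d + 1, N))
  ix <- aperm(ix, c(3, 2, 1)) # [i, k+1, dof]
  n_cnodes <- if (ocp$control_rep == "linear") N + 1 else N
  iu <- matrix(n_state + seq_len(n_cnodes * nu), nrow = n_cnodes, byrow = TRUE)
  nz_core <- n_state + n_cnodes * nu
  itf <- if (ocp$free_tf) nz_core + 1L else NA_integer_
  nz_core <- nz_core + as.integer(ocp$free_tf)
  tf_ref <- if (ocp$free_tf) ocp$tf$upper else ocp$tf
  # normalized node times (fraction of horizon)
  tau_grid <- outer(seq_len(N) - 1, nodes, function(i, tk) (i + tk) / N)
  list(N = N, d = d, nx = nx, nu = nu, nodes = nodes, D = D,
       qweights = lg$weights, ix = ix, iu = iu, itf = itf,
       nz_core = nz_core, free_tf = ocp$free_tf, tf_ref = tf_ref,
       control_rep = ocp$control_rep, n_cnodes = n_cnodes,
       tau_grid = tau_grid)
}

# control value indices and interpolation coefficients at node (i, k)
control_coef <- function(layout, i, k) {
  if (layout$control_rep == "constant") {
    list(nodes = i, coef = 1)
  } else {
    tk <- layout$nodes[k + 1]
    if (tk == 0) list(nodes = i, coef = 1)
    else list(nodes = c(i, i + 1), coef = c(1 - tk, tk))
  }
}

#' Quadratic objective term over state trajectories
#'
#' Builds the quadrature approximation of
#' `weight * sum_dofs int ((target - x_dof)/norm)^2 dt` using the LGR weights
#' of each mesh interval.
#'
#' @param layout an [ocp_layout()].
#' @param dofs state indices entering the term.
#' @param weight scalar weight.
#' @param target function(t) returning a matrix (rows = times, cols = dofs)
#'   of tracked values, or a constant (default 0).
#' @param norm normalizing divisor per dof (default 1).
#' @param name term label for the objective breakdown.
#' @return objective term (list) consumed by [transcribe()].
#' @export
obj_term_states <- function(layout, dofs, weight, target = 0, norm = 1,
                            name = "states") {
  norm <- rep(norm, length.out = length(dofs))
  nrows <- layout$N * layout$d * length(dofs)
  ii <- integer(nrows); jj <- integer(nrows); vv <- numeric(nrows)
  b <- numeric(nrows); W <- numeric(nrows)
  r <- 0L
  for (i in seq_len(layout$N)) for (k in seq_len(layout$d)) {
    tnorm <- layout$tau_grid[i, k + 1]
    tg <- if (is.function(target)) target(tnorm) else
      matrix(target, 1, length(dofs))
    for (jd in seq_along(dofs)) {
      r <- r + 1L
      ii[r] <- r; jj[r] <- layout$ix[i, k + 1, dofs[jd]]
      vv[r] <- 1 / norm[jd]
      b[r] <- tg[1, jd] / norm[jd]
      W[r] <- layout$qweights[k] * weight / layout$N
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(nrows, layout$nz_core))
  list(name = name, A = A, b = b, W = W)
}

#' Quadratic objective term over linear combinations of controls
#'
#' As [obj_term_states()] but the tracked signals are `C %*% u` for a
#' coefficient matrix `C` (one row per signal); covers plain control
#' penalties (`C` rows picking single controls) as well as summed signals
#' such as per-foot ground reaction forces or net moments assembled from
#' several actuators.
#'
#' @inheritParams obj_term_states
#' @param C numeric matrix (nsignal x nu).
#' @export
obj_term_controls <- function(layout, C, weight, target = 0, norm = 1,
                              name = "controls") {
  C <- as.matrix(C)
  nsig <- nrow(C)
  norm <- rep(norm, length.out = nsig)
  nrows_max <- layout$N * layout$d * nsig * (2 + (layout$control_rep == "linear"))
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  b <- numeric(layout$N * layout$d * nsig); W <- b
  r <- 0L
  for (i in seq_len(layout$N)) for (k in seq_len(layout$d)) {
    tnorm <- layout$tau_grid[i, k + 1]
    tg <- if (is.function(target)) target(tnorm) else matrix(target, 1, nsig)
    cc <- control_coef(layout, i, k)
    for (s in seq_len(nsig)) {
      r <- r + 1L
      nzc <- which(C[s, ] != 0)
      for (cn in seq_along(cc$nodes)) {
        ii <- c(ii, rep(r, length(nzc)))
        jj <- c(jj, layout$iu[cc$nodes[cn], nzc])
        vv <- c(vv, cc$coef[cn] * C[s, nzc] / norm[s])
      }
      b[r] <- tg[1, s] / norm[s]
      W[r] <- layout$qweights[k] * weight / layout$N
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(r, layout$nz_core))
  list(name = name, A = A, b = b[seq_len(r)], W = W[seq_len(r)])
}

#' Mayer term on the (free) final time
#'
#' @param layout an [ocp_layout()].
#' @param weight coefficient of `tf` in the objective.
#' @param name term label.
#' @export
obj_term_mayer_tf <- function(layout, weight, name = "time") {
  list(name = name, mayer_tf = weight)
}
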