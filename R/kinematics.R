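# Vectorized planar forward kinematics over time samples.
#
# All batch routines take T x ndof matrices (one row per time sample) and
# return T x nseg matrices per quantity. Scalars states may be passed as
# 1-row matrices via as_state_matrix().

as_state_matrix <- function(x, ndof) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ndof) stop("state dimension mismatch: expected ", ndof, " DOFs")
  x
}

#' Forward kinematics for a batch of states
#'
#' Computes global segment angles, joint-origin and centre-of-mass positions
#' (and, when velocities/accelerations are supplied, their time derivatives)
#' for every segment at every time sample.
#'
#' @param model a `sprint_model`.
#' @param Q T x ndof matrix of generalized coordinates (or a vector for one
#'   sample).
#' @param V,A optional matching matrices of velocities and accelerations.
#' @return list of T x nseg matrices: `phi`, `px`, `py`, `cx`, `cy` and, when
#'   requested, `omega`, `vx`, `vy`, `cvx`, `cvy`, `alpha`, `ax`, `ay`,
#'   `cax`, `cay`.
#' @export
forward_kinematics <- function(model, Q, V = NULL, A = NULL) {
  Q <- as_state_matrix(Q, model$ndof)
  if (!is.null(V)) V <- as_state_matrix(V, model$ndof)
  if (!is.null(A)) A <- as_state_matrix(A, model$ndof)
  n <- nrow(Q)
  ns <- model$nseg
  sg <- model$segments
  zeros <- function() matrix(0, n, ns)
  phi <- zeros(); px <- zeros(); py <- zeros(); cx <- zeros(); cy <- zeros()
  out <- list()
  do_v <- !is.null(V); do_a <- !is.null(A)
  if (do_v) { omega <- zeros(); vx <- zeros(); vy <- zeros(); cvx <- zeros(); cvy <- zeros() }
  if (do_a) { alpha <- zeros(); ax <- zeros(); ay <- zeros(); cax <- zeros(); cay <- zeros() }
  for (i in seq_len(ns)) {
    if (i == 1L) {
      phi[, 1] <- Q[, 3]
      px[, 1] <- Q[, 1]; py[, 1] <- Q[, 2]
      if (do_v) { omega[, 1] <- V[, 3]; vx[, 1] <- V[, 1]; vy[, 1] <- V[, 2] }
      if (do_a) { alpha[, 1] <- A[, 3]; ax[, 1] <- A[, 1]; ay[, 1] <- A[, 2] }
    } else {
      p <- model$parent_idx[i]
      d <- model$seg_dof[i]
      phi[, i] <- phi[, p] + Q[, d]
      cp <- cos(phi[, p]); sp <- sin(phi[, p])
      rx <- cp * sg$jx[i] - sp * sg$jy[i]
      ry <- sp * sg$jx[i] + cp * sg$jy[i]
      px[, i] <- px[, p] + rx
      py[, i] <- py[, p] + ry
      if (do_v) {
        omega[, i] <- omega[, p] + V[, d]
        vx[, i] <- vx[, p] - omega[, p] * ry
        vy[, i] <- vy[, p] + omega[, p] * rx
      }
      if (do_a) {
        alpha[, i] <- alpha[, p] + A[, d]
        ax[, i] <- ax[, p] - alpha[, p] * ry - omega[, p]^2 * rx
        ay[, i] <- ay[, p] + alpha[, p] * rx - omega[, p]^2 * ry
      }
    }
    ci <- cos(phi[, i]); si <- sin(phi[, i])
    ox <- ci * sg$cx[i] - si * sg$cy[i]
    oy <- si * sg$cx[i] + ci * sg$cy[i]
    cx[, i] <- px[, i] + ox
    cy[, i] <- py[, i] + oy
    if (do_v) {
      cvx[, i] <- vx[, i] - omega[, i] * oy
      cvy[, i] <- vy[, i] + omega[, i] * ox
    }
    if (do_a) {
      cax[, i] <- ax[, i] - alpha[, i] * oy - omega[, i]^2 * ox
      cay[, i] <- ay[, i] + alpha[, i] * ox - omega[, i]^2 * oy
    }
  }
  out <- list(phi = phi, px = px, py = py, cx = cx, cy = cy)
  if (do_v) out <- c(out, list(omega = omega, vx = vx, vy = vy, cvx = cvx, cvy = cvy))
  if (do_a) out <- c(out, list(alpha = alpha, ax = ax, ay = ay, cax = cax, cay = cay))
  out
}

#' Whole-body centre-of-mass state
#'
#' Mass-weighted average of the segment CoM positions (and velocities when
#' `V` is supplied).
#'
#' @inheritParams forward_kinematics
#' @return list with T-vectors `x`, `y` and, when `V` is given, `vx`, `vy`.
#' @export
com_state <- function(model, Q, V = NULL) {
  fk <- forward_kinematics(model, Q, V)
  m <- model$segments$mass
  mt <- sum(m)
  out <- list(
    x = drop(fk$cx %*% m) / mt,
    y = drop(fk$cy %*% m) / mt
  )
  if (!is.null(V)) {
    out$vx <- drop(fk$cvx %*% m) / mt
    out$vy <- drop(fk$cvy %*% m) / mt
  }
  out
}

#' Contact sphere kinematics
#'
#' World positions and (optionally) velocities of every contact sphere centre.
#'
#' @inheritParams forward_kinematics
#' @param fk optionally a precomputed [forward_kinematics()] result.
#' @return list of T x nsphere matrices `x`, `y` (and `vx`, `vy`).
#' @export
sphere_kinematics <- function(model, Q, V = NULL, fk = NULL) {
  if (is.null(model$spheres)) stop("model has no contact spheres")
  if (is.null(fk)) fk <- forward_kinematics(model, Q, V)
  sp <- model$spheres
  nsph <- nrow(sp)
  n <- nrow(fk$phi)
  X <- matrix(0, n, nsph); Y <- X
  do_v <- !is.null(V) || !is.null(fk$omega)
  if (do_v) { VX <- X; VY <- X }
  for (s in seq_len(nsph)) {
    i <- sp$seg[s]
    ci <- cos(fk$phi[, i]); si <- sin(fk$phi[, i])
    ox <- ci * sp$x[s] - si * sp$y[s]
    oy <- si * sp$x[s] + ci * sp$y[s]
    X[, s] <- fk$px[, i] + ox
    Y[, s] <- fk$py[, i] + oy
    if (do_v) {
      VX[, s] <- fk$vx[, i] - fk$omega[, i] * oy
      VY[, s] <- fk$vy[, i] + fk$omega[, i] * ox
    }
  }
  out <- list(x = X, y = Y)
  if (do_v) { out$vx <- VX; out$vy <- VY }
  out
}

#' Mechanical energy of a batch of states
#'
#' Kinetic plus gravitational potential energy; used for conservation checks
#' of ballistic (flight-phase) trajectories.
#'
#' @inheritParams forward_kinematics
#' @return T-vector of total mechanical energy in joules.
#' @export
mechanical_energy <- function(model, Q, V) {
  fk <- forward_kinematics(model, Q, V)
  m <- model$segments$mass
  I <- model$segments$inertia
  ke <- 0.5 * drop((fk$cvx^2 + fk$cvy^2) %*% m) + 0.5 * drop(fk$omega^2 %*% I)
  pe <- model$gravity * drop(fk$cy %*% m)
  ke + pe
}
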