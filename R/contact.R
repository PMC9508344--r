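# Smooth Hunt-Crossley foot-ground contact, MTP springs and aerodynamic drag.

# Numerically safe softplus positive part with scale s:
# s * log(1 + exp(x / s)), tending to max(x, 0) as s -> 0.
softplus <- function(x, s) {
  z <- x / s
  s * (pmax(z, 0) + log1p(exp(-abs(z))))
}

# Smooth Hunt-Crossley law for one sphere: penetration delta = radius - y,
# normal force k * softplus(delta)^(3/2) * clamp(1 + d * ddot), with the
# dissipation bracket smoothly clamped to be non-negative, and a tanh-smoothed
# Coulomb friction force opposing slip.
hc_sphere_force <- function(y, vx, vy, radius, stiffness, dissipation,
                            friction, v_smooth, delta_smooth) {
  delta <- radius - y
  dhat <- softplus(delta, delta_smooth)
  bracket <- softplus(1 + dissipation * (-vy), 0.05)
  fn <- stiffness * dhat^1.5 * bracket
  ft <- -friction * fn * tanh(vx / v_smooth)
  list(fn = fn, ft = ft)
}

#' Contact model ground reaction forces
#'
#' Evaluates the smooth Hunt-Crossley contact law at every sphere for a batch
#' of states and sums the planar force components per foot. The normal force
#' is `k * delta_hat^(3/2) * (1 + d * delta_dot)` with `delta_hat` a softplus
#' positive part of the penetration and the dissipation bracket smoothly
#' clamped at zero; the tangential force is `-mu * Fn * tanh(v_slip /
#' v_smooth)`. Forces vanish smoothly as the sphere separates from the ground.
#'
#' @param model a `sprint_model` with contact spheres.
#' @param Q,V coordinate and velocity matrices (T x ndof) or vectors for a
#'   single state.
#' @return list with `per_sphere` (data.frame/list of T x nsphere matrices
#'   `fx`, `fy` -- for a single state, vectors), `right` and `left` (T x 2
#'   matrices of summed anterior-posterior and vertical GRF per foot), and
#'   `total`.
#' @export
contact_grf <- function(model, Q, V) {
  single <- is.null(dim(Q))
  Q <- as_state_matrix(Q, model$ndof)
  V <- as_state_matrix(V, model$ndof)
  sk <- sphere_kinematics(model, Q, V)
  sp <- model$spheres
  n <- nrow(Q)
  FX <- matrix(0, n, nrow(sp)); FY <- FX
  for (s in seq_len(nrow(sp))) {
    f <- hc_sphere_force(sk$y[, s], sk$vx[, s], sk$vy[, s],
                         sp$radius[s], sp$stiffness[s], sp$dissipation[s],
                         sp$friction[s], sp$v_smooth[s], sp$delta_smooth[s])
    FX[, s] <- f$ft
    FY[, s] <- f$fn
  }
  colnames(FX) <- colnames(FY) <- sp$name
  ir <- which(sp$foot == "right"); il <- which(sp$foot == "left")
  sumf <- function(M, idx) if (length(idx)) rowSums(M[, idx, drop = FALSE]) else numeric(n)
  right <- cbind(ap = sumf(FX, ir), vertical = sumf(FY, ir))
  left <- cbind(ap = sumf(FX, il), vertical = sumf(FY, il))
  out <- list(per_sphere = list(fx = FX, fy = FY),
              right = right, left = left,
              total = right + left)
  if (single) {
    out$per_sphere <- list(fx = drop(FX), fy = drop(FY))
    out$right <- drop(right); out$left <- drop(left); out$total <- drop(out$total)
  }
  out
}

#' Linear MTP rotational spring moment
#'
#' Passive moment of the rotational spring representing the sprinting spike
#' and forefoot structures at a metatarsophalangeal joint:
#' `-k * (q - neutral)`.
#'
#' @param q_mtp MTP joint angle(s) in radians.
#' @param k spring stiffness in Nm/rad.
#' @param neutral neutral (zero-moment) angle in radians.
#' @return moment(s) in Nm.
#' @export
mtp_spring_moment <- function(q_mtp, k, neutral = 0) {
  -k * (q_mtp - neutral)
}

#' Aerodynamic drag force
#'
#' Horizontal drag opposing the centre-of-mass motion,
#' `F = -0.5 * rho * Cd * Af * vx * |vx|`, applied at the whole-body CoM.
#'
#' @param vx horizontal CoM velocity (m/s), vectorized.
#' @param params list with `rho` (air density, kg/m^3), `cd` (drag
#'   coefficient) and `area` (frontal area, m^2).
#' @return drag force(s) in newtons (negative when moving forward).
#' @export
aerodynamic_drag <- function(vx, params) {
  if (any(unlist(params[c("rho", "cd", "area")]) <= 0)) {
    stop("drag parameters must be positive")
  }
  -0.5 * params$rho * params$cd * params$area * vx * abs(vx)
}
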