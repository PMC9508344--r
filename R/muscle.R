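# Hill-type muscle-tendon units: characteristic curves, polynomial geometry,
# implicit (tendon-force-state) contraction dynamics and activation-rate
# constraints.

#' Hill model characteristic curves
#'
#' Returns the parameter set for the tendon force-length, active and passive
#' fibre force-length, and fibre force-velocity curves. Defaults follow the
#' widely used exponential-tendon / Gaussian-sum parameterization for
#' muscle-driven trajectory optimization; the active force-length and
#' force-velocity curves are rescaled so that they equal exactly 1 at optimal
#' fibre length and zero fibre velocity. All coefficients can be overridden.
#'
#' @param tendon list with `c1`, `c2`, `c3`, `kT` for
#'   `fT(lt) = c1 * exp(kT * (lt - c2)) - c3`.
#' @param active 3 x 4 matrix of Gaussian coefficients (rows b1..b3).
#' @param velocity length-4 vector `d` for
#'   `fv(v) = d1 * log(d2 * v + d3 + sqrt((d2 * v + d3)^2 + 1)) + d4`.
#' @param passive list with `kpe` and `e0` for the exponential passive curve.
#' @return object of class `hill_curves`.
#' @export
hill_curves <- function(tendon = list(c1 = 0.200, c2 = 0.995, c3 = 0.250, kT = 35),
                        active = rbind(c(0.815, 1.055, 0.162, 0.0633),
                                       c(0.433, 0.717, -0.0299, 0.200),
                                       c(0.100, 1.000, 0.354, 0.000)),
                        velocity = c(-0.318, -8.149, -0.374, 0.886),
                        passive = list(kpe = 4.0, e0 = 0.6)) {
  cur <- structure(list(tendon = tendon, active = active, velocity = velocity,
                        passive = passive, act_scale = 1, vel_scale = 1),
                   class = "hill_curves")
  cur$act_scale <- 1 / active_fl(1, cur)
  cur$vel_scale <- 1 / force_velocity(0, cur)
  cur
}

# tendon force-length: normalized tendon force as a function of normalized
# tendon length (zero at/below the effective slack length by construction of
# its use range; the exponential law crosses zero at lt = c2 + log(c3/c1)/kT).
tendon_fl <- function(lt_norm, curves) {
  with(curves$tendon, c1 * exp(kT * (lt_norm - c2)) - c3)
}

# inverse of tendon_fl: normalized tendon length from normalized tendon force
tendon_fl_inverse <- function(ft_norm, curves) {
  with(curves$tendon, c2 + log((ft_norm + c3) / c1) / kT)
}

active_fl <- function(lm_norm, curves) {
  b <- curves$active
  f <- 0
  for (r in seq_len(nrow(b))) {
    f <- f + b[r, 1] * exp(-0.5 * (lm_norm - b[r, 2])^2 / (b[r, 3] + b[r, 4] * lm_norm)^2)
  }
  f * curves$act_scale
}

force_velocity <- function(vm_norm, curves) {
  d <- curves$velocity
  z <- d[2] * vm_norm + d[3]
  (d[1] * log(z + sqrt(z^2 + 1)) + d[4]) * curves$vel_scale
}

passive_fl <- function(lm_norm, curves) {
  with(curves$passive, (exp(kpe * (lm_norm - 1) / e0) - 1) / (exp(kpe) - 1))
}

#' Define a muscle-tendon unit
#'
#' @param name MTU name.
#' @param dofs character vector of spanned DOF names.
#' @param fmax maximal isometric force (N).
#' @param lmo optimal fibre length (m).
#' @param lts tendon slack length (m).
#' @param penn_opt pennation angle at optimal fibre length (rad), in
#'   `[0, pi/2)`.
#' @param vmax maximal contraction velocity (optimal fibre lengths per
#'   second).
#' @param poly list (one element per spanned DOF) of polynomial coefficients
#'   in ascending powers; MTU length is `const + sum_j poly_j(q_j)` so the
#'   moment arm about DOF j is `-poly_j'(q_j)`.
#' @param const constant term of the length polynomial (m).
#' @param qrange optional 2-column matrix of per-DOF validity ranges (rad).
#' @return object of class `mtu_params`.
#' @export
mtu_params <- function(name, dofs, fmax, lmo, lts, penn_opt = 0, vmax = 10,
                       poly, const, qrange = NULL) {
  stopifnot(fmax > 0, lmo > 0, lts > 0, penn_opt >= 0, penn_opt < pi / 2,
            length(poly) == length(dofs))
  structure(list(name = name, dofs = dofs, fmax = fmax, lmo = lmo, lts = lts,
                 penn_opt = penn_opt, vmax = vmax, poly = poly, const = const,
                 qrange = qrange), class = "mtu_params")
}

polyval_asc <- function(coef, x) {
  out <- 0
  for (k in rev(seq_along(coef))) out <- out * x + coef[k]
  out
}

polyder_asc <- function(coef) {
  if (length(coef) <= 1L) return(0)
  coef[-1] * seq_len(length(coef) - 1L)
}

#' Musculotendon geometry from polynomial length functions
#'
#' Evaluates the MTU length, lengthening velocity, and moment arms at a
#' configuration. Lengths are additive per-DOF polynomials; the moment arm
#' about a spanned DOF is minus the partial derivative of length with respect
#' to that coordinate, and the lengthening velocity is the chain-rule sum.
#' Configurations outside the declared validity range trigger a warning and
#' polynomial extrapolation.
#'
#' @param q named numeric vector of coordinates covering the spanned DOFs.
#' @param v optional named velocities (defaults to zeros).
#' @param params an `mtu_params`.
#' @return list with `length` (m), `velocity` (m/s) and `moment_arms` (named,
#'   m).
#' @export
mtu_geometry <- function(q, params, v = NULL) {
  qd <- q[params$dofs]
  if (anyNA(qd)) stop("q must be named and cover the spanned DOFs")
  if (!is.null(params$qrange)) {
    lo <- params$qrange[, 1]; hi <- params$qrange[, 2]
    if (any(qd < lo | qd > hi)) {
      warning("coordinate outside MTU geometry validity range for ", params$name,
              "; extrapolating")
    }
  }
  len <- params$const
  arms <- stats::setNames(numeric(length(params$dofs)), params$dofs)
  vel <- 0
  for (j in seq_along(params$dofs)) {
    cf <- params$poly[[j]]
    len <- len + polyval_asc(cf, qd[j])
    dl <- polyval_asc(polyder_asc(cf), qd[j])
    arms[j] <- -dl
    if (!is.null(v)) vel <- vel + dl * v[params$dofs[j]]
  }
  list(length = unname(len), velocity = unname(vel), moment_arms = arms)
}

#' Implicit Hill equilibrium residual
#'
#' Residual of the tendon-force-state contraction dynamics,
#' `FT_tilde - cos(theta) * (a * f_act(lm) * f_v(vm) + f_pass(lm))`, where the
#' fibre length follows from subtracting the tendon length (obtained by
#' inverting the tendon curve at the current normalized tendon force) from the
#' musculotendon length, under a constant-thickness pennation model. The
#' fibre velocity is derived from the musculotendon lengthening velocity and
#' the tendon force rate control `u_ftdot`.
#'
#' @param q,v named coordinates and velocities over the spanned DOFs.
#' @param ft_tilde normalized tendon force (state).
#' @param a activation in `[0, 1]` (state).
#' @param params an `mtu_params`.
#' @param curves a `hill_curves`.
#' @param u_ftdot time derivative of the normalized tendon force (control),
#'   default 0.
#' @return scalar residual (dimensionless force); zero at dynamic
#'   equilibrium.
#' @export
hill_equilibrium_residual <- function(q, v, ft_tilde, a, params, curves,
                                      u_ftdot = 0) {
  geo <- mtu_geometry(q, params, v)
  lt <- params$lts * tendon_fl_inverse(ft_tilde, curves)
  h <- params$lmo * sin(params$penn_opt)
  proj <- geo$length - lt
  lm <- sqrt(h^2 + proj^2)
  if (proj <= 0 || lm <= 0) stop("non-positive fibre length for ", params$name)
  cos_th <- proj / lm
  # tendon lengthening rate from the force-rate control via the tendon curve
  dlt_dft <- params$lts / (curves$tendon$kT * (ft_tilde + curves$tendon$c3))
  vt <- dlt_dft * u_ftdot
  vm <- (geo$velocity - vt) * cos_th
  lm_norm <- lm / params$lmo
  vm_norm <- vm / (params$vmax * params$lmo)
  fce <- a * active_fl(lm_norm, curves) * force_velocity(vm_norm, curves)
  fpe <- passive_fl(lm_norm, curves)
  unname(ft_tilde - cos_th * (fce + fpe))
}

#' Activation-rate feasibility constraints
#'
#' The first-order activation dynamics are imposed as two inequality
#' constraints on the activation-rate control: `u_adot + a / tau_d >= 0`
#' (deactivation cannot be faster than the deactivation time constant allows)
#' and `u_adot + a / tau_a <= 1 / tau_a` (activation cannot exceed the rate
#' towards full excitation).
#'
#' @param a activation(s) in `[0, 1]`.
#' @param u_adot activation-rate control(s) (1/s).
#' @param tau_a activation time constant (s), default 0.015.
#' @param tau_d deactivation time constant (s), default 0.060.
#' @return list with `g_lower` (feasible iff `>= 0`) and `g_upper` (feasible
#'   iff `<= 0`).
#' @export
activation_rate_constraints <- function(a, u_adot, tau_a = 0.015, tau_d = 0.060) {
  stopifnot(tau_a > 0, tau_d > 0)
  list(g_lower = u_adot + a / tau_d,
       g_upper = u_adot + a / tau_a - 1 / tau_a)
}

#' Net joint moment contribution of a set of muscles
#'
#' Moment on DOF j is the sum over muscles of
#' `FT_tilde_i * Fmax_i * moment_arm_ij`.
#'
#' @param q named coordinate vector.
#' @param ft_tilde numeric vector of normalized tendon forces, one per MTU.
#' @param params_list list of `mtu_params`.
#' @param dof_names DOF names over which to report moments.
#' @return named moment vector (Nm).
#' @export
muscle_moments <- function(q, ft_tilde, params_list, dof_names) {
  out <- stats::setNames(numeric(length(dof_names)), dof_names)
  for (i in seq_along(params_list)) {
    p <- params_list[[i]]
    geo <- mtu_geometry(q, p)
    for (d in p$dofs) {
      if (d %in% dof_names) out[d] <- out[d] + ft_tilde[i] * p$fmax * geo$moment_arms[d]
    }
  }
  out
}

#' Default planar leg muscle set
#'
#' Eight MTUs per leg (iliopsoas, glutei, biarticular hamstrings, rectus
#' femoris, vasti, gastrocnemius, soleus, tibialis anterior) with
#' literature-scale isometric strengths and constant-dominant moment-arm
#' polynomials; intended for unit-level exercises and small muscle-driven
#' problems on the default planar model.
#'
#' @param side `"r"` or `"l"`.
#' @return list of `mtu_params`.
#' @export
default_leg_muscles <- function(side = "r") {
  hip <- paste0("q_thigh_", side); knee <- paste0("q_shank_", side)
  ank <- paste0("q_foot_", side)
  mk <- function(name, dofs, fmax, lmo, lts, arms, penn = 0.1) {
    # arms: moment arm (m) per dof; length poly = -arm * q  (constant arm)
    mtu_params(paste0(name, "_", side), dofs, fmax, lmo, lts, penn_opt = penn,
               poly = lapply(arms, function(r) c(0, -r)),
               const = lts + lmo * cos(penn) + 0.02)
  }
  list(
    mk("iliopsoas", hip, 2342, 0.117, 0.115, arms = list(0.035)),
    mk("glutei", hip, 1944, 0.157, 0.100, arms = list(-0.055)),
    mk("hamstrings", c(hip, knee), 2594, 0.100, 0.330, arms = list(-0.060, -0.030)),
    mk("rectfem", c(hip, knee), 1169, 0.076, 0.346, arms = list(0.040, 0.045)),
    mk("vasti", knee, 5000, 0.095, 0.160, arms = list(0.042)),
    mk("gastroc", c(knee, ank), 1558, 0.059, 0.390, arms = list(-0.015, -0.050)),
    mk("soleus", ank, 3549, 0.044, 0.280, arms = list(-0.048), penn = 0.44),
    mk("tibant", ank, 905, 0.068, 0.240, arms = list(0.035))
  )
}
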