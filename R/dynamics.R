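# Batch inverse dynamics and the implicit equation-of-motion residual.
#
# The skeletal path constraint is
#   M(q) u_vdot + C(q, v) + G(q) - J_Ext' Ext(grf, drag) - [0; tau] = 0,
# one row per DOF, with zeros at the three unactuated base rows. Everything
# below is vectorized across time samples; generalized forces are assembled by
# the virtual-work (Jacobian) method, which for a planar tree reduces to dot
# products with lever arms about each joint.

# Generalized force Q(q, v, a) = M a + C + G required to realize accelerations
# `A` under gravity (no externals). T x ndof matrix.
inverse_dynamics_batch <- function(model, Q, V, A, gravity = model$gravity) {
  Q <- as_state_matrix(Q, model$ndof)
  V <- as_state_matrix(V, model$ndof)
  A <- as_state_matrix(A, model$ndof)
  fk <- forward_kinematics(model, Q, V, A)
  m <- model$segments$mass
  I <- model$segments$inertia
  n <- nrow(Q)
  out <- matrix(0, n, model$ndof)
  colnames(out) <- model$dof_names
  # base translations: Newton for the total system
  out[, 1] <- drop(fk$cax %*% m)
  out[, 2] <- drop((fk$cay + gravity) %*% m)
  # angle rows: lever arms about the DOF's joint origin
  for (j in 3:model$ndof) {
    segs <- model$subtree[[j]]
    ajx <- if (j == 3L) fk$px[, 1] else fk$px[, model$seg_of_dof[j]]
    ajy <- if (j == 3L) fk$py[, 1] else fk$py[, model$seg_of_dof[j]]
    acc <- 0
    for (i in segs) {
      acc <- acc +
        m[i] * (-(fk$cy[, i] - ajy) * fk$cax[, i] +
                  (fk$cx[, i] - ajx) * (fk$cay[, i] + gravity)) +
        I[i] * fk$alpha[, i]
    }
    out[, j] <- acc
  }
  out
}

# Generalized forces of external point forces applied at the contact sphere
# centres (per-sphere force components FX, FY: T x nsphere) and of the
# aerodynamic drag force (T-vector, horizontal, acting at the whole-body CoM
# carried by the base segment). T x ndof matrix.
external_generalized_forces <- function(model, Q, V = NULL, FX = NULL, FY = NULL,
                                        drag_fx = NULL, fk = NULL) {
  Q <- as_state_matrix(Q, model$ndof)
  if (is.null(fk)) fk <- forward_kinematics(model, Q, V)
  n <- nrow(Q)
  out <- matrix(0, n, model$ndof)
  colnames(out) <- model$dof_names
  if (!is.null(FX)) {
    sk <- sphere_kinematics(model, Q, fk = fk)
    sp <- model$spheres
    out[, 1] <- out[, 1] + rowSums(FX)
    out[, 2] <- out[, 2] + rowSums(FY)
    for (s in seq_len(nrow(sp))) {
      iseg <- sp$seg[s]
      for (j in model$path[[iseg]]) {
        ajx <- if (j == 3L) fk$px[, 1] else fk$px[, model$seg_of_dof[j]]
        ajy <- if (j == 3L) fk$py[, 1] else fk$py[, model$seg_of_dof[j]]
        out[, j] <- out[, j] -
          (sk$y[, s] - ajy) * FX[, s] + (sk$x[, s] - ajx) * FY[, s]
      }
    }
  }
  if (!is.null(drag_fx)) {
    cm <- com_state(model, Q)
    out[, 1] <- out[, 1] + drag_fx
    # attached to the base segment at the instantaneous CoM location
    out[, 3] <- out[, 3] - (cm$y - fk$py[, 1]) * drag_fx
  }
  out
}

# Residual of the implicit skeletal dynamics, batch form.
# TAU: T x n_internal matrix of net joint moments (internal DOFs, in
# model$internal_dofs order). FX/FY per-sphere applied GRF controls.
eom_residual_batch <- function(model, Q, V, U_vdot, TAU = NULL,
                               FX = NULL, FY = NULL, drag_fx = NULL) {
  Q <- as_state_matrix(Q, model$ndof)
  res <- inverse_dynamics_batch(model, Q, V, U_vdot)
  res <- res - external_generalized_forces(model, Q, V, FX, FY, drag_fx)
  if (!is.null(TAU)) {
    if (is.null(dim(TAU))) TAU <- matrix(TAU, nrow = 1)
    res[, -(1:3)] <- res[, -(1:3)] - TAU
  }
  if (!is.null(model$mtp)) {
    for (dn in model$mtp$dofs) {
      j <- match(dn, model$dof_names)
      res[, j] <- res[, j] - mtp_spring_moment(Q[, j], model$mtp$stiffness,
                                               model$mtp$neutral)
    }
  }
  res
}

#' Implicit equation-of-motion residual
#'
#' Evaluates the skeletal path constraint
#' `M(q) u_vdot + C(q,v) + G(q) - J_Ext' Ext(grf, drag) - [0; tau]` for a
#' single state. A zero vector indicates the supplied accelerations, applied
#' moments and external forces are dynamically consistent. The residual is
#' smooth in all arguments and exactly linear in `u_vdot`, `tau` and `grf`.
#'
#' @param model a `sprint_model`.
#' @param q,v generalized coordinates and velocities (length ndof).
#' @param u_vdot generalized accelerations (length ndof).
#' @param tau net joint moments over internal DOFs (length ndof - 3), or NULL.
#' @param grf per-sphere applied force matrix (nsphere x 2, columns fx, fy),
#'   or NULL for no contact forces.
#' @param drag horizontal drag force in newtons (scalar), or NULL.
#' @return numeric vector, one entry per DOF (N for translations, Nm for
#'   rotations).
#' @export
eom_residual <- function(model, q, v, u_vdot, tau = NULL, grf = NULL, drag = NULL) {
  if (length(q) != model$ndof || length(v) != model$ndof || length(u_vdot) != model$ndof) {
    stop("q, v and u_vdot must have length ", model$ndof)
  }
  if (!is.null(tau) && length(tau) != model$ndof - 3L) {
    stop("tau must have length ", model$ndof - 3L)
  }
  if (anyNA(c(q, v, u_vdot, tau, grf, drag))) stop("NaN/NA in inputs")
  FX <- FY <- NULL
  if (!is.null(grf)) {
    grf <- matrix(grf, ncol = 2)
    if (nrow(grf) != nrow(model$spheres)) stop("grf must have one row per contact sphere")
    FX <- matrix(grf[, 1], 1); FY <- matrix(grf[, 2], 1)
  }
  drop(eom_residual_batch(model, q, v, u_vdot,
                          TAU = if (is.null(tau)) NULL else matrix(tau, 1),
                          FX = FX, FY = FY,
                          drag_fx = if (is.null(drag)) NULL else drag))
}

#' Joint-space mass matrix, bias forces and gravity vector
#'
#' Extracted column-by-column from inverse dynamics; used by the forward
#' dynamics helper and by equivalence tests against a Lagrangian derivation.
#'
#' @param model a `sprint_model`.
#' @param q coordinates (length ndof).
#' @return `mass_matrix`: ndof x ndof matrix. `bias_forces`: the
#'   velocity-dependent vector C(q, v). `gravity_forces`: G(q).
#' @export
mass_matrix <- function(model, q) {
  nd <- model$ndof
  M <- matrix(0, nd, nd)
  for (k in seq_len(nd)) {
    e <- numeric(nd); e[k] <- 1
    M[, k] <- inverse_dynamics_batch(model, q, numeric(nd), e, gravity = 0)
  }
  (M + t(M)) / 2
}

#' @rdname mass_matrix
#' @param v velocities (length ndof).
#' @export
bias_forces <- function(model, q, v) {
  drop(inverse_dynamics_batch(model, q, v, numeric(model$ndof), gravity = 0))
}

#' @rdname mass_matrix
#' @export
gravity_forces <- function(model, q) {
  drop(inverse_dynamics_batch(model, q, numeric(model$ndof), numeric(model$ndof)))
}

#' Forward dynamics
#'
#' Solves the equation of motion for the generalized accelerations given net
#' joint moments and (optionally) contact/drag forces evaluated from the
#' current state.
#'
#' @inheritParams eom_residual
#' @param contact logical; evaluate the contact model and apply its forces.
#' @param drag logical; apply aerodynamic drag.
#' @return acceleration vector (length ndof).
#' @export
forward_dynamics <- function(model, q, v, tau = NULL, contact = FALSE, drag = FALSE) {
  nd <- model$ndof
  rhs <- -bias_forces(model, q, v) - gravity_forces(model, q)
  if (!is.null(tau)) rhs[-(1:3)] <- rhs[-(1:3)] + tau
  if (contact && !is.null(model$spheres)) {
    cg <- contact_grf(model, q, v)
    rhs <- rhs + drop(external_generalized_forces(model, q, v,
                                                  FX = matrix(cg$per_sphere$fx, 1),
                                                  FY = matrix(cg$per_sphere$fy, 1)))
  }
  if (drag) {
    cm <- com_state(model, q, v)
    fd <- aerodynamic_drag(cm$vx, model$drag)
    rhs <- rhs + drop(external_generalized_forces(model, q, drag_fx = fd))
  }
  if (!is.null(model$mtp)) {
    for (dn in model$mtp$dofs) {
      j <- match(dn, model$dof_names)
      rhs[j] <- rhs[j] + mtp_spring_moment(q[j], model$mtp$stiffness, model$mtp$neutral)
    }
  }
  drop(solve(mass_matrix(model, q), rhs))
}
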