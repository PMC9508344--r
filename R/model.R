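#' Construct a planar musculoskeletal model specification
#'
#' Builds the rigid-segment tree used throughout the package: a floating base
#' (the pelvis, with anterior-posterior and vertical translations plus a
#' rotation) and a chain of revolute joints, together with the environment
#' force elements (smooth Hunt-Crossley contact spheres, optional linear MTP
#' rotational springs, aerodynamic drag applied at the whole-body centre of
#' mass) and an actuator map declaring how each internal degree of freedom is
#' driven (net-moment torque actuator, muscles, plus a bounded reserve).
#'
#' Conventions: +x is the direction of travel, +y is up, angles are
#' counter-clockwise positive in radians; a segment's global angle is the sum
#' of the base rotation and the relative joint angles on its path, with zero
#' corresponding to the upright neutral pose. Clockwise (negative) thigh and
#' trunk angles therefore correspond to extension and forward inclination.
#' All units are SI.
#'
#' @param segments data.frame with columns `name`, `parent` (empty string for
#'   the root), `jx`, `jy` (joint location in the parent frame), `mass`,
#'   `inertia` (about own CoM), `cx`, `cy` (CoM in own frame, relative to the
#'   proximal joint).
#' @param spheres data.frame of contact spheres: `name`, `segment`, `x`, `y`
#'   (centre in the segment frame), `radius`, `stiffness` (N/m^1.5),
#'   `dissipation` (s/m), `friction`, `v_smooth` (m/s), `delta_smooth` (m),
#'   `foot` ("right"/"left").
#' @param drag list with `rho` (kg/m^3), `cd`, `area` (m^2).
#' @param gravity gravitational acceleration magnitude (m/s^2).
#' @param actuators list with `torque_bound` and `reserve_bound`: named numeric
#'   vectors (Nm) over internal DOFs; optionally `muscle_dofs`.
#' @param mtp optional list with `dofs` (character), `stiffness` (Nm/rad) and
#'   `neutral` (rad) describing linear rotational springs at MTP joints.
#' @return an object of class `sprint_model`.
#' @export
model_spec <- function(segments, spheres = NULL, drag = list(rho = 1.225, cd = 0.9, area = 0.45),
                       gravity = 9.81, actuators = NULL, mtp = NULL) {
  stopifnot(is.data.frame(segments))
  need <- c("name", "parent", "jx", "jy", "mass", "inertia", "cx", "cy")
  if (!all(need %in% names(segments))) {
    stop("segments must have columns: ", paste(need, collapse = ", "))
  }
  if (any(segments$mass <= 0)) stop("segment masses must be > 0")
  if (any(segments$inertia <= 0)) stop("segment inertias must be > 0")
  root <- which(segments$parent == "")
  if (length(root) != 1L || root != 1L) stop("exactly one root segment, listed first")
  parent_idx <- match(segments$parent, segments$name)
  if (any(is.na(parent_idx[-1]))) stop("unknown parent segment")
  if (any(parent_idx[-1] >= seq_along(parent_idx)[-1])) {
    stop("segments must be listed parents-first")
  }
  nseg <- nrow(segments)
  dof_names <- c("pelvis_tx", "pelvis_ty", "pelvis_rot",
                 if (nseg > 1) paste0("q_", segments$name[-1]))
  ndof <- length(dof_names)
  # angle DOF column for each segment (root -> pelvis_rot)
  seg_dof <- c(3L, if (nseg > 1) 3L + seq_len(nseg - 1L))
  # path of angle DOFs from root to each segment (inclusive)
  path <- vector("list", nseg)
  for (i in seq_len(nseg)) {
    path[[i]] <- if (i == 1L) 3L else c(path[[parent_idx[i]]], seg_dof[i])
  }
  # for each angle DOF: the segments it moves (subtree of its segment)
  seg_of_dof <- match(seq_len(ndof), seg_dof) # segment whose joint is this dof
  subtree <- vector("list", ndof)
  for (j in 3:ndof) {
    s <- seg_of_dof[j]
    subtree[[j]] <- which(vapply(path, function(p) j %in% p, logical(1)))
  }
  if (!is.null(spheres)) {
    stopifnot(is.data.frame(spheres))
    if (any(is.na(match(spheres$segment, segments$name)))) {
      stop("contact sphere references unknown segment")
    }
    if (any(spheres$radius <= 0) || any(spheres$stiffness <= 0) ||
        any(spheres$dissipation < 0) || any(spheres$v_smooth <= 0) ||
        any(spheres$delta_smooth <= 0)) {
      stop("invalid contact sphere parameters")
    }
    spheres$seg <- match(spheres$segment, segments$name)
  }
  if (any(unlist(drag[c("rho", "cd", "area")]) <= 0)) stop("drag parameters must be > 0")
  internal <- dof_names[-(1:3)]
  if (is.null(actuators)) {
    actuators <- list(
      torque_bound = stats::setNames(rep(3000, length(internal)), internal),
      reserve_bound = stats::setNames(rep(10, length(internal)), internal),
      muscle_dofs = character(0)
    )
  }
  if (!is.null(mtp)) {
    if (!all(mtp$dofs %in% internal)) stop("mtp dofs must be internal DOFs")
    actuators$reserve_bound[mtp$dofs] <- 40
  }
  structure(list(
    segments = segments, nseg = nseg, parent_idx = parent_idx,
    dof_names = dof_names, ndof = ndof, seg_dof = seg_dof, path = path,
    seg_of_dof = seg_of_dof, subtree = subtree,
    spheres = spheres, drag = drag, gravity = gravity,
    actuators = actuators, mtp = mtp,
    internal_dofs = internal
  ), class = "sprint_model")
}

#' @export
print.sprint_model <- function(x, ...) {
  cat("<sprint_model>", x$nseg, "segments,", x$ndof, "DOFs (",
      paste(x$dof_names, collapse = ", "), ")\n")
  cat("  total mass:", sum(x$segments$mass), "kg;",
      if (is.null(x$spheres)) 0 else nrow(x$spheres), "contact spheres\n")
  invisible(x)
}

#' Default planar two-legged sprint model
#'
#' Eleven-DOF sagittal model: pelvis floating base, lumbar joint to a lumped
#' trunk+head segment, a shoulder-mounted arm-swing segment (both upper limbs
#' lumped into one planar rotator, which provides the angular-momentum
#' exchange that arms give a sprinter), and hip/knee/ankle per leg, with a
#' heel sphere and a metatarsal sphere pair under each foot. Anthropometry is
#' scaled to a 72.2 kg sprinter.
#'
#' @param mass total body mass in kg (segment masses are scaled
#'   proportionally).
#' @param contact list overriding contact defaults (`stiffness`, `dissipation`,
#'   `friction`, `v_smooth`, `delta_smooth`, `radius`).
#' @return a `sprint_model`.
#' @export
default_model <- function(mass = 72.2, contact = list()) {
  segs <- data.frame(
    name    = c("pelvis", "trunk", "arms", "thigh_r", "shank_r", "foot_r",
                "thigh_l", "shank_l", "foot_l"),
    parent  = c("", "pelvis", "trunk", "pelvis", "thigh_r", "shank_r",
                "pelvis", "thigh_l", "shank_l"),
    jx      = c(0, 0, 0, 0, 0, 0, 0, 0, 0),
    jy      = c(0, 0.10, 0.42, -0.06, -0.47, -0.46, -0.06, -0.47, -0.46),
    mass    = c(8.2, 27.0, 7.0, 10.1, 3.9, 1.0, 10.1, 3.9, 1.0),
    inertia = c(0.035, 1.10, 1.20, 0.160, 0.055, 0.005, 0.160, 0.055, 0.005),
    cx      = c(0, 0, 0, 0, 0, 0.06, 0, 0, 0.06),
    cy      = c(0, 0.26, -0.35, -0.20, -0.20, -0.05, -0.20, -0.20, -0.05),
    stringsAsFactors = FALSE
  )
  scl <- mass / sum(segs$mass)
  segs$mass <- segs$mass * scl
  segs$inertia <- segs$inertia * scl
  cpar <- utils::modifyList(list(
    stiffness = 3e6, dissipation = 2, friction = 0.8,
    v_smooth = 0.15, delta_smooth = 1e-4, radius = 0.03
  ), contact)
  # the forefoot carries a pair of half-stiffness spheres at the metatarsal
  # heads (coincident in the sagittal plane), which shares the high forefoot
  # loads across two force controls
  sph <- do.call(rbind, lapply(c("r", "l"), function(side) {
    data.frame(
      name = paste0(c("heel_", "toe_med_", "toe_lat_"), side),
      segment = paste0("foot_", side),
      x = c(-0.04, 0.175, 0.175), y = c(-0.07, -0.07, -0.07),
      radius = cpar$radius,
      stiffness = cpar$stiffness * c(1, 0.5, 0.5),
      dissipation = cpar$dissipation, friction = cpar$friction,
      v_smooth = cpar$v_smooth, delta_smooth = cpar$delta_smooth,
      foot = if (side == "r") "right" else "left",
      stringsAsFactors = FALSE
    )
  }))
  model_spec(segs, spheres = sph)
}

#' Read a model specification from a YAML configuration file
#'
#' The schema mirrors the arguments of [model_spec()]: top-level keys
#' `segments` (list of per-segment maps), `spheres`, `drag`, `gravity`,
#' `actuators` and `mtp`. All quantities are SI.
#'
#' @param path path to a YAML file.
#' @return a `sprint_model`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  to_df <- function(lst) do.call(rbind, lapply(lst, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  segs <- to_df(cfg$segments)
  if (is.null(segs$parent)) segs$parent <- ""
  segs$parent[is.na(segs$parent)] <- ""
  sph <- if (!is.null(cfg$spheres)) to_df(cfg$spheres) else NULL
  act <- cfg$actuators
  if (!is.null(act)) {
    act$torque_bound <- unlist(act$torque_bound)
    act$reserve_bound <- unlist(act$reserve_bound)
  }
  model_spec(segs, spheres = sph,
             drag = if (!is.null(cfg$drag)) cfg$drag else list(rho = 1.225, cd = 0.9, area = 0.45),
             gravity = if (!is.null(cfg$gravity)) cfg$gravity else 9.81,
             actuators = act, mtp = cfg$mtp)
}
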