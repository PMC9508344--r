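# Outcome measures: performance, impulses, touchdown/take-off kinematics,
# front-side/back-side classification, and peak net joint moments.

#' Average horizontal external power
#'
#' Rate of change of horizontal kinetic energy between the start and end of a
#' simulation: `(m vf^2 / 2 - m v0^2 / 2) / tf` using horizontal CoM
#' velocities.
#'
#' @param mass body mass (kg).
#' @param v0,vf initial and terminal horizontal CoM velocities (m/s).
#' @param tf elapsed time (s), > 0.
#' @return power in watts.
#' @export
average_horizontal_power <- function(mass, v0, vf, tf) {
  if (tf <= 0) stop("tf must be positive")
  0.5 * mass * (vf^2 - v0^2) / tf
}

#' Horizontal impulses over a stance phase
#'
#' Net, propulsive and braking impulses of the anterior-posterior ground
#' reaction force over a time window, by trapezoidal quadrature of the full
#' signal and of its positive and negative parts.
#'
#' @param grf_ap anterior-posterior GRF series (N).
#' @param time matching time grid (s).
#' @param window `c(t0, t1)` within the series.
#' @return named vector `net`, `propulsive`, `braking` (N s).
#' @export
horizontal_impulses <- function(grf_ap, time, window) {
  sel <- time >= window[1] - 1e-9 & time <= window[2] + 1e-9
  if (sum(sel) < 2) stop("empty impulse window")
  tt <- time[sel]; f <- grf_ap[sel]
  c(net = pracma::trapz(tt, f),
    propulsive = pracma::trapz(tt, pmax(f, 0)),
    braking = pracma::trapz(tt, pmin(f, 0)))
}

#' Detect stance phases from the vertical ground reaction force
#'
#' Maximal runs where the vertical GRF is at or above the threshold;
#' touchdown is the first sample of a run and take-off the last.
#'
#' @param grf_vertical vertical GRF series (N) on a uniform grid.
#' @param time matching time grid (s).
#' @param threshold detection threshold (N), default 20.
#' @return list of windows `c(touchdown, takeoff)` (possibly empty).
#' @export
detect_stance <- function(grf_vertical, time, threshold = 20) {
  on <- grf_vertical >= threshold
  if (!any(on)) return(list())
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (k in which(r$values)) {
    out[[length(out) + 1]] <- c(time[starts[k]], time[ends[k]])
  }
  out
}

# uniform time-series extraction from tracking/predictive results: states on
# the deduplicated collocation grid, contact-model GRF, net moments at
# interval starts
simulation_series <- function(x) {
  if (inherits(x, "sprint_tracking") || inherits(x, "sprint_predictive")) {
    model <- x$model
    cl <- x$layout
    sol <- x$sol
    g <- solution_grid(sol)
    nd <- model$ndof
    Q <- g$X[, seq_len(nd), drop = FALSE]
    V <- g$X[, nd + seq_len(nd), drop = FALSE]
    colnames(Q) <- colnames(V) <- model$dof_names
    cg <- contact_grf(model, Q, V)
    n_nodes <- nrow(sol$U)
    tau <- sol$U[, cl$i_act, drop = FALSE] + sol$U[, cl$i_res, drop = FALSE]
    colnames(tau) <- model$internal_dofs
    mass <- sum(model$segments$mass)
    list(t = g$t, Q = Q, V = V, grf = list(right = cg$right, left = cg$left),
         tau = tau, tau_t = (seq_len(n_nodes) - 1) / sol$layout$N * sol$tf,
         mass = mass, model = model, tf = sol$tf)
  } else if (inherits(x, "sprint_experiment")) {
    v <- if (!is.null(x$v)) x$v else stop("experiment lacks velocities; preprocess() first")
    model <- x$meta$model
    list(t = x$time, Q = x$q, V = v, grf = x$grf,
         tau = x$tau, tau_t = x$time, mass = x$mass, model = model,
         tf = x$time[length(x$time)] - x$time[1])
  } else {
    stop("unsupported simulation object")
  }
}

#' Touchdown kinematics of a stance phase
#'
#' Horizontal velocity of the distal-foot contact-sphere centroid and the
#' horizontal CoM-foot distance (positive when the foot is ahead of the CoM)
#' at the touchdown instant of a stance window.
#'
#' @param x a `sprint_tracking`, `sprint_predictive` or generated
#'   `sprint_experiment`.
#' @param window stance window `c(t_td, t_to)`.
#' @param foot `"right"` or `"left"`.
#' @return named vector `foot_speed` (m/s) and `td_distance` (m).
#' @export
touchdown_metrics <- function(x, window, foot = "right") {
  ss <- simulation_series(x)
  model <- ss$model
  i <- which.min(abs(ss$t - window[1]))
  if (abs(ss$t[i] - window[1]) > 0.05) stop("no stance detected near the window start")
  q <- ss$Q[i, ]; v <- ss$V[i, ]
  sk <- sphere_kinematics(model, q, v)
  idx <- which(model$spheres$foot == foot)
  cx <- mean(sk$x[1, idx]); cvx <- mean(sk$vx[1, idx])
  cm <- com_state(model, q, v)
  c(foot_speed = cvx, td_distance = cx - cm$x)
}

#' Take-off angles of a stance phase
#'
#' Hip flexion-extension and knee flexion angles (relative joint angles, deg;
#' full knee extension is 0 and knee flexion negative, hip flexion positive)
#' and the thigh and trunk segment angles relative to the global vertical
#' (deg; clockwise rotations -- extension and forward inclination -- are
#' negative), evaluated at the take-off instant.
#'
#' @inheritParams touchdown_metrics
#' @return named vector `hip`, `knee`, `thigh`, `trunk` (deg).
#' @export
takeoff_angles <- function(x, window, foot = "right") {
  ss <- simulation_series(x)
  model <- ss$model
  i <- which.min(abs(ss$t - window[2]))
  q <- ss$Q[i, ]
  side <- if (foot == "right") "_r" else "_l"
  hip <- q[paste0("q_thigh", side)]
  knee <- q[paste0("q_shank", side)]
  thigh <- q["pelvis_rot"] + hip
  trunk <- q["pelvis_rot"] + q["q_trunk"]
  out <- c(hip = unname(hip), knee = unname(knee),
           thigh = unname(thigh), trunk = unname(trunk)) * 180 / pi
  out
}

#' Trunk-to-thigh angle and front-side/back-side label
#'
#' The coaching criterion angle `180 + (theta_thigh - theta_trunk)` (deg)
#' between the thigh and the line drawn through the torso: values above 180
#' reflect front-side mechanics, below 180 back-side mechanics, with a
#' neutral band of 180 +/- 1.
#'
#' @param thigh,trunk segment angles from the global vertical (deg, clockwise
#'   negative), each in (-180, 180).
#' @return list with `angle` (deg) and `label` ("front-side", "back-side" or
#'   "neutral").
#' @export
trunk_thigh_angle <- function(thigh, trunk) {
  angle <- unname(180 + (thigh - trunk))
  label <- if (angle > 181) "front-side" else if (angle < 179) "back-side" else "neutral"
  list(angle = angle, label = label)
}

#' Peak net flexor and extensor moments within a stance phase
#'
#' Signed extrema of a net joint moment series within a window, with their
#' timing as a percentage of stance (ties broken by the earliest occurrence).
#'
#' @param tau net joint moment series (Nm).
#' @param time matching time grid (s).
#' @param window stance window `c(t_td, t_to)`.
#' @return named vector `peak_pos`, `peak_neg` (Nm), `t_pos_pct`, `t_neg_pct`
#'   (percent of stance).
#' @export
peak_moments <- function(tau, time, window) {
  sel <- which(time >= window[1] - 1e-9 & time <= window[2] + 1e-9)
  if (length(sel) == 0) stop("empty window")
  tt <- time[sel]; f <- tau[sel]
  ip <- sel[which.max(f)]; im <- sel[which.min(f)]
  pct <- function(i) 100 * (time[i] - window[1]) / (window[2] - window[1])
  c(peak_pos = max(f), peak_neg = min(f),
    t_pos_pct = pct(ip), t_neg_pct = pct(im))
}

# round half away from zero (printing convention for percentages)
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage change between two values
#'
#' `100 (new/old - 1)`, rounded half away from zero to one decimal, the
#' convention used for printed comparisons.
#'
#' @param new,old values to compare; `old` must be nonzero.
#' @param digits decimals to round to (default 1).
#' @return percentage change.
#' @export
percent_change <- function(new, old, digits = 1) {
  if (any(old == 0)) stop("reference value must be nonzero")
  round_half_away(100 * (new / old - 1), digits)
}

#' Outcome report for one simulation
#'
#' Collects every outcome measure for a tracking or predictive result:
#' average horizontal external power, terminal horizontal CoM velocity, time
#' horizon, per-stance impulses and durations, touchdown kinematics, take-off
#' angles with the trunk-to-thigh classification, and per-joint peak net
#' moments during stance.
#'
#' @param x a `sprint_tracking` or `sprint_predictive`.
#' @param threshold stance-detection threshold on the vertical GRF (N).
#' @return list of class `outcome_report`.
#' @export
outcome_report <- function(x, threshold = 20) {
  ss <- simulation_series(x)
  cm <- com_state(ss$model, ss$Q, ss$V)
  n <- length(ss$t)
  power <- average_horizontal_power(ss$mass, cm$vx[1], cm$vx[n], ss$tf)
  keep_real <- function(ws) Filter(function(w) diff(w) >= 0.03, ws)
  stance <- list(
    right = keep_real(detect_stance(ss$grf$right[, "vertical"], ss$t, threshold)),
    left = keep_real(detect_stance(ss$grf$left[, "vertical"], ss$t, threshold))
  )
  per_stance <- list()
  for (ft in c("right", "left")) {
    for (w in stance[[ft]]) {
      key <- ft
      imp <- horizontal_impulses(ss$grf[[ft]][, "ap"], ss$t, w)
      td <- touchdown_metrics(x, w, foot = ft)
      ta <- takeoff_angles(x, w, foot = ft)
      ttl <- trunk_thigh_angle(ta["thigh"], ta["trunk"])
      side <- if (ft == "right") "_r" else "_l"
      taut <- ss$tau_t
      wm <- c(max(w[1], taut[1]), min(w[2], taut[length(taut)]))
      pk <- list(
        hip = peak_moments(ss$tau[, paste0("q_thigh", side)], taut, wm),
        knee = peak_moments(ss$tau[, paste0("q_shank", side)], taut, wm),
        ankle = peak_moments(ss$tau[, paste0("q_foot", side)], taut, wm)
      )
      per_stance[[key]] <- list(window = w, duration = diff(w), impulses = imp,
                                touchdown = td, takeoff = ta,
                                trunk_thigh = ttl, peaks = pk)
    }
  }
  structure(list(
    power = power, v0 = cm$vx[1], v_end = cm$vx[n], tf = ss$tf,
    stance = per_stance,
    config = if (!is.null(x$config)) x$config else "tracking"
  ), class = "outcome_report")
}

#' @export
print.outcome_report <- function(x, ...) {
  cat("<outcome_report>", x$config, "\n")
  cat(sprintf("  average horizontal external power: %.1f W\n", x$power))
  cat(sprintf("  terminal horizontal CoM velocity: %.2f m/s; horizon %.3f s\n",
              x$v_end, x$tf))
  for (nm in names(x$stance)) {
    s <- x$stance[[nm]]
    cat(sprintf("  %s stance %.3f s: net/prop/brake %.1f/%.1f/%.1f Ns; trunk-thigh %.0f deg (%s)\n",
                nm, s$duration, s$impulses["net"], s$impulses["propulsive"],
                s$impulses["braking"], s$trunk_thigh$angle, s$trunk_thigh$label))
  }
  invisible(x)
}

#' Comparison table across a predictive suite
#'
#' Per-simulation outcome summary plus percentage changes relative to the
#' data-tracking simulation. Percentage changes of paired quantities across
#' the two stance phases are reported under both averaging conventions
#' (ratio of averages and average of ratios), which differ when the two
#' stances change by different amounts.
#'
#' @param suite a `sprint_suite`.
#' @param threshold stance-detection threshold (N).
#' @return data.frame, one row per simulation (tracking first).
#' @export
compare_outcomes <- function(suite, threshold = 20) {
  recs <- c(list(tracking = suite$tracking),
            Filter(function(r) inherits(r, "sprint_predictive"), suite$runs))
  reps <- lapply(recs, outcome_report, threshold = threshold)
  base <- reps[[1]]
  row_of <- function(rep) {
    sr <- rep$stance[["right"]]; sl <- rep$stance[["left"]]
    data.frame(
      config = rep$config,
      power_w = rep$power,
      v_end = rep$v_end,
      tf = rep$tf,
      power_change_pct = if (identical(rep, base)) 0 else percent_change(rep$power, base$power),
      stance_r = if (!is.null(sr)) sr$duration else NA,
      stance_l = if (!is.null(sl)) sl$duration else NA,
      net_imp_r = if (!is.null(sr)) sr$impulses["net"] else NA,
      net_imp_l = if (!is.null(sl)) sl$impulses["net"] else NA,
      trunk_thigh_r = if (!is.null(sr)) sr$trunk_thigh$angle else NA,
      trunk_thigh_l = if (!is.null(sl)) sl$trunk_thigh$angle else NA,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(reps, row_of))
  rownames(out) <- NULL
  out
}
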