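# Experiment datasets: containers, preprocessing and basic metrics.

#' Construct an experiment dataset
#'
#' Container for the time series a data-tracking simulation consumes:
#' generalized coordinates, per-foot ground reaction forces and internal net
#' joint moments on a common monotone time grid, plus body mass and stance
#' windows.
#'
#' @param time monotone time grid (s).
#' @param q T x ndof coordinate matrix (columns named by DOF).
#' @param grf list with `right` and `left`, each a T x 2 matrix with columns
#'   `ap` and `vertical` (N).
#' @param tau T x n_internal net joint moment matrix (Nm).
#' @param mass body mass (kg).
#' @param stance list with `right` and `left` stance windows `c(t0, t1)`.
#' @param grf_sphere optional per-sphere force matrices (`fx`, `fy`) used to
#'   warm-start GRF controls.
#' @param meta list of metadata (seed, trial id, sampling rate, generator
#'   diagnostics).
#' @return object of class `sprint_experiment`.
#' @export
sprint_experiment <- function(time, q, grf, tau, mass, stance,
                              grf_sphere = NULL, meta = list()) {
  if (any(diff(time) <= 0)) stop("time grid must be strictly increasing")
  stopifnot(nrow(q) == length(time), nrow(tau) == length(time),
            nrow(grf$right) == length(time), nrow(grf$left) == length(time),
            mass > 0)
  for (s in stance) {
    if (s[1] < time[1] - 1e-9 || s[2] > time[length(time)] + 1e-9) {
      stop("stance window outside the time horizon")
    }
  }
  structure(list(time = time, q = q, grf = grf, tau = tau, mass = mass,
                 stance = stance, grf_sphere = grf_sphere, meta = meta),
            class = "sprint_experiment")
}

#' @export
print.sprint_experiment <- function(x, ...) {
  cat("<sprint_experiment>", length(x$time), "samples over",
      format(x$time[length(x$time)] - x$time[1]), "s;",
      ncol(x$q), "DOFs; mass", x$mass, "kg\n")
  invisible(x)
}

# cubic interpolating splines (FMM end conditions: exact for cubics) per
# column; returns function(t, deriv) -> matrix
colwise_splines <- function(time, M) {
  funs <- lapply(seq_len(ncol(M)), function(j) {
    stats::splinefun(time, M[, j], method = "fmm")
  })
  nm <- colnames(M)
  function(t, deriv = 0) {
    out <- vapply(funs, function(f) f(t, deriv = deriv), numeric(length(t)))
    if (length(t) == 1L) out <- matrix(out, 1)
    colnames(out) <- nm
    out
  }
}

# forward-backward Butterworth low-pass with cut-off correction so the
# effective attenuation order matches `order` (each pass applies order/2).
zero_phase_butter <- function(x, fs, cutoff, order = 4) {
  if (cutoff >= fs / 2) stop("cut-off frequency must be below the Nyquist frequency")
  npass <- 2
  corr <- (2^(1 / npass) - 1)^(-1 / (2 * (order / npass)))
  wc <- min(cutoff * corr / (fs / 2), 0.999)
  bf <- signal::butter(order / npass, wc, type = "low")
  pad <- round(min(length(x) - 1, 3 * fs / cutoff))
  xe <- c(2 * x[1] - rev(x[2:(pad + 1)]), x, 2 * x[length(x)] - rev(x[(length(x) - pad):(length(x) - 1)]))
  y <- signal::filtfilt(bf, xe)
  y[(pad + 1):(pad + length(x))]
}

#' Preprocess an experiment dataset
#'
#' Zero-phase fourth-order Butterworth low-pass filtering (default 20 Hz
#' cut-off) of the kinematics and ground reaction forces, followed by cubic
#' B-spline representations of the filtered kinematics so that coordinates,
#' velocities and accelerations can be evaluated on any time grid.
#'
#' @param exp a `sprint_experiment` on a uniform time grid.
#' @param cutoff low-pass cut-off frequency (Hz), default 20.
#' @param order effective Butterworth order, default 4 (two zero-phase passes
#'   of order 2 with the standard cut-off correction).
#' @return the experiment with filtered series and added spline accessors
#'   `q_fun(t, deriv)`, `grf_fun(t)` (6 columns: right ap/vertical, left
#'   ap/vertical summed per foot), `tau_fun(t)`, plus `v` and `a` matrices on
#'   the sample grid.
#' @export
preprocess <- function(exp, cutoff = 20, order = 4) {
  dt <- diff(exp$time)
  if (max(abs(dt - dt[1])) > 1e-9) stop("preprocess() requires uniform sampling")
  fs <- 1 / dt[1]
  if (is.na(cutoff)) { # spline representation only, no filtering
    qf <- exp$q
    gr <- exp$grf$right
    gl <- exp$grf$left
  } else {
    if (cutoff >= fs / 2) stop("cut-off frequency must be below the Nyquist frequency")
    qf <- apply(exp$q, 2, zero_phase_butter, fs = fs, cutoff = cutoff, order = order)
    colnames(qf) <- colnames(exp$q)
    gr <- apply(exp$grf$right, 2, zero_phase_butter, fs = fs, cutoff = cutoff, order = order)
    gl <- apply(exp$grf$left, 2, zero_phase_butter, fs = fs, cutoff = cutoff, order = order)
  }
  colnames(gr) <- colnames(gl) <- c("ap", "vertical")
  out <- exp
  out$q <- qf
  out$grf <- list(right = gr, left = gl)
  out$q_fun <- colwise_splines(exp$time, qf)
  G <- cbind(gr, gl)
  colnames(G) <- c("r_ap", "r_vertical", "l_ap", "l_vertical")
  out$grf_fun <- colwise_splines(exp$time, G)
  out$tau_fun <- colwise_splines(exp$time, exp$tau)
  out$v <- out$q_fun(exp$time, deriv = 1)
  out$a <- out$q_fun(exp$time, deriv = 2)
  out$meta$preprocessed <- list(cutoff = cutoff, order = order)
  out
}

#' Root-mean-squared difference between two aligned series
#'
#' @param a,b equal-length numeric vectors.
#' @return `sqrt(mean((a - b)^2))` in the series' units.
#' @export
rmsd <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ")
  sqrt(mean((a - b)^2))
}
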