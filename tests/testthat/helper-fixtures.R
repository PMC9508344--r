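# Shared fixtures, generated once per test run.

# three-link serial chain used for Lagrangian-equivalence oracles
chain3_model <- function() {
  segs <- data.frame(
    name = c("s1", "s2", "s3"),
    parent = c("", "s1", "s2"),
    jx = c(0, 0.1, 0.05), jy = c(0, -0.4, -0.35),
    mass = c(5, 3, 2), inertia = c(0.08, 0.05, 0.02),
    cx = c(0.02, 0, 0.01), cy = c(-0.2, -0.18, -0.12),
    stringsAsFactors = FALSE
  )
  model_spec(segs)
}

# pendulum on a (nominally massless) floating base
pendulum_model <- function() {
  segs <- data.frame(
    name = c("base", "rod"), parent = c("", "base"),
    jx = c(0, 0), jy = c(0, 0),
    mass = c(1e-6, 2), inertia = c(1e-9, 2 * 0.5^2 / 12),
    cx = c(0, 0), cy = c(0, -0.25),
    stringsAsFactors = FALSE
  )
  model_spec(segs)
}

# the default synthetic sprint dataset and its tracking solution are shared
# across test files (generation and the solve are deterministic)
synth_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synth_sprint(synth_config(seed = 1))
    cache
  }
})

tracking_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_tracking(synth_fixture(), N = 50, control_rep = "linear")
    }
    cache
  }
})

# finite-difference gravity/Coriolis/mass-matrix oracle from the Lagrangian
lagrangian_oracle <- function(model, q, v) {
  nd <- model$ndof
  KE <- function(vv) {
    mechanical_energy(model, matrix(q, 1), matrix(vv, 1)) -
      mechanical_energy(model, matrix(q, 1), matrix(0 * vv, 1))
  }
  M <- matrix(0, nd, nd)
  for (i in seq_len(nd)) for (j in seq_len(nd)) {
    ei <- numeric(nd); ei[i] <- 1
    ej <- numeric(nd); ej[j] <- 1
    M[i, j] <- KE(ei + ej) - KE(ei) - KE(ej)
  }
  h <- 1e-6
  dM <- array(0, c(nd, nd, nd))
  for (k in seq_len(nd)) {
    qp <- q; qm <- q
    qp[k] <- qp[k] + h; qm[k] <- qm[k] - h
    dM[, , k] <- (mass_matrix_at(model, qp) - mass_matrix_at(model, qm)) / (2 * h)
  }
  C <- numeric(nd)
  for (i in seq_len(nd)) {
    s <- 0
    for (j in seq_len(nd)) for (k in seq_len(nd)) {
      s <- s + 0.5 * (dM[i, j, k] + dM[i, k, j] - dM[j, k, i]) * v[j] * v[k]
    }
    C[i] <- s
  }
  PE <- function(qq) {
    fk <- forward_kinematics(model, matrix(qq, 1))
    model$gravity * drop(fk$cy %*% model$segments$mass)
  }
  G <- numeric(nd)
  for (k in seq_len(nd)) {
    qp <- q; qm <- q
    qp[k] <- qp[k] + h; qm[k] <- qm[k] - h
    G[k] <- (PE(qp) - PE(qm)) / (2 * h)
  }
  list(M = M, C = C, G = G)
}

# energy-based mass matrix (independent of inverse dynamics)
mass_matrix_at <- function(model, q) {
  nd <- model$ndof
  KE <- function(vv) {
    mechanical_energy(model, matrix(q, 1), matrix(vv, 1)) -
      mechanical_energy(model, matrix(q, 1), matrix(0 * vv, 1))
  }
  M <- matrix(0, nd, nd)
  for (i in seq_len(nd)) for (j in seq_len(nd)) {
    ei <- numeric(nd); ei[i] <- 1
    ej <- numeric(nd); ej[j] <- 1
    M[i, j] <- KE(ei + ej) - KE(ei) - KE(ej)
  }
  M
}
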