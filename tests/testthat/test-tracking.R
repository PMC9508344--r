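test_that("normalizers follow the 10%-of-range rules with the pelvis override", {
  exp <- preprocess(synth_fixture(), cutoff = NA)
  model <- exp$meta$model
  nm <- normalization_spec(exp, model)
  expect_equal(unname(nm$q[1]), 0.01) # anterior-posterior pelvis translation
  j <- 4 # an ordinary coordinate
  expect_equal(unname(nm$q[j]), 0.1 * diff(range(exp$q[, j])), tolerance = 1e-12)
  expect_equal(unname(nm$tau[2]), 0.1 * diff(range(exp$tau[, 2])), tolerance = 1e-12)
  expect_equal(unname(nm$res), unname(model$actuators$reserve_bound))
})

test_that("bounds follow the 25%-beyond-extrema rule with fixed control bounds", {
  exp <- preprocess(synth_fixture(), cutoff = NA)
  model <- exp$meta$model
  bg <- tracking_bounds_and_guess(exp, model)
  j <- 5
  r <- diff(range(exp$q[, j]))
  expect_equal(unname(bg$x_lb[j]), min(exp$q[, j]) - 0.25 * r, tolerance = 1e-9)
  expect_equal(unname(bg$x_ub[j]), max(exp$q[, j]) + 0.25 * r, tolerance = 1e-9)
  cl <- sprintsim:::control_layout(model)
  expect_true(all(bg$u_ub[cl$i_grf] == 2500))
  expect_true(all(bg$u_lb[cl$i_grf] == -2500))
  expect_true(all(bg$u_ub[cl$i_res] == 10)) # no MTP DOFs in the default model
  # a signal with min 0 and max 10 gets bounds [-2.5, 12.5]
  rb <- cbind(sig = c(0, 2, 10, 4))
  out <- local({
    lo <- min(rb); hi <- max(rb); r <- hi - lo
    c(lo - 0.25 * r, hi + 0.25 * r)
  })
  expect_equal(out, c(-2.5, 12.5))
})

test_that("MTP reserve bounds widen to 40 Nm when an MTP DOF is declared", {
  segs <- default_model()$segments
  m <- model_spec(segs, spheres = default_model()$spheres,
                  mtp = list(dofs = "q_foot_r", stiffness = 25, neutral = 0))
  expect_equal(unname(m$actuators$reserve_bound["q_foot_r"]), 40)
  expect_equal(unname(m$actuators$reserve_bound["q_shank_r"]), 10)
})

test_that("the tracking objective breakdown sums to the total and scales as defined", {
  exp <- preprocess(synth_fixture(), cutoff = NA)
  model <- exp$meta$model
  ocp <- build_tracking_ocp(exp, model, N = 10)
  nlp <- transcribe(ocp)
  o <- nlp$obj(nlp$z0_s)
  # breakdown terms recomputed at a point must sum to the objective value
  tfv <- nlp$tf_guess
  parts <- vapply(nlp$qt_pre, function(q) {
    r <- q$bs - as.numeric(q$As %*% nlp$z0_s)
    tfv * sum(q$W * r * r)
  }, numeric(1))
  expect_equal(sum(parts), o$f, tolerance = 1e-10 * max(1, abs(o$f)))
  # shifting one tracked coordinate by exactly its normalizer adds ~ w1 * tf
  lay <- nlp$layout
  zs <- nlp$z0_s
  norms <- normalization_spec(exp, model)
  dof <- 4
  idx <- as.vector(lay$ix[, , dof])
  zshift <- zs
  zshift[idx] <- zshift[idx] + norms$q[dof] / nlp$s_eff[idx]
  o2 <- nlp$obj(zshift)
  expect_equal(o2$f - o$f, 0.1 * tfv, tolerance = 0.02 * 0.1 * tfv)
})

test_that("the tracking objective excludes MTP moments structurally", {
  # with an MTP DOF declared, the moment-tracking term has one row fewer
  exp <- preprocess(synth_fixture(), cutoff = NA)
  base <- exp$meta$model
  mtp_model <- model_spec(base$segments, spheres = base$spheres,
                          mtp = list(dofs = "q_foot_r", stiffness = 25, neutral = 0))
  lay1 <- ocp_layout(build_tracking_ocp(exp, base, N = 4))
  t1 <- build_tracking_ocp(exp, base, N = 4)$objective(lay1)
  t2 <- build_tracking_ocp(exp, mtp_model, N = 4)$objective(
    ocp_layout(build_tracking_ocp(exp, mtp_model, N = 4)))
  n_rows <- function(terms, nm) {
    nrow(terms[[which(vapply(terms, `[[`, character(1), "name") == nm)]]$A)
  }
  expect_equal(n_rows(t1, "track_tau") - n_rows(t2, "track_tau"),
               lay1$N * lay1$d) # one signal dropped at every quadrature node
})

test_that("tracking a clean synthetic experiment recovers it", {
  tr <- tracking_fixture()
  expect_true(tr$sol$status %in% c("solved", "stalled"))
  expect_lt(max(tr$rmsd$q_deg), 1)
  expect_lt(max(tr$rmsd$translations_cm), 0.3)
  expect_lt(max(tr$rmsd$grf_bw), 0.06)
  # net joint moments match the generator within 5% of each signal's peak
  exp <- tr$exp
  lay <- tr$sol$layout
  cl <- tr$layout
  tau_sim <- tr$sol$U[, cl$i_act, drop = FALSE] + tr$sol$U[, cl$i_res, drop = FALSE]
  t_nodes <- (seq_len(nrow(tau_sim)) - 1) / lay$N * tr$sol$tf
  tau_exp <- exp$tau_fun(t_nodes)
  for (j in seq_len(ncol(tau_sim))) {
    pk <- max(abs(tau_exp[, j]))
    expect_lt(rmsd(tau_sim[, j], tau_exp[, j]) / pk, 0.05)
  }
  # path constraints hold at interval starts within solver tolerance
  nlpc <- tr$sol$nlp
  zs <- (tr$sol$z - nlpc$mid) / nlpc$s_eff
  expect_lt(max(abs(nlpc$con(zs))), 5e-3)
})
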