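test_that("generated experiments are deterministic in the seed", {
  e1 <- synth_fixture()
  e2 <- synth_sprint(synth_config(seed = 1))
  expect_identical(e1$q, e2$q)
  expect_identical(e1$tau, e2$tau)
  e3 <- synth_sprint(synth_config(seed = 5))
  expect_false(isTRUE(all.equal(e1$q, e3$q)))
})

test_that("generated data are dynamically consistent", {
  exp <- synth_fixture()
  model <- exp$meta$model
  # internal rows balance exactly by construction; base rows below tolerance
  full <- eom_residual_batch(model, exp$q, exp$v, exp$a, TAU = exp$tau,
                             FX = exp$grf_sphere$fx, FY = exp$grf_sphere$fy,
                             drag_fx = exp$meta$drag)
  expect_lt(max(abs(full[, -(1:3)])), 1e-6)
  expect_lt(max(abs(full[, 1:3])), synth_config()$base_resid_tol)
  expect_lt(exp$meta$diagnostics$base_residual_max, synth_config()$base_resid_tol)
})

test_that("impulse-momentum closure holds on clean data", {
  exp <- synth_fixture()
  model <- exp$meta$model
  cm <- com_state(model, exp$q, exp$v)
  n <- length(exp$time)
  fx <- exp$grf$right[, "ap"] + exp$grf$left[, "ap"] + exp$meta$drag
  imp <- pracma::trapz(exp$time, fx)
  expect_equal(imp, exp$mass * (cm$vx[n] - cm$vx[1]),
               tolerance = 0.01 * abs(imp))
  fy <- exp$grf$right[, "vertical"] + exp$grf$left[, "vertical"] -
    exp$mass * model$gravity
  impy <- pracma::trapz(exp$time, fy)
  expect_equal(impy, exp$mass * (cm$vy[n] - cm$vy[1]), tolerance = 1)
})

test_that("ground reaction forces are stance-gated and pelvis advances", {
  exp <- synth_fixture()
  inr <- exp$time >= exp$stance$right[1] - 1e-9 & exp$time <= exp$stance$right[2] + 1e-9
  inl <- exp$time >= exp$stance$left[1] - 1e-9 & exp$time <= exp$stance$left[2] + 1e-9
  expect_lt(max(abs(exp$grf$right[!inr, ])), 1)
  expect_lt(max(abs(exp$grf$left[!inl, ])), 1)
  expect_gt(max(exp$grf$right[, "vertical"]), 1.8 * exp$mass * 9.81)
  expect_true(all(diff(exp$q[, "pelvis_tx"]) > 0))
})

test_that("noise is seeded and removed by the preprocessing chain", {
  cfg <- synth_config(seed = 3, noise_sd_q = 0.002)
  clean <- synth_sprint(synth_config(seed = 3))
  n1 <- add_noise(clean, cfg)
  n2 <- add_noise(clean, cfg)
  expect_identical(n1$q, n2$q)
  expect_false(isTRUE(all.equal(n1$q, clean$q)))
  # 20 Hz filtering of 250 Hz white noise leaves well under half the power
  pe <- preprocess(n1, cutoff = 20)
  resid <- pe$q[, 4:11] - clean$q[, 4:11]
  # compare against the filtering distortion of the clean signal itself
  pc <- preprocess(clean, cutoff = 20)
  base <- pc$q[, 4:11] - clean$q[, 4:11]
  noise_rms <- sqrt(mean((resid - base)^2))
  expect_lt(noise_rms, 0.6 * 0.002)
  # zero added noise changes nothing
  expect_identical(add_noise(clean, synth_config(seed = 3))$q, clean$q)
})
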