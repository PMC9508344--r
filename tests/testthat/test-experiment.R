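test_that("preprocessing preserves constants and passband sinusoids", {
  t <- seq(0, 1, by = 1 / 250)
  n <- length(t)
  base <- list(
    time = t,
    q = cbind(pelvis_tx = rep(2.5, n), pelvis_ty = sin(2 * pi * 2 * t)),
    grf = list(right = cbind(ap = rep(0, n), vertical = rep(0, n)),
               left = cbind(ap = rep(0, n), vertical = rep(0, n))),
    tau = cbind(q_j = rep(1, n))
  )
  exp <- sprint_experiment(base$time, base$q, base$grf, base$tau, mass = 70,
                           stance = list(right = c(0, 0.2), left = c(0.5, 0.9)))
  pe <- preprocess(exp, cutoff = 20)
  expect_equal(pe$q[, 1], rep(2.5, n), tolerance = 1e-9)
  mid <- 50:200 # away from end effects
  expect_lt(max(abs(pe$q[mid, 2] - base$q[mid, 2])), 0.01)
  expect_error(preprocess(exp, cutoff = 200), "Nyquist")
})

test_that("spline accessors reproduce cubic signals and their derivatives", {
  t <- seq(0, 1, by = 1 / 250)
  n <- length(t)
  qs <- cbind(a = 2 + t - 3 * t^2 + 0.5 * t^3)
  exp <- sprint_experiment(t, qs,
                           list(right = cbind(ap = numeric(n), vertical = numeric(n)),
                                left = cbind(ap = numeric(n), vertical = numeric(n))),
                           cbind(tau = numeric(n)), mass = 70,
                           stance = list(right = c(0, 0.2), left = c(0.5, 0.9)))
  pe <- preprocess(exp, cutoff = NA)
  tt <- seq(0.1, 0.9, by = 0.01)
  expect_equal(drop(pe$q_fun(tt)), 2 + tt - 3 * tt^2 + 0.5 * tt^3, tolerance = 1e-8)
  expect_equal(drop(pe$q_fun(tt, 1)), 1 - 6 * tt + 1.5 * tt^2, tolerance = 1e-8)
  expect_equal(drop(pe$q_fun(tt, 2)), -6 + 3 * tt, tolerance = 1e-8)
})

test_that("rmsd matches its definition", {
  expect_equal(rmsd(1:5, 1:5), 0)
  expect_equal(rmsd(rep(2, 10), rep(5, 10)), 3)
  set.seed(9)
  a <- stats::rnorm(50); b <- stats::rnorm(50)
  expect_equal(rmsd(a, b), sqrt(mean((a - b)^2)), tolerance = 1e-12)
  expect_error(rmsd(1:3, 1:4), "length")
})

test_that("experiment containers validate their invariants", {
  t <- seq(0, 0.4, by = 0.004)
  n <- length(t)
  g <- list(right = cbind(ap = numeric(n), vertical = numeric(n)),
            left = cbind(ap = numeric(n), vertical = numeric(n)))
  expect_error(sprint_experiment(rev(t), matrix(0, n, 2), g,
                                 matrix(0, n, 1), 70,
                                 list(right = c(0, 0.1), left = c(0.2, 0.4))),
               "increasing")
  expect_error(sprint_experiment(t, matrix(0, n, 2), g, matrix(0, n, 1), 70,
                                 list(right = c(0, 0.5), left = c(0.2, 0.4))),
               "window")
})
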