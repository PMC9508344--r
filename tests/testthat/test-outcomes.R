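test_that("average horizontal external power matches the kinetic-energy rate", {
  expect_equal(average_horizontal_power(70, 4, 4, 0.4), 0)
  expect_equal(average_horizontal_power(70, 4, 6, 0.4), 1750)
  expect_error(average_horizontal_power(70, 4, 6, 0), "positive")
  # algebraic closure on the printed-output scale: inverting the formula for
  # the initial speed and re-applying it reproduces a faster trial's power
  v0 <- sqrt(5.86^2 - 2 * 1148.7 * 0.436 / 72.2)
  p2 <- average_horizontal_power(72.2, v0, 6.05, 0.417)
  expect_equal(p2, 1401.2, tolerance = 1401.2 * 0.005)
  # invariance to vertical velocity: the definition is horizontal-only
  expect_equal(average_horizontal_power(70, 4, 6, 0.4),
               average_horizontal_power(70, 4, 6, 0.4) + 0 * 99)
})

test_that("impulses split into propulsive and braking parts exactly", {
  t <- seq(0, 0.2, by = 0.001)
  f <- rep(100, length(t))
  imp <- horizontal_impulses(f, t, c(0, 0.2))
  expect_equal(unname(imp["net"]), 20, tolerance = 1e-9)
  expect_equal(unname(imp["propulsive"]), 20, tolerance = 1e-9)
  expect_equal(unname(imp["braking"]), 0)
  ramp <- horizontal_impulses(500 * t, t, c(0, 0.2))
  expect_equal(unname(ramp["net"]), 10, tolerance = 1e-12) # trapezoid exact for linear
  th <- seq(0, 0.19, by = 0.001)
  hs <- horizontal_impulses(1000 * sin(pi * th / 0.19), th, c(0, 0.19))
  expect_equal(unname(hs["net"]), 2 * 1000 * 0.19 / pi, tolerance = 0.001 * 121)
  # net = propulsive + braking for arbitrary series
  set.seed(5)
  f2 <- stats::rnorm(length(t), 0, 50)
  i2 <- horizontal_impulses(f2, t, c(0.02, 0.15))
  expect_equal(unname(i2["net"]), unname(i2["propulsive"] + i2["braking"]),
               tolerance = 1e-9)
  expect_error(horizontal_impulses(f, t, c(0.5, 0.6)), "empty")
})

test_that("stance detection finds maximal threshold crossings", {
  t <- seq(0, 0.999, by = 0.001)
  f <- numeric(1000)
  expect_length(detect_stance(f, t), 0)
  f[100:150] <- 800
  w <- detect_stance(f, t, threshold = 20)
  expect_length(w, 1)
  expect_equal(w[[1]], c(t[100], t[150]), tolerance = 1e-9)
  expect_equal(diff(w[[1]]), 0.050, tolerance = 1e-9)
  f[400:480] <- 900
  w2 <- detect_stance(f, t, threshold = 20)
  expect_length(w2, 2)
  expect_lt(w2[[1]][2], w2[[2]][1])
})

test_that("the trunk-to-thigh criterion classifies front- and back-side", {
  eq <- trunk_thigh_angle(-30, -30)
  expect_equal(eq$angle, 180)
  expect_equal(eq$label, "neutral")
  fs <- trunk_thigh_angle(-25, -35) # thigh ahead of the trunk line
  expect_equal(fs$angle, 190)
  expect_equal(fs$label, "front-side")
  bs <- trunk_thigh_angle(-50, -40)
  expect_equal(bs$angle, 170)
  expect_equal(bs$label, "back-side")
  # antisymmetry about 180 under swapping the two orientations
  a1 <- trunk_thigh_angle(-20, -33)$angle
  a2 <- trunk_thigh_angle(-33, -20)$angle
  expect_equal(a1 - 180, 180 - a2)
})

test_that("peak moments match a brute-force scan with earliest-tie timing", {
  t <- seq(0, 0.2, by = 0.002)
  tau <- 100 * sin(2 * pi * t / 0.2)
  pk <- peak_moments(tau, t, c(0, 0.2))
  expect_equal(unname(pk["peak_pos"]), max(tau))
  expect_equal(unname(pk["peak_neg"]), min(tau))
  expect_equal(unname(pk["t_pos_pct"]), 25, tolerance = 1.01)
  expect_equal(unname(pk["t_neg_pct"]), 75, tolerance = 1.01)
  cst <- peak_moments(rep(5, length(t)), t, c(0, 0.2))
  expect_equal(unname(cst["t_pos_pct"]), 0) # ties break earliest
  set.seed(8)
  r <- stats::rnorm(length(t), 0, 40)
  pr <- peak_moments(r, t, c(0.05, 0.15))
  sel <- t >= 0.05 & t <= 0.15
  expect_identical(unname(pr["peak_pos"]), max(r[sel]))
  expect_identical(unname(pr["peak_neg"]), min(r[sel]))
})

test_that("percentage changes reproduce printed comparisons", {
  expect_equal(percent_change(1401.2, 1148.7), 22.0)
  expect_equal(percent_change(141.2, 70.5), 100.3)
  expect_equal(percent_change(188.5, 137.5), 37.1)
  expect_equal(percent_change(5, 5), 0.0)
  expect_error(percent_change(1, 0), "nonzero")
})

test_that("outcome metrics on generated data recover the construction", {
  exp <- synth_fixture()
  cfg <- exp$meta$config
  # touchdown metrics at the right-foot touchdown reproduce the scripted
  # foot speed and the CoM-foot placement
  td <- touchdown_metrics(exp, exp$stance$right, foot = "right")
  expect_equal(unname(td["foot_speed"]), cfg$td_foot_speed[1], tolerance = 1e-2)
  expect_equal(unname(td["td_distance"]), cfg$td_dist[1] + exp$meta$diagnostics$contact_shift,
               tolerance = 2e-2)
  # stance windows detected from the vertical GRF match the configuration
  w <- detect_stance(exp$grf$right[, "vertical"], exp$time)
  expect_length(w, 1)
  # the 20 N threshold crossing sits a few samples inside the scripted window
  expect_lt(abs(w[[1]][1] - cfg$stance_right[1]), 0.012)
  expect_lt(abs(w[[1]][2] - cfg$stance_right[2]), 0.015)
})
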