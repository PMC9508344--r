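test_that("characteristic curves are normalized and mutually consistent", {
  cur <- hill_curves()
  expect_equal(sprintsim:::active_fl(1, cur), 1, tolerance = 1e-12)
  expect_equal(sprintsim:::force_velocity(0, cur), 1, tolerance = 1e-12)
  # tendon curve and its inverse agree over the working range
  for (f in seq(0.01, 1.8, by = 0.05)) {
    expect_equal(sprintsim:::tendon_fl(sprintsim:::tendon_fl_inverse(f, cur), cur),
                 f, tolerance = 1e-9)
  }
})

test_that("polynomial geometry gives consistent arms and velocities", {
  cur <- hill_curves()
  pc <- mtu_params("const", "q1", 1000, 0.1, 0.2, poly = list(0.05), const = 0.25)
  g0 <- mtu_geometry(c(q1 = 0.7), pc, v = c(q1 = 2))
  expect_equal(unname(g0$moment_arms), 0, tolerance = 1e-12)
  expect_equal(g0$velocity, 0, tolerance = 1e-12)
  plin <- mtu_params("lin", "q1", 1000, 0.1, 0.2, poly = list(c(0, -0.04)),
                     const = 0.3)
  expect_equal(unname(mtu_geometry(c(q1 = -0.5), plin)$moment_arms), 0.04)
  pcub <- mtu_params("cub", "q1", 1000, 0.1, 0.2,
                     poly = list(c(0, 0.03, -0.01, 0.002)), const = 0.3)
  h <- 1e-6
  for (qv in c(-0.8, 0.1, 0.9)) {
    num <- (mtu_geometry(c(q1 = qv + h), pcub)$length -
              mtu_geometry(c(q1 = qv - h), pcub)$length) / (2 * h)
    g <- mtu_geometry(c(q1 = qv), pcub, v = c(q1 = 1.3))
    expect_equal(unname(g$moment_arms), -num, tolerance = 1e-7)
    expect_equal(g$velocity, num * 1.3, tolerance = 1e-7)
  }
  pr <- mtu_params("rng", "q1", 1000, 0.1, 0.2, poly = list(c(0, -0.04)),
                   const = 0.3, qrange = matrix(c(-1, 1), 1))
  expect_warning(mtu_geometry(c(q1 = 2), pr), "extrapolating")
})

test_that("the implicit Hill equilibrium balances at analytic operating points", {
  cur <- hill_curves()
  p <- mtu_params("m", "q1", 1000, 0.1, 0.2, penn_opt = 0, vmax = 10,
                  poly = list(c(0, -0.05)), const = 0.3)
  # full activation, optimal fibre length, zero velocity: FT = 1 + f_pass(1)
  ft <- 1 + sprintsim:::passive_fl(1, cur)
  lt <- 0.2 * sprintsim:::tendon_fl_inverse(ft, cur)
  q <- c(q1 = (0.3 - (lt + 0.1)) / 0.05)
  expect_equal(hill_equilibrium_residual(q, c(q1 = 0), ft, a = 1, p, cur), 0,
               tolerance = 1e-10)
  # slack inactive muscle: residual at FT ~ 0 is bounded by the passive
  # curve's small sub-slack tail
  r <- hill_equilibrium_residual(c(q1 = 1.2), c(q1 = 0), 1e-6, a = 0, p, cur)
  expect_lt(abs(r), 0.02)
  expect_error(hill_equilibrium_residual(c(q1 = 3.5), c(q1 = 0), 1.5, 1, p, cur),
               "fibre")
})

test_that("the equilibrium has a unique tendon-force root", {
  cur <- hill_curves()
  p <- mtu_params("m", "q1", 1000, 0.1, 0.2, penn_opt = 0.1, vmax = 10,
                  poly = list(c(0, -0.05)), const = 0.3)
  for (a in c(0.2, 0.5, 1)) {
    fts <- seq(0.01, 3, by = 0.01)
    rs <- vapply(fts, function(f) {
      tryCatch(hill_equilibrium_residual(c(q1 = 0.3), c(q1 = 0), f, a, p, cur),
               error = function(e) NA_real_)
    }, numeric(1))
    rs <- rs[!is.na(rs)]
    expect_equal(sum(diff(sign(rs)) != 0), 1)
  }
})

test_that("activation-rate constraints bound the first-order dynamics", {
  g <- activation_rate_constraints(0, 0)
  expect_equal(g$g_lower, 0)
  expect_equal(g$g_upper, -1 / 0.015, tolerance = 1e-12)
  g2 <- activation_rate_constraints(0.5, -0.5 / 0.060)
  expect_equal(g2$g_lower, 0, tolerance = 1e-12)
  g3 <- activation_rate_constraints(1, 1)
  expect_gt(g3$g_upper, 0) # cannot activate beyond full
  # feasible-set equivalence with the first-order activation ODE on a grid
  ok <- TRUE
  for (a in seq(0, 1, length.out = 50)) {
    for (e in seq(0, 1, length.out = 50)) {
      adot <- if (e >= a) (e - a) / 0.015 else (e - a) / 0.060
      g <- activation_rate_constraints(a, adot)
      if (g$g_lower < -1e-12 || g$g_upper > 1e-12) ok <- FALSE
    }
  }
  expect_true(ok)
})

test_that("muscle moments superpose and satisfy the virtual-work identity", {
  cur <- hill_curves()
  pflex <- mtu_params("flex", "q1", 1000, 0.1, 0.2, poly = list(c(0, -0.04)),
                      const = 0.3)
  pext <- mtu_params("ext", "q1", 1000, 0.1, 0.2, poly = list(c(0, 0.04)),
                     const = 0.3)
  expect_equal(unname(muscle_moments(c(q1 = 0.2), c(0, 0), list(pflex, pext), "q1")), 0)
  m1 <- muscle_moments(c(q1 = 0.2), c(0.5, 0), list(pflex, pext), "q1")
  expect_equal(unname(m1), 0.5 * 1000 * 0.04, tolerance = 1e-12)
  expect_equal(unname(muscle_moments(c(q1 = 0.2), c(0.5, 0.5), list(pflex, pext), "q1")), 0)
  # virtual work: moment = -d(F . length)/dq for constant normalized forces
  pcub <- mtu_params("cub", "q1", 800, 0.1, 0.2,
                     poly = list(c(0, 0.03, -0.01, 0.002)), const = 0.3)
  h <- 1e-6
  work <- function(qv) 0.6 * 800 * mtu_geometry(c(q1 = qv), pcub)$length
  num <- -(work(0.4 + h) - work(0.4 - h)) / (2 * h)
  expect_equal(unname(muscle_moments(c(q1 = 0.4), 0.6, list(pcub), "q1")), num,
               tolerance = 1e-8)
})
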