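test_that("static pendulum equilibrium and free fall satisfy the implicit EoM", {
  m <- pendulum_model()
  th <- 0.6
  tau_hold <- 2 * 9.81 * 0.25 * sin(th)
  r <- eom_residual(m, c(0, 0, 0, th), rep(0, 4), rep(0, 4), tau = tau_hold)
  expect_equal(unname(r[4]), 0, tolerance = 1e-10) # joint row balances
  # without the torque the joint row carries the full gravitational moment
  r0 <- eom_residual(m, c(0, 0, 0, th), rep(0, 4), rep(0, 4), tau = 0)
  expect_equal(unname(abs(r0[4])), 2 * 9.81 * 0.25 * sin(th), tolerance = 1e-10)
  # ballistic free fall (no rotation rates): u_vdot = (0, -g, 0, 0)
  rb <- eom_residual(m, c(0.3, 1.2, 0.2, 0.5), c(2, 1, 0, 0),
                     c(0, -9.81, 0, 0), tau = 0)
  expect_equal(max(abs(rb)), 0, tolerance = 1e-9)
  expect_error(eom_residual(m, c(NA, 0, 0, 0), rep(0, 4), rep(0, 4)), "NaN")
  expect_error(eom_residual(m, rep(0, 3), rep(0, 4), rep(0, 4)), "length")
})

test_that("the EoM residual is linear in accelerations, moments and forces", {
  model <- default_model()
  set.seed(21)
  nd <- model$ndof
  q <- stats::rnorm(nd, 0, 0.3); q[2] <- 1 # keep feet near the ground
  v <- stats::rnorm(nd)
  nsph <- nrow(model$spheres)
  r_of <- function(a, tau, grf) eom_residual(model, q, v, a, tau, grf)
  a1 <- stats::rnorm(nd); a2 <- stats::rnorm(nd)
  t1 <- stats::rnorm(nd - 3); t2 <- stats::rnorm(nd - 3)
  g1 <- matrix(stats::rnorm(2 * nsph), nsph)
  g2 <- matrix(stats::rnorm(2 * nsph), nsph)
  lhs <- r_of(a1 + 2 * a2, t1 + 2 * t2, g1 + 2 * g2)
  rhs <- r_of(a1, t1, g1) + 2 * r_of(a2, t2, g2) -
    2 * r_of(numeric(nd), numeric(nd - 3), matrix(0, nsph, 2))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("mass matrix, bias and gravity match a Lagrangian derivation", {
  model <- chain3_model()
  set.seed(31)
  for (trial in 1:20) {
    q <- stats::rnorm(model$ndof)
    v <- stats::rnorm(model$ndof)
    or <- lagrangian_oracle(model, q, v)
    expect_equal(mass_matrix(model, q), or$M, tolerance = 1e-8)
    expect_equal(unname(bias_forces(model, q, v)), or$C, tolerance = 1e-6)
    expect_equal(unname(gravity_forces(model, q)), or$G, tolerance = 1e-6)
  }
})

test_that("ballistic flight conserves mechanical energy under RK4", {
  model <- default_model()
  q0 <- c(0, 2.0, -0.2, 0.1, 0.05, 0.3, -0.5, -0.1, -0.2, -0.4, 0.2)
  v0 <- c(4, 0.5, 0.8, -0.5, 0.3, 1, 2, -1, -2, 1, 0.5)
  nd <- model$ndof
  x <- c(q0, v0)
  dt <- 1e-4
  deriv <- function(x) {
    q <- x[1:nd]; v <- x[nd + 1:nd]
    c(v, forward_dynamics(model, q, v, tau = rep(0, nd - 3)))
  }
  E0 <- mechanical_energy(model, matrix(q0, 1), matrix(v0, 1))
  for (i in 1:1000) {
    k1 <- deriv(x); k2 <- deriv(x + dt / 2 * k1)
    k3 <- deriv(x + dt / 2 * k2); k4 <- deriv(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  E1 <- mechanical_energy(model, matrix(x[1:nd], 1), matrix(x[nd + 1:nd], 1))
  expect_lt(abs(E1 - E0) / abs(E0), 1e-6)
})

test_that("whole-body CoM velocity is the time derivative of CoM position", {
  model <- default_model()
  set.seed(41)
  q <- stats::rnorm(model$ndof, 0, 0.3); q[2] <- 1
  v <- stats::rnorm(model$ndof)
  h <- 1e-6
  cm <- com_state(model, q, v)
  cp <- com_state(model, q + h * v)
  cmm <- com_state(model, q - h * v)
  expect_equal(cm$vx, (cp$x - cmm$x) / (2 * h), tolerance = 1e-6)
  expect_equal(cm$vy, (cp$y - cmm$y) / (2 * h), tolerance = 1e-6)
})

test_that("two equal point masses average to the midpoint CoM", {
  segs <- data.frame(
    name = c("a", "b"), parent = c("", "a"),
    jx = c(0, 2), jy = c(0, 0), mass = c(1, 1), inertia = c(0.01, 0.01),
    cx = c(0, 0), cy = c(0, 0), stringsAsFactors = FALSE
  )
  m <- model_spec(segs)
  cm <- com_state(m, c(0, 0, 0, 0))
  expect_equal(cm$x, 1)
  expect_equal(cm$y, 0)
})
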