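# analytic minimum-effort double integrator: rest-to-rest unit displacement
# in unit time; continuous optimum u(t) = 6 - 12 t with cost 12, and the
# exact piecewise-constant discrete optimum 12 N^2 / (N^2 - 1)
make_di <- function(N, rep = "constant", tf = 1) {
  define_ocp(
    nx = 2, nu = 1, N = N, d = 3, tf = tf,
    linear_dyn = list(A = matrix(c(0, 0, 1, 0), 2, 2), B = matrix(c(0, 1), 2, 1)),
    x_lb = c(-10, -10), x_ub = c(10, 10), u_lb = -50, u_ub = 50,
    x_fix = list(list(i = 1, k = 0, dof = 1, value = 0),
                 list(i = 1, k = 0, dof = 2, value = 0),
                 list(i = N, k = 3, dof = 1, value = 1),
                 list(i = N, k = 3, dof = 2, value = 0)),
    objective = function(l) list(obj_term_controls(l, matrix(1, 1, 1), 1,
                                                   name = "effort")),
    control_rep = rep
  )
}

test_that("minimum-effort transcription reaches its analytic optima", {
  s1 <- solve_ocp(make_di(10), control = list(tol = 1e-5))
  expect_true(s1$status %in% c("solved", "stalled"))
  expect_equal(s1$objective, 12 * 100 / 99, tolerance = 1e-3)
  # with piecewise-linear controls the continuous optimum is representable
  s2 <- solve_ocp(make_di(10, "linear"), control = list(tol = 1e-5))
  expect_equal(s2$objective, 12, tolerance = 1e-3)
})

test_that("zero dynamics keeps every collocation state at its initial value", {
  oz <- define_ocp(nx = 1, nu = 1, N = 5, d = 3, tf = 1,
                   linear_dyn = list(A = matrix(0, 1, 1), B = matrix(0, 1, 1)),
                   x_lb = -5, x_ub = 5, u_lb = -1, u_ub = 1,
                   x_fix = list(list(i = 1, k = 0, dof = 1, value = 0.7)),
                   objective = function(l) list(obj_term_controls(l, matrix(1, 1, 1), 1)))
  sz <- solve_ocp(oz, control = list(tol = 1e-6))
  expect_lt(max(abs(sz$X - 0.7)), 1e-8)
})

test_that("minimum-time double integrator finds the bang-bang horizon", {
  N <- 40
  ot <- define_ocp(nx = 2, nu = 1, N = N, d = 3,
                   tf = list(lower = 0.5, upper = 5, guess = 3),
                   linear_dyn = list(A = matrix(c(0, 0, 1, 0), 2, 2),
                                     B = matrix(c(0, 1), 2, 1)),
                   x_lb = c(-10, -10), x_ub = c(10, 10), u_lb = -1, u_ub = 1,
                   x_fix = list(list(i = 1, k = 0, dof = 1, value = 0),
                                list(i = 1, k = 0, dof = 2, value = 0),
                                list(i = N, k = 3, dof = 1, value = 1),
                                list(i = N, k = 3, dof = 2, value = 0)),
                   x_guess = function(t) c(t, 1), u_guess = 0,
                   objective = function(l) list(obj_term_mayer_tf(l, 1)))
  st <- solve_ocp(ot, control = list(tol = 1e-3))
  expect_true(st$status %in% c("solved", "stalled"))
  expect_equal(st$tf, 2, tolerance = 2 / N)
})

test_that("mesh refinement reduces the piecewise-constant discretization error", {
  errs <- vapply(c(5, 10, 20), function(N) {
    s <- solve_ocp(make_di(N), control = list(tol = 1e-6))
    abs(s$objective - 12)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("continuity constraints hold at solutions", {
  s <- solve_ocp(make_di(8), control = list(tol = 1e-6))
  for (i in 1:7) {
    expect_equal(s$X[i, 4, ], s$X[i + 1, 1, ], tolerance = 1e-6)
  }
})

test_that("scaling the problem by 1e3 leaves the unscaled solution unchanged", {
  N <- 8
  base <- solve_ocp(make_di(N), control = list(tol = 1e-7))
  big <- define_ocp(
    nx = 2, nu = 1, N = N, d = 3, tf = 1,
    linear_dyn = list(A = matrix(c(0, 0, 1, 0), 2, 2), B = matrix(c(0, 1), 2, 1)),
    x_lb = 1e3 * c(-10, -10), x_ub = 1e3 * c(10, 10), u_lb = -5e4, u_ub = 5e4,
    x_fix = list(list(i = 1, k = 0, dof = 1, value = 0),
                 list(i = 1, k = 0, dof = 2, value = 0),
                 list(i = N, k = 3, dof = 1, value = 1e3),
                 list(i = N, k = 3, dof = 2, value = 0)),
    objective = function(l) list(obj_term_controls(l, matrix(1, 1, 1), 1e-6)))
  sb <- solve_ocp(big, control = list(tol = 1e-7))
  expect_equal(sb$X[, , 1] / 1e3, base$X[, , 1], tolerance = 1e-6)
})

test_that("a free horizon with collapsed bounds reproduces the fixed-time problem", {
  N <- 8
  fixed <- make_di(N)
  collapsed <- define_ocp(
    nx = 2, nu = 1, N = N, d = 3, tf = list(lower = 1, upper = 1),
    linear_dyn = list(A = matrix(c(0, 0, 1, 0), 2, 2), B = matrix(c(0, 1), 2, 1)),
    x_lb = c(-10, -10), x_ub = c(10, 10), u_lb = -50, u_ub = 50,
    x_fix = list(list(i = 1, k = 0, dof = 1, value = 0),
                 list(i = 1, k = 0, dof = 2, value = 0),
                 list(i = N, k = 3, dof = 1, value = 1),
                 list(i = N, k = 3, dof = 2, value = 0)),
    objective = function(l) list(obj_term_controls(l, matrix(1, 1, 1), 1)))
  expect_false(collapsed$free_tf) # equal bounds collapse to the fixed horizon
  nf <- transcribe(fixed)
  nc <- transcribe(collapsed)
  expect_identical(nf$nz, nc$nz) # same variable layout after collapsing
  s1 <- solve_ocp(fixed, control = list(tol = 1e-7))
  s2 <- solve_ocp(collapsed, control = list(tol = 1e-7))
  expect_equal(s1$objective, s2$objective, tolerance = 1e-8)
})

test_that("infeasible bounds are rejected at definition time", {
  expect_error(define_ocp(nx = 1, nu = 1, N = 2, d = 2, tf = 1,
                          linear_dyn = list(A = matrix(0), B = matrix(0)),
                          x_lb = 1, x_ub = -1, u_lb = 0, u_ub = 1),
               "infeasible")
})
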