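test_that("flipped LGR nodes include the right endpoint and integrate exactly", {
  for (d in 1:6) {
    lg <- lgr_nodes(d)
    expect_length(lg$nodes, d)
    expect_equal(lg$nodes[d], 1)
    expect_true(all(diff(lg$nodes) > 0))
    expect_true(all(lg$weights > 0))
    expect_equal(sum(lg$weights), 1, tolerance = 1e-12)
  }
  lg3 <- lgr_nodes(3)
  expect_equal(lg3$nodes, c(0.1550510, 0.6449490, 1), tolerance = 1e-6)
  expect_equal(lg3$weights, c(0.3764030, 0.5124858, 0.1111111), tolerance = 1e-6)
  # exactness up to degree 2d - 2 (x^4 for d = 3)
  expect_equal(sum(lg3$weights * lg3$nodes^4), 0.2, tolerance = 1e-10)
  expect_error(lgr_nodes(0), "integer")
})

test_that("quadrature is exact for random polynomials up to degree 2d - 2", {
  set.seed(11)
  for (d in 2:4) {
    lg <- lgr_nodes(d)
    for (trial in 1:100) {
      coef <- stats::rnorm(2 * d - 1) # degree 2d - 2
      vals <- vapply(lg$nodes, function(x) sum(coef * x^(seq_along(coef) - 1)),
                     numeric(1))
      exact <- sum(coef / seq_along(coef))
      expect_equal(sum(lg$weights * vals), exact, tolerance = 1e-10)
    }
  }
})

test_that("Lagrange differentiation is exact for representable polynomials", {
  lg <- lgr_nodes(3)
  nodes <- c(0, lg$nodes)
  D <- lagrange_differentiation(nodes)
  expect_equal(drop(D %*% rep(2.5, 4)), rep(0, 3), tolerance = 1e-12)
  expect_equal(drop(D %*% nodes), rep(1, 3), tolerance = 1e-12)
  expect_equal(drop(D %*% nodes^3), 3 * lg$nodes^2, tolerance = 1e-12)
  expect_error(lagrange_differentiation(c(0, 0.5, 0.5)), "distinct")
})
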