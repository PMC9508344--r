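test_that("moment masks free exactly the named sagittal groups", {
  model <- default_model()
  mk <- build_mask("K-free", model)
  expect_equal(attr(mk, "config"), "K-free")
  expect_equal(sort(names(which(mk == 0))), c("q_shank_l", "q_shank_r"))
  m3 <- build_mask("A-K-H-free", model)
  expect_equal(sort(names(which(m3 == 0))),
               sort(c("q_foot_l", "q_foot_r", "q_shank_l", "q_shank_r",
                      "q_thigh_l", "q_thigh_r")))
  expect_true(all(build_mask("none", model) == 1))
  # letter orderings are aliases of the same configuration
  expect_identical(unclass(build_mask("K-H-free", model)),
                   unclass(build_mask("H-K-free", model)))
  expect_identical(attr(build_mask("H-A-free", model), "config"), "A-H-free")
  expect_error(build_mask("Q-free", model), "unknown")
})

test_that("the predictive normalizer realizes the 2%-of-range rule", {
  # a 250 Nm range gives a 5 Nm permissible-error scale
  expect_equal(0.02 * 250, 5)
  tr <- tracking_fixture()
  ref <- sprintsim:::tracking_moment_reference(tr)
  expect_equal(unname(0.02 * ref$range[1]),
               0.02 * diff(range(ref$tau[, 1])), tolerance = 1e-12)
})

test_that("freed moments carry no tracking rows in the objective", {
  tr <- tracking_fixture()
  ocp_all <- build_predictive_ocp(tr, "none", N = 4)
  ocp_k <- build_predictive_ocp(tr, "K-free", N = 4)
  lay <- ocp_layout(ocp_all)
  rows_of <- function(ocp) {
    terms <- ocp$objective(ocp_layout(ocp))
    nm <- vapply(terms, `[[`, character(1), "name")
    nrow(terms[[which(nm == "track_tau")]]$A)
  }
  # two knee moments dropped at every quadrature node
  expect_equal(rows_of(ocp_all) - rows_of(ocp_k), 2 * lay$N * lay$d)
})

test_that("terminal boundary windows implement the +/- 10 degree rule", {
  tr <- tracking_fixture()
  ocp <- build_predictive_ocp(tr, "K-free", N = 6)
  g <- solution_grid(tr$sol)
  xT <- g$X[nrow(g$X), ]
  wnd <- ocp$x_window[[3]] # a relative joint angle
  expect_equal(wnd$ub - xT[wnd$dof], 10 * pi / 180, tolerance = 1e-12)
  expect_equal(xT[wnd$dof] - wnd$lb, 10 * pi / 180, tolerance = 1e-12)
  # 9.9 degrees is inside the window; 10.1 degrees is not
  expect_true(xT[wnd$dof] + 9.9 * pi / 180 < wnd$ub)
  expect_false(xT[wnd$dof] + 10.1 * pi / 180 < wnd$ub)
  # base coordinates are not windowed
  dofs <- vapply(ocp$x_window, `[[`, numeric(1), "dof")
  expect_false(any(dofs <= 3))
  # the initial multibody state is pinned to the tracking solution
  fix0 <- Filter(function(f) f$i == 1 && f$k == 0, ocp$x_fix)
  expect_length(fix0, 2 * tr$model$ndof)
  vals <- vapply(fix0, `[[`, numeric(1), "value")
  expect_equal(vals, unname(g$X[1, ]), tolerance = 1e-12)
})

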