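test_that("separated spheres produce negligible force", {
  model <- default_model()
  q <- numeric(model$ndof); q[2] <- 1.5 # pelvis high: all spheres airborne
  cg <- contact_grf(model, q, numeric(model$ndof))
  k <- model$spheres$stiffness[1]
  s <- model$spheres$delta_smooth[1]
  expect_lt(max(abs(cg$per_sphere$fy)), 1e-6 * k * s^1.5)
  expect_equal(sum(abs(cg$total)), 0, tolerance = 1e-6)
})

test_that("static penetration follows the Hunt-Crossley closed form", {
  # a single sphere with a vanishing smoothing scale: k delta^(3/2)
  model <- default_model(contact = list(delta_smooth = 1e-9))
  sp <- model$spheres
  # place the right toe pair at exactly 1 mm penetration by construction:
  # solve for the pelvis height that puts the toe sphere centre at r - delta
  q <- numeric(model$ndof)
  sk <- sphere_kinematics(model, q, numeric(model$ndof))
  target <- sp$radius[2] - 0.001
  q[2] <- target - sk$y[1, 2]
  cg <- contact_grf(model, q, numeric(model$ndof))
  fn_toe_pair <- unname(cg$per_sphere$fy[2] + cg$per_sphere$fy[3])
  expect_equal(fn_toe_pair, 3e6 * 0.001^1.5, tolerance = 1e-3)
  expect_equal(fn_toe_pair, 94.868, tolerance = 1e-3)
})

test_that("tangential force vanishes at zero slip and opposes slip", {
  model <- default_model()
  q <- numeric(model$ndof)
  sk <- sphere_kinematics(model, q, numeric(model$ndof))
  q[2] <- (model$spheres$radius[2] - 0.002) - sk$y[1, 2]
  v0 <- numeric(model$ndof)
  cg0 <- contact_grf(model, q, v0)
  expect_equal(unname(cg0$per_sphere$fx[2]), 0, tolerance = 1e-12)
  vf <- v0; vf[1] <- 0.3 # forward slip
  cgf <- contact_grf(model, q, vf)
  expect_lt(unname(cgf$per_sphere$fx[2]), 0) # friction opposes forward slip
})

test_that("normal force is non-negative and monotone in static penetration", {
  model <- default_model()
  sk0 <- sphere_kinematics(default_model(), numeric(11), numeric(11))
  fn <- vapply(seq(-0.01, 0.008, length.out = 80), function(dlt) {
    q <- numeric(11)
    q[2] <- (model$spheres$radius[2] - dlt) - sk0$y[1, 2]
    contact_grf(model, q, numeric(11))$per_sphere$fy[2]
  }, numeric(1))
  expect_true(all(fn >= 0))
  expect_true(all(diff(fn) >= -1e-9))
})

test_that("MTP spring is linear through the neutral angle", {
  expect_equal(mtp_spring_moment(0.1, 25, neutral = 0.1), 0)
  expect_equal(mtp_spring_moment(0.2, 25), -5)
  expect_equal(mtp_spring_moment(0.4, 25), 2 * mtp_spring_moment(0.2, 25))
})

test_that("aerodynamic drag follows the quadratic law and flips sign", {
  p <- list(rho = 1.2, cd = 0.9, area = 0.45)
  expect_equal(aerodynamic_drag(0, p), 0)
  expect_equal(aerodynamic_drag(5, p), -6.075)
  expect_equal(aerodynamic_drag(-5, p), 6.075)
  expect_error(aerodynamic_drag(5, list(rho = -1, cd = 0.9, area = 0.45)),
               "positive")
})
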