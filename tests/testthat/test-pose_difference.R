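test_that("translation difference recovers pure shifts and rejects mismatches", {
  plan <- random_triad("maxilla", "planned")
  same <- fiducial_triad(plan$points, "maxilla", "postop")
  td <- translation_difference(plan, same)
  expect_equal(unname(td$components), c(0, 0, 0))
  expect_equal(td$magnitude, 0)

  adv <- fiducial_triad(sweep(plan$points, 2, c(5, 0, 0), "+"),
                        "maxilla", "postop")
  td <- translation_difference(plan, adv)
  expect_equal(unname(td$components), c(5, 0, 0))
  expect_equal(td$magnitude, 5)

  sh <- fiducial_triad(sweep(plan$points, 2, c(1, 2, 2), "+"),
                       "maxilla", "postop")
  expect_equal(translation_difference(plan, sh)$magnitude, 3)

  wrong <- fiducial_triad(plan$points, "mandible", "postop")
  expect_error(translation_difference(plan, wrong), "region mismatch")
  expect_error(translation_difference(same, adv), "planned")
})

test_that("Kabsch estimate is a proper rotation and recovers exact rotations", {
  set.seed(23)
  for (i in 1:20) {
    plan <- random_triad()
    rot <- random_rotation(30)
    post <- fiducial_triad(plan$points %*% t(rot$R), "maxilla", "postop")
    est <- estimate_rotation(vector_triad(plan), vector_triad(post))
    expect_lt(max(abs(t(est$R) %*% est$R - diag(3))), 1e-9)
    expect_equal(det(est$R), 1, tolerance = 1e-9)
    expect_equal(sqrt(sum(est$transformed_y_axis^2)), 1, tolerance = 1e-9)
    # elementwise comparison: the geodesic metric's acos cannot resolve
    # agreement this tight
    expect_lt(max(abs(est$R - rot$R)), 1e-9)
    expect_lt(est$residual_rmse, 1e-9)
  }

  plan <- random_triad()
  est0 <- estimate_rotation(vector_triad(plan), vector_triad(
    fiducial_triad(plan$points, "maxilla", "postop")))
  expect_equal(est0$R, diag(3), tolerance = 1e-12)
  expect_equal(est0$transformed_y_axis, c(0, 1, 0), tolerance = 1e-12)
})

test_that("noise-free rigid round trip recovers translation and Euler angles", {
  set.seed(29)
  for (i in 1:20) {
    plan <- random_triad()
    ang <- stats::runif(3, -25, 25)
    t0 <- stats::rnorm(3, 0, 4)
    R0 <- euler_to_matrix(ang[1], ang[2], ang[3])
    b <- colMeans(plan$points)
    pts <- sweep(sweep(plan$points, 2, b) %*% t(R0), 2, b + t0, "+")
    post <- fiducial_triad(pts, "maxilla", "postop")
    pd <- pose_difference(plan, post)
    expect_equal(unname(pd$translation$components), t0, tolerance = 1e-9)
    expect_equal(c(pd$rotation$pitch, pd$rotation$roll, pd$rotation$yaw),
                 ang, tolerance = 1e-9)
    expect_false(pd$rotation$gimbal_lock)
  }
})

test_that("rotation angle conventions behave as documented", {
  plan <- random_triad()
  id_est <- estimate_rotation(vector_triad(plan), vector_triad(
    fiducial_triad(plan$points, "maxilla", "postop")))

  std <- rotation_angles(id_est, "standard")
  expect_equal(c(std$pitch, std$roll, std$yaw), c(0, 0, 0))

  # the literal single-axis formulas are degenerate at the identity:
  # yaw = atan2(1, 0) = 90 degrees even though nothing rotated
  lit <- rotation_angles(id_est, "y_axis_literal")
  expect_equal(c(lit$pitch, lit$roll, lit$yaw), c(0, 0, 90))

  # pure rotation about x: both conventions agree on pitch
  est_x <- estimate_rotation(vector_triad(plan), vector_triad(
    fiducial_triad(plan$points %*% t(rot_for_test(5, 0, 0)), "maxilla", "postop")))
  expect_equal(rotation_angles(est_x, "standard")$pitch, 5, tolerance = 1e-9)
  expect_equal(rotation_angles(est_x, "y_axis_literal")$pitch, 5,
               tolerance = 1e-9)
  expect_equal(rotation_angles(est_x, "standard")$roll, 0, tolerance = 1e-9)
  expect_equal(rotation_angles(est_x, "standard")$yaw, 0, tolerance = 1e-9)

  # pure rotation about z: literal roll is the negative of standard yaw
  for (yaw in c(-17, -4, 3, 12)) {
    est_z <- estimate_rotation(vector_triad(plan), vector_triad(
      fiducial_triad(plan$points %*% t(rot_for_test(0, 0, yaw)),
                     "maxilla", "postop")))
    expect_equal(rotation_angles(est_z, "y_axis_literal")$roll,
                 -rotation_angles(est_z, "standard")$yaw, tolerance = 1e-9)
  }
})

test_that("gimbal lock is flagged but not fatal", {
  e <- matrix_to_euler(euler_to_matrix(10, 90, 0))
  expect_true(e$gimbal_lock)
  expect_true(all(is.finite(c(e$pitch, e$roll, e$yaw))))
  expect_equal(abs(e$roll), 90)
})

test_that("rotation estimation is equivariant under a global rotation", {
  set.seed(31)
  for (i in 1:10) {
    plan <- random_triad()
    rot <- random_rotation(20)
    noisy <- plan$points %*% t(rot$R) + matrix(stats::rnorm(9, 0, 0.1), 3, 3)
    post <- fiducial_triad(noisy, "maxilla", "postop")
    est <- estimate_rotation(vector_triad(plan), vector_triad(post))

    G <- random_rotation(180)$R
    plan_g <- fiducial_triad(plan$points %*% t(G), "maxilla", "planned")
    post_g <- fiducial_triad(post$points %*% t(G), "maxilla", "postop")
    est_g <- estimate_rotation(vector_triad(plan_g), vector_triad(post_g))
    expect_equal(est_g$R, G %*% est$R %*% t(G), tolerance = 1e-9)
    expect_equal(est_g$residual_rmse, est$residual_rmse, tolerance = 1e-9)
  }
})

test_that("pose difference composes translation and rotation on constructed ground truth", {
  plan <- random_triad()
  b <- colMeans(plan$points)
  pts <- sweep(sweep(plan$points, 2, b) %*% t(rot_for_test(3, 0, 0)),
               2, b + c(5, 0, 0), "+")
  pd <- pose_difference(plan, fiducial_triad(pts, "maxilla", "postop"))
  expect_equal(pd$translation$magnitude, 5, tolerance = 1e-9)
  expect_equal(pd$rotation$pitch, 3, tolerance = 1e-9)
  expect_equal(pd$rotation$roll, 0, tolerance = 1e-9)
  expect_equal(pd$rotation$yaw, 0, tolerance = 1e-9)
  expect_lt(pd$rotation_estimate$residual_rmse, 1e-9)

  row <- as.data.frame(pd)
  expect_equal(row$dx_mm, 5, tolerance = 1e-9)
  expect_equal(row$pitch_deg, 3, tolerance = 1e-9)
  expect_identical(row$convention, "standard")
})
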