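test_that("fit_line recovers exact and symmetric directions", {
  d <- c(1, 1, 0) / sqrt(2)
  pts <- outer(seq(-3, 3, length.out = 7), d)
  f <- fit_line(pts)
  expect_equal(abs(sum(f$direction * d)), 1, tolerance = 1e-12)
  expect_equal(f$rms_residual, 0, tolerance = 1e-9)
  # ellipse with major axis along y
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  ell <- cbind(0 * th, 3 * sin(th), 1 * cos(th))
  f2 <- fit_line(ell)
  expect_equal(abs(f2$direction[2]), 1, tolerance = 1e-9)
  expect_error(fit_line(matrix(c(1, 2, 3), 1)), "degenerate-geometry")
})

test_that("fit_sphere recovers generating parameters and rejects coplanar input", {
  set.seed(21)
  u <- random_unit(200)
  pts <- sweep(5 * u, 2, c(1, 2, 3), "+")
  f <- fit_sphere(pts)
  expect_equal(f$center, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(f$radius, 5, tolerance = 1e-9)
  expect_lt(f$rms_residual, 1e-9)
  # noisy: center recovered to noise scale
  fn <- fit_sphere(pts + matrix(rnorm(600, sd = 0.05), ncol = 3))
  expect_lt(sqrt(sum((fn$center - c(1, 2, 3))^2)), 0.05)
  expect_error(fit_sphere(cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), 0)),
               "degenerate-geometry")
})

test_that("sphere fit error shrinks with sample size at fixed noise", {
  errs <- sapply(c(50, 800), function(n) {
    mean(sapply(1:8, function(s) {
      set.seed(100 + s)
      pts <- sweep(5 * random_unit(n), 2, c(1, 2, 3), "+") +
        matrix(rnorm(3 * n, sd = 0.1), ncol = 3)
      sqrt(sum((fit_sphere(pts)$center - c(1, 2, 3))^2))
    }))
  })
  expect_lt(errs[2], errs[1])
})

test_that("fit_cylinder recovers axis and radius, degrades gracefully with noise", {
  set.seed(22)
  d <- c(0, 0, 1)
  tt <- runif(150, -4, 4); ph <- runif(150, 0, 2 * pi)
  pts <- cbind(2 * cos(ph), 2 * sin(ph), tt)
  f <- fit_cylinder(pts)
  expect_lt(acos(pmin(1, abs(sum(f$axis_direction * d)))), 1e-6)
  expect_equal(f$radius, 2, tolerance = 1e-6)
  # half-shell sampling with noise
  ph2 <- runif(150, 0, pi)
  pts2 <- cbind(2 * cos(ph2), 2 * sin(ph2), runif(150, -4, 4)) +
    matrix(rnorm(450, sd = 0.02), ncol = 3)
  f2 <- fit_cylinder(pts2)
  expect_lt(acos(pmin(1, abs(sum(f2$axis_direction * d)))) * 180 / pi, 1)
  expect_error(fit_cylinder(matrix(1, 10, 3)), "degenerate-geometry")
})

test_that("long-bone ACS recovers the constructed fixture axes", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  prox <- cbind(0, 1.5 * sin(th), 3 * cos(th))    # major axis along z
  dist <- cbind(10, 1.0 * sin(th), 2 * cos(th))
  lm <- landmark_set(prox, dist,
                     reference_points = list(ventral = c(5, 0, -4)))
  a <- build_long_bone_acs(lm, "keep_long_axis", "proximal")
  expect_equal(a$x_axis, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(abs(a$z_axis[3]), 1, tolerance = 1e-9)
  v <- validate_acs(a)
  expect_true(v$pass)
  # ventral reference point must end on the negative z side
  expect_lt(sum((c(5, 0, -4) - a$origin) * a$z_axis), 0)
})

test_that("the retained axis is untouched by orthogonalization", {
  set.seed(23)
  for (i in 1:10) {
    R0 <- random_rotation(); t0 <- rnorm(3, sd = 10)
    fx <- synth_landmarks("long_bone", pose = rigid_transform(R0, t0),
                          seed = 30 + i)
    lm <- fx$landmarks
    mp <- colMeans(lm$proximal_perimeter); md <- colMeans(lm$distal_perimeter)
    long_axis <- (md - mp) / sqrt(sum((md - mp)^2))
    a1 <- build_long_bone_acs(lm, "keep_long_axis", "proximal")
    expect_equal(a1$x_axis, long_axis, tolerance = 1e-12)
    a2 <- build_long_bone_acs(lm, "keep_fe_axis", "distal")
    zfit <- fit_line(lm$distal_perimeter)$direction
    expect_equal(abs(sum(a2$z_axis * zfit)), 1, tolerance = 1e-9)
    expect_true(validate_acs(a1)$pass && validate_acs(a2)$pass)
  }
})

test_that("ACS construction is covariant under rigid motions", {
  fx0 <- synth_landmarks("long_bone", seed = 7)
  a0 <- build_long_bone_acs(fx0$landmarks, "keep_long_axis", "proximal")
  set.seed(24)
  for (i in 1:5) {
    R0 <- random_rotation(); t0 <- rnorm(3, sd = 20)
    fx <- synth_landmarks("long_bone", pose = rigid_transform(R0, t0), seed = 7)
    a <- build_long_bone_acs(fx$landmarks, "keep_long_axis", "proximal")
    expect_equal(a$origin, as.numeric(R0 %*% a0$origin) + t0, tolerance = 1e-9)
    expect_equal(a$x_axis, as.numeric(R0 %*% a0$x_axis), tolerance = 1e-9)
    expect_equal(a$z_axis, as.numeric(R0 %*% a0$z_axis), tolerance = 1e-9)
  }
})

test_that("pelvis and acetabular ACSs follow the mediolateral/pitch construction", {
  pv <- synth_landmarks("pelvis", pitch_deg = 10, yaw_deg = 20, seed = 5)
  res <- build_pelvis_and_acetabular_acs(pv$left_acet, pv$right_acet,
                                         pv$sacral_body, pv$caudal_ref,
                                         up = pv$up)
  expect_equal(res$pelvis$y_axis, pv$truth$pelvis$y_axis, tolerance = 1e-6)
  expect_equal(res$pelvis$origin, pv$truth$pelvis$origin, tolerance = 1e-6)
  # pitch preserved, yaw discarded: X has no mediolateral component and the
  # 10 degree pitch of the generating cylinder
  expect_lt(abs(sum(res$pelvis$x_axis * res$pelvis$y_axis)), 1e-9)
  expect_equal(res$pelvis$x_axis, pv$truth$pelvis$x_axis, tolerance = 1e-5)
  for (nm in c("pelvis", "left_hip", "right_hip")) {
    expect_true(validate_acs(res[[nm]], tol = 1e-9)$pass)
  }
  # acetabular origins at the sphere centroids
  expect_equal(res$right_hip$origin, pv$truth$centers$right, tolerance = 1e-6)
  expect_equal(res$left_hip$origin, pv$truth$centers$left, tolerance = 1e-6)
  # hip LAR axis points laterally on each side
  expect_gt(sum(res$right_hip$x_axis * res$pelvis$y_axis), 0.99)
  expect_lt(sum(res$left_hip$x_axis * res$pelvis$y_axis), -0.99)
})

test_that("coincident acetabular centroids are rejected", {
  pv <- synth_landmarks("pelvis", seed = 6)
  expect_error(
    build_pelvis_and_acetabular_acs(pv$right_acet, pv$right_acet,
                                    pv$sacral_body, pv$caudal_ref),
    "degenerate-geometry")
})

test_that("validate_acs flags perturbed triads and passes repaired ones", {
  a <- romsfp:::new_acs(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_true(validate_acs(a)$pass)
  expect_equal(validate_acs(a)$orthogonality, 0)
  bad <- a
  bad$y_axis <- romsfp:::normalize(c(1e-3, 1, 0))
  expect_false(validate_acs(bad)$pass)
  # Gram-Schmidt repair
  y <- bad$y_axis - sum(bad$y_axis * bad$x_axis) * bad$x_axis
  y <- y / sqrt(sum(y^2))
  fixed <- romsfp:::new_acs(a$origin, bad$x_axis, y,
                            romsfp:::cross3(bad$x_axis, y))
  expect_true(validate_acs(fixed)$pass)
})
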