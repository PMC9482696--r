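test_that("sweep trials respect the torque threshold and recover model extents", {
  mod <- joint_limit_model(semi_axes = c(60, 40, 50))
  tr <- simulate_exvivo_trial(mod, sweep_spec("FAL", c(fe = 2, abad = 2, lar = 2)))
  expect_true(all(tr$torque < mod$torque_threshold))
  ext <- model_axis_extents(mod)          # torque-limited: semi + tau/stiffness
  s <- rom_summary(tr)
  expect_lte(abs(s["FE", "max"] - ext["fe_z", "max"]), 2)
  expect_lte(abs(s["FE", "min"] - ext["fe_z", "min"]), 2)
  expect_lte(abs(s["ABAD", "max"] - ext["abad_y", "max"]), 2)
  expect_lte(abs(s["LAR", "max"] - ext["lar_x", "max"]), 2)
})

test_that("zero torque threshold emits only the center pose", {
  mod <- joint_limit_model(center = c(10, -5, 20), semi_axes = c(60, 40, 50),
                           torque_threshold = 0)
  tr <- simulate_exvivo_trial(mod, sweep_spec("FAL"))
  expect_length(tr, 1)
  expect_equal(unname(matrix_to_euler(tr$rotations[, , 1])), c(10, -5, 20),
               tolerance = 1e-9)
})

test_that("sweep simulation is bit-stable and labeled ex vivo", {
  mod <- joint_limit_preset("knee")
  a <- simulate_exvivo_trial(mod, sweep_spec("ALF", c(fe = 5, abad = 5, lar = 5)))
  b <- simulate_exvivo_trial(mod, sweep_spec("ALF", c(fe = 5, abad = 5, lar = 5)))
  expect_identical(a$rotations, b$rotations)
  expect_identical(a$torque, b$torque)
  expect_identical(a$meta$context, "ex_vivo")
  expect_identical(a$meta$sequence, "ALF")
})

test_that("six-sequence union covers the feasible-set boundary", {
  mod <- joint_limit_model(semi_axes = c(50, 35, 40),
                           coupling = matrix(c(1, .15, .1, .1, 1, .12, 0, .08, 1),
                                             3, 3, byrow = TRUE))
  trials <- simulate_exvivo_protocol(mod, steps = c(fe = 4, abad = 4, lar = 4))
  eul <- do.call(rbind, lapply(trials, function(tr) {
    as.matrix(pose_sequence_euler(tr)[, c("fe_z", "abad_y", "lar_x")])
  }))
  set.seed(51)
  bnd <- sample_model_boundary(mod, 150)
  dmax <- max(vapply(seq_len(nrow(bnd)), function(i) {
    sqrt(min(rowSums(sweep(eul, 2, bnd[i, ])^2)))
  }, 0))
  expect_lt(dmax, 2 * 4 * sqrt(3))  # within two (diagonal) grid steps
})

test_that("strides are periodic, contained, and reproducible", {
  mod <- joint_limit_preset("hip")
  spec <- contained_stride_spec(mod)
  st <- simulate_stride(mod, spec)
  expect_length(st, 401)
  e <- pose_sequence_euler(st)
  expect_lt(max(abs(e[1, 3:5] - e[401, 3:5])), 1)
  expect_identical(st$meta$context, "in_vivo")
  st2 <- simulate_stride(mod, spec)
  expect_identical(st$rotations, st2$rotations)
  # zero amplitude: constant at the mean pose
  flat <- simulate_stride(mod, stride_spec(mean = mod$center,
                                           amplitude = c(0, 0, 0)))
  ef <- pose_sequence_euler(flat)
  expect_equal(unname(as.matrix(ef[, 3:5])),
               matrix(mod$center, 401, 3, byrow = TRUE), tolerance = 1e-9)
  # envelope violation errors
  expect_error(
    simulate_stride(mod, stride_spec(mean = mod$center,
                                     amplitude = c(200, 0, 0))),
    "infeasible-stride")
})

test_that("noisy strides are seeded deterministically", {
  mod <- joint_limit_preset("knee")
  sp <- contained_stride_spec(mod, frac = 0.25, noise_deg = 0.5, seed = 9L)
  a <- simulate_stride(mod, sp); b <- simulate_stride(mod, sp)
  expect_identical(a$rotations, b$rotations)
})

test_that("landmark fixtures recover their ground truth, noiseless and noisy", {
  fx <- synth_landmarks("long_bone", seed = 3)
  a <- build_long_bone_acs(fx$landmarks, "keep_long_axis", "proximal")
  expect_lt(max(abs(a$x_axis - fx$truth$proximal$x_axis)), 1e-6)
  expect_lt(max(abs(a$z_axis - fx$truth$proximal$z_axis)), 1e-6)
  expect_lt(max(abs(a$origin - fx$truth$proximal$origin)), 1e-6)
  # sigma = 0.1 mm noise: axis errors under 2 degrees
  fxn <- synth_landmarks("long_bone", noise_sd = 0.1, seed = 4)
  an <- build_long_bone_acs(fxn$landmarks, "keep_long_axis", "proximal")
  expect_lt(geodesic_angle(an$x_axis, fxn$truth$proximal$x_axis), 2)
  expect_lt(geodesic_angle(an$z_axis, fxn$truth$proximal$z_axis), 2)
  # pelvis: sphere centers recovered exactly without noise
  pv <- synth_landmarks("pelvis", seed = 5)
  res <- build_pelvis_and_acetabular_acs(pv$left_acet, pv$right_acet,
                                         pv$sacral_body, pv$caudal_ref,
                                         up = pv$up)
  expect_lt(max(abs(res$primitives$right_sphere$center - pv$truth$centers$right)),
            1e-6)
  expect_lt(max(abs(res$primitives$left_sphere$center - pv$truth$centers$left)),
            1e-6)
})

test_that("marker trials round-trip through pose recovery", {
  set.seed(52)
  tmpl <- marker_template(matrix(rnorm(21), 7, 3) * 30)
  e <- cbind(seq(-40, 40, by = 2), 10, -20)
  s <- pose_sequence(romsfp:::euler_to_matrix_many(e), rate_hz = 30)
  trial <- synth_marker_trial(tmpl, s)
  rec <- recover_pose_sequence(trial)
  expect_length(rec$dropped, 0)
  for (i in seq_len(length(s))) {
    expect_lt(max(abs(rec$sequence$rotations[, , i] - s$rotations[, , i])), 1e-9)
  }
  # noisy: mean rotation error below half a degree
  trial_n <- synth_marker_trial(tmpl, s, noise_mm = 0.1, seed = 8)
  rec_n <- recover_pose_sequence(trial_n)
  errs <- vapply(seq_len(length(s)), function(i) {
    geodesic_angle(rec_n$sequence$rotations[, , i], s$rotations[, , i])
  }, 0)
  expect_lt(mean(errs), 0.5)
  # occlusion: 3 visible still solvable, 2 visible dropped
  trial_o <- synth_marker_trial(tmpl, s)
  trial_o$positions[1:4, , 5] <- NA
  rec_o <- recover_pose_sequence(trial_o)
  expect_length(rec_o$dropped, 0)
  trial_o$positions[5, , 5] <- NA
  rec_o2 <- recover_pose_sequence(trial_o)
  expect_equal(rec_o2$dropped, 5L)
})

test_that("an in-model stride lies wholly inside the dense ex vivo pose space", {
  mod <- joint_limit_model(center = c(-10, 0, -30), semi_axes = c(55, 45, 50),
                           coupling = matrix(c(1, .15, .1, .1, 1, .12, 0, .08, 1),
                                             3, 3, byrow = TRUE))
  trials <- simulate_exvivo_protocol(mod, steps = c(fe = 5, abad = 5, lar = 5))
  regs <- sfp_regions(pool_specimens(lapply(trials, project_sfp)))
  st <- simulate_stride(mod, contained_stride_spec(mod))
  cmp <- compare_invivo_exvivo(project_sfp(st), regs)
  expect_equal(unname(cmp$inside_fraction), c(1, 1, 1))
})
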