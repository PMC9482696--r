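make_template <- function(n = 7, seed = 42, scale = 30) {
  set.seed(seed)
  marker_template(matrix(rnorm(3 * n), n, 3) * scale)
}

test_that("pose_from_markers recovers exact rigid transforms", {
  tmpl <- make_template()
  res <- pose_from_markers(tmpl, tmpl$reference_positions)
  expect_equal(res$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(res$transform$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(res$rmsd, 0, tolerance = 1e-9)
  set.seed(43)
  for (i in 1:10) {
    R0 <- random_rotation(); t0 <- rnorm(3, sd = 50)
    obs <- sweep(tmpl$reference_positions %*% t(R0), 2, t0, "+")
    res <- pose_from_markers(tmpl, obs)
    expect_equal(res$transform$rotation, R0, tolerance = 1e-9)
    expect_equal(res$transform$translation, t0, tolerance = 1e-9)
  }
})

test_that("pose recovery under marker noise stays below half a degree", {
  tmpl <- make_template()
  set.seed(44)
  errs <- sapply(1:50, function(i) {
    R0 <- random_rotation()
    obs <- tmpl$reference_positions %*% t(R0) +
      matrix(rnorm(21, sd = 0.1), ncol = 3)
    res <- pose_from_markers(tmpl, obs)
    geodesic_angle(res$transform$rotation, R0)
  })
  expect_lt(mean(errs), 0.5)
})

test_that("the marker solution is globally optimal and invariant to ordering", {
  tmpl <- make_template()
  set.seed(45)
  R0 <- random_rotation()
  obs <- tmpl$reference_positions %*% t(R0) +
    matrix(rnorm(21, sd = 0.5), ncol = 3)
  res <- pose_from_markers(tmpl, obs)
  rmsd_of <- function(R) {
    cr <- colMeans(tmpl$reference_positions); co <- colMeans(obs)
    t_ <- co - as.numeric(R %*% cr)
    fit <- sweep(tmpl$reference_positions %*% t(R), 2, t_, "+")
    sqrt(mean(rowSums((fit - obs)^2)))
  }
  for (i in 1:100) expect_lte(res$rmsd, rmsd_of(random_rotation()) + 1e-12)
  # permutation invariance (template and observations permuted together)
  perm <- sample(7)
  tmpl_p <- marker_template(tmpl$reference_positions[perm, ])
  res_p <- pose_from_markers(tmpl_p, obs[perm, ])
  expect_equal(res_p$transform$rotation, res$transform$rotation,
               tolerance = 1e-9)
  # uniform translation of the frame shifts only the translation
  res_t <- pose_from_markers(tmpl, sweep(obs, 2, c(10, -20, 5), "+"))
  expect_equal(res_t$transform$rotation, res$transform$rotation,
               tolerance = 1e-9)
})

test_that("degenerate marker configurations are rejected", {
  tmpl <- make_template()
  obs <- tmpl$reference_positions
  obs[1:5, ] <- NA
  expect_error(pose_from_markers(tmpl, obs), "insufficient-markers")
  expect_error(marker_template(outer(1:5, c(1, 1, 0))), "collinear")
  expect_error(marker_template(matrix(rnorm(6), 2, 3)), "insufficient-markers")
})

test_that("compose_chain agrees with the homogeneous-matrix oracle", {
  expect_equal(compose_chain(rigid_transform(), rigid_transform(),
                             rigid_transform())$rotation, diag(3))
  set.seed(46)
  tfs <- lapply(1:3, function(i) rigid_transform(random_rotation(), rnorm(3)))
  hom <- function(tf) rbind(cbind(tf$rotation, tf$translation), c(0, 0, 0, 1))
  H <- hom(tfs[[1]]) %*% hom(tfs[[2]]) %*% hom(tfs[[3]])
  chained <- compose_chain(tfs[[1]], tfs[[2]], tfs[[3]])
  expect_equal(chained$rotation, H[1:3, 1:3], tolerance = 1e-12)
  expect_equal(chained$translation, H[1:3, 4], tolerance = 1e-12)
  # associativity
  ab_c <- compose_chain(compose_chain(tfs[[1]], tfs[[2]]), tfs[[3]])
  a_bc <- compose_chain(tfs[[1]], compose_chain(tfs[[2]], tfs[[3]]))
  expect_equal(ab_c$rotation, a_bc$rotation, tolerance = 1e-12)
  expect_equal(ab_c$translation, a_bc$translation, tolerance = 1e-12)
  # chain then inverse chain
  inv <- compose_chain(invert_transform(tfs[[3]]), invert_transform(tfs[[2]]),
                       invert_transform(tfs[[1]]))
  round_trip <- compose_chain(chained, inv)
  expect_equal(round_trip$rotation, diag(3), tolerance = 1e-12)
  expect_equal(round_trip$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_error(compose_chain(rigid_transform(), list()), "invalid-transform")
})

test_that("detect_pose_jumps flags exactly the injected discontinuities", {
  e <- cbind(seq(0, 99), 0, 0)          # smooth 1 degree per frame sweep
  s <- pose_sequence(romsfp:::euler_to_matrix_many(e), rate_hz = 30)
  expect_equal(nrow(detect_pose_jumps(s, 10)), 0)
  e2 <- e
  e2[50:100, 1] <- e2[50:100, 1] + 30   # 30 degree jump entering frame 50
  s2 <- pose_sequence(romsfp:::euler_to_matrix_many(e2), rate_hz = 30)
  flags <- detect_pose_jumps(s2, 10)
  expect_equal(flags$frame, 50)
  expect_equal(flags$step_deg, 31, tolerance = 1e-9)
  one <- pose_sequence(diag(3))
  expect_equal(nrow(detect_pose_jumps(one, 10)), 0)
})

test_that("trial sufficiency needs all three planar and two clean interaction trials", {
  smooth_seq <- function(label, jump = FALSE) {
    e <- cbind(seq(0, 30, by = 1), 0, 0)
    if (jump) e[20:31, 1] <- e[20:31, 1] + 40
    pose_sequence(romsfp:::euler_to_matrix_many(e), rate_hz = 30,
                  sequence = label)
  }
  planars <- lapply(c("planar-FE", "planar-ABAD", "planar-LAR"), smooth_seq)
  good <- filter_sufficient_trials(c(planars, lapply(c("FAL", "LFA"), smooth_seq)))
  expect_true(good$sufficient)
  expect_length(good$kept, 5)
  one_int <- filter_sufficient_trials(c(planars, list(smooth_seq("FAL"))))
  expect_false(one_int$sufficient)
  # three interaction trials, two damaged: only one survives
  damaged <- filter_sufficient_trials(c(planars,
    list(smooth_seq("FAL"), smooth_seq("ALF", jump = TRUE),
         smooth_seq("LFA", jump = TRUE))))
  expect_false(damaged$sufficient)
  expect_length(damaged$rejected, 2)
  # a damaged planar trial also breaks sufficiency
  bad_planar <- filter_sufficient_trials(c(
    lapply(c("planar-FE", "planar-ABAD"), smooth_seq),
    list(smooth_seq("planar-LAR", jump = TRUE),
         smooth_seq("FAL"), smooth_seq("LFA"))))
  expect_false(bad_planar$sufficient)
  unl <- smooth_seq("FAL"); unl$meta$sequence <- "mystery"
  expect_error(filter_sufficient_trials(list(unl)), "missing-label")
})
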