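seq_from_euler <- function(e, ...) {
  pose_sequence(romsfp:::euler_to_matrix_many(as.matrix(e)), rate_hz = 30, ...)
}

test_that("rom_summary reports extrema, ranges and concomitant angles", {
  # constant sequence: all ranges zero
  s0 <- seq_from_euler(rbind(c(12, -5, 40), c(12, -5, 40)))
  r0 <- rom_summary(s0)
  expect_equal(r0$range, c(0, 0, 0))
  expect_equal(r0$max, r0$min)
  # synthetic sweep with known limits
  s1 <- seq_from_euler(cbind(seq(-40, 70, by = 1), 0, 0))
  r1 <- rom_summary(s1)
  expect_equal(r1["FE", "max"], 70, tolerance = 1e-9)
  expect_equal(r1["FE", "min"], -40, tolerance = 1e-9)
  expect_equal(r1["FE", "range"], 110, tolerance = 1e-9)
  # concomitant angles come from the extremal frame
  e2 <- rbind(c(-10, 3, -36), c(31, -7, -133), c(5, 20, -80))
  r2 <- rom_summary(seq_from_euler(e2))
  expect_equal(r2["LAR", "max"], -36, tolerance = 1e-7)
  expect_equal(r2["LAR", "fe_at_max"], -10, tolerance = 1e-7)
  expect_equal(r2["LAR", "abad_at_max"], 3, tolerance = 1e-7)
  expect_equal(r2["LAR", "fe_at_min"], 31, tolerance = 1e-7)
})

test_that("rom_summary is invariant to frame order and breaks ties earliest", {
  set.seed(41)
  e <- cbind(runif(30, -80, 40), runif(30, -50, 50), runif(30, -120, 0))
  a <- rom_summary(seq_from_euler(e))
  b <- rom_summary(seq_from_euler(e[sample(30), ]))
  expect_equal(a$max, b$max, tolerance = 1e-9)
  expect_equal(a$min, b$min, tolerance = 1e-9)
  expect_equal(a$range, b$range, tolerance = 1e-9)
  # duplicate extreme: earliest frame wins
  e_tie <- rbind(c(50, 1, 2), c(10, 3, 4), c(50, 5, 6))
  r <- rom_summary(seq_from_euler(e_tie))
  expect_equal(r["FE", "frame_at_max"], 1)
  expect_equal(r["FE", "abad_at_max"], 1, tolerance = 1e-7)
})

test_that("table rounding is half-away-from-zero with range from unrounded extrema", {
  expect_equal(romsfp:::round_half_away(c(0.5, -0.5, 1.5, -1.5, 2.4)),
               c(1, -1, 2, -2, 2))
  # unrounded extrema 28.6 / -85.6: rounded cells 29 / -86, but the range
  # rounds from 114.2 to 114 (not 29 - (-86) = 115)
  s <- seq_from_euler(rbind(c(28.6, 6, -73), c(-85.6, 24, -97)))
  tab <- rom_table(rom_summary(s), specimen = "demo")
  fe <- tab[tab$axis == "FE", ]
  expect_equal(fe$max, 29)
  expect_equal(fe$min, -86)
  expect_equal(fe$range, 114)
  expect_lte(abs(fe$range - (fe$max - fe$min)), 1)
})

test_that("published hip worked example: Sal10 FE range is 114", {
  ref <- salamander_rom_reference()
  sal10 <- ref[ref$specimen == "Sal10" & ref$axis == "FE", ]
  s <- seq_from_euler(rbind(
    c(sal10$max_fe, sal10$max_abad, sal10$max_lar),
    c(sal10$min_fe, sal10$min_abad, sal10$min_lar)))
  tab <- rom_table(rom_summary(s))
  fe <- tab[tab$axis == "FE", ]
  expect_equal(fe$max, 29)
  expect_equal(fe$min, -85)
  expect_equal(fe$range, 114)
  expect_equal(sal10$printed_range, 114)
})

test_that("mirror-then-summarise equals the sign map on the summary", {
  set.seed(42)
  e <- cbind(runif(40, -80, 40), runif(40, -50, 50), runif(40, -120, 0))
  s <- seq_from_euler(e, side = "left")
  direct <- rom_summary(s)
  mirrored <- rom_summary(mirror_sequence(s))
  # fe and lar negate (max/min swap), abad unchanged
  expect_equal(mirrored["FE", "max"], -direct["FE", "min"], tolerance = 1e-7)
  expect_equal(mirrored["FE", "min"], -direct["FE", "max"], tolerance = 1e-7)
  expect_equal(mirrored["LAR", "max"], -direct["LAR", "min"], tolerance = 1e-7)
  expect_equal(mirrored["ABAD", "max"], direct["ABAD", "max"], tolerance = 1e-7)
  expect_equal(mirrored["FE", "range"], direct["FE", "range"], tolerance = 1e-7)
})

test_that("compare_invivo_exvivo counts inside fractions and null-pose reachability", {
  # ex vivo: broad grid around the null pose
  g <- as.matrix(expand.grid(fe = seq(-50, 50, by = 5),
                             abad = seq(-35, 35, by = 5),
                             lar = seq(-40, 40, by = 10)))
  ex <- project_sfp(seq_from_euler(g, joint = "hip", side = "right",
                                   specimen = "ex"))
  regs <- sfp_regions(ex)
  # in vivo strictly inside
  t_ <- seq(0, 1, length.out = 100)
  inv_e <- cbind(30 * sin(2 * pi * t_), 20 * cos(2 * pi * t_),
                 25 * sin(2 * pi * t_ + 1))
  inv <- project_sfp(seq_from_euler(inv_e, joint = "hip", side = "right",
                                    specimen = "in"))
  cmp <- compare_invivo_exvivo(inv, regs)
  expect_equal(unname(cmp$inside_fraction), c(1, 1, 1))
  expect_true(cmp$null_pose_reachable)
  # displace 5% of frames far outside
  inv_e2 <- inv_e
  inv_e2[1:5, 1] <- 170
  cmp2 <- compare_invivo_exvivo(
    project_sfp(seq_from_euler(inv_e2, joint = "hip", side = "right")), regs)
  expect_equal(cmp2$inside_fraction[["x"]], 0.95)
  expect_equal(cmp2$outside_frames$x, 1:5)
  # ex vivo region far from the null pose: identity tips excluded
  g3 <- as.matrix(expand.grid(fe = seq(-40, 40, by = 10),
                              abad = seq(-30, 30, by = 10),
                              lar = seq(-150, -60, by = 10)))
  regs3 <- sfp_regions(project_sfp(seq_from_euler(g3, joint = "hip",
                                                  side = "right")))
  cmp3 <- compare_invivo_exvivo(inv, regs3)
  expect_false(cmp3$null_pose_reachable)
})

test_that("range ratios divide in vivo by the pooled ex vivo range", {
  ex1 <- rom_summary(seq_from_euler(cbind(seq(-60, 20, 10), 0, 0)))
  ex2 <- rom_summary(seq_from_euler(cbind(seq(-20, 60, 10), 0, 0)))
  inv <- rom_summary(seq_from_euler(cbind(seq(-30, 30, 10), 0, 0)))
  g <- as.matrix(expand.grid(seq(-60, 60, 20), seq(-10, 10, 5), seq(-10, 10, 5)))
  regs <- sfp_regions(project_sfp(seq_from_euler(g)))
  cmp <- compare_invivo_exvivo(project_sfp(seq_from_euler(cbind(seq(-30, 30, 10), 0, 0))),
                               regs, inv, list(ex1, ex2))
  expect_equal(cmp$range_ratio[["FE"]], 60 / 120, tolerance = 1e-9)
})
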