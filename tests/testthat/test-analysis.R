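# Depth-dose extraction, normalization, beam mixing, angle combination,
# DVHs and profile deviation.

test_that("depth_profile averages the 5 mm cylinder per depth slab", {
  d <- fake_dose(3e-12, size = 2, voxel = 0.2)
  pr <- depth_profile(d, "z", 0.5)
  expect_true(all(abs(pr$dose - 3e-12) < 1e-20))   # uniform -> flat

  # dose only outside the cylinder -> all-zero profile
  g <- make_slab_phantom("water", 2, 0.2)
  arr <- array(0, g$dims)
  arr[1, , ] <- 5e-12                               # lateral edge column
  pr2 <- depth_profile(dose_grid(arr, g, 1), "z", 0.5)
  expect_true(all(pr2$dose == 0))

  # a linear ramp along depth is reproduced at voxel centers
  ramp <- array(rep(seq_len(10), each = 100), c(10, 10, 10))
  pr3 <- depth_profile(dose_grid(ramp * 1e-12, g, 1), "z", 0.5)
  expect_equal(pr3$dose, seq_len(10) * 1e-12, tolerance = 1e-9)
})

test_that("tiny integration radius falls back to the axial column with a warning", {
  d <- fake_dose(1e-12, size = 2, voxel = 0.2)
  expect_warning(pr <- depth_profile(d, "z", radius = 0.01), "single axial")
  expect_equal(length(pr$dose), 10)
})

test_that("normalize_at_dmax is idempotent, scale-invariant, and refines the vertex", {
  y <- exp(-(seq(0.1, 3.9, 0.2) - 2.07)^2)
  p <- depth_profile_curve(seq(0.1, 3.9, 0.2), y)
  n1 <- normalize_at_dmax(p)
  expect_equal(max(n1$dose), 1)
  n2 <- normalize_at_dmax(n1)
  expect_equal(n2$dose, n1$dose)
  n3 <- normalize_at_dmax(depth_profile_curve(p$depth, 7.3 * y))
  expect_equal(n3$dose, n1$dose)
  # discrete parabola peaking between samples: vertex between voxel centers
  yq <- 1 - (p$depth - 2.03)^2
  nq <- normalize_at_dmax(depth_profile_curve(p$depth, pmax(yq, 0)))
  expect_equal(nq$dmax_depth, 2.03, tolerance = 1e-6)
  expect_error(normalize_at_dmax(depth_profile_curve(1:3, c(0, 0, 0))),
               "all-zero")
})

test_that("shift_profile translates depth only and composes to identity", {
  p <- normalize_at_dmax(depth_profile_curve(1:10, c(1:5, 5:1)))
  expect_equal(shift_profile(p, 0), p)
  expect_equal(shift_profile(shift_profile(p, 0.5), -0.5), p)
  s <- shift_profile(p, 0.5)
  expect_equal(s$dmax_depth, p$dmax_depth + 0.5)
  expect_equal(s$dose, p$dose)
})

test_that("mix_beams rescales each component to its prescription share", {
  d1 <- fake_dose(2e-12); d2 <- fake_dose(4e-12)
  one <- mix_beams(list(d1, d2), c(2e-12, 4e-12), c(1, 0), prescription = 10)
  expect_equal(one$dose, array(10, dim(d1$dose)))
  halves <- mix_beams(list(d1, d1), c(2e-12, 2e-12), c(0.5, 0.5),
                      prescription = 10)
  full <- mix_beams(list(d1), c(2e-12), 1, prescription = 10)
  expect_equal(halves$dose, full$dose, tolerance = 1e-12)
  expect_error(mix_beams(list(d1), c(0), 1), "zero d_max")
  expect_error(mix_beams(list(d1, d2), c(1e-12, 1e-12), c(0.5, 0.6)),
               "sum to 1")
})

test_that("the 80/20 electron mix equals the weighted sum of normalized components", {
  # distinct 6 and 12 MeV-like depth shapes on the same grid
  g <- make_slab_phantom("water", 2, 0.2)
  z <- rep(seq_len(10), each = 100)
  p6 <- array(exp(-(z - 3)^2 / 4) * 1e-12, g$dims)
  p12 <- array(exp(-(z - 6)^2 / 8) * 2e-12, g$dims)
  d6 <- dose_grid(p6, g, 1); d12 <- dose_grid(p12, g, 1)
  mixed <- mix_beams(list(d6, d12), c(max(p6), max(p12)), c(0.8, 0.2))
  want <- 0.8 * p6 / max(p6) + 0.2 * p12 / max(p12)
  expect_equal(mixed$dose, want, tolerance = 1e-12)
})

test_that("combine_angles is an exact weighted sum keyed by angle", {
  d0 <- fake_dose(1e-12); d90 <- fake_dose(2e-12)
  d180 <- fake_dose(3e-12); d270 <- fake_dose(4e-12)
  ds <- list("0" = d0, "90" = d90, "180" = d180, "270" = d270)
  one <- combine_angles(ds, c("90" = 1))
  expect_equal(one$dose, d90$dose)
  # 70% LATS (0/180) + 30% APPA (90/270) as per-angle weights
  w <- c("0" = 0.35, "180" = 0.35, "90" = 0.15, "270" = 0.15)
  got <- combine_angles(ds, w)
  lats <- (d0$dose + d180$dose) / 2
  appa <- (d90$dose + d270$dose) / 2
  expect_equal(got$dose, 0.7 * lats + 0.3 * appa, tolerance = 1e-12)
  expect_error(combine_angles(ds[1:2], c("0" = 0.5, "270" = 0.5)), "missing")
  expect_error(combine_angles(ds, c("0" = 0.7, "90" = 0.7)), "sum to 1")
})

test_that("DVHs reproduce the step, plateau and uniform-random references", {
  g <- make_slab_phantom("water", 2, 0.2)
  mask <- structure_mask("m", array(TRUE, g$dims))
  D <- 4
  uni <- dose_grid(array(D, g$dims), g, 1)
  dvh <- compute_dvh(uni, mask, bin_width = 0.1)
  expect_equal(dvh$volume_fraction[dvh$dose_edges <= D],
               rep(1, sum(dvh$dose_edges <= D)))
  expect_equal(dvh$volume_fraction[dvh$dose_edges > D],
               rep(0, sum(dvh$dose_edges > D)))

  half <- array(0, g$dims); half[, , 1:5] <- D
  dvh2 <- compute_dvh(dose_grid(half, g, 1), mask, bin_width = 0.1)
  mid <- dvh2$dose_edges > 0 & dvh2$dose_edges <= D
  expect_equal(dvh2$volume_fraction[mid], rep(0.5, sum(mid)))
  expect_equal(dvh2$volume_fraction[1], 1)

  set.seed(31)
  gbig <- make_slab_phantom("water", 5, 0.1)
  vals <- array(runif(prod(gbig$dims), 0, D), gbig$dims)
  dvh3 <- compute_dvh(dose_grid(vals, gbig, 1),
                      structure_mask("m", array(TRUE, gbig$dims)))
  want <- pmax(1 - dvh3$dose_edges / D, 0)
  expect_lt(max(abs(dvh3$volume_fraction - want)), 0.01)
  expect_error(compute_dvh(uni, structure_mask("e", array(FALSE, g$dims))),
               "empty")
})

test_that("DVHs are monotone with correct endpoints on random dose fields", {
  g <- make_slab_phantom("water", 2, 0.2)
  set.seed(17)
  for (k in 1:5) {
    vals <- array(rexp(prod(g$dims)) * 10^runif(1, -13, -11), g$dims)
    dvh <- compute_dvh(dose_grid(vals, g, 1),
                       structure_mask("m", array(runif(prod(g$dims)) < 0.5,
                                                 g$dims)))
    expect_true(all(diff(dvh$volume_fraction) <= 1e-12))
    expect_equal(dvh$volume_fraction[1], 1)
    expect_lt(dvh$volume_fraction[length(dvh$volume_fraction)], 1e-12)
  }
  # mean-dose identity on a full mask
  vals <- array(runif(prod(g$dims)), g$dims)
  mask <- structure_mask("m", array(TRUE, g$dims))
  dvh <- compute_dvh(dose_grid(vals, g, 1), mask, bin_width = 0.002)
  expect_lt(abs(dvh_mean_dose(dvh) - mean(vals)), 0.001)
})

test_that("profile_deviation matches its closed-form examples", {
  p1 <- normalize_at_dmax(depth_profile_curve(1:10, c(1:5, 5:1)))
  expect_equal(profile_deviation(list(p1, p1)), 0)
  # values 1.00 and 1.02 at the evaluation point
  a <- depth_profile_curve(1:5, rep(1.00, 5))
  b <- depth_profile_curve(1:5, rep(1.02, 5))
  expect_equal(profile_deviation(list(a, b), at = 3), 0.02 / 1.02,
               tolerance = 1e-9)
  # scaled copies coincide after normalization
  p2 <- normalize_at_dmax(depth_profile_curve(1:10, 3.7 * c(1:5, 5:1)))
  expect_equal(profile_deviation(list(p1, p2)), 0)
  expect_error(profile_deviation(list(p1)), ">= 2")
  far <- depth_profile_curve(100:110, rep(1, 11))
  expect_error(profile_deviation(list(p1, far)), "disjoint")
})

test_that("curve CSV exports round-trip", {
  p <- depth_profile_curve(c(0.1, 0.2, 0.3), c(1, 2, 1))
  f <- tempfile(fileext = ".csv")
  write_curve_csv(p, f)
  p2 <- read_depth_dose_csv(f)
  expect_equal(p2$depth, p$depth)
  expect_equal(p2$dose, p$dose)
  dvh <- structure(list(dose_edges = c(0, 1), volume_fraction = c(1, 0)),
                   class = "dvh_curve")
  f2 <- tempfile(fileext = ".csv")
  write_curve_csv(dvh, f2)
  expect_true(file.exists(f2))
  tab <- dvh_long_table(list(eyes = dvh, lungs = dvh))
  expect_equal(nrow(tab), 4)
  expect_equal(unique(tab$structure), c("eyes", "lungs"))
})
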