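# Condensed-history transport: conservation, determinism, range fidelity
# and batch statistics.

# total deposited energy in MeV per history
.edep_mev <- function(dg, grid) {
  sum(dg$dose * grid$density) * prod(grid$spacing) * 1e-3 /
    1.602176634e-13
}

test_that("air-only voxels receive negligible dose compared to water", {
  air_grid <- voxel_grid(c(-1, -1, 0), rep(0.2, 3),
                         array(1L, c(10, 10, 10)),
                         array(get_material("air")$density, c(10, 10, 10)),
                         "air")
  beam <- beam_spec("proton", spectrum = spectrum(50, 1), axis = "+z",
                    field = c(0.5, 0.5))
  cfg <- transport_config(n_histories = 100)
  d_air <- run_transport(air_grid, beam, cfg, seed = 1)
  water_grid <- make_slab_phantom("water", 2, 0.2)
  d_wat <- run_transport(water_grid, beam, cfg, seed = 1)
  # energy deposited crossing 2 cm of air is ~rho_air/rho_water of the
  # same water path (about 1e-3)
  expect_lt(.edep_mev(d_air, air_grid), 2e-3 * .edep_mev(d_wat, water_grid))
})

test_that("energy is conserved exactly with straggling and scattering disabled", {
  cube <- make_slab_phantom("water", 6, 0.1)
  cfg <- transport_config(n_histories = 200, straggling = FALSE,
                          scattering = FALSE, radiative = FALSE)
  for (pb in list(
    beam_spec("proton", spectrum = spectrum(50, 1), axis = "+z",
              field = c(1, 1)),
    beam_spec("electron", energy = 6.02, spread = 0, axis = "+z",
              parallel = TRUE, field = c(1, 1)))) {
    dg <- run_transport(cube, pb, cfg, seed = 3, field = c(1, 1))
    e0 <- if (pb$particle == "proton") 50 else 6.02
    # .edep_mev is already per history (dose is per source particle)
    expect_lt(abs(.edep_mev(dg, cube) - e0) / e0, 1e-3)
  }
})

test_that("zero histories give an all-zero dose grid", {
  cube <- make_slab_phantom("water", 2, 0.2)
  beam <- beam_spec("proton", spectrum = spectrum(50, 1), axis = "+z")
  dg <- run_transport(cube, beam, transport_config(n_histories = 0))
  expect_true(all(dg$dose == 0))
  expect_equal(dg$histories, 0)
})

test_that("the same seed reproduces bitwise-identical dose", {
  cube <- make_slab_phantom("water", 4, 0.2)
  beam <- beam_spec("proton", spectrum = spectrum(40, 1), axis = "+z")
  cfg <- transport_config(n_histories = 500)
  d1 <- run_transport(cube, beam, cfg, seed = 11)
  d2 <- run_transport(cube, beam, cfg, seed = 11)
  expect_identical(d1$dose, d2$dose)
  d3 <- run_transport(cube, beam, cfg, seed = 12)
  expect_false(identical(d3$dose, d1$dose))
})

test_that("deterministic proton stopping depth matches the CSDA oracle", {
  cube <- make_slab_phantom("water", 6, 0.05)
  beam <- beam_spec("proton", spectrum = spectrum(50, 1), axis = "+z",
                    field = c(0.3, 0.3))
  cfg <- transport_config(n_histories = 30, straggling = FALSE,
                          scattering = FALSE)
  dg <- run_transport(cube, beam, cfg, seed = 2)
  zprof <- apply(dg$dose, 3, sum)
  stop_depth <- (max(which(zprof > 0)) - 0.5) * 0.05
  oracle <- csda_range(water(), "proton", 50)
  expect_lt(abs(stop_depth - oracle) / oracle, 0.02)
})

test_that("proton depth dose shows a Bragg peak with a sharp distal falloff", {
  cube <- make_slab_phantom("water", 6, 0.1)
  beam <- beam_spec("proton", spectrum = spectrum(50, 1), axis = "+z",
                    field = c(1.0, 1.0))
  dg <- run_transport(cube, beam, transport_config(n_histories = 3000),
                      seed = 4)
  pr <- depth_profile(dg, "z", 0.5)
  pk <- which.max(pr$dose)
  expect_gt(pr$dose[pk], 2 * pr$dose[2])        # entrance << peak
  beyond <- pr$depth > pr$depth[pk] + 0.3
  expect_lt(max(pr$dose[beyond]), 0.01 * pr$dose[pk])
})

test_that("combine_batches reproduces the two-point formulas and scales sem", {
  g <- make_slab_phantom("water", 1, 0.2)
  mk <- function(v) dose_grid(array(v, g$dims), g, histories = 10)
  D <- 2e-12
  same <- combine_batches(list(mk(D), mk(D)))
  expect_equal(same$dose, array(D, g$dims))
  expect_true(all(same$sem == 0))
  expect_equal(same$histories, 20)

  two <- combine_batches(list(mk(D), mk(3 * D)))
  expect_equal(two$dose, array(2 * D, g$dims))
  expect_equal(two$sem, array(D / sqrt(2), g$dims), tolerance = 1e-12)

  expect_error(combine_batches(list(mk(D))), ">= 2")
  g2 <- make_slab_phantom("water", 1, 0.1)
  expect_error(combine_batches(list(mk(D),
                                    dose_grid(array(D, g2$dims), g2, 10))),
               "aligned")
})

test_that("batch sem shrinks like 1/sqrt(n) under regrouping", {
  cube <- make_slab_phantom("water", 3, 0.3)
  beam <- beam_spec("proton", spectrum = spectrum(25, 1), axis = "+z",
                    field = c(1, 1))
  cfg <- transport_config(n_histories = 400)
  batches <- lapply(1:10, function(s) run_transport(cube, beam, cfg, seed = s))
  all10 <- combine_batches(batches)
  pairs <- lapply(seq(1, 10, 2), function(i)
    combine_batches(batches[c(i, i + 1)]))
  five <- combine_batches(lapply(pairs, function(p) {
    p$sem <- NULL; p
  }))
  hot <- all10$dose > 0.2 * max(all10$dose)
  ratio <- mean(five$sem[hot]) / mean(all10$sem[hot])
  # sem over 5 pair-means vs 10 singles: same underlying variance, so the
  # standard errors should agree within statistical scatter
  expect_gt(ratio, 0.6); expect_lt(ratio, 1.6)
})

test_that("run_batches attaches sem and sums histories", {
  cube <- make_slab_phantom("water", 2, 0.2)
  beam <- beam_spec("proton", spectrum = spectrum(30, 1), axis = "+z",
                    field = c(0.8, 0.8))
  dg <- run_batches(cube, beam,
                    transport_config(n_histories = 300, n_batches = 3,
                                     base_seed = 5))
  expect_false(is.null(dg$sem))
  expect_equal(dg$histories, 900)
  expect_true(all(dg$sem >= 0))
})
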