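# Material definitions, HU conversion and the charged-particle physics
# primitives (stopping power, range, scattering, straggling).

test_that("built-in materials satisfy their invariants", {
  lib <- material_library()
  expect_true(all(c("water", "air", "solid_water", "PMMA", "soft_tissue",
                    "adipose", "muscle", "lung", "bone") %in% names(lib)))
  for (m in lib) {
    expect_lt(abs(sum(m$composition) - 1), 1e-6)
    expect_gt(m$density, 0)
    expect_gt(m$I_eV, 0)
    expect_gt(m$X0, 0)
  }
  # the solid-water vendor composition is carried exactly
  sw <- lib$solid_water
  expect_equal(unname(sw$composition[c("H", "C", "Ca")]),
               c(0.0809, 0.6717, 0.0231))
  expect_equal(sw$density, 1.04)
  # water's standard mean excitation energy
  expect_equal(lib$water$I_eV, 75)
})

test_that("material() rejects invalid compositions", {
  expect_error(material("x", c(H = 0.5, O = 0.4), 1), "sum to 1")
  expect_error(material("x", c(H = 0.5, Xx = 0.5), 1), "unknown element")
  expect_error(material("x", c(H = 0.1119, O = 0.8881), -1), "density")
})

test_that("proton stopping power decreases over the SPE band and scales with density", {
  w <- water()
  s <- collision_stopping_power(w, "proton", c(20, 40, 60, 80))
  expect_true(all(diff(s) < 0))
  # exact linear density scaling at fixed composition
  w2 <- material("water2", w$composition, 2 * w$density, I_eV = w$I_eV)
  expect_equal(collision_stopping_power(w2, "proton", 50),
               2 * collision_stopping_power(w, "proton", 50))
  # vacuum-like density limit
  w0 <- material("thin", w$composition, 1e-9, I_eV = w$I_eV)
  expect_lt(collision_stopping_power(w0, "proton", 50), 1e-7)
  expect_error(collision_stopping_power(w, "proton", -5), "positive")
  expect_error(collision_stopping_power(w, "proton", 0.001), "validity floor")
})

test_that("csda_range is zero at zero, strictly increasing, and Bragg-Kleeman-like", {
  w <- water()
  expect_equal(csda_range(w, "proton", 0), 0)
  E <- seq(20, 80, 5)
  r <- csda_range(w, "proton", E)
  expect_true(all(diff(r) > 0))
  # fit R = alpha E^p to the table itself; the power law should describe
  # the numeric integral to within 3% over the SPE band
  fit <- stats::lm(log(r) ~ log(E))
  rel <- abs(exp(fitted(fit)) - r) / r
  expect_lt(max(rel), 0.03)
  # exponent in the known ballpark for protons in water
  p <- unname(coef(fit)[2])
  expect_gt(p, 1.6); expect_lt(p, 1.9)
})

test_that("Highland scattering sigma has the expected step and energy behavior", {
  w <- water()
  s1 <- scattering_sigma(w, "proton", 50, 0.05)
  s4 <- scattering_sigma(w, "proton", 50, 0.20)
  expect_gt(s1, 0)
  # quadrupled step -> sigma doubled within the log correction (+-15%)
  expect_lt(abs(s4 / s1 - 2), 0.3)
  # sigma -> 0 as step -> 0
  expect_lt(scattering_sigma(w, "proton", 50, 1e-9), 1e-4)
  # higher energy scatters less at fixed step
  expect_lt(scattering_sigma(w, "proton", 80, 0.1),
            scattering_sigma(w, "proton", 20, 0.1))
  expect_error(scattering_sigma(w, "proton", 50, 0), "step")
})

test_that("straggling sigma scales as sqrt(step) and is small vs mean loss", {
  w <- water()
  expect_equal(straggling_sigma(w, "proton", 50, 0.4),
               2 * straggling_sigma(w, "proton", 50, 0.1))
  # 50 MeV protons, 1 mm water: width << mean energy loss
  sig <- straggling_sigma(w, "proton", 50, 0.1)
  mean_loss <- collision_stopping_power(w, "proton", 50) * 0.1
  expect_lt(sig / mean_loss, 0.15)
})

test_that("HU conversion follows the Hounsfield anchors and the boundary rule", {
  conv <- hu_to_material(c(0, -1000, -200, 120, 3000, -5000))
  expect_equal(conv$material[1], "soft_tissue")
  expect_equal(conv$density[1], 1.00)
  expect_equal(conv$material[2], "air")
  # exact boundary -> lower bin
  expect_equal(conv$material[3], "lung")
  expect_equal(conv$material[4], "soft_tissue")
  # clamped above and below the span
  expect_equal(conv$material[5], "bone")
  expect_equal(conv$material[6], "air")
})

test_that("density is monotone non-decreasing over an HU ramp", {
  hu <- seq(-1100, 3000, by = 7)
  d <- hu_to_material(hu)$density
  expect_true(all(diff(d) >= -1e-12))
  expect_true(all(d > 0))
})

test_that("hu_table validates contiguity and positivity", {
  expect_error(hu_table(data.frame(hu_low = numeric(), hu_high = numeric(),
                                   material = character(), a = numeric(),
                                   b = numeric())), "empty")
  bad <- data.frame(hu_low = c(-100, 50), hu_high = c(0, 100),
                    material = "water", a = 1, b = 0)
  expect_error(hu_table(bad), "contiguous")
})

test_that("material library round-trips through its text format", {
  lib <- material_library()
  f <- tempfile(fileext = ".txt")
  writeLines(c("material demo", "density 1.5", "I 80",
               "elements H 0.5 O 0.5", "end"), f)
  m <- read_material_library(f)$demo
  expect_equal(m$density, 1.5)
  expect_equal(m$I_eV, 80)
  expect_equal(unname(m$composition), c(0.5, 0.5))
})
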