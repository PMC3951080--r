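# Voxelized world construction: rasterization, CT import with BODY
# cropping, and enclosure padding.

test_that("square polygon spanning 4x4 voxel centers rasterizes to 16 voxels/slice", {
  g <- make_slab_phantom("water", 1, 0.1)  # 10x10x10, centers at -0.45..0.45
  sq <- list(list(z = 0.05, xy = rbind(c(-0.2, -0.2), c(0.2, -0.2),
                                       c(0.2, 0.2), c(-0.2, 0.2))))
  m <- rasterize_contour(sq, g)
  expect_equal(sum(m$mask), 16)          # 4x4 centers strictly inside
  expect_true(all(which(apply(m$mask, 3, any)) == 1))
})

test_that("empty contour list gives an all-false mask", {
  g <- make_slab_phantom("water", 1, 0.1)
  expect_false(any(rasterize_contour(list(), g)$mask))
})

test_that("large circle rasterizes to within 2% of its analytic area", {
  g <- make_slab_phantom("water", c(10, 10, 0.2), 0.1)
  r <- 3.5
  th <- seq(0, 2 * pi, length.out = 200)[-200]
  circ <- list(list(z = 0.1, xy = cbind(r * cos(th), r * sin(th))))
  m <- rasterize_contour(circ, g)
  area <- sum(m$mask[, , 1]) * 0.1^2
  expect_lt(abs(area - pi * r^2) / (pi * r^2), 0.02)
})

test_that("self-intersecting polygons warn but return the even-odd result", {
  g <- make_slab_phantom("water", 1, 0.1)
  bow <- list(list(z = 0.05, xy = rbind(c(-0.3, -0.3), c(0.3, 0.3),
                                        c(0.3, -0.3), c(-0.3, 0.3))))
  expect_warning(rasterize_contour(bow, g), "self-intersecting")
})

test_that("load_ct maps HU inside BODY, airs the outside, and crops to BODY", {
  # synthetic 3-slice series, all HU = 0, BODY covering one center voxel
  ct <- list(hu = array(0, c(3, 3, 3)), origin = c(0, 0, 0),
             spacing = c(1, 1, 1))
  body <- array(FALSE, c(3, 3, 3)); body[2, 2, 2] <- TRUE
  res <- load_ct(ct, body)
  expect_equal(res$grid$dims, c(1L, 1L, 1L))
  expect_equal(res$grid$materials[res$grid$material_index[1, 1, 1]],
               "soft_tissue")
  expect_equal(res$grid$density[1, 1, 1], 1.00)

  # BODY covering everything: no crop, no interior air
  body_all <- array(TRUE, c(3, 3, 3))
  res2 <- load_ct(ct, body_all)
  expect_equal(dim(res2$grid$density), c(3L, 3L, 3L))
  expect_false(any(res2$grid$materials[res2$grid$material_index] == "air"))

  # checkerboard HU {-1000, 0}: per-voxel lookup matches hu_to_material
  hu <- array(0, c(4, 4, 4))
  hu[seq(1, 64, 2)] <- -1000
  ct3 <- list(hu = hu, origin = c(0, 0, 0), spacing = c(1, 1, 1))
  res3 <- load_ct(ct3, array(TRUE, c(4, 4, 4)))
  want <- hu_to_material(as.numeric(hu))$material
  got <- res3$grid$materials[res3$grid$material_index]
  expect_equal(as.vector(got), want)
})

test_that("cropping never discards a BODY voxel", {
  set.seed(5)
  body <- array(runif(125) < 0.2, c(5, 5, 5))
  body[3, 3, 3] <- TRUE
  ct <- list(hu = array(0, c(5, 5, 5)), origin = c(0, 0, 0),
             spacing = c(0.5, 0.5, 0.5))
  res <- load_ct(ct, body)
  expect_equal(sum(res$body$mask), sum(body))
})

test_that("enclosure padding: identity at zero, exact layer counts, shell mass", {
  ph <- make_slab_phantom("water", 2, 0.1)
  same <- add_enclosure(ph, wall_thickness = 0, air_gap = 0)
  expect_identical(same$density, ph$density)

  # 5 mm wall + 10 cm gap at 1 mm voxels: 100 air + 5 PMMA layers per face
  small <- make_slab_phantom("water", 1, 0.1)
  pad <- add_enclosure(small, wall_thickness = 0.5, air_gap = 10,
                       axes = c("x", "y"))
  expect_equal(pad$dims[1], 10L + 2L * (100L + 5L))
  expect_equal(pad$dims[3], 10L)
  mats <- pad$materials[pad$material_index[, 111, 5]]  # row through the payload band
  expect_equal(mats[1:5], rep("PMMA", 5))
  expect_equal(mats[6:105], rep("air", 100))

  # mass increases by the PMMA shell mass (air negligible at 1e-3)
  pad1 <- add_enclosure(small, wall_thickness = 0.5, air_gap = 0.5,
                        axes = c("x", "y"))
  shell_outer <- (1 + 2 * 0.5 + 2 * 0.5)^2
  shell_inner <- (1 + 2 * 0.5)^2
  shell_mass <- (shell_outer - shell_inner) * 1 * 1.19  # z-extent 1 cm
  got <- grid_mass(pad1) - grid_mass(small)
  expect_lt(abs(got - shell_mass) / shell_mass, 1e-3)
})

test_that("grid validation catches bad inputs", {
  g <- make_slab_phantom("water", 1, 0.1)
  g$density[1] <- -1
  expect_error(validate_grid(g), "density")
  g2 <- make_slab_phantom("water", 1, 0.1)
  g2$material_index[1] <- 99L
  expect_error(validate_grid(g2), "resolve")
  expect_error(make_slab_phantom("unobtainium", 1, 0.1), "unknown material")
})
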