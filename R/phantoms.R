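# Synthetic fixture generators: homogeneous slabs, PMMA-wall/air-gap rigs
# and a parameterized digital minipig-like body.  All generators are
# deterministic functions of their arguments.

#' Homogeneous slab phantom
#'
#' A rectilinear block of one material at its reference density, centered
#' laterally on the origin with its upstream (z = 0) face at the origin
#' plane: x and y span [-size/2, size/2], z spans [0, size].
#'
#' @param material_name a built-in material name (e.g. `"solid_water"`,
#'   `"water"`).
#' @param size edge lengths in cm (scalar or length 3).
#' @param voxel voxel size in cm (scalar for isotropic, or length 3 for
#'   anisotropic scoring, e.g. coarse lateral x fine depth).
#' @return a `voxel_grid`.
#' @export
make_slab_phantom <- function(material_name, size, voxel) {
  mat <- get_material(material_name)  # errors on unknown material
  size <- rep(size, length.out = 3)
  voxel <- rep(voxel, length.out = 3)
  dims <- round(size / voxel)
  if (any(abs(dims * voxel - size) > 1e-6))
    stop("size must be a multiple of the voxel dimension")
  dims <- as.integer(dims)
  voxel_grid(origin = c(-size[1] / 2, -size[2] / 2, 0),
             spacing = voxel,
             material_index = array(1L, dims),
             density = array(mat$density, dims),
             materials = material_name)
}

#' PMMA-wall / air-gap rig for the beam-gap study
#'
#' Prepends, upstream (low z) of a phantom, an air gap and then a PMMA
#' wall.  The wall's upstream face is held at z = 0 for every gap, so the
#' phantom recedes as the gap grows; the phantom voxel payload is
#' unchanged.  The beam is assumed to travel along +z.
#'
#' @param gap air gap between wall and phantom, cm (>= 0).
#' @param wall PMMA wall thickness, cm (default 0.5 = 5 mm).
#' @param phantom a `voxel_grid` (e.g. from [make_slab_phantom()]).
#' @return a `voxel_grid` with dims `(nx, ny, n_wall + n_gap + nz)` and
#'   origin z = 0 at the wall's upstream face.
#' @export
make_airgap_rig <- function(gap, wall = 0.5, phantom) {
  if (gap < 0) stop("gap must be >= 0")
  vz <- phantom$spacing[3]
  n_wall <- round(wall / vz)
  n_gap <- round(gap / vz)
  mats <- unique(c(phantom$materials, "air", "PMMA"))
  i_air <- match("air", mats); i_pmma <- match("PMMA", mats)
  d <- phantom$dims
  nd <- c(d[1], d[2], d[3] + n_wall + n_gap)
  mi <- array(i_air, nd)
  de <- array(get_material("air")$density, nd)
  if (n_wall > 0) {
    mi[, , seq_len(n_wall)] <- i_pmma
    de[, , seq_len(n_wall)] <- get_material("PMMA")$density
  }
  zsel <- n_wall + n_gap + seq_len(d[3])
  mi[, , zsel] <- phantom$material_index
  de[, , zsel] <- phantom$density
  voxel_grid(origin = c(phantom$origin[1], phantom$origin[2], 0),
             spacing = phantom$spacing, material_index = mi, density = de,
             materials = mats)
}

# fixed proportions of the digital animal, as fractions of crown-rump
# length L (lateral semi-axes) or of the reference 54 cm animal (eyes);
# constants are documented here so cross-size DVH comparisons reproduce
.ANIMAL <- list(
  girth_frac = 0.55,       # lateral body diameter = 0.55 * L
  skin_cm_ref = 0.2,       # skin shell 2 mm at L = 54, scales with L
  lung_center = c(0.32, 0.0, 0.18),   # fractions of (a, b, c) semi-axes
  lung_semi = c(0.26, 0.45, 0.22),    # fractions of (a, b, c)
  bfo_col_r_frac = 0.055,  # dorsal column radius / L
  bfo_col_y = -0.62,       # column center, fraction of b (dorsal = -y)
  bfo_col_z = 0.80,        # column half-length, fraction of c
  limb_r_frac = 0.030,     # limb rod radius / L
  limb_x = 0.45, limb_z = 0.35, limb_y_span = c(-0.1, 0.55),
  eye_r_ref = 1.5,         # eye sphere radius (cm) at L = 54, scales
  eye_center = c(0.22, 0.25, 0.93),   # fractions of (a, b, c)
  ref_length = 54)

#' Parameterized digital minipig-like body
#'
#' An idealized stand-in for a CT-derived animal geometry: a prolate
#' ellipsoidal soft-tissue body with its long axis along z (crown-rump),
#' lateral diameter 0.55 x length; a skin shell (outermost BODY voxel
#' layers to ~2 mm scaled thickness); two lung ellipsoids at 0.3 g/cm^3;
#' blood-forming-organ (BFO) marrow as a dorsal bone column plus four limb
#' rods at bone density; and two eye spheres near the cranial (+z) end.
#' All proportions are fixed fractions of the crown-rump length, so two
#' sizes differ only by uniform scale.
#'
#' @param crown_rump crown-rump length, cm (> 0); the study sizes are
#'   ~54 cm (small) and ~63 cm (large).
#' @param voxel isotropic voxel size, cm (default 0.2).
#' @return list with `grid` (a `voxel_grid`) and `masks` (named list of
#'   `structure_mask`: BODY, skin, lungs, BFO, eyes).
#' @export
make_digital_animal <- function(crown_rump, voxel = 0.2) {
  if (crown_rump <= 0) stop("crown_rump must be > 0")
  P <- .ANIMAL
  L <- crown_rump
  s <- L / P$ref_length                    # uniform scale factor
  c_ax <- L / 2                            # z semi-axis
  a_ax <- P$girth_frac * L / 2             # x semi-axis
  b_ax <- a_ax                             # y semi-axis
  skin_t <- P$skin_cm_ref * s
  if (skin_t < 2 * voxel)
    warning("voxel too coarse to resolve the skin shell (< 2 voxels)")

  margin <- 2 * voxel
  half <- c(a_ax, b_ax, c_ax) + margin
  dims <- as.integer(ceiling(2 * half / voxel))
  org <- -dims * voxel / 2
  cx <- org[1] + (seq_len(dims[1]) - 0.5) * voxel
  cy <- org[2] + (seq_len(dims[2]) - 0.5) * voxel
  cz <- org[3] + (seq_len(dims[3]) - 0.5) * voxel

  # normalized coordinates (fractions of the body semi-axes), broadcast
  X <- array(cx / a_ax, dims)
  Y <- array(rep(cy / b_ax, each = dims[1]), dims)
  Z <- array(rep(cz / c_ax, each = dims[1] * dims[2]), dims)

  ellipsoid <- function(ctr, semi) {
    # ctr, semi as fractions of (a, b, c)
    ((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
      ((Z - ctr[3]) / semi[3])^2 <= 1
  }
  sphere_cm <- function(ctr_frac, r_cm) {
    ((X - ctr_frac[1]) * a_ax)^2 + ((Y - ctr_frac[2]) * b_ax)^2 +
      ((Z - ctr_frac[3]) * c_ax)^2 <= r_cm^2
  }

  body <- X^2 + Y^2 + Z^2 <= 1

  # skin: BODY minus BODY shrunk by skin_t (ellipsoid with semi-axes
  # reduced by the shell thickness)
  inner <- (X * a_ax / (a_ax - skin_t))^2 + (Y * b_ax / (b_ax - skin_t))^2 +
    (Z * c_ax / (c_ax - skin_t))^2 <= 1
  skin <- body & !inner

  lungs <- ellipsoid(c(+P$lung_center[1], P$lung_center[2], P$lung_center[3]),
                     P$lung_semi) |
           ellipsoid(c(-P$lung_center[1], P$lung_center[2], P$lung_center[3]),
                     P$lung_semi)

  col_r <- P$bfo_col_r_frac * L
  bfo <- ((X * a_ax)^2 + ((Y - P$bfo_col_y) * b_ax)^2 <= col_r^2) &
    (abs(Z) <= P$bfo_col_z)
  limb_r <- P$limb_r_frac * L
  for (sx in c(-1, 1)) for (sz in c(-1, 1)) {
    rod <- (((X - sx * P$limb_x) * a_ax)^2 +
              ((Z - sz * P$limb_z) * c_ax)^2 <= limb_r^2) &
      (Y >= P$limb_y_span[1] & Y <= P$limb_y_span[2])
    bfo <- bfo | rod
  }

  eye_r <- P$eye_r_ref * s
  eyes <- sphere_cm(c(+P$eye_center[1], P$eye_center[2], P$eye_center[3]),
                    eye_r) |
          sphere_cm(c(-P$eye_center[1], P$eye_center[2], P$eye_center[3]),
                    eye_r)

  # keep organs strictly inside the body and pairwise disjoint
  lungs <- lungs & inner
  bfo <- bfo & inner & !lungs
  eyes <- eyes & inner & !lungs & !bfo

  mats <- c("air", "soft_tissue", "lung", "bone")
  lib <- material_library()
  mi <- array(1L, dims)
  de <- array(lib$air$density, dims)
  mi[body] <- 2L; de[body] <- lib$soft_tissue$density
  mi[lungs] <- 3L; de[lungs] <- lib$lung$density
  mi[bfo] <- 4L; de[bfo] <- lib$bone$density
  # eyes are soft tissue (already 2)

  grid <- voxel_grid(org, rep(voxel, 3), mi, de, mats)
  masks <- list(BODY = structure_mask("BODY", body),
                skin = structure_mask("skin", skin),
                lungs = structure_mask("lungs", lungs),
                BFO = structure_mask("BFO", bfo),
                eyes = structure_mask("eyes", eyes))
  list(grid = grid, masks = masks)
}
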