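# Voxelized world construction: grids, structure masks, contour
# rasterization, CT import and enclosure padding.
#
# Coordinate convention: world coordinates in cm, axes (x lateral,
# y anterior-posterior, z crown-rump).  Voxel indices are 1-based in R
# (0-based in the transport core); voxel i spans
# [origin + (i-1) * spacing, origin + i * spacing)  -- half-open.

#' Construct a voxel grid
#'
#' @param origin corner of the first voxel, cm (length 3).
#' @param spacing voxel size per axis, cm (length 3, > 0).
#' @param material_index integer 3-D array of 1-based indices into
#'   `materials`.
#' @param density numeric 3-D array, g/cm^3 (> 0 everywhere).
#' @param materials character vector of material names (resolvable in the
#'   material library).
#' @return object of class `voxel_grid` with fields `origin`, `spacing`,
#'   `dims`, `material_index`, `density`, `materials`.
#' @export
voxel_grid <- function(origin, spacing, material_index, density, materials) {
  g <- structure(list(origin = as.numeric(origin),
                      spacing = as.numeric(spacing),
                      dims = dim(material_index),
                      material_index = material_index,
                      density = density,
                      materials = materials),
                 class = "voxel_grid")
  validate_grid(g)
  g
}

#' Validate a voxel grid's invariants
#' @param g a `voxel_grid`.
#' @return `g` invisibly; errors on violation.
#' @export
validate_grid <- function(g) {
  stopifnot(inherits(g, "voxel_grid"))
  if (length(g$origin) != 3 || length(g$spacing) != 3)
    stop("origin and spacing must have length 3")
  if (any(g$spacing <= 0)) stop("spacing must be > 0 on every axis")
  if (!identical(dim(g$material_index), dim(g$density)) ||
      length(dim(g$material_index)) != 3)
    stop("material_index and density must be 3-D arrays of equal dims")
  rng <- range(g$material_index)
  if (rng[1] < 1 || rng[2] > length(g$materials))
    stop("material_index values must resolve in the grid's material list")
  lib <- material_library()
  bad <- setdiff(g$materials, names(lib))
  if (length(bad) > 0) stop("unknown material(s): ", paste(bad, collapse = ", "))
  if (any(g$density <= 0)) stop("density must be > 0 everywhere")
  invisible(g)
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing (%g, %g, %g) cm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) cm; materials: %s\n",
              x$origin[1], x$origin[2], x$origin[3],
              paste(x$materials, collapse = ", ")))
  invisible(x)
}

#' Voxel center coordinates along one axis
#' @param g a `voxel_grid`.
#' @param axis 1, 2 or 3 (or "x", "y", "z").
#' @return numeric vector of voxel-center world coordinates, cm.
#' @export
voxel_centers <- function(g, axis) {
  if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
  g$origin[axis] + (seq_len(g$dims[axis]) - 0.5) * g$spacing[axis]
}

#' Geometric center of a grid, cm
#' @param g a `voxel_grid`.
#' @export
grid_center <- function(g) g$origin + g$dims * g$spacing / 2

#' Total mass of a grid, g
#' @param g a `voxel_grid`.
#' @export
grid_mass <- function(g) sum(g$density) * prod(g$spacing)

#' Construct a structure mask
#' @param name structure name (e.g. BODY, skin, lungs, BFO, eyes).
#' @param mask logical 3-D array aligned to a grid.
#' @return object of class `structure_mask`.
#' @export
structure_mask <- function(name, mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  structure(list(name = name, mask = mask), class = "structure_mask")
}

# ---------------------------------------------------------------------------
# Contour rasterization (even-odd rule on voxel centers)

# even-odd point-in-polygon, vectorized over points
.points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xin <- vx[i] + (py[crosses] - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xin)
    }
    j <- i
  }
  inside
}

# warn (once per call) about self-intersecting slices; even-odd result is
# still well defined, so only a heads-up is needed
.segments_self_intersect <- function(vx, vy) {
  n <- length(vx)
  if (n < 4) return(FALSE)
  seg <- cbind(vx, vy, c(vx[-1], vx[1]), c(vy[-1], vy[1]))
  for (i in seq_len(n - 2)) {
    jj <- seq(i + 2, n)
    jj <- jj[!(i == 1 & jj == n)]
    for (j in jj) {
      d1 <- (seg[j, 3] - seg[j, 1]) * (seg[i, 2] - seg[j, 2]) -
        (seg[j, 4] - seg[j, 2]) * (seg[i, 1] - seg[j, 1])
      d2 <- (seg[j, 3] - seg[j, 1]) * (seg[i, 4] - seg[j, 2]) -
        (seg[j, 4] - seg[j, 2]) * (seg[i, 3] - seg[j, 1])
      d3 <- (seg[i, 3] - seg[i, 1]) * (seg[j, 2] - seg[i, 2]) -
        (seg[i, 4] - seg[i, 2]) * (seg[j, 1] - seg[i, 1])
      d4 <- (seg[i, 3] - seg[i, 1]) * (seg[j, 4] - seg[i, 2]) -
        (seg[i, 4] - seg[i, 2]) * (seg[j, 3] - seg[i, 1])
      if (d1 * d2 < 0 && d3 * d4 < 0) return(TRUE)
    }
  }
  FALSE
}

#' Rasterize per-slice contour polygons to a structure mask
#'
#' A voxel belongs to the structure iff its center lies inside the polygon
#' of the slice containing the voxel-center z (even-odd rule).  Slices with
#' no polygon rasterize to all-false.
#'
#' @param contours list of slices, each `list(z = <cm>, xy = <n x 2 matrix
#'   of (x, y) vertices in cm>)`; multiple polygons may share a z.
#' @param grid a `voxel_grid`.
#' @param name structure name for the returned mask.
#' @return a `structure_mask` aligned to `grid`.
#' @export
rasterize_contour <- function(contours, grid, name = "BODY") {
  mask <- array(FALSE, dim = grid$dims)
  if (length(contours) == 0) return(structure_mask(name, mask))
  cx <- voxel_centers(grid, 1)
  cy <- voxel_centers(grid, 2)
  cz <- voxel_centers(grid, 3)
  px <- rep(cx, times = grid$dims[2])
  py <- rep(cy, each = grid$dims[1])
  warned <- FALSE
  for (ct in contours) {
    xy <- ct$xy
    if (is.null(dim(xy)) || nrow(xy) < 3) stop("contour polygon needs >= 3 vertices")
    # vertex list is implicitly closed; drop an explicitly repeated
    # first vertex if present
    if (isTRUE(all.equal(xy[1, ], xy[nrow(xy), ])))
      xy <- xy[-nrow(xy), , drop = FALSE]
    if (nrow(xy) < 3) stop("contour polygon needs >= 3 distinct vertices")
    if (!warned && .segments_self_intersect(xy[, 1], xy[, 2])) {
      warning("self-intersecting contour polygon; even-odd result returned")
      warned <- TRUE
    }
    # z slab containing this slice's plane
    iz <- which(abs(cz - ct$z) <= grid$spacing[3] / 2 + 1e-9)
    if (length(iz) == 0) next
    inside <- .points_in_polygon(px, py, xy[, 1], xy[, 2])
    sl <- matrix(inside, grid$dims[1], grid$dims[2])
    for (k in iz) mask[, , k] <- mask[, , k] | sl
  }
  structure_mask(name, mask)
}

# ---------------------------------------------------------------------------
# CT import

#' Build a voxelized world from CT data plus a body contour
#'
#' Voxels inside the BODY contour get a material and density from the HU
#' conversion table; voxels outside BODY are set to air; the grid is
#' cropped to the BODY bounding box.
#'
#' @param ct either the result of [read_ct_series()] or a list with fields
#'   `hu` (3-D array), `origin` (cm), `spacing` (cm).
#' @param body body contour: a list of slices as in [rasterize_contour()],
#'   or an already-rasterized logical array aligned to the CT.
#' @param table an `hu_table`.
#' @return list with `grid` (a `voxel_grid`) and `body` (the cropped BODY
#'   `structure_mask`).
#' @export
load_ct <- function(ct, body, table = default_hu_table()) {
  hu <- ct$hu
  stopifnot(length(dim(hu)) == 3)
  full <- voxel_grid(ct$origin, ct$spacing,
                     array(1L, dim(hu)), array(1.0, dim(hu)),
                     materials = "water")
  if (is.array(body)) {
    if (!identical(dim(body), dim(hu))) stop("body mask dims must match CT")
    bmask <- body
  } else {
    bmask <- rasterize_contour(body, full, name = "BODY")$mask
  }
  if (!any(bmask)) stop("BODY contour rasterizes to an empty mask")

  conv <- hu_to_material(as.numeric(hu), table)
  mats <- unique(c(conv$material, "air"))
  mat_idx <- array(match(conv$material, mats), dim(hu))
  dens <- array(conv$density, dim(hu))
  air_i <- match("air", mats)
  mat_idx[!bmask] <- air_i
  dens[!bmask] <- get_material("air")$density

  # crop to the BODY bounding box (never discards a BODY voxel)
  rng <- lapply(1:3, function(ax) {
    pr <- apply(bmask, ax, any)
    range(which(pr))
  })
  sel <- lapply(rng, function(r) seq(r[1], r[2]))
  grid <- voxel_grid(
    origin = ct$origin + (vapply(rng, `[`, numeric(1), 1) - 1) * ct$spacing,
    spacing = ct$spacing,
    material_index = mat_idx[sel[[1]], sel[[2]], sel[[3]], drop = FALSE],
    density = dens[sel[[1]], sel[[2]], sel[[3]], drop = FALSE],
    materials = mats)
  body_mask <- structure_mask("BODY",
                              bmask[sel[[1]], sel[[2]], sel[[3]], drop = FALSE])
  list(grid = grid, body = body_mask)
}

# ---------------------------------------------------------------------------
# Enclosure padding

.ensure_materials <- function(g, extra) {
  add <- setdiff(extra, g$materials)
  if (length(add) > 0) g$materials <- c(g$materials, add)
  g
}

#' Surround a grid with an air gap and a PMMA enclosure wall
#'
#' Expands the grid by `air_gap` of air and then `wall_thickness` of PMMA
#' on the selected lateral faces; the original voxel payload is unchanged.
#' Layer counts are `round(thickness / spacing)` per axis.
#'
#' @param grid a `voxel_grid`.
#' @param wall_thickness PMMA wall thickness, cm (>= 0).
#' @param air_gap air gap between grid and wall, cm (>= 0).
#' @param axes axes to pad (subset of `c("x", "y")` by default; the
#'   crown-rump z axis is left open, configurable).
#' @return the padded `voxel_grid`.
#' @export
add_enclosure <- function(grid, wall_thickness = 0.5, air_gap = 10,
                          axes = c("x", "y")) {
  if (wall_thickness < 0 || air_gap < 0) stop("thickness/gap must be >= 0")
  ax_idx <- match(axes, c("x", "y", "z"))
  if (any(is.na(ax_idx))) stop("axes must be in x, y, z")
  g <- .ensure_materials(grid, c("air", "PMMA"))
  air <- get_material("air"); pmma <- get_material("PMMA")
  i_air <- match("air", g$materials); i_pmma <- match("PMMA", g$materials)

  d <- g$dims
  n_gap <- integer(3); n_wall <- integer(3)
  for (ax in ax_idx) {
    n_gap[ax] <- round(air_gap / g$spacing[ax])
    n_wall[ax] <- round(wall_thickness / g$spacing[ax])
  }
  n_pad <- n_gap + n_wall
  if (all(n_pad == 0)) return(g)
  nd <- d + 2L * n_pad
  mi <- array(i_air, nd); de <- array(air$density, nd)
  # wall = rectangular frame: a voxel is PMMA if it lies in the outermost
  # n_wall layers along any padded axis
  in_wall_1d <- lapply(1:3, function(ax) {
    idx <- seq_len(nd[ax])
    if (n_wall[ax] == 0) rep(FALSE, nd[ax])
    else idx <= n_wall[ax] | idx > nd[ax] - n_wall[ax]
  })
  wall <- outer(outer(in_wall_1d[[1]], in_wall_1d[[2]], `|`),
                in_wall_1d[[3]], `|`)
  mi[wall] <- i_pmma
  de[wall] <- pmma$density
  mi[n_pad[1] + seq_len(d[1]), n_pad[2] + seq_len(d[2]),
     n_pad[3] + seq_len(d[3])] <- g$material_index
  de[n_pad[1] + seq_len(d[1]), n_pad[2] + seq_len(d[2]),
     n_pad[3] + seq_len(d[3])] <- g$density
  voxel_grid(g$origin - n_pad * g$spacing, g$spacing, mi, de, g$materials)
}
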