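# Primary-particle sources: the large-field clinical electron beam
# (circular planar source, square clip at isocenter, long SSD) and the
# broad parallel SPE proton beam driven by a discrete energy spectrum.

#' Beam specification
#'
#' @param particle `"electron"` or `"proton"`.
#' @param energy nominal kinetic energy, MeV (electron beams; ignored when
#'   a `spectrum` is given).
#' @param spread relative Gaussian energy spread.  Interpreted as sigma =
#'   `spread * energy` when `spread_is_sigma` is `TRUE` (default), or as
#'   FWHM otherwise.
#' @param spectrum a `spectrum` object (discrete energies + weights) for
#'   proton beams; see [spectrum()].
#' @param source_radius radius of the circular planar source, cm.
#' @param source_to_isocenter distance source -> isocenter, cm.
#' @param clip_halfwidth half-width of the square clip aperture at the
#'   isocenter plane, cm (34 x 34 cm field -> 17).
#' @param ssd source-to-surface distance, cm.
#' @param angle beam angle about the grid's long (z) axis: 0, 90, 180 or
#'   270 degrees (0 -> +x, 90 -> +y, 180 -> -x, 270 -> -y), or `NULL` to
#'   use `axis`.
#' @param axis beam travel axis when `angle` is `NULL`: `"+z"` (default),
#'   `"-z"`, `"+x"`, ... Used for depth-dose work on slab phantoms.
#' @param parallel logical; `TRUE` for a broad parallel beam (protons).
#' @param field lateral half-extents (cm, length 2) of the parallel-beam
#'   face; `NULL` = grid entrance face plus a 2 cm margin each side.
#' @param spread_is_sigma see `spread`.
#' @return object of class `beam_spec`.
#' @export
beam_spec <- function(particle = c("electron", "proton"), energy = NULL,
                      spread = 0.10, spectrum = NULL,
                      source_radius = 2, source_to_isocenter = 100,
                      clip_halfwidth = 17, ssd = 500,
                      angle = NULL, axis = "+z",
                      parallel = (particle == "proton"), field = NULL,
                      spread_is_sigma = TRUE) {
  particle <- match.arg(particle)
  if (!is.null(angle) && !angle %in% c(0, 90, 180, 270))
    stop("angle must be one of 0, 90, 180, 270")
  if (!is.null(spectrum) && !inherits(spectrum, "spectrum"))
    stop("spectrum must be a spectrum object")
  if (is.null(spectrum) && is.null(energy))
    stop("either energy or spectrum is required")
  if (!parallel && is.null(spectrum) && clip_halfwidth <= 0)
    stop("clip_halfwidth must be > 0 for a diverging beam")
  structure(list(particle = particle, energy = energy, spread = spread,
                 spectrum = spectrum, source_radius = source_radius,
                 source_to_isocenter = source_to_isocenter,
                 clip_halfwidth = clip_halfwidth, ssd = ssd,
                 angle = angle, axis = axis, parallel = parallel,
                 field = field, spread_is_sigma = spread_is_sigma),
            class = "beam_spec")
}

#' Unit beam direction for a spec
#' @param spec a `beam_spec`.
#' @return length-3 unit vector.
#' @export
beam_direction <- function(spec) {
  if (!is.null(spec$angle)) {
    # exact cardinal directions so opposed angles mirror exactly
    return(switch(as.character(spec$angle),
                  "0" = c(1, 0, 0), "90" = c(0, 1, 0),
                  "180" = c(-1, 0, 0), "270" = c(0, -1, 0)))
  }
  switch(spec$axis,
         "+x" = c(1, 0, 0), "-x" = c(-1, 0, 0),
         "+y" = c(0, 1, 0), "-y" = c(0, -1, 0),
         "+z" = c(0, 0, 1), "-z" = c(0, 0, -1),
         stop("axis must be one of +x,-x,+y,-y,+z,-z"))
}

# orthonormal vectors spanning the plane perpendicular to d
.perp_frame <- function(d) {
  a <- if (abs(d[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- c(d[2] * a[3] - d[3] * a[2],
          d[3] * a[1] - d[1] * a[3],
          d[1] * a[2] - d[2] * a[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# center of the grid face the beam enters, and the distance convention:
# the source sits `ssd` upstream of that face along -d, the isocenter
# `source_to_isocenter` downstream of the source
.entry_center <- function(grid, d) {
  ctr <- grid_center(grid)
  half <- grid$dims * grid$spacing / 2
  ax <- which.max(abs(d))
  ctr[ax] <- ctr[ax] - sign(d[ax]) * half[ax]
  ctr
}

#' Sample electron primaries
#'
#' Positions are uniform on the circular planar source; each primary aims
#' at a point uniform on the square clip aperture in the isocenter plane,
#' so every isocenter-plane crossing lies inside the clip by construction.
#' Energies are Gaussian about the nominal with relative spread
#' `spec$spread`, truncated to positive values by resampling.
#'
#' @param n number of primaries.
#' @param spec a `beam_spec` with `particle = "electron"`.
#' @param grid the `voxel_grid` to be irradiated (fixes the source frame).
#' @param aim_halfwidth optional reduced aim-aperture half-width at the
#'   isocenter plane, cm; defaults to the full `clip_halfwidth`.  Sampling
#'   a sub-aperture of the (uniform-fluence) clipped field concentrates
#'   histories on a small phantom without changing relative dose.
#' @return n x 8 matrix (x, y, z, ux, uy, uz, E, weight); uses the current
#'   R RNG stream.
#' @export
sample_electron_primaries <- function(n, spec, grid, aim_halfwidth = NULL) {
  stopifnot(spec$particle == "electron")
  d <- beam_direction(spec)
  fr <- .perp_frame(d)
  entry <- .entry_center(grid, d)
  src_ctr <- entry - d * spec$ssd
  iso_ctr <- src_ctr + d * spec$source_to_isocenter
  h <- if (is.null(aim_halfwidth)) spec$clip_halfwidth else aim_halfwidth
  if (h > spec$clip_halfwidth)
    stop("aim_halfwidth cannot exceed the clip aperture")

  # uniform on the source disc
  r <- spec$source_radius * sqrt(runif(n))
  phi <- runif(n, 0, 2 * pi)
  p1 <- r * cos(phi); p2 <- r * sin(phi)
  pos <- cbind(src_ctr[1] + p1 * fr$e1[1] + p2 * fr$e2[1],
               src_ctr[2] + p1 * fr$e1[2] + p2 * fr$e2[2],
               src_ctr[3] + p1 * fr$e1[3] + p2 * fr$e2[3])
  # uniform aim point on the (sub-)aperture
  a1 <- runif(n, -h, h); a2 <- runif(n, -h, h)
  aim <- cbind(iso_ctr[1] + a1 * fr$e1[1] + a2 * fr$e2[1],
               iso_ctr[2] + a1 * fr$e1[2] + a2 * fr$e2[2],
               iso_ctr[3] + a1 * fr$e1[3] + a2 * fr$e2[3])
  dir <- aim - pos
  dir <- dir / sqrt(rowSums(dir^2))

  nominal <- spec$energy
  sigma <- if (spec$spread_is_sigma) spec$spread * nominal
           else spec$spread * nominal / (2 * sqrt(2 * log(2)))
  if (sigma == 0) {
    E <- rep(nominal, n)
  } else {
    E <- rnorm(n, nominal, sigma)
    while (any(E <= 0)) E[E <= 0] <- rnorm(sum(E <= 0), nominal, sigma)
  }
  cbind(pos, dir, E, rep(1, n))
}

#' Sample broad-parallel primaries
#'
#' Positions uniform over a rectangular field face just upstream of the
#' grid; directions exactly along the beam axis; energies drawn from the
#' discrete spectrum by its weights (or fixed at `spec$energy`).  The SPE
#' proton beam uses this; any `beam_spec` with `parallel = TRUE` (e.g. a
#' test electron beam) is sampled the same way.
#'
#' @param n number of primaries.
#' @param spec a `beam_spec` with `parallel = TRUE` and a `spectrum` (or a
#'   single `energy`, treated as a one-line spectrum).
#' @param grid the target `voxel_grid`.
#' @param field lateral half-extents (cm, length 2) overriding
#'   `spec$field`; default grid entrance face + 2 cm margin per side.
#' @return n x 8 matrix as in [sample_electron_primaries()].
#' @export
sample_proton_primaries <- function(n, spec, grid, field = NULL) {
  stopifnot(spec$parallel)
  d <- beam_direction(spec)
  fr <- .perp_frame(d)
  entry <- .entry_center(grid, d)
  src_ctr <- entry - d * 1.0  # 1 cm upstream of the face (vacuum gap)

  if (is.null(field)) field <- spec$field
  if (is.null(field)) {
    half <- grid$dims * grid$spacing / 2
    lat <- half[order(abs(d))[1:2]]  # the two axes perpendicular to d
    field <- rep(max(lat) + 2, 2)    # square face covering the entrance
  }
  a1 <- runif(n, -field[1], field[1])
  a2 <- runif(n, -field[2], field[2])
  pos <- cbind(src_ctr[1] + a1 * fr$e1[1] + a2 * fr$e2[1],
               src_ctr[2] + a1 * fr$e1[2] + a2 * fr$e2[2],
               src_ctr[3] + a1 * fr$e1[3] + a2 * fr$e2[3])
  dir <- matrix(d, n, 3, byrow = TRUE)

  if (!is.null(spec$spectrum)) {
    sp <- spec$spectrum
    if (all(sp$weights == 0)) stop("all-zero spectrum")
    E <- sp$energies[sample.int(length(sp$energies), n, replace = TRUE,
                                prob = sp$weights)]
  } else {
    E <- rep(spec$energy, n)
  }
  cbind(pos, dir, E, rep(1, n))
}

#' Sample primaries for any beam spec
#' @inheritParams sample_electron_primaries
#' @param ... passed to the particle-specific sampler.
#' @return n x 8 primaries matrix.
#' @export
sample_primaries <- function(n, spec, grid, ...) {
  if (spec$parallel) sample_proton_primaries(n, spec, grid, ...)
  else if (spec$particle == "electron")
    sample_electron_primaries(n, spec, grid, ...)
  else stop("non-parallel proton sources are not modeled")
}
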