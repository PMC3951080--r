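# SPE proton-spectrum unfolding: pristine-Bragg-peak basis generation and
# non-negative least-squares recovery of the energy spectrum from a
# measured depth-dose curve.

#' Discrete proton energy spectrum
#'
#' @param energies MeV, strictly ascending.
#' @param weights non-negative weights (relative particle fluences).
#' @return object of class `spectrum`.
#' @export
spectrum <- function(energies, weights) {
  if (length(energies) != length(weights)) stop("length mismatch")
  if (any(diff(energies) <= 0)) stop("energies must be strictly ascending")
  if (any(weights < 0)) stop("weights must be >= 0")
  structure(list(energies = as.numeric(energies),
                 weights = as.numeric(weights)),
            class = "spectrum")
}

#' Normalize a spectrum's weights to sum to 1
#' @param sp a `spectrum`.
#' @export
normalize_spectrum <- function(sp) {
  s <- sum(sp$weights)
  if (s <= 0) return(sp)
  spectrum(sp$energies, sp$weights / s)
}

#' Read / write the two-column spectrum file
#'
#' Plain text `energy_MeV weight` rows, `#` comments; the file format
#' consumed by the proton beam model.
#'
#' @param path file path.
#' @export
read_spectrum <- function(path) {
  df <- read.table(path, header = FALSE, comment.char = "#",
                   col.names = c("energy", "weight"))
  spectrum(df$energy, df$weight)
}

#' @rdname read_spectrum
#' @param sp a `spectrum`.
#' @export
write_spectrum <- function(sp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# energy_MeV weight", con)
  writeLines(sprintf("%.6g %.10g", sp$energies, sp$weights), con)
  invisible(path)
}

#' Build a pristine Bragg-peak basis
#'
#' Runs one monoenergetic broad-parallel proton simulation per energy on a
#' water cube and extracts the central-axis depth-dose curve (mean dose in
#' a 5 mm-radius cylinder per depth slab).  Columns can be cached to disk
#' keyed by (energy, configuration) so repeated unfolds are cheap.
#'
#' @param energies MeV, strictly ascending (the SPE band is 20-80 MeV in
#'   1 MeV increments).
#' @param cube water cube `voxel_grid`; default 10 cm cube of 0.5 mm
#'   voxels as used for basis generation.
#' @param cfg a `transport_config`; `base_seed + index - 1` seeds the
#'   per-energy runs.
#' @param radius profile integration radius, cm.
#' @param field lateral half-extents (cm) of the sampled parallel beam
#'   face.  The broad beam is laterally uniform, so only the scoring
#'   cylinder plus a lateral-equilibrium margin needs illumination;
#'   proton lateral spread over these ranges is a few mm, so the default
#'   1.5 cm (1 cm margin beyond the 5 mm integration radius) is ample.
#' @param cache_dir optional directory for cached columns.
#' @return object of class `bragg_basis`: `energies`, `depths` (cm),
#'   `curves` (depth x energy matrix, dose per history).
#' @export
build_basis <- function(energies,
                        cube = make_slab_phantom("water", 10, 0.05),
                        cfg = transport_config(n_histories = 1e4),
                        radius = 0.5, field = c(1.5, 1.5),
                        cache_dir = NULL) {
  if (any(diff(energies) <= 0)) stop("energies must be strictly ascending")
  key_of <- function(E) {
    sprintf("bragg_E%.3f_h%d_v%.4f_s%d", E, cfg$n_histories,
            cube$spacing[3], cfg$base_seed)
  }
  cols <- vector("list", length(energies))
  depths <- NULL
  for (i in seq_along(energies)) {
    E <- energies[i]
    cached <- NULL
    if (!is.null(cache_dir)) {
      f <- file.path(cache_dir, paste0(key_of(E), ".csv"))
      if (file.exists(f)) cached <- read.csv(f)
    }
    if (!is.null(cached)) {
      depths <- cached$depth
      cols[[i]] <- cached$dose
      next
    }
    beam <- beam_spec("proton", spectrum = spectrum(E, 1), axis = "+z")
    dg <- run_transport(cube, beam, cfg, seed = cfg$base_seed + i - 1,
                        field = field)
    pr <- depth_profile(dg, axis = "z", radius = radius)
    depths <- pr$depth
    cols[[i]] <- pr$dose
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(data.frame(depth = pr$depth, dose = pr$dose),
                file.path(cache_dir, paste0(key_of(E), ".csv")),
                row.names = FALSE)
    }
  }
  curves <- do.call(cbind, cols)
  peaks <- apply(curves, 2, which.max)
  if (any(diff(peaks) < 0))
    warning("basis peak depths are not strictly increasing with energy; ",
            "increase histories or refine voxels")
  structure(list(energies = as.numeric(energies), depths = depths,
                 curves = curves),
            class = "bragg_basis")
}

#' Unfold a spectrum from a measured depth-dose curve (NNLS)
#'
#' Resamples the measured curve onto the basis depth grid (linear
#' interpolation, no extrapolation: depths outside the measured support or
#' beyond the deepest basis peak are trimmed) and solves
#' min || basis w - measured ||_2 subject to w >= 0 (Lawson-Hanson NNLS).
#'
#' @param measured a `depth_profile` (or list with `depth`, `dose`).
#' @param basis a `bragg_basis`.
#' @return list with `spectrum` (raw weights), `spectrum_normalized`
#'   (weights summing to 1), `residual_norm`, and `depths_used`.
#' @export
nnls_fit <- function(measured, basis) {
  dmax_basis <- basis$depths[which.max(basis$curves[, ncol(basis$curves)])]
  sel <- basis$depths >= min(measured$depth) &
    basis$depths <= min(max(measured$depth), dmax_basis)
  if (!any(sel)) stop("no overlap between measured depths and the basis grid")
  b <- approx(measured$depth, measured$dose, xout = basis$depths[sel])$y
  A <- basis$curves[sel, , drop = FALSE]
  fit <- pracma::lsqnonneg(A, b)
  w <- pmax(fit$x, 0)
  sp <- spectrum(basis$energies, w)
  list(spectrum = sp,
       spectrum_normalized = normalize_spectrum(sp),
       residual_norm = sqrt(sum((A %*% w - b)^2)),
       depths_used = basis$depths[sel])
}

#' Predict a depth-dose profile from a spectrum and basis
#'
#' The linear combination `basis$curves %*% w` on the basis depth grid.
#' Spectrum energies must all be present in the basis.
#'
#' @param sp a `spectrum`.
#' @param basis a `bragg_basis`.
#' @return a `depth_profile`.
#' @export
predict_profile <- function(sp, basis) {
  idx <- match(sp$energies, basis$energies)
  if (any(is.na(idx)))
    stop("spectrum contains energies absent from the basis: ",
         paste(sp$energies[is.na(idx)], collapse = ", "))
  dose <- as.numeric(basis$curves[, idx, drop = FALSE] %*% sp$weights)
  depth_profile_curve(basis$depths, dose)
}
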