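# Material definitions and Hounsfield-unit conversion.
#
# Elemental data: Z, atomic mass A (g/mol), mean excitation energy I (eV).
# Radiation lengths are computed per element from Tsai's approximation
# X0 = 716.4 A / (Z (Z+1) ln(287/sqrt(Z))) g/cm^2 and combined by mass
# fraction; I for mixtures follows the Bragg additivity rule.

.ELEMENTS <- data.frame(
  symbol = c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Cl", "Ar", "K", "Ca"),
  Z      = c(1, 6, 7, 8, 11, 12, 15, 16, 17, 18, 19, 20),
  A      = c(1.008, 12.011, 14.007, 15.999, 22.990, 24.305, 30.974, 32.06,
             35.45, 39.948, 39.098, 40.078),
  I_eV   = c(19.2, 78.0, 82.0, 95.0, 149.0, 156.0, 173.0, 180.0, 174.0,
             188.0, 190.0, 191.0),
  stringsAsFactors = FALSE
)

.element_x0 <- function(Z, A) 716.4 * A / (Z * (Z + 1) * log(287 / sqrt(Z)))

#' Define a material
#'
#' A material is an elemental composition (mass fractions summing to 1), a
#' reference mass density, a mean excitation energy and a radiation length.
#' When `I_eV` is `NULL` it is derived from the elemental I values by Bragg
#' additivity; the radiation length is always derived from the composition.
#'
#' @param name material name.
#' @param composition named numeric vector of element mass fractions
#'   (names from H, C, N, O, Na, Mg, P, S, Cl, Ar, K, Ca); must sum to 1
#'   within 1e-6.
#' @param density reference mass density in g/cm^3 (> 0).
#' @param I_eV mean excitation energy in eV, or `NULL` to derive it.
#' @return an object of class `material` with fields `name`, `composition`,
#'   `density`, `I_eV`, `Z_over_A` (mol/g) and `X0` (g/cm^2).
#' @export
material <- function(name, composition, density, I_eV = NULL) {
  stopifnot(is.numeric(composition), !is.null(names(composition)))
  unknown <- setdiff(names(composition), .ELEMENTS$symbol)
  if (length(unknown) > 0)
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  if (abs(sum(composition) - 1) > 1e-6)
    stop("mass fractions must sum to 1 (got ", sum(composition), ")")
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  idx <- match(names(composition), .ELEMENTS$symbol)
  w <- as.numeric(composition)
  za_i <- .ELEMENTS$Z[idx] / .ELEMENTS$A[idx]
  Z_over_A <- sum(w * za_i)
  if (is.null(I_eV)) {
    I_eV <- exp(sum(w * za_i * log(.ELEMENTS$I_eV[idx])) / Z_over_A)
  }
  if (I_eV <= 0) stop("mean excitation energy must be > 0")
  X0 <- 1 / sum(w / .element_x0(.ELEMENTS$Z[idx], .ELEMENTS$A[idx]))
  structure(
    list(name = name, composition = composition, density = density,
         I_eV = I_eV, Z_over_A = Z_over_A, X0 = X0),
    class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s  rho=%.4g g/cm^3  I=%.4g eV  Z/A=%.4f  X0=%.3f g/cm^2\n",
              x$name, x$density, x$I_eV, x$Z_over_A, x$X0))
  comp <- paste(sprintf("%s %.4f", names(x$composition), x$composition),
                collapse = ", ")
  cat("  composition:", comp, "\n")
  invisible(x)
}

#' Read a material library from a plain-text definition file
#'
#' The format is a sequence of records:
#' \preformatted{
#' material <name>
#' density <g/cm3>
#' I <eV>            # optional; derived by Bragg additivity when absent
#' elements <sym> <fraction> <sym> <fraction> ...
#' end
#' }
#' Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return named list of `material` objects.
#' @export
read_material_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  mats <- list()
  cur <- NULL
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1]]
    key <- tok[1]
    if (key == "material") {
      cur <- list(name = tok[2], I = NULL)
    } else if (key == "density") {
      cur$density <- as.numeric(tok[2])
    } else if (key == "I") {
      cur$I <- as.numeric(tok[2])
    } else if (key == "elements") {
      v <- tok[-1]
      comp <- as.numeric(v[seq(2, length(v), by = 2)])
      names(comp) <- v[seq(1, length(v), by = 2)]
      cur$composition <- comp
    } else if (key == "end") {
      mats[[cur$name]] <- material(cur$name, cur$composition, cur$density,
                                   I_eV = cur$I)
      cur <- NULL
    } else {
      stop("unrecognized key in material file: ", key)
    }
  }
  mats
}

#' Built-in material library
#'
#' Water, air, Gammex-type solid water, PMMA and a tissue set (soft tissue,
#' adipose, muscle, lung, bone) loaded from the definition file shipped with
#' the package.  The library is cached for the session.
#'
#' @param path optional path to an alternative material definition file.
#' @return named list of `material` objects.
#' @export
material_library <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.voxdose_env$material_library))
      return(.voxdose_env$material_library)
    path <- system.file("extdata", "materials.txt", package = "voxdose")
    lib <- read_material_library(path)
    .voxdose_env$material_library <- lib
    return(lib)
  }
  read_material_library(path)
}

#' Look up one built-in material by name
#' @param name material name in the built-in library.
#' @return a `material`.
#' @export
get_material <- function(name) {
  lib <- material_library()
  if (!name %in% names(lib)) stop("unknown material: ", name)
  lib[[name]]
}

# ---------------------------------------------------------------------------
# Hounsfield-unit conversion

#' Construct an HU conversion table
#'
#' Maps contiguous HU ranges to materials with a piecewise-affine density
#' model density = a + b * HU (g/cm^3).  A Hounsfield value exactly on a bin
#' boundary is assigned to the lower bin; values outside the supported span
#' are clamped to it.
#'
#' @param entries data.frame with columns `hu_low`, `hu_high`, `material`,
#'   `a`, `b` (ascending, contiguous, non-overlapping).
#' @param materials material library used to validate the names.
#' @return an object of class `hu_table`.
#' @export
hu_table <- function(entries, materials = material_library()) {
  need <- c("hu_low", "hu_high", "material", "a", "b")
  if (!all(need %in% names(entries))) stop("entries must have columns ",
                                           paste(need, collapse = ", "))
  if (nrow(entries) == 0) stop("HU conversion table is empty")
  entries <- entries[order(entries$hu_low), , drop = FALSE]
  if (any(entries$hu_high <= entries$hu_low))
    stop("each bin must have hu_high > hu_low")
  if (nrow(entries) > 1 &&
      any(abs(entries$hu_low[-1] - entries$hu_high[-nrow(entries)]) > 1e-9))
    stop("HU bins must be contiguous and non-overlapping")
  bad <- setdiff(entries$material, names(materials))
  if (length(bad) > 0) stop("unknown material(s) in HU table: ",
                            paste(bad, collapse = ", "))
  # density must stay positive across every bin (affine -> check endpoints)
  d_lo <- entries$a + entries$b * entries$hu_low
  d_hi <- entries$a + entries$b * entries$hu_high
  if (any(d_lo <= 0) || any(d_hi <= 0))
    stop("density model must be positive across each HU bin")
  structure(list(entries = entries, materials = names(materials)),
            class = "hu_table")
}

#' Read an HU conversion table from a plain-text file
#'
#' Rows of `hu_low hu_high material a b`; `#` comments allowed.  Allows the
#' full granularity of stoichiometric calibration schemes via a user file.
#'
#' @param path file path.
#' @param materials material library for validation.
#' @return an `hu_table`.
#' @export
read_hu_table <- function(path, materials = material_library()) {
  df <- read.table(path, header = FALSE, comment.char = "#",
                   col.names = c("hu_low", "hu_high", "material", "a", "b"),
                   stringsAsFactors = FALSE)
  hu_table(df, materials)
}

#' Default 4-bin HU conversion table
#'
#' air below -950 HU, lung -950..-200, soft tissue -200..+120, bone above
#' +120, with affine density ramps continuous at the bin boundaries and the
#' Hounsfield anchor points rho(0 HU) = 1.00 g/cm^3 and rho(-1000 HU) = air.
#'
#' @return an `hu_table`.
#' @export
default_hu_table <- function() {
  if (!is.null(.voxdose_env$default_hu_table))
    return(.voxdose_env$default_hu_table)
  path <- system.file("extdata", "hu_table_default.txt", package = "voxdose")
  tab <- read_hu_table(path)
  .voxdose_env$default_hu_table <- tab
  tab
}

#' Convert Hounsfield units to (material, density)
#'
#' Deterministic bin lookup with the boundary rule "exact boundary goes to
#' the lower bin"; HU outside the table span is clamped to the span before
#' lookup.
#'
#' @param hu numeric vector of Hounsfield units.
#' @param table an `hu_table`.
#' @return list with `material` (character), `material_index` (index into
#'   the table's material name set, see `grid_materials`), and `density`
#'   (g/cm^3), each of `length(hu)`.
#' @export
hu_to_material <- function(hu, table = default_hu_table()) {
  if (!inherits(table, "hu_table")) stop("table must be an hu_table")
  e <- table$entries
  hu <- pmin(pmax(hu, min(e$hu_low)), max(e$hu_high))
  # bins are (hu_low, hu_high]; the lowest bin also includes its hu_low
  idx <- findInterval(hu, e$hu_low, left.open = TRUE) # boundary -> lower bin
  idx[idx < 1] <- 1L
  mat <- e$material[idx]
  dens <- e$a[idx] + e$b[idx] * hu
  list(material = mat,
       material_index = match(mat, unique(e$material)),
       density = dens)
}
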