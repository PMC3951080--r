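# Portable array container: a single self-describing binary file holding
# named arrays plus attributes (JSON header + raw little-endian payloads).
# Round-trips bit-exactly; used as the on-disk form of voxel grids and
# dose matrices.
#
# Layout: magic "VXC1" | int32 header length | header JSON (UTF-8) |
# payloads in header order.  dtypes: float64, int32, uint8.

.vxc_sizes <- c(float64 = 8L, int32 = 4L, uint8 = 1L)

#' Write arrays and attributes to a portable container file
#'
#' @param path output file.
#' @param arrays named list of numeric/integer/logical arrays (logical is
#'   stored as uint8).
#' @param attrs named list of scalar/vector attributes (stored in the
#'   JSON header).
#' @return `path`, invisibly.
#' @export
write_container <- function(path, arrays, attrs = list()) {
  stopifnot(length(arrays) == 0 || !is.null(names(arrays)))
  meta <- lapply(names(arrays), function(nm) {
    a <- arrays[[nm]]
    dtype <- if (is.logical(a)) "uint8" else if (is.integer(a)) "int32"
             else "float64"
    list(name = nm, dtype = dtype,
         dims = if (is.null(dim(a))) length(a) else dim(a))
  })
  header <- jsonlite::toJSON(list(arrays = meta, attrs = attrs),
                             auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("VXC1"), con)
  writeBin(length(hraw), con, size = 4, endian = "little")
  writeBin(hraw, con)
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    if (is.logical(a)) {
      writeBin(as.raw(as.integer(a)), con)
    } else if (is.integer(a)) {
      writeBin(as.vector(a), con, size = 4, endian = "little")
    } else {
      writeBin(as.vector(as.numeric(a)), con, size = 8, endian = "little")
    }
  }
  invisible(path)
}

#' Read a portable container file
#'
#' @param path file written by [write_container()].
#' @return list with `arrays` (named, dims restored) and `attrs`.
#' @export
read_container <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "VXC1") stop("not a voxdose container: ", path)
  hlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                               simplifyVector = TRUE)
  arrays <- list()
  meta <- header$arrays
  for (i in seq_len(NROW(meta))) {
    nm <- meta$name[i]
    dtype <- meta$dtype[i]
    dims <- if (is.list(meta$dims)) meta$dims[[i]] else meta$dims[i]
    n <- prod(dims)
    a <- switch(dtype,
      float64 = readBin(con, "double", n, size = 8, endian = "little"),
      int32 = readBin(con, "integer", n, size = 4, endian = "little"),
      uint8 = as.logical(as.integer(readBin(con, "raw", n))),
      stop("unknown dtype: ", dtype))
    if (length(dims) > 1) dim(a) <- dims
    arrays[[nm]] <- a
  }
  list(arrays = arrays, attrs = header$attrs)
}

#' Write / read a voxel grid as a container file
#' @param g a `voxel_grid`.
#' @param path file path.
#' @export
write_grid <- function(g, path) {
  write_container(path,
                  arrays = list(material_index = g$material_index,
                                density = g$density),
                  attrs = list(origin = g$origin, spacing = g$spacing,
                               materials = g$materials, kind = "voxel_grid"))
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  x <- read_container(path)
  voxel_grid(x$attrs$origin, x$attrs$spacing,
             x$arrays$material_index, x$arrays$density,
             x$attrs$materials)
}

#' Write / read a dose grid as a container file
#' @param d a `dose_grid`.
#' @param path file path.
#' @export
write_dose <- function(d, path) {
  arrays <- list(dose = d$dose)
  if (!is.null(d$sem)) arrays$sem <- d$sem
  write_container(path, arrays = arrays,
                  attrs = list(origin = d$origin, spacing = d$spacing,
                               histories = d$histories, kind = "dose_grid"))
}

#' @rdname write_dose
#' @export
read_dose <- function(path) {
  x <- read_container(path)
  structure(list(dose = x$arrays$dose, sem = x$arrays$sem,
                 histories = x$attrs$histories,
                 origin = x$attrs$origin, spacing = x$attrs$spacing,
                 dims = dim(x$arrays$dose)),
            class = "dose_grid")
}

#' Write a labeled-mask volume (animal masks) as a container file
#' @param masks named list of `structure_mask`s.
#' @param path file path.
#' @export
write_masks <- function(masks, path) {
  lab <- array(0L, dim(masks[[1]]$mask))
  for (i in seq_along(masks)) lab[masks[[i]]$mask] <- i
  write_container(path, arrays = list(labels = lab),
                  attrs = list(names = names(masks), kind = "label_volume"))
}
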