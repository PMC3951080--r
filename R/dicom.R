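# Minimal DICOM support: explicit-VR little-endian reading of CT image
# slices and writing of RT-Dose (and synthetic CT) files.  Covers the tag
# subset needed to exchange dose matrices and CT geometry with clinical
# visualization software; sequences (SQ) and compressed transfer syntaxes
# are out of scope.  World units here are cm; DICOM stores mm.

.UID_ROOT <- "1.2.826.0.1.3680043.10763."   # generated-by-voxdose UID arm
.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
.SOP_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"

.uid_for <- function(x) {
  # deterministic UID from content so identical runs write identical files
  h <- sum(as.numeric(utf8ToInt(paste(format(x), collapse = ""))) *
             seq_along(utf8ToInt(paste(format(x), collapse = "")))) %% 1e9
  paste0(.UID_ROOT, format(h, scientific = FALSE), ".",
         length(x) %% 997)
}

.u16_to_raw <- function(v) {
  v <- as.integer(round(v))
  writeBin(as.integer(ifelse(v > 32767L, v - 65536L, v)), raw(),
           size = 2, endian = "little")
}

.raw_to_u16 <- function(r) {
  v <- readBin(r, "integer", length(r) / 2, size = 2, signed = TRUE,
               endian = "little")
  ifelse(v < 0, v + 65536, v)
}

# one explicit-VR little-endian data element as a raw vector
.dcm_element <- function(group, element, vr, value) {
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(element), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  body <- switch(vr,
    UI = { r <- charToRaw(value); if (length(r) %% 2) r <- c(r, as.raw(0)); r },
    UL = writeBin(as.integer(value), raw(), size = 4, endian = "little"),
    US = .u16_to_raw(value),
    OW = value,  # already raw
    AT = value,  # already raw (tag pair)
    {  # string VRs: CS, DS, IS, LO, SH, DA, TM, PN, ST
      s <- paste(value, collapse = "\\")
      r <- charToRaw(s)
      if (length(r) %% 2) r <- c(r, charToRaw(" "))
      r
    })
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(body), con = raw(), size = 4, endian = "little"), body)
  } else {
    c(head, .u16_to_raw(length(body)), body)
  }
}

.dcm_file <- function(sop_class, sop_instance, dataset_elements) {
  meta <- c(
    .dcm_element(0x0002, 0x0002, "UI", sop_class),
    .dcm_element(0x0002, 0x0003, "UI", sop_instance),
    .dcm_element(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE),
    .dcm_element(0x0002, 0x0012, "UI", paste0(.UID_ROOT, "1")))
  c(raw(128), charToRaw("DICM"),
    .dcm_element(0x0002, 0x0000, "UL", length(meta)),
    meta, dataset_elements)
}

.ds_fmt <- function(x) sprintf("%.8g", x)

#' Write a dose grid as a DICOM RT-Dose file
#'
#' Standard single-SOP RT-Dose: 16-bit unsigned pixel grid with
#' `DoseGridScaling` chosen so the stored integers span the dose range
#' (quantization <= 0.1% of the maximum dose); grid geometry is taken
#' from the dose grid's frame (cm -> mm).  Re-reading reproduces the dose
#' within the quantization bound.
#'
#' @param dose a `dose_grid`.
#' @param path output file.
#' @param frame optional list overriding `origin` (cm) and `spacing` (cm)
#'   of the CT frame of reference.
#' @return `path`, invisibly.
#' @export
write_rtdose <- function(dose, path, frame = NULL) {
  origin <- if (!is.null(frame$origin)) frame$origin else dose$origin
  spacing <- if (!is.null(frame$spacing)) frame$spacing else dose$spacing
  if (is.null(origin) || is.null(spacing))
    stop("missing frame info (origin/spacing)")
  d <- dose$dose
  dims <- dim(d)
  dmax <- max(d)
  scaling <- if (dmax > 0) dmax / 65535 else 1
  stored <- round(d / scaling)
  ipp_mm <- (origin + spacing / 2) * 10   # center of the first voxel
  offsets_mm <- (seq_len(dims[3]) - 1) * spacing[3] * 10
  sop <- .uid_for(c(dims, dmax, sum(d)))
  el <- c(
    .dcm_element(0x0008, 0x0016, "UI", .SOP_RTDOSE),
    .dcm_element(0x0008, 0x0018, "UI", sop),
    .dcm_element(0x0008, 0x0060, "CS", "RTDOSE"),
    .dcm_element(0x0020, 0x0032, "DS", .ds_fmt(ipp_mm)),
    .dcm_element(0x0020, 0x0037, "DS", .ds_fmt(c(1, 0, 0, 0, 1, 0))),
    .dcm_element(0x0028, 0x0002, "US", 1),
    .dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcm_element(0x0028, 0x0008, "IS", as.character(dims[3])),
    .dcm_element(0x0028, 0x0009, "AT",
                 c(writeBin(0x3004L, raw(), size = 2, endian = "little"),
                   writeBin(0x000cL, raw(), size = 2, endian = "little"))),
    .dcm_element(0x0028, 0x0010, "US", dims[2]),   # Rows (y)
    .dcm_element(0x0028, 0x0011, "US", dims[1]),   # Columns (x)
    .dcm_element(0x0028, 0x0030, "DS", .ds_fmt(c(spacing[2], spacing[1]) * 10)),
    .dcm_element(0x0028, 0x0100, "US", 16),
    .dcm_element(0x0028, 0x0101, "US", 16),
    .dcm_element(0x0028, 0x0102, "US", 15),
    .dcm_element(0x0028, 0x0103, "US", 0),
    .dcm_element(0x3004, 0x0002, "CS", "GY"),
    .dcm_element(0x3004, 0x0004, "CS", "PHYSICAL"),
    .dcm_element(0x3004, 0x000a, "CS", "PLAN"),
    .dcm_element(0x3004, 0x000c, "DS", .ds_fmt(offsets_mm)),
    .dcm_element(0x3004, 0x000e, "DS", sprintf("%.10e", scaling)),
    .dcm_element(0x7fe0, 0x0010, "OW", .u16_to_raw(as.vector(stored))))
  writeBin(.dcm_file(.SOP_RTDOSE, sop, el), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Reading

.dcm_parse <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  pos <- 133L
  els <- list()
  n <- length(raw)
  while (pos + 8 <= n + 1) {
    grp <- .raw_to_u16(raw[pos:(pos + 1)])
    ele <- .raw_to_u16(raw[(pos + 2):(pos + 3)])
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- readBin(raw[(pos + 8):(pos + 11)], "integer", 1, size = 4,
                     endian = "little")
      body_start <- pos + 12L
    } else {
      len <- .raw_to_u16(raw[(pos + 6):(pos + 7)])
      body_start <- pos + 8L
    }
    if (len < 0) stop("undefined lengths are not supported")
    key <- sprintf("%04x,%04x", grp, ele)
    els[[key]] <- list(vr = vr, raw = raw[seq(body_start, length.out = len)])
    pos <- body_start + len
  }
  els
}

.dcm_value <- function(els, key, required = TRUE) {
  e <- els[[key]]
  if (is.null(e)) {
    if (required) stop("missing DICOM tag (", key, ")")
    return(NULL)
  }
  switch(e$vr,
    US = .raw_to_u16(e$raw),
    UL = readBin(e$raw, "integer", length(e$raw) / 4, size = 4,
                 endian = "little"),
    DS = as.numeric(strsplit(trimws(rawToChar(e$raw)), "\\\\")[[1]]),
    IS = as.integer(strsplit(trimws(rawToChar(e$raw)), "\\\\")[[1]]),
    OW = e$raw,
    trimws(rawToChar(e$raw)))
}

#' Read a DICOM RT-Dose file
#'
#' @param path RT-Dose file (explicit VR little endian).
#' @return a `dose_grid` (Gy; geometry in cm).
#' @export
read_rtdose <- function(path) {
  els <- .dcm_parse(path)
  nx <- .dcm_value(els, "0028,0011")
  ny <- .dcm_value(els, "0028,0010")
  nz <- .dcm_value(els, "0028,0008")
  scaling <- .dcm_value(els, "3004,000e")
  ps <- .dcm_value(els, "0028,0030") / 10
  offs <- .dcm_value(els, "3004,000c") / 10
  dz <- if (length(offs) > 1) offs[2] - offs[1] else ps[1]
  ipp <- .dcm_value(els, "0020,0032") / 10
  stored <- .raw_to_u16(.dcm_value(els, "7fe0,0010"))
  dose <- array(stored * scaling, c(nx, ny, nz))
  spacing <- c(ps[2], ps[1], dz)
  structure(list(dose = dose, sem = NULL, histories = NA,
                 origin = ipp - spacing / 2, spacing = spacing,
                 dims = c(nx, ny, nz)),
            class = "dose_grid")
}

#' Write a synthetic CT series (one file per slice)
#'
#' Support for building test/demo geometries: writes a Hounsfield-unit
#' volume as standard CT image slices (16-bit signed, rescale intercept
#' 0/slope 1).  Files are named `ct_###.dcm` under `dir`.
#'
#' @param hu 3-D HU array (x, y, z).
#' @param origin corner of voxel (1,1,1), cm.
#' @param spacing voxel spacing, cm.
#' @param dir output directory (created).
#' @return character vector of file paths.
#' @export
write_ct_series <- function(hu, origin, spacing, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dims <- dim(hu)
  series <- .uid_for(c(dims, sum(hu)))
  paths <- character(dims[3])
  for (k in seq_len(dims[3])) {
    ipp_mm <- c((origin[1:2] + spacing[1:2] / 2) * 10,
                (origin[3] + (k - 0.5) * spacing[3]) * 10)
    sop <- .uid_for(c(dims, k, sum(hu[, , k])))
    px <- as.integer(round(as.vector(hu[, , k])))
    el <- c(
      .dcm_element(0x0008, 0x0016, "UI", .SOP_CT),
      .dcm_element(0x0008, 0x0018, "UI", sop),
      .dcm_element(0x0008, 0x0060, "CS", "CT"),
      .dcm_element(0x0020, 0x000e, "UI", series),
      .dcm_element(0x0020, 0x0013, "IS", as.character(k)),
      .dcm_element(0x0020, 0x0032, "DS", .ds_fmt(ipp_mm)),
      .dcm_element(0x0020, 0x0037, "DS", .ds_fmt(c(1, 0, 0, 0, 1, 0))),
      .dcm_element(0x0028, 0x0002, "US", 1),
      .dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcm_element(0x0028, 0x0010, "US", dims[2]),
      .dcm_element(0x0028, 0x0011, "US", dims[1]),
      .dcm_element(0x0028, 0x0030, "DS",
                   .ds_fmt(c(spacing[2], spacing[1]) * 10)),
      .dcm_element(0x0018, 0x0050, "DS", .ds_fmt(spacing[3] * 10)),
      .dcm_element(0x0028, 0x0100, "US", 16),
      .dcm_element(0x0028, 0x0101, "US", 16),
      .dcm_element(0x0028, 0x0102, "US", 15),
      .dcm_element(0x0028, 0x0103, "US", 1),  # signed
      .dcm_element(0x0028, 0x1052, "DS", "0"),
      .dcm_element(0x0028, 0x1053, "DS", "1"),
      .dcm_element(0x7fe0, 0x0010, "OW",
                   writeBin(px, raw(), size = 2, endian = "little")))
    paths[k] <- file.path(dir, sprintf("ct_%03d.dcm", k))
    writeBin(.dcm_file(.SOP_CT, sop, el), paths[k])
  }
  paths
}

#' Read a DICOM CT series into an HU volume
#'
#' Slices are sorted by their z position; non-uniform slice spacing is
#' rejected.
#'
#' @param paths character vector of slice files, or a directory.
#' @return list with `hu` (3-D array), `origin` (cm), `spacing` (cm).
#' @export
read_ct_series <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.dcm$", full.names = TRUE)
  if (length(paths) == 0) stop("no CT slices found")
  slices <- lapply(paths, function(p) {
    els <- .dcm_parse(p)
    nx <- .dcm_value(els, "0028,0011")
    ny <- .dcm_value(els, "0028,0010")
    ps <- .dcm_value(els, "0028,0030") / 10
    ipp <- .dcm_value(els, "0020,0032") / 10
    slope <- .dcm_value(els, "0028,1053", required = FALSE)
    icept <- .dcm_value(els, "0028,1052", required = FALSE)
    if (is.null(slope)) slope <- 1
    if (is.null(icept)) icept <- 0
    px <- readBin(.dcm_value(els, "7fe0,0010"), "integer", nx * ny,
                  size = 2, signed = TRUE, endian = "little")
    list(hu = matrix(px * slope + icept, nx, ny), ipp = ipp,
         ps = c(ps[2], ps[1]))
  })
  z <- vapply(slices, function(s) s$ipp[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  if (length(z) > 1) {
    dz <- diff(z)
    if (max(abs(dz - dz[1])) > 1e-6)
      stop("non-uniform slice spacing")
    dz <- dz[1]
  } else dz <- 1
  hu <- array(0, c(dim(slices[[1]]$hu), length(z)))
  for (k in seq_along(slices)) hu[, , k] <- slices[[k]]$hu
  sp <- c(slices[[1]]$ps, dz)
  origin <- c(slices[[1]]$ipp[1:2] - sp[1:2] / 2, z[1] - dz / 2)
  list(hu = hu, origin = origin, spacing = sp)
}

#' Read a JSON contour file (fallback structure format)
#'
#' Documented fallback for DICOM RT-Structure: a JSON object
#' `{"name": ..., "slices": [{"z": <cm>, "xy": [[x, y], ...]}, ...]}`.
#'
#' @param path JSON file.
#' @return list of slices usable by [rasterize_contour()], with attribute
#'   `name`.
#' @export
read_json_contour <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  slices <- lapply(j$slices, function(s) {
    list(z = s$z, xy = do.call(rbind, lapply(s$xy, unlist)))
  })
  attr(slices, "name") <- if (!is.null(j$name)) j$name else "BODY"
  slices
}
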