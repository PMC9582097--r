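#' Detector image container
#'
#' Bundles a raw ("for processing") detector pixel matrix with its physical
#' pixel spacing and the exposure metadata needed downstream (STP, NPS, MTF).
#'
#' @param pixels Integer-valued matrix of detector pixel values; rows increase
#'   downward, columns rightward (0-based origins are used for all region
#'   arithmetic).
#' @param dx,dy Pixel spacing in the column (x) and row (y) direction, mm.
#' @param kvp Tube voltage, kV, or `NA` if absent from the source metadata.
#' @param mas Tube load, mAs, or `NA`.
#' @param anode_filter Anode/filter label, e.g. `"W/Rh"`, or `NA`.
#' @param chest_wall_side Which image border faces the chest wall:
#'   `"top"`, `"bottom"`, `"left"` or `"right"`.
#' @return An object of class `detector_image`.
#' @export
detector_image <- function(pixels, dx, dy, kvp = NA_real_, mas = NA_real_,
                           anode_filter = NA_character_,
                           chest_wall_side = "bottom") {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (!is.numeric(dx) || length(dx) != 1L || is.na(dx) || dx <= 0)
    stop("dx must be a single positive number (mm)")
  if (!is.numeric(dy) || length(dy) != 1L || is.na(dy) || dy <= 0)
    stop("dy must be a single positive number (mm)")
  if (any(pixels < 0, na.rm = TRUE)) stop("pixel values must be non-negative")
  chest_wall_side <- match.arg(chest_wall_side,
                               c("top", "bottom", "left", "right"))
  structure(
    list(pixels = pixels, dx = dx, dy = dy,
         kvp = as.numeric(kvp), mas = as.numeric(mas),
         anode_filter = as.character(anode_filter),
         chest_wall_side = chest_wall_side),
    class = "detector_image")
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf("<detector_image> %d x %d px, dx=%g mm, dy=%g mm\n",
              nrow(x$pixels), ncol(x$pixels), x$dx, x$dy))
  cat(sprintf("  kVp=%s mAs=%s anode/filter=%s chest wall side=%s\n",
              format(x$kvp), format(x$mas), x$anode_filter,
              x$chest_wall_side))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Raw fixture format: <base>.hdr key=value sidecar + <base>.raw 16-bit
# little-endian pixels, row-major. Exists so tests and synthetic studies never
# need a DICOM round trip; DICOM remains the primary interface.

#' Write a detector image in the raw fixture format
#'
#' Writes `<path>.hdr` (plain-text `key=value` sidecar with dimensions,
#' spacing and exposure metadata) and `<path>.raw` (unsigned 16-bit
#' little-endian pixels, row-major).
#'
#' @param image A [detector_image()].
#' @param path Output path without extension (or with `.raw`, which is
#'   stripped).
#' @return `path`, invisibly.
#' @export
write_raw_image <- function(image, path) {
  stopifnot(inherits(image, "detector_image"))
  base <- sub("\\.(raw|hdr)$", "", path)
  px <- image$pixels
  if (any(px > 65535)) stop("pixel values exceed 16-bit range")
  hdr <- c(
    sprintf("rows=%d", nrow(px)),
    sprintf("cols=%d", ncol(px)),
    sprintf("dx_mm=%.17g", image$dx),
    sprintf("dy_mm=%.17g", image$dy),
    sprintf("kvp=%s", ifelse(is.na(image$kvp), "", format(image$kvp, digits = 17))),
    sprintf("mas=%s", ifelse(is.na(image$mas), "", format(image$mas, digits = 17))),
    sprintf("anode_filter=%s", ifelse(is.na(image$anode_filter), "", image$anode_filter)),
    sprintf("chest_wall_side=%s", image$chest_wall_side))
  writeLines(hdr, paste0(base, ".hdr"))
  con <- file(paste0(base, ".raw"), "wb")
  on.exit(close(con))
  # row-major: write the transpose so that rows are contiguous
  writeBin(as.integer(t(px)), con, size = 2, endian = "little")
  invisible(base)
}

read_raw_image <- function(path) {
  base <- sub("\\.(raw|hdr)$", "", path)
  hdr_path <- paste0(base, ".hdr")
  raw_path <- paste0(base, ".raw")
  if (!file.exists(hdr_path) || !file.exists(raw_path))
    stop("cannot read raw fixture image: missing ", hdr_path, " or ", raw_path)
  kv <- strsplit(readLines(hdr_path), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), "")
  names(vals) <- keys
  need <- c("rows", "cols", "dx_mm", "dy_mm")
  if (!all(need %in% keys))
    stop("raw fixture header lacks required keys: ",
         paste(setdiff(need, keys), collapse = ", "))
  nr <- as.integer(vals[["rows"]]); nc <- as.integer(vals[["cols"]])
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = nr * nc, size = 2, signed = FALSE,
               endian = "little")
  if (length(v) != nr * nc)
    stop("raw pixel payload truncated in ", raw_path)
  px <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
  num_or_na <- function(key) {
    s <- if (key %in% keys) vals[[key]] else ""
    if (identical(s, "")) NA_real_ else as.numeric(s)
  }
  chr_or_na <- function(key) {
    s <- if (key %in% keys) vals[[key]] else ""
    if (identical(s, "")) NA_character_ else s
  }
  detector_image(px,
                 dx = as.numeric(vals[["dx_mm"]]),
                 dy = as.numeric(vals[["dy_mm"]]),
                 kvp = num_or_na("kvp"), mas = num_or_na("mas"),
                 anode_filter = chr_or_na("anode_filter"),
                 chest_wall_side = if ("chest_wall_side" %in% keys)
                   vals[["chest_wall_side"]] else "bottom")
}

# ---------------------------------------------------------------------------
# Minimal DICOM support: single-frame monochrome, Explicit VR Little Endian,
# uncompressed. Covers exactly the subset the measurement chain needs.

.dicom_tag <- function(group, element) sprintf("%04X%04X", group, element)

.TAG_PIXEL_SPACING        <- .dicom_tag(0x0028, 0x0030)
.TAG_IMAGER_PIXEL_SPACING <- .dicom_tag(0x0018, 0x1164)
.TAG_ROWS                 <- .dicom_tag(0x0028, 0x0010)
.TAG_COLS                 <- .dicom_tag(0x0028, 0x0011)
.TAG_BITS_ALLOC           <- .dicom_tag(0x0028, 0x0100)
.TAG_PIXEL_REP            <- .dicom_tag(0x0028, 0x0103)
.TAG_KVP                  <- .dicom_tag(0x0018, 0x0060)
.TAG_EXPOSURE_MAS         <- .dicom_tag(0x0018, 0x1152)
.TAG_EXPOSURE_UAS         <- .dicom_tag(0x0018, 0x1153)
.TAG_ANODE                <- .dicom_tag(0x0018, 0x1191)
.TAG_FILTER               <- .dicom_tag(0x0018, 0x7050)
.TAG_PIXEL_DATA           <- .dicom_tag(0x7FE0, 0x0010)

.u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
.u32 <- function(raw4) .u16(raw4[1:2]) + 65536 * .u16(raw4[3:4])

# Parses an explicit-VR-little-endian element stream into a named list of raw
# payloads keyed by "GGGGEEEE". Stops at end of `buf` or after `stop_group`.
.parse_dicom_elements <- function(buf, pos, stop_before_group = NULL) {
  out <- list()
  n <- length(buf)
  long_vrs <- c("OB", "OW", "OF", "OL", "OD", "SQ", "UC", "UR", "UT", "UN")
  while (pos + 7L <= n) {
    group <- .u16(buf[pos:(pos + 1L)])
    if (!is.null(stop_before_group) && group >= stop_before_group) break
    element <- .u16(buf[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- .u32(buf[(pos + 8L):(pos + 11L)])
      data_start <- pos + 12L
    } else {
      len <- .u16(buf[(pos + 6L):(pos + 7L)])
      data_start <- pos + 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements unsupported")
    key <- .dicom_tag(group, element)
    out[[key]] <- if (len > 0) buf[data_start:(data_start + len - 1L)] else raw(0)
    pos <- data_start + len
  }
  list(elements = out, pos = pos)
}

.dicom_str <- function(el, key) {
  if (is.null(el[[key]])) return(NA_character_)
  trimws(rawToChar(el[[key]]))
}
.dicom_num <- function(el, key) {
  s <- .dicom_str(el, key)
  if (is.na(s) || s == "") NA_real_ else suppressWarnings(as.numeric(s))
}

#' Read a single-frame DICOM detector image
#'
#' Supports uncompressed single-frame monochrome images in Explicit VR Little
#' Endian transfer syntax. Pixel spacing (0028,0030) or Imager Pixel Spacing
#' (0018,1164) is required; KVP, Exposure (mAs or uAs) and anode/filter are
#' read when present and flagged `NA` otherwise, never silently defaulted.
#'
#' @param path Path to a DICOM part-10 file.
#' @return A [detector_image()].
#' @export
read_dicom <- function(path) {
  if (!file.exists(path)) stop("cannot read DICOM file: ", path)
  buf <- readBin(path, "raw", n = file.info(path)$size)
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  meta <- .parse_dicom_elements(buf, 133L, stop_before_group = 0x0008)
  ts <- .dicom_str(meta$elements, .dicom_tag(0x0002, 0x0010))
  if (!is.na(ts) && !(ts %in% "1.2.840.10008.1.2.1"))
    stop("unsupported DICOM transfer syntax: ", ts,
         " (only Explicit VR Little Endian is supported)")
  el <- .parse_dicom_elements(buf, meta$pos)$elements

  spacing <- .dicom_str(el, .TAG_PIXEL_SPACING)
  if (is.na(spacing)) spacing <- .dicom_str(el, .TAG_IMAGER_PIXEL_SPACING)
  if (is.na(spacing) || spacing == "")
    stop("DICOM metadata error: no Pixel Spacing or Imager Pixel Spacing in ",
         path, " (spacing is required for all frequency-domain analysis)")
  sp <- as.numeric(strsplit(spacing, "\\\\")[[1]])
  if (length(sp) == 1L) sp <- c(sp, sp)
  # DICOM order: row spacing (dy) first, then column spacing (dx)
  dy <- sp[1]; dx <- sp[2]

  nr <- .u16(el[[.TAG_ROWS]]); nc <- .u16(el[[.TAG_COLS]])
  bits <- if (!is.null(el[[.TAG_BITS_ALLOC]])) .u16(el[[.TAG_BITS_ALLOC]]) else 16L
  if (!bits %in% c(8L, 16L)) stop("unsupported BitsAllocated: ", bits)
  pix_raw <- el[[.TAG_PIXEL_DATA]]
  if (is.null(pix_raw)) stop("DICOM file has no pixel data: ", path)
  v <- if (bits == 16L)
    readBin(pix_raw, "integer", n = nr * nc, size = 2, signed = FALSE,
            endian = "little")
  else as.integer(pix_raw[seq_len(nr * nc)])
  if (length(v) < nr * nc) stop("DICOM pixel payload truncated in ", path)
  px <- matrix(v[seq_len(nr * nc)], nrow = nr, ncol = nc, byrow = TRUE)

  mas <- .dicom_num(el, .TAG_EXPOSURE_MAS)
  if (is.na(mas)) {
    uas <- .dicom_num(el, .TAG_EXPOSURE_UAS)
    if (!is.na(uas)) mas <- uas / 1000
  }
  anode <- .dicom_str(el, .TAG_ANODE)
  filt <- .dicom_str(el, .TAG_FILTER)
  af <- if (!is.na(anode) && !is.na(filt)) paste0(anode, "/", filt)
        else NA_character_
  detector_image(px, dx = dx, dy = dy, kvp = .dicom_num(el, .TAG_KVP),
                 mas = mas, anode_filter = af)
}

.dicom_element_raw <- function(group, element, vr, payload) {
  if (length(payload) %% 2L == 1L)
    payload <- c(payload, as.raw(if (vr %in% c("UI")) 0x00 else 0x20))
  head <- writeBin(c(as.integer(group), as.integer(element)), raw(),
                   size = 2, endian = "little")
  if (vr %in% c("OB", "OW", "UN", "SQ", "UT")) {
    c(head, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(payload), raw(), size = 4, endian = "little"), payload)
  } else {
    c(head, charToRaw(vr),
      writeBin(length(payload), raw(), size = 2, endian = "little"), payload)
  }
}

.dicom_str_element <- function(group, element, vr, value) {
  .dicom_element_raw(group, element, vr, charToRaw(as.character(value)))
}

#' Write a detector image as a minimal DICOM file
#'
#' Produces a part-10 Explicit VR Little Endian single-frame monochrome file
#' with the attributes [read_dicom()] consumes (dimensions, Imager Pixel
#' Spacing, KVP, Exposure, anode/filter, 16-bit pixel data).
#'
#' @param image A [detector_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(image, path) {
  stopifnot(inherits(image, "detector_image"))
  px <- image$pixels
  if (any(px > 65535)) stop("pixel values exceed 16-bit range")
  ts_uid <- "1.2.840.10008.1.2.1"
  meta <- c(
    .dicom_element_raw(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .dicom_str_element(0x0002, 0x0010, "UI", ts_uid))
  meta_len <- .dicom_element_raw(0x0002, 0x0000, "UL",
    writeBin(length(meta), raw(), size = 4, endian = "little"))

  af <- if (is.na(image$anode_filter)) c(NA, NA)
        else strsplit(image$anode_filter, "/", fixed = TRUE)[[1]]
  body <- c(
    .dicom_str_element(0x0008, 0x0060, "CS", "MG"),
    if (!is.na(image$kvp))
      .dicom_str_element(0x0018, 0x0060, "DS", format(image$kvp, digits = 10)),
    if (!is.na(image$mas))
      .dicom_str_element(0x0018, 0x1153, "IS",
                         sprintf("%d", as.integer(round(image$mas * 1000)))),
    .dicom_str_element(0x0018, 0x1164, "DS",
      paste(format(image$dy, digits = 10), format(image$dx, digits = 10),
            sep = "\\")),
    if (!anyNA(af) && length(af) == 2L)
      .dicom_str_element(0x0018, 0x1191, "CS", af[1]),
    if (!anyNA(af) && length(af) == 2L)
      .dicom_str_element(0x0018, 0x7050, "CS", af[2]),
    .dicom_element_raw(0x0028, 0x0002, "US",
      writeBin(1L, raw(), size = 2, endian = "little")),
    .dicom_str_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dicom_element_raw(0x0028, 0x0010, "US",
      writeBin(nrow(px), raw(), size = 2, endian = "little")),
    .dicom_element_raw(0x0028, 0x0011, "US",
      writeBin(ncol(px), raw(), size = 2, endian = "little")),
    .dicom_element_raw(0x0028, 0x0100, "US",
      writeBin(16L, raw(), size = 2, endian = "little")),
    .dicom_element_raw(0x0028, 0x0101, "US",
      writeBin(16L, raw(), size = 2, endian = "little")),
    .dicom_element_raw(0x0028, 0x0102, "US",
      writeBin(15L, raw(), size = 2, endian = "little")),
    .dicom_element_raw(0x0028, 0x0103, "US",
      writeBin(0L, raw(), size = 2, endian = "little")),
    .dicom_element_raw(0x7FE0, 0x0010, "OW",
      writeBin(as.integer(t(px)), raw(), size = 2, endian = "little")))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  writeBin(c(meta_len, meta, body), con)
  invisible(path)
}

#' Read a detector image (DICOM or raw fixture format)
#'
#' Dispatches on the file: DICOM part-10 files (by magic bytes or `.dcm`
#' extension) go through [read_dicom()]; anything else is treated as the raw
#' fixture format (`.hdr` + `.raw` sidecar pair).
#'
#' @param path Path to the image file.
#' @return A [detector_image()].
#' @export
read_image <- function(path) {
  probe <- if (file.exists(path)) path else paste0(sub("\\.(raw|hdr)$", "", path), ".raw")
  if (!file.exists(probe) && !file.exists(paste0(sub("\\.(raw|hdr)$", "", path), ".hdr")))
    stop("cannot read image, file does not exist: ", path)
  if (file.exists(path) && !grepl("\\.(raw|hdr)$", path)) {
    buf <- readBin(path, "raw", n = 132)
    if (length(buf) >= 132 && rawToChar(buf[129:132]) == "DICM")
      return(read_dicom(path))
  }
  read_raw_image(path)
}

#' Extract a square physical analysis region from a detector image
#'
#' Cuts a `floor(side_mm/dx) x floor(side_mm/dy)`-pixel block. The default
#' placement centres the region in the image; `placement = "chest_wall"`
#' centres it laterally and puts its inner edge `chest_wall_offset_mm` from
#' the chest-wall border of the detector.
#'
#' @param image A [detector_image()].
#' @param side_mm Nominal physical side length of the region, mm.
#' @param placement `"center"` (default) or `"chest_wall"`.
#' @param chest_wall_offset_mm Distance from the chest-wall border to the
#'   region's inner edge when `placement = "chest_wall"`, mm.
#' @return An `analysis_region`: list with `pixels`, 0-based `origin_row`,
#'   `origin_col`, `side_mm`, and the parent spacings `dx`, `dy`.
#' @export
extract_analysis_region <- function(image, side_mm, placement = c("center", "chest_wall"),
                                    chest_wall_offset_mm = 0) {
  stopifnot(inherits(image, "detector_image"))
  placement <- match.arg(placement)
  n_cols <- as.integer(floor(side_mm / image$dx))
  n_rows <- as.integer(floor(side_mm / image$dy))
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  if (n_rows > nr || n_cols > nc)
    stop(sprintf(
      "analysis region of %g mm needs %d x %d pixels but image is only %d x %d",
      side_mm, n_rows, n_cols, nr, nc))
  if (placement == "center") {
    r0 <- (nr - n_rows) %/% 2L
    c0 <- (nc - n_cols) %/% 2L
  } else {
    side <- image$chest_wall_side
    off_rows <- as.integer(round(chest_wall_offset_mm / image$dy))
    off_cols <- as.integer(round(chest_wall_offset_mm / image$dx))
    r0 <- (nr - n_rows) %/% 2L
    c0 <- (nc - n_cols) %/% 2L
    if (side == "top") r0 <- off_rows
    if (side == "bottom") r0 <- nr - n_rows - off_rows
    if (side == "left") c0 <- off_cols
    if (side == "right") c0 <- nc - n_cols - off_cols
    if (r0 < 0L || c0 < 0L || r0 + n_rows > nr || c0 + n_cols > nc)
      stop("chest-wall placement pushes the analysis region outside the image")
  }
  structure(
    list(pixels = image$pixels[(r0 + 1L):(r0 + n_rows),
                               (c0 + 1L):(c0 + n_cols), drop = FALSE],
         origin_row = r0, origin_col = c0, side_mm = side_mm,
         dx = image$dx, dy = image$dy),
    class = "analysis_region")
}
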