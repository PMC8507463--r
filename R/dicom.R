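# Minimal DICOM Part-10 codec: explicit VR little endian
# (transfer syntax 1.2.840.10008.1.2.1), single-frame monochrome,
# 16-bit unsigned pixels. This covers exactly the files the fixture
# generator emits; any other transfer syntax is rejected with a clear
# error rather than misread.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"
IMPLEMENTATION_UID <- "1.2.826.0.1.3680043.10.1462.1"
UID_ROOT <- "1.2.826.0.1.3680043.10.1462"

# VRs whose length field is 4 bytes after a 2-byte reserved gap
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16le <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L))
.u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}
.read_u16 <- function(raw, pos) as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
.read_u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

.dcm_pad <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

# One data element, explicit VR little endian
.dcm_element <- function(group, elem, vr, value_raw) {
  tag <- c(.u16le(group), .u16le(elem))
  if (vr %in% .long_vrs) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)), .u32le(length(value_raw)), value_raw)
  } else {
    c(tag, charToRaw(vr), .u16le(length(value_raw)), value_raw)
  }
}

.dcm_str <- function(group, elem, vr, value) {
  pad <- if (vr == "UI") as.raw(0x00) else as.raw(0x20)
  .dcm_element(group, elem, vr, .dcm_pad(charToRaw(as.character(value)), pad))
}

.dcm_us <- function(group, elem, value) .dcm_element(group, elem, "US", .u16le(as.integer(value)))

.fmt_ds <- function(x) paste(vapply(x, function(v) sprintf("%.10g", v), ""), collapse = "\\")

#' Write a single-frame monochrome DICOM file
#'
#' Writes a DICOM Part-10 file (explicit VR little endian, 16-bit
#' unsigned MONOCHROME2) with the metadata the study engine consumes:
#' `Rows`/`Columns`, `PixelSpacing`, `RescaleSlope`/`RescaleIntercept`,
#' `WindowCenter`/`WindowWidth`, `SeriesNumber` and `InstanceNumber`.
#'
#' @param path output file path.
#' @param pixels integer matrix (rows x cols) of stored pixel values in
#'   `[0, 65535]`; values outside are clamped.
#' @param meta named list; recognised fields: `pixel_spacing_mm`
#'   (length-2 numeric, row then column, mm), `rescale_slope`,
#'   `rescale_intercept`, `window` (list with `center`, `width`),
#'   `series_number`, `instance_number`, `sop_instance_uid`,
#'   `series_instance_uid`, `study_instance_uid`, `patient_id`.
#'   Omitted fields are simply not written (no PixelSpacing tag means a
#'   unitless image downstream).
#' @return `path`, invisibly.
#' @export
write_dicom <- function(path, pixels, meta = list()) {
  stopifnot(is.matrix(pixels))
  rows <- nrow(pixels)
  cols <- ncol(pixels)
  v <- as.integer(round(pmin(pmax(as.vector(t(pixels)), 0), 65535)))
  # two's complement so writeBin(size = 2) accepts the full unsigned range
  v <- ifelse(v > 32767L, v - 65536L, v)
  con <- rawConnection(raw(0), "wb")
  writeBin(v, con, size = 2L, endian = "little")
  pix_raw <- rawConnectionValue(con)
  close(con)

  g <- function(x, default) if (is.null(x)) default else x
  sop_uid <- g(meta$sop_instance_uid, paste0(UID_ROOT, ".9.9.9"))

  ds <- c(
    .dcm_str(0x0008, 0x0016, "UI", SOP_SECONDARY_CAPTURE),
    .dcm_str(0x0008, 0x0018, "UI", sop_uid),
    .dcm_str(0x0008, 0x0060, "CS", "OT"),
    .dcm_str(0x0010, 0x0010, "PN", g(meta$patient_id, "SYNTHETIC")),
    .dcm_str(0x0010, 0x0020, "LO", g(meta$patient_id, "SYNTHETIC")),
    .dcm_str(0x0020, 0x000D, "UI", g(meta$study_instance_uid, paste0(UID_ROOT, ".1"))),
    .dcm_str(0x0020, 0x000E, "UI", g(meta$series_instance_uid, paste0(UID_ROOT, ".2"))),
    .dcm_str(0x0020, 0x0011, "IS", g(meta$series_number, 1L)),
    .dcm_str(0x0020, 0x0013, "IS", g(meta$instance_number, 1L)),
    .dcm_us(0x0028, 0x0002, 1L),
    .dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcm_us(0x0028, 0x0010, rows),
    .dcm_us(0x0028, 0x0011, cols)
  )
  if (!is.null(meta$pixel_spacing_mm)) {
    ds <- c(ds, .dcm_str(0x0028, 0x0030, "DS", .fmt_ds(meta$pixel_spacing_mm)))
  }
  ds <- c(
    ds,
    .dcm_us(0x0028, 0x0100, 16L),
    .dcm_us(0x0028, 0x0101, 16L),
    .dcm_us(0x0028, 0x0102, 15L),
    .dcm_us(0x0028, 0x0103, 0L)
  )
  if (!is.null(meta$window)) {
    ds <- c(
      ds,
      .dcm_str(0x0028, 0x1050, "DS", .fmt_ds(meta$window$center)),
      .dcm_str(0x0028, 0x1051, "DS", .fmt_ds(meta$window$width))
    )
  }
  if (!is.null(meta$rescale_intercept) || !is.null(meta$rescale_slope)) {
    ds <- c(
      ds,
      .dcm_str(0x0028, 0x1052, "DS", .fmt_ds(g(meta$rescale_intercept, 0))),
      .dcm_str(0x0028, 0x1053, "DS", .fmt_ds(g(meta$rescale_slope, 1)))
    )
  }
  ds <- c(ds, .dcm_element(0x7FE0, 0x0010, "OW", pix_raw))

  file_meta <- c(
    .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    .dcm_str(0x0002, 0x0002, "UI", SOP_SECONDARY_CAPTURE),
    .dcm_str(0x0002, 0x0003, "UI", sop_uid),
    .dcm_str(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
    .dcm_str(0x0002, 0x0012, "UI", IMPLEMENTATION_UID)
  )
  out <- c(
    raw(128), charToRaw("DICM"),
    .dcm_element(0x0002, 0x0000, "UL", .u32le(length(file_meta))),
    file_meta,
    ds
  )
  writeBin(out, path)
  invisible(path)
}

.dcm_tag_key <- function(group, elem) sprintf("%04X,%04X", group, elem)

#' Read a DICOM file written in explicit VR little endian
#'
#' Parses the Part-10 preamble, the file meta group and the data set,
#' returning the attributes the engine uses plus the pixel matrix.
#' Files in other transfer syntaxes raise a database error; files
#' without the `DICM` magic return `NULL` through [is_dicom_file()]
#' guards upstream.
#'
#' @param path DICOM file path.
#' @param pixels read the pixel data (set `FALSE` for metadata-only scans).
#' @return list with `rows`, `cols`, `pixel_spacing_mm` (or `NULL`),
#'   `rescale_slope`, `rescale_intercept`, `window` (or `NULL`),
#'   `instance_number`, `series_number`, `sop_instance_uid` and
#'   `pixels` (integer matrix, stored values, or `NULL`).
#' @export
read_dicom <- function(path, pixels = TRUE) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM") {
    database_error(sprintf("not a DICOM Part-10 file: %s", path))
  }
  pos <- 133L
  tags <- list()
  pix_raw <- NULL
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- .read_u16(raw, pos)
    elem <- .read_u16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      database_error(sprintf("unsupported encoding (implicit VR?) in %s at byte %d", path, pos))
    }
    if (vr %in% .long_vrs) {
      len <- .read_u32(raw, pos + 8L)
      data_pos <- pos + 12L
    } else {
      len <- .read_u16(raw, pos + 6L)
      data_pos <- pos + 8L
    }
    if (data_pos + len - 1 > n) {
      database_error(sprintf("truncated DICOM element in %s", path))
    }
    val_raw <- if (len > 0) raw[data_pos:(data_pos + len - 1)] else raw(0)
    key <- .dcm_tag_key(group, elem)
    if (group == 0x7FE0 && elem == 0x0010) {
      pix_raw <- val_raw
      pos <- data_pos + len
      break
    }
    tags[[key]] <- list(vr = vr, raw = val_raw)
    pos <- as.integer(data_pos + len)
  }

  str_val <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(t$raw[t$raw != as.raw(0)]))
  }
  us_val <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    .read_u16(t$raw, 1L)
  }
  ds_val <- function(key) {
    s <- str_val(key)
    if (is.null(s) || !nzchar(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }

  ts <- str_val("0002,0010")
  if (!is.null(ts) && ts != TS_EXPLICIT_LE) {
    database_error(sprintf("unsupported transfer syntax %s in %s", ts, path))
  }
  rows <- us_val("0028,0010")
  cols <- us_val("0028,0011")
  if (is.null(rows) || is.null(cols)) {
    database_error(sprintf("missing Rows/Columns in %s", path))
  }

  pix <- NULL
  if (pixels) {
    if (is.null(pix_raw)) database_error(sprintf("no pixel data in %s", path))
    if (length(pix_raw) < 2 * rows * cols) {
      database_error(sprintf("pixel data shorter than Rows*Columns in %s", path))
    }
    v <- readBin(pix_raw, "integer", n = rows * cols, size = 2L,
                 signed = FALSE, endian = "little")
    pix <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  }

  spacing <- ds_val("0028,0030")
  win <- NULL
  wc <- ds_val("0028,1050")
  ww <- ds_val("0028,1051")
  if (!is.null(wc) && !is.null(ww)) win <- list(center = wc[1], width = ww[1])
  slope <- ds_val("0028,1053")
  intercept <- ds_val("0028,1052")
  inst <- str_val("0020,0013")
  sn <- str_val("0020,0011")

  list(
    rows = rows, cols = cols,
    pixel_spacing_mm = spacing,
    rescale_slope = if (is.null(slope)) 1.0 else slope[1],
    rescale_intercept = if (is.null(intercept)) 0.0 else intercept[1],
    window = win,
    instance_number = if (is.null(inst) || !nzchar(inst)) NA_integer_ else as.integer(inst),
    series_number = if (is.null(sn) || !nzchar(sn)) NA_integer_ else as.integer(sn),
    sop_instance_uid = str_val("0008,0018"),
    pixels = pix
  )
}

#' Test whether a file looks like a DICOM Part-10 file
#'
#' Checks for the 128-byte preamble followed by the `DICM` magic bytes.
#'
#' @param path file path.
#' @return `TRUE` or `FALSE`.
#' @export
is_dicom_file <- function(path) {
  if (!file.exists(path) || isTRUE(file.info(path)$isdir)) return(FALSE)
  if (file.size(path) < 132) return(FALSE)
  head <- readBin(path, "raw", n = 132)
  identical(rawToChar(head[129:132]), "DICM")
}
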