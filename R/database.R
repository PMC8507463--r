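# Case database: a folder tree root/<case>/<series>/<instances>. The
# ordering contract is deterministic — lexicographic case folders,
# lexicographic series folders (series slot order), instances by
# InstanceNumber with filename as tie-break — so every scan of the same
# tree yields the same database. Pixel coordinates everywhere are
# 0-based (row, col) with the origin at the top-left pixel center.

#' Scan a DICOM folder tree into a case database
#'
#' Non-DICOM files are skipped with a warning; a case with no readable
#' series, or an empty root, is an error. Metadata is read at scan time;
#' pixel data is read on demand via [read_pixels()].
#'
#' @param root study image folder (`root/<case>/<series>/<files>`).
#' @return a `case_database`: `root` plus an ordered list of `case`
#'   objects, each holding ordered `series` with per-instance metadata.
#' @export
scan_image_database <- function(root) {
  if (!dir.exists(root)) database_error(sprintf("image root '%s' does not exist", root))
  case_dirs <- sort(list.dirs(root, recursive = FALSE, full.names = TRUE))
  if (!length(case_dirs)) {
    database_error(sprintf("image root '%s' contains no case folders", root))
  }
  cases <- lapply(case_dirs, function(cdir) {
    series_dirs <- sort(list.dirs(cdir, recursive = FALSE, full.names = TRUE))
    series <- list()
    for (sdir in series_dirs) {
      files <- sort(list.files(sdir, full.names = TRUE))
      keep <- files[vapply(files, is_dicom_file, TRUE)]
      skipped <- setdiff(files, keep)
      for (f in skipped) {
        warning(sprintf("skipping non-DICOM file '%s'", f), call. = FALSE)
      }
      if (!length(keep)) next
      metas <- lapply(keep, read_dicom, pixels = FALSE)
      inst_no <- vapply(metas, function(m) {
        if (is.na(m$instance_number)) .Machine$integer.max else m$instance_number
      }, 0L)
      ord <- order(inst_no, basename(keep))
      instances <- lapply(ord, function(i) {
        list(path = keep[i], meta = metas[[i]])
      })
      series[[length(series) + 1L]] <- structure(list(
        series_id = basename(sdir),
        instances = instances,
        is_stack = length(instances) > 1L
      ), class = "image_series")
    }
    if (!length(series)) {
      database_error(sprintf("case '%s' has no readable series", basename(cdir)))
    }
    if (length(series) > 16L) {
      database_error(sprintf("case '%s' has %d series; at most 16 are supported",
                             basename(cdir), length(series)))
    }
    structure(list(case_id = basename(cdir), series = series), class = "case")
  })
  slots <- vapply(cases, function(cs) length(cs$series), 0L)
  structure(list(root = root, cases = cases,
                 uniform_slots = length(unique(slots)) == 1L),
            class = "case_database")
}

#' Case ids of a database, in scan order
#' @param db a `case_database`.
#' @return character vector.
#' @export
case_ids <- function(db) vapply(db$cases, function(cs) cs$case_id, "")

#' Fetch one case by id
#' @param db a `case_database`.
#' @param case_id case id.
#' @return a `case`.
#' @export
db_case <- function(db, case_id) {
  for (cs in db$cases) if (cs$case_id == case_id) return(cs)
  database_error(sprintf("no case '%s' in database", case_id))
}

#' Series-slot count shared by the database's cases
#'
#' Validated, not assumed: if cases disagree, the maximum is returned
#' and [validate_config()] flags it.
#'
#' @param db a `case_database`.
#' @return integer.
#' @export
db_series_slots <- function(db) {
  max(vapply(db$cases, function(cs) length(cs$series), 0L))
}

#' Extract display/measurement metadata for one instance
#'
#' Missing `RescaleSlope`/`RescaleIntercept` default to 1/0. A missing
#' `PixelSpacing` flags the image `unitless`; mm-returning measurements
#' refuse unitless images rather than silently reporting pixels.
#'
#' @param instance an instance from a `case_database` (list with
#'   `path` and `meta`), or a DICOM file path.
#' @return an `image_meta` list: `rows`, `cols`, `pixel_spacing_mm`
#'   (`c(row_mm, col_mm)` or `NULL`), `unitless`, `rescale_slope`,
#'   `rescale_intercept`, `default_window`.
#' @export
read_image_meta <- function(instance) {
  m <- if (is.character(instance)) read_dicom(instance, pixels = FALSE)
       else instance$meta
  spacing <- m$pixel_spacing_mm
  unitless <- is.null(spacing) || length(spacing) < 2L || any(spacing <= 0)
  structure(list(
    rows = m$rows, cols = m$cols,
    pixel_spacing_mm = if (unitless) NULL else spacing[1:2],
    unitless = unitless,
    rescale_slope = m$rescale_slope,
    rescale_intercept = m$rescale_intercept,
    default_window = m$window
  ), class = "image_meta")
}

#' Read an instance's stored pixel matrix
#' @param instance instance from a `case_database`, or a file path.
#' @return integer matrix (rows x cols) of stored values.
#' @export
read_pixels <- function(instance) {
  path <- if (is.character(instance)) instance else instance$path
  read_dicom(path, pixels = TRUE)$pixels
}

#' @export
print.case_database <- function(x, ...) {
  cat(sprintf("Case database at '%s': %d case(s), %d series slot(s)\n",
              x$root, length(x$cases), db_series_slots(x)))
  invisible(x)
}
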