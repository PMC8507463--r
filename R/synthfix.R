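# Synthetic DICOM study generator: small, fully deterministic image
# databases (case/series/instance folder trees) with known ground truth,
# so every module — and end-to-end scripted sessions — runs with zero
# external data. Pixel patterns are analytic (constant, gradient, disk)
# or seeded noise; UIDs and pixel data are pure functions of the spec,
# so the same spec reproduces byte-identical files.

#' Describe a synthetic study
#'
#' @param n_cases number of cases.
#' @param series_per_case series slots per case (at most 16).
#' @param stack_depth instances per series (1 = single image).
#' @param rows,cols image dimensions in pixels.
#' @param pattern pixel pattern: `list(type = "constant", value = v)`,
#'   `list(type = "gradient")`,
#'   `list(type = "disk", center = c(r, c), radius = r_px, fg = , bg = )`
#'   or `list(type = "noise", mean = , sd = )`.
#' @param pixel_spacing_mm `c(row_mm, col_mm)`, or `NULL` for unitless
#'   images.
#' @param rescale `c(slope, intercept)`.
#' @param window optional `list(center = , width = )` default window.
#' @param seed integer; drives noise and UID generation.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(n_cases, series_per_case = 1L, stack_depth = 1L,
                         rows = 32L, cols = 32L,
                         pattern = list(type = "constant", value = 1000),
                         pixel_spacing_mm = c(1, 1),
                         rescale = c(1, 0), window = NULL, seed = 0L) {
  if (n_cases < 1L || series_per_case < 1L || stack_depth < 1L ||
      rows < 1L || cols < 1L) {
    spec_error("all fixture dimensions must be positive")
  }
  if (series_per_case > 16L) {
    spec_error("at most 16 series per case are supported")
  }
  if (!pattern$type %in% c("constant", "gradient", "disk", "noise")) {
    spec_error(sprintf("unknown pixel pattern '%s'", pattern$type))
  }
  structure(list(
    n_cases = as.integer(n_cases),
    series_per_case = as.integer(series_per_case),
    stack_depth = as.integer(stack_depth),
    rows = as.integer(rows), cols = as.integer(cols),
    pattern = pattern, pixel_spacing_mm = pixel_spacing_mm,
    rescale = rescale, window = window, seed = as.integer(seed)
  ), class = "fixture_spec")
}

.pattern_pixels <- function(pattern, rows, cols, seed_key) {
  switch(pattern$type,
    constant = matrix(pattern$value, rows, cols),
    gradient = {
      denom <- max(1L, rows + cols - 2L)
      outer(0:(rows - 1L), 0:(cols - 1L),
            function(r, c) round((r + c) / denom * 4095))
    },
    disk = {
      d2 <- outer((0:(rows - 1L) - pattern$center[1])^2,
                  (0:(cols - 1L) - pattern$center[2])^2, `+`)
      ifelse(d2 < pattern$radius^2, pattern$fg, pattern$bg)
    },
    noise = with_seed(seed_key, {
      m <- if (is.null(pattern$mean)) 1000 else pattern$mean
      matrix(pmin(65535, pmax(0, round(stats::rnorm(rows * cols, m, pattern$sd)))),
             rows, cols)
    })
  )
}

.synth_uid <- function(seed, ...) {
  paste0(UID_ROOT, ".", fnv1a32(paste(c(seed, ...), collapse = "/")),
         ".", paste(c(...), collapse = "."))
}

.write_series <- function(dir, spec, pattern, case_i, series_j) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_len(spec$stack_depth)) {
    pix <- .pattern_pixels(pattern, spec$rows, spec$cols,
                           derive_seed(spec$seed, "pix", case_i, series_j, k))
    meta <- list(
      pixel_spacing_mm = spec$pixel_spacing_mm,
      rescale_slope = spec$rescale[1], rescale_intercept = spec$rescale[2],
      window = spec$window,
      series_number = series_j, instance_number = k,
      study_instance_uid = .synth_uid(spec$seed, case_i),
      series_instance_uid = .synth_uid(spec$seed, case_i, series_j),
      sop_instance_uid = .synth_uid(spec$seed, case_i, series_j, k),
      patient_id = sprintf("SYNTH%03d", case_i)
    )
    if (is.null(spec$rescale)) meta$rescale_slope <- meta$rescale_intercept <- NULL
    write_dicom(file.path(dir, sprintf("i%03d.dcm", k)), pix, meta)
  }
}

#' Generate a synthetic DICOM study folder
#'
#' Lays out `out_dir/caseNNN/sNN/iNNN.dcm` and writes a `manifest.txt`
#' (two-delimiter dialect) recording the ground truth of every series.
#' Deterministic: the same spec produces byte-identical pixel data.
#'
#' @param spec a `fixture_spec`.
#' @param out_dir output folder (created if needed).
#' @return invisibly, a list with `root` (the image folder) and
#'   `manifest` (tibble: case_id, series_id, pattern).
#' @export
make_study <- function(spec, out_dir) {
  if (!inherits(spec, "fixture_spec")) spec_error("spec must be a fixture_spec")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  recs <- list()
  for (i in seq_len(spec$n_cases)) {
    cid <- sprintf("case%03d", i)
    for (j in seq_len(spec$series_per_case)) {
      sid <- sprintf("s%02d", j)
      .write_series(file.path(out_dir, cid, sid), spec, spec$pattern, i, j)
      rows[[length(rows) + 1L]] <- list(case_id = cid, series_id = sid,
                                        pattern = spec$pattern$type)
      recs <- c(recs, list(log_record(
        "event", "synth", cid, j - 1L,
        payload = c("series", log_subfields(sid, spec$pattern$type))
      )))
    }
  }
  cat(write_log(recs), file = file.path(out_dir, "manifest.txt"), sep = "")
  invisible(list(
    root = out_dir,
    manifest = tibble::tibble(
      case_id = vapply(rows, function(r) r$case_id, ""),
      series_id = vapply(rows, function(r) r$series_id, ""),
      pattern = vapply(rows, function(r) r$pattern, "")
    )
  ))
}

#' Generate a complete alternative-forced-choice study
#'
#' Builds a ready-to-run study folder: a property file with randomized
#' series placement, an image database in which exactly one series per
#' case carries the signal (a disk) and the rest are signal-absent, and
#' a truth table mapping each case to its signal slot. With randomized
#' placement the signal lands on a different canvas per observer, so no
#' image pre-arrangement is needed; a scripted observer that reads the
#' truth scores proportion correct 1.0 (see [afc_script()]).
#'
#' @param n_cases number of AFC cases.
#' @param monitor_layouts layout kinds, one per monitor (e.g. `"2x2"`
#'   for 4-AFC on one monitor). The total canvas count M is the number
#'   of alternatives and of series per case; M must be at least 2.
#' @param signal disk parameters: `list(center, radius, fg, bg)`.
#' @param out_dir study folder to create.
#' @param seed master seed (drives truth slots, placements, noise).
#' @param rows,cols image dimensions.
#' @return list: `study_dir`, `cfg` (parsed `study_config`), `truth`
#'   (tibble: `case_id`, `signal_slot`), `n_alternatives`.
#' @export
make_afc_study <- function(n_cases, monitor_layouts = "2x2",
                           signal = list(center = NULL, radius = 4,
                                         fg = 3000, bg = 1000),
                           out_dir, seed = 1L, rows = 16L, cols = 16L) {
  grid <- build_canvas_grid(monitor_layouts)
  m <- nrow(grid$canvases)
  if (m < 2L) {
    spec_error("an AFC study needs at least 2 canvases (alternatives)")
  }
  if (is.null(signal$center)) signal$center <- c((rows - 1) / 2, (cols - 1) / 2)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img_root <- file.path(out_dir, "images")

  base_spec <- fixture_spec(
    n_cases = n_cases, series_per_case = m, stack_depth = 1L,
    rows = rows, cols = cols, pixel_spacing_mm = c(1, 1), seed = seed
  )
  signal_pat <- list(type = "disk", center = signal$center,
                     radius = signal$radius, fg = signal$fg, bg = signal$bg)
  absent_pat <- list(type = "constant", value = signal$bg)

  truth_slot <- integer(n_cases)
  recs <- list()
  for (i in seq_len(n_cases)) {
    cid <- sprintf("case%03d", i)
    slot <- with_seed(derive_seed(seed, "afc_truth", cid), sample.int(m, 1L)) - 1L
    truth_slot[i] <- slot
    for (j in seq_len(m)) {
      pat <- if (j - 1L == slot) signal_pat else absent_pat
      .write_series(file.path(img_root, cid, sprintf("s%02d", j)),
                    base_spec, pat, i, j)
    }
    recs <- c(recs, list(log_record(
      "event", "synth", cid, slot, payload = c("signal_slot", log_subfields(slot))
    )))
  }
  cat(write_log(recs), file = file.path(out_dir, "truth.txt"), sep = "")

  props <- paste0(
    "study_name = afc_synthetic\n",
    "image_root = images\n",
    "n_monitors = ", length(monitor_layouts), "\n",
    "monitor_layouts = ", paste(monitor_layouts, collapse = ", "), "\n",
    "series_placement = randomized\n",
    "master_seed = ", seed, "\n",
    "question.signal_canvas.prompt = Global index of the canvas containing the signal\n",
    "question.signal_canvas.kind = choice\n",
    "question.signal_canvas.allowed = ", paste(0:(m - 1L), collapse = ","), "\n",
    "question.signal_canvas.required = true\n"
  )
  writeLines(props, file.path(out_dir, "study.properties"))

  list(
    study_dir = out_dir,
    cfg = parse_study_properties(file.path(out_dir, "study.properties")),
    truth = tibble::tibble(case_id = sprintf("case%03d", seq_len(n_cases)),
                           signal_slot = truth_slot),
    n_alternatives = m
  )
}

#' Read the truth table of a generated AFC study
#' @param study_dir folder created by [make_afc_study()].
#' @return tibble: `case_id`, `signal_slot`.
#' @export
read_afc_truth <- function(study_dir) {
  lf <- parse_log(readLines(file.path(study_dir, "truth.txt"), warn = FALSE))
  recs <- Filter(function(r) log_unescape(r$payload[1]) == "signal_slot",
                 lf$records)
  tibble::tibble(
    case_id = vapply(recs, function(r) r$case_id, ""),
    signal_slot = vapply(recs, function(r) r$series_slot, 0L)
  )
}

#' Global canvas index showing the signal for one observer and case
#'
#' Decodes the AFC truth through the observer's randomized placement:
#' the slot that carries the signal, mapped to the canvas it landed on.
#'
#' @param cfg the AFC study's `study_config`.
#' @param truth truth tibble from [make_afc_study()]/[read_afc_truth()].
#' @param observer_id observer identifier.
#' @param case_id case identifier.
#' @return 0-based global canvas index.
#' @export
afc_signal_canvas <- function(cfg, truth, observer_id, case_id) {
  slot <- truth$signal_slot[truth$case_id == case_id]
  if (!length(slot)) spec_error(sprintf("case '%s' not in truth table", case_id))
  # AFC studies carry one series per canvas
  pl <- assign_series_to_canvases(cfg, total_canvases(cfg), observer_id, case_id)
  grid <- build_canvas_grid(cfg)
  hit <- pl[pl$series_slot == slot, ]
  canvas_global_idx(grid, hit$monitor_idx, hit$canvas_idx)
}

#' Write a scripted observer for an AFC study
#'
#' `"ideal"` answers the true signal canvas for every case (proportion
#' correct 1 by construction); `"random"` guesses uniformly over the
#' alternatives.
#'
#' @param cfg,truth study config and truth table.
#' @param db the study's `case_database`.
#' @param observer_id observer identifier.
#' @param strategy `"ideal"` or `"random"`.
#' @param guess_seed seed for the random guesser.
#' @return character vector of response-script lines (see
#'   [run_script()]).
#' @export
afc_script <- function(cfg, truth, db, observer_id,
                       strategy = c("ideal", "random"), guess_seed = 0L) {
  strategy <- match.arg(strategy)
  ord <- case_order(cfg, db, observer_id)
  m <- total_canvases(cfg)
  lines <- character(0)
  for (cid in ord) {
    ans <- if (strategy == "ideal") {
      afc_signal_canvas(cfg, truth, observer_id, cid)
    } else {
      with_seed(derive_seed(guess_seed, "guess", observer_id, cid),
                sample.int(m, 1L)) - 1L
    }
    lines <- c(lines,
               paste("answer", "signal_canvas", ans, sep = "\t"),
               "submit")
  }
  lines
}

#' Score an AFC observer's log against the truth
#'
#' @param study_dir AFC study folder.
#' @param observer_id observer whose log to score.
#' @param cfg,truth study config and truth table.
#' @return proportion of cases where the logged answer equals the true
#'   signal canvas.
#' @export
afc_score <- function(study_dir, observer_id, cfg, truth) {
  lf <- parse_log(readLines(.log_path(study_dir, observer_id), warn = FALSE))
  ans <- export_table(lf, "case_answer")
  ans <- ans[ans$question_id == "signal_canvas", ]
  if (!nrow(ans)) spec_error("log contains no signal_canvas answers")
  correct <- vapply(seq_len(nrow(ans)), function(i) {
    as.integer(ans$value[i]) ==
      afc_signal_canvas(cfg, truth, observer_id, ans$case_id[i])
  }, TRUE)
  mean(correct)
}
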