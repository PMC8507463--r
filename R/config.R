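# Study property file: the single plain-text file that fully determines
# a study design and observer privileges. Dialect: `key = value` lines,
# `#` comments, comma-separated lists, question blocks as
# `question.<id>.<field> = ...`. Unknown keys warn and are kept out of
# the config; missing mandatory keys fail fast with the line number.

LAYOUT_KINDS <- c("1x1", "1x2", "2x1", "2x2")

#' Canvas count of a monitor layout
#'
#' A monitor shows 1, 2 or 4 canvases: `1x1` full-screen, `1x2`/`2x1`
#' two canvases side-by-side or stacked, `2x2` four canvases.
#'
#' @param layout character vector of layout kinds.
#' @return integer vector of canvas counts.
#' @export
layout_canvases <- function(layout) {
  bad <- setdiff(layout, LAYOUT_KINDS)
  if (length(bad)) {
    config_error(sprintf("unknown canvas layout '%s' (valid: %s)",
                         bad[1], paste(LAYOUT_KINDS, collapse = ", ")))
  }
  c("1x1" = 1L, "1x2" = 2L, "2x1" = 2L, "2x2" = 4L)[layout]
}

.parse_bool <- function(value, key, line) {
  v <- tolower(trimws(value))
  if (v %in% c("true", "yes", "1", "on")) return(TRUE)
  if (v %in% c("false", "no", "0", "off")) return(FALSE)
  config_error(sprintf("line %d: key '%s' has non-boolean value '%s'",
                       line, key, value))
}

.parse_int <- function(value, key, line) {
  v <- suppressWarnings(as.integer(trimws(value)))
  if (is.na(v)) {
    config_error(sprintf("line %d: key '%s' has non-integer value '%s'",
                         line, key, value))
  }
  v
}

.split_list <- function(value) {
  if (!nzchar(trimws(value))) return(character(0))
  trimws(strsplit(value, ",", fixed = TRUE)[[1]])
}

FEATURE_FLAGS <- c("allow_window_change", "allow_zoom_pan", "allow_cine",
                   "allow_temporary_layout", "allow_multiselect")

#' Parse a study property file
#'
#' Reads the `key = value` study description and returns a validated
#' `study_config`. Mandatory keys: `study_name`, `image_root`,
#' `n_monitors`, `monitor_layouts`. Defaults for the rest: fixed series
#' placement filling canvases in monitor-major, row-major order; all
#' feature flags on; notes and measurements enabled; `master_seed = 0`
#' (mandatory when `series_placement = randomized`, since reproducible
#' assignments are the point of seeding).
#'
#' Question blocks declare observer tasks:
#' \preformatted{
#' question.conf.prompt  = Confidence that a lesion is present
#' question.conf.kind    = scale        # scale | choice | free_text
#' question.conf.allowed = 1,2,3,4
#' question.conf.required = true
#' question.conf.linked_to_mark = false
#' }
#' Questions with `linked_to_mark = true` attach to localization marks.
#'
#' @param text property-file content: a single string, a character
#'   vector of lines, or a file path.
#' @return a `study_config` list.
#' @export
parse_study_properties <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  } else if (length(text) == 1L) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }

  kv <- list()     # key -> list(value, line)
  qfields <- list()  # question id -> named list of fields
  qorder <- character(0)
  for (i in seq_along(text)) {
    line <- sub("#.*$", "", text[i])
    if (!nzchar(trimws(line))) next
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) {
      config_error(sprintf("line %d: expected 'key = value', got '%s'",
                           i, trimws(text[i])))
    }
    key <- trimws(substr(line, 1, eq - 1))
    value <- trimws(substr(line, eq + 1, nchar(line)))
    if (!nzchar(key)) {
      config_error(sprintf("line %d: empty key", i))
    }
    if (grepl("^question\\.", key)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (length(parts) < 3L) {
        config_error(sprintf("line %d: question key '%s' must be question.<id>.<field>",
                             i, key))
      }
      qid <- paste(parts[2:(length(parts) - 1L)], collapse = ".")
      fld <- parts[length(parts)]
      if (!qid %in% qorder) qorder <- c(qorder, qid)
      qfields[[qid]][[fld]] <- list(value = value, line = i)
    } else {
      kv[[key]] <- list(value = value, line = i)
    }
  }

  need <- function(key) {
    if (is.null(kv[[key]])) {
      config_error(sprintf("missing mandatory key '%s'", key))
    }
    kv[[key]]
  }
  opt <- function(key, default) {
    if (is.null(kv[[key]])) list(value = default, line = NA_integer_, is_default = TRUE)
    else kv[[key]]
  }

  known <- c("study_name", "image_root", "n_monitors", "monitor_layouts",
             "series_placement", "fixed_placement_map", "master_seed",
             "notes_enabled", "measurements_enabled", FEATURE_FLAGS)
  unknown <- setdiff(names(kv), known)
  for (k in unknown) {
    warning(sprintf("ignoring unknown property key '%s' (line %d)",
                    k, kv[[k]]$line), call. = FALSE)
  }

  study_name <- need("study_name")$value
  image_root <- need("image_root")$value
  nm <- need("n_monitors")
  n_monitors <- .parse_int(nm$value, "n_monitors", nm$line)
  if (n_monitors < 1L || n_monitors > 4L) {
    config_error(sprintf("line %d: n_monitors = %d outside the supported range 1..4",
                         nm$line, n_monitors))
  }
  ml <- need("monitor_layouts")
  layouts <- .split_list(ml$value)
  if (length(layouts) != n_monitors) {
    config_error(sprintf(
      "line %d: monitor_layouts lists %d layouts for n_monitors = %d",
      ml$line, length(layouts), n_monitors))
  }
  layout_canvases(layouts)  # validates the kinds

  sp <- opt("series_placement", "fixed")
  placement <- tolower(trimws(sp$value))
  if (!placement %in% c("fixed", "randomized")) {
    config_error(sprintf("series_placement must be 'fixed' or 'randomized', got '%s'",
                         sp$value))
  }
  if (placement == "randomized" && is.null(kv[["master_seed"]])) {
    config_error("master_seed is mandatory when series_placement = randomized")
  }
  ms <- opt("master_seed", "0")
  master_seed <- .parse_int(ms$value, "master_seed", ms$line)

  fixed_map <- NULL
  if (!is.null(kv[["fixed_placement_map"]])) {
    fm <- kv[["fixed_placement_map"]]
    entries <- .split_list(fm$value)
    parsed <- lapply(entries, function(e) {
      m <- regmatches(e, regexec("^([0-9]+):([0-9]+)\\.([0-9]+)$", e))[[1]]
      if (length(m) != 4L) {
        config_error(sprintf(
          "line %d: fixed_placement_map entry '%s' must be slot:monitor.canvas (0-based)",
          fm$line, e))
      }
      as.integer(m[2:4])
    })
    fixed_map <- tibble::tibble(
      series_slot = vapply(parsed, `[`, 0L, 1L),
      monitor_idx = vapply(parsed, `[`, 0L, 2L),
      canvas_idx = vapply(parsed, `[`, 0L, 3L)
    )
    if (anyDuplicated(fixed_map$series_slot)) {
      config_error(sprintf("line %d: fixed_placement_map repeats a series slot", fm$line))
    }
    if (anyDuplicated(paste(fixed_map$monitor_idx, fixed_map$canvas_idx))) {
      config_error(sprintf("line %d: fixed_placement_map maps two slots to one canvas",
                           fm$line))
    }
  }

  features <- lapply(FEATURE_FLAGS, function(f) {
    e <- opt(f, "true")
    .parse_bool(e$value, f, if (is.na(e$line)) 0L else e$line)
  })
  names(features) <- FEATURE_FLAGS

  questions <- list()
  for (qid in qorder) {
    f <- qfields[[qid]]
    getf <- function(name, default = NULL) {
      if (is.null(f[[name]])) default else f[[name]]$value
    }
    kind <- tolower(getf("kind", "free_text"))
    if (!kind %in% c("scale", "choice", "free_text")) {
      config_error(sprintf("question '%s': unknown kind '%s'", qid, kind))
    }
    allowed <- .split_list(getf("allowed", ""))
    if (kind %in% c("scale", "choice") && !length(allowed)) {
      config_error(sprintf(
        "question '%s': kind '%s' needs a non-empty 'allowed' list", qid, kind))
    }
    req_line <- if (!is.null(f[["required"]])) f[["required"]]$line else 0L
    lnk_line <- if (!is.null(f[["linked_to_mark"]])) f[["linked_to_mark"]]$line else 0L
    questions[[qid]] <- list(
      id = qid,
      prompt = getf("prompt", qid),
      kind = kind,
      allowed = allowed,
      required = .parse_bool(getf("required", "false"), "required", req_line),
      linked_to_mark = .parse_bool(getf("linked_to_mark", "false"),
                                   "linked_to_mark", lnk_line)
    )
  }

  ne <- opt("notes_enabled", "true")
  me <- opt("measurements_enabled", "true")

  cfg <- structure(list(
    study_name = study_name,
    image_root = image_root,
    n_monitors = n_monitors,
    monitor_layouts = unname(layouts),
    series_placement = placement,
    fixed_placement_map = fixed_map,
    master_seed = master_seed,
    features = features,
    questions = Filter(function(q) !q$linked_to_mark, questions),
    localization_questions = Filter(function(q) q$linked_to_mark, questions),
    notes_enabled = .parse_bool(ne$value, "notes_enabled",
                                if (is.na(ne$line)) 0L else ne$line),
    measurements_enabled = .parse_bool(me$value, "measurements_enabled",
                                       if (is.na(me$line)) 0L else me$line)
  ), class = "study_config")

  if (!is.null(fixed_map)) .check_map_canvases(cfg, fixed_map)
  cfg
}

.check_map_canvases <- function(cfg, map) {
  cap <- layout_canvases(cfg$monitor_layouts)
  for (k in seq_len(nrow(map))) {
    m <- map$monitor_idx[k]
    if (m < 0L || m >= cfg$n_monitors) {
      config_error(sprintf("fixed_placement_map references monitor %d (study has %d)",
                           m, cfg$n_monitors))
    }
    if (map$canvas_idx[k] < 0L || map$canvas_idx[k] >= cap[m + 1L]) {
      config_error(sprintf(
        "fixed_placement_map references canvas %d on monitor %d (layout %s has %d)",
        map$canvas_idx[k], m, cfg$monitor_layouts[m + 1L], cap[m + 1L]))
    }
  }
  invisible(TRUE)
}

#' Serialize a study config back to property-file text
#'
#' Canonical write-back: `parse_study_properties(serialize_study_properties(cfg))`
#' reproduces `cfg`.
#'
#' @param cfg a `study_config`.
#' @return single string of property-file text.
#' @export
serialize_study_properties <- function(cfg) {
  lines <- c(
    sprintf("study_name = %s", cfg$study_name),
    sprintf("image_root = %s", cfg$image_root),
    sprintf("n_monitors = %d", cfg$n_monitors),
    sprintf("monitor_layouts = %s", paste(cfg$monitor_layouts, collapse = ", ")),
    sprintf("series_placement = %s", cfg$series_placement),
    sprintf("master_seed = %d", cfg$master_seed),
    sprintf("notes_enabled = %s", tolower(cfg$notes_enabled)),
    sprintf("measurements_enabled = %s", tolower(cfg$measurements_enabled)),
    vapply(FEATURE_FLAGS, function(f) {
      sprintf("%s = %s", f, tolower(cfg$features[[f]]))
    }, "")
  )
  if (!is.null(cfg$fixed_placement_map)) {
    m <- cfg$fixed_placement_map
    lines <- c(lines, sprintf("fixed_placement_map = %s", paste(
      sprintf("%d:%d.%d", m$series_slot, m$monitor_idx, m$canvas_idx),
      collapse = ", ")))
  }
  for (q in c(cfg$questions, cfg$localization_questions)) {
    lines <- c(lines,
      sprintf("question.%s.prompt = %s", q$id, q$prompt),
      sprintf("question.%s.kind = %s", q$id, q$kind),
      if (length(q$allowed)) {
        sprintf("question.%s.allowed = %s", q$id, paste(q$allowed, collapse = ","))
      },
      sprintf("question.%s.required = %s", q$id, tolower(q$required)),
      sprintf("question.%s.linked_to_mark = %s", q$id, tolower(q$linked_to_mark))
    )
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Stable digest of a study config
#'
#' Ties logs and assignments to the study design that produced them, so
#' a resumed session on a silently edited study is detectable.
#'
#' @param cfg a `study_config`.
#' @return 8-hex-digit string.
#' @export
config_digest <- function(cfg) {
  h <- fnv1a32(serialize_study_properties(cfg))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Total canvas count of a config
#' @param cfg a `study_config`.
#' @return integer, at most 16.
#' @export
total_canvases <- function(cfg) {
  sum(layout_canvases(cfg$monitor_layouts))
}

#' Look up a question definition by id
#' @param cfg a `study_config`.
#' @param qid question id.
#' @return question list or `NULL`.
#' @export
find_question <- function(cfg, qid) {
  all_q <- c(cfg$questions, cfg$localization_questions)
  for (q in all_q) if (q$id == qid) return(q)
  NULL
}

#' Validate a study config against a case database
#'
#' Collects every violation instead of stopping at the first, mirroring
#' how a study owner debugs a property file: series count versus canvas
#' capacity, fixed-map coverage, and response design sanity. Informative
#' notes (e.g. canvases that will stay empty) are reported alongside.
#'
#' @param cfg a `study_config`.
#' @param db a `case_database`.
#' @return a `validation_report`: tibble with columns `severity`
#'   (`"error"`/`"note"`), `code`, `message`; attribute `ok` is `TRUE`
#'   iff no errors.
#' @export
validate_config <- function(cfg, db) {
  findings <- list()
  add <- function(severity, code, message) {
    findings[[length(findings) + 1L]] <<- list(severity = severity,
                                               code = code, message = message)
  }
  n_canvas <- total_canvases(cfg)
  n_series <- db_series_slots(db)

  if (n_series > n_canvas) {
    add("error", "capacity", sprintf(
      "cases have %d series but the layout offers only %d canvases",
      n_series, n_canvas))
  } else if (n_series < n_canvas) {
    add("note", "blank_canvases", sprintf(
      "%d of %d canvases will remain empty (black)", n_canvas - n_series, n_canvas))
  }

  if (cfg$series_placement == "fixed" && !is.null(cfg$fixed_placement_map)) {
    covered <- sort(cfg$fixed_placement_map$series_slot)
    want <- 0:(n_series - 1L)
    missing <- setdiff(want, covered)
    if (length(missing)) {
      add("error", "map_coverage", sprintf(
        "fixed_placement_map omits series slot(s) %s",
        paste(missing, collapse = ", ")))
    }
    extra <- setdiff(covered, want)
    if (length(extra)) {
      add("note", "map_surplus", sprintf(
        "fixed_placement_map covers unused slot(s) %s",
        paste(extra, collapse = ", ")))
    }
  }

  if (!length(cfg$questions) && !length(cfg$localization_questions)) {
    add("note", "no_questions",
        "study defines no questions; only notes/measurements can be recorded")
  }
  tbl <- if (length(findings)) {
    tibble::tibble(
      severity = vapply(findings, function(f) f$severity, ""),
      code = vapply(findings, function(f) f$code, ""),
      message = vapply(findings, function(f) f$message, "")
    )
  } else {
    tibble::tibble(severity = character(), code = character(),
                   message = character())
  }
  structure(tbl, ok = !any(tbl$severity == "error"),
            class = c("validation_report", class(tbl)))
}

#' @export
print.validation_report <- function(x, ...) {
  ok <- attr(x, "ok")
  cat(sprintf("Study validation: %s\n", if (ok) "OK" else "FAILED"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %s: %s\n", x$severity[i], x$code[i], x$message[i]))
  }
  invisible(x)
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("Study '%s': %d monitor(s) [%s], %d canvases, placement %s, seed %d\n",
              x$study_name, x$n_monitors,
              paste(x$monitor_layouts, collapse = ", "),
              total_canvases(x), x$series_placement, x$master_seed))
  cat(sprintf("  questions: %d case-level, %d mark-linked\n",
              length(x$questions), length(x$localization_questions)))
  invisible(x)
}
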