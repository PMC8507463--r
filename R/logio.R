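# Study log: line-oriented text using exactly two delimiter characters —
# TAB between fields and "|" between subfields inside one field. Free text
# is backslash-escaped so the round trip is lossless: "\\" -> backslash,
# "\t" -> TAB, "\p" -> pipe, "\n" -> newline, "\r" -> carriage return.
# TAB pastes straight into spreadsheet columns; "|" groups e.g. a
# coordinate pair within a single column.

LOG_FIELD_DELIM <- "\t"
LOG_SUBFIELD_DELIM <- "|"

LOG_RECORD_KINDS <- c("header", "case_answer", "mark", "measurement",
                      "note", "event", "edit")

# split that keeps trailing empty fields (strsplit drops them)
.split_fields <- function(s, delim) {
  strsplit(paste0(s, delim), delim, fixed = TRUE)[[1]]
}

# minimum payload fields (after the 4 fixed columns) per record kind
.log_min_payload <- c(header = 4L, case_answer = 2L, mark = 4L,
                      measurement = 5L, note = 1L, event = 2L, edit = 2L)

#' Escape free text for a log field
#'
#' @param x character vector.
#' @return escaped character vector containing no delimiter characters.
#' @export
log_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x <- gsub("|", "\\p", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\r", "\\r", x, fixed = TRUE)
}

#' Undo [log_escape()]
#' @param x escaped character vector.
#' @return original text.
#' @export
log_unescape <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- character(0)
    i <- 1L
    n <- length(chars)
    while (i <= n) {
      ch <- chars[i]
      if (ch == "\\" && i < n) {
        nxt <- chars[i + 1L]
        out <- c(out, switch(nxt,
          "\\" = "\\", t = "\t", p = "|", n = "\n", r = "\r", nxt
        ))
        i <- i + 2L
      } else {
        out <- c(out, ch)
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Construct a log record
#'
#' A record is one line of the study log: a record kind, the observer,
#' the case, an optional series slot, and kind-specific payload fields.
#' Payload subfields (e.g. a coordinate pair) are joined with `|` by the
#' caller via [log_subfields()].
#'
#' @param kind one of `r paste(LOG_RECORD_KINDS, collapse=", ")`.
#' @param observer_id observer identifier.
#' @param case_id case identifier, or `NA` for file-level records.
#' @param series_slot 0-based series slot, or `NA`.
#' @param payload character vector of payload fields (unescaped).
#' @return a `log_record` list.
#' @export
log_record <- function(kind, observer_id, case_id = NA, series_slot = NA,
                       payload = character(0)) {
  if (!kind %in% LOG_RECORD_KINDS) {
    log_parse_error(sprintf("unknown record kind '%s'", kind))
  }
  structure(
    list(kind = kind, observer_id = as.character(observer_id),
         case_id = if (is.na(case_id)) NA_character_ else as.character(case_id),
         series_slot = if (is.na(series_slot)) NA_integer_ else as.integer(series_slot),
         payload = as.character(payload)),
    class = "log_record"
  )
}

#' Join subfields with the subfield delimiter
#' @param ... atomic values forming one field.
#' @return single string with `|`-joined, escaped subfields.
#' @export
log_subfields <- function(...) {
  paste(log_escape(as.character(c(...))), collapse = LOG_SUBFIELD_DELIM)
}

#' Split a field into its subfields
#' @param field one payload field as returned by [parse_log()].
#' @return character vector of unescaped subfields.
#' @export
log_split_subfields <- function(field) {
  log_unescape(.split_fields(field, LOG_SUBFIELD_DELIM))
}

.format_record <- function(rec) {
  fields <- c(
    rec$kind,
    log_escape(rec$observer_id),
    if (is.na(rec$case_id)) "-"
    else if (rec$case_id == "-") "\\-"  # literal "-" must not read back as NA
    else log_escape(rec$case_id),
    if (is.na(rec$series_slot)) "-" else as.character(rec$series_slot),
    rec$payload  # payload fields are pre-escaped at construction time
  )
  paste(fields, collapse = LOG_FIELD_DELIM)
}

#' Serialize log records to text
#'
#' One record per line; the only characters in delimiter role are TAB
#' (between fields) and `|` (between subfields).
#'
#' @param records list of `log_record` objects.
#' @return single string (lines joined with `\n`, trailing newline).
#' @export
write_log <- function(records) {
  lines <- vapply(records, .format_record, "")
  paste0(paste(lines, collapse = "\n"), if (length(lines)) "\n" else "")
}

#' Append records to a log file
#'
#' Appends only — earlier bytes are never rewritten, which gives a
#' crash-safe audit trail (edits are new records, not rewrites).
#'
#' @param path log file path.
#' @param records list of `log_record` objects.
#' @return `path`, invisibly.
#' @export
append_log <- function(path, records) {
  cat(write_log(records), file = path, append = TRUE, sep = "")
  invisible(path)
}

#' Parse a study log
#'
#' Inverse of [write_log()]: `parse_log(write_log(x))` reproduces `x`
#' field-for-field, including free text containing delimiter characters.
#'
#' @param text log content (single string or character vector of lines).
#' @param partial if `TRUE`, a malformed line terminates parsing and the
#'   records before it are returned (with attribute `error`); if `FALSE`
#'   a malformed line raises a parse error naming the line.
#' @return a `log_file` list: `header` (named list, possibly empty) and
#'   `records` (list of `log_record`).
#' @export
parse_log <- function(text, partial = FALSE) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  text <- text[nzchar(text)]
  records <- vector("list", length(text))
  err <- NULL
  n_ok <- 0L
  for (i in seq_along(text)) {
    fields <- .split_fields(text[i], LOG_FIELD_DELIM)
    kind <- fields[1]
    bad <- NULL
    if (!kind %in% LOG_RECORD_KINDS) {
      bad <- sprintf("line %d: unknown record kind '%s'", i, kind)
    } else if (length(fields) < 4L + .log_min_payload[[kind]]) {
      bad <- sprintf("line %d: %s record has %d fields, expected at least %d",
                     i, kind, length(fields), 4L + .log_min_payload[[kind]])
    }
    if (!is.null(bad)) {
      if (partial) { err <- bad; break }
      log_parse_error(bad, line = i)
    }
    records[[i]] <- log_record(
      kind = kind,
      observer_id = log_unescape(fields[2]),
      case_id = if (fields[3] == "-") NA else log_unescape(fields[3]),
      series_slot = if (fields[4] == "-") NA else as.integer(fields[4]),
      payload = if (length(fields) > 4L) fields[5:length(fields)] else character(0)
    )
    n_ok <- i
  }
  records <- records[seq_len(n_ok)]
  header <- list()
  hdr <- Filter(function(r) r$kind == "header", records)
  if (length(hdr)) {
    p <- log_unescape(hdr[[1]]$payload)
    header <- list(study_name = p[1], config_digest = p[2],
                   master_seed = as.integer(p[3]), created = p[4],
                   observer_id = hdr[[1]]$observer_id)
  }
  structure(list(header = header, records = records, error = err),
            class = "log_file")
}

#' Characters used in delimiter role in a serialized log
#'
#' Escaped delimiter characters inside free text are not in delimiter
#' role; this scans the raw text, where escapes keep them out entirely.
#'
#' @param text serialized log text.
#' @return character vector of distinct delimiter-role characters.
#' @export
log_delimiter_chars <- function(text) {
  chars <- unique(strsplit(gsub("[^\t|]", "", text), "", fixed = TRUE)[[1]])
  sort(chars)
}

#' Export log records of one kind as a tidy table
#'
#' Flattens records into one row per record with a stable column order,
#' ready for CSV/spreadsheet import.
#'
#' @param log a `log_file` from [parse_log()].
#' @param kind one of `"case_answer"`, `"mark"`, `"measurement"`,
#'   `"note"`, `"event"`, `"edit"` (aliases `"answers"`, `"marks"`,
#'   `"measurements"`, `"notes"` accepted).
#' @return a tibble (possibly 0-row, always with the kind's columns).
#' @export
export_table <- function(log, kind) {
  alias <- c(answers = "case_answer", marks = "mark",
             measurements = "measurement", notes = "note")
  if (kind %in% names(alias)) kind <- alias[[kind]]
  if (!kind %in% setdiff(LOG_RECORD_KINDS, "header")) {
    log_parse_error(sprintf("cannot export records of kind '%s'", kind))
  }
  recs <- Filter(function(r) r$kind == kind, log$records)
  base <- function(r) list(observer_id = r$observer_id, case_id = r$case_id,
                           series_slot = r$series_slot)
  row_fun <- switch(kind,
    case_answer = function(r) {
      p <- log_unescape(r$payload)
      c(base(r), list(question_id = p[1], value = p[2]))
    },
    mark = function(r) {
      p <- r$payload
      addr <- log_split_subfields(p[2])
      pt <- log_split_subfields(p[4])
      linked <- if (length(p) > 4L) {
        paste(log_unescape(p[5:length(p)]), collapse = ";")
      } else ""
      c(base(r), list(mark_idx = as.integer(log_unescape(p[1])),
                      monitor_idx = as.integer(addr[1]),
                      canvas_idx = as.integer(addr[2]),
                      stack_index = as.integer(log_unescape(p[3])),
                      row = as.numeric(pt[1]), col = as.numeric(pt[2]),
                      linked_answers = linked))
    },
    measurement = function(r) {
      p <- r$payload
      addr <- log_split_subfields(p[2])
      res <- log_split_subfields(p[5])
      mk <- log_unescape(p[1])
      c(base(r), list(meas_kind = mk,
                      monitor_idx = as.integer(addr[1]),
                      canvas_idx = as.integer(addr[2]),
                      stack_index = as.integer(log_unescape(p[3])),
                      geometry = paste(log_split_subfields(p[4]), collapse = ";"),
                      distance_mm = if (mk == "distance") as.numeric(res[1]) else NA_real_,
                      area_mm2 = if (mk != "distance") as.numeric(res[1]) else NA_real_,
                      mean_value = if (mk != "distance") as.numeric(res[2]) else NA_real_))
    },
    note = function(r) c(base(r), list(text = log_unescape(r$payload[1]))),
    event = function(r) {
      p <- log_unescape(r$payload)
      c(base(r), list(event = p[1], detail = p[2],
                      timestamp = if (length(p) > 2L) p[3] else NA_character_))
    },
    edit = function(r) {
      p <- log_unescape(r$payload)
      c(base(r), list(target_kind = p[1],
                      fields = paste(p[-1], collapse = ";")))
    }
  )
  cols <- switch(kind,
    case_answer = list(observer_id = character(), case_id = character(),
                       series_slot = integer(), question_id = character(),
                       value = character()),
    mark = list(observer_id = character(), case_id = character(),
                series_slot = integer(), mark_idx = integer(),
                monitor_idx = integer(), canvas_idx = integer(),
                stack_index = integer(), row = numeric(), col = numeric(),
                linked_answers = character()),
    measurement = list(observer_id = character(), case_id = character(),
                       series_slot = integer(), meas_kind = character(),
                       monitor_idx = integer(), canvas_idx = integer(),
                       stack_index = integer(), geometry = character(),
                       distance_mm = numeric(), area_mm2 = numeric(),
                       mean_value = numeric()),
    note = list(observer_id = character(), case_id = character(),
                series_slot = integer(), text = character()),
    event = list(observer_id = character(), case_id = character(),
                 series_slot = integer(), event = character(),
                 detail = character(), timestamp = character()),
    edit = list(observer_id = character(), case_id = character(),
                series_slot = integer(), target_kind = character(),
                fields = character())
  )
  if (!length(recs)) return(tibble::as_tibble(cols))
  rows <- lapply(recs, row_fun)
  tibble::as_tibble(do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  })))
}

#' Mask wall-clock timestamps in serialized log text
#'
#' Timestamps are real in logs but excluded from determinism
#' comparisons; this replaces them with a fixed token.
#'
#' @param text serialized log text.
#' @return text with ISO-8601 timestamps replaced by `<TS>`.
#' @export
mask_timestamps <- function(text) {
  gsub("[0-9]{4}-[0-9]{2}-[0-9]{2}[T ][0-9]{2}:[0-9]{2}:[0-9]{2}(\\.[0-9]+)?",
       "<TS>", text)
}

.now_iso <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
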