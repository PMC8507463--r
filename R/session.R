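# Observer session state machine. Review mode is forward-only: the
# cursor never decreases, and a submitted case can never be revisited.
# Show mode is read-only free navigation for the study owner; edit mode
# additionally appends edit records (the log is append-only, so edits
# are new records, never rewrites — an audit trail that also makes
# resume-after-crash a pure log replay).

.empty_response <- function() {
  list(answers = list(), marks = list(), note = "", measurements = list())
}

.assignment_path <- function(study_dir, observer_id) {
  file.path(study_dir, paste0(observer_id, ".assignment"))
}
.log_path <- function(study_dir, observer_id) {
  file.path(study_dir, paste0(observer_id, ".log"))
}

#' Start (or resume) an observer session
#'
#' First login in review mode creates the observer's assignment (case
#' order + placements) and an empty log; a later login replays the log
#' and resumes at the first incomplete case. Show and edit mode require
#' an existing log. A log whose header digest does not match the current
#' study configuration is refused.
#'
#' @param cfg a `study_config`.
#' @param db a `case_database`.
#' @param observer_id observer identifier.
#' @param mode `"review"`, `"show"` or `"edit"`.
#' @param study_dir study folder (holds logs and assignment sidecars).
#' @return a `session_state`.
#' @export
start_session <- function(cfg, db, observer_id,
                          mode = c("review", "show", "edit"),
                          study_dir) {
  mode <- match.arg(mode)
  apath <- .assignment_path(study_dir, observer_id)
  lpath <- .log_path(study_dir, observer_id)

  if (mode %in% c("show", "edit") && !file.exists(lpath)) {
    session_error(sprintf("no log for observer '%s'; nothing to %s",
                          observer_id, mode))
  }

  if (file.exists(apath)) {
    assignment <- read_assignment(apath)
  } else {
    assignment <- init_observer(cfg, db, observer_id)
    write_assignment(assignment, apath, cfg)
  }

  responses <- list()
  completed <- character(0)
  if (file.exists(lpath)) {
    lf <- parse_log(readLines(lpath, warn = FALSE))
    if (length(lf$header) &&
        !identical(lf$header$config_digest, config_digest(cfg))) {
      session_error("log was recorded under a different study configuration (digest mismatch)")
    }
    replayed <- .replay_records(lf$records)
    responses <- replayed$responses
    completed <- replayed$completed
  } else {
    append_log(lpath, list(log_record("header", observer_id, payload = c(
      log_escape(cfg$study_name), config_digest(cfg),
      as.character(cfg$master_seed), log_escape(.now_iso())
    ))))
  }

  n <- length(assignment$case_order)
  if (mode == "review") {
    incomplete <- which(!assignment$case_order %in% completed)
    cursor <- if (length(incomplete)) incomplete[1] else n + 1L
  } else {
    cursor <- 1L
  }

  structure(list(
    cfg = cfg, db = db, observer_id = observer_id, mode = mode,
    assignment = assignment, cursor = cursor,
    responses = responses, completed = completed,
    finished = cursor > n, pending = .empty_response(),
    study_dir = study_dir, log_path = lpath
  ), class = "session_state")
}

# rebuild responses/completion from log records, applying edits in order
.replay_records <- function(records) {
  responses <- list()
  completed <- character(0)
  touch <- function(cid) {
    if (is.null(responses[[cid]])) responses[[cid]] <<- .empty_response()
  }
  apply_payload <- function(cid, kind, payload, slot = NA_integer_) {
    touch(cid)
    if (kind == "case_answer") {
      p <- log_unescape(payload)
      responses[[cid]]$answers[[p[1]]] <<- p[2]
    } else if (kind == "note") {
      responses[[cid]]$note <<- log_unescape(payload[1])
    } else if (kind == "mark") {
      addr <- as.integer(log_split_subfields(payload[2]))
      pt <- as.numeric(log_split_subfields(payload[4]))
      linked <- list()
      if (length(payload) > 4L) {
        for (f in payload[5:length(payload)]) {
          qv <- log_split_subfields(f)
          linked[[qv[1]]] <- qv[2]
        }
      }
      responses[[cid]]$marks[[length(responses[[cid]]$marks) + 1L]] <<-
        list(monitor_idx = addr[1], canvas_idx = addr[2],
             stack_index = as.integer(log_unescape(payload[3])),
             row = pt[1], col = pt[2], linked = linked)
    } else if (kind == "measurement") {
      addr <- as.integer(log_split_subfields(payload[2]))
      res <- as.numeric(log_split_subfields(payload[5]))
      mk <- log_unescape(payload[1])
      res_names <- if (mk == "distance") "distance_mm" else c("area_mm2", "mean_value")
      names(res) <- res_names[seq_along(res)]
      responses[[cid]]$measurements[[length(responses[[cid]]$measurements) + 1L]] <<-
        list(kind = mk, monitor_idx = addr[1], canvas_idx = addr[2],
             stack_index = as.integer(log_unescape(payload[3])),
             geometry = as.numeric(log_split_subfields(payload[4])),
             result = as.list(res))
    }
  }
  for (r in records) {
    if (r$kind %in% c("case_answer", "note", "mark", "measurement")) {
      apply_payload(r$case_id, r$kind, r$payload, r$series_slot)
    } else if (r$kind == "event") {
      if (log_unescape(r$payload[1]) == "case_completed") {
        completed <- union(completed, r$case_id)
      }
    } else if (r$kind == "edit") {
      apply_payload(r$case_id, log_unescape(r$payload[1]),
                    r$payload[-1], r$series_slot)
    }
  }
  list(responses = responses, completed = completed)
}

#' Case currently under the cursor
#' @param sess a `session_state`.
#' @return case id, or `NA` when the session is finished.
#' @export
current_case_id <- function(sess) {
  if (sess$cursor > length(sess$assignment$case_order)) return(NA_character_)
  sess$assignment$case_order[sess$cursor]
}

.require_mode <- function(sess, modes, what) {
  if (!sess$mode %in% modes) {
    permission_error(sprintf("%s is not allowed in %s mode", what, sess$mode))
  }
}

#' Answer a case-level question on the current case
#' @param sess a `session_state` in review mode.
#' @param qid question id from the study config.
#' @param value answer value; for scale/choice questions it must be one
#'   of the question's allowed values.
#' @return updated session.
#' @export
add_answer <- function(sess, qid, value) {
  .require_mode(sess, "review", "answering")
  if (sess$finished) session_error("session is finished")
  q <- find_question(sess$cfg, qid)
  if (is.null(q) || q$linked_to_mark) {
    config_error(sprintf("no case-level question '%s' in this study", qid))
  }
  value <- as.character(value)
  if (q$kind %in% c("scale", "choice") && !value %in% q$allowed) {
    config_error(sprintf("value '%s' not allowed for question '%s' (allowed: %s)",
                         value, qid, paste(q$allowed, collapse = ", ")))
  }
  sess$pending$answers[[qid]] <- value
  sess
}

.mark_bounds_check <- function(sess, case_id, monitor_idx, canvas_idx,
                               row, col) {
  pl <- sess$assignment$placements[[case_id]]
  hit <- which(pl$monitor_idx == monitor_idx & pl$canvas_idx == canvas_idx)
  if (!length(hit)) {
    assignment_error(sprintf(
      "no series is displayed on monitor %d canvas %d for case '%s'",
      monitor_idx, canvas_idx, case_id))
  }
  slot <- pl$series_slot[hit]
  case <- db_case(sess$db, case_id)
  meta <- read_image_meta(case$series[[slot + 1L]]$instances[[1]])
  if (row < 0 || row > meta$rows - 1 || col < 0 || col > meta$cols - 1) {
    measurement_error(sprintf(
      "mark (%g, %g) outside image bounds %d x %d", row, col,
      meta$rows, meta$cols))
  }
  slot
}

#' Place a localization mark with its linked answers
#'
#' Marks carry the canvas, the stack position and the image point, plus
#' answers to the study's mark-linked questions. Marks are mutable until
#' the case is submitted (see [remove_mark()]); in edit mode the mark is
#' appended to the log immediately as an edit record.
#'
#' @param sess a `session_state` in review or edit mode.
#' @param monitor_idx,canvas_idx 0-based canvas address the mark was
#'   made on.
#' @param row,col 0-based image coordinates.
#' @param stack_index 0-based stack position.
#' @param linked named list/vector of answers to mark-linked questions.
#' @param case_id case to mark (edit mode only; review marks the
#'   current case).
#' @return updated session.
#' @export
add_mark <- function(sess, monitor_idx, canvas_idx, row, col,
                     stack_index = 0L, linked = list(), case_id = NULL) {
  .require_mode(sess, c("review", "edit"), "marking")
  cid <- if (sess$mode == "edit" && !is.null(case_id)) case_id
         else current_case_id(sess)
  if (is.na(cid)) session_error("session is finished")
  slot <- .mark_bounds_check(sess, cid, monitor_idx, canvas_idx, row, col)
  linked <- as.list(linked)
  for (qid in names(linked)) {
    q <- find_question(sess$cfg, qid)
    if (is.null(q) || !q$linked_to_mark) {
      config_error(sprintf("no mark-linked question '%s' in this study", qid))
    }
    v <- as.character(linked[[qid]])
    if (q$kind %in% c("scale", "choice") && !v %in% q$allowed) {
      config_error(sprintf("value '%s' not allowed for question '%s'", v, qid))
    }
    linked[[qid]] <- v
  }
  mark <- list(monitor_idx = as.integer(monitor_idx),
               canvas_idx = as.integer(canvas_idx),
               stack_index = as.integer(stack_index),
               row = as.numeric(row), col = as.numeric(col), linked = linked)
  if (sess$mode == "review") {
    sess$pending$marks[[length(sess$pending$marks) + 1L]] <- mark
  } else {
    if (is.null(sess$responses[[cid]])) sess$responses[[cid]] <- .empty_response()
    idx <- length(sess$responses[[cid]]$marks) + 1L
    sess$responses[[cid]]$marks[[idx]] <- mark
    append_log(sess$log_path, list(log_record(
      "edit", sess$observer_id, cid, slot,
      payload = c("mark", .mark_payload(mark, idx))
    )))
  }
  sess
}

.mark_payload <- function(mark, idx) {
  p <- c(log_escape(as.character(idx)),
         log_subfields(mark$monitor_idx, mark$canvas_idx),
         log_escape(as.character(mark$stack_index)),
         log_subfields(mark$row, mark$col))
  for (qid in names(mark$linked)) {
    p <- c(p, log_subfields(qid, mark$linked[[qid]]))
  }
  p
}

.measurement_payload <- function(m) {
  c(log_escape(m$kind),
    log_subfields(m$monitor_idx, m$canvas_idx),
    log_escape(as.character(m$stack_index)),
    log_subfields(m$geometry),
    log_subfields(unlist(m$result)))
}

#' Remove a not-yet-submitted mark
#' @param sess a `session_state` in review mode.
#' @param idx 1-based index into the pending marks.
#' @return updated session.
#' @export
remove_mark <- function(sess, idx) {
  .require_mode(sess, "review", "removing a mark")
  if (idx < 1L || idx > length(sess$pending$marks)) {
    session_error(sprintf("no pending mark %d", idx))
  }
  sess$pending$marks[[idx]] <- NULL
  sess
}

#' Set the general note for the current case
#' @param sess a `session_state` in review mode.
#' @param text free text (no length limit).
#' @return updated session.
#' @export
set_note <- function(sess, text) {
  .require_mode(sess, "review", "writing a note")
  if (!isTRUE(sess$cfg$notes_enabled)) {
    permission_error("notes are disabled in this study")
  }
  sess$pending$note <- as.character(text)
  sess
}

#' Store a computed measurement into the pending case response
#'
#' The observer chooses which measurements end up in the log; only
#' stored measurements are written, with their full geometry, so their
#' locations can be reviewed in retrospect (show mode).
#'
#' @param sess a `session_state` in review mode.
#' @param m a `measurement` from [distance_mm()], [circle_roi_stats()]
#'   or [polygon_roi_stats()].
#' @return updated session.
#' @export
store_measurement <- function(sess, m) {
  if (sess$mode == "show") {
    permission_error("show mode is read-only; measurements cannot be stored")
  }
  .require_mode(sess, "review", "storing a measurement")
  if (!isTRUE(sess$cfg$measurements_enabled)) {
    permission_error("measurements are disabled in this study")
  }
  canvas <- if (is.null(m$canvas)) c(0L, 0L) else as.integer(m$canvas)
  geometry <- switch(m$kind,
    distance = c(m$geometry$p1, m$geometry$p2),
    circle_roi = c(m$geometry$center, m$geometry$radius_px),
    polygon_roi = as.numeric(t(m$geometry$vertices))
  )
  norm <- list(kind = m$kind, monitor_idx = canvas[1], canvas_idx = canvas[2],
               stack_index = as.integer(m$stack_index),
               geometry = as.numeric(geometry),
               result = lapply(m$result, as.numeric))
  sess$pending$measurements[[length(sess$pending$measurements) + 1L]] <- norm
  sess
}

.missing_required <- function(sess) {
  missing <- character(0)
  for (q in sess$cfg$questions) {
    if (q$required && is.null(sess$pending$answers[[q$id]])) {
      missing <- c(missing, q$id)
    }
  }
  for (mk in sess$pending$marks) {
    for (q in sess$cfg$localization_questions) {
      if (q$required && is.null(mk$linked[[q$id]])) {
        missing <- c(missing, q$id)
      }
    }
  }
  unique(missing)
}

#' Submit the current case and advance
#'
#' Gated on every required question being answered (case-level, and
#' mark-linked for each mark). The whole case block — answers, marks,
#' stored measurements, note, completion event — is appended to the log
#' in one write, then the cursor moves forward. After the last case the
#' session is finished.
#'
#' @param sess a `session_state` in review mode.
#' @return updated session.
#' @export
submit_and_advance <- function(sess) {
  .require_mode(sess, "review", "submitting")
  if (sess$finished) session_error("all cases are already submitted")
  missing <- .missing_required(sess)
  if (length(missing)) {
    incomplete_error(sprintf("required question(s) unanswered: %s",
                             paste(missing, collapse = ", ")),
                     questions = missing)
  }
  cid <- current_case_id(sess)
  obs <- sess$observer_id
  pl <- sess$assignment$placements[[cid]]
  slot_of <- function(monitor_idx, canvas_idx) {
    hit <- which(pl$monitor_idx == monitor_idx & pl$canvas_idx == canvas_idx)
    if (length(hit)) pl$series_slot[hit] else NA_integer_
  }

  recs <- list()
  for (qid in names(sess$pending$answers)) {
    recs <- c(recs, list(log_record(
      "case_answer", obs, cid,
      payload = c(log_escape(qid), log_escape(sess$pending$answers[[qid]]))
    )))
  }
  for (i in seq_along(sess$pending$marks)) {
    mk <- sess$pending$marks[[i]]
    recs <- c(recs, list(log_record(
      "mark", obs, cid, slot_of(mk$monitor_idx, mk$canvas_idx),
      payload = .mark_payload(mk, i)
    )))
  }
  for (m in sess$pending$measurements) {
    recs <- c(recs, list(log_record(
      "measurement", obs, cid, slot_of(m$monitor_idx, m$canvas_idx),
      payload = .measurement_payload(m)
    )))
  }
  if (nzchar(sess$pending$note)) {
    recs <- c(recs, list(log_record(
      "note", obs, cid, payload = log_escape(sess$pending$note)
    )))
  }
  recs <- c(recs, list(log_record(
    "event", obs, cid,
    payload = c("case_completed", log_escape(as.character(sess$cursor)),
                log_escape(.now_iso()))
  )))
  append_log(sess$log_path, recs)

  sess$responses[[cid]] <- sess$pending
  sess$completed <- union(sess$completed, cid)
  sess$pending <- .empty_response()
  sess$cursor <- sess$cursor + 1L
  sess$finished <- sess$cursor > length(sess$assignment$case_order)
  sess
}

#' Try to move to the previous case
#'
#' In review mode this always fails: observers cannot return to a
#' previous case, which protects the study from threshold drift and
#' fatigue biases. In show/edit mode the owner navigates freely.
#'
#' @param sess a `session_state`.
#' @return updated session (show/edit) — review mode raises a
#'   navigation error and leaves the state unchanged.
#' @export
attempt_back <- function(sess) {
  if (sess$mode == "review") {
    navigation_error("cannot return to a previous case during review")
  }
  sess$cursor <- max(1L, sess$cursor - 1L)
  sess
}

#' Jump to a case (show/edit mode only)
#' @param sess a `session_state` in show or edit mode.
#' @param case_id target case id.
#' @return updated session.
#' @export
goto_case <- function(sess, case_id) {
  .require_mode(sess, c("show", "edit"), "free navigation")
  idx <- which(sess$assignment$case_order == case_id)
  if (!length(idx)) session_error(sprintf("no case '%s' in this assignment", case_id))
  sess$cursor <- idx
  sess
}

#' Change a recorded answer (edit mode)
#'
#' Appends an edit record — the original answer stays in the log, the
#' edit supersedes it on replay.
#'
#' @param sess a `session_state` in edit mode.
#' @param case_id case whose answer to change.
#' @param qid question id.
#' @param value new value (validated against the question).
#' @return updated session.
#' @export
edit_answer <- function(sess, case_id, qid, value) {
  .require_mode(sess, "edit", "editing answers")
  q <- find_question(sess$cfg, qid)
  if (is.null(q)) config_error(sprintf("no question '%s' in this study", qid))
  value <- as.character(value)
  if (q$kind %in% c("scale", "choice") && !value %in% q$allowed) {
    config_error(sprintf("value '%s' not allowed for question '%s'", value, qid))
  }
  if (is.null(sess$responses[[case_id]])) {
    session_error(sprintf("case '%s' has no recorded response to edit", case_id))
  }
  append_log(sess$log_path, list(log_record(
    "edit", sess$observer_id, case_id,
    payload = c("case_answer", log_escape(qid), log_escape(value))
  )))
  sess$responses[[case_id]]$answers[[qid]] <- value
  sess
}

#' Rebuild a session purely from its log
#'
#' The reconstruction contract: after any sequence of events, a session
#' rebuilt from the log equals the in-memory session (responses,
#' completion set, cursor).
#'
#' @inheritParams start_session
#' @return a `session_state`.
#' @export
rebuild_session <- function(cfg, db, observer_id, mode = "review",
                            study_dir) {
  start_session(cfg, db, observer_id, mode, study_dir)
}

#' @export
print.session_state <- function(x, ...) {
  cat(sprintf("Session %s [%s]: case %d/%d%s\n", x$observer_id, x$mode,
              min(x$cursor, length(x$assignment$case_order)),
              length(x$assignment$case_order),
              if (x$finished) " (finished)" else ""))
  invisible(x)
}
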