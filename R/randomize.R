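# Deterministic per-observer randomization. Every draw is a pure
# function of (master_seed, stream label, observer_id[, case_id]): the
# tuple is hashed with 32-bit FNV-1a into a seed for R's Mersenne
# Twister, and the global RNG state is saved and restored around the
# draw. Adding an observer therefore never perturbs any other
# observer's order, and re-running a study reproduces every assignment.

# 32-bit FNV-1a over the UTF-8 bytes of a string, in double arithmetic
# (products are kept under 2^53 by splitting into 16-bit halves).
fnv1a32 <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in as.integer(charToRaw(enc2utf8(s)))) {
    lo <- h %% 65536
    hi <- h %/% 65536
    lo <- bitwXor(as.integer(lo), b)  # b < 256 touches the low half only
    h <- hi * 65536 + lo
    h <- (h %% 65536 * p + ((h %/% 65536 * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Derive a reproducible RNG seed from study coordinates
#'
#' @param master_seed integer study seed from the property file.
#' @param ... further coordinates (stream label, observer id, case id).
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, ...) {
  key <- paste(c(as.character(master_seed), as.character(c(...))),
               collapse = "\x1f")
  as.integer(fnv1a32(key) %% 2147483647)
}

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

#' Per-observer case presentation order
#'
#' Each observer sees the cases in a unique randomised order, drawn
#' uniformly over permutations and fixed by `(master_seed, observer_id)`.
#'
#' @param cfg a `study_config`.
#' @param db a `case_database`.
#' @param observer_id observer identifier.
#' @return character vector: permutation of the database's case ids.
#' @export
case_order <- function(cfg, db, observer_id) {
  ids <- case_ids(db)
  if (!length(ids)) database_error("case database is empty")
  if (length(ids) == 1L) return(ids)
  with_seed(derive_seed(cfg$master_seed, "case_order", observer_id),
            sample(ids))
}

#' Map a case's series slots onto monitor canvases
#'
#' In `fixed` placement mode the configured map (or the default fill
#' order: canvases in monitor-major, row-major order) is used for every
#' observer. In `randomized` mode an injective slot-to-canvas mapping is
#' drawn uniformly (shuffle the canvas list, take a prefix), fixed by
#' `(master_seed, observer_id, case_id)` — the mechanism that lets AFC
#' studies run without pre-arranged image sets. Canvases left unmapped
#' are displayed empty (black).
#'
#' @param cfg a `study_config`.
#' @param case a `case` from the database, or an integer series count.
#' @param observer_id observer identifier.
#' @param case_id case identifier (defaults to `case$case_id`).
#' @return tibble with columns `series_slot`, `monitor_idx`,
#'   `canvas_idx` (all 0-based), one row per series slot.
#' @export
assign_series_to_canvases <- function(cfg, case, observer_id,
                                      case_id = NULL) {
  n_series <- if (is.numeric(case)) as.integer(case) else length(case$series)
  if (is.null(case_id)) {
    case_id <- if (is.numeric(case)) "case" else case$case_id
  }
  grid <- build_canvas_grid(cfg)
  n_canvas <- nrow(grid$canvases)
  if (n_series > n_canvas) {
    assignment_error(sprintf(
      "case '%s' has %d series but the layout offers only %d canvases",
      case_id, n_series, n_canvas))
  }
  if (cfg$series_placement == "fixed") {
    if (!is.null(cfg$fixed_placement_map)) {
      m <- cfg$fixed_placement_map
      m <- m[m$series_slot < n_series, , drop = FALSE]
      if (nrow(m) != n_series) {
        assignment_error(sprintf(
          "fixed placement map covers %d of %d series slots for case '%s'",
          nrow(m), n_series, case_id))
      }
      idx <- order(m$series_slot)
      return(tibble::tibble(series_slot = m$series_slot[idx],
                            monitor_idx = m$monitor_idx[idx],
                            canvas_idx = m$canvas_idx[idx]))
    }
    pick <- seq_len(n_series)
  } else {
    pick <- with_seed(
      derive_seed(cfg$master_seed, "placement", observer_id, case_id),
      sample(n_canvas)
    )[seq_len(n_series)]
  }
  tibble::tibble(
    series_slot = 0:(n_series - 1L),
    monitor_idx = grid$canvases$monitor_idx[pick],
    canvas_idx = grid$canvases$canvas_idx[pick]
  )
}

#' Materialize an observer's full assignment
#'
#' The assignment fixes, for one observer, the case presentation order
#' and the series-to-canvas placement of every case.
#'
#' @param cfg a `study_config`.
#' @param db a `case_database`.
#' @param observer_id observer identifier.
#' @return an `assignment` list: `observer_id`, `case_order`,
#'   `placements` (named list of placement tibbles, one per case).
#' @export
init_observer <- function(cfg, db, observer_id) {
  ord <- case_order(cfg, db, observer_id)
  placements <- lapply(ord, function(cid) {
    assign_series_to_canvases(cfg, db_case(db, cid), observer_id, cid)
  })
  names(placements) <- ord
  structure(list(observer_id = observer_id, case_order = ord,
                 placements = placements),
            class = "assignment")
}

#' Write an assignment sidecar file
#'
#' Same two-delimiter dialect as the study log, so assignments are
#' inspectable with the same tooling.
#'
#' @param assignment an `assignment`.
#' @param path output path.
#' @param cfg the `study_config` (for the header digest).
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path, cfg) {
  obs <- assignment$observer_id
  recs <- list(
    log_record("header", obs, payload = c(
      log_escape(cfg$study_name), config_digest(cfg),
      as.character(cfg$master_seed), log_escape(.now_iso())
    )),
    log_record("event", obs, payload = c(
      "case_order", log_subfields(assignment$case_order)
    ))
  )
  for (cid in assignment$case_order) {
    p <- assignment$placements[[cid]]
    for (k in seq_len(nrow(p))) {
      recs <- c(recs, list(log_record(
        "event", obs, case_id = cid, series_slot = p$series_slot[k],
        payload = c("placement", log_subfields(p$monitor_idx[k], p$canvas_idx[k]))
      )))
    }
  }
  cat(write_log(recs), file = path, sep = "")
  invisible(path)
}

#' Read an assignment sidecar file
#' @param path sidecar path written by [write_assignment()].
#' @return an `assignment`.
#' @export
read_assignment <- function(path) {
  lf <- parse_log(readLines(path, warn = FALSE))
  ev <- Filter(function(r) r$kind == "event", lf$records)
  ord <- NULL
  rows <- list()
  for (r in ev) {
    p <- log_unescape(r$payload[1])
    if (p == "case_order") {
      ord <- log_split_subfields(r$payload[2])
    } else if (p == "placement") {
      mc <- as.integer(log_split_subfields(r$payload[2]))
      rows[[length(rows) + 1L]] <- list(case_id = r$case_id,
                                        series_slot = r$series_slot,
                                        monitor_idx = mc[1], canvas_idx = mc[2])
    }
  }
  if (is.null(ord)) log_parse_error(sprintf("no case_order record in %s", path))
  placements <- lapply(ord, function(cid) {
    sel <- Filter(function(x) x$case_id == cid, rows)
    sel <- sel[order(vapply(sel, function(x) x$series_slot, 0L))]
    tibble::tibble(
      series_slot = vapply(sel, function(x) x$series_slot, 0L),
      monitor_idx = vapply(sel, function(x) x$monitor_idx, 0L),
      canvas_idx = vapply(sel, function(x) x$canvas_idx, 0L)
    )
  })
  names(placements) <- ord
  structure(list(observer_id = lf$records[[1]]$observer_id,
                 case_order = ord, placements = placements),
            class = "assignment")
}
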