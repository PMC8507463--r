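# Monitor/canvas geometry and per-canvas display state. Canvases are
# enumerated monitor-major, row-major within each monitor (0-based).
# Display state lives per series slot of the current case; the slot's
# canvas comes from the placement, so temporary layout changes move or
# hide series without touching their window/zoom/scroll state.

#' Enumerate the canvases of a study's monitor configuration
#'
#' @param cfg a `study_config` (or a character vector of layout kinds).
#' @return a `canvas_grid`: `layouts` plus a tibble `canvases` with
#'   0-based `monitor_idx`, `canvas_idx` and `global_idx`, enumerated
#'   monitor-major, row-major.
#' @export
build_canvas_grid <- function(cfg) {
  layouts <- if (is.character(cfg)) cfg else cfg$monitor_layouts
  counts <- layout_canvases(layouts)
  if (length(layouts) < 1L || length(layouts) > 4L) {
    config_error(sprintf("%d monitors requested; 1..4 supported", length(layouts)))
  }
  monitor_idx <- rep(seq_along(layouts) - 1L, counts)
  canvas_idx <- unlist(lapply(counts, function(k) 0:(k - 1L)))
  structure(list(
    layouts = unname(layouts),
    canvases = tibble::tibble(
      monitor_idx = monitor_idx,
      canvas_idx = as.integer(canvas_idx),
      global_idx = seq_along(monitor_idx) - 1L
    )
  ), class = "canvas_grid")
}

#' Global canvas index of a (monitor, canvas) address
#' @param grid a `canvas_grid`.
#' @param monitor_idx,canvas_idx 0-based address.
#' @return 0-based global index.
#' @export
canvas_global_idx <- function(grid, monitor_idx, canvas_idx) {
  as.integer(mapply(function(m, cv) {
    hit <- grid$canvases$monitor_idx == m & grid$canvases$canvas_idx == cv
    if (!any(hit)) {
      config_error(sprintf("no canvas %d on monitor %d", cv, m))
    }
    grid$canvases$global_idx[hit]
  }, monitor_idx, canvas_idx))
}

.default_display_state <- function(meta, n_instances) {
  win <- meta$default_window
  if (is.null(win)) win <- list(center = 32768, width = 65536)
  list(window = c(center = win$center, width = win$width),
       zoom = 1.0, pan = c(dx = 0, dy = 0),
       stack_index = 0L, n_instances = n_instances,
       is_stack = n_instances > 1L, selected = FALSE)
}

#' Build the display view of one case
#'
#' Combines the canvas grid, the observer's series placement for the
#' case, and a fresh display state per series (window from the image's
#' default window tags, zoom 1, no pan, stack at the first instance).
#'
#' @param cfg a `study_config`.
#' @param case a `case` from the database.
#' @param placement placement tibble from [assign_series_to_canvases()].
#' @return a `case_view`: `grid`, `placement` (with a `hidden` column),
#'   `states` (named by series slot), `default` (snapshot for revert).
#' @export
create_case_view <- function(cfg, case, placement) {
  grid <- build_canvas_grid(cfg)
  placement$hidden <- FALSE
  states <- lapply(seq_len(nrow(placement)), function(k) {
    slot <- placement$series_slot[k]
    ser <- case$series[[slot + 1L]]
    .default_display_state(read_image_meta(ser$instances[[1]]),
                           length(ser$instances))
  })
  names(states) <- as.character(placement$series_slot)
  structure(list(cfg = cfg, case_id = case$case_id, grid = grid,
                 placement = placement, states = states, default = NULL),
            class = "case_view")
}

#' Temporarily change one monitor's canvas layout
#'
#' Lets the observer e.g. inspect one stack full-screen (`1x1`) or two
#' of four images side-by-side (`1x2`/`2x1`). Series whose canvases
#' vanish are hidden, never deleted; the default layout and placement
#' are recoverable with [revert_temporary_layout()], and display states
#' survive the round trip. The change never persists into the
#' assignment or the log.
#'
#' @param view a `case_view`.
#' @param monitor_idx 0-based monitor to change.
#' @param new_layout one of `"1x1"`, `"1x2"`, `"2x1"`, `"2x2"`.
#' @param keep_slots series slots (on that monitor) to keep visible, in
#'   display order; defaults to the first slots that fit.
#' @return modified `case_view`.
#' @export
apply_temporary_layout <- function(view, monitor_idx, new_layout,
                                   keep_slots = NULL) {
  if (!isTRUE(view$cfg$features$allow_temporary_layout)) {
    permission_error("temporary layout changes are prohibited in this study")
  }
  if (monitor_idx < 0L || monitor_idx >= length(view$grid$layouts)) {
    config_error(sprintf("no monitor %d", monitor_idx))
  }
  if (is.null(view$default)) {
    view$default <- list(grid = view$grid, placement = view$placement)
  }
  layouts <- view$grid$layouts
  layouts[monitor_idx + 1L] <- new_layout
  new_grid <- build_canvas_grid(layouts)
  cap <- layout_canvases(new_layout)

  pl <- view$placement
  on_mon <- which(pl$monitor_idx == monitor_idx & !pl$hidden)
  slots_here <- pl$series_slot[on_mon]
  if (is.null(keep_slots)) {
    keep_slots <- slots_here[seq_len(min(cap, length(slots_here)))]
  } else {
    if (!all(keep_slots %in% slots_here)) {
      assignment_error("keep_slots must be series currently shown on that monitor")
    }
    if (length(keep_slots) > cap) {
      assignment_error(sprintf("layout %s shows at most %d series", new_layout, cap))
    }
  }
  for (i in on_mon) {
    slot <- pl$series_slot[i]
    if (slot %in% keep_slots) {
      pl$canvas_idx[i] <- as.integer(which(keep_slots == slot) - 1L)
      pl$hidden[i] <- FALSE
    } else {
      pl$hidden[i] <- TRUE
    }
  }
  view$grid <- new_grid
  view$placement <- pl
  view
}

#' Restore the default layout after a temporary change
#' @param view a `case_view`.
#' @return the view with the default grid and placement; display states
#'   are kept as they are (preserved across the round trip).
#' @export
revert_temporary_layout <- function(view) {
  if (is.null(view$default)) return(view)
  view$grid <- view$default$grid
  view$placement <- view$default$placement
  view$default <- NULL
  view
}

#' Select or deselect series for multi-canvas operations
#' @param states display-state list of a `case_view`.
#' @param slots series slots to select.
#' @param exclusive drop previous selection first (default `TRUE`).
#' @return updated states.
#' @export
select_canvases <- function(states, slots, exclusive = TRUE) {
  for (k in names(states)) {
    sel <- as.integer(k) %in% slots
    if (exclusive) states[[k]]$selected <- sel
    else if (sel) states[[k]]$selected <- TRUE
  }
  states
}

#' Apply a display-property delta to every selected canvas
#'
#' Multi-select propagation: the delta lands on exactly the selected
#' canvases, all others untouched. Feature flags gate each property —
#' a prohibited window change raises a permission error and leaves the
#' states unchanged.
#'
#' @param states display-state list.
#' @param change one of `list(window = c(dcenter, dwidth))`,
#'   `list(zoom = factor)`, `list(pan = c(dx, dy))`.
#' @param features the study's feature flags.
#' @return updated states.
#' @export
set_display_property <- function(states, change, features) {
  sel <- names(states)[vapply(states, function(s) isTRUE(s$selected), TRUE)]
  if (!length(sel)) permission_error("no canvas is selected")
  prop <- names(change)[1]
  gate <- switch(prop,
    window = features$allow_window_change,
    zoom = features$allow_zoom_pan,
    pan = features$allow_zoom_pan,
    config_error(sprintf("unknown display property '%s'", prop))
  )
  if (!isTRUE(gate)) {
    permission_error(sprintf("changing '%s' is prohibited in this study", prop))
  }
  for (k in sel) {
    s <- states[[k]]
    if (prop == "window") {
      w <- s$window + change$window
      if (w[["width"]] <= 0) {
        measurement_error("window width must stay positive")
      }
      s$window <- w
    } else if (prop == "zoom") {
      z <- s$zoom * change$zoom
      if (z <= 0) measurement_error("zoom must stay positive")
      s$zoom <- z
    } else {
      s$pan <- s$pan + change$pan
    }
    states[[k]] <- s
  }
  states
}

#' Scroll the selected stacks
#'
#' Synchronized scrolling: every selected stack advances by `delta`,
#' clamped to its own valid range. Selected single images are a no-op,
#' not an error.
#'
#' @param states display-state list.
#' @param delta signed scroll amount.
#' @return updated states.
#' @export
scroll_stacks <- function(states, delta) {
  for (k in names(states)) {
    s <- states[[k]]
    if (isTRUE(s$selected) && s$n_instances > 1L) {
      s$stack_index <- max(0L, min(s$n_instances - 1L,
                                   s$stack_index + as.integer(delta)))
      states[[k]] <- s
    }
  }
  states
}

#' One cine-loop step
#'
#' Cine is modeled as repeated unit scrolls with wraparound — a pure
#' state iterator with no timing.
#'
#' @param states display-state list.
#' @param features feature flags (`allow_cine` gates it).
#' @return updated states.
#' @export
cine_step <- function(states, features) {
  if (!isTRUE(features$allow_cine)) {
    permission_error("cine loop is prohibited in this study")
  }
  for (k in names(states)) {
    s <- states[[k]]
    if (isTRUE(s$selected) && s$n_instances > 1L) {
      s$stack_index <- (s$stack_index + 1L) %% s$n_instances
      states[[k]] <- s
    }
  }
  states
}

#' Map stored pixel values to 8-bit display values
#'
#' The modality rescale (`slope * v + intercept`) is applied first, then
#' the DICOM linear VOI window function, clamped to `[0, 255]` and
#' rounded half-up. Monotone non-decreasing in the stored value for
#' positive slope.
#'
#' @param stored_value numeric vector of stored pixel values.
#' @param meta an `image_meta` (supplies slope/intercept).
#' @param window `c(center, width)` with `width > 0`.
#' @return integer vector in `[0, 255]`.
#' @export
window_to_display <- function(stored_value, meta, window) {
  center <- window[[1]]
  width <- window[[2]]
  if (width <= 0) measurement_error("window width must be positive")
  x <- meta$rescale_slope * stored_value + meta$rescale_intercept
  if (width > 1) {
    y <- ((x - (center - 0.5)) / (width - 1) + 0.5) * 255
  } else {
    y <- ifelse(x <= center - 0.5, 0, 255)
  }
  as.integer(pmin(255, pmax(0, floor(y + 0.5))))
}
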