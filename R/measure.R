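# Physical measurements. Convention: area is geometric (analytic
# formula on the continuous figure), the mean is sampled over pixel
# centers — centers strictly inside a circle, even-odd-inside for a
# polygon with boundary centers excluded. Means use modality values
# (slope * v + intercept) by default, since a raw stored-value mean is
# rarely diagnostically meaningful; `rescaled = FALSE` gives raw means.
# Coordinates are 0-based (row, col), pixel centers at integers.

.check_point_bounds <- function(p, meta, what = "point") {
  if (p[1] < 0 || p[1] > meta$rows - 1 || p[2] < 0 || p[2] > meta$cols - 1) {
    measurement_error(sprintf(
      "%s (%g, %g) outside image bounds %d x %d", what, p[1], p[2],
      meta$rows, meta$cols))
  }
  invisible(TRUE)
}

.measurement <- function(kind, geometry, result, canvas = NULL,
                         stack_index = 0L) {
  structure(list(kind = kind, canvas = canvas, stack_index = stack_index,
                 geometry = geometry, result = result, stored = FALSE),
            class = "measurement")
}

#' Distance between two image points, in millimetres
#'
#' Euclidean distance with anisotropic pixel spacing:
#' `sqrt((drow * row_mm)^2 + (dcol * col_mm)^2)`. The endpoints are
#' recorded verbatim so the measured line can be reviewed in retrospect.
#'
#' @param p1,p2 numeric `(row, col)` pixel coordinates (0-based).
#' @param meta an `image_meta`. Must carry pixel spacing: a unitless
#'   image raises a units error (use `allow_px = TRUE` to get an
#'   explicit pixel-unit measurement instead).
#' @param allow_px return pixel units when spacing is missing.
#' @param canvas optional canvas address `c(monitor_idx, canvas_idx)`.
#' @param stack_index 0-based stack position the measurement was made on.
#' @return a `measurement` with `result$distance_mm` (or
#'   `result$distance_px` when `allow_px` kicks in).
#' @export
distance_mm <- function(p1, p2, meta, allow_px = FALSE, canvas = NULL,
                        stack_index = 0L) {
  .check_point_bounds(p1, meta, "start point")
  .check_point_bounds(p2, meta, "end point")
  d_px <- c(p2[1] - p1[1], p2[2] - p1[2])
  if (meta$unitless) {
    if (!allow_px) {
      units_error("image has no PixelSpacing; distance in mm is undefined (set allow_px = TRUE for pixel units)")
    }
    return(.measurement("distance", list(p1 = p1, p2 = p2),
                        list(distance_px = sqrt(sum(d_px^2))),
                        canvas, stack_index))
  }
  sp <- meta$pixel_spacing_mm
  d <- sqrt((d_px[1] * sp[1])^2 + (d_px[2] * sp[2])^2)
  .measurement("distance", list(p1 = p1, p2 = p2),
               list(distance_mm = d), canvas, stack_index)
}

.roi_mean <- function(image, meta, inside_idx, rescaled) {
  v <- image[inside_idx]
  if (rescaled) v <- meta$rescale_slope * v + meta$rescale_intercept
  mean(v)
}

#' Circular ROI: area and mean pixel value
#'
#' Area is analytic: `pi * radius_px^2 * row_mm * col_mm`. The mean is
#' taken over pixels whose centers fall strictly inside the circle.
#'
#' @param image integer matrix of stored pixel values (rows x cols).
#' @param meta an `image_meta`.
#' @param center numeric `(row, col)` circle center, 0-based pixels.
#' @param radius_px circle radius in pixels, positive.
#' @param rescaled compute the mean on modality values (default) or on
#'   raw stored values.
#' @param canvas,stack_index see [distance_mm()].
#' @return a `measurement` with `result$area_mm2` and `result$mean_value`.
#' @export
circle_roi_stats <- function(image, meta, center, radius_px,
                             rescaled = TRUE, canvas = NULL,
                             stack_index = 0L) {
  if (radius_px <= 0) measurement_error("radius must be positive")
  .check_point_bounds(center, meta, "circle center")
  if (meta$unitless) {
    units_error("image has no PixelSpacing; ROI area in mm2 is undefined")
  }
  rows <- nrow(image)
  cols <- ncol(image)
  r0 <- max(0L, floor(center[1] - radius_px))
  r1 <- min(rows - 1L, ceiling(center[1] + radius_px))
  c0 <- max(0L, floor(center[2] - radius_px))
  c1 <- min(cols - 1L, ceiling(center[2] + radius_px))
  rr <- r0:r1
  cc <- c0:c1
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, `+`)
  inside <- d2 < radius_px^2
  if (!any(inside)) {
    measurement_error("no pixel center falls inside the circle")
  }
  idx <- which(inside, arr.ind = TRUE)
  lin <- cbind(rr[idx[, 1]] + 1L, cc[idx[, 2]] + 1L)
  sp <- meta$pixel_spacing_mm
  .measurement(
    "circle_roi",
    list(center = center, radius_px = radius_px),
    list(area_mm2 = pi * radius_px^2 * sp[1] * sp[2],
         mean_value = .roi_mean(image, meta, lin, rescaled)),
    canvas, stack_index
  )
}

# signed shoelace area in squared pixels; vertices as n x 2 (row, col)
shoelace_area <- function(vertices) {
  r <- vertices[, 1]
  c_ <- vertices[, 2]
  n <- nrow(vertices)
  j <- c(2:n, 1)
  sum(r * c_[j] - r[j] * c_) / 2
}

# proper segment intersection for the simplicity check
.orient <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}
.on_segment <- function(a, b, p) {
  min(a[1], b[1]) <= p[1] && p[1] <= max(a[1], b[1]) &&
    min(a[2], b[2]) <= p[2] && p[2] <= max(a[2], b[2])
}
.segments_cross <- function(a, b, c, d) {
  o1 <- .orient(a, b, c); o2 <- .orient(a, b, d)
  o3 <- .orient(c, d, a); o4 <- .orient(c, d, b)
  if (((o1 > 0) != (o2 > 0)) && ((o3 > 0) != (o4 > 0)) &&
      o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0) return(TRUE)
  if (o1 == 0 && .on_segment(a, b, c)) return(TRUE)
  if (o2 == 0 && .on_segment(a, b, d)) return(TRUE)
  if (o3 == 0 && .on_segment(c, d, a)) return(TRUE)
  if (o4 == 0 && .on_segment(c, d, b)) return(TRUE)
  FALSE
}

is_simple_polygon <- function(vertices) {
  n <- nrow(vertices)
  if (n < 3L) return(FALSE)
  for (i in seq_len(n)) {
    a <- vertices[i, ]; b <- vertices[i %% n + 1L, ]
    for (j in seq_len(n)) {
      if (j == i) next
      # adjacent edges share an endpoint legitimately
      if (abs(i - j) == 1L || abs(i - j) == n - 1L) next
      c_ <- vertices[j, ]; d <- vertices[j %% n + 1L, ]
      if (.segments_cross(a, b, c_, d)) return(FALSE)
    }
  }
  TRUE
}

# even-odd (crossing-number) point-in-polygon test, vectorized over
# points; points exactly on an edge are reported NA (boundary).
points_in_polygon <- function(pr, pc, vertices) {
  n <- nrow(vertices)
  inside <- rep(FALSE, length(pr))
  boundary <- rep(FALSE, length(pr))
  for (i in seq_len(n)) {
    a <- vertices[i, ]
    b <- vertices[i %% n + 1L, ]
    # vectorized orientation of every point against edge a-b
    crs <- (b[1] - a[1]) * (pc - a[2]) - (b[2] - a[2]) * (pr - a[1])
    on_edge <- crs == 0 &
      pr >= pmin(a[1], b[1]) & pr <= pmax(a[1], b[1]) &
      pc >= pmin(a[2], b[2]) & pc <= pmax(a[2], b[2])
    boundary <- boundary | on_edge
    # ray cast along +col from the point: edge crosses if it spans pr
    spans <- (a[1] > pr) != (b[1] > pr)
    xi <- a[2] + (pr - a[1]) / (b[1] - a[1]) * (b[2] - a[2])
    crossing <- spans & (pc < xi)
    inside <- xor(inside, crossing & !is.na(crossing))
  }
  ifelse(boundary, NA, inside)
}

#' Freeform (polygon) ROI: area and mean pixel value
#'
#' Area is the shoelace formula scaled by the pixel spacing:
#' `|shoelace| * row_mm * col_mm`. The mean is taken over pixel centers
#' inside the polygon by the even-odd rule; centers exactly on the
#' boundary are excluded.
#'
#' @param image integer matrix of stored pixel values.
#' @param meta an `image_meta`.
#' @param vertices numeric matrix (n x 2) of `(row, col)` vertices of a
#'   simple (non-self-intersecting) polygon, n >= 3.
#' @param rescaled,canvas,stack_index see [circle_roi_stats()].
#' @return a `measurement` with `result$area_mm2` and `result$mean_value`.
#' @export
polygon_roi_stats <- function(image, meta, vertices, rescaled = TRUE,
                              canvas = NULL, stack_index = 0L) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) {
    measurement_error("polygon ROI needs at least 3 vertices")
  }
  apply(vertices, 1, .check_point_bounds, meta = meta, what = "vertex")
  if (!is_simple_polygon(vertices)) {
    measurement_error("polygon is self-intersecting")
  }
  if (meta$unitless) {
    units_error("image has no PixelSpacing; ROI area in mm2 is undefined")
  }
  r0 <- max(0L, floor(min(vertices[, 1])))
  r1 <- min(nrow(image) - 1L, ceiling(max(vertices[, 1])))
  c0 <- max(0L, floor(min(vertices[, 2])))
  c1 <- min(ncol(image) - 1L, ceiling(max(vertices[, 2])))
  gr <- expand.grid(row = r0:r1, col = c0:c1)
  status <- points_in_polygon(gr$row, gr$col, vertices)
  keep <- which(!is.na(status) & status)
  if (!length(keep)) {
    measurement_error("no pixel center falls inside the polygon")
  }
  lin <- cbind(gr$row[keep] + 1L, gr$col[keep] + 1L)
  sp <- meta$pixel_spacing_mm
  .measurement(
    "polygon_roi",
    list(vertices = vertices),
    list(area_mm2 = abs(shoelace_area(vertices)) * sp[1] * sp[2],
         mean_value = .roi_mean(image, meta, lin, rescaled)),
    canvas, stack_index
  )
}

#' @export
print.measurement <- function(x, ...) {
  res <- paste(sprintf("%s = %.4g", names(x$result), unlist(x$result)),
               collapse = ", ")
  cat(sprintf("<measurement %s: %s%s>\n", x$kind, res,
              if (x$stored) " [stored]" else ""))
  invisible(x)
}
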