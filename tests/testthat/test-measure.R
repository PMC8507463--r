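# Independent oracles: distances/areas have closed forms; ROI means are
# checked against (a) a plain double-loop pixel enumeration and (b)
# mgcv::in.out for polygons — both independent of the vectorized
# implementation path.

circle_mean_oracle <- function(image, meta, center, radius, rescaled = TRUE) {
  vals <- c()
  for (r in 0:(nrow(image) - 1)) {
    for (c in 0:(ncol(image) - 1)) {
      if ((r - center[1])^2 + (c - center[2])^2 < radius^2) {
        vals <- c(vals, image[r + 1, c + 1])
      }
    }
  }
  if (rescaled) vals <- meta$rescale_slope * vals + meta$rescale_intercept
  mean(vals)
}

test_that("distance matches closed forms, including anisotropic spacing", {
  m <- fake_meta(spacing = c(1, 1))
  expect_equal(distance_mm(c(0, 0), c(3, 4), m)$result$distance_mm, 5)
  m2 <- fake_meta(spacing = c(0.5, 0.5))
  expect_equal(distance_mm(c(0, 0), c(3, 4), m2)$result$distance_mm, 2.5)
  m3 <- fake_meta(spacing = c(2, 1))
  expect_equal(distance_mm(c(0, 0), c(3, 4), m3)$result$distance_mm, sqrt(52))
  # endpoints are recorded verbatim for retrospective review
  d <- distance_mm(c(1, 2), c(6, 2), m)
  expect_equal(d$geometry, list(p1 = c(1, 2), p2 = c(6, 2)))
})

test_that("unitless images refuse mm results unless pixels are explicit", {
  m <- fake_meta(spacing = NULL)
  expect_error(distance_mm(c(0, 0), c(3, 4), m), class = "obsdex_units_error")
  d <- distance_mm(c(0, 0), c(3, 4), m, allow_px = TRUE)
  expect_equal(d$result$distance_px, 5)
  img <- matrix(1L, 64, 64)
  expect_error(circle_roi_stats(img, m, c(32, 32), 5),
               class = "obsdex_units_error")
})

test_that("circle ROI: analytic area and affine-invariant constant mean", {
  img <- matrix(7L, 64, 64)
  m <- fake_meta(slope = 2, intercept = -1)
  cr <- circle_roi_stats(img, m, c(31.5, 31.5), 10)
  expect_equal(cr$result$area_mm2, pi * 100)
  expect_equal(cr$result$mean_value, 13)  # affine of a constant image
  raw <- circle_roi_stats(img, m, c(31.5, 31.5), 10, rescaled = FALSE)
  expect_equal(raw$result$mean_value, 7)
  expect_error(circle_roi_stats(img, m, c(10.5, 10.5), 0.2),
               class = "obsdex_measurement_error")  # no center inside
})

test_that("polygon ROI: shoelace areas match hand geometry", {
  img <- matrix(1L, 64, 64)
  m5 <- fake_meta(spacing = c(0.5, 0.5))
  sq <- rbind(c(10, 10), c(10, 30), c(30, 30), c(30, 10))
  expect_equal(polygon_roi_stats(img, m5, sq)$result$area_mm2, 100)
  m1 <- fake_meta()
  tri <- rbind(c(0, 0), c(0, 10), c(10, 0))
  expect_equal(polygon_roi_stats(img, m1, tri)$result$area_mm2, 50)
  bowtie <- rbind(c(0, 0), c(10, 10), c(0, 10), c(10, 0))
  expect_error(polygon_roi_stats(img, m1, bowtie),
               class = "obsdex_measurement_error")
})

test_that("circle mean equals exhaustive pixel-center enumeration", {
  set.seed(501)
  for (i in 1:40) {
    n <- sample(16:96, 1)
    img <- matrix(sample(0:4000, n * n, replace = TRUE), n, n)
    m <- fake_meta(rows = n, cols = n,
                   slope = sample(c(1, 2), 1), intercept = sample(c(0, -100), 1))
    center <- stats::runif(2, 6, n - 7)
    radius <- stats::runif(1, 1.5, 6)
    got <- circle_roi_stats(img, m, center, radius)
    expect_equal(got$result$mean_value,
                 circle_mean_oracle(img, m, center, radius))
  }
})

test_that("polygon mean matches an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(502)
  for (i in 1:40) {
    n <- sample(24:128, 1)
    img <- matrix(sample(0:4000, n * n, replace = TRUE), n, n)
    m <- fake_meta(rows = n, cols = n)
    # random convex polygon (angular sort keeps it simple)
    k <- sample(3:8, 1)
    cx <- stats::runif(2, n / 3, 2 * n / 3)
    ang <- sort(stats::runif(k, 0, 2 * pi))
    rad <- stats::runif(k, 3, n / 3)
    verts <- cbind(cx[1] + rad * cos(ang), cx[2] + rad * sin(ang))
    verts <- pmin(pmax(verts, 0.3), n - 1.3)
    if (!obsdex:::is_simple_polygon(verts)) next  # clamping can break convexity
    got <- try(polygon_roi_stats(img, m, verts), silent = TRUE)
    if (inherits(got, "try-error")) next  # degenerate: no interior centers
    gr <- expand.grid(r = 0:(n - 1), c = 0:(n - 1))
    inside <- mgcv::in.out(rbind(verts, verts[1, ]),
                           cbind(gr$r, gr$c))
    oracle_mean <- mean(img[cbind(gr$r[inside] + 1, gr$c[inside] + 1)])
    expect_equal(got$result$mean_value, oracle_mean)
  }
})

test_that("translation and spacing scale laws hold", {
  set.seed(503)
  img <- matrix(500L, 80, 80)
  m <- fake_meta(rows = 80, cols = 80, spacing = c(0.8, 1.2))
  m2 <- fake_meta(rows = 80, cols = 80, spacing = c(1.6, 2.4))
  verts <- rbind(c(10, 10), c(10, 22), c(25, 28), c(22, 9))
  a <- polygon_roi_stats(img, m, verts)
  shifted <- polygon_roi_stats(img, m, verts + 13)
  expect_equal(shifted$result$area_mm2, a$result$area_mm2)
  expect_equal(shifted$result$mean_value, a$result$mean_value)
  # doubling both spacings quadruples area, doubles distance
  expect_equal(polygon_roi_stats(img, m2, verts)$result$area_mm2,
               4 * a$result$area_mm2)
  expect_equal(distance_mm(c(0, 0), c(3, 4), m2)$result$distance_mm,
               2 * distance_mm(c(0, 0), c(3, 4), m)$result$distance_mm)
})

test_that("geometry outside the image bounds is rejected", {
  m <- fake_meta(rows = 32, cols = 32)
  img <- matrix(1L, 32, 32)
  expect_error(distance_mm(c(0, 0), c(40, 4), m),
               class = "obsdex_measurement_error")
  expect_error(circle_roi_stats(img, m, c(-3, 5), 2),
               class = "obsdex_measurement_error")
})
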