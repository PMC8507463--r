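test_that("generated studies re-scan to their spec, deterministically", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(2, 3, 1, rows = 12, cols = 10,
                       pattern = list(type = "gradient"),
                       pixel_spacing_mm = c(0.6, 0.8), seed = 5)
  res <- make_study(spec, file.path(dir, "a"))
  expect_equal(nrow(res$manifest), 6L)
  db <- scan_image_database(file.path(dir, "a"))
  expect_length(db$cases, 2L)
  expect_equal(db_series_slots(db), 3L)
  inst <- db$cases[[1]]$series[[1]]$instances[[1]]
  meta <- read_image_meta(inst)
  expect_equal(meta$pixel_spacing_mm, c(0.6, 0.8))
  expect_equal(c(meta$rows, meta$cols), c(12L, 10L))

  # identical spec -> byte-identical files
  make_study(spec, file.path(dir, "b"))
  fa <- list.files(file.path(dir, "a"), recursive = TRUE, pattern = "dcm$",
                   full.names = TRUE)
  fb <- list.files(file.path(dir, "b"), recursive = TRUE, pattern = "dcm$",
                   full.names = TRUE)
  expect_equal(length(fa), length(fb))
  for (k in seq_along(fa)) {
    expect_identical(readBin(fa[k], "raw", file.size(fa[k])),
                     readBin(fb[k], "raw", file.size(fb[k])))
  }
})

test_that("noise patterns are seeded and reproducible", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(1, 1, 2, rows = 8, cols = 8,
                       pattern = list(type = "noise", mean = 500, sd = 40),
                       seed = 77)
  make_study(spec, file.path(dir, "n1"))
  make_study(spec, file.path(dir, "n2"))
  p1 <- read_pixels(file.path(dir, "n1", "case001", "s01", "i001.dcm"))
  p2 <- read_pixels(file.path(dir, "n2", "case001", "s01", "i001.dcm"))
  q1 <- read_pixels(file.path(dir, "n1", "case001", "s01", "i002.dcm"))
  expect_identical(p1, p2)
  expect_false(identical(p1, q1))  # instances draw distinct noise
})

test_that("disk fixtures agree with circular ROI measurements", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(1, 1, 1, rows = 32, cols = 32,
                       pattern = list(type = "disk", center = c(15, 15),
                                      radius = 6, fg = 3000, bg = 1000),
                       seed = 1)
  make_study(spec, dir)
  f <- file.path(dir, "case001", "s01", "i001.dcm")
  img <- read_pixels(f)
  meta <- read_image_meta(f)
  # the measurement circle coincides with the drawn disk: pure foreground
  m <- circle_roi_stats(img, meta, c(15, 15), 6)
  expect_equal(m$result$mean_value, 3000)
  expect_equal(m$result$area_mm2, pi * 36)
  # a ring well outside is pure background
  out <- circle_roi_stats(img, meta, c(4, 26), 3)
  expect_equal(out$result$mean_value, 1000)
})

test_that("invalid fixture specs are refused", {
  expect_error(fixture_spec(0, 1), class = "obsdex_spec_error")
  expect_error(fixture_spec(1, 17), class = "obsdex_spec_error")
  expect_error(fixture_spec(1, 1, pattern = list(type = "plasma")),
               class = "obsdex_spec_error")
  expect_error(make_afc_study(2, "1x1", out_dir = tempfile()),
               class = "obsdex_spec_error")  # AFC needs >= 2 alternatives
})

test_that("AFC truth is recoverable through any observer's placement", {
  dir <- withr::local_tempdir()
  st <- make_afc_study(8, "2x2", out_dir = dir, seed = 13)
  truth2 <- read_afc_truth(dir)
  expect_equal(truth2, st$truth)
  db <- scan_image_database(file.path(dir, "images"))
  for (obs in c("r1", "r2")) {
    for (cid in st$truth$case_id) {
      gidx <- afc_signal_canvas(st$cfg, st$truth, obs, cid)
      # the canvas decoded from truth+assignment really shows the disk
      pl <- assign_series_to_canvases(st$cfg, 4L, obs, cid)
      grid <- build_canvas_grid(st$cfg)
      slot <- pl$series_slot[canvas_global_idx(grid, pl$monitor_idx,
                                               pl$canvas_idx) == gidx]
      img <- read_pixels(db_case(db, cid)$series[[slot + 1]]$instances[[1]])
      expect_gt(max(img), 1000)  # disk present
    }
  }
})

test_that("an ideal scripted observer is always right; 2-AFC runs too", {
  dir <- withr::local_tempdir()
  st <- make_afc_study(5, "1x2", out_dir = dir, seed = 3)
  expect_equal(st$n_alternatives, 2L)
  db <- scan_image_database(file.path(dir, "images"))
  run_script(st$cfg, db, dir, "ideal", afc_script(st$cfg, st$truth, db, "ideal"))
  expect_equal(afc_score(dir, "ideal", st$cfg, st$truth), 1.0)
})
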