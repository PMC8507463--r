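test_that("canvas grids enumerate monitor-major, row-major", {
  g <- build_canvas_grid(c("2x2", "1x2"))
  expect_equal(nrow(g$canvases), 6L)
  expect_equal(g$canvases$monitor_idx, c(0L, 0L, 0L, 0L, 1L, 1L))
  expect_equal(g$canvases$canvas_idx, c(0:3, 0:1))
  expect_equal(canvas_global_idx(g, 1, 1), 5L)

  expect_equal(nrow(build_canvas_grid(rep("2x2", 4))$canvases), 16L)
  expect_equal(nrow(build_canvas_grid("1x2")$canvases), 2L)
  expect_equal(nrow(build_canvas_grid("1x1")$canvases), 1L)
})

test_that("canvas capacity never exceeds 16, with equality only at 4x 2x2", {
  set.seed(77)
  for (i in 1:50) {
    layouts <- sample(c("1x1", "1x2", "2x1", "2x2"), sample(1:4, 1),
                      replace = TRUE)
    n <- nrow(build_canvas_grid(layouts)$canvases)
    expect_lte(n, 16L)
    if (n == 16L) expect_equal(layouts, rep("2x2", 4))
  }
})

make_view <- function(layouts = "2x2", n_series = 4, stack_depth = 1) {
  st <- demo_study(n_cases = 1, series_per_case = n_series,
                   stack_depth = stack_depth, layouts = layouts)
  pl <- assign_series_to_canvases(st$cfg, st$db$cases[[1]], "obs")
  list(view = create_case_view(st$cfg, st$db$cases[[1]], pl), st = st)
}

test_that("temporary layout hides series and reverts losslessly", {
  v <- make_view()$view
  before <- list(grid = v$grid, placement = v$placement)
  v$states <- select_canvases(v$states, 2)
  v$states[["2"]]$zoom <- 2.5  # state must survive the round trip

  v1 <- apply_temporary_layout(v, 0, "1x1", keep_slots = 2)
  expect_equal(nrow(v1$grid$canvases), 1L)
  shown <- v1$placement[!v1$placement$hidden, ]
  expect_equal(shown$series_slot, 2L)
  expect_equal(sum(v1$placement$hidden), 3L)

  v2 <- apply_temporary_layout(v, 0, "1x2", keep_slots = c(0, 1))
  shown2 <- v2$placement[!v2$placement$hidden, ]
  expect_equal(shown2$series_slot, c(0L, 1L))
  expect_equal(shown2$canvas_idx, c(0L, 1L))

  r <- revert_temporary_layout(v1)
  expect_equal(r$grid, before$grid)
  expect_equal(r$placement, before$placement)
  expect_equal(r$states[["2"]]$zoom, 2.5)
})

test_that("temporary layout respects the feature flag", {
  made <- make_view()
  v <- made$view
  v$cfg$features$allow_temporary_layout <- FALSE
  expect_error(apply_temporary_layout(v, 0, "1x1"),
               class = "obsdex_permission_error")
})

test_that("display deltas land on exactly the selected canvases", {
  v <- make_view()$view
  w0 <- vapply(v$states, function(s) s$window[["width"]], 0)
  st <- select_canvases(v$states, c(0, 2))
  st <- set_display_property(st, list(window = c(0, 100)),
                             v$cfg$features)
  w1 <- vapply(st, function(s) s$window[["width"]], 0)
  expect_equal(w1 - w0, c("0" = 100, "1" = 0, "2" = 100, "3" = 0))

  st <- select_canvases(st, 1)
  st <- set_display_property(st, list(zoom = 2), v$cfg$features)
  expect_equal(st[["1"]]$zoom, 2)
  expect_equal(st[["0"]]$zoom, 1)
})

test_that("frame property: random selections touch only themselves", {
  v <- make_view()$view
  set.seed(42)
  for (i in 1:25) {
    sel <- sample(0:3, sample(1:4, 1))
    st <- select_canvases(v$states, sel)
    st2 <- set_display_property(st, list(pan = c(3, -2)), v$cfg$features)
    moved <- vapply(st2, function(s) any(s$pan != 0), TRUE)
    expect_equal(unname(moved), 0:3 %in% sel)
  }
})

test_that("prohibited properties raise and leave states unchanged", {
  made <- make_view()
  v <- made$view
  feats <- v$cfg$features
  feats$allow_window_change <- FALSE
  st <- select_canvases(v$states, 0)
  expect_error(set_display_property(st, list(window = c(10, 10)), feats),
               class = "obsdex_permission_error")
  expect_equal(select_canvases(v$states, 0), st)
})

test_that("scrolling is synchronized, clamped, and skips single images", {
  v <- make_view("2x2", n_series = 2, stack_depth = 10)$view
  # make slot 1 a single image for the mixed-selection case
  v$states[["1"]]$n_instances <- 1L
  v$states[["1"]]$is_stack <- FALSE

  st <- select_canvases(v$states, c(0, 1))
  st <- scroll_stacks(st, 5)
  expect_equal(st[["0"]]$stack_index, 5L)
  expect_equal(st[["1"]]$stack_index, 0L)  # single image: no-op

  st <- scroll_stacks(st, 100)
  expect_equal(st[["0"]]$stack_index, 9L)  # clamped to last instance
  st <- scroll_stacks(st, -100)
  expect_equal(st[["0"]]$stack_index, 0L)

  st <- scroll_stacks(st, 9)
  st <- cine_step(st, v$cfg$features)
  expect_equal(st[["0"]]$stack_index, 0L)  # cine wraps around
})

test_that("window mapping matches the linear VOI function", {
  meta <- fake_meta(slope = 1, intercept = 0)
  w <- c(100, 200)
  expect_equal(window_to_display(-1000, meta, w), 0L)    # below the window
  expect_equal(window_to_display(5000, meta, w), 255L)   # above the window
  expect_equal(window_to_display(100, meta, w), 128L)    # centre maps to mid-gray
  expect_equal(window_to_display(0, meta, w), 0L)  # exact lower edge

  # rescale applies first: stored 562 with slope 2, intercept -1024 -> 100
  meta2 <- fake_meta(slope = 2, intercept = -1024)
  expect_equal(window_to_display(562, meta2, w), 128L)

  # monotone non-decreasing in the stored value for positive slope
  v <- seq(-200, 400, by = 7)
  y <- window_to_display(v, meta, w)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y >= 0 & y <= 255))
})
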