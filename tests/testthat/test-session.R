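fresh_session <- function(st, observer = "obs1", mode = "review") {
  start_session(st$cfg, st$db, observer, mode, st$dir)
}

test_that("a fresh review session starts at the first case, empty-handed", {
  st <- demo_study(n_cases = 3)
  sess <- fresh_session(st)
  expect_equal(sess$cursor, 1L)
  expect_false(sess$finished)
  expect_length(sess$responses, 0)
  expect_equal(current_case_id(sess), sess$assignment$case_order[1])
})

test_that("show/edit mode without an existing log is refused", {
  st <- demo_study(n_cases = 2)
  expect_error(fresh_session(st, mode = "show"),
               class = "obsdex_session_error")
})

test_that("submitting walks forward and finishes after the last case", {
  st <- demo_study(n_cases = 2)
  sess <- fresh_session(st)
  sess <- add_answer(sess, "conf", "3")
  sess <- submit_and_advance(sess)
  expect_equal(sess$cursor, 2L)
  sess <- add_answer(sess, "conf", "1")
  sess <- submit_and_advance(sess)
  expect_true(sess$finished)
  expect_error(submit_and_advance(sess), class = "obsdex_session_error")
  lf <- parse_log(readLines(sess$log_path))
  expect_equal(sort(unique(export_table(lf, "answers")$case_id)),
               c("case001", "case002"))
})

test_that("required questions gate submission without advancing", {
  st <- demo_study(n_cases = 2)
  sess <- fresh_session(st)
  err <- tryCatch(submit_and_advance(sess), error = function(e) e)
  expect_s3_class(err, "obsdex_incomplete_error")
  expect_match(conditionMessage(err), "conf")
  expect_equal(sess$cursor, 1L)
  # a mark missing its required linked answer also gates
  sess2 <- add_answer(sess, "conf", "2")
  sess2$cfg$localization_questions$loc_conf$required <- TRUE
  sess2 <- add_mark(sess2, 0, 0, 5, 5)
  expect_error(submit_and_advance(sess2), class = "obsdex_incomplete_error")
})

test_that("review navigation is strictly forward-only", {
  st <- demo_study(n_cases = 3)
  sess <- fresh_session(st)
  sess <- add_answer(sess, "conf", "2")
  sess <- submit_and_advance(sess)
  expect_error(attempt_back(sess), class = "obsdex_navigation_error")
  expect_equal(sess$cursor, 2L)
})

test_that("forward-only holds over randomized review event streams", {
  st <- demo_study(n_cases = 4)
  set.seed(701)
  for (rep in 1:5) {
    dir2 <- withr::local_tempdir()
    file.copy(file.path(st$dir, "images"), dir2, recursive = TRUE)
    st2 <- list(cfg = st$cfg, db = scan_image_database(file.path(dir2, "images")),
                dir = dir2)
    sess <- fresh_session(st2, sprintf("rand%d", rep))
    cursors <- sess$cursor
    for (step in 1:30) {
      if (sess$finished) break
      ev <- sample(c("answer", "mark", "note", "back", "submit"), 1,
                   prob = c(.3, .15, .15, .15, .25))
      sess <- switch(ev,
        answer = add_answer(sess, "conf", sample(1:4, 1)),
        mark = add_mark(sess, 0, sample(0:2, 1), 3, 3,
                        linked = list(loc_conf = sample(1:3, 1))),
        note = set_note(sess, "random walk"),
        back = tryCatch(attempt_back(sess),
                        obsdex_navigation_error = function(e) sess),
        submit = tryCatch(submit_and_advance(sess),
                          obsdex_incomplete_error = function(e) sess)
      )
      cursors <- c(cursors, sess$cursor)
    }
    expect_true(all(diff(cursors) >= 0))
  }
})

test_that("sessions resume from the log at the first incomplete case", {
  st <- demo_study(n_cases = 4)
  sess <- fresh_session(st)
  for (i in 1:2) {
    sess <- add_answer(sess, "conf", "4")
    sess <- set_note(sess, sprintf("note %d", i))
    sess <- submit_and_advance(sess)
  }
  resumed <- fresh_session(st)  # same observer, same study dir
  expect_equal(resumed$cursor, 3L)
  expect_equal(resumed$completed, sess$completed)
  expect_equal(resumed$responses, sess$responses)
})

test_that("log replay reconstructs the in-memory state after every event", {
  st <- demo_study(n_cases = 3, series_per_case = 2)
  sess <- fresh_session(st)
  check <- function(sess) {
    re <- rebuild_session(st$cfg, st$db, "obs1", "review", st$dir)
    expect_equal(re$responses, sess$responses)
    expect_equal(re$completed, sess$completed)
    expect_equal(re$cursor, sess$cursor)
    expect_equal(re$finished, sess$finished)
  }
  check(sess)
  sess <- add_answer(sess, "conf", "1")
  sess <- add_mark(sess, 0, 1, 7.5, 9, linked = list(loc_conf = "2"))
  sess <- set_note(sess, "suspicious density | upper lobe")
  img <- read_pixels(st$db$cases[[1]]$series[[1]]$instances[[1]])
  meta <- read_image_meta(st$db$cases[[1]]$series[[1]]$instances[[1]])
  sess <- store_measurement(sess, distance_mm(c(0, 0), c(3, 4), meta,
                                              canvas = c(0, 0)))
  sess <- submit_and_advance(sess); check(sess)
  sess <- add_answer(sess, "conf", "2")
  sess <- store_measurement(sess, circle_roi_stats(img, meta, c(10, 10), 3,
                                                   canvas = c(0, 0)))
  sess <- submit_and_advance(sess); check(sess)
  sess <- add_answer(sess, "conf", "3")
  sess <- submit_and_advance(sess); check(sess)
  expect_true(sess$finished)
})

test_that("marks validate bounds and are mutable until submission", {
  st <- demo_study(n_cases = 2, rows = 16, cols = 16)
  sess <- fresh_session(st)
  expect_error(add_mark(sess, 0, 0, 99, 3),
               class = "obsdex_measurement_error")
  sess <- add_mark(sess, 0, 0, 3, 3)
  sess <- add_mark(sess, 0, 1, 5, 5)
  sess <- remove_mark(sess, 1)
  sess <- add_answer(sess, "conf", "1")
  sess <- submit_and_advance(sess)
  marks <- export_table(parse_log(readLines(sess$log_path)), "marks")
  expect_equal(nrow(marks), 1L)
  expect_equal(marks$row, 5)
})

test_that("show mode is read-only; edit mode appends edit records", {
  st <- demo_study(n_cases = 2)
  sess <- fresh_session(st)
  for (i in 1:2) {
    sess <- add_answer(sess, "conf", "1")
    sess <- submit_and_advance(sess)
  }
  show <- fresh_session(st, mode = "show")
  expect_error(store_measurement(show, distance_mm(c(0, 0), c(1, 1),
                                                   fake_meta())),
               class = "obsdex_permission_error")
  expect_error(add_mark(show, 0, 0, 1, 1), class = "obsdex_permission_error")
  show <- attempt_back(goto_case(show, "case002"))
  expect_equal(show$cursor, 1L)

  ed <- fresh_session(st, mode = "edit")
  ed <- edit_answer(ed, "case001", "conf", "4")
  expect_equal(ed$responses[["case001"]]$answers$conf, "4")
  lf <- parse_log(readLines(ed$log_path))
  edits <- export_table(lf, "edit")
  expect_equal(nrow(edits), 1L)
  # replay applies the edit on top of the original answer
  re <- fresh_session(st, mode = "show")
  expect_equal(re$responses[["case001"]]$answers$conf, "4")
  # edit mode never touches order or placements
  expect_equal(ed$assignment, sess$assignment)
})

test_that("a log from a different configuration is refused on resume", {
  st <- demo_study(n_cases = 2)
  sess <- fresh_session(st)
  cfg2 <- st$cfg
  cfg2$study_name <- "tampered"
  expect_error(start_session(cfg2, st$db, "obs1", "review", st$dir),
               class = "obsdex_session_error")
})
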