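# Fixtures are generated in code at test time; nothing binary ships.

# property-file text for a small localization study
demo_properties <- function(n_monitors = 1L, layouts = "2x2",
                            placement = "fixed", seed = 42L,
                            extra = character(0)) {
  c(
    "# synthetic demo study",
    "study_name = demo",
    "image_root = images",
    sprintf("n_monitors = %d", n_monitors),
    sprintf("monitor_layouts = %s", paste(layouts, collapse = ", ")),
    sprintf("series_placement = %s", placement),
    sprintf("master_seed = %d", seed),
    "question.conf.prompt = Confidence a lesion is present",
    "question.conf.kind = scale",
    "question.conf.allowed = 1,2,3,4",
    "question.conf.required = true",
    "question.loc_conf.prompt = Confidence in this localization",
    "question.loc_conf.kind = scale",
    "question.loc_conf.allowed = 1,2,3",
    "question.loc_conf.linked_to_mark = true",
    extra
  )
}

# a ready study on disk: images + property file; returns cfg, db, dir
demo_study <- function(n_cases = 3L, series_per_case = 3L,
                       stack_depth = 1L, layouts = "2x2",
                       placement = "fixed", seed = 42L,
                       rows = 24L, cols = 24L,
                       pattern = list(type = "gradient")) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  spec <- fixture_spec(n_cases, series_per_case, stack_depth,
                       rows = rows, cols = cols, pattern = pattern,
                       seed = seed)
  make_study(spec, file.path(dir, "images"))
  props <- demo_properties(length(layouts), layouts, placement, seed)
  writeLines(props, file.path(dir, "study.properties"))
  cfg <- parse_study_properties(file.path(dir, "study.properties"))
  db <- scan_image_database(file.path(dir, "images"))
  list(cfg = cfg, db = db, dir = dir)
}

# image_meta without touching disk
fake_meta <- function(rows = 64L, cols = 64L, spacing = c(1, 1),
                      slope = 1, intercept = 0, window = NULL) {
  structure(list(
    rows = rows, cols = cols,
    pixel_spacing_mm = spacing,
    unitless = is.null(spacing),
    rescale_slope = slope, rescale_intercept = intercept,
    default_window = window
  ), class = "image_meta")
}

# adversarial free text for round-trip fuzzing
random_nasty_text <- function(n = 1L) {
  pool <- c(letters, LETTERS, 0:9, "\t", "|", "\\", "\n", " ", "=",
            "#", ",", ".", "-", "å", "ö")
  vapply(seq_len(n), function(i) {
    paste(sample(pool, sample(0:24, 1), replace = TRUE), collapse = "")
  }, "")
}

random_record <- function() {
  kind <- sample(c("case_answer", "note", "event", "measurement"), 1)
  payload <- switch(kind,
    case_answer = log_escape(random_nasty_text(2)),
    note = log_escape(random_nasty_text(1)),
    event = log_escape(random_nasty_text(2)),
    measurement = c(log_escape("distance"), log_subfields(0, 1), "0",
                    log_subfields(stats::runif(4, 0, 9)),
                    log_subfields(stats::runif(1)))
  )
  log_record(kind, observer_id = random_nasty_text(1),
             case_id = random_nasty_text(1),
             series_slot = sample(c(NA, 0:15), 1), payload = payload)
}
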