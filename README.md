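# obsdex

A headless, scriptable R engine for **medical-image observer-performance
studies** — the ROC / FROC / alternative-forced-choice (AFC) experiments in
which radiologists rate, localize or choose among DICOM images so that
imaging protocols can be compared at matched diagnostic performance.

Study administration software in this field has to do a few very specific
things correctly, and `obsdex` implements them as a library plus CLI so they
can be tested and automated rather than clicked through:

- **Folder-based DICOM case database.** A study is a folder tree
  `root/<case>/<series>/<instances>`; each case holds up to 16 series
  (single images or stacks), ordered deterministically (lexicographic
  folders, instances by `InstanceNumber`).
- **Multi-monitor, multi-canvas display model.** Up to 4 monitors, each
  laid out `1x1`, `1x2`, `2x1` or `2x2` — at most 16 simultaneous
  images/stacks per case. Per-canvas window/zoom/pan/scroll state,
  multi-select propagation, temporary layout changes, and the DICOM linear
  VOI mapping (modality rescale `slope·v + intercept` applied first).
- **Deterministic per-observer randomization.** Case order is a unique
  uniform permutation per observer; series-to-canvas placement can be
  randomized per case and observer, which is what makes *M*-AFC designs
  possible without pre-arranging image sets. Every draw is a pure function
  of `(master_seed, observer_id[, case_id])`.
- **Physical measurements.** Distance in mm with recorded endpoints,
  `sqrt((Δrow·row_mm)² + (Δcol·col_mm)²)`; circular ROI area
  `π r² · row_mm · col_mm` and freeform ROI area `|shoelace| · row_mm ·
  col_mm`, both with the mean pixel value over enclosed pixel centers.
  Images without `PixelSpacing` refuse mm results instead of mislabeling
  pixels.
- **Forward-only sessions.** In review mode observers can never return to
  a previous case (a guard against threshold drift and fatigue biases);
  the study owner has free navigation in show (read-only) and edit modes.
- **Two-delimiter study log.** Append-only text, multiple lines per case,
  exactly two delimiter characters (TAB between fields, `|` between
  subfields), backslash-escaped free text, lossless `parse(write(x)) = x`,
  and tidy CSV export per record kind.
- **Synthetic DICOM generator.** Deterministic Part-10 fixtures (constant /
  gradient / disk / noise patterns) and complete ready-to-run AFC studies
  with ground-truth tables, so everything above runs with zero external
  data.

## Worked example: a 4-AFC study end to end

```r
library(obsdex)

td <- file.path(tempdir(), "readme_demo")
st <- make_afc_study(n_cases = 50, monitor_layouts = "2x2",
                     out_dir = td, seed = 42)
db <- scan_image_database(file.path(td, "images"))
db
#> Case database at '.../readme_demo/images': 50 case(s), 4 series slot(s)
validate_config(st$cfg, db)
#> Study validation: OK

# scripted observers: one reads the ground truth, one guesses
run_script(st$cfg, db, td, "reader_A",
           afc_script(st$cfg, st$truth, db, "reader_A", "ideal"))
run_script(st$cfg, db, td, "reader_B",
           afc_script(st$cfg, st$truth, db, "reader_B", "random", guess_seed = 7))
afc_score(td, "reader_A", st$cfg, st$truth)
#> [1] 1
afc_score(td, "reader_B", st$cfg, st$truth)
#> [1] 0.16

lf <- parse_log(readLines(file.path(td, "reader_A.log")))
export_table(lf, "answers")
#> # A tibble: 50 × 5
#>   observer_id case_id series_slot question_id   value
#>   <chr>       <chr>         <int> <chr>         <chr>
#> 1 reader_A    case032          NA signal_canvas 2
#> 2 reader_A    case035          NA signal_canvas 3
#> 3 reader_A    case042          NA signal_canvas 0
#> # ℹ 47 more rows
```

Each of the 50 cases holds 4 series, exactly one carrying a disk signal;
placement is randomized per case and observer, so `reader_A`'s perfect
proportion correct (1.0) demonstrates that the ground truth is recoverable
through the randomized assignment, while `reader_B`'s 0.16 is what a
uniform guesser earns on 50 four-alternative cases. The answers table shows
the observer-specific case order (case032 first for this seed) ready for
downstream ROC/AFC analysis in any statistics package.

The same study runs from a shell:

```sh
inst/cli/obsdex validate   $STUDY_DIR
inst/cli/obsdex run        $STUDY_DIR reader_A --script responses.txt
inst/cli/obsdex export     $STUDY_DIR reader_A --kind answers --out answers.csv
```

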