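---
title: "The obsdex observer-study engine: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The obsdex observer-study engine: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obsdex)
```

## What the engine models

Observer-performance studies present human readers with medical images
under controlled conditions and record their responses — ratings (ROC),
localized findings (FROC), or a forced choice among *M* simultaneously
displayed alternatives (*M*-AFC). `obsdex` is the administrative machinery
of such a study, headless: everything a study viewer does *except* draw
pixels on a monitor and capture mouse events. The state it manages —
configuration, case database, per-observer assignments, display state,
measurements, session progress, and the response log — is exactly the state
whose correctness determines whether a study's data can be trusted, so each
piece is an ordinary testable function.

A study is fully determined by a plain-text property file plus an image
folder. That single-source-of-truth design has a corollary the engine
enforces: logs and assignment sidecars embed a digest of the configuration,
and a session refuses to resume against a silently edited study.

## The display model

Monitors (1–4) are each divided into 1, 2 or 4 canvases (`1x1`, `1x2`,
`2x1`, `2x2`), giving at most $4 \times 4 = 16$ simultaneous series per
case. Canvases are enumerated **monitor-major, row-major within a
monitor**, 0-based. The within-monitor order is a convention this engine
fixes (nothing in the domain dictates it); all placements, logs and
scripts share it.

Each visible series carries an independent display state: window
$(c, w)$, zoom, pan, stack position, and a selection flag. Operations on
the selection (window deltas, zoom factors, pan, synchronized scrolling)
touch exactly the selected set — the "frame" property tested over random
selections. Feature flags from the property file gate each operation, so a
study can prohibit window or zoom changes when fixed viewing conditions
are part of the design; a prohibited operation raises a permission error
and provably leaves the state untouched.

Temporary layout changes (e.g. promoting one stack to full-screen `1x1`)
hide displaced series rather than deleting them; the default layout is
restored by `revert_temporary_layout()` with all display state intact, and
the change never leaks into the assignment or log — it is a transient of
the viewing session, not of the study design.

### Gray-scale mapping

Stored values map to display values through the modality rescale first
($x = \text{slope}\cdot v + \text{intercept}$ — applied at this single
point for all downstream consumers), then the DICOM-style linear VOI
function with window center $c$ and width $w$:

$$y = \left(\frac{x - (c - 0.5)}{w - 1} + 0.5\right)\cdot 255,$$

clamped to $[0, 255]$ and rounded half-up. For $w \le 1$ the mapping
degenerates to a threshold at $c - 0.5$. The mapping is monotone
non-decreasing in the stored value for positive slope (a property test
sweeps the input range). The specific transfer function is a design
choice: the domain names "window settings" but no formula, and the PS3.3
linear form is the interoperable default.

## Randomization

Two draws matter scientifically: the per-observer case order, and the
per-case, per-observer assignment of series slots to canvases (the AFC
enabler — with randomized placement, signal-present and signal-absent
series land on different canvases for every observer without any manual
image arrangement).

Both are pure functions of study coordinates. A 32-bit FNV-1a hash of
`(master_seed, stream-label, observer_id[, case_id])` seeds R's Mersenne
Twister; the global RNG state is saved and restored around every draw.
Consequences the tests pin down:

- identical inputs reproduce identical orders and placements (logs are
  reproducible across releases, given the documented generator);
- adding or re-running an observer never perturbs another observer's
  draws (independent streams, not a shared sequence);
- orders are uniform over permutations and placements uniform over
  canvases — checked by chi-square at $n = 3$ cases × 10 000 observers
  (6 permutation cells) and 1 series × 4 canvases × 4 000 draws, with the
  pass threshold $p > 0.001$ chosen to keep the false-alarm rate of the
  suite negligible while still detecting gross non-uniformity.

The injective placement is drawn by shuffling the canvas list and taking a
prefix, which is uniform over injective maps by symmetry of the shuffle.
Unmapped canvases are displayed empty (black): three series on a single
`2x2` monitor leave exactly one blank canvas. Counterbalanced designs
(Latin squares) are deliberately out of scope — the model here is uniform
randomization only.

## Physical measurements

Coordinates are 0-based `(row, col)` with the origin at the top-left
*pixel center*; pixel centers sit at integer coordinates. Measurements
convert to physical units through `PixelSpacing` (mm per pixel along row
and column, possibly anisotropic):

- **distance**: $\sqrt{(\Delta r \cdot s_r)^2 + (\Delta c \cdot s_c)^2}$
  mm, endpoints recorded verbatim so the line can be re-examined in show
  mode;
- **circular ROI**: area $\pi r^2 s_r s_c$ (analytic), mean over pixel
  centers *strictly inside* the circle;
- **freeform ROI**: area $|\text{shoelace}| \cdot s_r s_c$ (analytic),
  mean over pixel centers inside by the even–odd rule with boundary
  centers excluded; self-intersecting polygons are rejected (pairwise
  proper-intersection test on non-adjacent edges).

Area geometric, mean pixel-sampled is the clinical-viewer convention; the
strict-inequality pixel-center rule was chosen because it is unambiguous
and oracle-checkable — the suite compares every ROI mean against an
exhaustive per-pixel enumeration (plain double loop) and, for polygons,
against `mgcv::in.out` as an independent second implementation, on random
instances up to 128×128. The mean uses rescaled (modality) values by
default, since a raw stored-value mean is rarely diagnostically
meaningful; `rescaled = FALSE` exposes the raw mean for the cases where
the raw scale is wanted. Images without `PixelSpacing` are flagged
unitless and *refuse* mm/mm² results; pixel-unit distances must be
requested explicitly (`allow_px = TRUE`) so units can never be silently
mislabeled. The area unit is mm² throughout.

## Sessions and the log

A review session is forward-only: the cursor over the observer's case
order never decreases, submission is gated on every required question
(case-level, and mark-linked per localization mark), and a submitted case
block — answers, marks with linked answers, stored measurements, note,
completion event — is appended to the log in a single write. Crash
recovery is log replay: `start_session()` rebuilds responses from the log
and resumes at the first incomplete case, and the suite asserts replayed
state equals in-memory state after every event. Show mode is read-only;
edit mode appends *edit records* rather than rewriting — the log is
append-only by contract (earlier bytes are never touched), which yields
both an audit trail and well-defined replay semantics (edits supersede on
replay, originals remain inspectable). A case counts as completed when
submitted, not when displayed.

The log uses exactly two delimiter characters: TAB between fields and `|`
between subfields of one field (a coordinate pair, a question–value
pair). TAB was chosen because it pastes directly into spreadsheet columns;
`|` keeps composite values inside one column. The count is the domain
constraint; the particular characters and field orders are this engine's
own grammar. Free text is backslash-escaped (`\\`, `\t`, `\p`, `\n`,
`\r`), making `parse_log(write_log(x))` the identity — fuzz-tested over
randomized record sets whose text includes raw TABs, pipes, backslashes
and newlines. A literal case id `"-"` is escaped so it cannot collide with
the placeholder for "no case". `export_table()` flattens any record kind
to a stable-column tibble for CSV/statistics import; timestamps appear
only in event records and are masked (not deleted) for determinism
comparisons.

## The synthetic-data generator

`fixture_spec()`/`make_study()` emit DICOM Part-10 files — explicit VR
little endian, single-frame, 16-bit unsigned MONOCHROME2 — the one
transfer syntax the engine's reader accepts, written by the package's own
minimal codec and cross-checked in the suite against an independent DICOM
implementation (pydicom) where available. Pixel patterns are analytic
(constant, gradient, disk with known center/radius/foreground) or seeded
Gaussian noise; UIDs and pixel data are pure functions of the spec seed,
so regeneration is byte-identical. `make_afc_study()` produces a complete
runnable study: one disk-bearing series per case among $M$ otherwise
identical series, a truth table, and a property file with randomized
placement.

What the fixtures emulate is the *structure* of real studies (folder
hierarchy, stacks, spacing/rescale/window tags, signal-present vs
signal-absent alternatives). What they do not emulate: anatomy, realistic
noise texture and correlations, compressed transfer syntaxes, color or
multi-frame objects, or human observers. Passing tests therefore
demonstrate the engine's bookkeeping — ordering, randomization,
measurement arithmetic, log fidelity — not detectability or reading
behavior on clinical images; the ideal observer reads the truth table, so
its proportion correct of 1.0 validates the truth-through-placement
decoding, and the uniform guesser's ≈ $1/M$ validates scoring, nothing
more. Default AFC fixture conditions: 16×16 px images, 1×1 mm spacing,
disk radius 4 px, foreground 3000 against background 1000 — small enough
to generate thousands of cases quickly, structured enough that every
pipeline stage is exercised.

## Numerical and scale choices

- Problem sizes in the suite and acceptance script: 1000 randomized
  record sets for log round-trip; 10 000 observers × 3 cases and 4 000
  placement draws for the chi-square checks; 200 random ROI instances at
  up to 128×128; a 1000-case 4-AFC study for end-to-end scoring (the
  guesser is checked against the binomial 99% interval around 0.25 at
  $n = 1000$). These sizes make the statistical checks sharp while the
  whole suite runs in about a minute.
- Instance ordering ties (equal `InstanceNumber`) break by filename;
  missing `InstanceNumber` sorts last.
- Scrolling clamps per canvas independently to `[0, n-1]`; cine is a pure
  iterator — scroll(+1) with wraparound, no timing.
- Seeds derived from the master seed stay below $2^{31}$ (R's integer
  seeds); hash collisions between observer streams are possible in
  principle at the $2^{-32}$ scale and harmless (two observers would
  share an order, not corrupt one).

## Known limitations

- No GUI, no DICOM networking (PACS), no server/multi-site operation —
  the engine administers a local study folder, by design.
- The DICOM codec reads exactly the profile the generator writes; clinical
  archives with other transfer syntaxes must be converted before use.
  Unsupported syntaxes fail loudly rather than misread.
- Statistical analysis of the exported data (ROC/FROC curve fitting,
  AFC significance testing) is downstream work for dedicated tools; the
  engine's deliverable is tidy, lossless data.
- Edit mode covers answers, notes and marks; placements and case order
  are immutable after assignment, which is a guarantee, not a gap.
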