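---
title: "Beamlet sequence QA: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beamlet sequence QA: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beamletqa)
```

## The delivery model

`beamletqa` analyses logs from a ring-gantry linac with a binary
multi-leaf collimator. The machine model behind every computation is:

- the gantry rotates continuously at `gantry_rpm` (default 60 RPM) and the
  beam can only fire at `fp_per_rotation` evenly spaced angles per
  rotation (default 50, i.e. 7.2° sectors and 50 aperture updates per
  second at 60 RPM);
- the couch is stationary while the beam is on and advances by
  `couch_step_mm` (default 2.1 mm) between segments, in one direction only
  (one-pass plans); firing events are therefore grouped into independent
  *couch segments*;
- each MLC leaf is binary — fully open or fully closed at each firing
  position — so an aperture is a 64-bit mask;
- every beam-on firing position delivers the same MU quantum,
  `nominal_dose_rate / (gantry_rpm × fp_per_rotation)` = 1/3 MU by
  default. This constant is machine-level, not plan-level: plan MU totals
  are multiples of it, and delivered MU is the constant times the number
  of positions actually pulsed.

Angles are stored in degrees on an IEC-style convention (0° at the
vertical top, increasing in the rotation direction); couch positions in
mm. The zero reference of the gantry is a convention, not a measurement:
each rotation's start angle is stored explicitly in the event stream (the
synthetic generator uses 0° throughout), and validation only checks
*consistency* of each rotation with its own start angle, never an absolute
reference.

## The BLSQ dialect

Vendor log encodings are proprietary, so the toolkit defines an open,
human-diffable CSV dialect (BLSQ v1): a `#BLSQ v1` magic line, `#key=value`
headers (patient, fraction — 0 means plan —, plan MU, machine constants),
one column-header line, then one CSV row per firing event with the leaf
mask as a 64-character `0/1` string, leaf 0 first. Files are UTF-8 with
`\n` line endings; couch and gantry values are written with 3 decimals and
MU with 6 decimals, which round-trips all quantities to well inside the
validation tolerances (the MU constant 1/3 re-reads within 3.4e-7 MU).

Zero-MU firing positions are *representable and retained* in files: the
leaves still move through them and they occupy real delivery time, so the
reader keeps them and the analysis layer discards them. This keeps the
discard rule in one place (event indexing) instead of burying it in I/O.

`validate_sequence` reports rather than throws: couch monotonicity, couch
and gantry grid alignment (defaults 0.1 mm and 0.5°, generous against
log-file rounding yet far below one couch step / one 7.2° sector), MU
quantisation to within 1e-6 MU of 0 or the machine constant, mask shape,
and duplicate `(couch, rotation, firing)` keys are errors; zero-MU events
are informational warnings.

## Plan-vs-delivery comparison

Matching is by exact integer key `(couch_index, rotation_index,
firing_index)` over nonzero-MU events only. The machine fires on fixed
grids, and validation has already checked grid alignment, so integer
matching is unambiguous; no floating-point tolerance on couch or angle
enters the comparison. From the matched index:

- **skipped firing position** — nonzero-MU plan event absent from the
  delivery (the machine's designed mitigation for transient faults; skips
  alone are expected behaviour and the CLI exits 0 on them);
- **misfire** — delivered nonzero-MU event that is unplanned, carries a
  different leaf mask than planned (a matched-but-different event is a
  misfire, never a skip), or deviates from the MU constant by more than
  1e-6 MU. Any misfire is anomalous, so the CLI flags it with exit
  status 3.

MU reconciliation is pure counting: plan MU = (nonzero plan events) ×
constant, delivered MU = (matched events) × constant. Two identities
follow and are enforced to 1e-9 relative tolerance in the tests:
`mu_reduction = n_skipped × constant`, and percent MU reduction = percent
skipped. They are the mechanism behind the R² = 1.000 cohort fit below.

## Leaf-modulation metrics

Between consecutive events *within one couch segment*, the number of leaf
transitions is the Hamming distance of the two masks. Intervals crossing a
couch shift are excluded — the beam is off and the dwell time there is not
part of the 50 Hz stream. Zero-MU events contribute their masks and their
dwell time (the leaves move regardless of whether the pulse fires) but are
excluded from the open-count aggregation matrices.

The **average transition rate** is total transitions divided by beam-on
time (event count over the firing frequency). The **maximum transition
rate** needs a window choice, because an instantaneous per-interval figure
scaled to 50 Hz can only be a multiple of 50 leaves/s — too coarse to be
the quantity clinical reports quote. The default is a sliding one-second
window (`window_intervals = fp_per_rotation` = 50 intervals, one full
rotation at 60 RPM): the maximum over windows of summed transitions per
window duration. `window_intervals = 1` recovers the instantaneous
variant; the maximum is non-increasing in window length. A segment shorter
than the window contributes one whole-segment window. This default is a
declared choice, not something inferable from delivery logs alone.

Aggregation produces three integer matrices — leaf × couch, leaf × gantry
(binned by firing index, 50 bins, so plan-minus-delivery differences are
bin-exact), couch × gantry — counting leaf-open and beam-on events over
nonzero-MU events. For a skip-only delivery the difference maps are
non-negative and the couch × gantry difference sums exactly to the skip
count; their conservation identities (leaf × couch and leaf × gantry sums
equal) are property-tested.

## Cohort statistics

Per-fraction summaries copy the MU report; per-patient summaries use the
sample standard deviation (n−1 denominator; with a single fraction the SD
is reported as 0 and `n_fractions = 1` flags the degeneracy). The
per-patient percent skipped is the mean of per-fraction percentages (mean
of ratios), which is also the primary cohort-level aggregation. Display
rounding — percentages to 2 decimals, MU and rates and count means to 1 —
lives in the print/format methods only; stored values are unrounded.

Cohort fits are ordinary least squares via `stats::lm` (the independent
closed-form normal-equations check lives in the test suite): mean skipped
vs total planned positions, and mean MU reduction vs mean skipped. The
latter has slope equal to the machine MU constant, intercept 0, and
R² = 1 to 1e-9 whenever one machine constant governs the cohort — the
package treats deviation from that as a data-integrity signal, not a
statistical finding. The Pearson correlation between percent skipped and
the plan's average transition rate is reported descriptively; no
hypothesis tests or intervals are attached, as the summaries are
descriptive QA quantities.

## The synthetic cohort generator

Real logs are proprietary, so `synth_config`/`generate_cohort` emulate the
mechanics end to end and return the injected faults as ground truth. The
defaults describe the clinical regime the toolkit targets:

- target lengths 43–200 mm plus 3 couch margin steps on each side, giving
  27–102 couch segments;
- 5–9 complete gantry rotations per couch segment (partial rotations are
  not modelled), so plans carry roughly 7,000–35,000 firing events;
- 30% zero-MU firing positions, reflecting that beam-on time in clinical
  plans comfortably exceeds the time accounted for by beam-on pulses
  alone;
- 5–33 fractions per patient;
- skip probability 0.0019 per beam-on position — calibrated so a
  ~16,000-position plan skips about 30 positions per fraction, a ≈0.19%
  rate — and misfire probability 0.

The skip model is independent Bernoulli per firing position. Transient
hardware faults are short-lived and, empirically, skipping shows no strong
association with how aggressively the plan modulates, which supports a
modulation-independent, memoryless model; burst or correlated fault models
are out of scope. Misfires, when enabled, flip one uniformly chosen leaf
of a retained event. All randomness derives from the master seed through
per-patient/per-fraction multiplicative-congruential substreams (kept
below 2^31), so any single plan or fraction is reproducible in isolation.

Aperture models generate one contiguous open run per event:
`random-contiguous` (default) draws the run width from
`open_fraction_range` (default 10–60% of leaves) and a uniform position
independently per event; `sweep` drifts a fixed-width run one leaf per
firing position; `static` freezes it. None of these emulates a dose
optimiser. In particular, independent per-event draws produce far heavier
leaf modulation (average transition rates above 1,000 leaves/s) than
clinically optimised plans (tens of leaves/s), and the zero-MU positions
are placed independently rather than in the spatially structured patterns
an optimiser produces. Passing tests therefore demonstrate the
*bookkeeping* — detection, reconciliation, conservation, proportionality —
on sequences that obey the machine's mechanics, not that the simulator
reproduces clinical aperture statistics.

## Numerical and degenerate-input choices

- MU equality tolerance 1e-6 MU everywhere (quantisation check, misfire
  MU anomaly); file precision is chosen to stay inside it.
- Sequences with fewer than two events per segment yield empty transition
  profiles with rates 0, not errors.
- An empty plan (no beam-on events) is a usage error for MU
  reconciliation; an empty delivery is legal (everything skipped).
- `linear_fit` refuses fewer than 2 points or constant x; with constant y
  the fit is exact and R² is reported as 1.
- Non-monotonic (couch-reversing) sequences are rejected by validation;
  multi-pass deliveries are out of scope, and the integer match key would
  be ambiguous for them by design.

## Problem sizes in the shipped checks

The test suite exercises the pipeline on compact sequences (targets of
10–40 mm, 1–2 rotations per segment) across many seeds, which covers the
combinatorics while keeping the default run fast; the acceptance script
uses full-scale plans (about 9,000–22,000 beam-on positions, ten patients,
5–20 fractions) since the cohort-level fit is the quantity of interest
there. Scale does not affect any of the exact identities — they hold per
event — and the stochastic checks (binomial skip-rate recovery at ≥1e5
pooled events) state their own tolerances in standard errors.

## Known limitations

- The BLSQ dialect is this package's own; reading a vendor's binary log
  requires an external converter.
- Dose is out of scope: skipped positions are counted and reconciled in
  MU, not propagated to dose distributions.
- Interlock behaviour (persistent faults) is not modelled; the simulator
  only emulates transient, independent skips.
- Synthetic apertures are mechanically valid but not dosimetrically
  optimised (see above), so modulation metrics on simulated cohorts sit
  well above clinical ranges.
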