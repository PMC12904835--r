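---
title: "fragtrace: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fragtrace: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragtrace)
```

This vignette explains the model behind `fragtrace`, the assumptions each
step makes, the parameters that matter and why their defaults are what they
are, and the design decisions taken where reasonable alternatives existed.

## The measurement model

Gel electrophoresis separates DNA fragments by size: migration distance is,
over the useful range of an agarose or capillary assay, approximately linear
in the logarithm of fragment length. `fragtrace` therefore models the
position-to-size map as piecewise linear in log10(bp), anchored at the
detected peaks of a co-run size standard ("ladder"). Between consecutive
ladder knots the map is interpolated; beyond the outermost knots it is
extended with the nearest segment's slope and the affected positions are
flagged as extrapolated, so downstream quantification never silently relies
on them. Interpolation is exact at every knot by construction. A
linear-in-bp mode is available (`scale = "linear"` in `calibrate()`) for
instruments with near-linear migration; log10 is the default because it
matches the physics and, on our simulated traces, the ladder-knot recovery
is exact either way.

Ladder peaks are local maxima ranked by topographic prominence — the height
of a peak above the higher of the two saddles separating it from higher
terrain. Prominence is the natural criterion here because ladder bands ride
on a smooth background: absolute height would be confounded by baseline
drift, while prominence is invariant to it. The `expected_n` most prominent
maxima (with a minimum mutual separation) are matched 1:1, in migration
order, to the annotation entries. A count mismatch is a hard error that
states both counts and asks for a corrected annotation file: guessing a
partial matching would silently mis-size every sample on the gel.

The annotation file's entry order encodes the migration direction, so images
or tables may run small-to-large or large-to-small; nothing in the pipeline
assumes an orientation.

## Normalization and background

Loaded DNA concentration varies by orders of magnitude between samples, so
intensities are min–max scaled per sample to [0, 1] over the
marker-excluded, non-extrapolated range. This makes every downstream
quantity invariant to positive affine transforms `a*x + b` of the raw trace
(concentration independence) and is idempotent. A constant trace cannot be
scaled meaningfully; it maps to all zeros with a warning. Normalization can
be disabled to pass raw intensities through, e.g. when absolute comparisons
across lanes of one gel are wanted.

Background is corrected with a single sample-wide baseline — the minimum
in-range intensity — rather than a position-dependent one. Automated
electrophoresis devices produce flat backgrounds free of the lane-specific
contrast gradients of hand-poured gels, and a single offset keeps fractions
invariant to any constant shift of the raw trace. Traces from photographed
gels with strong illumination gradients are outside this assumption.

Marker (alignment) bands are spiked-in fragments, not sample DNA; each
marker size `m` contributes an exclusion window `[0.9 m, 1.1 m]`. The
relative width tracks the way band width scales with size on a log axis; it
is configurable (`marker_window_frac`) and markers can be kept with
`include_markers = TRUE`.

## Quantification

**Nucleosomal fractions.** Bins are inclusive integer bp ranges. The first
bin spans `min_bp` to `2 * min_bp` — with the default 100 bp floor this is
the canonical mononucleosomal window 100–200 bp — and subsequent bins have
width `step_bp` (default 200 bp: 201–400 dinucleosomal, 401–600, 601–800,
…). Fragments below 100 bp are excluded by default because primer/adapter
artifacts and degraded material accumulate there. Custom bins
(`parse_bins("50-700")`) may override the floor.

A position with size `s` belongs to bin `(low, high)` iff
`low <= round(s) <= high`. On a continuum this rounding rule is equivalent
to intersecting with `[low - 0.5, high + 0.5]`, and that is how the sum is
computed: each position owns the bp *cell* between the midpoints to its
neighbours (end cells mirrored outward by half a spacing), and a bin
collects the intensity-weighted overlap of every cell with its interval.
This cell-overlap integration has two properties a naive grid sum lacks:
fractions are stable under resampling of the same trace at different
position densities (boundary cells are split between adjacent bins instead
of jumping), and on a unit-spaced grid it reduces exactly to the plain sum.
The denominator is the union of all bins, so bins that tile the analysis
range sum to exactly 1.

**Peaks.** Sample peaks reuse the prominence/separation machinery of ladder
detection (prominence ≥ 5% of the in-range dynamic range, separation ≥ 2%
of the trace length — both exposed as arguments), after a light Gaussian
smoothing (sigma = 1% of the trace length, `smooth_sd = 0` to disable).
Smoothing is what keeps one broad dinucleosomal band from being split into
several numbered peaks by instrument noise; without it, 0-based peak
numbering — and therefore every "peak *n*" group comparison — becomes
meaningless on noisy traces. Each apex is then refined by fitting a
parabola through the surrounding points and taking its vertex, which
averages out sampling noise and removes the grid-quantization bias of a raw
argmax.

**Summary metrics** treat the corrected trace as an unnormalized density
over size: modal size is the bp at the maximum, mean and median are
intensity-weighted, entropy is Shannon entropy of the normalized trace (in
nats; bits available), skewness is the weighted third standardized moment,
and the short-to-long ratio divides signal in 100–150 bp by 151–220 bp —
the common liquid-biopsy convention for "short fragment" enrichment; both
windows are configurable. When the long window carries no signal the ratio
is reported as `NA`, never infinity. These metrics weight positions by
trace value alone (not bp-integrated mass): that is the convention under
which a two-point profile has entropy ln 2 and a single spike has entropy
0, which is how such descriptors are reported in practice.

**gDNA flagging.** High-molecular-weight signal in a cfDNA preparation
usually means genomic DNA from lysed cells. The fraction of in-range signal
above 1000 bp is reported and the sample flagged when it reaches 20%. Both
thresholds are defaults of this implementation, not community standards —
they are prominently configurable (`--gdna-size`, `--gdna-frac`) and should
be tuned to the assay.

## Group statistics

Fragment metrics from small clinical cohorts are rarely Gaussian, so the
default tests are rank-based: two-sided Mann–Whitney U for two groups,
Kruskal–Wallis for more (a Welch t-test is available via `test = "welch"`).
For combined n ≤ 20 the MWU p-value is computed exactly by enumerating all
`choose(m + n, m)` group assignments of the ranks, which handles ties
without approximation — two identical groups give exactly p = 1, and
complete separation at 4 vs 4 gives exactly p = 2/70. Beyond n = 20 the
normal approximation with tie correction takes over. Raw p-values are
primary; a Benjamini–Hochberg column (adjusted within each grouping
variable) is always emitted for transparency. Comparisons in which any
group has n < 3 are computed but flagged `low_n` — with two samples in a
group even a perfect separation cannot reach conventional significance, and
the flag keeps such results from being over-read.

## The synthetic-data generator

`simulate_electropherogram()` emulates a device export: lane 1 carries
narrow Gaussian ladder bands placed by the same log-linear migration model
the calibration assumes (a deliberately mismatched linear mode exists to
probe robustness), and each sample lane is a Gaussian mixture over fragment
size plus a constant baseline and seeded Gaussian noise, clamped at zero.
The generator records ground truth — true peak centers and bin fractions
obtained by brute-force integration of the noiseless mixture on a fine grid
— which serves as the oracle for every recovery test. `make_cohort()`
builds two-group cohorts whose mononucleosomal area share differs by a
known effect (reference share 0.4, per-sample biological jitter sd 0.02,
trace noise sd 0.05 by default), which drive the type-I-error and power
simulations. `render_gel_image()` paints a table as a striped gel PNG with
recorded lane centers, in both polarities.

What the generator does *not* emulate: dye fronts, spikes, saturation,
lane curvature or smile, position-dependent background, and band-width
dependence on size. Passing tests therefore demonstrate correctness of the
algorithms under idealized signal models, not robustness to every artifact
of real gels; the image module in particular assumes straight, vertical,
evenly illuminated lanes, as the documentation's image-quality guidance
states.

Simulation sizes used by the test-suite and validation script — 300
positions per trace, 100 replicates for noisy-recovery and power estimates,
1000 replicates for the type-I error — were chosen as the smallest sizes at
which the estimated rates have narrow enough Monte-Carlo error to be
meaningful (a binomial rate from 1000 draws has s.e. ≈ 0.007 near 0.05).

## Numerical and degenerate-input choices

- Gel images: converted to grayscale, Gaussian-blurred (sigma 1 px) to
  suppress compression noise, then Otsu-thresholded. Polarity is decided by
  class balance: bands occupy a minority of pixels, so if the bright class
  is the majority the bands must be dark and the image is inverted —
  after standardization bands are always bright. A median-versus-foreground
  comparison was considered and rejected: on a clean dark-bands-on-white
  image the global median equals the background level and the rule cannot
  trigger.
- Lane detection thresholds the column-mean profile with Otsu; runs
  narrower than 1% of the image width (minimum 2 px) are rejected as
  specks. A contrast-free profile is a detection error, not one full-width
  lane.
- Band extraction averages a center-aligned column band of half-width 25%
  of the lane span (configurable; 0 = single center column), which uses the
  most uniform part of the band while avoiding edge smear.
- Ties in rank tests: handled exactly by enumeration (small n) or by the
  standard tie-corrected variance (large n).
- Constant traces normalize to zero with a warning; zero-signal profiles
  are errors ("empty profile") everywhere a denominator would vanish.
- All validation errors are classed conditions
  (`fragtrace_format_error`, `fragtrace_calibration_error`, …) carrying the
  offending file/row/column, so batch runs can skip and report cleanly.
- Delimiters (comma/semicolon/tab) are sniffed per file from the header
  row; decimal commas are normalized when the field separator is not a
  comma; device-export preambles are skipped by scanning for a header line
  followed by numeric rows. Marker tokens in the annotation file are
  `marker`, `M` or `*` (case-insensitive) — the annotation syntax is this
  package's convention, documented here because device vendors define none.

## Known limitations

- Resolution is bounded by the electrophoresis assay; fine fragmentomic
  features (jagged ends, subnucleosomal oscillation) are invisible here and
  require sequencing.
- Absolute quantification (ng/µL) is out of scope; all outputs are relative
  to per-sample total signal.
- The image module performs no perspective, rotation or smile correction;
  photographs must follow the quality guidance.
- Statistical comparisons are unadjusted for covariates; the statistics
  table is a screening device, not a substitute for modelling.
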