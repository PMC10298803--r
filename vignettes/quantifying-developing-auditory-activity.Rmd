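---
title: "Quantifying spontaneous and sound-evoked activity in the developing auditory system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spontaneous and sound-evoked activity in the developing auditory system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonotopy)
```

# The problem

Before hearing onset, inner supporting cells (ISCs) of Kölliker's organ
release ATP spontaneously, exciting groups of inner hair cells (IHCs) and,
through them, spiral ganglion neurons and the central auditory pathway.  This
burst-like activity propagates to the inferior colliculus (IC) as band-shaped
events aligned with future isofrequency laminae.  Quantifying it requires a
chain of bespoke measurements — ΔF/F event segmentation on a supporting-cell
sheet, per-cell synchrony and recruitment statistics, osmotic crenation
detection in transmitted light, widefield tonotopic line-scan statistics,
automated ABR/DPOAE thresholds, and two-photon tuning curves — that this
package implements as tested, reusable functions, together with seeded
synthetic generators that emulate each recording modality with planted ground
truth.

# Signal conditioning

**ΔF/F.** `normalize_dff()` supports the two baselines in common use: the
per-pixel 10th percentile over the whole recording (movies) and the per-ROI
median (cell traces).  The percentile uses linear interpolation between order
statistics (R quantile type 7); the choice matters only at short trace
lengths, and is frozen here so every threshold downstream is reproducible.
Baselines at or below zero are an error naming the offending pixel/ROI, since
a ratio to a non-positive baseline is meaningless.

**Photobleach correction.** `correct_photobleach()` fits
$a\,e^{-t/\tau} + c$ by Levenberg–Marquardt least squares on the full trace,
initialized from a log-linear regression of the decaying part, and subtracts
only the exponential component (the offset is retained).  Traces without net
decay are returned unchanged with `converged = FALSE`; a failed fit is a
warning, never an error, so batch pipelines keep running.  Least squares on
the full trace slightly over-fits recordings dominated by events; with
minutes-long recordings and second-long transients the bias on event
amplitudes stays within a few percent (tested).

**Peak detection.** `detect_peaks()` implements the fixed-criterion rule:
a peak must exceed both a threshold (median + k·SD of the trace by default,
k = 3; or a fixed absolute level) and a minimum amplitude (10% ΔF/F for
calcium, configurable for currents).  The SD is the ordinary single-pass
standard deviation over the entire recording, events included — no event
exclusion is attempted, matching a plain MATLAB `std`.  A peak is a strict
local maximum; plateaus resolve to their first frame; endpoints are never
peaks.

# ISC event segmentation

`make_grid_rois()` overlays 10 × 10 px squares on the ISC region mask,
anchored at the mask's bounding box; edge squares holding less than half a
full square are discarded to avoid area bias.  Each ROI trace is the mean of
its member pixels, normalized with the 10th-percentile baseline.

`binarize_activity()` thresholds each ROI at its *own* median + 3 SD
(strictly greater), and `extract_events()` takes connected components of the
active (frame, row, col) raster.  Connectivity is 26-neighborhood by default
— the common 3-D default in MATLAB-style image processing — with a
6-neighborhood alternative exposed; components lasting fewer than 3 frames or
touching fewer than 5 distinct ROIs are removed.  The implementation builds a
voxel graph (igraph); the test suite checks it against two independent
oracles (a brute-force flood fill and a vectorized minimum-label relaxation)
on hundreds of random rasters, and verifies voxel conservation (every active
voxel is in exactly one surviving event or counted as filtered).

Merged events are split by k-means on (frame · w_t, row, col) voxel
coordinates (`split_overlapping_events()`).  The temporal weight w_t = 1
treats one frame as one grid unit; nothing in the data dictates a different
scale, so it is a configurable default.  The original procedure chose k by
visual confirmation, which cannot be automated faithfully; `suggest_split_k()`
offers a documented stand-in — count local maxima of the active-ROI-count
time series separated by a ≥ 30% trough — and is a trigger, not a claim about
the authors' judgment.  Split parts are re-checked against the size filters.

`summarize_events()` reports frequency as events per 0.01 mm² per minute.
The area normalization is printed in the source quantifications; the time
base is not, so per-minute is a documented, configurable choice.

# Hair-cell and neuron statistics

`correlation_summary()` computes all pairwise Pearson coefficients on the
ΔF/F traces (not on binarized rasters).  The scalar summary — "mean 80th
percentile correlation" — is ambiguous between taking the 80th percentile of
each ROI's correlations and averaging, or one pooled percentile over all
pairs; both are implemented, per-ROI-then-mean being the default.
Zero-variance traces yield missing pairs and are excluded from the summary.

`assign_ihc_to_isc_events()` counts an IHC for an ISC event if one of its
peaks falls inside the event's frame window; when windows overlap, the peak
goes to the earliest-starting event and is never reused.
`isc_ihc_regression()` is ordinary least squares of IHCs recruited on ISC
ROIs activated.  `filter_sgn_by_kcl()` keeps neurons whose ΔF/F exceeds 10%
during the high-K⁺ wash — note the statistic is a maximum over the window, so
its effective criterion rises with trace noise; the generator documentation
and the analysis scripts use soma-averaged noise levels (≈ 0.01 ΔF/F SD)
where this matters.  `pharmacology_window_compare()` excludes a 90 s wash-in
gap after the perfusion change from both rate windows.

# Crenation detection

`difference_movie()` subtracts frames 5 s apart.  `detect_crenations()`
follows the stated (unusual) order: threshold the absolute difference at its
per-frame mean + 3 SD, *then* smooth the binary mask with a σ = 12 px
Gaussian, re-binarize, and label 2-D components.  The re-binarization level
after smoothing is not specified anywhere; half of the smoothed maximum is
used because, for a step edge, the smoothed indicator crosses exactly ½ at
the original boundary — patch areas are therefore preserved for regions large
relative to σ (corner rounding costs ≈ (4−π)σ², about 1% of a 100 × 100 px
patch).  Two guards are documented choices: detections merge across
difference frames when they overlap by ≥ 25% of the smaller region (a slow
crenation spans several frame pairs but is one event), and frames whose
smoothed mask peaks below 0.1 are skipped (an isolated noise pixel smoothed
at σ = 12 peaks near 10⁻³; a filled patch near 1).

`count_centroids()` binarizes (Otsu by default), restricts to the region
mask, labels components and counts those ≥ 10 px.  Touching cells merge —
there is deliberately no watershed, so counts are "preserved-cell" counts,
not cell densities.

# Widefield IC analysis

Whole-IC events are peaks of the mean ΔF/F over each IC oval at a fixed 1%
threshold and 1% minimum amplitude; left and right peaks within ±1 s merge
into one bilateral event (event half-widths are multi-second, so a 1 s window
is conservative; it is configurable).  Dominance is simply the larger side.

`tonotopic_linescan()` samples a rotated rectangle (default 25 × 100) by
bilinear interpolation and averages across the short axis; nearest-neighbor
sampling is available for bit-stability experiments.  Band events are 2-D
regional maxima of the (position × time) profile above 2% ΔF/F, with
8-neighborhood plateau handling (a plateau counts once, at its centroid).
`band_width()` normalizes the spatial profile to its peak and counts the
contiguous run above 0.75 about the peak: for a Gaussian band of width σ this
converges to $2\sigma\sqrt{2\ln(4/3)} \approx 1.52\,\sigma$, the closed form
the tests check to within one position.  `spatial_integral()` is the
trapezoidal rule at unit spacing.

Tone-evoked responses are unmixed by stimulus, aligned −1 s…+3 s around
onset, and averaged over repeats; the summary amplitude is the post-onset
peak of the mean ROI trace minus the pre-onset baseline mean (the source
plots "tone-evoked fluorescence" without a formula; this is the simplest
definition consistent with it).  Rate-level thresholds reuse the ABR rule
(criterion = baseline mean + 2 SD, linear interpolation, censored sentinel),
because no explicit criterion is stated for the optical thresholds anywhere;
this is the package's decision, marked as such.  `activated_area()` counts
pixels above 15% ΔF/F times the pixel area.

# Audiometric thresholds

`abr_threshold()` builds its criterion as mean + 2 SD of peak-to-peak
background amplitudes pooled over every pre-stimulus background segment of
every level ("background signal" is undefined in the source; pre-stimulus
segments are the default, configurable).  The threshold is the lowest level
whose signal peak-to-peak exceeds the criterion with all higher levels also
above it (non-monotone dips below are flagged and the highest crossing used),
linearly interpolated in level–amplitude space between the bracketing levels,
clamped to the lowest tested level, with a censored sentinel one level step
above the maximum when nothing crosses — mirroring plotting at the detection
limit.

`dpoae_threshold()` reads the distortion-product amplitude at the spectral
bin nearest 2f₁−f₂ (f₁ = 0.909·Fc, f₂ = 1.09·Fc) and compares it, per level,
against mean + 2 SD of the adjacent band (±10 bins, excluding ±2 guard bins —
"adjacent" is otherwise unspecified), interpolating the crossing exactly as
for ABR.

# Two-photon tuning

Best frequency is the frequency of the global maximum over the
(frequency × level) response surface, ties going to the lower frequency with
a flag.  `bandwidth_gaussian()` fits a single-term Gaussian
$a\,e^{-((x-b)/c)^2}$ over $x = \log_2 f$ (the `Gauss1` form, so
σ = c/√2 octaves), initialized at a₀ = max amplitude, b₀ = argmax, c₀ = 1
octave; cells are excluded — not errors — on non-convergence, flat response,
fitted peak outside the tested range, or no curvature (c above twice the
tested span).  PCA runs on mean-centered, unscaled peak responses with cells
as observations, returning the three major component scores.  Responsiveness
(needed for "% neurons activated", never defined in the source) defaults to
max response > baseline mean + 3 baseline SD.

# What the generators emulate — and what they do not

Every generator draws from one seeded stream per call and restores the
caller's RNG state; identical configurations are bit-identical.  Each returns
the ground truth needed to predict its downstream analysis without re-running
the generator.

* `gen_isc_ihc_movie()` — flat elliptical event footprints on the lower-half
  ISC region with a trapezoidal time course (1-frame rise, 4-frame plateau,
  3-frame linear decay; the simplest shape compatible with the 3-frame
  duration filter — no kinetic model is asserted), coupled IHC transients in
  the oval ROIs whose centers fall under the footprint, optional exponential
  bleach, Gaussian noise.  Defaults: 2 Hz, 10 min, 0.83 µm/px (a 512 × 512 px
  field spanning 425 µm), 2 events/min, 40 µm footprints, 0.5 ΔF/F amplitude,
  0.05 ΔF/F noise — chosen once as typical pre-hearing explant conditions, at
  a 128 × 128 px field so a full movie fits comfortably in memory.
* `gen_sgn_traces()` — shared burst trains recruited per-ROI with probability
  ρ plus private bursts, and a terminal high-K⁺ ramp in the responsive
  fraction.
* `gen_widefield_ic()` — two IC ovals; events are Gaussian bands across the
  tonotopic axis with independent log-normal left/right amplitudes (the
  source reports variable hemispheric dominance without a model).  Planted
  amplitudes are *ROI-mean* ΔF/F — the band image is scaled so its mean over
  the oval equals the planted value — so ground truth is in the same units
  the whole-IC detector measures.  Evoked mode places band centers linearly
  in log₂ frequency and grows amplitude as a logistic in level; the planted
  threshold is the half-maximum level, so recovery tests pass
  `criterion = amp_max/2`.
* `gen_abr_series()` — a clean damped-sine wavelet in the analysis window
  (300-sweep averaging justifies a near-noiseless evoked component) whose
  peak-to-peak amplitude grows linearly in level, plus five 1 ms pre-stimulus
  background segments per level whose peak-to-peak amplitudes are drawn with
  the stated mean (3 µV) and SD.  The planted threshold is defined as the
  level where the *expected* signal crosses the *expected* criterion
  (background mean + 2 SD); recovered-threshold error then reflects exactly
  the criterion-estimation noise of the automated algorithm, which is the
  quantity worth testing.  Had the stated 1 µV noise been placed on each
  signal measurement instead, no algorithm could recover thresholds to 2 dB
  at 0.1 µV/dB growth — the crossing itself would jitter by ±10 dB.
* `gen_dpoae_spectra()` — flat noise floor with stated SD, primaries at the
  fixed ratios, and a distortion product at 2f₁−f₂ growing 1 dB/dB above the
  planted threshold, defined as the expected criterion crossing in the same
  way.
* `gen_crenation_movie()` — square patches darkening over 4 s at staggered
  onsets (so each 5 s difference frame carries at most one patch transition),
  laid out on a grid with ≥ 50 px separation; impossible layouts are
  rejected.
* `gen_2p_tuning()` — separable Gaussian-in-log-frequency × logistic-in-level
  response surfaces per cell, with BFs planted on the tested frequencies, or
  explicit archetype groups for clustering studies.

None of these model biophysics: no ATP diffusion, no indicator kinetics, no
hemodynamic or motion artifacts, no correlated (shot/photon) noise, no
breathing or cardiac rhythms.  Passing recovery tests therefore demonstrates
that the *algorithms* are correct and self-consistent under controlled,
known-truth conditions — not that the defaults reproduce any particular
biological recording.

# Numerical conventions and degenerate inputs

Frames, rows, and columns are 1-based inclusive indices; time is seconds from
recording start.  Strict inequalities everywhere a rule says "greater than"
(binarization, peak criteria, the K⁺ filter), so constant traces (SD = 0)
never fire.  Percentiles are quantile type 7.  Zero events yield frequency 0
with missing means; an all-zero band profile is an error (width of nothing);
empty masks are errors.  k-means uses 10 restarts under a local seed, making
splits deterministic.  TIFF movies are stored as 32-bit float pages with a
JSON sidecar (frame rate, pixel scale, affine rescale), so round-trips are
exact at float32 resolution; determinism checks compare in-memory objects and
manifest hashes, which are exact.

The test suite and acceptance script run the pipeline at deliberately
desk-scale problem sizes — 96–192 px fields, 5–10 min recordings, hundreds of
random rasters up to 50 × 20 × 20, 100 audiometric series, 200-cell tuning
cohorts — sizes the package's own test-design chose to make the statistical
checks sharp while keeping a full run in minutes.

# Known limitations

The k-selection trigger for event splitting is a heuristic stand-in for
visual confirmation.  Frequency normalization per minute is a documented
guess at an unprinted time base.  The evoked-threshold criterion and the ABR
background window are package decisions where the source is silent.  The
crenation minimum-peak floor trades a small amount of sensitivity to very
small patches (≲ 200 px at σ = 12) for robustness to speckle.  Touching cells
are counted once.  The 80th-percentile correlation summary ships in two modes
because the definition is genuinely ambiguous.
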