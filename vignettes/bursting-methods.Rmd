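---
title: "Quantifying transcriptional bursting, dynamic epistasis and promoter nucleosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcriptional bursting, dynamic epistasis and promoter nucleosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstepi)
```

# The measurement problem

A galactose-inducible yeast gene tagged with PP7 stem-loops produces a single
bright nuclear spot — the transcription site (TS) — whenever nascent RNAs
accumulate at the locus. Time-lapse imaging of that spot turns gene
regulation into a time series problem: each cell's TS intensity trace is
binarized into ON (bursting) and OFF periods, and regulation is summarized
by five parameters: the **active fraction** of cells, the **induction time**
(delay between carbon-source switch and the first burst), the **burst
duration**, the **time between bursts**, and the **burst intensity**.
Perturbations (e.g. nuclear depletion of a chromatin remodeler by
anchor-away, histone gene deletion, TATA mutation) change these parameters;
comparing a double perturbation with the product of its singles — *dynamic
epistasis* — asks whether two factors act in the same pathway, act
independently, or are redundant, per parameter rather than per endpoint.

This package implements the full measurement chain plus generative
simulators for every input, so each stage can be validated against known
ground truth without any raw microscopy or sequencing data.

# The trace model and its simulator

`simulate_traces()` draws, per cell:

* an activation flag (probability `active_prob`);
* an induction delay `t0 ~ dead_time + Gamma(n_steps, scale = 1/step_rate)` —
  the sum of `n_steps` sequential exponential activation steps, the
  first-passage model under which the fitted Gamma shape estimates the
  number of rate-limiting steps;
* alternating exponential ON/OFF dwell times (telegraph model, means
  `mean_on`, `mean_off` in minutes) tiling the remainder of the movie;
* per-frame intensity `state * mean_intensity * LN + N(bg_mean, bg_sd)`,
  with `LN` a unit-mean log-normal of coefficient of variation
  `intensity_cv`. The multiplicative log-normal reproduces the heavy-tailed
  burst-intensity distributions that the log-normal fit module targets;
  the trace is defined on the background-subtracted scale the photometry
  produces, so `bg_mean` defaults to 0.

Dwell intervals are stored truncated at the movie end (they tile the
post-induction window exactly; the censored last interval is flagged), and
the per-frame state is the interval indicator sampled at frame times.
Determinism: one top-level seed yields per-cell sub-seeds
(`derive_seeds()`), so outputs are byte-identical for identical inputs and
independent of evaluation order. What the simulator deliberately omits:
photobleaching, blinking, cell growth and movement, z-dependent PSF — so
passing tests validate the analysis chain, not robustness to those
real-data effects.

`render_movie()` turns traces into image stacks: one pixel-integrated 2D
Gaussian spot per ON cell (integrated intensity = trace value) at a fixed
position inside a per-cell tile, plus i.i.d. Gaussian camera noise on a
constant baseline.

# Live-cell quantification

**Drift correction** (`drift_correct()`) estimates per-frame translations
against frame 1 by phase correlation on the maximum-intensity projection
with parabolic sub-pixel interpolation. Stage drift is translational, so
translation-only is the default interpretation of registration here; frames
are shifted by the rounded offset and exposed edges take the frame median.

**Segmentation** (`segment_cells()`): global Otsu threshold, hole filling,
distance-map watershed to split touching cells (EBImage), minimum object
area 100 px by default.

**Photometry** (`gaussian_mask_fit()`, `quantify_ts()`): iterative
Gaussian-mask estimation in a square window of half-width `3 * psf_sigma`.
Within the window the spot amplitude and a constant local background are
solved *jointly* by linear least squares, and the centre is updated to the
signal-weighted centroid until it moves < 0.01 px (at most 100 iterations).
The joint fit rather than a perimeter-mean background is a deliberate
numerical choice: at a 3-sigma window the perimeter still contains about 2%
of the spot light, which would bias even noiseless recovery; the joint
linear fit is exact for the noiseless model and recovers planted intensities
to better than 1%. The attainable precision per frame is the Cramér–Rao
bound for an integrated-intensity estimator,
`sd = noise_sd * 2 * sigma * sqrt(pi)` (about 4.6 pixel-noise units at
sigma = 1.3 px); tests assert trace recovery against three times this
standard error. Detection per frame and cell uses three tiers: the
brightest in-cell maximum above `6 x bg_sd` (primary), a retry within
`fallback_radius` of previous detections above `4 x bg_sd` (fallback), and
measurement at the last known position otherwise (carried-over). The trace
endpoint is the last primary/fallback frame — an automatic surrogate for
manual endpoint curation, overridable via `end_frames`. z is handled by
maximum projection; live-cell spots are not fit in 3D (widefield stacks).

# Binarization and burst metrics

The ON threshold is `5 x` the background width, where the width is the
scale parameter of a Lorentzian (Cauchy) fit to intensities pooled from
four points (N/E/S/W) at a fixed ring distance from the TS across frames
(`estimate_background_sd()`). A Cauchy has no standard deviation, so the
fitted scale gamma plays that role; for purely Gaussian noise of s.d.
sigma the Cauchy MLE scale settles near `0.61 sigma` (HWHM-matched — about
6.3 for sigma = 10), making the effective threshold about `3 sigma` — low
enough to catch single-transcript signal, high enough that false ON frames
are rare. An HWHM-to-Gaussian-sigma conversion is available via
`mode = "sigma"`.

Cleanup applies two rules **in order**: delete ON runs of one frame, then
merge ON runs separated by one OFF frame. The order matters (an alternating
trace dies under delete-first and survives under merge-first) and is
configurable; delete-first is the default. The cleanup is idempotent.

`extract_burst_record()` reads induction time (first ON frame, frame 1 at
t = 0, plus the acquisition dead time `t_acquisition_offset`, default 0),
burst durations (ON runs x frame interval; a run still ON at the endpoint
is right-censored and excluded from duration statistics), inter-burst times
(interior OFF runs) and burst intensity (mean raw intensity of ON frames).
`summarize_population()` bootstraps **cells** (the independent units) with
1,000 repetitions: pooled interval values follow their cell, and the
reported value/error are the mean/s.d. of the bootstrap means. Active
fractions are reported from counts with square-root-of-count errors.

**Frame discretization.** Sampling exponential dwells at a finite frame
interval and deleting single-frame runs biases interval means upward (for
2-min bursts at 15-s frames, by roughly 18%). `discretize_truth()` passes
the ground-truth state series through the same frame grid and cleanup
rules, giving the discretization-corrected truth against which recovery is
judged; the measurement path is still exercised end to end (thresholding of
noisy intensities, run bookkeeping, bootstrap).

# Statistics

`bootstrap_asl_test()` implements the translation-null two-sample
bootstrap: both groups are recentred to the pooled mean, resampled within
group, and the two-sided achieved significance level is the add-one
Monte-Carlo p-value `(1 + #{|d*| >= |d_obs|}) / (B + 1)` for the difference
of means (a studentized variant is available). The add-one smoothing avoids
zero p-values and makes the test slightly conservative at small `B`.
`fisher_active()` wraps the exact two-sided Fisher test for active/inactive
counts; the test suite checks it against explicit hypergeometric
enumeration over every table with margins up to 12. `propagate_ratio()`
carries independent errors through ratios in the form
`sd_r = sqrt((sd_x/y)^2 + (x sd_y/y^2)^2)`, well defined at `x = 0`.

# Dynamic epistasis

Per parameter, the fractional change `f` is the ratio of bootstrap means
(perturbed over reference); for the active fraction, the ratio of count
fractions with propagated square-root errors. The expected double effect
under independence is the product `f_A * f_B` with multiplicatively
propagated errors, and `classify_interaction()` operationalizes the
comparison as `z = (f_obs - f_exp) / sqrt(sd_obs^2 + sd_exp^2)` with
`z_cut = 2`: above, synergistic (redundant processes); below the negative
cut, buffered (same pathway or opposing); otherwise as-expected
(independent). The z-score formalizes what a shaded ±s.d. expectation band
shows graphically; the cutoff is configurable. Reference conditions resolve
to the unperturbed (DMSO) condition of the same strain by default, with
explicit override rules for designs where a second perturbation is to be
read relative to an already-perturbed background
(`relative_reference_resolve()`). Replicates are pooled before
bootstrapping (cells from all replicates enter one population); a
per-replicate route is available by summarizing each replicate separately.

**Calibration study design.** `simulate_epistasis_replicate()` runs the
full chain on four simulated conditions (reference; x2; x1.5; double) and
classifies the double effect on the time between bursts. Movie length
matters here: only completed OFF intervals are measured, and
length-biased censoring shortens the observed mean to approximately
`mu (T - 2 mu) / (T - mu)` for true mean `mu` in a movie of length `T` — a
*concave* distortion that breaks the multiplicative null even when the
underlying effects are exactly independent (at `T = 240` min the null
z-scores centre near -0.6). The default calibration design therefore uses
`T = 960` min at 60-s frames — long-horizon, sparse-sampling imaging — which
keeps the distortion well below the sampling error of the fractional
changes while leaving dwell-time discretization negligible (intervals of
8-48 min against 1-min frames). With that design, 100 simulated
independent double perturbations classify as-expected about 95% of the
time and a doubled interaction is called synergistic essentially always.

# Distribution fits

Induction-time histograms (1-min bins, densities at bin centres, empty bins
as zeros) are fit by constrained least squares with an amplitude-scaled
Gamma pdf `A * dgamma(x, shape = k, scale = theta)`. The amplitude absorbs
the dead time between stimulus and acquisition start (early-inducing cells
are unobserved, so the histogram need not integrate to the model mass).
Bounds and starts: `A >= 1` (start 10), `k >= 1e-4` (start 10, or 1.0001
for re-induction), `theta > 0` (start 1). `k` — the shape — estimates the
number of rate-limiting activation steps; it is sometimes loosely called a
scale parameter, but it is used strictly as shape here. Burst durations and
inter-burst times use the same machinery with `A = 1` and `k >= 1` (start
1.0001); burst intensities are fit with a log-normal (`sigma >= 0` start
0.6, `mu` free start 5.5, 50 bins). Least squares on the histogram, not
maximum likelihood, is the estimator of record (MLE appears only as an
oracle in tests). For the log-normal, if the stated far-off start leaves
the optimizer on a flat plateau (data living three log-units below the
start), a moment-based restart is attempted — the bounds are unchanged.
Goodness of fit is `R^2 = 1 - sum((y - f)^2) / sum((y - ybar)^2)` on the
binned densities; conditions with `R^2 < 0.8` on their induction fit are
flagged as possible subpopulation mixtures (`screen_subpopulations()`),
with an extra marker when the sample is too sparse (< 50) for `R^2` to be
stable. Degenerate inputs (all values in one bin) return
`converged = FALSE` rather than an arbitrary fit.

# smFISH quantification

`detect_spots_3d()` finds 26-neighbourhood local maxima above
`6 x bg_sd` and quantifies them by the 3D analogue of the Gaussian-mask
fit; cells with no spots at all are absent from the table (in real data
those are unsegmentable or unpermeabilized cells and are excluded). The
RNA-equivalent unit is the **median cytoplasmic spot intensity over all
cells**; each cell's TS is its brightest nuclear spot, its nascent count is
TS intensity over the unit, and cells with fewer than 5 nascent RNAs are
inactive — the boundary is exact (5.000 is active, 4.999 is not), and
nascent counts are invariant to any global intensity rescaling.

Cell-cycle stage comes from total DAPI content per cell (computed from a
maximum-intensity projection in the imaging pipeline): a two-component
Gaussian mixture is fit to the raw values (mclust; the 50-bin histogram
informs initialization only), and cells are assigned G1 within
`[c1 - sd1, c1 + 0.75 sd1]`, G2 within `[c2 - 0.5 sd2, c2 + 1.5 sd2]`, S
between the windows, and unclassified outside the extremes. The window
notation "(sd, 0.75 sd) around the centre" is read as asymmetric
lower/upper multiples; both multipliers per window are exposed as arguments
(`g1_window`, `g2_window`) for the symmetric alternative. The windows are
deliberately narrow, so a substantial fraction of cells is S/unclassified
by design; recovery is therefore scored as concordance of G1/G2 calls with
the generative mixture component, which exceeds 90% already at 6-s.d.
component separation. Equal-mean mixtures collapse to all-unclassified
with a warning. `summarize_replicates()` averages the active fraction and
the mean nascent count of active cells across replicates with s.e.m.
errors, optionally per stage.

# MNase-seq nucleosome analysis

Fragments (0-based half-open intervals; BED in/out, GFF-style 1-based
inputs must be converted on read) are filtered to mono-nucleosome lengths
95-225 bp inclusive. Coverage counts **full fragment spans** (one count per
read pair — the standard MNase convention; a per-read mode would halve
spans) per chromosome and is normalized to per-chromosome sum 1, so depth
cancels between datasets; windows are views and never renormalized.

Nucleosome calling (`call_plus_one()`) per gene: extract the
prenormalization coverage in ±2,000 bp around the TSS from each reference
track, flip Crick-strand genes so downstream is positive, sum the tracks,
and smooth with a Gaussian kernel whose **FWHM is 40 bp**
(`sigma = 40 / sqrt(8 ln 2) ~ 17 bp`) — a "40-bp window" could also mean
`sigma = 40`, so the raw-sigma reading is available via the `sigma`
argument; results depend on this choice, hence both are exposed with FWHM
as default. The global minimum of the smoothed profile marks the NDR;
peaks are plateau-safe local maxima with prominence at least 5% of the
window maximum and at least 100 bp apart (the peak caller is a ~30-line
prominence filter, since only "a peak-calling function" is specified).
The -1 nucleosome is the last peak before the minimum, +1 the first after;
genes with fewer than two flanking peaks, or with -1/+1 farther than
1,000 bp from the TSS (peak-to-TSS distance), or without coverage, are
excluded with a recorded reason. NDR width is the -1 to +1 distance.
Downstream analyses reuse the reference calls: metagene profiles average
normalized strand-oriented coverage in ±1,000 bp around each gene's
reference +1; log2 fold-change matrices compare a depletion track against
averaged control replicates over the same windows with rows sorted by
ascending NDR width (pseudo-count = the uniform normalized per-base value,
1/chromosome-length, divided by the window length — small against any real
coverage, so covered bases report their true ratio and empty bases damp to
0); +1 shifts are TSS-oriented differences between per-depletion calls and
the pooled-reference calls, with medians per TATA / TATA-mismatch class;
and TATA-window occupancy sums normalized coverage over the 8-bp element.

The fragment simulator plants nucleosomes as Normal(center, 20 bp)
midpoint clouds with occupancy weights and Normal(150, 15) lengths
rejected outside [50, 300]. `promoter_architecture()` embeds each promoter
in a continuous nucleosome array (upstream and gene-body flanks at 165-bp
spacing): isolated promoters with empty flanks would put the window's
global minimum at its edge rather than in the NDR — a situation real
chromatin does not present — and the NDR (a ~300-bp gap against the 165-bp
array spacing) is then correctly the deepest minimum. With 10,000 filtered
fragments per gene, planted -1/+1 positions are recovered within ±10 bp
and a planted 40-bp depletion shift within ±10 bp of the median.

# Problem sizes and reproducibility

The validation suite runs entirely on simulated data at sizes chosen to
make Monte-Carlo error small against each tolerance: 300 cells for
telegraph recovery, 200 cells for binarization fidelity, 1,000 null
replicates for test calibration (999 bootstrap resamples each — the
add-one ASL is conservative at small resample counts), 100 replicate
studies of four conditions for the epistasis null and synergy rates, 2,000
samples per distribution fit, 2,000-3,000 cells for smFISH, and 8 genes x
10,000 fragments for the MNase chain. `scripts/acceptance.R` recomputes
all of these from scratch under a single command-line seed; every
stochastic stage is byte-identical under a fixed seed.

# Known limitations

* Burst inference is threshold-based, as specified; no hidden-Markov or
  Bayesian dwell-time machinery, and no analytic correction of the
  finite-frame-rate bias beyond the documented discretization accounting.
* Completed-interval censoring biases inter-burst means for movies short
  relative to the OFF time (quantified above); the epistasis calibration
  sizes movies accordingly, but single-condition summaries from short
  movies inherit the bias like the original measurement does.
* One TS per cell; diploid two-allele traces and TS tracking through
  mitosis are out of scope.
* The subpopulation screen flags poor single-population fits; it does not
  fit mixtures.
* MNase analysis consumes aligned fragments; alignment and
  low-vs-high-MNase chemistry are upstream of this package.
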