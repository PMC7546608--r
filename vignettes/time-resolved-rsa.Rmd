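---
title: "Time-resolved RSA for EEG: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved RSA for EEG: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsatime)
```

## The scientific question and the analysis model

Representational similarity analysis (RSA) asks whether the *geometry* of
neural responses -- which stimuli evoke similar patterns, which evoke
dissimilar ones -- matches the geometry predicted by a hypothesis variable.
For epoched EEG this can be asked millisecond by millisecond: at each time
bin we summarize the pairwise dissimilarity of the response patterns evoked
by every pair of conditions in a representational dissimilarity matrix
(RDM), and correlate that neural RDM with predictor RDMs built from
behaviour or stimulus attributes. The motivating use case is tracking when
cortical representations of facial attractiveness emerge: 100 face
identities, each participant rating every face (a binary yes/no judgment and
a 1-7 rating), plus a group-average "database" rating, the faces' sex,
ethnicity and age, and optionally feature activations from a face-trained
network, one matrix per layer.

The pipeline has four stages, each an exported function:

1. **Neural RDMs per time bin** -- `rdm_timecourse()` /
   `split_half_pca_rdm()`.
2. **Predictor RDMs** -- `build_predictor_suite()`: absolute differences of
   graded variables (ratings, mean yes/no codes, age), same/different
   contrasts for categories (sex, binarized ethnicity), `1 - r` between
   activation vectors.
3. **Model comparison per participant** -- `fit_timecourse()`: Spearman
   correlation between the vectorized lower triangles, or partial Spearman
   with a set of control RDMs regressed out of both sides; Fisher z
   (`atanh`) for group statistics.
4. **Group inference** -- `group_summary()`: per-bin one-sided t-tests of
   the participants' z values against zero, Benjamini-Hochberg FDR across
   bins, Cohen's `d = t / sqrt(n)`, onset (earliest corrected-significant
   bin) and peak (maximal t among significant bins) summaries.

## The split-half PCA estimator

Raw correlation distances between single-trial EEG patterns are dominated by
noise, so the neural RDM is estimated with cross-validation. For one time
bin the per-trial pattern is the channels-by-samples segment unfolded
channel-major into one vector (63 channels x 12 samples = 756 features at
the defaults). Then, per random split:

* trials are divided into two halves with an equal number of trials per
  condition (a condition's odd surplus trial joins a random half);
* a PCA is fitted on the first half's trial-level vectors; both halves are
  centred by the first half's feature means;
* the second half is projected onto the smallest leading set of components
  explaining at least 99% of the fitting-half variance (`variance_threshold`);
* projected trials are averaged per condition and every pair of condition
  means is scored as 1 minus their Pearson correlation;
* the roles of the halves are swapped and the two RDMs averaged.

The whole procedure is repeated (`n_repetitions`, default 50) with fresh
random splits and averaged. Everything is deterministic given the seed: a
single master integer feeds named substreams (per bin, per repetition) via a
counter-based hash, so a whole timecourse is reproducible from one number.

Numerical conventions worth stating explicitly:

* **Samples per bin.** A 50 ms bin at 250 Hz nominally spans 12.5 samples;
  we use `floor` (12 samples) and advance bins by exactly that many samples
  from the epoch start, keeping bins non-overlapping and reproducing the
  usual 756-feature pattern.
* **PCA is fitted on trial-level vectors**, not condition means, and the
  held-out half is centred by the *fitting* half's means -- projection of
  held-out data needs the fitting half's reference frame.
* **Scores versus reconstruction.** By default condition means are
  correlated in the retained component space (`projection = "scores"`).
  Pearson correlation is not invariant under the PCA rotation (it re-centres
  across coordinates), so even with `variance_threshold = 1` score-space
  distances differ slightly from sensor-space ones. The alternative
  `projection = "denoise"` projects patterns onto the retained basis and
  reconstructs them in sensor space before correlating; in that mode, with
  threshold 1 and noiseless data, the estimator agrees exactly with a plain
  split-average-correlate computation, which is how the test suite pins the
  estimator down against an independent oracle. Scores mode is the default
  because correlating in the reduced space is the common practice this
  pipeline mirrors.
* **Flagged entries.** A condition mean with no feature variance (including
  the two-condition corner case where only one component survives) has no
  defined correlation; such entries are NA, serialized as `NA` on disk, and
  removed pairwise before any model comparison.

## Model comparison conventions

Only the lower off-diagonal triangle of each RDM enters the analysis, in a
fixed row-major order used everywhere. Spearman correlations use average
ranks -- predictor RDMs built from 0/1 categories and a 1-7 scale are
heavily tied, and average ranks are the standard convention. The partial
correlation is the Pearson correlation of *residualized ranks*: all vectors
are rank-transformed once, the neural and predictor ranks are least-squares
residualized on an intercept plus the control ranks, and the residuals are
correlated (rank-then-residualize, not residualize-then-rank, matching the
usual partial-Spearman definition). Collinear control columns are dropped by
a rank-revealing QR with a warning. Fisher z uses `atanh` with rho clipped
to 1 - 1e-12 in magnitude so degenerate toy inputs cannot produce
infinities. If the controls absorb *all* of one side's rank variance (the
self-control case), the partial correlation is 0 by convention; NA is
reserved for genuinely undefined inputs.

## Group statistics

Tests are one-sided (positive correlations), reflecting the directional RSA
hypothesis. FDR correction is applied across all 34 bins including the
pre-stimulus ones by default -- correction "across time" without restriction
-- with `fdr_scope = "post_stimulus"` available to restrict the family. The
peak is the maximal-t significant bin (not the maximal mean correlation;
they can differ), and when nothing survives correction the global maximal-t
bin is reported but flagged `peak_significant = FALSE`. Degrees of freedom
are always `n - 1`; effect sizes are `d = t / sqrt(n)`, rounded to two
decimals only when printed.

## The forward simulator: what it emulates, and what it does not

`generate_dataset()` produces data with the canonical design: 23
participants, 100 faces x 7 blocks = 700 trials, 63 channels at 250 Hz,
epochs from -250 to 1450 ms. It exists to give every pipeline stage a known
ground truth, not to be a brain model.

**Behaviour.** Each participant's latent preference for face `f` is
`u(f) = lambda * standardized(db_rating) + (1 - lambda) * e(f)` with
idiosyncratic `e(f) ~ N(0, 1)`. Trial ratings are
`clip(round(3.5 + 1.5 * u + eps), 1, 7)` and yes/no responses threshold
`u + eps'` at zero, with trial noise sd 1. The default
`shared_taste_weight = 0.3` was chosen analytically (and confirmed by
simulation) so that per-participant mean responses correlate with the
database rating at roughly 0.35 -- the "moderate idiosyncrasy" regime in
which individual judgments carry real information beyond the group average.

**EEG.** Each injected geometry is a target RDM (a literal matrix or a
per-participant predictor: `"rating"`, `"db_rating"`, `"sex"`, ...),
embedded into `q` coordinates by classical MDS (`stats::cmdscale`; negative
eigenvalues of non-Euclidean RDMs, such as absolute-difference matrices, are
truncated and missing dimensions zero-filled). Coordinates are centred,
scaled to unit total variance, and mixed into channels by a random matrix
fixed per participant. A piecewise-linear envelope (onset, peak, offset)
modulates the pattern over time -- deliberately schematic, because recovery
tests need controllable onsets, not realistic ERP waveforms. White Gaussian
noise (`noise_sd`, in units of the unit-RMS signal) is added independently
per trial, channel and sample.

What the simulator deliberately omits: 1/f spectra, spatial channel
correlations, trial-to-trial amplitude variability, eye/muscle artifacts,
and any biophysical forward model. Passing recovery tests therefore shows
that the *pipeline* is correct and sensitive under its own assumptions; it
does not certify performance on real EEG, where noise is structured and
effect sizes are far smaller.

## Validation design and problem sizes

The test suite checks every estimator against an independent oracle
(straight-line reimplementation with `prcomp` for the split-half estimator;
the closed-form first-order partial-correlation formula on ranks; a
hand-rolled BH step-up) and then validates the pipeline end to end on
simulated data:

* **Recovery:** a `"rating"` geometry with a 150 ms onset injected into 10
  participants x 40 faces x 16 channels (3 split repetitions) must yield an
  earliest FDR-significant bin within one bin of 150-200 ms in at least 8 of
  10 datasets.
* **Null calibration:** with no injected geometry, no bin should survive FDR
  in at least 19 of 20 datasets (under the global null the family-wise
  rejection rate of BH is exactly the FDR level, so ~1 contaminated run in
  20 is the expected behaviour, not a failure of the code).
* **Partialing logic:** injecting only a shared-taste (`db_rating`) geometry
  must produce a plain individual-rating effect that disappears once the
  database rating is partialed out; injecting only a `sex` geometry must
  produce no attractiveness effect after controlling sex, ethnicity and age.

The reduced sizes (10 x 40 x 16, 2-3 repetitions instead of 23 x 100 x 63
and 50 repetitions) keep each simulated dataset small while leaving the
group tests well powered; the injected amplitude (1-2 times the noise sd at
the envelope peak) gives per-participant correlations around 0.2-0.4,
stronger than typical real-data effects by design, so that recovery
failures indicate bugs rather than power limits. `scripts/acceptance.R`
re-runs a three-dataset version of the recovery analysis and reports median
onset and peak effect size.

## Known limitations

* The estimator assumes every condition has at least two trials; sessions
  with heavier trial rejection must drop conditions upstream.
* Correlation-distance RDMs of effectively one-dimensional geometries (an
  absolute-difference RDM embeds on a line) saturate: noiseless patterns on
  a line correlate at +/-1, so graded structure is only recovered in the
  presence of noise or higher-dimensional signal. This is a property of
  correlation distance itself, not of the estimator.
* Partial Spearman removes controls linearly in rank space; strongly
  nonlinear relationships between control and neural geometry leave
  residual structure no rank-linear regression can remove.
* The onset statistic ("earliest significant bin") inherits the usual
  caveat of thresholded onsets: a single false positive in a pre-onset bin
  moves it early, which is why the null-calibration check matters.
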