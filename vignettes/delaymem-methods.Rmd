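---
title: "Methods: models, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulation design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`delaymem` analyzes delayed match-to-sample (DMS) fMRI experiments for
*ongoing encoding*: the hypothesis that activity persisting from a sample
stimulus into the maintenance delay continuously encodes the stimulus into
long-term memory, so its amplitude predicts later recognition strength.
Because no public scan data accompany this design, the package is built
around a synthetic generator with known ground truth; every analysis stage
is validated against what the generator put in.

## The encoding models

All three models describe the *neural* weight given to each 2 s time point
of the 12 s sample + delay epoch, before convolution with the hemodynamic
response:

| model | pre-convolution weights | hypothesis |
|---|---|---|
| `sample_only` | (1) | activity is purely stimulus-driven |
| `sample_plus_delay` | (1, 1, 1, 1, 1, 1) | activity persists undiminished |
| `decay` | (1, 2⁻², 3⁻², 4⁻², 5⁻², 6⁻²) | persistent activity wanes; weight at time point n is n⁻² |

The decay exponent is fixed at −2; it is a stated functional form, not a
fitted parameter. At TR = 2 s the epoch is 1 sample + 5 delay time points,
so all kernels have at most 6 weights.

## First-level model and assumptions

Per voxel, ordinary least squares of the BOLD series on: one encoding and
one 2 s test regressor per used confidence category (up to 10 interest
columns), HRF-convolved; plus per-run intercepts, per-run copies of the six
motion channels, and per-run centered cubic drift. Assumptions worth
stating:

- **No autocorrelation model.** Plain OLS is specified; variances assume
  i.i.d. residuals, which the synthetic noise satisfies by construction.
  Real scanner noise would need prewhitening; that is out of scope.
- **Categorization pools everything else.** Trials enter by confidence
  rating only, pooling match/non-match and correct/incorrect DMS trials;
  the inter-trial interval is absorbed by the run intercepts.
- **Test-regressor duration** is the 2 s test-phase duration (not otherwise
  specified in the source design).

The solver is a single QR decomposition of the shared design, applied to
all voxels at once; degrees of freedom use the matrix rank, not the column
count.

## Group model

Ratings map linearly to memory strength: 1 → −2, 2 → −1, 3 → 0, 4 → +1,
R → +2. Stacked encoding coefficients follow
`beta = subject intercept + gamma * code + error`, fit per voxel by
weighted least squares with weights equal to inverse first-level coefficient
variances, implemented by weighted within-subject centering (Frisch–Waugh;
exactly equivalent to the full normal equations, and what makes the
permutation loop cheap). Two open points were decided here:

- **Residual rescaling (default on).** Whether the original analysis took
  the weights as known variances or rescaled by the group residual mean
  square is not stated. The default multiplies the slope variance by
  `RSS_w / df` (classic WLS); `rescale = FALSE` gives the known-variance
  alternative. With 28 subjects × 5 categories and 8 missing cells the df
  is 103 either way.
- **Missing categories** simply contribute no rows; df shrinks per voxel.
  A single reported df across voxels requires identical masks, which the
  synthetic cohort satisfies.
- **Weight floor.** Noiseless simulations give zero first-level variance;
  weights are clipped at `weight_max = 1e8` so they stay finite.

## Inference

Uncorrected maps threshold |t| at the two-tailed Student-t critical value
(α = 0.01 default). Corrected inference uses the permutation distribution of
the image-wise maximum |t| over shuffles of the code vector:

- **Scheme.** The default shuffles the stacked code vector globally — the
  literal reading of permuting "the order of the response data" — with the
  same permutation at every voxel. A `within_subject` scheme is provided as
  the exchangeability-conservative option; under the null with subject
  intercepts in the model, both are valid, and the calibration test covers
  the default.
- **Two-sidedness.** The null records max |t|, giving two-sided validity;
  the observed map's sign is kept for reporting.
- **p definition.** Default is the literal "proportion of null maxima
  greater than observed", which can return 0; the `(b+1)/(B+1)` estimator
  is available and is what the super-uniformity property test uses.
- **Rank-breaking permutations** (code constant within all subjects) are
  redrawn and logged rather than silently included.
- **Cluster connectivity** defaults to 26 (corner-sharing), common
  neuroimaging practice; 6 and 18 are available.

## Posterior predictive model checking

The ROI series (mean over a sphere; membership is center-to-center distance
≤ radius in world mm, giving 171 voxels for a 5 mm sphere on a 1.5 mm grid)
is fit once per encoding model. Replicates draw σ² from its scaled
inverse-χ² posterior and coefficients from their conditional normal
(standard noninformative-prior conjugate forms — the source analysis does
not specify its simulation distribution), then add Gaussian noise.
Observed data and every replicate pass through the identical averaging
pipeline: z-score the whole series per participant, epoch −4…+24 s around
sample onsets on the TR grid (the window covers the ~6 s hemodynamic lag;
epochs leaving the run are dropped and counted), average within category
pooling trials, ±2 SE band over trials.

The original check was visual (curves leaving the simulation band). For
automated ranking a scalar was needed: misfit is the mean over categories
and time points of the squared standardized distance of the observed mean
from the replicate mean, with the pointwise min–max envelope (matching the
visual overlap criterion; a central-95% option exists) used for flagging.
This scalar is this package's own construction.

## The synthetic world

Defaults state one fixed scenario; they were chosen once and are not tuned
against test outcomes.

- **Timing.** 8 runs × 12 trials; 2 + 10 + 2 s phases; ITIs drawn balanced
  (four each of 6/10/14 s per run, shuffled). Balance is forced by
  arithmetic: only a 10 s mean ITI makes a run span exactly
  12×14 + 120 = 288 s = 144 volumes at TR = 2 s, reconciling the trial
  structure with the stated volume count. Whether the real jitter was
  balanced within run is unknown; the volume constraint decided it.
- **Behavior.** Ordinal-probit style: latent strength ~ N(1.4, 1) for
  studied items, N(0, 1) for lures, cut at thresholds (−0.3, 0.7, 1.7,
  2.4). These values put a simulated cohort near the reported behavior
  (DMS ≈ 95% correct via `p_dms = 0.95`; corrected recognition accuracy
  ≈ 48%: Φ(0.7) − Φ(−0.7) ≈ 0.52 at the old/new cut). The generator knows
  nothing about dual-process vs signal-detection accounts; it is the
  minimal model producing the 5-point scale with tunable separation.
- **Brain–behavior link.** Effect voxels respond on every trial with
  amplitude γ₀ + γ₁·code (defaults 1 and 0.5 signal units) shaped by the
  generative kernel, plus a γ₀ test response; noise SD 1 gives a
  single-trial amplitude/noise ratio of order 1, a realistic event-related
  regime. Nuisance: per-run random cubic drift (SD 0.5), AR(1) motion
  series with N(0, 0.1) per-voxel loadings, baseline 100.
- **Geometry.** Default grid 20×20×12 at 1.5 mm isotropic — a desk-scale
  stand-in for a ~14k-voxel MTL field — with a central 3×3×3 effect block.
  Tests and the acceptance suite shrink the grid further (6×6×4 or 4×4×2)
  but never the temporal protocol; spatial extent is irrelevant to the
  estimators, which share one design across voxels.

What a green test does *not* establish: robustness to autocorrelated or
non-Gaussian noise, susceptibility/dropout artifacts, anatomical
variability, eye movements, or mis-specified HRFs. The generator convolves
with the same canonical HRF family the analysis uses, so HRF mismatch is
deliberately not exercised (except that analysis and generation can be
given different parameters explicitly).

## Numerical choices and degenerate inputs

- Drift regressors: the source description's linear drift sequence
  (−72.5 to 72.5 step 1) has 146 values for 144 time points and cannot be
  used as printed; each run instead uses the 144-length centered unit-step
  sequence (−71.5…71.5), with each power re-centered within run so every
  drift column sums to zero.
- HRF: "double gamma" left unparameterized in the source; the canonical
  parameterization (peak delay 6 s, undershoot delay 16 s, dispersions 1 s,
  ratio 6, 32 s support, peak-normalized) is the default and fully
  overridable. Regressors are built on a 16× oversampled grid, convolved
  per run, and decimated back to the TR grid.
- All-zero motion channels are flagged and dropped at assembly rather than
  left to break the rank check; any other rank deficiency is an error that
  names the collinear columns.
- Constant series z-score to zero via a variance floor (1e−12); single-trial
  categories report a missing uncertainty band rather than zero.
- Model-ranking ties break by listed model order (`ties.method = "first"`);
  with continuous misfits ties have probability zero.
- Seeds: every stochastic function takes an explicit seed; the pipeline
  derives stage seeds from one master seed, and datasets record theirs.

## Known limitations

- Plain OLS variances (no prewhitening) transfer to real data only under
  approximately white noise.
- The group model treats a subject's category coefficients as independent
  given the subject intercept; their small shared-design covariance is
  ignored, as in the standard summary-statistics approach.
- The permutation test assumes code exchangeability under the null beyond
  subject means; strong per-subject variance differences would favor the
  `within_subject` scheme.
- The PPC misfit scalar is a pragmatic ranking device, not a calibrated
  test statistic; flagged time points are descriptive.
- NIfTI support is the minimal single-file little-endian subset this
  pipeline writes; it is not a general-purpose reader.
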