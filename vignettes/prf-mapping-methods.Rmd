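---
title: "Population receptive field mapping with prfmapr: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population receptive field mapping with prfmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfmapr)
```

## The problem

Population receptive field (pRF) mapping estimates, for every sampled
cortical location ("vertex"), the region of visual space that drives its
aggregate BOLD response. The classical forward-model approach assumes a
two-dimensional Gaussian receptive field with center `(x, y)` (degrees of
visual angle, Cartesian, fixation at the origin), spread `sigma` and
response amplitude `beta`. Given a *stimulus aperture movie* — the binary
mask of stimulated visual-field locations on each acquisition volume — the
predicted response is the aperture/Gaussian overlap per volume, convolved
with the subject's hemodynamic response function (HRF). Fitting inverts
this prediction per vertex, and the fitted centers yield polar-angle and
eccentricity maps, pRF-size-versus-eccentricity curves, and visual-field
coverage plots.

prfmapr implements this pipeline end to end for the classic
wedge-and-ring mapping designs, together with a synthetic-cortex
generator: because the motivating case study's patient data are not
publicly available, the package's validation rests on simulated cortices
with known ground truth, where the pipeline's claims (parameter recovery,
lesion detectability, the masked-stimulus control artifact) can be tested
rather than assumed. The behavioral companion module implements the
corresponding bedside computations: a 32-position computerized perimetry
screen, a forced-choice blindsight screen scored with a binomial Bayes
factor, adaptive staircases, and a robust illusion-strength estimator.

## Stimulus designs

Two scanning-session presets are built in (`session_movies()`):

* **Session 1, wide field** (fov radius 37.5 deg): a 36-deg wedge stepping
  18 deg per 3-s volume (20 volumes = 60 s per rotation, 8 cycles per
  run), and rings whose mid-radii follow a logarithmic schedule in 16
  steps with 10 repetitions. Each run is padded with 20 end-of-run blank
  volumes and preceded by 3 discarded dummy volumes: 183 volumes, 549 s.
* **Session 2, narrow field** (fov radius 9 deg): 3 wedge cycles or 12
  ring steps with 5 repetitions, 15 blank volumes: 78 volumes, 234 s.

The wedge cycle count of the wide-field session is not stated explicitly
in the source design description; 8 cycles is the unique integer that
reproduces the printed 183-volume run total (8 x 20 + 20 + 3) and is used
as the default. Wedge and ring runs are generated as homogeneous runs and
concatenated for fitting — the printed totals are identical under either
decomposition of a mixed run.

Grid conventions: the aperture grid is 101 x 101 cells spanning
[-fov, +fov] (odd size puts a cell center at fixation); a cell belongs to
a shape iff its center does. Polar angle is measured counter-clockwise
from 3 o'clock; the wedge's leading edge starts at 90 deg (12 o'clock,
configurable — the source does not state it). Ring thickness follows the
geometric means between consecutive mid-radii, so consecutive mid-radii
keep a constant ratio and the rings tile the mapped annulus; the smallest
mid-radius defaults to 0.28 deg (no smallest radius is printed; this is
roughly the narrow-field fixation-dot radius rounded up to one grid
cell). The fixation region and the contrast-ramped annulus around it are
treated as stimulated — a binary aperture cannot represent ramped
contrast, a deliberate simplification.

`mask_region()` implements the scotoma-control stimulus model: frames are
multiplied by a keep-predicate over visual-field coordinates (e.g.
`keep_quadrant("upper-right")` zeroes everything with `x < 0 | y < 0`).
Masking is idempotent, and a mask that blanks the whole stimulus is legal
(with a warning) because a degenerate control model is still a valid
object to reason about.

## The two-gamma HRF

The HRF is a difference of two gamma-shaped kernels with exactly the four
free parameters named in the experimental method: amplitude, peak
latency, undershoot latency, and peak/undershoot ratio:

```
hrf(t) = A * ( g(t; t_peak) - g(t; t_under) / ratio )
```

where `g(t; tau)` is a gamma density with fixed shape `kappa = 6`,
rescaled to unit peak. We use scale `tau / (kappa - 1)`, which places the
kernel's mode *exactly* at `tau`: the peak-latency parameter is then
literally the time of the peak, which keeps the parameter interpretable
and makes the "numeric peak sits at the peak latency" property exact
rather than approximate. Defaults are A = 1, peak 5 s, undershoot 15 s,
ratio 6 — the conventional canonical shape.

Subject-specific estimation (`estimate_hrf()`) follows the event design:
the full-field run shows the stimulus for one volume (3 s) followed by
27 s of blank, ten times; each vertex's series is averaged across the ten
repetitions; vertices are kept as *responsive* when mean minus SEM,
averaged over the first half of the trial window, exceeds zero. The
per-volume-all-positive reading of that rule is stricter and rejects
noisy but genuinely responsive vertices, so the averaged form is the
default and the strict form is available via `rule = "per_volume"`. The
two-gamma is then least-squares fitted (Nelder-Mead on logit-bounded
parameters: peak in [2, 10] s, undershoot in [8, 25] s, ratio in [1, 20];
the bounds prevent the two kernels from swapping roles) to the grand
average over responsive vertices, optionally per hemisphere. If no vertex
passes the rule, the fit refuses with an explicit error rather than
returning a garbage kernel; callers fall back to the canonical defaults.

## pRF fitting: the forward model and the coarse-to-fine search

**Preprocessing.** Per run, the first three volumes are discarded, each
vertex series is linearly detrended and then z-standardized (mean 0,
sd 1); runs are concatenated. Zero-variance vertices are flagged
unfittable instead of raising.

**Prediction filtering.** Predictions receive exactly the same filtering
as the data: the aperture/Gaussian overlap is convolved with the HRF
sampled at TR (kernel truncated at 32 s, output trimmed to the run
length), then linearly detrended and z-standardized *per run*. Filtering
model and data identically is what makes a noiseless model-generated
series an exact fixed point of the fit (R-squared 1 at the true
parameters). It also resolves an identifiability subtlety: with per-run
standardized data, no single unstandardized amplitude can match two
concatenated runs of different stimulus types, so `beta` is defined as
the least-squares scale of the *standardized* prediction — a
dimensionless amplitude in z units (1 for a noiseless vertex).

**Coarse stage.** An extensive grid search on heavily smoothed data
maximizes the Pearson correlation between candidate prediction and
series, omitting `beta` (correlation is scale-free). The default grid
has 15 polar angles x 12 log-spaced eccentricities (0.1 deg up to 1.5x
the outer stimulus eccentricity — the search space deliberately extends
beyond the stimulus) x 8 log-spaced sigmas (0.25 deg to half the maximal
eccentricity). Grid density is not prescribed by the source method;
these defaults balance basin coverage against runtime. Degenerate
(constant-prediction) candidates score `-Inf`; exact ties resolve to the
first candidate in enumeration order (angle fastest, then eccentricity,
then sigma).

"Heavily smoothed" refers to smoothing along the cortical surface in the
original method. A synthetic cortex has no geometry by default, so
`smooth_timeseries()` accepts a neighbor-graph average when an adjacency
is supplied and otherwise falls back to a temporal moving average (width
3 TR). Temporal smoothing — unlike surface smoothing — distorts the
temporal profile, so in that mode the candidate predictions are filtered
with the same moving average before correlating: like is compared with
like. Because the correlation surface on smoothed data can rank a
neighboring basin first, `fit_prf()` re-ranks every grid candidate by
the fine objective itself (explained sum of squares with `beta`
profiled) to choose the fine-stage start; the coarse *result* remains
the correlation maximizer.

**Fine stage.** Derivative-free minimization of the summed squared
residuals on the unsmoothed series over `(x, y, log sigma)`, with `beta`
solved in closed form at every evaluation (profiling the scale is
exactly equivalent to searching over it, at a third of the
dimensionality). The search is deliberately *not* a single joint
Nelder-Mead descent: near — but off — the true center, shrinking sigma
mimics the series almost perfectly, creating a deep local basin adjacent
to the true one into which a joint descent reliably falls at high
eccentricity, where the coarse grid is widest. The center profile at any
fixed reasonable sigma is well behaved, as is the sigma profile at a
good center, so the fine stage refines coordinate-wise first — a
center-only simplex search at the start sigma, a global 1-D sigma search
(12-point log-grid bracket plus golden-section refinement), a center
polish — from two starts (the best candidate's sigma and a mid-range
sigma at the same center), and releases all three parameters to
Nelder-Mead (400 iterations, relative tolerance 1e-9, plus a short
restart) only from the better of the two. With this scheme a noiseless
200-vertex wide-field cortex is recovered to better than 0.01 degrees
everywhere. Sigma stays positive via the log parameterization; centers
beyond the search-space bound are penalized smoothly. R-squared is
`1 - SS_res / SS_tot`, clamped to [0, 1]; negative fitted amplitudes are
allowed but flagged.

## The synthetic cortex

`make_ground_truth()` builds a retinotopically organized vertex
population: areas V1-V3, ventral/dorsal, both hemispheres, with the left
hemisphere representing the right hemifield and dorsal areas the lower
quadrant. Within each area-quadrant, centers tile the quadrant
deterministically (golden-angle spiral, uniform in area, 2-deg margins
off the meridians) — no RNG is needed for the geometry, which keeps
ground truth reproducible by construction. pRF size grows linearly with
eccentricity, `sigma = mult * (0.5 + 0.1 * ecc)` degrees with multipliers
1 / 1.5 / 2 for V1 / V2 / V3. These are synthetic conventions chosen to
mirror the qualitative size-versus-eccentricity pattern of the empirical
literature, not estimates of any individual's parameters.

`simulate_timeseries()` inverts the fitting model: per vertex the
noiseless forward prediction over every frame of the movie, scaled to
unit per-run standard deviation (z units), plus iid Gaussian noise of a
chosen `noise_sd` (AR(1) correlation is available but off by default —
the analysis model assumes none, and the default emulates the
z-standardized regime the pipeline operates in). A *lesion* predicate
simulates a cortical scotoma: lesioned vertices keep their ground truth
for scoring but emit pure noise — absent response, not absent tissue.

What the simulation does *not* emulate: cortical magnification and
surface geometry, physiological noise structure (cardiac/respiratory,
drift beyond linear), voxel sampling and partial-volume effects, and
between-vertex noise correlation. Passing recovery tests therefore show
that the *pipeline* is correct and sensitive under its own model class,
not that real scanner data would behave as cleanly.

## What the validation suite establishes

All problem sizes below were chosen once as the package's benchmark
conditions and are recomputed from scratch by `scripts/acceptance.R` and
the acceptance tests:

* **Design arithmetic** — the run totals above are exact integer
  identities (183 volumes / 549 s, 78 / 234 s, 20 frames / 60 s per
  wedge cycle, 64 perimetry trials, 9.375-deg ring spacing).
* **Round trip at zero noise** — 200 vertices under the wide-field
  two-run design: fitted centers within 0.05 deg, sigma within 5%,
  R-squared at least 0.999 per vertex.
* **Noise robustness** — the same cortex at `noise_sd = 0.5`: the
  recovery report's position RMSE and sigma truth-fit correlation are
  recomputed and reported. Note an intrinsic limit: with a 36-deg wedge
  stepping 18 deg per 3-s volume, ring steps on a log schedule, 360
  analysis volumes and sigma up to ~7.5 deg in simulated V3, the
  maximum-likelihood position error at this noise level is on the order
  of a degree for the largest, most eccentric pRFs (initializing the
  optimizer at the truth changes nothing — the likelihood optimum itself
  sits there). Sub-half-degree RMSE is achieved by the small-sigma,
  mid-eccentricity population (simulated V1), not by the pooled
  population.
* **Null calibration** — a pure-noise cortex: at 360 volumes the
  fine-stage R-squared stays below the 0.05 map threshold for at least
  95% of vertices, so the threshold used for map display is a genuine
  false-positive control.
* **Lesion detectability** — a 25% simulated scotoma (one visual
  quadrant silenced) is detected by sub-threshold R-squared with
  sensitivity and specificity above 0.9. This is the substantive point
  of the synthetic module: since the pipeline demonstrably *can* see a
  cortical scotoma, finding normal maps on intact input is an
  informative negative, not a blind spot.
* **Masked-stimulus control** — fitting a full-field-responsive cortex
  with an upper-right-only stimulus model displaces the majority of
  opposite-quadrant vertices out of their true quadrant, reproducing the
  known artifact pattern (estimates dragged toward the remaining
  stimulus, including into the ipsilateral-like hemifield).
* **Oracles** — the coarse stage agrees exactly with a naive exhaustive
  reimplementation; the closed-form binomial Bayes factor agrees with
  numerical integration to 1e-10 across all `k <= n <= 200`; 1-down/1-up
  and 2-down/1-up staircases converge to the simulated observer's 50%
  and 70.7% points.

## Behavioral computations

* **Perimetry screen** (`make_vf_session()`, `score_vf()`): 4 rings x 8
  sectors x 2 repetitions (one present, one absent) = 64 trials in
  seeded pseudo-random order. A position counts as intact only when the
  present trial was detected *and* the absent trial rejected — the
  source bookkeeping describes only false positives/negatives, so the
  conjunction rule is the package's (documented) classification choice.
* **Blindsight Bayes factor** (`bf01_binomial()`): two-sided by default
  with a uniform prior, closed form
  `(n+1) C(n,k) p0^k (1-p0)^(n-k)`; one-sided variants via truncated
  Beta marginals. The published per-run Bayes factors cannot be
  reproduced exactly because per-location trial counts are not printed;
  the implementation is validated against numerical integration instead.
* **Staircases** (`staircase()`, `staircase_step()`): transformed
  up-down rules with a reversal recorded at the pre-change level and the
  step size switching after the fifth reversal (the move that *creates*
  the fifth reversal still uses the large step — the switch applies
  "afterward").
* **Illusion strength** (`illusion_strength()`): reversals outside
  median +/- 2 MAD are discarded and the survivor mean returned. The MAD
  is the raw median absolute deviation (no 1.4826 consistency factor —
  the filter is a symmetric robust gate, not a normal-scale estimate),
  and boundary values are retained; with identical reversals (MAD 0) the
  estimate is that common value. Reversals from interleaved staircases
  are pooled before filtering.

## Known limitations

* Only the isotropic single-Gaussian pRF is implemented — no
  difference-of-Gaussians surround, no compressive spatial summation.
* Binary apertures cannot represent the ramped-contrast fixation annulus
  or the carrier pattern; only aperture geometry informs the model.
* ROI labels are supplied externally (the synthetic cortex ships its
  own); polar-angle-reversal boundary detection is out of scope.
* The fine stage is a local search: it is only as good as its coarse
  init, which is why the init refinement above exists. Pathological
  series can still converge to local optima; `r_squared` and flags are
  the diagnostic surface.
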