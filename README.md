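# prfmapr

Forward-model **population receptive field (pRF) mapping** in R, with a
synthetic retinotopic cortex for validation, and the behavioral
computations that accompany a visual-field case study (computerized
perimetry, a binomial Bayes-factor blindsight screen, adaptive
staircases, a robust illusion-strength estimator).

## Who this is for

Visual neuroscientists and methodologists who want a tested, scriptable
implementation of the classical Gaussian-pRF pipeline — and, just as
importantly, a way to *prove what the pipeline can and cannot detect*.
The motivating scenario is a patient with severe perimetric visual-field
loss whose retinotopic maps look normal: that negative finding is only
meaningful if the same pipeline demonstrably detects a cortical scotoma
when one is present. The synthetic-cortex module makes that
demonstration reproducible without any scanner data.

## The model

Each cortical vertex is summarized by a 2-D Gaussian receptive field
with center (x, y) and spread σ (degrees of visual angle) and amplitude
β. Given the binary stimulus aperture A_t (one mask per acquisition
volume) the predicted BOLD series is

    p_t = Σ_cells A_t(cx, cy) · exp(−((cx−x)² + (cy−y)²) / 2σ²)
    prediction = z( detrend( p * hrf ) )   per run, sampled at TR

with the HRF a two-gamma kernel (amplitude, peak latency, undershoot
latency, peak/undershoot ratio — estimated per subject from a 3 s
on / 27 s off full-field run). Fitting is coarse-to-fine: an extensive
grid search maximizing the Pearson correlation on smoothed data
(β omitted), then Nelder–Mead least squares on the unsmoothed series over
(x, y, log σ) with β solved in closed form. Fits are summarized as
polar-angle/eccentricity maps thresholded at R² ≥ 0.05, visual-field
coverage (the sum of unit-peak pRF profiles), and eccentricity-binned
curves of σ, β and R².

The built-in designs reproduce a two-session wedge-and-ring protocol:
wide field (37.5° radius; 36° wedge stepping 18° per 3-s volume, 8
cycles; 16 log-spaced ring steps × 10 reps; 183 volumes = 549 s per run)
and narrow field (9° radius; 3 cycles / 12 steps × 5 reps; 78 volumes =
234 s), plus a quadrant-masked control stimulus model for scotoma
artifact analysis.

## Worked example

Simulate a narrow-field session on a 48-vertex synthetic cortex, fit it,
and score recovery against the ground truth:

```r
library(prfmapr)

mv    <- session_movies(2, grid_n = 61)      # narrow-field (9 deg) designs
hrf   <- two_gamma_hrf()
truth <- make_ground_truth(48, max_ecc_deg = 9)
ts    <- simulate_timeseries(truth, mv$mapping, hrf, noise_sd = 0.5, seed = 7)
pre   <- preprocess_timeseries(lapply(mv$mapping$meta$runs,
                                      function(r) ts[, r]))
fits  <- fit_prf(pre$series, mv$mapping, hrf, unfittable = pre$unfittable)
recovery_report(truth, fits, threshold = 0.05)
#> <recovery_report> 48 vertices scored (R2 >= 0.05)
#>   parameter     bias   rmse correlation
#> 1         x -0.03036 0.2634      0.9985
#> 2         y  0.03507 0.3220      0.9977
#> 3     sigma -0.01151 0.3043      0.8550
#>   position RMSE: 0.416 deg
```

Every simulated vertex is recovered above threshold; centers come back
within a fraction of a degree at this noise level (signal sd 1, noise sd
0.5), and fitted σ tracks the built-in σ-versus-eccentricity law. Map
summaries follow the same grammar:

```r
map   <- retinotopic_map(fits, threshold = 0.05,
                         roi = truth[, c("vertex", "area")])
bin_by_eccentricity(threshold_map(map), "sigma_deg",
                    band_edges = seq(0, 9, by = 3))
#>   band ecc_lo ecc_hi ecc_mid  n mean   sem
#> 1    1      0      3     1.5  0   NA    NA
#> 2    2      3      6     4.5 24 1.48 0.107
#> 3    3      6      9     7.5 22 1.79 0.118
```

(The innermost band is empty for this small cortex and is reported as
missing, not zero.) `run_pipeline(pipeline_config(...))` chains the whole
thing — apertures → simulation → HRF estimation → pRF fits → maps,
coverage, recovery report — into a reproducible artifact directory, and
`mask_region(movie, keep_quadrant("upper-right"))` builds the
scotoma-control stimulus model.

Behavioral one-liners:

```r
bf01_binomial(5, 10)$bf01                      # 2.707 — evidence for chance
illusion_strength(c(0.18, 0.20, 0.22, 0.90))   # 0.20 — MAD filter drops 0.90
nrow(make_vf_session(seed = 1))                # 64 perimetry trials
```

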