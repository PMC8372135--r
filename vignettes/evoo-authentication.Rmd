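---
title: "Authenticating extra virgin olive oil by multi-sensor one-class fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating extra virgin olive oil by multi-sensor one-class fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoofuse)
```

## The screening problem

Extra virgin olive oil (EVOO) commands a premium over refined olive oils
(RVOO), olive-pomace oil (OPO) and ordinary seed oils, which makes dilution
of EVOO with cheaper oils a recurring fraud. Portable devices that measure
several optical fingerprints of the same cuvette — fluorescence emission
under 365 nm excitation (FLUO), visible diffuse transflectance (VIS) and
near-infrared transflectance (NIR) — allow non-invasive screening, but no
single channel is reliable on its own: fluorescence and colour carry the
pigment signature (pheophytin *a*'s Soret band at 400–500 nm and q-band at
600–700 nm) yet admixtures of translucent oils dilute it only gradually,
while NIR mostly reflects the triglyceride macro-composition that all edible
oils share.

`evoofuse` implements the data-analysis side of such a screener as a
one-class problem: models are trained on authentic EVOO only, every model
emits a nonnegative *class distance* (larger = less EVOO-like), and a sample
is flagged as non-EVOO when at least `min_votes` (default 2) of the selected
models vote "out-of-class". Training on the target class alone means the
screener does not need to enumerate all possible adulterants.

## Pipeline

1. **Spectral reduction** (`process_run()`): per measurement run, scans are
   screened for detector saturation (a plateau of `min_run = 3` points at
   the ceiling; a run is discarded for a sensor when more than half of its
   scans are flagged), averaged pointwise, dark/white reference corrected —
   `(scan − dark)/(white − dark)` for VIS/NIR, `scan − dark` for FLUO, which
   has no meaningful white standard — and trimmed to the usable window
   (NIR 1020–1833 nm, i.e. 814 of 895 one-nanometre pixels; VIS 400–740 nm;
   FLUO 340–780 nm).
2. **Preprocessing grid** (`enumerate_model_grid()`): SNV, SNV + quadratic
   detrend, Savitzky–Golay 1st/2nd derivatives (11-point window, quadratic
   polynomial — the minimal degree exact for both orders), and wavelet
   detail features (interpolation to 128 points, then a periodized
   orthonormal DWT: Haar levels 5–7 giving 7 coefficients, or the
   least-asymmetric length-8 filter, levels 3–5, giving 28), each applied to
   the full spectrum or to one of four equal-length sections (splitting
   first, each section modelled separately). The default grid is
   6 preprocessings × (full + 4 splits) × 5 algorithms = 150 combinations
   per sensor; the grid is configuration-driven rather than fixed.
3. **One-class algorithms** (`occ_fit()`): SIMCA (combined normalized
   orthogonal distance q and score leverage h, `d = sqrt((q/q0)² +
   (h/h0)²)`), kNN mean neighbour distance, PCA Q-residual, Mahalanobis
   distance with covariance shrinkage `Σ + λ·tr(Σ)/p·I` (spectra have far
   more wavelengths than EVOO training samples, so the raw covariance is
   singular; λ = 1e-3 by default), and a ν-one-class SVM with RBF kernel
   (ν = 0.1; gamma from the median heuristic `1/(2·median ‖xᵢ−xⱼ‖²)`), whose
   distance is the decision-function deficit `max(0, ρ − f(x))`.
4. **Ranking and selection** (`rank_model_grid()`, `rank_and_select()`):
   EVOO samples are split 0.8/0.2 at the *sample* level (all nine
   measurements of a sample travel together — the leakage audit in the
   result asserts this), hyperparameters are chosen by grouped 5-fold inner
   cross-validation, held-out EVOOs and all other samples are scored,
   distances are averaged per sample, and each model gets three AUROCs: EVOO
   vs lower-quality olive oils (RVOO + OPO), vs other edible oils, and vs
   adulterated EVOOs. Models are ranked by the unweighted mean of the three
   and the top 6 FLUO / 2 VIS / 2 NIR models are kept.
5. **Fusion and thresholds** (`tune_thresholds()`, `decide_samples()`):
   per-sample distances (mean over replicates, thresholded once) are turned
   into votes; the boundary counts as in-class. Scenario 1 sets each model's
   threshold just above (factor `1 + 1e-6`) the largest calibration-EVOO
   distance, so zero calibration EVOOs can vote out and the fused EVOO rate
   is 100% *by construction*. Scenario 2 searches a common quantile of each
   model's calibration-EVOO distances (grid 0.50–1.00 in steps of 0.01) and
   maximizes the fused detection rate of adulterated calibration samples
   subject to a fused EVOO correct rate of at least 0.75, preferring higher
   EVOO rates and then lower quantiles on ties; an infeasible floor falls
   back to scenario 1 with a warning.

## The synthetic study generator

No spectra of the original oil panel are publicly available, so the package
ships a generator (`study_design()`, `generate_study()`) that emulates the
study conditions and makes every downstream stage testable end to end:

* 16 EVOO, 32 RVOO, 9 OPO and 12 other edible oils, plus 20 EVOO admixtures
  with non-EVOO olive oils and 40 with other oils at 10/25/50% (v/v) — 129
  samples, each measured nine times (triplicate on three days), i.e. 1161
  measurement runs with 10 VIS + 10 FLUO + 255 NIR scans each.
* Class archetypes are sums of Gaussian bands. EVOO has the dominant q-band
  (strictly its largest FLUO band) and low between-sample variability
  (CV 0.08); refining/pomace processing degrades the pigments by 70–80%
  with high heterogeneity (CV 0.30–0.35); non-olive oils keep at most 5% of
  EVOO's q-band. NIR archetypes share identical overtone bands with only
  small (2–3.5%) class offsets, so NIR models are weak by construction.
  Individual oils perturb band amplitudes by lognormal factors of the class
  CV; admixtures mix latent spectra linearly in the volume fraction.
* A measurement run adds a dark baseline, a smooth illumination profile for
  the white-referenced VIS/NIR paths, i.i.d. Gaussian detector noise and a
  ±2% per-(sample, day) multiplicative drift factor standing in for storage
  degradation. Exactly 122 FLUO and 90 VIS runs are over-exposed and clipped
  at the 16-bit ceiling so the saturation filter removes them
  (1161 − 122 = 1039 and 1161 − 90 = 1071 retained). Noise, drift and CV
  magnitudes are free parameters with defaults chosen to give a realistic
  but solvable problem; the real instrument's values are not documented
  anywhere.
* Reproducibility: one root seed; each oil, admixture and run derives its
  own stream by hashing (seed, id, replicate), so any subset regenerates
  identically (`derive_seed()`).

What the generator does **not** emulate: asymmetric pigment band shapes,
fluorescence inner-filter effects in mixtures (mixing is linear by design),
the instrument's nonlinear pixel-to-wavelength calibration (grids are
uniform, so the VIS/FLUO used windows do not reproduce the published
155/201 pixel counts), and geographic-origin structure. Passing tests
therefore demonstrate the correctness of the machinery and the qualitative
behaviour of the method, not field performance on real oils.

## Numerical and design choices

* Trimming uses closed intervals (both endpoints kept); grids are stored
  explicitly and never assumed uniform outside the generator.
* The degenerate-reference floor for `white − dark` is 1e-9 detector units.
* Savitzky–Golay edges are dropped (output 10 points shorter), not padded:
  padding would fabricate boundary data.
* The DWT uses periodic boundaries at dyadic length 128 and returns detail
  coefficients only; "filter length 2" is read as the Haar wavelet and
  "least asymmetric, length 8" as symlet-4.
* Inner CV minimizes the mean held-out EVOO class distance with ties going
  to the lower complexity. For the raw PCA Q-residual this criterion cannot
  penalize extra components (held-out residual norms shrink monotonically
  as components are added — the naive-PRESS property), so component choice
  for that algorithm is effectively "largest candidate"; SIMCA's leverage
  term gives it a genuine CV minimum. The AUROC ranking stage, not the
  inner loop, decides which models are ultimately used.
* A grid of 150 models per sensor is enumerated by default. The published
  grid size (149) is prime and cannot be a full Cartesian product of the
  listed options; rather than imitating an unknown exclusion, the grid
  documents its own count.
* "Selected manually from the highest AUROCs" is replaced by a
  deterministic per-sensor quota top-k rule (ties to the lexicographically
  smaller key) so selection is reproducible.
* The final decision stage scores pure-EVOO samples out-of-fold (grouped
  5-fold) and everything else with the model fitted on all EVOO
  measurements; scenario-1's threshold rule then guarantees the 100% EVOO
  rate on exactly the distances used in the rate table.
* Single-sensor rate-table columns re-run the identical fusion machinery on
  the sensor's subset of selected models with the vote minimum rescaled as
  `max(1, round(min_votes · n_sensor / n_total))`.
* Whether adulterated samples enter ranking jointly over all mixture levels
  or per level is an open choice; they enter jointly here.

## Problem sizes used by the shipped checks

The test suite exercises the full default design (129 samples, 1161 runs)
once with a compact full-spectrum grid (2 preprocessings × 5 algorithms per
sensor, 2 outer repeats) and uses reduced-resolution sensors (113 NIR / 96
UV-Vis pixels) and a small oil panel for the per-module tests. The
acceptance script runs the default design with the full 150-model grid and
5 outer repeats. These sizes are the package's own choices for routine
verification; all of them are configuration, not constants.

## A short run

```{r example, eval = FALSE}
design <- study_design(seed = 1L)
res <- run_authentication_study(
  design,
  grid = enumerate_model_grid(preprocess = list("snv", "sg1"), splits = NA),
  n_repeats = 2L)
res$rate_tables$S1   # scenario 1: no false-negative EVOOs
res$rate_tables$S2   # scenario 2: fraud screening
res$detection$S2     # detection rate by adulteration fraction
```

## Known limitations

One-class calibration happens on the same synthetic panel it is evaluated
on (the study has no external validation set, matching the original design);
the scenario-2 search procedure is a reconstruction — the outcome tables are
reported in the source study but not the search itself; and the
reference-chemistry checker (`check_reference_limits()`) only tabulates
conformity against the regulatory EVOO limits, it does not model the wet-lab
assays.
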