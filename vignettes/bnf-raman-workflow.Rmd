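---
title: "Estimating biological nitrogen fixation from leaf Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating biological nitrogen fixation from leaf Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biological nitrogen fixation (BNF) — the fraction of a legume's nitrogen
derived from atmospheric N~2~ via rhizobial symbiosis, expressed as %BNF —
is conventionally quantified by ^15^N isotope-dilution mass spectrometry,
which is destructive, slow and expensive. Leaf Raman spectroscopy offers a
non-destructive alternative: fixation alters the plant's metabolite pools
(amino acids, glycerol, nucleobases, cell-wall carbohydrates), and those
metabolites have characteristic Raman bands. The catch is confounding:
nitrogen *availability* also changes leaf chemistry — most visibly the
strong pectin/carotenoid bands near 747, 1160 and 1525 cm^-1^ — so a naive
calibration risks measuring nitrogen status rather than fixation.

`ramanbnf` implements the full chemometric workflow: spectral
preprocessing, partial least squares regression (PLSR) calibration with
VIP-based peak selection, and an elastic-net regularisation step whose
penalty strength is chosen — nonstandardly — to minimise the predicted
%BNF of a *non-fixing control set*, making the calibration specific to
fixation. A synthetic-data generator emulating the fixing/non-fixing
greenhouse design makes every stage testable without any external data.

## The experimental design being emulated

Two sets of soybean plants: a *fixing* set inoculated with
*Bradyrhizobium japonicum*, and a *non-fixing* set grown sterile. Both are
crossed with four nitrogen treatments (2, 6, 10, 14 mM ammonium nitrate),
five replicate plants each, with three Raman acquisitions per plant
(400–1800 cm^-1^). Fertiliser nitrogen suppresses fixation, so the fixing
set spans a wide %BNF range; ground truth comes from ^15^N isotope
dilution (`ndfa_from_isotope()`): fixation of unenriched atmospheric N~2~
dilutes the ^15^N label relative to a non-fixing reference.

The non-fixing set truly fixes nothing, so any %BNF the model predicts for
it is leakage of nitrogen-availability signal — which is exactly what the
regularisation stage exploits.

## The synthetic-data generator

`synthetic_config()` / `generate_dataset()` simulate each acquisition as

* a broad fluorescence background (Gaussian hump plus linear ramp — leaf
  tissue under 785 nm excitation is fluorescence-dominated), with a small
  per-spectrum amplitude jitter;
* a sum of Lorentzian bands (the Raman-typical line shape): fifteen
  BNF-linked bands at the literature wavenumbers (674–1426 cm^-1^) whose
  amplitudes scale with the plant's %BNF, and three strong
  nitrogen-status bands (747, 1160, 1525 cm^-1^) scaling with the plant's
  effective nitrogen status;
* per-plant biological variability: a common scattering-efficiency factor
  (`scatter_jitter_sd = 0.06`; leaf thickness and laser coupling scale
  all bands together, which is also why the feature set is strongly
  collinear) and independent per-band amplitude jitter
  (`band_jitter_sd = 0.04`);
* additive Gaussian detector noise (`noise_sd = 25` counts) and Poisson
  cosmic-ray spikes for the despiking stage to remove.

The wavenumber grid is anchored at 600 cm^-1^ with step
(1770 − 600)/1096 cm^-1^ so the standard 600–1770 cm^-1^ analysis window
holds exactly 1097 channels.

Nitrogen status of the two sets is modelled asymmetrically, and this is
the scientifically load-bearing choice. Non-fixing plants track their
fertiliser treatment (2–14 mM). Fixing plants, sampled at six weeks when
the symbiosis fully supplies their demand, are *saturated* at a uniform
status (default 14 mM-equivalent), so within the fixing set the
nitrogen-status bands carry essentially no information about %BNF — yet
the calibration still couples to them, because the unpenalised fit uses
the strong carotenoid bands as an internal reference for the common
scattering factor. On control plants, whose carotenoid bands sit well
below the saturated fixing level and vary with treatment, that coupling
surfaces as a positive, nitrogen-correlated %BNF prediction — the leakage
the elastic net then removes. Alternative modes (`"residual"`,
`"tracking"`, and a `fixation_overshoot_mM` knob) are provided for
robustness experiments.

Per-plant %BNF is a treatment mean (85/60/35/15 % at 2/6/10/14 mM) plus
Gaussian between-plant jitter (SD 5), truncated to [0, 100]; non-fixing
plants are exactly 0. Each plant owns a deterministic child seed derived
from the root seed, so datasets are reproducible and extensible plant by
plant.

Effect sizes (`bnf_effect_size = 0.02` per %BNF unit,
`nitrogen_effect_size = 0.04` per mM) were calibrated once so that the
generated data reproduce the qualitative behaviour of real greenhouse
data — leave-one-out R² near 0.95 with one or two factors, a control-set
mean prediction of order 10–20 %BNF before regularisation, and a strict
improvement of the control objective at a positive penalty — and then
frozen. What passing tests on these data show is that the *pipeline*
behaves correctly under the assumed statistical structure; they cannot
show that real leaf spectra contain a BNF signal, that the Lorentzian/
additive model is chemically faithful, or that the saturation assumption
holds in any particular experiment.

## Preprocessing

Per acquisition, in order (`preprocess_pipeline()`):

1. **Despiking** (`despike()`): rolling-median filter (window 7 points),
   replacing points whose positive deviation from the local median
   exceeds 8 robust SDs (1.4826 × rolling MAD); screening repeats to a
   fixed point so the filter is idempotent. Single-spectrum despiking was
   chosen because the three measurements are taken at slightly different
   spots, making cross-replicate consensus unsafe.
2. **Savitzky–Golay smoothing** (`savgol_smooth()`): polynomial order 13,
   frame 51 points. At this order a raw-monomial design matrix is
   numerically singular, so the filter is built from an orthogonal
   polynomial basis with a QR projection; polynomial signals up to degree
   13 are reproduced exactly, and edge half-frames are smoothed with the
   boundary-anchored frame fit. The frame length is interpreted in grid
   points, the usual Savitzky–Golay convention.
3. **Baseline subtraction** (`baseline_ima()`): iterative moving-average
   baseline — starting from the spectrum, each of 50 iterations replaces
   the estimate by the pointwise minimum of itself and its 50 cm^-1^
   moving average. Broad fluorescence survives the averaging; narrow
   bands are planed off. The kernel is specified in cm^-1^ and converted
   to an odd number of grid points (≈47); boundary windows shrink rather
   than pad, avoiding edge droop. On known-truth fixtures the recovered
   baseline is accurate to ~1% RMS of the background amplitude and
   corrected peaks keep ≥97% of their height.
4. **Cropping** to the closed 600–1770 cm^-1^ window (1097 channels).
5. **Averaging** the three corrected spectra per plant
   (`average_measurements()`). Averaging after correction is the default;
   `average_before_baseline` flips the order for sensitivity analyses.

No normalisation is applied by default (`normalisation = "none"`): the
absolute intensity scale carries calibration information, and SNV/area
options are provided only for comparison.

## Calibration: PLSR, LOOCV, VIP

Peaks are detected on the mean corrected fixing-set spectrum as local
maxima with topographic prominence at least 2% of the spectrum maximum
(`detect_peaks()`); each feature is the windowed maximum (±2 cm^-1^) of
the corrected intensity at a peak (`extract_peak_features()`), tolerant
of small centre shifts. Overlapping bands (e.g. 695/704/713/726) merge
into single candidate features; this mirrors real spectra, where the
candidate table is coarser than the underlying band structure.

`fit_plsr()` implements single-response NIPALS PLSR on mean-centred,
unscaled features. Cross-validation is leave-one-out at the plant level
(`loocv_plsr()`), refitting from scratch in every fold; the optimal
factor count is the smallest whose validation R² is within 0.01 of the
maximum (a parsimony rule; the data rarely justify more than two
factors). Variable importance in projection (`vip_scores()`) satisfies
the identity ΣVIP² = P; features scoring below 1 are dropped and the
model refitted on the retained peaks. The VIP selection is not nested
inside the cross-validation, a deliberate match to common chemometric
practice and a documented source of optimism in the reported validation
R².

## Specificity: control-targeted elastic net

The elastic net minimises

J(β) = (1/2N) Σᵢ (yᵢ − β₀ − xᵢᵀβ)² + λ·P~α~(β),
P~α~(β) = (1−α)/2·‖β‖₂² + α·‖β‖₁,

with α = 0.5 (equal L1/L2 balance) and an unpenalised intercept, solved
by cyclic coordinate descent with soft-thresholding (`fit_enet()`;
deterministic fixed update order, convergence when the largest
coefficient change falls below 1e-8). The penalty is placed outside the
1/(2N) bracket — the standard convention, making λ comparable across
sample sizes — with a `lambda_inside_bracket` flag for the literal
alternative, which is the same family under λ → λ/(2N). The solver is
validated against the normal equations at λ = 0, a brute-force grid on
two-feature problems, and an independent convex solver (glmnet) to ~1e-9.

`regularisation_path()` fits the elastic net on the *full candidate peak
table* of the fixing set over a grid of 0 plus 40 log-spaced λ values up
to the full-shrinkage λ, warm-starting along the path, and records the
mean predicted %BNF of the non-fixing control set at each λ. λ* is the
grid value minimising that control output, ties broken toward smaller λ
(`select_lambda()`); control predictions are not clipped at zero during
selection (clipping would flatten the objective) and only at reporting.
This is explicitly *not* cross-validated λ selection: the tuning
objective is specificity, not validation error, and it deliberately
trades some fixing-set R² away.

Key wavenumbers (`select_key_wavenumbers()`) are features whose
regularised coefficient magnitude exceeds 0.1 *and* whose magnitude
dropped by more than 10% relative to λ = 0. As printed, this rule
excludes features whose coefficients grow under regularisation; an
`include_increases` flag admits them. At the default study conditions λ*
often sits in the strongly sparse regime where few coefficients clear the
0.1 magnitude threshold, so the key set is small (frequently empty at
some seeds) — an honest consequence of applying the literal rule to this
data scale, discussed rather than hidden.

## Numerical and design choices

* Grid anchoring at 600 cm^-1^ guarantees the 1097-channel window
  regardless of the acquisition range chosen.
* Zero-variance features are pinned at coefficient 0 in the coordinate
  descent rather than producing 0/0.
* NIPALS stops early (with a warning) when the deflated matrix runs out
  of rank; LOOCV caps the factor count at the per-fold rank.
* The moving average uses cumulative sums (O(n) per iteration) and the
  despike filter recomputes its statistics per pass; both operate on the
  uniform grid only and refuse non-uniform input.
* Determinism: every random draw descends from the configuration seed;
  reports carry no timestamps, so byte-identical reruns are testable.
* Problem sizes in the test suite: the full default design (40 plants,
  120 spectra, 1097 channels) is exercised in the end-to-end tests;
  unit tests use a unit-step grid with four well-separated bands so that
  band centres lie exactly on grid points.

## Known limitations

* The generator's additive Lorentzian model omits peak-position shifts,
  band-shape changes, detector nonlinearity and fluorescence
  photobleaching; real spectrometer grids are also slightly non-uniform.
* The saturation assumption for fixing plants is an idealisation; the
  `residual` and `tracking` modes bound the alternatives but real
  residual-deficiency structure may differ.
* VIP-then-refit without nesting inflates validation R²; treat reported
  LOOCV values as optimistic.
* λ* selection inherits the control set's sampling noise; with only 20
  control plants the selected λ varies considerably between seeds even
  though the qualitative dip is stable.
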