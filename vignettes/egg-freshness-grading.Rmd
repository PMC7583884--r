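---
title: "Grading egg freshness from scattering hyperspectral images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading egg freshness from scattering hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovospec)
```

## The problem

The freshness of a table egg is quantified by the Haugh unit,

$$HU = 100 \log_{10}\!\left(h + 7.57 - 1.7\,w^{0.37}\right),$$

where $h$ (mm) is the thick-albumen ("protein") height and $w$ (g) the egg
weight. Measuring $h$ requires breaking the egg, so non-destructive grading
from hyperspectral images is attractive. Under storage at room temperature
the Haugh unit falls almost linearly, about $-1.75$ units/day from a day-zero
value near $85.7$, and eggs are graded by storage week: AA (week 1),
A (week 2), B1 (week 3), B2 (week 4). Spoiled eggs beyond four weeks are
trivially recognizable and are outside the scope of the grading pipeline.

The imaging geometry matters. A camera above the egg can record dome-source
*reflection* (mostly shell information), *transmission* (interior information
diluted by raw source light), or fiber-optic *scattering* at incident angles
0-60 degrees. At 0 degrees the camera captures mostly light that propagated
through the interior (yolk, albumen, air chamber) and is therefore most
informative about freshness; as the angle grows, surface reflection
increasingly displaces interior scattering. `ovospec` implements the whole
grading workflow and makes this angle dependence a measurable property of
synthetic data rather than an assumption.

## The pipeline

1. **Synthetic scenes** (`simulate_cohort()`, `render_scene()`) — cohorts of
   eggs with HU-driven spectra per acquisition mode, and small image cubes
   with white/dark reference frames.
2. **Reflectance correction** (`black_white_correct()`) —
   $R = (I_0 - I_b)/(I_w - I_b)$ per pixel and band.
3. **ROI extraction** (`egg_mask()`, `roi_mean_spectra()`) — Otsu threshold,
   morphological closing, connected components, ellipse fit, per-egg mean
   spectrum.
4. **Preprocessing** (`preprocessor()`, `pp_fit()`, `pp_transform()`) — ten
   chemometric methods with a leak-free fit/apply contract.
5. **Wavelength selection** (`pca_reduce()`, `spa_select()`, `cars_select()`)
   — over a PLS1 core (`pls_fit()`).
6. **Classification** (`classifier_spec()`, `run_grid()`) — six weak
   classifiers swept over preprocessing x selection x mode.
7. **Stacking** (`oof_meta_features()`, `stack_ensemble()`) — two-layer
   ensemble with out-of-fold meta-features.
8. **Reporting** (`run_experiment()`, `angle_accuracy_curve()`) — accuracy
   versus incident angle.

## The synthetic-data model

Real spectra of the original 280-egg study were never deposited, so the
generator is a first-class, tested component that emulates the statistical
structure the analysis needs.

**Cohort model.** On storage day $d$, each egg draws
$HU = 85.70 - 1.75\,d + \varepsilon$, $\varepsilon \sim N(0, 4^2)$, a weight
uniform on 31.5-46.6 g, and a protein height back-solved from the Haugh
formula, so the formula round-trips exactly. The grade label is the storage
week. The noise sd 4.0 sits inside the observed weekly sds (3.6-5.5) of the
reference cohort.

**Spectral model.** A spectrum under mode $m$ is a three-endmember mixture

$$v(\lambda) = \alpha_m S_{int}(\lambda; HU) + (1-\alpha_m-\beta_m)
S_{shell}(\lambda) + \beta_m S_{src}(\lambda),$$

then distorted by a multiplicative gain $b \sim N(1, 0.10^2)$, an additive
offset $a \sim N(0, 0.05^2)$ and per-band noise $N(0, 0.01^2)$; negative
values are clipped at 0 (rare at these levels, and SNV/MSC are insensitive to
rare clips). Only the interior endmember carries freshness information:
Gaussian peaks at 450, 550, 680, 980 nm whose amplitudes are affine in
$(HU-60)/30$ with alternating signs. The interior fraction $\alpha$ encodes
the acquisition physics phenomenologically: $\alpha = 0.9$ at 0 degrees,
decaying linearly to $0.3$ at 60 degrees; $\alpha = 0.05$ for dome
reflection; $\alpha = 0.45$ with a source-bleed $\beta = 0.35$ for
transmission. 256 bands over 400-1000 nm stand in for the VNIR camera at
desk scale.

**Choosing the freshness contrast.** The one free constant with real leverage
is the per-unit-HU peak amplitude (`peak_haugh_amplitude`, default 0.013).
It was fixed a priori by a matched-filter argument: with ~43 effective
informative band-samples and per-band noise 0.01, the spectral HU-readout
error at the best geometry ($\alpha = 0.9$) is
$\sigma_{spec} \approx 0.046/(0.013 \cdot 0.9) \approx 4$ HU — that is, at
0 degrees the spectra predict HU about as well as published VNIR reflectance
calibrations (correlation $r \approx 0.93$). Because
$\sigma_{spec} \propto 1/\alpha$, the readout degrades smoothly with angle
(about 12 HU at 60 degrees) and collapses for reflection (about 70 HU,
near-chance), which is precisely the qualitative structure the angle report
is meant to detect.

**What the generator does not emulate.** No radiometric realism (no source
spectrum, no shell-pigment chemistry, no SWIR range), no conveyor motion, no
egg-shape variation; the scatter distortions are i.i.d. per spectrum rather
than correlated within a day or a hen. A green test therefore establishes
that the *pipeline* behaves correctly on data with the stated statistical
structure — not that the original instrument would reproduce any particular
accuracy figure.

## Two structural ceilings worth knowing about

Both follow from the stated world and are visible in the package's own
output.

*The label ceiling.* Ground truth is the storage week, but the spectra (like
the real measurement) encode the Haugh unit. Adjacent days differ by 1.75 HU
while the per-egg spread is 4 HU, so eggs near week boundaries are genuinely
ambiguous: even a perfect HU readout cannot classify weeks beyond roughly
81% accuracy (sum of boundary-crossing probabilities over the 28 days). Desk-
scale accuracies in the high 70s/low 80s at 0 degrees are therefore the
expected ceiling, not a defect — and far above the 25% chance level.

*The low-angle near-tie.* Because $\sigma_{spec}(\alpha) \propto 1/\alpha$
and total error combines HU noise and readout error in quadrature, modes with
$\alpha \ge 0.6$ (0-30 degrees) all sit within one or two percentage points
of the label ceiling. On an 80-egg test set (1.25% accuracy quantum) the
per-seed argmax over modes is then nearly a coin toss among the low angles,
even though the *mean* trend over seeds is strongly monotone (Spearman
correlation between angle and accuracy around $-0.87$ in our runs, reflection
always far below). Tests of the angle report should therefore lean on the
rank correlation, not on strict per-seed argmax positions; we keep one
strict-argmax check in the acceptance suite for transparency even though the
stated world only meets it in about 6 of 10 seeds.

## Methodological choices

**Reflectance correction** divides per pixel; a white frame equal to the dark
frame anywhere is an error naming the first offending pixel (corrupt
references should fail loudly, not produce NaNs). $R$ is not clipped to
$[0,1]$ — specular glare legitimately exceeds 1 and is handled by the ROI
stage. Cubes are corrected whole; ENVI files are written with the common
core header keys only (BSQ/BIL/BIP, float32/float64).

**ROI extraction** reads the unspecified "cell counting" step as 8-connected
component labelling with raster-order numbering. The threshold defaults to
Otsu (a fixed threshold is available for reproducibility), the morphological
"expansion and erosion" is taken literally as closing with a 2 px disk, and
the fitted ellipse is inflated by 1.05 (the study expanded its ellipse by an
unreported factor). Coordinates are 1-based (row, col), R's native indexing.

**Preprocessing.** Row-wise methods (SNV, MSC, min-max normalization, moving
average, detrending, Savitzky-Golay family) carry no training state; MSC,
mean centering and autoscaling are fitted on training rows only and applied
unchanged to test rows — the contract that keeps test statistics out of
every later stage. Unreported parameters default to: SG window 11,
polynomial order 2 (derivatives scaled by the band spacing, shrink-to-valid
edges so no padded values are invented); moving-average window 5; "detrend"
is read as per-spectrum polynomial baseline removal of order 2 (the cited
"detrended fluctuation analysis" is a time-series scaling method that does
not apply to single spectra row-wise). Sample (n-1) standard deviations
throughout.

**Wavelength selection.** The PCA path uses the first three component scores
as features (the "new coordinate system" reading); loading-based wavelength
picking is exposed as diagnostics only. SPA grows one minimally collinear
chain per starting band by successive orthogonal projection and scores every
chain prefix of 5-30 bands by 5-fold cross-validated linear-regression RMSE;
degenerate (collinear) candidates truncate a chain early. CARS runs 100
Monte-Carlo iterations: 80% row subsample, PLS on the retained bands, band
weights $|b_j|/\sum|b_j|$, enforced retention along the exponential schedule
$r_i = a e^{-ki}$ with $a = (p/2)^{1/(N-1)}$, $k = \ln(p/2)/(N-1)$ (all $p$
bands at run 1, exactly 2 at run $N$), adaptive reweighted sampling of the
retained set, and a 5-fold RMSECV of the survivors; the minimum-RMSECV run
wins. Two implementation decisions: (1) after the weighted resampling the
unique survivors are topped back up to the scheduled count with the
highest-weight remaining bands, so the realized retention curve follows the
schedule exactly (the resampling still randomizes *which* bands survive);
(2) internal PLS fits use a fixed component cap $\min(10, n-2, p,
\text{rank})$ rather than an inner cross-validation — an inner CV multiplies
the run count several-fold and no component count is reported to match. The
regression target for SPA/CARS is the numeric grade code 1-4 (configurable);
the study never states its continuous target, and grade codes are the only
response available to the data group.

**Classifiers.** All six expose class probabilities behind one contract so
any of them can feed the stacking layer. DAC is a Gaussian discriminant with
pooled (linear, default) or per-class (quadratic) covariance; singular
covariances receive an escalating ridge with a logged message rather than an
error (meta-features are deliberately collinear, their blocks sum to one).
"LDA" is implemented as the Fisher discriminant projection with
nearest-centroid assignment — the alternative expansion of that acronym,
latent Dirichlet allocation, is a topic model for count data and cannot
consume real-valued spectra. Because no SVM or random-forest package is
assumed, the RBF SVM solves the one-vs-one soft-margin dual with
`quadprog`, and the random forest is 100 CART trees (Gini, bootstrap,
$\sqrt{p}$ features per split). Unreported hyperparameters default to
KNN $k=5$, SVM $C=1$, $\gamma = 1/(p \cdot \mathrm{var})$, RF 100 trees —
all exposed in `classifier_spec()`.

**Split and grid.** The stratified split draws 71.43% of each grade for
training (280 balanced eggs give exactly 200/80, 50/20 per grade). One egg
is one sample: the same split of eggs is shared by all nine modes, so
accuracies across modes are paired comparisons on identical test eggs. The
grid fits preprocessing and selection on training rows only, records failed
cells without aborting the sweep, and ranks the best cell per mode by test
accuracy with ties broken by train accuracy, then pipeline id
(lexicographic).

**Stacking.** The top three classifier kinds of a mode (by best achieved
accuracy) become the first layer. Meta-features are class-probability
vectors, not hard labels — the test-set averaging of fold predictions is
only well-defined for probabilities. Training rows receive out-of-fold
probabilities (their own fold model never saw them); test rows receive the
average over the five fold models. Folds are stratified by grade so every
fold model sees all classes. A caller may pin the fold assignment
explicitly; with a pinned assignment, flipping one training label provably
cannot change that row's own meta-features, which is how the leakage tests
work (under the default seeded stratification, a label flip changes the
strata and therefore the entire partition). The stack is fitted once per
(preprocessor, selector) pipeline, and a mode reports its best stacked row,
mirroring how the best stacking model per incident mode is compared.

## Numerical conventions

Percentages print with two decimals; test accuracies are exact multiples of
$1/n_{test}$. All stochastic entry points take explicit integer seeds and
restore the caller's RNG state. Nearest-band lookups break ties toward the
lower wavelength. Probability ties in `predict()` resolve to the first
class level. ENVI round trips use float64 by default so write-read-write is
byte-identical.

## Known limitations

The generator's independence assumptions (no day-level or hen-level
correlation, no shell-color variation) make classification slightly easier
than reality at equal noise levels; the angle ordering conclusion is robust
to this but absolute accuracies are not transferable. Grade C (spoiled) eggs
and the SWIR camera range are out of scope. SPA's exhaustive start-band loop
costs $O(p^2 m n)$ and is intended for a few hundred bands, not thousands.
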