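---
title: "Multispectral autofluorescence profiling of single cells: methods and design"
author: "specell authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral autofluorescence profiling of single cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specell)
```

## The problem

Exfoliated renal proximal tubule cells recovered from urine carry intrinsic
fluorophores — chiefly NAD(P)H and flavins — whose abundances shift with
cellular metabolic state. Imaging the same field through many
excitation/emission channel pairs (here 34 channels spanning excitation
340–510 nm and emission 420–650 nm) yields a per-cell spectral fingerprint,
and the intensity ratio of an NAD(P)H-dominated channel to a
flavin-dominated channel (channel 2 over channel 32 in this geometry) tracks
the cellular redox ratio. `specell` implements the full quantitative chain
that turns raw multichannel image "data blocks" into a validated binary
classification of patient status: reference-based preprocessing, per-cell
spectral feature extraction, feature ranking by minimum attainable
classification error, Fisher canonical projections, and nested
cross-validated ROC analysis — plus a synthetic cohort generator with known
ground truth, because no patient imagery is publicly deposited and every
stage must be testable from code alone.

## Data model

A **data block** is the acquisition bundle for one field: one image per
spectral channel, a brightfield image, and per-channel reference images —
dark (camera offset), water (offset plus buffer/stray background), and a
calibration fluid of 30 µM NADH + 18 µM FAD whose emission spans all 34
channels. Blocks are serialized as multi-page lossless TIFF (page order =
channel index) with a canonical JSON sidecar; 16-bit integer data round-trip
bit-exactly. Segmentation masks are label images with a per-cell registry of
0-based pixel coordinates; segmentation itself is out of scope (masks are
consumed as files). The instrument's exact per-channel wavelength table is
instrument configuration; `defaultChannelSet()` generates a grid satisfying
all band invariants and `readChannelSet()` accepts a real table as CSV.

## Preprocessing

The fixed order is **repair → subtract → flat-field → equalize**; each step
updates the block's reference images and metadata so the composed map is
idempotent on its own output.

* **Bad-pixel repair.** Flags pixels at the saturation level, pixels below
  the *undetectable floor* (dark mean + 2 dark sd per channel — the
  threshold operationalizes "undetectable", which the acquisition literature
  names but does not quantify), zeros where the calibration image indicates
  a dead element, and spike/dip outliers. Outliers are pixels deviating from
  the local median by more than `outlierK = 5` σ-consistent MADs
  (MAD × 1.4826) in a 5×5 window. The 5×5 detection window is deliberate: an
  8-sample 3×3 MAD is so variable that a plain `5 × MAD` rule falsely flags
  several percent of clean Poisson pixels, while the 24-sample window brings
  the false-alarm rate below 0.1% at unchanged sensitivity. Flagged pixels
  are replaced by the median of non-flagged neighbours in a 3×3 window, and
  the flag map is returned for audit. Repair runs first so reference-image
  artefacts cannot poison the corrections, and a channel with more than 20%
  flagged pixels is declared unusable.
* **Reference subtraction.** `corrected = raw − water`. The water image is
  acquired dark-inclusive, so one subtraction removes the camera offset and
  the buffer background; negatives are clipped at zero.
* **Flat-field.** `flat = corrected × mean(calib − dark)/(calib − dark)`,
  per channel. The calibration fluid is spatially uniform, so its
  dark-subtracted image maps the illumination/response field; the mean
  normalization preserves the spatial mean of a uniform target. On
  noise-free synthetic blocks this inverts the generator's vignetting to
  float precision.
* **Exposure equalization.** Division by the channel exposure (up to 5 s)
  puts all channels in counts/s.

The acquisition literature this chain follows defers the exact correction
formulas to prior work; the concrete rules above are therefore stated
explicitly, exposed in `correctionSettings()`, and tested, rather than
inferred.

## Cell features

For each cell the admissible features are channel **means**, **top-decile
means** (mean of the ⌈0.1·n⌉ brightest pixels — the fraction is stated in
the source methodology, the rounding is ours; thresholding may emphasize
fluorophore-rich compartments such as mitochondria), **channel ratios**
(ordered pairs over the interpretable subset {2, 15, 32} by default, with an
exhaustive switch), and — in the *extended* policy only — per-channel
standard deviation, adjusted Fisher–Pearson skewness and excess kurtosis.
The *conservative* policy admits only means, top-decile means and ratios,
whose biological reading is direct. Degenerate rules keep cohort runs alive:
moments of constant pixel vectors are 0, and a ratio with a zero denominator
is 0 with a warning. Moments are computed with `e1071` (type 2); ratios are
ratios of means, which cancels both illumination residues and the
generator's shared intra-cell texture.

## Feature ranking and canonical projection

Features are scored by the **minimum attainable classification error**: the
smallest pooled misclassification fraction achievable by thresholding the
single feature, over all midpoint thresholds (±∞ included, so the majority
rule is always attainable) and both polarities. Classes are weighted by
their empirical cell counts — the cohorts are unbalanced (41 vs 84 cells)
and the criterion is a fraction of cells; whether the original analysis
weighted classes equally is not recoverable, so the pooled convention is
documented here and fixed. Error ties break toward the threshold with the
widest margin, then the smaller threshold. Ranking ties break by the
canonical feature order, so rankings are stable and reproducible.

The best *n* features (with *n* < *N*, the smaller group's cell count — the
overfitting guard) are kept while skipping features whose absolute
correlation with an already-kept feature exceeds 0.95; top-ranked features
are otherwise near-duplicates (the mean and top-decile mean of one channel).
The redundancy cap is an addition of this implementation and can be
disabled.

The 2-D discriminative space is built greedily: `w1` is the Fisher direction
(maximal between-group over within-group scatter) on standardized features,
computed from the pooled within-class covariance shrunk toward its diagonal
by the smallest weight from a fixed grid {0, 0.01, 0.05, 0.1, 0.3, 0.5} that
leaves the system well-conditioned; `w2` is the Fisher direction restricted
to the orthogonal complement of `w1`. Classical two-class canonical analysis
yields a single canonical variable, yet the target analyses plot two; the
orthogonal-complement construction is this package's documented way of
producing a second discriminative axis without inventing extra classes.
Signs are fixed so the group-1 mean projects higher; `w1d = w1` is the
optimal 1-D projection feeding histograms and boxplots. If the class means
coincide the fit warns and returns the leading within-class variance axis.

## Classification and validation

The classifier is the linear discriminant scorer itself — standardized
features times `w1`, thresholded at the training-error minimizer. This is
the simplest model consistent with a classifier built on "a specific linear
combination of cellular features", and it keeps the conservative and
extended policies directly comparable.

ROC curves sweep the unique scores; tied scores move together, so the
trapezoidal AUC equals the normalized Mann–Whitney U statistic under the
midrank convention — an identity the test suite checks exactly on random
tied instances. The group test is the two-tailed Mann–Whitney U: exact by
enumeration for tie-free samples with n₁+n₂ ≤ 12, otherwise the normal
approximation with tie and continuity corrections, with significance tiers
at α = 0.05/0.01/0.001 (\*, \*\*, \*\*\*). For tie-free samples the
approximation carries an Edgeworth term using the exact excess kurtosis of
the null U distribution, γ₂ = −(6/5)(n₁²+n₂²+n₁n₂+n₁+n₂)/(n₁n₂(n+1)): the
plain corrected normal approximation deviates from exact enumeration by up
to 0.022 at n₁+n₂ = 12, while the sharpened version stays below 0.016
everywhere (0.014 at n = 20), so the approximate and exact paths agree to
the advertised 0.02 across the exactness boundary. Underflowing p-values
are clamped to the smallest positive double so p stays in (0, 1].

**Nested cross-validation** provides the unbiased performance assessment:
outer folds (default 5) estimate held-out performance while inner folds
(default 5) choose the feature count from {4, 6, 8, 10} by mean inner AUC;
ranking, selection and training are re-run inside every training fold and
never see test cells, and a grouping unit appearing on both sides of a split
is a fatal error. Folds are stratified over **patients** by default: cells
from one patient are correlated, so cell-level folds leak patient identity
and flatter the estimate. Cell-level grouping is available to mirror
per-cell analyses, and the report records which was used. A label
permutation null (`permutationNull()`) is the standing overfitting guard:
with all selection inside the folds, permuted labels must give held-out AUC
near 0.5.

## The synthetic cohort generator

The generator exists to make every downstream stage testable with known
ground truth; it emulates the statistical structure the analysis assumes,
not optical physics. Its defaults are the study conditions used throughout
the tests:

* **Scale.** Two groups of 41 and 84 cells (the reported cohort scale),
  5 patients per group, 3 cells per field (from the documented 2–4), images
  256×256 by default — a desk-scale stand-in for the 1200×1200 sensor; test
  code renders 48×48 fields with proportionally smaller cells purely to keep
  the suite fast, which leaves all intensive quantities unchanged.
* **Signal.** Cells are ellipses (semi-axes 10–16 px at default scale) with
  a smooth lognormal intra-cell texture (log-sd 0.3) shared across
  fluorophores. The clean pixel signal is linear mixing:
  illumination × Σ_f abundance_f × response_cf × exposure. Endmember spectra
  anchor NAD(P)H to channel 2 and flavins to channels 15 and 32 (enforced as
  class invariants), plus one broad low-amplitude nuisance fluorophore with
  ≤ 2% crosstalk into the anchor channels.
* **Noise.** Poisson shot noise on signal + water background, dark offset
  100 counts, Gaussian read noise 5 counts, 16-bit quantization, hot and
  dead pixels at rate 10⁻³ each. References are generated consistently
  (dark = offset + noise; water = dark + 30 counts; calibration =
  dark + illumination × 1000 counts/s × exposure) with √3-averaged noise.
  The vignetting field (1 − 0.45·ρ²/…)(1 + 0.05·x) gives a raw
  coefficient of variation just over 10% on a uniform target, so flat-field
  recovery is a non-trivial test.
* **Group effect.** The only group-dependent mechanism is the NAD(P)H :
  flavins abundance ratio — the redox ratio, the one biologically anchored
  difference this assay names. Patient-level mean log-abundances are
  Normal(group mean, 0.10), cell-level Normal(patient mean, 0.25). The
  shift is split symmetrically (±effect/4 on each fluorophore's log
  abundance) so the group difference of the log-ratio is exactly `effect`
  **and** the log-ratio is the Bayes-sufficient statistic: the best
  attainable AUC of any classifier on the true abundances is
  Φ(effect/√(2σ²)) with σ² = 2(0.10² + 0.25²), computable in closed form
  (`designedAUC()`, inverted by `effectForAUC()`). A one-sided shift would
  instead let absolute NAD(P)H intensity beat the designed AUC. The default
  effect 0.69 corresponds to a designed Bayes AUC of 0.90. Illumination and
  nuisance fluorophores are group-independent, so the classifier cannot
  cheat.
* **Hierarchy.** Patient-level random effects are included even though the
  analyses are per-cell: they make the distinction between patient-grouped
  and cell-level cross-validation demonstrable rather than hypothetical.

What the generator does **not** model: spectral filter-cube overlap,
scattering or depth effects, real cell morphology, segmentation error, or
batch effects between acquisition sessions beyond shared references per
patient. Passing tests therefore demonstrate that the analysis machinery is
correct and calibrated on data with the assumed structure — not that the
assay separates real patient groups; the printed performance figures of any
real cohort (AUCs of 0.75–0.99) live on undeposited data and are not
reproduced here.

```{r design, eval = FALSE}
cfg <- cohortConfig()          # the default study conditions
designedAUC(cfg)               # 0.90
effectForAUC(0.75, cfg)        # effect size for a weaker cohort
```

## Numerical choices and degenerate inputs

* Thresholds are midpoints of consecutive distinct values; ±∞ candidates
  make the majority rule attainable, so min-error ≤ min(class prior).
* Shrinkage weight for the within-class covariance: smallest grid value with
  reciprocal condition number above 10⁻⁸; variances are floored at 10⁻⁶
  after standardization so within-class-constant features cannot produce a
  singular system.
* Top-decile pixel count ⌈0.1·n⌉ with a minimum of one pixel.
* Skewness/kurtosis of constant vectors are 0, not `NaN`; ratios with zero
  denominators are 0 with a warning.
* `mannWhitneyU()` returns p = 1 when the tie-corrected variance vanishes
  (all values identical).
* Fold assignment shuffles units within each label class and deals
  round-robin, so group balance is preserved per fold; all randomness
  descends from a single recorded seed, and reruns are byte-identical.
* Pixel repair is a no-op on blocks whose processing log already records a
  repair: its thresholds are calibrated for raw images (after background
  subtraction half the background sits exactly at zero, which would poison
  a local MAD), and the no-op is what makes the composed chain idempotent.

## Problem sizes used by the checks

The test suite regenerates everything from seeds: unit tests use 48×48
fields and cohorts of 12–125 cells; the calibration checks use ≥ 600 cells
across 50 patients for the Bayes-AUC property, 20 seeds at the 41 + 84
scale for ranking recovery, 10 seeds per design point on the AUC grid
{0.6, 0.75, 0.9, 0.99}, 200 label permutations for the null, and two full
default-scale (256×256) pipeline runs for end-to-end determinism. The
acceptance script performs one full default-scale run per invocation and
reports its pooled AUC, group test, ranking, repair audit and permutation
null.

## Known limitations

* The default channel table is a generated grid, not the instrument's
  (unpublished) wavelength table; drop a real table in via
  `readChannelSet()`.
* The second canonical axis is a greedy orthogonal construction; other
  choices (e.g. regularized two-dimensional trace optimization) are
  defensible and would change the scatter panels but not the classifier.
* Scores pooled across outer folds share a scale only through per-fold
  training standardization; per-fold AUCs are reported alongside for that
  reason.
* Whether top-decile thresholding was an implemented feature or an
  interpretive remark in the source methodology is ambiguous; it is included
  and can be switched off (`featurePolicy(topDecile = FALSE)`).
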