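---
title: "Estimating maize leaf carotenoids from reflectance: models, indices and design choices"
author: "caroSpectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating maize leaf carotenoids from reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caroSpectra)
```

## The estimation problem

Leaf carotenoid content (µg per g fresh weight) is conventionally
measured destructively: leaves are homogenized in 80 % acetone and the
extract's absorbance is read at 470, 644 and 663 nm. The same pigments,
in vivo, shape the leaf's reflectance spectrum — carotenoids absorb in
the blue and green, chlorophylls in the blue and red, and the transition
from pigment absorption to structural NIR scattering produces the "red
edge" near 680–750 nm. A calibration that maps a few reflectance bands
to wet-lab carotenoid values therefore allows rapid, non-destructive
monitoring.

`caroSpectra` implements that chain end to end: wet-lab arithmetic,
band-ratio indices, data-driven selection of sensitive bands, linear
calibration with grouped validation, and nonparametric tree ensembles.
Because leaf-level field datasets of this kind are rarely public, the
package also ships a synthetic study generator with the same statistical
structure, so every stage is testable and the whole analysis is
reproducible from a seed.

## Wet-lab equations and their inverse

`carotenoidContent()` evaluates

```
car = (1000·A470 − 3.27·chl_a − 104·chl_b) / 229  scaled by V/w
chl_a = 12.21·A663 − 2.81·A644
chl_b = 20.13·A644 − 5.03·A663
```

with V the extract volume (ml) and w the fresh tissue weight (g). The
conventional fresh-weight scaling multiplies the extract concentration
by V/w, but the formula as printed in the protocol this package follows
divides by V/w; both are exposed through the `scaling` argument
(`"as_printed"`, the default, and `"volume_multiplied"`), and the two
agree when V = w. Neither is asserted as the biologically correct one:
the ambiguity cannot be resolved from the arithmetic alone, and users
calibrating against their own laboratory protocol should pick the
variant matching it.

`pigmentsToAbsorbance()` inverts the system exactly (the chlorophyll
pair is a 2×2 linear solve; A470 follows from the carotenoid equation).
Negative computed pigments are returned with a warning rather than
clamped — they diagnose nonphysical absorbance inputs — while pigment
combinations that would demand negative absorbance are errors.

## The index registry

Seventeen indices are built in: eight classical two- and three-band
forms (RARS, SIPI, PSSR, CRI550, CRI700, mCRI_G, mCRI_RE, PRI) and the
nine CAR ratios over the bands 550, 678, 700 and 800 nm. Three
conventions matter:

* **Band values.** A point band is linearly interpolated between the two
  bracketing grid wavelengths (an exact grid hit returns the stored
  value); a window band such as R510–520 is the unweighted mean of all
  grid points inside the window (10 nm windows for the mCRI green and
  510–520 terms, 20 nm for 690–710). Interpolation rather than
  nearest-neighbour keeps indices continuous in wavelength and avoids
  grid-spacing artifacts.
* **The mCRI NIR anchor.** The mCRI formulas multiply by an unspecified
  NIR reflectance; the registry fixes it at 800 nm — the NIR wavelength
  the component analysis itself singles out — and makes it configurable
  (`builtinIndices(nirNm = ...)`).
* **Undefined values.** Any denominator of magnitude below 1e−12, and
  any non-finite result, yields `NA` rather than an error or a silent
  zero (SIPI on a perfectly flat spectrum is the canonical case).
  Downstream calibration drops such pairs pairwise and the pipeline log
  counts them per index.

Reflectance is treated in percent (0–100). All ratio and
normalized-difference forms are invariant under a uniform rescaling of
reflectance; the reciprocal-difference forms CRI550 and CRI700 scale as
1/c (the mCRI forms, multiplying a reciprocal difference by an NIR band,
are again invariant — the two factors cancel). The test suite asserts
this scale-behaviour table per index.

## Band selection: PCA, varimax, KMO

`pcaLoadings()` eigendecomposes the correlation matrix by default —
standardization is the safer general-purpose choice when variable scales
differ. For reflectance spectra, however, all variables share one
physical unit and the *amplitude* of variation carries the pigment
signal, so the pipeline's band-selection stage deliberately runs the
covariance (unstandardized) PCA; with standardization every visible
wavelength correlates near-perfectly with the first component and the
loading profile flattens into noise. Loadings are scaled so squared
column sums equal component variances, and explained percentages are
relative to the total variance.

`varimaxRotate()` is the classic Kaiser pairwise rotation: for each pair
of components the closed-form angle maximizing the pair's criterion is
applied, sweeping until no pair moves (tolerance 1e−6 on the angle, at
most 500 sweeps, warning on non-convergence). The pairwise form is
preferred over the SVD-update iteration because the latter stalls on
symmetric saddle configurations (an exact 45° mixture of a simple
structure — precisely the situation rotation exists to undo). Kaiser row
normalization is on by default, standard practice; note that with
normalization the criterion guaranteed not to decrease is that of the
row-normalized loadings. Communalities are preserved to numerical
precision, and `stats::varimax` serves as an independent cross-check in
the tests.

`kmo()` computes the Kaiser–Meyer–Olkin adequacy from the anti-image
partial correlations (inverse correlation matrix). Near-singular
matrices receive a 1e−8 ridge with a warning; exactly collinear variable
pairs are an error, since no ridge makes their partials meaningful. A
perfectly "adequate" dataset (all partials vanishing while simple
correlations persist) is a mathematical limit rather than an attainable
case, which the tests approach with large equicorrelated panels.

`selectSensitiveBands()` reads the k tallest local maxima of the
absolute loading profile, greedily enforcing a minimum separation
(default 15 nm) with deterministic ties to the lower wavelength;
boundary points count as maxima. The profile can be smoothed by a
centred moving average before peak reading (the pipeline uses 7 nm) —
sampling ripples otherwise split genuine peaks into near-duplicates that
consume selection slots. The pipeline takes three bands from the first
rotated component (blue, green and red absorption structure) and one
from the second (the red-edge block that rotation isolates), a choice
that reflects how two components suffice to capture the bulk of spectral
variance in pigment-driven data.

## Calibration, splits and metrics

Each index is calibrated by ordinary least squares,
`carotenoid = intercept + slope·index`, on pairwise-complete pairs.
Validation follows two families of schemes: year-grouped splits (train
on two years, test on the third, in all three rotations) and a pooled
seeded shuffle split. The pooled fraction defaults to 2/3 for the index
suite and 0.7 for the learner comparison — both configurable; the two
defaults mirror the two protocol descriptions the package follows.

`regressionMetrics()` returns six quantities, with y observed, ŷ
predicted, ȳ the observed mean:

* R² = 1 − Σ(y−ŷ)²/Σ(y−ȳ)²  (so test-set R² can be negative),
* RMSE = √(Σ(y−ŷ)²/n) (µg/g),
* NRMSE = RMSE/ȳ·100 (%),
* MAE = Σ|ŷ−y|/n,
* MBE = Σ(y−ŷ)/n — **mean of observed minus predicted**, so a negative
  MBE reads as overestimation; this sign convention is fixed here
  because index–symbol conventions vary across reports,
* NSE with the standard observed-variance denominator Σ(y−ȳ)², making
  it identical to the R² definition above; a variant normalizing by the
  spread of the predictions is available behind `nseAsPrinted = TRUE`
  for comparability with reports using that form.

Under this definition, OLS predictions evaluated on their own training
set satisfy R² = NSE = squared correlation and MBE = 0 exactly (normal
equations) — both are asserted as invariants in the tests.

## Tree ensembles

The learners are written from scratch, since their behaviour — not a
particular library's internals — is the contract:

* **`fitTree`** grows a binary regression tree by greedy variance
  reduction. Candidate thresholds are midpoints of consecutive distinct
  sorted feature values; children must hold at least `minLeaf` cases
  (default 2); growth stops at depth 25 or constant response. Gains
  within a data-scaled tolerance (1e−10·(Σy²+1)) are treated as exact
  ties and resolved to the lowest feature index, then the lowest
  threshold — identical partitions reached through different features
  are true ties, and float noise must not break them inconsistently.
* **`repPrune`** prunes bottom-up against a held-out set, replacing a
  subtree by a leaf (the training mean routed to that node) whenever
  held-out SSE does not increase; pruning-set SSE and node count are
  therefore non-increasing, which the tests assert on every randomized
  case.
* **`fitEnsemble`** builds bagging (bootstrap rows), random subspace
  (feature subsets of size ⌈p/2⌉, all rows), random forest (bootstrap
  rows plus per-node feature subsets of size max(1, ⌊p/3⌋)) and the
  pruned single tree (2/3 grow, 1/3 prune). Defaults: 100 members,
  5-fold cross-validation, 70/30 comparison split. Member i draws its
  randomness from `seed + i`, so fits are bit-reproducible and
  prediction (the plain member mean) is invariant to member order.

The implementation aims at behavioural, not bit-level, fidelity to any
particular toolbox: tie handling, pruning order and split scoring are
specified here and tested against an exhaustive brute-force split oracle
(exact tree equality for n ≤ 30) rather than against another program's
output.

## The synthetic study generator

`generateStudy()` emulates a three-year leaf-sampling campaign: 540
samples balanced over 3 years × 3 BBCH stages (16, 51, 79) × 5 sites
(site 1 non-irrigated), 1 nm grid from 400 to 1000 nm.

**Pigments.** Carotenoid is drawn from a truncated normal on
[114.72, 526.97] µg/g. The underlying mean is solved (1-D root find) so
the *truncated* distribution's mean equals the configured 382.31 µg/g —
naive truncation of N(382.31, 86.02²) at those asymmetric bounds would
bias the realized mean down by ≈8 µg/g. Total chlorophyll couples
linearly (chl = 100 + 5.5·car, a realistic maize leaf ratio) with noise
scaled so the realized carotenoid–chlorophyll R² approaches the 0.925
target; chlorophyll a:b is 3:1. Year effects are carotenoid mean shifts
only (+20, −28, +8 µg/g for the three years, summing to zero; the
dip emulates a drought season) applied inside the truncated draw, so the
range always holds and year-grouped validation is genuinely harder than
pooled validation. Per-year distributions of the emulated campaign are
fixtures of this generator, not claims about any real dataset.

**Spectra.** Reflectance is a 50 % NIR plateau minus Gaussian absorption
features attenuated by a logistic red edge,
`R(λ) = plateau − (1 − L(λ))·A(λ)`. The features (centre/width in nm,
strength in % reflectance per µg/g): carotenoid 465/32/0.0045 and
535/28/0.002; chlorophyll 430/28/0.005, a broad green-range depression
565/45/0.0016, a weak extract-position band 644/16/0.0005, and the
dominant in-vivo red absorption 678/9/0.013 (in vivo the red chlorophyll
absorption sits near 678 nm, red-shifted from the 663 nm extract
position). A pigment-independent visible floor (8 % Gaussian at 550 nm,
width 150) stands in for non-pigment backscatter. The red edge is a
logistic of width 8 nm centred at 700 nm, shifted by +0.012 nm per µg/g
chlorophyll about 2200 µg/g — the classic red-edge shift — plus an
independent structural jitter (sd 3 nm) representing leaf-architecture
variability. That jitter is what gives the red-edge region variance of
its own, letting varimax isolate an edge component whose loading peaks
near 700 nm; without it, all variance is a single pigment factor and no
local loading maximum exists between the red absorption and the NIR.
Additive Gaussian noise (default sd 0.5 % reflectance) is applied and
values are clipped to [0.1, 99]; a model whose strengths drive the
pre-clip *median* reflectance negative is rejected as misconfigured.

Feature centres and strengths were calibrated once, when the generator
was designed, so that the four target bands (550, 678, 700, 800 nm) are
genuinely informative and the leading CAR indices recover carotenoid
with pooled test R² well above 0.8 at the default noise; they are fixed
defaults, not tuning knobs. A deliberate consequence of the ratio
structure: bands that co-move with an index's denominator cancel, so the
green-region features are kept weak — the 550 nm signal exists (it must,
for band selection to find it) but does not dominate R550.

**What the generator does not emulate.** No radiative transfer
(PROSPECT-class leaf optics), no specular/BRDF effects, no canopy or
soil mixing, no instrument drift, no wavelength-correlated noise, no
stage-dependent spectral shape change. Passing tests on this generator
therefore demonstrate that the *analysis chain* is correct and sensitive
under its stated assumptions — a single dominant pigment factor with a
shifting red edge — not that any particular index will achieve the same
accuracy on field spectra, where structural and illumination effects
compete with pigment signal.

**Randomness.** All stochastic stages draw from substreams derived from
the master seed (pigments per year, red-edge jitter, spectral noise), so
any stage can be reproduced independently and identical configuration +
seed yields byte-identical pipeline reports (asserted in the tests).

## Problem sizes and runtime choices

The test suite exercises formula fidelity on 1000 random spectra and
1000 random metric pairs, tree/oracle equality on fixtures up to n = 30,
pruning contracts on 100 randomized trees, and pipeline-level recovery
on full 540-sample studies (three seeds for the learner comparison, five
seeds × three noise levels for the noise-degradation property). These
sizes keep the complete suite in the low minutes on a single CPU while
leaving the statistical assertions comfortably away from their
thresholds.

## Known limitations

* The spectral model is phenomenological; its parameters are chosen for
  statistical realism, not fitted to measured leaf optics.
* The index suite fits strictly linear calibrations; power/exponential
  index–pigment relations reported for some classical indices are out
  of scope.
* Varimax is the only rotation offered (no oblique rotations), and PCA
  the only extraction method (no maximum-likelihood factor analysis).
* M5P-style model trees (linear-model leaves) are not implemented; the
  ensemble family covers the four learners whose mechanics are specified
  above.
* The grid is irregular-capable throughout, but the generator emits a
  uniform 1 nm grid; instrument-specific grids (e.g. a 0.6 nm-precision
  spectrometer export) should be loaded, not simulated.
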