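---
title: "Deformation-based morphometry biomarker discovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformation-based morphometry biomarker discovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbmorph)
```

## The problem

Group-level morphometric analysis of 2D medical images asks: *where* does
the anatomy of a diseased cohort differ from controls, without a human
pre-specifying candidate measurements? `dbmorph` answers this with
deformation-based morphometry. Every subject is non-rigidly registered onto
a cohort reference; the displacement field that maps the reference onto
each subject is then the subject's complete morphological description, and
group differences in those fields — localized to grid cells — are candidate
image-based biomarkers. Machine learning (unsupervised cluster scoring for
selection, a supervised kernel SVM for validation) replaces the
hypothesis-driven choice of measurements.

This vignette documents the model assumptions, the tunable parameters, the
synthetic phantom used for validation, and the design decisions taken where
the method left genuine freedom.

## Pipeline stages and their assumptions

### Reference selection

The common coordinate frame is a real cohort member, not an atlas: the
subject minimizing the sum of standardized absolute deviations from the
per-measurement cohort means (`select_reference()`). Standardization
matters because morphometric measurements carry mixed units; raw signed
deviations would cancel and raw absolute deviations would let the
largest-unit column dominate. Ties break by table row order, so the result
is deterministic.

### Registration

Affine pre-registration removes scanner- and positioning-induced
differences (translation, rotation, scale, shear), optimizing mean squared
intensity difference with BFGS over a 3-level pyramid. This assumes all
images share one modality and comparable intensity distributions after
normalization — mutual information is deliberately out of scope.

Non-rigid registration is Thirion-style additive Demons: the per-pixel
update

$$v = \frac{(q \circ \varphi - r)\,\nabla r}{\lVert\nabla r\rVert^2 + \alpha^2 (q\circ\varphi - r)^2},$$

with $v = 0$ where the denominator is below $10^{-12}$, subtracted from the
accumulated field, which is Gaussian-smoothed after every iteration
(diffusion-like regularization). Defaults: smoothing sigma 1.5 px, 3
pyramid levels, 50 iterations per level, $\alpha = 1$ — all exposed through
the registration parameter list. The recovered field lives on the
reference grid and points into the query ("reference-pull"), which makes
cohort fields directly comparable cell by cell. If the sum of squared
differences rises for 10 consecutive iterations the level stops early and
the best field seen is kept; with noisy images this plateau detector often
fires once the data term has been exhausted, which is expected behaviour,
not failure — the flag is recorded in the field's attributes.

Two facts shape what the pipeline can see. First, displacements well below
the intensity-noise-limited resolving power (a few tenths of a pixel here)
are not recoverable; the phantom's study conditions keep the
between-subject deformation above that floor. Second, where the image is
locally untextured the problem is ill-posed along the isophote (the
aperture problem), so a weak-contrast displacement is partly attributed to
surrounding structure. This spreads a genuinely local anomaly over a
neighbourhood of a few cells and is the main reason localization is scored
against a tolerance of two cell widths rather than one cell.

### The phantom: what it emulates, what it does not

`phantom_spec()` defines the validation conditions. The reference is a
textured "head": nested ellipses with intensity offsets, a smooth gradient
and band-limited texture on an exactly-zero background, so the intensity
gradient is non-zero over most of the object and registration is
well-posed. Subjects are generated as

* a global affine jitter (rotation up to 3 degrees, translation up to 3 px
  by default) — scanner positioning error;
* a smooth stationary random deformation (white noise convolved with a
  Gaussian of 12 px correlation length, scaled to a 2 px maximum) —
  anatomical variability between individuals;
* for diseased subjects, a localized Gaussian displacement bump (3 px peak,
  8 px sigma by default) at a known locus with a direction fixed per
  lesion — the disease effect, modelled as a consistent anomaly that
  displaces the same anatomy the same way in every affected subject, with
  a per-subject amplitude jitter of ±10%;
* additive Gaussian intensity noise (SD 0.02 of the normalized range).

The composed field is returned as ground truth; warping the reference by
it reproduces the noise-free subject image exactly. The smooth field is
generated by circular FFT convolution so it is stationary: spatially padded
smoothing would concentrate variance at the borders and hand the amplitude
normalization to an edge artifact.

Default sizes (30 subjects, 15 per class, 128×128 px) were chosen as a
realistic small-cohort imaging study matching the scale of the clinical
setting the method targets. The phantom reproduces the statistical
structure the pipeline assumes — shared topology, smooth inter-subject
deformation, a localized disease effect — and nothing anatomical: passing
its tests demonstrates the machinery recovers planted effects under
realistic noise, not that any particular clinical population behaves this
way.

Deformation-direction conventions deserve care: the phantom stores the
*generative* field (reference → subject), while registration recovers the
*pull* field (reference grid → query), which is the inverse displacement.
`invert_field()` (fixed-point inversion) converts one into the other;
recovery tests compare the recovered field against the inverted ground
truth.

### Features

Fields are downsampled by area-weighted block means onto 3, 3.75 and 5 px
grids (fractional cells use box-filter overlap weights; the three rates are
analyzed independently, and downsampling doubles as smoothing over residual
registration error). Channels per cell: displacement magnitude, direction,
and optionally the Jacobian determinant computed on the coarse field by
central differences at the cell spacing (so all channels share geometry).
Cells are flattened row-major with channels interleaved, giving stable
column descriptors (`r{row}c{col}_{channel}_s{cell}`).

Direction is circular, so Euclidean consumers (2-means, SVM) receive it as
a (sin, cos) pair; the raw-angle mode remains available via
`encode_direction = FALSE`. The pair is weighted by the cell's cohort-mean
displacement magnitude and divided by sqrt(2). The weighting embodies a
measurement fact: the direction of a sub-pixel displacement is numerically
meaningless, and an unweighted angle would give such cells the same
footprint in the clustering distance as a cell with a three-pixel
displacement. Weighting by mean magnitude (a label-blind statistic,
computed from whatever subjects are in the matrix — training rows only
inside nested cross-validation) makes the two polar channels commensurate
in pixel units.

The pipeline excludes cells with no overlap of the reference tissue mask
(`mask_background = TRUE`): deformation values outside the imaged object
are pure regularizer extrapolation, and on diagnostic cohorts such cells
occasionally won selection by chance with no class signal at all. This is
the grid-level analogue of cropping the images to soft tissue.

### PCA denoising

PCA is fit across subjects (observations = subjects, variables = features)
per rate, jointly over both classes; the smallest leading set of components
reaching 95% cumulative explained variance is retained and the data are
reconstructed in the original feature space, so selection still operates on
per-location features. Columns are centered but not variance-scaled, and
the covariance uses the n−1 denominator. With small cohorts the matrix
rank is bounded by the subject count, so the discarded tail is the
finest-grained noise only; denoising here is deliberately mild.

### Scored SFFS

Selection is a scored variant of sequential floating forward selection.
One run takes a random ordering of all features. Forward pass: starting
from an empty subset whose reference quality is the majority-label
fraction, each feature is added in order (and stays regardless); its score
gets +1 if the subset's cluster quality strictly improved, −1 otherwise.
Backward pass: from the full subset, each feature is removed in the same
order; +1 if quality dropped without it, −1 otherwise (the empty subset
again scores the majority fraction). Ties count as non-improvement —
conservative, so inert features are penalized. Scores are summed over 250
random orderings; the top five features are the candidate biomarkers.

Cluster quality is a deterministic 2-means: centroids seeded with the two
rows at maximal Euclidean distance (ties to the lowest row index), Lloyd
iteration to an assignment fixed point (cap 100), quality = the fraction of
subjects whose cluster matches their label, maximized over the two
cluster-to-label pairings; identical rows fall back to the majority
fraction. Determinism (rather than random restarts) makes every score
reproducible. The implementation maintains a Gram matrix of the active
subset so each iteration costs O(subjects²) regardless of subset size,
which is what makes 250 orderings over thousands of features tractable.

Two design decisions matter for how this behaves in high dimension. First,
quality is evaluated on raw feature scales (pixels), not standardized
columns: the clustering then stays responsive to high-variance informative
cells deep into a pass, whereas unit-variance scaling turns the ranking
into a lottery among thousands of equal-footprint noise features.
Second, whether a non-improving feature stays in
the forward subset is ambiguous in a scored variant; here it stays (the
pass completes over all features) and only the score is penalized. The
backward pass updates its reference quality after every removal; the
alternative (holding it at the full-subset value) is noted as a sensitivity
variant but not implemented.

With thousands of candidates most additions cannot improve the clustering,
so almost every feature accumulates a strongly negative score and
candidates are effectively ranked by *least penalty*; what matters is the
ordering, not the sign.

### SVM validation and ROC aggregation

The top-5 features feed an RBF-kernel SVM (`e1071`), with features
standardized by training-set mean/SD (zero SD treated as 1) and defaults
C = 1, gamma = 1/(n_features × overall feature variance) — overridable.
Decision scores are signed so positive means diseased.

Cross-validation removes 5 random subjects per round (single-class
*training* splits are rejected and redrawn; the rejection count is
recorded), trains on the rest, and scores the held-out 5. Per round, the
pooled held-out scores are thresholded to a TPR at each of 101 FPR grid
points (the largest achievable TPR with FPR at or below the grid value);
the mean and variance over rounds give the reported curve — vertical
averaging, the standard reading of "mean TPR and FPR with variance
recorded at each point". Rounds whose test set happens to contain no
positive subject have undefined TPR and are excluded from the per-point
averages (their count is reported); with balanced cohorts they are a few
percent of rounds. AUC is the trapezoidal area of the mean curve. 1000
rounds are used by default; with small cohorts the distinct-split count is
modest, so rounds are sampled with replacement across the run and
duplicates are allowed.

Two evaluation protocols are implemented. *Pooled mode* (default) selects
features once on all subjects and cross-validates only the classifier —
the reference protocol, but optimistic on null data because selection saw
the test subjects. *Nested mode* re-runs SFFS inside every training split
(with a reduced ordering count, default 25, for tractability) and carries
no selection bias; it is the protocol under which a lesion-free cohort
scores chance-level AUC. Null-control experiments therefore use nested
mode, and the package asserts the directional relation (nested no more
optimistic than pooled mode on noise) in its tests.

### Biomarker mapping

A selected descriptor (row r, col c, cell s) maps to the half-open pixel
rectangle [⌊r·s⌋, ⌊(r+1)·s⌋) × [⌊c·s⌋, ⌊(c+1)·s⌋), clipped at the image
edge — floor-based intervals tile the reference without overlap, also for
fractional cells. Overlays draw rectangle outlines (not fills) in one
color per rate — red, green, cyan for 3, 3.75, 5 — so the underlying
anatomy stays visible. For phantoms, `localization_error()` reports the
distance from each rectangle center to the nearest planted lesion.

## Numerical choices and degenerate inputs

* Intensity normalization uses order-statistic (type-1) quantiles for the
  1%/99% anchors; interpolated quantiles would leave the operation very
  slightly non-idempotent after clipping.
* Constant images normalize to all zeros with a warning; zero-variance
  images are rejected by registration as ill-posed.
* Bilinear interpolation with edge-clamped sampling everywhere; image
  gradients by central differences, one-sided at borders.
* The zero displacement vector maps to polar (0, 0) by convention.
* Per-subject phantom seeds derive from the master seed by a fixed integer
  hash; all stage seeds derive from the experiment's master seed, so a
  report is regenerable from its config.
* 2-means empty-cluster states terminate the iteration (fixed point);
  farthest-pair ties resolve to the lowest row indices.
* SVM standardization guards zero-SD columns; the gamma heuristic guards
  zero variance.

## Problem sizes

The validation suite registers 128×128 cohorts of 30 subjects (the
phantom's default study conditions) for the lesioned end-to-end experiment
and the lesion-free null control; the null control uses the nested
protocol with 25 cross-validation rounds and 25 SFFS orderings per split
at the 3 px rate, sizes chosen to estimate a mean AUC honestly while
keeping a laptop-scale runtime. Unit and property tests use 64-px phantoms
and small synthetic matrices.

## Known limitations

* Strictly 2D, single-slice; no volumes, no multi-slice selection.
* One imaging modality at a time (MSE-based affine, no mutual
  information); no bias-field correction or skull stripping.
* The Demons variant is additive with diffusion-like regularization; no
  diffeomorphic or log-domain guarantees, so large or folding deformations
  are out of scope (the Jacobian map makes folding visible as negative
  determinants).
* The scored-SFFS ranking is a stochastic tournament: with thousands of
  candidate cells and weak contrast, near-lesion cells can be outranked by
  a halo of partially informative neighbours (the aperture problem again).
  The phantom experiments show this as occasional cohorts where fewer than
  three of the top five cells fall within the two-cell tolerance, with the
  AUC still high — the discriminative signal is real but less sharply
  localized for such draws.
* Pooled-mode AUC on null data is biased upward by construction; use nested
  mode for any claim about generalization.
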