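---
title: "Colorimetric tumor-fraction mapping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colorimetric tumor-fraction mapping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stainmap)
```

## The problem

Manual annotation of prostate cancer on whole-slide images (WSIs) of
prostatectomy specimens is slow and reader-dependent. H&E staining shows
morphology but hides the key diagnostic signal — the absence of the basal
cell layer around malignant glands and the overexpression of AMACR in
malignant epithelium. A triple-antibody IHC cocktail makes both visible:
HMWCK+p63 stain benign basal cells brown (DAB), AMACR stains malignant
epithelium red (Fast Red), and a hematoxylin counterstain renders stroma and
nuclei blue. `stainmap` quantifies paired H&E/IHC tiles colorimetrically,
regresses the percentage of malignant epithelium per analysis square, and
evaluates the resulting square-level cancer calls.

## Colorimetric models

**Optical density.** Brightfield transmitted intensity follows Beer–Lambert:
a pixel's optical density `OD_c = -log10(I_c / I0)` is linear in the amount
of stain. We fix the white reference `I0 = 255` and clamp intensities below
at 1 before the log, so a fully opaque pixel maps to the finite OD
`log10(255) ≈ 2.407`. A consequence worth knowing: stain mixtures whose
per-channel OD would exceed that cap are darker than an 8-bit brightfield
pixel can represent, so deconvolution round-trips are exact (to 1e-6) only
below it; the test suite samples concentrations in `[0, 1.1]` per stain,
which respects the cap with margin.

**Color deconvolution (CD).** The three stain signatures — measured on
singly-stained control slides as mean RGB OD triples, Fast Red
(0.283, 0.949, 0.757), DAB (0.461, 0.826, 1.0), hematoxylin
(0.21, 0.276, 0.176) — are normalized to unit Euclidean length and assembled
as the columns of a mixing basis; per-pixel concentrations are the basis
inverse applied to the pixel's OD. The raw vectors are not unit norm, so
normalization is a choice: it is standard deconvolution practice, keeps
concentrations in OD units along each stain direction, and leaves the
printed vectors intact in the default configuration. Negative concentrations
(off-basis colors) are clipped to zero as unphysical. A pixel is *positive*
for a stain when its concentration exceeds a per-stain threshold; the
published analyses used manually tuned, unpublished thresholds, so the
default here is 0.15 OD per stain, overridable in `cd_config()`. Per square
we report `%Pos`, the mean concentration over positive pixels (`mean_od`,
zero when no pixel is positive — the paper is ambiguous about the averaging
set, and averaging over positive pixels matches reporting the two numbers
side by side), and their product `OD × %Pos`, the predictive feature.

**Co-expression (CE).** `%Pos_CE` for red (resp. brown) counts pixels
positive for exactly that stain and not the other. Double-stained material —
intraglandular debris, corpora amylacea — inflates `%Pos` but not `%Pos_CE`,
which is why the full model keeps both. By construction
`%Pos_CE(s) ≤ %Pos(s)` for every tile.

**Positive pixel counting (PPC).** H&E compartments (nuclei, cytoplasm,
stroma) are counted by HSB color boxes (standard HSV, hue in degrees with
modular intervals, achromatic hue 0). The three boxes must be pairwise
disjoint — enforced at configuration load — so the three percentages can
never sum above 100 and `% unstained = 100 − (%nuclei + %cytoplasm +
%stroma)` is well defined. Squares more than 99% unstained (strict
inequality) lie outside the tissue and are excluded. One PPC configuration
is keyed per H&E staining batch, mirroring per-batch recalibration of
staining intensity.

## Grid, registration, and labeling

Analysis squares are 1,000 × 1,000 px (0.25 mm² at the native 0.5 µm/px
scan resolution), tiled from the image origin with partial edge squares
dropped rather than padded — padding would dilute per-square percentages.
Coordinates are 0-based half-open throughout.

The IHC tile is registered to the H&E tile by a rigid transform (rotation
about the image center plus translation) estimated by exhaustive normalized
cross-correlation on luminance images, coarse-to-fine: a downsampled
translation grid crossed with a rotation sweep, a mid-resolution rotation
refinement at one fifth of the sweep step, then a full-resolution
integer-pixel translation polish at the best rotation. The reference method
used unpublished proprietary registration; NCC search is robust, has no
tuning beyond the search bounds, and is testable against the phantom's known
misalignment (recovered within 1 px and 0.25° in the tests). Constant
(structureless) images are rejected.

Annotations are polygons (GeoJSON) in the H&E pixel frame. A square is
labeled cancer when at least 75% of its area — computed on masks rasterized
at full resolution, a pixel counting when its center is inside — lies in the
union of cancer regions, and it inherits the Gleason score of the region
contributing the largest overlap. The source method does not say how a
square spanning two differently-graded annotations is scored; the
largest-overlap rule is deterministic and order-independent, and exact ties
go to the higher grade group (clinically conservative). Squares at least 75%
inside negative (artifact) annotations are excluded, and exclusion takes
precedence over labeling.

## The regression model

The seven per-square features (three H&E percentages, two `OD × %Pos`, two
`%Pos_CE`) predict the ground-truth percentage of malignant epithelium via
an elastic net minimizing

$$\frac{1}{2m}\lVert X\omega - y\rVert_2^2
  + \alpha\rho\lVert\omega\rVert_1
  + \frac{\alpha(1-\rho)}{2}\lVert\omega\rVert_2^2 .$$

Choices the objective leaves open, and how they are resolved here:

* **Standardization and intercept.** Features mix percentages and OD
  products, so each column is standardized to zero mean and unit population
  variance (computed on the training portion only inside each CV fold), an
  unpenalized intercept is included, and the response stays on its 0–100
  scale. Penalizing raw heterogeneous columns would make `α` meaningless.
* **Optimization.** Cyclic coordinate descent with soft-thresholding
  (compiled inner loop), deterministic start at `ω = 0`, convergence when
  the largest per-cycle weight change falls below 1e-8 (tunable). The
  unpenalized case matches the normal equations to 1e-8 and penalized fits
  match glmnet to 1e-6 at matched parameterizations in the tests. Inside
  hyperparameter selection the solver walks each `ρ`'s `α` grid from largest
  to smallest with warm starts and covariance (Gram-matrix) updates, which
  keeps the grid search fast on the strongly collinear phantom features; the
  resulting cross-validation values are identical to independently fitted
  grid points (verified to 1e-6 in the tests).
* **Hyperparameters.** `(α, ρ)` are chosen to minimize the mean *penalized
  objective* on held-out folds of a leave-one-WSI-pair-out cross-validation
  — the literal published criterion. A held-out-MSE criterion is available
  (`criterion = "mse"`) because the literal reading mildly favors
  small-norm models; the literal reading is the default. Default grids:
  `α ∈ 10^{-4..1}` (13 log-spaced points), `ρ ∈ {0.1, 0.3, 0.5, 0.7, 0.9,
  1}`. Ties go to larger `α`, then larger `ρ` (the sparser model).
* **Predictions** are reported raw (they are the ROC scores) and clipped to
  `[0, 100]` for map rendering; whether the original analyses clipped is
  unstated, so both are emitted.

Four feature sets are trained: H&E only, IHC only, all except the two
co-expression features, and all seven.

## Evaluation

Square-level ROC analysis against the overlap-derived labels: the curve
sweeps `score ≥ threshold` over all distinct scores, AUC is the trapezoidal
area (identical to the pairwise concordance probability with ties counted
half, verified exhaustively in tests), and the operating point maximizes the
Youden index `J = sensitivity + specificity − 1`, ties toward higher
specificity. The decision rule is `score ≥ cutoff` everywhere — ROC,
sensitivity breakdowns, and map thresholding — for internal consistency.

Confidence intervals are percentile bootstrap intervals from hierarchical
resampling that respects the grouping of squares into WSI pairs: test-set
resampling draws pairs with replacement keeping all their squares; training
resampling additionally redraws squares within each sampled pair, at the
pair's original size (the within-pair sample-size convention is not stated
in the source; same-size is the standard cluster-bootstrap choice).
Replicates on which a statistic is undefined (single-class resamples) are
redrawn and counted. Two-sided p-values invert the bootstrap CI on a 0.001
grid, floored at `1/n_boot` since CI inversion cannot resolve below
replicate granularity. Sensitivities are also broken down by Gleason score
and grade group (GG ≤ 2 = 3+3/3+4 versus GG ≥ 3 = 4+3/4+4/4+5/5+4).

## The phantom generator

No image data are deposited with the source study, so the package ships a
seedable phantom generator that renders paired H&E/IHC tiles with exact
per-pixel ground truth. What it emulates:

* **Glands** are ellipses with an annular epithelial band and central lumen,
  one gland slot per analysis-square-sized cell; each gland is independently
  malignant with probability `malignant_fraction`. Benign glands carry a
  2–4 px basal ring rendered with DAB; malignant glands omit the ring and
  render their epithelium with Fast Red at concentration 0.9 (unless flagged
  by `amacr_dropout`, emulating AMACR-negative cancer variants; default 0).
* **The IHC tile** is synthesized per pixel by the forward Beer–Lambert
  model with the configured stain vectors, directly in a misaligned frame:
  each IHC pixel samples the scene at `true_transform(pixel)`, so the known
  rigid offset is exact and free of resampling artifacts.
* **The H&E tile** uses fixed colors for nuclei (purple, the inner half of
  each epithelial band), cytoplasm (pink, the outer half), and stroma (pale
  pink), chosen to occupy disjoint HSB boxes matched by
  `default_ppc_config()`.
* **Noise** is additive Gaussian in OD space (stain variability is
  multiplicative in intensity), clipped to valid intensities; default SD
  0.02 OD per channel, a mild jitter that keeps the rendered colors inside
  the PPC boxes.
* **Annotations.** Cancer outlines are dilated ellipses around malignant
  glands (dilation 12% of the square side), emulating coarse manual
  outlines: they cover ≳85% of the gland's own square and only a few percent
  of neighbors, so overlap labeling at the 75% rule reproduces the gland
  assignment — separability of the study is forced by construction, which
  is exactly what makes the end-to-end recovery test sharp. Artifact
  rectangles (dark folds on H&E, double-stained debris on IHC) become
  negative annotations; a `debris_fraction` knob scatters double-stained
  dots without negative annotation (default 0, no realism claimed — the
  prevalence of such debris is not quantified in the source).
* **Ground truth** per pixel is one of glass, stroma, lumen, benign
  epithelium, malignant epithelium, in the H&E frame, pre-noise and
  pre-transform. Images stay continuous in memory; writing to PNG quantizes
  to 8 bits, which alone injects ~3e-3 OD of rounding — exact-recovery
  checks therefore run on the in-memory pair.

What it does *not* emulate: chromatin texture, glandular architecture,
batch-to-batch H&E shifts (batches share one palette), scanner artifacts
beyond uniform jitter, or PIN/HGPIN mimics. Passing tests therefore
demonstrate the correctness of the measurement and modeling machinery, not
performance on real tissue.

## Study scale and determinism

The built-in study (`default_study_config()`) uses 10 training and 20 test
WSI pairs of 800 × 500 px with 100-px analysis squares — 40 squares per
pair, so the training set is the canonical 40 × 10 = 400 rows. The 100-px
square is a deliberate phantom-scale choice: the geometry of the 1,000-px /
0.25 mm² square is exercised at full scale in the grid module, while
rendering forty 1,000-px squares per tile would add nothing to the logic
being tested. Bootstrap CIs default to 1,000 replicates. Every stage derives
its RNG stream from the single study seed; identical configuration and seed
reproduce every artifact bit for bit, and each stage writes a manifest (a
hash of its configuration) that makes re-runs no-ops.

## Known limitations

* The phantom's benign squares are nearly featureless for the red channel,
  so the noise-free study is linearly separable; real slides are not.
* NCC registration assumes a mostly shared structure between the H&E and
  IHC luminance; heavy artifact coverage or near-constant tiles defeat it.
* Percentile bootstrap CIs (BCa is not implemented); with 20 test pairs the
  group-level resampling granularity is visible in the intervals.
* The OD clamp at intensity 1 caps measurable concentrations; saturated
  double stains alias onto the cap.
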