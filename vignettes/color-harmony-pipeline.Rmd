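---
title: "From pixels to perceived color harmony: the colorharmony pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pixels to perceived color harmony: the colorharmony pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colorharmony)
```

## The modeling problem

Color harmony — how pleasing a combination of colors feels — has been
studied for two centuries, but mostly on two- and three-color swatches.
This package implements a pipeline for *multi-color materials from real
scenes*: an image is reduced to a 16-dimensional vector of physical color
descriptors, and a linear model maps those descriptors to a harmony score
on the 5-level semantic-differential scale (−2 disharmonious … +2
harmonious). The approach assumes that once edge and semantic content are
blurred away, harmony judgments are driven by the statistics of the color
distribution itself — its lightness, its chromatic spread, how finely the
colors partition space, and how strongly neighboring colors contrast.

## The conversion chain and its one deliberate quirk

Channels are decoded to $[0,1]$ (8-bit values divided by 255) and pushed
through the BT.709 matrix to XYZ, normalized by the D65 white point
$(0.950456, 1, 1.088754)$, and mapped to CIELAB through
$f(t) = t^{1/3}$ above $(6/29)^3$ and its linear continuation below. Hue
angle and chroma are the polar coordinates of $(a^*, b^*)$, with the
two-argument arctangent (the textbook $\tan^{-1}(b^*/a^*)$ is
quadrant-ambiguous) and $h := 0$ when $C^* = 0$ — a harmless convention
because every downstream use multiplies by $C^*$.

The quirk: **no sRGB gamma expansion is applied before the matrix**. The
source formulation applies the linear matrix directly to the stored
channel values, and we reproduce that chain exactly so that feature values
are comparable with the reference model's training scale. A `gamma = TRUE`
flag provides the colorimetrically standard decoding for users who want
true CIELAB; the two chains give visibly different $L^*$ mid-tones, so
they must not be mixed within one dataset.

## Tunable parameters

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| `smooth_radius` | 50 | pixels | The circular-template radius at which observers stop recognizing edge/semantic content in ~720p film material. Scale it down proportionally for small images; it must not exceed the smaller image dimension. |
| `j` (palette) | 8 | clusters | Enough dominant colors to cover rich film scenes without fragmenting; the palette feeds only f16. |
| `connectivity` | 8 | – | Watershed adjacency; 4 is available, 8 keeps diagonal color runs connected. |
| `k` (CV) | 10 | folds | Standard for n in the low hundreds. |
| `threshold` | 0 | score | "Harmonious" means strictly positive score; a tie at 0 is classed disharmonious (strict inequality). |

The circular mean filter intersects its template with the image and
renormalizes, so borders average only real pixels; the center pixel is
included (ordinary mean filter). Filtering is done in RGB before any
conversion, matching the workflow order (smooth, then measure).

## Feature definitions worth spelling out

* **Moments (f1–f9).** Population ($1/N$) variances throughout; the third
  moments use the signed cube root $\mathrm{sign}(m)\,|m|^{1/3}$ so
  left-skewed lightness keeps a negative f7.
* **Space density (f11–f12).** The watershed treats the smoothed BT.709
  grayscale itself as topography — no gradient pre-step; the 50-px
  smoothing is the implicit over-segmentation control. f12 is the standard
  deviation of region sizes (the defining text says "standard deviation",
  so the square root is applied even though one printed formula omits it;
  this also keeps f12 dimensionally consistent with f16).
* **Neighborhood contrasts (f14, f15).** The sum of squared differences
  over *ordered* (center, in-image 8-neighbor) pairs divided by the number
  of pairs actually summed. Reading $N$ as the pair count (rather than the
  pixel count) makes the statistic a bounded mean squared local difference,
  independent of image size; border pixels simply contribute fewer pairs.
  No outer square root is taken, so units are squared. A single-pixel
  image has no pairs and returns 0.
* **Warm-cool degree.** $WC = -0.89 + 0.052\,C^*[\cos(h-50^\circ) +
  0.16\cos(2h-350^\circ)]$ from Ou's color-emotion work; achromatic pixels
  sit at the constant −0.89.

## Palette construction

Lloyd's algorithm runs on per-pixel $(L^*, a^*, b^*)$ vectors — the
chromatically meaningful space, chosen over an RGB reading of the
clustering step for consistency with every other computation. Seeding is
k-means++ under an explicit seed (reproducibility; plain random seeding
makes the 8-block recovery test flaky), convergence is centroid movement
$< 10^{-6}$ or 300 iterations, empty clusters are re-seeded at the point
farthest from its centroid, and numerically coincident centroids are
merged (so a uniform image reports one effective color, not eight copies).
Palettes are ordered by descending count with $L^*, a^*, b^*$ tie-breaks,
and strips are rendered with largest-remainder width apportionment.

## Watershed semantics

Immersion flooding is order-ambiguous on plateaus in its classic FIFO
formulation, so this implementation fixes a deterministic, synchronous
semantics: per gray level, existing basins claim plateau pixels in order
of geodesic distance *through the plateau*; a pixel whose minimal-distance
claimants span two or more basins becomes a watershed-line pixel (label
0); pixels reachable only via line pixels join the line; components
reached by nothing are new regional minima and seed new basins (numbered
by smallest linear index — an arbitrary but fixed tie-break). Basin labels
always beat line adjacency, line pixels belong to no region, and the
result is invariant under relabeling-free symmetries: adding a constant to
all gray values changes nothing, and mirroring the image mirrors the
labels. The test suite checks the implementation against an independent
per-basin breadth-first flooding oracle on random images.

## The harmony model and its missing anchor

The bundled `reference_harmony_model()` carries the published fitted
coefficients over seven min-max normalized features (f1, f4, f5, f11, f13,
f14, f15; intercept 0.249). The original training min/max values were
never published, so **absolute scores on new images are not anchored to
the original scale**: the model object carries no normalization bounds,
`predict_harmony()` takes its inputs as already normalized, and the CLI
refuses to score raw feature tables unless the user supplies `--norm` or
opts into `--batch-norm` (min/max from the scored batch). Silent
mis-scaling would be invisible, hence the hard guard.

Fitting is ordinary least squares through a QR decomposition;
rank-deficient designs are rejected unless the ridge fallback
($\lambda = 10^{-8}$, with a warning) is requested. The rule-based
attribute selection used to derive the published model is tool-specific
and under-documented, so it is replaced by optional greedy backward
elimination on cross-validated RMSE; the published model itself ships as a
constant rather than being re-derived. Cross-validation shuffles under a
fixed seed (default 0), stratifies only for the classification task, and
pools predictions across folds before computing r, MAE, RMSE and the
correct classification rate. Cronbach's alpha treats raters as the $K$
test components and materials as observations, with population variances,
matching the printed orientation; the margin is configurable.

## The synthetic world

The generators state the world the tests live in; none of their parameters
were adjusted after seeing test results.

* `make_blocks` builds axis-aligned full-width bands, so palette and
  region ground truth are exact by construction and are returned as
  sidecars — tests never re-derive truth from the image.
* `make_rating_matrix` defaults to 164 materials × 84 raters, the
  reference study's dimensions, with Gaussian rater noise rounded and
  clipped to the 5-level scale — the simplest noise model that produces
  legal ratings.
* `make_feature_dataset` draws features uniform on $[0,1]$ (the
  normalized scale) and generates targets from the reference model plus
  Gaussian noise, giving the OLS-recovery tests a known truth.

What a green suite establishes: the formulas, the degenerate cases, the
oracle equivalences, and parameter recovery under the stated noise. What
it does not establish: the published dataset-dependent results (feature
correlations near $r = -0.39$, regression accuracy 63.9%, classification
accuracy 80.2%, $\alpha = 0.908$) — those require the original rated
film-frame dataset, which is not distributable, and the acceptance targets
are accordingly the analytic constants of the model formulas.

## Numerical choices and degenerate inputs

Cumulative-sum windowing makes the circular filter $O(HW\,r)$, with a
constant-image short-circuit so uniformity survives float rounding exactly.
Squared distances are clamped at 0 against cancellation; centroids closer
than $10^{-9}$ merge; min-max normalization clamps out-of-range inference
values (warning only beyond $10^{-9}$, so re-scoring the fitting set stays
silent); entropy normalizes IEEE $-0$; out-of-gamut Lab→RGB conversions
clip to $[0,1]$ with a warning. Empty images, radii exceeding the image,
mismatched lengths, rank-deficient designs, constant correlation inputs
and sub-2-rater reliability all fail fast with explanatory errors.

## Known limitations

* No ICC profiles, chromatic adaptation beyond fixed D65, or CAM16; the
  default chain intentionally reproduces the no-gamma formulation.
* The watershed is direct-on-grayscale by design; gradient or
  marker-controlled variants are out of scope, so unsmoothed noisy images
  over-segment (use the smoothing radius as the control).
* Pure-R flooding and clustering are comfortable at test scale and at a
  few hundred thousand pixels, but are not tuned for 4K frames.
* The rating noise model is i.i.d. Gaussian; real raters drift, anchor and
  differ in scale use, so synthetic alpha values run high at these rater
  counts.
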