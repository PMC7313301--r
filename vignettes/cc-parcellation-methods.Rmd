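---
title: "Methods: unsupervised corpus callosum parcellation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised corpus callosum parcellation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccparcel)
```

## The problem

The corpus callosum (CC) is the largest white-matter tract of the brain and
appears as a bright arch in midsagittal T1-weighted MRI. Analyses of callosal
morphology work with a *parcellation* of the structure into five sub-regions
(rostrum/genu through splenium), ordered anterior to posterior. The two
standard parcellations — Witelson's and Hofer's — are purely geometric: they
cut the anterior–posterior (AP) extent at fixed fractions, identically for
every subject. `ccparcel` implements a fully automatic, *non-geometric*
alternative: the CC is segmented without supervision from a single slice,
over-segmented into SLIC superpixels, and the superpixels are grouped into
five parcels driven by the image itself. The geometric schemes are included
as baselines, together with a confusion-matrix evaluation harness and a
phantom generator that provides exact ground truth.

Two features make the segmentation part non-trivial. First, the fornix — a
thin white-matter structure of nearly identical intensity — frequently
touches the CC in midsagittal slices and must not be swept into the mask.
Second, no landmark marks the parcel boundaries, so any subdivision rule
must come either from geometry or from the data.

## Pipeline and models

### Anisotropic diffusion (preprocessing)

Noise is suppressed with Perona–Malik diffusion on the 4-connected lattice:

$$u^{t+1} = u^t + \lambda \sum_{d \in \{N,S,E,W\}} g(\nabla_d u)\, \nabla_d u,
\qquad g(s) = e^{-(s/\kappa)^2},$$

with reflecting boundaries (edge replication), so the scheme conserves the
global mean and obeys the maximum principle. Defaults: 15 iterations,
$\lambda = 0.25$ (the stability bound of the explicit scheme), exponential
conductance, and $\kappa = 0.12$ *on the normalized [0, 1] intensity scale*.
The choice of $\kappa$ matters: it must sit between the noise scale
(≈ 0.02–0.03 here) and the edge contrast (≈ 0.4). The conventional value 30
quoted for this filter assumes 0–255 intensities; applied to normalized
intensities it drives the conductance to 1 everywhere and the filter
degenerates to linear blurring, which we measured to smear structure
boundaries into intermediate-intensity ramps that later split off the CC rim
during clustering. A rational conductance $g(s) = 1/(1+(s/\kappa)^2)$ is
also available.

### Unsupervised classification (K-means + PNN)

Classification runs on the scalar normalized intensity. For a candidate
class count $k$, Lloyd's K-means (kmeans++ seeding, four deterministic
restarts, iterated until the assignment is stable or 300 iterations) defines
$k$ centroids; each class keeps a subsample of at most 256 of its member
intensities as *pattern units*. A probabilistic neural network (PNN) — a
Parzen-window classifier — then assigns every pixel to the class of maximal
kernel density

$$f_c(x) = \frac{1}{n_c}\sum_{u \in \text{units}(c)} \exp\!\left(-\frac{(x-u)^2}{2\sigma^2}\right),$$

with $\sigma$ defaulting to half the mean nearest-centroid gap, and ties
resolved toward the smaller class index. Intensity-only features keep the
classifier well-posed and match the appearance of published cluster maps;
texture or spatial features are deliberately out of scope.

Restart count and seeding were chosen because single-start random
initialization loses the global optimum on three-plateau test images in
roughly a quarter of seeds; kmeans++ with four restarts removed every such
failure in our studies without measurable cost.

### Choosing the number of classes (validity index)

The class count is selected by maximizing a cluster-validity score
`vmep_score()` over a range (default 2–6). The index treats each class as a
maximum-entropy density for its observed mean and variance — a Gaussian —
and scores the penalized log-likelihood of the resulting mixture,

$$V(k) = \frac{2\,L(k) - (3k-1)\log n}{n},$$

an MDL/BIC criterion (per class: mean, spread, proportion). Merging two
separated intensity modes into one class costs likelihood heavily; splitting
one mode gains almost nothing and pays the complexity penalty, so $V$ peaks
at the best-supported count. Class spreads are floored at $10^{-4}$ so flat
(zero-variance) classes stay finite; ties in the maximization go to the
smaller $k$.

This formulation was a genuinely open design point, and we record why the
obvious alternatives fail. Histogram-based indices built from between/within
class entropies or from the mutual information between class and binned
intensity look natural, but all variants we evaluated mis-select on at least
one of our two synthetic families: normalized between-class entropy rewards
splitting a Gaussian class (the within-entropy drop beats the $\log k$
penalty — every seed of the three-plateau study selected $k \ge 4$), while
$I(C; \text{bin})/\log k$ punishes unbalanced but correct partitions (on the
arch phantom, where the CC is ~8 % of pixels, it merges CC with tissue at
$k=2$). The failure is structural: a split of a unimodal class is genuinely
informative at any bin resolution, because bin edges can always resolve the
split point, so only a model-fit criterion penalizes it reliably. The
likelihood form keeps the maximum-entropy character (Gaussians are the
maximum-entropy members for fixed first two moments; $-L/n$ is the model
cross-entropy) and recovered the true count in 20/20 seeds for both the
two- and three-plateau conditions.

### CC isolation and fornix removal

The CC candidate class is the cluster with the highest mean intensity (the
CC is the brightest white-matter structure in these slices). Its binary mask
undergoes a radius-1 morphological opening, which severs thin bridges — the
fornix surrogate in the phantom is 2 px wide and is removed entirely — and
the 8-connected components are scored by a spatial prior

$$\text{score} = \text{area} \cdot \exp\!\left(-\frac{d^2}{2\tau^2}\right),$$

where $d$ is the distance from the component centroid to a point 40 % down
and 50 % across the image (the CC sits centrally and slightly above centre
in midsagittal slices) and $\tau$ is 25 % of the image diagonal. The best
component becomes the CC mask; if no component reaches 0.1 % of the image
area the pipeline reports "CC not found" rather than guessing. The contour
is traced with Moore-neighbour tracing, stopping when the walk is about to
repeat its first move out of the start pixel (the robust form of Jacob's
criterion); on a binary mask every border pixel is a spatial-gradient
maximum, so the traced chain is the maximal-gradient border.

### SLIC superpixels

Superpixels are generated by localized K-means over a joint
spatial–intensity distance. With $N$ in-scope pixels and $K$ requested
superpixels, seeds start on a grid of spacing $S = \sqrt{N/K}$, each
perturbed to the lowest-gradient position in its 3×3 neighbourhood, and the
assignment of each pixel searches only centres within a $2S \times 2S$
window. The combined distance is

$$C_d = \sqrt{I_d^2\,(S_d/S)^2 + e^2},$$

with $S_d$ the Euclidean pixel distance, $I_d$ the intensity distance, and
$e \in [0,1]$ the compactness coefficient. Two properties of this form
deserve note. First, $e$ enters as the same additive constant for every
candidate centre, so it cannot change which centre attains the minimum — it
is retained for interface fidelity, and the superpixel shape is governed by
the $I_d (S_d/S)$ product. Second, on locally flat regions $I_d = 0$ makes
all candidate centres equidistant; assignment therefore breaks ties by
smaller spatial distance, then smaller label, which reduces to a spatial
Voronoi partition there (and, on a globally constant image, to a near-square
tiling). Both facts are covered by tests.

$I_d$ defaults to $|N_j - N_i|$, the standard SLIC intensity term. A
root-sum variant $\sqrt{N_j + N_i}$, printed in part of the CC-parcellation
literature, is available via `intensity_mode = "root_sum"`; it is not a
metric (it does not vanish for equal intensities) and is provided for
comparability, not as a default.

Ten iterations (or convergence below 0.5 px of centre motion) are followed
by a connectivity pass: each superpixel keeps its largest 4-connected
fragment and orphan fragments are relabelled to the adjacent superpixel
sharing the longest border. The defaults $K = 200$, $e = 0.5$ target
256 × 256 slices; for parcellation SLIC runs *inside the CC mask* (seeds on
the S-grid restricted to the mask). Whole-slice operation is also supported,
and which of the two a practitioner prefers is a genuine open choice — ROI
mode is the pipeline default because it spends the full superpixel budget on
the structure of interest.

### Five parcels

**Geometric baselines.** Witelson cuts the AP extent at 1/3, 1/2, 2/3, 4/5;
Hofer at 1/6, 1/2, 2/3, 3/4 (both share the 1/2 and 2/3 cuts, so their third
parcels coincide exactly — a useful internal consistency check). The AP axis
is the first principal axis of the mask pixels, oriented so anterior points
toward smaller columns (`flip` inverts; image orientation is a convention,
not something a single slice can reveal). Each pixel's normalized axis
position $t \in [0,1)$ is compared with the boundary fractions; a position
exactly on a boundary joins the posterior parcel, and on axis-aligned
rectangles of extent $n$ the cut columns equal $\lfloor f \cdot n \rfloor$
exactly.

**Superpixel grouping.** No landmark defines how superpixels become five
parcels, so the rule is this package's design: superpixel centroids are
projected onto the AP axis and clustered by one-dimensional K-means
($k = 5$, deterministic farthest-point initialization, sample weights =
superpixel area × mean intensity), groups are relabelled 1–5 by ascending
mean projection, pixels inherit their superpixel's parcel, and a contiguity
repair pass reassigns any fragment disconnected from its parcel's main body
to the neighbour with the longest shared border. The weighting lets brighter
(more CC-typical) superpixels dominate boundary placement while area keeps
parcels balanced in pixel mass. This rule is data-driven — parcel
boundaries move with each subject's superpixel geometry — which is the
behavioural signature of non-geometric parcellation; we do not claim it is
the only reasonable grouping.

### Evaluation

For each parcel the prediction and ground truth are binarized one-vs-rest
and tallied into TP/TN/FP/FN over the full image. The five reported metrics
are

$$\mathrm{Dice}=\frac{2TP}{2TP+FN+FP},\quad
\mathrm{Acc}=\frac{TP+TN}{TP+FN+TN+FP},\quad
\mathrm{Sens}=\frac{TP}{TP+FN},$$
$$\mathrm{Spec}=\frac{TN}{TN+FP},\quad
\mathrm{Prec}=\frac{TP}{TP+FP}.$$

Background-inclusive TN is the default (it is what makes accuracy and
specificity run high in this kind of evaluation); `roi_only = TRUE`
restricts the tally to the union of the two foregrounds. Empty-vs-empty
Dice is defined as 1 (agreement on absence) with a logged note; other
zero-denominator metrics report `NA` markers rather than erroring.
`pairwise_dice_table()` computes per-parcel Dice for every unordered pair of
methods.

## The phantom generator

`make_phantom()` renders the test conditions: a downward-opening annular
arch (the CC surrogate) at intensity 0.85, an enclosing tissue ellipse at
0.45, background at 0.05, optional 2-px-wide fornix surrogate descending
from the arch's posterior underside (8-adjacent to but disjoint from the
arch, sharing its intensity — the classic trap), and additive Gaussian noise
of σ = 0.03 clipped to [0, 1]. The defaults are the "easy" condition:
adjacent intensity levels differ by 0.4 ≥ 5σ. Ground truth comprises the
exact arch mask and five equal-arc-length parcel bands (the natural analogue
of fixed-fraction schemes on a curved structure — a convention of this
generator, not of any published scheme). Everything is deterministic given
the seed.

What the phantom does *not* emulate: bias fields, partial-volume averaging,
Rician noise statistics, anatomical shape variability, and neighbouring
structures other than the single fornix surrogate. Passing the recovery
tests therefore demonstrates the pipeline's correctness and its fornix
robustness under controlled contrast, not clinical-grade performance on real
MRI.

## Numerical choices and degenerate inputs

* Diffusion: $\lambda \le 0.25$ enforced (explicit-scheme stability);
  constant images are exact fixed points.
* Normalization: min–max to [0, 1]; constant images map to zero;
  idempotent.
* K-means: empty clusters are revived at the farthest point from their
  centre; `k` above the number of distinct intensities is a validation
  error.
* Validity index: class spread floored at $10^{-4}$; empty classes and
  single-class maps are validation errors.
* SLIC: assignment ties break by (combined distance, spatial distance,
  label); grid-rounding seed surplus is trimmed to an evenly spaced subset
  so the superpixel count never exceeds $K$; pixels left unreached by every
  search window join the spatially nearest centre.
* Parcellation: near-isotropic masks (principal-axis variance ratio
  below 1.05) fall back to the column axis with a warning; masks shorter
  than 5 px along the axis, and masks covered by fewer than 5 superpixels,
  are validation errors; degenerate projection sets fall back to a rank
  split.
* All randomness flows through explicit integer seeds; repeated runs are
  bit-identical (the pipeline manifest records MD5 checksums to make this
  checkable).

## Problem sizes used in the shipped studies

The shipped tests and the acceptance script run entirely on generated data:
plateau images at 96 × 96 for model-selection recovery (20 seeds per
condition), structural SLIC checks on 64 × 64 phantoms (20 seeds), and the
full pipeline at the native 256 × 256 phantom size (20 seeds in the test
suite, 10 in the acceptance script). These sizes exercise every code path at
the study conditions while keeping a full run in the minutes range on one
core.

## Known limitations

* Single-slice only: no automatic midsagittal plane selection, no 3-D
  supervoxels, no DICOM.
* The superpixel-to-parcel grouping rule and the validity index are this
  package's documented interpretations of components that published
  descriptions leave unspecified; results that depend on their precise form
  are not claimed to reproduce any particular published table.
* Intensity-only clustering will not separate structures of equal intensity
  that touch; the fornix is handled by morphology and the spatial prior, not
  by the classifier.
* The geometric axis is a straight line; on strongly curved CCs a curved
  centerline parameterization would distribute parcels differently,
  especially in the limbs (genu/splenium).
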