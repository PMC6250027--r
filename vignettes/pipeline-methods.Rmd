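---
title: "Methods: nuclei detection and malignancy classification in cytological pleural effusion images"
author: "PleuraCAD authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclei detection and malignancy classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PleuraCAD)
```

# Scope and model

PleuraCAD implements a seven-stage computer-aided diagnosis pipeline for
cytological pleural effusion (CPE) microscopy: preprocessing, nuclei
segmentation, morphological postprocessing, overlapped-nuclei resolution,
feature extraction, feature selection, and classification. The deliverable
of the pipeline is a per-nucleus benign/malignant call; the cytological
premises are that malignant nuclei are larger, darker, and more coarsely
textured (chromatin clumping) than benign ones, and that these cues are
measurable once each nucleus is delineated as its own region.

Clinical CPE image sets with per-cell annotation are not publicly
distributable, so the package ships a synthetic scene generator
(`generateScene()`) that renders the cues the pipeline measures and serves
as the ground-truth oracle for every stage's tests.

# Synthetic scenes: what they emulate and what they do not

`SceneSpec()` fixes the study conditions: a 1024 x 1024 8-bit RGB canvas;
dark, roughly elliptical nuclei on a pale pink-grey background with a mild
diagonal illumination gradient (exercising the contrast stretch); a
configurable fraction of nuclei placed in touching pairs whose centre
distance is uniform in $[0.7, 1.1] \times (r_1 + r_2)$, guaranteeing the
concave necks the splitter looks for; impulse (salt-and-pepper, density
0.02) and Gaussian ($\sigma = 3$) acquisition noise.

Class contrast follows the malignancy cues: benign mean radius 10-16 px
versus malignant 16-26 px; malignant nuclei darker by 40 intensity units;
chromatin noise $\sigma$ of 5 (benign) versus 12 (malignant) on top of a
multiplicative low-frequency texture field. No quantitative morphometry of
real Pap-stained pleural-effusion cells was available to calibrate these
numbers; they were chosen once as plausible for 40x captures downscaled to
1024 px and are not tuned thereafter.

The generator does **not** emulate cytoplasm, stain spectra
(haematoxylin/eosin absorption), out-of-focus blur, or clusters of three
or more nuclei beyond what random placement produces. Passing tests
therefore demonstrate internal correctness and recoverability of planted
structure, not clinical performance.

# Preprocessing

Images are resized to the 1024 x 1024 working resolution (bilinear; a
Gaussian pre-smoothing with $\sigma = 0.5\sqrt{f^2 - 1}$ at decimation
factor $f$ suppresses aliasing that would contaminate texture features),
contrast-stretched per channel (percentiles 1/99 mapped to 0/255 --
standard 1% saturation; the stretch is monotone and a degenerate channel
passes through unchanged), then median-filtered per channel with the
smallest (3 x 3) window so impulse noise is removed without blurring
nucleus edges. Adjustment precedes filtering. The 3 x 3 path uses a
19-exchange median sorting network with edge-reflected borders.

# Hybrid SLIC/K-Means segmentation

SLIC superpixels (default 500, compactness 10) are computed in the joint
$[l\,a\,b\,x\,y]$ space with the conventional distance
$D^2 = d_{lab}^2 + (m/S)^2 d_{xy}^2$, $S = \sqrt{N/k}$, searching the
standard $2S \times 2S$ window for 10 sweeps; colour conversion uses sRGB
with the D65 standard observer. A connectivity pass then flood-fills
4-connected fragments; only fragments below $S^2/8$ are absorbed by a
neighbour. The bound matters: the nucleus scale in these images
($r \approx 10$-26 px, i.e. 300-2000 px of area) sits *below* the mean
superpixel area at 500 superpixels, so an aggressive minimum-size rule
would erase small nuclei outright.

Each superpixel is summarised by its componentwise **median** L\*a\*b\*
colour (robust to the few boundary pixels it may contain), and K-Means
with $k = 2$ (k-means++-style seeding, 10 restarts, explicit seed for
reproducibility) labels the cluster with the lower mean L\* as nuclei --
Pap-stained nuclei are reliably darker than background. Clustering 500
colour medians instead of $10^6$ pixels is what makes the hybrid fast;
the unit suite asserts the direction of that saving rather than absolute
times. K-Means runs on colour only, not position: nuclei of one class
share colour, not location.

# Multiscale morphological refinement

Opening deletes sub-element debris and closing smooths boundaries
(`openClose()`), with a disk structuring element. A single radius cannot
fit all objects, so refinement is per component: each connected component
is assigned the radius from $\{7, \dots, 15\}$ closest to half its
equivalent radius (clamped), is deleted if it does not survive its
opening, and is smoothed by a paired closing at half that radius (rounded
up). Components under `minArea = 50` px are dropped -- they are too small
to carry stable texture. The per-component rule is a deterministic
interpretation of a multiscale sweep; a global union over radii was
rejected because large radii erase exactly the small nuclei the sweep is
meant to protect.

# Overlap identification and splitting

Splitting is **gated**: a five-feature shape descriptor (solidity,
eccentricity, equivalent diameter, major/minor axis) feeds an RBF-kernel
SVM that classifies each component single/overlapped, and only overlapped
components are split. Gating prevents oversplitting of lone nuclei and
cuts cost; the test suite verifies that gated resolution never produces
more split errors than unconditional splitting on generated scenes. The
SVM is trained on synthetic single ellipses and fused pairs
(`makeOverlapShapeSet()`) because clinical shape annotations are not
distributable; the surrogate reaches about 93% held-out accuracy on its
own distribution.

For an overlapped clump, the closed contour is traced, smoothed with a
circular Gaussian ($\sigma = 3$ samples, curvature-scale-space style),
and its curvature extrema are tested for concavity by a chord-midpoint
rule: the midpoint of the chord spanning $\pm 5$ samples must fall
outside the region. Points must exceed the 90th percentile of curvature
magnitude; runs of adjacent candidates collapse to their sharpest member.
Convex shapes yield no concave points by construction.

The contour is cut at the concave points; segments are greedily merged
while the joint **direct least-squares ellipse fit** (stable reduced
scatter-matrix formulation, points centred and scaled before solving)
keeps a mean normalised radial residual below 0.05 and an axis ratio
below 4 -- nuclei are near-elliptical, so a good group is a near-perfect
arc set. Each final group contributes one ellipse; clump pixels are
reassigned to the ellipse with the smallest normalised radial distance,
so splitting conserves pixels exactly. If fewer than two concave points
exist or no valid grouping is found, the whole contour is fitted as one
ellipse (fail-safe: never split on weak evidence).

# The 201-feature vector

Codes F1-F201 in five blocks: 14 morphometric, 6 colorimetric means
(R, G, B, H, S, V), 49 colour-component first-order statistics (7
statistics x 7 components R, G, B, H, S, V, gray, component-major),
88 GLCM (22 statistics x 4 orientations, orientation-major), 44 GLRLM
(11 x 4). All channels live on the [0, 255] scale (H, S, V scaled up
from [0, 1]; gray is ITU-R 601 luma, $0.299R + 0.587G + 0.114B$).

Numerical conventions, fixed once: perimeter is chain-code length (axial
steps 1, diagonal $\sqrt 2$); axis lengths come from the image-moments
ellipse with the 1/12 pixel-extent correction; eccentricity is
$\sqrt{1 - (b/a)^2}$; kurtosis is excess kurtosis (the $-3$ term
included); a constant region has skewness and kurtosis defined as 0.
GLCM/GLRLM quantise gray to NG = 8 uniform bins over the fixed [0, 255]
range -- per-nucleus min-max scaling would decouple darkness from
texture, and darkness is a malignancy cue. Cooccurrence pairs (offset
d = 1) and runs are counted only inside the region mask; pairs accumulate
symmetrically; the four orientations are $(1,0), (1,1), (0,1), (-1,1)$
in raster steps, so rotating a region by 90 degrees exactly permutes the
orientation blocks (a property the suite asserts). Entropies use natural
logarithms with $0 \log 0 = 0$; correlation-type statistics are 0 when a
marginal variance vanishes; the sum-variance statistic is centred on the
sum-entropy value and the difference variance is the uncentred second
moment of the difference marginal -- both follow the classical
formulation this feature list derives from. The two "inverse difference
normalised" statistics use the standard $1 + |i-j|/L$ and
$1 + (i-j)^2/L^2$ denominators.

Both matrix families are verified against brute-force oracles (explicit
scalar pair/run enumeration) to $10^{-9}$ on random masked images, and
the FOS statistics against direct moments to $10^{-6}$ on integer
samples.

# SA-ANN feature selection

A classic simulated-annealing loop over fixed-cardinality subsets: one
uniform swap per iteration, downhill moves always accepted, uphill with
probability $\exp(-\Delta/T)$, geometric cooling $T_k = T_0\,\alpha^k$,
best-so-far returned. Operating defaults are 50 iterations, $T_0 = 10$,
$\alpha = 0.99$, subset size 20. The cost of a subset is the held-out
misclassification rate of a 3-layer feedforward network (10 hidden units,
logistic output) on a stratified 70/30 split, averaged over 3
weight-initialisation restarts to damp initialisation variance; split and
restarts are functions of the seed only, so a subset's cost is
reproducible. The network is trained with nnet's quasi-Newton (BFGS)
optimiser; the selector's behaviour depends on the cost *ranking*, not
the trainer brand, so any convergent second-order trainer is conformant.

The recovery experiment in the acceptance suite anneals over a reduced
candidate pool (5 planted informative + 15 noise columns) with a longer,
colder schedule (250 iterations, $T_0 = 0.5$, $\alpha = 0.95$). The
design follows from hitting-time arithmetic: with uniform one-swap
proposals over the full 201-column pool the expected time to propose the
last missing informative feature alone is
$\approx 5 \times 196 \approx 10^3$ iterations, far beyond a 50-iteration
budget at any temperature, so desk-scale recovery must shrink the pool,
not the claim. The planted signal uses the generator's `"subtypes"` mode
-- each positive row belongs to one informative column's subpopulation --
so every informative feature carries a roughly constant increment of
attainable accuracy and the planted set is uniquely identifiable; a plain
mean shift on five columns saturates after three or four features, making
"full recovery" ill-posed. This mirrors the biological reading that
different malignant subpopulations express different cues.

# Classification

The classifier is an ensemble of 100 bagged decision trees: each tree is
grown unpruned (complexity penalty 0, minimum split 5) on an n-out-of-n
bootstrap of the training rows restricted to the selected features, and
prediction is by majority vote with exact 50/50 ties resolved toward
malignant -- in a screening context a false negative costs more than a
false positive. Training reports a stratified 5-fold cross-validation
alongside the final model; the pipeline splits images 80/20 into
disjoint train/test sets at the *image* level, so no image contributes
nuclei to both sides, and cross-validation runs within the training
split. Metrics are the six confusion-matrix quantities (sensitivity,
specificity, precision, recall = sensitivity, F-score, accuracy) in
percent; a zero-denominator ratio is reported as 0 with a warning flag.

# Problem sizes and numerical choices

The test and acceptance runs use: 20 scenes of 1024 x 1024 px with 50
nuclei each for segmentation recovery (mean Dice is typically 0.97 or
higher; the suite requires at least 0.85 per scene); 30 two-disk clumps
of radius 15-25 px at centre distance $1.5r$ for the splitter; 20 (tests)
or 10 (acceptance script) seeds for annealing recovery; 800-row feature
tables at 15% prevalence for the ensemble. These sizes were chosen so a
single desk run exercises every stage in minutes while leaving the
statistical margins (binomial error of a rate over 20-30 trials) far from
each threshold.

Degenerate inputs are contracted, not patched over: empty masks raise or
return empty results per the API; constant channels pass through the
stretch; constant regions produce the defined FOS/GLCM values; a clump
with no concave evidence is never split; a collinear point set returns no
ellipse.

# Known limitations

* The synthetic scenes are the only validation substrate; no claim is
  made about clinical images.
* The overlap gate is trained on rendered shapes, not annotated clumps.
* Clumps of three or more nuclei are split correctly when necks are
  clearly concave, but heavily eroded necks (overlap beyond about 60% of
  the radius) can fall back to a single ellipse.
* Feature selection quality depends on the network cost's
  signal-to-noise; very small tables (under ~100 rows per class) make
  the annealer wander.
* The CLI (`inst/scripts/pleuracad.R`) is a thin wrapper; stage
  composition beyond the provided subcommands is done in R.
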