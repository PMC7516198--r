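---
title: "Detecting cells and quantifying monolayer topology in scratch-wound assays"
author: "scratchTopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cells and quantifying monolayer topology in scratch-wound assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scratchTopo)
```

## The analysis problem

A scratch-wound (wound-healing) assay scratches a gap into a confluent
cell monolayer and reads migratory capacity from how much of the gap the
cells cover over time, typically between 0 h and 24 h. Classical analyses
reduce each well to a single number — wound area — and discard everything
the image says about the cells themselves. At the magnification used for
whole-well imaging, full cell segmentation is unreliable, but *detection*
is not: one dot per cell centre is cheap to annotate and sufficient to
reconstruct a surprising amount of tissue-level structure.

scratchTopo implements that detection-first pipeline end to end:

1. **Detection.** A U-Net regresses a per-pixel *belief map* of
   cell-centre presence from a greyscale image; local maxima of the map
   are the detected cells.
2. **Wound segmentation.** The wound is recovered from the detected
   coordinates alone, as the largest connected cell-free region.
3. **Topology.** The Voronoi tessellation of the detected centres gives
   each cell a polygon class (side count), neighbours and an area proxy;
   local cell density (LCD) and its wound-normalised variant quantify the
   spatial coordination of spreading; per-well fold-change signatures are
   compared in principal-component space.

A synthetic-monolayer generator with known ground truth makes each stage
testable without any external imaging data.

## Belief-map regression

Dot annotations are turned into a regression target by placing each
annotation on its pixel and convolving with an isotropic Gaussian
(`renderBeliefMap`). The kernel sigma defaults to 2.5 px; the right value
scales with the apparent cell size. Two choices are worth stating:

* the single-point peak is normalised to 1, so detection thresholds have
  a stable meaning regardless of sigma;
* kernels are truncated at three sigma and clipped (not renormalised) at
  image borders, matching plain convolution of a point mask.

The network (`netSpec`, `buildModel`) is a U-Net with a constant channel
width (48 by default), two convolutions per block, leaky-ReLU (slope 0.1)
activations, no batch normalisation, 2x2 max-pooling on the way down and
2x2 nearest-neighbour upsampling with concatenated skip connections on
the way up; the first convolution is 7x7, all others 3x3, and a final 1x1
linear layer emits the single-channel map. Input sides must be divisible
by `2^depth`. Forward and backward passes are implemented in the package
(im2col + BLAS matrix products), so training runs anywhere R runs.

Training (`trainNet`) minimises per-pixel mean squared error with Adam.
Crops of 96x96 px (configurable) are sampled cell-centred with
probability 0.8 and uniformly otherwise, so most crops contain cells but
empty regions are still seen. Augmentation applies 90-degree rotations
and flips (lossless on a pixel grid — arbitrary-angle rotations would
resample both image and annotations for little extra variety), isotropic
scaling in [0.9, 1.1], and one of two intensity perturbations per crop:
multiplication by a factor in [0.5, 1.3] or subtraction of an offset in
[-0.2, 0.2]. Geometric transforms are applied in coordinate space and
re-rendered, never by transforming the target map. Intensity
augmentation is applied after normalisation to [0, 1] (raw 12-bit values
are divided by 4095 beforehand, `normaliseImage`). The reference
learning rate is 1.28e-4 for long runs; short runs (a few hundred steps)
want around 1e-3. One epoch is a fixed number of sampled crops
(`cropsPerEpoch`), since random cropping defines no natural epoch; the
returned model is the checkpoint of the epoch with the lowest validation
loss.

At inference, `extractLocalMaxima` normalises the predicted map by its
global maximum, takes a 3x3 maximum filter, keeps pixels equal to their
filtered value above a user threshold (default 0.2), and collapses
equal-valued plateaus to their row-major first pixel so output is
deterministic. Matching against ground truth (`matchDetections`) is an
optimal one-to-one assignment on the distance matrix with pairs beyond
10 px forbidden; this maximises matched pairs first and total distance
second, and subsumes nearest-neighbour matching (a greedy mode exists for
comparison, and the 10 px gate can instead be applied after an ungated
assignment via `gate = "post"`). Precision, recall and F-score follow in
the usual way.

## Wound segmentation from coordinates

`densityMask` marks every pixel with a detected centre within its 13x13
neighbourhood; `segmentWound` opens the complementary empty-space mask
with a 35x35 square structuring element — erasing intercellular gaps
smaller than the element — and returns the largest connected component
as the wound, with its area and centroid. Squares are used for both
elements because only their sizes are meaningful at this resolution.
Pixels outside the image count as covered, so borders are never read as
wound. The wound "centre" is the centroid of the t0 wound component;
because wounds can close completely by 24 h, all distance-based metrics
use the t0 centre at both timepoints. A monolayer with spacing at or
below the density kernel yields zero wound area and an undefined centre,
which downstream functions refuse with an explicit error.

## Topology metrics

`voronoiTopology` computes each cell's Voronoi region by incremental
half-plane clipping against neighbours in order of distance, with a
geometric bound that stops the scan once no remaining bisector can reach
the region. Side count equals the number of neighbours across ridges of
*positive* length: with four or more co-circular centres (e.g. a square
lattice) the diagonal "ridges" have zero length and create no adjacency,
which both matches the geometry and keeps results deterministic. Cells
whose region touches the image boundary, is clipped away entirely, or
has a vertex inside the wound mask are excluded from polygon statistics —
their polygons reflect the clipping, not the tissue.

Polygon classes are binned 4, 5, 6, 7, 8 and 9-or-more; regions with
three or fewer sides only arise from degenerate clipping and are
discarded. Under random spatial mixing, a focal cell with $s$ sides is
expected to share $s \cdot f_c$ sides with class $c$ of frequency $f_c$
(`expectedCooccurrence`); with 36% hexagons a hexagon expects
$6 \times 0.36 = 2.16$ hexagon-shared sides. Observed co-occurrence
(`observedCooccurrence`) tabulates, per focal class and neighbour class,
the distribution of the number of shared sides, row-normalised; one
neighbouring pair counts one shared side. Focal cells must have fully
classed neighbourhoods (no excluded neighbours), otherwise their count
vector would be censored.

Local cell density is the inverse distance to the k-th nearest
neighbour, with k = 36 as the primary scale (direct plus indirect
neighbours) and k = 10 secondary (`localCellDensity`); both are
configurable. Normalised LCD divides by the distance to the t0 wound
centre. The per-well signature (`wellSignature`) computes seven
distributional statistics — median, skewness, standard deviation and the
10/25/75/90% quantiles — of the wound-normalised version of each of the
three density measures (LCD at both ranks and Voronoi area), at each
timepoint, and their elementwise fold change t24/t0 (21 features).
Quantiles use the linear-interpolation convention and skewness the
adjusted Fisher–Pearson coefficient; no convention is canonical here, so
the choice is pinned and tested against hand-written formulas.
`projectSignatures` standardises each feature before PCA because fold
changes of different statistics live on different scales.

## The synthetic generator, and what it does not emulate

`generateMonolayer` places cells on a hexagonal lattice whose pitch is
set by the target count, jittered uniformly; confluent epithelia are
near-hexagonally packed, and jitter plus edge losses produce the natural
mix of polygon classes around the hexagonal mode. A minimum pairwise
separation is guaranteed by capping the effective jitter; a density that
cannot accommodate the separation raises a capacity error rather than
silently under-filling. `applyWound` carves a straight empty band (the
scratch) and, at t24, can thin the remaining cells with retention
probability increasing with distance from the gap — the simplest
mechanism that reproduces spatially coordinated spreading, where density
rises away from the healing front. `renderImage` draws nuclei as
Gaussian blobs and membranes as Gaussian-profile ridges along the
Voronoi boundaries, over a constant background with additive Gaussian
noise on the intensity-fraction scale (the same scale as the intensity
augmentations), quantised to the requested bit depth.

The generator emulates point-pattern statistics, not cell biology: there
is no cell morphology, no migration dynamics, no uneven illumination,
and nuclei are isotropic blobs. Detection scores on synthetic images
therefore validate the machinery (rendering, training, extraction,
matching), not performance on real stains, where texture and contrast
variation dominate the difficulty.

## Numerical choices and scales used in the checks

* Default study-like conditions: 512x1392 px fields with roughly 3000
  cells (about 0.0042 cells per px^2), 12-bit intensities.
* Voronoi clipping treats edges shorter than 1e-6 px as zero-length; the
  adjacency produced is checked against an all-pairs half-plane oracle.
* Assignment uses a shortest-augmenting-path solver; out-of-gate pairs
  get a cost large enough that match count always dominates distance.
* The end-to-end detection check trains a reduced-width network (depth 3,
  8 channels) on 224 fixed 64-px synthetic nuclei crops for 30 epochs at
  learning rate 1e-3 and requires pooled F >= 0.90 on 20 held-out
  128x128 images at the 10 px gate; these sizes keep the run in the
  minutes range on a single CPU while leaving a wide margin to the
  threshold.
* The density-gradient check evaluates the LCD-distance correlation on
  3000-cell fields with the t24 wound fully closed and cells within
  60 px of the image border removed. Both choices are deliberate: an
  open gap and the image border each truncate the 36-neighbour
  neighbourhood, lowering LCD there and inducing correlations with
  distance that have nothing to do with a density gradient. With them
  controlled, a strong thinning gradient gives r well above 0.3 and a
  uniform pattern gives |r| below 0.01.

## Worked example

```{r example, eval = FALSE}
# simulate one well
well <- simulateWell(
  monolayerSpec(512, 512, nCells = 1100, seed = 1),
  woundSpec("vertical", gapCentre = 256, gapWidthT0 = 100,
            gapWidthT24 = 30, gradientStrength = 0.6),
  renderSpec("nuclei"), seed = 1)

# wound metrics from the ground-truth coordinates
w0 <- segmentWound(densityMask(well$t0$points, 512, 512))
w24 <- segmentWound(densityMask(well$t24$points, 512, 512))
woundFoldChange(w0, w24)

# topology and the per-well signature
tab0 <- computeCellMetrics(well$t0$points, 512, 512, w0)
tab24 <- computeCellMetrics(well$t24$points, 512, 512, w24,
                            woundCentre = woundCentre(w0))
polygonDistribution(tab0)
sig <- wellSignature(tab0, tab24)
head(sig$foldChange)
```

## Limitations

* Training in plain R+BLAS is CPU-bound: full-scale training (hundreds
  of epochs at width 48 over hundreds of annotated patches) is hours of
  compute, so realistic use trains once and reuses the checkpoint.
* Sub-pixel localisation is out of scope; detections are pixel centres.
* Voronoi areas approximate cell areas only in confluent regions; near
  wounds and borders the excluded-cell flags must be respected.
* The co-occurrence baseline assumes independent random placement of
  classes; it is a null model, not a generative claim about tissues.
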