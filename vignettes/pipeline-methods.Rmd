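---
title: "The mracad detection pipeline: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mracad detection pipeline: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mracad` implements a two-step computer-assisted detection (CAD) system for
cerebral aneurysms in time-of-flight MR angiography (TOF-MRA). Step one
segments the arterial tree fully automatically and dilates it into a volume
of interest (VOI); step two scores every voxel of that VOI with a compact 3D
U-Net and turns predicted components into sphere markers a radiologist can
review. This vignette explains the models behind each stage, the parameters
that matter, the numerical choices that were genuinely open, and what the
synthetic phantom tests do and do not demonstrate.

## The image model

TOF-MRA displays in-flowing blood as bright signal on a dark parenchymal
background, with one important nuisance: the skull/scalp rim is also bright,
and typically holds the global intensity maximum. A `volume` in this package
is a plain 3D array with voxel spacing (mm) and a world origin attached;
axes are `(x, y, z)` with `z` the slice axis and world coordinates
`origin + (index - 1) * spacing`. Direction cosines are assumed
axis-aligned; oblique acquisitions are reoriented at read time and rejected
when they cannot be.

## Step one: automatic artery segmentation

**Bias-field correction.** Multiplicative shading is estimated in the log
domain by the N3/N4 family's iterative scheme: at each iteration the
residual log image is pushed through a histogram-sharpening step (Wiener
deconvolution of the intensity distribution, then the conditional
expectation `E[u | v]` of the uncorrupted intensity), and the remainder --
which by construction carries the field, not tissue contrast -- is fit by
the smooth field model and accumulated into the field estimate. The field
model is a low-order 3D polynomial (total degree 3, 20 terms): it
represents scanner shading faithfully but *cannot* follow anatomy, which
turned out to matter. Earlier iterations of this module used a Gaussian
low-pass field model instead; driven to convergence it behaves like local
contrast normalization -- it slowly absorbs compact bright structures (a
treadmill the histogram sharpening only delays, because partial-volume
values bridge the histogram modes), it inflates near the mask boundary
where the normalized convolution loses support, and it leaves the scheme
non-idempotent. The polynomial model eliminates all three failure modes at
once and recovers a synthetic linear field almost exactly. Because the
field is smooth it is fit on a grid downsampled by `shrink = 4` and
upsampled trilinearly, which keeps the cost negligible; the accumulated
log-field is clamped to `[-0.7, 0.7]` (field in roughly `[1/2, 2]`, the
plausible shading range). The corrected volume is rescaled so its
foreground mean matches the input (global brightness is not a free
parameter of the correction). The sharpening FWHM (0.3 log units) sits
between the within-tissue log-noise width of dim background voxels (~0.25)
and the smallest genuine mode separation; the Wiener noise floor (1e-3)
controls how completely the deconvolution exposes the field per iteration.

**Histogram normalization** (optional, for multi-scanner cohorts) matches
the deciles of a volume's foreground histogram to a reference volume's by a
monotone piecewise-linear map, extended linearly beyond the outermost
landmarks so that self-normalization is the identity. The reference defaults
to the first volume of a dataset.

**Skull stripping.** Seeds are found by the shrinking bounding-box rule:
from the center of each of the six volume faces a ray marches inward and
stops at the first voxel at or above the contact threshold (default 30% of
the volume maximum -- the same fraction used as the lower growing
threshold). Region growing then floods all voxels 26-connected to a seed
through the band `[0.30 * max, max]`, the grown mask is smoothed by binary
closing (ball radius 2, which bridges small contact gaps without invading
thin vessels), and the covered voxels are cut out. Two choices here were
open and are worth recording:

* *Enhancement order.* The sigmoid contrast remap (below) compresses the
  dynamic range so strongly that "30% of the maximum" lands below the
  background plateau of the enhanced image; skull stripping on enhanced
  data then leaks through background noise. The pipeline therefore strips
  the skull on the bias-corrected (pre-sigmoid) volume and applies the
  sigmoid afterwards, feeding enhancement into vessel segmentation and the
  network input.
* *Seeds per face.* Each face contributes at most its center ray's first
  contact point (up to 6 seeds), rather than every contact point of the
  face; one interior point per face suffices to seed a connected rim.

**Sigmoid vessel enhancement.** Intensities are remapped voxelwise by
`f(x) = (Max - Min) / (1 + exp(-(x - beta) / alpha)) + Min` with
`alpha = 400` and `beta = 600` intensity units. `Max`/`Min` default to the
input volume's own range, so the filter redistributes contrast around the
vessel intensity band (centered at `beta`) without rescaling the data; this
keeps later fraction-of-maximum thresholds meaningful.

**Automatic vessel segmentation.** The stripped, enhanced volume is
binarized strictly above a background value (default: its Otsu threshold,
configurable), the 26-connected foreground components are ranked by size,
and the five largest -- in practice the main arterial branches -- provide
both the intensity sample and the seeds. Vessel intensity in TOF-MRA is
modeled as Gaussian; the sample mean and n-1 standard deviation over the
seed-component voxels give automatic growing thresholds `mu - sigma` and
`mu + sigma`. One refinement proved necessary: a component's single
brightest voxel almost surely lies *above* `mu + sigma` (it is the maximum
of thousands of Gaussian draws), so the seed actually used is the
component's brightest voxel *inside* the growing band; ties break to the
smaller lexicographic index so runs are deterministic.

**Surface mesh.** The vessel surface is extracted at iso-value 0.5 from the
one-voxel zero-padded binary mask with a table-free marching-tetrahedra
scheme: every grid cube is split into the same six tetrahedra (the Kuhn
decomposition, whose face diagonals agree between neighboring cubes), each
tetrahedron contributes 0-2 triangles with vertices on its edges, and
vertices are deduplicated by the grid edge they lie on -- the mesh is
therefore watertight by construction. Because iso-surfacing a binary field
places every vertex at an edge midpoint, the raw surface is faceted and
overestimates areas by roughly 30%; six passes of uniform Laplacian
smoothing (step 0.6) relax the faceting and bring a digitized ball's area
to within about 1% of `4 * pi * r^2`. Both knobs are exposed
(`smooth_iters`, `lambda`).

**VOI dilation.** The vessel mask is dilated with the exact Euclidean ball
`{d : ||d|| <= 10}` (4169 lattice offsets at radius 10). The dilated mask is
the detection stage's search region, and the package's acceptance study
measures the property the detector relies on: on seeded phantoms the VOI
contains 100% of annotated aneurysm voxels.

## Step two: the detection network

The detector is a compact encoder-decoder FCN of the "context aggregation"
U-Net family. Each encoder level is a residual context block (two 3x3x3
convolutions with instance normalization and leaky ReLU, added back to the
input); levels are entered through stride-2 convolutions and double their
filter count. The decoder upsamples (nearest neighbor), halves filters,
concatenates the encoder skip, and localizes with a 3x3x3 plus 1x1x1
convolution pair. Deep supervision is architectural: 1x1x1 segmentation
heads at the deeper decoder levels are upsampled and summed into the final
two-class logits with weights 1, 1/2, 1/4, ..., so auxiliary gradients reach
the deep levels through a single loss. The loss is the sum of voxelwise
cross-entropy and soft Dice on the aneurysm class -- the standard companion
of this architecture family, chosen because lesion voxels are a vanishing
fraction of each block. Optimization is Adam at learning rate `5e-4`, batch
size 1, glorot-uniform initialization under a caller-supplied seed, and
early stopping on a 10% validation split (patience 10) with best-epoch
weights restored. All of this -- convolutions and their gradients included --
is implemented in the package (C++ kernels, R orchestration) and verified
against finite differences in the test suite.

Two-class semantics follow the annotation convention: inside the VOI,
vessel is *background* and aneurysm is *foreground*. Training targets are
the annotations dilated to spheres of the shared radius
`max(4, ceiling(0.03 * block_axis))` voxels (strictly above 3 voxels at a
128-voxel axis) centered on each annotated component's centroid. At
inference the same radius defines the sphere markers drawn at predicted
component centroids; likelihoods are zeroed outside the VOI, binarized
strictly above 0.5, and components smaller than `min_component_size = 5`
voxels (a noise floor; the choice was open) are suppressed. Markers are
mapped back to native world coordinates with the radius rescaled by the
block-to-native spacing ratio.

The default topology (128-voxel blocks, depth 4, 16 base filters) matches
the published operating point of this architecture family; the test suite
runs the identical code at 32 voxels, depth 3, 4 filters, which trains in
minutes on one CPU. `deep_supervision_levels` must not exceed `depth - 2`
(heads live on decoder levels); the divisibility requirement
`input_size %% 2^depth == 0` is validated at construction.

## Augmentation

Training sets are expanded exactly eightfold: the full factorial of
apply/skip over three filters, in order -- transverse flip, discrete
Gaussian smoothing (variance 4.0 voxels^2, kernel truncated at 32 taps),
and histogram equalization. The eightfold structure is what reproduces
dataset growth of the form 76 -> 608, 20 -> 160 and 96 -> 768. Labels
undergo only the flip; intensity filters never touch categorical data. The
"discrete Gaussian" filter is smoothing, not additive noise -- its
parameters (variance, max kernel width) are those of the smoothing filter
family, and the alternative reading would corrupt labels' geometric
alignment with no compensating benefit. The third filter is selectable
(`equalize`/`normalize`) because both names appear in common usage for the
same 8x expansion.

## The evaluation protocol

A detection sphere is a true positive iff strictly more than 30% of some
aneurysm's annotated voxels fall inside it; otherwise it is one false
positive, regardless of its size. An aneurysm is detected if any detection
captures it above the rule; one sphere may detect two aneurysms yet counts
as a single TP. Sensitivity is reported to one decimal (percent), FPs/case
to two decimals. Subgroup tables stratify by sex, age band (<60 / >=60),
hypertension, size bin (`<3.0`, `3.0-4.9`, `5.0-9.9`, `>=10.0` mm) and
arterial location; empty strata are undefined (`NA`), never 0%, and
count-weighted stratum sensitivities recompose the overall figure exactly.
Five-fold cross-validation splits are disjoint, balanced to within one case
and deterministic under their seed.

## The phantom generator

Synthetic phantoms provide ground truth for every stage. Each phantom is a
cube (default 64 voxels for tests, 128 for demonstrations) containing:

* background noise `N(60, 15)` clipped at zero;
* a bright spherical shell (`N(900, 40)`, thickness 2) at the periphery,
  separated from everything interior by a dark moat of at least 3 voxels --
  so the skull stripper *provably cannot* reach the vessels;
* a vessel tree of 3 smoothed random-walk tubes (radius 1.5-2.5 voxels)
  whose voxel intensities are i.i.d. `N(600, 20)` -- the mean sits at the
  sigmoid center `beta`, where TOF vessels live;
* spherical aneurysm bumps (radius 3-6 voxels) tangent to and overlapping a
  vessel wall, sharing the vessel intensity law (they are *not* brighter:
  the detector must learn shape, not intensity);
* an optional multiplicative linear bias field (amplitude 0.15 by default,
  i.e. roughly 0.85-1.15 across the volume).

The shell is modeled bright because the pipeline's skull stripper targets
the brightest peripheral structure; this is fidelity to the algorithm's
operating assumption, not to MR physics. Cohorts jitter the voxel spacing
per case so that aneurysm *diameters in mm* span all four size bins while
voxel radii stay in the detectable 3.5-5.5 range; patient metadata (sex
ratio 22:13, age ~ `N(57, 14)`, hypertension ~ 50%, locations weighted
toward the internal carotid) loosely mirror a screening cohort so the
subgroup code paths are exercised. Everything is bitwise deterministic
under the generator seed.

What phantom tests show: that the implementation satisfies its contracts
end to end -- segmentation keeps every aneurysm inside the VOI, the network
can learn to separate blob-shaped from tubular bright structure, markers and
matching arithmetic are exact. What they do not show: clinical performance.
Real TOF-MRA has vessel-intensity heterogeneity, pulsation and motion
artifacts, anatomical variation and annotation ambiguity that no such
phantom emulates; published sensitivities on clinical data cannot be
inferred from these tests.

## Problem sizes and numerical choices

The test suite and the acceptance study run at deliberately modest sizes,
chosen as the package's own verification scale: 64-voxel phantoms, 10-case
coverage studies, a 20-train / 8-test end-to-end cohort, and the
32-voxel / 4-filter network. At this scale the whole suite completes in
about 20 minutes on one CPU core. Other numerical decisions worth
recording:

* Resampling maps output voxel `i` to input coordinate `i * target/spacing`
  (corner-anchored), so voxel (1,1,1)'s world position is invariant; block
  resizing is center-aligned. Axis lengths round to the nearest voxel,
  preserving physical extent to within one voxel.
* Scaled-down training runs use a learning rate of `2e-3` rather than the
  full-scale default `5e-4`: with batch size 1 a 32-voxel network sees only
  a few thousand gradient steps in such runs, and the higher rate reaches
  the same optimum in the available steps.
* The end-to-end cohort run trains without the 8x augmentation (a config
  toggle, on by default at full scale): 20 distinct phantoms already
  provide more geometric variety than 8 filtered copies of fewer cases.
* Degenerate inputs: constant volumes are rejected where an operation is
  undefined (equalization, landmark estimation), passed through unchanged
  where identity is the correct answer (bias correction), or floored with a
  warning where a scale estimate degenerates (vessel sigma).
* Component and flood-fill connectivity is 26 throughout, matching the
  brute-force oracles in the tests; ties in component size or seed
  intensity break to the smaller lexicographic index.

## Known limitations

* DICOM support covers uncompressed single-frame scalar series in explicit
  or implicit VR little-endian; enhanced multi-frame objects and compressed
  transfer syntaxes are rejected with a format error.
* The bias model is multiplicative and smooth; slice-wise intensity jumps
  are outside its scope.
* The detector is a per-voxel classifier with sphere post-processing; it
  reports component centroids, not lesion extents, and multiple touching
  aneurysms merge into one component by construction.
* Training runs single-threaded on CPU; the full 128-voxel configuration is
  provided for completeness and reproduces the topology, not the wall-clock
  of GPU training.
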