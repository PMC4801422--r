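---
title: "Quantitative NMJ morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative NMJ morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmjmorph)
```

## The measurement problem

The *Drosophila* larval neuromuscular junction (NMJ) is a branched chain of
synaptic swellings ("boutons") that a motor neuron forms on a muscle fiber.
Its morphology — overall size, branching geometry, bouton number and the
number of presynaptic release sites (active zones, marked by Bruchpilot/Brp
puncta) — is a standard readout in synapse genetics, but is laborious and
subjective to quantify by hand. `nmjmorph` implements a fully scriptable
pipeline that derives, from a two-channel fluorescence z-stack (a terminal
marker such as Dlg1 plus the Brp spot channel) and a user-drawn region of
interest (ROI), three intermediate structures and nine per-NMJ features:

1. **NMJ outline** (terminal-marker projection, Renyi-entropy threshold):
   area (µm²), perimeter (µm), and bouton count via a distance-transform
   watershed.
2. **NMJ skeleton** (wider Li threshold, 2D thinning): total length,
   longest branch length, number of islands (disconnected compartments),
   branches, and branching points.
3. **Active zones** (3D local maxima in the spot channel within the
   outline): one count.

A second analysis variant (`run_bouton_variant()`) targets synaptic-vesicle
markers (Syt/Csp), which — unlike Dlg1 — leave interbouton regions fully
dark and therefore support accurate bouton counting: it uses a
moment-preserving threshold, a binary dilation before the watershed, a
10-px particle/area floor, and reports bouton area instead of the (here
meaningless) perimeter.

## Stage models and parameters

### Background subtraction

Wide-field images carry smooth out-of-focus haze. Every 2D stage starts
with rolling-ball background subtraction (`subtract_background()`,
radius 20 px): the background is the grey-level opening of the image by a
spherical (non-flat) structuring function; subtracting it preserves
objects whose diameter is small against the ball while removing slowly
varying haze. The radius trades haze removal against flattening of real
structure; 20 px comfortably exceeds the bouton diameter scale at the
default calibration (6.932 px/µm at 63x).

### Automatic thresholds

Four classical 256-bin histogram criteria are implemented from their
definitions (`renyi_entropy_threshold()`, `li_threshold()`,
`huang_threshold()`, `moments_threshold()`), each verified in the test
suite against an independent exhaustive scan of all candidate thresholds:

* **Renyi entropy** (outline stage; also skeleton stage for Hrp): the
  two-class Renyi entropy is maximized at orders ρ→1, ½ and 2 and the
  three thresholds are combined by the published weighting rule.
* **Li minimum cross entropy** (skeleton stage for Dlg1/Syt/Csp): sits at
  or below the Renyi threshold on low-contrast terminal stains, giving
  the deliberately wider segmentation the skeleton needs.
* **Huang fuzzy** (automatic spot-intensity floor in the wide-field
  preset).
* **Moments** (Tsai's moment-preserving rule; vesicle bouton variant).

Conventions, stated because the classical descriptions leave them open:
histograms use 256 bins linearly spanning the per-image `[min, max]`
range (so 16-bit data reduce to the 8-bit formulation); foreground is
*strictly above* the returned bin; ties break to the smallest qualifying
bin; a histogram with fewer than two occupied bins is an error.

### Watershed bouton splitting

Boutons appear as swellings separated by constrictions. The Euclidean
distance transform of the binary outline peaks inside each swelling and
dips at constrictions; the watershed of the inverted distance map splits
the outline at those dips (EBImage provides the transform and watershed).
Two parameters matter:

* `min_bouton_area = 100` px (10 px in the vesicle variant): regions below
  the floor are fragments, not boutons. The floors are part of the
  method's published configuration; the pipeline treats "exceeding" as
  `>=`.
* `tolerance = 0.5`: regional maxima of a discrete distance map differ by
  half-pixel quantization steps; merging maxima shallower than 0.5
  against their saddle is the standard EDM-watershed convention and
  suppresses spurious splits without merging real boutons.

Area and perimeter are measured on the outline *before* splitting, so
sub-floor fragments still count toward them.

### Perimeter convention

`measure_perimeter()` traces every outer and inner (hole) contour as the
closed polygon through boundary-pixel centers (Moore tracing) and sums
steps of 1 (axial) and √2 (diagonal). A single isolated pixel has
perimeter 0 under this convention. On a rasterized disc the convention
overestimates the true circumference by ≈5%; different platforms use
slightly different weighted estimators, and absolute perimeters are only
comparable within one convention.

### Skeleton and branch graph

The wider Li segmentation is thinned to a one-pixel, 8-connected skeleton
(two-subiteration Guo–Hall thinning, implemented in C). Three
post-processing steps make the derived graph robust:

* **Tip extension** (`extend_skeleton_tips()`): thinning retracts free
  branch ends by roughly the local half-width. Each endpoint is walked
  outward, inside the segmentation mask, for as long as the distance map
  stays at the endpoint's local radius — placing the tip at the end of
  the centerline instead of the thinning limit.
* **Hole filling**: thinning can leave 1–4 px background holes where
  branches cross; read literally these are micro-loops. They are filled
  and locally re-thinned before classification.
* **Spur pruning** (`spur_prune_um = 0.5` µm): terminal branches shorter
  than the cutoff (1–3 px artifacts of thinning at junctions and bulges)
  are removed and pixels reclassified once. Genuine short branches are an
  order of magnitude longer at this calibration.

Skeleton pixels with one 8-neighbour are endpoints, with three or more
junction pixels; mutually adjacent junction pixels collapse into a single
branching point, so one branching point connects three or more branches
regardless of its pixel-level footprint. Branch length is measured by
resampling the traced pixel chain every 7 px and summing chords: for
purely axial or diagonal branches this equals the classical step sum
(1/√2 weights), while for oblique branches it removes the staircase
inflation of the step sum (up to +8% at worst-case angles — more than the
5% accuracy the package aims for on planted trees).

The five features follow from the graph: total length (sum of branch
lengths), longest branch length (the maximal cycle-free
endpoint-to-endpoint path, found by exact depth-first search; graphs here
have few nodes, and for pathological cyclic graphs beyond 50 nodes the
weighted diameter is substituted and flagged), islands (connected
components), branches (edges) and branching points (junction nodes).

### Active-zone detection

The spot channel is first grey-closed in 3D (flat discrete ball,
radius 1) so that intensity dips inside one punctum do not split its
maximum. A voxel is a candidate maximum when it is `>=` all 26
neighbours; touching maximal voxels merge into one spot (centroid
reported). Spots are then filtered by

* an **intensity floor**: fixed (confocal preset: 250) or derived from
  the Huang threshold of the within-footprint histogram of the closed
  stack (wide-field preset), and
* a **prominence test** (`noise_tolerance`): a spot survives only if no
  strictly higher voxel is reachable without descending more than the
  tolerance below its peak (flood fill over `>= peak - tolerance`). The
  confocal preset fixes 100; the wide-field preset uses 10% of the
  within-footprint dynamic range, since no published wide-field value
  exists.

Counting is restricted to the footprint `outline & ROI`. Voxel
neighbourhoods ignore the ~2x z/xy anisotropy (0.3 µm z-steps vs 0.144
µm pixels); nothing in the method's description suggests an anisotropic
neighbourhood, and the choice is stated here so it can be revisited.

### Agreement statistics

`concordance_correlation()` implements Lin's coefficient with population
(1/n) moments and the Fisher-z confidence interval from Lin's asymptotic
standard error. `percent_deviation()` is `(manual − automated)/manual ×
100`, so automated-larger measurements give negative deviations (typical
for perimeter- and length-type features, where continuous thresholding
traces more detail than manual straight-line measurement).
`object_agreement()` computes the object-level ratios used for discrete
features — sensitivity = TP/(TP+FP), specificity = TP/(TP+FN). These
definitions are not the conventional epidemiological ones (they are
precision and recall, respectively); the function returns both namings to
prevent downstream confusion. Matching of automated to manual objects is
assumed done upstream; only the counts enter.

## The synthetic generator

`generate_nmj()` renders a two-channel stack with complete ground truth:
a planted tree topology (trunk plus recursively added arms, minimum
inter-arm angle 45°, collision-checked — at narrower angles the
rasterized junction wedge both displaces the medial axis and leaves no
valid bouton position on the arms), bouton swellings along the
branches, Brp-like puncta planted inside the terminal with a minimum 3D
separation, smooth background (constant, ramp or blobs), Gaussian sensor
noise, and a wide-field focus model (axial intensity falloff plus
per-plane defocus blur). Defaults follow the wide-field acquisition
geometry: 42 planes, 0.3 µm z-step, 6.932 px/µm.

Ground-truth bookkeeping drives several placement rules: a bouton is
seeded at every junction (an unswollen junction wedge would read as a
spurious watershed bouton), bead centers keep a separation floor (closer
swellings fuse into one), beads keep clear of branches other than their
own (they would bridge the branches and change the planted topology), and
long bare tube stretches are avoided (a bare stretch above the 100-px
floor would itself count as a bouton).

The `defocus` parameter scales the intensity of out-of-focus planes.
At its default of 1 the maximum projection carries realistic haze, which
partially fills interbouton constrictions — reproducing the documented
unreliability of watershed bouton counts on Dlg1-like markers. The
*noiseless reference conditions* used as the end-to-end oracle are
`noise_sd = 0`, constant background and `defocus = 0` (an in-focus
specimen): under these conditions every ground-truth count (islands,
branches, branching points, boutons, active zones) is recovered exactly,
and lengths to within ~10% (see limitations).

What the generator deliberately does **not** emulate: photon-physics
noise models (noise is Gaussian, not Poisson), spectral bleed-through,
chromatic or stage drift between channels, type 1s/1b terminal mixtures,
and muscle autofluorescence. Tests passing on these fixtures therefore
validate the algorithmic chain, not robustness to every property of real
micrographs.

## Problem sizes and runtime choices

The test-suite fixtures are desk-scale by design: 256×256 px frames
(≈37×37 µm), 42-plane stacks, 2 islands and 6 branches per specimen,
25 planted puncta (up to 70 in the spot-recovery fixtures), 25 random
trees for topology recovery, 30 vesicle fixtures and a 3-specimen
end-to-end batch. These sizes keep each property check in the
seconds-to-a-couple-of-minutes range on one CPU while leaving every
stage's behaviour observable.

## Known limitations

* Skeleton lengths on the full imaging path are accurate to ~10%, not the
  ~5% achieved on clean rasterized masks: at narrow inter-arm angles
  the medial-axis branch point of a rasterized junction is
  displaced into the wedge by roughly `r/tan(θ/2)` (r = effective tube
  half-width, θ the opening angle), which shortens the two adjacent arms. Thinner tubes and
  wider angles reduce the bias; it is documented rather than corrected.
* Bouton counting on continuous markers (Dlg1/Hrp) inherits the method's
  documented weakness: under realistic haze (`defocus = 1`) constrictions
  wash out and the watershed under- or over-segments. The vesicle variant
  is the accurate counter.
* 2D skeletonization of the maximum projection: branches crossing in z
  project onto each other and can merge. The method analyzes the stack in
  3D only for spot counting; the skeleton is planar by design.
* The prominence flood fill is exact but per-spot; stacks with tens of
  thousands of candidate maxima (far above the biological range) would be
  slow.
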