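---
title: "Perisomatic ultrastructure features: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perisomatic ultrastructure features: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perisoma)
```

## The problem

Dense electron-microscopy segmentations of cortical tissue contain tens of
thousands of cells, but most reconstructions are incomplete: axons are
fragmented, distal dendrites are truncated at volume borders, and
proofreading every cell is infeasible. The region that *is* reliably
reconstructed for essentially every cell is the perisomatic one — the
nucleus, the soma out to about 15 µm, and the postsynaptic structures within
about 60 µm of the nucleus centre. This package implements a cell-typing
pipeline that uses only that region: it extracts six nucleus features, seven
soma features and a 120-dimensional postsynaptic-shape (PSS) histogram per
cell, classifies cells with a five-model hierarchical cascade, and searches
the standardized feature space for rare connectivity-defined types such as
chandelier cells.

Every stage is testable without external data: the synthetic-data module
generates phantom nuclei, voxel volumes, postsynaptic shapes and labeled
cohorts whose ground truth is known analytically.

## Nucleus morphometry

`mesh_from_label()` contours the binary mask of a segment with a surface-net
dual contour (one vertex per mixed 2×2×2 voxel cell, quads across
sign-crossing edges of the voxel-center lattice) and keeps the largest
connected component. On voxelized spheres the enclosed volume agrees with
the voxel-count volume to better than 0.1%.

The six nucleus features are volume, surface area, their ratio, infolded
area, infolded area fraction, and cortical depth. Infolding is measured
against a *shrink-wrap* envelope (`shrink_wrap()`): starting from the radial
function of the convex support hull about the mesh centroid, vertex radii
are relaxed downward toward the mean of their graph neighbours but never
below the mesh surface. At convergence the wrap coincides with the mesh over
convex regions and spans invagination mouths with a graph-harmonic membrane.
The construction is idempotent, equivariant under rigid motion, and exact on
convex shapes; an earlier design based on morphological closing of the
radius field was rejected because it cannot distinguish a centroid offset
from a concavity. A vertex strictly deeper than **150 nm** below the wrap
lies within an infolding, and a face counts as folded when all three of its
vertices do — the conservative face rule slightly under-reads narrow fold
rims, which is visible in the phantom recovery error (≈0.01 at the default
mesh resolution).

Cortical depth uses a flat-pia convention: a configured plane
(`depth_reference()`, default pia at `y = 0` with depth increasing along
+y). Curved-streamline depth correction is out of scope.

### Why phantom invaginations are crater-shaped

The nucleus phantom (`make_nucleus_phantom()`) plants invaginations as
crater-like pits: a floor displaced inward by `fold_depth_nm` with near-step
walls, floor angle calibrated by bisection so the *detected* area fraction
(faces displaced beyond 150 nm, measured on the deformed surface) matches
the request, which is what the returned `true_fold_fraction` reports. Two
geometric facts force this design:

1. A smooth (Gaussian) dimple wide enough to hold, say, 20% of a 5-µm
   sphere's surface at 500 nm depth is *locally convex* — its depth is far
   below the sagitta of its own mouth — so no envelope construction can
   detect it; the displaced surface simply is the outer surface.
2. Even for a genuinely concave pocket, any smoothly sloped upper wall lies
   on the envelope and is unmeasurable; only the area inside the mouth
   corner can ever be counted.

Pits with steep walls and depths comfortably above both the 150-nm
threshold and the mouth sagitta (the defaults used in the tests: six pits,
1,200 nm deep, 20% total area on a 5-µm nucleus) make the planted fraction
recoverable to within 0.02. Real nuclear infoldings are deep creases and
channels, which is exactly this regime.

## Soma morphometry

Each nucleus is matched to the segmentation id occupying strictly more than
80% of its one-voxel surround shell; ties and split shells yield an
"unmatched" signal and the cell is excluded downstream. The somatic cutout
takes a 15-µm cube around the nucleus centroid and cleans the binary mask
with dilation by 5 voxels, cavity filling, and erosion by 3 voxels (all
6-connected, in voxel units on the anisotropic grid, matching the
voxel-space procedure), then contours and keeps the largest component. The
net +2-voxel bias inflates an 8-µm sphere's volume by ≈7% at 128 × 128 ×
80 nm voxels; this bias is documented rather than corrected because every
cell in a cohort shares it and the z-scored features are unaffected.
Fragments of falsely merged objects appear as disconnected islands of the
soma label and are dropped with the smaller components; missing-section
slabs up to twice the dilation radius are bridged.

Somatic synapses are the rows of the synapse table whose post id matches the
soma, lying within the cutout radius of the nucleus centroid and within
500 nm of the cutout surface (the table's positions are detector outputs,
so a surface tolerance is required; 500 nm is about one synaptic cleft plus
detector jitter).

## Postsynaptic shapes

For each synapse within 60 µm of the nucleus centre, a 3,500-nm region mesh
is cut out and segmented by local thickness. Thickness is a shape-diameter
probe: 30 rays in a 60° cone opposite the face normal, cosine-corrected
lengths reduced by their median (for a cylinder or sphere this estimates
the true diameter exactly). Ray casting is grid-accelerated; on meshes with
more than 8,000 faces the probe runs on a face subsample and values spread
over the face graph, since local thickness varies on scales much larger
than a face. Faces are soft-clustered on log-thickness with a 1-D Gaussian
mixture (components chosen by BIC, merged while mean thickness ratios are
below 1.6 — tighter ratios are indistinguishable on contoured meshes),
labels are mode-filtered over face adjacency, and edge-connected segments
smaller than 12 faces are absorbed.

The PSS itself is the union of segments reachable from the synapse-bearing
segment without crossing the *main shaft*, taken as the segment with the
largest area × thickness product. This segment-graph rule replaces a full
mesh-contraction skeleton: on spine synapses it returns the head plus neck,
on shaft synapses the shaft stretch, and on somatic synapses the membrane
patch, which is all the downstream embedding consumes. If the graph
bookkeeping fails, the synapse-bearing segment alone is returned and
flagged.

Shapes are pose-normalized (`normalize_pose()`): exactly `n_points`
(default 1,024) area-weighted surface samples, centred, rotated to the
principal axes with signs fixed by third moments and handedness — because
sampling uses the mesh's own face order under a fixed seed, rigidly moved
copies canonicalize to identical clouds.

Two interchangeable encoders map clouds to a 1,024-long latent vector. The
default is a deterministic classical descriptor (per-axis scales,
eigenvalue ratios, moments to order three, radial and pairwise-distance
histograms, zero-padded). The alternative is a tied-weight linear
autoencoder trained by gradient descent on a stable flattening of the cloud
(per-axis extents plus an 8×8×8 occupancy-density grid; a sorted-coordinate
flattening was rejected because the within-slice ordering is arbitrary and
drowns the signal). Its loss decreases monotonically from the first epoch
and training is deterministic under the seed. Both encoders separate the
three phantom classes at ≥90% cross-validated accuracy with a linear probe;
neither claims fidelity to any particular trained network — the dictionary
semantics only require a shape-discriminative embedding.

The bag-of-shapes dictionary is k-means with **k = 30** over the latent
corpus (50 restarts by default, fixed seed, ties to the lowest index);
assignment is nearest-centre by Euclidean distance. Counts over 30 shape
clusters × four 15-µm radial bins (half-open, last bin closed, distances
measured synapse-to-nucleus-centroid) flatten row-major to the
120-dimensional spatial shape histogram. Raw counts are used; cohort-level
z-scoring happens in the feature-assembly step.

## Feature assembly and normalization

The three-step object filter removes, in order: objects smaller than
**25 µm³** (strict), objects whose 15-µm bounding box contains more than
**20%** error/void voxels (strict), and objects the trained object model
predicts as errors. The classifier step naturally runs as a second pass
after a first cascade fit.

Sectioning artifacts impose abrupt multiplicative shifts on size features
along z; `z_slab_normalize()` divides each value by the mean of its
**800-nm** slab. Slab correction applies to the size features (volumes,
areas), with derived ratios recomputed afterwards, since the artifact is a
section-thickness scaling; a synthetic cohort with planted slab gains in
[0.5, 2] recovers gain-free feature ranks at Spearman ρ ≥ 0.99. All
features are then z-scored across cells with the population (divisor *n*)
standard deviation; constant columns are dropped with a warning and the
transform parameters are returned for reuse on new cells.

## The hierarchical cascade

Five models route cells through the taxonomy: (1) neuron / non-neuron /
error; (2) non-neuronal subclasses (astrocyte, microglia, oligodendrocyte,
OPC, pericyte); (3) excitatory / inhibitory; (4) excitatory subclasses
(23P, 4P, 5P-IT, 5P-ET, 5P-NP, 6P-IT, 6P-CT); (5) inhibitory subclasses
(BC, BPC, MC, NGC). Models 1–4 consume the 13 nucleus + soma features;
model 5 additionally consumes the 120 PSS columns. Cells predicted as
errors are routed no further; inhibitory-routed cells lacking a PSS block
are flagged pending, not dropped.

Each level runs a randomized search over six model families (linear and RBF
SVM, k-nearest neighbours, random forest, decision tree, single-hidden-layer
neural network) with 50 hyperparameter draws per family by default, scored
by stratified 10-fold cross-validation on accuracy with macro-F1 and then
family order as tie-breaks; fold assignments are kept for audit and the
whole search is deterministic under the seed. Hyperparameter ranges are
fixed in code (costs and gammas log-uniform over conventional decades,
k ∈ 1–25, and so on) — they are this package's choices, not claimed
faithful to any published search. The test suite and the acceptance script
use reduced search sizes (3–4 draws, 3–5 folds, three families, cohorts of
400 cells) so the full pipeline runs in minutes on one CPU; the defaults
remain the full-size search.

Excitatory cells that leak into the inhibitory branch separate cleanly in
the PSS-augmented space (spiny proximal dendrites load the spine-shape
bins). A binary excitatory-vs-inhibitory model trained on the PSS-augmented
features re-routes cells whose posterior exceeds 0.5 through the excitatory
subclass model; the observation in the source data is a separation, not a
rule, so the posterior threshold is an explicit, configurable design
choice.

Reported scores are *weighted accuracy*: the class-frequency-weighted mean
of per-class recall, with frequencies taken from the reference labels.

## Connectivity analyses

`nearest_neighbors()` is a k-d tree search in the z-scored feature space,
query excluded, distance ties broken toward the lower cell id.
`targeting_profile()` measures, for every output synapse, the angle φ
between the pia direction and the vector from the target soma to the
synapse (φ = 0 directly above the soma, 180 directly below, where the axon
initial segment sits) and the distance r. A cell is called a chandelier
when strictly more than **40%** of its outputs fall at φ ∈ [160°, 180°]
within 60 µm. NP-preference uses the inclusive reading — at least **30%**
of outputs onto 5P-NP cells — with the strict reading available as a flag,
since the two phrasings coexist in the source material. Enrichment is the
exact two-tailed Fisher test (probability-mass definition); the test suite
checks it against direct hypergeometric enumeration to 1e-12.

Proofreading deltas are set arithmetic over synapse ids; radial extent is
the 97th percentile (linear interpolation between order statistics) of
input-synapse distances; a cell is potentially truncated when its minimum
border distance is below the cohort's median radial extent; density maps
bin cells into 50-µm x–z bins scaled to counts per mm².

## What the synthetic data does and does not show

The generators emulate the *contracts* of each stage: watertight nuclei
with analytically tracked infolded area, voxel cells with controlled void
context and planted defects, three geometrically distinct postsynaptic
shape classes, and cohorts with Gaussian class-conditional features,
planted AIS-targeting and NP-targeting axons. They do not emulate EM
texture, segmentation-error morphology, real shape variability within a
class, or the label noise of human annotation. Passing tests therefore
demonstrate that the implementation computes the intended quantities and
that the pipeline recovers planted structure under its stated assumptions —
not that any particular accuracy will be achieved on real volumes, where
class overlap is far larger than in the separated phantom cohorts.

## Numerical choices and degenerate inputs

* Voxel morphology operates 6-connected in voxel units on the anisotropic
  grid; hole filling is border-connected background complementation.
* The shrink-wrap support hull uses up to 4,000 support directions and 300
  relaxation sweeps; convex meshes are fixed points to machine precision
  at the support-direction resolution (a few nm on a 5-µm nucleus).
* k-means ties and duplicate latents: fewer than k distinct vectors is an
  error; assignment ties go to the lowest centre index.
* Degenerate meshes (zero area, empty masks, absent labels) raise errors
  rather than returning silent zeros; unrepairable open meshes are wrapped
  as their largest component with a warning.
* Percentiles are type-7 (linear interpolation), fixed before any tests.
* All randomness descends from one user seed through a counter-based
  splitting scheme, so sub-generators are independently reproducible and
  every documented quantity is bit-reproducible for a given seed.

## Known limitations

* The shrink-wrap's support-hull initialization over-estimates the envelope
  on strongly non-star-shaped nuclei (e.g. deeply bilobed shapes); the
  relaxation step recovers most but not all of the deficit.
* The segment-graph PSS rule can merge a spine head with an adjacent spine
  if their necks touch within the region cutout.
* The linear autoencoder is a desk-scale stand-in trained on density-grid
  flattenings; on real corpora the deterministic descriptor encoder is the
  recommended default.
* Depth is measured against a flat pia; curved cortical geometry needs an
  external streamline correction before feature assembly.
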