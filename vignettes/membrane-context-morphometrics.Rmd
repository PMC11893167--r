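---
title: "Membrane-contextual morphometrics of mitochondria-associated ribosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane-contextual morphometrics of mitochondria-associated ribosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribomesh)
```

## The problem

Cryo-electron tomography of cells yields, per tomogram, (a) a table of
ribosome particles — 3D coordinates plus a ZYZ Euler triple from subtomogram
averaging — and (b) triangulated surface meshes of the outer and inner
mitochondrial membranes (OMM, IMM) from membrane segmentation. Most
nuclear-encoded mitochondrial proteins are imported through the OMM, and a
subpopulation of cytoplasmic ribosomes translates at the membrane with the
peptide exit tunnel pointed at the import machinery. `ribomesh` quantifies
that geometry: which ribosomes are *import-oriented*, whether they cluster,
which OMM regions they occupy relative to crista junctions, how the local
OMM–IMM spacing differs under them, and whether neighbouring ribosomes are
threaded on one mRNA (polysomes).

All internal lengths are Angstrom and all angles degrees; pixel and nm
conversions happen only at I/O boundaries.

## Orientation model

A particle's Euler triple $(\phi_{rot}, \theta_{tilt}, \psi)$ follows the
star-file convention: the reference-to-particle matrix is
$R_z(\phi)R_y(\theta)R_z(\psi)$, and the body-to-tomogram rotation used
throughout is its transpose,

$$R = \left(R_z(\phi)\,R_y(\theta)\,R_z(\psi)\right)^{\mathsf T}.$$

Landmarks are carried as body-frame offsets (`body_frame_offsets()`): the
peptide exit tunnel at $(0, 0, 120)$ Å (on the large-subunit surface, along
the body $+z$ axis), and the mRNA entry/exit sites at $(\pm 125, 0, 40)$ Å.
A landmark's tomogram position is $c + R\,o$ for center $c$ and offset $o$.
The exact body-frame coordinates of these landmarks are not universal
constants — they depend on the consensus average the poses refer to — so all
of them are configurable; the defaults place the geometry in the regime the
classifier's thresholds assume (center about 135 Å off the membrane, exit
tunnel ~15 Å above it when pointed straight down).

Whether a renderer applies $R$ or $R^{\mathsf T}$ is a genuine convention
ambiguity. The package resolves it internally: the synthetic generator and
the classifier share one convention, and the generator/classifier
consistency test (every planted import-oriented particle passes the
classifier's own rule) pins it. Numeric agreement with any external tool's
drawing convention is deliberately not claimed.

Membrane distance is **point-to-centroid**: the membrane is represented by
its triangle coordinates, so "distance to the nearest OMM triangle" means
Euclidean distance to the nearest triangle *centroid* (lowest index on
ties). An exact point-to-triangle mode exists behind `exact = TRUE` but is
not the default. Relative orientation is recorded as three angles, one per
body axis $u$:

$$\alpha = \arccos\left(\,\lvert (R u) \cdot \hat n \rvert\,\right) \in [0^\circ, 90^\circ],$$

with $\hat n$ the nearest triangle's unit normal; the absolute value folds
vector sign, so the record is independent of normal orientation.

## Classification

With defaults from `run_config()`:

* **import_oriented** — exit-tunnel-to-OMM distance ≤ `exit_cutoff` (95 Å);
* **proximal_non_import** — otherwise, center-to-OMM ≤ `proximity_cutoff`
  (250 Å);
* **background** — the rest.

The 95 Å threshold was originally a visual calibration; `sweep_exit_cutoff()`
reproduces it numerically by tabulating class counts across 0–120 Å
(including the 95/110/120 values that calibration explored). The headline
summary is the import fraction among membrane-proximal ribosomes,
$n_{import} / (n_{import} + n_{proximal})$, reported per tomogram and
pooled; a zero denominator yields `NA`, never 0.

## Spatial clustering

Ripley's K without edge correction:

$$K(r) = \frac{V}{n(n-1)} \sum_{i \ne j} \mathbf 1\!\left(d_{ij} \le r\right),$$

on a grid of 140 radii spanning 27–166 nm (the grid density is a package
choice; only the range is prescribed). Membrane-bound points are quasi-2D,
so the analytic 3D null $\frac{4}{3}\pi r^3$ (available via
`analytic = TRUE`) is biased for them. The default null is therefore
**surface-constrained**: $K_{CSR}(r)$ is the Monte-Carlo mean of the same
estimator over area-weighted uniform resamples of the same $n$ on the same
membrane (lifted by the particle standoff), which cancels edge and
dimensionality effects — and the reference volume $V$ — in the ratio
$K/K_{CSR}$. Clustering is summarised as the maximum ratio per 10-nm radius
interval (intervals aligned to multiples of 10 nm, so the (30, 40] nm
interval exists), and populations are compared per tomogram with the
Mann–Whitney U test.

The Mann–Whitney implementation enumerates all
$\binom{n_a+n_b}{n_a}$ assignments exactly for pooled sizes ≤ 12 (valid
under ties) and otherwise uses the normal approximation with tie and
continuity correction; two-sided p is $P(|U - \mu| \ge |u_{obs} - \mu|)$,
exploiting the symmetry of the null distribution of U about
$\mu = n_a n_b / 2$. Identical samples return $p = 1$, flagged degenerate.

## Membrane patches and crista overlap

*Ribosome-associated (co-translation-associated) patches*: the OMM
triangles nearest to import-oriented ribosomes (the seeds) plus every
triangle whose centroid lies within 150 Å of a seed centroid. The patch
radius is Euclidean, not geodesic — at this radius on these meshes the two
coincide except at extreme curvature, and the original search was a
coordinate-proximity query. The complement is the
non-co-translation-associated set; the partition is exact by construction
and asserted by area and count.

*Randomized patches*: equally many centers drawn area-weighted uniformly,
with every pairwise center distance **strictly** greater than 150 Å
(rejection sampling; the stated constraint is "> 150 Å"). Each draw records
its seed.

*Crista-associated OMM*: (1) select IMM triangles whose IMM-to-OMM distance
falls in 18–30 nm — the crista-junction regime; (2) project each to its
nearest OMM triangle; (3) expand by 15 nm (half a crista body width). The
band selection uses the normal-cone distance by default (see below);
an optional minimum-component-area filter stands in for the manual removal
of spurious CJ triangles — whether the original clean-up removed whole
components or single triangles is unknown, so the filter is off by default.

The *overlap fraction* is
$\mathrm{area}(\text{ribo} \cap \text{crista}) / \mathrm{area}(\text{ribo})$,
in $[0, 1]$, `NA` when the ribosome-associated set is empty.

## Intermembrane distances

Two per-triangle distance methods, always recorded with a method tag:

* **nearest-point** — source centroid to nearest target centroid (the
  k-d-tree-style query; default for patch-restricted OMM→IMM distances);
* **normal-cone** — nearest target centroid within a 30° half-angle cone
  around the source normal (surface-morphometrics style; default for
  full-surface maps and the CJ band selection). A cone miss is `NA`, never
  a large number. The cone axis must point at the other membrane, so it is
  the inward normal for OMM sources and the outward normal for IMM sources
  (`cone_direction`).

Whether the original CJ band used the cone or the nearest-point distance is
not stated; both are available and the default is documented here. Per-set
histograms use 100 equal-width bins over that set's own [min, max] (the
original range convention is unstated, so the range is per-tomogram and
per-set); the peak is the center of the most populated bin, ties to the
lower bin, undefined (flagged) below 2 defined distances.

## Polysome chains

Among import-oriented ribosomes, a directed link $i \to j$ is drawn when
the centers are within 30 nm **and** the 3′ mRNA entry of $i$ is within
`adjacency_cutoff` of the 5′ mRNA exit of $j$. "Directly adjacent" was a
manual call in the source analysis with no printed distance; here it is
operationalized as 60 Å by default — a ribosome-radius-scale tolerance —
and always reported with results. Because mRNA threads single-stranded
through each ribosome, every node keeps at most one inbound and one
outbound link, resolved greedily by smallest adjacency distance; the rare
cycles produced by symmetric geometry are broken at their weakest link.
Chains are maximal paths of ≥ 2 members, ordered 5′→3′; `end_to_end` is the
straight-line distance from the first member's 5′ exit site to the last
member's 3′ entry site (marker-based, matching how such distances are
measured on rendered models), and `path_length` sums intra-ribosome spans
plus inter-ribosome gaps, so `end_to_end <= path_length` always.

## The synthetic scene generator

`make_mitochondrion()` builds both membranes from one subdivided icosahedron
(default level 5, 20,480 faces): OMM vertices at radius $R$, IMM vertices at
$R - s(\hat u)$ for a spacing field $s$. Because both meshes share a
subdivision, every OMM triangle has a radially aligned IMM partner, and the
measured centroid-to-centroid distance reproduces the planted field to well
under 1% (the residual is the centroid-radius shortfall of an inscribed
triangle, < 0.1% at level 4+). Crista-junction wells are cosine-tapered
regions where the spacing rises to 240 Å, placing IMM triangles inside the
18–30 nm CJ band by construction; optional hard-edged zones plant two-level
fields (e.g. 110 Å under co-translational regions, 135 Å elsewhere).
Subdivision level 5 is the default because the classifier consistency
guarantee is a lattice property: with ~99 Å edges the nearest centroid is
never more than ~57 Å lateral of any surface point, so a particle whose
exit tunnel is 15 Å above the membrane always measures below the 95 Å
cutoff. At level 4 (197 Å edges) that margin is lost.

`decorate_particles()` places centers one standoff (135 Å, inside the 250 Å
proximity rule) above area-weighted-uniform surface points. Import-labelled
particles point the exit axis at the membrane with a random spin about it;
the rest get Haar-uniform rotations — of which a *geometric chance
fraction* (~1/3 with the default geometry) also passes the 95 Å rule, so
the expected classifier rate for planted fraction $f$ is
$f + (1-f)\,p_{chance}$, and the recovery tests estimate $p_{chance}$ with
an independent Monte-Carlo. Clustered mode is a Thomas-like
parent–offspring process (parents area-uniform, tangential Gaussian
offspring scatter at `cluster_scale`, radial reprojection): the analyses
only quantify clustering through K-ratios, so any planted aggregation at a
known scale suffices for recovery testing. Chain mode lays ribosomes along
great circles at `chain_spacing` with the entry/exit axes aligned so
consecutive sites are `chain_spacing` − 250 Å apart (50 Å at the 300 Å
default, inside the adjacency cutoff).

What the generator does **not** emulate: voxel-level tomogram noise, CTF,
segmentation and mesh-reconstruction artefacts, realistic crista lamellae,
missing-wedge anisotropy, or pose-estimation error. Passing recovery tests
therefore demonstrates correctness of the geometry and statistics on ideal
meshes, not robustness to real segmentation quality.

## Numerical choices

* Nearest-neighbour queries run through a uniform-grid spatial index
  (compiled) whose results are *exactly* those of an exhaustive scan —
  a cell is pruned only when its bounding box strictly exceeds the current
  best squared distance — with ties broken to the lowest index; property
  tests assert exact agreement with brute force.
* Degenerate (zero-area) triangles are dropped on ingestion with a count;
  closed meshes are re-wound so signed volume is positive (outward
  normals).
* K is computed from integer pair counts, so permuting point order leaves
  results bit-identical.
* Every random draw flows from an explicit seed through one private RNG
  stream per call (the caller's RNG state is restored), making scenes and
  whole pipeline runs byte-reproducible.
* Histogram ties, nearest-triangle ties, and link-resolution ties all
  break deterministically (lower bin / lower index / smaller distance then
  lower index).

## Problem sizes

The test suite and the acceptance script run on desk-scale scenes chosen to
make the statistics decisive: icospheres of radius 3000 Å at subdivision
4–5 (5,120–20,480 triangles), 60–2,000 particles per scene, 20 scenes per
recovery experiment, 50 null resamples per K curve, and 2,000
randomized-patch draws for the constraint checks. The CSR self-consistency
quantity (mean $K/K_{CSR}$ over the 27–166 nm grid, $n = 300$, 20 seeds)
is recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* Geodesic patch radii and curvature-based crista classification are out of
  scope; patches are Euclidean neighbourhoods.
* The CJ band and patch distances use triangle centroids; very coarse
  meshes inflate distances laterally (quantified above).
* The adjacency cutoff for polysome links cannot be validated against the
  original manual selections; treat detected chains as candidates.
* `summarize_classes()` import fractions on real data inherit whatever
  pose and segmentation errors the upstream pipeline made; the package
  quantifies geometry, it does not correct it.
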