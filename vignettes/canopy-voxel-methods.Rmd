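---
title: "Voxel-grid modeling of canopy space occupancy from TLS point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-grid modeling of canopy space occupancy from TLS point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canvox)
library(data.table)
```

## The problem

Dense, young planted stands — trees on a regular grid a little over a meter
apart — close canopy within a few years, and the interesting ecology then
happens in three dimensions: how much space each crown fills, how much of
that space it shares with neighbors of the same or another species, and how
the partitioning of canopy space shifts from one census to the next.
Conventional inventories (height, crown radii in a few directions) cannot
resolve this. Terrestrial laser scanning (TLS) can: a leaf-off multi-scan
campaign resolves individual branches at millimeter precision throughout a
plot.

`canvox` turns segmented per-tree TLS point clouds from one or more censuses
into a single plot-level, voxel-based accounting of canopy space: who
occupies each 10 cm cube of the canopy, in which year. All downstream
quantities — crown volume (CV), crown intersection volume (CIV), occupancy
class volumes, canopy-layer profiles, and between-census change maps — are
queries against that one table.

## The crown model

Each tree is split at its crown base height (CBH, from the field inventory;
measured as height above ground at the tree position) into stem and crown
points. The crown is then represented twice, and the representations merged:

1. **3D α-shape of the crown points.** The Delaunay tetrahedralization of
   the crown points is filtered to tetrahedra whose circumsphere radius is
   at most α; their union is the α-complex. Unlike the convex hull it
   follows concavities and may be disconnected; as α → ∞ it converges to
   the hull. The enclosed space — including interior volume shaded by the
   crown mantle — is converted to voxels by testing each voxel *center*
   against the retained tetrahedra (barycentric sign test, tolerance 1e-9).
2. **Direct voxelization of the crown and stem points** (half-open binning,
   `floor((coord - origin)/s)`), which catches branch tips protruding
   beyond the α-shape.

The union of both crown representations plus the directly voxelized stem is
the tree model; on a stem/crown collision the crown label wins, since CV and
CIV are defined on crown voxels. Per-voxel provenance (`alpha`, `points`,
`both`) is retained.

**Parameters.** α defaults to 0.5 m; sensible values for leaf-off crowns of
this size lie between roughly 0.3 and 1.0 m — smaller values perforate the
crown mantle, larger ones bridge real gaps between branches. Voxel edge
length defaults to 0.10 m (0.001 m³ per voxel); above ~0.5 m direct
voxelization over-expands small crowns. Whether a voxel belongs to the
α-shape is decided by its center: unbiased and reproducible, at the cost of
staircase effects no worse than half a voxel (an any-corner rule would
systematically dilate the shape).

## From trees to the plot table

All trees and censuses of a plot share one voxel grid whose origin is the
joint bounding box floored to voxel multiples, so a voxel index `(i, j, k)`
means the same cube of space for every tree and year. Each tree model is
added to the plot grid as one record per voxel; shared canopy space shows up
as several records at one index, and the *occupancy fold* of a voxel is its
number of distinct trees. Each record carries the voxel's height above
ground, `z_center − z_DTM(column)`, and voxels above 10.3 m (the default
analysis cap) are dropped.

The DTM comes from lowest-point rasterization of the (filtered) plot cloud
at 5 cm cells. Empty cells are filled by solving the discrete Laplace
equation over the missing cells with observed cells as boundary values — a
smooth, deterministic infill that reproduces affine ground exactly and
extends smoothly beyond the observed footprint. Interpolation over scattered
cell centers (barycentric, or an Akima-type C1 spline) is available as an
alternative (`fill_gaps(method =)`), with nearest-observed-cell values
outside the convex footprint; the triangulation backend those methods use
degrades badly on strictly gridded input, which is why the harmonic solve is
the default. The method used is recorded in the raster.

## Cleaning

Two standard cleaning steps precede everything: a statistical outlier filter
(mean distance to k = 10 nearest neighbours; points beyond the global mean
plus 1.5 standard deviations are dropped) and greedy minimum-distance
subsampling at 1 cm — a point is kept iff it is at least 1 cm from every
previously kept point, walking the cloud in input order. The greedy rule is
deterministic and guarantees both the minimum spacing and that every
discarded point is within 1 cm of a kept one. On survey-grade scans (0.036°
angular step, millimeter spacing near the scanner) subsampling removes the
vast majority of points while leaving crown structure intact; it is an
optional speed-up, not a requirement.

## Multitemporal coregistration

Censuses are recorded in different plot-local frames. Correspondence is by
planting-grid tree identity, never nearest-neighbour matching:

1. A 2 cm thick slice of each stem at 5 cm above ground is fit with an
   algebraic (Kåsa) least-squares circle; its center is the tree position.
2. A 4-parameter planar similarity (scale, rotation, translation) is
   estimated in closed form by least squares over matched positions. Both
   scans are metric, so the scale should be ≈ 1; a deviation beyond 1%
   triggers a warning rather than an error, as it usually indicates bad
   correspondences. Trees missing in either census (mortality, detection
   limits) are dropped with a warning.
3. Heights are leveled by the difference of plot-mean DTM elevations at the
   tree positions (`dz`); no 3D rotation is estimated because the scanner
   is leveled in the field.

Residual statistics (mean and RMS matched-pair distance) are attached to the
transform; on synthetic data with 2 mm point noise the mean residual is
well under 1 cm, comfortably within the ~2 cm accuracy needed to compare
10 cm voxels across years.

## Plot statistics

- **CV**: crown-voxel count × voxel volume.
- **CIV**: volume of the focal tree's crown voxels occupied by ≥ 2 trees,
  split into intraspecific (shared with ≥ 1 conspecific) and interspecific
  (≥ 1 heterospecific). A voxel shared with both kinds of neighbour counts
  once in each split but once only in the total; the two splits therefore
  need not sum to the total.
- **Occupancy class volumes** within an *investigation area* (default a
  6 m × 6 m square centered on the inner-core tree positions × 10.3 m
  height, 370.8 m³): each distinct voxel is counted once at its maximal
  fold (single, two-, three-, four-or-more-fold); the empty class is the
  region's voxel budget minus all occupied voxels, so classes sum exactly
  to the budget. Stem-only voxels are kept in the table (they matter for
  visualization) but excluded from CV, CIV and the class volumes, which
  are crown quantities.
- **Canopy layers**: the same accounting restricted to 1 m strata of height
  above ground; the two standard strata are centered on the plot mean tree
  height ("top") and on the mean crown center height, taken as the mean of
  (CBH + height)/2 ("middle") — the latter is an interpretation, flagged as
  such, since crown center height admits several definitions.
- **Change detection**: per-voxel occupancy difference between two years
  over a mandatory region. The default evaluation set is the union of
  voxels occupied in either year; `include_empty = TRUE` extends it to the
  full region budget, which mostly adds never-occupied voxels to the
  "unchanged" class and dilutes the percentages — with it, "unchanged"
  is dominated by air. Swapping the years exactly swaps the increased and
  decreased classes.

Region membership is by voxel center (half-open planimetric bounds, height
above ground in [0, cap]), and the region's voxel budget is counted per
column from the DTM, so conservation holds exactly even on sloping ground.

## The synthetic scene generator

Field TLS data cannot ship with a package, so `canvox` generates scenes
with the statistical structure of the real campaigns and known ground
truth: trees on a 1.29 m planting grid; tapered trunk cylinders with
diameters of 5–9 cm and heights of 4–8 m; 3-level recursive branching
crowns above a CBH of 25–45% of tree height, in two habits ("broad" crowns
reach ~1.15 m radius and interlock across the planting distance, "narrow"
stay within ~0.65 m); flat, tilted or undulating ground. Surfaces are
sampled at the range-dependent spacing of a phase-shift scanner
(`range × angular step`, nearest of nine simulated positions, default
0.036°) with isotropic Gaussian noise (default 2 mm). A second census is
derived by stretching crowns vertically and radially (growth), optionally
removing trees (mortality), and re-expressing everything in a rotated,
shifted frame whose true transform is recorded for recovery tests. A
ray-casting simulator with first-hit occlusion over sphere/cylinder/plane
primitives provides merged-scan clouds where occlusion matters.

What the generator does *not* emulate: foliage (scenes are leaf-off wood
only), beam divergence and multi-return physics, intensity, wind movement
between scans, and registration error between the nine scan positions
(assumed perfect, as the vendor sphere-target registration is out of
scope). Passing tests on synthetic scenes therefore validate the geometry
pipeline — filters, DTM, coregistration, α-shape, voxel accounting — not
the segmentation of real field data, which is assumed done upstream.

## Numerical choices

- **3D Delaunay**: an in-package incremental Bowyer–Watson
  tetrahedralization backs the α-shape. Construction runs on coordinates
  perturbed by a deterministic index-hashed jitter (3e-5 × span), which
  makes every insphere determinant decidable in double precision;
  circumradii and volumes are then computed from the *original*
  coordinates, so exact inputs give exact volumes (a regular tetrahedron's
  volume and circumradius are recovered to machine precision, gridded and
  cospherical point sets tile their hull exactly). The enclosing super
  tetrahedron sits 1e4 spans away — far enough that even sliver
  circumspheres cannot reach it, near enough that predicates keep ~3
  orders of magnitude of precision headroom. An inconsistent insertion
  cavity (detected by edge bookkeeping) triggers a deterministic retry
  with 5× jitter.
- **Ties and boundaries**: voxel binning is half-open everywhere (a point
  exactly on a boundary belongs to the higher cell); region bounds are
  half-open in x/y and closed at the height cap; barycentric membership
  uses a 1e-9 tolerance so voxel centers exactly on a shared tetra face
  are counted once.
- **Degenerate inputs** error out early with specific messages: < 4 or
  coplanar points for the α-shape (a crown with < 4 points falls back to
  direct voxelization with a warning), < 3 slice points or a collinear
  slice for the circle fit, < 2 matched trees for the transform, < 3
  observed cells for the DTM fill.
- **Determinism**: scene generation restores the caller's RNG state and
  depends only on the spec's seed; subsampling is order-stable; the
  pipeline writes a config hash into its manifest and reruns are
  bit-identical.

## Problem sizes

The shipped tests and the acceptance script run scenes of 1–4 trees sampled
at a 0.2–0.3° angular step (tens of thousands of points per tree, the same
per-point geometry as survey scans at 0.036°, which generate millions), with
one full-density single-tree scene exercised for the subsampling-reduction
figure. The voxel accounting itself is exercised up to full 6 m × 6 m ×
10.3 m regions (370,800 voxels). These sizes were chosen so the whole suite
documents the method's behaviour in minutes; nothing in the implementation
is specific to them, and the α-shape backbone handles tens of thousands of
crown points per tree in seconds.

## Known limitations

- CBH is an external input; the package does not estimate it from the
  cloud.
- Manual tree segmentation is assumed upstream; the generator sidesteps it
  by construction.
- The harmonic DTM infill is C0 at observed-cell boundaries (values are
  matched, derivatives are not); for strongly curved terrain with large
  holes, supply a denser ground cloud rather than relying on the infill.
- Leaf-on scenes violate the crown-model assumptions (the α-shape would
  model foliage plus shaded space); the method is designed for leaf-off
  campaigns.
- The conformal model absorbs small frame scale differences; genuinely
  non-rigid deformation between censuses (e.g., DTM error gradients) is
  not modeled beyond the single vertical shift.
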