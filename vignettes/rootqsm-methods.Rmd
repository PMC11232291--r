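---
title: "Reconstructing coarse-root architecture from laser scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing coarse-root architecture from laser scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rootqsm)
```

## The problem

Excavated coarse-root systems (roots of proximal diameter at least 1 cm) carry
the architectural record of how a tree allocated growth below ground —
total root length, volume and number, their distribution over root orders,
and their azimuthal asymmetry in response to slope and prevailing wind.
The reference measurement technique is contact digitization with a low
magnetic field tracker (LMFD), which yields a polyline with diameters for
every root but takes many hours per root system. Terrestrial laser scanning
(TLS) takes minutes, but yields only an unstructured point cloud of the root
surfaces. `rootqsm` turns such clouds into quantitative structure models
(QSMs) — rooted trees of fitted cylinders — and extracts the same traits the
digitization workflow reports, so the two methods can be calibrated against
each other.

## Coordinate conventions

All clouds live in a root frame with the collar at the origin, geographic
north along +X and up along +Z; Y points west so the frame is right-handed
(`set_frame()`). Azimuth is measured from +X toward east, and the four
cardinal quadrants are half-open 90-degree sectors centred on the axes
(N = [-45, 45) degrees, and so on). A cylinder contributes its length and
volume to the quadrant and depth bin of its midpoint; a root is counted in
the quadrant and depth of its base cylinder. Depth is measured below the
collar plane with a 0.30 m shallow/deep boundary; exactly 0.30 m falls in
the deep bin (the boundary itself must live somewhere, and assigning it to
the deep bin keeps the shallow bin strictly "less than 30 cm"). Rotating a
system by +90 degrees about Z therefore permutes quadrant traits
N→W→S→E, which is one of the package's invariant tests.

## The reconstruction pipeline

1. **Cover sets** (`generate_cover()`). The cloud is partitioned into
   patches of bounded spatial extent by a randomized greedy ball covering:
   points are visited in a seed-shuffled order, and each still-uncovered
   point claims every uncovered point within `PatchDiam/2`. Patch extent is
   bounded by `PatchDiam` by construction, patches are disjoint and
   exhaustive, and two patches are adjacent when some inter-patch point pair
   lies within `adjacency_factor * PatchDiam` (default factor 1). The seed
   is explicit because the covering — and hence every downstream statistic —
   is deliberately randomized; ensembles over seeds quantify that
   uncertainty.

   *Occlusion bridging.* Scans from a few fixed viewpoints leave shadowed
   strips where the patch graph loses its neighbour relation. Disconnected
   components of the patch graph are therefore re-joined by minimum-distance
   spanning edges between patch centroids (Kruskal over nearest
   inter-component pairs), capped at `bridge_gap_factor * PatchDiam`
   (default 3). Components farther apart than the cap stay disconnected and
   their patches end up unassigned. Setting the factor to 0 disables
   bridging.

2. **Stump and root bases** (`find_stump()`, `detect_root_bases()`). The
   stump is operationalized as the largest connected set of patches whose
   centroids lie within a vertical cylinder around the collar axis
   (radius = 1.5 times a taproot radius estimate, depth band 0–0.3 m, both
   configurable). The taproot radius is estimated as the median horizontal
   distance of near-collar points, which lie on the taproot surface. The
   stump is expanded by three layers of neighbouring patches; connected
   components of that expansion layer that (a) can be extended further and
   (b) leave the stump cylinder radially are root bases. The radial
   condition excludes the downward taproot continuation, which is order 0,
   not a lateral. Each base is consolidated by fitting a cylinder to its
   points and keeping the patches whose centroids lie within
   `proximity * radius` of the fitted surface (default 0.5; no number
   exists in the field literature, so it is exposed in the configuration).

3. **Segmentation** (`segment_roots()`, `merge_segments()`). Segments grow
   layer by layer from each base (and from the stump, whose chain becomes
   the order-0 taproot) through unassigned adjacent patches, advancing in
   round-robin lockstep so no segment can starve its neighbours. When a
   next layer splits into several connected components, components that
   reconnect through unassigned patches within two adjacency steps are
   transient (noise wrapping around the root at small `PatchDiam`) and are
   merged back; among the persistent components, the one best aligned with
   the segment's running direction (largest absolute cosine, ties broken by
   patch count then smallest patch id) continues the segment and the others
   spawn children with a recorded branch point. Children whose branch point
   sits at their parent's tip are merged into the parent when the combined
   chain keeps chord/path >= `straightness` (default 0.9 — "as long as
   possible while staying close to straight"), iterated to a fixed point.

4. **Cylinder modeling** (`model_segment()`, `fit_cylinder()`,
   `surface_coverage()`). Walking each segment base to tip, candidate
   cylinders of length {2, 3, 4, 6} x `PatchDiam` are fitted to the points
   ahead and scored by surface coverage: the fraction of non-empty cells in
   an azimuth-by-height grid on the cylinder surface (8 azimuth cells;
   height cells of roughly `PatchDiam` size). The highest-coverage
   candidate is emitted (ties favour the longer candidate, giving fewer,
   longer cylinders), the walk advances past it, and the next fit is
   initialized from the previous axis so the chain adapts to local
   curvature. The fit itself is Gauss-Newton least squares on orthogonal
   distance residuals (sum of squared distance-to-axis minus radius),
   initialized from the largest principal component, iterated to a relative
   parameter change below 1e-8 or 100 iterations. Windows with fewer than
   six points extend to the next candidate length; a tip remainder shorter
   than the smallest candidate is absorbed into the final cylinder.

   Two sanity passes keep junction artefacts from corrupting volumes: a
   child segment's first cylinder is extended back to its parent's surface
   (the junction gap is real root), and radii are capped so a cylinder
   never exceeds 1.25 times its within-segment predecessor nor, for a child
   segment's first cylinder, its parent cylinder's radius (roots taper
   tipward; unconstrained fits across junction point mixtures occasionally
   explode).

5. **Orders and traits** (`assign_orders()`, `compute_traits()`). The
   stump/taproot chain is order 0; a root emerging from an order-k root is
   order k+1 (centrifugal classification), with orders above 3 lumped into
   3 by default. A "root" is one segment — a maximal same-order cylinder
   chain — and only roots with proximal diameter (twice the base cylinder's
   radius) of at least 1 cm are counted, matching the coarse-root
   definition. Totals exclude the order-0 chain by default
   (`include_taproot` switches this), because the digitized reference
   traits are also reported for the lateral root network.

## PatchDiam calibration

`PatchDiam` is the resolution hyperparameter and every trait responds to it
strongly — small patches over-segment (inflating length and number), large
patches merge neighbouring roots (inflating volume, deflating number).
The calibration protocol (`sweep_patchdiam()`, `fit_interpolation()`,
`intersect_reference()`, `refine_and_ensemble()`) reconstructs QSMs across
the 18-value grid [5, 7.5, 10, 12.5, 15, 17.5, 20, 25, 30, 35, 40, 45, 50,
60, 70, 80, 90, 100] mm (a handful of replicate seeds per value, default
3), fits an ordinary least-squares line of each trait's mean on PatchDiam,
intersects that line with the trait value from the digitized reference, and
then refines by brute force: five replicate models at each candidate around
the intersection (multipliers 0.9, 1.0, 1.1), selecting the candidate whose
mean is closest to the reference. Twenty models at the selected PatchDiam
give the reported median and 5th/95th percentiles (linear interpolation
between order statistics, quantile type 7 — the protocol's source does not
pin a percentile definition, so the most common one is used and recorded
here). An intersection falling outside the swept grid is flagged with a
warning. The intersection is only meaningful when the line actually
describes the trait's response — the calibration protocol presupposes
strong linear fits — so when the fit explains less than half the variance
(R^2 < 0.5, which happens when a trait's response to PatchDiam is nearly
flat and the line has no meaningful root) or the intersection leaves the
swept range, the workflow in `recovery_experiment()` falls back to the
swept grid value whose mean trait is empirically closest to the reference.
The brute-force refinement still probes around whichever optimum is
chosen.
Optima are kept separate per trait; no compromise PatchDiam is computed.
`agreement_regression()` regresses reference on predicted values across
root systems and reports the slope, intercept, variance explained and the
two-sided t-test p-value of the slope.

## The synthetic generator and scanner

`generate_system()` builds procedural root systems with exactly known
traits: a near-vertical tapered taproot; first-order laterals attached at
sampled depths with azimuths drawn from quadrant asymmetry weights and
near-horizontal dive angles; second- and third-order branches attached at
sampled arc positions with radius ratios around 0.45–0.65 and branch angles
around 50 degrees. Defaults emulate the excavated mature-conifer systems
that motivate the package: about 1.2 m of taproot, laterals to about 1.1 m,
asymmetry favouring the downslope and windward quadrants. Truth traits are
exact sums over the generative cylinders and are cross-checked in the test
suite by an independent brute-force summation.

`scan_system()` emulates a tripod scanner: by default three viewpoints at
120-degree spacing at 4.5 m range, rays on a regular angular grid, exact
ray-cylinder intersection with nearest-hit occlusion, and Gaussian range
noise of 2 mm standard deviation added along each ray. The 4 mm spot size
is recorded scanner metadata; beam-footprint mixing, multiple returns and
intensity are deliberately not simulated. `digitize_system()` emulates the
contact digitization: polyline points every 2 cm along curved roots and
15 cm along straight ones, with true local diameters, written in the flat
tab-separated reference dialect that `read_reference()` parses. Reference
traits integrate conical frusta between measurement points,
`pi*l/12*(d1^2 + d1*d2 + d2^2)`, using the equivalent circular diameter
`sqrt(d1*d_perp)` where an oblong cross-section recorded a perpendicular
diameter.

What the generator does *not* emulate — and hence what passing recovery
tests cannot certify about field data: soil residue and background clutter
(assumed removed upstream), registration error between viewpoints, root
grafts and fused roots (the structure is forced to a tree), gravitational
sagging of long thin roots, bark roughness, and moisture-dependent return
intensity.

## Validation problem sizes

The package validates itself end to end with `recovery_experiment()`: a
10-root synthetic system is generated, scanned at three viewpoints with
2 mm noise, swept over the full 18-value grid with 3 seeds per value,
calibrated per trait against the known truth, and summarized by 20-model
ensembles. The default scene for this loop is desk-scale — a 0.8 m taproot
with 0.45–0.7 m first-order roots scanned at a 0.025-degree angular step,
about 2 mm point spacing and on the order of 1.5e5 points — chosen so the
roughly 160 reconstructions involved complete in minutes on one core while
staying in the sampling regime (point spacing below the smallest PatchDiam)
where the method is well posed. `scene = "study"` runs the same loop at the
full field dimensions. The acceptance script
(`scripts/acceptance.R`) reports the recovered traits, their relative
errors, interpolation fit quality, trend statistics and configuration
counts from exactly this loop.

## Numerical choices and degenerate inputs

* Cylinder fits require at least 6 points and reject exactly collinear or
  coplanar inputs (relative singular value below 1e-9). Inside
  `model_segment()` a failed or inconsistent fit (radius beyond twice the
  window extent) falls back to a principal-axis direction with the median
  radial distance as radius.
* `surface_coverage()` bins only points whose axial projection lies within
  the cylinder's height span; an empty bin set scores 0.
* Patches with fewer than 3 points, or with a degenerate projected hull,
  are skipped (and counted) by `estimate_density()` rather than given
  infinite density. The convex-hull area estimator under-covers patches
  that are only a few point-spacings wide — the hull of a disc sample
  misses a boundary annulus roughly one spacing deep — so the median
  spacing is reliable once the probe patch diameter is at least about
  fifteen spacings; below that it is biased low. The study-scale probe
  default (30 mm at millimetre spacing) is comfortably in the reliable
  regime.
* LAS output uses scale 0.001 m, so coordinates round-trip within 0.5 mm
  per axis. XYZ text is written at full double precision.
* Greedy-cover tie-breaking is by the seed-shuffled point order; all other
  orderings (component order, continuation ties, merge order) are
  deterministic by construction, so a `(cloud, PatchDiam, seed, config)`
  tuple reproduces a QSM bit for bit.
* Exactly one connected stump component is kept (the largest); if no patch
  falls in the stump region the reconstruction aborts with a frame-check
  hint rather than guessing a collar.

## Known limitations

* Order identification inherits the wrong-fork failure mode of
  branch-following methods: at a junction where the child is better aligned
  than the true continuation, the continuation is demoted one order. Totals
  are unaffected; per-order splits of length are the least reliable
  numbers, consistent with the method-comparison literature.
* Roots whose proximal end is hidden inside the stump region start their
  modeled chain at the stump boundary; the junction extension recovers most
  but not all of the proximal volume.
* Trait recovery degrades when point spacing approaches the smallest
  PatchDiam swept; the sweep flags and excludes grid values whose
  reconstructions fail outright, but sub-resolution values that merely
  degrade are kept, which is visible as attenuated traits at the smallest
  grid values in sparse scans.
* The generator draws azimuths independently per root, so two laterals can
  overlap; the segmentation then reports them faithfully as what the cloud
  shows, which may be one root.
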