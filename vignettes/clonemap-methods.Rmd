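---
title: "Methods: clonality statistics, membrane properties and morphometrics for multicolor fate mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonality statistics, membrane properties and morphometrics for multicolor fate mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonemap)
```

# The scientific problem

In a four-color Confetti reporter, recombined cells heritably express one
of mCFP, nGFP, YFP or RFP and pass the label to their progeny. If a tissue
insult triggers clonal proliferation, daughters stay near their mother and
same-colored cells become spatially clustered; under stochastic
(homeostatic) turnover the labels remain randomly interleaved. `clonemap`
quantifies this distinction and the downstream per-clone biology: how many
clones, how large, how proliferative, and — through patch-clamp and
morphology modules — what the cells in and around clones are like
functionally and structurally.

# The ring statistic and its Monte Carlo null

For a cell $c_n^j$ of color $l_n$ in image $j$, the same-color density in
the ring of radius $r_i$ and width $w$ is the count of other cells of that
color at planar distance $d$ with $r_i - w/2 < d \le r_i + w/2$ (strict
lower, inclusive upper bound), divided by the cylindrical ring volume
$V = s_j\, 2\pi r_i w$, where $s_j$ is the z-stack height. Two choices
deserve comment:

* **Planar distance.** The cylindrical volume is only consistent with
  annuli that extend through the full stack height, so the distance is
  measured in xy. A `distance = "3d"` switch (with spherical-shell
  volumes) exists for sensitivity analysis. Confocal stacks here are thin
  (~30 µm) relative to the radii (20–300 µm), so the two agree closely.
* **Edge correction.** When a ring extends beyond the rectangular image
  footprint, the volume is scaled by the in-footprint fraction of the
  annulus. This fraction is computed in closed form (corner decomposition
  of the circle–rectangle intersection area), which is exact and fast; a
  deterministic polar-quadrature fallback (3600 × 8 samples, absolute
  error ≤ 1e−3) is retained and tested against it and against Monte Carlo
  area estimates. Rings lying entirely outside the footprint have no
  defined density and are excluded from averaging. No z-edge correction is
  applied, consistent with the planar-distance choice.

Densities are averaged with unweighted nested means — cells within an
image, images within a mouse, mice within a (timepoint, condition) group —
so each animal contributes equally regardless of cell count.

The null model fixes every cell position and redraws colors independently
with replacement from a *sampling vector* containing all labeled cells of
the same animal within the analyzed group (one hemisphere condition; the
scope is configurable). Each of `n_sims = 1000` replicates relabels every
stack and recomputes the full nested average, and the per-radius 2nd and
98th percentiles of the replicate group curves (linear interpolation
between order statistics, for cross-implementation determinism) form the
envelope. A recorded density strictly above the upper percentile flags
clustering of same-colored cells beyond what random labeling produces.
Percentiles are taken over replicate group-level curves rather than pooled
per-cell densities: the group curve is the quantity plotted and
interpreted, so its own null distribution is the right yardstick.

Randomness uses one R stream seeded once per analysis, with a fixed
iteration order (replicates outer, stacks in sorted image-id order), the
convention of standard simulation packages; results are bit-reproducible
per seed.

# Clone detection

DBSCAN runs independently per color with ε = 50 µm and a minimum of 2
cells; at that minimum the core/border distinction collapses and the
result equals single-linkage connected components at cutoff ε, which the
tests exploit as an independent oracle. Cells without a same-color
neighbor within ε are singlets and are excluded from clone counts,
densities and sizes. Clone detection defaults to 3D Euclidean distance
(physical proximity), with an xy option mirroring the ring statistic.
Clone densities are averaged per hemisphere per mouse before group means;
clone sizes are pooled over all clones of a group. Clones spanning two
adjacent images are never merged (analysis is per image) — a documented
limitation shared with the upstream imaging design. The proliferation
index of a clone is the exact fraction of Ki-67-positive members.

# The synthetic study

Generators produce every input with ground truth, and their defaults *are*
the study conditions used in tests:

* **Homeostatic (CSR) fields:** homogeneous Poisson points at 1653
  cells/mm³ (the stable contralateral density) with equal color
  frequencies, in 650 × 650 × 30 µm stacks (the confocal field of view at
  the magnification used for counting; ~30 µm usable depth of a 40 µm
  section). Groups are 3 mice × 3 stacks.
* **Clonal fields:** a Thomas-type process — Poisson parents at 2272/mm³
  (the peak clone density in ischemic striatum; with mean clone size 5
  this reproduces the ~11,400 labeled cells/mm³ observed at one week),
  offspring counts 1 + Poisson(mean − 1) so clones of one cell exist (they
  are singlets to the detector, matching the minimum-two-cells rule),
  isotropic Gaussian dispersal with σ = 15 µm (typical within-clone
  nearest-neighbor distances well under the 50 µm relatedness threshold),
  rejection-resampled at the stack boundary to avoid edge pile-up, plus
  300 background singlets/mm³. An optional hard-core spacing on parents
  produces well-separated clones for exact-recovery experiments.
* **Ki-67:** per-cell Bernoulli flags with a probability that is a
  function of true clone size; a decreasing mapping (default
  min(0.9, 1.8/size)) reproduces the observed inverse relation between
  proliferation index and clone size.

What these simulations do *not* emulate: imaging artifacts (segmentation
errors, missed or doubled spots), inhomogeneous tissue (lesion-core cell
loss, vasculature), anisotropic clone shapes along fiber tracts, and
clones split across image borders. Passing tests therefore demonstrate
correctness of the statistics under the stated point-process models, not
robustness to all properties of real images.

A deliberate finding from the power analysis: with σ = 15 µm only ~6% of
same-clone pairs fall in the outermost "short" ring (50, 70], so while
radii 20–50 µm are flagged in essentially every simulated clonal group,
the flag at exactly 60 µm appears in about 84% of replicates — the
residual variance is a property of the process, not of the estimator.

# Membrane-property extraction

The trace generator is an RC + conductance model (currents in pA,
voltages in mV, conductances in nS, time in ms): capacitive transient
$(\Delta V / R_s)\,e^{-t/R_s C_m}$, ohmic leak $(V - V_{rev})/R_m$, a
delayed-rectifier Kv current $g_{out}\, n(t)\,(V - E_K)$ with first-order
Boltzmann activation (midpoint +10 mV, slope 10 mV; time constant
decreasing logistically from 25 to 2 ms with depolarization; $n$ starts at
its holding-potential steady state), and an inward-rectifier Kir current
$g_{in}\, a(V)\, h(t)\,(V - E_K)$ with instantaneous activation below
$E_K = -100$ mV and first-order inactivation engaged only below −100 mV
(time constant 15 ms at −170 mV, increasing e-fold per 40 mV). An optional
instantaneous linear component represents the late-phase non-delayed
outward current; no extra classifier group is added for it (such cells
fall in the outward-present group).

Extraction conventions, each a standard patch-clamp practice made explicit
because the source analyses leave them to lab software:

* steady-state IV = mean over the final 5 ms; single-latency readings use
  the median of the 3 surrounding samples;
* $R_m$ = inverse slope of the steady-state IV within ±20 mV of the
  −20 mV holding potential;
* $C_m$ = transient charge of the −10 mV step divided by 10 mV. A slow
  component (exponential + constant, fitted beyond 2 ms and extrapolated
  under the transient) is subtracted first so gating currents do not
  contaminate the charge integral; the integral runs over 5 estimated time
  constants with an analytic truncated-tail correction. Slow fits with
  time constants below 5 ms are rejected as spurious and replaced by a
  constant baseline;
* $V_{rev}$ = linear interpolation of the zero crossing of the −70 mV IV,
  the crossing nearest holding if several; reported missing if the IV does
  not change sign;
* specific conductances divide the stated two-step current differences by
  the voltage difference and $C_m$, floored at zero;
* presence thresholds for the classifier default to 0.1 nS/pF (well below
  the printed 0.5 nS/pF strong/moderate boundary, which is assigned
  inclusively to "strong"); both are configurable;
* kinetic fits are 3-parameter exponentials (Levenberg–Marquardt via
  minpack.lm, log-linear starting values) on the post-transient trace
  (first 2 ms discarded); non-convergent or flat traces are flagged, not
  errors.

# Morphometrics

Volume is foreground voxel count × voxel volume. Surface area is measured
on an isosurface mesh extracted by marching tetrahedra (6-tet cube
decomposition, anisotropic voxel size respected) at the 0.5 level of the
3×3×3 box-smoothed mask: meshing the raw binary lattice overestimates a
sphere's area by ~27%, while the smoothed mesh is within 0.2% for a
radius-20 ball — the smoothing is an accuracy device for the area
estimator only; volume and all other features use the raw mask. Sphericity
may exceed 1 by a small mesh tolerance on coarse shapes.

Inertia-ellipsoid semi-axes are $\sqrt{5\lambda_i}$ from the eigenvalues
of the second central moment matrix of voxel centers, the solid-ellipsoid
moment relation, stated explicitly because plugin conventions vary.
Coplanar masks are flagged as degenerate.

The 2D skeleton is computed on the maximum intensity projection with
Guo–Hall thinning — chosen over Zhang–Suen after the latter deleted
2-pixel-wide diagonal limbs of voxelized trees outright — with 8-connected
foreground. The skeleton graph takes endpoints and junctions as nodes
(adjacent junction pixels merge into one node; isolated cycles get an
anchor node), with edge weights of 1 per axial and √2 per diagonal step
times the pixel size; total skeleton length is the sum of edge weights and
the longest shortest path is the weighted graph diameter per component.
Skeletons of thick limbs end ~1 pixel short of the true tip and junction
merging absorbs ~1 pixel per junction; on the 100 µm three-segment test
tree the measured totals stay within 5%. Boundary-touching masks are
flagged so the pipeline can exclude cells crossing the image border.

# Pipeline and reproducibility

`run_pipeline()` executes all stages from one YAML config and one seed
(substream seeds are derived arithmetically per stage and group) and
writes tidy CSVs in a fixed layout plus a manifest; re-running with the
same config and seed reproduces outputs byte for byte. Problem sizes in
the test suite are scaled to desk scale — 200-replicate calibration runs
with 200-simulation bands, 50-replicate power runs, ≤ 500-cell stacks for
the oracle comparisons — chosen so the whole suite completes in a few
minutes while keeping Monte Carlo standard errors small against the
asserted tolerances.

# Known limitations

* Ring densities assume an axis-aligned rectangular footprint; irregular
  imaged regions would need a mask-based coverage fraction.
* The Monte Carlo band conditions on observed label frequencies per
  animal; with very few labeled cells per animal the band is wide and
  power is low.
* DBSCAN clone recovery degrades gracefully but inevitably when distinct
  same-color clones overlap in space (counts biased down, sizes up); the
  generator's hard-core option exists precisely to separate estimator
  error from process ambiguity.
* The conductance model is minimal (no series-resistance compensation, no
  liquid-junction correction, single Kv/Kir kinetic schemes); it is a test
  harness for the extraction conventions, not a biophysical cell model.
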