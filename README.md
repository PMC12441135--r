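# clonemap

Computational analysis of multicolor (Confetti) fate-mapping data for
microglia, for labs quantifying whether microgliosis after an insult (for
example ischemic stroke) is driven by *polyclonal proliferation* — the
simultaneous growth of many distinct clones — rather than stochastic
division or the dominance of a few clones.

In a Confetti reporter, each recombined cell heritably expresses one of
four fluorophores (mCFP, nGFP, YFP, RFP), so a clone appears as a spatial
cluster of same-colored cells. The package implements the four
computational arms of such a study, each exercisable end to end on seeded
synthetic data with known ground truth:

1. **Concentric-ring clonality statistic.** For every labeled cell
   $c_n^j$ in image $j$, overlapping rings with radii
   $r_i = 20, 30, \dots, 300\ \mu m$ and fixed width $w = 20\ \mu m$ are
   placed in the xy plane, and the same-color density per ring is

   $$d(c_n^j, r_i) = \frac{\left|\{c_q^j : r_i - \tfrac{w}{2} < \lVert c_n^j - c_q^j\rVert \le r_i + \tfrac{w}{2},\ l_q = l_n,\ q \ne n\}\right|}{V(r_i, w)}, \qquad V(r_i, w) = s_j \cdot 2\pi r_i w,$$

   with $s_j$ the z-stack height and $V$ reduced by the exact fraction of
   the ring lying outside the rectangular image footprint. Densities are
   averaged cells → images → mice → group (unweighted nested means). A
   Monte Carlo null fixes all positions and redraws each cell's color with
   replacement from its animal's label pool; the 2nd–98th percentile
   envelope of 1000 replicate group curves is the randomness band, and
   recorded densities above the upper bound indicate clonality.

2. **Clone quantification.** DBSCAN per color with neighborhood radius
   $\varepsilon = 50\ \mu m$ and a minimum of 2 cells per clone; cells
   without a same-color neighbor within 50 µm are singlets and are
   excluded. Outputs clones per mm³, clone-size distributions, and the
   per-clone proliferation index (Ki-67⁺ members / clone size).

3. **Membrane properties.** From voltage-step recordings (−170…+60 mV in
   10 mV steps, 50 ms, holdings −20 and −70 mV): membrane resistance
   (inverse IV slope around −20 mV), capacitance (capacitive-transient
   charge of the −10 mV step), reversal potential (zero crossing of the
   −70 mV IV), specific outward conductance (steps 0/−20 mV at 40 ms, per
   pF) and specific inward conductance (steps −120/−100 mV at 10 ms, per
   pF), then a four-group classification: small currents, moderate
   inward-only, strong inward-only (boundary 0.5 nS/pF), and
   inward-and-outward. Activation and inactivation time constants are fit
   per voltage.

4. **Morphometry.** From binary 3D cell masks: volume, isosurface-mesh
   surface area, sphericity $\pi^{1/3}(6V)^{2/3}/A$, inertia-ellipsoid
   semi-axes $\sqrt{5\lambda}$, and 2D-skeleton statistics (total length
   and longest shortest path) on the maximum intensity projection.

A seeded generator module produces every input with ground truth:
homogeneous (CSR) and Thomas-type clustered multicolor point patterns,
per-clone Ki-67 flags, conductance-model current traces (RC transient +
leak + delayed-rectifier Kv + inward-rectifier Kir), and voxelized shapes
(balls, ellipsoids, rods, branched trees).

## Worked example

```r
library(clonemap)

# a stroke-like field: ~2272 clones/mm^3 of mean size 5, sigma = 15 um
cg <- simulate_clonal_group(clonal_sim_config(), n_mice = 3,
                            stacks_per_mouse = 3, seed = 1)
mc <- monte_carlo_band(cg$study, ring_grid(), n_sims = 1000, seed = 2)
print(mc)
#> <ring_mc> 29 radii (20-300 um), 1000 sims, band 2-98%; 6/29 radii above upper band

clonality_call(mc)$flagged_radii
#> [1] 20 30 40 50 60 70

stats <- study_clone_stats(cg$study)
round(mean(stats$per_mouse$clones_per_mm3))
#> [1] 2043
mean(stats$per_clone$size)
#> [1] 6.244635
```

The recorded same-color densities exceed the randomization envelope at
20–70 µm — same-colored cells are closer together than random labeling
allows, the clonality signature — while DBSCAN recovers about 2040
clones/mm³ of mean size ≈ 6.2 from a process built with 2272 parents/mm³
and mean clone size 5 (nearby same-color clones occasionally merge, which
biases detected counts slightly down and sizes slightly up at this
density).

The numbered scripts under `analysis/` run the full workflow —
`01_simulate_study.R` builds a two-condition study (clustered "stroke"
vs CSR "contralateral" group, plus a 40-cell patch-clamp cohort and four
shape masks), `02`–`05` run the ring, clone, membrane-property and
morphometry analyses — writing tidy tables under `results/`.
`run_pipeline()` does the same from one YAML config and one seed, with
byte-reproducible outputs.

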