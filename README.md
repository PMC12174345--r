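# porescape

Spatial-organization analysis of membrane-protein pores from AFM data.

High-resolution AFM renders a beta-barrel pore such as VDAC1 — the most
abundant protein of the mitochondrial outer membrane — as a ~4.5 nm
depression in the bilayer surface. A micrograph of a reconstituted membrane
therefore reduces to a planar point pattern of pore centers, and questions
about protein organization (honeycomb-like lipid-protein assemblies,
filaments, dense aggregates, free monomers) become questions about the
statistics of that pattern. `porescape` is for structural biologists and
biophysicists who analyse such coordinate sets.

## What it computes

**Boundary-corrected radial distribution function.** For `N` pore centers
`P_i` in a patch surface `S_patch` (the concave or convex hull of the
positions dilated by a radius), with global density `rho = N / S_patch`:

```
g(r) = (1/N) * sum_i  N_i(r, dr) / ( rho * |S_ring(r, dr) n S_patch| )
```

where `N_i(r, dr)` counts neighbours of particle `i` in the ring
`[r - dr/2, r + dr/2)` and the normalization uses the intersection of the
ring with the patch — not the full ring `2*pi*r*dr` — so no particles near
the boundary are discarded. Shell integrals of `g(r)` give distance-context
profiles over six fixed classes (`<50`, `50–56`, `56–62`, `62–68`, `68–80`,
`80–86` Angstrom: clashing, direct, two lipid-separated shells, bridged,
row), with a patch-resampling analysis (15 nm patches, 100 repeats) for
heterogeneity.

**Cluster statistics.** DBSCAN on the pairwise distance matrix
(`epsilon = 5.3` nm, minimum sample size 2, so a dimer is a cluster;
equivalently, connected components of the epsilon-distance graph), with
the standard partition table: `f_mono`, `f_clust`, cluster count, mean
cluster size ± SEM.

**Pore detection.** Normalized cross-correlation against a zero-mean pore
template, greedy non-maximum suppression, sub-pixel centroid refinement,
and three nested confidence tiers from three correlation thresholds.

**Assembly models.** Coarse-grained protein+lipid templates placed at
measured coordinates with random rotation about the channel axis, greedy
grid-search clash minimization, sequential removal of overlapping lipids,
contact classification, first-shell lipid counts (~20 per leaflet), and
per-species lipid occupancy/enrichment maps on a 2 Angstrom grid (1.2- and
1.8-fold contours).

**Synthetic data.** Generators for glassy honeycomb packings (contact
spacing 5.5 nm = 4.5 nm pore + 1.0 nm lipid annulus), filament chains,
dense aggregates and Poisson controls; AFM-like topography rendering with
optional 5 nm nanobead protrusions; disc-and-shell templates. All
deterministic under a seed, with ground truth retained.

## Worked example

```r
library(porescape)

p <- generate_pattern("glassy", 300, region(200, 200), seed = 1)
patch <- compute_patch_surface(p, dilation_radius = 5)
r <- compute_rdf(p, patch, dr = 0.2, r_max = 20)
print(r)
#> <rdf> N = 300, rho = 0.02217 nm^-2, dr = 0.2 nm, r up to 20 nm
#>   peaks at: 5.50 nm (g=5.04), 10.70 nm (g=1.47), ...

cluster_particles(p)
#> <cluster_report> glassy: 300 particles, f_mono = 0.69, 43 clusters
#>   (f_clust = 0.31), <size> = 2.16 +/- 0.07 (SEM)

head(shell_occurrences(p), 3)
#>    label lo_A hi_A occurrence
#> 1  clash    0   50  0.0000000
#> 2 direct   50   56  1.4066667
#> 3 lipid_shell_1 56 62 1.0266667
```

The first `g(r)` maximum falls at 5.5 nm — the generator's hard-core
spacing, i.e. one pore diameter plus the lipid annulus — and the second
near 10.5 nm, the second shell of a dense disordered packing. The cluster
report says 69% of the particles are lipid-separated monomers at the
5.3 nm contact criterion, and the context profile shows where the
neighbours of an average pore sit: ~1.4 in soft direct contact, ~1.0 one
lipid shell away.

## Package layout

```
R/               implementation (synthesis, detection, spatial stats,
                 clustering, assembly, occupancy, composition, pipeline)
tests/testthat/  unit, property and acceptance tests with independent
                 oracles (union-find, double-loop RDF, closed forms)
vignettes/       methods vignette: models, assumptions, conventions
scripts/         acceptance script
inst/cli/        command-line wrapper
```
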