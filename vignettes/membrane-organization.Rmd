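---
title: "Quantifying membrane-protein organization from AFM coordinates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-protein organization from AFM coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porescape)
```

## The problem

Beta-barrel pores such as VDAC1 crowd the mitochondrial outer membrane and
organize into dense, lipid-intercalated assemblies whose geometry depends on
the surrounding lipids. High-resolution AFM resolves each pore as a ~4.5 nm
depression, so a micrograph reduces to a planar point pattern: the geometric
centers of the pores. `porescape` implements the statistics needed to
characterize such patterns — a boundary-corrected pair correlation function,
distance-context profiles, monomer/cluster partitions — plus the detection
step that produces the coordinates, a coarse-grained assembly-model builder
that puts stereochemistry back onto the coordinates, and a synthetic-data
generator so every stage can be validated without instrument data.

## The boundary-corrected radial distribution function

For `N` particles at positions `P_i` inside an analysis surface `S_patch`,
the global density is `rho = N / S_patch`. The RDF averages, over reference
particles, the neighbour count `N_i(r, dr)` in the ring
`[r - dr/2, r + dr/2)` normalized by the expected count in that ring:

```
g(r) = (1/N) * sum_i N_i(r, dr) / (rho * |S_ring(r, dr) n S_patch|)
```

The essential detail is the denominator: instead of the full ring area
`2*pi*r*dr`, each ring is clipped to the patch. Membrane patches are small
(tens to hundreds of particles), so discarding particles within `r` of the
boundary — the textbook alternative — would waste most of the data. The
intersection normalization keeps every particle and removes the edge bias;
the package demonstrates this on Poisson controls, where the corrected
estimator is flat at `g = 1` while the uncorrected one decays near the
boundary.

`S_patch` is the hull of all positions dilated by a radius (default 5 nm).
Two hull modes exist:

* **convex** — exact geometry: `chull()` vertices, dilated area in closed
  form via the Minkowski sum `A + P*R + pi*R^2`. Degenerate inputs reduce
  correctly (one particle gives a disc `pi*R^2`; collinear particles a
  capsule `pi*R^2 + 2*L*R`).
* **concave** (default) — a raster alpha-hull: morphological closing of the
  rasterized positions with a disc of radius `alpha = 2R` (Euclidean
  distance transforms at 0.5 nm/px), then dilation by `R`. Closing is
  contained in the convex hull, so concave area never exceeds convex area.
  If the closed set is disconnected the patch falls back to convex mode.

Ring-patch intersection areas are evaluated by angular sampling (256 points
per ring) with an interior-distance shortcut: rings further from the
boundary than their radius take the full ring area without sampling. At
0.5 nm/px raster resolution the area error is below 1% on the closed-form
fixtures, and library `g(r)` agrees with a literal double-loop oracle to
within 2%.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `dr` | 0.2 nm | bin width; fine enough to resolve the 0.6 nm (6 A) substructure of lipid-separated contacts |
| `dilation_radius` | 5 nm | hull dilation defining `S_patch`; not prescribed by the measurement itself, so it is an explicit free parameter |
| `r_max` | 50 nm | analysis range |
| `angular_samples` | 256 | ring-clipping resolution |

## Distance contexts and heterogeneity

Pairwise center distances are organized into six fixed classes (Angstrom):
clashing contact `< 50`, soft direct contact `[50, 56)`, two successive
6-A-wide shells of lipid-separated proteins `[56, 62)` and `[62, 68)`,
bridged `[68, 80)`, and row `[80, 86)`. The per-class "occurrence" is the
mean number of neighbours per reference protein in that distance range —
the discrete integral of `g(r) * rho * dA` over the class. The same class
table is the single source of truth for the assembly builder's contact
classification.

Occurrences are normalized per reference protein (mean over proteins), not
per structure; the alternative normalization would scale all classes by a
common factor and is recoverable by multiplying by `N`.

`patch_heterogeneity()` resamples the analysis on small patches: a protein
is chosen at random, neighbours within 15 nm are kept, and occurrences are
integrated to 10 nm (50 nm is the recommended setting for sparse
conditions, where 15 nm patches hold too few neighbours). This is repeated
100 times by default; centers are drawn without replacement, so a structure
with fewer than 100 proteins contributes each protein at most once. The
per-patch spread (SD) quantifies heterogeneity within a structure; on the
package's glassy fixtures the ensemble mean stays within 2 SD of the
whole-structure profile.

## Cluster statistics

`cluster_particles()` applies DBSCAN semantics to the pairwise distance
matrix with `epsilon = 5.3` nm and a minimum sample size of 2 counting the
point itself, so a dimer already forms a cluster. With these settings the
clusters are exactly the connected components of the epsilon-distance
graph and singletons are monomers — which is why the package tests the
implementation against an independent union-find oracle on hundreds of
random instances. Two conventions for "direct contact" circulate (5.3 and
5.6 nm); the default is 5.3, and `epsilon = 5.6` is one argument away.

Reports carry the standard partition metrics: `f_mono`, `f_clust`
(`f_mono + f_clust = 1` holds exactly), cluster count, and mean cluster
size over clusters (monomers excluded) with both SD and SEM. The
displayed dispersion is the SEM, which is consistent with how such tables
are conventionally quoted (e.g. a mean of 3.08 over 16 clusters carries
+/- 0.17).

## Pore detection

`detect_pores()` localizes pores by Pearson-normalized cross-correlation
(zero-mean template, locally normalized image windows, FFT-based
correlation with summed-area tables for the local moments). The template is
an inverted Gaussian of FWHM equal to the pore diameter; tip convolution is
deliberately not modelled. Local maxima above the least stringent threshold
go through greedy non-maximum suppression (higher correlation wins; exact
ties break by row then column, making outputs deterministic), then each
center is refined by a 3x3 centroid to sub-pixel precision. Detections are
assigned the most stringent of three correlation thresholds they pass
(defaults 0.8 / 0.6 / 0.45), yielding nested confidence tiers —
the core set is robust across all three stringencies, the looser sets add
progressively less certain positions. The stringency values themselves are
free parameters: the tiers' meaning is ordinal, not calibrated.

On high-SNR synthetic fixtures (25 pores, noise 0.05 nm vs 1.2 nm depth,
spacing >= 1.5x the pore diameter) recall and precision are 1.0 and the
localization error is well under one pixel; these are the regimes where
template matching is essentially exact, and say nothing about crowded or
drifting real movies.

## Assembly models

`build_assembly()` re-creates a stereochemical model from coordinates:
each site receives a randomly drawn protein+lipid template, rotated about
the membrane normal. The rotation search is a uniform grid (default 64
angles) offset by a random phase per site, greedy in placement order: the
angle minimizing the clash score (count of inter-instance protein-bead
pairs closer than 0.47 nm, one coarse bead diameter) against already
placed instances is kept, ties going to the random phase. Greedy-with-grid
is documented rather than joint optimization because the joint problem is
exponential in the number of sites; for disc-like (rotationally symmetric)
templates the greedy optimum provably coincides with the exhaustive
joint-grid optimum on pairs, and the package asserts exactly that.
A clash score of an energy form was deliberately avoided — only bead
overlap counts.

`prune_overlapping_lipids()` then removes, in placement order, lipid beads
of later instances lying within the cutoff of other instances' protein
beads or of earlier-retained lipids. Earlier instances win; the removal is
logged, conservative (`retained + pruned = initial`), idempotent, and
leaves no inter-instance bead pair below the cutoff.

Contacts are classified by center distance against the shared class table.
The mediation label uses a corridor convention (a flagged convention, not a
measurement): lipid beads inside the rectangle of width one protein
diameter between the two centers mark the pair as lipid-bridged (or mixed,
when the centers are at direct-contact distance); an empty corridor means
direct.

The shipped templates are synthetic disc-and-shell mimics — a 19-bead
barrel ring per leaflet plane (outer diameter 4.5 nm, small radial
irregularity so orientation matters), exactly 20 first-shell lipids per
leaflet at the annulus, filler lipids to the 5 nm extrusion cylinder at
bilayer packing density. MD-derived templates can be supplied as PDB.

## Occupancy and enrichment maps

`compute_occupancy_map()` bins beads per species and leaflet on a 2 A grid
without Gaussian averaging, and divides by the species' mean density over
the occupied region, so enrichment is relative to each lipid's own
abundance and averages to exactly 1. The conventional display contours are
1.2- and 1.8-fold. Maps are 2-D per leaflet — the top-view analysis
surface; a thin z-slicing mode was considered and rejected as outside the
analyses this package targets.

## The synthetic generator: what it emulates, and what not

The generator produces the four regimes the analyses assume, with
ground-truth positions retained for benchmarking:

* **glassy** honeycombs: cohesive sequential adsorption — each particle
  adsorbs at contact distance `spacing` (default 5.5 nm = 4.5 nm pore +
  1.0 nm lipid annulus) from a random placed particle, hard-core rejected
  — followed by jitter-relaxation sweeps anchored at the adsorption
  positions (amplitude 0.3 nm, hard core `spacing - jitter`). Plain
  random sequential adsorption was evaluated first and rejected: without
  contact cohesion the nearest-neighbour mode sits well above the spacing
  and the pair-distance histogram peaks near 5.9 nm rather than at
  contact, which contradicts the contact-dominated packing the analyses
  assume. Cohesive adsorption gives a modal nearest-neighbour distance at
  `spacing`, an amorphous (glass-like) arrangement, and a second RDF
  maximum near 10.5 nm — the expected second-shell position of a dense
  disordered packing of 5.5 nm discs.
* **filament**: correlated random-walk chains with particles at the
  spacing; persistence controls curvature.
* **dense**: cohesive packing at protein-contact spacing (4.5 nm).
* **poisson**: uniform i.i.d. positions, the CSR null.

Topography rendering places an inverted Gaussian of FWHM 4.5 nm per pore
(matching the smooth AFM depression without modelling tip geometry) and
optionally replaces a fraction of pores by 5 nm nanobead protrusions
offset 1.5 nm above the surface — the orientation assay's signature, a
peak where a hole was. Gaussian pixel noise is the only noise model: no
scan-line artefacts, drift, or tip convolution. Consequently, passing
detection tests bound the algorithmic error of the pipeline, not the
instrumental error of real movies.

The generator does not model the surface density of reconstituted
membranes (not derivable from first principles here): the glassy assembly
density is intrinsic to contact packing, and the Poisson control density
is the caller's choice. Both are documented free parameters.

## Numerical choices and conventions

* Coordinates are nm, origin lower-left, y up; images are row-major with
  row 1 at top. The conversions are round-trip tested (a pore rendered at
  known nm coordinates is detected at those coordinates).
* Self-pairs are excluded at the particle level: each pore contributes one
  center, so "pixels of the same pore" cannot pair with themselves.
* Raster resolution for patch masks is 0.5 nm/px; closing uses a 0.75 px
  slack on the erosion threshold so isolated seed pixels survive
  discretization.
* All file writes are atomic (write-to-temporary + rename).
* Determinism: every stochastic routine takes a `seed`; fixed seed gives
  bit-identical outputs, including NMS and rotation tie-breaks.
* Test problem sizes: the package's own validation uses n = 300 glassy /
  n = 2000 Poisson fixtures for the RDF, 200 random instances for the
  clustering oracle, and 100 random images for tier nesting — sizes at
  which the statistical claims are sharp while the full suite stays fast.

## Known limitations

* The concave hull is a raster construction; its area carries raster
  tolerance (~1%) rather than being exact like the convex closed form.
* The corridor-based mediation label is a geometric convention; it is not
  validated against molecular contacts.
* Greedy rotation optimization is only provably optimal for pairs of
  disc-like templates; for many irregular templates it is a documented
  heuristic.
* Enrichment maps need enough beads per cell (roughly > 100) before the
  1.2-fold contour is meaningful; single-model maps are sparse and should
  be pooled over repeats.

## A complete run

```{r, eval = FALSE}
p <- generate_pattern("glassy", 300, region(200, 200), seed = 1)
patch <- compute_patch_surface(p, dilation_radius = 5)
r <- compute_rdf(p, patch, dr = 0.2, r_max = 20)
rdf_peaks(r)                      # first maximum at the 5.5 nm spacing

shell_occurrences(p)              # distance-context profile
cluster_particles(p)              # monomer/cluster partition

m <- build_assembly(p, generate_template(seed = 2), seed = 3)
first_shell_lipids(m)             # ~20 per leaflet for isolated pores
map <- compute_occupancy_map(assembly_beads(m))
```
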