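---
title: "Probabilistic cell typing and spatial statistics for targeted ISS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic cell typing and spatial statistics for targeted ISS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(issmap)
```

## The problem

Targeted in situ sequencing (ISS) decodes barcoded amplicons of a fixed gene
panel directly in tissue sections, yielding a table of transcripts with
micrometre coordinates. To turn those spots into cell-level biology, studies
of the oligodendrocyte (OL) lineage use a reference-profile-driven workflow:
transcripts are attributed to segmented cells, each cell is scored against
single-cell RNA-seq expression profiles of the candidate populations (OPC,
COP, NFOL1/2, MFOL1/2, MOL1--6, VLMC), and the resulting per-cell posterior
probability vector -- drawn as a pie chart -- is collapsed winner-takes-all
into a called type. The called map then supports regional abundance
comparisons, kernel-density maps, cortical depth profiles, and
nearest-neighbor/neighborhood-enrichment statistics. `issmap` implements
that downstream pipeline together with a synthetic-tissue generator so every
stage can be exercised and tested without imaging data.

## The typing model

Spot-to-cell attribution is a hard assignment: a spot goes to the nearest
segmented-cell centroid if that Euclidean distance is at most `max_radius`
(default 15 µm, about three cell radii), otherwise it is background. The
full pciSeq framework treats spot-to-cell and cell-to-type assignment
jointly; we deliberately use the decoupled form because it is closed-form,
deterministic, and testable against independent enumeration, and every
downstream statistic consumes only the called map. Re-implementing the
joint variational model is out of scope.

Given a cell's gene counts $n_{cg}$ with total $N_c$, the likelihood of
type $k$ is independent Poisson per gene,

$$\mathcal{L}(k) = \prod_g \mathrm{Pois}\!\left(n_{cg};\; N_c\,
\frac{p_{gk}+\varepsilon}{\sum_{g'}(p_{g'k}+\varepsilon)}\right),$$

where $p_{gk}$ is the reference mean expression of gene $g$ in type $k$ and
$\varepsilon$ (default $10^{-3}$) is a pseudocount that keeps
zero-profile genes at finite log-likelihood. Profiles are normalized per
type, so the exposure $N_c$ contributes identically to every type and only
the transcript identity mix discriminates; the posterior is the softmax of
`counts %*% log(q)` plus the log prior (uniform by default -- no prior
information is assumed about regional composition). Cells with no assigned
transcripts get the prior exactly. Calling is `argmax`, with ties broken by
panel order so results are reproducible; only cells with at least one
assigned transcript of the pan-lineage marker (*Plp1* role) are retained,
mirroring the gate used to protect against false classification of
non-lineage cells. No probability cut is applied by default: ambiguous
cells are reported, not dropped, and `min_probability` exists for
sensitivity analyses.

Two summaries describe how called populations share probability mass: the
mean pie chart (row $k$ = mean posterior over cells called $k$) and the
confusion matrix (the same mean restricted to non-winning types,
renormalized, zero diagonal). The phrase "how often a type is called with
another" is ambiguous between these means and a top-2 co-occurrence count;
the mean-posterior reading is the default and `method = "top2"` gives the
runner-up tabulation.

## The synthetic-tissue generator

The generator defines the study conditions the tests assume; it is not a
tuning knob.

* **Panel.** `make_reference_profiles()` builds 13 types × 9 dedicated
  markers + 6 lineage-shared genes + 1 pan marker = 124 genes, the panel
  size of the OL mapping design. Marker level / off level default to
  3 / 0.05 (a 60-fold contrast); the pan marker is set twice the marker
  level because the lineage pan gene is distinctly highly expressed.
  Magnitudes are jittered log-normally so types are not exchangeable.
* **Geometry.** `make_layout("brain_coronal")` is a 2.5 × 1 mm cortical
  band (depth axis, layer breaks at fractional depths 0.10, 0.35, 0.50,
  0.75 giving layers I, II/III, IV, V, VI, and lateral-to-medial area
  strips S1, M1, M2, Cg1, Cg2) above a 2.5 × 0.25 mm callosal band.
  `"spinal_cord"` is a gray-matter butterfly polygon listed before the
  outer white-matter boundary; listed-order precedence replaces polygon
  holes, and the WM area subtracts the contained GM area.
* **Cells and spots.** Cells follow a homogeneous Poisson process per
  region at the preset density; types are drawn from the region's
  abundance fractions; per-gene counts are Poisson with mean proportional
  to the type profile scaled to the target transcripts per cell (a
  negative-binomial `dispersion` option exists for robustness studies);
  each transcript is displaced isotropically (σ = 3 µm) around its
  centroid. Background spots with uniform positions and gene identities
  are added at 5% of the true spot count -- the study data do not
  quantify decoding noise, so this default simply exercises the radius
  cut and misassignment paths.
* **Presets.** `simulate_preset()` fixes the reported stage conditions:
  mean transcripts per cell 13.4 / 14.6 / 17.4 and CTX / CC densities
  207/648, 194/750, 170/609 cells per mm² for p10 / p20 / p60; the
  abundance fractions are qualitative renderings of the reported
  compositions (early lineage stages dominant at P10, MOL5/6 dominant at
  P60). Under these defaults the per-cell distinct-gene count averages
  ≈10, matching the targeted-panel regime.

What the generator does *not* emulate: segmentation errors, spatially
correlated noise, optical crowding, cell-shaped (non-isotropic) spot
clouds, curved cortical geometry, and 3-D effects (sections are treated as
2-D, as in 10-µm cryosections). Passing tests therefore demonstrate the
correctness and calibration of the computations, not performance on real
imaging artifacts.

## Abundance and change statistics

Cells are counted per region by centroid point-in-polygon (cells outside
all regions are kept in an `unassigned` bucket), densities divide by the
annotation polygon area (not the convex hull of cells, matching the
"captured tissue area" convention), and relative occurrences divide by the
region's pan-marker-positive cells. The rate of change between conditions
is $100 - 100/(x/y)$ with $x$ the larger condition, so 30 vs 10 gives
66.66% (the increase of 20 is two thirds of the larger value). Types
absent in one condition give an
undefined (flagged) ratio rather than a spurious extreme. Group
comparisons across sections use one-way ANOVA with Tukey HSD per type
(paired t-tests are available via `stats`), reporting raw and adjusted
p-values with the conventional star thresholds; no family-wide correction
across types is applied by default, mirroring the per-contrast reporting
convention, and Benjamini--Hochberg can be applied by the caller via
`p.adjust`.

## Density maps and depth profiles

2-D maps use an isotropic Gaussian kernel on a regular grid (defaults:
bandwidth 100 µm, spacing 20 µm -- there is no field-standard bandwidth
for such maps, so the values used are recorded in the outputs), masked to
the region
polygon; unnormalized layers integrate to the cell count up to kernel mass
outside the polygon, and `normalize_section()` divides all layers by the
single maximum so the global max is exactly 1. The brain display
normalizes per section; the spinal-cord display applies the same operation
separately to GM and WM layer sets.

Depth profiles project centroids onto the straight pial-to-white-matter
axis (a documented simplification of atlas-registered cortical
streamlines), smooth the normalized depths with a 1-D Gaussian kernel
(default bandwidth 0.05 of cortical depth) using reflection at 0 and 1 so
each type's profile integrates exactly to its cell count, and integrate
between layer breaks in closed form for per-layer occupancies. Averaging
across sections can reasonably be done on raw or per-section-normalized
profiles, so `aggregate_profiles()` offers both.

## Neighborhood analysis

`build_graph()` computes the Delaunay triangulation (via `deldir`, the
planar dual of the Voronoi tessellation); each node's nearest neighbor is
its closest edge-neighbor, which equals the global nearest neighbor
because the Delaunay graph contains the nearest-neighbor graph -- a
property the tests verify against an all-pairs search. Degenerate inputs
(<3 points, collinear points) fall back to a direct search with the
triangulation flagged unavailable. Voronoi tiles are optional and clipped
against the convex hull of the supplied window polygon
(Sutherland--Hodgman requires a convex clip region); tiles are display
artifacts and do not influence any statistic. Edges are not pruned by
length by default; a maximum-edge-length option would be the natural
extension for sparse-field artifacts.

The enrichment test permutes labels over fixed positions, preserving the
label multiset and the graph exactly. The default statistic counts, per
ordered pair (a, b), cells of type a whose nearest neighbor is type b
(matching nearest-neighbor-likelihood heatmaps); `edge_count` counts
Delaunay edges between the types, a symmetric variant in the style of
adjacency-enrichment tools. With the default 1,000 seeded permutations
the p-value uses the add-one correction
$(1 + \#\{S_\pi \ge S_{obs}\})/(1 + B)$, so $p \in (0, 1]$ and exact ties
count conservatively; one-sided enrichment is the default and a two-sided
alternative doubles the smaller tail. Per-pair p-values are reported
without multiple-testing correction across the type pairs, again matching
the per-pair reporting convention.

## Numerical choices and degenerate inputs

* Posteriors are computed in log space with row-max subtraction; rows sum
  to 1 within 1e-9 (tested).
* Argmax ties: first type in panel order. Region ties: first region in
  listed order. Both documented, both deterministic.
* Zero-count cells → prior; zero-variance ANOVA → flagged `degenerate`;
  groups with <2 samples → `not_testable`; empty KDE layers and empty
  areas → flagged, not silently dropped; `sd = 0` permutation nulls → `NA`
  z with tie-counted p.
* All randomness flows through explicit seeds (`withr::with_seed`), and
  stage seeds are derived from one global seed so stages can be rerun in
  isolation; the full pipeline is bit-reproducible (tested).

## Problem sizes used in the tests

The test suite simulates sections at 0.5--1 mm scale (hundreds to a few
thousand cells, 10⁴--10⁵ spots), uses 100 random instances for the
posterior oracle, 50 point sets up to n = 1000 for the nearest-neighbor
oracle, 200 null tissues × 199 permutations for calibration of the
enrichment test, and 20 replicates × 4 sections for planted-effect
recovery. These sizes give stable statistics at interactive runtimes and
are the package's reference conditions.

## Known limitations

* The typing model ignores cell area and segmentation uncertainty (both
  carried in the tables for completeness); it is not a re-implementation
  of the joint pciSeq inference.
* Depth is a straight-axis projection; curved cortices need registered
  streamlines upstream.
* Neighborhoods are centroid-based; cells touch through processes long
  before their nuclei are adjacent, so "neighborhood" here means somatic
  proximity.
* The generator's background model is spatially uniform; structured noise
  (edge artifacts, autofluorescence) is not represented.

## A worked example

```{r example, eval = FALSE}
pre <- simulate_preset("p60", scale = 1000, seed = 1)
ty  <- run_typing(pre$tissue$spots, pre$tissue$cells, pre$profiles)
cc  <- call_cells(ty, pre$tissue$cells)
mean(cc$called_type == cc$true_type)       # typing accuracy
abundance_table(cc, pre$layout, types = pre$profiles$type_ids)

wm <- cc[assign_region(cc$x, cc$y, pre$layout) == "CC", ]
g  <- build_graph(wm)
enrichment_test(g, setNames(wm$called_type, wm$cell_id),
                n_permutations = 1000, seed = 1)
```
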