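---
title: "Spatially resolved immune phenotyping: methods and design notes"
author: "phenoshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially resolved immune phenotyping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoshape)
```

# What the package models

Multiplexed 3D fluorescence imaging of skin biopsies, followed by CD45-based
single-cell segmentation, yields one table per sample: for every segmented
immune cell its position (micrometres), morphology, and the mean fluorescence
intensity (MFI) of 7--10 marker channels. `phenoshape` takes it from there:

1. **Cell-type annotation** against binary *attribution matrices* (one
   column per immune-subset variant, entries 0/1 encoding the theoretical
   marker signature) using Spearman rank correlation.
2. **Activation status** (low/high) for designated populations, thresholded
   on the first peak of the marker's MFI density curve.
3. **Inflammatory cluster detection**: disjoint polygons of an alpha-shape
   computed over cell positions ("alpha-ROIs"), filtered by a minimum
   membership of 15 cells.
4. **Cell-to-structure distances**: each cell's distance to an alpha-shape
   model of the epidermis, via a k-d tree over the contour vertices.
5. **Quantification**: densities per mm^3, cluster composition, per-label
   distance summaries.

A synthetic-data generator with stored ground truth makes every stage
testable without imaging data.

# Annotation by dynamically adapted attribution matrices

Acquisition parameters (laser power, detector gain, fluorophore brightness)
differ between channels and between samples, so raw MFIs are not comparable
across channels. The binary reference table is therefore *adapted per
sample*: every 1-entry for marker $m$ is replaced by $\max_i \mathrm{MFI}_i(m)$,
the channel maximum over the sample's cells; 0-entries stay 0. Each cell's
MFI vector over the matrix's marker set is then compared with every adapted
column by Spearman's $\rho$ (Pearson correlation of average ranks), and the
cell receives the label of the best-correlated column:

$$\hat\ell_i = \arg\max_{c} \ \rho\big(\mathbf{x}_i, \mathbf{a}_c\big).$$

Rank correlation makes the assignment invariant to any monotone
transformation of a cell's intensities, which is why raw MFIs are used
directly (a log transform would change nothing).

Decisions the method statement leaves open, and how they are fixed here:

* **Ties.** Correlations are rounded to 12 significant digits; if the best
  value is attained by columns of two *different* labels the cell is
  assigned to the conservative sink class "Other". Columns that share a
  label are optional-marker variants (a subset that *can* express a marker
  is given both a 1-column and a 0-column, e.g. CD4 on gamma-delta T cells);
  the best variant represents the label and same-label ties are not
  ambiguous.
* **Degenerate cells.** A constant MFI vector (e.g. all zeros) has no
  defined ranks; all correlations are undefined and the cell is "Other".
* **Extra channels.** Correlation runs over the matrix's marker set only;
  a nuclear stain or unused channel is ignored (and reported by
  `validate_panel()`).

## Packaged panels

The lymphoid panel (markers CD45, CD20, CD3, TCRgd, CD4, CD8, CD57) encodes
B cells, NK cells, CD4 and CD8 T cells, gamma-delta T cells, and
double-negative/double-positive T cells; the myeloid panel (CD45, CD1c,
CD207, HLA-DR, Tryptase, MPO, Siglec8, CD123) encodes mast cells,
neutrophils, eosinophils, basophils, dermal dendritic cells (dDC),
Langerhans cells (LC) and CD207+ dDC. After activation splitting (below)
the vocabulary has 19 subsets — 9 lymphoid and 10 myeloid:

```{r}
panel_labels()
```

A deliberate design choice: the low/high activation variants are *not*
written into the binary matrices. The matrices annotate base cell types and
the density-threshold step splits them, because writing e.g. "CD57high"
columns into the matrix would replace the data-driven threshold with a
rank-correlation proxy for it.

## The gating oracle and accuracy validation

The supervised reference method is classical histo-cytometry: hierarchical,
flow-cytometry-style marker gates applied to the same per-cell statistics
(`default_gating()` packages both strategies; first satisfied rule wins,
positivity means MFI strictly above the marker cutoff). Agreement between
the two methods is measured as in the validation protocol: per-label cell
densities under a shared volume denominator, fitted by least squares across
labels; the regression coefficient $R$ (the signed correlation of the fit,
so $R \in [-1, 1]$; a raw slope would not respect the documented $[0.75, 1]$
bracket) summarises concordance.

On synthetic benchmarks the gating cutoffs are supplied by the generator —
the log-scale midpoint between the background and positive intensity
distributions per channel — playing the role of the expert-drawn manual
gates. When no cutoffs are given, `gate_cells()` falls back to the
first-density-peak threshold per marker; note that this fallback is a poor
oracle for markers with a large positive fraction (the first peak of a
mostly-positive channel sits in the positive mode).

# Activation thresholding

Within each target population (CD57 on CD4/CD8 T cells; HLA-DR on dDC, LC
and CD207+ dDC), the marker's density curve is estimated by a Gaussian KDE
— Silverman's rule-of-thumb bandwidth, 512 grid points spanning the observed
range; all three are exposed in `activation_config()` and a
grid-refinement test guards sensitivity — and the threshold is the MFI at
the *first* local maximum scanning from low MFI (a monotone-decreasing
curve peaks at the first grid point). Cells strictly above the threshold
get the "high" label.

This rule is implemented exactly as stated by the source method, and one of
its consequences deserves emphasis: the threshold sits at the *peak* of the
low-expression mode, so roughly half of that mode's mass lies above the
threshold. On a 50/50 two-component mixture the classified high fraction is
therefore expected near $w + (1-w)/2 \approx 0.75$, not $w = 0.5$, and the
package's validation suite records exactly that behaviour (the
planted-fraction recovery check is expected to fail under this rule; the
threshold-location and grid-stability checks pass). Users who need a valley
threshold rather than a first-peak threshold can pass explicit cutoffs to
`gate_cells()` / postprocess labels themselves.

MFI z-scores (`mfi_zscore()`) standardise with the sample standard
deviation ($n-1$), so that `sd(z)` is exactly 1 for the returned scores;
grouping (per sample, per population, per cohort) is left to the caller.

# Alpha-shapes, clusters, and distances

## Construction

The alpha-shape of a planar point set is built from its Delaunay
triangulation: a triangle is kept iff its circumradius is at most
$1/\alpha$; $\alpha = 0$ keeps everything (the convex hull). Kept triangles
that share edges form connected components; edges used by exactly one kept
triangle are the boundary, dissolved into closed polygons. Areas are
computed as the sum of kept-triangle areas, which is robust even when a
component's boundary contains holes. $\alpha$ is in inverse micrometres
since coordinates are in micrometres.

The triangulation is an incremental Bowyer--Watson implementation with a
far-away enclosing super-triangle ($10^5\times$ the data span, so that even
flat boundary slivers' circumcircles cannot reach it), strict in-circle
tests (cocircular quads keep whichever diagonal was built first — both are
valid), and deduplication of repeated points with a logged count. It is
validated against brute-force empty-circumcircle enumeration over all point
triples, and the $\alpha = 0$ area against `grDevices::chull()`.

Point membership ("inside or on the shape") is evaluated against the kept
triangles with a small signed-area tolerance, so boundary cells count as
inside; a cell on a boundary shared by two components joins the lower
component id, for determinism.

## Inflammatory clusters (alpha-ROIs)

Clusters are detected over all annotated cell positions with $\alpha = 0.1$
(circumradius cut-off 10 um, tuned for dense infiltrates) and a minimum
membership of 15 cells — the smallest cluster size observed in inflamed but
not in healthy tissue. Survivors carry polygon, area, members, per-label
composition and the unweighted centroid of member coordinates (the centre
definition is unspecified upstream; the arithmetic mean is the simplest
deterministic choice). Cells in no surviving cluster stay "unclustered" and
are retained everywhere else. Cluster density is reported per mm^2 or mm^3
— both denominators are supported because the upstream convention is
unstated; figures in the source material are per sample of fixed box size,
so either is consistent.

Two cautionary notes on $\alpha$. First, the upstream description of the
$\alpha$--tightness relation is internally inconsistent with its own
$1/\alpha$-radius construction; this implementation follows the
construction (larger $\alpha$ = smaller admissible circumradius = tighter
shapes), and both $\alpha$ values remain configurable. Second, the
epidermis default $\alpha = 0.4$ presumes a densely sampled contour
(vertex spacing well under $1/\alpha = 2.5$ um, as surface exports from
imaging software provide); the synthetic epidermis band is sampled at 5 um
spacing and is therefore modelled with $\alpha = 0.1$ in the packaged
fixtures.

## Epidermis distances

The epidermis surface vertices are projected to the x--y plane (cell
records are 3D, but the distance quantity is defined in the projection),
modelled as an alpha-shape, and the boundary vertices are indexed in a
static median-split k-d tree. Each cell inside or on the shape gets
$r = 0$; every other cell gets the distance to its nearest contour
*vertex* — not the nearest edge point — matching the definition of the
stored index; the contour sampling density bounds the resulting error. The
k-d tree is validated against an all-pairs scan (exact equality).

# The synthetic generator

`synthetic_spec()` / `generate_sample()` emulate the statistical structure
the pipeline consumes, not images:

* **Intensities** are log-normal (non-negative, right-skewed, like
  fluorescence): background `lognormal(log 10, 0.35)` and positive
  `lognormal(log 150, 0.35)` per channel — a 7.7-sdlog separation,
  comfortably in the "well-separated" regime. Each channel additionally
  carries a fixed brightness factor on a log-spaced half-decade ladder.
  The ladder emulates the different laser/gain/fluorophore scales that the
  dynamic matrix adaptation exists to absorb (with equal scales the
  adaptation step would be vacuous); its span is capped at half a decade so
  that every channel's positive signal stays at least ~4 sdlog above every
  channel's background, preserving global separability.
* **Ground truth** (subset label, activation state) is stored alongside,
  never inside, the cell table. Subset counts and activation splits are
  exact by construction, not sampled.
* **Layout**: Gaussian blobs (clusters), pinned positions (for distance
  fixtures), uniform background, inside a 600 x 400 x 20 um box
  (0.0048 mm^3) — the standard acquisition volume, which is also the
  default density denominator.
* **Epidermis**: a jittered vertex grid over a y-band (the jitter both
  mimics a real surface export and avoids exactly-cocircular grid quads in
  the triangulation).
* **Reproducibility**: one private RNG stream per sample keyed by the
  spec's seed; the caller's RNG state is untouched.

What the generator does *not* emulate: spatial intensity gradients,
spectral spillover, segmentation errors, cell-shape anisotropy, or
correlations between position and phenotype beyond the planted layout.
Passing tests therefore demonstrate correctness of the algorithms under
clean, well-separated conditions — not robustness to the full messiness of
real stained tissue.

`generate_benchmark_suite()` freezes the fixture set used by the validation
suite: the two-panel annotation benchmark (600 + 627 = 1227 cells, all 19
subsets, 50/50 activation mixes), a 2000-cell bimodal activation sample, a
cluster-filter sweep of 30 isolated blobs with sizes exactly 1..30
(blob sd 3 um, pairwise separations >= 80 um, i.e. more than 10 blob sd and
far beyond the 10 um circumradius cut-off), and an epidermis-distance sample
with populations pinned at 0, 10 and 100 um from the band. These problem
sizes keep the whole validation suite to well under a minute while leaving
all sampling-error margins (e.g. +/-0.05 on recovered fractions) intact.

# Known limitations

* Per-cell annotation accuracy with 7--8 markers is intrinsically limited
  for signature-nested subsets (e.g. double-negative T cells vs T-cell
  subsets); on the packaged benchmark per-cell agreement with gating is
  91--96% and the density regression R is 0.83--0.89, within the documented
  0.75--1 envelope of the method.
* The first-peak activation threshold over-calls the high class by design
  (see above).
* Alpha-shapes and distances are 2D projections; no 3D alpha-shapes.
* The Bowyer--Watson implementation targets the package's problem sizes
  (10^2--10^4 points); it is O(n^2) and not meant for very large point
  sets.
* Cohort-level statistics (cross-patient tests, hierarchical clustering,
  embeddings) are out of scope; `export_embedding_inputs()` hands tidy
  matrices to external tools.
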