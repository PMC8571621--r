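---
title: "Fusing two-grade land-cover structure into landscape metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing two-grade land-cover structure into landscape metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landfuse)
```

## The model

Hierarchical land-cover classifications nest a fine grade (G2) inside a
coarse grade (G1): every second-grade class $y_{ij}$ is subordinate to
exactly one first-grade class $x_i$. `landfuse` treats the coarse grade
as the target layer and asks, per analysis window, how much *vertical*
structure — subclass heterogeneity inside each coarse class — the window
actually realizes.

For a window with valid-cell proportions $p(x_i)$ and within-class
subclass proportions $p(y_{ij}\mid x_i)$, the conditional entropy of the
fine grade given the coarse grade decomposes over coarse classes,

$$H(Y\mid X) = \sum_i H_i', \qquad
  H_i' = -\,p(x_i)\sum_{j} p(y_{ij}\mid x_i)\,\ln p(y_{ij}\mid x_i),$$

and each class's realized entropy is normalized by its maximum
$\ln n_i$ (a uniform mix over the $n_i$ subclasses) to give a
dimensionless weight

$$w_i = \frac{H_i'}{\ln n_i} \in [0, 1].$$

Any landscape indicator that aggregates class-level components,
$LI_X = \sum_i LI_i$, then has a fused counterpart

$$FLI_X = \sum_i (1 + w_i)\,LI_i,$$

implemented for Shannon diversity ($LI_i = -p_i\ln p_i$), patch richness
($LI_i = 1$ per class present) and number of patches ($LI_i$ = per-class
patch count). Two consequences are load-bearing and tested as
invariants: $LI_X \le FLI_X \le 2\,LI_X$, with the lower bound attained
exactly when no present class has substructure; and when every parent
has a single subclass the fused surface is *identical* to the unfused
one, so fusion is a strict generalization, never a perturbation.

All probabilities are computed over the window's valid cells only;
NoData never enters a denominator. An empty window is a flagged state
(`total_valid = 0`), not an error, and maps to NoData in surfaces.

### The subclass count $n_i$

The definition of $n_i$ ("the number of subclasses of class $i$") is
genuinely ambiguous: it may count subclasses present in the window,
present anywhere in the dataset, or defined in the classification
scheme. All three readings are implemented (`n_source =` `"window"`,
`"dataset"`, `"scheme"`). The default is `"window"`: every other
probability in the weight formula is window-local, so the local choice
keeps $w_i$ a self-contained realized/maximum entropy ratio. The choice
matters in practice — a scheme with many never-observed subclasses
deflates weights under `"scheme"` — which is exactly why it is exposed
rather than fixed. When $n_i = 1$ the formula is $0/0$ and $w_i$ is
defined as 0, the continuous limit ($H_i' \to 0$) and the semantically
correct value (no substructure, no extra information).

### Probabilities from counts

$p(y_{ij}\mid x_i)$ is computed as
$\mathrm{count}(y_{ij})/\mathrm{count}(x_i)$. A formulation via
"the proportion of $y_{ij}$ in $x_i$" divided by $p(x_i)$ reduces to the
same quantity; the direct conditional form avoids a needless division.

## Moving windows

Surfaces follow the gradient model: a circular window is centered on
every cell and the window's metric value is written to that cell.

* **Window membership** uses the cell-center rule: a cell belongs to the
  window iff the Euclidean distance between cell centers is at most the
  radius (in cell units). Radii are specified in map units and divided
  by the cell size, so the same call scales across resolutions. Cells
  must be square; anisotropic grids are rejected because the circular
  geometry would be ill-defined.
* **Edges**: the default `edge_policy = "truncate"` computes on the
  in-bounds part of the window, with `min_valid_fraction = 0.5` — a
  center becomes NoData when fewer than half of the full window's cells
  are valid. This preserves study-area coverage while suppressing
  near-degenerate edge windows; `"nodata"` gives strict borders instead.
* **Patch counting** (NP) uses 8-connectivity by default (the common
  landscape-metrics convention), switchable to 4. Patches are delineated
  within the window footprint: a patch extending beyond the window
  counts once per in-window fragment, which is what "the metric within
  that window" means operationally.
* The sweep engine is an optimized per-center loop; its contract is that
  every center equals an independent single-window computation, and the
  test suite enforces exactly that (all nine metric-by-variant surfaces
  on a 32 x 32 raster against a brute-force per-center oracle, at
  tolerance 1e-9), together with translation equivariance.

## Information volume

To compare how much spatial information two surfaces carry, each surface
is min-max normalized, quantized to four decimal places (round half up,
symbols $0..10^4$; a constant surface quantizes to all zeros), and coded
with its own Huffman codebook built from its symbol frequencies. The
information volume is the total code length over valid cells; the
per-cell code lengths form a map of where the surface is locally
"surprising".

Numerical conventions, all of which affect determinism and are tested:

* Priority-queue ties during tree construction are broken by
  (weight, smallest contained symbol) ascending, so codebooks are
  reproducible across runs and platforms.
* A single-symbol alphabet is charged 1 bit per cell by convention
  (an honest floor; zero would make constant surfaces free).
* Codebooks satisfy the Kraft equality $\sum 2^{-\ell} = 1$ and the mean
  length lies in $[H_2, H_2 + 1)$; both are asserted on random
  frequency profiles, alongside optimality against random prefix-code
  adversaries.
* Binary (dichotomous) trees are used throughout — code lengths are in
  bits — while the entropy weights upstream use natural logarithms, as
  is conventional for diversity indices.

Comparison statistics for two surfaces: Pearson correlation over shared
valid cells (flagged `NA` with a warning under zero variance, never a
silent `NaN`); the degree-of-changes map, `|normalized(a) −
normalized(b)|` with each surface normalized independently over the
shared valid cells; and for per-cell information volumes the difference
map DIV, the area share RA of cells where the first surface carries more
bits, and the value ratio RV = (positive DIV) / (total |DIV|), flagged
undefined when DIV is identically zero. RV's one-line definition is an
interpretation of a terser description; it is isolated in
`compare_info_volume()` so an alternative reading is a one-function
change.

## The synthetic generator

`generate_landscape()` builds the coarse mosaic by thresholding a
Gaussian random field (smoothed with $\sigma = 5\,\mathrm{clump}$ cells)
at equal-area quantiles, then draws each cell's subclass from its
parent's subclass distribution — a symmetric-Dirichlet draw with
concentration `mix`. Small `mix` makes parents near-mono-subclass
(weights near 0), large `mix` near-uniform (weights near 1). All
randomness flows from one explicit seed through a private RNG scope, so
identical arguments give bit-identical rasters and generation never
disturbs the caller's random stream.

`generate_ecotone_landscape()` keeps one mosaic but draws subclasses
with `mix_outside = 0.1` outside and `mix_inside = 25` inside a
horizontal band (default: the middle third of rows), concentrating
vertical structure in the band the way an ecological transition zone
concentrates within-class turnover.

The ecotone fixture defaults to a fine-grained mosaic (`clump = 0.1`).
This is deliberate: the degree-of-changes comparison normalizes both
surfaces independently, and min-max normalization is sensitive to range
extremes, so any *horizontal* richness variation (a window somewhere
missing a class) confounds the vertical contrast the fixture exists to
exhibit. With parent patches small relative to the analysis window,
first-grade richness is saturated everywhere and the band contrast
isolates the vertical signal. The general generator keeps a coarser
default (`clump = 0.5`), which is the more realistic mosaic for
correlation-style analyses where both surfaces vary.

What the generator does *not* emulate: real LULC class-abundance
imbalance (classes are near-equal-area by construction), spatially
autocorrelated subclass mixing (subclasses are drawn independently per
cell given the parent), linear features (rivers, roads), and
registration or classification error between grades (pairs are
vertically consistent by construction). Passing tests therefore
demonstrate the method's internal correctness and its qualitative
behavior under controlled vertical structure — not calibrated
performance on any real map.

## Problem sizes and tolerances

The test suite runs entropy-oracle equivalence on 200 random
compositions (tolerance 1e-9 against a brute-force implementation that
shares no code), the sandwich bound on 1,000 random windows, the full
sweep-versus-oracle check on a 32 x 32 raster at radius 3, and the
ecotone and information-volume analyses on a 128 x 128 raster at window
radius 5 — sizes chosen so the complete suite runs in about a minute
while every check still exercises the full pipeline. Exact identities
(fusion with zero weights, FLI = G1LI under singleton subclasses) are
asserted bit-exactly, not within tolerance.

## Limitations

* Two grades only. A three-or-more-grade recursion (fuse grade 3 into
  grade 2, then the fused result into grade 1) is a natural extension
  but out of scope.
* Only SHDI, PR and NP are instantiated. The fusion step itself
  (`fuse()`) is generic over any component decomposition
  $LI_X = \sum_i LI_i$, so adding an indicator means writing its
  component function only.
* Raster I/O is ESRI ASCII grid (plus an opaque CRS tag); there is no
  reprojection, resampling, or multi-band support.
* Information volume ignores spatial topology by design — cells are
  coded independently — so it measures value heterogeneity, not spatial
  arrangement.
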