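---
title: "Methods: grid-level diagnosis and prescription of urban green-space carbon condition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid-level diagnosis and prescription of urban green-space carbon condition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ugci)
```

## The problem

Urban green spaces store and sequester carbon very unevenly: a 30 m grid cell
of interior forest, a compacted park lawn, and a strip of roadside trees are
different worlds for vegetation biomass, soil organic carbon, net CO2
exchange, and the soil's physical capacity to stabilise carbon. City-scale
management needs two things a single stock map does not give: a *diagnosis*
of where the combined carbon condition is poor, and a *prescription* of which
component is the bottleneck at each of those places.

This package implements both steps of that decision-support workflow on
co-registered 30 m grids, with a synthetic landscape generator so the whole
pipeline runs and is tested end-to-end without proprietary city rasters.

## Diagnosis: the composite index

Four components enter per grid cell $i$: vegetation carbon storage (tC/ha),
soil carbon storage (tC/ha), net carbon uptake (net ecosystem productivity,
tC/ha/yr), and soil carbon storage potential (percent silt+clay, a proxy for
mineral stabilisation capacity). Each component $j$ is min-max normalized
over all valid cells,

$$X'_{ij} = \frac{X_{ij} - X_{j,\min}}{X_{j,\max} - X_{j,\min}},$$

and aggregated linearly, $UGCI_i = \sum_j X'_{ij} W_j$, with entropy-based
weights: cell shares $P_{ij} = X'_{ij} / \sum_i X'_{ij}$, normalized Shannon
entropy $E_j = -\tfrac{1}{\ln n}\sum_i P_{ij}\ln P_{ij}$ (with
$0\ln 0 := 0$), and $W_j = (1-E_j)/\sum_j(1-E_j)$. A component that varies
strongly across the city carries more decision-relevant information and gets
more weight; a spatially flat component carries none. Cells are then cut into
four management levels at the quartiles of the index: `extremely_low`,
`low`, `moderate`, `high`. The two lowest levels are the intervention
targets.

Assumptions worth stating plainly: the aggregation is linear with no
interaction terms between components; weights are relative to the analysed
population of cells (adding or removing cells changes them); and min-max
normalization makes the index invariant to positive affine transforms of any
raw component but sensitive to outliers in the extremes that define the
range.

### Numerical choices

* **$0 \ln 0 := 0$** in the entropy sum — the standard continuity convention.
* **Degenerate components** (spatially constant): entropy set to 1, weight 0,
  normalized values 0, with a warning. Such a component cannot perturb the
  index. If *all* components are constant the weighting is undefined and the
  package stops.
* **Normalization population**: all valid (vegetated) cells citywide, i.e.
  one index surface — impervious and water cells carry no components and are
  nodata throughout. Per-class normalization is deliberately not the default:
  the index is meant to be comparable across land-cover types.
* **Quartiles**: linear interpolation between order statistics
  (`stats::quantile`, type 7). Boundary values are assigned to the upper
  level (a cell exactly at Q3 is `high`), matching the usual ">= threshold"
  reading of the top class. For distinct values the four levels are balanced
  within one cell of $n/4$. If the index is so uniform that the quartiles
  coincide, classification stops with an error rather than inventing levels;
  fixed thresholds can be supplied instead (e.g. to reuse cut-offs from a
  previous run).
* **Top-component ties** (for the ternary step): broken by the canonical
  component order (vegetation, soil, uptake, potential), so selection is
  deterministic.

## Prescription: ternary decomposition

For `low`/`extremely_low` cells the index is decomposed over the three
highest-weight components (the fourth, in practice the least informative one,
is dropped). The normalized values $(a, b, c)$ are closed to proportions
$X = a/(a+b+c)$ etc., and each cell's position on the 2-simplex is read as a
limitation pattern:

* **near a vertex** — one component is relatively strong, so the *other two*
  are the limited ones; management targets that weak pair;
* **near the centre** — all three components are uniformly (low) balanced;
  integrated management is needed;
* **$a=b=c=0$** — the cell is fully depleted; coordinates are undefined and
  the cell is reported as such (treated like "all limited" for strategy
  lookup).

The source framework describes "near" qualitatively. The defaults here are a
maximum proportion of at least **0.5** for vertex dominance and a Euclidean
distance of at most **0.15** from $(\tfrac13,\tfrac13,\tfrac13)$ for the
centre; both are exposed in the configuration (`ternary:` block) and in
`diagnose_limitation()`. Cells matching neither rule are `intermediate` and
fall through to the land-cover class's default strategy. Note a geometric
consequence: a cell with exactly one weak component and two comparable strong
ones sits near an *edge midpoint* of the simplex, which is vertex-classed
only if one strong component clearly dominates the other — single-component
deficits therefore surface most cleanly where the other two components are
asymmetric.

Strategies are data, not code: `inst/extdata/strategies.csv` maps (land-cover
class, limited components) to management text — litter retention and
shade-tolerant understory for forests, conservation agriculture for
cropland, decompaction plus organic amendments for parks, multilayered
drought-tolerant plantings for roadside vegetation — and can be localized by
editing the CSV.

## Component models

The closed-form carbon equations are available for building the component
rasters from primary data:

* **Vegetation stock**: $VCS = A\,V\,BEF\,D\,(1+R)\,CF$ (area ha, stock
  volume m³/ha, biomass expansion factor, wood density t/m³, root-shoot
  ratio, carbon fraction), with a fixed 0.8 correction factor for planted
  urban (roadside) trees.
* **Allometric ground truth**: $\sum_j \sum_i a_j\,DBH_{ij}^{b_j}$ per grid,
  with species-specific coefficients. The output unit follows the unit the
  coefficients were fitted in; the shipped coefficient table
  (`allometric_coefficients_synthetic.csv`) is a synthetic, representative
  set for testing, not a fitted reference.
* **GPP** (light-use efficiency): $LUE \cdot nPAR \cdot fPAR \cdot
  (0.382\,T_{air} + 0.0905\,VPD + 17.72) \cdot (1+LSWI)/(1+LSWI_{max})$, all
  three regression constants fixed. The EVI-to-fPAR and PAR-to-nPAR
  transforms are upstream of this package; both scalars are caller-supplied
  inputs in $[0,1]$.
* **Ecosystem respiration**: $(1 + 0.20\,GPP_{acc})\exp(1.16\,
  T_{air}/\max T_{air})$. $GPP_{acc}$ is the trailing 7-day (168-hour)
  mean-preserving accumulation (`gpp_trailing_acc()`), so it stays on the
  flux scale; leading cells with less than a week of history use what is
  available. The $\max T_{air}$ window is the evaluated series by default
  and is caller-controllable. No floor at zero is applied to either flux —
  the formulas are used as printed, and negative NEP (net emission) is a
  meaningful outcome.
* **Annual NEP**: hourly $GPP - R_{eco}$ integrated and converted with
  12 g C/mol and $10^4$ m²/ha; 1 µmol CO2 m⁻² s⁻¹ sustained over a 365-day
  year is 3.78432 tC ha⁻¹ (leap years follow from the hour count, which the
  integration takes from the series length).

Regridding contracts: categorical maps coarsen by *dominant class* (modal
class per block, nodata ignored, ties to the smallest class code —
deterministic and testable); continuous fields downscale by *bilinear
interpolation* between cell centres, clamped to the coarse centre lattice at
the margins and to the input range overall, with nearest-valid fallback next
to nodata.

## Landscape analytics

Patches are connected components of same-class cells (8-connectivity by
default, configurable to 4), labelled deterministically in reading order via
an adjacency graph. **Edges** are cells whose centre lies within 30 m of a
different-class or nodata cell centre (off-raster counts as nodata); at 30 m
resolution this is exactly the outermost one-cell ring of each patch, and the
implementation is tested against a brute-force all-pairs distance oracle.
Edge cells belong to their own patch; interior cells are the rest. Edge cells
are further classed by what they touch (impervious / green / mixed / other).

Edge-versus-interior contrasts use Welch's unequal-variance t-test per class,
reporting the relative deficit $100\,(\bar{x}_{int} - \bar{x}_{edge}) /
\bar{x}_{int}$. Patch size versus mean condition uses Pearson correlation on
log patch area (the log base does not affect $r$). Zonal summaries are plain
mean/sd/count per class.

## The synthetic landscape generator

`landscape_spec()` + `generate_landcover()` + `generate_components()` emulate
what the analyses need from a fragmented urban mosaic, not urban morphology:

* **Mosaic**: seed points are apportioned among classes by target area
  fractions (largest remainder) and scattered uniformly; every cell takes its
  nearest seed's class (integer squared distances; ties to the lowest seed
  index). This yields contiguous irregular patches whose realized fractions
  track the targets to within a few percentage points at 100×100 and larger.
  Default fractions: forest 0.30, park 0.10, agricultural 0.15, roadside
  0.05, water 0.05, remainder impervious.
* **Components**: per-cell truncated Gaussians (clamped at 0, and at 100 for
  the silt+clay percentage) around per-class means. The default means are
  anchored to published zonal statistics for a Korean metropolitan case
  where available — forest vegetation C 86.59 and roadside 9.44 tC/ha; NEP
  12.26 / 6.72 / 5.56 tC/ha/yr for forest / park / roadside; silt+clay means
  and sds per class; soil C inside the reported 24.35–52.57 tC/ha range —
  and set once to field-typical values where not (park vegetation C 35 and
  agricultural 5 tC/ha, agricultural NEP 4 tC/ha/yr, per-class soil C means,
  remaining sds at roughly 15–25% of the mean). These defaults are the
  package's study conditions and are not tuned per analysis.
* **Edge deficit**: an optional multiplicative factor in (0, 1] applied to
  component values in edge cells (uniformly, or per component to exercise
  specific ternary limitations). It injects a known ground truth: with
  deficit $d$, interiors exceed edges by $100(1-d)\%$ *on the raw component
  scale*. On the normalized/index scale the contrast is inflated by the
  min-max offset ($X_{j,\min} > 0$), which is why the parameter-recovery
  tests measure recovery on a raw component raster and check the index-scale
  contrast only for direction and significance.

What the generator does **not** emulate — and hence what passing tests do not
show about real data: spatial autocorrelation within classes beyond patch
structure, gradual (rather than one-ring) edge gradients, correlated noise
between components, heavy-tailed or skewed component distributions,
road-network geometry, and any temporal dynamics. Parameter recovery here
demonstrates the estimator chain is unbiased under its own assumptions, not
that a real city's edge deficit equals the synthetic one.

All generator outputs are deterministic functions of the spec's single seed
(land cover uses the seed itself; component noise uses seed + 1 so the two
stages are independently reproducible).

## Pipeline, formats, reproducibility

Rasters are exchanged as ESRI ASCII grids (`.asc`) with a `.prj` sidecar for
the CRS label — a plain-text, self-describing interchange format every GIS
reads; integer rasters round-trip bit-exactly and continuous rasters are
printed with 17 significant digits (exact for IEEE doubles). Rasters without
any CRS are rejected at read time since they cannot be co-registered.

The `run_simulate()` → `run_diagnose()` → `run_prescribe()` → `run_edges()`
→ `run_report()` chain (and the `inst/cli/ugci.R` wrapper with exit codes
0/2/3) is idempotent: a fixed config and seed reproduce every CSV/JSON/ASC
artifact byte-for-byte, which the test suite asserts with checksums. All
randomness flows from the single configured seed.

Problem sizes used by the shipped tests: unit tests run on toy grids up to
80×80; the index-invariance and parameter-recovery checks use the default
200×200 landscape (~24,000 valid cells, ≥10³ cells per major class), the
latter over 20 replicate seeds — large enough for the law-of-large-numbers
arguments the checks rely on while keeping the full suite in the tens of
seconds.

## Known limitations

* Weights, and therefore the index, are population-relative: two cities (or
  two subsets of one city) are not directly comparable on index values.
* The entropy weighting reads spatial variability as decision relevance; a
  component that is genuinely important but uniformly poor citywide receives
  a *low* weight.
* The quartile classification is rank-based by construction: 50% of cells
  are always `low` or `extremely_low`, so level shares carry no absolute
  meaning — the spatial pattern and the component decomposition do.
* The ternary step drops the lowest-weight component entirely; a cell
  limited only in that component is invisible to the prescription.
* The closed-form GPP/respiration equations are the deterministic cores of
  what are, in full deployments, calibrated or ML-corrected models; no such
  correction is included here, and cost-benefit considerations are outside
  the index by design.
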