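---
title: "Methods: from topographic change to spatial speciation-rate effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from topographic change to spatial speciation-rate effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topospec)
```

# The question and the model

Topographic change alters both the physical template of speciation
(barriers, habitat diversity) and the climate species experience. This
package estimates how much of the present-day spatial variation in
speciation rates is attributable to historical elevation change, versus
the climate changes it drives and versus present-day elevation and
temperature, using a piecewise path model over five node variables per
grid cell:

* `elev_change` — change in mean elevation (m), present minus
  palaeo-reconstruction (exogenous);
* `t_change` — change in mean annual temperature (°C), present minus past;
* `elev_now`, `t_now` — present-day means;
* `log_lambda` — log assemblage speciation rate.

The default DAG (`default_path_spec()`) has edges
`elev_change → {elev_now, t_change, t_now, log_lambda}`,
`t_change → {t_now, log_lambda}`, `elev_now → {t_now, log_lambda}` and
`t_now → log_lambda`. Historical changes may drive present-day values but
never the reverse; feedback links are rejected by the parser, so the model
stays a DAG. The `elev_change → t_now` edge is the one a missing-path
(d-separation) test adds to the a-priori structure; dropping it
(`default_path_spec(FALSE)`) lets the d-separation machinery rediscover it
on simulated data.

Cells are analysed in three overlapping subsets — uplift
(`elev_change > 0`), erosion (`elev_change < 0`), and all cells — because
elevation gain and loss are different geological processes with
potentially opposite biological consequences. Exact zeros belong to
neither class.

## Assumptions

1. Linearity of every structural equation on the transformed scales.
2. Spatially autocorrelated residuals of the speciation-rate equation are
   adequately described by a simultaneous autoregressive (SAR) error
   process over neighbour weights.
3. Species ranges, the phylogeny and the rasters refer to harmonised
   taxa and a shared equal-area frame (taxonomic matching and map
   projection happen upstream; species in ranges but not the rate table
   are dropped with a warning).
4. Assemblage rates summarise the per-cell species pool; the
   inverse-range weighting treats widespread species as weaker evidence
   about any single cell.

# Stage by stage

## Tip rates

`equal_splits()` computes ES(i) = Σⱼ lⱼ(1/2)^(j−1) along the tip-to-root
path (l₁ = terminal branch) in one pre-order pass via the recursion
g(child) = l + g(parent)/2, g(root) = 0; `dr_statistic()` returns
λ_DR = 1/ES in events/lineage/Myr. A root edge is excluded — it separates
nothing from the root. Polytomies are allowed (the depth index counts
edges, not bifurcations) and flagged in the output, since resolving them
would change the down-weighting. Zero-length terminal branches are
rejected: they would give infinite rates.

A note on calibration: under a pure-birth process the *harmonic* mean of
tip DR (equivalently 1/mean(ES)) estimates the birth rate; the arithmetic
mean is upward-biased by Jensen's inequality (E[1/ES] > 1/E[ES], roughly
+40% at b = 0.2 with 100 tips). The test suite asserts the harmonic-mean
form. Per-tip DR values themselves are used only relatively, as a spatial
field, where a monotone bias is harmless.

## Assemblage grid

Ranges are canonical as cell sets (TSV `species_id`, `cell_id`,
`taxon_group`), 0-based row-major on the declared grid; no CRS math
happens in the package. `weighted_cell_rates()` computes the
inverse-range-weighted arithmetic and geometric means per cell;
`filter_cells()` retains cells with at least one species of every required
taxon group, applied *after* dropping species missing from the rate table
(the occupancy that matters is the occupancy that can contribute a rate).

The response variable defaults to the **weighted geometric mean**: its log
is exactly the weighted mean of log rates, so the modelled response is
linear in the latent log-rate field — the natural scale for a
log-transformed response. The weighted arithmetic mean (the headline
statistic in comparable empirical work) is always computed alongside and
selectable via `rate_column`.

## Terrain and climate

`aggregate_raster()` means raster pixels into cells by pixel-centre
containment with half-open cell intervals [x0, x1), so every centre
belongs to exactly one cell; NODATA (sea) pixels are excluded and cells
with no valid pixel are masked. `change_layer()` is present − past with
mask union. `discard_submerged()` removes cells whose mean past elevation
is negative — comparisons require land at both time points; the reported
discarded fraction's denominator is configurable (candidate cells by
default, whole grid optionally) since either base can be meaningful.

`transform_variables()` applies the analysis transforms within the fitted
subset: log of the response; log of present elevation, with the offset
rule log(elev − min(elev) + 1) applied to the whole subset only when some
value is ≤ 0 (coastal/below-sea-level land) and recorded for
back-transformation; then centring/scaling of every variable to mean 0,
sd 1. Scaling is subset-relative because subsets are fitted separately and
standardized effects are subset-relative quantities; global scaling is a
config option. `collinearity_screen()` reports all pairwise Spearman ρ and
flags (not errors) when any |ρ| ≥ 0.6.

## Spatial statistics

`build_weights()` supports queen (default), rook and symmetrised
k-nearest-neighbour schemes, row-standardized. Queen contiguity is the
customary default for regular grids; knn is the fallback for fragmented
cell sets. Isolated cells are flagged and dropped from fits with a count —
after subsetting, adjacency symmetry guarantees removing them cannot
orphan anyone else.

`morans_i()` evaluates I = (n/S0)·zᵀWz/zᵀz, E[I] = −1/(n−1), with both the
Cliff–Ord normality variance and a seeded permutation test (default 999
shuffles; p = (1 + #{at least as extreme})/(n_perm + 1)). The default
alternative is "greater" — the diagnostic question is whether residuals
are *positively* clustered.

`fit_sar_error()` maximises the likelihood of y = Xβ + u, u = λWu + ε.
For fixed λ, β and σ² have closed forms from the filtered regression of
(I−λW)y on (I−λW)X; the Jacobian log|I−λW| = Σ log(1−λωᵢ) uses the
eigenvalues ω of W, which are real because the row-standardized W is
similar to the symmetric D^{-1/2}AD^{-1/2}; they are computed once per
weights object and cached (dense eigendecomposition — appropriate for the
n ≲ 10⁴ cells this design targets). λ is optimised by Brent search on
(1/ω_min, 1/ω_max) to tolerance 1e-8; if the interior optimum ever falls
below the λ = 0 likelihood the fit returns the OLS solution, so the ML
log-likelihood is never worse than OLS. Standard errors come from the
asymptotic information matrix (the β block is orthogonal to (λ, σ²));
coefficient p-values are two-sided z-tests, matching the convention that
effects with P > 0.05 are reported as non-significant.

## Path model, d-separation, effects

Equations are fitted independently (piecewise), each by SAR-error ML on
the pre-standardized subset, so each edge coefficient is already the
standardized effect β·sd(x)/sd(y). Standardization uses raw subset
standard deviations, not spatially filtered ones — effects are meant to be
interpretable on the observed data scale; this choice is documented
rather than hidden because either convention is defensible.

`dsep_test()` builds the union basis set: one claim per non-adjacent pair
(u, v), conditioning on the union of both parents, tested as the two-sided
p-value of u added to the SAR regression of the topologically later node
v. Fisher's C = −2Σ log p is compared to χ² with 2k df; p-values are
floored at 1e-300 with a warning to keep C finite. A saturated DAG yields
C = 0, df = 0, and a vacuous test. The default five-node DAG leaves
exactly one non-adjacent pair, (elev_now, t_change).

`total_effects()` reads the standardized edge matrix B off the fits and
decomposes: direct = edge coefficient (0 if absent), indirect = sum over
all directed paths of length ≥ 2 of products of edge coefficients, total =
direct + indirect (exact by construction). Two independent computations —
explicit path enumeration and (I−B)⁻¹ − I — must agree to 1e-12 or the
function errors. Group effects (elevation, temperature, historical,
present) are sums of member effects. `effect_uncertainty()` propagates
per-equation asymptotic coefficient covariance by Monte-Carlo (default
1000 draws, independent across equations because the fits are
independent); percentile intervals. Bootstrap refitting would also be
possible but costs a full SAR refit per draw; the Monte-Carlo default is
the pragmatic choice and the draw count is a parameter.
`percent_change_per_sd()` converts a standardized effect to
100·(exp(effect·sd(log λ)) − 1), the % change in the rate itself per 1
s.d. of predictor; `display_filter()` flags (never deletes) effects below
a 5%-per-s.d. display threshold.

# The synthetic world

`simulate_world()` generates the study system the analysis assumes, with
known truth:

* **Phylogeny** — `ape::rphylo` conditioned on n extant tips (default
  300), constant birth/death rates (defaults 0.2 / 0 per lineage per Myr,
  in the range of recent vertebrate estimates); extinct lineages never
  appear, extant trees are ultrametric.
* **Landscape** — the structural equations above on standardized scales.
  The exogenous elevation-change field is white noise convolved with a
  Gaussian kernel of scale `smooth_sigma` = 4 cells (~400 km): real
  topographic-change provinces are spatially coherent over hundreds of
  kilometres, and (see below) a rougher field would make the
  assemblage-level signal unrecoverable by construction. Default
  standardized path coefficients (`default_true_betas()`): 0.5
  (elev_change→elev_now), 0.4 (→t_change), −0.3 (→t_now), −0.5
  (elev_now→t_now), 0.3 (t_change→t_now), and 0.3/0.2/0.15/0.2 for the
  four effects on log λ — moderate, mixed-sign values with cooling under
  uplift. Mediator innovation sds are derived so every mediator has unit
  marginal variance, making the coefficients population standardized
  ones. Only the log λ equation's error is SAR-correlated
  (`sar_lambda` = 0.5, queen weights) — that is where residual
  autocorrelation is found and corrected in the analysis; the innovation
  sd is 0.6 on the structural scale. Physical scales: elevation sd 195 m
  (the magnitude of a 1-s.d. elevation change in comparable real data)
  around a 1000-m mean; temperature sd 5 °C around 10 °C; latent
  log λ = log(0.2) + 0.5·L, giving rates centred on 0.2/Myr with a
  realistic several-fold spread.
* **Ranges** — contiguous blobs grown by seeded random accretion under
  rook adjacency (the simplest contiguity model), sizes 1 + Geometric
  with mean 4 cells; tip rate = exp(mean latent log λ over the range +
  N(0, 0.2)). With 300 species on 900 cells this leaves roughly a quarter
  of cells empty — they simply drop out of the assemblage table, as cells
  without scorable species do in real data.

With the default mean of the elevation-change field at 0, uplift and
erosion cells are roughly balanced; the mean elevation of 1000 m keeps
past elevations essentially always positive, so the submerged-cell filter
is exercised by dedicated unit tests rather than by the default world.

## What the generator does and does not emulate

It reproduces the *statistical* structure the analysis assumes: the causal
DAG with known coefficients, SAR-correlated residuals, heterogeneous
contiguous ranges, and rate noise. It does **not** emulate orogeny or
climate physics, latitudinal gradients, taxonomic error, range-size/rate
correlations, phylogenetic signal in the latent field (tree and landscape
are independent), or coastlines/submergence. Passing tests therefore
demonstrate that the estimator chain is correct and calibrated under its
own assumptions — not that those assumptions hold for any real dataset.

## The estimand under range aggregation

The observable response is an assemblage mean: each species averages the
latent field over its range, so a cell's observed log rate is a smoothed
functional S·(latent) + noise of the field, where S is the row-stochastic
aggregation operator implied by the ranges. The true marginal effect of a
cell's *own* elevation change on its *assemblage* rate is therefore the
structural total effect shrunk by κ = cov(Sf, f)/var(f) (computed exactly
from the simulated ranges by `range_smoothing_factor()`; κ ≈ 0.9 at the
defaults). Ground-truth recovery is defined against this assemblage-level
estimand — the latent-field effect itself is not identifiable from
assemblage data without deconvolving S, which no grid-based analysis of
this kind attempts. This is also why the exogenous field's correlation
scale matters: for a field rough at the range scale κ collapses and the
assemblage carries almost no cell-level signal, which is a property of the
measurement design, not of the estimator.

# Numerical choices

* λ search interval (1/ω_min + 1e-6, 1/ω_max − 1e-6); Brent tolerance
  1e-8; eigenvalues cached per weights object.
* Dual-method effect decomposition tolerance 1e-12; cyclic coefficient
  matrices detected by nilpotency and rejected.
* d-separation p-values floored at 1e-300 (warn).
* Permutation tests seeded; p = (1+m)/(n_perm+1).
* Ties in topological sorting broken lexicographically, so equation order
  never changes results.
* Transform round-trips are exact to 1e-9 including the elevation offset
  rule.
* All cell ids 0-based row-major; pixel-centre containment with half-open
  intervals makes raster binning unambiguous.

# Problem sizes

The reference study conditions used throughout the tests and the
acceptance script are a 30 × 30 grid of 100-km cells with 300 species;
recovery and calibration properties are established over 100–200 seeded
replicates at those conditions (full-pipeline recovery, SAR parameter
recovery, Moran and d-separation calibration), smaller grids serving the
unit tests. These sizes give stable Monte-Carlo estimates of coverage and
rejection rates while keeping the whole suite quick on a single CPU.

# Known limitations

* Dense eigendecomposition limits SAR fits to ~10⁴ cells; sparse log-det
  approximations are out of scope.
* SAR *error* models only — no SAR lag, GMM, or Bayesian CAR variants.
* Asymptotic (information-matrix) standard errors; effect CIs assume
  per-equation asymptotic normality.
* Subset fits inherit the full-grid error process only approximately: the
  SAR process is re-estimated on the subset's own weights.
* GeoTIFF is not read or written; rasters travel as ESRI ASCII grids and
  must be pre-projected to the grid's equal-area frame.
* Rate truncation to a fixed recent time window (estimating rates only
  over the palaeo-data period) is not implemented.
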