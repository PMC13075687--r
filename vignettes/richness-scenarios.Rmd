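---
title: "Deciding among richness-generating scenarios: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding among richness-generating scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the pipeline

Why do some places hold more species of a clade than others? Four canonical
answers can be phrased as causal structures over six observed, cell-level
variables — temperature (T), precipitation (P), net primary productivity
(NPP), assemblage age (the mean time since the resident species arrived in
the region), tip speciation rate (DR), and log richness (lnS):

* **Stable persistence** — richness sits at an energy-set equilibrium:
  climate acts through productivity, productivity has the direct effect on
  richness.
* **Speciation balance** — richness sits at an equilibrium set by
  speciation: climate (especially temperature) and productivity drive DR,
  DR drives richness.
* **Historical legacy** — richness is out of equilibrium and reflects time:
  assemblage age drives richness.
* **Cradles of diversity** — richness is out of equilibrium and reflects
  speciation rate; the product of time and rate is linearized as additive
  age and DR paths (interactions are outside covariance-based path
  analysis).

`cladescape` implements the full decision pipeline for one clade:

1. delineate clades on a large phylogeny (`delineate_clades`),
2. delineate clade-specific biogeographic regions (`evoregions`),
3. fit the Dispersal–Extinction–Cladogenesis (DEC) range model and
   reconstruct ancestral ranges (`fit_dec`, `ancestral_ranges`),
4. derive per-cell assemblage ages from arrival times (`arrival_table`,
   `assemblage_age`),
5. compute DR tip rates and cell medians (`dr_statistic`,
   `cell_median_rate`),
6. fit the full path model and the four scenario models, and pick the
   best-supported scenario by AIC/BIC (`fit_path_model`,
   `select_scenario`).

`analyze_clade()` chains steps 2–6; `benchmark_suite()` plus
`evaluate_benchmark()` run everything against simulated clades with known
generative scenario.

# Clade delineation

Tips are embedded via the graph Laplacian L = D − A of the dense
patristic-distance graph (A = tip-to-tip path lengths, D = diagonal of row
sums) and clustered by k-means. Only tips enter the graph: tips define clade
membership. Clustering uses the eigenvectors of the **k − 1 largest**
eigenvalues: for k well-separated subtrees the between-group contrasts
occupy exactly k − 1 leading modes (the constant mode sits at eigenvalue 0),
while the k-th mode is already a within-group contrast whose amplitude can
exceed the between-group gap and mislead k-means — we verified exact
recovery for 2–5 planted subtrees with this rule and failures without it.
Defaults follow common practice for tetrapod-scale trees: 50 modalities
(40/60 as sensitivity settings), minimum clade size 50 species, paraphyletic
modalities retained but flagged (`extract_clades` reports the share of tips
excluded by the size filter).

# Evoregions

For the focal clade, each cell's occupancy row is smoothed by phylogenetic
similarity (S = 1 − d/max d) and rescaled to sum one, so Bray–Curtis
dissimilarity between cells measures phylogenetic turnover. Principal
coordinates of that dissimilarity (Gower double-centring; negative
eigenvalues dropped; axes retained while each explains ≥ 5% of
positive-eigenvalue variance) feed k-means for K = 2..10; the K with the
largest mean silhouette width wins. The 10-region cap keeps the downstream
DEC state space (2^K − 1 ranges) tractable. The upstream tool this stage
emulates couples fuzzy weighting with a discriminant analysis; since only
the ingredients are published, the ordination/selection pair here is an
explicit substitute isolated behind `pcps_axes()`/`select_evoregions()`.

# DEC ranges and assemblage age

Ranges are subsets of regions (at most `mmax`, default unconstrained).
Anagenesis: expansion R → R+{a} at rate d·|R|, contraction R → R−{a} at rate
e per area, single-area ranges contracting to an absorbing null range.
Cladogenesis: single-area ranges are inherited by both daughters; widespread
ranges split by vicariance (a vs R−{a}) or subset sympatry (a vs R), all
ordered outcomes equally weighted. The likelihood is computed by pruning
with per-node rescaling; branch propagation uses one eigendecomposition of Q
per likelihood evaluation (matrix-free exp(Qt)·v products per branch), with
an `ape::matexpo` fallback when Q is numerically defective. The root prior
is uniform over non-null ranges. ML fitting runs bounded quasi-Newton on
(log d, log e) from three starts, bounds [1e-4, 5] per Ma — rates below
1e-4/Ma are indistinguishable from zero on Ma-scale trees, and the bounds
keep the optimizer out of a flat boundary region.

**The null-range caveat.** On a fixed tree of extant species the absorbing
null range is never observed, and its survival penalty drives the ML
extirpation rate toward zero regardless of the true value — the documented
null-range bias of plain DEC. `condition_survival = TRUE` removes the
single-area → null transition (a lineage known to have survived cannot have
lost its last area), which restores identifiability of e; the pipeline
default remains plain DEC for comparability, and the flag is used where
parameter recovery itself is being tested.

**Arrival times.** A species' arrival in a region is the age of the deepest
ancestral node whose most-probable (argmax) reconstructed range contains the
region, walking tip → root and, by default, requiring uninterrupted
occupancy along the walk — a region lost and regained deeper in the tree
should not inflate the arrival age; `uninterrupted = FALSE` gives the
deepest occupied node anywhere on the path. If already the tip's parent
lacks the region, the species dispersed in after its most recent speciation
and receives the minimal arrival of 10 years (1e-5 Ma; branch lengths are in
Ma throughout). Assemblage age is the mean arrival over the species present
in a cell, evaluated for the cell's evoregion.

# DR tip rates

For tip i with root-to-tip edges e_1 (pendant) … e_N, the equal-splits
measure is ES_i = Σ_j len(e_j)·2^−(j−1) and DR_i = 1/ES_i. Cell values are
medians over co-occurring species (even counts: midpoint). DR is the sole
rate metric here — it is the primary metric of the workflow this package
implements, and Bayesian rate models are out of scope. A calibration note:
on Yule trees the *arithmetic* mean DR overshoots the true speciation rate
by roughly 40% (Jensen's inequality), while the harmonic mean 1/mean(ES)
recovers it within a few percent; the test suite asserts the harmonic form.

# Path models

All variables are observed, so path analysis suffices: each endogenous
variable is regressed on its parents, the ML solution for recursive systems
with uncorrelated errors (the suite checks that perturbing any coefficient
lowers the covariance likelihood). The implied covariance
Σ(θ) = (I−B)⁻¹Ψ(I−B)⁻ᵀ is compared with the sample covariance S through
F_ML = ln|Σ| + tr(SΣ⁻¹) − ln|S| − p and T = (n−1)·F_ML, from which
CFI, TLI, RMSEA (closed forms as usual) and SRMR (RMS of standardized
residual covariances, diagonal included) follow; the baseline model for the
incremental indices is independence (diagonal S). Parameter count
q = edges + endogenous residual variances + exogenous variances +
exogenous covariances; AIC = −2logL + 2q, BIC = −2logL + q·ln n. Richness is
ln-transformed (zero-richness cells are dropped — lnS is undefined there)
and all predictors are z-scored; coefficients are reported standardized
using model-implied standard deviations.

Indirect effects are products of standardized coefficients along directed
paths, grouped by the mediator whose edge enters richness (via productivity,
via age, via DR) — that classification partitions the indirect paths, so
direct + classes = total exactly (checked against the (I−B)⁻¹ total-effect
identity). Residual spatial structure is diagnosed with Moran's I on the
per-equation residuals; the default weight matrix is row-standardized
8-nearest-neighbour (the weighting scheme of the original analyses is not
stated; rook contiguity and user matrices are available), and
`with_spatial_covariates()` re-fits with z-scored latitude and longitude as
exogenous parents of every endogenous variable.

# Scenario selection

The four reduced models keep only each scenario's dominant pathways (plus
the climate → productivity base common to all); direct climate → richness
edges are excluded by default (they are the comparatively weak pathways
under every scenario) but the models are plain `path_model` objects and can
be swapped. **Every reduced model spans the same six variables** — variables
outside a scenario's pathways enter as free exogenous terms — because AIC
and BIC are only comparable between models of the same data. Ties are broken
by fewer free parameters, then by fixed name order. `tally_support()`
aggregates winners across clades by AIC and BIC separately, and
`clade_trait_effects()` regresses per-clade direct effects on clade traits
(crown age, thermal physiology, species diversity, geographic extent).

# The synthetic world

`make_world()` builds an 18 × 12 lattice: temperature falls linearly away
from the central (equator) row at 2 °C per row plus 1 °C noise;
precipitation is a smoothed Gaussian field (mean 1500, sd 400 mm/yr,
length-scale 3 cells); NPP = 3 + 0.5·z(T) + 1.5·z(P) + a smooth unit-sd
non-climatic field, truncated at zero. The precipitation-dominated NPP with
a broad-scale non-climatic component does two jobs: it keeps the
predictors' variance inflation factors below the conventional threshold of
5, and it keeps cell NPP a faithful proxy of the regional mean NPP that the
equilibrium dynamics respond to. Areas are six contiguous blocks on a 3 × 2
grid with rook adjacency: colonization can spread orthogonally to the
climate gradient, so historical contingency is not forced to align with
temperature; the founding region is drawn at random.

`simulate_clade()` is a Gillespie birth–death–dispersal process over the
areas. A lineage speciates at the mean of its range's regional rates (the
daughter starts in one region, drawn ∝ λ) — per-capita, not per occupied
region, which would multiply a widespread lineage's rate by its range size.
Extirpation acts per (lineage, region); dispersal adds an adjacent region at
rate m. Diversity dependence acts on extinction only, μ(region) =
μ0·N/K(region). Scenario defaults (per Ma):

| scenario | λ0 | μ0 | K | γ_T | m | τ |
|---|---|---|---|---|---|---|
| stable persistence | 0.5 | 0.5 | 12 × regional mean NPP | 0 | 0.02 | 25/μ0 |
| speciation balance | 0.5 | 0.5 | 12 × overall mean NPP | 1 | 0.02 | 25/μ0 |
| historical legacy | 0.3 | 0.05 | — | 0 | 0.02 | ln(100)/(λ−μ) |
| cradles of diversity | 0.25 | 0.05 | — | 1 | 0.05 | ln(100)/max λ(T) − μ |

Dispersal is slow in the equilibrium scenarios so regional richness settles
near K rather than being inflated by immigration. The nonequilibrium horizon
is the time for the fastest-growing region to reach ~100 species; the naive
alternative of a fixed fraction of 1/(λ−μ) leaves one or two species and is
unusable. A hard cap of 400 extant lineages bounds runtime; hitting it stops
the simulation at that moment (the tree stays ultrametric at the stop time).
Cell occupancy within occupied regions is thinned at probability 0.7; under
stable persistence the thinning probability scales with cell NPP — local
energy limiting local coexistence is that scenario's mechanism at cell
grain — while the other scenarios thin uniformly.

What a green test does and does not establish: the generator reproduces the
statistical skeleton the pipeline consumes (spatially autocorrelated
climate, an NPP field partly independent of climate, scenario-specific
coupling of richness to energy, rate, or time) but not range-splitting
cladogenesis (DEC is an inference model here, deliberately mismatched with
the generative dispersal process), trait evolution, heritable rate
variation, spherical geometry, or sampling error in occurrence data.

# Known limitations

* **Historical legacy vs cradles is weakly identified at desk scale.** In a
  finite time-limited radiation, regional richness equals elapsed time ×
  the *realized* stochastic diversification of that region's founders, and
  DR — by construction a measure of realized local branching density —
  picks the second factor up. Because the cradles model contains the
  age → lnS edge plus the DR pathways, it describes such realizations at
  least as well as the historical-legacy model and is frequently selected
  for them (the benchmark reports this honestly; stable persistence and
  speciation-balance-vs-cradles behave as expected). Discriminating the two
  would need worlds with rate-homogenized founders or non-nested model
  sets.
* DEC's extirpation rate is not identifiable from extant-only ranges under
  the plain null-range formulation (see above).
* The covariance-based engine fits linear, homoscedastic relations;
  interactive richness = age × rate dynamics are linearized.
* Moran's I is reported as a diagnostic; no spatially explicit covariance
  structure is fitted.
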