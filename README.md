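# cladescape

Why do some places hold more species of a clade than others? Four classic
answers differ in whether richness is at equilibrium and in what sets it:

| scenario | richness is... | dominant pathway |
|---|---|---|
| stable persistence | at an energy-set equilibrium | NPP → richness |
| speciation balance | at a speciation-set equilibrium | climate → DR → richness |
| historical legacy | time-limited (out of equilibrium) | assemblage age → richness |
| cradles of diversity | rate-limited (out of equilibrium) | DR → richness (+ age) |

`cladescape` implements, for macroecologists and biogeographers working with
time-calibrated phylogenies and gridded occurrence data, the full pipeline
that decides among these scenarios for each clade:

1. **Clade delineation** — spectral clustering of the tree's graph Laplacian
   (L = D − A over patristic distances A) into modalities; clades with
   ≥ 50 species retained, paraphyly flagged.
2. **Evoregions** — clade-specific regions from phylogenetic turnover:
   fuzzy (similarity-weighted) cell composition, principal coordinates of
   Bray–Curtis dissimilarity, silhouette-selected k-means (K ≤ 10).
3. **DEC ancestral ranges** — the Dispersal–Extinction–Cladogenesis model:
   ranges R ⊆ regions expand at rate d·|R|, contract at rate e per area, and
   split at nodes by vicariance or subset sympatry; likelihood by
   Felsenstein pruning, ML fit of (d, e), marginal reconstructions.
4. **Assemblage age** — per species and region, the age of the deepest
   ancestral node whose reconstructed range includes the region
   (uninterrupted from the tip; floor of 10 years = 1e-5 Ma for
   post-speciation dispersers); per cell, the mean over resident species.
5. **DR tip rates** — ES_i = Σ_j len(e_j)·2^−(j−1) along the root-to-tip
   path, DR_i = 1/ES_i; cell values are medians over co-occurring species.
6. **Path models** — recursive SEM over {T, P, NPP, age, DR, lnS}:
   equation-wise least squares (the ML solution), implied covariance
   Σ(θ) = (I−B)⁻¹Ψ(I−B)⁻ᵀ, discrepancy T = (n−1)·F_ML, CFI/TLI/RMSEA/SRMR,
   AIC = −2logL + 2q, BIC = −2logL + q·ln n, direct/indirect effect
   decomposition, VIF, and Moran's I residual diagnostics.
7. **Scenario selection** — the four reduced models (all spanning the same
   six variables) compared by AIC and BIC; lowest criterion wins.

A Gillespie birth–death–dispersal simulator (`make_world`,
`simulate_clade`, `benchmark_suite`) generates gridded worlds and clades
under each scenario with full ground truth, so every stage is testable
offline. See the methods vignette
(`vignettes/richness-scenarios.Rmd`) for the models, parameter choices, and
known limitations.

## Worked example

```r
library(cladescape)

world <- make_world(world_config(seed = 42))
clade <- simulate_clade(world, scenario_params("stable_persistence", seed = 7),
                        occupy_prob = 0.7)
length(clade$phy$tip.label)
#> [1] 237

an <- analyze_clade(clade$phy, clade$pam, clade$env, seed = 1, kmax = 6)
an
#> Clade analysis: 6 evoregions; DEC d = 0.00396, e = 0.000652; 214 cells
#> Direct standardized effects on lnS:
#>   temperature precipitation           npp           age            dr
#>         0.078         0.148         0.754         0.099        -0.069
#> Scenario winner (AIC): stable_persistence | (BIC): stable_persistence

an$support$table[, c("scenario", "aic", "bic", "delta_aic")]
#>              scenario      aic      bic delta_aic
#>    stable_persistence 2586.610 2637.099    0.0000
#>    speciation_balance 2911.543 2962.032  324.9331
#>     historical_legacy 2939.889 2990.378  353.2789
#>  cradles_of_diversity 2912.345 2966.200  325.7352

max(an$vif); an$moran_lnS
#> [1] 4.21
#> [1] 0.428
```

Reading the output: the pipeline recovered 6 evoregions on this simulated
clade, productivity carries by far the largest direct standardized effect on
log richness (β = 0.75) while assemblage age and DR are near zero — the
equilibrium, energy-driven signature — and the stable-persistence model wins
by both criteria with a margin of > 300 AIC units. Collinearity is below the
conventional VIF threshold of 5; the positive Moran's I on the richness
residuals shows the usual residual spatial structure, which the
`with_spatial_covariates()` refit probes.

Real data enter through `read_phylogeny()` (Newick), `read_pam()`
(cells × species CSV with `cell_id, lat, lon`), and `read_env()`
(`cell_id, temperature, precipitation, npp`).

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it simulates a small benchmark (two clades per scenario), runs the complete
pipeline on every clade, prints the per-clade scenario decisions, the
recovery accuracy, the support tally, and one full single-clade analysis,
and writes its JSON output to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
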