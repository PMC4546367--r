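# inflectr

Growth-curve inflection analytics and digital gene expression (DGE)
profiling for developmental-stage studies in livestock.

A recurring design in animal genomics models a population's sigmoid
growth curve, locates the **inflection point** — the age at which daily
gain peaks — and then profiles gene expression in muscle at three stages
defined by that point: before it (BIP), under it (UIP) and after it
(AIP). inflectr implements that whole computational pipeline as tidy,
pipe-friendly R functions:

- **Growth models** — least-squares fits of the logistic
  ($W_t = A/(1+Be^{-kt})$), Gompertz ($W_t = Ae^{-Be^{-kt}}$) and Von
  Bertalanffy ($W_t = A(1-Be^{-kt})^3$) curves, ranked by
  $R^2 = 1-\mathrm{RSE}/\mathrm{RST}$, with closed-form and numeric
  inflection age, weight and maximum daily gain.
- **Expression quantification** — RPKM normalization of tag-count
  matrices, expressed-transcript sets per stage, abundance-concentration
  profiles, hypergeometric saturation curves, replicate correlations.
- **Differential expression** — pooled conditional exact count test
  (Audic–Claverie style) with the conjunctive DEG rule
  $p \le 0.05$ and $|\log_2\mathrm{FC}| \ge 1$, plus average-linkage
  clustering of libraries on correlation distance.
- **Gene-set enrichment** — the EASE statistic (modified one-tailed
  Fisher test with the overlap cell decremented by one) under
  Benjamini–Hochberg correction.
- **QTL overlap** — the QTL-gene rule (region < 2 Mb, overlap at least
  half the gene or half the region) with per-chromosome chi-square
  enrichment tables.
- **qPCR** — relative expression by $2^{-\Delta\Delta C_t}$ with
  multi-reference normalization, and relative mtDNA copy number per
  diploid cell by $2^{\Delta C_t}$.
- **Synthetic data** — seed-deterministic generators for every input
  (growth records, overdispersed tag counts with planted DEGs and a
  truth table, gene/QTL interval catalogues, Ct tables), so the full
  pipeline runs and is testable offline.

See `vignettes/growth-inflection-dge.Rmd` for the models, assumptions and
design decisions in detail.

## Worked example

Simulate mean weight-by-age records under the package's default study
conditions — a Von Bertalanffy truth with inflection at 193.40 days /
62.61 kg / 455.43 g per day, 20 time points from birth to 250 days,
1 kg measurement noise — then fit and rank all three models:

```r
library(inflectr)

obs <- simulate_growth(growth_sim_config())  # defaults shown above, seed 1
cmp <- compare_models(obs)
dplyr::select(cmp, model, r2, t_star_days, w_star_kg, g_max_g_day)
#> # A tibble: 3 × 5
#>   model              r2 t_star_days w_star_kg g_max_g_day
#>   <chr>           <dbl>       <dbl>     <dbl>       <dbl>
#> 1 von_bertalanffy 0.999        204.      67.7        462.
#> 2 gompertz        0.999        177.      55.8        468.
#> 3 logistic        0.995        170.      52.4        510.
```

The Von Bertalanffy model ranks first by $R^2$, and its inflection
analytics land near the generating truth: maximum daily gain ~462 g/day
at ~204 days and ~68 kg (the inflection age and gain are estimated more
precisely than the inflection weight, which tracks the weakly identified
asymptote — see the vignette). The fitted object prints its parameters
and diagnostics:

```r
fit_growth_model(obs, "von_bertalanffy")
#> Sigmoid growth fit: von_bertalanffy
#>   A = 228.3415 kg, B = 0.844188, k = 0.00455454 /day  (n = 20)
#>   RSE = 14.8604 kg^2, RST = 16108.1691 kg^2, R^2 = 0.999077
```

Downstream, a synthetic 3-stage × 3-replicate tag-count experiment with
planted fold changes flows through quantification and DEG calling:

```r
sim  <- simulate_counts(count_sim_config(seed = 7))
degs <- call_degs(sim$counts, sim$annotation,
                  group_a = paste0("BIP_", 1:3),
                  group_b = paste0("UIP_", 1:3))
dplyr::arrange(degs, p_value)[1:3, c("gene_id", "log2fc", "p_value", "is_deg")]
#> # A tibble: 3 × 4
#>   gene_id log2fc  p_value is_deg
#>   <chr>    <dbl>    <dbl> <lgl>
#> 1 G00917   -2.64 3.97e-37 TRUE
#> 2 G00242   -2.47 6.74e-37 TRUE
#> 3 G00120    2.35 7.27e-37 TRUE
sum(degs$is_deg)
#> [1] 115
```

Each `is_deg` flag is the conjunction of the exact-test p-value (≤ 0.05)
and the pooled RPKM fold change (|log2FC| ≥ 1); `sim$truth` lists the
planted genes for benchmarking. `run_pipeline(pipeline_config(...))` ties
all stages together from files on disk and writes TSV outputs plus a JSON
report; `write_simulation_bundle()` materialises a complete synthetic
input set.

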