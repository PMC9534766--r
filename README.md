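# rvsat

Set-based rare-variant association tests for biobank-style case–control and
quantitative phenotypes, with ultra-rare variant collapsing.

## What it does, and for whom

Gene-based tests of rare variation (Burden, SKAT, SKAT-O) are the standard way
to find genes whose rare coding alleles move a phenotype. Two things routinely
go wrong in large cohorts: with heavily unbalanced case–control traits the
variance-component tests become badly anti-conservative when restricted to
very rare variants (maximum MAF 0.1% or 0.01%), and testing every gene under
several MAF cutoffs and functional-annotation masks multiplies both cost and
multiplicity. `rvsat` is for statistical geneticists who want those analyses
to run calibrated and reproducibly at desk scale:

* **Ultra-rare collapsing.** Within each testing set, variants with minor
  allele count MAC ≤ 10 (inclusive, configurable) are merged into one marker
  whose per-sample dosage is the maximum raw dosage among the ultra-rare
  variants the sample carries. The merged marker behaves like a moderately
  rare variant, removing the sparsity-driven skew that inflates SKAT-type
  tests and shrinking the marker count.
* **Score tests robust to imbalance.** Burden, SKAT
  (`Q = Σ_j S_j²` against the mixture `Σ_k λ_k χ²₁`, eigenvalues of the null
  covariance Φ) and SKAT-O
  (`Q_ρ = (1−ρ) Q_SKAT + ρ Q_Burden` over a mixing grid), with Beta(1,25)
  MAF weights by default and a Barndorff–Nielsen saddlepoint tail for
  binary-trait burden-type scores when |z| > 2. Mixture tails come from
  characteristic-function inversion with saddlepoint and moment-matching
  fallbacks.
* **A testing grid plus Cauchy aggregation.** Masks (LoF; LoF+missense;
  LoF+missense+synonymous) × maximum-MAF cutoffs (1%, 0.1%, 0.01%) per gene;
  per-cell p-values combine through `T = mean(tan((0.5 − p)π))`,
  `p = P(Cauchy > T)`, falling back to min-p Bonferroni when any cell has
  p = 1. Exome-wide significance is declared at p < 2.5×10⁻⁶.
* **A two-step design.** Step 1 fits the phenotype null model once (logistic
  IRLS or least squares; covariates-as-offset mode; optional sparse-GRM
  mixed model with relatedness cutoff 0.05 and a variance-ratio calibration).
  Step 2 reuses it for every gene.
* **A simulation framework** for type-I-error and power studies on synthetic
  exome-like genotypes (singleton-dominated MAF spectrum, configurable
  prevalence / case:control ratio, causal proportion and MAF-dependent
  effect sizes), fully reproducible from one seed.

## A worked example

Simulate one gene for 5,000 samples (1:19 case:control), fit the null model,
run the 3 × 3 testing grid, and combine the cells:

```r
library(rvsat)

set.seed(2024)
cfg <- sim_config(n_samples = 5000, n_variants = 150,
                  case_control_ratio = "1:19", seed = 2024)
gvs <- simulate_genotypes(cfg, gene_id = "GENE1")
ph  <- simulate_phenotype(gvs, cfg, null = TRUE)

fit   <- fit_null(ph$data, y ~ x1, trait_type = "binary")
cells <- run_gene(fit, gvs)
cells |> dplyr::select(mask_annotations, max_maf, m_markers_pre,
                       m_markers_post, collapsed, p_burden)
#> # A tibble: 9 × 6
#>   mask_annotations        max_maf m_markers_pre m_markers_post collapsed p_burden
#>   <chr>                     <dbl>         <int>          <int> <lgl>        <dbl>
#> 1 lof                      0.01              15              2 TRUE       0.702
#> 2 lof                      0.001             14              1 TRUE       0.213
#> 3 lof                      0.0001             5              1 TRUE       0.640
#> 4 lof,missense             0.01              94             16 TRUE       0.110
#> 5 lof,missense             0.001             79              1 TRUE       0.00415
#> 6 lof,missense             0.0001            46              1 TRUE       0.132
#> 7 lof,missense,synonymous  0.01             136             26 TRUE       0.989
#> 8 lof,missense,synonymous  0.001            111              1 TRUE       0.0147
#> 9 lof,missense,synonymous  0.0001            61              1 TRUE       0.0847

combine_gene(cells, "skato") |> dplyr::select(-cells)
#> # A tibble: 1 × 6
#>   gene  p_combined n_cells fallback_minp best_mask    best_max_maf
#>   <chr>      <dbl>   <int> <lgl>         <chr>               <dbl>
#> 1 GENE1     0.0266       9 FALSE         lof,missense        0.001
```

Reading the output: `m_markers_pre` is the number of qualifying variants in
the cell and `m_markers_post` the count after ultra-rare collapsing — in the
0.1% and 0.01% cells every qualifying variant is ultra-rare, so each
collapses to a single marker — the marker-count reduction that makes the
rarest cells both testable and cheap.
The gene-level p-value (0.027 here, under the null, so unremarkable) is the
Cauchy combination of the nine SKAT-O cells; `best_mask`/`best_max_maf`
record the most significant cell. `run_pipeline()` wraps the same flow from
VCF + group file + phenotype TSV to per-cell and per-gene TSVs, and
`inst/cli/rvsat` exposes `step1 / step2 / aggregate / simulate / report`
subcommands for shell use.

Real data enter through a VCF (GT or DS fields) and a plain-text group file
with two lines per gene:

```
GENE1 var 1:100:A:T 1:200:G:C ...
GENE1 anno lof missense ...
```

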