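---
title: "Set-based rare-variant association testing with ultra-rare collapsing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Set-based rare-variant association testing with ultra-rare collapsing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gene-based tests aggregate rare variants within a gene because single ultra-rare
variants carry almost no individual information. The standard toolkit is the
Burden test (a score test on the weighted sum of rare-allele dosages, powerful
when causal effects share a direction), SKAT (a variance-component score test
with statistic $Q = \sum_j S_j^2$, whose null law is a mixture of 1-df
chi-squares, powerful under mixed effect directions), and SKAT-O (the optimal
convex combination $Q_\rho = (1-\rho)\,Q_{\text{SKAT}} + \rho\,Q_{\text{Burden}}$
over a grid of $\rho$).

Two practical failure modes motivate this package's design. First, for binary
traits with heavy case-control imbalance the normal approximation to the score
statistic is poor, and variance-component tests restricted to very rare
variants (maximum MAF 0.1% or 0.01%) show inflated type I error: the score
contribution of a variant observed in a handful of carriers is extremely
skewed, and squaring it (as SKAT does) accumulates the skew. Second, testing
each gene under several maximum-MAF cutoffs and functional-annotation masks
multiplies cost and creates a multiplicity problem.

`rvsat` addresses both the way modern set-based pipelines do:

1. **Ultra-rare collapsing.** Before testing each variant set, variants with
   minor allele count (MAC) at or below a threshold (default 10, inclusive)
   are merged into a single marker whose per-sample dosage is the maximum raw
   dosage among the ultra-rare variants the sample carries. The collapsed
   marker behaves like a moderately rare variant, removing the worst of the
   sparsity-driven skew and shrinking the marker count.
2. **Saddlepoint adjustment (SPA).** Burden-type scores for binary traits are
   tested with a Barndorff-Nielsen saddlepoint tail of the exact conditional
   cumulant generating function whenever the standardized score exceeds 2 in
   absolute value, two-sided by doubling the smaller tail.
3. **A testing grid plus Cauchy aggregation.** Each gene is tested under the
   grid of annotation masks (LoF; LoF+missense; LoF+missense+synonymous) by
   maximum-MAF cutoffs (1%, 0.1%, 0.01%), and the per-cell p-values are
   combined by the Cauchy combination
   $T = \tfrac1k \sum_i \tan\{(0.5 - p_i)\pi\}$, $p = \Pr(C > T)$ for a
   standard Cauchy $C$ — robust to dependence among cells. Because the
   tangent transform is undefined at $p = 1$, a gene with any unity cell
   falls back to min-p with Bonferroni correction, `min(k * min(p), 1)`.

## The two-step architecture

**Step 1** fits the phenotype null model once per trait: logistic IRLS
(gradient tolerance $10^{-8}$) for binary traits, least squares for
quantitative ones, with optional rank-based inverse-normal transformation.
Two refinements mirror large-cohort practice:

* *Covariates as offset* (`offset_mode = TRUE`): the fitted covariate linear
  predictor is frozen, and Step 2 projects only the intercept out of the
  genotypes. Fitted means are identical to the full mode; when genotypes are
  orthogonal to covariates the score test is unchanged, and the per-gene cost
  drops because the projection design has one column.
* *Sparse-GRM mixed model* (`fit_null_mixed()`): a polygenic random effect
  with covariance $\tau\,\Psi$, where $\Psi$ is a genetic relationship matrix
  thresholded at a relatedness cutoff (default 0.05) so only close relatives
  remain. Quantitative traits are fitted by REML after rotating into the
  eigenbasis of $\Psi$ (the variance profile is one-dimensional in
  $\delta = \tau/\sigma^2$); binary traits by penalized quasi-likelihood,
  re-estimating $\tau$ on the working model to a $10^{-6}$ tolerance with a
  50-iteration cap. $\tau \ge 0$ is enforced; boundary fits report
  $\tau = 0$ exactly. The *variance ratio* — the mean over common probe
  markers (30 by convention) of the mixed-model score variance
  $g^\top P g$ over the naive GLM score variance — calibrates Step 2: the
  null covariance of the score vector is multiplied by it. It is exactly 1
  when no random effect is present.

**Step 2** computes, per testing cell, the score vector
$S = \tilde G_w^\top (y - \hat\mu)/\hat\phi$ and its null covariance
$\Phi = w^\top\!\big(G^\top W G - G^\top W X (X^\top W X)^{-1} X^\top W G\big) w
\cdot r$ (with $W$ the working weights, $r$ the variance ratio), then forms
Burden, SKAT and SKAT-O p-values from $(S, \Phi)$ alone.

## Numerical machinery

*Mixture-of-chi-square tails.* SKAT-type p-values need
$\Pr(\sum_k \lambda_k \chi^2_1 > q)$ for the eigenvalues $\lambda_k$ of
$\Phi$. A single eigenvalue is an exact chi-square tail. Otherwise the
characteristic function is inverted numerically on a uniform grid: the
midpoint rule's error is aliasing mass pushed beyond $2\pi/\text{step}$,
which a Chernoff bound keeps below the target accuracy ($10^{-9}$ by default);
the truncated oscillatory tail is corrected analytically by one integration
by parts. Below $p \approx 10^{-8}$, and whenever the inversion's error
estimate is unsatisfactory, the Kuonen saddlepoint approximation takes over
(it is extremely accurate in far tails), with Liu moment matching
(kurtosis-corrected) as the last resort. The method used is recorded per
result (`method_tail`). Eigenvalues below $10^{-10}\lambda_{\max}$ are
dropped. Study harnesses run the inversion at accuracy $10^{-7}$; that
trades invisible single-test error for roughly a third of the runtime.

*SKAT-O.* Per-$\rho$ tails use eigenvalues of
$R_\rho^{1/2}\,\Phi\,R_\rho^{1/2}$ with $R_\rho = (1-\rho)I + \rho
\mathbf{1}\mathbf{1}^\top$, whose square root is available in closed form.
The omnibus p-value integrates the minimum-p statistic over the common
burden-direction component (a 1-df chi-square), with the inner conditional
tail computed by kurtosis-matched moment approximation — the standard
construction. $\rho = 1$ is capped at $0.999$ inside the integral (the
$1/(1-\rho)$ threshold degenerates there); a single-element grid returns the
corresponding pure test, so the $\rho \in \{0\}$ / $\{1\}$ endpoints coincide
with SKAT / Burden to numerical precision. The omnibus value is clamped to
$[\min_\rho p_\rho,\ k\min_\rho p_\rho]$; if the integral fails the
Bonferroni bound is returned. The default grid is
$\{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$.

*SPA.* The cumulant generating function of
$S = \sum_i g_i (y_i - \mu_i)$ under $y_i \sim \text{Bernoulli}(\mu_i)$ is
exact; the saddlepoint is found by safeguarded root bracketing, and the tail
follows the Barndorff-Nielsen formula. Below $|z| = 2$ the normal
approximation is returned (the two agree there), and the root-finder falling
off the representable range also falls back to normal. With a single
post-collapse marker — the typical situation in the rarest MAF cell, where
every qualifying variant is ultra-rare — Burden, SKAT and SKAT-O coincide
with the single-variant score test; for binary traits `run_gene()` therefore
routes that cell through the SPA-adjusted test for all three, which is what
keeps the rarest cells calibrated under imbalance.

*Collapsed-marker conventions.* With the default Beta(1, 25) weighting, the
collapsed marker is formed from raw dosages and all weights (collapsed
marker included) are Beta densities of post-collapse marker MAFs, the
collapsed MAF being (sum of collapsed dosages)/(2N), capped at 0.5. With
user weights, ultra-rare dosages are multiplied by their weights *before*
the per-sample maximum, and the reported weight vector is all ones — the
tests must not re-weight; "no weights" is that scheme with unit weights.
MACs are recomputed per testing cell (post-mask), the MAC of dosage data is
the real-valued sum of minor-allele dosages, and the threshold is inclusive
(`MAC <= 10`). A collapsed column that happens to duplicate an existing
column is kept — the marker-count law
$K = \#\{\text{MAC} > t\} + \mathbf{1}[\#\{\text{MAC} \le t\} > 0]$ is exact.

*Aggregation edge cases.* The fallback triggers on exact unity only;
p-values within $10^{-15}$ of 1 are clamped to $1 - 10^{-15}$ before the
tangent transform, and $p < 10^{-15}$ uses the asymptote $1/(p\pi)$.
Untested cells (no qualifying variants) are absent from the combination
rather than imputed as $p = 1$, which would spuriously force the fallback.
Note that the combined p-value is monotone in every cell p-value within each
path; a perturbation that switches the fallback off can move it either way.

## The synthetic-data generator

`simulate_genotypes()` draws independent variants with hard-call genotypes in
Hardy-Weinberg proportions. The `wes_like` MAF spectrum is an 80/20 mixture
of a log-uniform ultra-rare component on $[10^{-5}, 2.5\times10^{-4}]$ and a
log-uniform rare-to-common tail on $[2.5\times10^{-4}, 0.05]$; at cohort
sizes in the thousands the bulk of realised variants have MAC at or below 10
and a large fraction are singletons, mimicking the singleton-dominated site
frequency spectrum of exome sequencing. Variants that realise as monomorphic
are redrawn (up to 10 times, then dropped); this conditions the realised
spectrum on polymorphism and further enriches singletons, exactly as
ascertained variant lists do. Annotations are assigned
lof/missense/synonymous at 0.1/0.6/0.3 by default.

`simulate_phenotype()` draws binary traits from
$\text{logit}\,\Pr(y = 1) = \alpha_0 + \gamma x_1 + \sum_{j \in C}\beta_j g_j$
with one standard-normal covariate ($\gamma = 0.5$), the intercept solved so
the marginal prevalence matches the target (within $10^{-3}$; the solver is
much tighter), causal variants sampled uniformly at rate `causal_prop` among
qualifying variants, and $|\beta_j| = c\,|\log_{10} \text{maf}_j|$ under the
`maf_log` effect model. The package's small/large effect-size conventions
are $c = 0.3$ and $c = 0.7$; these are conventions of this package's study
designs, not estimates from data. All randomness flows from one top-level
seed through named sub-streams (`derive_seed()`), so every study is exactly
reproducible from (config, seed).

What the generator does *not* emulate: linkage disequilibrium and haplotype
structure (variants are independent), relatedness between genotypes and the
GRM used by the mixed model (the recovery studies draw the polygenic term
directly from a family-block covariance), annotation-correlated allele
frequencies, and genotyping/calling error. Calibration and power results on
these synthetic data therefore speak to the statistical machinery — score
construction, tail approximation, collapsing, aggregation — not to the
vagaries of real exome data.

## Study designs and what they show

The packaged study harnesses use desk-scale designs chosen to run on a
single CPU in minutes while keeping the statistical phenomena visible:

* **Calibration (type I error).** N = 5,000 with case:control 1:99,
  800 genes of 200 `wes_like` variants, 25 independent null phenotype
  replicates (20,000 set tests per pipeline), testing the all-annotation
  mask at maximum MAF 0.01%. At this cutoff every qualifying variant is a
  singleton, so the with-collapsing pipeline tests a single collapsed marker
  per gene while the no-collapsing pipeline feeds ~40-100 singleton columns
  to the quadratic form. The contrast reproduces the inflation phenomenon:
  without collapsing, SKAT's empirical type I error at $\alpha = 0.01$ runs
  an order of magnitude above nominal; with collapsing plus SPA it returns
  to the nominal neighbourhood.

  A desk-scale caveat worth stating plainly: with 50 cases, a collapsed
  marker of ~75 carriers has less than one expected case-carrier, so its
  test statistic is strongly discrete. P-value-based summaries inherit that
  discreteness — the genomic-control $\lambda$ (a median statistic) sits
  wherever the count-0 atom falls, and can land well away from 1 for a
  perfectly honest test. At biobank scale (hundreds of thousands of samples,
  collapsed MACs in the thousands) the same machinery is effectively
  continuous. The empirical rejection rate at $\alpha$, not $\lambda$, is
  the robust calibration summary in the discrete regime; both are reported.

* **Small-sample oracles.** At N = 12 every quantity is computable exactly
  by enumerating all $2^{12}$ case-control outcomes. The SPA burden p-value
  is compared with the exact doubled-tail enumeration under the mid-p
  convention (half weight on the observed atom) — the exact quantity a
  continuous tail approximation of a lattice statistic estimates. SKAT is
  compared with a 200,000-replicate parametric bootstrap; here the mixture
  of chi-squares is itself an asymptotic approximation, and at N = 12 it
  deviates from the exact Bernoulli law by amounts that depend on where the
  observed statistic falls — a finite-sample gap of the statistic, not an
  implementation error (the implementation's $\Phi$ equals the enumerated
  covariance to machine precision).

* **Power.** 1,000 replicates per scenario at N = 5,000, prevalence 10%,
  significance at $\alpha = 10^{-3}$ (a desk-scale stand-in for the
  exome-wide $2.5\times10^{-6}$, keeping replicate counts tractable). Three
  claims are checked directionally: SKAT-O does not lose to Burden under
  sparse mixed-sign signal; collapsing does not lose to no-collapsing across
  low/small, low/large, high/large causal architectures; and the 3×3
  multi-mask Cauchy combination does not lose to a single wide cell when
  causal effects concentrate in ultra-rare LoF variants.

* **Variance-component recovery.** N = 1,000 in family blocks of 10 with
  within-family relatedness 0.5, quantitative traits: 100 replicates each at
  $\tau = 0$ and $\tau = 1$. The block size comes from a design
  calculation: the REML information for $(\tau, \sigma^2)$ on $F$ families
  with block covariance $\Psi_f$ gives
  $\text{sd}(\hat\tau \mid \tau = 0) \approx
  \{I_{\sigma\sigma}/(I_{\tau\tau}I_{\sigma\sigma} -
  I_{\tau\sigma}^2)\}^{1/2} \approx 0.03$ for 100 blocks of 10, so the
  study can resolve $\tau = 0$ at the 0.05 level in well over 90% of
  replicates (blocks of 4 give $\approx 0.05$, too coarse for that
  target). Expected behaviour: under $\tau = 0$ the estimate is below 0.05
  in at least 90% of replicates and the variance ratio averages 1; under
  $\tau = 1$ the mean estimate lands in [0.6, 1.4].

## Defaults that matter

| Parameter | Default | Meaning |
|---|---|---|
| `mac_threshold` | 10 | inclusive ultra-rare collapsing threshold (MAC) |
| weights | Beta(1, 25) on MAF | rare-variant up-weighting; at MAF 0 the weight is 25 |
| mask grid | 3 annotations × {1%, 0.1%, 0.01%} | LoF; +missense; +synonymous |
| `rho_grid` | {0, .01, .04, .09, .16, .25, .5, 1} | SKAT-O mixing grid |
| SPA trigger | \|z\| > 2 | below it the normal tail is used |
| GRM cutoff | 0.05 | relatedness below it is zeroed (sparse GRM) |
| probe markers | 30 | variance-ratio calibration |
| significance | 2.5e-6, strict < | exome-wide threshold for ~20k genes |
| tail accuracy | 1e-9 (1e-7 in study harnesses) | CF-inversion target |

## Known limitations

Full dense-GRM REML at biobank scale, leave-one-chromosome-out fitting, and
GRM marker pruning are out of scope; the sparse-GRM and plain-GLM paths
cover the fast route. The variance ratio is a single global factor (no MAC
stratification). SPA is applied to burden-type statistics and the collapsed
single-marker check, not inside the SKAT quadratic form, and exact
small-MAC resampling corrections are not implemented — ultra-rare
collapsing is this package's remedy for exactly that regime. Effect-size
magnitudes in the power scenarios are package conventions, and the
simulation results should be read as orderings, not absolute power
estimates for any real trait.
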