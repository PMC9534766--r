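# Synthetic WES-like genotype and phenotype generator. Genotypes are
# independent variants with a singleton-dominated MAF spectrum (hard calls
# drawn under Hardy-Weinberg proportions); binary phenotypes follow a
# logistic model whose intercept is solved so the marginal prevalence matches
# the target, with configurable causal architecture.

#' Simulation configuration
#'
#' @param n_samples number of samples (default 10000).
#' @param n_variants variants per gene (default 200).
#' @param maf_spectrum `"wes_like"` (an 80/20 mixture of a log-uniform
#'   ultra-rare component on \[1e-5, 2.5e-4\] and a log-uniform rare-to-common
#'   tail on \[2.5e-4, 0.05\], so at biobank-style sample sizes most variants
#'   realise MAC <= 10), `"uniform_log"` (log-uniform on \[1e-4, 0.05\]), or a
#'   single numeric MAF for a degenerate spectrum.
#' @param prevalence marginal case fraction for binary traits (default 0.1).
#' @param case_control_ratio optional string `"1:r"`; overrides `prevalence`
#'   with `1 / (1 + r)`.
#' @param causal_prop proportion of qualifying variants that are causal.
#' @param effect_model `"maf_log"` (`|beta| = effect_c * |log10 maf|`) or
#'   `"constant"` (`|beta| = effect_c`).
#' @param effect_c effect-size scale; 0.3 and 0.7 are the package's small-
#'   and large-effect conventions.
#' @param sign_mix fraction of causal effects with positive sign (default 1).
#' @param causal_annotations optional annotation subset causal variants are
#'   drawn from (default all).
#' @param causal_max_maf optional MAF ceiling for causal variants.
#' @param annotation_props probabilities of lof/missense/synonymous labels
#'   (default 0.1/0.6/0.3).
#' @param covariate_effect coefficient of the single standard-normal
#'   covariate in the phenotype model (default 0.5).
#' @param n_replicates replicates for study harnesses (default 2000).
#' @param seed mandatory top-level seed.
#' @return A list of class `rv_sim_config`.
#' @export
sim_config <- function(n_samples = 10000, n_variants = 200,
                       maf_spectrum = "wes_like",
                       prevalence = 0.1, case_control_ratio = NULL,
                       causal_prop = 0, effect_model = c("maf_log", "constant"),
                       effect_c = 0.3, sign_mix = 1,
                       causal_annotations = NULL, causal_max_maf = NULL,
                       annotation_props = c(lof = 0.1, missense = 0.6,
                                            synonymous = 0.3),
                       covariate_effect = 0.5,
                       n_replicates = 2000, seed) {
  effect_model <- match.arg(effect_model)
  if (missing(seed)) abort("`seed` is mandatory for reproducibility.")
  if (!is.null(case_control_ratio)) {
    parts <- as.numeric(strsplit(case_control_ratio, ":", fixed = TRUE)[[1]])
    if (length(parts) != 2 || any(!is.finite(parts)))
      abort("`case_control_ratio` must look like '1:99'.")
    prevalence <- parts[1] / sum(parts)
  }
  stopifnot(prevalence > 0, prevalence < 1, causal_prop >= 0, causal_prop <= 1,
            sign_mix >= 0, sign_mix <= 1, n_samples >= 10, n_variants >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 maf_spectrum = maf_spectrum, prevalence = prevalence,
                 causal_prop = causal_prop, effect_model = effect_model,
                 effect_c = effect_c, sign_mix = sign_mix,
                 causal_annotations = causal_annotations,
                 causal_max_maf = causal_max_maf,
                 annotation_props = annotation_props,
                 covariate_effect = covariate_effect,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "rv_sim_config")
}

draw_maf <- function(n, spectrum) {
  if (is.numeric(spectrum)) return(rep(spectrum, n))
  loguni <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))
  switch(spectrum,
         wes_like = {
           rare <- runif(n) < 0.8
           out <- numeric(n)
           out[rare] <- loguni(sum(rare), 1e-5, 2.5e-4)
           out[!rare] <- loguni(sum(!rare), 2.5e-4, 0.05)
           out
         },
         uniform_log = loguni(n, 1e-4, 0.05),
         abort(paste0("unknown maf_spectrum: ", spectrum)))
}

#' Simulate a synthetic gene's genotypes
#'
#' Independent variants; per-variant population MAF drawn from the configured
#' spectrum; hard-call genotypes drawn under Hardy-Weinberg proportions.
#' Variants that realise as monomorphic are redrawn up to 10 times, then
#' dropped. Annotations are assigned lof/missense/synonymous with the
#' configured proportions.
#'
#' @param cfg an [sim_config()].
#' @param gene_id id for the generated gene.
#' @param seed seed (default `cfg$seed`); the same seed reproduces the matrix
#'   bitwise.
#' @param sparse return the dosage matrix as a sparse [Matrix::Matrix]
#'   (default TRUE when `n_samples * n_variants >= 2.5e5`).
#' @return A [gene_variant_set()].
#' @export
simulate_genotypes <- function(cfg, gene_id = "gene1", seed = cfg$seed,
                               sparse = cfg$n_samples * cfg$n_variants >= 2.5e5) {
  stopifnot(inherits(cfg, "rv_sim_config"))
  n <- cfg$n_samples
  m <- cfg$n_variants
  withr::with_seed(derive_seed(seed, "genotypes"), {
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    maf <- numeric(m); keep <- logical(m)
    for (j in seq_len(m)) {
      for (try in 1:10) {
        f <- draw_maf(1, cfg$maf_spectrum)
        cnt <- drop(rmultinom(1, n, c((1 - f)^2, 2 * f * (1 - f), f^2)))
        if (cnt[2] + cnt[3] > 0) break
      }
      if (cnt[2] + cnt[3] == 0) next
      keep[j] <- TRUE
      maf[j] <- f
      carriers <- sample.int(n, cnt[2] + cnt[3])
      dose <- rep(c(1, 2), c(cnt[2], cnt[3]))
      ii <- c(ii, carriers); jj <- c(jj, rep(j, length(carriers))); xx <- c(xx, dose)
    }
    if (!any(keep)) abort("all simulated variants were monomorphic.",
                          class = "rvsat_no_variants")
    jmap <- cumsum(keep)
    sel <- keep[jj]
    G <- Matrix::sparseMatrix(i = ii[sel], j = jmap[jj[sel]], x = xx[sel],
                              dims = c(n, sum(keep)))
    anns <- sample(names(cfg$annotation_props), sum(keep), replace = TRUE,
                   prob = cfg$annotation_props)
    vids <- paste0("1:", which(keep) * 100, ":A:T")
    if (!sparse) G <- as.matrix(G)
    rownames(G) <- paste0("s", seq_len(n))
    colnames(G) <- vids
    gene_variant_set(gene_id, G, anns, variant_id = vids, flip = FALSE)
  })
}

#' Simulate a phenotype over a gene's genotypes
#'
#' Binary trait from `logit P(y = 1) = alpha0 + gamma * x1 + sum_causal
#' beta_j g_j`, with `alpha0` solved by root finding so the marginal
#' prevalence matches the target within 0.001. Causal variants are sampled
#' uniformly at rate `causal_prop` among qualifying variants (optionally
#' restricted by annotation and MAF ceiling); `null = TRUE` keeps the causal
#' draw (so the random stream is identical) but forces all effects to zero.
#'
#' @param gvs a [gene_variant_set()].
#' @param cfg an [sim_config()].
#' @param null simulate under the null of no genetic effect.
#' @param seed seed (default `cfg$seed`).
#' @return A list with `data` (tibble: `sample_id`, `y`, `x1`), `beta`
#'   (per-variant effects), `causal_idx`, `alpha0`, `achieved_prevalence`.
#' @export
simulate_phenotype <- function(gvs, cfg, null = TRUE, seed = cfg$seed) {
  stopifnot(inherits(cfg, "rv_sim_config"))
  n <- nrow(gvs$dosage)
  v <- gvs$variants
  withr::with_seed(derive_seed(seed, "phenotypes"), {
    qual <- rep(TRUE, nrow(v))
    if (!is.null(cfg$causal_annotations))
      qual <- qual & v$annotation %in% cfg$causal_annotations
    if (!is.null(cfg$causal_max_maf))
      qual <- qual & v$maf <= cfg$causal_max_maf
    n_causal <- round(sum(qual) * cfg$causal_prop)
    causal_idx <- if (n_causal > 0) sort(sample(which(qual), n_causal)) else integer(0)
    beta <- numeric(nrow(v))
    if (length(causal_idx) > 0) {
      mag <- switch(cfg$effect_model,
                    maf_log = cfg$effect_c * abs(log10(pmax(v$maf[causal_idx], 1e-8))),
                    constant = rep(cfg$effect_c, length(causal_idx)))
      sgn <- ifelse(runif(length(causal_idx)) < cfg$sign_mix, 1, -1)
      beta[causal_idx] <- mag * sgn
    }
    if (null) beta[] <- 0
    x1 <- rnorm(n)
    gbeta <- if (any(beta != 0))
      as.numeric(gvs$dosage %*% beta) else numeric(n)
    eta0 <- cfg$covariate_effect * x1 + gbeta
    fprev <- function(a) mean(plogis(a + eta0)) - cfg$prevalence
    if (fprev(-40) > 0 || fprev(15) < 0)
      abort("target prevalence unattainable with these effects.")
    alpha0 <- uniroot(fprev, c(-40, 15), tol = 1e-9)$root
    pr <- plogis(alpha0 + eta0)
    y <- rbinom(n, 1, pr)
    list(data = tibble(sample_id = gvs$sample_ids, y = y, x1 = x1),
         beta = beta, causal_idx = causal_idx, alpha0 = alpha0,
         achieved_prevalence = mean(pr))
  })
}

#' Simulate a block-diagonal family GRM with matching polygenic effects
#'
#' Utility for null-model recovery studies: samples are grouped into
#' families of the given size with within-family relatedness `r`, and a
#' polygenic vector `g ~ N(0, tau * Psi)` can be drawn from it.
#'
#' @param n samples; `family_size` members per family.
#' @param family_size family block size (default 4).
#' @param r within-family relatedness (default 0.5, full siblings).
#' @return A list with `psi` (dense matrix) and `chol` (its Cholesky factor).
#' @export
family_grm <- function(n, family_size = 4, r = 0.5) {
  block <- matrix(r, family_size, family_size)
  diag(block) <- 1
  nfam <- ceiling(n / family_size)
  psi <- matrix(0, n, n)
  for (f in seq_len(nfam)) {
    idx <- ((f - 1) * family_size + 1):min(f * family_size, n)
    psi[idx, idx] <- block[seq_along(idx), seq_along(idx)]
  }
  list(psi = psi, chol = chol(psi))
}
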