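# Type-I-error and power study harnesses. Each study is exactly reproducible
# from (config, seed): genotypes, phenotypes and any probes draw from named
# sub-streams of the top-level seed.

binom_ci <- function(k, n) {
  se <- sqrt(k / n * (1 - k / n) / n)
  c(lower = k / n - 1.96 * se, upper = k / n + 1.96 * se)
}

#' Empirical type-I-error study
#'
#' Draws a pool of synthetic genes once, then for each replicate simulates a
#' null binary phenotype, fits the null model and runs every gene through
#' each pipeline (a named vector of ultra-rare collapsing MAC thresholds;
#' threshold 0 disables collapsing). Reports empirical rejection rates with
#' binomial 95% CIs, genomic-control lambda, and Q-Q data per
#' (pipeline, test).
#'
#' @param cfg an [sim_config()]; `cfg$n_replicates` phenotype replicates.
#' @param pipelines named numeric vector of MAC collapsing thresholds
#'   (default `c(with_collapse = 10, without_collapse = 0)`).
#' @param masks list of [mask_spec()] cells to test (default: all three
#'   annotation classes at max MAF 0.01%).
#' @param n_genes genes in the pool (total tests = `n_genes * n_replicates`).
#' @param tests which tests to run.
#' @param alphas nominal levels for the empirical rates.
#' @param acc quadratic-form tail accuracy (the default trades a little of
#'   the single-test accuracy for throughput; individual tests use 1e-9).
#' @return An `rv_study_report` list: `rates`, `lambda`, `qq`, `pvals`,
#'   `config`.
#' @export
run_type1_study <- function(cfg,
                            pipelines = c(with_collapse = 10, without_collapse = 0),
                            masks = list(mask_spec(c("lof", "missense", "synonymous"),
                                                   1e-4)),
                            n_genes = 100,
                            tests = c("burden", "skat", "skato"),
                            alphas = c(0.05, 0.01),
                            acc = 1e-7) {
  stopifnot(inherits(cfg, "rv_sim_config"), length(pipelines) >= 1)
  genes <- lapply(seq_len(n_genes), function(g)
    simulate_genotypes(cfg, gene_id = paste0("g", g),
                       seed = derive_seed(cfg$seed, "genepool", g)))
  # masking and collapsing do not involve the phenotype, so the collapsed
  # sets are built once per (gene, pipeline, mask) and reused across all
  # phenotype replicates
  scheme <- weight_scheme()
  prepped <- lapply(genes, function(gvs) {
    lapply(seq_along(pipelines), function(pi_) {
      out <- list()
      for (mi in seq_along(masks)) {
        cell <- tryCatch({
          sub <- apply_mask(gvs, masks[[mi]])
          cs <- collapse_ultra_rare(sub, scheme = scheme,
                                    mac_threshold = pipelines[pi_])
          list(cs = cs, pre = ncol(sub$dosage), mask = masks[[mi]])
        }, rvsat_no_variants = function(e) NULL)
        if (!is.null(cell)) out[[length(out) + 1L]] <- cell
      }
      out
    })
  })
  rows <- vector("list", cfg$n_replicates * n_genes * length(pipelines))
  ri <- 0L
  failures <- 0L
  total <- 0L
  for (rep_i in seq_len(cfg$n_replicates)) {
    ph <- simulate_phenotype(genes[[1]], cfg, null = TRUE,
                             seed = derive_seed(cfg$seed, "replicate", rep_i))
    fit <- fit_null(ph$data, y ~ x1, trait_type = "binary")
    for (g in seq_len(n_genes)) {
      for (pi_ in seq_along(pipelines)) {
        total <- total + 1L
        res <- tryCatch({
          cells_g <- prepped[[g]][[pi_]]
          if (length(cells_g) == 0) tibble() else dplyr::bind_rows(
            lapply(cells_g, function(cell) {
              cs <- cell$cs
              sd_ <- score_decompose(fit, cs)
              single_spa <- ncol(cs$marker_matrix) == 1L &&
                fit$trait_type == "binary"
              bt <- if ("burden" %in% tests || single_spa) burden_test(sd_) else NULL
              st <- if ("skat" %in% tests) {
                if (single_spa) list(p = bt$p, q = sum(sd_$S^2),
                                     method = if (bt$spa_applied) "spa" else "exact")
                else skat_test(sd_, acc = acc)
              } else NULL
              ot <- if ("skato" %in% tests) {
                if (single_spa) list(p = bt$p) else skato_test(sd_, acc = acc)
              } else NULL
              tibble(gene = cs$gene_id,
                     mask_annotations = paste(cell$mask$annotations,
                                              collapse = ","),
                     max_maf = cell$mask$max_maf,
                     m_markers_pre = cell$pre,
                     m_markers_post = ncol(cs$marker_matrix),
                     collapsed = !is.null(cs$collapsed_index),
                     p_burden = if (is.null(bt)) NA_real_ else bt$p,
                     p_skat = if (is.null(st)) NA_real_ else st$p,
                     p_skato = if (is.null(ot)) NA_real_ else ot$p)
            }))
        }, error = function(e) NULL)
        if (is.null(res)) { failures <- failures + 1L; next }
        if (nrow(res) == 0) next
        res$pipeline <- names(pipelines)[pi_]
        res$replicate <- rep_i
        ri <- ri + 1L
        rows[[ri]] <- res
      }
    }
    if (failures > 0.01 * total && total > 200L)
      abort(paste0("more than 1% of replicates failed (", failures, "/",
                   total, ")."))
  }
  cells <- dplyr::bind_rows(rows[seq_len(ri)])
  pvals <- cells |>
    tidyr::pivot_longer(dplyr::all_of(paste0("p_", intersect(tests,
                          c("burden", "skat", "skato")))),
                        names_to = "test", values_to = "p",
                        names_prefix = "p_") |>
    dplyr::select("pipeline", "test", "replicate", "gene", "mask_annotations",
                  "max_maf", "p")
  rates <- pvals |>
    dplyr::group_by(.data$pipeline, .data$test) |>
    dplyr::reframe(alpha = alphas,
                   n_tests = length(.data$p),
                   empirical = vapply(alphas, function(a) mean(.data$p <= a),
                                      numeric(1))) |>
    dplyr::mutate(se = sqrt(.data$alpha * (1 - .data$alpha) / .data$n_tests),
                  ci_lower = .data$alpha - 1.96 * .data$se,
                  ci_upper = .data$alpha + 1.96 * .data$se,
                  within_ci = .data$empirical >= .data$ci_lower &
                    .data$empirical <= .data$ci_upper)
  lambda <- pvals |>
    dplyr::group_by(.data$pipeline, .data$test) |>
    dplyr::summarise(lambda_gc = lambda_gc(.data$p), .groups = "drop")
  qq <- pvals |>
    dplyr::group_by(.data$pipeline, .data$test) |>
    dplyr::reframe(qq_points(.data$p))
  structure(list(type = "type1", rates = rates, lambda = lambda, qq = qq,
                 pvals = pvals, config = cfg, n_genes = n_genes,
                 pipelines = pipelines),
            class = "rv_study_report")
}

#' Empirical power study
#'
#' For each scenario configuration, each replicate simulates a fresh gene and
#' a phenotype with causal effects, fits the null model, and runs each
#' pipeline over the mask grid. Per (scenario, pipeline, test) the report
#' holds the power of the Cauchy-combined gene-level p-value and of a single
#' reference cell (all annotations at the largest MAF cutoff), with binomial
#' standard errors and median chi-square statistics.
#'
#' @param cfgs named list of [sim_config()] scenarios.
#' @param pipelines named numeric vector of MAC collapsing thresholds.
#' @param masks mask grid (default the 3 x 3 grid).
#' @param alpha significance threshold for power (default 1e-3, the
#'   package's desk-scale stand-in for exome-wide 2.5e-6).
#' @param tests which tests to run.
#' @param single_cell reference cell for the single-mask comparison.
#' @param acc tail accuracy for throughput (see [run_type1_study()]).
#' @return An `rv_study_report` with `power` (one row per scenario x
#'   pipeline x test x measure) and `replicates` (per-replicate p-values).
#' @export
run_power_study <- function(cfgs,
                            pipelines = c(with_collapse = 10, without_collapse = 0),
                            masks = default_masks(),
                            alpha = 1e-3,
                            tests = c("burden", "skat", "skato"),
                            single_cell = mask_spec(c("lof", "missense",
                                                      "synonymous"), 0.01),
                            acc = 1e-7) {
  if (is.null(names(cfgs))) names(cfgs) <- paste0("scenario", seq_along(cfgs))
  reps <- list()
  for (sc in names(cfgs)) {
    cfg <- cfgs[[sc]]
    for (rep_i in seq_len(cfg$n_replicates)) {
      gvs <- simulate_genotypes(cfg, gene_id = paste0(sc, "_r", rep_i),
                                seed = derive_seed(cfg$seed, "powergene", rep_i))
      ph <- simulate_phenotype(gvs, cfg, null = FALSE,
                               seed = derive_seed(cfg$seed, "powerpheno", rep_i))
      fit <- fit_null(ph$data, y ~ x1, trait_type = "binary")
      for (pi_ in seq_along(pipelines)) {
        res <- run_gene(fit, gvs, masks = masks,
                        mac_threshold = pipelines[pi_], tests = tests, acc = acc)
        if (nrow(res) == 0) next
        for (tt in tests) {
          pcol <- res[[paste0("p_", tt)]]
          comb <- combine_gene(res |> dplyr::mutate(gene = gvs$gene_id), tt)
          single <- res |>
            dplyr::filter(.data$mask_annotations ==
                            paste(single_cell$annotations, collapse = ","),
                          .data$max_maf == single_cell$max_maf)
          reps[[length(reps) + 1L]] <- tibble(
            scenario = sc, pipeline = names(pipelines)[pi_], test = tt,
            replicate = rep_i,
            p_combined = comb$p_combined,
            p_single = if (nrow(single) == 1) single[[paste0("p_", tt)]]
                       else NA_real_)
        }
      }
    }
  }
  repl <- dplyr::bind_rows(reps)
  power <- repl |>
    tidyr::pivot_longer(c("p_combined", "p_single"), names_to = "measure",
                        values_to = "p", names_prefix = "p_") |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::group_by(.data$scenario, .data$pipeline, .data$test, .data$measure) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      power = mean(.data$p < alpha),
      se = sqrt(.data$power * (1 - .data$power) / .data$n_reps),
      median_chisq = median(qchisq(.data$p, df = 1, lower.tail = FALSE)),
      .groups = "drop")
  structure(list(type = "power", power = power, replicates = repl,
                 alpha = alpha, configs = cfgs, pipelines = pipelines),
            class = "rv_study_report")
}
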