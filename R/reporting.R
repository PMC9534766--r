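# Genomic-control and Q-Q summaries, plotting, and the end-to-end pipeline
# (null model -> set tests -> aggregation -> TSV/JSON outputs + manifest).

#' Genomic-control inflation factor
#'
#' `lambda = median(chi-square(1) quantile of 1 - p) / 0.4549364`; 1 for a
#' uniform p-value distribution, above 1 under inflation.
#'
#' @param pvals p-values in (0, 1].
#' @return Numeric lambda.
#' @examples
#' lambda_gc(runif(1000))
#' @export
lambda_gc <- function(pvals) {
  if (length(pvals) == 0) abort("`pvals` must be non-empty.")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    abort("p-values must lie in (0, 1].")
  median(qchisq(pvals, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Q-Q plot coordinates on the -log10 scale
#'
#' @param pvals p-values in (0, 1].
#' @return A tibble with `expected` (`-log10((i - 0.5) / n)`) and `observed`
#'   (sorted `-log10 p`), sorted ascending in `expected`.
#' @export
qq_points <- function(pvals) {
  if (length(pvals) == 0) abort("`pvals` must be non-empty.")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    abort("p-values must lie in (0, 1].")
  n <- length(pvals)
  obs <- sort(-log10(pvals))
  exp_ <- -log10((seq_len(n) - 0.5) / n)
  tibble(expected = sort(exp_), observed = obs)
}

#' Q-Q plot of p-values
#'
#' @param pvals numeric p-values, or a data frame with a p-value column.
#' @param p_col column name when `pvals` is a data frame.
#' @return A ggplot.
#' @export
plot_qq <- function(pvals, p_col = "p") {
  if (is.data.frame(pvals)) pvals <- pvals[[p_col]]
  qq <- qq_points(pvals)
  lam <- lambda_gc(pvals)
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  subtitle = sprintf("lambda[GC] = %.3f", lam)) +
    ggplot2::theme_minimal()
}

#' Q-Q panels for a study report
#' @param object an `rv_study_report`.
#' @param ... unused.
#' @method autoplot rv_study_report
#' @export
autoplot.rv_study_report <- function(object, ...) {
  qq <- object$qq
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$expected, y = .data$observed,
                                   colour = .data$test)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::facet_wrap(~pipeline) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' @export
print.rv_study_report <- function(x, ...) {
  cat("<rv_study_report>", x$type, "study\n")
  print(x$rates %||% x$power)
  if (!is.null(x$lambda)) print(x$lambda)
  invisible(x)
}

run_manifest <- function(config, seed, inputs = character()) {
  cfgfile <- tempfile()
  yaml::write_yaml(config, cfgfile)
  list(tool = "rvsat",
       version = as.character(utils::packageVersion("rvsat")),
       command = paste(commandArgs(), collapse = " "),
       config_hash = unname(tools::md5sum(cfgfile)),
       input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])),
       seed = seed,
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Run the end-to-end association pipeline
#'
#' Orchestrates Step 1 (null model), Step 2 (per-gene set tests over the
#' mask grid) and gene-level aggregation, writing a per-cell TSV, a
#' gene-level TSV, a Q-Q TSV and a JSON run manifest into `out_dir`.
#' Genes that fail are logged and skipped; more than 10% failures aborts.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   `vcf`, `group_file`, `pheno`, `pheno_col`, `covar_cols` (character
#'   vector, may be empty), `trait_type`, and optionally `offset_covariates`
#'   (logical), `sparse_grm` (3-column TSV id1/id2/value), `grm_cutoff`,
#'   `max_maf_cutoffs`, `annotation_masks` (list of character vectors),
#'   `mac_collapse_threshold`, `weights` (`"beta:1,25"`, `"none"`, or a
#'   file of per-variant weights), `combine` (test to aggregate), `seed`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `cells`, `genes`, `manifest` and the
#'   output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  groups <- parse_group_file(config$group_file)
  if (length(groups) == 0) abort("empty group file.", class = "rvsat_format_error")
  pheno <- read_pheno_tsv(config$pheno)
  covar <- config$covar_cols %||% character()
  fml <- stats::as.formula(paste(config$pheno_col, "~",
                                 if (length(covar)) paste(covar, collapse = "+")
                                 else "1"))
  trait <- config$trait_type %||% "binary"
  offset_mode <- isTRUE(config$offset_covariates)
  if (!is.null(config$sparse_grm)) {
    grm_df <- readr::read_tsv(config$sparse_grm, show_col_types = FALSE,
                              col_names = c("id1", "id2", "value"), skip = 0)
    ids <- pheno$sample_id
    i <- match(as.character(grm_df$id1), ids)
    j <- match(as.character(grm_df$id2), ids)
    ok <- !is.na(i) & !is.na(j)
    cutoff <- config$grm_cutoff %||% 0.05
    keep <- ok & (abs(grm_df$value) >= cutoff | grm_df$id1 == grm_df$id2)
    M <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = grm_df$value[keep],
                              dims = c(length(ids), length(ids)), symmetric = TRUE)
    fit <- fit_null_mixed(pheno, fml, grm = M, trait_type = trait,
                          offset_mode = offset_mode)
  } else {
    fit <- fit_null(pheno, fml, trait_type = trait, offset_mode = offset_mode)
  }
  max_mafs <- config$max_maf_cutoffs %||% c(0.01, 0.001, 0.0001)
  ann_sets <- config$annotation_masks %||%
    list("lof", c("lof", "missense"), c("lof", "missense", "synonymous"))
  masks <- default_masks(max_mafs = as.numeric(max_mafs),
                         annotation_sets = ann_sets)
  wspec <- config$weights %||% "beta:1,25"
  scheme <- if (identical(wspec, "none")) weight_scheme("none")
            else if (grepl("^beta:", wspec)) {
              ab <- as.numeric(strsplit(sub("^beta:", "", wspec), ",")[[1]])
              weight_scheme("beta_default", beta_a = ab[1], beta_b = ab[2])
            } else abort("unsupported weights spec (use 'beta:a,b' or 'none').")
  mac_thr <- config$mac_collapse_threshold %||% 10

  cells <- list()
  failures <- 0L
  for (g in names(groups)) {
    res <- tryCatch({
      gvs <- load_gene_dosages(config$vcf, pheno$sample_id,
                               groups[[g]]$variant_id, gene_id = g,
                               annotation = groups[[g]]$annotation)
      run_gene(fit, gvs, masks = masks, scheme = scheme,
               mac_threshold = mac_thr)
    }, rvsat_no_variants = function(e) tibble(),
       error = function(e) {
      inform(paste0("gene ", g, " failed: ", conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failures <- failures + 1L else cells[[g]] <- res
  }
  if (failures > 0.1 * length(groups))
    abort(paste0(failures, " of ", length(groups), " genes failed (> 10%)."))
  cell_tbl <- dplyr::bind_rows(cells)
  if (nrow(cell_tbl) == 0) abort("no testable cells in any gene.")
  gene_tbl <- aggregate_genes(cell_tbl, which = config$combine %||% "skato")
  qq <- qq_points(gene_tbl$p_combined)

  cell_path <- file.path(out_dir, "cells.tsv")
  gene_path <- file.path(out_dir, "genes.tsv")
  qq_path <- file.path(out_dir, "qq.tsv")
  readr::write_tsv(cell_tbl, cell_path)
  readr::write_tsv(dplyr::select(gene_tbl, -"cells"), gene_path)
  readr::write_tsv(qq, qq_path)
  manifest <- run_manifest(config, seed,
                           inputs = c(config$vcf, config$group_file, config$pheno))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cells = cell_tbl, genes = gene_tbl, manifest = manifest,
                 paths = c(cells = cell_path, genes = gene_path, qq = qq_path)))
}
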