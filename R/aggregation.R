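# Gene-level aggregation of per-cell p-values across the
# (annotation mask x max-MAF cutoff) grid: Cauchy combination, with a
# minimum-p Bonferroni fallback whenever any individual cell p equals 1
# (the Cauchy transform is undefined at unity).

#' Cauchy combination of p-values
#'
#' `T = mean(tan((0.5 - p) * pi))`; the combined p-value is the standard
#' Cauchy upper-tail probability of `T`. Robust to dependence among the
#' combined tests. For `p < 1e-15` the tangent term is computed as
#' `1 / (p * pi)` for numerical stability; p-values within `1e-15` of 1 are
#' clamped to `1 - 1e-15` (exact unity is a contract error here — route
#' through [combine_gene()], which applies the min-p fallback).
#'
#' @param pvals p-values strictly inside (0, 1).
#' @return The combined p-value in (0, 1).
#' @examples
#' cauchy_combine(c(0.5, 0.5, 0.5))  # 0.5
#' cauchy_combine(c(0.01, 0.5))      # ~0.02
#' @export
cauchy_combine <- function(pvals) {
  if (length(pvals) == 0) abort("`pvals` must be non-empty.")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals >= 1))
    abort("all p-values must lie strictly in (0, 1); use combine_gene() for the p = 1 fallback.",
          class = "rvsat_contract_error")
  pvals <- pmin(pvals, 1 - 1e-15)
  small <- pvals < 1e-15
  terms <- numeric(length(pvals))
  terms[!small] <- tanpi(0.5 - pvals[!small])
  terms[small] <- 1 / (pvals[small] * pi)
  tstat <- mean(terms)
  clamp_p(pcauchy(tstat, lower.tail = FALSE))
}

#' Combine a gene's per-cell results into one gene-level p-value
#'
#' Uses the Cauchy combination of the selected per-cell p-values unless any
#' cell has p exactly 1, in which case the minimum p-value with Bonferroni
#' correction (`min(min_p * n_cells, 1)`) is used instead. Cells that were
#' not tested (no qualifying variants) are simply absent and do not enter
#' the combination.
#'
#' @param cells tibble of per-cell results from [run_gene()] (one gene).
#' @param which which test's p-values to combine: `"skato"`, `"skat"` or
#'   `"burden"`.
#' @return A one-row tibble: `gene`, `p_combined`, `n_cells`,
#'   `fallback_minp`, `best_mask`, `best_max_maf`, plus a `cells`
#'   list-column with the input.
#' @export
combine_gene <- function(cells, which = c("skato", "skat", "burden")) {
  which <- match.arg(which)
  if (!is.data.frame(cells) || nrow(cells) == 0)
    abort("no tested cells for this gene.", class = "rvsat_no_variants")
  p <- cells[[paste0("p_", which)]]
  if (any(is.na(p))) abort(paste0("missing p_", which, " values in `cells`."))
  best <- which.min(p)
  if (any(p == 1)) {
    p_comb <- min(min(p) * length(p), 1)
    fallback <- TRUE
  } else {
    p_comb <- cauchy_combine(p)
    fallback <- FALSE
  }
  tibble(gene = cells$gene[1],
         p_combined = p_comb,
         n_cells = nrow(cells),
         fallback_minp = fallback,
         best_mask = cells$mask_annotations[best],
         best_max_maf = cells$max_maf[best],
         cells = list(cells))
}

#' Aggregate many genes' cell results
#'
#' @param cell_results tibble of per-cell results (multiple genes) as
#'   produced by binding [run_gene()] outputs.
#' @param which test to combine (see [combine_gene()]).
#' @param threshold exome-wide significance threshold for the `significant`
#'   flag (default 2.5e-6, strict `<`).
#' @return A tibble with one row per gene.
#' @export
aggregate_genes <- function(cell_results, which = c("skato", "skat", "burden"),
                            threshold = 2.5e-6) {
  which <- match.arg(which)
  out <- cell_results |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_map(~ combine_gene(.x |> dplyr::mutate(gene = .y$gene), which)) |>
    dplyr::bind_rows()
  out$significant <- significance_flag(out, threshold = threshold)
  out
}

#' Exome-wide significance flag
#'
#' TRUE iff the combined p-value is strictly below the threshold
#' (default 2.5e-6, the conventional exome-wide level for ~20,000 genes).
#'
#' @param gr a gene-result tibble with a `p_combined` column (or a single
#'   numeric p-value).
#' @param threshold significance threshold.
#' @return Logical vector.
#' @export
significance_flag <- function(gr, threshold = 2.5e-6) {
  p <- if (is.data.frame(gr)) gr$p_combined else gr
  p < threshold
}
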