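# Ultra-rare variant collapsing: variants with MAC <= threshold (default 10)
# within a testing set are merged into one marker before Burden/SKAT/SKAT-O.
# Three weighting schemes are supported: MAF-based Beta(1,25) weights computed
# on the collapsed matrix (default), user-supplied per-variant weights folded
# into the dosages before collapsing, and no weights.

#' Beta-density variant weight
#'
#' The default rare-variant up-weighting: the Beta(a, b) density evaluated at
#' the variant's minor allele frequency. With the default `a = 1`, `b = 25`
#' the weight is `25 * (1 - maf)^24`, strictly decreasing in MAF, so rarer
#' variants contribute more to the set statistics.
#'
#' @param maf minor allele frequency in `[0, 0.5]` (vectorised).
#' @param a,b Beta shape parameters (defaults 1 and 25).
#' @return Numeric vector of weights.
#' @examples
#' beta_weight(0)      # 25
#' beta_weight(0.01)   # ~19.64
#' @export
beta_weight <- function(maf, a = 1, b = 25) {
  if (any(!is.finite(maf)) || any(maf < 0) || any(maf > 0.5)) {
    abort("`maf` must lie in [0, 0.5].", class = "rvsat_domain_error")
  }
  dbeta(maf, shape1 = a, shape2 = b)
}

#' Weighting scheme for set-based tests
#'
#' @param kind `"beta_default"` (Beta(1,25) weights from per-marker MAF,
#'   computed after collapsing), `"user_weights"` (per-variant weights folded
#'   into the dosages before collapsing), or `"none"` (all weights one,
#'   collapsed like the user-weight scheme).
#' @param beta_a,beta_b Beta parameters for `"beta_default"`.
#' @param user_w non-negative per-variant weight vector; required (and only
#'   allowed) for `"user_weights"`.
#' @return An object of class `rv_weight_scheme`.
#' @export
weight_scheme <- function(kind = c("beta_default", "user_weights", "none"),
                          beta_a = 1, beta_b = 25, user_w = NULL) {
  kind <- match.arg(kind)
  if (kind == "user_weights") {
    if (is.null(user_w)) abort("`user_w` is required for kind = 'user_weights'.")
    if (any(user_w < 0)) abort("`user_w` must be non-negative.")
  } else if (!is.null(user_w)) {
    abort("`user_w` is only allowed for kind = 'user_weights'.")
  }
  structure(list(kind = kind, beta_a = beta_a, beta_b = beta_b,
                 user_w = user_w),
            class = "rv_weight_scheme")
}

#' Collapse ultra-rare variants within a testing set
#'
#' Variants whose minor allele count is at or below `mac_threshold` (inclusive;
#' default 10) are merged into a single collapsed marker; variants above the
#' threshold are kept as-is. Under the default Beta-weight scheme the collapsed
#' dosage of a sample is the maximum raw dosage among the ultra-rare variants
#' it carries, and all marker weights (collapsed marker included) are Beta
#' densities of the post-collapse marker MAFs. Under the user-weight scheme
#' each ultra-rare column is first multiplied by its weight and the collapsed
#' dosage is the maximum of the weighted dosages; surviving columns carry
#' their weights folded into the dosages, so the reported weight vector is
#' all ones and downstream tests must not re-weight. `"none"` is the
#' user-weight scheme with unit weights.
#'
#' MACs are recomputed on the matrix as supplied, i.e. on the masked sample
#' set, so collapsing is per testing set. On dosage data the MAC is the
#' (real-valued) sum of minor-allele dosages and the threshold comparison is
#' on that real value.
#'
#' @param gvs a [gene_variant_set()].
#' @param scheme a [weight_scheme()].
#' @param mac_threshold non-negative MAC threshold (default 10). A threshold
#'   of 0 collapses nothing.
#' @return An object of class `rv_collapsed_set`: a list with
#'   `marker_matrix` (N x K), `weights` (length K), `maf`, `mac`,
#'   `collapsed_index` (column index of the collapsed marker or `NULL`),
#'   `provenance` (variant ids merged into the collapsed marker),
#'   `marker_ids`, `mac_threshold`, `gene_id`.
#' @export
collapse_ultra_rare <- function(gvs, scheme = weight_scheme(), mac_threshold = 10) {
  stopifnot(inherits(gvs, "rv_gene_variant_set"), inherits(scheme, "rv_weight_scheme"))
  if (mac_threshold < 0) abort("`mac_threshold` must be >= 0.", class = "rvsat_domain_error")
  G <- gvs$dosage
  n <- nrow(G)
  mac <- as.numeric(Matrix::colSums(G))
  if (all(mac == 0)) abort("all variants are monomorphic; nothing to test.",
                           class = "rvsat_no_variants")
  if (!is.null(scheme$user_w) && length(scheme$user_w) != ncol(G)) {
    abort("`user_w` must have one weight per input variant.")
  }
  ur <- mac <= mac_threshold
  keep <- !ur
  ids <- gvs$variants$variant_id

  fold <- scheme$kind %in% c("user_weights", "none")
  w_in <- switch(scheme$kind,
                 beta_default = rep(1, ncol(G)),  # raw dosages collapse
                 user_weights = scheme$user_w,
                 none = rep(1, ncol(G)))

  keep_mat <- G[, keep, drop = FALSE]
  if (fold && any(keep)) {
    keep_mat <- keep_mat %*% Matrix::Diagonal(sum(keep), w_in[keep])
    if (!inherits(G, "Matrix")) keep_mat <- as.matrix(keep_mat)
  }

  if (any(ur)) {
    ur_mat <- G[, ur, drop = FALSE]
    if (fold) ur_mat <- col_scale(ur_mat, w_in[ur])
    collapsed <- row_max(ur_mat)
    marker <- cbind(as_dense(keep_mat), collapsed, deparse.level = 0)
    if (inherits(G, "Matrix") && ncol(keep_mat) > 0) {
      marker <- cbind(keep_mat, Matrix::Matrix(collapsed, ncol = 1, sparse = TRUE))
    }
    collapsed_index <- ncol(marker)
    provenance <- ids[ur]
    marker_ids <- c(ids[keep], paste0(gvs$gene_id, ":collapsed_mac", mac_threshold))
  } else {
    marker <- keep_mat
    collapsed_index <- NULL
    provenance <- character()
    marker_ids <- ids
  }

  out_mac <- as.numeric(Matrix::colSums(marker))
  out_maf <- pmin(out_mac / (2 * n), 0.5)
  weights <- if (scheme$kind == "beta_default") {
    beta_weight(out_maf, scheme$beta_a, scheme$beta_b)
  } else {
    rep(1, ncol(marker))
  }

  structure(list(marker_matrix = marker,
                 weights = weights,
                 maf = out_maf,
                 mac = out_mac,
                 collapsed_index = collapsed_index,
                 provenance = provenance,
                 marker_ids = marker_ids,
                 mac_threshold = mac_threshold,
                 scheme_kind = scheme$kind,
                 gene_id = gvs$gene_id,
                 sample_ids = gvs$sample_ids),
            class = "rv_collapsed_set")
}

#' @export
print.rv_collapsed_set <- function(x, ...) {
  cat("<rv_collapsed_set> gene", x$gene_id, "-", ncol(x$marker_matrix),
      "markers (", length(x$provenance), "ultra-rare collapsed, MAC <=",
      x$mac_threshold, ")\n")
  invisible(x)
}
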