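# Genotype and annotation IO: gene group files mapping genes to variants and
# functional annotations, per-gene dosage matrices from VCF, and
# (annotation, max-MAF) mask filtering.

ANNOTATION_TOKENS <- c("lof", "missense", "synonymous", "other")

#' Construct a per-gene variant set
#'
#' Container for one gene's dosage matrix together with per-variant MAF, MAC
#' and functional annotation. MAF and MAC are computed from the dosages in
#' minor-allele orientation: columns whose alternate-allele frequency exceeds
#' 0.5 are flipped to `2 - dosage` when `flip = TRUE`, so `maf <= 0.5` always
#' holds. On dosage data the MAC is the real-valued sum of minor-allele
#' dosages.
#'
#' @param gene_id gene identifier.
#' @param dosage N x M numeric matrix (base matrix or sparse
#'   [Matrix::Matrix]) of minor-allele dosages in `[0, 2]`; column names are
#'   variant ids `chr:pos:ref:alt`, row names sample ids.
#' @param annotation character vector (length M) with values among
#'   `lof`, `missense`, `synonymous`, `other`.
#' @param variant_id,chrom,pos optional explicit variant metadata; by default
#'   parsed from the dosage column names.
#' @param flip flip columns with allele frequency above 0.5 into minor-allele
#'   orientation (default TRUE, with a message per flipped variant).
#' @return An object of class `rv_gene_variant_set` with elements `gene_id`,
#'   `dosage`, `sample_ids` and a `variants` tibble
#'   (`variant_id`, `chrom`, `pos`, `annotation`, `maf`, `mac`).
#' @export
gene_variant_set <- function(gene_id, dosage, annotation,
                             variant_id = colnames(dosage),
                             chrom = NULL, pos = NULL, flip = TRUE) {
  if (is.null(dim(dosage)) || ncol(dosage) < 1L)
    abort("`dosage` must be a matrix with at least one column.",
          class = "rvsat_no_variants")
  m <- ncol(dosage)
  if (length(annotation) != m)
    abort("`annotation` must have one entry per variant.")
  bad <- setdiff(unique(annotation), ANNOTATION_TOKENS)
  if (length(bad) > 0)
    abort(paste0("unknown annotation token(s): ", paste(bad, collapse = ", "),
                 "; allowed: ", paste(ANNOTATION_TOKENS, collapse = ", ")),
          class = "rvsat_format_error")
  if (is.null(variant_id)) variant_id <- paste0("v", seq_len(m))
  if (anyDuplicated(variant_id))
    abort(paste0("duplicate variant ids in gene ", gene_id),
          class = "rvsat_format_error")
  parts <- strsplit(variant_id, ":", fixed = TRUE)
  if (is.null(chrom)) chrom <- vapply(parts, function(p) p[1], character(1))
  if (is.null(pos)) {
    pos <- suppressWarnings(vapply(parts, function(p) as.integer(p[2]), integer(1)))
  }
  n <- nrow(dosage)
  af <- as.numeric(Matrix::colSums(dosage)) / (2 * n)
  if (flip && any(af > 0.5)) {
    for (j in which(af > 0.5)) {
      inform(paste0("flipping variant ", variant_id[j],
                    " to minor-allele orientation (AF = ", signif(af[j], 4), ")"))
      dosage[, j] <- 2 - dosage[, j]
    }
  }
  mac <- as.numeric(Matrix::colSums(dosage))
  maf <- mac / (2 * n)
  structure(list(
    gene_id = gene_id,
    dosage = dosage,
    sample_ids = rownames(dosage) %||% paste0("s", seq_len(n)),
    variants = tibble(variant_id = variant_id, chrom = chrom, pos = pos,
                      annotation = annotation, maf = maf, mac = mac)
  ), class = "rv_gene_variant_set")
}

#' @export
print.rv_gene_variant_set <- function(x, ...) {
  cat("<rv_gene_variant_set>", x$gene_id, "-", nrow(x$dosage), "samples x",
      ncol(x$dosage), "variants\n")
  print(x$variants, n = 5)
  invisible(x)
}

#' Parse a gene group file
#'
#' The group file is plain text with two whitespace-delimited lines per gene:
#' `<gene> var <id1> <id2> ...` and `<gene> anno <a1> <a2> ...`, where
#' annotation tokens are `lof`, `missense`, `synonymous`, `other`.
#'
#' @param path path to the group file.
#' @return A named list (one element per gene, input order preserved) of
#'   tibbles with columns `variant_id` and `annotation`.
#' @export
parse_group_file <- function(path) {
  if (!file.exists(path)) abort(paste0("group file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    abort("group file is empty.", class = "rvsat_format_error")
  toks <- strsplit(trimws(lines), "\\s+")
  genes <- vapply(toks, `[`, character(1), 1L)
  kinds <- vapply(toks, `[`, character(1), 2L)
  if (!all(kinds %in% c("var", "anno")))
    abort("each group-file line must be '<gene> var ...' or '<gene> anno ...'.",
          class = "rvsat_format_error")
  out <- list()
  for (g in unique(genes)) {
    gi <- which(genes == g)
    vline <- gi[kinds[gi] == "var"]
    aline <- gi[kinds[gi] == "anno"]
    if (length(vline) != 1L || length(aline) != 1L)
      abort(paste0("gene ", g, " must have exactly one 'var' and one 'anno' line."),
            class = "rvsat_format_error")
    vids <- toks[[vline]][-(1:2)]
    annos <- toks[[aline]][-(1:2)]
    if (length(vids) != length(annos))
      abort(paste0("gene ", g, ": var line has ", length(vids),
                   " entries but anno line has ", length(annos), "."),
            class = "rvsat_format_error")
    if (length(vids) == 0) next
    if (anyDuplicated(vids))
      abort(paste0("gene ", g, ": duplicate variant id on var line."),
            class = "rvsat_format_error")
    bad <- setdiff(unique(annos), ANNOTATION_TOKENS)
    if (length(bad) > 0)
      abort(paste0("gene ", g, ": unknown annotation token(s) ",
                   paste(bad, collapse = ", "), "; allowed: ",
                   paste(ANNOTATION_TOKENS, collapse = ", ")),
            class = "rvsat_format_error")
    out[[g]] <- tibble(variant_id = vids, annotation = annos)
  }
  out
}

#' Load per-gene dosages from a VCF file
#'
#' Reads hard calls (GT) or dosages (DS, preferred when present) for the
#' requested variants, orients each column to the minor allele (flipping
#' `2 - dosage` when the alternate-allele frequency exceeds 0.5), and
#' mean-imputes missing genotypes to `2 * MAF` computed on the non-missing
#' samples. Multi-allelic records must be pre-split; they are rejected.
#'
#' @param vcf_path path to a VCF 4.x file (plain or bgzipped).
#' @param sample_ids ordered sample ids expected in the VCF; an error lists
#'   any that are missing.
#' @param variant_ids variant keys `chr:pos:ref:alt` to extract; absent
#'   variants are dropped with a warning.
#' @param gene_id gene id for the returned set.
#' @param annotation annotations aligned to `variant_ids` (defaults to
#'   `"other"`; typically joined from [parse_group_file()]).
#' @return A [gene_variant_set()].
#' @export
load_gene_dosages <- function(vcf_path, sample_ids, variant_ids,
                              gene_id = "gene",
                              annotation = rep("other", length(variant_ids))) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (nrow(vcf@gt) == 0) abort("VCF contains no genotype data.")
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    abort("multi-allelic records found; split them (one ALT per record) first.",
          class = "rvsat_format_error")
  keys <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"], sep = ":")
  vcf_samples <- colnames(vcf@gt)[-1]
  missing_samples <- setdiff(sample_ids, vcf_samples)
  if (length(missing_samples) > 0)
    abort(paste0("samples absent from VCF: ",
                 paste(missing_samples, collapse = ", ")))
  idx <- match(variant_ids, keys)
  absent <- is.na(idx)
  if (all(absent))
    abort("none of the requested variants found in the VCF.",
          class = "rvsat_no_variants")
  if (any(absent))
    warn(paste0("dropping ", sum(absent), " variant(s) absent from VCF: ",
                paste(variant_ids[absent], collapse = ", ")))
  idx <- idx[!absent]
  ann <- annotation[!absent]
  ids <- variant_ids[!absent]

  has_ds <- all(grepl("DS", vcf@gt[idx, "FORMAT"]))
  if (has_ds) {
    dm <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dm <- apply(gt, 2, function(col) {
      a1 <- substr(col, 1, 1); a2 <- substr(col, 3, 3)
      out <- suppressWarnings(as.numeric(a1) + as.numeric(a2))
      out
    })
    if (is.null(dim(dm))) dm <- matrix(dm, nrow = nrow(vcf@gt), dimnames = dimnames(gt))
  }
  dm <- t(dm[idx, sample_ids, drop = FALSE])
  colnames(dm) <- ids
  # impute missing to 2 * MAF (non-missing allele frequency), after flipping
  af <- colMeans(dm, na.rm = TRUE) / 2
  for (j in which(af > 0.5)) {
    inform(paste0("flipping variant ", ids[j],
                  " to minor-allele orientation (AF = ", signif(af[j], 4), ")"))
    dm[, j] <- 2 - dm[, j]
  }
  for (j in seq_len(ncol(dm))) {
    nas <- is.na(dm[, j])
    if (any(nas)) dm[nas, j] <- 2 * mean(dm[!nas, j]) / 2
  }
  gene_variant_set(gene_id, dm, ann, variant_id = ids, flip = FALSE)
}

#' Define an (annotations, max-MAF) testing mask
#'
#' @param annotations non-empty subset of `lof`, `missense`, `synonymous`.
#' @param max_maf maximum minor-allele frequency retained, in `(0, 0.5]`.
#' @return An object of class `rv_mask_spec`.
#' @export
mask_spec <- function(annotations, max_maf) {
  annotations <- as.character(annotations)
  if (length(annotations) == 0) abort("`annotations` must be non-empty.")
  bad <- setdiff(annotations, c("lof", "missense", "synonymous"))
  if (length(bad) > 0)
    abort(paste0("invalid mask annotation(s): ", paste(bad, collapse = ", ")))
  if (max_maf <= 0 || max_maf > 0.5)
    abort("`max_maf` must lie in (0, 0.5].", class = "rvsat_domain_error")
  structure(list(annotations = annotations, max_maf = max_maf),
            class = "rv_mask_spec")
}

#' The default 3 x 3 testing grid
#'
#' Three nested annotation masks (LoF only; LoF+missense;
#' LoF+missense+synonymous) crossed with three maximum MAF cutoffs
#' (1%, 0.1%, 0.01%).
#'
#' @param max_mafs MAF cutoffs (default `c(0.01, 0.001, 0.0001)`).
#' @param annotation_sets list of annotation subsets.
#' @return A list of [mask_spec()] objects.
#' @export
default_masks <- function(max_mafs = c(0.01, 0.001, 0.0001),
                          annotation_sets = list(
                            "lof",
                            c("lof", "missense"),
                            c("lof", "missense", "synonymous"))) {
  out <- list()
  for (ann in annotation_sets) for (mm in max_mafs) {
    out[[length(out) + 1L]] <- mask_spec(ann, mm)
  }
  out
}

#' Apply a testing mask to a gene variant set
#'
#' Retains exactly the variants whose annotation is in `mask$annotations`,
#' whose MAF is at most `mask$max_maf`, and which are polymorphic
#' (`mac > 0`); column order is preserved. An empty result signals a
#' condition of class `rvsat_no_variants` so callers can record the cell as
#' not tested.
#'
#' @param gvs a [gene_variant_set()].
#' @param mask a [mask_spec()].
#' @return A filtered [gene_variant_set()].
#' @export
apply_mask <- function(gvs, mask) {
  stopifnot(inherits(gvs, "rv_gene_variant_set"), inherits(mask, "rv_mask_spec"))
  v <- gvs$variants
  keep <- v$annotation %in% mask$annotations & v$maf <= mask$max_maf & v$mac > 0
  if (!any(keep))
    abort(paste0("no qualifying variants for gene ", gvs$gene_id,
                 " under mask (", paste(mask$annotations, collapse = ","),
                 "; max_maf ", mask$max_maf, ")"),
          class = "rvsat_no_variants")
  out <- gvs
  out$dosage <- gvs$dosage[, keep, drop = FALSE]
  out$variants <- tibble::new_tibble(lapply(unclass(v), `[`, keep),
                                     nrow = sum(keep))
  out
}

#' Write a gene variant set as plain-text VCF plus group file
#'
#' Emits a minimal VCF 4.2 (hard calls rounded from dosages when
#' `dosage_field = FALSE`, otherwise GT:DS) and the matching two-line group
#' file record, so simulated fixtures can round-trip through
#' [load_gene_dosages()] and [parse_group_file()].
#'
#' @param gvs a [gene_variant_set()].
#' @param vcf_path,group_path output paths.
#' @param dosage_field also emit a DS field (default TRUE).
#' @return Invisibly, `vcf_path`.
#' @export
write_gene_vcf <- function(gvs, vcf_path, group_path = NULL, dosage_field = TRUE) {
  G <- as_dense(gvs$dosage)
  v <- gvs$variants
  n <- nrow(G)
  samples <- gvs$sample_ids
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           if (dosage_field)
             "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- character(ncol(G))
  for (j in seq_len(ncol(G))) {
    parts <- strsplit(v$variant_id[j], ":", fixed = TRUE)[[1]]
    ref <- if (length(parts) >= 3) parts[3] else "A"
    alt <- if (length(parts) >= 4) parts[4] else "T"
    hard <- pmin(pmax(round(G[, j]), 0), 2)
    gt <- c("0/0", "0/1", "1/1")[hard + 1L]
    field <- if (dosage_field) paste0(gt, ":", format(G[, j], trim = TRUE)) else gt
    rows[j] <- paste(c(v$chrom[j], v$pos[j], v$variant_id[j], ref, alt, ".",
                       "PASS", ".", if (dosage_field) "GT:DS" else "GT", field),
                     collapse = "\t")
  }
  writeLines(c(hdr, rows), vcf_path)
  if (!is.null(group_path)) {
    writeLines(c(paste(c(gvs$gene_id, "var", v$variant_id), collapse = " "),
                 paste(c(gvs$gene_id, "anno", v$annotation), collapse = " ")),
               group_path)
  }
  invisible(vcf_path)
}

#' Read a phenotype/covariate table
#'
#' Tab-separated with a header row; must contain a `sample_id` column.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_pheno_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(df))
    abort("phenotype table must contain a `sample_id` column.",
          class = "rvsat_format_error")
  df$sample_id <- as.character(df$sample_id)
  df
}
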