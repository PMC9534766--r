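test_that("group files parse per gene with ordered variants and annotations", {
  f <- withr::local_tempfile(lines = c(
    "geneA var 1:100:A:T 1:200:G:C 1:300:T:A",
    "geneA anno lof missense synonymous",
    "geneB var 2:50:C:G",
    "geneB anno lof"))
  gm <- parse_group_file(f)
  expect_length(gm, 2L)
  expect_equal(gm$geneA$variant_id, c("1:100:A:T", "1:200:G:C", "1:300:T:A"))
  expect_equal(gm$geneA$annotation, c("lof", "missense", "synonymous"))
  expect_equal(nrow(gm$geneB), 1L)
})

test_that("malformed group files are rejected with informative errors", {
  f1 <- withr::local_tempfile(lines = c(
    "geneA var 1:100:A:T 1:100:A:T", "geneA anno lof lof"))
  expect_error(parse_group_file(f1), "duplicate", class = "rvsat_format_error")
  f2 <- withr::local_tempfile(lines = c(
    "geneA var 1:100:A:T 1:200:G:C", "geneA anno lof"))
  expect_error(parse_group_file(f2), "geneA", class = "rvsat_format_error")
  f3 <- withr::local_tempfile(lines = c(
    "geneA var 1:100:A:T", "geneA anno damaging"))
  expect_error(parse_group_file(f3), "lof", class = "rvsat_format_error")
})

test_that("VCF loading counts, flips and imputes dosages", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("s", 1:4)), collapse = "\t"),
    paste(c("1", "100", ".", "A", "T", ".", "PASS", ".", "GT",
            "0/1", "0/0", "0/0", "0/0"), collapse = "\t"),
    paste(c("1", "200", ".", "G", "C", ".", "PASS", ".", "GT",
            "1/1", "1/1", "1/1", "0/1"), collapse = "\t"),
    paste(c("1", "300", ".", "T", "A", ".", "PASS", ".", "GT",
            "0/1", "0/1", "./.", "0/0"), collapse = "\t")), vcf)
  gvs <- suppressMessages(load_gene_dosages(
    vcf, paste0("s", 1:4), c("1:100:A:T", "1:200:G:C", "1:300:T:A"),
    annotation = c("lof", "missense", "lof")))
  v <- gvs$variants
  # singleton: 1 ALT allele over 4 samples
  expect_equal(v$maf[1], 0.125)
  expect_equal(v$mac[1], 1)
  # ALT frequency 7/8 -> flipped to minor orientation
  expect_equal(v$maf[2], 0.125)
  expect_equal(as.numeric(gvs$dosage[, 2]), c(0, 0, 0, 1))
  # missing genotype imputed to mean dosage 2*MAF of non-missing
  expect_equal(as.numeric(gvs$dosage[3, 3]), 2 * mean(c(1, 1, 0) / 2))
})

test_that("VCF loading reports absent variants and missing samples", {
  gvs0 <- tiny_gvs()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_gene_vcf(gvs0, vcf)
  expect_warning(
    suppressMessages(load_gene_dosages(vcf, paste0("s", 1:12),
                      c("1:10:A:T", "9:9:G:C"))), "absent")
  expect_error(load_gene_dosages(vcf, c(paste0("s", 1:12), "ghost"),
                                 "1:10:A:T"), "ghost")
  expect_error(load_gene_dosages(vcf, paste0("s", 1:12), "9:9:G:C"),
               class = "rvsat_no_variants")
})

test_that("round trip through VCF + group file preserves the variant set", {
  withr::local_seed(5)
  G <- random_small_G(20, 6, p = 0.25)
  gvs <- gene_variant_set("rt", G, sample(c("lof", "missense", "synonymous"),
                                          6, replace = TRUE))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  grp <- withr::local_tempfile()
  write_gene_vcf(gvs, vcf, grp)
  gm <- parse_group_file(grp)
  back <- suppressMessages(load_gene_dosages(
    vcf, gvs$sample_ids, gm$rt$variant_id, gene_id = "rt",
    annotation = gm$rt$annotation))
  expect_equal(unname(as.matrix(back$dosage)), unname(as.matrix(gvs$dosage)))
  expect_equal(back$variants$maf, gvs$variants$maf)
  expect_equal(back$variants$mac, gvs$variants$mac)
  expect_equal(back$variants$annotation, gvs$variants$annotation)
})

test_that("masks filter by annotation, MAF and polymorphism; idempotent", {
  n <- 20
  G <- cbind(rbinom(n, 2, 0.3), c(1, rep(0, n - 1)), rep(0, n),
             c(1, 1, rep(0, n - 2)))
  colnames(G) <- paste0("1:", 1:4, ":A:T")
  rownames(G) <- paste0("s", 1:n)
  gvs <- gene_variant_set("g", G, c("lof", "missense", "lof", "lof"))
  m <- mask_spec("lof", max_maf = 0.06)
  sub <- apply_mask(gvs, m)
  # variant 1 too common, variant 2 wrong annotation, variant 3 monomorphic
  expect_equal(sub$variants$variant_id, "1:4:A:T")
  expect_equal(apply_mask(sub, m)$variants, sub$variants)  # idempotent
  # mask covering everything polymorphic is the identity on those columns
  all_m <- mask_spec(c("lof", "missense", "synonymous"), 0.5)
  expect_equal(ncol(apply_mask(gvs, all_m)$dosage), 3L)
  # no qualifying variants signals a typed condition, not p = 1
  expect_error(apply_mask(gvs, mask_spec("synonymous", 0.5)),
               class = "rvsat_no_variants")
})

test_that("annotation and MAF mask conditions commute", {
  withr::local_seed(9)
  G <- random_small_G(30, 10, 0.15)
  gvs <- gene_variant_set("g", G, sample(c("lof", "missense", "synonymous"),
                                         10, replace = TRUE))
  both <- tryCatch(apply_mask(gvs, mask_spec("lof", 0.1))$variants$variant_id,
                   rvsat_no_variants = function(e) character())
  ann_first <- tryCatch({
    a <- apply_mask(gvs, mask_spec("lof", 0.5))
    apply_mask(a, mask_spec(c("lof", "missense", "synonymous"), 0.1))$variants$variant_id
  }, rvsat_no_variants = function(e) character())
  expect_equal(both, ann_first)
})

test_that("minor-allele orientation caps MAF at 0.5", {
  withr::local_seed(3)
  G <- matrix(rbinom(40 * 5, 2, 0.8), 40, 5)
  colnames(G) <- paste0("1:", 1:5, ":A:T")
  gvs <- suppressMessages(gene_variant_set("g", G, rep("lof", 5)))
  expect_true(max(gvs$variants$maf) <= 0.5)
})
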