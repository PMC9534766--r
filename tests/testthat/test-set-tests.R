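test_that("score decomposition has the stated closed forms and bilinearity", {
  withr::local_seed(4)
  n <- 60
  # zero residuals -> zero scores
  X <- cbind(1, rnorm(n))
  yq <- drop(X %*% c(1, 2))
  dq <- data.frame(sample_id = paste0("s", 1:n), y = yq, x1 = X[, 2])
  fitq <- fit_null(dq, y ~ x1, trait_type = "quantitative")
  g <- matrix(rbinom(n, 2, 0.2), ncol = 1, dimnames = list(NULL, "1:5:A:T"))
  cs1 <- collapse_ultra_rare(gene_variant_set("g", g, "lof"),
                             weight_scheme("none"), 0)
  expect_equal(score_decompose(fitq, cs1)$S, 0, tolerance = 1e-10)

  # single marker, intercept-only binary: Phi = mu(1-mu) * sum (g - gbar)^2
  y <- rbinom(n, 1, 0.3)
  fitb <- tiny_binary_fit(y)
  sd1 <- score_decompose(fitb, cs1)
  mu <- fitb$mu_hat[1]
  expect_equal(drop(sd1$Phi), mu * (1 - mu) * sum((g - mean(g))^2),
               tolerance = 1e-10, ignore_attr = TRUE)

  # doubling all weights doubles S and quadruples Phi
  G3 <- random_small_G(n, 3, 0.2)
  gvs3 <- gene_variant_set("g", G3, rep("lof", 3))
  csA <- collapse_ultra_rare(gvs3, weight_scheme("user_weights",
                                                 user_w = c(1, 2, 0.5)), 0)
  csB <- collapse_ultra_rare(gvs3, weight_scheme("user_weights",
                                                 user_w = 2 * c(1, 2, 0.5)), 0)
  sdA <- score_decompose(fitb, csA)
  sdB <- score_decompose(fitb, csB)
  expect_equal(sdB$S, 2 * sdA$S, tolerance = 1e-12)
  expect_equal(sdB$Phi, 4 * sdA$Phi, tolerance = 1e-12)
})

test_that("burden test handles degenerate and single-marker cases", {
  withr::local_seed(5)
  n <- 40
  y <- rbinom(n, 1, 0.4)
  fit <- tiny_binary_fit(y)
  # constant genotype: projected burden has zero variance -> p = 1
  g0 <- matrix(2, n, 1, dimnames = list(NULL, "1:5:A:T"))
  cs0 <- collapse_ultra_rare(gene_variant_set("g", g0, "lof", flip = FALSE),
                             weight_scheme("none"), 0)
  expect_warning(b0 <- burden_test(score_decompose(fit, cs0)), "constant")
  expect_equal(b0$p, 1)
  # K = 1: burden equals the single-variant score test (normal/chi-square)
  g1 <- matrix(rbinom(n, 2, 0.3), ncol = 1, dimnames = list(NULL, "1:6:A:T"))
  cs1 <- collapse_ultra_rare(gene_variant_set("g", g1, "lof"),
                             weight_scheme("none"), 0)
  sd1 <- score_decompose(fit, cs1)
  b1 <- burden_test(sd1)
  if (!b1$spa_applied) {
    expect_equal(b1$p, pchisq(sum(sd1$S)^2 / sum(sd1$Phi), 1,
                              lower.tail = FALSE), tolerance = 1e-12)
  }
  expect_equal(b1$p, skat_test(sd1)$p, tolerance = 1e-10)
})

test_that("saddlepoint tail matches exact enumeration on a balanced fixture", {
  gvs <- tiny_gvs()
  y <- c(1, 1, 1, 0, 0, 0, 1, 1, 1, 0, 0, 0)
  fit <- tiny_binary_fit(y)
  cs <- collapse_ultra_rare(gvs, weight_scheme("user_weights",
                                               user_w = c(1.3, 0.9, 0.55)), 0)
  sd1 <- score_decompose(fit, cs)
  en <- enumerate_scores(projected_genotypes(sd1), fit$mu_hat)
  gb <- rowSums(projected_genotypes(sd1))
  # probe tail points of the exact score distribution
  for (sq in quantile(rowSums(en$Svec), c(0.975, 0.99))) {
    sp <- spa_pvalue(sq, gb, fit$mu_hat)
    pe <- enum_burden_p(en, sq, midp = TRUE)
    expect_lt(abs(log(sp$p / pe)), log(1.2))
  }
  # s = 0 -> p = 1; symmetry under score negation at mu = 0.5
  expect_equal(spa_pvalue(0, gb, fit$mu_hat)$p, 1)
  s1 <- spa_pvalue(3.1, gb, fit$mu_hat)$p
  s2 <- spa_pvalue(-3.1, -gb, fit$mu_hat)$p
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("SPA and normal approximations agree under a balanced design", {
  withr::local_seed(6)
  n <- 200
  y <- rep(c(0, 1), n / 2)
  fit <- tiny_binary_fit(y)
  g <- matrix(rbinom(n, 2, 0.25), ncol = 1, dimnames = list(NULL, "1:5:A:T"))
  cs <- collapse_ultra_rare(gene_variant_set("g", g, "lof"),
                            weight_scheme("none"), 0)
  sd1 <- score_decompose(fit, cs)
  gb <- rowSums(projected_genotypes(sd1))
  v <- sum(sd1$Phi)
  s <- 2.3 * sqrt(v)   # moderate standardized score
  sp <- spa_pvalue(s, gb, fit$mu_hat, var_s = v)
  expect_true(sp$spa_applied)
  expect_equal(sp$p, 2 * pnorm(-2.3), tolerance = 0.1)
})

test_that("SKAT reduces to the chi-square tail at K = 1 and handles Q = 0", {
  withr::local_seed(7)
  n <- 80
  d <- data.frame(sample_id = 1:n, y = rnorm(n))
  fit <- fit_null(d, y ~ 1, trait_type = "quantitative")
  g <- matrix(rbinom(n, 2, 0.2), ncol = 1, dimnames = list(NULL, "1:5:A:T"))
  cs <- collapse_ultra_rare(gene_variant_set("g", g, "lof"),
                            weight_scheme("none"), 0)
  sd1 <- score_decompose(fit, cs)
  st <- skat_test(sd1)
  expect_equal(st$p, pchisq(sum(sd1$S^2) / drop(sd1$Phi), df = 1,
                            lower.tail = FALSE), tolerance = 1e-12)
  sd0 <- sd1; sd0$S <- 0 * sd1$S
  expect_equal(skat_test(sd0)$p, 1)
})

test_that("SKAT agrees with a parametric bootstrap on a balanced fixture", {
  gvs <- tiny_gvs()
  y <- c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0)
  fit <- tiny_binary_fit(y)
  cs <- collapse_ultra_rare(gvs, weight_scheme("user_weights",
                                               user_w = c(1.3, 0.9, 0.55)), 0)
  sd1 <- score_decompose(fit, cs)
  st <- skat_test(sd1)
  withr::local_seed(8)
  B <- 50000
  n <- 12
  Gp <- projected_genotypes(sd1)
  yb <- matrix(rbinom(B * n, 1, rep(fit$mu_hat, each = B)), B, n)
  Qb <- rowSums(((yb - matrix(fit$mu_hat, B, n, byrow = TRUE)) %*% Gp)^2)
  pb <- mean(Qb >= sum(sd1$S^2) - 1e-9)
  # asymptotic mixture vs finite-sample bootstrap: close, not identical
  expect_lt(abs(st$p - pb), 0.03)
})

test_that("SKAT-O reduces to its endpoints and brackets the minimum p", {
  withr::local_seed(9)
  n <- 100
  d <- data.frame(sample_id = 1:n, y = rnorm(n), x1 = rnorm(n))
  fit <- fit_null(d, y ~ x1, trait_type = "quantitative")
  G <- random_small_G(n, 5, 0.15)
  cs <- collapse_ultra_rare(gene_variant_set("g", G, rep("lof", 5)),
                            mac_threshold = 0)
  sd1 <- score_decompose(fit, cs)
  expect_equal(skato_test(sd1, rho_grid = 1)$p, burden_test(sd1)$p,
               tolerance = 1e-10)
  expect_equal(skato_test(sd1, rho_grid = 0)$p, skat_test(sd1)$p,
               tolerance = 1e-10)
  ot <- skato_test(sd1)
  expect_gte(ot$p, min(ot$p_each) - 1e-12)
  expect_lte(ot$p, min(min(ot$p_each) * length(ot$rho_grid), 1) + 1e-12)
  expect_error(skato_test(sd1, rho_grid = c(0, 2)), class = "rvsat_domain_error")
})

test_that("SKAT-O null distribution is calibrated at moderate levels", {
  withr::local_seed(10)
  n <- 300
  G <- random_small_G(n, 8, 0.1)
  gvs <- gene_variant_set("g", G, rep("lof", 8))
  cs <- collapse_ultra_rare(gvs, mac_threshold = 0)
  x1 <- rnorm(n)
  pv <- vapply(1:400, function(i) {
    d <- data.frame(sample_id = 1:n, y = rnorm(n), x1 = x1)
    fit <- fit_null(d, y ~ x1, trait_type = "quantitative")
    skato_test(score_decompose(fit, cs), acc = 1e-7)$p
  }, numeric(1))
  emp <- mean(pv <= 0.05)
  expect_lt(abs(emp - 0.05), 1.96 * sqrt(0.05 * 0.95 / 400) + 0.02)
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("run_gene fills exactly the qualifying grid cells", {
  withr::local_seed(11)
  n <- 400
  # engineer MAFs: a common lof variant (fails 0.1%/0.01% cutoffs) and rare ones
  G <- cbind(rbinom(n, 2, 0.05),                      # maf ~ 5e-2 > 1%
             c(rep(1, 4), rep(0, n - 4)),             # maf 5e-3 <= 1%
             c(1, rep(0, n - 1)))                     # maf 1.25e-3
  colnames(G) <- paste0("1:", 1:3, ":A:T")
  gvs <- gene_variant_set("g", G, c("lof", "lof", "missense"))
  fit <- tiny_binary_fit(rbinom(n, 1, 0.3))
  res <- run_gene(fit, gvs)
  # 1% cutoff qualifies variants 2-3; no variant passes 0.1% or 0.01%
  expect_true(all(res$max_maf == 0.01))
  expect_setequal(unique(res$mask_annotations),
                  c("lof", "lof,missense", "lof,missense,synonymous"))
  # identical variant content across masks gives identical p-values
  lofmis <- res[res$mask_annotations == "lof,missense", ]
  all3 <- res[res$mask_annotations == "lof,missense,synonymous", ]
  expect_equal(lofmis$p_skato, all3$p_skato)
  # fully populated grid has 9 cells
  G2 <- random_small_G(n, 12, 0.002)
  gvs2 <- gene_variant_set("g2", G2, rep(c("lof", "missense", "synonymous"), 4))
  res2 <- run_gene(fit, gvs2)
  expect_lte(nrow(res2), 9L)
  expect_equal(nrow(run_gene(fit, gvs2,
                             masks = list(mask_spec("lof", 0.5),
                                          mask_spec(c("lof", "missense"), 0.5),
                                          mask_spec(c("lof", "missense",
                                                      "synonymous"), 0.5)))),
               3L)
})

test_that("all p-values are invariant under a consistent sample permutation", {
  withr::local_seed(12)
  n <- 150
  G <- random_small_G(n, 6, 0.05)
  x1 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1.5 + 0.5 * x1))
  d <- data.frame(sample_id = paste0("s", 1:n), y = y, x1 = x1)
  gvs <- gene_variant_set("g", G, rep(c("lof", "missense"), 3))
  fit <- fit_null(d, y ~ x1, trait_type = "binary")
  res <- run_gene(fit, gvs, masks = list(mask_spec(c("lof", "missense"), 0.5)))
  perm <- sample(n)
  dp <- d[perm, ]
  Gp <- G[perm, ]
  gvsp <- gene_variant_set("g", Gp, rep(c("lof", "missense"), 3))
  fitp <- fit_null(dp, y ~ x1, trait_type = "binary")
  resp <- run_gene(fitp, gvsp, masks = list(mask_spec(c("lof", "missense"), 0.5)))
  expect_equal(resp$p_burden, res$p_burden, tolerance = 1e-12)
  expect_equal(resp$p_skat, res$p_skat, tolerance = 1e-12)
  expect_equal(resp$p_skato, res$p_skato, tolerance = 1e-12)
})
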