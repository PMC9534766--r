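test_that("intercept-only logistic fit recovers the case fraction", {
  d <- data.frame(y = rep(c(1, 0), c(10, 90)))
  fit <- fit_null(d, y ~ 1, trait_type = "binary")
  expect_equal(unique(round(fit$mu_hat, 10)), 0.10)
  expect_equal(sum(fit$resid), 0, tolerance = 1e-8)
})

test_that("quantitative intercept-only fit centres the phenotype", {
  withr::local_seed(1)
  d <- data.frame(y = rnorm(50, 3, 2))
  fit <- fit_null(d, y ~ 1, trait_type = "quantitative")
  expect_equal(fit$resid, d$y - mean(d$y))
  expect_equal(fit$dispersion, var(d$y), tolerance = 1e-12)
})

test_that("degenerate phenotypes are rejected", {
  expect_error(fit_null(data.frame(y = rep(1, 20)), y ~ 1, "binary"),
               "single class")
  expect_error(fit_null(data.frame(y = rep(c(0.5, 1), 10)), y ~ 1, "binary"),
               "0/1")
  d <- data.frame(y = rbinom(20, 1, 0.5), x = 1)
  expect_error(fit_null(d, y ~ x, "binary"), "rank")
})

test_that("binary IRLS matches glm to high precision", {
  withr::local_seed(2)
  d <- data.frame(y = rbinom(300, 1, 0.2), x1 = rnorm(300), x2 = rnorm(300))
  fit <- fit_null(d, y ~ x1 + x2, trait_type = "binary")
  ref <- glm(y ~ x1 + x2, family = binomial(), data = d,
             control = glm.control(epsilon = 1e-12))
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
})

test_that("offset mode freezes mu and changes only the Step 2 projection", {
  withr::local_seed(3)
  n <- 500
  d <- data.frame(sample_id = paste0("s", 1:n),
                  y = rbinom(n, 1, 0.3), x1 = rnorm(n), x2 = rnorm(n))
  full <- fit_null(d, y ~ x1 + x2, trait_type = "binary")
  off <- fit_null(d, y ~ x1 + x2, trait_type = "binary", offset_mode = TRUE)
  expect_equal(off$mu_hat, full$mu_hat)
  expect_equal(ncol(off$X_proj), 1L)
  # genotype orthogonal to the covariates: score test p agrees across modes
  g0 <- rbinom(n, 2, 0.1)
  g <- matrix(resid(lm(g0 ~ d$x1 + d$x2)) + mean(g0), ncol = 1,
              dimnames = list(paste0("s", 1:n), "1:5:A:T"))
  gvs <- gene_variant_set("g", g, "lof", flip = FALSE)
  cs <- collapse_ultra_rare(gvs, weight_scheme("none"), mac_threshold = 0)
  p_full <- burden_test(score_decompose(full, cs))$p
  p_off <- burden_test(score_decompose(off, cs))$p
  expect_equal(p_off, p_full, tolerance = 1e-6)
})

test_that("single-variant score test p-values are uniform under the null", {
  # the binary-trait calibration that Step 2 relies on (KS at the 1% level)
  withr::local_seed(11)
  n <- 1000
  g <- matrix(rbinom(n, 2, 0.2), ncol = 1,
              dimnames = list(paste0("s", 1:n), "1:5:A:T"))
  gvs <- gene_variant_set("g", g, "lof")
  pv <- vapply(1:10000, function(i) {
    d <- data.frame(sample_id = paste0("s", 1:n), y = rbinom(n, 1, 0.1))
    fit <- tiny_binary_fit(d$y)
    burden_test(score_decompose(
      fit, collapse_ultra_rare(gvs, weight_scheme("none"), 0)))$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("sparse GRM identifies duplicates, zeroes unrelated pairs, unit diagonal", {
  withr::local_seed(7)
  m <- 2000; n <- 150
  p <- runif(m, 0.1, 0.5)
  geno <- matrix(rbinom(m * n, 2, rep(p, n)), m, n)
  geno[, n] <- geno[, n - 1]            # duplicated individual
  grm <- suppressWarnings(build_sparse_grm(geno, cutoff = 0.05))
  A <- as.matrix(grm$mat)
  expect_equal(A[n, n - 1], 1, tolerance = 0.1)
  offd <- A[upper.tri(A)]
  offd <- offd[-length(offd)]           # all but the duplicate pair
  expect_true(mean(offd == 0) > 0.9)    # unrelated pairs zeroed by the cutoff
  expect_true(all(abs(diag(A) - 1) < 0.15))
  expect_true(isSymmetric(A))
})

test_that("identity-GRM mixed fit reduces to the plain GLM fit", {
  withr::local_seed(8)
  n <- 200
  d <- data.frame(sample_id = paste0("s", 1:n), y = rnorm(n), x1 = rnorm(n))
  plain <- fit_null(d, y ~ x1, trait_type = "quantitative")
  mixed <- fit_null_mixed(d, y ~ x1, grm = diag(n), trait_type = "quantitative")
  expect_equal(mixed$mu_hat, plain$mu_hat, tolerance = 1e-4)
  expect_equal(mixed$resid, plain$resid, tolerance = 1e-4)
})

test_that("REML recovers the variance component on family data", {
  withr::local_seed(9)
  n <- 600
  fam <- family_grm(n, family_size = 4, r = 0.5)
  taus0 <- numeric(15); taus1 <- numeric(15)
  for (i in 1:15) {
    x <- rnorm(n)
    e <- rnorm(n)
    g1 <- drop(t(fam$chol) %*% rnorm(n))   # polygenic term, tau = 1
    d0 <- data.frame(sample_id = 1:n, y = 0.5 * x + e, x1 = x)
    d1 <- data.frame(sample_id = 1:n, y = 0.5 * x + g1 + e, x1 = x)
    taus0[i] <- fit_null_mixed(d0, y ~ x1, fam$psi, "quantitative")$tau
    taus1[i] <- fit_null_mixed(d1, y ~ x1, fam$psi, "quantitative")$tau
  }
  expect_gt(mean(taus0 < 0.05), 0.7)
  expect_gt(mean(taus1), 0.5)
  expect_lt(mean(taus1), 1.5)
})

test_that("variance ratio is 1 without a random effect and stable with one", {
  withr::local_seed(10)
  n <- 300
  fam <- family_grm(n, 4, 0.5)
  x <- rnorm(n)
  d <- data.frame(sample_id = 1:n, y = 0.5 * x + rnorm(n), x1 = x)
  fit <- fit_null_mixed(d, y ~ x1, fam$psi, "quantitative")
  probes <- matrix(rbinom(n * 40, 2, 0.3), n, 40)
  # with the variance component pinned at zero the ratio is 1 by construction
  fit0 <- fit; fit0$tau <- 0
  expect_equal(estimate_variance_ratio(fit0, probes)$variance_ratio, 1,
               tolerance = 1e-10)
  fit <- estimate_variance_ratio(fit, probes)
  expect_equal(fit$variance_ratio, 1, tolerance = 0.1)
  # plain GLM fit keeps ratio 1 by definition
  plain <- fit_null(d, y ~ x1, trait_type = "quantitative")
  expect_identical(estimate_variance_ratio(plain, probes)$variance_ratio, 1)
  # with a real variance component the ratio departs from 1 reproducibly
  g1 <- drop(t(fam$chol) %*% rnorm(n)) * 1.5
  d2 <- data.frame(sample_id = 1:n, y = 0.5 * x + g1 + rnorm(n), x1 = x)
  fit2 <- fit_null_mixed(d2, y ~ x1, fam$psi, "quantitative")
  r2 <- estimate_variance_ratio(fit2, probes)$variance_ratio
  r2b <- estimate_variance_ratio(fit2, probes[, c(2:40, 1)])$variance_ratio
  expect_gt(abs(r2 - 1), 0.005)
  expect_equal(r2, r2b, tolerance = 0.05)
})

test_that("binary PQL runs on family data and enforces tau >= 0", {
  withr::local_seed(12)
  n <- 200
  fam <- family_grm(n, 4, 0.5)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * x))
  d <- data.frame(sample_id = 1:n, y = y, x1 = x)
  fit <- fit_null_mixed(d, y ~ x1, fam$psi, "binary")
  expect_gte(fit$tau, 0)
  expect_true(all(fit$mu_hat > 0 & fit$mu_hat < 1))
  expect_true(fit$converged)
})

test_that("tidy and glance summarise the fit", {
  d <- data.frame(y = rbinom(50, 1, 0.4), x1 = rnorm(50))
  fit <- fit_null(d, y ~ x1, trait_type = "binary")
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "x1"))
  gl <- glance(fit)
  expect_equal(gl$n, 50L)
  expect_equal(gl$variance_ratio, 1)
})
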