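# Step 1: phenotype null models with no genotype terms. Plain GLM (logistic
# IRLS for binary traits, least squares for quantitative), an optional
# covariates-as-offset mode, and a sparse-GRM mixed model with a
# variance-ratio calibration for the Step 2 score tests.

#' Fit the phenotype null model (no genotype terms)
#'
#' Binary traits are fitted by iteratively reweighted least squares to a
#' gradient norm below 1e-8; quantitative traits by ordinary least squares
#' with `sigma^2 = RSS / (N - p)`. With `offset_mode = TRUE` the fitted
#' covariate linear predictor is frozen as an offset and downstream score
#' tests project out only the intercept (the fitted means are identical to
#' the full mode; only the Step 2 projection changes).
#'
#' @param data data frame with one row per sample.
#' @param formula model formula, e.g. `y ~ x1 + x2`.
#' @param trait_type `"binary"` (y in \{0,1\}) or `"quantitative"`.
#' @param sample_col column holding sample ids (default `"sample_id"`; a
#'   missing column yields row-number ids).
#' @param offset_mode freeze covariates as an offset for Step 2.
#' @param inverse_normalize rank-based inverse-normal transform the phenotype
#'   (quantitative traits only; default FALSE).
#' @return An object of class `rv_null_model` with fitted means `mu_hat`,
#'   residuals, working weights, design matrix, `variance_ratio` (1 until
#'   calibrated), and metadata. Use [tidy()] / [glance()] for summaries.
#' @examples
#' d <- data.frame(y = rbinom(100, 1, 0.1), x = rnorm(100))
#' fit <- fit_null(d, y ~ x, trait_type = "binary")
#' glance(fit)
#' @export
fit_null <- function(data, formula, trait_type = c("binary", "quantitative"),
                     sample_col = "sample_id", offset_mode = FALSE,
                     inverse_normalize = FALSE) {
  trait_type <- match.arg(trait_type)
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, data = mf)
  n <- length(y)
  if (n < 10) abort("need at least 10 samples.")
  if (qr(X)$rank < ncol(X)) abort("covariate design is rank deficient.")
  sample_ids <- if (sample_col %in% names(data)) as.character(data[[sample_col]])
                else as.character(seq_len(n))

  if (trait_type == "binary") {
    if (!is_binary_vec(y)) abort("binary trait must be coded 0/1.")
    if (length(unique(y)) < 2L)
      abort("binary trait has a single class; cannot fit a null model.")
    beta <- rep(0, ncol(X))
    beta[1] <- qlogis(mean(y))
    for (it in seq_len(100L)) {
      eta <- drop(X %*% beta)
      if (any(abs(eta) > 30))
        abort(paste0("linear predictor diverging (separation?); consider",
                     " penalized regression or removing covariates."),
              class = "rvsat_separation_error")
      mu <- plogis(eta)
      w <- mu * (1 - mu)
      grad <- drop(crossprod(X, y - mu))
      if (max(abs(grad)) < 1e-8) break
      z <- eta + (y - mu) / w
      beta <- qr.coef(qr(X * sqrt(w)), z * sqrt(w))
    }
    if (max(abs(grad)) >= 1e-8)
      warn("IRLS did not reach gradient norm < 1e-8 in 100 iterations.")
    mu_hat <- plogis(drop(X %*% beta))
    resid <- y - mu_hat
    work_w <- mu_hat * (1 - mu_hat)
    dispersion <- 1
  } else {
    if (inverse_normalize) {
      y <- qnorm((rank(y) - 0.5) / n)
    }
    qx <- qr(X)
    beta <- qr.coef(qx, y)
    mu_hat <- drop(X %*% beta)
    resid <- y - mu_hat
    dispersion <- max(sum(resid^2) / (n - ncol(X)), .Machine$double.eps)
    work_w <- rep(1 / dispersion, n)
  }

  X_proj <- if (offset_mode) X[, 1, drop = FALSE] else X

  structure(list(
    trait_type = trait_type,
    coefficients = setNames(as.numeric(beta), colnames(X)),
    mu_hat = mu_hat,
    resid = as.numeric(resid),
    # score-scale residuals: (y - mu) / dispersion
    resid_score = as.numeric(resid) / dispersion,
    work_w = as.numeric(work_w),
    dispersion = dispersion,
    X = X,
    X_proj = X_proj,
    offset_mode = offset_mode,
    tau = NULL,
    grm = NULL,
    variance_ratio = 1,
    sample_ids = sample_ids,
    n = n,
    converged = TRUE
  ), class = "rv_null_model")
}

#' @export
print.rv_null_model <- function(x, ...) {
  cat("<rv_null_model>", x$trait_type, "trait, N =", x$n,
      if (!is.null(x$tau)) paste0(", tau = ", signif(x$tau, 4)),
      if (x$offset_mode) ", covariates-as-offset", "\n")
  invisible(x)
}

#' @rdname fit_null
#' @param x an `rv_null_model`.
#' @param ... unused.
#' @method tidy rv_null_model
#' @export
tidy.rv_null_model <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = as.numeric(x$coefficients))
}

#' @rdname fit_null
#' @method glance rv_null_model
#' @export
glance.rv_null_model <- function(x, ...) {
  tibble(trait_type = x$trait_type, n = x$n,
         n_covariates = ncol(x$X) - 1L,
         dispersion = x$dispersion,
         tau = x$tau %||% NA_real_,
         variance_ratio = x$variance_ratio,
         offset_mode = x$offset_mode,
         converged = x$converged)
}

#' Build a sparse genetic relationship matrix
#'
#' GRM entries are means over markers of standardized-genotype products;
#' off-diagonal entries below `cutoff` (default 0.05, retaining close
#' relatives only) are set to exactly zero and the matrix is stored sparse.
#'
#' @param genotypes M x N matrix of common-variant genotypes (markers in
#'   rows, samples in columns); at least 100 markers with MAF >= 1%.
#' @param cutoff relatedness cutoff (default 0.05).
#' @return An object of class `rv_sparse_grm` wrapping a symmetric sparse
#'   [Matrix::Matrix] and the cutoff.
#' @export
build_sparse_grm <- function(genotypes, cutoff = 0.05) {
  p <- rowMeans(genotypes) / 2
  poly <- p > 0 & p < 1
  if (any(!poly)) {
    warn(paste0("excluding ", sum(!poly), " monomorphic marker(s) from the GRM."))
    genotypes <- genotypes[poly, , drop = FALSE]
    p <- p[poly]
  }
  m <- nrow(genotypes)
  if (m < 100) abort("need at least 100 polymorphic common markers for the GRM.")
  common <- p >= 0.01 & p <= 0.99
  if (!all(common)) {
    genotypes <- genotypes[common, , drop = FALSE]
    p <- p[common]
    m <- nrow(genotypes)
  }
  z <- (genotypes - 2 * p) / sqrt(2 * p * (1 - p))
  A <- crossprod(z) / m
  A[abs(A) < cutoff & row(A) != col(A)] <- 0
  structure(list(mat = methods::as(methods::as(Matrix::Matrix(A), "symmetricMatrix"),
                                   "CsparseMatrix"),
                 cutoff = cutoff, n = ncol(A)),
            class = "rv_sparse_grm")
}

#' @export
print.rv_sparse_grm <- function(x, ...) {
  nz <- Matrix::nnzero(x$mat) - x$n
  cat("<rv_sparse_grm> N =", x$n, "- cutoff", x$cutoff, "-",
      nz, "off-diagonal entries retained\n")
  invisible(x)
}

# REML profile log-likelihood for the rotated quantitative LMM
# y = X beta + g + e, g ~ N(0, tau * Psi), e ~ N(0, sigma2 I).
# With Psi = U D U' and delta = tau / sigma2, V = sigma2 (I + delta D) after
# rotation; sigma2 profiles out in closed form.
reml_quant <- function(ytil, Xtil, d, delta) {
  n <- length(ytil); p <- ncol(Xtil)
  v <- 1 + delta * d
  XtVX <- crossprod(Xtil / v, Xtil)
  beta <- solve(XtVX, crossprod(Xtil / v, ytil))
  r <- ytil - Xtil %*% beta
  rss <- sum(r^2 / v)
  sigma2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(sigma2) + sum(log(v)) +
                determinant(XtVX, logarithm = TRUE)$modulus + (n - p))
  list(ll = as.numeric(ll), sigma2 = sigma2, beta = beta)
}

#' Fit a sparse-GRM mixed null model
#'
#' Adds a polygenic random effect with covariance `tau * GRM` to the null
#' model. Quantitative traits are fitted by REML after rotating into the GRM
#' eigenbasis; binary traits by penalized quasi-likelihood, re-estimating
#' `tau` on the working model until convergence (tolerance 1e-6 on `tau`,
#' at most 50 outer iterations). `tau >= 0` is enforced.
#'
#' @inheritParams fit_null
#' @param grm an [build_sparse_grm()] result (or any symmetric matrix),
#'   aligned to the rows of `data`.
#' @return An `rv_null_model` with `tau` set and random-effect-adjusted
#'   fitted values and residuals.
#' @export
fit_null_mixed <- function(data, formula, grm,
                           trait_type = c("binary", "quantitative"),
                           sample_col = "sample_id", offset_mode = FALSE) {
  trait_type <- match.arg(trait_type)
  Psi <- if (inherits(grm, "rv_sparse_grm")) grm$mat else grm
  base <- fit_null(data, formula, trait_type = trait_type,
                   sample_col = sample_col, offset_mode = offset_mode)
  y <- base$mu_hat + base$resid
  X <- base$X
  n <- base$n
  if (nrow(Psi) != n) abort("GRM dimension does not match the sample count.")

  if (trait_type == "quantitative") {
    eg <- eigen(as.matrix(Psi), symmetric = TRUE)
    d <- pmax(eg$values, 0)
    Ut <- t(eg$vectors)
    ytil <- drop(Ut %*% y)
    Xtil <- Ut %*% X
    opt <- optimize(function(ld) reml_quant(ytil, Xtil, d, exp(ld))$ll,
                    interval = c(log(1e-6), log(1e4)), maximum = TRUE,
                    tol = 1e-7)
    delta <- exp(opt$maximum)
    at_zero <- reml_quant(ytil, Xtil, d, 1e-12)
    best <- reml_quant(ytil, Xtil, d, delta)
    if (at_zero$ll >= best$ll - 1e-8) {  # boundary: tau = 0
      delta <- 0
      best <- at_zero
    }
    sigma2 <- best$sigma2
    tau <- delta * sigma2
    beta <- drop(best$beta)
    mu_hat <- drop(X %*% beta)
    fit <- base
    fit$coefficients <- setNames(beta, colnames(X))
    fit$mu_hat <- mu_hat
    fit$resid <- as.numeric(y - mu_hat)
    fit$dispersion <- sigma2
    fit$resid_score <- fit$resid / sigma2
    fit$work_w <- rep(1 / sigma2, n)
    fit$tau <- tau
    fit$grm <- Psi
    fit$converged <- TRUE
    return(fit)
  }

  # binary PQL: working LMM on z = eta + (y - mu)/w with Var = tau Psi + W^-1
  beta <- base$coefficients
  tau <- 0.1
  b <- rep(0, n)
  trajectory <- numeric(0)
  PsiD <- as.matrix(Psi)
  for (it in seq_len(50L)) {
    eta <- drop(X %*% beta) + b
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    eg <- eigen(sqrt(w) * t(sqrt(w) * t(PsiD)), symmetric = TRUE)
    d <- pmax(eg$values, 0)
    Ut <- t(eg$vectors)
    ztil <- drop(Ut %*% (sqrt(w) * z))
    Xtil <- Ut %*% (sqrt(w) * X)
    opt <- optimize(function(lt) reml_quant(ztil, Xtil, d, exp(lt))$ll,
                    interval = c(log(1e-6), log(1e3)), maximum = TRUE,
                    tol = 1e-8)
    dl <- exp(opt$maximum)
    rq <- reml_quant(ztil, Xtil, d, dl)
    tau_new <- dl * rq$sigma2
    if (reml_quant(ztil, Xtil, d, 1e-12)$ll >= rq$ll - 1e-8) tau_new <- 0
    # GLS update of beta and BLUP of b given tau_new
    Vw <- tau_new * PsiD + diag(1 / w)
    XtVinvX <- crossprod(X, solve(Vw, X))
    beta_new <- drop(solve(XtVinvX, crossprod(X, solve(Vw, z))))
    b <- drop(tau_new * PsiD %*% solve(Vw, z - drop(X %*% beta_new)))
    delta_par <- max(abs(tau_new - tau), max(abs(beta_new - beta)))
    trajectory <- c(trajectory, tau_new)
    beta <- beta_new
    tau <- tau_new
    if (delta_par < 1e-6) break
  }
  if (delta_par >= 1e-6)
    abort(paste0("PQL did not converge in 50 iterations; tau trajectory: ",
                 paste(signif(trajectory, 4), collapse = ", ")),
          class = "rvsat_convergence_error")
  eta <- drop(X %*% beta) + b
  mu_hat <- plogis(eta)
  fit <- base
  fit$coefficients <- setNames(as.numeric(beta), colnames(X))
  fit$mu_hat <- mu_hat
  fit$resid <- as.numeric(y - mu_hat)
  fit$resid_score <- fit$resid
  fit$work_w <- as.numeric(mu_hat * (1 - mu_hat))
  fit$tau <- tau
  fit$grm <- Psi
  fit$converged <- TRUE
  fit
}

#' Calibrate the score-variance ratio from probe markers
#'
#' Ratio of the mixed-model score variance `g' P g` (with
#' `P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1`, `V = tau * GRM + W^-1`) to the
#' naive GLM score variance, averaged over random common probe markers. The
#' ratio is stored in the returned fit and multiplies the null covariance of
#' Step 2 score statistics. It equals 1 when `tau = 0` and is 1 by definition
#' when no GRM is supplied.
#'
#' @param fit an `rv_null_model` from [fit_null_mixed()] (a GLM fit is
#'   returned unchanged with ratio 1).
#' @param probe_geno N x M matrix of common-variant genotype probes
#'   (at least 30 columns recommended; fewer triggers a warning).
#' @return The fit with `variance_ratio` updated.
#' @export
estimate_variance_ratio <- function(fit, probe_geno) {
  stopifnot(inherits(fit, "rv_null_model"))
  if (is.null(fit$tau) || is.null(fit$grm)) return(fit)
  probe_geno <- as_dense(probe_geno)
  if (ncol(probe_geno) < 30)
    warn("fewer than 30 probe markers; variance ratio is a best-effort estimate.")
  X <- fit$X
  w <- fit$work_w
  if (fit$trait_type == "binary") {
    V <- fit$tau * as.matrix(fit$grm) + diag(1 / w)
  } else {
    V <- fit$tau * as.matrix(fit$grm) + diag(fit$dispersion, fit$n)
  }
  ch <- chol(V)
  Vinv_X <- backsolve(ch, forwardsolve(t(ch), X))
  Vinv_G <- backsolve(ch, forwardsolve(t(ch), probe_geno))
  XtVX_inv <- solve(crossprod(X, Vinv_X))
  XtWX_inv <- solve(crossprod(X, X * w))
  ratios <- vapply(seq_len(ncol(probe_geno)), function(j) {
    g <- probe_geno[, j]
    xvg <- crossprod(Vinv_X, g)
    v_mixed <- sum(g * Vinv_G[, j]) - drop(crossprod(xvg, XtVX_inv %*% xvg))
    gw <- g * w
    xwg <- crossprod(X, gw)
    v_glm <- sum(g * gw) - drop(crossprod(xwg, XtWX_inv %*% xwg))
    v_mixed / v_glm
  }, numeric(1))
  ratio <- mean(ratios[is.finite(ratios)])
  if (!is.finite(ratio) || ratio <= 0)
    abort("variance ratio estimation failed (non-positive ratio).")
  fit$variance_ratio <- ratio
  fit
}
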