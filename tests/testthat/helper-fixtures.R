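# Shared fixtures and independent oracles used across the suite.

# small hand-constructed gene set: n samples x 3 variants, hard calls
tiny_gvs <- function(n = 12, annotation = c("lof", "missense", "synonymous")) {
  G <- cbind(c(2, 1, 1, 0, 0, 0, 1, 0, 1, 0, 0, 1),
             c(0, 1, 0, 1, 1, 0, 0, 1, 0, 1, 1, 0),
             c(1, 0, 1, 1, 0, 1, 0, 0, 1, 0, 1, 1))[seq_len(n), , drop = FALSE]
  rownames(G) <- paste0("s", seq_len(n))
  colnames(G) <- paste0("1:", 1:3 * 10, ":A:T")
  gene_variant_set("tinygene", G, annotation)
}

# balanced binary null fit on n samples (half cases), intercept only
tiny_binary_fit <- function(y) {
  n <- length(y)
  fit_null(data.frame(sample_id = paste0("s", seq_len(n)), y = y),
           y ~ 1, trait_type = "binary")
}

# enumeration oracle: exact distribution of score statistics over all 2^n
# Bernoulli(mu) outcomes. Returns the weighted outcomes and score vectors.
enumerate_scores <- function(G_proj, mu) {
  n <- length(mu)
  ymat <- as.matrix(expand.grid(rep(list(0:1), n)))
  pw <- drop(exp(ymat %*% log(mu) + (1 - ymat) %*% log(1 - mu)))
  Svec <- (ymat - matrix(mu, nrow(ymat), n, byrow = TRUE)) %*% G_proj
  list(pw = pw, Svec = Svec)
}

# exact two-sided burden p (doubled smaller tail). The mid-p convention
# (half weight on the observed atom) is the exact quantity comparable to a
# continuous tail approximation of a lattice statistic.
enum_burden_p <- function(en, s_obs, midp = TRUE) {
  b <- rowSums(en$Svec)
  at <- sum(en$pw[abs(b - s_obs) <= 1e-9])
  up <- sum(en$pw[b >= s_obs - 1e-9])
  dn <- sum(en$pw[b <= s_obs + 1e-9])
  if (midp) { up <- up - at / 2; dn <- dn - at / 2 }
  min(1, 2 * min(up, dn))
}

enum_skat_p <- function(en, q_obs, midp = FALSE) {
  qs <- rowSums(en$Svec^2)
  p <- sum(en$pw[qs >= q_obs - 1e-9])
  if (midp) p <- p - sum(en$pw[abs(qs - q_obs) <= 1e-9]) / 2
  p
}

# naive reference collapsing implementation (independent of the package
# internals): straight loops over the definition
naive_collapse <- function(G, mac_threshold, scheme = "beta_default", user_w = NULL) {
  mac <- colSums(G)
  ur <- which(mac <= mac_threshold)
  keep <- which(mac > mac_threshold)
  w_in <- switch(scheme, beta_default = rep(1, ncol(G)),
                 user_weights = user_w, none = rep(1, ncol(G)))
  fold <- scheme %in% c("user_weights", "none")
  cols <- list()
  for (j in keep) cols[[length(cols) + 1L]] <- G[, j] * (if (fold) w_in[j] else 1)
  if (length(ur) > 0) {
    cc <- rep(0, nrow(G))
    for (i in seq_len(nrow(G))) {
      vals <- 0
      for (j in ur) if (G[i, j] > 0) {
        vals <- c(vals, G[i, j] * (if (fold) w_in[j] else 1))
      }
      cc[i] <- max(vals)
    }
    cols[[length(cols) + 1L]] <- cc
  }
  M <- do.call(cbind, cols)
  w_out <- if (scheme == "beta_default") {
    maf <- pmin(colSums(M) / (2 * nrow(M)), 0.5)
    dbeta(maf, 1, 25)
  } else rep(1, ncol(M))
  list(M = M, weights = w_out, k = ncol(M),
       k_expected = length(keep) + as.integer(length(ur) > 0))
}

# random small genotype matrix for property tests
random_small_G <- function(n, m, p = 0.2) {
  G <- matrix(rbinom(n * m, 2, p), n, m)
  while (all(colSums(G) == 0)) G <- matrix(rbinom(n * m, 2, p), n, m)
  rownames(G) <- paste0("s", seq_len(n))
  colnames(G) <- paste0("1:", seq_len(m) * 7, ":A:T")
  G
}
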