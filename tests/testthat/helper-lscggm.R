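# Shared fixture builders; everything is generated in code under fixed seeds.

# random feasible parameter set (S_X - L_X strictly PD, L_X PSD)
rand_params <- function(p = 3, m = 2, latent = TRUE) {
  A <- matrix(rnorm(p * p), p)
  S_X <- crossprod(A) / p + diag(p)
  L_X <- if (latent) {
    # strictly PD so small finite-difference perturbations stay feasible
    B <- matrix(rnorm(p), p, 1) / 2
    tcrossprod(B) + 0.05 * diag(p)
  } else matrix(0, p, p)
  S_X <- S_X + L_X            # keep S_X - L_X = crossprod/p + I, PD
  S_ZX <- matrix(rnorm(m * p) / 2, m, p)
  L_ZX <- matrix(rnorm(m * p) / 4, m, p)
  crf_params(S_X, L_X, S_ZX, L_ZX)
}

# random sufficient statistics from data with real structure
rand_stats <- function(n = 80, p = 3, m = 2) {
  Y_Z <- matrix(rnorm(n * m), n, m)
  B <- matrix(rnorm(m * p) / 2, m, p)
  Y_X <- (if (m > 0) Y_Z %*% B else 0) + matrix(rnorm(n * p), n, p)
  suff_stats(Y_X, Y_Z)
}

# numeric gradient of the log-likelihood by central differences
fd_gradient <- function(params, stats, eps = 1e-6) {
  blocks <- c("S_X", "L_X", "S_ZX", "L_ZX")
  out <- list()
  for (b in blocks) {
    M <- params[[b]]
    G <- matrix(0, nrow(M), ncol(M))
    if (length(M) == 0) { out[[b]] <- G; next }
    sym <- b %in% c("S_X", "L_X")
    for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
      if (sym && j < i) next
      up <- params; dn <- params
      up[[b]][i, j] <- up[[b]][i, j] + eps
      dn[[b]][i, j] <- dn[[b]][i, j] - eps
      if (sym && i != j) {
        up[[b]][j, i] <- up[[b]][j, i] + eps
        dn[[b]][j, i] <- dn[[b]][j, i] - eps
      }
      d <- (log_likelihood(up, stats) - log_likelihood(dn, stats)) / (2 * eps)
      if (sym && i != j) { G[i, j] <- d / 2; G[j, i] <- d / 2 }
      else G[i, j] <- d
    }
    out[[b]] <- G
  }
  out
}

expect_matrix_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
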