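test_that("chain support follows the removed-link rule", {
  # every (i, i-1) pair except i divisible by 5: p = 32 gives 25 edges
  S32 <- sim_chain_precision(32, seed = 1)
  expect_equal(nrow(support_edges(S32, 1e-12)), 25L)
  S5 <- sim_chain_precision(5, seed = 2)
  expect_equal(nrow(support_edges(S5, 1e-12)), 3L)
  ed <- support_edges(S5, 1e-12)
  expect_true(all(ed$j - ed$i == 1))
  S2 <- sim_chain_precision(2, seed = 3)
  expect_equal(nrow(support_edges(S2, 1e-12)), 1L)
})

test_that("latent structure has the designed rank and reach", {
  set.seed(5)
  lat <- sim_latent_structure(32, 2)
  expect_equal(lat$h, 4L)
  expect_true(all(rowSums(lat$M_XH != 0) == 1))      # one latent per output
  expect_true(all(colSums(lat$M_XH != 0) == 8))      # p / h outputs each
  LX <- lat$M_XH %*% solve(lat$M_H, t(lat$M_XH))
  expect_equal(qr(LX)$rank, 4L)
  lat3 <- sim_latent_structure(32, 3)
  LX3 <- lat3$M_XH %*% solve(lat3$M_H, t(lat3$M_XH))
  expect_equal(qr(LX3)$rank, 8L)
  # d_H = k: one-to-one pairing, diagonal low-rank component
  lat_k <- sim_latent_structure(8, 3)
  LXk <- lat_k$M_XH %*% solve(lat_k$M_H, t(lat_k$M_XH))
  expect_lt(max(abs(LXk - diag(diag(LXk)))), 1e-12)
  expect_error(sim_latent_structure(8, 4), "0:k")
})

test_that("input-effect matrix satisfies the rank and degree design", {
  set.seed(6)
  M2 <- sim_input_effects(32, 2)
  expect_true(all(rowSums(M2 != 0) == 8))
  expect_true(all(colSums(M2 != 0) == 8))
  expect_equal(qr(M2)$rank, 4L)
  M3 <- sim_input_effects(32, 3)
  expect_true(all(rowSums(M3 != 0) == 4))
  expect_equal(qr(M3)$rank, 8L)
  # d_Z = k: permutation-like, one nonzero per row and column
  Mk <- sim_input_effects(16, 4)
  expect_true(all(rowSums(Mk != 0) == 1) && all(colSums(Mk != 0) == 1))
  # magnitudes stay inside the configured range
  expect_true(all(abs(M2[M2 != 0]) >= 0.2 - 1e-12 &
                    abs(M2[M2 != 0]) <= 0.4 + 1e-12))
})

edge_rule_count <- function(p) {
  i <- 2:p
  sum(i %% 5 != 0)
}

test_that("generative models are feasible with the designed structure", {
  set.seed(77)
  for (seed in 1:5) {
    des <- sim_design(k = 4, d_Z = sample(0:4, 1), d_H = sample(0:4, 1),
                      n = 100, seed = seed)
    mod <- sim_model(des)
    J <- rbind(cbind(mod$M_X, mod$M_XH), cbind(t(mod$M_XH), mod$M_H))
    expect_gt(min(eigen(J, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_equal(qr(mod$L_X)$rank, 2L^des$d_H)
    expect_true(all(mod$L_ZX == 0))
    expect_true(all(mod$M_ZH == 0))
    # marginal precision also PD
    expect_true(is_feasible(sim_true_params(mod)))
    # chain support preserved on the off-diagonal
    offdiag <- mod$S_X; diag(offdiag) <- 0
    expect_equal(edge_rule_count(des$p), nrow(support_edges(offdiag, 1e-12)))
  }
})

test_that("sampled data reproduce the population moments", {
  # independence design: no input effects
  des <- sim_design(k = 3, d_Z = 3, d_H = 1, n = 5000, seed = 11)
  mod <- sim_model(des)
  mod$S_ZX[] <- 0
  dat <- sim_dataset(mod, n = 5000)
  st <- crf_stats_from_data(dat)
  expect_lt(max(abs(st$Sigma_ZX)), 0.1)

  # heavy-tailed inputs: t(4) columns have variance 2
  des2 <- sim_design(k = 3, d_Z = 2, d_H = 2, n = 1e5, seed = 12)
  dat2 <- sim_dataset(sim_model(des2))
  zv <- apply(as.matrix(dat2[, attr(dat2, "z_cols")]), 2, var)
  expect_equal(mean(zv), 2, tolerance = 0.1)

  # conditional covariance concentrates on (S_X - L_X)^{-1}
  mod3 <- sim_model(sim_design(k = 3, d_Z = 2, d_H = 1, n = 1e5, seed = 13))
  dat3 <- sim_dataset(mod3)
  st3 <- crf_stats_from_data(dat3)
  cond_hat <- st3$Sigma_X -
    t(st3$Sigma_ZX) %*% solve(st3$Sigma_Z, st3$Sigma_ZX)
  cond_true <- solve(mod3$S_X - mod3$L_X)
  rel <- sqrt(sum((cond_hat - cond_true)^2)) / sqrt(sum(cond_true^2))
  expect_lt(rel, 0.05)
})

test_that("the benchmark grid enumerates designs and replicates", {
  grid <- sim_grid(k = 5, n = 3000, reps = 20, base_seed = 1)
  expect_equal(nrow(grid), 320L)
  expect_equal(nrow(dplyr::distinct(grid, d_Z, d_H)), 16L)
  grid2 <- sim_grid(k = 5, n = 3000, reps = 20, base_seed = 1)
  expect_identical(grid$seed, grid2$seed)
  # datasets regenerate bit-identically from their stored design
  d <- grid$design[[17]]
  m1 <- sim_model(d); m2 <- sim_model(d)
  expect_identical(m1$S_X, m2$S_X)
  expect_identical(sim_dataset(m1, n = 20), sim_dataset(m2, n = 20))
})
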