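test_that("sufficient statistics are 1/n-scaled cross products", {
  # hand-checkable case
  st <- suff_stats(Y_X = matrix(c(2, 2), 2, 1), Y_Z = matrix(c(1, -1), 2, 1))
  expect_equal(st$Sigma_Z, matrix(1, 1, 1))
  expect_equal(st$Sigma_X, matrix(4, 1, 1))
  expect_equal(st$Sigma_ZX, matrix(0, 1, 1))
  expect_equal(st$n, 2L)

  # a zero output column zeroes its row/column of Sigma_X
  set.seed(1)
  YX <- cbind(matrix(rnorm(20), 10, 2), 0)
  st2 <- suff_stats(YX)
  expect_true(all(st2$Sigma_X[3, ] == 0) && all(st2$Sigma_X[, 3] == 0))

  # brute-force entrywise oracle on random blocks
  set.seed(42)
  YZ <- matrix(rnorm(150), 50, 3); YX3 <- matrix(rnorm(200), 50, 4)
  st3 <- suff_stats(YX3, YZ)
  oracle <- matrix(0, 3, 4)
  for (a in 1:3) for (b in 1:4)
    oracle[a, b] <- sum(YZ[, a] * YX3[, b]) / 50
  expect_matrix_equal(st3$Sigma_ZX, oracle, 1e-12)
  # joint stacked moment matrix is PSD when built from data
  ev <- eigen(joint_second_moment(st3), symmetric = TRUE, only.values = TRUE)
  expect_gte(min(ev$values), -1e-10)
})

test_that("sufficient statistics validate their inputs", {
  expect_error(suff_stats(matrix(1, 2, 1), matrix(1, 3, 1)), "row counts")
  expect_error(suff_stats(matrix(c(1, NA), 2, 1)), "non-finite")
  # standardized columns give unit diagonals
  set.seed(7)
  YX <- matrix(rnorm(60), 20, 3) * 5 + 2
  st <- suff_stats(YX, center = TRUE, standardize = TRUE)
  expect_matrix_equal(diag(st$Sigma_X), rep(1, 3), 1e-12)
})

test_that("log-likelihood matches its closed forms and the density oracle", {
  # m = 0, identity everything: log det I - tr(I) = -p
  p <- 4
  par0 <- crf_params(diag(p))
  st0 <- as_crf_stats(diag(p), n = 10)
  expect_equal(log_likelihood(par0, st0), -p)

  # zero interaction blocks reduce to the m = 0 value
  set.seed(2)
  parz <- rand_params(3, 2); parz$S_ZX[] <- 0; parz$L_ZX[] <- 0
  stz <- rand_stats(60, 3, 2)
  st_m0 <- as_crf_stats(stz$Sigma_X, n = stz$n)
  par_m0 <- crf_params(parz$S_X, parz$L_X)
  expect_equal(log_likelihood(parz, stz), log_likelihood(par_m0, st_m0))

  # per-sample Gaussian density oracle: the likelihood equals the average
  # of log det(Omega) - r' Omega r over samples (twice the log density
  # plus the p*log(2*pi) constant)
  set.seed(8)
  n <- 40; m <- 2; p <- 3
  YZ <- matrix(rnorm(n * m), n, m); YX <- matrix(rnorm(n * p), n, p)
  st <- suff_stats(YX, YZ)
  par <- rand_params(p, m)
  cd <- conditional_distribution(par)
  Om <- solve(cd$conditional_covariance)
  acc <- 0
  for (i in seq_len(n)) {
    r <- YX[i, ] - drop(t(cd$coefficient_map) %*% YZ[i, ])
    acc <- acc + determinant(Om, logarithm = TRUE)$modulus[1] -
      drop(t(r) %*% Om %*% r)
  }
  expect_equal(log_likelihood(par, st), acc / n, tolerance = 1e-8)

  # infeasible parameters raise a domain error, not -Inf
  bad <- crf_params(diag(c(1, -1)), check = FALSE)
  expect_error(log_likelihood(bad, as_crf_stats(diag(2), n = 2)), "infeasible")
})

test_that("gradient matches finite differences and reflects S - L symmetry", {
  set.seed(3)
  par <- rand_params(3, 2)
  st <- rand_stats(70, 3, 2)
  g <- crf_gradient(par, st)
  fd <- fd_gradient(par, st)
  for (b in c("S_X", "L_X", "S_ZX", "L_ZX"))
    expect_lt(max(abs(g[[b]] - fd[[b]])) / max(1, max(abs(fd[[b]]))), 1e-4)
  # L-gradients are the negated S-gradients (dependence through S - L only)
  expect_matrix_equal(g$S_X + g$L_X, matrix(0, 3, 3), 1e-12)
  expect_matrix_equal(g$S_ZX + g$L_ZX, matrix(0, 2, 3), 1e-12)
  # stationarity at the conditional MLE
  Chat <- st$Sigma_X - t(st$Sigma_ZX) %*% solve(st$Sigma_Z, st$Sigma_ZX)
  RX <- solve(Chat); RZX <- -solve(st$Sigma_Z, st$Sigma_ZX %*% RX)
  g0 <- crf_gradient(crf_params(RX, S_ZX = RZX), st)
  expect_lt(max(abs(g0$S_X)), 1e-8)
  expect_lt(max(abs(g0$S_ZX)), 1e-8)
})

test_that("conditional law matches scalar algebra and latent marginalization", {
  # scalar case: S_X = 2, S_ZX = 1 gives mean map -z/2 and variance 1/2
  par1 <- crf_params(matrix(2), S_ZX = matrix(1))
  cd1 <- conditional_distribution(par1)
  expect_equal(drop(cd1$coefficient_map), -0.5)
  expect_equal(drop(cd1$conditional_covariance), 0.5)

  # explicit latent model: build the joint (X, H) | Z law, marginalize H by
  # partitioned inversion, compare with the low-rank parameterization
  set.seed(5)
  p <- 3; h <- 2; m <- 2
  A <- matrix(rnorm((p + h)^2), p + h)
  J <- crossprod(A) / 2 + 2 * diag(p + h)       # joint precision over (X, H)
  MX <- J[1:p, 1:p]; MXH <- J[1:p, p + 1:h]; MH <- J[p + 1:h, p + 1:h]
  MZX <- matrix(rnorm(m * p), m, p); MZH <- matrix(rnorm(m * h), m, h)
  par <- crf_params(S_X = MX, L_X = MXH %*% solve(MH) %*% t(MXH),
                    S_ZX = MZX, L_ZX = MZH %*% solve(MH) %*% t(MXH))
  cd <- conditional_distribution(par)
  SigJ <- solve(J)
  B_joint <- -cbind(MZX, MZH) %*% SigJ          # mean map of (X, H) | Z
  expect_matrix_equal(cd$conditional_covariance, SigJ[1:p, 1:p], 1e-10)
  expect_matrix_equal(cd$coefficient_map, B_joint[, 1:p], 1e-10)
})

test_that("objective penalty matches an independent SVD computation", {
  set.seed(6)
  par <- rand_params(3, 2)
  st <- rand_stats(60, 3, 2)
  lam <- 0.3; gam <- 0.6
  obj <- objective_value(par, st, lam, gam)
  pen <- lam * (gam * sum(abs(rbind(par$S_X, par$S_ZX))) +
                  (1 - gam) * sum(svd(rbind(par$L_X, par$L_ZX))$d))
  expect_equal(obj, -log_likelihood(par, st) + pen, tolerance = 1e-12)
  # L = 0 at gamma ~ 1: only the l1 term remains
  parl <- rand_params(3, 2, latent = FALSE); parl$L_ZX[] <- 0
  expect_equal(objective_value(parl, st, lam, 1 - 1e-12),
               -log_likelihood(parl, st) + lam * sum(abs(stacked_S(parl))),
               tolerance = 1e-6)
  # diagonal exemption
  obj_nd <- objective_value(par, st, lam, gam, penalize_diagonal = FALSE)
  expect_equal(obj - obj_nd, lam * gam * sum(abs(diag(par$S_X))))
})

test_that("objective is jointly convex and likelihood depends on S - L only", {
  set.seed(9)
  st <- rand_stats(60, 3, 2)
  for (i in 1:200) {
    p1 <- rand_params(3, 2); p2 <- rand_params(3, 2)
    pm <- crf_params((p1$S_X + p2$S_X) / 2, (p1$L_X + p2$L_X) / 2,
                     (p1$S_ZX + p2$S_ZX) / 2, (p1$L_ZX + p2$L_ZX) / 2)
    o1 <- objective_value(p1, st, 0.2, 0.5)
    o2 <- objective_value(p2, st, 0.2, 0.5)
    om <- objective_value(pm, st, 0.2, 0.5)
    expect_lte(om, (o1 + o2) / 2 + 1e-9)
  }
  # shift invariance of the likelihood
  par <- rand_params(3, 2)
  D <- crossprod(matrix(rnorm(9), 3)) / 10
  DZ <- matrix(rnorm(6) / 10, 2, 3)
  shifted <- crf_params(par$S_X + D, par$L_X + D,
                        par$S_ZX + DZ, par$L_ZX + DZ)
  expect_equal(log_likelihood(par, st), log_likelihood(shifted, st),
               tolerance = 1e-10)
})

test_that("penalty parameterizations convert consistently", {
  u <- penalty_to_unbounded(0.3, 0.25)
  back <- penalty_from_unbounded(u$lambda, u$gamma)
  expect_equal(back$lambda, 0.3)
  expect_equal(back$gamma, 0.25)
  # same objective under either form: lambda(g|S| + (1-g)|L|) =
  # lambda2(g2|S| + |L|)
  expect_equal(0.3 * 0.25, u$lambda * u$gamma)
  expect_equal(0.3 * 0.75, u$lambda)
})
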