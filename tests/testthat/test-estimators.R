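edge_key <- function(e) paste(e$i, e$j, sep = "-")

test_that("sparse-only conditional fits show nested supports along lambda", {
  # no latent variables in the truth: supports grow as lambda shrinks and
  # contain the true chain at moderate penalty
  des <- sim_design(k = 3, d_Z = 3, d_H = 3, n = 2000, seed = 21)
  mod <- sim_model(des)
  dat <- sim_dataset(mod)
  truth <- support_edges(mod$S_X, 1e-12)
  lams <- c(0.4, 0.15, 0.05, 0.02)
  sizes <- integer(0)
  found <- FALSE
  for (l in lams) {
    f <- fit_method(dat, "scggm", lambda = l, gamma = 0.9)
    ed <- support_edges(f$params$S_X)
    sizes <- c(sizes, nrow(ed))
    if (all(edge_key(truth) %in% edge_key(ed))) found <- TRUE
  }
  expect_true(all(diff(sizes) >= 0))
  expect_true(found)
})

test_that("joint fit at vanishing penalty recovers the precision matrix", {
  set.seed(23)
  n <- 6000; m <- 2; p <- 3
  YZ <- matrix(rnorm(n * m), n, m)
  YX <- YZ %*% matrix(rnorm(m * p) / 2, m, p) + matrix(rnorm(n * p), n, p)
  dat <- tibble::as_tibble(as.data.frame(cbind(YZ, YX)))
  names(dat) <- c("z1", "z2", "x1", "x2", "x3")
  f <- fit_method(dat, "glasso", lambda = 1e-8, gamma = 0.5,
                  z_cols = c("z1", "z2"),
                  options = solver_options(tol_primal = 1e-8,
                                           tol_dual = 1e-8, max_iter = 5000))
  st <- crf_stats_from_data(dat, z_cols = c("z1", "z2"))
  Om <- solve(joint_second_moment(st))
  expect_matrix_equal(f$joint_params$S_X, Om, 1e-5)
  # extracted X block equals the conditional precision of X given Z
  # (Schur complement identity)
  cond_prec <- solve(st$Sigma_X - t(st$Sigma_ZX) %*%
                       solve(st$Sigma_Z, st$Sigma_ZX))
  expect_matrix_equal(f$params$S_X, cond_prec, 1e-5)
})

test_that("joint methods on input-free data coincide with the conditional fit", {
  set.seed(24)
  YX <- matrix(rnorm(400), 100, 4) %*% diag(c(1, 2, 1, 0.5))
  dat <- tibble::as_tibble(as.data.frame(YX))
  f_lrps <- fit_method(dat, "lrps", lambda = 0.1, gamma = 0.5,
                       z_cols = character(0))
  f_full <- fit_method(dat, "lscggm", lambda = 0.1, gamma = 0.5,
                       z_cols = character(0))
  expect_matrix_equal(f_lrps$params$S_X, f_full$params$S_X, 1e-8)
  expect_matrix_equal(f_lrps$params$L_X, f_full$params$L_X, 1e-8)
  expect_error(fit_method(dat, "ridge", lambda = 0.1), "arg")
})

test_that("regularization paths start empty and grow monotonically", {
  des <- sim_design(k = 3, d_Z = 2, d_H = 2, n = 800, seed = 25)
  dat <- sim_dataset(sim_model(des))
  path <- regularization_path(dat, "lscggm", gammas = 0.6, n_lambda = 10,
                              options = solver_options(tol_primal = 1e-5,
                                                       tol_dual = 1e-5,
                                                       max_iter = 500))
  expect_s3_class(path, "crf_path")
  expect_equal(path$n_edges[1], 0L)                  # lambda_max definition
  steps <- diff(path$n_edges)
  expect_gte(mean(steps >= 0), 0.95)                 # non-decreasing almost everywhere
  expect_true(all(path$converged))
})

test_that("warm-started paths match cold-started supports", {
  des <- sim_design(k = 3, d_Z = 2, d_H = 3, n = 600, seed = 26)
  dat <- sim_dataset(sim_model(des))
  lams <- exp(seq(log(0.5), log(0.02), length.out = 6))
  opts <- solver_options(tol_primal = 1e-6, tol_dual = 1e-6, max_iter = 2000)
  pw <- regularization_path(dat, "lscggm", lambdas = lams, gammas = 0.5,
                            warm_start = TRUE, options = opts)
  pc <- regularization_path(dat, "lscggm", lambdas = lams, gammas = 0.5,
                            warm_start = FALSE, options = opts)
  expect_equal(pw$n_edges, pc$n_edges)
  expect_equal(pw$rank_L, pc$rank_L)
})

test_that("tidiers and plots expose the fit in tabular form", {
  des <- sim_design(k = 3, d_Z = 2, d_H = 2, n = 500, seed = 27)
  dat <- sim_dataset(sim_model(des))
  f <- fit_method(dat, "lscggm", lambda = 0.1, gamma = 0.5)
  td <- tidy(f)
  expect_true(all(c("block", "i", "j", "value") %in% names(td)))
  expect_true(all(td$block %in% c("S_X", "S_ZX")))
  gl <- glance(f)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_edges, nrow(support_edges(f$params$S_X)))
  path <- regularization_path(dat, "lscggm", lambdas = c(0.3, 0.1),
                              gammas = c(0.3, 0.7))
  pl <- autoplot(path)
  expect_s3_class(pl, "ggplot")
})
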