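ed <- function(...) {
  v <- c(...)
  if (is.null(v)) return(tibble::tibble(i = integer(0), j = integer(0)))
  m <- matrix(v, ncol = 2, byrow = TRUE)
  tibble::tibble(i = as.integer(m[, 1]), j = as.integer(m[, 2]))
}

test_that("precision and recall follow the counting conventions", {
  truth <- ed(1,2, 2,3, 3,4, 4,5)
  expect_equal(precision_recall(truth, truth),
               tibble::tibble(precision = 1, recall = 1))
  # empty estimate: precision 1 by convention, recall 0
  empty <- ed()
  expect_equal(precision_recall(empty, truth),
               tibble::tibble(precision = 1, recall = 0))
  # est = {a, b, x} vs truth of 4: precision 2/3, recall 1/2
  est <- ed(1,2, 2,3, 7,8)
  pr <- precision_recall(est, truth)
  expect_equal(pr$precision, 2 / 3)
  expect_equal(pr$recall, 1 / 2)
  expect_error(precision_recall(est, ed()), "empty")
})

test_that("AUC integrates the monotonized envelope", {
  # perfect curve through precision-1 points
  perfect <- tibble::tibble(recall = c(0.2, 0.6, 1), precision = c(1, 1, 1))
  expect_equal(pr_auc(perfect), 1)
  # single point: rectangular step
  single <- tibble::tibble(recall = 0.5, precision = 0.5)
  expect_equal(pr_auc(single), 0.25)
  fr <- fixed_recall_precision(single, c(0.1, 0.3, 0.5, 0.7, 1))
  expect_equal(fr$precision, c(0.5, 0.5, 0.5, 0, 0))
  # AUC bounded by the precision range
  set.seed(61)
  rand_curve <- tibble::tibble(recall = sort(runif(10)),
                               precision = runif(10, 0.2, 0.9))
  a <- pr_auc(rand_curve)
  expect_gte(a, 0)
  expect_lte(a, max(rand_curve$precision))
  # invariance to duplicated points
  expect_equal(pr_auc(rbind(rand_curve, rand_curve)), a)
})

test_that("volume under the surface averages AUC over gamma", {
  flat <- tidyr::expand_grid(gamma = c(0.2, 0.5, 0.8),
                             recall = c(0.5, 1), lambda = 1)
  flat$precision <- 1
  expect_equal(pr_vus(flat), 1)
  # AUC linear in gamma from 0 to 1 integrates to 1/2
  lin <- dplyr::bind_rows(purrr::map(seq(0, 1, 0.25), function(g)
    tibble::tibble(gamma = g, lambda = 1, recall = 1, precision = g)))
  expect_equal(pr_vus(lin), 0.5)
  # invariance under refinement of an already-linear segment
  lin2 <- dplyr::bind_rows(purrr::map(seq(0, 1, 0.05), function(g)
    tibble::tibble(gamma = g, lambda = 1, recall = 1, precision = g)))
  expect_lt(abs(pr_vus(lin2) - pr_vus(lin)), 1e-9)
  expect_error(pr_vus(dplyr::filter(lin, gamma == 0)), "two gamma")
})

test_that("PR curves from fitted paths score support recovery", {
  des <- sim_design(k = 3, d_Z = 2, d_H = 3, n = 1500, seed = 63)
  mod <- sim_model(des)
  dat <- sim_dataset(mod)
  path <- regularization_path(dat, "lscggm", gammas = c(0.3, 0.7),
                              n_lambda = 8)
  pr <- pr_curve(path, mod)
  expect_true(all(pr$precision >= 0 & pr$precision <= 1))
  expect_true(all(pr$recall >= 0 & pr$recall <= 1))
  expect_equal(nrow(pr), nrow(path))
  expect_gte(pr_vus(pr), 0)
})

test_that("consistency check is exact at the truth and reports errors", {
  des <- sim_design(k = 3, d_Z = 2, d_H = 1, n = 100, seed = 64)
  mod <- sim_model(des)
  at_truth <- list(params = sim_true_params(mod), m = mod$design$m,
                   p = mod$design$p)
  class(at_truth) <- "crf_fit"
  cc <- consistency_check(at_truth, mod)
  expect_true(cc$sign_agreement)
  expect_true(cc$rank_match)
  expect_true(cc$lx_psd)
  expect_equal(cc$err_S_inf, 0)
  expect_equal(cc$err_L_2, 0)
  expect_equal(cc$sx_sign_f1, 1)
  # a fitted model keeps the PSD guarantee on its low-rank block
  f <- fit_method(sim_dataset(mod), "lscggm", lambda = 0.15, gamma = 0.4)
  cf <- consistency_check(f, mod)
  expect_true(cf$lx_psd)
})

test_that("identifiability proxies match direct computations", {
  des <- sim_design(k = 5, d_Z = 2, d_H = 2, n = 100, seed = 65)
  mod <- sim_model(des)
  ib <- identifiability_bounds(mod)
  # direct counting of the stacked support degree
  S <- rbind(mod$S_X, mod$S_ZX)
  expect_equal(ib$mu_bound,
               max(max(rowSums(S != 0)), max(colSums(S != 0))))
  expect_equal(ib$rank_L, 4L)
  # one latent loading equally on all outputs: xi = 2 / sqrt(p)
  p <- 16
  mod_unif <- mod
  mod_unif$L_X <- tcrossprod(rep(1 / sqrt(p), p))
  mod_unif$L_ZX <- matrix(0, 2, p)
  mod_unif$S_X <- diag(p); mod_unif$S_ZX <- matrix(0, 2, p)
  expect_equal(identifiability_bounds(mod_unif)$xi_bound, 2 / sqrt(p))
  # diagonal low-rank component: maximally concentrated, xi = 2
  mod_diag <- mod_unif
  mod_diag$L_X <- diag(p)
  expect_equal(identifiability_bounds(mod_diag)$xi_bound, 2)
})
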