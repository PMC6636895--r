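#' Simulation design for structured conditional graphical models
#'
#' The simulated family is indexed by two integers: `d_Z` controls the rank
#' and sparsity of the input-effect matrix, `d_H` the number and reach of
#' latent confounders. The output dimension is `p = 2^k` and the input
#' dimension equals `p`. The graph over the outputs is always the same
#' chain with every fifth link removed.
#'
#' @param k output dimension exponent, `p = 2^k`.
#' @param d_Z input design integer in `0:k`; the input-effect matrix has
#'   rank `2^d_Z` and exactly `p / 2^d_Z` nonzeros in every row and column.
#' @param d_H latent design integer in `0:k`; there are `2^d_H` confounders,
#'   each impacting exactly `p / 2^d_H` outputs, each output tied to exactly
#'   one confounder.
#' @param n sample count.
#' @param seed integer seed making the generated model and data reproducible.
#' @param effect_range magnitude range the nonzero effects are drawn from
#'   (uniform over plus/minus this interval).
#' @param diag_slack added to row absolute sums when setting the diagonal of
#'   the joint precision (strict diagonal dominance, hence positive
#'   definiteness).
#' @return list of class `sim_design`.
#' @export
sim_design <- function(k = 5, d_Z = 2, d_H = 2, n = 3000, seed = 1,
                       effect_range = c(0.2, 0.4), diag_slack = 0.5) {
  stopifnot(k >= 1, d_Z >= 0, d_Z <= k, d_H >= 0, d_H <= k, n >= 1)
  structure(list(k = k, p = 2L^k, m = 2L^k, d_Z = d_Z, d_H = d_H, n = n,
                 seed = as.integer(seed), effect_range = effect_range,
                 diag_slack = diag_slack),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("<sim_design> p = m = %d, d_Z = %d, d_H = %d, n = %d, seed = %d\n",
              x$p, x$d_Z, x$d_H, x$n, x$seed))
  invisible(x)
}

rsign_unif <- function(n, range) {
  sample(c(-1, 1), n, replace = TRUE) * runif(n, range[1], range[2])
}

#' Chain precision support over the outputs
#'
#' Builds the p x p sparse component of the output precision: a chain over
#' the p variables with one link in five removed. Using 1-based indices, the
#' off-diagonal support is exactly `{(i, j): i = j + 1, i mod 5 != 0}`,
#' symmetrized. Nonzero magnitudes are drawn uniformly from plus/minus
#' `effect_range`; the diagonal is left at zero here and set globally for
#' diagonal dominance by [sim_model()].
#'
#' @param p number of outputs (`p >= 2`).
#' @param effect_range magnitude range of the nonzero entries.
#' @param seed optional seed (the caller usually manages seeding).
#' @return p x p symmetric matrix with zero diagonal.
#' @export
sim_chain_precision <- function(p, effect_range = c(0.2, 0.4), seed = NULL) {
  stopifnot(p >= 2)
  if (!is.null(seed)) set.seed(seed)
  S <- matrix(0, p, p)
  i <- 2:p
  i <- i[i %% 5 != 0]
  vals <- rsign_unif(length(i), effect_range)
  S[cbind(i, i - 1)] <- vals
  S[cbind(i - 1, i)] <- vals
  S
}

#' Latent confounder structure
#'
#' Generates the latent precision `M_H` (h x h, diagonal with jittered
#' positive entries) and the output-latent loading matrix `M_XH` (p x h)
#' with exactly one nonzero per row (each output tied to one confounder) and
#' exactly `p / h` nonzeros per column (each confounder reaching `p / h`
#' outputs), where `h = 2^d_H`. The implied low-rank component
#' `L_X = M_XH M_H^{-1} M_XH'` has rank exactly `h`; when `d_H = k` the
#' pairing is one-to-one and `L_X` is diagonal (no confounding).
#'
#' @param p number of outputs, a power of two.
#' @param d_H latent design integer.
#' @inheritParams sim_chain_precision
#' @return list with `M_H`, `M_XH`, `h`.
#' @export
sim_latent_structure <- function(p, d_H, effect_range = c(0.2, 0.4),
                                 seed = NULL) {
  k <- round(log2(p))
  if (2^k != p) stop("p must be a power of two", call. = FALSE)
  if (d_H < 0 || d_H > k) stop("d_H must lie in 0:k", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  h <- 2L^d_H
  group <- sample(rep(seq_len(h), each = p / h))   # exactly p/h outputs each
  M_XH <- matrix(0, p, h)
  M_XH[cbind(seq_len(p), group)] <- rsign_unif(p, effect_range)
  M_H <- diag(runif(h, 1, 1.2), h)
  list(M_H = M_H, M_XH = M_XH, h = h)
}

#' Input-effect matrix of a block design
#'
#' Generates the m x p input-effect matrix (`m = p`) with rank exactly
#' `2^d_Z` and exactly `p / 2^d_Z` nonzeros in every row and every column:
#' inputs and outputs are each partitioned at random into `2^d_Z` blocks,
#' paired off, and each within-block submatrix is a rank-one outer product
#' with entries of magnitude inside `effect_range`. With `d_Z = k` this is
#' a (signed, scaled) permutation: one input per output.
#'
#' @param p number of outputs (and inputs), a power of two.
#' @param d_Z input design integer.
#' @inheritParams sim_chain_precision
#' @return m x p matrix.
#' @export
sim_input_effects <- function(p, d_Z, effect_range = c(0.2, 0.4),
                              seed = NULL) {
  k <- round(log2(p))
  if (2^k != p) stop("p must be a power of two", call. = FALSE)
  if (d_Z < 0 || d_Z > k) stop("d_Z must lie in 0:k", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- 2L^d_Z
  b <- p / g
  in_blocks <- split(sample(seq_len(p)), rep(seq_len(g), each = b))
  out_blocks <- split(sample(seq_len(p)), rep(seq_len(g), each = b))
  M <- matrix(0, p, p)
  sr <- sqrt(effect_range)
  for (l in seq_len(g)) {
    u <- rsign_unif(b, sr)
    v <- rsign_unif(b, sr)
    M[in_blocks[[l]], out_blocks[[l]]] <- outer(u, v)
  }
  M
}

#' Ground-truth generative model of a simulation design
#'
#' Assembles the joint conditional precision over (outputs, latents), with
#' diagonals set to row absolute sums plus `diag_slack` (strict diagonal
#' dominance, so the joint precision is positive definite), and derives the
#' marginal decomposition: `S_X` (chain sparse part), `L_X = M_XH M_H^{-1}
#' M_XH'`, `S_ZX` (the input-effect matrix), `L_ZX = 0` (inputs do not act
#' on the latents in these designs).
#'
#' @param design a [sim_design()] object.
#' @return list of class `sim_model` with the building blocks (`M_X`, `M_H`,
#'   `M_XH`, `M_ZX`), the derived truth (`S_X`, `L_X`, `S_ZX`, `L_ZX`) and
#'   the design.
#' @export
sim_model <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  p <- design$p
  M_X <- sim_chain_precision(p, design$effect_range)
  lat <- sim_latent_structure(p, design$d_H, design$effect_range)
  M_ZX <- sim_input_effects(p, design$d_Z, design$effect_range)
  # joint precision over (X, H); diagonal by dominance
  J <- rbind(cbind(M_X, lat$M_XH), cbind(t(lat$M_XH), lat$M_H - diag(diag(lat$M_H))))
  diag_vals <- rowSums(abs(J)) + design$diag_slack
  M_X <- M_X + diag(diag_vals[seq_len(p)], p)
  M_H <- lat$M_H - diag(diag(lat$M_H)) + diag(diag_vals[p + seq_len(lat$h)], lat$h)
  L_X <- lat$M_XH %*% solve(M_H, t(lat$M_XH))
  structure(
    list(M_X = M_X, M_H = M_H, M_XH = lat$M_XH, M_ZX = M_ZX,
         M_ZH = matrix(0, p, lat$h),
         S_X = M_X, L_X = (L_X + t(L_X)) / 2,
         S_ZX = M_ZX, L_ZX = matrix(0, p, p),
         h = lat$h, design = design),
    class = "sim_model")
}

#' @export
print.sim_model <- function(x, ...) {
  cat(sprintf("<sim_model> p = %d, h = %d confounders, rank(L_X) = %d\n",
              nrow(x$S_X), x$h, qr(x$L_X)$rank))
  invisible(x)
}

#' True parameter set of a generative model
#'
#' @param model a [sim_model()] object.
#' @return the ground truth as a [crf_params()] object.
#' @export
sim_true_params <- function(model) {
  crf_params(model$S_X, model$L_X, model$S_ZX, model$L_ZX)
}

#' Sample a dataset from a generative model
#'
#' Inputs are drawn entrywise from a t-distribution with 4 degrees of
#' freedom (heavy-tailed, variance 2); outputs follow the implied Gaussian
#' conditional law after marginalizing the latents: mean
#' `-(S_X - L_X)^{-1} S_ZX' z`, covariance `(S_X - L_X)^{-1}`.
#'
#' @param model a [sim_model()] object.
#' @param n sample count (defaults to the design's `n`).
#' @param seed seed (defaults to the design's `seed + 1`).
#' @return tibble with columns `z1..zm` then `x1..xp`, one row per sample.
#' @export
sim_dataset <- function(model, n = model$design$n, seed = model$design$seed + 1L) {
  stopifnot(inherits(model, "sim_model"))
  set.seed(seed)
  p <- nrow(model$S_X); m <- nrow(model$S_ZX)
  R <- model$S_X - model$L_X
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("model is infeasible: S_X - L_X not PD", call. = FALSE)
  Y_Z <- matrix(rt(n * m, df = 4), n, m)
  Sigma_cond <- chol2inv(chol(R))
  B <- -model$S_ZX %*% Sigma_cond                # m x p; mean = t(B) z = z' B
  Y_X <- Y_Z %*% B + matrix(rnorm(n * p), n, p) %*% chol(Sigma_cond)
  out <- tibble::as_tibble(
    setNames(as.data.frame(cbind(Y_Z, Y_X)),
             c(paste0("z", seq_len(m)), paste0("x", seq_len(p)))))
  attr(out, "z_cols") <- paste0("z", seq_len(m))
  attr(out, "x_cols") <- paste0("x", seq_len(p))
  out
}

#' The full simulation grid of designs and replicate seeds
#'
#' Enumerates the benchmark grid: all `(d_Z, d_H)` pairs in `{2,...,k}` x
#' `{2,...,k}` by default (16 designs at `k = 5`), each replicated `reps`
#' times (320 datasets at the default 20 replicates), with per-dataset seeds
#' derived deterministically from `base_seed` by a counter scheme so any
#' dataset can be regenerated in isolation. Datasets are not materialized;
#' call [sim_model()] / [sim_dataset()] on a row's design.
#'
#' @param k dimension exponent (`p = 2^k`).
#' @param n samples per dataset.
#' @param reps replicates per design.
#' @param base_seed master seed.
#' @param d_values values taken by both design integers.
#' @return tibble with one row per dataset: `d_Z`, `d_H`, `rep`, `seed`, and
#'   a `design` list-column of [sim_design()] objects.
#' @export
sim_grid <- function(k = 5, n = 3000, reps = 20, base_seed = 1,
                     d_values = 2:k) {
  grid <- tidyr::expand_grid(d_Z = d_values, d_H = d_values,
                             rep = seq_len(reps))
  grid$seed <- (as.integer(base_seed) +
                  100003L * seq_len(nrow(grid))) %% 2147483629L
  grid$design <- purrr::pmap(grid[c("d_Z", "d_H", "seed")],
                             function(d_Z, d_H, seed)
                               sim_design(k = k, d_Z = d_Z, d_H = d_H,
                                          n = n, seed = seed))
  grid
}
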