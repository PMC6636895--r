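#' Conditional log-likelihood in sufficient-statistic form
#'
#' Average per-sample log-likelihood (up to the Gaussian constant) of the
#' conditional model, as a function of the differences `R_X = S_X - L_X` and
#' `R_ZX = S_ZX - L_ZX`:
#'
#' \deqn{\ell = \log\det R_X - tr(\Sigma_X R_X) - 2\,tr(\Sigma_{ZX} R_{ZX}')
#'   - tr(R_X^{-1} R_{ZX}' \Sigma_Z R_{ZX}).}
#'
#' With no inputs (m = 0) the last two terms vanish and this is the familiar
#' Gaussian log-likelihood \eqn{\log\det R_X - tr(\Sigma_X R_X)}.
#'
#' @param params a feasible [crf_params()] object.
#' @param stats a [suff_stats()] object with matching dimensions.
#' @return scalar log-likelihood value.
#' @export
log_likelihood <- function(params, stats) {
  stop_if_infeasible(params)
  R_X <- params$S_X - params$L_X
  ch <- chol(R_X)
  val <- 2 * sum(log(diag(ch))) - sum(stats$Sigma_X * R_X)
  if (params$m > 0) {
    R_ZX <- params$S_ZX - params$L_ZX
    val <- val - 2 * sum(stats$Sigma_ZX * R_ZX)
    # tr(R_X^{-1} R_ZX' Sigma_Z R_ZX) via a triangular solve
    W <- backsolve(ch, backsolve(ch, t(R_ZX), transpose = TRUE)) # R_X^{-1} R_ZX'
    val <- val - sum(W * t(stats$Sigma_Z %*% R_ZX))
  }
  val
}

#' Gradient of the conditional log-likelihood
#'
#' Derivatives of [log_likelihood()] with respect to each of the four blocks.
#' The likelihood depends on the parameters only through `S - L`, so the
#' `L`-block gradients are the negatives of the `S`-block gradients.
#' Gradients with respect to the symmetric blocks are returned symmetrized,
#' since solvers only evaluate at symmetric points.
#'
#' @inheritParams log_likelihood
#' @return A list with matrices `S_X`, `L_X`, `S_ZX`, `L_ZX`.
#' @export
crf_gradient <- function(params, stats) {
  stop_if_infeasible(params)
  R_X <- params$S_X - params$L_X
  C <- chol2inv(chol(R_X))
  if (params$m > 0) {
    R_ZX <- params$S_ZX - params$L_ZX
    SzR <- stats$Sigma_Z %*% R_ZX              # m x p
    Q <- crossprod(R_ZX, SzR)                  # R_ZX' Sigma_Z R_ZX, p x p
    g_SX <- C - stats$Sigma_X + C %*% Q %*% C
    g_SZX <- -2 * stats$Sigma_ZX - 2 * SzR %*% C
  } else {
    g_SX <- C - stats$Sigma_X
    g_SZX <- matrix(0, 0, params$p)
  }
  g_SX <- (g_SX + t(g_SX)) / 2
  list(S_X = g_SX, L_X = -g_SX, S_ZX = g_SZX, L_ZX = -g_SZX)
}

#' Conditional law of the outputs given the inputs
#'
#' Maps a feasible parameter set to the implied multivariate normal law
#' `Y_X | Y_Z = z ~ N(B' z, C)` with coefficient map
#' `B = -(S_ZX - L_ZX)(S_X - L_X)^{-1}` (m x p) and conditional covariance
#' `C = (S_X - L_X)^{-1}`.
#'
#' @param params a feasible [crf_params()] object.
#' @return list with `coefficient_map` (m x p) and `conditional_covariance`
#'   (p x p).
#' @export
conditional_distribution <- function(params) {
  stop_if_infeasible(params)
  Cov <- chol2inv(chol(params$S_X - params$L_X))
  B <- -(params$S_ZX - params$L_ZX) %*% Cov
  list(coefficient_map = B, conditional_covariance = (Cov + t(Cov)) / 2)
}

#' Penalized objective value
#'
#' The estimation objective: negative [log_likelihood()] plus the combined
#' penalty `lambda * (gamma * ||S||_1 + (1 - gamma) * ||L||_*)`, where `S` and
#' `L` are the stacked (p+m) x p views and the nuclear norm is the sum of
#' singular values of the stacked `L`. All entries of `S` (diagonal of `S_X`
#' included) are penalized unless `penalize_diagonal = FALSE`.
#'
#' @inheritParams log_likelihood
#' @param lambda positive overall penalty level.
#' @param gamma sparse/low-rank trade-off in (0, 1).
#' @param penalize_diagonal include `diag(S_X)` in the l1 term.
#' @return scalar objective value.
#' @export
objective_value <- function(params, stats, lambda, gamma,
                            penalize_diagonal = TRUE) {
  if (lambda < 0) stop("lambda must be nonnegative", call. = FALSE)
  if (gamma <= 0 || gamma >= 1) stop("gamma must lie in (0, 1)", call. = FALSE)
  S <- stacked_S(params)
  l1 <- sum(abs(S))
  if (!penalize_diagonal) l1 <- l1 - sum(abs(diag(params$S_X)))
  nuc <- sum(svd(stacked_L(params))$d)
  -log_likelihood(params, stats) + lambda * (gamma * l1 + (1 - gamma) * nuc)
}

#' Convert between the two penalty parameterizations
#'
#' The package uses `lambda * (gamma * ||S||_1 + (1-gamma) * ||L||_*)` with
#' `gamma` in (0, 1). The alternative form `lambda2 * (gamma2 * ||S||_1 +
#' ||L||_*)` with `gamma2` in (0, Inf) is equivalent via
#' `lambda2 = lambda * (1 - gamma)`, `gamma2 = gamma / (1 - gamma)`.
#'
#' @param lambda,gamma penalty in the bounded parameterization.
#' @return list with `lambda` and `gamma` of the unbounded form.
#' @export
penalty_to_unbounded <- function(lambda, gamma) {
  stopifnot(gamma > 0, gamma < 1)
  list(lambda = lambda * (1 - gamma), gamma = gamma / (1 - gamma))
}

#' @rdname penalty_to_unbounded
#' @param lambda2,gamma2 penalty in the unbounded parameterization.
#' @export
penalty_from_unbounded <- function(lambda2, gamma2) {
  stopifnot(gamma2 > 0)
  list(lambda = lambda2 * (1 + gamma2), gamma = gamma2 / (1 + gamma2))
}
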