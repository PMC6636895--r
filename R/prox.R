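#' Elementwise soft-thresholding (proximal operator of the l1 norm)
#'
#' `prox_l1(M, t)` returns the minimizer of `0.5 * ||X - M||_F^2 + t * ||X||_1`:
#' `sign(M) * pmax(|M| - t, 0)`. Entries flagged by `mask` are exempt from
#' the penalty and passed through unchanged (used for unpenalized diagonals).
#'
#' @param M numeric matrix.
#' @param t nonnegative threshold.
#' @param mask optional 0/1 matrix; 1 marks unpenalized entries.
#' @return matrix of the same shape as `M`.
#' @export
prox_l1 <- function(M, t, mask = NULL) {
  if (t < 0) stop("threshold t must be nonnegative", call. = FALSE)
  .prox_l1_cpp(as.matrix(M), t, if (is.null(mask)) NULL else as.matrix(mask))
}

#' Singular-value soft-thresholding (proximal operator of the nuclear norm)
#'
#' Shrinks all singular values of `M` by `t` and reconstructs; the minimizer
#' of `0.5 * ||X - M||_F^2 + t * ||X||_*`.
#'
#' @inheritParams prox_l1
#' @return matrix of the same shape as `M`.
#' @export
svd_soft_threshold <- function(M, t) {
  if (t < 0) stop("threshold t must be nonnegative", call. = FALSE)
  .svt_cpp(as.matrix(M), t)
}

#' Constrained proximal operator of the stacked nuclear norm
#'
#' Solves `argmin_L 0.5 * ||L - M||_F^2 + t * ||L||_*` over (p+m) x p
#' matrices whose top p x p block is symmetric positive semidefinite — the
#' subproblem of the ADMM low-rank update that has no closed form. The top
#' block of `M` is symmetrized on entry. Solved by Dykstra's alternating
#' scheme between singular-value shrinkage and the cone projection, which
#' converges to the exact constrained proximal point; the fixed-point
#' residual (relative Frobenius gap between the two half-steps) is reported.
#'
#' @inheritParams prox_l1
#' @param p size of the constrained top block (0 disables the constraint,
#'   recovering [svd_soft_threshold()]).
#' @param tol convergence tolerance on the fixed-point residual.
#' @param max_iter inner iteration cap; non-convergence is flagged, with the
#'   best iterate returned.
#' @return list with `argmin`, `inner_iterations`, `inner_residual`,
#'   `converged`.
#' @export
prox_stacked_nuclear_psd <- function(M, t, p, tol = 1e-8, max_iter = 100) {
  if (t < 0) stop("threshold t must be nonnegative", call. = FALSE)
  .prox_nuc_psd_cpp(as.matrix(M), t, as.integer(p), tol, as.integer(max_iter))
}

#' Projection onto matrices with eigenvalues at or above a floor
#'
#' Symmetrizes `M`, then clips its eigenvalues at `floor`. With `floor = 0`
#' this is the Frobenius-nearest positive semidefinite matrix; a small
#' positive floor is used as a strict-feasibility guard inside the solver.
#'
#' @param M symmetric matrix (symmetrized if slightly off).
#' @param floor eigenvalue floor.
#' @return symmetric matrix with smallest eigenvalue `>= floor`.
#' @export
project_psd <- function(M, floor = 0) {
  .project_psd_cpp(as.matrix(M), floor)
}
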