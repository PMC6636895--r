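#' Parameter set of a latent conditional Gaussian graphical model
#'
#' Bundles the four estimated matrices of the model: the sparse and low-rank
#' components of the conditional precision over the outputs (`S_X`, `L_X`,
#' both p x p symmetric) and of the input-output interaction block (`S_ZX`,
#' `L_ZX`, both m x p). The conditional law of the outputs given the inputs
#' only depends on the differences `S_X - L_X` and `S_ZX - L_ZX`; the split
#' into a sparse and a low-rank part is what the penalized estimators recover.
#'
#' A parameter set is *feasible* when `S_X - L_X` is positive definite and
#' `L_X` is positive semidefinite. The stacked (p+m) x p views
#' `S = rbind(S_X, S_ZX)` and `L = rbind(L_X, L_ZX)` are the objects the
#' l1 and nuclear-norm penalties act on.
#'
#' @param S_X p x p symmetric matrix, sparse component of the conditional
#'   precision of the outputs.
#' @param L_X p x p symmetric positive semidefinite matrix, low-rank
#'   component absorbing marginalized latent variables.
#' @param S_ZX m x p matrix of direct input effects (m = 0 allowed).
#' @param L_ZX m x p matrix, low-rank component of the input block.
#' @param check validate symmetry (tolerance `1e-10`) and shapes.
#' @return An object of class `crf_params`.
#' @export
crf_params <- function(S_X, L_X = NULL, S_ZX = NULL, L_ZX = NULL, check = TRUE) {
  S_X <- as.matrix(S_X)
  p <- nrow(S_X)
  if (is.null(L_X)) L_X <- matrix(0, p, p)
  if (is.null(S_ZX)) S_ZX <- matrix(0, 0, p)
  if (is.null(L_ZX)) L_ZX <- matrix(0, nrow(S_ZX), p)
  L_X <- as.matrix(L_X); S_ZX <- as.matrix(S_ZX); L_ZX <- as.matrix(L_ZX)
  m <- nrow(S_ZX)
  if (check) {
    if (ncol(S_X) != p) stop("S_X must be square", call. = FALSE)
    if (!all(dim(L_X) == c(p, p))) stop("L_X must be p x p", call. = FALSE)
    if (ncol(S_ZX) != p || !all(dim(L_ZX) == c(m, p)))
      stop("S_ZX and L_ZX must be m x p", call. = FALSE)
    if (max(abs(S_X - t(S_X))) > 1e-10) stop("S_X is not symmetric", call. = FALSE)
    if (max(abs(L_X - t(L_X))) > 1e-10) stop("L_X is not symmetric", call. = FALSE)
    if (!all(is.finite(S_X)) || !all(is.finite(L_X)) ||
        !all(is.finite(S_ZX)) || !all(is.finite(L_ZX)))
      stop("parameters contain non-finite values", call. = FALSE)
  }
  structure(
    list(S_X = (S_X + t(S_X)) / 2, L_X = (L_X + t(L_X)) / 2,
         S_ZX = S_ZX, L_ZX = L_ZX, p = p, m = m),
    class = "crf_params"
  )
}

#' @export
print.crf_params <- function(x, ...) {
  cat(sprintf("<crf_params> p = %d outputs, m = %d inputs\n", x$p, x$m))
  cat(sprintf("  feasible: %s; rank(L_X) (svals > 1e-8): %d\n",
              is_feasible(x),
              sum(svd(x$L_X)$d > 1e-8)))
  invisible(x)
}

#' Stacked penalty views of a parameter set
#'
#' @param params a [crf_params()] object.
#' @return `stacked_S`/`stacked_L`: the (p+m) x p matrices the l1 and nuclear
#'   penalties are applied to.
#' @export
stacked_S <- function(params) rbind(params$S_X, params$S_ZX)

#' @rdname stacked_S
#' @export
stacked_L <- function(params) rbind(params$L_X, params$L_ZX)

#' Feasibility of a parameter set
#'
#' Checks `S_X - L_X` positive definite and `L_X` positive semidefinite
#' (eigenvalues >= -1e-10).
#'
#' @param params a [crf_params()] object.
#' @param tol eigenvalue tolerance for the semidefinite check.
#' @return logical scalar.
#' @export
is_feasible <- function(params, tol = 1e-10) {
  ev_r <- eigen(params$S_X - params$L_X, symmetric = TRUE, only.values = TRUE)$values
  ev_l <- eigen(params$L_X, symmetric = TRUE, only.values = TRUE)$values
  min(ev_r) > 0 && min(ev_l) >= -tol
}

stop_if_infeasible <- function(params) {
  if (!is_feasible(params))
    stop("infeasible parameters: need S_X - L_X positive definite and L_X PSD",
         call. = FALSE)
  invisible(params)
}

#' Sufficient statistics of a conditional Gaussian model
#'
#' Forms the 1/n-scaled second-moment matrices of the input block `Y_Z`
#' (n x m) and output block `Y_X` (n x p): `Sigma_Z = Y_Z'Y_Z / n`,
#' `Sigma_X = Y_X'Y_X / n`, `Sigma_ZX = Y_Z'Y_X / n`. The model assumes
#' zero-mean data, so no centering is applied here; use `center = TRUE`
#' (or [quantile_normalize()]) upstream for real data.
#'
#' @param Y_X n x p numeric matrix (or data frame) of outputs.
#' @param Y_Z n x m numeric matrix of inputs; may have zero columns.
#' @param center subtract column means before forming the moments
#'   (default `FALSE`: simulator output is generated zero-mean).
#' @param standardize divide columns by their standard deviation (implies
#'   centering of the scale estimate only if `center` is also set).
#' @return An object of class `crf_stats` with fields `Sigma_Z`, `Sigma_X`,
#'   `Sigma_ZX`, `n`, `p`, `m`.
#' @export
suff_stats <- function(Y_X, Y_Z = NULL, center = FALSE, standardize = FALSE) {
  Y_X <- as.matrix(Y_X)
  if (is.null(Y_Z)) Y_Z <- matrix(0, nrow(Y_X), 0) else Y_Z <- as.matrix(Y_Z)
  n <- nrow(Y_X)
  if (n < 1) stop("need at least one sample", call. = FALSE)
  if (nrow(Y_Z) != n)
    stop(sprintf("row counts differ: Y_X has %d, Y_Z has %d", n, nrow(Y_Z)),
         call. = FALSE)
  if (!all(is.finite(Y_X)) || !all(is.finite(Y_Z)))
    stop("data contain non-finite values", call. = FALSE)
  scale_block <- function(M) {
    if (center) M <- sweep(M, 2, colMeans(M), "-")
    if (standardize && ncol(M) > 0) {
      s <- sqrt(colMeans(sweep(M, 2, colMeans(M), "-")^2))
      if (any(s == 0)) stop("cannot standardize a constant column", call. = FALSE)
      M <- sweep(M, 2, s, "/")
    }
    M
  }
  Y_X <- scale_block(Y_X); Y_Z <- scale_block(Y_Z)
  structure(
    list(Sigma_Z = crossprod(Y_Z) / n,
         Sigma_X = crossprod(Y_X) / n,
         Sigma_ZX = crossprod(Y_Z, Y_X) / n,
         n = n, p = ncol(Y_X), m = ncol(Y_Z)),
    class = "crf_stats"
  )
}

#' Assemble a `crf_stats` object from precomputed moment matrices
#'
#' @param Sigma_X p x p PSD matrix.
#' @param Sigma_Z m x m PSD matrix.
#' @param Sigma_ZX m x p matrix.
#' @param n sample count the moments were computed from.
#' @return A `crf_stats` object.
#' @export
as_crf_stats <- function(Sigma_X, Sigma_Z = NULL, Sigma_ZX = NULL, n = 1L) {
  Sigma_X <- as.matrix(Sigma_X)
  p <- ncol(Sigma_X)
  if (is.null(Sigma_Z)) Sigma_Z <- matrix(0, 0, 0)
  Sigma_Z <- as.matrix(Sigma_Z)
  m <- ncol(Sigma_Z)
  if (is.null(Sigma_ZX)) Sigma_ZX <- matrix(0, m, p)
  Sigma_ZX <- as.matrix(Sigma_ZX)
  if (max(abs(Sigma_X - t(Sigma_X))) > 1e-8 ||
      (m > 0 && max(abs(Sigma_Z - t(Sigma_Z))) > 1e-8))
    stop("moment matrices must be symmetric", call. = FALSE)
  structure(list(Sigma_Z = (Sigma_Z + t(Sigma_Z)) / 2,
                 Sigma_X = (Sigma_X + t(Sigma_X)) / 2,
                 Sigma_ZX = Sigma_ZX, n = as.integer(n), p = p, m = m),
            class = "crf_stats")
}

#' @export
print.crf_stats <- function(x, ...) {
  cat(sprintf("<crf_stats> n = %d, p = %d, m = %d\n", x$n, x$p, x$m))
  invisible(x)
}

#' Joint second-moment matrix over (Z, X)
#'
#' Stacks the blocks into the (m+p) x (m+p) matrix used by the joint
#' (unconditional) estimators and the SDP objective.
#'
#' @param stats a [suff_stats()] object.
#' @return A symmetric (m+p) x (m+p) matrix.
#' @export
joint_second_moment <- function(stats) {
  rbind(cbind(stats$Sigma_Z, stats$Sigma_ZX),
        cbind(t(stats$Sigma_ZX), stats$Sigma_X))
}
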