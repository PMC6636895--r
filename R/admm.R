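#' Options for the ADMM solver
#'
#' @param rho initial augmented-Lagrangian parameter.
#' @param adaptive_rho residual-balancing adaptation of `rho` (factor 2 when
#'   primal and dual residuals differ by more than 10x).
#' @param tol_primal,tol_dual relative stopping tolerances on the primal and
#'   dual residuals.
#' @param max_iter outer iteration cap.
#' @param inner_tol tolerance of the inexact likelihood subproblem solve.
#' @param inner_sweeps alternation sweeps of the likelihood subproblem.
#' @param prox_max_iter iteration cap of the constrained nuclear prox.
#' @param pd_floor eigenvalue floor keeping `S_X - L_X` strictly positive
#'   definite.
#' @return list of class `solver_options`.
#' @export
solver_options <- function(rho = 1.0, adaptive_rho = TRUE,
                           tol_primal = 1e-5, tol_dual = 1e-5,
                           max_iter = 1000, inner_tol = 1e-9,
                           inner_sweeps = 8, prox_max_iter = 100,
                           pd_floor = 1e-8) {
  stopifnot(rho > 0, tol_primal > 0, tol_dual > 0, max_iter >= 1,
            inner_tol > 0, pd_floor > 0)
  structure(list(rho = rho, adaptive_rho = adaptive_rho,
                 tol_primal = tol_primal, tol_dual = tol_dual,
                 max_iter = as.integer(max_iter), inner_tol = inner_tol,
                 inner_sweeps = as.integer(inner_sweeps),
                 prox_max_iter = as.integer(prox_max_iter),
                 pd_floor = pd_floor),
            class = "solver_options")
}

#' Fit the penalized conditional model by ADMM
#'
#' Minimizes the penalized negative conditional log-likelihood
#' `-loglik(S - L) + lambda * (gamma * ||S||_1 + (1 - gamma) * ||L||_*)`
#' subject to `S_X - L_X` positive definite and `L_X` PSD, by a multi-block
#' ADMM: a consensus variable carries the smooth likelihood block (updated by
#' eigendecomposition-based closed forms), the sparse block is a soft
#' threshold, and the low-rank block is the iterative constrained nuclear
#' prox ([prox_stacked_nuclear_psd()]). With `m = 0` this is the low-rank
#' plus sparse problem on the outputs alone.
#'
#' @param stats a [suff_stats()] object.
#' @param lambda positive penalty level.
#' @param gamma sparse/low-rank trade-off in (0, 1).
#' @param options a [solver_options()] list.
#' @param warm_start optional previous fit (a `crf_fit` or [crf_params()])
#'   used to initialize the iterates.
#' @param fix_L_zero freeze the low-rank component at zero (sparse-only
#'   estimators).
#' @param penalize_diagonal include `diag(S_X)` in the l1 penalty.
#' @return An object of class `crf_fit`: `params` ([crf_params()]),
#'   `objective`, `iterations`, `converged`, residual traces, `lambda`,
#'   `gamma`, and solver diagnostics.
#' @export
fit_admm <- function(stats, lambda, gamma, options = solver_options(),
                     warm_start = NULL, fix_L_zero = FALSE,
                     penalize_diagonal = TRUE) {
  stopifnot(inherits(stats, "crf_stats"))
  if (lambda < 0) stop("lambda must be nonnegative", call. = FALSE)
  if (gamma <= 0 || gamma >= 1) stop("gamma must lie in (0, 1)", call. = FALSE)
  warm <- NULL
  if (!is.null(warm_start)) {
    ws <- if (inherits(warm_start, "crf_fit")) warm_start$params else warm_start
    warm <- list(S = rbind(ws$S_X, ws$S_ZX), L = rbind(ws$L_X, ws$L_ZX))
    if (inherits(warm_start, "crf_fit") && !is.null(warm_start$dual))
      warm$U <- warm_start$dual
  }
  res <- .admm_fit_cpp(stats$Sigma_Z, stats$Sigma_X, stats$Sigma_ZX,
                       lambda, gamma,
                       options$rho, options$adaptive_rho,
                       options$tol_primal, options$tol_dual,
                       options$max_iter, options$inner_tol,
                       options$inner_sweeps, options$prox_max_iter,
                       options$pd_floor, fix_L_zero, penalize_diagonal,
                       warm)
  params <- crf_params(res$S_X, res$L_X, res$S_ZX, res$L_ZX, check = FALSE)
  obj <- objective_value(params, stats, lambda, gamma,
                         penalize_diagonal = penalize_diagonal)
  structure(
    list(params = params, objective = obj,
         iterations = res$iterations, converged = res$converged,
         primal_residuals = res$primal_residuals,
         dual_residuals = res$dual_residuals,
         objective_trace = res$objective_trace,
         prox_inner_iterations = res$prox_inner_iterations,
         rho_final = res$rho_final, dual = res$U,
         lambda = lambda, gamma = gamma,
         fix_L_zero = fix_L_zero, penalize_diagonal = penalize_diagonal,
         n = stats$n, p = stats$p, m = stats$m),
    class = "crf_fit")
}

#' @export
print.crf_fit <- function(x, ...) {
  cat(sprintf(paste0("<crf_fit> p = %d, m = %d, lambda = %.4g, gamma = %.3g\n",
                     "  %s after %d iterations, objective %.6g\n"),
              x$p, x$m, x$lambda, x$gamma,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$objective))
  invisible(x)
}

#' Stationarity diagnostics of a fitted model
#'
#' Measures how far a fit is from satisfying the first-order optimality
#' conditions of the penalized objective. Two complementary views are
#' reported: natural-map (proximal fixed-point) residuals for the sparse and
#' low-rank blocks, which account for the PSD cone exactly, and elementwise
#' l1 subgradient violations (`|grad| <= lambda * gamma` off the support,
#' equality on it).
#'
#' @param fit a `crf_fit` object.
#' @param stats the [suff_stats()] the fit was computed from.
#' @param lambda,gamma penalty configuration (defaults taken from the fit).
#' @param step proximal step length of the natural map.
#' @return list with `prox_residual_S`, `prox_residual_L`,
#'   `l1_max_violation`, `grad_norm` and the full violation matrix.
#' @export
kkt_report <- function(fit, stats, lambda = fit$lambda, gamma = fit$gamma,
                       step = 1) {
  params <- fit$params
  g <- crf_gradient(params, stats)      # gradient of the log-likelihood
  gS <- -rbind(g$S_X, g$S_ZX)           # gradient of the smooth loss wrt S
  S <- stacked_S(params); L <- stacked_L(params)
  mask <- NULL
  if (!fit$penalize_diagonal) {
    mask <- matrix(0, nrow(S), ncol(S))
    mask[cbind(seq_len(params$p), seq_len(params$p))] <- 1
  }
  S_next <- prox_l1(S - step * gS, step * lambda * gamma, mask)
  res_S <- max(abs(S - S_next))
  gL <- -gS                              # smooth loss gradient wrt L
  pr <- prox_stacked_nuclear_psd(L - step * gL, step * lambda * (1 - gamma),
                                 params$p, tol = 1e-10, max_iter = 500)
  res_L <- max(abs(L - pr$argmin))
  # elementwise l1 subgradient check
  on_support <- abs(S) > 1e-8
  viol <- matrix(0, nrow(S), ncol(S))
  viol[!on_support] <- pmax(abs(gS[!on_support]) - lambda * gamma, 0)
  viol[on_support] <- abs(gS[on_support] + lambda * gamma * sign(S[on_support]))
  if (!is.null(mask)) viol[mask == 1] <- abs(gS[mask == 1])
  list(prox_residual_S = res_S, prox_residual_L = res_L,
       l1_max_violation = max(viol), grad_norm = max(abs(gS)),
       l1_violations = viol)
}
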