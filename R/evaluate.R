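edge_key <- function(edges) paste(edges$i, edges$j, sep = "-")

#' Precision and recall of a recovered edge set
#'
#' Both arguments are undirected off-diagonal edge sets (tibbles with
#' columns `i < j`, as returned by [support_edges()]). Precision of an empty
#' estimate is 1 by convention, so precision/recall curves start at recall 0.
#'
#' @param est_support estimated edge set.
#' @param true_support true edge set (must be nonempty).
#' @return tibble with `precision` and `recall`.
#' @export
precision_recall <- function(est_support, true_support) {
  if (nrow(true_support) == 0)
    stop("true support is empty: precision/recall undefined", call. = FALSE)
  inter <- length(intersect(edge_key(est_support), edge_key(true_support)))
  tibble::tibble(
    precision = if (nrow(est_support) == 0) 1 else inter / nrow(est_support),
    recall = inter / nrow(true_support))
}

#' Precision/recall curve of a regularization path
#'
#' Scores the sparse output block of every fit on a path against the true
#' edge set; one point per (gamma, lambda).
#'
#' @param path a [regularization_path()] tibble.
#' @param truth a [sim_model()] object, a true `S_X` matrix, or an edge-set
#'   tibble.
#' @param threshold support threshold applied to the estimates.
#' @return tibble with `gamma`, `lambda`, `n_edges`, `precision`, `recall`.
#' @export
pr_curve <- function(path, truth, threshold = 1e-6) {
  true_edges <- true_edge_set(truth)
  purrr::map_dfr(seq_len(nrow(path)), function(r) {
    fit <- path$fit[[r]]
    if (is.null(fit)) return(tibble::tibble())
    est <- support_edges(fit$params$S_X, threshold)
    pr <- precision_recall(est, true_edges)
    tibble::tibble(gamma = path$gamma[r], lambda = path$lambda[r],
                   n_edges = nrow(est),
                   precision = pr$precision, recall = pr$recall)
  })
}

true_edge_set <- function(truth) {
  if (inherits(truth, "sim_model")) return(support_edges(truth$S_X, 1e-12))
  if (is.matrix(truth)) return(support_edges(truth, 1e-12))
  stopifnot(all(c("i", "j") %in% names(truth)))
  truth
}

# Monotonized upper envelope of precision as a function of recall:
# env(r) = max precision over curve points with recall >= r.
pr_envelope <- function(curve) {
  ord <- order(curve$recall, curve$precision)
  r <- curve$recall[ord]; p <- curve$precision[ord]
  env <- rev(cummax(rev(p)))
  keep <- !duplicated(r, fromLast = TRUE)     # one point per recall level
  tibble::tibble(recall = r[keep], precision = env[keep])
}

#' Area under a precision/recall curve
#'
#' Trapezoidal area under the monotonized upper precision envelope, treating
#' precision as 0 beyond the largest achieved recall; a single-point curve
#' contributes its rectangular step.
#'
#' @param curve tibble with `precision` and `recall` columns (one gamma).
#' @return scalar in \[0, 1\].
#' @export
pr_auc <- function(curve) {
  if (nrow(curve) == 0) return(0)
  env <- pr_envelope(curve)
  r <- env$recall; p <- env$precision
  if (r[1] > 0) { r <- c(0, r); p <- c(p[1], p) }   # flat extension to 0
  sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Precisions at fixed recall levels
#'
#' Right-continuous interpolation of the monotonized envelope at the given
#' recall levels: the precision at the smallest achieved recall at or above
#' each level, 0 beyond the maximum achieved recall.
#'
#' @param curve tibble with `precision` and `recall`.
#' @param recalls recall levels to report.
#' @return tibble with `recall` and `precision`.
#' @export
fixed_recall_precision <- function(curve, recalls = seq(0.1, 1, by = 0.1)) {
  env <- pr_envelope(curve)
  prec <- vapply(recalls, function(r) {
    ok <- env$recall >= r - 1e-12
    if (!any(ok)) 0 else max(env$precision[ok])
  }, numeric(1))
  tibble::tibble(recall = recalls, precision = prec)
}

#' Volume under the precision/recall surface
#'
#' Integrates the per-gamma AUC over the gamma grid by the trapezoid rule,
#' normalized by the gamma range, summarizing sensitivity to both tuning
#' parameters at once.
#'
#' @param curves tibble from [pr_curve()] covering at least two gamma
#'   values.
#' @return scalar in \[0, 1\].
#' @export
pr_vus <- function(curves) {
  aucs <- curves |>
    dplyr::group_by(.data$gamma) |>
    dplyr::group_modify(~ tibble::tibble(auc = pr_auc(.x))) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gamma)
  if (nrow(aucs) < 2)
    stop("need at least two gamma values for a surface", call. = FALSE)
  g <- aucs$gamma; a <- aucs$auc
  sum(diff(g) * (head(a, -1) + tail(a, -1)) / 2) / (max(g) - min(g))
}

#' Sign and rank consistency of a fit against the ground truth
#'
#' Reports whether the fitted sparse component reproduces the exact sign
#' pattern of the truth (at the support threshold), whether the fitted
#' low-rank component has the true rank, the PSD status of its output
#' block, and the error norms `max(||S_hat - S*||_inf, ||L_hat - L*||_2)`.
#'
#' @param fit a `crf_fit`.
#' @param truth a [sim_model()] object.
#' @param threshold support threshold.
#' @return tibble with one row of diagnostics.
#' @export
consistency_check <- function(fit, truth, threshold = 1e-6) {
  S_hat <- stacked_S(fit$params); L_hat <- stacked_L(fit$params)
  S_true <- rbind(truth$S_X, truth$S_ZX)
  L_true <- rbind(truth$L_X, truth$L_ZX)
  sgn <- function(M) { out <- sign(M); out[abs(M) <= threshold] <- 0; out }
  sign_match <- identical(sgn(S_hat), sgn(S_true))
  f1 <- sign_f1(fit$params$S_X, truth$S_X, threshold)
  tibble::tibble(
    sign_agreement = sign_match,
    sx_sign_f1 = f1,
    rank_match = l_rank(L_hat) == qr(L_true)$rank,
    rank_L_hat = l_rank(L_hat),
    lx_psd = min(eigen(fit$params$L_X, symmetric = TRUE,
                       only.values = TRUE)$values) >= -1e-8,
    err_S_inf = max(abs(S_hat - S_true)),
    err_L_2 = if (nrow(L_true) > 0) max(svd(L_hat - L_true)$d) else 0)
}

# F1 score of the off-diagonal support of the output block
sign_f1 <- function(S_hat, S_true, threshold = 1e-6) {
  est <- support_edges(S_hat, threshold)
  tru <- support_edges(S_true, 1e-12)
  inter <- length(intersect(edge_key(est), edge_key(tru)))
  if (nrow(est) == 0 || inter == 0) return(0)
  prec <- inter / nrow(est); rec <- inter / nrow(tru)
  2 * prec * rec / (prec + rec)
}

#' Identifiability diagnostics of a ground-truth model
#'
#' Computable proxies for the rank-sparsity incoherence quantities that
#' govern when the sparse + low-rank decomposition is well-posed:
#' `mu_bound`, the maximum number of nonzeros in any row or column of the
#' stacked sparse truth (a sparsity-pattern bound), and `xi_bound`,
#' `2 * max_i ||P_U e_i||`, twice the largest coordinate leverage of the
#' column space of the stacked low-rank truth (an incoherence bound: small
#' when latent effects are diffuse, 2 when a basis vector lies in the
#' column space). These are documented upper-bound proxies, not the exact
#' variational quantities.
#'
#' @param truth a [sim_model()] object.
#' @return tibble with `max_degree`, `mu_bound`, `xi_bound`, `rank_L`.
#' @export
identifiability_bounds <- function(truth) {
  S <- rbind(truth$S_X, truth$S_ZX)
  nz <- abs(S) > 1e-12
  mu_bound <- max(max(rowSums(nz)), max(colSums(nz)))
  L <- rbind(truth$L_X, truth$L_ZX)
  r <- qr(L)$rank
  if (r == 0) xi_bound <- 0 else {
    U <- svd(L, nu = r, nv = 0)$u
    xi_bound <- 2 * max(sqrt(rowSums(U^2)))
  }
  deg <- max(colSums(abs(truth$S_X) > 1e-12) - 1)
  tibble::tibble(max_degree = deg, mu_bound = mu_bound,
                 xi_bound = xi_bound, rank_L = r)
}
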