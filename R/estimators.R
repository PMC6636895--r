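#' Build sufficient statistics from a samples-by-variables data frame
#'
#' Splits the columns of `data` into input (Z) and output (X) blocks by
#' explicit names or a prefix — no positional guessing — and forms the
#' second-moment matrices.
#'
#' @param data data frame or matrix, one row per sample.
#' @param z_cols character vector of input column names; all remaining
#'   columns are outputs. Defaults to the `z_cols` attribute that simulated
#'   datasets carry.
#' @param z_prefix alternatively, a name prefix identifying input columns.
#' @param center,standardize column preprocessing before forming moments
#'   (see [suff_stats()]); defaults off, as simulator output is zero-mean.
#' @return a [suff_stats()] object.
#' @export
crf_stats_from_data <- function(data, z_cols = NULL, z_prefix = NULL,
                                center = FALSE, standardize = FALSE) {
  if (inherits(data, "crf_stats")) return(data)
  df <- as.data.frame(data)
  if (is.null(z_cols)) {
    if (!is.null(z_prefix))
      z_cols <- names(df)[startsWith(names(df), z_prefix)]
    else z_cols <- attr(data, "z_cols")
  }
  if (is.null(z_cols)) z_cols <- character(0)
  if (!all(z_cols %in% names(df)))
    stop("unknown input columns: ",
         paste(setdiff(z_cols, names(df)), collapse = ", "), call. = FALSE)
  x_cols <- setdiff(names(df), z_cols)
  suff_stats(as.matrix(df[x_cols]), as.matrix(df[z_cols]),
             center = center, standardize = standardize)
}

#' Off-diagonal support of an estimated output precision
#'
#' Undirected edge set of the sparse component: off-diagonal entries whose
#' symmetrized magnitude `max(|S_ij|, |S_ji|)` exceeds `threshold`.
#'
#' @param S_X p x p matrix (a fit's sparse component or a truth).
#' @param threshold magnitude threshold (solver-tolerance scale).
#' @return tibble with columns `i < j`, one row per edge.
#' @export
support_edges <- function(S_X, threshold = 1e-6) {
  S_X <- as.matrix(S_X)
  A <- pmax(abs(S_X), abs(t(S_X)))
  idx <- which(upper.tri(A) & A > threshold, arr.ind = TRUE)
  tibble::tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
}

#' Numerical rank of a low-rank component
#'
#' Number of singular values above `tol_rel` times the largest one.
#'
#' @param L matrix.
#' @param tol_rel relative singular-value threshold.
#' @return integer rank (0 for a zero matrix).
#' @export
l_rank <- function(L, tol_rel = 1e-6) {
  d <- svd(as.matrix(L))$d
  if (length(d) == 0 || d[1] <= 0) return(0L)
  sum(d > tol_rel * d[1])
}

#' Fit one of the four structure-learning methods
#'
#' Uniform front-end over the estimators compared in the benchmark:
#' * `lscggm` — sparse + low-rank conditional model (the full machinery);
#' * `scggm` — sparse conditional model, low-rank component frozen at zero;
#' * `lrps` — low-rank plus sparse decomposition of the *joint* precision
#'   over (Z, X), fitted with the m = 0 machinery on the joint second-moment
#'   matrix; the conditional blocks are then extracted as submatrices;
#' * `glasso` — graphical lasso on the joint precision (`lrps` with the
#'   low-rank component frozen).
#'
#' @param data data frame (see [crf_stats_from_data()]) or a [suff_stats()]
#'   object.
#' @param method one of `"lscggm"`, `"scggm"`, `"lrps"`, `"glasso"`.
#' @param lambda,gamma penalty configuration. `gamma` is ignored by the
#'   sparse-only methods (`scggm`, `glasso`), whose l1 weight is
#'   `lambda * gamma` so that sparse-only fits nest the full methods.
#' @param options a [solver_options()] list.
#' @param warm_start optional previous fit of the same method.
#' @param ... passed to [crf_stats_from_data()].
#' @return A `crf_fit`; for the joint methods the `params` are the extracted
#'   conditional blocks and `joint_params` carries the full (m+p) fit.
#' @export
fit_method <- function(data, method = c("lscggm", "scggm", "lrps", "glasso"),
                       lambda, gamma = 0.5, options = solver_options(),
                       warm_start = NULL, ...) {
  method <- match.arg(method)
  stats <- crf_stats_from_data(data, ...)
  p <- stats$p; m <- stats$m
  if (method %in% c("lscggm", "scggm")) {
    fit <- fit_admm(stats, lambda, gamma, options = options,
                    warm_start = warm_start,
                    fix_L_zero = method == "scggm")
    fit$method <- method
    return(fit)
  }
  # joint methods: m = 0 machinery on the (m+p) second-moment matrix
  joint_stats <- as_crf_stats(joint_second_moment(stats), n = stats$n)
  ws <- NULL
  if (!is.null(warm_start) && !is.null(warm_start$joint_fit))
    ws <- warm_start$joint_fit
  jfit <- fit_admm(joint_stats, lambda, gamma, options = options,
                   warm_start = ws, fix_L_zero = method == "glasso")
  zi <- seq_len(m); xi <- m + seq_len(p)
  params <- crf_params(jfit$params$S_X[xi, xi],
                       jfit$params$L_X[xi, xi],
                       jfit$params$S_X[zi, xi, drop = FALSE],
                       jfit$params$L_X[zi, xi, drop = FALSE],
                       check = FALSE)
  fit <- jfit
  fit$joint_fit <- jfit
  fit$joint_params <- jfit$params
  fit$params <- params
  fit$method <- method
  fit$p <- p; fit$m <- m
  fit
}

#' Smallest penalty emptying the estimated support
#'
#' Bisection search (log scale) for the smallest `lambda` at which the fit
#' has no off-diagonal edges in its sparse output block; the default path
#' grid is log-spaced over `[lambda_max / 100, lambda_max]`.
#'
#' @inheritParams fit_method
#' @param threshold support threshold (see [support_edges()]).
#' @param rel_tol bisection stopping tolerance on the log scale.
#' @return positive scalar.
#' @export
lambda_max <- function(data, method = "lscggm", gamma = 0.5,
                       options = solver_options(tol_primal = 1e-3,
                                                tol_dual = 1e-3,
                                                max_iter = 150),
                       threshold = 1e-6, rel_tol = 0.05, ...) {
  stats <- crf_stats_from_data(data, ...)
  prev <- NULL
  n_edges <- function(l) {
    f <- fit_method(stats, method, lambda = l, gamma = gamma,
                    options = options, warm_start = prev)
    prev <<- f
    nrow(support_edges(f$params$S_X, threshold))
  }
  hi <- 1
  while (n_edges(hi) > 0 && hi < 2^16) hi <- hi * 2
  lo <- hi / 2
  while (lo > 2^-16 && n_edges(lo) == 0) { hi <- lo; lo <- lo / 2 }
  for (i in 1:8) {
    mid <- sqrt(lo * hi)
    if (n_edges(mid) == 0) hi <- mid else lo <- mid
    if (log(hi / lo) < rel_tol) break
  }
  hi
}

#' Regularization path over a penalty grid
#'
#' Fits the chosen method at every (lambda, gamma) combination, warm-started
#' along decreasing lambda within each gamma. Individual non-convergences
#' are recorded and the path continues.
#'
#' @inheritParams fit_method
#' @param lambdas decreasing positive grid; when `NULL`, a per-gamma grid is
#'   used: one bisection fixes `lambda_max` at the median gamma, per-gamma
#'   maxima scale inversely with gamma (the effective l1 weight is
#'   `lambda * gamma`), and each grid is log-spaced with `n_lambda` points
#'   over `[lambda_max / 100, lambda_max]`.
#' @param gammas gamma grid in (0, 1) (singleton for the sparse-only
#'   methods).
#' @param n_lambda grid size when `lambdas` is `NULL`.
#' @param warm_start warm-start consecutive fits along the path.
#' @param support_threshold threshold for the reported edge counts.
#' @return tibble of class `crf_path`: one row per (gamma, lambda) with the
#'   fit in a list-column plus `n_edges`, `rank_L`, `objective`, `converged`.
#' @export
regularization_path <- function(data,
                                method = c("lscggm", "scggm", "lrps", "glasso"),
                                lambdas = NULL, gammas = 0.5, n_lambda = 25,
                                options = solver_options(),
                                warm_start = TRUE,
                                support_threshold = 1e-6, ...) {
  method <- match.arg(method)
  stats <- crf_stats_from_data(data, ...)
  grids <- NULL
  if (is.null(lambdas)) {
    g_ref <- sort(gammas)[ceiling(length(gammas) / 2)]
    lmax_ref <- lambda_max(stats, method = method, gamma = g_ref)
    grids <- lapply(gammas, function(g) {
      lmax <- lmax_ref * g_ref / g
      exp(seq(log(lmax), log(lmax / 100), length.out = n_lambda))
    })
  } else {
    lambdas <- sort(lambdas, decreasing = TRUE)
    grids <- rep(list(lambdas), length(gammas))
  }
  rows <- purrr::map(seq_along(gammas), function(gi) {
    g <- gammas[gi]
    prev <- NULL
    purrr::map(grids[[gi]], function(l) {
      fit <- tryCatch(
        fit_method(stats, method, lambda = l, gamma = g, options = options,
                   warm_start = if (warm_start) prev else NULL),
        error = function(e) NULL)
      if (!is.null(fit)) prev <<- fit
      n_edges <- if (is.null(fit)) NA_integer_ else
        nrow(support_edges(fit$params$S_X, support_threshold))
      rank_L <- if (is.null(fit)) NA_integer_ else
        l_rank(stacked_L(fit$params))
      objective <- if (is.null(fit)) NA_real_ else fit$objective
      converged <- isTRUE(fit$converged)
      tibble::tibble(
        gamma = g, lambda = l, fit = list(fit),
        n_edges = n_edges, rank_L = rank_L,
        objective = objective, converged = converged)
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  attr(out, "method") <- method
  attr(out, "support_threshold") <- support_threshold
  class(out) <- c("crf_path", class(out))
  out
}
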