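#' Complementary-pairs stability selection along a penalty path
#'
#' Draws `B` complementary pairs of disjoint half-samples, fits the
#' regularization path on each of the `2B` subsamples, and counts an edge as
#' selected by a subsample if it appears anywhere along the lambda path
#' ("pointwise" max-over-path selection). The inclusion probability of an
#' edge is the fraction of subsamples selecting it. The selection threshold
#' `tau` is the smallest value at which the expected number of falsely
#' selected edges, bounded by `q^2 / ((2 tau - 1) * p_cand)` with `q` the
#' average per-subsample selected-set size and `p_cand = p (p - 1) / 2`
#' candidate edges, stays within `error_budget`.
#'
#' @param data samples-by-variables data frame (see
#'   [crf_stats_from_data()]); subsampling needs the raw data, not moments.
#' @param method,gammas,lambdas,options,support_threshold passed to
#'   [regularization_path()]; `gammas` must be a single value here.
#' @param B number of complementary pairs (each contributes two disjoint
#'   subsamples of size `floor(n / 2)`).
#' @param tau fixed inclusion threshold in (0.5, 1]; when `NULL` (default)
#'   it is calibrated from `error_budget`.
#' @param error_budget bound on the expected number of false discoveries.
#' @param seed base seed; per-pair seeds are derived from it.
#' @param z_cols,z_prefix column roles, as in [crf_stats_from_data()].
#' @param per_lambda count selection per lambda value instead of
#'   max-over-path, and use the most selective single lambda.
#' @return list of class `stability_result`: `probabilities` (tibble of
#'   edges and inclusion probabilities), `selected` (edge tibble), `tau`,
#'   `q`, `B`, `ev_bound`, and the node count `p`.
#' @export
stability_select <- function(data, method = "lscggm", gammas = 0.5,
                             lambdas = NULL, B = 50, tau = NULL,
                             error_budget = 1, seed = 1,
                             options = solver_options(tol_primal = 1e-4,
                                                      tol_dual = 1e-4,
                                                      max_iter = 300),
                             support_threshold = 1e-6,
                             z_cols = NULL, z_prefix = NULL,
                             per_lambda = FALSE) {
  stopifnot(length(gammas) == 1, B >= 1)
  df <- as.data.frame(data)
  if (is.null(z_cols) && is.null(z_prefix)) z_cols <- attr(data, "z_cols")
  n <- nrow(df)
  if (n < 4) stop("need at least 4 samples to split", call. = FALSE)
  half <- floor(n / 2)
  if (is.null(lambdas)) {
    lmax <- lambda_max(crf_stats_from_data(df, z_cols = z_cols,
                                           z_prefix = z_prefix),
                       method = method, gamma = gammas)
    lambdas <- exp(seq(log(lmax), log(lmax / 100), length.out = 15))
  }
  stats0 <- crf_stats_from_data(df, z_cols = z_cols, z_prefix = z_prefix)
  p <- stats0$p
  p_cand <- p * (p - 1) / 2
  counts <- new.env(parent = emptyenv())
  sizes <- numeric(0)
  for (b in seq_len(B)) {
    set.seed((seed + 7919L * b) %% 2147483629L)
    perm <- sample(n)
    halves <- list(perm[seq_len(half)], perm[half + seq_len(half)])
    for (idx in halves) {
      path <- regularization_path(df[idx, , drop = FALSE], method = method,
                                  lambdas = lambdas, gammas = gammas,
                                  options = options,
                                  support_threshold = support_threshold,
                                  z_cols = z_cols, z_prefix = z_prefix)
      sel <- unique(unlist(purrr::map(path$fit, function(f) {
        if (is.null(f)) return(character(0))
        e <- support_edges(f$params$S_X, support_threshold)
        edge_key(e)
      })))
      if (per_lambda) {
        per <- purrr::map(path$fit, function(f) {
          if (is.null(f)) return(character(0))
          edge_key(support_edges(f$params$S_X, support_threshold))
        })
        sizes <- c(sizes, mean(lengths(per)))
      } else {
        sizes <- c(sizes, length(sel))
      }
      for (k in sel) assign(k, (if (exists(k, counts)) get(k, counts) else 0) + 1,
                            counts)
    }
  }
  keys <- ls(counts)
  probs <- if (length(keys) == 0) numeric(0) else
    vapply(keys, get, numeric(1), envir = counts) / (2 * B)
  ij <- if (length(keys) == 0) matrix(integer(0), 0, 2) else
    do.call(rbind, lapply(strsplit(keys, "-"), as.integer))
  prob_tbl <- tibble::tibble(i = ij[, 1], j = ij[, 2],
                             inclusion_probability = unname(probs)) |>
    dplyr::arrange(dplyr::desc(.data$inclusion_probability))
  q <- mean(sizes)
  ev_bound <- function(t) q^2 / ((2 * t - 1) * p_cand)
  if (is.null(tau)) {
    tau_star <- (q^2 / (error_budget * p_cand) + 1) / 2
    if (tau_star > 1) {
      warning("error budget unachievable with observed q = ",
              signif(q, 3), "; returning empty selection", call. = FALSE)
      tau <- Inf
    } else tau <- max(tau_star, 0.5 + 1e-9)
  }
  selected <- prob_tbl[prob_tbl$inclusion_probability >= tau - 1e-12, ,
                       drop = FALSE]
  structure(list(probabilities = prob_tbl, selected = selected,
                 tau = tau, q = q, B = B,
                 ev_bound = if (is.finite(tau)) ev_bound(tau) else NA_real_,
                 p = p, gamma = gammas, lambdas = lambdas),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(paste0("<stability_result> B = %d pairs, q = %.2f, ",
                     "tau = %.3f, %d edges selected (E(V) bound %.3g)\n"),
              x$B, x$q, x$tau, nrow(x$selected), x$ev_bound))
  invisible(x)
}

#' Expected-false-discovery bound of complementary-pairs selection
#'
#' The Meinshausen-Buhlmann bound `E(V) <= q^2 / ((2 tau - 1) * p_cand)`
#' for average selected-set size `q`, inclusion threshold `tau` and
#' `p_cand` candidate edges.
#'
#' @param q average selected-set size along the path.
#' @param p_cand number of candidate edges.
#' @param tau inclusion threshold in (0.5, 1].
#' @return scalar bound on the expected number of false discoveries.
#' @export
stability_ev_bound <- function(q, p_cand, tau) {
  stopifnot(tau > 0.5, tau <= 1)
  q^2 / ((2 * tau - 1) * p_cand)
}

#' Jaccard similarity of two undirected graphs
#'
#' `|E1 intersect E2| / |E1 union E2|` over the edge sets; 1 when both are
#' empty. Graphs are edge tibbles (columns `i`, `j`) or `stability_result`
#' objects; node label sets must agree when labels are attached.
#'
#' @param g1,g2 edge-set tibbles or `stability_result` objects.
#' @return scalar in \[0, 1\].
#' @export
jaccard_index <- function(g1, g2) {
  e1 <- if (inherits(g1, "stability_result")) g1$selected else g1
  e2 <- if (inherits(g2, "stability_result")) g2$selected else g2
  l1 <- attr(e1, "labels"); l2 <- attr(e2, "labels")
  if (!is.null(l1) && !is.null(l2) && !identical(sort(l1), sort(l2)))
    stop("node label sets differ", call. = FALSE)
  k1 <- edge_key(e1); k2 <- edge_key(e2)
  u <- length(union(k1, k2))
  if (u == 0) return(1)
  length(intersect(k1, k2)) / u
}

#' Pairwise similarity of selections across the gamma grid
#'
#' Jaccard index between the graphs selected at every pair of gamma values,
#' used to locate the "stable region": the longest contiguous run of gammas
#' whose pairwise similarities all reach `stable_threshold`.
#'
#' @param results list of `stability_result` objects (or edge tibbles),
#'   ordered by gamma.
#' @param gammas optional gamma values labelling the results.
#' @param stable_threshold similarity defining the stable region.
#' @return list with the symmetric `similarity` matrix (unit diagonal) and
#'   `stable_region`, the index range of the longest stable block.
#' @export
gamma_similarity <- function(results, gammas = NULL, stable_threshold = 0.9) {
  n <- length(results)
  if (n < 2) stop("need at least two gamma values", call. = FALSE)
  M <- diag(1, n)
  for (a in seq_len(n - 1))
    for (b in (a + 1):n)
      M[a, b] <- M[b, a] <- jaccard_index(results[[a]], results[[b]])
  if (!is.null(gammas)) dimnames(M) <- list(gammas, gammas)
  best <- c(1L, 1L)
  for (a in seq_len(n)) {
    b <- a
    while (b < n && all(M[a:(b + 1), a:(b + 1)] >= stable_threshold)) b <- b + 1
    if (b - a > best[2] - best[1]) best <- c(a, b)
  }
  list(similarity = M, stable_region = best)
}
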