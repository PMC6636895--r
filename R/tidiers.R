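#' Tidy a fitted conditional graphical model
#'
#' One row per nonzero entry of the estimated components: output-output
#' edges of the sparse block (`block = "S_X"`), input-output effects
#' (`block = "S_ZX"`), with the entry values.
#'
#' @param x a `crf_fit`.
#' @param threshold magnitude threshold for reporting an entry.
#' @param ... unused.
#' @return tibble with `block`, `i`, `j`, `value`.
#' @export
tidy.crf_fit <- function(x, threshold = 1e-6, ...) {
  S_X <- x$params$S_X
  ed <- support_edges(S_X, threshold)
  ed$value <- S_X[cbind(ed$i, ed$j)]
  ed$block <- "S_X"
  out <- ed
  if (x$m > 0) {
    Z <- x$params$S_ZX
    idx <- which(abs(Z) > threshold, arr.ind = TRUE)
    if (nrow(idx) > 0)
      out <- dplyr::bind_rows(out, tibble::tibble(
        i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
        value = Z[idx], block = "S_ZX"))
  }
  dplyr::select(out, "block", "i", "j", "value")
}

#' One-row summary of a fitted conditional graphical model
#'
#' @param x a `crf_fit`.
#' @param ... unused.
#' @return tibble with the penalty configuration, objective, edge count,
#'   low-rank component rank and convergence diagnostics.
#' @export
glance.crf_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, gamma = x$gamma,
    objective = x$objective,
    n_edges = nrow(support_edges(x$params$S_X)),
    rank_L = l_rank(stacked_L(x$params)),
    iterations = x$iterations, converged = x$converged,
    n = x$n, p = x$p, m = x$m)
}

#' @export
tidy.stability_result <- function(x, ...) x$probabilities

#' @export
glance.stability_result <- function(x, ...) {
  tibble::tibble(B = x$B, q = x$q, tau = x$tau,
                 n_selected = nrow(x$selected), ev_bound = x$ev_bound)
}

#' Plot a regularization path
#'
#' Edge count of the sparse output block against the penalty level, one
#' line per gamma.
#'
#' @param object a [regularization_path()] tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.crf_path <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lambda, y = .data$n_edges,
                                       colour = factor(.data$gamma))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "edges in the sparse block",
                  colour = expression(gamma)) +
    ggplot2::theme_minimal()
}

#' Plot precision/recall curves
#'
#' @param curves output of [pr_curve()].
#' @return a ggplot object, one curve per gamma.
#' @export
plot_pr_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$recall, y = .data$precision,
                                       colour = factor(.data$gamma))) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(colour = expression(gamma)) +
    ggplot2::theme_minimal()
}

#' Plot inclusion probabilities of a stability selection
#'
#' @param object a `stability_result`.
#' @param top number of edges shown.
#' @param ... unused.
#' @return a ggplot object with the selection threshold marked.
#' @export
autoplot.stability_result <- function(object, top = 30, ...) {
  d <- utils::head(object$probabilities, top)
  d$edge <- paste0(d$i, "-", d$j)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$edge, .data$inclusion_probability),
    y = .data$inclusion_probability)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = min(object$tau, 1.05),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "inclusion probability") +
    ggplot2::theme_minimal()
}

#' Heatmap of selection similarity across the gamma grid
#'
#' @param sim output of [gamma_similarity()].
#' @return a ggplot object.
#' @export
plot_gamma_similarity <- function(sim) {
  M <- sim$similarity
  d <- tibble::as_tibble(as.data.frame(as.table(M)), .name_repair = "minimal")
  names(d) <- c("gamma1", "gamma2", "jaccard")
  ggplot2::ggplot(d, ggplot2::aes(.data$gamma1, .data$gamma2,
                                  fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = expression(gamma[1]), y = expression(gamma[2]),
                  fill = "Jaccard") +
    ggplot2::theme_minimal()
}
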