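#' Read a delimited numeric matrix
#'
#' TSV (default) or CSV with a header row of column names and no row names.
#' Validates rectangularity and finiteness; parse problems are reported with
#' their row and column.
#'
#' @param path file path; delimiter inferred from the extension (`.csv` is
#'   comma, anything else tab) unless `delim` is given.
#' @param delim optional field delimiter.
#' @return numeric matrix with column names.
#' @export
read_matrix <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(delim))
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # base-R parsing: strtod is correctly rounded, so 17-digit text round
  # trips to the identical double
  tb <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delim,
                      colClasses = "character", check.names = FALSE,
                      comment.char = "", quote = ""),
    error = function(e)
      stop("ragged row in ", path, ": ", conditionMessage(e), call. = FALSE))
  M <- matrix(NA_real_, nrow(tb), ncol(tb),
              dimnames = list(NULL, names(tb)))
  for (j in seq_len(ncol(tb))) {
    v <- suppressWarnings(as.numeric(tb[[j]]))
    bad <- which(is.na(v) & !tb[[j]] %in% c("NA", "NaN"))
    if (length(bad) > 0)
      stop(sprintf("parse error at row %d, column %d of %s: %s",
                   bad[1], j, path, tb[[j]][bad[1]]), call. = FALSE)
    M[, j] <- v
  }
  if (anyNA(M) || !all(is.finite(M))) {
    bad <- which(!is.finite(M), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at row %d, column %d of %s",
                 bad[1], bad[2], path), call. = FALSE)
  }
  M
}

#' Write a numeric matrix as delimited text
#'
#' Values are printed with shortest round-trip precision (17 significant
#' digits where needed), so a write/read round trip reproduces the matrix
#' exactly.
#'
#' @param M matrix or data frame.
#' @param path output path; delimiter inferred as in [read_matrix()].
#' @param delim optional field delimiter.
#' @export
write_matrix <- function(M, path, delim = NULL) {
  if (is.null(delim))
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  M <- as.matrix(M)
  if (is.null(colnames(M))) colnames(M) <- paste0("V", seq_len(ncol(M)))
  # 17 significant digits: exact binary round trip for doubles
  chr <- apply(M, 2, function(x) sprintf("%.17g", x))
  if (is.null(dim(chr))) chr <- matrix(chr, nrow = nrow(M))
  lines <- c(paste(colnames(M), collapse = delim),
             apply(chr, 1, paste, collapse = delim))
  writeLines(lines, path)
  invisible(path)
}

#' Quantile normalization to standard-normal scores
#'
#' Replaces values by the standard-normal quantiles of their mid-ranks
#' `(rank - 0.5) / n` (ties averaged), then standardizes to mean 0 and
#' population standard deviation 1. Rank-equivariant: a permutation of the
#' input permutes the output identically.
#'
#' @param x numeric vector with at least 2 values; must not be constant.
#' @return numeric vector of the same length.
#' @export
quantile_normalize <- function(x) {
  if (length(x) < 2) stop("need at least two values", call. = FALSE)
  if (length(unique(x)) == 1)
    stop("cannot quantile normalize a constant vector", call. = FALSE)
  r <- rank(x, ties.method = "average")
  q <- qnorm((r - 0.5) / length(x))
  q <- q - mean(q)
  q / sqrt(mean(q^2))
}

#' Run a full analysis from a single configuration
#'
#' Executes a reproducible pipeline described by one JSON-serializable
#' configuration list: either simulate a dataset (`simulate` block with
#' `k`, `d_Z`, `d_H`, `n`) or read one (`data` block with `path` and
#' `z_cols`/`z_prefix`), fit a method or a path (`fit` block with `method`,
#' `lambda`/`lambdas`, `gamma`/`gammas`), optionally score against the
#' simulated truth, and write results (estimate TSVs, a results JSON with
#' convergence diagnostics, and the echoed configuration) into `out_dir`.
#' Every random step is seeded from `config$seed`.
#'
#' @param config named list (or path to a JSON file).
#' @param out_dir output directory, created if missing; `NULL` returns the
#'   results invisibly without writing.
#' @return list with the fitted objects and summary tibbles.
#' @export
run_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  seed <- config$seed %||% 1L
  truth <- NULL
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    des <- sim_design(k = sc$k %||% 3, d_Z = sc$d_Z %||% 2,
                      d_H = sc$d_H %||% 2, n = sc$n %||% 500, seed = seed)
    truth <- sim_model(des)
    data <- sim_dataset(truth)
    z_cols <- attr(data, "z_cols")
  } else if (!is.null(config$data)) {
    if (!file.exists(config$data$path))
      stop("input path does not exist: ", config$data$path, call. = FALSE)
    M <- read_matrix(config$data$path)
    data <- tibble::as_tibble(as.data.frame(M))
    z_cols <- config$data$z_cols
    if (is.null(z_cols) && !is.null(config$data$z_prefix))
      z_cols <- names(data)[startsWith(names(data), config$data$z_prefix)]
    if (isTRUE(config$data$center) || isTRUE(config$data$standardize)) {
      x_cols <- setdiff(names(data), z_cols)
      data[x_cols] <- lapply(data[x_cols], function(v) {
        v <- v - mean(v)
        if (isTRUE(config$data$standardize)) v <- v / sd(v)
        v
      })
    }
  } else stop("config needs a `simulate` or `data` block", call. = FALSE)
  fc <- config$fit %||% list()
  method <- fc$method %||% "lscggm"
  out <- list(config = config)
  if (!is.null(fc$lambdas) || !is.null(fc$gammas)) {
    path <- regularization_path(data, method = method,
                                lambdas = fc$lambdas,
                                gammas = fc$gammas %||% 0.5,
                                n_lambda = fc$n_lambda %||% 25,
                                z_cols = z_cols)
    out$path <- path
    if (!is.null(truth)) {
      out$pr <- pr_curve(path, truth)
      if (length(unique(out$pr$gamma)) >= 2) out$vus <- pr_vus(out$pr)
    }
  } else {
    fit <- fit_method(data, method = method, lambda = fc$lambda %||% 0.1,
                      gamma = fc$gamma %||% 0.5, z_cols = z_cols)
    out$fit <- fit
    if (!is.null(truth)) out$consistency <- consistency_check(fit, truth)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$fit)) {
      write_matrix(out$fit$params$S_X, file.path(out_dir, "S_X.tsv"))
      write_matrix(out$fit$params$L_X, file.path(out_dir, "L_X.tsv"))
      if (out$fit$m > 0) {
        write_matrix(out$fit$params$S_ZX, file.path(out_dir, "S_ZX.tsv"))
        write_matrix(out$fit$params$L_ZX, file.path(out_dir, "L_ZX.tsv"))
      }
    }
    summary <- list(
      seed = seed, method = method,
      converged = if (!is.null(out$fit)) out$fit$converged else
        all(out$path$converged, na.rm = TRUE),
      objective = if (!is.null(out$fit)) out$fit$objective else NULL,
      n_edges = if (!is.null(out$fit))
        nrow(support_edges(out$fit$params$S_X)) else out$path$n_edges,
      vus = out$vus)
    jsonlite::write_json(summary, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
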