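#' Semidefinite-program reformulation of the estimation objective
#'
#' Builds the exact SDP form of the penalized conditional likelihood problem.
#' Auxiliary variables make every nonsmooth term linear: `W` (m x m) closes
#' the likelihood's quartic term through the PSD block
#' `K = [[W, S_ZX - L_ZX], [(S_ZX - L_ZX)', S_X - L_X]]`; `F` dominates `|S|`
#' elementwise for the l1 term; `H1`, `H2` give the nuclear norm through the
#' epigraph identity `||L||_* = min 0.5 * (tr H1 + tr H2)` over
#' `[[H1, L], [L', H2]] PSD`. The objective is
#' `tr(K Sigma_O) - logdet(K_XX) + lambda * gamma * sum(F) +
#'  lambda * (1 - gamma) * 0.5 * (tr H1 + tr H2)` where `Sigma_O` is the
#' joint (m+p) second-moment matrix and `K_XX = S_X - L_X` is the precision
#' block of `K` (the log-det barrier enforcing its strict definiteness).
#'
#' @param stats a [suff_stats()] object.
#' @param lambda,gamma penalty configuration (bounded parameterization).
#' @return An object of class `sdp_problem`: variable descriptors
#'   (tibble of name/rows/cols/cone), constraint descriptors, the objective
#'   coefficients, and the originating `stats`.
#' @export
build_sdp <- function(stats, lambda, gamma) {
  stopifnot(inherits(stats, "crf_stats"))
  p <- stats$p; m <- stats$m; q <- p + m
  vars <- tibble::tibble(
    name = c("S_X", "L_X", "S_ZX", "L_ZX", "W", "F", "H1", "H2"),
    rows = c(p, p, m, m, m, q, q, p),
    cols = c(p, p, p, p, m, p, q, p),
    cone = c("symmetric", "psd", "free", "free", "symmetric",
             "nonnegative", "symmetric", "symmetric"))
  if (m == 0) vars <- vars[!vars$name %in% c("S_ZX", "L_ZX", "W"), ]
  constraints <- list(
    list(id = "K_psd",
         description = "[[W, S_ZX - L_ZX], [., S_X - L_X]] is PSD",
         cone = "psd", dim = q),
    list(id = "SX_pd",
         description = "S_X - L_X positive definite (log-det barrier)",
         cone = "pd", dim = p),
    list(id = "LX_psd", description = "L_X is PSD", cone = "psd", dim = p),
    list(id = "H_psd", description = "[[H1, L], [L', H2]] is PSD",
         cone = "psd", dim = q + p),
    list(id = "F_dom", description = "-F_ij <= S_ij <= F_ij elementwise",
         cone = "linear", dim = 2L * q * p))
  structure(list(variables = vars, constraints = constraints,
                 Sigma_O = joint_second_moment(stats),
                 stats = stats, lambda = lambda, gamma = gamma,
                 p = p, m = m),
            class = "sdp_problem")
}

#' @export
print.sdp_problem <- function(x, ...) {
  cat(sprintf("<sdp_problem> p = %d, m = %d, lambda = %.4g, gamma = %.3g\n",
              x$p, x$m, x$lambda, x$gamma))
  cat(sprintf("  %d variable blocks, %d constraint families\n",
              nrow(x$variables), length(x$constraints)))
  invisible(x)
}

#' Evaluate the SDP objective at a full variable assignment
#'
#' @param problem an [build_sdp()] object.
#' @param vars named list with entries matching the problem's variable
#'   blocks (`S_X`, `L_X`, `S_ZX`, `L_ZX`, `W`, `F`, `H1`, `H2`).
#' @return scalar objective value.
#' @export
sdp_objective <- function(problem, vars) {
  p <- problem$p; m <- problem$m
  RX <- vars$S_X - vars$L_X
  if (m > 0) {
    RZX <- vars$S_ZX - vars$L_ZX
    K <- rbind(cbind(vars$W, RZX), cbind(t(RZX), RX))
  } else K <- RX
  sum(K * problem$Sigma_O) - determinant(RX, logarithm = TRUE)$modulus[1] +
    problem$lambda * problem$gamma * sum(vars$F) +
    problem$lambda * (1 - problem$gamma) * 0.5 *
      (sum(diag(vars$H1)) + sum(diag(vars$H2)))
}

#' Export an SDP problem description as plain JSON
#'
#' Writes variable shapes, cone memberships, constraint descriptors and the
#' numeric objective coefficients so that any external conic solver can be
#' attached to the problem.
#'
#' @param problem an [build_sdp()] object.
#' @param path output file path; when `NULL` the JSON string is returned.
#' @export
sdp_to_json <- function(problem, path = NULL) {
  doc <- list(
    dimensions = list(p = problem$p, m = problem$m),
    penalty = list(lambda = problem$lambda, gamma = problem$gamma),
    variables = problem$variables,
    constraints = problem$constraints,
    objective = list(
      description = paste("tr(K Sigma_O) - logdet(S_X - L_X) +",
                          "lambda*gamma*sum(F) +",
                          "lambda*(1-gamma)*(tr(H1)+tr(H2))/2"),
      Sigma_O = problem$Sigma_O))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

# ---- bundled high-accuracy back-end -------------------------------------

# Douglas-Rachford solve of the constrained nuclear prox
#   argmin 0.5||X - M||^2 + t ||X||_* s.t. top p x p block symmetric PSD.
# Independent of the Dykstra scheme used inside the ADMM; pure R.
dr_prox_nuclear_psd <- function(M, t, p, tol = 1e-11, max_iter = 2000,
                                z0 = NULL) {
  if (p > 0) {
    top <- M[seq_len(p), , drop = FALSE]
    M[seq_len(p), ] <- (top + t(top)) / 2
  }
  proj_C <- function(X) {
    if (p == 0) return(X)
    X[seq_len(p), ] <- project_psd(X[seq_len(p), , drop = FALSE], 0)
    X
  }
  svt_r <- function(V, th) {
    sv <- svd(V)
    d <- pmax(sv$d - th, 0)
    sv$u %*% (d * t(sv$v))
  }
  z <- if (is.null(z0)) M else z0
  scale <- max(1, sqrt(sum(M^2)))
  y <- proj_C(z)
  for (it in seq_len(max_iter)) {
    x <- svt_r((M + z) / 2, t / 2)       # prox of 0.5||.-M||^2 + t||.||_*
    y <- proj_C(2 * x - z)
    z <- z + y - x
    if (sqrt(sum((x - y)^2)) / scale <= tol) break
  }
  list(argmin = proj_C(x), z = z, iterations = it)
}

# Accelerated proximal gradient (FISTA, backtracking + restart) on the
# composite objective; the oracle path, kept separate from the C++ ADMM.
fista_solve <- function(stats, lambda, gamma, tol = 1e-9, max_iter = 5000,
                        penalize_diagonal = TRUE) {
  p <- stats$p; m <- stats$m; q <- p + m
  SigZ <- stats$Sigma_Z; SigX <- stats$Sigma_X; SigZX <- stats$Sigma_ZX
  nll <- function(S, L) {
    RX <- S[seq_len(p), , drop = FALSE] - L[seq_len(p), , drop = FALSE]
    RX <- (RX + t(RX)) / 2
    ev <- eigen(RX, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-13) return(Inf)
    val <- -sum(log(ev)) + sum(SigX * RX)
    if (m > 0) {
      RZX <- S[p + seq_len(m), , drop = FALSE] - L[p + seq_len(m), , drop = FALSE]
      C <- chol2inv(chol(RX))
      val <- val + 2 * sum(SigZX * RZX) + sum(C * crossprod(RZX, SigZ %*% RZX))
    }
    val
  }
  grad_nll <- function(S, L) {
    RX <- S[seq_len(p), , drop = FALSE] - L[seq_len(p), , drop = FALSE]
    RX <- (RX + t(RX)) / 2
    C <- chol2inv(chol(RX))
    if (m > 0) {
      RZX <- S[p + seq_len(m), , drop = FALSE] - L[p + seq_len(m), , drop = FALSE]
      SzR <- SigZ %*% RZX
      Q <- crossprod(RZX, SzR)
      gX <- -C + SigX - C %*% Q %*% C
      gZX <- 2 * SigZX + 2 * SzR %*% C
      rbind((gX + t(gX)) / 2, gZX)
    } else {
      gX <- -C + SigX
      (gX + t(gX)) / 2
    }
  }
  pen <- function(S, L, nucd) {
    l1 <- if (penalize_diagonal) sum(abs(S)) else
      sum(abs(S)) - sum(abs(S[cbind(seq_len(p), seq_len(p))]))
    lambda * gamma * l1 + lambda * (1 - gamma) * nucd
  }
  mask <- NULL
  if (!penalize_diagonal) {
    mask <- matrix(0, q, p)
    mask[cbind(seq_len(p), seq_len(p))] <- 1
  }
  soft <- function(M, t) {
    out <- sign(M) * pmax(abs(M) - t, 0)
    if (!is.null(mask)) out[mask == 1] <- M[mask == 1]
    out
  }
  S <- rbind(diag(p), matrix(0, m, p)); L <- matrix(0, q, p)
  YS <- S; YL <- L
  zdr <- NULL
  tk <- 1; tau <- 1
  F_old <- nll(S, L) + pen(S, L, 0)
  stall <- 0
  for (it in seq_len(max_iter)) {
    fy <- nll(YS, YL)
    if (!is.finite(fy)) {      # extrapolation left the PD domain: restart
      YS <- S; YL <- L; tk <- 1
      fy <- nll(YS, YL)
    }
    g <- grad_nll(YS, YL)
    # inner prox tolerance tightens as the outer iteration progresses
    dr_tol <- max(1e-12, min(1e-6, 10 / it^2))
    repeat {
      S1 <- soft(YS - tau * g, tau * lambda * gamma)
      dr <- dr_prox_nuclear_psd(YL + tau * g, tau * lambda * (1 - gamma), p,
                                tol = dr_tol, z0 = zdr)
      L1 <- dr$argmin
      f1 <- nll(S1, L1)
      dS <- S1 - YS; dL <- L1 - YL
      ub <- fy + sum(g * dS) - sum(g * dL) +
        (sum(dS^2) + sum(dL^2)) / (2 * tau)
      if (is.finite(f1) && f1 <= ub + 1e-12) break
      tau <- tau / 2
      if (tau < 1e-14) stop("oracle line search failed", call. = FALSE)
    }
    zdr <- dr$z
    nucd <- sum(svd(L1)$d)
    F_new <- f1 + pen(S1, L1, nucd)
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    if (F_new > F_old) {          # restart momentum
      YS <- S1; YL <- L1; tk <- 1
    } else {
      YS <- S1 + ((tk - 1) / t_next) * (S1 - S)
      YL <- L1 + ((tk - 1) / t_next) * (L1 - L)
      tk <- t_next
    }
    S <- S1; L <- L1
    if (abs(F_new - F_old) <= tol * max(1, abs(F_new))) stall <- stall + 1
    else stall <- 0
    F_old <- F_new
    if (stall >= 5) break
    tau <- min(tau * 1.1, 10)
  }
  list(S = S, L = L, objective = F_old, iterations = it,
       converged = stall >= 5)
}

#' Solve the SDP reformulation on a small instance
#'
#' High-accuracy solution of the problem described by [build_sdp()]. The
#' bundled back-end solves the equivalent composite problem by an
#' accelerated proximal-gradient method with backtracking and adaptive
#' restart run to a tight tolerance, then reconstructs the full SDP variable
#' assignment (`W` from the Schur-complement equality, `F = |S|`, `H1`/`H2`
#' from the singular value decomposition of the stacked low-rank block).
#' Intended as a correctness oracle at desk scale (p + m up to ~50), not a
#' large-scale solver. A user-supplied conic back-end can be attached via
#' `backend`.
#'
#' @param problem an [build_sdp()] object.
#' @param solver_tol relative objective tolerance of the bundled back-end.
#' @param max_iter iteration cap of the bundled back-end.
#' @param backend `"fista"` (bundled) or a function
#'   `function(problem, solver_tol)` returning a named variable list.
#' @return A `crf_fit` object whose `objective` is the penalized likelihood
#'   objective of the extracted parameters; `sdp_vars` carries the full
#'   variable assignment and `sdp_objective` its SDP objective value.
#' @export
solve_sdp <- function(problem, solver_tol = 1e-9, max_iter = 5000,
                      backend = "fista") {
  stopifnot(inherits(problem, "sdp_problem"))
  p <- problem$p; m <- problem$m
  if (is.function(backend)) {
    vars <- backend(problem, solver_tol)
    if (is.null(vars))
      stop("conic back-end returned no solution", call. = FALSE)
  } else if (identical(backend, "fista")) {
    sol <- fista_solve(problem$stats, problem$lambda, problem$gamma,
                       tol = solver_tol, max_iter = max_iter)
    S <- sol$S; L <- sol$L
    SX <- S[seq_len(p), , drop = FALSE]; LX <- L[seq_len(p), , drop = FALSE]
    RX <- SX - LX
    sv <- svd(L)
    H1 <- sv$u %*% (sv$d * t(sv$u))
    H2 <- sv$v %*% (sv$d * t(sv$v))
    if (m > 0) {
      SZX <- S[p + seq_len(m), , drop = FALSE]
      LZX <- L[p + seq_len(m), , drop = FALSE]
      RZX <- SZX - LZX
      W <- RZX %*% chol2inv(chol((RX + t(RX)) / 2)) %*% t(RZX)
    } else {
      SZX <- matrix(0, 0, p); LZX <- matrix(0, 0, p); W <- matrix(0, 0, 0)
    }
    vars <- list(S_X = SX, L_X = LX, S_ZX = SZX, L_ZX = LZX,
                 W = W, F = abs(S), H1 = H1, H2 = H2)
  } else {
    stop("no conic back-end available: pass `backend` as a function or use ",
         "the bundled \"fista\" back-end", call. = FALSE)
  }
  params <- crf_params(vars$S_X, vars$L_X, vars$S_ZX, vars$L_ZX, check = FALSE)
  obj <- objective_value(params, problem$stats, problem$lambda, problem$gamma)
  structure(
    list(params = params, objective = obj,
         iterations = if (exists("sol", inherits = FALSE)) sol$iterations else NA,
         converged = if (exists("sol", inherits = FALSE)) sol$converged else TRUE,
         lambda = problem$lambda, gamma = problem$gamma,
         fix_L_zero = FALSE, penalize_diagonal = TRUE,
         sdp_vars = vars, sdp_objective = sdp_objective(problem, vars),
         n = problem$stats$n, p = p, m = m, method = "sdp"),
    class = "crf_fit")
}
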