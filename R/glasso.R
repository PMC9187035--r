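# Sparse inverse covariance estimation (graphical LASSO) with automatic
# penalty selection.

#' Graphical LASSO estimate at a fixed penalty
#'
#' Solves the l1-penalized inverse-covariance objective
#' `argmin_Theta sum_ij S_ij Theta_ij - log det(Theta) + rho sum_ij |Theta_ij|`
#' by block coordinate descent, returning both the estimated covariance
#' `Sigma_hat` and its sparse inverse `Theta_hat`. Non-convergence or
#' non-finite outputs are flagged, not raised.
#'
#' @param S Symmetric numeric matrix with finite entries.
#' @param rho Regularization parameter (>= 0).
#' @param maxit Outer iteration cap (default 100).
#' @param tol Convergence tolerance, relative to the mean absolute
#'   off-diagonal of `S` (default 1e-6).
#' @return A `glasso_fit` object with fields `S`, `sigma` (Sigma_hat),
#'   `theta` (Theta_hat), `rho`, `converged`, `iterations`, `finite`.
#' @export
glasso_estimate <- function(S, rho, maxit = 100L, tol = 1e-6) {
  S <- as.matrix(S)
  if (anyNA(S) || any(!is.finite(S))) {
    stop_usage("input matrix contains non-finite entries")
  }
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8) {
    stop_usage("input matrix must be symmetric")
  }
  S <- (S + t(S)) / 2
  res <- .glasso_cd(S, rho, as.integer(maxit), tol)
  structure(list(S = S, sigma = res$w, theta = res$theta, rho = rho,
                 converged = isTRUE(res$converged) && isTRUE(res$finite),
                 iterations = res$iterations, finite = isTRUE(res$finite)),
            class = "glasso_fit")
}

#' @export
print.glasso_fit <- function(x, ...) {
  cat(sprintf("<glasso_fit> p = %d; rho = %.3f; %s in %d iteration(s)\n",
              nrow(x$S), x$rho,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

glasso_feasible <- function(S, rho, maxit = 100L) {
  fit <- glasso_estimate(S, rho, maxit = maxit)
  fit$converged && fit$finite &&
    all(is.finite(fit$sigma)) && all(is.finite(fit$theta))
}

#' Automatic selection of the glasso penalty
#'
#' Binary search over `(0.01, 0.99)` for the minimal penalty at which both
#' the estimated covariance matrix and its inverse are fully defined (finite,
#' converged). Feasibility is assumed monotone in `rho`; the search works on
#' a grid of the given resolution and returns the feasible upper end of the
#' final interval.
#'
#' @param S Symmetric matrix.
#' @param resolution Grid resolution (default 0.01).
#' @param range Search range (default `c(0.01, 0.99)`).
#' @param maxit Iteration cap passed to [glasso_estimate()].
#' @return The selected `rho` (numeric scalar).
#' @export
auto_rho <- function(S, resolution = 0.01, range = c(0.01, 0.99),
                     maxit = 100L) {
  lo <- range[1]
  hi <- range[2]
  if (glasso_feasible(S, lo, maxit)) return(lo)
  if (!glasso_feasible(S, hi, maxit)) {
    rlang::abort(sprintf(
      "no rho in (%.2f, %.2f) yields defined glasso output", lo, hi),
      class = "coevgraph_infeasible_error")
  }
  # invariant: lo infeasible, hi feasible
  while (hi - lo > resolution + 1e-12) {
    mid <- round((lo + hi) / 2 / resolution) * resolution
    if (mid <= lo || mid >= hi) break
    if (glasso_feasible(S, mid, maxit)) hi <- mid else lo <- mid
  }
  hi
}

#' Graphical-LASSO regularization of a covariance matrix
#'
#' Feeds a (post-processed) coupling matrix through sparse inverse covariance
#' estimation at an automatically selected (or given) penalty. Masked entries
#' are imputed as 0 (independence) before estimation; the count is recorded.
#'
#' @param cov A `cov_matrix`.
#' @param rho Penalty; selected by [auto_rho()] when `NULL`.
#' @param maxit Iteration cap.
#' @return A `cov_matrix` whose `values` hold the estimated covariance
#'   `Sigma_hat`; the precision matrix is retrievable via
#'   [precision_matrix()], the fitted object via `attr(, "glasso_fit")`.
#' @export
regularized_matrix <- function(cov, rho = NULL, maxit = 100L) {
  S <- cov$values
  n_imputed <- sum(!is.finite(S))
  S[!is.finite(S)] <- 0
  if (is.null(rho)) rho <- auto_rho(S, maxit = maxit)
  fit <- glasso_estimate(S, rho, maxit = maxit)
  vals <- (fit$sigma + t(fit$sigma)) / 2
  dimnames(vals) <- dimnames(cov$values)
  neff <- matrix(cov$neff_median, nrow(vals), ncol(vals))
  out <- new_cov_matrix(vals, cov$metric, cov$alphabet, cov$post_processed,
                        cov$query, cov$n_seq, neff, rho = rho,
                        provenance = sprintf("%s+glasso(rho=%.2f)",
                                             cov$metric, rho))
  out$neff_median <- cov$neff_median
  out$n_imputed <- n_imputed
  attr(out, "glasso_fit") <- fit
  out
}

#' Precision matrix of a glasso-regularized covariance matrix
#' @param cov A `cov_matrix` returned by [regularized_matrix()].
#' @return The estimated sparse inverse covariance `Theta_hat`.
#' @export
precision_matrix <- function(cov) {
  fit <- attr(cov, "glasso_fit")
  if (is.null(fit)) stop_usage("matrix carries no glasso fit")
  fit$theta
}
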