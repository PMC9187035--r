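# Covariance metrics: mutual information, chi-squared, PSSM-based Pearson.

#' Mutual information of a column pair
#'
#' Natural-log mutual information over the (sub-normalized) weighted state
#' probabilities; terms with zero joint probability contribute nothing.
#'
#' @param probs A `pair_probs` object.
#' @return The MI score in nats, or `NA` for a degenerate pair.
#' @export
mutual_information <- function(probs) {
  if (probs$degenerate) return(NA_real_)
  E <- outer(probs$p_i, probs$p_j)
  P <- probs$p_ij
  pos <- P > 0
  sum(P[pos] * log(P[pos] / E[pos]))
}

#' Chi-squared coupling of a column pair
#'
#' `sum over states of (p_ij - p_i p_j)^2 / (p_i p_j)`, skipping states with
#' zero expected probability.
#'
#' @param probs A `pair_probs` object.
#' @return The chi-squared score, or `NA` for a degenerate pair.
#' @export
chi_squared <- function(probs) {
  if (probs$degenerate) return(NA_real_)
  E <- outer(probs$p_i, probs$p_j)
  P <- probs$p_ij
  pos <- E > 0
  sum((P[pos] - E[pos])^2 / E[pos])
}

#' Convert chi-squared scores to cumulative probabilities
#'
#' Lower-tail CDF of the chi-squared distribution with one degree of freedom,
#' mapping raw coupling scores onto `[0, 1]`.
#'
#' @param chi2 Non-negative score(s).
#' @return Probabilities in `[0, 1]`.
#' @export
chi2_to_probability <- function(chi2) {
  if (any(chi2 < 0, na.rm = TRUE)) stop_usage("chi-squared scores must be >= 0")
  pchisq(chi2, df = 1)
}

#' PSSM-based Pearson correlation of a column pair
#'
#' Each aligned sequence realizes a substitution score at a column: the PSSM
#' log-odds of its residue at that query position. The score is the
#' phylogeny-weighted Pearson correlation of the two columns' realized
#' scores, clipped to `[-1, 1]` and taken by absolute value. Means and
#' standard deviations are weighted population statistics over the sequences
#' that are non-gap (and non-`X`) at both columns; the `stats` flag switches
#' to per-column ("global") statistics over each column's own non-gap set.
#'
#' @param msa A trimmed `msa`.
#' @param pssm A `pssm_profile` for the query.
#' @param weights A `seq_weights` object.
#' @param i,j 1-based column indices.
#' @param stats `"pairwise"` (default) or `"global"`.
#' @return `|r|` in `[0, 1]`, or `NA` when either column has zero score
#'   variance or the pair is degenerate.
#' @export
pearson_covariance <- function(msa, pssm, weights, i, j,
                               stats = c("pairwise", "global")) {
  stats <- match.arg(stats)
  m <- seq_char_matrix(msa$seqs)
  ci <- m[, i]
  cj <- m[, j]
  keep <- is_residue(ci) & is_residue(cj)
  if (!any(keep)) return(NA_real_)
  w <- unname(weights$w)[keep]
  n_eff <- sum(w)
  si <- pssm_score(pssm, i, ci[keep])
  sj <- pssm_score(pssm, j, cj[keep])
  mom <- function(col, s, wv) {
    mu <- sum(wv * s) / sum(wv)
    sg <- sqrt(sum(wv * (s - mu)^2) / sum(wv))
    list(mu = mu, sigma = sg)
  }
  if (stats == "pairwise") {
    mi_ <- mom(i, si, w)
    mj_ <- mom(j, sj, w)
  } else {
    ki <- is_residue(ci)
    kj <- is_residue(cj)
    mi_ <- mom(i, pssm_score(pssm, i, ci[ki]), unname(weights$w)[ki])
    mj_ <- mom(j, pssm_score(pssm, j, cj[kj]), unname(weights$w)[kj])
  }
  if (mi_$sigma <= 0 || mj_$sigma <= 0) return(NA_real_)
  r <- sum(w * (si - mi_$mu) * (sj - mj_$mu)) / (n_eff * mi_$sigma * mj_$sigma)
  abs(max(-1, min(1, r)))
}

## ---- Full matrices ---------------------------------------------------------

new_cov_matrix <- function(values, metric, alphabet, post_processed, query,
                           n_seq, neff, rho = NA_real_, provenance = metric) {
  mask <- !is.finite(values)
  values[mask] <- NA_real_
  structure(list(values = values, metric = metric, alphabet = alphabet,
                 post_processed = post_processed, mask = mask,
                 query = query, L = nrow(values), n_seq = n_seq,
                 neff_median = stats::median(neff[upper.tri(neff, diag = TRUE)]),
                 neff_min = min(neff), rho = rho, provenance = provenance),
            class = "cov_matrix")
}

#' @export
print.cov_matrix <- function(x, ...) {
  cat(sprintf(
    "<cov_matrix> %s (%s-letter)%s; L = %d; N = %d; N_eff median = %.2f%s\n",
    x$metric,
    if (x$metric == "pearson") "score" else x$alphabet,
    if (x$post_processed) " [post-processed]" else "",
    x$L, x$n_seq, x$neff_median,
    if (!is.na(x$rho)) sprintf("; glasso rho = %.2f", x$rho) else ""))
  invisible(x)
}

#' Covariance matrix over all column pairs
#'
#' Computes the chosen metric for every pair of (trimmed) alignment columns,
#' using phylogeny-weighted sub-normalized probabilities, and applies the
#' standard post-processing: chi-squared scores become chi-squared(df = 1)
#' cumulative probabilities and Pearson scores are absolute values (both in
#' `[0, 1]`). Degenerate pairs (no sequence non-gap at both columns; zero
#' score variance for Pearson) are masked as `NA`.
#'
#' @param msa A trimmed `msa`.
#' @param metric `"chi2"`, `"mi"` or `"pearson"`.
#' @param alphabet `"2"` or `"20"`; applies to `mi` and `chi2` only.
#' @param pssm A `pssm_profile`; required for `metric = "pearson"`.
#' @param weights Optional precomputed `seq_weights`; computed at the default
#'   80% threshold when absent.
#' @param post_process Apply the CDF / absolute-value transform (default TRUE).
#' @return A `cov_matrix` object (L x L symmetric; diagonal included).
#' @export
covariance_matrix <- function(msa, metric = c("chi2", "mi", "pearson"),
                              alphabet = c("2", "20"), pssm = NULL,
                              weights = NULL, post_process = TRUE) {
  metric <- match.arg(metric)
  alphabet <- match.arg(alphabet)
  if (metric == "pearson" && is.null(pssm)) {
    stop_usage("metric 'pearson' requires a PSSM profile")
  }
  if (is.null(weights)) weights <- compute_weights(msa)
  w <- unname(weights$w)
  m <- seq_char_matrix(msa$seqs)
  V <- matrix(as.numeric(matrix(m %in% amino_acids(), nrow(m))), nrow(m))
  neff <- crossprod(V, w * V)

  if (metric == "pearson") {
    vals <- pearson_matrix(m, V, w, pssm, neff)
  } else if (alphabet == "2") {
    vals <- binary_metric_matrix(m, V, w, msa$query_index, neff, metric)
  } else {
    vals <- full_metric_matrix(m, V, w, neff, metric)
  }
  vals[neff == 0] <- NA_real_
  if (post_process && metric == "chi2") {
    ok <- is.finite(vals)
    vals[ok] <- chi2_to_probability(vals[ok])
  }
  vals <- (vals + t(vals)) / 2   # enforce exact symmetry
  dimnames(vals) <- list(seq_len(ncol(m)), seq_len(ncol(m)))
  new_cov_matrix(vals, metric, alphabet,
                 post_processed = post_process && metric != "mi",
                 query = query_sequence(msa), n_seq = msa$N, neff = neff)
}

# 2-letter MI / chi2 for all pairs via weighted cross-products.
binary_metric_matrix <- function(m, V, w, query_index, neff, metric) {
  L <- ncol(m)
  qrow <- m[query_index, ]
  Mm <- (m == matrix(qrow, nrow(m), L, byrow = TRUE)) * V   # match & valid
  Nm <- (1 - (m == matrix(qrow, nrow(m), L, byrow = TRUE))) * V
  wc <- function(X, Y) crossprod(X, w * Y)
  n11 <- wc(Mm, Mm); n10 <- wc(Mm, Nm); n01 <- wc(Nm, Mm); n00 <- wc(Nm, Nm)
  denom <- neff + 1
  acc <- matrix(0, L, L)
  cells <- list(list(n11, "1", "1"), list(n10, "1", "0"),
                list(n01, "0", "1"), list(n00, "0", "0"))
  # marginals within the pair-included set
  mi1 <- n11 + n10; mi0 <- n01 + n00
  mj1 <- n11 + n01; mj0 <- n10 + n00
  marg_i <- list("1" = mi1, "0" = mi0)
  marg_j <- list("1" = mj1, "0" = mj0)
  for (cell in cells) {
    P <- cell[[1]] / denom
    E <- (marg_i[[cell[[2]]]] / denom) * (marg_j[[cell[[3]]]] / denom)
    if (metric == "mi") {
      t1 <- P * log(P / E)
      t1[P <= 0] <- 0
    } else {
      t1 <- (P - E)^2 / E
      t1[E <= 0] <- 0
    }
    acc <- acc + t1
  }
  acc
}

# 20-letter MI / chi2 for all pairs.
full_metric_matrix <- function(m, V, w, neff, metric) {
  L <- ncol(m)
  aas <- amino_acids()
  X <- lapply(aas, function(a) (m == a) * 1)
  names(X) <- aas
  denom <- neff + 1
  # marginal weighted counts of letter a at i within pairs with j: X_a' W V
  marg_i <- lapply(X, function(Xa) crossprod(Xa, w * V))
  marg_j <- lapply(X, function(Xb) crossprod(V, w * Xb))
  acc <- matrix(0, L, L)
  for (a in aas) {
    wXa <- w * X[[a]]
    Pi <- marg_i[[a]] / denom
    for (b in aas) {
      P <- crossprod(X[[b]], wXa) / denom   # count of (a at i, b at j)
      # note: crossprod(X_b, w X_a)[i,j] = sum_l w_l X_b[l,i] X_a[l,j] gives
      # (b at i, a at j); use t() orientation below
      P <- t(P)
      E <- Pi * (marg_j[[b]] / denom)
      if (metric == "mi") {
        t1 <- P * log(P / E)
        t1[P <= 0] <- 0
      } else {
        t1 <- (P - E)^2 / E
        t1[E <= 0] <- 0
      }
      acc <- acc + t1
    }
  }
  acc
}

# |r| for all pairs via weighted cross-products (pairwise statistics).
pearson_matrix <- function(m, V, w, pssm, neff) {
  L <- ncol(m)
  S <- matrix(0, nrow(m), L)
  for (i in seq_len(L)) {
    ok <- V[, i] == 1
    S[ok, i] <- pssm_score(pssm, i, m[ok, i])
  }
  wc <- function(X, Y) crossprod(X, w * Y)
  sum_i <- wc(S, V)          # [i,j] = weighted sum of s_i over pair set
  sum_j <- wc(V, S)
  ss_i <- wc(S * S, V)
  ss_j <- wc(V, S * S)
  cr <- wc(S, S)
  mu_i <- sum_i / neff
  mu_j <- sum_j / neff
  var_i <- pmax(ss_i / neff - mu_i^2, 0)
  var_j <- pmax(ss_j / neff - mu_j^2, 0)
  cov_ij <- cr / neff - mu_i * mu_j
  r <- cov_ij / sqrt(var_i * var_j)
  r[var_i < 1e-10 | var_j < 1e-10] <- NA_real_
  abs(pmin(pmax(r, -1), 1))
}
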