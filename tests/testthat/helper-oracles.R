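# Independent brute-force oracles: naive loops over sequences/states, a
# numerically integrated chi-squared CDF, an exhaustive clique enumerator,
# and a proximal-gradient solver for the l1-penalized inverse covariance.
# None of these share code paths with the package implementation.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

naive_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n_both <- 0L; n_match <- 0L
  for (k in seq_along(ca)) {
    if (ca[k] != "-" && cb[k] != "-") {
      n_both <- n_both + 1L
      if (ca[k] == cb[k] && ca[k] %in% AAS) n_match <- n_match + 1L
    }
  }
  if (n_both == 0L) 0 else n_match / n_both
}

naive_weights <- function(seqs, thr = 0.8) {
  n <- length(seqs)
  w <- numeric(n)
  for (a in seq_len(n)) {
    cnt <- 0L
    for (b in seq_len(n)) if (naive_identity(seqs[a], seqs[b]) > thr) cnt <- cnt + 1L
    w[a] <- 1 / cnt
  }
  w
}

# Weighted pair probabilities by explicit per-sequence loops.
naive_probs <- function(seqs, w, i, j, alphabet = "2", query_index = 1L) {
  states <- if (alphabet == "2") c("0", "1") else AAS
  cnt <- matrix(0, length(states), length(states),
                dimnames = list(states, states))
  n_eff <- 0
  qi <- substr(seqs[query_index], i, i)
  qj <- substr(seqs[query_index], j, j)
  for (l in seq_along(seqs)) {
    ri <- substr(seqs[l], i, i); rj <- substr(seqs[l], j, j)
    if (!(ri %in% AAS) || !(rj %in% AAS)) next
    n_eff <- n_eff + w[l]
    si <- if (alphabet == "2") { if (ri == qi) "1" else "0" } else ri
    sj <- if (alphabet == "2") { if (rj == qj) "1" else "0" } else rj
    cnt[si, sj] <- cnt[si, sj] + w[l]
  }
  list(p = cnt / (n_eff + 1), n_eff = n_eff)
}

naive_mi <- function(pr) {
  p <- pr$p
  pi_ <- rowSums(p); pj_ <- colSums(p)
  acc <- 0
  for (x in rownames(p)) for (y in colnames(p)) {
    if (p[x, y] > 0) acc <- acc + p[x, y] * log(p[x, y] / (pi_[x] * pj_[y]))
  }
  unname(acc)
}

naive_chi2 <- function(pr) {
  p <- pr$p
  pi_ <- rowSums(p); pj_ <- colSums(p)
  acc <- 0
  for (x in rownames(p)) for (y in colnames(p)) {
    e <- pi_[x] * pj_[y]
    if (e > 0) acc <- acc + (p[x, y] - e)^2 / e
  }
  unname(acc)
}

naive_pearson <- function(seqs, scores, w, i, j) {
  # scores: L x 20 matrix with colnames = amino acids
  si <- c(); sj <- c(); wk <- c()
  for (l in seq_along(seqs)) {
    ri <- substr(seqs[l], i, i); rj <- substr(seqs[l], j, j)
    if (!(ri %in% AAS) || !(rj %in% AAS)) next
    si <- c(si, scores[i, ri]); sj <- c(sj, scores[j, rj]); wk <- c(wk, w[l])
  }
  if (length(wk) == 0) return(NA_real_)
  n_eff <- sum(wk)
  mi_ <- sum(wk * si) / n_eff
  mj_ <- sum(wk * sj) / n_eff
  sdi <- sqrt(sum(wk * (si - mi_)^2) / n_eff)
  sdj <- sqrt(sum(wk * (sj - mj_)^2) / n_eff)
  if (sdi < 1e-5 || sdj < 1e-5) return(NA_real_)
  r <- sum(wk * (si - mi_) * (sj - mj_)) / (n_eff * sdi * sdj)
  unname(abs(min(1, max(-1, r))))
}

# Lower-tail chi-squared(df = 1) CDF by numeric integration of the closed-
# form density  f(t) = t^{-1/2} exp(-t/2) / (sqrt(2) * Gamma(1/2)).
chi2_cdf_numeric <- function(x) {
  dens <- function(t) t^(-0.5) * exp(-t / 2) / (sqrt(2) * sqrt(pi))
  vapply(x, function(xx) {
    if (xx <= 0) return(0)
    stats::integrate(dens, 0, xx, rel.tol = 1e-12)$value
  }, 0)
}

# All maximal cliques of size >= min_size by exhaustive subset enumeration.
brute_cliques <- function(adj, min_size = 2L) {
  n <- nrow(adj)
  res <- list()
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, bitwShiftL(1, 0:(n - 1))) > 0)
    if (length(S) < min_size) next
    sub <- adj[S, S, drop = FALSE]
    diag(sub) <- TRUE
    if (!all(sub)) next
    outside <- setdiff(seq_len(n), S)
    extendable <- any(vapply(outside, function(v) all(adj[v, S]), TRUE))
    if (!extendable) res[[length(res) + 1L]] <- S
  }
  if (length(res) > 0) {
    key <- vapply(res, function(v) paste(sprintf("%06d", v), collapse = ","), "")
    res <- res[order(-lengths(res), key)]
  }
  res
}

# Proximal-gradient (FISTA, backtracking) solver for
#   min sum(S * Theta) - logdet(Theta) + rho * sum(abs(Theta)).
fista_glasso <- function(S, rho, iters = 20000, tol = 1e-11) {
  p <- nrow(S)
  logdet <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)
  fsm <- function(M) sum(S * M) - logdet(M)
  Theta <- diag(1 / (diag(S) + rho), p)
  Y <- Theta
  tk <- 1
  Lc <- 1
  for (k in seq_len(iters)) {
    G <- S - solve(Y)
    repeat {
      Z <- Y - G / Lc
      Tn <- sign(Z) * pmax(abs(Z) - rho / Lc, 0)
      Tn <- (Tn + t(Tn)) / 2
      ev <- min(eigen(Tn, symmetric = TRUE, only.values = TRUE)$values)
      if (ev > 1e-12 &&
          fsm(Tn) <= fsm(Y) + sum(G * (Tn - Y)) +
            Lc / 2 * sum((Tn - Y)^2) + 1e-13) break
      Lc <- Lc * 2
      if (Lc > 1e12) break
    }
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Ynew <- Tn + ((tk - 1) / tn) * (Tn - Theta)
    if (min(eigen(Ynew, symmetric = TRUE, only.values = TRUE)$values) < 1e-12) {
      Ynew <- Tn
      tn <- 1
    }
    delta <- max(abs(Tn - Theta))
    Theta <- Tn
    Y <- Ynew
    tk <- tn
    if (delta < tol && k > 10) break
  }
  Theta
}
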