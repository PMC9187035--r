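test_that("MI and chi-squared vanish on exactly factorized tables", {
  p_i <- c("0" = 0.3, "1" = 0.7)
  p_j <- c("0" = 0.45, "1" = 0.55)
  pr <- manual_probs(outer(p_i, p_j), p_i, p_j)
  expect_equal(mutual_information(pr), 0)
  expect_equal(chi_squared(pr), 0)
})

test_that("per-pair metrics equal four-term brute-force sums on 2x2 tables", {
  p_ij <- matrix(c(0.4, 0.05, 0.1, 0.4), 2, 2,
                 dimnames = list(c("0", "1"), c("0", "1")))
  pr <- manual_probs(p_ij)
  mi_hand <- sum(vapply(1:4, function(k) {
    x <- c(1, 2, 1, 2)[k]; y <- c(1, 1, 2, 2)[k]
    p <- p_ij[x, y]
    if (p == 0) 0 else p * log(p / (sum(p_ij[x, ]) * sum(p_ij[, y])))
  }, 0))
  chi_hand <- sum(vapply(1:4, function(k) {
    x <- c(1, 2, 1, 2)[k]; y <- c(1, 1, 2, 2)[k]
    e <- sum(p_ij[x, ]) * sum(p_ij[, y])
    (p_ij[x, y] - e)^2 / e
  }, 0))
  expect_equal(mutual_information(pr), mi_hand, tolerance = 1e-14)
  expect_equal(chi_squared(pr), chi_hand, tolerance = 1e-14)

  # anti-correlated table is strictly positive
  anti <- manual_probs(matrix(c(0.0, 0.45, 0.45, 0.0), 2, 2,
                              dimnames = list(c("0", "1"), c("0", "1"))))
  expect_gt(chi_squared(anti), 0)
})

test_that("self-pair MI equals the plug-in column entropy", {
  msa <- msa_of("ACCA", "ACCC", "CCCA", "AACA")
  w <- manual_weights(rep(1, 4))
  for (i in 1:4) {
    pr <- pair_probabilities(msa, w, i, i)
    h <- -sum(pr$p_i[pr$p_i > 0] * log(pr$p_i[pr$p_i > 0]))
    expect_equal(mutual_information(pr), h, tolerance = 1e-12)
  }
})

test_that("chi-squared to probability matches a numerically integrated CDF", {
  expect_equal(chi2_to_probability(0), 0)
  expect_equal(chi2_to_probability(3.841), 0.950, tolerance = 1e-3)
  xs <- c(0.01, 0.5, 1, 3.841, 7.2)
  expect_equal(chi2_to_probability(xs), chi2_cdf_numeric(xs),
               tolerance = 1e-9)
  expect_true(all(diff(chi2_to_probability(xs)) > 0))
  expect_error(chi2_to_probability(-0.1), class = "coevgraph_usage_error")
})

test_that("Pearson scores: self-correlation, sign-flip, hand evaluation", {
  msa <- msa_of("ACD", "CDA", "DAC")
  w <- manual_weights(rep(1, 3))
  scores <- matrix(0L, 3, 20, dimnames = list(NULL, PSSM_ORDER <- c(
    "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")))
  scores[, "A"] <- c(4L, 1L, -2L)
  scores[, "C"] <- c(-1L, 5L, 0L)
  scores[, "D"] <- c(2L, -3L, 6L)
  pssm <- new_pssm(scores, residues = c("A", "C", "D"))

  expect_equal(pearson_covariance(msa, pssm, w, 1, 1), 1.0)
  expect_equal(pearson_covariance(msa, pssm, w, 2, 3),
               naive_pearson(msa$seqs, scores, rep(1, 3), 2, 3),
               tolerance = 1e-12)

  # a column whose realized scores are an exact negative affine transform
  msa2 <- msa_of("AA", "CC", "DD")
  s2 <- matrix(0L, 2, 20, dimnames = list(NULL, PSSM_ORDER))
  s2[1, c("A", "C", "D")] <- c(1L, 2L, 3L)
  s2[2, c("A", "C", "D")] <- c(-2L, -4L, -6L)
  pssm2 <- new_pssm(s2, residues = c("A", "A"))
  expect_equal(pearson_covariance(msa2, pssm2, w, 1, 2), 1.0)

  # conserved column (zero sigma) is masked
  msa3 <- msa_of("AA", "AC", "AD")
  expect_true(is.na(pearson_covariance(msa3, pssm2, w, 1, 2)))
})

test_that("full matrices match naive loops on random gapped alignments", {
  for (rep in 1:4) {
    sim <- generate_msa(L = 6, N = 12, gap_rate = 0.12, seed = 300 + rep)
    msa <- sim$msa
    wn <- naive_weights(msa$seqs)
    w <- compute_weights(msa)
    expect_equal(unname(w$w), wn, tolerance = 1e-12)
    pssm <- generate_pssm(msa, w)

    for (spec_case in list(c("mi", "2"), c("chi2", "2"),
                           c("mi", "20"), c("chi2", "20"))) {
      metric <- spec_case[1]; ab <- spec_case[2]
      cm <- covariance_matrix(msa, metric, ab, weights = w,
                              post_process = FALSE)
      for (i in 1:6) for (j in i:6) {
        pr <- naive_probs(msa$seqs, wn, i, j, alphabet = ab)
        expected <- if (pr$n_eff == 0) NA_real_ else
          if (metric == "mi") naive_mi(pr) else naive_chi2(pr)
        expect_equal(cm$values[i, j], expected, tolerance = 1e-10,
                     label = sprintf("%s/%s-letter (%d,%d)", metric, ab, i, j))
      }
    }

    sc <- pssm$scores
    colnames(sc) <- pssm$aa_order
    cmr <- covariance_matrix(msa, "pearson", pssm = pssm, weights = w)
    for (i in 1:6) for (j in i:6) {
      expect_equal(cmr$values[i, j],
                   naive_pearson(msa$seqs, sc, wn, i, j),
                   tolerance = 1e-10)
    }
  }
})

test_that("post-processed chi2 matrices are CDF-transformed and symmetric", {
  sim <- generate_msa(L = 10, N = 30, seed = 5)
  raw <- covariance_matrix(sim$msa, "chi2", post_process = FALSE)
  cdf <- covariance_matrix(sim$msa, "chi2", post_process = TRUE)
  expect_equal(cdf$values, matrix(pchisq(raw$values, df = 1), 10, 10,
                                  dimnames = dimnames(raw$values)))
  expect_true(all(cdf$values >= 0 & cdf$values <= 1, na.rm = TRUE))
  expect_identical(cdf$values, t(cdf$values))
  expect_true(all(raw$values >= -1e-12, na.rm = TRUE))
  mi <- covariance_matrix(sim$msa, "mi")
  expect_true(all(mi$values >= -1e-12, na.rm = TRUE))
})

test_that("planted perfectly-coupled pair attains the top off-diagonal score", {
  sim <- generate_msa(L = 12, N = 80,
                      planted = data.frame(i = 3, j = 9, strength = 1),
                      seed = 77)
  for (metric in c("chi2", "mi")) {
    cm <- covariance_matrix(sim$msa, metric)
    vals <- cm$values
    diag(vals) <- NA
    top <- which(vals == max(vals, na.rm = TRUE), arr.ind = TRUE)
    expect_true(any(top[, 1] == 3 & top[, 2] == 9))
  }
})

test_that("single-sequence alignments carry no pairwise variation", {
  msa <- msa_of("ACDEF")
  cm <- covariance_matrix(msa, "chi2", post_process = FALSE)
  off <- cm$values[upper.tri(cm$values)]
  expect_true(all(off == off[1]))   # constant: no information to rank pairs
  pssm <- generate_pssm(msa)
  cmr <- covariance_matrix(msa, "pearson", pssm = pssm)
  expect_true(all(is.na(cmr$values)))  # zero variance everywhere
})

test_that("duplicating every sequence leaves all metrics unchanged", {
  sim <- generate_msa(L = 8, N = 10, seed = 13)
  msa <- sim$msa
  pssm <- generate_pssm(msa)
  for (k in c(2L, 3L)) {
    dup <- new_msa(rep(msa$seqs, each = k), query_index = 1L)
    for (metric in c("chi2", "mi")) {
      a <- covariance_matrix(msa, metric)
      b <- covariance_matrix(dup, metric)
      expect_equal(a$values, b$values, tolerance = 1e-9)
    }
    a <- covariance_matrix(msa, "pearson", pssm = pssm)
    b <- covariance_matrix(dup, "pearson", pssm = pssm)
    expect_equal(a$values, b$values, tolerance = 1e-9)
  }
})

test_that("2- and 20-letter chi2 agree on binary-composition columns", {
  # every column holds only the query residue and one fixed alternative
  set.seed(41)
  q <- sample(amino_acids(), 10, replace = TRUE)
  alt <- vapply(q, function(a) sample(setdiff(amino_acids(), a), 1), "")
  seqs <- vapply(1:15, function(l) {
    paste(ifelse(stats::runif(10) < 0.5, q, alt), collapse = "")
  }, "")
  msa <- new_msa(c(paste(q, collapse = ""), seqs))
  w <- compute_weights(msa)
  c2 <- covariance_matrix(msa, "chi2", "2", weights = w, post_process = FALSE)
  c20 <- covariance_matrix(msa, "chi2", "20", weights = w,
                           post_process = FALSE)
  expect_equal(c2$values, c20$values, tolerance = 1e-10)
})

test_that("pearson requires a PSSM and matrices mask degenerate pairs", {
  sim <- generate_msa(L = 6, N = 8, seed = 3)
  expect_error(covariance_matrix(sim$msa, "pearson"),
               class = "coevgraph_usage_error")
})
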