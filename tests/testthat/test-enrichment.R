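test_that("log-odds counts reproduce hand-worked values and NA rules", {
  expect_equal(lo_from_counts(4, 5, 10, 101), log((4 / 9) / (5 / 100)))
  expect_equal(lo_from_counts(4, 5, 10, 101), 2.1848, tolerance = 1e-4)
  # all and only functional residues covarying: reduces to log((N-1)/n)
  expect_equal(lo_from_counts(9, 9, 10, 520), log(519 / 9))
  expect_equal(lo_from_counts(9, 9, 10, 520), 4.054, tolerance = 1e-3)
  # zero or undefined logarithm arguments
  expect_true(is.na(lo_from_counts(0, 5, 10, 101)))
  expect_true(is.na(lo_from_counts(4, 0, 10, 101)))
  expect_true(is.na(lo_from_counts(0, 0, 1, 101)))
  expect_true(is.na(lo_from_counts(1, 1, 1, 101)))
})

test_that("LO sign tracks the enrichment ratio over random counts", {
  set.seed(83)
  for (k in 1:200) {
    N <- sample(50:500, 1)
    Rf <- sample(2:20, 1)
    n <- sample(1:(N - 1), 1)
    r <- sample(1:min(n, Rf - 1), 1)
    lo <- lo_from_counts(r, n, Rf, N)
    expect_equal(lo > 0, r / (Rf - 1) > n / (N - 1))
  }
})

test_that("neighborhood LO counts covarying partners above the cutoff", {
  V <- matrix(0, 8, 8)
  edge <- function(a, b, s) V[a, b] <<- V[b, a] <<- s
  edge(1, 2, 0.9); edge(1, 3, 0.8); edge(1, 4, 0.7); edge(1, 5, 0.2)
  cm <- manual_cov(V)
  ann <- coevgraph:::annotation_from_records(tibble::tibble(
    protein_id = "P", ligand_code = "ZN", position = c(1L, 2L, 3L, 7L),
    residue = "A"))
  # at cutoff 0.5: partners of 1 are {2,3,4}; same-function {2,3}
  expect_equal(lo_score(cm, ann, 1, "metal", 0.5),
               lo_from_counts(2, 3, 4, 8))
  # cutoff above every score: n = 0
  expect_true(is.na(lo_score(cm, ann, 1, "metal", 0.95)))
  # unannotated residue is a usage error
  expect_error(lo_score(cm, ann, 5, "metal", 0.5),
               class = "coevgraph_usage_error")
  # masked entries never count
  V[1, 4] <- V[4, 1] <- NA
  cm2 <- manual_cov(V)
  expect_equal(lo_score(cm2, ann, 1, "metal", 0.5),
               lo_from_counts(2, 2, 4, 8))
})

test_that("clique LO counts by membership, not by direct coupling", {
  ann <- coevgraph:::annotation_from_records(tibble::tibble(
    protein_id = "P", ligand_code = "ZN",
    position = as.integer(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)), residue = "A"))
  # clique = {i} + the 9 other functional residues in a 101-residue protein
  expect_equal(lo_clique(1:10, ann, 1, "metal", N = 101),
               log((9 / 9) / (9 / 100)))
  expect_equal(lo_clique(1:10, ann, 1, "metal", N = 101), 2.408,
               tolerance = 1e-3)
  # no functional members besides i
  ann2 <- coevgraph:::annotation_from_records(tibble::tibble(
    protein_id = "P", ligand_code = "ZN", position = c(1L, 50L),
    residue = "A"))
  expect_true(is.na(lo_clique(c(1L, 20L, 30L), ann2, 1, "metal", N = 101)))
  expect_error(lo_clique(c(2L, 3L), ann, 1, "metal", N = 101),
               class = "coevgraph_usage_error")
  # members count toward n regardless of their pairwise score with i
  expect_equal(lo_clique(c(1L, 2L, 40L), ann, 1, "metal", N = 101),
               lo_from_counts(1, 2, 10, 101))
})

test_that("clique LO equals neighborhood LO when the clique is the cutoff neighborhood", {
  # positions {1,2,3} fully interconnected above the cutoff, nothing else
  V <- matrix(0, 9, 9)
  for (a in 1:3) for (b in 1:3) if (a != b) V[a, b] <- 0.9
  cm <- manual_cov(V)
  ann <- coevgraph:::annotation_from_records(tibble::tibble(
    protein_id = "P", ligand_code = "ZN", position = c(1L, 2L, 5L),
    residue = "A"))
  g <- build_graph(cm, 0.5)
  cl <- maximal_cliques(g)
  expect_equal(cl$cliques, list(1:3))
  expect_equal(lo_clique(cl$cliques[[1]], ann, 1, "metal", N = 9),
               lo_score(cm, ann, 1, "metal", 0.5))
})

test_that("P(LO) is the empirical survival fraction and monotone", {
  expect_equal(as.numeric(p_lo(c(0.1, 0.5), 1)), 0)
  expect_equal(as.numeric(p_lo(c(2, 3), 1)), 1)
  expect_equal(as.numeric(p_lo(c(1, 2, 3, 4), 2.5)), 0.5)
  v <- c(1, NA, 2, NA, 3)
  out <- p_lo(v, 1.5)
  expect_equal(as.numeric(out), 2 / 3)
  expect_equal(attr(out, "n_na"), 2L)
  expect_true(is.na(p_lo(c(NA_real_, NA_real_), 1)))
  cuts <- seq(-2, 5, by = 0.5)
  ps <- vapply(cuts, function(cc) as.numeric(p_lo(c(-1, 0, 1, 2, 2, 3), cc)), 0)
  expect_true(all(diff(ps) <= 0))
})

test_that("propensities are background-normalized log ratios", {
  # one protein: each amino acid exactly 20 times -> F_a = 0.05 for all
  seqv <- paste(rep(amino_acids(), each = 20), collapse = "")
  # 10 metal sites, 4 of them C (C block spans positions 21-40)
  pos <- c(21L, 22L, 23L, 24L,          # C
           1L, 41L, 61L, 81L, 101L, 121L)  # A, D, E, F, G, H
  ann <- coevgraph:::annotation_from_records(tibble::tibble(
    protein_id = "P", ligand_code = "ZN", position = pos, residue = NA))
  tab <- propensity_table(ann, c(P = seqv))
  expect_equal(tab$metal[tab$aa == "C"], log(0.4 / 0.05))
  expect_equal(tab$metal[tab$aa == "C"], 2.079, tolerance = 1e-3)
  # f equal to background gives zero propensity: here f_A = 0.1, F_A = 0.05
  expect_equal(tab$metal[tab$aa == "A"], log(0.1 / 0.05))
  # never-observed amino acid is NA
  expect_true(is.na(tab$metal[tab$aa == "W"]))
  # reconstruction: exp(P) * F = f for all non-NA cells
  f <- attr(tab, "f"); F_a <- attr(tab, "F")
  nz <- !is.na(f[, "metal"]) & f[, "metal"] > 0
  expect_equal(exp(tab$metal[nz]) * F_a[nz], f[nz, "metal"],
               tolerance = 1e-12)
})

test_that("distance distributions bin consecutive same-ligand separations", {
  mk <- function(pos, code = "ZN", id = "P1") tibble::tibble(
    protein_id = id, ligand_code = code, position = as.integer(pos),
    residue = "A")
  ann <- coevgraph:::annotation_from_records(mk(c(10, 12)))
  d <- distance_distribution(ann)
  expect_equal(d$metal, c(100, 0, 0))
  expect_equal(d$bin, c("1-4", "5-29", "30-1000"))

  ann2 <- coevgraph:::annotation_from_records(mk(c(1, 3, 40)))
  d2 <- distance_distribution(ann2)
  expect_equal(d2$metal, c(50, 0, 50))
  expect_equal(sum(d2$metal), 100)

  # single annotated residue contributes nothing
  ann3 <- coevgraph:::annotation_from_records(
    dplyr::bind_rows(mk(5), mk(c(2, 4), code = "COA", id = "P2")))
  d3 <- distance_distribution(ann3)
  expect_true(all(is.na(d3$metal)))
  expect_equal(d3$`coenzyme A`, c(100, 0, 0))

  # all-pairs alternative: {1,3,40} -> distances {2, 37, 39}
  d4 <- distance_distribution(ann2, all_pairs = TRUE)
  expect_equal(d4$metal, c(100 / 3, 0, 200 / 3), tolerance = 1e-9)

  # distances beyond the last bin edge clamp into it
  ann5 <- coevgraph:::annotation_from_records(mk(c(1, 1500)))
  expect_equal(distance_distribution(ann5)$metal, c(0, 0, 100))
})

test_that("benchmark summaries count distinct residues per category", {
  rows <- tibble::tibble(
    protein_id = c("P1", "P1", "P1", "P2", "P2"),
    ligand_code = c("ZN", "MG", "FE", "GLC", "GLC"),
    position = c(1L, 2L, 3L, 7L, 7L),
    residue = "A")
  ann <- coevgraph:::annotation_from_records(rows)
  s <- benchmark_summary(ann)
  expect_equal(s$n_residues[s$category == "metal"], 3L)
  expect_equal(s$n_residues[s$category == "sugar"], 1L)
  empty <- coevgraph:::annotation_from_records(rows[0, ])
  expect_equal(nrow(benchmark_summary(empty)), 0L)
})

test_that("per-protein LO reports have the per-residue x per-cutoff shape", {
  sim <- generate_msa(L = 20, N = 80,
                      planted = data.frame(i = c(3, 8), j = c(13, 17),
                                           strength = c(1, 1)),
                      seed = 91)
  cm <- covariance_matrix(sim$msa, "chi2")
  ann <- generate_annotation(sim$truth, "metal")
  rep_ <- protein_lo_report(cm, ann, cutoffs = c(0.3, 0.5))
  expect_equal(nrow(rep_), 4L)
  expect_equal(names(rep_), c("position", "residue", "category", "0.3", "0.5"))
  expect_equal(rep_$position, c(3L, 8L, 13L, 17L))
  # above the background noise ceiling each planted residue covaries
  # essentially only with its planted partner, which is annotated too
  expect_true(all(is.na(rep_$`0.5`) | rep_$`0.5` > 1))
  expect_gte(sum(is.finite(rep_$`0.5`)), 2L)

  # cutoff above the maximum: all NA
  rep_hi <- protein_lo_report(cm, ann, cutoffs = 1.1)
  expect_true(all(is.na(rep_hi$`1.1`)))

  # unannotated protein: empty report with a warning
  expect_warning(
    rep0 <- protein_lo_report(cm, ann, cutoffs = 0.5, protein = "nope"),
    "no annotated")
  expect_equal(nrow(rep0), 0L)

  # clique mode agrees with direct clique evaluation
  repc <- protein_lo_report(cm, ann, cutoffs = 0.5, mode = "clique")
  g <- build_graph(cm, 0.5)
  cl <- maximal_cliques(g)
  in3 <- cl$cliques[vapply(cl$cliques, function(q) 3 %in% q, TRUE)]
  expect_gt(length(in3), 0L)
  expected <- max(vapply(in3, function(q)
    lo_clique(q, ann, 3, "metal", N = cm$L), 0), na.rm = TRUE)
  expect_equal(repc$`0.5`[repc$position == 3], expected)
})

test_that("pooled LO values feed the survival probability", {
  sim <- generate_msa(L = 16, N = 60,
                      planted = data.frame(i = 4, j = 11, strength = 1),
                      seed = 15)
  cm <- covariance_matrix(sim$msa, "chi2")
  ann <- generate_annotation(sim$truth, "metal", n_decoys = 2)
  pool <- lo_pool(cm, ann, cutoff = 0.5)
  expect_equal(names(pool), c("protein_id", "category", "position", "lo"))
  expect_equal(nrow(pool), 4L)
  pv <- p_lo(pool$lo, 0)
  expect_true(is.na(pv) || (pv >= 0 && pv <= 1))
})
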