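# Log-odds enrichment of same-function residues among covarying positions,
# amino-acid propensities, and benchmark summaries.

#' Log-odds from enrichment counts
#'
#' `LO = log((r / (Rf - 1)) / (n / (N - 1)))` with natural log: `r`
#' same-function residues among the `n` covarying (or clique) partners of a
#' residue, `Rf` residues carrying the function in the protein, `N` protein
#' length. Returns `NA` whenever an argument of the logarithm is 0 or
#' undefined (zero `r`, zero `n`, or `Rf <= 1`).
#'
#' @param r,n,Rf,N Non-negative integer counts.
#' @return The LO score, or `NA`.
#' @export
lo_from_counts <- function(r, n, Rf, N) {
  ifelse(r <= 0 | n <= 0 | Rf <= 1 | N <= 1,
         NA_real_,
         log((r / (Rf - 1)) / (n / (N - 1))))
}

#' Log-odds enrichment of a residue's covarying neighborhood
#'
#' For annotated residue `i`: `n` counts positions `j != i` whose unmasked
#' covariance score with `i` is at or above the cutoff, `r` counts those that
#' share the function.
#'
#' @param cov A `cov_matrix` for the protein.
#' @param annotation A `site_annotation` tibble.
#' @param i 1-based residue position; must be annotated with `category`.
#' @param category Ligand category.
#' @param cutoff Covariance cutoff `c`.
#' @param protein Protein id in `annotation`; defaults to its single id.
#' @param N Protein length (defaults to `cov$L`).
#' @return The LO score, or `NA` (see [lo_from_counts()]).
#' @export
lo_score <- function(cov, annotation, i, category, cutoff,
                     protein = NULL, N = NULL) {
  if (is.null(protein)) protein <- unique(annotation$protein_id)[1]
  if (is.null(N)) N <- cov$L
  sites <- annotated_positions(annotation, protein, category)
  if (!(i %in% sites)) {
    stop_usage("position %d is not annotated with category '%s'", i, category)
  }
  sc <- cov$values[i, ]
  covarying <- which(!is.na(sc) & sc >= cutoff)
  covarying <- setdiff(covarying, i)
  n <- length(covarying)
  r <- length(intersect(covarying, sites))
  lo_from_counts(r, n, length(sites), N)
}

#' Log-odds enrichment within a clique
#'
#' Clique-based variant: `n` is the clique size minus one (all members except
#' `i`, whether or not they covary with `i` directly above the cutoff), `r`
#' the members sharing the function.
#'
#' @param clique Integer vector of clique member positions (must contain `i`).
#' @param annotation A `site_annotation` tibble.
#' @param i Residue position.
#' @param category Ligand category.
#' @param protein Protein id; defaults to the annotation's single id.
#' @param N Protein length.
#' @return The LO score, or `NA`.
#' @export
lo_clique <- function(clique, annotation, i, category, protein = NULL,
                      N = NULL) {
  if (!(i %in% clique)) stop_usage("position %d is not in the clique", i)
  if (is.null(protein)) protein <- unique(annotation$protein_id)[1]
  if (is.null(N)) stop_usage("protein length N is required")
  sites <- annotated_positions(annotation, protein, category)
  others <- setdiff(clique, i)
  lo_from_counts(length(intersect(others, sites)), length(others),
                 length(sites), N)
}

#' Empirical LO survival probability
#'
#' `P(LO)` = fraction of finite LO values at or above the cutoff (1 minus
#' the empirical cumulative probability). `NA` values never participate;
#' their count is attached as attribute `n_na`.
#'
#' @param lo_values Numeric vector of LO scores (may contain `NA`).
#' @param lo_cutoff LO threshold.
#' @return Probability in `[0, 1]`, or `NA` when no finite value exists.
#' @export
p_lo <- function(lo_values, lo_cutoff) {
  v <- lo_values[is.finite(lo_values)]
  out <- if (length(v) == 0L) NA_real_ else mean(v >= lo_cutoff)
  attr(out, "n_na") <- length(lo_values) - length(v)
  attr(out, "n_finite") <- length(v)
  out
}

#' Amino-acid binding propensities per ligand category
#'
#' `P(a | l) = log(f_al / F_a)`: the fraction `f_al` of amino acid `a` among
#' all annotated residues of ligand `l` (pooled across proteins), normalized
#' to the background frequency `F_a` of `a` over all residues of all
#' sequences. Cells with `f_al = 0` are `NA`.
#'
#' @param annotation A `site_annotation` tibble.
#' @param sequences Named character vector (protein id to ungapped sequence)
#'   or tibble with columns `id`, `sequence`.
#' @return Tibble of class `propensity_table`: column `aa` plus one column
#'   per category; fractions and background attached as attributes `f` and
#'   `F`.
#' @export
propensity_table <- function(annotation, sequences) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$id)
  }
  aas <- amino_acids()
  allres <- unlist(strsplit(toupper(unname(sequences)), "", fixed = TRUE))
  allres <- allres[allres %in% aas]
  bg <- table(factor(allres, levels = aas))
  F_a <- as.numeric(bg) / sum(bg)
  names(F_a) <- aas
  cats <- sort(unique(annotation$category))
  f <- matrix(NA_real_, 20, length(cats), dimnames = list(aas, cats))
  n_mismatch <- 0L
  for (cc in cats) {
    sub <- annotation[annotation$category == cc, ]
    letters_obs <- character(0)
    for (k in seq_len(nrow(sub))) {
      seqk <- sequences[[sub$protein_id[k]]]
      if (is.null(seqk) || sub$position[k] > nchar(seqk)) next
      aa <- toupper(substr(seqk, sub$position[k], sub$position[k]))
      if (!is.na(sub$residue[k]) && nzchar(sub$residue[k]) &&
          aa != toupper(sub$residue[k])) {
        n_mismatch <- n_mismatch + 1L
      }
      if (aa %in% aas) letters_obs <- c(letters_obs, aa)
    }
    if (length(letters_obs) > 0) {
      tt <- table(factor(letters_obs, levels = aas))
      f[, cc] <- as.numeric(tt) / sum(tt)
    }
  }
  if (n_mismatch > 0) {
    warn(sprintf("%d annotated residue letter(s) disagree with the sequences",
                 n_mismatch))
  }
  P <- log(f / F_a)
  P[!is.finite(P)] <- NA_real_
  P[is.na(f) | f == 0] <- NA_real_
  out <- tibble::as_tibble(as.data.frame(P), rownames = "aa") |>
    tibble::as_tibble()
  names(out) <- c("aa", cats)
  structure(out, class = c("propensity_table", class(out)),
            f = f, F = F_a, n_mismatch = n_mismatch)
}

#' Distance distribution of same-ligand binding sites
#'
#' Distances between consecutive sorted positions binding the same ligand
#' category within a protein, pooled across proteins, binned (default 1-4,
#' 5-29, 30-1000; larger distances clamp into the last bin) and expressed as
#' percentages per category (summing to 100). With `all_pairs = TRUE` all
#' pairwise distances are used instead of consecutive ones.
#'
#' @param annotation A `site_annotation` tibble.
#' @param breaks Lower bin edges (default `c(1, 5, 30)`).
#' @param upper Upper clamp for the last bin (default 1000).
#' @param all_pairs Use all pairwise distances (default FALSE).
#' @return Tibble with column `bin` plus one percentage column per category
#'   (`NA` where a category has no pair anywhere).
#' @export
distance_distribution <- function(annotation, breaks = c(1, 5, 30),
                                  upper = 1000, all_pairs = FALSE) {
  labels <- c(paste0(breaks[-length(breaks)], "-",
                     breaks[-1] - 1),
              paste0(breaks[length(breaks)], "-", upper))
  cats <- sort(unique(annotation$category))
  out <- matrix(NA_real_, length(labels), length(cats),
                dimnames = list(labels, cats))
  for (cc in cats) {
    dd <- annotation |>
      dplyr::filter(.data$category == cc) |>
      dplyr::group_by(.data$protein_id) |>
      dplyr::summarise(d = list({
        p <- sort(unique(.data$position))
        if (length(p) < 2L) integer(0)
        else if (all_pairs) as.integer(stats::dist(p))
        else diff(p)
      }), .groups = "drop")
    d <- unlist(dd$d)
    if (length(d) == 0L) next
    d <- pmin(d, upper)
    bin <- findInterval(d, breaks)
    bin[bin < 1L] <- 1L
    tt <- tabulate(bin, nbins = length(labels))
    out[, cc] <- 100 * tt / sum(tt)
  }
  tibble::as_tibble(as.data.frame(out), rownames = "bin")
}

#' Per-category residue counts
#'
#' Total distinct (protein, position) residues per ligand category.
#'
#' @param annotation A `site_annotation` tibble.
#' @return Tibble with columns `category`, `n_residues`.
#' @export
benchmark_summary <- function(annotation) {
  annotation |>
    dplyr::distinct(.data$protein_id, .data$category, .data$position) |>
    dplyr::count(.data$category, name = "n_residues") |>
    dplyr::arrange(dplyr::desc(.data$n_residues))
}

#' Per-residue, per-cutoff LO report
#'
#' One row per annotated residue (and category), one column per cutoff —
#' the shape used to report LO scores of a protein's binding residues. In
#' `"clique"` mode the reported value is the maximum finite clique-based LO
#' over the maximal cliques containing the residue at that cutoff.
#'
#' @param cov A `cov_matrix`.
#' @param annotation A `site_annotation` tibble for the same protein.
#' @param cutoffs Covariance cutoffs (columns of the report).
#' @param protein Protein id; defaults to the annotation's single id.
#' @param mode `"neighbors"` (direct covariance partners) or `"clique"`.
#' @param min_separation,min_size Graph/clique parameters for clique mode.
#' @return Tibble of class `lo_report`: `position`, `residue`, `category`,
#'   then one numeric column per cutoff (`NA` cells allowed).
#' @export
protein_lo_report <- function(cov, annotation, cutoffs = seq(0.1, 0.9, 0.1),
                              protein = NULL,
                              mode = c("neighbors", "clique"),
                              min_separation = 1L, min_size = 2L) {
  mode <- match.arg(mode)
  if (is.null(protein)) protein <- unique(annotation$protein_id)[1]
  ann <- annotation[annotation$protein_id == protein, ]
  qchars <- strsplit(cov$query, "", fixed = TRUE)[[1]]
  if (nrow(ann) == 0L) {
    warn(sprintf("no annotated residues for protein '%s'", protein))
    out <- tibble::tibble(position = integer(), residue = character(),
                          category = character())
    for (cval in cutoffs) out[[format_cutoff(cval)]] <- numeric(0)
    class(out) <- c("lo_report", class(out))
    return(out)
  }
  base <- ann |>
    dplyr::distinct(.data$category, .data$position) |>
    dplyr::arrange(.data$category, .data$position) |>
    dplyr::mutate(residue = qchars[.data$position]) |>
    dplyr::select("position", "residue", "category")
  for (cval in cutoffs) {
    if (mode == "neighbors") {
      vals <- purrr::map2_dbl(base$position, base$category, function(p, cc) {
        lo_score(cov, annotation, p, cc, cval, protein = protein)
      })
    } else {
      g <- build_graph(cov, cval, min_separation)
      cl <- maximal_cliques(g, min_size)
      vals <- purrr::map2_dbl(base$position, base$category, function(p, cc) {
        containing <- cl$cliques[vapply(cl$cliques, function(q) p %in% q, TRUE)]
        if (length(containing) == 0L) return(NA_real_)
        los <- vapply(containing, function(q) {
          lo_clique(q, annotation, p, cc, protein = protein, N = cov$L)
        }, 0)
        if (all(is.na(los))) NA_real_ else max(los, na.rm = TRUE)
      })
    }
    base[[format_cutoff(cval)]] <- vals
  }
  class(base) <- c("lo_report", class(base))
  base
}

format_cutoff <- function(x) format(x, trim = TRUE)

#' Pooled per-residue LO values at one cutoff
#'
#' Concatenates the LO value of every annotated residue (per category) of
#' every protein present in both the annotation and the supplied matrices —
#' the pooled distribution from which `P(LO)` is computed.
#'
#' @param matrices Named list of `cov_matrix` objects (names are protein ids),
#'   or a single `cov_matrix` for a single-protein annotation.
#' @param annotation A `site_annotation` tibble.
#' @param cutoff Covariance cutoff.
#' @param mode `"neighbors"` or `"clique"` (see [protein_lo_report()]).
#' @return Tibble with columns `protein_id`, `category`, `position`, `lo`.
#' @export
lo_pool <- function(matrices, annotation, cutoff,
                    mode = c("neighbors", "clique")) {
  mode <- match.arg(mode)
  if (inherits(matrices, "cov_matrix")) {
    matrices <- setNames(list(matrices), unique(annotation$protein_id)[1])
  }
  rows <- purrr::map(intersect(names(matrices),
                               unique(annotation$protein_id)),
                     function(pid) {
    rep_ <- protein_lo_report(matrices[[pid]], annotation, cutoffs = cutoff,
                              protein = pid, mode = mode)
    tibble::tibble(protein_id = pid, category = rep_$category,
                   position = rep_$position,
                   lo = rep_[[format_cutoff(cutoff)]])
  })
  dplyr::bind_rows(rows)
}

#' Export an LO report / propensity table / distance table as TSV
#' @param x A tibble (e.g. from [protein_lo_report()], [propensity_table()],
#'   [distance_distribution()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, na = "NA")
  invisible(path)
}
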