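# Synthetic alignments with planted covarying column pairs, redundancy
# groups, toy PSSMs and annotations.

#' Generate a synthetic alignment with planted covarying pairs
#'
#' Background columns are drawn independently per sequence from the
#' background residue distribution. Each planted pair `(i, j, strength)`
#' shares a latent binary signal: a sequence draws a coin and carries either
#' the query residue or a fixed alternative residue at both columns; with
#' probability `1 - strength` each column's state is re-drawn independently,
#' so `strength = 1` gives perfect coupling and `strength = 0` independence.
#' Redundancy groups are built by mutating a fresh seed sequence at 5% of
#' positions per member, guaranteeing over 80% within-group identity to
#' exercise the phylogenetic weighting. The first row is the query (no gaps).
#'
#' @param L Number of columns (>= 2).
#' @param N Number of sequences including the query (>= 2).
#' @param planted Data frame / tibble with columns `i`, `j`, `strength`, or
#'   `NULL`. Planted columns must be distinct and within `L`.
#' @param redundancy Integer vector of near-duplicate group sizes, or `NULL`.
#' @param background Named probability vector over the 20 amino acids
#'   (default uniform).
#' @param gap_rate Per-cell gap probability for non-query rows (default 0).
#' @param seed Integer seed; fully determines the output.
#' @return List with elements `msa` (an [new_msa()] object) and `truth`
#'   (class `synthetic_truth`: planted pairs with their alternative residues,
#'   redundancy group row indices, the query string, `background`,
#'   `gap_rate`, `seed`, and empty `decoys`).
#' @export
generate_msa <- function(L = 50L, N = 200L, planted = NULL, redundancy = NULL,
                         background = NULL, gap_rate = 0, seed = 1L) {
  if (L < 2L || N < 2L) stop_usage("need L >= 2 and N >= 2")
  aas <- amino_acids()
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), aas)
  }
  background <- background[aas] / sum(background)
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    cols <- c(planted$i, planted$j)
    if (any(cols < 1L) || any(cols > L)) {
      stop_usage("planted columns must lie in [1, %d]", L)
    }
    if (anyDuplicated(cols)) {
      stop_usage("planted pairs must not share columns")
    }
  }
  n_red <- if (is.null(redundancy)) 0L else sum(redundancy)
  if (n_red > N - 1L) stop_usage("redundancy groups exceed N - 1 sequences")

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  query <- sample(aas, L, replace = TRUE, prob = background)
  m <- matrix("", N, L)
  m[1, ] <- query
  n_free <- N - 1L - n_red
  for (l in seq_len(n_free)) {
    m[1L + l, ] <- sample(aas, L, replace = TRUE, prob = background)
  }
  groups <- list()
  row <- 1L + n_free
  n_mut <- max(1L, floor(0.05 * L))
  for (gs in (redundancy %||% integer(0))) {
    seed_seq <- sample(aas, L, replace = TRUE, prob = background)
    idx <- integer(gs)
    for (k in seq_len(gs)) {
      row <- row + 1L
      member <- seed_seq
      pos <- sample.int(L, n_mut)
      member[pos] <- vapply(member[pos], function(a) {
        sample(setdiff(aas, a), 1L)
      }, "")
      m[row, ] <- member
      idx[k] <- row
    }
    groups[[length(groups) + 1L]] <- idx
  }

  truth_pairs <- NULL
  if (!is.null(planted) && nrow(planted) > 0) {
    alt <- function(a) sample(setdiff(aas, a), 1L)
    planted$alt_i <- vapply(query[planted$i], alt, "")
    planted$alt_j <- vapply(query[planted$j], alt, "")
    for (k in seq_len(nrow(planted))) {
      i <- planted$i[k]; j <- planted$j[k]; s <- planted$strength[k]
      for (l in 2:N) {
        z <- stats::runif(1) < 0.5
        si <- if (z) query[i] else planted$alt_i[k]
        sj <- if (z) query[j] else planted$alt_j[k]
        if (stats::runif(1) > s) {
          si <- if (stats::runif(1) < 0.5) query[i] else planted$alt_i[k]
        }
        if (stats::runif(1) > s) {
          sj <- if (stats::runif(1) < 0.5) query[j] else planted$alt_j[k]
        }
        m[l, i] <- si
        m[l, j] <- sj
      }
    }
    truth_pairs <- planted
  }

  if (gap_rate > 0) {
    for (l in 2:N) {
      gpos <- stats::runif(L) < gap_rate
      m[l, gpos] <- "-"
    }
  }

  ids <- c("query", paste0("seq", seq_len(N - 1L) + 1L))
  msa <- new_msa(apply(m, 1L, paste0, collapse = ""), ids = ids,
                 query_index = 1L, col_map = seq_len(L))
  truth <- structure(
    list(planted = truth_pairs, redundancy_groups = groups,
         query_seq = paste0(query, collapse = ""),
         background = background, gap_rate = gap_rate, seed = seed,
         decoys = integer(0), category = NULL),
    class = "synthetic_truth")
  list(msa = msa, truth = truth)
}

#' Planted column positions of a synthetic truth
#' @param truth A `synthetic_truth`.
#' @return Sorted integer vector of planted columns (may be empty).
#' @export
planted_positions <- function(truth) {
  if (is.null(truth$planted)) return(integer(0))
  sort(unique(c(truth$planted$i, truth$planted$j)))
}

#' Generate toy binding-site annotations from a synthetic truth
#'
#' Marks the planted-pair columns as binding sites of the category;
#' optionally adds decoy sites on background (non-planted) columns, recorded
#' in the attributes.
#'
#' @param truth A `synthetic_truth`.
#' @param category Ligand category (default `"metal"`).
#' @param n_decoys Number of decoy positions (default 0).
#' @param protein Protein id for the records (default `"query"`).
#' @param seed Seed for decoy placement (default `truth$seed + 1`).
#' @return A `site_annotation` tibble; decoy positions in attribute
#'   `decoys`, planted positions in attribute `planted`.
#' @export
generate_annotation <- function(truth, category = "metal", n_decoys = 0L,
                                protein = "query", seed = truth$seed + 1L) {
  pp <- planted_positions(truth)
  if (length(pp) == 0L) stop_usage("truth has no planted pairs")
  qchars <- strsplit(truth$query_seq, "", fixed = TRUE)[[1]]
  decoys <- integer(0)
  if (n_decoys > 0L) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    free <- setdiff(seq_along(qchars), pp)
    decoys <- sort(sample(free, n_decoys))
  }
  pos <- c(pp, decoys)
  ann <- tibble::tibble(protein_id = protein, category = category,
                        position = as.integer(sort(pos)),
                        residue = qchars[sort(pos)])
  structure(ann, class = c("site_annotation", class(ann)),
            decoys = decoys, planted = pp, skipped = 0L)
}

#' Generate a toy PSSM from an alignment
#'
#' Log-odds of the phylogeny-weighted column residue frequencies
#' (pseudo-counted) against the uniform background, doubled and rounded to
#' integers in the PSI-BLAST ASCII layout — enough to exercise the
#' Pearson-correlation metric and the PSSM reader round-trip.
#'
#' @param msa A trimmed `msa`.
#' @param weights Optional `seq_weights`; computed when absent.
#' @return A `pssm_profile` whose rows carry the query residues.
#' @export
generate_pssm <- function(msa, weights = NULL) {
  if (is.null(weights)) weights <- compute_weights(msa)
  m <- seq_char_matrix(msa$seqs)
  w <- unname(weights$w)
  aas <- amino_acids()
  qchars <- strsplit(query_sequence(msa), "", fixed = TRUE)[[1]]
  scores <- matrix(0L, msa$L, 20, dimnames = list(NULL, PSSM_AA_ORDER))
  for (i in seq_len(msa$L)) {
    col <- m[, i]
    keep <- col %in% aas
    cnt <- vapply(split(w[keep], factor(col[keep], levels = aas)), sum, 0)
    f <- (cnt + 0.05) / (sum(cnt) + 1)
    s <- round(2 * log2(f / 0.05))
    scores[i, ] <- as.integer(s[match(PSSM_AA_ORDER, aas)])
  }
  new_pssm(scores, qchars)
}

#' Write the synthetic truth as JSON
#' @param truth A `synthetic_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  obj <- list(planted = truth$planted,
              redundancy_groups = truth$redundancy_groups,
              query_seq = truth$query_seq,
              gap_rate = truth$gap_rate, seed = truth$seed,
              decoys = truth$decoys)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
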