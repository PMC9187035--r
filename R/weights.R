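# Phylogenetic sequence weighting and weighted pair probabilities.

#' Pairwise identity of two aligned sequences
#'
#' Identical residue pairs divided by the number of columns where both
#' sequences are non-gap. `X` never matches anything (including another `X`).
#' Returns 0 when no mutually non-gap column exists.
#'
#' @param a,b Aligned strings of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
sequence_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop_usage("sequences have unequal lengths")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  both <- !(ca %in% GAP_CHARS) & !(cb %in% GAP_CHARS)
  if (!any(both)) return(0)
  matches <- sum(ca[both] == cb[both] & is_residue(ca[both]))
  matches / sum(both)
}

# Full N x N identity matrix via per-letter cross-products:
# matches[a,b] = number of columns where both carry the same amino acid,
# nongap[a,b] = number of mutually non-gap columns.
identity_matrix <- function(msa) {
  m <- seq_char_matrix(msa$seqs)
  V <- (!(m %in% GAP_CHARS))
  dim(V) <- dim(m)
  Vn <- V * 1
  nongap <- tcrossprod(Vn)
  matches <- matrix(0, msa$N, msa$N)
  for (aa in amino_acids()) {
    Xa <- (m == aa) * 1
    matches <- matches + tcrossprod(Xa)
  }
  idm <- matches / pmax(nongap, 1L)
  idm[nongap == 0L] <- 0
  dimnames(idm) <- list(msa$ids, msa$ids)
  idm
}

#' Compute per-sequence phylogenetic weights
#'
#' Each sequence is weighted by the inverse size of its high-identity
#' neighborhood: `w_a = 1 / |{b : seqid(a, b) > threshold}|`, with `b`
#' ranging over all sequences including `a` itself, so every weight lies in
#' `(0, 1]` and near-duplicate groups share a total weight near 1.
#'
#' @param msa An `msa` object.
#' @param threshold Identity threshold as a fraction (default 0.80); the
#'   comparison is strict (`>`).
#' @return A `seq_weights` object with fields `w` (named numeric), `threshold`
#'   and the cached `identity` matrix.
#' @export
compute_weights <- function(msa, threshold = 0.80) {
  idm <- identity_matrix(msa)
  nbhd <- rowSums(idm > threshold)   # diagonal seqid = 1 counts the self
  w <- 1 / nbhd
  structure(list(w = setNames(as.numeric(w), msa$ids), threshold = threshold,
                 identity = idm),
            class = "seq_weights")
}

#' @export
print.seq_weights <- function(x, ...) {
  cat(sprintf("<seq_weights> %d sequences; threshold > %.0f%%; sum(w) = %.3f\n",
              length(x$w), 100 * x$threshold, sum(x$w)))
  invisible(x)
}

#' Export weights as a two-column tibble
#' @param x A `seq_weights` object.
#' @param ... Unused.
#' @return Tibble with columns `id`, `weight`.
#' @export
tidy.seq_weights <- function(x, ...) {
  tibble::tibble(id = names(x$w), weight = unname(x$w))
}

#' Weighted state probabilities for one column pair
#'
#' Sequences carrying a gap or `X` at either column are excluded; the
#' effective count `N_eff` is the weight sum of the included sequences.
#' Every probability uses the sub-normalized form
#' `p(s) = weighted count of s / (N_eff + 1)`, so the state probabilities of
#' a column sum to `N_eff / (N_eff + 1) < 1` by construction. Marginals are
#' computed on the same included-sequence set as the joint.
#'
#' In the 2-letter alphabet a residue is encoded `"1"` when it matches the
#' query residue of its column and `"0"` otherwise; in the 20-letter alphabet
#' states are the amino acids themselves.
#'
#' @param msa A trimmed `msa`.
#' @param weights A `seq_weights` object for `msa`.
#' @param i,j 1-based column indices.
#' @param alphabet `"2"` (query match/mismatch) or `"20"`.
#' @return A `pair_probs` object with fields `p_i`, `p_j` (named marginal
#'   vectors), `p_ij` (joint matrix), `N_eff`, `alphabet`, `degenerate`.
#' @export
pair_probabilities <- function(msa, weights, i, j,
                               alphabet = c("2", "20")) {
  alphabet <- match.arg(alphabet)
  if (i < 1L || i > msa$L || j < 1L || j > msa$L) {
    stop_usage("column index out of range [1, %d]", msa$L)
  }
  m <- seq_char_matrix(msa$seqs)
  ci <- m[, i]
  cj <- m[, j]
  keep <- is_residue(ci) & is_residue(cj)
  w <- unname(weights$w)[keep]
  n_eff <- sum(w)
  states <- if (alphabet == "2") c("0", "1") else amino_acids()
  if (n_eff == 0) {
    z <- setNames(numeric(length(states)), states)
    return(structure(list(
      p_i = z, p_j = z,
      p_ij = matrix(0, length(states), length(states),
                    dimnames = list(states, states)),
      N_eff = 0, alphabet = alphabet, degenerate = TRUE),
      class = "pair_probs"))
  }
  qi <- m[msa$query_index, i]
  qj <- m[msa$query_index, j]
  enc <- function(x, q) {
    if (alphabet == "2") ifelse(x == q, "1", "0") else x
  }
  xi <- factor(enc(ci[keep], qi), levels = states)
  xj <- factor(enc(cj[keep], qj), levels = states)
  denom <- n_eff + 1
  p_ij <- as.matrix(tapply_weighted(xi, xj, w, states)) / denom
  p_i <- rowSums(p_ij)
  p_j <- colSums(p_ij)
  structure(list(p_i = p_i, p_j = p_j, p_ij = p_ij, N_eff = n_eff,
                 alphabet = alphabet, degenerate = FALSE),
            class = "pair_probs")
}

# Weighted 2-way contingency counts over fixed state levels.
tapply_weighted <- function(xi, xj, w, states) {
  k <- length(states)
  out <- matrix(0, k, k, dimnames = list(states, states))
  idx <- cbind(as.integer(xi), as.integer(xj))
  for (r in seq_along(w)) {
    out[idx[r, 1], idx[r, 2]] <- out[idx[r, 1], idx[r, 2]] + w[r]
  }
  out
}

#' @export
print.pair_probs <- function(x, ...) {
  cat(sprintf("<pair_probs> %s-letter; N_eff = %.3f%s\n", x$alphabet, x$N_eff,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
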