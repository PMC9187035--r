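# Shared constants and small helpers.

#' The 20 standard amino acids
#'
#' One-letter codes in alphabetical order. Gap is `"-"`, unknown is `"X"`;
#' neither is part of the state alphabet used for covariance counting.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# PSI-BLAST PSSM column order (the header order of the ASCII matrix).
PSSM_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

GAP_CHARS <- c("-")

is_residue <- function(x) x %in% amino_acids()

stop_usage <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "coevgraph_usage_error")
}

stop_format <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "coevgraph_format_error")
}

stop_empty <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "coevgraph_empty_input_error")
}

# Split aligned sequences into an N x L character matrix.
seq_char_matrix <- function(seqs) {
  if (length(seqs) == 0L) stop_empty("no sequences")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}
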