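# Small construction helpers shared across tests.

msa_of <- function(..., query_index = 1L) {
  new_msa(c(...), query_index = query_index)
}

# Weights object with hand-assigned weights (bypasses identity computation).
manual_weights <- function(w, ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(w))
  structure(list(w = stats::setNames(as.numeric(w), ids), threshold = 0.8,
                 identity = NULL),
            class = "seq_weights")
}

# pair_probs object built directly from probability tables.
manual_probs <- function(p_ij, p_i = rowSums(p_ij), p_j = colSums(p_ij),
                         n_eff = 1, alphabet = "2") {
  structure(list(p_i = p_i, p_j = p_j, p_ij = p_ij, N_eff = n_eff,
                 alphabet = alphabet, degenerate = FALSE),
            class = "pair_probs")
}

# cov_matrix wrapping an explicit symmetric score matrix.
manual_cov <- function(values, metric = "chi2", alphabet = "2",
                       query = NULL) {
  L <- nrow(values)
  if (is.null(query)) query <- paste(rep("A", L), collapse = "")
  coevgraph:::new_cov_matrix(values, metric, alphabet, post_processed = TRUE,
                             query = query, n_seq = 10L,
                             neff = matrix(10, L, L))
}

write_fasta_fixture <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

write_sites_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(vapply(rows, paste, "", collapse = "\t"), path)
  path
}

# A random ungapped MSA (uniform residues) as raw strings.
random_msa_strings <- function(n, l) {
  vapply(seq_len(n), function(i) {
    paste(sample(amino_acids(), l, replace = TRUE), collapse = "")
  }, "")
}
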