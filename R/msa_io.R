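# Alignment, PSSM, and binding-site annotation I/O.

#' Construct a multiple sequence alignment object
#'
#' An `msa` is an ordered set of equal-length aligned sequences over the 20
#' amino acids, the gap character `"-"` and the unknown character `"X"`. The
#' query (anchor) sequence is one of the rows, by convention the first.
#'
#' @param seqs Character vector of aligned sequences (equal lengths).
#' @param ids Sequence identifiers; defaults to `names(seqs)` or `seq1..seqN`.
#' @param query_index 1-based index of the query row (default 1).
#' @param col_map Optional integer vector mapping alignment columns to 1-based
#'   query positions (set by [trim_to_query()]).
#'
#' @return An object of class `msa` with fields `seqs`, `ids`, `query_index`,
#'   `N` (number of sequences) and `L` (alignment length).
#' @export
new_msa <- function(seqs, ids = NULL, query_index = 1L, col_map = NULL) {
  if (length(seqs) < 1L) stop_empty("alignment has no sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop_format("aligned sequences have unequal lengths (%s)",
                paste(unique(lens), collapse = ", "))
  }
  if (lens[1] < 1L) stop_empty("alignment has zero columns")
  if (is.null(ids)) ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (query_index < 1L || query_index > length(seqs)) {
    stop_usage("query_index %d out of range [1, %d]", query_index, length(seqs))
  }
  seqs <- unname(seqs)
  structure(
    list(seqs = seqs, ids = ids, query_index = as.integer(query_index),
         N = length(seqs), L = unname(lens[1]),
         col_map = col_map),
    class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns; query: %s (row %d)\n",
              x$N, x$L, x$ids[x$query_index], x$query_index))
  invisible(x)
}

#' Query sequence of an alignment
#' @param msa An [new_msa()] object.
#' @return The query row as a single string.
#' @export
query_sequence <- function(msa) msa$seqs[msa$query_index]

# Uppercase, '.' -> '-', non-standard residue letters -> 'X'.
normalize_alignment_strings <- function(seqs) {
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  allowed <- paste0(c(amino_acids(), "X", "-"), collapse = "")
  gsub(sprintf("[^%s]", allowed), "X", seqs)
}

#' Read a query-anchored aligned FASTA file
#'
#' The first record is taken as the query unless `query_index` says otherwise.
#' Residues are uppercased, `.` gaps become `-`, and non-standard letters
#' (B, Z, J, U, O, ...) become `X`.
#'
#' @param path Path to an aligned FASTA file.
#' @param query_index 1-based index of the query record (default 1).
#' @return An `msa` object.
#' @export
read_alignment <- function(path, query_index = 1L) {
  if (!file.exists(path)) stop_usage("file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop_empty("empty alignment file: %s", path)
  seqs <- normalize_alignment_strings(as.character(set))
  new_msa(seqs, ids = names(set), query_index = query_index)
}

#' Write an alignment as aligned FASTA
#' @param msa An `msa` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  set <- Biostrings::BStringSet(setNames(msa$seqs, msa$ids))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Trim an alignment to the query columns
#'
#' Removes every column where the query carries a gap, so that the remaining
#' columns correspond one-to-one to query residues (1-based positions). The
#' original alignment columns kept are recorded in `col_map`. Idempotent.
#'
#' @param msa An `msa` object.
#' @return A trimmed `msa`; `L` equals the ungapped query length.
#' @export
trim_to_query <- function(msa) {
  qchars <- strsplit(query_sequence(msa), "", fixed = TRUE)[[1]]
  keep <- !(qchars %in% GAP_CHARS)
  if (!any(keep)) stop_empty("query sequence is all gaps")
  if (all(keep)) {
    if (is.null(msa$col_map)) msa$col_map <- seq_len(msa$L)
    return(msa)
  }
  m <- seq_char_matrix(msa$seqs)[, keep, drop = FALSE]
  seqs <- apply(m, 1L, paste0, collapse = "")
  col_map <- if (is.null(msa$col_map)) which(keep) else msa$col_map[keep]
  new_msa(seqs, ids = msa$ids, query_index = msa$query_index, col_map = col_map)
}

## ---- PSSM ------------------------------------------------------------------

#' Construct a PSSM profile
#'
#' Position-specific log-odds substitution scores, one row per (trimmed)
#' query position, in the PSI-BLAST 20-column order.
#'
#' @param scores L x 20 numeric matrix of log-odds scores.
#' @param residues Character vector of query residues, one per row.
#' @param aa_order Column amino-acid order (default PSI-BLAST order).
#' @return A `pssm_profile` object.
#' @export
new_pssm <- function(scores, residues, aa_order = PSSM_AA_ORDER) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L) stop_format("PSSM must have 20 score columns")
  if (nrow(scores) != length(residues)) {
    stop_format("PSSM rows (%d) do not match residue count (%d)",
                nrow(scores), length(residues))
  }
  colnames(scores) <- aa_order
  structure(list(scores = scores, residues = residues, aa_order = aa_order),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> %d positions x 20 amino acids\n", nrow(x$scores)))
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the standard PSI-BLAST text matrix: a header line carrying the
#' 20-letter column order, then one row per query position whose first score
#' block holds the 20 log-odds integers. Any trailing blocks (weighted
#' percentages, information content) are ignored.
#'
#' @param path Path to the ASCII PSSM file.
#' @param query Optional ungapped query string; if supplied, row count and
#'   per-row residue letters are checked against it.
#' @return A `pssm_profile`.
#' @export
read_pssm <- function(path, query = NULL) {
  if (!file.exists(path)) stop_usage("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  aa_order <- NULL
  rows <- list()
  for (tk in toks) {
    if (length(tk) == 0L || tk[1] == "") next
    if (is.null(aa_order) && length(tk) >= 20L && all(nchar(tk) == 1L) &&
        all(tk[1:20] %in% c(amino_acids(), "B", "Z", "X", "*"))) {
      aa_order <- tk[1:20]
      next
    }
    if (grepl("^[0-9]+$", tk[1])) {
      if (length(tk) < 22L || !nchar(tk[2]) == 1L) {
        stop_format("unparsable PSSM row: '%s'", paste(tk, collapse = " "))
      }
      sc <- suppressWarnings(as.numeric(tk[3:22]))
      if (anyNA(sc)) {
        stop_format("unparsable PSSM scores in row %s", tk[1])
      }
      rows[[length(rows) + 1L]] <- list(pos = as.integer(tk[1]),
                                        res = tk[2], scores = sc)
    }
  }
  if (length(rows) == 0L) stop_empty("no PSSM rows parsed from %s", path)
  if (is.null(aa_order)) aa_order <- PSSM_AA_ORDER
  scores <- do.call(rbind, lapply(rows, `[[`, "scores"))
  residues <- vapply(rows, `[[`, "", "res")
  if (!is.null(query)) {
    qchars <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
    qchars <- qchars[!(qchars %in% GAP_CHARS)]
    if (length(qchars) != nrow(scores)) {
      rlang::abort(sprintf(
        "PSSM has %d rows but query has %d residues",
        nrow(scores), length(qchars)), class = "coevgraph_consistency_error")
    }
    if (!all(residues == qchars)) {
      rlang::abort("PSSM row residues do not match the query sequence",
                   class = "coevgraph_consistency_error")
    }
  }
  new_pssm(scores, residues, aa_order)
}

#' Write a PSSM in the PSI-BLAST ASCII layout
#'
#' @param pssm A `pssm_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts"),
    con)
  writeLines(paste0("           ", paste(sprintf("%3s", pssm$aa_order),
                                         collapse = " ")), con)
  for (i in seq_len(nrow(pssm$scores))) {
    writeLines(paste0(sprintf("%5d %s  ", i, pssm$residues[i]),
                      paste(sprintf("%3d", round(pssm$scores[i, ])),
                            collapse = " ")), con)
  }
  invisible(path)
}

# Score of amino acid `aa` at query position `pos`.
pssm_score <- function(pssm, pos, aa) {
  pssm$scores[pos, match(aa, pssm$aa_order)]
}

## ---- Binding-site annotations ---------------------------------------------

#' PDB ligand code to ligand category map
#'
#' The seven benchmark categories and their PDB ligand codes: DNA/RNA (NUC),
#' metal (CA, CU, FE, FE2, MG, MN, ZN), dinucleotide (NDP, NAD, NAP),
#' nucleoside (ADP, AMP, ATP, GDP), heme (HEC, HEM), sugar (BGC, FUC, GAL,
#' GLC, MAN, NAG), coenzyme A (COA).
#'
#' @return Named character vector mapping ligand code to category.
#' @export
ligand_categories <- function() {
  c(NUC = "DNA/RNA",
    CA = "metal", CU = "metal", FE = "metal", FE2 = "metal",
    MG = "metal", MN = "metal", ZN = "metal",
    NDP = "dinucleotide", NAD = "dinucleotide", NAP = "dinucleotide",
    ADP = "nucleoside", AMP = "nucleoside", ATP = "nucleoside",
    GDP = "nucleoside",
    HEC = "heme", HEM = "heme",
    BGC = "sugar", FUC = "sugar", GAL = "sugar", GLC = "sugar",
    MAN = "sugar", NAG = "sugar",
    COA = "coenzyme A")
}

#' Read ligand-binding-site annotations
#'
#' Tab-separated records `protein_id<TAB>ligand_code<TAB>position<TAB>residue`
#' with `#` comment lines. Ligand codes are collapsed to the seven categories
#' via [ligand_categories()]; records with unknown codes are skipped with a
#' warning; duplicate (protein, category, position) records are deduplicated.
#'
#' @param path Path to the TSV file.
#' @param categories Code-to-category map; replaceable for custom registries.
#' @return A tibble of class `site_annotation` with columns `protein_id`,
#'   `category`, `position`, `residue`; the number of skipped records is
#'   stored in attribute `skipped`.
#' @export
read_annotations <- function(path, categories = ligand_categories()) {
  if (!file.exists(path)) stop_usage("file not found: %s", path)
  df <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                        col_types = "ccic", progress = FALSE)
  if (nrow(df) == 0L) {
    ann <- tibble::tibble(protein_id = character(), category = character(),
                          position = integer(), residue = character())
    return(structure(ann, class = c("site_annotation", class(ann)),
                     skipped = 0L))
  }
  names(df) <- c("protein_id", "ligand_code", "position", "residue")
  if (any(is.na(df$position)) || any(df$position < 1L)) {
    stop_format("non-positive or unparsable position in %s", path)
  }
  annotation_from_records(df, categories)
}

# Collapse codes to categories, skip unknown, deduplicate.
annotation_from_records <- function(df, categories = ligand_categories()) {
  cat <- unname(categories[toupper(df$ligand_code)])
  unknown <- is.na(cat)
  if (any(unknown)) {
    warn(sprintf("skipped %d record(s) with unknown ligand code(s): %s",
                 sum(unknown),
                 paste(unique(df$ligand_code[unknown]), collapse = ", ")))
  }
  ann <- df |>
    dplyr::mutate(category = cat) |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::distinct(.data$protein_id, .data$category, .data$position,
                    .keep_all = TRUE) |>
    dplyr::select("protein_id", "category", "position", "residue") |>
    dplyr::arrange(.data$protein_id, .data$category, .data$position)
  structure(ann, class = c("site_annotation", class(ann)),
            skipped = sum(unknown))
}

#' Write annotations as the input TSV dialect
#'
#' Categories are written back as a representative PDB ligand code (the first
#' code of each category), so files round-trip through [read_annotations()].
#'
#' @param annotation A `site_annotation` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotation, path) {
  map <- ligand_categories()
  rep_code <- setNames(names(map)[!duplicated(map)], map[!duplicated(map)])
  out <- tibble::tibble(protein_id = annotation$protein_id,
                        ligand_code = unname(rep_code[annotation$category]),
                        position = annotation$position,
                        residue = annotation$residue)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Annotated positions for one protein and category
#' @param annotation A `site_annotation` tibble.
#' @param protein Protein id.
#' @param category Ligand category.
#' @return Sorted integer vector of 1-based positions.
#' @export
annotated_positions <- function(annotation, protein, category) {
  sort(annotation$position[annotation$protein_id == protein &
                             annotation$category == category])
}

## ---- Benchmark filtering ---------------------------------------------------

# Global percent identity between two unaligned sequences (Needleman-Wunsch,
# BLOSUM62), as a fraction of aligned columns.
unaligned_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Apply the benchmark-set filtering criteria
#'
#' Retains proteins that are at least `min_length` residues long, have at
#' least `min_homologs` homology hits, and share less than `max_identity`
#' pairwise sequence identity with every protein retained before them
#' (greedy, in input order).
#'
#' @param proteins Tibble with columns `id`, `sequence` (optional if `length`
#'   given), `length` (optional), `n_homologs`.
#' @param min_length Minimum sequence length (default 30).
#' @param min_homologs Minimum homology hits (default 100).
#' @param max_identity Redundancy threshold (default 0.25); candidates with
#'   identity `>= max_identity` to a retained protein are dropped.
#' @param identity Optional precomputed symmetric identity matrix (fractions)
#'   with rows/columns in input order; computed from `sequence` by global
#'   alignment when absent.
#' @return The retained rows of `proteins`, in input order.
#' @export
apply_benchmark_filters <- function(proteins, min_length = 30L,
                                    min_homologs = 100L, max_identity = 0.25,
                                    identity = NULL) {
  proteins <- tibble::as_tibble(proteins)
  if (is.null(proteins$length)) {
    proteins$length <- nchar(proteins$sequence)
  }
  eligible <- proteins$length >= min_length &
    proteins$n_homologs >= min_homologs
  kept <- integer(0)
  for (k in seq_len(nrow(proteins))) {
    if (!eligible[k]) next
    redundant <- FALSE
    for (r in kept) {
      idk <- if (!is.null(identity)) {
        identity[k, r]
      } else {
        unaligned_identity(proteins$sequence[k], proteins$sequence[r])
      }
      if (idk >= max_identity) { redundant <- TRUE; break }
    }
    if (!redundant) kept <- c(kept, k)
  }
  proteins[kept, , drop = FALSE]
}
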