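# Covariance-threshold protein graphs, conservation, cliques, cutoff sweeps.

#' Build a residue graph at a covariance cutoff
#'
#' Nodes are all residue positions (isolated nodes retained); edges connect
#' pairs with unmasked score at or above the cutoff and sequence separation
#' `|i - j| >= min_separation`.
#'
#' @param cov A `cov_matrix`.
#' @param cutoff Score cutoff.
#' @param min_separation Minimum sequence separation for an edge (default 1,
#'   i.e. only self-pairs are excluded).
#' @param entropy Optional per-position conservation scores (from
#'   [column_entropy()]) stored as a node attribute.
#' @return A `protein_graph`: the thresholded [igraph::graph] plus `cutoff`
#'   and `min_separation`.
#' @export
build_graph <- function(cov, cutoff, min_separation = 1L, entropy = NULL) {
  if (min_separation < 1L) stop_usage("min_separation must be >= 1")
  L <- cov$L
  vals <- cov$values
  idx <- which(upper.tri(vals), arr.ind = TRUE)
  sep_ok <- (idx[, 2] - idx[, 1]) >= min_separation
  sc <- vals[idx]
  keep <- sep_ok & !is.na(sc) & sc >= cutoff
  edges <- idx[keep, , drop = FALSE]
  g <- igraph::make_empty_graph(n = L, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(L))
  igraph::V(g)$position <- seq_len(L)
  igraph::V(g)$residue <- strsplit(cov$query, "", fixed = TRUE)[[1]]
  if (!is.null(entropy)) igraph::V(g)$entropy <- entropy
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges), score = sc[keep])
  }
  structure(list(graph = g, cutoff = cutoff,
                 min_separation = as.integer(min_separation),
                 metric = cov$metric),
            class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  cat(sprintf("<protein_graph> %d nodes, %d edges at cutoff %.3g (%s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$cutoff, x$metric))
  invisible(x)
}

#' Per-column conservation (Shannon entropy)
#'
#' Weighted amino-acid frequency distribution per column (gaps and `X`
#' excluded, frequencies renormalized over the non-gap weight), natural-log
#' Shannon entropy, normalized by `log(20)` to `[0, 1]`. With
#' `include_gaps = TRUE` the gap is a 21st symbol and the normalizer is
#' `log(21)`.
#'
#' @param msa A trimmed `msa`.
#' @param weights A `seq_weights` object; computed at the default threshold
#'   when absent.
#' @param include_gaps Count the gap as a symbol (default FALSE).
#' @return Numeric vector of length `L` in `[0, 1]` (`NA` for columns with no
#'   countable symbol).
#' @export
column_entropy <- function(msa, weights = NULL, include_gaps = FALSE) {
  if (is.null(weights)) weights <- compute_weights(msa)
  m <- seq_char_matrix(msa$seqs)
  w <- unname(weights$w)
  syms <- if (include_gaps) c(amino_acids(), "-") else amino_acids()
  vapply(seq_len(ncol(m)), function(i) {
    col <- m[, i]
    keep <- col %in% syms
    if (!any(keep)) return(NA_real_)
    f <- vapply(split(w[keep], factor(col[keep], levels = syms)), sum, 0)
    f <- f[f > 0] / sum(f)
    -sum(f * log(f)) / log(length(syms))
  }, 0)
}

#' Enumerate maximal cliques of a residue graph
#'
#' All maximal cliques of at least `min_size` nodes, in a canonical order:
#' members sorted ascending, cliques sorted by size (descending) then
#' lexicographically by member positions.
#'
#' @param graph A `protein_graph`.
#' @param min_size Minimum clique size reported (default 2; singletons are
#'   visible as isolated graph nodes instead).
#' @return A `clique_set`: list with `cliques` (list of sorted integer
#'   vectors), `sizes`, and the source `cutoff`.
#' @export
maximal_cliques <- function(graph, min_size = 2L) {
  raw <- igraph::max_cliques(graph$graph, min = min_size)
  cl <- lapply(raw, function(v) sort(as.integer(igraph::V(graph$graph)$position[v])))
  if (length(cl) > 0) {
    key <- vapply(cl, function(v) paste(sprintf("%06d", v), collapse = ","), "")
    ord <- order(-lengths(cl), key)
    cl <- cl[ord]
  }
  structure(list(cliques = cl, sizes = lengths(cl), cutoff = graph$cutoff),
            class = "clique_set")
}

#' @export
print.clique_set <- function(x, ...) {
  cat(sprintf("<clique_set> %d maximal clique(s) at cutoff %.3g%s\n",
              length(x$cliques), x$cutoff,
              if (length(x$cliques) > 0)
                sprintf("; sizes %d..%d", min(x$sizes), max(x$sizes)) else ""))
  invisible(x)
}

#' Sweep covariance cutoffs and summarize the resulting graphs
#'
#' For each cutoff of an ascending grid: number of non-isolated nodes, edge
#' count, maximal clique count, largest and median clique size, and the
#' clique-size histogram.
#'
#' @param cov A `cov_matrix`.
#' @param grid Ascending cutoffs (default `seq(0.1, 0.9, by = 0.1)`).
#' @param min_separation Passed to [build_graph()].
#' @param min_size Passed to [maximal_cliques()].
#' @return A tibble of class `cutoff_sweep` with columns `cutoff`, `nodes`,
#'   `edges`, `cliques`, `max_clique`, `median_clique` and list-column
#'   `clique_sizes`.
#' @export
cutoff_sweep <- function(cov, grid = seq(0.1, 0.9, by = 0.1),
                         min_separation = 1L, min_size = 2L) {
  if (is.unsorted(grid, strictly = TRUE)) {
    stop_usage("cutoff grid must be sorted ascending")
  }
  rows <- purrr::map(grid, function(cval) {
    g <- build_graph(cov, cval, min_separation)
    cl <- maximal_cliques(g, min_size)
    deg <- igraph::degree(g$graph)
    tibble::tibble(
      cutoff = cval,
      nodes = sum(deg > 0),
      edges = igraph::ecount(g$graph),
      cliques = length(cl$cliques),
      max_clique = if (length(cl$sizes) > 0) max(cl$sizes) else 0L,
      median_clique = if (length(cl$sizes) > 0) stats::median(cl$sizes) else
        NA_real_,
      clique_sizes = list(cl$sizes))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cutoff_sweep", class(out))
  out
}

## ---- exports ---------------------------------------------------------------

#' Export a residue graph
#'
#' @param graph A `protein_graph`.
#' @param path Output path.
#' @param format `"graphml"` or `"edgelist"` (3-column TSV: i, j, score).
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph$graph, path, format = "graphml")
  } else {
    readr::write_tsv(tidy(graph), path)
  }
  invisible(path)
}

#' Export cliques, one per line, comma-separated positions
#' @param cliques A `clique_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cliques <- function(cliques, path) {
  writeLines(vapply(cliques$cliques, paste, "", collapse = ","), path)
  invisible(path)
}

#' Export a covariance matrix as TSV with a metadata sidecar
#'
#' Square TSV with 1-based positions as header row and first column, `NA`
#' for masked entries; a `key=value` sidecar (`<path>.meta`) records metric,
#' alphabet, N, the N_eff median and, if applicable, the glasso penalty.
#'
#' @param cov A `cov_matrix`.
#' @param path Output path.
#' @param meta Sidecar path (default `<path>.meta`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(cov, path, meta = paste0(path, ".meta")) {
  df <- as.data.frame(cov$values)
  names(df) <- as.character(seq_len(cov$L))
  df <- cbind(pos = seq_len(cov$L), df)
  readr::write_tsv(tibble::as_tibble(df), path)
  writeLines(c(
    sprintf("metric=%s", cov$metric),
    sprintf("alphabet=%s", cov$alphabet),
    sprintf("post_processed=%s", cov$post_processed),
    sprintf("provenance=%s", cov$provenance),
    sprintf("query=%s", cov$query),
    sprintf("n_seq=%d", cov$n_seq),
    sprintf("neff_median=%.6g", cov$neff_median),
    sprintf("rho=%s", ifelse(is.na(cov$rho), "NA", sprintf("%.4f", cov$rho)))),
    meta)
  invisible(path)
}

#' Read a covariance matrix written by [write_matrix()]
#' @param path Matrix TSV path.
#' @param meta Sidecar path (default `<path>.meta`).
#' @return A `cov_matrix`.
#' @export
read_matrix <- function(path, meta = paste0(path, ".meta")) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  dimnames(vals) <- list(df$pos, names(df)[-1])
  md <- list(metric = "chi2", alphabet = "2", post_processed = TRUE,
             query = paste(rep("X", nrow(vals)), collapse = ""),
             n_seq = NA_integer_, neff_median = NA_real_, rho = NA_real_)
  if (file.exists(meta)) {
    kv <- strsplit(readLines(meta, warn = FALSE), "=", fixed = TRUE)
    for (p_ in kv) md[[p_[1]]] <- paste(p_[-1], collapse = "=")
  }
  out <- new_cov_matrix(vals, md$metric, md$alphabet,
                        post_processed = isTRUE(as.logical(md$post_processed)),
                        query = md$query,
                        n_seq = suppressWarnings(as.integer(md$n_seq)),
                        neff = matrix(suppressWarnings(as.numeric(md$neff_median)),
                                      nrow(vals), ncol(vals)),
                        rho = suppressWarnings(as.numeric(md$rho)),
                        provenance = md$provenance %||% md$metric)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
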