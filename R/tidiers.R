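# broom-style tidiers and ggplot2 methods for the package's result types.

#' Tidy a covariance matrix into per-pair records
#'
#' @param x A `cov_matrix`.
#' @param diagonal Include the diagonal (default FALSE).
#' @param drop_na Drop masked pairs (default FALSE).
#' @param ... Unused.
#' @return Tibble with columns `i`, `j` (1-based, `i < j` unless `diagonal`)
#'   and `score`.
#' @export
tidy.cov_matrix <- function(x, diagonal = FALSE, drop_na = FALSE, ...) {
  idx <- which(upper.tri(x$values, diag = diagonal), arr.ind = TRUE)
  out <- tibble::tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                        score = x$values[idx])
  if (drop_na) out <- dplyr::filter(out, !is.na(.data$score))
  dplyr::arrange(out, .data$i, .data$j)
}

#' One-row summary of a covariance matrix
#' @param x A `cov_matrix`.
#' @param ... Unused.
#' @return Tibble with metric, alphabet, dimensions and masking/penalty info.
#' @export
glance.cov_matrix <- function(x, ...) {
  tibble::tibble(metric = x$metric, alphabet = x$alphabet,
                 post_processed = x$post_processed, L = x$L, n_seq = x$n_seq,
                 neff_median = x$neff_median,
                 n_masked = sum(x$mask[upper.tri(x$mask)]),
                 rho = x$rho, provenance = x$provenance)
}

#' Heatmap of a covariance matrix
#' @param object A `cov_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cov_matrix <- function(object, ...) {
  df <- tidy(object, diagonal = TRUE)
  df2 <- dplyr::bind_rows(df, dplyr::rename(df, i = "j", j = "i"))
  ggplot2::ggplot(df2, ggplot2::aes(.data$i, .data$j, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "position", y = "position",
                  fill = object$provenance,
                  title = sprintf("%s covariance (%s-letter)", object$metric,
                                  object$alphabet)) +
    ggplot2::theme_minimal()
}

#' Tidy a glasso fit
#' @param x A `glasso_fit`.
#' @param ... Unused.
#' @return Tibble with columns `i`, `j`, `s` (input), `sigma` (estimated
#'   covariance) and `theta` (precision).
#' @export
tidy.glasso_fit <- function(x, ...) {
  idx <- which(upper.tri(x$S, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                 s = x$S[idx], sigma = x$sigma[idx], theta = x$theta[idx])
}

#' One-row summary of a glasso fit
#' @param x A `glasso_fit`.
#' @param ... Unused.
#' @return Tibble with `rho`, convergence info and precision sparsity.
#' @export
glance.glasso_fit <- function(x, ...) {
  off <- x$theta[upper.tri(x$theta)]
  tibble::tibble(p = nrow(x$S), rho = x$rho, converged = x$converged,
                 iterations = x$iterations,
                 sparsity = if (length(off) > 0) mean(off == 0) else
                   NA_real_)
}

#' Tidy a protein graph into its edge list
#' @param x A `protein_graph`.
#' @param ... Unused.
#' @return Tibble with columns `i`, `j`, `score`.
#' @export
tidy.protein_graph <- function(x, ...) {
  e <- igraph::as_edgelist(x$graph, names = FALSE)
  tibble::tibble(i = as.integer(pmin(e[, 1], e[, 2])),
                 j = as.integer(pmax(e[, 1], e[, 2])),
                 score = igraph::E(x$graph)$score %||%
                   rep(NA_real_, nrow(e))) |>
    dplyr::arrange(.data$i, .data$j)
}

#' One-row summary of a protein graph
#' @param x A `protein_graph`.
#' @param ... Unused.
#' @return Tibble with cutoff, node/edge counts and non-isolated node count.
#' @export
glance.protein_graph <- function(x, ...) {
  deg <- igraph::degree(x$graph)
  tibble::tibble(cutoff = x$cutoff, nodes = igraph::vcount(x$graph),
                 connected_nodes = sum(deg > 0),
                 edges = igraph::ecount(x$graph),
                 min_separation = x$min_separation)
}

#' Plot a protein graph
#'
#' Fruchterman-Reingold layout; nodes colored by conservation entropy when
#' available, isolated nodes omitted for readability.
#'
#' @param object A `protein_graph`.
#' @param drop_isolated Hide isolated nodes (default TRUE).
#' @param seed Layout seed (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protein_graph <- function(object, drop_isolated = TRUE, seed = 1L,
                                   ...) {
  g <- object$graph
  if (drop_isolated) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(
    x = xy[, 1], y = xy[, 2],
    label = paste0(igraph::V(g)$residue, igraph::V(g)$position),
    entropy = igraph::V(g)$entropy %||% rep(NA_real_, igraph::vcount(g)))
  e <- igraph::as_edgelist(g, names = FALSE)
  edges <- tibble::tibble(x = xy[e[, 1], 1], y = xy[e[, 1], 2],
                          xend = xy[e[, 2], 1], yend = xy[e[, 2], 2])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          color = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y, color = .data$entropy),
                        size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$label),
                       vjust = -1, size = 2.5) +
    ggplot2::scale_color_viridis_c(na.value = "steelblue") +
    ggplot2::labs(title = sprintf("residue graph, cutoff %.2g", object$cutoff),
                  color = "entropy") +
    ggplot2::theme_void()
}

#' Tidy a clique set
#' @param x A `clique_set`.
#' @param ... Unused.
#' @return Tibble with columns `clique` (index), `size`, `position` (long
#'   form, one row per clique member).
#' @export
tidy.clique_set <- function(x, ...) {
  if (length(x$cliques) == 0L) {
    return(tibble::tibble(clique = integer(), size = integer(),
                          position = integer()))
  }
  tibble::tibble(clique = rep(seq_along(x$cliques), x$sizes),
                 size = rep(x$sizes, x$sizes),
                 position = unlist(x$cliques))
}

#' Plot node/edge/clique distributions across cutoffs
#' @param object A `cutoff_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object (facets: nodes, edges, cliques, max clique size).
#' @export
autoplot.cutoff_sweep <- function(object, ...) {
  long <- object |>
    dplyr::select("cutoff", "nodes", "edges", "cliques", "max_clique") |>
    tidyr::pivot_longer(-"cutoff", names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(.data$cutoff, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "covariance cutoff", y = NULL) +
    ggplot2::theme_minimal()
}

#' Density plot of pooled LO values
#' @param lo_values Numeric vector (or tibble from [lo_pool()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_lo_density <- function(lo_values, ...) {
  if (is.data.frame(lo_values)) lo_values <- lo_values$lo
  df <- tibble::tibble(lo = lo_values[is.finite(lo_values)])
  ggplot2::ggplot(df, ggplot2::aes(.data$lo)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::labs(x = "LO", y = "density") +
    ggplot2::theme_minimal()
}

#' Export a cutoff sweep as TSV
#' @param sweep A `cutoff_sweep` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  readr::write_tsv(dplyr::select(tibble::as_tibble(sweep), -"clique_sizes"),
                   path)
  invisible(path)
}
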