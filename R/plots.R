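#' Plot a PCoA ordination
#'
#' Scatter of two principal coordinates, optionally colored by a metadata
#' grouping (tissue, plant, ...), with the variance explained by each axis
#' in the labels.
#'
#' @param object A `pcoa_ordination`.
#' @param metadata Optional `sample_metadata` to color by.
#' @param axes Length-2 integer vector of axes to draw (default 1:2).
#' @param color Metadata column used for color (default `"tissue"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pcoa_ordination <- function(object, metadata = NULL, axes = c(1, 2),
                                     color = "tissue", ...) {
  df <- tidy(object)
  ax <- paste0("axis", axes)
  if (!all(ax %in% names(df))) {
    stop("ordination has fewer than ", max(axes), " axes", call. = FALSE)
  }
  pct <- 100 * object$proportion_explained[axes]
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, metadata, by = "sample_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]]))
  p <- if (!is.null(metadata) && color %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data[[color]]), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::labs(
      x = sprintf("PCo%d (%.1f%%)", axes[1], pct[1]),
      y = sprintf("PCo%d (%.1f%%)", axes[2], pct[2])) +
    ggplot2::theme_minimal()
}

#' Plot the node-versus-sample frequency distribution
#'
#' Histogram of how many samples each consensus MS/MS node was observed
#' in — ubiquitous chemistry (the internal standard) sits at the right
#' edge, tissue-specific compounds at the left.
#'
#' @param nodes List of `consensus_spectrum` or a `molecular_network`.
#' @return A ggplot object.
#' @export
plot_node_frequency <- function(nodes) {
  df <- node_sample_frequency(nodes)
  ggplot2::ggplot(df, ggplot2::aes(.data$n_samples)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "samples in which the MS/MS spectrum is observed",
                  y = "consensus nodes") +
    ggplot2::theme_minimal()
}

#' Plot a molecular network
#'
#' Simple force-directed layout of the pruned network with nodes sized by
#' member count; intended as a quick QC view (interactive exploration
#' belongs in Cytoscape via [write_network_graphml()]).
#'
#' @param object A `molecular_network`.
#' @param metadata Optional `sample_metadata`; nodes are colored by the
#'   tissue contributing most member scans.
#' @param seed Layout seed (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.molecular_network <- function(object, metadata = NULL, seed = 1L,
                                       ...) {
  ids <- vapply(object$nodes, function(n) n$node_id, character(1))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  if (nrow(object$edges)) {
    g <- igraph::add_edges(g, rbind(match(object$edges$node_a, ids),
                                    match(object$edges$node_b, ids)))
  }
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nd <- tibble::tibble(
    node_id = ids, x = xy[, 1], y = xy[, 2],
    n_members = vapply(object$nodes, function(n) n$n_members, integer(1)))
  if (!is.null(metadata)) {
    lut <- stats::setNames(metadata$tissue, metadata$sample_id)
    nd$tissue <- vapply(object$nodes, function(n) {
      names(which.max(table(lut[n$members$sample_id])))
    }, character(1))
  }
  ed <- object$edges
  p <- ggplot2::ggplot(nd, ggplot2::aes(.data$x, .data$y))
  if (nrow(ed)) {
    seg <- tibble::tibble(
      x = nd$x[match(ed$node_a, nd$node_id)],
      y = nd$y[match(ed$node_a, nd$node_id)],
      xend = nd$x[match(ed$node_b, nd$node_id)],
      yend = nd$y[match(ed$node_b, nd$node_id)])
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      color = "grey70", linewidth = 0.3)
  }
  p <- if (!is.null(metadata)) {
    p + ggplot2::geom_point(ggplot2::aes(size = .data$n_members,
                                         color = .data$tissue))
  } else {
    p + ggplot2::geom_point(ggplot2::aes(size = .data$n_members))
  }
  p + ggplot2::scale_size_area(max_size = 5) +
    ggplot2::theme_void()
}

#' Tidy a molecular network into a node tibble
#' @param x A `molecular_network`.
#' @param ... Unused.
#' @return A tibble: `node_id`, `precursor_mz`, `n_members`, `n_samples`,
#'   `component`, `library_hit`.
#' @exportS3Method generics::tidy
tidy.molecular_network <- function(x, ...) {
  nf <- node_sample_frequency(x)
  comp <- network_components(x)
  out <- dplyr::left_join(nf, comp, by = "node_id")
  out$n_members <- vapply(x$nodes, function(n) n$n_members, integer(1))
  hit <- rep(NA_character_, nrow(out))
  if (!is.null(x$annotations) && nrow(x$annotations)) {
    m <- match(out$node_id, x$annotations$node_id)
    hit[!is.na(m)] <- x$annotations$compound_name[m[!is.na(m)]]
  }
  out$library_hit <- hit
  out
}

#' One-line summary of a molecular network
#' @param x A `molecular_network`.
#' @param ... Unused.
#' @return A one-row tibble: `n_nodes`, `n_edges`, `n_components`,
#'   `n_annotated`, `annotation_rate_pct`.
#' @exportS3Method generics::glance
glance.molecular_network <- function(x, ...) {
  comp <- network_components(x)
  n_ann <- if (is.null(x$annotations)) 0L else nrow(x$annotations)
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    n_components = if (nrow(comp)) length(unique(comp$component)) else 0L,
    n_annotated = n_ann,
    annotation_rate_pct = if (length(x$nodes)) {
      100 * n_ann / length(x$nodes)
    } else 0)
}
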