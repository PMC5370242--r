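#' Export a molecular network as GraphML
#'
#' Writes the pruned network for interactive exploration in Cytoscape or any
#' GraphML-aware graph tool. Node attributes: `precursor_mz`, `n_members`,
#' `n_samples`, per-group member counts (`group_<name>`), and `library_hit`
#' (empty string when unannotated). Edge attributes: `cosine`, `n_matched`,
#' `delta_mz` (precursor mass difference).
#'
#' @param network A `molecular_network`.
#' @param path Output path.
#' @param metadata Optional `sample_metadata`; when given, per-tissue member
#'   counts are attached to each node.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path, metadata = NULL) {
  nodes <- network$nodes
  ids <- vapply(nodes, function(n) n$node_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate node ids in network", call. = FALSE)
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  if (length(nodes)) {
    igraph::V(g)$name <- ids
    igraph::V(g)$precursor_mz <- vapply(nodes, function(n) n$precursor_mz,
                                        numeric(1))
    igraph::V(g)$n_members <- vapply(nodes, function(n) n$n_members, integer(1))
    igraph::V(g)$n_samples <- vapply(nodes, function(n) {
      length(unique(n$members$sample_id))
    }, integer(1))
    ann <- network$annotations
    hit <- rep("", length(nodes))
    if (!is.null(ann) && nrow(ann)) {
      m <- match(ids, ann$node_id)
      hit[!is.na(m)] <- ann$compound_name[m[!is.na(m)]]
    }
    igraph::V(g)$library_hit <- hit
    if (!is.null(metadata)) {
      lut <- stats::setNames(metadata$tissue, metadata$sample_id)
      for (grp in sort(unique(metadata$tissue[!metadata$is_blank]))) {
        cnt <- vapply(nodes, function(n) {
          sum(lut[unique(n$members$sample_id)] == grp, na.rm = TRUE)
        }, numeric(1))
        g <- igraph::set_vertex_attr(g, paste0("group_", grp), value = cnt)
      }
    }
  }
  ed <- network$edges
  if (!is.null(ed) && nrow(ed)) {
    g <- igraph::add_edges(g, rbind(match(ed$node_a, ids),
                                    match(ed$node_b, ids)))
    igraph::E(g)$cosine <- ed$cosine
    igraph::E(g)$n_matched <- ed$n_matched
    igraph::E(g)$delta_mz <- ed$delta_mz
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
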