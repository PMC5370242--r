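#' Cluster MS/MS spectra into consensus nodes
#'
#' Greedy single-pass clustering with a fixed sort order, so the result is a
#' pure function of the input multiset: spectra are sorted by precursor m/z,
#' then sample id, then scan id, and each joins the first existing cluster
#' whose consensus precursor lies within `prec_tol_da` and whose consensus
#' spectrum scores at least `cluster_cosine` (unshifted cosine at
#' `frag_tol_da`); otherwise it seeds a new cluster. Consensus peaks are the
#' intensity-weighted mean m/z and summed intensity of member peaks merged
#' at `frag_tol_da`; the consensus precursor is the TIC-weighted mean of
#' member precursors. Clusters with fewer than `min_members` spectra are
#' discarded, and each surviving consensus is re-filtered with the
#' top-6-per-50-Da rule so downstream scoring sees the same peak density as
#' its inputs.
#'
#' @param spectra List of filtered MS2 `ms_spectrum` objects.
#' @param prec_tol_da Precursor tolerance in Da (default 0.02).
#' @param frag_tol_da Fragment tolerance in Da (default 0.02).
#' @param cluster_cosine Minimum unshifted cosine to join (default 0.7).
#' @param min_members Minimum cluster size kept (default 2; singletons are
#'   discarded).
#' @param top_n,window_da Consensus re-filter parameters (default 6 / 50).
#' @return A list of `consensus_spectrum` objects.
#' @export
cluster_spectra <- function(spectra, prec_tol_da = 0.02, frag_tol_da = 0.02,
                            cluster_cosine = 0.7, min_members = 2L,
                            top_n = 6, window_da = 50) {
  if (!length(spectra)) return(list())
  prec <- vapply(spectra, function(s) s$precursor_mz, numeric(1))
  sid <- vapply(spectra, function(s) s$sample_id, character(1))
  scid <- vapply(spectra, function(s) s$scan_id, character(1))
  ord <- order(prec, sid, scid)
  spectra <- spectra[ord]
  prec <- prec[ord]

  clusters <- list()   # each: consensus ms_spectrum, members tibble rows, tic
  cl_prec <- numeric(0)
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    joined <- FALSE
    if (length(clusters)) {
      cand <- which(abs(cl_prec - prec[i]) <= prec_tol_da)
      for (ci in cand) {   # first qualifying cluster wins
        sc <- cosine_score(clusters[[ci]]$consensus, s,
                           frag_tol_da = frag_tol_da, shifted = FALSE)
        if (sc$cosine >= cluster_cosine) {
          clusters[[ci]] <- merge_into_cluster(clusters[[ci]], s, frag_tol_da)
          cl_prec[ci] <- clusters[[ci]]$consensus$precursor_mz
          joined <- TRUE
          break
        }
      }
    }
    if (!joined) {
      clusters[[length(clusters) + 1L]] <- list(
        consensus = s,
        members = list(list(sample_id = s$sample_id, scan_id = s$scan_id)),
        tic = sum(s$peaks[, "intensity"])
      )
      cl_prec <- c(cl_prec, prec[i])
    }
  }
  clusters <- Filter(function(cl) length(cl$members) >= min_members, clusters)
  out <- vector("list", length(clusters))
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    cons <- filter_window_top_n(cl$consensus, top_n = top_n,
                                window_da = window_da)
    members <- tibble::tibble(
      sample_id = vapply(cl$members, `[[`, character(1), "sample_id"),
      scan_id = vapply(cl$members, `[[`, character(1), "scan_id")
    )
    out[[k]] <- structure(
      list(node_id = sprintf("N%04d", k),
           precursor_mz = cons$precursor_mz,
           peaks = cons$peaks,
           members = members,
           n_members = nrow(members)),
      class = "consensus_spectrum")
  }
  out
}

# Merge spectrum s into cluster cl: match s's peaks to consensus peaks at
# frag_tol (nearest first), average m/z by intensity, sum intensities;
# unmatched peaks append. Precursor becomes the TIC-weighted member mean.
merge_into_cluster <- function(cl, s, frag_tol_da) {
  cons <- cl$consensus
  cpk <- cons$peaks
  spk <- s$peaks
  used <- rep(FALSE, nrow(cpk))
  new_rows <- list()
  for (j in seq_len(nrow(spk))) {
    d <- abs(cpk[, "mz"] - spk[j, "mz"])
    d[used] <- Inf
    if (nrow(cpk) && min(d) <= frag_tol_da) {
      t <- which.min(d)
      wsum <- cpk[t, "intensity"] + spk[j, "intensity"]
      cpk[t, "mz"] <- (cpk[t, "mz"] * cpk[t, "intensity"] +
                         spk[j, "mz"] * spk[j, "intensity"]) / wsum
      cpk[t, "intensity"] <- wsum
      used[t] <- TRUE
    } else {
      new_rows[[length(new_rows) + 1L]] <- spk[j, ]
    }
  }
  if (length(new_rows)) cpk <- rbind(cpk, do.call(rbind, new_rows))
  cpk <- cpk[order(cpk[, "mz"]), , drop = FALSE]
  stic <- sum(s$peaks[, "intensity"])
  new_prec <- (cons$precursor_mz * cl$tic + s$precursor_mz * stic) /
    (cl$tic + stic)
  cons$peaks <- cpk
  cons$precursor_mz <- new_prec
  cl$consensus <- cons
  cl$members[[length(cl$members) + 1L]] <- list(sample_id = s$sample_id,
                                                scan_id = s$scan_id)
  cl$tic <- cl$tic + stic
  cl
}

#' @export
print.consensus_spectrum <- function(x, ...) {
  cat(sprintf("<consensus_spectrum> %s  precursor %.4f  %d members (%d samples)  %d peaks\n",
              x$node_id, x$precursor_mz, x$n_members,
              length(unique(x$members$sample_id)), nrow(x$peaks)))
  invisible(x)
}

# Consensus node as a plain ms_spectrum (for scoring / MGF export).
node_spectrum <- function(node) {
  new_spectrum(scan_id = node$node_id, ms_level = 2L, rt_seconds = 0,
               peaks = node$peaks, precursor_mz = node$precursor_mz,
               sample_id = "consensus")
}

#' Build a molecular network from consensus nodes
#'
#' Scores every node pair with the shifted (modified) cosine; an edge is
#' created iff cosine >= `edge_cosine` and the matched-peak count >=
#' `min_matched`. The edge set is then pruned to mutual top-K: an edge
#' survives iff it ranks within the `top_k` highest-cosine edges of both of
#' its endpoints (ties broken toward the lower partner node id).
#'
#' @param nodes List of `consensus_spectrum` objects.
#' @param edge_cosine Minimum cosine (default 0.7).
#' @param min_matched Minimum matched peaks, inclusive (default 4, the
#'   parameter convention of the networking tools this mirrors; pass 5 for
#'   the strict "more than 4" reading).
#' @param frag_tol_da Fragment tolerance in Da (default 0.02).
#' @param top_k Edges retained per node (default 10).
#' @return A `molecular_network`: `nodes`, `edges` tibble
#'   (`node_a, node_b, cosine, n_matched, delta_mz`), empty `annotations`.
#' @export
build_network <- function(nodes, edge_cosine = 0.7, min_matched = 4L,
                          frag_tol_da = 0.02, top_k = 10L) {
  ids <- vapply(nodes, function(n) n$node_id, character(1))
  n <- length(nodes)
  ea <- character(0); eb <- character(0)
  ec <- numeric(0); em <- integer(0); ed <- numeric(0)
  if (n >= 2L) {
    specs <- lapply(nodes, node_spectrum)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        sc <- cosine_score(specs[[i]], specs[[j]], frag_tol_da = frag_tol_da,
                           shifted = TRUE)
        if (sc$cosine >= edge_cosine && sc$n_matched >= min_matched) {
          ea <- c(ea, ids[i]); eb <- c(eb, ids[j])
          ec <- c(ec, sc$cosine); em <- c(em, sc$n_matched)
          ed <- c(ed, nodes[[i]]$precursor_mz - nodes[[j]]$precursor_mz)
        }
      }
    }
  }
  edges <- tibble::tibble(node_a = ea, node_b = eb, cosine = ec,
                          n_matched = em, delta_mz = ed)
  edges <- prune_top_k(edges, top_k)
  structure(list(nodes = nodes, edges = edges,
                 annotations = empty_annotations()),
            class = "molecular_network")
}

# Mutual top-K pruning: an edge survives iff for both endpoints it is among
# that endpoint's top_k edges by descending cosine (ties -> lower partner id).
prune_top_k <- function(edges, top_k) {
  if (!nrow(edges)) return(edges)
  long <- dplyr::bind_rows(
    tibble::tibble(node = edges$node_a, partner = edges$node_b,
                   cosine = edges$cosine, edge = seq_len(nrow(edges))),
    tibble::tibble(node = edges$node_b, partner = edges$node_a,
                   cosine = edges$cosine, edge = seq_len(nrow(edges)))
  )
  long <- long[order(long$node, -long$cosine, long$partner), ]
  long$rank <- stats::ave(seq_len(nrow(long)), long$node,
                          FUN = seq_along)
  ok_per_endpoint <- tapply(long$rank <= top_k, long$edge, all)
  keep <- as.logical(ok_per_endpoint[as.character(seq_len(nrow(edges)))])
  edges[keep, ]
}

#' @export
print.molecular_network <- function(x, ...) {
  cat(sprintf("<molecular_network> %d nodes, %d edges, %d library hits\n",
              length(x$nodes), nrow(x$edges),
              if (is.null(x$annotations)) 0L else nrow(x$annotations)))
  invisible(x)
}

empty_annotations <- function() {
  tibble::tibble(node_id = character(0), library_id = character(0),
                 compound_name = character(0), cosine = numeric(0),
                 n_matched = integer(0), precursor_ppm_error = numeric(0))
}

#' Remove blank-derived nodes from a network
#'
#' Solvent and system blanks carry instrument and carry-over background;
#' every node with at least one member scan from a blank sample is removed
#' (`mode = "any"`, the conservative rule), along with its incident edges.
#' `mode = "exclusive"` removes only nodes whose members all come from
#' blanks.
#'
#' @param network A `molecular_network`.
#' @param metadata A `sample_metadata` covering all member sample ids.
#' @param mode `"any"` (default) or `"exclusive"`.
#' @return The filtered `molecular_network`.
#' @export
subtract_blanks <- function(network, metadata, mode = c("any", "exclusive")) {
  mode <- match.arg(mode)
  blank_ids <- metadata$sample_id[metadata$is_blank]
  known <- metadata$sample_id
  keep <- vapply(network$nodes, function(nd) {
    ms <- unique(nd$members$sample_id)
    missing <- setdiff(ms, known)
    if (length(missing)) {
      stop("node ", nd$node_id, " has member sample(s) absent from metadata: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    n_blank <- sum(ms %in% blank_ids)
    if (mode == "any") n_blank == 0L else n_blank < length(ms)
  }, logical(1))
  kept_ids <- vapply(network$nodes[keep], function(n) n$node_id, character(1))
  network$nodes <- network$nodes[keep]
  ed <- network$edges
  network$edges <- ed[ed$node_a %in% kept_ids & ed$node_b %in% kept_ids, ]
  if (!is.null(network$annotations) && nrow(network$annotations)) {
    network$annotations <-
      network$annotations[network$annotations$node_id %in% kept_ids, ]
  }
  network
}

#' Match consensus nodes against a spectral reference library
#'
#' For each node, candidate records are library spectra whose precursor lies
#' within `prec_tol_da`; a candidate is a hit when the unshifted cosine at
#' `frag_tol_da` reaches `match_cosine` with at least `min_matched` matched
#' peaks and the precursor mass error is within `ppm_cap`. The best-cosine
#' hit per node is reported.
#'
#' @param nodes List of `consensus_spectrum` (or a `molecular_network`).
#' @param library List of annotated `ms_spectrum` from
#'   [read_spectral_library()].
#' @param prec_tol_da Precursor tolerance in Da (default 0.02).
#' @param frag_tol_da Fragment tolerance in Da (default 0.02).
#' @param match_cosine Minimum cosine (default 0.7).
#' @param min_matched Minimum matched peaks (default 4).
#' @param ppm_cap Maximum |precursor ppm error| (default 20).
#' @return A tibble of hits: `node_id, library_id, compound_name, cosine,
#'   n_matched, precursor_ppm_error`. Unmatched nodes are absent.
#' @export
library_search <- function(nodes, library, prec_tol_da = 0.02,
                           frag_tol_da = 0.02, match_cosine = 0.7,
                           min_matched = 4L, ppm_cap = 20) {
  if (inherits(nodes, "molecular_network")) nodes <- nodes$nodes
  if (!length(library)) stop("spectral library is empty", call. = FALSE)
  lib_prec <- vapply(library, function(s) s$precursor_mz, numeric(1))
  hits <- empty_annotations()
  for (nd in nodes) {
    cand <- which(abs(lib_prec - nd$precursor_mz) <= prec_tol_da)
    best <- NULL
    ns <- node_spectrum(nd)
    for (ci in cand) {
      rec <- library[[ci]]
      ppm <- 1e6 * (nd$precursor_mz - rec$precursor_mz) / rec$precursor_mz
      if (abs(ppm) > ppm_cap) next
      sc <- cosine_score(ns, rec, frag_tol_da = frag_tol_da, shifted = FALSE)
      if (sc$cosine < match_cosine || sc$n_matched < min_matched) next
      if (is.null(best) || sc$cosine > best$cosine) {
        best <- tibble::tibble(node_id = nd$node_id,
                               library_id = rec$annotation$library_id,
                               compound_name = rec$annotation$compound_name,
                               cosine = sc$cosine,
                               n_matched = as.integer(sc$n_matched),
                               precursor_ppm_error = ppm)
      }
    }
    if (!is.null(best)) hits <- dplyr::bind_rows(hits, best)
  }
  hits
}

#' Per-node sample frequency
#'
#' How many distinct samples contributed an MS/MS scan to each node — the
#' quantity behind the node-versus-sample frequency plot (the internal
#' standard sits at the total sample count; rare compounds at 1).
#'
#' @param nodes List of `consensus_spectrum` (or a `molecular_network`).
#' @return A tibble: `node_id`, `precursor_mz`, `n_samples`.
#' @export
node_sample_frequency <- function(nodes) {
  if (inherits(nodes, "molecular_network")) nodes <- nodes$nodes
  tibble::tibble(
    node_id = vapply(nodes, function(n) n$node_id, character(1)),
    precursor_mz = vapply(nodes, function(n) n$precursor_mz, numeric(1)),
    n_samples = vapply(nodes, function(n) {
      length(unique(n$members$sample_id))
    }, integer(1))
  )
}

#' Tissue-overlap (Venn) counts of MS/MS nodes
#'
#' For each node, the set of tissue groups among its member samples defines
#' one region of the k-set Venn partition; counts over all nodes sum to the
#' node count. Blank samples are excluded from grouping.
#'
#' @param nodes List of `consensus_spectrum` (or a `molecular_network`).
#' @param metadata A `sample_metadata`.
#' @param grouping Metadata column to group by (default `"tissue"`).
#' @return A tibble: `region` (`+`-joined sorted group names), `n_groups`,
#'   `count`.
#' @export
msms_tissue_overlap <- function(nodes, metadata, grouping = "tissue") {
  if (inherits(nodes, "molecular_network")) nodes <- nodes$nodes
  lut <- stats::setNames(as.character(metadata[[grouping]]),
                         metadata$sample_id)
  blank <- stats::setNames(metadata$is_blank, metadata$sample_id)
  regions <- vapply(nodes, function(nd) {
    ms <- unique(nd$members$sample_id)
    ms <- ms[!blank[ms]]
    grp <- sort(unique(lut[ms]))
    paste(grp, collapse = "+")
  }, character(1))
  regions <- regions[nzchar(regions)]
  tab <- table(regions)
  tibble::tibble(
    region = names(tab),
    n_groups = lengths(strsplit(names(tab), "+", fixed = TRUE)),
    count = as.integer(tab)
  ) |> dplyr::arrange(dplyr::desc(.data$n_groups), .data$region)
}

#' Write the network edge list as TSV
#'
#' Mirrors the pairs files of networking services: one line per edge with
#' `node_a, node_b, cosine, n_matched, delta_mz`.
#'
#' @param network A `molecular_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  df <- as.data.frame(network$edges)
  con <- file(path, "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(lapply(df, function(x) {
               if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
             }), sep = "\t")))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write library annotations as TSV
#' @param annotations Annotation tibble from [library_search()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  df <- as.data.frame(annotations)
  con <- file(path, "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(lapply(df, function(x) {
               if (is.numeric(x) && !is.integer(x)) sprintf("%.17g", x)
               else as.character(x)
             }), sep = "\t")))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Re-read consensus nodes exported by the network stage
#'
#' Rebuilds `consensus_spectrum` objects from the `nodes.mgf` /
#' `node_members.tsv` pair the pipeline writes, so later stages (library
#' matching, statistics) can resume from disk with values identical to the
#' in-memory originals.
#'
#' @param mgf_path Path to the consensus `nodes.mgf`.
#' @param members_path Path to `node_members.tsv`.
#' @return A list of `consensus_spectrum`.
#' @export
read_network_nodes <- function(mgf_path, members_path) {
  specs <- read_spectral_library(mgf_path, dialect = "mgf")
  members <- utils::read.delim(members_path, stringsAsFactors = FALSE)
  lapply(specs, function(s) {
    mem <- members[members$node_id == s$scan_id, , drop = FALSE]
    structure(
      list(node_id = s$scan_id, precursor_mz = s$precursor_mz,
           peaks = s$peaks,
           members = tibble::tibble(sample_id = mem$sample_id,
                                    scan_id = mem$scan_id),
           n_members = nrow(mem)),
      class = "consensus_spectrum")
  })
}

#' Connected components (molecular families) of a network
#'
#' @param network A `molecular_network`.
#' @return A tibble: `node_id`, `component` (integer label; nodes with no
#'   edges form singleton components).
#' @export
network_components <- function(network) {
  ids <- vapply(network$nodes, function(n) n$node_id, character(1))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  if (nrow(network$edges)) {
    g <- igraph::add_edges(g, rbind(match(network$edges$node_a, ids),
                                    match(network$edges$node_b, ids)))
  }
  comp <- igraph::components(g)
  tibble::tibble(node_id = ids, component = as.integer(comp$membership))
}
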