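#' Pipeline parameter set
#'
#' All tunable thresholds of the pipeline in one validated list, at the
#' defaults of the reference workflow: MS1 signal threshold 2.0e6 with a
#' 0.3 s minimum peak width; 10 ppm mass and 10 s retention-time
#' tolerances; baseline-cutoff deconvolution at 1.0e4 with a 2 min maximum
#' peak width; MS/MS filtering at +/-17 Da around the precursor and top 6
#' peaks per 50 Da window; 0.02 Da precursor and fragment tolerances;
#' cosine 0.7 with at least 4 matched peaks; top-10 edges per node; a
#' 20 ppm precursor cap on library hits; 3 ordination axes.
#'
#' @param ... Named overrides of any default listed above.
#' @return A validated list of class `pipeline_params`.
#' @export
pipeline_params <- function(...) {
  p <- list(
    noise_threshold = 2.0e6,
    min_width_seconds = 0.3,
    baseline = 1.0e4,
    max_width_seconds = 120,
    mz_tol_ppm = 10,
    rt_tol_seconds = 10,
    max_charge = 2L,
    precursor_window_da = 17,
    window_top_n = 6L,
    window_da = 50,
    prec_tol_da = 0.02,
    frag_tol_da = 0.02,
    cosine_threshold = 0.7,
    min_matched = 4L,
    top_k = 10L,
    ppm_cap = 20,
    n_axes = 3L,
    blank_mode = "any",
    matrix_blank_filter = FALSE,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(dots)] <- dots
  num <- c("noise_threshold", "min_width_seconds", "baseline",
           "max_width_seconds", "mz_tol_ppm", "rt_tol_seconds",
           "precursor_window_da", "window_da", "prec_tol_da", "frag_tol_da",
           "ppm_cap")
  for (nm in num) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0) {
      stop("parameter '", nm, "' must be a positive number", call. = FALSE)
    }
  }
  structure(p, class = c("pipeline_params", "list"))
}

#' Read or write a pipeline configuration file
#'
#' A flat YAML file holding the parameter set plus input paths and the
#' output directory; [pipeline_params()] validates the parameters. The
#' config round-trips through serialization unchanged.
#'
#' @param path YAML path.
#' @return For `read_pipeline_config`, a list with `params`
#'   (`pipeline_params`), `inputs` and `output_dir`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  params <- do.call(pipeline_params, raw$params %||% list())
  list(params = params,
       inputs = raw$inputs %||% list(),
       output_dir = raw$output_dir %||% ".")
}

#' @rdname read_pipeline_config
#' @param config A config list (as returned by `read_pipeline_config`).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(list(params = unclass(config$params),
                        inputs = config$inputs,
                        output_dir = config$output_dir), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full cartography pipeline
#'
#' Executes the stages in order — feature finding and alignment, MS/MS
#' clustering and networking with blank subtraction, library search,
#' presence/absence statistics (binary Jaccard, PCoA, Venn), and 3D
#' ion-map export — writing every artifact plus a JSON manifest of per-stage
#' counts. Identical inputs and parameters yield identical manifests and
#' byte-identical CSV artifacts. On any stage failure the partially written
#' output directory is removed.
#'
#' @param runs Named list of `ms_run` objects, or a character vector of
#'   mzML/mzXML paths.
#' @param metadata A `sample_metadata` (or CSV path).
#' @param mesh An `ms_mesh` (or STL path), or `NULL` to skip coordinate
#'   validation and ion-map export.
#' @param library Optional spectral library (list of annotated spectra or
#'   an MGF/MSP path).
#' @param output_dir Directory for artifacts (created; must not already
#'   contain a manifest unless `overwrite = TRUE`).
#' @param params A [pipeline_params()] list.
#' @param overwrite Allow writing into an existing output dir.
#' @return The run manifest (list), invisibly; artifacts on disk.
#' @export
run_pipeline <- function(runs, metadata, mesh = NULL, library = NULL,
                         output_dir, params = pipeline_params(),
                         overwrite = FALSE) {
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  if (is.character(mesh)) mesh <- read_mesh_stl(mesh)
  if (is.character(library)) library <- read_spectral_library(library)
  created <- !dir.exists(output_dir)
  if (!created && !overwrite &&
      file.exists(file.path(output_dir, "manifest.json"))) {
    stop("output_dir already holds a pipeline run; set overwrite = TRUE",
         call. = FALSE)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit({
    if (!ok) unlink(file.path(output_dir, list.files(output_dir)),
                    recursive = TRUE)
  })

  manifest <- list(params = unclass(params),
                   config_hash = hash_object(unclass(params)),
                   input_checksums = input_checksums(runs),
                   stages = list(), files = list())

  st <- stage_features(runs, metadata, output_dir, params)
  manifest$stages$features <- st$counts
  manifest$files <- c(manifest$files, st$files)

  nt <- stage_network(st$spectra, metadata, output_dir, params)
  manifest$stages$network <- nt$counts
  manifest$files <- c(manifest$files, nt$files)

  if (!is.null(library)) {
    mt <- stage_match(nt$network, library, output_dir, params)
    manifest$stages$match <- mt$counts
    manifest$files <- c(manifest$files, mt$files)
    nt$network$annotations <- mt$annotations
  }
  # rewrite graphml with annotations attached
  write_network_graphml(nt$network, file.path(output_dir, "network.graphml"),
                        metadata = metadata)

  sm <- stage_stats(st$matrix, metadata, output_dir, params)
  manifest$stages$stats <- sm$counts
  manifest$files <- c(manifest$files, sm$files)

  if (!is.null(mesh)) {
    mp <- stage_map(st$matrix, metadata, mesh, output_dir, params)
    manifest$stages$map <- mp$counts
    manifest$files <- c(manifest$files, mp$files)
  }

  manifest$files <- sort(unique(c(unlist(manifest$files), "manifest.json")))
  mpath <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}

# ---- stages ---------------------------------------------------------------
# Each stage takes validated in-memory objects, writes its artifacts into
# output_dir, and returns counts + file names + objects downstream stages
# need. `run_pipeline` is a straight composition of these, and the CLI
# subcommands call the same functions, so stepwise and single-shot execution
# produce identical artifacts.

stage_features <- function(runs, metadata, output_dir, params) {
  if (is.character(runs)) {
    paths <- runs
    runs <- lapply(paths, read_run)
    names(runs) <- vapply(runs, function(r) r$run_id, character(1))
  }
  known <- metadata$sample_id
  bad <- setdiff(names(runs), known)
  if (length(bad)) {
    stop("features stage: run(s) missing from metadata: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n_scans <- sum(vapply(runs, function(r) length(r$scans), integer(1)))
  feats <- lapply(runs, find_features, params = params)
  n_feat <- sum(vapply(feats, nrow, integer(1)))
  m <- align_features(feats, mz_tol_ppm = params$mz_tol_ppm,
                      rt_tol_seconds = params$rt_tol_seconds)
  if (isTRUE(params$matrix_blank_filter)) {
    blanks <- intersect(fm_sample_ids(m),
                        metadata$sample_id[metadata$is_blank])
    if (length(blanks)) {
      in_blank <- rowSums(fm_areas(m)[, blanks, drop = FALSE] > 0) > 0
      m <- m[!in_blank, ]
    }
  }
  fp <- file.path(output_dir, "feature_matrix.csv")
  write_feature_matrix(m, fp)
  spectra <- unlist(lapply(runs, ms2_scans), recursive = FALSE,
                    use.names = FALSE)
  list(matrix = m, spectra = spectra,
       counts = list(runs = length(runs), scans_read = n_scans,
                     ms2_spectra = length(spectra),
                     features_detected = n_feat, rows_aligned = nrow(m)),
       files = "feature_matrix.csv")
}

stage_network <- function(spectra, metadata, output_dir, params) {
  filtered <- lapply(spectra, function(s) {
    s <- filter_precursor_window(s, params$precursor_window_da)
    filter_window_top_n(s, params$window_top_n, params$window_da)
  })
  filtered <- Filter(function(s) nrow(s$peaks) > 0, filtered)
  nodes <- cluster_spectra(filtered, prec_tol_da = params$prec_tol_da,
                           frag_tol_da = params$frag_tol_da,
                           cluster_cosine = params$cosine_threshold,
                           top_n = params$window_top_n,
                           window_da = params$window_da)
  n_clustered <- length(nodes)
  network <- build_network(nodes, edge_cosine = params$cosine_threshold,
                           min_matched = params$min_matched,
                           frag_tol_da = params$frag_tol_da,
                           top_k = params$top_k)
  n_edges_raw <- nrow(network$edges)
  network <- subtract_blanks(network, metadata, mode = params$blank_mode)
  files <- c("nodes.mgf", "node_members.tsv", "edges.tsv", "network.graphml")
  write_mgf(lapply(network$nodes, node_spectrum),
            file.path(output_dir, "nodes.mgf"),
            titles = vapply(network$nodes, function(n) n$node_id,
                            character(1)))
  members <- dplyr::bind_rows(lapply(network$nodes, function(n) {
    dplyr::mutate(n$members, node_id = n$node_id, .before = 1)
  }))
  if (!nrow(members)) {
    members <- tibble::tibble(node_id = character(0),
                              sample_id = character(0),
                              scan_id = character(0))
  }
  write_tsv_lf(members, file.path(output_dir, "node_members.tsv"))
  write_edge_list(network, file.path(output_dir, "edges.tsv"))
  write_network_graphml(network, file.path(output_dir, "network.graphml"),
                        metadata = metadata)
  list(network = network,
       counts = list(ms2_filtered = length(filtered),
                     nodes_clustered = n_clustered,
                     nodes_after_blank_subtraction = length(network$nodes),
                     edges_after_pruning = nrow(network$edges),
                     edges_before_blank_subtraction = n_edges_raw),
       files = files)
}

stage_match <- function(network, library, output_dir, params) {
  hits <- library_search(network, library,
                         prec_tol_da = params$prec_tol_da,
                         frag_tol_da = params$frag_tol_da,
                         match_cosine = params$cosine_threshold,
                         min_matched = params$min_matched,
                         ppm_cap = params$ppm_cap)
  write_annotations(hits, file.path(output_dir, "annotations.tsv"))
  n_nodes <- length(network$nodes)
  list(annotations = hits,
       counts = list(library_records = length(library),
                     library_hits = nrow(hits),
                     annotation_rate_pct = if (n_nodes) {
                       round(100 * nrow(hits) / n_nodes, 2)
                     } else 0),
       files = "annotations.tsv")
}

stage_stats <- function(m, metadata, output_dir, params) {
  mn <- tic_normalize(m)
  d <- jaccard_distances(mn)
  ord <- suppressWarnings(pcoa(d, n_axes = params$n_axes))
  vc <- venn_counts(m, metadata, grouping = "tissue")
  write_distance_matrix(d, file.path(output_dir, "jaccard_distances.csv"))
  write_ordination(ord, file.path(output_dir, "pcoa.csv"))
  jsonlite::write_json(
    list(regions = vc$regions, total = vc$total,
         center_count = vc$center_count, center_pct = vc$center_pct),
    file.path(output_dir, "venn_ms1.json"), auto_unbox = TRUE, digits = NA)
  list(counts = list(samples = attr(d, "Size"),
                     axes = ncol(ord$coordinates),
                     venn_total = vc$total,
                     venn_center = vc$center_count),
       files = c("jaccard_distances.csv", "pcoa.csv", "venn_ms1.json"))
}

stage_map <- function(m, metadata, mesh, output_dir, params) {
  eim <- build_eim_table(m, metadata, mesh)
  write_ili_table(eim, file.path(output_dir, "eim_ili.csv"))
  list(counts = list(spots = nrow(eim),
                     feature_columns = ncol(eim) - 5L),
       files = "eim_ili.csv")
}

# md5 of a canonical JSON rendering (stable across sessions, unlike
# serialize(), which embeds the R version)
hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

input_checksums <- function(runs) {
  if (is.character(runs)) {
    as.list(stats::setNames(unname(tools::md5sum(runs)), basename(runs)))
  } else {
    list(in_memory = hash_object(lapply(runs, function(r) {
      list(r$run_id, length(r$scans))
    })))
  }
}

write_tsv_lf <- function(df, path) {
  df <- as.data.frame(df)
  con <- file(path, "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(lapply(df, as.character),
                                            sep = "\t")))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
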