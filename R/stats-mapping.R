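#' Normalize a feature matrix to total ion current
#'
#' Divides every area by its sample-column sum, so each sample's feature
#' intensities sum to 1. Presence/absence analyses downstream (binary
#' Jaccard) are invariant to this step; it matters for intensity-scaled
#' exports and plots.
#'
#' @param m A `feature_matrix`.
#' @return The normalized `feature_matrix`.
#' @export
tic_normalize <- function(m) {
  sids <- fm_sample_ids(m)
  for (sid in sids) {
    s <- sum(m[[sid]])
    if (s <= 0) {
      stop("sample '", sid, "' has zero total ion current; cannot normalize",
           call. = FALSE)
    }
    m[[sid]] <- m[[sid]] / s
  }
  m
}

#' Binary Jaccard distances between samples
#'
#' Binarizes the matrix (presence = area > `min_area`) and computes
#' d(i, j) = 1 - |P_i intersect P_j| / |P_i union P_j| for every sample
#' pair. Two samples with empty presence sets are at distance 0.
#'
#' @param m A `feature_matrix`.
#' @param min_area Presence threshold; a feature is present where
#'   area > `min_area` (default 0).
#' @return A [stats::dist] object labeled with sample ids.
#' @export
jaccard_distances <- function(m, min_area = 0) {
  p <- fm_areas(m) > min_area
  storage.mode(p) <- "double"
  inter <- crossprod(p)                  # |P_i intersect P_j|
  sizes <- diag(inter)
  union <- outer(sizes, sizes, `+`) - inter
  d <- 1 - inter / union
  d[union == 0] <- 0                     # both empty -> identical
  stats::as.dist(d)
}

#' Principal coordinates analysis
#'
#' Classical metric MDS: Gower double-centering of -d^2/2 followed by a
#' symmetric eigendecomposition (delegated to [stats::cmdscale()]). Axes
#' are eigenvectors scaled by the square root of their (positive)
#' eigenvalues, in descending order; negative eigenvalues are reported but
#' contribute no axes and no correction (Cailliez/Lingoes) is applied. For
#' cross-backend stability every axis is sign-fixed so its
#' largest-magnitude coordinate is positive.
#'
#' @param d A [stats::dist] or symmetric distance matrix.
#' @param n_axes Number of axes requested (default 3); truncated with a
#'   warning when fewer positive eigenvalues exist.
#' @return A `pcoa_ordination`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending), `proportion_explained` (per returned
#'   axis, over the positive-eigenvalue sum).
#' @export
pcoa <- function(d, n_axes = 3L) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  labels <- attr(d, "Labels")
  if (is.null(labels)) labels <- paste0("sample", seq_len(n))
  k_req <- min(n_axes, n - 1L)
  fit <- stats::cmdscale(d, k = k_req, eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  k <- min(k_req, pos)
  if (k < n_axes) {
    warning("only ", k, " positive-eigenvalue axes available; requested ",
            n_axes, call. = FALSE)
  }
  k <- min(k, ncol(fit$points))
  coords <- fit$points[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- labels
  colnames(coords) <- paste0("axis", seq_len(k))
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    proportion_explained = if (k) eig[seq_len(k)] / sum(eig[eig > 0]) else numeric(0)
  ), class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("<pcoa_ordination> %d samples, %d axes (%.1f%% explained)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * sum(x$proportion_explained)))
  invisible(x)
}

#' Tidy a PCoA result into per-sample scores
#' @param x A `pcoa_ordination`.
#' @param ... Unused.
#' @return A tibble: `sample_id` then one column per axis.
#' @exportS3Method generics::tidy
tidy.pcoa_ordination <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(x$coordinates)),
                   tibble::as_tibble(x$coordinates))
}

#' One-line summary of a PCoA result
#' @param x A `pcoa_ordination`.
#' @param ... Unused.
#' @return A one-row tibble: `n_samples`, `n_axes`, `prop_explained`,
#'   `n_negative_eigenvalues`.
#' @exportS3Method generics::glance
glance.pcoa_ordination <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    n_axes = ncol(x$coordinates),
    prop_explained = sum(x$proportion_explained),
    n_negative_eigenvalues = sum(x$eigenvalues < 0)
  )
}

#' Group-overlap (Venn) counts of MS1 features
#'
#' A feature belongs to a group when it is present (area > `min_area`) in
#' at least one of the group's samples; each feature then falls into
#' exactly one region of the k-group Venn partition. Region counts sum to
#' the number of features present in at least one group, and the all-groups
#' region is also reported as a percentage of that total.
#'
#' @param m A `feature_matrix`.
#' @param metadata A `sample_metadata`; blanks are excluded.
#' @param grouping Metadata column to group by (default `"tissue"`).
#' @param min_area Presence threshold (default 0).
#' @return A list: `regions` tibble (`region`, `n_groups`, `count`),
#'   `total` (features in >= 1 group), `center_count` and `center_pct`
#'   (the all-groups region).
#' @export
venn_counts <- function(m, metadata, grouping = "tissue", min_area = 0) {
  md <- metadata[!metadata$is_blank, , drop = FALSE]
  sids <- fm_sample_ids(m)
  unmapped <- setdiff(sids, metadata$sample_id)
  if (length(unmapped)) {
    stop("sample(s) missing from metadata: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  sids <- intersect(sids, md$sample_id)
  groups <- sort(unique(as.character(md[[grouping]])))
  present <- fm_areas(m)[, sids, drop = FALSE] > min_area
  lut <- stats::setNames(as.character(md[[grouping]]), md$sample_id)
  in_group <- vapply(groups, function(g) {
    cols <- sids[lut[sids] == g]
    if (!length(cols)) rep(FALSE, nrow(present))
    else rowSums(present[, cols, drop = FALSE]) > 0
  }, logical(nrow(present)))
  in_group <- matrix(in_group, nrow = nrow(present),
                     dimnames = list(NULL, groups))
  region <- apply(in_group, 1, function(r) paste(groups[r], collapse = "+"))
  region <- region[nzchar(region)]
  tab <- table(region)
  regions <- tibble::tibble(
    region = names(tab),
    n_groups = lengths(strsplit(names(tab), "+", fixed = TRUE)),
    count = as.integer(tab)
  ) |> dplyr::arrange(dplyr::desc(.data$n_groups), .data$region)
  total <- sum(regions$count)
  center <- paste(groups, collapse = "+")
  center_count <- if (center %in% regions$region) {
    regions$count[regions$region == center]
  } else 0L
  list(regions = regions, total = total, center_count = center_count,
       center_pct = if (total) 100 * center_count / total else 0)
}

#' Build the 'ili extracted-ion-map table
#'
#' One row per non-blank sample carrying its 3D coordinates, spot radius
#' and the full per-feature intensity vector (raw areas by default). Feature
#' columns are labeled `mz_<m/z>_rt_<rt>s` with 4-decimal m/z and 1-decimal
#' RT. Coordinates are validated against the mesh bounding box expanded by
#' one spot radius.
#'
#' @param m A `feature_matrix`.
#' @param metadata A `sample_metadata`.
#' @param mesh An `ms_mesh` (optional; skips the bounding-box check when
#'   `NULL`).
#' @param scale `"raw"` (default: areas as integrated), `"tic"` (TIC-
#'   normalized) or `"feature_max"` (each feature scaled to max 1).
#' @return An `ili_table` tibble: `name, x, y, z, radius`, then features.
#' @export
build_eim_table <- function(m, metadata, mesh = NULL,
                            scale = c("raw", "tic", "feature_max")) {
  scale <- match.arg(scale)
  if (scale == "tic") m <- tic_normalize(m)
  md <- metadata[!metadata$is_blank, , drop = FALSE]
  sids <- intersect(fm_sample_ids(m), md$sample_id)
  if (!length(sids)) stop("no non-blank samples in the matrix", call. = FALSE)
  md <- md[match(sids, md$sample_id), , drop = FALSE]
  if (!is.null(mesh)) {
    bad <- check_coords_in_mesh(md, mesh)
    if (length(bad)) {
      stop("sample(s) outside the mesh bounding box (+radius): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  a <- t(fm_areas(m)[, sids, drop = FALSE])
  if (scale == "feature_max") {
    mx <- apply(a, 2, max)
    mx[mx == 0] <- 1
    a <- sweep(a, 2, mx, `/`)
  }
  colnames(a) <- sprintf("mz_%.4f_rt_%.1fs", m$mz, m$rt_seconds)
  out <- dplyr::bind_cols(
    tibble::tibble(name = md$sample_id, x = md$x, y = md$y, z = md$z,
                   radius = md$radius),
    tibble::as_tibble(a)
  )
  class(out) <- c("ili_table", class(out))
  out
}

#' Write a distance matrix to CSV
#' @param d A [stats::dist].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  mat <- as.matrix(d)
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
  write_csv_lf(df, path)
  invisible(path)
}

#' Write an ordination to CSV
#'
#' Per-sample axis scores; the full eigenvalue spectrum rides along in a
#' `# eigenvalues:` comment line after the header.
#'
#' @param ord A `pcoa_ordination`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ordination <- function(ord, path) {
  df <- as.data.frame(tidy(ord))
  tmp <- tempfile()
  write_csv_lf(df, tmp)
  lines <- readLines(tmp)
  unlink(tmp)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(lines[1],
               paste0("# eigenvalues: ",
                      paste(sprintf("%.17g", ord$eigenvalues), collapse = " ")),
               lines[-1]), con, sep = "\n")
  invisible(path)
}
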