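#' Centroid an MS1 scan above a noise threshold
#'
#' Splits the peak list into "islands" of points closer than
#' `profile_gap_da` in m/z. Islands of one or two points are treated as
#' centroided sticks and pass through; larger islands are treated as
#' profile data and reduced to their local maxima, with the apex m/z
#' refined by a 3-point parabolic fit through the maximum and its
#' neighbours. Centroids below `noise_threshold` are dropped.
#'
#' @param spectrum An MS1 `ms_spectrum`.
#' @param noise_threshold Minimum centroid intensity (default 2.0e6, the
#'   signal threshold used for feature extraction).
#' @param profile_gap_da m/z gap above which adjacent points are considered
#'   separate peaks rather than one profile (default 0.05 Da).
#' @return Numeric matrix of centroids (`mz`, `intensity`), possibly empty.
#' @export
detect_masses <- function(spectrum, noise_threshold = 2.0e6,
                          profile_gap_da = 0.05) {
  if (spectrum$ms_level != 1L) {
    stop("detect_masses expects an MS1 spectrum", call. = FALSE)
  }
  pk <- spectrum$peaks
  if (!nrow(pk)) return(empty_centroids())
  mz <- pk[, "mz"]
  it <- pk[, "intensity"]
  island <- cumsum(c(TRUE, diff(mz) > profile_gap_da))
  cents <- lapply(split(seq_along(mz), island), function(idx) {
    if (length(idx) <= 2L) {
      # too short to be a profile: keep each point as a stick centroid
      return(lapply(idx, function(j) c(mz[j], it[j])))
    }
    centroid_profile(mz[idx], it[idx])
  })
  out <- matrix(unlist(cents), ncol = 2L, byrow = TRUE)
  colnames(out) <- c("mz", "intensity")
  out <- out[out[, "intensity"] >= noise_threshold, , drop = FALSE]
  out[order(out[, "mz"]), , drop = FALSE]
}

empty_centroids <- function() {
  matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("mz", "intensity")))
}

# Local maxima of a profile island; each refined by a parabola through
# (mz, intensity) at the apex and its two neighbours (general quadratic fit,
# valid for non-uniform m/z spacing).
centroid_profile <- function(mz, it) {
  n <- length(mz)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i == 1L) -Inf else it[i - 1L]
    right <- if (i == n) -Inf else it[i + 1L]
    it[i] > left && it[i] >= right
  }, logical(1))
  lapply(which(is_max), function(i) {
    if (i == 1L || i == n) return(c(mz[i], it[i]))
    parabola_apex(mz[(i - 1L):(i + 1L)], it[(i - 1L):(i + 1L)])
  })
}

parabola_apex <- function(x, y) {
  # fit y = a x^2 + b x + c through three points
  X <- cbind(x^2, x, 1)
  coef <- tryCatch(solve(X, y), error = function(e) NULL)
  if (is.null(coef) || coef[1] >= 0) return(c(x[2], y[2]))
  apex_x <- -coef[2] / (2 * coef[1])
  if (apex_x < x[1] || apex_x > x[3]) return(c(x[2], y[2]))
  apex_y <- coef[1] * apex_x^2 + coef[2] * apex_x + coef[3]
  c(apex_x, apex_y)
}

#' Build extracted ion chromatograms from a run
#'
#' Chains centroids scan to scan: a centroid joins the open trace whose
#' running intensity-weighted m/z center is within `mz_tol_ppm` (closest
#' ppm wins when several qualify; one centroid per trace per scan).
#' Unmatched centroids open new traces. Traces spanning less than
#' `min_width_seconds` of retention time are discarded.
#'
#' @param run An `ms_run`.
#' @param mz_tol_ppm Chaining tolerance in ppm (default 10).
#' @param min_width_seconds Minimum trace span in seconds (default 0.3).
#' @param noise_threshold Passed to [detect_masses()].
#' @return A list of `eic` objects: `center_mz`, `trace` (rt, intensity
#'   matrix), `sample_id`.
#' @export
build_eics <- function(run, mz_tol_ppm = 10, min_width_seconds = 0.3,
                       noise_threshold = 2.0e6) {
  scans <- ms1_scans(run)
  sample_id <- if (length(scans)) scans[[1]]$sample_id else run$run_id
  # open trace state: center mz, weight sum, rt/int accumulators
  centers <- numeric(0)
  weights <- numeric(0)
  traces <- list()
  for (s in scans) {
    cents <- detect_masses(s, noise_threshold = noise_threshold)
    if (!nrow(cents)) next
    taken <- rep(FALSE, length(centers))
    assigned <- integer(nrow(cents))
    for (ci in seq_len(nrow(cents))) {     # centroids ascend in m/z
      mzc <- cents[ci, "mz"]
      if (length(centers)) {
        dppm <- abs(mzc - centers) / centers * 1e6
        ok <- which(dppm <= mz_tol_ppm & !taken)
        if (length(ok)) {
          pick <- ok[which.min(dppm[ok])]
          assigned[ci] <- pick
          taken[pick] <- TRUE
          next
        }
      }
      assigned[ci] <- 0L
    }
    for (ci in seq_len(nrow(cents))) {
      mzc <- cents[ci, "mz"]
      inten <- cents[ci, "intensity"]
      ti <- assigned[ci]
      if (ti == 0L) {
        centers <- c(centers, mzc)
        weights <- c(weights, inten)
        traces[[length(traces) + 1L]] <- list(rt = s$rt_seconds, int = inten)
        next
      }
      centers[ti] <- (centers[ti] * weights[ti] + mzc * inten) /
        (weights[ti] + inten)
      weights[ti] <- weights[ti] + inten
      traces[[ti]]$rt <- c(traces[[ti]]$rt, s$rt_seconds)
      traces[[ti]]$int <- c(traces[[ti]]$int, inten)
    }
  }
  out <- list()
  for (ti in seq_along(traces)) {
    tr <- traces[[ti]]
    if (length(tr$rt) < 2L) next
    if (tr$rt[length(tr$rt)] - tr$rt[1] < min_width_seconds) next
    out[[length(out) + 1L]] <- structure(
      list(center_mz = centers[ti],
           trace = cbind(rt = tr$rt, intensity = tr$int),
           sample_id = sample_id),
      class = "eic")
  }
  out
}

#' @export
print.eic <- function(x, ...) {
  cat(sprintf("<eic> m/z %.4f, %d points, rt %.1f-%.1f s\n", x$center_mz,
              nrow(x$trace), x$trace[1, "rt"], x$trace[nrow(x$trace), "rt"]))
  invisible(x)
}

#' Deconvolute an ion chromatogram into features
#'
#' Baseline-cutoff deconvolution: contiguous runs of trace points with
#' intensity above `baseline` become candidate peaks, each reported with its
#' apex retention time, apex height, and trapezoidal area over the
#' above-baseline segment. Segments wider than `max_width_seconds` are split
#' at their deepest internal minimum, recursively; segments narrower than
#' `min_width_seconds` are dropped.
#'
#' @param eic An `eic` from [build_eics()].
#' @param baseline Signal threshold (default 1.0e4).
#' @param max_width_seconds Maximum peak width (default 120, i.e. 2 min).
#' @param min_width_seconds Minimum peak width (default 0.3).
#' @return A tibble of features: `mz`, `rt_seconds`, `area`, `height`,
#'   `sample_id`. Zero rows when nothing clears the baseline.
#' @export
deconvolute <- function(eic, baseline = 1.0e4, max_width_seconds = 120,
                        min_width_seconds = 0.3) {
  rt <- eic$trace[, "rt"]
  it <- eic$trace[, "intensity"]
  above <- it > baseline
  feats <- list()
  if (any(above)) {
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      idx <- starts[k]:ends[k]
      feats <- c(feats, split_segment(rt[idx], it[idx], max_width_seconds,
                                      min_width_seconds))
    }
  }
  if (!length(feats)) {
    return(tibble::tibble(mz = numeric(0), rt_seconds = numeric(0),
                          area = numeric(0), height = numeric(0),
                          sample_id = character(0)))
  }
  tibble::tibble(
    mz = eic$center_mz,
    rt_seconds = vapply(feats, `[[`, numeric(1), "rt"),
    area = vapply(feats, `[[`, numeric(1), "area"),
    height = vapply(feats, `[[`, numeric(1), "height"),
    sample_id = eic$sample_id
  )
}

# Deepest-valley split of an above-baseline segment (worklist form of the
# recursive rule). A cut is placed at the deepest interior local minimum
# that is a genuine dip (strictly below at least one neighbour); a segment
# with no such valley — a lone flank, hump or plateau — cannot be
# meaningfully split and is reported whole even when over-wide.
split_segment <- function(rt, it, max_width, min_width) {
  out <- list()
  work <- list(c(1L, length(rt)))
  while (length(work)) {
    rng <- work[[length(work)]]
    work[[length(work)]] <- NULL
    a <- rng[1]; b <- rng[2]
    width <- rt[b] - rt[a]
    if (width < min_width || b - a < 1L) next
    if (width > max_width && b - a >= 2L) {
      interior <- (a + 1L):(b - 1L)
      dip <- it[interior] <= it[interior - 1L] &
        it[interior] <= it[interior + 1L] &
        (it[interior] < it[interior - 1L] | it[interior] < it[interior + 1L])
      valleys <- interior[dip]
      if (length(valleys)) {
        cut <- valleys[which.min(it[valleys])]
        work[[length(work) + 1L]] <- c(a, cut)
        work[[length(work) + 1L]] <- c(cut, b)
        next
      }
    }
    seg <- a:b
    apex <- seg[which.max(it[seg])]
    out[[length(out) + 1L]] <- list(rt = rt[apex], height = it[apex],
                                    area = trapezoid(rt[seg], it[seg]))
  }
  # report in elution order regardless of worklist traversal
  if (length(out) > 1L) {
    out <- out[order(vapply(out, `[[`, numeric(1), "rt"))]
  }
  out
}

trapezoid <- function(x, y) {
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Remove isotope companions from a feature list
#'
#' For each feature F (processed in ascending m/z), any feature whose m/z
#' sits at F.mz + k * 1.003355 / z (k = 1..3, z = 1..`max_charge`) within
#' `mz_tol_ppm`, whose retention time is within `rt_tol_seconds`, and whose
#' area does not exceed F's is removed as a +k isotopologue; the lowest-m/z
#' member of every chain is kept. Pure spacing only — no intensity-ratio
#' model is applied.
#'
#' @param features Feature tibble from one sample.
#' @param mz_tol_ppm m/z tolerance in ppm (default 10).
#' @param rt_tol_seconds RT tolerance in seconds (default 10).
#' @param max_charge Highest charge state considered (default 2).
#' @return The de-isotoped feature tibble.
#' @export
remove_isotopes <- function(features, mz_tol_ppm = 10, rt_tol_seconds = 10,
                            max_charge = 2L) {
  if (!nrow(features)) return(features)
  if (length(unique(features$sample_id)) > 1L) {
    stop("remove_isotopes expects features from a single sample",
         call. = FALSE)
  }
  ord <- order(features$mz, features$rt_seconds)
  features <- features[ord, ]
  removed <- rep(FALSE, nrow(features))
  for (i in seq_len(nrow(features))) {
    if (removed[i]) next
    for (z in seq_len(max_charge)) {
      for (k in 1:3) {
        target <- features$mz[i] + k * 1.003355 / z
        tol <- target * mz_tol_ppm * 1e-6
        hits <- which(!removed &
                        abs(features$mz - target) <= tol &
                        abs(features$rt_seconds - features$rt_seconds[i]) <=
                          rt_tol_seconds &
                        features$area <= features$area[i])
        removed[hits[hits != i]] <- TRUE
      }
    }
  }
  features[!removed, ]
}

#' Detect features for one run
#'
#' Convenience composition of [build_eics()], [deconvolute()] and
#' [remove_isotopes()] with the pipeline's default thresholds.
#'
#' @param run An `ms_run`.
#' @param params A [pipeline_params()] list.
#' @return A feature tibble for the run's sample.
#' @export
find_features <- function(run, params = pipeline_params()) {
  eics <- build_eics(run, mz_tol_ppm = params$mz_tol_ppm,
                     min_width_seconds = params$min_width_seconds,
                     noise_threshold = params$noise_threshold)
  feats <- dplyr::bind_rows(lapply(eics, deconvolute,
                                   baseline = params$baseline,
                                   max_width_seconds = params$max_width_seconds,
                                   min_width_seconds = params$min_width_seconds))
  if (!nrow(feats)) {
    return(tibble::tibble(mz = numeric(0), rt_seconds = numeric(0),
                          area = numeric(0), height = numeric(0),
                          sample_id = character(0)))
  }
  remove_isotopes(feats, mz_tol_ppm = params$mz_tol_ppm,
                  rt_tol_seconds = params$rt_tol_seconds,
                  max_charge = params$max_charge)
}

#' Align per-sample feature lists into a feature matrix
#'
#' Greedy join aligner. Samples are processed in lexicographic sample-id
#' order (so the result does not depend on input order); within a sample,
#' features are processed by ascending m/z then RT. Each feature joins the
#' aligned row minimizing (dppm / mz_tol_ppm)^2 + (drt / rt_tol_seconds)^2
#' among rows with both deltas within tolerance (deltas measured against the
#' row's running intensity-weighted consensus m/z and RT; equal scores break
#' to the lower row index), else starts a new row. A row takes at most one
#' feature per sample: on a collision the better-scoring feature keeps the
#' row and the loser starts a new row.
#'
#' @param per_sample_features Named list (or bind_rows-able tibble with a
#'   `sample_id` column) of per-sample feature tibbles.
#' @param mz_tol_ppm m/z tolerance in ppm (default 10).
#' @param rt_tol_seconds RT tolerance in seconds (default 10).
#' @return A `feature_matrix` tibble: `row_id`, `mz`, `rt_seconds`, then one
#'   area column per sample (0 where absent).
#' @export
align_features <- function(per_sample_features, mz_tol_ppm = 10,
                           rt_tol_seconds = 10) {
  if (is.data.frame(per_sample_features)) {
    per_sample_features <- split(per_sample_features,
                                 per_sample_features$sample_id)
  }
  ids <- vapply(per_sample_features, function(f) {
    u <- unique(f$sample_id)
    if (length(u) != 1L) stop("each feature table must be single-sample",
                              call. = FALSE)
    u
  }, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in alignment input: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  ord <- order(ids)
  per_sample_features <- per_sample_features[ord]
  ids <- ids[ord]

  rows_mz <- numeric(0)
  rows_rt <- numeric(0)
  rows_w <- numeric(0)
  members <- list()     # each: list of (sample_idx, area, mz, rt, score)

  add_row <- function(si, f) {
    rows_mz <<- c(rows_mz, f$mz)
    rows_rt <<- c(rows_rt, f$rt_seconds)
    rows_w <<- c(rows_w, f$area)
    members[[length(members) + 1L]] <<- stats::setNames(
      list(list(area = f$area, mz = f$mz, rt = f$rt_seconds,
                score = 0)), ids[si])
  }
  absorb <- function(ri, si, f, score) {
    w <- rows_w[ri]
    rows_mz[ri] <<- (rows_mz[ri] * w + f$mz * f$area) / (w + f$area)
    rows_rt[ri] <<- (rows_rt[ri] * w + f$rt_seconds * f$area) / (w + f$area)
    rows_w[ri] <<- w + f$area
    members[[ri]][[ids[si]]] <<- list(area = f$area, mz = f$mz,
                                      rt = f$rt_seconds, score = score)
  }

  for (si in seq_along(per_sample_features)) {
    feats <- per_sample_features[[si]]
    if (!nrow(feats)) next
    feats <- feats[order(feats$mz, feats$rt_seconds), ]
    for (fi in seq_len(nrow(feats))) {
      f <- feats[fi, ]
      if (length(rows_mz)) {
        dppm <- abs(f$mz - rows_mz) / rows_mz * 1e6
        drt <- abs(f$rt_seconds - rows_rt)
        ok <- which(dppm <= mz_tol_ppm & drt <= rt_tol_seconds)
      } else ok <- integer(0)
      placed <- FALSE
      if (length(ok)) {
        score <- (dppm[ok] / mz_tol_ppm)^2 + (drt[ok] / rt_tol_seconds)^2
        pick <- ok[which.min(score)]   # ties -> lowest row index
        sc <- min(score)
        prev <- members[[pick]][[ids[si]]]
        if (is.null(prev)) {
          absorb(pick, si, f, sc)
          placed <- TRUE
        } else if (sc < prev$score) {
          # new feature wins the row; previous occupant starts a new row
          evicted <- prev
          members[[pick]][[ids[si]]] <- NULL
          # rebuild row consensus without the evicted member
          mem <- members[[pick]]
          areas <- vapply(mem, `[[`, numeric(1), "area")
          rows_mz[pick] <- sum(vapply(mem, `[[`, numeric(1), "mz") * areas) /
            sum(areas)
          rows_rt[pick] <- sum(vapply(mem, `[[`, numeric(1), "rt") * areas) /
            sum(areas)
          rows_w[pick] <- sum(areas)
          absorb(pick, si, f, sc)
          add_row(si, list(mz = evicted$mz, rt_seconds = evicted$rt,
                           area = evicted$area))
          placed <- TRUE
        }
      }
      if (!placed) add_row(si, f)   # no candidate row, or lost the collision
    }
  }

  n_rows <- length(rows_mz)
  areas <- matrix(0, nrow = n_rows, ncol = length(ids),
                  dimnames = list(NULL, ids))
  for (ri in seq_len(n_rows)) {
    for (sid in names(members[[ri]])) {
      areas[ri, sid] <- members[[ri]][[sid]]$area
    }
  }
  ord_rows <- order(rows_mz, rows_rt)
  out <- tibble::tibble(
    row_id = sprintf("F%04d", seq_len(n_rows)),
    mz = rows_mz[ord_rows],
    rt_seconds = rows_rt[ord_rows]
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(areas[ord_rows, , drop = FALSE]))
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Sample columns of a feature matrix
#' @param m A `feature_matrix`.
#' @return Character vector of sample ids.
#' @export
fm_sample_ids <- function(m) {
  setdiff(names(m), c("row_id", "mz", "rt_seconds"))
}

#' Area matrix of a feature matrix
#' @param m A `feature_matrix`.
#' @return Numeric matrix, rows = aligned features, columns = samples.
#' @export
fm_areas <- function(m) {
  a <- as.matrix(m[, fm_sample_ids(m), drop = FALSE])
  rownames(a) <- m$row_id
  a
}

#' Write a feature matrix to CSV
#'
#' The ".csv matrix of samples and features with the area under the curve":
#' columns `row_id, mz, rt_seconds`, then one per-sample area column.
#'
#' @param m A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path) {
  write_csv_lf(as.data.frame(m), path)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path CSV path.
#' @return A `feature_matrix` tibble.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("row_id", "mz", "rt_seconds") %in% names(df))) {
    stop("'", path, "' is not a feature-matrix CSV", call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  class(out) <- c("feature_matrix", class(out))
  out
}
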