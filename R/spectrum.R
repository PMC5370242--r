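#' Construct a single mass spectrum
#'
#' The atomic data unit of the pipeline: one MS1 survey scan or one MS2
#' product-ion scan, with its peak list held as a two-column numeric matrix.
#' Peaks are always stored sorted ascending by m/z.
#'
#' @param scan_id Scan identifier, unique within a run.
#' @param ms_level Integer, 1 (survey) or 2 (product-ion).
#' @param rt_seconds Retention time in seconds (all internal times are
#'   seconds; minute-based values are converted on read).
#' @param peaks Two-column numeric matrix (`mz`, `intensity`) or a data frame
#'   with those columns. May have zero rows.
#' @param precursor_mz Precursor m/z in Da; required for MS2, must be absent
#'   (`NA`) for MS1.
#' @param sample_id Sample the scan belongs to.
#' @param annotation Optional named list of library annotations
#'   (`compound_name`, `library_id`).
#' @return An object of class `ms_spectrum`.
#' @export
new_spectrum <- function(scan_id, ms_level, rt_seconds, peaks,
                         precursor_mz = NA_real_, sample_id = NA_character_,
                         annotation = NULL) {
  peaks <- as_peak_matrix(peaks)
  ms_level <- as.integer(ms_level)
  if (!ms_level %in% c(1L, 2L)) {
    stop("ms_level must be 1 or 2, got ", ms_level, call. = FALSE)
  }
  if (is.na(rt_seconds) || rt_seconds < 0) {
    stop("rt_seconds must be a non-negative number", call. = FALSE)
  }
  if (ms_level == 2L && (is.na(precursor_mz) || precursor_mz <= 0)) {
    stop("MS2 spectrum '", scan_id, "' lacks a positive precursor m/z",
         call. = FALSE)
  }
  if (ms_level == 1L && !is.na(precursor_mz)) {
    stop("MS1 spectrum '", scan_id, "' must not carry a precursor m/z",
         call. = FALSE)
  }
  structure(
    list(scan_id = as.character(scan_id), ms_level = ms_level,
         rt_seconds = as.numeric(rt_seconds),
         precursor_mz = as.numeric(precursor_mz),
         peaks = peaks, sample_id = as.character(sample_id),
         annotation = annotation),
    class = "ms_spectrum"
  )
}

# Coerce to a sorted, validated mz/intensity matrix.
as_peak_matrix <- function(peaks) {
  if (is.data.frame(peaks)) peaks <- as.matrix(peaks[, c("mz", "intensity")])
  if (is.null(peaks) || length(peaks) == 0L) {
    peaks <- matrix(numeric(0), ncol = 2L)
  }
  if (!is.matrix(peaks) || ncol(peaks) != 2L) {
    stop("peaks must be a two-column (mz, intensity) matrix", call. = FALSE)
  }
  colnames(peaks) <- c("mz", "intensity")
  storage.mode(peaks) <- "double"
  if (anyNA(peaks)) stop("peak list contains NA values", call. = FALSE)
  if (nrow(peaks) && any(peaks[, "mz"] <= 0)) {
    stop("peak m/z values must be positive", call. = FALSE)
  }
  if (nrow(peaks) && any(peaks[, "intensity"] < 0)) {
    stop("peak intensities must be non-negative", call. = FALSE)
  }
  peaks[order(peaks[, "mz"]), , drop = FALSE]
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum> %s  MS%d  rt %.2f s  %d peaks",
              x$scan_id, x$ms_level, x$rt_seconds, nrow(x$peaks)))
  if (!is.na(x$precursor_mz)) cat(sprintf("  precursor %.4f", x$precursor_mz))
  if (!is.null(x$annotation$compound_name)) {
    cat("  [", x$annotation$compound_name, "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Construct a raw LC-MS/MS run
#'
#' An ordered scan list for one injection. Scans are sorted by retention
#' time on construction; every MS2 scan must follow at least one MS1 scan.
#'
#' @param run_id Run identifier (conventionally the sample id).
#' @param scans List of [new_spectrum()] objects.
#' @param source_path Path the run was read from, if any.
#' @return An object of class `ms_run`.
#' @export
new_run <- function(run_id, scans, source_path = NA_character_) {
  stopifnot(is.list(scans))
  rts <- vapply(scans, function(s) s$rt_seconds, numeric(1))
  scans <- scans[order(rts)]
  levels <- vapply(scans, function(s) s$ms_level, integer(1))
  if (length(scans) && !any(levels == 1L)) {
    stop("run '", run_id, "' contains no MS1 scans", call. = FALSE)
  }
  if (any(levels == 2L) && which(levels == 2L)[1] < which(levels == 1L)[1]) {
    stop("run '", run_id, "' has an MS2 scan before any MS1 survey scan",
         call. = FALSE)
  }
  structure(list(run_id = as.character(run_id), scans = scans,
                 source_path = source_path),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  levels <- vapply(x$scans, function(s) s$ms_level, integer(1))
  cat(sprintf("<ms_run> %s: %d scans (%d MS1, %d MS2)\n", x$run_id,
              length(x$scans), sum(levels == 1L), sum(levels == 2L)))
  invisible(x)
}

#' Tidy a run into a per-scan tibble
#'
#' @param x An `ms_run`.
#' @param ... Unused.
#' @return A tibble with one row per scan: `scan_id`, `ms_level`,
#'   `rt_seconds`, `precursor_mz`, `n_peaks`, `tic`.
#' @exportS3Method generics::tidy
tidy.ms_run <- function(x, ...) {
  tibble::tibble(
    scan_id = vapply(x$scans, function(s) s$scan_id, character(1)),
    ms_level = vapply(x$scans, function(s) s$ms_level, integer(1)),
    rt_seconds = vapply(x$scans, function(s) s$rt_seconds, numeric(1)),
    precursor_mz = vapply(x$scans, function(s) s$precursor_mz, numeric(1)),
    n_peaks = vapply(x$scans, function(s) nrow(s$peaks), integer(1)),
    tic = vapply(x$scans, function(s) sum(s$peaks[, "intensity"]), numeric(1))
  )
}

#' Tidy a spectrum into a peak tibble
#' @param x An `ms_spectrum`.
#' @param ... Unused.
#' @return A tibble with columns `mz`, `intensity`.
#' @exportS3Method generics::tidy
tidy.ms_spectrum <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$peaks))
}

ms2_scans <- function(run) {
  Filter(function(s) s$ms_level == 2L, run$scans)
}

ms1_scans <- function(run) {
  Filter(function(s) s$ms_level == 1L, run$scans)
}
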