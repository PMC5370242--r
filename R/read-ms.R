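#' Read an LC-MS/MS run from mzML or mzXML
#'
#' Parsing is delegated to the proteowizard-backed mzR reader; the returned
#' run is validated against the pipeline's invariants: scans ordered by
#' retention time, retention times in seconds (minute-recorded mzML values
#' are converted), peak lists sorted by m/z, every MS2 scan carrying a
#' positive precursor m/z and following an MS1 survey scan.
#'
#' @param path Path to an `.mzML` or `.mzXML` file.
#' @param sample_id Sample identifier to stamp onto each scan; defaults to
#'   the file name without extension.
#' @return An `ms_run`.
#' @export
read_run <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(mzML|mzXML)$", "", basename(path), ignore.case = TRUE)
  }
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) {
                       stop("cannot parse '", path, "' as mzML/mzXML: ",
                            conditionMessage(e), call. = FALSE)
                     })
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (!nrow(hdr)) stop("run '", path, "' contains no scans", call. = FALSE)
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  scans <- vector("list", nrow(hdr))
  for (i in seq_len(nrow(hdr))) {
    lvl <- hdr$msLevel[i]
    prec <- if (lvl >= 2L) hdr$precursorMZ[i] else NA_real_
    if (lvl >= 2L && (is.na(prec) || prec <= 0)) {
      stop("format error in '", path, "': MS2 scan ", hdr$acquisitionNum[i],
           " lacks a positive precursor m/z", call. = FALSE)
    }
    pm <- pk[[i]]
    colnames(pm) <- c("mz", "intensity")
    scans[[i]] <- new_spectrum(
      scan_id = paste0("scan=", hdr$acquisitionNum[i]),
      ms_level = min(lvl, 2L),
      rt_seconds = hdr$retentionTime[i],
      peaks = pm,
      precursor_mz = prec,
      sample_id = sample_id
    )
  }
  new_run(run_id = sample_id, scans = scans, source_path = path)
}

#' Write an LC-MS/MS run to mzML or mzXML
#'
#' Serializes an `ms_run` (typically a synthetic one) through mzR's
#' proteowizard writer so the pipeline's own reader path is exercised on
#' standard files.
#'
#' @param run An `ms_run`.
#' @param path Output path; the extension selects the dialect.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  outformat <- if (grepl("\\.mzXML$", path, ignore.case = TRUE)) "mzxml" else "mzml"
  scans <- run$scans
  n <- length(scans)
  pks <- lapply(scans, function(s) unname(s$peaks))
  lvl <- vapply(scans, function(s) s$ms_level, integer(1))
  prec <- vapply(scans, function(s) s$precursor_mz, numeric(1))
  npk <- vapply(pks, nrow, integer(1))
  tic <- vapply(pks, function(p) sum(p[, 2]), numeric(1))
  bp <- t(vapply(pks, function(p) {
    if (nrow(p)) p[which.max(p[, 2]), ] else c(0, 0)
  }, numeric(2)))
  # last preceding MS1 scan for each MS2
  prec_scan <- integer(n)
  last_ms1 <- 0L
  for (i in seq_len(n)) {
    if (lvl[i] == 1L) last_ms1 <- i else prec_scan[i] <- last_ms1
  }
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lvl,
    polarity = 1L, peaksCount = npk, totIonCurrent = tic,
    retentionTime = vapply(scans, function(s) s$rt_seconds, numeric(1)),
    basePeakMZ = bp[, 1], basePeakIntensity = bp[, 2],
    collisionEnergy = ifelse(lvl == 2L, 25, 0), ionisationEnergy = 0,
    lowMZ = vapply(pks, function(p) if (nrow(p)) min(p[, 1]) else 0, numeric(1)),
    highMZ = vapply(pks, function(p) if (nrow(p)) max(p[, 1]) else 0, numeric(1)),
    precursorScanNum = prec_scan,
    precursorMZ = ifelse(lvl == 2L, prec, 0),
    precursorCharge = ifelse(lvl == 2L, 1L, 0L),
    precursorIntensity = ifelse(lvl == 2L, 1e4, 0),
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(lvl == 2L, prec, NA_real_),
    isolationWindowLowerOffset = ifelse(lvl == 2L, 1, NA_real_),
    isolationWindowUpperOffset = ifelse(lvl == 2L, 1, NA_real_),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  suppressWarnings(mzR::writeMSData(pks, file = path, header = hdr,
                                    outformat = outformat))
  invisible(path)
}

#' Read an annotated spectral reference library
#'
#' Parses MGF (`BEGIN IONS`/`END IONS` blocks) or MSP (`Name:`/`Num Peaks:`
#' records) into annotated MS2 spectra for library matching. Records without
#' a precursor m/z are skipped with a warning; a library with zero valid
#' records is an error.
#'
#' @param path Path to the library file.
#' @param dialect `"mgf"` or `"msp"`; default guesses from the extension.
#' @return A list of `ms_spectrum` objects, each carrying
#'   `annotation$compound_name` and `annotation$library_id`.
#' @export
read_spectral_library <- function(path, dialect = c("auto", "mgf", "msp")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.msp$", path, ignore.case = TRUE)) "msp" else "mgf"
  }
  lines <- readLines(path, warn = FALSE)
  specs <- if (dialect == "mgf") parse_mgf(lines, path) else parse_msp(lines, path)
  if (!length(specs)) {
    stop("spectral library '", path, "' contains no valid records",
         call. = FALSE)
  }
  specs
}

parse_mgf <- function(lines, path) {
  begins <- grep("^\\s*BEGIN IONS\\s*$", lines)
  ends <- grep("^\\s*END IONS\\s*$", lines)
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF '", path, "': unbalanced BEGIN/END IONS", call. = FALSE)
  }
  specs <- list()
  skipped <- 0L
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- toupper(sub("=.*", "", block[kv]))
    vals <- sub("^[^=]*=", "", block[kv])
    pep <- vals[keys == "PEPMASS"][1]
    prec <- if (is.na(pep)) NA_real_ else
      suppressWarnings(as.numeric(strsplit(trimws(pep), "\\s+")[[1]][1]))
    peak_lines <- trimws(block[!kv])
    peak_lines <- peak_lines[nzchar(peak_lines)]
    peaks <- parse_peak_lines(peak_lines, path)
    if (is.na(prec) || prec <= 0 || nrow(peaks) == 0L) {
      skipped <- skipped + 1L
      next
    }
    name <- vals[keys == "TITLE"][1]
    lid <- vals[keys == "SPECTRUMID"][1]
    if (is.na(lid)) lid <- paste0("MGF", sprintf("%05d", k))
    rt <- suppressWarnings(as.numeric(vals[keys == "RTINSECONDS"][1]))
    specs[[length(specs) + 1L]] <- new_spectrum(
      scan_id = lid, ms_level = 2L,
      rt_seconds = if (is.na(rt)) 0 else rt,
      peaks = peaks, precursor_mz = prec, sample_id = "library",
      annotation = list(compound_name = if (is.na(name)) lid else name,
                        library_id = lid)
    )
  }
  if (skipped) {
    warning(skipped, " record(s) in '", path,
            "' skipped (missing precursor or empty peak list)", call. = FALSE)
  }
  specs
}

parse_msp <- function(lines, path) {
  name_idx <- grep("^Name:\\s*", lines, ignore.case = TRUE)
  if (!length(name_idx)) return(list())
  bounds <- c(name_idx, length(lines) + 1L)
  specs <- list()
  skipped <- 0L
  for (k in seq_along(name_idx)) {
    block <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    getf <- function(key) {
      m <- grep(paste0("^", key, ":\\s*"), block, ignore.case = TRUE, value = TRUE)
      if (!length(m)) return(NA_character_)
      trimws(sub("^[^:]*:\\s*", "", m[1]))
    }
    name <- getf("Name")
    prec <- suppressWarnings(as.numeric(getf("PrecursorMZ")))
    if (is.na(prec)) prec <- suppressWarnings(as.numeric(getf("Precursor_mz")))
    npk_line <- grep("^Num ?Peaks:\\s*", block, ignore.case = TRUE)
    if (!length(npk_line)) {
      stop("malformed MSP '", path, "': record '", name,
           "' lacks a Num Peaks line", call. = FALSE)
    }
    npk <- suppressWarnings(as.integer(sub("^[^:]*:\\s*", "",
                                           block[npk_line[1]])))
    peak_lines <- if (npk_line[1] < length(block)) {
      trimws(block[seq.int(npk_line[1] + 1L, length(block))])
    } else character(0)
    peak_lines <- peak_lines[nzchar(peak_lines)]
    peaks <- parse_peak_lines(peak_lines, path)
    if (nrow(peaks) != npk) {
      stop("malformed MSP '", path, "': record '", name, "' declares ", npk,
           " peaks but lists ", nrow(peaks), call. = FALSE)
    }
    if (is.na(prec) || prec <= 0 || nrow(peaks) == 0L) {
      skipped <- skipped + 1L
      next
    }
    lid <- getf("DB#")
    if (is.na(lid)) lid <- paste0("MSP", sprintf("%05d", k))
    specs[[length(specs) + 1L]] <- new_spectrum(
      scan_id = lid, ms_level = 2L, rt_seconds = 0,
      peaks = peaks, precursor_mz = prec, sample_id = "library",
      annotation = list(compound_name = name, library_id = lid)
    )
  }
  if (skipped) {
    warning(skipped, " record(s) in '", path,
            "' skipped (missing precursor)", call. = FALSE)
  }
  specs
}

parse_peak_lines <- function(peak_lines, path) {
  empty <- matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("mz", "intensity")))
  if (!length(peak_lines)) return(empty)
  # NIST-style MSP may pack several "mz int" pairs per line separated by ";"
  pairs <- trimws(unlist(strsplit(peak_lines, ";", fixed = TRUE)))
  pairs <- pairs[nzchar(pairs)]
  if (!length(pairs)) return(empty)
  fields <- strsplit(pairs, "\\s+", perl = TRUE)
  mz <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 1L)))
  it <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  if (anyNA(mz) || anyNA(it)) {
    stop("malformed peak line in '", path, "'", call. = FALSE)
  }
  cbind(mz = mz, intensity = it)
}

#' Write spectra as MGF
#'
#' Emits `BEGIN IONS` blocks readable by [read_spectral_library()] and by
#' external networking tools; used for consensus-node export and for the
#' synthetic reference library.
#'
#' @param spectra List of `ms_spectrum` (MS2).
#' @param path Output path.
#' @param titles Optional character vector of TITLE values; defaults to each
#'   spectrum's annotation name or scan id.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path, titles = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  out <- character(0)
  for (k in seq_along(spectra)) {
    s <- spectra[[k]]
    title <- if (!is.null(titles)) titles[k]
      else if (!is.null(s$annotation$compound_name)) s$annotation$compound_name
      else s$scan_id
    out <- c(out, "BEGIN IONS",
             paste0("TITLE=", title),
             paste0("PEPMASS=", sprintf("%.17g", s$precursor_mz)),
             paste0("SPECTRUMID=", s$scan_id),
             paste0("RTINSECONDS=", sprintf("%.17g", s$rt_seconds)),
             "CHARGE=1+",
             sprintf("%.17g %.17g", s$peaks[, "mz"], s$peaks[, "intensity"]),
             "END IONS", "")
  }
  writeLines(out, con, sep = "\n")
  invisible(path)
}
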