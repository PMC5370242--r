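#' Remove fragment peaks near the precursor
#'
#' Product-ion spectra retain residual precursor signal and its isotopes and
#' small neutral losses; these dominate naive similarity scores. Peaks with
#' |m/z - precursor m/z| <= `half_window_da` (boundary inclusive) are
#' removed before clustering, networking and library search.
#'
#' @param s An MS2 `ms_spectrum`.
#' @param half_window_da Exclusion half-window in Da (default 17, i.e. a
#'   +/-17 Da window around the precursor).
#' @return The filtered spectrum, flagged `precursor_window_applied`.
#' @export
filter_precursor_window <- function(s, half_window_da = 17) {
  if (s$ms_level != 2L) {
    stop("precursor-window filter requires an MS2 spectrum", call. = FALSE)
  }
  keep <- abs(s$peaks[, "mz"] - s$precursor_mz) > half_window_da
  s$peaks <- s$peaks[keep, , drop = FALSE]
  s$precursor_window_applied <- TRUE
  s
}

#' Keep only locally dominant fragment peaks
#'
#' A peak is retained iff it ranks within the `top_n` most intense peaks in
#' the `window_da`-wide window centered on itself (sliding windows, not
#' fixed bins, so the result has no bin-boundary artifacts). Intensity ties
#' rank the lower-m/z peak first.
#'
#' @param s An `ms_spectrum`.
#' @param top_n Peaks to keep per window (default 6).
#' @param window_da Window width in Da (default 50).
#' @return The filtered spectrum, flagged `window_topn_applied`.
#' @export
filter_window_top_n <- function(s, top_n = 6, window_da = 50) {
  pk <- s$peaks
  n <- nrow(pk)
  if (n > top_n) {
    mz <- pk[, "mz"]
    it <- pk[, "intensity"]
    half <- window_da / 2
    keep <- logical(n)
    for (i in seq_len(n)) {
      inwin <- which(abs(mz - mz[i]) <= half)
      # rank of peak i among window members: ties broken toward lower m/z
      better <- it[inwin] > it[i] | (it[inwin] == it[i] & mz[inwin] < mz[i])
      keep[i] <- sum(better) < top_n
    }
    s$peaks <- pk[keep, , drop = FALSE]
  }
  s$window_topn_applied <- TRUE
  s
}

#' Cosine similarity between two fragment spectra
#'
#' Computes the (modified) cosine score used throughout molecular
#' networking. Intensities are square-root transformed (`transform =
#' "sqrt"`, the networking convention; `"none"` disables it). Candidate
#' fragment pairs are those within `frag_tol_da` of each other directly,
#' plus — when `shifted = TRUE` — pairs offset by the precursor mass
#' difference, which links structural analogs differing by one modification.
#' The score is defined by the maximum-weight one-to-one matching over
#' candidate pairs (weight = product of transformed intensities), normalized
#' by the two spectra's transformed Euclidean norms. The matching is solved
#' exactly (branch-and-bound) up to `exact_limit` candidate pairs and by
#' descending-weight greedy above that.
#'
#' @param a,b MS2 `ms_spectrum` objects (already filtered).
#' @param frag_tol_da Fragment m/z tolerance in Da (default 0.02).
#' @param shifted Also match precursor-delta-shifted pairs (modified cosine).
#' @param transform `"sqrt"` (default) or `"none"`.
#' @param exact_limit Candidate-pair count up to which the assignment is
#'   solved exactly (default 64, which covers every pair of spectra with up
#'   to 8 peaks each).
#' @return A list with `cosine` (in [0, 1]) and `n_matched`.
#' @export
cosine_score <- function(a, b, frag_tol_da = 0.02, shifted = FALSE,
                         transform = c("sqrt", "none"), exact_limit = 64L) {
  transform <- match.arg(transform)
  pa <- a$peaks
  pb <- b$peaks
  if (!nrow(pa) || !nrow(pb)) return(list(cosine = 0, n_matched = 0L))
  ia <- if (transform == "sqrt") sqrt(pa[, "intensity"]) else pa[, "intensity"]
  ib <- if (transform == "sqrt") sqrt(pb[, "intensity"]) else pb[, "intensity"]
  norm <- sqrt(sum(ia^2)) * sqrt(sum(ib^2))
  if (norm == 0) return(list(cosine = 0, n_matched = 0L))
  shift <- if (shifted) {
    if (is.na(a$precursor_mz) || is.na(b$precursor_mz)) {
      stop("shifted cosine requires precursor m/z on both spectra",
           call. = FALSE)
    }
    a$precursor_mz - b$precursor_mz
  } else NA_real_
  pairs <- candidate_pairs(pa[, "mz"], pb[, "mz"], frag_tol_da, shift)
  if (!nrow(pairs)) return(list(cosine = 0, n_matched = 0L))
  w <- ia[pairs[, 1]] * ib[pairs[, 2]]
  sol <- max_weight_matching(pairs, w, exact_limit)
  list(cosine = min(1, sol$weight / norm), n_matched = sol$n)
}

# All (i, j) with |mz_a[i]-mz_b[j]| <= tol, plus shifted pairs when shift
# is set. Duplicates (a pair matching both ways) are collapsed.
candidate_pairs <- function(mza, mzb, tol, shift = NA_real_) {
  direct <- outer(mza, mzb, function(x, y) abs(x - y) <= tol)
  hits <- which(direct, arr.ind = TRUE)
  if (!is.na(shift) && shift != 0) {
    sh <- outer(mza, mzb, function(x, y) abs((x - y) - shift) <= tol)
    hits <- rbind(hits, which(sh & !direct, arr.ind = TRUE))
  }
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  hits
}

# Maximum-weight one-to-one matching over candidate pairs.
# Exact branch-and-bound up to exact_limit pairs; greedy beyond. On exact
# solves, ties between equal-weight matchings resolve to the one found first
# in descending-weight order, which is deterministic.
max_weight_matching <- function(pairs, w, exact_limit = 64L) {
  ord <- order(-w, pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  w <- w[ord]
  np <- length(w)
  if (np == 0L) return(list(weight = 0, n = 0L))
  if (np > exact_limit) return(greedy_matching(pairs, w))
  suffix <- rev(cumsum(rev(w)))
  best <- new.env(parent = emptyenv())
  best$weight <- -1
  best$n <- 0L
  recurse <- function(i, used_a, used_b, acc, n_acc) {
    if (i > np || acc + suffix[i] <= best$weight) {
      if (acc > best$weight) {
        best$weight <- acc
        best$n <- n_acc
      }
      return(invisible())
    }
    ai <- pairs[i, 1]
    bi <- pairs[i, 2]
    if (!(ai %in% used_a) && !(bi %in% used_b)) {
      recurse(i + 1L, c(used_a, ai), c(used_b, bi), acc + w[i], n_acc + 1L)
    }
    recurse(i + 1L, used_a, used_b, acc, n_acc)
    invisible()
  }
  recurse(1L, integer(0), integer(0), 0, 0L)
  list(weight = best$weight, n = best$n)
}

greedy_matching <- function(pairs, w) {
  used_a <- logical(max(pairs[, 1]))
  used_b <- logical(max(pairs[, 2]))
  total <- 0
  n <- 0L
  for (i in seq_along(w)) {
    ai <- pairs[i, 1]
    bi <- pairs[i, 2]
    if (!used_a[ai] && !used_b[bi]) {
      used_a[ai] <- TRUE
      used_b[bi] <- TRUE
      total <- total + w[i]
      n <- n + 1L
    }
  }
  list(weight = total, n = n)
}
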