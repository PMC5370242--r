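#' Write an 'ili intensity table
#'
#' Serializes a per-spot intensity table to the CSV layout the 'ili browser
#' viewer consumes next to the STL model: header `name,X,Y,Z,radius` followed
#' by one column per feature. Numbers are written at full double precision
#' (`%.17g`, trailing representation trimmed by R's `format`), with "."
#' decimal marks, RFC-4180 quoting and LF line endings, so rewriting the
#' same table is byte-identical.
#'
#' @param table An `ili_table` tibble from [build_eim_table()], or any data
#'   frame whose first five columns are `name, x, y, z, radius` followed by
#'   feature columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ili_table <- function(table, path) {
  df <- as.data.frame(table)
  if (ncol(df) < 5L) stop("ili table needs name,x,y,z,radius columns",
                          call. = FALSE)
  if (anyDuplicated(df[[1]])) {
    stop("duplicate sample names in ili table: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df[, 2:5])) {
    stop("every ili row must carry coordinates and a radius", call. = FALSE)
  }
  # missing intensities render as 0; 'ili maps numeric columns only
  feat <- df[, -(1:5), drop = FALSE]
  feat[is.na(feat)] <- 0
  df[, -(1:5)] <- feat
  names(df)[1:5] <- c("name", "X", "Y", "Z", "radius")
  write_csv_lf(df, path)
  invisible(path)
}

#' Read an 'ili intensity table
#'
#' Inverse of [write_ili_table()]; used for round-trip checks and for
#' resuming a pipeline from exported artifacts.
#'
#' @param path CSV path.
#' @return A tibble of class `ili_table`.
#' @export
read_ili_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 5L || !identical(names(df)[1:5], c("name", "X", "Y", "Z", "radius"))) {
    stop("'", path, "' is not an ili intensity table (expected ",
         "name,X,Y,Z,radius header)", call. = FALSE)
  }
  names(df)[1:5] <- c("name", "x", "y", "z", "radius")
  out <- tibble::as_tibble(df)
  class(out) <- c("ili_table", class(out))
  out
}

# Deterministic RFC-4180 CSV: comma separator, "." decimal, LF endings,
# quotes only where needed, full double precision. Field order and row order
# are the caller's; no hash ordering is involved anywhere.
write_csv_lf <- function(df, path) {
  fmt_cell <- function(x) {
    if (is.numeric(x)) {
      out <- vapply(x, function(v) {
        if (is.na(v)) return("")
        if (is.finite(v) && v == round(v) && abs(v) < 1e15) {
          sprintf("%.0f", v)
        } else {
          sprintf("%.17g", v)
        }
      }, character(1))
      return(out)
    }
    x <- as.character(x)
    x[is.na(x)] <- ""
    needs <- grepl('[",\n\r]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
  }
  cols <- lapply(df, fmt_cell)
  header <- paste(fmt_cell(names(df)), collapse = ",")
  body <- do.call(paste, c(cols, sep = ","))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
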