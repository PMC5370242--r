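#' Read or validate a sample metadata table
#'
#' Metadata joins each LC-MS run to its biological context: which plant and
#' tissue the extract came from, whether it is a solvent/system blank, and
#' the 3D coordinates (mesh model units) plus spot radius used for ion-map
#' rendering. Blanks may omit coordinates; non-blank samples must carry them.
#'
#' @param x Path to a CSV file with columns
#'   `sample_id, plant, tissue, is_blank, x, y, z, radius`, or a data frame
#'   with those columns.
#' @param mesh Optional `ms_mesh`; when given, non-blank coordinates are
#'   checked to lie inside the mesh bounding box expanded by one spot radius.
#' @return A validated tibble of class `sample_metadata`.
#' @export
read_sample_metadata <- function(x, mesh = NULL) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("no such file: ", x, call. = FALSE)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  md <- tibble::as_tibble(x)
  required <- c("sample_id", "plant", "tissue", "is_blank",
                "x", "y", "z", "radius")
  missing <- setdiff(required, names(md))
  if (length(missing)) {
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  md$sample_id <- as.character(md$sample_id)
  md$is_blank <- as.logical(md$is_blank)
  if (anyNA(md$is_blank)) stop("is_blank must be TRUE/FALSE", call. = FALSE)
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  nb <- !md$is_blank
  coords <- as.matrix(md[, c("x", "y", "z")])
  if (any(nb & (is.na(coords[, 1]) | is.na(coords[, 2]) | is.na(coords[, 3])))) {
    stop("non-blank samples must carry x/y/z coordinates", call. = FALSE)
  }
  if (any(nb & (is.na(md$radius) | md$radius <= 0))) {
    stop("non-blank samples must carry a positive spot radius", call. = FALSE)
  }
  if (!is.null(mesh)) {
    bad <- check_coords_in_mesh(md, mesh)
    if (length(bad)) {
      stop("sample(s) outside the mesh bounding box (+radius): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  class(md) <- c("sample_metadata", class(md))
  md
}

# Returns sample_ids of non-blank samples whose spot lies outside bbox+radius.
check_coords_in_mesh <- function(md, mesh) {
  bb <- mesh_bbox(mesh)
  nb <- md[!md$is_blank, , drop = FALSE]
  if (!nrow(nb)) return(character(0))
  lo <- sweep(-as.matrix(nb[, c("x", "y", "z")]), 2, bb[1, ], `+`) # lo - x
  hi <- sweep(as.matrix(nb[, c("x", "y", "z")]), 2, bb[2, ], `-`)  # x - hi
  out <- pmax(apply(lo, 1, max), apply(hi, 1, max)) > nb$radius
  nb$sample_id[out]
}

#' Write a sample metadata table to CSV
#' @param metadata A `sample_metadata` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  write_csv_lf(as.data.frame(metadata)[, c("sample_id", "plant", "tissue",
                                           "is_blank", "x", "y", "z", "radius")],
               path)
  invisible(path)
}
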