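#' Construct a triangle-surface mesh
#'
#' Holds the scanned 3D surface model the ion maps are painted onto.
#' Vertices are in model units; the sampling-spot coordinates in the sample
#' metadata are assumed to be in the same units.
#'
#' @param vertices Numeric matrix, n x 3 (x, y, z).
#' @param faces Integer matrix, m x 3 of 1-based vertex indices.
#' @return An object of class `ms_mesh`.
#' @export
new_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  if (ncol(vertices) != 3L) stop("vertices must be n x 3", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must be m x 3", call. = FALSE)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  if (nrow(faces) == 0L) stop("mesh has no faces", call. = FALSE)
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  bb <- apply(vertices, 2, range)
  if (any(bb[2, ] - bb[1, ] <= 0)) {
    stop("mesh bounding box has zero extent in at least one axis",
         call. = FALSE)
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "ms_mesh")
}

#' @export
print.ms_mesh <- function(x, ...) {
  bb <- mesh_bbox(x)
  cat(sprintf("<ms_mesh> %d vertices, %d faces; bbox [%.3g,%.3g]x[%.3g,%.3g]x[%.3g,%.3g]\n",
              nrow(x$vertices), nrow(x$faces),
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Bounding box of a mesh
#' @param mesh An `ms_mesh`.
#' @return A 2 x 3 matrix: rows are min and max, columns x, y, z.
#' @export
mesh_bbox <- function(mesh) {
  bb <- apply(mesh$vertices, 2, range)
  rownames(bb) <- c("min", "max")
  bb
}

#' Read a surface mesh from an STL file
#'
#' Accepts binary and ASCII STL. Vertices repeated across facets are
#' de-duplicated by exact coordinate equality (the mesh is consumed as-is by
#' 'ili; no geometry repair is attempted); the triangle count is preserved.
#'
#' @param path Path to an `.stl` file.
#' @return An `ms_mesh`.
#' @export
read_mesh_stl <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tris <- if (is_ascii_stl(path)) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(tris) == 0L) stop("STL file '", path, "' contains no facets",
                             call. = FALSE)
  # tris: 3n x 3 matrix of vertices, consecutive triples are triangles
  key <- paste(tris[, 1], tris[, 2], tris[, 3], sep = "|")
  idx <- match(key, unique(key))
  vertices <- tris[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  new_mesh(vertices, faces)
}

# Binary STL has an 80-byte header then a uint32 facet count; an ASCII file
# starts with "solid" AND actually contains "facet" keywords (some binary
# exporters also write "solid" into the header, so check both).
is_ascii_stl <- function(path) {
  head <- readBin(path, "raw", n = 512L)
  printable <- head[(head >= as.raw(32) & head <= as.raw(126)) |
                      head %in% as.raw(c(9L, 10L, 13L))]
  txt <- rawToChar(printable)
  all_text <- length(printable) == sum(head != as.raw(0))
  grepl("^[ \t\r\n]*solid", txt, useBytes = TRUE) &&
    (grepl("facet", txt, fixed = TRUE, useBytes = TRUE) ||
       (all_text && grepl("endsolid", txt, useBytes = TRUE)))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3L != 0L) {
    stop("malformed ASCII STL '", path, "': vertex count not a multiple of 3",
         call. = FALSE)
  }
  if (!length(vl)) return(matrix(numeric(0), ncol = 3L))
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"), function(f) {
    v <- suppressWarnings(as.numeric(f[2:4]))
    if (anyNA(v)) stop("malformed ASCII STL vertex line", call. = FALSE)
    v
  }, numeric(3)))
  nums
}

read_stl_binary <- function(path) {
  size <- file.info(path)$size
  if (size < 84) stop("truncated binary STL '", path, "'", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  expected <- 84 + n * 50
  if (size < expected) {
    stop("truncated binary STL '", path, "': header declares ", n,
         " facets but file is too short", call. = FALSE)
  }
  body <- readBin(con, "raw", n = n * 50L)
  dim(body) <- c(50L, n)
  # per facet: 12 float32 (normal + 3 vertices) + uint16 attribute
  floats <- readBin(as.vector(body[1:48, ]), "numeric", n = 12L * n,
                    size = 4L, endian = "little")
  m <- matrix(floats, nrow = 12L)  # columns are facets
  verts <- m[4:12, , drop = FALSE] # drop the normal
  matrix(as.vector(verts), ncol = 3L, byrow = TRUE)
}

#' Write a mesh as ASCII STL
#'
#' Used mainly by the synthetic-plant generator to emit fixture meshes;
#' output is plain text and deterministic.
#'
#' @param mesh An `ms_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")  # binary connection for LF-only line endings
  on.exit(close(con))
  out <- character(2L + 7L * nrow(f))
  out[1] <- "solid mscarto"
  pos <- 2L
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    nrm <- facet_normal(tri)
    out[pos] <- sprintf("  facet normal %.9g %.9g %.9g", nrm[1], nrm[2], nrm[3])
    out[pos + 1L] <- "    outer loop"
    out[pos + 2:4] <- sprintf("      vertex %.9g %.9g %.9g",
                              tri[, 1], tri[, 2], tri[, 3])
    out[pos + 5L] <- "    endloop"
    out[pos + 6L] <- "  endfacet"
    pos <- pos + 7L
  }
  out[pos] <- "endsolid mscarto"
  writeLines(out, con, sep = "\n")
  invisible(path)
}

facet_normal <- function(tri) {
  u <- tri[2, ] - tri[1, ]
  w <- tri[3, ] - tri[1, ]
  n <- c(u[2] * w[3] - u[3] * w[2],
         u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  len <- sqrt(sum(n^2))
  if (len > 0) n / len else c(0, 0, 1)
}

#' Write a mesh as binary STL
#'
#' Provided for dialect-parity testing of [read_mesh_stl()].
#'
#' @param mesh An `ms_mesh`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "mscarto binary stl"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    nrm <- facet_normal(tri)
    writeBin(as.numeric(c(nrm, t(tri))), con, size = 4L, endian = "little")
    writeBin(as.integer(0), con, size = 2L, endian = "little")
  }
  invisible(path)
}
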