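#' Read an STL surface file
#'
#' Reads binary or ASCII STL (auto-detected) into an indexed [trimesh()].
#' STL stores a triangle soup; duplicate vertices within 1e-6 mm are merged
#' to recover shared topology. Facet normals stored in the file are
#' discarded; orientation is taken from the vertex winding. Coordinates are
#' taken to be millimetres by contract (STL carries no units).
#'
#' @param path file location.
#' @param name label for the resulting mesh; defaults to the file name.
#' @return a validated [trimesh()].
#' @export
read_stl <- function(path, name = NULL) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  if (is.null(name)) name <- sub("\\.[sS][tT][lL]$", "", basename(path))
  tri <- if (stl_is_binary(path)) read_stl_binary(path)
         else read_stl_ascii(path)
  soup_to_trimesh(tri, name)
}

# Binary STL: 80-byte header, uint32 facet count, then per facet
# 12 little-endian float32 (normal + 3 vertices) + uint16 attribute.
stl_is_binary <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(size, 84L))
  if (length(head) >= 84L) {
    n <- readBin(head[81:84], "integer", size = 4L, endian = "little")
    if (!is.na(n) && n >= 0 && size == 84 + 50 * as.numeric(n)) return(TRUE)
  }
  !identical(rawToChar(head[1:min(5L, length(head))]), "solid")
}

read_stl_binary <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  if (size < 84) stop("truncated binary STL '", path, "': only ", size,
                      " bytes, header needs 84")
  readBin(con, "raw", n = 80L)
  n <- readBin(con, "integer", size = 4L, endian = "little")
  expect <- 84 + 50 * as.numeric(n)
  if (size < expect)
    stop("truncated binary STL '", path, "': ", n, " facets declared need ",
         expect, " bytes, file ends at byte ", size)
  raw <- readBin(con, "raw", n = 50L * n)
  idx <- rep(seq(0L, by = 50L, length.out = n), each = 48L) +
         rep(1:48, times = n)
  floats <- readBin(raw[idx], "numeric", size = 4L, n = 12L * n,
                    endian = "little")
  m <- matrix(floats, ncol = 12L, byrow = TRUE)
  # columns 4:12 are the three vertices; 1:3 the stored normal (discarded)
  v <- matrix(t(m[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  v
}

read_stl_ascii <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE)
  at <- which(toks == "vertex")
  if (length(at) == 0L || length(at) %% 3L != 0L)
    stop("malformed ASCII STL '", path, "': found ", length(at),
         " vertex records (need a positive multiple of 3)")
  xyz <- suppressWarnings(
    matrix(as.numeric(toks[rep(at, each = 3L) + 1:3]), ncol = 3L,
           byrow = TRUE))
  if (anyNA(xyz))
    stop("malformed ASCII STL '", path, "': non-numeric vertex coordinates")
  xyz
}

# triangle soup (3 consecutive rows per facet) -> merged indexed mesh
soup_to_trimesh <- function(soup, name, tol = 1e-6) {
  key <- paste(round(soup[, 1] / tol), round(soup[, 2] / tol),
               round(soup[, 3] / tol))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  verts <- soup[first, , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  trimesh(verts, faces, name = name)
}

#' Write a mesh to an STL file
#'
#' @param mesh a valid [trimesh()].
#' @param path destination file.
#' @param dialect `"binary"` (compact; coordinates stored as 32-bit floats)
#'   or `"ascii"` (full double precision; exact round trip).
#' @return `path`, invisibly.
#' @details Facet normals are recomputed from the winding. Note the binary
#'   dialect is defined on 32-bit floats, so round-tripping coordinates of
#'   magnitude ~100 mm is exact only to about 1e-5 mm (one float ULP); the
#'   ASCII dialect is written with 17 significant digits and round-trips
#'   exactly up to the 1e-6 mm vertex merge.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  validate_trimesh(mesh)
  co <- face_corners(mesh)
  nrm <- cross3(co$b - co$a, co$c - co$a)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  n <- nrow(mesh$faces)
  if (dialect == "ascii") {
    lines <- c(paste("solid", mesh$name),
               sprintf(paste0("facet normal %.17g %.17g %.17g\n",
                              " outer loop\n",
                              "  vertex %.17g %.17g %.17g\n",
                              "  vertex %.17g %.17g %.17g\n",
                              "  vertex %.17g %.17g %.17g\n",
                              " endloop\nendfacet"),
                       nrm[, 1], nrm[, 2], nrm[, 3],
                       co$a[, 1], co$a[, 2], co$a[, 3],
                       co$b[, 1], co$b[, 2], co$b[, 3],
                       co$c[, 1], co$c[, 2], co$c[, 3]),
               paste("endsolid", mesh$name))
    con <- tryCatch(file(path, "w"),
                    error = function(e) stop("cannot write '", path, "': ",
                                             conditionMessage(e)))
    on.exit(close(con))
    writeLines(lines, con)
  } else {
    con <- tryCatch(file(path, "wb"),
                    error = function(e) stop("cannot write '", path, "': ",
                                             conditionMessage(e)))
    on.exit(close(con))
    header <- charToRaw(formatC(paste("centroidtrack", mesh$name),
                                width = -80))
    writeBin(header[1:80], con)
    writeBin(as.integer(n), con, size = 4L, endian = "little")
    per_facet <- cbind(nrm, co$a, co$b, co$c)  # n x 12
    floats <- writeBin(as.numeric(t(per_facet)), raw(), size = 4L,
                       endian = "little")
    fm <- matrix(floats, ncol = 48L, byrow = TRUE)
    attr_bytes <- matrix(as.raw(0L), nrow = n, ncol = 2L)
    writeBin(as.vector(t(cbind(fm, attr_bytes))), con)
  }
  invisible(path)
}
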