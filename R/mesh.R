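#' Indexed triangle mesh
#'
#' Constructs a validated indexed triangle surface. All coordinates are in
#' millimetres. The mesh is the object every stage of the displacement
#' pipeline consumes and produces: region-of-interest surfaces segmented at
#' two time points, their coarse spatial-reference counterparts, and the
#' synthetic study meshes.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates (mm).
#' @param faces integer matrix, m x 3, 1-based vertex indices with
#'   counter-clockwise winding defining the outward normal.
#' @param name text label carried through reports
#'   (e.g. `"maxilla_t0_accurate"`).
#' @return an object of class `trimesh` with elements `vertices`, `faces`,
#'   `name`.
#' @details Validity requires: at least 4 vertices and 4 faces, all face
#'   indices in range, no face with a repeated vertex, and every face area
#'   above the degeneracy floor of 1e-12 mm^2.
#' @export
trimesh <- function(vertices, faces, name = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  mesh <- structure(list(vertices = vertices, faces = faces,
                         name = as.character(name)[1]),
                    class = "trimesh")
  validate_trimesh(mesh)
  mesh
}

#' Validate a triangle mesh
#'
#' Checks the `trimesh` invariants and stops with an informative error when
#' one fails. Returns the mesh invisibly so it can be used in pipelines.
#'
#' @param mesh a `trimesh`.
#' @return the mesh, invisibly.
#' @export
validate_trimesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!is.matrix(v) || ncol(v) != 3L)
    stop("vertices must be an n x 3 matrix")
  if (!is.matrix(f) || ncol(f) != 3L)
    stop("faces must be an m x 3 matrix")
  if (anyNA(v) || any(!is.finite(v)))
    stop("vertices contain non-finite coordinates")
  if (nrow(v) < 4L)
    stop("mesh must have at least 4 vertices, got ", nrow(v))
  if (nrow(f) < 4L)
    stop("mesh must have at least 4 faces, got ", nrow(f))
  if (anyNA(f) || any(f < 1L) || any(f > nrow(v)))
    stop("face indices out of range [1, ", nrow(v), "]")
  rep_v <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  if (any(rep_v))
    stop("faces with repeated vertices: ",
         paste(utils::head(which(rep_v), 5L), collapse = ", "))
  ar <- face_areas(mesh)
  degen <- ar <= 1e-12
  if (any(degen))
    stop("degenerate (zero-area) faces below 1e-12 mm^2: ",
         paste(utils::head(which(degen), 5L), collapse = ", "))
  invisible(mesh)
}

#' @export
print.trimesh <- function(x, ...) {
  bb <- bbox(x)
  cat(sprintf("trimesh '%s': %d vertices, %d faces\n", x$name,
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# per-face corner coordinate matrices (m x 3 each), internal
face_corners <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  list(a = v[f[, 1], , drop = FALSE],
       b = v[f[, 2], , drop = FALSE],
       c = v[f[, 3], , drop = FALSE])
}

cross3 <- function(u, w) {
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

#' Per-face areas of a mesh
#'
#' @param mesh a `trimesh`.
#' @return numeric vector of face areas (mm^2).
#' @export
face_areas <- function(mesh) {
  co <- face_corners(mesh)
  cr <- cross3(co$b - co$a, co$c - co$a)
  0.5 * sqrt(rowSums(cr^2))
}

bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2, min),
        max = apply(mesh$vertices, 2, max))
}

#' Surface centroid of a mesh
#'
#' The single 3D point used to summarise a region of interest's spatial
#' position; displacements are differences of these points between time
#' points. Three definitions are offered:
#'
#' * `area_weighted_surface` (default): sum over faces of area times face
#'   barycenter, divided by total area. Invariant to retriangulation of the
#'   same surface, which makes it robust to differing mesh densities.
#' * `vertex_mean`: plain mean of the unique vertices. Sensitive to sampling
#'   density; offered for sensitivity analysis.
#' * `enclosed_volume`: centroid of the enclosed solid via the divergence
#'   theorem; requires a watertight mesh.
#'
#' @param mesh a `trimesh`.
#' @param method one of `"area_weighted_surface"`, `"vertex_mean"`,
#'   `"enclosed_volume"`.
#' @return an object of class `centroid`: list with `point` (xyz, mm),
#'   `method` and `source_mesh`.
#' @export
surface_centroid <- function(mesh, method = c("area_weighted_surface",
                                              "vertex_mean",
                                              "enclosed_volume")) {
  method <- match.arg(method)
  validate_trimesh(mesh)
  if (method == "area_weighted_surface") {
    ar <- face_areas(mesh)
    total <- sum(ar)
    if (total <= 1e-12) stop("degenerate mesh: total area below floor")
    co <- face_corners(mesh)
    bary <- (co$a + co$b + co$c) / 3
    point <- colSums(bary * ar) / total
  } else if (method == "vertex_mean") {
    point <- colMeans(unique(mesh$vertices))
  } else {
    if (!is_watertight(mesh))
      stop("enclosed_volume centroid requires a closed (watertight) mesh")
    co <- face_corners(mesh)
    # signed tetrahedron decomposition about the origin:
    # V_f = det(a,b,c)/6 ; tet centroid = (a+b+c+0)/4
    svol <- rowSums(co$a * cross3(co$b, co$c)) / 6
    vol <- sum(svol)
    if (abs(vol) <= 1e-12) stop("degenerate mesh: enclosed volume ~ 0")
    point <- colSums(((co$a + co$b + co$c) / 4) * svol) / vol
  }
  names(point) <- c("x", "y", "z")
  structure(list(point = point, method = method, source_mesh = mesh$name),
            class = "centroid")
}

#' @export
print.centroid <- function(x, ...) {
  cat(sprintf("centroid of '%s' (%s): (%.4f, %.4f, %.4f) mm\n",
              x$source_mesh, x$method, x$point[1], x$point[2], x$point[3]))
  invisible(x)
}

# undirected unique edge index pairs, internal
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Is a mesh watertight?
#'
#' A mesh is watertight (closed and consistently oriented) when every
#' directed half-edge appears exactly once and is matched by its reverse:
#' each undirected edge is then shared by exactly two faces of opposite
#' winding, the condition under which the enclosed-volume centroid is
#' well defined.
#'
#' @param mesh a `trimesh`.
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  fwd <- c(paste(f[, 1], f[, 2]), paste(f[, 2], f[, 3]),
           paste(f[, 3], f[, 1]))
  rev <- c(paste(f[, 2], f[, 1]), paste(f[, 3], f[, 2]),
           paste(f[, 1], f[, 3]))
  !anyDuplicated(fwd) && all(fwd %in% rev)
}

# Make face windings consistent across shared edges (breadth-first flood
# over face adjacency), then flip globally so the enclosed signed volume is
# positive (outward normals). Internal; used by the procedural generators.
orient_faces <- function(vertices, faces) {
  m <- nrow(faces)
  ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  keys <- c(ekey(faces[, 1], faces[, 2]), ekey(faces[, 2], faces[, 3]),
            ekey(faces[, 3], faces[, 1]))
  adj <- split(rep(seq_len(m), 3L), keys)
  flipped <- logical(m)
  visited <- logical(m)
  dir_edges <- function(f) {
    tri <- faces[f, ]
    if (flipped[f]) tri <- tri[c(1, 3, 2)]
    cbind(tri, tri[c(2, 3, 1)])
  }
  queue <- integer(m)
  queue[1] <- 1L
  head <- 1L
  tail <- 1L
  visited[1] <- TRUE
  while (head <= tail) {
    f <- queue[head]
    head <- head + 1L
    de <- dir_edges(f)
    for (r in 1:3) {
      for (g in adj[[ekey(de[r, 1], de[r, 2])]]) {
        if (g == f || visited[g]) next
        dg <- dir_edges(g)
        has_rev <- any(dg[, 1] == de[r, 2] & dg[, 2] == de[r, 1])
        if (!has_rev) flipped[g] <- TRUE
        visited[g] <- TRUE
        tail <- tail + 1L
        queue[tail] <- g
      }
    }
  }
  faces[flipped, ] <- faces[flipped, c(1, 3, 2)]
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  if (sum(rowSums(a * cross3(b, cc))) < 0) faces <- faces[, c(3, 2, 1)]
  faces
}

#' Mesh quality metrics
#'
#' Summaries used to judge whether two meshes are comparable enough for
#' centroid tracking: comparably dense, evenly triangulated, and covering the
#' same spatial extent.
#'
#' @param mesh a `trimesh`.
#' @return object of class `mesh_quality`: `n_vertices`, `n_faces`,
#'   `total_area` (mm^2), `edge_length_cv` (SD/mean of unique undirected edge
#'   lengths), `bbox_min`, `bbox_max` (mm).
#' @export
mesh_quality <- function(mesh) {
  validate_trimesh(mesh)
  e <- mesh_edges(mesh)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  bb <- bbox(mesh)
  structure(list(n_vertices = nrow(mesh$vertices),
                 n_faces = nrow(mesh$faces),
                 total_area = sum(face_areas(mesh)),
                 edge_length_cv = stats::sd(len) / mean(len),
                 bbox_min = unname(bb[1, ]),
                 bbox_max = unname(bb[2, ])),
            class = "mesh_quality")
}

#' @export
print.mesh_quality <- function(x, ...) {
  cat(sprintf(paste0("mesh quality: %d vertices, %d faces, area %.2f mm^2,",
                     " edge-length CV %.3f\n"),
              x$n_vertices, x$n_faces, x$total_area, x$edge_length_cv))
  invisible(x)
}

#' Comparability policy for centroid tracking
#'
#' Thresholds for [check_comparability()]. Centroid tracking is only
#' meaningful when the two time-point meshes were cropped with the same
#' boundaries and triangulated at similar density; these rules catch
#' decimation and cropping mismatches while tolerating independent
#' segmentations of the same region.
#'
#' @param max_face_ratio_dev maximum relative deviation of the face-count
#'   ratio from 1 (default 0.10).
#' @param max_area_ratio_dev maximum relative deviation of the total-area
#'   ratio from 1 (default 0.10).
#' @param max_extent_diff_mm maximum per-axis difference of the
#'   centroid-centered bounding-box extents (default 2.0 mm).
#' @param max_edge_cv maximum edge-length coefficient of variation for either
#'   mesh (default 0.6).
#' @return a list of class `comparability_policy`.
#' @export
comparability_policy <- function(max_face_ratio_dev = 0.10,
                                 max_area_ratio_dev = 0.10,
                                 max_extent_diff_mm = 2.0,
                                 max_edge_cv = 0.6) {
  structure(list(max_face_ratio_dev = max_face_ratio_dev,
                 max_area_ratio_dev = max_area_ratio_dev,
                 max_extent_diff_mm = max_extent_diff_mm,
                 max_edge_cv = max_edge_cv),
            class = "comparability_policy")
}

#' Check whether two meshes are comparable for centroid tracking
#'
#' Verifies, rule by rule, that two region-of-interest meshes can be compared
#' through their centroids: (1) similar face counts, (2) similar total area,
#' (3) matching bounding-box extents after centering each mesh on its own
#' centroid (same crop boundaries), (4) even triangulation (low edge-length
#' CV) in both. Failures are reported, never raised.
#'
#' @param a,b `trimesh` objects.
#' @param policy a [comparability_policy()].
#' @return object of class `comparability_report`: per-rule verdicts with the
#'   measured values, and `pass` = all rules passed.
#' @export
check_comparability <- function(a, b, policy = comparability_policy()) {
  qa <- mesh_quality(a)
  qb <- mesh_quality(b)
  face_ratio <- qa$n_faces / qb$n_faces
  area_ratio <- qa$total_area / qb$total_area
  ca <- surface_centroid(a)$point
  cb <- surface_centroid(b)$point
  ext_a <- qa$bbox_max - qa$bbox_min
  ext_b <- qb$bbox_max - qb$bbox_min
  # extents are translation invariant; centering documents that only the
  # shape of the crop is compared, not its position
  extent_diff <- abs(ext_a - ext_b)
  rules <- list(
    face_count = list(
      value = face_ratio,
      pass = abs(face_ratio - 1) <= policy$max_face_ratio_dev),
    total_area = list(
      value = area_ratio,
      pass = abs(area_ratio - 1) <= policy$max_area_ratio_dev),
    bbox_extents = list(
      value = extent_diff,
      pass = all(extent_diff <= policy$max_extent_diff_mm)),
    edge_length_cv = list(
      value = c(qa$edge_length_cv, qb$edge_length_cv),
      pass = qa$edge_length_cv <= policy$max_edge_cv &&
             qb$edge_length_cv <= policy$max_edge_cv)
  )
  structure(list(rules = rules,
                 pass = all(vapply(rules, `[[`, logical(1), "pass")),
                 policy = policy,
                 meshes = c(a$name, b$name),
                 centroid_a = ca, centroid_b = cb),
            class = "comparability_report")
}

#' @export
print.comparability_report <- function(x, ...) {
  cat(sprintf("comparability of '%s' vs '%s': %s\n", x$meshes[1],
              x$meshes[2], if (x$pass) "PASS" else "FAIL"))
  for (nm in names(x$rules)) {
    r <- x$rules[[nm]]
    cat(sprintf("  %-14s %s  (%s)\n", nm,
                if (r$pass) "pass" else "FAIL",
                paste(signif(r$value, 4), collapse = ", ")))
  }
  invisible(x)
}

#' Midpoint (1-to-4) subdivision of a mesh
#'
#' Splits every face into four by inserting edge midpoints. The surface is
#' preserved pointwise, so the area-weighted surface centroid is unchanged;
#' used mainly to test that property and to refine synthetic meshes.
#'
#' @param mesh a `trimesh`.
#' @return the subdivided `trimesh` (4x the faces).
#' @export
subdivide_midpoint <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  mid <- (v[e[, 1], , drop = FALSE] + v[e[, 2], , drop = FALSE]) / 2
  mid_idx <- stats::setNames(nrow(v) + seq_len(nrow(e)), key)
  ek <- function(i, j) paste(pmin(i, j), pmax(i, j))
  m12 <- mid_idx[ek(f[, 1], f[, 2])]
  m23 <- mid_idx[ek(f[, 2], f[, 3])]
  m13 <- mid_idx[ek(f[, 1], f[, 3])]
  newf <- rbind(cbind(f[, 1], m12, m13),
                cbind(m12, f[, 2], m23),
                cbind(m13, m23, f[, 3]),
                cbind(m12, m23, m13))
  trimesh(rbind(v, mid), unname(newf), name = mesh$name)
}
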