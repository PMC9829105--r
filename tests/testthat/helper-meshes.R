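# Small fixture meshes built in code.

# closed unit cube [0,1]^3, 8 vertices, 12 outward-wound faces
unit_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0
    c(5, 6, 7), c(6, 8, 7),  # z = 1
    c(1, 2, 5), c(2, 6, 5),  # y = 0
    c(3, 7, 4), c(4, 7, 8),  # y = 1
    c(1, 5, 3), c(3, 5, 7),  # x = 0
    c(2, 4, 6), c(4, 8, 6))  # x = 1
  trimesh(v, f, name = "unit_cube")
}

# regular tetrahedron-like simplex with vertices at origin and unit axes
unit_tetra <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  trimesh(v, f, name = "unit_tetra")
}

# regular octahedron: all 12 edges have length sqrt(2)
octahedron <- function() {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  trimesh(v, f, name = "octahedron")
}

# planar unit square at height z, fanned into 4 triangles about its center
square_plate <- function(z = 0, size = 1) {
  s <- size
  v <- rbind(c(0, 0, z), c(s, 0, z), c(s, s, z), c(0, s, z),
             c(s / 2, s / 2, z))
  f <- rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5))
  trimesh(v, f, name = sprintf("plate_z%g", z))
}

# the triangle (0,0,0),(1,0,0),(0,1,0) split into 4 coplanar sub-triangles
# (a single triangle is below the 4-face validity floor)
unit_triangle_patch <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(0.5, 0, 0), c(0.5, 0.5, 0), c(0, 0.5, 0))
  f <- rbind(c(1, 4, 6), c(4, 2, 5), c(6, 5, 3), c(4, 5, 6))
  trimesh(v, f, name = "unit_triangle_patch")
}

# UV-sphere triangulation of radius r (rotationally symmetric fixture)
uv_sphere <- function(r = 25, n_lat = 14) {
  n_lon <- 2L * n_lat
  lat <- seq_len(n_lat - 1) / n_lat * pi
  lon <- (seq_len(n_lon) - 1) / n_lon * 2 * pi
  g <- expand.grid(lon = lon, lat = lat)
  v <- r * cbind(sin(g$lat) * cos(g$lon), cos(g$lat),
                 sin(g$lat) * sin(g$lon))
  top <- nrow(v) + 1L
  bot <- nrow(v) + 2L
  v <- rbind(v, c(0, r, 0), c(0, -r, 0))
  idx <- function(i, j) (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  j <- seq_len(n_lon)
  f <- list(cbind(top, idx(1, j), idx(1, j + 1)))
  for (i in seq_len(n_lat - 2)) {
    f[[length(f) + 1L]] <- cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    f[[length(f) + 1L]] <- cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  f[[length(f) + 1L]] <- cbind(bot, idx(n_lat - 1, j + 1), idx(n_lat - 1, j))
  trimesh(v, do.call(rbind, f), name = "sphere")
}

# random rotation matrix (seeded by the caller)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

# crop: drop every face having any vertex with coordinate > threshold on axis
crop_mesh <- function(mesh, axis = 1, frac = 0.3) {
  rng <- range(mesh$vertices[, axis])
  cut <- rng[2] - frac * diff(rng)
  keep <- apply(matrix(mesh$vertices[mesh$faces, axis],
                       nrow = nrow(mesh$faces)), 1,
                function(x) all(x <= cut))
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- match(f, used)
  trimesh(mesh$vertices[used, , drop = FALSE],
          matrix(remap, ncol = 3), name = paste0(mesh$name, "_crop"))
}
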