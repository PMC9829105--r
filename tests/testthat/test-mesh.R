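test_that("all centroid definitions agree on the symmetric cube", {
  cube <- unit_cube()
  for (method in c("area_weighted_surface", "vertex_mean",
                   "enclosed_volume")) {
    expect_equal(unname(surface_centroid(cube, method)$point),
                 c(0.5, 0.5, 0.5), tolerance = 1e-12)
  }
})

test_that("area-weighted centroid of a planar patch is its barycenter", {
  expect_equal(unname(surface_centroid(unit_triangle_patch())$point),
               c(1 / 3, 1 / 3, 0), tolerance = 1e-12)
})

test_that("volume centroid matches the closed-form simplex value", {
  # solid simplex with vertices at origin and unit axes: centroid at
  # the mean of its four vertices
  expect_equal(unname(surface_centroid(unit_tetra(),
                                       "enclosed_volume")$point),
               c(0.25, 0.25, 0.25), tolerance = 1e-12)
  # and it differs from the surface centroid (area-weighted over faces)
  expect_gt(max(abs(surface_centroid(unit_tetra())$point -
                    c(0.25, 0.25, 0.25))), 1e-3)
})

test_that("volume centroid requires a watertight surface", {
  open_mesh <- unit_cube()
  open_mesh$faces <- open_mesh$faces[1:10, ]
  expect_false(is_watertight(open_mesh))
  expect_error(surface_centroid(open_mesh, "enclosed_volume"), "watertight")
  expect_true(is_watertight(unit_cube()))
})

test_that("centroids are equivariant under rigid motion", {
  roi <- generate_roi_mesh("mandible", 800, seed = 5)
  for (seed in 1:5) {
    set.seed(seed)
    T <- rigid_transform(random_rotation(), stats::rnorm(3, sd = 20))
    moved <- apply_rigid(roi, T)
    for (method in c("area_weighted_surface", "vertex_mean",
                     "enclosed_volume")) {
      expect_equal(unname(surface_centroid(moved, method)$point),
                   unname(transform_points(
                     surface_centroid(roi, method)$point, T)),
                   tolerance = 1e-9)
    }
  }
})

test_that("area-weighted centroid is invariant under subdivision", {
  roi <- generate_roi_mesh("maxilla", 600, seed = 9)
  fine <- subdivide_midpoint(roi)
  expect_equal(nrow(fine$faces), 4L * nrow(roi$faces))
  expect_equal(unname(surface_centroid(fine)$point),
               unname(surface_centroid(roi)$point), tolerance = 1e-9)
  # the vertex mean does NOT share this invariance
  expect_gt(max(abs(surface_centroid(fine, "vertex_mean")$point -
                    surface_centroid(roi, "vertex_mean")$point)), 1e-6)
})

test_that("centroid lies inside the bounding box", {
  for (roi in c("maxilla", "mandible")) {
    m <- generate_roi_mesh(roi, 600, seed = 2)
    q <- mesh_quality(m)
    p <- surface_centroid(m)$point
    expect_true(all(p >= q$bbox_min & p <= q$bbox_max))
  }
})

test_that("mesh quality metrics match their definitions on the cube", {
  q <- mesh_quality(unit_cube())
  expect_identical(q$n_faces, 12L)
  expect_identical(q$n_vertices, 8L)
  expect_equal(q$total_area, 6)
  expect_equal(q$bbox_min, c(0, 0, 0))
  expect_equal(q$bbox_max, c(1, 1, 1))
})

test_that("a uniform tessellation has zero edge-length spread", {
  expect_lt(mesh_quality(octahedron())$edge_length_cv, 1e-9)
})

test_that("edge-length CV matches brute-force edge enumeration", {
  m <- generate_roi_mesh("mandible", 600, seed = 31)
  # independent enumeration: every undirected edge exactly once
  f <- m$faces
  keys <- unique(c(paste(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
                   paste(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
                   paste(pmin(f[, 1], f[, 3]), pmax(f[, 1], f[, 3]))))
  idx <- do.call(rbind, strsplit(keys, " "))
  lens <- sqrt(rowSums((m$vertices[as.integer(idx[, 1]), ] -
                        m$vertices[as.integer(idx[, 2]), ])^2))
  expect_equal(mesh_quality(m)$edge_length_cv, sd(lens) / mean(lens),
               tolerance = 1e-12)
})

test_that("trimesh invariants are enforced", {
  v <- unit_cube()$vertices
  f <- unit_cube()$faces
  expect_error(trimesh(v, rbind(f, c(1, 1, 2))), "repeated")
  expect_error(trimesh(v, rbind(f, c(1, 2, 99))), "out of range")
  expect_error(trimesh(v[1:3, ], matrix(1:3, 4, 3, byrow = TRUE)),
               "at least 4 vertices|repeated")
})

test_that("a mesh is comparable with itself", {
  m <- generate_roi_mesh("maxilla", 600, seed = 1)
  rep <- check_comparability(m, m)
  expect_true(rep$pass)
  expect_true(all(vapply(rep$rules, `[[`, logical(1), "pass")))
})

test_that("decimation beyond the face-count threshold is flagged", {
  m <- generate_roi_mesh("maxilla", 1200, seed = 1)
  half <- degrade_mesh(m, degradation_config(keep_face_fraction = 0.5,
                                             vertex_jitter_sd = 0))
  rep <- check_comparability(m, half)
  expect_false(rep$rules$face_count$pass)
  expect_false(rep$pass)
})

test_that("cropping one end is caught by the bbox-extent rule", {
  m <- generate_roi_mesh("maxilla", 1200, seed = 4)
  cropped <- crop_mesh(m, axis = 1, frac = 0.3)
  # oracle: extent difference on the cropped axis
  dx <- diff(range(m$vertices[, 1])) - diff(range(cropped$vertices[, 1]))
  expect_gt(dx, 2)
  rep <- check_comparability(m, cropped)
  expect_false(rep$rules$bbox_extents$pass)
  expect_gt(rep$rules$bbox_extents$value[1], 2)
})
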