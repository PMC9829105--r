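test_that("RMS of a mesh against itself is zero", {
  m <- generate_roi_mesh("maxilla", 600, seed = 7)
  expect_lt(surface_rms(m, m, 1000, seed = 1), 1e-9)
})

test_that("constant-offset plates give RMS equal to the offset", {
  ref <- square_plate(z = 0)
  moving <- square_plate(z = 0.5)
  expect_equal(surface_rms(moving, ref, 2000, seed = 3), 0.5,
               tolerance = 1e-9)
})

test_that("known closest-point distances give the closed-form RMS", {
  ref <- square_plate(z = 0, size = 10)
  d <- point_mesh_distance(rbind(c(5, 5, 3), c(2, 2, -4)), ref)$dist
  expect_equal(d, c(3, 4), tolerance = 1e-12)
  expect_equal(sqrt(mean(d^2)), sqrt(12.5), tolerance = 1e-12)
})

test_that("point-to-triangle distance hits edges and vertices exactly", {
  ref <- square_plate(z = 0, size = 1)
  # beyond the corner: distance to the corner vertex, not a vertex mean
  expect_equal(point_mesh_distance(c(2, 2, 0), ref)$dist,
               sqrt(2), tolerance = 1e-12)
  # beyond one edge
  expect_equal(point_mesh_distance(c(0.5, -3, 4), ref)$dist,
               5, tolerance = 1e-12)
})

test_that("RMS is invariant under a joint rigid motion", {
  m <- generate_roi_mesh("mandible", 800, seed = 2)
  d <- degrade_mesh(m, degradation_config(0.4, 0.1, seed = 5))
  base <- surface_rms(m, d, 2000, seed = 9)
  set.seed(17)
  T <- rigid_transform(random_rotation(), stats::rnorm(3, sd = 15))
  joint <- surface_rms(apply_rigid(m, T), apply_rigid(d, T), 2000, seed = 9)
  expect_equal(joint, base, tolerance = 1e-6)
})

test_that("ICP on identical meshes returns the identity", {
  m <- generate_roi_mesh("maxilla", 800, seed = 3)
  rep <- icp_align(m, m, icp_config(n_samples = 1500))
  expect_true(rep$converged)
  expect_lt(rep$rms, 1e-6)
  expect_lt(max(abs(rep$transform$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(rep$transform$translation)), 1e-6)
})

test_that("ICP recovers a known rigid displacement of an exact copy", {
  m <- generate_roi_mesh("mandible", 800, seed = 8)
  truth <- rigid_transform(axis_rotation("y", 5), c(5, -3, 2))
  moved <- apply_rigid(m, truth)
  # exact-copy alignment converges linearly: give the solver room
  rep <- icp_align(moved, m, icp_config(n_samples = 1500, max_iter = 1500,
                                        tol_mm = 1e-7))
  expect_true(rep$converged)
  resid <- compose_rigid(truth, rep$transform)  # moved back onto m
  expect_lt(rotation_angle_deg(resid$rotation), 0.01)
  expect_lt(max(abs(resid$translation)), 1e-3)
})

test_that("ICP recovery holds across the perturbation envelope", {
  m <- generate_roi_mesh("maxilla", 800, seed = 13)
  for (seed in 1:5) {
    set.seed(seed)
    axis <- stats::rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
    ang <- stats::runif(1, -15, 15)
    K <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
               c(-axis[2], axis[1], 0))
    R <- diag(3) + sin(ang * pi / 180) * K +
         (1 - cos(ang * pi / 180)) * K %*% K
    truth <- rigid_transform(R, stats::runif(3, -20, 20))
    rep <- icp_align(apply_rigid(m, truth), m,
                     icp_config(n_samples = 1200, max_iter = 1500,
                                tol_mm = 1e-7, seed = seed))
    expect_true(rep$converged)
    resid <- compose_rigid(truth, rep$transform)
    expect_lt(rotation_angle_deg(resid$rotation), 0.05)
    expect_lt(max(abs(resid$translation)), 1e-2)
  }
})

test_that("ICP never worsens the RMS and reports both endpoints", {
  m <- generate_roi_mesh("maxilla", 1000, seed = 21)
  d <- degrade_mesh(m, degradation_config(0.3, 0.15, seed = 2))
  moved <- degrade_mesh(m, degradation_config(1, 0, 2, 2, seed = 3))
  rep <- icp_align(moved, d, icp_config(n_samples = 1200, tol_mm = 1e-4))
  expect_lte(rep$rms, rep$rms_initial)
  expect_true(rep$converged)
})

test_that("degraded references still localize the surface to ~0.1 mm", {
  # dense enough that the RMS is dominated by the jitter, not by the
  # decimation chord error
  m <- generate_roi_mesh("mandible", 3200, seed = 4)
  true_centroid <- surface_centroid(m)$point
  shifts <- matrix(NA_real_, 8, 3)
  for (r in 1:8) {
    ref <- degrade_mesh(m, degradation_config(0.3, 0.2, seed = 100 + r))
    rep <- icp_align(m, ref, icp_config(n_samples = 1200, tol_mm = 1e-4,
                                        seed = r))
    expect_true(rep$converged)
    expect_lt(rep$rms, 0.35)
    expect_gt(rep$rms, 0)
    shifts[r, ] <- transform_points(true_centroid, rep$transform) -
                   true_centroid
  }
  # the reference perturbations are unbiased: mean centroid misplacement
  # stays well below the single-repeat scatter
  expect_lt(max(abs(colMeans(shifts))), 0.1)
})

test_that("rotationally symmetric surfaces converge with near-zero RMS", {
  sph <- uv_sphere(r = 25, n_lat = 12)
  spun <- apply_rigid(sph, rigid_transform(axis_rotation("y", 40)))
  rep <- icp_align(spun, sph, icp_config(n_samples = 1200, max_iter = 300,
                                         tol_mm = 1e-4))
  # the rotation is unidentifiable; the fit must still converge onto the
  # surface itself
  expect_true(rep$converged)
  expect_lt(rep$rms, 0.2)
})

test_that("non-overlapping inputs yield a diverged report, not an error", {
  m <- generate_roi_mesh("maxilla", 600, seed = 6)
  d <- degrade_mesh(m, degradation_config(0.5, 0.3, seed = 1))
  cfg <- icp_config(n_samples = 800, divergence_gate_mm = 1e-4)
  rep <- icp_align(m, d, cfg)
  expect_false(rep$converged)
  expect_identical(rep$iterations, 0L)
})
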