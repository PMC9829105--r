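test_that("mesh generation is deterministic in (roi, n, seed)", {
  a <- generate_roi_mesh("maxilla", 800, seed = 12)
  b <- generate_roi_mesh("maxilla", 800, seed = 12)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  c <- generate_roi_mesh("maxilla", 800, seed = 13)
  expect_false(isTRUE(all.equal(a$vertices, c$vertices)))
})

test_that("generated ROIs are watertight, on-target and anatomical scale", {
  for (roi in c("maxilla", "mandible")) {
    for (seed in c(1, 17)) {
      m <- generate_roi_mesh(roi, 2000, seed = seed)
      q <- mesh_quality(m)
      expect_true(is_watertight(m))
      expect_lt(abs(q$n_faces - 2000) / 2000, 0.2)
      extents <- q$bbox_max - q$bbox_min
      expect_true(all(extents >= 40 & extents <= 80))
    }
  }
  expect_error(generate_roi_mesh("maxilla", 100), ">= 500")
})

test_that("generated ROIs have no rotational symmetry", {
  for (roi in c("maxilla", "mandible")) {
    m <- generate_roi_mesh(roi, 1500, seed = 5)
    for (ax in c("x", "y", "z")) {
      spun <- apply_rigid(m, rigid_transform(axis_rotation(ax, 30)))
      expect_gt(surface_rms(spun, m, 1500, seed = 2), 1)
    }
  }
})

test_that("plans are deterministic, in-envelope and uniform", {
  p1 <- sample_plan("maxilla", "P01", seed = 4)
  p2 <- sample_plan("maxilla", "P01", seed = 4)
  expect_identical(p1$translation, p2$translation)

  env <- default_envelope()
  draws <- t(vapply(1:2000, function(s)
    sample_plan("mandible", "P01", env, seed = s)$translation,
    numeric(3)))
  for (i in 1:3) {
    b <- env[[c("x", "y", "z")[i]]]
    expect_true(all(draws[, i] >= b[1] & draws[, i] <= b[2]))
    se <- diff(b) / sqrt(12) / sqrt(nrow(draws))
    expect_lt(abs(mean(draws[, i]) - mean(b)), 3 * se)
  }

  fixed <- sample_plan("maxilla", "P9",
                       envelope = list(x = c(2, 2), y = c(-1, -1),
                                       z = c(0.5, 0.5)), seed = 1)
  expect_equal(unname(fixed$translation), c(2, -1, 0.5))
  expect_error(sample_plan("maxilla", "P1",
                           envelope = list(x = c(3, 1), y = c(-1, 1),
                                           z = c(-1, 1))),
               "envelope")
})

test_that("applying a plan translates the mesh exactly and reversibly", {
  m <- generate_roi_mesh("maxilla", 800, seed = 3)
  expect_identical(apply_plan(m, c(0, 0, 0))$vertices, m$vertices)
  plan <- sample_plan("maxilla", "P01", seed = 2)
  moved <- apply_plan(m, plan)
  expect_equal(unname(surface_centroid(moved)$point -
                      surface_centroid(m)$point),
               unname(plan$translation), tolerance = 1e-9)
  back <- apply_plan(moved, -plan$translation)
  expect_lt(max(abs(back$vertices - m$vertices)), 1e-12)
})

test_that("a null degradation leaves the mesh untouched", {
  m <- generate_roi_mesh("mandible", 800, seed = 6)
  out <- degrade_mesh(m, degradation_config(1, 0, 0, 0, seed = 1))
  expect_identical(out$vertices, m$vertices)
  expect_identical(out$faces, m$faces)
})

test_that("vertex jitter has the prescribed magnitude", {
  m <- generate_roi_mesh("maxilla", 2000, seed = 2)
  sd_mm <- 0.2
  out <- degrade_mesh(m, degradation_config(1, sd_mm, seed = 9))
  disp <- sqrt(rowSums((out$vertices - m$vertices)^2))
  # mean of a 3-dof chi distribution: sd * sqrt(2) * gamma(2) / gamma(3/2)
  expected <- sd_mm * sqrt(2) * gamma(2) / gamma(1.5)
  expect_lt(abs(mean(disp) - expected) / expected, 0.05)
})

test_that("decimation hits its face budget and stays on the surface", {
  m <- generate_roi_mesh("maxilla", 3000, seed = 4)
  out <- degrade_mesh(m, degradation_config(0.3, 0, seed = 5))
  target <- round(0.3 * nrow(m$faces))
  expect_lt(abs(nrow(out$faces) - target) / target, 0.05)
  expect_lt(surface_rms(out, m, 2000, seed = 1), 0.5)
  expect_error(degrade_mesh(m, degradation_config(0.01)), "refused")
})

test_that("pre-misalignment is rigid and within its bounds", {
  m <- generate_roi_mesh("mandible", 800, seed = 7)
  out <- degrade_mesh(m, degradation_config(1, 0, 2, 2, seed = 11))
  # rigid: all pairwise distances preserved
  idx <- seq(1, nrow(m$vertices), by = 17)
  expect_equal(dist(out$vertices[idx, ]), dist(m$vertices[idx, ]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # rotation is about the centroid, translation bounded by 2 mm
  shift <- surface_centroid(out)$point - surface_centroid(m)$point
  expect_lte(sqrt(sum(shift^2)), 2 + 1e-6)
  # seeded: reproducible
  out2 <- degrade_mesh(m, degradation_config(1, 0, 2, 2, seed = 11))
  expect_identical(out$vertices, out2$vertices)
})
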