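# Synthetic validation study: procedural region-of-interest meshes, random
# surgical plans, mesh degradation emulating the quality gap between
# threshold-based reconstructions and semi-automatic segmentations, and the
# end-to-end study driver.

# closed UV-sphere topology: returns list(dirs = unit directions n x 3,
# faces = m x 3). Poles at +-Y.
unit_sphere_grid <- function(n_lat, n_lon) {
  lat <- seq_len(n_lat - 1) / n_lat * pi          # exclude poles
  lon <- (seq_len(n_lon) - 1) / n_lon * 2 * pi
  g <- expand.grid(lon = lon, lat = lat)
  dirs <- cbind(sin(g$lat) * cos(g$lon), cos(g$lat), sin(g$lat) * sin(g$lon))
  top <- nrow(dirs) + 1L
  bot <- nrow(dirs) + 2L
  dirs <- rbind(dirs, c(0, 1, 0), c(0, -1, 0))
  idx <- function(i, j) (i - 1L) * n_lon + ((j - 1L) %% n_lon) + 1L
  faces <- list()
  j <- seq_len(n_lon)
  faces[[1]] <- cbind(top, idx(1, j), idx(1, j + 1))
  for (i in seq_len(n_lat - 2)) {
    faces[[length(faces) + 1L]] <- cbind(idx(i, j), idx(i + 1, j),
                                         idx(i + 1, j + 1))
    faces[[length(faces) + 1L]] <- cbind(idx(i, j), idx(i + 1, j + 1),
                                         idx(i, j + 1))
  }
  faces[[length(faces) + 1L]] <- cbind(bot, idx(n_lat - 1, j + 1),
                                       idx(n_lat - 1, j))
  list(dirs = dirs, faces = do.call(rbind, faces))
}

# sum of Gaussian bumps on the unit sphere, evaluated at directions
sphere_bumps <- function(dirs, centers, amp, width) {
  out <- numeric(nrow(dirs))
  for (k in seq_len(nrow(centers))) {
    d2 <- rowSums(sweep(dirs, 2, centers[k, ])^2)
    out <- out + amp[k] * exp(-d2 / width[k]^2)
  }
  out
}

#' Generate a synthetic region-of-interest mesh
#'
#' Procedural stand-in for a segmented bone segment, at anatomical scale
#' (bounding box 40-80 mm per axis), closed (watertight), and deliberately
#' free of rotational symmetry so that rigid registration is identifiable:
#'
#' * `maxilla`: an ellipsoidal shell with distinct semi-axes, a deterministic
#'   alveolar-ridge band and seeded asymmetric surface bumps;
#' * `mandible`: a horseshoe (partial torus) whose rami rise at the ends,
#'   with a left/right thickness asymmetry and seeded bumps.
#'
#' Fully deterministic given `(roi, n_faces_target, seed)`.
#'
#' @param roi `"maxilla"` or `"mandible"`.
#' @param n_faces_target approximate face count (>= 500; achieved within
#'   about 20 percent).
#' @param seed integer seed for the per-subject shape variation.
#' @return a watertight `trimesh` centered near the origin.
#' @export
generate_roi_mesh <- function(roi = c("maxilla", "mandible"),
                              n_faces_target = 2000L, seed = 1L) {
  roi <- match.arg(roi)
  if (n_faces_target < 500L) stop("n_faces_target must be >= 500")
  with_seed(derive_seed(seed, "roi_mesh", roi), {
    if (roi == "maxilla") {
      # faces ~ 2 * n_lon * (n_lat - 1), with n_lon = 2 * n_lat
      n_lat <- max(6L, round(sqrt(n_faces_target / 4) + 0.5))
      grid <- unit_sphere_grid(n_lat, 2L * n_lat)
      semi <- c(32, 27, 22.5) * stats::runif(3, 0.97, 1.04)
      ridge <- 0.05 * exp(-((grid$dirs[, 2] + 0.35) / 0.25)^2) *
               (1 + 0.5 * grid$dirs[, 1])
      nb <- 5L
      centers <- matrix(stats::rnorm(3 * nb), nb)
      centers <- centers / sqrt(rowSums(centers^2))
      bump <- sphere_bumps(grid$dirs, centers,
                           amp = stats::runif(nb, 0.03, 0.06) *
                                 sample(c(-1, 1), nb, replace = TRUE),
                           width = stats::runif(nb, 0.45, 0.7))
      r <- 1 + ridge + bump
      verts <- sweep(grid$dirs * r, 2, semi, `*`)
      faces <- grid$faces
    } else {
      # horseshoe: ring angle a in [-thm, thm], tube angle v; rami rise in Y
      n_v <- max(6L, round(sqrt(n_faces_target / 4.4) + 0.5))
      n_u <- 2L * n_v + 1L
      thm <- 110 * pi / 180
      a <- seq(-thm, thm, length.out = n_u)
      v <- (seq_len(n_v) - 1) / n_v * 2 * pi
      Rc <- 26 * stats::runif(1, 0.97, 1.05)
      r0 <- 6.5 * stats::runif(1, 0.95, 1.05)
      rise <- 30 * stats::runif(1, 0.97, 1.05)
      nb <- 4L
      bump_a <- stats::runif(nb, -thm, thm)
      bump_v <- stats::runif(nb, 0, 2 * pi)
      bump_amp <- stats::runif(nb, 0.6, 1.4) *
                  sample(c(-1, 1), nb, replace = TRUE)
      g <- expand.grid(v = v, a = a)
      # left/right asymmetric tube radius plus condylar thickening
      rad <- r0 * (1 + 0.12 * sin(g$a) + 0.25 * (abs(g$a) / thm)^3)
      for (k in seq_len(nb))
        rad <- rad + bump_amp[k] *
               exp(-((g$a - bump_a[k]) / 0.35)^2 -
                   ((cos(g$v - bump_v[k]) - 1) / 0.5)^2)
      cx <- Rc * cos(g$a)
      cz <- Rc * sin(g$a)
      cy <- rise * (abs(g$a) / thm)^2.2
      # tube section spanned by the outward radial and the vertical
      ox <- cos(g$a); oz <- sin(g$a)
      verts <- cbind(cx + rad * cos(g$v) * ox,
                     cy + rad * sin(g$v),
                     cz + rad * cos(g$v) * oz)
      idx <- function(i, j) (i - 1L) * n_v + ((j - 1L) %% n_v) + 1L
      jj <- seq_len(n_v)
      faces <- list()
      for (i in seq_len(n_u - 1L)) {
        faces[[length(faces) + 1L]] <- cbind(idx(i, jj), idx(i + 1, jj),
                                             idx(i + 1, jj + 1))
        faces[[length(faces) + 1L]] <- cbind(idx(i, jj), idx(i + 1, jj + 1),
                                             idx(i, jj + 1))
      }
      cap1 <- nrow(verts) + 1L
      cap2 <- nrow(verts) + 2L
      verts <- rbind(verts, c(cx[1], cy[1], cz[1]),
                     c(cx[length(cx)], cy[length(cy)], cz[length(cz)]))
      faces[[length(faces) + 1L]] <- cbind(cap1, idx(1, jj + 1), idx(1, jj))
      faces[[length(faces) + 1L]] <- cbind(cap2, idx(n_u, jj),
                                           idx(n_u, jj + 1))
      faces <- do.call(rbind, faces)
    }
    verts <- sweep(verts, 2, colMeans(verts))
    faces <- orient_faces(verts, unname(as.matrix(faces)))
    trimesh(verts, faces,
            name = sprintf("%s_seed%d", roi, as.integer(seed)))
  })
}

#' Random surgical plan within a displacement envelope
#'
#' Draws the planned per-axis translation of a bone segment uniformly within
#' clinically feasible per-axis bounds, emulating the random choice of
#' surgical movements within a discrepancy envelope. Plans are
#' translation-only: the centroid method quantifies translations, so
#' rotations are excluded from plans by design.
#'
#' @param roi `"maxilla"` or `"mandible"`.
#' @param patient_id label for the synthetic patient.
#' @param envelope list with numeric `x`, `y`, `z` ranges `c(lower, upper)`
#'   in mm; default ±15 (sagittal), ±15 (vertical), ±5 (transversal).
#' @param seed integer seed.
#' @return object of class `simulation_plan`: `patient_id`, `roi`,
#'   `translation` (xyz mm), `seed`.
#' @export
sample_plan <- function(roi = c("maxilla", "mandible"), patient_id = "P1",
                        envelope = default_envelope(), seed = 1L) {
  roi <- match.arg(roi)
  for (ax in c("x", "y", "z")) {
    b <- envelope[[ax]]
    if (length(b) != 2L || anyNA(b) || any(!is.finite(b)) || b[1] > b[2])
      stop("envelope$", ax, " must be finite c(lower, upper)")
  }
  translation <- with_seed(derive_seed(seed, "plan", patient_id, roi), {
    c(x = stats::runif(1, envelope$x[1], envelope$x[2]),
      y = stats::runif(1, envelope$y[1], envelope$y[2]),
      z = stats::runif(1, envelope$z[1], envelope$z[2]))
  })
  structure(list(patient_id = patient_id, roi = roi,
                 translation = translation, seed = as.integer(seed)),
            class = "simulation_plan")
}

#' Default per-axis displacement envelope (mm)
#'
#' @return list with `x`, `y`, `z` ranges.
#' @export
default_envelope <- function() {
  list(x = c(-15, 15), y = c(-15, 15), z = c(-5, 5))
}

#' @export
print.simulation_plan <- function(x, ...) {
  cat(sprintf("plan %s/%s: (%+.2f, %+.2f, %+.2f) mm\n", x$patient_id,
              x$roi, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a surgical plan to a mesh
#'
#' Pure translation of the segment by the planned displacement.
#'
#' @param mesh a `trimesh`.
#' @param plan a [sample_plan()] result, or a numeric xyz translation.
#' @return the translated `trimesh`.
#' @export
apply_plan <- function(mesh, plan) {
  t <- if (inherits(plan, "simulation_plan")) plan$translation
       else as.numeric(plan)
  apply_rigid(mesh, rigid_transform(diag(3), t))
}

#' Mesh degradation configuration
#'
#' Emulates the quality gap between an accurate segmentation and a coarse
#' threshold-based reconstruction: edge-collapse decimation to a fraction of
#' the faces, isotropic Gaussian vertex jitter, and an optional random rigid
#' pre-misalignment (used on accurate models, whose own spatial position is
#' not trusted and must be recovered by registration).
#'
#' @param keep_face_fraction fraction of faces kept, in (0, 1].
#' @param vertex_jitter_sd per-axis Gaussian jitter SD, mm (>= 0).
#' @param max_translation_mm upper bound of the random pre-misalignment
#'   translation magnitude (0 disables).
#' @param max_rotation_deg upper bound of the random pre-misalignment
#'   rotation angle about the mesh centroid (0 disables).
#' @param seed integer seed for all stochastic stages.
#' @return list of class `degradation_config`.
#' @export
degradation_config <- function(keep_face_fraction = 0.3,
                               vertex_jitter_sd = 0.15,
                               max_translation_mm = 0,
                               max_rotation_deg = 0,
                               seed = 1L) {
  stopifnot(keep_face_fraction > 0, keep_face_fraction <= 1,
            vertex_jitter_sd >= 0, max_translation_mm >= 0,
            max_rotation_deg >= 0)
  structure(list(keep_face_fraction = keep_face_fraction,
                 vertex_jitter_sd = vertex_jitter_sd,
                 max_translation_mm = max_translation_mm,
                 max_rotation_deg = max_rotation_deg,
                 seed = as.integer(seed)),
            class = "degradation_config")
}

#' Degrade a mesh
#'
#' Seeded pipeline: shortest-edge midpoint-collapse decimation down to
#' `keep_face_fraction` of the faces (with a seeded perturbation of the
#' collapse order so replicates differ), then per-vertex isotropic Gaussian
#' jitter, then an optional random rigid pre-misalignment. The result is a
#' valid `trimesh`; watertightness is not guaranteed after decimation.
#'
#' @param mesh a `trimesh`.
#' @param config a [degradation_config()].
#' @return the degraded `trimesh`.
#' @export
degrade_mesh <- function(mesh, config = degradation_config()) {
  validate_trimesh(mesh)
  target <- round(config$keep_face_fraction * nrow(mesh$faces))
  if (target < 100L)
    stop("decimation to ", target, " faces refused (minimum 100)")
  with_seed(derive_seed(config$seed, "degrade"), {
    if (config$keep_face_fraction < 1) {
      dec <- cpp_decimate(mesh$vertices, mesh$faces, as.integer(target),
                          stats::runif(997))
      v <- dec$vertices
      f <- dec$faces
    } else {
      v <- mesh$vertices
      f <- mesh$faces
    }
    if (config$vertex_jitter_sd > 0)
      v <- v + matrix(stats::rnorm(length(v), 0, config$vertex_jitter_sd),
                      ncol = 3L)
    out <- trimesh(v, f, name = paste0(mesh$name, "_degraded"))
    if (config$max_translation_mm > 0 || config$max_rotation_deg > 0) {
      axis <- stats::rnorm(3)
      axis <- axis / sqrt(sum(axis^2))
      ang <- stats::runif(1, 0, config$max_rotation_deg) * pi / 180
      K <- rbind(c(0, -axis[3], axis[2]),
                 c(axis[3], 0, -axis[1]),
                 c(-axis[2], axis[1], 0))
      R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
      tr <- stats::rnorm(3)
      tr <- tr / sqrt(sum(tr^2)) *
            stats::runif(1, 0, config$max_translation_mm)
      ctr <- surface_centroid(out)$point
      # rotate about the centroid, then translate
      out <- apply_rigid(out, rigid_transform(
        R, as.numeric(ctr - R %*% ctr) + tr))
    }
    out
  })
}
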