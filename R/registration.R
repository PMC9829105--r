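#' Area-uniform random points on a mesh surface
#'
#' Samples faces with probability proportional to area, then samples
#' uniformly inside each face by the square-root barycentric trick.
#'
#' @param mesh a `trimesh`.
#' @param n number of points.
#' @param seed integer seed (sampling is always seeded for reproducibility).
#' @return n x 3 matrix of points on the surface (mm).
#' @export
sample_surface_points <- function(mesh, n, seed = 1L) {
  validate_trimesh(mesh)
  ar <- face_areas(mesh)
  with_seed(seed, {
    fi <- sample.int(length(ar), n, replace = TRUE, prob = ar)
    r1 <- sqrt(stats::runif(n))
    r2 <- stats::runif(n)
    co <- face_corners(mesh)
    a <- co$a[fi, , drop = FALSE]
    b <- co$b[fi, , drop = FALSE]
    c <- co$c[fi, , drop = FALSE]
    (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c
  })
}

#' Unsigned distance from points to a mesh surface
#'
#' Exact point-to-triangle distances (closest point anywhere on the surface,
#' not nearest vertex), computed in compiled code.
#'
#' @param points n x 3 matrix or xyz vector (mm).
#' @param mesh reference `trimesh`.
#' @return list with `dist` (n distances, mm), `points` (n x 3 closest
#'   surface points), `face` (1-based index of the face hit).
#' @export
point_mesh_distance <- function(points, mesh) {
  validate_trimesh(mesh)
  p <- if (is.null(dim(points))) matrix(as.numeric(points), 1L)
       else as.matrix(points)
  cpp_closest_points(p, mesh$vertices, mesh$faces)
}

#' Root-mean-square surface deviation
#'
#' The superimposition-quality metric: draws `n_samples` points
#' area-uniformly on `moving` (seeded), measures each point's unsigned
#' distance to the closest point on `reference`'s surface, and returns the
#' root of the mean of squared distances. One-directional by design: the
#' accurate model is evaluated against the spatial-reference model.
#'
#' @param moving `trimesh` whose surface is sampled.
#' @param reference `trimesh` against which distances are measured.
#' @param n_samples number of sample points (>= 100).
#' @param seed integer seed for the sampling.
#' @return RMS distance in mm.
#' @export
surface_rms <- function(moving, reference, n_samples = 5000L, seed = 1L) {
  if (n_samples < 100L) stop("n_samples must be >= 100")
  pts <- sample_surface_points(moving, n_samples, seed = seed)
  d <- point_mesh_distance(pts, reference)$dist
  sqrt(mean(d^2))
}

#' ICP configuration
#'
#' @param n_samples surface sample points per alignment (default 5000).
#' @param max_iter maximum ICP iterations (default 100).
#' @param tol_mm stop when the RMS improvement drops below this (default
#'   1e-6 mm).
#' @param seed integer seed for the surface sampling.
#' @param trim_fraction fraction of worst-matching pairs discarded at each
#'   update (default 0: the two models are the same anatomy, so no outlier
#'   rejection is needed).
#' @param divergence_gate_mm initial RMS above which the meshes are declared
#'   non-overlapping and the alignment reported as diverged (default 50 mm).
#' @return list of class `icp_config`.
#' @export
icp_config <- function(n_samples = 5000L, max_iter = 100L, tol_mm = 1e-6,
                       seed = 1L, trim_fraction = 0,
                       divergence_gate_mm = 50) {
  stopifnot(n_samples >= 100L, max_iter >= 1L, tol_mm > 0,
            trim_fraction >= 0, trim_fraction < 1)
  structure(list(n_samples = as.integer(n_samples),
                 max_iter = as.integer(max_iter), tol_mm = tol_mm,
                 seed = as.integer(seed), trim_fraction = trim_fraction,
                 divergence_gate_mm = divergence_gate_mm),
            class = "icp_config")
}

# closed-form least-squares rigid motion (Kabsch/Umeyama) moving src -> dst
kabsch <- function(src, dst, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(src))
  w <- weights / sum(weights)
  mu_s <- colSums(src * w)
  mu_d <- colSums(dst * w)
  H <- crossprod(sweep(src, 2, mu_s) * w, sweep(dst, 2, mu_d))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  rigid_transform(R, mu_d - as.numeric(R %*% mu_s))
}

#' Best-fit rigid alignment by iterative closest point
#'
#' Aligns an accurate surface model onto its coarser spatial-reference
#' counterpart. Point-to-point ICP: (a) sample points area-uniformly on
#' `moving` once (seeded), (b) pair each transformed sample with its closest
#' point on `reference`'s surface (exact point-to-triangle), (c) solve the
#' least-squares rigid motion in closed form (SVD of the cross-covariance),
#' (d) apply and repeat until the RMS improvement falls below `tol_mm` or
#' `max_iter` is reached. Initialization translates `moving`'s surface
#' centroid onto `reference`'s, with identity rotation.
#'
#' Non-overlapping inputs (initial RMS above the divergence gate) return a
#' report with `converged = FALSE` rather than raising.
#'
#' @param moving `trimesh` to be aligned (accurate model).
#' @param reference `trimesh` serving as spatial reference.
#' @param config an [icp_config()].
#' @return object of class `alignment_report`: `transform` (cumulative
#'   [rigid_transform()] mapping `moving` onto `reference`), `rms` (final
#'   RMS, mm), `rms_initial`, `n_samples`, `iterations`, `converged`.
#' @export
icp_align <- function(moving, reference, config = icp_config()) {
  validate_trimesh(moving)
  validate_trimesh(reference)
  samples <- sample_surface_points(moving, config$n_samples,
                                   seed = config$seed)
  init_t <- surface_centroid(reference)$point -
            surface_centroid(moving)$point
  total <- rigid_transform(diag(3), init_t)
  cur <- transform_points(samples, total)

  closest <- cpp_closest_points(cur, reference$vertices, reference$faces)
  rms <- sqrt(mean(closest$dist^2))
  rms_initial <- rms
  if (rms_initial > config$divergence_gate_mm) {
    return(structure(list(transform = total, rms = rms,
                          rms_initial = rms_initial,
                          n_samples = config$n_samples, iterations = 0L,
                          converged = FALSE),
                     class = "alignment_report"))
  }

  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    iterations <- it
    keep <- seq_len(nrow(cur))
    if (config$trim_fraction > 0) {
      k <- ceiling(length(keep) * (1 - config$trim_fraction))
      keep <- order(closest$dist)[seq_len(k)]
    }
    upd <- kabsch(cur[keep, , drop = FALSE],
                  closest$points[keep, , drop = FALSE])
    total <- compose_rigid(total, upd)
    cur <- transform_points(cur, upd)
    closest <- cpp_closest_points(cur, reference$vertices, reference$faces,
                                  closest$face)
    new_rms <- sqrt(mean(closest$dist^2))
    if (rms - new_rms < config$tol_mm) {
      rms <- min(rms, new_rms)
      converged <- TRUE
      break
    }
    rms <- new_rms
  }
  structure(list(transform = total, rms = rms, rms_initial = rms_initial,
                 n_samples = config$n_samples, iterations = iterations,
                 converged = converged),
            class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf(paste0("ICP alignment: %s in %d iterations, RMS %.4f mm",
                     " (initial %.4f mm, %d samples)\n"),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$rms, x$rms_initial, x$n_samples))
  print(x$transform)
  invisible(x)
}

#' Serialize an alignment report to a JSON-ready list
#'
#' @param report an `alignment_report`.
#' @return plain list suitable for `jsonlite::write_json()`.
#' @export
alignment_report_json <- function(report) {
  list(rotation = report$transform$rotation,
       translation = report$transform$translation,
       rms_mm = report$rms, rms_initial_mm = report$rms_initial,
       n_samples = report$n_samples, iterations = report$iterations,
       converged = report$converged)
}
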