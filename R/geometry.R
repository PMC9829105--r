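#' Cartesian coordinate frame for displacement decomposition
#'
#' The clinician-defined axis system in which centroid displacements are
#' reported: X sagittal, Y vertical, Z transversal. In practice the frame is
#' derived from the patient's natural head position and exported alongside
#' the surface models; here it is an explicit origin plus three orthonormal
#' axes, which avoids any Euler-angle convention ambiguity.
#'
#' Sign convention used throughout the package: +X anterior, +Y superior,
#' +Z toward the patient's right. Every report carries the frame so results
#' are self-describing.
#'
#' @param origin numeric xyz, mm.
#' @param axis_x,axis_y,axis_z numeric xyz unit vectors (sagittal, vertical,
#'   transversal). Near-orthonormal input (deviation < 1e-6) is
#'   re-orthonormalized; larger deviation is rejected, as is a left-handed
#'   triple.
#' @return object of class `cartesian_frame`.
#' @export
cartesian_frame <- function(origin = c(0, 0, 0),
                            axis_x = c(1, 0, 0),
                            axis_y = c(0, 1, 0),
                            axis_z = c(0, 0, 1)) {
  origin <- as.numeric(origin)
  R <- cbind(as.numeric(axis_x), as.numeric(axis_y), as.numeric(axis_z))
  if (length(origin) != 3L || any(dim(R) != c(3L, 3L)) || anyNA(R))
    stop("frame needs a 3-vector origin and three 3-vector axes")
  dev <- max(abs(crossprod(R) - diag(3)))
  if (dev >= 1e-6)
    stop("axes are not orthonormal (max deviation ", signif(dev, 3),
         "); frames must be within 1e-6 of orthonormal")
  if (det(R) < 0)
    stop("left-handed axis triple (x cross y must equal z)")
  if (dev > 0) R <- orthonormalize(R)
  structure(list(origin = origin, axis_x = R[, 1], axis_y = R[, 2],
                 axis_z = R[, 3]),
            class = "cartesian_frame")
}

# nearest rotation matrix by SVD projection, internal
orthonormalize <- function(R) {
  s <- svd(R)
  U <- s$u %*% t(s$v)
  if (det(U) < 0) {
    s$v[, 3] <- -s$v[, 3]
    U <- s$u %*% t(s$v)
  }
  U
}

#' @export
print.cartesian_frame <- function(x, ...) {
  cat("cartesian frame (mm): origin", sprintf("(%.3f, %.3f, %.3f)\n",
      x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  X sagittal    (%+.4f, %+.4f, %+.4f)\n",
              x$axis_x[1], x$axis_x[2], x$axis_x[3]))
  cat(sprintf("  Y vertical    (%+.4f, %+.4f, %+.4f)\n",
              x$axis_y[1], x$axis_y[2], x$axis_y[3]))
  cat(sprintf("  Z transversal (%+.4f, %+.4f, %+.4f)\n",
              x$axis_z[1], x$axis_z[2], x$axis_z[3]))
  invisible(x)
}

#' Read a Cartesian frame from a JSON file
#'
#' Expects a JSON object `{origin:[x,y,z], axis_x:[...], axis_y:[...],
#' axis_z:[...], units:"mm"}`. Axes are validated and, when within 1e-6 of
#' orthonormal, re-orthonormalized.
#'
#' @param path file location.
#' @return a [cartesian_frame()].
#' @export
load_frame <- function(path) {
  if (!file.exists(path)) stop("frame file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse frame file '", path, "': ",
                         conditionMessage(e)))
  need <- c("origin", "axis_x", "axis_y", "axis_z")
  if (!all(need %in% names(obj)))
    stop("frame file must contain fields: ", paste(need, collapse = ", "))
  if (!is.null(obj$units) && !identical(obj$units, "mm"))
    stop("frame units must be mm, got '", obj$units, "'")
  cartesian_frame(obj$origin, obj$axis_x, obj$axis_y, obj$axis_z)
}

#' Write a Cartesian frame to a JSON file
#'
#' @param frame a [cartesian_frame()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  jsonlite::write_json(list(origin = frame$origin, axis_x = frame$axis_x,
                            axis_y = frame$axis_y, axis_z = frame$axis_z,
                            units = "mm"),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Express points in a Cartesian frame
#'
#' Maps world coordinates p to frame coordinates
#' `((p - origin) . axis_x, (p - origin) . axis_y, (p - origin) . axis_z)`.
#'
#' @param points numeric xyz vector or n x 3 matrix (mm, world coordinates).
#' @param frame a [cartesian_frame()].
#' @return same shape as `points`, in frame coordinates.
#' @export
to_frame_coords <- function(points, frame) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(as.numeric(points), 1L) else as.matrix(points)
  R <- cbind(frame$axis_x, frame$axis_y, frame$axis_z)
  out <- sweep(p, 2, frame$origin) %*% R
  if (vec) drop(out) else out
}

#' Map frame coordinates back to world coordinates
#'
#' Inverse of [to_frame_coords()].
#'
#' @inheritParams to_frame_coords
#' @return same shape as `points`, in world coordinates.
#' @export
from_frame_coords <- function(points, frame) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(as.numeric(points), 1L) else as.matrix(points)
  R <- cbind(frame$axis_x, frame$axis_y, frame$axis_z)
  out <- sweep(p %*% t(R), 2, frame$origin, `+`)
  if (vec) drop(out) else out
}

#' Rigid transform (rotation + translation)
#'
#' Maps x to `R x + t`. Houses both the best-fit alignment recovered by
#' registration and the simulated surgical displacements.
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1 (within
#'   1e-9; small drift is re-orthonormalized).
#' @param translation numeric xyz, mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  R <- as.matrix(rotation)
  t <- as.numeric(translation)
  if (any(dim(R) != c(3L, 3L)) || length(t) != 3L || anyNA(R) || anyNA(t))
    stop("rigid transform needs a 3x3 rotation and a 3-vector translation")
  dev <- max(abs(crossprod(R) - diag(3)))
  if (dev >= 1e-9) {
    if (dev >= 1e-6)
      stop("rotation is not orthonormal (max deviation ", signif(dev, 3), ")")
    R <- orthonormalize(R)
  }
  if (det(R) < 0) stop("rotation has determinant -1 (reflection)")
  structure(list(rotation = R, translation = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf(paste0("rigid transform: rotation %.4f deg,",
                     " translation (%.4f, %.4f, %.4f) mm\n"),
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation angle of a rotation matrix, in degrees
#'
#' @param R 3 x 3 rotation matrix.
#' @return angle in degrees in \[0, 180\].
#' @export
rotation_angle_deg <- function(R) {
  ctheta <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ctheta))) * 180 / pi
}

#' Apply a rigid transform to points or a mesh
#'
#' Every vertex v maps to `R v + t`; mesh topology is unchanged.
#'
#' @param x a `trimesh` or an n x 3 matrix / xyz vector of points.
#' @param transform a [rigid_transform()].
#' @return transformed object of the same type.
#' @export
apply_rigid <- function(x, transform) {
  if (!inherits(transform, "rigid_transform"))
    transform <- rigid_transform(transform$rotation, transform$translation)
  if (inherits(x, "trimesh")) {
    x$vertices <- transform_points(x$vertices, transform)
    return(x)
  }
  transform_points(x, transform)
}

#' @rdname apply_rigid
#' @param points n x 3 matrix or xyz vector.
#' @export
transform_points <- function(points, transform) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(as.numeric(points), 1L) else as.matrix(points)
  out <- sweep(p %*% t(transform$rotation), 2, transform$translation, `+`)
  if (vec) drop(out) else out
}

#' Compose two rigid transforms
#'
#' Returns the transform that applies `t1` first, then `t2`:
#' `x -> R2 (R1 x + t1) + t2`. The rotation product is re-orthonormalized if
#' numerical drift exceeds 1e-12.
#'
#' @param t1,t2 [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
compose_rigid <- function(t1, t2) {
  R <- t2$rotation %*% t1$rotation
  if (max(abs(crossprod(R) - diag(3))) > 1e-12) R <- orthonormalize(R)
  rigid_transform(R, as.numeric(t2$rotation %*% t1$translation) +
                       t2$translation)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Rotation matrix about a coordinate axis
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle_deg rotation angle, degrees (right-hand rule).
#' @return 3 x 3 rotation matrix.
#' @export
axis_rotation <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c2 <- cos(a); s2 <- sin(a)
  switch(axis,
         x = rbind(c(1, 0, 0), c(0, c2, -s2), c(0, s2, c2)),
         y = rbind(c(c2, 0, s2), c(0, 1, 0), c(-s2, 0, c2)),
         z = rbind(c(c2, -s2, 0), c(s2, c2, 0), c(0, 0, 1)))
}
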