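#' Bundle the two quality grades of one time point
#'
#' Each time point contributes two surface models of the same region of
#' interest: an accurate segmentation-grade mesh (shape authority, but with
#' no trustworthy spatial position of its own) and a coarser
#' spatial-reference mesh that carries the position in the common coordinate
#' system. The accurate mesh is aligned onto its reference before its
#' centroid is read off.
#'
#' @param accurate accurate `trimesh` (segmentation grade).
#' @param reference coarse `trimesh` carrying the spatial position.
#' @param label `"initial"` or `"final"`.
#' @param policy [comparability_policy()] used to vet the accurate/reference
#'   pair. The default is looser than the cross-time-point policy: the two
#'   grades legitimately differ in density (the reference is decimated) and
#'   the accurate model may arrive in a different orientation, so only area
#'   and extent are loosely constrained.
#' @return object of class `timepoint_models`.
#' @export
timepoint_models <- function(accurate, reference,
                             label = c("initial", "final"),
                             policy = reference_grade_policy()) {
  label <- match.arg(label)
  validate_trimesh(accurate)
  validate_trimesh(reference)
  comp <- check_comparability(accurate, reference, policy)
  if (!comp$pass)
    stop("accurate and reference meshes of the ", label,
         " time point are not comparable; failing rules: ",
         paste(names(Filter(function(r) !r$pass, comp$rules)),
               collapse = ", "))
  structure(list(accurate = accurate, reference = reference, label = label,
                 comparability = comp),
            class = "timepoint_models")
}

#' Comparability policy for accurate-vs-reference pairs
#'
#' The reference mesh is deliberately coarse, so face count is not
#' constrained and area/extent tolerances are wide; this policy only rejects
#' pairs that plainly do not depict the same region.
#'
#' @return a [comparability_policy()].
#' @export
reference_grade_policy <- function() {
  comparability_policy(max_face_ratio_dev = Inf,
                       max_area_ratio_dev = 0.5,
                       max_extent_diff_mm = 10,
                       max_edge_cv = 1.5)
}

#' Track the centroid displacement of a region of interest
#'
#' The core measurement: for each time point, the accurate mesh is aligned
#' (best fit, ICP) onto its spatial-reference mesh and the area-weighted
#' surface centroid of the aligned mesh is expressed in the Cartesian frame;
#' the displacement is the coordinate difference, final minus initial.
#' Both alignment RMS values are carried in the record so poor
#' superimpositions can be rejected downstream.
#'
#' @param t0,t1 [timepoint_models()] for the initial and final time points.
#' @param frame [cartesian_frame()] in which to decompose the displacement.
#' @param roi label: `"maxilla"`, `"mandible"` or any other region name.
#' @param icp an [icp_config()].
#' @param policy [comparability_policy()] applied between `t0$accurate` and
#'   `t1$accurate` (same crop boundaries across time). When the accurate
#'   meshes arrive in unrelated orientations, pass a policy with a looser
#'   extent rule.
#' @param centroid_method passed to [surface_centroid()].
#' @param rms_warn_mm warn when either alignment RMS exceeds this
#'   (default 0.5 mm).
#' @return object of class `displacement_record` with `dx`, `dy`, `dz` (mm,
#'   frame axes: sagittal, vertical, transversal), the two `centroid`s, the
#'   two `alignment_report`s, the frame and the ROI label.
#' @export
track_displacement <- function(t0, t1, frame = cartesian_frame(),
                               roi = "maxilla", icp = icp_config(),
                               policy = comparability_policy(),
                               centroid_method = "area_weighted_surface",
                               rms_warn_mm = 0.5) {
  stopifnot(inherits(t0, "timepoint_models"),
            inherits(t1, "timepoint_models"))
  comp <- check_comparability(t0$accurate, t1$accurate, policy)
  if (!comp$pass)
    stop("time-point accurate meshes are not comparable (same ROI crop ",
         "required); failing rules: ",
         paste(names(Filter(function(r) !r$pass, comp$rules)),
               collapse = ", "))

  align_one <- function(tp, stage) {
    cfg <- icp
    cfg$seed <- derive_seed(icp$seed, "icp", stage)
    rep <- icp_align(tp$accurate, tp$reference, cfg)
    if (!rep$converged)
      stop("ICP did not converge for the ", tp$label, " time point ",
           "(initial RMS ", signif(rep$rms_initial, 4), " mm)")
    rep
  }
  a0 <- align_one(t0, "t0")
  a1 <- align_one(t1, "t1")
  if (max(a0$rms, a1$rms) > rms_warn_mm)
    warning("alignment RMS exceeds ", rms_warn_mm, " mm (t0 ",
            signif(a0$rms, 3), ", t1 ", signif(a1$rms, 3),
            "); superimposition quality is doubtful")

  c0 <- surface_centroid(apply_rigid(t0$accurate, a0$transform),
                         method = centroid_method)
  c1 <- surface_centroid(apply_rigid(t1$accurate, a1$transform),
                         method = centroid_method)
  p0 <- to_frame_coords(c0$point, frame)
  p1 <- to_frame_coords(c1$point, frame)
  d <- p1 - p0
  structure(list(roi = roi, dx = d[1], dy = d[2], dz = d[3],
                 centroid_initial = c0, centroid_final = c1,
                 alignment_initial = a0, alignment_final = a1,
                 frame = frame, centroid_method = centroid_method),
            class = "displacement_record")
}

#' @export
print.displacement_record <- function(x, ...) {
  cat(sprintf("displacement of %s (centroid: %s)\n", x$roi,
              x$centroid_method))
  cat(sprintf("  X sagittal    %+8.4f mm\n", x$dx))
  cat(sprintf("  Y vertical    %+8.4f mm\n", x$dy))
  cat(sprintf("  Z transversal %+8.4f mm\n", x$dz))
  cat(sprintf("  alignment RMS: t0 %.4f mm, t1 %.4f mm\n",
              x$alignment_initial$rms, x$alignment_final$rms))
  invisible(x)
}

#' Per-axis error of a measured displacement against a plan
#'
#' Sign convention (fixed and documented): measured minus planned, per axis.
#'
#' @param measured a `displacement_record`.
#' @param planned numeric xyz, the planned translation (mm).
#' @return named numeric xyz error vector (mm).
#' @export
displacement_error <- function(measured, planned) {
  planned <- as.numeric(planned)
  stopifnot(length(planned) == 3L)
  out <- c(x = measured$dx, y = measured$dy, z = measured$dz) - planned
  out
}

#' Serialize a displacement record to a JSON-ready list
#'
#' @param record a `displacement_record`.
#' @return plain list suitable for `jsonlite::write_json()`.
#' @export
displacement_record_json <- function(record) {
  list(roi = record$roi,
       displacement_mm = c(record$dx, record$dy, record$dz),
       axes = c("X sagittal", "Y vertical", "Z transversal"),
       sign_convention = "+X anterior, +Y superior, +Z patient-right",
       centroid_method = record$centroid_method,
       centroid_initial = unname(record$centroid_initial$point),
       centroid_final = unname(record$centroid_final$point),
       alignment_initial = alignment_report_json(record$alignment_initial),
       alignment_final = alignment_report_json(record$alignment_final),
       frame = list(origin = record$frame$origin,
                    axis_x = record$frame$axis_x,
                    axis_y = record$frame$axis_y,
                    axis_z = record$frame$axis_z))
}
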