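#' Configuration of the synthetic validation study
#'
#' Bundles every tunable of [run_validation_study()]. A fully defaulted
#' configuration runs the whole study. Defaults:
#'
#' * meshes of ~2400 faces per region of interest, which puts the alignment
#'   RMS of the degraded references near the 0.2-0.3 mm scale typical of
#'   well-superimposed clinical surface models;
#' * plans uniform within the ±15/±15/±5 mm envelope;
#' * reference models heavily degraded (30 percent of faces kept, 0.15 mm
#'   vertex jitter) but left in their true spatial position, emulating
#'   coarse threshold-based reconstructions that still carry the position;
#' * accurate models kept at full quality but given a random rigid
#'   pre-misalignment of up to 2 mm / 2 degrees, emulating segmentation
#'   output whose own orientation is not trusted and must be recovered by
#'   the best-fit alignment;
#' * ICP with 1500 area-uniform samples, at most 80 iterations and a 1e-4 mm
#'   improvement tolerance — on degraded meshes the RMS plateaus at the
#'   jitter scale, so the tight default tolerance only adds iterations
#'   without moving the recovered transform;
#' * a cross-time-point comparability policy whose extent rule is widened to
#'   6 mm, since the pre-misaligned accurate meshes are rotated copies whose
#'   axis-aligned bounding boxes legitimately differ.
#'
#' @param n_faces_target faces per generated region-of-interest mesh.
#' @param envelope per-axis plan bounds, see [default_envelope()].
#' @param ref_degradation [degradation_config()] for reference models.
#' @param accurate_degradation [degradation_config()] for accurate models.
#' @param icp an [icp_config()].
#' @param frame the [cartesian_frame()] used for decomposition.
#' @param policy cross-time-point [comparability_policy()].
#' @param rms_warn_mm alignment-RMS warning threshold, mm.
#' @return list of class `study_config`.
#' @export
study_config <- function(n_faces_target = 2400L,
                         envelope = default_envelope(),
                         ref_degradation = degradation_config(
                           keep_face_fraction = 0.3,
                           vertex_jitter_sd = 0.15),
                         accurate_degradation = degradation_config(
                           keep_face_fraction = 1,
                           vertex_jitter_sd = 0,
                           max_translation_mm = 2,
                           max_rotation_deg = 2),
                         icp = icp_config(n_samples = 1500L, max_iter = 80L,
                                          tol_mm = 1e-4),
                         frame = cartesian_frame(),
                         policy = comparability_policy(
                           max_extent_diff_mm = 6),
                         rms_warn_mm = 0.5) {
  structure(list(n_faces_target = as.integer(n_faces_target),
                 envelope = envelope, ref_degradation = ref_degradation,
                 accurate_degradation = accurate_degradation, icp = icp,
                 frame = frame, policy = policy, rms_warn_mm = rms_warn_mm),
            class = "study_config")
}

# degrade with a derived seed, internal
degrade_with_seed <- function(mesh, cfg, seed) {
  cfg$seed <- seed
  degrade_mesh(mesh, cfg)
}

#' Run the synthetic validation study
#'
#' End-to-end emulation of the validation design: for each synthetic patient
#' and each region of interest (maxilla and mandible), generate a subject
#' mesh, draw a random surgical plan, build initial and post-plan time
#' points (accurate model pre-misaligned; reference model degraded in true
#' position), run the align-centroid-subtract pipeline, and record the
#' per-axis error of the measured against the planned translation.
#'
#' Replicates emulate repeated measurements by independent examiners /
#' sessions: every stochastic stage (degradation, pre-misalignment, ICP
#' sampling) is re-run with fresh derived seeds, while subject meshes and
#' plans are shared. Each patient, region and stage draws from its own
#' derived RNG stream, so adding patients or replicates never perturbs
#' earlier cases.
#'
#' Cases refused by the tracking stage (comparability failure, ICP
#' divergence) are recorded as failed rows and the study continues.
#'
#' @param n_patients number of synthetic patients (>= 2).
#' @param n_replicates number of replicate measurement runs per case.
#' @param config a [study_config()].
#' @param seed master seed; every stage seed derives from it.
#' @return object of class `hvsp_study`: `cases` (per-case data frame:
#'   patient, roi, replicate, planned/measured/error per axis, alignment
#'   RMS, convergence flag), `summary` (per roi and axis error statistics,
#'   see [accuracy_summary()]), `agreement` (replicate 1 vs 2 reliability,
#'   see [replicate_agreement()]; `NULL` when `n_replicates < 2`), `plans`,
#'   `config`, `seed`.
#' @export
run_validation_study <- function(n_patients = 10L, n_replicates = 2L,
                                 config = study_config(), seed = 1L) {
  if (n_patients < 2L) stop("n_patients must be >= 2")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  rois <- c("maxilla", "mandible")
  rows <- list()
  plans <- list()
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%02d", i)
    for (roi in rois) {
      mesh <- generate_roi_mesh(roi, config$n_faces_target,
                                seed = derive_seed(seed, "mesh", pid, roi))
      plan <- sample_plan(roi, pid, config$envelope,
                          seed = derive_seed(seed, "planseed", pid))
      plans[[paste(pid, roi)]] <- plan
      t0_truth <- mesh
      t1_truth <- apply_plan(mesh, plan)
      for (r in seq_len(n_replicates)) {
        row <- data.frame(patient = pid, roi = roi, replicate = r,
                          planned_x = plan$translation[["x"]],
                          planned_y = plan$translation[["y"]],
                          planned_z = plan$translation[["z"]],
                          measured_x = NA_real_, measured_y = NA_real_,
                          measured_z = NA_real_, error_x = NA_real_,
                          error_y = NA_real_, error_z = NA_real_,
                          rms_t0 = NA_real_, rms_t1 = NA_real_,
                          converged = FALSE, message = "",
                          stringsAsFactors = FALSE)
        # alignment-RMS warnings are informational at study level (the RMS
        # itself is recorded per case); only errors mark a case as failed
        res <- tryCatch(suppressWarnings({
          ref0 <- degrade_with_seed(t0_truth, config$ref_degradation,
                                    derive_seed(seed, "ref", pid, roi, r, 0))
          ref1 <- degrade_with_seed(t1_truth, config$ref_degradation,
                                    derive_seed(seed, "ref", pid, roi, r, 1))
          acc0 <- degrade_with_seed(t0_truth, config$accurate_degradation,
                                    derive_seed(seed, "acc", pid, roi, r, 0))
          acc1 <- degrade_with_seed(t1_truth, config$accurate_degradation,
                                    derive_seed(seed, "acc", pid, roi, r, 1))
          tp0 <- timepoint_models(acc0, ref0, "initial")
          tp1 <- timepoint_models(acc1, ref1, "final")
          icp <- config$icp
          icp$seed <- derive_seed(seed, "icp", pid, roi, r)
          rec <- track_displacement(tp0, tp1, config$frame, roi, icp,
                                    policy = config$policy,
                                    rms_warn_mm = config$rms_warn_mm)
          err <- displacement_error(rec, plan$translation)
          list(rec = rec, err = err)
        }), error = function(e) e)
        if (inherits(res, "error")) {
          row$message <- conditionMessage(res)
        } else {
          rec <- res$rec
          row$measured_x <- rec$dx
          row$measured_y <- rec$dy
          row$measured_z <- rec$dz
          row$error_x <- res$err[["x"]]
          row$error_y <- res$err[["y"]]
          row$error_z <- res$err[["z"]]
          row$rms_t0 <- rec$alignment_initial$rms
          row$rms_t1 <- rec$alignment_final$rms
          row$converged <- TRUE
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  cases <- do.call(rbind, rows)
  structure(list(cases = cases,
                 summary = accuracy_summary(cases),
                 agreement = if (n_replicates >= 2L)
                               replicate_agreement(cases, 1L, 2L),
                 plans = plans, config = config, seed = as.integer(seed),
                 n_patients = as.integer(n_patients),
                 n_replicates = as.integer(n_replicates)),
            class = "hvsp_study")
}

#' Per-case table in long format
#'
#' One row per patient, region, replicate and axis, with the planned and
#' measured displacement; the format consumed by the `stats` command.
#'
#' @param study an `hvsp_study`, or its `cases` data frame.
#' @return data frame with columns `patient`, `roi`, `axis`, `replicate`,
#'   `planned`, `measured`.
#' @export
study_cases_long <- function(study) {
  cases <- if (inherits(study, "hvsp_study")) study$cases else study
  cases <- cases[cases$converged, , drop = FALSE]
  do.call(rbind, lapply(c("x", "y", "z"), function(ax) {
    data.frame(patient = cases$patient, roi = cases$roi, axis = ax,
               replicate = cases$replicate,
               planned = cases[[paste0("planned_", ax)]],
               measured = cases[[paste0("measured_", ax)]],
               stringsAsFactors = FALSE)
  }))
}

#' Per-axis accuracy summary of a study
#'
#' For every region of interest and axis, summarises the error (measured
#' minus planned) over all converged cases: mean, SD, SE, 95 percent
#' confidence interval, paired t statistic and p-value against zero mean
#' difference, Shapiro-Wilk normality p of the errors, and the mean absolute
#' error.
#'
#' @param cases the per-case data frame of an `hvsp_study` (or the study).
#' @return data frame, one row per roi x axis.
#' @export
accuracy_summary <- function(cases) {
  if (inherits(cases, "hvsp_study")) cases <- cases$cases
  ok <- cases[cases$converged, , drop = FALSE]
  out <- list()
  for (roi in unique(ok$roi)) {
    for (ax in c("x", "y", "z")) {
      sub <- ok[ok$roi == roi, , drop = FALSE]
      tt <- paired_t(paired_series(sub[[paste0("measured_", ax)]],
                                   sub[[paste0("planned_", ax)]],
                                   label = paste(roi, ax)))
      err <- sub[[paste0("error_", ax)]]
      sw <- if (length(unique(err)) > 2L && length(err) >= 3L)
              shapiro_normality(err)$p else NA_real_
      out[[length(out) + 1L]] <-
        data.frame(roi = roi, axis = ax, n = tt$n, mean = tt$mean,
                   sd = tt$sd, se = tt$se, ci_low = tt$ci_low,
                   ci_high = tt$ci_high, t = tt$t, p = tt$p,
                   shapiro_p = sw, mean_abs = mean(abs(err)),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Reliability between two replicate runs
#'
#' Treats two replicates as two examiners measuring the same cases and
#' quantifies their agreement per region of interest and axis: two-way
#' absolute-agreement single-measurement intraclass correlation (ICC(A,1)),
#' and Bland-Altman mean difference with 95 percent limits of agreement.
#'
#' @param cases per-case data frame of an `hvsp_study` (or the study).
#' @param rep_a,rep_b replicate numbers to compare.
#' @return data frame, one row per roi x axis: `icc`, `mean_diff`,
#'   `loa_low`, `loa_high`, `coverage`, `n`.
#' @export
replicate_agreement <- function(cases, rep_a = 1L, rep_b = 2L) {
  if (inherits(cases, "hvsp_study")) cases <- cases$cases
  ok <- cases[cases$converged, , drop = FALSE]
  a <- ok[ok$replicate == rep_a, , drop = FALSE]
  b <- ok[ok$replicate == rep_b, , drop = FALSE]
  key <- function(d) paste(d$patient, d$roi)
  common <- intersect(key(a), key(b))
  a <- a[match(common, key(a)), , drop = FALSE]
  b <- b[match(common, key(b)), , drop = FALSE]
  out <- list()
  for (roi in unique(a$roi)) {
    sel <- a$roi == roi
    for (ax in c("x", "y", "z")) {
      va <- a[sel, paste0("measured_", ax)]
      vb <- b[sel, paste0("measured_", ax)]
      if (length(va) < 2L) {
        # fewer than two complete subjects (failed cases): agreement
        # undefined for this stratum
        out[[length(out) + 1L]] <-
          data.frame(roi = roi, axis = ax, n = length(va), icc = NA_real_,
                     mean_diff = NA_real_, loa_low = NA_real_,
                     loa_high = NA_real_, coverage = NA_real_,
                     stringsAsFactors = FALSE)
        next
      }
      icc <- icc_agreement(cbind(va, vb))
      ba <- bland_altman(paired_series(va, vb, label = paste(roi, ax)))
      out[[length(out) + 1L]] <-
        data.frame(roi = roi, axis = ax, n = length(va), icc = icc$icc,
                   mean_diff = ba$mean_diff, loa_low = ba$loa_low,
                   loa_high = ba$loa_high, coverage = ba$coverage,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.hvsp_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic validation study: %d patients x 2 ROIs x ",
                     "%d replicates (%d/%d cases converged)\n"),
              x$n_patients, x$n_replicates, sum(x$cases$converged),
              nrow(x$cases)))
  cat("\nper-axis error summary (measured - planned, mm):\n")
  print(format(x$summary, digits = 3), row.names = FALSE)
  if (!is.null(x$agreement)) {
    cat("\nreplicate 1 vs 2 agreement:\n")
    print(format(x$agreement, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.hvsp_study <- function(object, ...) {
  rms <- c(object$cases$rms_t0, object$cases$rms_t1)
  structure(list(summary = object$summary, agreement = object$agreement,
                 rms_mean = mean(rms, na.rm = TRUE),
                 rms_sd = stats::sd(rms, na.rm = TRUE),
                 n_failed = sum(!object$cases$converged)),
            class = "summary.hvsp_study")
}

#' @export
print.summary.hvsp_study <- function(x, ...) {
  print(format(x$summary, digits = 3), row.names = FALSE)
  if (!is.null(x$agreement)) print(format(x$agreement, digits = 3),
                                   row.names = FALSE)
  cat(sprintf("alignment RMS %.3f +/- %.3f mm; %d failed cases\n",
              x$rms_mean, x$rms_sd, x$n_failed))
  invisible(x)
}
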