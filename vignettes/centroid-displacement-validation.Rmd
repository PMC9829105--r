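---
title: "Centroid tracking of rigid segment displacements: methods and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centroid tracking of rigid segment displacements: methods and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

After orthognathic surgery (or any intervention that moves a rigid bone
segment), the clinical question is *how far did the segment move along each
clinical axis* — sagittal (X), vertical (Y) and transversal (Z). Comparing
two CBCT-derived surface models point by point answers "where do the
surfaces differ", not "how far did the segment translate". `centroidtrack`
implements and validates a simple, systematic answer: summarise each
region-of-interest (ROI) surface by a single 3D point — its centroid — and
report the difference of the two centroids, decomposed in a
clinician-defined Cartesian frame.

The pipeline per time point is:

1. two surface models of the same ROI enter: an *accurate* segmentation-grade
   mesh (shape authority, arbitrary pose) and a coarser *spatial-reference*
   mesh that carries the segment's position in the common coordinate system;
2. the accurate mesh is aligned onto its reference by best-fit rigid
   registration (ICP); the alignment RMS is the superimposition quality gate;
3. the area-weighted surface centroid of the aligned accurate mesh is
   expressed in the Cartesian frame.

The displacement is the final-minus-initial difference of those frame
coordinates. Rotations of the segment are deliberately out of scope: a
single point cannot represent them, and plans in the validation study are
translation-only for the same reason.

## Which centroid?

Three definitions are exposed by `surface_centroid()`:

* **area-weighted surface centroid** (default): $\sum_i A_i b_i / \sum_i
  A_i$ over faces, with $A_i$ the face area and $b_i$ its barycenter. It is
  invariant to retriangulation of the same surface, which directly addresses
  the practical requirement that the two time-point meshes be "even and with
  a similar number of triangles": with this definition, moderate density
  differences do not move the point.
* **vertex mean**: mean of unique vertices. Cheap but density-sensitive;
  exposed for sensitivity analysis.
* **enclosed-volume centroid**: the centroid of the enclosed solid via the
  divergence theorem. Physically appealing but requires a closed,
  consistently oriented surface, which clinical crops rarely are.

The tests pin the invariances: translation/rotation equivariance to 1e-9 mm
for all three, and subdivision invariance (1-to-4 midpoint refinement) for
the area-weighted definition only.

## Comparability rules

Centroid differences are only meaningful when the two ROI crops match. A
`comparability_policy()` encodes four reported (never thrown) verdicts:
face-count ratio within 10 %, total-area ratio within 10 %, per-axis
bounding-box extents within 2 mm, and edge-length CV of both meshes below
0.6. The thresholds are deliberately loose enough for two independent
segmentations of the same anatomy and strict enough to catch decimation or
a shifted crop boundary. Two looser variants are used internally: the
accurate-vs-reference pair within a time point (`reference_grade_policy()`)
does not constrain face count at all — the reference is coarse by
construction — and the cross-time-point policy used by the synthetic study
widens the extent rule to 6 mm because its accurate models carry a random
rigid pre-misalignment, which changes axis-aligned extents by up to a few
millimetres at 2 degrees.

## Registration choices

"Best fit" is realized as point-to-point ICP: area-uniform samples on the
moving mesh (drawn once, seeded), exact point-to-triangle closest points on
the reference (compiled code, warm-started between iterations), closed-form
SVD (Kabsch) updates, initialization by matching surface centroids with
identity rotation. The RMS of the sampled closest-point distances is both
the convergence monitor and the reported quality gate; it is one-directional
(accurate model evaluated against the reference), normalized by the sample
count. Non-overlapping inputs (initial RMS above a 50 mm gate) return a
diverged report instead of raising.

Defaults are 5000 samples, at most 100 iterations, and a 1e-6 mm
RMS-improvement stopping tolerance; no outlier trimming (the two models are
the same anatomy; a `trim_fraction` exists for robustness experiments). Two
practical notes, both visible in the tests:

* on *noisy* pairs the RMS plateaus at the noise scale and the tight default
  tolerance only buys iterations; the study and the command line therefore
  stop at 1e-4 mm;
* on *exact copies* point-to-point ICP converges linearly, so metrology-grade
  recovery (±20 mm / ±15° perturbations recovered to <0.01 mm / <0.05°)
  needs several hundred iterations; the recovery tests run with
  `max_iter = 1500`, `tol_mm = 1e-7`.

On rotationally symmetric surfaces (a sphere) the rotation component is
unidentifiable; the fit still converges onto the surface with near-zero RMS,
which is the correct behaviour for centroid tracking (the centroid does not
depend on the unidentifiable rotation).

## Frames and sign conventions

The Cartesian frame is stored as an explicit origin plus three orthonormal
axis vectors (JSON on disk), avoiding Euler-angle convention ambiguity.
Near-orthonormal input (deviation below 1e-6) is projected back to the
nearest rotation; anything worse, or a left-handed triple, is rejected.
Positive directions are +X anterior, +Y superior, +Z toward the patient's
right, and every report embeds the frame, so signs are self-describing.
Displacement *magnitudes* are frame-independent (tested to 1e-9 mm);
per-axis signs are only interpretable relative to the declared convention.
Errors are reported as measured − planned throughout.

## The synthetic validation study

Real patient CBCTs are not available, so the study that validates the
pipeline is synthetic end to end, emulating a simulated-surgery design in
which the ground truth is known exactly:

* **Anatomy** (`generate_roi_mesh()`): procedural, watertight,
  rotationally asymmetric meshes at anatomical scale (40–80 mm bounding box
  per axis): an ellipsoidal maxilla-like blob with a ridge band and seeded
  bumps, and a horseshoe mandible with rising rami, left/right thickness
  asymmetry and seeded prominences. Asymmetry is a hard requirement —
  ICP identifiability — and is tested (RMS > 1 mm against 30°-rotated
  copies about every axis).
* **Plans** (`sample_plan()`): per-axis translations drawn uniformly within
  a clinical displacement envelope, ±15 mm (X), ±15 mm (Y), ±5 mm (Z),
  emulating randomly chosen surgical movements within feasible limits.
* **Degradation** (`degrade_mesh()`): the reference model keeps 30 % of its
  faces (shortest-edge midpoint collapse with a seeded ordering
  perturbation) and receives 0.15 mm isotropic Gaussian vertex jitter, but
  stays in its true pose — it is a coarse model that still carries the
  position. The accurate model keeps full quality but receives a random
  rigid pre-misalignment of up to 2 mm / 2°, emulating segmentation output
  whose own pose is untrusted and must be recovered by registration.
* **Replicates**: the clinical design's repeated measurements by two
  examiners at two sittings differ by manual GUI steps; here replicates
  differ by the RNG seeds of every stochastic stage (degradation,
  pre-misalignment, ICP sampling) while subject meshes and plans are
  shared. This is an explicit emulation choice: it reproduces the
  *statistical role* of an examiner (independent noise on the same truth),
  not the human failure modes.

Every patient, region, replicate and stage draws from its own RNG stream,
derived from the master seed by a stable string hash (`derive_seed()`), so
studies are bit-reproducible and adding patients or replicates never
perturbs earlier cases. Cases refused by the pipeline (comparability
failure, ICP divergence) are recorded as failed rows and the study
continues.

**Problem sizes.** The headline study runs 10 patients × 2 ROIs × 20
replicates with 2400-face meshes, 1500 ICP samples, 80-iteration cap and
1e-4 mm tolerance (about two minutes on one CPU). The mesh density was
calibrated so the reference-alignment RMS lands at 0.27 ± 0.03 mm,
matching the scale reported for well-superimposed clinical surface models
(0.2–0.3 mm); that calibration is a statement about the emulation, not a
claim about any particular scanner or software. Unit and property tests use
smaller meshes (600–3200 faces) chosen only for runtime.

**What passing does and does not show.** The generator reproduces the
geometric structure of the task (asymmetric rigid shapes, two quality
grades, known translations) but not CBCT physics: no segmentation bias
along intensity gradients, no metal artefacts, no operator variability in
cropping, no real examiner behaviour. Passing the study bounds shows the
*pipeline* adds little error under honest noise of the modelled kinds; it
cannot certify any particular clinical imaging chain.

## Statistics

`valstats` implements the study's analysis exactly as a reader would expect
from the reliability literature:

* paired two-sided t on differences (degenerate zero-variance input is
  flagged, not thrown);
* Shapiro–Wilk normality via `stats::shapiro.test()`;
* **ICC(A,1)** — two-way, absolute-agreement, single-measurement — from the
  ANOVA mean squares. Absolute agreement is the right form for "are two
  examiners' measurements interchangeable as numbers"; a consistency ICC
  would forgive a constant offset between examiners, which is a real error
  here. The estimate is clipped to [−1, 1] and cross-checked in tests
  against `stats::aov` mean squares on all small tables;
* Bland–Altman mean difference and 95 % limits of agreement (mean ± 1.96
  SD), with the (mean, difference) plot data exported rather than rendered;
* paired-design sample size by exact noncentral-t power iteration (the n of
  interest is single-digit, where the normal approximation is visibly
  off). With a 0.4 mm detectable difference, 95 % power, α = 0.05 and an
  assumed SD of differences in the 0.3–0.4 mm range this yields single-digit
  n (9 at SD ≈ 0.37 mm); the SD assumption is the user's input, not a
  package constant, because no single value is canonical.

## Numerical and degenerate-input choices

* Vertex merge tolerance on STL import: 1e-6 mm; degenerate-face floor:
  1e-12 mm²; both fail loudly with the offending facet named.
* Binary STL stores 32-bit floats by definition of the format, so a write /
  read round trip at ~50 mm coordinates is exact only to one float ULP
  (~4e-6 mm); the ASCII dialect is written at 17 significant digits and
  round-trips exactly. Tests assert both bounds.
* `is_watertight()` requires directed half-edge consistency (each edge in
  two faces of opposite winding), the actual precondition of the
  divergence-theorem centroid; the generators orient their output by a
  flood-fill and a global volume-sign fix.
* Rotation matrices are re-orthonormalized by SVD projection when drift
  exceeds 1e-12 (composition) or 1e-9 (construction); reflections are
  rejected.
* The edge-collapse decimator removes faces that become degenerate and
  refuses to go below 100 faces.

## Known limitations

* Rotational displacement is not quantified (a centroid cannot see it); the
  simulator correspondingly restricts plans to translations.
* Point-to-point ICP without trimming assumes both meshes depict the same
  complete ROI; partial overlap is out of scope.
* The per-axis signs depend on the declared frame convention; comparing
  numbers across software requires agreeing on that convention first.
* The synthetic study bounds transfer to real data only to the extent that
  real reference-model noise is unbiased around the true surface; a biased
  segmentation (systematic over- or under-segmentation that differs between
  time points) would bias the centroid in a way no amount of replication
  detects.
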