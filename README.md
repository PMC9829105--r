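# centroidtrack

Quantifies how far a rigid anatomical segment translated between two
time-point 3D surface models — the verification step of virtual surgical
planning (VSP) in orthognathic surgery, where a maxillary (LeFort I) or
mandibular (BSSO) segment is moved by a planned amount and the achieved
movement must be measured on follow-up imaging. It is written for
clinician-researchers and imaging scientists who work with STL surface
models segmented from CBCT.

## Method

Each time point contributes two meshes of the same region of interest
(ROI): an accurate segmentation-grade mesh *M* (shape authority, untrusted
pose) and a coarse spatial-reference mesh *R* that carries the segment's
position in the common coordinate system. For each time point *t*:

1. **align**: best-fit rigid registration (point-to-point ICP with
   closed-form SVD updates) of *M<sub>t</sub>* onto *R<sub>t</sub>*; the RMS
   of sampled closest-point distances gates the superimposition quality;
2. **summarise**: the area-weighted surface centroid
   c<sub>t</sub> = Σ<sub>i</sub> A<sub>i</sub> b<sub>i</sub> / Σ<sub>i</sub> A<sub>i</sub>
   (faces *i*, area *A*, barycenter *b*) of the aligned accurate mesh —
   a definition invariant to retriangulation density;
3. **decompose**: c<sub>t</sub> is expressed in a clinician-defined
   Cartesian frame (X sagittal, Y vertical, Z transversal).

The reported displacement is the per-axis difference
**d** = c<sub>final</sub> − c<sub>initial</sub>; rotations are explicitly
out of scope (a single point cannot represent them).

Because real patient scans cannot ship with the package, it also contains a
full synthetic validation study: procedural watertight maxilla/mandible
meshes, random translation plans inside a clinical displacement envelope
(±15/±15/±5 mm), mesh degradation emulating the coarse-reference vs
accurate-segmentation quality gap, replicate "examiner" runs, and the
reproducibility statistics (paired *t*, Shapiro–Wilk, ICC(A,1),
Bland–Altman limits of agreement, noncentral-*t* sample size).

## Worked example

One synthetic case, measured under the study's default degradation — the
reference meshes keep 30 % of their faces with 0.15 mm vertex jitter, and
the accurate meshes are misaligned by up to 2 mm / 2° before tracking:

```r
library(centroidtrack)

mesh  <- generate_roi_mesh("maxilla", n_faces_target = 2400, seed = 42)
plan  <- c(-2.5, 7.5, -2.0)          # planned translation, mm (X, Y, Z)
t1    <- apply_plan(mesh, plan)

ref0 <- degrade_mesh(mesh, degradation_config(0.3, 0.15, seed = 1))
ref1 <- degrade_mesh(t1,   degradation_config(0.3, 0.15, seed = 2))
acc0 <- degrade_mesh(mesh, degradation_config(1, 0, 2, 2, seed = 3))
acc1 <- degrade_mesh(t1,   degradation_config(1, 0, 2, 2, seed = 4))

rec <- track_displacement(
  timepoint_models(acc0, ref0, "initial"),
  timepoint_models(acc1, ref1, "final"),
  roi    = "maxilla",
  icp    = icp_config(n_samples = 1500, tol_mm = 1e-4),
  policy = comparability_policy(max_extent_diff_mm = 6))
rec
#> displacement of maxilla (centroid: area_weighted_surface)
#>   X sagittal     -2.5188 mm
#>   Y vertical     +7.4946 mm
#>   Z transversal  -1.9633 mm
#>   alignment RMS: t0 0.2595 mm, t1 0.2644 mm

round(displacement_error(rec, plan), 4)
#>       x       y       z
#> -0.0188 -0.0054  0.0367
```

The planned movement is recovered to a few hundredths of a millimetre even
though both references were heavily degraded; the two alignment RMS values
(~0.26 mm) are the superimposition-quality gate a user would inspect before
trusting the numbers. With degradation disabled the recovery is exact to
1e-6 mm.

The full study is one call — `run_validation_study(10, 20, seed = 1)` —
and prints per-axis error summaries and replicate-agreement tables; see the
vignette for the design and `?run_validation_study` for the output layout.

## Command line

A thin wrapper (`inst/cli/centroidtrack`, or `ct_main()` from R) exposes
four commands: `simulate` (emit one synthetic case as STL files plus a plan
manifest), `track` (four STL files + frame JSON in, displacement report
out), `validate` (the full synthetic study), and `stats` (accuracy and
reliability tables from a per-case CSV). All outputs are seeded and
bit-reproducible.

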