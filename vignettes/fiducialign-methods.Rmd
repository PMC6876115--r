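---
title: "Methods: intra-extraoral registration with tray-mounted fiducial geometries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intra-extraoral registration with tray-mounted fiducial geometries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Orthodontic, prosthetic and orthognathic planning often needs the position of
the maxillary (and mandibular) dentoalveolar arch expressed in the coordinate
frame of the patient's face. The conventional route — facebow, plaster casts,
articulator — is mechanical and error-prone; CT-based routes carry radiation.
A radiation-free alternative captures a 3D facial surface scan while the
patient bites on a modified impression tray that carries a rigid *fiducial
geometry* (a sphere or a cross) outside the mouth. The fiducial is visible in
both the facial scan and a separate extraoral scan of the tray, so it acts as
the common reference that transports the intraoral anatomy — recorded by the
tray's silicone impression — into the face frame.

`fiducialign` implements that workflow end to end in silico: parametric
fiducial and tray geometry, a virtual structured-light scanner, landmark-seeded
rigid registration, surface-deviation (RMSE) scoring, and the rank statistics
used to compare the two marker designs. Everything is deterministic given a
seed, and every stage is testable without any real scan data.

## The six-step workflow

1. **Facial scan** with the tray in situ (the fiducials protrude extraorally).
2. **Extraoral scan** of the tray with its impression.
3. **Segmentation** of the scans into parts (`connected_components()`,
   `crop()` with declarative plane/box/landmark-radius regions).
4. **Fiducial alignment**: corresponding points are picked on the fiducial
   surfaces in both scans; a Kabsch least-squares fit seeds an ICP refinement
   restricted to the fiducial region (`align_by_fiducial()`). This yields the
   tray-to-face transform.
5. **Positive counterfeit**: the arch impression is cropped out of the tray
   scan and its triangle winding reversed (`invert_normals()`), turning the
   negative mould into the positive arch surface. The digitized plaster model
   is then ICP-fitted to this counterfeit along the gumline region.
6. **Mandible placement**: >= 3 occlusal contact points in maximal
   intercuspation pose the mandibular model relative to the maxillary one
   (Kabsch), optionally refined by a tight-gate ICP.

`chain_to_face_frame()` composes stages 4-6 into the two transforms of
interest (maxilla-to-face, mandible-to-face);
`run_six_step_workflow()` orchestrates a full synthetic run and scores the
result against ground truth.

## The registration machinery

**Kabsch fit.** Given corresponding point sets, the rotation comes from the
SVD of the cross-covariance with a sign correction on the smallest singular
direction, so reflections are impossible and no scaling is ever applied
(scanner data and dental models are metric). Degenerate configurations
(fewer than 3 points, collinear points with second singular value below
1e-9) raise typed errors.

**ICP.** Point-to-surface correspondences (exact nearest point on the target
triangle mesh, found through a uniform spatial grid written in C++),
rejection of correspondences beyond `reject_distance_mm` (default 1 mm in
`icp()`, 2 mm in the chain), Kabsch update, iterate until the RMS change
drops below `tolerance_mm` (1e-6 mm) or 100 iterations. The RMS objective is
guarded to be monotone non-increasing: an update that would increase it is
rejected and iteration stops at the previous pose. Nearest-triangle ties
break toward the lowest triangle index, so results are deterministic under
face permutation.

**Coarse-to-fine gumline fit.** The plaster-model frame may start several mm
away from the impression. With only a tight rejection gate, the surviving
correspondences are a biased subset and ICP can stall in a minimum aliased
by one tooth — we observed exactly this in the noiseless limit. The chain
therefore fits the model in two passes: an 8 mm gate to absorb the initial
offset, then the 2 mm gate for precision. The noiseless chain then recovers
the maxilla pose to ~6e-6 mm.

**Why the synthetic tray carries both markers.** A sphere is invariant under
rotation about its centre, and a cylinder about its axis: no
surface-registration method can observe those degrees of freedom. A tray
with a single spherical fiducial would leave one rotation unconstrained.
The synthetic scene therefore mounts the sphere and the cross assemblies at
opposite ends of the tray plate; two separated markers pin all six degrees
of freedom, which is also how physical facebow-style jigs avoid the same
degeneracy. For the same reason the ICP pose-recovery tests check full 6-dof
recovery on the cross marker and centre (translation) recovery on the
sphere.

**Mandible fit.** Occluding arches touch only at cusp contacts; an
unrestricted surface ICP between them would collapse the interocclusal gap.
The mandible is therefore posed by the occlusal-landmark Kabsch fit alone by
default; `refine_mandible = TRUE` adds an ICP with a 0.5 mm gate that is
kept only if it converges.

## The virtual scanner

`simulate_scan()` emulates three artefacts of a hand-held structured-light
scanner and nothing else:

* **Finite sampling.** The surface is refined by longest-edge bisection
  until edges reach `sample_spacing`. The scanner class the study targets
  resolves ~0.1 mm, which is the default; simulations in the tests and the
  acceptance script use 0.5-3 mm depending on surface size so a full run
  fits a single desktop CPU. This scaling affects sampling density only —
  noise, smoothing and all registration parameters stay at instrument scale.
* **Point noise.** Each vertex is displaced along its area-weighted normal
  by N(0, `noise_sigma`^2); the default 0.05 mm matches the instrument's
  stated point accuracy. Noise is line-of-sight by design; an isotropic
  option exists behind a flag. The RMS of the noise equals sigma, which the
  calibration test confirms to within 10% at n >= 1e4 samples.
* **Edge radiusing.** Scanned sharp edges come back rounded. We reproduce
  this with `smoothing_iters` uniform Laplacian passes (lambda = 0.5) — one
  interpretable knob instead of an optics model. Smoothing is contractive
  (each vertex moves into the convex hull of its neighbours), so bounding
  boxes never grow. Because the cross has sharp edges and the sphere has
  none, smoothing biases the cross scan more: `edge_rounding_bias()` makes
  the study's scannability result reproducible in silico.

Back-face culling against a set of view directions models partial coverage;
a configuration that removes every face raises a typed empty-scan error.
One integer seed drives one private random stream per scan; the global RNG
state is untouched and identical configurations give bitwise-identical
scans.

**Surrogates.** `make_face_surrogate()` is a half-ellipsoid
(~120 x 180 x 90 mm) with a Gaussian nose boss and low-amplitude
seed-specific relief; `make_arch_surrogate()` is a parabolic horseshoe ridge
(~50 mm wide) with `n_teeth` cusp bumps and exactly that many height maxima
along its midline. They reproduce the scale and the feature content the
registration needs (a protruding landmarkable face, a cusped arch that locks
ICP), not anatomy: no soft-tissue deformation, no grimacing, no intraoral
undercuts, no scanner occlusion shadows. A green simulation therefore
establishes that the *pipeline* is correct and that the sphere-vs-cross
ordering follows from edge radiusing — it does not certify clinical
accuracy on real faces.

## Deviation metric

`surface_deviation()` samples the source surface area-weighted (a
deterministic golden-ratio lattice in barycentric coordinates, so the metric
is exactly rigid-invariant and tessellation density cannot bias it) and
takes the unsigned distance of each sample to the nearest point of the
reference surface. RMSE is directed source-to-reference by default —
scans are compared *to* originals; a symmetric mode (the larger of the two
directed RMSEs) is available. No cutoff is applied by default because
fiducial comparisons overlap fully; a cutoff for partial overlap excludes
and counts far points. Exactness is pinned two ways: the point-to-triangle
primitive against a 400 x 400 barycentric grid-search oracle, and whole-mesh
RMSE against an exhaustive all-samples-times-all-triangles minimum on small
meshes.

Tables print RMSE rounded half-up to 2 decimals (`round_half_up()`;
R's own `round()` is half-even and would turn 0.355 into 0.35).

## Statistics

Per-participant RMSE pairs are compared with rank tests, exact by
enumeration because the study sizes are tiny (n = 5 and n = 10):

* `wilcoxon_signed_rank()`: W+ with average ranks on tied magnitudes;
  zero differences dropped by default (the classic convention; Pratt's
  method available — the fixture table contains two zeros and the source
  states no policy). Exact p enumerates all 2^n sign assignments of the
  observed ranks, which remains valid with ties; larger n uses the
  tie-corrected normal approximation with continuity correction. Two-sided
  p doubles the smaller tail, capped at 1.
* `mann_whitney_exact()`: U with average ranks; exact p enumerates all
  choose(na + nb, na) group assignments of the observed pooled values.

On the packaged scannability table the two columns separate completely and
the exact rank-sum p is 2/252 ~= 0.0079, satisfying the published "p <
0.008". The published analysis names the signed-rank test, but with n = 5
pairs the exact signed-rank null cannot produce a p below 0.0625, so the
printed bound is only attainable under the two-sample rank-sum reading;
both tests are provided and `reproduce_paper_tables()` reports the
recomputed values next to the printed ones with per-cell match flags. Two
printed cells are flagged as mismatches rather than patched: the
scannability cross mean (printed 0.36; the five printed cells average
0.354, which rounds to 0.35) and the in-face p-value (printed 0.70; zeros
dropped, the exact p from the printed differences is 0.55).

## Numerical choices

* Rotations are validated to R'R = I and det R = +1 within 1e-9; transform
  composition satisfies the group axioms to 1e-12.
* ICP: tolerance 1e-6 mm RMS change, max 100 iterations, monotone guard at
  1e-12; fiducial-region mask radius 15 mm around the landmark picks.
* STL I/O quantizes to float32 on write (both dialects describe the same
  triangle soup); reads merge bitwise-identical vertices to recover indexed
  topology; malformed files report the offending byte offset or line.
* Longest-edge bisection breaks ties toward the lowest edge index with a
  relative 1e-9 tolerance so refinement is invariant to ulp-level coordinate
  perturbations (translation equivariance of the scanner).
* Crop keeps whole faces by the centroid rule — no triangle splitting; at
  scan sampling density the ragged boundary is far below registration
  tolerances.
* Marker defaults (sphere radius 10 mm; cross arms 20 x 6 x 6 mm; base
  cylinder 8 x 10 mm; mount offset 15 mm) are stand-ins: the published
  design states no dimensions. They are large enough to scan at 0.1 mm
  resolution and small enough to sit on a tray handle; all are
  configurable. The threaded base is a plain cylinder — threads contribute
  nothing to registration and break watertightness.
* Landmark picking jitter defaults to 0.15 mm s.d. per coordinate, a
  plausible scale for interactive point selection on a 0.1 mm-resolution
  surface; the repetition study re-randomizes exactly this jitter on frozen
  scans, mirroring a protocol that restarts from the digitized models.

## Known limitations

* Simulated RMSE magnitudes (~0.05-0.1 mm) sit below the published
  human-study values (~0.24-0.36 mm): real scans add motion, soft-tissue
  change, spray, and reconstruction artefacts the simulator deliberately
  omits. Only orderings and recovery bounds are compared, never magnitudes.
* Adaptive refinement leaves T-junction seams; scans are triangle soups
  near those seams rather than watertight surfaces (real scans are not
  watertight either). `connected_components()` offers vertex connectivity
  to segment robustly across seams.
* No non-rigid registration: facial expression change between captures is
  an error source the workflow cannot correct.
* Mesh booleans are out of scope; assemblies are concatenations.
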