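---
title: "Methods: quantifying the fidelity of threshold-segmented CBCT meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the fidelity of threshold-segmented CBCT meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the model and its assumptions, the parameters that matter,
what the synthetic data do and do not emulate, the numerical choices,
and the places where the design was genuinely open. It states no
empirical result that the test suite or the acceptance script does not
itself compute.

## The problem

A dental stone cast can be digitized indirectly by scanning it in a
cone-beam CT (CBCT) device and exporting the iso-surface of the
Hounsfield-unit (HU) volume at a chosen window level as an STL mesh.
The exported surface depends strongly on that level: too low and the
model is dilated (soft, noisy material included), too high and it is
eroded. The workflow in this package measures, for a sweep of 13
levels (1425–2625 HU in 100-unit steps), how far each segmented mesh
deviates from a reference surface, selects the level that minimizes a
bespoke error index, and tests device and threshold effects with
repeated-measures ANOVA.

## The phantom and the forward model

Real bench studies scan physical casts; no such raw data can ship with
a package. The `phantom` module instead *states a world*: a parametric
arch — a circular-arc gingiva band carrying ellipsoidal tooth bumps,
blended with a smooth (log-sum-exp) union so the surface is C1 and
watertight by construction — whose implicit field is sampled on a fine
grid and extracted with the same marching-tetrahedra kernel used for
segmentation. The field is strictly negative on the grid boundary, so
the surface is closed; determinism is bit-for-bit in `(spec, seed)`.

The acquisition model is deliberately minimal, covering exactly the
degradations the bench literature attributes to threshold sensitivity:

1. **Partial volume**: each voxel's occupancy fraction is computed
   analytically — exactly along z via column-ray crossings, 4×4
   sub-rays per voxel in x/y — and mapped to
   `hu_air + occupancy * (hu_stone - hu_air)`.
2. **Blur**: isotropic Gaussian point-spread function of
   `psf_sigma_mm`, truncated at 4σ, border-renormalized.
3. **Noise**: i.i.d. Gaussian HU noise.
4. **Calibration**: affine `v -> gain * v + offset`, clamped to the
   displayed HU scale (−1000..7000).

No cone-beam reconstruction, beam hardening, or scatter is simulated
(explicit non-goals). Consequently a green phantom test establishes
that the *pipeline* — segmentation, registration, statistics —
behaves correctly and that threshold/device effects propagate as the
physics of blur and noise dictate; it does **not** establish absolute
error magnitudes of any physical scanner. Phantom deviations are an
order of magnitude below bench values (microns, not tens of microns)
precisely because the synthetic world lacks reconstruction artifacts.

**Device presets.** Three presets mirror the study design: a low-blur,
low-noise device (`NewtomVG`-like: σ = 0.08 mm, noise 40 HU) and two
identical higher-blur, higher-noise devices (`Planmeca80`/`Planmeca90`:
σ = 0.18 mm, noise 150 HU) that differ only in their noise
realization — encoding the finding that the two exposure settings of
the same device were statistically indistinguishable. The preset
values are surrogates, not measurements. With `hu_air = −800` and
`hu_stone = 5050` the air/stone midpoint is 2125 HU: inside the sweep,
asymmetrically placed (700 HU above the lowest level, 500 below the
highest) so the error is maximal at 1425 HU and rises more slowly
above the minimum, as the bench study describes. With symmetric blur
the iso-surface at the midpoint is unbiased, so the DI-minimizing
threshold is recoverable by construction.

**Scale.** The default arch (radius 6.5 mm, 4 teeth; acceptance study
4.5 mm, 3 teeth) is a reduced segment, not an anatomically scaled
arch. This is a runtime choice — the full crossed study (10 cases × 3
devices × 13 thresholds ≈ 390 segmentations plus ~780 registrations)
must fit a single-CPU test budget — made once, before any acceptance
outcome was observed. The voxel pitch stays at the protocol's
0.150 mm, so partial-volume and blur effects are at realistic scale
relative to the voxel grid.

## Segmentation

`extract_mesh()` runs marching **tetrahedra** on the Kuhn 6-tet cube
subdivision rather than classic marching cubes: it needs no case
table, has no ambiguous configurations, and — because every cube uses
the same subdivision — is face-to-face consistent, so extracted
surfaces are closed whenever the iso-surface stays inside the grid.
Vertices are linearly interpolated along tetrahedral edges (cube
edges, face diagonals and the main diagonal), one shared vertex per
crossed edge. Faces are oriented with outward normals (from stone to
air). The largest connected component (by area) is kept, suppressing
noise speckle; degenerate faces are removed by exact vertex welding
followed by dropping duplicate-index faces, which provably cannot open
the surface.

A consequence worth documenting: on a *binary* volume any
linear-interpolation iso-surfacer produces a faceted staircase whose
area overestimates a sphere's by ~27%. Geometric accuracy tests
therefore use the partial-volume construction (a one-voxel linear
transition), where area agrees with the closed form to better than
0.1% and vertices sit within half a voxel of the true radius — the
same construction the forward model produces, so this is the relevant
regime.

The window *width* (2500 HU) is carried for provenance only: the
exported surface is the window-*level* iso-surface; width is a display
concept.

## Registration

Two stages, as in the bench protocol:

* `coarse_register()`: closed-form weighted Kabsch (SVD) fit on ≥3
  corresponding points, no scaling; collinear/coincident
  configurations are rejected by a rank test. Tests verify it against
  an independent quaternion (Horn) oracle to 1e−9.
* `icp_register()`: samples `n_sample_pairs` area-weighted points
  *once* on the moving surface, then alternates exact closest-point
  pairing (AABB tree, exact point-to-triangle distance) with weighted
  Kabsch updates.

**Outlier guard and monotonicity.** Pairs beyond 10× the *median
initial* pair distance get zero weight, and the trimmed set is then
frozen. The design was originally per-iteration re-trimming, but a
changing active set changes the objective between iterations, breaking
the guaranteed monotone decrease of the trimmed RMS and (observed in
development) stalling convergence when the enforcement treated a
weight-flip as divergence. With a frozen set the objective is provably
non-increasing; the enforcement (any increase reverts the last update
and stops) then never triggers in normal operation. Convergence stops
when the RMS improves by less than `convergence_tol_mm`. A transform
that is numerically the identity (<1e−9 rad/mm) is snapped to the
exact identity so registering identical meshes is a true no-op —
which also makes the pipeline bit-deterministic when two devices
present identical volumes.

A registration fails with a structured error when *every* initial
closest-point distance exceeds a guard radius (default: a quarter of
the fixed mesh's bounding-box diagonal) — the non-overlap case.

`software_self_test()` replicates the clone-perturb-register check:
random rigid perturbations (axis uniform on the sphere, angle uniform
in 1–5°, translation uniform 0.5–2 mm per axis — the protocol says
only "moved in a random way") with 0.05 mm noise on the picked coarse
correspondences so the fine stage is actually exercised.

## Deviation statistics

`face_deviations()` computes, for **every face** of the test mesh, the
absolute Euclidean distance from the face *centroid* to its exact
closest point anywhere on the reference surface. Whether the original
bench software measured at vertices or centroids is unrecorded; the
centroid matches the "each and every face" phrasing and is flagged as
a choice, not ground truth. Distances are unsigned by design.

`summarize_deviations()` reports median, IQR (75th − 25th percentile),
mean, SD, the 95% bound, and the Dissimilarity Index

DI = median(mm) × IQR(mm) × 1000.

Numerical choices: quantiles use the linear-interpolation rule (R
type 7) — at small n the median/IQR depend on this, so it is fixed
and documented. The 95% bound deliberately trims the extreme 5% of
errors; with ≥5% injected outliers its value is independent of their
magnitude. DI is stored dimensionless per the formula (the bench
table labels it "mm²" although the ×1000 factor makes it 1000·mm²; we
note the inconsistency rather than propagate it). DI scales
quadratically under distance scaling, which the tests assert exactly.

## The sweep pipeline

`run_case()` mirrors the protocol order: extract all device × level
meshes → finely register the group to a hub mesh → *simultaneously*
crop all of them with one region (faces kept when their centroid lies
inside; open boundaries allowed) → register each cropped mesh to the
reference → per-face deviations → summaries. Open choices resolved
here: the hub is the mid-sweep (1925 HU) extraction of the first
device, as the most anatomically complete; DI ties break toward the
lower HU (ties essentially never occur with continuous data); the
crop region is an explicit config box (default: teeth plus the spec's
gingiva band) because the bench crop was interactive and determinism
is required. Phantom volumes share the reference frame, so the coarse
stage inside the pipeline is the identity — standing in for manual
point picking — while `coarse_register()` itself is exercised and
tested separately. Per-registration sampling seeds derive from the
sweep level only, so identical volumes yield identical results.

`summarize_study()` reproduces the descriptive-table layout: per
device and pooled, mean/SD/min/max and the 95% CI half-width
`t(n−1, 0.975)·SD/√n` of best thresholds and median deviations, plus
means of p95, IQR and DI. A single-row group returns `NA` for SD/CI
(undefined, flagged rather than fabricated).

## Inference

All ANOVA machinery is hand-built (it is part of the replicated
method), with oracles in the tests:

* One-way repeated measures: SS split into condition/subject/residual;
  `F = MS_cond / MS_res` on `(k−1), (k−1)(n−1)` df. Verified against
  a from-scratch loop oracle and `stats::aov` to 1e−10, and equal to
  the squared paired t in two-level designs.
* Two-way fully-within: each effect tested against its own
  effect-by-subject error. Greenhouse-Geisser ε is computed from the
  covariance of the effect's orthonormal-contrast-transformed
  responses (`ε = tr(S)²/(q·tr(S²))`, interaction contrasts via the
  Kronecker product), clipped to `[1/q, 1]`; ε = 1 exactly under
  compound symmetry. Main-effect F, p and ε match an independent
  implementation (pingouin) on a frozen fixture; for >2-level
  interactions pingouin's ε estimator differs and warns of its own
  inaccuracy, so the package keeps the standard contrast-covariance
  definition. Corrected p-values use ε-deflated df; both uncorrected
  and corrected p are always reported (the "if appropriate" convention
  — correct when ε < 0.75 — is left to the caller, who has both).
* Pairwise comparisons are paired t-tests with Dunn-Šidák adjustment
  `p' = 1−(1−p)^m` and Šidák-level confidence intervals; simple main
  effects run the modality family at each threshold level.
  Degenerate cases are pinned: constant data give F = 0 and p = 1
  (not 0/0), with a relative `1e−12·SS_total` floor absorbing
  floating-point residue in exactly-additive designs.
* `repeatability()` registers and summarizes **all ordered pairs** of
  repeated scans (n·(n−1); 10 scans → 90 pairs), each mesh serving as
  reference in turn, returning the mean of per-pair means and the mean
  of per-pair SDs.

The exact published F statistics cannot be reproduced bit-for-bit
because their inputs exist only at 1–3 printed digits; ANOVA
correctness is established by the oracles instead, and the packaged
fixture reproduces the descriptive tables at printed precision (two
table cells differ by exactly one unit in the last printed digit —
input-rounding artifacts of the original tables, allowed for
explicitly in the checks).

## Known limitations

* The forward model omits reconstruction physics (FDK, beam hardening,
  scatter, focal-spot penumbra); absolute phantom errors are
  optimistic and only relative/structural conclusions transfer.
* Point-to-point ICP converges slowly for tangential sliding on
  smooth, nearly symmetric shapes; the phantom's tooth bumps break the
  symmetry, and the acceptance tests budget enough iterations
  (hundreds at ~2 ms each) for machine-precision recovery.
* The DICOM subset is a minimal explicit-VR little-endian CT profile
  (one slice per file, MONOCHROME2, int16 + slope/intercept); it
  round-trips the package's own volumes and position-sorts slices but
  is not a general DICOM reader.
* STL welding is exact (bit-identical coordinates); meshes written by
  software that perturbs coordinates per-facet would not re-index
  identically.
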