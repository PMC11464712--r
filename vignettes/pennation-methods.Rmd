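---
title: "Methods: 2D pennation-angle mapping from muscle DTI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2D pennation-angle mapping from muscle DTI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

The pennation angle (PA) of a skeletal muscle is the angle between its
fascicles and the tendon or aponeurosis they insert on. In muscles such as
the supraspinatus, whose anterior bundle is bipennate around a central
intramuscular tendon, the PA changes early in disease (fatty infiltration,
musculotendinous retraction), which makes it a candidate imaging biomarker.
Ultrasound, the usual in vivo tool, is operator-dependent and cannot reach
the posterior bundle well.

Diffusion tensor imaging offers an operator-independent alternative. Water
diffuses preferentially along muscle fibers, so the principal eigenvector
`e1` of the local diffusion tensor aligns with the fiber direction. This
package implements a deliberately low-complexity, highly standardized 2D
measurement on an imaging plane angled along the intramuscular tendon:

1. fit a diffusion tensor per voxel from the diffusion-weighted volumes,
2. project `e1` onto the imaging plane: `v_p = v - (v . n) n`, with `n` the
   through-plane (slice-select) direction in the world frame,
3. take the angle between `v_p` and the manually drawn tendon line `T`:
   `PA = arccos(|v_p . T| / |v_p|)`, reported in degrees,
4. average the per-voxel PA over freehand anterior and posterior ROIs.

The absolute value folds the angle into [0, 90] degrees because fiber
directions are axial — `v` and `-v` describe the same fascicle. Reported
in vivo values for the supraspinatus (around 16 degrees anteriorly and 11
degrees posteriorly) live comfortably inside this range. A fiber that is
perpendicular to the imaging plane has no defined in-plane direction; the
projection degenerates (`|v_p| < 1e-6`) and the voxel becomes NaN, excluded
from ROI statistics.

This is intentionally a 2D method: it measures the component of fascicle
obliquity visible in the standardized imaging plane, not the full 3D
fascicle-to-tendon angle that tractography-based frameworks estimate. The
two do not agree in general and are not meant to.

## Tensor estimation

The signal model is monoexponential: `S = S0 exp(-b g' D g)`. Taking logs
makes the model linear in `(ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`, and the
default estimator is ordinary least squares on log-signals — the
transparent baseline, exact on noiseless data. A weighted variant
(weights = squared predicted signals, the first-order variance model for
log-transformed magnitude data) is available behind `method = "wls"` and
recorded in the field's metadata. The design matrix requires at least 7
volumes spanning at least 6 non-collinear diffusion directions; rank
deficiency is a hard error rather than a silent pseudo-inverse.

Numerical policies worth knowing:

* **Non-positive samples** cannot be log-transformed. They are excluded
  per voxel; if fewer than 7 usable samples remain the signal is floored
  at `1e-6 x` the voxel's mean b = 0 signal and the voxel is flagged
  invalid (`valid = FALSE`), propagating to NaN in every derived map.
* **Negative eigenvalues** (possible under noise) are kept in the field —
  they carry information about fit quality — and clamped to zero only
  inside the FA computation, which keeps FA in [0, 1].
* **Eigenvector sign** is canonicalized (first non-negligible component
  positive) so that repeated runs and serialized outputs are deterministic;
  the PA is invariant to this choice.
* **Default mask**: mean b = 0 image thresholded by Otsu's method,
  overridable by an explicit mask.

## Tendon direction

The tendon is annotated once per examination as an ordered polyline on the
slice of maximal tendon visibility. The package derives a single global
unit direction `T` as the principal axis of the vertex scatter — a total
least-squares line through the world-frame vertices, computed after
removing any through-plane component (relevant for oblique acquisitions).
TLS rather than first-to-last-vertex keeps the direction stable when the
polyline is drawn with small hand jitter. Using one global direction per
slice, rather than a local tangent along a curved tendon, mirrors the
manual measurement convention this method standardizes; the choice is
stored in the PA map object so downstream users can see it. For a visibly
curved tendon the global direction under-represents local angles — a known
limitation, not silently corrected.

## Registration

All volumes are aligned to the first b = 0 volume before fitting.
The built-in method is intensity-based rigid (3 translations + 3 rotations
about the volume center) or affine (plus log-scales and shears)
registration with a normalized cross-correlation metric, a two-level
multi-resolution pyramid, an exhaustive integer-voxel translation search on
the coarse level (guarding the simplex optimizer against nearby false NCC
optima), and Nelder-Mead refinement. Registration is 3D per volume; moving
volumes are resampled exactly once with trilinear interpolation and clamped
at zero, and the reference volume is copied bit-identically. If
optimization fails or ends worse than identity, the transform falls back to
identity with a warning. Non-rigid registration — what one would use on
real eddy-current-distorted data — is a research field of its own; the
`transform_fun` hook lets an external non-rigid tool slot into the same
pipeline position.

## Tractography

Deterministic tensor tracking is provided for visualization. At each
streamline step the diffusion-weighted signals are trilinearly interpolated
at the current point, a tensor is fitted to the interpolated signals, and
the trajectory follows its principal eigenvector (first-order Euler,
bidirectional from each seed, each step sign-aligned with the previous one
because eigenvectors are axial). Termination: leaving the volume or mask, a
degenerate local fit, or an inter-step turn above the angular cutoff.

Defaults follow the validated protocol: cutoff 20 degrees, minimum
retained length 50 mm, seeds drawn uniformly in the mask from a fixed RNG
seed, 100000 streamlines. The step size defaults to 0.1 x the smallest
voxel dimension — a common deterministic-tracking choice that samples
curvature finely relative to the grid; it, like every constraint, is a
visible parameter. A seed-attempt cap of 100 x the target count guarantees
termination on masks that cannot support the requested count (the set is
returned short, with a warning). With a fixed seed the output is
bit-reproducible. FA-based stopping is deliberately absent: it is not part
of the protocol this package reproduces.

## Reliability statistics

Repeated PA measurements (subjects x readers x sessions) are assessed with
absolute-agreement intraclass correlation coefficients from the two-way
model (McGraw–Wong ICC(A,1)):

```
ICC(A,1) = (MSR - MSE) / (MSR + (k - 1) MSE + (k/n)(MSC - MSE))
```

with MSR/MSC/MSE the subject, measurement and error mean squares.
Absolute agreement, unlike consistency, penalizes systematic offsets
between readers or sessions — the right property for a biomarker whose
absolute value is interpreted. Confidence intervals use the standard
F-based construction with Satterthwaite degrees of freedom; the
average-measures variant ICC(A,k) is available with Spearman–Brown
transformed bounds. Because the literature this method sits in rarely
names the variant, the package defaults to single measures — the
conservative choice, describing one reader on one occasion — and labels
the variant in every output rather than leaving it implicit. Estimates are
categorized as excellent (> 0.90), good (0.75–0.90), moderate
(0.50–0.75) or poor (< 0.50).

`design_slices()` builds the matrices of the three standard designs:
test-retest (per reader, subjects x sessions), inter-reader (per session,
subjects x readers), and intra-reader (per session, subjects x reading
occasions, when an `occasion` column is present). `aggregate_ratings()`
averages each subject over sessions and readers before cohort summaries;
with a balanced design the grand mean equals the mean of the
per-reader-per-session cell means, which is how the package reproduces a
published cohort mean from a printed measurement table. Missing cells are
an error, never imputed; zero total variance makes the ICC undefined and
is also an error rather than a fabricated 1.0.

## The digital phantom

Real shoulder DTI of this protocol cannot be redistributed, so validation
rests on a digital bipennate phantom with known ground truth. It emulates:
a straight in-plane tendon line; an anterior compartment whose two
mirrored bundles run at +PA and -PA to the tendon on either side of it
(default 16 degrees); a parallel-fibered posterior compartment (default 11
degrees); optional out-of-plane fiber elevation; per-voxel tensors with
eigenvalues (2.1, 1.6, 1.4) x 1e-3 mm^2/s (typical literature values for
skeletal muscle — the study this emulates reports no diffusivities, so
these are configurable defaults chosen once); signals from the
monoexponential model over 64 spherical-Fibonacci directions at
b = 450 s/mm^2 plus three b = 0 volumes; and Rician noise (magnitude of a
complex Gaussian perturbation, sigma = S0/SNR), because magnitude MRI noise
is Rician, not Gaussian. The default grid is 64 x 64 x 15 voxels at
0.75 x 0.75 x 3 mm — the protocol's slice geometry at a reduced in-plane
matrix, which keeps a full phantom fit around a few seconds.

What the phantom does **not** emulate: realistic supraspinatus geometry,
fat infiltration, susceptibility/EPI distortion, physiological motion, or
spatially varying coil sensitivity. Tests passing on the phantom therefore
demonstrate correctness of the computational chain (geometry, fitting,
projection, aggregation, tracking), not robustness to every artifact of
in vivo shoulder imaging.

A companion generator simulates ratings tables from independent Gaussian
subject, reader, session and residual effects, so that ICC estimates can be
checked against closed-form variance ratios
(`var_subject / (var_subject + var_rater + var_error)` for single
measures).

## Validation problem sizes and numerical bounds

The shipped test-suite and the acceptance script use these scales, chosen
to exercise every code path at desk scale:

* tensor-fit exactness: the full default phantom (39360 muscle voxels, 67
  volumes), worst-case relative tensor error ~1e-14;
* PA recovery: ROI means within 0.01 degrees of 16/11 noiselessly and
  within 1 degree at SNR 30 (observed ~0.1 degree);
* tractography: 1000 streamlines on an 80 mm straight-fiber slab (all
  retained at >= 50 mm, straight to ~1e-14 voxels, no inter-step angle
  above the cutoff) and a 30 mm slab (zero retained);
* ICC: closed form vs a brute-force `aov()` decomposition on 200 random
  10 x 3 tables (agreement ~1e-15), parameter recovery of a 0.8
  variance-ratio ICC within 0.02 at n = 5000, and >= 93% empirical
  coverage of the 95% CI over 1000 simulated 10 x 3 tables.

One regression bound deserves a note. For the phantom tensor at SNR 30
over the 67-volume scheme, the Monte Carlo median angular error of `e1`
sits near 4.6 degrees (verified against an independent implementation of
the same estimator); the package's seeded regression test bounds it at 5
degrees. Sub-3-degree medians require roughly SNR 50 under this scheme —
useful context when judging per-voxel (rather than ROI-averaged) angles on
real data.

## Known limitations

* The 2D PA is plane-dependent by design; it is standardized by the
  acquisition convention (plane angled along the tendon), not invariant to
  it.
* One global tendon direction per slice; curved tendons are
  under-modelled.
* Rigid/affine registration only, with a hook for external non-rigid
  tools; eddy-current distortions are not fully rigid.
* OLS tensor fitting has no outlier rejection; a corrupted volume
  influences every voxel it intersects.
* The ICC machinery assumes complete, balanced designs and errors
  otherwise — by intent, since silent imputation would change the
  statistic.
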