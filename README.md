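# pennation

Two-dimensional pennation-angle (PA) mapping of skeletal muscle from
diffusion tensor MRI, with the reliability statistics used to validate
such measurements.

The pennation angle — the angle between a muscle's fascicles and the
tendon they insert on — changes early in rotator-cuff disease, but its
usual in vivo measurement (ultrasound) is operator-dependent and cannot
reach the posterior supraspinatus. Because water diffusion in muscle is
fastest along the fibers, the first eigenvector **v** of the per-voxel
diffusion tensor tracks the local fascicle direction, and a standardized
2D PA can be computed on an imaging plane angled along the intramuscular
tendon:

```
v_p = v - (v . n) n                      projection onto the imaging plane
PA  = arccos( |v_p . T| / |v_p| )        angle to the tendon line T, in [0, 90] deg
```

with **n** the through-plane direction and **T** the unit direction of a
manually drawn tendon line. The package provides the full chain for
researchers working on quantitative muscle MRI:

* **image_io** — NIfTI volumes (via RNifti), FSL-style `.bval`/`.bvec`
  gradient tables, ROI label maps, tendon annotations, ratings CSVs, and
  TCK streamline files;
* **registration** — intensity-based rigid/affine alignment of all volumes
  to the first b = 0 image (NCC metric, multi-resolution), plus a hook for
  external non-rigid tools;
* **tensor_model** — log-linear (OLS, optionally WLS) tensor fitting with
  eigen-decomposition, FA and MD maps;
* **pennation_map** — tendon direction by total least squares, per-voxel PA
  maps, ROI aggregation;
* **tractography** — deterministic tensor streamlines with trilinear
  signal interpolation, 20-degree angular cutoff and 50 mm minimum length;
* **reliability_stats** — absolute-agreement ICCs (two-way model, single or
  average measures) with F-based confidence intervals, reliability
  categories, and test-retest / inter-reader / intra-reader design slicing;
* **phantom_sim** — a digital bipennate-muscle phantom with known ground
  truth (tendon line, compartment angles, tensors, Rician noise) and a
  ratings-table simulator, so everything is testable without patient data.

## Worked example

Simulate a noisy bipennate phantom (anterior bundles at ±16°, posterior at
11°, SNR 30), fit tensors, compute the PA map and aggregate the ROIs:

```r
library(pennation)

ph    <- generate_phantom(phantom_spec(snr = 30, seed = 2))
field <- fit_tensor(ph$stack, ph$gradients, mask = ph$truth$mask)
pa    <- compute_pa_map(field, ph$truth$annotation)
summarize_rois(pa, ph$truth$rois)
#> # A tibble: 2 × 4
#>   label mean_pa sd_pa n_voxels
#>   <int>   <dbl> <dbl>    <int>
#> 1     1    15.9  4.76     1152
#> 2     2    11.2  4.65     1280
```

Label 1 is the anterior ROI, label 2 the posterior ROI. At SNR 30 the ROI
means recover the generating angles (16° and 11°) to about a tenth of a
degree under the default seeds, while the per-voxel SD (~4.7°) shows the
noise level a single voxel carries — the reason ROI averaging is part of
the method. `autoplot(pa)` renders the map; `plot(set)` does the same for
streamline sets from `track_streamlines()`.

Reliability analysis of repeated readings (here simulated with a strong
subject effect):

```r
ratings <- generate_ratings(15.6, n_subjects = 10, n_raters = 3, n_sessions = 3,
                            var_subject = 4, var_rater = 0.1, var_error = 0.4,
                            seed = 5)
reliability_report(ratings)
#> # A tibble: 6 × 9
#>   design       stratum variant estimate conf_low conf_high category  ...
#> 1 test-retest  R1      single     0.931    0.820     0.981 excellent
#> 2 test-retest  R2      single     0.921    0.794     0.978 excellent
#> 3 test-retest  R3      single     0.925    0.793     0.979 excellent
#> 4 inter-reader 1       single     0.806    0.331     0.950 good
#> 5 inter-reader 2       single     0.833    0.535     0.954 good
#> 6 inter-reader 3       single     0.908    0.733     0.975 excellent
```

Each row is one design stratum: subjects × sessions for one reader
(test-retest) or subjects × readers for one session (inter-reader), with
the absolute-agreement ICC, its 95% CI and the conventional category.

### Command line

A thin wrapper around the same functions lives at `inst/cli/pennation.R`:

```sh
Rscript inst/cli/pennation.R simulate --out phantom --snr 30 --seed 2
Rscript inst/cli/pennation.R pa-map --dwi phantom/dwi.nii.gz \
    --bval phantom/dwi.bval --bvec phantom/dwi.bvec \
    --tendon phantom/tendon.yaml --rois phantom/rois.nii.gz --out out
Rscript inst/cli/pennation.R icc --ratings ratings.csv --out icc_out
```

Every subcommand writes a `manifest.yaml` (version, parameters, input MD5
digests, timestamp) into its output directory.

### Tendon annotation schema

No standard exists for in-plane polylines, so the annotation is a small
YAML file:

```yaml
slice: 8          # 1-based slice index
slice_axis: 3     # through-plane voxel axis
vertices:         # ordered [x, y] in-plane voxel coordinates, 0-based
- [9.0, 21.0]
- [54.0, 21.0]
```

Voxel coordinates are 0-based in all on-disk formats (NIfTI convention);
the R API uses 1-based indices, and all geometry is computed in world
millimetres through the NIfTI affine.

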