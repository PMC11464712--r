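#' Specification of the digital bipennate-muscle phantom
#'
#' The phantom emulates a muscle with a straight intramuscular tendon in
#' the imaging plane, a bipennate anterior compartment whose two mirrored
#' fiber bundles run at +PA and -PA to the tendon on either side of the
#' tendon line, and a parallel-fibered ("strap-like") posterior compartment
#' at its own angle. Per voxel a diffusion tensor is built from the
#' prescribed eigenvalues with the first eigenvector set by the
#' compartment's angle, the diffusion signal follows the monoexponential
#' tensor model S = S0 exp(-b g' D g), and Rician noise is added at a
#' configurable SNR (sigma = S0 / SNR; magnitude data).
#'
#' Defaults: 64 x 64 x 15 grid at 0.75 x 0.75 x 3 mm; anterior PA 16 deg,
#' posterior PA 11 deg; eigenvalues (2.1, 1.6, 1.4) x 1e-3 mm^2/s, typical
#' literature values for skeletal muscle; 64 diffusion directions at
#' b = 450 s/mm^2 plus 3 b = 0 volumes.
#'
#' @param dim Grid shape (3 integers).
#' @param voxel_size Voxel size in mm (3 values).
#' @param slice 1-based slice carrying the tendon annotation.
#' @param anterior_pa,posterior_pa Compartment pennation angles, degrees in
#'   \[0, 90\].
#' @param elevation Out-of-plane elevation per compartment, degrees
#'   (length 2: anterior, posterior).
#' @param evals Tensor eigenvalues (mm^2/s), descending, all > 0.
#' @param s0 Baseline signal.
#' @param snr Signal-to-noise ratio S0/sigma; `Inf` for noiseless data.
#' @param n_dirs Number of diffusion-weighted directions.
#' @param bval Diffusion weighting (s/mm^2).
#' @param n_b0 Number of b = 0 reference volumes (placed first).
#' @param seed RNG seed for the noise (reproducible datasets).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(64, 64, 15),
                         voxel_size = c(0.75, 0.75, 3),
                         slice = 8L,
                         anterior_pa = 16,
                         posterior_pa = 11,
                         elevation = c(0, 0),
                         evals = c(2.1, 1.6, 1.4) * 1e-3,
                         s0 = 1000,
                         snr = Inf,
                         n_dirs = 64L,
                         bval = 450,
                         n_b0 = 3L,
                         seed = 1L) {
  stopifnot(length(dim) == 3, all(dim >= 8), length(voxel_size) == 3,
            all(voxel_size > 0), slice >= 1, slice <= dim[3])
  if (anterior_pa < 0 || anterior_pa > 90 || posterior_pa < 0 || posterior_pa > 90) {
    stop("compartment pennation angles must lie in [0, 90] degrees")
  }
  if (!(all(diff(evals) <= 0) && all(evals > 0))) {
    stop("eigenvalues must be positive and sorted descending")
  }
  if (!(snr > 0)) stop("SNR must be positive (use Inf for noiseless)")
  structure(
    list(dim = as.integer(dim), voxel_size = as.numeric(voxel_size),
         slice = as.integer(slice), anterior_pa = anterior_pa,
         posterior_pa = posterior_pa, elevation = elevation,
         evals = evals, s0 = s0, snr = snr, n_dirs = as.integer(n_dirs),
         bval = bval, n_b0 = as.integer(n_b0), seed = seed),
    class = "phantom_spec"
  )
}

# Deterministic, well-spread hemisphere directions (spherical Fibonacci
# lattice restricted to z >= 0); standard construction for synthetic
# gradient schemes.
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                      # uniform in [0, 1): upper hemisphere
  phi <- i * pi * (3 - sqrt(5))   # golden-angle increments
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Gradient scheme of the phantom acquisition
#' @param spec A `phantom_spec`.
#' @return A [gradient_table] with `n_b0` leading b = 0 volumes.
#' @export
phantom_gradient_table <- function(spec) {
  g <- fibonacci_hemisphere(spec$n_dirs)
  bvals <- c(rep(0, spec$n_b0), rep(spec$bval, spec$n_dirs))
  bvecs <- rbind(matrix(0, spec$n_b0, 3), g)
  gradient_table(bvals, bvecs)
}

# Compartment geometry, in voxel rows of the second in-plane axis (y):
# tendon line along +x at y = y_t; anterior band around it split into the
# two mirrored bipennate bundles; posterior band below; a one-voxel
# exclusion zone flanks the tendon (the tendon itself carries no fiber
# signal and is excluded from ROIs, as in manual ROI placement).
phantom_geometry <- function(spec) {
  ny <- spec$dim[2]
  y_t <- round(ny * 0.35)
  half <- max(3L, round(ny * 0.15))
  list(
    tendon_row = y_t,
    anterior_rows = setdiff(seq(max(2L, y_t - half), min(ny - 1L, y_t + half)),
                            (y_t - 1L):(y_t + 1L)),
    posterior_rows = seq(min(ny - 1L, y_t + half + 3L),
                         min(ny - 1L, y_t + half + 2L + 2L * half)),
    exclusion_rows = (y_t - 1L):(y_t + 1L)
  )
}

#' Generate the bipennate-muscle phantom dataset
#'
#' Builds the 4D diffusion-weighted stack, the gradient table and the
#' ground truth: first-eigenvector field, pennation-angle map, ROI label
#' map (1 = anterior, 2 = posterior) and tendon annotation. The dataset is
#' reproducible: the same spec (including seed) gives a bit-identical
#' stack.
#'
#' @param spec A [phantom_spec].
#' @return A list of class `phantom_data` with elements `stack`,
#'   `gradients`, `truth` (fields `e1`, `pa`, `rois`, `annotation`,
#'   `anterior_pa`, `posterior_pa`, `mask`).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  geo <- phantom_geometry(spec)
  if (length(intersect(geo$anterior_rows, geo$exclusion_rows)) ||
      length(intersect(geo$posterior_rows, geo$exclusion_rows))) {
    stop("phantom compartments overlap the tendon exclusion zone")
  }
  d <- spec$dim
  affine <- affine_from_voxel_size(spec$voxel_size)
  tab <- phantom_gradient_table(spec)
  n <- plane_normal_from_affine(affine, 3L)       # (0,0,1) for this affine
  t_dir <- unit(affine[1:3, 1])                   # tendon along +x in world

  rot_in_plane <- function(angle_deg, elev_deg) {
    a <- angle_deg * pi / 180
    e <- elev_deg * pi / 180
    ip <- cos(a) * t_dir + sin(a) * unit(pracma_cross(n, t_dir))
    unit(cos(e) * ip + sin(e) * n)
  }

  e1_ant_plus <- rot_in_plane(spec$anterior_pa, spec$elevation[1])
  e1_ant_minus <- rot_in_plane(-spec$anterior_pa, spec$elevation[1])
  e1_post <- rot_in_plane(spec$posterior_pa, spec$elevation[2])

  ny <- d[2]
  rois <- array(0L, dim = d)
  e1 <- array(NA_real_, dim = c(d, 3))
  pa_truth <- array(NaN, dim = d)
  nvox <- prod(d)
  assign_rows <- function(rows, label, dir, pa_val) {
    sel <- which(slice.index(rois, 2) %in% rows)
    if (!is.na(label)) rois[sel] <<- label
    for (c3 in 1:3) e1[sel + (c3 - 1) * nvox] <<- dir[c3]
    pa_truth[sel] <<- pa_val
  }
  y_above <- geo$anterior_rows[geo$anterior_rows < geo$tendon_row]
  y_below <- geo$anterior_rows[geo$anterior_rows > geo$tendon_row]
  assign_rows(y_above, 1L, e1_ant_plus, fold_pa(spec$anterior_pa))
  assign_rows(y_below, 1L, e1_ant_minus, fold_pa(spec$anterior_pa))
  assign_rows(geo$posterior_rows, 2L, e1_post, fold_pa(spec$posterior_pa))
  # tendon voxels: fibers along the tendon itself, not part of any ROI
  assign_rows(geo$exclusion_rows, NA, t_dir, 0)

  mask <- !is.nan(pa_truth)

  # tensors -> signals
  lam <- spec$evals
  g <- bvec_matrix(tab)
  b <- tab$b
  dirs <- list(e1_ant_plus, e1_ant_minus, e1_post, t_dir)
  signal_for_dir <- function(dir) {
    e2 <- unit(pracma_cross(n, dir))
    if (abs(abs(sum(dir * n)) - 1) < 1e-9) e2 <- unit(pracma_cross(c(1, 0, 0), dir))
    e3 <- unit(pracma_cross(dir, e2))
    D <- lam[1] * tcrossprod(dir) + lam[2] * tcrossprod(e2) + lam[3] * tcrossprod(e3)
    q <- rowSums((g %*% D) * g)
    spec$s0 * exp(-b * q)
  }
  sigs <- lapply(dirs, signal_for_dir)

  nvol <- nrow(tab)
  data <- array(0, dim = c(d, nvol))
  region_sel <- list(
    which(slice.index(rois, 2) %in% y_above),
    which(slice.index(rois, 2) %in% y_below),
    which(slice.index(rois, 2) %in% geo$posterior_rows),
    which(slice.index(rois, 2) %in% geo$exclusion_rows)
  )
  for (r in seq_along(region_sel)) {
    sel <- region_sel[[r]]
    for (v in seq_len(nvol)) data[sel + (v - 1) * nvox] <- sigs[[r]][v]
  }

  if (is.finite(spec$snr)) {
    sigma <- spec$s0 / spec$snr
    data <- withr::with_seed(spec$seed, {
      n1 <- array(rnorm(length(data), 0, sigma), dim = dim(data))
      n2 <- array(rnorm(length(data), 0, sigma), dim = dim(data))
      sqrt((data + n1)^2 + n2^2)
    })
  }

  x_lo <- round(d[1] * 0.15); x_hi <- round(d[1] * 0.85)
  annotation <- tendon_annotation(
    slice = spec$slice,
    vertices = rbind(c(x_lo, geo$tendon_row - 1), c(x_hi, geo$tendon_row - 1)),
    slice_axis = 3L, affine = affine
  )

  structure(
    list(
      stack = dwi_stack(data, affine, 3L),
      gradients = tab,
      truth = list(
        e1 = e1, pa = pa_truth, rois = rois, annotation = annotation,
        anterior_pa = fold_pa(spec$anterior_pa),
        posterior_pa = fold_pa(spec$posterior_pa),
        mask = mask, tendon_direction = t_dir, plane_normal = n
      ),
      spec = spec
    ),
    class = "phantom_data"
  )
}

fold_pa <- function(a) {
  a <- abs(a) %% 180
  if (a > 90) 180 - a else a
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Simulate a ratings table for reliability analysis
#'
#' Each measurement is the true ROI mean plus independent Gaussian subject,
#' rater, session and residual effects with the given variances — the
#' generating model of the two-way ANOVA decomposition behind the
#' absolute-agreement ICC. With zero rater and session variance the
#' expected single-measures ICC is var_subject / (var_subject + var_error).
#'
#' @param true_mean True pennation angle (degrees).
#' @param n_subjects,n_raters,n_sessions Design size.
#' @param var_subject,var_rater,var_session,var_error Variance components
#'   (deg^2), all >= 0.
#' @param seed RNG seed.
#' @return A ratings tibble with columns `subject`, `rater`, `session`,
#'   `value`.
#' @export
generate_ratings <- function(true_mean, n_subjects = 10L, n_raters = 3L,
                             n_sessions = 3L, var_subject = 1, var_rater = 0,
                             var_session = 0, var_error = 0.25, seed = 1L) {
  stopifnot(var_subject >= 0, var_rater >= 0, var_session >= 0, var_error >= 0)
  withr::with_seed(seed, {
    subj_eff <- rnorm(n_subjects, 0, sqrt(var_subject))
    rater_eff <- rnorm(n_raters, 0, sqrt(var_rater))
    sess_eff <- rnorm(n_sessions, 0, sqrt(var_session))
    df <- tidyr::expand_grid(
      subject = paste0("S", seq_len(n_subjects)),
      rater = paste0("R", seq_len(n_raters)),
      session = seq_len(n_sessions)
    )
    df$value <- true_mean +
      subj_eff[as.integer(factor(df$subject, levels = paste0("S", seq_len(n_subjects))))] +
      rater_eff[as.integer(factor(df$rater, levels = paste0("R", seq_len(n_raters))))] +
      sess_eff[df$session] +
      rnorm(nrow(df), 0, sqrt(var_error))
    df
  })
}

#' Write a complete phantom bundle to disk
#'
#' Writes the NIfTI volume, bval/bvec files, ROI label map, tendon
#' annotation and a ground-truth sidecar (YAML) into a directory.
#'
#' @param phantom A `phantom_data` from [generate_phantom].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named list of the written paths.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    dwi = file.path(dir, "dwi.nii.gz"),
    bval = file.path(dir, "dwi.bval"),
    bvec = file.path(dir, "dwi.bvec"),
    rois = file.path(dir, "rois.nii.gz"),
    tendon = file.path(dir, "tendon.yaml"),
    truth = file.path(dir, "truth.yaml")
  )
  write_dwi(phantom$stack, phantom$gradients, paths$dwi, paths$bval, paths$bvec)
  write_roi_labels(phantom$truth$rois, phantom$stack$affine, paths$rois)
  write_tendon_annotation(phantom$truth$annotation, paths$tendon)
  yaml::write_yaml(
    list(anterior_pa = phantom$truth$anterior_pa,
         posterior_pa = phantom$truth$posterior_pa,
         tendon_direction = as.numeric(phantom$truth$tendon_direction),
         snr = if (is.finite(phantom$spec$snr)) phantom$spec$snr else "Inf",
         seed = phantom$spec$seed),
    paths$truth
  )
  invisible(paths)
}
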