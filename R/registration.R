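#' Register all volumes to the first b = 0 reference
#'
#' Eddy-current and motion inconsistency between diffusion-weighted volumes
#' is reduced by aligning every volume to the first b = 0 volume before
#' tensor fitting. Intensity-based rigid (3 translations + 3 rotations) or
#' affine (adds scales and shears, 12 parameters) registration is used,
#' with a normalized cross-correlation metric, a two-level multi-resolution
#' pyramid and Nelder-Mead optimization; each moving volume is resampled
#' once with trilinear interpolation on the reference grid. Registration is
#' 3D per volume. The reference volume is copied untouched. A hook for an
#' external non-rigid tool is provided via `transform_fun`.
#'
#' @param stack A [dwi_stack].
#' @param table The matching [gradient_table] (identifies b = 0 volumes).
#' @param mode `"rigid"`, `"affine"` or `"none"` (bypass: input returned
#'   unchanged).
#' @param transform_fun Optional function `(moving_3d, reference_3d,
#'   affine) -> resampled_3d` replacing the built-in registration, e.g. a
#'   wrapper around an external non-rigid tool.
#' @param maxit Optimizer iteration cap per resolution level.
#' @return A list with `stack` (aligned [dwi_stack]) and `transforms`
#'   (per-volume parameter vectors; zeros for the reference).
#' @export
register_to_b0 <- function(stack, table, mode = c("rigid", "affine", "none"),
                           transform_fun = NULL, maxit = 200) {
  mode <- match.arg(mode)
  if (mode == "none" && is.null(transform_fun)) {
    return(list(stack = stack, transforms = NULL))
  }
  b0 <- which(table$b == 0)
  if (!length(b0)) stop("no b = 0 volume to use as registration reference")
  ref_idx <- b0[1]
  d <- dim(stack$data)
  ref <- stack$data[, , , ref_idx]
  out <- stack$data
  n_par <- if (mode == "affine") 12L else 6L
  transforms <- matrix(0, d[4], n_par)

  if (!is.null(transform_fun)) {
    for (v in seq_len(d[4])) {
      if (v == ref_idx) next
      out[, , , v] <- pmax(transform_fun(stack$data[, , , v], ref, stack$affine), 0)
    }
    return(list(stack = dwi_stack(out, stack$affine, stack$slice_axis),
                transforms = NULL))
  }

  geom <- registration_geometry(stack)
  for (v in seq_len(d[4])) {
    if (v == ref_idx) next
    res <- register_volume(stack$data[, , , v], ref, geom, mode, maxit)
    transforms[v, ] <- res$par
    out[, , , v] <- res$resampled
  }
  list(stack = dwi_stack(out, stack$affine, stack$slice_axis),
       transforms = transforms)
}

registration_geometry <- function(stack) {
  d <- dim(stack$data)[1:3]
  A <- stack$affine
  idx <- arrayInd(seq_len(prod(d)), d) - 1
  W <- vox0_to_world(A, idx)
  center <- vox0_to_world(A, matrix((d - 1) / 2, 1))
  list(dim = d, affine = A, Ainv = solve(A), W = W, center = as.numeric(center))
}

# Parameters: translations (mm), rotations (rad) about the volume center,
# then for affine: log-scales and shears. Maps fixed-frame world points
# into the moving volume's frame (the resampling transform).
transform_points <- function(W, par, center) {
  R <- rotation_zyx(par[4], par[5], par[6])
  M <- R
  if (length(par) >= 12) {
    Sh <- diag(3)
    Sh[1, 2] <- par[10]; Sh[1, 3] <- par[11]; Sh[2, 3] <- par[12]
    M <- R %*% Sh %*% diag(exp(par[7:9]))
  }
  sweep(sweep(W, 2, center) %*% t(M), 2, center + par[1:3], `+`)
}

rotation_zyx <- function(rx, ry, rz) {
  Rx <- matrix(c(1, 0, 0, 0, cos(rx), sin(rx), 0, -sin(rx), cos(rx)), 3, 3)
  Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3, 3)
  Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

sample_moving <- function(moving, geom, par) {
  Wm <- transform_points(geom$W, par, geom$center)
  U <- t(geom$Ainv[1:3, 1:3] %*% t(Wm) + geom$Ainv[1:3, 4])
  interp_trilinear(moving, U)
}

ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 10) return(-1)
  a <- a[ok]; b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0) return(-1)
  cor(a, b)
}

register_volume <- function(moving, ref, geom, mode, maxit) {
  n_par <- if (mode == "affine") 12L else 6L
  par0 <- rep(0, n_par)
  scales <- c(rep(1, 3), rep(0.02, 3), rep(0.02, 6))[seq_len(n_par)]

  levels <- list()
  if (all(geom$dim >= 16)) {
    ds_ref <- downsample_block_mean(ref, 2L)
    ds_mov <- downsample_block_mean(moving, 2L)
    A2 <- geom$affine
    A2[1:3, 1:3] <- A2[1:3, 1:3] * 2
    stack2 <- list(data = array(ds_ref, c(dim(ds_ref), 1)), affine = A2)
    g2 <- registration_geometry(list(data = stack2$data, affine = A2))
    levels[[1]] <- list(ref = ds_ref, mov = ds_mov, geom = g2, maxit = maxit)
  }
  levels[[length(levels) + 1]] <- list(ref = ref, mov = moving, geom = geom,
                                       maxit = max(50, maxit %/% 2))

  par <- par0
  ok <- TRUE
  # exhaustive integer-voxel translation search on the coarsest level guards
  # the local optimizer against nearby false NCC optima
  lv1 <- levels[[1]]
  vs1 <- voxel_size_from_affine(lv1$geom$affine)
  best <- Inf
  ref1 <- as.numeric(lv1$ref)
  for (dx in -3:3) for (dy in -3:3) for (dz in -2:2) {
    t3 <- c(dx, dy, dz) * vs1
    val <- -ncc(ref1, sample_moving(lv1$mov, lv1$geom, c(t3, par0[-(1:3)])))
    if (val < best) { best <- val; par[1:3] <- t3 }
  }
  for (lv in levels) {
    fn <- function(p) -ncc(as.numeric(lv$ref), sample_moving(lv$mov, lv$geom, p))
    # translation-only pre-stage stabilizes the full optimization
    fn_t <- function(p3) fn(c(p3, par[-(1:3)]))
    fit_t <- tryCatch(
      optim(par[1:3], fn_t, method = "Nelder-Mead",
            control = list(maxit = lv$maxit, reltol = 1e-8)),
      error = function(e) NULL
    )
    if (!is.null(fit_t)) par[1:3] <- fit_t$par
    fit <- tryCatch(
      optim(par, fn, method = "Nelder-Mead",
            control = list(maxit = lv$maxit, reltol = 1e-8,
                           parscale = scales)),
      error = function(e) NULL
    )
    if (is.null(fit)) { ok <- FALSE; break }
    par <- fit$par
  }

  id_score <- ncc(as.numeric(ref), sample_moving(moving, geom, par0))
  final_score <- if (ok) ncc(as.numeric(ref), sample_moving(moving, geom, par)) else -1
  if (!ok || !is.finite(final_score) || final_score < id_score - 1e-6) {
    warning("registration did not improve on identity; falling back to identity transform")
    par <- par0
  }
  vals <- sample_moving(moving, geom, par)
  vals[!is.finite(vals)] <- 0
  vals <- pmax(vals, 0)
  list(par = par, resampled = array(vals, geom$dim))
}
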