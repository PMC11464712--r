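# Internal geometry helpers. Conventions used throughout the package:
#  * R arrays are indexed 1-based; the NIfTI affine maps 0-based voxel
#    indices to world millimetres, so world = A %*% c(i - 1, j - 1, k - 1, 1).
#  * All angles and lengths are computed in the world frame; angles are
#    reported in degrees.

RAD2DEG <- 180 / pi

vnorm <- function(x) sqrt(sum(x^2))

unit <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  x / n
}

#' @noRd
#' Flip the sign of an axial direction so its first component of
#' non-negligible magnitude is positive. Fiber directions are axial (v and
#' -v are the same fiber), so a deterministic representative is chosen.
canonical_sign <- function(v, tol = 1e-12) {
  for (x in v) {
    if (abs(x) > tol) {
      if (x < 0) return(-v)
      return(v)
    }
  }
  v
}

angle_between_deg <- function(a, b) {
  ca <- sum(unit(a) * unit(b))
  acos(max(-1, min(1, ca))) * RAD2DEG
}

# Default affine for a synthetic grid: scaling by voxel size, optional origin.
affine_from_voxel_size <- function(voxel_size, origin = c(0, 0, 0)) {
  A <- diag(4)
  A[1, 1] <- voxel_size[1]
  A[2, 2] <- voxel_size[2]
  A[3, 3] <- voxel_size[3]
  A[1:3, 4] <- origin
  A
}

# idx0: N x 3 matrix of 0-based (possibly fractional) voxel coordinates.
vox0_to_world <- function(affine, idx0) {
  idx0 <- rbind_points(idx0)
  w <- affine %*% rbind(t(idx0), 1)
  t(w[1:3, , drop = FALSE])
}

world_to_vox0 <- function(affine, pts) {
  pts <- rbind_points(pts)
  v <- solve(affine) %*% rbind(t(pts), 1)
  t(v[1:3, , drop = FALSE])
}

rbind_points <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else p
}

# Unit world-frame direction of the through-plane (slice-select) axis.
plane_normal_from_affine <- function(affine, slice_axis = 3L) {
  unit(affine[1:3, slice_axis])
}

voxel_size_from_affine <- function(affine) {
  apply(affine[1:3, 1:3], 2, vnorm)
}

# Trilinear interpolation of a 3D array at 0-based continuous voxel
# coordinates (N x 3). Returns NA for points outside [0, dim - 1].
interp_trilinear <- function(arr, u) {
  u <- rbind_points(u)
  d <- dim(arr)
  n <- nrow(u)
  out <- rep(NA_real_, n)
  inside <- u[, 1] >= 0 & u[, 1] <= d[1] - 1 &
    u[, 2] >= 0 & u[, 2] <= d[2] - 1 &
    u[, 3] >= 0 & u[, 3] <= d[3] - 1
  if (!any(inside)) return(out)
  uu <- u[inside, , drop = FALSE]
  i0 <- pmin(floor(uu[, 1]), d[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(uu[, 2]), d[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(uu[, 3]), d[3] - 2); k0 <- pmax(k0, 0)
  fx <- uu[, 1] - i0; fy <- uu[, 2] - j0; fz <- uu[, 3] - k0
  base <- function(i, j, k) 1 + i + d[1] * (j + d[2] * k)
  v <- numeric(sum(inside))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di == 1) fx else 1 - fx) *
      (if (dj == 1) fy else 1 - fy) *
      (if (dk == 1) fz else 1 - fz)
    v <- v + w * arr[base(i0 + di, j0 + dj, k0 + dk)]
  }
  out[inside] <- v
  out
}

# Block-mean downsampling by an integer factor per axis (for the
# multi-resolution registration pyramid). Trailing voxels that do not fill
# a complete block are dropped.
downsample_block_mean <- function(arr, factor = 2L) {
  d <- dim(arr)
  nd <- d %/% factor
  if (any(nd < 2)) return(arr)
  arr <- arr[seq_len(nd[1] * factor), seq_len(nd[2] * factor), seq_len(nd[3] * factor), drop = FALSE]
  dim(arr) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  out <- apply(arr, c(2, 4, 6), mean)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
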