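#' Design matrix of the log-linear diffusion tensor model
#'
#' Under the monoexponential tensor model the log-signal is linear in the
#' tensor elements: ln S = ln S0 - b g' D g. Each volume contributes one row
#' mapping the coefficient vector (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) to
#' its log-signal; b = 0 rows have zero diffusion entries. At least 7
#' volumes with at least 6 non-collinear diffusion-weighted directions are
#' required for the system to be determined.
#'
#' @param table A [gradient_table].
#' @return Numeric matrix (n_volumes x 7) with columns
#'   `lnS0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz`.
#' @export
dti_design_matrix <- function(table) {
  b <- table$b
  g <- bvec_matrix(table)
  X <- cbind(
    1,
    -b * g[, 1]^2,
    -b * g[, 2]^2,
    -b * g[, 3]^2,
    -2 * b * g[, 1] * g[, 2],
    -2 * b * g[, 1] * g[, 3],
    -2 * b * g[, 2] * g[, 3]
  )
  colnames(X) <- c("lnS0", "Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  if (nrow(X) < 7 || qr(X)$rank < 7) {
    stop("gradient scheme underdetermined: need >= 7 volumes spanning >= 6 non-collinear b > 0 directions")
  }
  X
}

#' Fit a diffusion tensor per voxel
#'
#' Ordinary least squares on log-signals per masked voxel (the transparent
#' baseline estimator; weighted least squares — with weights equal to the
#' squared predicted signals, the usual first-order variance model for
#' log-transformed Rician magnitude data — is available via
#' `method = "wls"`). Non-positive samples cannot be log-transformed and
#' are excluded from a voxel's fit; if fewer than 7 usable samples remain,
#' the signal is floored at 1e-6 of the voxel's mean b = 0 signal and the
#' voxel is flagged invalid. The eigen-system is computed per voxel with
#' eigenvalues sorted descending and each eigenvector sign-canonicalized
#' (first non-negligible component positive), since fiber orientation is
#' axial.
#'
#' @param stack A [dwi_stack], already registered to the b = 0 reference.
#' @param table The matching [gradient_table].
#' @param mask Logical 3D array selecting voxels to fit. Default: voxels
#'   whose mean b = 0 signal exceeds an Otsu threshold.
#' @param method `"ols"` (default) or `"wls"`.
#' @return An object of class `dti_field` with per-voxel arrays: `coef`
#'   (i, j, k, 7), `evals` (i, j, k, 3), `evecs` (i, j, k, 3, 3; last index
#'   selects the eigenvector), `valid`, `mask`, plus the affine and the fit
#'   metadata.
#' @export
fit_tensor <- function(stack, table, mask = NULL, method = c("ols", "wls")) {
  method <- match.arg(method)
  d <- dim(stack$data)
  nvol <- d[4]
  if (nvol != nrow(table)) {
    stop(sprintf("stack has %d volumes but gradient table has %d entries", nvol, nrow(table)))
  }
  X <- dti_design_matrix(table)
  if (is.null(mask)) mask <- default_b0_mask(stack, table)
  if (!is.logical(mask)) mask <- array(mask > 0, dim = dim(mask))
  if (!all(dim(mask) == d[1:3])) stop("mask dimensions do not match the stack")
  sel <- which(mask)
  if (!length(sel)) stop("mask is empty: no voxels to fit")

  nvox <- prod(d[1:3])
  V <- matrix(stack$data, nvox, nvol)
  S <- V[sel, , drop = FALSE]
  b0mean <- rowMeans(S[, table$b == 0, drop = FALSE])
  if (!any(table$b == 0)) b0mean <- rowMeans(S)

  coef <- matrix(NA_real_, length(sel), 7)
  valid <- rep(TRUE, length(sel))

  pos <- S > 0
  allpos <- rowSums(pos) == nvol
  P <- solve(crossprod(X), t(X))  # 7 x nvol pseudo-inverse (full rank checked)

  if (any(allpos)) {
    B <- log(S[allpos, , drop = FALSE])
    if (method == "ols") {
      coef[allpos, ] <- tcrossprod(B, P)
    } else {
      idx <- which(allpos)
      for (ii in seq_along(idx)) {
        coef[idx[ii], ] <- wls_fit(X, B[ii, ], S[idx[ii], ])
      }
    }
  }
  for (i in which(!allpos)) {
    use <- pos[i, ]
    si <- S[i, ]
    if (sum(use) >= 7 && qr(X[use, , drop = FALSE])$rank == 7) {
      yi <- log(si[use])
      Xi <- X[use, , drop = FALSE]
      coef[i, ] <- if (method == "ols") {
        qr.solve(Xi, yi)
      } else {
        wls_fit(Xi, yi, si[use])
      }
    } else {
      floor_val <- 1e-6 * max(b0mean[i], .Machine$double.eps)
      yi <- log(pmax(si, floor_val))
      coef[i, ] <- if (method == "ols") qr.solve(X, yi) else wls_fit(X, yi, pmax(si, floor_val))
      valid[i] <- FALSE
    }
  }

  evals <- matrix(NA_real_, length(sel), 3)
  evecs <- array(NA_real_, c(length(sel), 3, 3))
  for (i in seq_along(sel)) {
    Dm <- tensor_from_coef(coef[i, ])
    if (any(!is.finite(Dm))) { valid[i] <- FALSE; next }
    es <- eigen(Dm, symmetric = TRUE)
    evals[i, ] <- es$values
    for (j in 1:3) evecs[i, , j] <- canonical_sign(es$vectors[, j])
  }

  shape <- d[1:3]
  field <- list(
    coef = fill_array(coef, shape, sel, 7),
    evals = fill_array(evals, shape, sel, 3),
    evecs = fill_array(matrix(evecs, length(sel), 9), shape, sel, c(3, 3)),
    valid = fill_array(matrix(valid, ncol = 1), shape, sel, NULL, fill = FALSE, logical = TRUE),
    mask = mask,
    affine = stack$affine,
    slice_axis = stack$slice_axis,
    method = method
  )
  class(field) <- "dti_field"
  field
}

wls_fit <- function(X, y, s) {
  w <- s^2
  XtW <- t(X * w)
  as.numeric(solve(XtW %*% X, XtW %*% y))
}

tensor_from_coef <- function(cf) {
  matrix(c(cf[2], cf[5], cf[6],
           cf[5], cf[3], cf[7],
           cf[6], cf[7], cf[4]), 3, 3)
}

fill_array <- function(vals, shape, sel, extra, fill = NA_real_, logical = FALSE) {
  if (is.null(extra)) {
    out <- array(if (logical) as.logical(fill) else fill, dim = shape)
    out[sel] <- vals[, 1]
    return(out)
  }
  n_extra <- prod(extra)
  out <- array(fill, dim = c(shape, extra))
  nvox <- prod(shape)
  for (j in seq_len(n_extra)) {
    idx <- sel + (j - 1) * nvox
    out[idx] <- vals[, j]
  }
  out
}

#' @export
print.dti_field <- function(x, ...) {
  cat(sprintf("<dti_field> %s grid, %d voxels fitted (%d valid), %s estimator\n",
              paste(dim(x$valid), collapse = " x "),
              sum(x$mask), sum(x$valid, na.rm = TRUE), toupper(x$method)))
  invisible(x)
}

# Foreground mask from the mean b = 0 image via Otsu's threshold.
default_b0_mask <- function(stack, table) {
  b0 <- which(table$b == 0)
  if (!length(b0)) stop("cannot build a default mask: no b = 0 volume present")
  m <- apply(stack$data[, , , b0, drop = FALSE], 1:3, mean)
  rng <- range(m)
  if (diff(rng) == 0) return(array(TRUE, dim = dim(m)))
  norm <- (m - rng[1]) / diff(rng)
  thr <- EBImage::otsu(matrix(norm, nrow = dim(m)[1]), range = c(0, 1))
  array(norm > thr, dim = dim(m))
}

#' First eigenvector at a voxel
#' @param field A `dti_field`.
#' @param i,j,k 1-based voxel indices.
#' @return Unit 3-vector (world frame) or NAs where not fitted.
#' @export
principal_eigenvector <- function(field, i, j, k) {
  field$evecs[i, j, k, , 1]
}

#' Scalar maps (FA and MD) from a fitted tensor field
#'
#' Mean diffusivity is the eigenvalue average; fractional anisotropy is
#' `sqrt(3/2) * ||lambda - MD|| / ||lambda||` with negative eigenvalues
#' clamped to zero inside the FA computation only (the field keeps raw
#' eigenvalues). Voxels flagged invalid map to NaN.
#'
#' @param field A `dti_field`.
#' @return A list of class `scalar_maps` with 3D arrays `fa` and `md`.
#' @export
scalar_maps <- function(field) {
  shape <- dim(field$valid)
  nvox <- prod(shape)
  ev <- matrix(field$evals, nvox, 3)
  md <- rowMeans(ev)
  evc <- pmax(ev, 0)
  mdc <- rowMeans(evc)
  num <- sqrt(rowSums((evc - mdc)^2))
  den <- sqrt(rowSums(evc^2))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  bad <- !as.vector(field$valid)
  fa[bad] <- NaN
  md[bad] <- NaN
  structure(list(fa = array(fa, shape), md = array(md, shape), affine = field$affine),
            class = "scalar_maps")
}
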