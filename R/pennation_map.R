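#' Tendon direction from annotation vertices
#'
#' The tendon line is drawn as an ordered polyline on a single slice; its
#' direction is the principal axis of the vertex scatter (a total
#' least-squares line through the in-plane world-frame vertices), embedded
#' in 3D with zero through-plane component. One global direction is used
#' per slice — the measurement convention is a single angle against the
#' drawn tendon, not a local tangent. The sign is canonicalized (the
#' direction is axial).
#'
#' @param vertices Matrix of in-plane 0-based voxel coordinates (n x 2).
#' @param affine 4x4 voxel-to-world matrix.
#' @param slice_axis Through-plane voxel axis.
#' @param slice 1-based slice index the polyline lies on.
#' @return Unit 3-vector in the world frame, orthogonal to the plane normal.
#' @export
fit_tendon_direction <- function(vertices, affine, slice_axis = 3L, slice = 1L) {
  vertices <- as.matrix(vertices)
  if (nrow(unique(round(vertices, 9))) < 2) {
    stop("tendon direction undefined: all vertices coincide")
  }
  in_plane <- setdiff(1:3, slice_axis)
  vox <- matrix(0, nrow(vertices), 3)
  vox[, in_plane] <- vertices
  vox[, slice_axis] <- slice - 1
  w <- vox0_to_world(affine, vox)
  n <- plane_normal_from_affine(affine, slice_axis)
  # remove any through-plane component (oblique affines) before the TLS fit
  w_in <- w - outer(as.numeric(w %*% n), n)
  pc <- prcomp(w_in, center = TRUE, scale. = FALSE)
  t_dir <- pc$rotation[, 1]
  t_dir <- t_dir - sum(t_dir * n) * n
  canonical_sign(unit(t_dir))
}

#' Pennation angle of a fiber direction against the tendon
#'
#' The first eigenvector `v` is projected onto the imaging plane
#' (`v_p = v - (v . n) n`) and the angle between the projection and the
#' tendon direction is returned in degrees, folded into \[0, 90\] via the
#' absolute dot product (fibers are axial, so v and -v are the same
#' fiber). A fiber perpendicular to the plane (|v_p| < 1e-6) has no
#' defined in-plane direction and yields NaN.
#'
#' @param v Unit fiber direction (3-vector, world frame).
#' @param tendon Unit tendon direction, orthogonal to `normal`.
#' @param normal Unit plane normal (through-plane direction, world frame).
#' @return Angle in degrees in \[0, 90\], or NaN for a degenerate projection.
#' @export
pennation_angle <- function(v, tendon, normal) {
  for (nm in list(v = v, tendon = tendon, normal = normal)) {
    if (length(nm) != 3) stop("directions must be 3-vectors")
  }
  if (abs(vnorm(v) - 1) > 1e-3) stop("`v` must be a unit vector")
  if (abs(vnorm(tendon) - 1) > 1e-3) stop("`tendon` must be a unit vector")
  if (abs(vnorm(normal) - 1) > 1e-3) stop("`normal` must be a unit vector")
  if (abs(sum(tendon * normal)) > 1e-6) {
    stop("tendon direction must lie in the imaging plane (tendon . normal != 0)")
  }
  vp <- v - sum(v * normal) * normal
  np <- vnorm(vp)
  if (np < 1e-6) return(NaN)
  ca <- abs(sum(vp * tendon)) / np
  acos(min(1, ca)) * RAD2DEG
}

#' Compute the 2D pennation-angle map of a slice
#'
#' Applies [pennation_angle] to the first eigenvector of every masked,
#' valid voxel of the annotation slice, against the single global tendon
#' direction of the annotation. Invalid or unmasked voxels map to NaN.
#'
#' @param field A `dti_field` from [fit_tensor].
#' @param annotation A `tendon_annotation` on a slice of the field's grid.
#' @param mask Optional logical 3D array overriding the field's mask.
#' @return An object of class `pa_map`: the in-plane angle matrix
#'   (degrees), slice index, tendon direction and plane normal used.
#' @export
compute_pa_map <- function(field, annotation, mask = NULL) {
  shape <- dim(field$valid)
  ax <- annotation$slice_axis
  if (ax != field$slice_axis) {
    stop("annotation slice axis does not match the field's slice axis")
  }
  k <- annotation$slice
  if (k < 1 || k > shape[ax]) {
    stop(sprintf("annotation slice %d outside volume (1..%d)", k, shape[ax]))
  }
  t_dir <- annotation$direction %||%
    fit_tendon_direction(annotation$vertices, field$affine, ax, k)
  n <- plane_normal_from_affine(field$affine, ax)
  t_dir <- canonical_sign(unit(t_dir - sum(t_dir * n) * n))

  mask <- mask %||% field$mask
  slice_index <- slice.index(array(0, shape), ax)
  on_slice <- which(slice_index == k & mask & field$valid)
  in_plane <- setdiff(1:3, ax)
  pa <- matrix(NaN, shape[in_plane[1]], shape[in_plane[2]])
  if (!length(on_slice)) {
    warning("mask is empty on the annotation slice; pennation map is all NaN")
  } else {
    idx <- arrayInd(on_slice, shape)
    nvox <- prod(shape)
    # evecs layout: (i, j, k, component, eigenvector); eigenvector 1 occupies
    # the first three component planes
    e1 <- cbind(field$evecs[on_slice], field$evecs[on_slice + nvox],
                field$evecs[on_slice + 2 * nvox])
    for (r in seq_len(nrow(idx))) {
      pa[idx[r, in_plane[1]], idx[r, in_plane[2]]] <-
        pennation_angle(unit(e1[r, ]), t_dir, n)
    }
  }
  structure(
    list(pa = pa, slice = k, slice_axis = ax, tendon_direction = t_dir,
         plane_normal = n, affine = field$affine),
    class = "pa_map"
  )
}

#' @export
print.pa_map <- function(x, ...) {
  v <- x$pa[is.finite(x$pa)]
  cat(sprintf("<pa_map> slice %d, %d finite voxels", x$slice, length(v)))
  if (length(v)) cat(sprintf(", PA %.1f-%.1f deg", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Aggregate a pennation-angle map over regions of interest
#'
#' NaN-excluding mean, standard deviation and voxel count of the PA map per
#' ROI label on the map's slice. Labels whose voxels are all NaN are
#' dropped with a warning.
#'
#' @param map A `pa_map`.
#' @param rois 3D integer label array on the same grid (0 = background), or
#'   the list returned by [read_roi_labels].
#' @return A tibble with columns `label`, `mean_pa`, `sd_pa`, `n_voxels`.
#' @export
summarize_rois <- function(map, rois) {
  if (is.list(rois) && !is.null(rois$labels)) rois <- rois$labels
  in_plane <- setdiff(1:3, map$slice_axis)
  full_dim <- dim(rois)
  if (!all(full_dim[in_plane] == dim(map$pa))) {
    stop("ROI label map grid does not match the pennation map")
  }
  roi_slice <- extract_slice(rois, map$slice_axis, map$slice)
  labels <- sort(setdiff(unique(as.integer(roi_slice)), 0L))
  rows <- lapply(labels, function(lb) {
    v <- map$pa[roi_slice == lb]
    v <- v[is.finite(v)]
    if (!length(v)) return(NULL)
    tibble::tibble(label = lb, mean_pa = mean(v), sd_pa = stats::sd(v), n_voxels = length(v))
  })
  dropped <- labels[vapply(rows, is.null, logical(1))]
  if (length(dropped)) {
    warning("ROI label(s) with no finite pennation values dropped: ",
            paste(dropped, collapse = ", "))
  }
  dplyr::bind_rows(rows)
}

extract_slice <- function(arr, axis, k) {
  switch(axis,
         `1` = arr[k, , ],
         `2` = arr[, k, ],
         `3` = arr[, , k])
}
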