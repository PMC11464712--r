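#' Construct a diffusion-weighted image stack
#'
#' A `dwi_stack` holds a 4D signal array (i, j, k, volume), the NIfTI
#' voxel-to-world affine (mapping 0-based voxel indices to millimetres) and
#' the index of the through-plane (slice-select) voxel axis. All geometry in
#' the package — tendon directions, pennation angles, streamline lengths —
#' is computed in the world frame defined by this affine.
#'
#' @param data 4D numeric array, dimensions (i, j, k, volume). Negative
#'   intensities are clamped to zero (magnitude MRI data is non-negative).
#' @param affine 4x4 voxel-to-world matrix (NIfTI convention, 0-based voxel
#'   indices); must be invertible.
#' @param slice_axis Index (1-3) of the through-plane voxel axis.
#' @return An object of class `dwi_stack`.
#' @export
dwi_stack <- function(data, affine = NULL, slice_axis = 3L) {
  if (length(dim(data)) != 4) stop("`data` must be a 4D array (i, j, k, volume)")
  if (is.null(affine)) affine <- diag(4)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) stop("`affine` must be a 4x4 matrix")
  if (abs(det(affine)) < 1e-12) stop("`affine` is not invertible")
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) stop("`slice_axis` must be 1, 2 or 3")
  vs <- voxel_size_from_affine(affine)
  if (any(vs <= 0)) stop("voxel sizes derived from the affine must be positive")
  data[data < 0] <- 0
  structure(
    list(data = data, affine = affine, voxel_size = vs, slice_axis = slice_axis),
    class = "dwi_stack"
  )
}

#' @export
print.dwi_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<dwi_stack> %d x %d x %d voxels, %d volumes, voxel size %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], d[4], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]
  ))
  invisible(x)
}

#' Construct a gradient table
#'
#' Per-volume diffusion weighting: b-values in s/mm^2 and unit gradient
#' directions. Directions of b > 0 volumes must have unit norm; they are
#' re-normalized when within 1e-3 of unit length and rejected beyond that.
#' Directions of b = 0 volumes may be zero vectors.
#'
#' @param bvals Numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs Numeric matrix, one row per volume, columns (x, y, z).
#' @return A tibble of class `gradient_table` with columns `b`, `gx`, `gy`, `gz`.
#' @export
gradient_table <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3) stop("`bvecs` must have 3 columns")
  if (length(bvals) != nrow(bvecs)) {
    stop(sprintf(
      "gradient table length mismatch: %d b-values but %d directions",
      length(bvals), nrow(bvecs)
    ))
  }
  if (any(bvals < 0)) stop("b-values must be non-negative")
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > 0
  bad <- dw & abs(nrm - 1) > 1e-3
  if (any(bad)) {
    stop(sprintf(
      "non-unit gradient direction(s) at volume(s) %s (|norm - 1| > 1e-3)",
      paste(which(bad), collapse = ", ")
    ))
  }
  fix <- dw & nrm > 0
  bvecs[fix, ] <- bvecs[fix, , drop = FALSE] / nrm[fix]
  out <- tibble::tibble(b = as.numeric(bvals), gx = bvecs[, 1], gy = bvecs[, 2], gz = bvecs[, 3])
  class(out) <- c("gradient_table", class(out))
  out
}

bvec_matrix <- function(table) cbind(table$gx, table$gy, table$gz)

#' Read a diffusion-weighted volume with its FSL-style gradient table
#'
#' Loads a 4D NIfTI volume together with `.bval`/`.bvec` text files (FSL
#' dialect: b-values on one line; directions as three lines of x, y, z
#' components). The number of table entries must match the number of
#' volumes.
#'
#' @param volume_path Path to a 4D NIfTI file.
#' @param bval_path Path to the b-value text file.
#' @param bvec_path Path to the gradient-direction text file (3 x N).
#' @param slice_axis Through-plane voxel axis (default 3).
#' @return A list with elements `stack` (a [dwi_stack]) and `gradients`
#'   (a [gradient_table]).
#' @export
read_dwi <- function(volume_path, bval_path, bvec_path, slice_axis = 3L) {
  for (p in c(volume_path, bval_path, bvec_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  img <- RNifti::readNifti(volume_path)
  if (length(dim(img)) != 4) stop("expected a 4D volume, got ", length(dim(img)), "D")
  affine <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  affine <- matrix(as.numeric(affine), 4, 4)
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- scan(bvec_path, quiet = TRUE)
  if (length(bv) %% 3 != 0) stop("bvec file does not contain a 3 x N table")
  bvecs <- t(matrix(bv, nrow = 3, byrow = TRUE))
  nvol <- dim(img)[4]
  if (length(bvals) != nvol) {
    stop(sprintf("volume count (%d) does not match b-value count (%d)", nvol, length(bvals)))
  }
  if (nrow(bvecs) != nvol) {
    stop(sprintf("volume count (%d) does not match direction count (%d)", nvol, nrow(bvecs)))
  }
  list(
    stack = dwi_stack(array(as.numeric(img), dim = dim(img)), affine, slice_axis),
    gradients = gradient_table(bvals, bvecs)
  )
}

#' Write a diffusion-weighted stack with its gradient table
#'
#' @param stack A [dwi_stack].
#' @param gradients A [gradient_table].
#' @param volume_path,bval_path,bvec_path Output paths.
#' @return Invisibly, `volume_path`.
#' @export
write_dwi <- function(stack, gradients, volume_path, bval_path, bvec_path) {
  write_nifti_array(stack$data, stack$affine, volume_path)
  cat(paste(format(gradients$b, scientific = FALSE, trim = TRUE), collapse = " "),
    "\n", sep = "", file = bval_path)
  g <- bvec_matrix(gradients)
  writeLines(apply(t(g), 1, function(r) paste(format(r, digits = 17), collapse = " ")), bvec_path)
  invisible(volume_path)
}

write_nifti_array <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::pixdim(img) <- voxel_size_from_affine(affine)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D NIfTI label map of regions of interest
#'
#' @param path Path to a 3D NIfTI file with non-negative integer labels
#'   (0 = background).
#' @return A list with `labels` (3D integer array) and `affine`.
#' @export
read_roi_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3) stop("ROI label map must be 3D")
  if (any(arr < 0) || any(abs(arr - round(arr)) > 1e-6)) {
    stop("ROI labels must be non-negative integers")
  }
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  list(labels = array(as.integer(round(arr)), dim = dim(arr)), affine = affine)
}

#' Write a 3D label map as NIfTI
#' @param labels 3D integer array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param path Output path.
#' @export
write_roi_labels <- function(labels, affine, path) {
  write_nifti_array(labels, affine, path)
}

#' Tendon annotation: a polyline drawn on one slice
#'
#' The tendon is annotated as an ordered polyline of in-plane points on a
#' named slice of the b = 0 image. Vertices are 0-based voxel coordinates in
#' the two in-plane axes (the through-plane axis is excluded). The unit
#' tendon direction in the world frame is derived by [fit_tendon_direction]
#' when an affine is available.
#'
#' @param slice 1-based slice index.
#' @param vertices Numeric matrix, one row per vertex, two columns of
#'   in-plane 0-based voxel coordinates. At least two distinct vertices.
#' @param slice_axis Through-plane voxel axis (default 3).
#' @param affine Optional 4x4 affine; when given, the world-frame tendon
#'   direction is computed and stored in `$direction`.
#' @return An object of class `tendon_annotation`.
#' @export
tendon_annotation <- function(slice, vertices, slice_axis = 3L, affine = NULL) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2) stop("`vertices` must have two in-plane columns")
  if (nrow(unique(round(vertices, 9))) < 2) {
    stop("tendon annotation needs at least 2 distinct vertices")
  }
  slice <- as.integer(slice)
  if (slice < 1) stop("`slice` must be a positive 1-based index")
  obj <- structure(
    list(slice = slice, vertices = vertices, slice_axis = as.integer(slice_axis),
         direction = NULL, plane_normal = NULL),
    class = "tendon_annotation"
  )
  if (!is.null(affine)) {
    obj$direction <- fit_tendon_direction(vertices, affine, slice_axis, slice)
    obj$plane_normal <- plane_normal_from_affine(affine, slice_axis)
  }
  obj
}

#' Read a tendon annotation file
#'
#' The annotation is a small YAML file with fields `slice` (1-based slice
#' index), `slice_axis`, and `vertices` (a list of `[x, y]` in-plane 0-based
#' voxel coordinates). All vertices lie on the single named slice; an
#' annotation spanning several slices is rejected.
#'
#' @param path Path to the annotation file.
#' @param affine Optional affine used to derive the world-frame direction.
#' @return A `tendon_annotation`.
#' @export
read_tendon_annotation <- function(path, affine = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$slice) || is.null(doc$vertices)) {
    stop("annotation file must contain `slice` and `vertices`")
  }
  if (length(doc$slice) != 1) stop("tendon annotation must lie on a single slice")
  verts <- do.call(rbind, lapply(doc$vertices, function(v) {
    if (length(v) != 2) stop("each vertex must be an [x, y] pair")
    as.numeric(v)
  }))
  tendon_annotation(doc$slice, verts, doc$slice_axis %||% 3L, affine)
}

#' Write a tendon annotation file
#' @param annotation A `tendon_annotation`.
#' @param path Output path.
#' @export
write_tendon_annotation <- function(annotation, path) {
  yaml::write_yaml(
    list(
      slice = annotation$slice,
      slice_axis = annotation$slice_axis,
      vertices = lapply(seq_len(nrow(annotation$vertices)),
                        function(i) as.numeric(annotation$vertices[i, ]))
    ),
    path
  )
  invisible(path)
}

#' Read a ratings table
#'
#' Long-format pennation-angle measurements indexed by subject, rater and
#' session (CSV with header `subject,rater,session,value`; an optional
#' `occasion` column distinguishes repeated reading sessions of one rater
#' for intra-reader designs). Duplicate (subject, rater, session
#' \[, occasion\]) records and non-finite values are rejected.
#'
#' @param path Path to the CSV file.
#' @return A tibble with the ratings.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ratings(tibble::as_tibble(df))
}

validate_ratings <- function(df) {
  need <- c("subject", "rater", "session", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ratings table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(df$value))) stop("ratings values must be finite")
  keys <- intersect(c("subject", "rater", "session", "occasion"), names(df))
  if (anyDuplicated(df[keys])) stop("duplicate (subject, rater, session) records in ratings table")
  df
}

#' Write a ratings table as CSV
#' @param ratings Tibble with columns subject, rater, session, value.
#' @param path Output path.
#' @export
write_ratings <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' Streamline sets and their on-disk format
#'
#' Streamlines are ordered 3D point sequences in world millimetres. On disk
#' they use the TCK track format (text header followed by little-endian
#' 32-bit float triplets, streamlines separated by NaN triplets and the file
#' terminated by an Inf triplet), which standard tractography viewers read.
#'
#' @param streamlines List of numeric matrices (n_points x 3), world mm.
#' @param step_size Step size in mm used to generate the streamlines
#'   (optional, stored for length accounting).
#' @return An object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines, step_size = NA_real_) {
  for (s in streamlines) {
    if (!is.matrix(s) || ncol(s) != 3) stop("each streamline must be an n x 3 matrix")
    if (!all(is.finite(s))) stop("streamline contains non-finite points")
  }
  lengths <- vapply(streamlines, function(s) {
    if (nrow(s) < 2) return(0)
    sum(sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2)))
  }, numeric(1))
  structure(list(streamlines = streamlines, lengths = lengths, step_size = step_size),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d streamlines", length(x$streamlines)))
  if (length(x$lengths)) {
    cat(sprintf(", length %.1f-%.1f mm", min(x$lengths), max(x$lengths)))
  }
  cat("\n")
  invisible(x)
}

#' @rdname streamline_set
#' @param set A `streamline_set`.
#' @param path Output path (conventionally `.tck`).
#' @export
write_streamlines <- function(set, path) {
  if (!inherits(set, "streamline_set")) set <- streamline_set(set)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    "mrtrix tracks\ndatatype: Float32LE\ncount: ", length(set$streamlines), "\n"
  )
  # 'file: . <offset>' points at the first byte of binary data; the offset
  # depends on its own width, so fix the header size after composing it.
  offset <- nchar(header) + nchar("file: . \nEND\n")
  repeat {
    line <- paste0("file: . ", offset, "\n")
    total <- nchar(header) + nchar(line) + nchar("END\n")
    if (total == offset) break
    offset <- total
  }
  writeChar(paste0(header, "file: . ", offset, "\nEND\n"), con, eos = NULL)
  for (s in set$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname streamline_set
#' @export
read_streamlines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  # header is the text up to (and including) the END line; stop before the
  # binary section to avoid embedded NULs
  end_pat <- charToRaw("END\n")
  header_len <- NA_integer_
  for (i in seq_len(min(4096, length(raw_all)) - 3)) {
    if (identical(raw_all[i:(i + 3)], end_pat)) { header_len <- i + 3L; break }
  }
  if (is.na(header_len)) stop("TCK header terminator not found")
  txt <- rawToChar(raw_all[seq_len(header_len)])
  if (!startsWith(txt, "mrtrix tracks")) stop("not a TCK streamline file: ", path)
  m <- regmatches(txt, regexpr("file: \\. [0-9]+", txt))
  if (!length(m)) stop("TCK header missing data offset")
  offset <- as.integer(sub("file: \\. ", "", m))
  vals <- readBin(raw_all[(offset + 1):length(raw_all)], "numeric",
                  n = (length(raw_all) - offset) / 4, size = 4, endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  streams <- list()
  cur <- NULL
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    if (all(is.infinite(p))) break
    if (all(is.nan(p))) {
      streams[[length(streams) + 1]] <- cur %||% matrix(numeric(0), 0, 3)
      cur <- NULL
    } else {
      cur <- rbind(cur, p)
    }
  }
  streamline_set(streams)
}
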