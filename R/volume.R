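#' 3D intensity volume
#'
#' A `vssl_volume` wraps a 3D numeric array in `(z, y, x)` axis order (0-based,
#' half-open window conventions are used throughout the package) together with
#' per-axis voxel spacing in micrometres and, for crops, the voxel offset of
#' the crop origin inside its parent volume.  Spacing is carried as opaque
#' metadata: nothing in the package uses it numerically.
#'
#' @param data 3D numeric array, axis order (z, y, x); all values finite.
#' @param spacing numeric length-3, voxel size per axis in micrometres.
#' @param origin_offset integer length-3, 0-based voxel offset relative to the
#'   parent volume (all zeros for a root volume).
#' @return an object of class `vssl_volume`.
#' @export
new_volume <- function(data, spacing = c(2.5, 2.5, 2.5), origin_offset = c(0L, 0L, 0L)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("volume data must be a 3D array, got %s", paste(dim(data), collapse = "x"))
  if (any(dim(data) <= 0L)) stopf("volume shape must be strictly positive")
  if (!all(is.finite(data))) stopf("volume contains non-finite values")
  structure(
    list(data = data, spacing = as.numeric(spacing),
         origin_offset = as.integer(origin_offset)),
    class = "vssl_volume")
}

#' @export
print.vssl_volume <- function(x, ...) {
  cat(sprintf("<vssl_volume %s, spacing %s um, offset (%s), range [%.4g, %.4g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ","),
              paste(x$origin_offset, collapse = ","),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.vssl_volume <- function(x) dim(x$data)

as_volume <- function(x, ...) {
  if (inherits(x, "vssl_volume")) x else new_volume(x, ...)
}

#' Sparse label volume
#'
#' Binary vessel mask paired with a per-slice indicator of which z-slices carry
#' human-placed annotation.  Shape follows the paired intensity volume.
#'
#' @param mask binary 3D array (z, y, x), values in \{0, 1\}.
#' @param annotated_slices logical vector of length `dim(mask)[1]`; which
#'   z-slices are annotated.  Defaults to all slices (dense ground truth).
#' @param origin_offset as in [new_volume()].
#' @return an object of class `vssl_labels`.
#' @export
new_labels <- function(mask, annotated_slices = NULL, origin_offset = c(0L, 0L, 0L)) {
  if (!is.array(mask) || length(dim(mask)) != 3L) stopf("label mask must be a 3D array")
  if (!is_binary(mask)) stopf("label mask must be binary (0/1)")
  nz <- dim(mask)[1]
  if (is.null(annotated_slices)) annotated_slices <- rep(TRUE, nz)
  if (length(annotated_slices) != nz)
    stopf("annotated_slices has length %d but mask has %d slices",
          length(annotated_slices), nz)
  structure(
    list(mask = mask, annotated_slices = as.logical(annotated_slices),
         origin_offset = as.integer(origin_offset)),
    class = "vssl_labels")
}

#' @export
print.vssl_labels <- function(x, ...) {
  cat(sprintf("<vssl_labels %s, %d/%d slices annotated, %.4f%% labeled>\n",
              paste(dim(x$mask), collapse = "x"),
              sum(x$annotated_slices), length(x$annotated_slices),
              100 * mean(x$mask)))
  invisible(x)
}

as_mask_array <- function(labels) {
  if (inherits(labels, "vssl_labels")) labels$mask
  else if (is.array(labels)) labels
  else stopf("expected a vssl_labels object or a 3D array")
}

#' Assemble ordered 2D slices into a volume
#'
#' Slice `i` of the input list becomes z-index `i` of the volume (slice 1 at
#' z = 0 in 0-based terms).  Values are promoted to double.
#'
#' @param slices list of 2D numeric matrices, all with identical shape.
#' @param spacing voxel spacing metadata, see [new_volume()].
#' @return a [new_volume()] of shape `(n_slices, nrow, ncol)`.
#' @export
stack_to_volume <- function(slices, spacing = c(2.5, 2.5, 2.5)) {
  if (length(slices) == 0L) stopf("no slices supplied")
  shp <- dim(slices[[1]])
  if (is.null(shp) || length(shp) != 2L) stopf("slices must be 2D matrices")
  for (i in seq_along(slices)) {
    if (!identical(dim(slices[[i]]), shp))
      stopf("slice %d has shape %s, expected %s", i,
            paste(dim(slices[[i]]), collapse = "x"), paste(shp, collapse = "x"))
  }
  vol <- array(0, dim = c(length(slices), shp[1], shp[2]))
  for (i in seq_along(slices)) vol[i, , ] <- as.numeric(slices[[i]])
  new_volume(vol, spacing = spacing)
}

#' Normalize a volume
#'
#' `zscore` centres to mean 0 and scales to unit standard deviation over all
#' voxels (population sd); `minmax` rescales to `[0, 1]`.  A constant volume
#' maps to all zeros under either method.
#'
#' @param volume a [new_volume()] or 3D array.
#' @param method `"zscore"` or `"minmax"`.
#' @return a volume with the same shape and metadata.
#' @export
normalize_volume <- function(volume, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  v <- as_volume(volume)
  x <- v$data
  if (method == "zscore") {
    mu <- mean(x)
    sd0 <- sqrt(mean((x - mu)^2))
    v$data <- if (sd0 == 0) array(0, dim(x)) else (x - mu) / sd0
  } else {
    lo <- min(x); hi <- max(x)
    v$data <- if (hi == lo) array(0, dim(x)) else (x - lo) / (hi - lo)
  }
  v
}

otsu_threshold <- function(x, levels = 256L) {
  # Otsu's between-class variance maximizer on a fixed-bin histogram.
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(lo)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    return(EBImage::otsu(array(x, dim = c(length(x), 1)), range = c(lo, hi),
                         levels = levels))
  }
  h <- tabulate(pmin(levels, 1L + as.integer((x - lo) / (hi - lo) * levels)), levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  lo + (k / levels) * (hi - lo)
}

#' Crop a volume to its foreground bounding box
#'
#' Removes non-tissue margins by cropping to the tight axis-aligned bounding
#' box of voxels whose intensity exceeds a threshold.  With
#' `threshold = "auto"` the threshold is chosen by Otsu's method on the
#' intensity histogram.
#'
#' @param volume a [new_volume()] or 3D array.
#' @param threshold numeric cutoff, or `"auto"`.
#' @return a list with `volume` (the crop, with `origin_offset` updated so the
#'   crop maps back into its parent exactly) and `offset` (0-based, (z, y, x)).
#' @export
crop_foreground <- function(volume, threshold = "auto") {
  v <- as_volume(volume)
  x <- v$data
  thr <- if (identical(threshold, "auto")) otsu_threshold(x) else {
    if (!is.numeric(threshold)) stopf("threshold must be numeric or \"auto\"")
    threshold
  }
  fg <- which(x > thr, arr.ind = TRUE)
  if (nrow(fg) == 0L) stopf("no voxel above threshold %.6g: nothing to segment", thr)
  lo <- apply(fg, 2, min); hi <- apply(fg, 2, max)
  cropped <- x[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  off <- as.integer(lo - 1L)
  out <- new_volume(cropped, spacing = v$spacing,
                    origin_offset = v$origin_offset + off)
  list(volume = out, offset = off)
}

#' Read and write volumes as NIfTI
#'
#' Volumes are written with an identity orientation and the voxel spacing on
#' the affine diagonal; label volumes are written as unsigned 8-bit.  Note the
#' on-disk NIfTI axis order is (x, y, z), so the (z, y, x) in-memory array is
#' reversed on the way in and out.
#'
#' @param volume a [new_volume()] or 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  v <- as_volume(volume)
  arr <- aperm(v$data, c(3, 2, 1))          # (x, y, z) on disk
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(v$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stopf("expected a 3D NIfTI volume at %s", path)
  sp <- RNifti::pixdim(img)
  new_volume(aperm(arr, c(3, 2, 1)), spacing = rev(sp[seq_len(3)]))
}

#' @param labels a [new_labels()] object.
#' @rdname write_volume_nifti
#' @export
write_labels_nifti <- function(labels, path) {
  m <- as_mask_array(labels)
  arr <- aperm(m, c(3, 2, 1))
  img <- RNifti::asNifti(array(as.integer(arr), dim(arr)), datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_labels_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L) stopf("expected a 3D NIfTI label volume at %s", path)
  new_labels(aperm(arr, c(3, 2, 1)))
}

natural_sort <- function(paths) {
  base <- basename(paths)
  num <- suppressWarnings(as.numeric(gsub("\\D", "", base)))
  ord <- order(is.na(num), num, base)
  paths[ord]
}

#' Read an ordered TIFF slice stack as a volume
#'
#' Files are ordered by natural sort of their names (numeric runs compared as
#' numbers), then stacked with [stack_to_volume()].
#'
#' @param paths character vector of TIFF file paths, or a directory containing
#'   them.
#' @inheritParams stack_to_volume
#' @export
read_tiff_stack <- function(paths, spacing = c(2.5, 2.5, 2.5)) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.tiff?$", full.names = TRUE,
                        ignore.case = TRUE)
  if (length(paths) == 0L) stopf("no TIFF slices found")
  paths <- natural_sort(paths)
  slices <- lapply(paths, function(p) {
    s <- tiff::readTIFF(p, as.is = FALSE)
    if (length(dim(s)) == 3L) s <- s[, , 1]   # collapse greyscale-as-RGB
    s
  })
  stack_to_volume(slices, spacing = spacing)
}

#' Write a volume as an ordered TIFF slice stack
#'
#' Intensities are min-max rescaled to `[0, 1]` for storage (TIFF float in
#' that range); slice `i` is written as `slice_%04d.tif`.
#'
#' @param volume a [new_volume()] or 3D array.
#' @param dir output directory, created if needed.
#' @return the written paths, invisibly.
#' @export
write_tiff_stack <- function(volume, dir) {
  v <- as_volume(volume)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  x <- v$data
  lo <- min(x); hi <- max(x)
  xs <- if (hi == lo) array(0, dim(x)) else (x - lo) / (hi - lo)
  nz <- dim(x)[1]
  paths <- file.path(dir, sprintf("slice_%04d.tif", seq_len(nz)))
  for (i in seq_len(nz)) tiff::writeTIFF(xs[i, , ], paths[i], bits.per.sample = 32L)
  invisible(paths)
}
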