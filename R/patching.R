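#' Plan overlapping cubic patches over a volume
#'
#' Patch origins lie on a per-axis grid at multiples of `stride`; if the last
#' grid position does not make the window end exactly at the volume edge, a
#' final clamped position is appended so that the union of half-open windows
#' `[origin, origin + size)` covers every voxel.  Origins are ordered
#' lexicographically in (z, y, x).
#'
#' @param shape volume shape (z, y, x).
#' @param size cubic patch edge length, voxels.
#' @param stride per-axis step, voxels; `0 < stride <= size`.
#' @return an object of class `vssl_patchset`: list with `origins` (n x 3
#'   integer matrix, 0-based), `size`, `stride`, `source_shape`.
#' @export
plan_patches <- function(shape, size, stride = max(1L, size %/% 2L)) {
  shape <- as.integer(shape); size <- as.integer(size); stride <- as.integer(stride)
  if (stride <= 0L || stride > size) stopf("stride must satisfy 0 < stride <= size")
  if (any(size > shape))
    stopf("patch size %d exceeds volume shape (%s); pad the volume or choose a smaller size",
          size, paste(shape, collapse = "x"))
  axis_positions <- function(extent) {
    pos <- seq.int(0L, extent - size, by = stride)
    last <- extent - size
    if (pos[length(pos)] != last) pos <- c(pos, last)
    pos
  }
  pz <- axis_positions(shape[1]); py <- axis_positions(shape[2]); px <- axis_positions(shape[3])
  grid <- expand.grid(x = px, y = py, z = pz)   # z varies slowest -> lexicographic (z,y,x)
  origins <- as.matrix(grid[, c("z", "y", "x")])
  origins <- origins[order(origins[, 1], origins[, 2], origins[, 3]), , drop = FALSE]
  dimnames(origins) <- NULL
  structure(list(origins = origins, size = size, stride = stride,
                 source_shape = shape),
            class = "vssl_patchset")
}

#' @export
print.vssl_patchset <- function(x, ...) {
  cat(sprintf("<vssl_patchset %d patches of %d^3, stride %d, source %s>\n",
              nrow(x$origins), x$size, x$stride,
              paste(x$source_shape, collapse = "x")))
  invisible(x)
}

#' @export
length.vssl_patchset <- function(x) nrow(x$origins)

check_patchset <- function(ps, shape) {
  if (!identical(as.integer(shape), ps$source_shape))
    stopf("patchset was planned for shape (%s) but volume has shape (%s)",
          paste(ps$source_shape, collapse = ","), paste(shape, collapse = ","))
}

patch_window <- function(origin, size) {
  lapply(1:3, function(a) (origin[a] + 1L):(origin[a] + size))
}

#' Filter patches by labeled-voxel density
#'
#' Keeps the patches whose labeled-voxel percentage strictly exceeds a level,
#' mirroring the practice of discarding (near-)empty training patches when
#' labels are sparse.  `level = "strict_positive"` (the literal "> 0" rule)
#' keeps any patch with at least one labeled voxel; a numeric `level` keeps
#' patches with `100 * labeled/total > level`.
#'
#' @param patchset a [plan_patches()] result.
#' @param labels a [new_labels()] or binary array of the patchset's source
#'   shape.
#' @param level `"strict_positive"` or a percentage >= 0.
#' @return a filtered `vssl_patchset` (origins subset, same order).
#' @export
filter_by_label_density <- function(patchset, labels, level = "strict_positive") {
  mask <- as_mask_array(labels)
  check_patchset(patchset, dim(mask))
  total <- patchset$size^3
  counts <- vapply(seq_len(nrow(patchset$origins)), function(i) {
    w <- patch_window(patchset$origins[i, ], patchset$size)
    sum(mask[w[[1]], w[[2]], w[[3]]])
  }, numeric(1))
  keep <- if (identical(level, "strict_positive")) counts >= 1 else {
    if (!is.numeric(level) || level < 0) stopf("level must be \"strict_positive\" or a percentage >= 0")
    100 * counts / total > level
  }
  out <- patchset
  out$origins <- patchset$origins[keep, , drop = FALSE]
  out
}

#' Extract patch arrays
#'
#' @param volume a [new_volume()] or 3D array.
#' @param patchset a [plan_patches()] result (possibly filtered).
#' @return list of 3D arrays, one per patch, in patchset order.
#' @export
extract_patches <- function(volume, patchset) {
  x <- if (inherits(volume, "vssl_volume")) volume$data else volume
  check_patchset(patchset, dim(x))
  lapply(seq_len(nrow(patchset$origins)), function(i) {
    w <- patch_window(patchset$origins[i, ], patchset$size)
    x[w[[1]], w[[2]], w[[3]], drop = FALSE]
  })
}

#' Stitch patch predictions back into a volume
#'
#' Each voxel's value is the arithmetic mean of all overlapping patch
#' predictions covering it (uniform weights).  Stitching an unmodified
#' extraction reproduces the source volume exactly for any valid patchset.
#'
#' @param patches list of prediction arrays, one per patchset index, each of
#'   the declared cubic size.
#' @param patchset the [plan_patches()] result the patches came from; must
#'   still cover the full source shape (a density-filtered set generally does
#'   not).
#' @param blend only `"mean"` is implemented.
#' @return a [new_volume()] of the source shape.
#' @export
stitch_patches <- function(patches, patchset, blend = "mean") {
  blend <- match.arg(blend, "mean")
  if (length(patches) != nrow(patchset$origins))
    stopf("got %d patches for %d patch indices", length(patches), nrow(patchset$origins))
  shape <- patchset$source_shape
  acc <- array(0, dim = shape)
  cnt <- array(0, dim = shape)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    if (!identical(dim(p), rep(patchset$size, 3L)) &&
        !identical(as.integer(dim(p)), rep(patchset$size, 3L)))
      stopf("patch %d has shape (%s), expected %d^3", i,
            paste(dim(p), collapse = ","), patchset$size)
    w <- patch_window(patchset$origins[i, ], patchset$size)
    acc[w[[1]], w[[2]], w[[3]]] <- acc[w[[1]], w[[2]], w[[3]]] + p
    cnt[w[[1]], w[[2]], w[[3]]] <- cnt[w[[1]], w[[2]], w[[3]]] + 1
  }
  if (any(cnt == 0)) {
    miss <- which(cnt == 0, arr.ind = TRUE)
    lo <- apply(miss, 2, min); hi <- apply(miss, 2, max)
    stopf("uncovered voxels: bounding box (%s)..(%s); the patchset does not cover the volume",
          paste(lo - 1L, collapse = ","), paste(hi - 1L, collapse = ","))
  }
  new_volume(acc / cnt)
}

#' Percentage of labeled voxels in a volume
#'
#' The labeled-volume accounting used to characterize sparsely annotated
#' datasets: `100 * labeled / total`, reported at 4 decimal places.
#'
#' @param labels a [new_labels()] or binary 3D array.
#' @return percentage, rounded to 4 decimal places.
#' @seealso [labeled_fraction_counts()] for the count-based form.
#' @export
labeled_fraction <- function(labels) {
  mask <- as_mask_array(labels)
  if (length(mask) == 0L) stopf("empty label volume")
  if (!is_binary(mask)) stopf("mask must be binary")
  labeled_fraction_counts(sum(mask), length(mask))
}

#' @param n_labeled labeled voxel count.
#' @param n_total total voxel count (> 0).
#' @rdname labeled_fraction
#' @export
labeled_fraction_counts <- function(n_labeled, n_total) {
  if (n_total <= 0) stopf("empty label volume")
  round(100 * n_labeled / n_total, 4)
}

#' Serialize or load a patch manifest as YAML
#'
#' Stores the source shape, size, stride and 0-based origins so extraction and
#' stitching can run in separate processes.
#'
#' @param patchset a `vssl_patchset`.
#' @param path YAML file path.
#' @export
write_patch_manifest <- function(patchset, path) {
  yaml::write_yaml(list(
    source_shape = as.integer(patchset$source_shape),
    size = patchset$size, stride = patchset$stride,
    origins = apply(patchset$origins, 1, as.integer, simplify = FALSE)), path)
  invisible(path)
}

#' @rdname write_patch_manifest
#' @export
read_patch_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  origins <- do.call(rbind, lapply(m$origins, as.integer))
  structure(list(origins = origins, size = as.integer(m$size),
                 stride = as.integer(m$stride),
                 source_shape = as.integer(m$source_shape)),
            class = "vssl_patchset")
}
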