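#' Dice overlap between two binary masks
#'
#' `2 |P intersect G| / (|P| + |G|)`.  When both masks are empty the score is
#' defined as 1.0: all-background patches are common in sparsely labeled
#' volumes and an empty prediction against an empty reference is a perfect
#' agreement under this convention.
#'
#' @param pred,gt binary arrays of identical shape.
#' @return Dice score in `[0, 1]`.
#' @export
dice_score <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stopf("pred shape (%s) does not match gt shape (%s)",
          paste(dim(pred), collapse = ","), paste(dim(gt), collapse = ","))
  if (!is_binary(pred) || !is_binary(gt)) stopf("masks must be binary")
  s <- sum(pred) + sum(gt)
  if (s == 0) return(1.0)
  2 * sum(pred * gt) / s
}

#' Dice restricted to annotated slices
#'
#' With slice-cadence annotation, voxels on unannotated slices have no ground
#' truth, and evaluating there miscounts genuine vessels as false positives.
#' This metric computes [dice_score()] over the union of annotated z-slices
#' only; with every slice annotated it reduces to the dense score.
#'
#' @param pred binary prediction array.
#' @param gt a [new_labels()] carrying an `annotated_slices` indicator.
#' @return Dice score in `[0, 1]` over the annotated region.
#' @export
masked_dice <- function(pred, gt) {
  stopifnot(inherits(gt, "vssl_labels"))
  if (!identical(dim(pred), dim(gt$mask)))
    stopf("pred shape does not match label shape")
  ann <- gt$annotated_slices
  if (!any(ann)) stopf("no annotated slices to evaluate")
  dice_score(pred[ann, , , drop = FALSE], gt$mask[ann, , , drop = FALSE])
}

#' Full evaluation report
#'
#' Dense Dice, annotation-aware Dice, positive fractions of prediction and
#' ground truth, and the voxel count evaluated.
#'
#' @param pred binary prediction array.
#' @param gt a [new_labels()] (dense or sparse).
#' @return a list of class `vssl_eval_report`.
#' @export
eval_report <- function(pred, gt) {
  stopifnot(inherits(gt, "vssl_labels"))
  structure(list(
    dice = dice_score(pred, gt$mask),
    masked_dice = masked_dice(pred, gt),
    positive_fraction_pred = mean(pred),
    positive_fraction_gt = mean(gt$mask),
    n_voxels_evaluated = length(pred)), class = "vssl_eval_report")
}

#' @export
print.vssl_eval_report <- function(x, ...) {
  cat(sprintf(paste0("<vssl_eval_report dice=%.4f masked_dice=%.4f ",
                     "pos_pred=%.4f pos_gt=%.4f n=%d>\n"),
              x$dice, x$masked_dice, x$positive_fraction_pred,
              x$positive_fraction_gt, x$n_voxels_evaluated))
  invisible(x)
}

#' Write an evaluation report as JSON
#' @param report a [eval_report()].
#' @param path output path.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render a slice with colored mask overlays
#'
#' Writes a PNG of one grayscale z-slice with up to four masks blended over
#' it as semi-transparent colors.  The blend is additive and
#' order-independent: at each pixel the gray value is attenuated by the total
#' covering opacity and each mask adds `opacity * color`; the result is
#' clamped to `[0, 1]`.  With no masks the image is the plain grayscale
#' slice; a single full-coverage mask at opacity 1 yields a uniform color
#' plane.
#'
#' @param volume a [new_volume()] or 3D array.
#' @param z slice index (1-based).
#' @param masks named list of binary 3D arrays (or [new_labels()]); names are
#'   colors understood by [grDevices::col2rgb()], e.g.
#'   `list(red = pred, green = gt)`.
#' @param path output PNG path.
#' @param opacity per-mask overlay opacity in `(0, 1]`.
#' @return `path`, invisibly.
#' @export
overlay_export <- function(volume, z, masks = list(), path, opacity = 0.5) {
  x <- if (inherits(volume, "vssl_volume")) volume$data else volume
  if (z < 1 || z > dim(x)[1]) stopf("slice index %d out of range [1, %d]", z, dim(x)[1])
  if (length(masks) > 4L) stopf("at most 4 masks can be overlaid")
  sl <- x[z, , ]
  lo <- min(x); hi <- max(x)
  g <- if (hi == lo) matrix(0, nrow(sl), ncol(sl)) else (sl - lo) / (hi - lo)
  rgb <- array(rep(g, 3L), dim = c(dim(sl), 3L))
  if (length(masks)) {
    cover <- matrix(0, nrow(sl), ncol(sl))
    add <- array(0, dim = dim(rgb))
    for (nm in names(masks)) {
      m <- as_mask_array(masks[[nm]])[z, , ]
      col <- as.numeric(grDevices::col2rgb(nm)) / 255
      cover <- cover + opacity * m
      for (ch in 1:3) add[, , ch] <- add[, , ch] + opacity * m * col[ch]
    }
    cover <- pmin(cover, 1)
    for (ch in 1:3) rgb[, , ch] <- (1 - cover) * rgb[, , ch] + add[, , ch]
    rgb <- pmin(pmax(rgb, 0), 1)
  }
  png::writePNG(rgb, path)
  invisible(path)
}
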