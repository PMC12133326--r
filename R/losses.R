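#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)`.
#' The smoothing term `eps` guards the empty-mask case (an all-background
#' patch against an all-zero prediction scores loss ~0, not 0/0).
#'
#' @param pred probability map, values in `[0, 1]`.
#' @param target binary mask of the same shape.
#' @param eps smoothing term (> 0) added to numerator and denominator.
#' @return scalar loss in `[0, 1)`.
#' @export
dice_loss <- function(pred, target, eps = 1e-6) {
  if (!identical(dim(pred), dim(target)))
    stopf("pred shape (%s) does not match target shape (%s)",
          paste(dim(pred), collapse = ","), paste(dim(target), collapse = ","))
  if (eps <= 0) stopf("eps must be > 0")
  1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

# Dice loss together with its gradient w.r.t. pred.
dice_loss_grad <- function(pred, target, eps = 1e-6) {
  num <- 2 * sum(pred * target) + eps
  den <- sum(pred) + sum(target) + eps
  grad <- -(2 * target * den - num) / den^2
  list(loss = 1 - num / den, grad = grad)
}

#' Consistency (MSE) loss between two probability maps
#'
#' Mean squared voxelwise difference; symmetric in its arguments, zero iff the
#' maps are identical.
#'
#' @param p_plus,p_minus probability maps of identical shape.
#' @return scalar >= 0.
#' @export
consistency_loss <- function(p_plus, p_minus) {
  if (!identical(dim(p_plus), dim(p_minus)))
    stopf("decoder output shapes differ: (%s) vs (%s)",
          paste(dim(p_plus), collapse = ","), paste(dim(p_minus), collapse = ","))
  mean((p_plus - p_minus)^2)
}

consistency_loss_grad <- function(p_plus, p_minus) {
  n <- length(p_plus)
  d <- p_plus - p_minus
  list(loss = mean(d^2), g_plus = 2 * d / n, g_minus = -2 * d / n)
}

# Accept either a single named element or a list of them.
batchify <- function(x, fields) {
  if (is.null(x) || length(x) == 0L) return(list())
  if (all(fields %in% names(x))) list(x) else x
}

#' Combined loss of the dual-decoder consistency scheme
#'
#' `L_total = Dice(p_final, target)` averaged over the labeled batch plus
#' `alpha` times the mean consistency (MSE) loss between the two decoders'
#' maps over the unlabeled batch.  An empty unlabeled batch leaves the pure
#' supervised term; an empty labeled batch leaves `alpha` times the
#' consistency term.
#'
#' @param labeled list of elements with `p_final` (probability map) and
#'   `target` (binary mask); may be empty if `unlabeled` is not.
#' @param unlabeled list of elements with `p_plus` and `p_minus`; may be empty
#'   if `labeled` is not.
#' @param alpha unsupervised-loss weight (>= 0).
#' @return scalar total loss, with attributes `supervised` and `consistency`
#'   holding the two per-stream mean terms.
#' @export
mismatch_total_loss <- function(labeled, unlabeled, alpha) {
  if (alpha < 0) stopf("alpha must be >= 0")
  labeled <- batchify(labeled, c("p_final", "target"))
  unlabeled <- batchify(unlabeled, c("p_plus", "p_minus"))
  if (length(labeled) == 0L && length(unlabeled) == 0L)
    stopf("both batches are empty")
  sup <- if (length(labeled))
    mean(vapply(labeled, function(b) dice_loss(b$p_final, b$target), numeric(1)))
  else 0
  con <- if (length(unlabeled))
    mean(vapply(unlabeled, function(b) consistency_loss(b$p_plus, b$p_minus), numeric(1)))
  else 0
  structure(sup + alpha * con, supervised = sup, consistency = con)
}
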