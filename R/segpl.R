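#' Configuration of the pseudo-labelling EM scheme
#'
#' Pseudo-labelling framed as expectation-maximization: the E-step thresholds
#' the model's probabilities on unlabeled patches at a fixed confidence `T`
#' to produce binary pseudo-labels, the M-step updates the weights on a
#' combined Dice loss over labeled and pseudo-labeled data, and the loop
#' iterates to convergence.
#'
#' @param threshold_T pseudo-label confidence threshold, in (0, 1); default
#'   0.5.  A voxel whose probability is `>= T` receives pseudo-label 1 (ties
#'   at exactly `T` map to 1).
#' @param alpha weight of the unsupervised Dice term (>= 0).
#' @param max_iterations EM iteration budget.
#' @param convergence_tol stop when the relative change of the exponentially
#'   smoothed total loss over a `window`-step stretch falls below this.
#' @param window smoothing/stopping window in steps.
#' @param e_step_every recompute pseudo-labels every this many steps
#'   (1 = every batch, the online-EM default).
#' @return an object of class `vssl_segpl_config`.
#' @export
segpl_config <- function(threshold_T = 0.5, alpha = 1, max_iterations = 100L,
                         convergence_tol = 0, window = 100L, e_step_every = 1L) {
  if (threshold_T <= 0 || threshold_T >= 1) stopf("threshold_T must lie in (0, 1)")
  if (alpha < 0) stopf("alpha must be >= 0")
  structure(list(threshold_T = threshold_T, alpha = alpha,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 window = as.integer(window),
                 e_step_every = as.integer(e_step_every)),
            class = "vssl_segpl_config")
}

#' Threshold probabilities into binary pseudo-labels
#'
#' Voxelwise rule: pseudo-label 1 iff probability `>= T` (the tie at exactly
#' `T` maps to 1).
#'
#' @param probs probability array.
#' @param threshold `T` in (0, 1).
#' @return 0/1 array of the same shape.
#' @export
pseudo_labels <- function(probs, threshold) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must lie in (0, 1)")
  p <- array(as.numeric(probs >= threshold), dim = dim(probs))
  p
}

#' E-step: generate pseudo-labels for unlabeled patches
#'
#' Runs the model on each unlabeled patch and thresholds the resulting
#' probability map at `T`.  The pseudo-labels are plain arrays detached from
#' the model: the following M-step treats them as fixed targets.
#'
#' @param model a single-output `vssl_net` (or any function mapping a patch to
#'   a probability array).
#' @param patches non-empty list of unlabeled patch arrays.
#' @param threshold confidence threshold `T` in (0, 1).
#' @return an object of class `vssl_pseudo_batch`: list with `probs`, `pseudo`
#'   (parallel lists) and `threshold_used`.
#' @export
e_step <- function(model, patches, threshold = 0.5) {
  if (length(patches) == 0L) stopf("empty unlabeled batch")
  predict1 <- if (is.function(model)) model
              else function(x) net_forward(model, x)$p
  probs <- lapply(patches, predict1)
  structure(list(probs = probs,
                 pseudo = lapply(probs, pseudo_labels, threshold = threshold),
                 threshold_used = threshold),
            class = "vssl_pseudo_batch")
}

#' M-step combined loss
#'
#' `L_total = L_L + alpha * L_U`, where `L_L` is the mean supervised Dice loss
#' over the labeled batch and `L_U` the mean Dice loss of the unlabeled
#' predictions against their fixed pseudo-labels.
#'
#' @param labeled_pred list of probability maps on labeled patches (or one).
#' @param labels matching binary target masks.
#' @param unlabeled_pred list of probability maps on unlabeled patches.
#' @param pseudo matching pseudo-label masks from the most recent E-step (a
#'   `vssl_pseudo_batch` or list of arrays).
#' @param alpha unsupervised-loss weight (>= 0).
#' @return scalar total loss with attributes `L_L` and `L_U`.
#' @export
m_step_loss <- function(labeled_pred, labels, unlabeled_pred, pseudo, alpha) {
  if (alpha < 0) stopf("alpha must be >= 0")
  if (is.array(labeled_pred)) { labeled_pred <- list(labeled_pred); labels <- list(labels) }
  if (is.array(unlabeled_pred)) unlabeled_pred <- list(unlabeled_pred)
  if (inherits(pseudo, "vssl_pseudo_batch")) pseudo <- pseudo$pseudo
  if (is.array(pseudo)) pseudo <- list(pseudo)
  if (length(unlabeled_pred) != length(pseudo))
    stopf("%d unlabeled predictions vs %d pseudo-label maps",
          length(unlabeled_pred), length(pseudo))
  L_L <- if (length(labeled_pred))
    mean(mapply(dice_loss, labeled_pred, labels)) else 0
  L_U <- if (length(unlabeled_pred))
    mean(mapply(dice_loss, unlabeled_pred, pseudo)) else 0
  structure(L_L + alpha * L_U, L_L = L_L, L_U = L_U)
}

#' Fit a model by pseudo-label expectation-maximization
#'
#' Alternates E-steps (pseudo-label generation at fixed threshold `T`) with
#' gradient M-steps on the combined Dice loss, drawing seeded batches with
#' replacement from the two streams.  Stops at `max_iterations` or when the
#' relative change of the exponentially smoothed total loss over a window
#' falls below `convergence_tol`.  Aborts with a diagnostic on non-finite
#' loss.
#'
#' @param model a single-output `vssl_net` (modified in place and returned).
#' @param labeled list of elements with `x` (patch) and `y` (binary mask).
#' @param unlabeled non-empty list of patch arrays.
#' @param config a [segpl_config()].
#' @param batch_size labeled patches per step.
#' @param unlabeled_ratio unlabeled:labeled patches per step.
#' @param lr Adam learning rate.
#' @param seed seed for batch sampling.
#' @return list with `model` and `log`, a data.frame with per-iteration
#'   `iteration`, `L_L`, `L_U`, `L_total`, `positive_fraction`.
#' @export
segpl_fit <- function(model, labeled, unlabeled, config,
                      batch_size = 2L, unlabeled_ratio = 1L, lr = 1e-2,
                      seed = 1L) {
  stopifnot(inherits(config, "vssl_segpl_config"))
  if (length(labeled) == 0L || length(unlabeled) == 0L)
    stopf("both data streams must be non-empty")
  if (config$max_iterations == 0L)
    return(list(model = model, log = empty_train_log()))
  lab_stream <- rng_stream(derive_seed(seed, 1L))
  unl_stream <- rng_stream(derive_seed(seed, 2L))
  opt <- adam_init(model)
  log <- vector("list", config$max_iterations)
  ema <- NULL; ema_hist <- numeric(0)
  pl <- NULL
  for (it in seq_len(config$max_iterations)) {
    li <- with_stream(lab_stream, sample.int(length(labeled), batch_size, replace = TRUE))
    n_unl <- batch_size * unlabeled_ratio
    ui <- if (n_unl > 0)
      with_stream(unl_stream, sample.int(length(unlabeled), n_unl, replace = TRUE))
    else integer(0)
    zero_grads(model)
    L_L <- 0
    for (i in li) {
      out <- net_forward(model, labeled[[i]]$x, keep_ctx = TRUE)
      dl <- dice_loss_grad(out$p, labeled[[i]]$y)
      L_L <- L_L + dl$loss / length(li)
      net_backward(model, out, list(p = dl$grad / length(li)))
    }
    L_U <- 0; pos <- NA_real_
    if (config$alpha > 0 && length(ui)) {
      # E-step: pseudo-labels thresholded from the current model, detached;
      # online mode (e_step_every = 1) refreshes them from each step's own
      # forward pass, periodic mode freezes the whole pool between refreshes.
      if (config$e_step_every > 1L &&
          (is.null(pl) || (it - 1L) %% config$e_step_every == 0L))
        pl <- e_step(model, unlabeled, config$threshold_T)$pseudo
      pos_acc <- 0
      for (j in seq_along(ui)) {
        out <- net_forward(model, unlabeled[[ui[j]]], keep_ctx = TRUE)
        target <- if (config$e_step_every > 1L) pl[[ui[j]]]
                  else pseudo_labels(out$p, config$threshold_T)
        du <- dice_loss_grad(out$p, target)
        L_U <- L_U + du$loss / length(ui)
        pos_acc <- pos_acc + mean(target) / length(ui)
        net_backward(model, out, list(p = config$alpha * du$grad / length(ui)))
      }
      pos <- pos_acc
    }
    L_total <- L_L + config$alpha * L_U
    if (!is.finite(L_total))
      stopf("divergence at iteration %d: non-finite loss (L_L=%.4g, L_U=%.4g)",
            it, L_L, L_U)
    opt <- adam_step(model, opt, lr)
    log[[it]] <- data.frame(iteration = it, L_L = L_L, L_U = L_U,
                            L_total = L_total, positive_fraction = pos)
    ema <- if (is.null(ema)) L_total else 0.95 * ema + 0.05 * L_total
    ema_hist <- c(ema_hist, ema)
    if (config$convergence_tol > 0 && it > config$window) {
      prev <- ema_hist[it - config$window]
      if (abs(ema - prev) / max(abs(prev), 1e-12) < config$convergence_tol) {
        log <- log[seq_len(it)]
        break
      }
    }
  }
  list(model = model, log = do.call(rbind, log[!vapply(log, is.null, logical(1))]))
}

empty_train_log <- function() {
  data.frame(iteration = integer(0), L_L = numeric(0), L_U = numeric(0),
             L_total = numeric(0), positive_fraction = numeric(0))
}
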