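#' Training configuration
#'
#' One configuration drives the supervised, consistency (dual-decoder) and
#' pseudo-labelling (EM) training loops.  The seed fixes every stochastic
#' component — weight initialization, batch sampling and augmentation draws
#' each consume an independent derived RNG stream, so runs are reproducible
#' bit-for-bit (single-threaded CPU) and a loop that never touches the
#' unlabeled stream draws exactly the same labeled batches as one that does.
#'
#' @param method `"supervised"`, `"mismatch"` (dual-decoder consistency) or
#'   `"segpl"` (pseudo-label EM).
#' @param alpha unsupervised-loss weight (>= 0).
#' @param batch_size labeled patches per step.
#' @param unlabeled_ratio unlabeled:labeled patches per step (>= 0).
#' @param crop_size random-crop edge length fed to the network, voxels; must
#'   not exceed the stored patch size and must be divisible by
#'   `2^(depth - 1)`.
#' @param learning_rate Adam learning rate.
#' @param iterations gradient steps.
#' @param seed master seed.
#' @param density_level patch filter level passed to
#'   [filter_by_label_density()] when planning data.
#' @param validation_cadence validate every this many steps (0 = never).
#' @param backbone `"single"` or `"mismatch"`; defaults to the method's
#'   natural architecture (`"mismatch"` for the dual-decoder method, single
#'   decoder otherwise).  The supervised loop can be run on the dual-decoder
#'   architecture, where its loss is the Dice of `p_final`.
#' @param augmentation `"crop"` (random 3D crop only) or `"full"` (random
#'   contrast, zoom, orthogonal axis permutation, then crop); defaults by
#'   method: the consistency scheme uses `"crop"`, the EM scheme `"full"`.
#' @param base_channels,depth,dilation_rate network hyperparameters, see
#'   [mismatch_config()].
#' @param threshold_T pseudo-label threshold (EM method only).
#' @param e_step_every recompute pseudo-labels for the whole unlabeled pool
#'   every this many steps (EM method only).  Between E-steps the cached
#'   pseudo-labels are fixed targets that are co-augmented with their patches,
#'   so the M-step optimizes against a stationary target; `1` refreshes
#'   online from each step's forward pass.
#' @param warmup steps of supervised-only training before the unsupervised
#'   term activates (pseudo-labelling needs the model to first learn from the
#'   labeled data so that early low-confidence predictions do not collapse the
#'   pseudo-labels to background; 0 disables the warm-up).
#' @param alpha_ramp steps over which the unsupervised weight ramps linearly
#'   from 0 to `alpha` after the warm-up (0 = switch on at full weight).
#'   Ramping damps the positive feedback of self-training: early
#'   pseudo-labels inherit the model's own mistakes, and applying them at
#'   full weight can run away toward an all-foreground or all-background
#'   fixed point before the supervised signal can correct them.
#' @param flatten_tol early-cut tolerance on the moving-average loss slope
#'   per step (0 disables the cut).
#' @param flatten_window window for the moving average, steps.
#' @return an object of class `vssl_train_config`.
#' @export
train_config <- function(method = c("supervised", "mismatch", "segpl"),
                         alpha = 1, batch_size = 2L, unlabeled_ratio = 1L,
                         crop_size = 96L, learning_rate = 1e-2,
                         iterations = 100L, seed = 1L,
                         density_level = "strict_positive",
                         validation_cadence = 0L,
                         backbone = NULL, augmentation = NULL,
                         base_channels = 4L, depth = 2L, dilation_rate = 5L,
                         threshold_T = 0.5, e_step_every = 25L,
                         warmup = 0L, alpha_ramp = 0L,
                         flatten_tol = 0, flatten_window = 20L) {
  method <- match.arg(method)
  if (alpha < 0) stopf("alpha must be >= 0")
  if (unlabeled_ratio < 0) stopf("unlabeled_ratio must be >= 0")
  backbone <- backbone %||% if (method == "mismatch") "mismatch" else "single"
  backbone <- match.arg(backbone, c("single", "mismatch"))
  augmentation <- augmentation %||% if (method == "segpl") "full" else "crop"
  augmentation <- match.arg(augmentation, c("crop", "full"))
  if (crop_size %% 2L^(depth - 1L) != 0L)
    stopf("crop_size %d is not divisible by 2^(depth-1) = %d", crop_size, 2L^(depth - 1L))
  structure(list(method = method, alpha = alpha,
                 batch_size = as.integer(batch_size),
                 unlabeled_ratio = as.integer(unlabeled_ratio),
                 crop_size = as.integer(crop_size),
                 learning_rate = learning_rate,
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 density_level = density_level,
                 validation_cadence = as.integer(validation_cadence),
                 backbone = backbone, augmentation = augmentation,
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 dilation_rate = as.integer(dilation_rate),
                 threshold_T = threshold_T,
                 e_step_every = as.integer(e_step_every),
                 warmup = as.integer(warmup),
                 alpha_ramp = as.integer(alpha_ramp),
                 flatten_tol = flatten_tol,
                 flatten_window = as.integer(flatten_window)),
            class = "vssl_train_config")
}

#' Seeded batch stream over labeled and unlabeled patch pools
#'
#' Each call to the returned function yields one step's indices:
#' `batch_size` labeled indices and `batch_size * unlabeled_ratio` unlabeled
#' indices, sampled with replacement from their pools.  The two pools are
#' sampled from independent derived RNG streams, so they cycle independently,
#' and the same config yields the same sequence of batches.
#'
#' @param n_labeled labeled pool: a count, a patch list, or a
#'   `vssl_patchset` (> 0 elements).
#' @param n_unlabeled unlabeled pool, same forms (may be empty only if the
#'   method is supervised or `unlabeled_ratio` is 0).
#' @param config a [train_config()].
#' @return a function `next_batch()` returning
#'   `list(labeled = <idx>, unlabeled = <idx>)`.
#' @export
make_batches <- function(n_labeled, n_unlabeled, config) {
  stopifnot(inherits(config, "vssl_train_config"))
  if (!is.numeric(n_labeled)) n_labeled <- length(n_labeled)
  if (!is.numeric(n_unlabeled)) n_unlabeled <- length(n_unlabeled)
  if (n_labeled <= 0L) stopf("labeled stream is empty")
  n_unl_step <- config$batch_size * config$unlabeled_ratio
  needs_unl <- config$method != "supervised" && n_unl_step > 0L && config$alpha > 0
  if (needs_unl && n_unlabeled <= 0L)
    stopf("method \"%s\" requires unlabeled data but the unlabeled stream is empty",
          config$method)
  lab_stream <- rng_stream(derive_seed(config$seed, 1L))
  unl_stream <- rng_stream(derive_seed(config$seed, 2L))
  function() {
    li <- with_stream(lab_stream, sample.int(n_labeled, config$batch_size, replace = TRUE))
    ui <- if (needs_unl)
      with_stream(unl_stream, sample.int(n_unlabeled, n_unl_step, replace = TRUE))
    else integer(0)
    list(labeled = li, unlabeled = ui)
  }
}

# Zoom a 3D array about its centre by factor s, resampled back to its own
# shape.  method "linear" = trilinear, "nearest" for label maps.
resample_zoom <- function(a, s, method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (s == 1) return(a)
  d <- dim(a)
  ax <- lapply(d, function(n) {
    ctr <- (n + 1) / 2
    pmin(pmax(ctr + (seq_len(n) - ctr) / s, 1), n)
  })
  if (method == "nearest") {
    i1 <- round(ax[[1]]); i2 <- round(ax[[2]]); i3 <- round(ax[[3]])
    return(a[i1, i2, i3, drop = FALSE])
  }
  lo <- lapply(ax, floor); fr <- mapply(function(x, l) x - l, ax, lo, SIMPLIFY = FALSE)
  hi <- mapply(function(l, n) pmin(l + 1, n), lo, d, SIMPLIFY = FALSE)
  out <- array(0, dim = d)
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    iz <- if (cz) hi[[1]] else lo[[1]]
    iy <- if (cy) hi[[2]] else lo[[2]]
    ix <- if (cx) hi[[3]] else lo[[3]]
    wz <- if (cz) fr[[1]] else 1 - fr[[1]]
    wy <- if (cy) fr[[2]] else 1 - fr[[2]]
    wx <- if (cx) fr[[3]] else 1 - fr[[3]]
    w <- outer(outer(wz, wy), wx)
    out <- out + w * a[iz, iy, ix, drop = FALSE]
  }
  out
}

#' On-the-fly augmentation of a patch (and its labels)
#'
#' The `"crop"` scheme applies a random 3D crop to `crop_size`.  The `"full"`
#' scheme applies random contrast scaling (image only), random isotropic zoom
#' resampled back to the original shape (trilinear for the image,
#' nearest-neighbour for labels), a random orthogonal axis permutation, then
#' the random crop.  Label maps undergo exactly the same geometric transforms
#' as the image and never the intensity ones.
#'
#' @param patch 3D image array.
#' @param labels optional binary mask of the same shape.
#' @param scheme `"crop"` or `"full"`.
#' @param crop_size output edge length (<= every patch dimension).
#' @param stream a [rng_stream()] supplying the random draws.
#' @param params optional explicit parameter draws overriding the stream:
#'   list with any of `contrast`, `zoom`, `perm` (axis permutation),
#'   `origin` (1-based crop corner).
#' @param contrast_range,zoom_range sampling ranges for the `"full"` scheme.
#' @return list with `patch` and (if given) `labels`, both of shape
#'   `crop_size^3`, plus the `params` used.
#' @export
augment_patch <- function(patch, labels = NULL, scheme = c("crop", "full"),
                          crop_size, stream = rng_stream(0L), params = NULL,
                          contrast_range = c(0.8, 1.2), zoom_range = c(0.9, 1.1)) {
  scheme <- match.arg(scheme)
  d <- dim(patch)
  if (any(crop_size > d))
    stopf("crop_size %d exceeds patch shape (%s)", crop_size, paste(d, collapse = ","))
  if (!is.null(labels) && !identical(dim(labels), d))
    stopf("labels shape does not match patch shape")
  draw <- function(name, expr) if (!is.null(params[[name]])) params[[name]] else expr
  used <- list()
  if (scheme == "full") {
    used$contrast <- draw("contrast", with_stream(stream, runif(1, contrast_range[1], contrast_range[2])))
    used$zoom <- draw("zoom", with_stream(stream, runif(1, zoom_range[1], zoom_range[2])))
    used$perm <- draw("perm", with_stream(stream, sample(3L)))
    mu <- mean(patch)
    patch <- mu + used$contrast * (patch - mu)
    if (used$zoom != 1) {
      patch <- resample_zoom(patch, used$zoom, "linear")
      if (!is.null(labels)) labels <- resample_zoom(labels, used$zoom, "nearest")
    }
    if (!identical(used$perm, 1:3)) {
      patch <- aperm(patch, used$perm)
      if (!is.null(labels)) labels <- aperm(labels, used$perm)
      d <- dim(patch)
    }
  }
  used$origin <- draw("origin", with_stream(stream, {
    vapply(d, function(n) if (n == crop_size) 1L else sample.int(n - crop_size + 1L, 1L), integer(1))
  }))
  w <- lapply(1:3, function(a) used$origin[a]:(used$origin[a] + crop_size - 1L))
  out <- list(patch = patch[w[[1]], w[[2]], w[[3]], drop = FALSE], params = used)
  if (!is.null(labels)) out$labels <- labels[w[[1]], w[[2]], w[[3]], drop = FALSE]
  out
}

model_from_config <- function(config, seed) {
  net_cfg <- mismatch_config(in_channels = 1L,
                             base_channels = config$base_channels,
                             depth = config$depth,
                             dilation_rate = config$dilation_rate,
                             patch_size = config$crop_size)
  if (config$backbone == "mismatch") build_mismatch(net_cfg, seed = seed)
  else build_unet(net_cfg, seed = seed)
}

final_prob <- function(model, x) {
  out <- net_forward(model, x)
  out$p %||% out$p_final
}

validate_dice <- function(model, validation) {
  mean(vapply(validation, function(v) {
    p <- final_prob(model, v$x)
    dice_score(array(as.numeric(p >= 0.5), dim(p)), v$y)
  }, numeric(1)))
}

#' Fit a segmentation model
#'
#' Unified training loop for the three methods.  Every step draws a seeded
#' labeled batch (and, for the semi-supervised methods with `alpha > 0`, an
#' unlabeled batch), augments it, computes the method's loss and takes one
#' Adam step:
#'
#' * `supervised` — Dice loss on the model's final prediction;
#' * `mismatch`   — Dice on `p_final` plus `alpha` times the decoder
#'   consistency (MSE) loss on unlabeled patches;
#' * `segpl`      — Dice on labeled patches plus `alpha` times Dice against
#'   fixed pseudo-labels thresholded at `threshold_T` on unlabeled patches.
#'
#' With `alpha = 0` the unlabeled stream is never consumed, so the two
#' semi-supervised loops reduce exactly (bit-for-bit) to the supervised loop
#' on the same backbone.  Training aborts on a non-finite loss, returning the
#' last finite-state model.  If `flatten_tol > 0`, the run is cut early once
#' the moving-average loss slope flattens below the tolerance.
#'
#' @param config a [train_config()].
#' @param labeled list of elements with `x` (patch array) and `y` (binary
#'   mask).  Unannotated voxels in sparse masks are treated as background
#'   unless the pair carries an `annotated` slice indicator and
#'   `masked_loss = TRUE`.
#' @param unlabeled list of patch arrays (may be empty for supervised runs).
#' @param validation optional list of `x`/`y` pairs with dense ground truth;
#'   validated every `validation_cadence` steps.
#' @param masked_loss restrict the supervised Dice to annotated slices when a
#'   labeled element has an `annotated` logical vector.
#' @param resume a `state` element from a previous [fit_model()] result to
#'   continue an interrupted run; the continuation reproduces the
#'   uninterrupted run exactly.
#' @return list with `model`, `log` (data.frame: step, L_sup, L_unsup,
#'   L_total, val_dice) and `state` (resumable snapshot).
#' @export
fit_model <- function(config, labeled, unlabeled = list(), validation = NULL,
                      masked_loss = FALSE, resume = NULL) {
  stopifnot(inherits(config, "vssl_train_config"))
  if (length(labeled) == 0L) stopf("labeled stream is empty")
  needs_unl <- config$method != "supervised" && config$alpha > 0 &&
    config$unlabeled_ratio > 0L
  if (needs_unl && length(unlabeled) == 0L)
    stopf("method \"%s\" with alpha > 0 requires unlabeled data", config$method)

  if (is.null(resume)) {
    model <- model_from_config(config, derive_seed(config$seed, 3L))
    opt <- adam_init(model)
    streams <- list(lab = rng_stream(derive_seed(config$seed, 1L)),
                    unl = rng_stream(derive_seed(config$seed, 2L)),
                    aug_lab = rng_stream(derive_seed(config$seed, 4L)),
                    aug_unl = rng_stream(derive_seed(config$seed, 5L)))
    step0 <- 0L
    log <- list()
  } else {
    model <- model_from_config(config, derive_seed(config$seed, 3L))
    net_load_state(model, resume$model_state)
    opt <- resume$opt
    streams <- lapply(resume$stream_states, function(s) {
      e <- new.env(parent = emptyenv()); e$state <- s; class(e) <- "vssl_rng"; e
    })
    step0 <- resume$step
    log <- resume$log
  }

  n_unl_step <- config$batch_size * config$unlabeled_ratio
  crop <- config$crop_size
  pl_cache <- NULL
  for (step in seq_len(config$iterations)) {
    if (step <= step0) next
    li <- with_stream(streams$lab,
                      sample.int(length(labeled), config$batch_size, replace = TRUE))
    ui <- if (needs_unl && step > config$warmup)
      with_stream(streams$unl, sample.int(length(unlabeled), n_unl_step, replace = TRUE))
    else integer(0)

    zero_grads(model)
    L_sup <- 0
    for (i in li) {
      aug <- augment_patch(labeled[[i]]$x, labeled[[i]]$y,
                           scheme = config$augmentation, crop_size = crop,
                           stream = streams$aug_lab)
      out <- net_forward(model, aug$patch, keep_ctx = TRUE)
      pred <- out$p %||% out$p_final
      target <- aug$labels
      if (masked_loss && !is.null(labeled[[i]]$annotated)) {
        zsel <- labeled[[i]]$annotated[aug$params$origin[1]:(aug$params$origin[1] + crop - 1L)]
        dl <- dice_loss_grad(pred[zsel, , , drop = FALSE], target[zsel, , , drop = FALSE])
        grad <- array(0, dim(pred)); grad[zsel, , ] <- dl$grad
      } else {
        dl <- dice_loss_grad(pred, target)
        grad <- dl$grad
      }
      L_sup <- L_sup + dl$loss / length(li)
      gkey <- if (model$kind == "mismatch") "p_final" else "p"
      net_backward(model, out, setNames(list(grad / length(li)), gkey))
    }

    eff_alpha <- if (config$alpha_ramp > 0L)
      config$alpha * min(1, max(0, step - config$warmup) / config$alpha_ramp)
    else config$alpha
    L_unsup <- 0
    if (length(ui)) {
      if (config$method == "segpl" && config$e_step_every > 1L) {
        # periodic E-step: thresholded pseudo-labels for the whole pool,
        # frozen until the next refresh
        since <- step - config$warmup
        if (is.null(pl_cache) || (since - 1L) %% config$e_step_every == 0L)
          pl_cache <- lapply(e_step(model, unlabeled, config$threshold_T)$pseudo,
                             identity)
      }
      for (i in ui) {
        if (config$method == "mismatch") {
          aug <- augment_patch(unlabeled[[i]], scheme = config$augmentation,
                               crop_size = crop, stream = streams$aug_unl)
          out <- net_forward(model, aug$patch, keep_ctx = TRUE)
          cl <- consistency_loss_grad(out$p_plus, out$p_minus)
          L_unsup <- L_unsup + cl$loss / length(ui)
          net_backward(model, out,
                       list(p_plus = eff_alpha * cl$g_plus / length(ui),
                            p_minus = eff_alpha * cl$g_minus / length(ui)))
        } else if (config$e_step_every > 1L) {
          # M-step against the cached pseudo-labels, co-augmented with the
          # patch exactly like a labeled pair
          aug <- augment_patch(unlabeled[[i]], pl_cache[[i]],
                               scheme = config$augmentation,
                               crop_size = crop, stream = streams$aug_unl)
          out <- net_forward(model, aug$patch, keep_ctx = TRUE)
          du <- dice_loss_grad(out$p, aug$labels)
          L_unsup <- L_unsup + du$loss / length(ui)
          net_backward(model, out, list(p = eff_alpha * du$grad / length(ui)))
        } else {                      # online EM: E-step from this forward pass
          aug <- augment_patch(unlabeled[[i]], scheme = config$augmentation,
                               crop_size = crop, stream = streams$aug_unl)
          out <- net_forward(model, aug$patch, keep_ctx = TRUE)
          pl <- pseudo_labels(out$p, config$threshold_T)
          du <- dice_loss_grad(out$p, pl)
          L_unsup <- L_unsup + du$loss / length(ui)
          net_backward(model, out, list(p = eff_alpha * du$grad / length(ui)))
        }
      }
    }

    L_total <- L_sup + eff_alpha * L_unsup
    if (!is.finite(L_total)) {
      warning(sprintf("non-finite loss at step %d; aborting with last-good model", step))
      break
    }
    opt <- adam_step(model, opt, config$learning_rate)

    val <- NA_real_
    if (!is.null(validation) && config$validation_cadence > 0L &&
        step %% config$validation_cadence == 0L)
      val <- validate_dice(model, validation)
    log[[length(log) + 1L]] <- data.frame(step = step, L_sup = L_sup,
                                          L_unsup = L_unsup, L_total = L_total,
                                          val_dice = val)

    if (config$flatten_tol > 0 && length(log) >= 2L * config$flatten_window) {
      lt <- vapply(log, function(r) r$L_total, numeric(1))
      n <- length(lt); w <- config$flatten_window
      slope <- abs(mean(lt[(n - w + 1L):n]) - mean(lt[(n - 2L * w + 1L):(n - w)])) / w
      if (slope < config$flatten_tol) break
    }
  }
  log_df <- if (length(log)) do.call(rbind, log) else
    data.frame(step = integer(0), L_sup = numeric(0), L_unsup = numeric(0),
               L_total = numeric(0), val_dice = numeric(0))
  state <- list(model_state = net_state(model), opt = opt,
                stream_states = lapply(streams, function(s) s$state),
                step = if (nrow(log_df)) max(log_df$step) else 0L,
                log = log)
  list(model = model, log = log_df, state = state)
}

#' Patch-wise prediction over a whole volume
#'
#' Plans overlapping patches of the model's configured input size, predicts
#' each, and stitches the probability maps back with mean blending.
#'
#' @param model a trained `vssl_net`.
#' @param volume a [new_volume()] or 3D array.
#' @param stride patch stride (default half the model's patch size).
#' @return a [new_volume()] of probabilities with the input's shape.
#' @export
predict_volume <- function(model, volume,
                           stride = max(1L, model$config$patch_size %/% 2L)) {
  x <- if (inherits(volume, "vssl_volume")) volume$data else volume
  size <- model$config$patch_size
  ps <- plan_patches(dim(x), size, stride)
  preds <- lapply(extract_patches(x, ps), function(p) final_prob(model, p))
  stitch_patches(preds, ps)
}
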