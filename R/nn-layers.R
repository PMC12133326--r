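# Minimal neural-network primitives for 3D volumes.
#
# Activations are arrays with dim (z, y, x, channels).  Each convolution
# layer is an environment holding weights, bias and accumulated gradients;
# forward/backward passes are explicit functions (no autograd tape), with
# the heavy kernels in src/conv3d.cpp.  All computation is double precision,
# single-threaded and deterministic.

as_act <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); x } else x
}

conv_layer <- function(k, cin, cout, dilation = 1L) {
  e <- new.env(parent = emptyenv())
  e$k <- as.integer(k); e$cin <- as.integer(cin); e$cout <- as.integer(cout)
  e$dilation <- as.integer(dilation)
  fan_in <- k^3 * cin
  # He-style init; draws come from whatever RNG state is active at build time
  e$w <- array(rnorm(k^3 * cin * cout, sd = sqrt(2 / fan_in)),
               dim = c(k, k, k, cin, cout))
  e$b <- numeric(cout)
  e$gw <- array(0, dim = dim(e$w)); e$gb <- numeric(cout)
  class(e) <- "vssl_conv"
  e
}

conv_apply <- function(layer, x) {
  d <- dim(x)
  y <- .conv3d_fwd(as.numeric(x), as.integer(d),
                   as.numeric(layer$w), as.integer(dim(layer$w)),
                   layer$b, layer$dilation)
  dim(y) <- c(d[1:3], layer$cout)
  y
}

conv_back <- function(layer, x, gy) {
  d <- dim(x)
  r <- .conv3d_bwd(as.numeric(x), as.integer(d),
                   as.numeric(layer$w), as.integer(dim(layer$w)),
                   as.numeric(gy), layer$dilation)
  layer$gw <- layer$gw + array(r$gw, dim(layer$w))
  layer$gb <- layer$gb + r$gb
  gx <- r$gx; dim(gx) <- d
  gx
}

relu_fwd <- function(x) { x[x < 0] <- 0; x }
relu_bwd <- function(y, gy) { gy[y <= 0] <- 0; gy }

sigmoid_fwd <- function(x) 1 / (1 + exp(-x))
sigmoid_bwd <- function(p, gp) gp * p * (1 - p)

pool2 <- function(x) {
  d <- dim(x)
  y <- .avgpool2_fwd(as.numeric(x), as.integer(d))
  dim(y) <- c(d[1:3] %/% 2L, d[4]); y
}
pool2_bwd <- function(gy, xdim) {
  g <- .avgpool2_bwd(as.numeric(gy), as.integer(xdim)); dim(g) <- xdim; g
}
up2 <- function(x) {
  d <- dim(x)
  y <- .upsample2_fwd(as.numeric(x), as.integer(d))
  dim(y) <- c(d[1:3] * 2L, d[4]); y
}
up2_bwd <- function(gy, xdim) {
  g <- .upsample2_bwd(as.numeric(gy), as.integer(xdim)); dim(g) <- xdim; g
}

cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# ---- parameter bookkeeping -------------------------------------------------

net_layers <- function(model) {
  out <- list()
  walk <- function(x) {
    if (inherits(x, "vssl_conv")) out[[length(out) + 1L]] <<- x
    else if (is.list(x)) for (el in x) walk(el)
  }
  walk(model$parts)
  out
}

zero_grads <- function(model) {
  for (l in net_layers(model)) { l$gw[] <- 0; l$gb[] <- 0 }
  invisible(model)
}

#' Extract or restore network weights
#'
#' `net_state()` returns all weights and biases as a plain list (together with
#' the build config), suitable for serialization with [save_checkpoint()];
#' `net_load_state()` writes such a list back into a model of the same
#' architecture.
#'
#' @param model a model built by [build_mismatch()] or [build_unet()].
#' @export
net_state <- function(model) {
  layers <- net_layers(model)
  list(config = model$config, kind = model$kind,
       params = lapply(layers, function(l) list(w = l$w, b = l$b)))
}

#' @param state a list from [net_state()].
#' @rdname net_state
#' @export
net_load_state <- function(model, state) {
  layers <- net_layers(model)
  if (length(layers) != length(state$params))
    stopf("checkpoint has %d parameter tensors, model expects %d",
          length(state$params), length(layers))
  for (i in seq_along(layers)) {
    if (!identical(dim(layers[[i]]$w), dim(state$params[[i]]$w)))
      stopf("checkpoint tensor %d shape mismatch", i)
    layers[[i]]$w <- state$params[[i]]$w
    layers[[i]]$b <- state$params[[i]]$b
  }
  invisible(model)
}

#' Save or load a model checkpoint
#'
#' Checkpoints embed the build configuration, so [load_checkpoint()] can
#' reconstruct the architecture before restoring weights.  Storage is R
#' serialization via [saveRDS()].
#'
#' @param model a built model.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(net_state(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  st <- readRDS(path)
  model <- if (identical(st$kind, "mismatch")) build_mismatch(st$config, seed = 0L)
           else build_unet(st$config, seed = 0L)
  net_load_state(model, st)
  model
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(model) {
  layers <- net_layers(model)
  list(t = 0L,
       m = lapply(layers, function(l) list(w = array(0, dim(l$w)), b = numeric(l$cout))),
       v = lapply(layers, function(l) list(w = array(0, dim(l$w)), b = numeric(l$cout))))
}

adam_step <- function(model, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  layers <- net_layers(model)
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    opt$m[[i]]$w <- beta1 * opt$m[[i]]$w + (1 - beta1) * l$gw
    opt$v[[i]]$w <- beta2 * opt$v[[i]]$w + (1 - beta2) * l$gw^2
    opt$m[[i]]$b <- beta1 * opt$m[[i]]$b + (1 - beta1) * l$gb
    opt$v[[i]]$b <- beta2 * opt$v[[i]]$b + (1 - beta2) * l$gb^2
    l$w <- l$w - lr * (opt$m[[i]]$w / bc1) / (sqrt(opt$v[[i]]$w / bc2) + eps)
    l$b <- l$b - lr * (opt$m[[i]]$b / bc1) / (sqrt(opt$v[[i]]$b / bc2) + eps)
  }
  opt
}
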