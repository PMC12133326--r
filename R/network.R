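#' Configuration of the dual-decoder consistency network
#'
#' The network is a plain 3D encoder-decoder backbone (per-level channel
#' doubling, average-pool downsampling, nearest-neighbour upsampling, skip
#' concatenation) with one shared encoder and two parallel decoders whose
#' attention side-branches carry opposed effective-receptive-field (ERF)
#' biases:
#'
#' * the positive (dilation-biased) decoder computes a sigmoid attention map
#'   with a dilated 3x3x3 convolution (dilation `dilation_rate`, default 5)
#'   and merges it into the main branch by element-wise multiplication,
#'   widening the ERF to favour foreground dilation;
#' * the negative (erosion-biased) decoder computes its attention with a
#'   pointwise 1x1x1 convolution — the shortest possible side path — which
#'   narrows the ERF and biases toward erosion.
#'
#' @param in_channels input image channels (1 for grayscale volumes).
#' @param base_channels feature channels at the finest level; doubled per
#'   encoder level.
#' @param depth number of encoder levels (>= 2).
#' @param dilation_rate dilation of the positive decoder's side branch (>= 1).
#' @param patch_size cubic input edge length; must be divisible by
#'   `2^(depth - 1)`.
#' @param attention `"shifted"` builds the opposed attention branches;
#'   `"none"` builds two topologically identical plain decoders (a symmetry
#'   harness: with tied weights the two outputs coincide).
#' @return an object of class `vssl_mismatch_config`.
#' @export
mismatch_config <- function(in_channels = 1L, base_channels = 4L, depth = 2L,
                            dilation_rate = 5L, patch_size = 32L,
                            attention = c("shifted", "none")) {
  attention <- match.arg(attention)
  if (depth < 2L) stopf("depth must be >= 2")
  if (dilation_rate < 1L) stopf("dilation_rate must be >= 1")
  if (patch_size %% 2L^(depth - 1L) != 0L)
    stopf("patch_size %d is not divisible by 2^(depth-1) = %d",
          patch_size, 2L^(depth - 1L))
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 dilation_rate = as.integer(dilation_rate),
                 patch_size = as.integer(patch_size),
                 attention = attention),
            class = "vssl_mismatch_config")
}

build_encoder <- function(cfg) {
  ch <- cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L)
  cin <- c(cfg$in_channels, ch[-cfg$depth])
  lapply(seq_len(cfg$depth), function(l) conv_layer(3L, cin[l], ch[l]))
}

build_decoder <- function(cfg, type = c("plain", "pasb", "nasb")) {
  type <- match.arg(type)
  ch <- cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L)
  convs <- if (cfg$depth > 1L)
    lapply(seq_len(cfg$depth - 1L), function(l) conv_layer(3L, ch[l + 1L] + ch[l], ch[l]))
  else list()
  side <- switch(type,
    plain = NULL,
    pasb = conv_layer(3L, ch[1], ch[1], dilation = cfg$dilation_rate),
    nasb = conv_layer(1L, ch[1], ch[1]))
  list(type = type, convs = convs, side = side, head = conv_layer(1L, ch[1], 1L))
}

#' Build the dual-decoder consistency model
#'
#' One shared encoder feeds a positive (dilation-biased) and a negative
#' (erosion-biased) attention-shifting decoder; the final prediction is the
#' voxelwise mean of the two decoder probability maps.
#'
#' @param config a [mismatch_config()].
#' @param seed integer; fixes weight initialization.
#' @return a model of class `vssl_net` (kind `"mismatch"`).
#' @export
build_mismatch <- function(config, seed = 1L) {
  stopifnot(inherits(config, "vssl_mismatch_config"))
  stream <- rng_stream(seed)
  with_stream(stream, {
    types <- if (config$attention == "shifted") c("pasb", "nasb") else c("plain", "plain")
    parts <- list(enc = build_encoder(config),
                  dec_plus = build_decoder(config, types[1]),
                  dec_minus = build_decoder(config, types[2]))
    structure(list(kind = "mismatch", config = config, parts = parts),
              class = "vssl_net")
  })
}

#' Build the single-decoder backbone
#'
#' The same encoder-decoder as [build_mismatch()] with one plain decoder and
#' no attention branch; used for supervised training and as the
#' pseudo-labelling backbone.
#'
#' @inheritParams build_mismatch
#' @return a model of class `vssl_net` (kind `"unet"`).
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "vssl_mismatch_config"))
  stream <- rng_stream(seed)
  with_stream(stream, {
    parts <- list(enc = build_encoder(config),
                  dec = build_decoder(config, "plain"))
    structure(list(kind = "unet", config = config, parts = parts),
              class = "vssl_net")
  })
}

#' @export
print.vssl_net <- function(x, ...) {
  np <- sum(vapply(net_layers(x), function(l) length(l$w) + length(l$b), numeric(1)))
  cat(sprintf("<vssl_net kind=%s depth=%d base=%d dilation=%d params=%d>\n",
              x$kind, x$config$depth, x$config$base_channels,
              x$config$dilation_rate, np))
  invisible(x)
}

encoder_forward <- function(enc, x) {
  e <- vector("list", length(enc))
  h <- x
  for (l in seq_along(enc)) {
    if (l > 1L) h <- pool2(h)
    pre_in <- h
    h <- relu_fwd(conv_apply(enc[[l]], h))
    e[[l]] <- h
    attr(e, paste0("in", l)) <- pre_in
  }
  e
}

encoder_backward <- function(enc, ctx_e, ge) {
  # ge: list of gradients w.r.t. each encoder activation (may contain NULLs)
  D <- length(enc)
  g <- NULL
  for (l in D:1) {
    gl <- ge[[l]] %||% 0
    if (!is.null(g)) gl <- gl + g
    gl <- relu_bwd(ctx_e[[l]], gl)
    gin <- conv_back(enc[[l]], attr(ctx_e, paste0("in", l)), gl)
    g <- if (l > 1L) pool2_bwd(gin, dim(ctx_e[[l - 1L]])) else NULL
    if (l == 1L) return(gin)
  }
}

decoder_forward <- function(dec, e) {
  D <- length(e)
  ctx <- list(e_dims = lapply(e, dim))
  h <- e[[D]]
  hs <- list()
  for (i in seq_along(dec$convs)) {
    l <- D - i                      # level being produced
    u <- up2(h)
    cat_in <- cat_ch(u, e[[l]])
    ctx[[paste0("hdim", i)]] <- dim(h)
    ctx[[paste0("cat", i)]] <- cat_in
    h <- relu_fwd(conv_apply(dec$convs[[i]], cat_in))
    ctx[[paste0("h", i)]] <- h
  }
  if (!is.null(dec$side)) {
    ctx$f_in <- h
    a <- sigmoid_fwd(conv_apply(dec$side, h))
    ctx$att <- a
    h <- h * a
  }
  ctx$head_in <- h
  logit <- conv_apply(dec$head, h)
  p <- sigmoid_fwd(logit)
  ctx$p <- p
  list(p = p, ctx = ctx)
}

decoder_backward <- function(dec, ctx, gp) {
  D <- length(ctx$e_dims)
  glogit <- sigmoid_bwd(ctx$p, gp)
  gh <- conv_back(dec$head, ctx$head_in, glogit)
  if (!is.null(dec$side)) {
    ga <- gh * ctx$f_in
    gf <- gh * ctx$att
    gside <- sigmoid_bwd(ctx$att, ga)
    gf <- gf + conv_back(dec$side, ctx$f_in, gside)
    gh <- gf
  }
  ge <- vector("list", D)
  for (i in rev(seq_along(dec$convs))) {
    l <- D - i
    gh <- relu_bwd(ctx[[paste0("h", i)]], gh)
    gcat <- conv_back(dec$convs[[i]], ctx[[paste0("cat", i)]], gh)
    cu <- ctx[[paste0("hdim", i)]][4]
    gu <- gcat[, , , seq_len(cu), drop = FALSE]
    gskip <- gcat[, , , cu + seq_len(ctx$e_dims[[l]][4]), drop = FALSE]
    ge[[l]] <- (ge[[l]] %||% 0) + gskip
    gh <- up2_bwd(gu, ctx[[paste0("hdim", i)]])
  }
  ge[[D]] <- (ge[[D]] %||% 0) + gh
  ge
}

#' Forward pass of a built model
#'
#' For a dual-decoder model the result holds `p_plus` and `p_minus` — the
#' positive and negative decoder probability maps — and `p_final`, their exact
#' voxelwise mean; for the single-decoder backbone it holds `p`.  Maps share
#' the input's spatial shape and lie in `[0, 1]`.
#'
#' @param model a `vssl_net`.
#' @param x input patch: 3D array (z, y, x) or 4D (z, y, x, channels).
#' @param keep_ctx keep the caches needed for [net_backward()].
#' @return list of probability maps (3D arrays); with `keep_ctx = TRUE`, a
#'   `ctx` element is attached.
#' @export
net_forward <- function(model, x, keep_ctx = FALSE) {
  x <- as_act(x)
  e <- encoder_forward(model$parts$enc, x)
  drop_ch <- function(p) { d <- dim(p); dim(p) <- d[1:3]; p }
  if (model$kind == "mismatch") {
    fp <- decoder_forward(model$parts$dec_plus, e)
    fm <- decoder_forward(model$parts$dec_minus, e)
    out <- list(p_plus = drop_ch(fp$p), p_minus = drop_ch(fm$p),
                p_final = drop_ch((fp$p + fm$p) / 2))
    if (keep_ctx) out$ctx <- list(x = x, e = e, plus = fp$ctx, minus = fm$ctx)
  } else {
    fd <- decoder_forward(model$parts$dec, e)
    out <- list(p = drop_ch(fd$p))
    if (keep_ctx) out$ctx <- list(x = x, e = e, dec = fd$ctx)
  }
  out
}

#' Backward pass: accumulate parameter gradients
#'
#' Propagates gradients of a scalar loss with respect to the forward pass's
#' probability maps back through the network, accumulating weight gradients in
#' the model's layers, and returns the gradient with respect to the input.
#' A gradient supplied for `p_final` is split equally between the two decoders
#' (`p_final` is their mean).
#'
#' @param model the `vssl_net` used in the forward pass.
#' @param out the [net_forward()] result with `keep_ctx = TRUE`.
#' @param grads named list of gradient arrays: any of `p_plus`, `p_minus`,
#'   `p_final` (dual-decoder) or `p` (single-decoder).
#' @return gradient w.r.t. the input, same shape as the input.
#' @export
net_backward <- function(model, out, grads) {
  ctx <- out$ctx
  if (is.null(ctx)) stopf("forward pass was run without keep_ctx = TRUE")
  add_ch <- function(g) { if (!is.null(g) && length(dim(g)) == 3L) dim(g) <- c(dim(g), 1L); g }
  if (model$kind == "mismatch") {
    gfin <- add_ch(grads$p_final)
    gp <- add_ch(grads$p_plus) %||% 0
    gm <- add_ch(grads$p_minus) %||% 0
    if (!is.null(gfin)) { gp <- gp + gfin / 2; gm <- gm + gfin / 2 }
    zero <- array(0, dim = dim(ctx$x)[1:3])
    if (identical(gp, 0)) gp <- array(0, dim = c(dim(zero), 1L))
    if (identical(gm, 0)) gm <- array(0, dim = c(dim(zero), 1L))
    ge_p <- decoder_backward(model$parts$dec_plus, ctx$plus, gp)
    ge_m <- decoder_backward(model$parts$dec_minus, ctx$minus, gm)
    ge <- lapply(seq_along(ge_p), function(i) (ge_p[[i]] %||% 0) + (ge_m[[i]] %||% 0))
    encoder_backward(model$parts$enc, ctx$e, ge)
  } else {
    gp <- add_ch(grads$p)
    ge <- decoder_backward(model$parts$dec, ctx$dec, gp)
    encoder_backward(model$parts$enc, ctx$e, ge)
  }
}

#' Measure the effective receptive field of each decoder
#'
#' The ERF is estimated from input gradients: for each random input, the
#' gradient of the central output voxel of a decoder's probability map is
#' propagated back to the input; absolute gradient mass is accumulated over
#' all `n_inputs` inputs (individual inputs can have locally dead ReLU paths)
#' and the ERF radius is the root mean squared distance from the centre
#' weighted by that accumulated mass.  The dilation-biased decoder should
#' measure a strictly larger radius than the erosion-biased one.
#'
#' @param model a dual-decoder `vssl_net`.
#' @param decoder `"plus"` or `"minus"`.
#' @param n_inputs number of random inputs to average over.
#' @param size input edge length (defaults to the configured patch size).
#' @param seed seed for the random inputs.
#' @return mean ERF radius in voxels.
#' @export
erf_radius <- function(model, decoder = c("plus", "minus"), n_inputs = 10L,
                       size = model$config$patch_size, seed = 1L) {
  decoder <- match.arg(decoder)
  stopifnot(model$kind == "mismatch")
  stream <- rng_stream(seed)
  ctr <- (size + 1) / 2
  coord <- seq_len(size) - ctr
  d2 <- outer(outer(coord^2, coord^2, `+`), coord^2, `+`)  # squared distance grid
  mass <- array(0, dim = c(size, size, size))
  for (i in seq_len(n_inputs)) {
    x <- with_stream(stream, array(rnorm(size^3), dim = c(size, size, size)))
    out <- net_forward(model, x, keep_ctx = TRUE)
    g <- array(0, dim = c(size, size, size))
    g[ceiling(ctr), ceiling(ctr), ceiling(ctr)] <- 1
    zero_grads(model)
    gx <- net_backward(model, out,
                       if (decoder == "plus") list(p_plus = g) else list(p_minus = g))
    dim(gx) <- c(size, size, size)
    mass <- mass + abs(gx)
  }
  zero_grads(model)
  if (sum(mass) == 0) return(0)
  sqrt(sum(mass * d2) / sum(mass))
}
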