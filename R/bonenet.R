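#' Detection network configuration
#'
#' A compact residual encoder-decoder for per-landmark voting vector
#' fields and a bone segmentation map.  The encoder is a ResNet-style
#' stack of four stages of two-convolution basic blocks whose depths
#' default to `c(3, 3, 4, 3)` -- the baseline `c(2, 2, 2, 2)` stack
#' deepened by one, one, two and one extra blocks.  Spatial resolution
#' bottoms out at 1/8 of the input (later stages use dilated
#' convolutions instead of further striding); the decoder recovers full
#' resolution with three upsample+convolution steps, and its first
#' skip connection is sourced from encoder stage `skip_stage`
#' (default the 3rd).  The head emits `2 * k` vector-field channels
#' plus 2 segmentation logits at full resolution.
#'
#' @param input_size Square input edge length; must be divisible by 8.
#' @param k Number of landmarks.
#' @param depths Encoder stage depths (4 integers).
#' @param widths Encoder stage channel widths (4 integers).
#' @param stem_width Channels of the initial stride-2 convolution.
#' @param decoder_width Channels of the decoder convolutions.
#' @param skip_stage Encoder stage feeding the first decoder skip
#'   (2 = the baseline shortcut, 3 = the deepened variant).
#' @return An object of class `bonenet_config`.
#' @export
bonenet_config <- function(input_size = 64L, k = 8L,
                           depths = c(3L, 3L, 4L, 3L),
                           widths = c(8L, 16L, 32L, 32L),
                           stem_width = 8L, decoder_width = 16L,
                           skip_stage = 3L) {
  if (input_size %% 8L != 0L)
    stop("input_size must be divisible by 8 (the encoder bottoms at 1/8)")
  stopifnot(length(depths) == 4, length(widths) == 4, all(depths >= 1),
            k >= 1, skip_stage %in% c(2L, 3L, 4L))
  structure(list(input_size = as.integer(input_size), k = as.integer(k),
                 depths = as.integer(depths), widths = as.integer(widths),
                 stem_width = as.integer(stem_width),
                 decoder_width = as.integer(decoder_width),
                 skip_stage = as.integer(skip_stage)),
            class = "bonenet_config")
}

init_conv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0,
                     sqrt(2 / (kh * kw * cin))), c(kh, kw, cin, cout))
}

#' Build the detection network
#'
#' Allocates and initializes all parameters (He-normal convolutions,
#' unit-gain batchnorm) for a [bonenet_config()].  Deterministic given
#' `seed`.
#'
#' @param config A [bonenet_config()].
#' @param seed Integer RNG seed for initialization.
#' @return An object of class `bonenet`: `config`, `params` (flat named
#'   list of arrays) and `bn` (running batchnorm statistics).
#' @export
build_bonenet <- function(config = bonenet_config(), seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  p <- list(); bn <- list()
  add_conv <- function(name, kh, kw, cin, cout) {
    p[[paste0(name, ".W")]] <<- init_conv(kh, kw, cin, cout)
    p[[paste0(name, ".b")]] <<- numeric(cout)
  }
  add_bn <- function(name, c) {
    p[[paste0(name, ".gamma")]] <<- rep(1, c)
    p[[paste0(name, ".beta")]] <<- numeric(c)
    e <- new.env(parent = emptyenv())
    e$mean <- numeric(c); e$var <- rep(1, c)
    bn[[name]] <<- e
  }
  add_conv("stem.conv", 3, 3, 1, config$stem_width)
  add_bn("stem.bn", config$stem_width)
  cin <- config$stem_width
  for (s in 1:4) {
    w <- config$widths[s]
    for (bk in seq_len(config$depths[s])) {
      pre <- sprintf("stage%d.block%d", s, bk)
      add_conv(paste0(pre, ".conv1"), 3, 3, cin, w)
      add_bn(paste0(pre, ".bn1"), w)
      add_conv(paste0(pre, ".conv2"), 3, 3, w, w)
      add_bn(paste0(pre, ".bn2"), w)
      if (cin != w || (s == 2 && bk == 1))
        add_conv(paste0(pre, ".proj"), 1, 1, cin, w)
      cin <- w
    }
  }
  dw <- config$decoder_width
  add_conv("dec0.conv", 1, 1, config$widths[4], dw); add_bn("dec0.bn", dw)
  add_conv("skip8.conv", 1, 1, config$widths[config$skip_stage], dw)
  add_conv("skip4.conv", 1, 1, config$widths[1], dw)
  add_conv("skip2.conv", 1, 1, config$stem_width, dw)
  for (u in 1:3) {
    add_conv(sprintf("dec%d.conv", u), 3, 3, dw, dw)
    add_bn(sprintf("dec%d.bn", u), dw)
  }
  add_conv("head.conv", 1, 1, dw, 2L * config$k + 2L)
  structure(list(config = config, params = p, bn = bn), class = "bonenet")
}

#' @export
print.bonenet <- function(x, ...) {
  cat(sprintf("<bonenet> input %d, %d landmarks, stage depths [%s], %d parameters\n",
              x$config$input_size, x$config$k,
              paste(x$config$depths, collapse = ","), count_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param net A `bonenet`.
#' @return Integer count.
#' @export
count_params <- function(net) sum(vapply(net$params, length, 0L))

block_forward <- function(x, pre, p, bn, stride, dil, train) {
  c1 <- conv2d_forward(x, p[[paste0(pre, ".conv1.W")]],
                       p[[paste0(pre, ".conv1.b")]], stride, dil)
  b1 <- bn_forward(c1$out, p[[paste0(pre, ".bn1.gamma")]],
                   p[[paste0(pre, ".bn1.beta")]], bn[[paste0(pre, ".bn1")]],
                   train)
  r1 <- relu_forward(b1$out)
  c2 <- conv2d_forward(r1$out, p[[paste0(pre, ".conv2.W")]],
                       p[[paste0(pre, ".conv2.b")]], 1L, dil)
  b2 <- bn_forward(c2$out, p[[paste0(pre, ".bn2.gamma")]],
                   p[[paste0(pre, ".bn2.beta")]], bn[[paste0(pre, ".bn2")]],
                   train)
  has_proj <- !is.null(p[[paste0(pre, ".proj.W")]])
  sc <- if (has_proj)
    conv2d_forward(x, p[[paste0(pre, ".proj.W")]],
                   p[[paste0(pre, ".proj.b")]], stride, 1L)
  else list(out = x, cache = NULL)
  r2 <- relu_forward(b2$out + sc$out)
  list(out = r2$out,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, sc = sc$cache,
                    r2 = r2$cache, has_proj = has_proj))
}

block_backward <- function(dout, pre, p, cache, g) {
  d <- relu_backward(cache$r2, dout)
  bb2 <- bn_backward(cache$b2, p[[paste0(pre, ".bn2.gamma")]], d)
  g[[paste0(pre, ".bn2.gamma")]] <- bb2$dgamma
  g[[paste0(pre, ".bn2.beta")]] <- bb2$dbeta
  cb2 <- conv2d_backward(cache$c2, p[[paste0(pre, ".conv2.W")]], bb2$dx)
  g[[paste0(pre, ".conv2.W")]] <- cb2$dW
  g[[paste0(pre, ".conv2.b")]] <- cb2$db
  dr1 <- relu_backward(cache$r1, cb2$dx)
  bb1 <- bn_backward(cache$b1, p[[paste0(pre, ".bn1.gamma")]], dr1)
  g[[paste0(pre, ".bn1.gamma")]] <- bb1$dgamma
  g[[paste0(pre, ".bn1.beta")]] <- bb1$dbeta
  cb1 <- conv2d_backward(cache$c1, p[[paste0(pre, ".conv1.W")]], bb1$dx)
  g[[paste0(pre, ".conv1.W")]] <- cb1$dW
  g[[paste0(pre, ".conv1.b")]] <- cb1$db
  dx <- cb1$dx
  if (cache$has_proj) {
    sb <- conv2d_backward(cache$sc, p[[paste0(pre, ".proj.W")]], d)
    g[[paste0(pre, ".proj.W")]] <- sb$dW
    g[[paste0(pre, ".proj.b")]] <- sb$db
    dx <- dx + sb$dx
  } else dx <- dx + d
  list(dx = dx, g = g)
}

#' Forward pass of the detection network
#'
#' @param net A `bonenet`.
#' @param x Input tensor `(H, W, N, 1)` (or an `H x W` matrix for a
#'   single image).
#' @param train Training mode (batch statistics) or evaluation mode
#'   (running statistics).
#' @return A list: `fields` `(H, W, N, 2k)`, `seg` logits
#'   `(H, W, N, 2)`, and `cache` for the backward pass (training mode).
#' @export
bonenet_forward <- function(net, x, train = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  p <- net$params; bn <- net$bn; cfg <- net$config
  caches <- list()
  stem_c <- conv2d_forward(x, p[["stem.conv.W"]], p[["stem.conv.b"]], 2L, 1L)
  stem_b <- bn_forward(stem_c$out, p[["stem.bn.gamma"]], p[["stem.bn.beta"]],
                       bn[["stem.bn"]], train)
  stem_r <- relu_forward(stem_b$out)
  pool <- maxpool2_forward(stem_r$out)
  caches$stem <- list(c = stem_c$cache, b = stem_b$cache, r = stem_r$cache,
                      pool = pool$cache)

  h <- pool$out
  stage_out <- vector("list", 4)
  stage_cfg <- list(list(stride = 1L, dil = 1L), list(stride = 2L, dil = 1L),
                    list(stride = 1L, dil = 2L), list(stride = 1L, dil = 4L))
  for (s in 1:4) {
    blocks <- list()
    for (bk in seq_len(cfg$depths[s])) {
      pre <- sprintf("stage%d.block%d", s, bk)
      st <- if (bk == 1L) stage_cfg[[s]]$stride else 1L
      r <- block_forward(h, pre, p, bn, st, stage_cfg[[s]]$dil, train)
      h <- r$out
      blocks[[bk]] <- r$cache
    }
    caches[[sprintf("stage%d", s)]] <- blocks
    stage_out[[s]] <- h
  }

  d0c <- conv2d_forward(stage_out[[4]], p[["dec0.conv.W"]],
                        p[["dec0.conv.b"]], 1L, 1L)
  d0b <- bn_forward(d0c$out, p[["dec0.bn.gamma"]], p[["dec0.bn.beta"]],
                    bn[["dec0.bn"]], train)
  d0r <- relu_forward(d0b$out)
  sk8 <- conv2d_forward(stage_out[[cfg$skip_stage]], p[["skip8.conv.W"]],
                        p[["skip8.conv.b"]], 1L, 1L)
  h8 <- d0r$out + sk8$out
  caches$dec0 <- list(c = d0c$cache, b = d0b$cache, r = d0r$cache,
                      sk = sk8$cache)

  dims8 <- dim(h8)
  Uh4 <- upsample_matrix(dims8[1]); Uw4 <- upsample_matrix(dims8[2])
  u1 <- upsample2_forward(h8, Uh4, Uw4)
  d1c <- conv2d_forward(u1$out, p[["dec1.conv.W"]], p[["dec1.conv.b"]], 1L, 1L)
  d1b <- bn_forward(d1c$out, p[["dec1.bn.gamma"]], p[["dec1.bn.beta"]],
                    bn[["dec1.bn"]], train)
  d1r <- relu_forward(d1b$out)
  sk4 <- conv2d_forward(stage_out[[1]], p[["skip4.conv.W"]],
                        p[["skip4.conv.b"]], 1L, 1L)
  h4 <- d1r$out + sk4$out
  caches$dec1 <- list(up = u1$cache, c = d1c$cache, b = d1b$cache,
                      r = d1r$cache, sk = sk4$cache, Uh = Uh4, Uw = Uw4)

  dims4 <- dim(h4)
  Uh2 <- upsample_matrix(dims4[1]); Uw2 <- upsample_matrix(dims4[2])
  u2 <- upsample2_forward(h4, Uh2, Uw2)
  d2c <- conv2d_forward(u2$out, p[["dec2.conv.W"]], p[["dec2.conv.b"]], 1L, 1L)
  d2b <- bn_forward(d2c$out, p[["dec2.bn.gamma"]], p[["dec2.bn.beta"]],
                    bn[["dec2.bn"]], train)
  d2r <- relu_forward(d2b$out)
  sk2 <- conv2d_forward(stem_r$out, p[["skip2.conv.W"]],
                        p[["skip2.conv.b"]], 1L, 1L)
  h2 <- d2r$out + sk2$out
  caches$dec2 <- list(up = u2$cache, c = d2c$cache, b = d2b$cache,
                      r = d2r$cache, sk = sk2$cache, Uh = Uh2, Uw = Uw2)

  dims2 <- dim(h2)
  Uh1 <- upsample_matrix(dims2[1]); Uw1 <- upsample_matrix(dims2[2])
  u3 <- upsample2_forward(h2, Uh1, Uw1)
  d3c <- conv2d_forward(u3$out, p[["dec3.conv.W"]], p[["dec3.conv.b"]], 1L, 1L)
  d3b <- bn_forward(d3c$out, p[["dec3.bn.gamma"]], p[["dec3.bn.beta"]],
                    bn[["dec3.bn"]], train)
  d3r <- relu_forward(d3b$out)
  hd <- conv2d_forward(d3r$out, p[["head.conv.W"]], p[["head.conv.b"]],
                       1L, 1L)
  caches$dec3 <- list(up = u3$cache, c = d3c$cache, b = d3b$cache,
                      r = d3r$cache, Uh = Uh1, Uw = Uw1)
  caches$head <- hd$cache

  out <- hd$out
  k2 <- 2L * cfg$k
  list(fields = out[, , , seq_len(k2), drop = FALSE],
       seg = out[, , , k2 + 1:2, drop = FALSE],
       cache = caches)
}

bonenet_backward <- function(net, cache, dfields, dseg) {
  p <- net$params; cfg <- net$config
  g <- list()
  dout <- array(0, c(dim(dfields)[1:3], 2L * cfg$k + 2L))
  dout[, , , seq_len(2L * cfg$k)] <- dfields
  dout[, , , 2L * cfg$k + 1:2] <- dseg

  hb <- conv2d_backward(cache$head, p[["head.conv.W"]], dout)
  g[["head.conv.W"]] <- hb$dW; g[["head.conv.b"]] <- hb$db
  d <- relu_backward(cache$dec3$r, hb$dx)
  bb <- bn_backward(cache$dec3$b, p[["dec3.bn.gamma"]], d)
  g[["dec3.bn.gamma"]] <- bb$dgamma; g[["dec3.bn.beta"]] <- bb$dbeta
  cb <- conv2d_backward(cache$dec3$c, p[["dec3.conv.W"]], bb$dx)
  g[["dec3.conv.W"]] <- cb$dW; g[["dec3.conv.b"]] <- cb$db
  dh2 <- upsample2_backward(cache$dec3$up, cache$dec3$Uh, cache$dec3$Uw,
                            cb$dx)

  sb <- conv2d_backward(cache$dec2$sk, p[["skip2.conv.W"]], dh2)
  g[["skip2.conv.W"]] <- sb$dW; g[["skip2.conv.b"]] <- sb$db
  dstem_extra <- sb$dx
  d <- relu_backward(cache$dec2$r, dh2)
  bb <- bn_backward(cache$dec2$b, p[["dec2.bn.gamma"]], d)
  g[["dec2.bn.gamma"]] <- bb$dgamma; g[["dec2.bn.beta"]] <- bb$dbeta
  cb <- conv2d_backward(cache$dec2$c, p[["dec2.conv.W"]], bb$dx)
  g[["dec2.conv.W"]] <- cb$dW; g[["dec2.conv.b"]] <- cb$db
  dh4 <- upsample2_backward(cache$dec2$up, cache$dec2$Uh, cache$dec2$Uw,
                            cb$dx)

  sb <- conv2d_backward(cache$dec1$sk, p[["skip4.conv.W"]], dh4)
  g[["skip4.conv.W"]] <- sb$dW; g[["skip4.conv.b"]] <- sb$db
  dstage1_extra <- sb$dx
  d <- relu_backward(cache$dec1$r, dh4)
  bb <- bn_backward(cache$dec1$b, p[["dec1.bn.gamma"]], d)
  g[["dec1.bn.gamma"]] <- bb$dgamma; g[["dec1.bn.beta"]] <- bb$dbeta
  cb <- conv2d_backward(cache$dec1$c, p[["dec1.conv.W"]], bb$dx)
  g[["dec1.conv.W"]] <- cb$dW; g[["dec1.conv.b"]] <- cb$db
  dh8 <- upsample2_backward(cache$dec1$up, cache$dec1$Uh, cache$dec1$Uw,
                            cb$dx)

  sb <- conv2d_backward(cache$dec0$sk, p[["skip8.conv.W"]], dh8)
  g[["skip8.conv.W"]] <- sb$dW; g[["skip8.conv.b"]] <- sb$db
  dskip_stage_extra <- sb$dx
  d <- relu_backward(cache$dec0$r, dh8)
  bb <- bn_backward(cache$dec0$b, p[["dec0.bn.gamma"]], d)
  g[["dec0.bn.gamma"]] <- bb$dgamma; g[["dec0.bn.beta"]] <- bb$dbeta
  cb <- conv2d_backward(cache$dec0$c, p[["dec0.conv.W"]], bb$dx)
  g[["dec0.conv.W"]] <- cb$dW; g[["dec0.conv.b"]] <- cb$db
  dstage4 <- cb$dx
  if (cfg$skip_stage == 4L) dstage4 <- dstage4 + dskip_stage_extra

  dcur <- dstage4
  for (s in 4:1) {
    for (bk in rev(seq_len(cfg$depths[s]))) {
      pre <- sprintf("stage%d.block%d", s, bk)
      r <- block_backward(dcur, pre, p, cache[[sprintf("stage%d", s)]][[bk]],
                          g)
      dcur <- r$dx; g <- r$g
    }
    if (s == cfg$skip_stage + 1L && s <= 4L) dcur <- dcur + dskip_stage_extra
    if (s == 2L) dcur <- dcur + dstage1_extra
  }

  dpool <- maxpool2_backward(cache$stem$pool, dcur)
  dstem <- dpool + dstem_extra
  d <- relu_backward(cache$stem$r, dstem)
  bb <- bn_backward(cache$stem$b, p[["stem.bn.gamma"]], d)
  g[["stem.bn.gamma"]] <- bb$dgamma; g[["stem.bn.beta"]] <- bb$dbeta
  cb <- conv2d_backward(cache$stem$c, p[["stem.conv.W"]], bb$dx)
  g[["stem.conv.W"]] <- cb$dW; g[["stem.conv.b"]] <- cb$db
  g
}

huber <- function(e) ifelse(abs(e) < 1, 0.5 * e^2, abs(e) - 0.5)
huber_grad <- function(e) pmin(pmax(e, -1), 1)

#' Training loss: masked smooth-L1 plus segmentation cross entropy
#'
#' The vector-field term is the smooth-L1 (Huber, delta = 1) difference
#' between predicted and target fields restricted to the ground-truth
#' mask, averaged over masked pixels and landmarks (each landmark
#' contributes its two components' Huber sum).  The segmentation term
#' is the softmax cross entropy of the two-channel logits against the
#' mask, averaged over all pixels.  The two terms are added by default
#' (`ce_sign = 1`); `ce_sign = -1` reproduces a subtractive convention.
#'
#' @param fields Predicted fields `(H, W, N, 2k)`.
#' @param seg Predicted segmentation logits `(H, W, N, 2)`.
#' @param target_fields Target fields, same shape as `fields`.
#' @param mask Ground-truth segment: `(H, W, N)` array or `H x W`
#'   matrix (logical/0-1).
#' @param ce_sign `+1` (default) or `-1`.
#' @param grad Also return gradients w.r.t. `fields` and `seg`.
#' @return A list with `total`, `field_term`, `ce_term` (and `dfields`,
#'   `dseg` when `grad = TRUE`).
#' @export
bonenet_loss <- function(fields, seg, target_fields, mask, ce_sign = 1,
                         grad = FALSE) {
  d <- dim(fields)
  k <- d[4] %/% 2L
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1L))
  m <- array(as.numeric(mask), d[1:3])
  n_masked <- sum(m)
  e <- fields - target_fields
  mexp <- array(m, d)                      # recycles across channels
  fl <- sum(huber(e) * mexp) / max(1, n_masked * k)

  mx <- pmax(seg[, , , 1, drop = FALSE], seg[, , , 2, drop = FALSE])
  e1 <- exp(seg[, , , 1, drop = FALSE] - mx)
  e2 <- exp(seg[, , , 2, drop = FALSE] - mx)
  z <- e1 + e2
  p_bone <- array(e2 / z, d[1:3])
  npix <- prod(d[1:3])
  ce <- -sum(m * log(pmax(p_bone, 1e-12)) +
               (1 - m) * log(pmax(1 - p_bone, 1e-12))) / npix

  out <- list(total = fl + ce_sign * ce, field_term = fl, ce_term = ce)
  if (grad) {
    out$dfields <- huber_grad(e) * mexp / max(1, n_masked * k)
    dlogit_bone <- (p_bone - m) / npix * ce_sign
    dseg <- array(0, c(d[1:3], 2L))
    dseg[, , , 1] <- -dlogit_bone
    dseg[, , , 2] <- dlogit_bone
    out$dseg <- dseg
  }
  out
}

#' Training configuration
#'
#' Adam optimizer with a multistep learning-rate schedule: the base
#' rate is multiplied by `decay_rate^e` over the first `decay_epochs`
#' epochs (the reference protocol uses base rate `1e-5` over a maximum
#' of 600 epochs at full scale; the desk-scale default uses a larger
#' base rate and 30 epochs so a freshly initialized network moves
#' measurably).
#'
#' @param base_lr Base learning rate.
#' @param decay_rate Multiplicative decay per epoch during the first
#'   `decay_epochs` epochs.
#' @param decay_epochs Number of decaying epochs (0 disables decay).
#' @param max_epochs Training epochs.
#' @param batch_size Samples per gradient step.
#' @param seed Integer RNG seed (shuffling).
#' @return An object of class `train_config`.
#' @export
train_config <- function(base_lr = 1e-3, decay_rate = 0.5,
                         decay_epochs = 5L, max_epochs = 30L,
                         batch_size = 4L, seed = 1L) {
  stopifnot(base_lr > 0, max_epochs >= 1, batch_size >= 1)
  structure(list(base_lr = base_lr, decay_rate = decay_rate,
                 decay_epochs = as.integer(decay_epochs),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)), class = "train_config")
}

#' Reference full-scale training protocol
#'
#' Base learning rate `1e-5` decayed by `0.5^e` over the first five
#' epochs, up to 600 epochs; intended for full-resolution GPU-scale
#' training and provided for completeness.
#' @param ... Overrides passed to [train_config()].
#' @return A [train_config()].
#' @export
reference_train_protocol <- function(...)
  train_config(base_lr = 1e-5, decay_rate = 0.5, decay_epochs = 5L,
               max_epochs = 600L, ...)

#' Assemble a training sample
#'
#' Normalizes an image and encodes the per-landmark voting vector
#' fields from a mask and ground-truth pixel coordinates.
#'
#' @param image Numeric matrix (radiograph).
#' @param mask Logical matrix (bone segment).
#' @param landmarks_rc `k x 2` matrix of `(row, col)` landmark pixels.
#' @return A list `x` (standardized image), `fields` `(H, W, 2k)`,
#'   `mask`.
#' @export
make_training_sample <- function(image, mask, landmarks_rc) {
  k <- nrow(landmarks_rc)
  d <- dim(image)
  fields <- array(0, c(d, 2L * k))
  for (i in seq_len(k))
    fields[, , 2L * i - 1:0] <- encode_vector_field(mask, landmarks_rc[i, ])
  x <- (image - mean(image)) / (stats::sd(image) + 1e-8)
  list(x = x, fields = fields, mask = mask)
}

#' Train the detection network
#'
#' Minimizes [bonenet_loss()] with Adam under the [train_config()]
#' schedule.  Deterministic given the seeds (single-threaded BLAS
#' assumed).  Aborts with diagnostics if the loss becomes non-finite.
#'
#' @param samples List of samples from [make_training_sample()].
#' @param net A `bonenet` (see [build_bonenet()]); its input size must
#'   match the samples.
#' @param config A [train_config()].
#' @param val_samples Optional held-out samples evaluated per epoch.
#' @return A list: `net` (trained), `history` (data.frame of per-epoch
#'   `epoch`, `lr`, `train_loss`, `val_loss`).
#' @export
train_bonenet <- function(samples, net, config = train_config(),
                          val_samples = NULL) {
  stopifnot(length(samples) >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  stack <- function(ss) {
    n <- length(ss); d <- dim(ss[[1]]$x); k2 <- dim(ss[[1]]$fields)[3]
    x <- array(0, c(d, n, 1L)); f <- array(0, c(d, n, k2))
    m <- array(0, c(d, n))
    for (i in seq_len(n)) {
      x[, , i, 1] <- ss[[i]]$x
      f[, , i, ] <- ss[[i]]$fields
      m[, , i] <- ss[[i]]$mask
    }
    list(x = x, f = f, m = m)
  }
  val <- if (length(val_samples)) stack(val_samples)

  st <- adam_state(net$params)
  hist <- data.frame()
  n <- length(samples)
  for (e in seq_len(config$max_epochs)) {
    lr <- config$base_lr *
      config$decay_rate^min(e - 1L, config$decay_epochs)
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (b0 in seq(1, n, by = config$batch_size)) {
      ids <- ord[b0:min(n, b0 + config$batch_size - 1L)]
      bt <- stack(samples[ids])
      fw <- bonenet_forward(net, bt$x, train = TRUE)
      ls <- bonenet_loss(fw$fields, fw$seg, bt$f, bt$m, grad = TRUE)
      if (!is.finite(ls$total))
        stop(sprintf("training diverged at epoch %d (loss %g)", e, ls$total))
      g <- bonenet_backward(net, fw$cache, ls$dfields, ls$dseg)
      upd <- adam_update(net$params, g, st, lr)
      net$params <- upd$params
      st <- upd$state
      ep_loss <- ep_loss + ls$total; nb <- nb + 1
    }
    vl <- NA_real_
    if (!is.null(val)) {
      fv <- bonenet_forward(net, val$x, train = FALSE)
      vl <- bonenet_loss(fv$fields, fv$seg, val$f, val$m)$total
    }
    hist <- rbind(hist, data.frame(epoch = e, lr = lr,
                                   train_loss = ep_loss / nb,
                                   val_loss = vl))
  }
  list(net = net, history = hist)
}

#' Detect landmarks in an image with a trained network
#'
#' Runs the network in evaluation mode, takes the predicted
#' segmentation (argmax of the two logits, optionally overridden by a
#' provided mask), and votes each landmark from its predicted field.
#'
#' @param net A trained `bonenet`.
#' @param image Numeric matrix; standardized internally.
#' @param mask Optional logical matrix overriding the predicted
#'   segment.
#' @param config A [voting_config()].
#' @return List of `landmark_observation2d`, one per landmark; entries
#'   are `NULL` where voting degenerates.
#' @export
detect_landmarks <- function(net, image, mask = NULL,
                             config = voting_config()) {
  x <- (image - mean(image)) / (stats::sd(image) + 1e-8)
  fw <- bonenet_forward(net, x, train = FALSE)
  if (is.null(mask))
    mask <- fw$seg[, , 1, 2] > fw$seg[, , 1, 1]
  k <- net$config$k
  out <- vector("list", k)
  for (i in seq_len(k)) {
    f <- fw$fields[, , 1, 2L * i - 1:0]
    out[[i]] <- tryCatch(vote_landmark(f, mask, config),
                         error = function(e) NULL)
  }
  out
}
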