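# Minimal convolutional-network primitives used by the landmark
# detection network.  Tensors are numeric arrays laid out (H, W, N, C)
# so that the channel dimension flattens last (matrix views are
# (H*W*N) x C, which feeds BLAS matrix products directly).

nn_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}
nn_unmat <- function(m, d) { dim(m) <- d; m }

# zero padding along H and W
nn_pad <- function(x, ph, pw) {
  d <- dim(x)
  out <- array(0, c(d[1] + sum(ph), d[2] + sum(pw), d[3], d[4]))
  out[ph[1] + seq_len(d[1]), pw[1] + seq_len(d[2]), , ] <- x
  out
}

# "same"-style convolution: output spatial size = input / stride
conv2d_forward <- function(x, W, b, stride = 1L, dilation = 1L) {
  d <- dim(x); kh <- dim(W)[1]; kw <- dim(W)[2]; cout <- dim(W)[4]
  ho <- d[1] %/% stride; wo <- d[2] %/% stride
  need_h <- (ho - 1L) * stride + (kh - 1L) * dilation + 1L
  need_w <- (wo - 1L) * stride + (kw - 1L) * dilation + 1L
  ph <- max(0L, need_h - d[1]); pw <- max(0L, need_w - d[2])
  pads <- c(ph %/% 2L, ph - ph %/% 2L)
  padsw <- c(pw %/% 2L, pw - pw %/% 2L)
  P <- nn_pad(x, pads, padsw)
  out <- matrix(rep(b, each = ho * wo * d[3]), ho * wo * d[3], cout)
  rows0 <- (seq_len(ho) - 1L) * stride
  cols0 <- (seq_len(wo) - 1L) * stride
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    sl <- P[rows0 + (i - 1L) * dilation + 1L,
            cols0 + (j - 1L) * dilation + 1L, , , drop = FALSE]
    Wij <- W[i, j, , ]
    if (is.null(dim(Wij))) Wij <- matrix(Wij, dim(W)[3], cout)
    out <- out + nn_mat(sl) %*% Wij
  }
  list(out = nn_unmat(out, c(ho, wo, d[3], cout)),
       cache = list(P = P, din = d, pads = pads, padsw = padsw,
                    stride = stride, dilation = dilation,
                    kdim = dim(W)))
}

conv2d_backward <- function(cache, W, dout) {
  dd <- dim(dout)
  kh <- cache$kdim[1]; kw <- cache$kdim[2]
  cin <- cache$kdim[3]; cout <- cache$kdim[4]
  dmat <- nn_mat(dout)
  dW <- array(0, cache$kdim)
  dP <- array(0, dim(cache$P))
  rows0 <- (seq_len(dd[1]) - 1L) * cache$stride
  cols0 <- (seq_len(dd[2]) - 1L) * cache$stride
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    ri <- rows0 + (i - 1L) * cache$dilation + 1L
    cj <- cols0 + (j - 1L) * cache$dilation + 1L
    sl <- cache$P[ri, cj, , , drop = FALSE]
    dW[i, j, , ] <- crossprod(nn_mat(sl), dmat)
    Wij <- W[i, j, , ]
    if (is.null(dim(Wij))) Wij <- matrix(Wij, cin, cout)
    dsl <- nn_unmat(tcrossprod(dmat, Wij), c(dd[1], dd[2], dd[3], cin))
    dP[ri, cj, , ] <- dP[ri, cj, , , drop = FALSE] + dsl
  }
  db <- colSums(dmat)
  d <- cache$din
  dx <- dP[cache$pads[1] + seq_len(d[1]),
           cache$padsw[1] + seq_len(d[2]), , , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

bn_forward <- function(x, gamma, beta, state, train = TRUE,
                      momentum = 0.1, eps = 1e-5) {
  m <- nn_mat(x)
  if (train) {
    mu <- colMeans(m)
    va <- colMeans(sweep(m, 2, mu)^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean; va <- state$var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(m, 2, mu), 2, inv, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = nn_unmat(out, dim(x)),
       cache = list(xhat = xhat, inv = inv, dims = dim(x)))
}

bn_backward <- function(cache, gamma, dout) {
  dm <- nn_mat(dout)
  n <- nrow(dm)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2, gamma, "*")
  mean_dxhat <- colMeans(dxhat)
  mean_dxhat_xhat <- colMeans(dxhat * cache$xhat)
  dx <- dxhat -
    matrix(mean_dxhat, n, ncol(dm), byrow = TRUE) -
    cache$xhat * matrix(mean_dxhat_xhat, n, ncol(dm), byrow = TRUE)
  dx <- sweep(dx, 2, cache$inv, "*")
  list(dx = nn_unmat(dx, cache$dims), dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(cache, dout) dout * cache

maxpool2_forward <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  a <- x[i1, j1, , , drop = FALSE]; b <- x[i2, j1, , , drop = FALSE]
  cc <- x[i1, j2, , , drop = FALSE]; e <- x[i2, j2, , , drop = FALSE]
  out <- pmax(a, b, cc, e)
  m1 <- a == out
  m2 <- (b == out) & !m1
  m3 <- (cc == out) & !m1 & !m2
  m4 <- !(m1 | m2 | m3)
  list(out = out, cache = list(m = list(m1, m2, m3, m4), din = d))
}

maxpool2_backward <- function(cache, dout) {
  d <- cache$din
  dx <- array(0, d)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  dx[i1, j1, , ] <- dout * cache$m[[1]]
  dx[i2, j1, , ] <- dout * cache$m[[2]]
  dx[i1, j2, , ] <- dout * cache$m[[3]]
  dx[i2, j2, , ] <- dout * cache$m[[4]]
  dx
}

# factor-2 bilinear interpolation matrix (2n x n)
upsample_matrix <- function(n) {
  U <- matrix(0, 2L * n, n)
  for (i in seq_len(2L * n)) {
    x <- (i - 0.5) / 2 + 0.5
    lo <- floor(x); t <- x - lo
    lo <- min(max(lo, 1L), n)
    hi <- min(lo + 1L, n)
    U[i, lo] <- U[i, lo] + (1 - t)
    U[i, hi] <- U[i, hi] + t
  }
  U
}

upsample2_forward <- function(x, Uh, Uw) {
  d <- dim(x)
  m <- Uh %*% matrix(x, d[1])                    # H axis
  y <- array(m, c(2L * d[1], d[2], d[3], d[4]))
  y <- aperm(y, c(2, 1, 3, 4))
  m <- Uw %*% matrix(y, d[2])
  y <- array(m, c(2L * d[2], 2L * d[1], d[3], d[4]))
  list(out = aperm(y, c(2, 1, 3, 4)), cache = d)
}

upsample2_backward <- function(cache, Uh, Uw, dout) {
  d <- cache
  y <- aperm(dout, c(2, 1, 3, 4))
  m <- crossprod(Uw, matrix(y, 2L * d[2]))
  y <- array(m, c(d[2], 2L * d[1], d[3], d[4]))
  y <- aperm(y, c(2, 1, 3, 4))
  m <- crossprod(Uh, matrix(y, 2L * d[1]))
  array(m, d)
}

# Adam optimizer over a flat named list of arrays
adam_state <- function(params)
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_update <- function(params, grads, state, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}
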