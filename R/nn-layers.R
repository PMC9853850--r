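# Low-level neural-network primitives.
#
# All layers operate on dense base-R arrays and matrices so that the heavy
# lifting (convolutions via kernel-shifted GEMMs, recurrent steps, dense
# layers) runs inside BLAS. Sequence data is carried between layers as a
# 3-D array with dimensions (time, batch, channels); head layers operate on
# (batch, channels) matrices. Every layer has an analytic backward pass;
# correctness is established by finite-difference gradient checks in the
# test suite.

.glorot <- function(nr, nc, gain = 1) {
  lim <- gain * sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.as_mat <- function(a, nr, nc) {
  dim(a) <- c(nr, nc)
  a
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- layer constructors -------------------------------------------------

.layer_conv <- function(c_in, n_filters, kernel) {
  stopifnot(kernel %% 2L == 1L)
  w <- array(0, dim = c(kernel, c_in, n_filters))
  lim <- sqrt(6 / (kernel * c_in + kernel * n_filters))
  w[] <- stats::runif(length(w), -lim, lim)
  list(type = "conv", kernel = kernel, c_in = c_in, n_out = n_filters,
       params = list(W = w, b = numeric(n_filters)))
}

.layer_bn <- function(n_ch, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", n_out = n_ch, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, n_ch), beta = numeric(n_ch)),
       state = list(mean = numeric(n_ch), var = rep(1, n_ch)))
}

.layer_relu <- function(n_ch) list(type = "relu", n_out = n_ch,
                                   params = list())

.layer_pool <- function(n_ch, factor) {
  list(type = "pool", factor = as.integer(factor), n_out = n_ch,
       params = list())
}

.layer_dropout <- function(n_ch, p) {
  list(type = "dropout", p = p, n_out = n_ch, params = list())
}

.layer_gru <- function(c_in, units, return_seq) {
  h <- units
  list(type = "gru", c_in = c_in, units = h, return_seq = return_seq,
       n_out = h,
       params = list(W = .glorot(c_in, 3L * h),
                     Uzr = .glorot(h, 2L * h),
                     Uh = .glorot(h, h),
                     b = numeric(3L * h)))
}

.layer_gap <- function(n_ch) list(type = "gap", n_out = n_ch,
                                  params = list())

.layer_dense <- function(c_in, units, activation = "linear") {
  list(type = "dense", c_in = c_in, n_out = units, activation = activation,
       params = list(W = .glorot(c_in, units), b = numeric(units)))
}

# ---- forward passes -----------------------------------------------------
# Each returns list(out, cache); `mode` is list(training=, mc_dropout=).
# BatchNorm uses batch statistics only in training mode (Monte Carlo
# dropout keeps BN frozen at the running statistics).

.fwd_conv <- function(layer, a) {
  d <- dim(a)
  k <- layer$kernel; f <- layer$n_out; cin <- layer$c_in
  w <- layer$params$W
  dim(w) <- c(k * cin, f) # rows ordered kernel-offset-fastest, per channel
  out <- .cpp_conv_fwd(a, w, layer$params$b, k)
  list(out = out, cache = list(a = a, d = d))
}

.bwd_conv <- function(layer, cache, dout) {
  d <- cache$d
  k <- layer$kernel; f <- layer$n_out; cin <- layer$c_in
  w <- layer$params$W
  dim(w) <- c(k * cin, f)
  res <- .cpp_conv_bwd(cache$a, w, dout, k)
  dw <- res$dW
  dim(dw) <- c(k, cin, f)
  list(dinput = res$dinput, grads = list(W = dw, b = as.numeric(res$db)))
}

.fwd_bn <- function(layer, a, mode) {
  d <- dim(a)
  f <- layer$n_out
  nr <- length(a) %/% f
  res <- .cpp_bn_fwd(a, f, layer$params$gamma,
                     layer$params$beta, layer$state$mean, layer$state$var,
                     mode$training, layer$momentum, layer$eps)
  y <- res$y
  dim(y) <- d
  state_new <- NULL
  if (mode$training) {
    state_new <- list(mean = as.numeric(res$new_mean),
                      var = as.numeric(res$new_var))
  }
  list(out = y,
       cache = list(xhat = res$xhat, istd = as.numeric(res$istd), d = d,
                    nr = nr, training = mode$training),
       state = state_new)
}

.bwd_bn <- function(layer, cache, dout) {
  nr <- cache$nr; f <- layer$n_out
  res <- .cpp_bn_bwd(dout, cache$xhat, cache$istd,
                     layer$params$gamma, cache$training)
  dx <- res$dinput
  dim(dx) <- cache$d
  list(dinput = dx,
       grads = list(gamma = as.numeric(res$dgamma),
                    beta = as.numeric(res$dbeta)))
}

.fwd_relu <- function(layer, a) {
  y <- .cpp_relu_fwd(a)
  list(out = y, cache = list(y = y))
}

.bwd_relu <- function(layer, cache, dout) {
  list(dinput = .cpp_relu_bwd(dout, cache$y), grads = list())
}

.fwd_pool <- function(layer, a) {
  d <- dim(a)
  res <- .cpp_pool_fwd(a, layer$factor)
  list(out = res$out,
       cache = list(wh = res$wh, d = d, p = layer$factor))
}

.bwd_pool <- function(layer, cache, dout) {
  da <- .cpp_pool_bwd(dout, cache$wh, cache$d[1L], cache$p)
  list(dinput = da, grads = list())
}

.fwd_dropout <- function(layer, a, mode) {
  active <- (mode$training || isTRUE(mode$mc_dropout)) &&
    !isTRUE(mode$no_dropout) && layer$p > 0
  if (!active) {
    return(list(out = a, cache = list(mask = NULL)))
  }
  mask <- (stats::runif(length(a)) >= layer$p) / (1 - layer$p)
  out <- a * mask
  dim(out) <- dim(a)
  list(out = out, cache = list(mask = mask))
}

.bwd_dropout <- function(layer, cache, dout) {
  if (!is.null(cache$mask)) {
    dout <- dout * cache$mask
  }
  list(dinput = dout, grads = list())
}

.fwd_gru <- function(layer, a) {
  d <- dim(a); tt <- d[1L]; n <- d[2L]; cin <- d[3L]
  h <- layer$units
  p <- layer$params
  # reorder to batch-fastest rows so that rows (t-1)*n + 1 ... t*n of the
  # projected matrix hold time step t
  xmat <- .as_mat(aperm(a, c(2L, 1L, 3L)), tt * n, cin)
  xw <- xmat %*% p$W
  xw <- xw + rep(p$b, each = tt * n)
  zs <- array(0, dim = c(tt, n, h)); rs <- zs; hts <- zs; hprevs <- zs
  hseq <- zs
  hcur <- matrix(0, n, h)
  for (t in seq_len(tt)) {
    rows <- ((t - 1L) * n + 1L):(t * n)
    xw_t <- xw[rows, , drop = FALSE]
    u <- hcur %*% p$Uzr
    z <- .sigmoid(xw_t[, seq_len(h), drop = FALSE] +
                    u[, seq_len(h), drop = FALSE])
    r <- .sigmoid(xw_t[, h + seq_len(h), drop = FALSE] +
                    u[, h + seq_len(h), drop = FALSE])
    ht <- tanh(xw_t[, 2L * h + seq_len(h), drop = FALSE] +
                 (r * hcur) %*% p$Uh)
    hprevs[t, , ] <- hcur
    hcur <- (1 - z) * hcur + z * ht
    zs[t, , ] <- z; rs[t, , ] <- r; hts[t, , ] <- ht
    hseq[t, , ] <- hcur
  }
  out <- if (layer$return_seq) hseq else hcur
  list(out = out,
       cache = list(xmat = xmat, zs = zs, rs = rs, hts = hts,
                    hprevs = hprevs, tt = tt, n = n, h = h))
}

.bwd_gru <- function(layer, cache, dout) {
  tt <- cache$tt; n <- cache$n; h <- cache$h
  p <- layer$params
  uz <- p$Uzr[, seq_len(h), drop = FALSE]
  ur <- p$Uzr[, h + seq_len(h), drop = FALSE]
  g <- matrix(0, tt * n, 3L * h)
  duzr <- matrix(0, h, 2L * h)
  duh <- matrix(0, h, h)
  dh <- matrix(0, n, h)
  if (layer$return_seq) {
    dseq <- dout
  } else {
    dlast <- .as_mat(dout, n, h)
  }
  for (t in rev(seq_len(tt))) {
    if (layer$return_seq) {
      dh <- dh + .as_mat(dseq[t, , , drop = FALSE], n, h)
    } else if (t == tt) {
      dh <- dh + dlast
    }
    z <- .as_mat(cache$zs[t, , , drop = FALSE], n, h)
    r <- .as_mat(cache$rs[t, , , drop = FALSE], n, h)
    ht <- .as_mat(cache$hts[t, , , drop = FALSE], n, h)
    hp <- .as_mat(cache$hprevs[t, , , drop = FALSE], n, h)
    dht <- dh * z * (1 - ht^2)
    dz <- dh * (ht - hp) * z * (1 - z)
    d_rh <- tcrossprod(dht, p$Uh)
    dr <- d_rh * hp * r * (1 - r)
    rows <- ((t - 1L) * n + 1L):(t * n)
    g[rows, seq_len(h)] <- dz
    g[rows, h + seq_len(h)] <- dr
    g[rows, 2L * h + seq_len(h)] <- dht
    duzr <- duzr + crossprod(hp, cbind(dz, dr))
    duh <- duh + crossprod(r * hp, dht)
    dh <- dh * (1 - z) + tcrossprod(dz, uz) + tcrossprod(dr, ur) +
      d_rh * r
  }
  dx <- tcrossprod(g, p$W) # rows batch-fastest, grouped by time step
  dinput <- aperm(array(dx, dim = c(n, tt, layer$c_in)), c(2L, 1L, 3L))
  list(dinput = dinput,
       grads = list(W = crossprod(cache$xmat, g),
                    Uzr = duzr, Uh = duh, b = colSums(g)))
}

.layer_flatten <- function(n_out) list(type = "flatten", n_out = n_out,
                                       params = list())

.fwd_flatten <- function(layer, a) {
  d <- dim(a)
  out <- .as_mat(aperm(a, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
  list(out = out, cache = list(d = d))
}

.bwd_flatten <- function(layer, cache, dout) {
  d <- cache$d
  da <- aperm(array(dout, dim = c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
  list(dinput = da, grads = list())
}

.fwd_gap <- function(layer, a) {
  d <- dim(a); tt <- d[1L]
  m <- .as_mat(a, tt, d[2L] * d[3L])
  list(out = matrix(colMeans(m), d[2L], d[3L]), cache = list(d = d))
}

.bwd_gap <- function(layer, cache, dout) {
  d <- cache$d; tt <- d[1L]
  da <- array(rep(as.numeric(dout) / tt, each = tt), dim = d)
  list(dinput = da, grads = list())
}

.fwd_dense <- function(layer, a) {
  x <- if (is.matrix(a)) a else .as_mat(a, dim(a)[1L], dim(a)[2L])
  y <- x %*% layer$params$W + rep(layer$params$b, each = nrow(x))
  mask <- NULL
  if (layer$activation == "relu") {
    mask <- y > 0
    y[!mask] <- 0
  }
  list(out = y, cache = list(x = x, mask = mask))
}

.bwd_dense <- function(layer, cache, dout) {
  if (!is.null(cache$mask)) dout[!cache$mask] <- 0
  list(dinput = tcrossprod(dout, layer$params$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

# softmax probabilities from logits, numerically stable
.softmax <- function(z) {
  m <- z[, 1L]
  for (j in seq_len(ncol(z))[-1L]) m <- pmax(m, z[, j])
  e <- exp(z - m)
  e / rowSums(e)
}

# cross-entropy loss and gradient wrt logits; y is an integer class index
.softmax_ce <- function(z, y) {
  p <- .softmax(z)
  n <- nrow(z)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), y)] + eps))
  dz <- p
  dz[cbind(seq_len(n), y)] <- dz[cbind(seq_len(n), y)] - 1
  list(loss = loss, probs = p, dlogits = dz / n)
}
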