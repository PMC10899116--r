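# Numerical primitives for the segmentation network.
#
# Feature maps are numeric arrays dim (H, W, C). Convolutions are im2col +
# BLAS matmul; every spatial resampling (bilinear up, area-average down,
# adaptive average pooling) is expressed as a separable linear map
# y = A x t(B) per channel, so one forward/backward pair covers them all.

conv_params <- function(k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L,
                        init = c("he", "zero", "identity"), norm = FALSE) {
  init <- match.arg(init)
  W <- switch(init,
    he = matrix(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                k * k * cin, cout),
    zero = matrix(0, k * k * cin, cout),
    identity = {
      # 1x1 identity mapping where cin == cout (used in tests)
      stopifnot(k == 1L, cin == cout)
      diag(cout)
    })
  p <- list(W = W, k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad), cin = as.integer(cin),
            cout = as.integer(cout))
  if (norm) {
    # instance-normalized conv: no bias, per-channel affine after
    # normalization over the spatial grid (batch-free, deterministic)
    p$gamma <- rep(1, cout)
    p$beta <- numeric(cout)
  } else {
    p$b <- numeric(cout)
  }
  p
}

IN_EPS <- 1e-5

# Normalized convolutions use per-patch (instance) statistics while training
# - required for a correct, batch-free backward pass - and frozen calibrated
# statistics at inference (see calibrate_norm_stats), the usual batch-norm
# train/eval split. An uncalibrated network falls back to per-patch
# statistics at inference.
conv_fwd <- function(x, p, want_cache = TRUE, stats = NULL) {
  d <- dim(x)
  col <- cpp_im2col(x, p$k, p$stride, p$pad)
  out <- col %*% p$W
  ho <- (d[1] + 2L * p$pad - p$k) %/% p$stride + 1L
  wo <- (d[2] + 2L * p$pad - p$k) %/% p$stride + 1L
  cache <- if (want_cache) list(col = col, din = d) else NULL
  if (is.null(p$gamma)) {
    out <- sweep(out, 2L, p$b, "+")
  } else {
    train_mode <- want_cache || !is.null(stats) || is.null(p$rm)
    if (train_mode) {
      mu <- colMeans(out)
      v <- colMeans(out^2) - mu^2
      if (!is.null(stats) && !is.null(p$name)) {
        s <- stats[[p$name]]
        if (is.null(s)) s <- list(mu = 0, m2 = 0, n = 0L)
        stats[[p$name]] <- list(mu = s$mu + mu, m2 = s$m2 + v + mu^2,
                                n = s$n + 1L)
      }
    } else {
      mu <- p$rm
      v <- p$rv
    }
    sigma <- sqrt(v + IN_EPS)
    xhat <- sweep(sweep(out, 2L, mu, "-"), 2L, sigma, "/")
    out <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
    if (want_cache) { cache$xhat <- xhat; cache$sigma <- sigma }
  }
  dim(out) <- c(ho, wo, p$cout)
  if (want_cache) { cache$out <- out; cache } else list(out = out)
}

conv_bwd <- function(dout, p, cache) {
  dm <- matrix(dout, ncol = p$cout)
  if (is.null(p$gamma)) {
    db <- colSums(dm)
    g <- list(db = db)
  } else {
    dgamma <- colSums(dm * cache$xhat)
    dbeta <- colSums(dm)
    n <- nrow(dm)
    # backward through per-channel normalization
    dm <- sweep(dm, 2L, p$gamma, "*")
    dm <- sweep(dm, 2L, colMeans(dm), "-") -
      cache$xhat * matrix(colMeans(dm * cache$xhat), n, p$cout, byrow = TRUE)
    dm <- sweep(dm, 2L, cache$sigma, "/")
    g <- list(dgamma = dgamma, dbeta = dbeta)
  }
  dW <- crossprod(cache$col, dm)
  dcol <- tcrossprod(dm, p$W)
  dx <- cpp_col2im(dcol, cache$din[1], cache$din[2], p$cin, p$k, p$stride, p$pad)
  c(list(dx = dx, dW = dW), g)
}

# assemble the gradient list of a conv layer from conv_bwd output
conv_grads <- function(r) {
  g <- list(W = r$dW)
  if (!is.null(r$db)) g$b <- r$db
  else { g$gamma <- r$dgamma; g$beta <- r$dbeta }
  g
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

# backward through relu given the *output* of the forward pass
relu_bwd <- function(dout, out) {
  dout[out <= 0] <- 0
  dout
}

# Bilinear interpolation matrix (n_out x n_in), half-pixel-center convention.
interp_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  i0 <- pmin(floor(src), n_in - 1)
  fr <- src - i0
  i1 <- pmin(i0 + 1, n_in - 1)
  idx <- seq_len(n_out)
  A[cbind(idx, i0 + 1)] <- A[cbind(idx, i0 + 1)] + (1 - fr)
  A[cbind(idx, i1 + 1)] <- A[cbind(idx, i1 + 1)] + fr
  A
}

# Area-average pooling matrix for adaptive pooling to n_out cells
# (PyTorch-style near-equal segments; exact block means when n_in %% n_out == 0).
avg_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- floor((i - 1) * n_in / n_out) + 1
    hi <- ceiling(i * n_in / n_out)
    A[i, lo:hi] <- 1 / (hi - lo + 1)
  }
  A
}

# y[,,c] = A %*% x[,,c] %*% t(B) for every channel
lin2d_fwd <- function(x, A, B) {
  d <- dim(x)
  out <- array(0, c(nrow(A), nrow(B), d[3]))
  for (c in seq_len(d[3])) out[, , c] <- A %*% x[, , c] %*% t(B)
  out
}

lin2d_bwd <- function(dy, A, B, din) {
  dx <- array(0, c(din[1], din[2], din[3]))
  for (c in seq_len(din[3])) dx[, , c] <- t(A) %*% dy[, , c] %*% B
  dx
}

resize_bilinear <- function(x, h_out, w_out = h_out) {
  lin2d_fwd(x, interp_matrix(h_out, dim(x)[1]), interp_matrix(w_out, dim(x)[2]))
}

# Integer-factor area-average downsampling (alias-free block means).
downsample_area <- function(x, factor) {
  d <- dim(x)
  stopifnot(d[1] %% factor == 0, d[2] %% factor == 0)
  lin2d_fwd(x, avg_matrix(d[1] %/% factor, d[1]),
            avg_matrix(d[2] %/% factor, d[2]))
}

global_avg_pool <- function(x) {
  apply(x, 3L, mean)
}

dense_params <- function(nin, nout, init = c("he", "zero")) {
  init <- match.arg(init)
  W <- if (init == "he")
    matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nout, nin)
  else matrix(0, nout, nin)
  list(W = W, b = numeric(nout))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Row-stable softmax over the third array dimension.
softmax3 <- function(x) {
  d <- dim(x)
  M <- matrix(x, d[1] * d[2], d[3])
  M <- M - M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  E <- exp(M)
  P <- E / rowSums(E)
  array(P, d)
}

# backward of row softmax: given P (post-softmax) and dP, return dZ
softmax_rows_bwd <- function(P, dP) {
  P * (dP - rowSums(dP * P))
}
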