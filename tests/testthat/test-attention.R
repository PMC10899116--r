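# First-/second-order attention and pyramid pooling against straight-line
# oracles.

test_that("first-order gate limits: saturated -> identity, zero -> half", {
  C <- 6L
  fine <- withr::with_seed(1, array(runif(5 * 5 * C), c(5, 5, C)))
  coarse <- withr::with_seed(2, array(runif(3 * 3 * C), c(3, 3, C)))
  sat <- list(fc1 = list(W = matrix(0, C, C), b = rep(0, C)),
              fc2 = list(W = matrix(0, C, C), b = rep(50, C)))
  expect_equal(first_order_attention(coarse, fine, sat), fine,
               tolerance = 1e-12)
  zero <- list(fc1 = list(W = matrix(0, C, C), b = rep(0, C)),
               fc2 = list(W = matrix(0, C, C), b = rep(0, C)))
  expect_equal(first_order_attention(coarse, fine, zero), 0.5 * fine)
  expect_error(first_order_attention(array(0, c(3, 3, 4)), fine), "mismatch")
})

test_that("first-order attention equals pool-dense-sigmoid-scale recompute", {
  C <- 8L
  fine <- withr::with_seed(3, array(rnorm(4 * 4 * C), c(4, 4, C)))
  coarse <- withr::with_seed(4, array(rnorm(4 * 4 * C), c(4, 4, C)))
  w <- withr::with_seed(5, list(
    fc1 = list(W = matrix(rnorm(2 * C), 2, C), b = rnorm(2)),
    fc2 = list(W = matrix(rnorm(C * 2), C, 2), b = rnorm(C))))
  got <- first_order_attention(coarse, fine, w)
  z <- vapply(seq_len(C), function(c) mean(coarse[, , c]), numeric(1))
  h <- pmax(as.vector(w$fc1$W %*% z + w$fc1$b), 0)
  g <- 1 / (1 + exp(-(as.vector(w$fc2$W %*% h + w$fc2$b))))
  expected <- fine
  for (c in seq_len(C)) expected[, , c] <- fine[, , c] * g[c]
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("second-order attention: constant-map closed form and bypass", {
  # two identical constant maps with equal channel values: Gram rows are
  # constant, softmax rows uniform, each remixed channel is the channel
  # mean; the two ordered pairs sum to twice that
  C <- 3L
  f <- array(3, c(4, 4, C))
  out <- second_order_attention(list(f, f))
  expect_equal(out, array(6, c(4, 4, C)), tolerance = 1e-10)
  # distinct channel values: rows are no longer uniform; closed form is
  # softmax over 4*v_i*v_j (HW = 16 so the Gram scale is sqrt(HW) = 4)
  v <- c(2, 5, 11)
  fv <- array(rep(v, each = 16), c(4, 4, C))
  W <- exp(4 * outer(v, v) - apply(4 * outer(v, v), 1, max))
  W <- W / rowSums(W)
  expect_equal(second_order_attention(list(fv, fv))[1, 1, ],
               2 * as.vector(W %*% v), tolerance = 1e-10)
  # single stream is bypassed untouched
  expect_identical(second_order_attention(list(f)), f)
  expect_error(second_order_attention(list(f, array(0, c(5, 5, C)))),
               "share grid")
})

test_that("second-order attention equals a brute-force Gram recomputation", {
  C <- 4L; H <- 8L
  f1 <- withr::with_seed(6, array(rnorm(H * H * C), c(H, H, C)))
  f2 <- withr::with_seed(7, array(rnorm(H * H * C), c(H, H, C)))
  got <- second_order_attention(list(f1, f2))
  X1 <- t(matrix(f1, H * H, C)); X2 <- t(matrix(f2, H * H, C))
  sm <- function(G) {
    E <- exp(G - apply(G, 1, max))
    E / rowSums(E)
  }
  sc <- 1 / sqrt(H * H)
  Y <- sm(X1 %*% t(X2) * sc) %*% X2 + sm(X2 %*% t(X1) * sc) %*% X1
  expect_equal(got, array(t(Y), c(H, H, C)), tolerance = 1e-10)
})

test_that("pyramid pooling with one bin broadcasts the global mean", {
  C <- 4L
  x <- withr::with_seed(8, array(abs(rnorm(6 * 6 * C)) + 0.5, c(6, 6, C)))
  w <- gpseg:::ppm_init(C, bins = 1L, init = "identity")
  # wire the fusion conv to pass the pooled branch straight through: center
  # tap of the 3x3 kernel on the branch channels
  w$fuse$W[] <- 0; w$fuse$b[] <- 0
  for (cc in seq_len(C)) {
    idx <- 1L + 1L * 3L + 9L * (C + cc - 1L) + 1L  # kh=1,kw=1 (0-based), cin=C+cc
    w$fuse$W[idx, cc] <- 1
  }
  out <- pyramid_pool(x, bins = 1L, weights = w)
  gm <- vapply(seq_len(C), function(c) mean(x[, , c]), numeric(1))
  for (cc in seq_len(C))
    expect_equal(out[, , cc], matrix(gm[cc], 6, 6), tolerance = 1e-10)
})

test_that("pyramid pooling keeps constant inputs constant", {
  C <- 8L
  x <- array(rep(seq_len(C), each = 144), c(12, 12, C))
  bins <- c(1L, 2L, 3L, 6L)
  w <- withr::with_seed(9, gpseg:::ppm_init(C, bins))
  # every pooled branch of a constant input is constant at the input value:
  # adaptive pooling and bilinear upsampling are both averaging operators
  for (bi in seq_along(bins)) {
    b <- bins[bi]
    P <- gpseg:::lin2d_fwd(x, gpseg:::avg_matrix(b, 12), gpseg:::avg_matrix(b, 12))
    for (cc in seq_len(C))
      expect_equal(as.vector(P[, , cc]), rep(cc, b * b))
    U <- gpseg:::lin2d_fwd(P, gpseg:::interp_matrix(12, b),
                           gpseg:::interp_matrix(12, b))
    for (cc in seq_len(C))
      expect_equal(as.vector(U[, , cc]), rep(cc, 144))
  }
  # the fused output is constant away from the zero-padded border
  out <- pyramid_pool(x, bins, weights = w)
  for (cc in seq_len(C))
    expect_lt(max(abs(out[2:11, 2:11, cc] - out[6, 6, cc])), 1e-9)
  expect_error(pyramid_pool(x, bins = 13L), "larger than the feature grid")
})

test_that("pyramid pooling equals a straight-line recomputation", {
  C <- 16L; H <- 12L; bins <- c(1L, 2L, 3L, 6L)
  x <- withr::with_seed(10, array(rnorm(H * H * C), c(H, H, C)))
  w <- withr::with_seed(11, gpseg:::ppm_init(C, bins))
  got <- pyramid_pool(x, bins, weights = w)
  # independent recomputation: block means (bins divide the grid), 1x1 conv,
  # bilinear upsampling with half-pixel centers, concat, 3x3 same conv, relu
  up1d <- function(n_out, n_in) {
    A <- matrix(0, n_out, n_in)
    for (i in seq_len(n_out)) {
      s <- min(max((i - 0.5) * n_in / n_out - 0.5, 0), n_in - 1)
      i0 <- min(floor(s), n_in - 1); fr <- s - i0
      A[i, i0 + 1] <- A[i, i0 + 1] + 1 - fr
      A[i, min(i0 + 2, n_in)] <- A[i, min(i0 + 2, n_in)] + fr
    }
    A
  }
  cr <- C %/% length(bins)
  cat <- array(0, c(H, H, C + length(bins) * cr))
  cat[, , 1:C] <- x
  for (bi in seq_along(bins)) {
    b <- bins[bi]
    P <- array(0, c(b, b, C))
    f <- H / b
    for (i in 1:b) for (j in 1:b) for (cc in 1:C)
      P[i, j, cc] <- mean(x[((i - 1) * f + 1):(i * f),
                            ((j - 1) * f + 1):(j * f), cc])
    R <- array(0, c(b, b, cr))
    Wm <- w$red[[bi]]$W
    for (i in 1:b) for (j in 1:b)
      R[i, j, ] <- pmax(as.vector(t(Wm) %*% P[i, j, ] + w$red[[bi]]$b), 0)
    A <- up1d(H, b)
    for (cc in 1:cr)
      cat[, , C + (bi - 1) * cr + cc] <- A %*% R[, , cc] %*% t(A)
  }
  Cin <- dim(cat)[3]
  fused <- array(0, c(H, H, C))
  padded <- array(0, c(H + 2, H + 2, Cin))
  padded[2:(H + 1), 2:(H + 1), ] <- cat
  for (i in 1:H) for (j in 1:H) {
    patch <- padded[i:(i + 2), j:(j + 2), ]
    fused[i, j, ] <- pmax(as.vector(t(w$fuse$W) %*% as.vector(patch)) +
                            w$fuse$b, 0)
  }
  expect_equal(got, fused, tolerance = 1e-9)
})
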