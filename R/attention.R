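# Cross-stream attention operators and the pyramid pooling module.
#
# First-order attention: the globally pooled coarse-stream features pass
# through a two-layer bottleneck with a sigmoid, producing a per-channel gate
# in (0,1)^C that rescales the finer stream's early features - global context
# steering low-level feature learning.
#
# Second-order attention: for each ordered pair of streams, the C x C Gram
# interaction of flattened features (scaled by 1/sqrt(HW)) is row-softmaxed
# and used to remix the target stream's channels; the fused map is the sum
# over pairs. It is parameter-free and captures stream relationships at the
# level of channel co-activation.

fo_init <- function(channels, reduction = 4L, init = "he") {
  hidden <- max(1L, channels %/% reduction)
  list(fc1 = dense_params(channels, hidden, init = if (init == "he") "he" else "zero"),
       fc2 = dense_params(hidden, channels, init = if (init == "he") "he" else "zero"))
}

fo_fwd <- function(coarse, fine, w, want_cache = TRUE) {
  z <- global_avg_pool(coarse)
  a1 <- drop(w$fc1$W %*% z) + w$fc1$b
  h <- pmax(a1, 0)
  a2 <- drop(w$fc2$W %*% h) + w$fc2$b
  g <- sigmoid(a2)
  out <- sweep(fine, 3L, g, "*")
  if (want_cache)
    list(out = out, z = z, h = h, g = g, fine = fine, dcoarse_dim = dim(coarse))
  else list(out = out)
}

fo_bwd <- function(dout, w, cache) {
  C <- length(cache$g)
  dg <- vapply(seq_len(C), function(c) sum(dout[, , c] * cache$fine[, , c]),
               numeric(1))
  dfine <- sweep(dout, 3L, cache$g, "*")
  da2 <- dg * cache$g * (1 - cache$g)
  dW2 <- tcrossprod(da2, cache$h)
  db2 <- da2
  dh <- drop(crossprod(w$fc2$W, da2))
  dh[cache$h <= 0] <- 0
  dW1 <- tcrossprod(dh, cache$z)
  db1 <- dh
  dz <- drop(crossprod(w$fc1$W, dh))
  npx <- prod(cache$dcoarse_dim[1:2])
  dcoarse <- array(rep(dz / npx, each = npx), cache$dcoarse_dim)
  list(dfine = dfine, dcoarse = dcoarse,
       grads = list(fc1 = list(W = dW1, b = db1), fc2 = list(W = dW2, b = db2)))
}

#' First-order cross-stream channel attention
#'
#' Rescales the channels of a finer stream's feature map by a gate in
#' `(0,1)^C` computed from the globally pooled coarse-stream features through
#' a two-layer bottleneck with sigmoid output. Spatial size is unchanged.
#'
#' @param coarse_feats,fine_feats numeric arrays `H x W x C` (grids may
#'   differ; channel counts must agree with the gate weights).
#' @param weights gate weights as produced by the network builder; if `NULL`,
#'   freshly He-initialized weights for `C` channels are drawn from the
#'   current RNG.
#' @param reduction bottleneck reduction ratio for default weights.
#' @return The gated `fine_feats`, same dimensions as the input.
#' @export
first_order_attention <- function(coarse_feats, fine_feats, weights = NULL,
                                  reduction = 4L) {
  C <- dim(fine_feats)[3]
  if (dim(coarse_feats)[3] != C)
    stop("channel mismatch between coarse and fine feature maps")
  if (is.null(weights)) weights <- fo_init(C, reduction)
  if (ncol(weights$fc1$W) != C)
    stop("gate weights do not match the feature channel count")
  fo_fwd(coarse_feats, fine_feats, weights, want_cache = FALSE)$out
}

so_fwd <- function(flist, want_cache = TRUE) {
  S <- length(flist)
  d <- dim(flist[[1]])
  HW <- d[1] * d[2]
  sc <- 1 / sqrt(HW)
  X <- lapply(flist, function(f) t(matrix(f, HW, d[3])))  # C x HW
  Y <- matrix(0, d[3], HW)
  Ps <- list()
  for (a in seq_len(S)) for (b in seq_len(S)) {
    if (a == b) next
    G <- (X[[a]] %*% t(X[[b]])) * sc
    G <- G - apply(G, 1L, max)
    E <- exp(G)
    P <- E / rowSums(E)
    Y <- Y + P %*% X[[b]]
    if (want_cache) Ps[[paste(a, b)]] <- P
  }
  out <- array(t(Y), d)
  if (want_cache) list(out = out, X = X, P = Ps, d = d, sc = sc)
  else list(out = out)
}

so_bwd <- function(dout, cache) {
  d <- cache$d
  HW <- d[1] * d[2]
  dY <- t(matrix(dout, HW, d[3]))
  S <- length(cache$X)
  dX <- lapply(cache$X, function(x) matrix(0, nrow(x), ncol(x)))
  for (a in seq_len(S)) for (b in seq_len(S)) {
    if (a == b) next
    P <- cache$P[[paste(a, b)]]
    Xb <- cache$X[[b]]
    dP <- dY %*% t(Xb)
    dX[[b]] <- dX[[b]] + crossprod(P, dY)
    dG <- softmax_rows_bwd(P, dP)
    dX[[a]] <- dX[[a]] + (dG %*% Xb) * cache$sc
    dX[[b]] <- dX[[b]] + (crossprod(dG, cache$X[[a]])) * cache$sc
  }
  lapply(dX, function(m) array(t(m), d))
}

#' Second-order (Gram) cross-stream attention
#'
#' For every ordered pair of stream feature maps (all resampled to a common
#' grid with equal channel count), computes the `C x C` Gram interaction of
#' flattened features scaled by `1/sqrt(HW)`, row-softmaxes it, and uses it to
#' remix the target stream's channels. The fused output is the sum over
#' pairs. With a single stream the operation is bypassed (ablation contract).
#'
#' @param stream_feats list of numeric arrays `H x W x C` on the same grid.
#' @return Fused feature map, same dimensions as each input.
#' @export
second_order_attention <- function(stream_feats) {
  stopifnot(is.list(stream_feats), length(stream_feats) >= 1L)
  if (length(stream_feats) == 1L) return(stream_feats[[1]])
  d <- dim(stream_feats[[1]])
  for (f in stream_feats[-1])
    if (!identical(dim(f), d))
      stop("stream feature maps must share grid and channel count")
  so_fwd(stream_feats, want_cache = FALSE)$out
}

ppm_init <- function(channels, bins, init = "he", norm = FALSE) {
  nb <- length(bins)
  cr <- channels %/% nb
  stopifnot(cr >= 1L)
  list(red = lapply(seq_len(nb), function(i)
         conv_params(1L, channels, cr,
                     init = if (init == "identity") "identity" else init,
                     norm = norm)),
       fuse = conv_params(3L, channels + nb * cr, channels,
                          init = if (init == "identity") "he" else init,
                          norm = norm),
       cr = cr)
}

ppm_fwd <- function(x, bins, w, want_cache = TRUE, stats = NULL) {
  d <- dim(x)
  if (any(bins > min(d[1], d[2])))
    stop("pyramid bin larger than the feature grid")
  nb <- length(bins)
  cr <- w$cr
  cat <- array(0, c(d[1], d[2], d[3] + nb * cr))
  cat[, , seq_len(d[3])] <- x
  br <- vector("list", nb)
  for (i in seq_len(nb)) {
    b <- bins[i]
    Ab <- avg_matrix(b, d[1]); Bb <- avg_matrix(b, d[2])
    P <- lin2d_fwd(x, Ab, Bb)
    cv <- conv_fwd(P, w$red[[i]], want_cache, stats)
    r <- relu_fwd(cv$out)
    Au <- interp_matrix(d[1], b); Bu <- interp_matrix(d[2], b)
    U <- lin2d_fwd(r, Au, Bu)
    cat[, , d[3] + (i - 1L) * cr + seq_len(cr)] <- U
    if (want_cache) br[[i]] <- list(Ab = Ab, Bb = Bb, Au = Au, Bu = Bu,
                                    cv = cv, r = r)
  }
  fz <- conv_fwd(cat, w$fuse, want_cache, stats)
  out <- relu_fwd(fz$out)
  if (want_cache) list(out = out, fz = fz, br = br, d = d, nb = nb, cr = cr)
  else list(out = out)
}

ppm_bwd <- function(dout, bins, w, cache) {
  d <- cache$d
  dfz <- relu_bwd(dout, cache$out)
  cb <- conv_bwd(dfz, w$fuse, cache$fz)
  dcat <- cb$dx
  dx <- dcat[, , seq_len(d[3]), drop = FALSE]
  gred <- vector("list", cache$nb)
  for (i in seq_len(cache$nb)) {
    bc <- cache$br[[i]]
    cr <- cache$cr
    dU <- dcat[, , d[3] + (i - 1L) * cr + seq_len(cr), drop = FALSE]
    dr <- lin2d_bwd(dU, bc$Au, bc$Bu, dim(bc$r))
    dr <- relu_bwd(dr, bc$r)
    rb <- conv_bwd(dr, w$red[[i]], bc$cv)
    gred[[i]] <- conv_grads(rb)
    dx <- dx + lin2d_bwd(rb$dx, bc$Ab, bc$Bb, d)
  }
  list(dx = dx, grads = list(red = gred, fuse = conv_grads(cb)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pyramid pooling over a feature map
#'
#' For each bin size `b`, adaptively average-pools the input to `b x b`,
#' reduces channels to `C/length(bins)` with a 1x1 convolution, bilinearly
#' upsamples back to the input grid, concatenates all pooled branches with
#' the input, and fuses with a 3x3 convolution back to `C` channels. This
#' distributes global pattern context into the high-level features; spatial
#' size is unchanged.
#'
#' @param feats numeric array `H x W x C`.
#' @param bins integer vector of bin sizes (default `c(1, 2, 3, 6)`), each
#'   at most the spatial grid size.
#' @param weights module weights from the network builder; if `NULL`, freshly
#'   initialized weights are drawn from the current RNG.
#' @return Feature map `H x W x C`.
#' @export
pyramid_pool <- function(feats, bins = c(1L, 2L, 3L, 6L), weights = NULL) {
  if (length(bins) == 0L) stop("ppm_bins must be non-empty")
  if (is.null(weights)) weights <- ppm_init(dim(feats)[3], bins)
  ppm_fwd(feats, bins, weights, want_cache = FALSE)$out
}
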