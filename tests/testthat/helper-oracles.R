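# Independent straight-line oracles used across the suite. These deliberately
# re-derive results with plain-R brute force (flood fill, per-block modes,
# direct formula evaluation) so they share no code path with the package
# internals they check.

# flood-fill connected components (queue-based, plain R)
flood_components <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nxt <- 0L
  for (w in seq_len(W)) for (h in seq_len(H)) {
    if (mask[h, w] == 0 || lab[h, w] != 0) next
    nxt <- nxt + 1L
    queue <- matrix(c(h, w), 1)
    lab[h, w] <- nxt
    while (nrow(queue) > 0) {
      cur <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        nh <- cur[1] + nb[k, 1]; nw <- cur[2] + nb[k, 2]
        if (nh < 1 || nh > H || nw < 1 || nw > W) next
        if (mask[nh, nw] == 0 || lab[nh, nw] != 0) next
        lab[nh, nw] <- nxt
        queue <- rbind(queue, c(nh, nw))
      }
    }
  }
  lab
}

# per-block majority with lowest-class tie-break
block_mode_oracle <- function(m, f) {
  Ho <- ceiling(nrow(m) / f); Wo <- ceiling(ncol(m) / f)
  out <- matrix(0L, Ho, Wo)
  for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    rows <- ((i - 1) * f + 1):min(i * f, nrow(m))
    cols <- ((j - 1) * f + 1):min(j * f, ncol(m))
    tab <- table(m[rows, cols])
    best <- as.integer(names(tab))[tab == max(tab)]
    out[i, j] <- min(best)
  }
  out
}

# standard distance straight from the formula
standard_distance_oracle <- function(x, y, N) {
  n <- length(x)
  sqrt((sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n * N))
}

# assemble an island_set by hand from centroids (for formula-level tests)
make_island_set <- function(x, y, N, mpp = 7.2, class_id = 3L) {
  structure(list(
    islands = tibble::tibble(id = seq_along(x),
                             pixel_count = rep(1L, length(x)),
                             area_mm2 = rep((mpp / 1000)^2, length(x)),
                             x = x, y = y, hull_px = rep(1, length(x)),
                             solidity = rep(1, length(x))),
    n = length(x), N = N, mpp = mpp, class_id = class_id),
    class = "island_set")
}

# a small random label mask over the full codebook
random_mask <- function(H, W, mpp = 7.2, p0 = 0.5, seed = NULL) {
  draw <- function() {
    m <- matrix(sample(0:6, H * W, replace = TRUE,
                       prob = c(p0, rep((1 - p0) / 6, 6))), H, W)
    label_mask(m, mpp = mpp)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
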