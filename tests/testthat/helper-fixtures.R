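# Trained-network fixtures shared across tests. Training is expensive, so
# each fixture is built lazily once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# The scaled overfit configuration: the full three-stream fo+so network with
# pyramid pooling at reduced width, on 96 px tiles.
scaled_config <- function(patch_size = 96L) {
  network_config(fusion = "fo+so", width_multiplier = 0.5,
                 patch_size = patch_size)
}

# 20 single-pattern tiles used by the overfit learning check
overfit_tiles <- function(n = 20L, size = 96L) {
  pats <- rep(pattern_names(), length.out = n)
  lapply(seq_along(pats), function(i) {
    tl <- generate_pattern_tile(pats[i], size = size, seed = 100L + i)
    list(patch = tl$patch, mask = tl$mask)
  })
}

# Overfit learning check: 20 synthetic tiles, 30 epochs, fixed seed.
overfit_fixture <- function() {
  if (!is.null(.fixture_cache$overfit)) return(.fixture_cache$overfit)
  pairs <- overfit_tiles()
  net <- build_network(scaled_config(), seed = 1L)
  res <- train_network(net, pairs,
                       train_schedule(epochs = 30L, batch_size = 2L,
                                      lr = c(1e-3, 1e-3, 1e-4), seed = 1L))
  .fixture_cache$overfit <- list(network = res$network, pairs = pairs,
                                 history = res$history)
  .fixture_cache$overfit
}

# The end-to-end evaluation scene: a solid-predominant tumor with a
# papillary block and five dispersed acinar islands at analysis resolution
# (250 x 250 @ 7.2 um/px; rendered at 4000 x 4000 @ 0.45 um/px).
e2e_layout <- function() {
  generate_island_layout(list(
    island_spec("solid", 10000, "square", centroid = c(65, 65)),
    island_spec("papillary", 2500, "square", centroid = c(190, 60)),
    island_spec("acinar", 300, "disc", centroid = c(40, 170)),
    island_spec("acinar", 300, "disc", centroid = c(120, 160)),
    island_spec("acinar", 300, "disc", centroid = c(210, 170)),
    island_spec("acinar", 300, "disc", centroid = c(60, 230)),
    island_spec("acinar", 300, "disc", centroid = c(200, 230))),
    canvas = c(250L, 250L), mpp = 7.2)
}

# Slide-inference fixture: network overfit on crops of the evaluation slide
# itself (island-core, island-rim and random crops with per-class budgets;
# class-weighted loss at batch size 1). This is an overfit check of the
# whole-slide plumbing, not a generalization claim.
slide_net_fixture <- function() {
  if (!is.null(.fixture_cache$slide)) return(.fixture_cache$slide)
  lay <- e2e_layout()
  sl <- generate_slide(lay$mask, factor = 16L, seed = 9L)
  img <- unclass(sl$slide)
  m20 <- unclass(sl$mask20)
  side <- nrow(m20)
  ps <- 96L
  crop_at <- function(cy, cx) {
    oy <- min(max(round(cy - ps / 2), 0), side - ps)
    ox <- min(max(round(cx - ps / 2), 0), side - ps)
    list(patch = image_patch(img[oy + 1:ps, ox + 1:ps, , drop = FALSE]),
         mask = label_mask(m20[oy + 1:ps, ox + 1:ps], 0.45))
  }
  pairs <- list()
  set.seed(21)
  budget <- c("3" = 14L, "2" = 14L, "6" = 16L)
  for (k in names(budget)) {
    rows <- which(lay$truth$class_id == as.integer(k))
    n_each <- ceiling(budget[[k]] / length(rows))
    got <- 0L
    for (r in rows) {
      half <- sqrt(lay$truth$pixel_count[r]) * 16 / 2
      rad <- sqrt(lay$truth$pixel_count[r] / pi) * 16
      for (j in seq_len(n_each)) {
        if (got >= budget[[k]]) break
        pairs[[length(pairs) + 1L]] <- if (j %% 3 == 0) {
          th <- stats::runif(1, 0, 2 * pi)      # island-rim crop
          crop_at(16 * lay$truth$y[r] + rad * sin(th),
                  16 * lay$truth$x[r] + rad * cos(th))
        } else {                                 # island-core crop
          crop_at(16 * lay$truth$y[r] + stats::runif(1, -half, half),
                  16 * lay$truth$x[r] + stats::runif(1, -half, half))
        }
        got <- got + 1L
      }
    }
  }
  for (j in 1:20)
    pairs[[length(pairs) + 1L]] <-
      crop_at(stats::runif(1, ps / 2, side - ps / 2),
              stats::runif(1, ps / 2, side - ps / 2))
  cw <- gpseg:::class_weights_for(pairs)
  net <- build_network(scaled_config(), seed = 1L)
  res <- train_network(net, pairs,
                       train_schedule(epochs = 34L, batch_size = 1L,
                                      lr = c(1e-3, 1e-3, 1e-4), seed = 1L),
                       class_weights = cw)
  .fixture_cache$slide <- list(network = res$network, layout = lay,
                               slide = sl)
  .fixture_cache$slide
}
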