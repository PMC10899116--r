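# Deterministic generators: tiles, layouts, tumors.

test_that("pattern tiles are pure functions of (pattern, size, seed)", {
  a <- generate_pattern_tile("cribriform", 96, seed = 3)
  b <- generate_pattern_tile("cribriform", 96, seed = 3)
  expect_identical(a$patch, b$patch)
  expect_identical(a$mask, b$mask)
  c <- generate_pattern_tile("cribriform", 96, seed = 4)
  expect_false(identical(unclass(a$patch), unclass(c$patch)))
  expect_error(generate_pattern_tile("oncocytic", 96), "unknown pattern")
})

test_that("tile masks contain exactly background and the requested pattern", {
  for (p in pattern_names()) {
    tl <- generate_pattern_tile(p, 96, seed = 11)
    classes <- sort(unique(as.vector(unclass(tl$mask))))
    expect_equal(classes, c(0L, pattern_classes()[[p]]))
    expect_equal(dim(unclass(tl$patch))[1:2], dim(unclass(tl$mask)))
  }
})

test_that("the six textures are separable by their white-space fraction", {
  wf <- vapply(pattern_names(), function(p) {
    tl <- generate_pattern_tile(p, 160, seed = 21)
    white_fraction(tl$patch, unclass(tl$mask) > 0)
  }, numeric(1))
  # every pair differs by a visible margin
  gaps <- abs(outer(wf, wf, "-"))
  expect_gt(min(gaps[upper.tri(gaps)]), 0.02)
})

test_that("island layouts emit ground truth the analysis modules recover", {
  lay <- generate_island_layout(list(
    island_spec("acinar", 25, "square", c(10, 10)),
    island_spec("acinar", 25, "square", c(30, 28))), canvas = c(48, 48))
  isl <- extract_islands(lay$mask, "acinar")
  expect_equal(isl$n, 2L)
  expect_equal(isl$islands$pixel_count, c(25L, 25L))
  # engineered two-island geometry reproduces the analytic d: centroids at
  # (10,10) and (30,28), N = realized tumor pixel count
  N <- sum(unclass(lay$mask) != 0L)
  d_expected <- sqrt((2 * 10^2 + 2 * 9^2) / (2 * N))
  expect_equal(acinar_scattering(isl),
               standard_distance_oracle(lay$truth$x, lay$truth$y, N))
  expect_equal(acinar_scattering(isl), d_expected)

  # many random specs: exact round-trip of counts and centroids
  set.seed(5)
  specs <- list()
  for (i in 1:12) {
    cx <- 20 + 42 * ((i - 1) %% 4); cy <- 20 + 42 * ((i - 1) %/% 4)
    shape <- sample(c("square", "L"), 1)
    target <- if (shape == "square") sample(c(25, 49, 100), 1)
              else sample(c(27, 48, 75, 147), 1)   # 3 a^2
    specs[[i]] <- island_spec(sample(1:6, 1), target, shape, c(cx, cy))
  }
  lay2 <- generate_island_layout(specs, canvas = c(160, 180))
  for (k in sort(unique(lay2$truth$class_id))) {
    isl <- extract_islands(lay2$mask, k)
    tr <- lay2$truth[lay2$truth$class_id == k, ]
    expect_equal(isl$n, nrow(tr))
    expect_setequal(isl$islands$pixel_count, tr$pixel_count)
    expect_equal(sort(round(isl$islands$x, 6)), sort(round(tr$x, 6)))
    expect_equal(sort(round(isl$islands$y, 6)), sort(round(tr$y, 6)))
  }
  # realized counts are exact for square/L (side^2 and 3 a^2 construction)
  expect_identical(lay2$truth$pixel_count, lay2$truth$target_px)

  # curved shapes meet the 2% contract once targets exceed the
  # rasterization granularity
  curved <- generate_island_layout(list(
    island_spec("acinar", 300, "disc", c(30, 30)),
    island_spec("solid", 400, "ellipse", c(90, 32)),
    island_spec("papillary", 500, "disc", c(35, 90))),
    canvas = c(128, 128))
  expect_true(all(abs(curved$truth$pixel_count - curved$truth$target_px) /
                    curved$truth$target_px <= 0.02))
})

test_that("infeasible placements error out", {
  expect_error(generate_island_layout(list(
    island_spec("solid", 400, "square", c(5, 5))), canvas = c(32, 32)),
    "does not fit")
  expect_error(generate_island_layout(list(
    island_spec("solid", 100, "square", c(16, 16)),
    island_spec("acinar", 100, "square", c(18, 18))), canvas = c(32, 32)),
    "overlaps")
})

test_that("tumor masks hit the pooled target while slides differ", {
  spec <- tumor_spec(c(lepidic = .55, acinar = .30, papillary = .05,
                       solid = .10), n_slides = 3, seed = 7)
  masks <- generate_tumor_masks(spec)
  expect_length(masks, 3L)
  comp <- compute_proportions(masks)
  expect_true(all(abs(comp$g - spec$proportions) <= 0.01))
  # per-slide compositions deliberately differ from the pooled mix
  per_slide <- comp$S / rowSums(comp$S)
  expect_gt(max(abs(sweep(per_slide, 2, comp$g))), 0.01)
  # pooling vs averaging: the mean of per-slide proportions is NOT g
  expect_false(isTRUE(all.equal(colMeans(per_slide), comp$g,
                                tolerance = 1e-3)))
  # determinism
  expect_identical(generate_tumor_masks(spec), masks)
})

test_that("uniform tumors reach maximal Shannon diversity", {
  spec <- tumor_spec(setNames(rep(1 / 6, 6), pattern_names()),
                     n_slides = 2, seed = 3)
  comp <- compute_proportions(generate_tumor_masks(spec))
  expect_equal(shannon_diversity(comp), log(6), tolerance = 0.01)
})

test_that("rendered slides carry consistent masks and resolution metadata", {
  lay <- generate_island_layout(list(
    island_spec("solid", 100, "square", c(12, 12))), canvas = c(24, 24))
  out <- generate_slide(lay$mask, factor = 8, seed = 2)
  expect_equal(dim(unclass(out$slide))[1:2], c(192, 192))
  expect_equal(mpp(out$slide), 7.2 / 8)
  expect_equal(unclass(out$mask20),
               unclass(lay$mask)[rep(1:24, each = 8), rep(1:24, each = 8)],
               ignore_attr = TRUE)
  expect_identical(unclass(generate_slide(lay$mask, 8, seed = 2)$slide),
                   unclass(out$slide))
})
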