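# Island morphometry and the acinar scattering statistic.

test_that("islands of separated squares are found with exact counts", {
  m <- matrix(0L, 40, 40)
  m[5:9, 5:9] <- 3L
  m[25:29, 30:34] <- 3L
  isl <- extract_islands(label_mask(m, 7.2), "acinar")
  expect_equal(isl$n, 2L)
  expect_equal(isl$islands$pixel_count, c(25L, 25L))
  expect_equal(isl$N, 50L)
  expect_setequal(round(isl$islands$y, 6), c(7, 27))
})

test_that("diagonal pixels merge under 8-connectivity and split under 4", {
  m <- matrix(0L, 6, 6)
  m[2, 2] <- 3L; m[3, 3] <- 3L
  expect_equal(extract_islands(label_mask(m, 7.2), 3L, connectivity = 8)$n, 1L)
  expect_equal(extract_islands(label_mask(m, 7.2), 3L, connectivity = 4)$n, 2L)
})

test_that("component pixel counts equal a brute-force flood fill", {
  for (seed in 1:4) {
    m <- withr::with_seed(seed, {
      b <- matrix(0L, 30, 30)
      b[stats::runif(900) < 0.35] <- 3L
      b
    })
    isl <- extract_islands(label_mask(m, 7.2), 3L)
    ref <- flood_components(m == 3L, connectivity = 8)
    expect_equal(isl$n, max(ref))
    expect_equal(sort(isl$islands$pixel_count),
                 sort(as.integer(table(ref[ref > 0]))))
  }
})

test_that("island morphology: exact area conversion and hull solidity", {
  m <- matrix(0L, 20, 20)
  m[6:15, 6:15] <- 3L
  isl <- extract_islands(label_mask(m, 7.2), 3L)
  expect_equal(isl$islands$area_mm2, 100 * (7.2 / 1000)^2)  # 0.005184 mm^2
  expect_equal(isl$islands$solidity, 1)

  # L-shape: 10x5 and 5x10 arms sharing a 5x5 corner
  L <- matrix(0L, 20, 20)
  L[3:12, 3:7] <- 3L
  L[8:12, 3:12] <- 3L
  li <- extract_islands(label_mask(L, 7.2), 3L)
  expect_lt(li$islands$solidity, 1)
  # oracle: lattice points in the hull polygon via Pick's theorem
  # (interior = area - boundary/2 + 1; total = area + boundary/2 + 1)
  pts <- which(L == 3L, arr.ind = TRUE)
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  hx <- pts[hull, 2]; hy <- pts[hull, 1]
  j <- c(length(hx), seq_len(length(hx) - 1))
  area <- abs(sum(hx[j] * hy - hx * hy[j]) / 2)
  gcd <- function(a, b) ifelse(b == 0, a, Recall(b, a %% b))
  boundary <- sum(gcd(abs(hx - hx[j]), abs(hy - hy[j])))
  hull_px_oracle <- area + boundary / 2 + 1
  expect_equal(li$islands$hull_px, hull_px_oracle)
  expect_equal(li$islands$solidity,
               li$islands$pixel_count / li$islands$hull_px)
})

test_that("scattering score matches the formula, with invariances", {
  expect_equal(acinar_scattering(make_island_set(5, 9, N = 100)), 0)
  two <- make_island_set(c(0, 2), c(0, 0), N = 4)
  expect_equal(acinar_scattering(two), 0.5)  # sqrt(2 / (2*4))
  set.seed(9)
  for (i in 1:5) {
    x <- stats::runif(50, 0, 200); y <- stats::runif(50, 0, 150)
    N <- sample(1000:50000, 1)
    s <- make_island_set(x, y, N)
    d <- acinar_scattering(s)
    expect_equal(d, standard_distance_oracle(x, y, N))
    # permutation invariance
    p <- sample(50)
    expect_equal(acinar_scattering(make_island_set(x[p], y[p], N)), d)
    # translation invariance
    expect_equal(acinar_scattering(make_island_set(x + 37, y - 11, N)), d)
    # scale coordinates by s, N by s^2 -> unchanged
    expect_equal(acinar_scattering(make_island_set(3 * x, 3 * y, 9 * N)), d)
  }
  # contracting centroids toward the mean center never increases d
  x <- c(10, 40, 90, 120); y <- c(5, 60, 15, 80); N <- 5000
  d_prev <- acinar_scattering(make_island_set(x, y, N))
  for (a in seq(0.9, 0.1, by = -0.2)) {
    xs <- mean(x) + a * (x - mean(x)); ys <- mean(y) + a * (y - mean(y))
    d_now <- acinar_scattering(make_island_set(xs, ys, N))
    expect_lte(d_now, d_prev + 1e-12)
    d_prev <- d_now
  }
  # no islands: undefined and flagged, distinct from zero
  none <- make_island_set(numeric(0), numeric(0), N = 100)
  none$n <- 0L; none$islands <- none$islands[0, ]
  expect_true(is.na(acinar_scattering(none)))
  expect_equal(attr(acinar_scattering(none), "reason"), "no islands")
})

test_that("tumor summary aggregates slides by median and dichotomizes at 0.36", {
  s1 <- make_island_set(c(0, 10), c(0, 0), N = 500)   # some d1
  s2 <- make_island_set(c(0, 40), c(0, 0), N = 500)   # larger d2
  d1 <- acinar_scattering(s1); d2 <- acinar_scattering(s2)
  summ <- tumor_spatial_summary(list(s1, s2))
  expect_equal(summ$scattering_d, median(c(d1, d2)))
  # engineered medians around the cutoff
  hi <- tumor_spatial_summary(list(make_island_set(c(0, 40), c(0, 0), N = 100),
                                   make_island_set(c(0, 60), c(0, 0), N = 100)))
  expect_gt(hi$scattering_d, 0.36)
  expect_equal(hi$scattering_class, "high")
  lo <- tumor_spatial_summary(list(make_island_set(5, 5, N = 100)))
  expect_equal(lo$scattering_d, 0)
  expect_equal(lo$scattering_class, "low")
  # slides with no islands are excluded from the median, not imputed as 0
  empty <- make_island_set(numeric(0), numeric(0), N = 100)
  empty$n <- 0L; empty$islands <- empty$islands[0, ]
  mix <- tumor_spatial_summary(list(s2, empty))
  expect_equal(mix$scattering_d, d2)
})

test_that("summary morphology honours the 5% acinar eligibility gate", {
  lay <- generate_island_layout(list(
    island_spec("acinar", 100, "square", c(20, 20)),
    island_spec("acinar", 200, "square", c(60, 20)),
    island_spec("acinar", 289, "square", c(40, 60))), canvas = c(80, 80))
  isl <- extract_islands(lay$mask, "acinar")
  summ <- tumor_spatial_summary(list(isl),
                                composition = compute_proportions(lay$mask))
  expect_equal(summ$n_islands, 3L)
  expect_equal(summ$mean_acinar_area_mm2,
               mean(lay$truth$pixel_count) * (7.2 / 1000)^2)
  ineligible <- tumor_spatial_summary(list(isl),
    composition = pattern_composition(c(acinar = 0.04, solid = 0.96)))
  expect_false(ineligible$eligible)
  expect_true(is.na(ineligible$mean_acinar_area_mm2))
  expect_false(is.na(ineligible$scattering_d))  # scattering still computed
})
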