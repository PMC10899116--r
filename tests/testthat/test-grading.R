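# Pattern quantification, IASLC grading and agreement statistics.

mask_from_counts <- function(counts, mpp = 7.2) {
  # row-major fill of exact per-class pixel counts onto a square canvas
  n <- sum(counts)
  side <- ceiling(sqrt(n / 0.8))
  m <- matrix(0L, side, side)
  lab <- rep.int(as.integer(names(counts)), counts)
  m[seq_along(lab)] <- lab
  label_mask(m, mpp = mpp)
}

test_that("pooled proportions follow the count formula, not per-slide averages", {
  s1 <- mask_from_counts(c(`1` = 100L, `3` = 50L))
  s2 <- mask_from_counts(c(`3` = 50L))
  comp <- compute_proportions(list(s1, s2))
  expect_equal(unname(comp$g[c("lepidic", "acinar")]), c(0.5, 0.5))
  expect_equal(sum(comp$g), 1)

  # deliberately unequal per-slide mixes with a known pooled mix: averaging
  # per-slide proportions would give a different answer
  a <- mask_from_counts(c(`1` = 900L, `6` = 100L))   # slide A: 90/10
  b <- mask_from_counts(c(`1` = 100L, `6` = 900L))   # slide B: 10/90 but equal size
  pooled <- compute_proportions(list(a, b))
  expect_equal(unname(pooled$g[["lepidic"]]), 0.5)
  c2 <- mask_from_counts(c(`1` = 80L, `6` = 20L))    # small slide, 80/20
  pooled2 <- compute_proportions(list(a, c2))
  mean_of_props <- mean(c(0.9, 0.8))
  expect_equal(unname(pooled2$g[["lepidic"]]), 980 / 1100)
  expect_false(isTRUE(all.equal(unname(pooled2$g[["lepidic"]]), mean_of_props)))

  # single slide, only solid
  solo <- compute_proportions(mask_from_counts(c(`6` = 37L)))
  expect_equal(unname(solo$g[["solid"]]), 1)
})

test_that("proportions match a brute-force pixel tally on random masks", {
  for (seed in 1:3) {
    masks <- lapply(1:3, function(i) random_mask(24, 30, seed = seed * 10 + i))
    comp <- compute_proportions(masks)
    tally <- numeric(6)
    for (m in masks) for (k in 1:6) tally[k] <- tally[k] + sum(unclass(m) == k)
    expect_equal(unname(comp$g), tally / sum(tally))
    expect_equal(sum(comp$g), 1, tolerance = 1e-12)
  }
})

test_that("composition is invariant to slide order and flags empty tumors", {
  masks <- lapply(1:3, function(i) random_mask(20, 20, seed = i))
  g1 <- compute_proportions(masks)$g
  g2 <- compute_proportions(rev(masks))$g
  expect_equal(g1, g2)
  empty <- label_mask(matrix(0L, 10, 10), mpp = 7.2)
  comp <- compute_proportions(empty)
  expect_false(comp$defined)
  expect_error(predominant_pattern(comp), "undefined")
  expect_error(shannon_diversity(comp), "undefined")
})

test_that("predominant pattern is the argmax with the higher-grade tie rule", {
  expect_equal(predominant_pattern(
    pattern_composition(c(acinar = 0.6, solid = 0.4))), "acinar")
  expect_equal(predominant_pattern(
    pattern_composition(c(lepidic = 0.5, acinar = 0.5))), "acinar")
  priority <- pattern_names()  # codes 1..6, higher = higher grade
  set.seed(42)
  for (i in 1:30) {
    g <- stats::runif(6)
    g <- round(g / sum(g), 3)
    g[1] <- 1 - sum(g[-1])
    names(g) <- priority
    comp <- pattern_composition(g)
    winners <- which(g == max(g))
    expect_equal(predominant_pattern(comp), priority[max(winners)])
  }
})

test_that("IASLC grading truth table, including the exact 20% boundary", {
  g1 <- compute_proportions(generate_tumor_masks(tumor_spec(
    c(lepidic = .55, acinar = .30, papillary = .05, solid = .10), seed = 1)))
  expect_equal(iaslc_grade(g1)$grade, 1L)
  g2 <- compute_proportions(generate_tumor_masks(tumor_spec(
    c(acinar = .60, papillary = .25, lepidic = .05, micropapillary = .10),
    seed = 2)))
  expect_equal(iaslc_grade(g2)$grade, 2L)
  # boundary: high-grade fraction exactly 20% -> grade 3
  g3 <- compute_proportions(generate_tumor_masks(tumor_spec(
    c(acinar = .50, lepidic = .30, solid = .15, cribriform = .05), seed = 3)))
  expect_equal(iaslc_grade(g3)$high_grade_fraction, 0.2)
  expect_equal(iaslc_grade(g3)$grade, 3L)
})

test_that("grade never drops when the high-grade fraction rises across 20%", {
  # sweep: lepidic- and acinar-predominant compositions with increasing
  # high-grade share; exact counts so the boundary is hit exactly
  for (pred in c("lepidic", "acinar")) {
    last <- 0L
    for (hg in seq(0L, 60L, by = 5L)) {
      counts <- setNames(c(100L - hg, hg), c(pred, "solid"))
      comp <- compute_proportions(mask_from_counts(
        setNames(counts, c(pattern_classes()[[pred]], 6L))))
      gr <- iaslc_grade(comp)$grade
      expect_gte(gr, last)
      if (hg >= 20L && hg < 50L) expect_equal(gr, 3L)
      last <- gr
    }
  }
})

test_that("Shannon diversity matches analytic values and bounds", {
  expect_equal(shannon_diversity(pattern_composition(c(solid = 1))), 0)
  expect_equal(shannon_diversity(
    pattern_composition(setNames(rep(1 / 6, 6), pattern_names()))), log(6))
  expect_equal(shannon_diversity(
    pattern_composition(c(lepidic = 0.5, acinar = 0.5))), log(2))
  set.seed(7)
  for (i in 1:20) {
    g <- stats::runif(6); g <- g / sum(g)
    H <- shannon_diversity(pattern_composition(setNames(g, pattern_names())))
    expect_gte(H, 0)
    expect_lte(H, log(6) + 1e-12)
  }
})

test_that("Dice coefficient matches brute-force set arithmetic", {
  m <- random_mask(16, 16, seed = 1)
  expect_equal(dice_coefficient(m, m, 3L), 1)
  a <- label_mask(matrix(c(rep(3L, 50), rep(0L, 50)), 10, 10), mpp = 7.2)
  b <- label_mask(matrix(c(rep(0L, 50), rep(3L, 50)), 10, 10), mpp = 7.2)
  expect_equal(dice_coefficient(a, b, 3L), 0)
  for (seed in 1:5) {
    p <- random_mask(12, 18, seed = seed)
    t <- random_mask(12, 18, seed = seed + 100)
    for (k in c(0L, 3L, 6L)) {
      A <- which(unclass(p) == k); B <- which(unclass(t) == k)
      expected <- if (length(A) + length(B) == 0) 1 else
        2 * length(intersect(A, B)) / (length(A) + length(B))
      expect_equal(dice_coefficient(p, t, k), expected)
      expect_equal(dice_coefficient(p, t, k), dice_coefficient(t, p, k))
    }
  }
  expect_error(dice_coefficient(random_mask(4, 4), random_mask(4, 5), 1L),
               "shape")
})

test_that("rater agreement: Cohen and Fleiss kappas match closed forms", {
  # perfect agreement
  perf <- cbind(r1 = c(1, 2, 3, 1, 2), r2 = c(1, 2, 3, 1, 2))
  expect_equal(rater_agreement(perf)$kappa, 1)
  # two raters with confusion table [[20,5],[10,15]]:
  # po = 35/50, pe = (30*25 + 20*25)/50^2 = 0.5, kappa = (0.7-0.5)/0.5 = 0.4
  calls <- rbind(
    matrix(c("a", "a"), 20, 2, byrow = TRUE),
    matrix(c("a", "b"), 5, 2, byrow = TRUE),
    matrix(c("b", "a"), 10, 2, byrow = TRUE),
    matrix(c("b", "b"), 15, 2, byrow = TRUE))
  ra <- rater_agreement(calls)
  expect_equal(ra$kappa, 0.4)
  expect_equal(ra$percent_agreement, 35 / 50)
  expect_equal(ra$method, "cohen")
  # label permutation invariance
  swap <- ifelse(calls == "a", "z", "a")
  expect_equal(rater_agreement(swap)$kappa, ra$kappa)
  # Fleiss for three raters against a direct recomputation
  set.seed(3)
  M <- matrix(sample(1:3, 60, replace = TRUE), 20, 3)
  fl <- rater_agreement(M)
  cats <- sort(unique(as.vector(M)))
  cnt <- t(apply(M, 1, function(r) tabulate(match(r, cats), length(cats))))
  Pbar <- mean((rowSums(cnt^2) - 3) / (3 * 2))
  Pe <- sum((colSums(cnt) / sum(cnt))^2)
  expect_equal(fl$kappa, (Pbar - Pe) / (1 - Pe))
  expect_equal(fl$method, "fleiss")
  # degenerate single-category input is flagged, not an error
  one <- matrix(1, 5, 2)
  expect_true(rater_agreement(one)$undefined)
  expect_true(is.na(rater_agreement(one)$kappa))
})
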