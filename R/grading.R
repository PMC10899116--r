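# Tumor-level pattern quantification, IASLC grading and evaluation
# statistics.
#
# The tumor-level proportion of pattern j pools pixel counts over the m
# slides of a tumor:
#   g_j = sum_i S_ij / sum_i sum_j S_ij
# (pooled counts, NOT the average of per-slide proportions), with the
# denominator running over the six patterns only - non-tumor pixels are
# excluded. The predominant pattern is argmax(g_j); IASLC grade 1 is
# lepidic-predominant, grade 2 acinar- or papillary-predominant, and grade 3
# any tumor whose combined cribriform+micropapillary+solid fraction is 20%
# or more (or whose predominant pattern is itself high grade). The 20%
# boundary is evaluated on exact pixel counts.

#' Pooled growth-pattern composition of a tumor
#'
#' @param masks a `label_mask` or list of them (the slides of one tumor,
#'   at analysis resolution).
#' @param slide_ids optional character names for the slides.
#' @return An object of class `pattern_composition` with per-slide pixel
#'   counts `S` (slides x 6 patterns), pooled proportions `g`, the total
#'   tumor pixel count, and a `defined` flag (FALSE when no tumor pixel
#'   exists on any slide).
#' @export
compute_proportions <- function(masks, slide_ids = NULL) {
  if (inherits(masks, "label_mask")) masks <- list(masks)
  stopifnot(length(masks) >= 1L)
  S <- t(vapply(masks, function(m) class_counts(m)[-1L], numeric(6)))
  dimnames(S) <- list(slide_ids %||% paste0("slide", seq_along(masks)),
                      pattern_names())
  total <- sum(S)
  g <- if (total > 0) colSums(S) / total else setNames(rep(NA_real_, 6),
                                                       colnames(S))
  structure(list(S = S, g = g, total_px = total, m = length(masks),
                 defined = total > 0),
            class = "pattern_composition")
}

#' Construct a composition directly from proportions
#'
#' Convenience constructor for compositions known analytically (no masks);
#' proportions over the six patterns must be non-negative and sum to 1.
#'
#' @param g named numeric vector of proportions; names from
#'   [pattern_names()] (missing patterns are 0).
#' @return A `pattern_composition`.
#' @export
pattern_composition <- function(g) {
  full <- setNames(numeric(6), pattern_names())
  if (is.null(names(g))) stop("g must be named by pattern")
  bad <- setdiff(names(g), pattern_names())
  if (length(bad)) stop("unknown pattern(s): ", paste(bad, collapse = ", "))
  full[names(g)] <- g
  if (any(full < 0) || abs(sum(full) - 1) > 1e-8)
    stop("proportions must be non-negative and sum to 1")
  S <- matrix(full, 1L, dimnames = list("slide1", pattern_names()))
  structure(list(S = S, g = full, total_px = 1, m = 1L, defined = TRUE),
            class = "pattern_composition")
}

#' @export
print.pattern_composition <- function(x, ...) {
  cat(sprintf("<pattern_composition> %d slide(s), %s tumor px\n",
              x$m, format(x$total_px, big.mark = ",")))
  if (x$defined) print(round(x$g, 4)) else cat("  undefined (no tumor pixels)\n")
  invisible(x)
}

#' @export
tidy.pattern_composition <- function(x, ...) {
  tibble::tibble(pattern = names(x$g),
                 pixels = as.numeric(colSums(x$S)),
                 proportion = as.numeric(x$g))
}

stop_if_undefined <- function(comp) {
  stopifnot(inherits(comp, "pattern_composition"))
  if (!comp$defined)
    stop("composition is undefined (no tumor pixels on any slide)")
}

#' Predominant growth pattern
#'
#' The pattern with the highest pooled proportion; exact ties are broken in
#' favor of the architecturally higher-grade pattern (solid > micropapillary
#' > cribriform > acinar > papillary > lepidic), the clinically conservative
#' choice.
#'
#' @param comp a `pattern_composition`.
#' @return Pattern name (character scalar).
#' @export
predominant_pattern <- function(comp) {
  stop_if_undefined(comp)
  g <- comp$g
  # class codes increase with grade, so the last maximum is the tie-winner
  winners <- which(g == max(g))
  names(g)[max(winners)]
}

#' Automated IASLC grade
#'
#' Grade 1: lepidic-predominant with less than 20% combined high-grade
#' (cribriform + micropapillary + solid) patterns. Grade 2: acinar- or
#' papillary-predominant with less than 20% high-grade patterns. Grade 3:
#' any tumor with 20% or more high-grade patterns (boundary inclusive), or a
#' high-grade predominant pattern. The 20% comparison uses exact arithmetic
#' on pixel counts (`5 * high_grade_pixels >= total_pixels`) so boundary
#' compositions cannot flip through floating-point rounding.
#'
#' @param comp a `pattern_composition`.
#' @return An object of class `tumor_grade`: predominant pattern, integer
#'   grade 1-3, and the high-grade fraction.
#' @export
iaslc_grade <- function(comp) {
  stop_if_undefined(comp)
  hg_names <- names(pattern_classes())[high_grade_classes() + 1L]
  hg_px <- sum(colSums(comp$S)[hg_names])
  total <- comp$total_px
  hg_frac <- hg_px / total
  pred <- predominant_pattern(comp)
  grade <- if (5 * hg_px >= total || pred %in% hg_names) 3L
           else if (pred == "lepidic") 1L
           else 2L
  structure(list(predominant = pred, grade = grade,
                 high_grade_fraction = hg_frac, g = comp$g),
            class = "tumor_grade")
}

#' @export
print.tumor_grade <- function(x, ...) {
  cat(sprintf("<tumor_grade> IASLC grade %d (%s-predominant, %.1f%% high grade)\n",
              x$grade, x$predominant, 100 * x$high_grade_fraction))
  invisible(x)
}

#' @export
glance.tumor_grade <- function(x, ...) {
  tibble::tibble(predominant = x$predominant, grade = x$grade,
                 high_grade_fraction = x$high_grade_fraction)
}

#' Shannon diversity of the pattern composition
#'
#' `H = -sum_j g_j ln g_j` over the non-zero pattern proportions (natural
#' log), a measure of intratumoral pattern heterogeneity in `[0, ln 6]`.
#'
#' @param comp a `pattern_composition`.
#' @return Numeric scalar.
#' @export
shannon_diversity <- function(comp) {
  stop_if_undefined(comp)
  g <- comp$g[comp$g > 0]
  -sum(g * log(g))
}

#' Dice overlap coefficient for one class
#'
#' `2|A n B| / (|A| + |B|)` between the pixel sets of `class_id` in two
#' masks of identical shape; defined as 1 when the class is absent from
#' both.
#'
#' @param pred,truth `label_mask`s (or integer matrices) of the same shape.
#' @param class_id class code 0-6.
#' @return Numeric scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth, class_id) {
  p <- unclass(pred); t <- unclass(truth)
  if (!identical(dim(p), dim(t))) stop("masks must have the same shape")
  a <- p == class_id
  b <- t == class_id
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# macro Dice over the six pattern classes, pooled across a list of mask pairs
macro_dice <- function(preds, truths, classes = 1:6) {
  vapply(classes, function(k) {
    inter <- 0; tot <- 0
    for (i in seq_along(preds)) {
      a <- unclass(preds[[i]]) == k
      b <- unclass(truths[[i]]) == k
      inter <- inter + sum(a & b)
      tot <- tot + sum(a) + sum(b)
    }
    if (tot == 0) 1 else 2 * inter / tot
  }, numeric(1)) |> mean()
}

#' Inter-rater agreement statistics
#'
#' Percent agreement plus a chance-corrected kappa: Cohen's kappa for two
#' raters, Fleiss' kappa for three or more. Computed from exact count
#' fractions. When all raters use a single category throughout, kappa is
#' undefined (returned as `NA` with a flag).
#'
#' @param labels matrix or data frame, cases in rows, raters in columns,
#'   categorical calls over a shared codebook.
#' @return List of class `rater_agreement`: `percent_agreement` (mean
#'   pairwise), `kappa`, `method`, `undefined` flag.
#' @export
rater_agreement <- function(labels) {
  M <- as.matrix(labels)
  if (ncol(M) < 2L || nrow(M) < 2L)
    stop("need at least two raters and two cases")
  cats <- sort(unique(as.vector(M)))
  r <- ncol(M); n <- nrow(M)
  pairs <- utils::combn(r, 2)
  pa <- mean(apply(pairs, 2, function(p) mean(M[, p[1]] == M[, p[2]])))
  undefined <- length(cats) < 2L
  if (undefined) {
    kap <- NA_real_
    method <- "undefined"
  } else if (r == 2L) {
    tab <- table(factor(M[, 1], cats), factor(M[, 2], cats))
    po <- sum(diag(tab)) / n
    pe <- sum(rowSums(tab) * colSums(tab)) / n^2
    kap <- (po - pe) / (1 - pe)
    method <- "cohen"
  } else {
    cnt <- t(apply(M, 1, function(row) tabulate(match(row, cats),
                                                length(cats))))
    Pi <- (rowSums(cnt^2) - r) / (r * (r - 1))
    Pbar <- mean(Pi)
    pj <- colSums(cnt) / (n * r)
    Pe <- sum(pj^2)
    kap <- (Pbar - Pe) / (1 - Pe)
    method <- "fleiss"
  }
  structure(list(percent_agreement = pa, kappa = kap, method = method,
                 undefined = undefined),
            class = "rater_agreement")
}

#' @export
print.rater_agreement <- function(x, ...) {
  cat(sprintf("<rater_agreement> %.1f%% agreement, kappa = %s (%s)\n",
              100 * x$percent_agreement,
              if (is.na(x$kappa)) "NA" else sprintf("%.3f", x$kappa),
              x$method))
  invisible(x)
}

#' @importFrom stats setNames median
NULL

#' Tidy a fitted object
#'
#' Generic re-exported locally so composition/grade/spatial results can be
#' turned into tibbles without depending on broom.
#'
#' @param x object to tidy.
#' @param ... unused.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
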