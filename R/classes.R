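#' Growth-pattern class codebook
#'
#' The seven-class pixel codebook used throughout the package: code 0 is
#' non-tumor tissue/background, codes 1-6 are the six lung adenocarcinoma
#' growth patterns. Codes are ordered so that a higher code is an
#' architecturally higher-grade pattern, which the predominant-pattern
#' tie-break exploits.
#'
#' @return Named integer vector mapping class names to codes 0-6.
#' @export
#' @examples
#' pattern_classes()
pattern_classes <- function() {
  c("non-tumor" = 0L, lepidic = 1L, papillary = 2L, acinar = 3L,
    cribriform = 4L, micropapillary = 5L, solid = 6L)
}

#' @rdname pattern_classes
#' @export
pattern_names <- function() names(pattern_classes())[-1L]

#' @rdname pattern_classes
#' @details `high_grade_classes()` returns the codes of the high-grade
#'   patterns (cribriform, micropapillary, solid) used by the IASLC 20% rule.
#' @export
high_grade_classes <- function() c(4L, 5L, 6L)

N_CLASSES <- 7L

#' RGB image container
#'
#' A thin wrapper around an `H x W x 3` numeric array of 8-bit RGB values with
#' a microns-per-pixel (`mpp`) attribute. Used both for 768 px training
#' patches and for whole synthetic slides.
#'
#' @param pixels numeric array `H x W x 3`, values in `[0, 255]`.
#' @param mpp microns per pixel (default 0.45, the x20-equivalent scan
#'   resolution).
#' @return An object of class `image_patch`.
#' @export
image_patch <- function(pixels, mpp = 0.45) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  if (!is.numeric(mpp) || mpp <= 0) stop("mpp must be a positive number")
  structure(pixels, mpp = mpp, class = "image_patch")
}

#' Pixel label mask container
#'
#' An integer matrix of class codes 0-6 (see [pattern_classes()]) with a
#' microns-per-pixel attribute. This is the interchange object between the
#' segmentation network and the grading/spatial analytics: predictions at x20
#' (~0.45 um/px) and analysis-resolution masks at x1.25 (~7.2 um/px) use the
#' same container.
#'
#' @param labels integer matrix with values in 0..6.
#' @param mpp microns per pixel of the raster.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, mpp) {
  if (is.array(labels) && length(dim(labels)) == 2L) labels <- as.matrix(labels)
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  rng <- range(labels)
  if (rng[1] < 0L || rng[2] >= N_CLASSES)
    stop("labels must be class codes in 0..6")
  if (missing(mpp) || !is.numeric(mpp) || mpp <= 0)
    stop("a positive mpp is required on every label mask")
  structure(labels, mpp = mpp, class = "label_mask")
}

#' @rdname label_mask
#' @param x a `label_mask` or `image_patch`.
#' @export
mpp <- function(x) {
  v <- attr(x, "mpp")
  if (is.null(v)) stop("object carries no mpp metadata")
  v
}

#' Per-pixel class probability map
#'
#' `H x W x 7` array of class probabilities; every pixel's seven values are
#' non-negative and sum to one (the simplex invariant of the softmax output).
#'
#' @param probs numeric array `H x W x 7`.
#' @param tol tolerance on the per-pixel sum (default 1e-5).
#' @return An object of class `prob_map`.
#' @export
prob_map <- function(probs, tol = 1e-5) {
  stopifnot(is.array(probs), length(dim(probs)) == 3L,
            dim(probs)[3] == N_CLASSES)
  if (min(probs) < -tol) stop("probabilities must be non-negative")
  s <- rowSums(matrix(probs, ncol = N_CLASSES))
  if (max(abs(s - 1)) > tol)
    stop("per-pixel probabilities must sum to 1 within tolerance")
  structure(probs, class = "prob_map")
}

#' @export
print.label_mask <- function(x, ...) {
  cnt <- cpp_class_counts(unclass(x), N_CLASSES)
  cat(sprintf("<label_mask> %d x %d @ %.3f um/px\n", nrow(x), ncol(x), mpp(x)))
  nm <- names(pattern_classes())
  present <- which(cnt > 0)
  cat("  pixels:", paste(sprintf("%s=%d", nm[present], cnt[present]),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.image_patch <- function(x, ...) {
  cat(sprintf("<image_patch> %d x %d x 3 @ %.3f um/px\n",
              dim(x)[1], dim(x)[2], mpp(x)))
  invisible(x)
}

# per-class pixel counts of a mask, named over the full codebook
class_counts <- function(mask) {
  cnt <- cpp_class_counts(unclass(mask), N_CLASSES)
  names(cnt) <- names(pattern_classes())
  cnt
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
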