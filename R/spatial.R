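# Island-level morphometry and the acinar scattering score.
#
# An island is a connected component (8-connectivity by default) of one
# pattern class in the analysis-resolution label mask. Morphology is pixel
# area (converted to mm^2 through the mask's mpp) and solidity - the
# proportion of pixels in the island's convex hull that belong to the
# island (1 for convex shapes, lower for ragged ones). Dispersion is the
# standard distance of the island centroids,
#   d = sqrt( (sum_i (x_i - x_0)^2 + sum_i (y_i - y_0)^2) / (n * N) ),
# where n is the island count, N the tissue area in pixels at mask
# resolution, and (x_0, y_0) the mean center; d is dimensionless, 0 for a
# single island, and grows as acini spread over the tissue.

# lattice points covered by the convex hull of a set of pixel centers;
# x = column index, y = row index
hull_pixel_count <- function(x, y) {
  n <- length(x)
  if (n <= 1L) return(n)
  pts <- unique(cbind(x, y))
  if (nrow(pts) == 1L) return(1L)
  ch <- grDevices::chull(pts)
  hx <- pts[ch, 1]; hy <- pts[ch, 2]
  if (length(ch) <= 2L || abs(polygon_area(hx, hy)) < 1e-12) {
    # degenerate (collinear) hull: count lattice points on the segment
    ex <- range(pts[, 1]); ey <- range(pts[, 2])
    ddx <- ex[2] - ex[1]; ddy <- ey[2] - ey[1]
    if (ddx == 0) return(ddy + 1L)
    if (ddy == 0) return(ddx + 1L)
    g <- gcd2(ddx, ddy)
    return(g + 1L)
  }
  # orient counter-clockwise, then count bounding-box pixel centers lying in
  # every edge half-plane (boundary inclusive)
  if (polygon_area(hx, hy) < 0) { hx <- rev(hx); hy <- rev(hy) }
  gx <- seq(min(hx), max(hx))
  gy <- seq(min(hy), max(hy))
  G <- expand.grid(x = gx, y = gy)
  inside <- rep(TRUE, nrow(G))
  m <- length(hx)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (G$y - hy[i]) - (hy[j] - hy[i]) * (G$x - hx[i])
    inside <- inside & cross >= -1e-9
  }
  sum(inside)
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

#' Extract the islands of one pattern class
#'
#' Labels the connected components of `class_id` in the mask and measures
#' each island: pixel count, area in mm^2 (`pixel_count * (mpp/1000)^2`),
#' centroid (unweighted mean of member pixel centers; `x` = column, `y` =
#' row), convex-hull pixel count and solidity.
#'
#' @param mask a `label_mask` (with mpp).
#' @param class_id class code 1-6 (name or code).
#' @param connectivity 8 (default) or 4.
#' @param tissue_px tissue area N in pixels at mask resolution; defaults to
#'   the count of non-background pixels in the mask. Override when a
#'   luminance-threshold tissue mask from the underlying image is available.
#' @return An object of class `island_set`: a tibble of islands, the island
#'   count `n`, tissue area `N`, `mpp` and `class_id`. An absent class
#'   yields an empty set, not an error.
#' @export
extract_islands <- function(mask, class_id = "acinar", connectivity = 8L,
                            tissue_px = NULL) {
  m <- mpp(mask)
  if (is.character(class_id))
    class_id <- pattern_classes()[[class_id]]
  stopifnot(class_id %in% 1:6, connectivity %in% c(4L, 8L))
  lab <- cpp_label_components((unclass(mask) == class_id) * 1L,
                              as.integer(connectivity))
  N <- tissue_px %||% sum(unclass(mask) != 0L)
  k <- max(lab)
  if (k == 0L) {
    isl <- tibble::tibble(id = integer(), pixel_count = integer(),
                          area_mm2 = numeric(), x = numeric(), y = numeric(),
                          hull_px = numeric(), solidity = numeric())
  } else {
    idx <- which(lab > 0L)
    comp <- lab[idx]
    rows <- (idx - 1L) %% nrow(lab) + 1L
    cols <- (idx - 1L) %/% nrow(lab) + 1L
    px_area <- (m / 1000)^2
    isl <- tibble::tibble(
      id = seq_len(k),
      pixel_count = as.integer(tabulate(comp, k)),
      x = as.numeric(tapply(cols, comp, mean)),
      y = as.numeric(tapply(rows, comp, mean)),
      hull_px = vapply(seq_len(k), function(i)
        as.numeric(hull_pixel_count(cols[comp == i], rows[comp == i])),
        numeric(1)))
    isl$area_mm2 <- isl$pixel_count * px_area
    isl$solidity <- isl$pixel_count / isl$hull_px
    isl <- isl[, c("id", "pixel_count", "area_mm2", "x", "y", "hull_px",
                   "solidity")]
  }
  structure(list(islands = isl, n = k, N = N, mpp = m,
                 class_id = as.integer(class_id)),
            class = "island_set")
}

#' @export
print.island_set <- function(x, ...) {
  cat(sprintf("<island_set> %d island(s) of class %s, tissue N = %d px @ %.3f um/px\n",
              x$n, names(pattern_classes())[x$class_id + 1L], x$N, x$mpp))
  invisible(x)
}

#' @export
tidy.island_set <- function(x, ...) x$islands

#' Island morphology table
#'
#' @param islands an `island_set`.
#' @return Tibble with one row per island: `area_mm2` and `solidity` (plus
#'   identifiers); the per-island morphology features.
#' @export
island_morphology <- function(islands) {
  stopifnot(inherits(islands, "island_set"))
  islands$islands[, c("id", "area_mm2", "solidity")]
}

#' Acinar scattering score (standard distance)
#'
#' The RMS deviation of island centroids from their mean center, normalized
#' by `sqrt(n * N)`:
#' `d = sqrt((sum (x_i - x_0)^2 + sum (y_i - y_0)^2) / (n * N))`.
#' Dimensionless; 0 for a single island; invariant to translation and to
#' scaling coordinates by `s` with `N` by `s^2`. With no island the score is
#' undefined and `NA` is returned (distinct from 0), with attribute
#' `reason`.
#'
#' @param islands an `island_set` (any class, typically acinar).
#' @return Numeric scalar `d`, or flagged `NA` when `n = 0`.
#' @export
acinar_scattering <- function(islands) {
  stopifnot(inherits(islands, "island_set"))
  if (islands$N <= 0) stop("tissue area N must be positive")
  if (islands$n == 0L)
    return(structure(NA_real_, reason = "no islands"))
  x <- islands$islands$x
  y <- islands$islands$y
  sqrt((sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
         (islands$n * islands$N))
}

#' Tumor-level spatial summary
#'
#' Pools the islands of all slides of a tumor: mean island area and mean
#' solidity over all islands (reported only when the tumor's acinar
#' proportion is at least `min_acinar_fraction`, else flagged ineligible),
#' and the scattering score as the median of per-slide standard distances
#' over slides with at least one island, dichotomized at `cutoff` (strictly
#' greater is "high").
#'
#' @param per_slide list of `island_set`s, one per slide.
#' @param composition optional `pattern_composition` used for the >= 5%
#'   acinar eligibility test of the morphology features.
#' @param min_acinar_fraction eligibility threshold (default 0.05).
#' @param cutoff scattering dichotomization cutoff (default 0.36, a fixed
#'   externally calibrated value).
#' @return An object of class `tumor_spatial_summary`.
#' @export
tumor_spatial_summary <- function(per_slide, composition = NULL,
                                  min_acinar_fraction = 0.05,
                                  cutoff = 0.36) {
  stopifnot(is.list(per_slide), length(per_slide) >= 1L,
            all(vapply(per_slide, inherits, logical(1), "island_set")))
  pooled <- do.call(rbind, lapply(per_slide, function(s) s$islands))
  eligible <- TRUE
  acinar_frac <- NA_real_
  if (!is.null(composition)) {
    stop_if_undefined(composition)
    acinar_frac <- composition$g[["acinar"]]
    eligible <- acinar_frac >= min_acinar_fraction
  }
  mean_area <- if (eligible && nrow(pooled) > 0) mean(pooled$area_mm2)
               else NA_real_
  mean_solidity <- if (eligible && nrow(pooled) > 0) mean(pooled$solidity)
                   else NA_real_
  d_slides <- vapply(per_slide, function(s)
    if (s$n >= 1L) as.numeric(acinar_scattering(s)) else NA_real_, numeric(1))
  d_avail <- d_slides[!is.na(d_slides)]
  scattering_d <- if (length(d_avail)) median(d_avail) else NA_real_
  scattering_class <- if (is.na(scattering_d)) NA_character_
                      else if (scattering_d > cutoff) "high" else "low"
  structure(list(mean_acinar_area_mm2 = mean_area,
                 mean_solidity = mean_solidity,
                 scattering_d = scattering_d,
                 scattering_class = scattering_class,
                 per_slide_d = d_slides,
                 n_islands = nrow(pooled),
                 eligible = eligible,
                 acinar_fraction = acinar_frac,
                 cutoff = cutoff),
            class = "tumor_spatial_summary")
}

#' @export
print.tumor_spatial_summary <- function(x, ...) {
  cat("<tumor_spatial_summary>\n")
  cat(sprintf("  islands: %d; mean area %.5f mm^2; mean solidity %.3f%s\n",
              x$n_islands, x$mean_acinar_area_mm2, x$mean_solidity,
              if (!x$eligible) " (ineligible: <5% acinar)" else ""))
  cat(sprintf("  scattering d = %.4f -> %s (cutoff %.2f)\n",
              x$scattering_d, x$scattering_class, x$cutoff))
  invisible(x)
}

#' @export
glance.tumor_spatial_summary <- function(x, ...) {
  tibble::tibble(mean_acinar_area_mm2 = x$mean_acinar_area_mm2,
                 mean_solidity = x$mean_solidity,
                 scattering_d = x$scattering_d,
                 scattering_class = x$scattering_class,
                 n_islands = x$n_islands,
                 eligible = x$eligible)
}
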