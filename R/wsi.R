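# Slide-level inference: tiling, Reinhard-style color normalization,
# per-tile prediction, stitching, majority downsampling to the analysis
# resolution (x1.25, ~7.2 um/px) and small-component postprocessing.

tile_starts <- function(n, t) {
  if (n <= t) return(0L)
  s <- seq.int(0L, by = t, length.out = n %/% t)
  if (n %% t != 0L) s <- c(s, n - t)
  as.integer(s)
}

#' Tile a slide raster
#'
#' Splits a raster into a non-overlapping `tile_px` grid; edge tiles are
#' anchored to the slide edge (and may overlap the previous tile). Each
#' tile records its slide-coordinate origin (0-based row/col). A slide
#' smaller than one tile yields a single background-padded tile, flagged.
#'
#' @param slide `image_patch`, `label_mask`, 3D RGB array or 2D matrix.
#' @param tile_px tile side in pixels (default 2000 at x20).
#' @return An object of class `tile_grid`: list of tiles with origins, plus
#'   the slide dimensions needed for [stitch_tiles()].
#' @export
tile_image <- function(slide, tile_px = 2000L) {
  x <- unclass(slide)
  d <- dim(x)
  is3d <- length(d) == 3L
  H <- d[1]; W <- d[2]
  padded <- H < tile_px || W < tile_px
  if (padded) {
    fill <- if (is3d) 255 else 0L
    full <- if (is3d) array(fill, c(max(H, tile_px), max(W, tile_px), d[3]))
            else matrix(fill, max(H, tile_px), max(W, tile_px))
    if (is3d) full[1:H, 1:W, ] <- x else full[1:H, 1:W] <- x
    x <- full
  }
  ys <- tile_starts(dim(x)[1], tile_px)
  xs <- tile_starts(dim(x)[2], tile_px)
  tiles <- list()
  for (oy in ys) for (ox in xs) {
    tl <- if (is3d) x[oy + 1:tile_px, ox + 1:tile_px, , drop = FALSE]
          else x[oy + 1:tile_px, ox + 1:tile_px, drop = FALSE]
    tiles[[length(tiles) + 1L]] <- list(data = tl, origin = c(oy, ox))
  }
  structure(list(tiles = tiles, dim = d, tile_px = as.integer(tile_px),
                 padded = padded, mpp = attr(slide, "mpp")),
            class = "tile_grid")
}

#' @rdname tile_image
#' @param grid a `tile_grid`.
#' @return `stitch_tiles()` returns the reassembled raster (round-trip
#'   identity with [tile_image()]).
#' @export
stitch_tiles <- function(grid) {
  stopifnot(inherits(grid, "tile_grid"))
  d <- grid$dim
  is3d <- length(d) == 3L
  Hp <- max(d[1], grid$tile_px); Wp <- max(d[2], grid$tile_px)
  out <- if (is3d) array(0, c(Hp, Wp, d[3])) else matrix(0L, Hp, Wp)
  t <- grid$tile_px
  for (tl in grid$tiles) {
    oy <- tl$origin[1]; ox <- tl$origin[2]
    if (is3d) out[oy + 1:t, ox + 1:t, ] <- tl$data
    else out[oy + 1:t, ox + 1:t] <- tl$data
  }
  if (is3d) out[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
  else out[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
}

#' Color-normalization target statistics
#'
#' Per-channel mean and spread of an RGB image in CIE Lab, the perceptual
#' space used for Reinhard-style statistics matching.
#'
#' @param image RGB array (0-255).
#' @return An object of class `normalization_stats` (`mean`, `sd` per Lab
#'   channel).
#' @export
normalization_stats <- function(image) {
  lab <- rgb_to_lab(unclass(image))
  s <- apply(lab, 2, stats::sd)
  if (any(s <= 0)) stop("target image has zero variance in a Lab channel")
  structure(list(mean = colMeans(lab), sd = s), class = "normalization_stats")
}

#' @rdname normalization_stats
#' @details `default_target_stats()` returns the frozen target shipped with
#'   the package: the Lab statistics of a balanced six-pattern synthetic
#'   montage (a stand-in for a reference H&E tile; values frozen once at
#'   generation).
#' @export
default_target_stats <- function() {
  structure(list(mean = c(77.54, 18.67, -10.06),
                 sd = c(19.63, 10.76, 12.44)),
            class = "normalization_stats")
}

rgb_to_lab <- function(img) {
  M <- matrix(img, ncol = 3L) / 255
  grDevices::convertColor(M, from = "sRGB", to = "Lab")
}

lab_to_rgb <- function(lab, dims) {
  M <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  array(pmin(pmax(M, 0), 1) * 255, dims)
}

#' Normalize a tile's color to a target
#'
#' Reinhard-style statistics matching: the tile is mapped to CIE Lab, each
#' channel is re-centered and re-scaled to the target statistics, and the
#' result mapped back to sRGB. Deterministic and idempotent up to gamut
#' clipping (about one 8-bit intensity level). A blank (zero-variance) tile
#' is returned unchanged with attribute `normalized = FALSE`.
#'
#' @param tile RGB array (0-255), e.g. one tile from [tile_image()].
#' @param target a [normalization_stats()] (default the shipped target).
#' @return The normalized tile (same dimensions, 0-255).
#' @export
normalize_tile <- function(tile, target = default_target_stats()) {
  stopifnot(inherits(target, "normalization_stats"))
  x <- unclass(tile)
  lab <- rgb_to_lab(x)
  s <- apply(lab, 2, stats::sd)
  if (any(s < 1e-6)) {
    attr(tile, "normalized") <- FALSE
    return(tile)
  }
  # iterate the statistics match to its fixed point: sRGB gamut clipping
  # perturbs the matched statistics slightly, so a second pass re-centers
  # them (this also makes the operator idempotent to within one 8-bit level)
  for (it in 1:3) {
    for (c in 1:3)
      lab[, c] <- (lab[, c] - mean(lab[, c])) / stats::sd(lab[, c]) *
        target$sd[c] + target$mean[c]
    clipped <- pmin(pmax(grDevices::convertColor(lab, "Lab", "sRGB"), 0), 1)
    lab <- grDevices::convertColor(clipped, "sRGB", "Lab")
    dev <- max(abs(colMeans(lab) - target$mean),
               abs(apply(lab, 2, stats::sd) - target$sd))
    if (dev < 0.05) break
  }
  out <- array(clipped * 255, dim(x))
  if (!is.null(attr(tile, "mpp"))) attr(out, "mpp") <- attr(tile, "mpp")
  if (inherits(tile, "image_patch")) class(out) <- "image_patch"
  attr(out, "normalized") <- TRUE
  out
}

#' Majority-vote label downsampling
#'
#' Downsamples a label raster by an integer factor; each output pixel takes
#' the majority class of its block (ties to the lowest class index). Edge
#' blocks may be partial; output dimensions are `ceiling(input/factor)`.
#' The mpp is multiplied by the factor.
#'
#' @param mask a `label_mask`.
#' @param factor integer >= 1 (default 16: x20 to x1.25).
#' @return A `label_mask` at the coarser resolution.
#' @export
downsample_mask <- function(mask, factor = 16L) {
  stopifnot(factor >= 1L, factor == as.integer(factor))
  if (factor == 1L) return(mask)
  out <- cpp_block_mode(unclass(mask), as.integer(factor), N_CLASSES)
  label_mask(out, mpp = mpp(mask) * factor)
}

#' Per-class small-component area thresholds
#'
#' The empirical postprocessing thresholds: lepidic components under 0.05
#' mm^2 and papillary/cribriform/solid components under 0.015 mm^2 are
#' removed; acinar and micropapillary are never filtered.
#'
#' @param lepidic,papillary,cribriform,solid thresholds in mm^2.
#' @return Named numeric vector over the filtered classes.
#' @export
filter_thresholds <- function(lepidic = 0.05, papillary = 0.015,
                              cribriform = 0.015, solid = 0.015) {
  th <- c(lepidic = lepidic, papillary = papillary,
          cribriform = cribriform, solid = solid)
  if (any(th < 0)) stop("thresholds must be non-negative")
  th
}

#' Remove small pattern components
#'
#' Relabels to background every connected component (8-connectivity) of a
#' thresholded class whose area is strictly below its threshold. Classes
#' without a threshold (acinar, micropapillary) are never altered.
#' Idempotent.
#'
#' @param mask a `label_mask` (mpp required for the pixel-to-mm^2
#'   conversion `(mpp/1000)^2`).
#' @param thresholds named vector from [filter_thresholds()].
#' @return The filtered `label_mask`.
#' @export
remove_small_components <- function(mask, thresholds = filter_thresholds()) {
  m <- mpp(mask)
  px_area <- (m / 1000)^2
  lab <- unclass(mask)
  for (nm in names(thresholds)) {
    k <- pattern_classes()[[nm]]
    comp <- cpp_label_components((lab == k) * 1L, 8L)
    if (max(comp) == 0L) next
    areas <- tabulate(comp[comp > 0L], max(comp)) * px_area
    drop <- which(areas < thresholds[[nm]])
    if (length(drop)) lab[comp %in% drop] <- 0L
  }
  label_mask(lab, mpp = m)
}

#' Whole-slide growth-pattern inference
#'
#' The full inference pipeline: the slide is cut into `tile_px` tiles at
#' x20, each tile is color-normalized to the target, chopped into
#' `patch_px` patches (edge-anchored), predicted, reassembled and stitched;
#' the stitched x20 label raster is majority-downsampled by
#' `downsample_factor` to the analysis resolution and postprocessed with
#' [remove_small_components()].
#'
#' @param network a trained `gpseg_network`.
#' @param slide `image_patch` (mpp metadata required; no guessing).
#' @param tile_px tile side (default 2000).
#' @param patch_px network patch side (default the config patch size).
#' @param target normalization target; `NULL` disables normalization.
#' @param downsample_factor x20-to-analysis downsampling (default 16).
#' @param postprocess apply the small-component filter.
#' @param thresholds thresholds for the filter.
#' @return A `label_mask` at analysis resolution
#'   (`mpp = downsample_factor * slide mpp`).
#' @export
infer_slide <- function(network, slide, tile_px = 2000L, patch_px = NULL,
                        target = default_target_stats(),
                        downsample_factor = 16L, postprocess = TRUE,
                        thresholds = filter_thresholds()) {
  stopifnot(inherits(network, "gpseg_network"))
  m <- attr(slide, "mpp")
  if (is.null(m)) stop("slide has no mpp metadata; refusing to guess")
  patch_px <- patch_px %||% network$config$patch_size
  x <- unclass(slide)
  d <- dim(x)
  grid <- tile_image(slide, tile_px)
  out_tiles <- lapply(grid$tiles, function(tl) {
    img <- tl$data
    if (!is.null(target)) img <- normalize_tile(img, target)
    t <- dim(img)[1]
    lab <- matrix(0L, t, t)
    for (oy in tile_starts(t, patch_px)) for (ox in tile_starts(t, patch_px)) {
      pw <- min(patch_px, t)
      sub <- img[oy + 1:pw, ox + 1:pw, , drop = FALSE]
      if (pw < patch_px) {  # tile smaller than a patch: pad to patch
        pad <- array(255, c(patch_px, patch_px, 3))
        pad[1:pw, 1:pw, ] <- sub
        pl <- predict_patch(network, pad)$labels[1:pw, 1:pw]
      } else {
        pl <- unclass(predict_patch(network, sub)$labels)
      }
      lab[oy + 1:pw, ox + 1:pw] <- pl
    }
    list(data = lab, origin = tl$origin)
  })
  lab_grid <- structure(list(tiles = out_tiles, dim = d[1:2],
                             tile_px = grid$tile_px, padded = grid$padded,
                             mpp = m),
                        class = "tile_grid")
  full <- label_mask(stitch_tiles(lab_grid), mpp = m)
  small <- downsample_mask(full, downsample_factor)
  if (postprocess) small <- remove_small_components(small, thresholds)
  small
}
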