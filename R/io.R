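# On-disk interchange: PNG rasters with JSON sidecars, and network
# checkpoints (serialized weights + a JSON description of the config).

#' Read and write label masks
#'
#' Masks are stored as 8-bit grayscale PNG with the class code as the pixel
#' value (0-6), plus a JSON sidecar (`<path>.json`) carrying the mpp, class
#' names and palette. `read_label_mask()` restores the mask with its mpp.
#'
#' @param mask a [label_mask()].
#' @param path PNG file path.
#' @return `write_label_mask()` returns `path` invisibly;
#'   `read_label_mask()` returns a `label_mask`.
#' @export
write_label_mask <- function(mask, path) {
  png::writePNG(unclass(mask) / 255, path)
  side <- list(mpp = mpp(mask),
               class_names = names(pattern_classes()),
               class_codes = unname(pattern_classes()),
               palette = mask_palette())
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("missing sidecar ", side_path, " (mpp is required, not guessed)")
  side <- jsonlite::read_json(side_path)
  label_mask(round(img * 255), mpp = as.numeric(side$mpp))
}

mask_palette <- function() {
  c("#FFFFFF", "#7FC97F", "#BEAED4", "#FDC086", "#F0027F", "#386CB0",
    "#BF5B17")
}

#' Read and write RGB image patches
#'
#' @param patch an [image_patch()].
#' @param path PNG file path.
#' @param mpp microns per pixel to record when reading (sidecar value wins
#'   if present).
#' @return `read_image_patch()` returns an `image_patch`.
#' @export
write_image_patch <- function(patch, path) {
  png::writePNG(unclass(patch) / 255, path)
  jsonlite::write_json(list(mpp = attr(patch, "mpp")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_image_patch
#' @export
read_image_patch <- function(path, mpp = 0.45) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  side_path <- paste0(path, ".json")
  if (file.exists(side_path))
    mpp <- as.numeric(jsonlite::read_json(side_path)$mpp)
  image_patch(img[, , 1:3] * 255, mpp = mpp)
}

#' Save and load network checkpoints
#'
#' A checkpoint is a single serialized file of the weights plus a JSON
#' sidecar describing the [network_config()].
#'
#' @param network a `gpseg_network`.
#' @param path checkpoint file path.
#' @return `load_checkpoint()` returns a `gpseg_network`.
#' @export
save_checkpoint <- function(network, path) {
  stopifnot(inherits(network, "gpseg_network"))
  saveRDS(list(config = unclass(network$config), params = network$params),
          path)
  jsonlite::write_json(unclass(network$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- structure(obj$config, class = "network_config")
  net <- build_network(cfg, seed = 1L)
  net$params <- obj$params
  net
}

#' Read training pairs from a directory
#'
#' Images (`<stem>.png`) and masks (`<stem>_mask.png`) are matched by
#' filename stem; each must have its JSON sidecar.
#'
#' @param dir directory containing the pairs.
#' @return List of `list(patch, mask)` training pairs.
#' @export
read_training_pairs <- function(dir) {
  masks <- list.files(dir, pattern = "_mask\\.png$", full.names = TRUE)
  if (!length(masks)) stop("no *_mask.png files found in ", dir)
  lapply(masks, function(mp) {
    ip <- sub("_mask\\.png$", ".png", mp)
    if (!file.exists(ip)) stop("missing image for mask ", mp)
    list(patch = read_image_patch(ip), mask = read_label_mask(mp))
  })
}
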