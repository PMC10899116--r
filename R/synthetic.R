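# Deterministic synthetic-data generators.
#
# Three generators make every other module testable without slide archives:
# (a) H&E-caricature tiles with ground-truth masks, one texture per growth
#     pattern (pure functions of (spec, seed));
# (b) label-mask layouts with prescribed island geometry for the
#     morphometry/scattering round-trips;
# (c) multi-slide "tumors" with prescribed pooled pattern composition.
#
# The tile textures are caricatures designed to be separable by a small
# convolutional network - distinct lumen geometry, nuclear density and
# white-space fraction per pattern - not histologically realistic renderings;
# they must not be read as a segmentation benchmark.

HE_WHITE <- c(245, 245, 245)
HE_STROMA <- c(240, 198, 222)  # pale eosin stroma (non-tumor)
HE_PINK <- c(222, 140, 188)    # eosin-stained tumor stroma / gland body
HE_DARK <- c(64, 44, 126)      # hematoxylin nuclei
HE_MASS <- c(140, 96, 168)     # cribriform nuclear mass
HE_SOLID <- c(96, 62, 140)     # solid nuclear sheet

disc_offsets <- function(r) {
  s <- floor(r)
  g <- expand.grid(dy = -s:s, dx = -s:s)
  g[g$dy^2 + g$dx^2 <= r^2, ]
}

# stamp filled discs of radius r at centers (cy, cx) into 3 channel matrices
stamp_discs <- function(ch, cy, cx, r, col) {
  off <- disc_offsets(r)
  H <- nrow(ch[[1]]); W <- ncol(ch[[1]])
  for (i in seq_len(nrow(off))) {
    yy <- cy + off$dy[i]; xx <- cx + off$dx[i]
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    if (!any(ok)) next
    idx <- cbind(yy[ok], xx[ok])
    for (c in 1:3) ch[[c]][idx] <- col[c]
  }
  ch
}

jitter_grid <- function(H, W, spacing, jitter) {
  cy <- seq(spacing %/% 2, H, by = spacing)
  cx <- seq(spacing %/% 2, W, by = spacing)
  g <- expand.grid(cy = cy, cx = cx)
  n <- nrow(g)
  g$cy <- round(g$cy + stats::runif(n, -jitter, jitter))
  g$cx <- round(g$cx + stats::runif(n, -jitter, jitter))
  g
}

new_canvas <- function(H, W, col) {
  lapply(1:3, function(c) matrix(col[c], H, W))
}

# non-tumor tissue: pale stroma with smooth isotropic mottling - a stable,
# low-frequency blotch signature that resembles no striped, ringed or dotted
# tumor texture
render_background <- function(H, W) {
  ch <- new_canvas(H, W, HE_STROMA)
  xg <- matrix(seq_len(W), H, W, byrow = TRUE)
  yg <- matrix(seq_len(H), H, W)
  ph <- stats::runif(4, 0, 50)
  blotch <- sin(2 * pi * (xg + ph[1]) / 41) * sin(2 * pi * (yg + ph[2]) / 53) +
    sin(2 * pi * (xg + ph[3]) / 59) * sin(2 * pi * (yg + ph[4]) / 37)
  shade <- 7 * blotch
  for (c in 1:3) ch[[c]] <- ch[[c]] - pmax(shade, 0)
  ch
}

# full-rectangle texture for one pattern class; draws from the current RNG
render_texture <- function(class_name, H, W) {
  xg <- matrix(seq_len(W), H, W, byrow = TRUE)
  yg <- matrix(seq_len(H), H, W)
  ch <- switch(class_name,
    solid = {
      # near-uniform dark nuclear sheet of densely packed nuclei, no lumina
      ch <- new_canvas(H, W, HE_SOLID)
      g <- jitter_grid(H, W, 4L, 1)
      stamp_discs(ch, g$cy, g$cx, 1.8, HE_DARK)
    },
    acinar = {
      # fine-grained nucleus rings around small white lumina on pink stroma
      ch <- new_canvas(H, W, HE_PINK)
      g <- jitter_grid(H, W, 11L, 1.5)
      ch <- stamp_discs(ch, g$cy, g$cx, 4.2, HE_DARK)
      stamp_discs(ch, g$cy, g$cx, 2.4, HE_WHITE)
    },
    cribriform = {
      # one mid-tone nuclear mass densely punched with white lumina
      ch <- new_canvas(H, W, HE_MASS)
      p <- jitter_grid(H, W, 8L, 1)
      stamp_discs(ch, p$cy, p$cx, 3.2, HE_WHITE)
    },
    papillary = {
      # frond cross-sections: large pink fibrovascular cores rimmed by dark
      # nuclei, floating in white space (the color inverse of acinar glands)
      ch <- new_canvas(H, W, HE_WHITE)
      g <- jitter_grid(H, W, 24L, 4)
      ch <- stamp_discs(ch, g$cy, g$cx, 11, HE_DARK)
      stamp_discs(ch, g$cy, g$cx, 8.5, HE_PINK)
    },
    micropapillary = {
      # sparse small detached nuclear tufts floating in white space
      ch <- new_canvas(H, W, HE_WHITE)
      g <- jitter_grid(H, W, 16L, 4)
      stamp_discs(ch, g$cy, g$cx, 2.6, HE_DARK)
    },
    lepidic = {
      # thin curvilinear septa (alveolar walls) with sparse nuclei
      ch <- new_canvas(H, W, HE_WHITE)
      ph <- stats::runif(4, 0, 40)
      w1 <- abs(sin(2 * pi * (xg + ph[1] + 6 * sin(2 * pi * (yg + ph[2]) / 40)) / 16)) < 0.25
      w2 <- abs(sin(2 * pi * (yg + ph[3] + 6 * sin(2 * pi * (xg + ph[4]) / 40)) / 16)) < 0.25
      wall <- w1 | w2
      for (c in 1:3) ch[[c]][wall] <- HE_PINK[c]
      g <- jitter_grid(H, W, 7L, 2)
      on_wall <- wall[cbind(pmin(pmax(g$cy, 1), H), pmin(pmax(g$cx, 1), W))]
      stamp_discs(ch, g$cy[on_wall], g$cx[on_wall], 1.4, HE_DARK)
    },
    stop("unknown pattern: ", class_name))
  ch
}

# smooth random blob region with randomized center and radius, so that the
# tumor region carries no fixed positional cue a network could shortcut on
blob_region <- function(H, W) {
  cy <- H * stats::runif(1, 0.3, 0.7); cx <- W * stats::runif(1, 0.3, 0.7)
  r0 <- stats::runif(1, 0.28, 0.52) * min(H, W)
  a <- stats::runif(3, 0.03, 0.09)
  ph <- stats::runif(3, 0, 2 * pi)
  xg <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  yg <- matrix(seq_len(H), H, W) - cy
  th <- atan2(yg, xg)
  rr <- r0 * (1 + a[1] * sin(2 * th + ph[1]) + a[2] * sin(3 * th + ph[2]) +
                a[3] * sin(4 * th + ph[3]))
  sqrt(xg^2 + yg^2) < rr
}

#' Generate a synthetic growth-pattern tile
#'
#' Renders an H&E-caricature texture for one growth pattern inside a smooth
#' random blob region surrounded by non-tumor stroma, with the matching
#' ground-truth mask (blob = pattern class, rest = 0). Pure function of
#' `(pattern, size, seed)`: the same seed reproduces the tile bit for bit.
#' Textures caricature the defining geometry of each pattern (packed nuclei,
#' lumen rings, punched lumina, fronds, tufts, septa) and differ in
#' white-space fraction, but are not histologically realistic.
#'
#' @param pattern pattern name from [pattern_names()].
#' @param size tile side in pixels (default 768).
#' @param seed integer seed.
#' @param mpp microns per pixel recorded on the outputs (default 0.45).
#' @return List with `patch` (an [image_patch()]) and `mask` (a
#'   [label_mask()]).
#' @export
generate_pattern_tile <- function(pattern, size = 768L, seed = 1L,
                                  mpp = 0.45) {
  if (!pattern %in% pattern_names()) stop("unknown pattern: ", pattern)
  with_seed(seed, {
    region <- blob_region(size, size)
    tex <- render_texture(pattern, size, size)
    ch <- render_background(size, size)
    for (c in 1:3) {
      ch[[c]][region] <- tex[[c]][region]
      ch[[c]] <- ch[[c]] + matrix(stats::rnorm(size * size, 0, 4), size, size)
    }
    img <- array(0, c(size, size, 3))
    for (c in 1:3) img[, , c] <- pmin(pmax(ch[[c]], 0), 255)
    mask <- matrix(0L, size, size)
    mask[region] <- pattern_classes()[[pattern]]
    list(patch = image_patch(img, mpp = mpp),
         mask = label_mask(mask, mpp = mpp))
  })
}

#' White-space fraction of a tile
#'
#' The fraction of near-white pixels (all channels above 200), the trivial
#' texture statistic that separates the six synthetic pattern textures.
#'
#' @param patch `image_patch` or RGB array.
#' @param region optional logical matrix restricting the statistic.
#' @return Numeric scalar in `[0, 1]`.
#' @export
white_fraction <- function(patch, region = NULL) {
  x <- unclass(patch)
  w <- x[, , 1] > 200 & x[, , 2] > 200 & x[, , 3] > 200
  if (!is.null(region)) mean(w[region]) else mean(w)
}

# ---- island layouts --------------------------------------------------------

shape_pixels <- function(shape, target_px) {
  # returns integer offset matrix (dy, dx) around an anchor, chosen so the
  # realized pixel count is within 2% of target (exact for square and L)
  switch(shape,
    square = {
      side <- max(1L, as.integer(round(sqrt(target_px))))
      as.matrix(expand.grid(dy = 0:(side - 1L), dx = 0:(side - 1L)))
    },
    L = {
      a <- max(1L, as.integer(round(sqrt(target_px / 3))))
      v <- expand.grid(dy = 0:(2L * a - 1L), dx = 0:(a - 1L))
      h <- expand.grid(dy = a:(2L * a - 1L), dx = a:(2L * a - 1L))
      as.matrix(unique(rbind(v, h)))
    },
    disc = {
      best <- NULL; bestdiff <- Inf
      for (r in seq(sqrt(target_px / pi) * 0.85, sqrt(target_px / pi) * 1.15,
                    by = 0.02)) {
        o <- disc_offsets(r)
        if (abs(nrow(o) - target_px) < bestdiff) {
          bestdiff <- abs(nrow(o) - target_px)
          best <- o
        }
      }
      as.matrix(best)
    },
    ellipse = {
      best <- NULL; bestdiff <- Inf
      b0 <- sqrt(target_px / (2 * pi))
      for (b in seq(b0 * 0.85, b0 * 1.15, by = 0.02)) {
        s <- floor(2 * b)
        g <- expand.grid(dy = -s:s, dx = -s:s)
        o <- g[(g$dy / b)^2 + (g$dx / (2 * b))^2 <= 1, ]
        if (abs(nrow(o) - target_px) < bestdiff) {
          bestdiff <- abs(nrow(o) - target_px)
          best <- o
        }
      }
      as.matrix(best)
    },
    stop("unknown shape: ", shape))
}

#' Island specification
#'
#' @param class_id pattern class (name or code 1-6).
#' @param target_px target pixel count (realized within 2%; exact for
#'   `square` and `L`).
#' @param shape one of `"square"`, `"disc"`, `"L"`, `"ellipse"`.
#' @param centroid island centroid `c(x, y)` in mask pixel coordinates.
#' @return A list of class `island_spec`.
#' @export
island_spec <- function(class_id, target_px, shape = "square", centroid) {
  if (is.character(class_id)) class_id <- pattern_classes()[[class_id]]
  stopifnot(class_id %in% 1:6, target_px >= 1, length(centroid) == 2L)
  structure(list(class_id = as.integer(class_id),
                 target_px = as.integer(target_px),
                 shape = match.arg(shape, c("square", "disc", "L", "ellipse")),
                 centroid = as.numeric(centroid)),
            class = "island_spec")
}

#' Generate a label-mask layout with prescribed islands
#'
#' Places the specified islands (non-overlapping) on a background canvas and
#' emits the realized ground truth (pixel count, centroid) alongside, so the
#' morphometry and scattering modules can be checked by round-trip.
#'
#' @param specs list of [island_spec()]s.
#' @param canvas `c(H, W)` canvas size in pixels.
#' @param mpp microns per pixel (default 7.2, the analysis resolution).
#' @param seed integer seed (reserved for randomized placements; the
#'   layout itself is deterministic in the specs).
#' @return List with `mask` (a [label_mask()]) and `truth` (a tibble with
#'   one row per island: class, shape, target and realized pixel count,
#'   realized centroid).
#' @export
generate_island_layout <- function(specs, canvas = c(256L, 256L), mpp = 7.2,
                                   seed = 1L) {
  stopifnot(is.list(specs), length(specs) >= 1L)
  if (inherits(specs, "island_spec")) specs <- list(specs)
  H <- canvas[1]; W <- canvas[2]
  mask <- matrix(0L, H, W)
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    off <- shape_pixels(sp$shape, sp$target_px)
    # anchor so the realized centroid lands on the requested one
    anchor_y <- round(sp$centroid[2] - mean(off[, "dy"]))
    anchor_x <- round(sp$centroid[1] - mean(off[, "dx"]))
    yy <- anchor_y + off[, "dy"]
    xx <- anchor_x + off[, "dx"]
    if (any(yy < 1 | yy > H | xx < 1 | xx > W))
      stop("island ", i, " does not fit the canvas")
    idx <- cbind(yy, xx)
    if (any(mask[idx] != 0L))
      stop("island ", i, " overlaps a previously placed island")
    mask[idx] <- sp$class_id
    realized <- nrow(off)
    if (abs(realized - sp$target_px) / sp$target_px > 0.02)
      warning("island ", i, " realized pixel count deviates >2% from target")
    rows[[i]] <- tibble::tibble(
      id = i, class_id = sp$class_id, shape = sp$shape,
      target_px = sp$target_px, pixel_count = realized,
      x = mean(xx), y = mean(yy))
  }
  list(mask = label_mask(mask, mpp = mpp), truth = do.call(rbind, rows))
}

# ---- tumors ----------------------------------------------------------------

largest_remainder <- function(x, total = round(sum(x))) {
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Tumor specification
#'
#' @param proportions named target proportions over the six patterns
#'   (non-negative, sum to 1; missing patterns are 0).
#' @param n_slides number of slides for the tumor.
#' @param slide_px total tumor pixels pooled across slides.
#' @param seed integer seed controlling the per-slide allocation.
#' @return A list of class `tumor_spec`.
#' @export
tumor_spec <- function(proportions, n_slides = 3L, slide_px = 60000L,
                       seed = 1L) {
  full <- setNames(numeric(6), pattern_names())
  full[names(proportions)] <- proportions
  if (any(full < 0) || abs(sum(full) - 1) > 1e-8)
    stop("proportions must be non-negative and sum to 1")
  structure(list(proportions = full, n_slides = as.integer(n_slides),
                 total_px = as.integer(slide_px), seed = as.integer(seed)),
            class = "tumor_spec")
}

#' Generate multi-slide tumor masks with a prescribed composition
#'
#' Builds `n_slides` label masks whose POOLED pixel composition matches the
#' target proportions to within 1/total_px (integer allotment by largest
#' remainder), while per-slide compositions deliberately differ - so pooling
#' counts versus averaging per-slide proportions is discriminated.
#'
#' @param spec a [tumor_spec()].
#' @return List of [label_mask()]s at 7.2 um/px.
#' @export
generate_tumor_masks <- function(spec) {
  stopifnot(inherits(spec, "tumor_spec"))
  with_seed(spec$seed, {
    ct <- largest_remainder(spec$proportions * spec$total_px, spec$total_px)
    A <- matrix(0L, spec$n_slides, 6)
    for (j in 1:6) {
      if (ct[j] == 0L) next
      w <- stats::runif(spec$n_slides, 0.2, 1)
      A[, j] <- largest_remainder(ct[j] * w / sum(w), ct[j])
    }
    lapply(seq_len(spec$n_slides), function(i) {
      npx <- sum(A[i, ])
      side <- ceiling(sqrt(max(npx, 1L) / 0.7))
      m <- matrix(0L, side, side)
      lab_seq <- rep.int(1:6, A[i, ])
      if (length(lab_seq))
        m[seq_along(lab_seq)] <- lab_seq
      label_mask(m, mpp = 7.2)
    })
  })
}

#' Render a synthetic slide from a label mask
#'
#' Upsamples an analysis-resolution label mask to x20 by pixel replication
#' and renders each class region with its caricature texture (class 0 as
#' non-tumor stroma), producing a slide image the whole-slide pipeline can
#' consume, together with the x20 ground-truth mask.
#'
#' @param mask a [label_mask()] at analysis resolution.
#' @param factor upsampling factor (default 16: x1.25 to x20).
#' @param seed integer seed for the textures.
#' @return List with `slide` (an [image_patch()] at `mpp(mask)/factor`),
#'   `mask20` (the x20 ground truth) and `mask` (the input).
#' @export
generate_slide <- function(mask, factor = 16L, seed = 1L) {
  m <- mpp(mask)
  big <- unclass(mask)[rep(seq_len(nrow(mask)), each = factor),
                       rep(seq_len(ncol(mask)), each = factor)]
  H <- nrow(big); W <- ncol(big)
  with_seed(seed, {
    ch <- render_background(H, W)
    for (k in sort(unique(as.vector(big)))) {
      if (k == 0L) next
      tex <- render_texture(pattern_names()[k], H, W)
      sel <- big == k
      for (c in 1:3) ch[[c]][sel] <- tex[[c]][sel]
    }
    img <- array(0, c(H, W, 3))
    for (c in 1:3)
      img[, , c] <- pmin(pmax(ch[[c]] +
        matrix(stats::rnorm(H * W, 0, 4), H, W), 0), 255)
    list(slide = image_patch(img, mpp = m / factor),
         mask20 = label_mask(big, mpp = m / factor),
         mask = mask)
  })
}
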