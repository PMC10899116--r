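# Training: augmentation, pixel-wise cross-entropy, Adam with the three-phase
# step-wise learning rate, and gradient accumulation over mini-batches.

#' Training schedule
#'
#' The reference schedule is 60 epochs at batch size 8 with pixel-wise
#' cross-entropy minimized by Adam under a three-phase step-wise learning
#' rate: 1e-3 for epochs 1-10, 1e-4 for 11-50, 1e-5 for 51-60. Scaled-down
#' runs (fewer epochs) keep the same phase proportions.
#'
#' @param epochs number of epochs (60 for the full schedule).
#' @param batch_size gradient-accumulation batch size (8 in the full
#'   schedule).
#' @param lr the three phase learning rates, non-increasing.
#' @param seed integer seed controlling shuffling and augmentation draws.
#' @return An object of class `train_schedule`.
#' @export
train_schedule <- function(epochs = 60L, batch_size = 8L,
                           lr = c(1e-3, 1e-4, 1e-5), seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, length(lr) == 3L)
  if (any(diff(lr) > 0)) stop("learning rate phases must be non-increasing")
  ends <- if (epochs == 60L) c(10L, 50L)
          else pmax(1L, as.integer(round(epochs * c(10, 50) / 60)))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, phase_ends = ends, seed = as.integer(seed)),
            class = "train_schedule")
}

#' @rdname train_schedule
#' @param schedule a `train_schedule`.
#' @param epoch epoch number (1-based).
#' @export
lr_at_epoch <- function(schedule, epoch) {
  ifelse(epoch <= schedule$phase_ends[1], schedule$lr[1],
         ifelse(epoch <= schedule$phase_ends[2], schedule$lr[2],
                schedule$lr[3]))
}

#' Augmentation policy
#'
#' One jointly sampled geometric transform (rotation, shift, zoom) is applied
#' identically to image and mask; saturation/hue jitter applies to the image
#' only. Rotation fill is reflected for images and class 0 for masks.
#'
#' @param max_rotation_deg rotation sampled uniformly in `+/-` this angle.
#' @param max_shift_frac shift sampled uniformly up to this fraction of the
#'   patch size, per axis.
#' @param zoom_range,saturation_range,hue_range uniform sampling ranges.
#' @param color_aug_enabled disable for within-cohort cross-validation runs.
#' @return An object of class `augment_policy`.
#' @export
augment_policy <- function(max_rotation_deg = 90, max_shift_frac = 0.2,
                           zoom_range = c(0.8, 1.2),
                           saturation_range = c(0.8, 2.0),
                           hue_range = c(-0.1, 0.1),
                           color_aug_enabled = TRUE) {
  structure(list(max_rotation_deg = max_rotation_deg,
                 max_shift_frac = max_shift_frac,
                 zoom_range = zoom_range,
                 saturation_range = saturation_range,
                 hue_range = hue_range,
                 color_aug_enabled = isTRUE(color_aug_enabled)),
            class = "augment_policy")
}

# identity policy helper (all ranges collapsed)
identity_policy <- function() {
  augment_policy(max_rotation_deg = 0, max_shift_frac = 0,
                 zoom_range = c(1, 1), saturation_range = c(1, 1),
                 hue_range = c(0, 0), color_aug_enabled = FALSE)
}

reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  j <- ifelse(j < 0, j + p, j)
  j <- pmin(j, p - j)
  j + 1L
}

# joint affine warp: out = zoom * R(theta) (src - c) + c + shift, inverted for
# sampling; bilinear + reflect for the image, nearest + class-0 fill for mask
warp_pair <- function(img, mask, theta_deg, shift, zoom) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  th <- theta_deg * pi / 180
  gy <- matrix(seq_len(H), H, W) - cy - shift[1]
  gx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx - shift[2]
  sy <- (cos(th) * gy + sin(th) * gx) / zoom + cy
  sx <- (-sin(th) * gy + cos(th) * gx) / zoom + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  ry0 <- reflect_index(y0, H); ry1 <- reflect_index(y0 + 1, H)
  rx0 <- reflect_index(x0, W); rx1 <- reflect_index(x0 + 1, W)
  out <- img
  for (c in seq_len(d[3])) {
    ch <- img[, , c]
    out[, , c] <- ch[cbind(c(ry0), c(rx0))] * (1 - fy) * (1 - fx) +
      ch[cbind(c(ry1), c(rx0))] * fy * (1 - fx) +
      ch[cbind(c(ry0), c(rx1))] * (1 - fy) * fx +
      ch[cbind(c(ry1), c(rx1))] * fy * fx
  }
  rn <- round(sy); cn <- round(sx)
  inside <- rn >= 1 & rn <= H & cn >= 1 & cn <= W
  mwarp <- matrix(0L, H, W)
  mwarp[inside] <- mask[cbind(rn[inside], cn[inside])]
  list(img = out, mask = mwarp)
}

hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

color_jitter <- function(img, sat_factor, hue_shift) {
  d <- dim(img)
  M <- pmin(pmax(matrix(img, ncol = 3L), 0), 255)
  hsv <- grDevices::rgb2hsv(t(M), maxColorValue = 255)
  h <- (hsv[1, ] + hue_shift) %% 1
  s <- pmin(pmax(hsv[2, ] * sat_factor, 0), 1)
  rgb <- hsv_to_rgb(h, s, hsv[3, ]) * 255
  array(rgb, d)
}

#' Jointly augment an image patch and its mask
#'
#' Samples one geometric transform (rotation, shift, zoom) applied
#' identically to both, plus optional saturation/hue jitter applied to the
#' image only. With all ranges collapsed to the identity the pair is
#' returned bit-identical. Deterministic for a fixed `seed`.
#'
#' @param patch `image_patch` or `H x W x 3` array (values 0-255).
#' @param mask `label_mask` or integer matrix aligned with `patch`.
#' @param policy an [augment_policy()].
#' @param seed optional integer; when given, draws come from a local RNG and
#'   the caller's RNG state is untouched.
#' @return List with augmented `patch` and `mask` (sizes unchanged).
#' @export
augment_pair <- function(patch, mask, policy = augment_policy(), seed = NULL) {
  img <- unclass(patch)
  msk <- unclass(mask)
  stopifnot(identical(dim(img)[1:2], dim(msk)))
  do_draw <- function() {
    theta <- stats::runif(1, -policy$max_rotation_deg, policy$max_rotation_deg)
    shift <- stats::runif(2, -policy$max_shift_frac, policy$max_shift_frac) *
      dim(img)[1:2]
    zoom <- stats::runif(1, policy$zoom_range[1], policy$zoom_range[2])
    satf <- stats::runif(1, policy$saturation_range[1], policy$saturation_range[2])
    hue <- stats::runif(1, policy$hue_range[1], policy$hue_range[2])
    list(theta = theta, shift = shift, zoom = zoom, satf = satf, hue = hue)
  }
  dr <- with_seed(seed, do_draw())
  geom_identity <- dr$theta == 0 && all(dr$shift == 0) && dr$zoom == 1
  if (!geom_identity) {
    wp <- warp_pair(img, msk, dr$theta, dr$shift, dr$zoom)
    img <- wp$img
    msk <- wp$mask
  }
  if (policy$color_aug_enabled && !(dr$satf == 1 && dr$hue == 0))
    img <- pmin(pmax(color_jitter(img, dr$satf, dr$hue), 0), 255)
  mpp_i <- attr(patch, "mpp") %||% 0.45
  mpp_m <- attr(mask, "mpp") %||% mpp_i
  list(patch = image_patch(img, mpp = mpp_i),
       mask = label_mask(msk, mpp = mpp_m))
}

# ---- loss and optimizer ----------------------------------------------------

ce_loss_grad <- function(probs, labels, weights = NULL,
                         n_classes = N_CLASSES) {
  d <- dim(probs)
  npx <- d[1] * d[2]
  M <- matrix(probs, npx, d[3])
  idx <- cbind(seq_len(npx), as.integer(labels) + 1L)
  w <- if (is.null(weights)) rep(1, npx) else weights[idx[, 2]]
  wsum <- sum(w)
  loss <- -sum(w * log(pmax(M[idx], 1e-12))) / wsum
  dM <- M
  dM[idx] <- dM[idx] - 1
  dM <- dM * (w / wsum)
  list(loss = loss, dlogits = array(dM, d))
}

# inverse-sqrt-frequency class weights over a training set, clamped so no
# class dominates the objective
class_weights_for <- function(pairs, n_classes = N_CLASSES,
                              clamp = c(0.5, 4)) {
  cnt <- numeric(n_classes)
  for (p in pairs) {
    cc <- cpp_class_counts(unclass(p$mask), n_classes)
    cnt <- cnt + cc
  }
  w <- sqrt(sum(cnt) / (n_classes * pmax(cnt, 1)))
  w <- pmin(pmax(w, clamp[1]), clamp[2])
  w / mean(w)
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.numeric(b)) return(a + b)
  for (nm in names(b)) a[[nm]] <- grads_add(a[[nm]], b[[nm]])
  a
}

grads_scale <- function(g, s) {
  if (is.numeric(g)) return(g * s)
  for (nm in names(g)) g[[nm]] <- grads_scale(g[[nm]], s)
  g
}

adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v) {
    if (is.numeric(g)) {
      if (is.null(m)) { m <- g * 0; v <- g * 0 }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      return(list(p = p, m = m, v = v))
    }
    for (nm in names(g)) {
      r <- rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
      p[[nm]] <- r$p
      if (is.null(m)) m <- list()
      if (is.null(v)) v <- list()
      m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    list(p = p, m = m, v = v)
  }
  for (nm in names(grads)) {
    r <- rec(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    params[[nm]] <- r$p
    state$m[[nm]] <- r$m
    state$v[[nm]] <- r$v
  }
  params
}

#' Train a segmentation network
#'
#' Minimizes pixel-wise cross-entropy with Adam under the schedule's
#' three-phase step-wise learning rate, with gradient accumulation over
#' `batch_size` patches. Seeded and repeatable: a fixed schedule seed gives
#' identical shuffling, augmentation draws and loss trajectories.
#'
#' @param network a built `gpseg_network`.
#' @param pairs non-empty list of training pairs `list(patch, mask)` (see
#'   [generate_pattern_tile()] and [read_training_pairs()]).
#' @param schedule a [train_schedule()].
#' @param policy optional [augment_policy()]; `NULL` trains on the raw pairs.
#' @param class_weights optional length-7 vector of per-class loss weights
#'   (e.g. inverse-frequency weights for strongly imbalanced training sets);
#'   `NULL` weighs every pixel equally.
#' @param verbose print per-epoch loss.
#' @return List with the trained `network` and `history`, a tibble with one
#'   row per epoch (`epoch`, `loss`, `lr`).
#' @export
train_network <- function(network, pairs, schedule = train_schedule(),
                          policy = NULL, class_weights = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(network, "gpseg_network"),
            inherits(schedule, "train_schedule"))
  if (length(pairs) == 0L) stop("training requires at least one pair")
  set.seed(schedule$seed)
  state <- adam_state()
  hist <- vector("list", schedule$epochs)
  for (ep in seq_len(schedule$epochs)) {
    lr <- lr_at_epoch(schedule, ep)
    ord <- sample(length(pairs))
    losses <- numeric(0)
    for (start in seq(1L, length(ord), by = schedule$batch_size)) {
      take <- ord[start:min(start + schedule$batch_size - 1L, length(ord))]
      acc <- NULL
      for (i in take) {
        pr <- pairs[[i]]
        if (!is.null(policy)) pr <- augment_pair(pr$patch, pr$mask, policy)
        fw <- forward_network(network, unclass(pr$patch), want_cache = TRUE)
        lg <- ce_loss_grad(fw$probs, unclass(pr$mask), class_weights)
        losses <- c(losses, lg$loss)
        g <- backward_network(network, fw$cache, lg$dlogits)
        acc <- grads_add(acc, g)
      }
      acc <- grads_scale(acc, 1 / length(take))
      network$params <- adam_step(network$params, acc, state, lr)
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses), lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  lr %.0e", ep, mean(losses), lr))
  }
  list(network = network, history = do.call(rbind, hist))
}
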