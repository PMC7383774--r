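#' Standardise a frame to network input geometry
#'
#' Resamples the longer side to `target` pixels (aspect ratio preserved,
#' bilinear), zero-pads the shorter side symmetrically to a `target x target`
#' square, and min-max rescales intensities to `[0, 1]` per frame. A
#' constant-intensity frame maps to all zeros rather than raising an error.
#'
#' @param frame Numeric matrix (grayscale image).
#' @param target Output size in px.
#' @return A `target x target` numeric matrix in `[0, 1]`.
#' @export
standardize <- function(frame, target = 256L) {
  d <- dim(frame)
  if (is.null(d) || any(d == 0L)) abort("frame must be a nonempty matrix")
  geo <- standardize_geometry(d, target)
  rs <- geo$resized
  res <- if (all(rs == d)) frame else
    as.array(EBImage::resize(frame, w = rs[1L], h = rs[2L],
                             filter = "bilinear"))
  out <- matrix(0, target, target)
  out[geo$pad[1L] + seq_len(rs[1L]), geo$pad[2L] + seq_len(rs[2L])] <- res
  rng <- range(out)
  if (rng[2L] > rng[1L]) (out - rng[1L]) / (rng[2L] - rng[1L]) else out * 0
}

#' Standardise a label map with nearest-neighbour resampling
#'
#' Applies the same geometric transform as [standardize()] but with
#' nearest-neighbour interpolation (labels stay integer) and no intensity
#' rescale.
#'
#' @param mask Integer matrix of class labels.
#' @param target Output size in px.
#' @return A `target x target` integer matrix.
#' @export
standardize_labels <- function(mask, target = 256L) {
  d <- dim(mask)
  geo <- standardize_geometry(d, target)
  rs <- geo$resized
  res <- if (all(rs == d)) mask else
    as.array(EBImage::resize(mask, w = rs[1L], h = rs[2L], filter = "none"))
  out <- matrix(0L, target, target)
  out[geo$pad[1L] + seq_len(rs[1L]), geo$pad[2L] + seq_len(rs[2L])] <-
    as.integer(round(res))
  out
}

#' Augmentation configuration
#'
#' Settings for training-time augmentation: random zoom, rotation, crop,
#' horizontal/vertical flip, and additive Gaussian noise (noise on the image
#' only). Ranges default to conventional "aggressive-but-in-frame" values.
#'
#' @param zoom_range Scale factor range.
#' @param rotation_range Maximum absolute rotation in degrees.
#' @param crop_size Output crop in px; must not exceed `pad_size`.
#' @param pad_size Size of the standardized input the augmenter expects.
#' @param hflip_prob,vflip_prob Flip probabilities.
#' @param gaussian_noise_sigma Noise standard deviation in intensity units.
#' @param crop `"random"` or `"center"`.
#' @param max_attempts Re-draws allowed when a transform pushes all annular
#'   pixels out of the crop.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(zoom_range = c(0.9, 1.1), rotation_range = 15,
                                crop_size = 224L, pad_size = 256L,
                                hflip_prob = 0.5, vflip_prob = 0.5,
                                gaussian_noise_sigma = 0.01,
                                crop = c("random", "center"),
                                max_attempts = 5L) {
  crop <- match.arg(crop)
  if (crop_size > pad_size) abort("crop_size must not exceed pad_size")
  probs <- c(hflip_prob, vflip_prob)
  if (any(probs < 0 | probs > 1)) abort("flip probabilities must be in [0, 1]")
  structure(list(zoom_range = zoom_range, rotation_range = rotation_range,
                 crop_size = as.integer(crop_size),
                 pad_size = as.integer(pad_size),
                 hflip_prob = hflip_prob, vflip_prob = vflip_prob,
                 gaussian_noise_sigma = gaussian_noise_sigma, crop = crop,
                 max_attempts = as.integer(max_attempts)),
            class = "augmentation_config")
}

resize_to_canvas <- function(img, z, size, filter) {
  rs <- max(1L, round(size * z))
  res <- if (rs == size) img else
    as.array(EBImage::resize(img, w = rs, h = rs, filter = filter))
  if (rs == size) return(res)
  out <- matrix(0, size, size)
  if (rs > size) {
    off <- floor((rs - size) / 2)
    out[] <- res[off + seq_len(size), off + seq_len(size)]
  } else {
    off <- floor((size - rs) / 2)
    out[off + seq_len(rs), off + seq_len(rs)] <- res
  }
  out
}

apply_geom <- function(img, draw, cfg, filter) {
  out <- resize_to_canvas(img, draw$zoom, cfg$pad_size, filter)
  if (draw$angle != 0) {
    out <- as.array(EBImage::rotate(out, draw$angle,
                                    output.dim = c(cfg$pad_size, cfg$pad_size),
                                    filter = filter, bg.col = 0))
  }
  if (draw$hflip) out <- out[, rev(seq_len(ncol(out)))]
  if (draw$vflip) out <- out[rev(seq_len(nrow(out))), ]
  out[draw$r0 + seq_len(cfg$crop_size), draw$c0 + seq_len(cfg$crop_size)]
}

#' Apply a random augmentation to an image/mask pair
#'
#' Draws one geometric transform (zoom, rotation, flips, crop) and applies it
#' identically to the image (bilinear) and the mask (nearest neighbour, so
#' labels stay integer); Gaussian noise is added to the image only. If the
#' transform removes every annular pixel from the crop, the draw is repeated
#' up to `max_attempts` times; a still-degenerate result carries attribute
#' `degenerate = TRUE` so a trainer can skip it.
#'
#' @param frame Numeric matrix of size `pad_size x pad_size`.
#' @param mask Integer matrix of the same size.
#' @param config An [augmentation_config()].
#' @param seed Optional seed; otherwise the current RNG stream is used.
#' @return A list with `frame` and `mask`, both `crop_size x crop_size`.
#' @export
augment <- function(frame, mask, config = augmentation_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!identical(dim(frame), dim(mask))) {
    abort("frame and mask must have the same shape")
  }
  had_annulus <- any(mask > 0L)
  span <- config$pad_size - config$crop_size
  for (attempt in seq_len(max(1L, config$max_attempts))) {
    draw <- list(
      zoom = runif(1L, config$zoom_range[1L], config$zoom_range[2L]),
      angle = if (config$rotation_range > 0)
        runif(1L, -config$rotation_range, config$rotation_range) else 0,
      hflip = runif(1L) < config$hflip_prob,
      vflip = runif(1L) < config$vflip_prob,
      r0 = if (config$crop == "random" && span > 0L)
        sample.int(span + 1L, 1L) - 1L else floor(span / 2),
      c0 = if (config$crop == "random" && span > 0L)
        sample.int(span + 1L, 1L) - 1L else floor(span / 2)
    )
    fr <- apply_geom(frame, draw, config, "bilinear")
    mk <- apply_geom(mask, draw, config, "none")
    storage.mode(mk) <- "integer"
    if (config$gaussian_noise_sigma > 0) {
      fr <- fr + rnorm(length(fr), sd = config$gaussian_noise_sigma)
      dim(fr) <- c(config$crop_size, config$crop_size)
    }
    if (!had_annulus || any(mk > 0L)) {
      return(list(frame = fr, mask = mk))
    }
  }
  out <- list(frame = fr, mask = mk)
  attr(out, "degenerate") <- TRUE
  out
}

augment_pair <- function(frame, mask, config) augment(frame, mask, config)
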