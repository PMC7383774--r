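#' @keywords internal
rmsprop_init <- function(params) {
  rapply(params, function(p) array(0, dim(p) %||% length(p)), how = "replace")
}

# elementwise RMSProp update on the nested parameter list
rmsprop_step <- function(params, grads, state, lr, alpha, eps) {
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      v <- alpha * state[[nm]][[pn]] + (1 - alpha) * g * g
      state[[nm]][[pn]] <- v
      params[[nm]][[pn]] <- params[[nm]][[pn]] - lr * g / (sqrt(v) + eps)
    }
  }
  list(params = params, state = state)
}

#' Run one training epoch
#'
#' Performs one pass over the supplied batches: forward pass, class-weighted
#' softmax cross-entropy, backpropagation, and an RMSProp parameter update per
#' batch. With a fixed batch order and RNG state the result is fully
#' deterministic.
#'
#' @param net An [build_network()] network.
#' @param batches List of batches, each a list with `x` (array
#'   `H x W x 1 x n`) and `y` (integer array `H x W x n`, labels 0..C-1).
#' @param weights A [loss_config()].
#' @param opt RMSProp accumulator state from a previous call, or `NULL` to
#'   start fresh.
#' @param lr Learning rate.
#' @param alpha RMSProp smoothing coefficient for the squared-gradient
#'   average.
#' @param eps Numerical stabiliser added to the RMS denominator.
#' @return A list with the updated `net`, optimiser state `opt`, and the
#'   `mean_loss` over batches.
#' @export
train_epoch <- function(net, batches, weights = loss_config(), opt = NULL,
                        lr = 1e-3, alpha = 0.99, eps = 1e-8) {
  if (is.null(opt)) opt <- rmsprop_init(net$params)
  losses <- numeric(length(batches))
  for (i in seq_along(batches)) {
    b <- batches[[i]]
    fw <- net_forward(net, b$x, train = TRUE)
    net <- fw$net
    lg <- weighted_ce_loss(fw$logits, b$y, weights, grad = TRUE)
    if (!is.finite(lg$loss)) {
      abort(paste0("non-finite training loss at batch ", i,
                   "; reduce the learning rate or check the input scaling"))
    }
    losses[i] <- lg$loss
    grads <- net_backward(net, fw$cache, lg$dlogits)
    up <- rmsprop_step(net$params, grads, opt, lr, alpha, eps)
    net$params <- up$params
    opt <- up$state
  }
  list(net = net, opt = opt, mean_loss = mean(losses))
}

# Geometry of the standardisation transform for a frame of size `d` resized
# to fit a `target` square: scale then symmetric zero-padding.
standardize_geometry <- function(d, target) {
  scale <- target / max(d)
  rs <- round(d * scale)
  list(scale = scale, resized = rs,
       pad = floor((c(target, target) - rs) / 2))
}

prepare_pair <- function(frame, mask, size) {
  list(x = standardize(frame, size),
       y = standardize_labels(mask, size))
}

#' Train the annulus segmenter on a set of cases
#'
#' Assembles per-frame training pairs from a list of cases (each a list with a
#' `cine` [cine_sequence] and `masks` [label_map_sequence], as produced by
#' [generate_case()]), standardises them to the network input size, optionally
#' augments, and runs RMSProp training for the requested number of epochs.
#'
#' @param cases List of cases with `cine` and `masks` entries.
#' @param net_config A [network_config()].
#' @param weights A [loss_config()].
#' @param epochs Number of epochs.
#' @param frames_per_case Frames sampled per case per epoch (`Inf` = all).
#' @param batch_size Frames per batch.
#' @param augment An [augmentation_config()] applied per sampled frame, or
#'   `NULL` for none. Its `crop_size` must equal the network input size.
#' @param lr,alpha RMSProp settings (see [train_epoch()]).
#' @param seed Integer seed governing initialisation, frame sampling and
#'   augmentation.
#' @param verbose Print the per-epoch mean loss.
#' @return A list with the trained `net`, the optimiser state, and the vector
#'   of per-epoch mean losses (`loss_history`).
#' @export
train_segmenter <- function(cases, net_config = network_config(),
                            weights = loss_config(), epochs = 10L,
                            frames_per_case = 4L, batch_size = 8L,
                            augment = NULL, lr = 1e-3, alpha = 0.99,
                            seed = 1L, verbose = FALSE) {
  if (!is.null(augment) && augment$crop_size != net_config$input_size) {
    abort("augmentation crop_size must equal the network input_size")
  }
  set.seed(seed)
  net <- build_network(net_config)
  size <- net_config$input_size
  pre_size <- if (is.null(augment)) size else augment$pad_size
  # standardise every frame once
  std <- lapply(cases, function(cs) {
    fr <- cs$cine$frames
    mk <- label_array(cs$masks)
    nT <- dim(fr)[3L]
    list(x = lapply(seq_len(nT), function(t) standardize(fr[, , t], pre_size)),
         y = lapply(seq_len(nT), function(t)
           standardize_labels(mk[, , t], pre_size)))
  })
  opt <- NULL
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    pairs <- list()
    for (ci in seq_along(std)) {
      nT <- length(std[[ci]]$x)
      take <- if (is.finite(frames_per_case) && frames_per_case < nT) {
        sample.int(nT, frames_per_case)
      } else seq_len(nT)
      for (t in take) {
        x <- std[[ci]]$x[[t]]
        y <- std[[ci]]$y[[t]]
        if (!is.null(augment)) {
          ag <- augment_pair(x, y, augment)
          x <- ag$frame; y <- ag$mask
        }
        pairs[[length(pairs) + 1L]] <- list(x = x, y = y)
      }
    }
    ord <- sample.int(length(pairs))
    batches <- list()
    for (s in seq(1L, length(ord), by = batch_size)) {
      ids <- ord[s:min(s + batch_size - 1L, length(ord))]
      xb <- array(0, c(size, size, 1L, length(ids)))
      yb <- array(0L, c(size, size, length(ids)))
      for (j in seq_along(ids)) {
        xb[, , 1L, j] <- pairs[[ids[j]]]$x
        yb[, , j] <- pairs[[ids[j]]]$y
      }
      batches[[length(batches) + 1L]] <- list(x = xb, y = yb)
    }
    res <- train_epoch(net, batches, weights, opt, lr = lr, alpha = alpha)
    net <- res$net
    opt <- res$opt
    history[ep] <- res$mean_loss
    if (verbose) message(sprintf("epoch %d/%d: loss %.5f", ep, epochs,
                                 res$mean_loss))
  }
  list(net = net, opt = opt, loss_history = history)
}

#' Segment every frame of a cine sequence
#'
#' Standardises each frame to the network input size, runs a deterministic
#' single forward pass (no test-time augmentation), and returns the argmax
#' label maps together with the geometric transform needed to map positions
#' back to the original frame coordinates.
#'
#' @param net A trained `rvtrack_net`.
#' @param cine A [cine_sequence].
#' @param batch_size Frames per forward batch.
#' @return A [label_map_sequence] in standardized geometry, with attribute
#'   `transform` (list with `scale` and `pad`) mapping standardized
#'   coordinates back to the original frame: `orig = (std - pad) / scale`.
#' @export
predict_labels <- function(net, cine, batch_size = 8L) {
  fr <- cine$frames
  d <- dim(fr)
  size <- net$config$input_size
  geo <- standardize_geometry(d[1:2], size)
  n <- d[3L]
  labs <- array(0L, c(size, size, n))
  for (s in seq(1L, n, by = batch_size)) {
    ids <- s:min(s + batch_size - 1L, n)
    xb <- array(0, c(size, size, 1L, length(ids)))
    for (j in seq_along(ids)) xb[, , 1L, j] <- standardize(fr[, , ids[j]], size)
    fw <- net_forward(net, xb, train = FALSE)
    labs[, , ids] <- logits_to_labels(fw$logits)
  }
  out <- label_map_sequence(labs, pixel_spacing = cine$pixel_spacing)
  attr(out, "transform") <- list(scale = geo$scale, pad = geo$pad)
  out
}
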