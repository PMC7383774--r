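#' Network architecture configuration
#'
#' Describes the residual U-net used to segment the tricuspid annulus: a
#' contracting/expanding fully convolutional network in which every
#' convolutional block is wrapped as a residual module (identity shortcut, or a
#' 1x1 projection where the channel count changes), with skip connections
#' concatenating encoder features into the decoder and learned
#' transposed-convolution upsampling.
#'
#' @param n_classes Number of output classes `C`. Default 3: background (0),
#'   lateral annulus (1), septal annulus (2).
#' @param depth Number of resolution levels. The input size must be divisible
#'   by `2^(depth - 1)`.
#' @param base_channels Channel count at the first level; doubled at each
#'   deeper level.
#' @param input_size Spatial input size in pixels (square).
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_classes = 3L, depth = 5L, base_channels = 32L,
                           input_size = 224L) {
  n_classes <- as.integer(n_classes)
  depth <- as.integer(depth)
  base_channels <- as.integer(base_channels)
  input_size <- as.integer(input_size)
  if (n_classes < 2L) abort("n_classes must be at least 2")
  if (depth < 1L) abort("depth must be at least 1")
  if (input_size %% (2L^(depth - 1L)) != 0L) {
    abort(sprintf("input_size %d is not divisible by 2^(depth-1) = %d",
                  input_size, 2L^(depth - 1L)))
  }
  structure(list(n_classes = n_classes, depth = depth,
                 base_channels = base_channels, input_size = input_size),
            class = "network_config")
}

#' Loss configuration: per-class weights
#'
#' Class weights for the weighted softmax cross-entropy loss. The default
#' weights down-weight the overwhelmingly prevalent non-annular background
#' class (0.2) relative to the annular classes (0.8 each).
#'
#' @param class_weights Nonnegative numeric vector, one weight per class.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(class_weights = c(0.2, 0.8, 0.8)) {
  if (any(class_weights < 0) || !any(class_weights > 0)) {
    abort("class weights must be nonnegative with at least one positive entry")
  }
  structure(list(class_weights = as.numeric(class_weights)),
            class = "loss_config")
}

he_init <- function(fan_in, n) rnorm(n, sd = sqrt(2 / fan_in))

# channel plan helpers
level_channels <- function(cfg, l) cfg$base_channels * 2L^(l - 1L)

new_resblock_params <- function(cin, cout) {
  p <- list(
    W1 = matrix(he_init(9 * cin, 9 * cin * cout), 9 * cin, cout),
    b1 = numeric(cout),
    g1 = rep(1, cout), be1 = numeric(cout),
    W2 = matrix(he_init(9 * cout, 9 * cout * cout), 9 * cout, cout),
    b2 = numeric(cout),
    g2 = rep(1, cout), be2 = numeric(cout)
  )
  if (cin != cout) {
    p$Wp <- matrix(he_init(cin, cin * cout), cin, cout)
    p$bp <- numeric(cout)
  }
  p
}

new_bn_state <- function(cout) list(mean = numeric(cout), var = rep(1, cout))

#' Build a residual U-net segmentation network
#'
#' Constructs the network with freshly initialised parameters (He
#' initialisation for convolutions, unit-gamma/zero-beta batch
#' normalisation). The network maps a `1 x H x W` grayscale image to a
#' `C x H x W` map of per-pixel class logits.
#'
#' @param config A [network_config()].
#' @param seed Optional integer seed for reproducible initialisation.
#' @return An object of class `rvtrack_net`.
#' @export
build_network <- function(config = network_config(), seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  if (!is.null(seed)) set.seed(seed)
  d <- config$depth
  params <- list()
  bn <- list()
  for (l in seq_len(d)) {
    cin <- if (l == 1L) 1L else level_channels(config, l - 1L)
    cout <- level_channels(config, l)
    params[[paste0("enc", l)]] <- new_resblock_params(cin, cout)
    bn[[paste0("enc", l)]] <- list(bn1 = new_bn_state(cout),
                                   bn2 = new_bn_state(cout))
  }
  if (d > 1L) {
    for (l in seq(d - 1L, 1L)) {
      cin <- level_channels(config, l + 1L)
      cout <- level_channels(config, l)
      params[[paste0("up", l)]] <- list(
        W = matrix(he_init(4 * cin, 4 * cin * cout), 4 * cin, cout),
        b = numeric(cout),
        g = rep(1, cout), be = numeric(cout)
      )
      bn[[paste0("up", l)]] <- list(bn = new_bn_state(cout))
      params[[paste0("dec", l)]] <- new_resblock_params(2L * cout, cout)
      bn[[paste0("dec", l)]] <- list(bn1 = new_bn_state(cout),
                                     bn2 = new_bn_state(cout))
    }
  }
  cfin <- level_channels(config, 1L)
  params$final <- list(W = matrix(he_init(cfin, cfin * config$n_classes),
                                  cfin, config$n_classes),
                       b = numeric(config$n_classes))
  structure(list(config = config, params = params, bn = bn),
            class = "rvtrack_net")
}

#' @export
print.rvtrack_net <- function(x, ...) {
  cfg <- x$config
  npar <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, 0))
  cat(sprintf(
    "<rvtrack_net> residual U-net: depth %d, base %d channels, %d classes, input %dx%d, %s parameters\n",
    cfg$depth, cfg$base_channels, cfg$n_classes, cfg$input_size,
    cfg$input_size, format(npar, big.mark = ",")))
  invisible(x)
}

# ---- batch norm ------------------------------------------------------------

bn_forward <- function(x, gamma, beta, state, train, momentum = 0.1,
                       eps = 1e-5) {
  if (train) {
    st <- .channel_stats(x)
    mu <- st$mean
    v <- st$var
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  y <- .bn_apply(x, gamma, beta, mu, inv)
  list(y = y, cache = list(x = x, mu = mu, inv = inv, gamma = gamma),
       state = state)
}

bn_backward <- function(dy, cache) {
  g <- .bn_bw(cache$x, dy, cache$gamma, cache$mu, cache$inv)
  list(dx = g$dx, dgamma = g$dgamma, dbeta = g$dbeta)
}

relu <- function(x) .relu_fw(x)

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  y[, , seq_len(da[3L]), ] <- a
  y[, , da[3L] + seq_len(db[3L]), ] <- b
  y
}

# ---- residual block --------------------------------------------------------

resblock_forward <- function(p, bnst, x, train) {
  c1 <- .conv2d_fw(x, p$W1, p$b1, 3L, 1L)
  b1 <- bn_forward(c1, p$g1, p$be1, bnst$bn1, train)
  r1 <- relu(b1$y)
  c2 <- .conv2d_fw(r1, p$W2, p$b2, 3L, 1L)
  b2 <- bn_forward(c2, p$g2, p$be2, bnst$bn2, train)
  sc <- if (is.null(p$Wp)) x else .conv2d_fw(x, p$Wp, p$bp, 1L, 0L)
  s <- b2$y + sc
  y <- relu(s)
  list(y = y,
       cache = list(x = x, b1 = b1$cache, r1 = r1, b2 = b2$cache,
                    pre1 = b1$y, pre_out = s),
       bnst = list(bn1 = b1$state, bn2 = b2$state))
}

resblock_backward <- function(p, cache, dy) {
  ds <- .relu_bw(dy, cache$pre_out)
  # shortcut branch
  if (is.null(p$Wp)) {
    dx_sc <- ds
    dWp <- NULL; dbp <- NULL
  } else {
    g <- .conv2d_bw(cache$x, p$Wp, ds, 1L, 0L)
    dx_sc <- g$dx; dWp <- g$dw; dbp <- g$db
  }
  # main branch
  bb2 <- bn_backward(ds, cache$b2)
  g2 <- .conv2d_bw(cache$r1, p$W2, bb2$dx, 3L, 1L)
  dr1 <- .relu_bw(g2$dx, cache$pre1)
  bb1 <- bn_backward(dr1, cache$b1)
  g1 <- .conv2d_bw(cache$x, p$W1, bb1$dx, 3L, 1L)
  grads <- list(W1 = g1$dw, b1 = g1$db, g1 = bb1$dgamma, be1 = bb1$dbeta,
                W2 = g2$dw, b2 = g2$db, g2 = bb2$dgamma, be2 = bb2$dbeta)
  if (!is.null(dWp)) {
    grads$Wp <- dWp
    grads$bp <- dbp
  }
  list(dx = g1$dx + dx_sc, grads = grads)
}

# ---- full network ----------------------------------------------------------

#' Forward pass of the segmentation network
#'
#' @param net An `rvtrack_net`.
#' @param x Input batch, array `H x W x 1 x N` with intensities in `[0, 1]`.
#' @param train Logical; batch statistics (and running-average updates) are
#'   used when `TRUE`, stored running statistics when `FALSE`.
#' @return A list with `logits` (array `H x W x C x N`), the updated `net`
#'   (running batch-norm statistics), and an opaque `cache` for
#'   [net_backward()].
#' @export
net_forward <- function(net, x, train = FALSE) {
  cfg <- net$config
  d <- cfg$depth
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x)[1:2], 1L, dim(x)[3L])
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L, 1L)
  cache <- list()
  skips <- list()
  h <- x
  for (l in seq_len(d)) {
    nm <- paste0("enc", l)
    rb <- resblock_forward(net$params[[nm]], net$bn[[nm]], h, train)
    net$bn[[nm]] <- rb$bnst
    cache[[nm]] <- rb$cache
    h <- rb$y
    if (l < d) {
      skips[[l]] <- h
      mp <- .maxpool2_fw(h)
      cache[[paste0("pool", l)]] <- list(idx = mp$idx, xdim = dim(h))
      h <- mp$y
    }
  }
  if (d > 1L) {
    for (l in seq(d - 1L, 1L)) {
      nm <- paste0("up", l)
      p <- net$params[[nm]]
      u <- .upconv2_fw(h, p$W, p$b)
      bu <- bn_forward(u, p$g, p$be, net$bn[[nm]]$bn, train)
      net$bn[[nm]]$bn <- bu$state
      ru <- relu(bu$y)
      cache[[nm]] <- list(x = h, b = bu$cache, pre = bu$y,
                          skip_dim = dim(skips[[l]]))
      h2 <- concat_channels(skips[[l]], ru)
      nm2 <- paste0("dec", l)
      rb <- resblock_forward(net$params[[nm2]], net$bn[[nm2]], h2, train)
      net$bn[[nm2]] <- rb$bnst
      cache[[nm2]] <- rb$cache
      h <- rb$y
    }
  }
  logits <- .conv2d_fw(h, net$params$final$W, net$params$final$b, 1L, 0L)
  cache$final_in <- h
  list(logits = logits, net = net, cache = cache)
}

#' Backward pass: parameter gradients from the logit gradient
#'
#' @param net An `rvtrack_net`.
#' @param cache The cache returned by [net_forward()] with `train = TRUE`.
#' @param dlogits Gradient of the scalar loss with respect to the logits.
#' @return A list of parameter gradients with the same nesting as
#'   `net$params`.
#' @export
net_backward <- function(net, cache, dlogits) {
  cfg <- net$config
  d <- cfg$depth
  grads <- list()
  gf <- .conv2d_bw(cache$final_in, net$params$final$W, dlogits, 1L, 0L)
  grads$final <- list(W = gf$dw, b = gf$db)
  dh <- gf$dx
  dskips <- list()
  if (d > 1L) {
    for (l in seq_len(d - 1L)) {
      nm2 <- paste0("dec", l)
      rb <- resblock_backward(net$params[[nm2]], cache[[nm2]], dh)
      grads[[nm2]] <- rb$grads
      nm <- paste0("up", l)
      uc <- cache[[nm]]
      nskip <- uc$skip_dim[3L]
      dskips[[l]] <- rb$dx[, , seq_len(nskip), , drop = FALSE]
      dru <- rb$dx[, , nskip + seq_len(dim(rb$dx)[3L] - nskip), ,
                   drop = FALSE]
      dbu <- .relu_bw(dru, uc$pre)
      bb <- bn_backward(dbu, uc$b)
      gu <- .upconv2_bw(uc$x, net$params[[nm]]$W, bb$dx)
      grads[[nm]] <- list(W = gu$dw, b = gu$db, g = bb$dgamma, be = bb$dbeta)
      dh <- gu$dx
    }
  }
  for (l in seq(d, 1L)) {
    nm <- paste0("enc", l)
    if (l < d) {
      pc <- cache[[paste0("pool", l)]]
      dh <- .maxpool2_bw(dh, pc$idx, as.integer(pc$xdim)) + dskips[[l]]
    }
    rb <- resblock_backward(net$params[[nm]], cache[[nm]], dh)
    grads[[nm]] <- rb$grads
    dh <- rb$dx
  }
  grads
}

# ---- weighted softmax cross-entropy ----------------------------------------

#' Class-weighted softmax cross-entropy loss
#'
#' Per-pixel loss `-W[i] * ln(softmax(x)[i])`, where `x` is the pixel's logit
#' vector, `i` its true class, and `W` the class-weight vector; the reported
#' loss is the unweighted mean of these per-pixel terms over all pixels in the
#' batch (so the numeric scale depends on the weight vector).
#'
#' @param logits Array `H x W x C x N` of per-pixel class logits (a `C`-vector
#'   or `C x n` matrix of single-pixel logit vectors is also accepted).
#' @param truth Integer array `H x W x N` of true class labels in
#'   `0..C-1` (0 = background/non-annular).
#' @param weights A [loss_config()] or a numeric weight vector of length `C`.
#' @param grad Logical; also return the gradient with respect to the logits.
#' @return The scalar loss, or (with `grad = TRUE`) a list with `loss` and
#'   `dlogits`.
#' @export
weighted_ce_loss <- function(logits, truth, weights = loss_config(),
                             grad = FALSE) {
  w <- if (inherits(weights, "loss_config")) weights$class_weights else
    as.numeric(weights)
  if (is.null(dim(logits))) dim(logits) <- c(1L, 1L, length(logits), 1L)
  if (length(dim(logits)) == 2L) {
    dim(logits) <- c(1L, 1L, dim(logits))
  }
  d <- dim(logits)
  C <- d[3L]
  if (length(w) != C) abort("weight vector length must equal the class count")
  lab <- as.integer(truth)
  if (length(lab) != d[1L] * d[2L] * d[4L]) {
    abort("truth labels do not match the logit geometry")
  }
  if (any(lab < 0L | lab >= C)) {
    abort(sprintf("truth labels must lie in 0..%d", C - 1L))
  }
  res <- .wce_loss(logits, lab, w, grad)
  if (!grad) return(res$loss)
  list(loss = res$loss, dlogits = res$dlogits)
}

#' Per-pixel class probabilities and hard labels from logits
#'
#' @param logits Array `H x W x C x N`.
#' @return Integer array `H x W x N` of argmax class labels (0-based).
#' @export
logits_to_labels <- function(logits) {
  d <- dim(logits)
  lm <- matrix(aperm(logits, c(3L, 1L, 2L, 4L)), nrow = d[3L])
  lab <- max.col(t(lm), ties.method = "first") - 1L
  array(as.integer(lab), c(d[1L], d[2L], d[4L]))
}
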