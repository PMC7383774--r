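test_that("network configuration validates divisibility and class count", {
  expect_s3_class(network_config(3, 5, 32, 224), "network_config")
  expect_error(network_config(3, 5, 32, 100), "divisible")
  expect_error(network_config(1, 3, 8, 64), "at least 2")
})

test_that("network output has the contracted shape and zero final layer gives uniform logits", {
  cfg <- tiny_net_config()
  net <- build_network(cfg, seed = 1)
  x <- array(runif(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  fw <- net_forward(net, x)
  expect_equal(dim(fw$logits), c(16L, 16L, 3L, 2L))

  net0 <- net
  net0$params$final$W[] <- 0
  net0$params$final$b[] <- 0
  lg <- net_forward(net0, x)$logits
  expect_equal(max(abs(lg)), 0)
  # uniform logits: softmax gives 1/C everywhere
  expect_equal(weighted_ce_loss(lg, array(1L, c(16, 16, 2)),
                                loss_config(c(0.2, 0.8, 0.8))),
               0.8 * log(3), tolerance = 1e-12)
})

test_that("doubling base channels grows conv parameters about fourfold", {
  count_w <- function(base) {
    net <- build_network(network_config(3, 2, base, 16), seed = 1)
    sum(vapply(net$params, function(m) {
      sum(vapply(m[grepl("^W", names(m))], length, 0))
    }, 0))
  }
  ratio <- count_w(16) / count_w(8)
  expect_gt(ratio, 3.4)
  expect_lt(ratio, 4.1)
})

test_that("weighted cross-entropy matches its closed form on 1-pixel cases", {
  # uniform logits, C = 2, true class annular, W = (0.2, 0.8)
  expect_equal(weighted_ce_loss(c(0, 0), 1L, c(0.2, 0.8)),
               0.8 * log(2), tolerance = 1e-9)
  expect_equal(0.8 * log(2), 0.5545, tolerance = 1e-4)

  # generic hand-computed case
  x <- c(1.5, -0.3, 0.7)
  w <- c(0.2, 0.8, 0.8)
  p <- exp(x) / sum(exp(x))
  for (cl in 0:2) {
    expect_equal(weighted_ce_loss(x, cl, w), -w[cl + 1] * log(p[cl + 1]),
                 tolerance = 1e-9)
  }

  # dominant true-class logit drives the loss to zero
  expect_lt(weighted_ce_loss(c(50, 0), 0L, c(0.2, 0.8)), 1e-12)
  # zero weight on the true class zeroes the loss
  expect_equal(weighted_ce_loss(c(3, -2), 0L, c(0, 1)), 0)

  expect_error(weighted_ce_loss(c(0, 0), 5L, c(0.5, 0.5)), "0..1")
  expect_error(loss_config(c(-1, 1)), "nonnegative")
})

test_that("softmax normalisation holds: per-pixel probabilities sum to one", {
  cfg <- tiny_net_config()
  net <- build_network(cfg, seed = 3)
  x <- array(runif(16 * 16 * 1 * 1), c(16, 16, 1, 1))
  lg <- net_forward(net, x)$logits
  # explicit per-pixel softmax
  p <- exp(lg)
  tot <- p[, , 1, 1] + p[, , 2, 1] + p[, , 3, 1]
  expect_equal(max(abs((p[, , 1, 1] + p[, , 2, 1] + p[, , 3, 1]) / tot - 1)),
               0, tolerance = 1e-12)
  # equivalently, with unit class weights the loss gradient sums to zero over
  # classes at every pixel (sum_c p_c = 1)
  y <- array(0L, c(16, 16, 1))
  g <- weighted_ce_loss(lg, y, c(1, 1, 1), grad = TRUE)$dlogits
  expect_equal(max(abs(g[, , 1, 1] + g[, , 2, 1] + g[, , 3, 1])), 0,
               tolerance = 1e-12)
})

test_that("backpropagation matches numerical gradients", {
  cfg <- network_config(3, 3, 4, 8)
  net <- build_network(cfg, seed = 42)
  set.seed(1)
  xb <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  yb <- array(sample(0:2, 128, TRUE), c(8, 8, 2))
  lw <- loss_config()
  fw <- net_forward(net, xb, train = TRUE)
  lg <- weighted_ce_loss(fw$logits, yb, lw, grad = TRUE)
  gr <- net_backward(net, fw$cache, lg$dlogits)
  f <- function(n2) {
    weighted_ce_loss(net_forward(n2, xb, train = TRUE)$logits, yb, lw)
  }
  eps <- 1e-6
  for (nm in names(gr)) {
    for (pn in names(gr[[nm]])) {
      p <- net$params[[nm]][[pn]]
      for (i in unique(c(1L, length(p) %/% 2L + 1L))) {
        n2 <- net
        n2$params[[nm]][[pn]][i] <- p[i] + eps
        lp <- f(n2)
        n2$params[[nm]][[pn]][i] <- p[i] - eps
        lm <- f(n2)
        expect_equal(gr[[nm]][[pn]][i], (lp - lm) / (2 * eps),
                     tolerance = 1e-4)
      }
    }
  }
})

test_that("training reduces the loss below the uniform baseline and is seeded", {
  cs <- generate_case(tiny_phantom_config(seed = 2))
  cfg <- network_config(3, 3, 4, 32)
  run <- function(lr) {
    train_segmenter(list(cs), net_config = cfg, epochs = 8,
                    frames_per_case = 2, batch_size = 2, lr = lr, seed = 6)
  }
  fit <- run(2e-3)
  # weighted uniform-logit baseline: mean over pixels of W[i] * ln 3; the
  # background class dominates, so the bound is conservative
  uniform_upper <- 0.8 * log(3)
  expect_lt(tail(fit$loss_history, 1), min(fit$loss_history[1], uniform_upper))

  fit2 <- run(2e-3)
  expect_identical(fit$loss_history, fit2$loss_history)
  expect_identical(fit$net$params, fit2$net$params)

  # zero learning rate leaves parameters at initialisation
  fit0 <- run(0)
  net_init <- build_network(cfg, seed = 6)
  expect_equal(fit0$net$params$final$W, net_init$params$final$W)
})

test_that("non-finite loss aborts with learning-rate guidance", {
  cfg <- tiny_net_config()
  net <- build_network(cfg, seed = 1)
  net$params$final$W[] <- NaN
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  y <- array(0L, c(16, 16, 1))
  expect_error(train_epoch(net, list(list(x = x, y = y))),
               "learning rate|non-finite")
})
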