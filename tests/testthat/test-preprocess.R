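test_that("standardize pads, resamples and rescales as specified", {
  # 256x200 -> 28-px zero bands on each side of the short axis
  f <- matrix(runif(256 * 200, 0.2, 1), 256, 200)
  out <- standardize(f, 256L)
  expect_equal(dim(out), c(256L, 256L))
  expect_true(all(out[, 1:28] == 0))
  expect_true(all(out[, 229:256] == 0))
  expect_true(any(out[, 29:228] > 0))

  # min-max rescale to [0, 1]
  f2 <- matrix(runif(64 * 64, 10, 110), 64, 64)
  out2 <- standardize(f2, 64L)
  expect_equal(min(out2), 0)
  expect_equal(max(out2), 1)

  # downsampling without padding
  f3 <- matrix(runif(512 * 512), 512, 512)
  out3 <- standardize(f3, 256L)
  expect_equal(dim(out3), c(256L, 256L))
  expect_gt(min(out3), -1e-12)   # no zero bands were added
  expect_gt(mean(out3 > 0), 0.99)

  # constant frame maps to zeros, not an error
  expect_equal(standardize(matrix(5, 32, 32), 32L), matrix(0, 32, 32))
})

test_that("standardize_labels keeps labels integer and subsets values", {
  m <- matrix(0L, 60, 40)
  m[20:24, 18:22] <- 1L
  m[40:44, 10:14] <- 2L
  out <- standardize_labels(m, 48L)
  expect_true(is.integer(out))
  expect_true(all(unique(as.integer(out)) %in% c(0L, 1L, 2L)))
  expect_true(all(c(1L, 2L) %in% out))
})

test_that("identity augmentation is a center-crop passthrough", {
  cfg <- augmentation_config(zoom_range = c(1, 1), rotation_range = 0,
                             crop_size = 24L, pad_size = 32L,
                             hflip_prob = 0, vflip_prob = 0,
                             gaussian_noise_sigma = 0, crop = "center")
  f <- matrix(runif(32 * 32), 32, 32)
  m <- matrix(0L, 32, 32); m[14:18, 14:18] <- 1L
  out <- augment(f, m, cfg, seed = 1)
  expect_equal(out$frame, f[5:28, 5:28])
  expect_equal(out$mask, m[5:28, 5:28])
})

test_that("horizontal flip reflects the mask centroid about the midline", {
  cfg <- augmentation_config(zoom_range = c(1, 1), rotation_range = 0,
                             crop_size = 32L, pad_size = 32L,
                             hflip_prob = 1, vflip_prob = 0,
                             gaussian_noise_sigma = 0, crop = "center")
  f <- matrix(runif(32 * 32), 32, 32)
  m <- matrix(0L, 32, 32); m[10:12, 5:7] <- 1L
  c0 <- mask_centroid(m, 1L)
  out <- augment(f, m, cfg, seed = 2)
  c1 <- mask_centroid(out$mask, 1L)
  expect_equal(c1[["col"]], (32 - 1) - c0[["col"]])
  expect_equal(c1[["row"]], c0[["row"]])
})

test_that("noise perturbs the image but never the mask", {
  cfg <- augmentation_config(zoom_range = c(1, 1), rotation_range = 0,
                             crop_size = 32L, pad_size = 32L,
                             hflip_prob = 0, vflip_prob = 0,
                             gaussian_noise_sigma = 0.05, crop = "center")
  f <- matrix(runif(32 * 32), 32, 32)
  m <- matrix(0L, 32, 32); m[10:12, 5:7] <- 2L
  out <- augment(f, m, cfg, seed = 3)
  expect_false(identical(out$frame, f))
  expect_identical(out$mask, m)
})

test_that("augmented label values are a subset of the originals", {
  cfg <- augmentation_config(crop_size = 24L, pad_size = 32L)
  f <- matrix(runif(32 * 32), 32, 32)
  m <- matrix(0L, 32, 32); m[8:10, 8:10] <- 1L; m[20:22, 20:22] <- 2L
  set.seed(10)
  for (i in 1:10) {
    out <- augment(f, m, cfg)
    expect_true(all(unique(as.integer(out$mask)) %in% c(0L, 1L, 2L)))
  }
})

test_that("geometric transform moves mask centroid with the image content", {
  # a single bright blob; after augmentation the brightest image region and
  # the mask must still coincide (within nearest-neighbour error)
  cfg <- augmentation_config(crop_size = 40L, pad_size = 56L,
                             gaussian_noise_sigma = 0)
  f <- matrix(0, 56, 56)
  f[25:31, 20:26] <- 1
  m <- matrix(0L, 56, 56); m[25:31, 20:26] <- 1L
  set.seed(42)
  for (i in 1:8) {
    out <- augment(f, m, cfg)
    if (!is.null(attr(out, "degenerate"))) next
    bright <- which(out$frame > 0.5, arr.ind = TRUE)
    if (nrow(bright) == 0) next
    bc <- colMeans(bright) - 1
    mc <- mask_centroid(out$mask, 1L)
    expect_lt(abs(bc[1L] - mc[["row"]]), 1.5)
    expect_lt(abs(bc[2L] - mc[["col"]]), 1.5)
  }
})

test_that("augmentation draws are reproducible under a seed", {
  cfg <- augmentation_config(crop_size = 24L, pad_size = 32L)
  f <- matrix(runif(32 * 32), 32, 32)
  m <- matrix(0L, 32, 32); m[15:17, 15:17] <- 1L
  a <- augment(f, m, cfg, seed = 7)
  b <- augment(f, m, cfg, seed = 7)
  expect_identical(a, b)
})
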