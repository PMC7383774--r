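test_that("zero amplitude gives zero truth indices", {
  cs <- generate_case(tiny_phantom_config(lateral_amplitude = 0,
                                          septal_amplitude = 0))
  expect_equal(cs$truth_indices$ltad, c(0, 0))
  expect_equal(cs$truth_indices$ctad, c(0, 0))
})

test_that("truth LTAD equals the configured amplitude up to discretisation", {
  cfg <- phantom_config(image_size = 128L, pixel_spacing = 0.05,
                        n_frames = 30L, lateral_amplitude = 1.8,
                        septal_amplitude = 1.0, label_radius = 3L, seed = 2L)
  cs <- generate_case(cfg)
  ti <- cs$truth_indices
  # even frame count samples the full excursion exactly
  expect_equal(ti$ltad[ti$annulus == "lateral"], 1.8, tolerance = 1e-9)
  expect_equal(ti$ltad[ti$annulus == "septal"], 1.0, tolerance = 1e-9)
  # brute-force over the stored truth track agrees
  xy <- as.matrix(cs$truth_tracks[cs$truth_tracks$annulus == "lateral",
                                  c("row", "col")])
  brute <- max(stats::dist(xy)) * cfg$pixel_spacing
  expect_equal(ti$ltad[ti$annulus == "lateral"], brute)
})

test_that("identical config and seed reproduce bit-identical arrays", {
  a <- generate_case(tiny_phantom_config(seed = 31))
  b <- generate_case(tiny_phantom_config(seed = 31))
  expect_identical(a$cine$frames, b$cine$frames)
  expect_identical(a$masks$labels, b$masks$labels)
  c2 <- generate_case(tiny_phantom_config(seed = 32))
  expect_false(identical(a$cine$frames, c2$cine$frames))
})

test_that("masks are disks at the truth positions, inside the sector", {
  cfg <- tiny_phantom_config(seed = 9)
  cs <- generate_case(cfg)
  sec <- rvtrack:::sector_mask(cfg)
  arr <- cs$masks$labels
  for (t in c(1L, 5L, 10L)) {
    for (a in c("lateral", "septal")) {
      cl <- annulus_classes[[a]]
      px <- which(arr[, , t] == cl, arr.ind = TRUE)
      expect_gt(nrow(px), 0)
      expect_true(all(sec[px]))
      # center of mass within 0.5 px of the stored truth position
      tp <- cs$truth_tracks[cs$truth_tracks$frame == t &
                              cs$truth_tracks$annulus == a, ]
      cm <- mask_centroid(arr[, , t], cl)
      expect_lt(abs(cm[["row"]] - tp$row), 0.5)
      expect_lt(abs(cm[["col"]] - tp$col), 0.5)
    }
  }
})

test_that("truth LTAD increases strictly with amplitude", {
  amps <- c(0.2, 0.5, 0.8, 1.1)
  lt <- vapply(amps, function(a) {
    cs <- generate_case(tiny_phantom_config(lateral_amplitude = a))
    cs$truth_indices$ltad[cs$truth_indices$annulus == "lateral"]
  }, numeric(1L))
  expect_true(all(diff(lt) > 0))
})

test_that("oversized amplitude is rejected with a sizing error", {
  expect_error(generate_case(tiny_phantom_config(lateral_amplitude = 10)),
               "outside the image|sector")
})

test_that("cohort prevalence, determinism and range separation", {
  coh <- generate_cohort(10, 0.3, config = tiny_phantom_config(), seed = 3)
  expect_equal(sum(coh$truth$dysfunction), 3L)
  coh2 <- generate_cohort(10, 0.3, config = tiny_phantom_config(), seed = 3)
  expect_identical(coh$truth, coh2$truth)

  # disjoint amplitude ranges: truth-based classification is perfect
  expect_equal(roc_auc(coh$truth$truth_ltad_lateral,
                       coh$truth$dysfunction)$auc, 1.0)

  coh0 <- generate_cohort(5, 0, config = tiny_phantom_config(), seed = 3)
  expect_false(any(coh0$truth$dysfunction))

  expect_warning(
    generate_cohort(4, 0.5, config = tiny_phantom_config(),
                    normal_range = c(0.6, 1.0),
                    dysfunction_range = c(0.4, 0.8), seed = 1),
    "overlap")
})
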