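test_that("bland_altman matches hand arithmetic with the n-1 denominator", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)

  # differences {1, -1}: mean 0, sample SD sqrt(2), LOA +/- 1.96*sqrt(2)
  ba <- bland_altman(c(1, 0), c(0, 1))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)

  # constant bias
  ba5 <- bland_altman(x + 5, x)
  expect_equal(ba5$mean_diff, 5)
  expect_equal(c(ba5$loa_low, ba5$loa_high), c(5, 5))

  expect_error(bland_altman(1, numeric(0)), "paired")
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("LOA cover about 95% of Gaussian differences", {
  set.seed(2024)
  base <- rnorm(200, 10, 2)
  a <- base + rnorm(200, 0, 0.5)
  b <- base + rnorm(200, 0, 0.5)
  ba <- bland_altman(a, b)
  cover <- mean(ba$diffs >= ba$loa_low & ba$diffs <= ba$loa_high)
  expect_gte(cover, 0.93)
})

test_that("ICC(2,1) matches independent oracle values", {
  # identical columns with nonconstant rows: perfect agreement
  r1 <- icc(cbind(c(1, 2, 3, 7), c(1, 2, 3, 7)))
  expect_identical(r1$estimate, 1)
  expect_identical(c(r1$ci_lower, r1$ci_upper), c(1, 1))

  # {1,2,3} vs {2,3,4}: MSR = 2, MSC = 1.5, MSE = 0 -> ICC = 2/3 exactly
  r2 <- icc(cbind(1:3, 2:4))
  expect_equal(r2$estimate, 2 / 3, tolerance = 1e-12)
  expect_lt(r2$estimate, 1)  # absolute agreement penalises the constant shift

  # 8x2 fixture: reference value computed with an independent two-way
  # random-effects implementation
  M <- rbind(c(9.1, 9.4), c(11.8, 11.5), c(7.6, 8.1), c(10.2, 9.9),
             c(12.4, 12.0), c(8.8, 9.0), c(10.9, 11.3), c(9.7, 9.2))
  r3 <- icc(M)
  expect_equal(r3$estimate, 0.968429455198563, tolerance = 1e-6)
  expect_equal(round(r3$ci_lower, 2), 0.85)
  expect_equal(round(r3$ci_upper, 2), 0.99)

  # no case effect: near-zero ICC on permuted noise
  set.seed(99)
  v <- rnorm(50)
  r4 <- icc(cbind(v, sample(v)))
  expect_lt(abs(r4$estimate), 0.3)

  # zero between-case variance is undefined, not an error
  r5 <- icc(cbind(rep(1, 5), rep(1, 5)))
  expect_true(is.na(r5$estimate))
})

test_that("rank-formulation AUC equals brute-force pair enumeration", {
  # dysfunction = low score: perfectly separated
  r <- roc_auc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1.0)
  # one swap: 3 of 4 pairs concordant
  r2 <- roc_auc(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(r2$auc, 0.75)

  set.seed(11)
  for (i in 1:30) {
    n <- sample(6:20, 1)
    sc <- sample(1:10, n, replace = TRUE)   # ties on purpose
    lb <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(lb) || all(lb)) next
    brute <- 0
    for (p in which(lb)) for (q in which(!lb)) {
      brute <- brute + (sc[p] < sc[q]) + 0.5 * (sc[p] == sc[q])
    }
    brute <- brute / (sum(lb) * sum(!lb))
    expect_equal(roc_auc(sc, lb)$auc, brute, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("DeLong interval agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  sc <- rnorm(40)
  lb <- rep(c(TRUE, FALSE), each = 20)
  sc[lb] <- sc[lb] - 1
  r <- roc_auc(sc, lb)
  ref <- pROC::roc(response = lb, predictor = sc, direction = ">",
                   levels = c(FALSE, TRUE), quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(c(r$ci_lower, r$ci_upper), ci[c(1, 3)], tolerance = 1e-6)
})

test_that("operating point maximises specificity under the sensitivity floor", {
  # perfectly separated: sens = spec = 1 at the separating cutoff
  op <- operating_point(c(1, 2, 3, 10, 11, 12), c(TRUE, TRUE, TRUE, FALSE,
                                                  FALSE, FALSE), 0.8)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  expect_true(op$floor_attained)

  # 10 positives below 10 negatives except one overlap; check against an
  # exhaustive confusion-table enumeration over all 21 candidate cutoffs
  sc <- c(1:9, 10.5, 10, 11:19)
  lb <- c(rep(TRUE, 10), rep(FALSE, 10))
  op2 <- operating_point(sc, lb, 0.8)
  cand <- rvtrack:::candidate_cutoffs(sc)
  expect_length(cand, 21L)
  best <- NULL
  for (ct in cand) {
    pred <- sc < ct
    sens <- sum(pred & lb) / sum(lb)
    spec <- sum(!pred & !lb) / sum(!lb)
    if (sens > 0.8 && (is.null(best) || spec > best$spec ||
                       (spec == best$spec && sens > best$sens) ||
                       (spec == best$spec && sens == best$sens &&
                        ct < best$ct))) {
      best <- list(ct = ct, sens = sens, spec = spec)
    }
  }
  expect_equal(op2$cutoff, best$ct)
  expect_equal(op2$sensitivity, best$sens)
  expect_equal(op2$specificity, best$spec)

  # degenerate constant scores: only the all-or-none boundary cutoffs exist,
  # and the call-everyone-positive boundary trivially satisfies the floor
  op3 <- operating_point(c(5, 5, 5, 5), c(TRUE, TRUE, FALSE, FALSE), 0.8)
  expect_true(op3$floor_attained)
  expect_equal(op3$sensitivity, 1)
  expect_equal(op3$specificity, 0)
})

test_that("confusion statistics are coherent at the chosen cutoff", {
  set.seed(21)
  sc <- rnorm(60)
  lb <- rep(c(TRUE, FALSE), 30)
  sc[lb] <- sc[lb] - 1.5
  op <- operating_point(sc, lb, 0.8)
  cm <- op$confusion
  expect_equal(op$sensitivity, cm$tp / (cm$tp + cm$fn))
  expect_equal(op$specificity, cm$tn / (cm$tn + cm$fp))
  expect_equal(op$accuracy, (cm$tp + cm$tn) / 60)
  expect_equal(op$ppv, cm$tp / (cm$tp + cm$fp))
  expect_equal(op$npv, cm$tn / (cm$tn + cm$fn))
  expect_gt(op$sensitivity, 0.8)
})

test_that("group_compare matches the closed-form pooled t test", {
  res <- group_compare(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
  # pooled t for {1,2,3} vs {7,8,9}: t = -6/sqrt(2/3) = -7.348469...
  expect_equal(res$statistic, -6 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$p_value, 0.0018262606682599833, tolerance = 1e-9)
  expect_equal(res$df, 4)

  # null behaviour at large n
  set.seed(8)
  v <- rnorm(400)
  g <- rep(c("x", "y"), 200)
  expect_gt(group_compare(v, g)$p_value, 0.05)
  expect_error(group_compare(1:3, rep("a", 3)), "2 groups")
})

test_that("tertile means increase for a monotone stratifier", {
  set.seed(4)
  strat <- runif(60)
  vals <- 2 * strat + rnorm(60, 0, 0.01)
  tt <- tertile_trend(vals, strat)
  expect_equal(nrow(tt$tertiles), 3L)
  expect_true(all(diff(tt$tertiles$mean) > 0))
  expect_lt(tt$p_trend, 1e-6)
})

test_that("agreement and diagnostic reports assemble their tidy summaries", {
  set.seed(12)
  a <- rnorm(30, 10)
  b <- a + rnorm(30, 0.2, 0.3)
  ar <- agreement_report(a, b)
  td <- tidy(ar)
  expect_true(all(c("mean_diff", "loa_low", "loa_high", "pearson_r", "icc",
                    "slope", "intercept") %in% names(td)))
  expect_true(td$loa_low <= td$mean_diff && td$mean_diff <= td$loa_high)
  expect_true(abs(td$pearson_r) <= 1)

  sc <- c(rnorm(15, 1), rnorm(15, 3))
  lb <- rep(c(TRUE, FALSE), each = 15)
  dr <- diagnostic_report(sc, lb)
  tdd <- tidy(dr)
  expect_true(all(c("auc", "ci_lower", "ci_upper", "cutoff", "sensitivity",
                    "specificity", "accuracy", "ppv", "npv") %in% names(tdd)))
  expect_gt(tdd$auc, 0.5)
})
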