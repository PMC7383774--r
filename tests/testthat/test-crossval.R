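test_that("fold sizes are balanced and assignment is by case", {
  p <- make_folds(sprintf("c%02d", 1:12), k = 6, seed = 1)
  expect_equal(sort(as.integer(table(p$fold))), rep(2L, 6))

  # 101 cases into 6 folds: five of 17 and one of 16
  p101 <- make_folds(sprintf("c%03d", 1:101), k = 6, seed = 2)
  expect_equal(sort(as.integer(table(p101$fold))), c(16L, rep(17L, 5)))
  expect_equal(sort(unique(p101$fold)), 1:6)
  expect_setequal(p101$case_id, sprintf("c%03d", 1:101))

  # deterministic under seed
  expect_identical(make_folds(letters[1:10], 5, seed = 9),
                   make_folds(letters[1:10], 5, seed = 9))
  expect_error(make_folds(letters[1:3], k = 5), "between 1")
})

dummy_cases <- function(n) {
  lapply(seq_len(n), function(i) {
    list(case_id = sprintf("c%02d", i), value = i * 10)
  })
}

test_that("run_cv trains one model per fold and predicts each case once", {
  cases <- dummy_cases(12)
  plan <- make_folds(vapply(cases, `[[`, "", "case_id"), k = 6, seed = 4)
  trained <- 0L
  trainer <- function(train_cases, fold) {
    trained <<- trained + 1L
    list(train_ids = vapply(train_cases, `[[`, "", "case_id"))
  }
  predictor <- function(model, case) {
    tibble::tibble(pred = case$value, n_train = length(model$train_ids))
  }
  res <- run_cv(cases, plan, trainer, predictor)
  expect_equal(trained, 6L)
  expect_equal(nrow(res), 12L)
  expect_equal(anyDuplicated(res$case_id), 0L)
  expect_equal(res$n_train, rep(10L, 12))

  # leave-one-out degenerate case
  cases3 <- dummy_cases(3)
  plan3 <- make_folds(vapply(cases3, `[[`, "", "case_id"), k = 3, seed = 1)
  res3 <- run_cv(cases3, plan3, trainer, predictor)
  expect_equal(nrow(res3), 3L)
})

test_that("results are invariant to case order", {
  cases <- dummy_cases(9)
  plan <- make_folds(vapply(cases, `[[`, "", "case_id"), k = 3, seed = 7)
  trainer <- function(train_cases, fold) {
    mean(vapply(train_cases, `[[`, 0, "value"))
  }
  predictor <- function(model, case) tibble::tibble(pred = case$value - model)
  r1 <- run_cv(cases, plan, trainer, predictor)
  r2 <- run_cv(rev(cases), plan, trainer, predictor)
  expect_equal(r1, r2)
})

test_that("the leakage guard fires on a corrupted plan", {
  cases <- dummy_cases(6)
  plan <- make_folds(vapply(cases, `[[`, "", "case_id"), k = 3, seed = 2)
  # sabotage: claim a case belongs to a fold it is not assigned to
  expect_error(
    rvtrack:::leakage_guard(plan, fold = 1L,
                            train_ids = plan$case_id[plan$fold != 2],
                            predict_id = plan$case_id[plan$fold == 2][1L]),
    "leakage")
  # and the honest path passes
  expect_true(
    rvtrack:::leakage_guard(plan, fold = 2L,
                            train_ids = plan$case_id[plan$fold != 2],
                            predict_id = plan$case_id[plan$fold == 2][1L]))
})

test_that("no leakage across many seeded re-plans", {
  cases <- dummy_cases(10)
  ids <- vapply(cases, `[[`, "", "case_id")
  trainer <- function(train_cases, fold) {
    vapply(train_cases, `[[`, "", "case_id")
  }
  predictor <- function(model, case) {
    # the guard inside run_cv already asserts; double-check here
    expect_false(case$case_id %in% model)
    tibble::tibble(ok = TRUE)
  }
  for (s in 1:20) {
    res <- run_cv(cases, make_folds(ids, k = sample(2:5, 1), seed = s),
                  trainer, predictor)
    expect_true(all(res$ok))
  }
})
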