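#' Case-level fold assignment
#'
#' Randomly partitions case identifiers into `k` nonoverlapping folds whose
#' sizes differ by at most one. The split is always by case: every frame of a
#' case shares its fold, so no model instance can be tested on frames it was
#' trained on.
#'
#' @param case_ids Character (or coercible) vector of unique case ids.
#' @param k Number of folds.
#' @param seed Integer seed; the same seed reproduces the assignment.
#' @return A `fold_plan`: a tibble with columns `case_id` and `fold`, with
#'   attributes `k` and `seed`.
#' @export
make_folds <- function(case_ids, k = 6L, seed = 1L) {
  case_ids <- as.character(case_ids)
  if (anyDuplicated(case_ids)) abort("case_ids must be unique")
  n <- length(case_ids)
  k <- as.integer(k)
  if (k < 1L || k > n) abort(sprintf("k = %d must be between 1 and the number of cases (%d)", k, n))
  set.seed(seed)
  ord <- sample(case_ids)
  plan <- tibble(case_id = ord, fold = rep(seq_len(k), length.out = n)) |>
    dplyr::arrange(.data$case_id)
  structure(plan, k = k, seed = seed,
            class = c("fold_plan", class(tibble())))
}

leakage_guard <- function(plan, fold, train_ids, predict_id) {
  if (predict_id %in% train_ids) {
    abort(sprintf("cross-validation leakage: case %s predicted by a model trained on it", predict_id))
  }
  pf <- plan$fold[plan$case_id == predict_id]
  if (length(pf) != 1L || pf != fold) {
    abort(sprintf("cross-validation leakage: case %s predicted outside its assigned fold", predict_id))
  }
  invisible(TRUE)
}

#' Run case-level cross-validation
#'
#' For each fold, a fresh model is trained (via `trainer`) on the cases of
#' the other `k - 1` folds and applied (via `predictor`) only to the held-out
#' cases, so every case receives exactly one prediction. A leakage guard
#' asserts — as a hard failure, not a warning — that no case is ever
#' predicted by a model that saw it in training.
#'
#' @param cases Named list of cases, or a list whose elements carry a
#'   `case_id` field.
#' @param plan A [make_folds()] plan covering exactly these cases.
#' @param trainer `function(train_cases, fold)` returning a fitted model.
#' @param predictor `function(model, case)` returning a one-row data frame
#'   of per-case outputs.
#' @return A tibble of per-case predictions with `case_id` and `fold`
#'   columns, ordered by case id.
#' @export
run_cv <- function(cases, plan, trainer, predictor) {
  ids <- vapply(cases, function(cs) as.character(cs$case_id %||% NA_character_),
                character(1L))
  if (anyNA(ids)) {
    if (is.null(names(cases))) abort("cases must carry case_id fields or names")
    ids <- names(cases)
  }
  if (!setequal(ids, plan$case_id)) {
    abort("fold plan does not cover exactly the supplied cases")
  }
  k <- attr(plan, "k")
  out <- list()
  for (f in seq_len(k)) {
    test_ids <- plan$case_id[plan$fold == f]
    train_ids <- setdiff(ids, test_ids)
    model <- trainer(cases[match(train_ids, ids)], f)
    for (id in test_ids) {
      leakage_guard(plan, f, train_ids, id)
      pred <- predictor(model, cases[[match(id, ids)]])
      pred$case_id <- id
      pred$fold <- f
      out[[length(out) + 1L]] <- pred
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::relocate("case_id", "fold") |>
    dplyr::arrange(.data$case_id)
}
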