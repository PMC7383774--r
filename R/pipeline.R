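#' Fully automated quantification of one cine sequence
#'
#' The end-to-end automated pipeline for a single case: segment every frame
#' with the network, track each annulus as the center of mass of its labelled
#' pixels, median-smooth the trajectories, map positions back to the original
#' frame geometry, and compute LTAD and CTAD per annulus. Inference is a
#' single deterministic pass: repeating the call with the same weights and
#' input reproduces the indices exactly.
#'
#' @param net A trained `rvtrack_net`.
#' @param cine A [cine_sequence].
#' @param window Median-smoothing window in frames (odd).
#' @param batch_size Frames per forward batch.
#' @return A tibble of per-annulus indices (see [displacement_indices()])
#'   with the smoothed trajectory attached as attribute `trajectory`.
#' @export
quantify <- function(net, cine, window = 3L, batch_size = 8L) {
  labs <- predict_labels(net, cine, batch_size = batch_size)
  tr <- track_sequence(labs, pixel_spacing = cine$pixel_spacing)
  tr <- transform_trajectory(tr, attr(labs, "transform"))
  tr <- smooth_trajectory(tr, window = window)
  idx <- displacement_indices(tr, max_gap = window)
  attr(idx, "trajectory") <- tr
  idx
}

indices_wide <- function(idx) {
  out <- list()
  for (i in seq_len(nrow(idx))) {
    a <- idx$annulus[i]
    out[[paste0("ltad_", a)]] <- idx$ltad[i]
    out[[paste0("ctad_", a)]] <- idx$ctad[i]
    out[[paste0("frac_missing_", a)]] <- idx$frac_missing[i]
    out[[paste0("valid_", a)]] <- idx$valid[i]
  }
  out$unit <- idx$unit[1L]
  tibble::as_tibble(out)
}

#' Quantify a list of cases with one trained model
#'
#' @param net A trained `rvtrack_net`.
#' @param cases List of cases with `cine` entries (e.g. [generate_case()]
#'   output) or bare [cine_sequence] objects.
#' @param window,batch_size See [quantify()].
#' @return A tibble, one row per case, with `case_id` and wide index columns
#'   (`ltad_lateral`, `ctad_lateral`, `ltad_septal`, `ctad_septal`, quality
#'   columns and `unit`).
#' @export
quantify_cohort <- function(net, cases, window = 3L, batch_size = 8L) {
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    cine <- if (inherits(cs, "cine_sequence")) cs else cs$cine
    idx <- quantify(net, cine, window = window, batch_size = batch_size)
    w <- indices_wide(idx)
    w$case_id <- if (!is.null(cs$case_id)) cs$case_id else sprintf("case%02d", i)
    w
  })
  dplyr::bind_rows(rows) |> dplyr::relocate("case_id")
}

#' Cross-validated quantification of a phantom cohort
#'
#' Trains one fresh segmentation model per fold (on the other folds' cases
#' only) and quantifies each case with the model that never saw it, via
#' [run_cv()] and its leakage guard.
#'
#' @param cohort A [generate_cohort()] result (or plain list of cases).
#' @param k Number of folds.
#' @param net_config,weights,epochs,frames_per_case,batch_size,augment,lr
#'   Passed to [train_segmenter()].
#' @param window Median-smoothing window for [quantify()].
#' @param seed Seed controlling the fold assignment and per-fold training.
#' @param verbose Print per-fold progress.
#' @return A tibble of per-case indices with `case_id` and `fold` columns.
#' @export
crossval_quantify <- function(cohort, k = 6L, net_config = network_config(),
                              weights = loss_config(), epochs = 10L,
                              frames_per_case = 4L, batch_size = 8L,
                              augment = NULL, lr = 1e-3, window = 3L,
                              seed = 1L, verbose = FALSE) {
  cases <- if (inherits(cohort, "phantom_cohort")) cohort$cases else cohort
  ids <- vapply(cases, function(cs) cs$case_id, character(1L))
  plan <- make_folds(ids, k = k, seed = seed)
  trainer <- function(train_cases, fold) {
    if (verbose) message(sprintf("fold %d/%d: training on %d cases", fold, k,
                                 length(train_cases)))
    train_segmenter(train_cases, net_config = net_config, weights = weights,
                    epochs = epochs, frames_per_case = frames_per_case,
                    batch_size = batch_size, augment = augment, lr = lr,
                    seed = seed + fold)$net
  }
  predictor <- function(model, case) {
    indices_wide(quantify(model, case$cine, window = window,
                          batch_size = batch_size))
  }
  run_cv(cases, plan, trainer, predictor)
}

#' Agreement and diagnostic evaluation of cohort indices
#'
#' Builds, for each displacement index, the diagnostic-performance report
#' against a binary dysfunction reference, in the usual evaluation layout
#' (AUC with CI, sensitivity-constrained cutoff, sens/spec/accuracy/PPV/NPV).
#'
#' @param values Tibble of per-case indices (as from [quantify_cohort()]).
#' @param labels Logical dysfunction reference, one per row of `values`.
#' @param index_cols Index columns to evaluate.
#' @param sensitivity_floor See [operating_point()].
#' @return A tibble with one row per index; the full `diagnostic_report`
#'   objects are attached as attribute `reports`.
#' @export
evaluate_diagnostics <- function(values, labels,
                                 index_cols = c("ltad_lateral", "ctad_lateral",
                                                "ltad_septal", "ctad_septal"),
                                 sensitivity_floor = 0.80) {
  reports <- lapply(index_cols, function(cl) {
    diagnostic_report(values[[cl]], labels,
                      sensitivity_floor = sensitivity_floor)
  })
  names(reports) <- index_cols
  out <- dplyr::bind_rows(lapply(index_cols, function(cl) {
    dplyr::bind_cols(tibble(index = cl), tidy(reports[[cl]]))
  }))
  attr(out, "reports") <- reports
  out
}

#' Agreement between two quantification runs or methods
#'
#' Per-index agreement statistics (Bland-Altman, Pearson, ICC(2,1), linear
#' regression) between two sets of per-case index values paired by `case_id`.
#'
#' @param x,y Tibbles from [quantify_cohort()] (must share case ids).
#' @param index_cols Index columns to compare.
#' @return A tibble with one row per index; `agreement_report` objects are
#'   attached as attribute `reports`.
#' @export
evaluate_agreement <- function(x, y,
                               index_cols = c("ltad_lateral", "ctad_lateral",
                                              "ltad_septal", "ctad_septal")) {
  m <- dplyr::inner_join(x, y, by = "case_id", suffix = c("_a", "_b"))
  if (nrow(m) != nrow(x)) abort("x and y must cover the same case ids")
  reports <- lapply(index_cols, function(cl) {
    agreement_report(m[[paste0(cl, "_a")]], m[[paste0(cl, "_b")]])
  })
  names(reports) <- index_cols
  out <- dplyr::bind_rows(lapply(index_cols, function(cl) {
    dplyr::bind_cols(tibble(index = cl), tidy(reports[[cl]]))
  }))
  attr(out, "reports") <- reports
  out
}
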