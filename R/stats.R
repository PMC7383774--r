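#' Bland-Altman agreement analysis
#'
#' Mean of the paired differences `a - b` and limits of agreement at
#' `mean ± 1.96 SD`, with the sample standard deviation (n - 1 denominator).
#'
#' @param a,b Paired measurements (equal length, at least 2 pairs).
#' @param loa_multiplier Multiplier for the limits of agreement.
#' @return An object of class `bland_altman` with fields `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n`, plus the paired values.
#' @export
bland_altman <- function(a, b, loa_multiplier = 1.96) {
  if (length(a) != length(b)) abort("a and b must be paired (equal length)")
  if (length(a) < 2L) abort("Bland-Altman requires at least 2 pairs")
  d <- a - b
  m <- mean(d)
  s <- sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - loa_multiplier * s,
                 loa_high = m + loa_multiplier * s,
                 n = length(d), a = a, b = b, diffs = d,
                 loa_multiplier = loa_multiplier),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean difference %.4g, LOA (%.4g, %.4g), n = %d\n",
              x$mean_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff, loa_low = x$loa_low,
         loa_high = x$loa_high, n = x$n)
}

#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tibble(mean = (object$a + object$b) / 2, diff = object$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_diff, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "mean of methods", y = "difference",
                  title = "Bland-Altman agreement")
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement — the
#' standard model for inter-observer (or inter-run) agreement. The 95%
#' confidence interval uses the standard F-based interval. With zero
#' between-case variance the coefficient is undefined and reported as `NA`.
#'
#' @param ratings Numeric matrix, cases in rows and raters/runs in columns
#'   (at least 3 cases, 2 raters).
#' @param conf_level Confidence level for the interval.
#' @return An object of class `icc_result` with `estimate`, `ci_lower`,
#'   `ci_upper`, `n`, `k`.
#' @export
icc <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  n <- nrow(x)
  k <- ncol(x)
  if (k < 2L) abort("ICC requires at least 2 raters")
  if (n < 3L) abort("ICC requires at least 3 cases")
  if (anyNA(x)) abort("ICC requires complete ratings")
  grand <- mean(x)
  rm_ <- rowMeans(x)
  cm_ <- colMeans(x)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  resid <- x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (msr == 0 && denom <= 0) {
    est <- NA_real_
    ci <- c(NA_real_, NA_real_)
  } else {
    est <- (msr - mse) / denom
    if (mse == 0 && msc == 0) {
      ci <- c(1, 1)   # perfect, variance-free agreement
    } else {
      alpha <- 1 - conf_level
      a <- (k * est) / (n * (1 - est))
      b <- 1 + k * est * (n - 1) / (n * (1 - est))
      if (!is.finite(a) || !is.finite(b)) {
        ci <- c(NA_real_, NA_real_)
      } else {
        v <- (a * msc + b * mse)^2 /
          ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
        fl <- qf(1 - alpha / 2, n - 1, v)
        fu <- qf(1 - alpha / 2, v, n - 1)
        lower <- n * (msr - fl * mse) /
          (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
        upper <- n * (fu * msr - mse) /
          (k * msc + (k * n - k - n) * mse + n * fu * msr)
        ci <- c(lower, upper)
      }
    }
  }
  structure(list(estimate = est, ci_lower = ci[1L], ci_upper = ci[2L],
                 n = n, k = k, conf_level = conf_level,
                 model = "ICC(2,1) two-way random, absolute agreement"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s: %.4f (%d%% CI %.4f-%.4f), n = %d cases x %d raters\n",
              x$model, x$estimate, round(100 * x$conf_level), x$ci_lower,
              x$ci_upper, x$n, x$k))
  invisible(x)
}

#' @export
tidy.icc_result <- function(x, ...) {
  tibble(estimate = x$estimate, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
         n = x$n, k = x$k)
}

# orientation: the positive (dysfunctional) class has LOWER displacement,
# so scores are negated internally when positive_low = TRUE
oriented_scores <- function(scores, positive_low) {
  if (positive_low) -scores else scores
}

#' ROC area under the curve
#'
#' AUC by the Mann-Whitney rank formulation (ties handled by midranks), with
#' a confidence interval by DeLong's method (or a seeded stratified
#' bootstrap). Orientation: by default a lower score indicates dysfunction
#' (the positive class), matching the direction of impairment of annular
#' displacement indices.
#'
#' @param scores Numeric index values.
#' @param labels Logical (or 0/1) dysfunction labels; `TRUE` is positive.
#' @param positive_low If `TRUE` (default), lower scores indicate the
#'   positive class.
#' @param conf_level Confidence level.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param boot_n Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return An object of class `auc_result` with `auc`, `ci_lower`,
#'   `ci_upper`, counts and settings.
#' @export
roc_auc <- function(scores, labels, positive_low = TRUE, conf_level = 0.95,
                    ci_method = c("delong", "bootstrap"), boot_n = 2000L,
                    seed = 1L) {
  ci_method <- match.arg(ci_method)
  lab <- as.logical(labels)
  if (length(scores) != length(lab)) abort("scores and labels must be paired")
  if (!any(lab) || all(lab)) abort("both classes must be present")
  s <- oriented_scores(scores, positive_low)
  pos <- s[lab]
  neg <- s[!lab]
  n1 <- length(pos)
  n0 <- length(neg)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (ci_method == "delong") {
    # placements
    v10 <- vapply(pos, function(p) (sum(p > neg) + 0.5 * sum(p == neg)) / n0,
                  numeric(1L))
    v01 <- vapply(neg, function(q) (sum(pos > q) + 0.5 * sum(pos == q)) / n1,
                  numeric(1L))
    se <- sqrt(var(v10) / n1 + var(v01) / n0)
    z <- qnorm(1 - (1 - conf_level) / 2)
    ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * se))
  } else {
    set.seed(seed)
    stat <- replicate(boot_n, {
      i1 <- sample.int(n1, replace = TRUE)
      i0 <- sample.int(n0, replace = TRUE)
      rr <- rank(c(pos[i1], neg[i0]))
      (sum(rr[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    })
    ci <- unname(quantile(stat, c((1 - conf_level) / 2,
                                  1 - (1 - conf_level) / 2)))
  }
  structure(list(auc = auc, ci_lower = ci[1L], ci_upper = ci[2L],
                 n_pos = n1, n_neg = n0, positive_low = positive_low,
                 conf_level = conf_level, ci_method = ci_method),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI %.3f-%.3f; %s), %d positive / %d negative\n",
              x$auc, round(100 * x$conf_level), x$ci_lower, x$ci_upper,
              x$ci_method, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.auc_result <- function(x, ...) {
  tibble(auc = x$auc, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' ROC curve points
#'
#' Sensitivity/specificity at every candidate cutoff (interior midpoints of
#' sorted unique scores plus the two all-or-none boundary cutoffs), suitable
#' for CSV export or plotting.
#'
#' @inheritParams roc_auc
#' @return A tibble with `cutoff`, `sensitivity`, `specificity`.
#' @export
roc_curve <- function(scores, labels, positive_low = TRUE) {
  lab <- as.logical(labels)
  cuts <- candidate_cutoffs(scores)
  dplyr::bind_rows(lapply(cuts, function(ct) {
    cm <- confusion_at(scores, lab, ct, positive_low)
    tibble(cutoff = ct, sensitivity = cm$sens, specificity = cm$spec)
  }))
}

candidate_cutoffs <- function(scores) {
  u <- sort(unique(scores))
  mids <- if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2 else numeric()
  c(-Inf, mids, Inf)
}

confusion_at <- function(scores, lab, cutoff, positive_low) {
  pred <- if (positive_low) scores < cutoff else scores > cutoff
  tp <- sum(pred & lab)
  fp <- sum(pred & !lab)
  fn <- sum(!pred & lab)
  tn <- sum(!pred & !lab)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       acc = (tp + tn) / length(lab),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Sensitivity-constrained operating point
#'
#' Among candidate cutoffs (interior midpoints of the sorted unique scores
#' plus the two boundary cutoffs), selects those with sensitivity strictly
#' above `sensitivity_floor` and, among them, the one with maximal
#' specificity; ties are broken toward higher sensitivity, then toward the
#' lower cutoff. If no cutoff attains the floor, the maximum-sensitivity
#' cutoff is reported with `floor_attained = FALSE`.
#'
#' @inheritParams roc_auc
#' @param sensitivity_floor Required sensitivity (strict), default 0.80.
#' @return An object of class `operating_point` with the chosen `cutoff`,
#'   `sensitivity`, `specificity`, `accuracy`, `ppv`, `npv`,
#'   `floor_attained`, and the confusion counts.
#' @export
operating_point <- function(scores, labels, sensitivity_floor = 0.80,
                            positive_low = TRUE) {
  lab <- as.logical(labels)
  if (!any(lab) || all(lab)) abort("both classes must be present")
  if (sensitivity_floor < 0 || sensitivity_floor >= 1) {
    abort("sensitivity_floor must be in [0, 1)")
  }
  cuts <- candidate_cutoffs(scores)
  grid <- dplyr::bind_rows(lapply(cuts, function(ct) {
    cm <- confusion_at(scores, lab, ct, positive_low)
    tibble(cutoff = ct, sens = cm$sens, spec = cm$spec, acc = cm$acc,
           ppv = cm$ppv, npv = cm$npv, tp = cm$tp, fp = cm$fp, fn = cm$fn,
           tn = cm$tn)
  }))
  eligible <- grid[grid$sens > sensitivity_floor, ]
  attained <- nrow(eligible) > 0L
  pool <- if (attained) eligible else grid[grid$sens == max(grid$sens), ]
  pool <- pool[order(-pool$spec, -pool$sens, pool$cutoff), ]
  best <- pool[1L, ]
  structure(list(cutoff = best$cutoff, sensitivity = best$sens,
                 specificity = best$spec, accuracy = best$acc,
                 ppv = best$ppv, npv = best$npv,
                 floor_attained = attained,
                 sensitivity_floor = sensitivity_floor,
                 positive_low = positive_low,
                 confusion = list(tp = best$tp, fp = best$fp, fn = best$fn,
                                  tn = best$tn)),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(
    "Operating point (sens > %.0f%%%s): cutoff %.4g, sens %.2f, spec %.2f, acc %.2f, PPV %.2f, NPV %.2f\n",
    100 * x$sensitivity_floor,
    if (x$floor_attained) "" else ", NOT attained", x$cutoff, x$sensitivity,
    x$specificity, x$accuracy, x$ppv, x$npv))
  invisible(x)
}

#' @export
tidy.operating_point <- function(x, ...) {
  tibble(cutoff = x$cutoff, sensitivity = x$sensitivity,
         specificity = x$specificity, accuracy = x$accuracy, ppv = x$ppv,
         npv = x$npv, floor_attained = x$floor_attained)
}

#' Two-group comparison (Student's t test)
#'
#' Two-sided unpaired t test between two groups, pooled variance by default
#' (Welch available), expressed as mean ± SD per group.
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping vector.
#' @param var_equal Pooled-variance (classic Student) when `TRUE`.
#' @return A tibble with group means/SDs, the t statistic, degrees of
#'   freedom and two-sided p value.
#' @export
group_compare <- function(values, groups, var_equal = TRUE) {
  g <- factor(groups)
  if (nlevels(g) != 2L) abort("group_compare requires exactly 2 groups")
  if (any(table(g) == 0L)) abort("both groups must be nonempty")
  tt <- t.test(values ~ g, var.equal = var_equal)
  lv <- levels(g)
  tibble(group1 = lv[1L], group2 = lv[2L],
         mean1 = mean(values[g == lv[1L]]), sd1 = sd(values[g == lv[1L]]),
         mean2 = mean(values[g == lv[2L]]), sd2 = sd(values[g == lv[2L]]),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' Tertile stratification with a trend test
#'
#' Splits cases at the empirical 33.3/66.7 percentiles of a stratifying
#' variable (for example a conventional annular-excursion measure), reports
#' per-tertile means of the index, and tests for a trend across tertiles by
#' one-way ANOVA.
#'
#' @param values Index values.
#' @param stratifier Variable defining the tertiles.
#' @return A list of class `tertile_trend`: `tertiles` (tibble with n,
#'   mean, sd per tertile) and `p_trend`.
#' @export
tertile_trend <- function(values, stratifier) {
  if (length(values) != length(stratifier)) {
    abort("values and stratifier must be paired")
  }
  br <- quantile(stratifier, c(0, 1 / 3, 2 / 3, 1))
  tert <- cut(stratifier, breaks = unique(br), include.lowest = TRUE,
              labels = FALSE)
  tert <- factor(tert, labels = paste0("T", sort(unique(tert))))
  if (any(table(tert) < 3L)) abort("each tertile needs at least 3 cases")
  fit <- aov(values ~ tert)
  p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  tb <- tibble(tertile = levels(tert),
               n = as.integer(table(tert)),
               mean = as.numeric(tapply(values, tert, mean)),
               sd = as.numeric(tapply(values, tert, sd)))
  structure(list(tertiles = tb, p_trend = p), class = "tertile_trend")
}

#' @export
print.tertile_trend <- function(x, ...) {
  print(x$tertiles)
  cat(sprintf("trend p (one-way ANOVA) = %.4g\n", x$p_trend))
  invisible(x)
}

#' @export
tidy.tertile_trend <- function(x, ...) {
  dplyr::mutate(x$tertiles, p_trend = x$p_trend)
}

#' Agreement report between two measurement methods
#'
#' Combines the Bland-Altman analysis, Pearson correlation, ICC(2,1) and a
#' linear regression of method `a` on method `b` into the standard agreement
#' summary.
#'
#' @param a,b Paired measurements (e.g. automated vs manual indices).
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(a, b) {
  ba <- bland_altman(a, b)
  fit <- stats::lm(a ~ b)
  sxy <- sd(a) > 0 && sd(b) > 0
  structure(list(
    bland_altman = ba,
    pearson_r = if (sxy) stats::cor(a, b) else NA_real_,
    icc = icc(cbind(a, b)),
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L])
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  print(x$bland_altman)
  cat(sprintf("Pearson r = %.3f; regression a = %.3f + %.3f b\n",
              x$pearson_r, x$intercept, x$slope))
  print(x$icc)
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) {
  dplyr::bind_cols(tidy(x$bland_altman),
                   tibble(pearson_r = x$pearson_r,
                          icc = x$icc$estimate,
                          icc_ci_lower = x$icc$ci_lower,
                          icc_ci_upper = x$icc$ci_upper,
                          slope = x$slope, intercept = x$intercept))
}

#' Diagnostic-performance report for one index
#'
#' ROC AUC with confidence interval plus the sensitivity-constrained
#' operating point and its confusion-matrix statistics.
#'
#' @inheritParams operating_point
#' @param conf_level Confidence level for the AUC interval.
#' @param ci_method AUC interval method (see [roc_auc()]).
#' @return An object of class `diagnostic_report` with `auc`
#'   ([roc_auc()] result), `operating_point` ([operating_point()] result)
#'   and the ROC curve points.
#' @export
diagnostic_report <- function(scores, labels, sensitivity_floor = 0.80,
                              positive_low = TRUE, conf_level = 0.95,
                              ci_method = "delong") {
  structure(list(
    auc = roc_auc(scores, labels, positive_low, conf_level,
                  ci_method = ci_method),
    operating_point = operating_point(scores, labels, sensitivity_floor,
                                      positive_low),
    curve = roc_curve(scores, labels, positive_low)
  ), class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  print(x$auc)
  print(x$operating_point)
  invisible(x)
}

#' @export
tidy.diagnostic_report <- function(x, ...) {
  dplyr::bind_cols(tidy(x$auc), tidy(x$operating_point))
}

#' @export
glance.diagnostic_report <- function(x, ...) tidy(x)

#' @export
autoplot.diagnostic_report <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::annotate("point",
                      x = 1 - object$operating_point$specificity,
                      y = object$operating_point$sensitivity,
                      colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC %.3f)", object$auc$auc))
}
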