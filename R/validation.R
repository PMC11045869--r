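#' Binarize true METs for one classification task
#'
#' The three one-vs-rest classification tasks evaluated on the test set:
#' SED (positive when `met <= sed_max`), MVPA (positive when
#' `met >= mvpa_min`) and VPA (positive when `met >= vpa_min`).
#'
#' @param mets Positive MET values.
#' @param category One of `"SED"`, `"MVPA"`, `"VPA"`.
#' @param thresholds A [met_thresholds()] object.
#' @return An integer vector of 0/1 labels.
#' @export
binarize_by_category <- function(mets, category, thresholds = met_thresholds()) {
  if (any(mets <= 0)) stop("`mets` must be positive.", call. = FALSE)
  switch(match.arg(category, c("SED", "MVPA", "VPA")),
    SED  = as.integer(mets <= thresholds$sed_max),
    MVPA = as.integer(mets >= thresholds$mvpa_min),
    VPA  = as.integer(mets >= thresholds$vpa_min)
  )
}

#' Youden's J statistic
#'
#' `J = sensitivity + specificity - 1`, the distance of an operating point
#' above the chance diagonal.
#'
#' @param sensitivity,specificity Proportions in \[0, 1\].
#' @return J in \[-1, 1\].
#' @export
youden_index <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  sensitivity + specificity - 1
}

wilson_ci <- function(x, n, conf = 0.95) {
  # the chi-squared warning concerns the test statistic, not the interval
  test <- suppressWarnings(stats::prop.test(x, n, correct = FALSE,
                                            conf.level = conf))
  as.numeric(test$conf.int)
}

#' Sensitivity, specificity and Youden index at an operating point
#'
#' Computes sensitivity (TP / (TP + FN)), specificity (TN / (TN + FP)) and
#' Youden's J from paired binary labels, with Wilson score 95% confidence
#' intervals for the two proportions.
#'
#' @param truth,pred Binary vectors (0/1 or logical) of equal length; `truth`
#'   must contain both classes.
#' @return A one-row tibble with columns `sensitivity`, `sens_low`,
#'   `sens_high`, `specificity`, `spec_low`, `spec_high`, `youden`.
#' @export
confusion_metrics <- function(truth, pred) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  if (length(truth) != length(pred)) {
    stop("`truth` and `pred` must have equal length.", call. = FALSE)
  }
  if (length(unique(truth)) < 2) {
    stop("`truth` contains a single class; sensitivity/specificity undefined.",
         call. = FALSE)
  }
  tp <- sum(truth == 1 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  sens_ci <- wilson_ci(tp, tp + fn)
  spec_ci <- wilson_ci(tn, tn + fp)
  tibble::tibble(
    sensitivity = sens, sens_low = sens_ci[1], sens_high = sens_ci[2],
    specificity = spec, spec_low = spec_ci[1], spec_high = spec_ci[2],
    youden = youden_index(sens, spec)
  )
}

#' ROC area under the curve with DeLong interval
#'
#' AUC via the concordance (trapezoidal) estimator with ties counted one
#' half, plus a 95% confidence interval and variance from DeLong's method.
#' Higher scores must indicate the positive class (for the SED task pass the
#' negated estimated MET as the score).
#'
#' @param truth Binary labels (0/1 or logical); both classes required.
#' @param score Continuous classification scores.
#' @return A one-row tibble with `auc`, `auc_low`, `auc_high`, `auc_var`.
#' @export
roc_auc <- function(truth, score) {
  truth <- as.integer(truth)
  if (length(truth) != length(score)) {
    stop("`truth` and `score` must have equal length.", call. = FALSE)
  }
  if (length(unique(truth)) < 2) {
    stop("`truth` contains a single class; AUC undefined.", call. = FALSE)
  }
  roc <- pROC::roc(response = truth, predictor = score,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(pROC::ci.auc(roc, method = "delong"))
  tibble::tibble(
    auc = as.numeric(pROC::auc(roc)),
    auc_low = max(0, ci[1]),
    auc_high = min(1, ci[3]),
    auc_var = suppressWarnings(pROC::var(roc, method = "delong"))
  )
}

#' Compare two AUCs from independent samples
#'
#' Unpaired z-test on the difference of two AUCs using their DeLong
#' variances, for comparing the same classification task across two
#' independent participant groups. The caller is responsible for
#' independence; for correlated (same-sample) ROC curves this test does not
#' apply.
#'
#' @param auc_a,auc_b The two AUC estimates.
#' @param var_a,var_b Their DeLong variances.
#' @return A one-row tibble with `z` and two-sided `p`.
#' @export
compare_auc <- function(auc_a, var_a, auc_b, var_b) {
  stopifnot(var_a >= 0, var_b >= 0)
  diff <- auc_a - auc_b
  se <- sqrt(var_a + var_b)
  z <- if (se == 0) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else {
    diff / se
  }
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' MET error metrics
#'
#' Pooled MAE, MAPE (percent) and RMSE between estimated and true METs, each
#' with the SD of its per-minute components (absolute errors, absolute
#' percentage errors, root squared errors), and — when participant ids are
#' supplied — the mean and SD of the per-participant metric.
#'
#' @param true_mets Positive criterion METs.
#' @param est_mets Estimated METs, same length.
#' @param participant_ids Optional vector of participant ids for the
#'   per-participant summary.
#' @return A tibble with one row per metric (`mae`, `mape`, `rmse`):
#'   `overall`, `minute_sd`, `participant_mean`, `participant_sd`.
#' @export
error_metrics <- function(true_mets, est_mets, participant_ids = NULL) {
  if (length(true_mets) != length(est_mets)) {
    stop("`true_mets` and `est_mets` must have equal length.", call. = FALSE)
  }
  if (any(true_mets <= 0)) {
    stop("`true_mets` must be positive.", call. = FALSE)
  }
  d <- est_mets - true_mets
  per_minute <- list(
    mae = abs(d),
    mape = abs(d) / true_mets * 100,
    rmse = abs(d)  # root of the per-minute squared error
  )
  pooled <- c(mae = mean(abs(d)),
              mape = mean(abs(d) / true_mets) * 100,
              rmse = sqrt(mean(d^2)))
  out <- tibble::tibble(
    metric = names(pooled),
    overall = unname(pooled),
    minute_sd = vapply(per_minute, stats::sd, numeric(1))
  )
  if (!is.null(participant_ids)) {
    per_part <- tibble::tibble(id = participant_ids, t = true_mets,
                               e = est_mets) |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(
        mae = mean(abs(.data$e - .data$t)),
        mape = mean(abs(.data$e - .data$t) / .data$t) * 100,
        rmse = sqrt(mean((.data$e - .data$t)^2)),
        .groups = "drop"
      )
    out$participant_mean <- c(mean(per_part$mae), mean(per_part$mape),
                              mean(per_part$rmse))
    out$participant_sd <- c(stats::sd(per_part$mae), stats::sd(per_part$mape),
                            stats::sd(per_part$rmse))
  }
  out
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are taken as `estimated - true` by default. Bias is the mean
#' difference; the limits of agreement are `bias +/- 1.96 * SD` of the
#' differences (sample SD, n - 1). The midpoint of the limits always equals
#' the bias.
#'
#' @inheritParams error_metrics
#' @param direction `"est_minus_true"` (default) or `"true_minus_est"`.
#' @return A one-row tibble with `bias`, `loa_low`, `loa_high`, `sd_diff`.
#' @export
bland_altman <- function(true_mets, est_mets,
                         direction = c("est_minus_true", "true_minus_est")) {
  direction <- match.arg(direction)
  if (length(true_mets) != length(est_mets)) {
    stop("Inputs must have equal length.", call. = FALSE)
  }
  if (length(true_mets) < 2) {
    stop("Bland-Altman limits need at least 2 pairs.", call. = FALSE)
  }
  d <- if (direction == "est_minus_true") est_mets - true_mets
       else true_mets - est_mets
  bias <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measures intraclass
#' correlation between paired measurements, from the standard mean-squares
#' decomposition: with n pairs and k = 2 raters,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @inheritParams error_metrics
#' @return The ICC value (a single number, at most 1).
#' @export
icc21 <- function(true_mets, est_mets) {
  if (length(true_mets) != length(est_mets)) {
    stop("Inputs must have equal length.", call. = FALSE)
  }
  n <- length(true_mets)
  if (n < 2) stop("ICC needs at least 2 pairs.", call. = FALSE)
  ratings <- cbind(true_mets, est_mets)
  k <- 2
  grand <- mean(ratings)
  if (all(ratings == grand)) {
    stop("Zero total variance; ICC undefined.", call. = FALSE)
  }
  row_means <- rowMeans(ratings)
  col_means <- colMeans(ratings)
  ss_total <- sum((ratings - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_error / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation (average ranks for ties) between true and estimated
#' METs, with the p-value from the asymptotic t approximation.
#'
#' @inheritParams error_metrics
#' @return A one-row tibble with `rho` and `p`.
#' @export
spearman_corr <- function(true_mets, est_mets) {
  if (length(true_mets) != length(est_mets)) {
    stop("Inputs must have equal length.", call. = FALSE)
  }
  if (length(true_mets) < 3) {
    stop("Spearman correlation needs at least 3 pairs.", call. = FALSE)
  }
  if (stats::sd(true_mets) == 0 || stats::sd(est_mets) == 0) {
    stop("Constant input; Spearman correlation undefined.", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(true_mets, est_mets, method = "spearman", exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value)
}

#' Evaluate a fitted model on held-out minutes
#'
#' Runs the full validation battery on a test set: MET estimation for every
#' minute, one-vs-rest classification metrics (sensitivity, specificity,
#' Youden, AUC with DeLong interval) for SED, MVPA and VPA using the
#' continuous estimated MET as ROC score (negated for SED) and the
#' categorized estimate as the operating point, plus MAE/MAPE/RMSE,
#' Bland-Altman bias and limits of agreement, ICC(2,1) and Spearman
#' correlation. Test participants must be disjoint from the model's training
#' participants.
#'
#' @param model A fitted `met_model`.
#' @param minutes Test minutes: data frame with `participant_id`, `pa_avg`,
#'   `pa_var`, `steps`, `gender`, `bmi`, `true_met`.
#' @param group Optional group label carried into the report.
#' @return A `met_validation` object.
#' @export
evaluate_met_model <- function(model, minutes, group = NA_character_) {
  stopifnot(inherits(model, "met_model"))
  overlap <- intersect(unique(as.character(minutes$participant_id)),
                       model$train_participants)
  if (length(overlap) > 0) {
    stop("Participant leakage: test set shares participants with training (",
         paste(utils::head(overlap, 3), collapse = ", "),
         if (length(overlap) > 3) ", ..." else "", ").", call. = FALSE)
  }
  if (any(minutes$true_met <= 0)) {
    stop("`true_met` must be positive.", call. = FALSE)
  }
  thresholds <- do.call(met_thresholds, model$thresholds)
  pred <- estimate_mets(model, minutes)
  pred$true_met <- minutes$true_met

  classification <- purrr::map_dfr(c("SED", "MVPA", "VPA"), function(task) {
    truth <- binarize_by_category(pred$true_met, task, thresholds)
    pred_bin <- binarize_by_category(pred$estimated_met, task, thresholds)
    score <- if (task == "SED") -pred$estimated_met else pred$estimated_met
    dplyr::bind_cols(
      tibble::tibble(category = task),
      confusion_metrics(truth, pred_bin),
      roc_auc(truth, score)
    )
  })

  structure(
    list(
      group = group,
      n_participants = length(unique(minutes$participant_id)),
      n_minutes = nrow(pred),
      classification = classification,
      errors = error_metrics(pred$true_met, pred$estimated_met,
                             pred$participant_id),
      bland_altman = bland_altman(pred$true_met, pred$estimated_met),
      icc = icc21(pred$true_met, pred$estimated_met),
      spearman = spearman_corr(pred$true_met, pred$estimated_met),
      predictions = dplyr::select(
        pred, "participant_id", "true_met", "estimated_met",
        "predicted_class", "category"
      )
    ),
    class = "met_validation"
  )
}

#' Compare classification AUCs between two validation reports
#'
#' Per-category unpaired z-tests (DeLong variances) on the AUC difference
#' between two reports from independent participant groups.
#'
#' @param report_a,report_b `met_validation` objects.
#' @return A tibble with one row per category: both AUCs, `z`, `p`.
#' @export
compare_reports_auc <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "met_validation"),
            inherits(report_b, "met_validation"))
  a <- report_a$classification
  b <- report_b$classification
  purrr::map_dfr(a$category, function(cat) {
    ra <- a[a$category == cat, ]
    rb <- b[b$category == cat, ]
    dplyr::bind_cols(
      tibble::tibble(category = cat, auc_a = ra$auc, auc_b = rb$auc),
      compare_auc(ra$auc, ra$auc_var, rb$auc, rb$auc_var)
    )
  })
}

#' @export
print.met_validation <- function(x, ...) {
  cat("<met_validation>", if (!is.na(x$group)) paste0(" group: ", x$group),
      "\n  ", x$n_minutes, " minutes from ", x$n_participants,
      " participants\n\n", sep = "")
  cls <- x$classification
  cat("  Classification (operating point = categorized estimated METs):\n")
  for (i in seq_len(nrow(cls))) {
    cat(sprintf(
      "    %-4s sens %5.1f%% (%.1f-%.1f)  spec %5.1f%% (%.1f-%.1f)  J %.2f  AUC %.2f (%.2f-%.2f)\n",
      cls$category[i], 100 * cls$sensitivity[i], 100 * cls$sens_low[i],
      100 * cls$sens_high[i], 100 * cls$specificity[i], 100 * cls$spec_low[i],
      100 * cls$spec_high[i], cls$youden[i], cls$auc[i], cls$auc_low[i],
      cls$auc_high[i]))
  }
  err <- x$errors
  cat("\n  MET estimation:\n")
  for (i in seq_len(nrow(err))) {
    cat(sprintf("    %-5s %.2f +/- %.2f%s\n", toupper(err$metric[i]),
                err$overall[i], err$minute_sd[i],
                if (err$metric[i] == "mape") " %" else " METs"))
  }
  ba <- x$bland_altman
  cat(sprintf("    bias %.2f METs, 95%% LoA [%.2f, %.2f]\n",
              ba$bias, ba$loa_low, ba$loa_high))
  cat(sprintf("    ICC(2,1) %.2f, Spearman rho %.2f (p %s)\n", x$icc,
              x$spearman$rho, format.pval(x$spearman$p, digits = 2)))
  invisible(x)
}

#' @export
tidy.met_validation <- function(x, ...) {
  cls <- x$classification |>
    tidyr::pivot_longer(-"category", names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(panel = "classification", .before = 1)
  err <- x$errors |>
    tidyr::pivot_longer(-"metric", names_to = "summary",
                        values_to = "value") |>
    dplyr::transmute(panel = "agreement",
                     category = NA_character_,
                     metric = paste(.data$metric, .data$summary, sep = "_"),
                     value = .data$value)
  extra <- tibble::tibble(
    panel = "agreement", category = NA_character_,
    metric = c("bias", "loa_low", "loa_high", "icc", "spearman_rho",
               "spearman_p"),
    value = c(x$bland_altman$bias, x$bland_altman$loa_low,
              x$bland_altman$loa_high, x$icc, x$spearman$rho, x$spearman$p)
  )
  dplyr::bind_rows(cls, err, extra)
}

#' @export
glance.met_validation <- function(x, ...) {
  cls <- x$classification
  tibble::tibble(
    n_minutes = x$n_minutes,
    n_participants = x$n_participants,
    auc_sed = cls$auc[cls$category == "SED"],
    auc_mvpa = cls$auc[cls$category == "MVPA"],
    auc_vpa = cls$auc[cls$category == "VPA"],
    mae = x$errors$overall[x$errors$metric == "mae"],
    mape = x$errors$overall[x$errors$metric == "mape"],
    rmse = x$errors$overall[x$errors$metric == "rmse"],
    bias = x$bland_altman$bias,
    icc = x$icc,
    spearman_rho = x$spearman$rho
  )
}
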