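test_that("binarize_by_category applies the cut-points", {
  mets <- c(1.0, 2.0, 4.0, 7.0)
  expect_equal(binarize_by_category(mets, "SED"), c(1L, 0L, 0L, 0L))
  expect_equal(binarize_by_category(mets, "MVPA"), c(0L, 0L, 1L, 1L))
  expect_equal(binarize_by_category(mets, "VPA"), c(0L, 0L, 0L, 1L))
  expect_error(binarize_by_category(mets, "LPAx"))
  expect_error(binarize_by_category(c(-1, 2), "SED"), "positive")
})

test_that("confusion_metrics computes sens/spec/Youden with Wilson CIs", {
  truth <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  pred  <- c(1, 1, 1, 0, 0, 0, 0, 0, 1, 1)
  m <- confusion_metrics(truth, pred)
  expect_equal(m$sensitivity, 3 / 4)
  expect_equal(m$specificity, 4 / 6)
  expect_equal(m$youden, 3 / 4 + 4 / 6 - 1)
  wilson <- suppressWarnings(prop.test(3, 4, correct = FALSE))$conf.int
  expect_equal(c(m$sens_low, m$sens_high), as.numeric(wilson))

  perfect <- confusion_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$youden, 1)

  expect_error(confusion_metrics(c(1, 1, 1), c(1, 0, 1)), "single class")
})

test_that("J = sens + spec - 1 on every contingency table", {
  set.seed(31)
  for (i in 1:50) {
    truth <- rbinom(40, 1, 0.5)
    if (length(unique(truth)) < 2) next
    pred <- rbinom(40, 1, 0.5)
    m <- confusion_metrics(truth, pred)
    expect_equal(m$youden, m$sensitivity + m$specificity - 1)
  }
})

test_that("roc_auc matches closed forms and the concordance oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(2, 4))$auc, 0.5)
  # positives {3, 1}, negatives {2, 0}: 3 of 4 pairs concordant
  expect_equal(roc_auc(c(1, 1, 0, 0), c(3, 1, 2, 0))$auc, 0.75)
  expect_error(roc_auc(c(1, 1), c(0.3, 0.4)), "single class")

  set.seed(17)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(truth)) < 2) next
    score <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    expect_equal(roc_auc(truth, score)$auc, oracle_auc(truth, score),
                 tolerance = 1e-12)
  }
})

test_that("compare_auc is an unpaired z-test on the AUC difference", {
  same <- compare_auc(0.9, 0.001, 0.9, 0.001)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  # construct z = 1.96 exactly
  d <- 0.08
  v <- (d / 1.96)^2
  out <- compare_auc(0.9, v / 2, 0.82, v / 2)
  expect_equal(out$z, 1.96)
  expect_equal(out$p, 2 * pnorm(-1.96))
  expect_equal(out$p, 0.05, tolerance = 1e-3)
})

test_that("error metrics match hand computations", {
  zero <- error_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(zero$overall, c(0, 0, 0))

  m <- error_metrics(c(2, 4), c(3, 3))
  expect_equal(m$overall[m$metric == "mae"], 1)
  expect_equal(m$overall[m$metric == "rmse"], 1)
  expect_equal(m$overall[m$metric == "mape"], mean(c(1 / 2, 1 / 4)) * 100)

  m <- error_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m$overall[m$metric == "mae"], 2 / 3)
  expect_equal(m$overall[m$metric == "rmse"], sqrt(2 / 3))

  expect_error(error_metrics(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(error_metrics(c(0, 2), c(1, 2)), "positive")
})

test_that("per-participant error summaries match a direct computation", {
  true <- c(1, 2, 3, 4)
  est <- c(1.5, 2, 2, 5)
  ids <- c("a", "a", "b", "b")
  m <- error_metrics(true, est, ids)
  mae_a <- mean(c(0.5, 0)); mae_b <- mean(c(1, 1))
  expect_equal(m$participant_mean[m$metric == "mae"], mean(c(mae_a, mae_b)))
  expect_equal(m$participant_sd[m$metric == "mae"], sd(c(mae_a, mae_b)))
})

test_that("MAE never exceeds RMSE", {
  set.seed(9)
  for (i in 1:30) {
    n <- sample(5:100, 1)
    true <- runif(n, 0.5, 10)
    est <- true + rnorm(n, sd = runif(1, 0.01, 3))
    m <- error_metrics(true, est)
    expect_lte(m$overall[m$metric == "mae"],
               m$overall[m$metric == "rmse"] + 1e-12)
  }
})

test_that("bland_altman computes bias and 1.96-SD limits", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(same[c("bias", "loa_low", "loa_high")]),
               c(bias = 0, loa_low = 0, loa_high = 0))

  # differences -1, 0, 1: SD exactly 1
  ba <- bland_altman(c(2, 2, 2), c(1, 2, 3))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)

  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("limits of agreement are symmetric about the bias on all inputs", {
  set.seed(23)
  for (i in 1:30) {
    n <- sample(3:200, 1)
    true <- runif(n, 0.5, 10)
    est <- true + rnorm(n, mean = runif(1, -1, 1), sd = runif(1, 0.01, 2))
    ba <- bland_altman(true, est)
    expect_equal((ba$loa_low + ba$loa_high) / 2, ba$bias, tolerance = 1e-12)
    expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff,
                 tolerance = 1e-12)
  }
})

test_that("icc21 matches the variance-components oracle", {
  a <- c(9, 6, 8, 7, 10, 6)
  b <- c(2, 1, 4, 1, 5, 2)
  expect_equal(icc21(a, b), oracle_icc21(a, b), tolerance = 1e-10)

  x <- c(1, 2, 3, 4, 5)
  expect_equal(icc21(x, x), 1)

  # absolute agreement: a constant shift lowers the ICC, more with larger shift
  icc_shift <- function(c) icc21(x, x + c)
  expect_lt(icc_shift(0.5), 1)
  expect_lt(icc_shift(2), icc_shift(0.5))
  expect_lt(icc_shift(4), icc_shift(2))

  expect_error(icc21(rep(2, 4), rep(2, 4)), "Zero total variance")
})

test_that("icc21 equals the oracle on random pairings", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(4:60, 1)
    a <- rnorm(n, 5, 2)
    b <- a + rnorm(n, 0.3, runif(1, 0.1, 2))
    expect_equal(icc21(a, b), oracle_icc21(a, b), tolerance = 1e-10)
  }
})

test_that("spearman_corr is a rank correlation with monotone invariance", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(spearman_corr(x, x * 2 + 1)$rho, 1)
  expect_equal(spearman_corr(x, -x)$rho, -1)

  set.seed(6)
  a <- runif(50, 1, 9)
  b <- a + rnorm(50)
  expect_equal(spearman_corr(a, b)$rho, spearman_corr(exp(a), b)$rho)
  expect_equal(spearman_corr(a, b)$rho, spearman_corr(a, b^3)$rho)

  expect_error(spearman_corr(rep(1, 5), 1:5), "Constant")
  expect_error(spearman_corr(1:2, 2:1), "at least 3")
})

test_that("evaluate_met_model runs the full battery on noiseless data", {
  train <- make_noiseless_minutes(sprintf("T%02d", 1:10))
  test <- make_noiseless_minutes(sprintf("H%02d", 1:4))
  model <- fit_met_model(train, seed = 3)
  report <- suppressWarnings(evaluate_met_model(model, test, group = "adult"))

  expect_equal(report$classification$auc, c(1, 1, 1))
  expect_lte(report$errors$overall[report$errors$metric == "mae"], 0.1)
  expect_equal(report$n_minutes, nrow(test))
  expect_equal(report$n_participants, 4)

  # training participants in the test set -> leakage error
  expect_error(evaluate_met_model(model, train[1:30, ]), "leakage")
})

test_that("shuffled estimates give chance-level AUC", {
  set.seed(77)
  true_mets <- runif(600, 0.8, 9)
  shuffled <- sample(true_mets)
  truth <- binarize_by_category(true_mets, "MVPA")
  expect_lt(abs(roc_auc(truth, shuffled)$auc - 0.5), 0.07)
})

test_that("report comparison, tidiers and plots work end to end", {
  train_a <- make_noiseless_minutes(sprintf("T%02d", 1:8))
  test_a <- make_noiseless_minutes(sprintf("H%02d", 1:3))
  model <- fit_met_model(train_a, seed = 1)
  rep_a <- suppressWarnings(evaluate_met_model(model, test_a, group = "adult"))

  study <- simulate_study(6, "child", seed = 3)
  minutes <- study_minutes(study)
  model_b <- fit_met_model(dplyr::filter(minutes, split == "train"), seed = 3,
                           c_grid = c(1, 100))
  rep_b <- suppressWarnings(evaluate_met_model(
    model_b, dplyr::filter(minutes, split == "test"), group = "child"))

  cmp <- compare_reports_auc(rep_a, rep_b)
  expect_equal(cmp$category, c("SED", "MVPA", "VPA"))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))

  td <- tidy(rep_b)
  expect_true(all(c("panel", "metric", "value") %in% names(td)))
  gl <- glance(rep_b)
  expect_true(all(c("auc_sed", "mae", "icc", "spearman_rho") %in% names(gl)))

  expect_s3_class(plot_bland_altman(rep_b), "ggplot")
  expect_s3_class(plot_roc(rep_b), "ggplot")
  expect_s3_class(autoplot(rep_b, "scatter"), "ggplot")
})
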