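test_that("met_to_category maps the published MET means and interval edges", {
  expect_equal(as.character(met_to_category(c(1.01, 2.23, 3.66, 9.40))),
               c("SED", "LPA", "MPA", "VPA"))
  expect_equal(as.character(met_to_category(c(1.49, 1.50, 2.99, 3.00, 5.99, 6.00))),
               c("SED", "LPA", "LPA", "MPA", "MPA", "VPA"))
  expect_error(met_to_category(0), "positive")
  expect_error(met_to_category(-1), "positive")
})

test_that("met_to_category is a monotone partition", {
  set.seed(14)
  mets <- sort(runif(500, 0.01, 12))
  cats <- met_to_category(mets)
  expect_false(is.unsorted(cats))          # ordered factor, monotone
  expect_false(anyNA(cats))                # total on (0, Inf)
})

test_that("category_to_class3 collapses MPA and VPA into MVPA", {
  expect_equal(as.character(category_to_class3(c("SED", "LPA", "MPA", "VPA"))),
               c("SED", "LPA", "MVPA", "MVPA"))
  expect_error(category_to_class3("HARD"), "Unknown")
})

test_that("featurize applies log1p and codes gender", {
  minutes <- tibble::tibble(pa_avg = c(0, exp(1) - 1), pa_var = c(0, 2),
                            steps = c(0L, 30L),
                            gender = c("female", "male"), bmi = c(20, 25))
  f <- featurize(minutes)
  expect_equal(f$log_pa_avg, c(0, 1))
  expect_equal(f$log_pa_var, log1p(c(0, 2)))
  expect_equal(f$log_steps, log1p(c(0, 30)))
  expect_equal(f$gender_code, c(0, 1))
  expect_identical(featurize(minutes), f)  # pure

  minutes$pa_avg[1] <- -0.1
  expect_error(featurize(minutes), "non-negative")
})

test_that("training recovers a noiseless linear generative model exactly", {
  train <- make_noiseless_minutes(sprintf("T%02d", 1:10))
  test <- make_noiseless_minutes(sprintf("H%02d", 1:4))
  model <- fit_met_model(train, seed = 3)

  est <- estimate_mets(model, test)
  expect_lte(mean(abs(est$estimated_met - test$true_met)), 0.1)

  # predicted classes agree with the true classes on separable data
  truth <- category_to_class3(met_to_category(test$true_met))
  expect_gt(mean(est$predicted_class == truth), 0.99)
})

test_that("per-class regressors equal the normal-equations solve", {
  study <- simulate_study(8, "adult", seed = 5)
  minutes <- dplyr::filter(study_minutes(study), split == "train")
  model <- fit_met_model(minutes, seed = 2)

  feats <- featurize(minutes)
  labels <- category_to_class3(met_to_category(minutes$true_met))
  for (nm in c("log_pa_avg", "log_pa_var", "log_steps", "bmi")) {
    feats[[nm]] <- (feats[[nm]] - model$center[[nm]]) / model$scale[[nm]]
  }
  X <- as.matrix(feats[c("log_pa_avg", "log_pa_var", "log_steps",
                         "gender_code", "bmi")])
  for (cl in c("SED", "LPA", "MVPA")) {
    sel <- labels == cl
    expect_equal(unname(model$regressors[[cl]]),
                 unname(oracle_ols(X[sel, ], minutes$true_met[sel])),
                 tolerance = 1e-8)
  }
})

test_that("training is deterministic and validates its contract", {
  train <- make_noiseless_minutes(sprintf("T%02d", 1:6))
  m1 <- fit_met_model(train, seed = 11)
  m2 <- fit_met_model(train, seed = 11)
  expect_identical(m1$regressors, m2$regressors)
  expect_identical(m1$svm, m2$svm)
  expect_identical(m1$C, m2$C)

  sed_only <- dplyr::filter(train, true_met <= 1.49)
  expect_error(fit_met_model(sed_only, seed = 1), "LPA")

  one_participant <- dplyr::filter(train, participant_id == "T01")
  expect_error(fit_met_model(one_participant, seed = 1),
               "at least 2 participants")
})

test_that("parameter recovery: coefficients lie within 3 SE of truth", {
  # generating model inside the MVPA range: met = 3 + 2*log_pa_avg + 0.05*bmi
  set.seed(20)
  n <- 400
  pa <- runif(n, 1.5, 6)
  minutes <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:10), each = n / 10),
    pa_avg = pa,
    pa_var = runif(n, 0, 4),
    steps = as.integer(rpois(n, 12)),
    gender = sample(c("male", "female"), n, replace = TRUE),
    bmi = runif(n, 18, 30),
    true_met = 3 + 2 * log1p(pa) + 0.05 * runif(n, 18, 30)
  )
  # rebuild true_met so bmi is the actual covariate, plus small noise
  minutes$true_met <- 3 + 2 * log1p(minutes$pa_avg) + 0.05 * minutes$bmi +
    rnorm(n, 0, 0.05)
  # anchor SED and LPA (all below 3 METs) so training is legal without
  # contaminating the MVPA regressor with a second generating law
  anchors <- make_noiseless_minutes(c("A1", "A2"),
                                    pa_grid = c(0, 0.05, 0.10, 0.30, 0.45))
  model <- fit_met_model(dplyr::bind_rows(minutes, anchors), seed = 4)

  # back-transform the MVPA regressor to the raw log/bmi scale
  b <- model$regressors$MVPA
  raw_slope_pa <- b[["log_pa_avg"]] / model$scale[["log_pa_avg"]]
  raw_slope_bmi <- b[["bmi"]] / model$scale[["bmi"]]

  mv <- dplyr::filter(dplyr::bind_rows(minutes, anchors), true_met >= 3)
  fit <- lm(true_met ~ log1p(pa_avg) + log1p(pa_var) + log1p(steps) +
              I(gender == "male") + bmi, data = mv)
  se <- summary(fit)$coefficients[, "Std. Error"]
  expect_lt(abs(raw_slope_pa - 2), 3 * se[["log1p(pa_avg)"]])
  expect_lt(abs(raw_slope_bmi - 0.05), 3 * se[["bmi"]])
})

test_that("estimates clamp at the MET floor and stay category-consistent", {
  train <- make_noiseless_minutes(sprintf("T%02d", 1:6))
  model <- fit_met_model(train, seed = 8)

  # force a negative regression output
  forced <- model
  for (cl in names(forced$regressors)) {
    forced$regressors[[cl]][] <- 0
    forced$regressors[[cl]][["(intercept)"]] <- -0.3
  }
  newdata <- train[1:5, ]
  est <- estimate_mets(forced, newdata)
  expect_true(all(est$estimated_met == 0.5))

  est <- estimate_mets(model, make_noiseless_minutes("H1"))
  expect_equal(est$category, met_to_category(est$estimated_met))

  expect_error(estimate_mets(list(), newdata), "met_model")
})

test_that("model JSON round trip preserves estimates exactly", {
  train <- make_noiseless_minutes(sprintf("T%02d", 1:6))
  model <- fit_met_model(train, seed = 15)
  path <- withr::local_tempfile(fileext = ".json")
  save_met_model(model, path)
  restored <- load_met_model(path)

  set.seed(30)
  newdata <- tibble::tibble(
    pa_avg = runif(100, 0, 7), pa_var = runif(100, 0, 10),
    steps = as.integer(rpois(100, 8)),
    gender = sample(c("male", "female"), 100, replace = TRUE),
    bmi = runif(100, 15, 35)
  )
  expect_identical(estimate_mets(model, newdata)$estimated_met,
                   estimate_mets(restored, newdata)$estimated_met)
  expect_identical(estimate_mets(model, newdata)$predicted_class,
                   estimate_mets(restored, newdata)$predicted_class)

  corrupt <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", corrupt)
  expect_error(load_met_model(corrupt), "parse")

  unversioned <- withr::local_tempfile(fileext = ".json")
  writeLines('{"classes": ["SED"]}', unversioned)
  expect_error(load_met_model(unversioned), "schema_version")
})

test_that("more generator noise never helps classification accuracy", {
  acc_at <- function(jitter, seeds) {
    vapply(seeds, function(s) {
      study <- simulate_study(6, "adult", seed = s, jitter_sd = jitter)
      minutes <- study_minutes(study)
      tr <- dplyr::filter(minutes, split == "train")
      te <- dplyr::filter(minutes, split == "test")
      model <- fit_met_model(tr, seed = s, c_grid = c(1, 100))
      est <- estimate_mets(model, te)
      truth <- category_to_class3(met_to_category(te$true_met))
      mean(vapply(levels(truth), function(cl) {
        sel <- truth == cl
        if (!any(sel)) return(NA_real_)
        mean(est$predicted_class[sel] == cl)
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
  }
  seeds <- 1:5
  low <- mean(acc_at(0.02, seeds))
  high <- mean(acc_at(0.5, seeds))
  expect_lte(high, low + 0.05)  # Monte-Carlo jitter allowance
})

test_that("tidy and glance summarize a fitted model", {
  model <- fit_met_model(make_noiseless_minutes(sprintf("T%02d", 1:6)),
                         seed = 2)
  td <- tidy(model)
  expect_equal(nrow(td), 3 * 6)  # 3 classes x (intercept + 5 features)
  gl <- glance(model)
  expect_equal(gl$n_participants, 6)
  expect_true(gl$C %in% c(0.01, 0.1, 1, 10, 100))
})
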