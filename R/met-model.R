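#' MET intensity cut-points
#'
#' The standard MET thresholds separating sedentary (SED, 0-1.49 METs),
#' light (LPA, 1.50-2.99), moderate (MPA, 3.00-5.99) and vigorous (VPA,
#' >= 6.00) physical activity. `sed_max` is the inclusive upper bound of SED;
#' `mvpa_min` and `vpa_min` are the inclusive lower bounds of MPA and VPA.
#'
#' @param sed_max,mvpa_min,vpa_min Cut-points in METs; must be strictly
#'   increasing.
#' @return A `met_thresholds` list.
#' @export
met_thresholds <- function(sed_max = 1.49, mvpa_min = 3.00, vpa_min = 6.00) {
  if (!(sed_max < mvpa_min && mvpa_min < vpa_min)) {
    stop("Thresholds must be strictly increasing.", call. = FALSE)
  }
  structure(list(sed_max = sed_max, mvpa_min = mvpa_min, vpa_min = vpa_min),
            class = "met_thresholds")
}

pa_categories <- function() c("SED", "LPA", "MPA", "VPA")
pa_classes3 <- function() c("SED", "LPA", "MVPA")

#' Categorize METs into intensity levels
#'
#' Interval lookup of MET values against the intensity cut-points:
#' `met <= sed_max` is SED, `met < mvpa_min` is LPA, `met < vpa_min` is MPA,
#' anything above is VPA. The categories partition (0, Inf) and the mapping
#' is monotone.
#'
#' @param met Numeric vector of positive MET values.
#' @param thresholds A [met_thresholds()] object.
#' @return A factor with ordered levels SED < LPA < MPA < VPA.
#' @export
#' @examples
#' met_to_category(c(1.01, 2.23, 3.66, 9.40))
met_to_category <- function(met, thresholds = met_thresholds()) {
  if (!is.numeric(met) || any(!is.finite(met)) || any(met <= 0)) {
    stop("`met` must be positive finite values.", call. = FALSE)
  }
  out <- ifelse(met <= thresholds$sed_max, "SED",
         ifelse(met < thresholds$mvpa_min, "LPA",
         ifelse(met < thresholds$vpa_min, "MPA", "VPA")))
  factor(out, levels = pa_categories(), ordered = TRUE)
}

#' Collapse four intensity categories to the three classifier classes
#'
#' The classifier works on three classes: SED, LPA and MVPA, where MVPA
#' merges moderate and vigorous activity.
#'
#' @param category Character or factor of SED/LPA/MPA/VPA values.
#' @return A factor with levels SED, LPA, MVPA.
#' @export
category_to_class3 <- function(category) {
  category <- as.character(category)
  bad <- setdiff(unique(category), pa_categories())
  if (length(bad) > 0) {
    stop("Unknown categories: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- ifelse(category %in% c("MPA", "VPA"), "MVPA", category)
  factor(out, levels = pa_classes3())
}

model_feature_names <- function() {
  c("log_pa_avg", "log_pa_var", "log_steps", "gender_code", "bmi")
}

continuous_feature_names <- function() {
  c("log_pa_avg", "log_pa_var", "log_steps", "bmi")
}

#' Build the model feature columns
#'
#' Adds the model's five predictors to a minutes table: `log(1 + x)` of the
#' three watch features (`log1p` keeps the exactly-zero sedentary minutes
#' finite), a male=1/female=0 gender code, and BMI passed through.
#' Featurization is pure and deterministic; standardization happens inside
#' the fitted model using training-set constants.
#'
#' @param minutes A data frame with columns `pa_avg`, `pa_var`, `steps`,
#'   `gender`, `bmi`.
#' @return The input tibble with columns `log_pa_avg`, `log_pa_var`,
#'   `log_steps`, `gender_code` added (`bmi` is already present).
#' @export
featurize <- function(minutes) {
  missing <- setdiff(c("pa_avg", "pa_var", "steps", "gender", "bmi"),
                     names(minutes))
  if (length(missing) > 0) {
    stop("`minutes` is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw <- c(minutes$pa_avg, minutes$pa_var, minutes$steps)
  if (any(!is.finite(raw)) || any(raw < 0)) {
    stop("Raw features must be finite and non-negative.", call. = FALSE)
  }
  if (!all(minutes$gender %in% c("male", "female"))) {
    stop("`gender` must be \"male\" or \"female\".", call. = FALSE)
  }
  dplyr::mutate(
    tibble::as_tibble(minutes),
    log_pa_avg = log1p(.data$pa_avg),
    log_pa_var = log1p(.data$pa_var),
    log_steps = log1p(.data$steps),
    gender_code = as.numeric(.data$gender == "male")
  )
}

standardize_features <- function(feats, center, scale) {
  for (nm in names(center)) {
    feats[[nm]] <- (feats[[nm]] - center[[nm]]) / scale[[nm]]
  }
  feats
}

# Fit one binary linear SVM (positive class vs rest) and extract the
# hyperplane so prediction and serialization are plain linear algebra.
fit_ovr_svm <- function(x, positive, cost) {
  y <- factor(ifelse(positive, "yes", "no"), levels = c("yes", "no"))
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm orients the decision value toward whichever label appears first in
  # the training data; read the orientation off the decision-value column name
  dv <- stats::predict(fit, x[1, , drop = FALSE], decision.values = TRUE)
  if (identical(colnames(attr(dv, "decision.values")), "no/yes")) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

svm_decision_matrix <- function(x, hyperplanes) {
  scores <- vapply(hyperplanes, function(h) drop(x %*% h$w + h$b),
                   numeric(nrow(x)))
  matrix(scores, nrow = nrow(x),
         dimnames = list(NULL, names(hyperplanes)))
}

predict_class3 <- function(x, hyperplanes) {
  scores <- svm_decision_matrix(x, hyperplanes)
  cls <- colnames(scores)[max.col(scores, ties.method = "first")]
  factor(cls, levels = pa_classes3())
}

macro_accuracy <- function(truth, pred) {
  mean(vapply(levels(truth), function(cl) {
    sel <- truth == cl
    if (!any(sel)) return(NA_real_)
    mean(pred[sel] == cl)
  }, numeric(1)), na.rm = TRUE)
}

make_grouped_folds <- function(ids, n_folds) {
  unique_ids <- unique(ids)
  shuffled <- sample(unique_ids)
  fold_of <- rep(seq_len(n_folds), length.out = length(shuffled))
  lapply(seq_len(n_folds), function(f) ids %in% shuffled[fold_of == f])
}

ols_coefficients <- function(x, y) {
  X <- cbind(`(intercept)` = 1, x)
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0  # rank-deficient columns contribute nothing
  coefs
}

#' Fit the hierarchical MET-estimation model
#'
#' The two-stage estimator: a linear-kernel support vector machine classifies
#' each minute as SED, LPA or MVPA (one-vs-rest; regularization constant C
#' chosen by grid search with participant-grouped 5-fold cross-validation
#' maximizing macro accuracy), then one ordinary least-squares regression per
#' true intensity class maps the five features (log pa_avg, log pa_var,
#' log steps, gender, BMI) to METs. Continuous features are standardized with
#' training-set constants that are stored in the model. Regressors are
#' trained on true-class instances; at prediction time the predicted class
#' routes each minute to its regressor.
#'
#' @param minutes Training minutes: a data frame with columns
#'   `participant_id`, `pa_avg`, `pa_var`, `steps`, `gender`, `bmi`,
#'   `true_met`. At least 2 participants and all three intensity classes must
#'   be present.
#' @param seed Integer seed controlling fold assignment.
#' @param c_grid Candidate values of the SVM cost parameter C.
#' @param n_folds Number of cross-validation folds (grouped by participant).
#' @param thresholds [met_thresholds()] used to derive class labels from
#'   `true_met`.
#' @param met_floor Lower clamp for estimated METs, in METs. Default 0.5.
#' @return A `met_model` object.
#' @export
fit_met_model <- function(minutes, seed = 1L,
                          c_grid = c(0.01, 0.1, 1, 10, 100),
                          n_folds = 5L,
                          thresholds = met_thresholds(),
                          met_floor = 0.5) {
  required <- c("participant_id", "pa_avg", "pa_var", "steps", "gender",
                "bmi", "true_met")
  missing <- setdiff(required, names(minutes))
  if (length(missing) > 0) {
    stop("Training data is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(unique(minutes$participant_id)) < 2) {
    stop("Training requires at least 2 participants.", call. = FALSE)
  }
  if (any(minutes$true_met <= 0)) {
    stop("`true_met` must be positive.", call. = FALSE)
  }

  feats <- featurize(minutes)
  labels <- category_to_class3(met_to_category(feats$true_met, thresholds))
  absent <- setdiff(pa_classes3(), levels(droplevels(labels)))
  if (length(absent) > 0) {
    stop("Training data has no instances of class ",
         paste(absent, collapse = ", "),
         "; all of SED, LPA and MVPA must be represented.", call. = FALSE)
  }

  cont <- continuous_feature_names()
  center <- vapply(feats[cont], mean, numeric(1))
  scale <- vapply(feats[cont], stats::sd, numeric(1))
  scale[scale == 0 | !is.finite(scale)] <- 1
  feats_std <- standardize_features(feats, center, scale)
  X <- as.matrix(feats_std[model_feature_names()])

  set.seed(seed)
  folds <- make_grouped_folds(feats$participant_id, n_folds)
  cv <- purrr::map_dfr(c_grid, function(cost) {
    scores <- vapply(folds, function(hold) {
      tr_lab <- droplevels(labels[!hold])
      if (nlevels(tr_lab) < 3 || !any(hold)) return(NA_real_)
      planes <- lapply(stats::setNames(nm = pa_classes3()), function(cl) {
        fit_ovr_svm(X[!hold, , drop = FALSE], labels[!hold] == cl, cost)
      })
      pred <- predict_class3(X[hold, , drop = FALSE], planes)
      macro_accuracy(labels[hold], pred)
    }, numeric(1))
    tibble::tibble(C = cost, cv_macro_accuracy = mean(scores, na.rm = TRUE))
  })
  best_c <- cv$C[which.max(cv$cv_macro_accuracy)]

  hyperplanes <- lapply(stats::setNames(nm = pa_classes3()), function(cl) {
    fit_ovr_svm(X, labels == cl, best_c)
  })

  regressors <- lapply(stats::setNames(nm = pa_classes3()), function(cl) {
    sel <- labels == cl
    ols_coefficients(X[sel, , drop = FALSE], feats$true_met[sel])
  })

  structure(
    list(
      schema_version = "metwatch-model/1",
      classes = pa_classes3(),
      feature_names = model_feature_names(),
      center = center,
      scale = scale,
      svm = hyperplanes,
      C = best_c,
      cv = cv,
      regressors = regressors,
      thresholds = unclass(thresholds),
      met_floor = met_floor,
      n_minutes = nrow(minutes),
      train_participants = sort(unique(as.character(minutes$participant_id))),
      seed = as.integer(seed)
    ),
    class = "met_model"
  )
}

#' @export
print.met_model <- function(x, ...) {
  cat("<met_model> linear-SVM + per-class least squares\n",
      "  trained on ", x$n_minutes, " minutes from ",
      length(x$train_participants), " participants\n",
      "  C = ", x$C, " (CV macro accuracy ",
      sprintf("%.3f", max(x$cv$cv_macro_accuracy)), ")\n", sep = "")
  invisible(x)
}

#' Estimate METs for new minutes
#'
#' Runs the hierarchical model on featurized minutes: the SVM predicts the
#' intensity class, the predicted class's least-squares regressor produces
#' the MET estimate (clamped below at the model's floor), and the estimate is
#' categorized with the intensity cut-points.
#'
#' @param model A fitted `met_model`.
#' @param minutes A data frame with columns `pa_avg`, `pa_var`, `steps`,
#'   `gender`, `bmi`.
#' @return The input tibble with columns `predicted_class`, `estimated_met`
#'   and `category` appended.
#' @export
estimate_mets <- function(model, minutes) {
  if (!inherits(model, "met_model")) {
    stop("`model` must be a fitted met_model.", call. = FALSE)
  }
  feats <- featurize(minutes) |>
    standardize_features(model$center, model$scale)
  X <- as.matrix(feats[model$feature_names])
  cls <- predict_class3(X, model$svm)
  Xd <- cbind(`(intercept)` = 1, X)
  est <- vapply(seq_len(nrow(X)), function(i) {
    drop(Xd[i, ] %*% model$regressors[[as.character(cls[i])]])
  }, numeric(1))
  est <- pmax(est, model$met_floor)
  dplyr::mutate(
    tibble::as_tibble(minutes),
    predicted_class = cls,
    estimated_met = est,
    category = met_to_category(est, do.call(met_thresholds, model$thresholds))
  )
}

#' @export
predict.met_model <- function(object, newdata, ...) {
  estimate_mets(object, newdata)
}

#' Save / load a fitted model as versioned JSON
#'
#' The model file stores the schema id, standardization constants, SVM
#' hyperplanes and chosen C, per-class regression coefficients and the
#' thresholds, at full floating-point precision so a save/load round trip
#' reproduces estimates exactly.
#'
#' @param model A `met_model`.
#' @param path File path for the JSON model file.
#' @return `save_met_model()` returns `path` invisibly; `load_met_model()`
#'   returns the restored `met_model`.
#' @export
save_met_model <- function(model, path) {
  stopifnot(inherits(model, "met_model"))
  # coefficients serialize as %.17g strings: 17 significant digits
  # round-trip IEEE doubles exactly, which plain JSON numbers do not
  num17 <- function(x) {
    out <- as.list(sprintf("%.17g", x))
    names(out) <- names(x)
    out
  }
  payload <- unclass(model)
  payload$cv <- as.list(model$cv)
  payload$center <- num17(model$center)
  payload$scale <- num17(model$scale)
  payload$svm <- lapply(model$svm, function(h)
    list(w = num17(h$w), b = sprintf("%.17g", h$b)))
  payload$regressors <- lapply(model$regressors, num17)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_met_model
#' @export
load_met_model <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop("Cannot parse model file: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(payload$schema_version)) {
    stop("Model file has no schema_version field.", call. = FALSE)
  }
  if (!identical(payload$schema_version, "metwatch-model/1")) {
    stop("Unsupported model schema: ", payload$schema_version, call. = FALSE)
  }
  renum <- function(x) {
    out <- as.numeric(unlist(x))
    names(out) <- names(x)
    out
  }
  payload$svm <- lapply(payload$svm, function(h) {
    list(w = renum(h$w), b = as.numeric(h$b))
  })
  payload$regressors <- lapply(payload$regressors, renum)
  payload$center <- renum(payload$center)
  payload$scale <- renum(payload$scale)
  payload$cv <- tibble::as_tibble(payload$cv)
  payload$thresholds <- as.list(payload$thresholds)
  structure(payload, class = "met_model")
}

#' @export
tidy.met_model <- function(x, ...) {
  purrr::map_dfr(names(x$regressors), function(cl) {
    tibble::tibble(
      class = cl,
      term = names(x$regressors[[cl]]),
      estimate = unname(x$regressors[[cl]])
    )
  })
}

#' @export
glance.met_model <- function(x, ...) {
  tibble::tibble(
    n_minutes = x$n_minutes,
    n_participants = length(x$train_participants),
    C = x$C,
    cv_macro_accuracy = max(x$cv$cv_macro_accuracy)
  )
}
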