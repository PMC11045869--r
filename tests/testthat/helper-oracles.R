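# Independent brute-force oracles used to check the package implementations.
# These are deliberately naive (explicit loops, closed forms) and share no
# code with the package internals.

oracle_mean_abs_diff <- function(x) {
  total <- 0
  for (i in 2:length(x)) total <- total + abs(x[i] - x[i - 1])
  total / (length(x) - 1)
}

oracle_pa_var <- function(x, pa_avg) {
  total <- 0
  for (i in 2:length(x)) total <- total + (abs(x[i] - x[i - 1]) - pa_avg)^2
  total / (length(x) - 1)
}

# AUC as pairwise concordance over all positive-negative pairs, ties 1/2
oracle_auc <- function(truth, score) {
  pos <- score[truth == 1]
  neg <- score[truth == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# OLS by explicit normal equations; rank-deficient columns (e.g. a feature
# constant within one intensity class) get coefficient 0, mirroring the
# pivoting convention of the implementation
oracle_ols <- function(X, y) {
  Xd <- cbind(1, X)
  qrd <- qr(Xd)
  keep <- qrd$pivot[seq_len(qrd$rank)]
  beta <- rep(0, ncol(Xd))
  Xk <- Xd[, keep, drop = FALSE]
  beta[keep] <- drop(solve(t(Xk) %*% Xk, t(Xk) %*% y))
  beta
}

# ICC(2,1) from explicit sums of squares (n pairs, 2 raters)
oracle_icc21 <- function(a, b) {
  ratings <- cbind(a, b)
  n <- nrow(ratings); k <- 2
  grand <- mean(ratings)
  msr <- k * sum((rowMeans(ratings) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(ratings) - grand)^2) / (k - 1)
  sse <- sum((ratings - grand)^2) -
    k * sum((rowMeans(ratings) - grand)^2) -
    n * sum((colMeans(ratings) - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

make_window <- function(ax, ay = rep(0, 120), az = rep(0, 120)) {
  tibble::tibble(t = seq(0, 59.5, by = 0.5), ax = ax, ay = ay, az = az)
}

# Minutes table on which true METs are an exact linear function of
# log1p(pa_avg) (met = 1 + 4 * log1p(pa_avg)) and the three intensity
# classes are linearly separable; other features vary non-collinearly so
# the per-class OLS designs are full rank.
make_noiseless_minutes <- function(participant_ids, reps = 2,
                                   pa_grid = c(0, 0.05, 0.10, 0.30, 0.45,
                                               0.90, 1.70, 3.50, 6.40)) {
  purrr::map_dfr(seq_along(participant_ids), function(i) {
    pa <- rep(pa_grid, reps)
    tibble::tibble(
      participant_id = participant_ids[i],
      pa_avg = pa,
      pa_var = pa^2,
      steps = as.integer(round(20 * pa)),
      gender = ifelse(i %% 2 == 0, "male", "female"),
      bmi = 19 + 0.5 * i,
      true_met = 1 + 4 * log1p(pa)
    )
  })
}
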