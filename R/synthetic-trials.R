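#' Built-in sequential activity protocol
#'
#' The seven-activity sequential trial used for calibration studies of this
#' kind, from sedentary to vigorous: sitting, standing still, slow walking,
#' quick walking, ascending/descending stairs, jogging, and running or rope
#' skipping. Children's protocols exclude jogging (it proved too variable for
#' that age group), leaving six activities. Each activity carries the
#' group-specific criterion MET distribution (mean and SD of
#' calorimetry-measured METs) and a nominal cadence driving the accelerometer
#' synthesizer.
#'
#' Cadences are chosen to be realistic for each activity while avoiding
#' multiples of 120 steps/min, which a 2 Hz sampler cannot see.
#'
#' @param group `"adult"` or `"child"`.
#' @return A tibble with columns `activity`, `nominal_intensity`, `met_mean`,
#'   `met_sd`, `cadence`.
#' @export
activity_protocol <- function(group = c("adult", "child")) {
  group <- match.arg(group)
  base <- tibble::tribble(
    ~activity,        ~nominal_intensity, ~adult_mean, ~adult_sd, ~child_mean, ~child_sd, ~cadence,
    "sitting",        "SED",              1.01,        0.13,      1.04,        0.19,      0,
    "standing_still", "SED",              1.11,        0.19,      1.19,        0.42,      0,
    "slow_walking",   "LPA",              2.23,        0.62,      2.52,        0.80,      100,
    "quick_walking",  "MPA",              3.66,        1.14,      3.56,        1.32,      110,
    "stairs",         "MPA",              5.30,        1.89,      6.01,        2.18,      105,
    "jogging",        "VPA",              6.41,        2.38,      NA,          NA,        130,
    "run_rope_skip",  "VPA",              9.40,        3.74,      6.68,        2.58,      155
  )
  if (group == "adult") {
    out <- dplyr::transmute(base, .data$activity, .data$nominal_intensity,
                            met_mean = .data$adult_mean, met_sd = .data$adult_sd,
                            .data$cadence)
  } else {
    out <- base |>
      dplyr::filter(.data$activity != "jogging") |>
      dplyr::transmute(.data$activity, .data$nominal_intensity,
                       met_mean = .data$child_mean, met_sd = .data$child_sd,
                       .data$cadence)
  }
  out
}

# group-level anthropometry used by the participant simulator
group_demographics <- function(group) {
  switch(group,
    adult = list(age_range = c(21, 34), age_mean = 24.9, age_sd = 2.6,
                 height_mean = 169.2, height_sd = 7.2,
                 weight_mean = 61.7, weight_sd = 8.7),
    child = list(age_range = c(9, 13), age_mean = 12.3, age_sd = 1.0,
                 height_mean = 160.5, height_sd = 10.3,
                 weight_mean = 52.6, weight_sd = 12.5),
    stop("unknown group: ", group, call. = FALSE)
  )
}

# Truncated-normal draws by rejection; deterministic under the caller's seed.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# derive a reproducible 32-bit sub-seed from a master seed and stream indices
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.numeric(master) %% 2147483647
  for (k in idx) {
    s <- (s * 16807 + as.numeric(k) * 2654435 + 1) %% 2147483647
  }
  as.integer(s)
}

#' Simulate a participant table
#'
#' Draws demographics for one group from truncated normal distributions
#' calibrated to the study populations (adults: height 169.2 +/- 7.2 cm,
#' weight 61.7 +/- 8.7 kg, age 21-34; children: height 160.5 +/- 10.3 cm,
#' weight 52.6 +/- 12.5 kg, age 9-13). Gender is balanced (males first when
#' `n` is odd). BMI is derived as weight / (height in m)^2.
#'
#' @param n Number of participants (>= 1).
#' @param group `"adult"` or `"child"`.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A tibble with columns `participant_id`, `group`, `gender`, `age`,
#'   `height_cm`, `weight_kg`, `bmi`.
#' @export
simulate_participants <- function(n, group = c("adult", "child"), seed = 1L) {
  if (!is.numeric(n) || n < 1) {
    stop("`n` must be at least 1.", call. = FALSE)
  }
  n <- as.integer(n)
  group <- match.arg(group)
  demo <- group_demographics(group)
  set.seed(seed)
  height <- rtrunc_norm(n, demo$height_mean, demo$height_sd,
                        demo$height_mean - 3 * demo$height_sd,
                        demo$height_mean + 3 * demo$height_sd)
  weight <- rtrunc_norm(n, demo$weight_mean, demo$weight_sd,
                        pmax(demo$weight_mean - 3 * demo$weight_sd, 15),
                        demo$weight_mean + 3 * demo$weight_sd)
  age <- round(rtrunc_norm(n, demo$age_mean, demo$age_sd,
                           demo$age_range[1], demo$age_range[2]), 1)
  gender <- rep(c("male", "female"), length.out = n)
  tibble::tibble(
    participant_id = sprintf("%s%03d", toupper(substr(group, 1, 1)), seq_len(n)),
    group = group,
    gender = gender,
    age = age,
    height_cm = height,
    weight_kg = weight,
    bmi = weight / (height / 100)^2
  )
}

#' Simulate a per-minute criterion MET series for one activity trial
#'
#' Emulates the minute-averaged indirect-calorimetry trace of one trial: a
#' participant-level steady-state MET is drawn from
#' `Normal(met_mean, met_sd)` truncated below at 0.5 (a physiological floor),
#' the first three minutes ramp linearly from 1.0 MET (rest) toward the
#' steady state (warm-up, later excluded from analysis), and the remaining
#' minutes sit at the steady state plus small minute-to-minute noise with SD
#' `minute_noise_factor * met_sd`. Most of the published per-activity SD is
#' attributed to between-participant variation in the steady state.
#'
#' @param activity A one-row activity spec as returned by
#'   [activity_protocol()] (needs `met_mean`, `met_sd`).
#' @param duration Trial length in minutes; one of 14, 15, 16.
#' @param seed Integer seed.
#' @param minute_noise_factor Fraction of `met_sd` used as the SD of
#'   minute-level noise around the steady state. Default 0.1.
#' @return A numeric vector of length `duration` of true METs (all >= 0.5).
#' @export
simulate_true_mets <- function(activity, duration = 15L, seed = 1L,
                               minute_noise_factor = 0.1) {
  if (!duration %in% c(14L, 15L, 16L)) {
    stop("`duration` must be 14, 15 or 16 minutes.", call. = FALSE)
  }
  if (is.na(activity$met_mean) || is.na(activity$met_sd)) {
    stop("Activity \"", activity$activity,
         "\" has no MET distribution for this protocol.", call. = FALSE)
  }
  stopifnot(activity$met_mean > 0, activity$met_sd >= 0)
  set.seed(seed)
  steady <- if (activity$met_sd == 0) {
    activity$met_mean
  } else {
    rtrunc_norm(1, activity$met_mean, activity$met_sd, lower = 0.5)
  }
  warm <- 1 + (steady - 1) * (1:3) / 4  # 3-minute linear ramp from rest
  rest <- steady + stats::rnorm(duration - 3, 0, minute_noise_factor * activity$met_sd)
  pmax(c(warm, rest), 0.5)
}

#' Synthesize one minute of raw triaxial accelerometer data
#'
#' The generative link between metabolic intensity and wrist acceleration
#' that makes the pipeline testable end-to-end: the dominant axis carries a
#' sinusoid at the activity's cadence with amplitude
#' `amplitude_per_met * (true_met - 1)` (clamped at 0, so resting minutes are
#' flat), plus Gaussian jitter; the other two axes carry the same sinusoid at
#' half amplitude plus independent jitter, and a 1 g gravity offset sits on
#' the z axis. Under this link the extracted `pa_avg` is monotone in
#' expectation in `true_met`.
#'
#' @param true_met True MET value for the minute (>= 0.5).
#' @param cadence Steps per minute driving the sinusoid frequency.
#' @param seed Integer seed.
#' @param amplitude_per_met Signal units of sinusoid amplitude per MET above
#'   1. Default 0.25.
#' @param jitter_sd SD of additive Gaussian jitter per sample. Default 0.02.
#' @return A minute window: tibble with 120 rows and columns `t`, `ax`, `ay`,
#'   `az`.
#' @export
synthesize_accel_stream <- function(true_met, cadence, seed = 1L,
                                    amplitude_per_met = 0.25,
                                    jitter_sd = 0.02) {
  stopifnot(true_met >= 0.5, cadence >= 0)
  set.seed(seed)
  t <- seq(0, 59.5, by = 0.5)
  amp <- amplitude_per_met * max(true_met - 1, 0)
  freq <- cadence / 60  # Hz
  phase <- stats::runif(1, 0, 2 * pi)
  carrier <- amp * sin(2 * pi * freq * t + phase)
  n <- length(t)
  tibble::tibble(
    t = t,
    ax = carrier + stats::rnorm(n, 0, jitter_sd),
    ay = 0.5 * carrier + stats::rnorm(n, 0, jitter_sd),
    az = 1 + 0.5 * carrier + stats::rnorm(n, 0, jitter_sd)
  )
}

#' Drop warm-up and wind-down minutes from a trial
#'
#' Removes the first three minutes and the last minute of each trial, the
#' window over which energy expenditure has not reached (or is leaving) a
#' steady state.
#'
#' @param minutes A tibble of trial minutes with a `minute_index` column
#'   (1-based within one trial).
#' @return The retained minutes, order preserved.
#' @export
trim_trial <- function(minutes) {
  if (nrow(minutes) < 5) {
    stop("A trial must have at least 5 minutes to trim (got ",
         nrow(minutes), ").", call. = FALSE)
  }
  last <- max(minutes$minute_index)
  dplyr::filter(minutes, .data$minute_index > 3, .data$minute_index < last)
}

#' Exclude invalid minutes
#'
#' Keeps only minutes where the watch was worn, energy expenditure was in a
#' stable state, and the watch recorded the PA feature fields.
#'
#' @param minutes A tibble of trial minutes with logical `worn` and `stable`
#'   columns and feature columns `pa_avg`, `pa_var`, `steps`.
#' @return The valid minutes (possibly zero rows).
#' @export
exclude_invalid <- function(minutes) {
  dplyr::filter(
    minutes,
    .data$worn, .data$stable,
    !is.na(.data$pa_avg), !is.na(.data$pa_var), !is.na(.data$steps)
  )
}

#' Assign participants to training and testing sets
#'
#' Participant-level random split: `round(n * train_fraction)` participants
#' (round half up) go to the training set, the rest to testing. All of a
#' participant's minutes inherit the assignment, so the two sets never share
#' a participant.
#'
#' @param participants A participant tibble (needs `participant_id`).
#' @param train_fraction Fraction assigned to training. Default 0.7.
#' @param seed Integer seed.
#' @return The participant tibble with a `split` column (`"train"`/`"test"`).
#' @export
split_participants <- function(participants, train_fraction = 0.7, seed = 1L) {
  n <- nrow(participants)
  if (n < 2) {
    stop("Need at least 2 participants to split.", call. = FALSE)
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1).", call. = FALSE)
  }
  set.seed(seed)
  n_train <- as.integer(floor(n * train_fraction + 0.5))  # round half up
  n_train <- min(max(n_train, 1L), n - 1L)
  train_ids <- sample(participants$participant_id, n_train)
  dplyr::mutate(participants,
                split = ifelse(.data$participant_id %in% train_ids,
                               "train", "test"))
}

#' Simulate a complete activity-trial study
#'
#' Generates a full synthetic study for one group: participants, the
#' sequential activity protocol, per-minute criterion METs, raw 2 Hz
#' accelerometer windows (reduced on the fly to the watch's per-minute
#' features), wear/stability flags, carried-through luminance and UV fields,
#' and a participant-level train/test split. All randomness flows from the
#' single `seed` through per-stream sub-seeds, so one seed yields a
#' bit-identical dataset.
#'
#' @param n Number of participants.
#' @param group `"adult"` or `"child"`.
#' @param seed Master integer seed.
#' @param train_fraction Passed to [split_participants()].
#' @param minute_noise_factor Passed to [simulate_true_mets()].
#' @param amplitude_per_met,jitter_sd Passed to [synthesize_accel_stream()].
#' @param p_not_worn,p_unstable Per-minute probabilities of a non-wear or
#'   unstable-energy-expenditure flag. Defaults 0.02 and 0.03.
#' @param protocol Activity protocol tibble; defaults to
#'   [activity_protocol()] for the group.
#' @param keep_raw If `TRUE`, the returned object also carries the raw
#'   accelerometer stream (large). Default `FALSE`.
#' @return A `pa_study` object: list with tibbles `participants` (including
#'   `split`) and `minutes`, plus the generating `config`.
#' @export
simulate_study <- function(n, group = c("adult", "child"), seed = 1L,
                           train_fraction = 0.7,
                           minute_noise_factor = 0.1,
                           amplitude_per_met = 0.25, jitter_sd = 0.02,
                           p_not_worn = 0.02, p_unstable = 0.03,
                           protocol = NULL, keep_raw = FALSE) {
  group <- match.arg(group)
  if (is.null(protocol)) protocol <- activity_protocol(group)
  participants <- simulate_participants(n, group, seed = derive_seed(seed, 1)) |>
    split_participants(train_fraction, seed = derive_seed(seed, 2))

  raw_streams <- if (keep_raw) vector("list", 0) else NULL
  origin <- as.POSIXct("2023-03-01 08:00:00", tz = "UTC")

  minutes <- purrr::map_dfr(seq_len(nrow(participants)), function(i) {
    pid <- participants$participant_id[i]
    minute_offset <- 0L
    purrr::map_dfr(seq_len(nrow(protocol)), function(a) {
      act <- protocol[a, ]
      s_trial <- derive_seed(seed, 100, i, a)
      set.seed(s_trial)
      duration <- sample(c(14L, 15L, 16L), 1)
      worn <- stats::runif(duration) >= p_not_worn
      stable <- stats::runif(duration) >= p_unstable
      lux <- matrix(round(exp(stats::rnorm(duration * 3, 5.5, 0.6)), 1),
                    ncol = 3)
      uv <- matrix(round(stats::rexp(duration * 3, 10), 3), ncol = 3)
      mets <- simulate_true_mets(act, duration,
                                 seed = derive_seed(seed, 200, i, a),
                                 minute_noise_factor = minute_noise_factor)
      rows <- purrr::map_dfr(seq_len(duration), function(m) {
        window <- synthesize_accel_stream(
          mets[m], act$cadence, seed = derive_seed(seed, 300, i, a, m),
          amplitude_per_met = amplitude_per_met, jitter_sd = jitter_sd
        )
        feats <- if (worn[m]) {
          extract_minute_features(window)
        } else {
          tibble::tibble(pa_avg = NA_real_, pa_var = NA_real_,
                         steps = NA_integer_, dominant_axis = NA_character_)
        }
        if (keep_raw && worn[m]) {
          raw_streams[[length(raw_streams) + 1]] <<- dplyr::mutate(
            window,
            participant_id = pid,
            minute_start = origin + 60 * (minute_offset + m - 1),
            .before = 1
          )
        }
        tibble::tibble(
          participant_id = pid,
          activity = act$activity,
          minute_index = m,
          timestamp = origin + 60 * (minute_offset + m - 1),
          true_met = mets[m],
          worn = worn[m],
          stable = stable[m],
          wear_status = ifelse(worn[m], "worn", "not_worn"),
          lux1 = lux[m, 1], lux2 = lux[m, 2], lux3 = lux[m, 3],
          uv1 = uv[m, 1], uv2 = uv[m, 2], uv3 = uv[m, 3]
        ) |>
          dplyr::bind_cols(feats)
      })
      minute_offset <<- minute_offset + duration + 5L  # 5-minute rest gap
      rows
    })
  })

  study <- structure(
    list(
      participants = participants,
      minutes = minutes,
      config = list(
        n = n, group = group, seed = seed, train_fraction = train_fraction,
        minute_noise_factor = minute_noise_factor,
        amplitude_per_met = amplitude_per_met, jitter_sd = jitter_sd,
        p_not_worn = p_not_worn, p_unstable = p_unstable
      )
    ),
    class = "pa_study"
  )
  if (keep_raw) study$raw <- dplyr::bind_rows(raw_streams)
  study
}

#' @export
print.pa_study <- function(x, ...) {
  cat("<pa_study> ", x$config$group, " group: ",
      nrow(x$participants), " participants (",
      sum(x$participants$split == "train"), " train / ",
      sum(x$participants$split == "test"), " test), ",
      nrow(x$minutes), " trial minutes\n", sep = "")
  invisible(x)
}

#' Analysis-ready minutes of a study
#'
#' Applies the protocol's exclusion rules to a simulated study: warm-up and
#' final minutes are trimmed per trial, invalid minutes are dropped, and the
#' participant's split and covariates are joined on.
#'
#' @param study A `pa_study` object.
#' @return A tibble of valid analysis minutes with participant covariates and
#'   `split`.
#' @export
study_minutes <- function(study) {
  stopifnot(inherits(study, "pa_study"))
  study$minutes |>
    dplyr::group_by(.data$participant_id, .data$activity) |>
    dplyr::group_modify(~ trim_trial(.x)) |>
    dplyr::ungroup() |>
    exclude_invalid() |>
    dplyr::left_join(
      dplyr::select(study$participants, "participant_id", "group", "gender",
                    "bmi", "split"),
      by = "participant_id"
    )
}
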