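minute_record_columns <- function() {
  c("participant_id", "timestamp", "pa_avg", "pa_var", "steps",
    "lux1", "lux2", "lux3", "uv1", "uv2", "uv3", "wear_status")
}

#' Read and write per-minute smartwatch records
#'
#' The watch emits one record per minute: timestamp, average of PA, variance
#' of PA, step count, three luminance readings (lx), three UV readings, and
#' wear status. Luminance and UV are carried through but unused by the model.
#' Timestamps are serialized as ISO-8601 at minute resolution; `strict_dialect
#' = TRUE` additionally accepts the watch's native `year/month/day hh:mm:ss`
#' display form on read. Reads are validated: a missing column, a duplicate
#' participant-minute, an unknown wear status or an unparseable row is an
#' error naming the offending column or line.
#'
#' @param path CSV file path.
#' @param strict_dialect Also accept `YYYY/MM/DD HH:MM:SS` timestamps.
#' @return A tibble of minute records.
#' @export
read_minute_records <- function(path, strict_dialect = FALSE) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(minute_record_columns(), names(raw))
  if (length(missing) > 0) {
    stop("Minute-record file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ts <- parse_minute_timestamp(raw$timestamp, strict_dialect)
  bad_ts <- which(is.na(ts))
  if (length(bad_ts) > 0) {
    stop("Unparseable timestamp on data line(s): ",
         paste(utils::head(bad_ts, 5), collapse = ", "), call. = FALSE)
  }
  bad_wear <- which(!raw$wear_status %in% c("worn", "not_worn"))
  if (length(bad_wear) > 0) {
    stop("Invalid wear_status on data line(s): ",
         paste(utils::head(bad_wear, 5), collapse = ", "),
         " (must be \"worn\" or \"not_worn\").", call. = FALSE)
  }
  out <- tibble::tibble(
    participant_id = raw$participant_id,
    timestamp = ts,
    pa_avg = parse_num(raw$pa_avg, "pa_avg"),
    pa_var = parse_num(raw$pa_var, "pa_var"),
    steps = as.integer(parse_num(raw$steps, "steps", allow_na = TRUE)),
    lux1 = parse_num(raw$lux1, "lux1", allow_na = TRUE),
    lux2 = parse_num(raw$lux2, "lux2", allow_na = TRUE),
    lux3 = parse_num(raw$lux3, "lux3", allow_na = TRUE),
    uv1 = parse_num(raw$uv1, "uv1", allow_na = TRUE),
    uv2 = parse_num(raw$uv2, "uv2", allow_na = TRUE),
    uv3 = parse_num(raw$uv3, "uv3", allow_na = TRUE),
    wear_status = raw$wear_status
  )
  dup <- duplicated(out[c("participant_id", "timestamp")])
  if (any(dup)) {
    stop("Duplicate participant-minute on data line(s): ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  }
  out
}

parse_minute_timestamp <- function(x, strict_dialect = FALSE) {
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d %H:%M"),
                   optional = TRUE)
  if (strict_dialect) {
    alt <- as.POSIXct(x, tz = "UTC", format = "%Y/%m/%d %H:%M:%S",
                      optional = TRUE)
    ts[is.na(ts)] <- alt[is.na(ts)]
  }
  as.POSIXct(trunc(ts, units = "mins"))  # minute resolution
}

parse_num <- function(x, column, allow_na = FALSE) {
  missing_val <- is.na(x) | x == ""
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !missing_val)
  if (length(bad) > 0) {
    stop("Non-numeric ", column, " on data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!allow_na && any(missing_val)) {
    stop("Missing ", column, " on data line(s): ",
         paste(utils::head(which(missing_val), 5), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @rdname read_minute_records
#' @param records A tibble of minute records (columns as produced by
#'   [read_minute_records()] or [simulate_study()]).
#' @export
write_minute_records <- function(records, path) {
  missing <- setdiff(minute_record_columns(), names(records))
  if (length(missing) > 0) {
    stop("`records` is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- records[minute_record_columns()]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write criterion MET series
#'
#' The per-minute criterion (indirect-calorimetry) METs: columns
#' `participant_id`, `timestamp`, `met`. Nonpositive METs are rejected.
#'
#' @param path CSV file path.
#' @return A tibble with `participant_id`, `timestamp`, `met`.
#' @export
read_criterion_mets <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(c("participant_id", "timestamp", "met"), names(raw))
  if (length(missing) > 0) {
    stop("Criterion-MET file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  met <- parse_num(raw$met, "met")
  if (any(met <= 0)) {
    stop("Nonpositive MET on data line(s): ",
         paste(utils::head(which(met <= 0), 5), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    participant_id = raw$participant_id,
    timestamp = parse_minute_timestamp(raw$timestamp),
    met = met
  )
}

#' @rdname read_criterion_mets
#' @param mets A tibble with `participant_id`, `timestamp`, `met`.
#' @export
write_criterion_mets <- function(mets, path) {
  out <- mets[c("participant_id", "timestamp", "met")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write participant tables
#'
#' Participants CSV: `participant_id`, `group`, `gender`, `age`, `height_cm`,
#' `weight_kg` (plus optional `split`). BMI is (re)computed on load as
#' weight / (height in m)^2; BMI outside 10-60 kg/m^2 triggers a warning.
#'
#' @param path CSV file path.
#' @return A participant tibble including `bmi`.
#' @export
read_participants <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("participant_id", "group", "gender", "age", "height_cm",
                "weight_kg")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("Participant file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    participant_id = raw$participant_id,
    group = raw$group,
    gender = raw$gender,
    age = parse_num(raw$age, "age"),
    height_cm = parse_num(raw$height_cm, "height_cm"),
    weight_kg = parse_num(raw$weight_kg, "weight_kg")
  )
  out$bmi <- out$weight_kg / (out$height_cm / 100)^2
  if ("split" %in% names(raw)) out$split <- raw$split
  flagged <- which(out$bmi < 10 | out$bmi > 60)
  if (length(flagged) > 0) {
    warning("BMI outside 10-60 kg/m^2 for participant(s): ",
            paste(utils::head(out$participant_id[flagged], 5), collapse = ", "),
            call. = FALSE)
  }
  out
}

#' @rdname read_participants
#' @param participants A participant tibble.
#' @export
write_participants <- function(participants, path) {
  keep <- intersect(c("participant_id", "group", "gender", "age", "height_cm",
                      "weight_kg", "bmi", "split"), names(participants))
  readr::write_csv(participants[keep], path, progress = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' The configuration driving simulation and model fitting. Defaults reproduce
#' the reference study protocol: 24 adults and 18 children, a 70/30
#' participant-level split, the built-in activity protocol, and the default
#' generator noise parameters.
#'
#' @param seed Master seed.
#' @return A named list (a validated run config).
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    # n_participants rather than a bare "n": YAML 1.1 parses the key "n" as
    # the boolean FALSE
    groups = list(adult = list(n_participants = 24L),
                  child = list(n_participants = 18L)),
    train_fraction = 0.7,
    minute_noise_factor = 0.1,
    amplitude_per_met = 0.25,
    jitter_sd = 0.02,
    p_not_worn = 0.02,
    p_unstable = 0.03,
    c_grid = c(0.01, 0.1, 1, 10, 100),
    thresholds = list(sed_max = 1.49, mvpa_min = 3.00, vpa_min = 6.00)
  )
}

#' Read a run configuration from YAML
#'
#' Missing fields fall back to [default_run_config()]; the merged config is
#' validated before use.
#'
#' @param path YAML file path.
#' @param seed Fallback seed if the file does not set one.
#' @return A validated run config list.
#' @export
read_run_config <- function(path, seed = 1L) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(seed), user)
  # a user-supplied groups block replaces the default set entirely
  if (!is.null(user$groups)) cfg$groups <- user$groups
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A run-config list.
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  if (!is.numeric(config$seed) || length(config$seed) != 1) {
    stop("Config `seed` must be a single integer.", call. = FALSE)
  }
  if (!is.list(config$groups) || length(config$groups) == 0 ||
      !all(names(config$groups) %in% c("adult", "child"))) {
    stop("Config `groups` must name adult and/or child entries.",
         call. = FALSE)
  }
  for (g in names(config$groups)) {
    n <- config$groups[[g]]$n_participants
    if (!is.numeric(n) || n < 2) {
      stop("Config group \"", g, "\" needs n_participants >= 2.",
           call. = FALSE)
    }
  }
  if (config$train_fraction <= 0 || config$train_fraction >= 1) {
    stop("Config `train_fraction` must be in (0, 1).", call. = FALSE)
  }
  for (nm in c("minute_noise_factor", "amplitude_per_met", "jitter_sd",
               "p_not_worn", "p_unstable")) {
    if (!is.numeric(config[[nm]]) || config[[nm]] < 0) {
      stop("Config `", nm, "` must be non-negative.", call. = FALSE)
    }
  }
  do.call(met_thresholds, config$thresholds)  # validates ordering
  config$seed <- as.integer(config$seed)
  config
}

#' Serialize a validation report to JSON
#'
#' Writes (or renders) the full report — sample sizes, per-category
#' classification metrics, error metrics, Bland-Altman, ICC and Spearman —
#' as deterministic JSON (no timestamps), so identical inputs yield
#' byte-identical files.
#'
#' @param report A `met_validation` object.
#' @param path Output path; if `NULL`, the JSON string is returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
write_validation_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "met_validation"))
  payload <- list(
    schema_version = "metwatch-report/1",
    group = report$group,
    n_participants = report$n_participants,
    n_minutes = report$n_minutes,
    classification = report$classification,
    errors = report$errors,
    bland_altman = report$bland_altman,
    icc = report$icc,
    spearman = report$spearman
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

# provenance block written beside every CLI output; content is a pure
# function of config + seed so reruns are byte-identical
write_provenance <- function(config, dir) {
  prov <- list(
    package = "metwatch",
    version = as.character(utils::packageVersion("metwatch")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    config = config
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prov)
}
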