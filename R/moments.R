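#' Moment specification for a synthetic cohort
#'
#' A moment specification fixes, for every candidate indicator, the target
#' sample mean, sample standard deviation (divisor `n - 1`) and Pearson
#' correlation with the criterion variable, plus the criterion's own mean and
#' SD. It is the calibration object consumed by [generate_exact()] and
#' [generate_sampled()].
#'
#' @param indicators A data frame with columns `indicator` (unique names),
#'   `mean`, `sd` (strictly positive) and `r` (correlation with the
#'   criterion, strictly inside (-1, 1)).
#' @param criterion_name Name of the criterion column, distinct from every
#'   indicator name.
#' @param criterion_mean,criterion_sd Target mean and SD (positive) of the
#'   criterion column.
#'
#' @return An object of class `moment_spec`: a list with elements
#'   `indicators` (tibble) and `criterion` (named list).
#' @export
#' @examples
#' moment_spec(
#'   data.frame(indicator = c("a", "b"), mean = c(0, 1), sd = c(1, 2),
#'              r = c(0.5, -0.3)),
#'   criterion_name = "y", criterion_mean = 10, criterion_sd = 2
#' )
moment_spec <- function(indicators, criterion_name, criterion_mean, criterion_sd) {
  indicators <- tibble::as_tibble(indicators)
  needed <- c("indicator", "mean", "sd", "r")
  missing_cols <- setdiff(needed, names(indicators))
  if (length(missing_cols) > 0) {
    stop("`indicators` is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  indicators <- indicators[needed]
  if (anyDuplicated(indicators$indicator)) {
    stop("indicator names must be unique", call. = FALSE)
  }
  if (criterion_name %in% indicators$indicator) {
    stop("criterion name '", criterion_name, "' collides with an indicator name",
         call. = FALSE)
  }
  if (any(!is.finite(indicators$mean)) || any(!is.finite(indicators$sd)) ||
      any(!is.finite(indicators$r))) {
    stop("moment specification contains non-finite values", call. = FALSE)
  }
  if (any(indicators$sd <= 0) || criterion_sd <= 0) {
    stop("all standard deviations must be strictly positive", call. = FALSE)
  }
  if (any(abs(indicators$r) >= 1)) {
    stop("all criterion correlations must satisfy |r| < 1", call. = FALSE)
  }
  structure(
    list(
      indicators = indicators,
      criterion = list(name = criterion_name,
                       mean = as.numeric(criterion_mean),
                       sd = as.numeric(criterion_sd))
    ),
    class = "moment_spec"
  )
}

#' @export
print.moment_spec <- function(x, ...) {
  cat("<moment_spec> ", nrow(x$indicators), " indicators, criterion '",
      x$criterion$name, "' (mean ", format(x$criterion$mean),
      ", sd ", format(x$criterion$sd), ")\n", sep = "")
  print(x$indicators, ...)
  invisible(x)
}

#' Read a moment specification from YAML or JSON
#'
#' The file layout mirrors [moment_spec()]: a top-level `criterion` mapping
#' with `name`, `mean`, `sd`, and an `indicators` list whose entries carry
#' `name`, `mean`, `sd` and `r`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `moment_spec`.
#' @export
read_moment_spec <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$criterion) || is.null(raw$indicators)) {
    stop("spec file must contain 'criterion' and 'indicators' entries", call. = FALSE)
  }
  ind <- purrr::map_dfr(raw$indicators, function(e) {
    tibble::tibble(indicator = as.character(e$name),
                   mean = as.numeric(e$mean),
                   sd = as.numeric(e$sd),
                   r = as.numeric(e$r))
  })
  moment_spec(ind,
              criterion_name = as.character(raw$criterion$name),
              criterion_mean = as.numeric(raw$criterion$mean),
              criterion_sd = as.numeric(raw$criterion$sd))
}

#' Write a moment specification to YAML
#'
#' @param spec A `moment_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_moment_spec <- function(spec, path) {
  stopifnot(inherits(spec, "moment_spec"))
  out <- list(
    criterion = spec$criterion,
    indicators = purrr::pmap(spec$indicators[c("indicator", "mean", "sd", "r")],
                             function(indicator, mean, sd, r) {
                               list(name = indicator, mean = mean, sd = sd, r = r)
                             })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Published calibration moments for the juvenile trampoline cohort
#'
#' Summary statistics of the 16 representative indicators and the pre-jump
#' height criterion from a published study of 16 juvenile trampoline
#' gymnasts: per-indicator mean and SD together with each indicator's Pearson
#' correlation with pre-jump height. These are the default calibration values
#' for the synthetic cohort generators; the study's raw athlete-level data
#' were never deposited, so the moments are the only quantitative anchor.
#'
#' Units are heterogeneous (cm, degrees, counts, questionnaire scores,
#' dimensionless ratios); the `unit` column records them. Negative
#' correlations mark indicators oriented against the criterion (e.g. state
#' anxiety).
#'
#' @return A `moment_spec` whose criterion is `pre_jump_height`
#'   (mean 3.13 m, SD 0.36 m) over 16 indicators.
#' @export
#' @examples
#' trampoline_moments()
trampoline_moments <- function() {
  ind <- tibble::tribble(
    ~indicator,                    ~mean,  ~sd,    ~r,      ~unit,
    "leg_length_ratio",            0.565,  0.011,  0.875,   "ratio to height",
    "bmi",                         17.23,  1.62,   0.771,   "kg/m^2",
    "height",                      152.66, 9.98,   0.840,   "cm",
    "daily_acrophobia",            40.81,  18.60,  0.495,   "rating",
    "ankle_cushioning",            10.15,  5.09,   0.576,   "degree",
    "standing_long_jump",          212.75, 17.64,  0.871,   "cm",
    "shoulder_width_ratio",        0.195,  0.007,  0.762,   "ratio to height",
    "arm_hang_angle",              173.44, 5.15,   0.627,   "degree",
    "hip_angle_landing",           21.14,  2.19,   0.675,   "degree",
    "counter_pre_jump_ratio",      0.144,  0.015,  0.754,   "ratio",
    "hanging_leg_raise_30s",       19.69,  1.16,   0.686,   "repetitions",
    "time_perception_10s",         0.209,  0.144, -0.287,   "s (absolute error)",
    "self_rotation_10",            66.69,  78.17, -0.292,   "degree (error)",
    "supine_leg_raise_45",         4.56,   4.15,  -0.254,   "degree (error)",
    "state_anxiety",               37.44,  6.13,  -0.631,   "STAI score",
    "trampoline_acrophobia",       13.31,  3.49,  -0.554,   "score"
  )
  spec <- moment_spec(ind[c("indicator", "mean", "sd", "r")],
                      criterion_name = "pre_jump_height",
                      criterion_mean = 3.13, criterion_sd = 0.36)
  spec$indicators$unit <- ind$unit
  spec
}

#' Published grey relational grades for the trampoline indicator system
#'
#' The grey relational grade of each of the 16 representative indicators
#' against pre-jump height, with the companion Pearson correlation and its
#' reported significance, as printed in the same study that
#' [trampoline_moments()] is calibrated to. Useful as input to
#' [rank_and_classify()] and as a reference ordering.
#'
#' @return A tibble with columns `indicator`, `pearson_r`, `significant`
#'   (logical, p < 0.05 reported) and `grade`, in the published rank order.
#' @export
#' @examples
#' rank_and_classify(trampoline_grades()$grade)
trampoline_grades <- function() {
  tibble::tribble(
    ~indicator,               ~pearson_r, ~significant, ~grade,
    "standing_long_jump",      0.871,     TRUE,         0.9469,
    "height",                  0.840,     TRUE,         0.9428,
    "leg_length_ratio",        0.875,     TRUE,         0.9408,
    "shoulder_width_ratio",    0.762,     TRUE,         0.9369,
    "arm_hang_angle",          0.627,     TRUE,         0.9345,
    "counter_pre_jump_ratio",  0.754,     TRUE,         0.9316,
    "hanging_leg_raise_30s",   0.686,     TRUE,         0.9315,
    "bmi",                     0.771,     TRUE,         0.9288,
    "hip_angle_landing",       0.675,     TRUE,         0.9203,
    "state_anxiety",          -0.631,     TRUE,         0.9116,
    "trampoline_acrophobia",  -0.554,     TRUE,         0.8659,
    "daily_acrophobia",        0.495,     TRUE,         0.8274,
    "ankle_cushioning",        0.576,     TRUE,         0.8023,
    "time_perception_10s",    -0.287,     FALSE,        0.7486,
    "supine_leg_raise_45",    -0.254,     FALSE,        0.6732,
    "self_rotation_10",       -0.292,     FALSE,        0.6574
  )
}
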