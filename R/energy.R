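#' @keywords internal
pa_columns <- function() {
  c("pa1_sit_h_wk", "pa2_stand_h_wk", "pa3_walk_h_wk", "pa4_heavy_h_wk",
    "pa5_mod_h_wk", "pa6_vig_h_wk", "pa7_vvig_h_wk")
}

cohort_required_columns <- function() {
  c("id", "age", "sex", "weight_kg", "height_cm", "sleep_h_day", pa_columns())
}

# Extract the n x 7 matrix of weekly activity hours, with checks.
pa_matrix <- function(cohort) {
  missing <- setdiff(pa_columns(), names(cohort))
  if (length(missing)) {
    stop("cohort is missing activity column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(cohort[, pa_columns(), drop = FALSE])
  if (any(!is.na(m) & m < 0)) {
    stop("activity hours must be non-negative", call. = FALSE)
  }
  m
}

#' Body surface area
#'
#' Power-law body surface area for Japanese adults:
#' \deqn{BSA (cm^2) = weight^{0.444} \times height^{0.663} \times 88.83}
#' with weight in kg and height in cm.
#'
#' @param weight_kg Body weight, kg (> 0).
#' @param height_cm Height, cm (> 0).
#' @return Body surface area in cm^2; strictly increasing in both arguments.
#' @export
body_surface_area <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_cm)) ||
      any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("weight and height must be finite and > 0", call. = FALSE)
  }
  weight_kg^0.444 * height_cm^0.663 * 88.83
}

#' Basal metabolic rate
#'
#' \deqn{BMR (kcal/day) = standard (kcal/m^2/h) \times BSA (cm^2) \times 24 / 10000}
#' where the standard value comes from a (sex, age-band) reference table.
#'
#' @inheritParams body_surface_area
#' @inheritParams bmr_standard_value
#' @return BMR in kcal/day.
#' @export
basal_metabolic_rate <- function(age, sex, weight_kg, height_cm,
                                 table = default_bmr_table()) {
  std <- bmr_standard_value(age, sex, table)
  std * body_surface_area(weight_kg, height_cm) * 24 / 10000
}

#' Energy expenditure of a single activity
#'
#' \deqn{EE (kcal) = MET \times hours \times weight (kg) \times 1.05}
#'
#' @param met Activity intensity, METs (>= 0).
#' @param hours Time spent, h (>= 0).
#' @param weight_kg Body weight, kg (>= 0).
#' @return Energy expenditure in kcal.
#' @export
activity_energy <- function(met, hours, weight_kg) {
  if (any(met < 0) || any(hours < 0) || any(weight_kg < 0)) {
    stop("activity_energy() arguments must be non-negative", call. = FALSE)
  }
  met * hours * weight_kg * 1.05
}

#' Residual off-duty light activity time
#'
#' The week holds 168 h; whatever is not sleep or one of the seven reported
#' categories is off-duty light activity (PA8):
#' `168 - 7 * sleep_h_day - sum(PA1..PA7)`.
#'
#' @param sleep_h_day Sleep, h/day, in \[0, 24\].
#' @param pa_h_wk Numeric vector of 7 weekly activity hours, or a cohort
#'   data.frame (then all arguments are taken column-wise).
#' @param clip If `TRUE`, negative residuals (over-reported time) are clipped
#'   to 0 with a warning instead of raising an error.
#' @return Residual light-activity time, h/week.
#' @export
residual_light_hours <- function(sleep_h_day, pa_h_wk = NULL, clip = FALSE) {
  if (is.data.frame(sleep_h_day)) {
    cohort <- sleep_h_day
    pa <- pa_matrix(cohort)
    sleep <- cohort$sleep_h_day
  } else if (is.matrix(pa_h_wk)) {
    pa <- pa_h_wk
    sleep <- sleep_h_day
  } else {
    pa <- matrix(pa_h_wk, nrow = length(sleep_h_day), ncol = 7L, byrow = TRUE)
    sleep <- sleep_h_day
  }
  if (any(sleep < 0 | sleep > 24)) {
    stop("sleep_h_day must lie in [0, 24]", call. = FALSE)
  }
  res <- 168 - 7 * sleep - rowSums(pa)
  neg <- !is.na(res) & res < -1e-9
  if (any(neg)) {
    if (clip) {
      warning(sum(neg), " profile(s) over-report time; residual light hours ",
              "clipped to 0 (largest deficit ",
              format(max(-res[neg]), digits = 4), " h/week)", call. = FALSE)
      res[neg] <- 0
    } else {
      stop("inconsistent activity profile: sleep plus reported activity ",
           "exceeds 168 h/week (deficit ",
           paste(format(-res[neg], digits = 4), collapse = ", "),
           " h/week)", call. = FALSE)
    }
  }
  pmax(res, 0)
}

#' Questionnaire total energy expenditure
#'
#' Daily TEE implied by the questionnaire under a given MET set:
#' \deqn{TEE = BMR \times sleep/24 + TEF + \sum_{i=1}^{8} weight \times 1.05
#'   \times PA_i \times MET_i}
#' with weekly activity hours converted to h/day (PA_i / 7), PA8 the residual
#' light time, and the thermic effect of food TEF = TEE / 10. The TEF
#' definition is self-referential, so the sum S of the sleep and activity
#' terms is closed algebraically: TEE = S / 0.9.
#'
#' @param cohort Cohort data.frame (see [load_cohort()] for the schema).
#' @param mets A [met_set()].
#' @param table BMR reference table.
#' @param clip Passed to [residual_light_hours()].
#' @param components If `TRUE`, return a data.frame with the sleep, activity
#'   and TEF components alongside the total.
#' @return Numeric vector of TEE, kcal/day (or a component data.frame).
#' @export
questionnaire_tee <- function(cohort, mets, table = default_bmr_table(),
                              clip = FALSE, components = FALSE) {
  mets <- as_met_set(mets)
  pa <- pa_matrix(cohort)
  bmr <- basal_metabolic_rate(cohort$age, cohort$sex, cohort$weight_kg,
                              cohort$height_cm, table)
  pa8 <- residual_light_hours(cohort$sleep_h_day, pa, clip = clip)
  met_h_day <- cbind(pa, pa8) %*% mets$met / 7
  sleep_ee <- bmr * cohort$sleep_h_day / 24
  activity_ee <- cohort$weight_kg * 1.05 * as.numeric(met_h_day)
  tee <- (sleep_ee + activity_ee) / 0.9
  if (components) {
    data.frame(sleep_ee = sleep_ee, activity_ee = activity_ee,
               tef = 0.1 * tee, tee = tee)
  } else {
    tee
  }
}

#' Accelerometer (device) total energy expenditure for one participant
#'
#' Assembles daily TEE over a 7-day wear period: the device's own EE, plus
#' imputed EE for non-wear episodes (MET x hours x weight x 1.05; bathing is
#' fixed at 1.5 METs), plus sleep EE as BMR x sleep/24. Returns the 7-day
#' mean.
#'
#' @param daily_device_ee Numeric vector of 7 daily device EE values, kcal.
#' @param sleep_h_day Numeric vector of 7 daily sleep durations, h.
#' @param age,sex,weight_kg,height_cm Participant anthropometry.
#' @param nonwear Optional data.frame of non-wear episodes with columns
#'   `day` (1-7), `duration_h`, `met`, `kind`
#'   ("bathing", "sleep", "other-known", "unknown"). Bathing episodes are
#'   assigned 1.5 METs regardless of `met`; other kinds need an explicit
#'   `met` (an `NA` MET on a non-bathing episode is an imputation error).
#' @param table BMR reference table.
#' @return Mean daily TEE over the 7 days, kcal/day.
#' @export
lifecorder_tee <- function(daily_device_ee, sleep_h_day, age, sex, weight_kg,
                           height_cm, nonwear = NULL,
                           table = default_bmr_table()) {
  if (length(daily_device_ee) != 7L || length(sleep_h_day) != 7L) {
    stop("device EE and sleep must each cover exactly 7 days", call. = FALSE)
  }
  if (any(daily_device_ee < 0)) {
    stop("device EE must be non-negative", call. = FALSE)
  }
  if (any(sleep_h_day < 0 | sleep_h_day > 24)) {
    stop("sleep_h_day must lie in [0, 24]", call. = FALSE)
  }
  bmr <- basal_metabolic_rate(age, sex, weight_kg, height_cm, table)
  imputed <- numeric(7L)
  if (!is.null(nonwear) && nrow(nonwear) > 0L) {
    stopifnot(all(c("day", "duration_h", "met", "kind") %in% names(nonwear)))
    if (any(nonwear$day < 1L | nonwear$day > 7L)) {
      stop("non-wear episode days must be in 1..7", call. = FALSE)
    }
    if (any(nonwear$duration_h < 0)) {
      stop("non-wear durations must be non-negative", call. = FALSE)
    }
    met <- ifelse(nonwear$kind == "bathing", 1.5, nonwear$met)
    if (any(is.na(met))) {
      stop("non-wear episode of kind '",
           nonwear$kind[which(is.na(met))[1L]],
           "' has no assigned MET; cannot impute its energy expenditure",
           call. = FALSE)
    }
    ee <- activity_energy(met, nonwear$duration_h, weight_kg)
    imputed <- as.numeric(tapply(ee, factor(nonwear$day, levels = 1:7), sum))
    imputed[is.na(imputed)] <- 0
  }
  daily <- daily_device_ee + imputed + bmr * sleep_h_day / 24
  mean(daily)
}

#' Weekly moderate-to-vigorous physical activity (MVPA)
#'
#' Hours per week spent in questionnaire categories whose MET value is at
#' least `threshold` (default 3 METs). Sleep (1.0 MET) and residual light
#' activity are never counted. Note the category logic depends on the MET
#' set: under the midrange set "moderate" (3.0 METs) qualifies, under the
#' estimated set (2.4 METs) it does not.
#'
#' @inheritParams questionnaire_tee
#' @param threshold MVPA intensity threshold, METs (inclusive).
#' @return Numeric vector, h/week.
#' @export
mvpa_hours <- function(cohort, mets, threshold = 3.0) {
  mets <- as_met_set(mets)
  pa <- pa_matrix(cohort)
  qualifies <- mets$met[1:7] >= threshold
  rowSums(pa[, qualifies, drop = FALSE])
}

#' Weekly exercise volume (Ex = MET x hour)
#'
#' MET-hours per week accumulated in categories at or above the intensity
#' threshold, the Japanese guideline "Ex" quantity.
#'
#' @inheritParams mvpa_hours
#' @return Numeric vector, MET·h/week.
#' @export
exercise_volume <- function(cohort, mets, threshold = 3.0) {
  mets <- as_met_set(mets)
  pa <- pa_matrix(cohort)
  qualifies <- mets$met[1:7] >= threshold
  as.numeric(pa[, qualifies, drop = FALSE] %*% mets$met[1:7][qualifies])
}
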