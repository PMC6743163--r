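#' Basal metabolic standard reference table (synthetic stand-in)
#'
#' Basal metabolic standard values in kcal/m^2/h by sex and age band, the
#' lookup used by [basal_metabolic_rate()]. The original Japanese reference
#' values are published in nutrition references that are not reproduced here;
#' the shipped table is a synthetic stand-in on the same scale (adult women
#' around 30-33 kcal/m^2/h, declining with age), chosen so that TEE for a
#' typical middle-aged woman lands in the observed 1800-2200 kcal/day range.
#' Replace it with [read_bmr_table()] for substantive use.
#'
#' @return A data.frame with columns `sex`, `age_min`, `age_max`,
#'   `kcal_per_m2_per_h`.
#' @export
default_bmr_table <- function() {
  tab <- data.frame(
    sex = rep(c("female", "male"), each = 6L),
    age_min = rep(c(18L, 30L, 40L, 50L, 60L, 70L), 2L),
    age_max = rep(c(29L, 39L, 49L, 59L, 69L, 79L), 2L),
    kcal_per_m2_per_h = c(
      33.2, 32.7, 32.0, 31.2, 30.2, 29.5,   # female
      37.5, 36.5, 35.6, 34.5, 33.3, 32.5),  # male
    stringsAsFactors = FALSE
  )
  validate_bmr_table(tab)
}

#' Read / write a basal metabolic reference table
#'
#' CSV with columns `sex`, `age_min`, `age_max`, `kcal_per_m2_per_h`.
#' Bands must be contiguous and non-overlapping within sex, values positive.
#'
#' @param path File path.
#' @return `read_bmr_table()` returns the validated table;
#'   `write_bmr_table()` returns `path` invisibly.
#' @export
read_bmr_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sex", "age_min", "age_max", "kcal_per_m2_per_h")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("BMR table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_bmr_table(tab)
}

#' @rdname read_bmr_table
#' @param table A BMR reference table.
#' @export
write_bmr_table <- function(table, path) {
  utils::write.csv(validate_bmr_table(table), path, row.names = FALSE)
  invisible(path)
}

validate_bmr_table <- function(table) {
  stopifnot(is.data.frame(table))
  if (any(table$kcal_per_m2_per_h <= 0)) {
    stop("BMR standard values must be > 0", call. = FALSE)
  }
  if (any(table$age_min > table$age_max)) {
    stop("BMR table bands must satisfy age_min <= age_max", call. = FALSE)
  }
  for (s in unique(table$sex)) {
    bands <- table[table$sex == s, , drop = FALSE]
    bands <- bands[order(bands$age_min), , drop = FALSE]
    if (nrow(bands) > 1L) {
      gap <- bands$age_min[-1L] - bands$age_max[-nrow(bands)]
      if (any(gap != 1L)) {
        stop("BMR table bands for sex '", s,
             "' must be contiguous and non-overlapping", call. = FALSE)
      }
    }
  }
  table
}

#' Look up the basal metabolic standard value
#'
#' @param age Age(s) in years.
#' @param sex `"female"` or `"male"` (recycled).
#' @param table A BMR reference table, see [default_bmr_table()].
#' @return Numeric vector of standard values, kcal/m^2/h.
#' @export
bmr_standard_value <- function(age, sex = "female", table = default_bmr_table()) {
  n <- max(length(age), length(sex))
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    hit <- table$sex == sex[i] & table$age_min <= age[i] & age[i] <= table$age_max
    if (sum(hit) != 1L) {
      stop("no BMR reference band covers age ", age[i], " (sex '", sex[i], "')",
           call. = FALSE)
    }
    out[i] <- table$kcal_per_m2_per_h[hit]
  }
  out
}
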