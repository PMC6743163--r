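#' Activity category names
#'
#' The seven questionnaire categories (four occupational: sitting, standing,
#' walking, heavy work; three leisure: moderate, vigorous, very vigorous)
#' plus the derived residual category, off-duty light activity.
#'
#' @return Character vector of length 8.
#' @export
met_categories <- function() {
  c("sitting", "standing", "walking", "heavy_work",
    "moderate", "vigorous", "very_vigorous", "light")
}

#' Questionnaire MET intensity ranges
#'
#' The half-open intensity interval \eqn{[L_i, U_i)} offered to respondents as
#' examples for each category; `very_vigorous` is unbounded above.
#'
#' @return A data.frame with columns `category`, `lower`, `upper`.
#' @export
met_bounds <- function() {
  data.frame(
    category = met_categories(),
    lower = c(1.0, 1.2, 2.0, 4.0, 3.0, 5.0, 8.0, 1.0),
    upper = c(1.5, 2.0, 4.0, 8.0, 5.0, 8.0, Inf, 2.0),
    stringsAsFactors = FALSE
  )
}

#' Construct a MET intensity set
#'
#' A `met_set` holds one MET value per activity category together with the
#' category intensity ranges. Use [met_midrange()] for the questionnaire's
#' assigned midrange values and [met_estimated()] for the posterior reference
#' values recovered by the calibration.
#'
#' @param values Numeric vector of 8 positive MET values, ordered as
#'   [met_categories()].
#' @param label Short label carried through summaries ("midrange",
#'   "estimated", or custom).
#' @return An object of class `met_set` with elements `met` (named numeric),
#'   `bounds` and `label`.
#' @export
met_set <- function(values, label = "custom") {
  if (!is.numeric(values) || length(values) != 8L) {
    stop("`values` must be a numeric vector of length 8", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all MET values must be finite and > 0", call. = FALSE)
  }
  values <- as.numeric(values)
  names(values) <- met_categories()
  structure(list(met = values, bounds = met_bounds(), label = label),
            class = "met_set")
}

#' Midrange MET set
#'
#' The intensity assigned a priori to each category: the midpoint-style value
#' of the range shown to respondents (1.3 sitting, 1.5 standing, 2.5 walking,
#' 6.0 heavy work, 3.0 moderate, 6.0 vigorous, 10.0 very vigorous) and 1.5
#' for residual off-duty light activity.
#'
#' @return A `met_set`.
#' @export
met_midrange <- function() {
  met_set(c(1.3, 1.5, 2.5, 6.0, 3.0, 6.0, 10.0, 1.5), label = "midrange")
}

#' Estimated reference MET set
#'
#' The posterior reference intensities obtained by calibrating the
#' questionnaire against accelerometer TEE in the validation study:
#' 1.2 sitting, 1.6 standing, 1.8 walking, 4.5 heavy work, 2.4 moderate,
#' 4.4 vigorous, 9.4 very vigorous, 1.1 light.
#'
#' @return A `met_set`.
#' @export
met_estimated <- function() {
  met_set(c(1.2, 1.6, 1.8, 4.5, 2.4, 4.4, 9.4, 1.1), label = "estimated")
}

#' @export
print.met_set <- function(x, ...) {
  cat("MET set (", x$label, ")\n", sep = "")
  print(round(x$met, 3))
  invisible(x)
}

is_met_set <- function(x) inherits(x, "met_set")

as_met_set <- function(x, label = "custom") {
  if (is_met_set(x)) return(x)
  met_set(x, label = label)
}
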