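#' Paired differences between questionnaire and device TEE
#'
#' Mean and SD of the per-person difference (questionnaire - device), plus
#' the percentage difference. The percentage difference is computed on the
#' cohort means by default, `(mean(Q) - mean(L)) / mean(L) * 100`; a
#' per-pair mode (mean of the individual ratios) is available.
#'
#' @param questionnaire,device Paired numeric vectors of daily TEE, kcal/day.
#' @param percent_method `"means"` (default) or `"pairwise"`.
#' @return List with `n`, `mean_difference`, `sd_difference`,
#'   `percentage_difference`.
#' @export
paired_differences <- function(questionnaire, device,
                               percent_method = c("means", "pairwise")) {
  percent_method <- match.arg(percent_method)
  check_pairs(questionnaire, device, min_n = 2L)
  diff <- questionnaire - device
  pct <- switch(percent_method,
    means = (mean(questionnaire) - mean(device)) / mean(device) * 100,
    pairwise = mean((questionnaire - device) / device) * 100
  )
  list(n = length(diff),
       mean_difference = mean(diff),
       sd_difference = stats::sd(diff),
       percentage_difference = pct)
}

check_pairs <- function(q, l, min_n) {
  if (length(q) != length(l)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (length(q) < min_n) {
    stop("at least ", min_n, " pairs are required (got ", length(q), ")",
         call. = FALSE)
  }
  if (any(!is.finite(q)) || any(!is.finite(l))) {
    stop("paired TEE values must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Bland-Altman agreement quantities
#'
#' Bias (mean difference), 95% limits of agreement (bias +/- 1.96 SD of the
#' differences) and the per-pair plot table of (mean, difference) points.
#'
#' @inheritParams paired_differences
#' @return List with `bias`, `sd_difference`, `loa_lower`, `loa_upper`, and
#'   `table` (data.frame with columns `mean`, `difference`).
#' @export
bland_altman <- function(questionnaire, device) {
  check_pairs(questionnaire, device, min_n = 3L)
  diff <- questionnaire - device
  bias <- mean(diff)
  s <- stats::sd(diff)
  list(bias = bias,
       sd_difference = s,
       loa_lower = bias - 1.96 * s,
       loa_upper = bias + 1.96 * s,
       table = data.frame(mean = (questionnaire + device) / 2,
                          difference = diff))
}

#' Intraclass correlation coefficient, ICC(2,1) absolute agreement
#'
#' Two-way model, absolute agreement, single measurement (McGraw & Wong
#' ICC(A,1)), computed from the two-way ANOVA mean squares of the n x 2
#' (subject x method) table, with the F-distribution 95% confidence
#' interval.
#'
#' @inheritParams paired_differences
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List with `estimate`, `ci_lower`, `ci_upper`, `conf_level` and the
#'   mean squares `msr` (rows), `msc` (columns), `mse` (error).
#' @export
icc_agreement <- function(questionnaire, device, conf_level = 0.95) {
  check_pairs(questionnaire, device, min_n = 5L)
  y <- cbind(questionnaire, device)
  n <- nrow(y)
  k <- 2L
  grand <- mean(y)
  row_m <- rowMeans(y)
  col_m <- colMeans(y)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((y - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0) {
    warning("no between-subject variance; ICC is degenerate", call. = FALSE)
  }
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  est <- if (denom == 0) 1 else (msr - mse) / denom
  # F-based CI (McGraw & Wong 1996, case 2A single measure)
  alpha <- 1 - conf_level
  r <- est
  a <- k * r / (n * (1 - r))
  b <- 1 + k * r * (n - 1) / (n * (1 - r))
  if (!is.finite(a) || !is.finite(b) || mse == 0) {
    # perfect agreement: interval collapses
    return(list(estimate = est, ci_lower = est, ci_upper = est,
                conf_level = conf_level, msr = msr, msc = msc, mse = mse))
  }
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(estimate = est, ci_lower = lower, ci_upper = upper,
       conf_level = conf_level, msr = msr, msc = msc, mse = mse)
}

#' Full method-agreement report
#'
#' Bundles [paired_differences()], [bland_altman()] and [icc_agreement()]
#' for a paired cohort.
#'
#' @param pairs Data.frame with columns `id`, `questionnaire_tee`,
#'   `lifecorder_tee` (kcal/day, both positive).
#' @inheritParams paired_differences
#' @return List of class `agreement_report`.
#' @export
agreement_report <- function(pairs, percent_method = "means") {
  stopifnot(all(c("questionnaire_tee", "lifecorder_tee") %in% names(pairs)))
  q <- pairs$questionnaire_tee
  l <- pairs$lifecorder_tee
  if (any(q <= 0) || any(l <= 0)) {
    stop("TEE values must be positive", call. = FALSE)
  }
  structure(list(
    differences = paired_differences(q, l, percent_method),
    bland_altman = bland_altman(q, l),
    icc = icc_agreement(q, l)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  d <- x$differences
  cat(sprintf("Paired TEE agreement (n = %d)\n", d$n))
  cat(sprintf("  mean difference: %.1f +/- %.1f kcal/day (%.1f%%)\n",
              d$mean_difference, d$sd_difference, d$percentage_difference))
  cat(sprintf("  limits of agreement: [%.1f, %.1f] kcal/day\n",
              x$bland_altman$loa_lower, x$bland_altman$loa_upper))
  cat(sprintf("  ICC(2,1): %.2f (95%% CI %.2f-%.2f)\n",
              x$icc$estimate, x$icc$ci_lower, x$icc$ci_upper))
  invisible(x)
}
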