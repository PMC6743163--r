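#' Sequential exclusion filtering
#'
#' Applies exclusion criteria in the stated order; a record is attributed to
#' the first criterion it trips, so the per-criterion counts are mutually
#' exclusive and sum (with the retained count) to the input size.
#'
#' @param roster Data.frame carrying one logical flag column per criterion.
#' @param criteria Character vector of flag column names, in exclusion order.
#'   Defaults to the baseline-survey criteria: pregnancy, missing
#'   anthropometry, missing activity responses.
#' @return List with `retained` (the filtered roster) and `report` (list:
#'   `n_input`, `n_excluded` named by criterion, `n_retained`).
#' @export
apply_exclusions <- function(roster,
                             criteria = c("pregnant", "missing_anthro",
                                          "missing_activity")) {
  missing <- setdiff(criteria, names(roster))
  if (length(missing)) {
    stop("roster is missing exclusion flag column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n_input <- nrow(roster)
  attributed <- rep(NA_character_, n_input)
  for (crit in criteria) {
    flag <- as.logical(roster[[crit]])
    flag[is.na(flag)] <- FALSE
    hit <- flag & is.na(attributed)
    attributed[hit] <- crit
  }
  n_excluded <- vapply(criteria, function(crit) sum(attributed == crit,
                                                    na.rm = TRUE), integer(1))
  retained <- roster[is.na(attributed), , drop = FALSE]
  report <- list(n_input = n_input,
                 n_excluded = as.list(n_excluded),
                 n_retained = nrow(retained))
  stopifnot(report$n_input == sum(n_excluded) + report$n_retained)
  list(retained = retained, report = report)
}

#' Age-group labels for the baseline analysis
#'
#' Bins ages into the five study strata 25-29, 30-39, 40-49, 50-59, 60-69
#' (inclusive integer ranges; ages below 25 or at/above 70 are errors).
#'
#' @param age Numeric vector of ages in years.
#' @return Ordered factor of group labels.
#' @export
age_bin <- function(age) {
  if (any(!is.finite(age)) || any(age < 25) || any(age >= 70)) {
    bad <- age[!is.finite(age) | age < 25 | age >= 70]
    stop("age(s) outside the 25-69 study range: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  cut(age, breaks = c(25, 30, 40, 50, 60, 70), right = FALSE,
      labels = age_group_labels(), ordered_result = TRUE)
}

age_group_labels <- function() c("25-29", "30-39", "40-49", "50-59", "60-69")

#' Per-age-group TEE and MVPA summaries
#'
#' Computes questionnaire TEE (kcal/day) and MVPA (h/week) for every record
#' under the given MET set, then summarises each age group and the whole
#' cohort: n, mean, SD, median and quartiles.
#'
#' @param roster Retained, complete baseline roster (cohort schema columns).
#' @param mets A [met_set()].
#' @param table BMR reference table.
#' @param clip Passed to [questionnaire_tee()] for over-reported profiles.
#' @return Data.frame with one row per age group plus an `overall` row;
#'   attribute `met_label` carries the MET set label.
#' @export
group_summaries <- function(roster, mets, table = default_bmr_table(),
                            clip = FALSE) {
  mets <- as_met_set(mets)
  tee <- questionnaire_tee(roster, mets, table, clip = clip)
  mvpa <- mvpa_hours(roster, mets)
  grp <- age_bin(roster$age)
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  summarise_one <- function(idx, label) {
    data.frame(
      group = label, n = length(idx),
      tee_mean = mean(tee[idx]), tee_sd = sd0(tee[idx]),
      tee_median = stats::median(tee[idx]),
      tee_q25 = stats::quantile(tee[idx], 0.25, names = FALSE),
      tee_q75 = stats::quantile(tee[idx], 0.75, names = FALSE),
      mvpa_mean = mean(mvpa[idx]), mvpa_sd = sd0(mvpa[idx]),
      mvpa_median = stats::median(mvpa[idx]),
      mvpa_q25 = stats::quantile(mvpa[idx], 0.25, names = FALSE),
      mvpa_q75 = stats::quantile(mvpa[idx], 0.75, names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  rows <- list()
  for (label in levels(grp)) {
    idx <- which(grp == label)
    if (!length(idx)) {
      warning("age group ", label, " is empty; omitted", call. = FALSE)
      next
    }
    rows[[label]] <- summarise_one(idx, label)
  }
  rows[["overall"]] <- summarise_one(seq_along(tee), "overall")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "met_label") <- mets$label
  out
}

# Mann-Whitney count of (y > x) pairs with ties counted 1/2, via midranks.
mw_count <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(y) + length(x)]) - length(y) * (length(y) + 1) / 2
}

jt_statistic <- function(groups) {
  k <- length(groups)
  total <- 0
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      total <- total + mw_count(groups[[i]], groups[[j]])
    }
  }
  total
}

#' Jonckheere-Terpstra trend test across ordered groups
#'
#' Tests for a monotone location trend across `k >= 3` ordered groups. The
#' statistic is the sum over ordered group pairs of Mann-Whitney counts
#' (ties counted 1/2). The two-sided p-value uses the normal approximation
#' with tie-corrected variance; for pooled sizes `N <= 12` (or on request)
#' an exact permutation enumeration over all group assignments is used.
#'
#' @param groups List of numeric vectors, in increasing group order; each
#'   non-empty.
#' @param exact `NULL` (auto: exact when `N <= 12`), `TRUE` or `FALSE`.
#' @return List with `statistic`, `mean`, `variance`, `z`, `p_value`,
#'   `method` ("normal" or "exact").
#' @export
jonckheere_terpstra <- function(groups, exact = NULL) {
  if (!is.list(groups) || length(groups) < 3L) {
    stop("jonckheere_terpstra() needs >= 3 ordered groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop("all groups must be non-empty", call. = FALSE)
  }
  n_i <- vapply(groups, length, integer(1))
  big_n <- sum(n_i)
  pooled <- unlist(groups, use.names = FALSE)
  jt <- jt_statistic(groups)
  mu <- (big_n^2 - sum(n_i^2)) / 4

  if (is.null(exact)) exact <- big_n <= 12L
  if (exact) {
    stats_all <- jt_permutation_distribution(pooled, n_i)
    dev <- abs(stats_all - mu)
    p <- mean(dev >= abs(jt - mu) - 1e-9)
    return(list(statistic = jt, mean = mu,
                variance = stats::var(stats_all) * (length(stats_all) - 1) /
                  length(stats_all),
                z = NA_real_, p_value = p, method = "exact"))
  }

  # tie-corrected variance over the pooled tie pattern
  t_j <- table(pooled)
  f1 <- function(v) sum(v * (v - 1) * (2 * v + 5))
  f2 <- function(v) sum(v * (v - 1) * (v - 2))
  f3 <- function(v) sum(v * (v - 1))
  v <- (big_n * (big_n - 1) * (2 * big_n + 5) - f1(n_i) - f1(t_j)) / 72 +
    f2(n_i) * f2(t_j) / (36 * big_n * (big_n - 1) * (big_n - 2)) +
    f3(n_i) * f3(t_j) / (8 * big_n * (big_n - 1))
  if (v <= 0) {
    return(list(statistic = jt, mean = mu, variance = 0, z = 0, p_value = 1,
                method = "normal"))
  }
  z <- (jt - mu) / sqrt(v)
  list(statistic = jt, mean = mu, variance = v, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), method = "normal")
}

# All JT statistics over distinct assignments of the pooled values to the
# ordered groups (sizes n_i), enumerated recursively by choosing index sets.
jt_permutation_distribution <- function(pooled, n_i) {
  out <- numeric(0)
  recurse <- function(remaining_idx, groups_so_far, sizes_left) {
    if (!length(sizes_left)) {
      out[[length(out) + 1L]] <<- jt_statistic(groups_so_far)
      return(invisible(NULL))
    }
    size <- sizes_left[1L]
    if (length(sizes_left) == 1L) {
      recurse(integer(0),
              c(groups_so_far, list(pooled[remaining_idx])), integer(0))
      return(invisible(NULL))
    }
    picks <- utils::combn(remaining_idx, size, simplify = FALSE)
    for (p in picks) {
      recurse(setdiff(remaining_idx, p),
              c(groups_so_far, list(pooled[p])), sizes_left[-1L])
    }
  }
  recurse(seq_along(pooled), list(), n_i)
  unlist(out)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' @param groups Named (or unnamed) list of numeric vectors, each of length
#'   >= 2.
#' @return List with `F`, `p_value`, and `tukey` (data.frame of pairwise
#'   differences with adjusted p-values from the studentized range
#'   distribution).
#' @export
anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("anova_tukey() needs >= 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs n >= 2", call. = FALSE)
  }
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    stop("zero within-group variance in every group; ANOVA is degenerate",
         call. = FALSE)
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, integer(1))),
               levels = names(groups))
  )
  fit <- stats::aov(y ~ g, data = df)
  tab <- summary(fit)[[1L]]
  hsd <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(hsd), hsd,
                      row.names = NULL, check.names = FALSE)
  names(tukey) <- c("comparison", "diff", "lwr", "upr", "p_adj")
  list(F = tab[["F value"]][1L], p_value = tab[["Pr(>F)"]][1L], tukey = tukey)
}

#' Pairwise Mann-Whitney tests with Bonferroni adjustment
#'
#' All C(k,2) two-sided Mann-Whitney (Wilcoxon rank-sum) tests using the
#' tie-corrected normal approximation (no continuity correction), with each
#' p-value multiplied by the number of comparisons and capped at 1.
#'
#' @param groups Named (or unnamed) list of numeric vectors.
#' @param exact Use the exact rank-sum distribution (no ties only) instead
#'   of the normal approximation.
#' @return Symmetric matrix of Bonferroni-adjusted p-values (diagonal `NA`).
#' @export
pairwise_mannwhitney_bonferroni <- function(groups, exact = FALSE) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need >= 2 groups", call. = FALSE)
  }
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  m <- k * (k - 1) / 2
  p <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      raw <- stats::wilcox.test(groups[[i]], groups[[j]],
                                exact = exact, correct = FALSE)$p.value
      p[i, j] <- p[j, i] <- min(1, raw * m)
    }
  }
  p
}
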