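#' Load a cohort CSV
#'
#' Reads a validation-cohort or baseline-roster CSV (comma-separated, UTF-8,
#' "." decimal, header required) into the package's standard schema. The
#' leisure-activity columns may be reported in minutes/week — any activity
#' column headed `*_min_wk` is divided by 60 and renamed `*_h_wk`, so files
#' may mix the two conventions as the source tables do. Rows sharing an `id`
#' (two-season participants) are averaged into a single record.
#'
#' @param path CSV path.
#' @param require_device If `TRUE`, require the `lifecorder_tee_kcal_day`
#'   column (validation cohorts).
#' @param average_duplicates Average numeric columns over repeated ids.
#' @return Cohort data.frame in the standard schema (activity in h/week).
#' @export
load_cohort <- function(path, require_device = FALSE,
                        average_duplicates = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  # normalise minute-convention activity headers
  min_cols <- grep("^pa[1-7]_.*_min_wk$", names(raw), value = TRUE)
  for (col in min_cols) {
    raw[[col]] <- raw[[col]] / 60
    names(raw)[names(raw) == col] <- sub("_min_wk$", "_h_wk", col)
  }
  required <- cohort_required_columns()
  if (require_device) required <- c(required, "lifecorder_tee_kcal_day")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("cohort file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(required, c("id", "sex"))
  bad_rows <- integer(0)
  for (col in num_cols) {
    if (!is.numeric(raw[[col]])) {
      coerced <- suppressWarnings(as.numeric(raw[[col]]))
      bad_rows <- union(bad_rows,
                        which(is.na(coerced) & !is.na(raw[[col]]) &
                                nzchar(raw[[col]])))
      raw[[col]] <- coerced
    }
  }
  if (length(bad_rows)) {
    warning("dropping ", length(bad_rows), " malformed row(s) at line(s) ",
            paste(utils::head(sort(bad_rows) + 1L, 10L), collapse = ", "),
            call. = FALSE)
    raw <- raw[-bad_rows, , drop = FALSE]
  }
  if (average_duplicates && anyDuplicated(raw$id)) {
    num <- vapply(raw, is.numeric, logical(1))
    num["id"] <- FALSE
    agg <- stats::aggregate(raw[num], by = list(id = raw$id), FUN = mean)
    first <- raw[!duplicated(raw$id), !num, drop = FALSE]
    raw <- merge(first, agg, by = "id", sort = FALSE)
  }
  rownames(raw) <- NULL
  raw
}

#' Write a cohort CSV
#'
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the calibration study end to end
#'
#' Fits the MET calibration MCMC on a validation cohort, summarises the
#' posterior, computes questionnaire TEE under both the posterior-mean
#' ("estimated") and midrange MET sets, and reports agreement of each
#' against the device TEE. Optionally writes `chain.csv`,
#' `posterior.json`, `agreement_estimated.json`, `agreement_midrange.json`
#' under `out_dir`.
#'
#' @param cohort Validation cohort data.frame (with
#'   `lifecorder_tee_kcal_day`).
#' @param priors A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param table BMR reference table.
#' @param out_dir Optional output directory.
#' @return List with `chain`, `posterior` (summary data.frame),
#'   `estimated_mets`, `tee` (per-person data.frame), `agreement_estimated`,
#'   `agreement_midrange`.
#' @export
run_study1 <- function(cohort, priors = prior_spec(), config = mcmc_config(),
                       table = default_bmr_table(), out_dir = NULL) {
  chain <- run_mcmc(cohort, priors, config, table)
  posterior <- summarize_posterior(chain)
  est <- posterior_met_set(chain, label = "estimated")
  tee <- data.frame(
    id = cohort$id,
    questionnaire_tee_estimated = questionnaire_tee(cohort, est, table),
    questionnaire_tee_midrange = questionnaire_tee(cohort, met_midrange(),
                                                   table),
    lifecorder_tee = cohort$lifecorder_tee_kcal_day,
    stringsAsFactors = FALSE
  )
  agr_est <- agreement_report(data.frame(
    id = tee$id, questionnaire_tee = tee$questionnaire_tee_estimated,
    lifecorder_tee = tee$lifecorder_tee))
  agr_mid <- agreement_report(data.frame(
    id = tee$id, questionnaire_tee = tee$questionnaire_tee_midrange,
    lifecorder_tee = tee$lifecorder_tee))
  out <- list(chain = chain, posterior = posterior, estimated_mets = est,
              tee = tee, agreement_estimated = agr_est,
              agreement_midrange = agr_mid)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(chain$draws, file.path(out_dir, "chain.csv"),
                     row.names = FALSE)
    write_json(posterior, file.path(out_dir, "posterior.json"))
    write_json(unclass_report(agr_est),
               file.path(out_dir, "agreement_estimated.json"))
    write_json(unclass_report(agr_mid),
               file.path(out_dir, "agreement_midrange.json"))
    utils::write.csv(tee, file.path(out_dir, "tee.csv"), row.names = FALSE)
  }
  out
}

unclass_report <- function(agr) {
  list(differences = agr$differences,
       bland_altman = agr$bland_altman[c("bias", "sd_difference",
                                         "loa_lower", "loa_upper")],
       icc = agr$icc[c("estimate", "ci_lower", "ci_upper", "conf_level")])
}

#' Run the baseline cohort study end to end
#'
#' Applies the exclusion pipeline, summarises TEE and MVPA per age group
#' under each requested MET set, and runs the between-group battery:
#' one-way ANOVA + Tukey HSD on TEE, Jonckheere-Terpstra trend test and
#' pairwise Mann-Whitney (Bonferroni) on MVPA. Optionally writes
#' `exclusions.json`, `group_summaries.csv` and `tests.json` under
#' `out_dir`.
#'
#' @param roster Baseline roster data.frame with exclusion flag columns.
#' @param metsets Named list of [met_set()] objects (default: estimated and
#'   midrange).
#' @param table BMR reference table.
#' @param clip Passed to TEE computation for over-reported profiles.
#' @param out_dir Optional output directory.
#' @return List with `exclusions`, and per MET set: `summaries`,
#'   `anova_tee`, `jt_mvpa`, `mannwhitney_mvpa`.
#' @export
run_study2 <- function(roster,
                       metsets = list(estimated = met_estimated(),
                                      midrange = met_midrange()),
                       table = default_bmr_table(), clip = FALSE,
                       out_dir = NULL) {
  excl <- apply_exclusions(roster)
  retained <- excl$retained
  grp <- age_bin(retained$age)
  results <- list(exclusions = excl$report)
  summary_rows <- list()
  for (label in names(metsets)) {
    mets <- as_met_set(metsets[[label]])
    tee <- questionnaire_tee(retained, mets, table, clip = clip)
    mvpa <- mvpa_hours(retained, mets)
    tee_groups <- split(tee, grp)
    mvpa_groups <- split(mvpa, grp)
    summ <- group_summaries(retained, mets, table, clip = clip)
    summ$met_set <- label
    summary_rows[[label]] <- summ
    results[[label]] <- list(
      summaries = summ,
      anova_tee = anova_tukey(tee_groups),
      jt_mvpa = jonckheere_terpstra(mvpa_groups),
      mannwhitney_mvpa = pairwise_mannwhitney_bonferroni(mvpa_groups)
    )
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_json(excl$report, file.path(out_dir, "exclusions.json"))
    utils::write.csv(do.call(rbind, summary_rows),
                     file.path(out_dir, "group_summaries.csv"),
                     row.names = FALSE)
    tests <- lapply(results[names(metsets)], function(r) {
      list(anova_tee = r$anova_tee[c("F", "p_value")],
           tukey_tee = r$anova_tee$tukey,
           jt_mvpa = r$jt_mvpa[c("statistic", "z", "p_value", "method")],
           mannwhitney_mvpa = as.data.frame(r$mannwhitney_mvpa))
    })
    write_json(tests, file.path(out_dir, "tests.json"))
  }
  results
}
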