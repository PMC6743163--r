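#!/usr/bin/env Rscript
# Step 3: method agreement between questionnaire TEE and device TEE.
#
# Computes per-person questionnaire TEE under (a) the posterior-mean METs
# from step 2 and (b) the a-priori midrange METs, and compares each against
# the device TEE: mean/percentage difference, Bland-Altman limits of
# agreement and ICC(2,1). Writes the agreement report JSON and the
# Bland-Altman plot tables.

suppressPackageStartupMessages(library(metcal))
suppressPackageStartupMessages(library(optparse))

opts <- parse_args(OptionParser(option_list = list(
  make_option("--cohort", type = "character",
              default = "results/validation_cohort.csv"),
  make_option("--posterior", type = "character",
              default = "results/study1/posterior.csv"),
  make_option("--outdir", type = "character", default = "results/study1")
)))

cohort <- load_cohort(opts$cohort, require_device = TRUE)
post <- read.csv(opts$posterior)
est <- met_set(post$mean[match(met_categories(), post$parameter)],
               label = "estimated")

dir.create(opts$outdir, recursive = TRUE, showWarnings = FALSE)
for (mets in list(est, met_midrange())) {
  pairs <- data.frame(
    id = cohort$id,
    questionnaire_tee = questionnaire_tee(cohort, mets),
    lifecorder_tee = cohort$lifecorder_tee_kcal_day)
  rep <- agreement_report(pairs)
  cat(sprintf("\n== %s METs ==\n", mets$label))
  print(rep)
  jsonlite::write_json(
    list(differences = rep$differences,
         bland_altman = rep$bland_altman[c("bias", "sd_difference",
                                           "loa_lower", "loa_upper")],
         icc = rep$icc[c("estimate", "ci_lower", "ci_upper")]),
    file.path(opts$outdir, sprintf("agreement_%s.json", mets$label)),
    auto_unbox = TRUE, digits = NA)
  write.csv(rep$bland_altman$table,
            file.path(opts$outdir,
                      sprintf("bland_altman_%s.csv", mets$label)),
            row.names = FALSE)
}
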