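#!/usr/bin/env Rscript
# Step 1: simulate the accelerometer validation cohort.
#
# Draws a 31-woman cohort emulating the validation study's participant
# characteristics (age ~49, BMI ~22, sleep ~7.2 h/day, ~38 h/week of work),
# with device TEE = questionnaire TEE under the reference ("estimated") MET
# set plus 150 kcal/day of device noise. Writes the cohort CSV consumed by
# steps 2 and 3.

suppressPackageStartupMessages(library(metcal))
suppressPackageStartupMessages(library(optparse))

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 20260921L),
  make_option("--n", type = "integer", default = 31L),
  make_option("--out", type = "character",
              default = "results/validation_cohort.csv")
)))

cfg <- validation_config(n = opts$n, seed = opts$seed)
cohort <- generate_validation_cohort(cfg)
dir.create(dirname(opts$out), recursive = TRUE, showWarnings = FALSE)
write_cohort(cohort, opts$out)

work <- rowSums(cohort[, c("pa1_sit_h_wk", "pa2_stand_h_wk",
                           "pa3_walk_h_wk", "pa4_heavy_h_wk")])
cat(sprintf("wrote %d records to %s\n", nrow(cohort), opts$out))
cat(sprintf("  age %.1f +/- %.1f y; sleep %.2f h/day; work %.1f h/week\n",
            mean(cohort$age), sd(cohort$age), mean(cohort$sleep_h_day),
            mean(work)))
cat(sprintf("  device TEE %.0f +/- %.0f kcal/day (true METs: %s)\n",
            mean(cohort$lifecorder_tee_kcal_day),
            sd(cohort$lifecorder_tee_kcal_day), cfg$true_mets$label))
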