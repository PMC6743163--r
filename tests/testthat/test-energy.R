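test_that("body surface area follows the power formula", {
  expect_equal(body_surface_area(1, 1), 88.83)
  expect_equal(body_surface_area(53, 158), 14854.1497152066, tolerance = 1e-12)
  # strictly increasing in both arguments
  expect_true(body_surface_area(54, 158) > body_surface_area(53, 158))
  expect_true(body_surface_area(53, 159) > body_surface_area(53, 158))
  expect_error(body_surface_area(0, 158), "> 0")
  expect_error(body_surface_area(53, -1), "> 0")
})

test_that("basal metabolic rate combines standard value, BSA and hours", {
  # standard value 1 kcal/m2/h with BSA forced to 10,000 cm^2 -> 24 kcal/day
  tab <- data.frame(sex = "female", age_min = 18L, age_max = 79L,
                    kcal_per_m2_per_h = 1)
  w <- 50
  h <- exp((log(10000 / 88.83) - 0.444 * log(w)) / 0.663) # BSA == 10000
  expect_equal(basal_metabolic_rate(45, "female", w, h, tab), 24,
               tolerance = 1e-12)
  # default-table value, frozen from an independent evaluation
  expect_equal(basal_metabolic_rate(45, "female", 53, 158),
               1140.79869812787, tolerance = 1e-10)
  expect_error(basal_metabolic_rate(95, "female", 53, 158,
                                    default_bmr_table()),
               "age 95")
})

test_that("activity energy is MET x hours x weight x 1.05", {
  expect_equal(activity_energy(1, 1, 1), 1.05)
  expect_equal(activity_energy(3.0, 2, 50), 315.0)
  expect_equal(activity_energy(0, 5, 60), 0)
  expect_error(activity_energy(-1, 1, 1), "non-negative")
  # linear and homogeneous in each argument
  expect_equal(activity_energy(2 * 1.7, 3, 60), 2 * activity_energy(1.7, 3, 60))
})

test_that("residual light hours conserve the weekly time budget", {
  expect_equal(residual_light_hours(8, rep(0, 7)), 112)
  expect_equal(residual_light_hours(24, rep(0, 7)), 0)
  expect_error(residual_light_hours(8, c(120, rep(0, 6))), "inconsistent")
  expect_warning(
    out <- residual_light_hours(8, matrix(c(120, rep(0, 6)), 1), clip = TRUE),
    "clipped")
  expect_equal(out, 0)
  # exact conservation for accepted profiles
  set.seed(41)
  coh <- random_cohort(50)
  pa8 <- residual_light_hours(coh)
  total <- 7 * coh$sleep_h_day + rowSums(coh[, grep("^pa", names(coh))]) + pa8
  expect_equal(total, rep(168, 50), tolerance = 1e-12)
})

test_that("questionnaire TEE closes the TEF identity and matches the oracle", {
  rec <- data.frame(id = "w1", age = 45, sex = "female", weight_kg = 53,
                    height_cm = 158, sleep_h_day = 7.2,
                    pa1_sit_h_wk = 14, pa2_stand_h_wk = 12,
                    pa3_walk_h_wk = 11, pa4_heavy_h_wk = 1,
                    pa5_mod_h_wk = 0.6, pa6_vig_h_wk = 0.12,
                    pa7_vvig_h_wk = 0, stringsAsFactors = FALSE)
  # frozen from the independent fixed-point TEF oracle
  expect_equal(questionnaire_tee(rec, met_midrange()), 2063.36956604262,
               tolerance = 1e-10)
  comp <- questionnaire_tee(rec, met_midrange(), components = TRUE)
  expect_equal(comp$tef, 0.1 * comp$tee, tolerance = 1e-12)
  expect_equal(comp$sleep_ee + comp$activity_ee + comp$tef, comp$tee,
               tolerance = 1e-9)
  # degenerate all-sleep profile: TEE = BMR / 0.9
  asleep <- rec
  asleep$sleep_h_day <- 24
  asleep[grep("^pa", names(asleep))] <- 0
  expect_equal(questionnaire_tee(asleep, met_midrange()),
               basal_metabolic_rate(45, "female", 53, 158) / 0.9,
               tolerance = 1e-12)
})

test_that("questionnaire TEE is monotone in METs and weight", {
  set.seed(42)
  coh <- random_cohort(20)
  base <- questionnaire_tee(coh, met_estimated())
  for (i in 1:8) {
    up <- met_estimated()$met
    up[i] <- up[i] + 0.5
    expect_true(all(questionnaire_tee(coh, met_set(up)) >= base - 1e-12),
                info = paste("MET", i))
  }
  heavier <- coh
  heavier$weight_kg <- coh$weight_kg + 5
  expect_true(all(questionnaire_tee(heavier, met_estimated()) > base))
})

test_that("TEF closure holds on 1000 random valid profiles", {
  set.seed(7)
  coh <- random_cohort(1000)
  comp <- questionnaire_tee(coh, met_midrange(), components = TRUE)
  resid <- comp$tee - (comp$sleep_ee + comp$activity_ee)
  expect_equal(resid / comp$tee, rep(0.1, 1000), tolerance = 1e-9)
})

test_that("device TEE assembly imputes non-wear and sleep correctly", {
  # sleep-only day: all device EE 0, sleep 24 -> BMR
  bmr <- basal_metabolic_rate(45, "female", 53, 158)
  expect_equal(lifecorder_tee(rep(0, 7), rep(24, 7), 45, "female", 53, 158),
               bmr, tolerance = 1e-12)
  # a 1 h bathing episode for 60 kg adds 1.5 * 1 * 60 * 1.05 = 94.5 kcal
  nw <- data.frame(day = 1L, duration_h = 1, met = NA_real_, kind = "bathing")
  base <- lifecorder_tee(rep(1000, 7), rep(7, 7), 45, "female", 60, 158)
  with_bath <- lifecorder_tee(rep(1000, 7), rep(7, 7), 45, "female", 60, 158,
                              nonwear = nw)
  expect_equal(with_bath - base, 94.5 / 7, tolerance = 1e-12)
  # frozen 7-day fixture from the independent oracle
  nw2 <- data.frame(day = c(1L, 3L, 5L),
                    duration_h = c(0.5, 1, 0.3),
                    met = c(NA, 2.0, NA),
                    kind = c("bathing", "other-known", "bathing"))
  got <- lifecorder_tee(c(1200, 1100, 1300, 1250, 1150, 1400, 1000),
                        c(7, 7.5, 6.5, 8, 7, 7.2, 7.8),
                        45, "female", 53, 158, nonwear = nw2)
  expect_equal(got, 1571.7538905031, tolerance = 1e-10)
  expect_error(lifecorder_tee(rep(0, 6), rep(8, 6), 45, "female", 53, 158),
               "7 days")
  nw_bad <- data.frame(day = 2L, duration_h = 1, met = NA_real_,
                       kind = "unknown")
  expect_error(lifecorder_tee(rep(0, 7), rep(8, 7), 45, "female", 53, 158,
                              nonwear = nw_bad),
               "no assigned MET")
})

test_that("energy model matches the brute-force oracle on random inputs", {
  set.seed(99)
  coh <- random_cohort(100)
  for (mets in list(met_midrange(), met_estimated())) {
    expect_equal(questionnaire_tee(coh, mets), oracle_qtee(coh, mets),
                 tolerance = 1e-9)
  }
  expect_equal(body_surface_area(coh$weight_kg, coh$height_cm),
               oracle_bsa(coh$weight_kg, coh$height_cm), tolerance = 1e-12)
  for (i in 1:10) {
    dev <- runif(7, 800, 1600)
    slp <- runif(7, 5, 9)
    nw <- data.frame(day = sample(1:7, 2), duration_h = runif(2, 0.2, 1),
                     met = c(NA, runif(1, 1, 4)),
                     kind = c("bathing", "other-known"))
    got <- lifecorder_tee(dev, slp, coh$age[i], "female", coh$weight_kg[i],
                          coh$height_cm[i], nonwear = nw)
    want <- oracle_lifecorder(dev, slp, coh$age[i], "female",
                              coh$weight_kg[i], coh$height_cm[i], nonwear = nw)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("MVPA category logic depends on the MET set as documented", {
  prof <- data.frame(id = "p", age = 40, sex = "female", weight_kg = 55,
                     height_cm = 158, sleep_h_day = 7,
                     pa1_sit_h_wk = 0, pa2_stand_h_wk = 0, pa3_walk_h_wk = 0,
                     pa4_heavy_h_wk = 2, pa5_mod_h_wk = 1, pa6_vig_h_wk = 0,
                     pa7_vvig_h_wk = 0, stringsAsFactors = FALSE)
  # estimated METs: moderate (2.4) excluded -> only heavy work counts
  expect_equal(mvpa_hours(prof, met_estimated()), 2)
  # midrange METs: moderate (3.0) included at the inclusive threshold
  expect_equal(mvpa_hours(prof, met_midrange()), 3)
  empty <- prof
  empty[grep("^pa", names(empty))] <- 0
  expect_equal(mvpa_hours(empty, met_estimated()), 0)
  # qualifying category sets
  expect_equal(unname(which(met_estimated()$met[1:7] >= 3)), c(4L, 6L, 7L))
  expect_equal(unname(which(met_midrange()$met[1:7] >= 3)), c(4L, 5L, 6L, 7L))
})

test_that("MVPA responds to moving moderate time into vigorous", {
  set.seed(17)
  coh <- random_cohort(25)
  shifted <- coh
  shifted$pa6_vig_h_wk <- shifted$pa6_vig_h_wk + shifted$pa5_mod_h_wk
  shifted$pa5_mod_h_wk <- 0
  # estimated: moderate doesn't count, vigorous does -> strictly more MVPA
  gain <- mvpa_hours(shifted, met_estimated()) - mvpa_hours(coh, met_estimated())
  expect_equal(gain, coh$pa5_mod_h_wk, tolerance = 1e-12)
  # midrange: both count -> unchanged
  expect_equal(mvpa_hours(shifted, met_midrange()),
               mvpa_hours(coh, met_midrange()), tolerance = 1e-12)
  # estimated MVPA never exceeds midrange MVPA plus nothing extra beyond
  # the moderate column
  expect_true(all(mvpa_hours(coh, met_estimated()) <=
                    mvpa_hours(coh, met_midrange()) + 1e-12))
})

test_that("exercise volume weights qualifying hours by their METs", {
  prof <- data.frame(id = "p", age = 40, sex = "female", weight_kg = 55,
                     height_cm = 158, sleep_h_day = 7,
                     pa1_sit_h_wk = 0, pa2_stand_h_wk = 0, pa3_walk_h_wk = 0,
                     pa4_heavy_h_wk = 0, pa5_mod_h_wk = 1, pa6_vig_h_wk = 0,
                     pa7_vvig_h_wk = 0, stringsAsFactors = FALSE)
  expect_equal(exercise_volume(prof, met_midrange()), 3.0)
  prof$pa5_mod_h_wk <- 0
  expect_equal(exercise_volume(prof, met_midrange()), 0)
  prof$pa4_heavy_h_wk <- 2
  expect_equal(exercise_volume(prof, met_estimated()), 9.0)
})

test_that("MET set constructors carry the published values and bounds", {
  expect_equal(unname(met_midrange()$met),
               c(1.3, 1.5, 2.5, 6.0, 3.0, 6.0, 10.0, 1.5))
  expect_equal(unname(met_estimated()$met),
               c(1.2, 1.6, 1.8, 4.5, 2.4, 4.4, 9.4, 1.1))
  b <- met_bounds()
  expect_equal(b$lower, c(1.0, 1.2, 2.0, 4.0, 3.0, 5.0, 8.0, 1.0))
  expect_true(all(b$lower < b$upper))
  expect_error(met_set(c(1, 2, 3)), "length 8")
  expect_error(met_set(c(-1, rep(1, 7))), "> 0")
})
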