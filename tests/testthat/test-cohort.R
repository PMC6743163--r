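test_that("sequential exclusions attribute to the first tripped criterion", {
  # mutually exclusive flags reproduce the printed arithmetic
  roster <- exclusion_fixture_roster(
    48618, c(pregnant = 998, missing_anthro = 1416, missing_activity = 15267))
  out <- apply_exclusions(roster)
  expect_equal(out$report$n_retained, 30937)
  expect_equal(out$report$n_excluded$pregnant, 998)
  # overlapping flags: first criterion wins, counts still conserve
  r2 <- data.frame(id = 1:6,
                   pregnant = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                   missing_anthro = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
                   missing_activity = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  out2 <- apply_exclusions(r2)
  expect_equal(out2$report$n_excluded$pregnant, 2)
  expect_equal(out2$report$n_excluded$missing_anthro, 1)
  expect_equal(out2$report$n_excluded$missing_activity, 1)
  expect_equal(out2$report$n_retained, 2)
  expect_equal(out2$report$n_input,
               sum(unlist(out2$report$n_excluded)) + out2$report$n_retained)
  # empty roster
  out3 <- apply_exclusions(r2[0, ])
  expect_equal(out3$report$n_retained, 0)
  expect_equal(sum(unlist(out3$report$n_excluded)), 0)
  # custom criteria order (validation-study exclusions)
  v <- exclusion_fixture_roster(
    41, c(no_sleep_diary = 2, device_not_worn = 7, missing_activity = 1))
  outv <- apply_exclusions(v, criteria = c("no_sleep_diary",
                                           "device_not_worn",
                                           "missing_activity"))
  expect_equal(outv$report$n_retained, 31)
  expect_error(apply_exclusions(data.frame(id = 1)), "missing exclusion flag")
})

test_that("age binning uses the five study strata", {
  expect_equal(as.character(age_bin(c(25, 29, 30, 39, 40, 55, 60, 69))),
               c("25-29", "25-29", "30-39", "30-39", "40-49", "50-59",
                 "60-69", "60-69"))
  expect_error(age_bin(24), "outside")
  expect_error(age_bin(70), "outside")
  expect_true(is.ordered(age_bin(30)))
})

test_that("group summaries aggregate TEE and MVPA per stratum", {
  one <- data.frame(id = "a", age = 33, sex = "female", weight_kg = 55,
                    height_cm = 158, sleep_h_day = 7,
                    pa1_sit_h_wk = 10, pa2_stand_h_wk = 10, pa3_walk_h_wk = 5,
                    pa4_heavy_h_wk = 1, pa5_mod_h_wk = 1, pa6_vig_h_wk = 0,
                    pa7_vvig_h_wk = 0, stringsAsFactors = FALSE)
  s <- suppressWarnings(group_summaries(one, met_estimated()))
  row <- s[s$group == "30-39", ]
  expect_equal(row$n, 1)
  expect_equal(row$tee_mean, questionnaire_tee(one, met_estimated()))
  expect_equal(row$tee_sd, 0)
  expect_equal(row$tee_median, row$tee_mean)
  expect_equal(row$mvpa_mean, 1)  # heavy work only under estimated METs
  # two-group toy with hand-computed medians
  two <- rbind(one, one, one)
  two$id <- c("a", "b", "c")
  two$age <- c(33, 34, 52)
  two$pa4_heavy_h_wk <- c(1, 3, 5)
  s2 <- suppressWarnings(group_summaries(two, met_estimated()))
  expect_equal(s2$mvpa_median[s2$group == "30-39"], 2)
  expect_equal(s2$mvpa_median[s2$group == "50-59"], 5)
  expect_equal(s2$n[s2$group == "overall"], 3)
})

test_that("midrange TEE exceeds estimated TEE on the same roster", {
  roster <- generate_baseline_roster(baseline_config(n = 2000, seed = 12))
  retained <- apply_exclusions(roster)$retained
  tee_mid <- questionnaire_tee(retained, met_midrange())
  tee_est <- questionnaire_tee(retained, met_estimated())
  # midrange >= estimated componentwise except standing (1.5 vs 1.6) and
  # light; the aggregate is forced upward
  expect_gt(mean(tee_mid), mean(tee_est))
  expect_gt(mean(tee_mid > tee_est), 0.95)
})

test_that("Jonckheere-Terpstra statistic, ties, and exact enumeration", {
  # fully concordant groups: every cross-pair counts -> 4 + 4 + 4 = 12
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  r <- jonckheere_terpstra(g, exact = FALSE)
  expect_equal(r$statistic, 12)
  expect_equal(r$statistic, oracle_jt_stat(g))
  # all observations identical: no trend signal, p = 1
  r0 <- jonckheere_terpstra(list(rep(2, 3), rep(2, 3), rep(2, 3)),
                            exact = FALSE)
  expect_equal(r0$z, 0)
  expect_equal(r0$p_value, 1)
  # random small data: exact p matches the full enumeration oracle
  set.seed(51)
  for (rep_i in 1:3) {
    g3 <- list(rnorm(3), rnorm(3), rnorm(3))
    got <- jonckheere_terpstra(g3, exact = TRUE)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, oracle_jt_exact_p(g3), tolerance = 1e-12)
  }
  # with ties too
  gt <- list(c(1, 1, 2), c(2, 3, 3), c(1, 4, 4))
  expect_equal(jonckheere_terpstra(gt, exact = TRUE)$p_value,
               oracle_jt_exact_p(gt), tolerance = 1e-12)
  expect_equal(jonckheere_terpstra(gt, exact = FALSE)$statistic,
               oracle_jt_stat(gt))
  expect_error(jonckheere_terpstra(list(1:3, 4:6)), ">= 3")
  expect_error(jonckheere_terpstra(list(1:3, numeric(0), 4:6)), "non-empty")
})

test_that("JT normal approximation is sane on moderate samples", {
  set.seed(52)
  g <- lapply(1:4, function(i) rnorm(15, mean = 0.4 * i))
  r <- jonckheere_terpstra(g, exact = FALSE)
  expect_lt(r$p_value, 0.05)
  expect_gt(r$z, 0)
  # declining trend gives negative z
  rdec <- jonckheere_terpstra(rev(g), exact = FALSE)
  expect_lt(rdec$z, 0)
})

test_that("one-way ANOVA with Tukey matches base aov and the two-group t-test", {
  set.seed(53)
  g <- list(a = rnorm(10, 0), b = rnorm(10, 0.1), c = rnorm(10, 1))
  r <- anova_tukey(g)
  # independent sums-of-squares computation
  y <- unlist(g)
  grand <- mean(y)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  f_hand <- (ssb / 2) / (ssw / 27)
  expect_equal(r$F, f_hand, tolerance = 1e-10)
  expect_equal(nrow(r$tukey), 3)
  # identical group means: F ~ 0, adjusted p ~ 1
  gg <- list(a = c(1, 2, 3), b = c(2, 1, 3), c = c(3, 2, 1))
  r2 <- anova_tukey(gg)
  expect_lt(r2$F, 1e-10)
  expect_true(all(r2$tukey$p_adj > 0.999))
  # two groups: Tukey adjusted p equals the pooled-variance t-test p
  g2 <- list(a = rnorm(8), b = rnorm(8, 0.7))
  r3 <- anova_tukey(g2)
  t_p <- t.test(g2$a, g2$b, var.equal = TRUE)$p.value
  expect_equal(r3$tukey$p_adj, t_p, tolerance = 1e-6)
  expect_error(anova_tukey(list(a = c(1, 1), b = c(2, 2))), "degenerate")
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("pairwise Mann-Whitney applies the Bonferroni multiplier", {
  set.seed(54)
  g5 <- lapply(1:5, function(i) rnorm(12, 0.3 * i))
  p <- pairwise_mannwhitney_bonferroni(g5)
  expect_equal(dim(p), c(5, 5))
  expect_equal(sum(!is.na(p)) / 2, 10)  # C(5,2) comparisons
  raw12 <- wilcox.test(g5[[1]], g5[[2]], exact = FALSE,
                       correct = FALSE)$p.value
  expect_equal(p[1, 2], min(1, raw12 * 10), tolerance = 1e-12)
  expect_true(all(p[upper.tri(p)] >= raw12 * 0 &
                    p[upper.tri(p)] <= 1))
  # identical groups -> all adjusted p = 1
  gid <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  expect_equal(pairwise_mannwhitney_bonferroni(gid)[1, 2], 1)
  # tiny fixture: exact mode matches the enumeration oracle
  x <- c(1.2, 3.4, 2.2); y <- c(5.1, 4.4, 6.0, 2.9)
  got <- pairwise_mannwhitney_bonferroni(list(x = x, y = y), exact = TRUE)
  expect_equal(got[1, 2], oracle_mw_exact_p(x, y), tolerance = 1e-12)
})
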