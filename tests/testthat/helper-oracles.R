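# Independent brute-force reimplementations of the energy model and the
# statistics, used as oracles. Deliberately written with different code
# paths than the package (scalar loops, fixed-point TEF iteration,
# aov()-based mean squares, exhaustive enumeration).

oracle_bsa <- function(w, h) 88.83 * exp(0.444 * log(w) + 0.663 * log(h))

oracle_bmr <- function(std, w, h) std * oracle_bsa(w, h) * 24 * (1 / 10000)

oracle_std_value <- function(age, sex, table) {
  for (r in seq_len(nrow(table))) {
    if (table$sex[r] == sex && age >= table$age_min[r] &&
        age <= table$age_max[r]) {
      return(table$kcal_per_m2_per_h[r])
    }
  }
  stop("no band")
}

# Questionnaire TEE for one record, with TEF obtained by fixed-point
# iteration of TEE = base + TEF, TEF = TEE / 10 (rather than the algebraic
# closure the package uses).
oracle_qtee_record <- function(rec, mets, table) {
  std <- oracle_std_value(rec$age, rec$sex, table)
  bmr <- oracle_bmr(std, rec$weight_kg, rec$height_cm)
  pa <- c(rec$pa1_sit_h_wk, rec$pa2_stand_h_wk, rec$pa3_walk_h_wk,
          rec$pa4_heavy_h_wk, rec$pa5_mod_h_wk, rec$pa6_vig_h_wk,
          rec$pa7_vvig_h_wk)
  pa8 <- 168 - 7 * rec$sleep_h_day - sum(pa)
  stopifnot(pa8 >= -1e-9)
  paw <- c(pa, max(pa8, 0))
  m <- if (inherits(mets, "met_set")) mets$met else mets
  base <- bmr * rec$sleep_h_day / 24
  for (i in 1:8) {
    base <- base + rec$weight_kg * 1.05 * (paw[i] / 7) * m[i]
  }
  tee <- base
  for (it in 1:400) {
    new <- base + 0.1 * tee
    if (abs(new - tee) < 1e-12) break
    tee <- new
  }
  tee
}

oracle_qtee <- function(cohort, mets, table = default_bmr_table()) {
  vapply(seq_len(nrow(cohort)), function(i) {
    oracle_qtee_record(cohort[i, ], mets, table)
  }, numeric(1))
}

oracle_lifecorder <- function(daily_ee, sleep, age, sex, w, h,
                              nonwear = NULL, table = default_bmr_table()) {
  std <- oracle_std_value(age, sex, table)
  bmr <- oracle_bmr(std, w, h)
  total <- 0
  for (d in 1:7) {
    day <- daily_ee[d] + bmr * sleep[d] / 24
    if (!is.null(nonwear)) {
      for (r in seq_len(nrow(nonwear))) {
        if (nonwear$day[r] == d) {
          m <- if (nonwear$kind[r] == "bathing") 1.5 else nonwear$met[r]
          day <- day + m * nonwear$duration_h[r] * w * 1.05
        }
      }
    }
    total <- total + day
  }
  total / 7
}

oracle_log_posterior <- function(mets, sigma, cohort, priors, table) {
  mets <- unname(mets)
  if (priors$truncate) {
    b <- priors$bounds
    if (any(mets < b$lower | mets >= b$upper)) return(-Inf)
  }
  if (sigma <= 0) return(-Inf)
  q <- oracle_qtee(cohort, mets, table)
  ll <- 0
  for (j in seq_along(q)) {
    ll <- ll + dnorm(cohort$lifecorder_tee_kcal_day[j], q[j], sigma,
                     log = TRUE)
  }
  lp <- 0
  for (i in 1:8) {
    lp <- lp + dgamma(mets[i], shape = priors$shape[i], rate = priors$rate[i],
                      log = TRUE)
  }
  s <- priors$sigma_scale
  lp_sigma <- log(2) - log(s) - 0.5 * log(2 * pi) - sigma^2 / (2 * s^2)
  ll + lp + lp_sigma
}

# ICC(A,1) via aov() mean squares (long-format two-way ANOVA).
oracle_icc <- function(q, l) {
  n <- length(q)
  df <- data.frame(y = c(q, l),
                   subject = factor(rep(seq_len(n), 2)),
                   method = factor(rep(c("q", "l"), each = n)))
  ms <- summary(aov(y ~ subject + method, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}

# JT statistic by triple loops.
oracle_jt_stat <- function(groups) {
  total <- 0
  k <- length(groups)
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      for (x in groups[[i]]) {
        for (y in groups[[j]]) {
          total <- total + (y > x) + 0.5 * (y == x)
        }
      }
    }
  }
  total
}

# Exact two-sided JT permutation p-value for exactly 3 groups, by nested
# combn enumeration (independent of the package's recursive enumerator).
oracle_jt_exact_p <- function(groups) {
  stopifnot(length(groups) == 3)
  pooled <- unlist(groups)
  n1 <- length(groups[[1]]); n2 <- length(groups[[2]])
  n3 <- length(groups[[3]]); N <- n1 + n2 + n3
  obs <- oracle_jt_stat(groups)
  stats_all <- c()
  for (s1 in combn(N, n1, simplify = FALSE)) {
    rest <- setdiff(seq_len(N), s1)
    for (s2 in combn(rest, n2, simplify = FALSE)) {
      s3 <- setdiff(rest, s2)
      stats_all <- c(stats_all,
                     oracle_jt_stat(list(pooled[s1], pooled[s2], pooled[s3])))
    }
  }
  mu <- mean(stats_all)
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}

# Exact two-sided Mann-Whitney p by enumeration (no ties).
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled); n1 <- length(x)
  u_obs <- sum(outer(x, y, ">")) # U for x over y
  us <- sapply(combn(N, n1, simplify = FALSE), function(idx) {
    sum(outer(pooled[idx], pooled[-idx], ">"))
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# A random valid cohort for property tests (draws kept strictly inside the
# time budget).
random_cohort <- function(n, with_device = FALSE) {
  sleep <- runif(n, 5, 9)
  pa <- matrix(0, n, 7)
  for (i in seq_len(n)) {
    budget <- 168 - 7 * sleep[i]
    raw <- runif(7, 0, c(40, 40, 30, 8, 4, 2, 1))
    if (sum(raw) > 0.9 * budget) raw <- raw * 0.9 * budget / sum(raw)
    pa[i, ] <- raw
  }
  colnames(pa) <- c("pa1_sit_h_wk", "pa2_stand_h_wk", "pa3_walk_h_wk",
                    "pa4_heavy_h_wk", "pa5_mod_h_wk", "pa6_vig_h_wk",
                    "pa7_vvig_h_wk")
  cohort <- data.frame(id = sprintf("R%04d", seq_len(n)),
                       age = sample(25:69, n, replace = TRUE),
                       sex = "female",
                       weight_kg = runif(n, 42, 80),
                       height_cm = runif(n, 145, 175),
                       sleep_h_day = sleep,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(pa))
  if (with_device) {
    cohort$lifecorder_tee_kcal_day <-
      questionnaire_tee(cohort, met_estimated()) + rnorm(n, 0, 120)
  }
  cohort
}
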