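#' Prior specification for MET calibration
#'
#' Independent gamma priors on the eight MET intensities and a half-normal
#' prior on the residual scale sigma. By default each gamma prior is centred
#' on the midrange MET value with shape 4 (coefficient of variation 0.5),
#' giving the right-skewed positive support the calibration assumes without
#' dominating the likelihood. The questionnaire's printed intensity ranges
#' can optionally be imposed as hard truncation bounds; this is off by
#' default because the reference estimates themselves fall outside the
#' printed ranges for three categories.
#'
#' @param mean Prior means, length 8 (default: midrange MET values).
#' @param shape Gamma shapes, length 8 or scalar (default 4).
#' @param truncate Impose the printed category bounds as hard support limits?
#' @param bounds Bounds table as from [met_bounds()].
#' @param sigma_scale Scale (kcal) of the half-normal prior on the residual
#'   SD sigma; default 300 kcal (weakly informative on the daily-TEE scale).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mean = met_midrange()$met, shape = 4,
                       truncate = FALSE, bounds = met_bounds(),
                       sigma_scale = 300) {
  shape <- rep_len(shape, 8L)
  mean <- rep_len(as.numeric(mean), 8L)
  stopifnot(all(shape > 0), all(mean > 0), sigma_scale > 0,
            all(bounds$lower < bounds$upper))
  structure(list(shape = shape, rate = shape / mean, mean = mean,
                 truncate = isTRUE(truncate), bounds = bounds,
                 sigma_scale = sigma_scale),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' @param n_burnin Burn-in iterations discarded (default 1000).
#' @param n_keep Kept iterations (default 10,000).
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param init_mets Initial MET values (default midrange).
#' @param init_sigma Initial residual SD, kcal (default 200).
#' @param proposal_scale Initial log-scale random-walk SDs for the 9
#'   parameters (MET1..8, sigma).
#' @param target_accept Robbins-Monro target acceptance rate for the
#'   componentwise updates (default 0.44); adaptation runs during burn-in
#'   only, so the kept chain is Markov.
#' @param fixed Logical length-9 vector; `TRUE` components are held at their
#'   initial values (useful for conditional-posterior checks).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_burnin = 1000, n_keep = 10000, seed = NULL,
                        init_mets = met_midrange(), init_sigma = 200,
                        proposal_scale = rep(0.15, 9L), target_accept = 0.44,
                        fixed = rep(FALSE, 9L)) {
  stopifnot(n_burnin > 0, n_keep > 0, init_sigma > 0,
            length(proposal_scale) == 9L, all(proposal_scale > 0),
            length(fixed) == 9L)
  structure(list(n_burnin = as.integer(n_burnin), n_keep = as.integer(n_keep),
                 seed = seed, init_mets = as_met_set(init_mets),
                 init_sigma = init_sigma, proposal_scale = proposal_scale,
                 target_accept = target_accept, fixed = as.logical(fixed)),
            class = "mcmc_config")
}

# Linearised questionnaire-TEE design: Q = a + X %*% met, per record.
# a is the sleep/BMR term and X the per-MET activity coefficients, both
# already divided by 0.9 so the TEF closure is baked in.
tee_design <- function(cohort, table = default_bmr_table()) {
  pa <- pa_matrix(cohort)
  pa8 <- residual_light_hours(cohort$sleep_h_day, pa)
  bmr <- basal_metabolic_rate(cohort$age, cohort$sex, cohort$weight_kg,
                              cohort$height_cm, table)
  a <- bmr * cohort$sleep_h_day / 24 / 0.9
  X <- cbind(pa, pa8) / 7 * (cohort$weight_kg * 1.05 / 0.9)
  colnames(X) <- met_categories()
  list(a = as.numeric(a), X = X,
       L = cohort$lifecorder_tee_kcal_day)
}

log_prior_mets <- function(mets, priors) {
  if (priors$truncate &&
      (any(mets < priors$bounds$lower) || any(mets >= priors$bounds$upper))) {
    return(-Inf)
  }
  sum(stats::dgamma(mets, shape = priors$shape, rate = priors$rate, log = TRUE))
}

log_prior_sigma <- function(sigma, priors) {
  if (sigma <= 0) return(-Inf)
  s <- priors$sigma_scale
  log(2) - log(s) - 0.5 * log(2 * pi) - sigma^2 / (2 * s^2)
}

#' Log posterior density of the calibration model
#'
#' Observation model: accelerometer TEE_j ~ Normal(Q_j(mets), sigma^2),
#' independent across participants, where Q_j is the questionnaire TEE of
#' record j under the candidate MET vector. Returns the unnormalised log
#' posterior (full normal log-likelihood including constants, plus gamma
#' log-priors on the METs and the half-normal log-prior on sigma); `-Inf`
#' outside the prior support.
#'
#' @param mets Numeric vector of 8 candidate MET values.
#' @param sigma Residual SD, kcal.
#' @param cohort Validation cohort data.frame including
#'   `lifecorder_tee_kcal_day`.
#' @param priors A [prior_spec()].
#' @param table BMR reference table.
#' @return Log density (scalar).
#' @export
log_posterior <- function(mets, sigma, cohort, priors = prior_spec(),
                          table = default_bmr_table()) {
  if (nrow(cohort) == 0L) {
    stop("empty validation cohort", call. = FALSE)
  }
  if (is.null(cohort$lifecorder_tee_kcal_day)) {
    stop("cohort lacks the `lifecorder_tee_kcal_day` column", call. = FALSE)
  }
  lp <- log_prior_mets(mets, priors) + log_prior_sigma(sigma, priors)
  if (!is.finite(lp)) return(-Inf)
  d <- tee_design(cohort, table)
  q <- d$a + as.numeric(d$X %*% mets)
  lp + sum(stats::dnorm(d$L, mean = q, sd = sigma, log = TRUE))
}

#' Run the MET calibration MCMC
#'
#' Componentwise random-walk Metropolis on the log scale over the nine
#' parameters (MET1..MET8, sigma), with Robbins-Monro adaptation of the
#' proposal scales towards the target acceptance rate during burn-in only.
#' The questionnaire TEE is linear in the MET vector, so proposals are
#' evaluated by incremental residual updates.
#'
#' @inheritParams log_posterior
#' @param config An [mcmc_config()].
#' @return An object of class `met_chain`: list with `draws` (n_keep x 9
#'   matrix, columns MET categories then `sigma`), `accept` (per-parameter
#'   acceptance rates over kept iterations), `proposal_scale` (adapted),
#'   `config` and `priors` echoes.
#' @export
run_mcmc <- function(cohort, priors = prior_spec(), config = mcmc_config(),
                     table = default_bmr_table()) {
  if (nrow(cohort) < 2L) {
    stop("MET calibration needs at least 2 validation records", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  d <- tee_design(cohort, table)
  n <- length(d$L)
  degenerate <- colSums(abs(d$X)) < 1e-8
  if (any(degenerate)) {
    warning("no activity time recorded for category(ies): ",
            paste(colnames(d$X)[degenerate], collapse = ", "),
            "; the corresponding MET posterior(s) are prior-dominated",
            call. = FALSE)
  }

  mets <- as.numeric(config$init_mets$met)
  sigma <- config$init_sigma
  if (priors$truncate) {
    # start inside the truncated support
    lo <- priors$bounds$lower
    hi <- priors$bounds$upper
    mets <- pmin(pmax(mets, lo), ifelse(is.finite(hi), hi - 1e-6, mets))
  }
  scales <- config$proposal_scale
  fixed <- config$fixed
  target <- config$target_accept

  resid <- d$L - d$a - as.numeric(d$X %*% mets)
  rss <- sum(resid^2)
  loglik <- -n * log(sigma) - rss / (2 * sigma^2)
  lp_met <- vapply(1:8, function(i) {
    stats::dgamma(mets[i], priors$shape[i], priors$rate[i], log = TRUE)
  }, numeric(1))

  n_iter <- config$n_burnin + config$n_keep
  draws <- matrix(NA_real_, config$n_keep, 9L,
                  dimnames = list(NULL, c(met_categories(), "sigma")))
  acc_kept <- numeric(9L)

  in_bounds <- function(i, value) {
    !priors$truncate ||
      (value >= priors$bounds$lower[i] && value < priors$bounds$upper[i])
  }

  for (iter in seq_len(n_iter)) {
    adapting <- iter <= config$n_burnin
    gamma_rm <- 1 / max(iter, 10)^0.6
    for (i in 1:8) {
      if (fixed[i]) next
      prop <- mets[i] * exp(stats::rnorm(1, 0, scales[i]))
      alpha <- 0
      if (in_bounds(i, prop)) {
        dq <- d$X[, i] * (prop - mets[i])
        new_resid <- resid - dq
        new_rss <- sum(new_resid^2)
        new_loglik <- -n * log(sigma) - new_rss / (2 * sigma^2)
        new_lp <- stats::dgamma(prop, priors$shape[i], priors$rate[i],
                                log = TRUE)
        # log-scale random walk: Jacobian term log(prop) - log(current)
        lr <- (new_loglik - loglik) + (new_lp - lp_met[i]) +
          log(prop) - log(mets[i])
        alpha <- min(1, exp(lr))
        if (stats::runif(1) < alpha) {
          mets[i] <- prop
          resid <- new_resid
          rss <- new_rss
          loglik <- new_loglik
          lp_met[i] <- new_lp
          if (!adapting) acc_kept[i] <- acc_kept[i] + 1
        }
      }
      if (adapting) scales[i] <- scales[i] * exp(gamma_rm * (alpha - target))
    }
    if (!fixed[9L]) {
      prop <- sigma * exp(stats::rnorm(1, 0, scales[9L]))
      new_loglik <- -n * log(prop) - rss / (2 * prop^2)
      lr <- (new_loglik - loglik) +
        (log_prior_sigma(prop, priors) - log_prior_sigma(sigma, priors)) +
        log(prop) - log(sigma)
      alpha <- min(1, exp(lr))
      if (stats::runif(1) < alpha) {
        sigma <- prop
        loglik <- new_loglik
        if (!adapting) acc_kept[9L] <- acc_kept[9L] + 1
      }
      if (adapting) scales[9L] <- scales[9L] * exp(gamma_rm * (alpha - target))
    }
    if (!adapting) {
      draws[iter - config$n_burnin, ] <- c(mets, sigma)
    }
  }

  structure(list(draws = draws,
                 accept = acc_kept / config$n_keep,
                 proposal_scale = scales,
                 config = config, priors = priors, n_records = n),
            class = "met_chain")
}

#' @export
print.met_chain <- function(x, ...) {
  cat("MET calibration chain: ", nrow(x$draws), " kept draws, ",
      x$n_records, " records\n", sep = "")
  print(round(colMeans(x$draws), 3))
  invisible(x)
}

# Spectral density at frequency zero via an AR fit (for the Geweke
# diagnostic); falls back to the sample variance for degenerate chains.
spectrum0_ar <- function(x) {
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(0)
  fit <- try(stats::ar(x, aic = TRUE), silent = TRUE)
  if (inherits(fit, "try-error") || length(fit$ar) == 0L) return(v)
  fit$var.pred / (1 - sum(fit$ar))^2
}

effective_sample_size <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  lag_max <- min(n - 1L, max(50L, floor(10 * log10(n))))
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1L]
  # initial positive-sum truncation: stop at the first non-positive lag
  neg <- which(rho <= 0)
  if (length(neg)) rho <- rho[seq_len(neg[1L] - 1L)]
  ess <- n / (1 + 2 * sum(rho))
  min(max(ess, 1), n)
}

geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  x1 <- x[seq_len(max(2L, floor(frac1 * n)))]
  x2 <- x[seq.int(n - max(2L, floor(frac2 * n)) + 1L, n)]
  denom <- spectrum0_ar(x1) / length(x1) + spectrum0_ar(x2) / length(x2)
  if (denom <= 0) return(0)
  (mean(x1) - mean(x2)) / sqrt(denom)
}

#' Summarise a calibration chain
#'
#' Posterior mean, SD, empirical 2.5% and 97.5% percentiles, effective
#' sample size (autocorrelation-sum estimator) and the Geweke z-score
#' (first 10% vs last 50% of the chain) for each parameter.
#'
#' @param chain A `met_chain` from [run_mcmc()], or a draws matrix.
#' @return A data.frame, one row per parameter.
#' @export
summarize_posterior <- function(chain) {
  draws <- if (inherits(chain, "met_chain")) chain$draws else as.matrix(chain)
  if (nrow(draws) == 0L) stop("empty chain", call. = FALSE)
  out <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    q2.5 = apply(draws, 2, stats::quantile, probs = 0.025, names = FALSE),
    q97.5 = apply(draws, 2, stats::quantile, probs = 0.975, names = FALSE),
    ess = apply(draws, 2, effective_sample_size),
    geweke_z = apply(draws, 2, geweke_z),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Posterior-mean MET set from a chain
#'
#' @param chain A `met_chain`.
#' @param label Label for the resulting [met_set()].
#' @return A `met_set` of the eight posterior means.
#' @export
posterior_met_set <- function(chain, label = "posterior_mean") {
  stopifnot(inherits(chain, "met_chain"))
  met_set(colMeans(chain$draws[, 1:8, drop = FALSE]), label = label)
}
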