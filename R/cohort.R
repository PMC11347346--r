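# Synthetic patient-cohort generator emulating a contemporary head-and-neck
# radiotherapy registry: covariates, a regimen mix with realistic frequencies,
# BED-derived treatment, Weibull proportional-hazards survival with a
# threshold BED effect, right censoring and competing causes of death.

#' Specification of a synthetic cohort
#'
#' Collects every parameter of the synthetic data-generating process:
#' covariate distributions, the fractionation-regimen mix, the survival
#' model (Weibull proportional hazards with a piecewise/threshold effect of
#' the dose-dependent BED), censoring, and competing causes of death.
#' Defaults emulate the published registry: 3,346 patients, the published
#' regimen frequencies, a mostly male HPV-driven oropharyngeal population,
#' and a protective effect of BED above 61.8 Gy.
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; identical spec + seed gives an identical
#'   cohort.
#' @param regimen_weights Data frame with `fractions`, `dose_per_fraction`,
#'   `fractions_per_day`, `prob`; defaults to the published regimen
#'   frequencies ([radcure_regimen_table()]).
#' @param covariate_params,effect_params,censoring_params,competing_risk_params
#'   Named lists overriding individual defaults (see the package vignette
#'   for each entry's meaning and units).
#' @param confounding Log-odds shift of receiving a high-BED regimen per
#'   unit of (stage - 3); 0 means regimen assignment is independent of
#'   covariates.
#' @param alpha_beta Alpha/beta ratios (Gy) at which BED columns are added;
#'   a single value yields columns `bed_simp`, `bed_di`, `bed_dd`, several
#'   values add suffixed variants (`bed_dd_7`, ...).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 3346, seed = 1,
                        regimen_weights = NULL,
                        covariate_params = list(),
                        effect_params = list(),
                        censoring_params = list(),
                        competing_risk_params = list(),
                        confounding = 0,
                        alpha_beta = 10) {
  if (n_patients < 1) stop("`n_patients` must be positive", call. = FALSE)
  if (is.null(regimen_weights)) {
    tab <- radcure_regimen_table()
    regimen_weights <- data.frame(
      fractions = tab$fractions,
      dose_per_fraction = tab$dose_per_fraction,
      fractions_per_day = tab$fractions_per_day,
      prob = tab$n_patients / sum(tab$n_patients))
  }
  if (abs(sum(regimen_weights$prob) - 1) > 1e-8 ||
      any(regimen_weights$prob < 0))
    stop("regimen weights must be non-negative and sum to 1", call. = FALSE)

  cov_def <- list(
    age_mean = 62, age_sd = 11, age_range = c(25, 90),
    p_male = 0.77,
    smoking_p_zero = 0.35, smoking_shape = 2, smoking_scale = 15,
    stage_probs = c(0.03, 0.10, 0.15, 0.32, 0.40),   # stages 0..4
    hpv_probs = c(positive = 0.60, negative = 0.17, unknown = 0.23),
    p_chemo = 0.55,
    rt_years = 2005:2017,
    site_probs = c(Oropharynx = 0.50, Larynx = 0.20,
                   Lip_Oral_Cavity = 0.12, Hypopharynx = 0.06,
                   Nasal_Cavity = 0.02, Esophagus = 0.02, none = 0.08))
  eff_def <- list(
    baseline_shape = 1.1, baseline_scale = 9,
    beta = c(Age = 0.035, Sex = 0.10, Smoking_PY = 0.006,
             Stage_numeric = 0.25, HPV_Positive = -0.7,
             HPV_Unknown = -0.2, Chemo = -0.3, RT_year = -0.02),
    centers = c(Age = 62, Sex = 0.77, Smoking_PY = 20, Stage_numeric = 3,
                HPV_Positive = 0.6, HPV_Unknown = 0.23, Chemo = 0.55,
                RT_year = 2011),
    bed_threshold = 61.8,        # Gy, on the dose-dependent BED scale
    bed_loghr = -0.28,           # log hazard ratio of the high-BED arm
    effect_modifier = NULL)      # e.g. list(variable="Stage_numeric", max_value=2)
  cen_def <- list(rate = 0.05, admin_cap = 12)
  cmp_def <- list(base_probs = c(index_cancer = 0.45, other_cancer = 0.20,
                                 other_causes = 0.35),
                  age_coef = 0.03)

  stopifnot(all(names(covariate_params) %in% names(cov_def)),
            all(names(effect_params) %in% names(eff_def)),
            all(names(censoring_params) %in% names(cen_def)),
            all(names(competing_risk_params) %in% names(cmp_def)))
  cov_def[names(covariate_params)] <- covariate_params
  eff_def[names(effect_params)] <- effect_params
  cen_def[names(censoring_params)] <- censoring_params
  cmp_def[names(competing_risk_params)] <- competing_risk_params
  bad <- c(cov_def$p_male, cov_def$smoking_p_zero, cov_def$p_chemo,
           cov_def$stage_probs, cov_def$hpv_probs, cov_def$site_probs,
           cmp_def$base_probs)
  if (any(bad < 0) || any(bad > 1))
    stop("probabilities in the spec must lie in [0, 1]", call. = FALSE)

  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 regimen_weights = regimen_weights,
                 covariate_params = cov_def, effect_params = eff_def,
                 censoring_params = cen_def,
                 competing_risk_params = cmp_def,
                 confounding = confounding, alpha_beta = alpha_beta),
            class = "cohort_spec")
}

#' Two-arm randomized cohort specification
#'
#' Convenience wrapper for causal validation runs: patients are assigned
#' with probability `p_high` to the standard high-BED schedule (35 x 2 Gy)
#' and otherwise to a low-BED schedule (25 x 2 Gy), independently of all
#' covariates, which makes the binarised BED a randomized treatment.
#'
#' @inheritParams cohort_spec
#' @param p_high Probability of the high-BED arm.
#' @param ... Passed on to [cohort_spec()].
#' @export
randomized_cohort_spec <- function(n_patients = 5000, seed = 1,
                                   p_high = 0.5, ...) {
  w <- data.frame(fractions = c(35L, 25L), dose_per_fraction = c(2, 2),
                  fractions_per_day = 1L, prob = c(p_high, 1 - p_high))
  cohort_spec(n_patients = n_patients, seed = seed, regimen_weights = w,
              confounding = 0, ...)
}

# Draw the covariate block of a cohort (no regimen, no outcome).
draw_covariates <- function(spec, n) {
  cp <- spec$covariate_params
  age <- rnorm(n, cp$age_mean, cp$age_sd)
  age <- pmin(pmax(age, cp$age_range[1]), cp$age_range[2])
  sex <- rbinom(n, 1, cp$p_male)
  smoking <- ifelse(runif(n) < cp$smoking_p_zero, 0,
                    rgamma(n, shape = cp$smoking_shape,
                           scale = cp$smoking_scale))
  stage <- sample(0:4, n, replace = TRUE, prob = cp$stage_probs)
  hpv <- sample(names(cp$hpv_probs), n, replace = TRUE,
                prob = cp$hpv_probs)
  chemo <- rbinom(n, 1, cp$p_chemo)
  rt_year <- sample(cp$rt_years, n, replace = TRUE)
  site <- sample(names(cp$site_probs), n, replace = TRUE,
                 prob = cp$site_probs)
  d <- data.frame(Age = age, Sex = sex, Smoking_PY = smoking,
                  Stage_numeric = stage,
                  HPV_Positive = as.integer(hpv == "positive"),
                  HPV_Unknown = as.integer(hpv == "unknown"),
                  Chemo = chemo, RT_year = rt_year)
  for (s in cohort_sites) d[[s]] <- as.integer(site == s)
  d
}

# Linear predictor of the Weibull PH model, excluding the treatment term.
cohort_lp <- function(spec, covariates) {
  ep <- spec$effect_params
  lp <- rep(0, nrow(covariates))
  for (nm in names(ep$beta))
    lp <- lp + ep$beta[[nm]] * (covariates[[nm]] - ep$centers[[nm]])
  lp
}

# Per-patient treatment log-hazard term under optional effect modification.
cohort_theta <- function(spec, covariates) {
  ep <- spec$effect_params
  theta <- rep(ep$bed_loghr, nrow(covariates))
  mod <- ep$effect_modifier
  if (!is.null(mod))
    theta <- theta * as.numeric(covariates[[mod$variable]] <= mod$max_value)
  theta
}

# BED columns for given regimen assignment, at each alpha/beta ratio.
add_bed_columns <- function(d, spec) {
  reg <- d[, c("fractions", "dose_per_fraction", "fractions_per_day")]
  for (r in spec$alpha_beta) {
    suffix <- if (length(spec$alpha_beta) == 1L) "" else paste0("_", r)
    g_di <- repopulation_params_di()$g
    g_dd <- repopulation_params_dd()$g
    d[[paste0("bed_simp", suffix)]] <- bed_simp(reg, r = r)
    d[[paste0("bed_di", suffix)]] <-
      bed_di(reg, repopulation_params_di(r = r, g = g_di))
    d[[paste0("bed_dd", suffix)]] <-
      bed_dd(reg, repopulation_params_dd(r = r, g = g_dd))
  }
  d
}

#' Generate a synthetic cohort
#'
#' Draws covariates, assigns a fractionation regimen (optionally confounded
#' by stage), derives the three BED variants, and simulates survival from a
#' Weibull proportional-hazards model whose log hazard is linear in the
#' covariates plus a threshold term for high dose-dependent BED. Right
#' censoring combines an exponential loss-to-follow-up process with an
#' administrative cap; deaths are assigned a cause from age-tilted
#' cause-specific probabilities.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame of class `cohort_table`; one row per patient with
#'   covariates, regimen and BED columns, `time` (years), `event` (0/1) and
#'   `cause` (`none`, `index_cancer`, `other_cancer`, `other_causes`).
#' @examples
#' head(sample_cohort(cohort_spec(n_patients = 100, seed = 7)))
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    d <- draw_covariates(spec, n)

    # regimen assignment, optionally tilted by stage toward high-BED
    w <- spec$regimen_weights
    reg_bed <- bed_dd(data.frame(fractions = w$fractions,
                                 dose_per_fraction = w$dose_per_fraction,
                                 fractions_per_day = w$fractions_per_day))
    high <- reg_bed > spec$effect_params$bed_threshold
    p_high0 <- sum(w$prob[high])
    if (spec$confounding != 0 && p_high0 > 0 && p_high0 < 1) {
      p_high <- stats::plogis(stats::qlogis(p_high0) +
                                spec$confounding * (d$Stage_numeric - 3))
      grp <- runif(n) < p_high
      idx <- integer(n)
      if (any(grp))
        idx[grp] <- which(high)[sample.int(sum(high), sum(grp),
                                           replace = TRUE,
                                           prob = w$prob[high])]
      if (any(!grp))
        idx[!grp] <- which(!high)[sample.int(sum(!high), sum(!grp),
                                             replace = TRUE,
                                             prob = w$prob[!high])]
    } else {
      idx <- sample(seq_len(nrow(w)), n, replace = TRUE, prob = w$prob)
    }
    d$fractions <- w$fractions[idx]
    d$dose_per_fraction <- w$dose_per_fraction[idx]
    d$fractions_per_day <- w$fractions_per_day[idx]
    d$total_dose <- d$fractions * d$dose_per_fraction
    d <- add_bed_columns(d, spec)

    # survival process
    ep <- spec$effect_params
    ab <- spec$alpha_beta
    bed_col <- if (length(ab) == 1L) "bed_dd" else
      paste0("bed_dd_", if (10 %in% ab) 10 else ab[1])
    treated <- as.numeric(d[[bed_col]] > ep$bed_threshold)
    lp <- cohort_lp(spec, d) + cohort_theta(spec, d) * treated
    u <- runif(n)
    t_event <- ep$baseline_scale *
      (-log(u) / exp(lp))^(1 / ep$baseline_shape)

    cn <- spec$censoring_params
    c_rand <- if (cn$rate > 0) rexp(n, cn$rate) else rep(Inf, n)
    c_all <- pmin(c_rand, cn$admin_cap)
    d$time <- pmax(pmin(t_event, c_all), 1e-4)
    d$event <- as.integer(t_event <= c_all)

    # cause of death for events, age-tilted toward non-cancer causes
    cmp <- spec$competing_risk_params
    logits <- matrix(log(cmp$base_probs), nrow = n, ncol = 3,
                     byrow = TRUE)
    logits[, 3] <- logits[, 3] + cmp$age_coef * (d$Age - 62)
    probs <- exp(logits) / rowSums(exp(logits))
    cause_draw <- vapply(seq_len(n), function(i)
      sample(names(cmp$base_probs), 1L, prob = probs[i, ]), character(1))
    d$cause <- ifelse(d$event == 1L, cause_draw, "none")
    d$cause <- factor(d$cause, levels = c("none", names(cmp$base_probs)))

    class(d) <- c("cohort_table", "data.frame")
    attr(d, "spec") <- spec
    d
  })
}

#' True treatment effects under a cohort specification
#'
#' Computes the ground-truth average causal effect of high vs. low BED on
#' restricted mean survival time (years) and survival probability
#' (percentage points) at each horizon, by numerically integrating the two
#' counterfactual Weibull survival functions and averaging over a large
#' covariate sample drawn from the spec. This is the oracle against which
#' the doubly robust estimator is validated.
#'
#' @param spec A [cohort_spec()].
#' @param horizons Horizons in years.
#' @param n_draws Size of the covariate sample for the outer expectation.
#' @return Data frame with `horizon`, `rmst_effect` (years), `sp_effect`
#'   (percentage points).
#' @export
true_effects <- function(spec, horizons = 1:12, n_draws = 2000) {
  stopifnot(inherits(spec, "cohort_spec"))
  horizons <- sort(horizons)
  if (any(horizons <= 0)) stop("horizons must be positive", call. = FALSE)
  ep <- spec$effect_params
  with_seed(spec$seed + 104729L, {
    d <- draw_covariates(spec, n_draws)
    lp <- cohort_lp(spec, d)
    theta <- cohort_theta(spec, d)
    grid <- sort(unique(c(seq(0, max(horizons), length.out = 801),
                          horizons)))
    base <- (grid / ep$baseline_scale)^ep$baseline_shape
    mean_surv <- function(extra) {
      # columns = grid times, averaged over the covariate draw
      colMeans(exp(-outer(exp(lp + extra), base)))
    }
    s1 <- mean_surv(theta)
    s0 <- mean_surv(0)
    dt <- diff(grid)
    cum1 <- c(0, cumsum((head(s1, -1) + s1[-1]) / 2 * dt))
    cum0 <- c(0, cumsum((head(s0, -1) + s0[-1]) / 2 * dt))
    i <- match(horizons, grid)
    data.frame(horizon = horizons,
               rmst_effect = cum1[i] - cum0[i],
               sp_effect = 100 * (s1[i] - s0[i]))
  })
}

#' Calibrate the treatment log-hazard ratio to a target effect
#'
#' Solves for the value of the high-BED log hazard ratio that produces a
#' desired true average effect (RMST in years, or SP in percentage points)
#' at a given horizon, using the [true_effects()] oracle and one-dimensional
#' root finding.
#'
#' @param spec A [cohort_spec()]; its `bed_loghr` is ignored.
#' @param target Target effect size.
#' @param horizon Horizon in years.
#' @param estimand `"RMST"` or `"SP"`.
#' @param interval Search interval for the log hazard ratio.
#' @param n_draws Covariate sample size for the oracle.
#' @return The spec with `effect_params$bed_loghr` replaced by the solution.
#' @export
solve_bed_loghr <- function(spec, target, horizon = 8,
                            estimand = c("RMST", "SP"),
                            interval = c(-2, 0.5), n_draws = 2000) {
  estimand <- match.arg(estimand)
  col <- if (estimand == "RMST") "rmst_effect" else "sp_effect"
  f <- function(theta) {
    s <- spec
    s$effect_params$bed_loghr <- theta
    true_effects(s, horizons = horizon, n_draws = n_draws)[[col]] - target
  }
  sol <- stats::uniroot(f, interval, tol = 1e-5)
  spec$effect_params$bed_loghr <- sol$root
  spec
}
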