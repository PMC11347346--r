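# Refutation battery: data perturbations that a trustworthy causal
# estimate must either shrug off (pure noise, placebo treatment,
# randomised outcomes) or detect (injected fake effects). Every
# perturbation is a pure function of (table, seed).

#' Append independent noise covariates
#'
#' Adds `k` independent standard-normal columns (`noise_1`, ...) to the
#' table. A robust causal estimate should shift by less than one standard
#' error when these are included as covariates.
#'
#' @param data Cohort data frame.
#' @param k Number of noise columns (`k = 0` returns the table unchanged).
#' @param seed Seed.
#' @export
add_noise_variables <- function(data, k, seed = 1L) {
  if (k < 0) stop("`k` must be >= 0", call. = FALSE)
  if (k == 0) return(data)
  with_seed(seed, {
    for (j in seq_len(k)) data[[paste0("noise_", j)]] <- rnorm(nrow(data))
    data
  })
}

#' Placebo treatment
#'
#' Permutes the treatment column, destroying any real treatment-outcome
#' link while preserving both marginals. Estimated effects on the placebo
#' table should be statistically indistinguishable from zero.
#'
#' @param data Cohort data frame.
#' @param treatment Treatment column name.
#' @param seed Seed.
#' @export
placebo_treatment <- function(data, treatment = "W", seed = 1L) {
  with_seed(seed, {
    data[[treatment]] <- sample(data[[treatment]])
    data
  })
}

#' Randomise outcomes
#'
#' Jointly permutes the outcome columns (`time`, `event` and, when
#' present, `cause`) across patients, severing the covariate-outcome and
#' treatment-outcome links.
#'
#' @inheritParams placebo_treatment
#' @export
randomize_outcomes <- function(data, seed = 1L) {
  with_seed(seed, {
    idx <- sample.int(nrow(data))
    cols <- intersect(c("time", "event", "cause"), names(data))
    data[cols] <- data[idx, cols]
    data
  })
}

#' Inject a fake survival benefit
#'
#' Shifts the uncensored survival times of treated patients by `delta`
#' years, re-censoring at the administrative cap. A sufficiently sensitive
#' estimator must detect the induced effect as significantly positive.
#'
#' @param data Cohort data frame.
#' @param delta Added years of survival for treated events (>= 0).
#' @param treatment Treatment column name.
#' @param admin_cap Administrative censoring cap in years.
#' @param seed Unused; kept so every refutation shares the
#'   `(table, seed)` signature.
#' @export
inject_fake_effect <- function(data, delta, treatment = "W",
                               admin_cap = 12, seed = 1L) {
  if (delta < 0) stop("`delta` must be >= 0", call. = FALSE)
  if (delta == 0) return(data)
  sel <- data[[treatment]] == 1 & data$event == 1
  shifted <- data$time[sel] + delta
  capped <- shifted > admin_cap
  data$time[sel] <- pmin(shifted, admin_cap)
  data$event[sel][capped] <- 0L
  if ("cause" %in% names(data)) {
    lev <- levels(data$cause)
    data$cause[which(sel)[capped]] <- lev[1L]
  }
  data
}

#' Run the refutation battery
#'
#' Estimates a reference effect, then re-estimates after each enabled
#' perturbation and checks the numeric criterion of each test:
#' \itemize{
#'   \item noise injection: ATE shift below 1 reference SE;
#'   \item placebo treatment / randomised outcomes: `|ATE| < 2 SE` at
#'     every horizon;
#'   \item fake effect: ATE exceeds the reference by more than 2 SE.
#' }
#'
#' @param data Cohort data frame.
#' @param task A [causal_task()].
#' @param seed Seed shared by the perturbations.
#' @param estimand Estimand the criteria are evaluated on.
#' @param horizon Horizon for the noise and fake-effect checks (default:
#'   the reference peak-effect horizon).
#' @param noise_k Noise columns to inject (0 disables the test).
#' @param fake_delta Injected benefit in years (0 disables the test).
#' @param ... Passed to [estimate_effects()] (nuisance choices, folds...).
#' @return Data frame of class `refutation_result`: one row per test with
#'   the perturbed and reference estimates, the criterion text and a pass
#'   flag.
#' @export
refutation_battery <- function(data, task, seed = 1L, estimand = "RMST",
                               horizon = NULL, noise_k = 5L,
                               fake_delta = 1, ...) {
  ref <- estimate_effects(data, task, seed = seed, ...)
  if (is.null(horizon)) horizon <- peak_horizon(ref, estimand)
  pick <- function(rep_, h = NULL) {
    a <- rep_$ate[rep_$ate$estimand == estimand, ]
    if (!is.null(h)) a <- a[a$horizon == h, ]
    a
  }
  ref_h <- pick(ref, horizon)
  rows <- list()

  if (noise_k > 0) {
    noisy <- add_noise_variables(data, noise_k, seed)
    ntask <- task
    ntask$covariates <- c(task$covariates,
                          paste0("noise_", seq_len(noise_k)))
    est <- pick(estimate_effects(noisy, ntask, seed = seed, ...), horizon)
    rows$noise <- data.frame(
      test = "noise_injection", estimate = est$estimate,
      reference = ref_h$estimate,
      criterion = "|ATE shift| < 1 reference SE",
      pass = abs(est$estimate - ref_h$estimate) < ref_h$se)
  }

  for (nm in c("placebo_treatment", "randomize_outcomes")) {
    pert <- if (nm == "placebo_treatment")
      placebo_treatment(data, task$treatment, seed)
    else randomize_outcomes(data, seed)
    a <- pick(estimate_effects(pert, task, seed = seed, ...))
    rows[[nm]] <- data.frame(
      test = nm, estimate = a$estimate[which.max(abs(a$estimate / a$se))],
      reference = ref_h$estimate,
      criterion = "|ATE| < 2 SE at every horizon",
      pass = all(abs(a$estimate) < 2 * a$se))
  }

  if (fake_delta > 0) {
    fake <- inject_fake_effect(data, fake_delta, task$treatment)
    est <- pick(estimate_effects(fake, task, seed = seed, ...), horizon)
    rows$fake <- data.frame(
      test = "fake_effect", estimate = est$estimate,
      reference = ref_h$estimate,
      criterion = "ATE > reference + 2 SE",
      pass = est$estimate - ref_h$estimate >
        2 * sqrt(est$se^2 + ref_h$se^2))
  }

  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("refutation_result", "data.frame")
  attr(out, "estimand") <- estimand
  attr(out, "horizon") <- horizon
  out
}
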