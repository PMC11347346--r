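# Targeted causal stage: cross-fitted augmented inverse-propensity-weighted
# (doubly robust) scores for the effect of a binary treatment on restricted
# mean survival time and survival probability under right censoring, with
# inverse-probability-of-censoring weighting. Per-patient effects come from
# a regression forest on the scores; effect modification from the best
# linear projection of the scores with heteroskedasticity-robust inference.

#' Causal task definition
#'
#' @param treatment Name of the binary treatment column (e.g. a binarised
#'   BED variant). The other BED columns must not appear among the
#'   covariates.
#' @param covariates Confounder columns; defaults to the clinical set
#'   Sex, Smoking_PY, Stage_numeric, HPV_Positive, HPV_Unknown, Chemo,
#'   RT_year, Age.
#' @param horizons Horizon grid in years (positive, sorted).
#' @param estimands Any of `"RMST"` (years) and `"SP"` (percentage
#'   points).
#' @export
causal_task <- function(treatment = "W",
                        covariates = cohort_covariates,
                        horizons = 1:12,
                        estimands = c("RMST", "SP")) {
  estimands <- match.arg(estimands, several.ok = TRUE)
  horizons <- sort(unique(horizons))
  if (any(horizons <= 0)) stop("horizons must be positive", call. = FALSE)
  if (any(grepl("^bed_", covariates)))
    stop("BED columns must not be used as covariates of the causal stage",
         call. = FALSE)
  structure(list(treatment = treatment, covariates = covariates,
                 horizons = horizons, estimands = estimands),
            class = "causal_task")
}

# Step-function survival helpers: `times` are the jump points of a
# right-continuous survival curve, `surv` an (n x length(times)) matrix.
step_surv_at <- function(times, surv, h) {
  idx <- findInterval(h, times)
  if (idx == 0L) rep(1, nrow(surv)) else surv[, idx]
}

step_rmst <- function(times, surv, h) {
  keep <- which(times < h)
  knots <- c(0, times[keep], h)
  widths <- diff(knots)
  cbind(1, surv[, keep, drop = FALSE]) %*% widths
}

# Left-continuous Kaplan-Meier evaluation G(t-) for censoring weights.
km_left <- function(fit_times, fit_surv, t) {
  idx <- findInterval(t, fit_times, left.open = TRUE)
  out <- rep(1, length(t))
  out[idx > 0] <- fit_surv[idx[idx > 0]]
  out
}

# Nuisance predictions on `test` given a `train` fold.
fit_propensity <- function(train, test, treatment, covariates, method,
                           num_trees, seed) {
  W <- train[[treatment]]
  switch(method,
    constant = rep(mean(W), nrow(test)),
    glm = {
      f <- stats::reformulate(covariates, response = treatment)
      fit <- stats::glm(f, data = train, family = stats::binomial())
      as.numeric(stats::predict(fit, newdata = test, type = "response"))
    },
    forest = {
      d <- train[, covariates, drop = FALSE]
      d$.W <- factor(W, levels = c(0, 1))
      fit <- ranger::ranger(.W ~ ., data = d, probability = TRUE,
                            num.trees = num_trees, seed = seed,
                            num.threads = 1L)
      p <- stats::predict(fit, data = test[, covariates, drop = FALSE],
                          num.threads = 1L)$predictions
      as.numeric(p[, "1"])
    },
    stop("unknown propensity method: ", method, call. = FALSE))
}

# Conditional survival curves per arm evaluated on `test`; returns for each
# arm a list(times, surv) step representation.
fit_outcome_curves <- function(train, test, treatment, covariates, method,
                               num_trees, seed) {
  out <- list()
  if (method == "constant") {
    km <- survival::survfit(survival::Surv(time, event) ~ 1, data = train)
    srow <- matrix(km$surv, nrow = 1)
    for (w in c("0", "1"))
      out[[w]] <- list(times = km$time,
                       surv = srow[rep(1L, nrow(test)), , drop = FALSE])
    return(out)
  }
  for (w in c(0, 1)) {
    arm <- train[train[[treatment]] == w, , drop = FALSE]
    if (nrow(arm) < 10L || sum(arm$event) < 2L)
      stop("treatment arm ", w, " too small in a training fold",
           call. = FALSE)
    if (method == "cox") {
      f <- stats::reformulate(covariates, response =
                                "survival::Surv(time, event)")
      fit <- survival::coxph(f, data = arm, ties = "breslow")
      bh <- survival::basehaz(fit, centered = FALSE)
      lp <- as.numeric(stats::predict(fit, newdata = test,
                                      type = "lp", reference = "zero"))
      surv <- exp(-outer(exp(lp), bh$hazard))
      out[[as.character(w)]] <- list(times = bh$time, surv = surv)
    } else if (method == "forest") {
      fit <- ranger::ranger(
        survival::Surv(time, event) ~ .,
        data = arm[, c("time", "event", covariates)],
        num.trees = num_trees, min.node.size = 15L,
        seed = seed + w, num.threads = 1L)
      pr <- stats::predict(fit, data = test[, covariates, drop = FALSE],
                           num.threads = 1L)
      out[[as.character(w)]] <- list(times = pr$unique.death.times,
                                     surv = pr$survival)
    } else stop("unknown outcome method: ", method, call. = FALSE)
  }
  out
}

#' Doubly robust treatment-effect estimation
#'
#' Cross-fitted augmented inverse-propensity-weighted (AIPW) estimation of
#' the average effect of a binary treatment on restricted mean survival
#' time and/or survival probability at a grid of horizons. For each fold,
#' the propensity, the censoring distribution (Kaplan-Meier of the
#' censoring process) and arm-specific conditional survival curves are
#' estimated on the remaining folds; doubly robust scores combine the
#' outcome-model predictions with inverse-probability-of-censoring-weighted
#' residuals. The estimator is consistent if either the propensity or the
#' outcome model is correctly specified.
#'
#' @param data Cohort data frame containing `time`, `event`, the treatment
#'   column and the covariates.
#' @param task A [causal_task()].
#' @param folds Number of cross-fitting folds; `1` disables cross-fitting
#'   (nuisances fit and evaluated in-sample).
#' @param seed Seed for fold assignment and forests.
#' @param propensity `"glm"` (logistic regression), `"forest"`
#'   (probability forest) or `"constant"` (marginal treated fraction; a
#'   deliberately covariate-free model).
#' @param outcome `"forest"` (arm-specific survival forests), `"cox"`
#'   (arm-specific proportional-hazards fits) or `"constant"` (pooled
#'   Kaplan-Meier, covariate- and arm-free).
#' @param num_trees Trees for forest nuisances.
#' @param trim Propensity clamping bounds; more than `max_trim_frac` of
#'   patients outside the bounds aborts with a positivity error.
#' @param max_trim_frac See `trim`.
#' @param g_min Floor for the censoring survival probability in the
#'   weights.
#' @param cap_quantile Horizons above this quantile of follow-up are
#'   dropped (with a warning) to keep censoring weights stable.
#' @return Object of class `causal_effect_report`: `ate` (horizon x
#'   estimand table of estimate, SE, n), `scores` (per-estimand n x
#'   horizon matrices of doubly robust scores), `fold_effects`, fold ids,
#'   propensities, and the task.
#' @export
estimate_effects <- function(data, task, folds = 10L, seed = 1L,
                             propensity = c("glm", "forest", "constant"),
                             outcome = c("forest", "cox", "constant"),
                             num_trees = 200L, trim = c(0.05, 0.95),
                             max_trim_frac = 0.20, g_min = 0.05,
                             cap_quantile = 0.95) {
  propensity <- match.arg(propensity)
  outcome <- match.arg(outcome)
  stopifnot(inherits(task, "causal_task"))
  need <- c("time", "event", task$treatment, task$covariates)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  W <- data[[task$treatment]]
  if (!all(W %in% c(0, 1)))
    stop("treatment must be binary 0/1", call. = FALSE)
  if (length(unique(W)) < 2L)
    stop("both treatment arms must be non-empty", call. = FALSE)

  horizons <- task$horizons
  cap <- stats::quantile(data$time, cap_quantile, names = FALSE)
  if (any(horizons > cap)) {
    warning(sprintf(
      "dropping %d horizon(s) beyond the %.0f%% follow-up quantile (%.2f y)",
      sum(horizons > cap), 100 * cap_quantile, cap), call. = FALSE)
    horizons <- horizons[horizons <= cap]
    if (!length(horizons))
      stop("no horizons left below the follow-up cap", call. = FALSE)
  }

  n <- nrow(data)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  e_hat <- rep(NA_real_, n)
  scores <- lapply(task$estimands, function(e)
    matrix(NA_real_, n, length(horizons),
           dimnames = list(NULL, horizons)))
  names(scores) <- task$estimands
  n_trimmed <- 0L

  for (k in seq_len(folds)) {
    te <- if (folds == 1L) rep(TRUE, n) else fold_id == k
    train <- if (folds == 1L) data else data[!te, , drop = FALSE]
    test <- data[te, , drop = FALSE]
    e <- fit_propensity(train, test, task$treatment, task$covariates,
                        propensity, num_trees, seed + k)
    n_trimmed <- n_trimmed + sum(e < trim[1] | e > trim[2])
    e <- pmin(pmax(e, trim[1]), trim[2])
    e_hat[te] <- e

    cen <- survival::survfit(survival::Surv(time, 1 - event) ~ 1,
                             data = train)
    curves <- fit_outcome_curves(train, test, task$treatment,
                                 task$covariates, outcome, num_trees,
                                 seed + k)
    Wt <- test[[task$treatment]]
    ipw <- Wt / e - (1 - Wt) / (1 - e)
    for (j in seq_along(horizons)) {
      h <- horizons[j]
      D <- as.numeric(test$time > h | test$event == 1)
      G <- pmax(km_left(cen$time, cen$surv, pmin(test$time, h)), g_min)
      wgt <- D / G
      for (est in task$estimands) {
        if (est == "SP") {
          y <- as.numeric(test$time > h)
          mu1 <- step_surv_at(curves[["1"]]$times, curves[["1"]]$surv, h)
          mu0 <- step_surv_at(curves[["0"]]$times, curves[["0"]]$surv, h)
        } else {
          y <- pmin(test$time, h)
          mu1 <- as.numeric(step_rmst(curves[["1"]]$times,
                                      curves[["1"]]$surv, h))
          mu0 <- as.numeric(step_rmst(curves[["0"]]$times,
                                      curves[["0"]]$surv, h))
        }
        muW <- ifelse(Wt == 1, mu1, mu0)
        phi <- mu1 - mu0 + ipw * wgt * (y - muW)
        if (est == "SP") phi <- 100 * phi
        scores[[est]][te, j] <- phi
      }
    }
  }
  if (n_trimmed / n > max_trim_frac)
    stop(sprintf(
      paste0("positivity violation: %.0f%% of propensities outside [%g, %g]",
             " after trimming; causal identification requires a nonzero",
             " treatment probability in every covariate stratum"),
      100 * n_trimmed / n, trim[1], trim[2]), call. = FALSE)

  ate <- do.call(rbind, lapply(task$estimands, function(est) {
    data.frame(horizon = horizons, estimand = est,
               estimate = colMeans(scores[[est]]),
               se = apply(scores[[est]], 2, stats::sd) / sqrt(n),
               n = n, row.names = NULL)
  }))
  fold_effects <- do.call(rbind, lapply(task$estimands, function(est) {
    do.call(rbind, lapply(seq_len(folds), function(k)
      data.frame(fold = k, horizon = horizons, estimand = est,
                 estimate = colMeans(scores[[est]][fold_id == k, ,
                                                   drop = FALSE]))))
  }))
  structure(list(ate = ate, scores = scores, fold_effects = fold_effects,
                 horizons = horizons,
                 estimands = task$estimands, fold_id = fold_id,
                 treatment = W, e_hat = e_hat,
                 covariate_data = data[, task$covariates, drop = FALSE],
                 trimmed_fraction = n_trimmed / n, n = n, task = task,
                 nuisance = c(propensity = propensity, outcome = outcome)),
            class = "causal_effect_report")
}

#' @export
print.causal_effect_report <- function(x, ...) {
  cat(sprintf("doubly robust effect estimates (n = %d, %s propensity, %s outcome)\n",
              x$n, x$nuisance["propensity"], x$nuisance["outcome"]))
  print(x$ate, row.names = FALSE)
  invisible(x)
}

# Horizon at which the mean effect of an estimand peaks.
peak_horizon <- function(report, estimand) {
  a <- report$ate[report$ate$estimand == estimand, ]
  a$horizon[which.max(a$estimate)]
}

#' Per-patient treatment effects
#'
#' Fits a regression forest of the doubly robust scores on the covariates;
#' out-of-bag predictions give conditional average treatment effect (CATE)
#' estimates per patient, with optional infinitesimal-jackknife standard
#' errors. Also reports a histogram summary and the share of patients with
#' a positive estimated effect.
#'
#' @param report A `causal_effect_report`.
#' @param estimand `"SP"` or `"RMST"`.
#' @param horizon Horizon in years; default: the horizon where the mean
#'   effect of `estimand` peaks.
#' @param num_trees Trees of the CATE forest.
#' @param se_method `"jackknife"` (forest variance estimate),
#'   `"none"`.
#' @param seed Forest seed.
#' @param breaks Histogram bin specification (as in [hist()]).
#' @return List of class `per_patient_effects`: `cate`, `cate_se`,
#'   `horizon`, `estimand`, `share_positive`, `histogram`.
#' @export
per_patient_effects <- function(report, estimand = "SP", horizon = NULL,
                                num_trees = 500L,
                                se_method = c("jackknife", "none"),
                                seed = 1L, breaks = 30) {
  se_method <- match.arg(se_method)
  stopifnot(inherits(report, "causal_effect_report"),
            estimand %in% report$estimands)
  if (is.null(horizon)) horizon <- peak_horizon(report, estimand)
  j <- match(as.character(horizon), colnames(report$scores[[estimand]]))
  if (is.na(j)) stop("horizon not in the report grid", call. = FALSE)
  d <- report$covariate_data
  d$.phi <- report$scores[[estimand]][, j]
  fit <- ranger::ranger(.phi ~ ., data = d, num.trees = num_trees,
                        min.node.size = 20L, seed = seed,
                        keep.inbag = se_method == "jackknife",
                        num.threads = 1L)
  cate <- fit$predictions     # out-of-bag
  cate_se <- NULL
  if (se_method == "jackknife") {
    pr <- stats::predict(fit, data = d, type = "se",
                         se.method = "infjack", num.threads = 1L)
    cate_se <- pr$se
  }
  structure(list(cate = cate, cate_se = cate_se, horizon = horizon,
                 estimand = estimand, share_positive = mean(cate > 0),
                 histogram = graphics::hist(cate, breaks = breaks,
                                            plot = FALSE)),
            class = "per_patient_effects")
}

#' Best linear projection of the treatment effect
#'
#' Ordinary least squares of the doubly robust scores on the covariates
#' with heteroskedasticity-robust (sandwich, HC3) standard errors. The
#' coefficients measure how each covariate modifies the treatment effect,
#' not its main effect on mortality: a large p-value means the covariate
#' does not detectably modulate the benefit of treatment, even if it
#' strongly predicts survival itself.
#'
#' @param report A `causal_effect_report`.
#' @param estimand,horizon Which score column to project (default: the
#'   peak-effect horizon).
#' @param covariates Covariate subset; `character(0)` gives the
#'   intercept-only projection, whose intercept equals the ATE.
#' @return Data frame with `term`, `estimate`, `se`, `statistic`,
#'   `p_value`. Collinear covariates are dropped with a warning.
#' @export
blp <- function(report, estimand = "RMST", horizon = NULL,
                covariates = NULL) {
  stopifnot(inherits(report, "causal_effect_report"),
            estimand %in% report$estimands)
  if (is.null(horizon)) horizon <- peak_horizon(report, estimand)
  j <- match(as.character(horizon), colnames(report$scores[[estimand]]))
  if (is.na(j)) stop("horizon not in the report grid", call. = FALSE)
  if (is.null(covariates)) covariates <- names(report$covariate_data)
  d <- report$covariate_data[, covariates, drop = FALSE]
  d$.phi <- report$scores[[estimand]][, j]
  f <- if (length(covariates)) stats::reformulate(covariates, ".phi")
  else stats::as.formula(".phi ~ 1")
  fit <- stats::lm(f, data = d)
  if (anyNA(stats::coef(fit))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    warning("dropping collinear covariate(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    keep <- setdiff(covariates, dropped)
    return(blp(report, estimand, horizon, covariates = keep))
  }
  ct <- lmtest::coeftest(fit, vcov. = sandwich::vcovHC(fit, type = "HC3"))
  data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
             statistic = ct[, 3], p_value = ct[, 4], row.names = NULL)
}

#' Kaplan-Meier comparison with logrank test
#'
#' Univariate comparison of the survival curves of the two treatment arms,
#' with the two-sided logrank test.
#'
#' @param data Cohort data frame with `time` and `event`.
#' @param W Binary treatment vector (or treatment column name).
#' @return List with `curves` (tidy per-arm KM data frame), `chisq`,
#'   `p_value`.
#' @export
km_logrank <- function(data, W) {
  if (is.character(W) && length(W) == 1L) W <- data[[W]]
  d <- data.frame(time = data$time, event = data$event, W = W)
  for (w in unique(W))
    if (sum(d$event[d$W == w]) < 1L)
      stop("arm ", w, " has no events", call. = FALSE)
  if (length(unique(W)) != 2L)
    stop("treatment must have exactly two non-empty arms", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ W, data = d)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ W, data = d)
  arm <- rep(sub("^W=", "", names(fit$strata)), fit$strata)
  curves <- data.frame(arm = arm, time = fit$time, surv = fit$surv,
                       lower = fit$lower, upper = fit$upper)
  list(curves = curves, chisq = as.numeric(sd$chisq), p_value = p)
}
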