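# Competing-risks stage: nonparametric cause-specific cumulative hazards
# (Nelson-Aalen), Aalen-Johansen cumulative incidence functions, and
# permutation variable importance from cause-specific forest ensembles.

#' Competing-risks analysis of a cohort
#'
#' For each cause of death, computes the cause-specific Nelson-Aalen
#' cumulative hazard (CSCHF) and the Aalen-Johansen cumulative incidence
#' function (CIF) on a common time grid; by construction the CIFs and the
#' all-cause survival function satisfy `sum(CIF_c(t)) + S(t) = 1`. A
#' cause-specific forest ensemble (other causes treated as censored at
#' their event time) provides permutation variable importance per cause:
#' the increase in ensemble prediction error after permuting each feature.
#'
#' @param data Cohort data frame with `time`, `event` and a `cause` factor
#'   whose first level marks censored patients.
#' @param features Feature columns for the cause-specific forests; `NULL`
#'   skips the forest/VIMP stage.
#' @param cfg A [forest_config()] (default: the 300-tree competing-risks
#'   preset).
#' @param seed Seed for the forests.
#' @return List of class `competing_risks_report`: `times`, `surv`
#'   (all-cause), `cif` (matrix time x cause), `cschf` (list of per-cause
#'   Nelson-Aalen data frames), `vimp` (features x causes matrix or
#'   `NULL`), `models`.
#' @export
competing_risks_analysis <- function(data, features = NULL,
                                     cfg = forest_config("competing_risks"),
                                     seed = 1L) {
  if (!"cause" %in% names(data))
    stop("`data` must contain a `cause` column", call. = FALSE)
  cause <- as.factor(data$cause)
  causes <- levels(cause)[-1L]
  if (any(data$event == 1L & cause == levels(cause)[1L]))
    stop("events with cause equal to the censoring level", call. = FALSE)

  # multistate Aalen-Johansen estimator; pstate rows sum to 1 with the
  # remaining mass in the "still alive" state
  ms <- survival::survfit(survival::Surv(time, cause) ~ 1, data = data)
  states <- ms$states
  alive <- which(states == "(s0)")
  cif <- ms$pstate[, -alive, drop = FALSE]
  colnames(cif) <- states[-alive]
  cif <- cif[, causes, drop = FALSE]

  for (cs in causes) {
    if (sum(cause == cs & data$event == 1L) == 0L)
      warning("cause '", cs, "' has zero events; its CIF is identically 0",
              call. = FALSE)
  }

  cschf <- lapply(causes, function(cs) {
    fit <- survival::survfit(
      survival::Surv(time, as.integer(cause == cs)) ~ 1, data = data,
      stype = 2, ctype = 1)
    data.frame(time = fit$time, cumhaz = fit$cumhaz)
  })
  names(cschf) <- causes

  vimp <- NULL
  models <- NULL
  if (!is.null(features)) {
    models <- list()
    vimp <- matrix(NA_real_, length(features), length(causes),
                   dimnames = list(features, causes))
    for (cs in causes) {
      d <- data[, c("time", features)]
      d$event <- as.integer(cause == cs)
      if (sum(d$event) == 0L) {
        vimp[, cs] <- 0
        next
      }
      fit <- ranger::ranger(
        survival::Surv(time, event) ~ .,
        data = d[, c("time", "event", features)],
        num.trees = cfg$num_trees, min.node.size = cfg$min_node_size,
        importance = "permutation", seed = seed, num.threads = 1L)
      models[[cs]] <- fit
      vimp[, cs] <- fit$variable.importance[features]
    }
  }

  structure(list(times = ms$time, surv = ms$pstate[, alive],
                 cif = cif, cschf = cschf, vimp = vimp, models = models),
            class = "competing_risks_report")
}
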