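#' Fractionation regimen
#'
#' Describes a radiotherapy schedule: `m` fractions of `d` Gy delivered once
#' (QD) or twice (BID) daily, five treatment days per week. The elapsed
#' treatment time in days is derived from the schedule unless an explicit
#' duration is supplied.
#'
#' @param num_fractions Number of fractions `m` (positive integer).
#' @param dose_per_fraction Dose per fraction `d` in Gy (> 0).
#' @param fractions_per_day 1 (QD) or 2 (BID).
#' @param duration_weeks Optional treatment duration in weeks; when `NULL`
#'   it is derived as `m / (5 * fractions_per_day)`.
#' @return An object of class `fractionation_regimen`.
#' @examples
#' standard <- fractionation_regimen(35, 2)
#' bed_simp(standard) # 84 Gy at alpha/beta = 10
#' @export
fractionation_regimen <- function(num_fractions, dose_per_fraction,
                                  fractions_per_day = 1L,
                                  duration_weeks = NULL) {
  m <- num_fractions
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != round(m))
    stop("`num_fractions` must be a single positive integer", call. = FALSE)
  if (length(dose_per_fraction) != 1L || !is.finite(dose_per_fraction) ||
      dose_per_fraction <= 0)
    stop("`dose_per_fraction` must be a single positive value (Gy)",
         call. = FALSE)
  if (!fractions_per_day %in% c(1L, 2L))
    stop("`fractions_per_day` must be 1 (QD) or 2 (BID)", call. = FALSE)
  if (is.null(duration_weeks))
    duration_weeks <- m / (5 * fractions_per_day)
  if (duration_weeks <= 0)
    stop("`duration_weeks` must be positive", call. = FALSE)
  structure(
    list(num_fractions = as.integer(m),
         dose_per_fraction = as.numeric(dose_per_fraction),
         fractions_per_day = as.integer(fractions_per_day),
         duration_weeks = as.numeric(duration_weeks)),
    class = "fractionation_regimen")
}

#' @export
print.fractionation_regimen <- function(x, ...) {
  cat(sprintf("<regimen> %d x %.4g Gy (%s), %.3g weeks, total %.4g Gy\n",
              x$num_fractions, x$dose_per_fraction,
              if (x$fractions_per_day == 2L) "BID" else "QD",
              x$duration_weeks,
              x$num_fractions * x$dose_per_fraction))
  invisible(x)
}

# Coerce a regimen object or a data frame with columns
# fractions / dose_per_fraction [/ fractions_per_day / duration_weeks]
# to a plain list of vectors.
regimen_fields <- function(regimen) {
  if (inherits(regimen, "fractionation_regimen")) {
    return(list(m = regimen$num_fractions, d = regimen$dose_per_fraction,
                fpd = regimen$fractions_per_day,
                weeks = regimen$duration_weeks))
  }
  if (is.data.frame(regimen)) {
    need <- c("fractions", "dose_per_fraction")
    miss <- setdiff(need, names(regimen))
    if (length(miss))
      stop("regimen table is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    fpd <- if ("fractions_per_day" %in% names(regimen))
      as.integer(regimen$fractions_per_day) else rep(1L, nrow(regimen))
    weeks <- if ("duration_weeks" %in% names(regimen))
      regimen$duration_weeks else regimen$fractions / (5 * fpd)
    return(list(m = regimen$fractions, d = regimen$dose_per_fraction,
                fpd = fpd, weeks = weeks))
  }
  stop("`regimen` must be a fractionation_regimen or a regimen data frame",
       call. = FALSE)
}

#' Elapsed treatment days for a fractionation schedule
#'
#' Converts a number of fractions into treatment days, duration in weeks and
#' elapsed calendar days from first to last fraction (first fraction at day
#' 0). Treatment is assumed to run on weekdays only, starting on a Monday.
#'
#' Conventions for the elapsed-day count:
#' \describe{
#'   \item{`"calendar"`}{exact weekday count,
#'     `T = 7 * floor((D - 1) / 5) + (D - 1) %% 5` with `D` treatment days;
#'     equals `7 * weeks - 3` for whole-week schedules.}
#'   \item{`"7w"`, `"7w-3"`, `"7w-2"`}{affine functions of the duration in
#'     weeks.}
#' }
#'
#' @param m Number of fractions (positive integer, vectorised).
#' @param fractions_per_day 1 or 2.
#' @param days_per_week Treatment days per week (default 5).
#' @param convention Day-count convention, see Details.
#' @return A list with `treatment_days`, `duration_weeks`, `elapsed_days`.
#' @examples
#' duration_from_fractions(35)$elapsed_days # 46
#' duration_from_fractions(60, fractions_per_day = 2)$duration_weeks # 6
#' @export
duration_from_fractions <- function(m, fractions_per_day = 1L,
                                    days_per_week = 5L,
                                    convention = c("calendar", "7w",
                                                   "7w-3", "7w-2")) {
  convention <- match.arg(convention)
  if (any(m < 1))
    stop("`m` must be >= 1", call. = FALSE)
  D <- ceiling(m / fractions_per_day)
  weeks <- m / (days_per_week * fractions_per_day)
  elapsed <- switch(convention,
    "calendar" = 7 * floor((D - 1) / days_per_week) +
      (D - 1) %% days_per_week,
    "7w"   = 7 * weeks,
    "7w-3" = 7 * weeks - 3,
    "7w-2" = 7 * weeks - 2)
  list(treatment_days = D, duration_weeks = weeks,
       elapsed_days = pmax(elapsed, 0))
}

# Resolve elapsed treatment time T (days) for regimen input.
treatment_time <- function(regimen, convention = "calendar") {
  f <- regimen_fields(regimen)
  duration_from_fractions(f$m, f$fpd, convention = convention)$elapsed_days
}

#' Repopulation parameter sets
#'
#' Parameter containers for the two accelerated-repopulation (AR) BED models.
#' In the dose-independent (DI) model AR switches on at a fixed time `T_k`
#' after the start of treatment; in the dose-dependent (DD) model AR switches
#' on once the natural log of the tumour-cell surviving fraction drops below
#' `-C`, so both onset and rate depend on the daily kill intensity.
#'
#' The background slow repopulation rate `g` is not part of the published
#' parameter set; when `g = NULL` it is calibrated from the standard
#' 35 x 2 Gy / 7-week regimen so that the model reproduces the reference BED
#' of that schedule (64.17 Gy for DI, 62.19 Gy for DD). See
#' [calibrate_repopulation()].
#'
#' @param alpha Radiosensitivity in 1/Gy.
#' @param lam Accelerated repopulation rate in 1/day.
#' @param T_k AR onset time in days (DI model).
#' @param C Dimensionless log-kill threshold triggering AR (DD model).
#' @param g Background repopulation rate in 1/day, or `NULL` to calibrate.
#' @param r Alpha/beta ratio in Gy (default 10, typical for HNSCC).
#' @param convention Day-count convention used when `g` is calibrated.
#' @return A list of class `repopulation_params` with a `model` field.
#' @examples
#' repopulation_params_di()$g # ~0.0165 per day
#' @export
repopulation_params_di <- function(alpha = 0.069, lam = 0.035, T_k = 28.6,
                                   g = NULL, r = 10,
                                   convention = "calendar") {
  check_positive(c(alpha = alpha, lam = lam, T_k = T_k, r = r))
  p <- structure(list(model = "DI", alpha = alpha, lam = lam, T_k = T_k,
                      g = g, r = r),
                 class = "repopulation_params")
  if (is.null(g)) {
    p$g <- calibrate_repopulation(standard_anchor("DI"), model = "DI",
                                  params = p, convention = convention)$g
  } else if (g < 0) {
    stop("`g` must be >= 0", call. = FALSE)
  }
  p
}

#' @rdname repopulation_params_di
#' @export
repopulation_params_dd <- function(alpha = 0.224, lam = 1.17, C = 14.5,
                                   g = NULL, r = 10,
                                   convention = "calendar") {
  check_positive(c(alpha = alpha, lam = lam, C = C, r = r))
  p <- structure(list(model = "DD", alpha = alpha, lam = lam, C = C,
                      g = g, r = r),
                 class = "repopulation_params")
  if (is.null(g)) {
    p$g <- calibrate_repopulation(standard_anchor("DD"), model = "DD",
                                  params = p, convention = convention)$g
  } else if (g < 0) {
    stop("`g` must be >= 0", call. = FALSE)
  }
  p
}

check_positive <- function(x) {
  # Inf is a legal limit (e.g. a never-reached repopulation threshold)
  bad <- is.na(x) | x <= 0
  if (any(bad))
    stop("parameter(s) must be positive: ",
         paste(names(x)[bad], collapse = ", "), call. = FALSE)
  invisible(x)
}

# Shared linear-quadratic kill term m * alpha * d * (d + r) / r, i.e. the
# total log cell kill of the schedule (dimensionless).
lq_kill <- function(m, d, alpha, r) m * alpha * d * (d + r) / r

#' Biologically effective dose without repopulation
#'
#' `BED_simp = m * d * (1 + d / r)` under the linear-quadratic model,
#' ignoring tumour repopulation. Independent of treatment duration and of
#' QD/BID scheduling.
#'
#' @param regimen A [fractionation_regimen()] or a regimen data frame with
#'   columns `fractions`, `dose_per_fraction` (vectorised).
#' @param r Alpha/beta ratio in Gy.
#' @return BED in Gy (numeric vector).
#' @examples
#' bed_simp(fractionation_regimen(25, 2.4)) # 74.4
#' @export
bed_simp <- function(regimen, r = 10) {
  f <- regimen_fields(regimen)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("`r` must be positive", call. = FALSE)
  if (any(f$m <= 0) || any(f$d <= 0))
    stop("fractions and dose per fraction must be positive", call. = FALSE)
  f$m * f$d * (1 + f$d / r)
}

#' BED with dose-independent accelerated repopulation
#'
#' `BED_DI = [m a d (d + r) / r - g T - lam * max(0, T - T_k)] / a`, where
#' `T` is the elapsed treatment time in days. Repopulation subtracts dose
#' credit linearly in time: a slow background component over the whole
#' course plus an accelerated component after the fixed onset `T_k`.
#'
#' @inheritParams bed_simp
#' @param params A [repopulation_params_di()] object.
#' @param convention Day-count convention (see [duration_from_fractions()]).
#' @param T_days Optional explicit elapsed time in days, overriding the
#'   schedule-derived value.
#' @return BED in Gy. May fall below the physical dose and can be negative
#'   for extreme durations; negative values trigger a warning, not clamping.
#' @export
bed_di <- function(regimen, params = repopulation_params_di(),
                   convention = "calendar", T_days = NULL) {
  stopifnot(inherits(params, "repopulation_params"), params$model == "DI")
  f <- regimen_fields(regimen)
  T <- if (is.null(T_days)) treatment_time(regimen, convention) else T_days
  if (any(!is.finite(T)))
    stop("treatment duration could not be resolved", call. = FALSE)
  out <- (lq_kill(f$m, f$d, params$alpha, params$r) - params$g * T -
            params$lam * pmax(0, T - params$T_k)) / params$alpha
  warn_negative_bed(out, "BED_DI")
  out
}

#' BED with dose-dependent accelerated repopulation
#'
#' In the DD model the mean daily log-kill rate is
#' `k = m a d (d + r) / (r T)`; accelerated repopulation starts once the
#' cumulative log kill reaches the threshold `C`, i.e. at time `C / k`, and
#' proceeds at rate `lam * (1 - exp(-k))` so that more intense daily kill
#' both advances the onset and raises the repopulation rate:
#' `BED_DD = [m a d (d + r) / r - g T - lam (1 - exp(-k)) max(0, T - C / k)]
#' / a`.
#'
#' @inheritParams bed_di
#' @param params A [repopulation_params_dd()] object.
#' @export
bed_dd <- function(regimen, params = repopulation_params_dd(),
                   convention = "calendar", T_days = NULL) {
  stopifnot(inherits(params, "repopulation_params"), params$model == "DD")
  f <- regimen_fields(regimen)
  T <- if (is.null(T_days)) treatment_time(regimen, convention) else T_days
  if (any(!is.finite(T)) || any(T <= 0))
    stop("BED_DD requires a positive treatment duration", call. = FALSE)
  E <- lq_kill(f$m, f$d, params$alpha, params$r)
  k <- E / T
  out <- (E - params$g * T -
            params$lam * (1 - exp(-k)) * pmax(0, T - params$C / k)) /
    params$alpha
  warn_negative_bed(out, "BED_DD")
  out
}

warn_negative_bed <- function(x, label) {
  if (any(x < 0))
    warning(sprintf("%d negative %s value(s); formulas are not clamped",
                    sum(x < 0), label), call. = FALSE)
  invisible(x)
}

# The standard 35 x 2 Gy / 7-week schedule and its reference BED values,
# used as the single calibration anchor for the hidden background rate g.
standard_anchor <- function(model = c("DI", "DD")) {
  model <- match.arg(model)
  data.frame(fractions = 35L, dose_per_fraction = 2,
             fractions_per_day = 1L,
             target = if (model == "DI") 64.17 else 62.19)
}

#' Calibrate the background repopulation rate
#'
#' The background slow repopulation rate `g` enters both AR models linearly,
#' so given anchor regimens with known target BED values the least-squares
#' `g` has a closed form. Optionally, the best day-count convention is also
#' selected from a candidate set by minimising the summed squared residuals.
#'
#' @param anchors Data frame with columns `fractions`, `dose_per_fraction`,
#'   `target` (Gy) and optionally `fractions_per_day`, `duration_weeks`.
#' @param model `"DI"` or `"DD"`.
#' @param params Parameter object for the chosen model; its `g` is ignored.
#' @param convention A single convention, or several to search over.
#' @param tol Maximum acceptable absolute anchor residual (Gy).
#' @return A list with `g`, `convention` and `residuals` (Gy, per anchor).
#' @examples
#' calibrate_repopulation(
#'   data.frame(fractions = 35, dose_per_fraction = 2, target = 62.19),
#'   model = "DD")$g
#' @export
calibrate_repopulation <- function(anchors, model = c("DI", "DD"),
                                   params = NULL,
                                   convention = "calendar", tol = 0.5) {
  model <- match.arg(model)
  if (!is.data.frame(anchors) || nrow(anchors) < 1L ||
      !"target" %in% names(anchors))
    stop("`anchors` must be a data frame with a `target` column",
         call. = FALSE)
  if (is.null(params)) {
    params <- if (model == "DI")
      repopulation_params_di(g = 0) else repopulation_params_dd(g = 0)
  }
  best <- NULL
  for (conv in convention) {
    f <- regimen_fields(anchors)
    T <- treatment_time(anchors, conv)
    E <- lq_kill(f$m, f$d, params$alpha, params$r)
    ar <- if (model == "DI") {
      params$lam * pmax(0, T - params$T_k)
    } else {
      k <- E / T
      params$lam * (1 - exp(-k)) * pmax(0, T - params$C / k)
    }
    # target = (E - ar - g T) / alpha  =>  least squares in g
    resid0 <- E - ar - params$alpha * anchors$target
    g <- sum(resid0 * T) / sum(T * T)
    g <- max(g, 0)
    res <- (E - ar - g * T) / params$alpha - anchors$target
    cand <- list(g = g, convention = conv, residuals = res,
                 sse = sum(res^2))
    if (is.null(best) || cand$sse < best$sse) best <- cand
  }
  if (max(abs(best$residuals)) > tol)
    stop("calibration failed: no g >= 0 fits the anchors within ", tol,
         " Gy (residuals: ",
         paste(sprintf("%.3f", best$residuals), collapse = ", "), ")",
         call. = FALSE)
  best$sse <- NULL
  best
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.125 -> 0.13 at 2 digits), matching
#' the convention used for tabulated BED values. `round()` in R rounds
#' half-to-even, which differs on exact ties such as 70.125.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' BED comparison table for a set of regimens
#'
#' Computes the three BED variants for each regimen at one or more
#' alpha/beta ratios and reports each value's difference from the standard
#' regimen (35 x 2 Gy over 7 weeks by default), mirroring the usual
#' regimen-comparison layout.
#'
#' @param regimens Regimen data frame (columns `fractions`,
#'   `dose_per_fraction`, optional `fractions_per_day`, `duration_weeks`).
#' @param r_values Alpha/beta ratios in Gy.
#' @param standard Row index of the standard regimen in `regimens`, or a
#'   one-row regimen data frame appended if absent.
#' @param convention Day-count convention.
#' @param digits Decimals for the tabulated values (half-up rounding);
#'   `NULL` keeps full precision.
#' @return A data frame with one row per regimen and, per alpha/beta ratio,
#'   columns `bed_simp_<r>`, `bed_di_<r>`, `bed_dd_<r>` and matching
#'   `diff_*` columns (value minus the standard regimen's value).
#' @export
bed_table <- function(regimens, r_values = c(7, 10, 13),
                      standard = NULL, convention = "calendar",
                      digits = 2) {
  f <- regimen_fields(regimens)
  tab <- data.frame(fractions = f$m, dose_per_fraction = f$d,
                    fractions_per_day = f$fpd,
                    total_dose = f$m * f$d,
                    duration_weeks = f$weeks)
  std_idx <- standard
  if (is.null(std_idx)) {
    std_idx <- which(f$m == 35L & f$d == 2 & f$fpd == 1L)[1]
    if (is.na(std_idx)) {
      regimens <- rbind(tab[, c("fractions", "dose_per_fraction",
                                "fractions_per_day", "duration_weeks")],
                        data.frame(fractions = 35L, dose_per_fraction = 2,
                                   fractions_per_day = 1L,
                                   duration_weeks = 7))
      return(bed_table(regimens, r_values, standard = nrow(regimens),
                       convention = convention, digits = digits))
    }
  }
  reg <- tab
  names(reg)[1:2] <- c("fractions", "dose_per_fraction")
  # g is calibrated once at the default alpha/beta of 10 Gy and reused for
  # the sensitivity ratios, so that only r varies across table variants
  g_di <- repopulation_params_di(convention = convention)$g
  g_dd <- repopulation_params_dd(convention = convention)$g
  for (r in r_values) {
    pdi <- repopulation_params_di(r = r, g = g_di)
    pdd <- repopulation_params_dd(r = r, g = g_dd)
    vals <- list(bed_simp = bed_simp(reg, r = r),
                 bed_di = bed_di(reg, pdi, convention),
                 bed_dd = bed_dd(reg, pdd, convention))
    for (nm in names(vals)) {
      v <- vals[[nm]]
      dif <- v - v[std_idx]
      if (!is.null(digits)) {
        v <- round_half_up(v, digits)
        dif <- round_half_up(dif, digits)
      }
      tab[[paste0(nm, "_", r)]] <- v
      tab[[paste0("diff_", nm, "_", r)]] <- dif
    }
  }
  tab
}
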