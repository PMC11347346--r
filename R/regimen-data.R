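#' Reference fractionation-regimen frequency table
#'
#' The published breakdown of radiotherapy schedules in the RADCURE cohort
#' (3,346 definitively irradiated head-and-neck cancer patients, 2005-2017):
#' number of fractions, total dose and patient count per regimen. Dose per
#' fraction is derived as `total_dose / fractions`. Schedules with 50 or
#' more fractions are twice-daily (BID); all others are once-daily.
#'
#' @return Data frame with columns `fractions`, `total_dose`,
#'   `dose_per_fraction`, `fractions_per_day`, `n_patients`.
#' @examples
#' sum(radcure_regimen_table()$n_patients) # 3346
#' @export
radcure_regimen_table <- function() {
  tab <- data.frame(
    fractions = c(35L, 25L, 40L, 20L, 33L, 30L, 25L, 20L, 34L, 32L, 40L,
                  31L, 33L, 60L, 20L, 20L, 21L, 22L, 27L, 30L, 33L, 34L,
                  36L, 37L, 39L, 40L, 40L, 41L, 45L),
    total_dose = c(70, 60, 64, 51, 66, 60, 50, 50, 68, 64, 60, 62, 69.96,
                   66, 52, 55, 53.55, 52.8, 60, 66, 59.4, 70, 54.4, 69.6,
                   74, 62.4, 50.8, 67.6, 66),
    n_patients = c(2289L, 386L, 263L, 227L, 91L, 28L, 19L, 9L, 6L, 4L, 3L,
                   2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,
                   1L, 1L, 1L, 1L))
  tab$dose_per_fraction <- tab$total_dose / tab$fractions
  tab$fractions_per_day <- ifelse(tab$fractions >= 50L, 2L, 1L)
  tab[, c("fractions", "total_dose", "dose_per_fraction",
          "fractions_per_day", "n_patients")]
}

#' Summarise a regimen frequency table
#'
#' Bookkeeping over a regimen table: total patients, the modal regimen, and
#' how many non-standard regimens exceed a patient-count threshold.
#'
#' @param tab Regimen table as returned by [radcure_regimen_table()].
#' @param standard_fractions,standard_total_dose Definition of the standard
#'   regimen (default 35 fractions / 70 Gy).
#' @param min_patients Count threshold (default 50).
#' @return List with `total_patients`, `n_regimens`, `modal_regimen`
#'   (one-row data frame), and `n_other_regimens_over_threshold`.
#' @export
regimen_summary <- function(tab, standard_fractions = 35L,
                            standard_total_dose = 70,
                            min_patients = 50L) {
  need <- c("fractions", "total_dose", "n_patients")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("regimen table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  is_std <- tab$fractions == standard_fractions &
    tab$total_dose == standard_total_dose
  list(
    total_patients = sum(tab$n_patients),
    n_regimens = nrow(tab),
    modal_regimen = tab[which.max(tab$n_patients), , drop = FALSE],
    n_other_regimens_over_threshold =
      sum(tab$n_patients[!is_std] > min_patients))
}
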