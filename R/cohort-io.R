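# CSV round-trip for cohort tables with schema validation.

cohort_mandatory_cols <- c(cohort_covariates, "time", "event")
cohort_onehot_cols <- c("Sex", "HPV_Positive", "HPV_Unknown", "Chemo",
                        "event", cohort_sites)

#' Write a cohort table to CSV
#'
#' Numeric columns are serialised with 17 significant digits so that a
#' write/read cycle reproduces the table bit-for-bit.
#'
#' @param table A cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  out <- as.data.frame(table)
  for (nm in names(out)) {
    if (is.double(out[[nm]]))
      out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates the schema: all mandatory analysis columns must be present,
#' one-hot indicator columns must be strictly 0/1, follow-up times must be
#' positive. Unknown extra columns are preserved and reported.
#'
#' @param path CSV path.
#' @return A `cohort_table` data frame.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cohort_mandatory_cols, names(d))
  if (length(miss))
    stop("cohort file is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  onehot <- intersect(cohort_onehot_cols, names(d))
  bad <- onehot[vapply(onehot, function(nm)
    any(!d[[nm]] %in% c(0L, 1L)), logical(1))]
  if (length(bad))
    stop("non-binary values in one-hot column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(d$time <= 0))
    stop("`time` must be strictly positive", call. = FALSE)
  if (any(d$HPV_Positive + d$HPV_Unknown > 1))
    stop("HPV_Positive and HPV_Unknown must not both be 1", call. = FALSE)
  known <- c(cohort_mandatory_cols, cohort_onehot_cols, "cause",
             "fractions", "dose_per_fraction", "fractions_per_day",
             "total_dose",
             grep("^bed_", names(d), value = TRUE))
  extra <- setdiff(names(d), known)
  if (length(extra))
    message("read_cohort: preserving unknown column(s): ",
            paste(extra, collapse = ", "))
  dbl <- intersect(c("Age", "Smoking_PY", "dose_per_fraction",
                     "total_dose", "time",
                     grep("^bed_", names(d), value = TRUE)), names(d))
  for (nm in dbl) d[[nm]] <- as.numeric(d[[nm]])
  if ("cause" %in% names(d)) {
    std <- c("none", "index_cancer", "other_cancer", "other_causes")
    lv <- if (all(unique(d$cause) %in% std)) std else
      union(std, unique(d$cause))
    d$cause <- factor(d$cause, levels = lv)
  }
  class(d) <- c("cohort_table", "data.frame")
  d
}
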