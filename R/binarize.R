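# Dichotomisation of continuous BED variants at SHAP-guided cut-points.

#' Cut-point specification for a BED variant
#'
#' Default cut-points follow the SHAP-guided choices for each variant:
#' 61.8 Gy for the dose-dependent BED, 57.6 Gy for the dose-independent
#' BED, and 70 Gy for the no-repopulation BED (chosen by matching the
#' percentile of the dose-dependent cut-point).
#'
#' @param variant `"bed_dd"`, `"bed_di"` or `"bed_simp"`.
#' @param cutpoint Cut-point in Gy (default per variant).
#' @param provenance How the cut-point was chosen: `"manual"`,
#'   `"shap_changepoint"` or `"percentile"`.
#' @export
cutpoint_spec <- function(variant = c("bed_dd", "bed_di", "bed_simp"),
                          cutpoint = NULL,
                          provenance = c("manual", "shap_changepoint",
                                         "percentile")) {
  variant <- match.arg(variant)
  provenance <- match.arg(provenance)
  if (is.null(cutpoint))
    cutpoint <- switch(variant, bed_dd = 61.8, bed_di = 57.6,
                       bed_simp = 70)
  structure(list(variant = variant, cutpoint = as.numeric(cutpoint),
                 provenance = provenance),
            class = "cutpoint_spec")
}

#' Binarise BED values at a cut-point
#'
#' Strict mapping: values `<=` cut-point become 0, values `>` cut-point
#' become 1. A degenerate (all-0 or all-1) result triggers a warning since
#' it breaks the positivity requirement of the downstream causal stage.
#'
#' @param values Numeric BED values (Gy).
#' @param spec A [cutpoint_spec()] or a single numeric cut-point.
#' @return Integer 0/1 vector.
#' @examples
#' binarize(c(60, 61.8, 62), 61.8) # 0 0 1
#' @export
binarize <- function(values, spec) {
  cut <- if (inherits(spec, "cutpoint_spec")) spec$cutpoint else
    as.numeric(spec)
  out <- as.integer(values > cut)
  if (length(out) > 1L && length(unique(out)) == 1L)
    warning("degenerate treatment: all values map to ", out[1L],
            " (positivity violation downstream)", call. = FALSE)
  out
}

#' Suggest a BED cut-point from a SHAP relative-risk curve
#'
#' Formalises "where a clear change in mortality prediction is visible":
#' the change-point is the feature value minimising the two-segment
#' piecewise-constant sum of squared errors of the (smoothed) normalised
#' SHAP curve, reported as the midpoint between the two adjacent support
#' values. If the curve is flat (no variance to explain) the method falls
#' back to a percentile of the BED distribution.
#'
#' @param curve Data frame with columns `feature_value` and
#'   `rel_risk_smooth` (or `rel_risk`), e.g. one feature's rows from
#'   [normalize_shap()].
#' @param method `"changepoint"` or `"percentile"`.
#' @param values BED values defining the percentile distribution
#'   (required for `method = "percentile"` and for the flat-curve
#'   fallback).
#' @param p Percentile in `[0, 1]` for `method = "percentile"`.
#' @return Cut-point in Gy.
#' @export
suggest_cutpoint <- function(curve, method = c("changepoint", "percentile"),
                             values = NULL, p = NULL) {
  method <- match.arg(method)
  if (method == "percentile") {
    if (is.null(values) || is.null(p))
      stop("percentile mode needs `values` and `p`", call. = FALSE)
    return(as.numeric(stats::quantile(values, p, names = FALSE)))
  }
  ycol <- if ("rel_risk_smooth" %in% names(curve)) "rel_risk_smooth" else
    "rel_risk"
  o <- order(curve$feature_value)
  x <- curve$feature_value[o]
  y <- curve[[ycol]][o]
  n <- length(y)
  if (n < 10L)
    stop("change-point detection needs at least 10 support points",
         call. = FALSE)
  tot <- sum((y - mean(y))^2)
  if (tot < 1e-12) {
    warning("flat SHAP curve: no change-point; falling back to percentile",
            call. = FALSE)
    if (is.null(values)) values <- x
    if (is.null(p)) p <- 0.5
    return(as.numeric(stats::quantile(values, p, names = FALSE)))
  }
  # two-segment piecewise-constant SSE via prefix sums
  cs <- cumsum(y)
  cs2 <- cumsum(y^2)
  k <- seq_len(n - 1L)
  sse_left <- cs2[k] - cs[k]^2 / k
  sse_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  best <- which.min(sse_left + sse_right)
  (x[best] + x[best + 1L]) / 2
}

#' Percentile of a reference cut-point within its BED distribution
#'
#' Returns the empirical fraction of reference values at or below the
#' reference cut-point; applying this percentile to another BED variant's
#' distribution transfers the dichotomisation "at a similar percentile".
#'
#' @param ref_values Reference BED values (Gy).
#' @param ref_cutpoint Reference cut-point (Gy).
#' @export
cutpoint_percentile <- function(ref_values, ref_cutpoint) {
  mean(ref_values <= ref_cutpoint)
}
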