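# Exact interventional Shapley attributions for an arbitrary scalar model
# output. For each explained patient and feature coalition S, the value
# function v(S) is the model output averaged over a background sample with
# the coalition's features replaced by the patient's values; Shapley values
# are then combined exactly over all 2^p coalitions, which makes the
# local-accuracy identity (base value + sum of attributions = model output)
# hold to floating-point precision. Cost is O(2^p) model calls, intended for
# the small clinical feature sets used here (p <= ~12).

#' Shapley attributions for a survival-forest risk score
#'
#' Computes exact interventional SHAP values of a scalar model output with
#' respect to a background sample. By default the explained output is the
#' forest's log cumulative hazard at the training median event time, so
#' `exp()` of an attribution reads as a multiplicative risk factor.
#'
#' @param model A `bedsurv_forest` (ignored when `predict_fun` is given).
#' @param data Data frame of patients to explain.
#' @param features Feature columns to attribute over (at most
#'   `max_features`).
#' @param predict_fun Optional function `(data.frame) -> numeric` replacing
#'   the forest risk score; it receives frames containing exactly the
#'   `features` columns.
#' @param background Background data frame defining the reference
#'   distribution; defaults to a sample of `n_background` rows of `data`.
#' @param n_background Background sample size when `background` is `NULL`.
#' @param time Reference time for the risk score (default: training median
#'   event time).
#' @param seed Seed for the background sample.
#' @param max_features Safety cap on `2^p` enumeration.
#' @return List of class `shap_result`: `values` (patients x features
#'   matrix), `base_value`, `fx` (model output per patient), `feature_data`.
#' @export
shap_values <- function(model, data, features = NULL, predict_fun = NULL,
                        background = NULL, n_background = 20L,
                        time = NULL, seed = 1L, max_features = 14L) {
  if (is.null(features)) features <- model$features
  p <- length(features)
  if (p < 1L) stop("need at least one feature", call. = FALSE)
  if (p > max_features)
    stop("exact Shapley enumeration capped at ", max_features,
         " features (2^p coalitions)", call. = FALSE)
  if (is.null(predict_fun))
    predict_fun <- function(d) risk_score(model, d, time = time)
  if (is.null(background)) {
    background <- with_seed(seed, {
      data[sample.int(nrow(data), min(n_background, nrow(data))), ,
           drop = FALSE]
    })
  }
  # only the attributed features are ever varied; frames passed to
  # `predict_fun` carry exactly these columns
  data <- data[, features, drop = FALSE]
  background <- background[, features, drop = FALSE]
  n <- nrow(data)
  B <- nrow(background)
  nsub <- bitwShiftL(1L, p)
  sizes <- vapply(seq_len(nsub) - 1L, bitcount, integer(1))

  # v(S) for every coalition: n x 2^p matrix. Interior coalitions are
  # evaluated in chunks of several coalitions per model call to amortise
  # prediction overhead.
  V <- matrix(NA_real_, n, nsub)
  V[, 1L] <- mean(predict_fun(background))
  V[, nsub] <- predict_fun(data)
  base_rows <- background[rep(seq_len(B), times = n), , drop = FALSE]
  interior <- seq_len(nsub - 2L)          # subset codes 1 .. 2^p - 2
  per_chunk <- max(1L, floor(2e5 / (n * B)))
  for (chunk in split(interior, ceiling(seq_along(interior) / per_chunk))) {
    frames <- lapply(chunk, function(s) {
      in_s <- which(bitwAnd(s, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
      mixed <- base_rows
      for (j in in_s)
        mixed[[features[j]]] <- rep(data[[features[j]]], each = B)
      mixed
    })
    out <- predict_fun(do.call(rbind, frames))
    out <- matrix(out, ncol = length(chunk))
    for (i in seq_along(chunk))
      V[, chunk[i] + 1L] <- rowMeans(matrix(out[, i], nrow = n,
                                            byrow = TRUE))
  }

  # exact Shapley combination: weight |S|! (p - |S| - 1)! / p!
  wt <- exp(lfactorial(0:(p - 1)) + lfactorial(p - 1 - 0:(p - 1)) -
              lfactorial(p))
  phi <- matrix(0, n, p, dimnames = list(NULL, features))
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(seq_len(nsub) - 1L, bit) == 0L)
    for (s in without) {
      sz <- sizes[s]
      phi[, j] <- phi[, j] + wt[sz + 1L] * (V[, s + bit] - V[, s])
    }
  }
  structure(list(values = phi, base_value = V[1L, 1L], fx = V[, nsub],
                 feature_data = data[, features, drop = FALSE],
                 background = background),
            class = "shap_result")
}

bitcount <- function(x) {
  n <- 0L
  while (x > 0L) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

#' Normalised SHAP relative-risk curves
#'
#' Maps attributions computed on a log-risk scale to a relative-risk scale
#' via `exp()`: 1 means no change from the population average, 1.1 a 10%
#' higher predicted mortality risk. Per feature, the curve of relative risk
#' versus feature value is smoothed by a running median.
#'
#' @param shap A `shap_result`.
#' @param window Odd running-median window length (capped at the number of
#'   points).
#' @return Data frame with `feature`, `feature_value`, `shap`, `rel_risk`,
#'   `rel_risk_smooth`, sorted by feature value within feature.
#' @export
normalize_shap <- function(shap, window = 11L) {
  stopifnot(inherits(shap, "shap_result"))
  out <- list()
  for (f in colnames(shap$values)) {
    x <- shap$feature_data[[f]]
    phi <- shap$values[, f]
    o <- order(x)
    rr <- exp(phi[o])
    k <- min(window, length(rr))
    if (k %% 2L == 0L) k <- k - 1L
    sm <- if (k >= 3L) stats::runmed(rr, k) else rr
    out[[f]] <- data.frame(feature = f, feature_value = x[o],
                           shap = phi[o], rel_risk = rr,
                           rel_risk_smooth = as.numeric(sm))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Correlation between features and their SHAP columns
#'
#' Pearson correlation matrix between feature values and per-feature
#' attributions; the diagonal (a feature against its own SHAP column)
#' summarises how monotonically the model uses the feature.
#'
#' @param shap A `shap_result`.
#' @return p x p correlation matrix (features x SHAP columns).
#' @export
shap_feature_correlations <- function(shap) {
  stopifnot(inherits(shap, "shap_result"))
  X <- as.matrix(shap$feature_data)
  S <- shap$values
  suppressWarnings(stats::cor(X, S))
}
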