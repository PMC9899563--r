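# Model evaluation: accuracy metrics, calibration bins, severity-category
# remission tables and inter-model prediction correlations.

#' Continuous-outcome accuracy metrics
#'
#' \eqn{R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y_{eval})^2} with the
#' total sum of squares centred on the *evaluation* set's own mean, so a
#' miscentred constant prediction can score below zero; RMSE and MAE as
#' usual.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 2).
#' @return List with `r_squared`, `rmse`, `mae`, `n`.
#' @export
continuous_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  err <- observed - predicted
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- if (ss_tot == 0) {
    warning("constant observed outcome: R-squared undefined")
    NA_real_
  } else 1 - sum(err^2) / ss_tot
  list(r_squared = r2, rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
       n = length(observed))
}

#' Binary-outcome accuracy metrics
#'
#' AUC by the rank (Mann-Whitney) formulation with tie correction; Brier
#' score as the mean squared difference between predicted probability and
#' outcome.
#'
#' @param observed 0/1 vector.
#' @param predicted_prob Probabilities in `[0, 1]`.
#' @return List with `auc`, `brier`, `n`.
#' @export
binary_metrics <- function(observed, predicted_prob) {
  stopifnot(length(observed) == length(predicted_prob),
            all(observed %in% c(0, 1)),
            all(predicted_prob >= 0 & predicted_prob <= 1))
  n1 <- sum(observed == 1)
  n0 <- sum(observed == 0)
  auc <- if (n1 == 0 || n0 == 0) {
    warning("single-class outcome: AUC undefined")
    NA_real_
  } else {
    r <- rank(predicted_prob)  # midranks handle ties
    (sum(r[observed == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(auc = auc, brier = mean((predicted_prob - observed)^2),
       n = length(observed))
}

#' Calibration bins of fixed size
#'
#' Patients are sorted by predicted value (ascending) and grouped into
#' consecutive bins of `bin_size`; a trailing remainder is kept as a
#' flagged partial bin. Per-bin mean predicted, mean observed and observed
#' remission fraction are returned.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param remission Optional 0/1 vector (observed remission).
#' @param bin_size Bin size (default 50).
#' @return Data frame with one row per bin: `bin`, `n`, `mean_predicted`,
#'   `mean_observed`, `remission_fraction`, `partial`.
#' @export
calibration_bins <- function(observed, predicted, remission = NULL,
                             bin_size = 50L) {
  stopifnot(length(observed) == length(predicted), bin_size >= 1)
  o <- order(predicted)
  n <- length(predicted)
  bin <- ceiling(seq_len(n) / bin_size)
  out <- data.frame(
    bin = unique(bin),
    n = as.integer(tabulate(bin)),
    mean_predicted = as.numeric(tapply(predicted[o], bin, mean)),
    mean_observed = as.numeric(tapply(observed[o], bin, mean)),
    remission_fraction = if (is.null(remission)) NA_real_ else
      as.numeric(tapply(remission[o], bin, mean))
  )
  out$partial <- out$n < bin_size
  out
}

# Severity bands on the 0-63 follow-up scale.
severity_breaks <- function() {
  data.frame(category = c("minimal", "mild", "moderate", "severe"),
             lower = c(0L, 14L, 20L, 29L),
             upper = c(13L, 19L, 28L, 63L),
             stringsAsFactors = FALSE)
}

#' Observed remission by predicted severity category
#'
#' Predicted follow-up totals are rounded half-up to the nearest integer,
#' clamped to 0-63 (with a warning if any fall outside), and assigned to
#' the standard severity bands: minimal 0-13, mild 14-19, moderate 20-28,
#' severe 29-63. The observed remission fraction is reported per band.
#'
#' @param predicted Predicted follow-up totals (real-valued).
#' @param remission Observed 0/1 remission flags.
#' @return Data frame with one row per category: `category`, `lower`,
#'   `upper`, `n`, `remission_fraction`.
#' @export
severity_category_remission <- function(predicted, remission) {
  stopifnot(length(predicted) == length(remission))
  rounded <- floor(predicted + 0.5)  # round half-up
  if (any(rounded < 0 | rounded > 63)) {
    warning("predicted scores outside [0, 63] after rounding: clamped")
    rounded <- pmin(pmax(rounded, 0), 63)
  }
  br <- severity_breaks()
  cat_idx <- findInterval(rounded, br$lower)
  br$n <- as.integer(tabulate(cat_idx, nbins = 4))
  br$remission_fraction <- vapply(1:4, function(i) {
    if (br$n[i] == 0) NA_real_ else mean(remission[cat_idx == i])
  }, numeric(1))
  br
}

#' Inter-model prediction correlation matrix
#'
#' Pearson correlations between the prediction vectors of the models; a
#' constant vector (the null model) yields `NA` for its row/column with a
#' warning.
#'
#' @param predictions Named list (or matrix) of equal-length prediction
#'   vectors, one per model.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
prediction_correlations <- function(predictions) {
  M <- if (is.matrix(predictions)) predictions else
    do.call(cbind, predictions)
  stopifnot(ncol(M) >= 2)
  const <- apply(M, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("constant prediction vector(s): correlation undefined for ",
            paste(colnames(M)[const], collapse = ", "))
  }
  R <- suppressWarnings(stats::cor(M))
  diag(R) <- 1
  R
}
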