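# Predictor-set construction: weighted sum scores, unweighted totals, and
# individual-item predictor sets. Weights always come from a training-set
# fit and are never re-estimated on test data.

sum_score_labels <- function() {
  c("bdi_score", "anx_score", "social_support", "life_events", "alcohol")
}

new_score_set <- function(model_form, x, meta, weights_used = NULL) {
  structure(list(model_form = model_form,
                 predictor_labels = colnames(x),
                 x = x, meta = meta, weights_used = weights_used),
            class = "score_set")
}

score_meta <- function(tables) {
  pooled <- do.call(rbind, lapply(tables, function(d) {
    d[, c("study_id", "patient_id", "outcome_bdi", "remission")]
  }))
  rownames(pooled) <- NULL
  pooled
}

#' Weighted sum-score predictors
#'
#' Builds the five predictors of the weighted-sum-score models: a weighted
#' BDI score (sum of rescaled weight x item over the 21 items), a weighted
#' anxiety score (over the 8 subscale totals), and each auxiliary total
#' multiplied by its weight. Weights are frozen from the training fit.
#'
#' @param tables List of complete study data frames.
#' @param weights A [weight_vector()] covering all 32 baseline variables.
#' @return A `score_set` with predictor matrix (patients x 5) and patient
#'   metadata.
#' @export
weighted_scores <- function(tables, weights) {
  stopifnot(inherits(weights, "weight_vector"))
  w <- stats::setNames(weights$rescaled, weights$label)
  missing_w <- setdiff(baseline_labels(), names(w))
  if (length(missing_w)) {
    stop("weights missing for variable(s): ", paste(missing_w, collapse = ", "))
  }
  pooled <- do.call(rbind, lapply(tables, function(d) {
    as.matrix(d[, baseline_labels(), drop = FALSE])
  }))
  if (anyNA(pooled)) stop("tables must be complete (impute first)")
  bdi <- pooled[, bdi_item_labels(), drop = FALSE] %*%
    w[bdi_item_labels()]
  anx <- pooled[, anx_subscale_labels(), drop = FALSE] %*%
    w[anx_subscale_labels()]
  aux <- sweep(pooled[, aux_total_labels(), drop = FALSE], 2,
               w[aux_total_labels()], `*`)
  x <- cbind(bdi, anx, aux)
  colnames(x) <- sum_score_labels()
  new_score_set("weighted_sums", x, score_meta(tables), weights)
}

#' Unweighted sum-score predictors
#'
#' The five plain totals: BDI total (0-63), anxiety subscale total, and the
#' three auxiliary totals.
#'
#' @param tables List of complete study data frames.
#' @return A `score_set` (patients x 5).
#' @export
unweighted_scores <- function(tables) {
  pooled <- do.call(rbind, lapply(tables, function(d) {
    as.matrix(d[, baseline_labels(), drop = FALSE])
  }))
  if (anyNA(pooled)) stop("tables must be complete (impute first)")
  x <- cbind(rowSums(pooled[, bdi_item_labels(), drop = FALSE]),
             rowSums(pooled[, anx_subscale_labels(), drop = FALSE]),
             pooled[, aux_total_labels(), drop = FALSE])
  colnames(x) <- sum_score_labels()
  new_score_set("unweighted_sums", x, score_meta(tables))
}

#' Individual-item predictors
#'
#' All 32 baseline variables (21 BDI items, 8 anxiety subscale totals, 3
#' auxiliary totals) in fixed canonical order.
#'
#' @param tables List of complete study data frames.
#' @return A `score_set` (patients x 32).
#' @export
item_level_predictors <- function(tables) {
  pooled <- do.call(rbind, lapply(tables, function(d) {
    as.matrix(d[, baseline_labels(), drop = FALSE])
  }))
  if (anyNA(pooled)) stop("tables must be complete (impute first)")
  new_score_set("item_level", pooled, score_meta(tables))
}

#' Write a score set as CSV
#'
#' @param scores A `score_set`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_score_set_csv <- function(scores, path) {
  stopifnot(inherits(scores, "score_set"))
  utils::write.csv(cbind(scores$meta, as.data.frame(scores$x)), path,
                   row.names = FALSE)
  invisible(path)
}
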