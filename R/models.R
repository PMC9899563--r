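# The nine modelling approaches and their estimators.
#
#   1  EI1-weighted sum scores, OLS/logistic
#   2  EI2-weighted sum scores, OLS/logistic
#   3  PC/PR-weighted sum scores, OLS/logistic
#   4  CFA-loading-weighted sum scores, OLS/logistic
#   5  elastic net on unweighted sum scores
#   6  OLS/logistic on unweighted sum scores
#   7  elastic net on individual items
#   8  OLS/logistic on individual items
#   9  null model (training mean / training remission proportion)

#' Registry of the nine modelling approaches
#'
#' @return Data frame with one row per model: `model_id`, `weighting`,
#'   `form`, `estimator`, `label`.
#' @export
model_registry <- function() {
  data.frame(
    model_id = 1:9,
    weighting = c("EI1", "EI2", "PCPR", "CFA", "none", "none", "none",
                  "none", "none"),
    form = c(rep("weighted_sums", 4), "unweighted_sums", "unweighted_sums",
             "item_level", "item_level", "null"),
    estimator = c(rep("regression", 4), "ENR", "regression", "ENR",
                  "regression", "null"),
    label = c("EI1-weighted sums", "EI2-weighted sums",
              "PC/PR-weighted sums", "CFA-weighted sums",
              "ENR on sum scores", "OLS/logistic on sum scores",
              "ENR on items", "OLS/logistic on items", "null (train mean)"),
    stringsAsFactors = FALSE
  )
}

new_fitted_model <- function(model_id, outcome, estimator, intercept,
                             coefficients, extra = list()) {
  structure(c(list(model_id = model_id, outcome = outcome,
                   estimator = estimator, intercept = intercept,
                   coefficients = coefficients), extra),
            class = "fitted_prognostic_model")
}

#' Fit an unpenalised regression on a score set
#'
#' OLS for the continuous outcome, logistic (IRLS, capped at 100
#' iterations) for remission.
#'
#' @param scores A `score_set` for the training data.
#' @param outcome Numeric outcome vector aligned with the score rows
#'   (continuous total or 0/1 remission).
#' @param family `"gaussian"` or `"binomial"`.
#' @param model_id Identifier stored on the fit.
#' @return A `fitted_prognostic_model`.
#' @export
fit_regression <- function(scores, outcome, family = c("gaussian", "binomial"),
                           model_id = NA_integer_) {
  family <- match.arg(family)
  stopifnot(inherits(scores, "score_set"), length(outcome) == nrow(scores$x))
  if (anyNA(outcome)) stop("outcome must be complete")
  X <- scores$x
  # a weighted predictor whose weight rescaled to exactly 0 is a constant
  # zero column: the variable is excluded from this model (its information
  # is carried by the weighting, as in published weighted-sum models)
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  if (family == "gaussian") {
    if (nrow(X) <= ncol(X)) stop("need n > number of predictors for OLS")
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), outcome)
    if (any(is.na(fit$coefficients))) stop("singular design matrix")
    beta <- fit$coefficients
  } else {
    df <- data.frame(.y = outcome, X, check.names = FALSE)
    fit <- stats::glm(.y ~ ., data = df, family = stats::binomial(),
                      control = stats::glm.control(maxit = 100L))
    if (!fit$converged) stop("logistic regression did not converge ",
                             "(possible perfect separation)")
    beta <- stats::coef(fit)
    if (any(is.na(beta))) stop("singular design matrix")
  }
  new_fitted_model(model_id, if (family == "gaussian") "continuous"
                   else "remission",
                   "regression", unname(beta[1]), beta[-1],
                   list(family = family, model_form = scores$model_form,
                        dropped = dropped,
                        weights_used = scores$weights_used))
}

#' Fit an elastic-net regularised regression
#'
#' Coordinate-descent elastic net (via glmnet, predictors standardized
#' internally) over a grid of mixing parameters `alpha` and a per-alpha
#' regularisation path; the `(alpha, lambda)` pair minimising the mean
#' cross-validated deviance (binomial) or MSE (gaussian) is selected with
#' folds stratified by study, and the model is refit on the full training
#' data at that pair.
#'
#' @inheritParams fit_regression
#' @param alpha_grid Mixing-parameter grid in (0, 1].
#' @param lambda_grid Optional fixed lambda path (default: auto-scaled
#'   100-value path).
#' @param folds Number of CV folds.
#' @param seed Integer seed (fold assignment).
#' @param study Optional study label per row for stratified folds.
#' @param ... Passed on to [glmnet::cv.glmnet()] (e.g. `thresh`).
#' @return A `fitted_prognostic_model` storing `enr_alpha`, `enr_lambda`.
#' @export
fit_enr <- function(scores, outcome, family = c("gaussian", "binomial"),
                    alpha_grid = seq(0.05, 1, by = 0.05),
                    lambda_grid = NULL, folds = 10L, seed = 1L,
                    study = NULL, model_id = NA_integer_, ...) {
  family <- match.arg(family)
  stopifnot(inherits(scores, "score_set"), length(alpha_grid) >= 1,
            folds >= 2)
  X <- scores$x
  if (anyNA(outcome)) stop("outcome must be complete")
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  if (!all(keep)) {
    warning("excluding all-zero/constant predictor(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "enr"))
  foldid <- make_stratified_folds(if (is.null(study)) scores$meta$study_id
                                  else study, folds)

  type_measure <- if (family == "binomial") "deviance" else "mse"
  best <- list(cvm = Inf)
  for (alpha in alpha_grid) {
    cv <- glmnet::cv.glmnet(X, outcome, family = family, alpha = alpha,
                            lambda = lambda_grid, foldid = foldid,
                            type.measure = type_measure,
                            standardize = TRUE, ...)
    i <- which.min(cv$cvm)
    if (cv$cvm[i] < best$cvm) {
      best <- list(cvm = cv$cvm[i], alpha = alpha, lambda = cv$lambda[i],
                   fit = cv$glmnet.fit)
    }
  }
  beta <- as.numeric(stats::coef(best$fit, s = best$lambda))
  names(beta) <- c("(Intercept)", colnames(X))
  new_fitted_model(model_id, if (family == "gaussian") "continuous"
                   else "remission",
                   "ENR", unname(beta[1]), beta[-1],
                   list(family = family, model_form = scores$model_form,
                        enr_alpha = best$alpha, enr_lambda = best$lambda,
                        path_lambda = best$fit$lambda,
                        path_l1 = colSums(abs(as.matrix(best$fit$beta))),
                        weights_used = scores$weights_used))
}

make_stratified_folds <- function(study, folds) {
  foldid <- integer(length(study))
  for (s in unique(study)) {
    idx <- which(study == s)
    foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  foldid
}

#' Fit the null model
#'
#' Stores the training-set outcome mean (continuous) or remission
#' proportion (binary) as the constant prediction for every patient.
#'
#' @param outcome Training outcome vector (continuous total or 0/1 flag).
#' @param family `"gaussian"` or `"binomial"`.
#' @param model_id Identifier stored on the fit.
#' @return A `fitted_prognostic_model` with no coefficients.
#' @export
fit_null <- function(outcome, family = c("gaussian", "binomial"),
                     model_id = 9L) {
  family <- match.arg(family)
  outcome <- outcome[!is.na(outcome)]
  stopifnot(length(outcome) >= 1)
  new_fitted_model(model_id, if (family == "gaussian") "continuous"
                   else "remission",
                   "null", mean(outcome), numeric(0),
                   list(family = family, model_form = "null",
                        train_constant = mean(outcome)))
}

#' Predict from a fitted prognostic model
#'
#' Linear predictor plus intercept; inverse-logit applied for binomial
#' fits; the null model returns its stored constant.
#'
#' @param object A `fitted_prognostic_model`.
#' @param scores A `score_set` whose predictor labels match the training
#'   labels (ignored by the null model except for its length).
#' @param ... Unused.
#' @return Numeric vector of predictions (probabilities for binomial).
#' @export
predict.fitted_prognostic_model <- function(object, scores, ...) {
  n <- nrow(scores$x)
  if (object$estimator == "null") {
    return(rep(object$train_constant, n))
  }
  need <- names(object$coefficients)
  if (!all(need %in% colnames(scores$x))) {
    stop("score set labels do not match training labels")
  }
  eta <- object$intercept +
    as.numeric(scores$x[, need, drop = FALSE] %*% object$coefficients)
  if (object$family == "binomial") stats::plogis(eta) else eta
}

#' @export
print.fitted_prognostic_model <- function(x, ...) {
  reg <- model_registry()
  lab <- if (!is.na(x$model_id)) reg$label[reg$model_id == x$model_id]
         else x$estimator
  cat(sprintf("Model %s (%s, %s outcome)\n",
              ifelse(is.na(x$model_id), "?", x$model_id), lab, x$outcome))
  if (x$estimator == "null") {
    cat(sprintf("  constant prediction: %.4f\n", x$train_constant))
  } else {
    cat(sprintf("  intercept %.4f, %d coefficient(s)\n", x$intercept,
                length(x$coefficients)))
    if (!is.null(x$enr_alpha)) {
      cat(sprintf("  selected alpha = %.2f, lambda = %.4g\n",
                  x$enr_alpha, x$enr_lambda))
    }
  }
  invisible(x)
}

#' @export
coef.fitted_prognostic_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' Serialise a fitted model to JSON
#'
#' Stores the model description, intercept, coefficients and selected
#' hyperparameters so published coefficients can be reused.
#'
#' @param model A `fitted_prognostic_model`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "fitted_prognostic_model"))
  jsonlite::write_json(
    list(model_id = model$model_id, outcome = model$outcome,
         estimator = model$estimator, family = model$family,
         model_form = model$model_form, intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         enr_alpha = model$enr_alpha, enr_lambda = model$enr_lambda,
         train_constant = model$train_constant),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
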