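# End-to-end comparison of the nine modelling approaches for both outcomes
# (18 fitted models), with external validation on held-out test studies and
# internal cross-validation of the training set.

#' Control parameters for a prognosis comparison run
#'
#' @param impute An [impute_policy()].
#' @param fgl_lambda1_grid,fgl_lambda2_grid Penalty grids for the fused
#'   network (10-fold CV selection).
#' @param fgl_folds Folds for network penalty selection.
#' @param fgl_rho,fgl_tol,fgl_max_iter ADMM options for [fgl()].
#' @param enr_alpha_grid Elastic-net mixing grid for the final model fits.
#' @param enr_folds Elastic-net CV folds.
#' @param cv_folds Folds for the internal cross-validation of the full
#'   training set.
#' @param cv_enr_alpha_grid Coarser mixing grid used when re-tuning the
#'   elastic net inside each internal-CV fold.
#' @param bin_size Calibration bin size (default 50 patients).
#' @param walktrap_steps Random-walk length for community detection.
#' @param run_internal_cv Run the internal cross-validation stage?
#' @return An object of class `prognosis_control`.
#' @export
prognosis_control <- function(impute = impute_policy(),
                              fgl_lambda1_grid = 10^seq(log10(0.05),
                                                        log10(0.5),
                                                        length.out = 5),
                              fgl_lambda2_grid = c(0.01, 0.1),
                              fgl_folds = 10L,
                              fgl_rho = NULL, fgl_tol = 1e-5,
                              fgl_max_iter = 5000L,
                              enr_alpha_grid = seq(0.05, 1, by = 0.05),
                              enr_folds = 10L,
                              cv_folds = 10L,
                              cv_enr_alpha_grid = seq(0.1, 1, by = 0.1),
                              bin_size = 50L,
                              walktrap_steps = 4L,
                              run_internal_cv = TRUE) {
  structure(list(impute = impute,
                 fgl_lambda1_grid = fgl_lambda1_grid,
                 fgl_lambda2_grid = fgl_lambda2_grid,
                 fgl_folds = as.integer(fgl_folds),
                 fgl_rho = fgl_rho, fgl_tol = fgl_tol,
                 fgl_max_iter = as.integer(fgl_max_iter),
                 enr_alpha_grid = enr_alpha_grid,
                 enr_folds = as.integer(enr_folds),
                 cv_folds = as.integer(cv_folds),
                 cv_enr_alpha_grid = cv_enr_alpha_grid,
                 bin_size = as.integer(bin_size),
                 walktrap_steps = as.integer(walktrap_steps),
                 run_internal_cv = isTRUE(run_internal_cv)),
            class = "prognosis_control")
}

# Estimate the four weight vectors on (complete) training tables.
estimate_weights <- function(tables, control, lambda1, lambda2) {
  sc <- standardized_covariances(tables)
  net <- fgl(sc$S, sc$n, lambda1, lambda2, rho = control$fgl_rho,
             tol = control$fgl_tol, max_iter = control$fgl_max_iter)
  cfa <- fit_one_factor(tables)
  list(network = net, cfa = cfa,
       weights = list(
         EI1 = centrality_weights(net, "EI1"),
         EI2 = centrality_weights(net, "EI2"),
         PCPR = centrality_weights(net, "PCPR",
                                   steps = control$walktrap_steps),
         CFA = loadings_to_weights(cfa)))
}

# Build the score set a given model form needs.
build_scores <- function(tables, form, weighting, weights) {
  switch(form,
         weighted_sums = weighted_scores(tables, weights[[weighting]]),
         unweighted_sums = unweighted_scores(tables),
         item_level = item_level_predictors(tables),
         null = unweighted_scores(tables))  # null ignores predictors
}

# All nine score sets keyed by form, computed once per table collection.
score_sets_for <- function(tables, weights) {
  reg <- model_registry()
  out <- list(unweighted_sums = unweighted_scores(tables),
              item_level = item_level_predictors(tables))
  for (m in which(reg$form == "weighted_sums")) {
    key <- paste0("weighted_sums_", reg$weighting[m])
    out[[key]] <- weighted_scores(tables, weights[[reg$weighting[m]]])
  }
  out
}

lookup_scores <- function(score_sets, form, weighting) {
  if (form == "weighted_sums") score_sets[[paste0("weighted_sums_",
                                                  weighting)]]
  else if (form == "null") score_sets[["unweighted_sums"]]
  else score_sets[[form]]
}

#' Fit and compare the nine prognostic modelling approaches
#'
#' The central fitting function: imputes the training and test studies
#' under the missing-data policy (test outcomes are never imputed; test
#' patients without an outcome are excluded), estimates the fused network
#' (penalties by stratified 10-fold CV) and the one-factor model on the
#' training studies only, constructs the four weighted and two unweighted
#' predictor sets, fits all nine approaches for both the continuous
#' follow-up total and remission (18 models), and evaluates every model on
#' the combined test set, per test study, and by internal cross-validation
#' of the training set. Entirely deterministic given `seed`.
#'
#' @param data A `study_set` (see [generate_multi_study()] /
#'   [read_study_set()]); test studies may be absent.
#' @param control A [prognosis_control()].
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @return An object of class `prognosis_comparison`; see the vignette.
#'   Key elements: `network`, `weights`, `models` (18 fits),
#'   `evaluation` (metric table over models, outcomes and scopes),
#'   `calibration`, `severity`, `prediction_correlations`.
#' @export
prognosis_comparison <- function(data, control = prognosis_control(),
                                 seed = 1L) {
  stopifnot(inherits(data, "study_set"), inherits(control,
                                                  "prognosis_control"))
  cl <- match.call()
  has_test <- length(data$test) > 0

  # --- missing-data policy ---------------------------------------------
  pol_train <- control$impute
  pol_train$seed <- derive_seed(seed, "impute_train")
  imp_train <- impute_tables(data$train, "train", pol_train)
  train_tables <- imp_train$tables

  n_excluded <- 0L
  test_tables <- list()
  imp_test <- NULL
  if (has_test) {
    pol_test <- control$impute
    pol_test$seed <- derive_seed(seed, "impute_test")
    pol_test$impute_training_outcome <- FALSE
    imp_test <- impute_tables(data$test, "test", pol_test)
    flt <- filter_test_outcomes(imp_test$tables)
    test_tables <- flt$tables
    n_excluded <- flt$n_excluded
  }

  # --- training-only weight estimation ---------------------------------
  sel <- select_penalties(train_tables,
                          lambda1_grid = control$fgl_lambda1_grid,
                          lambda2_grid = control$fgl_lambda2_grid,
                          folds = control$fgl_folds,
                          seed = derive_seed(seed, "fgl_cv"),
                          rho = control$fgl_rho, tol = control$fgl_tol,
                          max_iter = control$fgl_max_iter)
  wts <- estimate_weights(train_tables, control, sel$lambda1, sel$lambda2)

  # --- model fitting (9 x 2 outcomes) ----------------------------------
  train_scores <- score_sets_for(train_tables, wts$weights)
  meta_train <- train_scores$unweighted_sums$meta
  y_cont <- meta_train$outcome_bdi
  y_bin <- meta_train$remission
  reg <- model_registry()
  fit_for_outcome <- function(fam, y) {
    sets <- lapply(seq_len(9L), function(m) {
      lookup_scores(train_scores, reg$form[m], reg$weighting[m])
    })
    names(sets) <- reg$form
    # fit_nine indexes by form; pass a keyed list instead
    ok <- !is.na(y)
    models <- vector("list", 9L)
    for (m in seq_len(9L)) {
      if (reg$estimator[m] == "null") {
        models[[m]] <- fit_null(y[ok], fam, model_id = m)
        next
      }
      sc <- sets[[m]]
      sc$x <- sc$x[ok, , drop = FALSE]
      sc$meta <- sc$meta[ok, , drop = FALSE]
      models[[m]] <- if (reg$estimator[m] == "ENR") {
        fit_enr(sc, y[ok], fam, alpha_grid = control$enr_alpha_grid,
                folds = control$enr_folds, seed = seed + m, model_id = m)
      } else {
        fit_regression(sc, y[ok], fam, model_id = m)
      }
    }
    names(models) <- paste0("model_", 1:9)
    models
  }
  models <- list(continuous = fit_for_outcome("gaussian", y_cont),
                 remission = fit_for_outcome("binomial", y_bin))

  # --- external validation ---------------------------------------------
  evaluation <- NULL
  calibration <- severity <- NULL
  pred_cor <- NULL
  test_predictions <- NULL
  if (has_test) {
    test_scores <- score_sets_for(test_tables, wts$weights)
    meta_test <- test_scores$unweighted_sums$meta
    pred_mat <- function(outcome) {
      sapply(seq_len(9L), function(m) {
        sc <- lookup_scores(test_scores, reg$form[m], reg$weighting[m])
        stats::predict(models[[outcome]][[m]], sc)
      })
    }
    P_cont <- pred_mat("continuous")
    P_bin <- pred_mat("remission")
    colnames(P_cont) <- colnames(P_bin) <- paste0("model_", 1:9)
    test_predictions <- list(continuous = P_cont, remission = P_bin)

    scopes <- c(list(combined_test = rep(TRUE, nrow(meta_test))),
                stats::setNames(
                  lapply(unique(meta_test$study_id), function(s) {
                    meta_test$study_id == s
                  }),
                  paste0("per_study:", unique(meta_test$study_id))))
    rows <- list()
    for (sc_name in names(scopes)) {
      idx <- scopes[[sc_name]]
      for (m in seq_len(9L)) {
        cm <- continuous_metrics(meta_test$outcome_bdi[idx], P_cont[idx, m])
        bm <- binary_metrics(meta_test$remission[idx], P_bin[idx, m])
        rows[[length(rows) + 1L]] <- data.frame(
          model_id = m, scope = sc_name,
          r_squared = cm$r_squared, rmse = cm$rmse, mae = cm$mae,
          auc = bm$auc, brier = bm$brier, n = cm$n)
      }
    }
    evaluation <- do.call(rbind, rows)

    calibration <- lapply(1:8, function(m) {
      calibration_bins(meta_test$outcome_bdi, P_cont[, m],
                       meta_test$remission, control$bin_size)
    })
    names(calibration) <- paste0("model_", 1:8)
    severity <- lapply(1:8, function(m) {
      severity_category_remission(P_cont[, m], meta_test$remission)
    })
    names(severity) <- paste0("model_", 1:8)
    pred_cor <- suppressWarnings(prediction_correlations(P_cont))
  }

  # --- internal cross-validation ---------------------------------------
  internal_cv <- NULL
  if (control$run_internal_cv) {
    internal_cv <- internal_cross_validation(
      train_tables, model_ids = 1:9, outcomes = c("continuous", "remission"),
      folds = control$cv_folds, seed = derive_seed(seed, "cv"),
      control = control, lambda1 = sel$lambda1, lambda2 = sel$lambda2)
    evaluation <- rbind(evaluation, internal_cv$metrics)
  }

  train_rem <- mean(meta_train$remission, na.rm = TRUE)
  structure(list(call = cl, control = control, seed = seed,
                 penalty_selection = sel,
                 network = wts$network, cfa = wts$cfa,
                 weights = wts$weights,
                 impute_reports = list(train = imp_train$report,
                                       test = if (!is.null(imp_test))
                                         imp_test$report),
                 models = models,
                 n_train = nrow(meta_train),
                 n_test = if (has_test) sum(vapply(test_tables, nrow,
                                                   integer(1))) else 0L,
                 n_test_excluded = n_excluded,
                 train_remission_rate = train_rem,
                 test_remission_rate = if (has_test)
                   mean(do.call(rbind, test_tables)$remission) else NA_real_,
                 test_predictions = test_predictions,
                 evaluation = evaluation,
                 calibration = calibration,
                 severity = severity,
                 prediction_correlations = pred_cor,
                 internal_cv = internal_cv,
                 train_tables = train_tables,
                 test_tables = test_tables),
            class = "prognosis_comparison")
}

#' Internal cross-validation of the full modelling pipeline
#'
#' Training patients are partitioned into folds stratified by study. Inside
#' each fold-complement the weight-estimation stages are re-run from
#' scratch (fused network re-estimated at the supplied penalty pair, factor
#' model refitted, elastic net re-tuned), the requested models are fitted,
#' and held-out predictions are collected; metrics are computed once on the
#' pooled held-out predictions.
#'
#' @param tables Complete training-study data frames.
#' @param model_ids Subset of 1..9 to evaluate.
#' @param outcomes `"continuous"`, `"remission"`, or both.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed (fold assignment; ENR tuning).
#' @param control A [prognosis_control()].
#' @param lambda1,lambda2 Fused-network penalties (selected once on the
#'   full training set).
#' @return List with `metrics` (data frame, scope `"internal_cv"`) and
#'   `predictions` (pooled held-out predictions per outcome).
#' @export
internal_cross_validation <- function(tables, model_ids = 1:9,
                                      outcomes = c("continuous", "remission"),
                                      folds = 10L, seed = 1L,
                                      control = prognosis_control(),
                                      lambda1 = 0.1, lambda2 = 0.01) {
  stopifnot(folds >= 2, all(model_ids %in% 1:9))
  min_n <- min(vapply(tables, nrow, integer(1)))
  if (folds > min_n / 2) {
    stop("fold too small for network estimation (smallest study has ",
         min_n, " patients): use fewer folds")
  }
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  reg <- model_registry()
  need_net <- any(reg$weighting[model_ids] %in% c("EI1", "EI2", "PCPR"))
  need_cfa <- any(reg$weighting[model_ids] == "CFA")

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "folds"))
  fold_ids <- lapply(tables, function(d) sample(rep_len(seq_len(folds),
                                                        nrow(d))))

  n_tot <- sum(vapply(tables, nrow, integer(1)))
  fams <- c(continuous = "gaussian", remission = "binomial")[outcomes]
  preds <- lapply(outcomes, function(o) {
    matrix(NA_real_, n_tot, length(model_ids),
           dimnames = list(NULL, paste0("model_", model_ids)))
  })
  names(preds) <- outcomes
  obs <- data.frame(outcome_bdi = rep(NA_real_, n_tot),
                    remission = rep(NA_real_, n_tot))
  offsets <- c(0L, cumsum(vapply(tables, nrow, integer(1))))

  for (f in seq_len(folds)) {
    tr <- ho <- vector("list", length(tables))
    ho_rows <- integer(0)
    for (k in seq_along(tables)) {
      hold <- fold_ids[[k]] == f
      if (sum(!hold) < 2) {
        stop("fold too small for network estimation: use fewer folds")
      }
      tr[[k]] <- tables[[k]][!hold, , drop = FALSE]
      ho[[k]] <- tables[[k]][hold, , drop = FALSE]
      ho_rows <- c(ho_rows, offsets[k] + which(hold))
    }
    weights <- NULL
    if (need_net || need_cfa) {
      sc <- tryCatch(standardized_covariances(tr), error = function(e) {
        stop("fold too small for network estimation (", conditionMessage(e),
             "): use fewer folds")
      })
      net <- if (need_net) {
        fgl(sc$S, sc$n, lambda1, lambda2, rho = control$fgl_rho,
            tol = control$fgl_tol, max_iter = control$fgl_max_iter)
      }
      cfa <- if (need_cfa) fit_one_factor(tr)
      weights <- list()
      if (need_net) {
        weights$EI1 <- centrality_weights(net, "EI1")
        weights$EI2 <- centrality_weights(net, "EI2")
        weights$PCPR <- centrality_weights(net, "PCPR",
                                           steps = control$walktrap_steps)
      }
      if (need_cfa) weights$CFA <- loadings_to_weights(cfa)
    }
    tr_sets <- score_sets_for_subset(tr, reg, model_ids, weights)
    ho_sets <- score_sets_for_subset(ho, reg, model_ids, weights)
    meta_tr <- score_meta(tr)
    meta_ho <- score_meta(ho)
    obs$outcome_bdi[ho_rows] <- meta_ho$outcome_bdi
    obs$remission[ho_rows] <- meta_ho$remission

    for (o in outcomes) {
      fam <- fams[[o]]
      y <- if (o == "continuous") meta_tr$outcome_bdi else meta_tr$remission
      ok <- !is.na(y)
      for (j in seq_along(model_ids)) {
        m <- model_ids[j]
        if (reg$estimator[m] == "null") {
          fit <- fit_null(y[ok], fam, model_id = m)
          preds[[o]][ho_rows, j] <- rep(fit$train_constant, length(ho_rows))
          next
        }
        sc <- lookup_scores(tr_sets, reg$form[m], reg$weighting[m])
        sc$x <- sc$x[ok, , drop = FALSE]
        sc$meta <- sc$meta[ok, , drop = FALSE]
        fit <- if (reg$estimator[m] == "ENR") {
          fit_enr(sc, y[ok], fam, alpha_grid = control$cv_enr_alpha_grid,
                  folds = control$enr_folds,
                  seed = seed + 13L * f + m, model_id = m)
        } else {
          fit_regression(sc, y[ok], fam, model_id = m)
        }
        sc_ho <- lookup_scores(ho_sets, reg$form[m], reg$weighting[m])
        preds[[o]][ho_rows, j] <- stats::predict(fit, sc_ho)
      }
    }
  }

  rows <- list()
  for (o in outcomes) {
    for (j in seq_along(model_ids)) {
      m <- model_ids[j]
      if (o == "continuous") {
        keep <- !is.na(obs$outcome_bdi)
        cm <- continuous_metrics(obs$outcome_bdi[keep], preds[[o]][keep, j])
        rows[[length(rows) + 1L]] <- data.frame(
          model_id = m, scope = "internal_cv", r_squared = cm$r_squared,
          rmse = cm$rmse, mae = cm$mae, auc = NA_real_, brier = NA_real_,
          n = cm$n)
      } else {
        keep <- !is.na(obs$remission)
        bm <- binary_metrics(obs$remission[keep], preds[[o]][keep, j])
        rows[[length(rows) + 1L]] <- data.frame(
          model_id = m, scope = "internal_cv", r_squared = NA_real_,
          rmse = NA_real_, mae = NA_real_, auc = bm$auc, brier = bm$brier,
          n = bm$n)
      }
    }
  }
  metrics <- do.call(rbind, rows)
  # merge continuous and remission rows per model into one row
  metrics <- merge_cv_rows(metrics)
  list(metrics = metrics, predictions = preds, observed = obs)
}

score_sets_for_subset <- function(tables, reg, model_ids, weights) {
  out <- list()
  forms <- unique(reg$form[model_ids])
  if (any(c("unweighted_sums", "null") %in% forms)) {
    out$unweighted_sums <- unweighted_scores(tables)
  }
  if ("item_level" %in% forms) out$item_level <- item_level_predictors(tables)
  for (m in model_ids[reg$form[model_ids] == "weighted_sums"]) {
    key <- paste0("weighted_sums_", reg$weighting[m])
    out[[key]] <- weighted_scores(tables, weights[[reg$weighting[m]]])
  }
  out
}

merge_cv_rows <- function(metrics) {
  ids <- unique(metrics$model_id)
  out <- lapply(ids, function(m) {
    sub <- metrics[metrics$model_id == m, , drop = FALSE]
    row <- sub[1, , drop = FALSE]
    for (col in c("r_squared", "rmse", "mae", "auc", "brier")) {
      v <- sub[[col]][!is.na(sub[[col]])]
      row[[col]] <- if (length(v)) v[1] else NA_real_
    }
    row$n <- max(sub$n)
    row
  })
  do.call(rbind, out)
}

#' @export
print.prognosis_comparison <- function(x, ...) {
  cat("Comparison of nine prognostic modelling approaches\n")
  cat(sprintf("  training n = %d; test n = %d (%d excluded for missing outcome)\n",
              x$n_train, x$n_test, x$n_test_excluded))
  cat(sprintf("  fused network: lambda1 = %.4g, lambda2 = %.4g\n",
              x$network$lambda1, x$network$lambda2))
  cat(sprintf("  remission rate: %.1f%% train, %s test\n",
              100 * x$train_remission_rate,
              if (is.na(x$test_remission_rate)) "-" else
                sprintf("%.1f%%", 100 * x$test_remission_rate)))
  cat(sprintf("  %d fitted models (%d per outcome)\n",
              sum(lengths(x$models)), length(x$models$continuous)))
  if (!is.null(x$evaluation)) {
    comb <- x$evaluation[x$evaluation$scope == "combined_test", ]
    if (nrow(comb)) {
      cat("\nCombined test set:\n")
      print(format(comb[, c("model_id", "r_squared", "rmse", "mae", "auc",
                            "brier")], digits = 3), row.names = FALSE)
    }
  }
  invisible(x)
}

#' @export
summary.prognosis_comparison <- function(object, ...) {
  structure(list(evaluation = object$evaluation,
                 weights = object$weights,
                 n_models = sum(lengths(object$models)),
                 train_remission_rate = object$train_remission_rate,
                 test_remission_rate = object$test_remission_rate),
            class = "summary.prognosis_comparison")
}

#' @export
print.summary.prognosis_comparison <- function(x, ...) {
  cat(sprintf("%d fitted models; remission %.1f%% train / %s test\n",
              x$n_models, 100 * x$train_remission_rate,
              if (is.na(x$test_remission_rate)) "-" else
                sprintf("%.1f%%", 100 * x$test_remission_rate)))
  print(format(x$evaluation, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.prognosis_comparison <- function(object,
                                      outcome = c("continuous", "remission"),
                                      ...) {
  outcome <- match.arg(outcome)
  lapply(object$models[[outcome]], coef)
}

#' Predict follow-up outcomes for new patients
#'
#' Applies one of the fitted models, with its frozen training-derived
#' weights, to new complete study tables.
#'
#' @param object A [prognosis_comparison()] fit.
#' @param tables List of complete study data frames (standard schema).
#' @param model_id Which of the nine models to use.
#' @param outcome `"continuous"` (predicted follow-up total) or
#'   `"remission"` (predicted probability).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.prognosis_comparison <- function(object, tables, model_id = 6L,
                                         outcome = c("continuous",
                                                     "remission"), ...) {
  outcome <- match.arg(outcome)
  stopifnot(model_id %in% 1:9)
  reg <- model_registry()
  sc <- build_scores(tables, reg$form[model_id], reg$weighting[model_id],
                     object$weights)
  stats::predict(object$models[[outcome]][[model_id]], sc)
}

#' Write the evaluation report as JSON
#'
#' Metrics per (model, outcome, scope), calibration bins, severity tables,
#' the prediction correlation matrix and headline cohort quantities.
#'
#' @param x A `prognosis_comparison`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_evaluation_json <- function(x, path) {
  stopifnot(inherits(x, "prognosis_comparison"))
  jsonlite::write_json(
    list(evaluation = x$evaluation,
         calibration = x$calibration,
         severity = x$severity,
         prediction_correlations = x$prediction_correlations,
         n_train = x$n_train, n_test = x$n_test,
         n_test_excluded = x$n_test_excluded,
         train_remission_rate = x$train_remission_rate,
         test_remission_rate = x$test_remission_rate,
         lambda1 = x$network$lambda1, lambda2 = x$network$lambda2),
    path, auto_unbox = TRUE, digits = NA, na = "null", matrix = "rowmajor")
  invisible(path)
}
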