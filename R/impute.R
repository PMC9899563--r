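# Missing-data policy: iterative random-forest imputation of baseline
# variables with under-30% missingness; training outcomes imputable by
# configuration; test outcomes never imputed (patients without a test
# outcome are excluded from evaluation instead).

#' Imputation policy
#'
#' @param max_missing_fraction Exclusive upper bound on the per-variable
#'   missing fraction for a variable to be imputed (default 0.30: variables
#'   with < 30% missing are imputed, the rest are flagged and left as-is).
#' @param max_iterations Maximum number of imputation sweeps.
#' @param num_trees Trees per random forest.
#' @param seed Integer seed (imputation is deterministic given the seed).
#' @param impute_training_outcome Should missing training-set outcomes be
#'   imputed alongside the baseline variables?
#' @return An object of class `impute_policy`.
#' @export
impute_policy <- function(max_missing_fraction = 0.30,
                          max_iterations = 10L,
                          num_trees = 100L,
                          seed = 1L,
                          impute_training_outcome = FALSE) {
  stopifnot(max_missing_fraction > 0, max_missing_fraction <= 1,
            max_iterations >= 1, num_trees >= 1)
  structure(list(max_missing_fraction = max_missing_fraction,
                 max_iterations = as.integer(max_iterations),
                 num_trees = as.integer(num_trees),
                 seed = as.integer(seed),
                 impute_training_outcome = isTRUE(impute_training_outcome)),
            class = "impute_policy")
}

#' Impute missing values in a collection of study tables
#'
#' Pools the tables of one role and cycles over incomplete variables,
#' regressing each on all other variables (plus study membership) with a
#' random forest and filling its missing cells with the predictions, until
#' the sum of squared changes in the imputed values increases or
#' `max_iterations` is reached. Ordinal variables are rounded to their
#' valid range afterwards. Variables whose missing fraction is at or above
#' `max_missing_fraction` are left untouched and flagged. For `role =
#' "test"` the outcome column is never modified (nor used as a predictor).
#'
#' @param tables List of study data frames sharing the standard schema.
#' @param role `"train"` or `"test"`.
#' @param policy An [impute_policy()].
#' @return A list with elements `tables` (imputed list, same shapes) and
#'   `report` (per-variable missing fractions, imputed-cell counts, flagged
#'   variables, iterations used).
#' @export
impute_tables <- function(tables, role = c("train", "test"),
                          policy = impute_policy()) {
  role <- match.arg(role)
  stopifnot(inherits(policy, "impute_policy"), length(tables) >= 1)
  labs <- baseline_labels()
  candidate <- labs
  if (role == "train" && policy$impute_training_outcome) {
    candidate <- c(candidate, "outcome_bdi")
  }

  pooled <- do.call(rbind, lapply(tables, function(d) d[, c("study_id", labs,
                                                            "outcome_bdi")]))
  n <- nrow(pooled)
  miss_frac <- vapply(candidate, function(v) mean(is.na(pooled[[v]])),
                      numeric(1))
  fully_missing <- candidate[miss_frac == 1]
  if (length(fully_missing)) {
    stop("variable(s) entirely missing, cannot impute: ",
         paste(fully_missing, collapse = ", "))
  }
  flagged <- candidate[miss_frac >= policy$max_missing_fraction & miss_frac > 0]
  to_impute <- candidate[miss_frac < policy$max_missing_fraction &
                           miss_frac > 0]

  report <- list(
    role = role,
    missing_fraction = as.list(miss_frac),
    imputed_cells = as.list(stats::setNames(
      vapply(candidate, function(v) {
        if (v %in% to_impute) sum(is.na(pooled[[v]])) else 0L
      }, integer(1)), candidate)),
    flagged_not_imputed = flagged,
    iterations = 0L
  )
  if (!length(to_impute)) {
    return(list(tables = tables, report = report))
  }

  # Predictor frame: all baseline variables, study as a factor, and (train
  # role only, when outcomes are being imputed) the outcome itself.
  pred_vars <- labs
  if (role == "train" && policy$impute_training_outcome) {
    pred_vars <- c(pred_vars, "outcome_bdi")
  }
  work <- pooled[, pred_vars, drop = FALSE]
  na_idx <- lapply(to_impute, function(v) which(is.na(work[[v]])))
  names(na_idx) <- to_impute

  # Mean initialisation of every missing cell (rounded for ordinals later).
  for (v in pred_vars) {
    if (anyNA(work[[v]])) {
      work[[v]][is.na(work[[v]])] <- mean(work[[v]], na.rm = TRUE)
    }
  }
  work$study_id <- factor(pooled$study_id)

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(policy$seed)

  # Sweep variables in increasing order of missingness (missForest order).
  sweep_order <- to_impute[order(miss_frac[to_impute])]
  prev_change <- Inf
  prev_vals <- lapply(to_impute, function(v) work[[v]][na_idx[[v]]])
  names(prev_vals) <- to_impute
  iters <- 0L
  for (it in seq_len(policy$max_iterations)) {
    for (v in sweep_order) {
      obs <- setdiff(seq_len(n), na_idx[[v]])
      fit <- ranger::ranger(
        x = work[obs, setdiff(colnames(work), v), drop = FALSE],
        y = work[[v]][obs],
        num.trees = policy$num_trees, num.threads = 1L,
        seed = derive_seed(policy$seed, "impute_train") + it
      )
      pred <- stats::predict(
        fit, data = work[na_idx[[v]], setdiff(colnames(work), v),
                         drop = FALSE],
        num.threads = 1L
      )$predictions
      work[[v]][na_idx[[v]]] <- pred
    }
    iters <- it
    change <- sum(vapply(to_impute, function(v) {
      sum((work[[v]][na_idx[[v]]] - prev_vals[[v]])^2)
    }, numeric(1))) / max(sum(vapply(to_impute, function(v) {
      sum(work[[v]][na_idx[[v]]]^2)
    }, numeric(1))), .Machine$double.eps)
    if (change > prev_change) break
    prev_change <- change
    prev_vals <- lapply(to_impute, function(v) work[[v]][na_idx[[v]]])
    names(prev_vals) <- to_impute
  }
  report$iterations <- iters

  # Round imputed ordinals/totals back onto their valid integer ranges.
  rng <- variable_ranges()
  for (v in to_impute) {
    vals <- work[[v]][na_idx[[v]]]
    if (v == "outcome_bdi") {
      vals <- pmin(pmax(round(vals), 0L), 63L)
    } else {
      vals <- pmin(pmax(round(vals), rng$lower[[v]]), rng$upper[[v]])
    }
    work[[v]][na_idx[[v]]] <- vals
  }

  # Scatter pooled rows back into the per-study tables.
  offsets <- c(0L, cumsum(vapply(tables, nrow, integer(1))))
  out <- tables
  for (i in seq_along(tables)) {
    rows <- (offsets[i] + 1L):offsets[i + 1L]
    for (v in to_impute) {
      out[[i]][[v]] <- as.integer(round(work[[v]][rows]))
    }
    if (role == "train" && policy$impute_training_outcome &&
        "outcome_bdi" %in% to_impute) {
      out[[i]]$remission <- as.integer(out[[i]]$outcome_bdi <= REMISSION_CUTOFF)
    }
  }
  list(tables = out, report = report)
}

#' Exclude test patients without outcome data
#'
#' @param tables List of test-study data frames.
#' @return List with `tables` (rows with missing `outcome_bdi` removed) and
#'   `n_excluded` (total rows dropped).
#' @export
filter_test_outcomes <- function(tables) {
  kept <- lapply(tables, function(d) d[!is.na(d$outcome_bdi), , drop = FALSE])
  n_excluded <- sum(vapply(tables, function(d) sum(is.na(d$outcome_bdi)),
                           integer(1)))
  if (sum(vapply(kept, nrow, integer(1))) == 0L) {
    warning("all test outcomes missing: analysis set is empty")
  }
  list(tables = kept, n_excluded = n_excluded)
}

#' Write an imputation report as JSON
#'
#' @param report The `report` element returned by [impute_tables()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_impute_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
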