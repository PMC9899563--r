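# Multi-study synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# shared latent severity factor driving 32 ordinal/total baseline variables,
# residual item-item partial correlations on top of the factor, between-study
# heterogeneity as study-specific latent mean shifts, a follow-up severity
# total linearly related to latent severity and the auxiliary totals plus
# Gaussian noise, and configurable missingness.

#' Configuration for the synthetic multi-study cohort generator
#'
#' The defaults describe the bundled "paper-like" study conditions scaled by
#' `n_per_study`: a depressed primary-care population measured on 21
#' depressive-symptom items (0-3), 8 anxiety subscale totals (0-4) and three
#' auxiliary totals, with test studies systematically more severe than
#' training studies (a realistic train/test distribution shift).
#'
#' @param n_studies_train,n_studies_test Number of training / test studies.
#' @param n_per_study Integer vector of per-study sample sizes, recycled to
#'   `n_studies_train + n_studies_test` (training studies first).
#' @param latent_loadings Named numeric vector (all 32 baseline variables):
#'   loading of each variable's latent Gaussian on the severity factor;
#'   absolute values must be < 1.
#' @param residual_network Symmetric 32 x 32 matrix of residual partial
#'   correlations (zero diagonal): item-item dependence beyond the factor.
#' @param study_mean_shift_sd SD of the study-specific latent mean shift
#'   (between-study heterogeneity), drawn once per study.
#' @param test_latent_shift Additive latent mean shift applied to every test
#'   study (raises baseline severity in the test set).
#' @param test_outcome_shift Additive shift (points on the 0-63 scale)
#'   applied to test-study follow-up totals before rounding; emulates
#'   outcome-level distribution shift not captured by baseline severity.
#' @param outcome_coefficients Named numeric vector
#'   `c(intercept, latent, social_support, life_events, alcohol)`: linear
#'   effect of true latent severity and the auxiliary totals on the
#'   follow-up total.
#' @param outcome_noise_sd Residual SD of the follow-up total (>= 0).
#' @param missing_rate MCAR missingness fraction applied to baseline cells
#'   at generation time; must be < 0.30.
#' @param test_outcome_missing_rate Fraction of test-study follow-up totals
#'   set missing (loss to follow-up); training outcomes are never masked
#'   here.
#' @param bdi_cutprobs,anx_cutprobs Cumulative probabilities defining the
#'   latent-Gaussian thresholds for item categories (length 3 for 0-3 items,
#'   length 4 for 0-4 subscales).
#' @param aux_location,aux_scale Named location/scale used to map the three
#'   auxiliary latents onto their integer total-score ranges.
#' @param seed Integer seed; generation is a pure function of
#'   (config, seed).
#'
#' @return An object of class `cohort_config` (a named list, validated).
#' @seealso [generate_multi_study()], [paper_like_config()]
#' @export
cohort_config <- function(n_studies_train = 3L,
                          n_studies_test = 3L,
                          n_per_study = c(575L, 575L, 575L, 300L, 300L, 300L),
                          latent_loadings = default_latent_loadings(),
                          residual_network = default_residual_network(),
                          study_mean_shift_sd = 0.15,
                          test_latent_shift = 0.20,
                          test_outcome_shift = 2.1,
                          outcome_coefficients = c(intercept = 13,
                                                   latent = 6.5,
                                                   social_support = -0.15,
                                                   life_events = 0.25,
                                                   alcohol = 0.10),
                          outcome_noise_sd = 9,
                          missing_rate = 0.008,
                          test_outcome_missing_rate = 0.19,
                          bdi_cutprobs = c(0.35, 0.65, 0.85),
                          anx_cutprobs = c(0.25, 0.50, 0.75, 0.92),
                          aux_location = c(social_support = 14,
                                           life_events = 4, alcohol = 5),
                          aux_scale = c(social_support = 3,
                                        life_events = 2.5, alcohol = 3),
                          seed = 1L) {
  cfg <- list(
    n_studies_train = as.integer(n_studies_train),
    n_studies_test = as.integer(n_studies_test),
    n_per_study = as.integer(n_per_study),
    latent_loadings = latent_loadings,
    residual_network = residual_network,
    study_mean_shift_sd = study_mean_shift_sd,
    test_latent_shift = test_latent_shift,
    test_outcome_shift = test_outcome_shift,
    outcome_coefficients = outcome_coefficients,
    outcome_noise_sd = outcome_noise_sd,
    missing_rate = missing_rate,
    test_outcome_missing_rate = test_outcome_missing_rate,
    bdi_cutprobs = bdi_cutprobs,
    anx_cutprobs = anx_cutprobs,
    aux_location = aux_location,
    aux_scale = aux_scale,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @param ... Overrides passed on to [cohort_config()].
#' @export
paper_like_config <- function(...) cohort_config(...)

# Fixed plausible loadings: strongest for core depressive items, moderate
# for anxiety subscales, negative for social support.
default_latent_loadings <- function() {
  bdi <- rep(c(0.70, 0.55, 0.62, 0.48, 0.66, 0.58, 0.52), 3L)
  anx <- c(0.55, 0.50, 0.35, 0.38, 0.42, 0.45, 0.48, 0.40)
  aux <- c(-0.35, 0.30, 0.15)
  stats::setNames(c(bdi, anx, aux), baseline_labels())
}

# Sparse residual partial correlations among a few within-instrument pairs.
default_residual_network <- function() {
  labs <- baseline_labels()
  p <- length(labs)
  M <- matrix(0, p, p, dimnames = list(labs, labs))
  pairs <- rbind(
    c("bdi_02", "bdi_03"), c("bdi_04", "bdi_11"), c("bdi_10", "bdi_16"),
    c("bdi_15", "bdi_20"), c("bdi_01", "bdi_13"),
    c("anx_ga", "anx_worry"), c("anx_comp", "anx_obs")
  )
  for (i in seq_len(nrow(pairs))) {
    M[pairs[i, 1], pairs[i, 2]] <- M[pairs[i, 2], pairs[i, 1]] <- 0.15
  }
  M
}

validate_cohort_config <- function(cfg) {
  labs <- baseline_labels()
  fail <- function(field, why) {
    stop(sprintf("invalid cohort_config field '%s': %s", field, why),
         call. = FALSE)
  }
  if (cfg$n_studies_train < 0L || cfg$n_studies_test < 0L ||
      cfg$n_studies_train + cfg$n_studies_test < 1L) {
    fail("n_studies_train/n_studies_test", "need at least one study")
  }
  if (any(cfg$n_per_study < 1L)) fail("n_per_study", "all sizes must be >= 1")
  ll <- cfg$latent_loadings
  if (is.null(names(ll)) || !all(labs %in% names(ll))) {
    fail("latent_loadings", "must be named and cover all 32 baseline variables")
  }
  if (any(abs(ll) >= 1)) fail("latent_loadings", "absolute loadings must be < 1")
  R <- cfg$residual_network
  if (!is.matrix(R) || nrow(R) != length(labs) || ncol(R) != length(labs)) {
    fail("residual_network", "must be a 32 x 32 matrix")
  }
  if (max(abs(R - t(R))) > 1e-10) fail("residual_network", "must be symmetric")
  if (any(diag(R) != 0)) fail("residual_network", "diagonal must be zero")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 0.30) {
    fail("missing_rate", "must lie in [0, 0.30)")
  }
  if (cfg$test_outcome_missing_rate < 0 || cfg$test_outcome_missing_rate >= 1) {
    fail("test_outcome_missing_rate", "must lie in [0, 1)")
  }
  if (cfg$outcome_noise_sd < 0) fail("outcome_noise_sd", "must be >= 0")
  oc <- cfg$outcome_coefficients
  need <- c("intercept", "latent", "social_support", "life_events", "alcohol")
  if (is.null(names(oc)) || !all(need %in% names(oc))) {
    fail("outcome_coefficients",
         paste("must be named with", paste(need, collapse = ", ")))
  }
  invisible(cfg)
}

# Residual covariance implied by the residual partial-correlation matrix and
# the loadings: precision Omega = I - P, residual correlations cov2cor of
# its inverse, scaled to variances 1 - loading^2 so each latent Gaussian has
# unit total variance.
residual_covariance <- function(cfg) {
  labs <- baseline_labels()
  Omega <- diag(length(labs)) - cfg$residual_network[labs, labs]
  ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    stop("invalid cohort_config field 'residual_network': implied precision ",
         "matrix is not positive definite", call. = FALSE)
  }
  Re <- stats::cov2cor(solve(Omega))
  d <- sqrt(1 - cfg$latent_loadings[labs]^2)
  diag(d) %*% Re %*% diag(d)
}

#' Generate a multi-study synthetic cohort
#'
#' Items are generated by thresholding latent Gaussian variables whose
#' covariance combines a single severity factor with a residual
#' partial-correlation network; the follow-up total is a linear function of
#' true latent severity and the auxiliary totals plus Gaussian noise,
#' rounded and clipped to 0-63. Identical config yields byte-identical
#' output.
#'
#' @param config A [cohort_config()].
#' @return An object of class `study_set`: a list with elements `train` and
#'   `test`, each a list of per-study data frames (columns `study_id`,
#'   `patient_id`, the 32 baseline variables, `outcome_bdi`, `remission`).
#' @export
generate_multi_study <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  labs <- baseline_labels()
  K <- config$n_studies_train + config$n_studies_test
  sizes <- rep_len(config$n_per_study, K)
  Sigma_e <- residual_covariance(config)
  Le <- chol(Sigma_e)
  lam <- config$latent_loadings[labs]
  oc <- config$outcome_coefficients

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  shifts <- stats::rnorm(K, 0, config$study_mean_shift_sd)
  tables <- vector("list", K)
  for (k in seq_len(K)) {
    n <- sizes[k]
    is_test <- k > config$n_studies_train
    sid <- if (is_test) {
      sprintf("test_%02d", k - config$n_studies_train)
    } else {
      sprintf("train_%02d", k)
    }
    eta <- stats::rnorm(n) + shifts[k] +
      if (is_test) config$test_latent_shift else 0
    E <- matrix(stats::rnorm(n * length(labs)), n) %*% Le
    Xstar <- outer(eta, lam) + E
    colnames(Xstar) <- labs

    df <- data.frame(study_id = rep(sid, n),
                     patient_id = sprintf("%s_p%04d", sid, seq_len(n)),
                     stringsAsFactors = FALSE)
    bdi_cuts <- stats::qnorm(config$bdi_cutprobs)
    anx_cuts <- stats::qnorm(config$anx_cutprobs)
    for (v in bdi_item_labels()) {
      df[[v]] <- threshold_latent(Xstar[, v], bdi_cuts)
    }
    for (v in anx_subscale_labels()) {
      df[[v]] <- threshold_latent(Xstar[, v], anx_cuts)
    }
    rng <- variable_ranges()
    for (v in aux_total_labels()) {
      val <- round(config$aux_location[[v]] + config$aux_scale[[v]] * Xstar[, v])
      df[[v]] <- as.integer(pmin(pmax(val, rng$lower[[v]]), rng$upper[[v]]))
    }

    lin <- oc[["intercept"]] + oc[["latent"]] * eta +
      oc[["social_support"]] * df$social_support +
      oc[["life_events"]] * df$life_events +
      oc[["alcohol"]] * df$alcohol +
      if (is_test) config$test_outcome_shift else 0
    y <- lin + stats::rnorm(n, 0, config$outcome_noise_sd)
    y <- as.integer(pmin(pmax(round(y), 0L), 63L))
    if (is_test && config$test_outcome_missing_rate > 0) {
      y[stats::runif(n) < config$test_outcome_missing_rate] <- NA_integer_
    }
    df$outcome_bdi <- y
    df$remission <- as.integer(y <= REMISSION_CUTOFF)
    tables[[k]] <- df
  }

  out <- structure(
    list(train = tables[seq_len(config$n_studies_train)],
         test = if (config$n_studies_test > 0)
           tables[config$n_studies_train + seq_len(config$n_studies_test)]
         else list()),
    config = config,
    class = "study_set"
  )
  if (config$missing_rate > 0) {
    out <- inject_missingness(out, config$missing_rate,
                              scope = "baseline_only",
                              seed = derive_seed(config$seed, "missing"))
  }
  out
}

threshold_latent <- function(x, cuts) {
  as.integer(findInterval(x, cuts))
}

# Save/restore of the global RNG state so generation is side-effect free.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Inject missing-completely-at-random cells
#'
#' Each eligible cell is independently set missing with probability
#' `missing_rate`. Under scope `"baseline_only"` only the 32 baseline
#' columns are eligible (in every study); under
#' `"baseline_and_training_outcome"` the follow-up outcome of *training*
#' studies is eligible too. Test-study outcomes are never masked.
#'
#' @param x A `study_set` (see [generate_multi_study()]).
#' @param missing_rate Probability in `[0, 1)` for each eligible cell.
#' @param scope `"baseline_only"` or `"baseline_and_training_outcome"`.
#' @param seed Integer seed.
#' @return The `study_set` with masked cells.
#' @export
inject_missingness <- function(x, missing_rate,
                               scope = c("baseline_only",
                                         "baseline_and_training_outcome"),
                               seed = 1L) {
  scope <- match.arg(scope)
  stopifnot(inherits(x, "study_set"), missing_rate >= 0, missing_rate < 1)
  if (missing_rate == 0) return(x)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  mask_cols <- function(df, cols) {
    for (v in cols) {
      hit <- stats::runif(nrow(df)) < missing_rate
      df[[v]][hit] <- NA_integer_
    }
    df
  }
  labs <- baseline_labels()
  x$train <- lapply(x$train, function(df) {
    df <- mask_cols(df, labs)
    if (scope == "baseline_and_training_outcome") {
      df <- mask_cols(df, "outcome_bdi")
      df$remission <- as.integer(df$outcome_bdi <= REMISSION_CUTOFF)
    }
    df
  })
  x$test <- lapply(x$test, function(df) mask_cols(df, labs))
  x
}

#' @export
print.study_set <- function(x, ...) {
  ns <- function(l) vapply(l, nrow, integer(1))
  cat("Multi-study cohort:", length(x$train), "training and",
      length(x$test), "test studies\n")
  if (length(x$train)) {
    cat("  training n:", paste(ns(x$train), collapse = ", "),
        sprintf("(total %d)\n", sum(ns(x$train))))
  }
  if (length(x$test)) {
    nt <- ns(x$test)
    nout <- vapply(x$test, function(d) sum(!is.na(d$outcome_bdi)), integer(1))
    cat("  test n:    ", paste(nt, collapse = ", "),
        sprintf("(total %d, with outcome %d)\n", sum(nt), sum(nout)))
  }
  invisible(x)
}

#' Write / read a study set as CSV files with a JSON config sidecar
#'
#' One CSV per study (`train_01.csv`, ..., `test_01.csv`, ...) with the
#' fixed documented header (`study_id`, `patient_id`, the 32 baseline
#' variables, `outcome_bdi`, `remission`); missing cells are empty fields.
#' The generator configuration, when present, is stored as `config.json`.
#'
#' @param x A `study_set`.
#' @param dir Directory (created if absent).
#' @return `dir` (writer) or a `study_set` (reader), invisibly/visibly.
#' @export
write_study_set <- function(x, dir) {
  stopifnot(inherits(x, "study_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (role in c("train", "test")) {
    for (i in seq_along(x[[role]])) {
      utils::write.csv(x[[role]][[i]],
                       file.path(dir, sprintf("%s_%02d.csv", role, i)),
                       row.names = FALSE, na = "")
    }
  }
  cfg <- attr(x, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }
  invisible(dir)
}

#' @rdname write_study_set
#' @export
read_study_set <- function(dir) {
  read_role <- function(role) {
    files <- sort(list.files(dir, sprintf("^%s_[0-9]+\\.csv$", role),
                             full.names = TRUE))
    lapply(files, function(f) {
      df <- utils::read.csv(f, stringsAsFactors = FALSE,
                            colClasses = c(study_id = "character",
                                           patient_id = "character"))
      for (v in c(baseline_labels(), "outcome_bdi", "remission")) {
        df[[v]] <- as.integer(df[[v]])
      }
      df
    })
  }
  structure(list(train = read_role("train"), test = read_role("test")),
            class = "study_set")
}
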