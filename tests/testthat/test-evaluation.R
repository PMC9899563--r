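# Evaluation metrics, calibration bins, severity tables and prediction
# correlations.

test_that("continuous metrics follow the worked arithmetic", {
  perfect <- continuous_metrics(c(5, 10, 15), c(5, 10, 15))
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)

  m <- continuous_metrics(c(10, 20, 30), c(12, 18, 33))
  expect_equal(m$r_squared, 1 - 17 / 200)
  expect_equal(m$rmse, sqrt(17 / 3))
  expect_equal(m$mae, 7 / 3)

  const <- continuous_metrics(c(10, 20, 30), rep(15, 3))
  expect_equal(const$r_squared, 1 - 275 / 200)  # negative, as expected

  expect_warning(continuous_metrics(c(5, 5, 5), c(4, 5, 6)), "undefined")
})

test_that("binary metrics follow the rank formulation", {
  m <- binary_metrics(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(m$auc, 0.75)

  m2 <- binary_metrics(c(1, 0), c(0.8, 0.3))
  expect_equal(m2$brier, (0.04 + 0.09) / 2)

  # constant predictions: all ties, AUC 1/2
  expect_equal(binary_metrics(c(0, 1, 0, 1), rep(0.4, 4))$auc, 0.5)
  expect_warning(binary_metrics(c(1, 1), c(0.2, 0.9)), "single-class")
})

test_that("the rank AUC agrees with an independent ROC implementation", {
  set.seed(31)
  y <- stats::rbinom(200, 1, 0.4)
  p <- stats::plogis(stats::rnorm(200) + y)
  p <- round(p, 1)  # force ties
  ours <- binary_metrics(y, p)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("RMSE dominates MAE and the null model never beats the
           evaluation mean", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    y <- stats::rnorm(n, 20, 8)
    yhat <- y + stats::rnorm(n, 0, 3)
    m <- continuous_metrics(y, yhat)
    expect_gte(m$rmse, m$mae)
    # constant (null-like) prediction from a shifted training mean
    null_m <- continuous_metrics(y, rep(mean(y) + stats::rnorm(1, 0, 2), n))
    expect_lte(null_m$r_squared, 0)
  }
})

test_that("calibration bins partition the sorted predictions", {
  set.seed(51)
  pred <- stats::rnorm(120, 20, 5)
  obs <- pred + stats::rnorm(120)
  rem <- as.integer(obs <= 10)
  cb <- calibration_bins(obs, pred, rem, bin_size = 50)
  expect_equal(cb$n, c(50L, 50L, 20L))
  expect_identical(cb$partial, c(FALSE, FALSE, TRUE))
  expect_true(all(diff(cb$mean_predicted) > 0))
  expect_equal(sum(cb$n), 120L)

  # predicted == observed: per-bin means coincide
  cb2 <- calibration_bins(pred, pred, bin_size = 50)
  expect_equal(cb2$mean_predicted, cb2$mean_observed)

  # bin size 1 reproduces the sorted pairs
  cb3 <- calibration_bins(obs, pred, bin_size = 1)
  expect_equal(cb3$mean_predicted, sort(pred))
})

test_that("severity categories use the published boundaries and half-up
           rounding", {
  rem <- rep(0L, 6)
  tab <- severity_category_remission(c(13, 14, 28, 29, 13.4, 13.6), rem)
  expect_equal(tab$n, c(2L, 2L, 1L, 1L))  # 13, 13.4 -> minimal; 13.6, 14 -> mild
  expect_identical(tab$category, c("minimal", "mild", "moderate", "severe"))
  expect_identical(tab$lower, c(0L, 14L, 20L, 29L))
  expect_identical(tab$upper, c(13L, 19L, 28L, 63L))

  tab2 <- severity_category_remission(rep(5, 10), rep(c(1L, 0L), 5))
  expect_equal(tab2$remission_fraction[1], 0.5)
  expect_true(all(tab2$n[2:4] == 0))

  expect_warning(severity_category_remission(c(-3, 70), c(0L, 1L)),
                 "clamped")
})

test_that("prediction correlations are affine-invariant and flag
           constants", {
  set.seed(61)
  a <- stats::rnorm(50)
  M <- cbind(m1 = a, m2 = 2 * a + 3, m3 = -a, m9 = rep(5, 50))
  expect_warning(R <- prediction_correlations(M), "m9")
  expect_equal(R["m1", "m1"], 1)
  expect_equal(R["m1", "m2"], 1)
  expect_equal(R["m1", "m3"], -1)
  expect_true(is.na(R["m1", "m9"]))
  expect_equal(R, t(R))
})

test_that("internal cross-validation recovers a deterministic outcome and
           is seed-stable", {
  gs <- tiny_cohort(seed = 91, n_train = c(100, 100), n_test = NULL)
  tabs <- gs$train
  # overwrite the outcome with a (rounded) linear function of the sum scores
  for (i in seq_along(tabs)) {
    bdi <- rowSums(tabs[[i]][, bdi_item_labels()])
    y <- round(3 + 0.6 * bdi)
    tabs[[i]]$outcome_bdi <- as.integer(pmin(pmax(y, 0), 63))
    tabs[[i]]$remission <- as.integer(tabs[[i]]$outcome_bdi <= 10)
  }
  cv <- internal_cross_validation(tabs, model_ids = 6,
                                  outcomes = "continuous", folds = 5,
                                  seed = 2)
  expect_gt(cv$metrics$r_squared, 0.99)

  cv2 <- internal_cross_validation(tabs, model_ids = 6,
                                   outcomes = "continuous", folds = 5,
                                   seed = 2)
  expect_identical(cv$metrics, cv2$metrics)

  expect_error(internal_cross_validation(tabs, model_ids = 6, folds = 150),
               "fewer folds")
})

test_that("internal CV of a pure-noise outcome does not show spurious
           skill", {
  r2 <- numeric(11)
  for (s in 1:11) {
    gs <- generate_multi_study(cohort_config(
      n_per_study = 80, n_studies_train = 2, n_studies_test = 0,
      outcome_coefficients = c(intercept = 20, latent = 0,
                               social_support = 0, life_events = 0,
                               alcohol = 0),
      outcome_noise_sd = 8, missing_rate = 0, seed = 100 + s))
    cv <- internal_cross_validation(gs$train, model_ids = 6,
                                    outcomes = "continuous", folds = 5,
                                    seed = s)
    r2[s] <- cv$metrics$r_squared
  }
  expect_lte(stats::median(r2), 0)
})
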