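# The nine modelling approaches: estimators, limits and predictions.

test_that("the registry pins the model-id mapping", {
  reg <- model_registry()
  expect_identical(reg$model_id, 1:9)
  expect_identical(reg$weighting[1:4], c("EI1", "EI2", "PCPR", "CFA"))
  expect_identical(reg$estimator[c(5, 7)], c("ENR", "ENR"))
  expect_identical(reg$form[9], "null")
})

test_that("noise-free data are fit exactly by OLS", {
  x <- matrix(seq(-2, 2, length.out = 30), ncol = 1,
              dimnames = list(NULL, "x"))
  sc <- manual_score_set(x)
  fit <- fit_regression(sc, 2 + 3 * x[, 1], "gaussian")
  expect_equal(fit$intercept, 2, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["x"]), 3, tolerance = 1e-8)

  fit_const <- fit_regression(sc, rep(7, 30), "gaussian")
  expect_equal(fit_const$intercept, 7, tolerance = 1e-8)
  expect_equal(unname(fit_const$coefficients["x"]), 0, tolerance = 1e-8)
})

test_that("OLS coefficients match the normal-equations oracle", {
  set.seed(3)
  X <- cbind(a = stats::rnorm(5), b = stats::runif(5))
  y <- c(3, 1, 4, 1, 5)
  sc <- manual_score_set(X)
  fit <- fit_regression(sc, y, "gaussian")
  Xd <- cbind(1, X)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)[, 1]
  expect_equal(unname(c(fit$intercept, fit$coefficients)), unname(beta),
               tolerance = 1e-10)
})

test_that("elastic net limits: no penalty equals OLS, full shrinkage is
           the mean", {
  set.seed(9)
  n <- 300
  X <- cbind(a = stats::rnorm(n), b = stats::rnorm(n), c = stats::rnorm(n))
  y <- 1 + 2 * X[, 1] - X[, 2] + stats::rnorm(n, 0, 0.05)
  sc <- manual_score_set(X)
  enr <- fit_enr(sc, y, "gaussian", alpha_grid = 0.5,
                 lambda_grid = c(1, 0.1, 0.001, 0),
                 folds = 5, seed = 2, thresh = 1e-12)
  ols <- fit_regression(sc, y, "gaussian")
  expect_equal(enr$enr_lambda, 0)   # near-noise-free: CV picks lambda = 0
  expect_equal(coef(enr), coef(ols), tolerance = 1e-6)

  enr_big <- fit_enr(sc, y, "gaussian", alpha_grid = 1,
                     lambda_grid = c(1e6, 9e5), folds = 5, seed = 2)
  expect_true(all(enr_big$coefficients == 0))
  expect_equal(enr_big$intercept, mean(y), tolerance = 1e-8)
})

test_that("elastic net concentrates weight on true predictors", {
  set.seed(11)
  n <- 500
  X <- matrix(stats::rnorm(n * 32), n, 32,
              dimnames = list(NULL, paste0("p", 1:32)))
  y <- 2 * X[, 1] + 2 * X[, 2] + stats::rnorm(n)
  sc <- manual_score_set(X)
  fit <- fit_enr(sc, y, "gaussian", alpha_grid = c(0.5, 1), folds = 5,
                 seed = 4)
  mean_true <- mean(abs(fit$coefficients[1:2]))
  mean_null <- mean(abs(fit$coefficients[3:32]))
  expect_gt(mean_true, mean_null)
  # the stored regularisation path has non-increasing L1 norm in lambda
  o <- order(fit$path_lambda, decreasing = TRUE)
  expect_true(all(diff(fit$path_l1[o]) > -1e-8))
})

test_that("null models store the training constant", {
  fit <- fit_null(c(10, 20, 30), "gaussian")
  expect_equal(fit$train_constant, 20)
  expect_length(fit$coefficients, 0)
  fit_b <- fit_null(c(1, 0, 0, 1), "binomial")
  expect_equal(fit_b$train_constant, 0.5)
  sc <- manual_score_set(matrix(stats::rnorm(12), 6,
                                dimnames = list(NULL, c("a", "b"))))
  expect_equal(predict(fit, sc), rep(20, 6))
})

test_that("predictions follow the linear predictor and the inverse logit", {
  model <- structure(list(model_id = 6L, outcome = "continuous",
                          estimator = "regression", intercept = 1,
                          coefficients = c(a = 2, b = -1),
                          family = "gaussian"),
                     class = "fitted_prognostic_model")
  sc <- manual_score_set(cbind(a = c(1, 0), b = c(0, 3)))
  expect_equal(predict(model, sc), c(1 + 2, 1 - 3))

  logit <- model
  logit$family <- "binomial"
  logit$intercept <- 0
  logit$coefficients <- c(a = 0, b = 0)
  expect_equal(predict(logit, sc), c(0.5, 0.5))

  bad <- manual_score_set(cbind(z = c(1, 2)))
  expect_error(predict(model, bad), "labels")
})

test_that("logistic fits recover known odds structure", {
  set.seed(21)
  n <- 800
  x <- stats::rnorm(n)
  pr <- stats::plogis(-0.5 + 1.2 * x)
  y <- stats::rbinom(n, 1, pr)
  sc <- manual_score_set(cbind(x = x))
  fit <- fit_regression(sc, y, "binomial")
  expect_equal(fit$intercept, -0.5, tolerance = 0.25)
  expect_equal(unname(fit$coefficients["x"]), 1.2, tolerance = 0.25)
})

test_that("model predictions share a common severity signal", {
  # with a strong latent factor driving the outcome, the sum-score models
  # produce positively correlated predictions
  gs <- tiny_cohort(seed = 81, n_train = c(150, 150), n_test = 100)
  sc <- standardized_covariances(gs$train)
  net <- fgl(sc$S, sc$n, 0.05, 0.05)
  w_ei1 <- centrality_weights(net, "EI1")
  cfa <- fit_one_factor(gs$train)
  w_cfa <- loadings_to_weights(cfa)
  y <- unweighted_scores(gs$train)$meta$outcome_bdi
  m1 <- fit_regression(weighted_scores(gs$train, w_ei1), y, "gaussian")
  m4 <- fit_regression(weighted_scores(gs$train, w_cfa), y, "gaussian")
  m6 <- fit_regression(unweighted_scores(gs$train), y, "gaussian")
  p1 <- predict(m1, weighted_scores(gs$test, w_ei1))
  p4 <- predict(m4, weighted_scores(gs$test, w_cfa))
  p6 <- predict(m6, unweighted_scores(gs$test))
  expect_gt(stats::cor(p1, p4), 0)
  expect_gt(stats::cor(p1, p6), 0)
  expect_gt(stats::cor(p4, p6), 0)
})
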