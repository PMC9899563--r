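# Synthetic multi-study cohort generator.

test_that("noise-free degenerate config produces a constant outcome", {
  cfg <- cohort_config(
    n_per_study = c(30, 30), n_studies_train = 1, n_studies_test = 1,
    outcome_coefficients = c(intercept = 20, latent = 0,
                             social_support = 0, life_events = 0,
                             alcohol = 0),
    outcome_noise_sd = 0, test_outcome_shift = 0,
    test_outcome_missing_rate = 0, missing_rate = 0, seed = 3)
  gs <- generate_multi_study(cfg)
  all_y <- c(gs$train[[1]]$outcome_bdi, gs$test[[1]]$outcome_bdi)
  expect_true(all(all_y == 20L))
  expect_true(all(c(gs$train[[1]]$remission, gs$test[[1]]$remission) == 0L))
})

test_that("generation is a pure function of config and seed", {
  cfg7 <- cohort_config(n_per_study = c(40, 40, 30), n_studies_test = 1,
                        seed = 7)
  cfg8 <- cohort_config(n_per_study = c(40, 40, 30), n_studies_test = 1,
                        seed = 8)
  a <- generate_multi_study(cfg7)
  b <- generate_multi_study(cfg7)
  expect_identical(a, b)
  expect_false(identical(a$train[[1]], generate_multi_study(cfg8)$train[[1]]))
})

test_that("tables respect the schema invariants", {
  gs <- tiny_cohort(seed = 12)
  for (df in c(gs$train, gs$test)) {
    bdi_total <- rowSums(df[, bdi_item_labels()])
    expect_true(all(bdi_total >= 0 & bdi_total <= 63))
    expect_true(all(as.matrix(df[, bdi_item_labels()]) %in% 0:3))
    expect_true(all(as.matrix(df[, anx_subscale_labels()]) %in% 0:4))
    present <- !is.na(df$outcome_bdi)
    expect_true(all(df$outcome_bdi[present] >= 0 &
                      df$outcome_bdi[present] <= 63))
    expect_identical(df$remission[present],
                     as.integer(df$outcome_bdi[present] <= 10))
  }
})

test_that("remission flips between follow-up totals 10 and 11", {
  base <- list(n_per_study = 20, n_studies_train = 1, n_studies_test = 0,
               outcome_noise_sd = 0, missing_rate = 0, seed = 4)
  mk <- function(const) {
    cfg <- do.call(cohort_config, c(base, list(
      outcome_coefficients = c(intercept = const, latent = 0,
                               social_support = 0, life_events = 0,
                               alcohol = 0))))
    generate_multi_study(cfg)$train[[1]]
  }
  expect_true(all(mk(10)$remission == 1L))
  expect_true(all(mk(11)$remission == 0L))
})

test_that("inter-item correlations match the thresholded-Gaussian oracle", {
  lam <- stats::setNames(rep(0.7, 32), labs32)
  cfg <- cohort_config(n_studies_train = 1, n_studies_test = 0,
                       n_per_study = 5000, latent_loadings = lam,
                       residual_network = empty_network(),
                       study_mean_shift_sd = 0, missing_rate = 0, seed = 9)
  df <- generate_multi_study(cfg)$train[[1]]

  # Monte-Carlo oracle: correlation of two 0-3 items obtained by
  # thresholding bivariate normals with latent correlation 0.7 * 0.7
  set.seed(123)
  nmc <- 400000
  f <- stats::rnorm(nmc)
  cuts <- stats::qnorm(c(0.35, 0.65, 0.85))
  item <- function() findInterval(0.7 * f + sqrt(1 - 0.49) *
                                    stats::rnorm(nmc), cuts)
  oracle <- stats::cor(item(), item())

  pairs <- list(c("bdi_01", "bdi_02"), c("bdi_05", "bdi_17"),
                c("bdi_10", "anx_ga"))
  for (pr in pairs) {
    expect_lt(abs(stats::cor(df[[pr[1]]], df[[pr[2]]]) - oracle), 0.05)
  }
})

test_that("with an empty residual network, items are conditionally
           independent given the factor; a planted edge survives", {
  run <- function(net) {
    cfg <- cohort_config(n_studies_train = 1, n_studies_test = 0,
                         n_per_study = 6000, residual_network = net,
                         study_mean_shift_sd = 0, missing_rate = 0,
                         seed = 5)
    X <- scale(as.matrix(generate_multi_study(cfg)$train[[1]][, labs32]))
    f <- rowMeans(X)
    stats::cor(apply(X, 2, function(col) stats::resid(stats::lm(col ~ f))))
  }
  R0 <- run(empty_network())
  expect_lt(max(abs(R0[upper.tri(R0)])), 0.1)

  net <- empty_network()
  net["bdi_01", "bdi_02"] <- net["bdi_02", "bdi_01"] <- 0.3
  R1 <- run(net)
  expect_gt(R1["bdi_01", "bdi_02"], 0.15)
})

test_that("missingness injection has the right marginal rate and scope", {
  gs <- tiny_cohort(seed = 21, n_train = c(120, 120), n_test = c(80, 80))
  expect_identical(inject_missingness(gs, 0, seed = 1), gs)

  out <- inject_missingness(gs, 0.1, scope = "baseline_only", seed = 2)
  cells <- unlist(lapply(c(out$train, out$test),
                         function(d) is.na(as.matrix(d[, labs32]))))
  expect_gt(length(cells), 10000)
  expect_gt(mean(cells), 0.08)
  expect_lt(mean(cells), 0.12)
  # test outcomes never masked under baseline_only
  expect_false(anyNA(unlist(lapply(out$test, `[[`, "outcome_bdi"))))

  out2 <- inject_missingness(gs, 0.2, "baseline_and_training_outcome",
                             seed = 3)
  expect_true(anyNA(unlist(lapply(out2$train, `[[`, "outcome_bdi"))))
  expect_false(anyNA(unlist(lapply(out2$test, `[[`, "outcome_bdi"))))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(cohort_config(missing_rate = 0.31), "missing_rate")
  expect_error(cohort_config(n_per_study = 0), "n_per_study")
  expect_error(cohort_config(latent_loadings = stats::setNames(rep(1.2, 32),
                                                               labs32)),
               "latent_loadings")
  bad <- empty_network(); bad[1, 2] <- 0.5  # asymmetric
  expect_error(cohort_config(residual_network = bad), "residual_network")
})

test_that("CSV round trip preserves the study set", {
  gs <- generate_multi_study(cohort_config(
    n_per_study = c(25, 25, 20), n_studies_train = 2, n_studies_test = 1,
    missing_rate = 0.05, seed = 31))
  dir <- withr::local_tempdir()
  write_study_set(gs, dir)
  expect_true(file.exists(file.path(dir, "config.json")))
  back <- read_study_set(dir)
  for (role in c("train", "test")) {
    for (i in seq_along(gs[[role]])) {
      expect_equal(back[[role]][[i]], gs[[role]][[i]],
                   ignore_attr = "row.names")
    }
  }
})
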