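# Fused graphical LASSO estimation and penalty selection.

test_that("standardized covariances equal the hand-computed correlations", {
  # 4-row, 3-variable table; direct arithmetic oracle
  X <- cbind(a = c(1, 2, 3, 6), b = c(2, 1, 5, 4), c = c(0, 1, 1, 3))
  tab <- data.frame(study_id = "s1", X)
  res <- standardized_covariances(list(tab), vars = c("a", "b", "c"))
  manual <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  expect_equal(res$S[[1]]["a", "b"], manual(X[, 1], X[, 2]), tolerance = 1e-12)
  expect_equal(res$S[[1]]["a", "c"], manual(X[, 1], X[, 3]), tolerance = 1e-12)
  expect_equal(res$n, 4L)

  # perfectly correlated pair
  tab2 <- data.frame(study_id = "s1", a = 1:5, b = 2 * (1:5), c = c(1, 3, 2, 5, 4))
  res2 <- standardized_covariances(list(tab2), vars = c("a", "b", "c"))
  expect_equal(res2$S[[1]]["a", "b"], 1.0)

  # zero variance names the variable and the study
  tab3 <- data.frame(study_id = "sX", a = 1:5, b = rep(2, 5))
  expect_error(standardized_covariances(list(tab3), vars = c("a", "b")),
               "b.*sX")
})

test_that("unpenalised single-group limit recovers the inverse correlation", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  fit <- fgl(list(S), n = 10, lambda1 = 0, lambda2 = 0)
  expect_equal(unname(fit$Theta[[1]]), solve(S), tolerance = 1e-3)
  expect_equal(fit$W[1, 2], 0.5, tolerance = 1e-3)
})

test_that("full shrinkage and full fusion limits behave as advertised", {
  S1 <- random_correlation(4, seed = 11)
  S2 <- random_correlation(4, seed = 12)
  # lambda1 huge: empty network
  f_sparse <- fgl(list(S1, S2), n = c(40, 50), lambda1 = 1e3, lambda2 = 0)
  expect_true(all(f_sparse$W == 0))
  off <- f_sparse$Theta[[1]]; diag(off) <- 0
  expect_true(all(off == 0))
  # lambda2 huge: the per-study precisions agree
  f_fused <- fgl(list(S1, S2), n = c(40, 50), lambda1 = 0.01, lambda2 = 1e3)
  expect_lt(max(abs(f_fused$Theta[[1]] - f_fused$Theta[[2]])), 1e-3)
})

test_that("with no fusion penalty the joint fit separates into group fits", {
  S1 <- random_correlation(3, seed = 21)
  S2 <- random_correlation(3, seed = 22)
  joint <- fgl(list(S1, S2), n = c(30, 45), lambda1 = 0.2, lambda2 = 0,
               tol = 1e-7)
  solo1 <- fgl(list(S1), n = 30, lambda1 = 0.2, tol = 1e-7)
  solo2 <- fgl(list(S2), n = 45, lambda1 = 0.2, tol = 1e-7)
  expect_equal(joint$Theta[[1]], solo1$Theta[[1]], tolerance = 1e-4)
  expect_equal(joint$Theta[[2]], solo2$Theta[[1]], tolerance = 1e-4)
})

test_that("ADMM solution matches a generic numerical minimizer", {
  cases <- list(
    list(S = list(random_correlation(3, 1)), n = 20, l1 = 0.1, l2 = 0),
    list(S = list(random_correlation(2, 2), random_correlation(2, 3)),
         n = c(15, 20), l1 = 0.1, l2 = 0.1),
    list(S = list(random_correlation(3, 4), random_correlation(3, 5)),
         n = c(15, 20), l1 = 0.1, l2 = 0.1)
  )
  for (cs in cases) {
    fit <- fgl(cs$S, cs$n, cs$l1, cs$l2, tol = 1e-7)
    oracle <- fgl_oracle_objective(cs$S, cs$n, cs$l1, cs$l2)
    expect_lt(abs(fit$objective - oracle), 1e-4)
    # improvement over the diagonal start, and positive definiteness
    init <- lapply(cs$S, function(s) diag(1 / diag(s)))
    expect_lte(fit$objective,
               fgl_objective(init, cs$S, cs$n, cs$l1, cs$l2) + 1e-8)
    for (Th in fit$Theta) {
      expect_gt(min(eigen(Th, symmetric = TRUE, only.values = TRUE)$values),
                0)
    }
  }
})

test_that("fused edges are the mean of per-study partial correlations", {
  S1 <- random_correlation(3, seed = 31)
  S2 <- random_correlation(3, seed = 32)
  fit <- fgl(list(S1, S2), n = c(60, 60), lambda1 = 0.05, lambda2 = 0.05)
  pc <- function(Th) {
    d <- sqrt(diag(Th)); P <- -Th / outer(d, d); diag(P) <- 0; P
  }
  expect_equal(fit$W, (pc(fit$Theta[[1]]) + pc(fit$Theta[[2]])) / 2,
               tolerance = 1e-10)
  expect_true(all(abs(fit$W) < 1))
  expect_true(all(diag(fit$W) == 0))
})

test_that("penalty selection prefers a weak penalty under a dense truth", {
  # data generated from a dense precision matrix: heavy shrinkage underfits
  set.seed(77)
  p <- 6
  A <- matrix(stats::rnorm(p * p, 0, 0.3), p)
  Omega <- crossprod(A) + diag(p)
  Sigma <- solve(Omega)
  L <- chol(Sigma)
  mk <- function(n, sid) {
    X <- matrix(stats::rnorm(n * p), n) %*% L
    colnames(X) <- paste0("v", 1:p)
    data.frame(study_id = sid, X)
  }
  tabs <- list(mk(150, "s1"), mk(150, "s2"))
  sel <- select_penalties(tabs, lambda1_grid = c(0.01, 10),
                          lambda2_grid = 0.01, folds = 5, seed = 1,
                          vars = paste0("v", 1:p))
  expect_equal(sel$lambda1, 0.01)

  # single-element grids return without searching
  one <- select_penalties(tabs, 0.3, 0.1, folds = 5, seed = 1,
                          vars = paste0("v", 1:p))
  expect_equal(one$lambda1, 0.3)
  expect_equal(one$lambda2, 0.1)

  # seed contract
  sel2 <- select_penalties(tabs, lambda1_grid = c(0.01, 10),
                           lambda2_grid = 0.01, folds = 5, seed = 1,
                           vars = paste0("v", 1:p))
  expect_identical(sel$cv_scores, sel2$cv_scores)
})

test_that("edge-list export matches the fused matrix", {
  S1 <- random_correlation(3, seed = 41)
  fit <- fgl(list(S1), n = 50, lambda1 = 0.05)
  el <- network_edge_list(fit)
  expect_identical(nrow(el), 3L)
  expect_equal(el$weight[el$node_i == "v1" & el$node_j == "v2"],
               fit$W["v1", "v2"])
})
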