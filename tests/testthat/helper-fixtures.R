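# Shared fixtures: small synthetic cohorts and hand-built score sets.

labs32 <- baseline_labels()

empty_network <- function() {
  matrix(0, 32, 32, dimnames = list(labs32, labs32))
}

# Small, fast cohort with no missingness (for tests that need complete
# data); n_train / n_test give per-study sizes and implicitly the counts.
tiny_cohort <- function(seed = 7, n_train = c(60, 60, 60),
                        n_test = c(40, 40, 40), ...) {
  generate_multi_study(cohort_config(
    n_studies_train = length(n_train), n_studies_test = length(n_test),
    n_per_study = c(n_train, n_test),
    missing_rate = 0, test_outcome_missing_rate = 0,
    seed = seed, ...))
}

# A score_set built directly from a predictor matrix (single study).
manual_score_set <- function(x, outcome = NULL, remission = NULL,
                             form = "unweighted_sums") {
  n <- nrow(x)
  meta <- data.frame(
    study_id = rep("s1", n),
    patient_id = sprintf("p%03d", seq_len(n)),
    outcome_bdi = if (is.null(outcome)) rep(NA_real_, n) else outcome,
    remission = if (is.null(remission)) rep(NA_real_, n) else remission,
    stringsAsFactors = FALSE)
  structure(list(model_form = form, predictor_labels = colnames(x),
                 x = x, meta = meta, weights_used = NULL),
            class = "score_set")
}

# A weight_vector with the rescaled column fixed directly (bypasses the
# block rescaling so arithmetic examples can use exact weights).
manual_weights <- function(rescaled, method = "EI1") {
  stopifnot(length(rescaled) == 32, !is.null(names(rescaled)))
  out <- data.frame(label = names(rescaled), method = method,
                    raw = unname(rescaled), rescaled = unname(rescaled),
                    stringsAsFactors = FALSE)
  class(out) <- c("weight_vector", "data.frame")
  out
}

# Generic numerical minimizer of the FGL objective over Cholesky-
# parameterised positive-definite matrices (multi-start Nelder-Mead);
# independent of the ADMM path.
fgl_oracle_objective <- function(S, n, lambda1, lambda2, restarts = 4) {
  p <- nrow(S[[1]]); K <- length(S); m <- p * (p + 1) / 2
  fn <- function(par) {
    Theta <- vector("list", K)
    for (k in seq_len(K)) {
      v <- par[((k - 1) * m + 1):(k * m)]
      L <- matrix(0, p, p)
      L[lower.tri(L, diag = TRUE)] <- v
      diag(L) <- exp(diag(L))
      Theta[[k]] <- L %*% t(L)
    }
    fgl_objective(Theta, S, n, lambda1, lambda2)
  }
  best <- Inf
  set.seed(99)
  for (r in seq_len(restarts)) {
    init <- unlist(lapply(seq_len(K), function(k) {
      Th <- solve(S[[k]]) + diag(p) * 0.01 * r
      L <- t(chol(Th)); diag(L) <- log(diag(L))
      L[lower.tri(L, diag = TRUE)]
    }))
    if (r > 1) init <- init + stats::rnorm(length(init), 0, 0.05 * r)
    o <- stats::optim(init, fn, method = "Nelder-Mead",
                      control = list(maxit = 2e5, reltol = 1e-15))
    o <- stats::optim(o$par, fn, method = "Nelder-Mead",
                      control = list(maxit = 2e5, reltol = 1e-15))
    best <- min(best, o$value)
  }
  best
}

random_correlation <- function(p, seed, n = 50) {
  set.seed(seed)
  stats::cor(matrix(stats::rnorm(n * p), n, p))
}
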