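# Fused graphical LASSO (FGL) over multiple studies, by ADMM.
#
# One sparse Gaussian graphical model is estimated per study while an L1
# fusion penalty shrinks corresponding precision entries toward equality
# across studies, yielding a single fused partial-correlation network that
# is robust to between-study heterogeneity.  The objective is
#
#   sum_k n_k [ -log det Theta_k + tr(S_k Theta_k) ]
#     + lambda1 * sum_k sum_{i != j} |theta_ij^(k)|
#     + lambda2 * sum_{k < k'} sum_{i,j} |theta_ij^(k) - theta_ij^(k')|
#
# The Z-update proximal operator factorises (fusion first, then elementwise
# soft-thresholding); the pairwise fusion prox is solved exactly for any K
# by isotonic regression of shifted order statistics.

#' Per-study standardized covariance (correlation) matrices
#'
#' Variables are standardized within study, so the per-study input to the
#' fused network is the sample correlation matrix.
#'
#' @param tables List of complete study data frames.
#' @param vars Variables to include (default: the 32 baseline variables).
#' @return List with `S` (list of correlation matrices) and `n` (integer
#'   vector of per-study sample sizes).
#' @export
standardized_covariances <- function(tables, vars = baseline_labels()) {
  stopifnot(length(tables) >= 1)
  S <- vector("list", length(tables))
  n <- integer(length(tables))
  for (k in seq_along(tables)) {
    X <- as.matrix(tables[[k]][, vars, drop = FALSE])
    if (nrow(X) < 2) stop("need at least 2 patients per study")
    if (anyNA(X)) stop("tables must be complete (impute first)")
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      bad <- vars[sds == 0][1]
      stop(sprintf("zero-variance variable '%s' in study '%s'",
                   bad, tables[[k]]$study_id[1]))
    }
    S[[k]] <- stats::cor(X)
    n[k] <- nrow(X)
  }
  list(S = S, n = n)
}

# Exact proximal operator of tau * sum_{k<k'} |z_k - z_k'| applied
# columnwise to a K x M matrix A: for each column, sort a, shift the i-th
# order statistic by tau*(K + 1 - 2i), take the isotonic (PAVA) fit, and
# undo the sort.  K = 3 is fully vectorised (the common case).
fusion_prox <- function(A, tau) {
  K <- nrow(A)
  if (K == 1L || tau == 0) return(A)
  if (K == 2L) {
    d <- A[1, ] - A[2, ]
    shift <- pmin(abs(d) / 2, tau) * sign(d)
    rbind(A[1, ] - shift, A[2, ] + shift)
  } else if (K == 3L) {
    a1 <- A[1, ]; a2 <- A[2, ]; a3 <- A[3, ]
    s1 <- pmin(a1, a2, a3)
    s3 <- pmax(a1, a2, a3)
    s2 <- a1 + a2 + a3 - s1 - s3
    b1 <- s1 + 2 * tau; b2 <- s2; b3 <- s3 - 2 * tau
    m12 <- (b1 + b2) / 2; m23 <- (b2 + b3) / 2; mall <- (b1 + b2 + b3) / 3
    z1 <- ifelse(b1 <= b2, ifelse(b2 <= b3, b1, ifelse(b1 <= m23, b1, mall)),
                 ifelse(m12 <= b3, m12, mall))
    z2 <- ifelse(b1 <= b2, ifelse(b2 <= b3, b2, ifelse(b1 <= m23, m23, mall)),
                 ifelse(m12 <= b3, m12, mall))
    z3 <- ifelse(b1 <= b2, ifelse(b2 <= b3, b3, ifelse(b1 <= m23, m23, mall)),
                 ifelse(m12 <= b3, b3, mall))
    # ranks with index tie-breaking (a permutation even under ties)
    r1 <- 1L + (a1 > a2) + (a1 > a3)
    r2 <- 1L + (a2 >= a1) + (a2 > a3)
    r3 <- 1L + (a3 >= a1) + (a3 >= a2)
    pick <- function(r) ifelse(r == 1L, z1, ifelse(r == 2L, z2, z3))
    rbind(pick(r1), pick(r2), pick(r3))
  } else {
    shifts <- tau * (K + 1 - 2 * seq_len(K))
    apply(A, 2, function(a) {
      o <- order(a)
      z <- stats::isoreg(a[o] + shifts)$yf
      z[order(o)]
    })
  }
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Objective value of the fused graphical LASSO
#'
#' @param Theta List of precision matrices (one per study).
#' @param S List of sample correlation matrices.
#' @param n Per-study sample sizes.
#' @param lambda1 Sparsity penalty (off-diagonal L1).
#' @param lambda2 Fusion penalty (across-study pairwise L1).
#' @return The penalised negative log-likelihood (a scalar).
#' @export
fgl_objective <- function(Theta, S, n, lambda1, lambda2) {
  K <- length(Theta)
  val <- 0
  for (k in seq_len(K)) {
    ld <- determinant(Theta[[k]], logarithm = TRUE)
    if (ld$sign <= 0) return(Inf)
    val <- val + n[k] * (-as.numeric(ld$modulus) +
                           sum(S[[k]] * Theta[[k]]))
    off <- Theta[[k]]; diag(off) <- 0
    val <- val + lambda1 * sum(abs(off))
  }
  if (K > 1) {
    for (k in seq_len(K - 1)) {
      for (kk in (k + 1):K) {
        val <- val + lambda2 * sum(abs(Theta[[k]] - Theta[[kk]]))
      }
    }
  }
  val
}

#' Fit the fused graphical LASSO
#'
#' ADMM solver for the jointly penalised multi-study Gaussian graphical
#' model (see the package vignette for the objective). Returns per-study
#' precision matrices and the fused edge matrix `W`: the across-study mean
#' of per-study partial correlations
#' \eqn{-\theta_{ij}^{(k)} / \sqrt{\theta_{ii}^{(k)}\theta_{jj}^{(k)}}}.
#'
#' @param S List of per-study correlation matrices (symmetric, unit
#'   diagonal), e.g. from [standardized_covariances()].
#' @param n Per-study sample sizes (log-likelihood weights).
#' @param lambda1 Sparsity penalty, >= 0.
#' @param lambda2 Fusion penalty, >= 0.
#' @param rho ADMM step parameter; `NULL` (default) sets it on the scale of
#'   the sample-size-weighted likelihood, `max(1, mean(n)/5)`.
#' @param tol Convergence tolerance on the max-norm primal and dual
#'   residuals.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residuals.
#' @param warm_start Optional previous `fgl` fit (or list with `Theta`,
#'   `U`) to start from.
#' @return An object of class `fgl` with elements `node_labels`, `Theta`
#'   (list of precision matrices), `W` (fused partial-correlation edges,
#'   zero diagonal), `lambda1`, `lambda2`, `sample_sizes`, `iterations`,
#'   `objective`, `converged`.
#' @export
fgl <- function(S, n, lambda1, lambda2 = 0, rho = NULL, tol = 1e-5,
                max_iter = 5000L, warm_start = NULL) {
  stopifnot(is.list(S), length(S) == length(n), lambda1 >= 0, lambda2 >= 0)
  # step parameter on the scale of the n_k-weighted likelihood term
  if (is.null(rho)) rho <- max(1, mean(n) / 5)
  K <- length(S)
  p <- nrow(S[[1]])
  labs <- colnames(S[[1]])
  if (is.null(labs)) labs <- paste0("v", seq_len(p))
  for (k in seq_len(K)) {
    if (max(abs(S[[k]] - t(S[[k]]))) > 1e-8) stop("S must be symmetric")
  }

  if (!is.null(warm_start)) {
    Theta <- warm_start$Theta
    U <- warm_start$U
    if (is.null(U)) U <- rep(list(matrix(0, p, p)), K)
    Z <- Theta
  } else {
    Theta <- lapply(S, function(s) diag(1 / pmax(diag(s), 1e-8)))
    Z <- Theta
    U <- rep(list(matrix(0, p, p)), K)
  }

  Amat <- matrix(0, K, p * p)
  converged <- FALSE
  r_norm <- s_norm <- NA_real_
  it <- 0L
  for (it in seq_len(max_iter)) {
    # Theta-update: eigen solve of the per-study smooth subproblem
    for (k in seq_len(K)) {
      c_k <- rho / n[k]
      B <- c_k * (Z[[k]] - U[[k]]) - S[[k]]
      B <- (B + t(B)) / 2
      e <- eigen(B, symmetric = TRUE)
      theta_eig <- (e$values + sqrt(e$values^2 + 4 * c_k)) / (2 * c_k)
      Theta[[k]] <- e$vectors %*% (theta_eig * t(e$vectors))
    }
    # Z-update: fusion prox then soft-thresholding of off-diagonals
    for (k in seq_len(K)) Amat[k, ] <- as.vector(Theta[[k]] + U[[k]])
    Zmat <- fusion_prox(Amat, lambda2 / rho)
    Z_old <- Z
    offdiag <- as.vector(diag(p) == 0)
    for (k in seq_len(K)) {
      zk <- Zmat[k, ]
      zk[offdiag] <- soft_threshold(zk[offdiag], lambda1 / rho)
      Zk <- matrix(zk, p, p)
      Z[[k]] <- (Zk + t(Zk)) / 2
    }
    # dual update and residuals
    r_norm <- 0; s_norm <- 0
    for (k in seq_len(K)) {
      U[[k]] <- U[[k]] + Theta[[k]] - Z[[k]]
      r_norm <- max(r_norm, max(abs(Theta[[k]] - Z[[k]])))
      s_norm <- max(s_norm, rho * max(abs(Z[[k]] - Z_old[[k]])))
    }
    if (r_norm < tol && s_norm < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf(paste0("fused graphical lasso did not converge in %d ",
                        "iterations (primal residual %.2e, dual residual ",
                        "%.2e)"), max_iter, r_norm, s_norm))
  }

  Theta_out <- lapply(Z, function(z) {
    dimnames(z) <- list(labs, labs)
    z
  })
  # positive-definiteness check on the sparse solution
  for (k in seq_len(K)) {
    ev <- eigen(Theta_out[[k]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      # fall back to the (PD by construction) Theta iterate
      Theta_out[[k]] <- Theta[[k]]
      dimnames(Theta_out[[k]]) <- list(labs, labs)
    }
  }
  W <- matrix(0, p, p, dimnames = list(labs, labs))
  for (k in seq_len(K)) {
    d <- sqrt(diag(Theta_out[[k]]))
    P <- -Theta_out[[k]] / outer(d, d)
    diag(P) <- 0
    W <- W + P / K
  }
  W <- (W + t(W)) / 2

  structure(list(node_labels = labs, Theta = Theta_out, W = W,
                 lambda1 = lambda1, lambda2 = lambda2, sample_sizes = n,
                 iterations = it,
                 objective = fgl_objective(Theta_out, S, n, lambda1, lambda2),
                 converged = converged, U = U),
            class = "fgl")
}

#' @export
print.fgl <- function(x, ...) {
  p <- length(x$node_labels)
  nz <- sum(abs(x$W[upper.tri(x$W)]) > 0)
  cat(sprintf(paste0("Fused graphical LASSO: %d studies, %d nodes\n",
                     "  lambda1 = %.4g, lambda2 = %.4g\n",
                     "  %d of %d possible fused edges non-zero\n",
                     "  converged in %d ADMM iterations ",
                     "(objective %.4f)\n"),
              length(x$Theta), p, x$lambda1, x$lambda2,
              nz, p * (p - 1) / 2, x$iterations, x$objective))
  invisible(x)
}

#' Select FGL penalties by stratified 10-fold cross-validation
#'
#' Patients are partitioned into folds stratified by study; for each
#' `(lambda1, lambda2)` pair the model is fitted on the fold-complement and
#' scored by the held-out Gaussian log-likelihood
#' \eqn{\sum_k [\log\det\Theta_k - tr(S_k^{holdout}\Theta_k)]}. The pair
#' maximising the mean held-out log-likelihood is returned. A pair that
#' fails to converge in any fold is scored `-Inf` with a warning.
#'
#' @param tables List of complete training-study data frames.
#' @param lambda1_grid,lambda2_grid Non-empty penalty grids.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed controlling the fold assignment.
#' @param vars Variables forming the network nodes.
#' @param rho,tol,max_iter ADMM options passed to [fgl()].
#' @return List with `lambda1`, `lambda2`, and `cv_scores` (a data frame of
#'   mean held-out log-likelihood per grid pair).
#' @export
select_penalties <- function(tables,
                             lambda1_grid = 10^seq(log10(0.01), 0,
                                                   length.out = 10),
                             lambda2_grid = c(0, 0.01, 0.05, 0.1, 0.5),
                             folds = 10L, seed = 1L,
                             vars = baseline_labels(),
                             rho = NULL, tol = 1e-5, max_iter = 5000L) {
  stopifnot(length(lambda1_grid) >= 1, length(lambda2_grid) >= 1, folds >= 2)
  if (length(lambda1_grid) == 1L && length(lambda2_grid) == 1L) {
    return(list(lambda1 = lambda1_grid, lambda2 = lambda2_grid,
                cv_scores = data.frame(lambda1 = lambda1_grid,
                                       lambda2 = lambda2_grid,
                                       score = NA_real_)))
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "folds"))
  fold_ids <- lapply(tables, function(d) {
    sample(rep_len(seq_len(folds), nrow(d)))
  })

  grid <- expand.grid(lambda1 = sort(lambda1_grid, decreasing = TRUE),
                      lambda2 = lambda2_grid)
  scores <- matrix(0, nrow(grid), folds)
  for (f in seq_len(folds)) {
    train_sub <- hold_sub <- vector("list", length(tables))
    for (k in seq_along(tables)) {
      hold <- fold_ids[[k]] == f
      train_sub[[k]] <- tables[[k]][!hold, , drop = FALSE]
      hold_sub[[k]] <- tables[[k]][hold, , drop = FALSE]
    }
    sc_train <- standardized_covariances(train_sub, vars)
    sc_hold <- standardized_covariances(hold_sub, vars)
    warm <- NULL
    last_l2 <- grid$lambda2[1]
    for (g in seq_len(nrow(grid))) {
      if (grid$lambda2[g] != last_l2) warm <- NULL  # restart per lambda2 block
      last_l2 <- grid$lambda2[g]
      fit <- tryCatch(
        fgl(sc_train$S, sc_train$n, grid$lambda1[g], grid$lambda2[g],
            rho = rho, tol = tol, max_iter = max_iter, warm_start = warm),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        warning(sprintf("lambda1 = %.4g, lambda2 = %.4g failed in fold %d: %s",
                        grid$lambda1[g], grid$lambda2[g], f,
                        conditionMessage(fit)))
        scores[g, f] <- -Inf
        warm <- NULL
        next
      }
      warm <- fit
      ll <- 0
      for (k in seq_along(tables)) {
        Th <- fit$Theta[[k]]
        ld <- determinant(Th, logarithm = TRUE)
        if (ld$sign <= 0) { ll <- -Inf; break }
        ll <- ll + as.numeric(ld$modulus) - sum(sc_hold$S[[k]] * Th)
      }
      scores[g, f] <- ll
    }
  }
  mean_scores <- rowMeans(scores)
  best <- which.max(mean_scores)
  list(lambda1 = grid$lambda1[best], lambda2 = grid$lambda2[best],
       cv_scores = data.frame(lambda1 = grid$lambda1,
                              lambda2 = grid$lambda2,
                              score = mean_scores))
}

#' Export a fused network
#'
#' `write_network_json()` serialises node labels, penalties and matrices;
#' `network_edge_list()` returns (and `write_edge_list_csv()` writes) the
#' fused edges as a `node_i, node_j, weight` table.
#'
#' @param fit An [fgl()] object.
#' @param path Output file path.
#' @return `path` invisibly, or the edge-list data frame.
#' @export
write_network_json <- function(fit, path) {
  stopifnot(inherits(fit, "fgl"))
  jsonlite::write_json(
    list(node_labels = fit$node_labels, lambda1 = fit$lambda1,
         lambda2 = fit$lambda2, sample_sizes = fit$sample_sizes,
         fused_edges = fit$W, precision_matrices = fit$Theta),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_network_json
#' @export
network_edge_list <- function(fit) {
  stopifnot(inherits(fit, "fgl"))
  idx <- which(upper.tri(fit$W), arr.ind = TRUE)
  data.frame(node_i = fit$node_labels[idx[, 1]],
             node_j = fit$node_labels[idx[, 2]],
             weight = fit$W[idx],
             stringsAsFactors = FALSE)
}

#' @rdname write_network_json
#' @export
write_edge_list_csv <- function(fit, path) {
  utils::write.csv(network_edge_list(fit), path, row.names = FALSE)
  invisible(path)
}
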