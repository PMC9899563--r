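# One-factor confirmatory factor analysis by maximum likelihood, and its
# conversion to [0, 1] coefficient weights.

#' Fit a one-factor model to a covariance/correlation matrix
#'
#' Minimises the maximum-likelihood discrepancy
#' \eqn{F_{ML} = \log|\Sigma(\theta)| + tr(S\Sigma(\theta)^{-1}) -
#' \log|S| - p} for \eqn{\Sigma(\theta) = \lambda\lambda' + \Psi}
#' (factor variance fixed to 1, \eqn{\Psi} diagonal), by quasi-Newton
#' optimisation with analytic gradients from a leading-eigenvector start.
#' Residual variances are bounded below at a small positive value; hitting
#' the bound raises a Heywood flag. The sign convention makes the majority
#' of loadings positive.
#'
#' @param S Sample covariance (typically correlation) matrix.
#' @param tol Optimiser convergence tolerance.
#' @return An object of class `cfa_fit`: `loadings` (standardized),
#'   `residual_variances`, `fit_value` (the minimised discrepancy),
#'   `converged`, `heywood`.
#' @export
cfa_fit_matrix <- function(S, tol = 1e-8) {
  p <- nrow(S)
  stopifnot(p >= 3, max(abs(S - t(S))) < 1e-8)
  labs <- colnames(S)
  if (is.null(labs)) labs <- paste0("v", seq_len(p))
  ldS <- as.numeric(determinant(S, logarithm = TRUE)$modulus)

  e <- eigen(S, symmetric = TRUE)
  lam0 <- e$vectors[, 1] * sqrt(max(e$values[1], 1e-4))
  psi0 <- pmax(diag(S) - lam0^2, 0.05)
  lb <- 1e-4

  fml <- function(par) {
    lam <- par[1:p]; psi <- par[(p + 1):(2 * p)]
    Sigma <- tcrossprod(lam) + diag(psi, p)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldSig <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    ldSig + sum(Sinv * S) - ldS - p
  }
  grad <- function(par) {
    lam <- par[1:p]; psi <- par[(p + 1):(2 * p)]
    Sigma <- tcrossprod(lam) + diag(psi, p)
    Sinv <- chol2inv(chol(Sigma))
    G <- Sinv %*% (Sigma - S) %*% Sinv
    c(2 * as.numeric(G %*% lam), diag(G))
  }
  opt <- stats::optim(c(lam0, psi0), fml, grad, method = "L-BFGS-B",
                      lower = c(rep(-Inf, p), rep(lb, p)),
                      control = list(maxit = 2000L, factr = tol / 1e-15))
  lam <- opt$par[1:p]
  psi <- opt$par[(p + 1):(2 * p)]
  if (sum(lam > 0) < p / 2) lam <- -lam
  # standardized loadings on the correlation metric of S
  std <- lam / sqrt(diag(S))
  names(std) <- names(lam) <- names(psi) <- labs
  if (opt$convergence != 0) {
    stop("one-factor model failed to converge: ", opt$message)
  }
  structure(list(loadings = std, unstandardized = lam,
                 residual_variances = psi, fit_value = opt$value,
                 converged = TRUE, heywood = any(psi <= lb * 1.0001)),
            class = "cfa_fit")
}

#' Fit a unidimensional factor model to pooled training data
#'
#' Training tables are standardized within study (absorbing between-study
#' mean and scale heterogeneity), pooled, and a one-factor model is fitted
#' to the pooled correlation matrix.
#'
#' @param tables List of complete training-study data frames.
#' @param vars Variables to include (default: all 32 baseline variables).
#' @return A `cfa_fit` (see [cfa_fit_matrix()]).
#' @export
fit_one_factor <- function(tables, vars = baseline_labels()) {
  stopifnot(length(vars) >= 3)
  Z <- do.call(rbind, lapply(tables, function(d) {
    scale(as.matrix(d[, vars, drop = FALSE]))
  }))
  if (anyNA(Z)) stop("tables must be complete (impute first)")
  cfa_fit_matrix(stats::cor(Z))
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf(paste0("One-factor ML solution: %d variables, discrepancy ",
                     "F = %.5f%s\n"), length(x$loadings), x$fit_value,
              if (x$heywood) " (Heywood case: variance clamped)" else ""))
  cat("  loadings:", paste(sprintf("%.2f", utils::head(x$loadings, 8)),
                           collapse = " "),
      if (length(x$loadings) > 8) "...\n" else "\n")
  invisible(x)
}

#' @export
coef.cfa_fit <- function(object, ...) object$loadings

#' Convert factor loadings to coefficient weights
#'
#' Min-max rescales the standardized loadings to `[0, 1]` within instrument
#' blocks (same convention as the centrality weights).
#'
#' @param fit A `cfa_fit` from [fit_one_factor()].
#' @return A [weight_vector()] with method `"CFA"`.
#' @export
loadings_to_weights <- function(fit) {
  stopifnot(inherits(fit, "cfa_fit"), isTRUE(fit$converged))
  weight_vector(fit$loadings, "CFA")
}
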