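# Network centrality statistics on the fused partial-correlation network,
# converted to per-variable coefficient weights on [0, 1].

#' Expected influence centralities
#'
#' One-step expected influence of node i is the signed sum of its edges,
#' \eqn{EI1_i = \sum_j w_{ij}}; two-step expected influence adds each
#' neighbour's one-step influence weighted by the connecting edge,
#' \eqn{EI2_i = EI1_i + \sum_j w_{ij} EI1_j} (back-edges included, matching
#' the standard implementation).
#'
#' @param W Symmetric edge-weight matrix with zero diagonal.
#' @return Named numeric vector of raw centralities.
#' @export
expected_influence_one_step <- function(W) {
  check_edge_matrix(W)
  rowSums(W)
}

#' @rdname expected_influence_one_step
#' @export
expected_influence_two_step <- function(W) {
  ei1 <- expected_influence_one_step(W)
  ei1 + as.numeric(W %*% ei1)
}

check_edge_matrix <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (max(abs(W - t(W))) > 1e-8) stop("W must be symmetric")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  invisible(W)
}

#' Walktrap community detection on absolute edge weights
#'
#' Communities of densely interconnected nodes found by short random walks
#' (Walktrap), run on the absolute edge weights; the merge sequence is cut
#' at maximum modularity. Deterministic for fixed input.
#'
#' @param W Symmetric edge-weight matrix, zero diagonal; absolute weights
#'   are used as random-walk affinities.
#' @param steps Random-walk length (default 4).
#' @return Integer membership vector (named by node).
#' @export
walktrap_communities <- function(W, steps = 4L) {
  check_edge_matrix(W)
  A <- abs(W)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  # isolated vertices break the random walk; give each its own community
  deg <- igraph::degree(g)
  memb <- integer(nrow(A))
  names(memb) <- rownames(A)
  if (any(deg > 0)) {
    sub <- igraph::induced_subgraph(g, which(deg > 0))
    wt <- igraph::cluster_walktrap(sub, steps = steps)
    memb[deg > 0] <- igraph::membership(wt)
  }
  if (any(deg == 0)) {
    memb[deg == 0] <- max(memb) + seq_len(sum(deg == 0))
  }
  memb
}

#' Participation coefficient, participation ratio and their geometric mean
#'
#' On absolute weights, with \eqn{\kappa_i} the strength of node i and
#' \eqn{\kappa_{ic}} its strength into community c:
#' \eqn{PC_i = 1 - \sum_c (\kappa_{ic}/\kappa_i)^2}; the participation
#' ratio is the effective number of connections (inverse Herfindahl index)
#' \eqn{PR_i = (\sum_j |w_{ij}|)^2 / \sum_j w_{ij}^2}. Nodes with zero
#' strength get PC = PR = 0.
#'
#' @param W Symmetric edge-weight matrix, zero diagonal.
#' @param membership Community membership covering all nodes (e.g. from
#'   [walktrap_communities()]).
#' @return List with numeric vectors `pc`, `pr`, `geometric_mean`.
#' @export
participation_metrics <- function(W, membership) {
  check_edge_matrix(W)
  p <- nrow(W)
  stopifnot(length(membership) == p)
  A <- abs(W)
  strength <- rowSums(A)
  pc <- pr <- numeric(p)
  for (i in seq_len(p)) {
    if (strength[i] == 0) next
    kappa_c <- tapply(A[i, ], membership, sum)
    pc[i] <- 1 - sum((kappa_c / strength[i])^2)
    pr[i] <- strength[i]^2 / sum(W[i, ]^2)
  }
  gm <- sqrt(pc * pr)
  names(pc) <- names(pr) <- names(gm) <- rownames(W)
  list(pc = pc, pr = pr, geometric_mean = gm)
}

#' Centrality-based coefficient weights from a fused network
#'
#' Computes the requested centrality statistic on the fused edge matrix and
#' min-max rescales it to `[0, 1]` within instrument blocks (BDI items,
#' anxiety subscales, auxiliary totals).
#'
#' @param fit An [fgl()] object (or a bare symmetric edge matrix).
#' @param method `"EI1"` (one-step expected influence), `"EI2"` (two-step),
#'   or `"PCPR"` (geometric mean of participation coefficient and
#'   participation ratio on the Walktrap partition).
#' @param steps Walktrap random-walk length (PCPR only).
#' @return A [weight_vector()].
#' @export
centrality_weights <- function(fit, method = c("EI1", "EI2", "PCPR"),
                               steps = 4L) {
  method <- match.arg(method)
  W <- if (inherits(fit, "fgl")) fit$W else fit
  raw <- switch(method,
    EI1 = expected_influence_one_step(W),
    EI2 = expected_influence_two_step(W),
    PCPR = {
      memb <- walktrap_communities(W, steps = steps)
      pm <- participation_metrics(W, memb)
      if (length(unique(memb)) == 1L) {
        # trivial partition: PC is identically zero and carries no
        # information, so the geometric mean degenerates to PR alone
        pm$pr
      } else {
        pm$geometric_mean
      }
    })
  names(raw) <- rownames(W)
  weight_vector(raw, method)
}
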