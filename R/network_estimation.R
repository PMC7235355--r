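#' Solve the graphical lasso at a single penalty
#'
#' Maximizes `log det(Theta) - tr(S Theta) - penalty * sum_{i != j} |Theta_ij|`
#' (diagonal unpenalized) by block coordinate descent over the columns of
#' the working covariance. Convergence is declared when the maximum KKT
#' residual falls below `tol`, so the returned precision matrix carries an
#' explicit optimality certificate.
#'
#' @param S symmetric correlation matrix with unit diagonal (or a
#'   `correlation_matrix` object).
#' @param penalty nonnegative L1 penalty; at 0 the solution is the plain
#'   inverse of `S` (which must then be positive definite).
#' @param tol KKT residual tolerance.
#' @param max_iter maximum outer cycles.
#' @return List with `Theta` (precision matrix), `kkt` (final residual),
#'   `iterations`, `converged`.
#' @export
glasso_solve <- function(S, penalty, tol = 1e-4, max_iter = 1000) {
  S <- as_cor_input(S)
  if (penalty < 0) stop("penalty must be nonnegative")
  fit <- glasso_path_cpp(S, penalty, tol, as.integer(max_iter))
  if (!fit$converged[1])
    stop(sprintf(
      "graphical lasso did not converge: KKT residual %.3g after %d cycles (penalty %.4g, p = %d)",
      fit$kkt[1], fit$iterations[1], penalty, ncol(S)))
  Theta <- fit$thetas[[1]]
  dimnames(Theta) <- dimnames(S)
  list(Theta = Theta, kkt = fit$kkt[1], iterations = fit$iterations[1],
       converged = TRUE)
}

#' Construct a log-spaced penalty path
#'
#' Descends from `lambda_max` — the smallest penalty at which the estimated
#' network is empty (the largest absolute off-diagonal of `S`, by the KKT
#' bound) — down to `lambda_max * min_ratio`.
#'
#' @param S correlation matrix or `correlation_matrix` object.
#' @param n_points number of penalties (>= 2).
#' @param min_ratio ratio of the smallest to the largest penalty, in (0, 1).
#' @return Numeric vector of strictly decreasing penalties.
#' @export
lambda_path <- function(S, n_points = 100, min_ratio = 0.01) {
  S <- as_cor_input(S)
  if (n_points < 2) stop("n_points must be at least 2")
  if (min_ratio <= 0 || min_ratio >= 1) stop("min_ratio must be in (0, 1)")
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax == 0) {
    warning("all off-diagonal correlations are zero; degenerate single-point path at 0")
    return(0)
  }
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_points))
}

#' Extended Bayesian information criterion for a precision matrix
#'
#' `EBIC = -n (log det Theta - tr(S Theta)) + E log(n) + 4 E gamma log(p)`,
#' where `E` counts nonzero upper-triangle off-diagonal entries. `gamma = 0`
#' reduces to the ordinary BIC; larger `gamma` (conventionally up to 0.5)
#' penalizes edges more aggressively, yielding simpler models.
#'
#' @param Theta positive definite precision matrix.
#' @param S the correlation matrix the model was fit to.
#' @param n sample size.
#' @param gamma EBIC hyperparameter.
#' @return The EBIC score (scalar; lower is better).
#' @export
ebic_score <- function(Theta, S, n, gamma) {
  S <- as_cor_input(S)
  ch <- tryCatch(chol(Theta), error = function(e) NULL)
  if (is.null(ch)) stop("Theta is not positive definite")
  logdet <- 2 * sum(log(diag(ch)))
  loglik_term <- logdet - sum(S * Theta)  # tr(S Theta) for symmetric inputs
  E <- sum(Theta[upper.tri(Theta)] != 0)
  p <- ncol(Theta)
  -n * loglik_term + E * log(n) + 4 * E * gamma * log(p)
}

#' Estimate a regularized partial-correlation network
#'
#' Fits the graphical lasso along a descending penalty path (warm-started)
#' and selects the penalty minimizing the EBIC at the given `gamma`. The
#' selected precision matrix is rescaled to edge weights
#' `W_ij = -Theta_ij / sqrt(Theta_ii Theta_jj)` — regularized partial
#' correlations — with zero diagonal. Passing `lambda` skips the path
#' search and fits that single penalty (for studies that fix the penalty a
#' priori).
#'
#' @param cm a `correlation_matrix`, or a plain correlation matrix (then
#'   `n` is required and community labels default to one community).
#' @param n sample size (taken from `cm` when available).
#' @param gamma EBIC hyperparameter, conventionally between 0 and 0.5; 0.25 is a
#'   common compromise between discovery and parsimony.
#' @param lambda optional fixed penalty (disables EBIC selection).
#' @param n_points,min_ratio path geometry, see [lambda_path()].
#' @param tol,max_iter solver controls, see [glasso_solve()].
#' @return A `network_model`: list with `items`, `communities`, `W` (edge
#'   weights), `Theta`, `lambda_path`, `ebic_values`, `selected_lambda`,
#'   `gamma`, `n`.
#' @export
estimate_network <- function(cm, n = NULL, gamma = 0.25, lambda = NULL,
                             n_points = 100, min_ratio = 0.01,
                             tol = 1e-4, max_iter = 1000) {
  S <- as_cor_input(cm)
  if (is.null(n)) {
    if (inherits(cm, "correlation_matrix")) n <- cm$n
    else stop("sample size n must be supplied for a plain matrix")
  }
  items <- colnames(S)
  if (is.null(items)) items <- sprintf("V%02d", seq_len(ncol(S)))
  communities <- if (inherits(cm, "correlation_matrix")) cm$communities
                 else rep("all", ncol(S))
  if (is.null(lambda)) {
    path <- lambda_path(S, n_points = n_points, min_ratio = min_ratio)
  } else {
    if (lambda < 0) stop("lambda must be nonnegative")
    path <- lambda
  }
  fit <- glasso_select_cpp(S, path, tol, as.integer(max_iter), n, gamma)
  if (!all(fit$converged))
    stop(sprintf("graphical lasso failed to converge at penalty %.4g (KKT %.3g)",
                 path[which(!fit$converged)[1]], fit$kkt[which(!fit$converged)[1]]))
  ebic <- fit$ebic
  sel <- fit$selected_index
  Theta <- fit$theta
  dimnames(Theta) <- list(items, items)
  W <- theta_to_pcor(Theta)
  structure(
    list(items = items, communities = setNames(communities, items),
         W = W, Theta = Theta,
         lambda_path = path, ebic_values = ebic,
         selected_lambda = path[sel], gamma = gamma, n = n,
         kkt = fit$kkt, solver_iterations = fit$iterations),
    class = "network_model"
  )
}

# Precision matrix -> signed partial-correlation edge weights, zero diagonal.
theta_to_pcor <- function(Theta) {
  d <- sqrt(diag(Theta))
  W <- -Theta / tcrossprod(d)
  diag(W) <- 0
  (W + t(W)) / 2
}

as_cor_input <- function(S) {
  if (inherits(S, "correlation_matrix")) S <- S$S
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-10)
    stop("S must be a symmetric square matrix")
  if (max(abs(diag(S) - 1)) > 1e-10)
    stop("S must have unit diagonal (a correlation matrix)")
  (S + t(S)) / 2
}

#' @export
print.network_model <- function(x, ...) {
  E <- sum(x$W[upper.tri(x$W)] != 0)
  cat(sprintf("Partial-correlation network: %d nodes, %d edges\n",
              length(x$items), E))
  cat(sprintf("Selected penalty %.4g (gamma = %g, n = %d); max |edge| = %.3f\n",
              x$selected_lambda, x$gamma, x$n, max(abs(x$W))))
  invisible(x)
}

#' Edge list of a network model
#'
#' @param model a `network_model`.
#' @param nonzero_only drop zero-weight pairs (default).
#' @return data.frame with `node_a`, `node_b`, `weight`.
#' @export
network_edges <- function(model, nonzero_only = TRUE) {
  W <- model$W
  idx <- which(upper.tri(W), arr.ind = TRUE)
  out <- data.frame(node_a = model$items[idx[, 1]],
                    node_b = model$items[idx[, 2]],
                    weight = W[idx],
                    stringsAsFactors = FALSE)
  if (nonzero_only) out <- out[out$weight != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a network model (edge list, adjacency, GraphML)
#'
#' GraphML carries the community as a vertex attribute and the signed
#' weight plus a `sign` edge attribute (+1 positive association, -1
#' negative), the information usually rendered as green/red edges.
#'
#' @param model a `network_model`.
#' @param edge_list_path,adjacency_path,graphml_path output paths (NULL to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(model, edge_list_path = NULL,
                          adjacency_path = NULL, graphml_path = NULL) {
  written <- character(0)
  if (!is.null(edge_list_path)) {
    write.csv(network_edges(model), edge_list_path, row.names = FALSE)
    written <- c(written, edge_list_path)
  }
  if (!is.null(adjacency_path)) {
    df <- data.frame(item_id = model$items, model$W, check.names = FALSE)
    write.csv(df, adjacency_path, row.names = FALSE)
    written <- c(written, adjacency_path)
  }
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_adjacency_matrix(model$W, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    igraph::V(g)$community <- unname(model$communities[model$items])
    igraph::E(g)$sign <- ifelse(igraph::E(g)$weight >= 0, 1L, -1L)
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  invisible(written)
}
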