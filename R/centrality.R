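#' Expected influence of each node
#'
#' One-step expected influence is the signed sum of a node's edge weights,
#' `EI1(i) = sum_j W_ij`; unlike strength it preserves the direction of
#' associations, which matters in networks mixing positively and negatively
#' related symptoms. Two-step expected influence adds each neighbor's own
#' one-step influence, weighted by the connecting edge:
#' `EI2(i) = EI1(i) + sum_j W_ij EI1(j)`.
#'
#' @param W symmetric edge-weight matrix with zero diagonal.
#' @param steps 1 or 2.
#' @return Named numeric vector of expected influences.
#' @export
expected_influence <- function(W, steps = 1) {
  W <- check_weight_matrix(W)
  ei1 <- rowSums(W)
  if (steps == 1) return(ei1)
  if (steps == 2) return(ei1 + as.vector(W %*% ei1))
  stop("steps must be 1 or 2")
}

#' Bridge expected influence across a community partition
#'
#' One-step bridge expected influence restricts the sum to edges crossing
#' the partition: `BEI1(i) = sum over j in other communities of W_ij` — the
#' strength and direction of a node's ties to the other symptom cluster.
#' The two-step version adds the secondary influence a node exerts through
#' its immediate neighbors' own bridge influence:
#' `BEI2(i) = BEI1(i) + sum_j W_ij BEI1(j)`.
#'
#' @param W symmetric edge-weight matrix with zero diagonal.
#' @param communities character/factor vector of community labels, one per
#'   node (at least two distinct labels; no missing labels).
#' @param steps 1 or 2.
#' @return Named numeric vector of bridge expected influences.
#' @export
bridge_expected_influence <- function(W, communities, steps = 1) {
  W <- check_weight_matrix(W)
  p <- ncol(W)
  if (length(communities) != p || any(is.na(communities)) ||
      any(!nzchar(as.character(communities))))
    stop("every node needs a non-missing community label")
  communities <- as.character(communities)
  if (length(unique(communities)) < 2)
    stop("bridge influence requires at least two communities")
  cross <- outer(communities, communities, FUN = "!=")
  bei1 <- rowSums(W * cross)
  names(bei1) <- colnames(W)
  if (steps == 1) return(bei1)
  if (steps == 2) return(bei1 + as.vector(W %*% bei1))
  stop("steps must be 1 or 2")
}

check_weight_matrix <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (max(abs(W - t(W))) > 1e-10) stop("W must be symmetric")
  if (max(abs(diag(W))) > 1e-10) stop("W must have zero diagonal")
  W
}

#' Z-score a vector of centrality values
#'
#' Standardizes to mean 0, sample standard deviation 1 (n - 1 denominator).
#' Z-scored centralities are the conventional reporting scale.
#'
#' @param values numeric vector, length >= 2, nonconstant.
#' @return The standardized vector.
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("zscore needs at least 2 values")
  s <- sd(values)
  if (!is.finite(s) || s == 0)
    stop("zero variance: z-scores undefined, report raw values instead")
  (values - mean(values)) / s
}

#' Centrality table for a network model
#'
#' Computes one- and two-step expected influence and bridge expected
#' influence for every node, raw and z-scored (z-scores taken within each
#' metric across all nodes).
#'
#' @param model a `network_model`, or an edge-weight matrix (then
#'   `communities` is required).
#' @param communities community labels when `model` is a plain matrix.
#' @return A data.frame of class `centrality_table` with columns `item_id`,
#'   `community`, `ei1`, `ei2`, `bridge_ei1`, `bridge_ei2` and `z_`-prefixed
#'   standardized versions.
#' @export
centrality_table <- function(model, communities = NULL) {
  if (inherits(model, "network_model")) {
    W <- model$W
    communities <- unname(model$communities[model$items])
    items <- model$items
  } else {
    W <- check_weight_matrix(model)
    if (is.null(communities)) stop("communities required for a plain matrix")
    items <- colnames(W)
    if (is.null(items)) items <- sprintf("V%02d", seq_len(ncol(W)))
  }
  out <- data.frame(
    item_id = items,
    community = as.character(communities),
    ei1 = unname(expected_influence(W, 1)),
    ei2 = unname(expected_influence(W, 2)),
    bridge_ei1 = unname(bridge_expected_influence(W, communities, 1)),
    bridge_ei2 = unname(bridge_expected_influence(W, communities, 2)),
    stringsAsFactors = FALSE
  )
  for (metric in c("ei1", "ei2", "bridge_ei1", "bridge_ei2")) {
    out[[paste0("z_", metric)]] <- tryCatch(zscore(out[[metric]]),
                                            error = function(e) rep(NA_real_, nrow(out)))
  }
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Top-k nodes by a centrality metric
#'
#' @param table a `centrality_table`.
#' @param metric one of `"ei1"`, `"ei2"`, `"bridge_ei1"`, `"bridge_ei2"`
#'   (or a `z_`-prefixed variant; ordering is identical).
#' @param k how many nodes to return (defaults to all).
#' @return Character vector of `item_id`s in descending metric order; ties
#'   broken lexicographically by `item_id`.
#' @export
rank_nodes <- function(table, metric = "ei1", k = nrow(table)) {
  if (!metric %in% names(table))
    stop("unknown metric: ", metric)
  ord <- order(-table[[metric]], table$item_id)
  table$item_id[ord][seq_len(min(k, nrow(table)))]
}

#' Write a centrality table to CSV
#'
#' @param table a `centrality_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centrality_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
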