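#' Estimator configuration for resampling
#'
#' Bundles every choice needed to re-estimate the network on a resampled
#' dataset: correlation method, EBIC gamma (or a fixed penalty), and path
#' and solver controls. Holding this fixed across replicates is what makes
#' bootstrap draws comparable.
#'
#' @param method correlation method, `"spearman"` or `"pearson"`.
#' @param gamma EBIC hyperparameter.
#' @param lambda optional fixed penalty (disables EBIC selection).
#' @param n_points,min_ratio,tol,max_iter see [estimate_network()].
#' @return A list of class `estimator_config`.
#' @export
estimator_config <- function(method = "spearman", gamma = 0.25, lambda = NULL,
                             n_points = 100, min_ratio = 0.01,
                             tol = 1e-4, max_iter = 1000) {
  structure(list(method = method, gamma = gamma, lambda = lambda,
                 n_points = n_points, min_ratio = min_ratio,
                 tol = tol, max_iter = max_iter),
            class = "estimator_config")
}

#' Fit the network estimator to an item response matrix
#'
#' @param m an `item_response_matrix` (already reverse-coded and reduced).
#' @param estimator an [estimator_config()].
#' @return A `network_model`.
#' @export
fit_network <- function(m, estimator = estimator_config()) {
  cm <- correlation_matrix(m, method = estimator$method)
  estimate_network(cm, gamma = estimator$gamma, lambda = estimator$lambda,
                   n_points = estimator$n_points,
                   min_ratio = estimator$min_ratio,
                   tol = estimator$tol, max_iter = estimator$max_iter)
}

# Deterministic stream of per-replicate seeds below 2^31, derived from the
# master seed; replicate order therefore never affects results.
derive_seeds <- function(seed, k) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

edge_names <- function(items) {
  idx <- which(upper.tri(diag(length(items))), arr.ind = TRUE)
  paste(items[idx[, 1]], items[idx[, 2]], sep = "|")
}

upper_tri_vec <- function(W) W[upper.tri(W)]

# Order-statistic percentile interval: endpoints are actual stored draws.
percentile_ci <- function(x, alpha) {
  x <- x[!is.na(x)]
  c(lower = unname(quantile(x, alpha / 2, type = 1)),
    upper = unname(quantile(x, 1 - alpha / 2, type = 1)))
}

#' Nonparametric bootstrap of edge weights (and centralities)
#'
#' Resamples respondents with replacement `B` times, re-runs the full
#' estimator on each resample, and collects every edge weight plus each
#' node's expected influence and bridge expected influence. Per-edge 95%
#' percentile confidence intervals summarize sampling variation: wide
#' intervals mean the corresponding edge should not be over-interpreted.
#'
#' Replicates in which estimation fails (e.g. a resample leaves an item
#' constant) are recorded, excluded and counted; more than 5% failures is
#' an error.
#'
#' @param m an `item_response_matrix` (reverse-coded, item set already
#'   reduced — item selection is not re-run inside replicates, so that
#'   statistic vectors stay comparable).
#' @param estimator an [estimator_config()].
#' @param B number of bootstrap replicates.
#' @param seed master seed; every replicate derives its own seed from it,
#'   so reruns are bit-identical and replicate order is irrelevant.
#' @param alpha interval level (default 0.05 for 95% CIs).
#' @return A `bootstrap_result`: point estimates, `edge_samples`
#'   (B x n_edges), `ei_samples`, `bridge_ei_samples`, `ci_lower`,
#'   `ci_upper`, failure count, `seed`.
#' @export
nonparametric_bootstrap <- function(m, estimator = estimator_config(),
                                    B = 1000, seed = 1, alpha = 0.05) {
  stopifnot(inherits(m, "item_response_matrix"))
  if (B < 2) stop("B must be at least 2")
  point <- fit_network(m, estimator)
  items <- point$items
  enames <- edge_names(items)
  communities <- unname(point$communities[items])
  seeds <- derive_seeds(seed, B)
  edge_samples <- matrix(NA_real_, B, length(enames),
                         dimnames = list(NULL, enames))
  ei_samples <- matrix(NA_real_, B, length(items), dimnames = list(NULL, items))
  bei_samples <- matrix(NA_real_, B, length(items), dimnames = list(NULL, items))
  failed <- 0L
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    idx <- sample.int(m$n, m$n, replace = TRUE)
    fit <- tryCatch(fit_network(subset_respondents(m, idx), estimator),
                    error = function(e) NULL)
    if (is.null(fit)) { failed <- failed + 1L; next }
    edge_samples[b, ] <- upper_tri_vec(fit$W)
    ei_samples[b, ] <- expected_influence(fit$W, 1)
    bei_samples[b, ] <- bridge_expected_influence(fit$W, communities, 1)
  }
  if (failed > 0.05 * B)
    stop(sprintf("bootstrap failed in %d of %d replicates (> 5%%)", failed, B))
  cis <- apply(edge_samples, 2, percentile_ci, alpha = alpha)
  structure(
    list(point = point, B = B, seed = seed, alpha = alpha,
         edge_samples = edge_samples,
         ei_samples = ei_samples,
         bridge_ei_samples = bei_samples,
         ci_lower = cis["lower", ], ci_upper = cis["upper", ],
         n_failed = failed),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Edge-weight bootstrap: B = %d (%d failed), seed %d\n",
              x$B, x$n_failed, x$seed))
  nz <- upper_tri_vec(x$point$W) != 0
  cat(sprintf("Mean 95%% CI width over the %d nonzero edges: %.3f\n",
              sum(nz), mean(x$ci_upper[nz] - x$ci_lower[nz])))
  invisible(x)
}

#' Case-dropping bootstrap for statistic stability
#'
#' For each drop level, repeatedly re-estimates the network on random
#' subsets containing `(1 - level)` of the respondents (drawn without
#' replacement) and correlates the subset's statistic vector with the
#' full-sample one. Stable statistics keep high correlations even when
#' large fractions of the sample are dropped; [cs_coefficient()] condenses
#' this into a single number.
#'
#' Levels whose retained subset would fall below `p / 2` respondents are
#' skipped with a warning. Replicates with an undefined correlation
#' (constant statistic vector) are excluded and counted.
#'
#' @param m an `item_response_matrix` (reduced item set held fixed).
#' @param estimator an [estimator_config()].
#' @param statistic one or more of `"EI"`, `"bridge_EI"`, `"edge"`. With
#'   several, the same re-estimated networks serve all of them (replicate
#'   seeds do not depend on the statistic set).
#' @param drop_levels fractions of the sample to drop.
#' @param B subsets per level.
#' @param seed master seed.
#' @param correlation_threshold,probability_level CS rule parameters, see
#'   [cs_coefficient()].
#' @return A `stability_result` (or a named list of them when several
#'   statistics are requested): per-level correlation samples,
#'   `cs_coefficient`, thresholds, skipped levels, exclusion counts.
#' @export
case_dropping_bootstrap <- function(m, estimator = estimator_config(),
                                    statistic = "EI",
                                    drop_levels = seq(0.1, 0.9, by = 0.1),
                                    B = 1000, seed = 1,
                                    correlation_threshold = 0.7,
                                    probability_level = 0.95) {
  stopifnot(inherits(m, "item_response_matrix"))
  statistic <- match.arg(statistic, c("EI", "bridge_EI", "edge"),
                         several.ok = TRUE)
  drop_levels <- sort(unique(drop_levels))
  if (any(drop_levels <= 0 | drop_levels >= 1))
    stop("drop levels must lie strictly between 0 and 1")
  full <- fit_network(m, estimator)
  communities <- unname(full$communities[full$items])
  stat_vec <- function(W) {
    out <- list()
    if ("EI" %in% statistic) out$EI <- expected_influence(W, 1)
    if ("bridge_EI" %in% statistic)
      out$bridge_EI <- bridge_expected_influence(W, communities, 1)
    if ("edge" %in% statistic) out$edge <- upper_tri_vec(W)
    out
  }
  full_stats <- stat_vec(full$W)
  keep <- vapply(drop_levels, function(lv) {
    ok <- round(m$n * (1 - lv)) >= m$p / 2
    if (!ok) warning(sprintf(
      "drop level %.2f skipped: %d retained respondents < p/2 = %.1f",
      lv, round(m$n * (1 - lv)), m$p / 2))
    ok
  }, TRUE)
  skipped <- drop_levels[!keep]
  levels_used <- drop_levels[keep]
  if (length(levels_used) == 0) stop("no feasible drop level")
  seed_mat <- matrix(derive_seeds(seed, length(levels_used) * B),
                     nrow = length(levels_used))
  cors <- lapply(statistic, function(s)
    matrix(NA_real_, length(levels_used), B,
           dimnames = list(sprintf("%.2f", levels_used), NULL)))
  names(cors) <- statistic
  n_excluded <- setNames(integer(length(statistic)), statistic)
  for (li in seq_along(levels_used)) {
    n_sub <- round(m$n * (1 - levels_used[li]))
    for (b in seq_len(B)) {
      set.seed(seed_mat[li, b])
      idx <- sample.int(m$n, n_sub, replace = FALSE)
      fit <- tryCatch(fit_network(subset_respondents(m, idx), estimator),
                      error = function(e) NULL)
      if (is.null(fit)) next
      sub_stats <- stat_vec(fit$W)
      for (s in statistic) {
        r <- suppressWarnings(cor(full_stats[[s]], sub_stats[[s]]))
        if (is.na(r)) n_excluded[s] <- n_excluded[s] + 1L
        cors[[s]][li, b] <- r
      }
    }
  }
  results <- lapply(statistic, function(s) {
    res <- structure(
      list(statistic = s, drop_levels = levels_used,
           correlations = cors[[s]],
           correlation_threshold = correlation_threshold,
           probability_level = probability_level,
           B = B, seed = seed, skipped_levels = skipped,
           n_excluded = n_excluded[[s]]),
      class = "stability_result")
    res$cs_coefficient <- cs_coefficient(res)
    res
  })
  names(results) <- statistic
  if (length(results) == 1L) results[[1]] else results
}

#' Correlation-stability (CS) coefficient
#'
#' The largest tested drop level at which the correlation between the
#' subset statistic and the full-sample statistic stays at or above
#' `correlation_threshold` (default 0.7) with probability at least
#' `probability_level` (default 0.95); 0 if no level qualifies. By the
#' usual guideline a CS below 0.25 means the statistic should not be
#' interpreted, and above 0.5 is preferable.
#'
#' Replicates without a usable correlation — the subset statistic was
#' constant (typically an empty re-estimated network) or re-estimation
#' failed — count against the probability: an empty subset network is
#' evidence of instability, not missing data.
#'
#' @param s a `stability_result`.
#' @param correlation_threshold,probability_level override the thresholds
#'   stored in `s`.
#' @return The CS coefficient (a drop fraction, or 0).
#' @export
cs_coefficient <- function(s, correlation_threshold = s$correlation_threshold,
                           probability_level = s$probability_level) {
  probs <- apply(s$correlations, 1, function(row)
    sum(row >= correlation_threshold, na.rm = TRUE) / length(row))
  ok <- which(probs >= probability_level)
  if (length(ok) == 0) return(0)
  max(s$drop_levels[ok])
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Case-dropping bootstrap for %s: B = %d per level, seed %d\n",
              x$statistic, x$B, x$seed))
  cat(sprintf("CS coefficient = %.2f (correlation >= %.2f with probability >= %.2f)\n",
              x$cs_coefficient, x$correlation_threshold, x$probability_level))
  invisible(x)
}

#' Bootstrapped difference test between two quantities
#'
#' Given paired bootstrap draws of two statistics (two edges, or two nodes'
#' centralities), forms the percentile interval of their difference;
#' the difference is significant when 0 falls outside the closed
#' `(alpha/2, 1 - alpha/2)` interval. At `alpha = 1` the interval collapses
#' to a zero-width interval at the median, so any pair whose bootstrap
#' median difference is nonzero is declared "significant" — a degenerate
#' boundary case kept for completeness.
#'
#' @param x a `bootstrap_result`, or a numeric vector of draws of the first
#'   quantity.
#' @param pair when `x` is a `bootstrap_result`: a length-2 character
#'   vector naming two columns of the chosen sample matrix (edges as
#'   `"A|B"`, nodes by `item_id`). When `x` is numeric: the paired draws of
#'   the second quantity.
#' @param what which samples to compare when `x` is a `bootstrap_result`.
#' @param alpha significance level.
#' @return A one-row data.frame of class `difference_test_result`:
#'   `a`, `b`, `estimate` (median difference), `ci_lower`, `ci_upper`,
#'   `significant`, `alpha`.
#' @export
difference_test <- function(x, pair, what = c("edge", "EI", "bridge_EI"),
                            alpha = 0.05) {
  if (inherits(x, "bootstrap_result")) {
    what <- match.arg(what)
    mat <- switch(what, edge = x$edge_samples, EI = x$ei_samples,
                  bridge_EI = x$bridge_ei_samples)
    if (!all(pair %in% colnames(mat)))
      stop("pair not found among ", what, " samples: ",
           paste(setdiff(pair, colnames(mat)), collapse = ", "))
    a <- mat[, pair[1]]; b <- mat[, pair[2]]
    labels <- pair
  } else {
    a <- x; b <- pair
    if (length(a) != length(b))
      stop("paired samples must have matching replicate counts")
    labels <- c("a", "b")
    what <- "samples"
  }
  ok <- !is.na(a) & !is.na(b)
  d <- a[ok] - b[ok]
  ci <- percentile_ci(d, alpha)
  out <- data.frame(a = labels[1], b = labels[2], what = what,
                    estimate = unname(stats::median(d)),
                    ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
                    significant = ci[["lower"]] > 0 | ci[["upper"]] < 0,
                    alpha = alpha, stringsAsFactors = FALSE)
  class(out) <- c("difference_test_result", "data.frame")
  out
}

#' All pairwise bootstrapped difference tests for a centrality
#'
#' @param x a `bootstrap_result`.
#' @param what `"EI"`, `"bridge_EI"` or `"edge"`.
#' @param alpha significance level.
#' @return A `difference_test_result` data.frame, one row per pair.
#' @export
difference_tests_all <- function(x, what = "EI", alpha = 0.05) {
  stopifnot(inherits(x, "bootstrap_result"))
  mat <- switch(what, edge = x$edge_samples, EI = x$ei_samples,
                bridge_EI = x$bridge_ei_samples,
                stop("unknown statistic: ", what))
  cols <- colnames(mat)
  pairs <- utils::combn(cols, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k)
    difference_test(x, pairs[, k], what = what, alpha = alpha))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write bootstrap edge samples and CIs in long CSV format
#'
#' @param x a `bootstrap_result`.
#' @param samples_path optional long-format CSV (replicate, edge, value).
#' @param ci_path optional per-edge CI CSV.
#' @return Invisibly, the paths written.
#' @export
write_bootstrap_csv <- function(x, samples_path = NULL, ci_path = NULL) {
  written <- character(0)
  if (!is.null(samples_path)) {
    long <- data.frame(
      replicate = rep(seq_len(x$B), times = ncol(x$edge_samples)),
      edge = rep(colnames(x$edge_samples), each = x$B),
      value = as.vector(x$edge_samples))
    write.csv(long, samples_path, row.names = FALSE)
    written <- c(written, samples_path)
  }
  if (!is.null(ci_path)) {
    ci <- data.frame(edge = colnames(x$edge_samples),
                     estimate = upper_tri_vec(x$point$W),
                     ci_lower = unname(x$ci_lower),
                     ci_upper = unname(x$ci_upper))
    write.csv(ci, ci_path, row.names = FALSE)
    written <- c(written, ci_path)
  }
  invisible(written)
}

#' Write case-dropping correlations in long CSV format
#'
#' @param s a `stability_result`.
#' @param path output CSV (level, replicate, correlation).
#' @return `path`, invisibly.
#' @export
write_stability_csv <- function(s, path) {
  long <- data.frame(
    statistic = s$statistic,
    level = rep(s$drop_levels, times = ncol(s$correlations)),
    replicate = rep(seq_len(ncol(s$correlations)), each = nrow(s$correlations)),
    correlation = as.vector(s$correlations))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
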