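#' Test the difference between two dependent overlapping correlations
#'
#' Tests H0: rho_AC == rho_BC when both correlations are computed on the
#' same sample and share variable C (so the two estimates are dependent).
#' Uses the back-transformed-average variant of the Fisher-z test for
#' dependent overlapping correlations: with `z1 = atanh(r_AC)`,
#' `z2 = atanh(r_BC)` and `rbar = tanh((z1 + z2)/2)`,
#'
#' \deqn{c = \frac{r_{AB}(1 - 2\bar r^2) - \tfrac12 \bar r^2 (1 - 2\bar r^2 - r_{AB}^2)}{(1-\bar r^2)^2}}
#' \deqn{Z = \frac{(z_1 - z_2)\sqrt{n-3}}{\sqrt{2 - 2c}}}
#'
#' and a two-sided p-value from the standard normal.
#'
#' All three correlation arguments are vectorized (recycled to a common
#' length), so one call can test one pair of items against every third item.
#'
#' @param r_ac,r_bc the two correlations being compared (each with C).
#' @param r_ab the correlation between the two compared items.
#' @param n sample size (must be at least 4).
#' @return A list with numeric vectors `z` and `p`.
#' @export
dependent_correlation_test <- function(r_ac, r_bc, r_ab, n) {
  k <- max(length(r_ac), length(r_bc), length(r_ab))
  r_ac <- rep_len(r_ac, k); r_bc <- rep_len(r_bc, k); r_ab <- rep_len(r_ab, k)
  if (n < 4) stop("dependent correlation test requires n >= 4")
  if (any(abs(c(r_ac, r_bc)) >= 1))
    stop("correlations must be strictly inside (-1, 1); Fisher transform degenerates at |r| = 1")
  z1 <- atanh(r_ac)
  z2 <- atanh(r_bc)
  rbar <- tanh((z1 + z2) / 2)
  rb2 <- rbar^2
  cterm <- (r_ab * (1 - 2 * rb2) - 0.5 * rb2 * (1 - 2 * rb2 - r_ab^2)) / (1 - rb2)^2
  # c approximates the correlation between the two Fisher z estimates; the
  # approximation can stray above 1 for extreme inputs, where the test
  # degenerates (perfectly dependent estimates). Clip so Z stays finite:
  # any real profile difference then yields |Z| -> large, p -> 0.
  cterm <- pmin(cterm, 1 - 1e-10)
  z <- (z1 - z2) * sqrt(n - 3) / sqrt(2 - 2 * cterm)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Screen all item pairs for redundancy ("bad pairs")
#'
#' Candidate pairs are those with high multicollinearity: absolute
#' zero-order correlation at least `min_correlation` (the profile-equality
#' test is only meaningful — and only asked — for items that could
#' plausibly measure the same construct; without this gate, small samples
#' flag almost every pair simply because the comparisons lack power). For
#' each candidate pair (A, B), A's and B's correlation profiles are
#' compared against every third item C with
#' [dependent_correlation_test()]. If fewer than `1 - share_threshold` of
#' those comparisons are significant at `p_threshold`, the two items'
#' profiles are statistically indistinguishable for the required share of
#' third items and the pair is flagged as redundant — two questionnaire
#' items measuring the same construct.
#'
#' @param cm a `correlation_matrix` (from [correlation_matrix()]), or a
#'   plain correlation matrix with dimnames.
#' @param n sample size; taken from `cm$n` when omitted.
#' @param p_threshold significance level for each profile comparison.
#' @param share_threshold minimum share of non-significantly-different
#'   correlations for a pair to count as redundant (default 0.75, i.e. the
#'   pair is "bad" when the fraction of significant differences is below
#'   0.25).
#' @param min_correlation candidate gate: only pairs with
#'   `|r| >= min_correlation` are screened (set to 0 to screen every
#'   pair).
#' @return A `redundancy_report`: list with `bad_pairs` (data.frame of
#'   `item_a`, `item_b`, `prop_significant`, sorted ascending),
#'   `all_pairs` (the same statistic for every candidate pair),
#'   thresholds, and `removed_items`/`retained_items` (filled by
#'   [reduce_nodes()]).
#' @export
find_bad_pairs <- function(cm, n = NULL, p_threshold = 0.05,
                           share_threshold = 0.75, min_correlation = 0.5) {
  S <- if (inherits(cm, "correlation_matrix")) cm$S else as.matrix(cm)
  if (is.null(n)) {
    if (inherits(cm, "correlation_matrix")) n <- cm$n
    else stop("sample size n must be supplied for a plain matrix")
  }
  p <- ncol(S)
  if (p < 3) stop("redundancy screening needs at least 3 items")
  items <- colnames(S)
  if (is.null(items)) items <- sprintf("V%02d", seq_len(p))
  pairs <- utils::combn(p, 2)
  cand <- abs(S[cbind(pairs[1, ], pairs[2, ])]) >= min_correlation
  pairs <- pairs[, cand, drop = FALSE]
  prop <- numeric(ncol(pairs))
  # exact +-1 profile correlations (literal duplicate columns) are nudged
  # inside the Fisher-transformable range; the resulting huge z difference
  # correctly reads as "profiles certainly differ at this third item"
  clamp <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    cc <- setdiff(seq_len(p), c(a, b))
    res <- dependent_correlation_test(clamp(S[a, cc]), clamp(S[b, cc]),
                                      S[a, b], n)
    prop[k] <- mean(res$p < p_threshold)
  }
  all_pairs <- data.frame(
    item_a = items[pairs[1, ]],
    item_b = items[pairs[2, ]],
    prop_significant = prop,
    stringsAsFactors = FALSE
  )
  bad <- all_pairs[all_pairs$prop_significant < (1 - share_threshold), , drop = FALSE]
  bad <- bad[order(bad$prop_significant, bad$item_a, bad$item_b), , drop = FALSE]
  rownames(bad) <- NULL
  structure(
    list(bad_pairs = bad,
         all_pairs = all_pairs,
         p_threshold = p_threshold,
         share_threshold = share_threshold,
         min_correlation = min_correlation,
         n = n,
         items = items,
         abs_cor_sums = setNames(colSums(abs(S)) - 1, items),
         removed_items = character(0),
         retained_items = items,
         removal_log = data.frame(step = integer(0), removed = character(0),
                                  n_bad_pairs = integer(0),
                                  reason = character(0),
                                  stringsAsFactors = FALSE)),
    class = "redundancy_report"
  )
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat(sprintf("Redundancy report: %d items, %d bad pair(s) at p < %g, share >= %g\n",
              length(x$items), nrow(x$bad_pairs), x$p_threshold, x$share_threshold))
  if (nrow(x$bad_pairs) > 0) print(head(x$bad_pairs, 10))
  if (length(x$removed_items) > 0)
    cat("Removed:", paste(x$removed_items, collapse = ", "), "\n")
  invisible(x)
}

#' Remove one member of each redundant pair
#'
#' Iteratively removes items until no flagged pair survives. At each step
#' the removed item is the one participating in the most remaining bad
#' pairs (a chain A-B, B-C therefore costs only B); ties are broken by
#' removing the member with the *lower* sum of absolute correlations with
#' all other items (keeping the more informative node), then by removing
#' the lexicographically later `item_id`. Every decision is logged in the
#' returned report.
#'
#' @param m the `item_response_matrix` the report was computed from.
#' @param report a `redundancy_report` from [find_bad_pairs()].
#' @param policy removal policy; only `"max_bad_pairs"` is implemented.
#' @return A list with the reduced `responses` and the updated `report`.
#' @export
reduce_nodes <- function(m, report, policy = "max_bad_pairs") {
  stopifnot(inherits(report, "redundancy_report"))
  policy <- match.arg(policy)
  pairs <- report$bad_pairs[, c("item_a", "item_b")]
  removed <- character(0)
  log <- list()
  step <- 0L
  while (nrow(pairs) > 0L) {
    step <- step + 1L
    involved <- c(pairs$item_a, pairs$item_b)
    counts <- table(involved)
    cand <- names(counts)[counts == max(counts)]
    reason <- "most bad pairs"
    if (length(cand) > 1L) {
      sums <- report$abs_cor_sums[cand]
      cand <- cand[sums == min(sums)]
      reason <- "tie: lowest |r| sum"
      if (length(cand) > 1L) {
        cand <- max(cand)  # remove the lexicographically later id
        reason <- "tie: lexicographic"
      }
    }
    victim <- cand[1]
    log[[step]] <- data.frame(step = step, removed = victim,
                              n_bad_pairs = as.integer(max(counts)),
                              reason = reason, stringsAsFactors = FALSE)
    removed <- c(removed, victim)
    pairs <- pairs[pairs$item_a != victim & pairs$item_b != victim, , drop = FALSE]
  }
  report$removed_items <- removed
  report$retained_items <- setdiff(report$items, removed)
  report$removal_log <- if (length(log)) do.call(rbind, log) else report$removal_log
  list(responses = drop_items(m, removed), report = report)
}

#' Run the full redundancy-reduction stage
#'
#' Convenience wrapper: correlation matrix, pair screening, then node
#' removal in one call.
#'
#' @inheritParams find_bad_pairs
#' @param m an `item_response_matrix`.
#' @param method correlation method passed to [correlation_matrix()].
#' @return As [reduce_nodes()].
#' @export
reduce_items <- function(m, method = "spearman", p_threshold = 0.05,
                         share_threshold = 0.75, min_correlation = 0.5) {
  cm <- correlation_matrix(m, method = method)
  report <- find_bad_pairs(cm, p_threshold = p_threshold,
                           share_threshold = share_threshold,
                           min_correlation = min_correlation)
  reduce_nodes(m, report)
}

#' Serialize a redundancy report to JSON
#'
#' @param report a `redundancy_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_redundancy_json <- function(report, path) {
  jsonlite::write_json(
    list(p_threshold = report$p_threshold,
         share_threshold = report$share_threshold,
         min_correlation = report$min_correlation,
         n = report$n,
         bad_pairs = report$bad_pairs,
         removed_items = report$removed_items,
         retained_items = report$retained_items,
         removal_log = report$removal_log),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
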