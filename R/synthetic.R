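#' Specification of a synthetic questionnaire study
#'
#' Describes a two-community ordinal dataset generated from a latent
#' Gaussian graphical model: item counts and Likert level counts per
#' community, within-community edge density, a number of planted
#' cross-community (bridge) edges, partial-correlation magnitudes,
#' optional near-duplicate (redundant) items, reverse-coded items, and
#' missing-completely-at-random cells.
#'
#' Defaults describe the package's reference recovery fixture: 20 + 20
#' items, n = 2000, edge magnitudes 0.2-0.4 — large enough that the
#' estimator's operating characteristics (sensitivity, specificity, sign
#' agreement) are meaningful to measure. See [study_like_spec()] for the
#' small-sample preset that mimics a two-questionnaire clinical study.
#'
#' @param p_community_a,p_community_b base item counts per community
#'   (before any redundant duplicates are appended).
#' @param likert_levels_a,likert_levels_b number of response categories per
#'   community (7 mimics a seven-point frequency scale scored 0-6, 4 a
#'   four-point agreement scale scored 1-4).
#' @param likert_min_a,likert_min_b lowest response value per community.
#' @param within_density probability that an within-community node pair
#'   receives an edge.
#' @param n_bridge_edges number of planted cross-community edges.
#' @param weight_range magnitude range for planted partial correlations.
#' @param prob_negative probability that a planted edge is negative.
#'   Symptom items are keyed so that higher = more symptoms, so most
#'   conditional associations are positive; negative edges are a minority.
#' @param n_redundant_pairs number of near-duplicate items to append.
#' @param redundancy_noise_sd latent noise added to a duplicated item
#'   (0 duplicates exactly).
#' @param n_reverse_coded number of items stored in reversed orientation
#'   (with the metadata flag set, so ingestion un-reverses them).
#' @param reverse_community community from which reverse-coded items are
#'   drawn (`NULL` = any).
#' @param missing_rate fraction of cells set missing completely at random.
#' @param threshold_skew skewness of discretization thresholds; 0 gives
#'   equal-probability categories, positive values pile mass on the lowest
#'   categories (floor effects typical of symptom inventories).
#' @param n respondent count.
#' @param seed master seed; all sub-draws derive from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(p_community_a = 20, p_community_b = 20,
                           likert_levels_a = 7, likert_levels_b = 4,
                           likert_min_a = 0, likert_min_b = 1,
                           within_density = 0.1, n_bridge_edges = 3,
                           weight_range = c(0.2, 0.4), prob_negative = 0.5,
                           n_redundant_pairs = 0, redundancy_noise_sd = 0.1,
                           n_reverse_coded = 0, reverse_community = NULL,
                           missing_rate = 0, threshold_skew = 0,
                           n = 2000, seed = 1) {
  spec <- list(p_community_a = p_community_a, p_community_b = p_community_b,
               likert_levels_a = likert_levels_a, likert_levels_b = likert_levels_b,
               likert_min_a = likert_min_a, likert_min_b = likert_min_b,
               within_density = within_density, n_bridge_edges = n_bridge_edges,
               weight_range = weight_range, prob_negative = prob_negative,
               n_redundant_pairs = n_redundant_pairs,
               redundancy_noise_sd = redundancy_noise_sd,
               n_reverse_coded = n_reverse_coded,
               reverse_community = reverse_community,
               missing_rate = missing_rate, threshold_skew = threshold_skew,
               n = n, seed = seed)
  stopifnot(spec$prob_negative >= 0, spec$prob_negative <= 1,
            spec$p_community_a >= 1, spec$p_community_b >= 1,
            spec$within_density >= 0, spec$within_density <= 1,
            spec$missing_rate >= 0, spec$missing_rate < 1,
            length(weight_range) == 2, weight_range[1] <= weight_range[2],
            weight_range[1] > 0, weight_range[2] < 1,
            spec$n_redundant_pairs <= spec$p_community_a + spec$p_community_b,
            spec$n >= 2)
  max_bridge <- spec$p_community_a * spec$p_community_b
  if (spec$n_bridge_edges > max_bridge)
    stop("n_bridge_edges exceeds the number of cross-community pairs")
  class(spec) <- "synthetic_spec"
  spec
}

#' Study-like preset: two questionnaires, small clinical sample
#'
#' 20 + 63 base items plus 2 redundant duplicates per community (87 items
#' total: 22 on a seven-point scale, 65 on a four-point scale), n = 101
#' respondents, one reverse-coded item in the second community, and a
#' 0.08% missing rate — the shape of a symptom-network study pairing a
#' 22-item eating-disorder questionnaire with a 65-item autism-trait
#' questionnaire in a small clinical sample.
#'
#' @param seed master seed.
#' @param ... overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
study_like_spec <- function(seed = 1, ...) {
  args <- list(p_community_a = 20, p_community_b = 63,
               likert_levels_a = 7, likert_levels_b = 4,
               likert_min_a = 0, likert_min_b = 1,
               within_density = 0.1, n_bridge_edges = 3,
               weight_range = c(0.2, 0.4), prob_negative = 0.1,
               n_redundant_pairs = 4, redundancy_noise_sd = 0.1,
               n_reverse_coded = 1, reverse_community = "ASD",
               missing_rate = 0.0008, threshold_skew = 0.3,
               n = 101, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_spec, args)
}

synthetic_item_ids <- function(spec) {
  c(sprintf("ED%02d", seq_len(spec$p_community_a)),
    sprintf("ASD%02d", seq_len(spec$p_community_b)))
}

synthetic_scales <- function(spec) {
  scale_definitions(
    item_id = synthetic_item_ids(spec),
    instrument = rep(c("scaleA", "scaleB"),
                     c(spec$p_community_a, spec$p_community_b)),
    community = rep(c("ED", "ASD"),
                    c(spec$p_community_a, spec$p_community_b)),
    likert_min = rep(c(spec$likert_min_a, spec$likert_min_b),
                     c(spec$p_community_a, spec$p_community_b)),
    likert_max = rep(c(spec$likert_min_a + spec$likert_levels_a - 1L,
                       spec$likert_min_b + spec$likert_levels_b - 1L),
                     c(spec$p_community_a, spec$p_community_b)),
    reverse_coded = FALSE
  )
}

#' Build the planted sparse precision matrix and its ground truth
#'
#' Plants within-community edges at `within_density` in each diagonal
#' block and exactly `n_bridge_edges` cross-community edges (on distinct
#' node pairs), with magnitudes uniform in `weight_range` and signs
#' negative with probability `prob_negative`. Positive definiteness is
#' enforced in two stages: first each edge is rescaled so that every
#' node's total absolute off-diagonal weight stays below 0.9 (a Gershgorin
#' budget — this preserves strong edges on low-degree nodes, the way a
#' pair of near-duplicate items can share a very strong conditional
#' association, instead of uniformly flattening the whole network); then,
#' as a backstop, a common constant is added to the diagonal until the
#' smallest eigenvalue is at least 0.05. Neither stage changes a planted
#' sign, so the sign pattern is exact ground truth.
#'
#' @param spec a `synthetic_spec`.
#' @return A `ground_truth`: precision matrix `Theta`, implied
#'   partial-correlation matrix `pcor`, `communities`, `bridge_edges`
#'   data.frame, empty `redundant_pairs`, and the `scales` metadata.
#' @export
make_precision_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pa <- spec$p_community_a; pb <- spec$p_community_b
  p <- pa + pb
  items <- synthetic_item_ids(spec)
  communities <- rep(c("ED", "ASD"), c(pa, pb))
  Theta <- diag(p)
  draw_weight <- function(k)
    runif(k, spec$weight_range[1], spec$weight_range[2]) *
      ifelse(runif(k) < spec$prob_negative, -1, 1)
  # within-community edges
  for (block in list(seq_len(pa), pa + seq_len(pb))) {
    if (length(block) < 2) next
    pairs <- utils::combn(block, 2)
    on <- runif(ncol(pairs)) < spec$within_density
    w <- draw_weight(sum(on))
    sel <- pairs[, on, drop = FALSE]
    for (k in seq_len(ncol(sel))) {
      # planted magnitude is the target partial correlation; theta off-diag
      # gets the opposite sign (pcor_ij = -theta_ij at unit diagonal)
      Theta[sel[1, k], sel[2, k]] <- -w[k]
      Theta[sel[2, k], sel[1, k]] <- -w[k]
    }
  }
  # bridge edges on distinct cross-community pairs
  cross <- expand.grid(a = seq_len(pa), b = pa + seq_len(pb))
  sel <- cross[sample.int(nrow(cross), spec$n_bridge_edges), , drop = FALSE]
  wb <- draw_weight(nrow(sel))
  for (k in seq_len(nrow(sel))) {
    Theta[sel$a[k], sel$b[k]] <- -wb[k]
    Theta[sel$b[k], sel$a[k]] <- -wb[k]
  }
  # Gershgorin budget: rescale edges so every row's off-diagonal mass
  # stays below 0.9, keeping low-degree strong edges strong
  rs <- rowSums(abs(Theta)) - diag(Theta)
  if (any(rs > 0.9)) {
    fac <- pmin(1, 0.9 / rs)
    scale_mat <- outer(fac, fac, pmin)
    off <- Theta * scale_mat
    diag(off) <- diag(Theta)
    Theta <- off
  }
  # diagonal loading as a backstop until comfortably positive definite
  mineig <- min(eigen(Theta, symmetric = TRUE, only.values = TRUE)$values)
  if (mineig < 0.05) Theta <- Theta + diag(0.05 - mineig + 1e-6, p)
  dimnames(Theta) <- list(items, items)
  bridge_edges <- data.frame(
    node_a = items[sel$a], node_b = items[sel$b],
    weight = -Theta[cbind(sel$a, sel$b)] /
      sqrt(diag(Theta)[sel$a] * diag(Theta)[sel$b]),
    stringsAsFactors = FALSE)
  structure(
    list(Theta = Theta, pcor = theta_to_pcor(Theta),
         communities = setNames(communities, items),
         bridge_edges = bridge_edges,
         redundant_pairs = data.frame(original = character(0),
                                      duplicate = character(0),
                                      stringsAsFactors = FALSE),
         scales = synthetic_scales(spec)),
    class = "ground_truth"
  )
}

# Discretize one latent column into Likert categories through
# normal-quantile thresholds; skew > 0 concentrates mass near the floor.
discretize_latent <- function(x, levels, likert_min, sd_x, skew) {
  probs <- (seq_len(levels - 1) / levels)^exp(-skew)
  cuts <- qnorm(probs, mean = 0, sd = sd_x)
  as.integer(likert_min + findInterval(x, cuts))
}

#' Draw ordinal responses from the latent Gaussian model
#'
#' Samples `n` multivariate-normal vectors with covariance `solve(Theta)`,
#' discretizes each item through its community's Likert level count using
#' normal-quantile thresholds (equal-probability by default; positive
#' `threshold_skew` produces floor effects), stores `n_reverse_coded`
#' randomly chosen items in reversed orientation with the metadata flag
#' set, and finally blanks cells completely at random at `missing_rate`.
#'
#' The latent draw is attached as attribute `"latent"` so that
#' [inject_redundant_items()] can duplicate latent columns.
#'
#' @param gt a `ground_truth` from [make_precision_matrix()].
#' @param spec the same `synthetic_spec`.
#' @return An `item_response_matrix` (as administered: reverse-coded items
#'   still reversed, flags set).
#' @export
sample_likert <- function(gt, spec) {
  stopifnot(inherits(gt, "ground_truth"))
  Sigma <- solve(gt$Theta)
  p <- ncol(Sigma)
  latent <- MASS::mvrnorm(spec$n, mu = rep(0, p), Sigma = Sigma)
  latent <- matrix(latent, nrow = spec$n, dimnames = list(NULL, colnames(Sigma)))
  scales <- gt$scales
  values <- matrix(NA_integer_, spec$n, p)
  sds <- sqrt(diag(Sigma))
  levels_per_item <- ifelse(scales$community == "ED",
                            spec$likert_levels_a, spec$likert_levels_b)
  for (j in seq_len(p)) {
    values[, j] <- discretize_latent(latent[, j], levels_per_item[j],
                                     scales$likert_min[j], sds[j],
                                     spec$threshold_skew)
  }
  # mark and store reverse-coded items in administered (reversed) orientation
  if (spec$n_reverse_coded > 0) {
    pool <- if (is.null(spec$reverse_community)) seq_len(p)
            else which(scales$community == spec$reverse_community)
    rev_idx <- sort(sample(pool, min(spec$n_reverse_coded, length(pool))))
    for (j in rev_idx)
      values[, j] <- scales$likert_min[j] + scales$likert_max[j] - values[, j]
    scales$reverse_coded[rev_idx] <- TRUE
  }
  if (spec$missing_rate > 0) {
    blank <- which(runif(length(values)) < spec$missing_rate)
    values[blank] <- NA_integer_
  }
  m <- new_item_response_matrix(values, sprintf("S%04d", seq_len(spec$n)), scales)
  attr(m, "latent") <- latent
  m
}

#' Append near-duplicate (redundant) items
#'
#' Duplicates `n_redundant_pairs` randomly chosen items at the latent
#' level, adds Gaussian noise with sd `redundancy_noise_sd`, and
#' re-discretizes through the source item's thresholds; each (source,
#' duplicate) pair is recorded in the ground truth. Duplicates inherit the
#' source community, get ids suffixed `"d"`, and receive missing cells at
#' the same rate as the rest of the data. With half the pairs drawn from
#' each community (when counts allow), a reduction stage should remove one
#' member per pair and restore the base item counts.
#'
#' @param m the `item_response_matrix` from [sample_likert()] (must carry
#'   the `"latent"` attribute).
#' @param gt the matching `ground_truth`.
#' @param spec the `synthetic_spec`.
#' @return List with the augmented `responses` and updated `truth`.
#' @export
inject_redundant_items <- function(m, gt, spec) {
  k <- spec$n_redundant_pairs
  if (k == 0) return(list(responses = m, truth = gt))
  latent <- attr(m, "latent")
  if (is.null(latent)) stop("responses lack the latent attribute; regenerate with sample_likert()")
  scales <- m$scales
  # balance sources across communities where possible
  by_comm <- split(seq_len(m$p), scales$community)
  quota <- vapply(by_comm, function(ix) length(ix), 0L)
  want <- rep(floor(k / length(by_comm)), length(by_comm))
  want[seq_len(k - sum(want))] <- want[seq_len(k - sum(want))] + 1L
  src <- unlist(lapply(seq_along(by_comm), function(i)
    sample(by_comm[[i]], min(want[i], quota[i]))), use.names = FALSE)
  src <- src[seq_len(min(k, length(src)))]
  sds <- sqrt(diag(solve(gt$Theta)))
  new_cols <- matrix(NA_integer_, m$n, length(src))
  new_scales <- scales[src, , drop = FALSE]
  new_scales$item_id <- paste0(scales$item_id[src], "d")
  levels_src <- scales$likert_max[src] - scales$likert_min[src] + 1L
  for (t in seq_along(src)) {
    z <- latent[, src[t]] + rnorm(m$n, 0, spec$redundancy_noise_sd)
    new_cols[, t] <- discretize_latent(z, levels_src[t],
                                       scales$likert_min[src[t]],
                                       sds[src[t]], spec$threshold_skew)
    if (scales$reverse_coded[src[t]])
      new_cols[, t] <- scales$likert_min[src[t]] + scales$likert_max[src[t]] - new_cols[, t]
  }
  if (spec$missing_rate > 0) {
    blank <- which(runif(length(new_cols)) < spec$missing_rate)
    new_cols[blank] <- NA_integer_
  }
  all_scales <- rbind(scales, new_scales)
  rownames(all_scales) <- NULL
  class(all_scales) <- c("scale_definition", "data.frame")
  out <- new_item_response_matrix(cbind(m$values, new_cols),
                                  m$respondent_ids, all_scales)
  attr(out, "latent") <- latent
  gt$redundant_pairs <- data.frame(original = scales$item_id[src],
                                   duplicate = new_scales$item_id,
                                   stringsAsFactors = FALSE)
  list(responses = out, truth = gt)
}

#' Generate a complete synthetic study dataset
#'
#' Runs [make_precision_matrix()], [sample_likert()] and
#' [inject_redundant_items()] under a documented seed-derivation scheme:
#' the master seed spawns one sub-seed per stage (structure, sampling,
#' redundancy), so the same master seed always yields a byte-identical
#' dataset and changing one stage's draw count cannot perturb earlier
#' stages.
#'
#' @param spec a `synthetic_spec`.
#' @return List with `responses` (an `item_response_matrix`, as
#'   administered) and `truth` (a `ground_truth`).
#' @export
simulate_study_data <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  stage_seeds <- derive_seeds(spec$seed, 3)
  set.seed(stage_seeds[1])
  gt <- make_precision_matrix(spec)
  set.seed(stage_seeds[2])
  m <- sample_likert(gt, spec)
  set.seed(stage_seeds[3])
  inject_redundant_items(m, gt, spec)
}

#' Compare an estimated network with the planted ground truth
#'
#' Edge-presence sensitivity and specificity against the planted sparsity
#' pattern, sign agreement on recovered true edges, and a bridge-detection
#' indicator: whether any planted bridge node (an endpoint of a planted
#' cross-community edge) ranks in the top `top_k` nodes by absolute
#' one-step bridge expected influence. Magnitude ranking is used for the
#' indicator because planted bridge edges carry random signs: a negative
#' bridge edge makes its endpoints the most *negative* — not the largest —
#' signed bridge influence, yet they bridge the communities all the same.
#'
#' @param estimated a `network_model`.
#' @param gt the matching `ground_truth` (item sets must agree; redundant
#'   duplicates are expected to have been removed).
#' @param top_k rank window for bridge detection.
#' @return List with `sensitivity`, `specificity`, `sign_agreement`,
#'   `bridge_rank_success`, and the edge counts behind them.
#' @export
recovery_metrics <- function(estimated, gt, top_k = 3) {
  stopifnot(inherits(estimated, "network_model"), inherits(gt, "ground_truth"))
  items <- estimated$items
  if (!setequal(items, colnames(gt$Theta)))
    stop("item sets of the estimate and the ground truth differ")
  truW <- gt$pcor[items, items]
  estW <- estimated$W[items, items]
  ut <- upper.tri(truW)
  true_edge <- truW[ut] != 0
  est_edge <- estW[ut] != 0
  sens <- if (any(true_edge)) mean(est_edge[true_edge]) else NA_real_
  spec <- if (any(!true_edge)) mean(!est_edge[!true_edge]) else NA_real_
  both <- true_edge & est_edge
  sign_agree <- if (any(both))
    mean(sign(truW[ut][both]) == sign(estW[ut][both])) else NA_real_
  bridge_nodes <- unique(c(gt$bridge_edges$node_a, gt$bridge_edges$node_b))
  bridge_nodes <- intersect(bridge_nodes, items)
  comm <- unname(gt$communities[items])
  abs_bei <- abs(bridge_expected_influence(estW, comm, 1))
  top <- items[order(-abs_bei, items)][seq_len(min(top_k, length(items)))]
  list(sensitivity = sens, specificity = spec, sign_agreement = sign_agree,
       bridge_rank_success = length(intersect(top, bridge_nodes)) > 0,
       n_true_edges = sum(true_edge), n_estimated_edges = sum(est_edge),
       n_recovered = sum(both))
}

#' Serialize a ground truth object to JSON
#'
#' @param gt a `ground_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(gt, path) {
  jsonlite::write_json(
    list(items = colnames(gt$Theta),
         communities = unname(gt$communities),
         theta = gt$Theta,
         pcor = gt$pcor,
         bridge_edges = gt$bridge_edges,
         redundant_pairs = gt$redundant_pairs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
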