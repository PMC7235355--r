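# Shared fixtures and independent oracles. Oracles are deliberately naive
# (explicit loops, enumerations) so they stay independent of the package's
# vectorized implementations.

# random symmetric zero-diagonal weight matrix
random_weight_matrix <- function(p, density = 0.5, rng_max = 0.5) {
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (runif(1) < density) {
        w <- runif(1, -rng_max, rng_max)
        W[i, j] <- w
        W[j, i] <- w
      }
    }
  }
  dimnames(W) <- list(sprintf("N%02d", 1:p), sprintf("N%02d", 1:p))
  W
}

# brute-force expected influence, one and two step
brute_ei <- function(W, steps) {
  p <- ncol(W)
  ei1 <- numeric(p)
  for (i in 1:p) for (j in 1:p) if (j != i) ei1[i] <- ei1[i] + W[i, j]
  if (steps == 1) return(ei1)
  ei2 <- numeric(p)
  for (i in 1:p) {
    ei2[i] <- ei1[i]
    for (j in 1:p) if (j != i) ei2[i] <- ei2[i] + W[i, j] * ei1[j]
  }
  ei2
}

# brute-force bridge expected influence
brute_bei <- function(W, comm, steps) {
  p <- ncol(W)
  b1 <- numeric(p)
  for (i in 1:p) for (j in 1:p)
    if (j != i && comm[j] != comm[i]) b1[i] <- b1[i] + W[i, j]
  if (steps == 1) return(b1)
  b2 <- numeric(p)
  for (i in 1:p) {
    b2[i] <- b1[i]
    for (j in 1:p) if (j != i) b2[i] <- b2[i] + W[i, j] * b1[j]
  }
  b2
}

# small item response matrix built directly from a value matrix
make_irm <- function(values, likert_min = 0, likert_max = 6,
                     community = "ED", reverse = FALSE) {
  p <- ncol(values)
  scales <- scale_definitions(
    item_id = sprintf("I%02d", seq_len(p)),
    instrument = "test", community = community,
    likert_min = likert_min, likert_max = likert_max,
    reverse_coded = reverse)
  symptomnet:::new_item_response_matrix(values,
                                        sprintf("R%03d", seq_len(nrow(values))),
                                        scales)
}

# a small two-community dataset with clear structure, for resampling tests
small_structured_data <- function(n = 150, seed = 42) {
  spec <- synthetic_spec(p_community_a = 4, p_community_b = 4,
                         within_density = 0.5, n_bridge_edges = 2,
                         weight_range = c(0.3, 0.5), prob_negative = 0,
                         n = n, seed = seed)
  simulate_study_data(spec)$responses
}

# minimum vertex cover size by exhaustive search (for removal minimality)
min_vertex_cover_size <- function(edges, nodes) {
  if (nrow(edges) == 0) return(0L)
  for (k in 0:length(nodes)) {
    combs <- utils::combn(nodes, k, simplify = FALSE)
    for (set in combs) {
      covered <- mapply(function(a, b) a %in% set || b %in% set,
                        edges[[1]], edges[[2]])
      if (all(covered)) return(k)
    }
  }
  length(nodes)
}
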