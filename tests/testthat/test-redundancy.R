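test_that("dependent correlation test: symmetry, antisymmetry, degenerate input", {
  res <- dependent_correlation_test(0.4, 0.4, 0.2, 101)
  expect_equal(res$z, 0)
  expect_equal(res$p, 1)

  a <- dependent_correlation_test(0.5, 0.3, 0.4, 101)
  b <- dependent_correlation_test(0.3, 0.5, 0.4, 101)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)

  expect_error(dependent_correlation_test(1, 0.3, 0.4, 101), "Fisher")
  expect_error(dependent_correlation_test(0.5, 0.3, 0.4, 3), "n >= 4")
})

test_that("analytic p-value agrees with a Monte-Carlo null distribution", {
  # observed statistic for the documented configuration
  obs <- dependent_correlation_test(0.5, 0.3, 0.4, 101)
  # simulate the null: equal population correlations (0.4, the midpoint),
  # item-item correlation 0.4, n = 101; compare |Z| tail mass
  set.seed(2024)
  rho <- 0.4; rab <- 0.4; n <- 101
  Sigma <- matrix(c(1, rab, rho, rab, 1, rho, rho, rho, 1), 3, 3)
  ch <- chol(Sigma)
  B <- 20000
  zs <- numeric(B)
  for (i in seq_len(B)) {
    X <- matrix(rnorm(n * 3), n, 3) %*% ch
    S <- cor(X)
    zs[i] <- dependent_correlation_test(S[1, 3], S[2, 3], S[1, 2], n)$z
  }
  p_mc <- mean(abs(zs) >= abs(obs$z))
  expect_lt(abs(p_mc - obs$p), 0.02)
})

test_that("exact duplicates form a bad pair; independent items do not", {
  set.seed(3)
  v <- matrix(sample(0:6, 400 * 6, replace = TRUE), 400, 6)
  v[, 2] <- v[, 1]  # exact duplicate
  m <- make_irm(v)
  cm <- correlation_matrix(m)
  rep <- find_bad_pairs(cm)
  expect_true(any(rep$bad_pairs$item_a == "I01" & rep$bad_pairs$item_b == "I02"))
  expect_equal(
    rep$bad_pairs$prop_significant[rep$bad_pairs$item_a == "I01" &
                                   rep$bad_pairs$item_b == "I02"], 0)

  # independent items never reach the multicollinearity gate, so none are
  # flagged (without the gate, all-zero correlation profiles are mutually
  # indistinguishable by construction — the gate is what makes redundancy
  # mean "same construct" rather than "equally unrelated")
  set.seed(4)
  v2 <- matrix(sample(0:6, 1000 * 20, replace = TRUE), 1000, 20)
  cm2 <- correlation_matrix(make_irm(v2))
  rep2 <- find_bad_pairs(cm2)
  expect_equal(nrow(rep2$bad_pairs), 0)
})

test_that("bad-pair screening is invariant to item order", {
  set.seed(5)
  sim <- small_structured_data(n = 200, seed = 9)
  cm <- correlation_matrix(sim)
  rep1 <- find_bad_pairs(cm, min_correlation = 0.3)
  perm <- sample(ncol(cm$S))
  cmP <- cm
  cmP$S <- cm$S[perm, perm]
  rep2 <- find_bad_pairs(cmP, n = cm$n, min_correlation = 0.3)
  canon <- function(df) {
    key <- apply(df[, 1:2], 1, function(r) paste(sort(r), collapse = "|"))
    df <- df[order(key), ]
    data.frame(key = sort(key), prop = df$prop_significant)
  }
  expect_equal(canon(rep1$bad_pairs), canon(rep2$bad_pairs), tolerance = 1e-12)
})

test_that("node removal resolves bad pairs minimally and logs decisions", {
  set.seed(6)
  v <- matrix(sample(0:6, 200 * 5, replace = TRUE), 200, 5)
  m <- make_irm(v)
  cm <- correlation_matrix(m)

  # fabricate a report with a chain of bad pairs (A,B), (B,C)
  rep <- find_bad_pairs(cm, min_correlation = 0)
  rep$bad_pairs <- data.frame(item_a = c("I01", "I02"),
                              item_b = c("I02", "I03"),
                              prop_significant = c(0, 0),
                              stringsAsFactors = FALSE)
  out <- reduce_nodes(m, rep)
  expect_equal(out$report$removed_items, "I02")  # covers both pairs
  expect_equal(out$responses$p, 4)
  expect_equal(nrow(out$report$removal_log), 1)
  expect_equal(
    length(out$report$removed_items),
    min_vertex_cover_size(rep$bad_pairs[, 1:2], rep$items))
  expect_setequal(c(out$report$removed_items, out$report$retained_items),
                  rep$items)

  # no bad pairs: identity
  rep0 <- rep
  rep0$bad_pairs <- rep$bad_pairs[0, ]
  out0 <- reduce_nodes(m, rep0)
  expect_equal(out0$responses$p, 5)
  expect_length(out0$report$removed_items, 0)

  # a single duplicated pair loses exactly one member; with fully tied
  # statistics the lexicographically later id goes
  v2 <- v; v2[, 2] <- v2[, 1]
  m2 <- make_irm(v2)
  out2 <- reduce_items(m2)
  expect_equal(out2$report$removed_items, "I02")
  expect_equal(out2$responses$p, 4)
})

test_that("planted near-duplicates are detected and removed end-to-end", {
  sim <- simulate_study_data(synthetic_spec(
    p_community_a = 8, p_community_b = 8, n = 500,
    n_redundant_pairs = 2, redundancy_noise_sd = 0.1, seed = 31))
  m <- sim$responses
  out <- reduce_items(m)
  planted <- sim$truth$redundant_pairs
  for (i in seq_len(nrow(planted))) {
    expect_true(any(c(planted$original[i], planted$duplicate[i]) %in%
                      out$report$removed_items))
  }
})
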