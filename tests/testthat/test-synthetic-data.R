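test_that("the generator is byte-identical under a fixed seed", {
  spec <- study_like_spec(seed = 99)
  a <- simulate_study_data(spec)
  b <- simulate_study_data(spec)
  expect_identical(a$responses$values, b$responses$values)
  expect_identical(a$truth$Theta, b$truth$Theta)
  c <- simulate_study_data(study_like_spec(seed = 100))
  expect_false(identical(a$responses$values, c$responses$values))
})

test_that("planted precision matrices honor structure counts and stay PD", {
  # empty structure: diagonal precision
  gt0 <- local({
    set.seed(1)
    make_precision_matrix(synthetic_spec(within_density = 0, n_bridge_edges = 0))
  })
  expect_equal(gt0$Theta, diag(40), ignore_attr = TRUE)

  # exact bridge count in the cross block
  set.seed(2)
  gt3 <- make_precision_matrix(synthetic_spec(n_bridge_edges = 3))
  cross <- gt3$Theta[1:20, 21:40]
  expect_equal(sum(cross != 0), 3)
  expect_equal(nrow(gt3$bridge_edges), 3)

  # positive definiteness margin across many random specs
  set.seed(3)
  for (i in 1:20) {
    spec <- synthetic_spec(
      p_community_a = sample(5:15, 1), p_community_b = sample(5:15, 1),
      within_density = runif(1, 0, 0.5),
      n_bridge_edges = sample(0:4, 1),
      weight_range = sort(runif(2, 0.1, 0.7)),
      prob_negative = runif(1))
    gt <- make_precision_matrix(spec)
    ev <- eigen(gt$Theta, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), 0.05 - 1e-9)
    # partial correlation signs mirror the planted off-diagonal signs
    off <- row(gt$Theta) != col(gt$Theta)
    expect_true(all(sign(gt$pcor[off]) == sign(-gt$Theta[off])))
  }
})

test_that("sampled responses respect declared Likert ranges per community", {
  sim <- simulate_study_data(study_like_spec(seed = 17))
  m <- sim$responses
  for (j in seq_len(m$p)) {
    v <- m$values[, j]
    v <- v[!is.na(v)]
    expect_gte(min(v), m$scales$likert_min[j])
    expect_lte(max(v), m$scales$likert_max[j])
  }
  # community A on 7 levels (0-6), community B on 4 levels (1-4)
  expect_equal(unique(m$scales$likert_max[m$scales$community == "ED"]), 6L)
  expect_equal(unique(m$scales$likert_max[m$scales$community == "ASD"]), 4L)
  # 22 + 65 items as administered, including duplicates
  expect_equal(sum(m$scales$community == "ED"), 22)
  expect_equal(sum(m$scales$community == "ASD"), 65)
})

test_that("missingness and reverse coding follow the preset's design", {
  sim <- simulate_study_data(study_like_spec(seed = 4))
  m <- sim$responses
  expect_gt(m$missing_fraction, 0)
  expect_lt(m$missing_fraction, 0.004)
  expect_equal(sum(m$scales$reverse_coded), 1)
  expect_equal(m$scales$community[m$scales$reverse_coded], "ASD")

  complete <- simulate_study_data(
    synthetic_spec(missing_rate = 0, n = 50, seed = 5))$responses
  expect_false(anyNA(complete$values))
})

test_that("noise-free duplicates coincide with their source items", {
  spec <- synthetic_spec(p_community_a = 6, p_community_b = 6,
                         n_redundant_pairs = 2, redundancy_noise_sd = 0,
                         missing_rate = 0, n = 200, seed = 6)
  sim <- simulate_study_data(spec)
  pairs <- sim$truth$redundant_pairs
  expect_equal(nrow(pairs), 2)
  for (i in 1:2) {
    a <- sim$responses$values[, pairs$original[i]]
    b <- sim$responses$values[, pairs$duplicate[i]]
    expect_identical(a, b)
  }
})

test_that("Spearman correlations converge to the latent monotone transform", {
  spec <- synthetic_spec(p_community_a = 5, p_community_b = 5,
                         within_density = 0.4, weight_range = c(0.2, 0.4),
                         n = 10000, seed = 8)
  sim <- simulate_study_data(spec)
  latent_cor <- cov2cor(solve(sim$truth$Theta))
  # population Spearman of a bivariate normal: (6/pi) asin(rho / 2)
  target <- (6 / pi) * asin(latent_cor / 2)
  S <- correlation_matrix(sim$responses, method = "spearman")$S
  ut <- upper.tri(S)
  expect_lt(mean(abs(S[ut] - target[ut])), 0.03)
})

test_that("recovery metrics recognize perfect and empty estimates", {
  set.seed(9)
  gt <- make_precision_matrix(synthetic_spec(seed = 9))
  fake_model <- function(W) {
    structure(list(items = colnames(W),
                   communities = gt$communities,
                   W = W), class = "network_model")
  }
  perfect <- recovery_metrics(fake_model(gt$pcor), gt)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$sign_agreement, 1)

  empty <- recovery_metrics(fake_model(gt$pcor * 0), gt)
  expect_equal(empty$sensitivity, 0)
  expect_equal(empty$specificity, 1)

  bad <- fake_model(gt$pcor[c(2:nrow(gt$pcor), 1), c(2:nrow(gt$pcor), 1)])
  bad$items <- paste0("x", bad$items)
  expect_error(recovery_metrics(bad, gt), "item sets")
})

test_that("generator output feeds the loader through its own file formats", {
  sim <- simulate_study_data(synthetic_spec(p_community_a = 4,
                                            p_community_b = 4, n = 40,
                                            missing_rate = 0.01, seed = 10))
  csv <- tempfile(fileext = ".csv")
  yml <- tempfile(fileext = ".yaml")
  write_responses_csv(sim$responses, csv)
  write_scale_metadata(sim$responses$scales, yml)
  loaded <- load_responses(csv, read_scale_metadata(yml),
                           id_column = "respondent_id",
                           apply_reverse_coding = FALSE)
  expect_identical(loaded$values, sim$responses$values)
  json <- tempfile(fileext = ".json")
  write_ground_truth_json(sim$truth, json)
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$items, colnames(sim$truth$Theta))
})
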