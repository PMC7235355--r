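test_that("bootstrap is bit-reproducible and CIs are order statistics", {
  m <- small_structured_data(n = 120, seed = 5)
  est <- estimator_config(n_points = 40)
  b1 <- suppressWarnings(nonparametric_bootstrap(m, est, B = 12, seed = 7))
  b2 <- suppressWarnings(nonparametric_bootstrap(m, est, B = 12, seed = 7))
  expect_identical(b1$edge_samples, b2$edge_samples)
  expect_identical(b1$ci_lower, b2$ci_lower)

  # percentile endpoints must be actual stored draws (order statistics)
  for (e in sample(colnames(b1$edge_samples), 5)) {
    x <- b1$edge_samples[, e]
    x <- x[!is.na(x)]
    expect_true(b1$ci_lower[e] %in% x)
    expect_true(b1$ci_upper[e] %in% x)
    expect_lte(b1$ci_lower[e], median(x))
    expect_gte(b1$ci_upper[e], median(x))
  }
  expect_error(nonparametric_bootstrap(m, est, B = 1), "at least 2")
})

test_that("a strong planted edge has a bootstrap CI excluding zero", {
  spec <- synthetic_spec(p_community_a = 3, p_community_b = 3,
                         within_density = 0, n_bridge_edges = 1,
                         weight_range = c(0.55, 0.6), prob_negative = 0,
                         n = 800, seed = 77)
  sim <- simulate_study_data(spec)
  bridge <- sim$truth$bridge_edges
  b <- suppressWarnings(nonparametric_bootstrap(
    sim$responses, estimator_config(n_points = 40), B = 60, seed = 3))
  ename <- paste(sort(c(bridge$node_a[1], bridge$node_b[1]))[1],
                 sort(c(bridge$node_a[1], bridge$node_b[1]))[2], sep = "|")
  ename <- intersect(colnames(b$edge_samples),
                     c(ename, paste(bridge$node_b[1], bridge$node_a[1], sep = "|"),
                       paste(bridge$node_a[1], bridge$node_b[1], sep = "|")))[1]
  expect_gt(b$ci_lower[ename], 0)
})

test_that("case-dropping bootstrap is reproducible and correlations are sane", {
  m <- small_structured_data(n = 200, seed = 12)
  est <- estimator_config(n_points = 40)
  s1 <- suppressWarnings(case_dropping_bootstrap(
    m, est, statistic = "EI", drop_levels = c(0.1, 0.3, 0.5), B = 10, seed = 2))
  s2 <- suppressWarnings(case_dropping_bootstrap(
    m, est, statistic = "EI", drop_levels = c(0.1, 0.3, 0.5), B = 10, seed = 2))
  expect_identical(s1$correlations, s2$correlations)
  expect_true(all(abs(s1$correlations) <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(s1$cs_coefficient, cs_coefficient(s1))
})

test_that("multi-statistic case dropping equals separate runs", {
  m <- small_structured_data(n = 150, seed = 30)
  est <- estimator_config(n_points = 30)
  both <- suppressWarnings(case_dropping_bootstrap(
    m, est, statistic = c("EI", "bridge_EI"), drop_levels = c(0.2, 0.4),
    B = 8, seed = 5))
  ei_only <- suppressWarnings(case_dropping_bootstrap(
    m, est, statistic = "EI", drop_levels = c(0.2, 0.4), B = 8, seed = 5))
  expect_identical(both$EI$correlations, ei_only$correlations)
})

test_that("infeasible drop levels are skipped with a warning", {
  m <- small_structured_data(n = 60, seed = 3)
  expect_warning(
    s <- case_dropping_bootstrap(m, estimator_config(n_points = 20),
                                 drop_levels = c(0.2, 0.95), B = 4, seed = 1),
    "skipped")
  expect_equal(s$skipped_levels, 0.95)
})

test_that("CS coefficient implements the probability rule on hand-built fixtures", {
  fixture <- function(correlations, levels) {
    structure(list(statistic = "EI", drop_levels = levels,
                   correlations = correlations,
                   correlation_threshold = 0.7, probability_level = 0.95,
                   B = ncol(correlations), seed = 1,
                   skipped_levels = numeric(0), n_excluded = 0L),
              class = "stability_result")
  }
  levels <- c(0.1, 0.3, 0.5)
  # perfectly stable: CS = max tested level
  expect_equal(cs_coefficient(fixture(matrix(1, 3, 20), levels)), 0.5)
  # nothing retains 0.7: CS = 0
  expect_equal(cs_coefficient(fixture(matrix(0.5, 3, 20), levels)), 0)
  # mixed: level 0.1 has 19/20 >= 0.7 (0.95 ok), level 0.3 has 18/20 (0.90 fails)
  mat <- rbind(c(rep(0.9, 19), 0.1),
               c(rep(0.9, 18), 0.1, 0.1),
               rep(0.1, 20))
  expect_equal(cs_coefficient(fixture(mat, levels)), 0.1)
  # thresholds are overridable
  expect_equal(cs_coefficient(fixture(mat, levels), probability_level = 0.9), 0.3)
})

test_that("difference tests flag separated quantities and honor conventions", {
  # identical quantities: difference identically zero, never significant
  d0 <- difference_test(rep(0.4, 50), rep(0.4, 50))
  expect_false(d0$significant)
  expect_equal(d0$estimate, 0)

  # clearly separated paired draws
  set.seed(9)
  a <- rnorm(200, 0.6, 0.05)
  b <- rnorm(200, 0.0, 0.05)
  d1 <- difference_test(a, b, alpha = 0.05)
  expect_true(d1$significant)
  expect_gt(d1$ci_lower, 0)

  # alpha = 1: zero-width interval at the median
  d2 <- difference_test(a, b, alpha = 1)
  expect_equal(d2$ci_lower, d2$ci_upper)
  expect_true(d2$significant)

  expect_error(difference_test(a, b[1:10]), "matching replicate")
})

test_that("difference tests run against bootstrap samples by name", {
  m <- small_structured_data(n = 150, seed = 21)
  b <- suppressWarnings(nonparametric_bootstrap(
    m, estimator_config(n_points = 30), B = 20, seed = 4))
  nodes <- colnames(b$ei_samples)[1:2]
  d <- difference_test(b, nodes, what = "EI", alpha = 0.05)
  expect_s3_class(d, "difference_test_result")
  expect_equal(d$a, nodes[1])
  all_d <- difference_tests_all(b, what = "EI", alpha = 0.05)
  expect_equal(nrow(all_d), choose(ncol(b$ei_samples), 2))
  expect_error(difference_test(b, c("nope1", "nope2"), what = "EI"), "not found")
})

test_that("stability and bootstrap results serialize to long CSV", {
  m <- small_structured_data(n = 120, seed = 8)
  est <- estimator_config(n_points = 20)
  b <- suppressWarnings(nonparametric_bootstrap(m, est, B = 6, seed = 2))
  s <- suppressWarnings(case_dropping_bootstrap(m, est, drop_levels = 0.2,
                                                B = 6, seed = 2))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_bootstrap_csv(b, ci_path = f1)
  write_stability_csv(s, f2)
  ci <- read.csv(f1)
  expect_equal(nrow(ci), ncol(b$edge_samples))
  long <- read.csv(f2)
  expect_equal(nrow(long), 6)
  expect_true(all(c("level", "replicate", "correlation") %in% names(long)))
})
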