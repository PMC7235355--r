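test_that("identity input gives an identity precision matrix and empty network", {
  S <- diag(5)
  fit <- glasso_solve(S, 0.1)
  expect_equal(fit$Theta, diag(5), tolerance = 1e-10)
  net <- suppressWarnings(estimate_network(S, n = 100))
  expect_equal(sum(net$W != 0), 0)
})

test_that("penalties at or above the KKT bound give an empty model", {
  set.seed(11)
  X <- matrix(rnorm(200 * 6), 200, 6)
  S <- cor(X %*% matrix(rnorm(36, 0, 0.5), 6, 6))
  lmax <- max(abs(S[upper.tri(S)]))
  fit <- glasso_solve(S, lmax * 1.0001)
  expect_equal(sum(fit$Theta[upper.tri(fit$Theta)] != 0), 0)
})

test_that("zero-penalty solution matches closed-form partial correlations", {
  S <- matrix(c(1, .5, .3,
                .5, 1, .4,
                .3, .4, 1), 3, 3)
  fit <- glasso_solve(S, 0)
  W <- -fit$Theta / sqrt(tcrossprod(diag(fit$Theta)))
  pc <- function(rab, rac, rbc) (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
  expect_equal(W[1, 2], pc(.5, .3, .4), tolerance = 1e-6)
  expect_equal(W[1, 3], pc(.3, .5, .4), tolerance = 1e-6)
  expect_equal(W[2, 3], pc(.4, .5, .3), tolerance = 1e-6)
})

test_that("KKT conditions hold for returned solutions", {
  set.seed(12)
  for (rep in 1:5) {
    p <- sample(5:20, 1)
    X <- matrix(rnorm(100 * p), 100, p) %*% matrix(rnorm(p * p, 0, .4), p, p)
    S <- cor(X)
    lam <- runif(1, 0.05, 0.3)
    fit <- glasso_solve(S, lam, tol = 1e-4)
    Sigma_hat <- solve(fit$Theta)
    D <- Sigma_hat - S
    nz <- fit$Theta != 0 & row(S) != col(S)
    z <- fit$Theta == 0 & row(S) != col(S)
    if (any(nz))
      expect_lt(max(abs(D[nz] - lam * sign(fit$Theta[nz]))), 2e-4)
    if (any(z))
      expect_lt(max(abs(D[z])) - lam, 2e-4)
  }
})

test_that("lambda path is log-spaced, decreasing, and starts empty", {
  S <- matrix(c(1, .8, .8, 1), 2, 2)
  expect_equal(lambda_path(S, n_points = 2, min_ratio = 0.5), c(0.8, 0.4))
  set.seed(13)
  X <- matrix(rnorm(300), 100, 3)
  S2 <- cor(X)
  path <- lambda_path(S2, 25)
  expect_true(all(diff(path) < 0))
  fit <- glasso_solve(S2, path[1])
  expect_equal(sum(fit$Theta[upper.tri(fit$Theta)] != 0), 0)
  expect_error(lambda_path(S2, n_points = 1), "at least 2")
  expect_warning(lambda_path(diag(3)), "degenerate")
})

test_that("EBIC matches independent arithmetic and penalizes edges", {
  Theta <- matrix(c(2, .5, 0,
                    .5, 2, 0,
                    0, 0, 1), 3, 3)
  S <- matrix(c(1, -.2, .1,
                -.2, 1, 0,
                .1, 0, 1), 3, 3)
  n <- 100; gamma <- 0.25
  logdet_hand <- log(2 * 2 - 0.5 * 0.5)  # block determinant, by hand
  tr_hand <- 2 + 2 * (-.2) * .5 + 2 + 1   # sum S_ij Theta_ij expanded
  E <- 1
  hand <- -n * (logdet_hand - tr_hand) + E * log(n) + 4 * E * gamma * log(3)
  expect_equal(ebic_score(Theta, S, n, gamma), hand, tolerance = 1e-10)

  # gamma = 0 reduces to the BIC form
  expect_equal(ebic_score(Theta, S, n, 0),
               -n * (logdet_hand - tr_hand) + E * log(n), tolerance = 1e-10)

  # equal likelihood, more edges, gamma > 0: higher score
  Theta2 <- diag(3)
  S0 <- diag(3)
  expect_lt(ebic_score(Theta2, S0, n, 0.25),
            ebic_score(Theta2 + (matrix(1, 3, 3) - diag(3)) * 1e-300, S0,
                       n, 0.25))
  expect_error(ebic_score(matrix(c(1, 2, 2, 1), 2, 2), diag(2), 50, 0.25),
               "positive definite")
})

test_that("sparsity recovered and signs agree on a known 15-node model", {
  spec <- synthetic_spec(p_community_a = 8, p_community_b = 7,
                         within_density = 0.25, n_bridge_edges = 3,
                         weight_range = c(0.25, 0.4), n = 2000, seed = 21)
  sim <- simulate_study_data(spec)
  net <- fit_network(sim$responses)
  met <- recovery_metrics(net, sim$truth)
  expect_gte(met$sensitivity, 0.7)
  expect_gte(met$specificity, 0.8)
  expect_equal(met$sign_agreement, 1)
})

test_that("higher gamma never yields more edges", {
  set.seed(23)
  spec <- synthetic_spec(p_community_a = 10, p_community_b = 10,
                         within_density = 0.2, n = 400, seed = 23)
  sim <- simulate_study_data(spec)
  cm <- correlation_matrix(sim$responses)
  counts <- vapply(seq(0, 0.5, by = 0.1), function(g) {
    net <- estimate_network(cm, gamma = g)
    sum(net$W[upper.tri(net$W)] != 0)
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("edge weights are valid partial correlations tied to Theta", {
  sim <- simulate_study_data(synthetic_spec(n = 500, seed = 3))
  net <- fit_network(sim$responses)
  expect_true(isSymmetric(net$W))
  expect_equal(unname(diag(net$W)), rep(0, ncol(net$W)))
  expect_lt(max(abs(net$W)), 1)
  off <- row(net$W) != col(net$W)
  expect_true(all(sign(net$W[off]) == sign(-net$Theta[off])))
  ev <- eigen(net$Theta, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # sparsity patterns of W and Theta agree off-diagonal
  expect_identical(net$W[off] == 0, net$Theta[off] == 0)
})

test_that("fixed-lambda mode skips selection and is recorded", {
  sim <- simulate_study_data(synthetic_spec(n = 300, seed = 8))
  cm <- correlation_matrix(sim$responses)
  net <- estimate_network(cm, lambda = 0.25)
  expect_equal(net$selected_lambda, 0.25)
  expect_length(net$lambda_path, 1)
})

test_that("network exports round-trip: edge list, adjacency, GraphML", {
  sim <- simulate_study_data(synthetic_spec(n = 800, seed = 15))
  net <- fit_network(sim$responses)
  edge_csv <- tempfile(fileext = ".csv")
  adj_csv <- tempfile(fileext = ".csv")
  gml <- tempfile(fileext = ".graphml")
  write_network(net, edge_csv, adj_csv, gml)

  edges <- read.csv(edge_csv)
  expect_equal(nrow(edges), sum(net$W[upper.tri(net$W)] != 0))
  adj <- read.csv(adj_csv, check.names = FALSE)
  expect_equal(as.matrix(adj[, -1]), unname(net$W), ignore_attr = TRUE)

  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), length(net$items))
  expect_setequal(unique(igraph::V(g)$community), c("ED", "ASD"))
  expect_true(all(igraph::E(g)$sign %in% c(-1, 1)))
  expect_equal(sort(igraph::E(g)$weight),
               sort(net$W[upper.tri(net$W)][net$W[upper.tri(net$W)] != 0]))
})
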