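make_spd <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  stats::cov2cor(crossprod(A) + p * diag(p))
}

test_that("unpenalized glasso inverts S and full shrinkage empties the graph", {
  S <- make_spd(4, 30)
  f0 <- glasso(S, 0, tol = 1e-9, max_iter = 500)
  expect_equal(f0$K, solve(S), tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(max(abs(f0$W %*% f0$K - diag(4))), 1e-4)
  lam <- max(abs(S[upper.tri(S)]))
  f1 <- glasso(S, lam * 1.001)
  expect_equal(f1$K, diag(diag(f1$K)), ignore_attr = TRUE)
})

test_that("glasso objective matches a generic convex optimizer on p = 3", {
  for (seed in 1:5) {
    S <- make_spd(3, seed)
    lam <- 0.08
    fit <- glasso(S, lam, tol = 1e-8, max_iter = 1000)
    oracle <- nm_glasso_oracle(S, lam)
    expect_equal(nm_glasso_objective(fit$K, S, lam), oracle$objective,
                 tolerance = 1e-6)
  }
})

test_that("the solver merit is non-decreasing across sweeps", {
  S <- make_spd(6, 41)
  f <- glasso(S, 0.05, tol = 1e-9, max_iter = 2000, trace = TRUE)
  expect_true(all(diff(f$logdet_trace) >= -1e-10))
})

test_that("non-convergence raises a typed error carrying the last iterate", {
  S <- make_spd(5, 42)
  err <- tryCatch(glasso(S, 0.01, tol = 1e-12, max_iter = 1),
                  error = function(e) e)
  expect_s3_class(err, "glasso_nonconvergence")
  expect_true(is.matrix(err$iterate$W))
})

test_that("EBIC formula reduces to BIC at gamma 0 and penalizes edges", {
  S <- make_spd(5, 43)
  f <- glasso(S, 0.05)
  n <- 500
  ld <- as.numeric(determinant(f$K)$modulus)
  L <- (n / 2) * (ld - sum(S * f$K))
  E <- sum(abs(f$K[upper.tri(f$K)]) > 1e-8)
  expect_equal(ebic(f$K, S, n, gamma = 0), -2 * L + E * log(n))
  expect_equal(ebic(f$K, S, n, gamma = 0.5),
               -2 * L + E * log(n) + 4 * 0.5 * E * log(5))
  # a sparser model with equal likelihood cannot have higher EBIC
  expect_gte(ebic(f$K, S, n, 0.5), ebic(f$K, S, n, 0))
  expect_error(ebic(-diag(5), S, n), "positive definite")
})

test_that("EBIC selection prefers the empty graph under independence", {
  set.seed(44)
  X <- matrix(rnorm(5000 * 9), ncol = 9)
  net <- ebic_glasso(X, method = "pearson")
  expect_lte(net$n_edges, 1)
})

test_that("chain-graph structure is recovered with correct signs", {
  p <- 6
  P <- diag(p)
  for (i in 1:(p - 1)) P[i, i + 1] <- P[i + 1, i] <- -0.3
  ev <- min(eigen(P)$values)
  expect_gt(ev, 0)
  set.seed(45)
  X <- MASS::mvrnorm(5000, rep(0, p), solve(P))
  net <- ebic_glasso(X, method = "pearson")
  W <- net$weights
  for (i in 1:(p - 1)) expect_gt(W[i, i + 1], 0.15)
  # no strong spurious edges beyond the chain
  offchain <- abs(W[abs(row(W) - col(W)) > 1][W[abs(row(W) - col(W)) > 1] != 0])
  if (length(offchain)) expect_lt(max(offchain), 0.1)
})

test_that("edge count grows monotonically along the penalty path", {
  set.seed(46)
  tr <- build_truth_network(9, 0.2, 0.55, 0.7, seed = 46)
  X <- make_item_data(2000, tr, seed = 46)
  expect_no_warning(net <- ebic_glasso(X))
  expect_true(all(diff(net$path$n_edges) >= 0))
  # weights are bounded partial correlations on a zero diagonal
  expect_true(all(abs(net$weights) < 1))
  expect_equal(diag(net$weights), setNames(rep(0, 9), net$nodes))
  expect_true(isSymmetric(net$weights))
})

test_that("doubling n rescales EBIC but leaves the path fits unchanged", {
  set.seed(47)
  X <- matrix(rnorm(800 * 5), ncol = 5)
  S <- correlation_matrix(X, method = "pearson")
  n1 <- ebic_glasso(S = S, n = 800)
  n2 <- ebic_glasso(S = S, n = 1600)
  expect_equal(n1$path$n_edges, n2$path$n_edges)
  expect_equal(n1$path$lambda, n2$path$lambda)
  # re-scoring oracle: EBIC at doubled n recomputed from the same fits
  L1 <- -(n1$path$ebic - n1$path$n_edges * log(800) -
            4 * 0.5 * n1$path$n_edges * log(5)) / 2
  ebic2 <- -2 * (L1 * 2) + n2$path$n_edges * log(1600) +
    4 * 0.5 * n2$path$n_edges * log(5)
  expect_equal(n2$path$ebic[n2$path$converged],
               ebic2[n2$path$converged], tolerance = 1e-8)
})

test_that("covariates as nodes leave unrelated networks unchanged", {
  set.seed(48)
  tr <- build_truth_network(9, 0.2, 0.55, 0.7, seed = 48)
  items <- make_item_data(5000, tr, seed = 48)
  indep_cov <- data.frame(cov = rnorm(5000))
  base <- suppressWarnings(ebic_glasso(items, method = "pearson"))
  adj <- suppressWarnings(
    adjusted_network(items, indep_cov, method = "pearson"))
  expect_lt(max(abs(adj$weights - base$weights)), 0.05)
  expect_equal(adj$nodes, base$nodes)
  expect_equal(length(adj$joint$nodes), 10)
  expect_error(adjusted_network(items, data.frame(k = rep(1, 5000))),
               "constant")
})

test_that("a fully mediating covariate removes the mediated edge", {
  set.seed(49)
  n <- 5000
  m <- rnorm(n) # the mediator
  x1 <- 0.8 * m + 0.6 * rnorm(n)
  x2 <- 0.8 * m + 0.6 * rnorm(n)
  x3 <- rnorm(n)
  items <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  base <- suppressWarnings(ebic_glasso(items, method = "pearson"))
  adj <- suppressWarnings(
    adjusted_network(items, data.frame(m = m), method = "pearson"))
  expect_gt(base$weights["x1", "x2"], 0.3)
  expect_lt(abs(adj$weights["x1", "x2"]), 0.1)
})
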