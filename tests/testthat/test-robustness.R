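stab_stub <- function(correlations, proportions) {
  structure(list(proportions = proportions,
                 correlations = correlations,
                 B = nrow(correlations), seed = 1, n_failed = 0L,
                 strength = rep(1, 9)),
            class = "stability_result")
}

test_that("the CS-coefficient follows its defining criterion", {
  grid <- seq(0.05, 0.75, by = 0.05)
  all1 <- stab_stub(matrix(1, 50, length(grid)), grid)
  expect_equal(cs_coefficient(all1), 0.75)
  all0 <- stab_stub(matrix(0, 50, length(grid)), grid)
  expect_equal(cs_coefficient(all0), 0)
  # exactly proportions <= 0.4 qualify
  cors <- sapply(grid, function(q) if (q <= 0.4) rep(0.9, 100)
                 else c(rep(0.9, 80), rep(0.1, 20)))
  expect_equal(cs_coefficient(stab_stub(cors, grid)), 0.4)
  # monotone: raising every correlation cannot lower the CS-C
  cors2 <- pmin(cors + 0.3, 1)
  expect_gte(cs_coefficient(stab_stub(cors2, grid)),
             cs_coefficient(stab_stub(cors, grid)))
})

test_that("case-dropping correlations stay near 1 on redundant data", {
  set.seed(70)
  tr <- build_truth_network(9, 0.25, 0.5, 0.7, seed = 70)
  base <- make_item_data(400, tr, seed = 70)
  dup <- base[rep(seq_len(nrow(base)), 20), ] # 8000 rows, 20 copies each
  st <- case_drop_bootstrap(dup, proportions = c(0.25, 0.5), B = 12,
                            seed = 1, method = "pearson")
  expect_gte(min(st$correlations, na.rm = TRUE), 0.95)
  # dropping almost nothing leaves centrality intact
  tr2 <- build_truth_network(9, 0.25, 0.5, 0.7, seed = 71)
  items <- make_item_data(3000, tr2, seed = 71)
  st2 <- case_drop_bootstrap(items, proportions = 0.02, B = 12, seed = 2,
                             method = "pearson")
  expect_gte(median(st2$correlations, na.rm = TRUE), 0.99)
})

test_that("median stability decays with the drop proportion", {
  set.seed(72)
  tr <- build_truth_network(9, 0.25, 0.5, 0.7, seed = 72)
  items <- make_item_data(1000, tr, seed = 72)
  st <- case_drop_bootstrap(items, proportions = c(0.1, 0.5, 0.75), B = 40,
                            seed = 3, method = "pearson")
  med <- apply(st$correlations, 2, median, na.rm = TRUE)
  expect_true(med[1] >= med[3])
  # reproducible bit-for-bit under the same seed
  st2 <- case_drop_bootstrap(items, proportions = c(0.1, 0.5, 0.75), B = 40,
                             seed = 3, method = "pearson")
  expect_identical(st$correlations, st2$correlations)
})

test_that("edge bootstrap intervals are ordered and cover null edges", {
  set.seed(73)
  X <- as.data.frame(matrix(rnorm(400 * 4), ncol = 4))
  eb <- edge_bootstrap(X, B = 120, seed = 4, method = "pearson")
  expect_true(all(eb$lower <= eb$mean + 1e-12))
  expect_true(all(eb$mean <= eb$upper + 1e-12))
  # independence truth: intervals should cover 0
  expect_true(all(eb$lower <= 0 & eb$upper >= 0))
  expect_error(edge_bootstrap(X, B = 10), "at least 100")
  # duplicated data shrink the intervals towards points
  tr <- build_truth_network(9, 0.25, 0.5, 0.7, seed = 73)
  dup <- make_item_data(400, tr, seed = 73)[rep(1:400, 25), ]
  eb2 <- edge_bootstrap(dup, B = 100, seed = 5, method = "pearson")
  expect_lt(max(eb2$upper - eb2$lower), 0.1)
})

test_that("the network comparison test is null on identical data", {
  set.seed(74)
  tr <- build_truth_network(9, 0.25, 0.5, 0.7, seed = 74)
  items <- make_item_data(400, tr, seed = 74)
  r <- network_comparison_test(items, items, n_perm = 30, seed = 6,
                               method = "pearson")
  expect_equal(r$strength_diff, 0)
  expect_equal(r$max_edge_diff, 0)
  expect_equal(r$p_strength, 1)
  expect_equal(r$p_edge, 1)
  # p-values can never be exactly zero by the add-one rule
  expect_gt(r$p_strength, 0)
  # reproducibility
  g2 <- make_item_data(400, tr, seed = 75)
  a <- network_comparison_test(items, g2, n_perm = 40, seed = 7,
                               method = "pearson")
  b <- network_comparison_test(items, g2, n_perm = 40, seed = 7,
                               method = "pearson")
  expect_identical(a[c("strength_diff", "p_strength", "p_edge")],
                   b[c("strength_diff", "p_strength", "p_edge")])
})

test_that("a large single-edge difference is detected", {
  set.seed(76)
  n <- 2000
  make_pair <- function(r12) {
    P <- diag(9); P[1, 2] <- P[2, 1] <- -r12
    MASS::mvrnorm(n, rep(0, 9), stats::cov2cor(solve(P)))
  }
  hits <- sapply(1:5, function(i) {
    a <- as.data.frame(make_pair(0.4)); colnames(a) <- paste0("v", 1:9)
    b <- as.data.frame(make_pair(0.0)); colnames(b) <- paste0("v", 1:9)
    r <- network_comparison_test(a, b, n_perm = 60, seed = i,
                                 method = "pearson")
    r$p_edge < 0.05
  })
  expect_gte(mean(hits), 0.6)
})
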