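test_that("truth networks are reproducible, sparse and positive definite", {
  a <- build_truth_network(9, 0.3, 0.2, 0.4, seed = 7)
  b <- build_truth_network(9, 0.3, 0.2, 0.4, seed = 7)
  expect_identical(a, b)
  expect_true(isSymmetric(a$precision))
  expect_gt(min(eigen(a$precision, symmetric = TRUE)$values), 0)
  expect_true(all(abs(a$partials) < 1))
  # partial-correlation identity
  d <- sqrt(diag(a$precision))
  expect_equal(a$partials[1, 2], -a$precision[1, 2] / (d[1] * d[2]))

  empty <- build_truth_network(5, 0, 0.2, 0.4, seed = 1)
  expect_equal(empty$precision, diag(5))
  expect_true(all(empty$partials == 0))
  expect_error(build_truth_network(1, 0.5, 0.1, 0.2), "at least 2")
})

test_that("generated cohorts are deterministic and schema-valid", {
  cfg <- generator_config(n = 200, seed = 9)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(c1, f1); write_cohort_csv(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_s3_class(c1, "cohort_table")
  expect_true(all(as.matrix(c1[, phq_cols]) %in% 0:3))
  expect_true(all(c1$fatigue %in% 0:10))
  expect_true(all(c1$qol_1 %in% 1:5))
})

test_that("extreme thresholds make an item constant", {
  th <- symptomnet:::.default_thresholds()
  th$phq <- c(rep(list(th$phq), 8), list(c(100, 101, 102)))
  co <- generate_cohort(generator_config(n = 100, thresholds = th, seed = 2))
  expect_true(all(co$phq9_9 == 0))
  expect_false(all(co$phq9_1 == 0))
})

test_that("default config hits the calibrated depression prevalence", {
  sc <- score_cohort(generate_cohort(generator_config(n = 10000, seed = 31)))
  expect_lt(abs(100 * mean(sc$depressed) - 33.3), 2)
})

test_that("identity precision yields uncorrelated items", {
  tr <- build_truth_network(9, 0, 0.2, 0.4, seed = 1)
  items <- make_item_data(50000, tr, seed = 4)
  R <- cor(items)
  expect_lt(max(abs(R[upper.tri(R)])), 0.02)
})

test_that("a single strong latent partial surfaces as the largest polychoric", {
  P <- diag(9); P[1, 2] <- P[2, 1] <- -0.45 # strong positive partial
  d <- sqrt(diag(P))
  pa <- -P / outer(d, d); diag(pa) <- 0
  tr <- structure(list(p = 9, precision = P, partials = pa,
                       support = P != 0 & !diag(9), seed = 0),
                  class = "truth_network")
  items <- make_item_data(50000, tr, seed = 5)
  S <- correlation_matrix(items)
  off <- unclass(S); diag(off) <- 0
  expect_gt(S[1, 2], 0)
  expect_equal(max(off), S[1, 2])
})

test_that("marginal category frequencies follow the threshold gaps", {
  co <- generate_cohort(generator_config(n = 50000, seed = 6))
  tau <- symptomnet:::.default_thresholds()$gad
  # gad item latent is standard normal marginally
  expected <- diff(c(0, pnorm(tau), 1))
  observed <- as.numeric(table(factor(co$gad7_1, 0:3)) / nrow(co))
  expect_lt(max(abs(observed - expected)), 0.02)
})

test_that("zero covariate effects decouple depression and QOL", {
  tr <- build_truth_network(9, 0.3, 0.3, 0.5, seed = 11)
  cfg <- generator_config(n = 20000, truth = tr,
                          covariate_effects = list(anx_to_symptoms = 0,
                                                   fat_to_symptoms = 0,
                                                   gad_loading = 0.8,
                                                   dep_to_qol = 0),
                          seed = 8)
  sc <- score_cohort(generate_cohort(cfg))
  diff_means <- abs(mean(sc$qol_global[sc$depressed]) -
                    mean(sc$qol_global[!sc$depressed]))
  expect_lt(diff_means, 0.1)
  # and with the default effect the depressed have clearly lower QOL
  sc2 <- score_cohort(generate_cohort(generator_config(n = 20000, seed = 8)))
  expect_lt(mean(sc2$qol_global[sc2$depressed]),
            mean(sc2$qol_global[!sc2$depressed]) - 0.5)
})

test_that("generator configs can be read from JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n = 50, seed = 3,
                            truth_spec = list(p = 9, edge_density = 0.2,
                                              weight_low = 0.3,
                                              weight_high = 0.5, seed = 2),
                            covariate_effects = list(dep_to_qol = 0.5)),
                       f, auto_unbox = TRUE)
  cfg <- read_generator_config(f)
  expect_s3_class(cfg, "generator_config")
  expect_equal(cfg$n, 50L)
  expect_equal(cfg$covariate_effects$dep_to_qol, 0.5)
  expect_equal(cfg$covariate_effects$anx_to_symptoms, 0.35)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 50)
})
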