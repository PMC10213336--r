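test_that("Wald prevalence interval reproduces hand-computed bounds", {
  r <- prevalence_ci(357, 1101)
  expect_equal(unname(r$percent), c(32.4, 29.7, 35.2))
  # half-width 1.96 * sqrt(.25/100) = 0.098
  r2 <- prevalence_ci(50, 100)
  expect_equal(unname(r2$percent), c(50.0, 40.2, 59.8))
  r3 <- prevalence_ci(0, 100)
  expect_equal(r3$lower, 0)
  expect_equal(r3$proportion, 0)
  expect_error(prevalence_ci(1, 0), "positive")
  # width shrinks as 1/sqrt(n)
  w <- function(n) { x <- prevalence_ci(round(0.3 * n), n); x$upper - x$lower }
  expect_equal(w(1000) / w(4000), 2, tolerance = 0.02)
  # Wilson option brackets the proportion
  rw <- prevalence_ci(5, 20, method = "wilson")
  expect_true(rw$lower < 0.25 && rw$upper > 0.25)
})

test_that("Pearson chi-square has no continuity correction and standard df", {
  t1 <- pearson_chi2(matrix(c(152, 175, 205, 569), 2))
  expect_equal(t1$df, 1L)
  expect_equal(t1$chi2, unname(chisq.test(matrix(c(152, 175, 205, 569), 2),
                                          correct = FALSE)$statistic))
  prop <- matrix(c(10, 20, 30, 60), 2) # proportional rows
  expect_equal(pearson_chi2(prop)$chi2, 0)
  # invariance under permutation and transposition
  m <- matrix(c(90, 144, 248, 512, 19, 88), 2)
  expect_equal(pearson_chi2(m)$chi2, pearson_chi2(t(m))$chi2)
  expect_equal(pearson_chi2(m)$chi2, pearson_chi2(m[2:1, ])$chi2)
  expect_error(pearson_chi2(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(pearson_chi2(matrix(1:3)), "2 rows")
})

test_that("pooled t test matches df = n1+n2-2 and its raw-data variant", {
  expect_equal(pooled_t_test(5, 1, 10, 5, 1, 12)$t, 0)
  r <- pooled_t_test(43.3, 11.4, 744, 42.5, 12.1, 357)
  expect_equal(r$df, 1099)
  expect_true(r$t > 1.0 && r$t < 1.1)
  set.seed(1)
  x <- rnorm(15); y <- rnorm(20, 0.5)
  raw <- pooled_t_raw(x, y)
  summ <- pooled_t_test(mean(x), sd(x), 15, mean(y), sd(y), 20)
  expect_equal(raw$t, summ$t, tolerance = 1e-10)
  expect_equal(raw$t, unname(t.test(x, y, var.equal = TRUE)$statistic),
               tolerance = 1e-10)
  expect_error(pooled_t_test(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("rank-sum Z handles ties and matches an exact permutation oracle", {
  expect_warning(r0 <- wilcoxon_rank_sum(rep(1, 4), rep(1, 5)), "identical")
  expect_equal(r0$Z, 0)
  # disjoint supports, n = 30 each
  r <- wilcoxon_rank_sum(rnorm(30) + 100, rnorm(30))
  expect_gt(abs(r$Z), 6)
  # brute-force permutation distribution of the rank sum, n1 = n2 = 8
  exact_two_sided <- function(x, y) {
    obs <- wilcoxon_rank_sum(x, y)
    r_all <- rank(c(x, y))
    Ws <- colSums(matrix(r_all[utils::combn(16, 8)], nrow = 8))
    mu <- mean(Ws)
    c(approx = obs$p, exact = mean(abs(Ws - mu) >= abs(obs$W - mu) - 1e-9))
  }
  set.seed(4)
  shifted <- exact_two_sided(rnorm(8), rnorm(8, 0.8))
  expect_lt(abs(shifted["approx"] - shifted["exact"]), 0.01)
  set.seed(6)
  nullcase <- exact_two_sided(rnorm(8), rnorm(8))
  expect_lt(abs(nullcase["approx"] - nullcase["exact"]), 0.05)
})

test_that("ANCOVA group F reduces to the squared pooled t without covariates", {
  set.seed(4)
  y <- rnorm(100); g <- rep(c(TRUE, FALSE), 50)
  a <- ancova_group_effect(y, g)
  t <- pooled_t_raw(y[!g], y[g])
  expect_equal(a$F, t$t^2, tolerance = 1e-8)
  expect_equal(a$df1, 1L)
  expect_equal(a$df2, 98)
  # aliased covariate is reported
  expect_error(ancova_group_effect(y, g, data.frame(gg = as.numeric(g))),
               "rank-deficient")
})

test_that("ANCOVA p-values are uniform under a permuted null", {
  set.seed(5)
  n <- 500
  y <- rnorm(n); x <- rnorm(n)
  ps <- replicate(200, {
    g <- sample(rep(c(TRUE, FALSE), n / 2))
    ancova_group_effect(y, g, data.frame(x = x))$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})
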