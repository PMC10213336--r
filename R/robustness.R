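#' Case-dropping bootstrap for centrality stability
#'
#' For every drop proportion q on the grid and each of B replicates, a
#' subsample of \eqn{\lceil n(1-q) \rceil} rows is drawn without
#' replacement, the network re-estimated, and the Pearson correlation
#' between the subsample and full-sample strength vectors recorded.
#' Replicates whose re-estimation fails are recorded as `NA` and counted.
#'
#' @param data Data frame/matrix of item columns.
#' @param proportions Increasing grid of drop proportions in (0, 1)
#'   (default 0.05 to 0.75 by 0.05).
#' @param B Bootstrap replicates per proportion (1000 for full runs;
#'   reduce for quick checks).
#' @param seed Integer seed; the whole procedure is reproducible.
#' @param ... Network options passed to [ebic_glasso()].
#' @return A `stability_result`: `proportions`, `correlations` (B x
#'   length(grid) matrix), `B`, `seed`, `n_failed`, and the full-sample
#'   `strength` vector.
#' @export
case_drop_bootstrap <- function(data, proportions = seq(0.05, 0.75, by = 0.05),
                                B = 1000, seed = 1L, ...) {
  data <- as.data.frame(data)
  n <- nrow(data)
  stopifnot(all(diff(proportions) > 0), all(proportions > 0),
            all(proportions < 1))
  full <- ebic_glasso(data, ...)
  p <- length(full$nodes)
  if (n * (1 - max(proportions)) <= p)
    stop("largest drop proportion leaves too few rows", call. = FALSE)
  s_full <- strength_centrality(full)$strength

  set.seed(seed)
  cors <- matrix(NA_real_, B, length(proportions),
                 dimnames = list(NULL, paste0("q", proportions)))
  n_failed <- 0L
  for (j in seq_along(proportions)) {
    m <- ceiling(n * (1 - proportions[j]))
    for (b in seq_len(B)) {
      idx <- sample.int(n, m)
      s_sub <- tryCatch({
        fit <- suppressWarnings(ebic_glasso(data[idx, , drop = FALSE], ...))
        strength_centrality(fit)$strength
      }, error = function(e) NULL)
      if (is.null(s_sub) || sd(s_sub) == 0 || sd(s_full) == 0) {
        n_failed <- n_failed + 1L
      } else {
        cors[b, j] <- cor(s_sub, s_full)
      }
    }
  }
  structure(list(proportions = proportions, correlations = cors, B = B,
                 seed = seed, n_failed = n_failed, strength = s_full),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Case-dropping stability bootstrap (B = ", x$B, ")\n", sep = "")
  med <- apply(x$correlations, 2, stats::median, na.rm = TRUE)
  cat("  median strength correlation by drop proportion:\n")
  print(round(setNames(med, paste0(100 * x$proportions, "%")), 3))
  cat(sprintf("  CS-coefficient: %.2f\n", cs_coefficient(x)))
  invisible(x)
}

#' Correlation-stability coefficient
#'
#' The largest drop proportion on the grid at which, with probability at
#' least `prob` across bootstrap replicates, the subsample strength vector
#' still correlates at least `r_threshold` with the full-sample one
#' (equivalently, the empirical 5th percentile of the correlations is at or
#' above the threshold).  Values of at least 0.25 are minimally acceptable
#' and at least 0.5 preferred.  Returns 0 if no grid point qualifies.
#'
#' @param result A `stability_result`.
#' @param r_threshold Correlation threshold (default 0.7).
#' @param prob Required probability (default 0.95).
#' @return The CS-coefficient (a proportion in [0, max grid]).
#' @export
cs_coefficient <- function(result, r_threshold = 0.7, prob = 0.95) {
  stopifnot(inherits(result, "stability_result"),
            length(result$proportions) > 0)
  ok <- vapply(seq_along(result$proportions), function(j) {
    v <- result$correlations[, j]
    v <- v[!is.na(v)]
    length(v) > 0 && mean(v >= r_threshold) >= prob
  }, TRUE)
  if (!any(ok)) 0 else max(result$proportions[ok])
}

#' Nonparametric bootstrap of edge-weight accuracy
#'
#' Rows are resampled with replacement B times, the network re-estimated,
#' and per-edge bootstrap means with 2.5/97.5 percentile intervals
#' collected.  When an edge is selected in fewer than 2.5% of resamples the
#' raw percentile bounds can exclude the (tiny) bootstrap mean; the
#' interval is widened to always contain the mean.
#'
#' @inheritParams case_drop_bootstrap
#' @param B Number of resamples (>= 100).
#' @return An `edge_bootstrap` data frame: `node_a`, `node_b`, `sample`
#'   (full-data weight), `mean`, `lower`, `upper`, with attributes `B`,
#'   `seed`, `n_failed`.
#' @export
edge_bootstrap <- function(data, B = 1000, seed = 1L, ...) {
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  data <- as.data.frame(data)
  n <- nrow(data)
  full <- ebic_glasso(data, ...)
  ut <- upper.tri(full$weights)
  idxm <- which(ut, arr.ind = TRUE)
  draws <- matrix(NA_real_, B, sum(ut))
  set.seed(seed)
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    w <- tryCatch(suppressWarnings(
      ebic_glasso(data[idx, , drop = FALSE], ...))$weights[ut],
      error = function(e) NULL)
    if (is.null(w)) n_failed <- n_failed + 1L else draws[b, ] <- w
  }
  mn <- colMeans(draws, na.rm = TRUE)
  out <- data.frame(
    node_a = full$nodes[idxm[, 1]], node_b = full$nodes[idxm[, 2]],
    sample = full$weights[ut],
    mean = mn,
    lower = pmin(apply(draws, 2, quantile, 0.025, na.rm = TRUE), mn),
    upper = pmax(apply(draws, 2, quantile, 0.975, na.rm = TRUE), mn))
  structure(out, class = c("edge_bootstrap", "data.frame"),
            B = B, seed = seed, n_failed = n_failed)
}

.global_strength <- function(net) sum(abs(net$weights[upper.tri(net$weights)]))

#' Permutation test comparing two groups' networks
#'
#' Networks are estimated separately per group; the observed statistics are
#' the absolute difference in global strength (sum of absolute
#' upper-triangle edge weights) and the maximum absolute edge-weight
#' difference.  The null distribution is obtained by pooling the rows,
#' permuting group labels at the original group sizes, and re-estimating
#' both networks; p-values use the add-one rule
#' \eqn{p = (1 + \#\{perm \ge obs\})/(1 + n_{perm})} and so are never 0.
#'
#' @param data_a,data_b Item data for the two groups (same columns).
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param ... Network options passed to [ebic_glasso()].
#' @return An `nct_result`: `strength_diff`, `max_edge_diff`,
#'   `p_strength`, `p_edge`, `n_perm`, `seed`.
#' @export
network_comparison_test <- function(data_a, data_b, n_perm = 1000, seed = 1L,
                                    ...) {
  data_a <- as.data.frame(data_a); data_b <- as.data.frame(data_b)
  stopifnot(identical(colnames(data_a), colnames(data_b)))
  p <- ncol(data_a)
  if (nrow(data_a) <= p || nrow(data_b) <= p)
    stop("each group needs more rows than nodes", call. = FALSE)

  fit_stats <- function(da, db) {
    na <- suppressWarnings(ebic_glasso(da, ...))
    nb <- suppressWarnings(ebic_glasso(db, ...))
    c(strength = abs(.global_strength(na) - .global_strength(nb)),
      edge = max(abs(na$weights - nb$weights)))
  }
  obs <- fit_stats(data_a, data_b)

  pooled <- rbind(data_a, data_b)
  n1 <- nrow(data_a); N <- nrow(pooled)
  set.seed(seed)
  perm <- matrix(NA_real_, n_perm, 2)
  for (i in seq_len(n_perm)) {
    ia <- sample.int(N, n1)
    perm[i, ] <- tryCatch(
      fit_stats(pooled[ia, , drop = FALSE], pooled[-ia, , drop = FALSE]),
      error = function(e) c(NA_real_, NA_real_))
  }
  ok <- stats::complete.cases(perm)
  pval <- function(col) (1 + sum(perm[ok, col] >= obs[col])) / (1 + sum(ok))
  structure(list(strength_diff = unname(obs["strength"]),
                 max_edge_diff = unname(obs["edge"]),
                 p_strength = pval(1), p_edge = pval(2),
                 n_perm = sum(ok), seed = seed),
            class = "nct_result")
}

#' @export
print.nct_result <- function(x, ...) {
  cat("Network comparison test (", x$n_perm, " permutations)\n", sep = "")
  cat(sprintf("  global strength difference: %.4f (p = %.3f)\n",
              x$strength_diff, x$p_strength))
  cat(sprintf("  maximum edge difference:    %.4f (p = %.3f)\n",
              x$max_edge_diff, x$p_edge))
  invisible(x)
}
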