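#' Prevalence with a normal-approximation confidence interval
#'
#' Wald interval \eqn{p \pm z_{1-\alpha/2}\sqrt{p(1-p)/n}}, clipped to
#' [0, 1]; a Wilson score interval is available as an option.
#'
#' @param k Number of cases.
#' @param n Number of respondents (> 0).
#' @param alpha Two-sided error rate (default 0.05).
#' @param method `"wald"` (default) or `"wilson"`.
#' @return A list with `proportion`, `lower`, `upper` (proportions in
#'   [0, 1]) and `percent`, a length-3 vector rounded to one decimal on the
#'   percentage scale.
#' @examples
#' prevalence_ci(357, 1101)$percent # 32.4 (29.7, 35.2)
#' @export
prevalence_ci <- function(k, n, alpha = 0.05, method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("k must be in 0..n", call. = FALSE)
  p <- k / n
  z <- qnorm(1 - alpha / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- max(0, p - half); hi <- min(1, p + half)
  } else {
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- max(0, ctr - half); hi <- min(1, ctr + half)
  }
  list(proportion = p, lower = lo, upper = hi,
       percent = round(100 * c(estimate = p, lower = lo, upper = hi), 1),
       method = method, k = k, n = n)
}

#' Pearson chi-square test on a contingency table
#'
#' Classic Pearson statistic \eqn{\sum (O-E)^2/E} with expected counts from
#' the margins and no continuity correction, df = (r-1)(c-1).
#'
#' @param table An r x c matrix of nonnegative counts (r, c >= 2).
#' @return List with `chi2`, `df`, `p`, `expected`.
#' @export
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("contingency table needs at least 2 rows and 2 columns",
         call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers", call. = FALSE)
  N <- sum(table)
  if (N <= 0) stop("empty table", call. = FALSE)
  rm <- rowSums(table); cm <- colSums(table)
  if (any(rm == 0) || any(cm == 0))
    stop("zero row or column margin", call. = FALSE)
  E <- outer(rm, cm) / N
  chi2 <- sum((table - E)^2 / E)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       expected = E)
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Student's t with the pooled variance estimate and df = n1 + n2 - 2, as
#' used when comparing group means reported as mean (SD).  `pooled_t_raw()`
#' is the raw-data variant and agrees with the summary form evaluated at
#' the sample moments.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("negative SD", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) 0 else (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

#' @param x,y Raw samples for the two groups.
#' @rdname pooled_t_test
#' @export
pooled_t_raw <- function(x, y) {
  pooled_t_test(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' Wilcoxon rank-sum test with normal approximation
#'
#' Mid-ranks for ties; Z from the normal approximation with tie-corrected
#' variance and no continuity correction; two-sided p.
#'
#' @param x,y Nonempty numeric samples.
#' @return List with `Z`, `p`, and the rank-sum statistic `W` of `x`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty",
                                     call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * (N + 1 - tie_term)
  if (v <= 0) {
    warning("all values identical; Z set to 0")
    return(list(Z = 0, p = 1, W = W))
  }
  Z <- (W - mu) / sqrt(v)
  list(Z = Z, p = 2 * pnorm(abs(Z), lower.tail = FALSE), W = W)
}

#' ANCOVA: group effect on an outcome after covariate adjustment
#'
#' Fits the linear model `y ~ group + covariates` and tests the group term
#' by its Type-III partial F (extra sum of squares of the group term given
#' all covariates).  Adjusted group means are evaluated at covariate means.
#'
#' @param y Numeric outcome (e.g. global QOL).
#' @param group Binary grouping vector (logical or two-level factor).
#' @param covariates Optional data frame or matrix of covariates (numeric
#'   or coded).
#' @return An `ancova_result` list: `F`, `df1`, `df2`, `p`,
#'   `adjusted_means`.
#' @export
ancova_group_effect <- function(y, group, covariates = NULL) {
  group <- as.logical(group)
  stopifnot(length(unique(group)) == 2, length(y) == length(group))
  dat <- data.frame(y = y, group = group)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(y))
    dat <- cbind(dat, covariates)
  }
  full <- lm(y ~ ., data = dat)
  if (any(is.na(coef(full)))) {
    bad <- names(coef(full))[is.na(coef(full))]
    stop("rank-deficient design; aliased column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  reduced <- lm(y ~ . - group, data = dat)
  a <- anova(reduced, full)
  Fv <- a$F[2]; df1 <- a$Df[2]; df2 <- full$df.residual
  nd <- dat[c(which(!dat$group)[1], which(dat$group)[1]), , drop = FALSE]
  for (cn in setdiff(names(nd), c("y", "group")))
    if (is.numeric(nd[[cn]])) nd[[cn]] <- mean(dat[[cn]])
  adj <- stats::predict(full, newdata = nd)
  structure(list(F = Fv, df1 = df1, df2 = df2, p = a$`Pr(>F)`[2],
                 adjusted_means = setNames(as.numeric(adj),
                                           c("group=FALSE", "group=TRUE"))),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA group effect: F(%d, %d) = %.2f, p = %.3g\n",
              x$df1, x$df2, x$F, x$p))
  cat(sprintf("  adjusted means: %.2f (non-group) vs %.2f (group)\n",
              x$adjusted_means[1], x$adjusted_means[2]))
  invisible(x)
}
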