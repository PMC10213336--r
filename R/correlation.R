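# Gauss-Legendre nodes on [0, 1], cached at first use (correlation integrals)
.gl_env <- new.env(parent = emptyenv())
.gl_nodes <- function(n = 32) {
  key <- paste0("n", n)
  if (is.null(.gl_env[[key]]))
    .gl_env[[key]] <- pracma::gaussLegendre(n, 0, 1)
  .gl_env[[key]]
}

#' Standard bivariate normal CDF
#'
#' \eqn{P(X \le h, Y \le k)} for standard normal margins with correlation
#' `rho`, via the single-integral identity
#' \eqn{\Phi_2(h,k;\rho) = \Phi(h)\Phi(k) + \frac{1}{2\pi}\int_0^\rho
#' \frac{1}{\sqrt{1-r^2}} \exp\!\big(-\frac{h^2-2rhk+k^2}{2(1-r^2)}\big)dr}
#' evaluated by Gauss-Legendre quadrature.  Infinite limits are handled.
#'
#' @param h,k Upper limits (may be `-Inf`/`Inf`).
#' @param rho Correlation, |rho| < 1.
#' @return The rectangle probability.
#' @export
pbvnorm <- function(h, k, rho) {
  stopifnot(length(h) == 1, length(k) == 1, abs(rho) < 1)
  if (is.infinite(h) && h < 0) return(0)
  if (is.infinite(k) && k < 0) return(0)
  if (is.infinite(h)) return(pnorm(k))
  if (is.infinite(k)) return(pnorm(h))
  if (rho == 0) return(pnorm(h) * pnorm(k))
  gl <- .gl_nodes(32)
  r <- rho * gl$x
  f <- exp(-(h^2 - 2 * r * h * k + k^2) / (2 * (1 - r^2))) / sqrt(1 - r^2)
  pnorm(h) * pnorm(k) + rho * sum(gl$w * f) / (2 * pi)
}

.ord_thresholds <- function(x) {
  tab <- table(x)
  cum <- cumsum(tab) / length(x)
  c(-Inf, qnorm(cum[-length(cum)]), Inf)
}

#' Polychoric correlation of two ordinal variables
#'
#' Two-step estimator: category thresholds from the marginal cumulative
#' proportions via the inverse normal CDF, then the latent correlation
#' maximizing the bivariate-normal likelihood of the observed contingency
#' table.  Falls back to Spearman (with a warning) if the likelihood cannot
#' be evaluated.
#'
#' @param x,y Ordinal vectors (integer-coded), each with >= 2 observed
#'   categories.
#' @return The estimated latent correlation (scalar in (-1, 1)).
#' @export
polychoric_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("polychoric correlation requires >= 2 observed categories per variable",
         call. = FALSE)
  tx <- .ord_thresholds(x)
  ty <- .ord_thresholds(y)
  counts <- table(x, y)
  nr <- nrow(counts); nc <- ncol(counts)
  nll <- function(rho) {
    Pu <- matrix(0, nr + 1, nc + 1)
    for (i in seq_len(nr + 1))
      for (j in seq_len(nc + 1))
        Pu[i, j] <- pbvnorm(tx[i], ty[j], rho)
    # NOTE: tx has nr+1 entries including -Inf/Inf
    P <- Pu[-1, -1] - Pu[-(nr + 1), -1] - Pu[-1, -(nc + 1)] +
      Pu[-(nr + 1), -(nc + 1)]
    -sum(counts * log(pmax(P, 1e-300)))
  }
  fit <- tryCatch(optimize(nll, c(-0.999, 0.999), tol = 1e-7),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$objective)) {
    warning("polychoric likelihood failed; falling back to Spearman")
    return(cor(x, y, method = "spearman"))
  }
  fit$minimum
}

.is_ordinal <- function(v, max_levels = 12) {
  u <- unique(v[!is.na(v)])
  length(u) <= max_levels && all(u == round(u))
}

#' Repair a symmetric matrix to positive semidefiniteness
#'
#' Eigenvalues below 1e-6 are clipped to 1e-6 and the matrix renormalized
#' to unit diagonal.  Pairwise-estimated correlation matrices (polychoric
#' in particular) need not be PSD; the graphical lasso requires it.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @return List with `R` (the possibly repaired matrix) and `repaired`.
#' @export
repair_psd <- function(R) {
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) >= 1e-6) return(list(R = R, repaired = FALSE))
  vals <- pmax(ev$values, 1e-6)
  R2 <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
  list(R = stats::cov2cor(R2), repaired = TRUE)
}

#' Pairwise correlation matrix with positive-semidefinite repair
#'
#' Computes all pairwise correlations with the requested method.  With
#' `method = "polychoric"`, pairs of ordinal variables (integer-coded, at
#' most 12 levels) use the polychoric estimator and any pair involving a
#' continuous variable falls back to Pearson on the scores (a polyserial
#' approximation).  Because pairwise estimates need not form a PSD matrix,
#' negative eigenvalues are clipped at 1e-6 and the matrix renormalized to
#' unit diagonal; the repair is recorded in the `repaired` attribute.
#'
#' @param data Data frame or matrix with >= 2 numeric columns.
#' @param method `"polychoric"` (default), `"pearson"` or `"spearman"`.
#' @return A `correlation_matrix`: the p x p matrix with attributes
#'   `method`, `n`, `repaired`.
#' @export
correlation_matrix <- function(data,
                               method = c("polychoric", "pearson", "spearman")) {
  method <- match.arg(method)
  X <- as.matrix(as.data.frame(data))
  storage.mode(X) <- "double"
  p <- ncol(X)
  if (p < 2) stop("need at least 2 columns", call. = FALSE)
  R <- diag(p)
  if (method != "polychoric") {
    R <- cor(X, method = method)
  } else {
    ords <- apply(X, 2, .is_ordinal)
    for (i in seq_len(p - 1))
      for (j in (i + 1):p) {
        R[i, j] <- R[j, i] <- if (ords[i] && ords[j])
          polychoric_corr(X[, i], X[, j])
        else cor(X[, i], X[, j])
      }
  }
  rep_out <- repair_psd(R)
  R <- rep_out$R
  repaired <- rep_out$repaired
  dimnames(R) <- list(colnames(X), colnames(X))
  structure(R, class = c("correlation_matrix", "matrix"),
            method = method, n = nrow(X), repaired = repaired)
}
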