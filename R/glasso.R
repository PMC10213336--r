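#' Graphical lasso: L1-penalized sparse precision estimation
#'
#' Maximizes \eqn{\log\det K - \mathrm{tr}(SK) - \lambda \sum_{i \ne j}
#' |K_{ij}|} (off-diagonal penalty only, diagonal unpenalized) by block
#' coordinate descent with inner lasso solves.  Convergence is declared
#' when the mean absolute off-diagonal change of the covariance iterate W
#' falls below `tol` times the mean absolute off-diagonal of S.
#'
#' @param S Correlation (or covariance) matrix, PSD.
#' @param lambda Penalty, >= 0.
#' @param tol Relative convergence tolerance.
#' @param max_iter Maximum sweeps.
#' @param W_init Optional warm-start covariance iterate.
#' @param trace If `TRUE`, record the solver merit (log det W) per sweep.
#' @return List with `W` (covariance estimate), `K` (precision estimate),
#'   `converged`, `iter`, and `logdet_trace` when traced.  If `max_iter` is
#'   reached a `glasso_nonconvergence` error is raised carrying the last
#'   iterate in its `iterate` field.
#' @export
glasso <- function(S, lambda, tol = 1e-4, max_iter = 200, W_init = NULL,
                   trace = FALSE) {
  S <- unclass(as.matrix(S))
  stopifnot(isSymmetric(S, tol = 1e-8), lambda >= 0)
  fit <- .glasso_cpp(S, lambda, tol, as.integer(max_iter), W_init, trace)
  if (!fit$converged) {
    cond <- structure(
      class = c("glasso_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "glasso did not converge in %d iterations (lambda = %g)",
        max_iter, lambda),
        call = sys.call(-1), iterate = fit))
    stop(cond)
  }
  dimnames(fit$W) <- dimnames(fit$K) <- dimnames(S)
  fit
}

#' Extended Bayesian information criterion of a precision estimate
#'
#' \eqn{EBIC = -2L + E\,\ln n + 4 E \gamma \ln p} with
#' \eqn{L = (n/2)(\log\det K - \mathrm{tr}(SK))} and E the number of
#' nonzero upper-triangle off-diagonal entries of K (entries below 1e-8 in
#' magnitude count as structural zeros).  With `gamma = 0` this is the
#' ordinary BIC penalty.
#'
#' @param K Precision estimate (positive definite).
#' @param S The correlation matrix the model was fit to.
#' @param n Sample size.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @return The EBIC value (smaller is better).
#' @export
ebic <- function(K, S, n, gamma = 0.5) {
  K <- as.matrix(K); S <- unclass(as.matrix(S))
  p <- nrow(K)
  ld <- determinant(K, logarithm = TRUE)
  if (ld$sign <= 0) stop("precision estimate is not positive definite",
                         call. = FALSE)
  L <- (n / 2) * (as.numeric(ld$modulus) - sum(S * K))
  E <- sum(abs(K[upper.tri(K)]) > 1e-8)
  -2 * L + E * log(n) + 4 * E * gamma * log(p)
}

.partials_from_K <- function(K, zero_tol = 1e-8) {
  d <- sqrt(diag(K))
  Wts <- -K / outer(d, d)
  diag(Wts) <- 0
  Wts[abs(Wts) < zero_tol] <- 0
  (Wts + t(Wts)) / 2
}

#' Regularized partial-correlation network with EBIC penalty selection
#'
#' The package's central model fit.  A correlation matrix of the item
#' columns (polychoric by default, the convention for 0--3 ordinal symptom
#' ratings) is fed to a graphical-lasso path of `n_lambda` penalties,
#' log-spaced from \eqn{\lambda_{max}} (the largest absolute off-diagonal
#' correlation, giving an empty network) down to
#' `lambda_min_ratio` \eqn{\times \lambda_{max}}; the penalty minimizing
#' the extended BIC is selected.  Edge weights are the partial correlations
#' \eqn{w_{ij} = -K_{ij}/\sqrt{K_{ii}K_{jj}}} of the selected precision
#' estimate.
#'
#' @param data Data frame or matrix of item columns (one node per column),
#'   or `NULL` if `S` and `n` are supplied directly.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda Number of penalties on the path.
#' @param lambda_min_ratio Smallest penalty as a fraction of
#'   \eqn{\lambda_{max}}.
#' @param method Correlation method passed to [correlation_matrix()].
#' @param S Optional precomputed `correlation_matrix` (with `n` required).
#' @param n Sample size when `S` is supplied.
#' @param tol,max_iter Solver controls, see [glasso()].
#' @return A `symptom_network` object: `weights` (partial-correlation
#'   adjacency, zero diagonal), `K`, `lambda`, `gamma`, `ebic`, `n_edges`,
#'   `nodes`, `n`, the full `path` diagnostics, and the input correlation
#'   matrix.
#' @export
ebic_glasso <- function(data = NULL, gamma = 0.5, n_lambda = 100,
                        lambda_min_ratio = 0.01,
                        method = c("polychoric", "pearson", "spearman"),
                        S = NULL, n = NULL, tol = 1e-4, max_iter = 200) {
  method <- match.arg(method)
  if (is.null(S)) {
    stopifnot(!is.null(data))
    S <- correlation_matrix(data, method = method)
    n <- attr(S, "n")
  } else {
    stopifnot(!is.null(n))
    if (is.null(attr(S, "method"))) attr(S, "method") <- method
  }
  Sm <- unclass(as.matrix(S))
  p <- ncol(Sm)
  if (n <= p) warning("sample size does not exceed node count; ",
                      "estimates will be heavily regularized")
  nodes <- colnames(Sm)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))

  lambda_max <- max(abs(Sm[upper.tri(Sm)]))
  if (lambda_max <= 0) lambda_max <- 1e-4
  lambdas <- exp(seq(log(lambda_max), log(lambda_min_ratio * lambda_max),
                     length.out = n_lambda))
  pathfit <- .glasso_path_cpp(Sm, lambdas, tol, as.integer(max_iter))
  conv <- pathfit$converged & is.finite(pathfit$logdetK)
  if (!any(conv)) stop("no glasso fit on the penalty path converged",
                       call. = FALSE)
  E <- vapply(pathfit$K, function(K) sum(abs(.partials_from_K(K)[upper.tri(K)]) > 0),
              0L)
  # along decreasing lambda the active set should only grow
  if (any(diff(E[conv]) < 0))
    warning("edge count not monotone along the penalty path")
  L <- (n / 2) * (pathfit$logdetK - pathfit$trSK)
  ebic_vals <- -2 * L + E * log(n) + 4 * E * gamma * log(p)
  ebic_vals[!conv] <- Inf
  best <- which.min(ebic_vals)
  K <- pathfit$K[[best]]
  dimnames(K) <- list(nodes, nodes)
  weights <- .partials_from_K(K)
  dimnames(weights) <- list(nodes, nodes)

  structure(list(weights = weights, K = K, lambda = lambdas[best],
                 gamma = gamma, ebic = ebic_vals[best],
                 n_edges = sum(abs(weights[upper.tri(weights)]) > 0),
                 nodes = nodes, n = n,
                 method = attr(S, "method"),
                 repaired = isTRUE(attr(S, "repaired")),
                 correlation = Sm,
                 path = data.frame(lambda = lambdas, n_edges = E,
                                   ebic = ebic_vals, converged = conv)),
            class = "symptom_network")
}

#' Covariate-adjusted symptom network
#'
#' Re-estimates the symptom network with the covariates included as
#' additional nodes in one joint EBIC-gLASSO fit, so that symptom--symptom
#' edges become partial correlations conditioned on the covariates as well
#' as on the other symptoms.  The returned network is the symptom subgraph;
#' the full joint network is kept in the `joint` field.
#'
#' @param data Data frame/matrix of symptom item columns.
#' @param covariates Data frame/matrix of covariate columns (e.g. anxiety
#'   total and fatigue); constant columns are an error.
#' @param ... Passed to [ebic_glasso()].
#' @return A `symptom_network` over the symptom nodes with a `joint` field.
#' @export
adjusted_network <- function(data, covariates, ...) {
  covariates <- as.data.frame(covariates)
  const <- vapply(covariates, function(v) var(as.numeric(v)) == 0, TRUE)
  if (any(const))
    stop("constant covariate(s): ", paste(names(covariates)[const],
                                          collapse = ", "), call. = FALSE)
  joint_data <- cbind(as.data.frame(data), covariates)
  joint <- ebic_glasso(joint_data, ...)
  keep <- seq_len(ncol(as.data.frame(data)))
  sub <- joint
  sub$weights <- joint$weights[keep, keep, drop = FALSE]
  sub$K <- joint$K[keep, keep, drop = FALSE]
  sub$nodes <- joint$nodes[keep]
  sub$n_edges <- sum(abs(sub$weights[upper.tri(sub$weights)]) > 0)
  sub$correlation <- joint$correlation[keep, keep, drop = FALSE]
  sub$joint <- joint
  sub$adjusted_for <- colnames(covariates)
  sub
}

#' @export
print.symptom_network <- function(x, ...) {
  cat("EBIC-gLASSO partial-correlation network\n")
  cat(sprintf("  %d nodes, %d edges (lambda = %.4f, gamma = %.2f, EBIC = %.1f)\n",
              length(x$nodes), x$n_edges, x$lambda, x$gamma, x$ebic))
  cat(sprintf("  correlation input: %s, n = %d%s\n", x$method, x$n,
              if (x$repaired) " (PSD-repaired)" else ""))
  if (!is.null(x$adjusted_for))
    cat("  adjusted for:", paste(x$adjusted_for, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.symptom_network <- function(object, ...) object$weights

#' @export
summary.symptom_network <- function(object, ...) {
  cent <- strength_centrality(object)
  out <- list(network = object, centrality = cent,
              edges = network_edges(object))
  class(out) <- "summary.symptom_network"
  out
}

#' @export
print.summary.symptom_network <- function(x, ...) {
  print(x$network)
  cat("\nStrength centrality:\n")
  print(x$centrality, row.names = FALSE)
  cat("\nTop edges:\n")
  e <- x$edges[order(-abs(x$edges$weight)), ]
  print(head(e, 10), row.names = FALSE)
  invisible(x)
}

#' Edge list of a network
#'
#' @param network A `symptom_network`.
#' @param all If `FALSE` (default) only nonzero edges are returned.
#' @return Data frame `node_a`, `node_b`, `weight` (upper triangle).
#' @export
network_edges <- function(network, all = FALSE) {
  W <- network$weights
  p <- ncol(W)
  idx <- which(upper.tri(W), arr.ind = TRUE)
  out <- data.frame(node_a = network$nodes[idx[, 1]],
                    node_b = network$nodes[idx[, 2]],
                    weight = W[idx])
  if (!all) out <- out[out$weight != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot a symptom network
#'
#' Circular layout; edge width proportional to |weight|, green for positive
#' and red for negative partial correlations, node size proportional to
#' strength centrality.
#'
#' @param x A `symptom_network`.
#' @param ... Unused.
#' @export
plot.symptom_network <- function(x, ...) {
  p <- length(x$nodes)
  ang <- seq(0, 2 * pi, length.out = p + 1)[-1]
  xy <- cbind(cos(ang), sin(ang))
  graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1,
                 axes = FALSE, xlab = "", ylab = "")
  e <- network_edges(x)
  if (nrow(e)) {
    ia <- match(e$node_a, x$nodes); ib <- match(e$node_b, x$nodes)
    graphics::segments(xy[ia, 1], xy[ia, 2], xy[ib, 1], xy[ib, 2],
                       lwd = 8 * abs(e$weight) + 0.2,
                       col = ifelse(e$weight > 0, "darkgreen", "firebrick"))
  }
  s <- strength_centrality(x)$strength
  graphics::points(xy, cex = 1.5 + 3 * s / max(max(s), 1e-9), pch = 21,
                   bg = "lightsteelblue")
  graphics::text(xy * 1.18, labels = x$nodes, cex = 0.8)
  invisible(x)
}
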