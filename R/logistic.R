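#' Multiple logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Wald standard errors, odds ratios
#' and normal-approximation CIs \eqn{\exp(\hat\beta \pm z \cdot SE)}.  The
#' IRLS iterations are run explicitly so that the log-likelihood trace is
#' available; non-convergence and (quasi-)complete separation are flagged
#' rather than silently accepted.
#'
#' @param outcome Logical (or 0/1) response vector.
#' @param design Numeric matrix or data frame of coded covariates (no
#'   intercept column; one is added).
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the relative deviance change.
#' @param conf_level Confidence level for the Wald CIs.
#' @return A `logistic_fit` object: `coefficients` (data frame with
#'   estimate, se, z, p, OR, OR CI per term), `converged`, `separation`,
#'   `loglik`, `loglik_trace`, `n`.
#' @export
fit_logistic <- function(outcome, design, max_iter = 100, tol = 1e-10,
                         conf_level = 0.95) {
  y <- as.numeric(outcome)
  stopifnot(all(y %in% c(0, 1)))
  X <- as.matrix(cbind(`(Intercept)` = 1, as.data.frame(design)))
  storage.mode(X) <- "double"
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("outcome/design length mismatch", call. = FALSE)
  if (n <= k) stop("more parameters than observations", call. = FALSE)
  if (qr(X)$rank < k)
    stop("design matrix is rank deficient (constant or collinear columns)",
         call. = FALSE)

  beta <- rep(0, k)
  ll <- function(b) {
    eta <- drop(X %*% b)
    # log(1 + e^eta), numerically stable for large |eta|
    lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
    sum(y * eta - lse)
  }
  trace <- ll(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    l_new <- ll(beta_new)
    # step-halve if the likelihood would decrease (keeps the trace monotone)
    dir <- beta_new - beta
    step <- 1
    while (l_new < trace[length(trace)] && step > 1e-8) {
      step <- step / 2
      beta_new <- beta + step * dir
      l_new <- ll(beta_new)
    }
    trace <- c(trace, l_new)
    done <- abs(l_new - trace[length(trace) - 1]) <
      tol * (abs(l_new) + tol)
    beta <- beta_new
    if (done) { converged <- TRUE; break }
  }

  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  separation <- any(abs(beta[-1]) > 15) ||
    (all(mu[y == 1] > 1 - 1e-6) && all(mu[y == 0] < 1e-6))
  if (separation)
    warning("possible complete separation: coefficient estimates diverge")
  if (!converged)
    warning("IRLS did not converge in ", max_iter, " iterations")

  W <- mu * (1 - mu)
  info <- t(X * W) %*% X
  cov <- tryCatch(solve(info), error = function(e) matrix(NA, k, k))
  se <- sqrt(diag(cov))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  zs <- beta / se
  tab <- data.frame(
    term = colnames(X), estimate = beta, se = se, z = zs,
    p = 2 * pnorm(abs(zs), lower.tail = FALSE),
    OR = exp(beta), OR_lower = exp(beta - zq * se),
    OR_upper = exp(beta + zq * se), row.names = NULL)
  structure(list(coefficients = tab, converged = converged,
                 separation = separation, loglik = trace[length(trace)],
                 loglik_trace = trace, n = n),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat("Logistic regression (", x$n, " observations",
      if (!x$converged) ", NOT converged", ")\n", sep = "")
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], signif, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.logistic_fit <- function(object, ...) object

#' Code a scored cohort for the depression logistic model
#'
#' Builds the covariate design used for the multiple logistic regression of
#' depression status: age (continuous), female indicator, physical disease,
#' perceived financial status coded poor vs fair/good, social media use
#' coded often vs less, visit difficulty, GAD-7 total, fatigue, patient
#' diagnosis dummies with "other" as reference, and medication compliance
#' coded poor vs good.
#'
#' @param scored A `scored_cohort`.
#' @return A numeric data frame, one coded column per model term.
#' @export
depression_design <- function(scored) {
  stopifnot(inherits(scored, "scored_cohort"))
  data.frame(
    age = scored$age,
    female = as.numeric(scored$sex == "female"),
    physical_disease = as.numeric(scored$physical_disease),
    financial_poor = as.numeric(scored$financial_status == "poor"),
    social_media_often = as.numeric(scored$social_media_freq == "often"),
    visit_difficulty = as.numeric(scored$visit_difficulty),
    gad7_total = scored$gad7_total,
    fatigue = scored$fatigue,
    diagnosis_mdd = as.numeric(scored$diagnosis == "mdd"),
    diagnosis_bipolar = as.numeric(scored$diagnosis == "bipolar"),
    diagnosis_schizophrenia = as.numeric(scored$diagnosis == "schizophrenia"),
    compliance_poor = as.numeric(!scored$medication_compliance_good)
  )
}
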