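#' Ground-truth sparse precision matrix for simulated symptom networks
#'
#' Draws a random sparse symmetric precision matrix with a given expected
#' edge density, off-diagonal magnitudes uniform in
#' `[weight_low, weight_high]` with random signs, and positive definiteness
#' enforced by diagonal dominance (each diagonal entry is 1 plus the sum of
#' absolute off-diagonal entries in its row).  The implied
#' partial-correlation matrix and the boolean edge support are returned
#' alongside.
#'
#' @param p Number of nodes (>= 2).
#' @param edge_density Probability that any node pair is connected, in (0, 1].
#' @param weight_low,weight_high Range of absolute off-diagonal precision
#'   entries on the support.
#' @param seed Integer seed; the draw is reproducible.
#' @return A `truth_network` list: `p`, `precision`, `partials`, `support`.
#' @export
build_truth_network <- function(p, edge_density, weight_low, weight_high,
                                seed = 1L) {
  if (p < 2) stop("p must be at least 2", call. = FALSE)
  stopifnot(edge_density >= 0, edge_density <= 1,
            weight_low > 0 || edge_density == 0, weight_low <= weight_high)
  set.seed(seed)
  P <- matrix(0, p, p)
  ut <- upper.tri(P)
  m <- sum(ut)
  on <- runif(m) < edge_density
  w <- runif(m, weight_low, weight_high) * sample(c(-1, 1), m, replace = TRUE)
  P[ut] <- ifelse(on, w, 0)
  P <- P + t(P)
  diag(P) <- 1 + rowSums(abs(P))
  d <- sqrt(diag(P))
  partials <- -P / outer(d, d)
  diag(partials) <- 0
  support <- P != 0
  diag(support) <- FALSE
  structure(list(p = p, precision = P, partials = partials,
                 support = support, seed = seed),
            class = "truth_network")
}

#' @export
print.truth_network <- function(x, ...) {
  cat("Ground-truth network: ", x$p, " nodes, ",
      sum(x$support[upper.tri(x$support)]), " edges\n", sep = "")
  pr <- abs(x$partials[upper.tri(x$partials)])
  pr <- pr[pr > 0]
  if (length(pr))
    cat(sprintf("  |partial correlations| on support: %.2f--%.2f\n",
                min(pr), max(pr)))
  invisible(x)
}

# Default item thresholds on the standard-normal latent scale, calibrated so
# that cohorts generated under the default truth network reproduce the
# marginal behaviour typical of guardian surveys: PHQ-9 >= 5 prevalence near
# one third, mean GAD-7 total near 3, mean fatigue near 3, mean two-item QOL
# near 6.6.
.default_thresholds <- function() {
  list(
    phq     = c(0.60, 1.25, 1.75),
    gad     = c(0.58, 1.28, 1.76),
    fatigue = seq(-1.0, 2.5, length.out = 10),
    qol     = c(-2.50, -1.45, -0.05, 1.15)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' @param n Cohort size (>= 2).
#' @param truth A `truth_network` over the 9 latent symptom dimensions.
#'   The default is a fixed reference network (p = 9, density 0.3, weights
#'   0.3--0.5, its own fixed seed) so that the calibrated marginals -- in
#'   particular the ~1/3 depression prevalence -- do not drift with the
#'   sampling seed; pass your own `truth_network` to vary the structure.
#' @param thresholds List with elements `phq` (3 increasing cut points),
#'   `gad` (3), `fatigue` (10), `qol` (4), all on the standard-normal latent
#'   scale.  `phq`, `gad` and `qol` may each be a single vector shared by
#'   all items of the scale or a list of per-item vectors.
#' @param covariate_effects List: `anx_to_symptoms` and `fat_to_symptoms`
#'   (loadings of the shared anxiety and fatigue latents on each symptom
#'   latent; scalar or length 9), `gad_loading` (loading of the anxiety
#'   latent on each GAD-7 item latent), `dep_to_qol` (downward shift, in
#'   latent SD units, of the QOL item latents for depressed respondents).
#'   Setting all to zero makes the blocks independent.
#' @param demographics Named list of category probabilities (defaults mimic
#'   a hospital guardian sample: 40.1% male, 82.0% married, ...).
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n = 1101,
                             truth = build_truth_network(9, 0.3, 0.3, 0.5,
                                                         seed = 11L),
                             thresholds = .default_thresholds(),
                             covariate_effects = list(anx_to_symptoms = 0.35,
                                                      fat_to_symptoms = 0.25,
                                                      gad_loading = 0.8,
                                                      dep_to_qol = 1.0),
                             demographics = NULL,
                             seed = 1L) {
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  for (nm in names(thresholds)) {
    tv <- thresholds[[nm]]
    if (!is.list(tv)) tv <- list(tv)
    for (v in tv)
      if (is.unsorted(v, strictly = TRUE))
        stop("thresholds for '", nm, "' must be strictly increasing",
             call. = FALSE)
  }
  stopifnot(inherits(truth, "truth_network"), truth$p == 9)
  defaults <- list(
    male = 0.401, married = 0.820, employed = 0.812,
    senior_or_above = 0.615, rural = 0.425, physical_disease = 0.047,
    financial = c(poor = 0.213, fair = 0.690, good = 0.097),
    social_media = c(none_minimal = 0.077, sometimes = 0.323, often = 0.599),
    visit_difficulty = 0.297,
    diagnosis = c(mdd = 0.363, bipolar = 0.147, schizophrenia = 0.202,
                  other = 0.288),
    compliance_good = 0.704,
    age_mean = 43.1, age_sd = 11.6
  )
  if (!is.null(demographics)) defaults[names(demographics)] <- demographics
  structure(list(n = as.integer(n), truth = truth, thresholds = thresholds,
                 covariate_effects = covariate_effects,
                 demographics = defaults, seed = as.integer(seed)),
            class = "generator_config")
}

.per_item <- function(tau, k) {
  if (is.list(tau)) {
    stopifnot(length(tau) == k)
    tau
  } else rep(list(tau), k)
}

.threshold_items <- function(z, tau, offset = 0L) {
  z <- as.matrix(z)
  tau <- .per_item(tau, ncol(z))
  out <- vapply(seq_len(ncol(z)),
                function(j) findInterval(z[, j], tau[[j]]) + offset,
                integer(nrow(z)))
  matrix(as.integer(out), nrow = nrow(z))
}

#' Generate a synthetic guardian cohort
#'
#' Respondent-level ordinal items are produced by thresholding latent draws
#' from a multivariate normal whose precision matrix is the configured
#' ground-truth network (a probit measurement model, under which polychoric
#' correlation consistently recovers the latent correlations).  A shared
#' anxiety latent drives the GAD-7 items and, with a fatigue latent, loads
#' on the symptom latents; depression status (PHQ-9 total at or above the
#' cutoff) lowers the QOL item latents.  Demographics are drawn from the
#' configured marginals.  Output is deterministic given the config seed.
#'
#' @param config A [generator_config()].
#' @param cutoff PHQ-9 cutoff used for the depression-to-QOL effect.
#' @return A `cohort_table` with the generating config attached as the
#'   `config` attribute.
#' @export
generate_cohort <- function(config = generator_config(), cutoff = 5) {
  stopifnot(inherits(config, "generator_config"))
  tr <- config$truth
  ev <- min(eigen(tr$precision, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    stop("truth precision matrix is not positive definite", call. = FALSE)
  set.seed(config$seed)
  n <- config$n
  th <- config$thresholds
  ce <- config$covariate_effects
  dm <- config$demographics

  # unit-variance symptom latents with the truth partial-correlation structure
  Sigma <- solve(tr$precision)
  R <- stats::cov2cor(Sigma)
  L <- chol(R)
  Y <- matrix(rnorm(n * 9), n, 9) %*% L

  anx <- rnorm(n)
  fat <- rnorm(n)
  a <- rep_len(ce$anx_to_symptoms, 9)
  f <- rep_len(ce$fat_to_symptoms, 9)
  Ys <- sweep(Y, 2, sqrt(1 + a^2 + f^2), "/") +
    outer(anx, a / sqrt(1 + a^2 + f^2)) +
    outer(fat, f / sqrt(1 + a^2 + f^2))

  phq <- .threshold_items(Ys, th$phq)
  colnames(phq) <- .phq_cols

  lam <- ce$gad_loading
  G <- lam * matrix(anx, n, 7) + sqrt(max(0, 1 - lam^2)) * matrix(rnorm(n * 7), n, 7)
  gad <- .threshold_items(G, th$gad)
  colnames(gad) <- .gad_cols

  fatigue <- as.integer(findInterval(fat, th$fatigue))

  depressed <- rowSums(phq) >= cutoff
  Q <- matrix(rnorm(n * 2), n, 2) - ce$dep_to_qol * depressed
  qol <- .threshold_items(Q, th$qol, offset = 1L)
  colnames(qol) <- .qol_cols

  age <- round(pmax(18, rnorm(n, dm$age_mean, dm$age_sd)), 1)
  draw_cat <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  df <- data.frame(
    respondent_id = sprintf("R%05d", seq_len(n)),
    phq, gad, fatigue = fatigue, qol,
    age = age,
    sex = ifelse(runif(n) < dm$male, "male", "female"),
    education = ifelse(runif(n) < dm$senior_or_above,
                       "senior_or_above", "below_senior"),
    financial_status = draw_cat(dm$financial),
    social_media_freq = draw_cat(dm$social_media),
    diagnosis = draw_cat(dm$diagnosis),
    married = runif(n) < dm$married,
    employed = runif(n) < dm$employed,
    rural = runif(n) < dm$rural,
    physical_disease = runif(n) < dm$physical_disease,
    visit_difficulty = runif(n) < dm$visit_difficulty,
    medication_compliance_good = runif(n) < dm$compliance_good,
    stringsAsFactors = FALSE
  )
  out <- validate_cohort(df)
  attr(out, "config") <- config
  out
}

#' Read a generator configuration from JSON
#'
#' Accepts the fields of [generator_config()]; the truth network is either
#' rebuilt from `truth_spec` (`p`, `edge_density`, `weight_low`,
#' `weight_high`, `seed`) or taken from an explicit `precision` matrix.
#'
#' @param path Path to a JSON file.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  truth <- if (!is.null(cfg$truth_spec)) {
    ts <- cfg$truth_spec
    build_truth_network(ts$p, ts$edge_density, ts$weight_low, ts$weight_high,
                        seed = if (!is.null(ts$seed)) ts$seed else seed)
  } else if (!is.null(cfg$precision)) {
    P <- as.matrix(cfg$precision)
    d <- sqrt(diag(P))
    pa <- -P / outer(d, d); diag(pa) <- 0
    structure(list(p = nrow(P), precision = P, partials = pa,
                   support = abs(P) > 0 & !diag(nrow(P)), seed = seed),
              class = "truth_network")
  } else build_truth_network(9, 0.3, 0.3, 0.5, seed = 11L)
  args <- list(n = if (!is.null(cfg$n)) cfg$n else 1101, truth = truth,
               seed = seed)
  if (!is.null(cfg$thresholds)) args$thresholds <- lapply(cfg$thresholds, unlist)
  if (!is.null(cfg$covariate_effects))
    args$covariate_effects <- utils::modifyList(
      list(anx_to_symptoms = 0.35, fat_to_symptoms = 0.25, gad_loading = 0.8,
           dep_to_qol = 1.0), cfg$covariate_effects)
  if (!is.null(cfg$demographics)) args$demographics <- cfg$demographics
  do.call(generator_config, args)
}
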