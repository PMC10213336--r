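#' Configuration for the full analysis pipeline
#'
#' @param input Path to a cohort CSV, or a [generator_config()] to simulate
#'   one.
#' @param out_dir Output directory (created if needed).
#' @param cutoff PHQ-9 depression cutoff (default 5).
#' @param gamma,n_lambda,method Network hyperparameters, see
#'   [ebic_glasso()].
#' @param boot_B Case-dropping bootstrap replicates (default 1000; reduce
#'   for quick runs).
#' @param boot_proportions Drop-proportion grid.
#' @param n_perm Permutations for the subgroup comparison test.
#' @param subgroup If `TRUE`, additionally estimate the depressed-subgroup
#'   network and compare it to the non-depressed network.
#' @param stability If `TRUE` (default), run the stability bootstrap.
#' @param seed_boot,seed_perm Independent seeds for the bootstrap and
#'   permutation stages.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input, out_dir, cutoff = 5, gamma = 0.5,
                            n_lambda = 100,
                            method = c("polychoric", "pearson", "spearman"),
                            boot_B = 1000,
                            boot_proportions = seq(0.05, 0.75, by = 0.05),
                            n_perm = 1000, subgroup = FALSE, stability = TRUE,
                            seed_boot = 101L, seed_perm = 202L) {
  method <- match.arg(method)
  stopifnot(cutoff >= 0)
  if (is.character(input) && !file.exists(input))
    stop("input CSV not found: ", input, call. = FALSE)
  if (!is.character(input) && !inherits(input, "generator_config"))
    stop("input must be a CSV path or a generator_config", call. = FALSE)
  structure(list(input = input, out_dir = out_dir, cutoff = cutoff,
                 gamma = gamma, n_lambda = n_lambda, method = method,
                 boot_B = boot_B, boot_proportions = boot_proportions,
                 n_perm = n_perm, subgroup = subgroup, stability = stability,
                 seed_boot = as.integer(seed_boot),
                 seed_perm = as.integer(seed_perm)),
            class = "analysis_config")
}

.describe_cohort <- function(scored) {
  dep <- scored$depressed
  cat_row <- function(label, flag) {
    tab <- table(factor(flag, c(FALSE, TRUE)), factor(dep, c(FALSE, TRUE)))
    ct <- pearson_chi2(matrix(as.numeric(tab), 2))
    data.frame(variable = label, level = "yes",
               n_total = sum(flag), pct_total = round(100 * mean(flag), 1),
               n_nondep = sum(flag & !dep), n_dep = sum(flag & dep),
               statistic = round(ct$chi2, 1), test = "chi2",
               df = ct$df, p = ct$p)
  }
  multi_row <- function(label, f) {
    f <- factor(f)
    tab <- table(f, factor(dep, c(FALSE, TRUE)))
    ct <- pearson_chi2(matrix(as.numeric(tab), nrow = nlevels(f)))
    do.call(rbind, lapply(levels(f), function(lv) {
      data.frame(variable = label, level = lv,
                 n_total = sum(f == lv), pct_total = round(100 * mean(f == lv), 1),
                 n_nondep = sum(f == lv & !dep), n_dep = sum(f == lv & dep),
                 statistic = round(ct$chi2, 1), test = "chi2",
                 df = ct$df, p = ct$p)
    }))
  }
  num_row <- function(label, v, test = c("t", "wilcoxon")) {
    test <- match.arg(test)
    if (test == "t") {
      r <- pooled_t_raw(v[!dep], v[dep])
      stat <- r$t; df <- r$df; p <- r$p
    } else {
      r <- wilcoxon_rank_sum(v[!dep], v[dep])
      stat <- r$Z; df <- NA_integer_; p <- r$p
    }
    data.frame(variable = label, level = sprintf("mean %.1f (SD %.1f)",
                                                 mean(v), sd(v)),
               n_total = length(v), pct_total = NA_real_,
               n_nondep = sum(!dep), n_dep = sum(dep),
               statistic = round(abs(stat), 2), test = test, df = df, p = p)
  }
  rbind(
    cat_row("male", scored$sex == "male"),
    cat_row("married", scored$married),
    cat_row("employed", scored$employed),
    cat_row("education_senior_or_above",
            scored$education == "senior_or_above"),
    cat_row("rural", scored$rural),
    cat_row("physical_disease", scored$physical_disease),
    multi_row("financial_status", scored$financial_status),
    multi_row("social_media_freq", scored$social_media_freq),
    cat_row("visit_difficulty", scored$visit_difficulty),
    multi_row("diagnosis", scored$diagnosis),
    cat_row("medication_compliance_good", scored$medication_compliance_good),
    num_row("age", scored$age, "t"),
    num_row("gad7_total", scored$gad7_total, "wilcoxon"),
    num_row("fatigue", scored$fatigue, "wilcoxon"),
    num_row("qol_global", scored$qol_global, "t")
  )
}

#' Run the full survey analysis end-to-end
#'
#' Executes, in order: cohort loading/generation and scoring; the
#' descriptive comparison table; prevalence with CI; multiple logistic
#' regression of depression status; ANCOVA of global QOL; the EBIC-gLASSO
#' symptom network with strength centrality; the anxiety/fatigue-adjusted
#' network with a top-3 centrality comparison; the QOL flow network;
#' optionally the case-dropping stability bootstrap and the
#' depressed-subgroup network with a permutation comparison test.  Every
#' artifact is written to `config$out_dir` and stamped (in the manifest)
#' with the config hash and seeds; identical configs reproduce identical
#' files.
#'
#' @param config An [analysis_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A `report_bundle` list with all in-memory results and the output
#'   paths.
#' @export
run_full_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)
  bundle <- list(config = config)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    say(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }

  scored <- stage("score", {
    cohort <- if (is.character(config$input)) read_cohort_csv(config$input)
              else generate_cohort(config$input, cutoff = config$cutoff)
    if (!is.character(config$input))
      write_cohort_csv(cohort, outp("cohort.csv"))
    score_cohort(cohort, cutoff = config$cutoff)
  })
  bundle$scored <- scored
  n_dep <- sum(scored$depressed)

  bundle$prevalence <- stage("prevalence", {
    pr <- prevalence_ci(n_dep, nrow(scored))
    .write_json(pr[c("k", "n", "proportion", "lower", "upper", "method")],
                outp("prevalence.json"))
    pr
  })

  degenerate <- n_dep == 0 || n_dep == nrow(scored)
  if (degenerate)
    warning("degenerate depression split (", n_dep, "/", nrow(scored),
            "); group-comparison stages skipped")

  if (!degenerate) {
    bundle$descriptive <- stage("describe", {
      d <- .describe_cohort(scored)
      .write_table(d, outp("descriptive.csv"))
      d
    })
    bundle$logistic <- stage("logit", {
      fit <- fit_logistic(scored$depressed, depression_design(scored))
      .write_table(fit$coefficients, outp("logistic.csv"))
      fit
    })
    bundle$ancova <- stage("ancova", {
      a <- ancova_group_effect(scored$qol_global, scored$depressed,
                               depression_design(scored))
      .write_json(a[c("F", "df1", "df2", "p", "adjusted_means")],
                  outp("ancova.json"))
      a
    })
  }

  items <- scored[, .phq_cols]
  net_args <- list(gamma = config$gamma, n_lambda = config$n_lambda,
                   method = config$method)

  bundle$network <- stage("network", {
    net <- do.call(ebic_glasso, c(list(items), net_args))
    write_network(net, config$out_dir, "network")
    net
  })
  bundle$centrality <- stage("centrality", {
    cent <- strength_centrality(bundle$network)
    .write_table(cent, outp("centrality.csv"))
    cent
  })

  bundle$adjusted <- stage("adjusted_network", {
    adj <- do.call(adjusted_network,
                   c(list(items, scored[, c("gad7_total", "fatigue")]),
                     net_args))
    write_network(adj, config$out_dir, "adjusted_network")
    top3 <- function(net) strength_centrality(net)$node[
      order(strength_centrality(net)$rank)][1:3]
    cmp <- list(top3_unadjusted = top3(bundle$network),
                top3_adjusted = top3(adj),
                identical_sets = setequal(top3(bundle$network), top3(adj)))
    .write_json(cmp, outp("adjustment_comparison.json"))
    attr(adj, "comparison") <- cmp
    adj
  })

  bundle$flow <- stage("flow", {
    fnet <- do.call(ebic_glasso,
                    c(list(cbind(items, qol_global = scored$qol_global)),
                      net_args))
    fl <- flow_edges(fnet, "qol_global")
    .write_json(list(target = fl$target, direct = fl$direct,
                     layers = as.list(fl$layers)), outp("flow.json"))
    fl
  })

  if (config$stability) {
    bundle$stability <- stage("stability", {
      st <- do.call(case_drop_bootstrap,
                    c(list(items, proportions = config$boot_proportions,
                           B = config$boot_B, seed = config$seed_boot),
                      net_args))
      curves <- data.frame(
        proportion = rep(st$proportions, each = st$B),
        replicate = rep(seq_len(st$B), length(st$proportions)),
        correlation = as.vector(st$correlations))
      .write_table(curves, outp("stability_curves.csv"))
      .write_json(list(cs_coefficient = cs_coefficient(st),
                       B = st$B, seed = st$seed),
                  outp("cs_coefficient.json"))
      st
    })
  }

  if (config$subgroup && !degenerate) {
    bundle$subgroup <- stage("subgroup", {
      sub_items <- items[scored$depressed, , drop = FALSE]
      sub_net <- do.call(ebic_glasso, c(list(sub_items), net_args))
      write_network(sub_net, config$out_dir, "subgroup_network")
      nct <- do.call(network_comparison_test,
                     c(list(items[!scored$depressed, , drop = FALSE],
                            sub_items, n_perm = config$n_perm,
                            seed = config$seed_perm), net_args))
      .write_json(nct[c("strength_diff", "max_edge_diff", "p_strength",
                        "p_edge", "n_perm", "seed")], outp("nct.json"))
      list(network = sub_net, nct = nct)
    })
  }

  stage("manifest", {
    .write_json(list(
      config_hash = .config_hash(unclass(config)[setdiff(names(config),
                                                         "out_dir")]),
      n = nrow(scored), n_depressed = n_dep, cutoff = config$cutoff,
      gamma = config$gamma, n_lambda = config$n_lambda,
      method = config$method,
      seeds = list(
        generator = if (inherits(config$input, "generator_config"))
          config$input$seed else NULL,
        bootstrap = config$seed_boot, permutation = config$seed_perm)),
      outp("manifest.json"))
  })

  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Analysis report bundle (", nrow(x$scored), " respondents)\n", sep = "")
  cat(sprintf("  prevalence: %.1f%% (%.1f-%.1f)\n",
              x$prevalence$percent[1], x$prevalence$percent[2],
              x$prevalence$percent[3]))
  if (!is.null(x$network))
    cat(sprintf("  symptom network: %d edges; top strength: %s\n",
                x$network$n_edges,
                x$centrality$node[x$centrality$rank == 1]))
  if (!is.null(x$stability))
    cat(sprintf("  CS-coefficient: %.2f\n", cs_coefficient(x$stability)))
  cat("  outputs in: ", x$config$out_dir, "\n", sep = "")
  invisible(x)
}

#' Write a network's edge list, adjacency matrix and metadata
#'
#' @param network A `symptom_network`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(network, dir, prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_edges <- file.path(dir, paste0(prefix, "_edges.csv"))
  p_adj <- file.path(dir, paste0(prefix, "_adjacency.csv"))
  p_meta <- file.path(dir, paste0(prefix, "_meta.json"))
  .write_table(network_edges(network, all = TRUE), p_edges)
  adj <- as.data.frame(network$weights)
  adj <- cbind(node = network$nodes, adj)
  .write_table(adj, p_adj)
  .write_json(list(lambda = network$lambda, gamma = network$gamma,
                   ebic = network$ebic, n_edges = network$n_edges,
                   method = network$method, n = network$n,
                   psd_repaired = network$repaired,
                   adjusted_for = network$adjusted_for),
              p_meta)
  invisible(c(p_edges, p_adj, p_meta))
}
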