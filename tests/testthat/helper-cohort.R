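# small hand-built cohort data frame with valid values (no generator)
make_raw_cohort <- function(n = 5, seed = 42) {
  set.seed(seed)
  df <- data.frame(respondent_id = sprintf("G%03d", seq_len(n)))
  for (j in 1:9) df[[paste0("phq9_", j)]] <- sample(0:3, n, replace = TRUE)
  for (j in 1:7) df[[paste0("gad7_", j)]] <- sample(0:3, n, replace = TRUE)
  df$fatigue <- sample(0:10, n, replace = TRUE)
  df$qol_1 <- sample(1:5, n, replace = TRUE)
  df$qol_2 <- sample(1:5, n, replace = TRUE)
  df$age <- round(runif(n, 20, 70), 1)
  df$sex <- sample(c("male", "female"), n, replace = TRUE)
  df$education <- sample(c("below_senior", "senior_or_above"), n, TRUE)
  df$financial_status <- sample(c("poor", "fair", "good"), n, TRUE)
  df$social_media_freq <- sample(c("none_minimal", "sometimes", "often"), n, TRUE)
  df$diagnosis <- sample(c("mdd", "bipolar", "schizophrenia", "other"), n, TRUE)
  for (col in c("married", "employed", "rural", "physical_disease",
                "visit_difficulty", "medication_compliance_good"))
    df[[col]] <- sample(c(TRUE, FALSE), n, replace = TRUE)
  df
}

phq_cols <- paste0("phq9_", 1:9)

# items-only cohort for network estimation, generated under a known truth
make_item_data <- function(n, truth, seed, no_covariates = TRUE) {
  ce <- if (no_covariates)
    list(anx_to_symptoms = 0, fat_to_symptoms = 0, gad_loading = 0.8,
         dep_to_qol = 0)
  else list(anx_to_symptoms = 0.35, fat_to_symptoms = 0.25,
            gad_loading = 0.8, dep_to_qol = 1.0)
  cfg <- generator_config(n = n, truth = truth, covariate_effects = ce,
                          seed = seed)
  generate_cohort(cfg)[, phq_cols]
}
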