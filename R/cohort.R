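#' Cohort data model for guardian survey records
#'
#' A cohort table is a validated per-respondent data frame holding the four
#' instruments used throughout the package -- nine PHQ-9 items and seven
#' GAD-7 items (each 0--3), a single fatigue numeric rating (0--10), the two
#' WHOQOL-BREF global quality-of-life items (1--5) -- together with
#' demographic and clinical covariates.  [validate_cohort()] checks ranges
#' and category tokens and applies a complete-case policy for missing scale
#' items; [score_cohort()] adds instrument totals and the depression flag.
#'
#' @name cohort
NULL

.phq_cols <- paste0("phq9_", 1:9)
.gad_cols <- paste0("gad7_", 1:7)
.qol_cols <- c("qol_1", "qol_2")
.item_cols <- c(.phq_cols, .gad_cols, "fatigue", .qol_cols)

.cat_levels <- list(
  sex               = c("male", "female"),
  education         = c("below_senior", "senior_or_above"),
  financial_status  = c("poor", "fair", "good"),
  social_media_freq = c("none_minimal", "sometimes", "often"),
  diagnosis         = c("mdd", "bipolar", "schizophrenia", "other")
)
.bool_cols <- c("married", "employed", "rural", "physical_disease",
                "visit_difficulty", "medication_compliance_good")

#' Column schema of a cohort CSV
#'
#' @return A data frame with one row per column of the cohort dialect:
#'   name, type (`integer`, `numeric`, `boolean`, `categorical`, `string`),
#'   allowed range or tokens.
#' @export
cohort_schema <- function() {
  item_rng <- function(cols, lo, hi)
    data.frame(name = cols, type = "integer",
               min = lo, max = hi, tokens = NA_character_)
  rbind(
    data.frame(name = "respondent_id", type = "string",
               min = NA_real_, max = NA_real_, tokens = NA_character_),
    item_rng(.phq_cols, 0, 3),
    item_rng(.gad_cols, 0, 3),
    item_rng("fatigue", 0, 10),
    item_rng(.qol_cols, 1, 5),
    data.frame(name = "age", type = "numeric", min = 0, max = Inf,
               tokens = NA_character_),
    data.frame(name = names(.cat_levels), type = "categorical",
               min = NA_real_, max = NA_real_,
               tokens = vapply(.cat_levels, paste, "", collapse = "|")),
    data.frame(name = .bool_cols, type = "boolean",
               min = NA_real_, max = NA_real_, tokens = "true|false")
  )
}

.item_range <- function(col) {
  if (col %in% c(.phq_cols, .gad_cols)) c(0L, 3L)
  else if (col == "fatigue") c(0L, 10L)
  else c(1L, 5L)
}

#' Validate a raw cohort data frame
#'
#' Checks the column set against [cohort_schema()], coerces and range-checks
#' every scale item, checks category tokens, and applies the complete-case
#' policy: rows with any missing scale item are dropped (with a message) or
#' rejected, depending on `on_missing`.
#'
#' @param df A data frame with the cohort columns.  `respondent_id` may be
#'   absent, in which case sequential ids are generated.
#' @param on_missing `"drop"` (default) removes rows with missing scale
#'   items and records the count in the `n_dropped` attribute; `"error"`
#'   fails on the first missing value.
#' @return A `cohort_table` (a validated data frame).
#' @export
validate_cohort <- function(df, on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)

  need <- c(.item_cols, "age", names(.cat_levels), .bool_cols)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  if (!"respondent_id" %in% names(df))
    df$respondent_id <- sprintf("R%05d", seq_len(nrow(df)))
  df$respondent_id <- as.character(df$respondent_id)

  # scale items: integer, in range
  for (col in .item_cols) {
    v <- df[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad_parse <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad_parse))
      stop(sprintf("unparseable value in column '%s', row %d", col,
                   bad_parse[1]), call. = FALSE)
    rng <- .item_range(col)
    out <- which(!is.na(v) & (v < rng[1] | v > rng[2] | v != round(v)))
    if (length(out))
      stop(sprintf(
        "out-of-range value %s in column '%s', row %d (allowed %d..%d)",
        format(v[out[1]]), col, out[1], rng[1], rng[2]), call. = FALSE)
    df[[col]] <- as.integer(round(v))
  }

  miss <- !complete.cases(df[.item_cols])
  if (any(miss)) {
    if (on_missing == "error")
      stop("missing scale item in row ", which(miss)[1], call. = FALSE)
    message(sum(miss), " row(s) dropped for missing scale items (complete-case)")
    df <- df[!miss, , drop = FALSE]
    rownames(df) <- NULL
  }

  df$age <- as.numeric(df$age)
  if (any(is.na(df$age) | df$age <= 0))
    stop("invalid age in row ", which(is.na(df$age) | df$age <= 0)[1],
         call. = FALSE)

  for (col in names(.cat_levels)) {
    v <- tolower(as.character(df[[col]]))
    bad <- which(!v %in% .cat_levels[[col]])
    if (length(bad))
      stop(sprintf("invalid token '%s' in column '%s', row %d (allowed: %s)",
                   v[bad[1]], col, bad[1],
                   paste(.cat_levels[[col]], collapse = ", ")), call. = FALSE)
    df[[col]] <- v
  }
  for (col in .bool_cols) {
    v <- df[[col]]
    if (is.character(v)) v <- tolower(v) == "true"
    v <- as.logical(v)
    if (anyNA(v))
      stop(sprintf("invalid boolean in column '%s', row %d", col,
                   which(is.na(v))[1]), call. = FALSE)
    df[[col]] <- v
  }

  df <- df[, c("respondent_id", .item_cols, "age", names(.cat_levels),
               .bool_cols)]
  n_dropped <- sum(miss)
  structure(df, class = c("cohort_table", "data.frame"),
            n_dropped = n_dropped)
}

#' Score a single PHQ-9 item vector
#'
#' @param items Nine integers, each 0--3.
#' @param cutoff Total-score threshold at or above which a respondent is
#'   flagged as having clinically relevant depression (default 5).
#' @return A list with `total` (0--27) and `depressed` (logical).
#' @examples
#' score_phq9(c(1, 1, 1, 1, 1, 0, 0, 0, 0)) # total 5 -> depressed
#' @export
score_phq9 <- function(items, cutoff = 5) {
  if (length(items) != 9)
    stop("PHQ-9 requires exactly 9 items, got ", length(items), call. = FALSE)
  items <- as.numeric(items)
  bad <- which(is.na(items) | items < 0 | items > 3 | items != round(items))
  if (length(bad))
    stop(sprintf("PHQ-9 item %d is invalid (%s); items must be integers 0..3",
                 bad[1], format(items[bad[1]])), call. = FALSE)
  total <- as.integer(sum(items))
  list(total = total, depressed = total >= cutoff)
}

#' Score a cohort: instrument totals and the depression flag
#'
#' Adds `phq9_total` (0--27), `gad7_total` (0--21), `qol_global` (the sum of
#' the two WHOQOL-BREF items, 2--10) and the logical `depressed`
#' (`phq9_total >= cutoff`).
#'
#' @param table A `cohort_table` from [validate_cohort()] (a plain data
#'   frame is validated first).
#' @inheritParams score_phq9
#' @return A `scored_cohort` data frame.
#' @export
score_cohort <- function(table, cutoff = 5) {
  if (!inherits(table, "cohort_table")) table <- validate_cohort(table)
  tb <- as.data.frame(table)
  tb$phq9_total <- as.integer(rowSums(tb[.phq_cols]))
  tb$gad7_total <- as.integer(rowSums(tb[.gad_cols]))
  tb$qol_global <- as.integer(tb$qol_1 + tb$qol_2)
  tb$depressed <- tb$phq9_total >= cutoff
  structure(tb, class = c("scored_cohort", "cohort_table", "data.frame"),
            cutoff = cutoff)
}

#' @export
print.scored_cohort <- function(x, ...) {
  cat("Scored survey cohort: ", nrow(x), " respondents\n", sep = "")
  cat(sprintf("  depressed (PHQ-9 >= %d): %d (%.1f%%)\n",
              attr(x, "cutoff"), sum(x$depressed),
              100 * mean(x$depressed)))
  cat(sprintf("  mean PHQ-9 %.1f, GAD-7 %.1f, fatigue %.1f, global QOL %.1f\n",
              mean(x$phq9_total), mean(x$gad7_total), mean(x$fatigue),
              mean(x$qol_global)))
  invisible(x)
}

#' Read / write a cohort CSV
#'
#' The CSV dialect is UTF-8 with a header row; item columns are
#' `phq9_1..phq9_9`, `gad7_1..gad7_7`, `fatigue`, `qol_1`, `qol_2`;
#' categorical columns use the lower-case tokens of [cohort_schema()];
#' booleans are written as `true`/`false`.  Writing then reading reproduces
#' the table exactly.
#'
#' @param path File path.
#' @param on_missing Passed to [validate_cohort()].
#' @return `read_cohort_csv()` returns a `cohort_table`;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path, on_missing = "drop") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_cohort(df, on_missing = on_missing)
}

#' @param table A `cohort_table`.
#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(table, path) {
  if (!inherits(table, "cohort_table")) table <- validate_cohort(table)
  out <- as.data.frame(table)[, c("respondent_id", .item_cols, "age",
                                  names(.cat_levels), .bool_cols)]
  for (col in .bool_cols) out[[col]] <- ifelse(out[[col]], "true", "false")
  out$age <- format(out$age, trim = TRUE, scientific = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
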