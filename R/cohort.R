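#' @importFrom stats qnorm quantile median sd var
NULL

# Canonical categorical levels for cohort columns.
.pv_levels <- list(
  menopause = c("pre", "post", "unknown"),
  detection = c("screening", "symptoms", "unknown"),
  er        = c("positive", "negative"),
  her2      = c("positive", "negative", "unknown"),
  ki67      = c("positive", "negative", "unknown"),
  cause     = c("breast", "other", "unknown")
)

.pv_bool_cols <- c("hormone", "chemo", "trastuzumab", "radiotherapy", "dead")

.pv_canonical_cols <- c(
  "id", "age_years", "menopause", "detection", "size_mm", "grade", "nodes",
  "er", "her2", "ki67", "hormone", "chemo", "trastuzumab", "radiotherapy",
  "followup_years", "dead", "cause"
)

#' Days-per-year convention used for all day/year conversions
#' @keywords internal
DAYS_PER_YEAR <- 365.25

.parse_bool <- function(x) {
  out <- rep(NA, length(x))
  lx <- tolower(trimws(as.character(x)))
  out[lx %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[lx %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

.normalize_level <- function(x, levels, synonyms = NULL) {
  lx <- tolower(trimws(as.character(x)))
  if (!is.null(synonyms)) {
    for (canon in names(synonyms)) lx[lx %in% synonyms[[canon]]] <- canon
  }
  lx[!lx %in% levels] <- NA_character_
  lx
}

.level_synonyms <- list(
  menopause = list(pre = c("no", "premenopausal"), post = c("yes", "postmenopausal")),
  er        = list(positive = c("pos", "+", "er+"), negative = c("neg", "-", "er-")),
  her2      = list(positive = c("pos", "+"), negative = c("neg", "-"), unknown = c("na", "")),
  ki67      = list(positive = c("pos", "+"), negative = c("neg", "-"), unknown = c("na", "")),
  detection = list(screening = c("screen", "screen-detected"),
                   symptoms = c("symptomatic", "symptom"), unknown = c("na", "")),
  cause     = list(breast = c("breast cancer"), other = c("other cause"), unknown = c("na", ""))
)

#' Read and validate a patient-level cohort CSV
#'
#' Reads a comma-separated cohort file (UTF-8, header row) into a validated
#' cohort tibble. One row per patient with clinicopathological covariates,
#' adjuvant-treatment flags and follow-up outcome. Follow-up is stored
#' internally in years (`followup_years`), converted from the `followup_days`
#' column using 365.25 days per year. Categorical values are matched
#' case-insensitively and normalized to canonical levels.
#'
#' Rows that violate a field invariant (negative node count, non-positive age
#' or tumour size, a recorded cause of death for a living patient, an
#' unrecognizable categorical level, ...) are rejected with a diagnostic
#' naming the row and field; any invalid row aborts the read.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the column names used in the file (values).
#' @param age_range Admissible age range in years; ages outside it are a
#'   row-level validation error.
#' @return A `pv_cohort` tibble with columns `id`, `age_years`, `menopause`,
#'   `detection`, `size_mm`, `grade`, `nodes`, `er`, `her2`, `ki67`,
#'   `hormone`, `chemo`, `trastuzumab`, `radiotherapy`, `followup_years`,
#'   `dead`, `cause`.
#' @seealso [write_cohort()], [censor_at()], [baseline_table()]
#' @export
read_cohort <- function(path, schema = NULL, age_range = c(18, 100)) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw))
        stop("schema error: mapped column '", schema[[canon]], "' (for '", canon,
             "') not present in file")
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  mandatory <- c("id", "age_years", "size_mm", "grade", "nodes", "er",
                 "followup_days", "dead")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing))
    stop("schema error: missing mandatory column(s): ", paste(missing, collapse = ", "))
  as_cohort(raw, source = path, age_range = age_range)
}

#' Build a validated cohort from an in-memory data frame
#'
#' Same validation and normalization as [read_cohort()] but starting from a
#' data frame (e.g. one assembled in code). Optional categorical columns that
#' are absent default to `"unknown"`; absent treatment flags default to
#' `FALSE`. Extra (non-canonical) columns are retained untouched so they can
#' appear in [baseline_table()].
#'
#' @param df Data frame with at least the mandatory cohort columns.
#' @param source Provenance label stored as an attribute.
#' @param age_range Admissible age range in years.
#' @return A `pv_cohort` tibble.
#' @export
as_cohort <- function(df, source = "memory", age_range = c(18, 100)) {
  df <- tibble::as_tibble(df)
  n <- nrow(df)
  if (n == 0L) stop("cohort is empty")
  if (!"followup_years" %in% names(df)) {
    if (!"followup_days" %in% names(df))
      stop("schema error: missing mandatory column(s): followup_days")
    df$followup_years <- as.numeric(df$followup_days) / DAYS_PER_YEAR
  }
  for (col in c("menopause", "detection", "her2", "ki67"))
    if (!col %in% names(df)) df[[col]] <- "unknown"
  for (col in c("hormone", "chemo", "trastuzumab", "radiotherapy"))
    if (!col %in% names(df)) df[[col]] <- FALSE
  if (!"cause" %in% names(df)) df$cause <- NA_character_

  errs <- character(0)
  bad <- function(rows, field, msg) {
    if (any(rows, na.rm = TRUE)) {
      ids <- df$id[which(rows)]
      errs <<- c(errs, sprintf("row %s (id %s): field %s %s",
                               paste(which(rows), collapse = ","),
                               paste(ids, collapse = ","), field, msg))
    }
  }

  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("cohort ids are not unique")

  df$age_years <- suppressWarnings(as.numeric(df$age_years))
  bad(is.na(df$age_years) | df$age_years < age_range[1] | df$age_years > age_range[2],
      "age_years", sprintf("outside admissible range [%g, %g]", age_range[1], age_range[2]))
  df$size_mm <- suppressWarnings(as.numeric(df$size_mm))
  bad(is.na(df$size_mm) | df$size_mm <= 0, "size_mm", "must be a positive number")
  df$grade <- suppressWarnings(as.integer(df$grade))
  bad(is.na(df$grade) | !df$grade %in% 1:3, "grade", "must be 1, 2 or 3")
  df$nodes <- suppressWarnings(as.numeric(df$nodes))
  bad(is.na(df$nodes) | df$nodes < 0 | df$nodes != floor(df$nodes),
      "nodes", "must be a non-negative integer")
  df$nodes <- as.integer(df$nodes)
  df$followup_years <- suppressWarnings(as.numeric(df$followup_years))
  bad(is.na(df$followup_years) | df$followup_years < 0,
      "followup_days", "follow-up must be non-negative")

  for (col in c("menopause", "detection", "er", "her2", "ki67")) {
    df[[col]] <- .normalize_level(df[[col]], .pv_levels[[col]], .level_synonyms[[col]])
    bad(is.na(df[[col]]), col,
        paste0("must be one of {", paste(.pv_levels[[col]], collapse = ", "), "}"))
  }
  for (col in c("hormone", "chemo", "trastuzumab", "radiotherapy", "dead")) {
    df[[col]] <- .parse_bool(df[[col]])
    bad(is.na(df[[col]]), col, "must be a logical (true/false)")
  }
  df$cause <- ifelse(is.na(df$cause) | trimws(df$cause) == "", NA_character_,
                     .normalize_level(df$cause, .pv_levels$cause, .level_synonyms$cause))
  bad(!is.na(df$cause) & !df$dead, "cause", "present for a living patient")

  if (length(errs))
    stop("cohort validation failed:\n  ", paste(errs, collapse = "\n  "))

  extra <- setdiff(names(df), c(.pv_canonical_cols, "followup_days"))
  df <- df[, c(.pv_canonical_cols, extra)]
  attr(df, "provenance") <- list(source = source, schema_version = "1")
  class(df) <- c("pv_cohort", class(df))
  df
}

#' Write a cohort back to CSV
#'
#' Inverse of [read_cohort()]: follow-up is exported as `followup_days`
#' (years times 365.25) so a write/read cycle round-trips every field.
#'
#' @param cohort A `pv_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "pv_cohort"))
  out <- as.data.frame(cohort)
  out$followup_days <- out$followup_years * DAYS_PER_YEAR
  out$followup_years <- NULL
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Administratively censor a cohort at a fixed horizon
#'
#' Truncates follow-up at `horizon_years`: any patient followed beyond the
#' horizon is set to exactly the horizon, alive (`dead = FALSE`, cause
#' cleared). Death from any cause before or at the horizon is the event.
#' The operation is idempotent.
#'
#' @param cohort A `pv_cohort`.
#' @param horizon_years Positive censoring horizon in years.
#' @return The censored `pv_cohort`.
#' @export
censor_at <- function(cohort, horizon_years) {
  stopifnot(inherits(cohort, "pv_cohort"), horizon_years > 0)
  over <- cohort$followup_years > horizon_years
  cohort$followup_years[over] <- horizon_years
  cohort$dead[over] <- FALSE
  cohort$cause[over] <- NA_character_
  cohort
}

#' Group-comparison test for a contingency table of counts
#'
#' Pearson chi-squared test with the convention used throughout the package:
#' Yates continuity correction for 2x2 tables, no correction for larger
#' tables. A table with a zero margin is reported as not applicable rather
#' than an error.
#'
#' @param counts Matrix of counts (levels x groups).
#' @return List with `statistic`, `df`, `p_value`, `test`.
#' @export
contingency_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                test = "not applicable (zero margin)"))
  correct <- all(dim(counts) == c(2L, 2L))
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value),
       test = if (correct) "chi-squared (continuity-corrected)" else "chi-squared")
}

.fmt_mean_sd <- function(x) sprintf("%.1f (%.1f)", mean(x), sd(x))
.fmt_median_iqr <- function(x) sprintf("%.1f [%.1f]", median(x), stats::IQR(x))
.fmt_n_pct <- function(k, n) sprintf("%d (%.1f%%)", k, 100 * k / n)

#' Baseline characteristics table with group-comparison tests
#'
#' Summarizes a cohort per stratum of `group_var` and attaches a comparison
#' p-value per variable, in the style of a clinical "Table 1":
#' * continuous variables: mean (SD), two-sample t-test (Welch by default);
#' * count-like skewed variables (`nodes`): median \[IQR\], Mann-Whitney test;
#' * categorical variables: n (%) per level, Pearson chi-squared with
#'   continuity correction for 2x2 tables and none otherwise. `"unknown"`
#'   levels are retained as categories.
#'
#' @param cohort A `pv_cohort`.
#' @param group_var Grouping column (>= 2 non-empty levels), default `"er"`.
#' @param variables Columns to summarize; defaults to every canonical
#'   covariate plus any extra columns carried by the cohort.
#' @param pooled_t Use the pooled-variance t-test instead of Welch.
#' @return A `pv_baseline_table` tibble: one row per variable level with a
#'   formatted summary per stratum, plus `p_value` and `test` on the first
#'   row of each variable. Attribute `"n_strata"` holds stratum sizes.
#' @export
baseline_table <- function(cohort, group_var = "er", variables = NULL,
                           pooled_t = FALSE) {
  stopifnot(inherits(cohort, "pv_cohort"))
  g <- as.character(cohort[[group_var]])
  lev_g <- unique(g)
  if (length(lev_g) < 2) stop("group_var must have at least 2 non-empty levels")
  if (is.null(variables)) {
    variables <- setdiff(names(cohort),
                         c("id", group_var, "followup_years", "dead", "cause"))
  }
  n_strata <- table(factor(g, levels = lev_g))

  rows <- list()
  for (v in variables) {
    x <- cohort[[v]]
    if (is.logical(x)) x <- ifelse(x, "yes", "no")
    if (identical(v, "nodes")) {
      summ <- vapply(lev_g, function(l) .fmt_median_iqr(x[g == l]), "")
      ht <- tryCatch(stats::wilcox.test(x[g == lev_g[1]], x[g == lev_g[2]]),
                     error = function(e) NULL)
      rows[[v]] <- tibble::tibble(variable = v, level = NA_character_,
                                  !!!as.list(summ),
                                  p_value = if (is.null(ht)) NA_real_ else ht$p.value,
                                  test = "Mann-Whitney")
    } else if (is.numeric(x)) {
      summ <- vapply(lev_g, function(l) .fmt_mean_sd(x[g == l]), "")
      ht <- tryCatch(
        stats::t.test(x[g == lev_g[1]], x[g == lev_g[2]], var.equal = pooled_t),
        error = function(e) NULL)
      rows[[v]] <- tibble::tibble(variable = v, level = NA_character_,
                                  !!!as.list(summ),
                                  p_value = if (is.null(ht)) NA_real_ else ht$p.value,
                                  test = if (pooled_t) "t-test (pooled)" else "t-test (Welch)")
    } else {
      x <- as.character(x)
      lev_x <- if (!is.null(.pv_levels[[v]])) intersect(.pv_levels[[v]], unique(x))
               else sort(unique(x))
      counts <- vapply(lev_g, function(l)
        vapply(lev_x, function(k) sum(x == k & g == l), 0L), integer(length(lev_x)))
      counts <- matrix(counts, nrow = length(lev_x),
                       dimnames = list(lev_x, lev_g))
      tst <- contingency_test(counts)
      block <- tibble::tibble(variable = v, level = lev_x)
      for (l in lev_g)
        block[[l]] <- vapply(seq_along(lev_x), function(i)
          .fmt_n_pct(counts[i, l], sum(counts[, l])), "")
      block$p_value <- c(tst$p_value, rep(NA_real_, length(lev_x) - 1))
      block$test <- c(tst$test, rep(NA_character_, length(lev_x) - 1))
      rows[[v]] <- block
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_strata") <- as.integer(n_strata)
  names(attr(out, "n_strata")) <- names(n_strata)
  class(out) <- c("pv_baseline_table", class(out))
  out
}
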