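`%||%` <- function(a, b) if (is.null(a)) b else a

# Toy fixtures shared across tests: small coefficient sets with exponential
# (constant-hazard) baselines so every survival quantity has a closed form,
# plus in-code cohort builders.

# Coefficient set with a single PI term 0.5 * ln(nodes + 1) in both strata,
# exponential baselines H0(t) = rate * t, and simple treatment log-HRs.
toy_coefs <- function(rate_breast = 0.02, rate_other = 0.01,
                      pi_coef = 0.5, mi_a = 0.0698252, mi_b = 34.23391957,
                      treatments = list(hormone = -0.4, chemo = -0.2,
                                        trastuzumab = -0.3),
                      support = c(1e-6, 20)) {
  term <- list(covariate = "nodes", shift = 1, power = 0, coefficient = pi_coef)
  coefficient_set(
    version = "toy",
    strata = list(
      positive = list(pi_terms = list(term),
                      baseline_breast = baseline_exponential(rate_breast, support)),
      negative = list(pi_terms = list(term),
                      baseline_breast = baseline_exponential(rate_breast, support))),
    baseline_other = baseline_exponential(rate_other, support),
    treatments = treatments,
    mi = list(a = mi_a, b = mi_b),
    ranges = list(age_years = c(18, 100), size_mm = c(0.1, 500), nodes = c(0, 100)))
}

toy_record <- function(id = "p1", age_years = 60, menopause = "post",
                       detection = "symptoms", size_mm = 20, grade = 2L,
                       nodes = 0L, er = "positive", her2 = "negative",
                       ki67 = "unknown", hormone = FALSE, chemo = FALSE,
                       trastuzumab = FALSE, radiotherapy = FALSE) {
  tibble::tibble(id = id, age_years = age_years, menopause = menopause,
                 detection = detection, size_mm = size_mm, grade = grade,
                 nodes = nodes, er = er, her2 = her2, ki67 = ki67,
                 hormone = hormone, chemo = chemo, trastuzumab = trastuzumab,
                 radiotherapy = radiotherapy)
}

# Small valid cohort data frame with randomized covariates and follow-up.
make_cohort_df <- function(n = 20, seed = 1) {
  set.seed(seed)
  data.frame(
    id = sprintf("c%03d", seq_len(n)),
    age_years = round(runif(n, 30, 80), 1),
    menopause = sample(c("pre", "post"), n, replace = TRUE),
    detection = sample(c("screening", "symptoms", "unknown"), n, replace = TRUE,
                       prob = c(0.4, 0.55, 0.05)),
    size_mm = round(runif(n, 5, 60), 1),
    grade = sample(1:3, n, replace = TRUE),
    nodes = rpois(n, 1),
    er = sample(c("positive", "negative"), n, replace = TRUE, prob = c(0.8, 0.2)),
    her2 = sample(c("positive", "negative", "unknown"), n, replace = TRUE,
                  prob = c(0.2, 0.75, 0.05)),
    ki67 = sample(c("positive", "negative", "unknown"), n, replace = TRUE,
                  prob = c(0.05, 0.05, 0.9)),
    hormone = sample(c(TRUE, FALSE), n, replace = TRUE),
    chemo = sample(c(TRUE, FALSE), n, replace = TRUE),
    trastuzumab = FALSE,
    radiotherapy = sample(c(TRUE, FALSE), n, replace = TRUE),
    followup_days = round(runif(n, 100, 5500)),
    dead = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.3, 0.7)),
    stringsAsFactors = FALSE
  ) |> (\(d) { d$cause <- ifelse(d$dead, sample(c("breast", "other"), n,
                                                replace = TRUE), NA); d })()
}

# Expand a levels-by-groups count matrix into per-patient rows of a minimal
# valid cohort carrying the categorical variable of interest, for feeding
# baseline_table with printed contingency tables.
cohort_from_counts <- function(counts, var, group_var = "er",
                               group_levels = c("negative", "positive")) {
  n <- sum(counts)
  lev <- rep(rep(rownames(counts), ncol(counts)), as.vector(counts))
  grp <- rep(rep(group_levels, each = nrow(counts)), as.vector(counts))
  df <- data.frame(
    id = sprintf("t%04d", seq_len(n)), age_years = 55, menopause = "post",
    detection = "symptoms", size_mm = 20, grade = 2, nodes = 0,
    er = grp, her2 = "unknown", ki67 = "unknown",
    hormone = FALSE, chemo = FALSE, trastuzumab = FALSE, radiotherapy = FALSE,
    followup_days = 3650, dead = FALSE, stringsAsFactors = FALSE)
  df[[var]] <- lev
  as_cohort(df)
}

# Perfectly calibrated survival data: each patient's event time is drawn so
# that P(T <= horizon) equals the given predicted risk (exponential times,
# fully observed).
calibrated_outcomes <- function(risk, horizon) {
  rate <- -log(1 - risk) / horizon
  times <- stats::rexp(length(risk), rate)
  list(times = times, events = rep(TRUE, length(risk)))
}
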