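# End-to-end validation pipeline: censor the cohort, score every patient,
# and assemble discrimination and calibration results per ER stratum and
# horizon, the baseline table and a multivariable Cox model, into a single
# deterministic report.

.cox_covariate_frame <- function(cohort) {
  # Multivariable Cox coding: age and size linear, grade as a linear score,
  # node count, ER-negative / screening / treatment indicators. Patients
  # with unknown detection mode are excluded (their count is reported).
  keep <- cohort$detection != "unknown"
  data.frame(
    age = cohort$age_years[keep],
    screening = as.integer(cohort$detection[keep] == "screening"),
    size = cohort$size_mm[keep],
    grade = as.numeric(cohort$grade[keep]),
    nodes = as.numeric(cohort$nodes[keep]),
    er_negative = as.integer(cohort$er[keep] == "negative"),
    hormone = as.integer(cohort$hormone[keep]),
    chemo = as.integer(cohort$chemo[keep]),
    trastuzumab = as.integer(cohort$trastuzumab[keep])
  )
}

.km_summary <- function(km, horizons) {
  at <- km_at(km, horizons)
  list(horizons = horizons, estimate = at$estimate,
       lower = at$lower, upper = at$upper)
}

.age_group <- function(age) cut(age, c(0, 50, 65, Inf),
                                labels = c("<=50", "51-65", ">65"))
.size_group <- function(size) cut(size, c(0, 20, 50, Inf),
                                  labels = c("<=20mm", "21-50mm", ">50mm"))
.nodes_group <- function(nodes) cut(nodes, c(-1, 0, 3, Inf),
                                    labels = c("0", "1-3", ">3"))
.treatment_group <- function(cohort) {
  dplyr::case_when(
    cohort$hormone & cohort$chemo ~ "hormone+chemo",
    cohort$hormone ~ "hormone only",
    cohort$chemo ~ "chemo only",
    TRUE ~ "other/none")
}

#' Run the full external-validation analysis
#'
#' Executes the validation pipeline on a cohort: administrative censoring at
#' the longest horizon, per-patient risk prediction, and then per ER stratum
#' (plus the full cohort) and per horizon: Royston D, median-split survival
#' curves with log-rank test, ROC AUC, predicted-versus-observed calibration
#' tables stratified by ER status, age group, tumour size, nodal burden and
#' adjuvant treatment, and the Integrated Calibration Index with smoothed
#' calibration curves and predicted-risk density. Also produces the overall
#' Kaplan-Meier curves by ER status, the baseline characteristics table and
#' a multivariable Cox model of all-cause mortality. Risk scores are
#' predicted all-cause mortality `1 - S(t)` by the horizon; Royston D at a
#' horizon is computed on follow-up censored at that horizon.
#'
#' The report is fully deterministic for a given cohort, coefficient set and
#' configuration.
#'
#' @param cohort A `pv_cohort`.
#' @param coeffs A [coefficient_set()].
#' @param config List: `horizons` (default `c(5, 10)`), `knots` (calibration
#'   spline knots, default 3).
#' @return A `pv_validation_report` list.
#' @export
run_validation <- function(cohort, coeffs, config = list()) {
  stopifnot(inherits(cohort, "pv_cohort"), inherits(coeffs, "pv_coefs"))
  horizons <- config$horizons %||% c(5, 10)
  knots <- config$knots %||% 3
  cohort <- censor_at(cohort, max(horizons))
  preds <- score_cohort(cohort, coeffs, horizons = horizons)

  strata_labels <- c("all", intersect(c("positive", "negative"),
                                      unique(cohort$er)))
  skipped <- setdiff(c("positive", "negative"), unique(cohort$er))
  for (s in skipped)
    warning("ER stratum '", s, "' absent from cohort; omitted from report",
            call. = FALSE)

  km_by_er <- lapply(stats::setNames(nm = setdiff(strata_labels, "all")),
                     function(s) {
    idx <- cohort$er == s
    .km_summary(km_fit(cohort$followup_years[idx], cohort$dead[idx]), horizons)
  })

  results <- list()
  for (s in strata_labels) {
    idx <- if (s == "all") rep(TRUE, nrow(cohort)) else cohort$er == s
    tt <- cohort$followup_years[idx]; ee <- cohort$dead[idx]
    for (h in horizons) {
      p_s <- preds$s[preds$horizon == h][idx]
      risk <- 1 - p_s
      tt_h <- pmin(tt, h); ee_h <- ee & tt <= h
      stage <- function(name, expr) tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed for stratum ", s, ", horizon ", h,
             ": ", conditionMessage(e)))
      d <- stage("royston_d", royston_d(risk, tt_h, ee_h))
      auc <- stage("horizon_auc", horizon_auc(risk, tt, ee, h))
      ms <- stage("median_split", median_split(risk, tt_h, ee_h))
      cal <- stage("calibration", ici(risk, tt, ee, h, knots = knots))
      results[[paste(s, h, sep = "_")]] <- list(
        stratum = s, horizon = h, n = sum(idx),
        royston_d = list(D = d$D, se = d$se),
        auc = auc[c("auc", "lower", "upper", "n_cases", "n_controls",
                    "n_excluded")],
        median_split = list(threshold = ms$threshold, n_low = ms$n_low,
                            n_high = ms$n_high,
                            logrank_p = ms$logrank$p_value,
                            low_km = .km_summary(ms$low, horizons),
                            high_km = .km_summary(ms$high, horizons)),
        calibration = list(ici = cal$ici, degenerate = cal$degenerate,
                           curve = as.list(cal$curve),
                           density = as.list(cal$density)))
    }
  }

  s_mat <- do.call(cbind, lapply(horizons, function(h)
    preds$s[preds$horizon == h]))
  strat_defs <- list(
    er = cohort$er,
    age_group = .age_group(cohort$age_years),
    size_group = .size_group(cohort$size_mm),
    nodes_group = .nodes_group(cohort$nodes),
    treatment = .treatment_group(cohort))
  pred_obs <- lapply(strat_defs, function(g)
    predicted_observed_table(s_mat, cohort$followup_years, cohort$dead,
                             horizons, strata = g))
  pred_obs$overall <- predicted_observed_table(
    s_mat, cohort$followup_years, cohort$dead, horizons)

  n_unknown_detection <- sum(cohort$detection == "unknown")
  cox_tab <- tryCatch({
    cx <- cox_fit(.cox_covariate_frame(cohort),
                  cohort$followup_years[cohort$detection != "unknown"],
                  cohort$dead[cohort$detection != "unknown"])
    cx$coefficients
  }, error = function(e) {
    warning("multivariable Cox stage skipped: ", conditionMessage(e),
            call. = FALSE)
    NULL
  })

  report <- list(
    meta = list(package_version = as.character(utils::packageVersion("predictval")),
                coeffs_version = coeffs$version,
                horizons = horizons, knots = knots,
                n = nrow(cohort), n_unknown_detection = n_unknown_detection),
    baseline = if (length(unique(cohort$er)) >= 2) baseline_table(cohort, "er")
               else NULL,
    km_by_er = km_by_er,
    cox_all_cause = cox_tab,
    metrics = results,
    predicted_observed = pred_obs
  )
  class(report) <- "pv_validation_report"
  report
}

.listify <- function(x) {
  if (is.data.frame(x)) lapply(as.list(x), .listify)
  else if (is.list(x)) lapply(x, .listify)
  else if (is.factor(x)) as.character(x)
  else x
}

#' Write a validation report to disk
#'
#' Serializes the report as a single JSON file plus plot-ready CSV tables
#' (predicted-vs-observed tables, calibration curves with the identity
#' reference and risk density, and the multivariable Cox table). Output is
#' byte-identical across runs on identical inputs.
#'
#' @param report A `pv_validation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "pv_validation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(.listify(unclass(report)),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  po <- dplyr::bind_rows(report$predicted_observed, .id = "grouping")
  utils::write.csv(po, file.path(dir, "predicted_observed.csv"),
                   row.names = FALSE)
  curves <- dplyr::bind_rows(lapply(report$metrics, function(m)
    tibble::tibble(stratum = m$stratum, horizon = m$horizon,
                   predicted = m$calibration$curve$predicted,
                   observed = m$calibration$curve$observed,
                   identity = m$calibration$curve$identity)))
  utils::write.csv(curves, file.path(dir, "calibration_curves.csv"),
                   row.names = FALSE)
  if (!is.null(report$cox_all_cause))
    utils::write.csv(as.data.frame(report$cox_all_cause),
                     file.path(dir, "cox_all_cause.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$baseline),
                   file.path(dir, "baseline_table.csv"), row.names = FALSE)
  invisible(dir)
}
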