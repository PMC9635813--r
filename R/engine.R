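# Prognostic engine: PI / MI / TE linear predictors and the competing-risk
# survival composition S(t) = bS(t) * oS(t).
#
# The published formula writes bS = exp(-exp(baseline + PI + TE)). For this
# to yield probabilities in (0, 1) the "baseline ... at time t" must be the
# baseline LOG CUMULATIVE HAZARD, so the engine computes
#   bS(t) = exp(-H0(t) * exp(PI + TE)),   oS(t) = exp(-H0_other(t) * exp(MI)),
# i.e. proportional hazards on each cause-specific baseline, and composes
# overall survival under independent competing risks as S = bS * oS.

.clamp_records <- function(records, coeffs, clamp) {
  for (field in names(coeffs$ranges)) {
    if (!field %in% names(records)) next
    rng <- coeffs$ranges[[field]]
    out_of_range <- records[[field]] < rng[1] | records[[field]] > rng[2]
    if (any(out_of_range)) {
      if (!clamp)
        stop("covariate '", field, "' outside admissible range [",
             rng[1], ", ", rng[2], "] for ", sum(out_of_range), " record(s)")
      warning(sum(out_of_range), " value(s) of '", field,
              "' clamped to admissible range [", rng[1], ", ", rng[2], "]",
              call. = FALSE)
      records[[field]] <- pmin(pmax(records[[field]], rng[1]), rng[2])
    }
  }
  records
}

.as_records <- function(record) {
  if (is.data.frame(record)) tibble::as_tibble(record)
  else tibble::as_tibble(record[!vapply(record, is.null, TRUE)])
}

#' Prognostic index (PI)
#'
#' Sum of the weighted prognostic factors for the record's ER stratum:
#' `PI = sum coefficient * (transform(covariate) - center)` over numeric
#' terms plus the categorical level offsets. Covariates outside the
#' admissible ranges are clamped to the range bounds with a warning
#' (`clamp = FALSE` raises instead).
#'
#' @param record A patient record: one- or many-row data frame (or named
#'   list) with the cohort covariate columns.
#' @param coeffs A [coefficient_set()].
#' @param clamp Clamp out-of-range covariates instead of erroring.
#' @return Numeric vector of PI values, one per record.
#' @export
compute_pi <- function(record, coeffs, clamp = TRUE) {
  stopifnot(inherits(coeffs, "pv_coefs"))
  records <- .clamp_records(.as_records(record), coeffs, clamp)
  pi_out <- numeric(nrow(records))
  for (s in unique(as.character(records$er))) {
    stratum <- coeffs$strata[[s]]
    if (is.null(stratum)) stop("no coefficient stratum for ER level '", s, "'")
    idx <- which(records$er == s)
    acc <- numeric(length(idx))
    for (tm in stratum$pi_terms) {
      v <- records[[tm$covariate]][idx]
      if (!is.null(tm$levels)) {
        offsets <- unlist(tm$levels)
        lev <- as.character(v)
        miss <- setdiff(unique(lev), names(offsets))
        if (length(miss))
          stop("no level offset for '", tm$covariate, "' = ",
               paste(miss, collapse = ", "))
        acc <- acc + unname(offsets[lev])
      } else {
        acc <- acc + tm$coefficient *
          (eval_transform(as.numeric(v), tm) - (tm$center %||% 0))
      }
    }
    pi_out[idx] <- acc
  }
  pi_out
}

#' Other-cause mortality index (MI)
#'
#' Age-driven linear predictor for non-breast-cancer mortality:
#' `MI = a * ((age / 10)^2 - b)` with the constants carried by the
#' coefficient set (published defaults a = 0.0698252, b = 34.23391957).
#'
#' @param age_years Age(s) at diagnosis in years, positive.
#' @param coeffs A [coefficient_set()].
#' @return Numeric vector of MI values.
#' @export
compute_mi <- function(age_years, coeffs) {
  stopifnot(inherits(coeffs, "pv_coefs"))
  if (any(age_years <= 0)) stop("age must be positive")
  coeffs$mi$a * ((age_years / 10)^2 - coeffs$mi$b)
}

.te_applies <- function(name, entry, records) {
  ok <- rep(TRUE, nrow(records))
  if (name == "hormone") ok <- records$er == "positive"
  req <- entry$requires
  if (!is.null(req))
    for (field in names(req)) ok <- ok & records[[field]] == req[[field]]
  ok
}

#' Treatment effect (TE)
#'
#' Sum of the log-hazard-ratios of the adjuvant treatments each patient
#' received, restricted to treatments relevant to the patient: hormone
#' therapy contributes only for ER-positive tumours (a hormone flag on an
#' ER-negative record is excluded with a warning), and any `requires`
#' condition in the coefficient entry (e.g. trastuzumab requiring HER2
#' positivity) must hold. No treatments gives TE = 0. Radiotherapy carries
#' no term in the supported model and never contributes.
#'
#' @inheritParams compute_pi
#' @return Numeric vector of TE values.
#' @export
compute_te <- function(record, coeffs) {
  stopifnot(inherits(coeffs, "pv_coefs"))
  records <- .as_records(record)
  te <- numeric(nrow(records))
  for (name in names(coeffs$treatments)) {
    if (!name %in% names(records)) next
    flag <- as.logical(records[[name]])
    applies <- .te_applies(name, coeffs$treatments[[name]], records)
    if (name == "hormone" && any(flag & !applies))
      warning(sum(flag & !applies),
              " hormone-therapy flag(s) on ER-negative record(s) excluded from TE",
              call. = FALSE)
    te <- te + ifelse(flag & applies, coeffs$treatments[[name]]$loghr, 0)
  }
  te
}

#' Breast-cancer-specific survival bS(t)
#'
#' `bS(t) = exp(-exp(L0(t) + PI + TE))` with L0 the stratum's baseline log
#' cumulative hazard, equivalently `exp(-H0(t) * exp(PI + TE))`.
#'
#' @param t Horizon(s) in years within the baseline support.
#' @param pi,te Prognostic index and treatment effect (log-hazard scale).
#' @param stratum ER stratum label (`"positive"` or `"negative"`).
#' @param coeffs A [coefficient_set()].
#' @return Survival probabilities in `[0, 1]`.
#' @export
breast_survival <- function(t, pi, te, stratum, coeffs) {
  stopifnot(inherits(coeffs, "pv_coefs"))
  base <- coeffs$strata[[as.character(stratum)]]$baseline_breast
  if (is.null(base)) stop("no coefficient stratum for ER level '", stratum, "'")
  exp(-baseline_cumhaz(base, t) * exp(pi + te))
}

#' Other-cause survival oS(t)
#'
#' `oS(t) = exp(-exp(L0_other(t) + MI))` with the other-cause baseline log
#' cumulative hazard.
#'
#' @inheritParams breast_survival
#' @param mi Mortality index values.
#' @return Survival probabilities in `[0, 1]`.
#' @export
other_survival <- function(t, mi, coeffs) {
  stopifnot(inherits(coeffs, "pv_coefs"))
  exp(-baseline_cumhaz(coeffs$baseline_other, t) * exp(mi))
}

#' Predict overall survival for patient records
#'
#' Full risk prediction: computes PI, MI and TE per patient and the
#' composed survival probabilities `bS`, `oS` and `S = bS * oS` at each
#' requested horizon under independent competing risks.
#'
#' @inheritParams compute_pi
#' @param horizons Horizons in years (default 5 and 10).
#' @return A tibble with one row per patient and horizon: `id`, `er`, `pi`,
#'   `mi`, `te`, `horizon`, `bs`, `os`, `s`.
#' @export
predict_overall_survival <- function(record, coeffs, horizons = c(5, 10),
                                     clamp = TRUE) {
  records <- .clamp_records(.as_records(record), coeffs, clamp)
  n <- nrow(records)
  id <- if ("id" %in% names(records)) as.character(records$id) else as.character(seq_len(n))
  pi <- compute_pi(records, coeffs, clamp = FALSE)  # already clamped above
  mi <- compute_mi(records$age_years, coeffs)
  te <- compute_te(records, coeffs)
  out <- lapply(horizons, function(h) {
    bs <- numeric(n); os <- other_survival(h, mi, coeffs)
    for (s in unique(as.character(records$er))) {
      idx <- records$er == s
      bs[idx] <- breast_survival(h, pi[idx], te[idx], s, coeffs)
    }
    tibble::tibble(id = id, er = as.character(records$er), pi = pi, mi = mi,
                   te = te, horizon = h, bs = bs, os = os, s = bs * os)
  })
  dplyr::bind_rows(out)
}

#' @rdname predict_overall_survival
#' @param cohort A `pv_cohort`.
#' @export
score_cohort <- function(cohort, coeffs, horizons = c(5, 10), clamp = TRUE) {
  predict_overall_survival(cohort, coeffs, horizons = horizons, clamp = clamp)
}
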