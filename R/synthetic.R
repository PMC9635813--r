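# Synthetic cohorts: covariates drawn to emulate the marginal structure of
# an early-breast-cancer validation cohort (per-ER-stratum means, SDs and
# category frequencies), with event times drawn from the engine's own
# competing-risk model so that every downstream validation statistic has a
# known ground truth. Covariates are sampled independently within stratum;
# real joint dependence (e.g. grade-size) is deliberately not modelled.

#' Default synthetic-cohort specification
#'
#' Covariate samplers per ER stratum (truncated-normal age, truncated
#' log-normal tumour size matched to a target mean/SD, zero-inflated
#' negative-binomial node counts, categorical frequencies for grade,
#' menopause, detection mode, HER2 and Ki67), a treatment-assignment rule
#' giving the per-stratum adjuvant regimen mix, and an administrative
#' censoring model (uniform accrual over `accrual_years` with a guaranteed
#' `min_followup`, then a `cap`-year cap). Defaults emulate a South American
#' hospital cohort of 873 women with early breast cancer (85% ER-positive).
#'
#' @param n Default cohort size.
#' @param horizons Horizons (years) at which true survival is recorded.
#' @return A `pv_synth_spec` list; override elements before sampling to
#'   change the study conditions.
#' @export
synthetic_spec <- function(n = 873, horizons = c(5, 10)) {
  spec <- list(
    n = n,
    er_negative_prop = 130 / 873,
    horizons = horizons,
    censoring = list(accrual_years = 15, min_followup = 5, cap = 10),
    strata = list(
      positive = list(
        age = list(mean = 58.5, sd = 12.7, range = c(25, 85)),
        size = list(mean = 21.1, sd = 12.8, range = c(1, 120)),
        nodes = list(p_zero = 0.35, nb_size = 0.6, nb_mu = 1.6, max = 30),
        grade = c("1" = 240, "2" = 403, "3" = 100) / 743,
        menopause = c(pre = 230, post = 513) / 743,
        detection = c(screening = 276, symptoms = 459, unknown = 8) / 743,
        her2 = c(negative = 630, positive = 112, unknown = 1) / 743,
        ki67 = c(negative = 23, positive = 30, unknown = 690) / 743,
        regimens = c(hormone = 385, hormone_chemo = 293,
                     hormone_chemo_trastuzumab = 46, chemo = 15,
                     chemo_trastuzumab = 3, trastuzumab = 1) / 743,
        radiotherapy = 0.750
      ),
      negative = list(
        age = list(mean = 55.6, sd = 13.1, range = c(25, 85)),
        size = list(mean = 26.4, sd = 14.0, range = c(1, 120)),
        nodes = list(p_zero = 0.30, nb_size = 0.6, nb_mu = 2.4, max = 30),
        grade = c("1" = 3, "2" = 61, "3" = 66) / 130,
        menopause = c(pre = 46, post = 84) / 130,
        detection = c(screening = 35, symptoms = 94, unknown = 1) / 130,
        her2 = c(negative = 86, positive = 43, unknown = 1) / 130,
        ki67 = c(negative = 4, positive = 3, unknown = 123) / 130,
        regimens = c(chemo = 102, chemo_trastuzumab = 28) / 130,
        radiotherapy = 0.715
      )
    )
  )
  class(spec) <- "pv_synth_spec"
  .validate_synth_spec(spec)
  spec
}

.validate_synth_spec <- function(spec) {
  if (spec$n <= 0) stop("synthetic spec: n must be positive")
  if (spec$er_negative_prop < 0 || spec$er_negative_prop > 1)
    stop("synthetic spec: ER-negative proportion outside [0, 1]")
  for (s in names(spec$strata)) {
    st <- spec$strata[[s]]
    for (v in c("grade", "menopause", "detection", "her2", "ki67", "regimens")) {
      if (abs(sum(st[[v]]) - 1) > 1e-8)
        stop("synthetic spec: '", v, "' probabilities for stratum '", s,
             "' do not sum to 1")
      if (any(st[[v]] < 0)) stop("synthetic spec: negative probability in '", v, "'")
    }
    if (st$age$sd <= 0 || st$size$sd <= 0) stop("synthetic spec: non-positive SD")
  }
  invisible(spec)
}

.rtruncnorm <- function(n, mean, sd, range) {
  u <- stats::runif(n, stats::pnorm(range[1], mean, sd),
                    stats::pnorm(range[2], mean, sd))
  stats::qnorm(u, mean, sd)
}

.rtrunclnorm <- function(n, mean, sd, range) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  u <- stats::runif(n, stats::plnorm(range[1], meanlog, sdlog),
                    stats::plnorm(range[2], meanlog, sdlog))
  stats::qlnorm(u, meanlog, sdlog)
}

.rzinb <- function(n, p_zero, size, mu, max) {
  x <- stats::rnbinom(n, size = size, mu = mu)
  x[stats::runif(n) < p_zero] <- 0L
  pmin(x, max)
}

.rcat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Sample covariates for a synthetic cohort
#'
#' Draws `n` patient records (covariates and adjuvant-treatment flags, no
#' outcomes) from the spec's per-stratum samplers. Reproducible under a
#' fixed seed.
#'
#' @param spec A [synthetic_spec()].
#' @param n Number of records (default `spec$n`).
#' @param seed Integer seed.
#' @return Tibble of patient covariates and treatment flags.
#' @export
sample_covariates <- function(spec, n = spec$n, seed = 1L) {
  .validate_synth_spec(spec)
  set.seed(seed)
  er <- ifelse(stats::runif(n) < spec$er_negative_prop, "negative", "positive")
  out <- tibble::tibble(
    id = sprintf("P%06d", seq_len(n)), er = er,
    age_years = NA_real_, menopause = NA_character_, detection = NA_character_,
    size_mm = NA_real_, grade = NA_integer_, nodes = NA_integer_,
    her2 = NA_character_, ki67 = NA_character_,
    hormone = FALSE, chemo = FALSE, trastuzumab = FALSE, radiotherapy = FALSE)
  for (s in c("positive", "negative")) {
    st <- spec$strata[[s]]
    idx <- which(er == s)
    m <- length(idx)
    if (m == 0) next
    out$age_years[idx] <- .rtruncnorm(m, st$age$mean, st$age$sd, st$age$range)
    out$size_mm[idx] <- .rtrunclnorm(m, st$size$mean, st$size$sd, st$size$range)
    out$nodes[idx] <- .rzinb(m, st$nodes$p_zero, st$nodes$nb_size,
                             st$nodes$nb_mu, st$nodes$max)
    out$grade[idx] <- as.integer(.rcat(m, st$grade))
    out$menopause[idx] <- .rcat(m, st$menopause)
    out$detection[idx] <- .rcat(m, st$detection)
    out$her2[idx] <- .rcat(m, st$her2)
    out$ki67[idx] <- .rcat(m, st$ki67)
    reg <- .rcat(m, st$regimens)
    out$hormone[idx] <- grepl("hormone", reg)
    out$chemo[idx] <- grepl("chemo", reg)
    out$trastuzumab[idx] <- grepl("trastuzumab", reg)
    out$radiotherapy[idx] <- stats::runif(m) < st$radiotherapy
  }
  out
}

# Invert H0(t) * relhaz = target cumulative hazards by vectorized monotone
# bisection to 1e-8 years; Inf where the target exceeds H0 at the support end.
.invert_cumhaz <- function(baseline, targets) {
  tmax <- baseline$support[2]
  tmin <- baseline$support[1]
  out <- rep(Inf, length(targets))
  h_max <- baseline_cumhaz(baseline, tmax)
  h_min <- baseline_cumhaz(baseline, tmin)
  early <- targets <= h_min
  out[early] <- tmin * targets[early] / h_min  # linear extension is exact here
  todo <- which(!early & targets <= h_max)
  if (length(todo)) {
    lo <- rep(tmin, length(todo)); hi <- rep(tmax, length(todo))
    tg <- targets[todo]
    while (max(hi - lo) > 1e-8) {
      mid <- (lo + hi) / 2
      below <- baseline_cumhaz(baseline, mid) < tg
      lo[below] <- mid[below]
      hi[!below] <- mid[!below]
    }
    out[todo] <- (lo + hi) / 2
  }
  out
}

#' Sample competing-risk outcomes from the engine's own model
#'
#' For each record draws independent uniforms and inverts the cause-specific
#' cumulative hazards: the breast-cancer death time solves
#' `H0_breast(t) * exp(PI + TE) = -log(u1)` by monotone bisection (tolerance
#' 1e-8 years) and the other-cause time solves the analogous equation with
#' MI. The observed time is the minimum of the two death times and an
#' administrative censoring time (uniform over the accrual window), with the
#' event flag and cause of death recorded; the `cap`-year administrative cap
#' is applied last. Patients whose drawn hazard target exceeds the baseline
#' support are censored at the support end (counted in attribute
#' `n_support_censored`).
#'
#' @param records Covariate tibble (e.g. from [sample_covariates()]).
#' @param coeffs A [coefficient_set()].
#' @param censoring List with `accrual_years`, `min_followup`, `cap`.
#' @param seed Integer seed.
#' @return Tibble with `followup_years`, `dead`, `cause`.
#' @export
sample_outcomes <- function(records, coeffs,
                            censoring = list(accrual_years = 15,
                                             min_followup = 5, cap = 10),
                            seed = 1L) {
  set.seed(seed)
  n <- nrow(records)
  pi <- compute_pi(records, coeffs)
  mi <- compute_mi(records$age_years, coeffs)
  te <- compute_te(records, coeffs)
  u1 <- stats::runif(n); u2 <- stats::runif(n)
  t_breast <- rep(Inf, n)
  for (s in unique(as.character(records$er))) {
    idx <- which(records$er == s)
    base <- coeffs$strata[[s]]$baseline_breast
    t_breast[idx] <- .invert_cumhaz(base, -log(u1[idx]) / exp(pi[idx] + te[idx]))
  }
  t_other <- .invert_cumhaz(coeffs$baseline_other, -log(u2) / exp(mi))
  support_end <- min(vapply(coeffs$strata, function(s) s$baseline_breast$support[2],
                            0), coeffs$baseline_other$support[2])
  cens <- stats::runif(n, censoring$min_followup,
                       censoring$min_followup + censoring$accrual_years)
  t_death <- pmin(t_breast, t_other)
  n_support_censored <- sum(!is.finite(t_death) & cens > support_end)
  cens <- pmin(cens, support_end)
  obs <- pmin(t_death, cens)
  dead <- t_death <= cens
  cause <- ifelse(dead, ifelse(t_breast <= t_other, "breast", "other"),
                  NA_character_)
  cap <- censoring$cap
  over <- obs > cap
  obs[over] <- cap; dead[over] <- FALSE; cause[over] <- NA_character_
  structure(tibble::tibble(followup_years = obs, dead = dead, cause = cause),
            n_support_censored = n_support_censored)
}

#' Simulate a full cohort with known ground truth
#'
#' Composes [sample_covariates()] and [sample_outcomes()] (independent
#' sub-seeds split deterministically from `seed`) and records each
#' patient's true PI, MI, TE and true survival probabilities on the spec's
#' horizon grid, computed by the same engine that generated the outcomes.
#'
#' @inheritParams sample_covariates
#' @param coeffs A [coefficient_set()].
#' @return A `pv_sim_cohort` list: `cohort` (a `pv_cohort`), `truth`
#'   (tibble from [score_cohort()]), `coeffs_version`, `seed`.
#' @export
simulate_cohort <- function(spec, coeffs, n = spec$n, seed = 1L) {
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, 2)
  records <- sample_covariates(spec, n, seed = subseeds[1])
  outcomes <- sample_outcomes(records, coeffs, censoring = spec$censoring,
                              seed = subseeds[2])
  cohort <- as_cohort(dplyr::bind_cols(records, outcomes),
                      source = sprintf("simulated(seed=%d)", seed))
  truth <- score_cohort(cohort, coeffs, horizons = spec$horizons)
  structure(list(cohort = cohort, truth = truth,
                 coeffs_version = coeffs$version, seed = seed),
            class = "pv_sim_cohort")
}
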