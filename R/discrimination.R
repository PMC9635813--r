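# Discrimination of a prognostic model: Royston D prognostic separation,
# fixed-horizon ROC/AUC on censored follow-up, and median-split survival
# curves. These statistics are computed in-package; only the underlying Cox
# partial-likelihood maximization is delegated to survival::coxph.

#' Blom rankits (expected standard-normal order statistics)
#'
#' Maps values to `qnorm((r - 3/8) / (n + 1/4))` of their ranks, with tied
#' values receiving the rankit of their average rank.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rankits.
#' @export
blom_rankits <- function(x) {
  n <- length(x)
  stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
}

#' Royston D prognostic-separation statistic
#'
#' Ranks the prognostic values, replaces them by Blom rankits scaled by
#' `1 / sqrt(8 / pi)`, and fits a one-covariate Cox model on the scaled
#' rankits. D is the fitted coefficient and SE its standard error. D
#' estimates the log hazard ratio between two equal-sized risk groups formed
#' by splitting the prognostic index at its median; because only ranks
#' enter, D is invariant under any strictly increasing transform of the
#' prognostic values.
#'
#' @param pi_values Prognostic index (or any risk score) per patient, finite.
#' @param times Follow-up times in years.
#' @param events Event indicators (death from any cause).
#' @return List with `D`, `se` and `degenerate` (TRUE when the prognostic
#'   values are constant, in which case D = 0 and se = NA).
#' @export
royston_d <- function(pi_values, times, events) {
  stopifnot(length(pi_values) == length(times), all(is.finite(pi_values)))
  if (length(pi_values) < 10) stop("royston_d needs at least 10 observations")
  if (stats::sd(pi_values) == 0)
    return(list(D = 0, se = NA_real_, degenerate = TRUE))
  kappa <- sqrt(8 / pi)
  z <- blom_rankits(pi_values) / kappa
  fit <- cox_fit(data.frame(rankit = z), times, events)
  list(D = fit$coefficients$coef[1], se = fit$coefficients$se[1],
       degenerate = FALSE)
}

# Midrank-based DeLong structural components; O(n log n).
.delong_components <- function(cases, controls) {
  m <- length(cases); n <- length(controls)
  all_r <- rank(c(cases, controls), ties.method = "average")
  case_r <- rank(cases, ties.method = "average")
  ctrl_r <- rank(controls, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - case_r) / n             # per-case placement
  v01 <- 1 - (all_r[m + seq_len(n)] - ctrl_r) / m     # per-control placement
  auc <- mean(v10)
  var_auc <- stats::var(v10) / m + stats::var(v01) / n
  list(auc = auc, var = var_auc, v10 = v10, v01 = v01)
}

#' Fixed-horizon ROC AUC on censored follow-up
#'
#' Classifies patients at the horizon: cases died (any cause) at or before
#' it, controls were followed beyond it (or censored exactly at it);
#' patients censored alive before the horizon are excluded. The AUC is the
#' Mann-Whitney concordance of the risk score between cases and controls
#' with half credit for ties, with a DeLong confidence interval by default
#' or a seeded percentile bootstrap.
#'
#' @param risk Predicted death probability (or any risk score) per patient.
#' @param times Follow-up times in years.
#' @param events Event indicators.
#' @param horizon Horizon in years within the follow-up range.
#' @param ci `"delong"` or `"bootstrap"`.
#' @param level Confidence level.
#' @param boot_reps,boot_seed Bootstrap replications and seed.
#' @return List with `auc`, `lower`, `upper`, `n_cases`, `n_controls`,
#'   `n_excluded`, `ci_method`.
#' @export
horizon_auc <- function(risk, times, events, horizon, ci = c("delong", "bootstrap"),
                        level = 0.95, boot_reps = 2000, boot_seed = 1L) {
  ci <- match.arg(ci)
  stopifnot(length(risk) == length(times), length(times) == length(events))
  events <- as.logical(events)
  is_case <- events & times <= horizon
  is_control <- !is_case & times >= horizon
  excluded <- !is_case & !is_control
  m <- sum(is_case); n <- sum(is_control)
  if (m == 0 || n == 0)
    stop("degenerate horizon: ", m, " cases and ", n, " controls")
  dl <- .delong_components(risk[is_case], risk[is_control])
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (ci == "delong") {
    half <- z * sqrt(dl$var)
    lo <- max(0, dl$auc - half); hi <- min(1, dl$auc + half)
  } else {
    cs <- risk[is_case]; ct <- risk[is_control]
    aucs <- withr_seed_apply(boot_seed, boot_reps, function(...)
      .delong_components(sample(cs, m, replace = TRUE),
                         sample(ct, n, replace = TRUE))$auc)
    qs <- stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2))
    lo <- unname(qs[1]); hi <- unname(qs[2])
  }
  list(auc = dl$auc, lower = lo, upper = hi, n_cases = m, n_controls = n,
       n_excluded = sum(excluded), ci_method = ci)
}

# run f boot_reps times under a local seed, restoring RNG state after
withr_seed_apply <- function(seed, reps, f) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vapply(seq_len(reps), f, numeric(1))
}

#' Median-split survival curves
#'
#' Dichotomizes the risk distribution at its median (ties at the median go
#' to the low-risk group), fits a Kaplan-Meier curve per group and compares
#' them with the log-rank test.
#'
#' @inheritParams horizon_auc
#' @return List with `threshold`, `low` and `high` (`pv_km` curves),
#'   `n_low`, `n_high` and `logrank` (see [logrank_test()]).
#' @export
median_split <- function(risk, times, events) {
  stopifnot(length(risk) >= 4)
  med <- stats::median(risk)
  high <- risk > med
  if (!any(high) || all(high)) stop("no split possible: risks do not separate at the median")
  list(threshold = med,
       low = km_fit(times[!high], events[!high]),
       high = km_fit(times[high], events[high]),
       n_low = sum(!high), n_high = sum(high),
       logrank = logrank_test(times, events, ifelse(high, "high", "low")))
}
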