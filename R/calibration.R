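# Calibration of predicted against observed survival: stratified
# predicted-vs-observed tables, the Integrated Calibration Index (ICI), and
# restricted-cubic-spline smoothed calibration curves with the density of
# predicted risk.

#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline basis in Harrell's normalized
#' form: for K knots the basis has K - 1 columns (the linear term plus
#' K - 2 spline terms), linear beyond the boundary knots.
#'
#' @param x Numeric vector.
#' @param knots Knot locations, strictly increasing, length >= 3.
#' @return Matrix with `length(x)` rows and `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(unique(knots))
  K <- length(knots)
  stopifnot(K >= 3)
  norm <- (knots[K] - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), K - 1)
  out[, 1] <- x
  for (j in seq_len(K - 2)) {
    out[, j + 1] <- (pos3(x - knots[j]) -
      pos3(x - knots[K - 1]) * (knots[K] - knots[j]) / (knots[K] - knots[K - 1]) +
      pos3(x - knots[K]) * (knots[K - 1] - knots[j]) / (knots[K] - knots[K - 1])) / norm
  }
  colnames(out) <- c("x", paste0("s", seq_len(K - 2)))
  out
}

.default_knot_quantiles <- function(k) {
  switch(as.character(k),
         "3" = c(0.10, 0.50, 0.90),
         "4" = c(0.05, 0.35, 0.65, 0.95),
         "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
         seq(0.05, 0.95, length.out = k))
}

.clip_risk <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)

# Fit the calibration smoother: Cox model of all-cause death on an RCS basis
# of cll(predicted risk), with Breslow baseline. Returns a predictor
# function risk -> smoothed observed risk at the horizon, or NULL when the
# smoother is degenerate.
.fit_calibration_smoother <- function(predicted_risk, times, events, horizon,
                                      knots) {
  p <- .clip_risk(predicted_risk)
  cll <- log(-log(1 - p))
  if (stats::sd(cll) < 1e-8) return(NULL)
  kq <- .default_knot_quantiles(knots)
  kl <- unique(stats::quantile(cll, kq, names = FALSE, type = 7))
  if (length(kl) < 3) return(NULL)
  basis <- rcs_basis(cll, kl)
  dat <- data.frame(basis, .time = times, .event = as.integer(as.logical(events)))
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(colnames(basis), collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(survival::coxph(fml, data = dat, ties = "breslow")),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(stats::coef(fit)))) return(NULL)
  bh <- survival::basehaz(fit, centered = FALSE)
  h0 <- if (any(bh$time <= horizon))
    stats::approx(bh$time, bh$hazard, xout = horizon, method = "constant",
                  rule = 2, f = 0)$y
  else 0
  beta <- stats::coef(fit)
  function(risk) {
    cl <- log(-log(1 - .clip_risk(risk)))
    lp <- drop(rcs_basis(cl, kl) %*% beta)
    1 - exp(-h0 * exp(lp))
  }
}

.calibration_result <- function(predicted_risk, times, events, horizon, knots,
                                grid) {
  p <- .clip_risk(predicted_risk)
  smoother <- .fit_calibration_smoother(p, times, events, horizon, knots)
  degenerate <- is.null(smoother)
  if (degenerate) {
    obs <- 1 - km_at(km_fit(times, events), horizon)$estimate
    smoother <- function(risk) rep(obs, length(risk))
  }
  smoothed <- smoother(p)
  if (is.null(grid))
    grid <- seq(stats::quantile(p, 0.01), stats::quantile(p, 0.99),
                length.out = 100)
  dens <- stats::density(p, from = max(0, min(p) - 0.05),
                         to = min(1, max(p) + 0.05))
  out <- list(
    ici = mean(abs(p - smoothed)),
    horizon = horizon,
    curve = tibble::tibble(predicted = grid, observed = smoother(grid),
                           identity = grid),
    per_patient = tibble::tibble(predicted = p, smoothed = smoothed),
    density = tibble::tibble(risk = dens$x, density = dens$y),
    degenerate = degenerate
  )
  class(out) <- "pv_calibration"
  out
}

#' Integrated Calibration Index (ICI)
#'
#' Mean absolute difference between predicted death probabilities by the
#' horizon and observed probabilities from a smoothed calibration curve.
#' The smoother is a Cox model of all-cause death on a restricted cubic
#' spline basis of the complementary log-log transformed predicted risk,
#' with knots at default quantiles (10/50/90 percentiles for 3 knots) and a
#' Breslow baseline; each patient's smoothed observed risk is the model's
#' predicted death probability at the horizon. Near-constant predicted risk
#' falls back to the overall Kaplan-Meier risk at the horizon for every
#' patient, flagged `degenerate`.
#'
#' @param predicted_risk Predicted death probability by the horizon, in
#'   (0, 1); values are clipped to `[1e-6, 1 - 1e-6]` before the
#'   complementary log-log transform.
#' @param times Follow-up times in years.
#' @param events Event indicators (death from any cause).
#' @param horizon Horizon in years.
#' @param knots Number of restricted-cubic-spline knots (default 3).
#' @return A `pv_calibration` list: `ici`, `horizon`, `curve` (grid tibble
#'   `predicted`, `observed`, `identity`), `per_patient`, `density` (kernel
#'   density of predicted risk), `degenerate`.
#' @export
ici <- function(predicted_risk, times, events, horizon, knots = 3) {
  stopifnot(length(predicted_risk) == length(times),
            all(predicted_risk >= 0 & predicted_risk <= 1))
  .calibration_result(predicted_risk, times, events, horizon, knots, grid = NULL)
}

#' Smoothed calibration curve on a supplied grid
#'
#' Same smoother as [ici()], evaluated at the supplied grid of predicted
#' risks; the exported curve includes the identity-line reference.
#'
#' @inheritParams ici
#' @param grid Predicted-risk values at which to evaluate the curve.
#' @return A `pv_calibration` list (see [ici()]).
#' @export
calibration_curve <- function(predicted_risk, times, events, horizon,
                              grid = NULL, knots = 3) {
  .calibration_result(predicted_risk, times, events, horizon, knots, grid = grid)
}

#' Predicted-versus-observed survival table
#'
#' Tabulates, per stratum and horizon, the mean predicted survival (with a
#' normal-approximation confidence interval of the mean) against the
#' Kaplan-Meier observed survival (with its complementary log-log
#' interval). Empty strata are omitted with a warning.
#'
#' @param predicted Matrix of predicted survival probabilities S(t), one
#'   row per patient and one column per horizon (a vector is accepted for a
#'   single horizon).
#' @param times Follow-up times in years.
#' @param events Event indicators.
#' @param horizons Horizons in years matching the columns of `predicted`.
#' @param strata Optional factor of stratum labels (default: one stratum
#'   `"all"`).
#' @param level Confidence level.
#' @return A `pv_calibration_table` tibble: `stratum`, `horizon`, `n`,
#'   `predicted`, `pred_lower`, `pred_upper`, `observed`, `obs_lower`,
#'   `obs_upper`.
#' @export
predicted_observed_table <- function(predicted, times, events, horizons,
                                     strata = NULL, level = 0.95) {
  predicted <- as.matrix(predicted)
  stopifnot(nrow(predicted) == length(times), ncol(predicted) == length(horizons))
  if (is.null(strata)) strata <- rep("all", length(times))
  if (!is.factor(strata)) strata <- factor(strata)
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (s in levels(strata)) {
    idx <- strata == s
    if (!any(idx)) { warning("empty stratum '", s, "' omitted"); next }
    km <- km_fit(times[idx], events[idx])
    for (j in seq_along(horizons)) {
      pj <- predicted[idx, j]
      se <- stats::sd(pj) / sqrt(length(pj))
      obs <- km_at(km, horizons[j], level = level)
      rows[[length(rows) + 1]] <- tibble::tibble(
        stratum = s, horizon = horizons[j], n = sum(idx),
        predicted = mean(pj),
        pred_lower = max(0, mean(pj) - z * se),
        pred_upper = min(1, mean(pj) + z * se),
        observed = obs$estimate, obs_lower = obs$lower, obs_upper = obs$upper)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pv_calibration_table", class(out))
  out
}
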