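# Nonparametric and semiparametric survival estimation used by every
# downstream validation stage. Estimation is delegated to the survival
# package (survfit / survdiff / coxph); this module fixes the conventions
# (Greenwood variance, complementary-log-log confidence intervals, Efron
# ties) and returns tidy containers.

#' Kaplan-Meier fit with Greenwood variance
#'
#' Product-limit estimate of the survival function. Events precede
#' censorings at tied times (the standard convention). The stored variance
#' is the Greenwood estimate of Var(S(t)).
#'
#' @param times Follow-up times in years, non-negative.
#' @param events Logical (or 0/1) event indicators.
#' @return A `pv_km` object: tibble of steps (`time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `var_greenwood`) with attributes `n` and `var_logs`
#'   (variance of log S, the Greenwood cumulative sum).
#' @export
km_fit <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (length(times) == 0) stop("empty input to km_fit")
  if (any(times < 0)) stop("negative follow-up time")
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1, conf.type = "none")
  var_logs <- fit$std.err^2          # Greenwood sum d / (n (n - d))
  steps <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv,
    var_greenwood = ifelse(fit$surv > 0, fit$surv^2 * var_logs, 0)
  )
  structure(steps, n = length(times), var_logs = var_logs,
            class = c("pv_km", class(steps)))
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Step-function value at `t` with a pointwise confidence interval from the
#' Greenwood variance. The default interval is on the complementary
#' log-log scale (bounded in `[0, 1]`); `"plain"` (linear) and `"log"`
#' transforms are available. Evaluation beyond the last follow-up time
#' returns the last estimate flagged `beyond_support`.
#'
#' @param curve A `pv_km`.
#' @param t Time(s) in years, non-negative.
#' @param transform CI transform: `"cloglog"`, `"plain"` or `"log"`.
#' @param level Confidence level.
#' @return Tibble with `time`, `estimate`, `lower`, `upper`, `beyond_support`.
#' @export
km_at <- function(curve, t, transform = c("cloglog", "plain", "log"),
                  level = 0.95) {
  stopifnot(inherits(curve, "pv_km"), all(t >= 0))
  transform <- match.arg(transform)
  z <- stats::qnorm(1 - (1 - level) / 2)
  event_steps <- curve$n_event > 0
  st <- curve$time[event_steps]
  ss <- curve$surv[event_steps]
  vl <- attr(curve, "var_logs")[event_steps]
  idx <- findInterval(t, st)              # 0 before first event step
  est <- ifelse(idx == 0, 1, ss[pmax(idx, 1)])
  varl <- ifelse(idx == 0, 0, vl[pmax(idx, 1)])
  lower <- upper <- rep(NA_real_, length(t))
  pos <- est > 0 & est < 1 & varl > 0
  if (any(pos)) {
    s <- est[pos]; v <- varl[pos]
    if (transform == "cloglog") {
      se_cll <- sqrt(v) / abs(log(s))
      lower[pos] <- s^exp(z * se_cll)
      upper[pos] <- s^exp(-z * se_cll)
    } else if (transform == "plain") {
      half <- z * s * sqrt(v)
      lower[pos] <- pmax(0, s - half)
      upper[pos] <- pmin(1, s + half)
    } else {
      half <- z * sqrt(v)
      lower[pos] <- s * exp(-half)
      upper[pos] <- pmin(1, s * exp(half))
    }
  }
  degenerate <- !pos
  lower[degenerate] <- est[degenerate]
  upper[degenerate] <- est[degenerate]
  tibble::tibble(time = t, estimate = est, lower = lower, upper = upper,
                 beyond_support = t > max(curve$time))
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-squared test on 1 degree of freedom.
#'
#' @inheritParams km_fit
#' @param groups Two-level group labels.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop("log-rank test requires exactly two non-empty groups")
  sd <- survival::survdiff(survival::Surv(times, as.integer(as.logical(events))) ~ g)
  df <- length(sd$n) - 1
  list(statistic = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood (Efron tie handling by default,
#' Breslow optional) and returns per-covariate hazard ratios with Wald
#' confidence intervals and p-values. Non-convergence or a monotone
#' likelihood (perfect separation, diverging coefficient) raises a
#' diagnostic error rather than returning a silent result.
#'
#' @param covariates Numeric vector, matrix or data frame of covariates
#'   (one column per covariate).
#' @inheritParams km_fit
#' @param ties `"efron"` or `"breslow"`.
#' @param level Confidence level for the Wald intervals.
#' @return A `pv_cox` list: `coefficients` tibble (`term`, `coef`, `se`,
#'   `hr`, `lower`, `upper`, `p_value`), `vcov`, `loglik`, `iter`, `ties`.
#' @export
cox_fit <- function(covariates, times, events, ties = c("efron", "breslow"),
                    level = 0.95) {
  ties <- match.arg(ties)
  x <- as.data.frame(covariates)
  if (ncol(x) == 1 && is.null(colnames(covariates))) names(x) <- "x"
  stopifnot(nrow(x) == length(times))
  if (any(vapply(x, function(col) stats::var(as.numeric(col)) == 0, TRUE)))
    stop("constant covariate column in Cox fit")
  if (nrow(x) <= ncol(x)) stop("more covariates than informative observations")
  dat <- cbind(x, .time = times, .event = as.integer(as.logical(events)))
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~", paste(names(x), collapse = " + ")))
  warn <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) { warn <<- conditionMessage(w); invokeRestart("muffleWarning") })
  if (!is.null(warn) && grepl("infinite|converge|singular", warn, ignore.case = TRUE))
    stop("Cox fit did not converge cleanly: ", warn)
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 20))
    stop("Cox fit diagnostic: coefficient diverging (monotone likelihood?)")
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- list(
    coefficients = tibble::tibble(
      term = names(beta), coef = unname(beta), se = unname(se),
      hr = exp(unname(beta)),
      lower = exp(unname(beta - z * se)), upper = exp(unname(beta + z * se)),
      p_value = 2 * stats::pnorm(-abs(unname(beta) / unname(se)))),
    vcov = as.matrix(stats::vcov(fit)),
    loglik = fit$loglik, iter = fit$iter, ties = ties, fit = fit)
  class(out) <- "pv_cox"
  out
}

#' @export
print.pv_cox <- function(x, ...) {
  cat("<pv_cox> ties =", x$ties, ", iterations =", x$iter, "\n")
  print(x$coefficients)
  invisible(x)
}
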