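# Coefficient configuration: versioned model weights for a PREDICT-style
# prognostic model. A coefficient set holds, per ER stratum, the prognostic
# index (PI) term list, a baseline log-cumulative-hazard specification for
# breast-cancer mortality, a shared other-cause baseline, the mortality-index
# (MI) constants, treatment log-hazard-ratios and admissible covariate ranges.

.fp_powers <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Evaluate a fractional-polynomial transform
#'
#' Transforms a covariate value `v` as `x = (v + shift) / scale`, then applies
#' the fractional-polynomial power `p` (with `p = 0` meaning natural log).
#' With `log_multiplier = TRUE` the result is multiplied by `log(x)` (the
#' repeated-power convention, so `p = 0` with the flag gives `log(x)^2`).
#'
#' @param value Numeric vector.
#' @param spec List with `scale` (default 1), `power` (default 1), `shift`
#'   (default 0), `log_multiplier` (default FALSE).
#' @return Transformed numeric vector.
#' @export
eval_transform <- function(value, spec) {
  scale <- spec$scale %||% 1
  shift <- spec$shift %||% 0
  power <- spec$power %||% 1
  if (!power %in% .fp_powers)
    stop("unsupported fractional-polynomial power: ", power)
  x <- (value + shift) / scale
  if (any(x <= 0 & (power <= 0 || isTRUE(spec$log_multiplier))))
    stop("transform undefined: non-positive argument with log or negative power")
  base <- if (power == 0) log(x) else x^power
  if (isTRUE(spec$log_multiplier)) base * log(x) else base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a baseline log-cumulative-hazard specification
#'
#' Two forms are supported:
#' * `fp`: log H0(t) = intercept + sum_j coef_j * t^(p_j) (* log t if flagged),
#'   the fractional-polynomial form used by the published model baselines;
#' * `table`: a year-indexed lookup `time` -> `log_cumhaz`, interpolated
#'   linearly in log H0 (monotone whenever the table is monotone).
#'
#' Below `support[1]` the cumulative hazard is extended linearly in t from
#' (0, 0) to (t_min, H0(t_min)), keeping early horizons and event-time
#' inversion defined; above `support[2]` evaluation is an error.
#'
#' @param type `"fp"` or `"table"`.
#' @param intercept,terms For `fp`: intercept and list of
#'   `list(power, coefficient, log_multiplier)` terms in t.
#' @param time,log_cumhaz For `table`: knot times (years) and values.
#' @param support Supported horizon `c(t_min, t_max)` in years.
#' @return A `pv_baseline` list.
#' @export
baseline_spec <- function(type = c("fp", "table"), intercept = 0, terms = list(),
                          time = NULL, log_cumhaz = NULL, support = c(0.5, 15)) {
  type <- match.arg(type)
  b <- list(type = type, support = as.numeric(support))
  if (type == "fp") {
    b$intercept <- intercept
    b$terms <- terms
  } else {
    stopifnot(length(time) == length(log_cumhaz), length(time) >= 2)
    ord <- order(time)
    b$time <- as.numeric(time[ord]); b$log_cumhaz <- as.numeric(log_cumhaz[ord])
    b$support <- c(max(support[1], min(b$time)), min(support[2], max(b$time)))
  }
  class(b) <- "pv_baseline"
  b
}

#' Exponential toy baseline (constant hazard)
#'
#' Convenience constructor for tests and simulations: H0(t) = rate * t,
#' i.e. log H0(t) = log(rate) + log(t).
#'
#' @param rate Constant baseline hazard per year.
#' @param support Supported horizon in years.
#' @return A `pv_baseline`.
#' @export
baseline_exponential <- function(rate, support = c(1e-6, 15)) {
  baseline_spec("fp", intercept = log(rate),
                terms = list(list(power = 0, coefficient = 1)),
                support = support)
}

#' Baseline cumulative hazard H0(t)
#'
#' @param baseline A `pv_baseline`.
#' @param t Time(s) in years, within `[0, support[2]]`.
#' @return H0(t), vectorized; H0(0) = 0.
#' @export
baseline_cumhaz <- function(baseline, t) {
  stopifnot(inherits(baseline, "pv_baseline"))
  if (any(t < 0 | t > baseline$support[2] + 1e-12))
    stop("time outside baseline support [0, ", baseline$support[2], "]")
  tmin <- baseline$support[1]
  eval_log <- function(tt) {
    if (baseline$type == "fp") {
      acc <- rep(baseline$intercept, length(tt))
      for (tm in baseline$terms) {
        p <- tm$power %||% 1
        base <- if (p == 0) log(tt) else tt^p
        if (isTRUE(tm$log_multiplier)) base <- base * log(tt)
        acc <- acc + tm$coefficient * base
      }
      acc
    } else {
      stats::approx(baseline$time, baseline$log_cumhaz, xout = tt, rule = 2)$y
    }
  }
  out <- numeric(length(t))
  lo <- t < tmin
  if (any(!lo)) out[!lo] <- exp(eval_log(t[!lo]))
  if (any(lo)) out[lo] <- t[lo] / tmin * exp(eval_log(tmin))  # linear near-zero extension
  out
}

#' Baseline log cumulative hazard
#' @inheritParams baseline_cumhaz
#' @return log H0(t) (`-Inf` at t = 0).
#' @export
baseline_log_cumhaz <- function(baseline, t) log(baseline_cumhaz(baseline, t))

.check_baseline_monotone <- function(baseline, label) {
  grid <- seq(baseline$support[1], baseline$support[2], length.out = 201)
  h <- baseline_cumhaz(baseline, grid)
  if (any(diff(h) < -1e-10))
    stop("baseline '", label, "' has a decreasing cumulative hazard over its support")
  invisible(TRUE)
}

.known_record_fields <- c("age_years", "menopause", "detection", "size_mm",
                          "grade", "nodes", "er", "her2", "ki67")

.coerce_baseline <- function(x) {
  if (inherits(x, "pv_baseline")) return(x)
  if (!is.null(x$type) && x$type == "table")
    baseline_spec("table", time = x$time, log_cumhaz = x$log_cumhaz,
                  support = x$support %||% c(0.5, 15))
  else
    baseline_spec("fp", intercept = x$intercept %||% 0, terms = x$terms %||% list(),
                  support = x$support %||% c(0.5, 15))
}

#' Construct a validated coefficient set
#'
#' Assembles and validates model weights. Every invariant is checked at
#' construction: both ER strata present, every PI term names a known patient
#' field, every treatment flag used by the treatment-effect sum has an entry,
#' and every baseline cumulative hazard is non-decreasing over its support.
#'
#' @param version Version label (mandatory).
#' @param strata Named list with elements `positive` and `negative`, each a
#'   list with `pi_terms` (list of numeric-term or categorical-level terms)
#'   and `baseline_breast` (a baseline spec or its list form).
#' @param baseline_other Other-cause baseline spec.
#' @param treatments Named list of treatment log-hazard-ratios; must contain
#'   `hormone`, `chemo`, `trastuzumab` (`bisphosphonates` optional). Each
#'   entry is a number, or a list `list(loghr =, requires = list(field = level))`
#'   restricting the term to patients matching the requirement.
#' @param mi MI constants `list(a =, b =)`; defaults to the published
#'   0.0698252 and 34.23391957.
#' @param ranges Admissible covariate ranges, named list of `c(lo, hi)`.
#' @return A `pv_coefs` object.
#' @export
coefficient_set <- function(version, strata, baseline_other, treatments,
                            mi = list(a = 0.0698252, b = 34.23391957),
                            ranges = list(age_years = c(25, 85),
                                          size_mm = c(1, 400),
                                          nodes = c(0, 50))) {
  if (is.null(version) || !nzchar(version)) stop("coefficient set needs a version label")
  for (s in c("positive", "negative"))
    if (is.null(strata[[s]])) stop("missing ER stratum '", s, "' in coefficient set")
  for (s in names(strata)) {
    for (tm in strata[[s]]$pi_terms) {
      if (is.null(tm$covariate) || !tm$covariate %in% .known_record_fields)
        stop("PI term references unknown patient field: ",
             tm$covariate %||% "<missing>")
      if (is.null(tm$levels)) {
        if (is.null(tm$coefficient)) stop("numeric PI term for '", tm$covariate,
                                          "' lacks a coefficient")
        if (!(tm$power %||% 1) %in% .fp_powers)
          stop("PI term for '", tm$covariate, "' has unsupported power")
      }
    }
    strata[[s]]$baseline_breast <- .coerce_baseline(strata[[s]]$baseline_breast)
    .check_baseline_monotone(strata[[s]]$baseline_breast,
                             paste0("breast/", s))
  }
  baseline_other <- .coerce_baseline(baseline_other)
  .check_baseline_monotone(baseline_other, "other-cause")
  for (tr in c("hormone", "chemo", "trastuzumab"))
    if (is.null(treatments[[tr]]))
      stop("treatment effect entry missing for '", tr, "'")
  treatments <- lapply(treatments, function(x)
    if (is.list(x)) x else list(loghr = as.numeric(x)))
  if (is.null(mi$a) || is.null(mi$b)) stop("MI constants a and b are required")
  out <- list(version = version, strata = strata, baseline_other = baseline_other,
              treatments = treatments, mi = mi, ranges = ranges)
  class(out) <- "pv_coefs"
  out
}

.coefs_allowed_keys <- c("version", "strata", "baseline_other", "treatments",
                         "mi", "ranges")

#' Load a coefficient set from a YAML or JSON configuration file
#'
#' Parses and validates a versioned coefficient configuration. Unknown
#' top-level keys are rejected; all [coefficient_set()] invariants are
#' checked at load, so an invalid configuration fails with a message naming
#' the offending entry.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pv_coefs` object.
#' @export
load_coefficients <- function(path) {
  if (!file.exists(path)) stop("coefficient file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .coefs_allowed_keys)
  if (length(unknown))
    stop("unknown key(s) in coefficient config: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$version)) stop("coefficient config lacks a version label")
  ranges <- cfg$ranges
  if (!is.null(ranges)) ranges <- lapply(ranges, as.numeric)
  args <- list(version = as.character(cfg$version), strata = cfg$strata,
               baseline_other = cfg$baseline_other, treatments = cfg$treatments)
  if (!is.null(cfg$mi)) args$mi <- cfg$mi
  if (!is.null(ranges)) args$ranges <- ranges
  do.call(coefficient_set, args)
}

#' Shipped PREDICT v2.1 coefficient configuration
#'
#' Returns the path to the packaged coefficient file transcribed from the
#' public PREDICT v2.1 source. The transcription ships for end-to-end use;
#' package correctness is established on toy coefficient sets, so no result
#' in the test suite depends on these particular numbers.
#'
#' @return File path of the YAML configuration.
#' @export
predict_v21_path <- function() {
  system.file("extdata", "predict_v2.1.yaml", package = "predictval",
              mustWork = TRUE)
}

#' @export
print.pv_coefs <- function(x, ...) {
  cat("<pv_coefs> version", x$version, "\n")
  for (s in names(x$strata))
    cat("  stratum", s, ":", length(x$strata[[s]]$pi_terms), "PI terms, baseline",
        x$strata[[s]]$baseline_breast$type, "\n")
  cat("  treatments:", paste(names(x$treatments), collapse = ", "), "\n")
  invisible(x)
}
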