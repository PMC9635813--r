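test_that("prognostic index evaluates weighted transformed covariates", {
  co <- toy_coefs()                     # single term 0.5 * ln(nodes + 1)
  expect_equal(compute_pi(toy_record(nodes = 0L), co), 0)
  expect_equal(compute_pi(toy_record(nodes = 3L), co), 0.5 * log(4))
  # additivity: a two-term set gives the sum of single-term PIs
  two <- toy_coefs()
  size_term <- list(covariate = "size_mm", scale = 100, power = 0,
                    coefficient = 0.8, center = -1.5)
  for (s in names(two$strata))
    two$strata[[s]]$pi_terms <- c(two$strata[[s]]$pi_terms, list(size_term))
  rec <- toy_record(nodes = 3L, size_mm = 30)
  expect_equal(compute_pi(rec, two),
               0.5 * log(4) + 0.8 * (log(0.3) + 1.5), tolerance = 1e-12)
  # categorical offsets add on top of numeric terms
  cat_term <- list(covariate = "her2",
                   levels = list(positive = 0.24, negative = -0.07, unknown = 0))
  three <- toy_coefs()
  three$strata$positive$pi_terms <- c(three$strata$positive$pi_terms,
                                      list(cat_term))
  expect_equal(compute_pi(toy_record(nodes = 0L, her2 = "positive"), three), 0.24)
})

test_that("out-of-range covariates clamp with a warning or error in strict mode", {
  co <- toy_coefs()
  co$ranges$nodes <- c(0, 10)
  rec <- toy_record(nodes = 25L)
  expect_warning(pi_c <- compute_pi(rec, co), "clamped")
  expect_equal(pi_c, 0.5 * log(11))
  expect_error(compute_pi(rec, co, clamp = FALSE), "admissible range")
})

test_that("mortality index follows the published age formula", {
  co <- toy_coefs()
  expect_equal(compute_mi(10 * sqrt(34.23391957), co), 0, tolerance = 1e-12)
  expect_equal(compute_mi(60, co), 0.123317, tolerance = 1e-6)
  expect_equal(compute_mi(50, co), -0.644760, tolerance = 1e-6)
  expect_error(compute_mi(-5, co), "positive")
})

test_that("MI constants expressed in the transform DSL reproduce compute_mi", {
  co <- toy_coefs()
  mi_term <- list(covariate = "age_years", scale = 10, power = 2,
                  coefficient = co$mi$a, center = co$mi$b)
  dsl <- toy_coefs()
  dsl$strata$positive$pi_terms <- list(mi_term)
  ages <- seq(25, 85, by = 2.5)
  recs <- toy_record(id = as.character(seq_along(ages)), age_years = ages)
  expect_identical(compute_pi(recs, dsl), compute_mi(ages, co))
})

test_that("treatment effect sums log-HRs of stratum-relevant treatments", {
  co <- toy_coefs()                    # hormone -0.4, chemo -0.2, trastuzumab -0.3
  expect_equal(compute_te(toy_record(), co), 0)
  expect_equal(compute_te(toy_record(hormone = TRUE, chemo = TRUE), co), -0.6)
  # hormone flag on an ER-negative record is excluded with a warning
  expect_warning(
    te_neg <- compute_te(toy_record(er = "negative", hormone = TRUE,
                                    chemo = TRUE), co),
    "ER-negative")
  expect_equal(te_neg, -0.2)
  # a `requires` condition restricts the term (trastuzumab to HER2-positive)
  co$treatments$trastuzumab$requires <- list(her2 = "positive")
  expect_equal(compute_te(toy_record(trastuzumab = TRUE, her2 = "negative"), co), 0)
  expect_equal(compute_te(toy_record(trastuzumab = TRUE, her2 = "positive"), co),
               -0.3)
  # radiotherapy never contributes
  expect_equal(compute_te(toy_record(radiotherapy = TRUE), co), 0)
})

test_that("cause-specific survival matches the exponential closed forms", {
  co <- toy_coefs(rate_breast = 0.02, rate_other = 0.01)
  expect_equal(breast_survival(5, 0, 0, "positive", co), exp(-0.1),
               tolerance = 1e-12)
  expect_equal(other_survival(10, 0, co), exp(-0.1), tolerance = 1e-12)
  # unit cumulative hazard: L0 + PI + TE = 0 gives exp(-1)
  pi_unit <- -log(0.02 * 5)
  expect_equal(breast_survival(5, pi_unit, 0, "positive", co), exp(-1),
               tolerance = 1e-12)
  # no accumulated hazard at t = 0
  expect_equal(breast_survival(0, 1.3, 0.2, "positive", co), 1)
  # large MI drives other-cause survival toward 0
  expect_lt(other_survival(10, 30, co), 1e-6)
  # closed form exp(-lambda t e^(PI+TE)) to machine precision across a grid
  tt <- seq(0.5, 15, by = 0.5); pi <- 0.7; te <- -0.4
  expect_equal(breast_survival(tt, pi, te, "negative", co),
               exp(-0.02 * tt * exp(pi + te)), tolerance = 1e-12)
})

test_that("overall survival composes S = bS * oS exactly and monotonically", {
  co <- toy_coefs()
  rec <- toy_record(nodes = 2L, hormone = TRUE)
  horizons <- c(1, 2, 5, 7.5, 10, 15)
  rp <- predict_overall_survival(rec, co, horizons = horizons)
  expect_identical(rp$s, rp$bs * rp$os)
  expect_true(all(rp$s >= 0 & rp$s <= 1))
  for (col in c("bs", "os", "s"))
    expect_true(all(diff(rp[[col]]) <= 0), info = col)
  expect_equal(rp$pi, rep(0.5 * log(3), length(horizons)))
  expect_equal(rp$te, rep(-0.4, length(horizons)))
})

test_that("PI is strictly increasing in nodes under a positive coefficient", {
  co <- toy_coefs()
  nodes <- 0:15
  recs <- toy_record(id = as.character(nodes), nodes = as.integer(nodes))
  expect_true(all(diff(compute_pi(recs, co)) > 0))
})

test_that("scoring the shipped v2.1 model yields sane survival probabilities", {
  co <- load_coefficients(predict_v21_path())
  recs <- dplyr::bind_rows(
    toy_record(id = "low", age_years = 55, size_mm = 10, grade = 1L,
               nodes = 0L, detection = "screening", hormone = TRUE),
    toy_record(id = "high", age_years = 55, size_mm = 45, grade = 3L,
               nodes = 8L, er = "negative", chemo = TRUE))
  rp <- predict_overall_survival(recs, co, horizons = c(5, 10))
  expect_true(all(rp$s > 0 & rp$s < 1))
  # higher-burden patient has worse predicted survival at both horizons
  for (h in c(5, 10))
    expect_lt(rp$s[rp$id == "high" & rp$horizon == h],
              rp$s[rp$id == "low" & rp$horizon == h])
})
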