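test_that("restricted cubic spline basis is linear in the tails and smooth", {
  knots <- c(-1, 0, 1)
  x <- seq(-3, 3, by = 0.01)
  B <- rcs_basis(x, knots)
  expect_equal(ncol(B), 2)
  expect_equal(B[, 1], x)
  # linearity beyond boundary knots: second differences vanish
  right <- B[x > 1.5, 2]
  expect_lt(max(abs(diff(diff(right)))), 1e-10)
  left <- B[x < -1.5, 2]
  expect_lt(max(abs(diff(diff(left)))), 1e-10)
  # inside the knot span the spline term is non-linear
  mid <- B[x > -0.5 & x < 0.5, 2]
  expect_gt(max(abs(diff(diff(mid)))), 0)
})

test_that("ICI falls back to the overall KM risk for constant predictions", {
  # 2 deaths before the horizon among 10 fully followed patients: KM death
  # probability 0.2; constant predictions 0.2 are perfectly calibrated
  times <- c(1, 2, rep(8, 8)); events <- c(TRUE, TRUE, rep(FALSE, 8))
  cal <- ici(rep(0.2, 10), times, events, horizon = 5)
  expect_true(cal$degenerate)
  expect_equal(cal$ici, 0, tolerance = 1e-9)
  # mismatched constant predictions give exactly the absolute gap
  cal2 <- ici(rep(0.5, 10), times, events, horizon = 5)
  expect_equal(cal2$ici, 0.3, tolerance = 1e-9)
})

test_that("ICI is invariant to patient ordering", {
  set.seed(41)
  n <- 400
  risk <- runif(n, 0.05, 0.6)
  out <- calibrated_outcomes(risk, 5)
  a <- ici(risk, out$times, out$events, 5)$ici
  perm <- sample(n)
  b <- ici(risk[perm], out$times[perm], out$events[perm], 5)$ici
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("ICI is small for calibrated predictions and detects a known shift", {
  set.seed(55)
  n <- 4000
  risk <- runif(n, 0.05, 0.5)
  out <- calibrated_outcomes(risk, 5)
  cal <- ici(risk, out$times, out$events, 5)
  expect_false(cal$degenerate)
  expect_lt(cal$ici, 0.02)
  shifted <- pmin(risk + 0.10, 1 - 1e-6)
  expect_lt(abs(ici(shifted, out$times, out$events, 5)$ici - 0.10), 0.02)
})

test_that("ICI shrinks toward zero with sample size on calibrated cohorts", {
  # averaged over seeded replicates to separate the trend from MC noise
  icis <- vapply(c(500, 2000, 8000), function(n) {
    mean(vapply(1:10, function(s) {
      set.seed(1000 + s)
      risk <- runif(n, 0.05, 0.5)
      out <- calibrated_outcomes(risk, 5)
      ici(risk, out$times, out$events, 5)$ici
    }, 0))
  }, 0)
  expect_true(all(diff(icis) < 0))
  expect_lt(icis[3], 0.01)
})

test_that("calibration curves evaluate on a grid and expose miscalibration", {
  set.seed(63)
  n <- 3000
  risk <- runif(n, 0.05, 0.6)
  out <- calibrated_outcomes(risk, 5)
  # calibrated data: curve hugs the identity over the central risk range
  cc <- calibration_curve(risk, out$times, out$events, 5,
                          grid = seq(0.1, 0.5, by = 0.05))
  expect_equal(cc$curve$observed, cc$curve$identity, tolerance = 0.05)
  expect_lt(max(abs(cc$curve$observed - cc$curve$identity)), 0.03)
  # single grid point: single-row curve
  one <- calibration_curve(risk, out$times, out$events, 5, grid = 0.3)
  expect_equal(nrow(one$curve), 1)
  # monotone distortion: squared risks under-state risk, so the smoothed
  # observed curve lies above the identity at small predicted values
  cc2 <- calibration_curve(risk^2, out$times, out$events, 5,
                           grid = c(0.05, 0.1, 0.15))
  expect_true(all(cc2$curve$observed > cc2$curve$identity))
  # density of predicted risk accompanies every curve
  expect_true(all(c("risk", "density") %in% names(cc$density)))
  expect_gt(nrow(cc$density), 10)
})

test_that("predicted-observed tables honour weighting and stratum identities", {
  set.seed(71)
  n <- 500
  risk <- runif(n, 0.1, 0.5)
  out <- calibrated_outcomes(risk, 5)
  s_pred <- cbind(1 - risk)
  strata <- factor(rep(c("a", "b"), length.out = n))
  tab <- predicted_observed_table(s_pred, out$times, out$events, 5, strata)
  whole <- predicted_observed_table(s_pred, out$times, out$events, 5)
  # whole-cohort mean equals the size-weighted mean of stratum means
  expect_equal(whole$predicted,
               sum(tab$predicted * tab$n) / sum(tab$n), tolerance = 1e-12)
  expect_equal(sum(tab$n), n)
  expect_true(all(tab$predicted >= 0 & tab$predicted <= 1))
  expect_true(all(tab$obs_lower <= tab$observed & tab$observed <= tab$obs_upper))
  # constant predictions equal to the observed survival reproduce themselves
  km5 <- km_at(km_fit(out$times, out$events), 5)$estimate
  tab2 <- predicted_observed_table(cbind(rep(km5, n)), out$times, out$events, 5)
  expect_equal(tab2$predicted, km5)
  expect_equal(tab2$observed, km5)
  # empty stratum is omitted with a warning
  expect_warning(
    tab3 <- predicted_observed_table(s_pred, out$times, out$events, 5,
                                     factor(rep("a", n), levels = c("a", "z"))),
    "empty stratum")
  expect_equal(nrow(tab3), 1)
})

test_that("calibrated predictions agree with observed within decile strata", {
  set.seed(83)
  n <- 5000
  risk <- runif(n, 0.05, 0.6)
  out <- calibrated_outcomes(risk, 5)
  deciles <- cut(risk, quantile(risk, seq(0, 1, 0.1)), include.lowest = TRUE)
  tab <- predicted_observed_table(cbind(1 - risk), out$times, out$events, 5,
                                  deciles)
  # |mean predicted - KM observed| within the joint CI half-width per decile
  joint <- (tab$pred_upper - tab$pred_lower) / 2 +
    (tab$obs_upper - tab$obs_lower) / 2
  expect_true(all(abs(tab$predicted - tab$observed) < joint))
})
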