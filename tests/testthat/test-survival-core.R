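test_that("Kaplan-Meier product-limit matches hand calculations", {
  # no censoring: empirical fraction
  km <- km_fit(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(km_at(km, 2.5)$estimate, 0.5)
  # censored at 2: S(3) = (3/4) * (1/2) = 0.375
  km2 <- km_fit(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(km_at(km2, 3)$estimate, 0.375)
  # survival starts at 1, is non-increasing, variance non-negative
  expect_equal(km_at(km2, 0.5)$estimate, 1)
  expect_true(all(diff(km2$surv) <= 0))
  expect_true(all(km2$var_greenwood >= 0))
  # no events: S identically 1
  km3 <- km_fit(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km_at(km3, c(0, 2, 10))$estimate, c(1, 1, 1))
  expect_error(km_fit(numeric(0), logical(0)), "empty")
})

test_that("km_at confidence intervals follow the Greenwood variance", {
  km <- km_fit(c(1, 2, 3, 4), c(1, 0, 1, 1))
  # hand Greenwood at t = 3: sum d/(n(n-d)) = 1/(4*3) + 1/(2*1) = 7/12
  v <- 1 / 12 + 1 / 2
  s <- 0.375
  z <- qnorm(0.975)
  se_cll <- sqrt(v) / abs(log(s))
  at <- km_at(km, 3)
  expect_equal(at$lower, s^exp(z * se_cll), tolerance = 1e-10)
  expect_equal(at$upper, s^exp(-z * se_cll), tolerance = 1e-10)
  expect_true(at$lower >= 0 && at$upper <= 1)
  # plain transform clips to [0, 1]
  pl <- km_at(km, 3, transform = "plain")
  expect_equal(pl$lower, max(0, s - z * s * sqrt(v)), tolerance = 1e-10)
  # before the first event the CI is degenerate at 1
  expect_equal(unlist(km_at(km, 0.5)[, c("estimate", "lower", "upper")]),
               c(estimate = 1, lower = 1, upper = 1))
  # beyond the last follow-up time the estimate is flagged
  expect_true(km_at(km, 99)$beyond_support)
})

test_that("KM equals the empirical survival function without censoring", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:80, 1)
    times <- rexp(n, 0.3)
    km <- km_fit(times, rep(TRUE, n))
    grid <- sort(c(times, runif(10, 0, max(times))))
    expect_equal(km_at(km, grid)$estimate,
                 vapply(grid, function(g) mean(times > g), 0),
                 tolerance = 1e-12)
  }
})

test_that("large-sample KM recovers the exponential closed form", {
  set.seed(42)
  n <- 20000
  times <- rexp(n, 1)
  km <- km_fit(times, rep(TRUE, n))
  s1 <- km_at(km, 1)
  mc_se <- sqrt(exp(-1) * (1 - exp(-1)) / n)
  expect_lt(abs(s1$estimate - exp(-1)), 3 * mc_se)
  expect_true(s1$lower < exp(-1) && exp(-1) < s1$upper)
})

test_that("log-rank test separates groups and is null under label permutation", {
  set.seed(11)
  x <- rexp(100, 0.5)
  # identical samples in both groups: statistic ~ 0, p ~ 1
  lr0 <- logrank_test(c(x, x), rep(TRUE, 200), rep(c("a", "b"), each = 100))
  expect_lt(lr0$statistic, 1e-8)
  expect_equal(lr0$p_value, 1, tolerance = 1e-6)
  # strongly separated exponential groups (HR 4)
  t1 <- rexp(500, 1); t2 <- rexp(500, 4)
  lr <- logrank_test(c(t1, t2), rep(TRUE, 1000), rep(c("a", "b"), each = 500))
  expect_lt(lr$p_value, 0.001)
  # all-events group vs no-events group: positive statistic
  lr2 <- logrank_test(c(rexp(50, 1), rep(5, 50)),
                      rep(c(TRUE, FALSE), each = 50),
                      rep(c("a", "b"), each = 50))
  expect_gt(lr2$statistic, 0)
  expect_error(logrank_test(x, rep(TRUE, 100), rep("a", 100)), "two")
})

# independent oracle: Cox partial log-likelihood for one covariate, no ties
partial_loglik <- function(beta, x, times, events) {
  ord <- order(times)
  x <- x[ord]; events <- events[ord]
  eta <- beta * x
  # risk set of subject i: all j with time_j >= time_i
  sum(vapply(which(events == 1), function(i)
    eta[i] - log(sum(exp(eta[i:length(eta)]))), 0))
}

test_that("Cox fit maximizes the partial likelihood (brute-force oracle, n = 5)", {
  x <- c(0.5, -0.2, 1.0, 0.0, -1.0)
  times <- c(2, 5, 1, 4, 3)
  events <- c(1, 1, 1, 1, 1)
  fit <- cox_fit(x, times, events)
  oracle <- optimize(function(b) -partial_loglik(b, x, times, events),
                     c(-5, 5), tol = 1e-9)$minimum
  expect_equal(fit$coefficients$coef, oracle, tolerance = 1e-4)
})

test_that("Cox fit recovers a true hazard ratio and is null under permutation", {
  set.seed(21)
  n <- 2000
  g <- rep(0:1, each = n / 2)
  times <- rexp(n, exp(log(2) * g))
  fit <- cox_fit(g, times, rep(TRUE, n))
  expect_lt(abs(fit$coefficients$coef - log(2)), 0.1 * log(2))
  expect_true(fit$coefficients$lower < 2 & 2 < fit$coefficients$upper)
  # permuted covariate: coefficient within 3 SE of zero
  perm <- sample(g)
  fit0 <- cox_fit(perm, times, rep(TRUE, n))
  expect_lt(abs(fit0$coefficients$coef), 3 * fit0$coefficients$se)
})

test_that("Cox coefficients are location-invariant and scale inversely", {
  set.seed(5)
  n <- 300
  x <- rnorm(n)
  times <- rexp(n, exp(0.5 * x))
  events <- rep(TRUE, n)
  b <- cox_fit(x, times, events)$coefficients$coef
  expect_equal(cox_fit(x + 7, times, events)$coefficients$coef, b,
               tolerance = 1e-6)
  expect_equal(cox_fit(3 * x, times, events)$coefficients$coef, b / 3,
               tolerance = 1e-6)
})

test_that("Efron and Breslow tie handling agree exactly without tied events", {
  set.seed(8)
  n <- 150
  x <- rnorm(n)
  times <- rexp(n, exp(0.3 * x))      # continuous: no ties
  events <- runif(n) < 0.8
  fe <- cox_fit(x, times, events, ties = "efron")
  fb <- cox_fit(x, times, events, ties = "breslow")
  expect_equal(fe$coefficients$coef, fb$coefficients$coef, tolerance = 1e-10)
})

test_that("degenerate Cox inputs raise diagnostics instead of silent results", {
  expect_error(cox_fit(rep(1, 20), rexp(20), rep(TRUE, 20)), "constant")
  # perfect separation: monotone likelihood
  x <- c(rep(0, 10), rep(1, 10))
  times <- c(seq(1, 10), seq(11, 20))
  expect_error(cox_fit(x, times, rep(TRUE, 20)), "diverg|converge")
})
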