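# Logistic basking-occurrence model with backward AIC selection.

test_that("standardization has the closed form and is idempotent", {
  d <- data.frame(individual = "a", midday = c(0, 1, 0),
                  temp = c(1, 2, 3))
  s <- standardize_design(d, cols = "temp")
  expect_equal(s$temp, c(-1, 0, 1))  # sample sd of (1,2,3) is 1
  s2 <- standardize_design(s, cols = "temp")
  expect_equal(s2$temp, s$temp)
  expect_lt(abs(mean(s$temp)), 1e-10)
  expect_lt(abs(var(s$temp) - 1), 1e-10)
  expect_error(standardize_design(transform(d, temp = 5), cols = "temp"),
               "constant")
})

test_that("intercept-only model on a balanced response has the closed-form AIC", {
  n <- 40
  d <- data.frame(individual = "a", midday = rep(c(0, 1), n / 2))
  f <- fit_binomial(d, character(0))
  expect_equal(f$coefficients$estimate[1], 0, tolerance = 1e-8)
  expect_equal(f$aic, 2 + 2 * n * log(2), tolerance = 1e-8)
})

test_that("a single-class response cannot be fitted", {
  d <- data.frame(individual = "a", midday = rep(1, 20),
                  temp = rnorm(20))
  expect_error(fit_binomial(d, "temp"), "both response classes")
})

test_that("a known cloud slope is recovered within 2 SE at n = 1000", {
  d <- simulate_basking_design(1000, list(cloud = -2.5, day_length = 0.75),
                               seed = 101)
  f <- fit_binomial(d, c("cloud", "day_length"))
  co <- f$coefficients
  cl <- co[co$term == "cloud", ]
  expect_lt(abs(cl$estimate - (-2.5)), 2 * cl$se)
  expect_lt(cl$z, -5)
})

test_that("IRLS agrees with direct likelihood maximisation on 50 rows", {
  d <- simulate_basking_design(50, list(cloud = -1.2, rain = 0.4),
                               n_individuals = 2, seed = 7)
  f <- fit_binomial(d, c("cloud", "rain"))
  X <- cbind(d$individual == "I1", d$individual == "I2", d$cloud, d$rain)
  y <- d$midday
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  grad <- function(b) {
    eta <- as.numeric(X %*% b)
    -as.numeric(t(X) %*% (y - stats::plogis(eta)))
  }
  opt <- stats::optim(rep(0, 4), nll, grad, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  got <- f$coefficients$estimate
  expect_equal(sort(got), sort(opt$par), tolerance = 1e-6)
  expect_equal(f$loglik, -opt$value, tolerance = 1e-8)
})

test_that("AIC equals 2k - 2 logLik and separation is reported", {
  d <- simulate_basking_design(200, list(cloud = -1), seed = 3)
  f <- fit_binomial(d, "cloud")
  k <- nrow(f$coefficients)
  expect_equal(f$aic, 2 * k - 2 * f$loglik)
  # a perfectly separating predictor is named in the error
  d$sep <- ifelse(d$midday == 1, 1, -1)
  expect_error(fit_binomial(d, "sep"), "sep")
})

test_that("backward AIC keeps informative terms and drops pure noise", {
  d <- simulate_basking_design(400, list(cloud = -2), seed = 5)
  set.seed(6)
  d$noise <- rnorm(400)
  sel <- backward_aic(d, c("cloud", "noise"))
  expect_true("cloud" %in% sel$final$terms)
  expect_lte(sel$final$aic, sel$steps$aic[1])
  # a single informative term is retained
  sel1 <- backward_aic(d, "cloud")
  expect_identical(sel1$final$terms, "cloud")
})

test_that("noise-predictor drop rate matches the chi-square-1 theory", {
  # AIC drops a null term iff its likelihood-ratio statistic is below 2;
  # under the null that statistic is chi-square(1), so the expected drop
  # rate is P(chisq_1 < 2) = 0.843, not 1.
  drops <- vapply(1:40, function(r) {
    d <- simulate_basking_design(300, list(cloud = -2), n_individuals = 2,
                                 seed = 1000 + r)
    set.seed(2000 + r)
    d$noise <- rnorm(300)
    sel <- backward_aic(d, c("cloud", "noise"))
    !("noise" %in% sel$final$terms)
  }, logical(1))
  p <- stats::pchisq(2, df = 1)
  tol <- 3 * sqrt(p * (1 - p) / length(drops))
  expect_gte(mean(drops), p - tol)
  expect_lte(mean(drops), min(p + tol, 1))
})

test_that("recovered slope signs match the generating signs", {
  hits <- vapply(1:20, function(r) {
    d <- simulate_basking_design(
      1000, list(cloud = -1.5, rain = -0.6, day_length = 0.8),
      seed = 3000 + r)
    co <- fit_binomial(d, c("cloud", "rain", "day_length"))$coefficients
    est <- stats::setNames(co$estimate, co$term)
    est["cloud"] < 0 && est["rain"] < 0 && est["day_length"] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the design built from budgets has one row per individual-day", {
  run <- small_run()
  b <- run$ann$budgets
  b$individual <- "T01"
  w <- run$env$weather
  if (stats::sd(w$rain_mm) == 0) w$rain_mm[1] <- 1  # a dry spell happens
  attr(w, "origin") <- attr(run$env$weather, "origin")
  design <- build_design(b, w, run$env$sun)
  expect_equal(nrow(design), nrow(b))
  expect_true(all(abs(colMeans(design[c("temp", "cloud")])) < 1e-10))
  expect_setequal(design$midday, c(0, 1))
})
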