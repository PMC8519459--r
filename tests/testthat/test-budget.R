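# Daily budgets, laying alignment and the activity-temperature relation.

test_that("budget arithmetic on a constructed cycle", {
  # constant VeDBA 0.16 m s^-2; Night 9.3 h of a 24-h cycle
  bouts <- data.frame(
    cycle = 1L, cycle_date = as.Date("2017-05-20"),
    label = c("Night", "Morning", "Midday", "Evening"),
    t_start = c(0, 9.3, 16, 20) * 3600,
    t_end = c(9.3, 16, 20, 24) * 3600)
  bouts$duration_h <- (bouts$t_end - bouts$t_start) / 3600
  t <- seq(0, 86400, by = 10)
  b <- budget_cycles(bouts, list(), t, rep(0.16, length(t)), fs = 0.1)
  expect_equal(b$night_h, 9.3)
  expect_equal(b$night_vedba, 576)
  expect_equal(b$daily_vedba, 0.16 * 86400)
  # zero motion: all VeDBA fields zero
  b0 <- budget_cycles(bouts, list(), t, rep(0, length(t)), fs = 0.1)
  expect_equal(b0$daily_vedba, 0)
  expect_equal(b0$night_vedba, 0)
})

test_that("per-phase VeDBA integrals sum to the daily integral", {
  run <- small_run()
  b <- run$ann$budgets
  phase_sum <- b$night_integral + b$morning_integral + b$midday_integral +
    b$evening_integral
  expect_equal(phase_sum, b$daily_vedba, tolerance = 1e-6)
})

test_that("budget row count equals complete cycles and durations match truth", {
  run <- small_run()
  b <- run$ann$budgets
  expect_equal(nrow(b), attr(run$ann$bouts, "n_cycles"))
  # phase durations equal the generator schedule within 2 min per boundary
  tp <- run$ind$truth$phases
  for (k in seq_len(nrow(b))) {
    cyc <- run$ann$bouts[run$ann$bouts$cycle == b$cycle[k], ]
    night <- cyc[cyc$label == "Night", ]
    tn <- tp[tp$phase == "Night" &
               abs(tp$t_start - night$t_start) < 3600, ]
    if (nrow(tn) == 1) {
      expect_lt(abs(night$t_start - tn$t_start), 240)
    }
  }
})

test_that("laying alignment anchors day zero exactly once", {
  budgets <- data.frame(cycle = 1:10,
                        cycle_date = as.Date("2017-06-01") + 0:9)
  nesting <- data.frame(t_start = c(3.2, 5.3) * 86400,
                        t_end = c(3.25, 5.35) * 86400)
  aligned <- align_to_laying(budgets, nesting,
                             observed = 5.34 * 86400,
                             origin = as.POSIXct("2017-06-01",
                                                 tz = "UTC"))
  expect_true(attr(aligned, "aligned"))
  expect_equal(sum(aligned$days_from_laying == 0), 1)
  expect_equal(aligned$days_from_laying, -5:4)
  expect_identical(aligned$period[1], "pre")
  expect_identical(aligned$period[10], "post")
  expect_identical(aligned$period[5], "peri")
})

test_that("laying offsets span the deployment arithmetic", {
  budgets <- data.frame(cycle = 1:137,
                        cycle_date = as.Date("2017-04-14") + 0:136)
  nesting <- data.frame(t_start = 49.5 * 86400, t_end = 49.55 * 86400)
  aligned <- align_to_laying(budgets, nesting, observed = 49.55 * 86400,
                             origin = as.POSIXct("2017-04-14", tz = "UTC"))
  expect_equal(range(aligned$days_from_laying), c(-49, 87))
})

test_that("an individual with no successful nesting is flagged unaligned", {
  budgets <- data.frame(cycle = 1:5, cycle_date = as.Date("2017-06-01") + 0:4)
  aligned <- align_to_laying(budgets,
                             data.frame(t_start = numeric(0),
                                        t_end = numeric(0)))
  expect_false(attr(aligned, "aligned"))
  expect_true(all(is.na(aligned$days_from_laying)))
})

test_that("two clutches 22 days apart are both kept, anchored on the first", {
  budgets <- data.frame(cycle = 1:40,
                        cycle_date = as.Date("2017-05-20") + 0:39)
  nesting <- data.frame(t_start = c(5.6, 27.6) * 86400,
                        t_end = c(5.65, 27.65) * 86400)
  aligned <- align_to_laying(budgets, nesting,
                             observed = c(5.65, 27.65) * 86400,
                             origin = as.POSIXct("2017-05-20", tz = "UTC"))
  expect_equal(aligned$days_from_laying[6], 0)
  expect_identical(aligned$period[28], "peri")
})

test_that("activity-temperature slope is recovered and the null is covered", {
  set.seed(31)
  n <- 60
  temp <- runif(n, 10, 28)
  budgets <- data.frame(cycle = 1:n,
                        cycle_date = as.Date("2017-05-01") + 0:(n - 1),
                        daily_vedba = 2000 + 300 * temp + rnorm(n, 0, 500),
                        days_from_laying = -(n:1))
  rel <- activity_temperature_relation(
    budgets, data.frame(cycle_date = budgets$cycle_date, temp = temp))
  expect_false(is.null(rel$pre))
  expect_null(rel$post)
  expect_lt(abs(rel$pre$slope - 300), 2 * rel$pre$slope_se)
  # temperature-independent activity: slope CI contains zero
  budgets$daily_vedba <- 4000 + rnorm(n, 0, 500)
  rel0 <- activity_temperature_relation(
    budgets, data.frame(cycle_date = budgets$cycle_date, temp = temp))
  expect_lt(abs(rel0$pre$slope), 2 * rel0$pre$slope_se)
})

test_that("the hourly profile peak bin brackets a 25-degree hump", {
  set.seed(32)
  temp <- runif(2000, 8, 40)
  vedba <- 600 * exp(-(temp - 25)^2 / 50) * runif(2000) + 50
  hourly <- data.frame(temp = temp, vedba = vedba)
  rel <- activity_temperature_relation(
    data.frame(cycle_date = as.Date("2017-05-01"), daily_vedba = 1,
               days_from_laying = NA_integer_),
    data.frame(cycle_date = as.Date("2017-05-01"), temp = 20),
    hourly = hourly)
  expect_gte(rel$peak_bin, 23)
  expect_lte(rel$peak_bin, 27)
})
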