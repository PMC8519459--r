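# Stream I/O, metadata, and clock-drift correction.

write_tmp_env <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("a well-formed env file round-trips with zero drops", {
  df <- data.frame(time = 0:59, temp_c = 20, pressure_bar = 0.03,
                   light_lux = 100)
  p <- write_tmp_env(df)
  got <- read_env_stream(p)
  expect_equal(nrow(got), 60)
  expect_identical(attr(got, "n_dropped"), 0L)
  expect_identical(attr(got, "n_duplicates"), 0L)
  expect_equal(got$temp_c, df$temp_c)
})

test_that("duplicate timestamps keep the first record and are counted", {
  df <- data.frame(time = c(0, 1, 1, 2), temp_c = c(20, 21, 99, 22),
                   pressure_bar = 0.03, light_lux = 0)
  got <- read_env_stream(write_tmp_env(df))
  expect_equal(nrow(got), 3)
  expect_identical(attr(got, "n_duplicates"), 1L)
  expect_equal(got$temp_c, c(20, 21, 22))
})

test_that("unparseable rows are dropped and counted", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("time,temp_c,pressure_bar,light_lux",
               "0,20,0.03,100", "1,not_a_number,0.03,100", "2,21,0.03,100"),
             p)
  got <- read_env_stream(p)
  expect_equal(nrow(got), 2)
  expect_identical(attr(got, "n_dropped"), 1L)
})

test_that("a missing required column is a format error naming the column", {
  df <- data.frame(time = 0:9, temp_c = 20, light_lux = 0)
  expect_error(read_env_stream(write_tmp_env(df)), "pressure_bar")
})

test_that("ISO-8601 time columns are auto-detected", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("time,temp_c,pressure_bar,light_lux",
               "2017-05-15T00:00:00,20,0.03,100",
               "2017-05-15T00:00:01,20,0.03,100"), p)
  got <- read_env_stream(p)
  expect_equal(got$time, c(0, 1))
  expect_s3_class(attr(got, "origin"), "POSIXct")
})

test_that("write/read round trip of a generated deployment is lossless", {
  cfg <- generator_config(n_individuals = 1, n_days = 2, seed = 3,
                          attempts_mean = 0)
  env <- generate_environment(cfg)
  ind <- generate_individual(cfg, 1, env)
  # truncate to keep the fixture small; precision is what is under test
  dep <- list(env = ind$env[1:600, ], accel = ind$accel[1:3000, ],
              meta = ind$meta)
  dir <- tempfile()
  paths <- write_deployment(dep, dir)
  got <- read_deployment(paths["env"], paths["accel"], paths["meta"])
  expect_equal(got$env$time, round(dep$env$time, 3))
  expect_equal(got$env$temp_c, signif(dep$env$temp_c, 6))
  expect_equal(got$accel$az, signif(dep$accel$az, 6))
  expect_equal(got$meta$rtc_anchors[, "true_time"],
               dep$meta$rtc_anchors[, 2], ignore_attr = TRUE)
  # writing twice is byte-identical
  p2 <- write_deployment(dep, tempfile())
  expect_identical(readLines(paths["env"]), readLines(p2["env"]))
})

test_that("metadata with fewer than two RTC anchors is a config error", {
  p <- tempfile(fileext = ".yml")
  yaml::write_yaml(list(individual_id = "T01", body_mass_g = 700,
                        carapace_length_mm = 150, logger_mass_g = 7,
                        rtc_anchors = list(list(0, 0))), p)
  expect_error(read_deployment_meta(p), "2 RTC anchor")
})

test_that("zero-offset anchors give the identity remap", {
  anc <- rbind(c(0, 0), c(100, 100))
  t <- c(0, 12.5, 99, 100)
  expect_identical(correct_clock_drift(t, anc), t)
})

test_that("a 21.30-min drift over 141 days stretches ~9.06 s per day", {
  # linear-drift arithmetic: rate = 21.30*60 / (141*86400)
  anc <- rbind(c(0, 0), c(141 * 86400, 141 * 86400 + 21.30 * 60))
  rate <- 21.30 * 60 / (141 * 86400)
  expect_equal(rate, 1.049e-4, tolerance = 1e-3)
  got <- correct_clock_drift(86400, anc)
  expect_equal(got - 86400, 86400 * rate, tolerance = 1e-9)
  expect_equal(got - 86400, 9.06, tolerance = 1e-3)
})

test_that("anchors map exactly onto themselves", {
  anc <- rbind(c(0, 5), c(1000, 1020), c(2000, 2031))
  expect_equal(correct_clock_drift(anc[, 1], anc), anc[, 2])
})

test_that("non-monotone anchors are rejected", {
  expect_error(correct_clock_drift(1:10, rbind(c(0, 0), c(100, -5))),
               "non-monotone")
})

test_that("corrected inter-sample intervals stay within the drift bound", {
  anc <- rbind(c(0, 0), c(1000, 1001))
  t <- seq(0, 1000, by = 1)
  ct <- correct_clock_drift(t, anc)
  expect_true(all(diff(ct) > 0))
  expect_lt(max(abs(diff(ct) - 1)), 1.1e-3)
})

test_that("budget/event tables are written deterministically", {
  run <- small_run()
  dir1 <- tempfile(); dir2 <- tempfile()
  p1 <- write_tables(run$ann$budgets, list(nesting = run$ann$nesting), dir1)
  p2 <- write_tables(run$ann$budgets, list(nesting = run$ann$nesting), dir2)
  expect_identical(readLines(p1[1]), readLines(p2[1]))
  # empty event list still yields a header-only file
  p3 <- write_tables(run$ann$budgets,
                     list(empty = run$ann$nesting[0, ]), tempfile())
  lines <- readLines(p3[2])
  expect_length(lines, 1L)
  expect_match(lines, "t_start")
})
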