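# Epoch statistics, threshold classification, and cycle segmentation.

synth_env <- function(n, temp = 20, pressure = 0.03, light = 100, t0 = 0) {
  data.frame(time = t0 + 0:(n - 1), temp_c = rep_len(temp, n),
             pressure_bar = rep_len(pressure, n),
             light_lux = rep_len(light, n))
}

test_that("epoch statistics match direct recomputation", {
  env <- synth_env(180, temp = 20)
  st <- epoch_stats(env)
  expect_equal(nrow(st), 3)
  expect_equal(st$sd_temp, rep(0, 3))
  # alternating lux 0/2000: median and mean both 1000
  env$light_lux <- rep(c(0, 2000), 90)
  st <- epoch_stats(env)
  expect_equal(st$median_light, rep(1000, 3))
  expect_equal(st$mean_light, rep(1000, 3))
  # seeded normal: sample sd against brute-force recomputation
  set.seed(99)
  x <- rnorm(60, 20, 0.5)
  env2 <- synth_env(60, temp = x)
  st2 <- epoch_stats(env2)
  expect_equal(st2$sd_temp, sqrt(sum((x - mean(x))^2) / 59))
})

test_that("epochs with too few samples are invalid", {
  env <- synth_env(150)
  env <- env[env$time < 60 | env$time >= 120 | env$time %% 2 == 0, ]
  st <- epoch_stats(env)
  expect_true(st$valid[1])
  expect_false(st$valid[2])  # only 30 samples
})

test_that("threshold rules classify the published examples", {
  st <- data.frame(
    t_start = c(0, 60, 120, 180),
    n = 60,
    median_light = c(500, 500, 30000, 30000),
    mean_light = c(500, 500, 30000, 30000),
    sd_temp = c(0.2, 0.2, 0.5, 0.5),
    sd_pressure = c(0.001, 0.02, 0.02, 0.02),
    mean_temp = c(18, 18, 21, 18.5),
    min24_temp = 18,
    valid = TRUE
  )
  expect_identical(classify_epochs(st),
                   c("night", "other", "midday", "other"))
})

test_that("night precedence wins when both rules match", {
  st <- data.frame(t_start = 0, n = 60, median_light = 900,
                   mean_light = 30000, sd_temp = 0.1, sd_pressure = 1e-4,
                   mean_temp = 25, min24_temp = 18, valid = TRUE)
  expect_identical(classify_epochs(st), "night")
})

make_day_labels <- function(blocks) {
  # blocks: list of c(label, n_epochs)
  unlist(lapply(blocks, function(b) rep(b[[1]], b[[2]])))
}

label_stats <- function(labels, window = 60) {
  df <- data.frame(t_start = (seq_along(labels) - 1) * window,
                   valid = TRUE)
  attr(df, "window") <- window
  df
}

test_that("a clean constructed day yields four ordered bouts", {
  labels <- make_day_labels(list(
    list("night", 400), list("other", 300), list("midday", 300),
    list("other", 240), list("night", 200)))
  st <- label_stats(labels)
  bouts <- segment_cycles(st, labels)
  expect_equal(bouts$label, c("Night", "Morning", "Midday", "Evening"))
  expect_equal(bouts$duration_h * 60, c(400, 300, 300, 240))
  # partition: bouts tile the cycle
  expect_equal(bouts$t_start[-1], bouts$t_end[-4])
})

test_that("without midday the inter-night span is all Morning", {
  labels <- make_day_labels(list(
    list("night", 400), list("other", 700), list("night", 200)))
  bouts <- segment_cycles(label_stats(labels), labels)
  expect_equal(bouts$label, c("Night", "Morning"))
  expect_equal(sum(bouts$duration_h) * 60, 1100)
})

test_that("label flicker is smoothed and short runs dissolved", {
  labels <- make_day_labels(list(
    list("night", 100), list("other", 3), list("night", 100),  # gap closed
    list("other", 200), list("midday", 5), list("other", 200), # run killed
    list("midday", 200), list("other", 100), list("night", 150)))
  bouts <- segment_cycles(label_stats(labels), labels)
  expect_equal(bouts$label, c("Night", "Morning", "Midday", "Evening"))
  expect_equal(bouts$duration_h[1] * 60, 203)
  expect_equal(bouts$duration_h[3] * 60, 200)
})

test_that("a cycle without any night is flagged unsegmentable", {
  labels <- make_day_labels(list(list("other", 500)))
  bouts <- segment_cycles(label_stats(labels), labels)
  expect_equal(nrow(bouts), 0)
  expect_true(attr(bouts, "unsegmentable"))
})

test_that("raising the night light threshold never shortens Night", {
  run <- small_run()
  st <- run$ann$epochs
  night_time <- function(thr) {
    cfg <- segmentation_config(night_max_median_lux = thr)
    b <- segment_cycles(st, classify_epochs(st, cfg), cfg)
    sum(b$duration_h[b$label == "Night"])
  }
  t1 <- night_time(500); t2 <- night_time(1000); t3 <- night_time(5000)
  expect_lte(t1, t2 + 1e-9)
  expect_lte(t2, t3 + 1e-9)
})

test_that("synthetic deployment epochs are phased with >= 95% accuracy", {
  run <- small_run()
  expect_gte(run$eval$phase_accuracy_pct, 95)
})

test_that("bouts of each cycle tile the cycle exactly", {
  run <- small_run()
  b <- run$ann$bouts
  for (cy in unique(b$cycle)) {
    bb <- b[b$cycle == cy, ]
    expect_equal(bb$t_start[-1], bb$t_end[-nrow(bb)])
  }
})
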