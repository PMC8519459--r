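# Breathing, basking, diving and nesting detectors; validation arithmetic.

inject_spikes <- function(n, base = 0.037, at = NULL, amp = 0.005) {
  p <- rep(base, n)
  for (t in at) {
    idx <- t + (-2:2) + 1
    p[idx] <- p[idx] - amp * c(0.3, 0.7, 1, 0.7, 0.3)
  }
  p
}

test_that("flat pressure yields no inhalation events", {
  t <- 0:1199
  ev <- detect_inhalations(t, rep(0.037, 1200))
  expect_equal(nrow(ev), 0)
})

test_that("injected pressure spikes are each detected once", {
  t <- 0:1199
  at <- seq(100, 1100, length.out = 9)
  ev <- detect_inhalations(t, inject_spikes(1200, at = round(at)))
  expect_equal(nrow(ev), 9)
  expect_equal(ev$t, round(at), tolerance = 1)
  expect_gt(min(ev$rise_cm), 2)
})

test_that("spikes below the 2 cm threshold are ignored", {
  ev <- detect_inhalations(0:1199,
                           inject_spikes(1200, at = 600, amp = 0.0005))
  expect_equal(nrow(ev), 0)
})

test_that("events inside the refractory window collapse onto the first", {
  p <- inject_spikes(600, at = c(300, 303))
  ev <- detect_inhalations(0:599, p)
  expect_equal(nrow(ev), 1)
})

test_that("bout grouping follows the max-gap rule", {
  ev <- data.frame(t = seq(0, by = 17, length.out = 9),
                   pre_pressure = 0.037, min_pressure = 0.032,
                   rise_cm = 5)
  g <- group_breathing_bouts(ev)
  expect_equal(nrow(g$bouts), 1)
  expect_equal(g$bouts$n_inhalations, 9L)
  expect_equal(g$bouts$duration_s, 136)
  # two clusters 10 min apart form two bouts
  ev2 <- rbind(ev, transform(ev, t = t + 600 + 136))
  g2 <- group_breathing_bouts(ev2)
  expect_equal(nrow(g2$bouts), 2)
  # empty in, empty out
  g0 <- group_breathing_bouts(ev[0, ])
  expect_equal(nrow(g0$bouts), 0)
})

test_that("every inhalation belongs to exactly one bout and bouts do not overlap", {
  run <- small_run()
  inh <- run$ann$inhalations
  b <- run$ann$breathing
  expect_true(all(!is.na(inh$bout)))
  o <- order(b$t_start)
  expect_true(all(b$t_start[o][-1] > b$t_end[o][-nrow(b)]))
})

test_that("breathing rise statistics convert pressure differences to cm", {
  ev <- data.frame(t = c(0, 17), pre_pressure = c(0.037, 0.0369),
                   min_pressure = c(0.034, 0.0326), rise_cm = NA)
  g <- group_breathing_bouts(ev)
  rs <- breathing_rise_stats(g)
  expect_equal(rs$rise_cm, 4.4)   # pre 0.037, min 0.0326
  expect_length(rs$intervals_s, 0)  # single bout: no intervals
})

test_that("configured surfacing rise is recovered on a synthetic night", {
  set.seed(21)
  n <- 7200
  at <- seq(120, n - 120, by = 120)
  amp <- pmax(rnorm(length(at), 0.005, 0.0008), 0.003)
  p <- rep(0.037, n) + rnorm(n, 0, 5e-4)
  for (i in seq_along(at)) {
    idx <- at[i] + (-2:2) + 1
    p[idx] <- p[idx] - amp[i] * c(0.3, 0.7, 1, 0.7, 0.3)
  }
  ev <- detect_inhalations(0:(n - 1), p)
  g <- group_breathing_bouts(ev)
  rs <- breathing_rise_stats(g)
  se <- sd(rs$rise_cm) / sqrt(length(rs$rise_cm))
  expect_lt(abs(mean(rs$rise_cm) - 5), 2 * se + 0.5)
})

test_that("a linear warming ramp is one basking event", {
  t <- 0:1799
  temp <- 20 + 15 * t / 1800  # 20 -> 35 degC over 30 min
  ev <- detect_basking(t, temp)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$delta_t, 15, tolerance = 0.5)
  # constant temperature: nothing
  expect_equal(nrow(detect_basking(t, rep(25, 1800))), 0)
})

test_that("dive triggers fire on temperature drops and pressure rises", {
  t <- 0:599
  temp <- c(rep(36, 300), seq(36, 24, length.out = 30), rep(24, 270))
  p <- rep(0.001, 600)
  ev <- detect_dives(t, temp, p)
  expect_equal(nrow(ev), 1)
  expect_identical(ev$trigger, "temperature")
  # pressure ramp alone
  p2 <- c(rep(0, 300), seq(0, 0.03, length.out = 20), rep(0.03, 280))
  ev2 <- detect_dives(t, rep(30, 600), p2)
  expect_equal(nrow(ev2), 1)
  expect_identical(ev2$trigger, "pressure")
  # both triggers 10 s apart merge into one event
  p3 <- c(rep(0, 310), seq(0, 0.03, length.out = 20), rep(0.03, 270))
  ev3 <- detect_dives(t, temp, p3)
  expect_equal(nrow(ev3), 1)
  expect_identical(ev3$trigger, "temperature")
})

test_that("the nesting window rule matches its truth table", {
  # exhaustive check over the four threshold regions of each clause
  expect_true(nesting_window_flag(130, 40))   # clause 1
  expect_true(nesting_window_flag(60, 5))     # clause 2
  expect_false(nesting_window_flag(200, 60))  # roll too variable
  expect_false(nesting_window_flag(100, 30))  # pitch too low for clause 1
  expect_false(nesting_window_flag(35, 20))   # fails both
  expect_false(nesting_window_flag(0, 0))     # constant angles
  grid <- expand.grid(vp = c(20, 50, 130, 250), vr = c(5, 30, 70))
  manual <- with(grid, (vr < 50 & vp > 120) | (vr < 10 & vp > 40))
  expect_identical(nesting_window_flag(grid$vp, grid$vr), manual)
})

test_that("a pitch-oscillation bout is detected as one nesting event", {
  set.seed(8)
  fs <- 10
  n <- 3600 * fs
  t <- (0:(n - 1)) / fs
  pitch <- rnorm(n, 0, 2)
  roll <- rnorm(n, 0, 2)
  dig <- t >= 1200 & t < 1200 + 2400  # 40-min dig
  pitch[dig] <- pitch[dig] + 15 * sin(2 * pi * 0.2 * t[dig])
  ev <- detect_nesting(t, pitch, roll, vedba = rep(0.3, n))
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$t_start - 1200), 150)
  expect_gt(ev$duration_min, 35)
  expect_equal(ev$mean_vedba, 0.3)
  # quiet posture alone never flags
  expect_equal(nrow(detect_nesting(t, rnorm(n, 0, 2), rnorm(n, 0, 2))), 0)
})

test_that("validation arithmetic reproduces the printed percentages", {
  expect_equal(detection_rates(262, 38, 31)$fp_pct, 12.7)
  expect_equal(detection_rates(262, 38, 31)$fn_pct, 10.6)
  expect_equal(detection_rates(2795, 484, 425)$fp_pct, 14.8)
  expect_equal(detection_rates(2795, 484, 425)$fn_pct, 13.2)
})

test_that("overlap matching counts TP/FP/FN as expected", {
  det <- data.frame(t_start = c(0, 100, 200), t_end = c(10, 110, 210))
  tru <- data.frame(t_start = c(5, 300), t_end = c(20, 310))
  v <- validate_detections(det, tru)
  expect_equal(v$tp, 1L)
  expect_equal(v$fp, 2L)
  expect_equal(v$fn, 1L)
  v0 <- validate_detections(det[0, ], tru)
  expect_equal(v0$fn, 2L)
})

test_that("synthetic deployment detectors meet the operating point", {
  run <- small_run()
  ev <- run$eval
  expect_lte(ev$breathing$fp_pct, 20)
  expect_lte(ev$breathing$fn_pct, 20)
  expect_equal(ev$long_digs_detected, ev$long_digs_total)
  expect_equal(ev$dig_fp_on_digfree_days, 0L)
  # digging VeDBA is well above the deployment-wide level
  expect_gt(min(run$ann$nesting$mean_vedba), 0.25)
  # basking time recovered within 20%
  expect_lt(abs(ev$bask_time_detected_h - ev$bask_time_true_h) /
              ev$bask_time_true_h, 0.2)
})
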