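# Event detection: breathing bouts and inhalation events during Night,
# basking and diving during Midday, nest-digging from body-angle variance,
# and validation against ground-truth intervals.

#' Detect inhalation events in a Night pressure stream
#'
#' During nocturnal rest at the surface a breath shows as a transient
#' pressure decrease (the carapace rises out of the water).  The baseline is
#' a running median over `baseline_window` seconds; a candidate inhalation is
#' a local pressure minimum whose drop below baseline is at least
#' `min_rise_cm` of water (1 cm = 1e-3 bar).  Successive events closer than
#' `refractory` seconds are collapsed onto the first so that one surfacing is
#' never double-counted.
#'
#' @param time,pressure 1 Hz Night-phase pressure stream (s, bar).
#' @param min_rise_cm detection threshold, cm of water.
#' @param baseline_window running-median window, s.
#' @param refractory minimum spacing between events, s.
#' @return data.frame `t`, `pre_pressure` (baseline at the event, bar),
#'   `min_pressure` (bar), `rise_cm`.
#' @export
detect_inhalations <- function(time, pressure, min_rise_cm = 2,
                               baseline_window = 120, refractory = 5) {
  n <- length(pressure)
  empty <- data.frame(t = numeric(0), pre_pressure = numeric(0),
                      min_pressure = numeric(0), rise_cm = numeric(0))
  if (n < 5L) return(empty)
  k <- as.integer(baseline_window) + 1L
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  baseline <- stats::runmed(pressure, k, endrule = "median")
  deficit <- baseline - pressure
  cand <- runs_true(deficit >= min_rise_cm / 1000)
  if (nrow(cand) == 0L) return(empty)
  ev <- lapply(seq_len(nrow(cand)), function(i) {
    r <- cand$start[i]:cand$end[i]
    j <- r[which.min(pressure[r])]
    c(t = time[j], pre = baseline[j], minp = pressure[j])
  })
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev[, "t"]), , drop = FALSE]
  keep <- logical(nrow(ev))
  last <- -Inf
  for (i in seq_len(nrow(ev))) {
    if (ev[i, "t"] - last >= refractory) {
      keep[i] <- TRUE
      last <- ev[i, "t"]
    }
  }
  ev <- ev[keep, , drop = FALSE]
  data.frame(t = ev[, "t"], pre_pressure = ev[, "pre"],
             min_pressure = ev[, "minp"],
             rise_cm = (ev[, "pre"] - ev[, "minp"]) * 1000)
}

#' Group inhalation events into breathing bouts
#'
#' Events separated by at most `max_gap` seconds belong to one bout; a bout
#' spans its first to last event and a singleton event forms a one-inhalation
#' bout.  The default gap keeps a typical bout (about ten inhalations some
#' 17 s apart) together while inter-bout intervals of tens of minutes never
#' merge.
#'
#' @param inhalations data.frame from [detect_inhalations()].
#' @param max_gap maximum intra-bout gap between events, s.
#' @return list with `bouts` (data.frame `bout`, `t_start`, `t_end`,
#'   `duration_s`, `n_inhalations`) and `inhalations` (input plus `bout`
#'   column).
#' @export
group_breathing_bouts <- function(inhalations, max_gap = 60) {
  if (nrow(inhalations) == 0L) {
    return(list(
      bouts = data.frame(bout = integer(0), t_start = numeric(0),
                         t_end = numeric(0), duration_s = numeric(0),
                         n_inhalations = integer(0)),
      inhalations = cbind(inhalations, bout = integer(0))
    ))
  }
  inh <- inhalations[order(inhalations$t), , drop = FALSE]
  bout <- cumsum(c(1, diff(inh$t) > max_gap))
  inh$bout <- bout
  t_start <- tapply(inh$t, bout, min)
  t_end <- tapply(inh$t, bout, max)
  bouts <- data.frame(
    bout = as.integer(names(t_start)),
    t_start = as.numeric(t_start), t_end = as.numeric(t_end),
    duration_s = as.numeric(t_end - t_start),
    n_inhalations = as.integer(tabulate(bout))
  )
  list(bouts = bouts, inhalations = inh)
}

#' Per-bout breathing rise and inter-bout intervals
#'
#' The rise of a bout is the depth equivalent of the difference between the
#' baseline pressure just before the bout (the first event's baseline) and
#' the minimum pressure reached inside the bout.  Intervals are between
#' consecutive bout starts.
#'
#' @param grouped list from [group_breathing_bouts()].
#' @return list `rise_cm` (per bout), `mean_rise_cm`, `intervals_s`.
#' @export
breathing_rise_stats <- function(grouped) {
  bouts <- grouped$bouts
  inh <- grouped$inhalations
  if (nrow(bouts) == 0L) {
    return(list(rise_cm = numeric(0), mean_rise_cm = NA_real_,
                intervals_s = numeric(0)))
  }
  rise <- vapply(bouts$bout, function(b) {
    e <- inh[inh$bout == b, ]
    (e$pre_pressure[1] - min(e$min_pressure)) * 1000
  }, numeric(1))
  list(rise_cm = rise, mean_rise_cm = mean(rise),
       intervals_s = diff(bouts$t_start))
}

#' Detect basking events from a Midday temperature stream
#'
#' Basking (emersion in the sun) shows as a sustained, continuous rise of
#' tag temperature.  The stream is smoothed with a centred `smooth`-second
#' mean; maximal runs where the smoothed series is non-decreasing (within a
#' small per-sample tolerance `eps`) whose run-average slope is at least
#' `min_slope` and which last at least `min_duration` become events.
#'
#' @param time,temp 1 Hz Midday temperature stream (s, degC).
#' @param min_duration minimum event duration, s.
#' @param min_slope minimum run-average warming rate, degC per minute.
#' @param smooth smoothing window, s.
#' @param eps tolerated per-sample decrease of the smoothed series, degC.
#' @return data.frame `t_start`, `t_end`, `duration_s`, `delta_t` (total
#'   rise, degC).
#' @export
detect_basking <- function(time, temp, min_duration = 300, min_slope = 0.2,
                           smooth = 60, eps = 0.01) {
  n <- length(temp)
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration_s = numeric(0), delta_t = numeric(0))
  if (n < smooth + 2L) return(empty)
  k <- as.integer(smooth)
  if (k %% 2L == 0L) k <- k + 1L
  sm <- as.numeric(stats::filter(temp, rep(1 / k, k), sides = 2))
  h <- (k - 1L) %/% 2L
  sm[seq_len(h)] <- sm[h + 1L]
  sm[(n - h + 1L):n] <- sm[n - h]
  rising <- c(diff(sm) >= -eps, FALSE)
  rr <- runs_true(rising)
  if (nrow(rr) == 0L) return(empty)
  out <- lapply(seq_len(nrow(rr)), function(i) {
    i1 <- rr$start[i]; i2 <- rr$end[i]
    dur <- time[i2] - time[i1]
    if (dur < min_duration) return(NULL)
    dt <- sm[i2] - sm[i1]
    if (dt / (dur / 60) < min_slope) return(NULL)
    data.frame(t_start = time[i1], t_end = time[i2], duration_s = dur,
               delta_t = dt)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Detect diving events from sudden temperature drops or pressure rises
#'
#' A dive of a previously basking (warm, emerged) turtle shows either as a
#' sudden temperature drop (>= `dt_drop` degC over `dt_window` s) or as a
#' sudden pressure rise (>= `dp_rise` bar over `dp_window` s).  An event
#' opens at the first firing trigger; temperature and pressure triggers
#' within `merge_gap` seconds merge into one event whose `trigger` records
#' the first sensor to fire.
#'
#' @param time,temp,pressure 1 Hz streams (s, degC, bar).
#' @param dt_drop,dt_window temperature trigger: drop (degC) over window (s).
#' @param dp_rise,dp_window pressure trigger: rise (bar) over window (s).
#' @param merge_gap triggers within this many seconds merge, s.
#' @return data.frame `t_start`, `t_end`, `trigger`
#'   (`"temperature" | "pressure"`), `delta_t` (max temperature drop over
#'   the trigger window, degC).
#' @export
detect_dives <- function(time, temp, pressure, dt_drop = 2, dt_window = 60,
                         dp_rise = 0.01, dp_window = 30, merge_gap = 60) {
  n <- length(time)
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      trigger = character(0), delta_t = numeric(0))
  if (n <= max(dt_window, dp_window)) return(empty)
  lag_diff <- function(x, lag) c(rep(NA_real_, lag), x[(lag + 1L):n] -
                                   x[seq_len(n - lag)])
  tdrop <- -lag_diff(temp, as.integer(dt_window))
  prise <- lag_diff(pressure, as.integer(dp_window))
  ttrig <- !is.na(tdrop) & tdrop >= dt_drop
  ptrig <- !is.na(prise) & prise >= dp_rise
  any_trig <- ttrig | ptrig
  rr <- runs_true(close_gaps(any_trig, as.integer(merge_gap)))
  if (nrow(rr) == 0L) return(empty)
  out <- lapply(seq_len(nrow(rr)), function(i) {
    r <- rr$start[i]:rr$end[i]
    first_t <- suppressWarnings(min(which(ttrig[r])))
    first_p <- suppressWarnings(min(which(ptrig[r])))
    trig <- if (first_t <= first_p) "temperature" else "pressure"
    data.frame(t_start = time[r[1]], t_end = time[r[length(r)]],
               trigger = trig,
               delta_t = max(tdrop[r], 0, na.rm = TRUE))
  })
  do.call(rbind, out)
}

#' Nest-digging window rule on body-angle variances
#'
#' A 2-min window of 10 Hz pitch/roll angles is flagged as digging when
#' `var(roll) < 50 & var(pitch) > 120` or `var(roll) < 10 & var(pitch) > 40`
#' (variances in squared degrees, sample denominator).  The stereotyped
#' rear-leg digging drives large pitch oscillations while roll stays steady.
#'
#' @param var_pitch,var_roll window variances, deg^2.
#' @return logical.
#' @export
nesting_window_flag <- function(var_pitch, var_roll) {
  (var_roll < 50 & var_pitch > 120) | (var_roll < 10 & var_pitch > 40)
}

#' Detect nest-digging events from pitch/roll variance
#'
#' Sliding 2-min windows (stride `step` s) over the 10 Hz angle series are
#' flagged with [nesting_window_flag()]; flagged windows are merged across
#' gaps up to `merge_gap` seconds and merged runs of at least `min_event`
#' seconds become events.  `mean_vedba` is computed over the event span when
#' a VeDBA series is supplied.
#'
#' @param time,pitch,roll 10 Hz angle series (s, degrees).
#' @param vedba optional VeDBA series aligned with `time`.
#' @param window,step window length and stride, s.
#' @param min_event minimum event duration, s.
#' @param merge_gap maximum merged gap between flagged windows, s.
#' @param fs sampling frequency, Hz.
#' @return data.frame `t_start`, `t_end`, `duration_min`, `mean_vedba`.
#' @export
detect_nesting <- function(time, pitch, roll, vedba = NULL, window = 120,
                           step = 30, min_event = 300, merge_gap = 600,
                           fs = 10) {
  w <- as.integer(window * fs)
  s <- as.integer(step * fs)
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration_min = numeric(0), mean_vedba = numeric(0))
  if (length(time) < w) return(empty)
  vp <- rolling_window_stats(pitch, w, s)
  vr <- rolling_window_stats(roll, w, s)
  flag <- !is.na(vp$var) & !is.na(vr$var) &
    nesting_window_flag(vp$var, vr$var)
  if (!any(flag)) return(empty)
  # windows overlap; convert flagged windows to merged time intervals
  t0 <- time[vp$start[flag]]
  t1 <- t0 + window
  o <- order(t0)
  t0 <- t0[o]; t1 <- t1[o]
  grp <- cumsum(c(1, t0[-1] > cummax(t1[-length(t1)]) + merge_gap))
  out <- lapply(split(seq_along(t0), grp), function(i) {
    a <- min(t0[i]); b <- max(t1[i])
    if (b - a < min_event) return(NULL)
    mv <- if (is.null(vedba)) NA_real_ else {
      mean(vedba[time >= a & time <= b], na.rm = TRUE)
    }
    data.frame(t_start = a, t_end = b, duration_min = (b - a) / 60,
               mean_vedba = mv)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else { rownames(out) <- NULL; out }
}

#' Confusion counts and percentages for detected vs true event intervals
#'
#' A detection overlapping any truth interval is a true positive; a
#' detection overlapping none is a false positive; a truth interval
#' overlapped by no detection is a false negative.  Percentages follow the
#' validation arithmetic `FP% = FP/(TP+FP) * 100` and
#' `FN% = FN/(TP+FN) * 100`, rounded to one decimal.
#'
#' @param detected,truth data.frames with `t_start`, `t_end` columns.
#' @return list `tp`, `fp`, `fn`, `fp_pct`, `fn_pct`.
#' @export
validate_detections <- function(detected, truth) {
  if (nrow(detected) == 0L) {
    return(c(list(tp = 0L, fp = 0L, fn = nrow(truth)),
             detection_rates(0L, 0L, nrow(truth))))
  }
  det_hit <- vapply(seq_len(nrow(detected)), function(i) {
    overlaps_any(detected$t_start[i], detected$t_end[i],
                 truth$t_start, truth$t_end)
  }, logical(1))
  tru_hit <- vapply(seq_len(nrow(truth)), function(i) {
    overlaps_any(truth$t_start[i], truth$t_end[i],
                 detected$t_start, detected$t_end)
  }, logical(1))
  tp <- sum(det_hit)
  fp <- sum(!det_hit)
  fn <- sum(!tru_hit)
  c(list(tp = tp, fp = fp, fn = fn), detection_rates(tp, fp, fn))
}

#' False-positive and false-negative percentages from confusion counts
#'
#' @param tp,fp,fn confusion counts.
#' @return list `fp_pct = FP/(TP+FP)*100`, `fn_pct = FN/(TP+FN)*100`, both
#'   rounded to one decimal (NA when the denominator is zero).
#' @export
detection_rates <- function(tp, fp, fn) {
  fp_pct <- if (tp + fp > 0) round(fp / (tp + fp) * 100, 1) else NA_real_
  fn_pct <- if (tp + fn > 0) round(fn / (tp + fn) * 100, 1) else NA_real_
  list(fp_pct = fp_pct, fn_pct = fn_pct)
}
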