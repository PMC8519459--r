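# Time/energy budgets: per-cycle phase durations, hourly VeDBA, event
# counts, alignment relative to the egg-laying date, and the
# activity-temperature relation.
#
# "Hourly VeDBA" of a phase is the VeDBA time-integral over the phase
# divided by the phase duration in hours (m s^-1 per hour of phase): a
# constant VeDBA of 0.16 m s^-2 gives 0.16 * 3600 = 576 m s^-1 whatever the
# phase length.

#' Budget for one night-anchored cycle
#'
#' @param bouts bout rows of one cycle.
#' @param events list with optional `breathing` (bout table), `inhalations`,
#'   `nesting`, `basking` data.frames.
#' @param ci cumulative VeDBA integral (internal, from [cumtrapz()]).
#' @param coverage fraction of expected motion samples present in the cycle.
#' @return one-row data.frame.
#' @keywords internal
budget_one_cycle <- function(bouts, events, ci, coverage = 1) {
  cyc_start <- min(bouts$t_start)
  cyc_end <- max(bouts$t_end)
  phases <- c("Night", "Morning", "Midday", "Evening")
  dur <- integ <- stats::setNames(numeric(4), phases)
  for (ph in phases) {
    b <- bouts[bouts$label == ph, ]
    if (nrow(b) == 0L) next
    dur[ph] <- sum(b$t_end - b$t_start) / 3600
    integ[ph] <- sum(vapply(seq_len(nrow(b)), function(i) {
      interval_integral(ci, b$t_start[i], b$t_end[i])
    }, numeric(1)))
  }
  hourly <- ifelse(dur > 0, integ / dur, NA_real_)
  in_cycle <- function(df) {
    if (is.null(df)) {
      df <- data.frame(t_start = numeric(0), t_end = numeric(0),
                       duration_s = numeric(0), n_inhalations = integer(0))
    }
    df[df$t_start >= cyc_start & df$t_start < cyc_end, , drop = FALSE]
  }
  br <- in_cycle(events$breathing)
  ne <- in_cycle(events$nesting)
  ba <- in_cycle(events$basking)
  data.frame(
    cycle = bouts$cycle[1], cycle_date = bouts$cycle_date[1],
    night_h = dur["Night"], morning_h = dur["Morning"],
    midday_h = dur["Midday"], evening_h = dur["Evening"],
    night_vedba = hourly["Night"], morning_vedba = hourly["Morning"],
    midday_vedba = hourly["Midday"], evening_vedba = hourly["Evening"],
    night_integral = integ["Night"], morning_integral = integ["Morning"],
    midday_integral = integ["Midday"], evening_integral = integ["Evening"],
    daily_vedba = interval_integral(ci, cyc_start, cyc_end),
    basking_h = if (nrow(ba)) sum(ba$duration_s) / 3600 else 0,
    n_breathing_bouts = nrow(br),
    n_inhalations = if (nrow(br)) sum(br$n_inhalations) else 0L,
    n_nesting_events = nrow(ne),
    coverage = coverage,
    complete = coverage >= 0.95,
    row.names = NULL
  )
}

#' Daily budgets for all complete cycles of one individual
#'
#' Phase durations, per-phase hourly VeDBA (integral per hour of phase),
#' the VeDBA integral over the whole cycle, basking hours and event counts.
#' When phase bouts tile the cycle the per-phase integrals sum exactly to
#' the daily integral.  A cycle whose motion coverage is below 95% of the
#' expected samples is flagged `complete = FALSE` (below 80% it is flagged
#' `partial`).
#'
#' @param bouts bout table from [segment_cycles()].
#' @param events list of event tables (see [budget_one_cycle()]).
#' @param time,vedba motion series (10 Hz).
#' @param fs motion sampling frequency, Hz.
#' @return data.frame, one row per complete cycle.
#' @export
budget_cycles <- function(bouts, events, time, vedba, fs = 10) {
  if (nrow(bouts) == 0L) return(data.frame())
  ok <- is.finite(vedba)
  ci <- cumtrapz(time[ok], vedba[ok])
  rows <- lapply(split(seq_len(nrow(bouts)), bouts$cycle), function(i) {
    b <- bouts[i, ]
    span <- c(min(b$t_start), max(b$t_end))
    if (span[1] < min(ci$t) || span[2] > max(ci$t)) return(NULL)
    n_expected <- (span[2] - span[1]) * fs
    n_present <- sum(time[ok] >= span[1] & time[ok] < span[2])
    budget_one_cycle(b, events, ci, coverage = n_present / n_expected)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$partial <- out$coverage < 0.8
  rownames(out) <- NULL
  out
}

#' Align daily budgets to the egg-laying date
#'
#' Offsets each cycle relative to the individual's first successful laying
#' (`days_from_laying = 0` on the laying day, exactly once).  Nesting events
#' are successful when matched (within `match_tol` seconds) to an observed
#' nesting time from the deployment metadata; otherwise they are attempts.
#' The peri-laying period runs from the first attempt to the last nesting
#' event; days before are `pre`, after are `post`.  Without any success the
#' offsets are NA and `aligned` is FALSE.
#'
#' @param budgets data.frame from [budget_cycles()].
#' @param nesting detected nesting events (`t_start`, `t_end`).
#' @param observed numeric vector of observed nesting times (s), may be
#'   empty.
#' @param origin POSIXct deployment epoch used to date events.
#' @param match_tol matching tolerance, s.
#' @return budgets with `days_from_laying`, `period`
#'   (`pre`/`peri`/`post`), and attribute `aligned`.
#' @export
align_to_laying <- function(budgets, nesting, observed = numeric(0),
                            origin = NULL, match_tol = 7200) {
  budgets$days_from_laying <- NA_integer_
  budgets$period <- NA_character_
  if (nrow(budgets) == 0L) return(budgets)
  ev_date <- function(t) {
    if (!is.null(origin)) as.Date(origin + t, tz = "UTC")
    else as.Date("1970-01-01") + floor(t / 86400)
  }
  success <- logical(nrow(nesting))
  if (nrow(nesting) > 0L && length(observed) > 0L) {
    for (i in seq_len(nrow(nesting))) {
      success[i] <- any(observed >= nesting$t_start[i] - match_tol &
                          observed <= nesting$t_end[i] + match_tol)
    }
  }
  if (!any(success)) {
    attr(budgets, "aligned") <- FALSE
    return(budgets)
  }
  lay_t <- min(nesting$t_start[success])
  lay_date <- ev_date(lay_t)
  budgets$days_from_laying <-
    as.integer(as.Date(budgets$cycle_date) - lay_date)
  if (nrow(nesting) > 0L) {
    peri_from <- min(ev_date(nesting$t_start))
    peri_to <- max(ev_date(nesting$t_end))
    d <- as.Date(budgets$cycle_date)
    budgets$period <- ifelse(d < peri_from, "pre",
                             ifelse(d > peri_to, "post", "peri"))
  }
  attr(budgets, "aligned") <- TRUE
  budgets
}

#' Relation between daily activity and air temperature
#'
#' Fits daily VeDBA against daily mean air temperature by OLS, separately
#' before (`days_from_laying < 0`) and from the laying day on; a period with
#' fewer than `min_days` days is skipped (NULL fit).  When an hourly table
#' (`temp`, `vedba` per hour) is supplied, the nonlinear
#' activity-temperature profile is summarised by binning hourly VeDBA into
#' 2 degC temperature bins and reporting the bin whose upper decile of
#' hourly VeDBA is maximal.
#'
#' @param budgets aligned budgets (with `days_from_laying`).
#' @param daily_temp data.frame `cycle_date`, `temp` (daily mean air, degC).
#' @param hourly optional data.frame `temp`, `vedba` per hour.
#' @param bin_width temperature bin width, degC.
#' @param min_days minimum days per period for a fit.
#' @return list `pre`, `post` (each an [ols_fit()] result with a
#'   `slope_se` element, or NULL), `peak_bin` (midpoint degC, or NA),
#'   `profile` (per-bin upper-decile table).
#' @export
activity_temperature_relation <- function(budgets, daily_temp,
                                          hourly = NULL, bin_width = 2,
                                          min_days = 10) {
  m <- merge(budgets, daily_temp, by = "cycle_date")
  fit_period <- function(sel) {
    d <- m[sel & !is.na(m$days_from_laying), ]
    if (nrow(d) < min_days) return(NULL)
    f <- ols_fit(d$temp, d$daily_vedba)
    lmfit <- stats::lm(daily_vedba ~ temp, data = d)
    f$slope_se <- summary(lmfit)$coefficients["temp", "Std. Error"]
    f
  }
  pre <- fit_period(m$days_from_laying < 0)
  post <- fit_period(m$days_from_laying >= 0)
  peak_bin <- NA_real_
  profile <- NULL
  if (!is.null(hourly) && nrow(hourly) > 0L) {
    mid <- bin_width * floor(hourly$temp / bin_width) + bin_width / 2
    q90 <- tapply(hourly$vedba, mid, stats::quantile, probs = 0.9,
                  names = FALSE)
    profile <- data.frame(bin_mid = as.numeric(names(q90)),
                          vedba_q90 = as.numeric(q90))
    peak_bin <- profile$bin_mid[which.max(profile$vedba_q90)]
  }
  list(pre = pre, post = post, peak_bin = peak_bin, profile = profile)
}
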