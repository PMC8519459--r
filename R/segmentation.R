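# Phase segmentation: classify each 24-h cycle into Night, Morning, Midday
# and Evening from 1-min windowed statistics of light, temperature and
# pressure.
#
# Night epochs have low light (median < 1000 lux) together with highly
# consistent temperature (sd < 1 degC) and pressure (sd < 5e-3 bar); Midday
# epochs have high light (mean > 20000 lux) and temperature well above the
# running 24-h minimum.  Morning fills the span between Night and Midday,
# Evening between Midday and the next Night; when no Midday survives, the
# whole inter-Night span is Morning and no Evening is emitted.

#' Segmentation thresholds and smoothing parameters
#'
#' Defaults are the published threshold values for the night and midday
#' rules; the temperature-excess criterion ("several degrees above the daily
#' minimum") is operationalised as >= 2 degrees C and is configurable.
#' Smoothing closes label gaps up to `smoothing_gap_min` minutes and
#' dissolves runs shorter than `min_bout_min` minutes.
#'
#' @param night_max_median_lux night rule: epoch median light below this, lux.
#' @param night_max_sd_temp night rule: epoch temperature sd below this, degC.
#' @param night_max_sd_pressure night rule: epoch pressure sd below this, bar.
#' @param midday_min_mean_lux midday rule: epoch mean light above this, lux.
#' @param midday_min_temp_excess midday rule: epoch mean temperature at least
#'   this far above the running 24-h minimum, degC.
#' @param min_bout_min minimum surviving label run, minutes.
#' @param smoothing_gap_min maximum label gap closed by smoothing, minutes.
#' @export
segmentation_config <- function(night_max_median_lux = 1000,
                                night_max_sd_temp = 1,
                                night_max_sd_pressure = 5e-3,
                                midday_min_mean_lux = 20000,
                                midday_min_temp_excess = 2,
                                min_bout_min = 10,
                                smoothing_gap_min = 5) {
  cfg <- list(night_max_median_lux = night_max_median_lux,
              night_max_sd_temp = night_max_sd_temp,
              night_max_sd_pressure = night_max_sd_pressure,
              midday_min_mean_lux = midday_min_mean_lux,
              midday_min_temp_excess = midday_min_temp_excess,
              min_bout_min = min_bout_min,
              smoothing_gap_min = smoothing_gap_min)
  stopifnot(all(unlist(cfg) > 0))
  structure(cfg, class = "segmentation_config")
}

#' One-minute epoch statistics of an environmental stream
#'
#' Consecutive non-overlapping windows of `window` seconds aligned to the
#' stream origin.  Standard deviations use the sample (n-1) denominator.
#' An epoch is valid when it covers at least `min_valid` 1 Hz samples.
#' `min24_temp` is the running minimum of epoch temperature over the
#' trailing 24 h (truncated at the head of the record).
#'
#' @param env data.frame `time`, `temp_c`, `pressure_bar`, `light_lux`.
#' @param window epoch length, s.
#' @param min_valid minimum valid samples per epoch.
#' @return data.frame, one row per epoch: `t_start`, `n`, `median_light`,
#'   `mean_light`, `sd_temp`, `sd_pressure`, `mean_temp`, `min24_temp`,
#'   `valid`; attributes `window`, `origin`.
#' @export
epoch_stats <- function(env, window = 60, min_valid = 50) {
  idx <- floor((env$time + 1e-6) / window)
  # split boundaries (stream sorted by time)
  bnd <- c(which(diff(idx) != 0), length(idx))
  starts <- c(1L, head(bnd, -1L) + 1L)
  ids <- idx[starts]
  k <- length(starts)
  med_l <- mean_l <- sd_t <- sd_p <- mean_t <- min_t <- numeric(k)
  n <- integer(k)
  L <- env$light_lux; TT <- env$temp_c; P <- env$pressure_bar
  for (i in seq_len(k)) {
    r <- starts[i]:bnd[i]
    n[i] <- length(r)
    med_l[i] <- stats::median(L[r])
    mean_l[i] <- mean(L[r])
    sd_t[i] <- stats::sd(TT[r])
    sd_p[i] <- stats::sd(P[r])
    mean_t[i] <- mean(TT[r])
    min_t[i] <- min(TT[r])
  }
  # place epochs on a full grid so gaps appear as invalid epochs
  full <- seq.int(min(ids), max(ids))
  pos <- match(full, ids)
  df <- data.frame(
    t_start = full * window,
    n = ifelse(is.na(pos), 0L, n[pos]),
    median_light = med_l[pos], mean_light = mean_l[pos],
    sd_temp = sd_t[pos], sd_pressure = sd_p[pos],
    mean_temp = mean_t[pos], min_temp = min_t[pos]
  )
  df$valid <- df$n >= min_valid & stats::complete.cases(
    df[c("median_light", "sd_temp", "sd_pressure")])
  df$min24_temp <- trailing_min(ifelse(df$valid, df$min_temp, NA),
                                width = as.integer(86400 / window))
  attr(df, "window") <- window
  attr(df, "origin") <- attr(env, "origin")
  df
}

#' Classify epochs into raw night / midday / other labels
#'
#' Night: median light below threshold AND temperature sd AND pressure sd
#' below thresholds.  Midday: mean light above threshold AND mean temperature
#' at least the configured excess above the running 24-h minimum.  An epoch
#' matching both rules is labelled night (the night rule, a conjunction of
#' three conditions, is the more specific).  Invalid epochs are NA.
#'
#' @param stats epoch table from [epoch_stats()].
#' @param config [segmentation_config()].
#' @return character vector `"night" | "midday" | "other"`, NA when invalid.
#' @export
classify_epochs <- function(stats, config = segmentation_config()) {
  night <- stats$median_light < config$night_max_median_lux &
    stats$sd_temp < config$night_max_sd_temp &
    stats$sd_pressure < config$night_max_sd_pressure
  midday <- stats$mean_light > config$midday_min_mean_lux &
    (stats$mean_temp - stats$min24_temp) >= config$midday_min_temp_excess
  lab <- ifelse(night, "night", ifelse(midday, "midday", "other"))
  lab[!stats$valid] <- NA_character_
  lab
}

#' Segment raw epoch labels into phase bouts over night-anchored cycles
#'
#' Labels are smoothed per class (closing gaps up to `smoothing_gap_min`,
#' then dissolving runs shorter than `min_bout_min`).  Cycles run from one
#' Night onset to the next (not calendar midnight).  Within each cycle the
#' Night bout is the anchoring night run; Midday is the longest surviving
#' midday run between two Nights (ties broken by earliest start); Morning
#' fills Night end to Midday start and Evening Midday end to the next Night
#' start.  When no Midday survives, the whole inter-Night span is Morning.
#' Epochs before the first Night onset or after the last are not part of any
#' complete cycle and receive no bout.
#'
#' @param stats epoch table from [epoch_stats()].
#' @param labels raw labels from [classify_epochs()].
#' @param config [segmentation_config()].
#' @return data.frame of bouts: `cycle`, `cycle_date`, `label`, `t_start`,
#'   `t_end`, `duration_h`; attribute `n_cycles`.
#' @export
segment_cycles <- function(stats, labels,
                           config = segmentation_config()) {
  window <- attr(stats, "window") %||% 60
  gap <- as.integer(round(config$smoothing_gap_min * 60 / window))
  minb <- as.integer(round(config$min_bout_min * 60 / window))
  night <- drop_short_runs(close_gaps(labels == "night", gap), minb)
  midday <- (labels == "midday") & !night
  midday <- drop_short_runs(close_gaps(midday, gap), minb)
  nr <- runs_true(night)
  if (nrow(nr) == 0L) {
    out <- empty_bouts()
    attr(out, "n_cycles") <- 0L
    attr(out, "unsegmentable") <- TRUE
    return(out)
  }
  ts <- stats$t_start
  epoch_end <- function(i) ts[i] + window
  origin <- attr(stats, "origin")
  rows <- list()
  n_cycles <- nrow(nr) - 1L
  for (ci in seq_len(max(n_cycles, 0L))) {
    n1 <- nr[ci, ]; n2 <- nr[ci + 1L, ]
    cdate <- if (!is.null(origin)) {
      as.Date(origin + ts[n1$start], tz = "UTC")
    } else {
      as.Date("1970-01-01") + floor(ts[n1$start] / 86400)
    }
    add <- function(label, i1, i2) {
      rows[[length(rows) + 1L]] <<- data.frame(
        cycle = ci, cycle_date = cdate, label = label,
        t_start = ts[i1], t_end = epoch_end(i2),
        duration_h = (epoch_end(i2) - ts[i1]) / 3600
      )
    }
    add("Night", n1$start, n1$end)
    if (n2$start - 1L < n1$end + 1L) next
    inter <- seq.int(n1$end + 1L, n2$start - 1L)
    mr <- runs_true(midday[inter])
    if (nrow(mr) > 0L) {
      lens <- mr$end - mr$start + 1L
      best <- mr[which.max(lens), ]  # which.max takes the earliest tie
      m1 <- inter[1] + best$start - 1L
      m2 <- inter[1] + best$end - 1L
      if (m1 > n1$end + 1L) add("Morning", n1$end + 1L, m1 - 1L)
      add("Midday", m1, m2)
      if (m2 < n2$start - 1L) add("Evening", m2 + 1L, n2$start - 1L)
    } else {
      add("Morning", n1$end + 1L, n2$start - 1L)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_bouts()
  attr(out, "n_cycles") <- n_cycles
  attr(out, "origin") <- origin
  out
}

empty_bouts <- function() {
  data.frame(cycle = integer(0), cycle_date = as.Date(character(0)),
             label = character(0), t_start = numeric(0), t_end = numeric(0),
             duration_h = numeric(0))
}

#' Phase label of each epoch implied by a bout table
#'
#' @param stats epoch table from [epoch_stats()].
#' @param bouts bout table from [segment_cycles()].
#' @return character vector of phase labels (`Night`, `Morning`, `Midday`,
#'   `Evening`), NA for epochs outside every bout.
#' @export
phase_at_epochs <- function(stats, bouts) {
  out <- rep(NA_character_, nrow(stats))
  mid <- stats$t_start + (attr(stats, "window") %||% 60) / 2
  for (i in seq_len(nrow(bouts))) {
    inside <- mid >= bouts$t_start[i] & mid < bouts$t_end[i]
    out[inside] <- bouts$label[i]
  }
  out
}
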