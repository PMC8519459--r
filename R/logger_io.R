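# Logger I/O: reading and writing the delimited-text streams, deployment
# metadata, reference/weather series, and real-time-clock drift correction.
#
# All internal times are numeric seconds since a per-deployment epoch in UTC;
# streams carry the epoch as a POSIXct "origin" attribute.  Display in local
# time (UTC+2 at the study site) is left to the caller.

# Parse a time column that is either numeric seconds or ISO-8601 timestamps
# (auto-detected per file).  Returns list(t = seconds since origin, origin).
parse_time_column <- function(x, origin = NULL) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) {
    return(list(t = num, origin = origin))
  }
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(ts)) stop("unparseable time values in time column")
  if (is.null(origin)) origin <- ts[1]
  list(t = as.numeric(difftime(ts, origin, units = "secs")), origin = origin)
}

read_stream <- function(path, required, origin = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  pt <- parse_time_column(df$time, origin)
  df$time <- pt$t
  n0 <- nrow(df)
  for (col in setdiff(required, "time")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  bad <- !stats::complete.cases(df[required])
  df <- df[!bad, required, drop = FALSE]
  df <- df[order(df$time), , drop = FALSE]
  dup <- duplicated(df$time)
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "origin") <- pt$origin
  attr(df, "n_dropped") <- sum(bad)
  attr(df, "n_duplicates") <- sum(dup)
  df
}

#' Read a 1 Hz environmental stream
#'
#' Comma-delimited file with header `time,temp_c,pressure_bar,light_lux`;
#' `time` is ISO-8601 or float seconds (auto-detected).  Rows with
#' unparseable fields are dropped and counted (`n_dropped` attribute);
#' duplicate timestamps keep the first record (`n_duplicates` attribute) and
#' the result is sorted by time.
#'
#' @param path file path.
#' @param origin optional POSIXct epoch for ISO times.
#' @export
read_env_stream <- function(path, origin = NULL) {
  read_stream(path, c("time", "temp_c", "pressure_bar", "light_lux"), origin)
}

#' Read a 10 Hz tri-axial acceleration stream
#'
#' Comma-delimited file with header `time,ax,ay,az` (m s^-2); same parsing,
#' deduplication and bookkeeping rules as [read_env_stream()].
#' @inheritParams read_env_stream
#' @export
read_accel_stream <- function(path, origin = NULL) {
  read_stream(path, c("time", "ax", "ay", "az"), origin)
}

#' Read deployment metadata
#'
#' YAML file with fields `individual_id`, `body_mass_g`,
#' `carapace_length_mm`, `logger_mass_g`, `rtc_anchors` (list of
#' `[logger_time, true_time]` pairs, at least two required for drift
#' correction) and optional `nesting_observed` (timestamps, seconds).
#'
#' @param path YAML file path.
#' @export
read_deployment_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- yaml::read_yaml(path)
  anchors <- m$rtc_anchors
  if (is.null(anchors) || length(anchors) < 2L) {
    stop("configuration error: at least 2 RTC anchor pairs are required")
  }
  m$rtc_anchors <- do.call(rbind, lapply(anchors, as.numeric))
  colnames(m$rtc_anchors) <- c("logger_time", "true_time")
  if (is.null(m$body_mass_g) || m$body_mass_g <= 0) {
    stop("configuration error: body_mass_g must be positive")
  }
  m$nesting_observed <- as.numeric(unlist(m$nesting_observed))
  m
}

#' Read a full deployment (environment + acceleration + metadata)
#'
#' @param env_path,accel_path,meta_path file paths.
#' @return list with elements `env`, `accel`, `meta`.
#' @export
read_deployment <- function(env_path, accel_path, meta_path) {
  meta <- read_deployment_meta(meta_path)
  env <- read_env_stream(env_path)
  accel <- read_accel_stream(accel_path, origin = attr(env, "origin"))
  list(env = env, accel = accel, meta = meta)
}

#' Correct real-time-clock drift against GPS time anchors
#'
#' Remaps logger timestamps onto true time by piecewise-linear interpolation
#' through the anchor pairs (exactly linear with two anchors); times beyond
#' the outermost anchors are extrapolated with the adjacent segment's slope.
#' The correction is exact at every anchor and reduces to the identity when
#' all anchors have zero offset.
#'
#' @param t logger times, s.
#' @param anchors two-column matrix `(logger_time, true_time)`, >= 2 rows.
#' @return corrected times, s.
#' @export
correct_clock_drift <- function(t, anchors) {
  anchors <- anchors[order(anchors[, 1]), , drop = FALSE]
  lt <- anchors[, 1]
  tt <- anchors[, 2]
  if (nrow(anchors) < 2L) {
    stop("configuration error: at least 2 RTC anchor pairs are required")
  }
  if (any(diff(lt) <= 0) || any(diff(tt) <= 0)) {
    stop("anchors imply a non-monotone time remapping")
  }
  slopes <- diff(tt) / diff(lt)
  k <- findInterval(t, lt, all.inside = TRUE)
  tt[k] + (t - lt[k]) * slopes[pmin(k, length(slopes))]
}

fmt_num <- function(x, digits = 6) {
  formatC(signif(x, digits), format = "g", digits = digits)
}

write_stream_csv <- function(df, path, time_digits = 3) {
  out <- df
  out$time <- sprintf(paste0("%.", time_digits, "f"), df$time)
  for (col in setdiff(names(out), "time")) out[[col]] <- fmt_num(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write logger streams of a deployment to delimited text
#'
#' Times are written with 3 decimal places and measurements with 6
#' significant digits, the precision at which the write/read round trip is
#' lossless.
#'
#' @param dep list as returned by [generate_individual()] (elements `env`,
#'   `accel`, `meta`).
#' @param dir output directory (created if needed).
#' @return invisible named vector of file paths.
#' @export
write_deployment <- function(dep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- dep$meta$individual_id
  paths <- c(
    env = file.path(dir, paste0(id, "_env.csv")),
    accel = file.path(dir, paste0(id, "_accel.csv")),
    meta = file.path(dir, paste0(id, "_meta.yml"))
  )
  write_stream_csv(dep$env, paths["env"])
  write_stream_csv(dep$accel, paths["accel"])
  meta <- dep$meta
  meta$rtc_anchors <- apply(meta$rtc_anchors, 1, as.list, simplify = FALSE)
  yaml::write_yaml(meta, paths["meta"])
  invisible(paths)
}

#' Write budget and event tables
#'
#' Deterministic column order and number formatting: re-running on the same
#' input yields byte-identical files.  An empty event table produces a
#' header-only file.
#'
#' @param budgets daily-budget data.frame (see [budget_cycles()]).
#' @param events named list of event data.frames (e.g. `breathing`,
#'   `basking`, `dives`, `nesting`).
#' @param dir output directory.
#' @return invisible vector of file paths.
#' @export
write_tables <- function(budgets, events, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- file.access(dir, mode = 2) == 0
  if (!ok) stop("output directory is not writable: ", dir)
  paths <- character(0)
  p <- file.path(dir, "daily_budgets.csv")
  utils::write.csv(format_table(budgets), p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  for (nm in names(events)) {
    p <- file.path(dir, paste0("events_", nm, ".csv"))
    utils::write.csv(format_table(events[[nm]]), p, row.names = FALSE,
                     quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

format_table <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && !is.integer(df[[col]])) {
      df[[col]] <- fmt_num(df[[col]], 8)
    }
  }
  df
}

#' Read the reference field-temperature series
#'
#' Comma-delimited, 10-min cadence, header
#' `time,t_air,t_surface,t_20cm,t_bottom` (degrees C).
#' @inheritParams read_env_stream
#' @export
read_reference_series <- function(path, origin = NULL) {
  read_stream(path, c("time", "t_air", "t_surface", "t_20cm", "t_bottom"),
              origin)
}

#' Read the 3-hourly weather series
#'
#' Header `time,t_air_mulhouse,cloud_frac,rain_mm`.
#' @inheritParams read_env_stream
#' @export
read_weather_series <- function(path, origin = NULL) {
  read_stream(path, c("time", "t_air_mulhouse", "cloud_frac", "rain_mm"),
              origin)
}

#' Read a sunrise/sunset table
#'
#' Header `date,sunrise,sunset` with times in decimal hours UTC.
#' @param path file path.
#' @export
read_sun_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("date", "sunrise", "sunset"), names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  df$date <- as.Date(df$date)
  df
}
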