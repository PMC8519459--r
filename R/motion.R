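# Motion-signal module: static/dynamic decomposition of tri-axial
# acceleration, VeDBA/ODBA, body angles from the gravity vector, and the
# linear pressure-to-depth transform.

#' Standard gravity used throughout the package (m s^-2)
#' @keywords internal
GRAVITY <- 9.81

# Zero-phase low-pass with endpoint-reflective padding.  signal::filtfilt
# applies no padding of its own, so a raw call has large transients at both
# ends; reflecting ~30 s of signal about each endpoint suppresses them to
# below 1e-10 on a constant series.
zero_phase_lowpass <- function(x, flt, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- signal::filtfilt(flt, xp)
  y[(pad + 1L):(pad + n)]
}

#' Decompose raw acceleration into static and dynamic components
#'
#' Separates each axis of a 10 Hz tri-axial acceleration stream into a static
#' (gravitational/postural) component, obtained with a zero-phase low-pass
#' filter, and a dynamic (movement) component defined as raw minus static, so
#' that `static + dynamic` reconstructs the raw signal exactly on every
#' sample.
#'
#' The default filter is a 4th-order Butterworth low-pass with cutoff
#' `1/window` Hz applied forward-backward (zero phase); a centred moving
#' average of length `window` seconds is available as an alternative.  Half a
#' filter window at each end of the stream is flagged as edge transient and
#' should be excluded from event detection.
#'
#' @param accel data.frame with columns `time`, `ax`, `ay`, `az` (m s^-2),
#'   nominally uniform at `fs` Hz.
#' @param fs sampling frequency, Hz.
#' @param window low-pass window, seconds; the Butterworth cutoff is
#'   `1/window` Hz.
#' @param method `"butterworth"` (zero-phase, default) or `"moving-average"`.
#' @return data.frame with `time`, `static_x/y/z`, `dyn_x/y/z` and a logical
#'   `edge` column flagging the first and last `window/2` seconds.
#' @export
decompose_acceleration <- function(accel, fs = 10, window = 2,
                                   method = c("butterworth",
                                              "moving-average")) {
  method <- match.arg(method)
  n <- nrow(accel)
  if (n < 4 * window * fs) {
    stop("acceleration stream shorter than 4 low-pass windows")
  }
  lows <- if (method == "butterworth") {
    flt <- signal::butter(4, (1 / window) / (fs / 2), type = "low")
    pad <- as.integer(15 * window * fs)
    lapply(accel[c("ax", "ay", "az")], zero_phase_lowpass, flt = flt,
           pad = pad)
  } else {
    k <- as.integer(window * fs)
    if (k %% 2L == 0L) k <- k + 1L
    lapply(accel[c("ax", "ay", "az")], function(x) {
      y <- stats::filter(x, rep(1 / k, k), sides = 2)
      y <- as.numeric(y)
      # extend the centred mean into the half-window tails
      h <- (k - 1L) / 2L
      y[seq_len(h)] <- y[h + 1L]
      y[(n - h + 1L):n] <- y[n - h]
      y
    })
  }
  half <- window / 2
  edge <- accel$time < accel$time[1] + half |
    accel$time > accel$time[n] - half
  data.frame(
    time = accel$time,
    static_x = lows$ax, static_y = lows$ay, static_z = lows$az,
    dyn_x = accel$ax - lows$ax,
    dyn_y = accel$ay - lows$ay,
    dyn_z = accel$az - lows$az,
    edge = edge
  )
}

#' Vectorial dynamic body acceleration
#'
#' VeDBA is the Euclidean norm of the dynamic acceleration vector,
#' `sqrt(dx^2 + dy^2 + dz^2)`, a standard proxy for locomotor activity.
#'
#' @param dx,dy,dz dynamic components, m s^-2.
#' @return non-negative numeric vector, m s^-2.
#' @seealso [compute_odba()] for the Manhattan-sum alternative.
#' @export
compute_vedba <- function(dx, dy, dz) sqrt(dx^2 + dy^2 + dz^2)

#' Overall dynamic body acceleration (Manhattan sum)
#'
#' ODBA is `|dx| + |dy| + |dz|`; offered as an alternative activity metric,
#' not used by default anywhere in the pipeline.
#' @inheritParams compute_vedba
#' @export
compute_odba <- function(dx, dy, dz) abs(dx) + abs(dy) + abs(dz)

#' Time-integral of VeDBA over an interval
#'
#' Trapezoidal integral of the VeDBA series over `[from, to]`, in m s^-1.
#' Integrated over a full hour of constant VeDBA v the result is `v * 3600`.
#' Interval endpoints are linearly interpolated so that integrals over
#' adjacent intervals add exactly.
#'
#' @param time sample times, s.
#' @param vedba VeDBA per sample, m s^-2.
#' @param from,to interval bounds, s; must lie within the series coverage.
#' @export
integrate_vedba <- function(time, vedba, from = time[1],
                            to = time[length(time)]) {
  ci <- cumtrapz(time, vedba)
  interval_integral(ci, from, to)
}

#' Pitch and roll from the static acceleration vector
#'
#' Pitch is the angle of the surge (anterior-posterior) axis against the
#' horizontal, positive nose-up: `atan2(sx, sqrt(sy^2 + sz^2))`, bounded in
#' [-90, 90] degrees.  Roll is the rotation about the surge axis:
#' `atan2(sy, sz)`, in (-180, 180] degrees.  Samples whose static vector norm
#' is below `0.1 * g` carry no usable gravity direction; their angles are NA
#' and `ok` is FALSE.
#'
#' @param sx,sy,sz static components on surge, sway and heave axes, m s^-2.
#' @return data.frame with `pitch`, `roll` (degrees) and logical `ok`.
#' @export
accel_angles <- function(sx, sy, sz) {
  nrm <- sqrt(sx^2 + sy^2 + sz^2)
  ok <- nrm > 0.1 * GRAVITY
  pitch <- atan2(sx, sqrt(sy^2 + sz^2)) * 180 / pi
  roll <- atan2(sy, sz) * 180 / pi
  pitch[!ok] <- NA_real_
  roll[!ok] <- NA_real_
  data.frame(pitch = pitch, roll = roll, ok = ok)
}

# Static vector for a posture given pitch/roll in degrees (inverse of
# accel_angles up to the overall norm g); used by the simulator and tests.
posture_static <- function(pitch, roll, g = GRAVITY) {
  p <- pitch * pi / 180
  r <- roll * pi / 180
  cbind(x = g * sin(p),
        y = g * cos(p) * sin(r),
        z = g * cos(p) * cos(r))
}

#' Convert surface-referenced pressure to depth
#'
#' The tag pressure is calibrated to 0 bar at the surface with 0.1 bar per
#' metre of water, so depth in centimetres is `1000 * pressure`.  Small
#' negative readings (sensor noise above the surface) are clipped to 0; the
#' number of clipped samples is returned in the `n_clipped` attribute.
#'
#' @param pressure_bar numeric, bar, 0 at the surface.
#' @return depth in cm with attribute `n_clipped`.
#' @export
pressure_to_depth <- function(pressure_bar) {
  d <- pressure_bar * 1000
  neg <- !is.na(d) & d < 0
  d[neg] <- 0
  structure(d, n_clipped = sum(neg))
}

#' Full motion series from a raw acceleration stream
#'
#' Convenience wrapper: decomposition, VeDBA and body angles in one pass.
#'
#' @inheritParams decompose_acceleration
#' @param keep_components keep the six static/dynamic columns (doubles the
#'   memory footprint on long streams).
#' @return data.frame with `time`, `vedba`, `pitch`, `roll`, `ok`, `edge`
#'   (plus the component columns when requested).
#' @export
motion_series <- function(accel, fs = 10, window = 2,
                          method = c("butterworth", "moving-average"),
                          keep_components = FALSE) {
  dec <- decompose_acceleration(accel, fs = fs, window = window,
                                method = method)
  ang <- accel_angles(dec$static_x, dec$static_y, dec$static_z)
  out <- data.frame(
    time = dec$time,
    vedba = compute_vedba(dec$dyn_x, dec$dyn_y, dec$dyn_z),
    pitch = ang$pitch, roll = ang$roll, ok = ang$ok, edge = dec$edge
  )
  if (keep_components) out <- cbind(out, dec[-1L])
  out
}
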