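# Depth (stratum) inference: outside the Night phase the pressure record is
# too erratic for depth, so the occupied vertical stratum (air / water
# surface / 20 cm / bottom) is inferred by regressing tag temperature on
# each reference temperature series and picking the fit closest to
# intercept 0, slope 1, R^2 1.

#' Ordinary least-squares fit of y on x
#'
#' @param x,y paired numeric vectors (NA pairs dropped).
#' @return list `intercept`, `slope`, `r2` (squared Pearson correlation),
#'   `n`.
#' @export
ols_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("degenerate fit: fewer than 2 paired samples")
  if (stats::sd(x) == 0) stop("degenerate fit: zero variance in x")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  list(intercept = unname(co[1]), slope = unname(co[2]),
       r2 = stats::cor(x, y)^2, n = length(x))
}

stratum_score <- function(fit) {
  (1 - fit$r2) + abs(fit$slope - 1) + abs(fit$intercept) / 10
}

#' Infer the occupied stratum for one phase bout
#'
#' The tag temperature over the bout is regressed against each of the four
#' reference series (linearly interpolated from their 10-min cadence to the
#' tag timestamps).  Each fit is scored
#' `(1 - r2) + |slope - 1| + |intercept| / 10` (lower is better; 0 only for
#' an exact identity fit) and the winning stratum is the minimum-score fit.
#' Score differences below `tie_tol` flag the result ambiguous.  A reference
#' covering less than half the bout is skipped with a warning; if every
#' stratum is degenerate or skipped the result is NA with the ambiguous
#' flag.
#'
#' @param time,temp tag temperature within the bout (s, degC).
#' @param ref reference data.frame `time,t_air,t_surface,t_20cm,t_bottom`.
#' @param min_n minimum paired samples per stratum.
#' @param tie_tol score difference regarded as a tie.
#' @return list `stratum` (winner or NA), `ambiguous`, `fits` (data.frame
#'   `stratum,intercept,slope,r2,n,score`).
#' @export
best_stratum <- function(time, temp, ref, min_n = 30, tie_tol = 1e-6) {
  strata <- c(air = "t_air", surface = "t_surface",
              `20cm` = "t_20cm", bottom = "t_bottom")
  rows <- list()
  for (s in names(strata)) {
    rv <- stats::approx(ref$time, ref[[strata[[s]]]], xout = time,
                        rule = 1)$y
    cov <- mean(is.finite(rv))
    if (cov < 0.5) {
      warning("reference gap covers > 50% of bout for stratum ", s,
              "; stratum skipped")
      next
    }
    fit <- tryCatch(ols_fit(rv, temp), error = function(e) NULL)
    if (is.null(fit) || fit$n < min_n) next
    rows[[s]] <- data.frame(stratum = s, intercept = fit$intercept,
                            slope = fit$slope, r2 = fit$r2, n = fit$n,
                            score = stratum_score(fit))
  }
  fits <- do.call(rbind, rows)
  if (is.null(fits) || nrow(fits) == 0L) {
    return(list(stratum = NA_character_, ambiguous = TRUE,
                fits = data.frame()))
  }
  rownames(fits) <- NULL
  o <- order(fits$score)
  ambiguous <- nrow(fits) > 1L &&
    fits$score[o[2]] - fits$score[o[1]] < tie_tol
  list(stratum = fits$stratum[o[1]], ambiguous = ambiguous, fits = fits)
}

#' Stratum inference for every bout of a segmentation
#'
#' @param bouts bout table from [segment_cycles()].
#' @param env environmental stream (tag temperature source).
#' @param ref reference series.
#' @param labels phase labels to process (default Night only, where the
#'   inference is best constrained).
#' @return data.frame `cycle,cycle_date,label,stratum,intercept,slope,r2,
#'   ambiguous`, one row per processed bout.
#' @export
bout_strata <- function(bouts, env, ref, labels = "Night") {
  rows <- list()
  for (i in seq_len(nrow(bouts))) {
    if (!(bouts$label[i] %in% labels)) next
    sel <- env$time >= bouts$t_start[i] & env$time < bouts$t_end[i]
    if (sum(sel) < 30L) next
    bs <- best_stratum(env$time[sel], env$temp_c[sel], ref)
    win <- if (is.na(bs$stratum)) {
      data.frame(intercept = NA_real_, slope = NA_real_, r2 = NA_real_)
    } else {
      bs$fits[bs$fits$stratum == bs$stratum, c("intercept", "slope", "r2")]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cycle = bouts$cycle[i], cycle_date = bouts$cycle_date[i],
      label = bouts$label[i], stratum = bs$stratum,
      intercept = win$intercept, slope = win$slope, r2 = win$r2,
      ambiguous = bs$ambiguous
    )
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(cycle = integer(0), cycle_date = as.Date(character(0)),
               label = character(0), stratum = character(0),
               intercept = numeric(0), slope = numeric(0), r2 = numeric(0),
               ambiguous = logical(0))
}
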