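# Daily basking-occurrence model: logistic regression of Midday presence on
# standardized weather covariates with per-individual intercepts and
# backward AIC selection.
#
# The published analysis fitted a binomial GLMM with turtle identity as a
# random intercept; here the individual effect is a fixed per-individual
# intercept by default (deterministic and dependency-free), which for a
# handful of individuals with hundreds of days each is a close
# approximation.  See the methods vignette for the reasoning.

#' Build the basking design matrix
#'
#' One row per individual-day: the binary response (Midday phase present)
#' and weather covariates.  Cloud cover is the daily mean of the 3-hourly
#' fractions, rainfall the daily sum, air temperature the daily mean, and
#' day length comes from the sunrise/sunset table.  All predictors are
#' centred to mean 0 and scaled to sample variance 1 over the whole design;
#' centring/scaling constants are kept as attributes.
#'
#' @param budgets data.frame with `cycle_date` and `midday_h` columns plus
#'   an `individual` column.
#' @param weather 3-hourly weather data.frame (`time`, `t_air_mulhouse`,
#'   `cloud_frac`, `rain_mm`) with an `origin` attribute, or a pre-aggregated
#'   daily data.frame (`date`, `temp`, `cloud`, `rain`).
#' @param sun sunrise/sunset table (`date`, `sunrise`, `sunset`) in decimal
#'   hours UTC.
#' @return data.frame `individual`, `date`, `midday` (0/1) and standardized
#'   `temp`, `cloud`, `rain`, `day_length`.
#' @export
build_design <- function(budgets, weather, sun) {
  daily <- if (all(c("date", "temp", "cloud", "rain") %in% names(weather))) {
    weather
  } else {
    origin <- attr(weather, "origin")
    wdate <- if (!is.null(origin)) as.Date(origin + weather$time, tz = "UTC")
    else as.Date("1970-01-01") + floor(weather$time / 86400)
    data.frame(
      date = as.Date(names(tapply(weather$cloud_frac, wdate, mean))),
      temp = as.numeric(tapply(weather$t_air_mulhouse, wdate, mean)),
      cloud = as.numeric(tapply(weather$cloud_frac, wdate, mean)),
      rain = as.numeric(tapply(weather$rain_mm, wdate, sum))
    )
  }
  sun$day_length <- sun$sunset - sun$sunrise
  d <- merge(
    data.frame(individual = budgets$individual,
               date = as.Date(budgets$cycle_date),
               midday = as.integer(budgets$midday_h > 0)),
    daily, by = "date")
  d <- merge(d, sun[c("date", "day_length")], by = "date")
  d <- d[order(d$individual, d$date),
         c("individual", "date", "midday", "temp", "cloud", "rain",
           "day_length")]
  rownames(d) <- NULL
  standardize_design(d)
}

#' Centre and scale the predictor columns of a basking design
#'
#' Predictors are centred to mean 0 and scaled to sample variance 1; the
#' operation is idempotent.  A constant predictor cannot be standardized and
#' raises an error.
#'
#' @param design data.frame from [build_design()].
#' @param cols predictor columns.
#' @export
standardize_design <- function(design,
                               cols = c("temp", "cloud", "rain",
                                        "day_length")) {
  cols <- intersect(cols, names(design))
  centers <- scales <- stats::setNames(numeric(length(cols)), cols)
  for (col in cols) {
    x <- design[[col]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("standardization error: predictor '", col,
           "' is constant across rows")
    }
    centers[col] <- mean(x)
    scales[col] <- s
    design[[col]] <- (x - mean(x)) / s
  }
  attr(design, "centers") <- centers
  attr(design, "scales") <- scales
  design
}

#' Fit the binomial basking model
#'
#' Logistic regression (iteratively reweighted least squares via
#' `stats::glm`) of Midday presence on the given terms with a separate
#' fixed intercept per individual (a single common intercept when only one
#' individual is present).  Perfect separation is reported as an error
#' naming the offending term; non-convergence is an error.
#'
#' @param design standardized design from [build_design()].
#' @param terms character vector of predictor columns (may be empty for the
#'   intercept-only model).
#' @return list `coefficients` (data.frame `term`, `estimate`, `se`, `z`),
#'   `aic`, `loglik`, `n`, `terms`, `fit` (the glm object).
#' @export
fit_binomial <- function(design, terms) {
  if (length(unique(design$midday)) < 2L) {
    stop("both response classes must be present")
  }
  multi_id <- length(unique(design$individual)) > 1L
  rhs <- c(if (multi_id) "0 + factor(individual)" else "1", terms)
  fml <- stats::as.formula(paste("midday ~", paste(rhs, collapse = " + ")))
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = design,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  if (!fit$converged) stop("IRLS did not converge within 100 iterations")
  co <- summary(fit)$coefficients
  if (length(terms)) {
    big <- abs(co[terms, "Estimate"]) > 15
    if (any(big)) {
      stop("perfect separation suspected for term(s): ",
           paste(terms[big], collapse = ", "))
    }
  }
  list(
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], z = co[, 3],
                              row.names = NULL),
    aic = stats::AIC(fit),
    loglik = as.numeric(stats::logLik(fit)),
    n = nrow(design),
    terms = terms,
    fit = fit
  )
}

#' Backward AIC selection of the basking model
#'
#' Starting from the full term set, repeatedly drops the single term whose
#' removal lowers AIC the most (candidate terms examined in alphabetical
#' order, which makes ties deterministic) and stops when no removal lowers
#' AIC.  Per-individual intercepts are never dropped.
#'
#' @param design standardized design.
#' @param terms full candidate term set.
#' @return list `final` (the selected [fit_binomial()] result), `steps`
#'   (data.frame `step`, `dropped`, `aic`).
#' @export
backward_aic <- function(design, terms) {
  current <- sort(terms)
  fit <- fit_binomial(design, current)
  steps <- data.frame(step = 0L, dropped = "<full>", aic = fit$aic)
  repeat {
    if (length(current) == 0L) break
    cand_aic <- vapply(current, function(tm) {
      fit_binomial(design, setdiff(current, tm))$aic
    }, numeric(1))
    best <- which.min(cand_aic)  # first minimum in alphabetical order
    if (cand_aic[best] >= fit$aic) break
    dropped <- current[best]
    current <- setdiff(current, dropped)
    fit <- fit_binomial(design, current)
    steps <- rbind(steps, data.frame(step = nrow(steps),
                                     dropped = dropped, aic = fit$aic))
  }
  list(final = fit, steps = steps)
}
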