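#' Construct a multiday area-mean GMC series
#'
#' Dates must be strictly increasing, growth days (days since
#' transplanting) positive and increasing with date, and mean GMC stored as
#' a fraction in (0, 1) (the logarithmic growth-day model's printed
#' coefficients are only self-consistent on the fraction scale).
#'
#' @param date `Date` vector (or coercible).
#' @param growth_day numeric, days since transplanting.
#' @param mean_gmc numeric fractions in (0, 1), the daily area means.
#' @param n_subsamples integer, samples averaged per day (default 12
#'   one-square-meter cuts).
#' @return A `multiday_series` data frame.
#' @export
multiday_series <- function(date, growth_day, mean_gmc, n_subsamples = 12L) {
  date <- as.Date(date)
  if (any(diff(as.numeric(date)) <= 0)) stop("dates must strictly increase")
  if (any(growth_day <= 0) || any(diff(growth_day) <= 0))
    stop("growth days must be positive and increasing")
  if (any(mean_gmc <= 0 | mean_gmc >= 1))
    stop("mean_gmc must be a fraction in (0, 1)")
  structure(data.frame(date = date, growth_day = growth_day,
                       mean_gmc = mean_gmc,
                       n_subsamples = as.integer(n_subsamples)),
            class = c("multiday_series", "data.frame"))
}

# percent values and day offsets from a series (or plain percent vector)
series_pct <- function(series) {
  if (inherits(series, "multiday_series"))
    list(pct = series$mean_gmc * 100,
         day = as.numeric(series$date - series$date[1]),
         gd = series$growth_day)
  else
    list(pct = as.numeric(series), day = seq_along(series) - 1, gd = NULL)
}

#' Fit the constant daily GMC decline
#'
#' The mean of gap-normalized successive differences, in percentage points
#' per day (`method = "ols"` uses the regression slope on day instead).
#'
#' @param series a [multiday_series()] or numeric percent vector.
#' @param method `"diff"` (default) or `"ols"`.
#' @return A `decline_model` of kind `linear` with `delta` (pp/day).
#' @export
fit_linear <- function(series, method = c("diff", "ols")) {
  method <- match.arg(method)
  s <- series_pct(series)
  if (length(s$pct) < 2) stop("need at least 2 entries")
  delta <- if (method == "diff")
    mean(diff(s$pct) / diff(s$day))
  else
    unname(coef(lm(s$pct ~ s$day))[2])
  structure(list(kind = "linear", delta = delta), class = "decline_model")
}

#' Predict GMC with the constant daily decline
#' @param gmc0 origin GMC, percent.
#' @param delta daily decline, percentage points per day (negative).
#' @param i horizon in days (vectorized).
#' @return predicted GMC percent, floored at 0.
#' @export
predict_linear <- function(gmc0, delta, i) pmax(gmc0 + delta * i, 0)

#' Fit the constant daily GMC decline ratio
#'
#' Geometric mean of gap-normalized day-over-day ratios.
#'
#' @inheritParams fit_linear
#' @return A `decline_model` of kind `rate` with daily ratio `r`.
#' @export
fit_rate <- function(series) {
  s <- series_pct(series)
  if (length(s$pct) < 2) stop("need at least 2 entries")
  if (any(s$pct <= 0)) stop("non-positive GMC in series")
  r <- exp(mean(diff(log(s$pct)) / diff(s$day)))
  structure(list(kind = "rate", r = r), class = "decline_model")
}

#' Predict GMC with the constant daily ratio
#' @param gmc0 origin GMC, percent.
#' @param r daily ratio (typically just below 1).
#' @param i horizon in days (vectorized).
#' @return predicted GMC percent.
#' @export
predict_rate <- function(gmc0, r, i) gmc0 * r^i

#' Growth days implied by an origin GMC
#'
#' `GD = a1 ln(GMC0) + b1` with GMC0 a fraction; printed defaults
#' (-40.78, 36.02).
#'
#' @param gmc0 origin GMC as a fraction in (0, 1).
#' @param coeffs `c(a1, b1)`.
#' @return growth days (continuous).
#' @export
gd_from_gmc <- function(gmc0, coeffs = c(-40.78, 36.02)) {
  if (any(gmc0 <= 0)) stop("gmc0 must be positive")
  coeffs[1] * log(gmc0) + coeffs[2]
}

#' Predict GMC with the growth-day logarithmic model
#'
#' The origin GMC is mapped to its growth day by [gd_from_gmc()], then
#' `GMC_i = a2 ln(GD + i) + b2`; printed defaults (-0.514, 2.58).
#'
#' @param gmc0 origin GMC as a fraction in (0, 1).
#' @param i horizon in days (vectorized).
#' @param coeffs `c(a1, b1, a2, b2)`.
#' @return predicted GMC fraction, floored at 0.
#' @export
predict_gd_log <- function(gmc0, i,
                           coeffs = c(-40.78, 36.02, -0.514, 2.58)) {
  gd <- gd_from_gmc(gmc0, coeffs[1:2])
  if (any(gd + i <= 0)) stop("GD + i must be positive")
  pmax(coeffs[3] * log(gd + i) + coeffs[4], 0)
}

#' Fit the growth-day logarithmic model
#'
#' Ordinary least squares of growth day on `ln(GMC)` (the GD lookup) and of
#' GMC on `ln(GD)` (the forecaster), each with its R-squared.
#'
#' @param series a [multiday_series()] with growth-day labels.
#' @return A `decline_model` of kind `gd_log` with `coeffs`
#'   `c(a1, b1, a2, b2)` and `r_squared` (length 2).
#' @export
fit_gd_log <- function(series) {
  if (!inherits(series, "multiday_series") || is.null(series$growth_day))
    stop("fit_gd_log needs a multiday_series with growth-day labels")
  if (nrow(series) < 3) stop("need at least 3 entries")
  g <- series$mean_gmc
  if (max(g) == min(g)) stop("degenerate (constant) series")
  f1 <- lm(series$growth_day ~ log(g))
  f2 <- lm(g ~ log(series$growth_day))
  r2 <- function(f) {
    y <- f$model[[1]]
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  structure(list(kind = "gd_log",
                 coeffs = c(unname(coef(f1)[2]), unname(coef(f1)[1]),
                            unname(coef(f2)[2]), unname(coef(f2)[1])),
                 r_squared = c(gd_on_lngmc = r2(f1), gmc_on_lngd = r2(f2))),
            class = "decline_model")
}

#' @export
print.decline_model <- function(x, ...) {
  cat("<decline_model>", x$kind, "\n")
  switch(x$kind,
    linear = cat(sprintf("  delta = %.3f pp/day\n", x$delta)),
    rate = cat(sprintf("  daily ratio r = %.4f\n", x$r)),
    gd_log = cat(sprintf(
      "  GD = %.2f ln(GMC0) + %.2f;  GMC_i = %.4f ln(GD+i) + %.4f\n",
      x$coeffs[1], x$coeffs[2], x$coeffs[3], x$coeffs[4])))
  invisible(x)
}

#' Predict from any fitted decline model
#'
#' @param model a `decline_model`.
#' @param gmc0 origin GMC, percent.
#' @param i horizon in days (vectorized).
#' @return predicted GMC percent.
#' @export
predict_decline <- function(model, gmc0, i) {
  switch(model$kind,
    linear = predict_linear(gmc0, model$delta, i),
    rate = predict_rate(gmc0, model$r, i),
    gd_log = 100 * predict_gd_log(gmc0 / 100, i, model$coeffs),
    stop("unknown decline model kind"))
}

#' Horizon-wise mean absolute error of a decline model
#'
#' For every origin day t and horizon i, predicts from the observed
#' area-mean GMC at t and compares against the observed GMC at t + i days.
#'
#' @param series a [multiday_series()].
#' @param model a `decline_model`.
#' @param horizons integer horizons, default 1:8.
#' @return named numeric MAE per horizon, percentage points (`NA` for
#'   horizons with no (origin, target) pair).
#' @export
horizon_mae <- function(series, model, horizons = 1:8) {
  s <- series_pct(series)
  out <- setNames(rep(NA_real_, length(horizons)),
                  paste0("h", horizons))
  for (hz in seq_along(horizons)) {
    i <- horizons[hz]
    errs <- c()
    for (t in seq_along(s$day)) {
      u <- which(s$day == s$day[t] + i)
      if (length(u) == 1)
        errs <- c(errs, abs(predict_decline(model, s$pct[t], i) - s$pct[u]))
    }
    if (length(errs)) out[hz] <- mean(errs)
  }
  out
}

#' Three-band harvest recommendation
#'
#' GMC at or above 32% is inappropriate for harvest; between 28% and 32%
#' appropriate; below 28% most appropriate.
#'
#' @param gmc GMC percent (vectorized).
#' @return factor with levels `inappropriate`, `appropriate`,
#'   `most_appropriate`.
#' @export
harvest_band <- function(gmc) {
  if (any(gmc < 0)) stop("gmc must be non-negative")
  factor(ifelse(gmc >= 32, "inappropriate",
                ifelse(gmc >= 28, "appropriate", "most_appropriate")),
         levels = c("inappropriate", "appropriate", "most_appropriate"))
}
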