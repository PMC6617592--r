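#' Percent dry matter
#'
#' Dry-matter content of harvested herbage: `DW / FW`, returned both as a
#' fraction and as a percent (`x 100`). Trial summary tables customarily
#' print the fraction rounded to two decimals, so that form is returned
#' too.
#'
#' @param fw_g Fresh weight (g/row), > 0. Vectorized.
#' @param dw_g Dry weight (g/row), `0 <= dw_g <= fw_g`.
#' @return A tibble with columns `pdm` (fraction), `pdm_percent`,
#'   `pdm_printed` (fraction, 2 dp).
#' @examples
#' percent_dm(525.00, 154.15)  # 0.29
#' @export
percent_dm <- function(fw_g, dw_g) {
  if (any(fw_g <= 0)) {
    abort("`fw_g` must be positive.", class = "swardscan_domain_error")
  }
  if (any(dw_g < 0 | dw_g > fw_g)) {
    abort("`dw_g` must lie in [0, fw_g]: dry weight cannot exceed fresh weight.",
          class = "swardscan_domain_error")
  }
  frac <- dw_g / fw_g
  tibble(pdm = frac, pdm_percent = 100 * frac,
         pdm_printed = round(frac, 2))
}

#' Coefficient of variation
#'
#' `CV = sigma / mu` with `sigma` the sample (n - 1) standard deviation and
#' `mu` the sample mean, reported as a percent.
#'
#' @param values Numeric vector, `n >= 2`, nonzero mean.
#' @return A one-row tibble: `mean`, `sd`, `cv_percent`, `n`.
#' @examples
#' coefficient_of_variation(c(1, 3))  # cv 70.71%
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    abort("CV needs at least two values.", class = "swardscan_domain_error")
  }
  mu <- mean(values)
  if (mu == 0) {
    abort("CV is undefined for zero mean.", class = "swardscan_domain_error")
  }
  s <- sd(values)
  tibble(mean = mu, sd = s, cv_percent = 100 * s / mu, n = length(values))
}

#' Relative growth rate
#'
#' Log-difference growth per day: `RGR = (ln y2 - ln y1) / (t2 - t1)`.
#' Negative rates (contraction between scans) are legitimate output.
#'
#' @param y1,y2 Positive yields (or LV values) at the two time points.
#'   Vectorized.
#' @param t1,t2 Times in days, `t2 > t1`.
#' @return RGR in per-day units.
#' @examples
#' relative_growth_rate(100, 200, 0, 10)  # ln(2)/10 = 0.0693
#' @export
relative_growth_rate <- function(y1, y2, t1, t2) {
  if (any(y1 <= 0) || any(y2 <= 0)) {
    abort("RGR needs positive yields (log of a non-positive value).",
          class = "swardscan_domain_error")
  }
  if (any(t2 <= t1)) {
    abort("RGR needs `t2 > t1`.", class = "swardscan_domain_error")
  }
  (log(y2) - log(y1)) / (t2 - t1)
}

#' Least-squares fit of yield against the LV index
#'
#' Ordinary least squares of `y` on `x` with the summaries used when
#' calibrating the LV index against harvest weights: slope, Y-intercept,
#' their standard errors, the X-intercept (`-Y-intercept / slope` — with
#' LV regressed on fresh weight this is the fresh weight at which the index
#' extrapolates to zero, i.e. the unscannable residual), R^2 (squared
#' Pearson correlation) and the p-value of the slope.
#'
#' @param data A data frame holding the variables (optional; vectors may
#'   be passed directly).
#' @param x,y Column names (strings) when `data` is supplied, else numeric
#'   vectors. `n >= 2` complete pairs and non-constant `x` are required.
#' @return An object of class `lv_fit`; see [tidy()] and [glance()]
#'   methods, and `$slope`, `$y_intercept`, `$x_intercept`, `$r2`, `$n`.
#' @examples
#' linear_fit(x = 1:5, y = 2 * (1:5) + 1)
#' @export
linear_fit <- function(data = NULL, x, y) {
  if (!is.null(data)) {
    stopifnot(is.character(x), is.character(y))
    xv <- data[[x]]
    yv <- data[[y]]
  } else {
    xv <- x
    yv <- y
  }
  keep <- complete.cases(xv, yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 2) {
    abort("regression needs at least two complete observations.",
          class = "swardscan_domain_error")
  }
  if (sd(xv) == 0) {
    abort("`x` is constant; the fit is singular.",
          class = "swardscan_domain_error")
  }
  fit <- lm(yv ~ xv)
  # summary.lm warns on exact lines ("essentially perfect fit"); a perfect
  # calibration is a legitimate input here, not a user error
  cf <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(coef(fit)[2])
  y_int <- unname(coef(fit)[1])
  structure(
    list(slope = slope,
         y_intercept = y_int,
         x_intercept = if (slope != 0) -y_int / slope else NA_real_,
         r2 = suppressWarnings(summary(fit))$r.squared,
         slope_se = cf[2, 2],
         y_intercept_se = cf[1, 2],
         p_slope = cf[2, 4],
         n = length(xv),
         model = fit),
    class = "lv_fit")
}

#' @export
print.lv_fit <- function(x, ...) {
  cat(sprintf(
    "<lv_fit> n = %d: y = %.6g x + %.6g  (X-intercept %.4g, R^2 %.4f, slope p %.3g)\n",
    x$n, x$slope, x$y_intercept, x$x_intercept, x$r2, x$p_slope))
  invisible(x)
}

#' Tidy and summarise an `lv_fit`
#'
#' `tidy()` returns one row per coefficient (term, estimate, std.error,
#' statistic, p.value); `glance()` returns the one-row fit summary
#' including the X-intercept.
#'
#' @param x An `lv_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lv_fit <- function(x, ...) {
  cf <- suppressWarnings(summary(x$model))$coefficients
  tibble(term = c("(Intercept)", "x"),
         estimate = cf[, 1], std.error = cf[, 2],
         statistic = cf[, 3], p.value = cf[, 4])
}

#' @rdname tidy.lv_fit
#' @export
glance.lv_fit <- function(x, ...) {
  tibble(r.squared = x$r2, slope = x$slope, y_intercept = x$y_intercept,
         x_intercept = x$x_intercept, p.value = x$p_slope, n = x$n)
}

#' Per-interval growth series
#'
#' Turns an ordered series of (time, yield) observations into per-interval
#' growth summaries: the relative growth rate of each abutting interval and
#' the simple percent change per day (`(y2/y1 - 1) * 100 / dt`). Intervals
#' of contraction yield negative rates and are reported, not suppressed.
#'
#' @param observations A data frame with columns `t_days` (strictly
#'   increasing) and `y` (positive LV or yield values).
#' @return A `growth_series` tibble: `t1`, `t2`, `y1`, `y2`, `rgr`,
#'   `pct_per_day`.
#' @examples
#' growth_series(tibble::tibble(t_days = c(0, 10), y = c(100, 200)))
#' @export
growth_series <- function(observations) {
  stopifnot(all(c("t_days", "y") %in% names(observations)))
  t <- observations$t_days
  y <- observations$y
  if (length(t) < 2) {
    abort("a growth series needs at least two observations.",
          class = "swardscan_domain_error")
  }
  if (any(diff(t) <= 0)) {
    abort("`t_days` must be strictly increasing.",
          class = "swardscan_ordering_error")
  }
  n <- length(t)
  out <- tibble(
    t1 = t[-n], t2 = t[-1], y1 = y[-n], y2 = y[-1],
    rgr = relative_growth_rate(y[-n], y[-1], t[-n], t[-1]),
    pct_per_day = (y[-1] / y[-n] - 1) * 100 / diff(t))
  class(out) <- c("growth_series", class(out))
  out
}

#' Normalized covariance (correlation) matrix
#'
#' Pearson correlation matrix of the numeric columns of a per-entry
#' parameter table; every entry lies in `[-1, 1]`. Used to check whether
#' regression parameters co-vary across entries (a cultivar effect).
#' Zero-variance columns give `NA` entries with a warning.
#'
#' @param data A data frame; non-numeric columns are dropped.
#' @return A correlation matrix.
#' @examples
#' normalized_covariance(data.frame(a = 1:5, b = (1:5) * 2, c = -(1:5)))
#' @export
normalized_covariance <- function(data) {
  num <- data[vapply(data, is.numeric, logical(1))]
  if (ncol(num) < 2 || nrow(num) < 2) {
    abort("need at least two numeric columns and two rows.",
          class = "swardscan_domain_error")
  }
  zero_var <- vapply(num, function(v) sd(v, na.rm = TRUE) == 0, logical(1))
  if (any(zero_var)) {
    warn(sprintf("zero-variance column(s) give undefined correlations: %s",
                 paste(names(num)[zero_var], collapse = ", ")))
  }
  suppressWarnings(cor(as.matrix(num), use = "pairwise.complete.obs"))
}
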