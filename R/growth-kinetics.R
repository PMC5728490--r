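# Growth-rate estimation from OD600 time series.
#
# The fitting convention follows the classic smoothing-spline
# p-parameterization (p = 1 interpolating, p = 0 linear): minimize
#   p * sum (y_i - f(x_i))^2 + (1 - p) * integral f''(t)^2 dt.
# stats::smooth.spline penalizes on the abscissa rescaled to [0, 1], which
# scales the curvature integral by range(x)^3, hence the lambda mapping below.

#' Construct an OD600 time series
#'
#' @param time_h numeric vector of sampling times in hours, strictly
#'   increasing.
#' @param od numeric vector of OD600 readings, all positive.
#' @param condition condition label (e.g. `"0.2 mM Pi"`).
#' @param replicate replicate identifier.
#' @return A `data.frame` of class `od_series` with columns `time_h`, `od`,
#'   `condition`, `replicate`.
#' @examples
#' od_series(c(0, 1, 2, 3), 0.05 * 2^(0.5 * 0:3), condition = "rich")
#' @export
od_series <- function(time_h, od, condition = "unknown", replicate = "r1") {
  if (!is.numeric(time_h) || !is.numeric(od) || length(time_h) != length(od))
    stop_param("time_h and od must be numeric vectors of equal length")
  if (anyNA(time_h) || anyNA(od))
    stop_param("time_h and od must not contain missing values")
  if (any(diff(time_h) <= 0))
    stop_param("time_h must be strictly increasing")
  if (any(od <= 0))
    stop_param("od values must be positive")
  structure(
    data.frame(time_h = time_h, od = od,
               condition = as.character(condition),
               replicate = as.character(replicate)),
    class = c("od_series", "data.frame"))
}

#' Fit a smoothing spline to log2 OD and evaluate it on a 1-minute grid
#'
#' Fits a cubic smoothing spline to `log2(od)` versus time using the classic
#' p-parameterization (`smoothing` = p; p = 1 interpolates, p = 0 gives the
#' least-squares line) and evaluates the fit at 1-minute intervals spanning
#' the measured range. Point growth rates (doublings/hour) are computed at
#' every measured time point inside the evaluation window from the slope
#' across the two surrounding (+/- 1 minute) fitted values.
#'
#' @param series an [od_series()] (or data.frame with `time_h` and `od`).
#' @param smoothing smoothing parameter p in `[0, 1]`; default 0.4.
#' @param rate_window evaluation window (hours) inside which point growth
#'   rates are reported; default `c(0.5, 11.5)`.
#' @return An object of class `growth_profile`: a list with `grid_times`
#'   (hours, 1-minute spacing), `fitted_log2_od`, `times` (measured points in
#'   the window), `rates` (doublings/hour), `normalized_rates` (filled by
#'   [normalize_by_reference_density()]), `condition`, `replicate`.
#' @examples
#' s <- od_series(seq(0, 12, 0.5), 0.05 * 2^(0.6 * seq(0, 12, 0.5)))
#' prof <- fit_log_od(s)
#' growth_rate_at(prof, 5)  # ~0.6 doublings/hour
#' @export
fit_log_od <- function(series, smoothing = 0.4, rate_window = c(0.5, 11.5)) {
  if (!is.data.frame(series) || !all(c("time_h", "od") %in% names(series)))
    stop_param("series must have columns time_h and od")
  check_scalar(smoothing, "smoothing", 0, 1)
  x <- series$time_h
  y <- series$od
  if (any(!is.finite(y)) || any(y <= 0))
    stop_param("od values must be positive and finite")
  if (length(x) < 4L)
    stop("fit_log_od() needs at least 4 time points")
  ly <- log2(y)
  grid <- seq(min(x), max(x), by = 1 / 60)
  if (smoothing >= 1) {
    f <- stats::splinefun(x, ly, method = "natural")
    fitted <- f(grid)
  } else if (smoothing <= 0) {
    co <- stats::coef(stats::lm(ly ~ x))
    fitted <- co[[1]] + co[[2]] * grid
  } else {
    lam <- (1 - smoothing) / smoothing / diff(range(x))^3
    fit <- stats::smooth.spline(x, ly, lambda = lam, all.knots = TRUE,
                                penalty = 1, keep.data = FALSE)
    fitted <- stats::predict(fit, grid)$y
  }
  prof <- structure(list(
    grid_times = grid, fitted_log2_od = fitted,
    times = numeric(0), rates = numeric(0), normalized_rates = NULL,
    condition = series$condition[1] %||% "unknown",
    replicate = series$replicate[1] %||% "r1",
    smoothing = smoothing, rate_window = rate_window),
    class = "growth_profile")
  keep <- x >= max(rate_window[1], min(x) + 1 / 60) &
    x <= min(rate_window[2], max(x) - 1 / 60)
  prof$times <- x[keep]
  prof$rates <- vapply(prof$times, function(t) growth_rate_at(prof, t), 0)
  prof
}

#' @export
print.growth_profile <- function(x, ...) {
  cat("<growth_profile>", x$condition, "/", x$replicate, "\n")
  cat("  grid:", length(x$grid_times), "points,",
      sprintf("%.2f-%.2f h", min(x$grid_times), max(x$grid_times)), "\n")
  cat("  rates at", length(x$times), "measured points")
  if (length(x$rates))
    cat(sprintf(" (mean %.3f doublings/h)", mean(x$rates)))
  cat("\n")
  invisible(x)
}

grid_index <- function(profile, t) {
  i <- which.min(abs(profile$grid_times - t))
  if (i == 1L || i == length(profile$grid_times))
    stop("time ", t, " h too close to the edge of the fitted range")
  i
}

#' Growth rate at a time point from the fitted grid
#'
#' Central difference of the fitted log2 OD across t +/- 1 minute, in
#' doublings per hour. Rates are only defined for times inside the
#' evaluation window (default 0.5-11.5 h) and the fitted range.
#'
#' @param profile a `growth_profile` from [fit_log_od()].
#' @param t time in hours.
#' @return Growth rate in doublings/hour.
#' @export
growth_rate_at <- function(profile, t) {
  stopifnot(inherits(profile, "growth_profile"))
  check_scalar(t, "t")
  w <- profile$rate_window
  if (t < w[1] || t > w[2])
    stop("t = ", t, " h is outside the evaluation window [",
         w[1], ", ", w[2], "] h")
  if (t < min(profile$grid_times) || t > max(profile$grid_times))
    stop("t = ", t, " h is outside the fitted range")
  i <- grid_index(profile, t)
  g <- profile$grid_times
  f <- profile$fitted_log2_od
  (f[i + 1L] - f[i - 1L]) / (g[i + 1L] - g[i - 1L])
}

#' Normalize growth rates by a density-matched rich-medium reference
#'
#' For every measured point of `profile`, the reference grid point whose
#' fitted OD is closest to the sample's fitted OD is located (ties broken to
#' the earliest reference time, appropriate under monotone growth) and the
#' reference rate there (central difference across +/- 1 minute) is
#' subtracted. Sample ODs outside the reference's fitted OD range yield a
#' per-point `NA` with a warning rather than a failure.
#'
#' @param profile a `growth_profile` for the sample.
#' @param reference a `growth_profile` for the rich-medium reference.
#' @return `profile` with `normalized_rates` filled (same length as
#'   `profile$times`).
#' @export
normalize_by_reference_density <- function(profile, reference) {
  stopifnot(inherits(profile, "growth_profile"),
            inherits(reference, "growth_profile"))
  ref_od <- 2^reference$fitted_log2_od
  ref_rng <- range(ref_od)
  n_miss <- 0L
  norm <- vapply(seq_along(profile$times), function(k) {
    t <- profile$times[k]
    od <- 2^profile$fitted_log2_od[grid_index(profile, t)]
    if (od < ref_rng[1] || od > ref_rng[2]) {
      n_miss <<- n_miss + 1L
      return(NA_real_)
    }
    j <- which.min(abs(ref_od - od))  # which.min takes the earliest tie
    if (j == 1L) j <- 2L
    if (j == length(ref_od)) j <- length(ref_od) - 1L
    g <- reference$grid_times
    f <- reference$fitted_log2_od
    ref_rate <- (f[j + 1L] - f[j - 1L]) / (g[j + 1L] - g[j - 1L])
    profile$rates[k] - ref_rate
  }, 0)
  if (n_miss > 0L)
    warning(n_miss, " sample point(s) fall outside the reference OD range; ",
            "normalized rate set to NA there")
  profile$normalized_rates <- norm
  profile
}

#' Generations between two optical densities
#'
#' One generation is one doubling: `log2(od_final / od_initial)`. Rounding to
#' whole generations is left to reporting; the computation never rounds.
#'
#' @param od_initial,od_final positive OD600 values.
#' @return Number of generations (doublings), possibly fractional.
#' @examples
#' count_generations(0.05, 0.4)  # 3 generations
#' @export
count_generations <- function(od_initial, od_final) {
  check_scalar(od_initial, "od_initial", lower = .Machine$double.xmin)
  check_scalar(od_final, "od_final", lower = .Machine$double.xmin)
  log2(od_final / od_initial)
}

#' Generations across a serial-transfer dilution
#'
#' Computes the effective post-inoculation OD from the stock OD and the
#' dilution (`inoc_volume_ul` microliters into `culture_volume_ml`
#' milliliters), then counts doublings to the final OD. This is the
#' bookkeeping used for serial-transfer evolution experiments.
#'
#' @param stock_od OD600 of the stationary stock culture.
#' @param inoc_volume_ul inoculated volume in microliters.
#' @param culture_volume_ml culture volume in milliliters.
#' @param final_od OD600 reached before the next transfer.
#' @return Number of generations (doublings), possibly fractional.
#' @examples
#' # 10 ul of an OD-8.5 stock into 10 ml, grown to OD 4: ~9 generations
#' transfer_generations(8.5, 10, 10, 4)
#' @export
transfer_generations <- function(stock_od, inoc_volume_ul, culture_volume_ml,
                                 final_od) {
  check_scalar(stock_od, "stock_od", lower = .Machine$double.xmin)
  check_scalar(inoc_volume_ul, "inoc_volume_ul", lower = .Machine$double.xmin)
  check_scalar(culture_volume_ml, "culture_volume_ml",
               lower = .Machine$double.xmin)
  check_scalar(final_od, "final_od", lower = .Machine$double.xmin)
  od0 <- stock_od * inoc_volume_ul / (1000 * culture_volume_ml)
  count_generations(od0, final_od)
}
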