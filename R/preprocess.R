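#' Estimate the per-day measurement bias of remote-sensed canopy height
#'
#' Remote-sensed canopy height carries a multiplicative bias that changes
#' from flight to flight. Against manual ground truth the model is
#' `CH[d, i] = b_d * PH[d, i] + e[d, i]`, so the least-squares bias on each
#' day is the through-origin regression coefficient
#' `b_d = sum(PH * CH) / sum(PH^2)` over the plots measured both ways that
#' day. Days without ground truth get `b_d` by linear interpolation between
#' the nearest estimated days (boundary days carry the nearest estimate).
#'
#' @param uav Data frame of remote-sensed heights: `plot_id`, `day`, `value`.
#' @param manual Data frame of manual heights: `plot_id`, `day`, `value`;
#'   values must be positive.
#' @param days Optional integer vector of days the model must cover; default
#'   is the union of days present in `uav`.
#' @return An object of class `bias_model`: data frame with columns `day`,
#'   `bias`, `estimated` (`FALSE` where interpolated), `n_pairs`.
#' @export
estimate_daily_bias <- function(uav, manual, days = NULL) {
  stopifnot(all(c("plot_id", "day", "value") %in% names(uav)),
            all(c("plot_id", "day", "value") %in% names(manual)))
  if (is.null(days)) days <- sort(unique(uav$day))
  uav_key <- paste(uav$plot_id, uav$day)

  est_days <- sort(unique(manual$day))
  b_hat <- rep(NA_real_, length(est_days))
  n_pairs <- integer(length(est_days))
  for (k in seq_along(est_days)) {
    d <- est_days[k]
    md <- manual[manual$day == d, ]
    ch <- uav$value[match(paste(md$plot_id, d), uav_key)]
    ok <- !is.na(ch) & !is.na(md$value)
    ph <- md$value[ok]
    ch <- ch[ok]
    if (length(ph) == 0L) next
    if (all(ph == 0)) {
      stop("degenerate regression: all manual heights are zero on day ", d,
           call. = FALSE)
    }
    b_hat[k] <- sum(ph * ch) / sum(ph^2)
    n_pairs[k] <- length(ph)
  }
  have <- !is.na(b_hat)
  if (!any(have)) {
    stop("no day has both remote-sensed and manual heights", call. = FALSE)
  }
  est_days <- est_days[have]
  b_hat <- b_hat[have]
  n_pairs <- n_pairs[have]

  # linear interpolation to uncovered days; nearest estimate at boundaries
  bias <- stats::approx(est_days, b_hat, xout = days, rule = 2)$y
  out <- data.frame(day = days, bias = bias,
                    estimated = days %in% est_days,
                    n_pairs = n_pairs[match(days, est_days)])
  out$n_pairs[is.na(out$n_pairs)] <- 0L
  if (any(out$bias <= 0)) {
    stop("estimated bias is non-positive on some day; cannot correct",
         call. = FALSE)
  }
  class(out) <- c("bias_model", "data.frame")
  out
}

#' Correct remote-sensed heights by the per-day bias
#'
#' Replaces each observation by `value / b_d`. Traits other than height pass
#' through a bias of 1 upstream, so this is safe to apply to height series
#' only.
#'
#' @param series Data frame with columns `plot_id`, `day`, `value`.
#' @param bias A [estimate_daily_bias()] result covering every observation
#'   day.
#' @return `series` with `value` divided by the day's bias.
#' @export
correct_heights <- function(series, bias) {
  stopifnot(inherits(bias, "bias_model"))
  b <- bias$bias[match(series$day, bias$day)]
  if (anyNA(b)) {
    stop("bias model does not cover day(s): ",
         paste(unique(series$day[is.na(b)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(b <= 0)) stop("non-positive bias", call. = FALSE)
  series$value <- series$value / b
  series
}

#' Interpolate a growth curve with a cubic smoothing spline
#'
#' Fits a cubic smoothing spline (penalized residual sum of squares with
#' curvature penalty `lambda`) to one plot's observations and evaluates it at
#' every integer day in the observed range. The defaults 1e-4 (canopy area)
#' and 1e-3 (canopy height) refer to the `lambda` parameter of
#' [stats::smooth.spline()]'s standardized objective; parameterizations of
#' the smoothing penalty differ across spline implementations, so treat them
#' as calibrated defaults rather than universal constants.
#'
#' @param obs Data frame with columns `day` and `value` (one plot's series);
#'   at least 4 distinct days.
#' @param lambda Smoothing penalty (default 1e-3, the canopy-height value).
#' @param days Optional integer days at which to evaluate; default every
#'   integer day in the observed range.
#' @return Data frame with columns `day` and `value` (smoothed).
#' @export
smooth_growth_curve <- function(obs, lambda = 1e-3, days = NULL) {
  stopifnot(all(c("day", "value") %in% names(obs)))
  obs <- obs[is.finite(obs$value), ]
  if (length(unique(obs$day)) < 4L) {
    stop("need >= 4 observation days for smoothing-spline interpolation; ",
         "use a linear fit for shorter series", call. = FALSE)
  }
  if (is.null(days)) days <- seq(min(obs$day), max(obs$day))
  fit <- stats::smooth.spline(obs$day, obs$value, lambda = lambda,
                              cv = FALSE, keep.data = FALSE)
  data.frame(day = as.integer(days),
             value = stats::predict(fit, as.numeric(days))$y)
}

#' Smooth all plots of a phenotype table
#'
#' Applies [smooth_growth_curve()] per plot to a long phenotype table,
#' returning the dense smoothed series.
#'
#' @param phenotypes Data frame with columns `plot_id`, `day`, `value` (a
#'   `trait` column, if present, must be constant).
#' @param lambda Smoothing penalty passed through.
#' @return Data frame with columns `plot_id`, `day`, `value`.
#' @export
smooth_trial <- function(phenotypes, lambda = 1e-3) {
  if ("trait" %in% names(phenotypes) &&
      length(unique(phenotypes$trait)) > 1L) {
    stop("smooth_trial expects a single trait; split first", call. = FALSE)
  }
  parts <- lapply(split(phenotypes, phenotypes$plot_id), function(df) {
    sm <- smooth_growth_curve(df[, c("day", "value")], lambda = lambda)
    data.frame(plot_id = df$plot_id[1], sm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
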