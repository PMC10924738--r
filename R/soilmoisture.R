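#' Spatio-temporal kernel interpolation of soil moisture
#'
#' Soil moisture is measured on a sparse plot x day subset; every value is
#' interpolated as a weighted mean of measurements from the *same irrigation
#' row* (moisture is assumed independent across rows, each fed by its own
#' watering tube), with separable Gaussian weights in plot position and day:
#' `w = exp(-(l - l')^2 / lambda_s) * exp(-(d - d')^2 / lambda_t)`.
#'
#' @param measurements Data frame with columns `row`, `position` (integer
#'   location within the row), `day`, `value`.
#' @param lambda_s,lambda_t Spatial and temporal bandwidths (> 0).
#' @param targets Data frame with columns `row`, `position`, `day`.
#' @param exclude_self If `TRUE`, a measurement at exactly the target
#'   coordinates is excluded (used for leave-one-out cross-validation).
#' @return Numeric vector of interpolated values (% v/v), one per target
#'   row; a convex combination of same-row measurements.
#' @export
interpolate_moisture <- function(measurements, lambda_s, lambda_t, targets,
                                 exclude_self = FALSE) {
  stopifnot(all(c("row", "position", "day", "value") %in%
                  names(measurements)),
            all(c("row", "position", "day") %in% names(targets)))
  if (lambda_s <= 0 || lambda_t <= 0) {
    stop("bandwidths must be positive", call. = FALSE)
  }
  out <- rep(NA_real_, nrow(targets))
  for (r in unique(targets$row)) {
    mi <- measurements[measurements$row == r, ]
    ti <- which(targets$row == r)
    if (nrow(mi) == 0L) {
      stop("no soil-moisture measurements in row ", r, call. = FALSE)
    }
    ds2 <- outer(targets$position[ti], mi$position, "-")^2
    dt2 <- outer(targets$day[ti], mi$day, "-")^2
    W <- exp(-ds2 / lambda_s - dt2 / lambda_t)
    if (exclude_self) {
      W[ds2 == 0 & dt2 == 0] <- 0
    }
    sw <- rowSums(W)
    if (any(sw <= 0)) {
      stop("no measurement with positive weight for some target in row ", r,
           call. = FALSE)
    }
    out[ti] <- as.numeric(W %*% mi$value) / sw
  }
  out
}

#' Default bandwidth candidate grid
#'
#' 17 log-spaced values from 0.1 to 1000 inclusive.
#'
#' @return Numeric vector of length 17.
#' @export
bandwidth_grid <- function() {
  10^seq(log10(0.1), log10(1000), length.out = 17)
}

#' Select interpolation bandwidths by leave-one-out cross-validation
#'
#' Every measurement is predicted from the remaining measurements
#' (`exclude_self`) for each candidate `(lambda_s, lambda_t)` pair on the
#' grid, and the pair minimizing the root-mean-squared error is returned.
#' Ties are broken toward the smaller pair, `lambda_s` first (prefer
#' locality).
#'
#' @inheritParams interpolate_moisture
#' @param candidates_s,candidates_t Candidate bandwidth values; default the
#'   17-value log grid from 0.1 to 1000, searched jointly over all pairs.
#' @return List with `lambda_s`, `lambda_t`, `rmse` (the attained minimum),
#'   and `rmse_table` (data frame `lambda_s`, `lambda_t`, `rmse`, `n`).
#' @export
select_bandwidths <- function(measurements,
                              candidates_s = bandwidth_grid(),
                              candidates_t = bandwidth_grid()) {
  rows <- split(measurements, measurements$row)
  pre <- lapply(rows, function(mi) {
    list(ds2 = outer(mi$position, mi$position, "-")^2,
         dt2 = outer(mi$day, mi$day, "-")^2,
         y = mi$value)
  })
  ns <- length(candidates_s)
  nt <- length(candidates_t)
  sse <- matrix(0, ns, nt)
  cnt <- matrix(0L, ns, nt)
  for (p in pre) {
    n <- length(p$y)
    if (n < 2L) next
    Es <- lapply(candidates_s, function(l) exp(-p$ds2 / l))
    Et <- lapply(candidates_t, function(l) exp(-p$dt2 / l))
    self <- p$ds2 == 0 & p$dt2 == 0
    for (a in seq_len(ns)) {
      for (b in seq_len(nt)) {
        W <- Es[[a]] * Et[[b]]
        W[self] <- 0
        sw <- rowSums(W)
        ok <- sw > 0
        if (!any(ok)) next
        pred <- (W[ok, , drop = FALSE] %*% p$y) / sw[ok]
        sse[a, b] <- sse[a, b] + sum((pred - p$y[ok])^2)
        cnt[a, b] <- cnt[a, b] + sum(ok)
      }
    }
  }
  if (all(cnt == 0L)) {
    stop("LOOCV undefined: no row has two or more measurements",
         call. = FALSE)
  }
  rmse <- sqrt(sse / cnt)
  rmse[cnt == 0L] <- NA_real_
  tab <- data.frame(lambda_s = rep(candidates_s, nt),
                    lambda_t = rep(candidates_t, each = ns),
                    rmse = as.vector(rmse), n = as.vector(cnt))
  # argmin with lexicographic tie-break toward the smaller (lambda_s,
  # lambda_t)
  ok <- which(!is.na(tab$rmse))
  best <- ok[order(tab$rmse[ok], tab$lambda_s[ok], tab$lambda_t[ok])][1]
  list(lambda_s = tab$lambda_s[best], lambda_t = tab$lambda_t[best],
       rmse = tab$rmse[best], rmse_table = tab)
}

#' Interpolate soil moisture to every plot and day
#'
#' Runs [interpolate_moisture()] for the full plot x day grid of a trial
#' design, producing the dense moisture field the growth models consume.
#'
#' @inheritParams interpolate_moisture
#' @param design Data frame with columns `plot_id`, `row`, `position`.
#' @param days Integer vector of days to cover.
#' @param fill_missing_rows If `TRUE`, a design row with no measurements is
#'   filled from the adjacent measured rows (mean of their interpolations at
#'   the same position), with a warning; if `FALSE` (default) such rows are
#'   an error.
#' @return Data frame with exactly `nrow(design) * length(days)` rows:
#'   `plot_id`, `day`, `value`; attributes `lambda_s` and `lambda_t`.
#' @export
densify_moisture <- function(measurements, lambda_s, lambda_t, design, days,
                             fill_missing_rows = FALSE) {
  stopifnot(all(c("plot_id", "row", "position") %in% names(design)))
  targets <- data.frame(
    plot_id = rep(design$plot_id, each = length(days)),
    row = rep(design$row, each = length(days)),
    position = rep(design$position, each = length(days)),
    day = rep(as.numeric(days), nrow(design)),
    stringsAsFactors = FALSE)

  measured_rows <- unique(measurements$row)
  missing_rows <- setdiff(unique(design$row), measured_rows)
  if (length(missing_rows) > 0L && !fill_missing_rows) {
    stop("design row(s) without any soil-moisture measurement: ",
         paste(missing_rows, collapse = ", "),
         "; set fill_missing_rows = TRUE to borrow from adjacent rows",
         call. = FALSE)
  }

  value <- rep(NA_real_, nrow(targets))
  direct <- !targets$row %in% missing_rows
  value[direct] <- interpolate_moisture(
    measurements, lambda_s, lambda_t, targets[direct, , drop = FALSE],
    exclude_self = FALSE)

  if (length(missing_rows) > 0L) {
    warning("filling row(s) with no measurements from adjacent rows: ",
            paste(missing_rows, collapse = ", "), call. = FALSE)
    all_rows <- sort(unique(design$row))
    for (r in missing_rows) {
      k <- match(r, all_rows)
      neighbors <- intersect(all_rows[c(k - 1L, k + 1L)], measured_rows)
      if (length(neighbors) == 0L) neighbors <- measured_rows
      ti <- which(targets$row == r)
      acc <- matrix(NA_real_, length(ti), length(neighbors))
      for (j in seq_along(neighbors)) {
        tj <- targets[ti, , drop = FALSE]
        tj$row <- neighbors[j]
        acc[, j] <- interpolate_moisture(measurements, lambda_s, lambda_t,
                                         tj, exclude_self = FALSE)
      }
      value[ti] <- rowMeans(acc)
    }
  }

  out <- data.frame(plot_id = targets$plot_id, day = targets$day,
                    value = value, stringsAsFactors = FALSE)
  attr(out, "lambda_s") <- lambda_s
  attr(out, "lambda_t") <- lambda_t
  out
}
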