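#' Build a B-spline basis over the soil-moisture support
#'
#' Constructs a basis of exactly `Q` B-spline functions on the observed
#' moisture range: cubic degree (reduced to `Q - 1` when `Q <= 3`), boundary
#' knots at the observed minimum and maximum, and any interior knots at
#' equally spaced quantiles of the supplied moisture values. With the
#' intercept column included the basis is a partition of unity on its
#' support.
#'
#' @param moisture_values Numeric sample of soil-moisture values (% v/v)
#'   defining the support and interior-knot quantiles.
#' @param Q Number of basis functions (the daily-growth model grid uses 3,
#'   4, or 5).
#' @param degree Maximum polynomial degree (default cubic).
#' @return An object of class `bspline_basis`.
#' @export
build_basis <- function(moisture_values, Q, degree = 3L) {
  s <- moisture_values[is.finite(moisture_values)]
  rng <- range(s)
  if (diff(rng) <= 0) {
    stop("degenerate moisture support (min == max)", call. = FALSE)
  }
  Q <- as.integer(Q)
  if (Q < 1L) stop("Q must be >= 1", call. = FALSE)
  if (length(unique(s)) < Q) {
    stop("need at least Q distinct moisture values", call. = FALSE)
  }
  degree <- as.integer(min(degree, Q - 1L))
  n_interior <- max(0L, Q - (degree + 1L))
  knots <- NULL
  if (n_interior > 0L) {
    probs <- seq_len(n_interior) / (n_interior + 1)
    knots <- as.numeric(stats::quantile(s, probs, names = FALSE))
  }
  structure(list(Q = Q, degree = degree, knots = knots, support = rng),
            class = "bspline_basis")
}

#' Evaluate a B-spline basis
#'
#' Values outside the support are clamped to the boundary (reaction-norm
#' estimates at the periphery of the observed moisture range are unstable,
#' so extrapolation is replaced by the boundary value and flagged).
#'
#' @param basis A [bspline_basis].
#' @param s Numeric vector of soil-moisture values.
#' @return Matrix `[length(s) x Q]` of basis values, with logical attribute
#'   `extrapolated` marking clamped inputs.
#' @export
eval_basis <- function(basis, s) {
  stopifnot(inherits(basis, "bspline_basis"))
  lo <- basis$support[1]
  hi <- basis$support[2]
  extra <- s < lo | s > hi
  sc <- pmin(pmax(s, lo), hi)
  if (basis$Q == 1L) {
    B <- matrix(1, length(sc), 1L)  # constant basis
  } else {
    B <- splines::bs(sc, knots = basis$knots, degree = basis$degree,
                     intercept = TRUE, Boundary.knots = basis$support)
    B <- matrix(as.numeric(B), nrow = length(sc), ncol = basis$Q)
  }
  attr(B, "extrapolated") <- extra
  B
}

#' @export
print.bspline_basis <- function(x, ...) {
  cat(sprintf(
    "B-spline basis: Q = %d, degree %d, support [%.3g, %.3g], %d interior knot(s)\n",
    x$Q, x$degree, x$support[1], x$support[2], length(x$knots)))
  invisible(x)
}

# Training records for the varying-coefficient fit: one row per (plot, day)
# with the daily growth and the previous day's soil moisture.
# Validates the expected columns.
check_rn_records <- function(records) {
  need <- c("genotype_id", "day", "dy", "s_prev")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("training records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records
}

#' Fit the reaction-norm coefficients of one (genotype, day) target
#'
#' Solves the locally weighted least-squares problem of the
#' varying-coefficient daily-growth model: training record (i', d') receives
#' weight `max(G[i, i'], 0) * exp(-(d - d')^2 / lambda0)` -- genotypic
#' similarity times closeness of growth stage -- and the B-spline
#' coefficients minimizing the weighted residual sum of squares (plus an
#' optional ridge) are obtained from the normal equations in closed form.
#'
#' @param records Data frame of training records with columns `genotype_id`,
#'   `day`, `dy` (daily growth), `s_prev` (previous-day soil moisture).
#' @param kernel A [genomic_kernel] (or matrix) with row/column names
#'   covering all genotypes involved; negative entries are treated as zero.
#' @param lambda0 Day-kernel bandwidth (the model grid uses 10, 30, 50, 70).
#' @param target_genotype,target_day The target genotype id and day.
#' @param basis A [bspline_basis].
#' @param ridge Ridge penalty added to the normal equations; `NULL` (default)
#'   uses `1e-6 * sum(w) * var(dy)` for numerical stability, `0` gives the
#'   plain weighted least-squares solution.
#' @return Numeric coefficient vector of length `Q`, with attribute `sum_w`
#'   (effective weight mass).
#' @export
fit_target <- function(records, kernel, lambda0, target_genotype, target_day,
                       basis, ridge = NULL) {
  check_rn_records(records)
  K <- kernel_matrix(kernel)
  if (!target_genotype %in% rownames(K)) {
    stop("target genotype ", target_genotype, " not in kernel", call. = FALSE)
  }
  gw <- pmax(K[target_genotype, records$genotype_id], 0)
  tw <- exp(-(as.numeric(target_day) - records$day)^2 / lambda0)
  w <- as.numeric(gw * tw)
  Phi <- eval_basis(basis, records$s_prev)
  solve_wls(Phi, records$dy, w, ridge,
            label = paste0(target_genotype, "@", target_day))
}

# Weighted ridge normal equations; shared by fit_target and fit_all.
solve_wls <- function(Phi, dy, w, ridge, label = "") {
  sw <- sum(w)
  if (sw <= 0 || sum(w > 0) < 1L) {
    stop("no training records with positive weight for target ", label,
         call. = FALSE)
  }
  if (is.null(ridge)) ridge <- 1e-6 * sw * stats::var(dy)
  A <- crossprod(Phi, w * Phi)
  diag(A) <- diag(A) + ridge
  b <- crossprod(Phi, w * dy)
  cf <- tryCatch(solve(A, b), error = function(e) {
    stop(sprintf(
      "singular normal equations for target %s (effective weight %.3g): %s",
      label, sw, conditionMessage(e)), call. = FALSE)
  })
  cf <- as.numeric(cf)
  attr(cf, "sum_w") <- sw
  cf
}

#' Fit reaction norms for many (genotype, day) targets
#'
#' Runs [fit_target()] for every requested target, sharing all
#' precomputation. Because the weight of a record factorizes into a genotype
#' part and a day part, the per-day cross-product blocks are computed once
#' per genotype and recombined for every target day, which makes fitting all
#' genotype x day combinations fast. Results are identical to calling
#' [fit_target()] per target.
#'
#' @inheritParams fit_target
#' @param targets Data frame with columns `genotype_id` and `day`; default
#'   is every combination of genotype (rows of the kernel restricted to
#'   genotypes present in `records`) and training day.
#' @return An object of class `reaction_norm_fit`: `coefs` matrix
#'   `[n_targets x Q]` (rows `NA` for failed targets), `targets`, `basis`,
#'   `lambda0`, `ridge` policy, `kernel_kind`, and `sum_w` per target.
#' @export
fit_all <- function(records, kernel, lambda0, basis, ridge = NULL,
                    targets = NULL) {
  check_rn_records(records)
  K <- kernel_matrix(kernel)
  kind <- if (inherits(kernel, "genomic_kernel")) kernel$kind else "matrix"
  if (is.null(targets)) {
    targets <- expand.grid(
      genotype_id = intersect(rownames(K), unique(records$genotype_id)),
      day = sort(unique(records$day)),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  Q <- basis$Q
  Phi <- eval_basis(basis, records$s_prev)
  rec_days <- sort(unique(records$day))
  day_group <- match(records$day, rec_days)
  geno_idx <- match(records$genotype_id, rownames(K))
  if (anyNA(geno_idx)) {
    stop("training records contain genotypes absent from the kernel",
         call. = FALSE)
  }
  Kc <- pmax(K, 0)

  n_t <- nrow(targets)
  coefs <- matrix(NA_real_, n_t, Q)
  sum_w <- numeric(n_t)
  failures <- character(0)

  PhiY <- Phi * records$dy
  for (g in unique(targets$genotype_id)) {
    gw <- as.numeric(Kc[g, ])[geno_idx]
    # per-day cross-product blocks under the genotype weights
    A_blocks <- array(0, dim = c(Q * Q, length(rec_days)))
    b_blocks <- matrix(0, Q, length(rec_days))
    w_blocks <- numeric(length(rec_days))
    Pg <- Phi * gw
    for (dd in seq_along(rec_days)) {
      sel <- which(day_group == dd)
      A_blocks[, dd] <- as.vector(crossprod(Phi[sel, , drop = FALSE],
                                            Pg[sel, , drop = FALSE]))
      b_blocks[, dd] <- crossprod(PhiY[sel, , drop = FALSE], gw[sel])
      w_blocks[dd] <- sum(gw[sel])
    }
    rows <- which(targets$genotype_id == g)
    for (r in rows) {
      tw <- exp(-(as.numeric(targets$day[r]) - rec_days)^2 / lambda0)
      A <- matrix(A_blocks %*% tw, Q, Q)
      b <- as.numeric(b_blocks %*% tw)
      sw <- sum(w_blocks * tw)
      sum_w[r] <- sw
      rg <- if (is.null(ridge)) 1e-6 * sw * stats::var(records$dy) else ridge
      diag(A) <- diag(A) + rg
      cf <- tryCatch(as.numeric(solve(A, b)), error = function(e) NULL)
      if (is.null(cf) || sw <= 0) {
        failures <- c(failures,
                      paste0(g, "@", targets$day[r]))
      } else {
        coefs[r, ] <- cf
      }
    }
  }
  if (length(failures) > 0L) {
    warning(sprintf("%d target(s) failed (singular or zero weight): %s",
                    length(failures),
                    paste(utils::head(failures, 5), collapse = ", ")),
            call. = FALSE)
  }
  structure(list(coefs = coefs, targets = targets, basis = basis,
                 lambda0 = lambda0, ridge = ridge, kernel_kind = kind,
                 sum_w = sum_w, failures = failures),
            class = "reaction_norm_fit")
}

#' @export
print.reaction_norm_fit <- function(x, ...) {
  cat(sprintf(
    "Reaction-norm fit: %d targets, Q = %d, lambda0 = %g, %s kernel weights\n",
    nrow(x$targets), x$basis$Q, x$lambda0, x$kernel_kind))
  if (length(x$failures) > 0L) {
    cat("  failed targets:", length(x$failures), "\n")
  }
  invisible(x)
}

# Row index of a target in a reaction_norm_fit; error when absent.
rn_target_row <- function(fit, genotype, day) {
  r <- which(fit$targets$genotype_id == genotype &
               fit$targets$day == day)
  if (length(r) == 0L) {
    stop("no fitted target for genotype ", genotype, " on day ", day,
         call. = FALSE)
  }
  r[1]
}

#' Evaluate a fitted reaction norm
#'
#' Returns the predicted daily growth `sum_q c[q, i, d] * phi_q(s)` of a
#' fitted target at given soil-moisture values. Moisture outside the basis
#' support is clamped to the boundary and flagged.
#'
#' @param fit A [fit_all()] result.
#' @param genotype,day Target identity.
#' @param s Numeric vector of soil-moisture values.
#' @return Numeric vector of predicted daily growth with logical attribute
#'   `extrapolated`.
#' @export
evaluate_rn <- function(fit, genotype, day, s) {
  r <- rn_target_row(fit, genotype, day)
  cf <- fit$coefs[r, ]
  if (anyNA(cf)) {
    stop("target ", genotype, "@", day, " failed during fitting",
         call. = FALSE)
  }
  B <- eval_basis(fit$basis, s)
  out <- as.numeric(B %*% cf)
  attr(out, "extrapolated") <- attr(B, "extrapolated")
  out
}

#' Tabulate reaction-norm curves and group genotypes at a probe point
#'
#' For each requested day, evaluates every fitted genotype's reaction norm on
#' a moisture grid, marks which grid values were actually observed within
#' +/- 5 days of that day (estimates outside the observed range are
#' unstable), and optionally splits genotypes into terciles (low / mid /
#' high) by their curve value at a probe (day, moisture) point.
#'
#' @param fit A [fit_all()] result.
#' @param days Integer vector of days to tabulate (e.g. `c(20, 40, 60)`).
#' @param s_grid Moisture grid; default 50 points across the basis support.
#' @param moisture Optional data frame with columns `day` and `value` of
#'   observed soil moisture, used for the support mask (`NULL` marks all
#'   grid values in-support).
#' @param probe Optional `list(day =, s =)`; when given, genotypes are
#'   grouped into terciles of the curve value at the probe. Ties are broken
#'   stably by genotype id.
#' @param support_window Half-width (days) of the support window (default 5).
#' @return List with `curves` (data frame: genotype, day, s, value,
#'   in_support) and, when `probe` is given, `groups` (data frame: genotype,
#'   value, group) plus `probe`. If the probe moisture lies outside the basis
#'   support, the returned `probe$extrapolated` flag is set.
#' @export
extract_rn_curves <- function(fit, days, s_grid = NULL, moisture = NULL,
                              probe = NULL, support_window = 5) {
  if (is.null(s_grid)) {
    s_grid <- seq(fit$basis$support[1], fit$basis$support[2],
                  length.out = 50)
  }
  genotypes <- unique(fit$targets$genotype_id)
  curves <- NULL
  for (d in days) {
    mask <- rep(TRUE, length(s_grid))
    if (!is.null(moisture)) {
      win <- moisture$value[abs(moisture$day - d) <= support_window]
      mask <- if (length(win) == 0L) rep(FALSE, length(s_grid)) else
        s_grid >= min(win) & s_grid <= max(win)
    }
    for (g in genotypes) {
      v <- evaluate_rn(fit, g, d, s_grid)
      curves <- rbind(curves, data.frame(
        genotype_id = g, day = d, s = s_grid, value = as.numeric(v),
        in_support = mask, stringsAsFactors = FALSE))
    }
  }
  out <- list(curves = curves)
  if (!is.null(probe)) {
    vals <- vapply(genotypes, function(g)
      as.numeric(evaluate_rn(fit, g, probe$day, probe$s)), numeric(1))
    extrapolated <- probe$s < fit$basis$support[1] ||
      probe$s > fit$basis$support[2]
    n <- length(genotypes)
    sizes <- diff(floor(seq(0, n, length.out = 4)))
    ord <- order(vals, genotypes)  # stable tie-break on genotype id
    group <- character(n)
    group[ord] <- rep(c("low", "mid", "high"), times = sizes)
    out$groups <- data.frame(genotype_id = genotypes, value = vals,
                             group = factor(group,
                                            levels = c("low", "mid", "high")),
                             stringsAsFactors = FALSE)
    out$probe <- list(day = probe$day, s = probe$s,
                      extrapolated = extrapolated)
    if (extrapolated) {
      warning("probe moisture outside basis support: value extrapolated ",
              "(clamped to boundary)", call. = FALSE)
    }
  }
  out
}

#' Assemble varying-coefficient training records from trial tables
#'
#' Joins smoothed (or observed) daily phenotype values with dense soil
#' moisture into the record table the reaction-norm fit consumes: one row per
#' (plot, day > first) with daily growth `dy = y_d - y_{d-1}` and the
#' previous day's moisture `s_prev`.
#'
#' @param growth Data frame with columns `plot_id`, `day`, `value` (daily
#'   phenotype level).
#' @param moisture Data frame with columns `plot_id`, `day`, `value` (dense
#'   soil moisture).
#' @param design Data frame with columns `plot_id`, `genotype_id` (and
#'   optionally `environment`).
#' @return Data frame with columns `plot_id`, `genotype_id`, `environment`
#'   (if present in `design`), `day`, `dy`, `s_prev`.
#' @export
rn_records <- function(growth, moisture, design) {
  stopifnot(all(c("plot_id", "day", "value") %in% names(growth)),
            all(c("plot_id", "day", "value") %in% names(moisture)),
            all(c("plot_id", "genotype_id") %in% names(design)))
  out <- NULL
  sm_key <- paste(moisture$plot_id, moisture$day)
  for (p in unique(growth$plot_id)) {
    gp <- growth[growth$plot_id == p, ]
    gp <- gp[order(gp$day), ]
    if (nrow(gp) < 2L) next
    d <- gp$day[-1]
    dy <- diff(gp$value)
    s_prev <- moisture$value[match(paste(p, gp$day[-nrow(gp)]), sm_key)]
    keep <- !is.na(s_prev)
    if (!all(keep)) {
      d <- d[keep]; dy <- dy[keep]; s_prev <- s_prev[keep]
    }
    if (length(d) == 0L) next
    row <- design[match(p, design$plot_id), ]
    out <- rbind(out, data.frame(
      plot_id = p, genotype_id = row$genotype_id,
      environment = if ("environment" %in% names(design))
        row$environment else NA_character_,
      day = d, dy = dy, s_prev = s_prev, stringsAsFactors = FALSE))
  }
  if (is.null(out)) stop("no usable training records", call. = FALSE)
  rownames(out) <- NULL
  out
}
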