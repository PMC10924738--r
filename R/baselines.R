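#' Genomic BLUP with one random genotype effect
#'
#' Fits `y = X b + Z u + e` with `u ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` by REML, where `K` is a genomic relationship
#' matrix (or the identity). The variance ratio is profiled out on the
#' eigenbasis of `Z K Z'`, so a single bounded one-dimensional optimization
#' yields the REML estimates; BLUPs then come from the closed-form
#' mixed-model equations. Genotypes present in `K` but unobserved get
#' predictions through the kernel cross-covariance (zero under the
#' identity).
#'
#' @param y Numeric response vector.
#' @param genotype Character vector of genotype ids, same length as `y`.
#' @param environment Optional character vector of environment labels; when
#'   given, environments enter as fixed effects (cell means), otherwise a
#'   single intercept is used.
#' @param kernel A [genomic_kernel] (or matrix) with named rows covering all
#'   genotypes of interest, or `NULL` for an identity covariance over the
#'   observed genotypes.
#' @param var_ratio Optional fixed `sigma_g^2 / sigma_e^2`; when supplied,
#'   REML is skipped and BLUPs are computed at this ratio.
#' @return Object of class `gblup_fit`: `beta` (named fixed effects), `u`
#'   (named BLUPs for every genotype in `K`), `sigma2_g`, `sigma2_e`,
#'   `delta` (`sigma_e^2 / sigma_g^2`), `fitted`, and bookkeeping fields.
#' @export
fit_gblup <- function(y, genotype, environment = NULL, kernel = NULL,
                      var_ratio = NULL) {
  ctx <- gblup_context(genotype, environment, kernel)
  gblup_solve(ctx, y, var_ratio)
}

# Precomputes design matrices and the eigendecomposition of ZKZ' for a fixed
# training layout; reused across days when fitting per-day models.
gblup_context <- function(genotype, environment = NULL, kernel = NULL) {
  genotype <- as.character(genotype)
  n <- length(genotype)
  if (n < 2L) stop("need >= 2 observations", call. = FALSE)
  if (is.null(kernel)) {
    levels_g <- sort(unique(genotype))
    K <- diag(length(levels_g))
    dimnames(K) <- list(levels_g, levels_g)
    identity_k <- TRUE
  } else {
    K <- kernel_matrix(kernel)
    if (is.null(rownames(K))) {
      stop("kernel must carry genotype ids as dimnames", call. = FALSE)
    }
    if (!all(genotype %in% rownames(K))) {
      stop("genotype(s) absent from kernel: ",
           paste(utils::head(setdiff(genotype, rownames(K))), collapse = ", "),
           call. = FALSE)
    }
    ev_min <- min(eigen((K + t(K)) / 2, symmetric = TRUE,
                        only.values = TRUE)$values)
    if (ev_min < -1e-8 * max(sum(diag(K)) / nrow(K), 1)) {
      stop("kernel is not positive semidefinite (min eigenvalue ",
           signif(ev_min, 3), "); add a small diagonal jitter", call. = FALSE)
    }
    identity_k <- FALSE
  }
  gi <- match(genotype, rownames(K))
  Z <- matrix(0, n, nrow(K))
  Z[cbind(seq_len(n), gi)] <- 1
  if (is.null(environment)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    environment <- as.character(environment)
    lev <- sort(unique(environment))
    X <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
    X[cbind(seq_len(n), match(environment, lev))] <- 1
  }
  H <- Z %*% K %*% t(Z)
  eig <- eigen((H + t(H)) / 2, symmetric = TRUE)
  list(K = K, Z = Z, X = X, eig = eig, identity_k = identity_k,
       genotype = genotype, environment = environment)
}

gblup_solve <- function(ctx, y, var_ratio = NULL) {
  stopifnot(length(y) == nrow(ctx$Z))
  U <- ctx$eig$vectors
  d <- pmax(ctx$eig$values, 0)
  ys <- crossprod(U, y)
  Xs <- crossprod(U, ctx$X)
  n <- length(y)
  p <- qr(ctx$X)$rank

  reml_pieces <- function(delta) {
    w <- 1 / (d + delta)
    XtWX <- crossprod(Xs, w * Xs)
    beta <- solve(XtWX, crossprod(Xs, w * ys))
    r <- ys - Xs %*% beta
    s2g <- sum(w * r^2) / (n - p)
    list(beta = beta, s2g = s2g, w = w, XtWX = XtWX, r = r)
  }
  neg_reml_ll <- function(log_delta) {
    delta <- exp(log_delta)
    pc <- reml_pieces(delta)
    0.5 * ((n - p) * log(pc$s2g) - sum(log(pc$w)) +
             determinant(pc$XtWX, logarithm = TRUE)$modulus + (n - p))
  }

  if (is.null(var_ratio)) {
    opt <- stats::optimize(neg_reml_ll, c(log(1e-8), log(1e8)))
    delta <- exp(opt$minimum)
  } else {
    stopifnot(var_ratio > 0)
    delta <- 1 / var_ratio
  }
  pc <- reml_pieces(delta)
  beta <- stats::setNames(as.numeric(pc$beta), colnames(ctx$X))
  sigma2_g <- as.numeric(pc$s2g)
  sigma2_e <- sigma2_g * delta

  # BLUPs for every genotype in K: u = K Z' (ZKZ' + delta I)^{-1} (y - Xb)
  resid <- y - ctx$X %*% pc$beta
  Vinv_r <- U %*% (pc$w * crossprod(U, resid))
  u <- as.numeric(ctx$K %*% crossprod(ctx$Z, Vinv_r))
  names(u) <- rownames(ctx$K)
  fitted <- as.numeric(ctx$X %*% pc$beta + ctx$Z %*% u)

  structure(list(beta = beta, u = u, sigma2_g = sigma2_g,
                 sigma2_e = sigma2_e, delta = delta, fitted = fitted,
                 identity_k = ctx$identity_k,
                 env_levels = colnames(ctx$X)),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf(
    "GBLUP fit: %d fixed effect(s), %d genotype BLUPs, sigma2_g = %.4g, sigma2_e = %.4g\n",
    length(x$beta), length(x$u), x$sigma2_g, x$sigma2_e))
  invisible(x)
}

#' Predict from a GBLUP fit for (genotype, environment) pairs
#'
#' Fixed part plus genotype BLUP. A requested environment without a fixed
#' -effect estimate (the held-out environment in leave-one-environment-out
#' validation) falls back to the mean of the estimated environment effects,
#' with a message.
#'
#' @param fit A [fit_gblup()] result.
#' @param genotype Character vector of genotype ids.
#' @param environment Optional character vector of environment labels.
#' @return Numeric vector of predictions.
#' @export
predict_gblup <- function(fit, genotype, environment = NULL) {
  u <- fit$u[as.character(genotype)]
  u[is.na(u)] <- 0
  if (is.null(environment) || identical(fit$env_levels, "(Intercept)")) {
    mu <- rep(fit$beta[1], length(genotype))
  } else {
    mu <- fit$beta[as.character(environment)]
    if (anyNA(mu)) {
      message("environment(s) without fixed-effect estimate; using the ",
              "mean of estimated environment effects")
      mu[is.na(mu)] <- mean(fit$beta)
    }
  }
  as.numeric(mu + u)
}

#' Predict first-observation-day phenotypes under a CV scheme
#'
#' Applies the mixed-model variant matching the validation scheme:
#' * `CV-G` -- a separate kernel model per environment (mean + genomic
#'   random genotype effect); test genotypes are new, environments are not.
#' * `CV-E` -- one model across all training environments with environment
#'   fixed effects and an *identity* genotype covariance (test genotypes
#'   were observed in other environments).
#' * `CV-GE` -- as CV-E but with the genomic kernel, since neither the test
#'   genotypes nor the test environment were observed.
#'
#' @param train Data frame with columns `genotype_id`, `environment`,
#'   `value` (first-day phenotypes of the training set).
#' @param test Data frame with columns `genotype_id`, `environment`.
#' @param scheme One of `"CV-G"`, `"CV-E"`, `"CV-GE"`.
#' @param kernel A [genomic_kernel] covering all genotypes (ignored for
#'   CV-E).
#' @return `test` with a `value` column of predictions.
#' @export
predict_first_day <- function(train, test, scheme, kernel) {
  scheme <- match.arg(scheme, c("CV-G", "CV-E", "CV-GE"))
  out <- test
  out$value <- NA_real_
  if (scheme == "CV-G") {
    for (env in unique(test$environment)) {
      tr <- train[train$environment == env, ]
      if (nrow(tr) < 2L) {
        stop("CV-G needs training data in test environment ", env,
             call. = FALSE)
      }
      fit <- fit_gblup(tr$value, tr$genotype_id, kernel = kernel)
      sel <- out$environment == env
      out$value[sel] <- predict_gblup(fit, out$genotype_id[sel])
    }
  } else {
    fit <- fit_gblup(train$value, train$genotype_id, train$environment,
                     kernel = if (scheme == "CV-GE") kernel else NULL)
    out$value <- predict_gblup(fit, out$genotype_id, out$environment)
  }
  out
}

#' Per-day genomic-prediction benchmarks (GP and GPG)
#'
#' Single-trait genomic prediction applied independently to each observation
#' day. `GP` models the daily phenotype level directly; `GPG` models daily
#' growth (`y_d - y_{d-1}`) and accumulates predicted growth from the
#' first-day prediction, mimicking the structure of the sequential
#' reaction-norm models. Both use the mixed-model variant of the CV scheme
#' (see [predict_first_day()]).
#'
#' @param train Data frame with columns `plot_id`, `genotype_id`,
#'   `environment`, `day`, `value` (smoothed daily phenotypes of the
#'   training set).
#' @param test Data frame with columns `plot_id`, `genotype_id`,
#'   `environment` (one row per test plot).
#' @param scheme One of `"CV-G"`, `"CV-E"`, `"CV-GE"`.
#' @param kernel A [genomic_kernel].
#' @param model `"GP"` (level) or `"GPG"` (growth, accumulated).
#' @return Data frame `plot_id`, `genotype_id`, `environment`, `day`,
#'   `model`, `value` covering every test plot and day.
#' @export
run_gp_gpg <- function(train, test, scheme, kernel, model = c("GPG", "GP")) {
  model <- match.arg(model)
  scheme <- match.arg(scheme, c("CV-G", "CV-E", "CV-GE"))
  days <- sort(unique(train$day))

  day_slice <- function(d) train[train$day == d, ]
  # shared solver context per training layout (identical across days)
  predict_day <- function(values_df) {
    predict_first_day(values_df, test, scheme, kernel)$value
  }

  preds <- matrix(NA_real_, nrow(test), length(days))
  if (model == "GP") {
    for (k in seq_along(days)) {
      preds[, k] <- predict_day(day_slice(days[k]))
    }
  } else {
    first <- predict_day(day_slice(days[1]))
    preds[, 1] <- first
    # daily growth responses, aligned per plot
    tr_wide <- stats::reshape(
      train[, c("plot_id", "genotype_id", "environment", "day", "value")],
      idvar = c("plot_id", "genotype_id", "environment"),
      timevar = "day", direction = "wide")
    vals <- as.matrix(tr_wide[, paste0("value.", days), drop = FALSE])
    for (k in 2:length(days)) {
      gr <- data.frame(genotype_id = tr_wide$genotype_id,
                       environment = tr_wide$environment,
                       value = vals[, k] - vals[, k - 1],
                       stringsAsFactors = FALSE)
      preds[, k] <- preds[, k - 1] + predict_day(gr)
    }
  }
  data.frame(plot_id = rep(test$plot_id, length(days)),
             genotype_id = rep(test$genotype_id, length(days)),
             environment = rep(test$environment, length(days)),
             day = rep(days, each = nrow(test)),
             model = model,
             value = as.vector(preds),
             stringsAsFactors = FALSE)
}
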