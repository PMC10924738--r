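#' Simulate biallelic SNP genotypes
#'
#' Draws genotype scores in \{-1, 0, 1\} (homozygous reference, heterozygous,
#' homozygous alternative) for a structured accession panel: genotypes are
#' assigned to `cfg$n_subpops` subpopulations, per-marker ancestral allele
#' frequencies are drawn uniformly from `cfg$maf_range`, subpopulation
#' frequencies diverge from them under the Balding-Nichols model with
#' fixation index `cfg$fst`, and genotypes are drawn in Hardy-Weinberg
#' proportions at their subpopulation's frequency. The divergence gives the
#' genomic kernel the within-group relatedness blocks that make genomic
#' prediction of unseen genotypes informative. Markers whose *empirical*
#' minor allele frequency falls below the lower end of the spectrum (or
#' that come out monomorphic) are redrawn, so the matrix emulates marker
#' data that has already passed the usual MAF filter.
#'
#' @param cfg A [sim_config()].
#' @return Integer matrix `[n_genotypes x n_markers]` with entries in
#'   \{-1, 0, 1\}; rownames are genotype ids `G001, ...`, colnames marker
#'   ids; attribute `subpop` gives each genotype's subpopulation.
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_genotypes
  m <- cfg$n_markers
  lo <- cfg$maf_range[1]
  hi <- cfg$maf_range[2]
  subpop <- sample(rep_len(seq_len(cfg$n_subpops), n))

  draw_cols <- function(k) {
    p_anc <- stats::runif(k, lo, hi)
    # subpopulation frequencies: Balding-Nichols divergence around p_anc
    if (cfg$fst > 0 && cfg$n_subpops > 1L) {
      a <- p_anc * (1 - cfg$fst) / cfg$fst
      b <- (1 - p_anc) * (1 - cfg$fst) / cfg$fst
      psub <- matrix(stats::rbeta(cfg$n_subpops * k,
                                  rep(a, each = cfg$n_subpops),
                                  rep(b, each = cfg$n_subpops)),
                     cfg$n_subpops, k)
    } else {
      psub <- matrix(p_anc, cfg$n_subpops, k, byrow = TRUE)
    }
    # HWE genotype draws on the -1/0/1 scale at the subpopulation frequency
    u <- matrix(stats::runif(n * k), n, k)
    pm <- psub[subpop, , drop = FALSE]
    g <- matrix(-1L, n, k)
    g[u < 2 * pm * (1 - pm) + pm^2] <- 0L
    g[u < pm^2] <- 1L
    g
  }

  scores <- draw_cols(m)
  for (iter in seq_len(100L)) {
    p_hat <- (colMeans(scores) + 1) / 2
    maf_hat <- pmin(p_hat, 1 - p_hat)
    bad <- which(maf_hat < lo)
    if (length(bad) == 0L) break
    scores[, bad] <- draw_cols(length(bad))
  }
  dimnames(scores) <- list(sprintf("G%03d", seq_len(n)),
                           sprintf("M%05d", seq_len(m)))
  attr(scores, "subpop") <- subpop
  scores
}

# Deterministic watering pattern of one treatment as a function of
# days-since-first-observation. Cyclic treatments are exactly periodic by
# construction (anchored piecewise exponentials over the phase).
sm_pattern <- function(treatment, t, cfg) {
  set_pt <- cfg$sm_setpoint
  floor_ <- cfg$sm_floor
  switch(treatment,
    WW = rep(set_pt, length(t)),
    # sandy soil dries toward the floor within about a week
    W0 = floor_ + (set_pt - floor_) * exp(-t / 6),
    W5 = sm_cycle(t, period = 10, lo = floor_, hi = set_pt),
    W10 = sm_cycle(t, period = 20, lo = floor_, hi = set_pt),
    stop("unknown treatment label: ", treatment, call. = FALSE)
  )
}

# Exactly periodic on/off cycle: rises lo -> hi over the first half of the
# period, decays hi -> lo over the second half.
sm_cycle <- function(t, period, lo, hi) {
  half <- period / 2
  tau <- half / 2
  phase <- t %% period
  norm <- 1 - exp(-half / tau)
  up <- lo + (hi - lo) * (1 - exp(-phase / tau)) / norm
  down <- lo + (hi - lo) * (exp(-(phase - half) / tau) - exp(-half / tau)) /
    norm
  ifelse(phase < half, up, down)
}

#' Simulate soil-moisture series for one environment
#'
#' Generates per-plot daily volumetric soil moisture (% v/v) under one
#' watering treatment: a deterministic treatment pattern (constant set-point
#' for `WW`, exponential dry-down for `W0`, exactly periodic 5-on/5-off or
#' 10-on/10-off cycles for `W5`/`W10`), plus a smooth spatial effect along
#' each irrigation row and AR(1) day-to-day noise per plot.
#'
#' @param cfg A [sim_config()].
#' @param treatment One of `"WW"`, `"W0"`, `"W5"`, `"W10"`.
#' @param seed_offset Integer added to `cfg$seed` so different environments
#'   get independent noise realizations.
#' @return Numeric matrix `[n_plots x n_days]` (plots in layout order,
#'   columns named by day) with attributes `row` and `position` giving each
#'   plot's irrigation row and integer position within the row.
#' @export
simulate_soil_moisture <- function(cfg, treatment, seed_offset = 0L) {
  validate_sim_config(cfg)
  if (!treatment %in% c("WW", "W0", "W5", "W10")) {
    stop("unknown treatment label: ", treatment, call. = FALSE)
  }
  set.seed(cfg$seed + 1000L + as.integer(seed_offset))
  days <- cfg$days
  n_plots <- cfg$n_genotypes
  ppr <- cfg$plots_per_row
  row_of <- (seq_len(n_plots) - 1L) %/% ppr + 1L
  pos_of <- (seq_len(n_plots) - 1L) %% ppr + 1L
  n_days <- length(days)

  base <- sm_pattern(treatment, days - days[1], cfg)
  s <- matrix(base, n_plots, n_days, byrow = TRUE)

  # smooth spatial effect along each row, constant over the season
  if (cfg$sm_spatial_sd > 0) {
    for (r in unique(row_of)) {
      idx <- which(row_of == r)
      z <- stats::rnorm(length(idx))
      w <- outer(seq_along(idx), seq_along(idx),
                 function(a, b) exp(-(a - b)^2 / (2 * 2^2)))
      sm <- as.vector(w %*% z / rowSums(w))
      sm <- sm / max(stats::sd(sm), 1e-12) * cfg$sm_spatial_sd
      s[idx, ] <- s[idx, ] + sm
    }
  }

  # AR(1) temporal noise per plot
  if (cfg$sm_noise_sd > 0) {
    rho <- 0.6
    e <- matrix(stats::rnorm(n_plots * n_days, sd = cfg$sm_noise_sd),
                n_plots, n_days)
    for (j in 2:n_days) e[, j] <- rho * e[, j - 1] +
        sqrt(1 - rho^2) * e[, j]
    s <- s + e
  }

  s <- pmin(pmax(s, 0.2), 99.8)
  dimnames(s) <- list(NULL, as.character(days))
  attr(s, "row") <- row_of
  attr(s, "position") <- pos_of
  s
}

#' Simulate ground-truth reaction-norm coefficients
#'
#' Generates the true per-(genotype, day) B-spline coefficients `c[q, i, d]`
#' defining each genotype's daily-growth response to soil moisture. Each
#' coefficient is a smooth seasonal mean curve plus (i) a genetic deviation
#' with separable covariance (genomic kernel across genotypes x
#' squared-exponential kernel across days) and (ii) a day-smooth deviation
#' common to all genotypes. `cfg$h2_coef` sets the fraction of deviation
#' variance carried by the genetic term. Optionally plants three discrete
#' low-moisture response classes by offsetting the first (low-moisture) basis
#' coefficient inside an early-season window.
#'
#' @param cfg A [sim_config()].
#' @param kernel A [genomic_kernel] (or plain symmetric matrix) of dimension
#'   `n_genotypes`.
#' @return A list of class `rn_truth`: `coefs` array `[Q_true x n_genotypes x
#'   n_days]`, `basis` (the generating [bspline_basis]), `mu` matrix
#'   `[Q_true x n_days]`, and `classes` (factor of planted response classes,
#'   or `NULL`).
#' @export
simulate_true_reaction_norms <- function(cfg, kernel) {
  validate_sim_config(cfg)
  K <- kernel_matrix(kernel)
  n <- cfg$n_genotypes
  if (nrow(K) != n) {
    stop("kernel dimension (", nrow(K), ") does not match n_genotypes (",
         n, ")", call. = FALSE)
  }
  set.seed(cfg$seed + 2000L)
  days <- cfg$days
  D <- length(days)
  Q <- cfg$Q_true
  basis <- build_basis(seq(cfg$basis_support[1], cfg$basis_support[2],
                           length.out = 50), Q = Q)

  # seasonal mean: bell-shaped envelope times an increasing moisture
  # response; coefficient deviations are scaled by the same envelope so
  # growth-rate variance tracks the growth rate itself
  shape <- exp(-(days - cfg$growth_peak_day)^2 /
                 (2 * cfg$growth_peak_width^2))
  resp <- if (Q == 1L) cfg$resp_range[2] else
    cfg$resp_range[1] + (cfg$resp_range[2] - cfg$resp_range[1]) *
      (seq_len(Q) - 1) / (Q - 1)
  mu <- outer(resp, cfg$growth_max * shape)

  # matrix square roots for the separable deviations
  Ld <- psd_sqrt(exp(-outer(days, days, "-")^2 /
                       (2 * cfg$day_lengthscale^2)))
  Lg <- psd_sqrt(K)
  sd_g <- cfg$coef_sd * sqrt(cfg$h2_coef)
  sd_t <- cfg$coef_sd * sqrt(1 - cfg$h2_coef)

  coefs <- array(0, dim = c(Q, n, D))
  dev_shared <- NULL
  for (q in seq_len(Q)) {
    if (cfg$flat_norms && !is.null(dev_shared)) {
      dev <- dev_shared
    } else {
      gen <- sd_g * (Lg %*% matrix(stats::rnorm(n * D), n, D) %*% t(Ld))
      com <- sd_t * as.vector(Ld %*% stats::rnorm(D))
      dev <- (gen + matrix(com, n, D, byrow = TRUE)) *
        matrix(shape, n, D, byrow = TRUE)
      if (cfg$flat_norms) dev_shared <- dev
    }
    coefs[q, , ] <- matrix(mu[q, ], n, D, byrow = TRUE) + dev
  }

  classes <- NULL
  if (cfg$response_classes == 3L) {
    # classes are heritable and track the panel's family structure:
    # terciles of a polygenic score smoothed by the kernel itself (K z has
    # covariance K^2), so members of a genetic group share a response type
    score <- as.numeric(K %*% stats::rnorm(n))
    sizes <- diff(floor(seq(0, n, length.out = 4)))
    labels <- character(n)
    labels[order(score, seq_len(n))] <-
      rep(c("low", "mid", "high"), times = sizes)
    labels <- factor(labels, levels = c("low", "mid", "high"))
    names(labels) <- sprintf("G%03d", seq_len(n))
    offset <- c(low = -cfg$class_delta, mid = 0, high = cfg$class_delta)
    window <- exp(-((days - 20) / 8)^2)
    coefs[1, , ] <- coefs[1, , ] +
      outer(offset[as.character(labels)], window)
    classes <- labels
  }

  dimnames(coefs) <- list(paste0("q", seq_len(Q)),
                          sprintf("G%03d", seq_len(n)),
                          as.character(days))
  structure(list(coefs = coefs, basis = basis, mu = mu, classes = classes,
                 days = days),
            class = "rn_truth")
}

# Symmetric PSD square root via eigendecomposition; negative eigenvalues
# (numerical, or from clone-duplicated rows) are floored at zero.
psd_sqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate a complete synthetic field trial
#'
#' Runs the whole generative model: SNP genotypes, a linear genomic kernel,
#' ground-truth reaction norms, treatment-specific soil moisture, daily
#' growth accumulated from a log-normal initial size, per-day multiplicative
#' measurement bias on the observed canopy series, manual ground-truth
#' heights for a plot subset, and alternating-subset soil-moisture
#' measurements.
#'
#' Daily growth of plot *i* on day *d* is
#' `sum_q c[q, i, d] * phi_q(s[i, d-1]) + N(0, noise_sd_growth)`, i.e. the
#' reaction norm evaluated at the previous day's soil moisture. The observed
#' canopy value is `b_d * y + N(0, obs_noise_sd)` with `b_d` drawn uniformly
#' from `bias_range`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `synthetic_trial` with elements `design`,
#'   `phenotypes` (observed), `manual` (ground-truth heights), `moisture_obs`
#'   (sparse measurements), `moisture_true` (dense true moisture),
#'   `genotypes`, `kernel`, and `truth` (ground truth: `coefs`, `basis`,
#'   `classes`, `growth` and `trajectory` noise-free matrices, `realized`
#'   trajectory with growth noise, `bias` per day).
#' @export
#' @examples
#' cfg <- sim_config(n_genotypes = 6, n_markers = 40, days = 15:30,
#'                   treatments = c("WW", "W0"), seed = 7)
#' trial <- simulate_trial(cfg)
#' head(trial$phenotypes)
simulate_trial <- function(cfg) {
  validate_sim_config(cfg)
  genotypes <- simulate_genotypes(cfg)
  kernel <- build_linear_kernel(genotypes)
  truth <- simulate_true_reaction_norms(cfg, kernel)

  envs <- sim_environments(cfg)
  days <- cfg$days
  D <- length(days)
  n <- cfg$n_genotypes
  ppr <- cfg$plots_per_row

  design <- NULL
  moisture_true <- NULL
  moisture_obs <- NULL
  sm_list <- list()
  for (e in seq_along(envs)) {
    env <- envs[e]
    treatment <- sub("^Y[0-9]+-", "", env)
    set.seed(cfg$seed + 3000L + e)
    geno_order <- sample(seq_len(n))
    row_of <- (seq_len(n) - 1L) %/% ppr + 1L
    pos_of <- (seq_len(n) - 1L) %% ppr + 1L
    d_env <- data.frame(
      plot_id = sprintf("%s_P%03d", env, seq_len(n)),
      genotype_id = rownames(genotypes)[geno_order],
      environment = env,
      treatment = treatment,
      row = sprintf("%s_R%02d", env, row_of),
      position = pos_of,
      stringsAsFactors = FALSE
    )
    design <- rbind(design, d_env)

    s <- simulate_soil_moisture(cfg, treatment, seed_offset = e)
    sm_list[[env]] <- s
    moisture_true <- rbind(moisture_true, data.frame(
      plot_id = rep(d_env$plot_id, D),
      day = rep(days, each = n),
      value = as.vector(s),
      stringsAsFactors = FALSE
    ))

    # alternating-subset measurements: every other position is a measurement
    # target; targets split into groups measured on alternating days
    targets <- which(pos_of %% 2L == 1L)
    grp <- (seq_along(targets) - 1L) %% cfg$moisture_groups
    for (j in seq_along(targets)) {
      meas_days_idx <- which((seq_len(D) - 1L) %% cfg$moisture_groups ==
                               grp[j])
      p <- targets[j]
      moisture_obs <- rbind(moisture_obs, data.frame(
        row = d_env$row[p],
        position = pos_of[p],
        plot_id = d_env$plot_id[p],
        day = days[meas_days_idx],
        value = s[p, meas_days_idx],
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(design) <- NULL

  n_plots <- nrow(design)
  geno_idx <- match(design$genotype_id, rownames(genotypes))
  day_idx <- seq_len(D)

  # noise-free growth and trajectory; initial size is heritable on the log
  # scale (genetic part shared by all plots of a genotype)
  set.seed(cfg$seed + 4000L)
  u0 <- psd_sqrt(kernel_matrix(kernel)) %*% stats::rnorm(n) *
    cfg$init_size_sdlog * sqrt(cfg$h2_init)
  y0 <- exp(cfg$init_size_meanlog + as.numeric(u0)[geno_idx] +
              stats::rnorm(n_plots,
                           sd = cfg$init_size_sdlog * sqrt(1 - cfg$h2_init)))
  growth <- matrix(0, n_plots, D)       # column 1 stays zero (no growth day)
  for (p in seq_len(n_plots)) {
    env <- design$environment[p]
    within <- match(design$plot_id[p],
                    design$plot_id[design$environment == env])
    s_prev <- sm_list[[env]][within, seq_len(D - 1)]
    Phi <- eval_basis(truth$basis, s_prev)            # (D-1) x Q
    cf <- t(truth$coefs[, geno_idx[p], 2:D, drop = FALSE][, 1, ]) # (D-1) x Q
    if (dim(truth$coefs)[1] == 1L) cf <- matrix(cf, ncol = 1L)
    growth[p, 2:D] <- rowSums(Phi * cf)
  }
  trajectory <- y0 + t(apply(growth, 1, cumsum))

  # realized trajectory: persistent plot effect and daily growth noise
  # accumulate
  gnoise <- matrix(0, n_plots, D)
  if (cfg$plot_effect_sd > 0) {
    gnoise[, 2:D] <- stats::rnorm(n_plots, sd = cfg$plot_effect_sd)
  }
  if (cfg$noise_sd_growth > 0) {
    gnoise[, 2:D] <- gnoise[, 2:D] +
      stats::rnorm(n_plots * (D - 1), sd = cfg$noise_sd_growth)
  }
  realized <- y0 + t(apply(growth + gnoise, 1, cumsum))

  # per-day multiplicative measurement bias + observation noise
  bias <- stats::runif(D, cfg$bias_range[1], cfg$bias_range[2])
  names(bias) <- as.character(days)
  obs <- realized * matrix(bias, n_plots, D, byrow = TRUE)
  if (cfg$obs_noise_sd > 0) {
    eps <- matrix(stats::rnorm(n_plots * D, sd = cfg$obs_noise_sd),
                  n_plots, D)
    obs <- if (cfg$obs_noise_type == "relative") obs * (1 + eps) else
      obs + eps
  }

  phenotypes <- data.frame(
    plot_id = rep(design$plot_id, D),
    day = rep(days, each = n_plots),
    trait = cfg$trait,
    value = as.vector(obs),
    stringsAsFactors = FALSE
  )

  # manual ground truth: evenly spaced plots per environment, measured daily
  manual <- NULL
  for (env in envs) {
    idx <- which(design$environment == env)
    pick <- idx[unique(round(seq(1, length(idx),
                                 length.out = min(cfg$n_manual_plots,
                                                  length(idx)))))]
    manual <- rbind(manual, data.frame(
      plot_id = rep(design$plot_id[pick], D),
      day = rep(days, each = length(pick)),
      value = as.vector(realized[pick, ]),
      stringsAsFactors = FALSE
    ))
  }

  dimnames(growth) <- dimnames(trajectory) <- dimnames(realized) <-
    list(design$plot_id, as.character(days))
  truth$growth <- growth
  truth$trajectory <- trajectory
  truth$realized <- realized
  truth$bias <- bias
  truth$y0 <- stats::setNames(y0, design$plot_id)

  structure(list(config = cfg, design = design, phenotypes = phenotypes,
                 manual = manual, moisture_obs = moisture_obs,
                 moisture_true = moisture_true, genotypes = genotypes,
                 kernel = kernel, truth = truth),
            class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat("Synthetic field trial:", nrow(x$design), "plots,",
      x$config$n_genotypes, "genotypes,",
      length(sim_environments(x$config)), "environments,",
      length(x$config$days), "days\n")
  invisible(x)
}
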