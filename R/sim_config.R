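#' Configuration for a synthetic field trial
#'
#' Bundles every knob of the synthetic field-trial generator into a validated
#' object. Defaults describe a drought field trial of the kind the package
#' targets: ~200 inbred accessions grown in row/plot grids under four watering
#' regimes (well-watered `WW`, non-watered `W0`, and 5-day / 10-day on-off
#' cycles `W5` / `W10`), with daily canopy measurements from remote sensing
#' that carry a multiplicative per-day bias, and soil moisture measured on an
#' alternating subset of plots.
#'
#' @param trait `"canopy_height"` (cm; default) or `"canopy_area"` (m^2).
#'   The area preset rescales the trait-unit defaults (initial size,
#'   growth envelope, coefficient/noise SDs) to an area-like scale where
#'   plots start near zero relative to their final size, and drops the
#'   multiplicative flight bias (only height is bias-corrected against
#'   manual measurements).
#' @param n_genotypes Number of genotypes (inbred accessions). One plot per
#'   genotype per environment.
#' @param n_markers Number of biallelic SNP markers.
#' @param treatments Character vector of watering-pattern labels, a subset of
#'   `c("WW", "W0", "W5", "W10")`.
#' @param n_years Number of trial years; environments are all year x treatment
#'   combinations, labelled e.g. `"Y1-WW"`.
#' @param days Integer vector of observation days (days after sowing, DAS);
#'   must be consecutive and span at least 10 days.
#' @param Q_true Number of B-spline basis functions of the generating reaction
#'   norms.
#' @param h2_coef Heritability of the reaction-norm coefficients in `[0, 1]`:
#'   the fraction of coefficient deviation variance attributable to the
#'   genomic kernel (the rest is a day-smooth deviation common to all
#'   genotypes).
#' @param coef_sd Standard deviation of reaction-norm coefficient deviations
#'   (trait units per day).
#' @param day_lengthscale Length scale (days) of the squared-exponential
#'   kernel generating smooth day-to-day coefficient variation.
#' @param noise_sd_growth SD of additive Gaussian noise on daily growth
#'   (trait units per day).
#' @param plot_effect_sd SD of a persistent per-plot growth-rate effect
#'   (trait units per day), emulating non-genetic soil/micro-environment
#'   heterogeneity among plots; constant within a plot over the season.
#' @param bias_range Length-2 numeric interval from which the per-day
#'   multiplicative measurement bias is drawn uniformly; `c(1, 1)` disables
#'   bias.
#' @param obs_noise_sd SD of measurement noise on the observed canopy
#'   series: trait units when `obs_noise_type = "additive"`, a fraction of
#'   the current value when `"relative"`.
#' @param obs_noise_type `"additive"` (height: instrument error independent
#'   of plant size) or `"relative"` (area: segmentation error scales with
#'   canopy size; the area preset's default, at 5%).
#' @param maf_range Length-2 interval of per-marker ancestral minor allele
#'   frequencies (uniform spectrum).
#' @param n_subpops Number of subpopulations of the accession panel; marker
#'   frequencies diverge among them (Balding-Nichols model), giving the
#'   within-subpopulation relatedness a diversity panel shows.
#' @param fst Wright's fixation index controlling subpopulation divergence
#'   (0 gives an unstructured panel).
#' @param h2_init Heritability (on the log scale) of the initial plot size.
#' @param sm_setpoint,sm_floor Well-watered set-point and dry floor of soil
#'   moisture (% v/v).
#' @param sm_noise_sd SD of the AR(1) day-to-day soil-moisture noise (% v/v);
#'   0 gives the deterministic pattern.
#' @param sm_spatial_sd SD of the smooth spatial (along-row) soil-moisture
#'   effect (% v/v).
#' @param plots_per_row Number of plots per irrigation row.
#' @param init_size_meanlog,init_size_sdlog Log-normal parameters of the
#'   initial plot size on the first observation day (trait units).
#' @param growth_peak_day,growth_peak_width,growth_max Day of peak growth
#'   rate, Gaussian width (days) of the seasonal growth envelope, and maximum
#'   mean daily growth at high moisture (trait units/day).
#' @param resp_range Length-2 interval: relative mean response at the lowest
#'   and highest moisture basis function. Equal values give a flat reaction
#'   norm (no moisture effect).
#' @param flat_norms Logical; if `TRUE`, coefficient deviations are shared
#'   across basis functions so every genotype's reaction norm is flat in
#'   moisture whenever `resp_range` is constant.
#' @param response_classes Either 0 (off) or 3: plant three discrete
#'   low-moisture response classes (low/mid/high) by offsetting the first
#'   basis coefficient by `-class_delta`, 0, `+class_delta`.
#' @param class_delta Offset (trait units/day) separating adjacent planted
#'   response classes.
#' @param moisture_groups Number of alternating measurement groups for soil
#'   moisture (plots within a group are measured every `moisture_groups`-th
#'   day).
#' @param n_manual_plots Number of plots per environment with manual height
#'   ground truth (measured daily).
#' @param basis_support Length-2 numeric support of the generating moisture
#'   basis (% v/v).
#' @param seed Integer seed; all generator randomness flows from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_genotypes = 10, n_markers = 50, days = 15:30)
#' cfg$treatments
sim_config <- function(trait = c("canopy_height", "canopy_area"),
                       n_genotypes = 40,
                       n_markers = 500,
                       treatments = c("WW", "W0", "W5", "W10"),
                       n_years = 1,
                       days = 15:64,
                       Q_true = 3,
                       h2_coef = 0.7,
                       coef_sd = 0.35,
                       day_lengthscale = 10,
                       noise_sd_growth = 0.25,
                       plot_effect_sd = 0.15,
                       bias_range = c(0.9, 1.1),
                       obs_noise_sd = 1.0,
                       obs_noise_type = c("additive", "relative"),
                       maf_range = c(0.025, 0.5),
                       n_subpops = 8,
                       fst = 0.3,
                       sm_setpoint = 6,
                       sm_floor = 2,
                       sm_noise_sd = 0.3,
                       sm_spatial_sd = 0.3,
                       plots_per_row = 20,
                       init_size_meanlog = log(8),
                       init_size_sdlog = 0.3,
                       h2_init = 0.8,
                       growth_peak_day = 40,
                       growth_peak_width = 18,
                       growth_max = 1.8,
                       resp_range = c(0.25, 1),
                       flat_norms = FALSE,
                       response_classes = 0,
                       class_delta = 1.2,
                       moisture_groups = 2,
                       n_manual_plots = 8,
                       basis_support = c(1.5, 8),
                       seed = 1L) {
  trait <- match.arg(trait)
  if (trait == "canopy_area") {
    # area-like scale: plots start as small seedling canopies (~0.04 m^2)
    # and reach ~1.5-2 m^2; trait-unit defaults shrink accordingly (1/30),
    # and no multiplicative flight bias applies (area is not height-derived)
    k <- 1 / 30
    if (missing(init_size_meanlog)) init_size_meanlog <- log(0.04)
    if (missing(growth_max)) growth_max <- growth_max * k
    if (missing(coef_sd)) coef_sd <- coef_sd * k
    if (missing(noise_sd_growth)) noise_sd_growth <- noise_sd_growth * k
    if (missing(plot_effect_sd)) plot_effect_sd <- plot_effect_sd * k
    if (missing(obs_noise_sd)) obs_noise_sd <- 0.05
    if (missing(obs_noise_type)) obs_noise_type <- "relative"
    if (missing(class_delta)) class_delta <- class_delta * k
    if (missing(bias_range)) bias_range <- c(1, 1)
  }
  obs_noise_type <- match.arg(obs_noise_type)
  cfg <- list(
    trait = trait,
    n_genotypes = as.integer(n_genotypes), n_markers = as.integer(n_markers),
    treatments = as.character(treatments), n_years = as.integer(n_years),
    days = as.integer(days), Q_true = as.integer(Q_true),
    h2_coef = h2_coef, coef_sd = coef_sd, day_lengthscale = day_lengthscale,
    noise_sd_growth = noise_sd_growth, plot_effect_sd = plot_effect_sd,
    bias_range = bias_range,
    obs_noise_sd = obs_noise_sd, obs_noise_type = obs_noise_type,
    maf_range = maf_range,
    n_subpops = as.integer(n_subpops), fst = fst, h2_init = h2_init,
    sm_setpoint = sm_setpoint, sm_floor = sm_floor,
    sm_noise_sd = sm_noise_sd, sm_spatial_sd = sm_spatial_sd,
    plots_per_row = as.integer(plots_per_row),
    init_size_meanlog = init_size_meanlog, init_size_sdlog = init_size_sdlog,
    growth_peak_day = growth_peak_day, growth_peak_width = growth_peak_width,
    growth_max = growth_max, resp_range = resp_range,
    flat_norms = isTRUE(flat_norms),
    response_classes = as.integer(response_classes), class_delta = class_delta,
    moisture_groups = as.integer(moisture_groups),
    n_manual_plots = as.integer(n_manual_plots),
    basis_support = basis_support,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genotypes < 2L) {
    stop("sim_config: n_genotypes must be >= 2", call. = FALSE)
  }
  if (cfg$n_markers < 1L) {
    stop("sim_config: n_markers must be >= 1", call. = FALSE)
  }
  bad <- setdiff(cfg$treatments, c("WW", "W0", "W5", "W10"))
  if (length(bad) > 0L) {
    stop("sim_config: unknown treatment label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(cfg$days) < 2L || diff(range(cfg$days)) < 10L) {
    stop("sim_config: days must span at least 10 days", call. = FALSE)
  }
  if (any(diff(cfg$days) != 1L)) {
    stop("sim_config: days must be consecutive integers", call. = FALSE)
  }
  if (cfg$h2_coef < 0 || cfg$h2_coef > 1) {
    stop("sim_config: h2_coef must lie in [0, 1]", call. = FALSE)
  }
  sds <- c(cfg$coef_sd, cfg$noise_sd_growth, cfg$plot_effect_sd,
           cfg$obs_noise_sd, cfg$sm_noise_sd, cfg$sm_spatial_sd)
  if (any(sds < 0)) stop("sim_config: all SDs must be >= 0", call. = FALSE)
  if (length(cfg$bias_range) != 2L || any(cfg$bias_range <= 0)) {
    stop("sim_config: bias_range must be a positive length-2 interval",
         call. = FALSE)
  }
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("sim_config: maf_range must satisfy 0 < lo <= hi <= 0.5",
         call. = FALSE)
  }
  if (!cfg$response_classes %in% c(0L, 3L)) {
    stop("sim_config: response_classes must be 0 or 3", call. = FALSE)
  }
  if (cfg$Q_true < 2L) stop("sim_config: Q_true must be >= 2", call. = FALSE)
  if (cfg$fst < 0 || cfg$fst >= 1) {
    stop("sim_config: fst must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$h2_init < 0 || cfg$h2_init > 1) {
    stop("sim_config: h2_init must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_subpops < 1L || cfg$n_subpops > cfg$n_genotypes) {
    stop("sim_config: n_subpops must be in 1..n_genotypes", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic field-trial configuration\n")
  cat(sprintf("  genotypes: %d, markers: %d\n", x$n_genotypes, x$n_markers))
  cat(sprintf("  environments: %s x %d year(s)\n",
              paste(x$treatments, collapse = "/"), x$n_years))
  cat(sprintf("  days: %d..%d (DAS), Q_true = %d, h2_coef = %.2f\n",
              min(x$days), max(x$days), x$Q_true, x$h2_coef))
  cat(sprintf("  growth noise SD = %g, bias in [%g, %g], seed = %d\n",
              x$noise_sd_growth, x$bias_range[1], x$bias_range[2], x$seed))
  invisible(x)
}

#' Environment labels of a configuration
#'
#' All year x treatment combinations, labelled e.g. `"Y1-WW"`.
#'
#' @param cfg A [sim_config()].
#' @return Character vector of environment labels.
#' @export
sim_environments <- function(cfg) {
  as.vector(outer(paste0("Y", seq_len(cfg$n_years)), cfg$treatments,
                  paste, sep = "-"))
}
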