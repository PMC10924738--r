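# Shared fixtures, all generated in code.

# A small, fast trial configuration for unit tests.
tiny_config <- function(...) {
  defaults <- list(n_genotypes = 8, n_markers = 80, days = 15:34,
                   treatments = c("WW", "W0"), n_subpops = 2,
                   plots_per_row = 4, n_manual_plots = 4, seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Noise-free variant: deterministic biology, unit bias, exact observation.
noise_free_config <- function(...) {
  quiet <- list(noise_sd_growth = 0, plot_effect_sd = 0, obs_noise_sd = 0,
                bias_range = c(1, 1))
  do.call(tiny_config, utils::modifyList(quiet, list(...)))
}

# Hand-rolled weighted through-origin regression (bias oracle).
origin_slope <- function(x, y) sum(x * y) / sum(x^2)

# Brute-force weighted ridge normal equations (reaction-norm oracle),
# written with explicit loops, independent of the package's solver.
brute_force_wls <- function(Phi, y, w, ridge = 0) {
  Q <- ncol(Phi)
  A <- matrix(0, Q, Q)
  b <- numeric(Q)
  for (i in seq_along(y)) {
    for (q1 in seq_len(Q)) {
      b[q1] <- b[q1] + w[i] * Phi[i, q1] * y[i]
      for (q2 in seq_len(Q)) {
        A[q1, q2] <- A[q1, q2] + w[i] * Phi[i, q1] * Phi[i, q2]
      }
    }
  }
  solve(A + diag(ridge, Q), b)
}

# Random moisture measurement fixture spanning a few rows.
random_measurements <- function(n = 10, n_rows = 2, seed = 1) {
  set.seed(seed)
  data.frame(row = sample(paste0("R", seq_len(n_rows)), n, replace = TRUE),
             position = sample(1:6, n, replace = TRUE),
             day = sample(15:25, n, replace = TRUE),
             value = runif(n, 2, 7))
}
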