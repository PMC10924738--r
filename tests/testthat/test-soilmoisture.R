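test_that("interpolation is a convex combination of same-row measurements", {
  meas <- data.frame(row = "R1", position = 2, day = 18, value = 4.2)
  tgt <- data.frame(row = "R1", position = 5, day = 30)
  expect_equal(interpolate_moisture(meas, 1, 1, tgt), 4.2)

  m <- random_measurements(n = 30, n_rows = 3, seed = 2)
  targets <- expand.grid(row = unique(m$row), position = 1:6, day = 15:25,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  v <- interpolate_moisture(m, 5, 5, targets)
  for (r in unique(m$row)) {
    rng <- range(m$value[m$row == r])
    vi <- v[targets$row == r]
    expect_true(all(vi >= rng[1] - 1e-12 & vi <= rng[2] + 1e-12))
  }
})

test_that("interpolation matches a hand-computed weighted mean", {
  meas <- data.frame(row = "R1", position = c(1, 2, 4), day = c(20, 21, 20),
                     value = c(3, 5, 6))
  tgt <- data.frame(row = "R1", position = 2, day = 20)
  w <- exp(-(c(1, 2, 4) - 2)^2 / 1) * exp(-(c(20, 21, 20) - 20)^2 / 1)
  expect_equal(interpolate_moisture(meas, 1, 1, tgt),
               sum(w * meas$value) / sum(w), tolerance = 1e-12)

  # with tiny bandwidths the coincident measurement dominates
  expect_equal(interpolate_moisture(meas, 1e-6, 1e-6,
                                    data.frame(row = "R1", position = 2,
                                               day = 21)), 5)
  # excluding the coincident point removes it from the average
  v <- interpolate_moisture(meas, 1, 1,
                            data.frame(row = "R1", position = 2, day = 21),
                            exclude_self = TRUE)
  w2 <- exp(-(c(1, 4) - 2)^2 / 1) * exp(-(c(20, 20) - 21)^2 / 1)
  expect_equal(v, sum(w2 * meas$value[c(1, 3)]) / sum(w2), tolerance = 1e-12)

  expect_error(interpolate_moisture(meas, 1, 1,
                                    data.frame(row = "R9", position = 1,
                                               day = 20)),
               "no soil-moisture measurements")
})

test_that("interpolation is invariant to measurement record order", {
  m <- random_measurements(n = 20, n_rows = 2, seed = 3)
  targets <- data.frame(row = "R1", position = c(1, 3, 5), day = c(16, 20, 24))
  v1 <- interpolate_moisture(m, 2, 7, targets)
  set.seed(9)
  v2 <- interpolate_moisture(m[sample(nrow(m)), ], 2, 7, targets)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("LOOCV bandwidth selection equals the exhaustive-search oracle", {
  m <- random_measurements(n = 10, n_rows = 2, seed = 4)
  sel <- select_bandwidths(m)
  grid <- bandwidth_grid()
  expect_length(grid, 17)
  expect_equal(grid[1], 0.1)
  expect_equal(grid[17], 1000)

  # brute-force double loop with per-point exclusion
  oracle <- expand.grid(lambda_s = grid, lambda_t = grid)
  oracle$rmse <- NA_real_
  for (k in seq_len(nrow(oracle))) {
    errs <- numeric(0)
    for (i in seq_len(nrow(m))) {
      pred <- tryCatch(
        interpolate_moisture(m[-i, ], oracle$lambda_s[k], oracle$lambda_t[k],
                             m[i, c("row", "position", "day")]),
        error = function(e) NA_real_)
      # replicate exclude_self semantics: drop coincident duplicates too
      dup <- which(m$row == m$row[i] & m$position == m$position[i] &
                     m$day == m$day[i])
      if (length(dup) > 1L) {
        pred <- tryCatch(
          interpolate_moisture(m[-dup, ], oracle$lambda_s[k],
                               oracle$lambda_t[k],
                               m[i, c("row", "position", "day")]),
          error = function(e) NA_real_)
      }
      errs <- c(errs, pred - m$value[i])
    }
    oracle$rmse[k] <- sqrt(mean(errs^2, na.rm = TRUE))
  }
  got <- sel$rmse_table
  key <- paste(signif(got$lambda_s, 10), signif(got$lambda_t, 10))
  okey <- paste(signif(oracle$lambda_s, 10), signif(oracle$lambda_t, 10))
  expect_equal(got$rmse, oracle$rmse[match(key, okey)], tolerance = 1e-10)

  # selected pair attains the minimum with the lexicographic tie-break
  ok <- !is.na(oracle$rmse)
  best <- which(ok)[order(oracle$rmse[ok], oracle$lambda_s[ok],
                          oracle$lambda_t[ok])][1]
  expect_equal(sel$lambda_s, oracle$lambda_s[best])
  expect_equal(sel$lambda_t, oracle$lambda_t[best])
  expect_equal(sel$rmse, min(got$rmse, na.rm = TRUE))
})

test_that("a single-pair candidate grid is returned as-is", {
  m <- random_measurements(n = 8, n_rows = 1, seed = 5)
  sel <- select_bandwidths(m, candidates_s = 3, candidates_t = 12)
  expect_equal(sel$lambda_s, 3)
  expect_equal(sel$lambda_t, 12)
})

test_that("densify covers the full plot x day grid and honours shape", {
  cfg <- tiny_config()
  trial <- simulate_trial(cfg)
  dense <- densify_moisture(trial$moisture_obs, 5, 5, trial$design,
                            cfg$days)
  expect_equal(nrow(dense), nrow(trial$design) * length(cfg$days))
  expect_false(anyNA(dense$value))

  # missing row: error unless filling is allowed
  short <- trial$moisture_obs[trial$moisture_obs$row !=
                                trial$design$row[1], ]
  expect_error(densify_moisture(short, 5, 5, trial$design, cfg$days),
               "without any soil-moisture measurement")
  expect_warning(
    filled <- densify_moisture(short, 5, 5, trial$design, cfg$days,
                               fill_missing_rows = TRUE),
    "adjacent rows")
  expect_false(anyNA(filled$value))
})

test_that("densified cyclic treatment shows its watering period", {
  cfg <- tiny_config(treatments = "W5", days = 15:54, n_genotypes = 8)
  trial <- simulate_trial(cfg)
  sel <- list(lambda_s = 10, lambda_t = 0.5)
  dense <- densify_moisture(trial$moisture_obs, sel$lambda_s, sel$lambda_t,
                            trial$design, cfg$days)
  # lag-10 autocorrelation (full period) beats lag-5 (anti-phase)
  one <- dense$value[dense$plot_id == dense$plot_id[1]]
  ac <- acf(one, lag.max = 10, plot = FALSE)$acf
  expect_gt(ac[11], ac[6])
})
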