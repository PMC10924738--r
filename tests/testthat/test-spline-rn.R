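simple_kernel <- function(ids, K = NULL) {
  if (is.null(K)) K <- diag(length(ids))
  dimnames(K) <- list(ids, ids)
  K
}

test_that("basis construction yields Q functions that sum to one", {
  s <- runif(100, 2, 8)
  for (Q in c(3, 4, 5)) {
    b <- build_basis(s, Q = Q)
    expect_equal(b$Q, Q)
    grid <- seq(min(s), max(s), length.out = 100)
    B <- eval_basis(b, grid)
    expect_equal(ncol(B), Q)
    expect_true(all(B >= -1e-12))
    expect_equal(rowSums(B), rep(1, 100), tolerance = 1e-10)
  }
  # Q = 4 cubic has no interior knots; Q = 5 has one
  expect_length(build_basis(s, 4)$knots, 0)
  expect_length(build_basis(s, 5)$knots, 1)
  expect_equal(build_basis(s, 3)$degree, 2)
  expect_error(build_basis(rep(5, 10), 3), "degenerate")
})

test_that("evaluation outside the support clamps to the boundary", {
  b <- build_basis(runif(50, 2, 8), Q = 4)
  lo <- b$support[1]
  B <- eval_basis(b, c(lo - 1, lo, 10))
  expect_equal(B[1, ], B[2, ])
  expect_identical(attr(B, "extrapolated"), c(TRUE, FALSE, TRUE))
})

test_that("fit_target equals the brute-force weighted normal equations", {
  set.seed(20)
  for (Q in c(3, 4, 5)) {
    ids <- c("A", "B", "C")
    K <- simple_kernel(ids, matrix(c(1, .6, .2, .6, 1, .4, .2, .4, 1), 3))
    rec <- data.frame(genotype_id = sample(ids, 30, TRUE),
                      day = sample(15:40, 30, TRUE),
                      dy = rnorm(30), s_prev = runif(30, 2, 7))
    basis <- build_basis(rec$s_prev, Q = Q)
    cf <- fit_target(rec, K, 30, "B", 25, basis, ridge = 0)
    Phi <- eval_basis(basis, rec$s_prev)
    w <- pmax(K["B", rec$genotype_id], 0) * exp(-(25 - rec$day)^2 / 30)
    expect_equal(as.numeric(cf), as.numeric(brute_force_wls(Phi, rec$dy, w)),
                 tolerance = 1e-8)
  }
})

test_that("flat-weight fits reduce to ordinary least squares", {
  set.seed(21)
  ids <- c("A", "B")
  K <- simple_kernel(ids, matrix(1, 2, 2))  # all-ones kernel
  rec <- data.frame(genotype_id = rep(ids, each = 15),
                    day = rep(20, 30),
                    s_prev = runif(30, 2, 7))
  rec$dy <- 1.5 + 0.4 * rec$s_prev  # exactly linear in s
  basis <- build_basis(rec$s_prev, Q = 2)  # linear B-spline basis
  cf <- fit_target(rec, K, 1e9, "A", 20, basis, ridge = 0)
  pred <- as.numeric(eval_basis(basis, rec$s_prev) %*% cf)
  expect_equal(pred, rec$dy, tolerance = 1e-9)

  # single record, constant basis: coefficient equals that record's growth
  one <- rec[1, ]
  b1 <- build_basis(c(one$s_prev, one$s_prev + 1), Q = 1)
  cf1 <- fit_target(one, simple_kernel("A", matrix(1, 1, 1)), 10, "A",
                    one$day, b1, ridge = 0)
  expect_equal(as.numeric(cf1), one$dy, tolerance = 1e-10)
})

test_that("fit_all agrees with fit_target for every target", {
  set.seed(22)
  ids <- c("A", "B", "C", "D")
  K <- crossprod(matrix(rnorm(16), 4)) / 4 + diag(4) * 0.5
  K <- simple_kernel(ids, K)
  rec <- data.frame(genotype_id = sample(ids, 60, TRUE),
                    day = sample(15:40, 60, TRUE),
                    dy = rnorm(60), s_prev = runif(60, 2, 7))
  basis <- build_basis(rec$s_prev, Q = 3)
  targets <- expand.grid(genotype_id = ids, day = c(18, 27, 36),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fit <- fit_all(rec, K, 30, basis, ridge = 1e-4, targets = targets)
  for (r in seq_len(nrow(targets))) {
    cf <- fit_target(rec, K, 30, targets$genotype_id[r], targets$day[r],
                     basis, ridge = 1e-4)
    expect_equal(fit$coefs[r, ], as.numeric(cf), tolerance = 1e-8)
  }
})

test_that("targets with identical weight profiles share coefficients", {
  set.seed(23)
  ids <- c("A", "B", "C")
  # A and B are kernel-identical rows
  K <- matrix(c(1, 1, .3, 1, 1, .3, .3, .3, 1), 3,
              dimnames = list(ids, ids))
  rec <- data.frame(genotype_id = sample(ids, 40, TRUE),
                    day = sample(15:30, 40, TRUE),
                    dy = rnorm(40), s_prev = runif(40, 2, 7))
  basis <- build_basis(rec$s_prev, Q = 3)
  fit <- fit_all(rec, K, 20, basis,
                 targets = data.frame(genotype_id = c("A", "B"), day = 22))
  expect_equal(fit$coefs[1, ], fit$coefs[2, ], tolerance = 1e-10)

  # uniform weights: all targets share the pooled OLS solution
  Kones <- matrix(1, 3, 3, dimnames = list(ids, ids))
  fit2 <- fit_all(rec, Kones, 1e12, basis, ridge = 0,
                  targets = expand.grid(genotype_id = ids, day = c(16, 28),
                                        KEEP.OUT.ATTRS = FALSE,
                                        stringsAsFactors = FALSE))
  for (r in 2:nrow(fit2$targets)) {
    expect_equal(fit2$coefs[r, ], fit2$coefs[1, ], tolerance = 1e-8)
  }
})

test_that("reaction-norm evaluation is the basis expansion of the coefficients", {
  set.seed(24)
  ids <- "A"
  rec <- data.frame(genotype_id = "A", day = sample(15:30, 20, TRUE),
                    dy = rnorm(20), s_prev = runif(20, 2, 7))
  basis <- build_basis(rec$s_prev, Q = 4)
  fit <- fit_all(rec, simple_kernel(ids), 20, basis,
                 targets = data.frame(genotype_id = "A", day = 20))
  s <- seq(2.5, 6.5, length.out = 9)
  expect_equal(as.numeric(evaluate_rn(fit, "A", 20, s)),
               as.numeric(eval_basis(basis, s) %*% fit$coefs[1, ]),
               tolerance = 1e-12)

  # unit coefficient vector returns the matching basis function
  fit$coefs[1, ] <- c(0, 1, 0, 0)
  expect_equal(as.numeric(evaluate_rn(fit, "A", 20, s)),
               eval_basis(basis, s)[, 2], tolerance = 1e-12)
  fit$coefs[1, ] <- 0
  expect_equal(as.numeric(evaluate_rn(fit, "A", 20, s)), rep(0, 9))
  expect_error(evaluate_rn(fit, "Z", 20, s), "no fitted target")
})

test_that("weights grow with lambda0 and localize as it vanishes", {
  days <- 15:40
  w1 <- exp(-(25 - days)^2 / 10)
  w2 <- exp(-(25 - days)^2 / 70)
  expect_true(all(w2 >= w1))
  w0 <- exp(-(25 - days)^2 / 1e-9)
  expect_equal(sum(w0 > 1e-12), 1L)  # only the same-day record survives
})

test_that("coefficients scale linearly with the response", {
  set.seed(25)
  ids <- c("A", "B")
  K <- simple_kernel(ids, matrix(c(1, .5, .5, 1), 2))
  rec <- data.frame(genotype_id = sample(ids, 25, TRUE),
                    day = sample(15:30, 25, TRUE),
                    dy = rnorm(25), s_prev = runif(25, 2, 7))
  basis <- build_basis(rec$s_prev, Q = 3)
  cf <- fit_target(rec, K, 30, "A", 20, basis, ridge = 0)
  rec_k <- transform(rec, dy = dy * 6)
  cf_k <- fit_target(rec_k, K, 30, "A", 20, basis, ridge = 0)
  expect_equal(as.numeric(cf_k), 6 * as.numeric(cf), tolerance = 1e-9)
})

test_that("curve extraction masks support and groups genotypes stably", {
  set.seed(26)
  ids <- c("A", "B", "C")
  rec <- data.frame(genotype_id = sample(ids, 60, TRUE),
                    day = sample(15:30, 60, TRUE),
                    dy = rnorm(60), s_prev = runif(60, 2, 7))
  basis <- build_basis(rec$s_prev, Q = 3)
  fit <- fit_all(rec, simple_kernel(ids), 20, basis)
  moisture <- data.frame(day = c(18, 19, 20, 21, 22), value = c(3, 4, 5, 4, 3))
  ex <- extract_rn_curves(fit, 20, s_grid = seq(2, 7, 0.5),
                          moisture = moisture,
                          probe = list(day = 20, s = 3))
  # mask covers exactly the observed window's moisture range
  c20 <- ex$curves[ex$curves$genotype_id == "A", ]
  expect_identical(c20$in_support, c20$s >= 3 & c20$s <= 5)
  expect_setequal(as.character(ex$groups$group), c("low", "mid", "high"))

  # identical genotypes: degenerate values, stable id-ordered tie-break
  fit$coefs[] <- 1
  ex2 <- extract_rn_curves(fit, 20, probe = list(day = 20, s = 3))
  expect_equal(as.character(ex2$groups$group[order(ex2$groups$genotype_id)]),
               c("low", "mid", "high"))
})

test_that("recovery degrades monotonically with growth noise", {
  sds <- c(0, 0.5, 1.5)
  acc <- vapply(sds, function(ns) {
    cfg <- noise_free_config(noise_sd_growth = ns, n_genotypes = 8,
                             days = 15:39, seed = 31L)
    trial <- simulate_trial(cfg)
    rec <- rn_records(trial$phenotypes[, c("plot_id", "day", "value")],
                      trial$moisture_true, trial$design)
    basis <- build_basis(rec$s_prev, Q = 3)
    fit <- fit_all(rec, clip_negative(trial$kernel), 10, basis)
    sg <- seq(2.5, 5.5, length.out = 15)
    Phi_t <- eval_basis(trial$truth$basis, sg)
    Phi_f <- eval_basis(basis, sg)
    errs <- vapply(seq_len(nrow(fit$targets)), function(r) {
      g <- fit$targets$genotype_id[r]
      d <- as.character(fit$targets$day[r])
      tv <- as.numeric(Phi_t %*% trial$truth$coefs[, g, d])
      fv <- as.numeric(Phi_f %*% fit$coefs[r, ])
      sqrt(mean((fv - tv)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
})
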