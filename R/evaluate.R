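#' Build a cross-validation plan
#'
#' Three schemes over genotypes and environments (an environment is one
#' treatment x year combination):
#' * `CV-G` -- k-fold partition of genotypes, repeated; test = one genotype
#'   fold in every environment, training = the other folds everywhere.
#' * `CV-E` -- leave-one-environment-out; no genotype split.
#' * `CV-GE` -- every (genotype fold, environment) pair; training contains
#'   only other folds in other environments, so neither the test genotypes
#'   nor the test environment are seen during training.
#'
#' @param genotypes Character vector of genotype ids.
#' @param environments Character vector of environment labels.
#' @param scheme One of `"CV-G"`, `"CV-E"`, `"CV-GE"`.
#' @param k_folds Number of genotype folds (default 5).
#' @param repeats Number of random re-partitions (default 10; ignored for
#'   CV-E).
#' @param seed Integer seed for the partitions.
#' @return Object of class `cv_plan`: `scheme`, `folds` (list per repeat of
#'   integer fold assignments named by genotype), `environments`, and
#'   `cells` (data frame enumerating test cells: `rep`, `fold`,
#'   `environment`; `NA` where a dimension is not split).
#' @export
make_cv_plan <- function(genotypes, environments, scheme, k_folds = 5,
                         repeats = 10, seed = 1L) {
  scheme <- match.arg(scheme, c("CV-G", "CV-E", "CV-GE"))
  genotypes <- as.character(genotypes)
  environments <- as.character(environments)
  if (k_folds > length(genotypes)) {
    stop("k_folds exceeds the number of genotypes", call. = FALSE)
  }
  folds <- NULL
  if (scheme %in% c("CV-G", "CV-GE")) {
    set.seed(seed)
    folds <- lapply(seq_len(repeats), function(r) {
      f <- rep_len(seq_len(k_folds), length(genotypes))
      stats::setNames(sample(f), genotypes)
    })
  }
  cells <- switch(scheme,
    "CV-G" = expand.grid(rep = seq_len(repeats), fold = seq_len(k_folds),
                         environment = NA_character_,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    "CV-E" = data.frame(rep = 1L, fold = NA_integer_,
                        environment = environments,
                        stringsAsFactors = FALSE),
    "CV-GE" = expand.grid(rep = seq_len(repeats), fold = seq_len(k_folds),
                          environment = environments,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  structure(list(scheme = scheme, folds = folds, k_folds = k_folds,
                 repeats = if (scheme == "CV-E") 1L else repeats,
                 genotypes = genotypes, environments = environments,
                 cells = cells, seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("CV plan: %s, %d genotypes, %d environments, %d test cell(s)\n",
              x$scheme, length(x$genotypes), length(x$environments),
              nrow(x$cells)))
  invisible(x)
}

#' Training and test keys of one CV cell
#'
#' Resolves a row of `plan$cells` into disjoint training and test
#' (genotype, environment) key sets, asserting the scheme's integrity:
#' training and test never share a key, and under CV-GE they share neither a
#' genotype nor an environment.
#'
#' @param plan A [make_cv_plan()].
#' @param cell Row index into `plan$cells`.
#' @return List with `test` and `train` data frames (`genotype_id`,
#'   `environment`).
#' @export
cv_cell_split <- function(plan, cell) {
  row <- plan$cells[cell, ]
  all_keys <- expand.grid(genotype_id = plan$genotypes,
                          environment = plan$environments,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (plan$scheme == "CV-E") {
    test_g <- plan$genotypes
    test_e <- row$environment
    is_test <- all_keys$environment == test_e
    is_train <- !is_test
  } else {
    assign <- plan$folds[[row$rep]]
    test_g <- names(assign)[assign == row$fold]
    if (plan$scheme == "CV-G") {
      is_test <- all_keys$genotype_id %in% test_g
      is_train <- !is_test
    } else {
      is_test <- all_keys$genotype_id %in% test_g &
        all_keys$environment == row$environment
      is_train <- !(all_keys$genotype_id %in% test_g) &
        all_keys$environment != row$environment
    }
  }
  test <- all_keys[is_test, ]
  train <- all_keys[is_train, ]
  # integrity assertions (cheap, always on)
  key <- function(df) paste(df$genotype_id, df$environment)
  stopifnot(length(intersect(key(test), key(train))) == 0L)
  if (plan$scheme == "CV-GE") {
    stopifnot(length(intersect(test$genotype_id, train$genotype_id)) == 0L,
              length(intersect(test$environment, train$environment)) == 0L)
  }
  list(test = test, train = train)
}

#' Sequential whole-season trajectory prediction
#'
#' Starting from a first-day prediction, iterates the daily model forward:
#' `y_d = y_{d-1} + SP_{i,d}(s_{i,d-1})` for the spline reaction-norm model,
#' or `y_d = RF(y_{d-1}, g_i, s_{i,d-1}, d)` for the random forest. Each
#' day's prediction feeds the next; no observed phenotype of the predicted
#' plots is consulted.
#'
#' @param model A [fit_all()] reaction-norm fit or a [train_rf()] model.
#' @param first_day Data frame `plot_id`, `value`: predicted (or known)
#'   phenotype on the first day.
#' @param moisture Dense moisture data frame `plot_id`, `day`, `value`
#'   covering every day in `days` for every plot.
#' @param design Data frame `plot_id`, `genotype_id`.
#' @param days Integer vector of days (the first entry is the
#'   first-observation day).
#' @param kernel Required for RF models: the [genomic_kernel] supplying
#'   `g_i` columns.
#' @return Data frame `plot_id`, `day`, `value` over all plots and days.
#' @export
predict_trajectory <- function(model, first_day, moisture, design, days,
                               kernel = NULL) {
  days <- sort(as.integer(days))
  plots <- first_day$plot_id
  geno <- design$genotype_id[match(plots, design$plot_id)]
  sm_key <- paste(moisture$plot_id, moisture$day)
  S <- matrix(NA_real_, length(plots), length(days))
  for (k in seq_along(days)) {
    S[, k] <- moisture$value[match(paste(plots, days[k]), sm_key)]
  }
  if (anyNA(S[, -ncol(S)])) {
    bad <- days[-length(days)][colSums(is.na(S[, -ncol(S), drop = FALSE])) >
                                 0]
    stop("missing soil moisture on day(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  Y <- matrix(NA_real_, length(plots), length(days))
  Y[, 1] <- first_day$value

  if (inherits(model, "reaction_norm_fit")) {
    tkey <- paste(model$targets$genotype_id, model$targets$day)
    for (k in 2:length(days)) {
      rows <- match(paste(geno, days[k]), tkey)
      if (anyNA(rows)) {
        stop("reaction-norm fit lacks target(s) for day ", days[k],
             call. = FALSE)
      }
      Phi <- eval_basis(model$basis, S[, k - 1])
      Y[, k] <- Y[, k - 1] + rowSums(Phi * model$coefs[rows, , drop = FALSE])
    }
  } else if (inherits(model, "rf_growth_model")) {
    if (is.null(kernel)) {
      stop("RF trajectory prediction needs the genomic kernel", call. = FALSE)
    }
    G <- kernel_columns(kernel, geno, model$train_genotypes)
    for (k in 2:length(days)) {
      nd <- data.frame(y_prev = Y[, k - 1], s_prev = S[, k - 1],
                       d = days[k])
      nd <- cbind(nd, G)
      Y[, k] <- predict_next(model, nd)
    }
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"),
         call. = FALSE)
  }
  data.frame(plot_id = rep(plots, length(days)),
             day = rep(days, each = length(plots)),
             value = as.vector(Y), stringsAsFactors = FALSE)
}

#' Score predictions against the interpolated truth
#'
#' Pearson correlation between predicted and reference values per
#' (environment, day) cell, computed across the plots of the cell. When a
#' `rep` column is present (repeated CV), per-repeat correlations are
#' averaged per cell. Cells with zero variance on either side are flagged
#' undefined (`NA`) and excluded from tallies downstream.
#'
#' @param predictions Data frame `plot_id`, `environment`, `day`, `value`,
#'   optionally `rep`.
#' @param reference Data frame `plot_id`, `day`, `value` (typically the
#'   smoothed observed series).
#' @param min_pairs Minimum paired values per cell (default 3).
#' @return Object of class `accuracy_report`: data frame `environment`,
#'   `day`, `r` (mean over repeats), `n_reps`, `n_pairs`.
#' @export
score_accuracy <- function(predictions, reference, min_pairs = 3L) {
  stopifnot(all(c("plot_id", "environment", "day", "value") %in%
                  names(predictions)))
  if (!"rep" %in% names(predictions)) predictions$rep <- 1L
  ref_key <- paste(reference$plot_id, reference$day)
  predictions$truth <- reference$value[
    match(paste(predictions$plot_id, predictions$day), ref_key)]
  if (all(is.na(predictions$truth))) {
    stop("no overlapping (plot, day) keys between predictions and reference",
         call. = FALSE)
  }
  cells <- split(predictions,
                 list(predictions$environment, predictions$day),
                 drop = TRUE)
  out <- lapply(cells, function(cc) {
    rs <- vapply(split(cc, cc$rep), function(one) {
      ok <- !is.na(one$truth) & !is.na(one$value)
      if (sum(ok) < min_pairs) return(NA_real_)
      if (stats::sd(one$value[ok]) == 0 || stats::sd(one$truth[ok]) == 0) {
        return(NA_real_)
      }
      stats::cor(one$value[ok], one$truth[ok])
    }, numeric(1))
    data.frame(environment = cc$environment[1], day = cc$day[1],
               r = if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE),
               n_reps = sum(!is.na(rs)),
               n_pairs = sum(!is.na(cc$truth)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$environment, out$day), ]
  rownames(out) <- NULL
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' Count accuracy wins of one model over another
#'
#' Compares two accuracy reports cell by cell (same environment x day grid)
#' and counts the cells where the first model's correlation strictly exceeds
#' the second's. Undefined cells (NA on either side) are excluded; ties are
#' counted separately.
#'
#' @param report_a,report_b [score_accuracy()] results on identical grids.
#' @return List with `wins`, `losses`, `ties`, `total` (compared cells),
#'   `excluded` (undefined cells), and `by_environment` (data frame).
#' @export
compare_models <- function(report_a, report_b) {
  key_a <- paste(report_a$environment, report_a$day)
  key_b <- paste(report_b$environment, report_b$day)
  if (!identical(sort(key_a), sort(key_b))) {
    stop("accuracy reports cover different (environment, day) grids",
         call. = FALSE)
  }
  rb <- report_b$r[match(key_a, key_b)]
  ra <- report_a$r
  ok <- !is.na(ra) & !is.na(rb)
  by_env <- stats::aggregate(
    data.frame(wins = as.integer(ra > rb & ok),
               losses = as.integer(ra < rb & ok),
               ties = as.integer(ra == rb & ok)),
    by = list(environment = report_a$environment), FUN = sum)
  list(wins = sum(ra > rb & ok), losses = sum(ra < rb & ok),
       ties = sum(ra == rb & ok), total = sum(ok),
       excluded = sum(!ok), by_environment = by_env)
}

#' Run a full cross-validated trajectory-prediction experiment
#'
#' For every cell of a CV plan: predicts first-day phenotypes with the
#' scheme's mixed model, fits the requested daily-growth models on the
#' training plots only, and rolls each model forward through the season.
#' Returns pooled predictions ready for [score_accuracy()].
#'
#' @param plan A [make_cv_plan()].
#' @param growth Data frame `plot_id`, `day`, `value` (smoothed phenotypes
#'   of all plots).
#' @param moisture Dense moisture data frame `plot_id`, `day`, `value`.
#' @param design Data frame `plot_id`, `genotype_id`, `environment`.
#' @param kernel A [genomic_kernel] covering all genotypes.
#' @param models Character subset of `c("SP", "RF", "GPG", "GP")`.
#' @param Q,lambda0 Spline-model hyperparameters (basis size and day-kernel
#'   bandwidth).
#' @param mtry,n_trees Random-forest hyperparameters.
#' @param ridge Ridge policy for the spline fit (`NULL` = automatic).
#' @param seed Seed for the random forest.
#' @return Data frame `model`, `rep`, `plot_id`, `genotype_id`,
#'   `environment`, `day`, `value`.
#' @export
run_cv <- function(plan, growth, moisture, design, kernel,
                   models = c("SP", "RF"), Q = 3, lambda0 = 10,
                   mtry = 5, n_trees = 500, ridge = NULL, seed = 1L) {
  models <- match.arg(models, c("SP", "RF", "GPG", "GP"), several.ok = TRUE)
  days <- sort(unique(growth$day))
  first_day <- days[1]
  kclip <- clip_negative(kernel)
  gkey <- paste(growth$plot_id, growth$day)
  first_vals <- growth$value[match(paste(design$plot_id, first_day), gkey)]
  names(first_vals) <- design$plot_id

  out <- list()
  for (cell in seq_len(nrow(plan$cells))) {
    split_keys <- cv_cell_split(plan, cell)
    dkey <- paste(design$genotype_id, design$environment)
    test_plots <- design[dkey %in% paste(split_keys$test$genotype_id,
                                         split_keys$test$environment), ]
    train_plots <- design[dkey %in% paste(split_keys$train$genotype_id,
                                          split_keys$train$environment), ]
    if (nrow(test_plots) == 0L || nrow(train_plots) == 0L) next

    train_growth <- growth[growth$plot_id %in% train_plots$plot_id, ]
    fd_train <- data.frame(genotype_id = train_plots$genotype_id,
                           environment = train_plots$environment,
                           value = first_vals[train_plots$plot_id],
                           stringsAsFactors = FALSE)
    fd_test <- predict_first_day(
      fd_train,
      data.frame(genotype_id = test_plots$genotype_id,
                 environment = test_plots$environment,
                 stringsAsFactors = FALSE),
      plan$scheme, kernel)
    fd_test$plot_id <- test_plots$plot_id
    first_pred <- fd_test[, c("plot_id", "value")]
    rep_id <- plan$cells$rep[cell]

    add_pred <- function(model_name, traj) {
      traj$model <- model_name
      traj$rep <- rep_id
      traj$genotype_id <- test_plots$genotype_id[
        match(traj$plot_id, test_plots$plot_id)]
      traj$environment <- test_plots$environment[
        match(traj$plot_id, test_plots$plot_id)]
      out[[length(out) + 1L]] <<- traj
    }

    if ("SP" %in% models) {
      records <- rn_records(train_growth, moisture, train_plots)
      basis <- build_basis(records$s_prev, Q = Q)
      targets <- expand.grid(genotype_id = unique(test_plots$genotype_id),
                             day = days[-1], KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)
      fit <- fit_all(records, kclip, lambda0, basis, ridge = ridge,
                     targets = targets)
      add_pred("SP", predict_trajectory(fit, first_pred, moisture,
                                        test_plots, days))
    }
    if ("RF" %in% models) {
      tab <- assemble_rf_table(train_growth, moisture, train_plots, kernel,
                               sort(unique(train_plots$genotype_id)))
      rf <- train_rf(tab, mtry = min(mtry, ncol(tab) - 3L),
                     n_trees = n_trees, seed = seed + cell)
      add_pred("RF", predict_trajectory(rf, first_pred, moisture,
                                        test_plots, days, kernel = kernel))
    }
    for (bm in intersect(models, c("GPG", "GP"))) {
      tr <- data.frame(plot_id = train_plots$plot_id,
                       genotype_id = train_plots$genotype_id,
                       environment = train_plots$environment,
                       stringsAsFactors = FALSE)
      tr <- merge(tr, growth, by = "plot_id")
      te <- test_plots[, c("plot_id", "genotype_id", "environment")]
      pr <- run_gp_gpg(tr, te, plan$scheme, kernel, model = bm)
      pr <- pr[, c("plot_id", "day", "value")]
      add_pred(bm, pr)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("model", "rep", "plot_id", "genotype_id", "environment", "day",
          "value")]
}
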