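#' Assemble the random-forest training table
#'
#' One row per (plot, day after the first): response `y` (the phenotype
#' level that day) and predictors `y_prev` (previous day's level), the
#' genotype's genomic-kernel column against the *training* genotypes
#' (columns `g_<id>`, fixed order), `s_prev` (previous day's soil moisture),
#' and `d` (days after sowing). Restricting kernel columns to training
#' genotypes keeps the schema well-defined for unseen test genotypes, whose
#' relationships to the training set are computable from markers.
#'
#' @param growth Data frame `plot_id`, `day`, `value` (smoothed daily
#'   phenotypes).
#' @param moisture Data frame `plot_id`, `day`, `value` (dense soil
#'   moisture).
#' @param design Data frame `plot_id`, `genotype_id`.
#' @param kernel A [genomic_kernel] whose rows cover all plot genotypes and
#'   whose columns will be restricted to `train_genotypes`.
#' @param train_genotypes Character vector of training genotype ids defining
#'   the kernel-column schema.
#' @return Data frame with columns `plot_id`, `day`, `y`, `y_prev`,
#'   `s_prev`, `d`, and one `g_<id>` column per training genotype; rows with
#'   a missing growth or moisture value are dropped (count in attribute
#'   `n_dropped`).
#' @export
assemble_rf_table <- function(growth, moisture, design, kernel,
                              train_genotypes) {
  K <- kernel_matrix(kernel)
  train_genotypes <- as.character(train_genotypes)
  if (!all(train_genotypes %in% colnames(K))) {
    stop("kernel does not cover all training genotypes", call. = FALSE)
  }
  sm_key <- paste(moisture$plot_id, moisture$day)
  rows <- list()
  n_dropped <- 0L
  for (p in unique(growth$plot_id)) {
    gp <- growth[growth$plot_id == p, ]
    gp <- gp[order(gp$day), ]
    if (nrow(gp) < 2L) next
    geno <- design$genotype_id[match(p, design$plot_id)]
    if (is.na(geno) || !geno %in% rownames(K)) {
      stop("plot ", p, " has no genotype in the kernel", call. = FALSE)
    }
    s_prev <- moisture$value[match(paste(p, gp$day[-nrow(gp)]), sm_key)]
    keep <- !is.na(s_prev) & !is.na(gp$value[-1]) & !is.na(gp$value[-nrow(gp)])
    n_dropped <- n_dropped + sum(!keep)
    if (!any(keep)) next
    df <- data.frame(plot_id = p,
                     day = gp$day[-1][keep],
                     y = gp$value[-1][keep],
                     y_prev = gp$value[-nrow(gp)][keep],
                     s_prev = s_prev[keep],
                     d = gp$day[-1][keep],
                     stringsAsFactors = FALSE)
    g <- K[geno, train_genotypes]
    gmat <- matrix(g, nrow(df), length(g), byrow = TRUE)
    colnames(gmat) <- paste0("g_", train_genotypes)
    rows[[p]] <- cbind(df, gmat)
  }
  if (length(rows) == 0L) stop("empty training table", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "train_genotypes") <- train_genotypes
  out
}

#' Train the random-forest daily-growth model
#'
#' Regression forest `y = RF(y_prev, g, s_prev, d)` via `ranger`,
#' deterministic under the given seed (single thread).
#'
#' @param table A [assemble_rf_table()] result.
#' @param mtry Number of candidate predictors per split (the model grid uses
#'   5, 10, 15, 20, 25, 30); values exceeding the predictor count raise an
#'   error.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return Object of class `rf_growth_model` wrapping the fitted forest and
#'   its predictor schema.
#' @export
train_rf <- function(table, mtry = 5, n_trees = 500, seed = 1L) {
  predictors <- setdiff(names(table), c("plot_id", "day", "y"))
  if (mtry > length(predictors)) {
    stop(sprintf("mtry (%d) exceeds predictor count (%d)", mtry,
                 length(predictors)), call. = FALSE)
  }
  dat <- table[, c("y", predictors)]
  fit <- ranger::ranger(
    dependent.variable.name = "y", data = dat,
    num.trees = n_trees, mtry = mtry, seed = seed, num.threads = 1,
    respect.unordered.factors = "order")
  structure(list(forest = fit, predictors = predictors, mtry = mtry,
                 n_trees = n_trees, seed = seed,
                 train_genotypes = attr(table, "train_genotypes"),
                 y_range = range(table$y)),
            class = "rf_growth_model")
}

#' @export
print.rf_growth_model <- function(x, ...) {
  cat(sprintf(
    "Random-forest daily-growth model: %d trees, mtry = %d, %d predictors\n",
    x$n_trees, x$mtry, length(x$predictors)))
  invisible(x)
}

#' Predict next-day phenotype with the random forest
#'
#' @param model A [train_rf()] result.
#' @param newdata Data frame containing every predictor column of the model
#'   (`y_prev`, `s_prev`, `d`, and the `g_<id>` kernel columns).
#' @return Numeric vector of predicted next-day phenotype levels.
#' @export
predict_next <- function(model, newdata) {
  missing_cols <- setdiff(model$predictors, names(newdata))
  if (length(missing_cols) > 0L) {
    stop("newdata lacks predictor column(s): ",
         paste(utils::head(missing_cols, 5), collapse = ", "),
         if (length(missing_cols) > 5L) ", ...", call. = FALSE)
  }
  pred <- stats::predict(model$forest,
                         data = newdata[, model$predictors, drop = FALSE],
                         num.threads = 1)
  as.numeric(pred$predictions)
}

#' Kernel-column predictor rows for a set of genotypes
#'
#' Builds the `g_<id>` predictor block for given genotypes against a model's
#' training-genotype schema.
#'
#' @param kernel A [genomic_kernel].
#' @param genotypes Character vector of genotype ids (rows of the kernel).
#' @param train_genotypes Training genotype ids (columns).
#' @return Matrix `[length(genotypes) x length(train_genotypes)]` with
#'   `g_<id>` column names.
#' @export
kernel_columns <- function(kernel, genotypes, train_genotypes) {
  K <- kernel_matrix(kernel)
  out <- K[as.character(genotypes), as.character(train_genotypes),
           drop = FALSE]
  out <- matrix(out, length(genotypes), length(train_genotypes))
  colnames(out) <- paste0("g_", train_genotypes)
  out
}
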