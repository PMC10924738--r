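#' Table I/O with provenance headers
#'
#' All observational tables travel as long (tidy) CSV with explicit keys.
#' Files written by the package carry a `#`-prefixed provenance header
#' (package version and a content hash of the run configuration) that the
#' readers skip.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param config Optional run configuration list; hashed into the header.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hash <- if (is.null(config)) "none" else config_hash(config)
  writeLines(sprintf("# growthrn %s; config %s",
                     as.character(utils::packageVersion("growthrn")), hash),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Deterministic short hash of a configuration list (for provenance headers).
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Write a genotype score matrix as CSV
#'
#' Genotype ids in the first column, one column per marker, scores in
#' \{-1, 0, 1\} (empty for missing).
#'
#' @param scores Score matrix with genotype rownames.
#' @param path Output path.
#' @export
write_genotype_csv <- function(scores, path) {
  df <- data.frame(genotype_id = rownames(scores), scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read genotype scores from CSV or VCF
#'
#' CSV: first column `genotype_id`, remaining columns marker scores in
#' \{-1, 0, 1\}. VCF: biallelic records only (others skipped with a
#' reported count); the diploid GT field maps `0/0 -> -1`, `0/1 -> 0`,
#' `1/1 -> 1`, missing stays `NA`. VCF ingestion requires the `vcfR`
#' package.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, or `"vcf"`.
#' @return Score matrix `[n_genotypes x n_markers]` with dimnames; VCF input
#'   carries attribute `n_skipped` (non-biallelic records).
#' @export
read_genotypes <- function(path, format = c("auto", "csv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (anyDuplicated(df[[1]])) {
      stop("duplicate genotype ids in ", path, call. = FALSE)
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "numeric"
    rownames(m) <- as.character(df[[1]])
    bad <- !(m %in% c(-1, 0, 1) | is.na(m))
    if (any(bad)) {
      stop("malformed genotype scores (must be -1/0/1 or missing) in ",
           path, call. = FALSE)
    }
    return(m)
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  biallelic <- !grepl(",", alt) & !is.na(alt)
  n_skipped <- sum(!biallelic)
  gt <- vcfR::extract.gt(v[biallelic, ], element = "GT")
  if (anyDuplicated(colnames(gt))) {
    stop("duplicate sample ids in ", path, call. = FALSE)
  }
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_real_, length(x))
    out[x == "0/0"] <- -1
    out[x %in% c("0/1", "1/0")] <- 0
    out[x == "1/1"] <- 1
    out
  }
  m <- t(apply(gt, 1, code))
  m <- t(m)  # samples x markers
  rownames(m) <- colnames(gt)
  colnames(m) <- rownames(gt)
  attr(m, "n_skipped") <- n_skipped
  m
}

#' Write a complete synthetic trial to disk
#'
#' Emits the table dialects every downstream stage reads: `design.csv`,
#' `phenotypes.csv`, `moisture.csv` (sparse measurements),
#' `manual_heights.csv`, `genotypes.csv`, and `truth.json` (ground-truth
#' bundle: bias, initial sizes, planted classes, reaction-norm
#' coefficients).
#'
#' @param trial A [simulate_trial()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_trial <- function(trial, outdir) {
  stopifnot(inherits(trial, "synthetic_trial"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- trial$config
  write_table(trial$design, file.path(outdir, "design.csv"), cfg)
  write_table(trial$phenotypes, file.path(outdir, "phenotypes.csv"), cfg)
  write_table(trial$moisture_obs[, c("row", "position", "plot_id", "day",
                                     "value")],
              file.path(outdir, "moisture.csv"), cfg)
  write_table(trial$manual, file.path(outdir, "manual_heights.csv"), cfg)
  write_genotype_csv(trial$genotypes, file.path(outdir, "genotypes.csv"))
  truth <- trial$truth
  jsonlite::write_json(
    list(bias = as.list(truth$bias),
         y0 = as.list(truth$y0),
         classes = if (is.null(truth$classes)) NULL else
           as.character(truth$classes),
         days = truth$days,
         coefs = truth$coefs),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Validate the cross-table consistency of a run
#'
#' Cross-checks the keys of the input tables: every phenotype plot must be
#' in the design, every design genotype in the genotype matrix, and every
#' design row must carry soil-moisture measurements. Returns an itemized
#' report; any fatal item aborts when `stop_on_fatal`.
#'
#' @param design,phenotypes,moisture Data frames in the package's dialects.
#' @param genotypes Score matrix with genotype rownames (or `NULL` to skip).
#' @param stop_on_fatal Abort on fatal items (default `TRUE`).
#' @return Data frame `severity`, `item` (zero rows when consistent),
#'   invisibly when aborting.
#' @export
validate_run <- function(design, phenotypes = NULL, moisture = NULL,
                         genotypes = NULL, stop_on_fatal = TRUE) {
  items <- data.frame(severity = character(0), item = character(0),
                      stringsAsFactors = FALSE)
  note <- function(severity, item) {
    items[nrow(items) + 1L, ] <<- list(severity, item)
  }
  if (!is.null(phenotypes)) {
    unknown <- setdiff(unique(phenotypes$plot_id), design$plot_id)
    for (u in unknown) note("fatal", paste0("phenotype plot_id not in design: ", u))
  }
  if (!is.null(genotypes)) {
    unknown <- setdiff(unique(design$genotype_id), rownames(genotypes))
    for (u in unknown) note("fatal", paste0("design genotype not in genotype matrix: ", u))
  }
  if (!is.null(moisture)) {
    uncovered <- setdiff(unique(design$row), unique(moisture$row))
    for (u in uncovered) note("warning", paste0("design row without moisture measurements: ", u))
  }
  if (stop_on_fatal && any(items$severity == "fatal")) {
    stop("run validation failed:\n  ",
         paste(items$item[items$severity == "fatal"], collapse = "\n  "),
         call. = FALSE)
  }
  items
}

#' Read a run configuration from YAML
#'
#' Flat per-module namespacing; model hyperparameters outside their
#' documented grids produce a warning but do not abort (the grids are
#' `Q` in \{3, 4, 5\}, `lambda0` in \{10, 30, 50, 70\}, `mtry` in
#' \{5, 10, 15, 20, 25, 30\}).
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  check_grid <- function(name, grid) {
    v <- config[[name]]
    if (!is.null(v) && !all(v %in% grid)) {
      warning(sprintf("%s = %s is outside the documented grid {%s}",
                      name, paste(v, collapse = ","),
                      paste(grid, collapse = ", ")), call. = FALSE)
    }
  }
  check_grid("Q", c(3, 4, 5))
  check_grid("lambda0", c(10, 30, 50, 70))
  check_grid("mtry", c(5, 10, 15, 20, 25, 30))
  if (is.null(config$seed)) {
    stop("run configuration must set a seed", call. = FALSE)
  }
  config
}
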