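#' Reading and writing count tables and metadata
#'
#' Count tables are TSV/CSV with samples as rows, taxa as columns, the
#' first column holding sample ids and the header row taxon ids; the
#' transposed dialect (taxa as rows) is accepted via `taxa_as_rows = TRUE`.
#' Delimiter is inferred from the file extension (`.csv` = comma, otherwise
#' tab).
#'
#' @name io
NULL

infer_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a taxa count table
#'
#' @param path TSV or CSV file.
#' @param taxa_as_rows set TRUE when the file stores taxa as rows and
#'   samples as columns; the result is transposed to the canonical
#'   samples x taxa orientation.
#' @return Validated samples x taxa integer matrix with dimnames.
#' @export
read_counts <- function(path, taxa_as_rows = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = infer_sep(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  ids <- as.character(df[[1L]])
  taxa <- colnames(df)[-1L]  # before subsetting: [.data.frame repairs duplicates
  mat <- as.matrix(df[, -1L, drop = FALSE])
  colnames(mat) <- taxa
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))
    stop("non-numeric cells in column(s): ",
         paste(colnames(df)[-1L][bad], collapse = ", "))
  }
  nonint <- which(abs(mat - round(mat)) > 1e-8, arr.ind = TRUE)
  if (nrow(nonint) > 0L)
    stop(sprintf("non-integer count at row %s, column %s",
                 ids[nonint[1L, 1L]], colnames(mat)[nonint[1L, 2L]]))
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop(sprintf("negative count at row %s, column %s",
                 ids[neg[1L, 1L]], colnames(mat)[neg[1L, 2L]]))
  rownames(mat) <- ids
  if (taxa_as_rows) mat <- t(mat)
  validate_counts(mat)
  storage.mode(mat) <- "integer"
  mat
}

#' @rdname read_counts
#' @param counts samples x taxa matrix.
#' @param id_column header for the first (sample id) column.
#' @export
write_counts <- function(counts, path, id_column = "sample_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = infer_sep(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read per-subject clinical metadata
#'
#' CSV with a `sample_id` column; 0/1 flags for mortality and comorbidity
#' indicators.
#'
#' @param path CSV file.
#' @return data.frame with rownames set to `sample_id`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  md <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(md$sample_id)) stop("metadata must contain a sample_id column")
  if (anyDuplicated(md$sample_id)) stop("duplicate sample ids in metadata")
  rownames(md) <- md$sample_id
  if (!is.null(md$death28) && !is.null(md$death_free_days)) {
    bad <- md$death28 == 1 & md$death_free_days > 28
    if (any(bad)) stop("inconsistent metadata: death28 with death_free_days > 28 for ",
                       paste(md$sample_id[bad], collapse = ", "))
  }
  md
}

#' Run the full mortality-balance analysis pipeline
#'
#' Executes the complete analysis sequence on a cohort: prevalence filter,
#' zero replacement and closure (inside [fit_mmi()]), cross-validated MMI
#' selection, alpha-diversity panel contrasted by binarized MMI, bivariate
#' tests against 28-day mortality (including the MMI rows), the suite of
#' univariate / bivariate / trivariate elastic-net Cox models over APACHE
#' II, ARDS and binarized MMI, and Kaplan-Meier curves per MMI group.
#'
#' @param counts samples x taxa integer matrix, or a path readable by
#'   [read_counts()].
#' @param metadata data.frame or CSV path with the clinical columns used by
#'   `config` plus `death_free_days` and `event_observed`.
#' @param config an [mmi_config()].
#' @param out_dir optional directory; when given, the report JSON and the
#'   per-sample MMI / diversity / bivariate / Cox TSVs are written there.
#' @param cox_penalizer,cox_l1_ratio elastic-net settings for the Cox suite.
#' @return A `"pipeline_report"` list; see the vignette for the schema.
#' @export
run_pipeline <- function(counts, metadata, config = mmi_config(),
                         out_dir = NULL, cox_penalizer = 0.05,
                         cox_l1_ratio = 0.5) {
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  metadata <- as.data.frame(metadata)
  ids <- if (!is.null(metadata$sample_id)) as.character(metadata$sample_id) else rownames(metadata)
  common <- intersect(rownames(counts), ids)
  if (length(common) < 2L) stop("stage assemble: fewer than 2 samples shared between counts and metadata")
  dropped <- c(setdiff(rownames(counts), common), setdiff(ids, common))
  if (length(dropped) > 0L)
    warning("stage assemble: dropping unmatched samples: ", paste(dropped, collapse = ", "))
  rownames(metadata) <- ids
  counts <- counts[common, , drop = FALSE]
  metadata <- metadata[common, , drop = FALSE]

  fit <- withCallingHandlers(
    fit_mmi(counts, metadata, config),
    error = function(e) stop("stage fit_mmi: ", conditionMessage(e), call. = FALSE))

  md <- metadata
  md$mmi <- as.numeric(fit$mmi)
  md$mmi_positive <- as.integer(fit$mmi_positive)

  profile <- diversity_profile(counts)
  div_contrast <- group_contrast(profile[, setdiff(names(profile), c("sample_id")), drop = FALSE],
                                 fit$mmi_positive)

  biv <- bivariate_table(md, grouping = config$outcome_col)

  times <- md$death_free_days
  events <- md$event_observed
  cox_vars <- intersect(c("age", "sex_male", "diabetes", "malignancy",
                          "immunosuppressed", "sepsis3", "ards", "apache2",
                          "mmi_positive"), names(md))
  uni <- lapply(cox_vars, function(v)
    tryCatch(cox_fit(md[, v, drop = FALSE], times, events,
                     l1_ratio = cox_l1_ratio, penalizer = cox_penalizer),
             error = function(e) NULL))
  names(uni) <- cox_vars
  combos <- list(c("apache2", "ards"), c("apache2", "mmi_positive"),
                 c("ards", "mmi_positive"), c("apache2", "ards", "mmi_positive"))
  multi <- lapply(combos, function(vars)
    tryCatch(cox_fit(md[, vars, drop = FALSE], times, events,
                     l1_ratio = cox_l1_ratio, penalizer = cox_penalizer),
             error = function(e) NULL))
  names(multi) <- vapply(combos, paste, character(1), collapse = "+")

  km_groups <- list(
    mmi_positive = km_estimator(times[fit$mmi_positive], events[fit$mmi_positive]),
    mmi_negative = km_estimator(times[!fit$mmi_positive], events[!fit$mmi_positive]))

  mmi_death_tab <- matrix(c(sum(fit$mmi_positive & md[[config$outcome_col]] == 1),
                            sum(fit$mmi_positive & md[[config$outcome_col]] == 0),
                            sum(!fit$mmi_positive & md[[config$outcome_col]] == 1),
                            sum(!fit$mmi_positive & md[[config$outcome_col]] == 0)),
                          nrow = 2, byrow = TRUE,
                          dimnames = list(c("mmi_pos", "mmi_neg"), c("died", "survived")))

  report <- structure(list(
    provenance = list(package_version = as.character(utils::packageVersion("mmindex")),
                      config = unclass(config), n_samples = nrow(counts),
                      n_taxa = ncol(counts), timestamp = format(Sys.time(), tz = "UTC")),
    balance = list(numerator = fit$balance$numerator,
                   denominator = fit$balance$denominator,
                   log_base = fit$balance$log_base,
                   selected_size = fit$selected_size),
    scores_by_size = fit$scores_by_size,
    mmi = data.frame(sample_id = names(fit$mmi), mmi = as.numeric(fit$mmi),
                     mmi_positive = as.integer(fit$mmi_positive)),
    mmi_death_table = mmi_death_tab,
    mmi_death_fisher_p = fisher_exact_2x2(mmi_death_tab),
    diversity = profile, diversity_contrast = div_contrast,
    bivariate = biv,
    cox_univariate = uni, cox_multivariate = multi,
    km = km_groups), class = "pipeline_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @rdname run_pipeline
#' @param report a `"pipeline_report"`.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", row.names = FALSE, quote = FALSE)
  tsv(report$mmi, "mmi_per_sample.tsv")
  tsv(report$scores_by_size, "cv_scores_by_size.tsv")
  tsv(report$diversity, "diversity_per_sample.tsv")
  tsv(report$diversity_contrast, "diversity_contrast.tsv")
  tsv(report$bivariate, "bivariate_table.tsv")
  cox_rows <- do.call(rbind, c(
    lapply(names(report$cox_univariate), function(nm) {
      f <- report$cox_univariate[[nm]]
      if (is.null(f)) return(NULL)
      cbind(model = nm, f$table)
    }),
    lapply(names(report$cox_multivariate), function(nm) {
      f <- report$cox_multivariate[[nm]]
      if (is.null(f)) return(NULL)
      cbind(model = nm, f$table)
    })))
  if (!is.null(cox_rows)) tsv(cox_rows, "cox_models.tsv")
  json <- list(
    provenance = report$provenance, balance = report$balance,
    mmi_death_table = report$mmi_death_table,
    mmi_death_fisher_p = report$mmi_death_fisher_p,
    scores_by_size = report$scores_by_size,
    km = lapply(report$km, unclass))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report:", x$provenance$n_samples, "samples,",
      x$provenance$n_taxa, "taxa\n")
  cat("  MMI balance:", paste(x$balance$numerator, collapse = ","), "/",
      paste(x$balance$denominator, collapse = ","),
      sprintf("(size %d)\n", x$balance$selected_size))
  cat(sprintf("  Fisher p (MMI>0 x 28-day death): %.4f\n", x$mmi_death_fisher_p))
  invisible(x)
}
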