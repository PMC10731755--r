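#' Cross-validated greedy balance selection (the MMI search)
#'
#' Re-usable machinery behind [fit_mmi()]: score candidate balances by the
#' AUC of a logistic model of 28-day mortality on (balance value, clinical
#' covariates), grow balances greedily one taxon at a time, and choose the
#' balance size by repeated stratified cross-validation with a one-standard-
#' error simplicity rule.
#'
#' @name balance_search
NULL

# --- fast internal logistic fitting -----------------------------------------
# IRLS on a small dense design; falls back to a tiny ridge penalty when
# quasi-separation stalls convergence or blows up the coefficients.
logit_fit <- function(X, y, ridge = 0, max_iter = 25L, tol = 1e-8) {
  X <- cbind(1, X)
  p <- ncol(X)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    H <- XtW %*% X
    if (ridge > 0) H <- H + diag(ridge, p)
    beta_new <- tryCatch(drop(solve(H, XtW %*% z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) {  # singular information: stabilize
      if (ridge == 0) return(logit_fit(X[, -1, drop = FALSE], y, ridge = 1e-4, max_iter = max_iter, tol = tol))
      beta_new <- drop(solve(H + diag(1e-6, p), XtW %*% z))
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (!all(is.finite(beta)) || max(abs(beta)) > 1e3) {
      if (ridge == 0) return(logit_fit(X[, -1, drop = FALSE], y, ridge = 1e-4, max_iter = max_iter, tol = tol))
    }
    if (delta < tol) break
  }
  if (!all(is.finite(beta)) && ridge == 0)
    return(logit_fit(X[, -1, drop = FALSE], y, ridge = 1e-4, max_iter = max_iter, tol = tol))
  list(coefficients = beta, ridge = ridge)
}

logit_predict <- function(fit, X) drop(cbind(1, X) %*% fit$coefficients)

# Rank-based AUC (equals Mann-Whitney U / (n1*n0); average ranks for ties).
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: outcome has a single class")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_cov_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), nrow = n, ncol = 0))
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  if (nrow(covariates) != n) stop("covariates and samples differ in length")
  covariates
}

#' Score a balance by logistic-model AUC
#'
#' Fits a logistic regression of a binary outcome on the balance value plus
#' clinical covariates and returns the AUC of the fitted scores on the same
#' samples (apparent AUC). Quasi-separation is handled by refitting with a
#' small ridge penalty (1e-4), which leaves the AUC essentially unchanged
#' while keeping coefficients finite.
#'
#' @param bal a [balance()].
#' @param comp samples x taxa strictly positive matrix.
#' @param outcome 0/1 (or logical) vector with both classes present.
#' @param covariates optional samples x c numeric matrix.
#' @return A list with `score` (AUC), `balance`, and `model_coefficients`.
#' @export
score_balance <- function(bal, comp, outcome, covariates = NULL) {
  y <- as.integer(outcome)
  if (length(unique(y)) < 2L) stop("outcome has a single class; AUC is undefined")
  b <- balance_value(comp, bal)
  X <- cbind(balance = b, as_cov_matrix(covariates, length(y)))
  fit <- logit_fit(X, y)
  scores <- logit_predict(fit, X)
  list(balance = bal, score = auc_rank(scores, y),
       model_coefficients = fit$coefficients, apparent = TRUE)
}

# --- greedy search internals -------------------------------------------------
# All search steps operate on L = log(positive abundance matrix): the balance
# value is coef * (rowMeans(L[,num]) - rowMeans(L[,den])) / log(base), and
# since AUC is invariant to positive affine maps of the score, the
# coefficient and base are irrelevant during the search itself.

bal_score_from_logs <- function(L, num, den) {
  n1 <- if (length(num) == 1L) L[, num] else rowMeans(L[, num, drop = FALSE])
  d1 <- if (length(den) == 1L) L[, den] else rowMeans(L[, den, drop = FALSE])
  n1 - d1
}

score_sets <- function(L, num, den, y, cov) {
  b <- bal_score_from_logs(L, num, den)
  X <- cbind(b, cov)
  fit <- logit_fit(X, y)
  auc_rank(logit_predict(fit, X), y)
}

# Lexicographic comparison of a candidate's id sets for deterministic ties.
set_key <- function(num, den) paste(paste(sort(num), collapse = "|"),
                                    paste(sort(den), collapse = "|"), sep = "||")

#' Best single-pair balance
#'
#' Evaluates every unordered taxon pair as a 1-vs-1 balance, orients each so
#' the balance value correlates positively with the adverse outcome, and
#' returns the top scorer. Exact score ties are broken lexicographically by
#' taxon ids for reproducibility.
#'
#' @inheritParams score_balance
#' @param comp samples x taxa strictly positive matrix (>= 2 taxa).
#' @param log_base base for the returned balance object.
#' @return List with `numerator`, `denominator`, `score`.
#' @export
best_initial_pair <- function(comp, outcome, covariates = NULL, log_base = 10) {
  taxa <- colnames(comp)
  if (length(taxa) < 2L) stop("need at least 2 taxa to form a balance")
  y <- as.integer(outcome)
  cov <- as_cov_matrix(covariates, length(y))
  L <- log(comp)
  best <- NULL
  for (i in seq_len(length(taxa) - 1L)) for (j in (i + 1L):length(taxa)) {
    sc <- score_sets(L, taxa[i], taxa[j], y, cov)
    cand <- orient_pair(L, taxa[i], taxa[j], y)
    key <- set_key(cand$num, cand$den)
    if (is.null(best) || sc > best$score + 1e-12 ||
        (abs(sc - best$score) <= 1e-12 && key < best$key)) {
      best <- list(num = cand$num, den = cand$den, score = sc, key = key)
    }
  }
  list(numerator = best$num, denominator = best$den, score = best$score)
}

# Put the taxon whose enrichment tracks the adverse outcome in the numerator.
orient_pair <- function(L, a, b, y) {
  v <- L[, a] - L[, b]
  if (mean(v[y == 1]) >= mean(v[y == 0])) list(num = a, den = b) else list(num = b, den = a)
}

#' Extend a balance by one taxon
#'
#' Tries adding each remaining taxon to the numerator and to the denominator
#' (2(T-k) candidates) and returns the best-scoring extension; scores are
#' never compared across sizes here.
#'
#' @param candidate list with `numerator` and `denominator` character vectors.
#' @inheritParams best_initial_pair
#' @return List with the extended `numerator`, `denominator`, `score`.
#' @export
extend_balance <- function(candidate, comp, outcome, covariates = NULL) {
  taxa <- colnames(comp)
  used <- c(candidate$numerator, candidate$denominator)
  remaining <- setdiff(taxa, used)
  if (length(remaining) == 0L) stop("no taxa remain to extend the balance")
  y <- as.integer(outcome)
  cov <- as_cov_matrix(covariates, length(y))
  L <- log(comp)
  best <- NULL
  for (tx in remaining) for (side in c("num", "den")) {
    num <- candidate$numerator; den <- candidate$denominator
    if (side == "num") num <- c(num, tx) else den <- c(den, tx)
    sc <- score_sets(L, num, den, y, cov)
    key <- set_key(num, den)
    if (is.null(best) || sc > best$score + 1e-12 ||
        (abs(sc - best$score) <= 1e-12 && key < best$key)) {
      best <- list(num = num, den = den, score = sc, key = key)
    }
  }
  list(numerator = best$num, denominator = best$den, score = best$score)
}

# Greedy path: list of candidates for sizes 2..max_size on given samples.
greedy_path <- function(comp, y, cov, max_size) {
  path <- vector("list", max_size - 1L)
  cand <- best_initial_pair(comp, y, cov)
  path[[1L]] <- cand
  k <- 2L
  while (k < max_size && length(c(cand$numerator, cand$denominator)) < ncol(comp)) {
    cand <- extend_balance(cand, comp, y, cov)
    k <- k + 1L
    path[[k - 1L]] <- cand
  }
  path[!vapply(path, is.null, logical(1))]
}

# Stratified fold assignment: returns integer fold id per sample.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Choose the balance size by repeated cross-validation
#'
#' Within each training fold the greedy search grows a balance to
#' `max_size`; each size's balance is then scored on the held-out fold
#' (logistic model refit on the training fold, AUC on the held-out samples).
#' Mean and standard error per size are aggregated over all folds and
#' repeats. The `"1se"` rule picks the smallest size whose mean held-out
#' score is within one standard error of the best mean — the simplest
#' balance with comparable predictive ability; `"max"` picks the argmax.
#'
#' @param comp samples x taxa strictly positive matrix (already filtered and
#'   zero-replaced).
#' @param outcome 0/1 vector.
#' @param covariates optional samples x c matrix.
#' @param max_size largest balance size to consider (default 8).
#' @param n_folds folds per repeat (default 5), stratified by outcome.
#' @param n_repeats CV repeats (default 10).
#' @param rule `"1se"` (default) or `"max"`.
#' @param seed integer seed for the fold assignments.
#' @return List with `scores_by_size` (data.frame: size, mean, se, n_folds)
#'   and `selected_size`.
#' @export
cv_select_size <- function(comp, outcome, covariates = NULL, max_size = 8L,
                           n_folds = 5L, n_repeats = 10L,
                           rule = c("1se", "max"), seed = 1L) {
  rule <- match.arg(rule)
  y <- as.integer(outcome)
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  cov <- as_cov_matrix(covariates, length(y))
  max_size <- min(max_size, ncol(comp))
  if (max_size < 2L) stop("max_size must be at least 2")
  n_min <- min(table(y))
  if (n_folds > n_min) {
    warning("reducing n_folds to ", n_min, " so every fold sees both classes")
    n_folds <- n_min
  }
  sizes <- 2:max_size
  score_mat <- matrix(NA_real_, nrow = n_folds * n_repeats, ncol = length(sizes))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  row <- 0L
  for (rep_i in seq_len(n_repeats)) {
    fold <- stratified_folds(y, n_folds)
    for (f in seq_len(n_folds)) {
      row <- row + 1L
      test <- fold == f
      tr_comp <- comp[!test, , drop = FALSE]
      tr_y <- y[!test]; te_y <- y[test]
      tr_cov <- cov[!test, , drop = FALSE]; te_cov <- cov[test, , drop = FALSE]
      if (length(unique(te_y)) < 2L) next  # held-out AUC undefined; row stays NA
      path <- greedy_path(tr_comp, tr_y, tr_cov, max_size)
      Ltr <- log(tr_comp); Lte <- log(comp[test, , drop = FALSE])
      for (s in seq_along(path)) {
        cand <- path[[s]]
        btr <- bal_score_from_logs(Ltr, cand$numerator, cand$denominator)
        bte <- bal_score_from_logs(Lte, cand$numerator, cand$denominator)
        fit <- logit_fit(cbind(btr, tr_cov), tr_y)
        score_mat[row, s] <- auc_rank(logit_predict(fit, cbind(bte, te_cov)), te_y)
      }
    }
  }
  means <- colMeans(score_mat, na.rm = TRUE)
  ns <- colSums(!is.na(score_mat))
  ses <- apply(score_mat, 2L, stats::sd, na.rm = TRUE) / sqrt(pmax(ns, 1L))
  best <- which.max(means)
  selected <- if (rule == "1se") {
    sizes[min(which(means >= means[best] - ses[best]))]
  } else sizes[best]
  list(scores_by_size = data.frame(size = sizes, mean = means, se = ses, n_folds = ns),
       selected_size = selected, rule = rule, folds_seed = as.integer(seed))
}

#' Default configuration for the MMI pipeline
#'
#' @param prevalence_max_unobserved prevalence-filter threshold (default 0.20).
#' @param zero_low,zero_high uniform zero-replacement bounds.
#' @param log_base balance log base (default 10).
#' @param max_size,n_folds,n_repeats,rule cross-validation settings, see
#'   [cv_select_size()].
#' @param covariate_cols metadata columns entering the logistic model.
#' @param outcome_col metadata column holding the 0/1 28-day mortality flag.
#' @param seed master seed for zero replacement and fold assignment.
#' @return A named list of class `"mmi_config"`.
#' @export
mmi_config <- function(prevalence_max_unobserved = 0.20,
                       zero_low = 0.01, zero_high = 1.0, log_base = 10,
                       max_size = 8L, n_folds = 5L, n_repeats = 10L,
                       rule = "1se",
                       covariate_cols = c("age", "apache2"),
                       outcome_col = "death28", seed = 1L) {
  structure(list(prevalence_max_unobserved = prevalence_max_unobserved,
                 zero_low = zero_low, zero_high = zero_high, log_base = log_base,
                 max_size = as.integer(max_size), n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), rule = rule,
                 covariate_cols = covariate_cols, outcome_col = outcome_col,
                 seed = as.integer(seed)),
            class = "mmi_config")
}

#' Load an MMI configuration from a YAML file
#'
#' Recognized keys match the arguments of [mmi_config()] (plus the aliases
#' `folds`, `repeats` for `n_folds`, `n_repeats`); unknown keys error.
#'
#' @param path YAML file path.
#' @return An `"mmi_config"`.
#' @export
read_mmi_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$folds)) { raw$n_folds <- raw$folds; raw$folds <- NULL }
  if (!is.null(raw$repeats)) { raw$n_repeats <- raw$repeats; raw$repeats <- NULL }
  known <- names(formals(mmi_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(mmi_config, raw)
}

#' Fit the microbiome mortality index
#'
#' End-to-end balance selection: prevalence filter, uniform zero
#' replacement, closure, cross-validated size selection, then a final greedy
#' refit on all samples at the selected size. The final balance is oriented
#' so that larger MMI values accompany 28-day death (mean MMI among deaths
#' >= mean among survivors); `mmi_positive` binarizes the index at zero.
#'
#' @param counts samples x taxa nonnegative integer matrix.
#' @param metadata data.frame with one row per sample (rownames or
#'   `sample_id` column matching the count rows) providing the outcome and
#'   covariate columns named in `config`.
#' @param config an [mmi_config()].
#' @return Object of class `"mmi_fit"`: the selected [balance()], per-sample
#'   `mmi` and `mmi_positive`, `scores_by_size`, `selected_size`, and the
#'   filtered/replaced composition used.
#' @export
fit_mmi <- function(counts, metadata, config = mmi_config()) {
  stopifnot(inherits(config, "mmi_config"))
  metadata <- align_metadata(metadata, rownames(counts))
  y <- as.integer(metadata[[config$outcome_col]])
  if (anyNA(y) || length(unique(y)) < 2L)
    stop("stage fit_mmi/outcome: 28-day mortality must be 0/1 with both classes")
  cov <- as.matrix(metadata[, config$covariate_cols, drop = FALSE])
  storage.mode(cov) <- "double"

  filtered <- prevalence_filter(counts, config$prevalence_max_unobserved)
  pos <- replace_zeros(filtered, config$zero_low, config$zero_high,
                       seed = config$seed)
  comp <- closure(pos)

  sel <- cv_select_size(comp, y, cov, max_size = config$max_size,
                        n_folds = config$n_folds, n_repeats = config$n_repeats,
                        rule = config$rule, seed = config$seed)
  path <- greedy_path(comp, y, cov, max_size = sel$selected_size)
  final <- path[[length(path)]]

  bal <- balance(final$numerator, final$denominator, log_base = config$log_base)
  mmi <- balance_value(comp, bal)
  if (mean(mmi[y == 1]) < mean(mmi[y == 0])) {  # orient adverse = positive
    bal <- balance(final$denominator, final$numerator, log_base = config$log_base)
    mmi <- -mmi
  }
  names(mmi) <- rownames(counts)
  structure(list(balance = bal, mmi = mmi, mmi_positive = mmi > 0,
                 scores_by_size = sel$scores_by_size,
                 selected_size = sel$selected_size,
                 apparent_score = final$score,
                 folds_seed = sel$folds_seed, config = config,
                 composition = comp),
            class = "mmi_fit")
}

#' @export
print.mmi_fit <- function(x, ...) {
  cat("Microbiome mortality index fit\n")
  print(x$balance)
  cat(sprintf("  selected size %d (rule %s); apparent AUC %.3f\n",
              x$selected_size, x$config$rule, x$apparent_score))
  cat(sprintf("  MMI > 0 in %d / %d samples\n", sum(x$mmi_positive), length(x$mmi)))
  invisible(x)
}

# Align metadata rows to the count-table samples (intersection, warn on drop).
align_metadata <- function(metadata, sample_ids) {
  md <- as.data.frame(metadata)
  ids <- if (!is.null(md$sample_id)) as.character(md$sample_id) else rownames(md)
  if (is.null(ids)) stop("metadata needs rownames or a sample_id column")
  if (anyDuplicated(ids)) stop("duplicate sample ids in metadata")
  rownames(md) <- ids
  common <- intersect(sample_ids, ids)
  if (length(common) < length(sample_ids)) {
    dropped <- setdiff(sample_ids, ids)
    stop("metadata missing samples: ", paste(dropped, collapse = ", "))
  }
  md[sample_ids, , drop = FALSE]
}
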