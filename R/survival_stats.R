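#' Bivariate tests, Kaplan-Meier curves, and penalized Cox models
#'
#' The statistical toolkit behind the cohort tables: Fisher's exact test for
#' categorical variables, Wilcoxon rank-sum for quantitative ones, Student's
#' t for group means, product-limit survival curves per MMI group, and
#' elastic-net-regularized Cox proportional hazards over the first 28 days
#' of admission.
#'
#' @name survival_stats
NULL

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Probability-of-table rule: the p-value sums hypergeometric probabilities
#' (margins fixed) of all tables no more probable than the observed one.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(tab < 0) || any(abs(tab - round(tab)) > 1e-8)) stop("counts must be nonnegative integers")
  if (sum(tab) == 0) stop("empty table")
  stats::fisher.test(tab)$p.value
}

#' Wilcoxon rank-sum test
#'
#' `mode = "exact"` uses the exact null distribution (available without
#' ties; with ties R's standard fallback to the corrected normal
#' approximation applies, with a warning). `mode = "normal"` uses the
#' tie-corrected normal approximation with continuity correction. The
#' default `"auto"` is exact for combined sample size <= 20.
#'
#' @param x,y numeric samples.
#' @param mode `"auto"`, `"exact"`, or `"normal"`.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical; p = 1")
    return(1)
  }
  exact <- switch(mode, auto = length(x) + length(y) <= 20L,
                  exact = TRUE, normal = FALSE)
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Pooled-variance two-sample t-test
#'
#' @param x,y numeric samples with at least 2 values each.
#' @return List with `t`, `df`, `p`.
#' @export
t_test_two_sample <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 observations per group")
  if (stats::var(c(x - mean(x), y - mean(y))) == 0) stop("zero pooled variance")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Kaplan-Meier product-limit estimator
#'
#' Wraps `survival::survfit`. With no censoring the curve equals the
#' empirical survival function.
#'
#' @param times nonnegative event/censoring times (days).
#' @param events logical/0-1; TRUE = death observed at `times`.
#' @return Object of class `"km_curve"`: `time`, `surv`, `n_risk`,
#'   `n_event` vectors (time 0 with survival 1 included).
#' @export
km_estimator <- function(times, events) {
  if (length(times) == 0L) stop("empty input")
  if (any(times < 0)) stop("negative times")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  structure(list(time = c(0, fit$time), surv = c(1, fit$surv),
                 n_risk = c(length(times), fit$n.risk),
                 n_event = c(0, fit$n.event)),
            class = "km_curve")
}

#' @rdname km_estimator
#' @param curve a `"km_curve"`.
#' @param t time at which to evaluate the step function.
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  idx <- which(curve$time <= t)
  curve$surv[max(idx)]
}

#' Elastic-net-regularized Cox proportional hazards fit
#'
#' Observations are administratively censored at `horizon_days` (times past
#' the horizon are censored there), matching an analysis of the first 28
#' days of each admission. Point estimates come from the penalized partial
#' likelihood (`glmnet`, mixing parameter `l1_ratio`, penalty `penalizer`,
#' unstandardized covariates); with `penalizer = 0` an unpenalized
#' `survival::coxph` fit with Efron tie handling is used. Approximate 95%
#' Wald CIs and p-values are derived from the observed information of the
#' unpenalized partial likelihood evaluated at the reported coefficients —
#' for penalized fits these are approximate and should be read as
#' descriptive.
#'
#' @param covariates samples x p numeric matrix (or data.frame) with column
#'   names; constant columns are dropped with a warning.
#' @param times follow-up times in days.
#' @param events logical/0-1 death indicators.
#' @param l1_ratio elastic-net mixing (1 = lasso, 0 = ridge); default 0.5.
#' @param penalizer penalty strength lambda; default 0.05.
#' @param horizon_days administrative censoring horizon; default 28.
#' @return Object of class `"cox_fit"`: data.frame `table` with coef,
#'   hazard_ratio, ci_lower, ci_upper, p per covariate, plus the settings.
#' @export
cox_fit <- function(covariates, times, events, l1_ratio = 0.5,
                    penalizer = 0.05, horizon_days = 28) {
  X <- as.matrix(as.data.frame(covariates))
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ev <- as.integer(events)
  tt <- as.numeric(times)
  if (length(tt) != nrow(X) || length(ev) != nrow(X)) stop("length mismatch")
  ev[tt > horizon_days] <- 0L
  tt <- pmin(tt, horizon_days)
  if (length(unique(tt[ev == 1])) < 2L) stop("need events at >= 2 distinct times")
  keep <- apply(X, 2L, function(col) stats::sd(col) > 0)
  if (!all(keep)) {
    warning("dropping constant covariates: ", paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no non-constant covariates")

  if (penalizer > 0) {
    Xg <- X
    padded <- FALSE
    if (ncol(Xg) == 1L) {  # glmnet needs >= 2 columns; a zero column gets coef 0
      Xg <- cbind(Xg, .zero = 0)
      padded <- TRUE
    }
    gfit <- glmnet::glmnet(Xg, survival::Surv(tt, ev), family = "cox",
                           alpha = l1_ratio, lambda = penalizer,
                           standardize = FALSE)
    beta <- as.numeric(gfit$beta)
    if (padded) beta <- beta[1L]
    names(beta) <- colnames(X)
    # observed information of the unpenalized partial likelihood at beta
    info_fit <- survival::coxph(survival::Surv(tt, ev) ~ X, init = beta,
                                control = survival::coxph.control(iter.max = 0),
                                ties = "efron")
    se <- sqrt(diag(stats::vcov(info_fit)))
  } else {
    fit <- survival::coxph(survival::Surv(tt, ev) ~ X, ties = "efron")
    beta <- stats::setNames(as.numeric(stats::coef(fit)), colnames(X))
    se <- sqrt(diag(stats::vcov(fit)))
  }
  z <- beta / se
  tab <- data.frame(
    variable = colnames(X), coef = as.numeric(beta),
    hazard_ratio = exp(as.numeric(beta)),
    ci_lower = exp(as.numeric(beta) - 1.96 * se),
    ci_upper = exp(as.numeric(beta) + 1.96 * se),
    se = as.numeric(se), p = 2 * stats::pnorm(-abs(z)),
    row.names = NULL)
  structure(list(table = tab, l1_ratio = l1_ratio, penalizer = penalizer,
                 horizon_days = horizon_days, n = nrow(X), n_events = sum(ev)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (l1_ratio %.2f, penalizer %.3g, horizon %g days, %d events / %d)\n",
              x$l1_ratio, x$penalizer, x$horizon_days, x$n_events, x$n))
  print(x$table, digits = 3)
  invisible(x)
}

#' Bivariate analyses against 28-day mortality
#'
#' For every requested variable: quantitative variables are summarized as
#' median [IQR] per outcome group and tested by Wilcoxon rank-sum;
#' categorical (0/1) variables as n (%) and tested by Fisher's exact test.
#' Missing values are dropped per variable.
#'
#' @param metadata data.frame, one row per subject.
#' @param grouping name of the 0/1 outcome column (default "death28").
#' @param quantitative,categorical character vectors of column names; by
#'   default every numeric non-flag column / every 0-1 column other than the
#'   grouping is used.
#' @return data.frame mirroring a cohort bivariate table: variable, summary
#'   overall and per group, test used, p-value.
#' @export
bivariate_table <- function(metadata, grouping = "death28",
                            quantitative = NULL, categorical = NULL) {
  md <- as.data.frame(metadata)
  g <- md[[grouping]]
  if (is.null(g)) stop("grouping column not found: ", grouping)
  g <- as.logical(g)
  if (!any(g) || all(g)) stop("grouping must have both classes")
  is_flag <- vapply(md, function(col) is.logical(col) ||
                      (is.numeric(col) && all(col %in% c(0, 1, NA))), logical(1))
  if (is.null(categorical))
    categorical <- setdiff(names(md)[is_flag], c(grouping, "sample_id"))
  if (is.null(quantitative))
    quantitative <- setdiff(names(md)[vapply(md, is.numeric, logical(1)) & !is_flag],
                            c(grouping, "sample_id", "death_free_days"))
  fmt_mi <- function(x) sprintf("%.1f [%.1f, %.1f]",
                                stats::median(x, na.rm = TRUE),
                                stats::quantile(x, 0.25, na.rm = TRUE),
                                stats::quantile(x, 0.75, na.rm = TRUE))
  fmt_np <- function(x) sprintf("%d (%.0f%%)", sum(x, na.rm = TRUE),
                                100 * mean(x, na.rm = TRUE))
  rows <- list()
  for (v in quantitative) {
    x <- md[[v]]
    ok <- is.finite(x)
    p <- tryCatch(wilcoxon_rank_sum(x[ok & g], x[ok & !g], mode = "normal"),
                  error = function(e) NA_real_)
    rows[[v]] <- data.frame(variable = v, test = "wilcoxon",
                            overall = fmt_mi(x[ok]), died = fmt_mi(x[ok & g]),
                            survived = fmt_mi(x[ok & !g]), p = p)
  }
  for (v in categorical) {
    x <- as.integer(md[[v]])
    ok <- !is.na(x)
    tab <- matrix(c(sum(x[ok & g]), sum(x[ok & !g]),
                    sum(ok & g) - sum(x[ok & g]), sum(ok & !g) - sum(x[ok & !g])),
                  nrow = 2, byrow = TRUE)
    p <- if (stats::sd(x[ok]) == 0) NA_real_ else fisher_exact_2x2(tab)
    rows[[v]] <- data.frame(variable = v, test = "fisher",
                            overall = fmt_np(x[ok]), died = fmt_np(x[ok & g]),
                            survived = fmt_np(x[ok & !g]), p = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
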