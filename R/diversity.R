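#' Alpha-diversity panel
#'
#' Per-sample community summaries computed on raw counts (no zero
#' replacement, which would distort richness): Shannon entropy in bits,
#' Pielou and Simpson evenness, Simpson diversity, dominance, Chao1 richness
#' and Fisher's alpha. Dominance here is Simpson's sum of squared
#' proportions, so dominance + Simpson diversity = 1 exactly.
#'
#' @name diversity
NULL

nonzero_props <- function(counts_row) {
  if (anyNA(counts_row) || any(counts_row < 0)) stop("counts must be nonnegative")
  total <- sum(counts_row)
  if (total <= 0) stop("empty sample: all counts are zero")
  p <- counts_row[counts_row > 0] / total
  p
}

#' Shannon entropy
#' @param counts_row nonnegative counts for one sample.
#' @param base log base; default 2 (bits).
#' @return Entropy of the proportional abundances; 0 for a single taxon.
#' @export
shannon <- function(counts_row, base = 2) {
  p <- nonzero_props(counts_row)
  -sum(p * log(p, base = base))
}

#' @rdname shannon
#' @details Pielou evenness is Shannon entropy divided by its maximum
#'   `log(S_obs)` (any common base cancels); undefined (`NA`) for fewer than
#'   two observed taxa.
#' @export
pielou <- function(counts_row) {
  p <- nonzero_props(counts_row)
  s <- length(p)
  if (s < 2L) return(NA_real_)
  -sum(p * log2(p)) / log2(s)
}

#' @rdname shannon
#' @details Dominance is Simpson's index `sum(p_i^2)`; Simpson diversity is
#'   its complement `1 - sum(p_i^2)`; Simpson evenness is the inverse-Simpson
#'   effective taxon count divided by observed richness.
#' @export
dominance <- function(counts_row) {
  p <- nonzero_props(counts_row)
  sum(p^2)
}

#' @rdname shannon
#' @export
simpson_diversity <- function(counts_row) 1 - dominance(counts_row)

#' @rdname shannon
#' @export
simpson_evenness <- function(counts_row) {
  p <- nonzero_props(counts_row)
  (1 / sum(p^2)) / length(p)
}

#' Chao1 richness estimator
#'
#' Classic form `S_obs + F1^2 / (2 F2)` from singleton (F1) and doubleton
#' (F2) counts; when no doubletons are present the bias-corrected form
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` is used. Always at least the
#' observed richness.
#'
#' @param counts_row nonnegative integer counts for one sample.
#' @return Estimated total richness.
#' @export
chao1 <- function(counts_row) {
  if (any(abs(counts_row - round(counts_row)) > 1e-8))
    stop("chao1 requires integer counts")
  s_obs <- sum(counts_row > 0)
  f1 <- sum(counts_row == 1)
  f2 <- sum(counts_row == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Fisher's log-series alpha
#'
#' Solves `S = alpha * log(1 + N / alpha)` for alpha by bracketed
#' root-finding (tolerance 1e-9), where S is observed richness and N total
#' counts. Diverges when every individual is a distinct taxon (S = N), in
#' which case `NA` is returned with a warning.
#'
#' @param counts_row nonnegative integer counts for one sample.
#' @return Fisher's alpha, or `NA` when undefined.
#' @export
fisher_alpha <- function(counts_row) {
  if (any(abs(counts_row - round(counts_row)) > 1e-8))
    stop("fisher_alpha requires integer counts")
  s <- sum(counts_row > 0)
  n <- sum(counts_row)
  if (s < 1L) stop("empty sample: all counts are zero")
  if (s == n) {
    warning("Fisher's alpha diverges when all individuals are singletons")
    return(NA_real_)
  }
  f <- function(a) a * log1p(n / a) - s
  lower <- 1e-12
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(lower, upper), tol = 1e-9)$root
}

#' Rank-abundance profile
#'
#' Proportional abundances sorted in descending order; the first element is
#' the Berger-Parker maximum proportion.
#'
#' @param counts_row nonnegative counts for one sample.
#' @return Numeric vector of descending proportions summing to 1.
#' @export
rank_abundance <- function(counts_row) {
  sort(nonzero_props(counts_row), decreasing = TRUE)
}

#' Per-sample diversity profile
#'
#' @param counts samples x taxa nonnegative integer matrix.
#' @param shannon_base log base for Shannon entropy (default 2, bits).
#' @return data.frame with one row per sample: shannon, pielou,
#'   simpson_diversity, simpson_evenness, dominance, chao1, fisher_alpha,
#'   observed_richness.
#' @export
diversity_profile <- function(counts, shannon_base = 2) {
  validate_counts(counts)
  out <- data.frame(
    sample_id = rownames(counts),
    shannon = apply(counts, 1L, shannon, base = shannon_base),
    pielou = apply(counts, 1L, pielou),
    simpson_diversity = apply(counts, 1L, simpson_diversity),
    simpson_evenness = apply(counts, 1L, simpson_evenness),
    dominance = apply(counts, 1L, dominance),
    chao1 = apply(counts, 1L, chao1),
    fisher_alpha = suppressWarnings(apply(counts, 1L, fisher_alpha)),
    observed_richness = rowSums(counts > 0),
    row.names = rownames(counts))
  out
}

#' Contrast diversity metrics between two groups
#'
#' Group means and a pooled-variance Student t-test per metric, as used to
#' compare patients with positive vs negative MMI.
#'
#' @param profile output of [diversity_profile()].
#' @param groups logical or 0/1 vector (TRUE = group of interest), one per
#'   sample.
#' @return data.frame: metric, mean in each group, difference, t, p.
#' @export
group_contrast <- function(profile, groups) {
  g <- as.logical(groups)
  if (length(g) != nrow(profile)) stop("groups and profile differ in length")
  if (!any(g) || all(g)) stop("both groups must be nonempty")
  metrics <- setdiff(names(profile), "sample_id")
  rows <- lapply(metrics, function(m) {
    x <- profile[[m]][g]; y <- profile[[m]][!g]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    tt <- tryCatch(stats::t.test(x, y, var.equal = TRUE),
                   error = function(e) NULL)
    data.frame(metric = m, mean_group1 = mean(x), mean_group0 = mean(y),
               difference = mean(x) - mean(y),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value)
  })
  do.call(rbind, rows)
}
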