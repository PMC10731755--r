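#' Compositional-data primitives for microbiome count tables
#'
#' A taxa count table is a numeric matrix of nonnegative integer counts with
#' samples as rows and taxa as columns, both uniquely named. All downstream
#' analyses (balance search, CLR, diversity) start from this representation.
#'
#' @name composition
NULL

# Validate a samples x taxa count matrix. Returns the matrix invisibly.
validate_counts <- function(counts, require_integer = TRUE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (samples x taxa)")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("count table needs at least 2 samples and 2 taxa")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table must have sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts)) stop("count table contains missing values")
  if (any(counts < 0)) stop("count table contains negative values")
  if (require_integer && any(abs(counts - round(counts)) > 1e-8))
    stop("count table contains non-integer values")
  invisible(counts)
}

#' Filter taxa by prevalence
#'
#' Removes taxa that are unobserved (zero count) in at least
#' `max_unobserved_fraction` of samples; a taxon is retained exactly when its
#' fraction of zero-count samples is strictly below the threshold. The
#' inclusive reading means a taxon absent from exactly 20% of samples is
#' excluded under the default.
#'
#' @param counts samples x taxa matrix of nonnegative integer counts with
#'   dimnames.
#' @param max_unobserved_fraction taxa with a zero fraction at or above this
#'   value are dropped (default 0.20).
#' @return The filtered count matrix; column order of retained taxa preserved.
#' @examples
#' m <- matrix(c(5, 0, 1, 2, 3, 4), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("A", "B", "C")))
#' colnames(prevalence_filter(m, 0.5))
#' @export
prevalence_filter <- function(counts, max_unobserved_fraction = 0.20) {
  validate_counts(counts)
  stopifnot(is.numeric(max_unobserved_fraction), length(max_unobserved_fraction) == 1L,
            max_unobserved_fraction >= 0)
  zero_frac <- colMeans(counts == 0)
  keep <- zero_frac < max_unobserved_fraction
  if (!any(keep)) stop("no taxa survive the prevalence filter")
  counts[, keep, drop = FALSE]
}

#' Replace zero counts with small uniform draws
#'
#' Sparse 16S count tables contain many zeros that break log-ratio analysis.
#' Each zero cell is replaced by an independent uniform draw on
#' `[low, high)`; nonzero cells are untouched. Replacement is performed once
#' per dataset under one seed, before closure.
#'
#' @param counts samples x taxa nonnegative count matrix.
#' @param low,high bounds of the uniform replacement draw (defaults 0.01, 1).
#' @param seed optional integer; when supplied the replacement is
#'   reproducible and the caller's RNG state is left untouched.
#' @return A strictly positive real matrix of the same shape and dimnames.
#' @export
replace_zeros <- function(counts, low = 0.01, high = 1.0, seed = NULL) {
  validate_counts(counts, require_integer = FALSE)
  stopifnot(low > 0, high > low)
  zero_idx <- which(counts == 0)
  if (length(zero_idx) == 0L) return(counts)
  draw <- function() stats::runif(length(zero_idx), min = low, max = high)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  counts[zero_idx] <- draw()
  counts
}

#' Close a positive matrix to row proportions
#'
#' Divides each row by its sum so every sample becomes a composition
#' (proportions summing to one). Idempotent.
#'
#' @param mat samples x taxa matrix of strictly positive reals.
#' @return Matrix of row-wise proportions.
#' @export
closure <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("closure expects a numeric matrix")
  if (any(mat <= 0)) stop("closure requires strictly positive entries; replace zeros first")
  sweep(mat, 1L, rowSums(mat), "/")
}

#' Geometric mean
#'
#' Computed in log space for numerical stability.
#'
#' @param x vector of strictly positive reals.
#' @return `exp(mean(log(x)))`.
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0L) stop("geometric_mean of an empty vector is undefined")
  if (any(!is.finite(x)) || any(x <= 0)) stop("geometric_mean requires positive finite values")
  exp(mean(log(x)))
}

#' Centered log-ratio transform
#'
#' Maps each composition row x to `log(x) - mean(log(x))`, producing zero-sum
#' rows. The natural log is the conventional choice; the base only rescales
#' the output and is exposed for completeness.
#'
#' @param comp samples x taxa matrix of strictly positive proportions (or any
#'   strictly positive matrix; CLR is closure-invariant).
#' @param base log base (default natural).
#' @return Real matrix of the same shape; every row sums to zero.
#' @export
clr_transform <- function(comp, base = exp(1)) {
  if (!is.matrix(comp) || !is.numeric(comp)) stop("clr_transform expects a numeric matrix")
  if (any(comp <= 0)) stop("clr_transform requires strictly positive entries; replace zeros first")
  lx <- log(comp, base = base)
  lx - rowMeans(lx)
}

#' Construct a microbial balance
#'
#' A balance contrasts two disjoint, nonempty subsets of taxa through the
#' log-ratio of their geometric means, scaled by the normalization
#' coefficient `sqrt(p*q/(p+q))` for numerator size p and denominator size q
#' (equal to 1 when p = q = 2). The fitted 4-taxon balance of this package is
#' the microbiome mortality index (MMI).
#'
#' @param numerator,denominator character vectors of taxon ids; disjoint and
#'   nonempty.
#' @param log_base base of the log-ratio (default 10, for interpretability of
#'   order-of-magnitude contrasts).
#' @return An object of class `"balance"`.
#' @export
balance <- function(numerator, denominator, log_base = 10) {
  numerator <- as.character(numerator); denominator <- as.character(denominator)
  if (length(numerator) < 1L || length(denominator) < 1L)
    stop("numerator and denominator must each contain at least one taxon")
  if (anyDuplicated(numerator) || anyDuplicated(denominator))
    stop("duplicated taxon within a balance subset")
  if (length(intersect(numerator, denominator)) > 0L)
    stop("numerator and denominator must be disjoint")
  stopifnot(is.numeric(log_base), log_base > 0, log_base != 1)
  structure(
    list(numerator = numerator, denominator = denominator, log_base = log_base),
    class = "balance")
}

#' @rdname balance
#' @param p,q numerator and denominator sizes.
#' @export
balance_coefficient <- function(p, q) sqrt(p * q / (p + q))

#' @export
print.balance <- function(x, ...) {
  cat(sprintf("<balance> log%g [ g(%s) / g(%s) ] * %.4f\n", x$log_base,
              paste(x$numerator, collapse = ","),
              paste(x$denominator, collapse = ","),
              balance_coefficient(length(x$numerator), length(x$denominator))))
  invisible(x)
}

#' Evaluate a balance on compositional data
#'
#' Returns `sqrt(pq/(p+q)) * log_base(g(numerator)/g(denominator))` per
#' sample, where g is the geometric mean. Scale-invariant per sample, so it
#' may be computed on zero-replaced counts or on closed proportions
#' interchangeably.
#'
#' @param comp samples x taxa matrix of strictly positive values with taxon
#'   column names, or a single named positive vector.
#' @param bal a [balance()].
#' @return Numeric vector of per-sample balance values.
#' @export
balance_value <- function(comp, bal) {
  stopifnot(inherits(bal, "balance"))
  if (is.vector(comp)) comp <- matrix(comp, nrow = 1L, dimnames = list("s1", names(comp)))
  missing_taxa <- setdiff(c(bal$numerator, bal$denominator), colnames(comp))
  if (length(missing_taxa) > 0L)
    stop("taxa absent from the table: ", paste(missing_taxa, collapse = ", "))
  sub <- comp[, c(bal$numerator, bal$denominator), drop = FALSE]
  if (any(sub <= 0)) stop("balance_value requires strictly positive abundances")
  p <- length(bal$numerator); q <- length(bal$denominator)
  lx <- log(comp[, , drop = FALSE])
  num <- rowMeans(lx[, bal$numerator, drop = FALSE])
  den <- rowMeans(lx[, bal$denominator, drop = FALSE])
  unname(balance_coefficient(p, q) * (num - den) / log(bal$log_base))
}

#' Spearman correlation matrix between targets and features
#'
#' Rank correlations (average ranks for ties) of each target column against
#' each feature column, as used to relate the MMI and its component taxa to
#' the wider community.
#'
#' @param values samples x features numeric matrix.
#' @param targets samples x k numeric matrix (or vector).
#' @return k x features matrix of Spearman correlations; a constant target or
#'   feature column yields `NA` entries rather than an error.
#' @export
spearman_matrix <- function(values, targets) {
  if (is.vector(targets)) targets <- matrix(targets, ncol = 1L, dimnames = list(NULL, "target"))
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  if (nrow(values) != nrow(targets)) stop("values and targets must have the same number of samples")
  if (nrow(values) < 3L) stop("need at least 3 samples for rank correlations")
  out <- suppressWarnings(stats::cor(targets, values, method = "spearman"))
  out[!is.finite(out)] <- NA_real_
  out
}
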