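#' Sparse (optionally supervised) principal components
#'
#' Sequential rank-1 decomposition of column-centered CLR abundances by
#' truncated power iteration: each loading vector is hard-thresholded to its
#' `budget` largest-magnitude entries and renormalized at every iteration,
#' with projection deflation between components. When a supervising vector
#' (e.g. the MMI) is supplied, features are first screened to those whose
#' absolute Spearman correlation with the supervisor exceeds a configurable
#' quantile of all such correlations. With `budget` equal to the number of
#' features and no supervision the procedure reduces to ordinary PCA.
#'
#' @param x samples x features numeric matrix (CLR-transformed abundances).
#' @param k number of components (default 2).
#' @param budget maximum nonzero loadings per component.
#' @param supervise_with optional per-sample numeric vector used for feature
#'   screening and component sign orientation.
#' @param screen_quantile quantile of |Spearman correlation| below which
#'   features are screened out when supervising (default 0.5).
#' @param max_iter,tol power-iteration controls.
#' @return Object of class `"sparse_pca"`: `loadings` (features x k, zeros
#'   outside each component's support, unit L2 columns), `scores`
#'   (samples x k), `explained_variance`, `converged` flags, and the
#'   retained feature names (`screened_features`).
#' @export
sparse_pca <- function(x, k = 2L, budget = ncol(x), supervise_with = NULL,
                       screen_quantile = 0.5, max_iter = 500L, tol = 1e-10) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 samples")
  if (budget < 1L) stop("budget must be at least 1")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  all_features <- colnames(x)

  if (!is.null(supervise_with)) {
    if (length(supervise_with) != nrow(x)) stop("supervise_with length mismatch")
    rho <- abs(drop(spearman_matrix(x, supervise_with)))
    rho[is.na(rho)] <- 0
    keep <- rho >= stats::quantile(rho, screen_quantile)
    if (sum(keep) < 2L) keep <- rank(-rho) <= 2  # always keep >= 2 features
    x <- x[, keep, drop = FALSE]
  }
  budget <- min(budget, ncol(x))
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(xc) < 1e-12)) stop("matrix has no variance")
  total_var <- sum(xc^2)

  hard_threshold <- function(v, m) {
    if (sum(v != 0) > m) {
      cut <- sort(abs(v), decreasing = TRUE)[m]
      v[abs(v) < cut] <- 0
      # ties at the cutoff could exceed the budget; keep the first m by index
      nz <- which(v != 0)
      if (length(nz) > m) v[nz[-seq_len(m)]] <- 0
    }
    nrm <- sqrt(sum(v^2))
    if (nrm == 0) stop("thresholding annihilated the loading vector")
    v / nrm
  }

  p <- ncol(xc)
  loadings <- matrix(0, nrow = p, ncol = k, dimnames = list(colnames(xc), NULL))
  scores <- matrix(0, nrow = nrow(xc), ncol = k)
  expl <- numeric(k)
  converged <- logical(k)
  resid <- xc
  for (comp in seq_len(k)) {
    v <- svd(resid, nu = 0, nv = 1)$v[, 1]  # dense leading vector as init
    v <- hard_threshold(v, budget)
    for (it in seq_len(max_iter)) {
      v_new <- drop(crossprod(resid, resid %*% v))
      v_new <- hard_threshold(v_new, budget)
      if (max(abs(abs(v_new) - abs(v))) < tol) { v <- v_new; converged[comp] <- TRUE; break }
      v <- v_new
    }
    if (!converged[comp]) warning("component ", comp, " did not converge in ", max_iter, " iterations")
    s <- drop(resid %*% v)
    # sign convention: positive correlation with the supervisor, else
    # nonnegative first-sample score
    flip <- if (!is.null(supervise_with)) {
      suppressWarnings(stats::cor(s, supervise_with, method = "spearman")) < 0
    } else s[1] < 0
    if (isTRUE(flip)) { v <- -v; s <- -s }
    loadings[, comp] <- v
    scores[, comp] <- s
    expl[comp] <- sum(s^2) / total_var
    resid <- resid - tcrossprod(s, v)  # rank-1 deflation
  }
  structure(list(loadings = loadings, scores = scores,
                 explained_variance = expl, converged = converged,
                 budget = budget, screened_features = colnames(xc),
                 all_features = all_features),
            class = "sparse_pca")
}

#' Rank correlation between component scores and the MMI
#'
#' @param components a [sparse_pca()] result.
#' @param mmi per-sample numeric vector.
#' @return Numeric vector: Spearman correlation of each score column with
#'   the MMI (`NA` for a constant score column).
#' @export
component_mmi_correlation <- function(components, mmi) {
  stopifnot(inherits(components, "sparse_pca"))
  if (length(mmi) != nrow(components$scores)) stop("length mismatch")
  apply(components$scores, 2L, function(s) {
    if (stats::sd(s) == 0) return(NA_real_)
    suppressWarnings(stats::cor(s, mmi, method = "spearman"))
  })
}
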