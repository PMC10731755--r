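# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# AUC as the fraction of concordant (positive, negative) pairs, ties 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Two-sided Fisher p by full enumeration of the hypergeometric support
# (probability-of-table rule).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Rank-formula AUC for larger vectors where the pairwise loop is wasteful.
oracle_auc_fast <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(rank(scores)[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Spearman as Pearson on average ranks.
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# Small planted cohort for search tests: log-abundance matrix where taxa
# "A","B" separate the outcome and the rest are noise.
make_separating_comp <- function(n = 40, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  m <- matrix(exp(rnorm(n * 5)), nrow = n,
              dimnames = list(paste0("s", seq_len(n)), c("A", "B", "C", "D", "E")))
  m[, "A"] <- exp(rnorm(n, mean = 2 * y))     # high in deaths
  m[, "B"] <- exp(rnorm(n, mean = -2 * y))    # low in deaths
  list(comp = m / rowSums(m), outcome = y)
}
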