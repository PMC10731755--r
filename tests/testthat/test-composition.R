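make_counts <- function(mat, samples = paste0("s", seq_len(nrow(mat))),
                        taxa = paste0("t", seq_len(ncol(mat)))) {
  dimnames(mat) <- list(samples, taxa)
  mat
}

test_that("prevalence filter excludes taxa at or above the unobserved threshold", {
  # taxon zero in 2/10 samples (fraction exactly 0.20) is excluded;
  # zero-free taxon retained
  m <- make_counts(cbind(c(0, 0, rep(1, 8)), rep(2, 10), c(0, rep(3, 9))))
  kept <- prevalence_filter(m, 0.20)
  expect_equal(colnames(kept), c("t2", "t3"))

  # 5-sample table checked against direct enumeration of zero fractions
  m5 <- make_counts(cbind(c(0, 1, 1, 1, 1), c(1, 2, 3, 4, 5)))
  zero_frac <- apply(m5, 2, function(col) sum(col == 0) / length(col))
  expect_equal(colnames(prevalence_filter(m5, 0.20)),
               colnames(m5)[zero_frac < 0.20])
  expect_equal(ncol(prevalence_filter(m5, 0.20)), 1L)
})

test_that("prevalence filter edge thresholds and failure mode behave", {
  m <- make_counts(cbind(c(0, 1, 1), c(0, 0, 0), c(1, 1, 1)))
  expect_equal(ncol(prevalence_filter(m, 1 + 1e-9)), 3L)   # retain all
  expect_equal(colnames(prevalence_filter(m, 1e-12)), "t3") # only zero-free
  expect_error(prevalence_filter(make_counts(cbind(c(0, 0), c(0, 0))), 0.2),
               "no taxa survive")
})

test_that("zero replacement is bounded, seeded, and touches only zeros", {
  m <- make_counts(matrix(c(5, 0, 1, 2, 0, 4), nrow = 2))
  expect_identical(replace_zeros(make_counts(matrix(1:4, 2))), make_counts(matrix(1:4, 2)))
  r1 <- replace_zeros(m, seed = 42)
  r2 <- replace_zeros(m, seed = 42)
  r3 <- replace_zeros(m, seed = 43)
  expect_identical(r1, r2)
  zero_cells <- m == 0
  expect_true(all(r1[zero_cells] >= 0.01 & r1[zero_cells] < 1))
  expect_identical(r1[!zero_cells], m[!zero_cells])
  # different seeds differ only at previously-zero cells
  expect_identical(r1[!zero_cells], r3[!zero_cells])
  expect_false(any(r1[zero_cells] == r3[zero_cells]))
  expect_error(replace_zeros(make_counts(matrix(c(-1, 1, 1, 1), 2))), "negative")
})

test_that("closure produces unit-sum rows and is idempotent", {
  expect_equal(closure(make_counts(matrix(c(1, 1, 1, 2, 3, 5), nrow = 2, byrow = TRUE),
                                   taxa = paste0("t", 1:3)))[2, ],
               c(t1 = 0.2, t2 = 0.3, t3 = 0.5))
  expect_equal(unname(closure(matrix(rep(1, 4), 1))), matrix(0.25, 1, 4))
  set.seed(1)
  m <- matrix(rexp(60) + 0.01, nrow = 6)
  cl <- closure(m)
  expect_true(all(abs(rowSums(cl) - 1) < 1e-9))
  expect_equal(closure(cl), cl)
  expect_error(closure(matrix(c(1, 0, 1, 1), 2)), "positive")
})

test_that("geometric mean matches closed forms and rejects bad input", {
  expect_equal(geometric_mean(c(4, 9)), 6)
  expect_equal(geometric_mean(7.3), 7.3)
  expect_equal(geometric_mean(c(0.2, 0.05)), 0.1)
  expect_error(geometric_mean(numeric(0)))
  expect_error(geometric_mean(c(1, 0)))
})

test_that("CLR rows sum to zero, match hand arithmetic, and are closure-invariant", {
  u <- matrix(0.25, 1, 4, dimnames = list("s", paste0("t", 1:4)))
  expect_equal(unname(clr_transform(u)), matrix(0, 1, 4))
  row <- matrix(c(0.5, 0.25, 0.25), 1)
  m <- mean(log(c(0.5, 0.25, 0.25)))
  expect_equal(unname(clr_transform(row)), log(row) - m)
  set.seed(2)
  x <- matrix(rexp(50) + 0.01, nrow = 5)
  expect_true(all(abs(rowSums(clr_transform(x))) < 1e-9))
  expect_equal(clr_transform(closure(x)), clr_transform(x))
  expect_error(clr_transform(matrix(c(1, 0, 1, 1), 2)), "replace zeros")
})

test_that("balance value matches the worked log10 fixture", {
  comp <- matrix(c(0.2, 0.05, 0.01, 0.04), nrow = 1,
                 dimnames = list("s1", c("a", "b", "c", "d")))
  bal <- balance(c("a", "b"), c("c", "d"))
  expect_equal(balance_coefficient(2, 2), 1)
  expect_equal(balance_value(comp, bal), log10(5), tolerance = 1e-12)
  expect_equal(balance_value(comp, bal), 0.69897, tolerance = 1e-5)
  # all four values equal -> 0
  eq <- matrix(0.25, 1, 4, dimnames = list("s", c("a", "b", "c", "d")))
  expect_equal(balance_value(eq, bal), 0)
})

test_that("balance value is antisymmetric, permutation- and scale-invariant", {
  set.seed(3)
  comp <- matrix(rexp(6 * 8) + 0.01, nrow = 6,
                 dimnames = list(paste0("s", 1:6), letters[1:8]))
  bal <- balance(c("a", "c", "e"), c("b", "f"))
  v <- balance_value(comp, bal)
  expect_equal(balance_value(comp, balance(c("b", "f"), c("a", "c", "e"))), -v)
  expect_equal(balance_value(comp, balance(c("e", "a", "c"), c("f", "b"))), v)
  for (cc in c(0.1, 2.7, 100)) {
    scaled <- comp
    scaled[3, ] <- scaled[3, ] * cc
    expect_equal(balance_value(scaled, bal), v, tolerance = 1e-10)
  }
})

test_that("balance construction enforces disjoint nonempty subsets", {
  expect_error(balance(c("a"), c("a", "b")), "disjoint")
  expect_error(balance(character(0), "b"), "at least one")
  comp <- matrix(1, 2, 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_error(balance_value(comp, balance("a", "z")), "z")
})

test_that("spearman matrix matches rank-then-Pearson and flags constants", {
  set.seed(4)
  vals <- matrix(rnorm(5 * 3), nrow = 5)
  targ <- cbind(rnorm(5), c(2, 2, 2, 2, 2))
  sm <- spearman_matrix(vals, targ)
  for (j in 1:3) expect_equal(sm[1, j], oracle_spearman(targ[, 1], vals[, j]))
  expect_true(all(is.na(sm[2, ])))
  expect_equal(unname(spearman_matrix(vals[, 1], vals[, 1])[1, 1]), 1)
  expect_equal(unname(spearman_matrix(-vals[, 1], vals[, 1])[1, 1]), -1)
  expect_error(spearman_matrix(vals, rnorm(4)), "same number of samples")
})
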