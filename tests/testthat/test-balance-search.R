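test_that("logistic AUC scoring matches the pairwise-concordance oracle", {
  # 8-sample worked fixture with hand-ordered scores
  comp <- matrix(exp(c(3, 2.5, 2, 0.5, 1.5, 1, 0.2, 0.1)), ncol = 1)
  comp <- cbind(comp, 1)  # reference taxon
  dimnames(comp) <- list(paste0("s", 1:8), c("a", "b"))
  comp <- comp / rowSums(comp)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  res <- score_balance(balance("a", "b"), comp, y)
  b <- balance_value(comp, balance("a", "b"))
  expect_equal(res$score, oracle_auc(b, y))
  expect_true(res$score >= 0 && res$score <= 1)
})

test_that("a perfectly separating balance scores AUC 1 and noise scores ~0.5", {
  set.seed(10)
  y <- rep(c(0L, 1L), each = 10)
  comp <- matrix(exp(rnorm(40)), nrow = 20, dimnames = list(paste0("s", 1:20), c("a", "b")))
  comp[, "a"] <- exp(ifelse(y == 1, 2, -2))
  comp <- comp / rowSums(comp)
  expect_equal(score_balance(balance("a", "b"), comp, y)$score, 1)

  set.seed(11)
  y2 <- rbinom(200, 1, 0.5)
  noise <- matrix(exp(rnorm(400)), nrow = 200,
                  dimnames = list(paste0("s", 1:200), c("a", "b")))
  noise <- noise / rowSums(noise)
  expect_lt(abs(score_balance(balance("a", "b"), noise, y2)$score - 0.5), 0.1)
})

test_that("score_balance rejects a single-class outcome", {
  comp <- matrix(c(0.4, 0.6, 0.5, 0.5), 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_error(score_balance(balance("a", "b"), comp, c(1, 1)), "single class")
})

test_that("best initial pair finds the separating taxa by exhaustive scan", {
  fx <- make_separating_comp(n = 40, seed = 5)
  best <- best_initial_pair(fx$comp, fx$outcome)
  expect_setequal(c(best$numerator, best$denominator), c("A", "B"))
  # oriented so the balance tracks the adverse outcome
  expect_equal(best$numerator, "A")
  # exhaustive verification: no other pair scores higher
  taxa <- colnames(fx$comp)
  all_scores <- combn(taxa, 2, function(pr)
    score_balance(balance(pr[1], pr[2]), fx$comp, fx$outcome)$score)
  expect_equal(best$score, max(all_scores), tolerance = 1e-10)
})

test_that("exact pair ties break lexicographically", {
  set.seed(6)
  y <- rep(c(0L, 1L), 10)
  base <- exp(rnorm(20))
  # duplicated columns create exact ties between {a,c} and {a,d} style pairs
  comp <- cbind(d = base * exp(y), a = exp(rnorm(20)), c = base * exp(y))
  rownames(comp) <- paste0("s", 1:20)
  comp <- comp / rowSums(comp)
  best <- best_initial_pair(comp, y)
  key <- paste(sort(c(best$numerator, best$denominator)), collapse = "")
  expect_equal(key, "ac")  # lexicographically before "ad" variants with equal score
})

test_that("greedy extension adds a planted taxon on the correct side", {
  recovered <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    n <- 120
    y <- rep(c(0L, 1L), length.out = n)
    # three numerator-planted taxa plus noise
    m <- matrix(exp(rnorm(n * 6)), nrow = n,
                dimnames = list(paste0("s", 1:n), c("A", "B", "C", "D", "E", "F")))
    for (tx in c("A", "B")) m[, tx] <- exp(rnorm(n, mean = 1.5 * y))
    m[, "C"] <- exp(rnorm(n, mean = -1.5 * y))
    comp <- m / rowSums(m)
    cand <- list(numerator = "A", denominator = "C")
    ext <- extend_balance(cand, comp, y)
    if ("B" %in% ext$numerator) recovered <- recovered + 1L
  }
  expect_gte(recovered, 4L)
})

test_that("extend_balance errors when no taxa remain", {
  comp <- matrix(c(0.4, 0.6, 0.5, 0.5), 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_error(extend_balance(list(numerator = "a", denominator = "b"), comp, c(0, 1)),
               "no taxa remain")
})

test_that("cv_select_size is deterministic under a seed and respects rules", {
  fx <- make_separating_comp(n = 60, seed = 7)
  s1 <- cv_select_size(fx$comp, fx$outcome, max_size = 4, n_repeats = 2, seed = 99)
  s2 <- cv_select_size(fx$comp, fx$outcome, max_size = 4, n_repeats = 2, seed = 99)
  expect_identical(s1, s2)
  expect_true(s1$selected_size %in% s1$scores_by_size$size)
  smax <- cv_select_size(fx$comp, fx$outcome, max_size = 4, n_repeats = 2,
                         rule = "max", seed = 99)
  # the 1se choice is never more complex than the max-rule choice
  expect_lte(s1$selected_size, smax$selected_size)
})

test_that("cv_select_size reduces folds when a class is too small", {
  set.seed(8)
  comp <- matrix(exp(rnorm(30)), nrow = 10,
                 dimnames = list(paste0("s", 1:10), c("a", "b", "c")))
  comp <- comp / rowSums(comp)
  y <- c(1, 1, 1, rep(0, 7))
  expect_warning(cv_select_size(comp, y, max_size = 2, n_folds = 5,
                                n_repeats = 1, seed = 1), "reducing n_folds")
})

test_that("fit_mmi is deterministic, disjoint, and oriented toward death", {
  coh <- generate_cohort(synthetic_config(n_samples = 80, n_taxa = 20,
                                          balance_effect_beta = 3, seed = 21))
  cfg <- mmi_config(seed = 21, n_repeats = 2)
  f1 <- fit_mmi(coh$counts, coh$metadata, cfg)
  f2 <- fit_mmi(coh$counts, coh$metadata, cfg)
  expect_identical(f1$balance, f2$balance)
  expect_identical(f1$mmi, f2$mmi)

  expect_length(intersect(f1$balance$numerator, f1$balance$denominator), 0)
  expect_true(all(c(f1$balance$numerator, f1$balance$denominator) %in%
                    colnames(coh$counts)))
  expect_identical(f1$mmi_positive, f1$mmi > 0)
  y <- coh$metadata$death28
  expect_gte(mean(f1$mmi[y == 1]), mean(f1$mmi[y == 0]))
  p <- length(f1$balance$numerator); q <- length(f1$balance$denominator)
  expect_equal(p + q, f1$selected_size)
})

test_that("covariates-only information bounds: informative balance raises apparent AUC", {
  fx <- make_separating_comp(n = 60, seed = 12)
  covariates <- matrix(rnorm(60), ncol = 1, dimnames = list(NULL, "age"))
  with_bal <- score_balance(balance("A", "B"), fx$comp, fx$outcome, covariates)$score
  # covariate-only AUC via the same machinery: a constant balance adds nothing
  const_comp <- cbind(fx$comp, z1 = 0.5, z2 = 0.5) / (rowSums(fx$comp) + 1)
  cov_only <- score_balance(balance("z1", "z2"), const_comp, fx$outcome, covariates)$score
  expect_gte(with_bal, cov_only)
})
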