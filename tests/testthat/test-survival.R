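test_that("fisher exact matches full hypergeometric enumeration on small tables", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1.0)
  set.seed(30)
  for (i in 1:30) {
    n <- sample(4:15, 1)
    cells <- as.vector(rmultinom(1, n, rep(0.25, 4)))
    tab <- matrix(cells, 2)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), oracle_fisher_p(tab), tolerance = 1e-7)
  }
})

test_that("fisher exact is invariant to transpose and row/column swaps", {
  tab <- matrix(c(9, 2, 4, 11), 2)
  p <- fisher_exact_2x2(tab)
  expect_equal(fisher_exact_2x2(t(tab)), p)
  expect_equal(fisher_exact_2x2(tab[2:1, 2:1]), p)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("wilcoxon exact enumeration fixture and tie handling hold", {
  # 2 of the 20 equally likely rank assignments are as extreme
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12), mode = "exact"), 0.1)
  expect_warning(p <- wilcoxon_rank_sum(rep(2, 4), rep(2, 5)), "identical")
  expect_equal(p, 1)
  # identical multisets: stochastic equality, p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 5, 9), c(1, 5, 9), mode = "normal"), 1,
               tolerance = 1e-6)
})

test_that("normal-approximation wilcoxon p tracks the exact p", {
  set.seed(31)
  max_diff <- 0
  for (i in 1:100) {
    x <- rnorm(10); y <- rnorm(10, mean = 0.5)
    p_ex <- wilcoxon_rank_sum(x, y, mode = "exact")
    p_no <- wilcoxon_rank_sum(x, y, mode = "normal")
    max_diff <- max(max_diff, abs(p_ex - p_no))
  }
  expect_lt(max_diff, 0.01)
})

test_that("pooled t-test matches the closed form and is antisymmetric", {
  x <- c(1, 2, 3, 4); y <- c(3, 4, 5, 6)
  res <- t_test_two_sample(x, y)
  # closed form: t = (mx - my) / (sp * sqrt(1/4 + 1/4)), sp^2 pooled
  sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
  t_hand <- (mean(x) - mean(y)) / (sp * sqrt(0.5))
  expect_equal(res$t, t_hand)
  expect_equal(res$df, 6)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 6))
  swapped <- t_test_two_sample(y, x)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  expect_equal(t_test_two_sample(c(1, 2, 9), c(1, 2, 9))$p, 1)
  expect_error(t_test_two_sample(c(2, 2), c(2, 2)), "variance")
})

test_that("kaplan-meier matches the product-limit closed forms", {
  # no events: flat at 1
  km0 <- km_estimator(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # 31 subjects, 21 uncensored deaths before day 28
  times <- c(seq(2, 26, length.out = 21), rep(40, 10))
  events <- c(rep(1, 21), rep(0, 10))
  km <- km_estimator(times, events)
  expect_equal(km_survival_at(km, 28), 10 / 31)
  # one death among n at t=5
  km1 <- km_estimator(c(5, rep(9, 7)), c(1, rep(0, 7)))
  expect_equal(km_survival_at(km1, 5), 7 / 8)
  expect_error(km_estimator(numeric(0), logical(0)), "empty")
})

test_that("without censoring the KM curve equals the empirical survival function", {
  set.seed(32)
  times <- sample(1:60, 40, replace = TRUE)
  km <- km_estimator(times, rep(1, 40))
  for (t in c(5, 20, 35, 59)) {
    expect_equal(km_survival_at(km, t), mean(times > t))
  }
  expect_true(all(diff(km$surv) <= 1e-12))
})

test_that("unpenalized cox_fit agrees with a grid-search partial likelihood", {
  set.seed(33)
  n <- 30
  x <- rnorm(n)
  tt <- rexp(n, rate = 0.1 * exp(0.8 * x))
  fit <- cox_fit(data.frame(x = x), tt, rep(1, n), penalizer = 0, horizon_days = Inf)
  # independent oracle: maximize the Breslow log partial likelihood on a grid
  logpl <- function(b) {
    ord <- order(tt)
    xs <- x[ord]
    risk <- rev(cumsum(rev(exp(b * xs))))
    sum(b * xs - log(risk))
  }
  grid <- seq(-2, 3, by = 1e-3)
  b_star <- grid[which.max(vapply(grid, logpl, numeric(1)))]
  expect_equal(fit$table$coef, b_star, tolerance = 5e-3)
  expect_true(fit$table$ci_lower <= fit$table$hazard_ratio)
  expect_true(fit$table$ci_upper >= fit$table$hazard_ratio)
})

test_that("cox_fit under the null brackets HR = 1 and censors at the horizon", {
  set.seed(34)
  n <- 400
  g <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.05)
  fit <- cox_fit(data.frame(group = g), tt, rep(1, n), penalizer = 0)
  expect_lt(fit$table$ci_lower, 1)
  expect_gt(fit$table$ci_upper, 1)
  expect_equal(fit$n_events, sum(tt <= 28))
})

test_that("penalized fits shrink toward zero and handle a single covariate", {
  set.seed(35)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.05 * exp(0.9 * x))
  free <- cox_fit(data.frame(x = x), tt, rep(1, n), penalizer = 0)
  pen <- cox_fit(data.frame(x = x), tt, rep(1, n), penalizer = 0.05)
  expect_lt(abs(pen$table$coef), abs(free$table$coef))
  expect_gt(pen$table$hazard_ratio, 1)
  expect_warning(
    two <- cox_fit(data.frame(x = x, flat = 1), tt, rep(1, n), penalizer = 0.05),
    "constant")
  expect_equal(two$table$variable, "x")
})

test_that("bivariate table routes tests by variable type", {
  set.seed(36)
  n <- 60
  md <- data.frame(
    sample_id = paste0("s", 1:n),
    death28 = rep(c(1, 0), each = n / 2),
    apache2 = c(rnorm(n / 2, 30, 5), rnorm(n / 2, 24, 5)),
    ards = rbinom(n, 1, 0.5),
    constant_flag = rep(1, n))
  tab <- bivariate_table(md, grouping = "death28")
  expect_equal(tab$test[tab$variable == "apache2"], "wilcoxon")
  expect_equal(tab$test[tab$variable == "ards"], "fisher")
  expect_true(is.na(tab$p[tab$variable == "constant_flag"]))
  # quantitative p matches a direct wilcoxon on the same split
  p_direct <- wilcoxon_rank_sum(md$apache2[md$death28 == 1],
                                md$apache2[md$death28 == 0], mode = "normal")
  expect_equal(tab$p[tab$variable == "apache2"], p_direct)
})
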