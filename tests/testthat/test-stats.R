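test_that("equal constant samples carry no signal", {
  res <- associate(rep(5, 10), rep(c("a", "b"), each = 5))
  expect_identical(res$test, "wilcoxon")
  expect_gt(res$p_value, 0.99)
})

test_that("the Wilcoxon branch agrees with exhaustive permutation", {
  res <- associate(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  orc <- oracle_wilcoxon(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, orc$statistic)
  expect_equal(res$p_value, orc$p_value)

  set.seed(88)
  for (i in 1:15) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    v <- sample(seq_len(40), n1 + n2)  # distinct values: no ties
    g <- rep(c("a", "b"), c(n1, n2))
    res <- associate(v, g)
    orc <- oracle_wilcoxon(v[g == "a"], v[g == "b"])
    expect_equal(res$statistic, orc$statistic, label = paste("stat rep", i))
    expect_equal(res$p_value, orc$p_value, label = paste("p rep", i))
  }
})

test_that("three or more groups dispatch to Kruskal-Wallis", {
  v <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- associate(v, g)
  expect_identical(res$test, "kruskal_wallis")
  expect_equal(res$statistic, unname(kruskal.test(v, factor(g))$statistic))
})

test_that("categorical pairs dispatch to an uncorrected chi-square", {
  vals <- rep(c("x", "y"), each = 10)
  grps <- rep(c("a", "b"), each = 10)  # perfectly concordant 2x2
  res <- associate(vals, grps)
  expect_identical(res$test, "chi_square")
  expect_equal(res$statistic, 20)  # closed form for {{10,0},{0,10}}
  expect_lt(res$p_value, 0.01)
})

test_that("unobserved groups raise an error naming the group", {
  expect_error(associate(1:4, factor(rep("a", 4), levels = c("a", "b"))),
               "b")
  expect_error(associate(1:4, rep("a", 4)), "at least 2")
})

test_that("BH adjustment matches the step-up formula and its properties", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))

  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(1:10, 1))
    adj <- adjust_bh(p)
    expect_equal(adj, oracle_bh(p), label = paste("family", i))
    expect_true(all(adj >= p))
    expect_true(!is.unsorted(adj[order(p)]))  # order-preserving
    expect_true(all(adjust_bh(adj) >= adj))   # re-adjusting never decreases
  }
  # flat families are fixed points of the step-up procedure
  expect_equal(adjust_bh(rep(0.3, 6)), rep(0.3, 6))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("log-rank matches the hand-computed O-E statistic", {
  t_a <- c(1, 2, 3); t_b <- c(10, 20, 30)
  res <- survival_logrank(c(t_a, t_b), rep(1, 6),
                          rep(c("A", "B"), each = 3), horizon_months = Inf)
  expect_equal(res$statistic,
               oracle_logrank(c(t_a, t_b), rep(1, 6),
                              rep(c("A", "B"), each = 3)))
  ident <- survival_logrank(c(5, 9, 5, 9), rep(1, 4), rep(c("A", "B"), each = 2))
  expect_equal(ident$statistic, 0, tolerance = 1e-12)
})

test_that("events beyond the horizon are administratively censored", {
  res <- survival_logrank(c(70, 10, 20, 30), c(1, 1, 1, 0),
                          c("A", "A", "B", "B"), horizon_months = 60)
  # the 70-month event must count as censored at 60, not as an event
  expect_equal(sum(res$fit$n.event), 2)
  expect_equal(max(res$fit$time), 60)
})

test_that("the KM estimator is the empirical survivor function without censoring", {
  tm <- c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10)
  g <- rep(c("A", "B"), each = 5)
  res <- survival_logrank(tm, rep(1, 10), g, horizon_months = Inf)
  s <- res$fit[1]  # group A
  expect_equal(s$surv, 1 - ecdf(tm[g == "A"])(s$time))
  expect_true(all(diff(res$fit$surv[seq_len(5)]) <= 0))
})

test_that("feature screens adjust p values as one family", {
  set.seed(3)
  d <- data.frame(f1 = rnorm(20), f2 = rnorm(20), f3 = c(rnorm(10), rnorm(10, 4)),
                  grp = rep(c("a", "b"), each = 10))
  tab <- associate_table(d, c("f1", "f2", "f3"), "grp")
  expect_identical(nrow(tab), 3L)
  expect_equal(tab$p_adjusted, adjust_bh(tab$p_value))
  expect_true(all(tab$p_adjusted >= tab$p_value))
})
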