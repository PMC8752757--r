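test_that("pooled t-test matches the closed-form oracle and handles degeneracy", {
  r <- student_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3 * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(r$df, 4)
  o <- oracle_pooled_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, o$p_value, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1))
    r <- student_t(x, y)
    o <- oracle_pooled_t(x, y)
    expect_equal(r$statistic, o$statistic, tolerance = 1e-9)
    expect_equal(r$p_value, o$p_value, tolerance = 1e-9)
    # permuting within groups changes nothing
    r2 <- student_t(sample(x), sample(y))
    expect_equal(r2$statistic, r$statistic, tolerance = 1e-12)
  }

  ident <- student_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  flat <- student_t(c(1, 1), c(1, 1))
  expect_equal(flat$p_value, 1)
  expect_warning(unequal <- student_t(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(unequal$p_value, 0)

  # Welch differs from pooled under unequal variances
  x <- c(1, 2, 3, 10); y <- c(4.1, 4.2, 4.05)
  expect_false(isTRUE(all.equal(student_t(x, y, welch = TRUE)$p_value,
                                student_t(x, y)$p_value)))
})

test_that("one-way ANOVA matches the sum-of-squares oracle, drops singletons, equals t^2 on two groups", {
  g <- list(c(1, 2, 3), c(2, 4, 6, 8), c(0, 1))
  r <- one_way_anova(g)
  o <- oracle_anova_f(g)
  expect_equal(r$statistic, o$statistic, tolerance = 1e-9)
  expect_equal(r$p_value, o$p_value, tolerance = 1e-9)

  x <- c(1, 3, 5, 7); y <- c(2, 3, 1)
  f2 <- one_way_anova(list(x, y))
  expect_equal(f2$statistic, student_t(x, y)$statistic^2, tolerance = 1e-9)

  const <- one_way_anova(list(c(2, 2), c(2, 2, 2)))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)

  expect_message(dropped <- one_way_anova(list(c(1, 2), c(5), c(3, 4))),
                 "dropping")
  expect_equal(dropped$statistic,
               one_way_anova(list(c(1, 2), c(3, 4)))$statistic)
  expect_error(one_way_anova(list(c(1, 2), c(5))), "fewer than 2")
})

test_that("Pearson correlation matches the definition oracle and affine extremes", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$effect, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$effect, -1, tolerance = 1e-12)
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(length(a))
    r <- pearson_r(a, b); o <- oracle_pearson(a, b)
    expect_equal(r$effect, o$r, tolerance = 1e-9)
    expect_equal(r$p_value, o$p_value, tolerance = 1e-9)
  }
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("BH adjustment matches the hand step-up and is monotone", {
  expect_equal(bh_fdr(0.3)$q, 0.3)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$q, rep(0.04, 4))
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(1:15, 1))
    q <- bh_fdr(p)$q
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    # raising one raw p never lowers any q
    j <- sample(length(p), 1)
    p2 <- p; p2[j] <- min(1, p2[j] + runif(1) * (1 - p2[j]))
    expect_true(all(bh_fdr(p2)$q >= q - 1e-12))
  }
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("Kaplan-Meier estimator reproduces the product limit", {
  km <- km_estimator(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  none <- km_estimator(c(1, 5, 7), c(0, 0, 0))
  expect_equal(none$fn(c(0, 3, 10)), c(1, 1, 1))

  set.seed(41)
  time <- rexp(30); event <- rbinom(30, 1, 0.7)
  km <- km_estimator(time, event)
  o <- oracle_km(time, event)
  expect_equal(km$time, o$time)
  expect_equal(km$surv, o$surv, tolerance = 1e-9)
  # duplicating every record leaves S unchanged
  km2 <- km_estimator(rep(time, 2), rep(event, 2))
  expect_equal(km2$surv, km$surv, tolerance = 1e-9)
})

test_that("log-rank test matches the per-event-time tabulation oracle", {
  # 6-subject worked example with a tie
  time <- c(2, 4, 4, 6, 8, 10)
  event <- c(1, 1, 1, 0, 1, 1)
  group <- c("a", "b", "a", "b", "a", "b")
  r <- logrank_test(time, event, group)
  o <- oracle_logrank(time, event, group)
  expect_equal(r$statistic, o$statistic, tolerance = 1e-9)
  expect_equal(r$p_value, o$p_value, tolerance = 1e-9)
  # label swap invariance
  r2 <- logrank_test(time, event, ifelse(group == "a", "b", "a"))
  expect_equal(r2$statistic, r$statistic, tolerance = 1e-12)

  # identical cohorts duplicated into both labels -> chisq 0, p 1
  t0 <- c(1, 3, 5, 9); e0 <- c(1, 0, 1, 1)
  same <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  set.seed(51)
  for (i in 1:10) {
    n <- 20
    time <- round(rexp(n), 1)  # force ties
    event <- rbinom(n, 1, 0.8)
    group <- rep(c("a", "b"), 10)
    if (sum(event) == 0) next
    r <- logrank_test(time, event, group)
    o <- oracle_logrank(time, event, group)
    expect_equal(r$statistic, o$statistic, tolerance = 1e-9)
  }
  expect_warning(none <- logrank_test(c(1, 2), c(0, 0), c("a", "b")), "no events")
  expect_equal(none$p_value, 1)
})

test_that("Fisher exact test matches full margin-fixed enumeration", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1)$p_value, 1)
  r <- fisher_exact_2x2(8, 2, 1, 5)
  expect_equal(r$p_value, oracle_fisher_p(8, 2, 1, 5), tolerance = 1e-9)
  # transpose invariance
  expect_equal(fisher_exact_2x2(8, 1, 2, 5)$p_value, r$p_value, tolerance = 1e-12)
  set.seed(61)
  for (i in 1:25) {
    cells <- rpois(4, 4) + c(1, 0, 0, 1)
    if (any(rowSums(matrix(cells, 2, byrow = TRUE)) == 0) ||
        any(colSums(matrix(cells, 2, byrow = TRUE)) == 0)) next
    expect_equal(do.call(fisher_exact_2x2, as.list(cells))$p_value,
                 do.call(oracle_fisher_p, as.list(cells)), tolerance = 1e-9)
  }
  # continuity-corrected odds ratio on a zero cell
  expect_equal(fisher_exact_2x2(0, 5, 3, 2)$effect,
               (0.5 * 2.5) / (5.5 * 3.5), tolerance = 1e-12)
  expect_error(fisher_exact_2x2(0, 0, 3, 2), "margin")
})

test_that("hypergeometric tail matches exhaustive subset enumeration", {
  expect_equal(hypergeom_tail(0, 4, 10, 5), 1)
  expect_equal(hypergeom_tail(4, 4, 10, 5),
               oracle_hypergeom_tail(4, 4, 10, 5), tolerance = 1e-9)
  for (ov in 0:4) {
    expect_equal(hypergeom_tail(ov, 4, 10, 5),
                 oracle_hypergeom_tail(ov, 4, 10, 5), tolerance = 1e-9)
  }
  # non-increasing in overlap
  ps <- vapply(0:4, function(ov) hypergeom_tail(ov, 4, 10, 5), numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(hypergeom_tail(5, 4, 10, 5), "inconsistent")
})

test_that("quantile normalization equalizes columns, preserves ranks, is idempotent", {
  m <- cbind(a = c(1, 3), b = c(2, 4))
  expect_equal(unname(quantile_normalize(m)), cbind(c(1.5, 3.5), c(1.5, 3.5)))

  ident <- matrix(c(5, 1, 7, 5, 1, 7), ncol = 2)
  expect_equal(quantile_normalize(ident), ident)

  # tie-free matrix: columns share the exact rank-mean distribution and the
  # operation is idempotent
  set.seed(70)
  m0 <- matrix(abs(rnorm(60, 20)), 15, 4)
  qn0 <- quantile_normalize(m0)
  for (j in 1:4) {
    expect_equal(sort(qn0[, j]), sort(qn0[, 1]), tolerance = 1e-9)
    expect_equal(rank(qn0[, j]), rank(m0[, j]))
  }
  expect_equal(quantile_normalize(qn0), qn0, tolerance = 1e-9)

  # tied counts: ties within a column get the mean of their rank values
  set.seed(71)
  m <- matrix(rpois(60, 20), 15, 4)
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), unname(oracle_quantile_normalize(m)), tolerance = 1e-9)
  for (j in 1:4) expect_equal(rank(qn[, j]), rank(m[, j]))
  expect_warning(one <- quantile_normalize(m[, 1, drop = FALSE]), "single column")
  expect_equal(one, m[, 1, drop = FALSE])
})

test_that("tumor volume formula", {
  expect_equal(tumor_volume(10, 6), 180)
  expect_equal(tumor_volume(2, 2), 4)
  expect_equal(tumor_volume(7.2, 5.1), 0.5 * 7.2 * 5.1^2, tolerance = 1e-12)
  expect_error(tumor_volume(5, 6), "swapped")
})
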