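test_that("group_summary computes mean and SEM", {
  gs <- group_summary(c(5, 5, 5))
  expect_equal(gs$mean, 5); expect_equal(gs$sem, 0)
  gs2 <- group_summary(c(1, 2, 3))
  expect_equal(gs2$mean, 2)
  expect_equal(gs2$sem, 1 / sqrt(3))
  expect_warning(gs1 <- group_summary(42), "n = 1")
  expect_equal(gs1$sem, 0)
  expect_error(group_summary(numeric(0)), "empty")
  # invariance under shift
  expect_equal(group_summary(c(1, 2, 3) + 100)$sem, gs2$sem)
})

test_that("raw-mode t-tests agree with the stats::t.test oracle", {
  set.seed(5)
  for (rep in 1:10) {
    a <- rnorm(sample(3:20, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:20, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    ts <- ttest_unpaired(a, b, variant = "student")
    ref_s <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(ts$t, unname(ref_s$statistic), tolerance = 1e-12)
    expect_equal(ts$df, unname(ref_s$parameter), tolerance = 1e-12)
    expect_equal(ts$p, ref_s$p.value, tolerance = 1e-12)
    tw <- ttest_unpaired(a, b, variant = "welch")
    ref_w <- stats::t.test(a, b)
    expect_equal(tw$t, unname(ref_w$statistic), tolerance = 1e-12)
    expect_equal(tw$df, unname(ref_w$parameter), tolerance = 1e-12)
    expect_equal(tw$p, ref_w$p.value, tolerance = 1e-12)
  }
})

test_that("t-test symmetry and invariances", {
  set.seed(9)
  a <- rnorm(8); b <- rnorm(10, 1)
  t1 <- ttest_unpaired(a, b)
  t2 <- ttest_unpaired(b, a)
  expect_equal(t1$t, -t2$t)
  expect_equal(t1$p, t2$p)
  # shift and positive scaling invariance of t
  t3 <- ttest_unpaired((a + 5) * 2, (b + 5) * 2)
  expect_equal(t3$t, t1$t, tolerance = 1e-12)
  # identical samples: t = 0, p = 1
  t0 <- ttest_unpaired(a, a)
  expect_equal(t0$t, 0); expect_equal(t0$p, 1)
  # student and welch coincide for equal n and equal variance
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  expect_equal(ttest_unpaired(x, y, "student")$t,
               ttest_unpaired(x, y, "welch")$t, tolerance = 1e-12)
  expect_equal(ttest_unpaired(x, y, "student")$df,
               ttest_unpaired(x, y, "welch")$df, tolerance = 1e-12)
  expect_error(ttest_unpaired(1, c(1, 2)), "n >= 2")
})

test_that("summary-mode t-test reproduces the printed group comparison", {
  # means 3 and 0.36, sems 0.56 and 0.23, n = 14 and 14 (per-somite PL
  # counts, sibling vs maternal-zygotic mutant)
  tt <- ttest_unpaired(list(mean = 3, sem = 0.56, n = 14),
                       list(mean = 0.36, sem = 0.23, n = 14),
                       mode = "summary")
  expect_equal(tt$df, 26)
  expect_equal(tt$t, (3 - 0.36) / sqrt(0.56^2 + 0.23^2), tolerance = 1e-12)
  expect_equal(round(tt$t, 2), 4.36)
  expect_lt(tt$p, 0.001)
  # degenerate zero-sem summaries
  eq <- ttest_unpaired(list(mean = 2, sem = 0, n = 5),
                       list(mean = 2, sem = 0, n = 5), mode = "summary")
  expect_equal(eq$p, 1)
  ne <- ttest_unpaired(list(mean = 3, sem = 0, n = 5),
                       list(mean = 2, sem = 0, n = 5), mode = "summary")
  expect_equal(ne$p, 0)
})

test_that("star labels reproduce every printed (p, stars) pair", {
  pairs <- list(list(0.04, "*"), list(0.005, "**"), list(0.0075, "**"),
                list(0.0157, "*"), list(0.0036, "**"), list(0.0006, "***"),
                list(0.014, "*"), list(0.02, "*"), list(0.08, "ns"),
                list(0.24, "ns"), list(0.31, "ns"), list(1, "ns"),
                list(0.00005, "****"))
  for (pr in pairs)
    expect_equal(p_to_stars(pr[[1]]), pr[[2]])
  # gp-style thresholds use <= as printed (0.332 read as 0.0332)
  expect_equal(p_to_stars(0.0332, scheme = "gp"), "*")
  expect_equal(p_to_stars(0.04, scheme = "gp"), "ns")
  expect_equal(p_to_stars(0.0002, scheme = "gp"), "***")
  expect_equal(p_to_stars(0.0021, scheme = "gp"), "**")
  expect_equal(p_to_stars(0.0001, scheme = "gp"), "****")
  expect_error(p_to_stars(1.2), "\\[0, 1\\]")
  expect_error(p_to_stars(-0.1), "\\[0, 1\\]")
  # monotone: star count never increases as p grows
  ps <- c(0.00001, 0.0005, 0.004, 0.04, 0.4)
  stars <- vapply(ps, p_to_stars, "")
  rank <- c("****" = 4, "***" = 3, "**" = 2, "*" = 1, ns = 0)
  expect_true(all(diff(rank[stars]) <= 0))
})

test_that("pearson_regression agrees with dual-formula and lm oracles", {
  x <- c(1, 2, 3); y <- c(2, 4, 7)
  res <- pearson_regression(x, y)
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r_cov <- stats::cov(x, y) / (stats::sd(x) * stats::sd(y))
  expect_equal(r_def, r_cov, tolerance = 1e-12)
  expect_equal(res$r, r_def, tolerance = 1e-12)
  fit <- stats::lm(y ~ x)
  expect_equal(res$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(res$intercept, unname(coef(fit)[1]), tolerance = 1e-12)
  ct <- stats::cor.test(x, y)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  # perfect correlation
  res1 <- pearson_regression(1:5, (1:5) * 2 + 1)
  expect_equal(res1$r, 1); expect_equal(res1$r_squared, 1)
  expect_error(pearson_regression(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_regression(1:2, 1:2), "n >= 3")
})

test_that("Fisher-z interval brackets r and narrows with n", {
  set.seed(3)
  for (rep in 1:20) {
    r <- runif(1, -0.95, 0.95)
    n <- sample(5:200, 1)
    ci <- pearson_ci(r, n)
    expect_true(ci[1] <= r && r <= ci[2])
  }
  w <- vapply(c(10, 50, 200, 1000), function(n) diff(pearson_ci(0.5, n)), 0)
  expect_true(all(diff(w) < 0))
  # matches cor.test's Fisher interval on a real sample
  set.seed(11)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  ct <- stats::cor.test(x, y)
  expect_equal(pearson_ci(unname(ct$estimate), 40),
               unname(ct$conf.int[1:2]), tolerance = 1e-6)
})

test_that("legend_string formats like a figure legend", {
  a <- group_summary(c(2, 3, 4)); b <- group_summary(c(5, 6, 7))
  tt <- ttest_unpaired(c(2, 3, 4), c(5, 6, 7))
  s <- legend_string("ctrl", a, "treated", b, tt)
  expect_match(s, "ctrl: 3 ± 0.577, n = 3")
  expect_match(s, "p = ")
})
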