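test_that("site-effect LRT is null at identical sites, decisive at separated ones", {
  # identical sessions everywhere: no information about a site effect
  d0 <- counts_df(rep(c("A", "B", "C"), each = 4), rep(60, 12), rep(60, 12))
  t0 <- site_effect_test(d0)
  expect_equal(t0$statistic, 0, tolerance = 1e-8)
  expect_equal(t0$p_value, 1)
  expect_equal(t0$df, 2)
  # strong separation: decisive
  set.seed(9)
  pf <- rep(c(0.2, 0.5, 0.8), each = 10)
  n <- rep(100, 30)
  y <- rbinom(30, n, pf)
  d1 <- counts_df(rep(c("A", "B", "C"), each = 10), n - y, y)
  t1 <- site_effect_test(d1)
  expect_lt(t1$p_value, 0.001)
  expect_gte(t1$statistic, 0)
  # invariant to relabelling sites
  d2 <- d1; d2$site <- c(A = "Z", B = "Q", C = "M")[d2$site]
  expect_equal(site_effect_test(d2)$statistic, t1$statistic)
  expect_error(site_effect_test(counts_df(rep("A", 5), 1:5, 5:1)), "2 sites")
})

test_that("one-way ANOVA matches hand-computed F and the two-group t identity", {
  null_case <- one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(null_case$statistic, 0, tolerance = 1e-12)
  expect_equal(null_case$p_value, 1, tolerance = 1e-12)
  # two-group F equals the squared pooled t
  set.seed(13)
  x <- rnorm(12); g <- rep(c("a", "b"), each = 6)
  f2 <- one_way_anova(x, g)
  tt <- t.test(x[g == "a"], x[g == "b"], var.equal = TRUE)
  expect_equal(f2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(f2$p_value, tt$p.value, tolerance = 1e-10)
  # unbalanced 6 groups vs the textbook sum-of-squares computation
  set.seed(14)
  g6 <- rep(letters[1:6], times = c(8, 10, 9, 10, 7, 10))
  x6 <- rnorm(length(g6)) + (g6 == "c") * 1.5
  res <- one_way_anova(x6, g6)
  gm <- mean(x6)
  ssb <- sum(tapply(x6, g6, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(x6, g6, function(v) sum((v - mean(v))^2)))
  k <- 6; n <- length(x6)
  f_oracle <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(res$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(res$df, c(k - 1, n - k))
})

test_that("Tukey HSD flags exactly the shifted group and never undercuts raw p", {
  set.seed(15)
  g <- rep(letters[1:6], each = 10)
  x <- rnorm(60, sd = 0.5) + (g == "d") * 4
  tk <- tukey_hsd(x, g)
  expect_identical(nrow(tk), 15L)
  hit <- tk$p_adj < 0.05
  expect_identical(sort(tk$contrast[hit]),
                   sort(grep("d", tk$contrast, value = TRUE)))
  # family-wise adjustment can only raise pairwise p-values
  for (i in seq_len(nrow(tk))) {
    ab <- strsplit(tk$contrast[i], "-")[[1]]
    praw <- t.test(x[g == ab[1]], x[g == ab[2]], var.equal = TRUE)$p.value
    expect_gte(tk$p_adj[i] + 1e-8, praw)
  }
  # identical groups: nothing significant
  x0 <- rep(rnorm(10), 6)
  expect_true(all(tukey_hsd(x0, g)$p_adj > 0.95))
})

test_that("Pearson test reproduces hand-computed r and its invariances", {
  x <- 1:6
  expect_equal(pearson_test(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_test(x, -x)$estimate, -1)
  # worked example: r = 14.5 / 17.5 = 29/35
  y <- c(2, 1, 4, 3, 6, 5)
  r <- pearson_test(x, y)
  expect_equal(r$estimate, 29 / 35, tolerance = 1e-12)
  expect_equal(r$df, 4)
  # symmetry and affine invariance (sign tracking the slope)
  set.seed(16)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(pearson_test(a, b)$estimate, pearson_test(b, a)$estimate)
  expect_equal(pearson_test(3 * a - 7, b)$estimate, pearson_test(a, b)$estimate)
  expect_equal(pearson_test(-2 * a, b)$estimate, -pearson_test(a, b)$estimate)
  expect_error(pearson_test(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("linear fit reports R-squared, bounded p-values, and rejects singular designs", {
  d <- data.frame(x = 1:10, y = 2 * (1:10) + 5)
  f <- suppressWarnings(linear_fit(y ~ x, d)) # exact fit warns upstream
  expect_equal(f$r_squared, 1)
  expect_true(f$p_bounded)
  expect_identical(f$p_value, 1e-16)
  # orthogonal response: zero slope, zero R-squared
  d2 <- data.frame(x = rep(c(-1, 1), 10), y = rep(c(1, 1), 10) + rep(c(-1, 1), each = 10))
  f2 <- linear_fit(y ~ x, d2)
  expect_equal(unname(f2$coefficients["x", "Estimate"]), 0, tolerance = 1e-12)
  expect_equal(f2$r_squared, 0, tolerance = 1e-12)
  d3 <- data.frame(x = 1:10, z = 2 * (1:10), y = rnorm(10))
  expect_error(linear_fit(y ~ x + z, d3), "singular")
})

test_that("hypothesis panel survives a degenerate constant sex ratio", {
  sc <- synthetic_scenario("null", seed = 3)
  st <- generate_study(sc)
  sr <- site_sex_ratio(st$counts)
  sr$pct_female <- 50  # force degeneracy
  p <- hypothesis_panel(sr, st$costs, st$benthos_summary, st$cores)
  expect_true(all(vapply(p, function(t) is.na(t$p_value), logical(1))))
  expect_match(p$cost$note, "degenerate")
})

test_that("panel site-level biomass variant uses six-site pairing", {
  sc <- synthetic_scenario(seed = 4)
  st <- generate_study(sc)
  sr <- site_sex_ratio(st$counts)
  p <- hypothesis_panel(sr, st$costs, st$benthos_summary, st$cores,
                        biomass_level = "site")
  expect_equal(p$bottom$df, 4)       # 6 sites
  ps <- hypothesis_panel(sr, st$costs, st$benthos_summary, st$cores)
  expect_equal(ps$bottom$df, 58)     # 60 cores
})

test_that("null p-values are uniform for the core tests", {
  set.seed(19)
  p_r <- vapply(1:2000, function(i) pearson_test(rnorm(20), rnorm(20))$p_value, 0)
  expect_gt(stats::ks.test(p_r, "punif")$p.value, 0.01)
  p_f <- vapply(1:2000, function(i)
    one_way_anova(rnorm(30), rep(letters[1:6], each = 5))$p_value, 0)
  expect_gt(stats::ks.test(p_f, "punif")$p.value, 0.01)
})
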