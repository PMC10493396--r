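test_that("min-max normalization rescales each group to [0,1] independently", {
  tb <- tibble::tibble(subject = "r1", day = "d1", feature = "iskna",
                       value = c(0, 5, 10))
  out <- minmax_normalize(tb)
  expect_equal(out$value, c(0, 0.5, 1))
  # extremes already 0/1 stay put
  expect_equal(minmax_normalize(dplyr::mutate(tb, value = c(0, 0.25, 1)))$value,
               c(0, 0.25, 1))
  # disjoint-range rats map their own extremes independently
  two <- tibble::tibble(subject = rep(c("r1", "r2"), each = 3),
                        day = "d1", feature = "f",
                        value = c(0, 5, 10, 100, 150, 200))
  out2 <- minmax_normalize(two)
  expect_equal(out2$value, rep(c(0, 0.5, 1), 2))
  # invertible from the stored group extremes
  back <- out2$value * (out2$.max - out2$.min) + out2$.min
  expect_equal(back, two$value)
  # constant group -> missing with warning
  expect_warning(cz <- minmax_normalize(dplyr::mutate(tb, value = 3)), "constant")
  expect_true(all(is.na(cz$value)))
})

test_that("one-way ANOVA matches hand computation and brute-force sums of squares", {
  same <- anova_oneway(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  far <- anova_oneway(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
  expect_equal(far$statistic, 150)
  expect_equal(far$p_value, 0.00026, tolerance = 0.02)
  # oracle: explicit between/within sums of squares on random data
  set.seed(4)
  v <- rnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  res <- anova_oneway(v, g)
  grand <- mean(v)
  ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  f_oracle <- (ssb / 2) / (ssw / 27)
  expect_equal(res$statistic, f_oracle)
  expect_equal(res$p_value, pf(f_oracle, 2, 27, lower.tail = FALSE))
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(11)
  x <- rnorm(12, 0)
  y <- rnorm(15, 0.8)
  f <- anova_oneway(c(x, y), rep(c("x", "y"), c(12, 15)))$statistic
  t2 <- unname(t.test(x, y, var.equal = TRUE)$statistic^2)
  expect_equal(f, t2)
})

test_that("ANOVA type-I error is calibrated on null simulations", {
  set.seed(2026)
  reps <- 2000
  p <- vapply(seq_len(reps), function(i) {
    anova_oneway(rnorm(20), rep(c("a", "b"), each = 10))$p_value
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("Tukey-Kramer flags only the separated group and matches ptukey", {
  set.seed(6)
  none <- tukey_kramer(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_true(all(none$p_value > 0.99))
  v <- c(rnorm(8), rnorm(8), rnorm(8, 12))
  g <- rep(c("a", "b", "c"), each = 8)
  sep <- tukey_kramer(v, g)
  expect_lt(sep$p_value[sep$comparison == "a vs c"], 0.001)
  expect_lt(sep$p_value[sep$comparison == "b vs c"], 0.001)
  expect_gt(sep$p_value[sep$comparison == "a vs b"], 0.05)
  # independent check: p = P(q_range > observed q) with k = 3, df = 21
  expect_equal(sep$p_value,
               ptukey(sep$statistic, 3, 21, lower.tail = FALSE),
               tolerance = 1e-8)
  # balanced case agrees with stats::TukeyHSD directly
  fit <- aov(v ~ factor(g))
  hsd <- TukeyHSD(fit)[[1]]
  expect_equal(sort(sep$p_value), sort(unname(hsd[, "p adj"])), tolerance = 1e-8)
})

test_that("MANOVA reduces to ANOVA for one feature and separates planted clusters", {
  set.seed(10)
  v <- rnorm(20, rep(c(0, 1), each = 10))
  g <- rep(c("a", "b"), each = 10)
  m1 <- manova_wilks(matrix(v, ncol = 1), g)
  expect_equal(m1$p_value, anova_oneway(v, g)$p_value)
  # identical multivariate groups: lambda = 1, p ~ 1
  base <- cbind(rnorm(10), rnorm(10))
  same <- manova_wilks(rbind(base, base), g)
  expect_equal(same$statistic, 1, tolerance = 1e-8)
  expect_gt(same$p_value, 0.99)
  # two clusters 10 sigma apart
  far <- rbind(cbind(rnorm(20), rnorm(20)),
               cbind(rnorm(20, 10), rnorm(20, 10)))
  res <- manova_wilks(far, rep(c("a", "b"), each = 20))
  expect_lt(res$p_value, 1e-6)
})

test_that("band-table aggregation reproduces column means and is order-invariant", {
  tb <- band_power_fixture()
  agg <- aggregate_band_table(tb)
  base_vlf <- agg[agg$condition == "baseline" & agg$column == "vlf_pct", ]
  expect_equal(base_vlf$mean, mean(tb$vlf_pct[tb$condition == "baseline"]))
  expect_identical(base_vlf$n_used, 9L)
  shuffled <- tb[sample(nrow(tb)), ]
  expect_equal(aggregate_band_table(shuffled)$mean, agg$mean)
  one <- aggregate_band_table(tibble::tibble(subject = 1, condition = "AD",
                                             vlf_pct = 40))
  expect_equal(one$mean, 40)
  expect_error(aggregate_band_table(tibble::tibble(condition = "AD", x = 1)),
               "band-power")
})
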