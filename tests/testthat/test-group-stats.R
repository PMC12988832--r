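# Nonparametric group comparison and boxplot conventions.

groups_df <- function(...) {
  gs <- list(...)
  tibble::tibble(g = rep(seq_along(gs), lengths(gs)),
                 value = unlist(gs))
}

test_that("Kruskal-Wallis H matches brute-force rank arithmetic", {
  d <- groups_df(c(1, 2, 3), c(4, 5, 6))
  kw <- kruskal_wallis(d, group = "g")
  expect_equal(kw$statistic, kw_brute(list(c(1, 2, 3), c(4, 5, 6))),
               tolerance = 1e-12)
  expect_equal(round(kw$statistic, 3), 3.857)
  expect_equal(kw$df, 1)

  # with ties, against the same first-principles formula
  set.seed(4)
  gs <- list(sample(1:5, 20, TRUE), sample(2:6, 15, TRUE),
             sample(1:6, 25, TRUE))
  d2 <- groups_df(gs[[1]], gs[[2]], gs[[3]])
  expect_equal(kruskal_wallis(d2, group = "g")$statistic, kw_brute(gs),
               tolerance = 1e-10)
})

test_that("identical groups give H = 0, p = 1; degenerate data error", {
  d <- groups_df(c(1, 2, 3), c(1, 2, 3))
  kw <- kruskal_wallis(d, group = "g")
  expect_equal(kw$statistic, 0, tolerance = 1e-12)
  expect_equal(kw$p_value, 1)

  expect_error(kruskal_wallis(groups_df(rep(2, 5), rep(2, 6)), group = "g"),
               "no rank variation")
  expect_error(kruskal_wallis(groups_df(c(1, 2, 3)), group = "g"),
               ">= 2 groups")
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(8)
  d <- groups_df(rnorm(12), rnorm(15, 1), rnorm(9, 2))
  h1 <- kruskal_wallis(d, group = "g")$statistic
  d2 <- d; d2$value <- exp(d$value)
  expect_equal(kruskal_wallis(d2, group = "g")$statistic, h1,
               tolerance = 1e-12)
})

test_that("two-group Kruskal-Wallis agrees with the Mann-Whitney z test", {
  set.seed(12)
  a <- rnorm(20); b <- rnorm(25, 0.8)   # continuous, tie-free
  kw_p <- kruskal_wallis(groups_df(a, b), group = "g")$p_value
  # normal-approximation Mann-Whitney from first principles
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  U <- sum(rank(c(a, b))[1:n1]) - n1 * (n1 + 1) / 2
  z <- (U - n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  mw_p <- 2 * pnorm(-abs(z))
  expect_lt(abs(kw_p - mw_p) / mw_p, 0.10)
})

test_that("Dunn's test follows the tie-corrected rank-mean formula", {
  d <- groups_df(c(1, 2, 3), c(1, 2, 3))
  dn <- dunn_posthoc(d, group = "g")
  expect_equal(dn$z, 0, tolerance = 1e-12)
  expect_equal(dn$p_value, 1)

  # no-ties case against the hand formula
  d2 <- groups_df(c(1, 2, 3), c(10, 11, 12))
  dn2 <- dunn_posthoc(d2, group = "g")
  N <- 6
  z_hand <- (mean(1:3) - mean(4:6)) /
    sqrt(N * (N + 1) / 12 * (1 / 3 + 1 / 3))
  expect_equal(dn2$z, z_hand, tolerance = 1e-12)

  # relabeling the groups flips the sign, keeps the p-value
  d3 <- groups_df(c(10, 11, 12), c(1, 2, 3))
  dn3 <- dunn_posthoc(d3, group = "g")
  expect_equal(dn3$z, -dn2$z, tolerance = 1e-12)
  expect_equal(dn3$p_value, dn2$p_value, tolerance = 1e-12)

  # Bonferroni multiplies by the number of pairs, capped at 1
  set.seed(2)
  d4 <- groups_df(rnorm(10), rnorm(10, 2), rnorm(10, 4))
  pu <- dunn_posthoc(d4, group = "g")$p_value
  pb <- dunn_posthoc(d4, group = "g", adjust = "bonferroni")$p_value
  expect_equal(pb, pmin(pu * 3, 1), tolerance = 1e-12)
})

test_that("significance stars honor the strict thresholds", {
  expect_equal(significance_stars(0.03), "*")
  expect_equal(significance_stars(0.0009), "***")
  expect_equal(significance_stars(0.05), "ns")     # strict inequality
  expect_equal(significance_stars(0.009), "**")
  expect_equal(significance_stars(5e-5), "****")
  expect_equal(significance_stars(0.9), "ns")
  expect_error(significance_stars(1.2), "\\[0, 1\\]")
  expect_error(significance_stars(-0.1), "\\[0, 1\\]")
})

test_that("boxplot summaries use 1.5 IQR whiskers and type-7 quartiles", {
  b <- boxplot_summary(c(1, 2, 3, 4, 100))
  expect_equal(b$median, 3)
  expect_equal(b$q1, 2); expect_equal(b$q3, 4)
  expect_equal(b$outliers, 100)
  expect_equal(b$whisker_high, 4)

  bc <- boxplot_summary(rep(7, 5))
  expect_equal(bc$median, 7)
  expect_equal(bc$q1, bc$q3)
  expect_equal(length(bc$outliers), 0)

  bs <- boxplot_summary(c(-3, -1, 0, 1, 3))
  expect_equal(bs$median - bs$q1, bs$q3 - bs$median)
})

test_that("Shapiro-Wilk wrapper calibrates on normal and skewed data", {
  p_norm <- sapply(1:100, function(s) {
    set.seed(s)
    shapiro.test(rnorm(500))$p.value
  })
  d <- tibble::tibble(g = 1, value = rnorm(500))
  # wrapper returns the same statistic as the underlying test
  set.seed(1); x <- rnorm(100)
  sw <- shapiro_by_group(tibble::tibble(g = 1, value = x), group = "g")
  ref <- shapiro.test(x)
  expect_equal(sw$W, unname(ref$statistic))
  expect_equal(sw$p_value, ref$p.value)
  expect_gte(mean(p_norm > 0.05), 0.90)

  p_exp <- sapply(1:100, function(s) {
    set.seed(s + 1000)
    shapiro.test(rexp(500))$p.value
  })
  expect_gte(mean(p_exp < 0.05), 0.95)

  expect_error(shapiro_by_group(tibble::tibble(g = 1, value = c(1, 2)),
                                group = "g"), "3 <= n")
  expect_warning(shapiro_by_group(tibble::tibble(g = 1, value = rep(1, 10)),
                                  group = "g"), "constant")
})

test_that("a one-group location shift is detected with high power", {
  sizes <- c(28, 43, 39, 64, 48, 65)
  rejected <- sapply(1:200, function(s) {
    set.seed(s)
    d <- tibble::tibble(
      g = rep(seq_along(sizes), sizes),
      value = rnorm(sum(sizes)) + rep(c(1, 0, 0, 0, 0, 0), sizes))
    kruskal_wallis(d, group = "g")$p_value < 0.05
  })
  expect_gt(mean(rejected), 0.9)
})

test_that("compare_groups assembles the full comparison object", {
  samples <- sample_metric_groups(default_group_spec("gcnr"), seed = 3)
  cmp <- compare_groups(samples, value = "value")
  expect_s3_class(cmp, "pa_comparison")
  expect_equal(nrow(cmp$normality), 6)
  expect_equal(nrow(cmp$pairwise), choose(6, 2))
  expect_equal(glance(cmp), cmp$omnibus)
  expect_equal(tidy(cmp), cmp$pairwise)
  expect_true(all(cmp$pairwise$significance %in%
                    c("ns", "*", "**", "***", "****")))
  # the 20-min peak differs from the 10-min baseline in the default scene
  p_10_20 <- cmp$pairwise$p_value[cmp$pairwise$group1 == "10" &
                                    cmp$pairwise$group2 == "20"]
  expect_lt(p_10_20, 0.05)
  expect_s3_class(ggplot2::autoplot(cmp), "ggplot")
  expect_output(print(cmp), "Kruskal-Wallis")
})
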