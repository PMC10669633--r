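test_that("group summaries give sample mean and n-1 SD", {
  tab <- data.frame(group = c("a", "a", "a", "b"),
                    CA = c(1, 2, 3, 10), COID = c(4, 4, 4, 5),
                    CD = c(2, 2, 2, 9))
  s <- summarize_groups(tab)
  a_ca <- s[s$group == "a" & s$metric == "CA", ]
  expect_equal(a_ca$mean, 2)
  expect_equal(a_ca$sd, 1)
  b_ca <- s[s$group == "b" & s$metric == "CA", ]
  expect_equal(b_ca$mean, 10)
  expect_true(is.na(b_ca$sd))  # single observation: SD undefined

  set.seed(21)
  tab2 <- data.frame(group = rep(c("x", "y", "z"), each = 7),
                     CA = rnorm(21, 100, 10), COID = rnorm(21, 60, 5),
                     CD = rnorm(21, 1500, 100))
  s2 <- summarize_groups(tab2)
  for (g in c("x", "y", "z")) {
    v <- tab2$CA[tab2$group == g]
    expect_equal(s2[s2$group == g & s2$metric == "CA", "mean"],
                 sum(v) / length(v), tolerance = 1e-9)
    expect_equal(s2[s2$group == g & s2$metric == "CA", "sd"],
                 sqrt(sum((v - mean(v))^2) / (length(v) - 1)),
                 tolerance = 1e-9)
  }
})

test_that("one-way ANOVA matches hand computation and oneway.test", {
  v <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("a", "b", "c"), each = 3)
  a <- one_way_anova(v, g)
  # hand evaluation: group means 2, 3, 7; grand mean 4
  # SSB = 3*(4 + 1 + 9) = 42, SSW = 2 + 2 + 2 = 6 -> F = 21 on (2, 6) df
  expect_equal(a$F, 21, tolerance = 1e-12)
  expect_equal(a$df_between, 2L)
  expect_equal(a$df_within, 6L)
  ow <- stats::oneway.test(v ~ g, var.equal = TRUE)
  expect_equal(a$F, unname(ow$statistic), tolerance = 1e-9)
  expect_equal(a$p, unname(ow$p.value), tolerance = 1e-9)
  expect_equal(unname(a$group_means), c(2, 3, 7))
})

test_that("with two groups F equals the squared pooled-variance t statistic", {
  set.seed(31)
  x <- rnorm(12, 5, 2); y <- rnorm(15, 6, 2)
  a <- one_way_anova(c(x, y), rep(c("x", "y"), c(12, 15)))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p, tt$p.value, tolerance = 1e-9)
})

test_that("degenerate inputs: identical constant groups give F = 0, p = 1", {
  a <- one_way_anova(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  expect_error(one_way_anova(1:5, rep("a", 5)), "groups")
  expect_error(one_way_anova(1:3, c("a", "a", "b")), ">= 2 observations")
})

test_that("p-values are invariant under relabeling and constant shifts", {
  set.seed(41)
  v <- rnorm(18, 10, 3)
  g <- rep(c("a", "b", "c"), each = 6)
  p0 <- one_way_anova(v, g)$p
  relab <- c(a = "PD", b = "control", c = "MS")[g]
  expect_equal(one_way_anova(v, relab)$p, p0, tolerance = 1e-12)
  expect_equal(one_way_anova(v + 1234, g)$p, p0, tolerance = 1e-9)
  ph0 <- pairwise_posthoc(v, g)
  ph1 <- pairwise_posthoc(v + 1234, g)
  expect_equal(sort(ph0$p_adj), sort(ph1$p_adj), tolerance = 1e-9)
})

test_that("post hoc: identical groups are never flagged; m = 1 is uncorrected", {
  ph <- pairwise_posthoc(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_true(all(ph$p_adj == 1))
  expect_false(any(ph$significant))

  set.seed(51)
  x <- rnorm(10); y <- rnorm(10)
  ph2 <- pairwise_posthoc(c(x, y), rep(c("x", "y"), each = 10))
  expect_equal(ph2$p_adj, stats::t.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("a strongly shifted group is flagged in exactly its two pairs", {
  set.seed(61)
  v <- c(rnorm(10, 0, 1), rnorm(10, 0, 1), rnorm(10, 20, 1))
  g <- rep(c("a", "b", "c"), each = 10)
  ph <- pairwise_posthoc(v, g, alpha = 0.05)
  flagged <- ph[ph$significant, c("group1", "group2")]
  expect_equal(nrow(flagged), 2L)
  expect_true(all(apply(flagged, 1, function(r) "c" %in% r)))
  # cross-check each adjusted p against a direct Welch test * m
  for (j in seq_len(nrow(ph))) {
    x <- v[g == ph$group1[j]]; y <- v[g == ph$group2[j]]
    expect_equal(ph$p_adj[j],
                 min(1, stats::t.test(x, y)$p.value * 3), tolerance = 1e-12)
  }
})
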