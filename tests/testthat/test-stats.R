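# omnibus + post-hoc statistics scheme

toy_design <- function() {
  group_design(list(ctrl1 = c(1, 2, 3), ctrl2 = c(1, 2, 3),
                    exp = c(7, 8, 9)),
               c("control", "control", "experimental"))
}

test_that("identical groups give null omnibus and adjusted p = 1", {
  d <- group_design(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)),
                    c("control", "control", "experimental"))
  ra <- anova_bonferroni(d)
  expect_equal(ra$omnibus$statistic, 0)
  expect_true(all(ra$posthoc$p_adj == 1))
  rk <- kruskal_dunn(d)
  expect_equal(rk$omnibus$statistic, 0, tolerance = 1e-12)
  expect_true(all(rk$posthoc$p_adj >= 0.999))

  # all values tied across all groups: H = 0, p = 1, no division by zero
  dt <- group_design(list(a = c(5, 5), b = c(5, 5), c = c(5, 5)),
                     c("control", "control", "experimental"))
  rt <- kruskal_dunn(dt)
  expect_equal(rt$omnibus$statistic, 0)
  expect_equal(rt$omnibus$p, 1)
  expect_true(all(rt$posthoc$p_adj == 1))
})

test_that("ANOVA + Bonferroni matches hand-computed closed forms", {
  d <- toy_design()
  r <- anova_bonferroni(d)
  or <- oracle_anova(d$values, cbind(c("exp", "exp"), c("ctrl1", "ctrl2")))
  expect_equal(r$omnibus$statistic, or$F, tolerance = 1e-10)
  expect_equal(r$omnibus$p, or$p, tolerance = 1e-10)
  for (i in 1:2) {
    expect_equal(r$posthoc$statistic[i], unname(or$post[[i]]["t"]),
                 tolerance = 1e-10)
    expect_equal(r$posthoc$p_raw[i], unname(or$post[[i]]["p"]),
                 tolerance = 1e-10)
    expect_equal(r$posthoc$p_adj[i], unname(or$post[[i]]["p_adj"]),
                 tolerance = 1e-10)
  }
  # Bonferroni is exactly min(1, m * p)
  expect_equal(r$posthoc$p_adj, pmin(1, 2 * r$posthoc$p_raw))
  expect_equal(r$posthoc$df, c(6, 6))

  # cross-check the pooled-MS t against pairwise.t.test
  y <- unlist(d$values)
  g <- rep(names(d$values), lengths(d$values))
  pp <- pairwise.t.test(y, g, p.adjust.method = "none", pool.sd = TRUE)
  expect_equal(r$posthoc$p_raw[1], pp$p.value["exp", "ctrl1"],
               tolerance = 1e-10)
})

test_that("Kruskal-Wallis + Dunn matches brute-force rank arithmetic", {
  d <- group_design(list(a = c(1, 2, 3, 4), b = c(5, 6, 7, 8),
                         c = c(9, 10, 11, 12)),
                    c("control", "control", "experimental"))
  r <- kruskal_dunn(d)
  or <- oracle_kruskal_dunn(d$values, cbind(c("c", "c"), c("a", "b")))
  expect_equal(r$omnibus$statistic, or$H, tolerance = 1e-10)
  for (i in 1:2) {
    expect_equal(r$posthoc$statistic[i], unname(or$post[[i]]["z"]),
                 tolerance = 1e-10)
    expect_equal(r$posthoc$p_adj[i], unname(or$post[[i]]["p_adj"]),
                 tolerance = 1e-10)
  }

  # ties handled identically to kruskal.test's corrected H
  set.seed(71)
  vals <- list(a = sample(1:6, 8, TRUE), b = sample(1:6, 8, TRUE),
               c = sample(1:6, 8, TRUE))
  dt <- group_design(vals, c("control", "control", "experimental"))
  kw <- kruskal.test(unlist(vals), factor(rep(names(vals), each = 8)))
  expect_equal(kruskal_dunn(dt)$omnibus$statistic, unname(kw$statistic))
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(72)
  vals <- list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10, 2))
  d1 <- group_design(vals, c("control", "control", "experimental"))
  d2 <- group_design(lapply(vals, function(v) exp(3 * v) + 1),
                     c("control", "control", "experimental"))
  expect_equal(kruskal_dunn(d1)$omnibus$statistic,
               kruskal_dunn(d2)$omnibus$statistic, tolerance = 1e-10)
})

test_that("two-group Dunn omnibus agrees with the Mann-Whitney normal approximation", {
  set.seed(73)
  a <- rnorm(12); b <- rnorm(12, 0.8)
  d <- group_design(list(a = a, b = b), c("control", "experimental"))
  r <- kruskal_dunn(d)
  w <- wilcox.test(b, a, exact = FALSE, correct = FALSE)
  expect_equal(r$omnibus$p, w$p.value, tolerance = 1e-6)
})

test_that("the normality gate routes as observed and honors the force flag", {
  set.seed(74)
  norm_vals <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  d <- group_design(norm_vals, c("control", "control", "experimental"))
  forced <- choose_test(d, force_nonparametric = TRUE)
  expect_equal(forced$omnibus$test, "Kruskal-Wallis")
  expect_match(forced$decision_trail[[1]], "forced")

  # Shapiro-Wilk power: normal groups go parametric in about 0.95^3 of
  # replicates (three independent gates at alpha = 0.05); exponential
  # groups are routed nonparametric
  set.seed(75)
  picks <- replicate(200, {
    dd <- group_design(list(a = rnorm(30), b = rnorm(30), c = rnorm(30)),
                       c("control", "control", "experimental"))
    choose_test(dd)$omnibus$test
  })
  p_expected <- 0.95^3
  expect_gte(mean(picks == "One-way ANOVA"),
             p_expected - 3 * sqrt(p_expected * (1 - p_expected) / 200))

  picks2 <- replicate(200, {
    dd <- group_design(list(a = rexp(30), b = rexp(30), c = rexp(30)),
                       c("control", "control", "experimental"))
    choose_test(dd)$omnibus$test
  })
  expect_gte(mean(picks2 == "Kruskal-Wallis"), 0.90)

  # too-small groups fall back to the nonparametric branch with a reason
  small <- group_design(list(a = c(1, 2), b = c(2, 3), c = c(3, 4)),
                        c("control", "control", "experimental"))
  rs <- choose_test(small)
  expect_equal(rs$omnibus$test, "Kruskal-Wallis")
  expect_true(any(grepl("cannot test normality", unlist(rs$decision_trail))))
})

test_that("familywise error of planned comparisons stays at or below alpha", {
  set.seed(76)
  fwer_anova <- mean(replicate(500, {
    d <- group_design(setNames(replicate(5, rnorm(8), simplify = FALSE),
                               paste0("g", 1:5)),
                      c("experimental", rep("control", 4)))
    any(anova_bonferroni(d)$posthoc$p_adj < 0.05)
  }))
  expect_lte(fwer_anova, 0.05 + 2.5 * sqrt(0.05 * 0.95 / 500))

  set.seed(77)
  fwer_kw <- mean(replicate(500, {
    d <- group_design(setNames(replicate(5, rnorm(8), simplify = FALSE),
                               paste0("g", 1:5)),
                      c("experimental", rep("control", 4)))
    any(kruskal_dunn(d)$posthoc$p_adj < 0.05)
  }))
  expect_lte(fwer_kw, 0.05 + 2.5 * sqrt(0.05 * 0.95 / 500))
})

test_that("the verdict requires significance against both controls with agreeing direction", {
  d <- toy_design()
  r <- anova_bonferroni(d)
  v <- vs_both_controls(r)
  expect_true(v$significant)
  expect_equal(v$direction, 1)

  # one weak comparison blocks the verdict
  d2 <- group_design(list(ctrl1 = c(1, 2, 3), ctrl2 = c(6.5, 7.5, 9.5),
                          exp = c(7, 8, 9)),
                     c("control", "control", "experimental"))
  v2 <- vs_both_controls(anova_bonferroni(d2))
  expect_false(v2$significant)

  # a report missing one control comparison errors
  r3 <- anova_bonferroni(d)
  r3$posthoc <- r3$posthoc[1, ]
  expect_error(vs_both_controls(r3), "incomplete-design")
})

test_that("reports render in figure-legend style", {
  txt <- format_stat_report(anova_bonferroni(toy_design()))
  expect_match(txt[1], "ANOVA")
  expect_match(txt[length(txt)], "P < 0.05")
})
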