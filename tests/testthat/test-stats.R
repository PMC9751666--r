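test_that("normality gate routes normal data to Welch, skewed to rank test", {
  set.seed(101)
  a <- rnorm(20); b <- rnorm(20, 0.5)
  expect_identical(normality_gate(a, b)$test, "welch_t")
  # heavy-tailed sample triggers the nonparametric branch
  set.seed(103)
  found_mw <- FALSE
  for (s in 1:5) {
    x <- exp(rnorm(20, sd = 2.5))
    g <- normality_gate(x, rnorm(20))
    if (g$test == "mann_whitney_u") { found_mw <- TRUE; break }
  }
  expect_true(found_mw)
  # degenerate zero-variance samples cannot be tested for normality
  expect_identical(normality_gate(rep(1, 10), rep(1, 10))$test,
                   "mann_whitney_u")
  expect_warning(g <- normality_gate(c(1, 2), c(3, 4)), "fewer than 3")
  expect_identical(g$test, "mann_whitney_u")
})

test_that("Mann-Whitney exact p equals full enumeration for small samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1)                 # 2 / C(6,3)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(7)
  for (i in 1:8) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    a <- round(rnorm(n1), 6); b <- round(rnorm(n2, 0.8), 6)
    expect_equal(mann_whitney_u(a, b)$p_value, oracle_mw_p(a, b),
                 tolerance = 1e-12, info = paste("case", i))
  }
})

test_that("Welch test matches closed-form arithmetic and the z limit", {
  eq <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(eq$statistic), 0)
  expect_equal(eq$p_value, 1)
  # hand-computable 2 vs 2: means 1 and 12, variances 2 and 8
  a <- c(0, 2); b <- c(10, 14)
  tt <- (mean(a) - mean(b)) / sqrt(2 / 2 + 8 / 2)
  df <- (2 / 2 + 8 / 2)^2 / ((2 / 2)^2 / 1 + (8 / 2)^2 / 1)
  r <- welch_t(a, b)
  expect_equal(unname(r$statistic), tt)
  expect_equal(r$df, df)
  expect_equal(r$p_value, 2 * pt(tt, df))
  # large n: Welch p consistent with a z-test within 1%
  set.seed(5)
  x <- rnorm(4000, 0.08); y <- rnorm(4000)
  z <- (mean(x) - mean(y)) / sqrt(var(x) / 4000 + var(y) / 4000)
  pz <- 2 * pnorm(-abs(z))
  expect_equal(welch_t(x, y)$p_value, pz, tolerance = 0.01)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("decision thresholds and stars follow the figure conventions", {
  expect_identical(significance_decision(c(0.04, 0.06, 0.2)),
                   c("significant", "trend", "not significant"))
  expect_identical(p_stars(c(0.2, 0.04, 0.009, 9e-4, 9e-5)),
                   c("n.s.", "*", "**", "***", "****"))
})

test_that("ANOVA with Tukey contrasts behaves across designs", {
  # four identical groups: F ~ 0, nothing significant
  vals <- rep(c(1, 2, 3, 4, 5), 4)
  grp <- rep(letters[1:4], each = 5)
  r <- anova_tukey(vals, grp)
  expect_lt(unname(r$anova$statistic), 1e-10)
  expect_true(all(r$pairs$decision == "not significant"))
  # one group shifted by 10 SD: every contrast with it is significant
  set.seed(31)
  vals2 <- c(rnorm(30), rnorm(10, mean = 10))
  grp2 <- rep(c("a", "b", "c", "d"), each = 10)
  r2 <- anova_tukey(vals2, grp2)
  hit <- grepl("d", r2$pairs$pair)
  expect_true(all(r2$pairs$p_adj[hit] < 0.05))
  expect_true(all(r2$pairs$p_adj[!hit] > 0.05))
  # two groups: F equals the squared pooled t statistic
  set.seed(33)
  x <- rnorm(12); y <- rnorm(12, 1)
  r3 <- anova_tukey(c(x, y), rep(c("a", "b"), each = 12))
  tpool <- t.test(x, y, var.equal = TRUE)$statistic
  expect_equal(unname(r3$anova$statistic), unname(tpool^2),
               tolerance = 1e-10)
  expect_error(anova_tukey(1:5, c("a", "a", "b", "b", "c")), "n >= 2")
})

test_that("tests are invariant to sample-order shuffles", {
  set.seed(41)
  a <- rnorm(12); b <- rnorm(12, 0.7)
  p0 <- two_group_test(a, b)$p_value
  for (i in 1:5) {
    expect_equal(two_group_test(sample(a), sample(b))$p_value, p0)
  }
  expect_gte(p0, 0)
  expect_lte(p0, 1)
})

test_that("biopsy percentages use the right denominators", {
  counts <- rbind(thymic_lymphoma = c(0, 7),
                  seminal_vesicles = c(6, 2))
  pct <- biopsy_percentages(counts, group_n = c(18, 20),
                            male_only = c(FALSE, TRUE),
                            male_n = c(10, 9))
  expect_equal(unname(pct["thymic_lymphoma", ]), c(0, 35))
  expect_equal(unname(pct["seminal_vesicles", ]), c(60, 22.2))
  expect_error(biopsy_percentages(matrix(30, 1, 1), 20), "exceeds")
  expect_error(biopsy_percentages(counts, c(18, 20),
                                  male_only = c(FALSE, TRUE)), "male_n")
})
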