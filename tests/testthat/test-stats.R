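test_that("the Shapiro-Wilk gate routes normal and skewed samples correctly", {
  g1 <- shapiro_wilk_gate(qnorm(ppoints(20)))
  expect_gt(g1$result$p_value, 0.05)
  expect_equal(g1$recommended_test, "parametric")
  set.seed(11)
  g2 <- shapiro_wilk_gate(exp(rnorm(50)))
  expect_lt(g2$result$p_value, 0.05)
  expect_equal(g2$recommended_test, "nonparametric")
  g3 <- shapiro_wilk_gate(rep(2, 10))
  expect_equal(g3$recommended_test, "degenerate")
  expect_error(shapiro_wilk_gate(c(1, 2)), "at least 3")
})

test_that("the pooled two-sample t test matches the hand-derived toy", {
  tt <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$statistic, -sqrt(3 / 2), tolerance = 1e-12) # -1.2247
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 0.288, tolerance = 1e-3)
  # identical groups
  t0 <- two_sample_t(c(5, 6, 7), c(5, 6, 7))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # antisymmetry
  ts <- two_sample_t(c(2, 3, 4), c(1, 2, 3))
  expect_equal(ts$statistic, -tt$statistic)
  expect_equal(ts$p_value, tt$p_value)
  # zero-variance degenerate cases
  z1 <- two_sample_t(c(2, 2), c(2, 2))
  expect_equal(z1$p_value, 1)
  z2 <- two_sample_t(c(2, 2), c(3, 3))
  expect_true(z2$degenerate)
})

test_that("Mann-Whitney matches the enumeration toy and symmetry properties", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_true(mw$exact)
  expect_equal(mw$p_value, 0.1) # 2/20 rank splits as extreme
  same <- mann_whitney_u(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_equal(same$p_value, 1)
  expect_false(same$exact) # ties force the corrected approximation
})

test_that("exact Mann-Whitney equals the enumeration oracle for small tie-free samples", {
  set.seed(55)
  for (n in 2:8) for (m in c(2L, 5L, 8L)) {
    a <- rnorm(n); b <- rnorm(m)
    got <- mann_whitney_u(a, b, exact_threshold = 8)
    expect_true(got$exact)
    expect_equal(got$p_value, mw_enum_oracle(a, b), tolerance = 1e-12,
                 label = sprintf("exact p (n=%d, m=%d)", n, m))
  }
})

test_that("exact and approximate Mann-Whitney p agree closely at n = m = 8", {
  set.seed(77)
  for (k in 1:10) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    pe <- mann_whitney_u(a, b, exact_threshold = 8)$p_value
    pa <- mann_whitney_u(a, b, exact_threshold = 0)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(91)
  a <- rlnorm(12); b <- rlnorm(15, 0.4)
  f <- function(x) x^3 + 2 * log(x)
  expect_equal(mann_whitney_u(a, b)$p_value,
               mann_whitney_u(f(a), f(b))$p_value)
  g <- list(a, b, rlnorm(9, 0.2))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, f))$statistic)
})

test_that("Kruskal-Wallis matches the hand-computed toy and is order invariant", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  kw <- kruskal_wallis(g)
  expect_equal(kw$statistic, 32 / 7, tolerance = 1e-9) # 4.571
  expect_equal(kw$df, 2)
  expect_equal(kruskal_wallis(g[c(3, 1, 2)])$statistic, kw$statistic)
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1, 1)))$statistic, 0)
})

test_that("two-group Kruskal-Wallis agrees with Mann-Whitney decisions", {
  set.seed(13)
  for (k in 1:20) {
    a <- rnorm(12); b <- rnorm(12, ifelse(k %% 2, 0, 1.2))
    pkw <- kruskal_wallis(list(a, b))$p_value
    pmw <- mann_whitney_u(a, b, exact_threshold = 0)$p_value
    expect_equal(pkw < 0.05, pmw < 0.05)
  }
})

test_that("Bonferroni post-hoc adjusts by the number of pairs and never below raw", {
  set.seed(17)
  g <- list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10, 2))
  for (method in c("dunn", "pairwise_mw")) {
    res <- posthoc_bonferroni(g, method = method)
    expect_length(res, 3)
    for (r in res) {
      expect_equal(r$p_value, min(1, 3 * r$p_raw), tolerance = 1e-12)
      expect_gte(r$p_value, r$p_raw)
      expect_true(r$adjusted)
    }
  }
  ident <- posthoc_bonferroni(list(a = rep(1, 6), b = rep(1, 6)))
  expect_equal(ident[[1]]$p_value, 1)
})

test_that("viability normalization divides by the control mean", {
  tab <- data.frame(condition = c("ctrl", "ctrl", "trt"),
                    value = c(1.0, 1.0, 0.5))
  out <- mts_normalize(tab, "ctrl")
  expect_equal(out$value, c(1, 1, 0.5))
  tab2 <- data.frame(condition = c("ctrl", "ctrl", "trt"),
                     value = c(0.8, 1.2, 0.7))
  out2 <- mts_normalize(tab2, "ctrl")
  expect_equal(out2$value[3], 0.7)
  expect_equal(mean(out2$value[1:2]), 1)
  expect_error(mts_normalize(data.frame(condition = "ctrl", value = 0),
                             "ctrl"), "positive")
})

test_that("marker-positive percentages are per-field ratios", {
  f <- data.frame(positive_count = c(80, 0, 45),
                  total_count = c(100, 50, 60))
  out <- ki67_percent(f)
  expect_equal(out$percent_positive, c(80, 0, 75))
  expect_error(ki67_percent(data.frame(positive_count = 1,
                                       total_count = 0)), "positive")
})
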