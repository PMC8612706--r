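# Cross-sectional statistics: frozen worked examples, antisymmetry and
# invariance properties, and oracle equivalence against brute-force formulas
# and the base-R reference tests.

test_that("hedges_g matches the hand-computed example and its symmetries", {
  r <- hedges_g(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$g, -2.4)                      # J = 0.8, raw d = -3
  expect_equal(r$fold_change, 0.4)
  expect_true(r$ci95[1] <= r$g && r$g <= r$ci95[2])

  same <- hedges_g(c(2, 3, 4), c(2, 3, 4))
  expect_equal(same$g, 0)
  expect_equal(same$fold_change, 1)

  x <- rnorm(8, 5); y <- rnorm(9, 4)
  a <- hedges_g(x, y); b <- hedges_g(y, x)
  expect_equal(a$g, -b$g)
  expect_equal(a$fold_change, 1 / b$fold_change)

  expect_warning(z <- hedges_g(c(1, 1, 1), c(2, 2, 2)), "infinite")
  expect_true(is.infinite(z$g) && z$g < 0)
})

test_that("hedges_g agrees with a brute-force evaluation on random samples", {
  set.seed(42)
  for (i in 1:250) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    x <- rnorm(n1, sd = runif(1, 0.5, 3)); y <- rnorm(n2, 1)
    # independent oracle: direct formula transcription
    df <- n1 + n2 - 2
    sp <- sqrt((sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df)
    g_oracle <- (1 - 3 / (4 * df - 1)) * (mean(x) - mean(y)) / sp
    se_oracle <- sqrt((n1 + n2) / (n1 * n2) + g_oracle^2 / (2 * df))
    r <- hedges_g(x, y)
    expect_equal(r$g, g_oracle, tolerance = 1e-10)
    expect_equal(r$ci95, g_oracle + c(-1, 1) * qnorm(0.975) * se_oracle,
                 tolerance = 1e-10)
  }
})

test_that("Mann-Whitney p matches wilcox.test in both regimes", {
  set.seed(7)
  for (i in 1:100) {
    n1 <- sample(3:9, 1); n2 <- sample(3:9, 1)
    x <- rnorm(n1); y <- rnorm(n2)  # continuous: no ties, exact branch
    expect_equal(mann_whitney_p(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  for (i in 1:50) {  # large/tied: normal approximation with corrections
    x <- sample(1:6, 25, replace = TRUE); y <- sample(1:6, 30, replace = TRUE)
    expect_equal(mann_whitney_p(x, y),
                 wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("spearman_cor frozen examples, monotone invariance, and oracle", {
  expect_equal(spearman_cor(1:6, (1:6)^3)$r, 1)
  expect_equal(spearman_cor(1:6, -(1:6))$r, -1)
  expect_equal(spearman_cor(1:5, c(1, 3, 2, 5, 4))$r, 0.8)  # 1 - 6*4/120
  expect_warning(r <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r$r))

  set.seed(9)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    # oracle: Pearson formula applied to mid-ranks, transcribed directly
    rx <- rank(x); ry <- rank(y)
    oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(spearman_cor(x, y)$r, oracle, tolerance = 1e-10)
    # invariant under strictly monotone transforms
    expect_equal(spearman_cor(exp(x), y)$r, oracle, tolerance = 1e-10)
  }
})

test_that("partial_spearman adjusts as specified", {
  set.seed(21)
  n <- 200
  age <- runif(n, 20, 60)
  x <- rnorm(n)
  # covariate identical to y: partial r ~ 0
  y <- age + rnorm(n, sd = 1e-8)
  expect_lt(abs(partial_spearman(x, y, data.frame(age = age))$r), 0.15)
  # x = y: partial r = 1 given non-degenerate residuals
  z <- rnorm(n)
  expect_equal(partial_spearman(z, z, data.frame(age = age))$r, 1)
  # independent covariate: matches plain Spearman within sampling error
  y2 <- 0.6 * x + rnorm(n)
  cov_ind <- data.frame(w = rnorm(n))
  expect_equal(partial_spearman(x, y2, cov_ind)$r,
               spearman_cor(x, y2)$r, tolerance = 0.06)
  # collinear covariates are dropped with a warning
  expect_warning(
    partial_spearman(x, y2, data.frame(a = age, b = 2 * age)), "collinear")
})

test_that("fisher_average: frozen examples and bounds property", {
  expect_equal(fisher_average(c(0.4, 0.4)), 0.4)
  expect_equal(fisher_average(c(0.5, -0.5)), 0)
  expect_equal(fisher_average(c(0.3, 0.7)),
               tanh((atanh(0.3) + atanh(0.7)) / 2))
  expect_equal(round(fisher_average(c(0.3, 0.7)), 3), 0.529)
  expect_warning(v <- fisher_average(c(1, 0.5)), "clipped")
  set.seed(5)
  for (i in 1:50) {
    rs <- runif(sample(2:8, 1), -0.95, 0.95)
    v <- fisher_average(rs)
    expect_true(v >= min(rs) - 1e-12 && v <= max(rs) + 1e-12)
    expect_equal(fisher_average(rs[1]), rs[1])
  }
})

test_that("kruskal_dunn: frozen H, permutation invariance, oracle equivalence", {
  k <- kruskal_dunn(1:6, rep(c("a", "b", "c"), each = 2), reference = "a")
  expect_equal(k$H, 32 / 7, tolerance = 1e-12)  # 4.571
  expect_equal(k$df, 2)

  same <- kruskal_dunn(rep(1, 9), rep(c("a", "b", "c"), 3), reference = "a")
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)

  set.seed(13)
  for (i in 1:100) {
    g <- rep(c("a", "b", "c", "d")[1:sample(3:4, 1)], each = sample(3:6, 1))
    v <- round(rnorm(length(g)), sample(0:2, 1))  # induce ties sometimes
    ours <- kruskal_dunn(v, g, reference = "a")
    ref <- kruskal.test(v, factor(g))
    expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    # permuting observation order leaves H unchanged
    p <- sample(seq_along(v))
    expect_equal(kruskal_dunn(v[p], g[p], reference = "a")$H, ours$H,
                 tolerance = 1e-12)
  }
})

test_that("friedman_dunn matches stats::friedman.test on random instances", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(4:10, 1); k <- sample(3:5, 1)
    m <- matrix(round(rnorm(n * k), sample(0:1, 1)), n, k,
                dimnames = list(NULL, paste0("c", 1:k)))
    ours <- friedman_dunn(m, reference = 1)
    ref <- friedman.test(m)
    expect_equal(ours$chisq, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("coregulation recovers shared participant-level structure", {
  # identical participant values in two subtypes -> entry 1
  f <- data.frame(participant = rep(paste0("P", 1:6), 2),
                  subtype = rep(c("A", "B"), each = 6),
                  CS = rep(c(1, 3, 2, 5, 4, 6), 2))
  cg <- suppressWarnings(coregulation(f, "CS"))
  expect_equal(unname(cg$matrix["A", "B"]), 1)

  # independent subtype values, n = 200 -> average near 0
  set.seed(31)
  f2 <- data.frame(participant = rep(paste0("P", 1:1000), 3),
                   subtype = rep(c("A", "B", "C"), each = 1000),
                   CS = rnorm(3000))
  expect_lt(abs(coregulation(f2, "CS")$average_rz), 0.08)

  # shared participant multiplier: average increases with shared variance
  avg_for <- function(mult_sd) {
    set.seed(77)
    mult <- exp(rnorm(200, 0, mult_sd))
    v <- as.vector(outer(mult, c(1, 1.5, 2)) * exp(matrix(rnorm(600, 0, 0.3), 200)))
    f3 <- data.frame(participant = rep(paste0("P", 1:200), 3),
                     subtype = rep(c("A", "B", "C"), each = 200), CS = v)
    coregulation(f3, "CS")$average_rz
  }
  a <- avg_for(0.1); b <- avg_for(0.3); c3 <- avg_for(0.8)
  expect_true(a < b && b < c3)
  # pairs below the shared-participant minimum are excluded
  f4 <- data.frame(participant = c("P1", "P2", "P3", "P1", "P2", "P3"),
                   subtype = rep(c("A", "B"), each = 3), CS = rnorm(6))
  expect_true(is.na(coregulation(f4, "CS")$matrix["A", "B"]))
})

test_that("abs_correlation_strength and set comparison behave as documented", {
  expect_equal(abs_correlation_strength(c(-0.4, 0.4)), 0.4)
  expect_equal(abs_correlation_strength(c(0.3, 0.3, 0.3)), 0.3)
  cmp <- compare_correlation_strength(rep(0.23, 10), rep(0.39, 10))
  expect_equal(cmp$percent_difference, (0.39 - 0.23) / 0.23 * 100)
})
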