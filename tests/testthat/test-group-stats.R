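# group_stats module: t-tests, ANOVA, MANOVA and LDA classification,
# each checked against hand-formula or matrix oracles.

test_that("one-sample t matches the hand formula and handles degenerate input", {
  res <- one_sample_t(c(1, 2, 3), mu0 = 0)
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-10)  # mean/(sd/sqrt(n))
  expect_equal(res$df, 2)
  sym <- one_sample_t(c(-2, -1, 0, 1, 2), mu0 = 0)
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
  expect_error(one_sample_t(5, 0), class = "wm_degenerate_sample_error")
  expect_error(one_sample_t(c(3, 3, 3), 0), class = "wm_degenerate_sample_error")
})

test_that("t statistics match brute-force formula oracles to 1e-10", {
  set.seed(18)
  for (rep in 1:10) {
    x <- rnorm(7); mu0 <- rnorm(1)
    res <- one_sample_t(x, mu0)
    t_oracle <- (mean(x) - mu0) / (sd(x) / sqrt(length(x)))
    expect_equal(res$statistic, t_oracle, tolerance = 1e-10)
    expect_equal(res$p_value, 2 * pt(-abs(t_oracle), length(x) - 1),
                 tolerance = 1e-10)
    a <- rnorm(8); b <- rnorm(12, sd = 2)
    res2 <- two_sample_t(a, b)
    se <- sqrt(var(a) / 8 + var(b) / 12)
    t2 <- (mean(a) - mean(b)) / se
    df2 <- se^4 / ((var(a) / 8)^2 / 7 + (var(b) / 12)^2 / 11)
    expect_equal(res2$statistic, t2, tolerance = 1e-10)
    expect_equal(res2$df, df2, tolerance = 1e-10)
    expect_equal(res2$p_value, 2 * pt(-abs(t2), df2), tolerance = 1e-10)
  }
})

test_that("two-sample t trivial and degenerate cases", {
  x <- c(0.2, 0.5, 0.9, 1.4)
  res <- two_sample_t(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(two_sample_t(c(0, 0, 0, 0), c(1, 1, 1, 1)),
               class = "wm_degenerate_sample_error")
  expect_error(two_sample_t(1, c(1, 2)), class = "wm_degenerate_sample_error")
})

test_that("per-axis ANOVA matches the sum-of-squares decomposition oracle", {
  set.seed(19)
  for (rep in 1:5) {
    y <- rnorm(30)
    g <- factor(rep(c("a", "b", "c"), each = 10))
    res <- per_axis_anova(y, g)
    grand <- mean(y)
    ss_b <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
    ss_w <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
    f_oracle <- (ss_b / 2) / (ss_w / 27)
    expect_equal(res$statistic, f_oracle, tolerance = 1e-10)
    expect_equal(res$df, c(2, 27))
    expect_equal(res$p_value, pf(f_oracle, 2, 27, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("ANOVA trivial/degenerate cases and group checks", {
  same <- per_axis_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  degen <- per_axis_anova(c(0, 0, 1, 1), c("a", "a", "b", "b"))
  expect_true(is.infinite(degen$statistic))
  expect_match(degen$test_name, "degenerate")
  expect_error(per_axis_anova(c(1, 2, 3), c("a", "a", "b")),
               class = "wm_sample_size_error")
})

test_that("MANOVA: identical group distributions give Pillai ~ 0, p ~ 1", {
  set.seed(20)
  x <- matrix(rnorm(40), 20, 2)
  scores <- rbind(x, x)
  labels <- rep(c("g1", "g2"), each = 20)
  res <- manova_scores(scores, labels)
  expect_lt(res$statistic, 1e-10)
  expect_gt(res$p_value, 0.999)
  expect_true(is.numeric(res$extra$wilks))
})

test_that("MANOVA with one axis reduces to the one-way ANOVA", {
  set.seed(21)
  y <- c(rnorm(10), rnorm(10, 1))
  g <- rep(c("a", "b"), each = 10)
  m <- manova_scores(matrix(y, ncol = 1), g)
  a <- per_axis_anova(y, g)
  expect_equal(m$statistic, a$statistic, tolerance = 1e-8)
  expect_equal(m$p_value, a$p_value, tolerance = 1e-8)
})

test_that("Pillai matches the E^-1 H eigenvalue oracle", {
  set.seed(22)
  n <- 15
  scores <- rbind(matrix(rnorm(n * 2), n, 2),
                  matrix(rnorm(n * 2, mean = 1.2), n, 2))
  g <- factor(rep(c("a", "b"), each = n))
  res <- manova_scores(scores, g)
  grand <- colMeans(scores)
  h <- matrix(0, 2, 2); e <- matrix(0, 2, 2)
  for (lev in levels(g)) {
    xs <- scores[g == lev, , drop = FALSE]
    d <- colMeans(xs) - grand
    h <- h + nrow(xs) * tcrossprod(d)
    e <- e + crossprod(sweep(xs, 2, colMeans(xs)))
  }
  ev <- eigen(solve(e) %*% h, only.values = TRUE)$values
  pillai_oracle <- sum(Re(ev) / (1 + Re(ev)))
  expect_equal(res$statistic, pillai_oracle, tolerance = 1e-8)
})

test_that("statistics are invariant to relabeling groups", {
  set.seed(23)
  y <- rnorm(24); g <- rep(c("a", "b", "c"), 8)
  g2 <- c(a = "z", b = "y", c = "x")[g]
  expect_equal(per_axis_anova(y, g)$statistic, per_axis_anova(y, g2)$statistic)
  sc <- matrix(rnorm(48), 24, 2)
  expect_equal(manova_scores(sc, g)$statistic, manova_scores(sc, g2)$statistic)
})

test_that("LDA: wide separation gives near-certain posteriors; 1-D matches closed form", {
  set.seed(24)
  sc <- rbind(matrix(rnorm(30), 15, 2),
              matrix(rnorm(30, mean = 20), 15, 2))  # >> 10 pooled SDs apart
  g <- rep(c("a", "b"), each = 15)
  rep_loo <- lda_classify(sc, g)
  expect_true(all(rep_loo$posterior_pct > 99))
  expect_equal(sum(rep_loo$confusion), 30)
  expect_equal(unname(rowSums(rep_loo$confusion)), c(15, 15))
  # 1-D resubstitution posterior = logistic of the linear discriminant score
  x <- c(rnorm(12, 0, 1), rnorm(12, 2, 1))
  g1 <- rep(c("a", "b"), each = 12)
  rep1 <- lda_classify(matrix(x, ncol = 1), g1, scheme = "resubstitution")
  m_a <- mean(x[1:12]); m_b <- mean(x[13:24])
  s2 <- (sum((x[1:12] - m_a)^2) + sum((x[13:24] - m_b)^2)) / 22
  delta <- (m_b - m_a) / s2
  post_b <- 1 / (1 + exp(-(delta * (x - (m_a + m_b) / 2))))
  oracle_pct <- c(mean(1 - post_b[1:12]), mean(post_b[13:24])) * 100
  expect_equal(unname(rep1$posterior_pct), oracle_pct, tolerance = 1e-6)
})

test_that("LDA guards minimum group sizes", {
  expect_error(lda_classify(matrix(rnorm(8), 4), c("a", "a", "b", "b")),
               class = "wm_sample_size_error")
})

test_that("type-I error of t-tests and ANOVA is near nominal alpha", {
  set.seed(25)
  n_rep <- 400
  rej_t <- rej_f <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    a <- rnorm(12); b <- rnorm(12)
    rej_t[i] <- two_sample_t(a, b)$p_value < 0.05
    y <- rnorm(24)
    rej_f[i] <- per_axis_anova(y, rep(c("a", "b"), each = 12))$p_value < 0.05
  }
  expect_lt(abs(mean(rej_t) - 0.05), 0.03)
  expect_lt(abs(mean(rej_f) - 0.05), 0.03)
})
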