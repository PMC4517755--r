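# Brute-force oracles used below: explicit sums of squares, model
# comparisons via lm(), permutation resampling, and stats' own
# aov/TukeyHSD/ptukey implementations.

test_that("weighted mean and SE reduce to the ordinary forms", {
  expect_equal(weighted_mean_se(c(80, 100), c(10, 30))$mean, 95)
  x <- c(3.1, 4.7, 2.2, 5.9, 4.4)
  w <- rep(2, 5)
  est <- weighted_mean_se(x, w)
  expect_equal(est$mean, mean(x))
  expect_equal(est$se, sd(x) / sqrt(5))
  expect_equal(weighted_mean_se(rep(7, 4), 1:4)$se, 0)
  expect_true(is.na(weighted_mean_se(5, 2)$se))
  expect_error(weighted_mean_se(1:3, c(1, -1, 1)), "positive")
})

test_that("one-way ANOVA matches brute-force sums of squares and aov", {
  y <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("a", "b", "c"), each = 3)
  fit <- oneway_anova(y, g)
  # brute force: SSB = sum n_i (mean_i - grand)^2, SSW by enumeration
  ssb <- sum(3 * (tapply(y, g, mean) - mean(y))^2)
  ssw <- sum(unlist(lapply(split(y, g), function(v) sum((v - mean(v))^2))))
  expect_equal(fit$terms$ss, c(ssb, ssw))          # 42, 6
  expect_equal(fit$terms$f_stat[1], (ssb / 2) / (ssw / 6))  # 21
  expect_equal(fit$terms$df, c(2, 6))
  ref <- summary(stats::aov(y ~ g))[[1]]
  expect_equal(fit$terms$f_stat[1], ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(fit$terms$p_value[1], ref[["Pr(>F)"]][1], tolerance = 1e-10)

  # identical groups: F = 0, p = 1
  f0 <- oneway_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(f0$terms$f_stat[1], 0)
  expect_equal(f0$terms$p_value[1], 1)
  # zero within-group variance with distinct means: degenerate
  expect_warning(fd <- oneway_anova(c(0, 0, 1, 1), c("a", "a", "b", "b")),
                 "degenerate|zero")
  expect_true(fd$degenerate)
  expect_equal(fd$terms$p_value[1], 0)

  # random unbalanced datasets agree with aov
  set.seed(42)
  for (i in 1:5) {
    gg <- factor(sample(letters[1:4], 40, replace = TRUE))
    yy <- rnorm(40) + as.numeric(gg) * 0.5
    mine <- oneway_anova(yy, gg)
    ref <- summary(stats::aov(yy ~ gg))[[1]]
    expect_equal(mine$terms$f_stat[1], ref[["F value"]][1],
                 tolerance = 1e-10)
    expect_equal(mine$terms$p_value[1], ref[["Pr(>F)"]][1],
                 tolerance = 1e-10)
  }
})

test_that("one-way p-value agrees with a permutation oracle", {
  set.seed(7)
  y <- round(rnorm(24, sd = 2) + rep(c(0, 0.8, 1.4), each = 8), 2)
  g <- rep(c("a", "b", "c"), each = 8)
  fit <- oneway_anova(y, g)
  fstat <- function(y, g) {
    gm <- tapply(y, g, mean); gn <- tapply(y, g, length)
    ssb <- sum(gn * (gm - mean(y))^2)
    ssw <- sum((y - gm[g])^2)
    (ssb / 2) / (ssw / (length(y) - 3))
  }
  B <- 10000
  perm <- vapply(seq_len(B), function(i) fstat(sample(y), g), numeric(1))
  p_perm <- mean(perm >= fit$terms$f_stat[1])
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / B)
  # permutation and F-distribution p agree within Monte-Carlo error plus a
  # small allowance for the discreteness of the permutation null
  expect_lt(abs(p_perm - fit$terms$p_value[1]), mc_err + 0.01)
})

test_that("two-way Type-II ANOVA matches car::Anova and balanced theory", {
  skip_if_not_installed("car")
  set.seed(11)
  # unbalanced 2x3 with interaction
  a <- factor(sample(c("t1", "t2"), 40, replace = TRUE, prob = c(0.6, 0.4)))
  b <- factor(sample(c("x", "y", "z"), 40, replace = TRUE))
  while (any(table(a, b) == 0)) {
    b <- factor(sample(c("x", "y", "z"), 40, replace = TRUE))
  }
  y <- rnorm(40) + (a == "t2") * 1 + (b == "z") * 0.5 +
    (a == "t2") * (b == "y") * 0.7
  fit <- twoway_anova(y, a, b, interaction = TRUE)
  ref <- car::Anova(stats::lm(y ~ a * b), type = 2)
  expect_equal(fit$terms$ss[1:3], ref$`Sum Sq`[1:3], tolerance = 1e-9)
  expect_equal(fit$terms$f_stat[1:3], ref$`F value`[1:3], tolerance = 1e-9)
  expect_equal(fit$terms$p_value[1:3], ref$`Pr(>F)`[1:3], tolerance = 1e-9)
  expect_equal(fit$df_den, 40 - 6)

  # model-comparison oracle: term SS = RSS(reduced) - RSS(full additive)
  rss <- function(f) sum(stats::residuals(stats::lm(f))^2)
  expect_equal(fit$terms$ss[1], rss(y ~ b) - rss(y ~ a + b))
  expect_equal(fit$terms$ss[2], rss(y ~ a) - rss(y ~ a + b))
  expect_equal(fit$terms$ss[3], rss(y ~ a + b) - rss(y ~ a * b))

  # balanced design: Type II equals the classical sequential decomposition
  ab <- expand.grid(a = c("t1", "t2"), b = c("x", "y"),
                    rep = 1:5)
  yy <- rnorm(20) + (ab$a == "t2") * 2
  fitb <- twoway_anova(yy, ab$a, ab$b)
  refb <- stats::anova(stats::lm(yy ~ a * b, data = ab))
  expect_equal(fitb$terms$ss[1:3], refb$`Sum Sq`[1:3], tolerance = 1e-9)

  # identical cell means in a balanced 2x2: all F = 0
  y0 <- rep(c(2, 2, 2, 2), each = 4) + rep(c(-1, 1), 8)
  a0 <- rep(c("t1", "t2"), each = 8)
  b0 <- rep(rep(c("x", "y"), each = 4), 2)
  fit0 <- twoway_anova(y0, a0, b0)
  expect_equal(fit0$terms$f_stat[1:3], c(0, 0, 0), tolerance = 1e-12)

  # empty cell with interaction requested
  expect_error(twoway_anova(rnorm(6), rep("t1", 6),
                            rep(c("x", "y"), 3)), "two levels")
  expect_error(twoway_anova(rnorm(6), c("t1", "t1", "t1", "t2", "t2", "t2"),
                            c("x", "x", "y", "x", "x", "x")), "empty cells")
})

test_that("79 lines in a 2x2 design with interaction leave 75 error df", {
  set.seed(3)
  trial <- sample(c("1", "2"), 79, replace = TRUE)
  bait <- sample(c("ten-eighty", "kolee"), 79, replace = TRUE)
  while (any(table(trial, bait) == 0)) {
    bait <- sample(c("ten-eighty", "kolee"), 79, replace = TRUE)
  }
  fit <- twoway_anova(rnorm(79), trial, bait, interaction = TRUE)
  expect_equal(fit$df_den, 75)
})

test_that("Fisher's LSD reproduces pooled t-tests without adjustment", {
  y <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("a", "b", "c"), each = 3)
  fit <- oneway_anova(y, g)
  lsd <- fisher_lsd(fit)
  # hand computation: t = diff / sqrt(mse * (1/3 + 1/3)), df = 6
  mse <- fit$mse
  t_ac <- (mean(y[1:3]) - mean(y[7:9])) / sqrt(mse * (2 / 3))
  row <- lsd[lsd$group_a == "a" & lsd$group_b == "c", ]
  expect_equal(row$statistic, t_ac)
  expect_equal(row$p_value, 2 * pt(-abs(t_ac), 6))
  # two groups: LSD p equals the pooled-variance two-sample t-test p
  y2 <- c(1.2, 3.4, 2.2, 4.1, 5.0, 6.3, 5.8)
  g2 <- rep(c("a", "b"), c(3, 4))
  p_lsd <- fisher_lsd(oneway_anova(y2, g2))$p_value
  expect_equal(p_lsd, stats::t.test(y2 ~ g2, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  # identical means: t = 0, p = 1
  same <- oneway_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(fisher_lsd(same)$p_value, 1)
})

test_that("Tukey's HSD matches stats' studentized-range machinery", {
  y <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("a", "b", "c"), each = 3)
  fit <- oneway_anova(y, g)
  hsd <- tukey_hsd(fit)
  ref <- stats::TukeyHSD(stats::aov(y ~ g))$g
  # TukeyHSD orders pairs b-a, c-a, c-b
  expect_equal(hsd$p_value, ref[c("b-a", "c-a", "c-b"), "p adj"],
               tolerance = 1e-6, ignore_attr = TRUE)
  # two groups: HSD equals LSD (q = t * sqrt(2))
  y2 <- c(1.2, 3.4, 2.2, 4.1, 5.0, 6.3, 5.8)
  g2 <- rep(c("a", "b"), c(3, 4))
  fit2 <- oneway_anova(y2, g2)
  expect_equal(tukey_hsd(fit2)$p_value, fisher_lsd(fit2)$p_value,
               tolerance = 1e-6)
})

test_that("pairwise p-values fall as mean separation grows", {
  resid <- rep(c(-1, 0, 1), 3)
  ps <- vapply(seq(0.5, 5, by = 0.5), function(d) {
    y <- rep(c(0, d, 2 * d), each = 3) + resid
    fit <- oneway_anova(y, rep(c("a", "b", "c"), each = 3))
    c(fisher_lsd(fit)$p_value[2], tukey_hsd(fit)$p_value[2])  # pair a-c
  }, numeric(2))
  expect_true(all(diff(ps[1, ]) < 0))
  expect_true(all(diff(ps[2, ]) < 0))
})

test_that("the numerically integrated studentized-range CDF is correct", {
  # published critical value q_{0.05; k=3, df=6} = 4.339
  expect_equal(1 - pstudrange(4.339, 3, 6), 0.05, tolerance = 0.05 * 0.01)
  # grid agreement with stats::ptukey
  for (k in c(2, 3, 5)) {
    for (df in c(5, 19, 75, Inf)) {
      for (q in c(0.5, 2, 3.5, 5)) {
        expect_equal(pstudrange(q, k, df), stats::ptukey(q, k, df),
                     tolerance = 1e-6)
      }
    }
  }
  expect_equal(pstudrange(0, 3, 6), 0)
  expect_error(pstudrange(2, 1, 6), "at least 2")
})

test_that("ANOVA layer reproduces published critical values to 3 s.f.", {
  # scale group separation until the one-way p-value is exactly 0.05 on a
  # k=3, N=22 layout (df 2, 19); the F at that point is the published
  # critical value F_{0.05; 2, 19} = 3.52
  set.seed(5)
  resid <- rnorm(22)
  g <- rep(c("a", "b", "c"), c(8, 7, 7))
  resid <- unlist(lapply(split(resid, g), function(v) v - mean(v)))
  f_of <- function(d) {
    y <- resid + c(0, 1, 2)[as.integer(factor(g))] * d
    oneway_anova(y, g)
  }
  d_star <- stats::uniroot(function(d) f_of(d)$terms$p_value[1] - 0.05,
                           c(0.01, 5), tol = 1e-10)$root
  expect_equal(f_of(d_star)$terms$f_stat[1], 3.52, tolerance = 0.005 / 3.52)
})
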