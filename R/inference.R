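# From-first-principles ANOVA layer: one-way and Type-II two-way sums of
# squares, Fisher's LSD and Tukey's HSD pairwise comparisons, a numerically
# integrated studentized-range CDF, and weighted means with SEs.

#' Weighted mean and standard error
#'
#' The mean is `sum(w * x) / sum(w)`. The SE uses the effective-sample-size
#' (design-effect) form: `SE^2 = sum(w * (x - m)^2) / (sum(w) * (n_eff - 1))`
#' with `n_eff = sum(w)^2 / sum(w^2)`. With equal weights this reduces to
#' the ordinary SE of the mean.
#'
#' @param values numeric vector.
#' @param weights positive weights, same length.
#' @return A list with `mean`, `se` (`NA` for a single value, which carries
#'   no spread information) and `n_eff`.
#' @examples
#' weighted_mean_se(c(80, 100), c(10, 30))$mean # 95
#' @export
weighted_mean_se <- function(values, weights = rep(1, length(values))) {
  if (length(values) != length(weights))
    stop("values and weights differ in length", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive", call. = FALSE)
  m <- sum(weights * values) / sum(weights)
  if (length(values) < 2)
    return(list(mean = m, se = NA_real_, n_eff = 1))
  n_eff <- sum(weights)^2 / sum(weights^2)
  se2 <- sum(weights * (values - m)^2) / (sum(weights) * (n_eff - 1))
  list(mean = m, se = sqrt(se2), n_eff = n_eff)
}

new_anova_fit <- function(terms, mse, df_den, group_means, group_ns,
                          data, type, degenerate = FALSE) {
  structure(list(terms = terms, mse = mse, df_den = df_den,
                 group_means = group_means, group_ns = group_ns,
                 data = data, type = type, degenerate = degenerate),
            class = "anova_fit")
}

#' @export
print.anova_fit <- function(x, ...) {
  cat(sprintf("<anova_fit> %s ANOVA%s\n", x$type,
              if (x$degenerate) " [degenerate: zero residual variance]"
              else ""))
  tab <- x$terms
  tab$ss <- signif(tab$ss, 5); tab$ms <- signif(tab$ms, 5)
  tab$f_stat <- signif(tab$f_stat, 4); tab$p_value <- signif(tab$p_value, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition: `F = MSB / MSW` with the p-value
#' from the upper tail of the F distribution. If the within-group variance
#' is exactly zero while group means differ, the fit is flagged degenerate
#' and `p = 0` is reported.
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor).
#' @return An object of class `anova_fit` with a `terms` table (`term`,
#'   `df`, `ss`, `ms`, `f_stat`, `p_value`), the residual `mse` and
#'   `df_den`, and per-group means and sizes.
#' @examples
#' fit <- oneway_anova(c(1, 2, 3, 2, 3, 4, 6, 7, 8),
#'                     rep(c("a", "b", "c"), each = 3))
#' fit$terms$f_stat[1] # 21.5
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2)
    stop("at least two groups are required", call. = FALSE)
  if (length(values) != length(groups))
    stop("values and groups differ in length", call. = FALSE)
  N <- length(values); k <- nlevels(groups)
  if (N <= k)
    stop("need more observations than groups", call. = FALSE)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(gn * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  df1 <- k - 1; df2 <- N - k
  msw <- ssw / df2
  degenerate <- ssw == 0 && ssb > 0
  f <- if (ssw == 0) { if (ssb > 0) Inf else 0 } else (ssb / df1) / msw
  p <- if (degenerate) 0 else if (ssw == 0) 1 else pf(f, df1, df2,
                                                      lower.tail = FALSE)
  if (degenerate)
    warning("zero within-group variance with distinct means; p = 0 reported",
            call. = FALSE)
  terms <- data.frame(
    term = c("groups", "Residuals"),
    df = c(df1, df2), ss = c(ssb, ssw),
    ms = c(ssb / df1, msw),
    f_stat = c(f, NA), p_value = c(p, NA))
  new_anova_fit(terms, mse = msw, df_den = df2,
                group_means = gm, group_ns = gn,
                data = list(values = values, factors = list(groups = groups)),
                type = "one-way", degenerate = degenerate)
}

rss_of <- function(y, mm) {
  fit <- lm.fit(mm, y)
  list(rss = sum(fit$residuals^2), rank = fit$rank)
}

#' Two-way analysis of variance with Type-II sums of squares
#'
#' Least-squares fit of a crossed two-factor design, unbalanced cells
#' allowed. Each main effect is tested by the increase in residual sum of
#' squares when it is dropped from the additive model (Type II); the
#' interaction is tested against the full model. With a balanced design the
#' Type-II sums of squares coincide with the classical sequential ones.
#' The residual degrees of freedom equal `N` minus the number of non-empty
#' cells when the interaction is included.
#'
#' @param values numeric response.
#' @param factor_a,factor_b crossed factors (coerced).
#' @param interaction include the interaction term?
#' @return An `anova_fit` whose `terms` table has one row per term plus the
#'   residual row. Cell means are stored in `group_means`.
#' @export
twoway_anova <- function(values, factor_a, factor_b, interaction = TRUE) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  N <- length(values)
  if (length(fa) != N || length(fb) != N)
    stop("factors and values differ in length", call. = FALSE)
  if (nlevels(fa) < 2 || nlevels(fb) < 2)
    stop("both factors need at least two levels", call. = FALSE)
  cells <- table(fa, fb)
  if (interaction && any(cells == 0))
    stop("interaction requested but the design has empty cells",
         call. = FALSE)
  d <- data.frame(y = values, A = fa, B = fb)
  m_a  <- rss_of(d$y, stats::model.matrix(~A, d))
  m_b  <- rss_of(d$y, stats::model.matrix(~B, d))
  m_ab <- rss_of(d$y, stats::model.matrix(~A + B, d))
  full <- if (interaction) rss_of(d$y, stats::model.matrix(~A * B, d))
          else m_ab
  df_den <- N - full$rank
  if (df_den <= 0)
    stop("no residual degrees of freedom", call. = FALSE)
  mse <- full$rss / df_den

  ss <- c(A = m_b$rss - m_ab$rss, B = m_a$rss - m_ab$rss)
  df <- c(A = m_ab$rank - m_b$rank, B = m_ab$rank - m_a$rank)
  if (interaction) {
    ss <- c(ss, `A:B` = m_ab$rss - full$rss)
    df <- c(df, `A:B` = full$rank - m_ab$rank)
  }
  degenerate <- mse == 0
  fstat <- (ss / df) / mse
  pval <- pf(fstat, df, df_den, lower.tail = FALSE)
  if (degenerate) {
    fstat <- ifelse(ss > 0, Inf, 0)
    pval <- ifelse(ss > 0, 0, 1)
    warning("zero residual variance; p-values degenerate", call. = FALSE)
  }
  terms <- data.frame(
    term = c(names(ss), "Residuals"),
    df = c(df, df_den), ss = c(ss, full$rss),
    ms = c(ss / df, mse),
    f_stat = c(fstat, NA), p_value = c(pval, NA))
  rownames(terms) <- NULL
  cell <- interaction(fa, fb, sep = ":")
  new_anova_fit(terms, mse = mse, df_den = df_den,
                group_means = tapply(values, cell, mean),
                group_ns = tapply(values, cell, length),
                data = list(values = values,
                            factors = list(A = fa, B = fb)),
                type = "two-way (Type II)", degenerate = degenerate)
}

# group means/sizes for pairwise comparisons; `term` picks a factor of a
# two-way fit (marginal means), default is the single factor of a one-way.
pairwise_groups <- function(fit, term) {
  if (is.null(term)) {
    if (fit$type != "one-way")
      stop("specify 'term' to compare levels of a two-way fit",
           call. = FALSE)
    return(list(means = fit$group_means, ns = fit$group_ns))
  }
  f <- fit$data$factors[[term]]
  if (is.null(f)) stop("unknown term: ", term, call. = FALSE)
  list(means = tapply(fit$data$values, f, mean),
       ns = tapply(fit$data$values, f, length))
}

pairwise_table <- function(fit, term, method, alpha) {
  g <- pairwise_groups(fit, term)
  k <- length(g$means)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  idx <- utils::combn(k, 2)
  lev <- names(g$means)
  out <- data.frame(
    group_a = lev[idx[1, ]], group_b = lev[idx[2, ]],
    mean_diff = as.numeric(g$means[idx[1, ]] - g$means[idx[2, ]]),
    row.names = NULL)
  inv_n <- as.numeric(1 / g$ns[idx[1, ]] + 1 / g$ns[idx[2, ]])
  if (fit$mse == 0) {
    out$stderr <- 0
    out$statistic <- ifelse(out$mean_diff == 0, 0, Inf)
    out$p_value <- ifelse(out$mean_diff == 0, 1, 0)
    warning("zero residual variance; pairwise p-values degenerate",
            call. = FALSE)
  } else if (method == "LSD") {
    out$stderr <- sqrt(fit$mse * inv_n)
    out$statistic <- out$mean_diff / out$stderr
    out$p_value <- 2 * pt(-abs(out$statistic), fit$df_den)
  } else {
    out$stderr <- sqrt(fit$mse / 2 * inv_n)
    out$statistic <- abs(out$mean_diff) / out$stderr
    out$p_value <- vapply(out$statistic, function(q)
      1 - pstudrange(q, k, fit$df_den), numeric(1))
  }
  out$method <- method
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Fisher's least-significant-difference pairwise comparisons
#'
#' Unadjusted pairwise t-tests on the group means of a fitted ANOVA, using
#' the pooled residual mean square and its degrees of freedom. With only
#' two groups the p-value equals the pooled two-sample t-test's.
#'
#' @param fit an [oneway_anova()] or [twoway_anova()] result.
#' @param term for a two-way fit, which factor's (marginal) means to
#'   compare; ignored for one-way fits.
#' @param alpha significance threshold recorded in the `significant`
#'   column.
#' @return A data frame with one row per pair: `group_a`, `group_b`,
#'   `mean_diff`, `stderr`, `statistic`, `p_value`, `method`,
#'   `significant`.
#' @export
fisher_lsd <- function(fit, term = NULL, alpha = 0.05) {
  pairwise_table(fit, term, "LSD", alpha)
}

#' Tukey's honestly-significant-difference pairwise comparisons
#'
#' Studentized-range tests on the group means of a fitted ANOVA; p-values
#' come from [pstudrange()], the numerically integrated studentized-range
#' distribution, with the Tukey-Kramer standard error for unequal group
#' sizes. With two groups the HSD p-value equals the LSD p-value (the
#' `q = t * sqrt(2)` identity).
#'
#' @inheritParams fisher_lsd
#' @return As [fisher_lsd()], with `method = "HSD"`.
#' @export
tukey_hsd <- function(fit, term = NULL, alpha = 0.05) {
  pairwise_table(fit, term, "HSD", alpha)
}

#' Studentized-range cumulative distribution function
#'
#' `P(Q <= q)` for the range of `k` independent standard normals divided by
#' an independent estimate of their standard deviation on `df` degrees of
#' freedom. Evaluated by nested numerical quadrature: the inner integral is
#' the conditional probability that the range of `k` normals is below
#' `q * s`, the outer integrates over the scaled-chi density of `s`.
#' `df = Inf` gives the range distribution of standard normals.
#'
#' @param q quantile (scalar).
#' @param k number of groups (>= 2).
#' @param df error degrees of freedom (may be `Inf`).
#' @return Lower-tail probability.
#' @examples
#' 1 - pstudrange(4.339, 3, 6) # ~0.05: the classical 5% critical value
#' @export
pstudrange <- function(q, k, df) {
  if (length(q) != 1 || !is.finite(q))
    stop("'q' must be a single finite number", call. = FALSE)
  if (k < 2) stop("'k' must be at least 2", call. = FALSE)
  if (q <= 0) return(0)
  prange <- function(w) {
    # P(range of k std normals <= w)
    f <- function(z) k * dnorm(z) * (pnorm(z) - pnorm(z - w))^(k - 1)
    integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  }
  if (!is.finite(df)) return(prange(q))
  if (df < 1) stop("'df' must be >= 1", call. = FALSE)
  # density of S = sqrt(chi^2_df / df)
  log_c <- (df / 2) * log(df / 2) - lgamma(df / 2) + log(2)
  f_outer <- function(s) {
    vapply(s, function(si) {
      exp(log_c + (df - 1) * log(si) - df * si^2 / 2) * prange(q * si)
    }, numeric(1))
  }
  integrate(f_outer, 0, Inf, rel.tol = 1e-8)$value
}
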