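#' Ordinary least squares of one effect size on another
#'
#' Unweighted simple linear regression (e.g. spatial on temporal effect
#' sizes for sites with both), with the slope F-test.
#'
#' @param y,x Numeric vectors (n >= 3, `var(x) > 0`).
#' @return List with `slope`, `slope_se`, `intercept`, `intercept_se`,
#'   `r2`, `f`, `df1`, `df2`, `p`.
#' @export
simple_linear <- function(y, x) {
  if (length(y) < 3) stop("need >= 3 observations")
  if (stats::var(x) == 0) stop("constant predictor: regression degenerate")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  list(slope = co[2, 1], slope_se = co[2, 2],
       intercept = co[1, 1], intercept_se = co[1, 2],
       r2 = sm$r.squared,
       f = unname(sm$fstatistic[1]),
       df1 = unname(sm$fstatistic[2]), df2 = unname(sm$fstatistic[3]),
       p = stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
}

#' One-way ANOVA of effect sizes by a study characteristic
#'
#' @param values Numeric response (effect sizes).
#' @param groups Grouping factor (>= 2 levels, each with >= 2 values).
#' @return List with `f`, `df1`, `df2`, `p`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need >= 2 groups")
  if (any(sizes < 2))
    stop("singleton group(s): ", paste(names(sizes)[sizes < 2], collapse = ", "))
  tab <- stats::anova(stats::aov(values ~ groups))
  list(f = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
       p = tab$`Pr(>F)`[1])
}

.dixon_ratio <- function(x_sorted, variant) {
  n <- length(x_sorted)
  lo <- switch(variant,
    r10 = (x_sorted[2] - x_sorted[1]) / (x_sorted[n] - x_sorted[1]),
    r11 = (x_sorted[2] - x_sorted[1]) / (x_sorted[n - 1] - x_sorted[1]),
    r21 = (x_sorted[3] - x_sorted[1]) / (x_sorted[n - 1] - x_sorted[1]),
    r22 = (x_sorted[3] - x_sorted[1]) / (x_sorted[n - 2] - x_sorted[1]))
  hi <- switch(variant,
    r10 = (x_sorted[n] - x_sorted[n - 1]) / (x_sorted[n] - x_sorted[1]),
    r11 = (x_sorted[n] - x_sorted[n - 1]) / (x_sorted[n] - x_sorted[2]),
    r21 = (x_sorted[n] - x_sorted[n - 2]) / (x_sorted[n] - x_sorted[2]),
    r22 = (x_sorted[n] - x_sorted[n - 2]) / (x_sorted[n] - x_sorted[3]))
  c(lo = lo, hi = hi)
}

#' Dixon's Q test for a single outlier
#'
#' Two-sided test of the most extreme value in a small sample. The ratio
#' variant follows the conventional sample-size ranges (r10 for n = 3--7,
#' r11 for 8--10, r21 for 11--13, r22 for 14--30); the statistic is the
#' larger of the low-side and high-side ratios and the p-value comes from a
#' seeded Monte-Carlo null of that same maximum under standard-normal
#' sampling.
#'
#' @param values Numeric vector, 3 <= n <= 30.
#' @param n_rep Monte-Carlo replicates for the null (default 1e5; standard
#'   error of p below 0.002).
#' @param seed Seed for the null simulation (default 1; local RNG scope).
#' @return List with `q`, `p`, `flagged_index` (index into `values` of the
#'   tested extreme), `variant`.
#' @export
dixon_q <- function(values, n_rep = 1e5, seed = 1) {
  n <- length(values)
  if (n < 3 || n > 30) stop("Dixon test supports 3 <= n <= 30")
  variant <- if (n <= 7) "r10" else if (n <= 10) "r11" else if (n <= 13) "r21" else "r22"
  ord <- order(values)
  ratios <- .dixon_ratio(values[ord], variant)
  q <- max(ratios)
  flagged <- if (which.max(ratios) == 1L) ord[1] else ord[n]

  null_q <- withr::with_seed(seed, {
    sims <- matrix(stats::rnorm(n_rep * n), n_rep, n)
    sims <- t(apply(sims, 1, sort))
    lo2 <- switch(variant, r10 = 2, r11 = 2, r21 = 3, r22 = 3)
    hiL <- switch(variant, r10 = n, r11 = n - 1, r21 = n - 1, r22 = n - 2)
    hiU <- switch(variant, r10 = 1, r11 = 2, r21 = 2, r22 = 3)
    loS <- (sims[, lo2] - sims[, 1]) / (sims[, hiL] - sims[, 1])
    hiS <- (sims[, n] - sims[, n + 1 - lo2]) / (sims[, n] - sims[, hiU])
    pmax(loS, hiS)
  })
  list(q = unname(q), p = mean(null_q >= q), flagged_index = flagged,
       variant = variant)
}

#' Per-group sample size for a two-sample two-tailed t-test
#'
#' Smallest integer n per group reaching the target power at effect size d,
#' computed exactly from the noncentral t distribution.
#'
#' @param d Standardized effect size (> 0).
#' @param alpha Two-sided type-I error rate (default 0.05).
#' @param power Target power (default 0.80).
#' @return Integer n per group.
#' @export
ttest_power_n <- function(d, alpha = 0.05, power = 0.80) {
  if (d <= 0) stop("effect size must be > 0")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must be in (0, 1)")
  pow_at <- function(n) {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  }
  n <- 2
  while (pow_at(n) < power) n <- n + 1
  n
}
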