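# Profiled ML log-likelihood machinery for the normal random-/mixed-effects
# meta-regression: marginal model y_i ~ N(x_i' beta, v_i + tau2).

.wls_fit <- function(y, X, w) {
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  beta <- solve(XtWX, XtW %*% y)
  list(beta = drop(beta), vcov = solve(XtWX), resid = drop(y - X %*% beta))
}

.profile_ll <- function(tau2, y, X, v) {
  w <- 1 / (v + tau2)
  fit <- .wls_fit(y, X, w)
  -0.5 * sum(log(2 * pi * (v + tau2))) - 0.5 * sum(w * fit$resid^2)
}

#' Fit a mixed-effects meta-regression by maximum likelihood
#'
#' Inverse-variance weighted random-/mixed-effects model: observed effects
#' `y_i ~ N(x_i' beta, v_i + tau2)`. The between-site variance `tau2` is
#' estimated by maximizing the (full, constant-inclusive) marginal normal
#' likelihood over `tau2 >= 0` (bounded 1-D optimization, tolerance 1e-8),
#' with the coefficients profiled out by weighted least squares. The
#' intercept of a moderator-free model is the average weighted effect size.
#'
#' @param yi Effect sizes.
#' @param vi Sampling variances (> 0).
#' @param X Design matrix (first column the intercept). Default:
#'   intercept only.
#' @param level Confidence level for Wald CIs (multiplier 1.96 at 0.95).
#' @return Object of class `meta_ml`: list with `beta` (estimate, SE,
#'   ci_lb, ci_ub per term), `tau2`, `logLik`, `k`, `p`, plus inputs.
#' @export
fit_ml_meta <- function(yi, vi, X = NULL, level = 0.95) {
  yi <- as.numeric(yi); vi <- as.numeric(vi)
  k <- length(yi)
  if (is.null(X)) X <- matrix(1, k, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("intercept", paste0("x", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  if (any(!is.finite(vi)) || any(vi <= 0)) stop("sampling variances must be > 0")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  if (k <= ncol(X)) stop("need more effect sizes than fixed-effect terms")

  upper <- max(10 * stats::var(yi), 10 * max(vi), 1e-3)
  opt <- stats::optimize(.profile_ll, c(0, upper), y = yi, X = X, v = vi,
                         maximum = TRUE, tol = 1e-8)
  tau2 <- opt$maximum
  # optimize() cannot return an exact boundary point; snap when the boundary
  # is at least as good.
  if (.profile_ll(0, yi, X, vi) >= opt$objective) tau2 <- 0
  ll <- .profile_ll(tau2, yi, X, vi)

  w <- 1 / (vi + tau2)
  fit <- .wls_fit(yi, X, w)
  se <- sqrt(diag(fit$vcov))
  zc <- if (abs(level - 0.95) < 1e-12) 1.96 else stats::qnorm(1 - (1 - level) / 2)
  beta <- data.frame(term = colnames(X), estimate = fit$beta, se = se,
                     ci_lb = fit$beta - zc * se, ci_ub = fit$beta + zc * se,
                     row.names = NULL)
  structure(list(beta = beta, tau2 = tau2, logLik = ll, k = k, p = ncol(X),
                 yi = yi, vi = vi, X = X),
            class = "meta_ml")
}

#' @export
print.meta_ml <- function(x, ...) {
  cat(sprintf("ML meta-regression: k = %d, p = %d, tau2 = %.4f, logLik = %.3f, AICc = %.3f\n",
              x$k, x$p, x$tau2, x$logLik, aicc(x)))
  print(x$beta, digits = 4)
  invisible(x)
}

# Generalized Q at a given tau2 (weights 1/(v + tau2), WLS coefficients
# re-estimated at that tau2); monotone decreasing in tau2.
.q_gen <- function(tau2, y, X, v) {
  w <- 1 / (v + tau2)
  fit <- .wls_fit(y, X, w)
  sum(w * fit$resid^2)
}

#' Heterogeneity statistics with confidence intervals
#'
#' `I2 = 100 * tau2 / (tau2 + s2)` with the typical within-study variance
#' `s2 = (k - 1) * sum(w) / ((sum w)^2 - sum(w^2))`, `w = 1/v`. The `tau2`
#' CI inverts the generalized Q statistic (Q-profile method) against the
#' chi-square with `k - p` df; the `I2` CI plugs the `tau2` bounds into the
#' `I2` formula.
#'
#' @param model A fitted [fit_ml_meta()] object.
#' @param level Confidence level (default 0.95).
#' @return List with `tau2`, `tau2_ci`, `i2` (percent), `i2_ci`, `s2`.
#' @export
heterogeneity <- function(model, level = 0.95) {
  y <- model$yi; v <- model$vi; X <- model$X
  k <- model$k; df <- k - model$p
  if (k < 3) stop("k < 3: heterogeneity CIs unavailable")
  w <- 1 / v
  s2 <- (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  i2_of <- function(t2) 100 * t2 / (t2 + s2)

  alpha <- 1 - level
  q_hi <- stats::qchisq(1 - alpha / 2, df)  # defines the LOWER tau2 bound
  q_lo <- stats::qchisq(alpha / 2, df)      # defines the UPPER tau2 bound
  upper <- max(100 * (model$tau2 + s2), 1)
  while (.q_gen(upper, y, X, v) > q_lo && upper < 1e8) upper <- upper * 10

  solve_tau2 <- function(target) {
    if (.q_gen(0, y, X, v) <= target) return(0)
    stats::uniroot(function(t2) .q_gen(t2, y, X, v) - target,
                   c(0, upper), tol = 1e-10)$root
  }
  t2_lb <- solve_tau2(q_hi)
  t2_ub <- solve_tau2(q_lo)
  list(tau2 = model$tau2, tau2_ci = c(t2_lb, t2_ub),
       i2 = i2_of(model$tau2), i2_ci = i2_of(c(t2_lb, t2_ub)), s2 = s2)
}

#' Test for residual heterogeneity
#'
#' `QE = sum(w_i * (y_i - x_i' beta0)^2)` with fixed-effect weights
#' `w_i = 1/v_i` and `beta0` the weighted least-squares fit at `tau2 = 0`;
#' compared to the chi-square with `k - p` df.
#'
#' @param model A fitted [fit_ml_meta()] object.
#' @return List with `qe`, `df`, `p`.
#' @export
qe_test <- function(model) {
  qe <- .q_gen(0, model$yi, model$X, model$vi)
  df <- model$k - model$p
  list(qe = qe, df = df, p = stats::pchisq(qe, df, lower.tail = FALSE))
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2p + 2p(p+1)/(k - p - 1)` with `p` counting the fixed
#' effects plus `tau2`, and the constant-inclusive ML log-likelihood.
#'
#' @param model A fitted [fit_ml_meta()] object.
#' @return AICc value.
#' @export
aicc <- function(model) {
  p <- model$p + 1
  k <- model$k
  if (k - p - 1 <= 0) stop("k <= p + 1: AICc undefined")
  -2 * model$logLik + 2 * p + 2 * p * (p + 1) / (k - p - 1)
}

#' All-subsets moderator search ranked by AICc
#'
#' Fits every subset of the candidate moderators (including the intercept-only
#' and global models), skipping subsets that contain a forbidden
#' (collinear) pair, and ranks them by AICc with Akaike weights.
#'
#' @param yi,vi Effect sizes and sampling variances.
#' @param covariates Data.frame of scaled moderator columns (rows aligned
#'   with `yi`).
#' @param moderators Character vector of candidate moderator names
#'   (default: all columns of `covariates`).
#' @param forbidden_pairs 2-column matrix of moderator names that may not
#'   co-occur (from [scale_and_screen()]).
#' @return List with `table` (one row per model: moderators, AICc, delta,
#'   weight, logLik, tau2, intercept) sorted by AICc, and `models` (the
#'   fitted objects, same order).
#' @export
model_search <- function(yi, vi, covariates, moderators = NULL,
                         forbidden_pairs = NULL) {
  if (is.null(moderators)) moderators <- names(covariates)
  m <- length(moderators)
  subsets <- lapply(0:(2^m - 1), function(b) moderators[bitwAnd(b, 2^(0:(m - 1))) > 0])
  # a subset needs k > p_fixed + tau2 + 1 observations for a defined AICc
  k <- length(yi)
  subsets <- subsets[lengths(subsets) + 3 < k]
  if (length(subsets) == 0) stop("too few effect sizes for any candidate model")
  if (!is.null(forbidden_pairs) && nrow(forbidden_pairs) > 0) {
    ok <- vapply(subsets, function(s) {
      !any(apply(forbidden_pairs, 1, function(pr) all(pr %in% s)))
    }, TRUE)
    subsets <- subsets[ok]
  }
  fits <- lapply(subsets, function(s) {
    X <- cbind(intercept = 1,
               as.matrix(covariates[, s, drop = FALSE]))
    fit_ml_meta(yi, vi, X)
  })
  aic <- vapply(fits, aicc, 0)
  ord <- order(aic)
  fits <- fits[ord]; subsets <- subsets[ord]; aic <- aic[ord]
  delta <- aic - aic[1]
  wts <- exp(-delta / 2); wts <- wts / sum(wts)
  tab <- data.frame(
    moderators = vapply(subsets, function(s)
      if (length(s)) paste(s, collapse = " + ") else "(intercept only)", ""),
    n_moderators = lengths(subsets),
    aicc = aic, delta_aicc = delta, weight = wts,
    logLik = vapply(fits, `[[`, 0, "logLik"),
    tau2 = vapply(fits, `[[`, 0, "tau2"),
    intercept = vapply(fits, function(f) f$beta$estimate[1], 0))
  list(table = tab, models = fits)
}

#' Forest-plot data for a set of effect sizes
#'
#' Per-site estimate, Wald 95% CI and inverse-variance weight, plus the
#' pooled (intercept-only ML) summary row.
#'
#' @param effects Data.frame with `site_id`, `estimate`, `variance`.
#' @return Data.frame ordered by descending estimate, summary row last.
#' @export
forest_data <- function(effects) {
  fit <- fit_ml_meta(effects$estimate, effects$variance)
  w <- 1 / effects$variance
  rows <- data.frame(site_id = effects$site_id,
                     estimate = effects$estimate,
                     ci_lb = effects$estimate - 1.96 * sqrt(effects$variance),
                     ci_ub = effects$estimate + 1.96 * sqrt(effects$variance),
                     weight = w / sum(w), pooled = FALSE)
  rows <- rows[order(-rows$estimate), ]
  summary_row <- data.frame(site_id = "pooled", estimate = fit$beta$estimate[1],
                            ci_lb = fit$beta$ci_lb[1], ci_ub = fit$beta$ci_ub[1],
                            weight = NA_real_, pooled = TRUE)
  rbind(rows, summary_row)
}
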