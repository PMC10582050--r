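#' Hedges' d standardized mean difference
#'
#' Small-sample corrected standardized mean difference of space use between
#' disturbance groups. The difference is taken high minus low, so d < 0 means
#' lower space use under high disturbance (human avoidance).
#'
#' @param mean_low,sd_low,n_low Low-disturbance group mean, sample SD and
#'   number of units.
#' @param mean_high,sd_high,n_high High-disturbance group analogues.
#' @return List with `estimate` (d) and `variance`:
#'   `d = J * (mean_high - mean_low) / s_pooled`, with the (n-1)-weighted
#'   pooled SD and `J = 1 - 3 / (4 * (n_low + n_high - 2) - 1)`;
#'   `variance = 1/n_low + 1/n_high + d^2 / (2 * (n_low + n_high))`.
#' @export
hedges_d <- function(mean_low, sd_low, n_low, mean_high, sd_high, n_high) {
  if (n_low < 2 || n_high < 2) stop("need >= 2 units per group for SMD")
  sp2 <- ((n_low - 1) * sd_low^2 + (n_high - 1) * sd_high^2) / (n_low + n_high - 2)
  if (sp2 <= 0) stop("zero pooled SD: SMD degenerate")
  m <- n_low + n_high - 2
  J <- 1 - 3 / (4 * m - 1)
  d <- J * (mean_high - mean_low) / sqrt(sp2)
  list(estimate = d,
       variance = 1 / n_low + 1 / n_high + d^2 / (2 * (n_low + n_high)))
}

#' Log response ratio of nocturnality
#'
#' `RR = ln(p_low / p_high)` of the nocturnal proportions of active
#' observations in the low and high disturbance groups; RR < 0 means more
#' nocturnal activity under high disturbance. The sampling variance is
#' `(1 - p_low) / (n_low * p_low) + (1 - p_high) / (n_high * p_high)`.
#'
#' @param p_low,p_high Nocturnal proportions, strictly inside (0, 1).
#' @param n_low,n_high Numbers of active observations per group.
#' @return List with `estimate` (RR) and `variance`.
#' @export
log_response_ratio <- function(p_low, n_low, p_high, n_high) {
  if (n_low < 1 || n_high < 1) stop("need >= 1 active observation per group")
  if (p_low <= 0 || p_low >= 1 || p_high <= 0 || p_high >= 1)
    stop("boundary proportion (0 or 1): RR variance undefined")
  list(estimate = log(p_low / p_high),
       variance = (1 - p_low) / (n_low * p_low) + (1 - p_high) / (n_high * p_high))
}

#' Back-transform RR to a percent nocturnality shift
#'
#' Percent increase of the high-disturbance nocturnal proportion relative to
#' the low-disturbance one: `(exp(-rr) - 1) * 100`.
#'
#' @param rr Log response ratio (scalar or vector).
#' @return Percent change.
#' @export
percent_nocturnality_shift <- function(rr) {
  stopifnot(all(is.finite(rr)))
  (exp(-rr) - 1) * 100
}

#' Per-site effect sizes from group summaries
#'
#' @param groups Output of [summarize_groups()].
#' @param site_id Site identifier.
#' @param temporal_eligible Compute the temporal RR (skip for daytime-only
#'   direct-observation studies).
#' @return Data.frame of `EffectSize` rows (`site_id`, `response`,
#'   `estimate`, `variance`, `n_low`, `n_high`, `p_low`, `p_high`).
#' @export
site_effect_sizes <- function(groups, site_id, temporal_eligible = TRUE) {
  lo <- groups$low; hi <- groups$high
  rows <- list()
  if (lo$n_units >= 2 && hi$n_units >= 2 && (lo$sd > 0 || hi$sd > 0)) {
    d <- hedges_d(lo$mean, lo$sd, lo$n_units, hi$mean, hi$sd, hi$n_units)
    rows$spatial <- data.frame(site_id = site_id, response = "spatial",
                               estimate = d$estimate, variance = d$variance,
                               n_low = lo$n_units, n_high = hi$n_units,
                               p_low = NA_real_, p_high = NA_real_)
  }
  if (temporal_eligible && lo$active >= 1 && hi$active >= 1) {
    pl <- lo$nocturnal / lo$active; ph <- hi$nocturnal / hi$active
    if (pl > 0 && pl < 1 && ph > 0 && ph < 1) {
      rr <- log_response_ratio(pl, lo$active, ph, hi$active)
      rows$temporal <- data.frame(site_id = site_id, response = "temporal",
                                  estimate = rr$estimate, variance = rr$variance,
                                  n_low = lo$active, n_high = hi$active,
                                  p_low = pl, p_high = ph)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
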