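# Chromatographic lipophilicity and polarity descriptors from isocratic
# retention data. All logarithms are base 10.

#' Logarithmic capacity factor
#'
#' `k' = (tR - t0) / t0`; returns `log10(k')`. A solute eluting at (or
#' before) the dead time is unretained and has no defined log k'.
#'
#' @param tr retention time (min).
#' @param t0 dead time (min, > 0).
#' @return dimensionless log10 capacity factor.
#' @export
log_capacity_factor <- function(tr, t0) {
  if (any(t0 <= 0)) stop("dead time t0 must be positive", call. = FALSE)
  if (any(tr <= t0))
    stop("unretained solute: tR must exceed t0 for a defined log k'",
         call. = FALSE)
  log10((tr - t0) / t0)
}

#' BRlogD from the capacity factor at 60% acetonitrile
#'
#' Calibration of the XBridge Shield RP18 system against octanol/water
#' log D: `BRlogD = 3.31 * log k'60 + 2.79`.
#'
#' @param log_k60 log10 capacity factor at 60% acetonitrile.
#' @return BRlogD (dimensionless).
#' @export
brlogd <- function(log_k60) 3.31 * log_k60 + 2.79

#' Expected IAM lipophilicity from BRlogD
#'
#' The calculated (lipophilicity-only) IAM index:
#' `clog kW IAM = 0.92 * BRlogD - 1.03`.
#'
#' @param brlogd_value BRlogD value.
#' @return clog kW IAM (dimensionless).
#' @export
clogkw_iam <- function(brlogd_value) 0.92 * brlogd_value - 1.03

#' log kW IAM by extrapolation to a fully aqueous mobile phase
#'
#' Ordinary least squares of `log k'` against %ACN over the measured
#' mobile-phase series; the intercept is the 0% ACN (100% buffer) value.
#'
#' @param series data frame with columns `pct_acn`, `tr_min`, `t0_min`
#'   (see [read_retention_table()]); all points must be retained.
#' @return list with `logkw` (intercept), `slope`, `r_squared`, `n`.
#' @export
logkw_iam <- function(series) {
  if (nrow(series) < 2L || length(unique(series$pct_acn)) < 2L)
    stop("need >= 2 distinct %ACN points to extrapolate", call. = FALSE)
  logk <- mapply(log_capacity_factor, series$tr_min, series$t0_min)
  fit <- stats::lm(logk ~ pct_acn, data = data.frame(logk = logk,
                                                     pct_acn = series$pct_acn))
  ss_tot <- sum((logk - mean(logk))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(logkw = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r_squared = r2,
       n = nrow(series))
}

#' Polarity excess of the IAM retention over lipophilicity
#'
#' `Delta log kW IAM = log kW IAM - (0.92 * BRlogD - 1.03)`; higher values
#' mean the membrane-like phase retains the solute more than its bulk
#' lipophilicity alone explains, i.e. the compound is more polar.
#'
#' @param logkw_iam_value measured log kW IAM.
#' @param brlogd_value BRlogD.
#' @return dimensionless difference.
#' @export
delta_logkw_iam <- function(logkw_iam_value, brlogd_value) {
  logkw_iam_value - clogkw_iam(brlogd_value)
}

#' Octanol-toluene log P difference and IMHB-propensity class
#'
#' `Delta log P oct-tol = log P(octanol/water) - log P(toluene/water)`.
#' Values above the threshold (strictly; default 2.5) indicate exposed
#' donor groups and hence the absence of IMHBs; at or below it the
#' compound is classed IMHB-prone.
#'
#' @param logp_oct octanol/water log P.
#' @param logp_tol toluene/water log P.
#' @param threshold class boundary (default 2.5).
#' @return list with `value` and `class` (`"no-IMHB-indicator"` or
#'   `"IMHB-prone"`).
#' @export
delta_logp_octtol <- function(logp_oct, logp_tol, threshold = 2.5) {
  v <- logp_oct - logp_tol
  list(value = v,
       class = if (v > threshold) "no-IMHB-indicator" else "IMHB-prone")
}

#' PLRP-S deviation from retention linearity at high cosolvent
#'
#' Fits `log k'` against %ACN on the linear low/mid-cosolvent range
#' (default up to 90% ACN) and evaluates the excess of the observed
#' retention at `eval_acn` (default 100%) over the linear prediction.
#' A positive deviation exceeding twice the prediction standard error
#' flags retained-at-high-cosolvent behavior consistent with a
#' conformational collapse that masks polarity (chameleon-consistent).
#'
#' @param series data frame with `pct_acn`, `tr_min`, `t0_min`.
#' @param fit_max_acn upper %ACN bound of the linear fit window.
#' @param eval_acn %ACN of the evaluated point (must be present in
#'   `series`).
#' @return list with `predicted`, `observed`, `deviation`, `se`,
#'   `flagged` and the fit `slope`/`intercept`.
#' @export
plrps_deviation <- function(series, fit_max_acn = 90, eval_acn = 100) {
  fit_set <- series[series$pct_acn <= fit_max_acn, , drop = FALSE]
  if (nrow(fit_set) < 3L)
    stop(sprintf("need >= 3 points at or below %g%% ACN to fit", fit_max_acn),
         call. = FALSE)
  obs_row <- series[series$pct_acn == eval_acn, , drop = FALSE]
  if (nrow(obs_row) < 1L)
    stop(sprintf("no observed point at %g%% ACN", eval_acn), call. = FALSE)
  logk <- mapply(log_capacity_factor, fit_set$tr_min, fit_set$t0_min)
  df <- data.frame(logk = logk, pct_acn = fit_set$pct_acn)
  fit <- stats::lm(logk ~ pct_acn, data = df)
  pred <- stats::predict(fit, newdata = data.frame(pct_acn = eval_acn),
                         se.fit = TRUE)
  observed <- log_capacity_factor(obs_row$tr_min[1], obs_row$t0_min[1])
  deviation <- observed - pred$fit[[1]]
  # the 1e-6 floor keeps numerically-zero deviations on exact lines (where
  # the prediction SE is also zero) from being flagged
  list(predicted = pred$fit[[1]], observed = observed,
       deviation = deviation, se = pred$se.fit[[1]],
       flagged = deviation > max(2 * pred$se.fit[[1]], 1e-6),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Full chromatographic descriptor record
#'
#' Convenience wrapper combining the descriptor formulas for one compound:
#' BRlogD from the 60% ACN capacity factor, log kW IAM extrapolation,
#' Delta log kW IAM, PLRP-S deviation and (optionally) Delta log P
#' oct-tol.
#'
#' @param retention data frame from [read_retention_table()] with rows for
#'   systems `"XBridge"`, `"IAM"` and `"PLRP-S"`.
#' @param logp_oct,logp_tol optional shake-flask log P values.
#' @return list of descriptor values.
#' @export
lipophilicity_record <- function(retention, logp_oct = NULL,
                                 logp_tol = NULL) {
  out <- list()
  xb <- retention[retention$system == "XBridge" & retention$pct_acn == 60, ]
  if (nrow(xb)) {
    lk <- log_capacity_factor(xb$tr_min[1], xb$t0_min[1])
    out$log_k60 <- lk
    out$brlogd <- brlogd(lk)
  }
  iam <- retention[retention$system == "IAM", ]
  if (nrow(iam) >= 2) {
    fit <- logkw_iam(iam)
    out$logkw_iam <- fit$logkw
    if (!is.null(out$brlogd))
      out$delta_logkw_iam <- delta_logkw_iam(fit$logkw, out$brlogd)
  }
  pl <- retention[retention$system == "PLRP-S", ]
  if (nrow(pl) >= 4 && any(pl$pct_acn == 100))
    out$plrps <- plrps_deviation(pl)
  if (nrow(pl) && any(pl$pct_acn == 80)) {
    r80 <- pl[pl$pct_acn == 80, ][1, ]
    out$log_k80_plrps <- log_capacity_factor(r80$tr_min, r80$t0_min)
  }
  if (!is.null(logp_oct) && !is.null(logp_tol))
    out$delta_logp_octtol <- delta_logp_octtol(logp_oct, logp_tol)
  out
}
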