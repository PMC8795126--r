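# Summary-data MR estimators and the sensitivity/heterogeneity battery.
# All estimators consume the harmonized instrument data.frame produced by
# harmonizeInstruments(): columns b_X, se_X, b_Y, se_Y (plus identifiers).

.check_harmonized <- function(h, min_n, caller) {
  need <- c("b_X", "se_X", "b_Y", "se_Y")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop(caller, ": harmonized input lacks ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(h) < min_n)
    stop(sprintf("%s needs at least %d instruments (got %d)",
                 caller, min_n, nrow(h)), call. = FALSE)
  invisible(h)
}

#' Wald ratio estimate from a single instrument
#'
#' \code{beta = b_Y / b_X} with the first-order delta-method standard error
#' \code{se = se_Y / |b_X|} (exposure-side uncertainty ignored, as is
#' standard for strong instruments) and a two-sided normal p-value.
#'
#' @param inst one-row harmonized instrument data.frame.
#' @return list with beta, se, pvalue, nsnp, method.
#' @export
waldRatio <- function(inst) {
  .check_harmonized(inst, 1, "waldRatio")
  if (nrow(inst) != 1)
    stop("waldRatio takes a single instrument", call. = FALSE)
  if (inst$b_X == 0)
    stop("waldRatio undefined: exposure effect b_X is zero", call. = FALSE)
  beta <- inst$b_Y / inst$b_X
  se <- inst$se_Y / abs(inst$b_X)
  list(method = "wald", beta = beta, se = se,
       pvalue = .z_pvalue(beta, se), nsnp = 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights \code{1/se_Y^2}:
#' \deqn{\hat\theta = \sum w_j b_{Xj} b_{Yj} / \sum w_j b_{Xj}^2.}
#' Cochran's Q is the weighted residual sum of squares on J - 1 df. Under
#' the default multiplicative random-effects model the standard error is
#' inflated by \code{max(1, sqrt(Q/(J-1)))} (under-dispersion floored at 1);
#' \code{dispersion = "fixed"} gives the fixed-effect SE. P-values are
#' two-sided normal. The mean F statistic
#' \code{(1/J) sum (b_X/se_X)^2} summarizes instrument strength.
#'
#' @param insts harmonized instruments (J >= 2).
#' @param dispersion "mre" (multiplicative random effects, default) or
#'   "fixed".
#' @return list with the estimate (beta, se, pvalue, nsnp, method) and the
#'   IVW half of the heterogeneity bundle (cochran_q, q_df, q_pvalue,
#'   mean_f).
#' @export
mrIVW <- function(insts, dispersion = c("mre", "fixed")) {
  dispersion <- match.arg(dispersion)
  .check_harmonized(insts, 2, "mrIVW")
  J <- nrow(insts)
  w <- 1 / insts$se_Y^2
  sxx <- sum(w * insts$b_X^2)
  theta <- sum(w * insts$b_X * insts$b_Y) / sxx
  Q <- sum(w * (insts$b_Y - theta * insts$b_X)^2)
  q_df <- J - 1L
  phi <- if (dispersion == "mre") max(1, sqrt(Q / q_df)) else 1
  se <- sqrt(1 / sxx) * phi
  list(method = "ivw", beta = theta, se = se,
       pvalue = .z_pvalue(theta, se), nsnp = as.integer(J),
       cochran_q = Q, q_df = q_df,
       q_pvalue = stats::pchisq(Q, q_df, lower.tail = FALSE),
       mean_f = mean((insts$b_X / insts$se_X)^2))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with a free
#' intercept (weights \code{1/se_Y^2}) after orienting every instrument so
#' that \code{b_X >= 0}. A non-zero intercept indicates directional
#' horizontal pleiotropy; the slope is the pleiotropy-adjusted causal
#' estimate. Ruecker's Q' is the weighted residual sum of squares on J - 2
#' df; standard errors are inflated by \code{max(1, sqrt(Q'/(J-2)))} and
#' p-values use the t distribution with J - 2 df. Instrument strength for
#' Egger is summarized by
#' \deqn{I^2_{GX} = \max(0, (Q_{GX} - (J-1)) / Q_{GX}),}
#' with \eqn{Q_{GX} = \sum (b_{Xj} - \bar b_w)^2 / se_{Xj}^2} and
#' \eqn{\bar b_w} the \code{1/se_X^2}-weighted mean of the oriented exposure
#' effects; values at or below 0.9 signal regression-dilution bias.
#'
#' @param insts harmonized instruments (J >= 3).
#' @return list with \code{slope} and \code{intercept} estimate lists plus
#'   rucker_q, qprime_df, qprime_pvalue, i2_gx and nsnp.
#' @export
mrEgger <- function(insts) {
  .check_harmonized(insts, 3, "mrEgger")
  J <- nrow(insts)
  flip <- ifelse(insts$b_X < 0, -1, 1)
  bx <- insts$b_X * flip
  by <- insts$b_Y * flip
  w <- 1 / insts$se_Y^2
  sw <- sum(w)
  xbar <- sum(w * bx) / sw
  ybar <- sum(w * by) / sw
  sxx <- sum(w * (bx - xbar)^2)
  # relative guard: rounding noise on identical b_X must not pass as spread
  if (sxx <= 1e-12 * sum(w * bx^2))
    stop("mrEgger: no spread in exposure effects (singular design)",
         call. = FALSE)
  slope <- sum(w * (bx - xbar) * (by - ybar)) / sxx
  intercept <- ybar - slope * xbar
  Qp <- sum(w * (by - intercept - slope * bx)^2)
  df <- J - 2L
  phi <- max(1, sqrt(Qp / df))
  se_slope <- sqrt(1 / sxx) * phi
  se_int <- sqrt(1 / sw + xbar^2 / sxx) * phi
  t_p <- function(est, se) {
    p <- 2 * stats::pt(-abs(est / se), df = df)
    max(p, .Machine$double.xmin)
  }
  wx <- 1 / insts$se_X^2
  bxw <- sum(wx * bx) / sum(wx)
  q_gx <- sum((bx - bxw)^2 / insts$se_X^2)
  i2_gx <- if (q_gx > 0) max(0, (q_gx - (J - 1)) / q_gx) else 0
  list(
    slope = list(method = "egger_slope", beta = slope, se = se_slope,
                 pvalue = t_p(slope, se_slope), nsnp = as.integer(J)),
    intercept = list(method = "egger_intercept", beta = intercept,
                     se = se_int, pvalue = t_p(intercept, se_int),
                     nsnp = as.integer(J)),
    rucker_q = Qp, qprime_df = df,
    qprime_pvalue = stats::pchisq(Qp, df, lower.tail = FALSE),
    i2_gx = i2_gx, nsnp = as.integer(J))
}

#' Combined heterogeneity and instrument-strength diagnostics
#'
#' Bundles Cochran's Q (IVW fit), Ruecker's Q' (Egger fit), the mean F
#' statistic and I2_GX into one record, the diagnostic block reported
#' alongside each sensitivity analysis. Q' never exceeds Q for the same
#' instruments because the Egger line nests the through-origin IVW line.
#' A chi-square upper-tail p is reported for each statistic; when the
#' degrees of freedom are not positive the p-value is NA.
#'
#' @param insts harmonized instruments (J >= 3 for the Egger components;
#'   with J == 2 the Egger fields are NA).
#' @param dispersion passed to \code{\link{mrIVW}}.
#' @return list: cochran_q, q_df, q_pvalue, rucker_q, qprime_df,
#'   qprime_pvalue, mean_f, i2_gx.
#' @export
heterogeneityStats <- function(insts, dispersion = "mre") {
  ivw <- mrIVW(insts, dispersion = dispersion)
  out <- list(cochran_q = ivw$cochran_q, q_df = ivw$q_df,
              q_pvalue = if (ivw$q_df > 0) ivw$q_pvalue else NA_real_,
              rucker_q = NA_real_, qprime_df = NA_integer_,
              qprime_pvalue = NA_real_, mean_f = ivw$mean_f,
              i2_gx = NA_real_)
  if (nrow(insts) >= 3) {
    eg <- mrEgger(insts)
    out$rucker_q <- eg$rucker_q
    out$qprime_df <- eg$qprime_df
    out$qprime_pvalue <- if (eg$qprime_df > 0) eg$qprime_pvalue else NA_real_
    out$i2_gx <- eg$i2_gx
  }
  out
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW effect excluding each instrument in turn; with only
#' two instruments each exclusion falls back to the other SNP's Wald ratio.
#'
#' @param insts harmonized instruments (J >= 2).
#' @param dispersion passed to \code{\link{mrIVW}}.
#' @return data.frame with one row per excluded variant: excluded, method,
#'   beta, se, pvalue, nsnp.
#' @export
leaveOneOut <- function(insts, dispersion = "mre") {
  .check_harmonized(insts, 2, "leaveOneOut")
  J <- nrow(insts)
  rows <- lapply(seq_len(J), function(j) {
    rest <- insts[-j, , drop = FALSE]
    fit <- if (nrow(rest) >= 2) mrIVW(rest, dispersion = dispersion) else
      waldRatio(rest)
    data.frame(excluded = insts$variant_id[j], method = fit$method,
               beta = fit$beta, se = fit$se, pvalue = fit$pvalue,
               nsnp = fit$nsnp, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' MR-PRESSO global heterogeneity and outlier test
#'
#' Simulation-based residual test for pleiotropic instrument outliers. For
#' each instrument j the IVW estimate is recomputed on the other J - 1
#' instruments; the observed residual of instrument j is
#' \code{d_j = w_j (b_Yj - theta_(-j) b_Xj)^2} with \code{w_j = 1/se_Yj^2},
#' and the observed global statistic is \code{RSS = sum d_j}. Under the
#' no-pleiotropy null, \code{n_sim} parametric replicates are drawn
#' (\code{b*_X ~ N(b_X, se_X^2)}, \code{b*_Y ~ N(theta_(-j) b_X, se_Y^2)})
#' and the same statistics recomputed. Empirical p-values use the
#' \code{(# >= observed + 1)/(n_sim + 1)} correction; per-instrument
#' p-values are Bonferroni-adjusted by J and instruments with adjusted
#' p < 0.05 are flagged as outliers. Fully deterministic given \code{seed}.
#' The distortion test is not computed.
#'
#' @param insts harmonized instruments (J >= 4).
#' @param n_sim number of parametric replicates (>= 100).
#' @param seed integer seed for the simulation stream.
#' @return list: global_rss, global_pvalue, outliers (data.frame with
#'   variant_id, rss, pvalue, adj_pvalue, outlier), n_sim, seed.
#' @export
mrPresso <- function(insts, n_sim = 1000, seed = 0) {
  .check_harmonized(insts, 4, "mrPresso")
  if (n_sim < 100)
    stop("mrPresso needs n_sim >= 100", call. = FALSE)
  J <- nrow(insts)
  w <- 1 / insts$se_Y^2
  # leave-one-out IVW estimates via totals
  s1 <- sum(w * insts$b_X * insts$b_Y)
  s2 <- sum(w * insts$b_X^2)
  theta_mj <- (s1 - w * insts$b_X * insts$b_Y) / (s2 - w * insts$b_X^2)
  d_obs <- w * (insts$b_Y - theta_mj * insts$b_X)^2
  rss_obs <- sum(d_obs)

  set.seed(as.integer(.substream(seed, "presso")))
  bx_star <- matrix(stats::rnorm(n_sim * J, mean = rep(insts$b_X, each = n_sim),
                                 sd = rep(insts$se_X, each = n_sim)),
                    nrow = n_sim)
  by_star <- matrix(stats::rnorm(n_sim * J,
                                 mean = rep(theta_mj * insts$b_X, each = n_sim),
                                 sd = rep(insts$se_Y, each = n_sim)),
                    nrow = n_sim)
  W <- matrix(w, nrow = n_sim, ncol = J, byrow = TRUE)
  S1 <- rowSums(W * bx_star * by_star)
  S2 <- rowSums(W * bx_star^2)
  theta_star <- (S1 - W * bx_star * by_star) / (S2 - W * bx_star^2)
  d_star <- W * (by_star - theta_star * bx_star)^2
  rss_star <- rowSums(d_star)

  global_p <- (sum(rss_star >= rss_obs) + 1) / (n_sim + 1)
  out_p <- (colSums(d_star >= matrix(d_obs, nrow = n_sim, ncol = J,
                                     byrow = TRUE)) + 1) / (n_sim + 1)
  adj <- pmin(1, out_p * J)
  list(global_rss = rss_obs, global_pvalue = global_p,
       outliers = data.frame(variant_id = insts$variant_id, rss = d_obs,
                             pvalue = out_p, adj_pvalue = adj,
                             outlier = adj < 0.05, stringsAsFactors = FALSE),
       n_sim = as.integer(n_sim), seed = seed)
}

#' Grouped MR across genes or tissues
#'
#' Decomposes a pathway signal by re-estimating the effect within each
#' gene's (or tissue's) instruments: the Wald ratio for singleton groups,
#' IVW otherwise — the forest-plot table behind the gene/tissue
#' heterogeneity assessment. Empty groups are skipped.
#'
#' @param insts harmonized instruments carrying gene_id and tissue columns.
#' @param by "gene" or "tissue".
#' @param dispersion passed to \code{\link{mrIVW}}.
#' @return data.frame: group, method, nsnp, beta, se, pvalue.
#' @export
groupedMr <- function(insts, by = c("gene", "tissue"), dispersion = "mre") {
  by <- match.arg(by)
  col <- if (by == "gene") "gene_id" else "tissue"
  .check_harmonized(insts, 1, "groupedMr")
  rows <- lapply(split(insts, insts[[col]]), function(g) {
    if (!nrow(g)) return(NULL)
    fit <- if (nrow(g) >= 2) mrIVW(g, dispersion = dispersion) else waldRatio(g)
    data.frame(group = g[[col]][1], method = fit$method, nsnp = fit$nsnp,
               beta = fit$beta, se = fit$se, pvalue = fit$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Full sensitivity battery for one exposure-outcome pair
#'
#' Produces the sensitivity-analysis block reported for a significant
#' pathway: IVW (with Cochran's Q), MR-Egger intercept and slope (with
#' Ruecker's Q' and I2_GX), and MR-PRESSO (outlier-robust global test),
#' plus the mean F statistic.
#'
#' @param insts harmonized instruments (J >= 4 for the PRESSO row; with
#'   fewer the PRESSO row is omitted).
#' @param outcome label copied into the output.
#' @param exposure label copied into the output.
#' @param dispersion IVW dispersion model.
#' @param presso_nsim MR-PRESSO replicates.
#' @param seed seed for the PRESSO stream.
#' @return data.frame with columns exposure, outcome, method, nsnp, beta,
#'   se, pvalue, het_stat, het_df, het_pvalue, mean_f, i2_gx.
#' @export
sensitivityBattery <- function(insts, outcome = "outcome",
                               exposure = "exposure", dispersion = "mre",
                               presso_nsim = 1000, seed = 0) {
  .check_harmonized(insts, 3, "sensitivityBattery")
  ivw <- mrIVW(insts, dispersion = dispersion)
  eg <- mrEgger(insts)
  row <- function(fit, het_stat = NA_real_, het_df = NA_integer_,
                  het_p = NA_real_)
    data.frame(exposure = exposure, outcome = outcome, method = fit$method,
               nsnp = fit$nsnp, beta = fit$beta, se = fit$se,
               pvalue = fit$pvalue, het_stat = het_stat, het_df = het_df,
               het_pvalue = het_p, mean_f = ivw$mean_f, i2_gx = eg$i2_gx,
               stringsAsFactors = FALSE)
  out <- rbind(
    row(ivw, ivw$cochran_q, ivw$q_df, ivw$q_pvalue),
    row(eg$intercept),
    row(eg$slope, eg$rucker_q, eg$qprime_df, eg$qprime_pvalue))
  if (nrow(insts) >= 4) {
    pr <- mrPresso(insts, n_sim = presso_nsim, seed = seed)
    keep <- insts[!insts$variant_id %in%
                    pr$outliers$variant_id[pr$outliers$outlier], , drop = FALSE]
    fit <- if (nrow(keep) >= 2) mrIVW(keep, dispersion = dispersion) else ivw
    out <- rbind(out, data.frame(
      exposure = exposure, outcome = outcome, method = "presso",
      nsnp = nrow(keep), beta = fit$beta, se = fit$se, pvalue = fit$pvalue,
      het_stat = pr$global_rss, het_df = NA_integer_,
      het_pvalue = pr$global_pvalue, mean_f = ivw$mean_f, i2_gx = eg$i2_gx,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
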