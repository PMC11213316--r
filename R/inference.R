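#' Satterthwaite scale and degrees of freedom for a smoothed site
#'
#' Under the null, each squared moderated t-statistic is approximately
#' chi-square with 1 df (the large-`nu` limit of F(1, nu)), so the smoothed
#' statistic `S(x_i)` is a linear combination of scaled chi-squares with mean
#' `1 + sum_w` and variance `2 * (1 + sum_w2)`. Matching these two moments to
#' a scaled chi-square `p * chisq(q)` gives
#' `p = (1 + sum_w2) / (1 + sum_w)` and `q = (1 + sum_w)^2 / (1 + sum_w2)`.
#' With normalized weights and at least one neighbor, `p * q = 2` and
#' `q` lies in `[2, 4)`; an isolated site has `p = q = 1` (plain chi-square 1).
#'
#' @param sum_w sum of neighbor weights (vectorized).
#' @param sum_w2 sum of squared neighbor weights.
#' @return Data frame with columns `p_xi`, `q_xi`.
#' @export
satterthwaite_params <- function(sum_w, sum_w2) {
  if (any(sum_w < 0) || any(sum_w2 < 0)) stop("weight sums must be >= 0")
  data.frame(p_xi = (1 + sum_w2) / (1 + sum_w),
             q_xi = (1 + sum_w)^2 / (1 + sum_w2))
}

#' P-value of a smoothed statistic
#'
#' Upper-tail probability of `S / p_xi` against a chi-square distribution with
#' `q_xi` degrees of freedom.
#'
#' @param S smoothed statistic(s), `>= 0`.
#' @param params data frame from [satterthwaite_params()] (or anything with
#'   `p_xi` and `q_xi`).
#' @return P-values in `[0, 1]`, strictly decreasing in `S`.
#' @export
site_pvalue <- function(S, params) {
  if (any(S < 0)) stop("S must be >= 0")
  stats::pchisq(S / params$p_xi, df = params$q_xi, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment across all site-level tests
#'
#' Standard step-up FDR adjustment, applied genome-wide in one family.
#'
#' @param p p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1, order-preserving).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Retain significant sites
#'
#' Keeps sites with adjusted p-value strictly below `alpha` (ties at exactly
#' `alpha` are removed), preserving genomic order.
#'
#' @param sites data frame containing a `p_adj` column.
#' @param alpha significance level in (0, 1); default 0.05.
#' @return The significant subset of `sites`.
#' @export
filter_significant <- function(sites, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  sites[sites$p_adj < alpha, , drop = FALSE]
}

#' Site-level inference from smoothed statistics
#'
#' Attaches Satterthwaite constants, raw and BH-adjusted p-values and the
#' significance flag to smoothed sites. Sites whose squared statistic is not
#' finite (zero posterior variance upstream) are dropped with a warning before
#' testing.
#'
#' @param smoothed output of [smooth_sites()].
#' @param alpha significance level; default 0.05.
#' @return `smoothed` with columns `p_xi`, `q_xi`, `p_raw`, `p_adj`,
#'   `significant` appended.
#' @export
infer_sites <- function(smoothed, alpha = 0.05) {
  ok <- is.finite(smoothed$S)
  if (!all(ok)) {
    warning(sum(!ok), " site(s) with non-finite smoothed statistic excluded from inference")
    smoothed <- smoothed[ok, , drop = FALSE]
  }
  pr <- satterthwaite_params(smoothed$sum_w, smoothed$sum_w2)
  smoothed$p_xi <- pr$p_xi
  smoothed$q_xi <- pr$q_xi
  smoothed$p_raw <- site_pvalue(smoothed$S, pr)
  smoothed$p_adj <- bh_adjust(smoothed$p_raw)
  smoothed$significant <- smoothed$p_adj < alpha
  smoothed
}
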