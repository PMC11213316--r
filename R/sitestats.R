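#' Convert beta-values to M-values
#'
#' M-values, `M = log2(beta / (1 - beta))`, are the analysis scale for linear
#' modeling of methylation data: they are approximately homoscedastic and
#' unbounded, unlike the proportion-scale beta-values. Values are clipped to
#' `[clip, 1 - clip]` first so that boundary betas do not map to infinities.
#'
#' @param beta numeric vector/matrix of beta-values.
#' @param clip clipping threshold in (0, 0.5); default 0.001.
#' @return M-values with the same shape as `beta`.
#' @export
beta_to_m <- function(beta, clip = 0.001) {
  if (any(!is.finite(beta))) stop("beta contains non-finite values")
  if (clip <= 0 || clip >= 0.5) stop("clip must be in (0, 0.5)")
  b <- pmin(pmax(beta, clip), 1 - clip)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dim(out) <- dim(beta)
  dimnames(out) <- dimnames(beta)
  out
}

#' Describe the sample design
#'
#' @param condition per-sample condition label (two groups, e.g. control vs
#'   treatment). The reference (control) level is the first factor level; the
#'   contrast tested is treatment minus control.
#' @param covariates optional data frame of per-sample covariates (e.g. sex,
#'   HPV status), one row per sample.
#' @param subject optional per-sample subject identifier for paired designs;
#'   pairing is handled as fixed-effect blocking on subject.
#' @return A list of class `design_info`.
#' @export
design_info <- function(condition, covariates = NULL, subject = NULL) {
  cond <- factor(condition)
  if (nlevels(cond) != 2L) stop("condition must have exactly two levels, got: ",
                                paste(levels(cond), collapse = ", "))
  if (any(table(cond) < 2L)) stop("each condition needs at least 2 samples")
  n <- length(cond)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per sample")
  }
  if (!is.null(subject)) {
    if (length(subject) != n) stop("subject ids must cover all samples")
    subject <- factor(subject)
  }
  structure(list(condition = cond, covariates = covariates, subject = subject),
            class = "design_info")
}

#' Build the design matrix for site-level linear models
#'
#' Intercept + condition indicator (+ covariates + subject blocks). Errors if
#' the matrix is rank deficient, naming the collinear columns.
#'
#' @param design a [design_info()].
#' @return List with `X` (design matrix) and `coef` (name of the condition
#'   contrast column, treatment - control).
#' @export
build_design_matrix <- function(design) {
  stopifnot(inherits(design, "design_info"))
  df <- data.frame(.cond = design$condition)
  if (!is.null(design$covariates)) df <- cbind(df, design$covariates)
  if (!is.null(design$subject)) df$.subject <- design$subject
  X <- stats::model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coef <- paste0(".cond", levels(design$condition)[2L])
  list(X = X, coef = coef)
}

#' Fit per-probe linear models on M-values
#'
#' Ordinary least squares per probe (via limma's array linear-model fitter),
#' returning the condition contrast (treatment minus control) on the M-value
#' scale, the residual variance and residual degrees of freedom per probe.
#' Probes with any missing value are dropped with a message.
#'
#' @param m probes x samples matrix of M-values with probe ids as rownames.
#' @param design a [design_info()].
#' @return List of class `site_fit`: `probe_id`, `effect`, `sigma2`,
#'   `residual_df`, `stdev_unscaled` (per-probe unscaled SD of the contrast).
#' @export
fit_site_models <- function(m, design) {
  if (is.null(rownames(m))) rownames(m) <- paste0("probe", seq_len(nrow(m)))
  if (length(design$condition) != ncol(m))
    stop("design describes ", length(design$condition), " samples but matrix has ",
         ncol(m), " columns")
  cc <- stats::complete.cases(m)
  if (!all(cc)) {
    message(sum(!cc), " probe(s) with missing values dropped before model fitting")
    m <- m[cc, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("need at least 2 complete probes to fit site models")
  dm <- build_design_matrix(design)
  if (nrow(dm$X) - qr(dm$X)$rank < 1L) stop("residual degrees of freedom < 1")
  fit <- limma::lmFit(m, dm$X)
  j <- match(dm$coef, colnames(fit$coefficients))
  structure(list(probe_id = rownames(m),
                 effect = unname(fit$coefficients[, j]),
                 sigma2 = unname(fit$sigma^2),
                 residual_df = unname(fit$df.residual),
                 stdev_unscaled = unname(fit$stdev.unscaled[, j])),
            class = "site_fit")
}

#' Empirical-Bayes squeezing of residual variances
#'
#' Shrinks per-probe residual variances toward a common prior by moment
#' matching on log-variances (the moderated-t hierarchical model: true
#' variances follow a scaled inverse chi-square prior with `d0` degrees of
#' freedom and scale `s0_sq`). Delegates to limma's `squeezeVar`.
#'
#' @param sigma2 per-probe residual variances (>= 0, finite).
#' @param residual_df residual degrees of freedom (scalar or per probe).
#' @return List with `d0` (prior df, possibly `Inf`), `s0_sq` (prior
#'   variance) and `var_post` (posterior = squeezed per-probe variances,
#'   `(d0*s0_sq + df*sigma2) / (d0 + df)`).
#' @export
squeeze_variances <- function(sigma2, residual_df) {
  if (length(sigma2) < 2L) stop("need at least 2 probes to estimate the variance prior")
  if (any(!is.finite(sigma2)) || any(sigma2 < 0)) stop("sigma2 must be finite and >= 0")
  if (all(sigma2 == 0)) stop("degenerate data: all residual variances are zero")
  sq <- limma::squeezeVar(sigma2, df = residual_df)
  list(d0 = sq$df.prior, s0_sq = sq$var.prior, var_post = sq$var.post)
}

# numerical stand-in for an infinite prior df when forming total df
.D0_CAP <- 1e9

#' Moderated t-statistics and squared statistics
#'
#' Combines the per-probe contrast with the squeezed variance into the
#' moderated t-statistic `t = effect / (stdev_unscaled * sqrt(var_post))`,
#' its total degrees of freedom `nu = residual_df + d0` (d0 capped at 1e9 to
#' stand in for an infinite prior), and `y = t^2`, the squared statistic that
#' feeds kernel smoothing.
#'
#' @param fit a `site_fit` from [fit_site_models()].
#' @param squeeze output of [squeeze_variances()]; computed from `fit` when
#'   omitted. Pass `d0 = 0` manually to recover ordinary (unmoderated) t.
#' @return Data frame of class `site_stats` with columns `probe_id`, `effect`,
#'   `sigma2`, `residual_df`, `moderated_t`, `nu`, `y`; prior estimates are
#'   attached as attributes `d0` and `s0_sq`. Probes with zero posterior
#'   variance get infinite t (flagged with a warning); they are excluded
#'   downstream.
#' @export
moderated_t <- function(fit, squeeze = NULL) {
  stopifnot(inherits(fit, "site_fit"))
  if (is.null(squeeze)) squeeze <- squeeze_variances(fit$sigma2, fit$residual_df)
  d0 <- min(squeeze$d0, .D0_CAP)
  var_post <- if (is.infinite(squeeze$d0)) rep_len(squeeze$s0_sq, length(fit$effect)) else squeeze$var_post
  se <- fit$stdev_unscaled * sqrt(var_post)
  t <- fit$effect / se
  if (any(!is.finite(t))) warning(sum(!is.finite(t)),
    " probe(s) with zero posterior variance reported as infinite t; excluded downstream")
  out <- data.frame(probe_id = fit$probe_id,
                    effect = fit$effect,
                    sigma2 = fit$sigma2,
                    residual_df = fit$residual_df,
                    moderated_t = t,
                    nu = fit$residual_df + d0,
                    y = t^2,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- squeeze$d0
  attr(out, "s0_sq") <- squeeze$s0_sq
  class(out) <- c("site_stats", "data.frame")
  out
}

#' Site-level statistics in one step
#'
#' Fits per-probe linear models, squeezes variances, and returns moderated
#' t-statistics and `y = t^2` per probe.
#'
#' @inheritParams fit_site_models
#' @return See [moderated_t()].
#' @export
site_statistics <- function(m, design) {
  moderated_t(fit_site_models(m, design))
}
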