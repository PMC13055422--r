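#' Inverse-variance fixed-effect pooling
#'
#' Pools study-level log odds ratios with weights `1/se^2`. The pooled mean is
#' `sum(w*y)/sum(w)`, its standard error `1/sqrt(sum(w))`, and Cochran's Q is
#' the weighted squared deviation of the studies from the pooled mean. This
#' is the building block of the DerSimonian-Laird estimator and is also
#' returned by [pool_dl()] whenever the moment estimate of the between-study
#' variance truncates to zero.
#'
#' @param log_or numeric vector of study log odds ratios.
#' @param se numeric vector of within-study standard errors (all > 0).
#' @param factor_id optional label carried into the result.
#' @return A `univariate_pool` object: list with `factor_id`, `n_studies`,
#'   `method`, `mu_hat`, `se_mu`, `ci95`, `tau2`, `Q`, `df`, `Q_p`, `I2`,
#'   `z`, `p`, and normalized `weights`.
#' @export
#' @examples
#' pool_fixed(c(0.5, 0.3), c(0.2, 0.2))
pool_fixed <- function(log_or, se, factor_id = NA_character_) {
  check_estimates(log_or, se)
  w <- 1 / se^2
  mu <- sum(w * log_or) / sum(w)
  se_mu <- sqrt(1 / sum(w))
  Q <- sum(w * (log_or - mu)^2)
  new_pool(factor_id, log_or, se, method = "FE",
           mu = mu, se_mu = se_mu, tau2 = 0, Q = Q, weights = w / sum(w))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment-based random-effects pooling of log odds ratios. The between-study
#' variance is `tau2 = max(0, (Q - df) / (sum(W) - sum(W^2)/sum(W)))` with
#' fixed-effect weights `W = 1/se^2`; the pooled estimate then uses
#' random-effects weights `1/(se^2 + tau2)`. Confidence intervals are Wald
#' (normal) at the 95% level, and the overall-effect test is the two-sided
#' normal z-test. When `Q <= df` the estimator truncates at `tau2 = 0` and
#' the result coincides with [pool_fixed()].
#'
#' @inheritParams pool_fixed
#' @return A `univariate_pool` object (see [pool_fixed()]), `method = "DL"`.
#' @export
#' @examples
#' tab <- glottic_table1()
#' keep <- !is.na(tab$log_or[, "aci"])
#' pool_dl(tab$log_or[keep, "aci"], tab$se[keep, "aci"], "aci")
pool_dl <- function(log_or, se, factor_id = NA_character_) {
  check_estimates(log_or, se)
  w <- 1 / se^2
  mu_f <- sum(w * log_or) / sum(w)
  Q <- sum(w * (log_or - mu_f)^2)
  df <- length(log_or) - 1
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (df > 0 && denom > 0) max(0, (Q - df) / denom) else 0
  w_re <- 1 / (se^2 + tau2)
  mu <- sum(w_re * log_or) / sum(w_re)
  se_mu <- sqrt(1 / sum(w_re))
  new_pool(factor_id, log_or, se, method = "DL",
           mu = mu, se_mu = se_mu, tau2 = tau2, Q = Q,
           weights = w_re / sum(w_re))
}

check_estimates <- function(log_or, se) {
  if (length(log_or) == 0) stop("at least one estimate is required")
  if (length(log_or) != length(se)) stop("log_or and se lengths differ")
  if (any(!is.finite(log_or))) stop("non-finite log odds ratio")
  if (any(!is.finite(se)) || any(se <= 0)) stop("standard errors must be > 0")
}

new_pool <- function(factor_id, log_or, se, method, mu, se_mu, tau2, Q, weights) {
  df <- length(log_or) - 1
  z <- mu / se_mu
  structure(list(
    factor_id = factor_id,
    n_studies = length(log_or),
    method = method,
    mu_hat = mu,
    se_mu = se_mu,
    ci95 = c(lo = mu - 1.96 * se_mu, hi = mu + 1.96 * se_mu),
    tau2 = tau2,
    Q = Q,
    df = df,
    Q_p = if (df >= 1) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_,
    I2 = i_squared(Q, df),
    z = z,
    p = 2 * stats::pnorm(-abs(z)),
    weights = weights), class = "univariate_pool")
}

#' @export
print.univariate_pool <- function(x, ...) {
  cat(sprintf("%s pooling%s: %d studies\n", x$method,
              if (is.na(x$factor_id)) "" else paste0(" [", x$factor_id, "]"),
              x$n_studies))
  cat(sprintf("  log OR %.3f (95%% CI %.3f to %.3f), OR %.2f\n",
              x$mu_hat, x$ci95["lo"], x$ci95["hi"], exp(x$mu_hat)))
  cat(sprintf("  tau2 %.4f, Q %.2f (df %d, p %s), I2 %.1f%%, z %.2f, p %.4f\n",
              x$tau2, x$Q, x$df,
              if (is.na(x$Q_p)) "NA" else sprintf("%.3f", x$Q_p),
              x$I2, x$z, x$p))
  invisible(x)
}

#' Higgins I-squared heterogeneity statistic
#'
#' `I2 = max(0, (Q - df) / Q) * 100`, the percentage of total variability in
#' the study estimates attributable to between-study heterogeneity rather
#' than sampling error. Values above 50% are conventionally read as
#' substantial heterogeneity; the companion Q-test is usually declared
#' significant at p < 0.10.
#'
#' @param Q Cochran heterogeneity statistic (>= 0).
#' @param df degrees of freedom, `n_studies - 1`.
#' @return Percentage in `[0, 100)`.
#' @export
#' @examples
#' i_squared(16, 8) # 50
i_squared <- function(Q, df) {
  if (!is.finite(Q) || Q < 0) stop("Q must be a non-negative number")
  if (df < 0) stop("df must be >= 0")
  if (Q <= 0) return(0)
  max(0, (Q - df) / Q) * 100
}

#' Reconstruct a Wald z statistic from an OR and its 95% CI
#'
#' Back-calculates the log-scale standard error from the width of a reported
#' 95% confidence interval, `se = (log(hi) - log(lo)) / (2 * 1.96)`, and
#' returns `z = log(or) / se`. This is a consistency check for published
#' summaries (the reconstruction is exact only up to the rounding of the
#' printed interval), not an estimator.
#'
#' @param or_point reported odds ratio (> 0).
#' @param ci length-2 vector `(lo, hi)` of the 95% CI bounds.
#' @return The Wald z statistic.
#' @export
#' @examples
#' z_from_or_ci(1.61, c(1.15, 2.26)) # about 2.8
z_from_or_ci <- function(or_point, ci) {
  if (length(ci) != 2) stop("ci must be (lo, hi)")
  lo <- ci[1]; hi <- ci[2]
  if (!(lo > 0 && hi > 0 && or_point > 0)) stop("OR and CI bounds must be > 0")
  if (!(lo < or_point && or_point < hi)) stop("need lo < or_point < hi")
  se <- (log(hi) - log(lo)) / (2 * stats::qnorm(0.975))
  log(or_point) / se
}

#' Forest-plot data for one factor
#'
#' Exports the per-study rows (log OR, 95% CI, normalized random-effects
#' weight) and the appended DerSimonian-Laird pooled row for a single factor,
#' in study order. Intended as the data layer behind a forest plot.
#'
#' @param table an `effect_table`.
#' @param factor_id the factor to export.
#' @return A data frame with columns `study`, `log_or`, `se`, `ci_lo`,
#'   `ci_hi`, `weight_pct` and a final `"pooled (DL)"` row.
#' @export
#' @examples
#' forest_data(glottic_table1(), "aci")
forest_data <- function(table, factor_id) {
  stopifnot(inherits(table, "effect_table"))
  if (!factor_id %in% colnames(table$log_or))
    stop("unknown factor: ", factor_id)
  keep <- !is.na(table$log_or[, factor_id])
  if (!any(keep)) stop("factor ", factor_id, " has no reporting studies")
  y <- table$log_or[keep, factor_id]
  s <- table$se[keep, factor_id]
  fit <- pool_dl(y, s, factor_id)
  rows <- data.frame(
    study = table$studies$citation_label[keep],
    log_or = y, se = s,
    ci_lo = y - 1.96 * s, ci_hi = y + 1.96 * s,
    weight_pct = 100 * fit$weights,
    stringsAsFactors = FALSE)
  pooled <- data.frame(
    study = "pooled (DL)",
    log_or = fit$mu_hat, se = fit$se_mu,
    ci_lo = fit$ci95[["lo"]], ci_hi = fit$ci95[["hi"]],
    weight_pct = 100, stringsAsFactors = FALSE)
  out <- rbind(rows, pooled)
  rownames(out) <- NULL
  out
}

#' Pool one factor of an effect table
#'
#' Convenience wrapper extracting a factor's column and applying
#' [pool_dl()] (default) or [pool_fixed()].
#'
#' @param table an `effect_table`.
#' @param factor_id the factor to pool.
#' @param method `"DL"` or `"FE"`.
#' @return A `univariate_pool` object.
#' @export
pool_factor <- function(table, factor_id, method = c("DL", "FE")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "effect_table"))
  if (!factor_id %in% colnames(table$log_or))
    stop("unknown factor: ", factor_id)
  keep <- !is.na(table$log_or[, factor_id])
  f <- if (method == "DL") pool_dl else pool_fixed
  f(table$log_or[keep, factor_id], table$se[keep, factor_id], factor_id)
}
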