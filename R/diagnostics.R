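#' Split-chain potential scale reduction factor
#'
#' Computes the split-chain Rhat: each chain is halved, the halves are
#' treated as separate sequences, and the usual between/within variance
#' ratio is formed. Values near 1.00 indicate the chains sample the same
#' stationary distribution; values clearly above 1 indicate non-convergence
#' (splitting also catches a single slowly-trending chain, which the
#' unsplit statistic misses).
#'
#' @param x a matrix with one column per chain, a list of numeric vectors,
#'   or a [coda::mcmc.list] of univariate chains.
#' @return The split-chain Rhat (>= 1, up to floating point).
#' @export
#' @examples
#' set.seed(1)
#' rhat_split(matrix(rnorm(4000), ncol = 4)) # ~1.00
rhat_split <- function(x) {
  if (inherits(x, "mcmc.list")) x <- lapply(x, as.numeric)
  if (is.matrix(x)) x <- lapply(seq_len(ncol(x)), function(j) x[, j])
  stopifnot(is.list(x), length(x) >= 1)
  n2 <- floor(min(lengths(x)) / 2)
  if (n2 < 2) return(NA_real_)
  halves <- unlist(lapply(x, function(v)
    list(v[seq_len(n2)], v[seq_len(n2) + n2])), recursive = FALSE)
  m <- length(halves)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n2 * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

mcmc_diagnostics <- function(mcmc_list, params) {
  ess_all <- coda::effectiveSize(mcmc_list[, params, drop = FALSE])
  rhat <- vapply(params, function(p)
    rhat_split(lapply(mcmc_list, function(ch) as.numeric(ch[, p]))), 0)
  data.frame(parameter = params, rhat = rhat,
             ess = as.numeric(ess_all[params]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Convergence diagnostics of an MCMC fit
#'
#' Per monitored scalar parameter: split-chain Rhat, effective sample size,
#' and a pass flag against the thresholds stored in the fit's config
#' (defaults: Rhat < 1.01 and ESS > 400). Trace series for plotting are in
#' `fit$draws` (a [coda::mcmc.list]).
#'
#' @param fit an `mvma_fit`.
#' @return Data frame with columns `parameter`, `rhat`, `ess`, `pass`; the
#'   attribute `"converged"` carries the overall gate.
#' @export
convergence_report <- function(fit) {
  stopifnot(inherits(fit, "mvma_fit"))
  if (fit$config$chains < 2)
    warning("fewer than 2 chains: between-chain diagnostics are not meaningful")
  d <- fit$diagnostics
  d$pass <- d$rhat < fit$config$rhat_threshold &
    d$ess > fit$config$ess_threshold
  attr(d, "converged") <- fit$converged
  d
}
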