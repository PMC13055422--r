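#' Configuration for a Bayesian multivariate meta-analysis fit
#'
#' Bundles the model variant, prior hyperparameters and MCMC protocol for
#' [fit_mvma()]. The default protocol is the full production run (3 chains,
#' 100 000 kept updates after a 100 000-update burn-in); [mvma_profile()]
#' supplies shorter presets for interactive work and test suites.
#'
#' Variants:
#' * `"H"` - within- and between-study correlations: each study's observed
#'   subvector is multivariate normal around its latent effects with
#'   covariance `se_j * se_k * rho_w` off the diagonal (a single shared
#'   within-study correlation `rho_w`, given a uniform prior restricted to
#'   the positive-definite range), and the latent study effects are
#'   multivariate normal around the overall effects with a full
#'   between-study correlation matrix.
#' * `"M0"` - between-study correlations only (diagonal within-study
#'   covariance).
#' * `"U"` - fully independent univariate random-effects pooling per factor.
#'
#' Priors: each overall log OR has a vague normal prior with SD
#' `prior_mu_sd`. In Model U each between-study SD has a `U(0,
#' prior_tau_upper)` prior. In Models H/M0 the between-study covariance uses
#' a separation-style scaled inverse-Wishart: a correlation matrix with
#' near-uniform marginal priors (inverse-Wishart with `J + 1` degrees of
#' freedom, rescaled to unit diagonal) and scale-expansion factors
#' `U(0, prior_tau_upper)`, giving weakly-informative priors on the
#' between-study SDs. `between_corr = "identity"` fixes the between-study
#' correlation matrix to the identity (used to verify the reduction
#' M0 -> U); `rho_w_fixed` pins the within-study correlation of Model H
#' (0 reduces H to M0).
#'
#' @param variant one of `"H"`, `"M0"`, `"U"`.
#' @param chains number of MCMC chains (>= 2 for convergence diagnostics).
#' @param burn_in discarded updates per chain (after `adapt` adaptation steps).
#' @param draws kept updates per chain.
#' @param thin thinning interval for kept draws.
#' @param seed integer seed; every chain's RNG is derived from it.
#' @param prior_mu_sd SD of the normal prior on each overall log OR.
#' @param prior_tau_upper upper bound of the uniform prior on each
#'   between-study SD (Model U) or scale-expansion factor (H/M0).
#' @param rho_w_fixed optional fixed value for the within-study correlation
#'   (Model H only); `NULL` means it gets the uniform prior.
#' @param between_corr `"wishart"` (estimated correlation matrix) or
#'   `"identity"`.
#' @param adapt JAGS adaptation steps before burn-in.
#' @param monitor_correlation monitor the between-study correlation matrix
#'   (H/M0)?
#' @param rhat_threshold,ess_threshold convergence gates: every monitored
#'   scalar must have split-chain Rhat below and effective sample size above
#'   these values for the fit to be flagged converged.
#' @return An object of class `mvma_config`.
#' @export
#' @examples
#' mvma_config("U", seed = 1, burn_in = 2000, draws = 2000)
mvma_config <- function(variant = c("U", "M0", "H"),
                        chains = 3, burn_in = 100000, draws = 100000,
                        thin = 1, seed = 1,
                        prior_mu_sd = 10, prior_tau_upper = 5,
                        rho_w_fixed = NULL,
                        between_corr = c("wishart", "identity"),
                        adapt = 1000,
                        monitor_correlation = TRUE,
                        rhat_threshold = 1.01, ess_threshold = 400) {
  variant <- match.arg(variant)
  between_corr <- match.arg(between_corr)
  stopifnot(chains >= 2, burn_in > 0, draws > 0, thin >= 1,
            prior_mu_sd > 0, prior_tau_upper > 0)
  if (!is.null(rho_w_fixed) && abs(rho_w_fixed) >= 1)
    stop("|rho_w_fixed| must be < 1")
  structure(list(variant = variant, chains = as.integer(chains),
                 burn_in = as.integer(burn_in), draws = as.integer(draws),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_mu_sd = prior_mu_sd,
                 prior_tau_upper = prior_tau_upper,
                 rho_w_fixed = rho_w_fixed, between_corr = between_corr,
                 adapt = as.integer(adapt),
                 monitor_correlation = isTRUE(monitor_correlation),
                 rhat_threshold = rhat_threshold,
                 ess_threshold = ess_threshold),
            class = "mvma_config")
}

#' MCMC protocol presets
#'
#' `"full"` is the production protocol (3 chains, 100 000 burn-in, 100 000
#' kept updates). `"test"` is a short profile (3 chains, 2 000 + 2 000) for
#' simulation sweeps. `"reduced"` (3 chains, 4 000 + 8 000) is a middle
#' ground whose Monte Carlo error on the glottic fixture is a few hundredths
#' of a log OR, adequate whenever tolerances are on the order of a tenth.
#'
#' @param name `"full"`, `"reduced"` or `"test"`.
#' @param ... further arguments passed to [mvma_config()].
#' @return An `mvma_config`.
#' @export
mvma_profile <- function(name = c("full", "reduced", "test"), ...) {
  name <- match.arg(name)
  sizes <- switch(name,
                  full = c(burn_in = 100000, draws = 100000),
                  reduced = c(burn_in = 4000, draws = 8000),
                  test = c(burn_in = 2000, draws = 2000))
  mvma_config(burn_in = sizes["burn_in"], draws = sizes["draws"], ...)
}

#' Within-study covariance matrix of one study's observed estimates
#'
#' Under Models M0 and U the matrix is diagonal with entries `se^2`. Under
#' Model H every off-diagonal entry is `rho_w * se_j * se_k`, a single shared
#' within-study correlation. The constant-correlation structure is positive
#' definite only for `rho_w > -1/(n - 1)`; values outside the admissible
#' range are rejected.
#'
#' @param se numeric vector of within-study standard errors for the factors
#'   the study reports.
#' @param variant `"H"`, `"M0"` or `"U"`.
#' @param rho_w within-study correlation (Model H only).
#' @return Symmetric positive-definite matrix with diagonal `se^2`.
#' @export
#' @examples
#' build_within_covariance(c(0.2, 0.3), "H", rho_w = 0.5) # off-diagonal 0.03
build_within_covariance <- function(se, variant = c("H", "M0", "U"),
                                    rho_w = 0) {
  variant <- match.arg(variant)
  if (length(se) < 1 || any(se <= 0)) stop("se must be positive")
  if (variant != "H" || length(se) == 1) return(diag(se^2, length(se)))
  if (abs(rho_w) >= 1) stop("|rho_w| must be < 1")
  if (rho_w <= -1 / (length(se) - 1))
    stop(sprintf("rho_w = %.3f makes a %d-dimensional constant-correlation matrix non-positive-definite",
                 rho_w, length(se)))
  S <- rho_w * tcrossprod(se)
  diag(S) <- se^2
  S
}

jags_model_u <- function() {
  # study effects integrated out exactly: y_ij ~ N(mu_j, s_ij^2 + tau_j^2).
  # The marginal form has no latent states, so the sampler stays mobile even
  # as tau -> 0 (the centered hierarchical form couples mu and the latent
  # effects rigidly there)
  "model {
    for (n in 1:N) {
      y[n] ~ dnorm(mu[fi[n]], 1 / (v[n] + pow(tau[fi[n]], 2)))
    }
    for (j in 1:J) {
      mu[j] ~ dnorm(0, pmu)
      tau[j] ~ dunif(0, tau_upper)
    }
  }"
}

jags_latent_block <- function(between_corr) {
  if (between_corr == "wishart") {
    "
    for (i in 1:I) {
      u[i,1:J] ~ dmnorm(zero[1:J], OmegaU[1:J,1:J])
      for (j in 1:J) { theta[i,j] <- mu[j] + xi[j]*u[i,j] }
    }
    for (j in 1:J) {
      mu[j] ~ dnorm(0, pmu)
      xi[j] ~ dunif(0, tau_upper)
    }
    OmegaU[1:J,1:J] ~ dwish(I0[1:J,1:J], wdf)
    SigU <- inverse(OmegaU)
    for (j in 1:J) {
      tau[j] <- xi[j]*sqrt(SigU[j,j])
      for (k in 1:J) { R[j,k] <- SigU[j,k]/sqrt(SigU[j,j]*SigU[k,k]) }
    }"
  } else {
    "
    for (i in 1:I) {
      u[i,1:J] ~ dmnorm(zero[1:J], I0[1:J,1:J])
      for (j in 1:J) { theta[i,j] <- mu[j] + xi[j]*u[i,j] }
    }
    for (j in 1:J) {
      mu[j] ~ dnorm(0, pmu)
      xi[j] ~ dunif(0, tau_upper)
      tau[j] <- xi[j]
    }"
  }
}

jags_model_m0 <- function(between_corr) {
  paste0("model {
    for (n in 1:N) { y[n] ~ dnorm(theta[si[n], fi[n]], py[n]) }",
    jags_latent_block(between_corr), "
  }")
}

jags_model_h <- function(between_corr, n_single, rho_fixed) {
  rho_line <- if (is.null(rho_fixed)) "rhow ~ dunif(rlo, rhi)"
              else "rhow <- rw_fixed"
  single_block <- if (n_single > 0)
    "
    for (n in 1:Ns) { ys[n] ~ dnorm(theta[ss[n], fs[n]], pys[n]) }" else ""
  paste0("model {
    for (q in 1:Imv) {
      for (a in 1:nobs[q]) {
        m[q,a] <- theta[mvs[q], fidx[q,a]]
        for (b in 1:nobs[q]) {
          Sw[q,a,b] <- se[q,a]*se[q,b]*((1-rhow)*equals(a,b) + rhow)
        }
      }
      Pw[q,1:nobs[q],1:nobs[q]] <- inverse(Sw[q,1:nobs[q],1:nobs[q]])
      y[q,1:nobs[q]] ~ dmnorm(m[q,1:nobs[q]], Pw[q,1:nobs[q],1:nobs[q]])
    }", single_block,
    jags_latent_block(between_corr), "
    ", rho_line, "
  }")
}

#' Fit a Bayesian multivariate meta-analysis of multiple factors
#'
#' Fits the configured model variant to a sparse effect table by MCMC
#' (JAGS). Missingness is handled through the observed-subvector marginal
#' likelihood: each study contributes a (multivariate) normal likelihood for
#' exactly the factors it reports, and unreported factors are never imputed.
#' Posterior summaries are medians with central 95% credible intervals on
#' the log-OR scale.
#'
#' Convergence is gated on the split-chain Rhat and effective sample size of
#' every monitored scalar (thresholds in the config); a failing fit is
#' returned with `converged = FALSE` and a warning, never silently.
#'
#' @param table an `effect_table`. Factors reported by fewer than two
#'   studies trigger a warning (apply [filter_min_studies()] first); the
#'   model still runs, with the prior dominating those factors.
#' @param config an [mvma_config()].
#' @return An object of class `mvma_fit` with components `summary` (data
#'   frame: `factor_id`, `n_studies`, `median`, `ci_lo`, `ci_hi`,
#'   `tau_median`), `correlation` (posterior-mean between-study correlation
#'   matrix, H/M0 only), `diagnostics` (per-parameter Rhat/ESS),
#'   `converged`, `draws` (a [coda::mcmc.list] of the scalar monitors),
#'   `mcse_median` (Monte Carlo standard error of each posterior median),
#'   and the call metadata (`variant`, `config`, `runtime_s`, `engine`).
#' @export
#' @examples
#' \donttest{
#' tab <- glottic_table1()
#' fit <- fit_mvma(tab, mvma_profile("test", variant = "U", seed = 1))
#' fit$summary
#' }
fit_mvma <- function(table, config = mvma_config()) {
  stopifnot(inherits(table, "effect_table"), inherits(config, "mvma_config"))
  validate_effect_table(table)
  t0 <- proc.time()[["elapsed"]]
  long <- as.data.frame(table)
  if (nrow(long) == 0) stop("empty effect table")
  fids <- table$factors$factor_id
  sids <- table$studies$study_id
  J <- length(fids); I <- length(sids)
  counts <- reporting_counts(table)
  if (any(counts < 2))
    warning("factor(s) reported by < 2 studies: ",
            paste(names(counts)[counts < 2], collapse = ", "),
            "; their posteriors are prior-dominated")
  variant <- config$variant
  if (J == 1 && variant != "U") {
    # with a single factor there are no correlations to model; all variants
    # coincide with univariate pooling
    variant_run <- "U"
  } else variant_run <- variant

  si <- match(long$study, sids)
  fi <- match(long$factor, fids)
  monitors <- c("mu", "tau")
  data <- list(J = J, pmu = 1 / config$prior_mu_sd^2,
               tau_upper = config$prior_tau_upper)

  if (variant_run == "U") {
    model_str <- jags_model_u()
    data <- c(data, list(y = long$log_or, v = long$se^2,
                         fi = fi, N = nrow(long)))
    inits_extra <- function() list(mu = rep(0, J), tau = rep(config$prior_tau_upper / 10, J))
  } else {
    data <- c(data, list(I = I, zero = rep(0, J), I0 = diag(J)))
    if (config$between_corr == "wishart") data$wdf <- J + 1
    if (variant_run == "M0") {
      model_str <- jags_model_m0(config$between_corr)
      data <- c(data, list(y = long$log_or, py = 1 / long$se^2,
                           si = si, fi = fi, N = nrow(long)))
    } else { # H
      nper <- tabulate(si, I)
      mvs <- which(nper >= 2)
      singles <- which(nper == 1)
      if (length(mvs) == 0) {
        # no study reports two factors jointly: rho_w is unidentified and the
        # likelihood factorises; fall back to the M0 structure
        model_str <- jags_model_m0(config$between_corr)
        data <- c(data, list(y = long$log_or, py = 1 / long$se^2,
                             si = si, fi = fi, N = nrow(long)))
        variant_run <- "M0"
      } else {
        mx <- max(nper)
        ym <- sem <- matrix(NA_real_, length(mvs), mx)
        fidx <- matrix(1L, length(mvs), mx) # padding index 1, never referenced
        for (q in seq_along(mvs)) {
          rows <- which(si == mvs[q])
          ym[q, seq_along(rows)] <- long$log_or[rows]
          sem[q, seq_along(rows)] <- long$se[rows]
          fidx[q, seq_along(rows)] <- fi[rows]
        }
        rlo <- -1 / (mx - 1) + 0.01
        data <- c(data, list(y = ym, se = sem, fidx = fidx,
                             nobs = nper[mvs], mvs = mvs,
                             Imv = length(mvs)))
        if (is.null(config$rho_w_fixed)) {
          data$rlo <- rlo; data$rhi <- 0.99
        } else {
          if (config$rho_w_fixed <= rlo - 0.01)
            stop("rho_w_fixed below the positive-definite bound ", signif(rlo, 3))
          data$rw_fixed <- config$rho_w_fixed
        }
        if (length(singles) > 0) {
          rows <- which(si %in% singles)
          data <- c(data, list(ys = long$log_or[rows], pys = 1 / long$se[rows]^2,
                               ss = si[rows], fs = fi[rows],
                               Ns = length(rows)))
        }
        model_str <- jags_model_h(config$between_corr, length(singles),
                                  config$rho_w_fixed)
        if (is.null(config$rho_w_fixed)) monitors <- c(monitors, "rhow")
      }
    }
    if (variant_run != "U") {
      if (config$between_corr == "wishart" && config$monitor_correlation)
        monitors <- c(monitors, "R")
      inits_extra <- function() {
        ini <- list(mu = rep(0, J), xi = rep(config$prior_tau_upper / 10, J))
        if (config$between_corr == "wishart") ini$OmegaU <- diag(J)
        if (variant_run == "H" && is.null(config$rho_w_fixed)) ini$rhow <- 0
        ini
      }
    }
  }

  inits <- lapply(seq_len(config$chains), function(ch) {
    c(inits_extra(),
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = (abs(config$seed) * 1009 + ch * 7919) %% 2147483647L))
  })
  jm <- rjags::jags.model(textConnection(model_str), data = data,
                          inits = inits, n.chains = config$chains,
                          n.adapt = config$adapt, quiet = TRUE)
  stats::update(jm, config$burn_in, progress.bar = "none")
  sm <- rjags::coda.samples(jm, monitors, n.iter = config$draws,
                            thin = config$thin, progress.bar = "none")

  pooled <- as.matrix(sm)
  vn <- colnames(pooled)
  mu_cols <- if (J == 1) intersect(c("mu", "mu[1]"), vn) else paste0("mu[", seq_len(J), "]")
  tau_cols <- if (J == 1) intersect(c("tau", "tau[1]"), vn) else paste0("tau[", seq_len(J), "]")

  qs <- t(apply(pooled[, mu_cols, drop = FALSE], 2, stats::quantile,
                probs = c(0.5, 0.025, 0.975), names = FALSE))
  summary <- data.frame(factor_id = fids,
                        n_studies = as.integer(counts[fids]),
                        median = qs[, 1], ci_lo = qs[, 2], ci_hi = qs[, 3],
                        tau_median = apply(pooled[, tau_cols, drop = FALSE], 2,
                                           stats::median),
                        row.names = NULL, stringsAsFactors = FALSE)

  scalar_cols <- setdiff(vn, grep("^R\\[", vn, value = TRUE))
  diag_df <- mcmc_diagnostics(sm, scalar_cols)
  converged <- all(diag_df$rhat < config$rhat_threshold, na.rm = TRUE) &&
    all(diag_df$ess > config$ess_threshold, na.rm = TRUE)
  if (!converged)
    warning("MCMC convergence gate failed (see convergence_report); ",
            "results flagged, interpret with care")

  correlation <- NULL
  if (variant_run %in% c("H", "M0")) {
    if (config$between_corr == "identity") {
      correlation <- diag(J); dimnames(correlation) <- list(fids, fids)
    } else if (config$monitor_correlation) {
      correlation <- matrix(colMeans(pooled[, grep("^R\\[", vn, value = TRUE),
                                            drop = FALSE]), J, J)
      correlation <- (correlation + t(correlation)) / 2
      diag(correlation) <- 1
      dimnames(correlation) <- list(fids, fids)
    }
  }

  mu_med <- summary$median
  names(mu_med) <- fids
  mcse <- 1.2533 * apply(pooled[, mu_cols, drop = FALSE], 2, stats::sd) /
    sqrt(pmax(diag_df$ess[match(mu_cols, diag_df$parameter)], 1))
  names(mcse) <- fids

  draws_keep <- sm[, scalar_cols, drop = FALSE]
  rhow_med <- if ("rhow" %in% vn) stats::median(pooled[, "rhow"]) else
    if (variant_run == "H") config$rho_w_fixed else NULL

  structure(list(variant = variant, variant_run = variant_run,
                 config = config, factor_ids = fids,
                 summary = summary, correlation = correlation,
                 rho_w_median = rhow_med,
                 diagnostics = diag_df, converged = converged,
                 draws = draws_keep, mcse_median = mcse,
                 runtime_s = proc.time()[["elapsed"]] - t0,
                 engine = paste("JAGS", rjags::jags.version())),
            class = "mvma_fit")
}

#' @export
print.mvma_fit <- function(x, ...) {
  cat(sprintf("mvma_fit: Model %s (%s), %d chains x %d kept draws, %s\n",
              x$variant, x$engine, x$config$chains, x$config$draws,
              if (x$converged) "converged" else "NOT CONVERGED"))
  s <- x$summary
  s$median <- round(s$median, 2); s$ci_lo <- round(s$ci_lo, 2)
  s$ci_hi <- round(s$ci_hi, 2); s$tau_median <- round(s$tau_median, 2)
  print(s, row.names = FALSE)
  if (!is.null(x$rho_w_median))
    cat(sprintf("within-study correlation (posterior median): %.2f\n",
                x$rho_w_median))
  invisible(x)
}

#' Fit Model U factor-by-factor
#'
#' Structural definition of Model U: each factor is pooled by an independent
#' univariate Bayesian random-effects model. Agrees with
#' `fit_mvma(variant = "U")` within Monte Carlo error; the joint fit is just
#' the concatenation of these independent models.
#'
#' @param table an `effect_table`.
#' @param config an [mvma_config()]; its variant field is ignored.
#' @return An `mvma_fit`-like object whose summary stacks the per-factor
#'   posteriors.
#' @export
model_u_as_univariate <- function(table, config = mvma_config()) {
  stopifnot(inherits(table, "effect_table"))
  fits <- lapply(table$factors$factor_id, function(f) {
    sub <- suppressWarnings(select_factors(table, f))
    cfg <- config; cfg$variant <- "U"
    suppressWarnings(fit_mvma(sub, cfg))
  })
  summary <- do.call(rbind, lapply(fits, `[[`, "summary"))
  rownames(summary) <- NULL
  diag_df <- do.call(rbind, Map(function(f, fit) {
    d <- fit$diagnostics; d$parameter <- paste0(f, ":", d$parameter); d
  }, table$factors$factor_id, fits))
  rownames(diag_df) <- NULL
  structure(list(variant = "U", variant_run = "U-perfactor", config = config,
                 factor_ids = table$factors$factor_id,
                 summary = summary, correlation = NULL,
                 diagnostics = diag_df,
                 converged = all(vapply(fits, `[[`, TRUE, "converged")),
                 draws = NULL,
                 mcse_median = do.call(c, lapply(fits, `[[`, "mcse_median")),
                 runtime_s = sum(vapply(fits, `[[`, 0, "runtime_s")),
                 engine = fits[[1]]$engine),
            class = "mvma_fit")
}

#' Posterior-mean between-study correlation matrix
#'
#' @param fit an `mvma_fit` from Model H or M0.
#' @return Symmetric unit-diagonal matrix of posterior-mean between-study
#'   correlations, factor ids as dimnames.
#' @export
posterior_correlation <- function(fit) {
  stopifnot(inherits(fit, "mvma_fit"))
  if (fit$variant == "U")
    stop("Model U fixes all between-study correlations to the identity; no estimated matrix to return")
  if (is.null(fit$correlation))
    stop("correlation matrix was not monitored in this fit")
  fit$correlation
}

#' Exponentiate a factor's posterior summary to the odds-ratio scale
#'
#' The exponential is monotone, so posterior quantiles map directly:
#' the median adjusted OR is `exp` of the median log OR and the credible
#' bounds are exponentiated bound-for-bound, preserving their order.
#'
#' @param fit an `mvma_fit`.
#' @param factor_id the factor to exponentiate.
#' @return List with `factor_id`, `model`, `or` and `ci` (length-2, 95%
#'   credible bounds on the OR scale).
#' @export
#' @examples
#' \donttest{
#' fit <- fit_mvma(glottic_table1(), mvma_profile("test", variant = "U", seed = 1))
#' exponentiate_summary(fit, "aci")
#' }
exponentiate_summary <- function(fit, factor_id) {
  stopifnot(inherits(fit, "mvma_fit"))
  row <- fit$summary[fit$summary$factor_id == factor_id, ]
  if (nrow(row) != 1) stop("unknown factor: ", factor_id)
  list(factor_id = factor_id, model = fit$variant,
       or = exp(row$median),
       ci = c(lo = exp(row$ci_lo), hi = exp(row$ci_hi)))
}
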