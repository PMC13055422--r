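#' Classify a posterior summary as significant or not
#'
#' A factor is called significant when its 95% credible interval excludes
#' zero on the log-OR scale. An interval touching zero exactly is classified
#' not significant (conservative closed-interval convention).
#'
#' @param ci_lo,ci_hi credible-interval bounds on the log-OR scale. A
#'   single-row data frame with columns `ci_lo`/`ci_hi` (as in
#'   `mvma_fit$summary`) may be passed as the first argument instead.
#' @return `TRUE` (significant) or `FALSE`.
#' @export
#' @examples
#' significance_classification(0.18, 1.62)  # TRUE
#' significance_classification(-1.81, 1.32) # FALSE
#' significance_classification(0, 1)        # FALSE: boundary convention
significance_classification <- function(ci_lo, ci_hi = NULL) {
  if (is.data.frame(ci_lo)) {
    stopifnot(nrow(ci_lo) == 1, all(c("ci_lo", "ci_hi") %in% names(ci_lo)))
    ci_hi <- ci_lo$ci_hi; ci_lo <- ci_lo$ci_lo
  }
  stopifnot(is.numeric(ci_lo), is.numeric(ci_hi), ci_lo <= ci_hi)
  ci_lo > 0 || ci_hi < 0
}

#' Factors significant under every fitted model
#'
#' @param fits named list of `mvma_fit` objects.
#' @return Character vector of factor ids whose 95% CrI excludes zero in all
#'   fits.
#' @export
consistently_significant <- function(fits) {
  stopifnot(length(fits) >= 1)
  sig_sets <- lapply(fits, function(f) {
    s <- f$summary
    s$factor_id[s$ci_lo > 0 | s$ci_hi < 0]
  })
  Reduce(intersect, sig_sets)
}

#' Univariate vs multivariate adjusted odds ratios for one factor
#'
#' Aligns the frequentist DerSimonian-Laird pooled OR of a factor with the
#' exponentiated posterior medians from each fitted model variant, and
#' reports the attenuation ratio (adjusted over unadjusted log OR).
#'
#' @param table an `effect_table`.
#' @param fits named list of `mvma_fit` objects (names `"H"`, `"M0"`, `"U"`;
#'   missing variants are reported as skipped).
#' @param factor_id the factor to compare (default the primary endpoint of
#'   the packaged analysis).
#' @return A list of class `adjusted_or_report`.
#' @export
adjusted_or_report <- function(table, fits, factor_id = "aci") {
  uni <- pool_factor(table, factor_id, method = "DL")
  per_model <- lapply(c(H = "H", M0 = "M0", U = "U"), function(v) {
    if (!v %in% names(fits)) return(list(skipped = TRUE))
    ex <- exponentiate_summary(fits[[v]], factor_id)
    row <- fits[[v]]$summary[fits[[v]]$summary$factor_id == factor_id, ]
    list(skipped = FALSE, or = ex$or, ci = ex$ci,
         log_or = row$median,
         attenuation = if (uni$mu_hat != 0) row$median / uni$mu_hat else NA_real_)
  })
  structure(list(factor_id = factor_id,
                 univariate = list(or = exp(uni$mu_hat),
                                   ci = exp(uni$ci95),
                                   log_or = uni$mu_hat, I2 = uni$I2,
                                   z = uni$z, p = uni$p),
                 adjusted = per_model),
            class = "adjusted_or_report")
}

#' @export
print.adjusted_or_report <- function(x, ...) {
  cat(sprintf("adjusted OR report for '%s'\n", x$factor_id))
  cat(sprintf("  univariate DL: OR %.2f (95%% CI %.2f-%.2f)\n",
              x$univariate$or, x$univariate$ci[1], x$univariate$ci[2]))
  for (v in names(x$adjusted)) {
    a <- x$adjusted[[v]]
    if (isTRUE(a$skipped)) cat(sprintf("  Model %-2s: skipped\n", v))
    else cat(sprintf("  Model %-2s: OR %.2f (95%% CrI %.2f-%.2f), attenuation %.2f\n",
                     v, a$or, a$ci[1], a$ci[2], a$attenuation))
  }
  invisible(x)
}

#' Run the full multi-factor meta-analysis pipeline
#'
#' Orchestrates load -> inclusion filter -> per-factor frequentist pooling ->
#' Bayesian fits of the requested model variants -> exponentiated comparison
#' for the primary factor, and writes machine-readable outputs: a JSON
#' report with full-precision numbers, a posterior-summary CSV (factor x
#' model medians and credible intervals), the Model H between-study
#' correlation matrix as CSV, and forest-plot data for the primary factor.
#' Seeds, engine version, convergence flags and runtimes are logged in the
#' report. Two runs with the same table, profile and seed produce identical
#' numeric payloads.
#'
#' @param table an `effect_table`, or a path to a long-layout CSV; `NULL`
#'   uses the packaged glottic carcinoma table.
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param models character subset of `c("H", "M0", "U")` to fit.
#' @param profile MCMC protocol preset name (see [mvma_profile()]).
#' @param min_studies inclusion rule: keep factors reported by at least this
#'   many studies.
#' @param primary_factor factor for the adjusted-OR comparison.
#' @param seed integer seed for all chains.
#' @return The report as a list (class `mfmeta_report`), invisibly when
#'   `out_dir` is given.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(models = "U", profile = "test", seed = 1)
#' rep$posterior$U
#' }
run_pipeline <- function(table = NULL, out_dir = NULL,
                         models = c("H", "M0", "U"),
                         profile = "reduced", min_studies = 2,
                         primary_factor = "aci", seed = 1) {
  models <- match.arg(models, c("H", "M0", "U"), several.ok = TRUE)
  if (is.null(table)) table <- glottic_table1()
  else if (is.character(table)) table <- read_effect_table(table, "long")
  stopifnot(inherits(table, "effect_table"))
  t0 <- proc.time()[["elapsed"]]

  table <- filter_min_studies(table, min_studies)
  if (!primary_factor %in% table$factors$factor_id)
    stop("pipeline stage 'filter': primary factor '", primary_factor,
         "' not retained")

  univariate <- lapply(table$factors$factor_id, function(f) {
    p <- pool_factor(table, f, "DL")
    data.frame(factor_id = f, n_studies = p$n_studies, log_or = p$mu_hat,
               ci_lo = p$ci95[["lo"]], ci_hi = p$ci95[["hi"]],
               tau2 = p$tau2, Q = p$Q, I2 = p$I2, z = p$z, p = p$p,
               stringsAsFactors = FALSE)
  })
  univariate <- do.call(rbind, univariate)

  fits <- list()
  for (v in models) {
    cfg <- mvma_profile(profile, variant = v, seed = seed)
    fits[[v]] <- tryCatch(suppressWarnings(fit_mvma(table, cfg)),
                          error = function(e)
                            stop("pipeline stage 'mvma-", v, "': ",
                                 conditionMessage(e)))
  }

  posterior <- lapply(fits, `[[`, "summary")
  sig <- lapply(fits, function(f)
    f$summary$factor_id[f$summary$ci_lo > 0 | f$summary$ci_hi < 0])
  report <- list(
    schema = "mfmeta-report/1",
    generated = list(seed = seed, profile = profile, models = models,
                     engine = fits[[1]]$engine,
                     package_version = as.character(utils::packageVersion("mfmeta")),
                     runtime_s = NA_real_),
    table = list(n_studies = nrow(table$log_or),
                 n_factors = ncol(table$log_or),
                 min_studies = min_studies),
    univariate = univariate,
    posterior = posterior,
    convergence = lapply(fits, function(f)
      list(converged = f$converged,
           worst_rhat = max(f$diagnostics$rhat, na.rm = TRUE),
           min_ess = min(f$diagnostics$ess, na.rm = TRUE))),
    significant = sig,
    consistently_significant = consistently_significant(fits),
    adjusted_or = unclass(adjusted_or_report(table, fits, primary_factor)))
  report$generated$runtime_s <- proc.time()[["elapsed"]] - t0
  class(report) <- "mfmeta_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    wide <- data.frame(factor_id = table$factors$factor_id,
                       n_studies = as.integer(reporting_counts(table)),
                       stringsAsFactors = FALSE)
    for (v in models) {
      s <- posterior[[v]]
      wide[[paste0(v, "_median")]] <- round(s$median, 2)
      wide[[paste0(v, "_ci_lo")]] <- round(s$ci_lo, 2)
      wide[[paste0(v, "_ci_hi")]] <- round(s$ci_hi, 2)
    }
    utils::write.csv(wide, file.path(out_dir, "posterior_summary.csv"),
                     row.names = FALSE)
    if ("H" %in% models && !is.null(fits$H$correlation))
      utils::write.csv(round(fits$H$correlation, 4),
                       file.path(out_dir, "correlations_H.csv"))
    utils::write.csv(forest_data(table, primary_factor),
                     file.path(out_dir, paste0("forest_", primary_factor, ".csv")),
                     row.names = FALSE)
    return(invisible(report))
  }
  report
}

#' Read back a pipeline report
#'
#' @param path path to a `report.json` written by [run_pipeline()].
#' @return The report list (class `mfmeta_report`).
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(rep$schema, "mfmeta-report/1"))
    stop("unrecognised report schema: ", rep$schema)
  class(rep) <- "mfmeta_report"
  rep
}
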