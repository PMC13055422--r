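# Short MCMC profiles are used throughout: their Monte Carlo error is far
# smaller than the tolerances asserted, and the convergence-gate warnings the
# short chains may emit are suppressed deliberately.
fit_q <- function(tab, ...) suppressWarnings(fit_mvma(tab, mvma_config(...)))

test_that("within-study covariance construction", {
  expect_equal(build_within_covariance(c(0.2, 0.3), "M0"),
               diag(c(0.04, 0.09)))
  expect_equal(build_within_covariance(c(0.2, 0.3), "U"),
               diag(c(0.04, 0.09)))
  expect_equal(build_within_covariance(c(0.2, 0.3), "H", 0),
               diag(c(0.04, 0.09)))
  S <- build_within_covariance(c(0.2, 0.3), "H", 0.5)
  expect_equal(S[1, 2], 0.03)
  expect_equal(diag(S), c(0.04, 0.09))
  expect_true(all(eigen(S, only.values = TRUE)$values > 0))
  expect_error(build_within_covariance(c(0.2, 0.3), "H", 1), "< 1")
  expect_error(build_within_covariance(c(0.2, 0.3, 0.4), "H", -0.6),
               "non-positive-definite")
})

test_that("single-factor posterior matches the conjugate closed form", {
  # one study, y = 0.5, s = 0.2, tau pinned at ~0, mu ~ N(0, 1): the
  # posterior is the precision-weighted normal-normal closed form
  y <- matrix(0.5, 1, 1, dimnames = list("s1", "f1"))
  s <- matrix(0.2, 1, 1, dimnames = dimnames(y))
  tab <- suppressWarnings(effect_table(y, s))
  fit <- fit_q(tab, variant = "U", burn_in = 4000, draws = 30000, seed = 11,
               prior_mu_sd = 1, prior_tau_upper = 1e-6)
  ref <- conjugate_posterior(0.5, 0.2, 1)
  draws <- as.matrix(fit$draws)[, "mu"]
  expect_equal(mean(draws), ref$mean, tolerance = 5e-4)
  expect_equal(sd(draws), ref$sd, tolerance = 5e-3)
  expect_equal(fit$summary$median, ref$mean, tolerance = 1e-3)
  # tail quantiles carry more Monte Carlo error than the mean
  expect_equal(fit$summary$ci_lo, ref$mean - 1.96 * ref$sd, tolerance = 0.03)
})

test_that("joint Model U agrees with factor-by-factor univariate fits", {
  tab <- glottic_table1()
  joint <- fit_q(tab, variant = "U", burn_in = 20000, draws = 60000, seed = 21)
  perfac <- suppressWarnings(model_u_as_univariate(
    tab, mvma_config(burn_in = 20000, draws = 60000, seed = 22)))
  diff <- abs(joint$summary$median - perfac$summary$median)
  tol <- pmax(0.02, 5 * sqrt(joint$mcse_median^2 + perfac$mcse_median^2))
  expect_true(all(diff < tol),
              info = paste(tab$factors$factor_id[diff >= tol], collapse = ","))
  # densely reported factors must agree tightly
  dense <- joint$summary$n_studies >= 6
  expect_true(all(diff[dense] < 0.03))
})

test_that("posterior correlation matrix is well-formed and U refuses", {
  tab <- select_factors(glottic_table1(),
                        c("aci", "t_substage", "gender", "age"))
  fit <- fit_q(tab, variant = "M0", burn_in = 2000, draws = 4000, seed = 31)
  R <- posterior_correlation(fit)
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 4))
  expect_true(all(R >= -1 & R <= 1))

  fitU <- fit_q(tab, variant = "U", burn_in = 1000, draws = 2000, seed = 32)
  expect_error(posterior_correlation(fitU), "identity")
})

test_that("credible intervals bracket the median and exponentiation is monotone", {
  tab <- glottic_table1()
  fit <- fit_q(tab, variant = "U", burn_in = 2000, draws = 4000, seed = 41)
  s <- fit$summary
  expect_true(all(s$ci_lo <= s$median & s$median <= s$ci_hi))
  expect_true(all(s$tau_median >= 0))

  ex <- exponentiate_summary(fit, "aci")
  row <- s[s$factor_id == "aci", ]
  expect_equal(ex$or, exp(row$median))
  expect_equal(unname(ex$ci), unname(exp(c(row$ci_lo, row$ci_hi))))
  expect_true(ex$ci[["lo"]] < ex$or && ex$or < ex$ci[["hi"]])
  expect_error(exponentiate_summary(fit, "nope"), "unknown factor")

  # pure arithmetic of the transform
  expect_equal(round(exp(0.36), 2), 1.43)
  expect_equal(round(exp(0.05), 2), 1.05)
  expect_equal(exp(0), 1)
})

test_that("seed determinism: identical config gives identical summaries", {
  tab <- select_factors(glottic_table1(), c("aci", "t_substage"))
  f1 <- fit_q(tab, variant = "M0", burn_in = 500, draws = 1000, seed = 99)
  f2 <- fit_q(tab, variant = "M0", burn_in = 500, draws = 1000, seed = 99)
  expect_identical(f1$summary, f2$summary)
  f3 <- fit_q(tab, variant = "M0", burn_in = 500, draws = 1000, seed = 100)
  expect_false(identical(f1$summary$median, f3$summary$median))
})

test_that("split-chain statistic separates mixed from unmixed chains", {
  set.seed(5)
  mixed <- matrix(rnorm(6000), ncol = 3)
  expect_equal(rhat_split(mixed), 1, tolerance = 0.02)

  # disjoint supports: statistic far above 1
  unmixed <- cbind(rnorm(2000, 0), rnorm(2000, 10), rnorm(2000, -10))
  expect_gt(rhat_split(unmixed), 3)

  # a single trending chain is caught by splitting
  trending <- matrix(seq(0, 5, length.out = 2000) + rnorm(2000, 0, 0.1), ncol = 1)
  expect_gt(rhat_split(trending), 1.5)
})

test_that("convergence report gates on Rhat and ESS", {
  tab <- select_factors(glottic_table1(), c("aci", "t_substage"))
  fit <- fit_q(tab, variant = "U", burn_in = 5000, draws = 20000, seed = 51)
  rep <- convergence_report(fit)
  expect_true(all(c("parameter", "rhat", "ess", "pass") %in% names(rep)))
  expect_true(all(rep$rhat < 1.01))
  expect_identical(attr(rep, "converged"), fit$converged)

  # absurdly short run must be flagged, not silently returned
  expect_warning(fit_mvma(tab, mvma_config(variant = "U", burn_in = 50,
                                           draws = 60, seed = 52)),
                 "convergence")
})

test_that("factors below the inclusion rule trigger a warning", {
  y <- matrix(c(0.5, 0.2, 0.3, NA), 2, 2,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  s <- matrix(c(0.2, 0.2, 0.2, NA), 2, 2, dimnames = dimnames(y))
  tab <- effect_table(y, s)
  expect_warning(fit_mvma(tab, mvma_config(variant = "U", burn_in = 2000,
                                           draws = 20000, seed = 1)),
                 "< 2 studies")
})
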