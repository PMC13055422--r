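test_that("fixed-effect pooling obeys its closed forms", {
  one <- pool_fixed(0.5, 0.2)
  expect_equal(one$mu_hat, 0.5)
  expect_equal(one$Q, 0)
  expect_equal(one$df, 0)

  # equal SEs: simple average
  sym <- pool_fixed(c(0.2, 0.8), c(0.3, 0.3))
  expect_equal(sym$mu_hat, 0.5)

  # ACI column of the fixture against the direct-formula oracle
  tab <- glottic_table1()
  keep <- !is.na(tab$log_or[, "aci"])
  y <- tab$log_or[keep, "aci"]; s <- tab$se[keep, "aci"]
  o <- oracle_pool(y, s, random = FALSE)
  fe <- pool_fixed(y, s)
  expect_equal(fe$mu_hat, o$mu, tolerance = 1e-12)
  expect_equal(fe$se_mu, o$se_mu, tolerance = 1e-12)
  expect_equal(fe$Q, o$Q, tolerance = 1e-12)

  expect_error(pool_fixed(numeric(0), numeric(0)), "at least one")
})

test_that("DerSimonian-Laird pooling matches the oracle and truncates at zero", {
  tab <- glottic_table1()
  keep <- !is.na(tab$log_or[, "aci"])
  y <- tab$log_or[keep, "aci"]; s <- tab$se[keep, "aci"]
  o <- oracle_pool(y, s)
  dl <- pool_dl(y, s)
  expect_equal(dl$mu_hat, o$mu, tolerance = 1e-12)
  expect_equal(dl$tau2, o$tau2, tolerance = 1e-12)
  expect_equal(dl$I2, o$I2, tolerance = 1e-12)
  expect_equal(unname(dl$weights), unname(o$weights), tolerance = 1e-12)

  # homogeneous input: Q <= df, so tau2 = 0 and DL equals fixed effect
  yh <- c(0.3, 0.31, 0.29); sh <- c(0.5, 0.5, 0.5)
  dlh <- pool_dl(yh, sh); feh <- pool_fixed(yh, sh)
  expect_equal(dlh$tau2, 0)
  expect_equal(dlh$mu_hat, feh$mu_hat)
  expect_equal(dlh$se_mu, feh$se_mu)

  single <- pool_dl(0.7, 0.3)
  expect_equal(single$mu_hat, 0.7)
  expect_equal(single$tau2, 0)
})

test_that("DL and FE agree with the oracle on random small tables", {
  set.seed(42)
  for (rep in 1:200) {
    est <- random_estimates(sample(2:10, 1))
    o <- oracle_pool(est$y, est$s)
    dl <- pool_dl(est$y, est$s)
    expect_equal(dl$mu_hat, o$mu, tolerance = 1e-10)
    expect_equal(dl$tau2, o$tau2, tolerance = 1e-10)
    expect_equal(dl$se_mu, o$se_mu, tolerance = 1e-10)
    # random-effects interval is never narrower than fixed-effect
    expect_gte(dl$se_mu, pool_fixed(est$y, est$s)$se_mu - 1e-12)
    # permutation invariance
    perm <- sample(length(est$y))
    dlp <- pool_dl(est$y[perm], est$s[perm])
    expect_equal(dlp$mu_hat, dl$mu_hat, tolerance = 1e-12)
    expect_equal(dlp$Q, dl$Q, tolerance = 1e-12)
  }
})

test_that("DL pooling agrees with metafor's implementation", {
  skip_if_not_installed("metafor")
  set.seed(7)
  for (rep in 1:25) {
    est <- random_estimates(sample(3:9, 1))
    dl <- pool_dl(est$y, est$s)
    rma <- metafor::rma(yi = est$y, sei = est$s, method = "DL", test = "z")
    expect_equal(dl$mu_hat, as.numeric(rma$b), tolerance = 1e-8)
    expect_equal(dl$se_mu, rma$se, tolerance = 1e-8)
    expect_equal(dl$tau2, rma$tau2, tolerance = 1e-8)
    expect_equal(dl$Q, rma$QE, tolerance = 1e-8)
    expect_equal(dl$I2, rma$I2, tolerance = 1e-6)
    expect_equal(dl$p, rma$pval, tolerance = 1e-8)
  }
})

test_that("I-squared arithmetic and truncation", {
  expect_equal(i_squared(16, 8), 50)
  expect_equal(i_squared(5, 8), 0)
  expect_equal(i_squared(30, 10), 200 / 3)
  expect_equal(i_squared(0, 0), 0)
  expect_error(i_squared(-1, 3), "non-negative")
})

test_that("z reconstruction from a published OR and CI", {
  # published univariate ACI summary: OR 1.61 (1.15-2.26), printed Z = 2.78;
  # reconstruction agrees up to the rounding of the printed interval
  z <- z_from_or_ci(1.61, c(1.15, 2.26))
  expect_gt(z, 2.70)
  expect_lt(z, 2.85)

  # symmetric CI around 1 gives z = 0
  expect_equal(z_from_or_ci(1, c(1 / 1.5, 1.5)), 0)

  # z is linear in the log point estimate at fixed interval width
  z1 <- z_from_or_ci(exp(0.2), exp(c(-0.5, 0.5)))
  z2 <- z_from_or_ci(exp(0.4), exp(c(-0.5, 0.5)))
  expect_equal(z2, 2 * z1)

  expect_error(z_from_or_ci(1.2, c(-0.5, 2)), "> 0")
  expect_error(z_from_or_ci(0.9, c(1.1, 2)), "lo < or_point")
})

test_that("forest data exports per-study rows plus a pooled row", {
  tab <- glottic_table1()
  fd <- forest_data(tab, "aci")
  expect_equal(nrow(fd), 10) # 9 studies + pooled
  expect_equal(fd$study[10], "pooled (DL)")
  expect_equal(sum(fd$weight_pct[1:9]), 100, tolerance = 0.01)
  dl <- pool_factor(tab, "aci")
  expect_equal(fd$log_or[10], dl$mu_hat)

  # single-study factor: full weight on the one study
  y <- matrix(c(0.5, 0.3, 0.2, NA), 2, 2,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  s <- matrix(c(0.2, 0.2, 0.1, NA), 2, 2, dimnames = dimnames(y))
  fd1 <- forest_data(effect_table(y, s), "b")
  expect_equal(fd1$weight_pct, c(100, 100))
  expect_error(forest_data(tab, "nope"), "unknown factor")
})
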