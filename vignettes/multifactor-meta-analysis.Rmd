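---
title: "Multivariate meta-analysis of multiple prognostic factors with mfmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate meta-analysis of multiple prognostic factors with mfmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Prognostic-factor evidence in small clinical literatures is typically
scattered: each published cohort reports univariate odds ratios for its own
subset of candidate factors, factors are mutually correlated (a tumour that
involves the anterior commissure also tends to be of higher T substage), and
no single study reports everything. Pooling each factor separately with a
conventional random-effects meta-analysis ignores both the correlation
between factors and the selective reporting, and can overstate the
importance of a factor that is merely a proxy for another.

`mfmeta` implements both stages of the standard answer to this situation:

1. **Univariate pooling** per factor - inverse-variance fixed effect,
   DerSimonian-Laird (DL) random effects, Cochran's Q, and I².
2. **Bayesian multivariate meta-analysis of multiple factors (MVMA-MF)** - a
   joint hierarchical model for all factors at once, fitted by MCMC, under
   three correlation assumptions (Models H, M0 and U below).

The package ships the early-stage glottic carcinoma dataset (nine cohorts
treated with definitive radiotherapy, fourteen risk-factor contrasts for
local recurrence, 56 of 126 cells observed) as `glottic_table1()`, and a
synthetic-table generator with known truth so every estimator can be checked
by parameter recovery.

## Data model

The currency of the package is the `effect_table`: a studies-by-factors
matrix of log odds ratios $y_{ij}$ with within-study standard errors
$s_{ij}$ and an implied missingness mask. Three conventions matter:

* a blank cell means *unreported*, and is treated as missing completely at
  random; a stored `0.00` is an observed estimate;
* every stored SE must be strictly positive;
* only univariate (unadjusted) contrasts belong in the table - estimates
  from multivariable regressions are a different estimand and are excluded
  from the packaged dataset.

The packaged table is curated in long form (one record per study-factor
pair) because the printed wide table is ragged; each value is explicitly
bound to its factor. One printed cell is ambiguous under a purely positional
reading: the Bignardi `0.00 (0.02)` entry. We assign it to tumour grading
rather than age, the assignment under which the per-factor reporting counts
are internally consistent with the source's own statement that exactly four
factors are available in at least seven of nine studies (ACI, T substage,
gender, age). The published posterior-summary table also prints slightly
smaller study counts for a few factors (8 vs 9 for ACI, 6 vs 7 for T
substage) without naming the excluded entries; the package keeps every
printed cell and provides `drop_cell()` so alternative inclusion variants
can be fitted and compared (the acceptance tests bracket the ambiguity with
leave-one-out refits).

## The three models

For study $i$ let $O_i$ be the set of factors it reports, $y_i(O_i)$ the
observed subvector, and $S_i$ its within-study covariance. The hierarchical
model is

$$y_i(O_i) \mid \theta_i \sim \mathcal{N}\!\big(\theta_i(O_i),\, S_i\big),
\qquad
\theta_i \sim \mathcal{N}\!\big(\mu,\, \Sigma_B\big),
\qquad
\Sigma_B = D\, R_B\, D,\; D = \mathrm{diag}(\tau_1,\dots,\tau_J).$$

The three variants differ only in which correlations they admit:

* **Model H**: $S_i$ has off-diagonals $\rho_W\, s_{ij} s_{ik}$ with a
  single shared within-study correlation $\rho_W$, and $R_B$ is a full
  correlation matrix. Within-study correlations are almost never published,
  which is exactly why the shared-$\rho_W$ device is used: one extra
  parameter, given a uniform prior over the range that keeps every $S_i$
  positive definite. A constant-correlation matrix of dimension $n$ is
  positive definite only for $\rho_W > -1/(n-1)$, so the prior support is
  $(-1/(n_{\max}-1) + 0.01,\ 0.99)$ with $n_{\max}$ the largest number of
  factors co-reported by any study.
* **Model M0**: $S_i$ diagonal (within-study errors independent), $R_B$
  full.
* **Model U**: both diagonal - equivalent to independent univariate
  Bayesian random-effects pooling per factor. `model_u_as_univariate()`
  fits the factors one at a time and is the structural definition against
  which the joint Model U fit is tested.

Missingness is handled by the **observed-subvector marginal likelihood**:
each study contributes a normal density of exactly the dimension it reports
(`U`/`M0` decompose into the observed scalar cells; `H` uses one
multivariate normal per study over its observed subvector). Nothing is
imputed; because marginals of a multivariate normal are obtained by
dropping rows and columns, this is exact for inference on $\mu$, the
$\tau_j$ and $R_B$, and it keeps the sampler state small on very sparse
tables.

## Priors and their rationale

The original analysis this package re-implements does not publish its
priors, so the defaults here are chosen to be vague by the standards of the
MVMA literature, and everything is configurable through `mvma_config()`:

* $\mu_j \sim \mathcal{N}(0, 10^2)$ - essentially flat over any plausible
  log OR.
* Model U: $\tau_j \sim U(0, 5)$; a between-study SD of 5 on the log-OR
  scale is already absurdly large, so the bound is not informative.
* Models H/M0: the between-study covariance uses a separation-style
  **scaled inverse-Wishart** construction:
  $u_i \sim \mathcal{N}(0, \Omega^{-1})$ with
  $\Omega \sim \mathrm{Wishart}(I_J,\ J+1)$,
  $\theta_i = \mu + \mathrm{diag}(\xi)\, u_i$, $\xi_j \sim U(0,5)$. The
  implied correlation matrix $R_B$ (the correlation part of $\Omega^{-1}$)
  has near-uniform marginal priors on every pairwise correlation, which is
  the weakly-informative behaviour wanted from an LKJ(1)-type prior; the
  scale expansion $\xi_j$ makes the implied prior on
  $\tau_j = \xi_j\,\mathrm{sd}(u_{\cdot j})$ weakly informative rather than
  exactly uniform. This construction was chosen because it keeps the
  latent layer conditionally conjugate, which the Gibbs engine exploits;
  a direct uniform-times-LKJ separation has no workable sampler there.
* $\rho_W \sim U$ over the positive-definite range, as above;
  `rho_w_fixed = 0` pins it (and provably reduces H to M0, a property the
  test suite checks).

Because the source's priors are unknown, results for Models H and M0 should
be read with a prior-sensitivity band in mind; Model U is the variant most
robust to prior choice, and the package's acceptance checks treat it as the
primary quantitative anchor while allowing wider bands for H and M0.

## Computation

The engine is JAGS via `rjags`, with the `glm` module loaded at package
load: its block samplers update the latent Gaussian layer jointly, which
matters on tables where a study reports a cell with a very small standard
error (the glottic table has SEs down to 0.02; with single-site updating
those cells rigidly couple the latent effect to the overall mean and the
chain crawls). Model U is fitted in the exactly marginalized form
$y_{ij} \sim \mathcal{N}(\mu_j,\, s_{ij}^2 + \tau_j^2)$ - no latent states
at all - which keeps it mobile even as $\tau_j \to 0$ and makes the
conjugate normal-normal closed form a usable oracle in the tests.

The production protocol is 3 chains, 100 000 burn-in, 100 000 kept updates
(`mvma_profile("full")`). Per-chain RNG seeds derive deterministically from
the config seed, so identical configurations reproduce identical summaries.
Convergence is gated numerically, not by eye: every monitored scalar must
have split-chain $\widehat{R} < 1.01$ and effective sample size $> 400$, or
the fit is flagged (`converged = FALSE`, with a warning) - never silently
returned. Proposals that would leave the positive-definite region are
impossible by construction (the Wishart layer) or excluded by prior support
($\rho_W$); nothing is projected or repaired.

Protocol sizes actually used by the packaged checks, chosen so that the
Monte Carlo error is far below each comparison's tolerance: Model U always
runs the full protocol (the marginalized sampler makes it cheap: roughly
half a minute for the 9x14 table). Model H runs at 3 x (10 000 + 50 000)
in the acceptance script and 3 x (4 000 + 8 000) in the test suite; M0 at
3 x (10 000 + 30 000) and below. At these sizes the posterior-median Monte
Carlo SE for every factor is a few hundredths of a log OR - an order of
magnitude below the 0.15 (Model U) and 0.35 (H/M0 prior-sensitivity)
bands used in the acceptance comparisons. The full-protocol Model H run
(about half an hour single-core) is available but not exercised routinely.

Numerical conventions: posterior summaries are medians with central 95%
credible intervals; displays round to 2 decimals but all stored numbers are
full precision; exponentiation to the OR scale maps quantiles directly
(monotone transform), so the median OR is `exp` of the median log OR. A
credible interval that touches zero exactly is classified *not significant*
(conservative closed-interval convention; the classifier is
`significance_classification()`).

## The synthetic-data generator

`simulate_table()` draws tables from exactly the generative model above:
latent effects $\theta_i$ multivariate normal around known $\mu$ with
$D R_B D$; within-study SEs log-uniform over a configurable range
(log-uniform because real SE spreads are heavy - the glottic table spans
0.02 to 1.27); observations multivariate normal with the shared $\rho_W$;
cells masked independently with per-factor reporting probabilities
(missing completely at random, matching the marginal-likelihood
assumption of the fitters). `table1_like_params()` mirrors the packaged
table's shape: nine studies, fourteen factors, reporting probabilities
equal to the observed reporting fractions, effects and between-study SDs at
the table's DL estimates, exchangeable between-study correlation 0.25 and
$\rho_W = 0.3$ as representative mid-range values.

What passing recovery tests do and do not show: the generator implements
the assumed model, so coverage near 95% demonstrates the fitter is
*internally* correct (no bugs, calibrated uncertainty under the model), not
that real reporting is missing-completely-at-random, that real within-study
correlations are shared and constant, or that real effects are normal. An
optional value-dependent masking mode is deliberately absent from the
defaults; MCAR is the assumption the inference itself makes.

Masks that would orphan a study (no estimates) or leave a factor below two
reporting studies are redrawn up to 1000 times; if the requested sparsity
makes that impossible the generator repairs the mask minimally and flags
the affected factors in the truth record instead of failing silently.

## Design choices that were genuinely open

* **DerSimonian-Laird** as the sole frequentist random-effects estimator:
  it is what the mainstream meta-analysis tooling this field uses defaults
  to, and its closed forms make independent arithmetic oracles trivial.
  REML and Hartung-Knapp are out of scope for v1.
* **Leave-one-out bracketing** rather than guessing which entries the
  source excluded when its per-factor study counts disagree with its own
  data table: the package always fits the table as printed, and the
  acceptance layer verifies the printed results are attainable within one
  cell's exclusion.
* **No CLI binary**: this is an analysis library; `run_pipeline()` plus the
  exported functions are the scripting surface, and the pipeline writes
  machine-readable JSON/CSV artifacts (posterior summary table, Model H
  correlation matrix, forest-plot data, full run metadata including seeds
  and convergence flags).
* The frequentist univariate headline of the source analysis (pooled OR
  1.61, I² 34%) was computed from per-study 2x2 event counts that were
  never published in numeric form; the package does not claim to reproduce
  those numbers from the effect table, and the test suite instead pins the
  pooling code to closed-form oracles and to an independent implementation
  (`metafor`).

## Known limitations

* Binary-outcome ORs only; no time-to-event structure, so recurrence timing
  is invisible to the model.
* A single shared $\rho_W$ is a crude stand-in for unknown within-study
  correlation structure; pairwise-specific correlations are not
  identifiable from a table this sparse.
* Factors reported by only two studies are effectively prior-dominated;
  their credible intervals are wide and prior-sensitive by construction,
  and the package warns rather than refuses.
* Posterior results for Models H and M0 depend on an unpublished original
  prior specification; agreement should be expected only within a
  sensitivity band, which is how the packaged checks are calibrated.

## Worked example

```{r example}
library(mfmeta)

tab <- filter_min_studies(glottic_table1(), 2)
pool_factor(tab, "aci")           # DL random-effects pooling of one factor

fit_u <- fit_mvma(tab, mvma_profile("full", variant = "U", seed = 1))
fit_u$summary                     # medians + 95% CrIs, log-OR scale
exponentiate_summary(fit_u, "aci")

rep <- run_pipeline(out_dir = "glottic-report", models = c("H", "M0", "U"),
                    profile = "reduced", seed = 1)
rep$consistently_significant      # factors significant under every model
```
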