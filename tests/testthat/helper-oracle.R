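# Independent arithmetic oracle for inverse-variance pooling: spreadsheet-style
# direct evaluation of the closed forms, coded separately from the package.
oracle_pool <- function(y, s, random = TRUE) {
  W <- 1 / s^2
  muF <- sum(W * y) / sum(W)
  Q <- sum(W * (y - muF)^2)
  df <- length(y) - 1
  tau2 <- 0
  if (random && df > 0) {
    denom <- sum(W) - sum(W^2) / sum(W)
    if (denom > 0) tau2 <- max(0, (Q - df) / denom)
  }
  w <- 1 / (s^2 + tau2)
  mu <- sum(w * y) / sum(w)
  se_mu <- sqrt(1 / sum(w))
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(mu = mu, se_mu = se_mu, tau2 = tau2, Q = Q, df = df, I2 = I2,
       z = mu / se_mu, weights = w / sum(w))
}

random_estimates <- function(n) {
  list(y = stats::rnorm(n, 0, 1), s = exp(stats::runif(n, log(0.05), log(1.2))))
}

tiny_table <- function() {
  y <- matrix(c(0.5, 0.2, NA,
                0.1, NA, 0.9,
                -0.3, 0.4, 0.6), 3, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("a", "b", "c")))
  s <- matrix(c(0.2, 0.3, NA,
                0.25, NA, 0.5,
                0.4, 0.3, 0.6), 3, 3, byrow = TRUE, dimnames = dimnames(y))
  effect_table(y, s)
}

# conjugate normal-normal posterior for one study, known tau = 0:
# y ~ N(mu, s^2), mu ~ N(0, sd0^2)
conjugate_posterior <- function(y, s, sd0) {
  prec <- 1 / s^2 + 1 / sd0^2
  list(mean = (y / s^2) / prec, sd = sqrt(1 / prec))
}
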