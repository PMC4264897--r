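# Independent brute-force oracles used to cross-check the fitting routines.
# These deliberately avoid lm()/cor(): straight normal equations and moment
# formulas, so agreement with the package is a genuine dual-route check.

ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- as.numeric(y - X %*% beta)
  n <- length(x)
  rss <- sum(res^2)
  list(intercept = beta[1], slope = beta[2], resid = res, rss = rss,
       slope_se = sqrt((rss / (n - 2)) / sum((x - mean(x))^2)))
}

sma_slope_oracle <- function(x, y) {
  n <- length(x)
  sx <- sqrt(sum((x - mean(x))^2) / (n - 1))
  sy <- sqrt(sum((y - mean(y))^2) / (n - 1))
  cxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sign(cxy) * sy / sx
}

pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Small random log-log dataset with controllable slope/noise.
rand_logpairs <- function(n = 20, slope = 2.5, intercept = -4.4,
                          sd_x = 0.2, noise = 0.1) {
  x <- rnorm(n, 1.2, sd_x)
  y <- intercept + slope * x + rnorm(n, 0, noise)
  list(x = x, y = y)
}

# Minimal morph_data construction from log pairs (mass/length on log scale).
morph_from_logpairs <- function(x, y, ...) {
  suppressWarnings(as_morph_data(data.frame(
    id = sprintf("r%03d", seq_along(x)),
    fresh_mass = exp(y), pronotum = exp(x), ...)))
}

quiet_pop <- function(config, seed = NULL) {
  suppressWarnings(generate_population(config, seed = seed))
}

# Two-group config on a common line, used by several null simulations.
null_two_group_config <- function(n = 50L, b = 2.5) {
  groups <- data.frame(name = c("a", "b"), n = n, alpha = -4.4,
                       mu_logL = 1.2, sigma_logL = 0.06,
                       stringsAsFactors = FALSE)
  synth_config(groups, b_true = b, sigma_cond = 0.07,
               sigma_meas_x = sqrt(0.07^2 + 0.02^2) / b, sigma_meas_y = 0.02)
}
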