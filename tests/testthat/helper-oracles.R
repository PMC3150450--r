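# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# exact logistic solution for phage-free growth
logistic_exact <- function(t, s0, mu, k) {
  k * s0 * exp(mu * t) / (k - s0 + s0 * exp(mu * t))
}

# Welch's t from first principles (closed form, no stats::t.test)
welch_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1) / length(a)
  vb <- sum((b - mean(b))^2) / (length(b) - 1) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# exact two-tailed binomial p by full enumeration with log-space pmf
# (minimum-likelihood convention)
binom_two_tailed_oracle <- function(k, n, p0) {
  logpmf <- lchoose(n, 0:n) + (0:n) * log(p0) + (n - (0:n)) * log1p(-p0)
  pmf <- exp(logpmf)
  sum(pmf[logpmf <= logpmf[k + 1] + 1e-9 * abs(logpmf[k + 1])])
}

# one-way ANOVA sums of squares by hand
anova_oracle <- function(groups) {
  all <- unlist(groups)
  grand <- mean(all)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, dfb = dfb, dfw = dfw, p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

# a small simulated coculture useful in several places
make_exponential_tc <- function(rate, times = seq(0, 3, by = 0.25),
                                scale = 1e3, entity = "infected_cells") {
  time_course(entity, times, scale * exp(rate * times))
}

# a rate_fit built from an already-log-scale response, for slope tests
fit_log_slope <- function(x, y) {
  fit <- stats::lm(y ~ x)
  rate_fit(slope = unname(stats::coef(fit)[2]),
           intercept = unname(stats::coef(fit)[1]),
           r_squared = suppressWarnings(stats::cor(x, y)^2),
           n_points = length(x), window = range(x),
           se = unname(suppressWarnings(sqrt(diag(stats::vcov(fit)))[2])))
}

ancova_interaction_p <- function(series) {
  ancova_slopes(series, contrasts = FALSE)$p_value
}

# Two-stage Monte-Carlo calibration check: the empirical rejection rate over
# n_sim null draws must sit within 2 binomial SEs of the target size; a
# single batch of an exactly calibrated test still lands outside that band
# ~5% of the time, so a failing batch is confirmed on one independent batch
# before the check is declared failed. A genuinely miscalibrated statistic
# fails both batches.
type1_within_band <- function(reject_once, center = 0.05, n_sim = 1000) {
  band <- 2 * sqrt(center * (1 - center) / n_sim)
  for (batch in 1:2) {
    rate <- mean(vapply(seq_len(n_sim), function(i) reject_once(), logical(1)))
    if (abs(rate - center) < band) return(TRUE)
  }
  FALSE
}
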