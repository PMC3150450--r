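as_group_data <- function(groups) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  groups <- lapply(groups, as.numeric)
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition via [stats::aov()]. With zero
#' within-group variance and equal group means, `F` is reported as 0 and
#' `p` as 1 (rather than `NaN`).
#'
#' @param groups list of >= 2 numeric vectors (named or not).
#' @return A list of class `anova_result`: `f_statistic`, `df_between`,
#'   `df_within`, `p_value`, `group_means`, `group_sizes`, and the
#'   underlying `aov` fit.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) coevo_stop("need >= 2 groups", "coevo_data_error")
  if (any(lengths(groups) < 1L)) coevo_stop("empty group", "coevo_data_error")
  df <- as_group_data(groups)
  if (nrow(df) <= length(groups)) {
    coevo_stop("need total N > number of groups", "coevo_data_error")
  }
  fit <- aov(value ~ group, data = df)
  tab <- suppressWarnings(anova(fit))  # degenerate zero-variance input warns
  f <- tab$`F value`[1L]
  p <- tab$`Pr(>F)`[1L]
  if (!is.finite(f)) {  # 0/0: no within-group variance, equal means
    if (tab$`Sum Sq`[1L] == 0) { f <- 0; p <- 1 }
  }
  structure(
    list(f_statistic = f, df_between = tab$Df[1L], df_within = tab$Df[2L],
         p_value = p,
         group_means = tapply(df$value, df$group, mean),
         group_sizes = as.integer(table(df$group)),
         fit = fit),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d,%d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  invisible(x)
}

#' Tukey (or Tukey-Kramer) honestly-significant-difference test
#'
#' All pairwise group comparisons after a one-way ANOVA, via
#' [stats::TukeyHSD()]. With unequal group sizes the Tukey-Kramer form is
#' used automatically (that is what `TukeyHSD` computes); the variant
#' actually applied is reported. The studentized-range statistic
#' \eqn{q = |\bar y_i - \bar y_j| / \sqrt{(MSE/2)(1/n_i + 1/n_j)}} is
#' attached per pair.
#'
#' @param groups list of >= 2 numeric vectors.
#' @param conf_level confidence level for the intervals.
#' @return A tibble of class `tukey_result` with columns `pair`,
#'   `difference`, `statistic` (q), `p_adjusted`, plus attribute `variant`
#'   (`"tukey"` or `"tukey_kramer"`).
#' @export
tukey_hsd <- function(groups, conf_level = 0.95) {
  res <- anova_oneway(groups)
  hsd <- TukeyHSD(res$fit, conf.level = conf_level)$group
  mse <- sum(res$fit$residuals^2) / res$df_within
  n <- res$group_sizes
  names(n) <- names(res$group_means)
  pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  q <- vapply(seq_along(pairs), function(i) {
    ni <- n[[pairs[[i]][1L]]]; nj <- n[[pairs[[i]][2L]]]
    se <- sqrt(mse / 2 * (1 / ni + 1 / nj))
    if (se == 0) 0 else abs(hsd[i, "diff"]) / se
  }, numeric(1L))
  out <- tibble::tibble(
    pair = rownames(hsd),
    difference = unname(hsd[, "diff"]),
    statistic = q,
    p_adjusted = unname(hsd[, "p adj"])
  )
  attr(out, "variant") <- if (length(unique(n)) == 1L) "tukey" else "tukey_kramer"
  class(out) <- c("tukey_result", class(out))
  out
}

#' Welch's unequal-variance t test
#'
#' Two-tailed, with Satterthwaite degrees of freedom, via
#' [stats::t.test()]. When both groups are degenerate (zero variance) with
#' equal means, `t = 0`, `p = 1` by convention.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return List with `t`, `df`, `p_value`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    coevo_stop("need >= 2 values per group", "coevo_data_error")
  }
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p_value = 1))
    }
    coevo_stop("both groups have zero variance with different means",
               "coevo_data_error")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Two-sample t test on fitted slopes
#'
#' Compares the slopes of two independent semi-log fits:
#' \eqn{t = (b_1 - b_2) / \sqrt{se_1^2 + se_2^2}} with
#' \eqn{df = n_1 + n_2 - 4} (two parameters estimated per fit), two-tailed.
#'
#' @param fit_a,fit_b [rate_fit()] objects carrying slope standard errors.
#' @return List with `t`, `df`, `p_value`.
#' @export
slope_t_test <- function(fit_a, fit_b) {
  if (is.na(fit_a$se) || is.na(fit_b$se)) {
    coevo_stop("both fits must carry slope standard errors (>= 3 points)",
               "coevo_data_error")
  }
  se <- sqrt(fit_a$se^2 + fit_b$se^2)
  df <- fit_a$n_points + fit_b$n_points - 4L
  if (df < 1L) coevo_stop("not enough points for a slope test", "coevo_data_error")
  t <- if (se == 0) {
    if (fit_a$slope == fit_b$slope) 0 else Inf * sign(fit_a$slope - fit_b$slope)
  } else (fit_a$slope - fit_b$slope) / se
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Analysis of covariance for semi-log slopes
#'
#' Fits the general linear model `y ~ x * group` (responses already on the
#' log scale), tests slope homogeneity with the interaction F
#' (`df = groups - 1`, `N - 2 * groups`), and compares slopes pairwise
#' using [emmeans::emtrends()] with the Tukey (studentized-range)
#' adjustment on the pooled residual variance.
#'
#' @param series named list of >= 2 groups, each a list or data frame with
#'   elements/columns `x` and `y` (>= 3 points per group); `y` on the log
#'   scale.
#' @param contrasts compute the pairwise slope contrasts (default `TRUE`;
#'   switch off when only the homogeneity test is needed).
#' @return A list of class `ancova_result`: `slopes` (per-group slope and
#'   SE), `interaction_f`, `df`, `p_value`, `contrasts` (pairwise slope
#'   differences with Tukey-adjusted p), and the `lm` fit.
#' @export
ancova_slopes <- function(series, contrasts = TRUE) {
  if (length(series) < 2L) coevo_stop("need >= 2 groups", "coevo_data_error")
  if (is.null(names(series)) || any(!nzchar(names(series)))) {
    names(series) <- paste0("g", seq_along(series))
  }
  for (nm in names(series)) {
    s <- series[[nm]]
    if (length(s$x) < 3L) {
      coevo_stop(sprintf("group '%s' has fewer than 3 points", nm),
                 "coevo_data_error")
    }
    if (sd(s$x) == 0) {
      coevo_stop(sprintf("collinear (constant) x in group '%s'", nm),
                 "coevo_fit_error")
    }
  }
  df <- do.call(rbind, lapply(names(series), function(nm) {
    data.frame(x = as.numeric(series[[nm]]$x), y = as.numeric(series[[nm]]$y),
               group = nm)
  }))
  df$group <- factor(df$group, levels = names(series))
  fit <- lm(y ~ x * group, data = df)
  tab <- suppressWarnings(anova(fit))  # noiseless inputs trip a perfect-fit warning
  f <- tab["x:group", "F value"]
  p <- tab["x:group", "Pr(>F)"]
  df_int <- tab["x:group", "Df"]
  df_res <- tab["Residuals", "Df"]
  ss_total <- sum(tab$`Sum Sq`)
  if (tab["x:group", "Sum Sq"] <= 1e-12 * max(ss_total, 1)) { f <- 0; p <- 1 }
  slopes_tbl <- contrasts_tbl <- NULL
  if (contrasts) {
    trends <- suppressWarnings(
      emmeans::emtrends(fit, pairwise ~ group, var = "x", adjust = "tukey"))
    sl <- as.data.frame(trends$emtrends)
    ct <- as.data.frame(trends$contrasts)
    slopes_tbl <- tibble::tibble(group = as.character(sl$group),
                                 slope = sl$x.trend, se = sl$SE)
    contrasts_tbl <- tibble::tibble(pair = as.character(ct$contrast),
                                    estimate = ct$estimate, se = ct$SE,
                                    t = ct$t.ratio, p_adjusted = ct$p.value)
  }
  structure(
    list(slopes = slopes_tbl, interaction_f = f, df = c(df_int, df_res),
         p_value = p, contrasts = contrasts_tbl, fit = fit),
    class = "ancova_result"
  )
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA slope homogeneity: F(%d,%d) = %.4g, p = %.4g\n",
              x$df[1L], x$df[2L], x$interaction_f, x$p_value))
  if (!is.null(x$slopes)) print(x$slopes)
  invisible(x)
}

#' Exact two-tailed binomial test (minimum-likelihood method)
#'
#' The two-tailed p-value is the total probability of all outcomes whose
#' point probability under `Binomial(n, p0)` does not exceed that of the
#' observed `k` (up to a relative tolerance of 1e-12 for ties), the common
#' convention for exact tests.
#'
#' @param k observed successes (integer, `0 <= k <= n`).
#' @param n trials.
#' @param p0 null success probability in (0, 1).
#' @return Two-tailed p-value.
#' @export
binomial_two_tailed <- function(k, n, p0) {
  k <- as.integer(round(k)); n <- as.integer(round(n))
  if (k < 0L || k > n) coevo_stop("need 0 <= k <= n", "coevo_domain_error")
  if (p0 <= 0 || p0 >= 1) coevo_stop("need p0 in (0,1)", "coevo_domain_error")
  d <- dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[k + 1L] * (1 + 1e-12)]))
}
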