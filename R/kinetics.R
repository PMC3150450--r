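#' Rate fit container
#'
#' Result of a semi-logarithmic rate fit: ordinary least squares of
#' `ln(value)` on time.
#'
#' @param slope fitted slope (per hour, or per minute for adsorption fits).
#' @param intercept fitted intercept on the `ln` scale.
#' @param r_squared squared Pearson correlation of `ln(value)` with time.
#' @param n_points number of points used.
#' @param window `(t_start, t_end)` actually used.
#' @param se standard error of the slope (`NA` with 2 points).
#' @param n_excluded number of non-positive values excluded from the log fit.
#' @param time_unit unit of the slope denominator.
#' @return An object of class `rate_fit`.
#' @export
rate_fit <- function(slope, intercept, r_squared, n_points, window, se,
                     n_excluded = 0L, time_unit = "hours") {
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         n_points = n_points, window = window, se = se,
         n_excluded = n_excluded, time_unit = time_unit),
    class = "rate_fit"
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> slope %.4g per %s (r^2 = %.3g, n = %d, window [%g, %g])\n",
              x$slope, sub("s$", "", x$time_unit), x$r_squared, x$n_points,
              x$window[1L], x$window[2L]))
  invisible(x)
}

fit_semilog <- function(times, values, window = NULL, time_unit = "hours") {
  if (!is.null(window)) {
    keep <- times >= window[1L] & times <= window[2L]
    times <- times[keep]
    values <- values[keep]
  }
  usable <- values > 0
  n_excluded <- sum(!usable)
  if (n_excluded > 0L) {
    message(sprintf("excluded %d non-positive value(s) from the log fit", n_excluded))
  }
  times <- times[usable]
  values <- values[usable]
  if (length(times) < 2L) {
    coevo_stop("fewer than 2 usable (positive) points in the fit window",
               "coevo_fit_error")
  }
  y <- log(values)
  fit <- lm(y ~ times)
  slope <- unname(coef(fit)[2L])
  r2 <- if (sd(y) == 0 || sd(times) == 0) 0 else suppressWarnings(cor(times, y)^2)
  se <- if (length(times) > 2L) {
    unname(suppressWarnings(sqrt(diag(vcov(fit)))[2L]))
  } else if (sd(y) == 0) 0 else NA_real_
  rate_fit(slope = slope, intercept = unname(coef(fit)[1L]), r_squared = r2,
           n_points = length(times), window = range(times), se = se,
           n_excluded = n_excluded, time_unit = time_unit)
}

tc_in_hours <- function(tc) {
  if (tc$time_unit == "minutes") {
    time_course(tc$entity, tc$times / 60, tc$values, time_unit = "hours")
  } else tc
}

#' Semi-logarithmic rate from a time course
#'
#' Ordinary least squares of `ln(value)` on time (hours); used for
#' infected-cell increase rates and free-phage amplification rates. Zero
#' values inside the window are excluded (with a message), never imputed.
#'
#' @param tc a [time_course()].
#' @param window optional `(t_start, t_end)` in hours; default all points.
#' @return A [rate_fit()] with the slope per hour.
#' @export
semilog_rate <- function(tc, window = NULL) {
  tc <- tc_in_hours(tc)
  fit_semilog(tc$times, tc$values, window, time_unit = "hours")
}

#' Specific growth rate from an OD or cell-density curve
#'
#' The same semi-logarithmic fit as [semilog_rate()], applied to `od600`
#' or `total_cells` series; kept as a named operation because it feeds the
#' growth-rate comparisons (ANCOVA) of uninfected hosts. When no window is
#' given, the fit uses the maximal prefix of the series with values below
#' `prefix_fraction` (default 40%) of the plateau (mean of the last three
#' points), and that window is reported in the result. Note that on a
#' logistic curve the semi-log slope underestimates the low-density growth
#' rate by roughly the average of `value/plateau` over the window; restrict
#' the window well below the plateau when an accurate rate is needed.
#'
#' @param tc a [time_course()] of entity `od600` or `total_cells`.
#' @param window optional `(t_start, t_end)` in hours.
#' @param prefix_fraction plateau fraction bounding the default window.
#' @return A [rate_fit()]; the slope is the specific growth rate per hour.
#' @export
specific_growth_rate <- function(tc, window = NULL, prefix_fraction = 0.4) {
  tc <- tc_in_hours(tc)
  if (!tc$entity %in% c("od600", "total_cells")) {
    coevo_stop("specific_growth_rate expects an od600 or total_cells series",
               "coevo_domain_error")
  }
  if (is.null(window)) {
    plateau <- mean(tail(tc$values, 3L))
    below <- tc$values < prefix_fraction * plateau
    last <- if (all(below)) length(below) else which(!below)[1L] - 1L
    if (last < 2L) last <- min(2L, length(tc$times))
    window <- c(tc$times[1L], tc$times[last])
  }
  fit_semilog(tc$times, tc$values, window, time_unit = "hours")
}

#' Time to reach stationary phase
#'
#' The plateau is the mean of the final three points; the series must end
#' within `epsilon` of its maximum. Returns the earliest time at which the
#' value reaches `(1 - epsilon) * plateau`, linearly interpolating between
#' samples.
#'
#' @param tc a [time_course()] of entity `od600` (or `total_cells`).
#' @param epsilon plateau tolerance as a fraction (default 0.05).
#' @return Time in hours.
#' @export
time_to_stationary <- function(tc, epsilon = 0.05) {
  tc <- tc_in_hours(tc)
  n <- length(tc$values)
  if (n < 3L) coevo_stop("need at least 3 points", "coevo_estimation_error")
  plateau <- mean(tail(tc$values, 3L))
  if (tc$values[n] < (1 - epsilon) * max(tc$values)) {
    coevo_stop("no plateau detected: series past a peak", "coevo_estimation_error")
  }
  # still rising at the end: compare against the value 10% of the span back
  span <- tc$times[n] - tc$times[1L]
  i_back <- which.min(abs(tc$times - (tc$times[n] - 0.1 * span)))
  if (i_back < n &&
      (tc$values[n] - tc$values[i_back]) > max(epsilon, 0.01) * plateau) {
    coevo_stop("no plateau detected: series still rising at its end",
               "coevo_estimation_error")
  }
  threshold <- (1 - epsilon) * plateau
  at_or_above <- which(tc$values >= threshold)
  if (length(at_or_above) == 0L) {
    coevo_stop("no plateau detected: threshold never reached",
               "coevo_estimation_error")
  }
  i <- at_or_above[1L]
  if (i == 1L) return(tc$times[1L])
  t0 <- tc$times[i - 1L]; t1 <- tc$times[i]
  v0 <- tc$values[i - 1L]; v1 <- tc$values[i]
  t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
}

#' Adsorption rate constant from an unadsorbed-phage decay assay
#'
#' Under mass-action adsorption to a fixed excess of cells, free phage
#' decays as \eqn{P(t) = P_0 e^{-kCt}} with `t` in minutes and `C` the cell
#' density; `k` is recovered as minus the semi-log slope divided by `C`.
#'
#' @param tc a [time_course()] of unadsorbed free phage with times in
#'   minutes (hours are converted).
#' @param cell_density cells/ml (> 0).
#' @return A [rate_fit()] whose slope is per minute, with extra elements
#'   `k_ads` (ml/cells/min) and `se_k`.
#' @export
adsorption_rate_constant <- function(tc, cell_density) {
  if (!is.finite(cell_density) || cell_density <= 0) {
    coevo_stop("cell_density must be positive", "coevo_domain_error")
  }
  times <- if (tc$time_unit == "hours") tc$times * 60 else tc$times
  fit <- fit_semilog(times, tc$values, NULL, time_unit = "minutes")
  fit$k_ads <- -fit$slope / cell_density
  fit$se_k <- if (is.na(fit$se)) NA_real_ else fit$se / cell_density
  fit
}

#' Fraction of cells infected at a time point
#'
#' Nearest-sample lookup in both series (tolerance: half the median
#' sampling interval), then infected density over total density.
#'
#' @param infected,total [time_course()] objects (PFU/ml infective centres
#'   and CFU/ml total cells).
#' @param at_time hours.
#' @return Fraction in `[0, 1]` (can exceed 1 if the assays disagree).
#' @export
infection_ratio <- function(infected, total, at_time) {
  lookup <- function(tc) {
    tc <- tc_in_hours(tc)
    i <- which.min(abs(tc$times - at_time))
    tol <- if (length(tc$times) > 1L) median(diff(tc$times)) / 2 else Inf
    if (abs(tc$times[i] - at_time) > tol) {
      coevo_stop(sprintf("no %s sample within %.3g h of t = %g",
                         tc$entity, tol, at_time),
                 "coevo_data_error")
    }
    tc$values[i]
  }
  inf <- lookup(infected)
  tot <- lookup(total)
  if (tot == 0) coevo_stop("total cell density is zero", "coevo_domain_error")
  inf / tot
}
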