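#' @title Growth-function and strength-duration fits
#'
#' @description
#' Fits to eABR amplitude growth functions: ordinary least squares for
#' monotone growth and a bounded continuous two-segment ("broken-stick")
#' model for saturating growth, plus the extra-sum-of-squares F-test that
#' replaces visual model choice. Strength-duration regressions express
#' thresholds in dB against log2 phase duration, yielding dB-per-doubling
#' slopes.
#'
#' Broken-stick parameter bounds (charge basis): slope of line 1 in
#' `[0.1, 50]` µV/nC, slope of line 2 in `[-2, 0]` µV/nC (forced to be 0
#' or negative so the knee marks saturation), y-intercept of line 1 in
#' `[-10, 2]` µV, knee in `[2, 20]` nC. Current-basis fits reuse the same
#' machinery with bounds rescaled by the condition's charge/current factor.
#'
#' @name growthfit
NULL

BROKEN_STICK_BOUNDS <- list(slope1 = c(0.1, 50), slope2 = c(-2, 0),
                            intercept1 = c(-10, 2), knee = c(2, 20))

# x-axis values and charge->x scale factor for the requested basis.
basis_x <- function(series, basis) {
  lv <- analysis_levels(series)
  if (basis == "charge") {
    list(x = lv$charge, scale = 1)
  } else {
    # nC per µA for this condition (constant across levels)
    fac <- lv$charge[1] / lv$current[1]
    list(x = lv$current, scale = fac)
  }
}

suprathreshold_levels <- function(series, criterion = 0.1) {
  thr <- detect_threshold(series, criterion)
  lv <- analysis_levels(series)
  if (!thr$defined) return(lv[0, , drop = FALSE])
  lv[lv$charge >= thr$threshold_charge, , drop = FALSE]
}

new_growth_fit <- function(model, basis, slope1, intercept1, r_squared,
                           slope2 = NA, knee = NA, n = NA, rss = NA,
                           flags = character()) {
  structure(list(model = model, unit_basis = basis, slope1 = slope1,
                 slope2 = slope2, intercept1 = intercept1, knee = knee,
                 r_squared = r_squared, n = n, rss = rss, flags = flags),
            class = "growth_fit")
}

#' Linear growth-function fit
#'
#' Ordinary least squares of amplitude against charge (or current) over
#' the suprathreshold levels.
#'
#' @param series a [growth_series()].
#' @param basis `"charge"` (µV/nC) or `"current"` (µV/µA).
#' @param criterion threshold criterion defining suprathreshold levels.
#' @return a `growth_fit` with `slope1`, `intercept1`, `r_squared`.
#' @export
fit_linear <- function(series, basis = c("charge", "current"),
                       criterion = 0.1) {
  basis <- match.arg(basis)
  lv <- suprathreshold_levels(series, criterion)
  if (nrow(lv) < 2) stop("need at least 2 suprathreshold levels")
  x <- if (basis == "charge") lv$charge else lv$current
  fit <- stats::lm(lv$amplitude ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((lv$amplitude - mean(lv$amplitude))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  flags <- if (nrow(lv) == 2) "low_n" else character()
  new_growth_fit("linear", basis, slope1 = unname(stats::coef(fit)[2]),
                 intercept1 = unname(stats::coef(fit)[1]), r_squared = r2,
                 n = nrow(lv), rss = ss_res, flags = flags)
}

broken_stick_value <- function(x, a1, s1, s2, k) {
  ifelse(x <= k, a1 + s1 * x, a1 + s1 * k + s2 * (x - k))
}

#' Broken-stick growth-function fit
#'
#' Bounded nonlinear least squares of the continuous two-segment model
#' (line 1 up to the knee, line 2 after) with multi-start over a grid of
#' knee candidates. Deterministic given the data.
#'
#' @inheritParams fit_linear
#' @param n_starts number of equispaced knee candidates inside the knee
#'   bounds (default 9).
#' @return a `growth_fit` with `slope1`, `slope2`, `intercept1`, `knee`.
#' @export
fit_broken_stick <- function(series, basis = c("charge", "current"),
                             criterion = 0.1, n_starts = 9) {
  basis <- match.arg(basis)
  lv <- suprathreshold_levels(series, criterion)
  if (nrow(lv) < 4) stop("need at least 4 suprathreshold levels")
  x <- if (basis == "charge") lv$charge else lv$current
  y <- lv$amplitude
  sc <- if (basis == "charge") 1 else lv$charge[1] / lv$current[1]
  # bounds rescaled to the working basis: slopes in µV/x-unit, knee in
  # x-units
  lb <- c(BROKEN_STICK_BOUNDS$intercept1[1],
          BROKEN_STICK_BOUNDS$slope1[1] * sc,
          BROKEN_STICK_BOUNDS$slope2[1] * sc,
          BROKEN_STICK_BOUNDS$knee[1] / sc)
  ub <- c(BROKEN_STICK_BOUNDS$intercept1[2],
          BROKEN_STICK_BOUNDS$slope1[2] * sc,
          BROKEN_STICK_BOUNDS$slope2[2] * sc,
          BROKEN_STICK_BOUNDS$knee[2] / sc)
  obj <- function(p) sum((y - broken_stick_value(x, p[1], p[2], p[3],
                                                 p[4]))^2)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  knees <- seq(lb[4], ub[4], length.out = n_starts)
  best <- NULL
  for (k0 in knees) {
    below <- x <= k0
    if (sum(below) >= 2) {
      cf <- stats::coef(stats::lm(y[below] ~ x[below]))
      a0 <- clamp(unname(cf[1]), lb[1], ub[1])
      s0 <- clamp(unname(cf[2]), lb[2], ub[2])
    } else {
      a0 <- clamp(0, lb[1], ub[1])
      s0 <- clamp(mean(y) / mean(x), lb[2], ub[2])
    }
    p0 <- c(a0, s0, clamp(-1e-3 * sc, lb[3], ub[3]), k0)
    res <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) stop("broken-stick optimizer failed for all starts")
  p <- best$par
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - best$value / ss_tot else 1
  at_bound <- abs(p[4] - lb[4]) < 1e-8 || abs(p[4] - ub[4]) < 1e-8
  flags <- if (at_bound) "knee_at_bound" else character()
  new_growth_fit("broken_stick", basis, slope1 = p[2], intercept1 = p[1],
                 r_squared = r2, slope2 = p[3], knee = p[4], n = length(y),
                 rss = best$value, flags = flags)
}

#' Choose between linear and broken-stick fits
#'
#' Automated replacement for visual model choice: the broken-stick model
#' is selected iff it reduces the residual sum of squares significantly
#' (extra-sum-of-squares F-test, alpha = 0.05) and its knee lies strictly
#' inside the tested range. A manual `override` is honored.
#'
#' @param linear_fit,broken_fit fits of the same data.
#' @param series the fitted [growth_series()].
#' @param alpha F-test significance level.
#' @param override `NULL`, `"linear"` or `"broken_stick"`.
#' @param criterion threshold criterion.
#' @return the selected `growth_fit` (with a `selection` attribute).
#' @export
select_model <- function(linear_fit, broken_fit, series, alpha = 0.05,
                         override = NULL, criterion = 0.1) {
  if (!is.null(override)) {
    sel <- if (override == "broken_stick") broken_fit else linear_fit
    attr(sel, "selection") <- paste0("override:", override)
    return(sel)
  }
  n <- broken_fit$n
  df2 <- n - 4
  pick_linear <- function(reason) {
    attr(linear_fit, "selection") <- reason
    linear_fit
  }
  if (df2 <= 0) return(pick_linear("too_few_points"))
  f_stat <- ((linear_fit$rss - broken_fit$rss) / 2) / (broken_fit$rss / df2)
  p_val <- if (broken_fit$rss <= 0) 0 else
    stats::pf(f_stat, 2, df2, lower.tail = FALSE)
  bx <- basis_x(series, broken_fit$unit_basis)
  interior <- broken_fit$knee > min(bx$x) && broken_fit$knee < max(bx$x) &&
    !"knee_at_bound" %in% broken_fit$flags
  if (is.finite(p_val) && p_val < alpha && interior) {
    attr(broken_fit, "selection") <- sprintf("f_test(p=%.4g)", p_val)
    broken_fit
  } else {
    pick_linear(sprintf("f_test(p=%.4g)", p_val))
  }
}

#' Strength-duration regression
#'
#' Least squares of threshold (in dB, 20 log10 convention) against log2
#' phase duration. The slope is in dB per doubling of the phase duration;
#' 0 dB re 1 nC/doubling corresponds to a perfect charge integrator, and
#' the charge-basis slope always exceeds the current-basis slope by
#' exactly 20 log10(2) = 6.0206 dB/doubling.
#'
#' @param durations phase durations in µs.
#' @param thresholds thresholds (charge in nC or current in µA) matching
#'   `durations`; `NA` (undefined) thresholds are dropped.
#' @param basis label recorded in the result: `"dB re 1 nC"` or
#'   `"dB re 1 uA"`.
#' @return object of class `sd_fit` with `slope` (dB/doubling),
#'   `intercept` (dB at 1 µs), `r_squared`, `basis`.
#' @export
strength_duration_fit <- function(durations, thresholds,
                                  basis = "dB re 1 nC") {
  ok <- !is.na(thresholds)
  durations <- durations[ok]
  thresholds <- thresholds[ok]
  if (length(durations) < 2) {
    stop("need >= 2 durations with defined thresholds")
  }
  x <- log2(durations)
  y <- to_db(thresholds)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, basis = basis, n = length(durations)),
            class = "sd_fit")
}
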