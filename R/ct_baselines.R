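#' Fit a four-parameter logistic to an amplification curve
#'
#' Least-squares fit of `F(c) = F_b + F_max / (1 + exp(-(c - c_half)/k))`.
#' Classical threshold-cycle estimators are all derived from this fitted
#' model rather than from raw finite differences, which amplify noise.
#' Initialization: `F_b` = minimum, `F_max` = range, `c_half` = first
#' half-range crossing, `k` = 2 cycles; bounded Gauss-Newton (`nls`, port
#' algorithm) with a bounded Nelder-Mead fallback.
#'
#' @param trace A [fluorescence_trace()], or any list with `cycles` and
#'   `fluorescence`.
#' @param cycles Optional subset of cycles to fit on (default: all).
#' @return A list of class `sigmoid_fit`: `F_b`, `F_max`, `c_half`, `k`,
#'   `residual_norm`, `n_cycles`.
#' @export
fit_logistic <- function(trace, cycles = NULL) {
  cyc <- trace$cycles
  f <- trace$fluorescence
  if (!is.null(cycles)) {
    keep <- cyc %in% cycles
    cyc <- cyc[keep]
    f <- f[keep]
  }
  if (length(cyc) < 5L)
    stop_peakfluo("at least 5 points are required to fit a logistic")
  rng <- diff(range(f))
  if (rng <= 0 || rng < 1e-8 * max(abs(f), 1))
    stop_peakfluo("trace has no dynamic range; logistic fit is degenerate")

  half <- min(f) + rng / 2
  i_half <- which(f >= half)[1]
  start <- list(F_b = min(f), F_max = rng,
                c_half = cyc[max(i_half, 2L)], k = 2)
  lower <- c(F_b = min(f) - rng, F_max = rng * 1e-3,
             c_half = min(cyc) - 3 * length(cyc), k = 0.05)
  upper <- c(F_b = max(f), F_max = 100 * rng,
             c_half = max(cyc) + 3 * length(cyc), k = length(cyc))

  df <- data.frame(cyc = cyc, f = f)
  fit <- tryCatch(
    stats::nls(f ~ F_b + F_max / (1 + exp(-(cyc - c_half) / k)),
               data = df, start = start, lower = lower, upper = upper,
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    p <- as.list(stats::coef(fit))
    rn <- sqrt(sum(stats::residuals(fit)^2))
  } else {
    # fallback: bounded quasi-Newton on the sum of squares
    sse <- function(par) {
      pred <- par[1] + par[2] / (1 + exp(-(cyc - par[3]) / par[4]))
      sum((f - pred)^2)
    }
    opt <- stats::optim(unlist(start), sse, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 500))
    p <- as.list(opt$par)
    names(p) <- c("F_b", "F_max", "c_half", "k")
    rn <- sqrt(opt$value)
  }
  if (!all(vapply(p, is.finite, TRUE)))
    stop_peakfluo("logistic fit did not converge (non-finite parameters; residual norm %.3g)", rn)
  structure(list(F_b = p$F_b, F_max = p$F_max, c_half = p$c_half, k = p$k,
                 residual_norm = rn, n_cycles = max(trace$cycles)),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> F_b=%.4g F_max=%.4g c_half=%.4g k=%.4g (resid %.3g)\n",
              x$F_b, x$F_max, x$c_half, x$k, x$residual_norm))
  invisible(x)
}

# Fitted curve and its baseline-subtracted form
predict_sigmoid <- function(fit, c) {
  fit$F_b + fit$F_max / (1 + exp(-(c - fit$c_half) / fit$k))
}

ct_estimate <- function(method, value) {
  structure(list(method = method, value = value), class = "ct_estimate")
}

#' @export
print.ct_estimate <- function(x, ...) {
  cat(sprintf("<ct_estimate> %s = %.4g\n", x$method, x$value))
  invisible(x)
}

as_sigmoid_fit <- function(x) {
  if (inherits(x, "sigmoid_fit")) x else fit_logistic(x)
}

#' Threshold-crossing Ct
#'
#' Scales the fitted logistic to \[0, 1\] (removing baseline and amplitude,
#' which makes the estimate scale-invariant) and returns the fractional
#' cycle at which the scaled curve crosses `threshold_fraction`.
#'
#' @param x A [fluorescence_trace()] or a [fit_logistic()] result.
#' @param threshold_fraction Fraction of the scaled amplitude, in (0, 1);
#'   default 0.1.
#' @return A `ct_estimate` (`method = "threshold"`). At 0.5 the Ct equals
#'   the inflection cycle `c_half` exactly.
#' @export
ct_threshold <- function(x, threshold_fraction = 0.1) {
  if (!is_num1(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1)
    stop_peakfluo("threshold_fraction must lie in (0, 1)")
  fit <- as_sigmoid_fit(x)
  ct <- fit$c_half + fit$k * stats::qlogis(threshold_fraction)
  if (ct < 1 || ct > fit$n_cycles)
    stop_peakfluo("scaled curve does not cross %.3g within the run (crossing at cycle %.2f)",
                  threshold_fraction, ct)
  ct_estimate("threshold", ct)
}

#' Derivative-maximum Ct
#'
#' Cycle at which the first (or second) derivative of the fitted logistic is
#' maximal, located on a dense cycle grid. For a pure logistic the
#' first-derivative maximum is `c_half` and the second-derivative maximum is
#' `c_half - k * log(2 + sqrt(3))`.
#'
#' @param x A [fluorescence_trace()] or a [fit_logistic()] result.
#' @param order 1 or 2.
#' @param grid_step Spacing of the dense evaluation grid in cycles.
#' @return A `ct_estimate` (`method = "d1max"` or `"d2max"`).
#' @export
ct_derivative <- function(x, order = 1L, grid_step = 0.001) {
  if (!order %in% c(1L, 2L))
    stop_peakfluo("order must be 1 or 2")
  fit <- as_sigmoid_fit(x)
  g <- seq(1, fit$n_cycles, by = grid_step)
  s <- stats::plogis((g - fit$c_half) / fit$k)
  d1 <- fit$F_max * s * (1 - s) / fit$k
  val <- if (order == 1L) d1 else d1 * (1 - 2 * s) / fit$k
  ct_estimate(if (order == 1L) "d1max" else "d2max", g[which.max(val)])
}

#' Cy0 tangent estimate
#'
#' Intersection of the inflection-point tangent of the fitted,
#' baseline-subtracted curve with the cycle axis:
#' `Cy0 = c_half - F(c_half) / F'(c_half)`, which for the logistic equals
#' `c_half - 2k`. Multiplying the fluorescence by a constant leaves Cy0
#' unchanged.
#'
#' @param x A [fluorescence_trace()] or a [fit_logistic()] result.
#' @return A `ct_estimate` (`method = "cy0"`).
#' @export
cy0 <- function(x) {
  fit <- as_sigmoid_fit(x)
  f_inf <- fit$F_max / 2                  # baseline-subtracted value at c_half
  d_inf <- fit$F_max / (4 * fit$k)        # slope at the inflection
  if (d_inf <= 0)
    stop_peakfluo("zero derivative at the inflection point")
  ct_estimate("cy0", fit$c_half - f_inf / d_inf)
}

#' F0 back-projection
#'
#' Fits the logistic on cycles up to `cutoff_cycle` only and back-projects
#' the fitted amplification component to cycle 0:
#' `F0 = F_max * plogis(-c_half / k)` (baseline subtracted, so that F0 is
#' proportional to the starting template rather than dominated by the
#' background level). The value is a fluorescence, not a cycle.
#'
#' F0 is template-proportional only when the cutoff sits in the exponential
#' phase (before the visible take-off departs from exponential growth) and
#' the baseline carries no drift — the logistic has no drift term, and an
#' uncorrected linear baseline biases the back-projection severely. The
#' cutoff must still be late enough that amplification is detectable above
#' the early-cycle linear trend (at least 6 early-residual standard
#' deviations and 5% of the background level).
#'
#' @param trace A [fluorescence_trace()].
#' @param cutoff_cycle Last cycle included in the fit.
#' @return A `ct_estimate` (`method = "f0"`, value in a.u.).
#' @export
f0_backproject <- function(trace, cutoff_cycle) {
  keep <- trace$cycles[trace$cycles <= cutoff_cycle]
  if (length(keep) < 5L)
    stop_peakfluo("fewer than 5 cycles before the cutoff")
  sub <- list(cycles = keep,
              fluorescence = trace$fluorescence[trace$cycles <= cutoff_cycle])
  # amplification must be visible before the cutoff: the signal has to rise
  # above the linear background trend fitted on the earliest cycles
  pre <- sub$fluorescence
  n_ref <- min(10L, length(pre) - 2L)
  ref <- stats::lm(y ~ x, data = data.frame(x = keep[seq_len(n_ref)],
                                            y = pre[seq_len(n_ref)]))
  dev <- pre - stats::predict(ref, newdata = data.frame(x = keep))
  s_ref <- stats::sd(stats::residuals(ref))
  if (max(dev) < max(6 * s_ref, 0.05 * stats::median(abs(pre))))
    stop_peakfluo("no amplification detectable before the cutoff cycle")
  fit <- fit_logistic(sub)
  ct_estimate("f0", fit$F_max * stats::plogis(-fit$c_half / fit$k))
}

#' Standard curve from a classical estimator
#'
#' Runs one of the surveyed estimators on each replicate-averaged group and
#' regresses the estimate on log10(concentration), mirroring how commercial
#' software builds a Ct standard curve. For `method = "f0"` the regression
#' uses log10(F0), which is linear in log10 template.
#'
#' @param traces Named list of [fluorescence_trace()].
#' @param layout A [plate_design()].
#' @param method One of `"ct"` (scaled threshold), `"d1"`, `"d2"`, `"cy0"`,
#'   `"f0"`.
#' @param threshold_fraction Passed to [ct_threshold()].
#' @param cutoff_cycle Passed to [f0_backproject()]; defaults to the last
#'   cycle.
#' @return A list of class `ct_curve`: per-group values, `slope`,
#'   `intercept`, `r_squared`, `method`.
#' @export
ct_standard_curve <- function(traces, layout, method = c("ct", "d1", "d2", "cy0", "f0"),
                              threshold_fraction = 0.1, cutoff_cycle = NULL) {
  method <- match.arg(method)
  validate_plate_design(layout)
  std_groups <- unique(layout$replicate_group[layout$role == "standard"])
  if (length(std_groups) < 2L)
    stop_peakfluo("at least two standard concentrations are required")
  value_of <- function(tr) {
    switch(method,
           ct = ct_threshold(tr, threshold_fraction)$value,
           d1 = ct_derivative(tr, 1L)$value,
           d2 = ct_derivative(tr, 2L)$value,
           cy0 = cy0(tr)$value,
           f0 = f0_backproject(tr, if (is.null(cutoff_cycle))
             max(tr$cycles) else cutoff_cycle)$value)
  }
  rows <- do.call(rbind, lapply(std_groups, function(g) {
    ids <- layout$well_id[layout$replicate_group == g]
    tr <- average_replicates(traces[ids], well_id = g)
    data.frame(replicate_group = g,
               concentration = layout$concentration[layout$replicate_group == g][1],
               value = value_of(tr), stringsAsFactors = FALSE)
  }))
  y <- if (method == "f0") log10(rows$value) else rows$value
  x <- log10(rows$concentration)
  fit <- stats::lm(y ~ x)
  r2 <- if (nrow(rows) >= 3L) summary(fit)$r.squared else NA_real_
  structure(list(points = rows, slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]), r_squared = r2,
                 method = method),
            class = "ct_curve")
}
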