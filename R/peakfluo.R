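#' PeakFluo algorithm parameters
#'
#' @param background_window Cycles used to estimate per-well background
#'   (default 1:10); must end before `start_cycle`.
#' @param background_mode `"mean"` (average fluorescence over the window,
#'   the default) or `"max"`.
#' @param start_cycle First processed cycle (default 11).
#' @param persistence Number of consecutive cycles above the running minimum
#'   required to declare the peak found (default 3).
#' @param validity_tolerance Positive excursion (a.u.) a cleaned sample
#'   signal may show before its peak without invalidating the assay.
#' @param quant_mode `"log10"` (invert the fitted line in log10-concentration
#'   space, default) or `"twopoint_raw"` (two-point slope arithmetic on raw
#'   concentrations, for strict pseudocode emulation).
#' @return A list of class `peakfluo_params`.
#' @export
peakfluo_params <- function(background_window = 1:10,
                            background_mode = c("mean", "max"),
                            start_cycle = 11L,
                            persistence = 3L,
                            validity_tolerance = 50,
                            quant_mode = c("log10", "twopoint_raw")) {
  background_mode <- match.arg(background_mode)
  quant_mode <- match.arg(quant_mode)
  if (max(background_window) >= start_cycle)
    stop_peakfluo("background window must end before start_cycle")
  if (!is_count(persistence))
    stop_peakfluo("persistence must be a positive integer")
  structure(list(background_window = as.integer(background_window),
                 background_mode = background_mode,
                 start_cycle = as.integer(start_cycle),
                 persistence = as.integer(persistence),
                 validity_tolerance = validity_tolerance,
                 quant_mode = quant_mode),
            class = "peakfluo_params")
}

#' Estimate per-well background fluorescence
#'
#' Background is the fluorescence observed before amplification is
#' detectable, estimated over the early-cycle window as either the average
#' (default) or the maximum of the raw signal.
#'
#' @param trace A [fluorescence_trace()].
#' @param window Integer cycle window, default 1:10.
#' @param mode `"mean"` or `"max"`.
#' @return Background level in a.u.
#' @export
estimate_background <- function(trace, window = 1:10,
                                mode = c("mean", "max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (length(window) == 0L || any(!window %in% trace$cycles))
    stop_peakfluo("background window must be a nonempty subset of the trace cycles")
  v <- trace$fluorescence[match(window, trace$cycles)]
  if (mode == "mean") mean(v) else max(v)
}

#' Subtract background and process noise from a trace
#'
#' The cleaned signal from the first processed cycle onward is
#' `(f(c) - bg) - (f0(c) - bg0)`: the well's own background-subtracted
#' fluorescence minus the background-subtracted negative control, which
#' carries the shared process fluorescence. The control cleaned against
#' itself is identically zero.
#'
#' @param trace A [fluorescence_trace()].
#' @param control_trace The plate's negative-control trace (replicate-averaged).
#' @param params A [peakfluo_params()].
#' @return An object of class `cleaned_trace` with elements `well_id`,
#'   `cycles` (from `start_cycle` on) and `cleaned`.
#' @export
clean_trace <- function(trace, control_trace, params = peakfluo_params()) {
  stopifnot(inherits(trace, "fluorescence_trace"),
            inherits(control_trace, "fluorescence_trace"))
  if (!identical(trace$cycles, control_trace$cycles))
    stop_peakfluo("trace and control must share the same cycle grid")
  bg <- estimate_background(trace, params$background_window,
                            params$background_mode)
  bg0 <- estimate_background(control_trace, params$background_window,
                             params$background_mode)
  keep <- trace$cycles >= params$start_cycle
  if (!any(keep))
    stop_peakfluo("start_cycle beyond end of trace")
  cleaned <- (trace$fluorescence[keep] - bg) -
    (control_trace$fluorescence[keep] - bg0)
  structure(list(well_id = trace$well_id, cycles = trace$cycles[keep],
                 cleaned = cleaned),
            class = "cleaned_trace")
}

#' Early-stopping peak detection
#'
#' Streams the cleaned signal cycle by cycle, maintaining the running minimum
#' of the signed values. Once `persistence` consecutive cycles exceed the
#' running minimum the peak is declared found and processing stops — on an
#' instrument this is the point where the qPCR run can be aborted. The peak
#' magnitude is the absolute value of the minimum; ties keep the first
#' occurrence. If the trace ends before the persistence criterion fires, the
#' global minimum seen so far is returned with `found = FALSE`.
#'
#' @param cleaned A [clean_trace()] result.
#' @param persistence Consecutive rising cycles required (default 3).
#' @return A list of class `peak_result`: `peak_magnitude`, `peak_cycle`,
#'   `stop_cycle`, `found`.
#' @export
find_peak <- function(cleaned, persistence = 3L) {
  stopifnot(inherits(cleaned, "cleaned_trace"))
  if (!is_count(persistence))
    stop_peakfluo("persistence must be a positive integer")
  v <- cleaned$cleaned
  cyc <- cleaned$cycles
  if (length(v) == 0L)
    stop_peakfluo("empty cleaned trace")
  run_min <- Inf
  min_cycle <- NA_integer_
  rising <- 0L
  stop_cycle <- cyc[length(cyc)]
  found <- FALSE
  for (i in seq_along(v)) {
    if (v[i] < run_min) {
      run_min <- v[i]
      min_cycle <- cyc[i]
      rising <- 0L
    } else if (v[i] > run_min) {
      rising <- rising + 1L
      if (rising >= persistence) {
        stop_cycle <- cyc[i]
        found <- TRUE
        break
      }
    } else {
      # tie with the running minimum: neither a new minimum (first occurrence
      # wins) nor evidence of rising
      rising <- 0L
    }
  }
  structure(list(peak_magnitude = abs(run_min), peak_cycle = min_cycle,
                 stop_cycle = stop_cycle, found = found),
            class = "peak_result")
}

#' @export
print.peak_result <- function(x, ...) {
  cat(sprintf("<peak_result> |peak| = %.4g at cycle %d, stopped at cycle %d (%s)\n",
              x$peak_magnitude, x$peak_cycle, x$stop_cycle,
              if (x$found) "early stop" else "end of trace"))
  invisible(x)
}

#' Average replicate traces
#'
#' Cycle-wise arithmetic mean of raw fluorescence. Averaging is done on raw
#' signals before cleaning; with per-well noise sd `s`, the averaged trace
#' has residual sd `s / sqrt(n)`.
#'
#' @param traces Nonempty list of [fluorescence_trace()] on a common grid.
#' @param well_id Identifier for the averaged trace (defaults to the ids
#'   joined with `+`).
#' @return A [fluorescence_trace()].
#' @export
average_replicates <- function(traces, well_id = NULL) {
  if (length(traces) == 0L)
    stop_peakfluo("cannot average an empty list of traces")
  stopifnot(all(vapply(traces, inherits, TRUE, "fluorescence_trace")))
  cyc <- traces[[1]]$cycles
  for (tr in traces)
    if (!identical(tr$cycles, cyc))
      stop_peakfluo("replicate traces must share the same cycle grid")
  m <- rowMeans(vapply(traces, `[[`, numeric(length(cyc)), "fluorescence"))
  if (is.null(well_id))
    well_id <- paste(vapply(traces, `[[`, "", "well_id"), collapse = "+")
  fluorescence_trace(well_id, m, cyc)
}

#' Assay validity gate
#'
#' A sample that amplifies before the negative control indicates interference
#' from free sequences; such a cartridge must be discarded. A cleaned sample
#' signal is flagged if it rises above `+tolerance` at any cycle up to the
#' cycle of its minimum (last occurrence of the minimum value, so a purely
#' positive excursion that returns to zero is still caught).
#'
#' @param sample_cleaned List of [clean_trace()] results (standards and
#'   unknowns; not the control).
#' @param tolerance Positive excursion allowed before the peak, a.u.
#' @return `TRUE` if the assay is valid; an empty list is vacuously valid.
#' @export
validate_assay <- function(sample_cleaned, tolerance = 50) {
  if (length(sample_cleaned) == 0L) return(TRUE)
  stopifnot(all(vapply(sample_cleaned, inherits, TRUE, "cleaned_trace")))
  for (ct in sample_cleaned) {
    v <- ct$cleaned
    i_min <- max(which(v == min(v)))
    if (any(v[seq_len(i_min)] > tolerance)) return(FALSE)
  }
  TRUE
}

#' Fit a peak-vs-log-concentration standard curve
#'
#' Ordinary least squares of peak magnitude on log10(concentration). With
#' exactly two concentrations this reduces to the two-point slope; R-squared
#' is only defined from three points on.
#'
#' @param concentrations Known standard concentrations in ng/mL (> 0), one
#'   per (replicate-averaged) peak.
#' @param peaks Peak magnitudes, a.u.
#' @return A list of class `standard_curve`: `slope` (a.u. per decade),
#'   `intercept`, `r_squared` (`NA` for two points), `fit_points`.
#' @export
fit_standard_curve <- function(concentrations, peaks) {
  if (length(concentrations) != length(peaks))
    stop_peakfluo("concentrations and peaks must have equal length")
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    stop_peakfluo("standard concentrations must be positive and finite")
  if (length(unique(concentrations)) < 2L)
    stop_peakfluo("at least two distinct standard concentrations are required")
  x <- log10(concentrations)
  fit <- stats::lm(peaks ~ x)
  r2 <- if (length(concentrations) >= 3L) {
    ss_tot <- sum((peaks - mean(peaks))^2)
    if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  } else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 fit_points = data.frame(log10_conc = x, peak = peaks)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> peak = %.4g + %.4g * log10(conc); R^2 = %s\n",
              x$intercept, x$slope,
              if (is.na(x$r_squared)) "NA (2 points)"
              else sprintf("%.4f", x$r_squared)))
  invisible(x)
}

#' Quantify a sample from its peak magnitude
#'
#' Default mode inverts the fitted line in log10 space:
#' `conc = 10^((peak - intercept) / slope)`, so a sample whose peak equals a
#' standard's fitted peak recovers that standard's concentration exactly.
#' `"twopoint_raw"` reproduces the two-point raw-concentration arithmetic of
#' the original pseudocode using the first and last fit points.
#'
#' @param peak Sample peak magnitude, a.u.
#' @param curve A [fit_standard_curve()] result.
#' @param mode `"log10"` or `"twopoint_raw"`.
#' @param min_slope Slopes with absolute value below this are treated as a
#'   flat (unusable) curve.
#' @return Estimated concentration in ng/mL.
#' @export
quantify_sample <- function(peak, curve, mode = c("log10", "twopoint_raw"),
                            min_slope = 1e-8) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "standard_curve"))
  if (mode == "log10") {
    if (abs(curve$slope) < min_slope)
      stop_peakfluo("standard curve is flat; quantification impossible")
    10^((peak - curve$intercept) / curve$slope)
  } else {
    fp <- curve$fit_points
    c1 <- 10^fp$log10_conc[1]
    c2 <- 10^fp$log10_conc[nrow(fp)]
    p1 <- fp$peak[1]
    p2 <- fp$peak[nrow(fp)]
    m <- (p1 - p2) / (c1 - c2)
    if (abs(m) < min_slope)
      stop_peakfluo("standard curve is flat; quantification impossible")
    (peak - p2) / m + c1
  }
}

#' Run the full PeakFluo pipeline on a plate
#'
#' Replicate wells are averaged on raw fluorescence; backgrounds are
#' estimated per averaged trace; every group is cleaned against the averaged
#' negative control; the early-stopping peak detector runs per group; the
#' validity gate checks that no sample amplified before the control; a
#' standard curve is fitted to the standards' peaks and used to quantify the
#' unknowns. If the assay is invalid, concentrations are withheld.
#'
#' @param traces Named list of [fluorescence_trace()] (e.g. from
#'   [simulate_plate()] or [read_plate()]).
#' @param layout A [plate_design()] covering every trace well.
#' @param params A [peakfluo_params()].
#' @return A list of class `peakfluo_result` with elements `groups`
#'   (per-group data.frame: role, concentration, peak, peak cycle, stop
#'   cycle, found), `curve`, `valid_assay`, `samples` (per-unknown estimated
#'   concentrations), `replicate_peaks` (per-well diagnostics) and `params`.
#' @export
run_peakfluo <- function(traces, layout, params = peakfluo_params()) {
  stopifnot(inherits(params, "peakfluo_params"))
  validate_plate_design(layout)
  missing_wells <- setdiff(layout$well_id, names(traces))
  if (length(missing_wells))
    stop_peakfluo("traces missing for wells: %s",
                  paste(missing_wells, collapse = ", "))
  std_groups <- unique(layout$replicate_group[layout$role == "standard"])
  if (length(std_groups) < 2L)
    stop_peakfluo("at least two standard concentrations are required")

  groups <- unique(layout$replicate_group)
  avg <- lapply(groups, function(g) {
    ids <- layout$well_id[layout$replicate_group == g]
    average_replicates(traces[ids], well_id = g)
  })
  names(avg) <- groups
  ctrl_group <- unique(layout$replicate_group[layout$role == "control"])
  control <- avg[[ctrl_group]]

  cleaned <- lapply(avg, clean_trace, control_trace = control, params = params)
  peaks <- lapply(cleaned, find_peak, persistence = params$persistence)

  info <- do.call(rbind, lapply(groups, function(g) {
    rows <- layout[layout$replicate_group == g, ]
    data.frame(replicate_group = g, role = rows$role[1],
               concentration = rows$concentration[1],
               peak_magnitude = peaks[[g]]$peak_magnitude,
               peak_cycle = peaks[[g]]$peak_cycle,
               stop_cycle = peaks[[g]]$stop_cycle,
               found = peaks[[g]]$found,
               stringsAsFactors = FALSE)
  }))
  rownames(info) <- NULL

  valid <- validate_assay(cleaned[setdiff(groups, ctrl_group)],
                          tolerance = params$validity_tolerance)

  std <- info[info$role == "standard", ]
  curve <- fit_standard_curve(std$concentration, std$peak_magnitude)

  unk <- info[info$role == "unknown", , drop = FALSE]
  samples <- if (nrow(unk)) {
    est <- if (valid) {
      vapply(unk$peak_magnitude, quantify_sample, numeric(1), curve = curve,
             mode = params$quant_mode)
    } else rep(NA_real_, nrow(unk))
    data.frame(replicate_group = unk$replicate_group,
               peak_magnitude = unk$peak_magnitude,
               estimated_concentration = est, stringsAsFactors = FALSE)
  } else {
    data.frame(replicate_group = character(0), peak_magnitude = numeric(0),
               estimated_concentration = numeric(0))
  }

  # per-replicate peaks against the averaged control, for dispersion checks
  replicate_peaks <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    pr <- find_peak(clean_trace(traces[[layout$well_id[i]]], control, params),
                    persistence = params$persistence)
    data.frame(well_id = layout$well_id[i],
               replicate_group = layout$replicate_group[i],
               peak_magnitude = pr$peak_magnitude, stringsAsFactors = FALSE)
  }))

  structure(list(groups = info, curve = curve, valid_assay = valid,
                 samples = samples, replicate_peaks = replicate_peaks,
                 params = params),
            class = "peakfluo_result")
}

#' @export
print.peakfluo_result <- function(x, ...) {
  cat("PeakFluo quantification\n")
  cat(sprintf("  assay valid: %s\n", x$valid_assay))
  print(x$curve)
  if (nrow(x$samples)) {
    cat("  samples:\n")
    for (i in seq_len(nrow(x$samples)))
      cat(sprintf("    %s: peak %.4g -> %s ng/mL\n",
                  x$samples$replicate_group[i], x$samples$peak_magnitude[i],
                  if (is.na(x$samples$estimated_concentration[i])) "withheld (invalid assay)"
                  else sprintf("%.4g", x$samples$estimated_concentration[i])))
  }
  invisible(x)
}
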