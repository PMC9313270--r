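#' Write a plate to wide CSV
#'
#' Format: header `cycle,<well_id_1>,...`, one row per cycle, values written
#' with 6 significant digits. [read_plate()] restores the plate bit-exactly
#' at that precision.
#'
#' @param traces Named list of [fluorescence_trace()] on a common grid.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plate <- function(traces, path) {
  stopifnot(length(traces) > 0L)
  cyc <- traces[[1]]$cycles
  for (tr in traces)
    if (!identical(tr$cycles, cyc))
      stop_peakfluo("all traces must share the same cycle grid")
  df <- data.frame(cycle = cyc)
  for (tr in traces)
    df[[tr$well_id]] <- format(signif(tr$fluorescence, 6), trim = TRUE,
                               scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate from wide CSV
#'
#' @param path CSV written by [write_plate()] (or any instrument export in
#'   the same layout).
#' @return Named list of [fluorescence_trace()].
#' @export
read_plate <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "cycle")
    stop_peakfluo("plate CSV must start with a 'cycle' column")
  wells <- header[-1]
  if (anyDuplicated(wells))
    stop_peakfluo("duplicate well column(s): %s",
                  paste(unique(wells[duplicated(wells)]), collapse = ", "))
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (any(df == "" | is.na(df)))
    stop_peakfluo("plate CSV contains empty cells (ragged rows?)")
  num <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (is.null(dim(num))) num <- matrix(num, nrow = nrow(df),
                                       dimnames = list(NULL, names(df)))
  if (any(!is.finite(num)))
    stop_peakfluo("plate CSV contains non-numeric cells")
  cyc <- as.integer(num[, "cycle"])
  if (cyc[1] != 1L || any(diff(cyc) != 1L))
    stop_peakfluo("cycle column must be contiguous integers from 1")
  traces <- lapply(wells, function(w)
    fluorescence_trace(w, num[, w], cyc))
  names(traces) <- wells
  traces
}

#' Write a plate layout to CSV
#'
#' Columns: `well_id,role,concentration_ng_ml,replicate_group`. By default
#' the concentration of unknown wells is masked (written empty), matching
#' how a layout looks before quantification.
#'
#' @param design A [plate_design()].
#' @param path Output path.
#' @param mask_unknowns Write empty concentration for unknown wells.
#' @return `path`, invisibly.
#' @export
write_layout <- function(design, path, mask_unknowns = TRUE) {
  validate_plate_design(design)
  conc <- ifelse(mask_unknowns & design$role == "unknown", "",
                 format(design$concentration, trim = TRUE,
                        scientific = FALSE))
  df <- data.frame(well_id = design$well_id, role = design$role,
                   concentration_ng_ml = conc,
                   replicate_group = design$replicate_group)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate layout from CSV
#'
#' @param path Layout CSV (see [write_layout()]).
#' @return A [plate_design()]; masked unknown concentrations come back `NA`.
#' @export
read_layout <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("well_id", "role", "concentration_ng_ml", "replicate_group")
  if (!all(need %in% names(df)))
    stop_peakfluo("layout CSV must have columns %s",
                  paste(need, collapse = ", "))
  conc <- suppressWarnings(as.numeric(df$concentration_ng_ml))
  conc[df$concentration_ng_ml == ""] <- NA_real_
  plate_design(df$well_id, df$role, conc, df$replicate_group)
}

# default run configuration tree; read_run_config() rejects keys absent here
default_run_config <- function() {
  list(
    seed = 1L,
    method = "peakfluo",
    simulate = TRUE,
    sim = list(standards = c(0.1, 1, 10), unknowns = c(0.3, 3),
               replicates = 3L, config = unclass(sim_config())),
    plate_file = NULL,
    layout_file = NULL,
    algorithm = list(background_mode = "mean", background_window = c(1L, 10L),
                     start_cycle = 11L, persistence = 3L,
                     validity_tolerance = 50, threshold_fraction = 0.1,
                     cutoff_cycle = NULL),
    classify = list(enabled = FALSE, threshold = 5, folds = 10L,
                    epochs = 12L, n_high = 201L, n_low = 77L),
    out = NULL
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_peakfluo("unknown configuration key(s): %s",
                  paste0(path, unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(user[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    else
      defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Build a run configuration
#'
#' Overrides are merged into the defaults; unknown keys are rejected, so a
#' typo in a configuration file fails loudly instead of being ignored.
#'
#' @param ... Named overrides of the default configuration (see
#'   `peakfluo:::default_run_config`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- merge_config(default_run_config(), list(...))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file of configuration overrides.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, user)
}

#' Write a run configuration to JSON
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

# invert a classical-estimator standard curve for an unknown's value
invert_ct_curve <- function(value, curve) {
  if (abs(curve$slope) < 1e-8)
    stop_peakfluo("standard curve is flat; quantification impossible")
  y <- if (curve$method == "f0") log10(value) else value
  10^((y - curve$intercept) / curve$slope)
}

#' Quantify a plate with a chosen method
#'
#' Routes to [run_peakfluo()] (`method = "peakfluo"`) or to one of the
#' classical estimators, which are run per replicate-averaged group and
#' calibrated against log10(concentration) the same way.
#'
#' @param traces Named list of [fluorescence_trace()].
#' @param layout A [plate_design()].
#' @param method `"peakfluo"`, `"ct"`, `"d1"`, `"d2"`, `"cy0"` or `"f0"`.
#' @param params [peakfluo_params()] (used by `"peakfluo"`).
#' @param threshold_fraction,cutoff_cycle Classical-estimator settings.
#' @return A list with `method`, `curve` (slope/intercept/R^2), `groups`,
#'   `samples`, and for PeakFluo `valid_assay` and stop cycles.
#' @export
quantify_plate <- function(traces, layout, method = "peakfluo",
                           params = peakfluo_params(),
                           threshold_fraction = 0.1, cutoff_cycle = NULL) {
  if (method == "peakfluo") {
    res <- run_peakfluo(traces, layout, params)
    return(list(method = "peakfluo",
                curve = list(slope = res$curve$slope,
                             intercept = res$curve$intercept,
                             r_squared = res$curve$r_squared),
                groups = res$groups, samples = res$samples,
                valid_assay = res$valid_assay, full = res))
  }
  curve <- ct_standard_curve(traces, layout, method = method,
                             threshold_fraction = threshold_fraction,
                             cutoff_cycle = cutoff_cycle)
  unk_groups <- unique(layout$replicate_group[layout$role == "unknown"])
  samples <- do.call(rbind, lapply(unk_groups, function(g) {
    ids <- layout$well_id[layout$replicate_group == g]
    tr <- average_replicates(traces[ids], well_id = g)
    val <- switch(method,
                  ct = ct_threshold(tr, threshold_fraction)$value,
                  d1 = ct_derivative(tr, 1L)$value,
                  d2 = ct_derivative(tr, 2L)$value,
                  cy0 = cy0(tr)$value,
                  f0 = f0_backproject(tr, if (is.null(cutoff_cycle))
                    max(tr$cycles) else cutoff_cycle)$value)
    data.frame(replicate_group = g, value = val,
               estimated_concentration = invert_ct_curve(val, curve),
               stringsAsFactors = FALSE)
  }))
  if (is.null(samples))
    samples <- data.frame(replicate_group = character(0), value = numeric(0),
                          estimated_concentration = numeric(0))
  list(method = method,
       curve = list(slope = curve$slope, intercept = curve$intercept,
                    r_squared = curve$r_squared),
       groups = curve$points, samples = samples)
}

#' Compare PeakFluo against the classical estimators
#'
#' Runs every requested method on the same plate and tabulates the
#' standard-curve coefficient of determination, the comparison the assay
#' uses to benchmark PeakFluo against commercial Ct software.
#'
#' @param traces Named list of [fluorescence_trace()].
#' @param layout A [plate_design()].
#' @param methods Methods to include.
#' @param ... Passed to [quantify_plate()].
#' @return A `data.frame` of class `method_comparison` with one row per
#'   method: `method`, `slope`, `intercept`, `r_squared`.
#' @export
compare_methods <- function(traces, layout,
                            methods = c("peakfluo", "ct", "d1", "d2", "cy0"),
                            ...) {
  rows <- lapply(methods, function(m) {
    q <- quantify_plate(traces, layout, method = m, ...)
    data.frame(method = m, slope = q$curve$slope,
               intercept = q$curve$intercept,
               r_squared = q$curve$r_squared, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("method_comparison", "data.frame")
  out
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Standard-curve R^2 by method\n")
  cat(sprintf("  %-10s %10s\n", "Method", "R^2"))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-10s %10.3f\n", x$method[i], x$r_squared[i]))
  invisible(x)
}

#' Run the configured pipeline
#'
#' Simulation (optional), quantification with the configured method, and
#' optionally classifier cross-validation; returns a structured report
#' carrying the package version and a hash of the configuration.
#'
#' @param config A [run_config()].
#' @return A list of class `results_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop_peakfluo("stage '%s' failed: %s", name, conditionMessage(e)))
    message(sprintf("[%s] done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }
  if (isTRUE(config$simulate)) {
    sim <- stage("simulate", {
      scfg <- do.call(sim_config, utils::modifyList(
        config$sim$config, list(seed = derive_seed(config$seed, "sim"))))
      design <- panel_design(config$sim$standards, config$sim$unknowns,
                             config$sim$replicates)
      list(traces = simulate_plate(design, scfg), layout = design)
    })
    traces <- sim$traces
    layout <- sim$layout
  } else {
    if (is.null(config$plate_file) || is.null(config$layout_file))
      stop_peakfluo("configuration is missing 'plate_file' or 'layout_file'")
    traces <- stage("read", read_plate(config$plate_file))
    layout <- read_layout(config$layout_file)
  }
  alg <- config$algorithm
  params <- peakfluo_params(
    background_window = seq(alg$background_window[1],
                            alg$background_window[2]),
    background_mode = alg$background_mode,
    start_cycle = alg$start_cycle, persistence = alg$persistence,
    validity_tolerance = alg$validity_tolerance)
  quant <- stage("quantify",
                 quantify_plate(traces, layout, method = config$method,
                                params = params,
                                threshold_fraction = alg$threshold_fraction,
                                cutoff_cycle = alg$cutoff_cycle))
  if (config$method == "peakfluo")
    for (i in seq_len(nrow(quant$groups)))
      message(sprintf("well group %s: stop cycle %d",
                      quant$groups$replicate_group[i],
                      quant$groups$stop_cycle[i]))
  cv <- if (isTRUE(config$classify$enabled)) {
    stage("classify", {
      ds <- make_cnn_dataset(
        n_high = config$classify$n_high, n_low = config$classify$n_low,
        cfg = do.call(sim_config, utils::modifyList(
          config$sim$config, list(seed = derive_seed(config$seed, "sim")))),
        seed = derive_seed(config$seed, "classify"),
        threshold = config$classify$threshold)
      rep <- cross_validate(ds, k = config$classify$folds,
                            seed = derive_seed(config$seed, "cv"),
                            epochs = config$classify$epochs)
      list(mean_accuracy = rep$mean_accuracy, sd_accuracy = rep$sd_accuracy,
           mean_loss = rep$mean_loss, sd_loss = rep$sd_loss)
    })
  } else NULL
  structure(list(
    method = quant$method,
    curve = quant$curve,
    groups = quant$groups,
    samples = quant$samples,
    valid_assay = if (!is.null(quant$valid_assay)) quant$valid_assay else NA,
    classification = cv,
    software_version = as.character(utils::packageVersion("peakfluo")),
    config_hash = config_hash(unclass(config)),
    seed = config$seed
  ), class = "results_report")
}

#' Write a results report to JSON
#' @param report A [run_pipeline()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}
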