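#' Simulator configuration
#'
#' Parameters of the four-phase amplification-curve simulator. The curve for a
#' well with starting template `y0` is
#' \deqn{f(c) = B + d\,c + A\,g(c - c_{on})}
#' where `B` is the baseline level, `d` the baseline drift per cycle,
#' `A = plateau_level - baseline_level` the common amplification amplitude, and
#' `g` a smoothed ramp that reproduces all four canonical qPCR phases:
#' background (flat), exponential take-off with per-cycle growth factor
#' `1 + E`, a quasi-linear phase of `ramp_cycles` cycles, and a common plateau.
#' The onset cycle `c_on` is where the template copy number
#' `y0 (1+E)^c` reaches `detection_threshold_copies`.
#'
#' Protein concentration maps to starting template through aptamer-adaptor
#' displacement: higher concentration displaces more complexes, leaving fewer
#' qPCR templates, so amplification starts later. The map is Langmuir-like,
#' `y0 = y0_control / (1 + conc / displacement_Kd)`.
#'
#' Noise has two components mirroring the assay's noise decomposition: a
#' process component shared by every well of a plate (a Gaussian random walk,
#' the part that negative-control subtraction removes) and independent
#' per-well Gaussian reader noise (photodiode/LED fluctuation, the part that
#' replicate averaging suppresses).
#'
#' @param n_cycles Number of thermal cycles (integer, default 40).
#' @param baseline_level Background fluorescence, arbitrary units.
#' @param baseline_drift Additive drift per cycle, a.u.
#' @param plateau_level Common plateau fluorescence, a.u.; must exceed
#'   `baseline_level`.
#' @param efficiency_E Reaction efficiency `E` in (0, 1]; template grows by
#'   `(1+E)` per cycle in the exponential phase.
#' @param detection_threshold_copies Copy number at which amplification
#'   becomes optically detectable.
#' @param y0_control Starting template copies in the 0 ng/mL negative control
#'   (no displacement, maximal template).
#' @param displacement_Kd Half-displacement concentration in ng/mL.
#' @param ramp_cycles Length of the quasi-linear growth phase in cycles.
#' @param noise_sd_well Per-well additive Gaussian noise sd, a.u.
#' @param noise_sd_process Step sd of the shared process random walk, a.u.
#' @param seed Integer seed; identical configurations and designs yield
#'   bit-identical plates.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cycles = 40L,
                       baseline_level = 100,
                       baseline_drift = 0.2,
                       plateau_level = 1100,
                       efficiency_E = 0.9,
                       detection_threshold_copies = 1e8,
                       y0_control = 1e4,
                       displacement_Kd = 0.02,
                       ramp_cycles = 14,
                       noise_sd_well = 5,
                       noise_sd_process = 2,
                       seed = 1L) {
  cfg <- list(
    n_cycles = as.integer(n_cycles),
    baseline_level = baseline_level,
    baseline_drift = baseline_drift,
    plateau_level = plateau_level,
    efficiency_E = efficiency_E,
    detection_threshold_copies = detection_threshold_copies,
    y0_control = y0_control,
    displacement_Kd = displacement_Kd,
    ramp_cycles = ramp_cycles,
    noise_sd_well = noise_sd_well,
    noise_sd_process = noise_sd_process,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_cycles) || cfg$n_cycles < 12)
    stop_peakfluo("n_cycles must be an integer >= 12 (background window plus processing)")
  if (!is_num1(cfg$efficiency_E) || cfg$efficiency_E <= 0 || cfg$efficiency_E > 1)
    stop_peakfluo("efficiency_E must lie in (0, 1]")
  if (cfg$plateau_level <= cfg$baseline_level)
    stop_peakfluo("plateau_level must exceed baseline_level")
  if (cfg$noise_sd_well < 0 || cfg$noise_sd_process < 0)
    stop_peakfluo("noise standard deviations must be >= 0")
  if (cfg$y0_control < 1)
    stop_peakfluo("y0_control must be >= 1 copy")
  if (cfg$displacement_Kd <= 0)
    stop_peakfluo("displacement_Kd must be > 0")
  if (cfg$ramp_cycles <= 0)
    stop_peakfluo("ramp_cycles must be > 0")
  if (cfg$detection_threshold_copies <= cfg$y0_control)
    stop_peakfluo("detection_threshold_copies must exceed y0_control")
  invisible(cfg)
}

#' Plate layout
#'
#' Assigns each well a role (`control`, `standard`, `unknown`), a
#' concentration in ng/mL and a replicate group. Exactly one replicate group
#' must be the 0 ng/mL negative control; standard concentrations must be
#' strictly positive and distinct across groups. Unknown wells carry their
#' true concentration for simulation; [write_layout()] masks it.
#'
#' @param well_id Character vector of unique well identifiers.
#' @param role One of `"control"`, `"standard"`, `"unknown"` per well.
#' @param concentration Concentration in ng/mL per well (`NA` allowed for
#'   unknowns read from a layout file).
#' @param replicate_group Grouping label; replicate wells share a group.
#' @return A `data.frame` of class `plate_design`.
#' @export
plate_design <- function(well_id, role, concentration, replicate_group) {
  design <- data.frame(
    well_id = as.character(well_id),
    role = as.character(role),
    concentration = as.numeric(concentration),
    replicate_group = as.character(replicate_group),
    stringsAsFactors = FALSE
  )
  validate_plate_design(design)
  class(design) <- c("plate_design", "data.frame")
  design
}

validate_plate_design <- function(design) {
  if (anyDuplicated(design$well_id))
    stop_peakfluo("well_id values must be unique")
  bad <- setdiff(unique(design$role), c("control", "standard", "unknown"))
  if (length(bad))
    stop_peakfluo("unknown role(s): %s", paste(bad, collapse = ", "))
  ctrl <- design[design$role == "control", ]
  if (length(unique(ctrl$replicate_group)) != 1L)
    stop_peakfluo("design must contain exactly one control replicate group")
  if (any(is.na(ctrl$concentration)) || any(ctrl$concentration != 0))
    stop_peakfluo("control wells must have concentration 0")
  std <- design[design$role == "standard", ]
  if (nrow(std)) {
    if (any(is.na(std$concentration)) || any(std$concentration <= 0))
      stop_peakfluo("standard concentrations must be strictly positive")
    per_group <- tapply(std$concentration, std$replicate_group, unique)
    if (any(lengths(per_group) != 1L))
      stop_peakfluo("a standard replicate group must have a single concentration")
    if (anyDuplicated(unlist(per_group)))
      stop_peakfluo("standard concentrations must be distinct across groups")
  }
  invisible(design)
}

#' Triplicate calibration panel design
#'
#' Convenience constructor for the assay's canonical plate: a 0 ng/mL
#' negative control plus standards at the given concentrations, each in
#' `replicates` wells, optionally followed by unknown samples.
#'
#' @param standards Standard concentrations in ng/mL (default 0.1, 1, 10).
#' @param unknowns True concentrations of unknown samples (used only by the
#'   simulator; masked in layout files).
#' @param replicates Wells per replicate group.
#' @return A [plate_design()].
#' @export
panel_design <- function(standards = c(0.1, 1, 10), unknowns = numeric(0),
                         replicates = 3L) {
  groups <- c(
    list(list(role = "control", conc = 0, group = "ctrl")),
    lapply(seq_along(standards), function(i)
      list(role = "standard", conc = standards[i],
           group = paste0("std", i))),
    lapply(seq_along(unknowns), function(i)
      list(role = "unknown", conc = unknowns[i],
           group = paste0("unk", i)))
  )
  rows <- do.call(rbind, lapply(groups, function(g) {
    data.frame(
      well_id = paste0(g$group, "_r", seq_len(replicates)),
      role = g$role, concentration = g$conc, replicate_group = g$group,
      stringsAsFactors = FALSE
    )
  }))
  plate_design(rows$well_id, rows$role, rows$concentration,
               rows$replicate_group)
}

#' Map protein concentration to starting template copies
#'
#' Aptamer-adaptor complexes are displaced by the target protein in a
#' Langmuir-like fashion, so the leftover template is inversely related to
#' concentration: `y0 = y0_control / (1 + conc / Kd)`, floored at one copy.
#' A 0 ng/mL sample keeps the full `y0_control`; at `conc = Kd` half the
#' complexes are displaced.
#'
#' @param conc Concentration(s) in ng/mL, non-negative.
#' @param cfg A [sim_config()].
#' @return Starting template copies (vectorized over `conc`).
#' @export
concentration_to_y0 <- function(conc, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(!is.finite(conc)) || any(conc < 0))
    stop_peakfluo("concentrations must be finite and >= 0")
  pmax(1, cfg$y0_control / (1 + conc / cfg$displacement_Kd))
}

#' Amplification onset cycle
#'
#' The cycle at which exponential growth `y0 (1+E)^n` reaches the detection
#' threshold: `log(threshold / y0) / log(1 + E)`. With `E = 1` each halving
#' of `y0` delays onset by exactly one cycle.
#'
#' @param y0 Starting template copies (>= 1; vectorized).
#' @param cfg A [sim_config()].
#' @return Real-valued onset cycle(s). Templates already at or above the
#'   threshold return 0 with a warning.
#' @export
onset_cycle <- function(y0, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(!is.finite(y0)) || any(y0 < 1))
    stop_peakfluo("y0 must be finite and >= 1")
  thr <- cfg$detection_threshold_copies
  if (any(y0 >= thr)) {
    warning("template already at detection threshold; onset set to 0")
  }
  pmax(0, log(thr / y0) / log1p(cfg$efficiency_E))
}

# Smoothed four-phase ramp on [0, 1]: softplus difference whose early tail
# grows by exactly (1+E) per cycle and whose mid-section is linear over
# `ramp` cycles. `x` is cycle minus onset.
amp_ramp <- function(x, E, ramp) {
  k <- 1 / log1p(E)
  sp <- function(z) {
    # overflow-safe softplus: k*log(1+exp(z/k))
    zk <- z / k
    k * ifelse(zk > 35, zk, log1p(exp(pmin(zk, 35))))
  }
  (sp(x) - sp(x - ramp)) / ramp
}

# Noise-free expected fluorescence at (possibly fractional) cycles `cyc` for
# onset cycle `c_on`.
expected_fluorescence <- function(cyc, c_on, cfg) {
  amp <- cfg$plateau_level - cfg$baseline_level
  cfg$baseline_level + cfg$baseline_drift * cyc +
    amp * amp_ramp(cyc - c_on, cfg$efficiency_E, cfg$ramp_cycles)
}

#' Construct a fluorescence trace
#'
#' @param well_id Well identifier.
#' @param fluorescence Numeric fluorescence vector, one value per cycle.
#' @param cycles 1-based contiguous integer cycle vector.
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(well_id, fluorescence,
                               cycles = seq_along(fluorescence)) {
  cycles <- as.integer(cycles)
  if (length(cycles) != length(fluorescence))
    stop_peakfluo("cycles and fluorescence must have equal length")
  if (length(cycles) == 0L || cycles[1] != 1L ||
      any(diff(cycles) != 1L))
    stop_peakfluo("cycles must be contiguous integers starting at 1")
  if (any(!is.finite(fluorescence)))
    stop_peakfluo("fluorescence must be finite")
  structure(list(well_id = as.character(well_id), cycles = cycles,
                 fluorescence = as.numeric(fluorescence)),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace> well %s, %d cycles, range [%.4g, %.4g]\n",
              x$well_id, length(x$cycles), min(x$fluorescence),
              max(x$fluorescence)))
  invisible(x)
}

#' Simulate one amplification trace
#'
#' Composes the four-phase curve for the given concentration with the shared
#' process-noise realization and independent per-well reader noise. All wells
#' of a plate share `process_noise` and the plateau level.
#'
#' @param conc Concentration in ng/mL.
#' @param cfg A [sim_config()].
#' @param process_noise Numeric vector of length `n_cycles`, the shared
#'   process component for this plate (use zeros for a noise-free well).
#' @param well_id Identifier for the returned trace.
#' @return A [fluorescence_trace()]. Consumes RNG draws for the per-well
#'   noise unless `noise_sd_well` is 0; seed control belongs to the caller
#'   (see [simulate_plate()]).
#' @export
simulate_trace <- function(conc, cfg, process_noise = numeric(cfg$n_cycles),
                           well_id = "well") {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(process_noise) != cfg$n_cycles)
    stop_peakfluo("process_noise must have length n_cycles (%d)", cfg$n_cycles)
  cyc <- seq_len(cfg$n_cycles)
  c_on <- onset_cycle(concentration_to_y0(conc, cfg), cfg)
  f <- expected_fluorescence(cyc, c_on, cfg) + process_noise
  if (cfg$noise_sd_well > 0)
    f <- f + stats::rnorm(cfg$n_cycles, 0, cfg$noise_sd_well)
  fluorescence_trace(well_id, f, cyc)
}

#' Simulate a plate
#'
#' One trace per design well. The shared process noise is a single Gaussian
#' random walk per plate (step sd `noise_sd_process`) added to every well;
#' replicate wells then differ only by per-well reader noise. Deterministic
#' under a fixed `cfg$seed`.
#'
#' @param design A [plate_design()] whose concentrations are all known.
#' @param cfg A [sim_config()].
#' @return A named list of [fluorescence_trace()] objects (class
#'   `fluorescence_plate`) with the design attached as attribute `design`.
#' @export
simulate_plate <- function(design, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_plate_design(design)
  if (!any(design$role == "control"))
    stop_peakfluo("design must contain a negative-control group (required for control subtraction)")
  if (any(is.na(design$concentration)))
    stop_peakfluo("all design concentrations must be known to the simulator")
  traces <- with_seed(cfg$seed, {
    pn <- if (cfg$noise_sd_process > 0)
      cumsum(stats::rnorm(cfg$n_cycles, 0, cfg$noise_sd_process))
    else numeric(cfg$n_cycles)
    lapply(seq_len(nrow(design)), function(i)
      simulate_trace(design$concentration[i], cfg, pn, design$well_id[i]))
  })
  names(traces) <- design$well_id
  structure(traces, class = "fluorescence_plate", design = design)
}
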