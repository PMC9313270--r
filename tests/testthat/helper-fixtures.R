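# Shared fixtures: all plates are generated in code at test time.

cfg_noisefree <- function(...) {
  sim_config(noise_sd_well = 0, noise_sd_process = 0, ...)
}

# canonical triplicate panel: control + standards {0.1, 1, 10} ng/mL
panel <- function(unknowns = numeric(0), replicates = 3L) {
  panel_design(unknowns = unknowns, replicates = replicates)
}

# a pure 4-parameter logistic trace
logistic_trace <- function(F_b = 1, F_max = 10, c_half = 20, k = 2,
                           n_cycles = 40, noise_sd = 0, well_id = "lg") {
  cyc <- seq_len(n_cycles)
  f <- F_b + F_max / (1 + exp(-(cyc - c_half) / k))
  if (noise_sd > 0) f <- f + stats::rnorm(n_cycles, 0, noise_sd)
  fluorescence_trace(well_id, f, cyc)
}

# brute-force peak oracle: plain argmin over the full cleaned signal,
# independent of the streaming implementation
brute_peak <- function(cleaned) {
  i <- which.min(cleaned$cleaned)
  list(peak_magnitude = abs(cleaned$cleaned[i]),
       peak_cycle = cleaned$cycles[i])
}

# fractional cycle at which a trace first crosses `level`
crossing_cycle <- function(trace, level) {
  f <- trace$fluorescence
  i <- which(f >= level)[1]
  if (is.na(i) || i == 1L) return(NA_real_)
  trace$cycles[i - 1L] + (level - f[i - 1L]) / (f[i] - f[i - 1L])
}
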