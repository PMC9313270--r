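test_that("estimate_background matches window statistics", {
  tr <- fluorescence_trace("w", rep(7, 20))
  expect_equal(estimate_background(tr), 7)
  tr2 <- fluorescence_trace("w", c(1:10, rep(0, 10)))
  expect_equal(estimate_background(tr2, 1:10, "mean"), 5.5)
  expect_equal(estimate_background(tr2, 1:10, "max"), 10)
  expect_error(estimate_background(tr2, 15:25), "window")
  # on a noise-free simulated trace with onset far past the window, the
  # background equals the pre-onset segment baseline + drift * mean(window)
  cfg <- cfg_noisefree(efficiency_E = 1, y0_control = 2,
                       detection_threshold_copies = 1e12)
  sim <- simulate_trace(0, cfg, numeric(cfg$n_cycles))
  expect_equal(estimate_background(sim, 1:10, "mean"),
               cfg$baseline_level + cfg$baseline_drift * mean(1:10),
               tolerance = 1e-6)
})

test_that("clean_trace subtracts background and the control", {
  cfg <- cfg_noisefree()
  plate <- simulate_plate(panel(replicates = 1L), cfg)
  ctrl <- plate$ctrl_r1
  # control cleaned against itself is identically zero
  cc <- clean_trace(ctrl, ctrl)
  expect_equal(cc$cleaned, rep(0, length(cc$cycles)))
  expect_identical(cc$cycles, 11:40)
  # two identical traces with equal backgrounds give zero
  expect_equal(clean_trace(plate$std2_r1, plate$std2_r1)$cleaned,
               rep(0, 30))
  # sample cleaned trace: ~0 early, dips negative, returns toward 0 at the
  # common plateau
  cs <- clean_trace(plate$std3_r1, ctrl)
  expect_true(abs(cs$cleaned[1]) < 0.05 * abs(min(cs$cleaned)))
  expect_true(min(cs$cleaned) < -500)
  expect_true(all(cs$cleaned < 25))
  expect_true(abs(cs$cleaned[length(cs$cleaned)]) <
                abs(min(cs$cleaned)) * 0.1)
  short <- fluorescence_trace("s", rep(1, 20))
  expect_error(clean_trace(short, ctrl), "grid")
})

test_that("find_peak streams the hand-traceable example", {
  cl <- structure(list(well_id = "w", cycles = 11:18,
                       cleaned = c(0, 0, -1, -3, -5, -4, -2, 0)),
                  class = "cleaned_trace")
  pk <- find_peak(cl, persistence = 2)
  expect_equal(pk$peak_magnitude, 5)
  expect_equal(pk$peak_cycle, 15L)
  expect_equal(pk$stop_cycle, 17L)
  expect_true(pk$found)
  # monotone nonincreasing: runs to the end, peak at the last cycle
  cl2 <- structure(list(well_id = "w", cycles = 11:20,
                        cleaned = -(1:10)), class = "cleaned_trace")
  pk2 <- find_peak(cl2, persistence = 2)
  expect_false(pk2$found)
  expect_equal(pk2$peak_cycle, 20L)
  expect_equal(pk2$stop_cycle, 20L)
  # ties keep the first occurrence
  cl3 <- structure(list(well_id = "w", cycles = 11:18,
                        cleaned = c(0, -2, -2, -2, 1, 1, 1, 1)),
                   class = "cleaned_trace")
  expect_equal(find_peak(cl3, persistence = 3)$peak_cycle, 12L)
  expect_error(find_peak(cl3, persistence = 0), "positive integer")
})

test_that("streamed peak equals the brute-force oracle on noise-free wells", {
  cfg <- cfg_noisefree()
  plate <- simulate_plate(panel(unknowns = c(0.3, 3)), cfg)
  ctrl <- average_replicates(plate[c("ctrl_r1", "ctrl_r2", "ctrl_r3")])
  for (w in setdiff(names(plate), c("ctrl_r1", "ctrl_r2", "ctrl_r3"))) {
    cl <- clean_trace(plate[[w]], ctrl)
    pk <- find_peak(cl, persistence = 3)
    or <- brute_peak(cl)
    expect_equal(pk$peak_magnitude, or$peak_magnitude)
    expect_equal(pk$peak_cycle, or$peak_cycle)
  }
})

test_that("average_replicates reduces per-well noise as sqrt(n)", {
  t1 <- fluorescence_trace("a", sin(1:30))
  expect_equal(average_replicates(list(t1))$fluorescence, t1$fluorescence)
  t2 <- fluorescence_trace("b", -sin(1:30))
  expect_equal(average_replicates(list(t1, t2))$fluorescence, rep(0, 30))
  expect_error(average_replicates(list()), "empty")
  # sampling property: residual sd of a triplicate mean ~ sigma / sqrt(3)
  cfg <- sim_config(noise_sd_process = 0, noise_sd_well = 5)
  resid <- unlist(lapply(1:40, function(s) {
    cfg$seed <- s
    plate <- simulate_plate(panel(replicates = 3L), cfg)
    avg <- average_replicates(plate[c("std2_r1", "std2_r2", "std2_r3")])
    mu <- simulate_trace(1, cfg_noisefree(), numeric(cfg$n_cycles))
    (avg$fluorescence - mu$fluorescence)[1:10]   # flat segment only
  }))
  expect_equal(sd(resid), 5 / sqrt(3), tolerance = 0.2)
})

test_that("validate_assay flags samples amplifying before the control", {
  cfg <- cfg_noisefree()
  plate <- simulate_plate(panel(replicates = 1L), cfg)
  ctrl <- plate$ctrl_r1
  cleaned <- lapply(plate[c("std1_r1", "std2_r1", "std3_r1")], clean_trace,
                    control_trace = ctrl)
  expect_true(validate_assay(cleaned, tolerance = 50))
  expect_true(validate_assay(list()))
  # adversarial plate: an "unknown" seeded with more template than the
  # control amplifies first; its cleaned signal is a positive bump
  hot <- simulate_trace(0, sim_config(noise_sd_well = 0,
                                      noise_sd_process = 0,
                                      y0_control = 8e4),
                        numeric(cfg$n_cycles), "hot")
  expect_false(validate_assay(list(clean_trace(hot, ctrl)), tolerance = 50))
})

test_that("fit_standard_curve reduces to the two-point slope and reports R2", {
  cv <- fit_standard_curve(c(0.1, 10), c(2, 6))
  expect_equal(cv$slope, 2)                      # per decade
  expect_true(is.na(cv$r_squared))
  expect_equal(cv$intercept + cv$slope * log10(0.1), 2)
  cv3 <- fit_standard_curve(c(0.1, 1, 10), c(2, 4, 6))
  expect_equal(cv3$r_squared, 1)
  expect_error(fit_standard_curve(c(1, 1), c(2, 3)), "distinct")
  expect_error(fit_standard_curve(c(0, 1), c(2, 3)), "positive")
})

test_that("quantify_sample inverts the calibration", {
  cv <- fit_standard_curve(c(0.1, 10), c(2, 6))
  # calibration identity
  expect_equal(quantify_sample(2, cv), 0.1, tolerance = 1e-9)
  expect_equal(quantify_sample(6, cv), 10, tolerance = 1e-9)
  # midway peak -> geometric mean of the two standards
  expect_equal(quantify_sample(4, cv), 1, tolerance = 1e-9)
  flat <- fit_standard_curve(c(0.1, 10), c(3, 3))
  expect_error(quantify_sample(3, flat), "flat")
  # strict pseudocode arithmetic on raw concentrations
  # m = (p1 - p2)/(c1 - c2) = (2-6)/(0.1-10); peak p2 maps to c1
  expect_equal(quantify_sample(6, cv, mode = "twopoint_raw"), 0.1)
  expect_equal(quantify_sample(2, cv, mode = "twopoint_raw"),
               (2 - 6) / ((2 - 6) / (0.1 - 10)) + 0.1)
})

test_that("run_peakfluo recovers unknowns on a noise-free panel", {
  cfg <- cfg_noisefree()
  design <- panel(unknowns = c(0.3, 3))
  res <- run_peakfluo(simulate_plate(design, cfg), design)
  expect_true(res$valid_assay)
  expect_true(res$curve$r_squared >= 0.99)
  err <- log10(res$samples$estimated_concentration) - log10(c(0.3, 3))
  expect_true(all(abs(err) <= 0.05))
  # control nullity and peak monotonicity in concentration
  g <- res$groups
  expect_equal(g$peak_magnitude[g$role == "control"], 0)
  std <- g[g$role != "control", ]
  std <- std[order(std$concentration), ]
  expect_true(all(diff(std$peak_magnitude) > 0))
  # early-stop economy: every amplifying well stops before the last cycle
  expect_true(all(g$stop_cycle[g$role != "control"] < cfg$n_cycles))
  expect_true(all(g$found[g$role != "control"]))
})

test_that("run_peakfluo flags an adversarial plate and degenerate input", {
  design <- panel(unknowns = 0.5)
  cfg <- cfg_noisefree()
  plate <- simulate_plate(design, cfg)
  # give the unknown more template than the control: it amplifies first
  hot_cfg <- sim_config(noise_sd_well = 0, noise_sd_process = 0,
                        y0_control = 8e4)
  for (w in c("unk1_r1", "unk1_r2", "unk1_r3"))
    plate[[w]] <- simulate_trace(0, hot_cfg, numeric(cfg$n_cycles), w)
  res <- run_peakfluo(plate, design)
  expect_false(res$valid_assay)
  expect_true(all(is.na(res$samples$estimated_concentration)))
  # pure-baseline plate: flat standard curve, quantification refuses
  flat <- lapply(plate, function(tr)
    fluorescence_trace(tr$well_id, rep(100, cfg$n_cycles)))
  expect_error(run_peakfluo(flat, design), "flat")
})

test_that("replicate averaging happens before cleaning in the pipeline", {
  cfg <- sim_config(seed = 5L)
  design <- panel()
  plate <- simulate_plate(design, cfg)
  res <- run_peakfluo(plate, design)
  ctrl <- average_replicates(plate[c("ctrl_r1", "ctrl_r2", "ctrl_r3")],
                             well_id = "ctrl")
  avg <- average_replicates(plate[c("std3_r1", "std3_r2", "std3_r3")],
                            well_id = "std3")
  pk <- find_peak(clean_trace(avg, ctrl), persistence = 3)
  expect_equal(res$groups$peak_magnitude[res$groups$replicate_group == "std3"],
               pk$peak_magnitude)
  expect_equal(nrow(res$replicate_peaks), 12L)
})
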