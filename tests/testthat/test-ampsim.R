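test_that("concentration_to_y0 follows the displacement hyperbola", {
  cfg <- sim_config(displacement_Kd = 1)
  expect_identical(concentration_to_y0(0, cfg), cfg$y0_control)
  expect_equal(concentration_to_y0(1, cfg), cfg$y0_control / 2)
  # grid ratios from the closed form with Kd = 1
  expect_equal(concentration_to_y0(c(0.1, 1, 10), cfg) / cfg$y0_control,
               c(1 / 1.1, 1 / 2, 1 / 11))
  # strictly decreasing in concentration
  y <- concentration_to_y0(seq(0, 20, by = 0.5), cfg)
  expect_true(all(diff(y) < 0))
  expect_error(concentration_to_y0(-1, cfg), "0")
})

test_that("onset_cycle inverts the exponential growth law", {
  cfg <- sim_config(efficiency_E = 1, detection_threshold_copies = 102400,
                    y0_control = 100)
  expect_equal(onset_cycle(100, cfg), 10)          # 100 * 2^10 = 102400
  expect_warning(o <- onset_cycle(102400, cfg), "threshold")
  expect_equal(o, 0)
  # doubling law: halving y0 delays onset by exactly one cycle at E = 1
  for (y0 in c(2, 64, 1000, 9999)) {
    expect_equal(onset_cycle(y0 / 2, cfg) - onset_cycle(y0, cfg), 1,
                 tolerance = 1e-9)
  }
  expect_error(onset_cycle(0.5, cfg), ">= 1")
})

test_that("simulate_trace reproduces the four phases", {
  cfg <- cfg_noisefree(baseline_drift = 0)
  tr <- simulate_trace(1, cfg, numeric(cfg$n_cycles))
  amp <- cfg$plateau_level - cfg$baseline_level
  # background phase: within 1% of the amplitude of the baseline
  expect_true(all(abs(tr$fluorescence[1:8] - cfg$baseline_level) <
                    0.01 * amp))
  # plateau: late cycles of an early-onset well approach plateau_level
  cfg2 <- cfg_noisefree(baseline_drift = 0, y0_control = 1e6,
                        ramp_cycles = 8)
  tr2 <- simulate_trace(0, cfg2, numeric(cfg2$n_cycles))
  expect_true(abs(tr2$fluorescence[cfg2$n_cycles] - cfg2$plateau_level) <
                0.02 * amp)
  expect_error(simulate_trace(1, cfg, numeric(3)), "length")
})

test_that("higher concentration crosses half-plateau strictly later", {
  cfg <- cfg_noisefree()
  half <- (cfg$baseline_level + cfg$plateau_level) / 2
  concs <- c(0, 0.1, 0.3, 1, 3, 10)
  cross <- vapply(concs, function(cc)
    crossing_cycle(simulate_trace(cc, cfg, numeric(cfg$n_cycles)), half),
    numeric(1))
  expect_true(all(diff(cross) > 0))
})

test_that("noise-free control crosses any threshold before every sample", {
  cfg <- cfg_noisefree()
  ctrl <- simulate_trace(0, cfg, numeric(cfg$n_cycles))
  for (level in c(150, 400, 800, 1050)) {
    c0 <- crossing_cycle(ctrl, level)
    for (cc in c(0.1, 1, 10)) {
      cs <- crossing_cycle(simulate_trace(cc, cfg, numeric(cfg$n_cycles)),
                           level)
      expect_true(c0 < cs)
    }
  }
})

test_that("simulate_plate is seed-reproducible and replicate-consistent", {
  cfg <- sim_config(seed = 11L)
  design <- panel()
  p1 <- simulate_plate(design, cfg)
  p2 <- simulate_plate(design, cfg)
  expect_identical(p1, p2)
  expect_length(p1, 12L)                      # 4 groups x 3 replicates
  # noise-free replicates are identical
  p0 <- simulate_plate(design, cfg_noisefree())
  expect_identical(p0$std1_r1$fluorescence, p0$std1_r2$fluorescence)
  # replicate wells differ only by per-well noise: with process+well noise,
  # subtracting the shared expected curve leaves iid-looking residuals, and
  # two replicates share their process component
  d_rep <- p1$std2_r1$fluorescence - p1$std2_r2$fluorescence
  expect_true(sd(d_rep) < 3 * cfg$noise_sd_well)
  # control has the earliest half-plateau crossing
  half <- (cfg$baseline_level + cfg$plateau_level) / 2
  cross <- vapply(p0, crossing_cycle, numeric(1), level = half)
  expect_true(all(cross[["ctrl_r1"]] < cross[setdiff(names(cross), c("ctrl_r1", "ctrl_r2", "ctrl_r3"))]))
})

test_that("plate design invariants are enforced", {
  expect_error(plate_design("w1", "control", 1, "g"), "concentration 0")
  expect_error(plate_design(c("w1", "w1"), c("control", "control"),
                            c(0, 0), c("g", "g")), "unique")
  expect_error(plate_design(c("a", "b"), c("control", "control"), c(0, 0),
                            c("g1", "g2")), "exactly one control")
  expect_error(plate_design(c("a", "b"), c("control", "standard"), c(0, -1),
                            c("g1", "g2")), "positive")
  expect_error(plate_design(c("a", "b", "c"),
                            c("control", "standard", "standard"),
                            c(0, 1, 1), c("g1", "g2", "g3")), "distinct")
  expect_error(simulate_plate(plate_design("a", "standard", 1, "g1"),
                              sim_config()), "control")
  d <- panel(unknowns = 0.5)
  d$concentration[d$role == "unknown"] <- NA
  expect_error(simulate_plate(d, sim_config()), "known")
})

test_that("sim_config rejects invalid parameter combinations", {
  expect_error(sim_config(efficiency_E = 0), "0, 1")
  expect_error(sim_config(efficiency_E = 1.2), "0, 1")
  expect_error(sim_config(plateau_level = 50), "exceed")
  expect_error(sim_config(noise_sd_well = -1), ">= 0")
  expect_error(sim_config(displacement_Kd = 0), "> 0")
  expect_error(sim_config(y0_control = 0.5), ">= 1")
  expect_error(sim_config(detection_threshold_copies = 10), "exceed")
})
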