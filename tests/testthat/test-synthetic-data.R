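# Generators: determinism, truncation, forward-model exactness, and the
# directional/ordering structure the downstream stages rely on.

test_that("generators are deterministic given a seed", {
  p <- population_params(n_cells = 25)
  expect_identical(sim_cell_population(p, seed = 7),
                   sim_cell_population(p, seed = 7))
  cells <- sim_cell_population(p, seed = 7)
  expect_identical(sim_calibration_traces(cells, seed = 3),
                   sim_calibration_traces(cells, seed = 3))
  expect_identical(sim_stimulation_traces(cells, seed = 3),
                   sim_stimulation_traces(cells, seed = 3))
  expect_identical(sim_fura_traces(cells[1:5, ], seed = 3),
                   sim_fura_traces(cells[1:5, ], seed = 3))
  expect_identical(sim_drinking_sessions(seed = 3),
                   sim_drinking_sessions(seed = 3))
  # different seeds actually differ
  expect_false(identical(sim_cell_population(p, seed = 7),
                         sim_cell_population(p, seed = 8)))
})

test_that("population sampling respects truncation and hits the target mean", {
  p <- population_params(n_cells = 10000)
  cells <- sim_cell_population(p, seed = 11)
  expect_true(all(cells$cl_i_mM >= p$lower_trunc))
  expect_true(all(cells$cl_i_mM <= p$upper_trunc))
  expect_true(all(cells$ksv_per_M > 0))
  # delivered (truncated) mean matches the configured 34.1 mM within 1%
  expect_lt(abs(mean(cells$cl_i_mM) / 34.1 - 1), 0.01)
  # degenerate scale collapses to a point mass
  cells0 <- sim_cell_population(population_params(sd_cl = 0, n_cells = 10),
                                seed = 1)
  expect_true(all(cells0$cl_i_mM == 34.1))
  # infeasible truncation is a configuration error
  expect_error(population_params(lower_trunc = 50, upper_trunc = 10),
               class = "clquant_config_error")
})

test_that("noiseless calibration plateaus equal the quenching forward model", {
  cells <- toy_cells()[1, ]
  sim <- sim_calibration_traces(cells, kinetics = noiseless(), seed = 1)
  pl <- detect_steady_states(sim$traces, sim$protocol)
  # hand-computed F0/(1 + Ksv C): 100, 77.64, 63.45, 53.65
  expected <- c(100, 77.6398, 63.4518, 53.6481)
  expect_equal(pl$plateau, expected, tolerance = 1e-3)
  # a 0 mM step is required
  expect_error(sim_calibration_traces(cells, conc_steps = c(20, 40)),
               class = "clquant_config_error")
})

test_that("stimulation traces move each cell toward equilibrium with the right sign", {
  cells <- toy_cells()
  sim <- sim_stimulation_traces(cells, kinetics = noiseless(), seed = 1)
  stim_window <- c(5, 35)
  calls <- classify_cells(sim$traces, stim_window)
  # cell above critical: efflux (fluorescence rises); below: influx
  expect_identical(calls$direction[calls$cell_id == "cell_a"], "efflux")
  expect_identical(calls$direction[calls$cell_id == "cell_b"], "influx")
  # cell exactly at equilibrium stays flat
  trc <- dplyr::filter(sim$traces, cell_id == "cell_c")
  expect_lt(diff(range(trc$fluorescence)) / mean(trc$fluorescence), 1e-9)
  expect_identical(calls$direction[calls$cell_id == "cell_c"], "none")
})

test_that("directional consistency holds across a noiseless population", {
  cells <- sim_cell_population(population_params(n_cells = 60), seed = 5)
  sim <- sim_stimulation_traces(cells, kinetics = noiseless(), seed = 5)
  calls <- classify_cells(sim$traces, c(5, 35))
  joined <- dplyr::left_join(calls, sim$truth, by = "cell_id")
  expect_identical(joined$direction, joined$true_direction)
})

test_that("lowering external chloride increases the mean efflux response", {
  cells <- sim_cell_population(population_params(n_cells = 40), seed = 9)
  hi <- sim_stimulation_traces(cells, ctx = equilibrium_context(cl_out_mM = 148),
                               kinetics = noiseless(), seed = 9)
  lo <- sim_stimulation_traces(cells, ctx = equilibrium_context(cl_out_mM = 6),
                               kinetics = noiseless(), seed = 9)
  amp_hi <- classify_cells(hi$traces, c(5, 35))$amplitude_pct
  amp_lo <- classify_cells(lo$traces, c(5, 35))$amplitude_pct
  expect_gt(mean(amp_lo), mean(amp_hi))
})

test_that("fura traces have guarded denominators and truth-scaled amplitudes", {
  cells <- toy_cells()
  sim <- sim_fura_traces(cells, seed = 2)
  f380 <- dplyr::filter(sim$traces, channel == "fura380")
  expect_true(all(f380$fluorescence > 0))
  # zero base amplitude gives a flat ratio
  flat <- sim_fura_traces(cells, amp_params = fura_params(amplitude = 0,
                                                          noise_sd = 0),
                          seed = 2)
  amps <- fura_amplitudes(flat$traces, stim_window = c(15, 20))
  expect_equal(amps$amplitude, rep(0, 3), tolerance = 1e-12)
  # noiseless measured amplitudes match stored ground truth
  clean <- sim_fura_traces(cells, amp_params = fura_params(noise_sd = 0),
                           seed = 2)
  amps <- fura_amplitudes(clean$traces, stim_window = c(15, 20))
  expect_equal(amps$amplitude, clean$truth$true_amplitude, tolerance = 0.02)
})

test_that("low-chloride populations produce smaller calcium transients", {
  wt <- sim_cell_population(population_params(n_cells = 150), seed = 21)
  ko <- sim_cell_population(ko_population_params(n_cells = 150), seed = 22)
  awt <- fura_amplitudes(sim_fura_traces(wt, seed = 21)$traces, c(15, 20))
  ako <- fura_amplitudes(sim_fura_traces(ko, seed = 22)$traces, c(15, 20))
  ratio <- mean(ako$amplitude) / mean(awt$amplitude)
  # generator default amplification is calibrated to about 0.615
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 0.75)
})

test_that("dose-response curves carry their generating truth", {
  exact <- sim_dose_response(noise_cv = 0)
  truth <- attr(exact, "truth")
  expect_equal(truth$ec50, 24.7)
  # the exact curve evaluates the Hill equation
  expect_equal(exact$response,
               1 / (1 + (24.7 / exact$concentration_uM)^2.1))
  # noisy draws are seeded
  a <- sim_dose_response(noise_cv = 0.05, seed = 9)
  expect_identical(a, sim_dose_response(noise_cv = 0.05, seed = 9))
  expect_false(identical(a$response, exact$response))
  expect_error(sim_dose_response(concentrations = c(0, 1)),
               class = "clquant_config_error")
})

test_that("drinking sessions follow the avoidance curve in expectation", {
  p <- behavior_params(intake_noise_cv = 0)
  dw <- sim_drinking_sessions(p, seed = 1)
  s <- exposure_intake_ratio(dw$sessions)
  # water controls sit at the baseline ratio
  expect_equal(unique(s$eir[s$concentration_uM == 0]), p$baseline_eir,
               tolerance = 1e-12)
  # the half-maximum falls at the configured EC50
  dw2 <- sim_drinking_sessions(p, concentrations = c(p$ec50), seed = 1)
  s2 <- exposure_intake_ratio(dw2$sessions)
  expect_equal(unique(s2$eir[s2$concentration_uM == p$ec50]),
               p$baseline_eir / 2, tolerance = 1e-12)
  # noiseless mean EIR is non-increasing in concentration
  means <- s |>
    dplyr::filter(concentration_uM > 0) |>
    dplyr::group_by(concentration_uM) |>
    dplyr::summarise(m = mean(eir), .groups = "drop") |>
    dplyr::arrange(concentration_uM)
  expect_true(all(diff(means$m) <= 1e-12))
})
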