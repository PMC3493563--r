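# Stern-Volmer calibration: exact inversion, round trips, flags, and
# recovery from noisy synthetic populations.

test_that("the exact forward-model points invert to Ksv 14.4 with r2 = 1", {
  pts <- tibble::tibble(cl_mM = c(0, 20, 40, 60),
                        plateau = c(100, 77.6398, 63.4518, 53.6481))
  fit <- fit_stern_volmer(pts)
  expect_equal(fit$ksv_per_M, 14.4, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  expect_false(fit$nonphysical)
})

test_that("degenerate and invalid calibration inputs are handled", {
  flat <- tibble::tibble(cl_mM = c(0, 20, 40), plateau = c(90, 90, 90))
  fit <- fit_stern_volmer(flat)
  expect_equal(fit$ksv_per_M, 0)
  expect_true(fit$nonphysical)
  expect_error(fit_stern_volmer(tibble::tibble(cl_mM = c(20, 40),
                                               plateau = c(70, 60))),
               class = "clquant_calibration_error")
  expect_error(fit_stern_volmer(tibble::tibble(cl_mM = c(0, 0),
                                               plateau = c(100, 101))),
               class = "clquant_calibration_error")
})

test_that("estimate_cl inverts the quenching relation and clamps negatives", {
  fit <- tibble::tibble(cell_id = c("a", "b", "c"), f0 = 100,
                        ksv_per_M = 14.4, r_squared = 1, n_points = 4)
  est <- estimate_cl(c(100, 67.07, 101), fit)
  expect_equal(est$cl_i_mM[1], 0, tolerance = 1e-12)
  expect_equal(est$cl_i_mM[2], 34.1, tolerance = 1e-2)
  expect_equal(est$cl_i_mM[3], 0)
  expect_identical(est$flag, c("ok", "ok", "clamped"))
  expect_error(estimate_cl(-1, fit[1, ]), class = "clquant_data_error")
  badfit <- dplyr::mutate(fit[1, ], ksv_per_M = -2)
  expect_error(estimate_cl(80, badfit), class = "clquant_calibration_error")
})

test_that("the quenching quotient at 34.1 mM with Ksv 14.4 is 0.491", {
  # unit consistency: concentrations converted from mM exactly once
  expect_equal(14.4 * 34.1 / 1000, 0.491, tolerance = 1e-3)
  f_rest <- 100 / (1 + 14.4 * 34.1 / 1000)
  fit <- tibble::tibble(cell_id = "a", f0 = 100, ksv_per_M = 14.4,
                        r_squared = 1, n_points = 4)
  expect_equal(estimate_cl(f_rest, fit)$cl_i_mM, 34.1, tolerance = 1e-9)
})

test_that("noiseless synthetic cells round-trip through the calibration stage", {
  cells <- sim_cell_population(population_params(n_cells = 30), seed = 4)
  sim <- sim_calibration_traces(cells, kinetics = noiseless(), seed = 4)
  res <- calibrate_cells(sim$traces, sim$protocol)
  joined <- dplyr::left_join(res$fits, cells, by = "cell_id")
  expect_lt(max(abs(joined$ksv_per_M.x / joined$ksv_per_M.y - 1)), 1e-6)
  est <- dplyr::left_join(res$estimates, cells, by = "cell_id")
  expect_lt(max(abs(est$cl_i_mM.x / est$cl_i_mM.y - 1)), 1e-6)
})

test_that("estimated chloride is strictly decreasing in resting fluorescence", {
  fit <- tibble::tibble(cell_id = "a", f0 = 100, ksv_per_M = 14.4,
                        r_squared = 1, n_points = 4)
  f_grid <- seq(40, 99, by = 1)
  ests <- vapply(f_grid, function(f) estimate_cl(f, fit)$cl_i_mM, numeric(1))
  expect_true(all(diff(ests) < 0))
})

test_that("noisy populations are recovered with small bias", {
  cells <- sim_cell_population(population_params(n_cells = 250), seed = 12)
  sim <- sim_calibration_traces(cells, seed = 12)  # default 1% frame noise
  res <- calibrate_cells(sim$traces, sim$protocol)
  joined <- dplyr::left_join(res$fits, cells, by = "cell_id")
  expect_lt(abs(mean(joined$ksv_per_M.x) / mean(joined$ksv_per_M.y) - 1), 0.02)
  est <- dplyr::left_join(res$estimates, cells, by = "cell_id")
  expect_lt(abs(mean(est$cl_i_mM.x) / mean(est$cl_i_mM.y) - 1), 0.02)
})

test_that("population summaries report mean, SEM and exclusion counts", {
  one <- tibble::tibble(cell_id = "a", f_rest = 90, cl_i_mM = 10, flag = "ok")
  s <- summarize_population(one)
  expect_equal(s$mean_cl_mM, 10)
  expect_equal(s$sem_cl_mM, 0)
  expect_equal(s$n, 1L)
  mix <- tibble::tibble(cell_id = c("a", "b", "c", "d"),
                        f_rest = 1, cl_i_mM = c(10, 20, 0, 5),
                        flag = c("ok", "ok", "clamped", "low_r2"))
  s2 <- summarize_population(mix)
  expect_equal(s2$n, 2L)
  expect_equal(s2$mean_cl_mM, 15)
  expect_equal(s2$sem_cl_mM, sd(c(10, 20)) / sqrt(2))
  expect_equal(s2$n_clamped, 1L)
  expect_equal(s2$n_low_r2, 1L)
  empty <- dplyr::mutate(one, flag = "clamped")
  expect_error(summarize_population(empty),
               class = "clquant_empty_population_error")
})

test_that("steady-state detection flags steps that are still settling", {
  cells <- toy_cells()[1, ]
  slow <- sim_calibration_traces(cells,
                                 kinetics = kinetics_params(rate_constant = 1e-3,
                                                            noise_sd = 0),
                                 seed = 1)
  pl <- detect_steady_states(slow$traces, slow$protocol)
  expect_true(any(pl$unsteady))
  fast <- sim_calibration_traces(cells, kinetics = noiseless(), seed = 1)
  pl2 <- detect_steady_states(fast$traces, fast$protocol)
  expect_false(any(pl2$unsteady))
  # window outside the trace is a protocol error
  bad_proto <- dplyr::mutate(fast$protocol,
                             end_s = ifelse(label == "cal_60mM", 1e6, end_s))
  expect_error(detect_steady_states(fast$traces, bad_proto),
               class = "clquant_protocol_error")
})

test_that("bleaching drift is measured and thresholded", {
  tr <- flat_trace(n = 80, dt = 15)
  chk <- bleaching_check(tr, window_s = 600)
  expect_equal(chk$drift_per_min, 0, tolerance = 1e-12)
  expect_true(chk$pass)
  # injected bleaching is recovered within 10%
  b <- 5e-4  # per frame, 15-s frames -> 0.2%/min
  cells <- toy_cells()[1, ]
  sim <- sim_calibration_traces(cells,
                                kinetics = kinetics_params(rate_constant = 0.5,
                                                           noise_sd = 0,
                                                           bleach_rate = b),
                                seed = 1)
  step1 <- dplyr::filter(sim$traces, time_s > 150, time_s <= 750)
  step1$time_s <- step1$time_s - 150
  chk2 <- bleaching_check(step1, window_s = 600)
  expected <- -b * 4  # 4 frames per minute
  expect_lt(abs(chk2$drift_per_min / expected - 1), 0.1)
  expect_error(bleaching_check(flat_trace(n = 2, dt = 15), window_s = 600),
               class = "clquant_data_error")
})
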