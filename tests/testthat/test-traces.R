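# Baseline statistics, relative change, k-sigma classification, ratio and
# amplitude extraction.

test_that("baseline statistics use the first 10 frames with sample SD", {
  tr <- flat_trace(n = 30, value = 100)
  bl <- baseline_stats(tr)
  expect_equal(bl$mean, 100)
  expect_equal(bl$sd, 0)
  alt <- tibble::tibble(time_s = 1:12,
                        fluorescence = c(rep(c(99, 101), 5), 500, 500))
  bl2 <- baseline_stats(alt)
  expect_equal(bl2$mean, 100)
  expect_equal(bl2$sd, sqrt(10 / 9), tolerance = 1e-9)  # = 1.054
  short <- flat_trace(n = 5)
  expect_error(baseline_stats(short), class = "clquant_data_error")
})

test_that("delta_f is the percent change relative to the baseline mean", {
  tr <- tibble::tibble(time_s = 1:12,
                       fluorescence = c(rep(100, 10), 100, 200))
  bl <- baseline_stats(tr)
  d <- delta_f(tr, bl)
  expect_equal(d$delta_f_pct[11], 0)
  expect_equal(d$delta_f_pct[12], 100)
  expect_error(delta_f(tr, tibble::tibble(mean = 0, sd = 1, n_frames = 10)),
               class = "clquant_data_error")
})

test_that("the 4-sigma rule assigns efflux/influx/none by signed extremum", {
  make_step <- function(step_sd) {
    noise <- rep(c(-1, 1), 15)  # baseline sd 1.017 around 100
    tibble::tibble(time_s = seq(0.5, 15, by = 0.5),
                   fluorescence = c(100 + noise[1:10],
                                    100 + noise[11:20] + step_sd * 1.0171,
                                    100 + noise[21:30]))
  }
  bl <- baseline_stats(make_step(0))
  up <- classify_response(make_step(6), bl, stim_window = c(5, 10), tail_s = 0)
  expect_identical(up$direction, "efflux")
  expect_gt(up$amplitude_pct, up$threshold_pct)
  down <- classify_response(make_step(-6), bl, stim_window = c(5, 10), tail_s = 0)
  expect_identical(down$direction, "influx")
  flat <- classify_response(make_step(0), bl, stim_window = c(5, 10), tail_s = 0)
  expect_identical(flat$direction, "none")
  # a perfectly flat noiseless trace is never a response (sd floor guards)
  tr <- flat_trace(n = 40)
  call <- classify_response(tr, baseline_stats(tr), stim_window = c(5, 15))
  expect_identical(call$direction, "none")
  expect_error(classify_response(tr, baseline_stats(tr),
                                 stim_window = c(100, 110)),
               class = "clquant_data_error")
})

test_that("classification is invariant under positive rescaling of the trace", {
  set.seed(42)
  base <- tibble::tibble(time_s = seq(0.5, 25, by = 0.5),
                         fluorescence = 100 + rnorm(50) +
                           c(rep(0, 20), rep(8, 10), rep(0, 20)))
  for (k in c(0.01, 1, 250)) {
    tr <- dplyr::mutate(base, fluorescence = fluorescence * k)
    bl <- baseline_stats(tr)
    call <- classify_response(tr, bl, stim_window = c(10, 15))
    ref <- classify_response(base, baseline_stats(base), stim_window = c(10, 15))
    expect_identical(call$direction, ref$direction)
    expect_equal(call$amplitude_pct, ref$amplitude_pct, tolerance = 1e-9)
  }
})

test_that("classification commutes with truncation outside the analysis windows", {
  set.seed(7)
  tr <- tibble::tibble(time_s = seq(0.5, 40, by = 0.5),
                       fluorescence = 100 + rnorm(80, sd = 0.5) +
                         c(rep(0, 30), rep(6, 20), rep(0, 30)))
  bl <- baseline_stats(tr)
  full <- classify_response(tr, bl, stim_window = c(15, 25), tail_s = 5)
  cut <- dplyr::filter(tr, time_s <= 31)  # drops frames after the tail
  same <- classify_response(cut, baseline_stats(cut), stim_window = c(15, 25),
                            tail_s = 5)
  expect_identical(full, same)
})

test_that("false-positive rate on flat noisy traces is consistent with the 4-sigma bound", {
  # the analytic Bonferroni bound holds for thresholds built from the true
  # noise SD, so the known baseline is supplied; the observed rate is
  # compared to bound + 3 binomial SEs
  set.seed(123)
  n_traces <- 10000
  n_window <- 40
  sigma <- 1
  bl <- tibble::tibble(mean = 100, sd = sigma, n_frames = 10)
  times <- seq(0.5, (10 + n_window) * 0.5, by = 0.5)
  hits <- vapply(seq_len(n_traces), function(i) {
    tr <- tibble::tibble(time_s = times,
                         fluorescence = 100 + rnorm(length(times), sd = sigma))
    call <- classify_response(tr, bl, stim_window = c(5.25, 25), tail_s = 0)
    call$direction != "none"
  }, logical(1))
  bound <- n_window * 2 * pnorm(-4)
  allowance <- 3 * sqrt(bound * (1 - bound) / n_traces)
  expect_lte(mean(hits), bound + allowance)
})

test_that("ratio traces divide aligned channels and guard the denominator", {
  t <- seq_len(20)
  f340 <- tibble::tibble(time_s = t, fluorescence = rep(50, 20), cell_id = "a")
  f380 <- tibble::tibble(time_s = t, fluorescence = rep(50, 20), cell_id = "a")
  r <- ratio_trace(f340, f380)
  expect_equal(r$ratio, rep(1, 20))
  r2 <- ratio_trace(dplyr::mutate(f340, fluorescence = fluorescence * 2), f380)
  expect_equal(r2$ratio, rep(2, 20))
  expect_error(ratio_trace(f340, dplyr::mutate(f380, time_s = time_s + 10)),
               class = "clquant_data_error")
  f380bad <- dplyr::mutate(f380, fluorescence = replace(fluorescence, 3, 0))
  expect_error(ratio_trace(f340, f380bad), class = "clquant_data_error")
})

test_that("ratio amplitude is peak minus baseline and shift-invariant", {
  r <- tibble::tibble(time_s = 1:30,
                      ratio = c(rep(0.8, 10), 0.8 + 0.4 * exp(-(1:20) / 6)))
  bl <- baseline_stats(r)
  amp <- response_amplitude(r, bl, stim_window = c(10, 20))
  expect_equal(amp, 0.4 * exp(-1 / 6), tolerance = 1e-9)
  shifted <- dplyr::mutate(r, ratio = ratio + 5)
  expect_equal(response_amplitude(shifted, baseline_stats(shifted), c(10, 20)),
               amp, tolerance = 1e-9)
  flat <- tibble::tibble(time_s = 1:30, ratio = rep(0.8, 30))
  expect_equal(response_amplitude(flat, baseline_stats(flat), c(10, 20)), 0)
})

test_that("viability filtering keeps cells with a KCl response", {
  responsive <- tibble::tibble(time_s = 1:40,
                               ratio = c(rep(0.8, 25), rep(1.4, 5), rep(0.8, 10)))
  silent <- tibble::tibble(time_s = 1:40, ratio = rep(0.8, 40))
  expect_true(viability_filter(responsive, kcl_window = c(25, 30),
                               min_amplitude = 0.2))
  expect_false(viability_filter(silent, kcl_window = c(25, 30),
                                min_amplitude = 0.2))
  expect_true(viability_filter(silent, kcl_window = c(25, 30),
                               min_amplitude = 0))
})
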