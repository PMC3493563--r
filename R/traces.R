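# Baseline statistics, relative fluorescence change, k-sigma response
# classification, and Fura-2 ratio / amplitude extraction.
#
# Sign convention (fixed here, used everywhere): MQAE fluorescence is
# quenched by chloride, so a fluorescence *increase* reports a *decrease* of
# intracellular chloride, i.e. efflux. Fura analyses never use direction
# labels.

#' Baseline statistics of a trace
#'
#' Mean and sample SD of the first `n_frames` frames (default 10, the
#' pre-stimulus baseline convention).
#'
#' @param trace Single-cell tibble with `time_s`, `fluorescence` (or a
#'   `ratio` column for ratio traces).
#' @param n_frames Number of leading frames.
#' @return One-row tibble: `mean`, `sd`, `n_frames`.
#' @export
#' @examples
#' tr <- tibble::tibble(time_s = 1:12, fluorescence = c(rep(100, 10), 150, 150))
#' baseline_stats(tr)
baseline_stats <- function(trace, n_frames = 10) {
  v <- trace_values(trace)
  if (length(v) < n_frames) {
    abort(sprintf("Trace has %d frames; baseline needs %d.", length(v), n_frames),
          class = "clquant_data_error")
  }
  v <- v[order(trace$time_s)][seq_len(n_frames)]
  tibble(mean = base::mean(v), sd = sd(v), n_frames = n_frames)
}

trace_values <- function(trace) {
  col <- intersect(c("fluorescence", "ratio"), names(trace))[1]
  if (is.na(col)) {
    abort("Trace needs a `fluorescence` or `ratio` column.",
          class = "clquant_data_error")
  }
  trace[[col]]
}

#' Relative fluorescence change
#'
#' \eqn{\Delta F_t = 100 (F_t - \bar F_{base}) / \bar F_{base}}, in percent
#' of the baseline mean.
#'
#' @param trace Single-cell tibble with `time_s`, `fluorescence`.
#' @param baseline Tibble from [baseline_stats()].
#' @return The input trace with a `delta_f_pct` column.
#' @export
delta_f <- function(trace, baseline) {
  if (baseline$mean <= 0) {
    abort("Baseline mean must be > 0 for a relative change.",
          class = "clquant_data_error")
  }
  mutate(trace, delta_f_pct = 100 * (trace_values(trace) - baseline$mean) /
           baseline$mean)
}

#' Classify a stimulus-evoked response (k-sigma rule)
#'
#' The response amplitude is the signed extremum of the relative change
#' \eqn{\Delta F} (percent of baseline) within the stimulus window plus a
#' post-stimulus tail. Only changes exceeding k times the baseline standard
#' deviation (default k = 4) count as responses; for MQAE, a positive
#' amplitude (fluorescence increase) is chloride efflux and a negative one
#' influx. A noiseless baseline is floored at 1e-6 of the baseline mean so
#' the threshold is defined.
#'
#' @param trace Single-cell tibble with `time_s`, `fluorescence`.
#' @param baseline Tibble from [baseline_stats()]. To test the thresholding
#'   rule against known noise, a baseline with known `mean` and `sd` may be
#'   supplied directly.
#' @param stim_window Numeric `c(start_s, end_s)` of the stimulus.
#' @param k Threshold multiplier.
#' @param tail_s Post-stimulus tail included in the search window (s).
#' @return One-row tibble: `direction` (`efflux`/`influx`/`none`),
#'   `amplitude_pct`, `threshold_pct`, `window_start_s`, `window_end_s`,
#'   `note`.
#' @export
classify_response <- function(trace, baseline, stim_window, k = 4,
                              tail_s = 10) {
  dfp <- delta_f(trace, baseline)
  win <- filter(dfp, .data$time_s >= stim_window[1],
                .data$time_s <= stim_window[2] + tail_s)
  if (nrow(win) == 0) {
    abort("Stimulus window contains no frames.", class = "clquant_data_error")
  }
  amp <- win$delta_f_pct[which.max(abs(win$delta_f_pct))]
  sd_floor <- max(baseline$sd, 1e-6 * baseline$mean)
  threshold <- k * 100 * sd_floor / baseline$mean
  direction <- if (amp > threshold) "efflux"
  else if (amp < -threshold) "influx"
  else "none"
  tibble(direction = direction, amplitude_pct = amp,
         threshold_pct = threshold,
         window_start_s = stim_window[1],
         window_end_s = stim_window[2] + tail_s,
         note = "MQAE: fluorescence increase = [Cl-]i decrease (efflux)")
}

#' Classify every cell of a stimulation dataset
#'
#' Maps [baseline_stats()] and [classify_response()] over the cells of a
#' long trace tibble.
#'
#' @param traces Long tibble (`time_s`, `cell_id`, `fluorescence`).
#' @param stim_window Numeric `c(start_s, end_s)`.
#' @param n_baseline Baseline frames per cell.
#' @param k,tail_s As in [classify_response()].
#' @return One row per cell with `cell_id` plus the [classify_response()]
#'   columns.
#' @export
classify_cells <- function(traces, stim_window, n_baseline = 10, k = 4,
                           tail_s = 10) {
  traces |>
    dplyr::group_split(.data$cell_id) |>
    purrr::map(function(d) {
      d <- arrange(d, .data$time_s)
      bl <- baseline_stats(d, n_frames = n_baseline)
      mutate(classify_response(d, bl, stim_window, k = k, tail_s = tail_s),
             cell_id = d$cell_id[1], .before = 1)
    }) |>
    bind_rows()
}

#' Fura-2 ratio trace
#'
#' Elementwise f340/f380 ratio of two aligned single-cell traces.
#'
#' @param f340,f380 Single-cell tibbles with `time_s`, `fluorescence`.
#' @return Tibble `time_s`, `ratio`, `cell_id`.
#' @export
ratio_trace <- function(f340, f380) {
  if (nrow(f340) != nrow(f380)) {
    abort("Channel traces have different frame counts.",
          class = "clquant_data_error")
  }
  f340 <- arrange(f340, .data$time_s)
  f380 <- arrange(f380, .data$time_s)
  dt <- stats::median(diff(f340$time_s))
  if (any(abs(f340$time_s - f380$time_s) > dt / 2)) {
    abort("Channel traces are misaligned in time.",
          class = "clquant_data_error")
  }
  if (any(f380$fluorescence <= 0)) {
    abort("380-nm channel contains non-positive values.",
          class = "clquant_data_error")
  }
  tibble(time_s = f340$time_s,
         ratio = f340$fluorescence / f380$fluorescence,
         cell_id = if ("cell_id" %in% names(f340)) f340$cell_id else NA_character_)
}

#' Ratio response amplitude
#'
#' Peak ratio within the stimulus window minus the baseline mean.
#'
#' @param ratio Tibble from [ratio_trace()].
#' @param baseline Tibble from [baseline_stats()] on the ratio trace.
#' @param stim_window Numeric `c(start_s, end_s)`.
#' @param tail_s Post-stimulus tail (s) included in the peak search.
#' @return Amplitude (dimensionless ratio units).
#' @export
response_amplitude <- function(ratio, baseline, stim_window, tail_s = 10) {
  win <- filter(ratio, .data$time_s >= stim_window[1],
                .data$time_s <= stim_window[2] + tail_s)
  if (nrow(win) == 0) {
    abort("Stimulus window contains no frames.", class = "clquant_data_error")
  }
  max(win$ratio) - baseline$mean
}

#' Viability filter by KCl depolarisation
#'
#' Neurons are verified by a depolarising high-potassium stimulus at the end
#' of a recording; cells without a calcium response to it are dropped.
#'
#' @param ratio Tibble from [ratio_trace()].
#' @param kcl_window Numeric `c(start_s, end_s)` of the KCl application.
#' @param min_amplitude Minimum ratio amplitude to keep the cell.
#' @param n_baseline Baseline frames.
#' @return Logical: keep (`TRUE`) or drop (`FALSE`).
#' @export
viability_filter <- function(ratio, kcl_window, min_amplitude,
                             n_baseline = 10) {
  bl <- baseline_stats(ratio, n_frames = n_baseline)
  response_amplitude(ratio, bl, kcl_window, tail_s = 0) >= min_amplitude
}

#' Per-cell Fura amplitudes of a dual-channel dataset
#'
#' Builds the ratio trace per cell and extracts the stimulus-evoked
#' amplitude.
#'
#' @param traces Long tibble with channels `fura340` and `fura380`.
#' @param stim_window Numeric `c(start_s, end_s)`.
#' @param n_baseline,tail_s As above.
#' @return Tibble `cell_id`, `amplitude`.
#' @export
fura_amplitudes <- function(traces, stim_window, n_baseline = 10,
                            tail_s = 10) {
  traces |>
    dplyr::group_split(.data$cell_id) |>
    purrr::map(function(d) {
      r <- ratio_trace(filter(d, .data$channel == "fura340"),
                       filter(d, .data$channel == "fura380"))
      bl <- baseline_stats(r, n_frames = n_baseline)
      tibble(cell_id = d$cell_id[1],
             amplitude = response_amplitude(r, bl, stim_window,
                                            tail_s = tail_s))
    }) |>
    bind_rows()
}
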