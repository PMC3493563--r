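# Per-cell Stern-Volmer calibration from double-ionophore steady states and
# conversion of resting fluorescence to intracellular chloride.

#' Detect per-step steady-state fluorescence
#'
#' For each cell and each calibration step, the plateau is the mean
#' fluorescence over the last `plateau_frac` of the frames in the step
#' window. A step is flagged unsteady when the fitted linear slope over that
#' tail (relative to the plateau, per frame) exceeds `slope_tol`; the flag is
#' advisory and does not exclude the step from downstream fits.
#'
#' @param traces Long trace tibble (`time_s`, `cell_id`, `fluorescence`).
#' @param protocol Protocol tibble with `label`, `start_s`, `end_s`, `cl_mM`;
#'   rows with `NA` `cl_mM` (e.g. a resting segment) are ignored.
#' @param plateau_frac Fraction of each step used for the plateau, from the
#'   end (default 0.2, i.e. the last 20 percent).
#' @param slope_tol Unsteadiness tolerance, relative units per frame
#'   (default 5e-4 = 0.05 percent per frame).
#' @return A tibble with `cell_id`, `cl_mM`, `plateau`, `slope_per_frame`,
#'   `unsteady`.
#' @export
detect_steady_states <- function(traces, protocol, plateau_frac = 0.2,
                                 slope_tol = 5e-4) {
  if (plateau_frac <= 0 || plateau_frac > 1) {
    abort("`plateau_frac` must be in (0, 1].", class = "clquant_config_error")
  }
  steps <- filter(protocol, !is.na(.data$cl_mM))
  if (nrow(steps) < 2) {
    abort("Fewer than 2 calibration steps in the protocol.",
          class = "clquant_calibration_error")
  }
  t_max <- max(traces$time_s)
  if (any(steps$end_s > t_max + 1e-9)) {
    abort("A calibration step window extends beyond the trace.",
          class = "clquant_protocol_error")
  }
  out <- purrr::pmap(steps, function(label, start_s, end_s, cl_mM, ...) {
    seg <- filter(traces, .data$time_s > start_s, .data$time_s <= end_s)
    if (nrow(seg) == 0) {
      abort(sprintf("No frames in calibration window '%s'.", label),
            class = "clquant_protocol_error")
    }
    # per cell: keep the last plateau_frac of frames, then a closed-form
    # least-squares slope of fluorescence against frame index over that tail
    seg |>
      arrange(.data$cell_id, .data$time_s) |>
      group_by(.data$cell_id) |>
      mutate(.rn = dplyr::row_number(),
             .keep_from = n() - max(2L, ceiling(plateau_frac * n())) + 1L) |>
      filter(.data$.rn >= .data$.keep_from) |>
      summarise(plateau = base::mean(.data$fluorescence),
                slope_per_frame = stats::cov(.data$.rn, .data$fluorescence) /
                  stats::var(.data$.rn) / plateau,
                .groups = "drop") |>
      mutate(cl_mM = cl_mM, unsteady = abs(.data$slope_per_frame) > slope_tol) |>
      select("cell_id", "cl_mM", "plateau", "slope_per_frame", "unsteady")
  })
  arrange(bind_rows(out), .data$cell_id, .data$cl_mM)
}

#' Fit the Stern-Volmer relation for one cell
#'
#' With \eqn{F_0} the measured fluorescence at 0 mM chloride, the quenching
#' relation \eqn{F_0 / F = 1 + K_{sv} C} is linear in the concentration C
#' (molar). The fit is a regression of \eqn{F_0/F - 1} on C through the
#' origin (the intercept is fixed by the measured F0), whose slope is Ksv in
#' per molar. The reported r-squared is the uncentred coefficient of
#' determination of that regression.
#'
#' @param points Tibble with columns `cl_mM` and a fluorescence column
#'   (`plateau` or `fluorescence`), one row per calibration concentration.
#'   Must contain a 0 mM point and at least 2 distinct concentrations.
#' @param cell_id Optional identifier carried into the result.
#' @return A one-row tibble: `cell_id`, `f0`, `ksv_per_M`, `r_squared`,
#'   `n_points`, `nonphysical` (TRUE when Ksv <= 0).
#' @export
#' @examples
#' pts <- tibble::tibble(cl_mM = c(0, 20, 40, 60),
#'                       plateau = 100 / (1 + 14.4 * c(0, 20, 40, 60) / 1000))
#' fit_stern_volmer(pts)
fit_stern_volmer <- function(points, cell_id = NA_character_) {
  fcol <- intersect(c("plateau", "fluorescence"), names(points))[1]
  if (is.na(fcol)) {
    abort("`points` needs a `plateau` or `fluorescence` column.",
          class = "clquant_calibration_error")
  }
  cl <- points$cl_mM
  f <- points[[fcol]]
  if (!any(cl == 0)) {
    abort("Stern-Volmer fit requires a 0 mM point to define F0.",
          class = "clquant_calibration_error")
  }
  if (length(unique(cl)) < 2) {
    abort("Stern-Volmer fit requires at least 2 distinct concentrations.",
          class = "clquant_calibration_error")
  }
  if (any(f <= 0)) {
    abort("Non-positive fluorescence in calibration points.",
          class = "clquant_data_error")
  }
  f0 <- base::mean(f[cl == 0])
  x <- cl / 1000           # molar
  y <- f0 / f - 1
  ksv <- sum(x * y) / sum(x^2)
  ss_res <- sum((y - ksv * x)^2)
  ss_tot <- sum(y^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  tibble(cell_id = cell_id, f0 = f0, ksv_per_M = ksv,
         r_squared = r2, n_points = length(cl),
         nonphysical = ksv <= 0)
}

#' Per-cell Stern-Volmer fits from detected plateaus
#'
#' Maps [fit_stern_volmer()] over the cells of a plateau table from
#' [detect_steady_states()].
#'
#' @param plateaus Tibble from [detect_steady_states()].
#' @return One row per cell, as in [fit_stern_volmer()].
#' @export
fit_stern_volmer_cells <- function(plateaus) {
  plateaus |>
    dplyr::group_split(.data$cell_id) |>
    purrr::map(function(d) fit_stern_volmer(d, cell_id = d$cell_id[1])) |>
    bind_rows() |>
    arrange(.data$cell_id)
}

#' Convert resting fluorescence to intracellular chloride
#'
#' Inverts the Stern-Volmer relation:
#' \eqn{[Cl^-]_i = (F_0/F_{rest} - 1) / K_{sv}}, reported in mM. Raw
#' negative estimates (resting fluorescence above F0, expected for noisy
#' cells near 0 mM) are clamped to 0 and flagged `clamped`; cells whose
#' calibration r-squared falls below `low_r2` are flagged `low_r2` and are
#' excluded from population summaries.
#'
#' @param f_rest Resting fluorescence (same units as the calibration
#'   trace); vectorised over cells when `fit` has matching rows.
#' @param fit Tibble of per-cell fits from [fit_stern_volmer_cells()] (or a
#'   single-row fit).
#' @param low_r2 Quality threshold on the calibration r-squared.
#' @return Tibble with `cell_id`, `f_rest`, `cl_i_mM`, `flag`
#'   (`ok`/`clamped`/`low_r2`).
#' @export
estimate_cl <- function(f_rest, fit, low_r2 = 0.9) {
  if (any(f_rest <= 0)) {
    abort("`f_rest` must be > 0.", class = "clquant_data_error")
  }
  if (any(fit$ksv_per_M <= 0)) {
    abort("Ksv must be > 0 to invert the quenching relation.",
          class = "clquant_calibration_error")
  }
  if (length(f_rest) != nrow(fit)) {
    abort("`f_rest` must have one value per fitted cell.",
          class = "clquant_data_error")
  }
  raw <- (fit$f0 / f_rest - 1) / fit$ksv_per_M * 1000
  flag <- dplyr::case_when(
    raw < 0 ~ "clamped",
    fit$r_squared < low_r2 ~ "low_r2",
    TRUE ~ "ok"
  )
  tibble(cell_id = fit$cell_id, f_rest = f_rest,
         cl_i_mM = pmax(raw, 0), flag = flag)
}

#' Population summary of chloride estimates
#'
#' Mean, SEM and n over estimates flagged `ok`; clamped and low-quality
#' cells are excluded and counted.
#'
#' @param estimates Tibble from [estimate_cl()].
#' @return One-row tibble: `mean_cl_mM`, `sem_cl_mM`, `n`, `n_clamped`,
#'   `n_low_r2`. SEM is reported as 0 when n = 1.
#' @export
summarize_population <- function(estimates) {
  ok <- filter(estimates, .data$flag == "ok")
  if (nrow(ok) == 0) {
    abort("No usable (ok-flagged) cells in the population.",
          class = "clquant_empty_population_error")
  }
  vals <- ok$cl_i_mM
  sem <- if (length(vals) > 1) sd(vals) / sqrt(length(vals)) else 0
  tibble(mean_cl_mM = base::mean(vals), sem_cl_mM = sem, n = length(vals),
         n_clamped = sum(estimates$flag == "clamped"),
         n_low_r2 = sum(estimates$flag == "low_r2"))
}

#' Photobleaching drift check
#'
#' Estimates the linear fluorescence drift of an unstimulated trace segment
#' as a relative slope per minute and compares it to a threshold (default 1
#' percent per minute). Dye bleaching would appear as a steady negative
#' drift.
#'
#' @param trace Single-cell tibble with `time_s`, `fluorescence`.
#' @param window_s Length of the segment (from the start of the trace) to
#'   analyse.
#' @param threshold Pass/fail threshold on `|drift|` (relative units per
#'   minute).
#' @return One-row tibble: `drift_per_min`, `pass`.
#' @export
bleaching_check <- function(trace, window_s, threshold = 0.01) {
  seg <- filter(trace, .data$time_s <= window_s)
  if (nrow(seg) < 3 || max(seg$time_s) - min(seg$time_s) < window_s * 0.5) {
    abort("Trace segment too short for a drift estimate.",
          class = "clquant_data_error")
  }
  fit <- lm(fluorescence ~ time_s, data = seg)
  drift <- unname(coef(fit)[2]) / base::mean(seg$fluorescence) * 60
  tibble(drift_per_min = drift, pass = abs(drift) <= threshold)
}

#' Resting fluorescence from a protocol's rest segment
#'
#' Mean fluorescence per cell over the frames of the protocol's resting
#' window (label `rest`, `cl_mM` NA), or over the first `n_frames` frames
#' when the protocol has no rest segment.
#'
#' @param traces Long trace tibble.
#' @param protocol Protocol tibble.
#' @param n_frames Fallback number of leading frames (default 10, the
#'   baseline convention).
#' @return Tibble `cell_id`, `f_rest`.
#' @export
resting_fluorescence <- function(traces, protocol = NULL, n_frames = 10) {
  rest <- if (!is.null(protocol)) filter(protocol, is.na(.data$cl_mM)) else NULL
  if (!is.null(rest) && nrow(rest) >= 1) {
    seg <- filter(traces, .data$time_s > rest$start_s[1],
                  .data$time_s <= rest$end_s[1])
  } else {
    seg <- traces |>
      group_by(.data$cell_id) |>
      dplyr::slice_min(.data$time_s, n = n_frames, with_ties = FALSE) |>
      ungroup()
  }
  seg |>
    group_by(.data$cell_id) |>
    summarise(f_rest = base::mean(.data$fluorescence), .groups = "drop")
}

#' Full calibration stage: traces to per-cell chloride estimates
#'
#' Convenience wrapper chaining steady-state detection, per-cell
#' Stern-Volmer fits, resting-fluorescence extraction and chloride
#' estimation.
#'
#' @param traces Long trace tibble.
#' @param protocol Protocol tibble with calibration steps (and optionally a
#'   rest segment).
#' @param plateau_frac,slope_tol Passed to [detect_steady_states()].
#' @param low_r2 Passed to [estimate_cl()].
#' @return A list with `fits`, `estimates`, `plateaus`.
#' @export
calibrate_cells <- function(traces, protocol, plateau_frac = 0.2,
                            slope_tol = 5e-4, low_r2 = 0.9) {
  plateaus <- detect_steady_states(traces, protocol, plateau_frac, slope_tol)
  fits <- fit_stern_volmer_cells(plateaus)
  frest <- resting_fluorescence(traces, protocol)
  fits <- left_join(fits, frest, by = "cell_id")
  estimates <- estimate_cl(fits$f_rest, fits, low_r2 = low_r2)
  list(fits = select(fits, -"f_rest"), estimates = estimates,
       plateaus = plateaus)
}
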