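# File formats and the end-to-end pipeline. Traces are written as wide CSV
# (column 1 `time_s`, one column per cell), protocols as YAML step lists,
# behavioral sessions as long CSV, and ground truth / manifests as JSON.
# All floating-point CSV output is written at 9 significant digits so
# re-runs diff cleanly.

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(signif(x, 9), format = "g", digits = 9))
}

#' Write a trace table as wide CSV
#'
#' @param traces Long tibble (`time_s`, `cell_id`, `fluorescence`, and
#'   optionally `channel`).
#' @param path Output file.
#' @param channel When the table holds several channels, which one to write.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path, channel = NULL) {
  if (!is.null(channel)) {
    traces <- filter(traces, .data$channel == !!channel)
  }
  wide <- traces |>
    select("time_s", "cell_id", "fluorescence") |>
    tidyr::pivot_wider(names_from = "cell_id", values_from = "fluorescence") |>
    arrange(.data$time_s)
  wide <- mutate(wide, across(dplyr::everything(), fmt_num))
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a wide trace CSV
#'
#' @param path CSV with column `time_s` and one column per cell.
#' @param channel Channel label to attach.
#' @return Long tibble (`time_s`, `cell_id`, `fluorescence`, `channel`).
#' @export
read_trace_csv <- function(path, channel = "mqae") {
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(wide)[1] != "time_s") {
    abort(sprintf("%s: first column must be `time_s` (found `%s`).",
                  path, names(wide)[1]),
          class = "clquant_parse_error")
  }
  if (is.unsorted(wide$time_s, strictly = TRUE)) {
    abort(sprintf("%s: `time_s` must be strictly increasing.", path),
          class = "clquant_data_error")
  }
  wide |>
    tidyr::pivot_longer(-"time_s", names_to = "cell_id",
                        values_to = "fluorescence") |>
    mutate(channel = channel) |>
    arrange(.data$cell_id, .data$time_s)
}

#' Write a protocol as YAML
#'
#' @param protocol Tibble with `label`, `start_s`, `end_s` and `cl_mM`
#'   and/or `stimulus`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  steps <- purrr::pmap(protocol, function(...) {
    step <- list(...)
    step[!vapply(step, function(v) is.na(v) || is.null(v), logical(1))]
  })
  yaml::write_yaml(list(steps = steps), path)
  invisible(path)
}

#' Read a protocol YAML
#'
#' @param path YAML file with a top-level `steps` list; each step has
#'   `label`, `start_s`, `end_s` and `cl_mM` (calibration) or `stimulus`.
#' @return Protocol tibble.
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$steps) || length(y$steps) == 0) {
    abort(sprintf("%s: no `steps` list found.", path),
          class = "clquant_parse_error")
  }
  rows <- purrr::imap(y$steps, function(s, i) {
    for (field in c("label", "start_s", "end_s")) {
      if (is.null(s[[field]])) {
        abort(sprintf("%s: step %d is missing `%s`.", path, i, field),
              class = "clquant_parse_error")
      }
    }
    tibble(label = s$label,
           start_s = as.numeric(s$start_s),
           end_s = as.numeric(s$end_s),
           cl_mM = if (is.null(s$cl_mM)) NA_real_ else as.numeric(s$cl_mM),
           stimulus = if (is.null(s$stimulus)) FALSE else isTRUE(s$stimulus))
  })
  proto <- bind_rows(rows)
  if (any(proto$end_s <= proto$start_s)) {
    abort(sprintf("%s: every step needs end_s > start_s.", path),
          class = "clquant_parse_error")
  }
  proto
}

session_cols <- c("mouse_id", "genotype", "concentration_uM",
                  "intake1_ul", "intake2_ul", "session_type")

#' Write behavioral sessions as CSV
#'
#' @param sessions Session tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sessions_csv <- function(sessions, path) {
  out <- sessions |>
    select(dplyr::all_of(session_cols)) |>
    mutate(across(c("concentration_uM", "intake1_ul", "intake2_ul"), fmt_num))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read behavioral sessions CSV
#'
#' @param path CSV with columns `mouse_id`, `genotype`, `concentration_uM`,
#'   `intake1_ul`, `intake2_ul`, `session_type`.
#' @return Session tibble.
#' @export
read_sessions_csv <- function(path) {
  s <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(session_cols, names(s))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing column(s) %s.", path,
                  paste(missing, collapse = ", ")),
          class = "clquant_parse_error")
  }
  s
}

#' Default pipeline configuration
#'
#' Every default mirrors the recording conventions of the study design:
#' 10-frame baselines, a 4-sigma response threshold, calibration steps at
#' 0/20/40/60 mM, 151 mM external chloride and a -54 mV resting potential.
#'
#' @param seed Master seed; each stage derives a named substream.
#' @param population A [population_params()] object.
#' @param kinetics A [kinetics_params()] object.
#' @param ctx An [equilibrium_context()].
#' @param conc_steps Calibration concentrations (mM).
#' @param n_baseline Baseline frames.
#' @param k Response threshold multiplier.
#' @param stim_window Stimulus window `c(start_s, end_s)` for the
#'   stimulation stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            population = population_params(),
                            kinetics = kinetics_params(),
                            ctx = equilibrium_context(),
                            conc_steps = c(0, 20, 40, 60),
                            n_baseline = 10,
                            k = 4,
                            stim_window = c(5, 35)) {
  structure(list(seed = seed, population = population, kinetics = kinetics,
                 ctx = ctx, conc_steps = conc_steps,
                 n_baseline = n_baseline, k = k, stim_window = stim_window),
            class = "pipeline_config")
}

config_known_keys <- function() {
  list(
    seed = NULL,
    population = names(formals(population_params)),
    kinetics = names(formals(kinetics_params)),
    equilibrium = c("cl_out_mM", "rmp_mV", "decade_slope_mV", "temperature_c"),
    conc_steps = NULL, n_baseline = NULL, k = NULL, stim_window = NULL
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected so typos surface instead of silently falling
#' back to defaults.
#'
#' @param path YAML file; any subset of the keys `seed`, `population`,
#'   `kinetics`, `equilibrium`, `conc_steps`, `n_baseline`, `k`,
#'   `stim_window`.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- config_known_keys()
  unknown <- setdiff(names(y), names(known))
  if (length(unknown) > 0) {
    abort(sprintf("%s: unknown config key(s): %s.", path,
                  paste(unknown, collapse = ", ")),
          class = "clquant_parse_error")
  }
  for (sec in c("population", "kinetics", "equilibrium")) {
    bad <- setdiff(names(y[[sec]]), known[[sec]])
    if (length(bad) > 0) {
      abort(sprintf("%s: unknown key(s) in `%s`: %s.", path, sec,
                    paste(bad, collapse = ", ")),
            class = "clquant_parse_error")
    }
  }
  pipeline_config(
    seed = y$seed %||% 1,
    population = do.call(population_params, y$population %||% list()),
    kinetics = do.call(kinetics_params, y$kinetics %||% list()),
    ctx = do.call(equilibrium_context, y$equilibrium %||% list()),
    conc_steps = unlist(y$conc_steps) %||% c(0, 20, 40, 60),
    n_baseline = y$n_baseline %||% 10,
    k = y$k %||% 4,
    stim_window = unlist(y$stim_window) %||% c(5, 35)
  )
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate -> calibrate -> classify -> equilibrium-predict ->
#' summarise on a seeded synthetic dataset, optionally writing all
#' intermediate tables plus a run manifest (config hash, seed, package
#' version) to `out_dir`. Identical config and seed give bit-identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return A list of class `pipeline_report`: `population_summary`,
#'   `calls`, `observed_efflux_fraction`, `predicted_efflux_fraction`
#'   (empirical, from the generated cells), `predicted_efflux_gaussian`
#'   (closed form at the configured population mean/SD), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  cells <- sim_cell_population(config$population, seed = seed)

  cal <- sim_calibration_traces(cells, conc_steps = config$conc_steps,
                                kinetics = config$kinetics, seed = seed)
  calres <- calibrate_cells(cal$traces, cal$protocol)
  pop <- summarize_population(calres$estimates)

  stim <- sim_stimulation_traces(cells, ctx = config$ctx,
                                 kinetics = config$kinetics, seed = seed)
  calls <- classify_cells(stim$traces, stim_window = config$stim_window,
                          n_baseline = config$n_baseline, k = config$k)
  observed <- base::mean(calls$direction == "efflux")
  predicted <- efflux_fraction(cells$cl_i_mM, config$ctx)
  predicted_gauss <- if (config$population$sd_cl > 0) {
    efflux_fraction(ctx = config$ctx, mean = config$population$mean_cl,
                    sd = config$population$sd_cl)
  } else {
    NA_real_
  }

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = seed,
    package = "clquant",
    version = as.character(utils::packageVersion("clquant"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trace_csv(cal$traces, file.path(out_dir, "calibration_mqae.csv"))
    write_protocol(cal$protocol, file.path(out_dir, "calibration_protocol.yaml"))
    write_trace_csv(stim$traces, file.path(out_dir, "stimulation_mqae.csv"))
    write_protocol(stim$protocol, file.path(out_dir, "stimulation_protocol.yaml"))
    readr::write_csv(mutate(calres$fits,
                            across(dplyr::where(is.numeric), fmt_num)),
                     file.path(out_dir, "stern_volmer_fits.csv"), progress = FALSE)
    readr::write_csv(mutate(calres$estimates,
                            across(dplyr::where(is.numeric), fmt_num)),
                     file.path(out_dir, "chloride_estimates.csv"), progress = FALSE)
    readr::write_csv(mutate(calls, across(dplyr::where(is.numeric), fmt_num)),
                     file.path(out_dir, "response_calls.csv"), progress = FALSE)
    jsonlite::write_json(
      list(true_cl_i_mM = cells$cl_i_mM, true_ksv_per_M = cells$ksv_per_M,
           true_f0 = cells$f0),
      file.path(out_dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }

  structure(list(population_summary = pop,
                 calls = calls,
                 observed_efflux_fraction = observed,
                 predicted_efflux_fraction = predicted,
                 predicted_efflux_gaussian = predicted_gauss,
                 manifest = manifest),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf("  mean [Cl-]i: %.2f +/- %.2f mM (n = %d)\n",
              x$population_summary$mean_cl_mM, x$population_summary$sem_cl_mM,
              x$population_summary$n))
  cat(sprintf("  efflux fraction: observed %.3f, predicted %.3f (Gaussian closed form %.3f)\n",
              x$observed_efflux_fraction, x$predicted_efflux_fraction,
              x$predicted_efflux_gaussian))
  cat(sprintf("  manifest hash: %s\n", x$manifest$config_hash))
  invisible(x)
}
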