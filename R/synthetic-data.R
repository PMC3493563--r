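# Seeded synthetic-data generators. Every generator takes an integer seed and
# derives a named substream from it, so pipelines built from several
# generators stay reproducible even when stages are added or reordered.

# deterministic substream seed below 2^31
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 1000003L) * 2099L + (h %% 104729L)
}

with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(code)
}

# mean of a Gaussian(mu, sd) truncated to [a, b]
truncnorm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd
  be <- (b - mu) / sd
  z <- pnorm(be) - pnorm(al)
  mu + sd * (dnorm(al) - dnorm(be)) / z
}

# location mu such that the [a, b]-truncated Gaussian with scale sd has the
# requested mean; the truncated mean is increasing in mu and spans (a, b)
truncnorm_match_mean <- function(target, sd, a, b) {
  if (target <= a || target >= b) {
    abort("Target mean must lie strictly inside the truncation bounds.",
          class = "clquant_config_error")
  }
  uniroot(function(m) truncnorm_mean(m, sd, a, b) - target,
          lower = a, upper = b, extendInt = "upX", tol = 1e-10)$root
}

# inverse-CDF sampler for the truncated Gaussian
rtruncnorm <- function(n, mu, sd, a, b) {
  pl <- pnorm(a, mu, sd)
  pu <- pnorm(b, mu, sd)
  qnorm(runif(n, pl, pu), mu, sd)
}

# multiplicative log-normal noise with unit mean (sdlog from a CV)
rlnorm_unit <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

cell_ids <- function(n) sprintf("cell_%04d", seq_len(n))

#' Simulate a population of chloride-loaded cells
#'
#' Draws per-cell resting \eqn{[Cl^-]_i}, Stern-Volmer constant and
#' unquenched fluorescence F0. Chloride is drawn from a truncated Gaussian
#' whose location is solved so that the delivered (truncated) population mean
#' equals `params$mean_cl`; Ksv from a Gaussian truncated at > 0; F0
#' log-normal with CV `params$f0_cv`.
#'
#' @param params A [population_params()] object.
#' @param seed Integer seed; identical seeds give identical populations.
#' @return A tibble with columns `cell_id`, `cl_i_mM`, `ksv_per_M`, `f0`.
#' @export
#' @examples
#' cells <- sim_cell_population(population_params(n_cells = 20), seed = 1)
#' mean(cells$cl_i_mM)
sim_cell_population <- function(params = population_params(), seed = 1) {
  stopifnot(inherits(params, "population_params"))
  with_substream(seed, "population", {
    n <- params$n_cells
    cl <- if (params$sd_cl == 0) {
      rep(params$mean_cl, n)
    } else {
      mu <- truncnorm_match_mean(params$mean_cl, params$sd_cl,
                                 params$lower_trunc, params$upper_trunc)
      rtruncnorm(n, mu, params$sd_cl, params$lower_trunc, params$upper_trunc)
    }
    ksv <- if (params$ksv_sd == 0) {
      rep(params$ksv_mean, n)
    } else {
      rtruncnorm(n, params$ksv_mean, params$ksv_sd, 1e-9, Inf)
    }
    f0 <- params$f0_mean * rlnorm_unit(n, params$f0_cv)
    tibble(cell_id = cell_ids(n), cl_i_mM = cl, ksv_per_M = ksv, f0 = f0)
  })
}

# Stern-Volmer forward model: fluorescence at chloride concentration cl (mM)
sv_fluorescence <- function(f0, ksv, cl_mM) {
  f0 / (1 + ksv * cl_mM / 1000)
}

# first-order relaxation of a state through a piecewise-constant target
relax_to_targets <- function(times, targets, start, rate) {
  out <- numeric(length(times))
  state <- start
  t_prev <- 0
  for (i in seq_along(times)) {
    dt <- times[i] - t_prev
    state <- targets[i] + (state - targets[i]) * exp(-rate * dt)
    out[i] <- state
    t_prev <- times[i]
  }
  out
}

apply_frame_noise <- function(f, kinetics) {
  n <- length(f)
  if (kinetics$bleach_rate > 0) {
    f <- f * (1 - kinetics$bleach_rate)^(seq_len(n) - 1)
  }
  if (kinetics$noise_sd > 0) {
    f <- f * (1 + rnorm(n, sd = kinetics$noise_sd))
  }
  f
}

#' Simulate double-ionophore calibration traces
#'
#' Generates MQAE fluorescence traces for a calibration experiment in which
#' ionophore-permeabilised cells are exposed to solutions of defined chloride
#' concentration (default 0, 20, 40 and 60 mM), each held until the
#' fluorescence plateaus (default 10 min per step, one frame every 15 s). An
#' initial rest segment records the cells at their own resting chloride, so
#' the same dataset supports resting-concentration estimation. The plateau of
#' each step follows the quenching forward model
#' \eqn{F = F_0 / (1 + K_{sv} C)} with C in molar; the approach to each
#' plateau is first-order with `kinetics$rate_constant`.
#'
#' @param cells Tibble from [sim_cell_population()].
#' @param conc_steps Ordered calibration concentrations (mM); must contain 0
#'   (needed to define F0).
#' @param step_duration_s Duration of each calibration step (s).
#' @param rest_duration_s Duration of the initial resting segment (s).
#' @param frame_dt_s Sampling interval (s); the calibration protocol samples
#'   slowly (15 s) to limit light exposure.
#' @param kinetics A [kinetics_params()] object.
#' @param seed Integer seed.
#' @return A list with `traces` (long tibble: `time_s`, `cell_id`,
#'   `fluorescence`, `channel`), `protocol` (tibble: `label`, `start_s`,
#'   `end_s`, `cl_mM`), and `truth` (the input `cells`).
#' @export
sim_calibration_traces <- function(cells,
                                   conc_steps = c(0, 20, 40, 60),
                                   step_duration_s = 600,
                                   rest_duration_s = 150,
                                   frame_dt_s = 15,
                                   kinetics = kinetics_params(),
                                   seed = 1) {
  stopifnot(inherits(kinetics, "kinetics_params"))
  if (length(conc_steps) == 0) {
    abort("`conc_steps` must be non-empty.", class = "clquant_config_error")
  }
  if (!any(conc_steps == 0)) {
    abort("`conc_steps` must include a 0 mM step (it defines F0).",
          class = "clquant_config_error")
  }
  starts <- rest_duration_s + (seq_along(conc_steps) - 1) * step_duration_s
  protocol <- tibble(
    label = c("rest", sprintf("cal_%gmM", conc_steps)),
    start_s = c(0, starts),
    end_s = c(rest_duration_s, starts + step_duration_s),
    cl_mM = c(NA_real_, conc_steps)
  )
  total_s <- max(protocol$end_s)
  times <- seq(frame_dt_s, total_s, by = frame_dt_s)
  with_substream(seed, "calibration_traces", {
    traces <- purrr::pmap(cells, function(cell_id, cl_i_mM, ksv_per_M, f0) {
      step_idx <- findInterval(times, protocol$start_s,
                               left.open = TRUE, rightmost.closed = TRUE)
      target_cl <- protocol$cl_mM[pmax(step_idx, 1)]
      target_cl[is.na(target_cl)] <- cl_i_mM
      cl_t <- relax_to_targets(times, target_cl, cl_i_mM,
                               kinetics$rate_constant)
      f <- sv_fluorescence(f0, ksv_per_M, cl_t)
      tibble(time_s = times, cell_id = cell_id,
             fluorescence = apply_frame_noise(f, kinetics),
             channel = "mqae")
    })
    list(traces = bind_rows(traces), protocol = protocol, truth = cells)
  })
}

#' Simulate stimulus-evoked chloride traces
#'
#' During each stimulus window, a cell's \eqn{[Cl^-]_i} relaxes first-order
#' toward the equilibrium concentration set by the membrane potential (the
#' critical concentration from [critical_cli()]): cells above it lose
#' chloride, so their MQAE fluorescence rises (efflux); cells below gain
#' chloride and their fluorescence falls (influx). Between stimuli the
#' concentration relaxes back to its resting value.
#'
#' @param cells Tibble from [sim_cell_population()].
#' @param protocol Tibble with columns `label`, `start_s`, `end_s`,
#'   `stimulus` (logical or character; non-`"none"`/`TRUE` rows are
#'   stimulation windows). If `NULL`, a default protocol with a 5 s baseline
#'   and one 30 s stimulus is used.
#' @param ctx An [equilibrium_context()] giving the membrane potential and
#'   external chloride; its critical concentration is the stimulus-on target.
#' @param kinetics A [kinetics_params()] object. Stimulation recordings are
#'   sampled at 2 Hz.
#' @param frame_dt_s Sampling interval (s).
#' @param duration_s Total trace duration (s); defaults to cover the protocol
#'   plus a 30 s recovery tail.
#' @param seed Integer seed.
#' @return A list with `traces`, `protocol`, `truth` (the cells plus the
#'   critical concentration and the expected response direction).
#' @export
sim_stimulation_traces <- function(cells, protocol = NULL,
                                   ctx = equilibrium_context(),
                                   kinetics = kinetics_params(),
                                   frame_dt_s = 0.5,
                                   duration_s = NULL,
                                   seed = 1) {
  stopifnot(inherits(kinetics, "kinetics_params"))
  if (is.null(protocol)) {
    protocol <- tibble(label = c("baseline", "stimulus"),
                       start_s = c(0, 5), end_s = c(5, 35),
                       stimulus = c(FALSE, TRUE))
  }
  stim <- as_stim_flags(protocol)
  crit <- critical_cli(ctx)
  duration_s <- duration_s %||% (max(protocol$end_s) + 30)
  times <- seq(frame_dt_s, duration_s, by = frame_dt_s)
  with_substream(seed, "stimulation_traces", {
    traces <- purrr::pmap(cells, function(cell_id, cl_i_mM, ksv_per_M, f0) {
      on_stim <- in_any_window(times, protocol$start_s[stim], protocol$end_s[stim])
      target <- ifelse(on_stim, crit, cl_i_mM)
      cl_t <- relax_to_targets(times, target, cl_i_mM, kinetics$rate_constant)
      f <- sv_fluorescence(f0, ksv_per_M, cl_t)
      tibble(time_s = times, cell_id = cell_id,
             fluorescence = apply_frame_noise(f, kinetics),
             channel = "mqae")
    })
    truth <- mutate(cells,
                    critical_cl_mM = crit,
                    true_direction = dplyr::case_when(
                      .data$cl_i_mM > crit ~ "efflux",
                      .data$cl_i_mM < crit ~ "influx",
                      TRUE ~ "none"))
    list(traces = bind_rows(traces), protocol = protocol, truth = truth)
  })
}

as_stim_flags <- function(protocol) {
  if ("stimulus" %in% names(protocol)) {
    s <- protocol$stimulus
    if (is.logical(s)) return(s)
    return(!(is.na(s) | s %in% c("none", "")))
  }
  rep(FALSE, nrow(protocol))
}

in_any_window <- function(times, starts, ends) {
  out <- rep(FALSE, length(times))
  for (i in seq_along(starts)) {
    out <- out | (times > starts[i] & times <= ends[i])
  }
  out
}

#' Simulate dual-channel Fura-2 traces
#'
#' Generates 340-nm and 380-nm emission traces sampled at 1 Hz whose ratio
#' shows one transient per stimulus window. The transient amplitude is the
#' base amplitude scaled by the chloride-dependent amplification term of
#' [fura_params()]; the 380-nm channel dips during the transient (as calcium
#' rises) and is floored at a small positive value so the ratio is defined
#' everywhere.
#'
#' @param cells Tibble from [sim_cell_population()].
#' @param protocol As in [sim_stimulation_traces()].
#' @param amp_params A [fura_params()] object.
#' @param frame_dt_s Sampling interval (s).
#' @param duration_s Total duration (s).
#' @param seed Integer seed.
#' @return A list with `traces` (long tibble, channels `fura340` and
#'   `fura380`), `protocol`, and `truth` (cells plus `true_amplitude`, the
#'   noiseless peak ratio change).
#' @export
sim_fura_traces <- function(cells, protocol = NULL,
                            amp_params = fura_params(),
                            frame_dt_s = 1,
                            duration_s = NULL,
                            seed = 1) {
  stopifnot(inherits(amp_params, "fura_params"))
  if (is.null(protocol)) {
    protocol <- tibble(label = c("baseline", "stimulus"),
                       start_s = c(0, 15), end_s = c(15, 20),
                       stimulus = c(FALSE, TRUE))
  }
  stim <- as_stim_flags(protocol)
  duration_s <- duration_s %||% (max(protocol$end_s) + 60)
  times <- seq(frame_dt_s, duration_s, by = frame_dt_s)
  onsets <- protocol$start_s[stim]
  with_substream(seed, "fura_traces", {
    traces <- purrr::pmap(cells, function(cell_id, cl_i_mM, ksv_per_M, f0) {
      gain <- 1 + amp_params$alpha *
        max(0, cl_i_mM - amp_params$critical_cl) / amp_params$critical_cl
      amp <- amp_params$amplitude * gain
      kern <- rowSums(vapply(onsets, function(t0) {
        transient_kernel(times, t0, amp_params$tau_rise, amp_params$tau_decay)
      }, numeric(length(times))))
      if (length(onsets) == 0) kern <- numeric(length(times))
      ratio <- amp_params$baseline_ratio + amp * kern
      f380 <- pmax(amp_params$f380_base * (1 - 0.3 * kern), 1e-6)
      f340 <- ratio * f380
      if (amp_params$noise_sd > 0) {
        f340 <- f340 + rnorm(length(times),
                             sd = amp_params$noise_sd * amp_params$baseline_ratio *
                               amp_params$f380_base)
        f380 <- pmax(f380 + rnorm(length(times),
                                  sd = amp_params$noise_sd * amp_params$f380_base),
                     1e-6)
      }
      bind_rows(
        tibble(time_s = times, cell_id = cell_id,
               fluorescence = f340, channel = "fura340"),
        tibble(time_s = times, cell_id = cell_id,
               fluorescence = f380, channel = "fura380")
      )
    })
    truth <- mutate(cells,
                    true_amplitude = amp_params$amplitude *
                      (1 + amp_params$alpha *
                         pmax(0, .data$cl_i_mM - amp_params$critical_cl) /
                         amp_params$critical_cl))
    list(traces = bind_rows(traces), protocol = protocol, truth = truth)
  })
}

# difference-of-exponentials transient, normalised to unit peak
transient_kernel <- function(times, t0, tau_rise, tau_decay) {
  dt <- pmax(times - t0, 0)
  k <- (1 - exp(-dt / tau_rise)) * exp(-dt / tau_decay)
  t_peak <- tau_rise * log(1 + tau_decay / tau_rise)
  k_peak <- (1 - exp(-t_peak / tau_rise)) * exp(-t_peak / tau_decay)
  k / k_peak
}

#' Simulate dose-response measurements
#'
#' Evaluates a Hill curve at the given concentrations, optionally with
#' multiplicative Gaussian noise. Defaults describe the GABA activation
#' curve of newborn wild-type trigeminal neurons (EC50 24.7 uM, Hill
#' coefficient 2.1, responses normalised to the saturating response); for
#' inhibition curves the bicuculline default midpoint is 1.3 uM.
#'
#' @param ec50 Midpoint (uM).
#' @param hill_n Hill coefficient.
#' @param top,bottom Response asymptotes.
#' @param direction `"activation"` or `"inhibition"`.
#' @param concentrations Concentrations (uM).
#' @param noise_cv Multiplicative noise CV (0 = exact curve).
#' @param seed Integer seed (used only when `noise_cv > 0`).
#' @return A tibble with `concentration_uM`, `response` and the generating
#'   parameters as attributes (`truth`).
#' @export
#' @examples
#' sim_dose_response()  # exact default activation curve
sim_dose_response <- function(ec50 = 24.7, hill_n = 2.1, top = 1, bottom = 0,
                              direction = c("activation", "inhibition"),
                              concentrations = c(1, 3, 10, 30, 100, 300),
                              noise_cv = 0, seed = 1) {
  direction <- match.arg(direction)
  if (any(concentrations <= 0)) {
    abort("`concentrations` must be positive.", class = "clquant_config_error")
  }
  r <- hill_curve(concentrations, ec50, hill_n, top, bottom, direction)
  if (noise_cv > 0) {
    r <- with_substream(seed, "dose_response", {
      r * (1 + rnorm(length(r), sd = noise_cv))
    })
  }
  out <- tibble(concentration_uM = concentrations, response = r)
  attr(out, "truth") <- list(ec50 = ec50, hill_n = hill_n, top = top,
                             bottom = bottom, direction = direction)
  out
}

#' Simulate brief-access drinking sessions
#'
#' Generates per-mouse, per-concentration drinking sessions for the
#' brief-access avoidance assay: a first exposure to solvent, a second to
#' capsaicin-adulterated water. First-exposure intakes are log-normal around
#' `params$intake1_mean`; second-exposure intakes equal the first intake
#' times the ground-truth Exposure Intake Ratio
#' \eqn{EIR(c) = baseline / (1 + (c/EC_{50})^n)} times unit-mean
#' multiplicative noise. Water/water control sessions (concentration 0) are
#' generated alongside.
#'
#' @param params A [behavior_params()] object.
#' @param concentrations Capsaicin concentrations (uM), given in ascending
#'   order during the assay.
#' @param genotype Label stored with each session.
#' @param seed Integer seed.
#' @return A list with `sessions` (tibble: `mouse_id`, `genotype`,
#'   `concentration_uM`, `intake1_ul`, `intake2_ul`, `session_type`) and
#'   `truth` (the generating curve parameters).
#' @export
sim_drinking_sessions <- function(params = behavior_params(),
                                  concentrations = c(1, 3, 10, 30, 100, 300),
                                  genotype = "WT",
                                  seed = 1) {
  stopifnot(inherits(params, "behavior_params"))
  if (any(concentrations <= 0)) {
    abort("`concentrations` must be positive (water controls are generated separately).",
          class = "clquant_config_error")
  }
  with_substream(seed, "drinking_sessions", {
    mice <- sprintf("mouse_%02d", seq_len(params$n_mice))
    grid <- tidyr::expand_grid(mouse_id = mice,
                               concentration_uM = c(0, sort(concentrations)))
    true_eir <- params$baseline_eir /
      (1 + (grid$concentration_uM / params$ec50)^params$hill_n)
    intake1 <- params$intake1_mean * rlnorm_unit(nrow(grid), params$intake_noise_cv)
    intake2 <- intake1 * true_eir * rlnorm_unit(nrow(grid), params$intake_noise_cv)
    sessions <- tibble(
      mouse_id = grid$mouse_id,
      genotype = genotype,
      concentration_uM = grid$concentration_uM,
      intake1_ul = intake1,
      intake2_ul = intake2,
      session_type = ifelse(grid$concentration_uM == 0,
                            "water_water", "solvent_capsaicin")
    )
    list(sessions = sessions,
         truth = list(ec50 = params$ec50, hill_n = params$hill_n,
                      baseline_eir = params$baseline_eir))
  })
}
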