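#' Parameters of the synthetic cell population
#'
#' Describes the distribution of resting intracellular chloride, per-cell
#' Stern-Volmer quenching constants and dye-loading fluorescence used by
#' [sim_cell_population()]. Defaults reproduce the wild-type population
#' measured in newborn mouse trigeminal ganglion neurons: an approximately
#' Gaussian \eqn{[Cl^-]_i} distribution with mean 34.1 mM (SD reconstructed
#' from the reported SEM at n = 16 as 6.9 * sqrt(16) = 27.6 mM), per-cell
#' Ksv of 14.4 +/- 3.3 per molar, truncated to a plausible single-cell range.
#'
#' The truncation bounds (2-110 mM) bracket the observed single-cell range
#' (7.8-102.1 mM). Because truncating a Gaussian shifts its mean, the sampler
#' solves for the underlying location so the *truncated* distribution has
#' mean `mean_cl`; see [sim_cell_population()].
#'
#' @param mean_cl Mean resting \eqn{[Cl^-]_i} (mM) of the delivered
#'   (truncated) population.
#' @param sd_cl Gaussian scale parameter (mM); must be positive (0 allowed as
#'   a degenerate point mass at `mean_cl`).
#' @param lower_trunc,upper_trunc Truncation bounds (mM).
#' @param n_cells Number of cells to draw.
#' @param ksv_mean,ksv_sd Mean and SD of the per-cell Stern-Volmer constant
#'   (per molar); sampled from a Gaussian truncated at > 0.
#' @param f0_mean Mean unquenched fluorescence F0 (arbitrary units).
#' @param f0_cv Coefficient of variation of F0 (log-normal, reflecting
#'   cell-to-cell dye loading differences).
#' @return A list of class `population_params`.
#' @seealso [ko_population_params()] for the NKCC1-null preset.
#' @export
#' @examples
#' population_params(n_cells = 50)
population_params <- function(mean_cl = 34.1, sd_cl = 27.6,
                              lower_trunc = 2, upper_trunc = 110,
                              n_cells = 200,
                              ksv_mean = 14.4, ksv_sd = 3.3,
                              f0_mean = 100, f0_cv = 0.2) {
  if (sd_cl < 0) abort("`sd_cl` must be >= 0.", class = "clquant_config_error")
  if (lower_trunc < 0) abort("`lower_trunc` must be >= 0.", class = "clquant_config_error")
  if (upper_trunc <= lower_trunc) {
    abort("`upper_trunc` must exceed `lower_trunc`.", class = "clquant_config_error")
  }
  if (ksv_mean <= 0) abort("`ksv_mean` must be > 0.", class = "clquant_config_error")
  if (sd_cl == 0 && (mean_cl < lower_trunc || mean_cl > upper_trunc)) {
    abort("Degenerate population mean lies outside the truncation bounds.",
          class = "clquant_config_error")
  }
  if (n_cells < 1) abort("`n_cells` must be >= 1.", class = "clquant_config_error")
  structure(list(mean_cl = mean_cl, sd_cl = sd_cl,
                 lower_trunc = lower_trunc, upper_trunc = upper_trunc,
                 n_cells = n_cells, ksv_mean = ksv_mean, ksv_sd = ksv_sd,
                 f0_mean = f0_mean, f0_cv = f0_cv),
            class = "population_params")
}

#' NKCC1-null population preset
#'
#' Convenience preset for the knockout population: mean 13.2 mM with SD
#' reconstructed as 1.1 * sqrt(33) = 6.3 mM.
#'
#' @inheritParams population_params
#' @param ... Further overrides passed to [population_params()].
#' @return A `population_params` object.
#' @export
ko_population_params <- function(n_cells = 200, ...) {
  population_params(mean_cl = 13.2, sd_cl = 6.3, n_cells = n_cells, ...)
}

#' First-order chloride kinetics and measurement noise
#'
#' The generators model intracellular chloride as relaxing exponentially
#' toward its current target (bath concentration under ionophores, or the
#' equilibrium concentration set by the membrane potential during a
#' stimulus). The source measurements report no kinetic constants (responses
#' occur "within short latency"), so the rate only has to settle well within
#' a calibration step; plateau-based estimates are insensitive to it.
#'
#' @param rate_constant Relaxation rate (1/s).
#' @param noise_sd Multiplicative Gaussian noise SD per frame (relative
#'   fluorescence units; 0.01 = 1 percent).
#' @param bleach_rate Fractional fluorescence loss per frame. Defaults to 0:
#'   control recordings showed no significant intensity loss over the
#'   protocol durations.
#' @return A list of class `kinetics_params`.
#' @export
kinetics_params <- function(rate_constant = 0.05, noise_sd = 0.01,
                            bleach_rate = 0) {
  if (rate_constant <= 0) abort("`rate_constant` must be > 0.", class = "clquant_config_error")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.", class = "clquant_config_error")
  if (bleach_rate < 0) abort("`bleach_rate` must be >= 0.", class = "clquant_config_error")
  structure(list(rate_constant = rate_constant, noise_sd = noise_sd,
                 bleach_rate = bleach_rate),
            class = "kinetics_params")
}

#' Parameters of the synthetic drinking-avoidance cohort
#'
#' Drinking sessions are generated with first-exposure intakes log-normal
#' around `intake1_mean` and second-exposure intakes shaped by a descending
#' Hill curve of the capsaicin concentration:
#' \deqn{EIR(c) = baseline / (1 + (c / EC_{50})^{n})}
#' Defaults describe the wild-type cohort: avoidance EC50 6.4 uM, water-day
#' Exposure Intake Ratio 1.11, first-exposure intake 242 ul with the
#' coefficient of variation implied by the reported SEM (14 ul at n = 10,
#' CV ~ 0.18). The Hill coefficient is not reported; 1.5 matches the
#' steepness of the published mean-ratio points.
#'
#' @param ec50 Avoidance EC50 (uM).
#' @param hill_n Hill coefficient (> 0).
#' @param baseline_eir Exposure Intake Ratio in the absence of capsaicin.
#' @param intake1_mean Mean first-exposure intake (ul).
#' @param intake_noise_cv Coefficient of variation of the multiplicative
#'   intake noise.
#' @param n_mice Cohort size.
#' @return A list of class `behavior_params`.
#' @seealso [ko_behavior_params()]
#' @export
behavior_params <- function(ec50 = 6.4, hill_n = 1.5, baseline_eir = 1.11,
                            intake1_mean = 242, intake_noise_cv = 0.18,
                            n_mice = 11) {
  if (ec50 <= 0) abort("`ec50` must be > 0.", class = "clquant_config_error")
  if (hill_n <= 0) abort("`hill_n` must be > 0.", class = "clquant_config_error")
  if (baseline_eir <= 0) abort("`baseline_eir` must be > 0.", class = "clquant_config_error")
  if (intake1_mean <= 0) abort("`intake1_mean` must be > 0.", class = "clquant_config_error")
  if (intake_noise_cv < 0) abort("`intake_noise_cv` must be >= 0.", class = "clquant_config_error")
  structure(list(ec50 = ec50, hill_n = hill_n, baseline_eir = baseline_eir,
                 intake1_mean = intake1_mean, intake_noise_cv = intake_noise_cv,
                 n_mice = n_mice),
            class = "behavior_params")
}

#' NKCC1-null behavior preset
#'
#' Knockout cohort defaults: avoidance EC50 17.3 uM, water-day ratio 1.15,
#' first-exposure intake 176 ul.
#'
#' @param ... Overrides passed to [behavior_params()].
#' @return A `behavior_params` object.
#' @export
ko_behavior_params <- function(...) {
  behavior_params(ec50 = 17.3, baseline_eir = 1.15, intake1_mean = 176, ...)
}

#' Parameters of synthetic Fura-2 calcium transients
#'
#' Each stimulus evokes a ratio transient with a difference-of-exponentials
#' time course. The transient amplitude scales with the chloride-dependent
#' amplification term
#' \deqn{A(cell) = amplitude \times (1 + \alpha \, \max(0, [Cl^-]_i - c^*)/c^*)}
#' where \eqn{c^*} is the critical chloride concentration for efflux
#' (17.7 mM at the default recording conditions). The default `alpha` is
#' calibrated so the knockout-to-wild-type mean amplitude ratio over the two
#' default populations is 0.615, i.e. a 38.5 percent amplitude reduction in
#' the low-chloride population.
#'
#' @param amplitude Base ratio amplitude (dimensionless f340/f380 units) of
#'   a transient with no chloride amplification.
#' @param tau_rise,tau_decay Rise and decay time constants (s).
#' @param alpha Amplification factor (dimensionless).
#' @param critical_cl Critical chloride concentration (mM) above which
#'   amplification engages.
#' @param baseline_ratio Resting f340/f380 ratio.
#' @param f380_base Resting 380-nm channel fluorescence (arbitrary units).
#' @param noise_sd Additive per-frame noise SD on each raw channel, relative
#'   to that channel's baseline.
#' @return A list of class `fura_params`.
#' @export
fura_params <- function(amplitude = 0.5, tau_rise = 2, tau_decay = 10,
                        alpha = 0.652, critical_cl = 17.7,
                        baseline_ratio = 0.8, f380_base = 1000,
                        noise_sd = 0.005) {
  if (amplitude < 0) abort("`amplitude` must be >= 0.", class = "clquant_config_error")
  if (tau_rise <= 0 || tau_decay <= 0) {
    abort("Time constants must be > 0.", class = "clquant_config_error")
  }
  if (critical_cl <= 0) abort("`critical_cl` must be > 0.", class = "clquant_config_error")
  if (f380_base <= 0) abort("`f380_base` must be > 0.", class = "clquant_config_error")
  structure(list(amplitude = amplitude, tau_rise = tau_rise,
                 tau_decay = tau_decay, alpha = alpha,
                 critical_cl = critical_cl, baseline_ratio = baseline_ratio,
                 f380_base = f380_base, noise_sd = noise_sd),
            class = "fura_params")
}
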