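# Nernst-equation computations for chloride: reversal potential, critical
# intracellular concentration for efflux, driving force, and the predicted
# efflux-competent fraction of a population.

#' Recording conditions for equilibrium calculations
#'
#' Bundles the external chloride concentration, resting membrane potential
#' and the Nernst decade slope (mV per tenfold concentration ratio). The
#' default slope of 58.0 mV/decade is the rounded constant conventionally
#' used at room temperature and reproduces the reference values computed at
#' these recording conditions (critical \eqn{[Cl^-]_i} 17.7 mM at -54 mV,
#' 151 mM external chloride). Alternatively, supply `temperature_c` to use
#' the physically exact slope \eqn{2.303\,RT/F} (58.57 mV/decade at 22 C),
#' which shifts the critical concentration to about 18.1 mM.
#'
#' @param cl_out_mM External chloride concentration (mM).
#' @param rmp_mV Resting membrane potential (mV, inside relative to outside).
#' @param decade_slope_mV Slope in mV per decade. Ignored when
#'   `temperature_c` is given.
#' @param temperature_c Optional temperature (Celsius) from which to derive
#'   the slope.
#' @return A list of class `equilibrium_context` with fields `cl_out_mM`,
#'   `rmp_mV`, `decade_slope_mV`, `slope_mode`.
#' @export
#' @examples
#' ctx <- equilibrium_context()
#' critical_cli(ctx)
equilibrium_context <- function(cl_out_mM = 151, rmp_mV = -54,
                                decade_slope_mV = 58,
                                temperature_c = NULL) {
  if (cl_out_mM <= 0) abort("`cl_out_mM` must be > 0.", class = "clquant_config_error")
  if (!is.null(temperature_c)) {
    decade_slope_mV <- nernst_decade_slope(temperature_c)
    mode <- "temperature"
  } else {
    mode <- "fixed"
  }
  if (decade_slope_mV <= 0) {
    abort("`decade_slope_mV` must be > 0.", class = "clquant_config_error")
  }
  structure(list(cl_out_mM = cl_out_mM, rmp_mV = rmp_mV,
                 decade_slope_mV = decade_slope_mV, slope_mode = mode),
            class = "equilibrium_context")
}

#' Nernst decade slope at a given temperature
#'
#' \eqn{2.303 \, R T / F} in mV per tenfold concentration ratio.
#'
#' @param temperature_c Temperature in Celsius.
#' @return Slope in mV/decade (58.57 at 22 C).
#' @export
nernst_decade_slope <- function(temperature_c) {
  r_gas <- 8.314462618   # J / (mol K)
  faraday <- 96485.33212 # C / mol
  1000 * log(10) * r_gas * (temperature_c + 273.15) / faraday
}

#' Chloride reversal potential
#'
#' For a monovalent anion the Nernst potential reduces to
#' \eqn{E_{Cl} = s \, \log_{10}([Cl^-]_i / [Cl^-]_o)} with s the decade
#' slope; it is negative when internal chloride is below external.
#'
#' @param cl_i_mM Intracellular chloride (mM); vectorised.
#' @param ctx An [equilibrium_context()].
#' @return Reversal potential(s) in mV.
#' @export
#' @examples
#' nernst_ecl(34.1, equilibrium_context())  # about -37.5 mV
nernst_ecl <- function(cl_i_mM, ctx = equilibrium_context()) {
  stopifnot(inherits(ctx, "equilibrium_context"))
  if (any(cl_i_mM <= 0)) {
    abort("`cl_i_mM` must be > 0.", class = "clquant_domain_error")
  }
  ctx$decade_slope_mV * log10(cl_i_mM / ctx$cl_out_mM)
}

#' Critical intracellular chloride for efflux
#'
#' The concentration at which the chloride reversal potential equals the
#' resting membrane potential: \eqn{c^* = [Cl^-]_o \, 10^{V_m / s}}. Cells
#' above it generate a depolarising chloride efflux when chloride channels
#' open; cells below it take up chloride.
#'
#' @param ctx An [equilibrium_context()].
#' @return Concentration in mM (17.7 at the default conditions).
#' @export
critical_cli <- function(ctx = equilibrium_context()) {
  stopifnot(inherits(ctx, "equilibrium_context"))
  ctx$cl_out_mM * 10^(ctx$rmp_mV / ctx$decade_slope_mV)
}

#' Predicted efflux-competent fraction of a population
#'
#' Fraction of cells whose resting chloride exceeds the critical
#' concentration. Given samples, the empirical fraction is returned; given a
#' Gaussian parameterisation (`mean` and `sd`), the closed form
#' \eqn{\Phi((\mu - c^*)/\sigma)} is used.
#'
#' @param cl_i_mM Numeric vector of per-cell chloride concentrations (mM).
#'   Omit when using `mean`/`sd`.
#' @param ctx An [equilibrium_context()].
#' @param mean,sd Optional Gaussian population parameters (mM).
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' efflux_fraction(mean = 34.1, sd = 27.6)  # about 0.72
efflux_fraction <- function(cl_i_mM = NULL, ctx = equilibrium_context(),
                            mean = NULL, sd = NULL) {
  crit <- critical_cli(ctx)
  if (!is.null(mean) && !is.null(sd)) {
    if (sd <= 0) abort("`sd` must be > 0 for the closed form.",
                       class = "clquant_domain_error")
    return(pnorm((mean - crit) / sd))
  }
  if (is.null(cl_i_mM) || length(cl_i_mM) == 0) {
    abort("Provide per-cell concentrations or a Gaussian mean and sd.",
          class = "clquant_domain_error")
  }
  base::mean(cl_i_mM > crit)
}

#' Equilibrium classification of cells
#'
#' Bundles, per cell, the reversal potential, the critical concentration,
#' the driving force (RMP minus reversal potential) and whether a
#' depolarising efflux is predicted (strictly above the critical
#' concentration).
#'
#' @param cl_i_mM Intracellular chloride (mM); vectorised.
#' @param ctx An [equilibrium_context()].
#' @return A tibble with columns `cl_i_mM`, `e_cl_mV`, `critical_cl_mM`,
#'   `driving_force_mV`, `efflux_predicted`.
#' @export
classify_equilibrium <- function(cl_i_mM, ctx = equilibrium_context()) {
  e_cl <- nernst_ecl(cl_i_mM, ctx)
  crit <- critical_cli(ctx)
  tibble(cl_i_mM = cl_i_mM,
         e_cl_mV = e_cl,
         critical_cl_mM = crit,
         driving_force_mV = ctx$rmp_mV - e_cl,
         efflux_predicted = cl_i_mM > crit)
}

#' @export
print.equilibrium_context <- function(x, ...) {
  cat("Equilibrium context\n")
  cat(sprintf("  [Cl-]o: %g mM, RMP: %g mV, slope: %.2f mV/decade (%s)\n",
              x$cl_out_mM, x$rmp_mV, x$decade_slope_mV, x$slope_mode))
  cat(sprintf("  critical [Cl-]i: %.2f mM\n", critical_cli(x)))
  invisible(x)
}
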