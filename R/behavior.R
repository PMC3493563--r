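# Brief-access drinking analysis: per-session Exposure Intake Ratio (EIR)
# and the concentration-avoidance curve with its EC50.

#' Exposure Intake Ratios of drinking sessions
#'
#' The avoidance statistic: the volume consumed during the second exposure
#' normalised to the first exposure of the same mouse, which controls for
#' between-animal differences in overall water consumption. Sessions with a
#' zero first intake cannot form a ratio and are dropped with a message
#' (animals sample the fluid on essentially every test, so this is
#' exceptional).
#'
#' @param sessions Tibble with `mouse_id`, `genotype`, `concentration_uM`,
#'   `intake1_ul`, `intake2_ul`, `session_type`.
#' @return The sessions that have `intake1_ul > 0`, with an `eir` column.
#' @export
#' @examples
#' s <- tibble::tibble(mouse_id = "m1", genotype = "WT", concentration_uM = 10,
#'                     intake1_ul = 242, intake2_ul = 264,
#'                     session_type = "solvent_capsaicin")
#' exposure_intake_ratio(s)$eir
exposure_intake_ratio <- function(sessions) {
  if (any(sessions$intake1_ul < 0 | sessions$intake2_ul < 0)) {
    abort("Intakes must be >= 0.", class = "clquant_data_error")
  }
  bad <- sessions$intake1_ul == 0
  if (any(bad)) {
    inform(sprintf("Excluding %d session(s) with zero first-exposure intake.",
                   sum(bad)))
  }
  sessions |>
    filter(.data$intake1_ul > 0) |>
    mutate(eir = .data$intake2_ul / .data$intake1_ul)
}

#' Concentration-avoidance curve for one genotype
#'
#' Computes the mean Exposure Intake Ratio (with SEM) at each capsaicin
#' concentration and fits a descending Hill curve across concentrations;
#' the fitted midpoint is the avoidance EC50.
#'
#' Intake ratios carry multiplicative noise (the variance of the ratio
#' grows with its mean), so by default the per-concentration ratios are
#' summarised for fitting by their geometric mean and the fit weights each
#' point by the inverse of its squared value — together equivalent, to
#' second order, to least squares on the log ratio, which is homoskedastic
#' under this noise model. Arithmetic means with inverse-SEM^2 weights are
#' available via `eir_scale = "linear"`, and are used automatically when
#' any ratio is zero (complete refusal) since the geometric mean is then
#' undefined. The reported per-concentration summary is always the
#' arithmetic mean with SEM, matching how such curves are plotted.
#'
#' The curve's lower asymptote is pinned at 0 (a saturating aversive
#' concentration drives intake to complete refusal); the top is fitted
#' rather than fixed at the water-day ratio, since solvent-day and
#' water-day baselines may differ. Flat (no-avoidance) data yield a
#' degenerate flag with an undefined EC50 instead of an error.
#'
#' @param sessions Session tibble for a single genotype (water/water control
#'   rows with concentration 0 are ignored by the fit).
#' @param min_mice Minimum mice per concentration (warning below).
#' @param eir_scale `"log"` (geometric-mean fit, default) or `"linear"`.
#' @return An object of class `avoidance_curve`: `genotype`, `summary`
#'   (per-concentration tibble `concentration_uM`, `mean_eir`, `sem_eir`,
#'   `n`), `fit` (a `hill_fit` or `NULL` when degenerate), `ec50`,
#'   `degenerate`.
#' @export
avoidance_curve <- function(sessions, min_mice = 2,
                            eir_scale = c("log", "linear")) {
  eir_scale <- match.arg(eir_scale)
  withratio <- if ("eir" %in% names(sessions)) sessions else exposure_intake_ratio(sessions)
  caps <- filter(withratio, .data$session_type == "solvent_capsaicin",
                 .data$concentration_uM > 0)
  if (nrow(caps) == 0) {
    abort("No capsaicin sessions to analyse.", class = "clquant_data_error")
  }
  summ <- caps |>
    group_by(.data$concentration_uM) |>
    summarise(mean_eir = base::mean(.data$eir),
              gm_eir = if (all(.data$eir > 0)) exp(base::mean(log(.data$eir))) else NA_real_,
              sem_eir = if (n() > 1) sd(.data$eir) / sqrt(n()) else NA_real_,
              n = n(), .groups = "drop") |>
    arrange(.data$concentration_uM)
  if (nrow(summ) < 4) {
    warn("Fewer than 4 concentrations; avoidance fit may be poorly determined.")
  }
  if (any(summ$n < min_mice)) {
    warn("Some concentrations have fewer mice than `min_mice`.")
  }
  genotype <- if ("genotype" %in% names(caps)) unique(caps$genotype)[1] else NA_character_
  use_log <- eir_scale == "log" && !anyNA(summ$gm_eir)
  pts <- tibble(concentration_uM = summ$concentration_uM,
                response = if (use_log) summ$gm_eir else summ$mean_eir,
                sem = summ$sem_eir)
  fit <- NULL
  degenerate <- FALSE
  if (sd(pts$response) == 0) {
    degenerate <- TRUE
  } else if (use_log) {
    w <- 1 / pmax(pts$response, max(pts$response) * 1e-3)^2
    fit <- fit_hill(pts, direction = "inhibition",
                    init_overrides = list(bottom = 0),
                    weights = w, fix = list(bottom = 0))
    degenerate <- !fit$converged
  } else {
    fit <- fit_hill(pts, direction = "inhibition",
                    init_overrides = list(bottom = 0),
                    weighted = TRUE, fix = list(bottom = 0))
    degenerate <- !fit$converged
  }
  structure(list(genotype = genotype, summary = summ, fit = fit,
                 ec50 = if (degenerate || is.null(fit)) NA_real_ else fit$ec50,
                 degenerate = degenerate),
            class = "avoidance_curve")
}

#' Horizontal shift between two avoidance curves
#'
#' The log10 ratio of the two fitted EC50s; positive when curve `b` lies to
#' the right of (is less sensitive than) curve `a`.
#'
#' @param curve_a,curve_b `avoidance_curve` objects with converged fits.
#' @return Shift in log10 concentration units.
#' @export
#' @examples
#' # log10(17.3 / 6.4) = 0.432
curve_shift <- function(curve_a, curve_b) {
  for (cv in list(curve_a, curve_b)) {
    if (cv$degenerate || is.null(cv$fit) || !cv$fit$converged) {
      abort("Both avoidance fits must have converged.",
            class = "clquant_fit_error")
    }
  }
  log10(curve_b$ec50 / curve_a$ec50)
}

#' @export
print.avoidance_curve <- function(x, ...) {
  cat(sprintf("Avoidance curve (%s): %d concentrations\n",
              x$genotype, nrow(x$summary)))
  if (x$degenerate) {
    cat("  degenerate (no avoidance detected); EC50 undefined\n")
  } else {
    cat(sprintf("  EC50: %.3g uM (Hill n %.3g, top %.3g)\n",
                x$ec50, x$fit$hill_n, x$fit$top))
  }
  invisible(x)
}

#' Tidy an avoidance curve
#'
#' @param x An `avoidance_curve`.
#' @param ... Unused.
#' @return The per-concentration summary tibble with the genotype attached.
#' @export
tidy.avoidance_curve <- function(x, ...) {
  mutate(x$summary, genotype = x$genotype, .before = 1)
}

#' Glance at an avoidance curve
#'
#' @param x An `avoidance_curve`.
#' @param ... Unused.
#' @return One-row tibble: `genotype`, `ec50_uM`, `hill_n`, `top`,
#'   `degenerate`.
#' @export
glance.avoidance_curve <- function(x, ...) {
  tibble(genotype = x$genotype, ec50_uM = x$ec50,
         hill_n = if (is.null(x$fit)) NA_real_ else x$fit$hill_n,
         top = if (is.null(x$fit)) NA_real_ else x$fit$top,
         degenerate = x$degenerate)
}

#' Plot an avoidance curve
#'
#' Mean Exposure Intake Ratio (+/- SEM) against concentration with the
#' fitted descending Hill curve.
#'
#' @param object An `avoidance_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.avoidance_curve <- function(object, ...) {
  s <- object$summary
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$concentration_uM,
                                       y = .data$mean_eir)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_eir - .data$sem_eir,
      ymax = .data$mean_eir + .data$sem_eir)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "capsaicin (uM)", y = "Exposure Intake Ratio",
                  title = sprintf("%s avoidance: EC50 %.3g uM",
                                  object$genotype, object$ec50)) +
    ggplot2::theme_minimal()
  if (!object$degenerate) {
    grid <- tibble(concentration_uM = 10^seq(log10(min(s$concentration_uM)) - 0.3,
                                             log10(max(s$concentration_uM)) + 0.3,
                                             length.out = 200))
    grid$mean_eir <- predict(object$fit, grid$concentration_uM)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}

#' Long-format ratio table for group statistics
#'
#' Emits the tidy per-session table (`mouse_id`, `genotype`,
#' `concentration_uM`, `eir`) consumed by standard repeated-measures
#' routines (e.g. `stats::aov` or afex/lme4 models); group-level inference
#' itself is delegated to those routines.
#'
#' @param sessions Session tibble (any genotypes).
#' @return Tidy tibble, capsaicin sessions only.
#' @export
eir_long_table <- function(sessions) {
  exposure_intake_ratio(sessions) |>
    filter(.data$session_type == "solvent_capsaicin") |>
    select("mouse_id", "genotype", "concentration_uM", "eir")
}
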