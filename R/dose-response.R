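# Hill-equation fitting for activation (EC50) and inhibition (IC50) curves.
# Nonlinear least squares via Levenberg-Marquardt (minpack.lm) on
# log10(EC50) for conditioning, with asymptotic standard errors from the
# Jacobian.

hill_curve <- function(c_uM, ec50, hill_n, top, bottom, direction) {
  if (direction == "activation") {
    bottom + (top - bottom) / (1 + (ec50 / c_uM)^hill_n)
  } else {
    bottom + (top - bottom) / (1 + (c_uM / ec50)^hill_n)
  }
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of the four-parameter Hill equation. For activation,
#' \deqn{r(c) = bottom + (top - bottom) / (1 + (EC_{50}/c)^{n})}
#' (increasing in c, `top` is the saturating response); for inhibition the
#' mirrored form \eqn{1/(1 + (c/IC_{50})^n)} is used (decreasing in c,
#' `top` is the response at zero dose). The midpoint is fitted on a log10
#' scale and bounded within two decades of the sampled concentrations; the
#' Hill coefficient within (0, 10].
#'
#' Initial values: top/bottom from the response extremes, the Hill
#' coefficient at 1, and the midpoint at the geometric mean of the two
#' concentrations bracketing the half-range response.
#'
#' @param points Tibble with `concentration_uM` (> 0) and `response`;
#'   optional `sem` enables 1/sem^2 weighting when `weighted = TRUE`.
#' @param direction `"activation"` or `"inhibition"`.
#' @param init_overrides Optional named list overriding initial values
#'   (`ec50`, `hill_n`, `top`, `bottom`).
#' @param weighted Use 1/sem^2 weights when an `sem` column is present.
#' @param weights Optional explicit per-point weight vector (overrides
#'   `weighted`).
#' @param fix Optional named list pinning parameters instead of fitting
#'   them, e.g. `list(bottom = 0)` when the lower asymptote is known.
#' @return An object of class `hill_fit` with elements `ec50`, `hill_n`,
#'   `top`, `bottom`, `se_ec50`, `se_hill`, `converged`, `rss`,
#'   `direction`, `data`. Non-convergence is reported with a warning, not an
#'   error; flat responses are a degenerate-fit error.
#' @export
#' @examples
#' c_uM <- c(1, 3, 10, 30, 100, 300)
#' pts <- tibble::tibble(concentration_uM = c_uM,
#'                       response = 1 / (1 + (24.7 / c_uM)^2.1))
#' fit <- fit_hill(pts, "activation")
#' fit$ec50
fit_hill <- function(points, direction = c("activation", "inhibition"),
                     init_overrides = NULL, weighted = FALSE,
                     weights = NULL, fix = NULL) {
  direction <- match.arg(direction)
  conc <- points$concentration_uM
  resp <- points$response
  if (any(conc <= 0)) {
    abort("Concentrations must be > 0 (handle zero dose as a baseline anchor).",
          class = "clquant_data_error")
  }
  if (length(unique(conc)) < 4) {
    warn("Fewer than 4 distinct concentrations; Hill fit may be poorly determined.")
  }
  if (sd(resp) == 0) {
    abort("All responses are equal; degenerate dose-response data.",
          class = "clquant_degenerate_fit_error")
  }
  w <- if (!is.null(weights)) {
    stopifnot(length(weights) == length(resp), all(weights > 0))
    weights
  } else if (weighted && "sem" %in% names(points) &&
             isTRUE(all(points$sem > 0))) {
    1 / points$sem^2
  } else {
    rep(1, length(resp))
  }

  top0 <- max(resp)
  bottom0 <- min(resp)
  half <- (top0 + bottom0) / 2
  ord <- order(conc)
  cs <- conc[ord]
  rs <- resp[ord]
  above <- if (direction == "activation") rs >= half else rs <= half
  i <- which(above)[1]
  ec0 <- if (is.na(i) || i == 1) exp(base::mean(log(range(conc)))) else sqrt(cs[i - 1] * cs[i])
  init <- list(ec50 = ec0, hill_n = 1, top = top0, bottom = bottom0)
  init[names(init_overrides)] <- init_overrides

  lo_l <- log10(min(conc)) - 2
  hi_l <- log10(max(conc)) + 2
  par_full <- c(lec50 = min(max(log10(init$ec50), lo_l), hi_l),
                hill_n = init$hill_n, top = init$top, bottom = init$bottom)
  lower_full <- c(lec50 = lo_l, hill_n = 1e-3, top = -Inf, bottom = -Inf)
  upper_full <- c(lec50 = hi_l, hill_n = 10, top = Inf, bottom = Inf)
  fixed <- unlist(fix) %||% numeric(0)
  if ("ec50" %in% names(fixed)) {
    fixed <- c(fixed[setdiff(names(fixed), "ec50")],
               lec50 = log10(unname(fixed[["ec50"]])))
  }
  free <- setdiff(names(par_full), names(fixed))
  assemble <- function(p_free) {
    full <- par_full
    full[free] <- p_free
    full[names(fixed)] <- fixed
    full
  }
  resid_fn <- function(p_free) {
    p <- assemble(p_free)
    sqrt(w) * (resp - hill_curve(conc, 10^p[["lec50"]], p[["hill_n"]],
                                 p[["top"]], p[["bottom"]], direction))
  }
  fit <- minpack.lm::nls.lm(
    par = par_full[free], fn = resid_fn,
    lower = lower_full[free],
    upper = upper_full[free],
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  converged <- fit$info %in% 1:4
  if (!converged) {
    warn(sprintf("Hill fit did not converge (info = %d); parameters reported anyway.",
                 fit$info))
  }
  p <- assemble(fit$par)
  ses_free <- hill_se(fit, length(resp))
  ses <- setNames(rep(NA_real_, length(par_full)), names(par_full))
  ses[names(ses_free)] <- ses_free
  structure(list(
    direction = direction,
    ec50 = 10^p[["lec50"]],
    hill_n = p[["hill_n"]],
    top = p[["top"]],
    bottom = p[["bottom"]],
    se_ec50 = log(10) * 10^p[["lec50"]] * ses[["lec50"]],
    se_hill = ses[["hill_n"]],
    converged = converged,
    rss = sum(fit$fvec^2),
    n = length(resp),
    data = as_tibble(points)
  ), class = "hill_fit")
}

# asymptotic SEs: sigma^2 (J'J)^-1 from the final Jacobian
hill_se <- function(fit, n_obs) {
  p <- length(fit$par)
  ses <- rep(NA_real_, p)
  names(ses) <- names(fit$par)
  if (n_obs > p) {
    sigma2 <- sum(fit$fvec^2) / (n_obs - p)
    jtj <- fit$hessian  # nls.lm stores J'J
    cov <- try(solve(jtj) * sigma2, silent = TRUE)
    if (!inherits(cov, "try-error")) ses <- sqrt(pmax(diag(cov), 0))
  }
  ses
}

#' Predict responses from a Hill fit
#'
#' @param object A `hill_fit`.
#' @param concentrations Concentrations (uM) at which to evaluate the curve.
#' @param ... Unused.
#' @return Numeric vector of responses.
#' @export
predict.hill_fit <- function(object, concentrations, ...) {
  hill_curve(concentrations, object$ec50, object$hill_n, object$top,
             object$bottom, object$direction)
}

#' @export
print.hill_fit <- function(x, ...) {
  lab <- if (x$direction == "activation") "EC50" else "IC50"
  cat(sprintf("Hill fit (%s)\n", x$direction))
  cat(sprintf("  %s: %.4g uM (SE %.3g), Hill n: %.3g (SE %.3g)\n",
              lab, x$ec50, x$se_ec50, x$hill_n, x$se_hill))
  cat(sprintf("  top: %.4g, bottom: %.4g, RSS: %.3g, converged: %s\n",
              x$top, x$bottom, x$rss, x$converged))
  invisible(x)
}

#' Tidy a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `std.error`).
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c(if (x$direction == "activation") "ec50" else "ic50",
                  "hill_n", "top", "bottom"),
         estimate = c(x$ec50, x$hill_n, x$top, x$bottom),
         std.error = c(x$se_ec50, x$se_hill, NA_real_, NA_real_))
}

#' Glance at a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return One-row tibble with fit diagnostics.
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n, converged = x$converged,
         direction = x$direction)
}

#' Plot a Hill fit
#'
#' Data points with the fitted curve on a log10 concentration axis.
#'
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hill_fit <- function(object, ...) {
  conc <- object$data$concentration_uM
  grid <- tibble(concentration_uM = 10^seq(log10(min(conc)) - 0.3,
                                           log10(max(conc)) + 0.3,
                                           length.out = 200))
  grid$response <- predict(object, grid$concentration_uM)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration_uM, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (uM)", y = "response",
                  title = sprintf("%s fit: midpoint %.3g uM, Hill n %.2g",
                                  object$direction, object$ec50, object$hill_n)) +
    ggplot2::theme_minimal()
}
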