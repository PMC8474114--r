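#' Plot a transport kinetics fit
#'
#' SHG field vs time with the fitted exponential overlaid.
#'
#' @param object A `transport_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.transport_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$E), alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "#2166ac",
                       linewidth = 0.8) +
    ggplot2::labs(
      x = "time since dye addition (s)",
      y = expression(E[SHG] ~ "(normalized)"),
      title = sprintf("Transport fit: tau = %.3g +/- %.2g s", object$tau, object$tau_se),
      subtitle = sprintf("R² = %.4f", object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Langmuir isotherm fit
#'
#' Measured time-zero intensities vs added concentration with the fitted
#' depletion-corrected Langmuir curve.
#'
#' @param object A `langmuir_fit`.
#' @param n_curve Points used to draw the smooth fitted curve.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.langmuir_fit <- function(object, n_curve = 200, ...) {
  d <- object$per_point
  Cs <- seq(0, max(d$conc_uM), length.out = n_curve)
  curve <- tibble(
    conc_uM = Cs,
    intensity = shg_isotherm_model(Cs, object$K, object$Nmax, object$A,
                                   object$B, object$alpha,
                                   coverage_exponent = object$coverage_exponent,
                                   water_conc = object$water_conc)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$conc_uM, y = .data$intensity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, color = "#2166ac") +
    ggplot2::labs(
      x = "added dye concentration (µM)",
      y = "time-zero SHG intensity (normalized)",
      title = sprintf("Modified Langmuir fit: K = %.3g, Nmax = %.3g µM",
                      object$K, object$Nmax)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a van't Hoff decomposition
#'
#' Adsorption free energy vs temperature with the fitted line
#' dG = dH - T dS.
#'
#' @param object A `vant_hoff_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.vant_hoff_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$temp_K, y = .data$dG)) +
    ggplot2::geom_point()
  if ("dG_se" %in% names(d) && any(is.finite(d$dG_se))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$dG - .data$dG_se, ymax = .data$dG + .data$dG_se),
      width = 0.4
    )
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "#2166ac") +
    ggplot2::labs(
      x = "temperature (K)",
      y = expression(Delta * G ~ "(kcal/mol)"),
      title = sprintf("dH = %.3g kcal/mol, dS = %.3g kcal/(mol K)",
                      object$dH, object$dS)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a potential of mean force
#'
#' Free energy vs the collective variable z, with a block-averaged error
#' ribbon when available.
#'
#' @param object A `pmf_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pmf_profile <- function(object, ...) {
  d <- object$profile %>% filter(is.finite(.data$W))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$z, y = .data$W))
  if (any(is.finite(d$err))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$W - .data$err, ymax = .data$W + .data$err),
      fill = "grey70", alpha = 0.5
    )
  }
  p +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::labs(
      x = "z, membrane–dye COM separation (Å)",
      y = "W(z) (kcal/mol)",
      title = sprintf("Potential of mean force at %g K", object$temp_K)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an orientation distribution
#'
#' Normalized cos(theta) histograms per group.
#'
#' @param object An `orientation_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.orientation_distribution <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_mid, y = .data$prob,
                               fill = .data$group)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5,
                      width = diff(object$breaks)[1]) +
    ggplot2::labs(
      x = expression(cos ~ theta ~ "(dipole vs membrane normal)"),
      y = "probability", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot transport rates vs concentration and temperature
#'
#' Rate constants k = 1/tau against concentration, one line per temperature.
#'
#' @param object A `rate_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rate_summary <- function(object, ...) {
  ggplot2::ggplot(object$rates,
                  ggplot2::aes(x = .data$conc_uM, y = .data$rate,
                               color = factor(.data$temp_K))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = object$per_temperature,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   color = factor(.data$temp_K))
    ) +
    ggplot2::labs(
      x = "added dye concentration (µM)",
      y = expression(k == 1 / tau ~ (s^-1)),
      color = "T (K)"
    ) +
    ggplot2::theme_minimal()
}
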