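#' Adsorption free energy from the equilibrium constant
#'
#' \eqn{\Delta G = -RT \ln K} with R = 1.9872e-3 kcal mol^-1 K^-1. K must be
#' dimensionless (water-reference convention); a first-order (delta-method)
#' uncertainty \eqn{\sigma_{\Delta G} = RT \, \sigma_K / K} is propagated
#' when `K_se` is given. Vectorized over temperatures.
#'
#' @param K Equilibrium constant(s), dimensionless, > 0.
#' @param temp Temperature(s) in kelvin.
#' @param K_se Optional standard error(s) on K.
#'
#' @return A tibble with columns `temp_K`, `K`, `dG` (kcal/mol) and `dG_se`.
#' @export
#' @examples
#' adsorption_free_energy(K = 9.1e7, temp = 298.15) # about -10.86 kcal/mol
adsorption_free_energy <- function(K, temp, K_se = NULL) {
  if (any(!is.finite(K)) || any(K <= 0)) abort("`K` must be > 0.")
  if (any(temp <= 0)) abort("`temp` must be > 0 (kelvin).")
  n <- max(length(K), length(temp))
  K <- rep_len(K, n)
  temp <- rep_len(temp, n)
  dG <- -.R_KCAL * temp * log(K)
  dG_se <- if (is.null(K_se)) rep(NA_real_, n) else {
    .R_KCAL * temp * rep_len(K_se, n) / K
  }
  tibble(temp_K = temp, K = K, dG = dG, dG_se = dG_se)
}

#' Van't Hoff decomposition of the adsorption free energy
#'
#' Fits the line \eqn{\Delta G(T) = \Delta H - T \Delta S} by least squares:
#' the intercept is the adsorption enthalpy change and minus the slope the
#' entropy change. The default fit is unweighted; `weighted = TRUE` weights
#' by `1/dG_se^2` when uncertainties are available (with equal uncertainties
#' the two coincide). Parameter standard errors come from the regression
#' covariance scaled by the residual variance.
#'
#' @param data A tibble with columns `temp_K` and `dG` (kcal/mol), optional
#'   `dG_se` — e.g. the output of [adsorption_free_energy()].
#' @param weighted Weight by `1/dG_se^2` when available.
#' @param scale_errors If `TRUE` (default), parameter standard errors are
#'   scaled by the residual variance (ordinary regression SEs). With
#'   `weighted = TRUE` and trustworthy measurement uncertainties,
#'   `scale_errors = FALSE` propagates the supplied `dG_se` directly
#'   (known-variance mode) — more honest when the fit has few points and the
#'   residual variance is itself poorly estimated.
#'
#' @return An object of class `vant_hoff_fit` with `dH`, `dS` (kcal/mol and
#'   kcal/(mol K)) and their standard errors; see [tidy()], [glance()],
#'   [autoplot()].
#' @export
#' @examples
#' dG <- adsorption_free_energy(K = c(9.1, 8.1, 7.2, 6.2) * 1e7,
#'                              temp = c(298.15, 303.15, 308.15, 313.15))
#' vant_hoff(dG)
vant_hoff <- function(data, weighted = FALSE, scale_errors = TRUE) {
  check_columns(data, c("temp_K", "dG"), "Free-energy series")
  d <- data %>% distinct(.data$temp_K, .keep_all = TRUE)
  if (nrow(d) < nrow(data)) {
    warn("Duplicate temperatures collapsed to their first occurrence.")
  }
  if (nrow(d) < 2 || diff(range(d$temp_K)) <= 0) {
    abort("At least 2 distinct temperatures spanning a nonzero range are required.")
  }
  if (nrow(d) < 3) {
    warn("Only 2 temperatures: the van't Hoff line is exactly determined, standard errors are undefined.")
  }
  use_w <- weighted && "dG_se" %in% names(d) &&
    all(is.finite(d$dG_se)) && all(d$dG_se > 0)
  m <- if (use_w) {
    lm(dG ~ temp_K, data = d, weights = 1 / d$dG_se^2)
  } else {
    lm(dG ~ temp_K, data = d)
  }
  cf <- summary(m)$coefficients
  dH <- cf["(Intercept)", "Estimate"]
  dS <- -cf["temp_K", "Estimate"]
  if (use_w && !scale_errors) {
    # known-variance propagation: cov = (X' W X)^-1, no residual scaling
    X <- cbind(1, d$temp_K)
    cv <- solve(t(X) %*% (X / d$dG_se^2))
    dH_se <- sqrt(cv[1, 1])
    dS_se <- sqrt(cv[2, 2])
  } else {
    dH_se <- if (nrow(d) > 2) cf["(Intercept)", "Std. Error"] else NA_real_
    dS_se <- if (nrow(d) > 2) cf["temp_K", "Std. Error"] else NA_real_
  }

  structure(
    list(
      dH = dH, dH_se = dH_se, dS = dS, dS_se = dS_se,
      r_squared = summary(m)$r.squared,
      sigma = summary(m)$sigma,
      n = nrow(d), weighted = use_w,
      data = d %>% mutate(fitted = unname(stats::fitted(m))),
      fit = m
    ),
    class = "vant_hoff_fit"
  )
}

#' Spontaneity of adsorption over a temperature range
#'
#' Reports the sign of \eqn{\Delta G(T) = \Delta H - T \Delta S} over a
#' temperature range. With \eqn{\Delta H < 0} and \eqn{\Delta S > 0} the
#' process is spontaneous at every positive temperature; otherwise the
#' crossover temperature \eqn{T^* = \Delta H / \Delta S} (when positive)
#' separates the spontaneous and non-spontaneous regimes.
#'
#' @param result A `vant_hoff_fit`, or a list/vector with elements `dH`
#'   and `dS`.
#' @param t_range Temperature range in kelvin (default liquid water,
#'   273--373 K).
#'
#' @return A list with `spontaneous_everywhere` (over `t_range`),
#'   `always_spontaneous` (all T > 0), `crossover_K` (NA when the sign never
#'   changes for T > 0), `dG_range` (ends of the range) and a `message`.
#' @export
#' @examples
#' spontaneity_report(list(dH = -4.685, dS = 0.021))
spontaneity_report <- function(result, t_range = c(273, 373)) {
  dH <- result$dH
  dS <- result$dS
  if (is.null(dH) || is.null(dS)) abort("`result` must provide `dH` and `dS`.")
  if (any(t_range <= 0)) abort("`t_range` must be positive (kelvin).")
  dG_at <- function(T) dH - T * dS
  dG_ends <- dG_at(t_range)
  crossover <- if (sign(dH) == sign(dS) && dS != 0) dH / dS else NA_real_
  if (!is.na(crossover) && crossover <= 0) crossover <- NA_real_
  spont_range <- all(dG_at(seq(t_range[1], t_range[2], length.out = 101)) < 0)
  always <- dH < 0 && dS >= 0
  msg <- if (always) {
    "dH < 0 and dS >= 0: adsorption is spontaneous (dG < 0) at all positive temperatures."
  } else if (dH >= 0 && dS <= 0) {
    "dH >= 0 and dS <= 0: adsorption is never spontaneous for T > 0."
  } else if (!is.na(crossover)) {
    sprintf("dG changes sign at T* = dH/dS = %.4g K; %s above T*.",
            crossover,
            if (dS > 0) "spontaneous" else "non-spontaneous")
  } else {
    "Sign of dG is constant over positive temperatures."
  }
  list(
    spontaneous_everywhere = spont_range,
    always_spontaneous = always,
    crossover_K = crossover,
    dG_range = setNames(dG_ends, paste0("T=", t_range)),
    message = msg
  )
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat("Van't Hoff decomposition: dG(T) = dH - T dS\n")
  cat(sprintf("  dH = %.4g +/- %.3g kcal/mol\n", x$dH, x$dH_se))
  cat(sprintf("  dS = %.4g +/- %.3g kcal/(mol K)\n", x$dS, x$dS_se))
  cat(sprintf("  %d temperatures, R^2 = %.4f%s\n", x$n, x$r_squared,
              if (x$weighted) ", weighted" else ""))
  invisible(x)
}
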