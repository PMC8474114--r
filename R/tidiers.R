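#' Tidy method for transport kinetics fits
#'
#' @param x A `transport_fit`.
#' @param ... Unused.
#' @return One row per parameter (`a0`, `a1`, `tau`) with estimates and
#'   standard errors.
#' @exportS3Method generics::tidy
tidy.transport_fit <- function(x, ...) {
  x$estimates
}

#' @rdname tidy.transport_fit
#' @exportS3Method generics::glance
glance.transport_fit <- function(x, ...) {
  tibble(
    tau = x$tau, tau_se = x$tau_se, r.squared = x$r_squared,
    nobs = x$n, n_clipped = x$n_clipped, weighted = x$weighted,
    conc_uM = x$conc_uM, temp_K = x$temp_K
  )
}

#' Tidy method for Langmuir isotherm fits
#'
#' @param x A `langmuir_fit`.
#' @param ... Unused.
#' @return One row per parameter (`K`, `Nmax`, `A`, and `B`/`alpha` when
#'   co-fitted) with estimates and standard errors.
#' @exportS3Method generics::tidy
tidy.langmuir_fit <- function(x, ...) {
  x$estimates
}

#' @rdname tidy.langmuir_fit
#' @exportS3Method generics::glance
glance.langmuir_fit <- function(x, ...) {
  tibble(
    K = x$K, K_se = x$K_se, K_low = x$K_ci[1], K_high = x$K_ci[2],
    Nmax = x$Nmax, Nmax_se = x$Nmax_se,
    r.squared = x$r_squared, df.residual = x$df_residual,
    nobs = nrow(x$per_point), temp_K = x$temp_K
  )
}

#' Tidy method for van't Hoff fits
#'
#' @param x A `vant_hoff_fit`.
#' @param ... Unused.
#' @return One row per thermodynamic parameter (`dH` in kcal/mol, `dS` in
#'   kcal/(mol K)).
#' @exportS3Method generics::tidy
tidy.vant_hoff_fit <- function(x, ...) {
  tibble(
    term = c("dH", "dS"),
    estimate = c(x$dH, x$dS),
    std.error = c(x$dH_se, x$dS_se)
  )
}

#' @rdname tidy.vant_hoff_fit
#' @exportS3Method generics::glance
glance.vant_hoff_fit <- function(x, ...) {
  tibble(
    dH = x$dH, dS = x$dS, r.squared = x$r_squared,
    sigma = x$sigma, nobs = x$n, weighted = x$weighted
  )
}

#' Tidy method for PMF profiles
#'
#' @param x A `pmf_profile`.
#' @param ... Unused.
#' @return The profile tibble (`z`, `W`, `err`, `counts`).
#' @exportS3Method generics::tidy
tidy.pmf_profile <- function(x, ...) {
  x$profile
}

#' @rdname tidy.pmf_profile
#' @exportS3Method generics::glance
glance.pmf_profile <- function(x, ...) {
  tibble(
    temp_K = x$temp_K, bin_width = x$bin_width,
    n_bins = nrow(x$profile),
    n_sampled = sum(is.finite(x$profile$W)),
    iterations = x$iterations, converged = x$converged,
    residual = x$residual, n_samples = x$n_samples
  )
}

#' Tidy method for rate summaries
#'
#' @param x A `rate_summary`.
#' @param ... Unused.
#' @return The per-temperature rate-vs-concentration lines.
#' @exportS3Method generics::tidy
tidy.rate_summary <- function(x, ...) {
  x$per_temperature
}

#' @rdname tidy.rate_summary
#' @exportS3Method generics::glance
glance.rate_summary <- function(x, ...) {
  if (is.null(x$temperature_trend)) {
    tibble(slope = NA_real_, intercept = NA_real_, n_temperatures = nrow(x$per_temperature))
  } else {
    x$temperature_trend %>% mutate(n_temperatures = .data$n) %>% select(-"n")
  }
}

#' Tidy method for orientation distributions
#'
#' @param x An `orientation_distribution`.
#' @param ... Unused.
#' @return Per-group orientation statistics (`mean_cos`, `spread`).
#' @exportS3Method generics::tidy
tidy.orientation_distribution <- function(x, ...) {
  x$stats
}

#' Tidy method for interfacial water counts
#'
#' @param x A `water_count`.
#' @param ... Unused.
#' @return The per-frame counts.
#' @exportS3Method generics::tidy
tidy.water_count <- function(x, ...) {
  x$per_frame
}

#' @rdname tidy.water_count
#' @exportS3Method generics::glance
glance.water_count <- function(x, ...) {
  tibble(mean = x$mean, se = x$se, nobs = x$n,
         cutoff = x$cutoff, side = x$side)
}
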