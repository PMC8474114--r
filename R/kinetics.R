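#' Convert SHG intensity to field
#'
#' The SHG field is the square root of the background-subtracted intensity,
#' \eqn{E = \sqrt{I}}. Negative intensities (possible after background
#' subtraction) are clipped to zero before the square root — the field
#' magnitude is non-negative — and the number of clipped points is recorded.
#' Per-point uncertainties propagate by the delta method,
#' \eqn{\sigma_E = \sigma_I / (2E)}, undefined (NA) where \eqn{E = 0}.
#'
#' @param trace A trace tibble with columns `time`, `intensity` and
#'   optionally `sigma` (see [simulate_shg_trace()] / [read_shg_trace()]).
#'
#' @return The trace with columns `field` and `sigma_field` added;
#'   `attr(, "n_clipped")` counts intensities clipped at zero.
#' @export
#' @examples
#' tr <- simulate_shg_trace(noise_sd = 0, seed = 1)
#' head(shg_field(tr))
shg_field <- function(trace) {
  check_columns(trace, c("time", "intensity"), "Trace")
  if (all(trace$intensity <= 0)) {
    abort("All intensities are <= 0: no SHG signal to convert to field.")
  }
  n_clipped <- sum(trace$intensity < 0)
  if (n_clipped > 0) {
    warn(sprintf("%d negative intensit%s clipped to 0 before sqrt.",
                 n_clipped, if (n_clipped > 1) "ies" else "y"))
  }
  field <- sqrt(pmax(trace$intensity, 0))
  sigma_field <- if ("sigma" %in% names(trace)) {
    ifelse(field > 0, trace$sigma / (2 * field), NA_real_)
  } else {
    rep(NA_real_, length(field))
  }
  out <- trace %>% mutate(field = field, sigma_field = sigma_field)
  attr(out, "n_clipped") <- n_clipped
  attr(out, "truth") <- attr(trace, "truth")
  out
}

#' Normalize a collection of traces to a reference condition
#'
#' All intensities are divided by the time-zero intensity of the reference
#' (concentration, temperature) condition, so the reference trace maps to 1
#' at t = 0 and the output is invariant under a common rescaling of the raw
#' intensities. Mirrors the experimental convention of normalizing to the
#' liposome signal immediately upon addition of 15 uM dye at 25 C.
#'
#' @param traces A long tibble of traces with columns `time`, `intensity`,
#'   `conc_uM`, `temp_K` (and optionally `sigma`, scaled identically).
#' @param ref_conc,ref_temp The reference condition; must be present.
#'
#' @return The traces with `intensity` (and `sigma`) rescaled.
#' @export
normalize_traces <- function(traces, ref_conc = 15, ref_temp = 298.15) {
  check_columns(traces, c("time", "intensity", "conc_uM", "temp_K"), "Trace collection")
  ref <- traces %>%
    filter(.data$conc_uM == ref_conc, .data$temp_K == ref_temp)
  if (nrow(ref) == 0) {
    abort(sprintf(
      "Reference condition (conc = %g uM, temp = %g K) not found in the collection.",
      ref_conc, ref_temp
    ))
  }
  i0 <- ref$intensity[which.min(ref$time)]
  if (!is.finite(i0) || i0 <= 0) {
    abort("Reference time-zero intensity must be positive.")
  }
  out <- traces %>% mutate(intensity = .data$intensity / i0)
  if ("sigma" %in% names(out)) out <- out %>% mutate(sigma = .data$sigma / i0)
  out
}

#' Fit the exponential transport model to one SHG trace
#'
#' Fits \eqn{E(t) = a_0 + a_1 e^{-t/\tau}} to the SHG field by
#' Levenberg--Marquardt least squares, weighted by the propagated field
#' uncertainties when available. The transport time tau is the time constant
#' of the field decay as adsorbed dye crosses to the inner leaflet, where
#' inner- and outer-surface contributions cancel.
#'
#' Initialization is derivative-free and robust: `a0` starts at the mean of
#' the last 10% of the field, `a1` at `E(0) - a0`, and `tau` at the first
#' time where `E - a0` has fallen to `a1 / e` (grid search). `tau` is bounded
#' to `tau_bounds` (default 1 s to 1e6 s, outside any plausible observation
#' window); a fit landing on a bound is flagged with a warning.
#'
#' @param trace A trace tibble; intensity is converted to field via
#'   [shg_field()] unless a `field` column is already present.
#' @param weighted Use `1/sigma_field^2` weights when uncertainties are
#'   available and well defined (default); otherwise unweighted.
#' @param tau_bounds Lower/upper bounds on tau (seconds).
#'
#' @return An object of class `transport_fit`: access parameters with
#'   [tidy()], fit statistics with [glance()], and plot with [autoplot()].
#' @export
#' @examples
#' tr <- simulate_shg_trace(a0 = 0.2, a1 = 0.8, tau = 300, noise_sd = 0.01, seed = 7)
#' fit <- fit_transport_time(tr)
#' tidy(fit)
fit_transport_time <- function(trace, weighted = TRUE, tau_bounds = c(1, 1e6)) {
  if (!"field" %in% names(trace)) trace <- shg_field(trace)
  d <- tibble(t = trace$time, E = trace$field,
              sE = if ("sigma_field" %in% names(trace)) trace$sigma_field else NA_real_)
  if (nrow(d) < 5) {
    abort("At least 5 points are required to fit the transport model.")
  }
  if (sd(d$E) < 1e-12) {
    abort("Trace is constant: the transport time is unidentifiable.")
  }

  # derivative-free initialization
  n_tail <- max(1L, ceiling(0.1 * nrow(d)))
  a0_init <- mean(tail(d$E, n_tail))
  a1_init <- d$E[1] - a0_init
  if (abs(a1_init) < 1e-12) a1_init <- sd(d$E)
  target <- a0_init + a1_init / exp(1)
  crossed <- if (a1_init > 0) which(d$E <= target) else which(d$E >= target)
  tau_init <- if (length(crossed) > 0) max(d$t[crossed[1]], tau_bounds[1]) else
    max(diff(range(d$t)) / 2, tau_bounds[1])
  tau_init <- min(max(tau_init, tau_bounds[1]), tau_bounds[2])
  init <- c(a0 = a0_init, a1 = a1_init, tau = tau_init)

  use_w <- weighted && all(is.finite(d$sE)) && all(d$sE > 0)
  w <- rep(1, nrow(d))

  span <- diff(range(d$t))
  if (span < tau_init) {
    warn(sprintf(
      "Trace spans %.3g s but the initial decay-time estimate is %.3g s; tau may be poorly constrained.",
      span, tau_init
    ))
  }

  do_fit <- function(w, start) {
    tryCatch(
      minpack.lm::nlsLM(
        E ~ a0 + a1 * exp(-t / tau),
        data = d, start = as.list(start), weights = w,
        lower = c(a0 = -Inf, a1 = -Inf, tau = tau_bounds[1]),
        upper = c(a0 = Inf, a1 = Inf, tau = tau_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) {
        abort(sprintf(
          "Transport fit did not converge (%s). Initialization was a0 = %.4g, a1 = %.4g, tau = %.4g.",
          conditionMessage(e), start[["a0"]], start[["a1"]], start[["tau"]]
        ))
      }
    )
  }

  fit <- do_fit(w, init)
  if (use_w) {
    # two-pass weighting: evaluate sigma_E on the first-pass fitted curve, not
    # on the noisy observations — weights built from observed E correlate with
    # the errors and bias tau
    cf1 <- coef(fit)
    E_hat <- pmax(cf1[["a0"]] + cf1[["a1"]] * exp(-d$t / cf1[["tau"]]), 1e-8)
    sI <- if ("sigma" %in% names(trace)) trace$sigma else
      d$sE * 2 * sqrt(pmax(trace$intensity, 0))
    sE_hat <- sI / (2 * E_hat)
    ok <- is.finite(sE_hat) & sE_hat > 0
    if (all(ok)) {
      w <- 1 / sE_hat^2
      fit <- do_fit(w, as.list(cf1))
    } else {
      use_w <- FALSE
    }
  }

  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  if (any(abs(est[["tau"]] - tau_bounds) < 1e-8 * max(1, tau_bounds))) {
    warn(sprintf("Fitted tau = %.4g s sits on a bound; estimate is unreliable.",
                 est[["tau"]]))
  }

  fitted_E <- est[["a0"]] + est[["a1"]] * exp(-d$t / est[["tau"]])
  ss_res <- sum((d$E - fitted_E)^2)
  ss_tot <- sum((d$E - mean(d$E))^2)
  r_squared <- 1 - ss_res / ss_tot

  structure(
    list(
      estimates = tibble(
        term = c("a0", "a1", "tau"),
        estimate = unname(est[c("a0", "a1", "tau")]),
        std.error = unname(se)
      ),
      tau = est[["tau"]], tau_se = unname(se[3]),
      r_squared = r_squared,
      weighted = use_w,
      conc_uM = if ("conc_uM" %in% names(trace)) trace$conc_uM[1] else NA_real_,
      temp_K = if ("temp_K" %in% names(trace)) trace$temp_K[1] else NA_real_,
      n = nrow(d),
      n_clipped = attr(trace, "n_clipped") %||% 0L,
      data = d %>% mutate(fitted = fitted_E),
      fit = fit
    ),
    class = "transport_fit"
  )
}

#' Fit transport times across a collection of traces
#'
#' Splits a long trace tibble by (concentration, temperature), fits each
#' condition with [fit_transport_time()], and returns one row per condition —
#' the shape [rate_analysis()] consumes.
#'
#' @inheritParams fit_transport_time
#' @param traces Long tibble with `time`, `intensity`, `conc_uM`, `temp_K`.
#' @return A tibble with columns `conc_uM`, `temp_K`, `tau`, `tau_se`,
#'   `a0`, `a1`, `r_squared`, `n`.
#' @export
fit_transport_times <- function(traces, weighted = TRUE, tau_bounds = c(1, 1e6)) {
  check_columns(traces, c("time", "intensity", "conc_uM", "temp_K"), "Trace collection")
  traces %>%
    group_by(.data$conc_uM, .data$temp_K) %>%
    dplyr::group_modify(function(d, key) {
      f <- fit_transport_time(d, weighted = weighted, tau_bounds = tau_bounds)
      tibble(
        tau = f$tau, tau_se = f$tau_se,
        a0 = f$estimates$estimate[1], a1 = f$estimates$estimate[2],
        r_squared = f$r_squared, n = f$n
      )
    }) %>%
    ungroup()
}

#' Summarize transport rate constants across concentration and temperature
#'
#' The rate constant is `k = 1/tau`. For each temperature with at least
#' `min_conc` distinct concentrations, `k` is regressed linearly on
#' concentration (ordinary least squares); the per-temperature slopes are
#' then regressed on temperature. Temperatures with too few concentrations
#' are excluded with a warning.
#'
#' @param fits A tibble of fits with columns `conc_uM`, `temp_K`, `tau`
#'   (as returned by [fit_transport_times()]).
#' @param min_conc Minimum distinct concentrations per temperature (default 3).
#'
#' @return An object of class `rate_summary` with components
#'   `per_temperature` (slope/intercept of k vs C per temperature) and
#'   `temperature_trend` (slope-vs-T line; NULL with fewer than 2 usable
#'   temperatures).
#' @export
rate_analysis <- function(fits, min_conc = 3) {
  check_columns(fits, c("conc_uM", "temp_K", "tau"), "Fit table")
  if (any(fits$tau <= 0)) abort("All `tau` values must be > 0.")

  counts <- fits %>%
    group_by(.data$temp_K) %>%
    summarise(n_conc = dplyr::n_distinct(.data$conc_uM), .groups = "drop")
  dropped <- counts$temp_K[counts$n_conc < min_conc]
  if (length(dropped) > 0) {
    warn(sprintf(
      "Temperature%s %s excluded from rate analysis: fewer than %d concentrations.",
      if (length(dropped) > 1) "s" else "",
      paste(format(dropped), collapse = ", "), min_conc
    ))
  }
  usable <- fits %>% filter(!.data$temp_K %in% dropped)
  if (nrow(usable) == 0) abort("No temperature has enough concentrations for rate analysis.")

  per_temp <- usable %>%
    mutate(rate = 1 / .data$tau) %>%
    group_by(.data$temp_K) %>%
    dplyr::group_modify(function(d, key) {
      m <- lm(rate ~ conc_uM, data = d)
      cf <- summary(m)$coefficients
      tibble(
        slope = cf["conc_uM", "Estimate"],
        slope_se = cf["conc_uM", "Std. Error"],
        intercept = cf["(Intercept)", "Estimate"],
        intercept_se = cf["(Intercept)", "Std. Error"],
        r_squared = summary(m)$r.squared,
        n = nrow(d)
      )
    }) %>%
    ungroup()

  trend <- NULL
  if (nrow(per_temp) >= 2) {
    m2 <- lm(slope ~ temp_K, data = per_temp)
    cf2 <- summary(m2)$coefficients
    trend <- tibble(
      slope = cf2["temp_K", "Estimate"],
      slope_se = if (nrow(per_temp) > 2) cf2["temp_K", "Std. Error"] else NA_real_,
      intercept = cf2["(Intercept)", "Estimate"],
      intercept_se = if (nrow(per_temp) > 2) cf2["(Intercept)", "Std. Error"] else NA_real_,
      r_squared = summary(m2)$r.squared,
      n = nrow(per_temp)
    )
  } else {
    warn("Fewer than 2 usable temperatures: slope-vs-temperature line not fitted.")
  }

  structure(
    list(per_temperature = per_temp, temperature_trend = trend,
         excluded_temps = dropped, rates = usable %>% mutate(rate = 1 / .data$tau)),
    class = "rate_summary"
  )
}

#' @export
print.transport_fit <- function(x, ...) {
  cat("SHG transport kinetics fit: E(t) = a0 + a1 * exp(-t/tau)\n")
  cat(sprintf("  tau = %.4g +/- %.2g s   (R^2 = %.4f, n = %d%s)\n",
              x$tau, x$tau_se, x$r_squared, x$n,
              if (x$weighted) ", weighted" else ""))
  if (is.finite(x$conc_uM) || is.finite(x$temp_K)) {
    cat(sprintf("  condition: C = %g uM, T = %g K\n", x$conc_uM, x$temp_K))
  }
  invisible(x)
}

#' @export
print.rate_summary <- function(x, ...) {
  cat("Transport rate summary (k = 1/tau)\n")
  cat("Per-temperature k-vs-C lines:\n")
  print(x$per_temperature)
  if (!is.null(x$temperature_trend)) {
    cat("Slope-vs-temperature line:\n")
    print(x$temperature_trend)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
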