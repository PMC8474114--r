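#' Simulate an SHG transport time trace
#'
#' Generates a background-subtracted, normalized SHG intensity time series for
#' one (concentration, temperature) condition. The underlying SHG field decays
#' exponentially as the adsorbed dye crosses to the inner leaflet,
#' \eqn{E(t) = a_0 + a_1 e^{-t/\tau}}, and the detected intensity is the
#' squared field plus additive Gaussian noise. With `noise_sd = 0` the
#' intensity equals the squared field exactly, so the generator is the exact
#' inverse of [fit_transport_time()].
#'
#' Noise is applied on the intensity (not the field), Gaussian and
#' homoscedastic by default, reflecting shot-noise-dominated
#' background-subtracted CCD spectra; `heteroscedastic = TRUE` scales the
#' noise standard deviation with \eqn{\sqrt{I}} instead.
#'
#' @param a0 Field baseline (normalized field units); the long-time plateau.
#' @param a1 Field decay amplitude.
#' @param tau Transport time constant in seconds; must be positive.
#' @param t_grid Sample times in seconds, strictly increasing. The default
#'   mimics a 1 s acquisition duty cycle with interleaved background frames
#'   (one retained point every 3 s over 30 min).
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param conc Added dye concentration in micromolar (metadata).
#' @param temp Temperature in kelvin (metadata).
#' @param heteroscedastic If `TRUE`, noise sd is `noise_sd * sqrt(I)`.
#' @param seed Optional integer seed; fixed seed gives bit-reproducible output.
#'
#' @return A tibble with columns `time`, `intensity`, `sigma`, `conc_uM`,
#'   `temp_K`. The generating parameters are stored in `attr(, "truth")`.
#' @export
#' @examples
#' tr <- simulate_shg_trace(a0 = 0.2, a1 = 0.8, tau = 300, noise_sd = 0, seed = 1)
#' tr$intensity[1] # (a0 + a1)^2 = 1 at t = 0
simulate_shg_trace <- function(a0 = 0.2, a1 = 0.8, tau = 300,
                               t_grid = seq(0, 1800, by = 3),
                               noise_sd = 0.01, conc = 15, temp = 298.15,
                               heteroscedastic = FALSE, seed = NULL) {
  check_number(a0, "a0")
  check_number(a1, "a1")
  check_number(tau, "tau", positive = TRUE)
  check_number(noise_sd, "noise_sd", non_negative = TRUE)
  check_number(conc, "conc", non_negative = TRUE)
  check_number(temp, "temp", positive = TRUE)
  if (length(t_grid) < 1L || any(diff(t_grid) <= 0)) {
    abort("`t_grid` must be non-empty and strictly increasing.")
  }

  field <- a0 + a1 * exp(-t_grid / tau)
  intensity_clean <- field^2
  sigma <- if (heteroscedastic) {
    noise_sd * sqrt(pmax(intensity_clean, .Machine$double.eps))
  } else {
    rep(noise_sd, length(t_grid))
  }
  intensity <- with_seed_maybe(seed, {
    intensity_clean + rnorm(length(t_grid), sd = sigma)
  })

  out <- tibble(
    time = as.numeric(t_grid),
    intensity = intensity,
    sigma = sigma,
    conc_uM = conc,
    temp_K = temp
  )
  attr(out, "truth") <- list(
    a0 = a0, a1 = a1, tau = tau, noise_sd = noise_sd,
    heteroscedastic = heteroscedastic, seed = seed
  )
  out
}

#' Simulate a time-zero SHG adsorption isotherm
#'
#' Applies the depletion-corrected Langmuir model ([shg_isotherm_model()])
#' forward at each added concentration and adds Gaussian intensity noise, so
#' the noiseless generator is the exact inverse of [fit_isotherm()].
#'
#' @param K Dimensionless adsorption equilibrium constant (water-reference
#'   convention); must be positive.
#' @param Nmax Maximum adsorption-site concentration in micromolar.
#' @param A SHG intensity at saturation (normalized units).
#' @param B Baseline intensity offset.
#' @param alpha Incoherent free-dye slope (intensity per micromolar).
#' @param C_grid Added dye concentrations in micromolar (non-negative).
#' @param noise_sd Gaussian intensity noise scale: the standard deviation
#'   itself under `noise_model = "constant"`, or the relative (fractional)
#'   noise under `noise_model = "proportional"`.
#' @param noise_model `"constant"` (homoscedastic, default) or
#'   `"proportional"` (sd proportional to the clean intensity, as for
#'   spectra averaged to a fixed relative precision).
#' @param temp Temperature in kelvin (metadata).
#' @param coverage_exponent Exponent on fractional coverage in the coherent
#'   term; 2 (default) squares the coverage (field proportional to adsorbate
#'   number, intensity to field squared), 1 gives the linear variant.
#' @param water_conc Water reference concentration in micromolar.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `conc_uM`, `intensity`, `sigma`, `temp_K`;
#'   generating parameters in `attr(, "truth")`.
#' @export
simulate_isotherm <- function(K = 9.1e7, Nmax = 5.4, A = 1, B = 0,
                              alpha = 0.002,
                              C_grid = c(0.5, 1, 2, 3, 4, 5, 6, 7, 8, 10, 12, 15),
                              noise_sd = 0.02,
                              noise_model = c("constant", "proportional"),
                              temp = 298.15, coverage_exponent = 2,
                              water_conc = .WATER_UM, seed = NULL) {
  noise_model <- match.arg(noise_model)
  check_number(K, "K", positive = TRUE)
  check_number(Nmax, "Nmax", positive = TRUE)
  check_number(noise_sd, "noise_sd", non_negative = TRUE)
  if (length(C_grid) == 0) abort("`C_grid` must not be empty.")
  if (any(C_grid < 0)) abort("`C_grid` must be non-negative.")

  clean <- shg_isotherm_model(C_grid, K = K, Nmax = Nmax, A = A, B = B,
                              alpha = alpha,
                              coverage_exponent = coverage_exponent,
                              water_conc = water_conc)
  sigma <- if (noise_model == "proportional") {
    noise_sd * abs(clean)
  } else {
    rep(noise_sd, length(C_grid))
  }
  intensity <- with_seed_maybe(seed, clean + rnorm(length(C_grid), sd = sigma))

  out <- tibble(
    conc_uM = as.numeric(C_grid),
    intensity = intensity,
    sigma = sigma,
    temp_K = temp
  )
  attr(out, "truth") <- list(
    K = K, Nmax = Nmax, A = A, B = B, alpha = alpha,
    coverage_exponent = coverage_exponent, water_conc = water_conc,
    noise_sd = noise_sd, noise_model = noise_model, seed = seed
  )
  out
}
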