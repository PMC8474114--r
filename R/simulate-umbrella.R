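#' Simulate umbrella-sampling windows from a known free-energy profile
#'
#' Draws samples of the collective variable z (the membrane--dye
#' center-of-mass separation along the interface normal, in angstroms) from
#' the exact biased density of each harmonic umbrella window,
#' \deqn{p_i(z) \propto \exp\{-[w(z) + \tfrac{1}{2} k_i (z - z_i)^2] / k_B T\},}
#' by inverse-CDF sampling on a fine grid. Samples are i.i.d. by default,
#' which gives clean statistics for validating the WHAM reconstruction; an
#' optional AR(1) correlation emulates the autocorrelation of molecular
#' dynamics for block-averaging tests (a stationary Gaussian copula preserves
#' the exact marginal density).
#'
#' @param w_true The true potential of mean force: a function of z returning
#'   kcal/mol (vectorized), or a two-column data frame (`z`, `W`) interpolated
#'   linearly.
#' @param centers Bias centers \eqn{z_i} in angstroms, one per window.
#' @param springs Harmonic spring constants in kcal mol^-1 A^-2 (recycled to
#'   the number of windows); must be positive.
#' @param n_samples Number of samples drawn per window.
#' @param temp Temperature in kelvin.
#' @param z_range Range of the sampling grid; defaults to all window centers
#'   plus/minus 5 bias standard deviations. Supplied ranges must cover every
#'   center +/- 3 sigma of its bias or the window is rejected.
#' @param dz Grid spacing for inverse-CDF sampling (angstroms).
#' @param ar1 AR(1) correlation coefficient in `[0, 1)`; 0 gives i.i.d. draws.
#' @param bias_offset Constant added to each window's bias potential
#'   (kcal/mol, recycled). Physically irrelevant — WHAM must absorb it into
#'   the window free energies — so it exists to exercise gauge invariance.
#' @param seed Optional integer seed.
#'
#' @return A tibble with one row per sample: `window`, `center`, `spring`,
#'   `bias_offset`, `step`, `z`, `temp_K`. The generating profile and settings
#'   are stored in `attr(, "truth")`.
#' @export
#' @examples
#' w <- function(z) 0.5 * 0.2 * z^2
#' s <- simulate_umbrella(w, centers = c(-2, 0, 2), springs = 5,
#'                        n_samples = 200, temp = 303, seed = 1)
simulate_umbrella <- function(w_true, centers, springs, n_samples = 2000,
                              temp = 303, z_range = NULL, dz = 0.01,
                              ar1 = 0, bias_offset = 0, seed = NULL) {
  if (length(centers) == 0) abort("`centers` must not be empty.")
  springs <- rep_len(springs, length(centers))
  bias_offset <- rep_len(bias_offset, length(centers))
  if (any(springs <= 0)) abort("`springs` must be > 0.")
  check_number(n_samples, "n_samples", positive = TRUE)
  check_number(temp, "temp", positive = TRUE)
  check_number(dz, "dz", positive = TRUE)
  if (ar1 < 0 || ar1 >= 1) abort("`ar1` must be in [0, 1).")

  wfun <- as_pmf_function(w_true)
  kBT <- .R_KCAL * temp
  sigma_bias <- sqrt(kBT / springs)

  if (is.null(z_range)) {
    z_range <- range(centers - 5 * sigma_bias, centers + 5 * sigma_bias)
  } else {
    covered <- centers - 3 * sigma_bias >= z_range[1] &
      centers + 3 * sigma_bias <= z_range[2]
    if (!all(covered)) {
      abort(sprintf(
        "`z_range` [%g, %g] does not cover window%s %s to +/- 3 bias sd.",
        z_range[1], z_range[2],
        if (sum(!covered) > 1) "s" else "",
        paste(which(!covered), collapse = ", ")
      ))
    }
  }
  z_grid <- seq(z_range[1], z_range[2], by = dz)
  w_grid <- wfun(z_grid)
  if (any(!is.finite(w_grid))) {
    abort("`w_true` must be finite on the sampling grid.")
  }

  draw_window <- function(i) {
    u_bias <- 0.5 * springs[i] * (z_grid - centers[i])^2
    log_p <- -(w_grid + u_bias) / kBT
    log_p <- log_p - max(log_p)
    p <- exp(log_p)
    cdf <- cumsum(p)
    cdf <- cdf / cdf[length(cdf)]
    u <- if (ar1 > 0) {
      # Gaussian copula AR(1): correlated uniforms with exact uniform marginal
      e <- rnorm(n_samples)
      g <- numeric(n_samples)
      g[1] <- e[1]
      for (t in 2:n_samples) g[t] <- ar1 * g[t - 1] + sqrt(1 - ar1^2) * e[t]
      stats::pnorm(g)
    } else {
      runif(n_samples)
    }
    idx <- findInterval(u, cdf) + 1L
    idx <- pmin(idx, length(z_grid))
    tibble(
      window = i,
      center = centers[i],
      spring = springs[i],
      bias_offset = bias_offset[i],
      step = seq_len(n_samples),
      z = z_grid[idx],
      temp_K = temp
    )
  }

  out <- with_seed_maybe(seed, purrr::map(seq_along(centers), draw_window))
  out <- bind_rows(out)
  attr(out, "truth") <- list(
    w_true = wfun, centers = centers, springs = springs,
    n_samples = n_samples, temp = temp, z_range = z_range, dz = dz,
    ar1 = ar1, seed = seed
  )
  out
}

# Coerce a PMF specification (function or (z, W) table) to a vectorized
# function of z.
as_pmf_function <- function(w_true) {
  if (is.function(w_true)) return(w_true)
  if (is.data.frame(w_true)) {
    check_columns(w_true, c("z", "W"), "`w_true`")
    zs <- w_true$z
    ws <- w_true$W
    return(function(z) approx(zs, ws, xout = z, rule = 2)$y)
  }
  abort("`w_true` must be a function of z or a data frame with columns `z`, `W`.")
}
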