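#' Adsorbed concentration under the depletion-corrected Langmuir model
#'
#' Classical Langmuir treatments assume the bulk adsorbate concentration is
#' unchanged by adsorption. For colloidal liposomes the cumulative surface
#' area is large enough that adsorption measurably depletes the bulk pool, so
#' the mass balance `M = C - N` must be solved jointly with the Langmuir
#' equilibrium. With a dimensionless equilibrium constant K (water-reference
#' convention, 55.5 M), the equilibrium condition
#' \deqn{K = \frac{N / N_{max}}{(1 - N/N_{max}) \, (C - N) / c_w}}
#' (with \eqn{c_w} the water concentration) reduces to a quadratic in N whose
#' physical (smaller) root is
#' \deqn{N = \tfrac{1}{2}\left[s - \sqrt{s^2 - 4 C N_{max}}\right],
#'   \quad s = C + N_{max} + c_w / K.}
#' At K of order 1e7--1e8 the naive root subtracts nearly equal numbers, so
#' the multiply-conjugate form \eqn{N = 2 C N_{max} / (s + \sqrt{s^2 - 4 C
#' N_{max}})} is used, which is stable for all parameter magnitudes.
#'
#' @param C Added adsorbate concentration(s), micromolar (non-negative).
#' @param K Dimensionless adsorption equilibrium constant (> 0).
#' @param Nmax Maximum adsorption-site concentration, micromolar (> 0).
#' @param water_conc Water reference concentration in micromolar
#'   (default 5.55e7, i.e. 55.5 M).
#'
#' @return Adsorbed concentration(s) N in micromolar, satisfying
#'   `0 <= N <= pmin(C, Nmax)`.
#' @export
#' @examples
#' adsorbed_conc(C = 2, K = 9.1e7, Nmax = 5.4)
#' adsorbed_conc(C = 8, K = 1e15, Nmax = 5) # infinite-affinity limit: Nmax
adsorbed_conc <- function(C, K, Nmax, water_conc = .WATER_UM) {
  if (any(C < 0)) abort("`C` must be non-negative.")
  check_number(K, "K", positive = TRUE)
  check_number(Nmax, "Nmax", positive = TRUE)
  check_number(water_conc, "water_conc", positive = TRUE)
  s <- C + Nmax + water_conc / K
  disc <- pmax(s^2 - 4 * C * Nmax, 0)
  N <- 2 * C * Nmax / (s + sqrt(disc))
  pmin(N, pmin(C, Nmax))
}

#' Predicted time-zero SHG intensity under the modified Langmuir model
#'
#' Composes three contributions: a coherent adsorbed-layer term proportional
#' to a power of the fractional coverage (the SHG field scales with adsorbate
#' number, intensity with field squared, so the default exponent is 2), an
#' incoherent free-dye term linear in the remaining bulk concentration
#' `M = C - N`, and a baseline offset:
#' \deqn{I_0(C) = B + \alpha M + A \,(N/N_{max})^p.}
#'
#' @inheritParams adsorbed_conc
#' @param A SHG intensity at saturation (normalized units).
#' @param B Baseline intensity offset.
#' @param alpha Free-dye slope, intensity per micromolar.
#' @param coverage_exponent Power `p` on the fractional coverage (2 default,
#'   1 for the linear variant).
#'
#' @return Predicted intensity, same length as `C`.
#' @export
shg_isotherm_model <- function(C, K, Nmax, A, B = 0, alpha = 0,
                               coverage_exponent = 2,
                               water_conc = .WATER_UM) {
  N <- adsorbed_conc(C, K, Nmax, water_conc = water_conc)
  M <- C - N
  B + alpha * M + A * (N / Nmax)^coverage_exponent
}

#' Fit the modified Langmuir isotherm to time-zero SHG intensities
#'
#' Nonlinear weighted least squares for `{K, Nmax, A, B}` (and `alpha` unless
#' fixed from a dye-only calibration series). K and Nmax are optimized on the
#' log scale, which enforces positivity and tames their disparate magnitudes;
#' standard errors on the natural scale come from the delta method.
#' Starting values come from a coarse profile search: for candidate (K, Nmax)
#' pairs the remaining parameters enter linearly and are solved exactly, and
#' the best candidate seeds the Levenberg--Marquardt polish.
#'
#' @param data Isotherm tibble with columns `conc_uM`, `intensity`, optional
#'   `sigma` (per-point uncertainty, used as weights), optional `temp_K`.
#' @param fix_alpha Fix the free-dye slope at this value (e.g. from a
#'   calibration without liposomes); `NULL` (default) co-fits it.
#' @param fix_B Fix the baseline at this value; `NULL` co-fits it.
#' @param coverage_exponent Coverage power in the coherent term (see
#'   [shg_isotherm_model()]).
#' @param water_conc Water reference concentration, micromolar.
#' @param weighted Use `1/sigma^2` weights when `sigma` is present.
#' @param conf_level Confidence level for the K interval (default 0.95).
#'
#' @return An object of class `langmuir_fit`; see [tidy()], [glance()],
#'   [autoplot()]. Components include `estimates` (with SEs), `K_ci` (log-
#'   scale t interval mapped through exp), and `per_point` with the adsorbed
#'   (`N`) and free (`M`) concentrations at each measured point, which
#'   satisfy `N + M = C` exactly.
#' @export
#' @examples
#' iso <- simulate_isotherm(K = 8e7, Nmax = 6, A = 1, noise_sd = 0.01, seed = 2)
#' fit <- fit_isotherm(iso)
#' tidy(fit)
fit_isotherm <- function(data, fix_alpha = NULL, fix_B = NULL,
                         coverage_exponent = 2, water_conc = .WATER_UM,
                         weighted = TRUE, conf_level = 0.95) {
  check_columns(data, c("conc_uM", "intensity"), "Isotherm data")
  C <- data$conc_uM
  I <- data$intensity
  if (any(C < 0)) abort("`conc_uM` must be non-negative.")
  n_distinct_C <- dplyr::n_distinct(C)
  if (n_distinct_C < 6) {
    warn(sprintf(
      "Only %d distinct concentrations: the isotherm fit needs points spanning sub- and near-saturation regimes to constrain K and Nmax.",
      n_distinct_C
    ))
  }
  if (sd(I) < 1e-12) {
    abort("All intensities are equal: isotherm parameters are unidentifiable.")
  }
  use_w <- weighted && "sigma" %in% names(data) &&
    all(is.finite(data$sigma)) && all(data$sigma > 0)
  w <- if (use_w) 1 / data$sigma^2 else rep(1, length(C))

  est_alpha <- is.null(fix_alpha)
  est_B <- is.null(fix_B)

  # Coarse profile search: (K, Nmax) on a log grid, linear params solved exactly
  Kcand <- 10^seq(5, 10, by = 0.25)
  Ncand <- exp(seq(log(max(min(C[C > 0]), 1e-3)), log(max(C) * 2), length.out = 25))
  best <- NULL
  for (Kc in Kcand) {
    for (Nc in Ncand) {
      N <- adsorbed_conc(C, Kc, Nc, water_conc)
      X <- cbind(cov = (N / Nc)^coverage_exponent)
      y <- I
      if (!est_B) y <- y - fix_B else X <- cbind(X, B = 1)
      if (!est_alpha) y <- y - fix_alpha * (C - N) else X <- cbind(X, alpha = C - N)
      ls <- lm.fit(X * sqrt(w), y * sqrt(w))
      ssr <- sum(ls$residuals^2)
      if (is.null(best) || ssr < best$ssr) {
        cf <- coef(ls)
        best <- list(
          ssr = ssr, K = Kc, Nmax = Nc, A = unname(cf["cov"]),
          B = if (est_B) unname(cf["B"]) else fix_B,
          alpha = if (est_alpha) unname(cf["alpha"]) else fix_alpha
        )
      }
    }
  }

  start <- c(logK = log(best$K), logNmax = log(best$Nmax), A = best$A)
  if (est_B) start <- c(start, B = best$B)
  if (est_alpha) start <- c(start, alpha = best$alpha)
  if (length(C) <= length(start)) {
    abort(sprintf(
      "%d data points cannot constrain %d free parameters; fix `alpha` and/or `B`, or add concentrations.",
      length(C), length(start)
    ))
  }

  model_fun <- function(logK, logNmax, A, B, alpha) {
    shg_isotherm_model(C, exp(logK), exp(logNmax), A, B, alpha,
                       coverage_exponent = coverage_exponent,
                       water_conc = water_conc)
  }
  resid_fun <- function(p) {
    B <- if (est_B) p[["B"]] else fix_B
    alpha <- if (est_alpha) p[["alpha"]] else fix_alpha
    # keep exp() finite if the optimizer wanders: K and Nmax far outside any
    # physical range are equivalent to the boundary for the fit
    logK <- min(max(p[["logK"]], log(1e-3)), log(1e18))
    logNmax <- min(max(p[["logNmax"]], log(1e-6)), log(1e9))
    sqrt(w) * (I - model_fun(logK, logNmax, p[["A"]], B, alpha))
  }

  lmfit <- minpack.lm::nls.lm(
    par = start, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 20000,
                                         ftol = 1e-12, ptol = 1e-12)
  )
  if (lmfit$info %in% c(0, 5, 9)) {
    abort(sprintf("Isotherm fit did not converge (nls.lm info %d: %s).",
                  lmfit$info, lmfit$message))
  }
  p <- lmfit$par
  df_resid <- length(C) - length(p)
  cov_scaled <- tryCatch({
    s2 <- lmfit$deviance / df_resid
    s2 * solve(lmfit$hessian)
  }, error = function(e) matrix(NA_real_, length(p), length(p),
                                dimnames = list(names(p), names(p))))
  se <- sqrt(pmax(diag(cov_scaled), 0))

  K_hat <- exp(p[["logK"]])
  Nmax_hat <- exp(p[["logNmax"]])
  se_logK <- se[["logK"]]
  tcrit <- qt(1 - (1 - conf_level) / 2, df = max(df_resid, 1))
  K_ci <- exp(p[["logK"]] + c(-1, 1) * tcrit * se_logK)
  if (is.finite(se_logK) && se_logK > log(10)) {
    warn("K is weakly identified (flat likelihood): the data lack curvature in the saturation region.")
  }

  B_hat <- if (est_B) p[["B"]] else fix_B
  alpha_hat <- if (est_alpha) p[["alpha"]] else fix_alpha
  N <- adsorbed_conc(C, K_hat, Nmax_hat, water_conc)
  fitted_I <- shg_isotherm_model(C, K_hat, Nmax_hat, p[["A"]], B_hat, alpha_hat,
                                 coverage_exponent = coverage_exponent,
                                 water_conc = water_conc)
  r_squared <- 1 - sum(w * (I - fitted_I)^2) / sum(w * (I - mean(I))^2)

  terms <- c("K", "Nmax", "A",
             if (est_B) "B", if (est_alpha) "alpha")
  estimates <- tibble(
    term = terms,
    estimate = c(K_hat, Nmax_hat, p[["A"]],
                 if (est_B) B_hat, if (est_alpha) alpha_hat),
    std.error = c(K_hat * se_logK, Nmax_hat * se[["logNmax"]], se[["A"]],
                  if (est_B) se[["B"]], if (est_alpha) se[["alpha"]])
  )

  structure(
    list(
      estimates = estimates,
      K = K_hat, K_se = K_hat * se_logK, K_ci = K_ci,
      Nmax = Nmax_hat, Nmax_se = Nmax_hat * se[["logNmax"]],
      A = p[["A"]], B = B_hat, alpha = alpha_hat,
      fixed = list(alpha = fix_alpha, B = fix_B),
      coverage_exponent = coverage_exponent, water_conc = water_conc,
      vcov_log = cov_scaled,
      per_point = tibble(conc_uM = C, intensity = I, fitted = fitted_I,
                         N = N, M = C - N),
      r_squared = r_squared, df_residual = df_resid,
      weighted = use_w, conf_level = conf_level,
      temp_K = if ("temp_K" %in% names(data)) data$temp_K[1] else NA_real_,
      iterations = lmfit$niter
    ),
    class = "langmuir_fit"
  )
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat("Depletion-corrected Langmuir isotherm fit\n")
  cat(sprintf("  K    = %.3g +/- %.2g (dimensionless, 55.5 M reference)\n",
              x$K, x$K_se))
  cat(sprintf("  Nmax = %.3g +/- %.2g uM\n", x$Nmax, x$Nmax_se))
  cat(sprintf("  A    = %.3g, B = %.3g, alpha = %.3g%s\n",
              x$A, x$B, x$alpha,
              if (!is.null(x$fixed$alpha)) " (alpha fixed)" else ""))
  cat(sprintf("  R^2 = %.4f on %d points\n", x$r_squared, nrow(x$per_point)))
  invisible(x)
}
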