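test_that("intensity-to-field conversion is sqrt with delta-method errors", {
  tr <- tibble::tibble(time = 0:3, intensity = c(1, 0.25, 0.04, 0),
                       sigma = rep(0.02, 4))
  f <- shg_field(tr)
  expect_equal(f$field, c(1, 0.5, 0.2, 0))
  expect_equal(f$sigma_field[1:3], c(0.01, 0.02, 0.05))
  expect_true(is.na(f$sigma_field[4])) # sigma undefined at E = 0

  # delta method agrees with Monte-Carlo propagation at I = 0.25 +/- 0.02
  set.seed(1)
  mc <- sd(sqrt(rnorm(2e5, 0.25, 0.02)))
  expect_equal(mc, 0.02, tolerance = 0.02)

  expect_error(shg_field(tibble::tibble(time = 0:2, intensity = c(-1, -2, 0))),
               "no SHG signal")
  expect_warning(
    shg_field(tibble::tibble(time = 0:2, intensity = c(-0.01, 0.5, 1))),
    "clipped"
  )
})

test_that("normalization maps the reference to 1 and is scale invariant", {
  traces <- dplyr::bind_rows(
    simulate_shg_trace(a0 = 0.2, a1 = 0.8, noise_sd = 0, conc = 15, temp = 298.15),
    simulate_shg_trace(a0 = 0.1, a1 = 0.4, noise_sd = 0, conc = 5, temp = 298.15)
  )
  nn <- normalize_traces(traces, ref_conc = 15, ref_temp = 298.15)
  expect_equal(nn$intensity[nn$conc_uM == 15][1], 1.0)

  scaled <- dplyr::mutate(traces, intensity = intensity * 5)
  expect_equal(normalize_traces(scaled, 15, 298.15)$intensity, nn$intensity)

  # a planted time-zero intensity ratio survives normalization
  ratio <- nn$intensity[nn$conc_uM == 5][1]
  expect_equal(ratio, (0.1 + 0.4)^2 / (0.2 + 0.8)^2)

  expect_error(normalize_traces(traces, ref_conc = 99, ref_temp = 298.15),
               "not found")
})

test_that("noiseless transport fit recovers parameters to optimizer tolerance", {
  tr <- simulate_shg_trace(a0 = 0.2, a1 = 0.8, tau = 300, noise_sd = 0)
  f <- fit_transport_time(tr)
  est <- setNames(f$estimates$estimate, f$estimates$term)
  expect_equal(est[["a0"]], 0.2, tolerance = 1e-6)
  expect_equal(est[["a1"]], 0.8, tolerance = 1e-6)
  expect_equal(est[["tau"]], 300, tolerance = 1e-6)
  expect_gt(f$r_squared, 1 - 1e-10)
})

test_that("transport fit rejects degenerate inputs", {
  const <- tibble::tibble(time = seq(0, 100, 10), intensity = rep(0.25, 11))
  expect_error(fit_transport_time(const), "unidentifiable")
  short <- simulate_shg_trace(noise_sd = 0, t_grid = c(0, 1, 2, 3))
  expect_error(fit_transport_time(short), "5 points")
})

test_that("transport fit is equivariant under time rescaling and translation", {
  tr <- simulate_shg_trace(a0 = 0.3, a1 = 0.6, tau = 200, noise_sd = 0.005,
                           seed = 12)
  f1 <- fit_transport_time(tr)
  # rescale time by 3: tau must scale by 3
  tr3 <- dplyr::mutate(tr, time = time * 3)
  f3 <- fit_transport_time(tr3)
  expect_equal(f3$tau, 3 * f1$tau, tolerance = 1e-6)
  # translate time by +t0 and refit: tau unchanged, amplitude re-expressed
  trs <- dplyr::mutate(tr, time = time + 120)
  fs <- fit_transport_time(trs)
  expect_equal(fs$tau, f1$tau, tolerance = 1e-3)
  a1_shift <- fs$estimates$estimate[fs$estimates$term == "a1"]
  expect_equal(a1_shift * exp(-120 / fs$tau),
               f1$estimates$estimate[f1$estimates$term == "a1"],
               tolerance = 1e-3)
})

test_that("fitted tau decreases with temperature when the generating tau does", {
  temps <- c(298.15, 303.15, 308.15, 313.15)
  taus_true <- c(600, 500, 420, 350) # monotone decreasing in T
  fits <- purrr::map2_dfr(temps, taus_true, function(T, tau) {
    tr <- simulate_shg_trace(tau = tau, noise_sd = 0.01, conc = 15, temp = T,
                             seed = round(T * 10))
    tibble::tibble(temp_K = T, tau = fit_transport_time(tr)$tau)
  })
  expect_true(all(diff(fits$tau) < 0))
})

test_that("rate analysis recovers exact linear structure and guards sparse input", {
  temps <- c(298, 308, 318)
  concs <- c(5, 10, 15, 20)
  m <- function(T) 4e-5 + 1e-6 * (T - 298)
  b <- 2e-4
  fits <- tidyr::expand_grid(temp_K = temps, conc_uM = concs) %>%
    dplyr::mutate(tau = 1 / (m(temp_K) * conc_uM + b))
  rs <- rate_analysis(fits)
  expect_equal(rs$per_temperature$slope, m(temps), tolerance = 1e-12)
  expect_equal(rs$per_temperature$intercept, rep(b, 3), tolerance = 1e-12)
  expect_equal(rs$temperature_trend$slope, 1e-6, tolerance = 1e-12)

  sparse <- dplyr::bind_rows(fits,
                             tibble::tibble(temp_K = 330, conc_uM = 5, tau = 100))
  expect_warning(rs2 <- rate_analysis(sparse), "excluded")
  expect_false(330 %in% rs2$per_temperature$temp_K)
  expect_error(rate_analysis(dplyr::mutate(fits, tau = -tau)), "> 0")
})

test_that("collection fitting returns one row per condition", {
  traces <- dplyr::bind_rows(
    simulate_shg_trace(tau = 300, conc = 10, temp = 298, noise_sd = 0.01, seed = 1),
    simulate_shg_trace(tau = 250, conc = 20, temp = 298, noise_sd = 0.01, seed = 2)
  )
  fits <- fit_transport_times(traces)
  expect_equal(nrow(fits), 2)
  expect_equal(fits$tau, c(300, 250), tolerance = 0.05)
})
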