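test_that("noiseless trace generation inverts the squared-field model exactly", {
  tr <- simulate_shg_trace(a0 = 0.2, a1 = 0.8, tau = 300, noise_sd = 0, seed = 1)
  expect_equal(tr$intensity[1], 1.0) # (a0 + a1)^2 at t = 0
  expect_equal(tr$intensity,
               (0.2 + 0.8 * exp(-tr$time / 300))^2, tolerance = 1e-12)

  flat <- simulate_shg_trace(a0 = 0.3, a1 = 0, noise_sd = 0)
  expect_true(all(abs(flat$intensity - 0.09) < 1e-12))
})

test_that("trace generator validates its specification and is reproducible", {
  expect_error(simulate_shg_trace(tau = -1), "tau")
  expect_error(simulate_shg_trace(tau = 0), "tau")
  expect_error(simulate_shg_trace(t_grid = c(0, 2, 1)), "increasing")
  expect_error(simulate_shg_trace(noise_sd = -0.1), "noise_sd")

  a <- simulate_shg_trace(noise_sd = 0.02, seed = 42)
  b <- simulate_shg_trace(noise_sd = 0.02, seed = 42)
  expect_identical(a$intensity, b$intensity)
  c <- simulate_shg_trace(noise_sd = 0.02, seed = 43)
  expect_false(identical(a$intensity, c$intensity))
  # generation must not disturb the session RNG stream
  set.seed(7); x1 <- rnorm(1)
  set.seed(7); invisible(simulate_shg_trace(seed = 9)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("noiseless isotherm generation matches the forward model limits", {
  iso0 <- simulate_isotherm(B = 0, noise_sd = 0, C_grid = c(0, 1, 5))
  expect_equal(iso0$intensity[1], 0) # nothing adsorbed, no free dye, no baseline

  sat <- simulate_isotherm(K = 1e8, Nmax = 5, A = 0.8, B = 0, alpha = 0,
                           noise_sd = 0, C_grid = c(1e5))
  expect_equal(sat$intensity, 0.8, tolerance = 1e-4) # saturation plateau = A

  expect_error(simulate_isotherm(C_grid = numeric()), "empty")
  expect_error(simulate_isotherm(C_grid = c(-1, 2)), "non-negative")
  expect_error(simulate_isotherm(K = 0), "K")
})

test_that("proportional noise scales sigma with the clean intensity", {
  iso <- simulate_isotherm(K = 8e7, Nmax = 6, A = 1, B = 0, alpha = 0,
                           noise_sd = 0.05, noise_model = "proportional",
                           seed = 3)
  clean <- shg_isotherm_model(iso$conc_uM, 8e7, 6, 1, 0, 0)
  expect_equal(iso$sigma, 0.05 * clean)
  # low-concentration points carry proportionally small noise
  expect_lt(iso$sigma[1], iso$sigma[length(iso$sigma)])
})

test_that("flat-PMF umbrella samples are Gaussian with variance kBT/k", {
  k <- 10; temp <- 303
  s <- simulate_umbrella(function(z) rep(0, length(z)), centers = 0,
                         springs = k, n_samples = 4000, temp = temp, seed = 2)
  v_expected <- 1.9872e-3 * temp / k
  v <- var(s$z)
  se_v <- v_expected * sqrt(2 / (nrow(s) - 1))
  expect_lt(abs(v - v_expected), 3 * se_v)
  expect_lt(abs(mean(s$z)), 3 * sqrt(v_expected / nrow(s)))
})

test_that("umbrella sampling of a harmonic PMF matches the combined Gaussian", {
  # w(z) = kappa z^2 / 2 plus bias k (z - zc)^2 / 2: product of Gaussians with
  # minimizer k zc / (kappa + k) and variance kBT / (kappa + k)
  kappa <- 2; k <- 6; zc <- 1.5; temp <- 303
  s <- simulate_umbrella(function(z) 0.5 * kappa * z^2, centers = zc,
                         springs = k, n_samples = 4000, temp = temp, seed = 8)
  mu_expected <- k * zc / (kappa + k)
  v_expected <- 1.9872e-3 * temp / (kappa + k)
  expect_lt(abs(mean(s$z) - mu_expected), 3 * sqrt(v_expected / nrow(s)))
})

test_that("umbrella sampler is deterministic and validates its grid", {
  a <- make_harmonic_windows(seed = 5)
  b <- make_harmonic_windows(seed = 5)
  expect_identical(a$z, b$z)
  expect_error(
    simulate_umbrella(function(z) 0 * z, centers = c(-10, 10), springs = 1,
                      n_samples = 10, z_range = c(-5, 5)),
    "does not cover"
  )
  expect_error(simulate_umbrella(function(z) 0 * z, centers = 0, springs = -1),
               "springs")
  expect_error(simulate_umbrella("no", centers = 0, springs = 1), "function")
})

test_that("umbrella histograms converge to the analytic biased density", {
  # max-bin deviation from the analytic Gaussian shrinks roughly as 1/sqrt(n)
  k <- 5; temp <- 303
  sdev <- sqrt(1.9872e-3 * temp / k)
  dev_for <- function(n, seed) {
    s <- simulate_umbrella(function(z) rep(0, length(z)), centers = 0,
                           springs = k, n_samples = n, temp = temp, seed = seed)
    br <- seq(-4 * sdev, 4 * sdev, length.out = 33)
    h <- hist(s$z[s$z > br[1] & s$z < br[33]], breaks = br, plot = FALSE)
    mids <- h$mids
    p_true <- dnorm(mids, 0, sdev) * diff(br)[1]
    max(abs(h$counts / n - p_true))
  }
  d_small <- mean(vapply(1:4, function(i) dev_for(500, 100 + i), numeric(1)))
  d_large <- mean(vapply(1:4, function(i) dev_for(8000, 200 + i), numeric(1)))
  expect_lt(d_large, d_small) # shrinks with n
  expect_lt(d_large, 2.5 * d_small / sqrt(8000 / 500)) # about 1/sqrt(n)
})

test_that("frame generator plants exact interfacial water counts and orientations", {
  fr <- simulate_frames(n_frames = 3, n_lipids = 20, n_waters = 100,
                        n_interfacial = 30, lipid_sd = 0, seed = 4)
  truth <- attr(fr, "truth")
  expect_equal(truth$n_interfacial, rep(30, 3))
  wc <- interfacial_water_count(fr)
  expect_equal(wc$per_frame$count, rep(30, 3))

  up <- simulate_frames(n_frames = 4, orientation = list(dist = "point", cos_theta = 1),
                        n_waters = 10, n_interfacial = 0, n_lipids = 5,
                        lipid_sd = 0, seed = 6)
  expect_equal(attr(up, "truth")$cos_theta, rep(1, 4))
})

test_that("frame generator validates charges and lipids", {
  expect_error(simulate_frames(n_lipids = 0), "interface")
  expect_error(simulate_frames(dye_charges = c(0.5, 0.2)), "net charge")
  expect_error(simulate_frames(n_interfacial = 50, n_waters = 10), "exceed")
  # net-neutral dye allowed when declared
  fr <- simulate_frames(n_frames = 1, dye_charges = c(0.5, -0.5),
                        net_charge = 0, n_waters = 5, n_interfacial = 0,
                        n_lipids = 2, seed = 1)
  expect_equal(sum(fr$charge[fr$role == "dye"]), 0)
})

test_that("planted angular distribution matches its generating law (GOF)", {
  or_spec <- list(dist = "cosnormal", mean = 0.6, sd = 0.15)
  fr <- simulate_frames(n_frames = 2000, n_lipids = 2, n_waters = 2,
                        n_interfacial = 0, orientation = or_spec, seed = 11)
  ct <- attr(fr, "truth")$cos_theta
  br <- seq(-1, 1, by = 0.2)
  counts <- tabulate(findInterval(ct, br, rightmost.closed = TRUE),
                     nbins = length(br) - 1)
  # truncated-normal bin probabilities
  trunc_mass <- pnorm(1, 0.6, 0.15) - pnorm(-1, 0.6, 0.15)
  p <- (pnorm(tail(br, -1), 0.6, 0.15) - pnorm(head(br, -1), 0.6, 0.15)) / trunc_mass
  keep <- p > 1e-6
  gof <- suppressWarnings(chisq.test(counts[keep], p = p[keep] / sum(p[keep])))
  expect_gt(gof$p.value, 0.01)
})
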