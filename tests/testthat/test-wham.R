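test_that("equilibration trim drops the leading fraction per window", {
  s <- make_harmonic_windows(centers = c(0, 1), n = 1800, seed = 3)
  t1 <- equilibration_trim(s) # default 4/18
  expect_equal(nrow(t1), 2 * 1400)
  expect_equal(min(t1$step), 401)

  big <- tibble::tibble(window = 1, center = 0, spring = 1,
                        step = 1:18000, z = rnorm(18000), temp_K = 303)
  expect_equal(nrow(equilibration_trim(big)), 14000)

  expect_equal(equilibration_trim(s, fraction = 0), dplyr::arrange(s, window, step),
               ignore_attr = TRUE)
  expect_error(equilibration_trim(s, count = 1800), "empty window")
})

test_that("unbiased single-window WHAM degenerates to Boltzmann inversion", {
  set.seed(21)
  s <- tibble::tibble(window = 1, center = 0, spring = 0,
                      step = 1:4000, z = rnorm(4000), temp_K = 303)
  p <- wham_solve(s, bin_width = 0.25, z_range = c(-3, 3))
  prof <- tidy(p) %>% dplyr::filter(is.finite(W))
  kBT <- 1.9872e-3 * 303
  w_hist <- -kBT * log(prof$counts / sum(prof$counts))
  w_hist <- w_hist - min(w_hist)
  expect_equal(prof$W, w_hist, tolerance = 1e-9)
})

test_that("WHAM is gauge invariant under constant bias offsets", {
  base <- make_harmonic_windows(kappa = 0.5, centers = seq(-3, 3, 1.5),
                                spring = 4, n = 500, seed = 7)
  shifted <- dplyr::mutate(base, bias_offset = c(5, -2, 0.5, 11, -7)[window])
  p0 <- wham_solve(base, tol = 1e-11)
  p1 <- wham_solve(shifted, tol = 1e-11)
  expect_lt(max(abs(p0$profile$W - p1$profile$W), na.rm = TRUE), 1e-8)
  # the offsets are absorbed into the window free-energy shifts
  expect_false(isTRUE(all.equal(p0$f$f, p1$f$f)))
})

test_that("the WHAM fixed point satisfies its own self-consistency tolerance", {
  s <- make_harmonic_windows(n = 300, seed = 9)
  p <- wham_solve(s, tol = 1e-9)
  expect_true(p$converged)
  expect_lt(p$residual, 1e-9)
  expect_true(all(is.finite(p$f$f)))
})

test_that("non-overlapping windows trigger a gap warning", {
  s <- make_harmonic_windows(kappa = 0, centers = c(-8, 8), spring = 50,
                             n = 200, seed = 2)
  expect_warning(wham_solve(s, z_range = c(-10, 10)), "overlap")
})

test_that("WHAM recovers a known double-well profile within block errors", {
  w_true <- function(z) -2 * exp(-(z - 1)^2 / 1) - 1.2 * exp(-(z + 2)^2 / 0.8)
  s <- simulate_umbrella(w_true, centers = seq(-5, 5, by = 1), springs = 3,
                         n_samples = 800, temp = 303, seed = 31)
  p <- pmf_block_error(s, n_blocks = 4, bin_width = 0.25)
  # well-sampled: inside the window ladder, with real occupancy; beyond the
  # outermost centers only window tails sample and the estimator extrapolates
  prof <- tidy(p) %>%
    dplyr::filter(is.finite(W), counts >= 100, z >= -5, z <= 5)
  truth <- w_true(prof$z)
  shift <- mean(prof$W - truth)
  dev <- abs(prof$W - truth - shift)
  err_level <- sqrt(mean(prof$err^2)) # the profile's block-averaged error
  expect_lt(max(dev), 3 * err_level)
})

test_that("block errors vanish for identical blocks and shrink as 1/sqrt(n)", {
  pattern <- rep(seq(-0.9, 0.9, length.out = 60), each = 2)
  s_ident <- tibble::tibble(window = 1, center = 0, spring = 2,
                            step = seq_len(4 * 120),
                            z = rep(pattern, 4), temp_K = 303)
  p <- pmf_block_error(s_ident, n_blocks = 4, bin_width = 0.25,
                       z_range = c(-1.5, 1.5))
  expect_true(all(p$profile$err[is.finite(p$profile$err)] < 1e-12))

  err_for <- function(n, seed) {
    s <- make_harmonic_windows(kappa = 1, centers = c(-1, 0, 1), spring = 3,
                               n = n, seed = seed)
    p <- pmf_block_error(s, n_blocks = 4, bin_width = 0.25)
    # fixed central bins: the set of occupied fringe bins grows with n and
    # would otherwise mask the 1/sqrt(n) shrinkage
    core <- p$profile$z >= -1.5 & p$profile$z <= 1.5
    mean(p$profile$err[core], na.rm = TRUE)
  }
  # averaged over seeds: a 4-block SE estimate has ~40% relative noise,
  # so a single pair of runs cannot resolve the scaling law
  r <- mean(vapply(1:4, function(s) err_for(500, s), numeric(1))) /
    mean(vapply(1:4, function(s) err_for(2000, s), numeric(1)))
  expect_gt(r, 2 / 1.3) # quadrupling samples should halve the error,
  expect_lt(r, 2 * 1.3) # within 30%
})

test_that("autocorrelated samples inflate the block error", {
  e_iid <- pmf_block_error(
    make_harmonic_windows(kappa = 1, centers = 0, spring = 3, n = 2000,
                          seed = 13, ar1 = 0),
    n_blocks = 4, bin_width = 0.25
  )
  e_ar <- pmf_block_error(
    make_harmonic_windows(kappa = 1, centers = 0, spring = 3, n = 2000,
                          seed = 13, ar1 = 0.9),
    n_blocks = 4, bin_width = 0.25
  )
  expect_gt(mean(e_ar$profile$err, na.rm = TRUE),
            mean(e_iid$profile$err, na.rm = TRUE))
})

test_that("barrier and minimum extraction finds planted features exactly", {
  z <- seq(0, 30, by = 0.1)
  W <- -6 * exp(-(z - 8)^2 / 2) + 0.5 * exp(-(z - 16)^2 / 1)
  p <- pmf_profile(z, W)
  feats <- barrier_and_minimum(p, bulk_region = c(24, 30))
  expect_equal(feats$barrier, 0.5, tolerance = 1e-6)
  expect_equal(feats$barrier_z, 16)
  expect_equal(feats$depth, -6, tolerance = 1e-6)
  expect_equal(feats$min_z, 8)
  expect_false(feats$barrierless)

  mono <- pmf_profile(z, -6 / (1 + exp(z - 5)))
  fm <- barrier_and_minimum(mono, bulk_region = c(24, 30))
  expect_equal(fm$barrier, 0)
  expect_true(fm$barrierless)

  flat <- pmf_profile(z, rep(0, length(z)))
  ff <- barrier_and_minimum(flat, bulk_region = c(24, 30))
  expect_equal(ff$barrier, 0)
  expect_equal(ff$depth, 0)

  expect_error(barrier_and_minimum(p, bulk_region = c(100, 110)), "outside")
})

test_that("block splitting validates its inputs", {
  s <- make_harmonic_windows(n = 100, seed = 1)
  expect_error(pmf_block_error(s, n_blocks = 1), "n_blocks")
  expect_warning(pmf_block_error(s, n_blocks = 3, bin_width = 0.5), "dropped")
})
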