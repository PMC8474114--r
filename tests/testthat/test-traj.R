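test_that("surface position is the mean over per-lipid outermost oxygens", {
  f1 <- make_frame(lipid_z = rep(30, 6), water_z = numeric())
  expect_equal(surface_z(f1), 30)

  # two lipids, two oxygens each: only the outermost per lipid counts
  f2 <- tibble::tibble(
    frame = 1L, role = "lipid_oxygen", lipid_id = c(1, 1, 2, 2),
    x = 0, y = 0, z = c(29, 27, 31, 26), charge = NA_real_,
    atom = 1:4
  )
  expect_equal(surface_z(f2), 30)
  expect_equal(surface_z(f2, leaflet = "lower"), (27 + 26) / 2)

  expect_error(surface_z(make_frame(lipid_z = numeric(), water_z = 1)),
               "no lipid oxygens")
})

test_that("surface estimate concentrates around the planted position", {
  fr <- simulate_frames(n_frames = 1, n_lipids = 200, lipid_sd = 1,
                        n_waters = 0, n_interfacial = 0, seed = 17)
  zs <- surface_z(dplyr::filter(fr, frame == 1))
  expect_lt(abs(zs - 30), 3 / sqrt(200))
})

test_that("dipole vector and angle follow the point-dipole geometry", {
  dye_z <- list(x = c(0, 0), y = c(0, 0), z = c(1, -1), charge = c(0.5, -0.5))
  f <- make_frame(lipid_z = 0, water_z = numeric(), dye = dye_z)
  d <- dipole_vector(f)
  expect_equal(d$norm, 1)          # |mu| = q * d = 0.5 e * 2 A
  expect_equal(d$cos_theta, 1)

  dye_x <- list(x = c(1, -1), y = c(0, 0), z = c(0, 0), charge = c(0.5, -0.5))
  fx <- make_frame(lipid_z = 0, water_z = numeric(), dye = dye_x)
  expect_equal(dipole_vector(fx)$cos_theta, 0)

  # zero net dipole is flagged
  dye_0 <- list(x = c(0, 0), y = c(0, 0), z = c(1, -1), charge = c(0.5, 0.5))
  f0 <- make_frame(lipid_z = 0, water_z = numeric(), dye = dye_0)
  expect_warning(d0 <- dipole_vector(f0), "zero norm")
  expect_true(is.na(d0$cos_theta))

  expect_error(dipole_vector(make_frame(lipid_z = 0, water_z = 1)), "dye")
})

test_that("dipole magnitude is rotation invariant and the angle tracks rotations", {
  base <- matrix(c(0.7, 0.1, 1.2, -0.4, 0.3, -0.8, 0.2, -0.9, 0.5),
                 ncol = 3, byrow = TRUE)
  q <- c(0.6, 0.3, 0.1)
  mu0 <- colSums(q * sweep(base, 2, colMeans(base)))
  set.seed(33)
  for (i in 1:10) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, 2 * pi))
    rot <- base %*% t(R)
    f <- tibble::tibble(frame = 1L, role = "dye", lipid_id = NA_integer_,
                        x = rot[, 1], y = rot[, 2], z = rot[, 3],
                        charge = q, atom = 1:3)
    d <- dipole_vector(f)
    expect_equal(d$norm, sqrt(sum(mu0^2)), tolerance = 1e-10)
    expect_equal(d$mu, as.numeric(R %*% mu0), tolerance = 1e-10)
  }
})

test_that("orientation distribution summarizes planted laws correctly", {
  fr_pt <- simulate_frames(n_frames = 60, n_lipids = 3, n_waters = 2,
                           n_interfacial = 0,
                           orientation = list(dist = "point", cos_theta = 0.8),
                           seed = 3)
  o <- orientation_distribution(fr_pt)
  expect_equal(o$stats$spread, 0, tolerance = 1e-12)
  expect_equal(o$stats$mean_cos, 0.8, tolerance = 1e-9)
  expect_equal(sum(o$histogram$prob), 1)

  # broader generating law at "higher temperature" gives larger spread
  fr_narrow <- simulate_frames(n_frames = 80, n_lipids = 3, n_waters = 2,
                               n_interfacial = 0, seed = 4,
                               orientation = list(dist = "cosnormal", mean = 0.7, sd = 0.08))
  fr_broad <- simulate_frames(n_frames = 80, n_lipids = 3, n_waters = 2,
                              n_interfacial = 0, seed = 5,
                              orientation = list(dist = "cosnormal", mean = 0.7, sd = 0.3))
  both <- dplyr::bind_rows(
    dplyr::mutate(fr_narrow, temp_label = "303K"),
    dplyr::mutate(fr_broad, frame = frame + 100, temp_label = "313K")
  )
  o2 <- orientation_distribution(both, group = "temp_label")
  s <- setNames(o2$stats$spread, o2$stats$group)
  expect_gt(s[["313K"]], s[["303K"]])
})

test_that("isotropic orientations give a uniform cos(theta) histogram", {
  fr <- simulate_frames(n_frames = 2000, n_lipids = 2, n_waters = 2,
                        n_interfacial = 0,
                        orientation = list(dist = "uniform"), seed = 8)
  ct <- attr(fr, "truth")$cos_theta
  counts <- tabulate(findInterval(ct, seq(-1, 1, 0.25), rightmost.closed = TRUE),
                     nbins = 8)
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("interfacial water counts match planted and uniform-density truths", {
  fr <- simulate_frames(n_frames = 6, n_lipids = 10, n_waters = 100,
                        n_interfacial = 30, lipid_sd = 0, seed = 10)
  wc <- interfacial_water_count(fr)
  expect_equal(wc$per_frame$count, rep(30, 6))
  expect_equal(wc$mean, 30)

  # near-zero cutoff with no water exactly at the surface
  tiny <- interfacial_water_count(fr, cutoff = 1e-9)
  expect_equal(tiny$mean, 0)
  expect_error(interfacial_water_count(fr, cutoff = 0), "cutoff")

  # uniform density rho: expected count = rho * slab thickness
  fru <- simulate_frames(n_frames = 40, n_lipids = 10, n_waters = 600,
                         lipid_sd = 0, water_mode = "uniform",
                         water_zrange = c(30, 90), seed = 12)
  wcu <- interfacial_water_count(fru, cutoff = 3.5)
  rho <- 600 / 60
  expect_lt(abs(wcu$mean - rho * 3.5), 3 * wcu$se)

  # counts are non-increasing as the cutoff shrinks
  c2 <- interfacial_water_count(fru, cutoff = 2)$mean
  expect_lte(c2, wcu$mean)
})

test_that("geometric observables are invariant under rigid translation", {
  fr <- simulate_frames(n_frames = 3, n_lipids = 10, n_waters = 50,
                        n_interfacial = 20, lipid_sd = 0.3,
                        orientation = list(dist = "cosnormal", mean = 0.5, sd = 0.2),
                        seed = 14)
  moved <- dplyr::mutate(fr, x = x + 7, y = y - 3, z = z + 11)
  f1 <- dplyr::filter(fr, frame == 1)
  m1 <- dplyr::filter(moved, frame == 1)
  expect_equal(surface_z(m1), surface_z(f1) + 11)
  expect_equal(dipole_vector(m1)$cos_theta, dipole_vector(f1)$cos_theta,
               tolerance = 1e-12)
  expect_equal(interfacial_water_count(moved)$per_frame$count,
               interfacial_water_count(fr)$per_frame$count)
})

test_that("displaced-water difference recovers the planted contrast", {
  far <- interfacial_water_count(
    simulate_frames(n_frames = 25, n_waters = 400, n_interfacial = 250,
                    lipid_sd = 0, seed = 20))
  ads <- interfacial_water_count(
    simulate_frames(n_frames = 25, n_waters = 400, n_interfacial = 180,
                    lipid_sd = 0, seed = 21))
  d <- displaced_waters(far, ads)
  expect_equal(d$displaced, 70)

  same <- displaced_waters(far, far)
  expect_equal(same$displaced, 0)

  one <- interfacial_water_count(
    simulate_frames(n_frames = 1, n_waters = 50, n_interfacial = 10,
                    lipid_sd = 0, seed = 22))
  expect_warning(ds <- displaced_waters(one, one), "single frame")
  expect_true(is.na(ds$se))

  mismatched <- interfacial_water_count(
    simulate_frames(n_frames = 2, n_waters = 50, n_interfacial = 10,
                    lipid_sd = 0, seed = 23), cutoff = 5)
  expect_error(displaced_waters(far, mismatched), "incompatible")
})
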