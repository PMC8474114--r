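# Shared fixtures, all generated in code.

# Independent oracle for the depletion-corrected Langmuir root: solve the
# equilibrium condition K = (N/Nmax) / [(1 - N/Nmax) (C - N) / W] for N by
# bisection, without using the closed form under test.
adsorbed_conc_bisect <- function(C, K, Nmax, water_conc = 5.55e7,
                                 tol = 1e-12) {
  if (C == 0) return(0)
  g <- function(N) {
    theta <- N / Nmax
    K * (1 - theta) * (C - N) / water_conc - theta
  }
  lo <- 0
  hi <- min(C, Nmax) * (1 - 1e-15)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# A small umbrella set over a harmonic truth, for quick WHAM checks.
make_harmonic_windows <- function(kappa = 0.3, centers = seq(-4, 4, by = 1),
                                  spring = 4, n = 400, temp = 303, seed = 1,
                                  ...) {
  simulate_umbrella(function(z) 0.5 * kappa * z^2, centers = centers,
                    springs = spring, n_samples = n, temp = temp,
                    seed = seed, ...)
}

# A frame tibble with explicit atom placement (single frame).
make_frame <- function(lipid_z, water_z, dye = NULL) {
  n_l <- length(lipid_z)
  atoms <- tibble::tibble(
    frame = 1L,
    role = c(rep("lipid_oxygen", n_l), rep("water_oxygen", length(water_z))),
    lipid_id = c(seq_len(n_l), rep(NA_integer_, length(water_z))),
    x = 0, y = 0,
    z = c(lipid_z, water_z),
    charge = NA_real_
  )
  if (!is.null(dye)) {
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      frame = 1L, role = "dye", lipid_id = NA_integer_,
      x = dye$x, y = dye$y, z = dye$z, charge = dye$charge
    ))
  }
  atoms$atom <- seq_len(nrow(atoms))
  atoms
}

# 3-D rotation matrix from axis-angle.
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle); C <- 1 - c_
  matrix(c(
    a[1]^2 * C + c_,        a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
    a[2] * a[1] * C + a[3] * s, a[2]^2 * C + c_,        a[2] * a[3] * C - a[1] * s,
    a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s, a[3]^2 * C + c_
  ), nrow = 3, byrow = TRUE)
}

table1_params <- function() {
  tibble::tibble(
    temp_K = c(298.15, 303.15, 308.15, 313.15),
    K = c(9.1e7, 8.1e7, 7.2e7, 6.2e7),
    Nmax = c(5.4, 5.7, 6.0, 6.9),
    A = c(1.0, 0.85, 0.69, 0.60)
  )
}
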