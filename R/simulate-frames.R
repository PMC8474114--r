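#' Simulate labeled trajectory frames with planted ground truth
#'
#' Builds toy trajectory frames for the geometric observables: a lipid
#' leaflet whose outermost oxygens define the membrane surface, water oxygens
#' with a controlled number planted inside the interfacial slab, and a rigid
#' two-atom cationic dye whose dipole orientation follows a prescribed
#' distribution. The interface is perpendicular to the z axis throughout.
#'
#' Each lipid contributes two oxygen atoms: an outer one at
#' `surface_z + Normal(0, lipid_sd)` and an inner one 2 A below it, so the
#' per-lipid outermost-oxygen rule in [surface_z()] is exercised. Waters are
#' placed either with exactly `n_interfacial` of them uniform inside the slab
#' `(surface_z, surface_z + cutoff)` and the rest strictly above it
#' (`water_mode = "planted"`), or uniformly over `water_zrange`
#' (`water_mode = "uniform"`, for density-expectation checks).
#'
#' @param n_frames Number of frames.
#' @param n_lipids Lipids in the dye-facing leaflet; must be >= 1 (the
#'   interface is undefined without lipid oxygens).
#' @param n_waters Total water oxygens per frame.
#' @param n_interfacial Waters planted inside the interfacial slab per frame
#'   (`water_mode = "planted"`).
#' @param surface_z Planted mean surface position (A).
#' @param lipid_sd Standard deviation of outer-oxygen z positions (A);
#'   0 gives a degenerate flat plane.
#' @param cutoff Interfacial slab thickness used for planting (A).
#' @param box Box dimensions `c(Lx, Ly, Lz)` in angstroms.
#' @param water_mode `"planted"` or `"uniform"` (see Details).
#' @param water_zrange z range for `water_mode = "uniform"`.
#' @param orientation Dye orientation law: a list with `dist` one of
#'   `"point"` (fields: `cos_theta`), `"uniform"` (isotropic on the sphere,
#'   so cos(theta) is uniform on \[-1, 1\]), or `"cosnormal"` (fields:
#'   `mean`, `sd`; normal on cos(theta) truncated to \[-1, 1\]).
#' @param dye_charges Partial charges (e) of the two dye atoms; must sum to
#'   `net_charge`.
#' @param dye_length Separation of the two dye atoms along the dipole axis (A).
#' @param dye_z z position of the dye centroid (A).
#' @param net_charge Net charge of the dye cation (e); +1 for a
#'   triphenylmethane cation like malachite green.
#' @param seed Optional integer seed.
#'
#' @return A tibble with one row per atom per frame: `frame`, `atom`, `role`
#'   (`"lipid_oxygen"`, `"water_oxygen"`, `"dye"`), `lipid_id`, `x`, `y`,
#'   `z`, `charge`. Planted truths (surface position, per-frame interfacial
#'   water count, per-frame cos(theta)) are in `attr(, "truth")`.
#' @export
simulate_frames <- function(n_frames = 100, n_lipids = 100, n_waters = 500,
                            n_interfacial = 50, surface_z = 30,
                            lipid_sd = 0, cutoff = 3.5,
                            box = c(50, 50, 100),
                            water_mode = c("planted", "uniform"),
                            water_zrange = NULL,
                            orientation = list(dist = "point", cos_theta = 1),
                            dye_charges = c(0.7, 0.3), dye_length = 2,
                            dye_z = 40, net_charge = 1, seed = NULL) {
  water_mode <- match.arg(water_mode)
  check_number(n_frames, "n_frames", positive = TRUE)
  check_number(cutoff, "cutoff", positive = TRUE)
  if (n_lipids < 1) {
    abort("`n_lipids` must be >= 1: with no lipid oxygens the interface is undefined.")
  }
  if (water_mode == "planted" && n_interfacial > n_waters) {
    abort("`n_interfacial` cannot exceed `n_waters`.")
  }
  if (length(dye_charges) != 2) {
    abort("`dye_charges` must give the two dye atom charges.")
  }
  if (abs(sum(dye_charges) - net_charge) > 1e-9) {
    abort(sprintf(
      "`dye_charges` must sum to the net charge %+g e (got %+g).",
      net_charge, sum(dye_charges)
    ))
  }
  if (water_mode == "uniform" && is.null(water_zrange)) {
    water_zrange <- c(surface_z, box[3])
  }

  draw_cos_theta <- function(n) {
    switch(orientation$dist,
      point = rep(orientation$cos_theta, n),
      uniform = runif(n, -1, 1),
      cosnormal = {
        ct <- rnorm(n, orientation$mean, orientation$sd)
        # resample out-of-range draws: truncation, not clipping, so no atom
        # piles up at the poles
        bad <- which(abs(ct) > 1)
        while (length(bad) > 0) {
          ct[bad] <- rnorm(length(bad), orientation$mean, orientation$sd)
          bad <- bad[abs(ct[bad]) > 1]
        }
        ct
      },
      abort("`orientation$dist` must be 'point', 'uniform' or 'cosnormal'.")
    )
  }

  build <- function() {
    cos_theta <- draw_cos_theta(n_frames)
    phi <- runif(n_frames, 0, 2 * pi)
    frames <- purrr::map(seq_len(n_frames), function(f) {
      # lipid oxygens: outer defines the surface, inner 2 A below
      outer_z <- surface_z + rnorm(n_lipids, sd = lipid_sd)
      lx <- runif(2 * n_lipids, 0, box[1])
      ly <- runif(2 * n_lipids, 0, box[2])
      lipids <- tibble(
        frame = f,
        role = "lipid_oxygen",
        lipid_id = rep(seq_len(n_lipids), each = 2),
        x = lx, y = ly,
        z = as.vector(rbind(outer_z, outer_z - 2)),
        charge = NA_real_
      )

      if (water_mode == "planted") {
        eps <- 1e-6 * cutoff
        z_in <- runif(n_interfacial, surface_z + eps, surface_z + cutoff - eps)
        z_out <- runif(n_waters - n_interfacial,
                       surface_z + cutoff + 0.5, box[3])
        wz <- c(z_in, z_out)
        n_truth <- n_interfacial
      } else {
        wz <- runif(n_waters, water_zrange[1], water_zrange[2])
        n_truth <- sum(wz > surface_z & wz - surface_z <= cutoff)
      }
      waters <- tibble(
        frame = f,
        role = "water_oxygen",
        lipid_id = NA_integer_,
        x = runif(n_waters, 0, box[1]),
        y = runif(n_waters, 0, box[2]),
        z = wz,
        charge = NA_real_
      )

      # rigid dye: two atoms straddling the centroid along the dipole axis
      st <- sqrt(1 - cos_theta[f]^2)
      axis <- c(st * cos(phi[f]), st * sin(phi[f]), cos_theta[f])
      centroid <- c(box[1] / 2, box[2] / 2, dye_z)
      # the more positive atom sits at +axis so the dipole points along +axis
      r1 <- centroid + axis * dye_length / 2
      r2 <- centroid - axis * dye_length / 2
      dye <- tibble(
        frame = f,
        role = "dye",
        lipid_id = NA_integer_,
        x = c(r1[1], r2[1]), y = c(r1[2], r2[2]), z = c(r1[3], r2[3]),
        charge = if (dye_charges[1] >= dye_charges[2]) dye_charges else rev(dye_charges)
      )
      list(frame = bind_rows(lipids, waters, dye), n_truth = n_truth)
    })
    list(
      atoms = bind_rows(purrr::map(frames, "frame")),
      n_interfacial_true = purrr::map_dbl(frames, "n_truth"),
      cos_theta_true = cos_theta
    )
  }

  built <- with_seed_maybe(seed, build())
  out <- built$atoms %>%
    group_by(.data$frame) %>%
    mutate(atom = dplyr::row_number()) %>%
    ungroup() %>%
    select("frame", "atom", "role", "lipid_id", "x", "y", "z", "charge")
  attr(out, "truth") <- list(
    surface_z = surface_z, cutoff = cutoff,
    n_interfacial = built$n_interfacial_true,
    cos_theta = built$cos_theta_true,
    dipole_norm = abs(dye_charges[1] - dye_charges[2]) * dye_length / 2,
    box = box, orientation = orientation, seed = seed
  )
  out
}
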