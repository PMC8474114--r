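#' Membrane surface position from outermost lipid oxygens
#'
#' The surface is defined per frame as the mean over lipids of each lipid's
#' outermost oxygen z coordinate on the dye-facing leaflet ("outermost" =
#' extremal z: maximal for the upper leaflet, minimal for the lower). Lipid
#' oxygens without a `lipid_id` are each treated as their own lipid.
#'
#' @param frame Atom tibble for one frame (columns `role`, `z`, optional
#'   `lipid_id`), or a multi-frame tibble with a `frame` column, in which
#'   case one surface per frame is returned.
#' @param leaflet `"upper"` (dye side at larger z, default) or `"lower"`.
#'
#' @return A single z (angstroms) for one frame, or a tibble
#'   (`frame`, `z_surface`) for many.
#' @export
surface_z <- function(frame, leaflet = c("upper", "lower")) {
  leaflet <- match.arg(leaflet)
  check_columns(frame, c("role", "z"), "Frame")
  if ("frame" %in% names(frame) && dplyr::n_distinct(frame$frame) > 1) {
    out <- frame %>%
      group_by(.data$frame) %>%
      dplyr::group_modify(function(d, key) {
        tibble(z_surface = surface_z_one(d, leaflet))
      }) %>%
      ungroup()
    return(out)
  }
  surface_z_one(frame, leaflet)
}

surface_z_one <- function(frame, leaflet) {
  ox <- frame %>% filter(.data$role == "lipid_oxygen")
  if (nrow(ox) == 0) abort("Frame has no lipid oxygens: the surface is undefined.")
  if (!"lipid_id" %in% names(ox) || all(is.na(ox$lipid_id))) {
    ox$lipid_id <- seq_len(nrow(ox))
  }
  extremal <- if (leaflet == "upper") max else min
  per_lipid <- ox %>%
    group_by(.data$lipid_id) %>%
    summarise(z_out = extremal(.data$z), .groups = "drop")
  mean(per_lipid$z_out)
}

#' Dipole moment of the dye and its orientation to the membrane normal
#'
#' \eqn{\mu = \sum_a q_a (r_a - r_{ref})} over the dye atoms. For a
#' net-charged species the dipole depends on the reference point, so it is
#' pinned explicitly: the dye center of mass (mass-weighted when a `mass`
#' column is present, otherwise the unweighted centroid). The orientation
#' angle theta is measured against the membrane normal +z.
#'
#' @param frame Atom tibble for one frame; dye atoms are rows with
#'   `role == "dye"` and must all carry a `charge`.
#' @param origin `"com"` (center of mass / centroid, default) or a numeric
#'   length-3 reference point.
#'
#' @return A list with `mu` (e A, length 3), `norm`, `cos_theta`, `theta`
#'   (radians). A zero-norm dipole yields `cos_theta = NA` with a warning.
#' @export
dipole_vector <- function(frame, origin = "com") {
  check_columns(frame, c("role", "x", "y", "z", "charge"), "Frame")
  dye <- frame %>% filter(.data$role == "dye")
  if (nrow(dye) == 0) abort("Frame has no dye atoms.")
  if (any(is.na(dye$charge))) {
    abort("All dye atoms must carry a partial charge for the dipole.")
  }
  r <- as.matrix(dye[, c("x", "y", "z")])
  ref <- if (is.numeric(origin) && length(origin) == 3) {
    origin
  } else if (identical(origin, "com")) {
    m <- if ("mass" %in% names(dye) && !any(is.na(dye$mass))) dye$mass else rep(1, nrow(dye))
    colSums(r * m) / sum(m)
  } else {
    abort("`origin` must be \"com\" or a numeric length-3 point.")
  }
  mu <- colSums(dye$charge * sweep(r, 2, ref))
  nrm <- sqrt(sum(mu^2))
  if (nrm < 1e-12) {
    warn("Dipole has zero norm: orientation angle undefined.")
    return(list(mu = mu, norm = 0, cos_theta = NA_real_, theta = NA_real_))
  }
  ct <- mu[3] / nrm
  list(mu = unname(mu), norm = nrm, cos_theta = unname(ct),
       theta = acos(max(-1, min(1, ct))))
}

#' Orientation distribution of the dye dipole
#'
#' Computes cos(theta) per frame (theta = angle between the dye dipole and
#' the membrane normal +z), histograms it per group, and summarizes each
#' group by the mean and the standard deviation of cos(theta) (the spread
#' statistic: 0 for a point mass, larger for broader angular distributions).
#' Isotropic orientations give a flat cos(theta) histogram.
#'
#' @param frames Multi-frame atom tibble (a `frame` column is required).
#' @param group Optional name of a column that partitions frames into groups
#'   (e.g. a temperature label or umbrella window); `NULL` treats all frames
#'   as one group.
#' @param breaks Histogram breaks on \[-1, 1\].
#' @param min_frames Groups with fewer frames trigger a warning (default 50).
#' @param origin Dipole reference point, as in [dipole_vector()].
#'
#' @return An object of class `orientation_distribution`: `stats` (per-group
#'   `n`, `mean_cos`, `spread`) and `histogram` (per-group normalized
#'   probabilities summing to 1). [tidy()] returns the stats.
#' @export
orientation_distribution <- function(frames, group = NULL,
                                     breaks = seq(-1, 1, by = 0.1),
                                     min_frames = 50, origin = "com") {
  check_columns(frames, c("frame", "role", "x", "y", "z", "charge"), "Frames")
  key_cols <- c("frame", group)
  per_frame <- frames %>%
    group_by(dplyr::across(dplyr::all_of(key_cols))) %>%
    dplyr::group_modify(function(d, key) {
      tibble(cos_theta = dipole_vector(d, origin = origin)$cos_theta)
    }) %>%
    ungroup()
  if (is.null(group)) {
    per_frame$.group <- "all"
  } else {
    per_frame$.group <- as.character(per_frame[[group]])
  }
  if (nrow(per_frame) == 0) abort("No frames to analyze.")

  stats_tbl <- per_frame %>%
    group_by(.data$.group) %>%
    summarise(
      n = dplyr::n(),
      mean_cos = mean(.data$cos_theta, na.rm = TRUE),
      spread = if (dplyr::n() > 1) sd(.data$cos_theta, na.rm = TRUE) else 0,
      .groups = "drop"
    ) %>%
    dplyr::rename(group = ".group")
  low <- stats_tbl$group[stats_tbl$n < min_frames]
  if (length(low) > 0) {
    warn(sprintf("Group%s %s ha%s fewer than %d frames; distributions are noisy.",
                 if (length(low) > 1) "s" else "", paste(low, collapse = ", "),
                 if (length(low) > 1) "ve" else "s", min_frames))
  }

  hist_tbl <- per_frame %>%
    group_by(.data$.group) %>%
    dplyr::group_modify(function(d, key) {
      ct <- pmin(pmax(d$cos_theta, -1), 1)
      cnt <- tabulate(findInterval(ct, breaks, rightmost.closed = TRUE),
                      nbins = length(breaks) - 1)
      tibble(
        bin_lo = head(breaks, -1), bin_hi = tail(breaks, -1),
        bin_mid = (head(breaks, -1) + tail(breaks, -1)) / 2,
        prob = cnt / sum(cnt)
      )
    }) %>%
    ungroup() %>%
    dplyr::rename(group = ".group")

  structure(
    list(stats = stats_tbl, histogram = hist_tbl, per_frame = per_frame,
         breaks = breaks),
    class = "orientation_distribution"
  )
}

#' Interfacial water count
#'
#' Counts, per frame, the water oxygens within `cutoff` angstroms (along z)
#' of the membrane surface as defined by [surface_z()]. The slab is
#' one-sided by default — the water side of the surface, matching a dye
#' approaching from the aqueous phase — with a two-sided option.
#'
#' @param frames Multi-frame atom tibble.
#' @param cutoff Slab thickness in angstroms (default 3.5).
#' @param side `"water"` (one-sided, default) or `"both"`.
#' @param leaflet Passed to [surface_z()].
#'
#' @return An object of class `water_count`: `per_frame` (tibble `frame`,
#'   `z_surface`, `count`) and `mean`, `se` (NA for a single frame).
#' @export
interfacial_water_count <- function(frames, cutoff = 3.5,
                                    side = c("water", "both"),
                                    leaflet = "upper") {
  side <- match.arg(side)
  check_number(cutoff, "cutoff", positive = TRUE)
  check_columns(frames, c("frame", "role", "z"), "Frames")

  per_frame <- frames %>%
    group_by(.data$frame) %>%
    dplyr::group_modify(function(d, key) {
      zs <- surface_z_one(d, leaflet)
      wz <- d$z[d$role == "water_oxygen"]
      dz <- if (leaflet == "upper") wz - zs else zs - wz
      inside <- if (side == "water") dz >= 0 & dz <= cutoff else abs(dz) <= cutoff
      tibble(z_surface = zs, count = sum(inside))
    }) %>%
    ungroup()

  n <- nrow(per_frame)
  structure(
    list(
      per_frame = per_frame,
      mean = mean(per_frame$count),
      se = if (n > 1) sd(per_frame$count) / sqrt(n) else NA_real_,
      n = n, cutoff = cutoff, side = side, leaflet = leaflet
    ),
    class = "water_count"
  )
}

#' Waters displaced upon adsorption
#'
#' Difference of mean interfacial water counts between a reference state
#' (dye far from the interface) and the adsorbed state, with the combined
#' standard error \eqn{\sqrt{SE_1^2 + SE_2^2}}. Each adsorbing molecule
#' displacing many interfacial waters is what turns an ordering adsorption
#' event into a net entropy gain.
#'
#' @param counts_far `water_count` for the dye-far (reference) system.
#' @param counts_adsorbed `water_count` for the adsorbed system.
#'
#' @return A list with `displaced` (mean difference, far minus adsorbed),
#'   `se` (NA, flagged, when either side has a single frame), and the two
#'   inputs' means.
#' @export
displaced_waters <- function(counts_far, counts_adsorbed) {
  stopifnot(inherits(counts_far, "water_count"),
            inherits(counts_adsorbed, "water_count"))
  if (counts_far$cutoff != counts_adsorbed$cutoff ||
      counts_far$side != counts_adsorbed$side) {
    abort("The two counts use incompatible slab definitions (cutoff or side differ).")
  }
  se <- if (is.na(counts_far$se) || is.na(counts_adsorbed$se)) {
    warn("A single frame on one side: the standard error of the displaced-water count is undefined.")
    NA_real_
  } else {
    sqrt(counts_far$se^2 + counts_adsorbed$se^2)
  }
  list(
    displaced = counts_far$mean - counts_adsorbed$mean,
    se = se,
    mean_far = counts_far$mean,
    mean_adsorbed = counts_adsorbed$mean
  )
}

#' @export
print.orientation_distribution <- function(x, ...) {
  cat("Dye dipole orientation distribution (cos theta vs membrane normal)\n")
  print(x$stats)
  invisible(x)
}

#' @export
print.water_count <- function(x, ...) {
  cat(sprintf(
    "Interfacial water count (|dz| <= %.3g A, %s-sided): mean %.4g +/- %.3g over %d frames\n",
    x$cutoff, if (x$side == "water") "one" else "two", x$mean,
    x$se, x$n
  ))
  invisible(x)
}
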