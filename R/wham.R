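#' Discard equilibration samples from umbrella windows
#'
#' Removes the leading samples of every window, in sample order. The default
#' fraction 4/18 mirrors the common practice of discarding the first 4 ns of
#' an 18 ns window and analyzing the last 14 ns.
#'
#' @param samples Umbrella-sample tibble (`window`, `step`, `z`, ...).
#' @param fraction Leading fraction to drop (ignored when `count` is given).
#' @param count Absolute number of leading samples to drop per window.
#'
#' @return The trimmed sample tibble.
#' @export
#' @examples
#' s <- simulate_umbrella(function(z) 0 * z, centers = 0, springs = 10,
#'                        n_samples = 18, temp = 303, seed = 1)
#' nrow(equilibration_trim(s)) # 14 retained
equilibration_trim <- function(samples, fraction = 4 / 18, count = NULL) {
  check_columns(samples, c("window", "step", "z"), "Umbrella samples")
  trimmed <- samples %>%
    group_by(.data$window) %>%
    arrange(.data$step, .by_group = TRUE) %>%
    dplyr::group_modify(function(d, key) {
      drop_n <- if (!is.null(count)) count else floor(fraction * nrow(d))
      if (drop_n >= nrow(d)) {
        abort(sprintf(
          "Trimming %d samples would empty window %s (only %d samples).",
          drop_n, format(key$window), nrow(d)
        ))
      }
      if (drop_n > 0) d[-seq_len(drop_n), ] else d
    }) %>%
    ungroup()
  attr(trimmed, "truth") <- attr(samples, "truth")
  trimmed
}

# Internal WHAM engine on precomputed histograms.
#   counts: nwin x nbins matrix of histogram counts
#   bias:   nwin x nbins matrix of bias energies U_i(z_b) (kcal/mol)
# Returns list(p, f, iterations, converged, residual).
wham_iterate <- function(counts, bias, kBT, tol = 1e-8, max_iter = 1e5) {
  N_i <- rowSums(counts)
  M_b <- colSums(counts)
  keep <- M_b > 0
  logC <- -bias / kBT          # nwin x nbins
  f <- rep(0, nrow(counts))    # window free-energy shifts (kcal/mol)

  log_sum_exp <- function(x) {
    m <- max(x)
    m + log(sum(exp(x - m)))
  }

  iter <- 0L
  repeat {
    iter <- iter + 1L
    # p_b = M_b / sum_i N_i exp((f_i - U_i(b)) / kBT), restricted to occupied bins
    denom_log <- apply(logC[, keep, drop = FALSE] + f / kBT, 2, log_sum_exp_w, log(N_i))
    log_p <- log(M_b[keep]) - denom_log
    log_p <- log_p - log_sum_exp(log_p) # normalize over occupied bins
    # f_i = -kBT log sum_b p_b exp(-U_i(b)/kBT)
    f_new <- -kBT * apply(logC[, keep, drop = FALSE], 1, function(lc) {
      log_sum_exp(lc + log_p)
    })
    f_new <- f_new - f_new[1] # gauge: first window's shift is zero
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol || iter >= max_iter) break
  }

  p_full <- rep(NA_real_, ncol(counts))
  p_full[keep] <- exp(log_p)
  list(p = p_full, f = f, iterations = iter, converged = iter < max_iter,
       residual = delta, occupied = keep)
}

# column-wise log-sum-exp with per-row log weights
log_sum_exp_w <- function(x, logw) {
  v <- x + logw
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' Reconstruct a potential of mean force by WHAM
#'
#' Solves the standard weighted-histogram self-consistency equations
#' \deqn{p(z_b) = \frac{\sum_i n_{ib}}{\sum_i N_i \,
#'   e^{[f_i - U_i(z_b)]/k_B T}}, \qquad
#'   f_i = -k_B T \ln \sum_b p(z_b)\, e^{-U_i(z_b)/k_B T},}
#' iterated until the window shifts change by less than `tol`, then returns
#' \eqn{W(z) = -k_B T \ln p(z)} on the histogram grid. Bins with no samples
#' are reported as missing rather than assigned infinite energy, which avoids
#' fabricating barriers in unsampled regions. The profile is referenced to
#' zero at the mean over `bulk_region` when given (the far-from-interface
#' plateau), otherwise at its minimum.
#'
#' @param samples Umbrella-sample tibble with columns `window`, `center`,
#'   `spring`, `z`, optional `bias_offset`, and a consistent `temp_K` (or
#'   pass `temp`).
#' @param bin_width Histogram bin width in angstroms (default 0.25, about a
#'   sixth of a typical 1.5 A window spacing).
#' @param z_range Grid range; default covers all window centers +/- 3 A.
#' @param tol Convergence tolerance on max |delta f_i| (kcal/mol).
#' @param max_iter Maximum self-consistency iterations.
#' @param temp Temperature in kelvin (taken from `temp_K` when absent).
#' @param bulk_region Length-2 z interval used as the zero reference.
#'
#' @return An object of class `pmf_profile`: `profile` (tibble `z`, `W`,
#'   `err`, `counts`), `f` (window shifts), iteration diagnostics. [tidy()]
#'   returns the profile; [autoplot()] draws it.
#' @export
wham_solve <- function(samples, bin_width = 0.25, z_range = NULL,
                       tol = 1e-8, max_iter = 1e5, temp = NULL,
                       bulk_region = NULL) {
  check_columns(samples, c("window", "center", "spring", "z"), "Umbrella samples")
  check_number(bin_width, "bin_width", positive = TRUE)
  if (is.null(temp)) {
    if (!"temp_K" %in% names(samples)) {
      abort("Supply `temp` or a `temp_K` column.")
    }
    temps <- unique(samples$temp_K)
    if (length(temps) > 1) {
      abort("Windows carry inconsistent temperatures; WHAM assumes one ensemble.")
    }
    temp <- temps
  }
  check_number(temp, "temp", positive = TRUE)
  kBT <- .R_KCAL * temp

  meta <- samples %>%
    distinct(.data$window, .data$center, .data$spring,
             bias_offset = if ("bias_offset" %in% names(samples)) .data$bias_offset else 0)
  meta <- meta %>% arrange(.data$center)
  if (nrow(meta) > dplyr::n_distinct(meta$window)) {
    abort("A window appears with more than one (center, spring) combination.")
  }

  # overlap diagnostic: adjacent windows' sample ranges should overlap
  if (nrow(meta) > 1) {
    ranges <- samples %>%
      group_by(.data$window) %>%
      summarise(lo = min(.data$z), hi = max(.data$z),
                center = .data$center[1], .groups = "drop") %>%
      arrange(.data$center)
    gaps <- which(head(ranges$hi, -1) < tail(ranges$lo, -1))
    if (length(gaps) > 0) {
      warn(sprintf(
        "Sampled ranges of adjacent windows do not overlap between centers %s; the PMF may be disconnected there.",
        paste(sprintf("%.3g-%.3g", ranges$center[gaps], ranges$center[gaps + 1]),
              collapse = ", ")
      ))
    }
  }

  if (is.null(z_range)) z_range <- range(meta$center) + c(-3, 3)
  edges <- seq(z_range[1], z_range[2] + bin_width - 1e-12, by = bin_width)
  mids <- head(edges, -1) + bin_width / 2
  nbins <- length(mids)

  win_ids <- meta$window
  counts <- matrix(0, nrow = nrow(meta), ncol = nbins)
  for (i in seq_along(win_ids)) {
    zi <- samples$z[samples$window == win_ids[i]]
    zi <- zi[zi >= edges[1] & zi < edges[length(edges)]]
    counts[i, ] <- tabulate(findInterval(zi, edges), nbins = nbins)
  }
  bias <- outer(seq_len(nrow(meta)), seq_len(nbins), function(i, b) {
    0.5 * meta$spring[i] * (mids[b] - meta$center[i])^2 + meta$bias_offset[i]
  })

  sol <- wham_iterate(counts, bias, kBT, tol = tol, max_iter = max_iter)
  if (!sol$converged) {
    warn(sprintf(
      "WHAM did not converge in %d iterations (residual %.3g kcal/mol); check window overlap.",
      sol$iterations, sol$residual
    ))
  }

  W <- -kBT * log(sol$p)
  W <- reference_pmf(W, mids, bulk_region)

  structure(
    list(
      profile = tibble(z = mids, W = W, err = NA_real_, counts = colSums(counts)),
      f = tibble(window = win_ids, center = meta$center, f = sol$f),
      temp_K = temp, kBT = kBT,
      bin_width = bin_width, z_range = z_range,
      bulk_region = bulk_region,
      iterations = sol$iterations, converged = sol$converged,
      residual = sol$residual, tol = tol,
      n_samples = sum(counts)
    ),
    class = "pmf_profile"
  )
}

# Reference a PMF to zero at the bulk-region mean (or the minimum).
reference_pmf <- function(W, z, bulk_region) {
  if (!is.null(bulk_region)) {
    in_bulk <- z >= bulk_region[1] & z <= bulk_region[2] & is.finite(W)
    if (!any(in_bulk)) {
      abort("`bulk_region` contains no sampled bins on the grid.")
    }
    W - mean(W[in_bulk])
  } else {
    W - min(W, na.rm = TRUE)
  }
}

#' Construct a PMF profile from explicit values
#'
#' Builds a `pmf_profile` directly from a free-energy curve — useful for
#' feature extraction on constructed or externally computed profiles.
#'
#' @param z Grid positions (angstroms), strictly increasing.
#' @param W Free energy at each position (kcal/mol).
#' @param err Optional per-bin standard errors.
#' @param temp Temperature in kelvin.
#' @return A `pmf_profile`.
#' @export
pmf_profile <- function(z, W, err = NA_real_, temp = 303) {
  if (length(z) != length(W)) abort("`z` and `W` must have equal length.")
  if (any(diff(z) <= 0)) abort("`z` must be strictly increasing.")
  structure(
    list(
      profile = tibble(z = as.numeric(z), W = as.numeric(W),
                       err = rep_len(as.numeric(err), length(z)),
                       counts = NA_real_),
      f = NULL, temp_K = temp, kBT = .R_KCAL * temp,
      bin_width = if (length(z) > 1) stats::median(diff(z)) else NA_real_,
      z_range = range(z), bulk_region = NULL,
      iterations = 0L, converged = TRUE, residual = 0, tol = NA_real_,
      n_samples = NA_real_
    ),
    class = "pmf_profile"
  )
}

#' Block-averaged statistical errors for a WHAM profile
#'
#' Splits each window's samples, in order, into `n_blocks` contiguous blocks
#' (dropping any remainder with a warning), solves WHAM independently per
#' block, re-references each block profile, and reports the per-bin standard
#' error as the between-block standard deviation divided by sqrt(n_blocks).
#' With correlated (e.g. AR(1)) samples the between-block variance exceeds
#' the naive i.i.d. estimate, which is the point of blocking.
#'
#' @inheritParams wham_solve
#' @param n_blocks Number of contiguous blocks (>= 2). Four blocks mirrors
#'   14 ns of retained data split into 3.5 ns blocks.
#'
#' @return A `pmf_profile` (full-data solution) whose `err` column is filled
#'   for bins occupied in every block; block profiles are attached as
#'   `$blocks`.
#' @export
pmf_block_error <- function(samples, n_blocks = 4, bin_width = 0.25,
                            z_range = NULL, tol = 1e-8, max_iter = 1e5,
                            temp = NULL, bulk_region = NULL) {
  if (n_blocks < 2) abort("`n_blocks` must be >= 2.")
  check_columns(samples, c("window", "step", "z"), "Umbrella samples")

  full <- wham_solve(samples, bin_width = bin_width, z_range = z_range,
                     tol = tol, max_iter = max_iter, temp = temp,
                     bulk_region = bulk_region)

  blocked <- samples %>%
    group_by(.data$window) %>%
    arrange(.data$step, .by_group = TRUE) %>%
    dplyr::group_modify(function(d, key) {
      per <- nrow(d) %/% n_blocks
      if (per < 1) {
        abort(sprintf("Window %s has fewer samples than blocks.", format(key$window)))
      }
      dropped <- nrow(d) - per * n_blocks
      if (dropped > 0) {
        warn(sprintf("Window %s: %d trailing samples dropped to form %d equal blocks.",
                     format(key$window), dropped, n_blocks))
      }
      d[seq_len(per * n_blocks), ] %>%
        mutate(block = rep(seq_len(n_blocks), each = per))
    }) %>%
    ungroup()

  block_W <- purrr::map(seq_len(n_blocks), function(b) {
    sb <- blocked %>% filter(.data$block == b)
    pb <- wham_solve(sb, bin_width = bin_width,
                     z_range = full$z_range, tol = tol,
                     max_iter = max_iter, temp = full$temp_K,
                     bulk_region = bulk_region)
    pb$profile$W
  })
  Wmat <- do.call(cbind, block_W)
  # re-reference each block consistently when no bulk region pinned it:
  # align block profiles to the full profile by their mean offset over bins
  # finite in both (the PMF is defined up to a constant per block)
  if (is.null(bulk_region)) {
    cnt <- full$profile$counts
    for (b in seq_len(n_blocks)) {
      common <- is.finite(Wmat[, b]) & is.finite(full$profile$W)
      # count-weighted offset: fringe bins carry large W noise and would
      # otherwise dominate the alignment
      off <- sum(cnt[common] * (Wmat[common, b] - full$profile$W[common])) /
        sum(cnt[common])
      Wmat[, b] <- Wmat[, b] - off
    }
  }
  n_fin <- rowSums(is.finite(Wmat))
  err <- ifelse(
    n_fin == n_blocks,
    apply(Wmat, 1, sd) / sqrt(n_blocks),
    NA_real_
  )
  full$profile$err <- err
  full$blocks <- Wmat
  full$n_blocks <- n_blocks
  full
}

#' Barrier height and well depth of a PMF
#'
#' References the profile to the mean over a declared bulk region (the
#' plateau far from the interface), finds the global minimum (the adsorption
#' well), and measures the barrier as the highest point on the approach path
#' between the bulk region and the minimum, relative to the plateau. When
#' that maximum does not rise above the plateau — a monotone descent — the
#' barrier is zero and the process is classified barrierless; when
#' block-averaged errors are available and the barrier is smaller than the
#' error at the barrier bin it is flagged as "within error" (essentially
#' barrierless).
#'
#' @param pmf A `pmf_profile`.
#' @param bulk_region Length-2 z interval declaring the bulk plateau; must
#'   intersect the sampled grid.
#' @param tol Barriers smaller than this (kcal/mol) are treated as zero —
#'   numerical ripple on a plateau is not a barrier.
#'
#' @return A list: `barrier` and `barrier_z`, `depth` and `min_z`,
#'   `barrierless`, `within_error`, `plateau`.
#' @export
barrier_and_minimum <- function(pmf, bulk_region, tol = 1e-6) {
  stopifnot(inherits(pmf, "pmf_profile"))
  prof <- pmf$profile %>% filter(is.finite(.data$W))
  if (nrow(prof) == 0) abort("PMF has no finite bins.")
  in_bulk <- prof$z >= bulk_region[1] & prof$z <= bulk_region[2]
  if (!any(in_bulk)) abort("`bulk_region` lies outside the sampled grid.")
  plateau <- mean(prof$W[in_bulk])

  i_min <- which.min(prof$W)
  depth <- prof$W[i_min] - plateau
  z_min <- prof$z[i_min]

  # approach path: bins between the well and the near edge of the bulk region
  bulk_mid <- mean(range(prof$z[in_bulk]))
  lo <- min(z_min, bulk_mid)
  hi <- max(z_min, bulk_mid)
  on_path <- prof$z >= lo & prof$z <= hi
  i_max <- which(on_path)[which.max(prof$W[on_path])]
  barrier <- max(prof$W[i_max] - plateau, 0)
  if (barrier < tol) barrier <- 0
  z_barrier <- if (barrier > 0) prof$z[i_max] else NA_real_

  err_at_barrier <- if (barrier > 0 && !all(is.na(prof$err))) prof$err[i_max] else NA_real_
  within_error <- !is.na(err_at_barrier) && barrier < err_at_barrier

  list(
    barrier = barrier, barrier_z = z_barrier,
    depth = depth, min_z = z_min,
    plateau = plateau,
    barrierless = barrier == 0,
    within_error = within_error
  )
}

#' @export
print.pmf_profile <- function(x, ...) {
  fin <- sum(is.finite(x$profile$W))
  cat(sprintf("Potential of mean force (WHAM, T = %g K)\n", x$temp_K))
  cat(sprintf("  %d bins of %.3g A on [%.3g, %.3g] A; %d sampled\n",
              nrow(x$profile), x$bin_width, x$z_range[1], x$z_range[2], fin))
  cat(sprintf("  converged in %d iterations (max |df| = %.2g kcal/mol)\n",
              x$iterations, x$residual))
  if (!all(is.na(x$profile$err))) {
    cat(sprintf("  block-averaged errors from %d blocks (median %.3g kcal/mol)\n",
                x$n_blocks, stats::median(x$profile$err, na.rm = TRUE)))
  }
  invisible(x)
}
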