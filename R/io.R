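#' Read and write SHG time traces as CSV with a JSON sidecar
#'
#' The trace dialect is a plain CSV with header columns `time`, `intensity`
#' and optionally `sigma`, `conc_uM`, `temp_K`; unknown extra columns are
#' accepted and preserved. When the trace carries generator ground truth
#' (`attr(, "truth")`), `write_shg_trace()` records it — including the seed —
#' in a `<path>.json` sidecar, and `read_shg_trace()` restores it.
#'
#' @param trace A trace tibble.
#' @param path CSV file path.
#' @return `read_shg_trace()` returns the trace tibble; `write_shg_trace()`
#'   returns `path` invisibly.
#' @export
write_shg_trace <- function(trace, path) {
  check_columns(trace, c("time", "intensity"), "Trace")
  utils::write.csv(trace, path, row.names = FALSE)
  write_truth_sidecar(trace, path)
  invisible(path)
}

#' @rdname write_shg_trace
#' @export
read_shg_trace <- function(path) {
  df <- read_numeric_csv(path, required = c("time", "intensity"))
  attr(df, "truth") <- read_truth_sidecar(path)
  df
}

#' Read and write adsorption isotherms as CSV with a JSON sidecar
#'
#' Same dialect conventions as [write_shg_trace()], with required columns
#' `conc_uM` and `intensity`.
#'
#' @param isotherm An isotherm tibble.
#' @param path CSV file path.
#' @export
write_isotherm <- function(isotherm, path) {
  check_columns(isotherm, c("conc_uM", "intensity"), "Isotherm")
  utils::write.csv(isotherm, path, row.names = FALSE)
  write_truth_sidecar(isotherm, path)
  invisible(path)
}

#' @rdname write_isotherm
#' @export
read_isotherm <- function(path) {
  df <- read_numeric_csv(path, required = c("conc_uM", "intensity"))
  attr(df, "truth") <- read_truth_sidecar(path)
  df
}

# Tolerant CSV reader: requires named numeric columns, reports malformed
# cells with their row numbers, keeps unknown extra columns.
read_numeric_csv <- function(path, required) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(raw, required, basename(path))
  for (col in required) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(suppress) & !is.na(v) & v != "NA")
      if (length(bad) > 0) {
        abort(sprintf(
          "Non-numeric value%s in column `%s` of %s at data row%s %s.",
          if (length(bad) > 1) "s" else "", col, basename(path),
          if (length(bad) > 1) "s" else "",
          paste(bad, collapse = ", ")
        ))
      }
      raw[[col]] <- suppress
    }
  }
  as_tibble(raw)
}

write_truth_sidecar <- function(obj, path) {
  truth <- attr(obj, "truth")
  if (is.null(truth)) return(invisible(NULL))
  truth <- truth[!vapply(truth, is.function, logical(1))]
  jsonlite::write_json(truth, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

read_truth_sidecar <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) return(NULL)
  jsonlite::read_json(side, simplifyVector = TRUE)
}

#' Write and read umbrella-sampling windows in the two-column dialect
#'
#' Each window goes to its own whitespace-separated two-column file
#' (sample index, z in angstroms) — the de facto input dialect of
#' umbrella-sampling post-processors — plus a `manifest.json` holding the
#' bias centers, spring constants, offsets, temperature and file names.
#'
#' @param samples Umbrella-sample tibble (see [simulate_umbrella()]).
#' @param dir Directory for the window files and manifest.
#' @return `write_umbrella_windows()` returns the manifest path invisibly;
#'   `read_umbrella_windows()` returns the sample tibble.
#' @export
write_umbrella_windows <- function(samples, dir) {
  check_columns(samples, c("window", "center", "spring", "step", "z"),
                "Umbrella samples")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- samples %>%
    distinct(.data$window, .data$center, .data$spring,
             bias_offset = if ("bias_offset" %in% names(samples)) .data$bias_offset else 0) %>%
    arrange(.data$window) %>%
    mutate(file = sprintf("window_%03d.dat", .data$window))
  for (i in seq_len(nrow(meta))) {
    d <- samples %>% filter(.data$window == meta$window[i]) %>% arrange(.data$step)
    utils::write.table(d[, c("step", "z")],
                       file.path(dir, meta$file[i]),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    temperature = unique(samples$temp_K %||% NA_real_)[1],
    windows = meta
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}

#' @rdname write_umbrella_windows
#' @export
read_umbrella_windows <- function(dir) {
  manifest_path <- if (dir.exists(dir)) file.path(dir, "manifest.json") else dir
  if (!file.exists(manifest_path)) {
    abort(sprintf("No umbrella manifest found at %s.", manifest_path))
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  base <- dirname(manifest_path)
  meta <- as_tibble(manifest$windows)
  out <- purrr::map(seq_len(nrow(meta)), function(i) {
    d <- utils::read.table(file.path(base, meta$file[i]),
                           col.names = c("step", "z"))
    tibble(
      window = meta$window[i], center = meta$center[i],
      spring = meta$spring[i],
      bias_offset = meta$bias_offset[i] %||% 0,
      step = d$step, z = d$z,
      temp_K = manifest$temperature
    )
  })
  bind_rows(out)
}

#' Write and read trajectory frames as XYZ with a JSON sidecar
#'
#' Frames are written in plain XYZ (atom count, comment line `frame <i>`,
#' then `element x y z` rows); per-atom roles, lipid ids, charges and the box
#' dimensions — which XYZ cannot carry — go to a `<path>.json` sidecar. The
#' atom list must be identical across frames.
#'
#' @param frames Multi-frame atom tibble (see [simulate_frames()]).
#' @param path XYZ file path.
#' @param box Optional box dimensions recorded in the sidecar.
#' @export
write_xyz_frames <- function(frames, path, box = NULL) {
  check_columns(frames, c("frame", "atom", "role", "x", "y", "z"), "Frames")
  element <- c(lipid_oxygen = "O", water_oxygen = "O", dye = "C")
  con <- file(path, "w")
  on.exit(close(con))
  frame_ids <- sort(unique(frames$frame))
  first <- frames %>% filter(.data$frame == frame_ids[1]) %>% arrange(.data$atom)
  for (f in frame_ids) {
    d <- frames %>% filter(.data$frame == f) %>% arrange(.data$atom)
    if (!identical(d$role, first$role)) {
      abort("Atom list must be identical across frames for XYZ output.")
    }
    writeLines(as.character(nrow(d)), con)
    writeLines(sprintf("frame %d", f), con)
    writeLines(sprintf("%s %.6f %.6f %.6f",
                       dplyr::coalesce(element[d$role], "X"), d$x, d$y, d$z),
               con)
  }
  sidecar <- list(
    roles = first$role,
    lipid_id = first$lipid_id,
    charge = first$charge,
    box = box
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_xyz_frames
#' @export
read_xyz_frames <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  side <- paste0(path, ".json")
  if (!file.exists(side)) {
    abort(sprintf("Missing sidecar %s (roles/charges are required).", side))
  }
  sidecar <- jsonlite::read_json(side, simplifyVector = TRUE)
  lines <- readLines(path)
  out <- list()
  i <- 1L
  f <- 0L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) abort(sprintf("Malformed XYZ atom count at line %d.", i))
    f <- f + 1L
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(coords))) {
      abort(sprintf("Non-numeric coordinates in frame %d of %s.", f, basename(path)))
    }
    out[[f]] <- tibble(
      frame = f, atom = seq_len(n),
      role = sidecar$roles,
      lipid_id = sidecar$lipid_id %||% NA_integer_,
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      charge = sidecar$charge %||% NA_real_
    )
    i <- i + 2L + n
  }
  res <- bind_rows(out)
  attr(res, "box") <- sidecar$box
  res
}

#' Write a PMF profile as three-column text plus a JSON summary
#'
#' @param pmf A `pmf_profile`.
#' @param path Output text path (columns z, W, err); a `<path>.json` summary
#'   holds the window shifts and convergence diagnostics.
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_profile"))
  utils::write.table(pmf$profile[, c("z", "W", "err")], path,
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  summary <- list(
    temperature = pmf$temp_K, bin_width = pmf$bin_width,
    z_range = pmf$z_range, iterations = pmf$iterations,
    converged = pmf$converged, residual = pmf$residual,
    f = if (!is.null(pmf$f)) pmf$f else NULL
  )
  jsonlite::write_json(summary, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a fit report as JSON
#'
#' Serializes any fitted object with [tidy()]/[glance()] methods
#' (`transport_fit`, `langmuir_fit`, `vant_hoff_fit`) to a JSON report of
#' parameter estimates and fit statistics.
#'
#' @param obj A fitted object.
#' @param path JSON output path.
#' @export
write_fit_report <- function(obj, path) {
  report <- list(
    class = class(obj)[1],
    estimates = tidy(obj),
    statistics = glance(obj)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}
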