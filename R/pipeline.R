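#' Processing run configuration
#'
#' Collects every tunable processing parameter with the package's documented
#' defaults. A config round-trips unchanged through JSON serialisation
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param filter_cutoff_hz Temporal high-pass cutoff, Hz.
#' @param window_width,window_step Lateral analysis window width and step,
#'   in positions.
#' @param band Frequency band (Hz) for dispersion extraction.
#' @param pad_t,pad_x k-space zero-padding factors.
#' @param min_peak_fraction Peak threshold for [extract_dispersion()].
#' @param f_mode Modulus summary mode, `"per_sample"` or `"per_position"`.
#' @param rho Tissue density, kg/m^3.
#' @param structure_threshold_db Structural intensity threshold (dB) for the
#'   tissue mask and thickness estimate.
#' @param depth_band Optional length-2 depth-pixel band for the
#'   spatio-temporal reduction; `NULL` derives it from the structural image.
#' @param thickness Optional plate thickness (m); `NULL` estimates it from
#'   the structural image via [thickness_from_structure()].
#' @param direction Wave propagation direction sign (`+1`: toward increasing
#'   lateral position).
#' @param seed Seed recorded in the run manifest.
#' @param label Run label.
#' @return A list of class `run_config`.
#' @export
run_config <- function(filter_cutoff_hz = 200, window_width = 32L,
                       window_step = 8L, band = c(400, 4000),
                       pad_t = 4L, pad_x = 4L, min_peak_fraction = 0.1,
                       f_mode = "per_sample", rho = 1000,
                       structure_threshold_db = 20, depth_band = NULL,
                       thickness = NULL, direction = 1, seed = 1L,
                       label = "run") {
  structure(
    list(filter_cutoff_hz = filter_cutoff_hz,
         window_width = as.integer(window_width),
         window_step = as.integer(window_step),
         band = as.numeric(band),
         pad_t = as.integer(pad_t), pad_x = as.integer(pad_x),
         min_peak_fraction = min_peak_fraction, f_mode = f_mode,
         rho = rho, structure_threshold_db = structure_threshold_db,
         depth_band = if (!is.null(depth_band)) as.integer(depth_band),
         thickness = thickness, direction = direction,
         seed = as.integer(seed), label = label),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[!vapply(x, is.null, NA)])
}

#' Plate thickness from the structural image
#'
#' Median over lateral columns of the above-threshold depth run length,
#' converted to metres: `(last - first + 1) * axial_pixel_pitch /
#' refractive_index`. The default `refractive_index = 1` reports geometric
#' (pixel) thickness; pass the tissue index to apply an optical-path
#' correction.
#'
#' @param structure Real matrix (depth x lateral), dB.
#' @param threshold_db Intensity threshold, dB.
#' @param column_range Optional length-2 lateral column range.
#' @param axial_pixel_pitch Depth pixel size, metres.
#' @param refractive_index Optical-path correction divisor (default 1).
#' @return Thickness in metres.
#' @export
thickness_from_structure <- function(structure, threshold_db,
                                     column_range = NULL,
                                     axial_pixel_pitch = 4e-6,
                                     refractive_index = 1) {
  if (length(structure) == 0L) stop("empty structural image")
  if (is.null(column_range)) column_range <- c(1L, ncol(structure))
  cols <- column_range[1]:column_range[2]
  runs <- vapply(cols, function(j) {
    idx <- which(structure[, j] >= threshold_db)
    if (length(idx) == 0L) return(NA_real_)
    diff(range(idx)) + 1
  }, 0)
  runs <- runs[is.finite(runs)]
  if (length(runs) == 0L) stop("no above-threshold pixels in the structural image")
  stats::median(runs) * axial_pixel_pitch / refractive_index
}

# derive the tissue depth band (first/last above-threshold depth pixel,
# median over columns) from a structural image
derive_depth_band <- function(structure, threshold_db) {
  firsts <- apply(structure, 2L, function(col) {
    idx <- which(col >= threshold_db)
    if (length(idx)) idx[1] else NA_integer_
  })
  lasts <- apply(structure, 2L, function(col) {
    idx <- which(col >= threshold_db)
    if (length(idx)) idx[length(idx)] else NA_integer_
  })
  if (all(is.na(firsts))) stop("no above-threshold pixels: cannot derive depth band")
  c(as.integer(round(stats::median(firsts, na.rm = TRUE))),
    as.integer(round(stats::median(lasts, na.rm = TRUE))))
}

#' Run the full elastography processing chain on one scan
#'
#' Executes, in order: Doppler phase extraction, phase-to-displacement
#' conversion, spatio-temporal mapping, high-pass filtering, k-space
#' transform and dispersion extraction (globally and per lateral window),
#' 2D velocity mapping, and the modulus summary. When `out_dir` is given,
#' writes the dispersion curve CSV, summary CSV, velocity TIFF (+ scale
#' sidecar), structural overlay PNG and a machine-readable JSON run manifest
#' (parameters, seed, package version).
#'
#' @param scan An [mb_scan()] or a path to an HDF5 container written by
#'   [write_mbscan()].
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List with `velocity_map`, `dispersion_curve`, `elasticity`,
#'   `thickness`, `depth_band`, and `files` (named paths, when written).
#' @export
run_process <- function(scan, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  label <- if (!is.null(attr(scan, "label"))) attr(scan, "label") else config$label
  if (is.character(scan)) scan <- read_mbscan(scan)
  stopifnot(inherits(scan, "mb_scan"))
  phase <- doppler_phase_shift(scan)
  field <- phase_to_displacement(phase, scan$config)
  depth_band <- if (!is.null(config$depth_band)) config$depth_band
                else derive_depth_band(scan$structure, config$structure_threshold_db)
  thickness <- if (!is.null(config$thickness)) config$thickness
               else thickness_from_structure(scan$structure,
                                             config$structure_threshold_db,
                                             axial_pixel_pitch = scan$config$axial_pixel_pitch)
  # global dispersion curve over the full lateral extent
  stm <- spatiotemporal_map(field, depth_band)
  stm <- crop_time(stm, c(min(scan$config$excitation_end_aline + 1L, nrow(stm$values)),
                          nrow(stm$values)))
  stm <- highpass_filter(stm, config$filter_cutoff_hz)
  ks <- kspace_transform(stm, config$pad_t, config$pad_x)
  curve <- extract_dispersion(ks, config$band, config$min_peak_fraction,
                              config$direction)
  mask_cols <- apply(scan$structure, 2L,
                     function(col) any(col >= config$structure_threshold_db))
  vmap <- local_velocity_map(field,
                             window_width = config$window_width,
                             window_step = config$window_step,
                             band = config$band,
                             depth_bands = list(depth_band),
                             cutoff_hz = config$filter_cutoff_hz,
                             pad_t = config$pad_t, pad_x = config$pad_x,
                             min_peak_fraction = config$min_peak_fraction,
                             direction = config$direction,
                             mask = matrix(mask_cols, nrow = 1L))
  elast <- summarize_elasticity(vmap, thickness = thickness, rho = config$rho,
                                f_mode = config$f_mode, label = label)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    label <- gsub("[^A-Za-z0-9._-]", "_", label)
    files <- c(
      dispersion = file.path(out_dir, paste0(label, "_dispersion.csv")),
      summary = file.path(out_dir, paste0(label, "_summary.csv")),
      velocity_tiff = file.path(out_dir, paste0(label, "_velocity.tif")),
      overlay_png = file.path(out_dir, paste0(label, "_overlay.png")),
      manifest = file.path(out_dir, paste0(label, "_manifest.json"))
    )
    write_dispersion_csv(curve, files[["dispersion"]])
    write_elasticity_csv(elast, files[["summary"]])
    write_velocity_tiff(vmap, files[["velocity_tiff"]])
    overlay_velocity_on_structure(scan$structure, vmap,
                                  config$structure_threshold_db,
                                  file = files[["overlay_png"]])
    manifest <- list(parameters = unclass(config),
                     seed = config$seed,
                     label = label,
                     software = "arfoce",
                     version = as.character(utils::packageVersion("arfoce")))
    jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  list(velocity_map = vmap, dispersion_curve = curve, elasticity = elast,
       thickness = thickness, depth_band = depth_band, files = files)
}

#' Sweep-level summary over labelled runs
#'
#' Aggregates per-label [elasticity_result()] rows. For an `"iop"`-style
#' sweep it reports the percent increase of velocity and modulus between the
#' first and last label and a quadratic trend fit of modulus (and velocity)
#' against the sweep variable; for a `"direction"` sweep it reports the
#' maximum absolute deviation of the modulus from its across-direction mean,
#' quantifying directional constancy.
#'
#' @param results List of [elasticity_result()] objects (precomputed
#'   summaries or `$elasticity` components of [run_process()] outputs),
#'   at least 2, with unique labels, in sweep order.
#' @param sweep_kind `"iop"` or `"direction"`.
#' @param x Optional numeric sweep variable per result (e.g. pressure in
#'   mmHg); default parsed from the labels, falling back to the sequence
#'   index.
#' @return List with `table` (data frame) plus, for `"iop"`:
#'   `velocity_increase_pct`, `modulus_increase_pct`, `velocity_fit`,
#'   `modulus_fit`; for `"direction"`: `max_modulus_deviation`,
#'   `max_velocity_deviation` (same units as the inputs).
#' @export
run_sweep <- function(results, sweep_kind = c("iop", "direction"), x = NULL) {
  sweep_kind <- match.arg(sweep_kind)
  results <- lapply(results, function(r) {
    if (is.list(r) && !inherits(r, "elasticity_result") && !is.null(r$elasticity))
      r$elasticity else r
  })
  if (length(results) < 2L) stop("need at least 2 labelled runs")
  for (r in results) stopifnot(inherits(r, "elasticity_result"))
  labels <- vapply(results, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate labels in sweep")
  tab <- data.frame(
    label = labels,
    thickness_um = vapply(results, function(r) r$thickness * 1e6, 0),
    mean_velocity_m_s = vapply(results, `[[`, 0, "mean_velocity"),
    velocity_sd = vapply(results, `[[`, 0, "velocity_sd"),
    mean_modulus_kpa = vapply(results, function(r) r$mean_modulus / 1e3, 0),
    modulus_sd = vapply(results, function(r) r$modulus_sd / 1e3, 0),
    n_repeats = vapply(results, `[[`, 0L, "n_repeats")
  )
  if (is.null(x)) {
    x <- suppressWarnings(as.numeric(gsub("[^0-9.eE+-]", "", labels)))
    if (any(!is.finite(x))) x <- seq_along(results)
  }
  out <- list(table = tab, sweep_kind = sweep_kind, x = x)
  if (sweep_kind == "iop") {
    n <- nrow(tab)
    out$velocity_increase_pct <- percent_increase(tab$mean_velocity_m_s[1],
                                                  tab$mean_velocity_m_s[n])
    out$modulus_increase_pct <- percent_increase(tab$mean_modulus_kpa[1],
                                                 tab$mean_modulus_kpa[n])
    if (n >= 4L) {
      out$velocity_fit <- quadratic_trend_fit(x, tab$mean_velocity_m_s)
      out$modulus_fit <- quadratic_trend_fit(x, tab$mean_modulus_kpa)
    }
  } else {
    out$max_modulus_deviation <-
      max(abs(tab$mean_modulus_kpa - mean(tab$mean_modulus_kpa))) * 1e3
    out$max_velocity_deviation <-
      max(abs(tab$mean_velocity_m_s - mean(tab$mean_velocity_m_s)))
  }
  out
}
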