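#' Write / read an M-B scan as an HDF5 container
#'
#' On-disk format (`mbscan_format = "1"`): datasets `/field_real`,
#' `/field_imag` (depth x time x lateral) and `/structure`
#' (depth x lateral), with root attributes mirroring the
#' [acquisition_config()] field names in SI units.
#'
#' @param scan An [mb_scan()].
#' @param path Output `.h5` file path (overwritten if present).
#' @return `path` invisibly (writer); an `mb_scan` (reader).
#' @export
write_mbscan <- function(scan, path) {
  stopifnot(inherits(scan, "mb_scan"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(Re(scan$field), path, "field_real")
  rhdf5::h5write(Im(scan$field), path, "field_imag")
  rhdf5::h5write(scan$structure, path, "structure")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute("1", fid, "mbscan_format")
  for (nm in names(scan$config))
    rhdf5::h5writeAttribute(scan$config[[nm]], fid, nm)
  invisible(path)
}

#' @rdname write_mbscan
#' @export
read_mbscan <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  present <- rhdf5::h5ls(path, recursive = FALSE)$name
  for (ds in c("field_real", "field_imag", "structure"))
    if (!ds %in% present)
      stop(sprintf("malformed MBScan container: missing dataset '/%s'", ds))
  at <- rhdf5::h5readAttributes(path, "/")
  if (is.null(at$mbscan_format))
    stop("malformed MBScan container: missing attribute 'mbscan_format'")
  if (!identical(as.character(at$mbscan_format), "1"))
    stop("unsupported mbscan_format version: ", at$mbscan_format)
  need <- setdiff(names(formals(acquisition_config)), character(0))
  missing_at <- setdiff(need, names(at))
  if (length(missing_at) > 0L)
    stop("malformed MBScan container: missing attribute '", missing_at[1], "'")
  cfg <- do.call(acquisition_config, lapply(at[need], as.vector))
  re <- rhdf5::h5read(path, "field_real")
  im <- rhdf5::h5read(path, "field_imag")
  st <- rhdf5::h5read(path, "structure")
  mb_scan(array(complex(real = re, imaginary = im), dim = dim(re)), cfg,
          structure = st)
}

# perceptually ordered blue->green->yellow velocity ramp
velocity_palette <- function(n = 256L) {
  grDevices::colorRamp(c("#440154", "#3B528B", "#21918C", "#5EC962", "#FDE725"))(
    seq(0, 1, length.out = n)) / 255
}

#' Render a velocity map over the structural image
#'
#' Draws the structural (log-intensity) image in greyscale and colours every
#' pixel whose intensity reaches `intensity_threshold` with the local phase
#' velocity; a vertical colour-bar strip is appended on the right. The
#' velocity limits in m/s are stored as PNG text metadata
#' (`velocity_min`, `velocity_max`, `units`).
#'
#' @param structure Real matrix (depth x lateral) of log-intensity, dB.
#' @param vmap A [local_velocity_map()] result; row `band` supplies the
#'   per-position velocities.
#' @param intensity_threshold Structure threshold in dB.
#' @param file Optional PNG output path.
#' @param vlim Optional length-2 colour-scale limits in m/s; default the
#'   finite velocity range.
#' @param band Velocity-map row (depth band) to render.
#' @return Invisibly, a list with the RGB array (`rgb`, depth x width x 3),
#'   the limits `vlim` and the number of coloured pixels `n_colored`.
#' @export
overlay_velocity_on_structure <- function(structure, vmap, intensity_threshold,
                                          file = NULL, vlim = NULL, band = 1L) {
  stopifnot(inherits(vmap, "velocity_map"))
  if (ncol(structure) != ncol(vmap$velocity))
    stop("structure and velocity map are not laterally aligned")
  v <- vmap$velocity[band, ]
  if (is.null(vlim)) {
    fin <- v[is.finite(v)]
    vlim <- if (length(fin)) range(fin) else c(0, 1)
    if (diff(vlim) == 0) vlim <- vlim + c(-0.5, 0.5)
  }
  pal <- velocity_palette()
  g <- (structure - min(structure)) / max(1e-12, diff(range(structure)))
  img <- array(rep(g, 3L), dim = c(nrow(structure), ncol(structure), 3L))
  colored <- 0L
  for (j in seq_len(ncol(structure))) {
    if (!is.finite(v[j]) || !vmap$mask[band, j]) next
    rows <- which(structure[, j] >= intensity_threshold)
    if (length(rows) == 0L) next
    u <- min(1, max(0, (v[j] - vlim[1]) / max(1e-12, diff(vlim))))
    ci <- pal[1L + round(u * (nrow(pal) - 1L)), ]
    img[rows, j, 1] <- ci[1]; img[rows, j, 2] <- ci[2]; img[rows, j, 3] <- ci[3]
    colored <- colored + length(rows)
  }
  # colour-bar strip: 2-pixel gap + ramp column block
  nbar <- max(4L, ncol(structure) %/% 16L)
  bar <- array(0, dim = c(nrow(img), nbar + 2L, 3L))
  ramp_idx <- round(seq(nrow(pal), 1L, length.out = nrow(img)))
  for (ch in 1:3)
    bar[, 3:(nbar + 2L), ch] <- matrix(pal[ramp_idx, ch], nrow(img), nbar)
  out <- array(0, dim = c(nrow(img), ncol(img) + nbar + 2L, 3L))
  out[, seq_len(ncol(img)), ] <- img
  out[, ncol(img) + seq_len(nbar + 2L), ] <- bar
  if (!is.null(file))
    png::writePNG(out, file, text = c(velocity_min = format(vlim[1]),
                                      velocity_max = format(vlim[2]),
                                      units = "m/s"))
  invisible(list(rgb = out, vlim = vlim, n_colored = colored))
}

#' Write a velocity map as a TIFF raster plus a JSON scale sidecar
#'
#' Velocities (m/s) are stored normalised to `[0, 1]` in a 32-bit TIFF; the
#' physical scale and offset are written to `<path>.json`
#' (`value_m_per_s = offset + scale * sample`). Non-finite pixels are
#' written as 0 and flagged in the sidecar mask count.
#'
#' @param vmap A [local_velocity_map()] result.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_velocity_tiff <- function(vmap, path) {
  stopifnot(inherits(vmap, "velocity_map"))
  v <- vmap$velocity
  fin <- is.finite(v)
  lo <- if (any(fin)) min(v[fin]) else 0
  hi <- if (any(fin)) max(v[fin]) else 1
  scale <- max(hi - lo, 1e-12)
  norm <- (v - lo) / scale
  norm[!fin] <- 0
  tiff::writeTIFF(norm, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(offset_m_per_s = lo, scale_m_per_s = scale,
         n_masked = sum(!fin), units = "m/s"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write elasticity results as a summary CSV table
#'
#' Columns:
#' `label,thickness_um,mean_velocity_m_s,velocity_sd,mean_modulus_kpa,modulus_sd,n_repeats`.
#'
#' @param results A list of [elasticity_result()] objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_elasticity_csv <- function(results, path) {
  if (inherits(results, "elasticity_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    stopifnot(inherits(r, "elasticity_result"))
    data.frame(label = r$label,
               thickness_um = r$thickness * 1e6,
               mean_velocity_m_s = r$mean_velocity,
               velocity_sd = r$velocity_sd,
               mean_modulus_kpa = r$mean_modulus / 1e3,
               modulus_sd = r$modulus_sd / 1e3,
               n_repeats = r$n_repeats)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a summary table of printed means into elasticity results
#'
#' Reads a CSV in the [write_elasticity_csv()] dialect (thickness in um,
#' modulus in kPa) and returns the rows as `elasticity_result` objects, e.g.
#' for feeding published summary tables into [run_sweep()].
#'
#' @param path CSV path.
#' @return List of [elasticity_result()] objects.
#' @export
read_elasticity_csv <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  need <- c("label", "thickness_um", "mean_velocity_m_s", "velocity_sd",
            "mean_modulus_kpa", "modulus_sd", "n_repeats")
  if (!all(need %in% names(df)))
    stop("summary CSV missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    elasticity_result(df$label[i], df$thickness_um[i] * 1e-6,
                      df$mean_velocity_m_s[i], df$velocity_sd[i],
                      df$mean_modulus_kpa[i] * 1e3, df$modulus_sd[i] * 1e3,
                      df$n_repeats[i]))
}
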