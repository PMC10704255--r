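#' OCT acquisition configuration
#'
#' Describes the M-B acquisition: a swept-source phase-sensitive OCT system
#' records `alines_per_position` A-lines at each lateral position (M-mode),
#' the acoustic-radiation-force push firing between
#' `excitation_start_aline` and `excitation_end_aline`, then the beam steps
#' laterally and the M-mode repeats (M-B protocol).
#'
#' @param center_wavelength Source centre wavelength lambda0 in metres.
#' @param aline_rate A-line (sweep) repetition rate in Hz.
#' @param alines_per_position Number of A-lines per lateral position.
#' @param excitation_start_aline,excitation_end_aline 1-based indices of the
#'   A-lines bracketing the ARF push.
#' @param lateral_positions_n Number of lateral beam positions.
#' @param lateral_step Lateral spacing between positions, metres.
#' @param refractive_index Bulk tissue refractive index `n` used in the
#'   phase-to-displacement conversion.
#' @param axial_pixel_pitch Axial (depth) pixel size in metres.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(center_wavelength = 1300e-9,
                               aline_rate = 50e3,
                               alines_per_position = 1000L,
                               excitation_start_aline = 101L,
                               excitation_end_aline = 125L,
                               lateral_positions_n = 256L,
                               lateral_step = 50e-6,
                               refractive_index = 1.38,
                               axial_pixel_pitch = 4e-6) {
  phys <- c(center_wavelength, aline_rate, alines_per_position,
            lateral_positions_n, lateral_step, refractive_index,
            axial_pixel_pitch)
  if (any(!is.finite(phys)) || any(phys <= 0))
    stop("all physical acquisition quantities must be positive")
  if (!(excitation_start_aline >= 1 &&
        excitation_start_aline < excitation_end_aline &&
        excitation_end_aline <= alines_per_position))
    stop("need 1 <= excitation_start_aline < excitation_end_aline <= alines_per_position")
  structure(
    list(center_wavelength = center_wavelength,
         aline_rate = aline_rate,
         alines_per_position = as.integer(alines_per_position),
         excitation_start_aline = as.integer(excitation_start_aline),
         excitation_end_aline = as.integer(excitation_end_aline),
         lateral_positions_n = as.integer(lateral_positions_n),
         lateral_step = lateral_step,
         refractive_index = refractive_index,
         axial_pixel_pitch = axial_pixel_pitch),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    paste0("acquisition_config: lambda0 = %g nm, %g kHz A-line rate, ",
           "%d A-lines/position (push @ %d-%d), %d positions x %g um, n = %g\n"),
    x$center_wavelength * 1e9, x$aline_rate / 1e3, x$alines_per_position,
    x$excitation_start_aline, x$excitation_end_aline,
    x$lateral_positions_n, x$lateral_step * 1e6, x$refractive_index))
  invisible(x)
}

#' M-B-mode complex OCT scan
#'
#' Container for the complex OCT field cube over (depth, time, lateral) plus
#' its acquisition metadata and a structural (log-intensity) image. If
#' `structure` is not supplied it is computed as
#' `20 * log10(time-mean of |field|)` per (depth, lateral) pixel.
#'
#' @param field Complex array, dim `(depth, time, lateral)` with
#'   `time == config$alines_per_position` and
#'   `lateral == config$lateral_positions_n`.
#' @param config An [acquisition_config()].
#' @param structure Optional real matrix `(depth, lateral)` of log-intensity
#'   in dB.
#' @return Object of class `mb_scan` with fields `field`, `config`,
#'   `structure`.
#' @export
mb_scan <- function(field, config, structure = NULL) {
  stopifnot(inherits(config, "acquisition_config"))
  if (!is.array(field) || length(dim(field)) != 3L)
    stop("'field' must be a 3-d array (depth x time x lateral)")
  if (!is.complex(field)) stop("'field' must be complex")
  d <- dim(field)
  if (d[2] != config$alines_per_position)
    stop("time dimension must equal config$alines_per_position")
  if (d[3] != config$lateral_positions_n)
    stop("lateral dimension must equal config$lateral_positions_n")
  if (is.null(structure)) {
    tmean <- rowMeans(aperm(Mod(field), c(1L, 3L, 2L)), dims = 2L)
    structure <- 20 * log10(pmax(tmean, .Machine$double.xmin))
  }
  if (!all(dim(structure) == d[c(1, 3)]))
    stop("'structure' must be (depth x lateral)")
  structure(list(field = field, config = config, structure = structure),
            class = "mb_scan")
}

#' @export
print.mb_scan <- function(x, ...) {
  d <- dim(x$field)
  cat(sprintf("mb_scan: %d depth x %d time x %d lateral complex samples\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Phase-resolved Doppler phase shift
#'
#' Inter-A-line Doppler phase at every (depth, lateral) pixel,
#' \deqn{\Delta\varphi_m = \mathrm{atan2}\!\big(\mathrm{Im}(F_m F_{m+1}^*),
#'   \mathrm{Re}(F_m F_{m+1}^*)\big) \in (-\pi, \pi],}
#' where `F_m` is the complex OCT signal at A-line `m`. With the simulator's
#' convention (optical phase decreases as the scatterer moves away from the
#' source) a positive phase shift corresponds to motion toward the beam
#' source.
#'
#' @param scan An [mb_scan()] with at least 2 A-lines per position.
#' @return Numeric array of phase shifts, dim `(depth, time - 1, lateral)`,
#'   values in `(-pi, pi]`.
#' @export
doppler_phase_shift <- function(scan) {
  stopifnot(inherits(scan, "mb_scan"))
  d <- dim(scan$field)
  if (d[2] < 2L) stop("need >=2 A-lines per position for Doppler processing")
  prod <- scan$field[, -d[2], , drop = FALSE] * Conj(scan$field[, -1L, , drop = FALSE])
  atan2(Im(prod), Re(prod))
}

#' Convert Doppler phase to axial displacement
#'
#' Element-wise linear map
#' \deqn{\Delta d = \frac{\lambda_0}{4 \pi n} \Delta\varphi,}
#' with `lambda0` the centre wavelength and `n` the tissue refractive index.
#'
#' @param phase Array of Doppler phase shifts in rad, dim
#'   `(depth, time - 1, lateral)` (a matrix or vector is also accepted and
#'   mapped element-wise).
#' @param config An [acquisition_config()].
#' @return A `displacement_field`: list with `displacement` (m, same dim as
#'   `phase`), `time_axis` (s; midpoint convention, step `1/aline_rate`),
#'   `lateral_axis` (m), `differential = TRUE` and the `config`.
#' @export
phase_to_displacement <- function(phase, config) {
  stopifnot(inherits(config, "acquisition_config"))
  if (any(!is.finite(phase))) stop("'phase' must be finite everywhere")
  disp <- config$center_wavelength * phase / (4 * pi * config$refractive_index)
  if (!(is.array(phase) && length(dim(phase)) == 3L)) return(disp)
  displacement_field(disp, config, differential = TRUE)
}

#' Construct a displacement field
#'
#' @param displacement Array (depth, time, lateral) of axial displacement, m.
#'   For Doppler-derived fields the time dimension is `alines - 1` and each
#'   sample is the inter-A-line differential displacement
#'   (`differential = TRUE`); simulator ground truth carries the absolute
#'   displacement on the full A-line grid (`differential = FALSE`).
#' @param config An [acquisition_config()].
#' @param differential Logical, see above.
#' @return Object of class `displacement_field`.
#' @keywords internal
#' @export
displacement_field <- function(displacement, config, differential = TRUE) {
  stopifnot(inherits(config, "acquisition_config"))
  if (!is.array(displacement) || length(dim(displacement)) != 3L)
    stop("'displacement' must be a 3-d array (depth x time x lateral)")
  nt <- dim(displacement)[2]
  t0 <- if (differential) 1 else 0
  structure(
    list(displacement = displacement,
         time_axis = (t0 + seq_len(nt) - 1) / config$aline_rate,
         lateral_axis = (seq_len(dim(displacement)[3]) - 1) * config$lateral_step,
         differential = isTRUE(differential),
         config = config),
    class = "displacement_field"
  )
}

#' Temporal phase unwrapping
#'
#' Removes 2*pi jumps along the time axis so that successive differences lie
#' in `(-pi, pi]`; the first sample is unchanged. Needed whenever the
#' inter-A-line phase may exceed pi in magnitude.
#'
#' @param phase Numeric vector (time), matrix (time x lateral) or 3-d array
#'   (depth x time x lateral) of phases in rad.
#' @return Unwrapped phases, same shape.
#' @export
unwrap_temporal <- function(phase) {
  unwrap1 <- function(v) {
    if (length(v) < 2L) return(v)
    d <- diff(v)
    d <- d - 2 * pi * round(d / (2 * pi))
    v[1] + c(0, cumsum(d))
  }
  if (is.null(dim(phase))) return(unwrap1(phase))
  if (length(dim(phase)) == 2L) return(apply(phase, 2L, unwrap1))
  out <- apply(phase, c(1L, 3L), unwrap1)      # result: time x depth x lateral
  aperm(out, c(2L, 1L, 3L))
}

#' Spatio-temporal displacement map
#'
#' Reduces a displacement field to a (time x lateral) map at a single depth
#' or as the mean over a depth band -- the representation on which k-space
#' dispersion analysis operates.
#'
#' @param field A [displacement_field()].
#' @param depth_range Length-2 integer vector `(first, last)` of depth pixel
#'   indices (inclusive). For `reduce = "single_depth"` only `depth_range[1]`
#'   is used.
#' @param reduce `"mean_over_range"` (default) or `"single_depth"`.
#' @return Object of class `spatiotemporal_map`: list with matrix `values`
#'   (time x lateral, metres), `time_axis`, `lateral_axis`,
#'   `depth_range_used`, `filtered = FALSE`, and the sampling rates `fs`
#'   (Hz) and `dx` (m).
#' @export
spatiotemporal_map <- function(field, depth_range,
                               reduce = c("mean_over_range", "single_depth")) {
  stopifnot(inherits(field, "displacement_field"))
  reduce <- match.arg(reduce)
  d <- dim(field$displacement)
  depth_range <- as.integer(depth_range)
  if (length(depth_range) != 2L || depth_range[1] > depth_range[2])
    stop("empty depth range")
  if (depth_range[1] < 1L || depth_range[2] > d[1])
    stop("depth range outside array bounds")
  vals <- if (reduce == "single_depth") {
    field$displacement[depth_range[1], , ]
  } else {
    rows <- depth_range[1]:depth_range[2]
    if (length(rows) == 1L) field$displacement[rows, , ]
    else colMeans(field$displacement[rows, , , drop = FALSE], dims = 1)
  }
  structure(
    list(values = matrix(vals, nrow = d[2], ncol = d[3]),
         time_axis = field$time_axis, lateral_axis = field$lateral_axis,
         depth_range_used = depth_range, reduce = reduce, filtered = FALSE,
         fs = field$config$aline_rate, dx = field$config$lateral_step),
    class = "spatiotemporal_map"
  )
}

#' Temporal high-pass filtering of a spatio-temporal map
#'
#' Removes DC and low-frequency drift (bulk motion, push recovery) from each
#' lateral column with a zero-phase (forward-backward) Butterworth high-pass.
#' Zero-phase filtering is used so arrival times are not biased.
#'
#' @param map A [spatiotemporal_map()].
#' @param cutoff_hz High-pass cutoff in Hz; must be below the temporal
#'   Nyquist frequency `fs/2`. Default 200 Hz.
#' @param order Butterworth order of the underlying filter (applied forward
#'   and backward). Default 4.
#' @return The filtered map with `filtered = TRUE`.
#' @export
highpass_filter <- function(map, cutoff_hz = 200, order = 4L) {
  stopifnot(inherits(map, "spatiotemporal_map"))
  if (cutoff_hz <= 0 || cutoff_hz >= map$fs / 2)
    stop("'cutoff_hz' must lie in (0, aline_rate/2)")
  bf <- signal::butter(order, cutoff_hz / (map$fs / 2), type = "high")
  v <- map$values
  v <- sweep(v, 2L, colMeans(v))          # remove DC before edge-padding filter
  for (j in seq_len(ncol(v)))
    v[, j] <- signal::filtfilt(bf, v[, j])
  map$values <- v
  map$filtered <- TRUE
  map
}

#' Crop a spatio-temporal map in time
#'
#' Restricts the map to a sample-index window, e.g. the post-excitation
#' samples used for wave tracking.
#'
#' @param map A [spatiotemporal_map()].
#' @param time_range Length-2 integer `(first, last)` sample indices.
#' @return The cropped map.
#' @export
crop_time <- function(map, time_range) {
  stopifnot(inherits(map, "spatiotemporal_map"))
  time_range <- as.integer(time_range)
  n <- nrow(map$values)
  if (time_range[1] < 1L || time_range[2] > n || time_range[1] > time_range[2])
    stop("invalid time range")
  idx <- time_range[1]:time_range[2]
  map$values <- map$values[idx, , drop = FALSE]
  map$time_axis <- map$time_axis[idx]
  map
}
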