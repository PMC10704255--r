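#' Acoustic-radiation-force excitation specification
#'
#' Describes the displacement transient launched by the focused-ultrasound
#' push as seen at the A-line rate: a Gaussian amplitude spectrum centred on
#' `center_frequency` with full width at half maximum `bandwidth`. The
#' MHz-range ultrasound carrier itself is far above the detection bandwidth
#' and is not modelled -- only the induced tissue displacement envelope
#' matters.
#'
#' @param center_frequency Spectral centre of the push transient, Hz.
#' @param bandwidth FWHM of the Gaussian amplitude spectrum, Hz; must
#'   satisfy `center_frequency - bandwidth/2 > 0`.
#' @param push_position Lateral coordinate of the ARF focus, metres.
#' @param push_duration Push duration in seconds (consistent with the
#'   excitation A-line window in [acquisition_config()]).
#' @param peak_displacement Peak tissue displacement, metres.
#' @return Object of class `excitation_spec`.
#' @export
excitation_spec <- function(center_frequency = 2000, bandwidth = 1500,
                            push_position = 0, push_duration = 500e-6,
                            peak_displacement = 150e-9) {
  if (center_frequency - bandwidth / 2 <= 0)
    stop("'center_frequency - bandwidth/2' must be positive")
  if (peak_displacement < 0) stop("'peak_displacement' must be >= 0")
  if (push_duration <= 0) stop("'push_duration' must be positive")
  structure(
    list(center_frequency = center_frequency, bandwidth = bandwidth,
         push_position = push_position, push_duration = push_duration,
         peak_displacement = peak_displacement),
    class = "excitation_spec"
  )
}

#' Phantom geometry for the synthetic M-B scan
#'
#' A laterally segmented plate phantom: each segment carries its own
#' [plate_material()], enabling lateral stiffness contrast; a homogeneous
#' plate is a single segment. The plate occupies the depth-pixel band
#' `tissue_band`; pixels outside it are background.
#'
#' @param segments List of segments, each a list with `width` (metres;
#'   `Inf` for "the rest of the lateral extent", allowed in the last
#'   segment only) and `material` (a [plate_material()]).
#' @param depth_pixels Number of depth pixels in the cube.
#' @param tissue_band Length-2 integer depth-pixel band occupied by tissue.
#' @param tissue_intensity_db,background_intensity_db Structural
#'   log-intensities used for the synthetic amplitude pattern.
#' @return Object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(segments, depth_pixels = 128L,
                             tissue_band = c(3L, 126L),
                             tissue_intensity_db = 40,
                             background_intensity_db = 5) {
  if (!is.list(segments) || length(segments) == 0L)
    stop("'segments' must be a non-empty list")
  for (s in segments) {
    if (!is.list(s) || is.null(s$width) || is.null(s$material))
      stop("each segment needs 'width' and 'material'")
    stopifnot(inherits(s$material, "plate_material"))
    if (s$width <= 0) stop("segment widths must be positive")
  }
  if (any(vapply(segments[-length(segments)], function(s) is.infinite(s$width), NA)))
    stop("only the last segment may have infinite width")
  tissue_band <- as.integer(tissue_band)
  if (tissue_band[1] < 1L || tissue_band[2] > depth_pixels ||
      tissue_band[1] > tissue_band[2])
    stop("'tissue_band' must lie within the depth extent")
  structure(
    list(segments = segments, depth_pixels = as.integer(depth_pixels),
         tissue_band = tissue_band,
         tissue_intensity_db = tissue_intensity_db,
         background_intensity_db = background_intensity_db),
    class = "phantom_geometry"
  )
}

#' Homogeneous plate phantom
#'
#' Convenience constructor: a single-segment phantom of Young's modulus `E`
#' (`mu = E/3`) spanning the whole lateral extent.
#'
#' @param E Young's modulus in Pa.
#' @param thickness Plate thickness in metres.
#' @param rho Density, kg/m^3.
#' @param ... Passed to [phantom_geometry()].
#' @return A [phantom_geometry()].
#' @export
homogeneous_phantom <- function(E, thickness = 496e-6, rho = 1000, ...) {
  phantom_geometry(
    list(list(width = Inf,
              material = plate_material(E / 3, rho, thickness))), ...)
}

# segment index for each lateral position
segment_index <- function(geom, x) {
  widths <- vapply(geom$segments, `[[`, 0, "width")
  edges <- cumsum(widths)
  edges[length(edges)] <- Inf
  findInterval(x, c(0, edges[-length(edges)]))
}

#' Simulate a dispersive A0 Lamb wavefield
#'
#' Builds the ground-truth axial displacement
#' \deqn{u(x, t) = \sum_j A(f_j) \cos\!\big(\phi_j(x) - 2\pi f_j (t - t_c)\big),}
#' where \eqn{\phi_j(x) = \int_{x_p}^{x} k_j(x')\,dx'} accumulates the local
#' A0 wavenumber `k_j = 2*pi*f_j / c_A0(f_j)` from [solve_a0_phase_velocity()]
#' per segment, and `A(f)` is the Gaussian excitation amplitude spectrum
#' scaled so the field peaks at `peak_displacement`. The coherent transient
#' is centred at `t_c`, one push duration (at least 3 envelope sigma) after
#' the push onset `t_p` (the excitation start A-line), so the field is
#' continuous at the gate. The field is exactly zero before `t_p` and
#' for positions behind the push (single-sided propagation away from the
#' focus), uniform across the tissue depth band and zero outside it. All
#' spectral phases are zero at the push location, i.e. a coherent transient.
#' The output is deterministic; `seed` is accepted for interface symmetry
#' with [displacement_to_mbscan()] but no randomness is used here.
#'
#' @param geom A [phantom_geometry()].
#' @param exc An [excitation_spec()].
#' @param config An [acquisition_config()].
#' @param seed Unused (the field is deterministic); kept for a uniform
#'   simulator interface.
#' @param n_components Number of spectral components across
#'   `center_frequency +/- 3 sigma`.
#' @return An absolute-displacement [displacement_field()]
#'   (`differential = FALSE`, time dimension = `alines_per_position`) with
#'   attribute `geometry`.
#' @export
simulate_wavefield <- function(geom, exc, config, seed = 1L,
                               n_components = 96L) {
  stopifnot(inherits(geom, "phantom_geometry"),
            inherits(exc, "excitation_spec"),
            inherits(config, "acquisition_config"))
  L <- config$lateral_positions_n
  nt <- config$alines_per_position
  x <- (seq_len(L) - 1) * config$lateral_step
  t <- (seq_len(nt) - 1) / config$aline_rate
  tp <- (config$excitation_start_aline - 1) / config$aline_rate
  D <- geom$depth_pixels
  ut <- matrix(0, nt, L)
  if (exc$peak_displacement > 0) {
    sigma <- exc$bandwidth / (2 * sqrt(2 * log(2)))
    fgrid <- seq(max(exc$center_frequency - 3 * sigma, 0.05 * exc$center_frequency),
                 exc$center_frequency + 3 * sigma, length.out = n_components)
    A <- exp(-(fgrid - exc$center_frequency)^2 / (2 * sigma^2))
    # centre the coherent transient far enough after the gate that the field
    # is continuous at the push onset (Gaussian tail < ~1% of peak)
    sigma_t <- 1 / (2 * pi * sigma)
    tc <- tp + max(exc$push_duration, 3 * sigma_t)
    seg <- segment_index(geom, x)
    mats <- lapply(geom$segments, `[[`, "material")
    ahead <- x >= exc$push_position
    i0 <- which.min(abs(x - exc$push_position))
    dx <- config$lateral_step
    w <- 2 * pi * fgrid
    for (j in seq_along(fgrid)) {
      kseg <- vapply(mats, function(m) {
        pt <- tryCatch(solve_a0_phase_velocity(fgrid[j], m),
                       error = function(e)
                         stop(sprintf("A0 dispersion unsolvable at f = %g Hz: %s",
                                      fgrid[j], conditionMessage(e)), call. = FALSE))
        pt$wavenumber
      }, 0)
      kx <- kseg[seg]
      # spatial phase accumulated from the push position outward
      cum <- cumsum(kx * dx) - kx[1] * dx
      phase_x <- cum - cum[i0]
      # u[t, x] += A_j cos(phase_x(x) - w_j (t - tc))
      ut <- ut + A[j] * cos(outer(-w[j] * (t - tc), phase_x, `+`))
    }
    ut[t < tp, ] <- 0
    ut[, !ahead] <- 0
    peak <- max(abs(ut))
    if (peak > 0) ut <- ut * (exc$peak_displacement / peak)
  }
  u <- array(0, dim = c(D, nt, L))
  band <- geom$tissue_band[1]:geom$tissue_band[2]
  for (d in band) u[d, , ] <- ut
  out <- displacement_field(u, config, differential = FALSE)
  attr(out, "geometry") <- geom
  attr(out, "excitation") <- exc
  out
}

#' Encode a displacement field as a synthetic complex M-B scan
#'
#' Inverse of the Doppler processing chain: each (depth, lateral) pixel
#' receives a time-frozen speckle amplitude (log-normal around the
#' geometry's structural intensity) and a static random phase; the axial
#' displacement modulates the optical phase by `-4*pi*n*u/lambda0` (so that
#' [doppler_phase_shift()] followed by [phase_to_displacement()] recovers
#' the inter-A-line displacement increments with positive sign), and i.i.d.
#' Gaussian phase noise of standard deviation `phase_noise_sd` emulates the
#' interferometric phase stability of the instrument.
#'
#' @param field An absolute-displacement [displacement_field()] from
#'   [simulate_wavefield()].
#' @param geom The [phantom_geometry()] (for structural intensities).
#' @param config An [acquisition_config()].
#' @param phase_noise_sd Per-sample optical phase noise SD in rad
#'   (default 0.1673, a typical swept-source phase stability).
#' @param seed Integer seed; identical seeds give bit-identical scans.
#' @param speckle_sdlog Log-SD of the per-pixel log-normal speckle
#'   amplitude.
#' @return An [mb_scan()].
#' @export
displacement_to_mbscan <- function(field, geom, config,
                                   phase_noise_sd = 0.1673, seed = 1L,
                                   speckle_sdlog = 0.4) {
  stopifnot(inherits(field, "displacement_field"),
            inherits(geom, "phantom_geometry"),
            inherits(config, "acquisition_config"))
  if (field$differential)
    stop("'field' must carry absolute displacement (simulator ground truth)")
  d <- dim(field$displacement)
  D <- d[1]; nt <- d[2]; L <- d[3]
  dphi_max <- if (nt > 1L)
    max(abs(field$displacement[, -1L, , drop = FALSE] -
            field$displacement[, -nt, , drop = FALSE])) else 0
  lim <- config$center_wavelength / (8 * config$refractive_index)
  if (dphi_max >= lim)
    warning(sprintf(paste0("max inter-A-line displacement %.3g m reaches lambda0/(8n)",
                           " = %.3g m; Doppler phase may wrap"), dphi_max, lim))
  set.seed(as.integer(seed %% .Machine$integer.max))
  band <- geom$tissue_band[1]:geom$tissue_band[2]
  base_db <- matrix(geom$background_intensity_db, D, L)
  base_db[band, ] <- geom$tissue_intensity_db
  amp <- 10^(base_db / 20) * matrix(exp(stats::rnorm(D * L, 0, speckle_sdlog)), D, L)
  phi0 <- matrix(stats::runif(D * L, -pi, pi), D, L)
  scale <- -4 * pi * config$refractive_index / config$center_wavelength
  f <- array(0i, dim = c(D, nt, L))
  for (m in seq_len(nt)) {
    ph <- matrix(scale * field$displacement[, m, ], D, L) + phi0
    if (phase_noise_sd > 0)
      ph <- ph + matrix(stats::rnorm(D * L, 0, phase_noise_sd), D, L)
    f[, m, ] <- complex(modulus = amp, argument = ph)
  }
  mb_scan(f, config)
}

#' Simulate a labelled stiffness series of M-B scans
#'
#' One homogeneous phantom per stiffness level per repeat (`mu = E/3`), each
#' with a distinct child seed; labels carry the nominal level. Pressure
#' mechanics are not modelled: the stiffness at each nominal level is
#' imposed directly.
#'
#' @param E_levels Young's moduli in Pa, one per level.
#' @param exc An [excitation_spec()].
#' @param config An [acquisition_config()].
#' @param thickness Plate thickness, metres.
#' @param rho Density, kg/m^3.
#' @param repeats Repeats per level.
#' @param seed Parent seed; child seeds are derived deterministically and
#'   are all distinct.
#' @param labels Optional labels, one per level; default `"E=<kPa>kPa"`.
#' @param phase_noise_sd Phase noise SD passed to
#'   [displacement_to_mbscan()].
#' @param geom_args List of extra arguments for [homogeneous_phantom()]
#'   (e.g. `depth_pixels`, `tissue_band`).
#' @return List of [mb_scan()] objects with attributes `label`, `seed`,
#'   `E_true`, `repeat_index`.
#' @export
make_iop_series <- function(E_levels, exc, config, thickness = 496e-6,
                            rho = 1000, repeats = 1L, seed = 1L,
                            labels = NULL, phase_noise_sd = 0.1673,
                            geom_args = list()) {
  if (length(E_levels) == 0L) stop("'E_levels' must be non-empty")
  if (is.null(labels))
    labels <- sprintf("E=%gkPa", E_levels / 1e3)
  if (length(labels) != length(E_levels))
    stop("'labels' must match 'E_levels'")
  scans <- list()
  idx <- 0L
  for (i in seq_along(E_levels)) {
    geom <- do.call(homogeneous_phantom,
                    c(list(E = E_levels[i], thickness = thickness, rho = rho),
                      geom_args))
    truth <- simulate_wavefield(geom, exc, config)
    for (r in seq_len(repeats)) {
      idx <- idx + 1L
      child <- as.integer((seed + 104729 * i + 7919 * r) %% 2147483647)
      scan <- displacement_to_mbscan(truth, geom, config,
                                     phase_noise_sd = phase_noise_sd,
                                     seed = child)
      attr(scan, "label") <- if (repeats > 1L)
        sprintf("%s#%d", labels[i], r) else labels[i]
      attr(scan, "level_label") <- labels[i]
      attr(scan, "seed") <- child
      attr(scan, "E_true") <- E_levels[i]
      attr(scan, "repeat_index") <- r
      scans[[idx]] <- scan
    }
  }
  scans
}
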