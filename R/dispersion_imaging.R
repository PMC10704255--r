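#' 2D Fourier (k-space) transform of a spatio-temporal map
#'
#' Transforms a (time x lateral) displacement map to the
#' (frequency, wavenumber) domain: the elastic-wave mode appears as a ridge
#' whose slope-from-origin at each frequency is the phase velocity
#' `c = 2*pi*f / k`. A separable taper is applied before zero-padding; the
#' output is one-sided in frequency and signed in wavenumber, with the axis
#' oriented so that a wave propagating toward increasing lateral position
#' appears at positive wavenumber.
#'
#' @param map A [spatiotemporal_map()] (expected filtered; pass
#'   `accept_unfiltered = TRUE` to transform a raw map).
#' @param pad_t,pad_x Integer zero-padding factors along time and space.
#' @param window Taper: `"hann"` (default) or `"none"`.
#' @param accept_unfiltered Logical; allow an unfiltered map.
#' @return Object of class `kspace_map`: `magnitude` (freq bins x wavenumber
#'   bins), `frequency_axis` (Hz, ascending from 0), `wavenumber_axis`
#'   (rad/m, ascending, signed), `zero_pad_factors`, `nt`, `nx` (original
#'   sample counts) and `window`.
#' @export
kspace_transform <- function(map, pad_t = 4L, pad_x = 4L,
                             window = c("hann", "none"),
                             accept_unfiltered = FALSE) {
  stopifnot(inherits(map, "spatiotemporal_map"))
  window <- match.arg(window)
  if (!map$filtered && !accept_unfiltered)
    stop("map is unfiltered; high-pass it first or set accept_unfiltered = TRUE")
  v <- map$values
  nt <- nrow(v); nx <- ncol(v)
  if (nt < 8L || nx < 8L) stop("need at least 8 samples along each axis")
  if (window == "hann") {
    wt <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nt) - 1) / (nt - 1))
    wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nx) - 1) / (nx - 1))
    v <- v * (wt %o% wx)
  }
  NT <- nt * as.integer(pad_t); NX <- nx * as.integer(pad_x)
  padded <- matrix(0, NT, NX)
  padded[seq_len(nt), seq_len(nx)] <- v
  F2 <- stats::fft(padded)
  # one-sided temporal frequency
  nf <- NT %/% 2L + 1L
  freq <- (seq_len(nf) - 1L) * map$fs / NT
  # spatial frequency xi (cycles/m), standard DFT ordering, then relabel so
  # that +x-propagating energy (which lands at xi < 0 for f > 0 with the
  # e^{-i...} transform) maps to positive physical wavenumber k = -2*pi*xi.
  xi <- c(0:(NX %/% 2L), -((NX - NX %/% 2L - 1L):1L)) / (NX * map$dx)
  if (NX %% 2L == 0L) xi[NX %/% 2L + 1L] <- -xi[NX %/% 2L + 1L] # Nyquist col
  k_phys <- -2 * pi * xi
  ord <- order(k_phys)
  magnitude <- Mod(F2[seq_len(nf), ord, drop = FALSE])
  structure(
    list(magnitude = magnitude, frequency_axis = freq,
         wavenumber_axis = k_phys[ord],
         zero_pad_factors = c(time = as.integer(pad_t), space = as.integer(pad_x)),
         nt = nt, nx = nx, window = window),
    class = "kspace_map"
  )
}

# 3-point parabolic peak interpolation; returns fractional offset in (-0.5, 0.5)
parabolic_offset <- function(y_m1, y_0, y_p1) {
  denom <- y_m1 - 2 * y_0 + y_p1
  if (!is.finite(denom) || denom >= 0) return(0)  # not a strict local max
  off <- 0.5 * (y_m1 - y_p1) / denom
  max(-0.5, min(0.5, off))
}

#' Extract the phase-velocity dispersion curve from a k-space map
#'
#' For every frequency bin in `band` whose wavenumber-peak magnitude reaches
#' `min_peak_fraction` of the global in-band maximum, the wavenumber of
#' maximum magnitude `k*` is located (argmax with 3-point parabolic sub-bin
#' refinement; ties broken toward the smaller wavenumber, i.e. the faster
#' velocity) and the phase velocity computed as `c = 2*pi*f / k*`. Only the
#' wavenumber half-plane matching the propagation direction is searched.
#'
#' @param kspace A [kspace_transform()] result.
#' @param band Length-2 frequency band (Hz) to scan.
#' @param min_peak_fraction Per-frequency peak threshold as a fraction of
#'   the global in-band maximum; bins failing it are omitted.
#' @param direction `+1` (default) searches positive wavenumbers
#'   (propagation toward increasing lateral position), `-1` negative.
#' @param refine Logical; disable to obtain the plain per-frequency argmax.
#' @param min_prominence SNR gate: a frequency row is kept only if its peak
#'   exceeds `min_prominence` times the row's median magnitude. For white
#'   noise the maximum of a few hundred magnitude bins is about 3 times the
#'   median, so the default 4 rejects noise-dominated rows while a coherent
#'   wave ridge passes easily. Set to 0 to disable.
#' @param freq_smooth_hz Optional ridge smoothing: boxcar average of the
#'   magnitude over this frequency width before peak picking. The mode ridge
#'   is locally linear in frequency, so a symmetric average leaves the peak
#'   wavenumber unbiased to first order while suppressing noise. 0 (default)
#'   disables it; the windowed velocity mapper uses 100 Hz.
#' @return A [dispersion_curve()].
#' @export
extract_dispersion <- function(kspace, band = c(400, 4000),
                               min_peak_fraction = 0.1, direction = 1,
                               refine = TRUE, min_prominence = 4,
                               freq_smooth_hz = 0) {
  stopifnot(inherits(kspace, "kspace_map"))
  if (band[1] >= band[2] || band[1] < 0 || band[2] > max(kspace$frequency_axis))
    stop("'band' must lie within the frequency axis range")
  f_idx <- which(kspace$frequency_axis >= band[1] & kspace$frequency_axis <= band[2])
  k <- kspace$wavenumber_axis
  k_idx <- if (direction >= 0) which(k > 0) else which(k < 0)
  sub <- kspace$magnitude[f_idx, k_idx, drop = FALSE]
  if (freq_smooth_hz > 0) {
    df <- diff(kspace$frequency_axis[1:2])
    hw <- as.integer(round(freq_smooth_hz / 2 / df))
    if (hw > 0L) {
      # boxcar over +/- hw rows of the full map, evaluated on the band rows
      full <- kspace$magnitude[, k_idx, drop = FALSE]
      cs <- rbind(0, apply(full, 2L, cumsum))
      nfull <- nrow(full)
      lo <- pmax(f_idx - hw, 1L); hi <- pmin(f_idx + hw, nfull)
      sub <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
    }
  }
  # threshold against the global maximum of the searched half-plane
  gmax <- max(kspace$magnitude[, k_idx])
  if (gmax <= 0) stop("empty dispersion curve: no energy in the k-space map")
  freqs <- numeric(0); vels <- numeric(0)
  for (i in seq_along(f_idx)) {
    row <- sub[i, ]
    pk <- max(row)
    if (pk < min_peak_fraction * gmax) next
    if (min_prominence > 0 && pk < min_prominence * stats::median(row)) next
    j <- which(row == pk)
    # tie toward smaller |k| (faster velocity)
    j <- j[which.min(abs(k[k_idx][j]))]
    if (length(which(row == pk)) > 1L)
      warning("wavenumber peak tie; taking the smaller wavenumber")
    off <- 0
    if (refine && j > 1L && j < length(row))
      off <- parabolic_offset(row[j - 1L], row[j], row[j + 1L])
    dk <- mean(diff(k[k_idx]))
    kstar <- k[k_idx][j] + off * dk
    f <- kspace$frequency_axis[f_idx[i]]
    if (!is.finite(kstar) || abs(kstar) <= 0 || f <= 0) next
    freqs <- c(freqs, f)
    vels <- c(vels, 2 * pi * f / abs(kstar))
  }
  if (length(freqs) == 0L)
    stop("empty dispersion curve: no frequency bin passed the peak threshold")
  dispersion_curve(freqs, vels, source = "global")
}

#' Dominant temporal frequency of a spatio-temporal map
#'
#' Frequency of maximum temporal-spectrum magnitude, averaged over the
#' lateral columns of `lateral_window`, with 3-point parabolic refinement.
#' The DC bin is excluded.
#'
#' @param map A [spatiotemporal_map()].
#' @param lateral_window Length-2 integer `(first, last)` lateral column
#'   indices; default the full lateral extent.
#' @return Dominant frequency in Hz.
#' @export
dominant_frequency <- function(map, lateral_window = NULL) {
  stopifnot(inherits(map, "spatiotemporal_map"))
  if (is.null(lateral_window)) lateral_window <- c(1L, ncol(map$values))
  lateral_window <- as.integer(lateral_window)
  if (lateral_window[1] > lateral_window[2] || lateral_window[1] < 1L ||
      lateral_window[2] > ncol(map$values))
    stop("empty or out-of-range lateral window")
  v <- map$values[, lateral_window[1]:lateral_window[2], drop = FALSE]
  spec <- rowMeans(Mod(stats::mvfft(v)))
  nf <- length(spec) %/% 2L + 1L
  spec <- spec[2:nf]                       # exclude DC
  if (max(spec) <= 1e-10 * sum(abs(v)))
    stop("zero spectrum: no dominant frequency")
  j <- which.max(spec)
  off <- if (j > 1L && j < length(spec))
    parabolic_offset(spec[j - 1L], spec[j], spec[j + 1L]) else 0
  (j + off) * map$fs / nrow(map$values)
}

#' Local 2D phase-velocity map
#'
#' Sliding-window k-space velocity estimation: for each depth band and each
#' overlapping lateral window the spatio-temporal map is extracted, cropped
#' to the post-excitation samples, high-pass filtered, transformed to
#' k-space, and the phase velocity read from the dispersion curve at the
#' window's dominant frequency. Window estimates are assigned to the window
#' centre and linearly interpolated to every lateral position. A window
#' whose extraction fails contributes `NA` (with a warning), never an error.
#'
#' @param field A differential [displacement_field()] (Doppler-derived).
#' @param window_width Lateral window width in positions (>= 8).
#' @param window_step Window step in positions.
#' @param band Frequency band (Hz) passed to [extract_dispersion()].
#' @param depth_bands List of length-2 integer depth bands; each yields one
#'   row of the velocity map.
#' @param cutoff_hz High-pass cutoff, Hz.
#' @param pad_t,pad_x Zero-padding factors for the windowed transforms.
#' @param min_peak_fraction Peak threshold for [extract_dispersion()].
#' @param direction Propagation direction sign (see [extract_dispersion()]).
#' @param freq_smooth_hz Ridge smoothing width for the windowed extraction
#'   (see [extract_dispersion()]); default 100 Hz.
#' @param time_range Sample-index window used for wave tracking; default
#'   all samples after the excitation window.
#' @param onset_guard Truncation guard: a window is rejected (NA) when the
#'   signal energy in its first few analysed samples exceeds this fraction of
#'   the window's peak block energy -- i.e. when the transient was already
#'   under way at the start of the analysis window, which happens for
#'   positions close to the push where the leading half of the pulse falls
#'   inside the excitation A-lines. Set to `Inf` to disable.
#' @param mask Optional logical matrix (depth_bands x lateral).
#' @return Object of class `velocity_map`: `velocity` (depth_bands x
#'   lateral, m/s), `mask`, `dominant_frequency` (Hz per lateral position),
#'   `dominant_frequency_global` (median over windows), `window_centers`,
#'   `depth_bands`, `lateral_axis`.
#' @export
local_velocity_map <- function(field, window_width = 32L, window_step = 8L,
                               band = c(400, 4000), depth_bands,
                               cutoff_hz = 200, pad_t = 4L, pad_x = 4L,
                               min_peak_fraction = 0.1, direction = 1,
                               freq_smooth_hz = 100, time_range = NULL,
                               onset_guard = 0.5, mask = NULL) {
  stopifnot(inherits(field, "displacement_field"))
  if (window_width < 8L) stop("'window_width' must be at least 8 positions")
  if (!is.list(depth_bands)) depth_bands <- list(depth_bands)
  L <- dim(field$displacement)[3]
  if (window_width > L) stop("lateral window wider than the lateral extent")
  starts <- seq(1L, L - window_width + 1L, by = window_step)
  centers <- starts + (window_width - 1) / 2
  if (is.null(time_range)) {
    first <- min(field$config$excitation_end_aline + 1L, dim(field$displacement)[2])
    time_range <- c(first, dim(field$displacement)[2])
  }
  nb <- length(depth_bands)
  vel <- matrix(NA_real_, nb, L)
  fdom_mat <- matrix(NA_real_, nb, length(starts))
  for (b in seq_len(nb)) {
    stm_full <- spatiotemporal_map(field, depth_bands[[b]])
    stm_full <- crop_time(stm_full, time_range)
    v_win <- rep(NA_real_, length(starts))
    for (w in seq_along(starts)) {
      cols <- starts[w]:(starts[w] + window_width - 1L)
      res <- tryCatch({
        sub <- stm_full
        sub$values <- stm_full$values[, cols, drop = FALSE]
        sub$lateral_axis <- stm_full$lateral_axis[cols]
        sub <- highpass_filter(sub, cutoff_hz)
        if (is.finite(onset_guard)) {
          blk <- max(16L, nrow(sub$values) %/% 32L)
          nblk <- nrow(sub$values) %/% blk
          e_blk <- vapply(seq_len(nblk), function(b)
            mean(sub$values[((b - 1L) * blk + 1L):(b * blk), ]^2), 0)
          if (e_blk[1] > onset_guard * max(e_blk))
            stop("transient truncated at the start of the analysis window")
        }
        f_dom <- dominant_frequency(sub)
        ks <- kspace_transform(sub, pad_t, pad_x)
        curve <- extract_dispersion(ks, band, min_peak_fraction, direction,
                                    freq_smooth_hz = freq_smooth_hz)
        # never extrapolate the curve to a dominant frequency it does not cover
        if (f_dom < min(curve$frequency) || f_dom > max(curve$frequency))
          stop(sprintf("dominant frequency %.0f Hz outside the extracted band",
                       f_dom))
        c(stats::approx(curve$frequency, curve$phase_velocity,
                        xout = f_dom)$y, f_dom)
      }, error = function(e) {
        warning(sprintf("window %d (band %d): %s", w, b, conditionMessage(e)),
                call. = FALSE)
        c(NA_real_, NA_real_)
      })
      v_win[w] <- res[1]
      fdom_mat[b, w] <- res[2]
    }
    ok <- is.finite(v_win)
    if (any(ok))
      vel[b, ] <- stats::approx(centers[ok], v_win[ok], xout = seq_len(L),
                                rule = if (sum(ok) > 1L) 1 else 2)$y
  }
  fdom_win <- colMeans(fdom_mat, na.rm = TRUE)
  ok <- is.finite(fdom_win)
  fdom_pos <- if (any(ok))
    stats::approx(centers[ok], fdom_win[ok], xout = seq_len(L),
                  rule = if (sum(ok) > 1L) 1 else 2)$y
  else rep(NA_real_, L)
  if (is.null(mask)) mask <- matrix(TRUE, nb, L)
  vel[!mask] <- NA_real_
  structure(
    list(velocity = vel, mask = mask & is.finite(vel),
         dominant_frequency = fdom_pos,
         dominant_frequency_global = stats::median(fdom_mat, na.rm = TRUE),
         window_centers = centers, depth_bands = depth_bands,
         lateral_axis = field$lateral_axis),
    class = "velocity_map"
  )
}

#' Summarise velocity maps into a mean modulus result
#'
#' Per repeat, the mean phase velocity over the mask is computed; Young's
#' modulus follows from [youngs_modulus_from_velocity()] either from the
#' repeat-mean velocity at the recorded global dominant frequency
#' (`f_mode = "per_sample"`, default) or per masked position at its local
#' dominant frequency, then averaged (`f_mode = "per_position"`). Means and
#' sample standard deviations are taken across repeats.
#'
#' @param vmaps A single [local_velocity_map()] result or a list of repeats.
#' @param thickness Full plate thickness H in metres.
#' @param rho Density in kg/m^3.
#' @param f_mode `"per_sample"` or `"per_position"`.
#' @param label Text label (e.g. an IOP level or a direction).
#' @return Object of class `elasticity_result`: `label`, `thickness`,
#'   `mean_velocity`, `velocity_sd` (m/s), `mean_modulus`, `modulus_sd`
#'   (Pa), `n_repeats`.
#' @export
summarize_elasticity <- function(vmaps, thickness, rho = 1000,
                                 f_mode = c("per_sample", "per_position"),
                                 label = "") {
  f_mode <- match.arg(f_mode)
  if (inherits(vmaps, "velocity_map")) vmaps <- list(vmaps)
  if (length(vmaps) < 1L) stop("need at least one repeat")
  v_rep <- numeric(length(vmaps)); e_rep <- numeric(length(vmaps))
  for (r in seq_along(vmaps)) {
    vm <- vmaps[[r]]
    stopifnot(inherits(vm, "velocity_map"))
    sel <- vm$mask & is.finite(vm$velocity)
    if (!any(sel)) stop("empty mask in repeat ", r)
    v_rep[r] <- mean(vm$velocity[sel])
    if (f_mode == "per_sample") {
      e_rep[r] <- youngs_modulus_from_velocity(
        v_rep[r], vm$dominant_frequency_global, thickness, rho)
    } else {
      cols <- which(colSums(sel) > 0)
      e_pos <- vapply(cols, function(j) {
        vj <- mean(vm$velocity[sel[, j], j])
        youngs_modulus_from_velocity(vj, vm$dominant_frequency[j], thickness, rho)
      }, 0)
      e_rep[r] <- mean(e_pos)
    }
  }
  n <- length(vmaps)
  structure(
    list(label = label, thickness = thickness,
         mean_velocity = mean(v_rep),
         velocity_sd = if (n > 1L) stats::sd(v_rep) else 0,
         mean_modulus = mean(e_rep),
         modulus_sd = if (n > 1L) stats::sd(e_rep) else 0,
         n_repeats = n),
    class = "elasticity_result"
  )
}

#' Construct an elasticity result from precomputed summary values
#'
#' Used to feed already-tabulated means (e.g. published summary tables) into
#' sweep-level reporting such as [run_sweep()].
#'
#' @param label Text label.
#' @param thickness Plate thickness in metres.
#' @param mean_velocity,velocity_sd Velocity summary, m/s.
#' @param mean_modulus,modulus_sd Modulus summary, Pa.
#' @param n_repeats Number of repeats behind the summary.
#' @return An `elasticity_result`.
#' @export
elasticity_result <- function(label, thickness, mean_velocity, velocity_sd,
                              mean_modulus, modulus_sd, n_repeats = 1L) {
  if (velocity_sd < 0 || modulus_sd < 0) stop("SDs must be non-negative")
  if (n_repeats < 1L) stop("'n_repeats' must be >= 1")
  structure(
    list(label = as.character(label), thickness = thickness,
         mean_velocity = mean_velocity, velocity_sd = velocity_sd,
         mean_modulus = mean_modulus, modulus_sd = modulus_sd,
         n_repeats = as.integer(n_repeats)),
    class = "elasticity_result"
  )
}

#' @export
print.elasticity_result <- function(x, ...) {
  cat(sprintf("%s: v = %.2f +/- %.2f m/s, E = %.2f +/- %.2f kPa (n = %d)\n",
              if (nzchar(x$label)) x$label else "elasticity_result",
              x$mean_velocity, x$velocity_sd,
              x$mean_modulus / 1e3, x$modulus_sd / 1e3, x$n_repeats))
  invisible(x)
}

#' Percent increase between two values
#'
#' `100 * (high - low) / low`, reported to two decimals.
#'
#' @param low Reference value (> 0).
#' @param high Comparison value.
#' @return Percent increase, rounded to two decimals.
#' @examples
#' percent_increase(7.97, 10.56)   # 32.50
#' percent_increase(191.66, 439.76) # 129.44
#' @export
percent_increase <- function(low, high) {
  if (!is.numeric(low) || any(low <= 0)) stop("'low' must be positive")
  round(100 * (high - low) / low, 2)
}

#' Ordinary least-squares quadratic trend fit
#'
#' Fits `y = a*x^2 + b*x + c` and reports the coefficients and the
#' goodness-of-fit `R^2 = 1 - SSE/SST`.
#'
#' @param x,y Numeric vectors, at least 4 points, `y` non-constant.
#' @return List with `coefficients` (named `a`, `b`, `c`), `r_squared`, and
#'   `fitted` values.
#' @export
quadratic_trend_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4L)
    stop("need at least 4 (x, y) points")
  if (stats::var(y) == 0) stop("'y' has zero variance")
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  list(coefficients = c(a = unname(cf[3]), b = unname(cf[2]), c = unname(cf[1])),
       r_squared = summary(fit)$r.squared,
       fitted = unname(stats::fitted(fit)))
}
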