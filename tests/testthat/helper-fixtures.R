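# Shared fixtures and independent oracles for the test suite.
# Test grids are deliberately small: the simulated wavefield is uniform over
# the tissue depth band, so a thin depth stack measures exactly the same
# velocities as the full-size cube. The axial pixel pitch is always chosen so
# that (band pixels) * pitch equals the physical plate thickness.

soft_tissue_rho <- 1000

# acquisition with a reduced depth stack; lateral sampling at the package
# default (50 um), full 1000-A-line M-mode timing
test_config <- function(lateral_n = 256L, alines = 1000L, band_px = 10L,
                        thickness = 496e-6, lateral_step = 50e-6) {
  acquisition_config(lateral_positions_n = lateral_n,
                     alines_per_position = alines,
                     lateral_step = lateral_step,
                     axial_pixel_pitch = thickness / band_px)
}

test_phantom <- function(E, thickness = 496e-6, band_px = 10L) {
  homogeneous_phantom(E, thickness = thickness, depth_pixels = band_px + 2L,
                      tissue_band = c(2L, band_px + 1L))
}

# simulate + encode in one step
test_scan <- function(E = 200e3, noise_sd = 0, seed = 1L, cfg = test_config(),
                      exc = excitation_spec(), band_px = 10L,
                      thickness = 496e-6) {
  geom <- test_phantom(E, thickness, band_px)
  truth <- simulate_wavefield(geom, exc, cfg)
  displacement_to_mbscan(truth, geom, cfg, phase_noise_sd = noise_sd,
                         seed = seed)
}

# --- independent oracles ------------------------------------------------

# A0 characteristic equation in its raw (cosh/sinh) form, solved by plain
# bisection: independent of the package's tanh-form residual and of uniroot
oracle_a0_root <- function(f, mu, rho, H, tol = 1e-6) {
  h <- H / 2
  VS <- sqrt(mu / rho)
  g <- function(cc) {
    w <- 2 * pi * f
    kL <- w / cc
    kS <- w / VS
    b <- sqrt(as.complex(kL^2 - kS^2))
    Re(4 * kL^3 * b * cosh(kL * h) * sinh(b * h) -
       (kS^2 - 2 * kL^2)^2 * sinh(kL * h) * cosh(b * h) -
       kS^4 * cosh(kL * h) * cosh(b * h))
  }
  lo <- 0.01 * VS; hi <- 0.99 * VS
  flo <- g(lo)
  stopifnot(sign(flo) != sign(g(hi)))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(g(mid)) == sign(flo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# brute-force per-frequency argmax dispersion read-out (no refinement)
oracle_kspace_argmax <- function(ks, band, min_peak_fraction = 0.1) {
  rows <- which(ks$frequency_axis >= band[1] & ks$frequency_axis <= band[2])
  cols <- which(ks$wavenumber_axis > 0)
  sub <- ks$magnitude[rows, cols, drop = FALSE]
  gmax <- max(sub)
  out <- NULL
  for (i in seq_along(rows)) {
    pk <- max(sub[i, ])
    if (pk < min_peak_fraction * gmax) next
    k <- ks$wavenumber_axis[cols][which.max(sub[i, ])]
    out <- rbind(out, c(ks$frequency_axis[rows[i]], 2 * pi * ks$frequency_axis[rows[i]] / k))
  }
  out
}

# build a spatio-temporal map directly from a (time x lateral) matrix
map_from_matrix <- function(u, fs = 50e3, dx = 50e-6, filtered = TRUE) {
  cfg <- acquisition_config(alines_per_position = nrow(u) + 1L,
                            lateral_positions_n = ncol(u),
                            lateral_step = dx, aline_rate = fs,
                            excitation_start_aline = 1L,
                            excitation_end_aline = 2L)
  fld <- displacement_field(array(u, dim = c(1L, nrow(u), ncol(u))), cfg)
  m <- spatiotemporal_map(fld, c(1L, 1L), reduce = "single_depth")
  m$filtered <- filtered
  m
}

# analytic travelling plane wave u(t, x) = cos(2 pi f t - k x)
plane_wave_map <- function(f0, c0, nt = 500L, L = 256L, fs = 50e3,
                           dx = 50e-6) {
  k0 <- 2 * pi * f0 / c0
  t <- (seq_len(nt) - 1) / fs
  x <- (seq_len(L) - 1) * dx
  map_from_matrix(outer(t, x, function(tt, xx) cos(2 * pi * f0 * tt - k0 * xx)),
                  fs = fs, dx = dx)
}

# minimal hand-built velocity map (for summary arithmetic tests)
uniform_velocity_map <- function(v, f_dom = 2000, L = 32L) {
  structure(
    list(velocity = matrix(v, 1L, L), mask = matrix(TRUE, 1L, L),
         dominant_frequency = rep(f_dom, L),
         dominant_frequency_global = f_dom,
         window_centers = seq_len(L), depth_bands = list(c(1L, 1L)),
         lateral_axis = (seq_len(L) - 1) * 50e-6),
    class = "velocity_map"
  )
}
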