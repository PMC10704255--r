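#' Elastic plate material for Lamb-wave modelling
#'
#' Bundles the mechanical description of a thin, soft, fluid-immersed plate
#' (the optic-nerve-head model): shear modulus, density, full thickness and
#' the derived half thickness used by the dispersion relation.
#'
#' The dispersion relation ([a0_dispersion_residual()]) works with the half
#' thickness `h = H/2`, whereas the low-frequency closed form
#' ([lamb_velocity_low_freq()]) and the modulus inversion
#' ([youngs_modulus_from_velocity()]) are written in terms of the full
#' thickness `H` as tabulated for tissue. Both are carried explicitly so
#' neither convention is silently reused for the other.
#'
#' @param shear_modulus Shear elasticity mu in Pa. For incompressible soft
#'   tissue `E = 3 * mu`.
#' @param density Mass density rho in kg/m^3. Default 1000 (soft-tissue
#'   convention).
#' @param thickness Full plate thickness H in metres.
#' @param shear_viscosity Shear viscosity eta in Pa s. Stored for
#'   completeness; the elastic solver requires it to be 0 (viscoelastic
#'   dispersion fitting is out of scope).
#' @param immersed Logical; `TRUE` for a fluid-loaded plate (the only case
#'   the solver supports), `FALSE` marks a vacuum-bounded plate.
#' @return An object of class `plate_material` with fields `mu`, `eta`,
#'   `rho`, `H`, `h` (`= H/2`), `immersed`.
#' @examples
#' m <- plate_material(shear_modulus = 64e3, thickness = 496e-6)
#' shear_velocity_from_modulus(3 * m$mu, m$rho) # 8 m/s
#' @export
plate_material <- function(shear_modulus, density = 1000, thickness,
                           shear_viscosity = 0, immersed = TRUE) {
  if (!is.numeric(shear_modulus) || length(shear_modulus) != 1L || shear_modulus <= 0)
    stop("'shear_modulus' must be a single positive number (Pa)")
  if (!is.numeric(density) || density <= 0)
    stop("'density' must be positive (kg/m^3)")
  if (!is.numeric(thickness) || thickness <= 0)
    stop("'thickness' must be positive (m)")
  if (shear_viscosity < 0) stop("'shear_viscosity' must be >= 0")
  structure(
    list(mu = shear_modulus, eta = shear_viscosity, rho = density,
         H = thickness, h = thickness / 2, immersed = isTRUE(immersed)),
    class = "plate_material"
  )
}

#' @export
print.plate_material <- function(x, ...) {
  cat(sprintf(
    "plate_material: mu = %.4g kPa (E = %.4g kPa), rho = %g kg/m^3, H = %g um%s\n",
    x$mu / 1e3, 3 * x$mu / 1e3, x$rho, x$H * 1e6,
    if (x$immersed) ", fluid-immersed" else ", in vacuum"))
  invisible(x)
}

#' Characteristic residual of the A0 leaky-Lamb dispersion relation
#'
#' Evaluates the zero-order antisymmetric (A0) characteristic equation for an
#' incompressible elastic plate immersed in an incompressible fluid of equal
#' density,
#' \deqn{4 k_L^3 \beta \cosh(k_L h)\sinh(\beta h)
#'   - (k_S^2 - 2 k_L^2)^2 \sinh(k_L h)\cosh(\beta h)
#'   = k_S^4 \cosh(k_L h)\cosh(\beta h),}
#' with \eqn{k_L = 2\pi f / c}, \eqn{k_S = 2\pi f / V_S},
#' \eqn{V_S = \sqrt{\mu/\rho}}, \eqn{\beta = \sqrt{k_L^2 - k_S^2}}
#' (principal branch) and `h` the half thickness. The returned value is the
#' real part of LHS minus RHS after dividing both sides by
#' \eqn{\cosh(k_L h)\cosh(\beta h)} (the cosh terms never vanish for real
#' arguments, so the roots are unchanged and the evaluation stays
#' overflow-safe at large `f * h`). Complex intermediates occur for
#' `c > V_S` where `beta` is imaginary; the residual is reported as its real
#' part and its imaginary part is zero on the A0 branch `0 < c < V_S`.
#'
#' In the thin-plate limit the root of this equation approaches the
#' fluid-corrected low-frequency closed form
#' `fluid_correction(lamb_velocity_low_freq(f, H, V_S))`.
#'
#' @param c Trial phase velocity in m/s (vectorised).
#' @param f Temporal frequency in Hz (scalar).
#' @param material A [plate_material()]; must be immersed and elastic
#'   (`eta == 0`).
#' @return Dimensionless residual(s), zero at a dispersion root.
#' @seealso [solve_a0_phase_velocity()]
#' @export
a0_dispersion_residual <- function(c, f, material) {
  stopifnot(inherits(material, "plate_material"))
  if (any(!is.finite(c)) || any(c <= 0)) stop("phase velocity 'c' must be positive")
  if (!is.numeric(f) || length(f) != 1L || f <= 0) stop("frequency 'f' must be positive")
  if (material$mu <= 0) stop("shear modulus must be positive")
  if (!material$immersed)
    stop("dispersion relation implemented for the fluid-immersed plate only")
  if (material$eta != 0)
    stop("elastic solver requires shear_viscosity == 0")
  w  <- 2 * pi * f
  VS <- sqrt(material$mu / material$rho)
  h  <- material$h
  kL <- w / c
  kS <- w / VS
  beta <- sqrt(as.complex(kL^2 - kS^2))
  # divided through by cosh(kL h) cosh(beta h)
  t1 <- 4 * kL^3 * beta * tanh(beta * h)
  t2 <- (kS^2 - 2 * kL^2)^2 * tanh(kL * h)
  t3 <- kS^4 + 0i
  scale <- pmax(Mod(t1), Mod(t2), Mod(t3))
  Re(t1 - t2 - t3) / scale
}

#' Solve the A0 dispersion relation for phase velocity
#'
#' Finds the zero-order antisymmetric Lamb-mode phase velocity at frequency
#' `f` by bracketed root finding ([stats::uniroot()], Brent) on
#' [a0_dispersion_residual()]. The default bracket `(0.01, 0.99) * V_S`
#' contains the single A0 root in the frequency regime of interest; the A0
#' phase velocity of this model is bounded above by the shear speed `V_S`.
#'
#' @param f Frequency in Hz (scalar, > 0).
#' @param material A [plate_material()].
#' @param bracket Length-2 numeric search interval in m/s. Default
#'   `c(0.01, 0.99) * V_S`.
#' @param tol Absolute solver tolerance on the velocity in m/s.
#' @return A `dispersion_point`: list with `frequency` (Hz),
#'   `phase_velocity` (m/s) and `wavenumber` (`2*pi*f/c`, rad/m).
#' @examples
#' m <- plate_material(64e3, thickness = 496e-6)
#' solve_a0_phase_velocity(2000, m)$phase_velocity # about 3.79 m/s
#' @export
solve_a0_phase_velocity <- function(f, material, bracket = NULL, tol = 1e-4) {
  stopifnot(inherits(material, "plate_material"))
  if (!is.numeric(f) || length(f) != 1L || f <= 0) stop("frequency 'f' must be positive")
  VS <- sqrt(material$mu / material$rho)
  if (is.null(bracket)) bracket <- c(0.01, 0.99) * VS
  if (length(bracket) != 2L || bracket[1] <= 0 || bracket[2] <= bracket[1])
    stop("'bracket' must be an increasing positive interval")
  g <- function(cc) a0_dispersion_residual(cc, f, material)
  lo <- g(bracket[1]); hi <- g(bracket[2])
  if (!is.finite(lo) || !is.finite(hi) || sign(lo) == sign(hi))
    stop(sprintf("no A0 root in bracket (%g, %g) m/s at f = %g Hz",
                 bracket[1], bracket[2], f))
  root <- stats::uniroot(g, interval = bracket, tol = tol)$root
  structure(list(frequency = f, phase_velocity = root,
                 wavenumber = 2 * pi * f / root),
            class = "dispersion_point")
}

#' Model A0 dispersion curve over a frequency grid
#'
#' Convenience wrapper around [solve_a0_phase_velocity()].
#'
#' @param frequencies Increasing vector of frequencies in Hz.
#' @inheritParams solve_a0_phase_velocity
#' @return A `dispersion_curve` data frame with columns `frequency`,
#'   `phase_velocity`, `wavenumber`.
#' @export
a0_dispersion_curve <- function(frequencies, material, bracket = NULL, tol = 1e-4) {
  pts <- lapply(frequencies, solve_a0_phase_velocity,
                material = material, bracket = bracket, tol = tol)
  dispersion_curve(
    frequency = vapply(pts, `[[`, 0, "frequency"),
    phase_velocity = vapply(pts, `[[`, 0, "phase_velocity"),
    source = "model"
  )
}

#' Construct a dispersion curve object
#'
#' @param frequency Strictly increasing frequencies in Hz.
#' @param phase_velocity Positive phase velocities in m/s.
#' @param source Provenance label, e.g. `"model"`, `"global"` or
#'   `"window at lateral index k"`.
#' @return Data frame of class `dispersion_curve` with columns `frequency`,
#'   `phase_velocity` and `wavenumber = 2*pi*frequency/phase_velocity`.
#' @export
dispersion_curve <- function(frequency, phase_velocity, source = "global") {
  if (length(frequency) == 0L) stop("empty dispersion curve")
  if (any(diff(frequency) <= 0)) stop("frequencies must be strictly increasing")
  if (any(phase_velocity <= 0)) stop("phase velocities must be positive")
  structure(
    data.frame(frequency = frequency, phase_velocity = phase_velocity,
               wavenumber = 2 * pi * frequency / phase_velocity),
    source = source, class = c("dispersion_curve", "data.frame")
  )
}

#' Low-frequency Lamb-wave phase velocity of a thin plate in vacuum
#'
#' Closed form for the flexural (A0) phase velocity of a thin plate in the
#' low-frequency limit, \eqn{V_{L,vac} = \sqrt{2\pi f H V_S / \sqrt 3}},
#' with `H` the full plate thickness.
#'
#' @param f Frequency in Hz.
#' @param H Full plate thickness in metres.
#' @param V_S Shear wave speed in m/s.
#' @return Phase velocity in m/s (vectorised over any argument).
#' @export
lamb_velocity_low_freq <- function(f, H, V_S) {
  if (any(f <= 0) || any(H <= 0) || any(V_S < 0))
    stop("'f' and 'H' must be positive, 'V_S' non-negative")
  sqrt(2 * pi * f * H * V_S / sqrt(3))
}

#' Fluid-loading correction for the Lamb-wave velocity
#'
#' A plate immersed in fluid on both faces carries added fluid mass, slowing
#' the flexural wave relative to the vacuum plate. For a fluid of density
#' equal to the plate density the low-frequency speed is reduced by exactly
#' \eqn{1/\sqrt 2}; this factor is also the unique one that makes
#' [lamb_velocity_low_freq()] consistent with
#' [youngs_modulus_from_velocity()] (round trip returns the input modulus).
#'
#' @param v_vacuum Vacuum-plate phase velocity in m/s (>= 0).
#' @return `v_vacuum / sqrt(2)`.
#' @export
fluid_correction <- function(v_vacuum) {
  if (any(v_vacuum < 0)) stop("'v_vacuum' must be non-negative")
  v_vacuum / sqrt(2)
}

#' Young's modulus from the measured Lamb-wave velocity
#'
#' Inverts the fluid-corrected thin-plate dispersion,
#' \deqn{E = \frac{9 \rho V_L^4}{(\pi f H)^2},}
#' where `V_L` is the fluid-loaded A0 phase velocity at frequency `f` and
#' `H` the full plate thickness. Exact inverse of the composition
#' `fluid_correction(lamb_velocity_low_freq(f, H, shear_velocity_from_modulus(E, rho)))`.
#'
#' @param V_L Measured phase velocity in m/s (>= 0; vectorised).
#' @param f Frequency at which `V_L` was read, Hz.
#' @param H Full plate thickness in metres.
#' @param rho Density in kg/m^3.
#' @return Young's modulus in Pa.
#' @export
youngs_modulus_from_velocity <- function(V_L, f, H, rho) {
  if (any(V_L < 0)) stop("'V_L' must be non-negative")
  if (any(f <= 0) || any(H <= 0) || any(rho <= 0))
    stop("'f', 'H' and 'rho' must be positive")
  9 * rho * V_L^4 / (pi * f * H)^2
}

#' Shear wave speed from Young's modulus
#'
#' For incompressible soft tissue `E = 3 rho V_S^2`, hence
#' `V_S = sqrt(E / (3 rho))`.
#'
#' @param E Young's modulus in Pa (>= 0).
#' @param rho Density in kg/m^3 (> 0).
#' @return Shear wave speed in m/s.
#' @export
shear_velocity_from_modulus <- function(E, rho) {
  if (any(E < 0)) stop("'E' must be non-negative")
  if (any(rho <= 0)) stop("'rho' must be positive")
  sqrt(E / (3 * rho))
}

#' Write / read a dispersion curve as CSV
#'
#' Plain-text interchange format with header
#' `frequency_hz,phase_velocity_m_per_s,wavenumber_rad_per_m`.
#'
#' @param curve A [dispersion_curve()].
#' @param path Output file path.
#' @return `path`, invisibly (writer); a `dispersion_curve` (reader).
#' @export
write_dispersion_csv <- function(curve, path) {
  stopifnot(inherits(curve, "dispersion_curve"))
  df <- data.frame(
    frequency_hz = curve$frequency,
    phase_velocity_m_per_s = curve$phase_velocity,
    wavenumber_rad_per_m = curve$wavenumber
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dispersion_csv
#' @export
read_dispersion_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frequency_hz", "phase_velocity_m_per_s")
  if (!all(need %in% names(df)))
    stop("not a dispersion-curve CSV: missing ", paste(setdiff(need, names(df)), collapse = ", "))
  dispersion_curve(df$frequency_hz, df$phase_velocity_m_per_s, source = "file")
}
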