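# The reference plate throughout: E = 192 kPa (mu = 64 kPa), rho = 1000,
# H = 496 um, giving V_S = 8 m/s exactly.
ref_mat <- plate_material(64e3, 1000, 496e-6)

test_that("plate material validates its invariants", {
  expect_equal(ref_mat$h, ref_mat$H / 2)
  expect_error(plate_material(-1, 1000, 496e-6), "positive")
  expect_error(plate_material(64e3, 0, 496e-6), "positive")
  expect_error(plate_material(64e3, 1000, 496e-6, shear_viscosity = -1), ">= 0")
})

test_that("dispersion residual vanishes at the independently bisected root", {
  for (f in c(800, 2000, 3500)) {
    root <- oracle_a0_root(f, 64e3, 1000, 496e-6)
    expect_lt(abs(a0_dispersion_residual(root, f, ref_mat)), 1e-6)
  }
})

test_that("residual brackets a sign change on (0, V_S) in the working regime", {
  for (f in c(500, 1000, 2000, 5000)) {
    lo <- a0_dispersion_residual(0.01 * 8, f, ref_mat)
    hi <- a0_dispersion_residual(0.99 * 8, f, ref_mat)
    expect_true(sign(lo) != sign(hi))
  }
})

test_that("residual sign pattern depends on the f*h product (thin-plate scaling)", {
  a <- 2
  mat_half <- plate_material(64e3, 1000, 496e-6 / a)
  cs <- seq(0.5, 7.5, length.out = 40)
  s1 <- sign(a0_dispersion_residual(cs, 1500, ref_mat))
  s2 <- sign(a0_dispersion_residual(cs, 1500 * a, mat_half))
  expect_identical(s1, s2)
})

test_that("residual and solver reject invalid domains", {
  expect_error(a0_dispersion_residual(-1, 2000, ref_mat), "positive")
  expect_error(a0_dispersion_residual(3, -2, ref_mat), "positive")
  visc <- plate_material(64e3, 1000, 496e-6, shear_viscosity = 1)
  expect_error(a0_dispersion_residual(3, 2000, visc), "viscosity")
  vac <- plate_material(64e3, 1000, 496e-6, immersed = FALSE)
  expect_error(a0_dispersion_residual(3, 2000, vac), "immersed")
  expect_error(solve_a0_phase_velocity(2000, ref_mat, bracket = c(7.9, 7.95)),
               "no A0 root in bracket")
})

test_that("A0 root matches the bisection oracle and the frozen fixture", {
  pt <- solve_a0_phase_velocity(2000, ref_mat)
  expect_equal(pt$phase_velocity, oracle_a0_root(2000, 64e3, 1000, 496e-6),
               tolerance = 1e-4)
  expect_equal(pt$phase_velocity, 3.786585, tolerance = 1e-4) # frozen oracle value
  expect_equal(pt$wavenumber, 2 * pi * 2000 / pt$phase_velocity)
  # within 15% of the corrected low-frequency closed form (3.794 m/s)
  closed <- fluid_correction(lamb_velocity_low_freq(2000, 496e-6, 8))
  expect_lt(abs(pt$phase_velocity - closed) / pt$phase_velocity, 0.15)
})

test_that("A0 phase velocity increases with frequency and stays below V_S", {
  cs <- vapply(c(1000, 2000, 4000, 20000),
               function(f) solve_a0_phase_velocity(f, ref_mat)$phase_velocity, 0)
  expect_true(all(diff(cs) > 0))
  expect_lt(cs[4], 8) # surface-wave plateau below the shear speed
})

test_that("solver agrees with the corrected closed form to 15% at low f*H", {
  for (f in seq(500, 2000, by = 250)) {
    sol <- solve_a0_phase_velocity(f, ref_mat)$phase_velocity
    closed <- fluid_correction(lamb_velocity_low_freq(f, 496e-6, 8))
    expect_lt(abs(sol - closed) / sol, 0.15)
  }
})

test_that("closed forms give the hand-computed reference values", {
  expect_equal(lamb_velocity_low_freq(8000, 496e-6, 8),
               sqrt(2 * pi * 8000 * 496e-6 * 8 / sqrt(3)))
  expect_equal(lamb_velocity_low_freq(8000, 496e-6, 8), 10.7313, tolerance = 1e-4)
  expect_equal(fluid_correction(10.7313), 7.5882, tolerance = 1e-4)
  # quadrupling f*H doubles the speed; V_S -> 0 collapses it
  expect_equal(lamb_velocity_low_freq(4 * 8000, 496e-6, 8),
               2 * lamb_velocity_low_freq(8000, 496e-6, 8))
  expect_equal(lamb_velocity_low_freq(8000, 496e-6, 0), 0)
  expect_error(lamb_velocity_low_freq(-1, 496e-6, 8))
  expect_error(fluid_correction(-0.1))
})

test_that("modulus inversion reproduces direct arithmetic", {
  expect_equal(youngs_modulus_from_velocity(7.588, 8000, 496e-6, 1000),
               9 * 1000 * 7.588^4 / (pi * 8000 * 496e-6)^2)
  expect_equal(youngs_modulus_from_velocity(7.588, 8000, 496e-6, 1000) / 1e3,
               192.0, tolerance = 2e-3)
  expect_equal(youngs_modulus_from_velocity(7.97, 8000, 496e-6, 1000) / 1e3,
               233.7, tolerance = 1e-3)
  expect_equal(youngs_modulus_from_velocity(0, 8000, 496e-6, 1000), 0)
  expect_error(youngs_modulus_from_velocity(1, 0, 496e-6, 1000))
})

test_that("shear speed and modulus are exact inverses", {
  expect_equal(shear_velocity_from_modulus(192e3, 1000), 8)
  expect_equal(shear_velocity_from_modulus(0, 1000), 0)
  expect_error(shear_velocity_from_modulus(-1, 1000))
  for (E in c(10e3, 97e3, 1000e3))
    expect_equal(3 * 1000 * shear_velocity_from_modulus(E, 1000)^2, E,
                 tolerance = 1e-12)
})

test_that("equation chain round-trips any modulus to 1e-9 relative", {
  set.seed(7)
  for (i in 1:25) {
    E <- stats::runif(1, 10e3, 1000e3)
    f <- stats::runif(1, 1000, 10000)
    H <- stats::runif(1, 300e-6, 700e-6)
    rho <- stats::runif(1, 900, 1100)
    VL <- fluid_correction(lamb_velocity_low_freq(f, H, shear_velocity_from_modulus(E, rho)))
    expect_equal(youngs_modulus_from_velocity(VL, f, H, rho), E,
                 tolerance = 1e-9)
  }
})

test_that("closed forms are bit-reproducible", {
  expect_identical(lamb_velocity_low_freq(1234.5, 496e-6, 8),
                   lamb_velocity_low_freq(1234.5, 496e-6, 8))
  expect_identical(solve_a0_phase_velocity(2000, ref_mat)$phase_velocity,
                   solve_a0_phase_velocity(2000, ref_mat)$phase_velocity)
})

test_that("dispersion curves round-trip through the CSV dialect", {
  curve <- a0_dispersion_curve(c(1000, 2000, 3000), ref_mat)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dispersion_csv(curve, path)
  hdr <- readLines(path, n = 1)
  expect_match(hdr, "frequency_hz")
  expect_match(hdr, "phase_velocity_m_per_s")
  expect_match(hdr, "wavenumber_rad_per_m")
  back <- read_dispersion_csv(path)
  expect_equal(back$phase_velocity, curve$phase_velocity, tolerance = 1e-12)
  expect_equal(back$wavenumber, curve$wavenumber, tolerance = 1e-12)
})
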