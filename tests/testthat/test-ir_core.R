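test_that("trajectory container enforces its invariants", {
  expect_error(dipole_trajectory(matrix(1, 3, 3), 2.5), "at least 4")
  expect_error(dipole_trajectory(matrix(1, 5, 2), 2.5), "3 columns")
  expect_error(dipole_trajectory(matrix(c(1, NA, rep(1, 13)), 5, 3), 2.5),
               "finite")
  expect_error(dipole_trajectory(matrix(1, 5, 3), -1), "positive")
  tr <- dipole_trajectory(matrix(0, 5, 3), 2.5, molecule_id = "x")
  expect_s3_class(tr, "dipole_trajectory")
  expect_output(print(tr), "5 samples")
})

test_that("sample count for a closed time span matches floor(1000 T/dt) + 1", {
  expect_identical(n_samples_for_span(100, 2.5), 40001L)
  expect_identical(n_samples_for_span(1, 1), 1001L)
  expect_identical(n_samples_for_span(0.0025, 2.5), 2L)
})

test_that("mean removal annihilates a constant dipole", {
  tr <- dipole_trajectory(cbind(1, 0, 0)[rep(1, 50), ], dt_fs = 1)
  acf <- compute_autocorrelation(tr, 10)
  expect_identical(acf$values, rep(0, 11))
})

test_that("pure-cosine ACF matches the 0.5 cos(w l dt) closed form", {
  nu0 <- 1000
  tr <- harmonic_dipole_series(list(harmonic_mode(nu0, 1)), 2.5, 20001)
  acf <- compute_autocorrelation(tr, 50)
  expected <- 0.5 * cos(2 * pi * C_CM_FS * nu0 * (0:50) * 2.5)
  expect_lt(max(abs(acf$values - expected)), 0.01 * 0.5) # within 1%
  expect_gte(acf$values[1], 0)
})

test_that("FFT autocorrelation equals the direct-sum oracle", {
  for (seed in 1:5) {
    tr <- random_traj(1000, seed)
    got <- compute_autocorrelation(tr, 200)$values
    want <- acf_direct(tr$dipoles, 200)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-10)
  }
  # detrend = "none" variant too
  tr <- random_traj(500, 99)
  got <- compute_autocorrelation(tr, 100, detrend = "none")$values
  want <- acf_direct(tr$dipoles, 100, subtract_mean = FALSE)
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-10)
})

test_that("autocorrelation rejects impossible lags and bad data", {
  tr <- random_traj(50, 1)
  expect_error(compute_autocorrelation(tr, 50), "max_lag")
  expect_silent(compute_autocorrelation(tr, 49))
})

test_that("Blackman window matches its defining cosine sum", {
  w <- blackman_window(4)
  expect_equal(w[1], 0, tolerance = 1e-12)
  expect_equal(w[2], 0.63, tolerance = 1e-12)
  # center of an odd window is exactly 0.42 + 0.5 + 0.08
  w9 <- blackman_window(9)
  expect_equal(w9[5], 1.0, tolerance = 1e-12)
  # symmetric, bounded, small at the ends
  for (N in c(2, 5, 16, 101)) {
    w <- blackman_window(N)
    expect_equal(w, rev(w))
    expect_true(all(w >= -1e-12 & w <= 1.0001))
    expect_lte(w[1], 0.01)
    expect_lte(w[N], 0.01)
  }
  expect_error(blackman_window(1), ">= 2")
})

test_that("quantum correction factor has the right value, limits, monotonicity", {
  expect_equal(quantum_correction_factor(0, 300), 1.0)
  # x/(1 - e^-x) at nu = 1000 cm^-1, T = 300 K
  expect_equal(quantum_correction_factor(1000, 300), 4.8356, tolerance = 1e-3)
  # large-nu asymptote: Q/x -> 1
  x_big <- 1.4387769 * 50000 / 300
  expect_equal(quantum_correction_factor(50000, 300) / x_big, 1,
               tolerance = 1e-12)
  nu <- seq(0, 6000, by = 10)
  q <- quantum_correction_factor(nu, 300)
  expect_true(all(q >= 1))
  expect_true(all(diff(q) >= 0))
  expect_error(quantum_correction_factor(-5, 300), ">= 0")
})

test_that("frequency axis has the published spacing and Nyquist range", {
  ax <- frequency_axis(40001, 2.5)
  expect_equal(round(ax[2] - ax[1], 4), 0.3336)
  expect_gte(nyquist_wavenumber(2.5), 6600)
  ax2 <- frequency_axis(2, 3.7)
  expect_equal(ax2, c(0, nyquist_wavenumber(3.7)))
})

test_that("zero dipole gives an all-zero spectrum, not an error", {
  tr <- dipole_trajectory(matrix(0, 100, 3), 2.5)
  sp <- ir_spectrum(tr)
  expect_true(all(sp$intensities == 0))
  expect_error(ir_spectrum(dipole_trajectory(matrix(0, 6, 3), 2.5)),
               "at least 8")
})

test_that("single-mode signals are recovered within one bin", {
  for (nu0 in c(500, 1000, 1500, 3000)) {
    tr <- harmonic_dipole_series(list(harmonic_mode(nu0, 1)), 2.5, 40001)
    sp <- ir_spectrum(tr)
    expect_lte(abs(peak_position(sp) - nu0), sp$resolution_cm1)
  }
})

test_that("default truncation keeps exactly 12,000 points at 0.3336 cm^-1", {
  tr <- harmonic_dipole_series(list(harmonic_mode(1500, 1)), 2.5, 40001)
  sp <- ir_spectrum(tr)
  expect_length(sp$intensities, 12000)
  expect_length(sp$wavenumbers_cm1, 12000)
  expect_equal(round(sp$resolution_cm1, 4), 0.3336)
  expect_equal(sp$wavenumbers_cm1[1], 0)
  expect_equal(diff(sp$wavenumbers_cm1),
               rep(sp$resolution_cm1, 11999), tolerance = 1e-12)
})

test_that("spectrum is linear: both peaks present, intensities scale as s^2", {
  cfg <- spectrum_config(correction = "none", normalize = FALSE)
  two <- harmonic_dipole_series(
    list(harmonic_mode(1000, 1), harmonic_mode(3000, 0.5)), 2.5, 40001)
  sp <- ir_spectrum(two, cfg)
  h1 <- max(sp$intensities[sp$wavenumbers_cm1 > 900 & sp$wavenumbers_cm1 < 1100])
  h2 <- max(sp$intensities[sp$wavenumbers_cm1 > 2900 & sp$wavenumbers_cm1 < 3100])
  expect_equal(h2 / h1, 0.25, tolerance = 0.05 * 0.25 / 0.25) # A^2 ratio, 5%
  one <- harmonic_dipole_series(list(harmonic_mode(1000, 1)), 2.5, 4001)
  one_scaled <- dipole_trajectory(3 * one$dipoles, one$dt_fs)
  r <- max(ir_spectrum(one_scaled, cfg)$intensities) /
    max(ir_spectrum(one, cfg)$intensities)
  expect_equal(r, 9, tolerance = 1e-8)
})

test_that("harmonic correction multiplies intensities by Q pointwise", {
  tr <- harmonic_dipole_series(list(harmonic_mode(1200, 1)), 2.5, 4001)
  raw <- ir_spectrum(tr, spectrum_config(correction = "none", normalize = FALSE))
  cor <- ir_spectrum(tr, spectrum_config(correction = "harmonic",
                                         normalize = FALSE))
  q <- quantum_correction_factor(raw$wavenumbers_cm1, 300)
  expect_equal(cor$intensities, raw$intensities * q, tolerance = 1e-12)
  expect_true(all(q >= 1) && all(diff(q) >= 0))
})

test_that("half-window applied to the ACF is 1 at lag 0 and ~0 at the end", {
  L <- 500L
  bw <- blackman_window(2L * L - 1L)
  half <- bw[L:(2L * L - 1L)]
  expect_equal(half[1], 1.0, tolerance = 1e-12)
  expect_lte(half[L], 0.01)
  expect_true(all(diff(half) <= 1e-12)) # decaying
})

test_that("windowing residual negatives stay at the Blackman sidelobe floor", {
  tr <- harmonic_dipole_series(list(harmonic_mode(1500, 1)), 2.5, 40001)
  sp <- ir_spectrum(tr, spectrum_config(correction = "none", normalize = FALSE))
  expect_gte(min(sp$intensities), -1e-3 * max(sp$intensities))
  expect_lt(min(sp$intensities), 0) # negatives are retained, not clipped
})

test_that("dipole text files round-trip in both dialects", {
  tr <- random_traj(20, 7, dt_fs = 2.5)
  f4 <- tempfile(); f3 <- tempfile()
  write.table(data.frame(t = (0:19) * 2.5, tr$dipoles), f4,
              row.names = FALSE, col.names = FALSE)
  write.table(tr$dipoles, f3, row.names = FALSE, col.names = FALSE)
  r4 <- read_dipole_trajectory(f4)
  r3 <- read_dipole_trajectory(f3, dt_fs = 2.5)
  expect_equal(r4$dt_fs, 2.5)
  expect_equal(unname(r4$dipoles), unname(tr$dipoles), tolerance = 1e-12)
  expect_equal(unname(r3$dipoles), unname(tr$dipoles), tolerance = 1e-12)
  expect_error(read_dipole_trajectory(f3), "dt_fs is required")
})

test_that("binary dipole arrays round-trip row-major (M, 3) doubles", {
  tr <- random_traj(16, 8, dt_fs = 2.5)
  fb <- tempfile()
  writeBin(as.vector(t(tr$dipoles)), fb, size = 8, endian = "little")
  back <- read_dipole_trajectory_bin(fb, dt_fs = 2.5)
  expect_equal(unname(back$dipoles), unname(tr$dipoles), tolerance = 1e-15)
  writeBin(1.0, fb)
  expect_error(read_dipole_trajectory_bin(fb, 2.5), "3-vector")
})
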