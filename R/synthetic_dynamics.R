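#' Harmonic mode specification
#'
#' One cosine component of a synthetic dipole signal.
#'
#' @param wavenumber_cm1 Mode wavenumber (> 0, below the Nyquist limit of the
#'   requested sampling).
#' @param amplitude_D Amplitude in Debye (> 0).
#' @param phase_rad Phase offset in radians.
#' @return A `harmonic_mode` list.
#' @export
harmonic_mode <- function(wavenumber_cm1, amplitude_D = 1, phase_rad = 0) {
  if (wavenumber_cm1 <= 0) stop_invalid("wavenumber_cm1 must be > 0")
  if (amplitude_D <= 0) stop_invalid("amplitude_D must be > 0")
  structure(list(wavenumber_cm1 = wavenumber_cm1, amplitude_D = amplitude_D,
                 phase_rad = phase_rad), class = "harmonic_mode")
}

#' Synthetic dipole trajectory from superposed harmonic modes
#'
#' Generates `mu_x(t) = sum_k A_k cos(2 pi c nu_k t + phi_k)` plus optional
#' i.i.d. Gaussian noise; the y and z components are zero. The resulting
#' spectrum has known peak positions and squared-amplitude intensity ratios,
#' making every downstream stage testable against construction.
#'
#' @param modes List of [harmonic_mode()] objects (may be empty).
#' @param dt_fs Sampling interval in femtoseconds.
#' @param n_samples Number of samples.
#' @param noise_sigma_D Standard deviation of added Gaussian noise (Debye).
#' @param seed RNG seed for the noise (default 0).
#' @param molecule_id Label for the trajectory.
#' @return A [dipole_trajectory()].
#' @examples
#' tr <- harmonic_dipole_series(list(harmonic_mode(1000, 1)), 2.5, 1001)
#' @export
harmonic_dipole_series <- function(modes, dt_fs, n_samples,
                                   noise_sigma_D = 0, seed = 0,
                                   molecule_id = "synthetic-harmonic") {
  nyq <- nyquist_wavenumber(dt_fs)
  t_fs <- (seq_len(n_samples) - 1) * dt_fs
  mu <- numeric(n_samples)
  for (i in seq_along(modes)) {
    m <- modes[[i]]
    if (!inherits(m, "harmonic_mode")) stop_invalid("modes must be harmonic_mode objects")
    if (m$wavenumber_cm1 >= nyq)
      stop_invalid("mode ", i, " at ", m$wavenumber_cm1,
                   " cm^-1 is aliased: Nyquist limit at dt = ", dt_fs,
                   " fs is ", round(nyq, 1), " cm^-1")
    mu <- mu + m$amplitude_D *
      cos(2 * pi * .c_cm_fs * m$wavenumber_cm1 * t_fs + m$phase_rad)
  }
  if (noise_sigma_D > 0)
    mu <- mu + with_seed(seed, stats::rnorm(n_samples, sd = noise_sigma_D))
  dipole_trajectory(cbind(mu, 0, 0), dt_fs = dt_fs, molecule_id = molecule_id)
}

#' Morse oscillator specification
#'
#' A 1-D Morse oscillator parameterized by its spectroscopic constants: the
#' harmonic wavenumber `omega_e`, the anharmonicity `omega_e x_e` and the
#' reduced mass. The well depth is `D_e = omega_e^2 / (4 omega_e x_e)` and the
#' quantum term values are `G(v) = omega_e (v + 1/2) - omega_e x_e (v + 1/2)^2`,
#' so the fundamental sits at `omega_e - 2 omega_e x_e` and the first overtone
#' at `2 omega_e - 6 omega_e x_e`, i.e. below twice the fundamental.
#'
#' The classical oscillation frequency at energy `E` is
#' `omega_e * sqrt(1 - E/D_e)`. The default `energy_frac` places the
#' trajectory at the semiclassical energy of the v = 1 level (the upper state
#' of the fundamental), where the classical frequency coincides with the
#' quantum 1<-0 transition wavenumber to first order.
#'
#' @param we_cm1 Harmonic wavenumber omega_e in cm^-1.
#' @param wexe_cm1 Anharmonicity omega_e x_e in cm^-1 (> 0, < omega_e / 10).
#' @param mass_amu Reduced mass in amu (default 1).
#' @param energy_frac Initial energy as a fraction of the well depth, in
#'   (0, 0.8). Default: the v = 1 term value divided by D_e.
#' @param dipole_linear Linear dipole coefficient (Debye per Angstrom).
#' @param dipole_quadratic Quadratic dipole coefficient (Debye per Angstrom^2);
#'   a nonzero value makes even harmonics of the motion IR-visible.
#' @return A `morse_spec` list (also carries derived `De_cm1`).
#' @export
morse_spec <- function(we_cm1, wexe_cm1, mass_amu = 1,
                       energy_frac = NULL,
                       dipole_linear = 1, dipole_quadratic = 0) {
  if (we_cm1 <= 0 || wexe_cm1 <= 0) stop_invalid("we_cm1 and wexe_cm1 must be > 0")
  if (wexe_cm1 >= we_cm1 / 10)
    stop_invalid("wexe_cm1 must be below we_cm1/10")
  if (mass_amu <= 0) stop_invalid("mass_amu must be > 0")
  De <- we_cm1^2 / (4 * wexe_cm1)
  if (is.null(energy_frac))
    energy_frac <- (1.5 * we_cm1 - 2.25 * wexe_cm1) / De
  if (energy_frac <= 0 || energy_frac >= 0.8)
    stop_invalid("energy_frac must be in (0, 0.8)")
  structure(list(we_cm1 = we_cm1, wexe_cm1 = wexe_cm1, mass_amu = mass_amu,
                 energy_frac = energy_frac, dipole_linear = dipole_linear,
                 dipole_quadratic = dipole_quadratic, De_cm1 = De),
            class = "morse_spec")
}

#' Default stable time step for Morse integration
#'
#' 1/512 of the harmonic period, small enough that velocity-Verlet energy
#' error stays below 1e-4 relative.
#'
#' @param spec A [morse_spec()].
#' @return Time step in femtoseconds.
#' @export
morse_default_dt <- function(spec) {
  1 / (512 * .c_cm_fs * spec$we_cm1)
}

#' Dipole trajectory of a Morse oscillator
#'
#' Integrates 1-D Morse dynamics `V(x) = D_e (1 - exp(-a x))^2` with
#' velocity-Verlet, starting at the minimum with kinetic energy
#' `energy_frac * D_e`, and maps position to dipole through
#' `mu(x) = dipole_linear * x + dipole_quadratic * x^2` (x in Angstrom).
#' The anharmonic waveform carries overtones of the orbital frequency, so the
#' resulting spectrum exhibits the overtone structure a harmonic signal lacks.
#'
#' @param spec A [morse_spec()].
#' @param dt_fs Sampling/integration time step in femtoseconds. Must satisfy
#'   `dt <= 1/(50 c omega_e)` for stable integration; the error message
#'   suggests [morse_default_dt()]. Default: `morse_default_dt(spec)`.
#' @param n_samples Number of samples to record.
#' @return A [dipole_trajectory()] with attribute `energy_drift` (maximum
#'   relative deviation of total energy over the run) and attribute
#'   `classical_frequency_cm1` (the analytic orbital frequency
#'   `omega_e * sqrt(1 - energy_frac)`).
#' @examples
#' sp <- morse_spec(3000, 50)
#' tr <- morse_dipole_series(sp, n_samples = 2000)
#' attr(tr, "energy_drift") < 1e-4
#' @export
morse_dipole_series <- function(spec, dt_fs = morse_default_dt(spec),
                                n_samples = 100000L) {
  stopifnot(inherits(spec, "morse_spec"))
  dt_max <- 1 / (50 * .c_cm_fs * spec$we_cm1)
  if (dt_fs > dt_max)
    stop_invalid("dt_fs = ", signif(dt_fs, 4), " fs is too large for stable ",
                 "integration at omega_e = ", spec$we_cm1, " cm^-1; use dt <= ",
                 signif(dt_max, 4), " fs (morse_default_dt suggests ",
                 signif(morse_default_dt(spec), 4), " fs)")
  mu_kg <- spec$mass_amu * .amu_kg
  De_J <- .h_J_s * .c_cm_s * spec$De_cm1
  a_m <- 2 * pi * .c_cm_s * spec$we_cm1 * sqrt(mu_kg / (2 * De_J)) # 1/m
  dt_s <- dt_fs * 1e-15
  E0 <- spec$energy_frac * De_J
  x <- numeric(n_samples) # metres
  v <- numeric(n_samples)
  x[1] <- 0
  v[1] <- sqrt(2 * E0 / mu_kg)
  force <- function(xx) {
    e <- exp(-a_m * xx)
    -2 * De_J * a_m * e * (1 - e)
  }
  f <- force(x[1])
  for (i in seq_len(n_samples - 1L)) {
    xn <- x[i] + v[i] * dt_s + 0.5 * (f / mu_kg) * dt_s^2
    fn <- force(xn)
    v[i + 1L] <- v[i] + 0.5 * (f + fn) / mu_kg * dt_s
    x[i + 1L] <- xn
    f <- fn
  }
  E <- 0.5 * mu_kg * v^2 + De_J * (1 - exp(-a_m * x))^2
  drift <- max(abs(E - E0)) / E0
  x_A <- x * 1e10
  mu <- spec$dipole_linear * x_A + spec$dipole_quadratic * x_A^2
  out <- dipole_trajectory(cbind(mu, 0, 0), dt_fs = dt_fs,
                           molecule_id = "synthetic-morse")
  attr(out, "energy_drift") <- drift
  attr(out, "classical_frequency_cm1") <-
    spec$we_cm1 * sqrt(1 - spec$energy_frac)
  out
}

#' Synthetic shielding specification
#'
#' True per-group chemical shifts and frame-to-frame variability for
#' generating multi-frame shielding sets with analytically known structure.
#' Shifts are converted to isotropic shieldings through the TMS reference, so
#' parsing + referencing + aggregation recovers the configured means.
#'
#' @param h_means_ppm True shift per hydrogen group (ppm).
#' @param c_means_ppm True shift per carbon group (ppm).
#' @param h_sigma_ppm Frame-to-frame standard deviation per H group (scalar
#'   recycled); the perturbation is shared within a group.
#' @param c_sigma_ppm Same for carbon groups.
#' @param n_frames Number of frames (>= 1).
#' @param seed RNG seed (default 0).
#' @param atom_jitter_ppm Optional atom-level i.i.d. jitter (default 0, so the
#'   two-level averaging contract is exactly checkable).
#' @param reference TMS reference used for the shift -> shielding conversion
#'   (default [tms_reference()] with H 31.0, C 188.0).
#' @return A `synthetic_shielding_spec` list.
#' @export
synthetic_shielding_spec <- function(h_means_ppm, c_means_ppm,
                                     h_sigma_ppm = 0, c_sigma_ppm = 0,
                                     n_frames = 10L, seed = 0,
                                     atom_jitter_ppm = 0,
                                     reference = tms_reference()) {
  if (n_frames < 1) stop_invalid("n_frames must be >= 1")
  if (any(h_sigma_ppm < 0) || any(c_sigma_ppm < 0) || atom_jitter_ppm < 0)
    stop_invalid("sigmas must be >= 0")
  structure(list(h_means_ppm = h_means_ppm, c_means_ppm = c_means_ppm,
                 h_sigma_ppm = h_sigma_ppm, c_sigma_ppm = c_sigma_ppm,
                 n_frames = as.integer(n_frames), seed = seed,
                 atom_jitter_ppm = atom_jitter_ppm, reference = reference),
            class = "synthetic_shielding_spec")
}

#' Generate synthetic shielding frames with known group structure
#'
#' Per frame, each atom's chemical shift is its group's true mean plus a
#' frame-level Gaussian perturbation shared within the group, plus optional
#' atom-level jitter; shifts are then converted to shieldings via the TMS
#' reference. Reproducible under the spec's seed.
#'
#' @param spec A [synthetic_shielding_spec()]; the group means must cover
#'   every group of `grouping`.
#' @param grouping An [atom_grouping()] (e.g. from [group_equivalent_atoms()]).
#' @return List of `shielding_frame` objects (length `spec$n_frames`).
#' @export
synthetic_shielding_frames <- function(spec, grouping) {
  stopifnot(inherits(spec, "synthetic_shielding_spec"),
            inherits(grouping, "atom_grouping"))
  nh <- length(grouping$h_groups)
  nc <- length(grouping$c_groups)
  if (length(spec$h_means_ppm) != nh)
    stop_invalid("h_means_ppm has ", length(spec$h_means_ppm),
                 " entries but the grouping has ", nh, " hydrogen groups")
  if (length(spec$c_means_ppm) != nc)
    stop_invalid("c_means_ppm has ", length(spec$c_means_ppm),
                 " entries but the grouping has ", nc, " carbon groups")
  hs <- rep_len(spec$h_sigma_ppm, nh)
  cs <- rep_len(spec$c_sigma_ppm, nc)
  natoms <- grouping$natoms
  elements <- grouping$elements
  ref <- spec$reference
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_frames), function(fi) {
      shifts <- rep(NA_real_, natoms)
      for (g in seq_len(nh)) {
        idx <- grouping$h_groups[[g]]
        shifts[idx] <- spec$h_means_ppm[g] + stats::rnorm(1, sd = hs[g]) +
          if (spec$atom_jitter_ppm > 0)
            stats::rnorm(length(idx), sd = spec$atom_jitter_ppm) else 0
      }
      for (g in seq_len(nc)) {
        idx <- grouping$c_groups[[g]]
        shifts[idx] <- spec$c_means_ppm[g] + stats::rnorm(1, sd = cs[g]) +
          if (spec$atom_jitter_ppm > 0)
            stats::rnorm(length(idx), sd = spec$atom_jitter_ppm) else 0
      }
      sigma <- rep(NA_real_, natoms)
      isH <- elements == "H"
      isC <- elements == "C"
      sigma[isH] <- ref$sigma_h_ppm - shifts[isH]
      sigma[isC] <- ref$sigma_c_ppm - shifts[isC]
      sigma[!(isH | isC)] <- 0
      shielding_frame(frame_id = as.character(fi - 1L), elements = elements,
                      sigma_iso_ppm = sigma, tms = ref)
    })
  })
}

# pool of small valid structures used for synthetic dataset records
.synthetic_smiles_pool <- c(
  "C", "CC", "CCO", "CC(C)O", "c1ccccc1", "Cc1ccccc1", "CC(=O)O",
  "c1ccncc1", "CCN", "CCOC", "CC(C)=O", "ClCCl", "Cc1ccc(C)cc1", "OCC(O)CO"
)

#' Generate schema-valid synthetic IR dataset records
#'
#' Produces `n` rows following the published IR table schema (id, smiles,
#' type, frequency axis, spectrum) with distinct ids, SMILES drawn from a
#' small pool of valid organic structures, element-type lists consistent with
#' the SMILES (explicit hydrogens appended after heavy atoms), and short
#' synthetic spectra. Deterministic under `seed`. Intended to exercise the
#' chunked writer and validators at full dataset scale without any download.
#'
#' @param n Number of records (>= 1).
#' @param seed RNG seed (default 0).
#' @param n_points Spectrum length per record (default 8; kept short so
#'   177,461 records fit comfortably in memory).
#' @return A tibble with columns `id`, `smiles`, `type`, `frequency_cm1`,
#'   `ir_spectra` (the last three are list columns), one row per record.
#' @export
make_synthetic_ir_records <- function(n, seed = 0, n_points = 8L) {
  if (n < 1) stop_invalid("n must be >= 1")
  n <- as.integer(n)
  pool <- .synthetic_smiles_pool
  pool_types <- lapply(pool, smiles_type_vector)
  axis <- frequency_axis(40000L, 2.5)[seq_len(n_points)]
  with_seed(seed, {
    pick <- sample.int(length(pool), n, replace = TRUE)
    intens <- matrix(stats::runif(n * n_points), nrow = n)
    intens <- intens / apply(intens, 1L, max)
    tibble::tibble(
      id = sprintf("mol_%07d", seq_len(n)),
      smiles = pool[pick],
      type = pool_types[pick],
      frequency_cm1 = rep(list(axis), n),
      ir_spectra = lapply(seq_len(n), function(i) intens[i, ])
    )
  })
}
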