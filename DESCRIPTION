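Package: mdspectra
Title: Anharmonic IR Spectra from Dipole Dynamics and Ensemble NMR Shift
    Post-Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for generating and post-processing computational molecular
    spectra. Computes anharmonic infrared spectra from dipole-moment time
    series via the dipole-dipole autocorrelation function, half-Blackman
    windowing, a cosine Fourier transform and a harmonic quantum correction
    factor. Post-processes per-frame isotropic NMR shieldings into
    TMS-referenced, symmetry-averaged chemical shifts with two-level
    (frame and equivalence-group) statistics. Includes synthetic dipole and
    shielding generators with analytically known structure (harmonic modes,
    Morse oscillators), tolerance-broadened spectral similarity scores,
    Morgan-fingerprint/Tanimoto chemical-space selection with Murcko scaffold
    split diagnostics, and chunked Parquet dataset schemas with validators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    arrow,
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    graphics,
    tibble
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
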