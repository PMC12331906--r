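---
title: "Methods: anharmonic IR from dipole dynamics and ensemble NMR post-processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anharmonic IR from dipole dynamics and ensemble NMR post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the models behind `mdspectra`, the choices made where
the methodology is genuinely open, and what the package's synthetic fixtures
do and do not demonstrate about real data.

## 1. IR spectra from dipole autocorrelation

### Model and assumptions

The IR absorption lineshape of a molecule is proportional to the Fourier
transform of its dipole–dipole autocorrelation function (ACF). Given a
classical dipole trajectory $\mu(t)$ sampled every $\Delta t$ over $M$
steps, the pipeline is:

1. subtract the time-mean dipole vector (`detrend = "subtract_mean"`);
2. estimate the ACF to lag depth $L = \lfloor M/2 \rfloor$ with the
   unbiased-per-lag estimator
   $C(\ell) = \frac{1}{M-\ell}\sum_t (\mu_t-\bar\mu)\cdot(\mu_{t+\ell}-\bar\mu)$,
   summed over the three Cartesian components;
3. multiply the ACF by the decaying half of a symmetric Blackman window of
   length $2L-1$ (weight exactly 1 at lag 0, 0 at lag $L-1$);
4. Fourier-transform the even extension of the windowed ACF (length
   $N_\mathrm{ext} = 2L$; equivalently a cosine transform), keeping the real
   part;
5. multiply by the harmonic quantum correction factor
   $Q(\nu) = x/(1-e^{-x})$, $x = \frac{hc}{k_B}\frac{\nu}{T}$,
   with $hc/k_B = 1.4387769\ \mathrm{cm\,K}$;
6. truncate to the first `max_points` axis points and optionally rescale to
   unit maximum.

The method's defining property is that anharmonic features — overtones,
combination bands, mode coupling — enter through the time-domain signal
itself, with no normal-mode (Hessian) analysis and hence no harmonic
truncation of the potential.

Assumptions: the trajectory is long compared to the slowest vibrational
period, equally spaced, and classical; the quantum correction repairs the
classical lineshape only at the harmonic level; absolute absorption units
are not reconstructed (intensities are arbitrary units, so `normalize`
defaults to `TRUE`).

### Parameters

| parameter | default | units | why |
|---|---|---|---|
| `dt_fs` | 2.5 | fs | production sampling cadence; Nyquist 6671 cm⁻¹ covers all IR-active fundamentals in vacuum (≤ ~3700 cm⁻¹) with margin |
| span | 100 ps → 40,001 samples | — | gives axis spacing 1/(2L·dt·c) = 0.3336 cm⁻¹ at the default lag depth |
| `max_points` | 12,000 | bins | retains ≈0–4000 cm⁻¹, the physically relevant range, at ~30% of the storage |
| `temperature_K` | 300 | K | the simulation temperature entering $Q(\nu)$ |
| `correction` | `"harmonic"` | — | `"none"` exposes the raw classical lineshape |

### Numerical choices

- **ACF estimator.** Unbiased-per-lag ($1/(M-\ell)$) with mean subtraction:
  long lags are not artificially damped and a constant dipole gives an
  exactly zero ACF. Evaluation is FFT-based (zero-padded to $\ge 2M$) and is
  tested to agree with the direct double-loop sum to $10^{-10}$ relative.
- **"Half-window" interpretation.** The taper applied to the ACF over lags
  $0..L-1$ is the decaying half of a Blackman window of length $2L-1$: the
  ACF is untouched at lag 0 and smoothly driven to zero at the last lag.
  This is the standard edge-effect suppression for truncated correlation
  functions; applying a full window (which would also attenuate lag 0) is
  the main alternative reading and is deliberately not used.
- **Axis convention.** Spacing is $1/(N_\mathrm{ext}\,\Delta t\,c)$ with
  $N_\mathrm{ext} = 2L$ the even-extension length. At 40,001 samples this
  gives 0.33356 cm⁻¹ per bin and an endpoint of 4002.4 cm⁻¹ for 12,000
  points. Published datasets of this kind quote slightly different endpoints
  depending on unstated FFT padding; the package documents its own
  convention rather than guessing another one.
- **Quantum correction variant.** Several correction factors exist
  (harmonic, standard, Schofield, ...). The harmonic factor is used because
  it is the one recommended for molecular IR from classical dynamics; it is
  isolated behind `quantum_correction_factor()` and can be switched off
  (`correction = "none"`), so other variants can be applied externally.
- **Negative intensities.** Windowing leaves small negative sidelobes
  (the Blackman sidelobe floor is ≈ −58 dB, i.e. ~10⁻³ of the peak in
  amplitude). They are retained, never clipped — silent clipping would hide
  numerical bugs. Tests assert they stay at that floor for synthetic
  signals.
- **Degenerate inputs.** An all-zero dipole trajectory returns an all-zero
  spectrum (not an error); fewer than 8 samples, non-finite components and
  aliased synthetic modes are errors.

## 2. Synthetic dynamics fixtures

`harmonic_dipole_series()` superposes cosines with known wavenumbers,
amplitudes and phases (plus optional white Gaussian noise), so peak
positions and squared-amplitude intensity ratios are known by construction.

`morse_dipole_series()` integrates the 1-D Morse potential
$V(x) = D_e(1 - e^{-ax})^2$ with velocity-Verlet, parameterized directly by
the spectroscopic constants $(\omega_e, \omega_e x_e, \mu)$ because the
checks use term values: $D_e = \omega_e^2/(4\omega_e x_e)$,
$\nu(1\!\leftarrow\!0) = \omega_e - 2\omega_e x_e$,
$\nu(2\!\leftarrow\!0) = 2\omega_e - 6\omega_e x_e$.

Two subtleties are worth recording:

- **Energy choice.** A single classical orbit at energy $E$ oscillates at
  $\nu_{cl}(E) = \omega_e\sqrt{1-E/D_e}$ and its spectrum carries harmonics
  at *exact integer multiples* of $\nu_{cl}$ — the classical trajectory
  cannot reproduce both quantum transition energies at once. The default
  `energy_frac` places the trajectory at the semiclassical $v=1$ term value
  ($E = 1.5\,\omega_e - 2.25\,\omega_e x_e$); for the reference fixture
  ($\omega_e = 3000$, $\omega_e x_e = 50$ cm⁻¹) this gives
  $\nu_{cl} = 2850$ cm⁻¹, within 2% of $\nu(1\!\leftarrow\!0) = 2900$, and
  an overtone at $2\nu_{cl} = 5700 = \nu(2\!\leftarrow\!0)$, visibly below
  twice the fundamental transition (5800). Tests therefore compare peak
  positions against the quantum term values, not against twice the measured
  fundamental (which is $2\nu_{cl}$ exactly, up to one bin).
- **Harmonic limit.** As `energy_frac` $f \to 0$ the fundamental converges
  to $\omega_e$ with deviation $f/2 + f^2/8 + \dots$; the convergence test
  uses the closed-form bound $0.6 f \omega_e$, which holds for all
  $f < 0.8$. (A linearized "$f/2$" bound would sit exactly on the measured
  value at any finite $f$.)
- **Integration step.** The default step is 1/512 of the harmonic period;
  velocity-Verlet then keeps the total-energy error below $10^{-4}$
  relative over the longest runs used (tested at 40,001 and 400,001 steps).
  Steps larger than 1/50 of the period are rejected with a suggestion.

`synthetic_shielding_frames()` draws per-frame group perturbations shared
within each symmetry group (plus optional atom-level jitter, default 0 so
the two-level contract is exactly checkable), then converts shifts to
shieldings through the TMS reference so the full parse → reference →
aggregate path is exercised. Noise is i.i.d. Gaussian per frame; no
colored noise, no conformational jumps.

**What the fixtures do not show.** Real MD dipoles have broadband spectral
content, rotational wings and mode-coupling cross terms; real shielding
ensembles have correlated, non-Gaussian frame-to-frame variation and
conformation-dependent symmetry breaking. Passing tests demonstrate the
*transform and statistics* are correct, not that any force field or DFT
setup is accurate.

## 3. NMR post-processing

Chemical shifts are $\delta = \sigma_\mathrm{TMS} - \sigma$ per nucleus
(H and C; other elements carry `NA`). Averaging is hierarchical: group
values within each frame (mean over symmetry-equivalent atoms), then means
across frames; this is the `"frames_last"` default, and a pooled
single-pass alternative is available for sensitivity checks (the two agree
exactly when group sizes and frame counts are balanced, and tests cover
both regimes).

- **Equivalence perception** is graph-based: iterative neighborhood
  refinement from invariants (element, aromaticity, formal charge, degree,
  hydrogen count) with bond labels, i.e. automorphism-orbit classes for
  chemically relevant graphs. Hydrogens are grouped by their attachment
  atom's class, which implements "same heavy atom, or symmetry-related
  ones" — methyl rotors, equivalent methyls (isopropyl: one 6-proton
  group), ring positions. Working on the aromatic (non-kekulized) graph is
  essential: alternating Kekulé bond orders would split the ortho/meta
  pairs of substituted benzenes. Known divergences, accepted by design:
  conformation-broken symmetry is ignored (equivalence is decided on the
  graph, not on 3-D geometry), and diastereotopic protons on one carbon
  are grouped together.
- **Std convention** is the population standard deviation (denominator
  $n$) of per-frame group values: the frames are treated as the full
  sampled ensemble, and a single frame cleanly yields 0. The $n-1$
  convention would make single-frame records undefined.
- **Shielding text dialect.** The parser/writer pair defines a minimal
  documented format (`# frame <id>`, one `index element [x y z] sigma`
  line per atom, optional `TMS H <v> C <v>` footer) rather than imitating
  any quantum-chemistry code's log layout; real logs are adapted by a
  user-supplied converter. Round-tripping is tested.
- **Record schema.** Nested records carry 0-based group indices and
  per-atom "unsorted" shift lists in the package atom order: heavy atoms
  in canonical SMILES order, then hydrogens grouped by parent atom. The
  order is a documented convention; validators check the partition,
  count and max-std invariants rather than assuming them.

## 4. Similarity scores

Peak lists are broadened with Gaussian kernels of width $\sigma$ equal to
the element's tolerance (0.1 ppm ¹H, 2.0 ppm ¹³C — reflecting the ~20-fold
difference in shift ranges) and compared by cosine similarity. The kernel
is a documented choice, not a claim of equivalence to any particular
published kernel: a Gaussian is smooth, differentiable and gives the
closed-form two-peak value $\exp(-d^2/(4\sigma^2))$ used as an oracle. The
grid step is $\sigma/5$, which keeps kernel mass complete to 0.1%; grids
must cover peaks by $\ge 4\sigma$.

IR spectra are compared window-wise (400–3950, 500–1500, 500–1000 cm⁻¹ by
default) on the stored curves without re-broadening; mismatched axes are
linearly interpolated onto the coarser one (deterministic,
resolution-safe). A spectrum with no intensity inside a window scores 0
against one that has some. Note that two spectra of the *same* signal at
different ACF depths have different linewidths, so their cosine score is
below 1 by the width mismatch alone — windowed scores compare curves, not
stick lists.

## 5. Chemical-space selection and split diagnostics

Morgan-style circular fingerprints (radius 2, 2048 bits by default — both
exposed, since published work rarely states them) are hashed environments
on the heavy-atom graph. Bit positions are implementation-specific, as with
any toolkit; all comparisons are within one fingerprint set.

k-means runs on the dense 0/1 vectors with the Euclidean metric and seeded
initialization from distinct fingerprint patterns; when duplicates leave
fewer distinct patterns than `k`, `k` is reduced accordingly. Selection
takes the member nearest its centroid first (ties by lower id), at least
`per_cluster` per nonempty cluster, and is deterministic under the seed. A
desk-scale default of k ≈ 100 per ~10⁴ molecules mirrors the published
ratio of 10⁴ clusters per ~2×10⁵ molecules; `k` scales with corpus size.

Murcko scaffolds are obtained by iteratively deleting terminal heavy atoms,
leaving ring systems and linkers; acyclic molecules map to the empty
scaffold and are counted separately. Severed attachment points become
hydrogens. One documented divergence from some toolkits: double-bonded
decorations on linkers (e.g. a benzophenone carbonyl oxygen) are stripped
with the side chains. Scaffold identity is decided on canonical SMILES so
frameworks from different molecules compare equal.

## 6. Validation metrics

`dipole_mae()` pools absolute component errors over frames and components
(`mae_xyz`) and averages absolute norm differences (`mae_norm`).
`dipole_r2()` uses $1 - SS_\mathrm{res}/SS_\mathrm{tot}$ with
$SS_\mathrm{tot}$ about the reference's own (per-component) mean, which
keeps the score invariant to a constant offset vector and reproduces the
characteristic failure mode of weakly polar molecules: for a near-constant
reference norm, a small absolute error still drives $R^2$ toward zero
(tested on a synthetic sweep). Zero reference variance returns an `NA`
marker, not an exception. Whether published MAEs pool components or average
per-axis values is usually unstated; pooling is chosen and documented.

## 7. Dataset schemas

The flat IR table (id, smiles, type, frequency, spectrum) is written as
chunked Parquet with nested list columns, 20,000 records per chunk and a
remainder file — at the full scale of 177,461 records, nine files with the
first eight holding 20,000 each, named `ir_chunk_00.parquet` onward (chunk
naming is not specified by the published layout; zero-padded indices are
this package's convention). The species map B:0 … Si:11 is validated as a
bijection. Nested NMR records are serialized as JSON-lines, which preserves
the multi-level per-frame dictionaries faithfully; `validate_nmr_record()`
applies the same report-based checks to records from either source.
Validation never mutates data; writers refuse invalid input before creating
any file.

## 8. Problem sizes used in tests

The suite runs IR pipelines at the full production geometry (40,001 steps)
where the published numbers depend on it, 1,000-step trajectories for the
ACF oracle (100 seeds), 300,001–400,001-step Morse integrations for the
term-value checks, 10-frame × 100-seed shielding ensembles for the recovery
rate, and one full-scale 177,461-record chunking run. These sizes were
chosen so every headline quantity is computed at the scale at which it is
quoted while the whole suite stays desk-scale.

## 9. Known limitations

- No MD, DFT or shielding computation: the package starts from dipole and
  shielding time series.
- Graph-based equivalence ignores conformation-broken symmetry and
  diastereotopicity; shift groupings for such cases are coarser than a
  strict NMR analysis would give.
- The SMILES reader targets the canonical dialect emitted by Open Babel
  (organic subset, brackets, aromatic lowercase, ring closures); exotic
  features (isotopes beyond plain numbers, polymers, reaction SMILES) are
  out of scope.
- Intensities are relative; no absorption-coefficient prefactor or
  absolute calibration is attempted.
- Fingerprint bits are not interchangeable with other toolkits' bits;
  Tanimoto values are comparable only within one fingerprint set.
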