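# Shared oracles and fixtures, independent of the implementation paths they
# check.

# speed of light in cm/fs, for closed-form expectations
C_CM_FS <- 2.99792458e-5

# direct-sum (O(N * L)) autocorrelation oracle with unbiased-per-lag
# normalization and optional mean removal
acf_direct <- function(dipoles, max_lag, subtract_mean = TRUE) {
  x <- as.matrix(dipoles)
  if (subtract_mean) x <- sweep(x, 2, colMeans(x))
  M <- nrow(x)
  vapply(0:max_lag, function(l) {
    sum(x[1:(M - l), , drop = FALSE] * x[(1 + l):M, , drop = FALSE]) / (M - l)
  }, 0)
}

# random dipole trajectory with a fixed seed
random_traj <- function(M, seed, dt_fs = 2.5) {
  set.seed(seed)
  dipole_trajectory(matrix(rnorm(3 * M), ncol = 3), dt_fs = dt_fs)
}

# argmax of a spectrum restricted to a wavenumber window
peak_position <- function(spectrum, lo = -Inf, hi = Inf) {
  keep <- which(spectrum$wavenumbers_cm1 >= lo & spectrum$wavenumbers_cm1 <= hi)
  i <- keep[which.max(spectrum$intensities[keep])]
  spectrum$wavenumbers_cm1[i]
}

# sub-bin peak position by parabolic interpolation through the three points
# around the argmax
peak_position_refined <- function(spectrum, lo = -Inf, hi = Inf) {
  keep <- which(spectrum$wavenumbers_cm1 >= lo & spectrum$wavenumbers_cm1 <= hi)
  i <- keep[which.max(spectrum$intensities[keep])]
  if (i <= 1 || i >= length(spectrum$intensities))
    return(spectrum$wavenumbers_cm1[i])
  y <- spectrum$intensities[(i - 1):(i + 1)]
  denom <- y[1] - 2 * y[2] + y[3]
  delta <- if (denom == 0) 0 else 0.5 * (y[1] - y[3]) / denom
  spectrum$wavenumbers_cm1[i] + delta * spectrum$resolution_cm1
}

# group-size signatures (sorted per element) frozen from an independent
# cheminformatics toolkit's canonical ranks (breakTies = FALSE) with the
# hydrogen rule "same heavy atom or equivalent attachment atoms"
GROUPING_ORACLE <- list(
  "C"                = list(C = c(1L),             H = c(4L)),
  "CCO"              = list(C = c(1L, 1L),         H = c(1L, 2L, 3L)),
  "c1ccccc1"         = list(C = c(6L),             H = c(6L)),
  "Cc1ccccc1"        = list(C = c(1L, 1L, 1L, 2L, 2L), H = c(1L, 2L, 2L, 3L)),
  "c1ccncc1"         = list(C = c(1L, 2L, 2L),     H = c(1L, 2L, 2L)),
  "CC(C)O"           = list(C = c(1L, 2L),         H = c(1L, 1L, 6L)),
  "Cc1ccc(C)cc1"     = list(C = c(2L, 2L, 4L),     H = c(4L, 6L)),
  "c1ccc2ccccc2c1"   = list(C = c(2L, 4L, 4L),     H = c(4L, 4L)),
  "CC(=O)O"          = list(C = c(1L, 1L),         H = c(1L, 3L)),
  "ClCCl"            = list(C = c(1L),             H = c(2L)),
  "CC(C)(C)C"        = list(C = c(1L, 4L),         H = c(12L)),
  "OCC(O)CO"         = list(C = c(1L, 2L),         H = c(1L, 1L, 2L, 4L))
)

group_sizes <- function(grouping) {
  list(C = sort(vapply(grouping$c_groups, length, 0L)),
       H = sort(vapply(grouping$h_groups, length, 0L)))
}

# small SMILES corpus for partition property tests
SMILES_CORPUS <- c(
  names(GROUPING_ORACLE),
  "CCN", "CCCO", "CCOC", "CC(C)=O", "CCC(=O)O", "NCC(=O)O", "c1ccco1",
  "c1cc[nH]c1", "c1ccsc1", "Cn1cccc1", "CC#N", "C=C", "C#C", "CC=O",
  "OC(=O)c1ccccc1", "Nc1ccccc1", "Oc1ccccc1", "Clc1ccccc1", "FC(F)F",
  "CS(=O)C", "COC(=O)C", "O=C(N)C", "C1CCCCC1", "C1CCNCC1", "C1CCOC1",
  "c1ccc(cc1)c1ccccc1", "OCCO", "CCCCCC", "CC(C)CC(C)(C)C", "CCOC(=O)C",
  "N#Cc1ccccc1", "CC(N)C(=O)O", "CCS", "BrCCBr", "IC(I)I", "OCc1ccccc1",
  "CNC", "C[Si](C)(C)C"
)
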