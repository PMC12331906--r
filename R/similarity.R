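#' NMR peak list
#'
#' @param shifts_ppm Peak positions in ppm.
#' @param weights Positive weights (default 1 per peak; use group
#'   multiplicities for ensemble peaks).
#' @return A `peak_list`.
#' @export
peak_list <- function(shifts_ppm, weights = NULL) {
  shifts_ppm <- as.numeric(shifts_ppm)
  if (is.null(weights)) weights <- rep(1, length(shifts_ppm))
  if (length(weights) != length(shifts_ppm))
    stop_invalid("shifts and weights must have equal length")
  if (any(weights <= 0)) stop_invalid("weights must be > 0")
  if (!all(is.finite(shifts_ppm))) stop_invalid("non-finite peak positions")
  structure(list(shifts_ppm = shifts_ppm, weights = as.numeric(weights)),
            class = "peak_list")
}

#' Similarity scoring settings
#'
#' Chemical-shift tolerances reflect the roughly 20-fold difference between
#' typical 1H and 13C shift ranges: 0.1 ppm for 1H, 2.0 ppm for 13C. IR
#' windows default to the full range 400-3950 cm^-1, the mid-infrared
#' 500-1500 cm^-1 and the fingerprint region 500-1000 cm^-1.
#'
#' @param tol_h_ppm 1H tolerance in ppm (default 0.1).
#' @param tol_c_ppm 13C tolerance in ppm (default 2.0).
#' @param grid_step_factor Broadening grid spacing as a fraction of the
#'   tolerance (default 0.2, i.e. sigma/5, keeping quadrature error of the
#'   Gaussian kernels below 0.1%).
#' @param ir_windows_cm1 List of `c(lo, hi)` wavenumber windows.
#' @return A `similarity_config`.
#' @export
similarity_config <- function(tol_h_ppm = 0.1, tol_c_ppm = 2.0,
                              grid_step_factor = 0.2,
                              ir_windows_cm1 = list(c(400, 3950),
                                                    c(500, 1500),
                                                    c(500, 1000))) {
  if (tol_h_ppm <= 0 || tol_c_ppm <= 0) stop_invalid("tolerances must be > 0")
  if (grid_step_factor <= 0) stop_invalid("grid_step_factor must be > 0")
  for (w in ir_windows_cm1)
    if (length(w) != 2L || w[1] >= w[2])
      stop_invalid("each IR window must be c(lo, hi) with lo < hi")
  structure(list(tol_h_ppm = tol_h_ppm, tol_c_ppm = tol_c_ppm,
                 grid_step_factor = grid_step_factor,
                 ir_windows_cm1 = ir_windows_cm1),
            class = "similarity_config")
}

#' Broaden a peak list onto a uniform grid
#'
#' Sum of Gaussian kernels centered at each peak with width
#' `sigma = tolerance` and height proportional to the peak weight. The grid
#' must cover every peak by at least 4 tolerances on each side so that the
#' kernel mass on the grid is complete to within 0.1%.
#'
#' @param peaks A [peak_list()].
#' @param tolerance_ppm Kernel width sigma (ppm).
#' @param grid Uniform, increasing grid (ppm).
#' @return Numeric intensity vector on the grid.
#' @export
broaden_peaks <- function(peaks, tolerance_ppm, grid) {
  stopifnot(inherits(peaks, "peak_list"))
  if (tolerance_ppm <= 0) stop_invalid("tolerance must be > 0")
  out_of_range <- peaks$shifts_ppm < grid[1] + 4 * tolerance_ppm - 1e-12 |
    peaks$shifts_ppm > grid[length(grid)] - 4 * tolerance_ppm + 1e-12
  if (any(out_of_range))
    stop_invalid("grid too narrow: peak at ",
                 peaks$shifts_ppm[which(out_of_range)[1]],
                 " ppm is not covered by 4 tolerances")
  v <- numeric(length(grid))
  for (k in seq_along(peaks$shifts_ppm)) {
    v <- v + peaks$weights[k] *
      exp(-(grid - peaks$shifts_ppm[k])^2 / (2 * tolerance_ppm^2))
  }
  v
}

#' Cosine similarity of two intensity vectors
#'
#' `a . b / (||a|| ||b||)`: symmetric, scale-invariant, in \[0, 1\] for
#' nonnegative inputs.
#'
#' @param a,b Equal-length nonnegative numeric vectors, each with at least
#'   one nonzero entry.
#' @return Similarity in \[0, 1\].
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b))
    stop_invalid("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop_invalid("cosine similarity is undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Tolerance-broadened NMR peak-list similarity
#'
#' Both peak lists are broadened with Gaussian kernels of width equal to the
#' element's chemical-shift tolerance on a shared grid, then compared by
#' cosine similarity. Identical weighted peak sets score 1; two unit peaks a
#' distance `d` apart score `exp(-d^2 / (4 sigma^2))`.
#'
#' @param computed,reference [peak_list()] objects (nonempty).
#' @param element `"H"` or `"C"` (selects the tolerance).
#' @param config A [similarity_config()].
#' @return Similarity in \[0, 1\].
#' @examples
#' nmr_similarity(peak_list(c(1, 3)), peak_list(c(1, 3)), "H")
#' @export
nmr_similarity <- function(computed, reference, element = c("H", "C"),
                           config = similarity_config()) {
  element <- match.arg(element)
  stopifnot(inherits(computed, "peak_list"), inherits(reference, "peak_list"))
  if (!length(computed$shifts_ppm) || !length(reference$shifts_ppm))
    stop_invalid("peak lists must be nonempty")
  tol <- if (element == "H") config$tol_h_ppm else config$tol_c_ppm
  all_shifts <- c(computed$shifts_ppm, reference$shifts_ppm)
  step <- tol * config$grid_step_factor
  grid <- seq(min(all_shifts) - 5 * tol, max(all_shifts) + 5 * tol, by = step)
  cosine_similarity(broaden_peaks(computed, tol, grid),
                    broaden_peaks(reference, tol, grid))
}

#' Windowed cosine similarity of two IR spectra
#'
#' Scores agreement within each configured wavenumber window. The stored
#' intensity curves are compared directly (they are already continuous
#' lineshapes); when the two axes differ, the finer spectrum is linearly
#' interpolated onto the coarser axis.
#'
#' @param a,b `ir_spectrum` objects whose axes cover each requested window.
#' @param config A [similarity_config()].
#' @return Named numeric vector, one cosine score in \[0, 1\] per window
#'   (names like `"400-3950"`).
#' @export
windowed_ir_similarity <- function(a, b, config = similarity_config()) {
  stopifnot(inherits(a, "ir_spectrum"), inherits(b, "ir_spectrum"))
  # interpolate the finer axis onto the coarser
  if (a$resolution_cm1 >= b$resolution_cm1) {
    coarse <- a; fine <- b
  } else {
    coarse <- b; fine <- a
  }
  lo_common <- max(min(coarse$wavenumbers_cm1), min(fine$wavenumbers_cm1))
  hi_common <- min(max(coarse$wavenumbers_cm1), max(fine$wavenumbers_cm1))
  scores <- vapply(config$ir_windows_cm1, function(w) {
    if (w[1] > hi_common || w[2] < lo_common)
      stop_invalid("window ", w[1], "-", w[2],
                   " cm^-1 lies outside the spectra")
    keep <- coarse$wavenumbers_cm1 >= max(w[1], lo_common) &
      coarse$wavenumbers_cm1 <= min(w[2], hi_common)
    x <- coarse$wavenumbers_cm1[keep]
    ya <- coarse$intensities[keep]
    yb <- stats::approx(fine$wavenumbers_cm1, fine$intensities, xout = x)$y
    ya <- pmax(ya, 0); yb <- pmax(yb, 0)
    # a spectrum with no intensity inside the window simply disagrees
    if (xor(sum(ya) == 0, sum(yb) == 0)) return(0)
    # order of (a, b) irrelevant: cosine is symmetric
    cosine_similarity(ya, yb)
  }, 0)
  names(scores) <- vapply(config$ir_windows_cm1,
                          function(w) paste0(w[1], "-", w[2]), "")
  scores
}
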