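#' Paired predicted/reference dipole set
#'
#' Frame-aligned dipole vectors from two sources (e.g. a surrogate model and
#' a first-principles reference) for one molecule.
#'
#' @param predicted,reference Numeric matrices with 3 columns (Debye), equal
#'   row counts >= 2, finite entries.
#' @param molecule_id Label.
#' @return A `dipole_pair_set`.
#' @export
dipole_pair_set <- function(predicted, reference, molecule_id = "") {
  predicted <- as.matrix(predicted); reference <- as.matrix(reference)
  if (ncol(predicted) != 3L || ncol(reference) != 3L)
    stop_invalid("dipole matrices must have 3 columns")
  if (nrow(predicted) != nrow(reference))
    stop_invalid("predicted and reference must have the same number of frames")
  if (nrow(predicted) < 2L) stop_invalid("need at least 2 frames")
  if (!all_finite(predicted) || !all_finite(reference))
    stop_invalid("non-finite dipole entries")
  structure(list(predicted = predicted, reference = reference,
                 molecule_id = as.character(molecule_id)),
            class = "dipole_pair_set")
}

#' Mean absolute error of dipole predictions
#'
#' `mae_xyz` pools the absolute component errors over all frames and all
#' three Cartesian components; `mae_norm` is the mean absolute difference of
#' the vector norms across frames. Both in Debye.
#'
#' @param pairs A [dipole_pair_set()].
#' @return Named numeric vector `c(mae_xyz, mae_norm)`.
#' @examples
#' p <- dipole_pair_set(rbind(c(1, 0, 0), c(0, 0, 0)),
#'                      matrix(0, 2, 3))
#' dipole_mae(p) # mae_xyz = 1/6, mae_norm = 0.5
#' @export
dipole_mae <- function(pairs) {
  stopifnot(inherits(pairs, "dipole_pair_set"))
  d <- pairs$predicted - pairs$reference
  norms_p <- sqrt(rowSums(pairs$predicted^2))
  norms_r <- sqrt(rowSums(pairs$reference^2))
  c(mae_xyz = mean(abs(d)), mae_norm = mean(abs(norms_p - norms_r)))
}

#' Coefficient of determination of dipole predictions
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` about the reference mean.
#' `r2_xyz` pools the three components (one score over all frames and
#' components); `r2_norm` scores the vector norm across frames. When the
#' reference has zero variance the score is undefined and `NA` is returned
#' (with the `undefined` attribute naming the affected quantity) — the
#' regime behind near-zero scores for weakly polar molecules, where a small
#' absolute error overwhelms a vanishing signal variance.
#'
#' @param pairs A [dipole_pair_set()].
#' @return Named numeric vector `c(r2_xyz, r2_norm)`; entries are `NA` where
#'   undefined.
#' @export
dipole_r2 <- function(pairs) {
  stopifnot(inherits(pairs, "dipole_pair_set"))
  r2 <- function(pred, ref) {
    ss_tot <- sum((ref - mean(ref))^2)
    if (ss_tot == 0) return(NA_real_)
    1 - sum((pred - ref)^2) / ss_tot
  }
  # xyz: pooled over components, each component centered about its own
  # reference mean (keeps the score invariant to a constant offset vector)
  ref_c <- sweep(pairs$reference, 2L, colMeans(pairs$reference))
  ss_tot_xyz <- sum(ref_c^2)
  r2_xyz <- if (ss_tot_xyz == 0) NA_real_ else
    1 - sum((pairs$predicted - pairs$reference)^2) / ss_tot_xyz
  out <- c(r2_xyz = r2_xyz,
           r2_norm = r2(sqrt(rowSums(pairs$predicted^2)),
                        sqrt(rowSums(pairs$reference^2))))
  undef <- names(out)[is.na(out)]
  if (length(undef)) attr(out, "undefined") <- undef
  out
}
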