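#' TMS shielding reference
#'
#' DFT-computed isotropic shieldings of tetramethylsilane, the conventional
#' zero point for 1H and 13C chemical shifts. A nucleus with shielding
#' `sigma` has chemical shift `delta = sigma_TMS - sigma`.
#'
#' @param sigma_h_ppm TMS proton shielding (ppm).
#' @param sigma_c_ppm TMS carbon shielding (ppm).
#' @return A `tms_reference` list.
#' @export
tms_reference <- function(sigma_h_ppm = 31.0, sigma_c_ppm = 188.0) {
  if (!is.finite(sigma_h_ppm) || !is.finite(sigma_c_ppm))
    stop_invalid("TMS shieldings must be finite")
  structure(list(sigma_h_ppm = sigma_h_ppm, sigma_c_ppm = sigma_c_ppm),
            class = "tms_reference")
}

#' Per-frame shielding data
#'
#' Isotropic shieldings of every atom in one MD frame, in a fixed atom order
#' shared by all frames of a molecule.
#'
#' @param frame_id Frame label.
#' @param elements Per-atom element symbols.
#' @param sigma_iso_ppm Per-atom isotropic shieldings (ppm).
#' @param xyz Optional per-atom coordinate matrix (Angstrom, 3 columns).
#' @param tms Optional [tms_reference()] attached to the frame.
#' @return A `shielding_frame` list.
#' @export
shielding_frame <- function(frame_id, elements, sigma_iso_ppm, xyz = NULL,
                            tms = NULL) {
  elements <- as.character(elements)
  if (length(elements) != length(sigma_iso_ppm))
    stop_invalid("elements and sigma_iso_ppm must have the same length")
  if (!is.null(xyz)) {
    xyz <- as.matrix(xyz)
    if (nrow(xyz) != length(elements) || ncol(xyz) != 3L)
      stop_invalid("xyz must be a (n_atoms x 3) matrix")
  }
  structure(list(frame_id = as.character(frame_id), elements = elements,
                 sigma_iso_ppm = as.numeric(sigma_iso_ppm), xyz = xyz,
                 tms = tms),
            class = "shielding_frame")
}

#' Parse a shielding output block
#'
#' Reads the package's plain-text shielding dialect (a minimal stand-in for
#' quantum-chemistry NMR log output; real logs can be adapted with a
#' user-supplied converter):
#' \preformatted{
#' # frame <frame_id>
#' <index> <element> [<x> <y> <z>] <sigma_iso_ppm>
#' ...
#' TMS H <sigma_h> C <sigma_c>      (optional footer)
#' }
#' Atom lines have 3 fields (index, element, shielding) or 6 fields (with
#' coordinates). Indices must be 1..n, each exactly once.
#'
#' @param text Raw text (single string or character vector of lines).
#' @return A [shielding_frame()]; the footer, when present, is attached as
#'   the `tms` element.
#' @examples
#' f <- parse_shielding_output(c("# frame 0", "1 H 26.0", "2 H 26.0",
#'                               "TMS H 31.0 C 188.0"))
#' f$tms$sigma_h_ppm
#' @export
parse_shielding_output <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  raw <- lines
  keep <- nzchar(trimws(lines))
  frame_id <- ""
  elements <- character(0); sigma <- numeric(0); idx <- integer(0)
  xyz <- NULL; tms <- NULL
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("frame[[:space:]]+(\\S+)", line))[[1]]
      if (length(m) == 2L) frame_id <- m[2]
      next
    }
    f <- strsplit(line, "[[:space:]]+")[[1]]
    if (identical(toupper(f[1]), "TMS")) {
      if (length(f) != 5L || toupper(f[2]) != "H" || toupper(f[4]) != "C")
        stop_invalid("malformed TMS footer at line ", ln, ": ", line)
      tms <- tms_reference(as.numeric(f[3]), as.numeric(f[5]))
      next
    }
    if (!length(f) %in% c(3L, 6L))
      stop_invalid("malformed atom line at line ", ln, " (expected 3 or 6 ",
                   "fields): ", line)
    i <- suppressWarnings(as.integer(f[1]))
    s <- suppressWarnings(as.numeric(f[length(f)]))
    if (is.na(i) || is.na(s))
      stop_invalid("malformed atom line at line ", ln, ": ", line)
    if (i %in% idx)
      stop_invalid("duplicate atom index ", i, " at line ", ln)
    idx <- c(idx, i)
    elements <- c(elements, f[2])
    sigma <- c(sigma, s)
    if (length(f) == 6L) {
      co <- suppressWarnings(as.numeric(f[3:5]))
      if (any(is.na(co)))
        stop_invalid("malformed coordinates at line ", ln, ": ", line)
      xyz <- rbind(xyz, co)
    }
  }
  if (length(idx) == 0L) stop_invalid("no atom lines found")
  if (!setequal(idx, seq_along(idx)))
    stop_invalid("atom indices must be 1..", length(idx))
  ord <- order(idx)
  if (!is.null(xyz)) {
    if (nrow(xyz) != length(idx))
      stop_invalid("coordinates present on some atom lines but not all")
    xyz <- xyz[ord, , drop = FALSE]
    rownames(xyz) <- NULL
  }
  shielding_frame(frame_id = frame_id, elements = elements[ord],
                  sigma_iso_ppm = sigma[ord], xyz = xyz, tms = tms)
}

#' Serialize a shielding frame to the fixture dialect
#'
#' Inverse of [parse_shielding_output()] up to whitespace.
#'
#' @param frame A [shielding_frame()].
#' @param digits Printed precision (default 6 significant digits).
#' @return A single string.
#' @export
write_shielding <- function(frame, digits = 6) {
  stopifnot(inherits(frame, "shielding_frame"))
  n <- length(frame$elements)
  lines <- paste0("# frame ", frame$frame_id)
  for (i in seq_len(n)) {
    if (!is.null(frame$xyz)) {
      lines <- c(lines, paste(i, frame$elements[i],
                              signif(frame$xyz[i, 1], digits),
                              signif(frame$xyz[i, 2], digits),
                              signif(frame$xyz[i, 3], digits),
                              signif(frame$sigma_iso_ppm[i], digits)))
    } else {
      lines <- c(lines, paste(i, frame$elements[i],
                              signif(frame$sigma_iso_ppm[i], digits)))
    }
  }
  if (!is.null(frame$tms))
    lines <- c(lines, paste("TMS H", signif(frame$tms$sigma_h_ppm, digits),
                            "C", signif(frame$tms$sigma_c_ppm, digits)))
  paste(lines, collapse = "\n")
}

#' Convert shieldings to TMS-referenced chemical shifts
#'
#' `delta_atom = sigma_TMS(element) - sigma_atom` in ppm for H and C atoms;
#' other elements get `NA` (no reference is defined for them).
#'
#' @param frame A [shielding_frame()].
#' @param ref A [tms_reference()]; defaults to the frame's own footer.
#' @return Numeric vector of per-atom shifts (ppm), `NA` for non-H/C atoms.
#' @export
reference_to_tms <- function(frame, ref = NULL) {
  stopifnot(inherits(frame, "shielding_frame"))
  if (is.null(ref)) ref <- frame$tms
  if (is.null(ref))
    stop_invalid("no TMS reference: pass `ref` or use a frame with a footer")
  stopifnot(inherits(ref, "tms_reference"))
  delta <- rep(NA_real_, length(frame$elements))
  isH <- frame$elements == "H"
  isC <- frame$elements == "C"
  delta[isH] <- ref$sigma_h_ppm - frame$sigma_iso_ppm[isH]
  delta[isC] <- ref$sigma_c_ppm - frame$sigma_iso_ppm[isC]
  delta
}

#' Symmetry-equivalence grouping of C and H atoms
#'
#' Construct or validate an atom grouping: disjoint groups of carbon atom
#' indices and of hydrogen atom indices (1-based, in the package atom order:
#' heavy atoms first, hydrogens appended by parent), each covering every atom
#' of its element.
#'
#' @param c_groups List of integer vectors (carbon atom indices).
#' @param h_groups List of integer vectors (hydrogen atom indices).
#' @param elements Full per-atom element vector.
#' @param smiles Optional canonical SMILES the grouping refers to.
#' @return An `atom_grouping` object.
#' @export
atom_grouping <- function(c_groups, h_groups, elements, smiles = NULL) {
  elements <- as.character(elements)
  check_part <- function(groups, elem, what) {
    idx <- unlist(groups)
    if (length(idx) != length(unique(idx)))
      stop_invalid(what, " groups are not disjoint")
    target <- which(elements == elem)
    if (!setequal(idx, target))
      stop_invalid(what, " groups must cover exactly the ", elem, " atoms")
    if (any(vapply(groups, length, 0L) == 0L))
      stop_invalid(what, " groups must be nonempty")
  }
  check_part(c_groups, "C", "carbon")
  check_part(h_groups, "H", "hydrogen")
  structure(list(c_groups = lapply(c_groups, as.integer),
                 h_groups = lapply(h_groups, as.integer),
                 elements = elements, natoms = length(elements),
                 smiles = smiles),
            class = "atom_grouping")
}

#' @export
print.atom_grouping <- function(x, ...) {
  cat(sprintf("<atom_grouping> %d atoms: %d C group(s) %s, %d H group(s) %s\n",
              x$natoms,
              length(x$c_groups),
              paste0("[", paste(vapply(x$c_groups, length, 0L), collapse = ","), "]"),
              length(x$h_groups),
              paste0("[", paste(vapply(x$h_groups, length, 0L), collapse = ","), "]")))
  invisible(x)
}

#' Group symmetry-equivalent C and H atoms of a molecule
#'
#' Two hydrogens share a group iff they are bonded to the same heavy atom or
#' their attachment atoms belong to the same graph-canonical equivalence
#' class (so all six methyl protons of isopropanol form one group); two
#' carbons share a group iff they belong to the same equivalence class.
#' Equivalence is perceived on the molecular graph
#' (see [atom_equivalence_classes()]), which matches chemical equivalence for
#' methyl rotors and ring symmetry; conformation-broken symmetry and
#' diastereotopic distinctions are deliberately ignored. Groups are reported
#' in ascending order of their lowest atom index.
#'
#' @param smiles SMILES string.
#' @return An [atom_grouping()] in the package atom order (heavy atoms in
#'   canonical SMILES order, hydrogens appended by parent atom).
#' @examples
#' group_equivalent_atoms("CCO") # methyl, methylene and hydroxyl protons
#' @export
group_equivalent_atoms <- function(smiles) {
  g <- if (inherits(smiles, "smiles_graph")) smiles else smiles_graph(smiles)
  classes <- atom_equivalence_classes(g)
  ord <- atom_order(g)
  c_idx <- which(g$element == "C")
  c_groups <- if (length(c_idx))
    unname(split(c_idx, classes[c_idx])) else list()
  h_idx <- ord$n_heavy + seq_along(ord$h_parent)
  h_groups <- if (length(h_idx))
    unname(split(h_idx, classes[ord$h_parent])) else list()
  by_lowest <- function(groups) {
    if (!length(groups)) return(groups)
    groups <- lapply(groups, sort)
    groups[order(vapply(groups, min, 0L))]
  }
  atom_grouping(by_lowest(c_groups), by_lowest(h_groups),
                elements = ord$elements, smiles = g$smiles_canonical)
}

#' Two-level averaging of chemical shifts
#'
#' The ensemble-averaging hierarchy: within each frame, symmetry-equivalent
#' atoms are averaged into one group value; the per-frame group values are
#' then averaged across frames. Variability is summarized as the population
#' standard deviation (denominator n) of the per-frame group values, so a
#' single frame cleanly yields zero. For balanced group sizes and frame
#' counts this equals the pooled single-pass mean; the pooled ordering is
#' also available for sensitivity checks.
#'
#' @param frames List of per-atom shift vectors (ppm; one per frame, equal
#'   lengths, `NA` for atoms of other elements) or a matrix with one row per
#'   frame.
#' @param grouping An [atom_grouping()] covering the atoms.
#' @param order `"frames_last"` (default; group within frame, then average
#'   across frames) or `"pooled"` (single mean over all member-atom shifts of
#'   all frames; stds still describe per-frame group values).
#' @return A `shift_aggregate` list with elements `h` and `c`, each holding
#'   `group_mean`, `group_std`, `max_std`, `per_frame` (frames x groups
#'   matrix); plus `n_frames`.
#' @examples
#' grp <- group_equivalent_atoms("C")
#' fr <- list(c(NA, 1, 1, 3, 3), c(NA, 2, 2, 4, 4))
#' aggregate_shifts(fr, grp)$h$group_mean
#' @export
aggregate_shifts <- function(frames, grouping,
                             order = c("frames_last", "pooled")) {
  order <- match.arg(order)
  stopifnot(inherits(grouping, "atom_grouping"))
  if (is.matrix(frames)) frames <- asplit(frames, 1L)
  lens <- vapply(frames, length, 0L)
  if (length(unique(lens)) != 1L)
    stop_invalid("frames have differing atom counts: ",
                 paste(unique(lens), collapse = ", "))
  if (lens[1] != grouping$natoms)
    stop_invalid("frames have ", lens[1], " atoms but the grouping covers ",
                 grouping$natoms)
  nf <- length(frames)
  one_element <- function(groups) {
    ng <- length(groups)
    per_frame <- matrix(NA_real_, nrow = nf, ncol = ng)
    for (fi in seq_len(nf)) for (gi in seq_len(ng)) {
      per_frame[fi, gi] <- mean(frames[[fi]][groups[[gi]]])
    }
    group_mean <- if (order == "frames_last") {
      colMeans(per_frame)
    } else {
      vapply(seq_len(ng), function(gi) {
        mean(unlist(lapply(frames, `[`, groups[[gi]])))
      }, 0)
    }
    group_std <- apply(per_frame, 2L, function(v) {
      sqrt(mean((v - mean(v))^2)) # population std across frames
    })
    list(group_mean = group_mean, group_std = group_std,
         max_std = if (ng) max(group_std) else 0,
         per_frame = per_frame)
  }
  structure(list(h = one_element(grouping$h_groups),
                 c = one_element(grouping$c_groups),
                 n_frames = nf, order = order),
            class = "shift_aggregate")
}

#' Assemble a nested NMR dataset record
#'
#' Builds the published nested NMR record for one molecule from per-frame
#' shielding data: TMS referencing, symmetry grouping, two-level averaging
#' and per-group uncertainty statistics, together with the raw shielding
#' text and coordinates per frame.
#'
#' @param id Molecule identifier.
#' @param smiles SMILES string (also used to derive the grouping when
#'   `grouping` is `NULL`).
#' @param frames List of [shielding_frame()] objects (consistent atom order).
#' @param grouping An [atom_grouping()]; derived from `smiles` by default.
#' @param reference A [tms_reference()]; defaults to the first frame's footer.
#' @param relaxed_xyz Optional relaxed-geometry coordinate matrix.
#' @return An `nmr_record` list with the published keys (`id`, `smiles`,
#'   `atoms`, `xyz`, `c_atoms_group_index`, `h_atoms_group_index`, `frames`,
#'   `number_of_frames`, `frame_ids`, `averaged_frames`, `h_nmr_std`,
#'   `c_nmr_std`, `h_nmr_max_std`, `c_nmr_max_std`). Group index lists are
#'   0-based in the record, matching the published convention.
#' @export
assemble_nmr_record <- function(id, smiles, frames, grouping = NULL,
                                reference = NULL, relaxed_xyz = NULL) {
  if (!length(frames)) stop_invalid("need at least one frame")
  stopifnot(all(vapply(frames, inherits, NA, "shielding_frame")))
  if (is.null(grouping)) grouping <- group_equivalent_atoms(smiles)
  if (is.null(reference)) reference <- frames[[1]]$tms
  if (is.null(reference))
    stop_invalid("no TMS reference available")
  natoms <- grouping$natoms
  for (f in frames) {
    if (length(f$elements) != natoms)
      stop_invalid("frame ", f$frame_id, " has ", length(f$elements),
                   " atoms; the grouping covers ", natoms)
    if (!identical(f$elements, grouping$elements))
      stop_invalid("frame ", f$frame_id,
                   " element order differs from the grouping")
  }
  shift_list <- lapply(frames, reference_to_tms, ref = reference)
  agg <- aggregate_shifts(shift_list, grouping)
  h_idx <- which(grouping$elements == "H")
  c_idx <- which(grouping$elements == "C")
  to0 <- function(groups) lapply(groups, function(ix) as.integer(ix - 1L))
  frame_entries <- lapply(seq_along(frames), function(fi) {
    delta <- shift_list[[fi]]
    list(
      c_nmr_grouped_peaks = lapply(grouping$c_groups, function(ix) delta[ix]),
      c_nmr_peaks_ave = unname(agg$c$per_frame[fi, ]),
      c_nmr_peaks_unsorted = delta[c_idx],
      h_nmr_grouped_peaks = lapply(grouping$h_groups, function(ix) delta[ix]),
      h_nmr_peaks_ave = unname(agg$h$per_frame[fi, ]),
      h_nmr_peaks_unsorted = delta[h_idx],
      nmr_cpmd_text = write_shielding(frames[[fi]]),
      xyz = frames[[fi]]$xyz
    )
  })
  names(frame_entries) <- vapply(frames, `[[`, "", "frame_id")
  structure(list(
    id = as.character(id),
    smiles = if (!is.null(grouping$smiles)) grouping$smiles else smiles,
    atoms = grouping$elements,
    xyz = relaxed_xyz,
    c_atoms_group_index = to0(grouping$c_groups),
    h_atoms_group_index = to0(grouping$h_groups),
    frames = frame_entries,
    number_of_frames = length(frames),
    frame_ids = names(frame_entries),
    averaged_frames = list(h_nmr_peaks = unname(agg$h$group_mean),
                           c_nmr_peaks = unname(agg$c$group_mean)),
    h_nmr_std = unname(agg$h$group_std),
    c_nmr_std = unname(agg$c$group_std),
    h_nmr_max_std = agg$h$max_std,
    c_nmr_max_std = agg$c$max_std
  ), class = "nmr_record")
}

#' @export
print.nmr_record <- function(x, ...) {
  cat(sprintf(
    "<nmr_record> %s (%s): %d atoms, %d frames, %d C / %d H groups\n",
    x$id, x$smiles, length(x$atoms), x$number_of_frames,
    length(x$c_atoms_group_index), length(x$h_atoms_group_index)))
  cat(sprintf("  max std: H %.3g ppm, C %.3g ppm\n",
              x$h_nmr_max_std, x$c_nmr_max_std))
  invisible(x)
}

#' Export per-group peaks of an NMR record as a flat table
#'
#' @param record An `nmr_record`.
#' @return Data frame with columns `element`, `group`, `shift_ppm`,
#'   `std_ppm`, `n_atoms`.
#' @export
nmr_peak_table <- function(record) {
  stopifnot(inherits(record, "nmr_record"))
  h <- data.frame(
    element = rep("H", length(record$h_atoms_group_index)),
    group = seq_along(record$h_atoms_group_index) - 1L,
    shift_ppm = record$averaged_frames$h_nmr_peaks,
    std_ppm = record$h_nmr_std,
    n_atoms = vapply(record$h_atoms_group_index, length, 0L))
  c_ <- data.frame(
    element = rep("C", length(record$c_atoms_group_index)),
    group = seq_along(record$c_atoms_group_index) - 1L,
    shift_ppm = record$averaged_frames$c_nmr_peaks,
    std_ppm = record$c_nmr_std,
    n_atoms = vapply(record$c_atoms_group_index, length, 0L))
  rbind(h, c_)
}
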