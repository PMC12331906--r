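# Published dataset schemas: flat IR rows (Parquet, chunked) and nested NMR
# records (JSON-lines). Validation is report-based and never mutates data.

#' Species-to-type integer map
#'
#' The published encoding of the twelve allowed elements:
#' B 0, Br 1, C 2, Cl 3, F 4, H 5, I 6, N 7, O 8, P 9, S 10, Si 11.
#'
#' @return Named integer vector (element -> code).
#' @export
species_type_map <- function() {
  c(B = 0L, Br = 1L, C = 2L, Cl = 3L, F = 4L, H = 5L, I = 6L,
    N = 7L, O = 8L, P = 9L, S = 10L, Si = 11L)
}

#' Element-type vector of a molecule
#'
#' Integer type codes in the package atom order (heavy atoms in canonical
#' SMILES order, then explicit hydrogens appended by parent atom), matching
#' the published `type` column.
#'
#' @param smiles SMILES string.
#' @return Integer vector of species codes.
#' @examples
#' smiles_type_vector("C") # one carbon (2) and four hydrogens (5)
#' @export
smiles_type_vector <- function(smiles) {
  g <- if (inherits(smiles, "smiles_graph")) smiles else smiles_graph(smiles)
  elems <- atom_order(g)$elements
  map <- species_type_map()
  codes <- map[elems]
  if (anyNA(codes))
    stop_invalid("element(s) outside the species map: ",
                 paste(unique(elems[is.na(codes)]), collapse = ", "))
  unname(codes)
}

#' One IR dataset record
#'
#' @param id Unique identifier.
#' @param smiles SMILES string.
#' @param type Integer species codes (0..11) per atom.
#' @param frequency_cm1 Wavenumber axis.
#' @param ir_spectra Quantum-corrected intensity vector (same length).
#' @return A one-row tibble in the IR table schema.
#' @export
ir_record <- function(id, smiles, type, frequency_cm1, ir_spectra) {
  tibble::tibble(id = as.character(id), smiles = as.character(smiles),
                 type = list(as.integer(type)),
                 frequency_cm1 = list(as.numeric(frequency_cm1)),
                 ir_spectra = list(as.numeric(ir_spectra)))
}

.ir_columns <- c("id", "smiles", "type", "frequency_cm1", "ir_spectra")

#' Validate IR dataset records
#'
#' Checks every record against the schema invariants: column completeness,
#' unique ids, type codes within the species map, equal-length frequency and
#' intensity vectors, and a type list whose length equals the atom count
#' implied by the SMILES with explicit hydrogens (only when
#' `check_atom_counts` is TRUE; parsing every SMILES is the expensive part).
#' Findings are collected into a report, never thrown.
#'
#' @param records Tibble/data frame of IR records.
#' @param check_atom_counts Verify type-list lengths against the SMILES
#'   (default FALSE).
#' @return Character vector of problems (empty when valid), each naming the
#'   offending record id.
#' @export
validate_ir_records <- function(records, check_atom_counts = FALSE) {
  problems <- character(0)
  missing_cols <- setdiff(.ir_columns, names(records))
  if (length(missing_cols))
    return(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  extra <- setdiff(names(records), .ir_columns)
  if (length(extra))
    problems <- c(problems,
                  paste0("unexpected column(s): ", paste(extra, collapse = ", ")))
  if (anyDuplicated(records$id))
    problems <- c(problems, paste0("duplicate id(s): ",
                                   paste(unique(records$id[duplicated(records$id)]),
                                         collapse = ", ")))
  tmin <- vapply(records$type, function(t) if (length(t)) min(t) else 0L, 0L)
  tmax <- vapply(records$type, function(t) if (length(t)) max(t) else 0L, 0L)
  bad_type <- which(tmin < 0L | tmax > 11L)
  for (i in bad_type)
    problems <- c(problems, paste0("record ", records$id[i],
                                   ": type codes outside 0..11"))
  lf <- lengths(records$frequency_cm1)
  ls <- lengths(records$ir_spectra)
  bad_len <- which(lf != ls)
  for (i in bad_len)
    problems <- c(problems, paste0("record ", records$id[i],
                                   ": frequency (", lf[i], ") and spectrum (",
                                   ls[i], ") lengths differ"))
  nonfinite <- which(!vapply(records$ir_spectra, all_finite, NA))
  for (i in nonfinite)
    problems <- c(problems, paste0("record ", records$id[i],
                                   ": non-finite intensities"))
  if (check_atom_counts) {
    cache <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(records))) {
      s <- records$smiles[i]
      n_exp <- tryCatch({
        if (is.null(cache[[s]])) cache[[s]] <- length(smiles_type_vector(s))
        cache[[s]]
      }, error = function(e) NA_integer_)
      if (is.na(n_exp)) {
        problems <- c(problems, paste0("record ", records$id[i],
                                       ": unparseable SMILES ", s))
      } else if (length(records$type[[i]]) != n_exp) {
        problems <- c(problems, paste0("record ", records$id[i],
                                       ": type list length ",
                                       length(records$type[[i]]),
                                       " != atom count ", n_exp))
      }
    }
  }
  problems
}

#' Plan the chunking of n records
#'
#' @param n Number of records.
#' @param chunk_size Records per chunk (>= 1).
#' @return Integer vector of chunk sizes: full chunks of `chunk_size` and a
#'   final remainder; `sum == n`, `length == ceiling(n / chunk_size)`.
#' @export
chunk_plan <- function(n, chunk_size) {
  if (chunk_size < 1) stop_invalid("chunk_size must be >= 1")
  n <- as.integer(n); chunk_size <- as.integer(chunk_size)
  if (n < 1) return(integer(0))
  n_full <- n %/% chunk_size
  rem <- n %% chunk_size
  c(rep(chunk_size, n_full), if (rem > 0L) rem)
}

#' Write IR records as chunked Parquet files
#'
#' Splits the records into files of exactly `chunk_size` rows (a final file
#' holds the remainder), named `ir_chunk_00.parquet`, `ir_chunk_01.parquet`,
#' ... in `out_dir`. The full published dataset of 177,461 records at the
#' default chunk size yields nine files, the first eight holding 20,000
#' records each. Records are validated first; any invalid record aborts the
#' write before any file is produced.
#'
#' @param records Tibble of IR records.
#' @param out_dir Output directory (created if needed).
#' @param chunk_size Records per chunk (default 20,000).
#' @param prefix File-name prefix (default `"ir_chunk_"`).
#' @return Character vector of file paths, in chunk order.
#' @export
write_ir_chunks <- function(records, out_dir, chunk_size = 20000L,
                            prefix = "ir_chunk_") {
  problems <- validate_ir_records(records)
  if (length(problems))
    stop_invalid("invalid records, nothing written:\n  ",
                 paste(utils::head(problems, 5), collapse = "\n  "))
  sizes <- chunk_plan(nrow(records), chunk_size)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  width <- max(2L, nchar(length(sizes) - 1L))
  paths <- character(length(sizes))
  start <- 1L
  for (k in seq_along(sizes)) {
    rows <- seq.int(start, start + sizes[k] - 1L)
    paths[k] <- file.path(out_dir,
                          sprintf("%s%0*d.parquet", prefix, width, k - 1L))
    arrow::write_parquet(records[rows, ], paths[k])
    start <- start + sizes[k]
  }
  paths
}

#' Read a chunked IR dataset
#'
#' Reads and concatenates Parquet chunk files in the given order and
#' validates the result; schema violations are collected into a report
#' attached as the `"validation"` attribute, never silently dropped.
#'
#' @param paths Parquet file paths (e.g. from [write_ir_chunks()]), or a
#'   directory containing `*.parquet` chunks.
#' @param check_atom_counts Passed to [validate_ir_records()].
#' @return Tibble of records with attribute `validation` (character vector
#'   of problems; empty when clean).
#' @export
read_ir_dataset <- function(paths, check_atom_counts = FALSE) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.parquet$",
                             full.names = TRUE))
  if (!length(paths)) stop_invalid("no parquet files to read")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop_invalid("missing file(s): ", paste(missing, collapse = ", "))
  parts <- lapply(paths, function(p) {
    x <- arrow::read_parquet(p)
    mc <- setdiff(.ir_columns, names(x))
    if (length(mc))
      stop_invalid("schema mismatch in ", p, ": missing column(s) ",
                   paste(mc, collapse = ", "))
    # arrow returns vctrs list_of columns; plain lists rbind and compare
    # cleanly downstream
    for (col in c("type", "frequency_cm1", "ir_spectra"))
      x[[col]] <- lapply(x[[col]], identity)
    x$type <- lapply(x$type, as.integer)
    x
  })
  out <- do.call(rbind, parts)
  attr(out, "validation") <- validate_ir_records(out, check_atom_counts)
  out
}

#' Validate a nested NMR record
#'
#' Report-based validation of the published nested schema: key completeness,
#' frame-count consistency (`number_of_frames` equals both the number of
#' frame entries and `length(frame_ids)`), per-element lengths of the
#' unsorted shift lists, nonnegative stds, `max_std` equal to the maximum of
#' its element's group stds, and group indices forming a partition of the
#' element's atoms.
#'
#' @param record An `nmr_record` (or a compatible named list).
#' @return Character vector of findings (empty when valid).
#' @export
validate_nmr_record <- function(record) {
  problems <- character(0)
  need <- c("id", "smiles", "atoms", "c_atoms_group_index",
            "h_atoms_group_index", "frames", "number_of_frames", "frame_ids",
            "averaged_frames", "h_nmr_std", "c_nmr_std", "h_nmr_max_std",
            "c_nmr_max_std")
  missing <- setdiff(need, names(record))
  if (length(missing))
    return(paste0("missing key(s): ", paste(missing, collapse = ", ")))
  nf <- record$number_of_frames
  if (nf != length(record$frame_ids))
    problems <- c(problems, sprintf(
      "number_of_frames (%d) != length(frame_ids) (%d)",
      nf, length(record$frame_ids)))
  if (nf != length(record$frames))
    problems <- c(problems, sprintf(
      "number_of_frames (%d) != number of frame entries (%d)",
      nf, length(record$frames)))
  atoms <- record$atoms
  n_h <- sum(atoms == "H"); n_c <- sum(atoms == "C")
  for (fi in seq_along(record$frames)) {
    fr <- record$frames[[fi]]
    if (length(fr$h_nmr_peaks_unsorted) != n_h)
      problems <- c(problems, sprintf(
        "frame %s: h_nmr_peaks_unsorted has %d entries for %d H atoms",
        names(record$frames)[fi], length(fr$h_nmr_peaks_unsorted), n_h))
    if (length(fr$c_nmr_peaks_unsorted) != n_c)
      problems <- c(problems, sprintf(
        "frame %s: c_nmr_peaks_unsorted has %d entries for %d C atoms",
        names(record$frames)[fi], length(fr$c_nmr_peaks_unsorted), n_c))
  }
  if (any(record$h_nmr_std < 0) || any(record$c_nmr_std < 0))
    problems <- c(problems, "negative standard deviation")
  chk_max <- function(stds, mx, what) {
    if (length(stds) && !isTRUE(all.equal(max(stds), mx, tolerance = 1e-9)))
      problems <<- c(problems, sprintf(
        "%s (%g) != max of group stds (%g)", what, mx, max(stds)))
  }
  chk_max(record$h_nmr_std, record$h_nmr_max_std, "h_nmr_max_std")
  chk_max(record$c_nmr_std, record$c_nmr_max_std, "c_nmr_max_std")
  chk_part <- function(groups, elem, what) {
    idx <- unlist(groups)
    target <- which(atoms == elem) - 1L # record indices are 0-based
    if (length(idx) != length(unique(idx)) || !setequal(idx, target))
      problems <<- c(problems, paste0(
        what, " is not a partition of the ", elem, " atoms"))
  }
  chk_part(record$c_atoms_group_index, "C", "c_atoms_group_index")
  chk_part(record$h_atoms_group_index, "H", "h_atoms_group_index")
  problems
}

#' Write NMR records as JSON-lines
#'
#' One record per line with the published keys. JSON-lines keeps the
#' arbitrarily nested per-frame dictionaries faithful and diff-able.
#'
#' @param records List of `nmr_record` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_nmr_records <- function(records, path) {
  if (inherits(records, "nmr_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(jsonlite::toJSON(unclass(r), auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(path)
}

#' Read NMR records from JSON-lines
#'
#' @param path File written by [write_nmr_records()].
#' @return List of `nmr_record` objects.
#' @export
read_nmr_records <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], function(ln) {
    r <- jsonlite::fromJSON(ln, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
    r$atoms <- unlist(r$atoms)
    r$frame_ids <- as.character(unlist(r$frame_ids))
    for (k in c("h_nmr_std", "c_nmr_std"))
      r[[k]] <- as.numeric(unlist(r[[k]]))
    r$c_atoms_group_index <- lapply(r$c_atoms_group_index,
                                    function(v) as.integer(unlist(v)))
    r$h_atoms_group_index <- lapply(r$h_atoms_group_index,
                                    function(v) as.integer(unlist(v)))
    for (fi in seq_along(r$frames)) {
      for (k in c("c_nmr_peaks_ave", "c_nmr_peaks_unsorted",
                  "h_nmr_peaks_ave", "h_nmr_peaks_unsorted"))
        r$frames[[fi]][[k]] <- as.numeric(unlist(r$frames[[fi]][[k]]))
    }
    r$averaged_frames <- lapply(r$averaged_frames,
                                function(v) as.numeric(unlist(v)))
    class(r) <- "nmr_record"
    r
  })
}
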