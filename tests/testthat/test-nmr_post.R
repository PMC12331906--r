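test_that("shielding parser reads the fixture dialect and its footer", {
  txt <- c("# frame 3",
           "1 C 160.5",
           "2 H 26.0", "3 H 26.0", "4 H 26.0", "5 H 26.0",
           "TMS H 31.0 C 188.0")
  fr <- parse_shielding_output(txt)
  expect_identical(fr$frame_id, "3")
  expect_identical(fr$elements, c("C", "H", "H", "H", "H"))
  expect_equal(fr$sigma_iso_ppm[2:5], rep(26.0, 4))
  expect_equal(fr$tms$sigma_h_ppm, 31.0)
  expect_equal(fr$tms$sigma_c_ppm, 188.0)
})

test_that("parser reports malformed lines with their line number", {
  expect_error(parse_shielding_output(c("# frame 0", "1 C x")), "line 2")
  expect_error(parse_shielding_output(c("# frame 0", "1 C 160", "1 H 26")),
               "duplicate atom index 1")
  expect_error(parse_shielding_output(c("# frame 0", "1 C 160", "3 H 26")),
               "indices must be 1")
  expect_error(parse_shielding_output("# frame 0"), "no atom lines")
})

test_that("write_shielding / parse_shielding_output round-trip, with and
           without coordinates", {
  xyz <- matrix(rnorm(15), ncol = 3)
  fr <- shielding_frame("7", c("C", "H", "H", "H", "H"),
                        c(160.123, 26.4, 26.5, 26.6, 26.7),
                        xyz = xyz, tms = tms_reference(31.2, 187.6))
  back <- parse_shielding_output(write_shielding(fr, digits = 9))
  expect_identical(back$frame_id, "7")
  expect_equal(back$sigma_iso_ppm, fr$sigma_iso_ppm, tolerance = 1e-7)
  expect_equal(back$xyz, unname(fr$xyz), tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(back$tms$sigma_c_ppm, 187.6)
})

test_that("TMS referencing: delta = sigma_TMS - sigma, NA for other elements", {
  fr <- shielding_frame("0", c("C", "H", "O"), c(188.0, 26.0, 100.0))
  ref <- tms_reference(31.0, 188.0)
  d <- reference_to_tms(fr, ref)
  expect_equal(d, c(0, 5, NA))
  # element-wise application equals a per-atom loop
  fr2 <- shielding_frame("0", rep(c("H", "C"), 5), rnorm(10, 100, 20))
  d2 <- reference_to_tms(fr2, ref)
  loop <- vapply(seq_len(10), function(i) {
    s <- if (fr2$elements[i] == "H") ref$sigma_h_ppm else ref$sigma_c_ppm
    s - fr2$sigma_iso_ppm[i]
  }, 0)
  expect_equal(d2, loop)
  expect_error(reference_to_tms(fr), "no TMS reference")
})

test_that("symmetry groupings match the independent canonical-rank oracle", {
  for (s in names(GROUPING_ORACLE)) {
    got <- group_sizes(group_equivalent_atoms(s))
    expect_identical(got, GROUPING_ORACLE[[s]], label = s)
  }
})

test_that("groupings are partitions over a broad SMILES corpus", {
  for (s in SMILES_CORPUS) {
    grp <- group_equivalent_atoms(s)
    c_idx <- unlist(grp$c_groups)
    h_idx <- unlist(grp$h_groups)
    expect_identical(sort(c_idx), which(grp$elements == "C"), label = s)
    expect_identical(sort(h_idx), which(grp$elements == "H"), label = s)
    expect_false(anyDuplicated(c(c_idx, h_idx)) > 0, label = s)
    # groups in ascending order of their lowest atom index
    if (length(grp$c_groups) > 1)
      expect_true(!is.unsorted(vapply(grp$c_groups, min, 0L)), label = s)
    if (length(grp$h_groups) > 1)
      expect_true(!is.unsorted(vapply(grp$h_groups, min, 0L)), label = s)
  }
})

test_that("unparseable SMILES is rejected", {
  expect_error(group_equivalent_atoms("not_a_smiles(("), "unparseable")
})

test_that("two-level averaging: hand-computed means and population stds", {
  grp <- atom_grouping(c_groups = list(1L), h_groups = list(c(2L, 3L)),
                       elements = c("C", "H", "H"))
  # one frame, group {a, b} with 1.0 and 3.0 -> mean 2, std 0
  one <- aggregate_shifts(list(c(10, 1, 3)), grp)
  expect_equal(one$h$group_mean, 2.0)
  expect_equal(one$h$group_std, 0.0)
  # two frames with group values 2 and 4 -> mean 3, population std 1
  two <- aggregate_shifts(list(c(10, 1, 3), c(12, 3, 5)), grp)
  expect_equal(two$h$group_mean, 3.0)
  expect_equal(two$h$group_std, 1.0)
  expect_equal(two$c$group_std, 1.0)
  expect_equal(two$h$max_std, 1.0)
})

test_that("aggregation is invariant to grouping-consistent relabeling and to
           constant offsets", {
  grp <- group_equivalent_atoms("CC(C)O") # isopropanol
  set.seed(5)
  frames <- replicate(6, rnorm(grp$natoms, 50, 5), simplify = FALSE)
  base <- aggregate_shifts(frames, grp)
  # permute atoms within each group
  perm <- seq_len(grp$natoms)
  for (g in c(grp$c_groups, grp$h_groups)) {
    if (length(g) > 1) perm[g] <- g[c(length(g), seq_len(length(g) - 1))]
  }
  frames_p <- lapply(frames, function(v) { v[perm] <- v; v })
  permd <- aggregate_shifts(frames_p, grp)
  expect_equal(permd$h$group_mean, base$h$group_mean)
  expect_equal(permd$c$group_std, base$c$group_std)
  # adding a constant shifts means, leaves stds alone
  shifted <- aggregate_shifts(lapply(frames, `+`, 7), grp)
  expect_equal(shifted$h$group_mean, base$h$group_mean + 7)
  expect_equal(shifted$h$group_std, base$h$group_std)
  expect_true(all(base$h$group_std >= 0))
  expect_gte(base$h$max_std, max(base$h$group_std) - 1e-12)
})

test_that("frames-last equals pooled averaging when balanced, differs when
           group values are weighted unevenly", {
  grp <- atom_grouping(c_groups = list(1L), h_groups = list(c(2L, 3L)),
                       elements = c("C", "H", "H"))
  frames <- list(c(1, 2, 4), c(3, 6, 8))
  a <- aggregate_shifts(frames, grp, order = "frames_last")
  b <- aggregate_shifts(frames, grp, order = "pooled")
  expect_equal(a$h$group_mean, b$h$group_mean) # balanced: identical
  # unbalanced pooling differs: weight frames unevenly via NA-free subsetting
  grp2 <- atom_grouping(c_groups = list(1L), h_groups = list(2L, 3L),
                        elements = c("C", "H", "H"))
  expect_equal(aggregate_shifts(frames, grp2)$h$group_mean, c(4, 6))
})

test_that("frame length mismatches are invalid data", {
  grp <- atom_grouping(c_groups = list(1L), h_groups = list(2L),
                       elements = c("C", "H"))
  expect_error(aggregate_shifts(list(c(1, 2), c(1, 2, 3)), grp), "differing")
})

test_that("assembled records honor the nested schema invariants", {
  grp <- group_equivalent_atoms("CCO")
  spec <- synthetic_shielding_spec(h_means_ppm = c(1.19, 3.66, 2.61),
                                   c_means_ppm = c(18.3, 57.8),
                                   h_sigma_ppm = 0.4, c_sigma_ppm = 1.5,
                                   n_frames = 10, seed = 11)
  frames <- synthetic_shielding_frames(spec, grp)
  rec <- assemble_nmr_record("ethanol-1", "CCO", frames, grp)
  expect_identical(rec$number_of_frames, 10L)
  expect_length(rec$frame_ids, 10)
  expect_length(validate_nmr_record(rec), 0)
  # unsorted lists follow atom order, one entry per atom of the element
  n_h <- sum(grp$elements == "H")
  for (fr in rec$frames) {
    expect_length(fr$h_nmr_peaks_unsorted, n_h)
    expect_length(fr$c_nmr_peaks_unsorted, sum(grp$elements == "C"))
  }
  # raw text is embedded and parseable
  back <- parse_shielding_output(rec$frames[[1]]$nmr_cpmd_text)
  expect_identical(back$elements, grp$elements)
})

test_that("zero-variance fixtures give max_std exactly 0", {
  grp <- group_equivalent_atoms("C")
  spec <- synthetic_shielding_spec(h_means_ppm = 0.23, c_means_ppm = -2.3,
                                   n_frames = 5, seed = 0)
  rec <- assemble_nmr_record("methane", "C",
                             synthetic_shielding_frames(spec, grp), grp)
  expect_identical(rec$h_nmr_max_std, 0)
  expect_identical(rec$c_nmr_max_std, 0)
})

test_that("known group means are recovered within 3 standard errors", {
  grp <- group_equivalent_atoms("CCO")
  truth_h <- c(1.2, 3.6, 2.6); truth_c <- c(18, 58)
  hits <- 0L; n_seeds <- 30L
  for (seed in seq_len(n_seeds)) {
    spec <- synthetic_shielding_spec(h_means_ppm = truth_h,
                                     c_means_ppm = truth_c,
                                     h_sigma_ppm = 1, c_sigma_ppm = 1,
                                     n_frames = 10, seed = seed)
    agg <- aggregate_shifts(
      lapply(synthetic_shielding_frames(spec, grp), reference_to_tms), grp)
    tol <- 3 * 1 / sqrt(10)
    if (all(abs(agg$h$group_mean - truth_h) < tol) &&
        all(abs(agg$c$group_mean - truth_c) < tol)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.8)
})

test_that("nmr records survive the JSON-lines round trip", {
  grp <- group_equivalent_atoms("c1ccccc1")
  spec <- synthetic_shielding_spec(h_means_ppm = 7.3, c_means_ppm = 128.5,
                                   h_sigma_ppm = 0.2, c_sigma_ppm = 1.1,
                                   n_frames = 3, seed = 2)
  rec <- assemble_nmr_record("benzene", "c1ccccc1",
                             synthetic_shielding_frames(spec, grp), grp)
  path <- tempfile(fileext = ".jsonl")
  write_nmr_records(list(rec), path)
  back <- read_nmr_records(path)[[1]]
  expect_length(validate_nmr_record(back), 0)
  expect_equal(back$averaged_frames$h_nmr_peaks,
               rec$averaged_frames$h_nmr_peaks, tolerance = 1e-12)
  expect_equal(back$h_nmr_max_std, rec$h_nmr_max_std, tolerance = 1e-12)
})

test_that("peak table flattens a record for spreadsheets", {
  grp <- group_equivalent_atoms("CCO")
  spec <- synthetic_shielding_spec(h_means_ppm = c(1.2, 3.6, 2.6),
                                   c_means_ppm = c(18, 58), n_frames = 2,
                                   seed = 0)
  rec <- assemble_nmr_record("e", "CCO",
                             synthetic_shielding_frames(spec, grp), grp)
  tab <- nmr_peak_table(rec)
  expect_identical(nrow(tab), 5L)
  expect_setequal(tab$element, c("H", "C"))
  expect_equal(sum(tab$n_atoms[tab$element == "H"]), 6)
})
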