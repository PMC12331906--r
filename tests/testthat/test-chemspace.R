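test_that("tanimoto on hand-built bit vectors, with the all-zero convention", {
  a <- c(1, 1, 0, 0, 1, 0, 0, 0)
  b <- c(0, 1, 0, 0, 1, 1, 1, 0) # |and| = 2, |or| = 5
  expect_equal(tanimoto(a, b), 0.4)
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0.0)
  expect_equal(tanimoto(numeric(8), numeric(8)), 1.0)
  expect_equal(tanimoto(numeric(8), a), 0.0)
  expect_error(tanimoto(a, c(1, 0)), "equal length")
  expect_equal(tanimoto(a, b), tanimoto(b, a))
})

test_that("max similarity to train equals the exhaustive double loop", {
  set.seed(3)
  qb <- matrix(runif(3 * 16) > 0.5, nrow = 3)
  tb <- matrix(runif(2 * 16) > 0.5, nrow = 2)
  q <- fingerprint_set(paste0("q", 1:3), qb)
  tr <- fingerprint_set(paste0("t", 1:2), tb)
  got <- max_similarity_to_train(q, tr)$max_similarity
  want <- vapply(1:3, function(i)
    max(vapply(1:2, function(j) tanimoto(qb[i, ], tb[j, ]), 0)), 0)
  expect_equal(unname(got), want)
  # a query that is also in train scores exactly 1
  q2 <- fingerprint_set(c("a", "b"), rbind(qb[1, ], qb[2, ]))
  tr2 <- fingerprint_set(c("x", "y"), rbind(tb[1, ], qb[1, ]))
  expect_equal(unname(max_similarity_to_train(q2, tr2)$max_similarity[1]), 1)
  expect_error(max_similarity_to_train(q, fingerprint_set(character(0),
    matrix(logical(0), 0, 16))), "empty")
})

test_that("threshold fractions count queries above 0.4 and 0.5", {
  bits <- rbind(c(1, 1, 1, 1), c(1, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 0, 1))
  q <- fingerprint_set(paste0("q", 1:4), bits)
  tr <- fingerprint_set("t", matrix(c(1, 1, 1, 1), 1))
  ms <- max_similarity_to_train(q, tr)
  # similarities: 1, 0.5, 0.25, 0.25
  expect_equal(unname(ms$fraction_above[">0.4"]), 0.5)
  expect_equal(unname(ms$fraction_above[">0.5"]), 0.25)
})

test_that("fingerprints are deterministic and rank chemical neighbors sensibly", {
  f1 <- morgan_fingerprint("CCO")
  f2 <- morgan_fingerprint("CCO")
  expect_identical(f1, f2)
  expect_length(f1, 2048)
  ethanol_propanol <- tanimoto(morgan_fingerprint("CCO"),
                               morgan_fingerprint("CCCO"))
  ethanol_benzene <- tanimoto(morgan_fingerprint("CCO"),
                              morgan_fingerprint("c1ccccc1"))
  expect_gt(ethanol_propanol, ethanol_benzene)
})

test_that("kmeans selection covers every nonempty cluster, deterministically", {
  # two well-separated synthetic blobs in bit space
  set.seed(1)
  blob1 <- matrix(rep(c(rep(TRUE, 24), rep(FALSE, 24)), 6), nrow = 6,
                  byrow = TRUE)
  blob2 <- matrix(rep(c(rep(FALSE, 24), rep(TRUE, 24)), 5), nrow = 5,
                  byrow = TRUE)
  flip <- function(m) { # a little within-blob variation
    for (i in seq_len(nrow(m))) m[i, sample(48, 3)] <- !m[i, sample(48, 3)]
    m
  }
  fps <- fingerprint_set(sprintf("m%02d", 1:11), rbind(flip(blob1), flip(blob2)),
                         n_bits = 48)
  sel <- kmeans_select(fps, k = 2, seed = 7)
  expect_identical(sel$k_used, 2L)
  expect_length(sel$selected, 2)
  # one pick per blob
  expect_length(unique(substr(sel$selected, 1, 1)), 1) # both are "m.."
  blob_of <- function(id) if (as.integer(substr(id, 2, 3)) <= 6) 1 else 2
  expect_setequal(vapply(sel$selected, blob_of, 0), c(1, 2))
  # deterministic under the seed
  expect_identical(sel$selected, kmeans_select(fps, 2, seed = 7)$selected)
  # every molecule selected at k = n
  all_sel <- kmeans_select(fps, k = 11, seed = 0)
  expect_setequal(all_sel$selected, fps$ids)
  expect_error(kmeans_select(fps, 12), "between 1")
})

test_that("per-cluster minimum picks are honored", {
  set.seed(2)
  fps <- fingerprint_set(sprintf("m%02d", 1:9),
                         matrix(runif(9 * 32) > 0.5, nrow = 9), n_bits = 32)
  sel <- kmeans_select(fps, k = 3, seed = 1, per_cluster = 2)
  expect_gte(length(sel$selected), 6)
  counts <- table(sel$cluster[sel$selected])
  expect_true(all(counts >= pmin(2, table(sel$cluster))))
})

test_that("murcko scaffolds strip side chains and map acyclics to ''", {
  expect_identical(murcko_scaffold("Cc1ccccc1"), murcko_scaffold("c1ccccc1"))
  expect_identical(murcko_scaffold("CCCCCC"), "")
  expect_identical(murcko_scaffold("CCc1ccncc1"), murcko_scaffold("c1ccncc1"))
  # ring-plus-linker frameworks survive
  biphenyl <- murcko_scaffold("c1ccc(cc1)-c1ccccc1")
  expect_identical(murcko_scaffold("Cc1ccc(cc1)-c1ccccc1C"), biphenyl)
  expect_true(nzchar(biphenyl))
})

test_that("scaffold table counts match hand enumeration and conserve inputs", {
  train <- c("Cc1ccccc1", "CCc1ccccc1", "c1ccncc1", "CCCC")
  test <- c("c1ccccc1", "c1ccco1", "CCO")
  st <- scaffold_table(train, test)
  benz <- murcko_scaffold("c1ccccc1")
  tab <- st$table
  expect_equal(tab$train[tab$scaffold == benz], 2)
  expect_equal(tab$test[tab$scaffold == benz], 1)
  expect_equal(unname(st$summary["n_test_scaffolds"]), 2)
  expect_equal(unname(st$summary["n_shared"]), 1)
  expect_equal(unname(st$summary["n_absent_from_train"]), 1)
  expect_equal(unname(st$summary["n_acyclic_train"]), 1)
  expect_equal(unname(st$summary["n_acyclic_test"]), 1)
  # totals conserve molecule counts (ring + acyclic = parseable input)
  expect_equal(sum(tab$train) + unname(st$summary["n_acyclic_train"]),
               length(train))
  expect_equal(sum(tab$test) + unname(st$summary["n_acyclic_test"]),
               length(test))
})

test_that("disjoint train/test scaffolds give zero overlap", {
  st <- scaffold_table("c1ccncc1", "c1ccccc1")
  expect_equal(unname(st$summary["n_test_scaffolds"]), 1)
  expect_equal(unname(st$summary["n_shared"]), 0)
  expect_equal(unname(st$summary["n_absent_from_train"]), 1)
})

test_that("unparseable SMILES are excluded with a warning and reported", {
  expect_warning(st <- scaffold_table(c("c1ccccc1", "(((bad"), "CCO"),
                 "unparseable")
  expect_identical(st$excluded$train, "(((bad")
  expect_equal(sum(st$table$train), 1)
})
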