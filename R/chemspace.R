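#' Morgan fingerprints of a molecule set
#'
#' @param smiles Character vector of SMILES.
#' @param ids Molecule identifiers (default the SMILES themselves; must be
#'   unique).
#' @param radius Circular-environment radius (default 2).
#' @param n_bits Fingerprint length (default 2048).
#' @return A `fingerprint_set`: list with `ids`, `bits` (logical matrix,
#'   one row per molecule), `radius`, `n_bits`.
#' @export
morgan_fingerprints <- function(smiles, ids = smiles, radius = 2L,
                                n_bits = 2048L) {
  if (anyDuplicated(ids)) stop_invalid("ids must be unique")
  if (length(ids) != length(smiles))
    stop_invalid("ids and smiles must have equal length")
  bits <- t(vapply(smiles, function(s)
    morgan_fingerprint(s, radius = radius, n_bits = n_bits),
    logical(n_bits)))
  rownames(bits) <- ids
  fingerprint_set(ids, bits, radius = radius, n_bits = n_bits)
}

#' Fingerprint set container
#'
#' @param ids Unique molecule identifiers.
#' @param bits Logical (or 0/1) matrix, one row per molecule.
#' @param radius,n_bits Fingerprint parameters.
#' @return A `fingerprint_set`.
#' @export
fingerprint_set <- function(ids, bits, radius = 2L, n_bits = ncol(bits)) {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "logical"
  if (nrow(bits) != length(ids))
    stop_invalid("bits must have one row per id")
  if (ncol(bits) != n_bits)
    stop_invalid("bit matrix width disagrees with n_bits")
  if (anyDuplicated(ids)) stop_invalid("ids must be unique")
  structure(list(ids = as.character(ids), bits = bits,
                 radius = as.integer(radius), n_bits = as.integer(n_bits)),
            class = "fingerprint_set")
}

#' Tanimoto similarity of two bit vectors
#'
#' The Jaccard index `|a & b| / (a | b)|` of the on-bit sets. Between two
#' all-zero vectors the similarity is defined as 1 (identical empty
#' substructure sets); all-zero against nonzero gives 0.
#'
#' @param a,b Logical (or 0/1) vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @examples
#' tanimoto(c(1, 1, 0, 1), c(0, 1, 0, 1))
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop_invalid("bit vectors must have equal length (", length(a),
                 " vs ", length(b), ")")
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}

#' Maximum Tanimoto similarity of query molecules to a training set
#'
#' For each query molecule, the maximum Tanimoto similarity to any molecule
#' of the training set — the standard diagnostic for how close held-out
#' chemistry sits to the training chemical space — plus the fraction of
#' queries exceeding the 0.4 and 0.5 thresholds.
#'
#' @param query,train `fingerprint_set` objects with matching parameters.
#' @param thresholds Thresholds for the summary fractions (default
#'   `c(0.4, 0.5)`).
#' @return List with `max_similarity` (named per query), and
#'   `fraction_above` (named by threshold).
#' @export
max_similarity_to_train <- function(query, train, thresholds = c(0.4, 0.5)) {
  stopifnot(inherits(query, "fingerprint_set"),
            inherits(train, "fingerprint_set"))
  if (nrow(train$bits) == 0L) stop_invalid("training set is empty")
  if (query$n_bits != train$n_bits || query$radius != train$radius)
    stop_invalid("fingerprint parameters of query and train differ")
  Q <- query$bits * 1; Tr <- train$bits * 1
  inter <- Q %*% t(Tr) # |a & b|
  pq <- rowSums(Q); pt <- rowSums(Tr)
  un <- outer(pq, pt, `+`) - inter
  sim <- ifelse(un == 0, 1, inter / un)
  best <- apply(sim, 1L, max)
  names(best) <- query$ids
  frac <- vapply(thresholds, function(th) mean(best > th), 0)
  names(frac) <- paste0(">", thresholds)
  list(max_similarity = best, fraction_above = frac)
}

#' Cluster-coverage training-set selection
#'
#' k-means clustering of the fingerprint bit vectors (treated as real
#' vectors, Euclidean metric, seeded initialization), then at least
#' `per_cluster` molecules from every nonempty cluster: members nearest
#' their centroid first, ties broken by lower id. Scaled-up corpora use a
#' proportionally larger `k`; the selection is deterministic under `seed`.
#'
#' @param fps A `fingerprint_set`.
#' @param k Number of clusters (1..number of molecules). When duplicate
#'   fingerprints leave fewer distinct vectors than `k`, `k` is reduced to
#'   the number of distinct vectors.
#' @param seed RNG seed (default 0).
#' @param per_cluster Minimum picks per nonempty cluster (default 1).
#' @return List with `selected` (character ids), `cluster` (integer cluster
#'   label per molecule, named), and `k_used`.
#' @export
kmeans_select <- function(fps, k, seed = 0, per_cluster = 1L) {
  stopifnot(inherits(fps, "fingerprint_set"))
  n <- nrow(fps$bits)
  if (k < 1 || k > n)
    stop_invalid("k must be between 1 and the number of molecules (", n, ")")
  x <- fps$bits * 1
  ux <- unique(x)
  k_used <- min(as.integer(k), nrow(ux))
  if (k_used == n) {
    # singleton clusters: every molecule is its own center
    cl <- seq_len(n)
    centers <- x
  } else {
    km <- with_seed(seed, {
      cts <- ux[sample.int(nrow(ux), k_used), , drop = FALSE]
      stats::kmeans(x, centers = cts, iter.max = 100L)
    })
    cl <- km$cluster
    centers <- km$centers
  }
  names(cl) <- fps$ids
  selected <- character(0)
  for (g in sort(unique(cl))) {
    members <- which(cl == g)
    d <- sqrt(rowSums((x[members, , drop = FALSE] -
                         matrix(centers[g, ], nrow = length(members),
                                ncol = ncol(x), byrow = TRUE))^2))
    ord <- members[order(d, fps$ids[members])]
    selected <- c(selected, fps$ids[ord[seq_len(min(per_cluster, length(ord)))]])
  }
  list(selected = selected, cluster = cl, k_used = k_used)
}

#' Murcko scaffold table and split-overlap summary
#'
#' Assigns each molecule its Murcko scaffold (ring systems plus linkers; the
#' empty scaffold `""` for acyclic molecules, counted separately), tabulates
#' per-scaffold train/test counts, and summarizes the overlap: how many of
#' the distinct test scaffolds also occur in the training split. Unparseable
#' SMILES are excluded from the counts with a warning and reported.
#'
#' @param train_smiles,test_smiles Character vectors of SMILES.
#' @param top_m How many scaffolds to rank in the two orderings (default 40).
#' @return List with `table` (data frame: scaffold, total, train, test,
#'   ranked by total), `top_by_total`, `top_by_test` (head of the two
#'   orderings), `summary` (test scaffold counts: `n_test_scaffolds`,
#'   `n_shared`, `n_absent_from_train`, plus acyclic counts), and `excluded`
#'   (the SMILES that failed to parse, by split).
#' @export
scaffold_table <- function(train_smiles, test_smiles, top_m = 40L) {
  one_split <- function(smiles) {
    scaffolds <- character(length(smiles))
    bad <- logical(length(smiles))
    for (i in seq_along(smiles)) {
      scaffolds[i] <- tryCatch(murcko_scaffold(smiles[i]),
                               error = function(e) {
                                 warning("excluding unparseable SMILES: ",
                                         smiles[i], call. = FALSE)
                                 bad[i] <<- TRUE
                                 NA_character_
                               })
    }
    list(scaffolds = scaffolds[!bad], excluded = smiles[bad])
  }
  tr <- one_split(train_smiles)
  te <- one_split(test_smiles)
  ring_tr <- tr$scaffolds[tr$scaffolds != ""]
  ring_te <- te$scaffolds[te$scaffolds != ""]
  all_sc <- sort(unique(c(ring_tr, ring_te)))
  tab <- data.frame(
    scaffold = all_sc,
    train = as.integer(table(factor(ring_tr, levels = all_sc))),
    test = as.integer(table(factor(ring_te, levels = all_sc))))
  tab$total <- tab$train + tab$test
  by_total <- tab[order(-tab$total, tab$scaffold), ]
  by_test <- tab[order(-tab$test, -tab$total, tab$scaffold), ]
  rownames(by_total) <- rownames(by_test) <- NULL
  test_sc <- unique(ring_te)
  shared <- intersect(test_sc, unique(ring_tr))
  list(
    table = by_total,
    top_by_total = utils::head(by_total, top_m),
    top_by_test = utils::head(by_test, top_m),
    summary = c(n_test_scaffolds = length(test_sc),
                n_shared = length(shared),
                n_absent_from_train = length(test_sc) - length(shared),
                n_acyclic_train = sum(tr$scaffolds == ""),
                n_acyclic_test = sum(te$scaffolds == "")),
    excluded = list(train = tr$excluded, test = te$excluded)
  )
}
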