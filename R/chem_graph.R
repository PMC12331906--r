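# Molecular graphs from SMILES.
#
# Input SMILES are validated and canonicalized through Open Babel
# (ChemmineOB), then the canonical string is parsed into an explicit
# heavy-atom graph with aromatic flags and implicit hydrogen counts.
# Parsing the aromatic (lowercase) form directly - rather than a kekulized
# connection table - is what makes graph-automorphism equivalence classes
# come out right for aromatic rings: alternating single/double Kekule bonds
# would artificially split symmetry-equivalent positions (e.g. the two ortho
# carbons of toluene).

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.default_valences <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                          S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1,
                          Si = 4, H = 1)

#' Canonicalize a SMILES string via Open Babel
#'
#' @param smiles A single SMILES string.
#' @return The canonical SMILES.
#' @keywords internal
ob_canonical_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop_invalid("smiles must be a single nonempty string")
  out <- tryCatch(
    suppressWarnings(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n"))),
    error = function(e) "")
  out <- strsplit(trimws(out), "[ \t\n]")[[1]]
  if (length(out) == 0L || !nzchar(out[1]))
    stop_invalid("unparseable SMILES: ", smiles)
  out[1]
}

# tokenizer/parser for the canonical SMILES dialect Open Babel emits
parse_canonical_smiles <- function(s) {
  atoms <- list() # element, aromatic, charge, h_explicit (NA -> implicit)
  bonds <- list() # i, j, order (1,2,3), aromatic (logical)
  prev_stack <- integer(0)
  prev <- NA_integer_
  pending_bond <- NULL # NULL = default
  ring_open <- list()  # digit -> list(atom, bond)
  i <- 1L
  n <- nchar(s)
  add_atom <- function(element, aromatic, charge = 0L, h_explicit = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, aromatic = aromatic,
                                         charge = charge, h_explicit = h_explicit)
    length(atoms)
  }
  add_bond <- function(a, b, sym) {
    if (is.null(sym)) {
      arom <- atoms[[a]]$aromatic && atoms[[b]]$aromatic
      ord <- 1L
    } else if (sym == ":") {
      arom <- TRUE; ord <- 1L
    } else {
      arom <- FALSE
      ord <- switch(sym, "-" = 1L, "/" = 1L, "\\" = 1L, "=" = 2L, "#" = 3L,
                    stop_invalid("unsupported bond symbol: ", sym))
    }
    bonds[[length(bonds) + 1L]] <<- list(i = a, j = b, order = ord,
                                         aromatic = arom)
  }
  close_ring <- function(digit, cur) {
    key <- as.character(digit)
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      sym <- if (!is.null(pending_bond)) pending_bond else op$bond
      add_bond(op$atom, cur, sym)
      ring_open[[key]] <<- NULL
    } else {
      ring_open[[key]] <<- list(atom = cur, bond = pending_bond)
    }
    pending_bond <<- NULL
  }
  attach_atom <- function(idx) {
    if (!is.na(prev)) {
      add_bond(prev, idx, pending_bond)
    }
    pending_bond <<- NULL
    prev <<- idx
  }
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) stop_invalid("unclosed bracket atom in SMILES: ", s)
      body <- substr(s, i + 1L, i + j - 2L)
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Z][a-z]?|[bcnops]|as|se)(@{0,2})(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?$",
        body))[[1]]
      if (length(m) == 0L)
        stop_invalid("cannot parse bracket atom [", body, "] in SMILES: ", s)
      elem_raw <- m[3]
      aromatic <- elem_raw %in% c("b", "c", "n", "o", "p", "s", "as", "se")
      element <- if (aromatic) {
        paste0(toupper(substr(elem_raw, 1, 1)), substr(elem_raw, 2, 10))
      } else elem_raw
      hx <- m[5]
      h_explicit <- if (is.na(hx) || !nzchar(hx)) 0L
        else if (hx == "H") 1L else as.integer(substr(hx, 2, 10))
      chs <- m[6]
      charge <- if (is.na(chs) || !nzchar(chs)) 0L
        else if (chs %in% c("+", "-")) ifelse(chs == "+", 1L, -1L)
        else if (grepl("^[+]+$", chs)) nchar(chs)
        else if (grepl("^[-]+$", chs)) -nchar(chs)
        else as.integer(chs)
      idx <- add_atom(element, aromatic, charge, h_explicit)
      attach_atom(idx)
      i <- i + j
    } else if (grepl("^[A-Z]", ch)) {
      two <- substr(s, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        idx <- add_atom(two, FALSE)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        idx <- add_atom(ch, FALSE)
        i <- i + 1L
      } else {
        stop_invalid("element ", ch, " must be written in brackets: ", s)
      }
      attach_atom(idx)
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- add_atom(toupper(ch), TRUE)
      attach_atom(idx)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch
      i <- i + 1L
    } else if (ch == "(") {
      prev_stack <- c(prev_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(prev_stack) == 0L) stop_invalid("unbalanced ')' in SMILES: ", s)
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(ch, prev)
      i <- i + 1L
    } else if (ch == "%") {
      close_ring(substr(s, i + 1L, i + 2L), prev)
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending_bond <- NULL
      i <- i + 1L
    } else if (ch == "@") { # stray chirality marks outside brackets: skip
      i <- i + 1L
    } else {
      stop_invalid("unexpected character '", ch, "' in SMILES: ", s)
    }
  }
  if (length(Filter(Negate(is.null), ring_open)) > 0L)
    stop_invalid("unclosed ring bond in SMILES: ", s)
  na <- length(atoms)
  elem <- vapply(atoms, `[[`, "", "element")
  arom <- vapply(atoms, `[[`, NA, "aromatic")
  charge <- vapply(atoms, function(a) as.integer(a$charge), 0L)
  h_exp <- vapply(atoms, function(a) as.integer(a$h_explicit), NA_integer_)
  bi <- vapply(bonds, function(b) b$i, 0L)
  bj <- vapply(bonds, function(b) b$j, 0L)
  bo <- vapply(bonds, function(b) b$order, 0L)
  ba <- vapply(bonds, function(b) b$aromatic, NA)
  # implicit hydrogens
  nH <- integer(na)
  for (k in seq_len(na)) {
    if (!is.na(h_exp[k])) { nH[k] <- h_exp[k]; next }
    vv <- .default_valences[[elem[k]]]
    if (is.null(vv)) { nH[k] <- 0L; next }
    deg_edges <- which(bi == k | bj == k)
    if (arom[k]) {
      # lowercase atom: one valence is consumed by the delocalized pi system
      used <- length(deg_edges) + 1L
      nH[k] <- max(0L, vv[1] - used)
    } else {
      bondsum <- sum(bo[deg_edges])
      fit <- vv[vv >= bondsum]
      nH[k] <- if (length(fit)) fit[1] - bondsum else 0L
    }
  }
  list(n = na, element = elem, aromatic = arom, charge = charge, n_h = nH,
       bond_i = bi, bond_j = bj, bond_order = bo, bond_aromatic = ba)
}

#' Molecular graph of a SMILES string
#'
#' Validates and canonicalizes the SMILES through Open Babel, then parses it
#' into an explicit heavy-atom graph: elements, aromatic flags, formal
#' charges, implicit hydrogen counts and a bond table. Heavy atoms are
#' numbered in canonical SMILES order; hydrogens are implicit counts on their
#' parent atoms.
#'
#' @param smiles SMILES string.
#' @return An object of class `smiles_graph`.
#' @examples
#' g <- smiles_graph("CCO")
#' g$element
#' g$n_h
#' @export
smiles_graph <- function(smiles) {
  canon <- ob_canonical_smiles(smiles)
  g <- parse_canonical_smiles(canon)
  g$smiles_input <- smiles
  g$smiles_canonical <- canon
  class(g) <- "smiles_graph"
  g
}

#' @export
print.smiles_graph <- function(x, ...) {
  cat(sprintf("<smiles_graph> %s: %d heavy atoms, %d bonds, %d hydrogens\n",
              x$smiles_canonical, x$n, length(x$bond_i), sum(x$n_h)))
  invisible(x)
}

# adjacency list with bond labels ("a" for aromatic, else order)
graph_adjacency <- function(g) {
  adj <- vector("list", g$n)
  lab <- ifelse(g$bond_aromatic, "a", as.character(g$bond_order))
  for (e in seq_along(g$bond_i)) {
    i <- g$bond_i[e]; j <- g$bond_j[e]
    adj[[i]] <- rbind(adj[[i]], c(j, lab[e]))
    adj[[j]] <- rbind(adj[[j]], c(i, lab[e]))
  }
  adj
}

#' Graph-canonical equivalence classes of heavy atoms
#'
#' Partitions heavy atoms into equivalence classes by iterative neighborhood
#' refinement (Morgan-style): atoms start with an invariant built from
#' element, aromaticity, charge, degree and hydrogen count, and are
#' repeatedly re-ranked by the sorted multiset of (bond label, neighbor rank)
#' pairs until the partition stabilizes. Atoms in the same class are related
#' by a local graph symmetry; for the molecules this package targets the
#' stable partition coincides with the automorphism orbits.
#'
#' @param g A [smiles_graph()].
#' @return Integer vector of class labels (1-based, dense) per heavy atom.
#' @export
atom_equivalence_classes <- function(g) {
  stopifnot(inherits(g, "smiles_graph"))
  if (g$n == 0L) return(integer(0))
  adj <- graph_adjacency(g)
  deg <- vapply(adj, function(a) if (is.null(a)) 0L else nrow(a), 0L)
  key <- paste(g$element, g$aromatic, g$charge, deg, g$n_h, sep = "|")
  rank <- match(key, sort(unique(key)))
  repeat {
    key2 <- vapply(seq_len(g$n), function(i) {
      a <- adj[[i]]
      nb <- if (is.null(a)) character(0)
        else sort(paste0(a[, 2], ":", rank[as.integer(a[, 1])]))
      paste(rank[i], paste(nb, collapse = ","), sep = "#")
    }, "")
    rank2 <- match(key2, sort(unique(key2)))
    if (length(unique(rank2)) == length(unique(rank))) break
    rank <- rank2
  }
  # dense labels in order of first appearance
  match(rank, unique(rank))
}

#' Full atom order of a molecule
#'
#' The package convention for per-atom arrays (type lists, shift lists,
#' coordinates): heavy atoms first, in canonical SMILES order, then all
#' hydrogens, grouped by parent heavy atom in parent order.
#'
#' @param g A [smiles_graph()].
#' @return List with `elements` (full symbol vector), `n_heavy`, `n_total`,
#'   and `h_parent` (heavy-atom index of each appended hydrogen).
#' @export
atom_order <- function(g) {
  stopifnot(inherits(g, "smiles_graph"))
  h_parent <- rep(seq_len(g$n), g$n_h)
  list(elements = c(g$element, rep("H", length(h_parent))),
       n_heavy = g$n, n_total = g$n + length(h_parent),
       h_parent = h_parent)
}

#' Morgan-style circular fingerprint of one molecule
#'
#' Hashed circular substructure fingerprint on the heavy-atom graph: each
#' atom's environment up to the given radius is hashed into bit positions of
#' a fixed-length vector. Bit positions are deterministic but specific to
#' this implementation (toolkits differ in their hash functions); Tanimoto
#' comparisons are meaningful within one fingerprint set.
#'
#' @param g A [smiles_graph()] or SMILES string.
#' @param radius Neighborhood radius (default 2).
#' @param n_bits Fingerprint length (default 2048).
#' @return Logical vector of length `n_bits`.
#' @export
morgan_fingerprint <- function(g, radius = 2L, n_bits = 2048L) {
  if (is.character(g)) g <- smiles_graph(g)
  stopifnot(inherits(g, "smiles_graph"))
  P <- 2147483647
  hmix <- function(a, b) ((a %% P) * 1000003 + b) %% P
  adj <- graph_adjacency(g)
  deg <- vapply(adj, function(a) if (is.null(a)) 0L else nrow(a), 0L)
  elem_code <- match(g$element, c(.organic_subset, "Si", "H", "Se", "As"))
  elem_code[is.na(elem_code)] <- 99L
  ids <- mapply(function(e, d, h, c2, ar) {
    hmix(hmix(hmix(hmix(e, d), h), c2 + 10), as.integer(ar))
  }, elem_code, deg, g$n_h, g$charge, g$aromatic)
  bond_code <- ifelse(g$bond_aromatic, 4, g$bond_order)
  all_ids <- ids
  if (radius >= 1) for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(g$n), function(i) {
      a <- adj[[i]]
      h <- hmix(r, ids[i])
      if (!is.null(a)) {
        nb <- sort(vapply(seq_len(nrow(a)), function(k) {
          e <- as.integer(a[k, 1])
          bc <- if (a[k, 2] == "a") 4 else as.numeric(a[k, 2])
          hmix(bc, ids[e])
        }, 0))
        for (v in nb) h <- hmix(h, v)
      }
      h
    }, 0)
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  bits <- logical(n_bits)
  bits[(all_ids %% n_bits) + 1] <- TRUE
  bits
}

#' Murcko scaffold of a molecule
#'
#' Ring systems plus the linkers connecting them, with all side chains
#' stripped: terminal heavy atoms are deleted iteratively until none remain.
#' Acyclic molecules therefore map to the empty scaffold `""`. Severed
#' attachment points become hydrogens. The scaffold is returned as a
#' canonical SMILES so identical frameworks from different molecules compare
#' equal (benzene and toluene both give `c1ccccc1`).
#'
#' @param smiles SMILES string (or a [smiles_graph()]).
#' @return Canonical scaffold SMILES, or `""` for acyclic molecules.
#' @export
murcko_scaffold <- function(smiles) {
  g <- if (inherits(smiles, "smiles_graph")) smiles else smiles_graph(smiles)
  keep <- rep(TRUE, g$n)
  repeat {
    deg <- integer(g$n)
    for (e in seq_along(g$bond_i)) {
      if (keep[g$bond_i[e]] && keep[g$bond_j[e]]) {
        deg[g$bond_i[e]] <- deg[g$bond_i[e]] + 1L
        deg[g$bond_j[e]] <- deg[g$bond_j[e]] + 1L
      }
    }
    drop <- keep & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  if (!any(keep)) return("")
  sub <- write_subgraph_smiles(g, which(keep))
  ob_canonical_smiles(sub)
}

# write a (possibly non-canonical) SMILES for the induced subgraph on `atoms`;
# severed substituents turn into implicit hydrogens on re-parsing
write_subgraph_smiles <- function(g, atoms) {
  sel <- sort(atoms)
  remap <- match(seq_len(g$n), sel) # old -> new or NA
  keep_e <- which(!is.na(remap[g$bond_i]) & !is.na(remap[g$bond_j]))
  bi <- remap[g$bond_i[keep_e]]; bj <- remap[g$bond_j[keep_e]]
  bo <- g$bond_order[keep_e]; ba <- g$bond_aromatic[keep_e]
  n <- length(sel)
  elem <- g$element[sel]; arom <- g$aromatic[sel]; charge <- g$charge[sel]
  full_deg <- integer(g$n)
  for (e in seq_along(g$bond_i)) {
    full_deg[g$bond_i[e]] <- full_deg[g$bond_i[e]] + 1L
    full_deg[g$bond_j[e]] <- full_deg[g$bond_j[e]] + 1L
  }
  sub_deg <- integer(n)
  for (e in seq_along(bi)) {
    sub_deg[bi[e]] <- sub_deg[bi[e]] + 1L
    sub_deg[bj[e]] <- sub_deg[bj[e]] + 1L
  }
  want_h <- g$n_h[sel] + (full_deg[sel] - sub_deg)
  adj <- vector("list", n)
  for (e in seq_along(bi)) {
    adj[[bi[e]]] <- rbind(adj[[bi[e]]], c(bj[e], e))
    adj[[bj[e]]] <- rbind(adj[[bj[e]]], c(bi[e], e))
  }
  bond_sym <- function(e) {
    if (ba[e]) "" else switch(bo[e], "", "=", "#")
  }
  atom_tok <- function(i) {
    el <- elem[i]
    if (charge[i] != 0) {
      cs <- if (charge[i] > 0) paste(rep("+", charge[i]), collapse = "")
            else paste(rep("-", -charge[i]), collapse = "")
      hs <- if (want_h[i] > 0) paste0("H", if (want_h[i] > 1) want_h[i] else "") else ""
      paste0("[", if (arom[i]) tolower(el) else el, hs, cs, "]")
    } else if (arom[i]) {
      if (el == "N" && want_h[i] > 0) "[nH]" else tolower(el)
    } else {
      el
    }
  }
  visited <- logical(n)
  used_edge <- logical(length(bi))
  ring_num <- 0L
  ring_label <- integer(length(bi)) # edge -> ring closure digit
  out <- character(0)
  emit <- function(txt) out <<- c(out, txt)
  # pre-pass: mark ring-closure edges via DFS spanning tree
  dfs_mark <- function(start) {
    stack <- list(c(start, 0L))
    seen <- logical(n); seen[start] <- TRUE
    parent_edge <- integer(n)
    order <- integer(0)
    while (length(stack)) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      i <- top[1]
      order <- c(order, i)
      a <- adj[[i]]
      if (!is.null(a)) for (k in seq_len(nrow(a))) {
        j <- as.integer(a[k, 1]); e <- as.integer(a[k, 2])
        if (!seen[j]) {
          seen[j] <- TRUE
          used_edge[e] <<- TRUE
          stack[[length(stack) + 1L]] <- c(j, e)
        } else if (!used_edge[e] && ring_label[e] == 0L) {
          ring_num <<- ring_num + 1L
          ring_label[e] <<- ring_num
        }
      }
    }
    seen
  }
  write_atom <- function(i, from_edge) {
    visited[i] <<- TRUE
    if (from_edge > 0L) emit(bond_sym(from_edge))
    emit(atom_tok(i))
    a <- adj[[i]]
    if (is.null(a)) return(invisible())
    # ring closure digits at this atom
    for (k in seq_len(nrow(a))) {
      e <- as.integer(a[k, 2])
      if (ring_label[e] > 0L) {
        emit(paste0(bond_sym(e),
                    if (ring_label[e] > 9L) paste0("%", ring_label[e])
                    else ring_label[e]))
        # bond symbol printed at most once per closure
        ring_label[e] <<- -ring_label[e]
      } else if (ring_label[e] < 0L) {
        lab <- -ring_label[e]
        emit(if (lab > 9L) paste0("%", lab) else as.character(lab))
        ring_label[e] <<- 0L
      }
    }
    children <- list()
    for (k in seq_len(nrow(a))) {
      j <- as.integer(a[k, 1]); e <- as.integer(a[k, 2])
      if (!visited[j] && used_edge[e]) children[[length(children) + 1L]] <- c(j, e)
    }
    if (length(children)) {
      for (k in seq_along(children)) {
        if (k < length(children)) emit("(")
        write_atom(children[[k]][1], children[[k]][2])
        if (k < length(children)) emit(")")
      }
    }
    invisible()
  }
  first <- TRUE
  for (start in seq_len(n)) {
    if (visited[start]) next
    dfs_mark(start)
    if (!first) emit(".")
    write_atom(start, 0L)
    first <- FALSE
  }
  paste(out, collapse = "")
}
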