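# Canonical atom ranking by iterative invariant refinement (Morgan-style
# Weisfeiler-Lehman colouring) with deterministic tie-breaking. Two SMILES
# writings of the same molecule (in the same aromatic form) refine to the
# same ranks up to automorphism, so the writer below emits the same string.

.dense_rank <- function(x) match(x, sort(unique(x)))

.mol_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a[k]; b <- mol$bonds$b[k]; o <- mol$bonds$order[k]
      adj[[a]] <- rbind(adj[[a]], c(b, o))
      adj[[b]] <- rbind(adj[[b]], c(a, o))
    }
  }
  adj
}

.refine_ranks <- function(ranks, adj) {
  n <- length(ranks)
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      nbsig <- if (is.null(nb)) "" else
        paste(sort(sprintf("%03.1f:%06d", nb[, 2], ranks[nb[, 1]])),
              collapse = ",")
      sprintf("%06d|%s", ranks[i], nbsig)
    }, "")
    new <- .dense_rank(sig)
    if (max(new) == max(ranks) && all(.dense_rank(ranks) == new)) break
    ranks <- new
  }
  ranks
}

.canonical_ranks <- function(mol) {
  atoms <- mol$atoms
  adj <- .mol_adjacency(mol)
  n <- nrow(atoms)
  degree <- vapply(adj, function(x) if (is.null(x)) 0L else nrow(x), 0L)
  init <- sprintf("%s|%d|%d|%d|%d", atoms$element, as.integer(atoms$aromatic),
                  atoms$charge, atoms$hcount, degree)
  ranks <- .refine_ranks(.dense_rank(init), adj)
  # tie-break: split the lowest still-tied class and re-refine; ties that
  # survive refinement are (in practice) automorphic, so the choice of member
  # does not change the emitted string
  while (max(ranks) < n) {
    tab <- table(ranks)
    tied <- as.integer(names(tab)[tab > 1L])
    cls <- min(tied)
    member <- which(ranks == cls)[1L]
    ranks <- ranks * 2L
    ranks[member] <- ranks[member] - 1L
    ranks <- .refine_ranks(.dense_rank(ranks), adj)
  }
  ranks
}

.atom_token <- function(mol, i, adj) {
  at <- mol$atoms[i, ]
  bsum <- if (is.null(adj[[i]])) 0 else sum(adj[[i]][, 2])
  sym <- if (at$aromatic) tolower(at$element) else at$element
  plain_ok <- at$element %in% .ORGANIC_SUBSET && at$charge == 0L &&
    .implicit_hcount(at$element, at$aromatic, bsum) == at$hcount
  if (plain_ok) return(sym)
  h <- if (at$hcount == 0L) "" else if (at$hcount == 1L) "H"
    else paste0("H", at$hcount)
  ch <- if (at$charge == 0L) ""
    else if (at$charge == 1L) "+"
    else if (at$charge == -1L) "-"
    else if (at$charge > 0L) paste0("+", at$charge)
    else paste0("-", abs(at$charge))
  paste0("[", sym, h, ch, "]")
}

.bond_token <- function(order, arom_a, arom_b) {
  if (order == 1) { if (arom_a && arom_b) "-" else "" }
  else if (order == 1.5) { if (arom_a && arom_b) "" else ":" }
  else if (order == 2) "="
  else if (order == 3) "#"
  else "$"
}

.ring_digit <- function(d) if (d <= 9L) as.character(d) else sprintf("%%%02d", d)

# Write one SMILES string for mol, visiting atoms in increasing `ranks`
# order. With canonical ranks this is the canonical writing; with random
# ranks it is a valid alternative writing of the same molecule.
.write_smiles <- function(mol, ranks) {
  n <- nrow(mol$atoms)
  adj <- .mol_adjacency(mol)
  arom <- mol$atoms$aromatic
  visited <- rep(FALSE, n)

  # classify edges into tree / ring by a rank-ordered DFS
  ring_bonds <- list() # each: c(a, b, order)
  children <- vector("list", n)
  edge_used <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  comp_roots <- integer(0)
  order_left <- order(ranks)
  for (root in order_left) {
    if (visited[root]) next
    comp_roots <- c(comp_roots, root)
    stack <- list(c(root, NA_integer_))
    visited[root] <- TRUE
    # recursive DFS via explicit recursion for child ordering
    dfs <- function(i) {
      nb <- adj[[i]]
      if (is.null(nb)) return(invisible())
      ord <- order(ranks[nb[, 1]])
      for (k in ord) {
        j <- nb[k, 1]; o <- nb[k, 2]
        if (!is.null(edge_used[[ekey(i, j)]])) next
        if (visited[j]) {
          edge_used[[ekey(i, j)]] <- TRUE
          ring_bonds[[length(ring_bonds) + 1L]] <<- c(i, j, o)
        } else {
          edge_used[[ekey(i, j)]] <- TRUE
          visited[j] <<- TRUE
          children[[i]] <<- c(children[[i]], j)
          dfs(j)
        }
      }
    }
    dfs(root)
  }

  # ring digit bookkeeping: digits are allocated in atom-writing order
  ring_at <- vector("list", n) # atom -> list of c(other, order)
  for (rb in ring_bonds) {
    ring_at[[rb[1]]] <- c(ring_at[[rb[1]]], list(c(rb[2], rb[3])))
    ring_at[[rb[2]]] <- c(ring_at[[rb[2]]], list(c(rb[1], rb[3])))
  }
  open_digit <- new.env(parent = emptyenv()) # ekey -> digit
  digit_free <- rep(TRUE, 99L)

  write_atom <- function(i, parent, bond_order) {
    btok <- if (is.na(parent)) "" else
      .bond_token(bond_order, arom[parent], arom[i])
    out <- paste0(btok, .atom_token(mol, i, adj))
    for (rb in ring_at[[i]]) {
      j <- rb[1]; o <- rb[2]
      key <- ekey(i, j)
      if (is.null(open_digit[[key]])) {
        d <- which(digit_free)[1L]
        digit_free[d] <<- FALSE
        open_digit[[key]] <- d
        out <- paste0(out, .bond_token(o, arom[i], arom[j]), .ring_digit(d))
      } else {
        d <- open_digit[[key]]
        digit_free[d] <<- TRUE
        out <- paste0(out, .ring_digit(d))
      }
    }
    ch <- children[[i]]
    if (!is.null(ch) && length(ch)) {
      orders <- vapply(ch, function(j) {
        nb <- adj[[i]]
        nb[nb[, 1] == j, 2][1]
      }, 0)
      for (k in seq_along(ch)) {
        part <- write_atom(ch[k], i, orders[k])
        out <- if (k < length(ch)) paste0(out, "(", part, ")")
          else paste0(out, part)
      }
    }
    out
  }

  paste(vapply(comp_roots, function(r) write_atom(r, NA_integer_, 0), ""),
        collapse = ".")
}

.key_cache <- new.env(parent = emptyenv())

#' Canonical SMILES of a molecule
#'
#' Deterministic canonical writing: identical molecules written as different
#' SMILES strings (same aromatic form) map to the same canonical string,
#' which the corpus module uses as the structure key for de-duplication.
#'
#' @param smiles a single SMILES string.
#' @return the canonical SMILES string.
#' @seealso [canonical_key()] for the vectorized, cached variant.
#' @examples
#' smiles_canonical("OCC") == smiles_canonical("CCO")
#' @export
smiles_canonical <- function(smiles) {
  mol <- smiles_parse(smiles)
  .write_smiles(mol, .canonical_ranks(mol))
}

#' Canonical structure keys for a vector of SMILES
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical keys (one per input).
#' @details Unparseable input raises an error of class
#'   `withdrawr_structure_error` carrying the offending string.
#' @export
canonical_key <- function(smiles) {
  vapply(smiles, function(s) {
    hit <- .key_cache[[s]]
    if (!is.null(hit)) return(hit)
    key <- tryCatch(smiles_canonical(s), error = function(e) {
      stop(structure(class = c("withdrawr_structure_error", "error",
                               "condition"),
                     list(message = sprintf("unparseable SMILES '%s': %s",
                                            s, conditionMessage(e)),
                          call = sys.call(-1), smiles = s)))
    })
    .key_cache[[s]] <- key
    key
  }, "", USE.NAMES = FALSE)
}

#' Re-write a SMILES string in a random equivalent form
#'
#' Produces an alternative valid writing of the same molecule by randomising
#' the atom visiting order (uses the R random number generator). Mainly a
#' test utility for exercising canonicalization.
#'
#' @param smiles a single SMILES string.
#' @return an equivalent SMILES string.
#' @export
smiles_rewrite <- function(smiles) {
  mol <- smiles_parse(smiles)
  .write_smiles(mol, sample(nrow(mol$atoms)))
}
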