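# Subgraph monomorphism (VF2-flavoured backtracking) between small molecular
# graphs. Atom compatibility = same element, aromaticity and formal charge;
# bond compatibility = same order (aromatic 1.5 matches aromatic only).
# Hydrogen counts are ignored, i.e. ordinary substructure semantics.

.match_order <- function(pat_adj, n) {
  # visit pattern atoms so that each (after the first) touches an earlier one
  ord <- 1L
  seen <- rep(FALSE, n); seen[1L] <- TRUE
  while (length(ord) < n) {
    nxt <- NA_integer_
    for (i in ord) {
      nb <- pat_adj[[i]]
      if (is.null(nb)) next
      cand <- nb[!seen[nb[, 1]], 1]
      if (length(cand)) { nxt <- cand[1]; break }
    }
    if (is.na(nxt)) nxt <- which(!seen)[1L] # disconnected pattern component
    seen[nxt] <- TRUE
    ord <- c(ord, nxt)
  }
  ord
}

#' Test whether a molecule contains a substructure
#'
#' @param smiles SMILES of the target molecule (character vector, vectorized).
#' @param pattern SMILES of the query fragment (single string). The fragment
#'   is matched as written: aromatic atoms match aromatic atoms, charges must
#'   agree, extra bonds in the target are allowed (monomorphism).
#' @return logical vector, one flag per target.
#' @examples
#' smiles_has_substructure("COc1cc(C=O)ccc1O", "c1ccccc1")
#' @export
smiles_has_substructure <- function(smiles, pattern) {
  pat <- smiles_parse(pattern)
  vapply(smiles, function(s) {
    .subgraph_match(smiles_parse(s), pat)
  }, FALSE, USE.NAMES = FALSE)
}

.subgraph_match <- function(mol, pat) {
  np <- nrow(pat$atoms); nt <- nrow(mol$atoms)
  if (np > nt) return(FALSE)
  pat_adj <- .mol_adjacency(pat)
  mol_adj <- .mol_adjacency(mol)
  pa <- pat$atoms; ta <- mol$atoms
  compat <- function(pi, ti) {
    pa$element[pi] == ta$element[ti] &&
      pa$aromatic[pi] == ta$aromatic[ti] &&
      pa$charge[pi] == ta$charge[ti]
  }
  ord <- .match_order(pat_adj, np)
  assign_map <- rep(NA_integer_, np)
  used <- rep(FALSE, nt)

  try_extend <- function(step) {
    if (step > np) return(TRUE)
    pi <- ord[step]
    # candidate targets: all compatible unused atoms; restrict via an
    # already-mapped neighbour when one exists
    nb <- pat_adj[[pi]]
    anchor <- NULL
    if (!is.null(nb)) {
      mapped <- nb[!is.na(assign_map[nb[, 1]]), , drop = FALSE]
      if (nrow(mapped)) anchor <- mapped
    }
    cands <- if (!is.null(anchor)) {
      tn <- mol_adj[[assign_map[anchor[1, 1]]]]
      if (is.null(tn)) integer(0)
      else tn[tn[, 2] == anchor[1, 2], 1]
    } else {
      seq_len(nt)
    }
    for (ti in cands) {
      if (used[ti] || !compat(pi, ti)) next
      # all mapped pattern neighbours must be connected with matching order
      ok <- TRUE
      if (!is.null(nb)) {
        for (k in seq_len(nrow(nb))) {
          pj <- nb[k, 1]
          if (is.na(assign_map[pj])) next
          tj <- assign_map[pj]
          tnb <- mol_adj[[ti]]
          hit <- !is.null(tnb) && any(tnb[, 1] == tj & tnb[, 2] == nb[k, 2])
          if (!hit) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      assign_map[pi] <<- ti; used[ti] <<- TRUE
      if (try_extend(step + 1L)) return(TRUE)
      assign_map[pi] <<- NA_integer_; used[ti] <<- FALSE
    }
    FALSE
  }
  try_extend(1L)
}
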