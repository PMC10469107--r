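# Hashed circular substructure fingerprints (ECFP-style): each atom's
# environment at radius 0..radius is hashed to a bit position. Used by the
# boosted-stumps baseline classifier.

.str_hash <- function(s) {
  h <- 7
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  h
}

#' Circular substructure fingerprint of a molecule
#'
#' @param smiles character vector of SMILES.
#' @param nbits fingerprint length (default 512).
#' @param radius maximum neighbourhood radius (default 2, ECFP4-like).
#' @return a 0/1 integer matrix with one row per molecule and `nbits` columns.
#' @export
morgan_fingerprint <- function(smiles, nbits = 512L, radius = 2L) {
  stopifnot(nbits >= 8L, radius >= 0L)
  out <- matrix(0L, nrow = length(smiles), ncol = nbits)
  for (m in seq_along(smiles)) {
    mol <- smiles_parse(smiles[m])
    adj <- .mol_adjacency(mol)
    at <- mol$atoms
    degree <- vapply(adj, function(x) if (is.null(x)) 0L else nrow(x), 0L)
    inv <- sprintf("%s|%d|%d|%d|%d", at$element, as.integer(at$aromatic),
                   at$charge, at$hcount, degree)
    bits <- integer(0)
    for (r in 0:radius) {
      bits <- c(bits, vapply(inv, .str_hash, 0, USE.NAMES = FALSE) %% nbits + 1)
      if (r < radius) {
        inv <- vapply(seq_along(inv), function(i) {
          nb <- adj[[i]]
          nbsig <- if (is.null(nb)) "" else
            paste(sort(sprintf("%s~%s", nb[, 2], inv[nb[, 1]])), collapse = ";")
          paste0(inv[i], ">", nbsig)
        }, "")
      }
    }
    out[m, unique(bits)] <- 1L
  }
  out
}
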