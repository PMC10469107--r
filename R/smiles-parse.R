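# Organic-subset elements that may be written without brackets, and the
# valences used to infer implicit hydrogen counts. N/P/S use the smallest
# standard valence consistent with the explicit bonds.
.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.VALENCES <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L
)

.SMILES_TOKEN_RE <- paste0(
  "(\\[[^]]+\\])|Cl|Br|[BCNOPSFI]|[bcnops]|",
  "%[0-9]{2}|[0-9]|[().]|[-=#$:/\\\\]"
)

#' Split a SMILES string into lexical tokens
#'
#' Atom-level tokenization: bracket atoms, two-letter halogens, organic-subset
#' atoms (aromatic lowercase included), two-digit ring closures (`%nn`),
#' single-digit ring closures, branch parentheses, the dot separator and bond
#' symbols each become one token. Characters not matching any token class are
#' returned as single-character tokens (the model tokenizer maps them to the
#' unknown id; the parser rejects them).
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens.
#' @examples
#' smiles_tokens("c1ccccc1Cl")
#' @export
smiles_tokens <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stop("empty SMILES string")
  out <- character(0)
  rest <- smiles
  while (nzchar(rest)) {
    m <- regexpr(.SMILES_TOKEN_RE, rest)
    if (m == 1L) {
      len <- attr(m, "match.length")
      out <- c(out, substr(rest, 1L, len))
      rest <- substr(rest, len + 1L, nchar(rest))
    } else {
      out <- c(out, substr(rest, 1L, 1L))
      rest <- substr(rest, 2L, nchar(rest))
    }
  }
  out
}

.parse_bracket_atom <- function(tok) {
  body <- substr(tok, 2L, nchar(tok) - 1L)
  m <- regexec(
    "^([0-9]+)?([A-Z][a-z]?|as|se|[bcnops]|\\*)(@@|@)?(H[0-9]*)?(\\+[0-9]*|-[0-9]*|\\++|-+)?(:[0-9]+)?$",
    body
  )
  parts <- regmatches(body, m)[[1]]
  if (length(parts) == 0L) {
    stop(sprintf("cannot parse bracket atom '%s'", tok))
  }
  sym <- parts[3]
  aromatic <- sym == tolower(sym) && sym != "*"
  element <- if (aromatic) {
    paste0(toupper(substr(sym, 1L, 1L)), substr(sym, 2L, nchar(sym)))
  } else {
    sym
  }
  hpart <- parts[5]
  hcount <- if (!nzchar(hpart)) 0L
    else if (hpart == "H") 1L
    else as.integer(substr(hpart, 2L, nchar(hpart)))
  cpart <- parts[6]
  charge <- 0L
  if (nzchar(cpart)) {
    sign <- if (substr(cpart, 1L, 1L) == "+") 1L else -1L
    digits <- gsub("[+-]", "", cpart)
    charge <- if (nzchar(digits)) sign * as.integer(digits)
      else sign * nchar(cpart)
  }
  list(element = element, aromatic = aromatic, charge = charge,
       hcount = hcount, bracket = TRUE)
}

.implicit_hcount <- function(element, aromatic, bond_order_sum) {
  if (aromatic) {
    # Daylight convention: unbracketed aromatic N/O/S/P carry no hydrogens
    # (pyrrole-type NH must be written [nH]); aromatic C/B fill to valence
    # with the aromatic bond counted as 1.5.
    if (element == "C") return(max(0L, 4L - as.integer(ceiling(bond_order_sum))))
    if (element == "B") return(max(0L, 3L - as.integer(ceiling(bond_order_sum))))
    return(0L)
  }
  val <- .VALENCES[[element]]
  if (is.null(val)) return(0L)
  need <- as.integer(ceiling(bond_order_sum))
  ok <- val[val >= need]
  if (length(ok) == 0L) return(0L)
  ok[1L] - need
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset, bracket atoms (isotope ignored, charge and
#' explicit hydrogen counts kept, stereo marks dropped), branches, single /
#' double / triple / aromatic bonds, directional bonds (read as single), ring
#' closures including `%nn`, and dot-separated components. Aromaticity is
#' taken as written (lowercase atoms); no aromaticity perception or
#' kekulization is performed, so a molecule must be compared in a consistent
#' aromatic form.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `withdrawr_mol`: a list with `atoms`
#'   (data.frame: element, aromatic, charge, hcount, bracket) and `bonds`
#'   (data.frame: a, b, order with aromatic bonds coded 1.5).
#' @examples
#' mol <- smiles_parse("COc1cc(C=O)ccc1O")
#' nrow(mol$atoms)
#' @export
smiles_parse <- function(smiles) {
  toks <- smiles_tokens(smiles)
  atoms <- list()
  bonds <- list()
  prev <- NA_integer_
  pending_bond <- NA_character_
  stack <- integer(0)
  ring_open <- list() # digit -> list(atom, bond)

  add_atom <- function(a) {
    atoms[[length(atoms) + 1L]] <<- a
    length(atoms)
  }
  bond_order <- function(sym, i, j) {
    if (!is.na(sym)) {
      return(switch(sym,
        "-" = 1, "/" = 1, "\\" = 1, "=" = 2, "#" = 3, "$" = 4, ":" = 1.5,
        stop(sprintf("unknown bond symbol '%s'", sym))
      ))
    }
    if (atoms[[i]]$aromatic && atoms[[j]]$aromatic) 1.5 else 1
  }
  add_bond <- function(i, j, sym) {
    bonds[[length(bonds) + 1L]] <<- c(i, j, bond_order(sym, i, j))
  }

  for (tok in toks) {
    first <- substr(tok, 1L, 1L)
    if (first == "[") {
      idx <- add_atom(.parse_bracket_atom(tok))
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      pending_bond <- NA_character_
      prev <- idx
    } else if (tok %in% .ORGANIC_SUBSET || tok %in% c("b", "c", "n", "o", "p", "s")) {
      aromatic <- tok %in% c("b", "c", "n", "o", "p", "s")
      element <- if (aromatic) toupper(tok) else tok
      idx <- add_atom(list(element = element, aromatic = aromatic,
                           charge = 0L, hcount = NA_integer_, bracket = FALSE))
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      pending_bond <- NA_character_
      prev <- idx
    } else if (grepl("^%?[0-9]", tok)) {
      digit <- sub("^%", "", tok)
      if (is.na(prev)) stop("ring closure digit before any atom")
      if (!is.null(ring_open[[digit]])) {
        op <- ring_open[[digit]]
        sym <- if (!is.na(pending_bond)) pending_bond else op$bond
        add_bond(op$atom, prev, if (is.na(sym)) NA_character_ else sym)
        ring_open[[digit]] <- NULL
      } else {
        ring_open[[digit]] <- list(atom = prev, bond = pending_bond)
      }
      pending_bond <- NA_character_
    } else if (tok == "(") {
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in SMILES")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok == ".") {
      prev <- NA_integer_
      pending_bond <- NA_character_
    } else if (tok %in% c("-", "=", "#", "$", ":", "/", "\\")) {
      pending_bond <- tok
    } else {
      stop(sprintf("unparseable SMILES '%s': unexpected token '%s'",
                   smiles, tok))
    }
  }
  if (length(stack) > 0L) stop("unbalanced '(' in SMILES")
  if (length(ring_open) > 0L) {
    stop(sprintf("unclosed ring bond(s) in SMILES '%s'", smiles))
  }
  if (length(atoms) == 0L) stop(sprintf("no atoms in SMILES '%s'", smiles))

  bond_df <- if (length(bonds)) {
    m <- do.call(rbind, bonds)
    data.frame(a = as.integer(m[, 1]), b = as.integer(m[, 2]), order = m[, 3])
  } else {
    data.frame(a = integer(0), b = integer(0), order = numeric(0))
  }
  atom_df <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    charge = vapply(atoms, function(a) as.integer(a$charge), 0L),
    hcount = vapply(atoms, function(a) as.integer(a$hcount), NA_integer_),
    bracket = vapply(atoms, `[[`, FALSE, "bracket"),
    stringsAsFactors = FALSE
  )
  # fill implicit hydrogens for unbracketed atoms
  for (i in seq_len(nrow(atom_df))) {
    if (is.na(atom_df$hcount[i])) {
      bsum <- sum(bond_df$order[bond_df$a == i | bond_df$b == i])
      atom_df$hcount[i] <- .implicit_hcount(atom_df$element[i],
                                            atom_df$aromatic[i], bsum)
    }
  }
  structure(list(atoms = atom_df, bonds = bond_df, smiles = smiles),
            class = "withdrawr_mol")
}

#' Distinct chemical elements of a molecule
#'
#' Implicit and explicit hydrogens count as the element H, so e.g. methane
#' written `C` has two elements (C, H) while `[Fe]` has one.
#'
#' @param smiles a SMILES string.
#' @return character vector of distinct element symbols.
#' @export
smiles_elements <- function(smiles) {
  mol <- smiles_parse(smiles)
  els <- unique(mol$atoms$element)
  if (any(mol$atoms$hcount > 0L)) els <- unique(c(els, "H"))
  sort(els)
}

#' @export
print.withdrawr_mol <- function(x, ...) {
  cat(sprintf("<withdrawr_mol> %d atoms, %d bonds: %s\n",
              nrow(x$atoms), nrow(x$bonds), x$smiles))
  invisible(x)
}
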