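# Atom-level SMILES tokenizer for the transformer classifier. Multi-letter
# elements (Cl, Br), bracket atoms and %nn ring closures are single tokens.
# Integer ids are contiguous from 0: pad = 0, unknown = 1, the classification
# summary token = 2, corpus tokens from 3.

PAD_ID <- 0L
UNK_ID <- 1L
CLS_ID <- 2L

#' Build a tokenizer specification from a SMILES corpus
#'
#' @param smiles character vector of training SMILES.
#' @param max_len number of sequence positions, summary token included
#'   (default 128).
#' @return object of class `withdrawr_tokenizer`: list with `vocab` (named
#'   integer vector token -> id), `max_len`.
#' @export
build_tokenizer <- function(smiles, max_len = 128L) {
  stopifnot(max_len >= 2L)
  toks <- sort(unique(unlist(lapply(smiles, smiles_tokens))))
  vocab <- c("<pad>" = PAD_ID, "<unk>" = UNK_ID, "<cls>" = CLS_ID,
             stats::setNames(seq_along(toks) + 2L, toks))
  structure(list(vocab = vocab, max_len = as.integer(max_len)),
            class = "withdrawr_tokenizer")
}

#' @export
print.withdrawr_tokenizer <- function(x, ...) {
  cat(sprintf("<withdrawr_tokenizer> %d tokens, max_len %d\n",
              length(x$vocab), x$max_len))
  invisible(x)
}

#' Encode a SMILES string as a fixed-length id sequence
#'
#' The summary token is prepended, the sequence is truncated or padded to
#' `max_len`, and tokens outside the vocabulary map to the unknown id.
#'
#' @param smiles a single SMILES string (non-empty).
#' @param tokenizer a `withdrawr_tokenizer`.
#' @return integer vector of length `tokenizer$max_len`.
#' @export
tokenize_smiles <- function(smiles, tokenizer) {
  if (!nzchar(smiles)) stop("cannot tokenize an empty SMILES string")
  toks <- smiles_tokens(smiles)
  ids <- unname(tokenizer$vocab[toks])
  ids[is.na(ids)] <- UNK_ID
  ids <- c(CLS_ID, ids)
  n <- tokenizer$max_len
  if (length(ids) > n) ids <- ids[seq_len(n)]
  c(ids, rep(PAD_ID, n - length(ids)))
}

#' Decode an id sequence back to tokens
#'
#' @param ids integer id vector.
#' @param tokenizer a `withdrawr_tokenizer`.
#' @return character vector of tokens (pad positions dropped).
#' @export
detokenize <- function(ids, tokenizer) {
  rev_vocab <- stats::setNames(names(tokenizer$vocab),
                               as.character(tokenizer$vocab))
  out <- unname(rev_vocab[as.character(ids)])
  out[ids != PAD_ID]
}

# matrix of ids (n x max_len) for a batch of SMILES
.tokenize_batch <- function(smiles, tokenizer) {
  t(vapply(smiles, tokenize_smiles, integer(tokenizer$max_len),
           tokenizer = tokenizer, USE.NAMES = FALSE))
}
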