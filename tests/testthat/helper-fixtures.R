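# Shared builders for tiny in-code fixtures.

# a drug-record data.frame in the shape parse_drug_table() returns
record_df <- function(smiles, status, source = "A",
                      id = sprintf("D%02d", seq_along(smiles))) {
  data.frame(
    drug_id = id, name = rep(NA_character_, length(smiles)),
    smiles = smiles, status = status,
    mapped_status = status, source = rep(source, length.out = length(smiles)),
    structure_less = !nzchar(smiles), stringsAsFactors = FALSE
  )
}

# a standardized database straight from smiles + labels
make_db <- function(name, smiles, labels) {
  rec <- record_df(smiles, ifelse(labels == 1L, "withdrawn", "approved"),
                   source = name)
  standardize_database(rec, source_name = name)$database
}

# write a source CSV in the corpus input format
write_source_csv <- function(path, ids, smiles, status) {
  df <- data.frame(id = ids, name = "", smiles = smiles, status = status,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

PLAIN_STATUS_MAP <- c(withdrawn = "withdrawn", approved = "approved")

# deterministic distinct small molecules for toy split corpora
TOY_SMILES <- c(x = "CCO", y = "CCN", z = "CCC", w = "CCCC", v = "CCOC")

# brute-force ROC AUC: all positive-negative pairs, ties count 1/2
auc_brute <- function(labels, scores) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  cmp <- outer(pos, neg, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# scalar-arithmetic attention oracle: explicit loops, no matrix algebra
attention_oracle <- function(Q, K, V) {
  nq <- nrow(Q); nk <- nrow(K); dk <- ncol(K); dv <- ncol(V)
  out <- matrix(0, nq, dv)
  for (i in seq_len(nq)) {
    logits <- numeric(nk)
    for (j in seq_len(nk)) {
      s <- 0
      for (t in seq_len(dk)) s <- s + Q[i, t] * K[j, t]
      logits[j] <- s / sqrt(dk)
    }
    w <- exp(logits - max(logits))
    w <- w / sum(w)
    for (d in seq_len(dv)) {
      acc <- 0
      for (j in seq_len(nk)) acc <- acc + w[j] * V[j, d]
      out[i, d] <- acc
    }
  }
  out
}
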