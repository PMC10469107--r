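# Fingerprint baseline: hashed circular substructure fingerprints fed to a
# gradient-boosted ensemble of depth-1 trees (stumps) with logistic loss.
# Stands in for the classical descriptor + boosted-trees baselines behind
# the same model interface as the transformer.

.stump_boost_fit <- function(X, y, n_rounds = 150L, shrinkage = 0.1) {
  n <- nrow(X)
  p0 <- mean(y)
  f0 <- log(p0 / (1 - p0))
  F <- rep(f0, n)
  ones <- colSums(X)             # count of molecules with each bit set
  stumps <- matrix(0, nrow = n_rounds, ncol = 3L) # feature, val0, val1
  for (r in seq_len(n_rounds)) {
    p <- .sigmoid(F)
    res <- y - p                 # negative gradient of logistic loss
    s1 <- as.numeric(res %*% X)  # residual sum where bit = 1
    s0 <- sum(res) - s1
    n1 <- ones
    n0 <- n - n1
    v1 <- ifelse(n1 > 0, s1 / n1, 0)
    v0 <- ifelse(n0 > 0, s0 / n0, 0)
    gain <- n1 * v1^2 + n0 * v0^2
    j <- which.max(gain)
    if (gain[j] <= 0) break
    stumps[r, ] <- c(j, v0[j], v1[j])
    F <- F + shrinkage * ifelse(X[, j] == 1L, v1[j], v0[j])
  }
  used <- stumps[, 1] != 0
  list(f0 = f0, shrinkage = shrinkage, stumps = stumps[used, , drop = FALSE])
}

.stump_boost_predict <- function(fit, X) {
  F <- rep(fit$f0, nrow(X))
  if (nrow(fit$stumps)) {
    for (r in seq_len(nrow(fit$stumps))) {
      s <- fit$stumps[r, ]
      F <- F + fit$shrinkage * ifelse(X[, s[1]] == 1L, s[3], s[2])
    }
  }
  .sigmoid(F)
}

#' Train the fingerprint + boosted-stumps baseline
#'
#' @param train data.frame with columns `smiles` and `label`.
#' @param settings list of options: `nbits` (fingerprint length, default
#'   512), `radius` (default 2), `n_rounds` (boosting rounds, default 150),
#'   `shrinkage` (default 0.1), `seed` (default 1; the fit itself is
#'   deterministic, the seed is recorded for interface parity).
#' @return a `withdrawr_model` with backend `"fingerprint"`.
#' @export
fingerprint_baseline_train <- function(train, settings = list()) {
  .check_training_set(train)
  s <- utils::modifyList(list(nbits = 512L, radius = 2L, n_rounds = 150L,
                              shrinkage = 0.1, seed = 1L), settings)
  X <- morgan_fingerprint(train$smiles, nbits = s$nbits, radius = s$radius)
  fit <- .stump_boost_fit(X, train$label, n_rounds = s$n_rounds,
                          shrinkage = s$shrinkage)
  history <- numeric(0)
  structure(list(backend = "fingerprint", tokenizer = NULL,
                 params = fit, config = s, threshold = 0.5,
                 history = history),
            class = "withdrawr_model")
}

.fingerprint_predict <- function(model, smiles) {
  ok <- nzchar(smiles)
  out <- rep(NA_real_, length(smiles))
  if (any(ok)) {
    scored <- vapply(which(ok), function(i) {
      tryCatch({
        X <- morgan_fingerprint(smiles[i], nbits = model$config$nbits,
                                radius = model$config$radius)
        .stump_boost_predict(model$params, X)
      }, error = function(e) NA_real_)
    }, 0)
    out[ok] <- scored
  }
  if (anyNA(out)) {
    warning(sprintf("%d of %d inputs could not be scored (NA returned)",
                    sum(is.na(out)), length(out)))
  }
  out
}
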