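# Supervised training of the SMILES classifiers. Both backends return a
# `withdrawr_model` exposing the same predict interface: a probability of
# withdrawal in [0,1] per SMILES and a decision threshold tau.

.adam_state <- function(params) {
  list(m = .zero_like(params), v = .zero_like(params), t = 0L)
}

.tree_map2 <- function(f, a, b) {
  if (is.list(a)) Map(function(x, y) .tree_map2(f, x, y), a, b) else f(a, b)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- .tree_map2(function(m, d) m / bc1, state$m, state$m)
  vhat <- .tree_map2(function(v, d) v / bc2, state$v, state$v)
  upd <- .tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mhat, vhat)
  params <- .tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.check_training_set <- function(train) {
  stopifnot(is.data.frame(train), all(c("smiles", "label") %in% names(train)))
  if (nrow(train) == 0L) stop("empty training set")
  if (length(unique(train$label)) < 2L) {
    stop("training set contains a single class; need both withdrawn and ",
         "not-withdrawn drugs")
  }
}

#' Train a withdrawal classifier
#'
#' @param train data.frame with columns `smiles` and `label` (1 = withdrawn).
#' @param config a [model_config()] (transformer backend) or a list of
#'   baseline settings (fingerprint backend, see
#'   [fingerprint_baseline_train()]).
#' @param backend `"transformer"` or `"fingerprint"`.
#' @return a `withdrawr_model`: list with `backend`, `tokenizer` (transformer
#'   only), `params`, `config`, `threshold` (default 0.5) and `history`
#'   (mean training loss per epoch/round).
#' @export
train_classifier <- function(train, config = model_config(),
                             backend = c("transformer", "fingerprint")) {
  backend <- match.arg(backend)
  if (backend == "fingerprint") {
    return(fingerprint_baseline_train(train, settings = config))
  }
  .check_training_set(train)
  cfg <- config
  stopifnot(inherits(cfg, "withdrawr_config"))
  set.seed(cfg$seed)
  tokenizer <- build_tokenizer(train$smiles, max_len = cfg$max_len)
  params <- .init_transformer_params(length(tokenizer$vocab), cfg)
  state <- .adam_state(params)
  n <- nrow(train)
  ids_list <- lapply(train$smiles, function(s) {
    ids <- tokenize_smiles(s, tokenizer)
    ids[seq_len(max(2L, sum(ids != PAD_ID)))] # strip padding, keep >= 2
  })
  y <- train$label
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      batch <- ord[start:min(start + cfg$batch_size - 1L, n)]
      grads <- NULL
      bloss <- 0
      for (i in batch) {
        dm <- .make_dropmask(length(ids_list[[i]]), cfg)
        fw <- .seq_forward(ids_list[[i]], params, cfg, dropmask = dm)
        p <- .sigmoid(fw$logit)
        eps <- 1e-12
        bloss <- bloss - (y[i] * log(p + eps) + (1 - y[i]) * log(1 - p + eps))
        gi <- .seq_backward((p - y[i]) / length(batch), fw$cache, params, cfg,
                            dropmask = dm)
        grads <- if (is.null(grads)) gi else .tree_add(grads, gi)
      }
      losses <- c(losses, bloss / length(batch))
      st <- .adam_step(params, grads, state, lr = cfg$lr)
      params <- st$params
      state <- st$state
    }
    history[epoch] <- mean(losses)
  }
  structure(list(backend = "transformer", tokenizer = tokenizer,
                 params = params, config = cfg, threshold = 0.5,
                 history = history),
            class = "withdrawr_model")
}

#' @export
print.withdrawr_model <- function(x, ...) {
  cat(sprintf("<withdrawr_model> backend '%s', threshold %.2f\n",
              x$backend, x$threshold))
  if (length(x$history)) {
    cat(sprintf("  training loss: %.4f -> %.4f over %d epochs\n",
                x$history[1], x$history[length(x$history)],
                length(x$history)))
  }
  invisible(x)
}

#' Predict withdrawal probabilities for a batch of SMILES
#'
#' Deterministic given the model parameters (dropout disabled). Items that
#' cannot be scored (e.g. empty strings) yield `NA` with a warning; the rest
#' of the batch is still scored.
#'
#' @param model a `withdrawr_model`.
#' @param smiles character vector of SMILES strings.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
forward_classifier <- function(model, smiles) {
  stopifnot(inherits(model, "withdrawr_model"))
  if (model$backend == "fingerprint") {
    return(.fingerprint_predict(model, smiles))
  }
  cfg <- model$config
  out <- vapply(smiles, function(s) {
    tryCatch({
      ids <- tokenize_smiles(s, model$tokenizer)
      ids <- ids[seq_len(max(2L, sum(ids != PAD_ID)))]
      .sigmoid(.seq_forward(ids, model$params, cfg)$logit)
    }, error = function(e) NA_real_)
  }, 0, USE.NAMES = FALSE)
  if (anyNA(out)) {
    warning(sprintf("%d of %d inputs could not be scored (NA returned)",
                    sum(is.na(out)), length(out)))
  }
  out
}

#' @export
predict.withdrawr_model <- function(object, smiles,
                                    type = c("prob", "label"), ...) {
  type <- match.arg(type)
  p <- forward_classifier(object, smiles)
  if (type == "prob") p else as.integer(p > object$threshold)
}

#' Save / load a classifier checkpoint
#'
#' Single-file archive holding the backend tag, tokenizer vocabulary,
#' parameters, configuration and decision threshold.
#'
#' @param model a `withdrawr_model`.
#' @param path checkpoint file path.
#' @return `path` invisibly (`save_model`); a `withdrawr_model`
#'   (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "withdrawr_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "withdrawr_model")) {
    stop(sprintf("'%s' is not a withdrawr model checkpoint", path))
  }
  model
}
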