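# Metric suite: ROC AUC (Mann-Whitney, ties count 1/2), PR-AUC (step-curve
# area, no interpolation), threshold metrics (accuracy, specificity,
# sensitivity, MCC with the 0/0 -> 0 convention), the disagreement-subset
# accuracy report and the probability-ranking report.

.check_predictions <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), length(labels) > 0L)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    stop("scores must be probabilities in [0, 1]")
  }
}

#' ROC AUC by pairwise concordance
#'
#' Equals the probability that a randomly chosen positive is scored above a
#' randomly chosen negative, with tied scores counting one half
#' (Mann-Whitney convention): `(concordant + 0.5 * tied) / (n_pos * n_neg)`.
#'
#' @param labels 0/1 vector of true labels.
#' @param scores numeric scores in `[0, 1]`.
#' @return the AUC value.
#' @export
roc_auc <- function(labels, scores) {
  .check_predictions(labels, scores)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall step curve
#'
#' Precision and recall are evaluated at every distinct score cutoff
#' (prediction positive when score >= cutoff) and the area is accumulated as
#' `sum over cutoffs of (recall step) x precision` -- the step-function
#' (average-precision) area, with no interpolation.
#'
#' @inheritParams roc_auc
#' @return the PR-AUC value.
#' @export
pr_auc <- function(labels, scores) {
  .check_predictions(labels, scores)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("pr_auc undefined: no positive labels")
  cuts <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prev_recall <- 0
  for (cut in cuts) {
    pred <- scores >= cut
    tp <- sum(pred & labels == 1L)
    precision <- tp / sum(pred)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

#' Threshold-dependent confusion metrics
#'
#' Classifies positive when `score > tau` (strict, so an all-zero-score model
#' is an all-negative predictor). MCC uses the convention 0 when any factor
#' of its denominator is 0, which reproduces the collapsed all-negative rows
#' of published benchmark tables.
#'
#' @inheritParams roc_auc
#' @param tau decision threshold in `(0, 1)` (default 0.5).
#' @return object of class `withdrawr_metrics`: list with `auc`, `pr_auc`
#'   (NA when undefined), `accuracy`, `specificity`, `sensitivity`, `mcc`,
#'   `tp`, `fp`, `tn`, `fn`, `tau`.
#' @export
confusion_metrics <- function(labels, scores, tau = 0.5) {
  .check_predictions(labels, scores)
  pred <- scores > tau
  tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
  tn <- sum(!pred & labels == 0L); fn <- sum(!pred & labels == 1L)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  sp <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  sn <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom2)
  auc <- tryCatch(roc_auc(labels, scores), error = function(e) NA_real_)
  pra <- tryCatch(pr_auc(labels, scores), error = function(e) NA_real_)
  structure(list(auc = auc, pr_auc = pra, accuracy = acc, specificity = sp,
                 sensitivity = sn, mcc = mcc, tp = tp, fp = fp, tn = tn,
                 fn = fn, tau = tau),
            class = "withdrawr_metrics")
}

#' @export
print.withdrawr_metrics <- function(x, ...) {
  cat(sprintf(
    "AUC %.4f  PR-AUC %.4f  ACC %.4f  Sp %.4f  Sn %.4f  MCC %.4f (tau=%.2f)\n",
    x$auc, x$pr_auc, x$accuracy, x$specificity, x$sensitivity, x$mcc, x$tau))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Disagreement-subset accuracy
#'
#' For the cohort of drugs approved in the training data but withdrawn in
#' the test database, the fraction the model flags as withdrawn
#' (`score > tau`): the "future withdrawal" detection rate.
#'
#' @param scores numeric scores of the disagreement-subset drugs.
#' @param tau decision threshold (default 0.5).
#' @return list with `n_disagreement`, `n_predicted`, `accuracy` (`NA` for
#'   an empty subset).
#' @export
disagreement_accuracy <- function(scores, tau = 0.5) {
  if (length(scores) == 0L) {
    return(list(n_disagreement = 0L, n_predicted = 0L, accuracy = NA_real_))
  }
  stopifnot(all(is.finite(scores)), all(scores >= 0 & scores <= 1))
  n_pred <- sum(scores > tau)
  list(n_disagreement = length(scores), n_predicted = n_pred,
       accuracy = n_pred / length(scores))
}

#' Probability-ranking report
#'
#' Sorts drugs by descending score (stable: ties keep input order) and
#' reports 1-based ranks, the ranks of named drugs and the rank of the first
#' label-0 drug.
#'
#' @param keys character identifiers (unique).
#' @param labels 0/1 true labels.
#' @param scores numeric scores.
#' @param named_keys optional character vector of keys whose ranks to report.
#' @return list with `ranking` (data.frame rank/key/label/score),
#'   `named_ranks` (named integer vector, `NA` for missing keys) and
#'   `first_negative_rank` (`NA` if no label-0 drug).
#' @export
rank_report <- function(keys, labels, scores, named_keys = NULL) {
  .check_predictions(labels, scores)
  stopifnot(length(keys) == length(scores), !anyDuplicated(keys))
  ord <- order(-scores) # order() is stable: ties keep input order
  ranking <- data.frame(rank = seq_along(keys), key = keys[ord],
                        label = labels[ord], score = scores[ord],
                        stringsAsFactors = FALSE)
  named_ranks <- NULL
  if (!is.null(named_keys)) {
    named_ranks <- vapply(named_keys, function(k) {
      hit <- which(ranking$key == k)
      if (length(hit)) hit[1] else NA_integer_
    }, 0L)
  }
  fneg <- which(ranking$label == 0L)
  list(ranking = ranking, named_ranks = named_ranks,
       first_negative_rank = if (length(fneg)) fneg[1] else NA_integer_)
}

#' Write a combined per-split metric report
#'
#' CSV mirroring the benchmark column order AUC, PR-AUC, ACC, Sp, Sn, MCC.
#'
#' @param metrics a `withdrawr_metrics` object (or list of them, one row
#'   each, with list names as row labels).
#' @param path output CSV path.
#' @export
write_metric_report <- function(metrics, path) {
  if (inherits(metrics, "withdrawr_metrics")) {
    metrics <- list(model = metrics)
  }
  df <- do.call(rbind, lapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    data.frame(model = nm, AUC = m$auc, PR_AUC = m$pr_auc, ACC = m$accuracy,
               Sp = m$specificity, Sn = m$sensitivity, MCC = m$mcc,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
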