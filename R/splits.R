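# Leave-one-database-out split construction. One database is the test set;
# the union of the others trains. Negative (approved, label-0) drugs come
# from a designated negative source. Two modes: "agree" removes any drug
# whose train-side and test-side labels conflict; "no_agree" keeps them and
# records the conflict keys, emulating drugs withdrawn only after training
# data was frozen.

#' Build one leave-one-database-out train/test split
#'
#' Test positives are the test database's withdrawn drugs. Test negatives
#' are the negative source's approved drugs that are annotated in the test
#' database and not withdrawn there. Train positives are drugs withdrawn in
#' any training database; train negatives are the remaining approved drugs
#' of the negative source (not withdrawn in training data, not annotated in
#' the test database). Same-label test duplicates are removed from train; in
#' `"agree"` mode conflicting drugs are removed from both sides, in
#' `"no_agree"` mode they are kept and recorded.
#'
#' @param databases named list of `withdrawr_database` objects (names are
#'   the source names).
#' @param test_db name of the held-out test database.
#' @param mode `"agree"` or `"no_agree"`.
#' @param negative_source name of the database supplying approved drugs.
#' @return an object of class `withdrawr_split`: list with `train`, `test`
#'   (data.frames key/smiles/label), `conflict_train0_test1`,
#'   `conflict_train1_test0` (character key vectors), `mode`, `test_db`,
#'   `negative_source`.
#' @export
build_cross_db_split <- function(databases, test_db,
                                 mode = c("agree", "no_agree"),
                                 negative_source = names(databases)[1]) {
  mode <- match.arg(mode)
  if (is.null(names(databases)) || any(!nzchar(names(databases)))) {
    stop("databases must be a named list")
  }
  if (!test_db %in% names(databases)) {
    stop(sprintf("unknown test database '%s' (have: %s)", test_db,
                 paste(names(databases), collapse = ", ")))
  }
  if (!negative_source %in% names(databases)) {
    stop(sprintf("unknown negative source '%s'", negative_source))
  }
  if (length(databases) < 2L) {
    stop("need at least one training database besides the test database")
  }
  train_dbs <- databases[setdiff(names(databases), test_db)]
  test_set <- databases[[test_db]]$drugs
  neg_pool <- databases[[negative_source]]$drugs

  smiles_of <- new.env(parent = emptyenv())
  for (db in databases) {
    for (i in seq_len(nrow(db$drugs))) {
      smiles_of[[db$drugs$key[i]]] <- db$drugs$smiles[i]
    }
  }

  # keys are sorted before any set materialization for reproducibility
  test_pos <- sort(test_set$key[test_set$label == 1L])
  test_annot <- sort(test_set$key)
  neg_approved <- sort(neg_pool$key[neg_pool$label == 0L])
  train_pos <- sort(unique(unlist(lapply(train_dbs, function(db) {
    db$drugs$key[db$drugs$label == 1L]
  }), use.names = FALSE)))

  # a negative goes to the test side when the drug is annotated (and not
  # withdrawn) in the test database; otherwise its approved claim stays on
  # the train side, where it may conflict with a test-side withdrawal
  test_neg <- setdiff(intersect(neg_approved, test_annot), test_pos)
  train_neg <- setdiff(setdiff(neg_approved, test_neg), train_pos)
  train_pos_kept <- setdiff(train_pos, test_pos)   # same-label dedup
  # (train negatives never coincide with test negatives by construction:
  # a negative annotated in the test database went to the test side)

  conflict_01 <- intersect(train_neg, test_pos)
  conflict_10 <- intersect(train_pos_kept, test_neg)

  if (mode == "agree") {
    train_neg <- setdiff(train_neg, conflict_01)
    train_pos_kept <- setdiff(train_pos_kept, conflict_10)
    test_pos <- setdiff(test_pos, conflict_01)
    test_neg <- setdiff(test_neg, conflict_10)
    conflict_01 <- character(0)
    conflict_10 <- character(0)
  }

  mk <- function(keys, label) {
    data.frame(key = keys,
               smiles = vapply(keys, function(k) smiles_of[[k]], ""),
               label = rep(label, length(keys)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  train <- rbind(mk(train_neg, 0L), mk(train_pos_kept, 1L))
  test <- rbind(mk(test_neg, 0L), mk(test_pos, 1L))
  train <- train[order(train$key), , drop = FALSE]; rownames(train) <- NULL
  test <- test[order(test$key), , drop = FALSE]; rownames(test) <- NULL

  if (nrow(train) == 0L || nrow(test) == 0L) {
    stop(sprintf(
      "split test_db='%s' mode='%s': empty %s set after construction",
      test_db, mode, if (nrow(train) == 0L) "train" else "test"))
  }
  structure(list(train = train, test = test,
                 conflict_train0_test1 = conflict_01,
                 conflict_train1_test0 = conflict_10,
                 mode = mode, test_db = test_db,
                 negative_source = negative_source),
            class = "withdrawr_split")
}

#' @export
print.withdrawr_split <- function(x, ...) {
  s <- split_statistics(x)
  cat(sprintf(
    "<withdrawr_split> test='%s' mode='%s': train %d-/%d+, test %d-/%d+, ratio %s; conflicts 0->1:%d 1->0:%d\n",
    x$test_db, x$mode, s$n_train_neg, s$n_train_pos, s$n_test_neg,
    s$n_test_pos, format(s$test_positive_ratio),
    length(x$conflict_train0_test1), length(x$conflict_train1_test0)))
  invisible(x)
}

#' Class counts and test positive ratio of a split
#'
#' The test positive ratio is the number of test positives divided by the
#' number of test negatives (not by the total), displayed to 4 decimals.
#'
#' @param split a `withdrawr_split`, or `NULL` if raw counts are given.
#' @param n_train_neg,n_train_pos,n_test_neg,n_test_pos raw counts;
#'   supplied directly when summarizing published tables.
#' @return list with the four counts and `test_positive_ratio` (`NA` when
#'   there are no test negatives).
#' @export
split_statistics <- function(split = NULL, n_train_neg = NULL,
                             n_train_pos = NULL, n_test_neg = NULL,
                             n_test_pos = NULL) {
  if (!is.null(split)) {
    stopifnot(inherits(split, "withdrawr_split"))
    n_train_neg <- sum(split$train$label == 0L)
    n_train_pos <- sum(split$train$label == 1L)
    n_test_neg <- sum(split$test$label == 0L)
    n_test_pos <- sum(split$test$label == 1L)
  }
  ratio <- if (n_test_neg == 0L) NA_real_
    else round(n_test_pos / n_test_neg, 4L)
  list(n_train_neg = n_train_neg, n_train_pos = n_train_pos,
       n_test_neg = n_test_neg, n_test_pos = n_test_pos,
       test_positive_ratio = ratio)
}

#' Disagreement subset of a no-agreement split
#'
#' The test drugs labelled withdrawn in the test database but carried as
#' approved (label 0) in the training data: the "future withdrawal" cohort.
#'
#' @param split a `withdrawr_split` built in `"no_agree"` mode.
#' @return data.frame (key, smiles, label) of the conflict drugs, each with
#'   test label 1.
#' @export
disagreement_subset <- function(split) {
  stopifnot(inherits(split, "withdrawr_split"))
  if (split$mode != "no_agree") {
    stop("disagreement_subset requires a split built in no_agree mode ",
         "(in agree mode the subset is empty by construction)")
  }
  out <- split$test[split$test$key %in% split$conflict_train0_test1, ,
                    drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize a split to a directory
#'
#' Writes `train.csv`, `test.csv` (key, smiles, label) and `stats.json`
#' (class counts, positive ratio, conflict key lists).
#'
#' @param split a `withdrawr_split`.
#' @param dir output directory (created if missing).
#' @export
write_split <- function(split, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(split$train, file.path(dir, "train.csv"), row.names = FALSE)
  utils::write.csv(split$test, file.path(dir, "test.csv"), row.names = FALSE)
  stats <- split_statistics(split)
  stats$mode <- split$mode
  stats$test_db <- split$test_db
  stats$conflict_train0_test1 <- as.list(split$conflict_train0_test1)
  stats$conflict_train1_test0 <- as.list(split$conflict_train1_test0)
  jsonlite::write_json(stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "list")
  invisible(dir)
}
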