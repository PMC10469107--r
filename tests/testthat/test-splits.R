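toy_corpus_1 <- function() {
  # A = {x:1, y:0}, B = {x:1, z:1}
  list(A = make_db("A", TOY_SMILES[c("x", "y")], c(1L, 0L)),
       B = make_db("B", TOY_SMILES[c("x", "z")], c(1L, 1L)))
}

toy_corpus_2 <- function() {
  # A = {x:0}, B = {x:1}: pure train/test label conflict
  list(A = make_db("A", TOY_SMILES["x"], 0L),
       B = make_db("B", TOY_SMILES["x"], 1L))
}

key_of <- function(nm) canonical_key(TOY_SMILES[[nm]])

test_that("agree-mode split removes same-label duplicates from train", {
  s <- build_cross_db_split(toy_corpus_1(), "B", mode = "agree",
                            negative_source = "A")
  expect_equal(s$train$key, key_of("y"))
  expect_equal(s$train$label, 0L)
  # x stays in test (duplicates are removed from the training side only)
  expect_setequal(s$test$key, c(key_of("x"), key_of("z")))
  expect_true(all(s$test$label == 1L))
  expect_length(s$conflict_train0_test1, 0L)
  expect_length(s$conflict_train1_test0, 0L)
})

test_that("no_agree mode keeps label conflicts and records them", {
  s <- build_cross_db_split(toy_corpus_2(), "B", mode = "no_agree",
                            negative_source = "A")
  expect_equal(s$train$key, key_of("x"))
  expect_equal(s$train$label, 0L)
  expect_equal(s$test$key, key_of("x"))
  expect_equal(s$test$label, 1L)
  expect_equal(s$conflict_train0_test1, key_of("x"))
  expect_length(s$conflict_train1_test0, 0L)
})

test_that("a total-conflict corpus errors out in agree mode", {
  expect_error(build_cross_db_split(toy_corpus_2(), "B", mode = "agree",
                                    negative_source = "A"),
               "empty")
})

test_that("configuration errors are explicit", {
  expect_error(build_cross_db_split(toy_corpus_1(), "C",
                                    negative_source = "A"),
               "unknown test database 'C'")
  expect_error(build_cross_db_split(toy_corpus_1(), "B",
                                    negative_source = "Z"),
               "negative source")
  expect_error(build_cross_db_split(toy_corpus_1()["B"], "B"),
               "at least one")
})

test_that("split statistics reproduce the published positive ratios", {
  # ratio = positives / NEGATIVES, checked against all published rows
  rows <- list(list(1949L, 616L, 0.316), list(2212L, 219L, 0.099),
               list(2915L, 1098L, 0.3766), list(1805L, 366L, 0.2027),
               list(1816L, 166L, 0.0914), list(2773L, 828L, 0.2985))
  for (r in rows) {
    st <- split_statistics(n_train_neg = 0L, n_train_pos = 0L,
                           n_test_neg = r[[1]], n_test_pos = r[[2]])
    expect_equal(st$test_positive_ratio, round(r[[2]] / r[[1]], 4))
    # published tables truncate/round to fewer digits
    expect_lt(abs(st$test_positive_ratio - r[[3]]), 1e-3)
  }
  expect_equal(split_statistics(n_train_neg = 1L, n_train_pos = 1L,
                                n_test_neg = 10L,
                                n_test_pos = 0L)$test_positive_ratio, 0)
  expect_true(is.na(split_statistics(n_train_neg = 1L, n_train_pos = 1L,
                                     n_test_neg = 0L,
                                     n_test_pos = 3L)$test_positive_ratio))
})

test_that("split statistics match brute-force recounts", {
  s <- build_cross_db_split(toy_corpus_1(), "B", mode = "agree",
                            negative_source = "A")
  st <- split_statistics(s)
  expect_equal(st$n_train_neg, sum(s$train$label == 0L))
  expect_equal(st$n_train_pos, sum(s$train$label == 1L))
  expect_equal(st$n_test_neg, sum(s$test$label == 0L))
  expect_equal(st$n_test_pos, sum(s$test$label == 1L))
})

test_that("disagreement subset returns the conflicted test drugs", {
  s <- build_cross_db_split(toy_corpus_2(), "B", mode = "no_agree",
                            negative_source = "A")
  dis <- disagreement_subset(s)
  expect_equal(dis$key, key_of("x"))
  expect_equal(dis$label, 1L)

  s1 <- build_cross_db_split(toy_corpus_1(), "B", mode = "no_agree",
                             negative_source = "A")
  expect_equal(nrow(disagreement_subset(s1)), 0L)
  s2 <- build_cross_db_split(toy_corpus_1(), "B", mode = "agree",
                             negative_source = "A")
  expect_error(disagreement_subset(s2), "no_agree")
})

test_that("splits obey leakage, purity and monotonicity invariants", {
  for (seed in 1:12) {
    corpus <- synthetic_corpus(synthetic_config(
      n_molecules = 50L, n_sources = 3L, flip_rate = 0.1, seed = seed))
    test_db <- paste0("source", 2L + seed %% 2L)
    na_split <- build_cross_db_split(corpus$databases, test_db,
                                     mode = "no_agree",
                                     negative_source = "source1")
    ag_split <- tryCatch(
      build_cross_db_split(corpus$databases, test_db, mode = "agree",
                           negative_source = "source1"),
      error = function(e) NULL)

    # leakage: no (key, label) pair occurs on both sides
    pairs <- function(df) paste(df$key, df$label)
    expect_length(intersect(pairs(na_split$train), pairs(na_split$test)), 0L)

    # conflict sets are exactly the cross-side label disagreements
    tr <- stats::setNames(na_split$train$label, na_split$train$key)
    te <- stats::setNames(na_split$test$label, na_split$test$key)
    common <- intersect(names(tr), names(te))
    expect_setequal(na_split$conflict_train0_test1,
                    common[tr[common] == 0L & te[common] == 1L])
    expect_setequal(na_split$conflict_train1_test0,
                    common[tr[common] == 1L & te[common] == 0L])

    if (!is.null(ag_split)) {
      expect_length(intersect(pairs(ag_split$train), pairs(ag_split$test)),
                    0L)
      # agree-mode purity: no key with two labels anywhere in the split
      expect_length(intersect(ag_split$train$key, ag_split$test$key), 0L)
      # mode monotonicity: agree sets are subsets of no_agree sets
      expect_true(all(pairs(ag_split$train) %in% pairs(na_split$train)))
      expect_true(all(pairs(ag_split$test) %in% pairs(na_split$test)))
    }
  }
})

test_that("split serialization writes train/test/stats artifacts", {
  dir <- withr::local_tempdir()
  s <- build_cross_db_split(toy_corpus_1(), "B", mode = "agree",
                            negative_source = "A")
  write_split(s, dir)
  expect_true(all(file.exists(file.path(dir, c("train.csv", "test.csv",
                                               "stats.json")))))
  stats <- jsonlite::read_json(file.path(dir, "stats.json"))
  expect_equal(stats$n_test_pos, 2L)
})
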