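test_that("roc_auc handles separation, reversal and the tied toy", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1)), 0)
  # 4 pos-neg pairs, one tied pair contributes 1/2: (3 + 0.5) / 4
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.8, 0.1)), 0.875)
  expect_error(roc_auc(c(1, 1), c(0.5, 0.6)), "both classes")
  expect_error(roc_auc(c(0, 1), c(0.5, 1.2)), "probabilities")
})

test_that("roc_auc equals brute-force concordance and obeys symmetries", {
  set.seed(211)
  for (rep in 1:60) {
    n <- sample(5:120, 1)
    labels <- c(0L, 1L, sample(0:1, n - 2L, replace = TRUE))
    scores <- round(stats::runif(n), 1) # coarse scores force ties
    a <- roc_auc(labels, scores)
    expect_identical(a, auc_brute(labels, scores))
    # invariant under strictly increasing transforms
    expect_equal(roc_auc(labels, scores^3), a, tolerance = 1e-12)
    # flipping labels maps AUC to 1 - AUC
    expect_equal(roc_auc(1L - labels, scores), 1 - a, tolerance = 1e-12)
  }
})

# independent PR oracle: explicit counting at every cutoff
pr_auc_oracle <- function(labels, scores) {
  cuts <- sort(unique(scores), decreasing = TRUE)
  area <- 0; prev_r <- 0
  for (ct in cuts) {
    tp <- 0; fp <- 0
    for (i in seq_along(scores)) {
      if (scores[i] >= ct) {
        if (labels[i] == 1L) tp <- tp + 1 else fp <- fp + 1
      }
    }
    r <- tp / sum(labels == 1L)
    area <- area + (r - prev_r) * tp / (tp + fp)
    prev_r <- r
  }
  area
}

test_that("pr_auc matches exhaustive cutoff enumeration", {
  expect_equal(pr_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  # constant scores: a single cutoff with precision = prevalence
  expect_equal(pr_auc(c(1, 0, 0, 0), rep(0.4, 4)), 0.25)
  expect_equal(pr_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.8, 0.1)),
               pr_auc_oracle(c(1, 1, 0, 0), c(0.9, 0.8, 0.8, 0.1)))
  set.seed(212)
  for (rep in 1:40) {
    n <- sample(4:60, 1)
    labels <- c(1L, sample(0:1, n - 1L, replace = TRUE))
    scores <- round(stats::runif(n), 1)
    expect_equal(pr_auc(labels, scores), pr_auc_oracle(labels, scores),
                 tolerance = 1e-12)
  }
  expect_error(pr_auc(c(0, 0), c(0.1, 0.2)), "no positive")
})

test_that("confusion metrics reproduce the all-negative benchmark rows", {
  # published agreement-split class counts with an all-negative predictor
  m1 <- confusion_metrics(rep(c(0L, 1L), c(1805L, 366L)), rep(0, 2171L))
  expect_equal(round(m1$accuracy, 4), 0.8314)
  expect_equal(m1$specificity, 1)
  expect_equal(m1$sensitivity, 0)
  expect_equal(m1$mcc, 0)
  m2 <- confusion_metrics(rep(c(0L, 1L), c(2773L, 828L)), rep(0, 3601L))
  expect_equal(round(m2$accuracy, 4), 0.7701)
  expect_equal(m2$specificity, 1)
  expect_equal(m2$mcc, 0)
  # perfect predictor
  m3 <- confusion_metrics(c(0L, 1L, 0L, 1L), c(0.1, 0.9, 0.2, 0.8))
  expect_equal(m3$accuracy, 1)
  expect_equal(m3$specificity, 1)
  expect_equal(m3$sensitivity, 1)
  expect_equal(m3$mcc, 1)
  expect_error(confusion_metrics(integer(0), numeric(0)), "length")
})

test_that("confusion counts and formulas are internally consistent", {
  set.seed(213)
  labels <- sample(0:1, 150, replace = TRUE)
  scores <- stats::runif(150)
  for (tau in c(0.25, 0.5, 0.8)) {
    m <- confusion_metrics(labels, scores, tau = tau)
    expect_equal(m$tp + m$fp + m$tn + m$fn, 150L)
    expect_equal(m$accuracy, (m$tp + m$tn) / 150)
    expect_equal(m$specificity, m$tn / (m$tn + m$fp))
    expect_equal(m$sensitivity, m$tp / (m$tp + m$fn))
    # (Sp, Sn) is exactly the ROC point at tau: (1 - FPR, TPR)
    fpr <- sum(scores > tau & labels == 0L) / sum(labels == 0L)
    tpr <- sum(scores > tau & labels == 1L) / sum(labels == 1L)
    expect_equal(m$specificity, 1 - fpr)
    expect_equal(m$sensitivity, tpr)
  }
  # classification is strictly score > tau
  m <- confusion_metrics(c(0L, 1L), c(0.5, 0.5), tau = 0.5)
  expect_equal(m$tp + m$fp, 0L)
})

test_that("disagreement accuracy reproduces the published cohort rows", {
  # counts printed in the future-withdrawal table; values are truncated
  # there (131/234 = 0.5598 prints as 0.559), hence the 1e-3 band
  make_scores <- function(n, k) c(rep(0.9, k), rep(0.1, n - k))
  d1 <- disagreement_accuracy(make_scores(42L, 29L))
  expect_equal(d1$n_predicted, 29L)
  expect_lt(abs(d1$accuracy - 0.690), 1e-3)
  d2 <- disagreement_accuracy(make_scores(220L, 111L))
  expect_lt(abs(d2$accuracy - 0.504), 1e-3)
  d3 <- disagreement_accuracy(make_scores(234L, 131L))
  expect_lt(abs(d3$accuracy - 0.559), 1e-3)
  expect_equal(disagreement_accuracy(rep(0.2, 5))$accuracy, 0)
  expect_true(is.na(disagreement_accuracy(numeric(0))$accuracy))
})

test_that("disagreement accuracy is non-increasing in the threshold", {
  set.seed(214)
  scores <- stats::runif(80)
  taus <- seq(0.05, 0.95, by = 0.05)
  accs <- vapply(taus, function(t) disagreement_accuracy(scores, t)$accuracy,
                 0)
  expect_true(all(diff(accs) <= 0))
})

test_that("single-class prediction vectors have MCC zero by convention", {
  labels <- sample(0:1, 30, replace = TRUE)
  expect_equal(confusion_metrics(labels, rep(0, 30))$mcc, 0)
  expect_equal(confusion_metrics(labels, rep(1, 30))$mcc, 0)
})

test_that("rank_report sorts stably and locates named and negative drugs", {
  rr <- rank_report(keys = c("a", "b", "c"), labels = c(1L, 0L, 1L),
                    scores = c(0.9, 0.8, 0.7), named_keys = c("c", "zz"))
  expect_equal(rr$ranking$key, c("a", "b", "c"))
  expect_equal(rr$first_negative_rank, 2L)
  expect_equal(unname(rr$named_ranks), c(3L, NA_integer_))
  # ties keep input order
  rr2 <- rank_report(c("p", "q"), c(0L, 1L), c(0.5, 0.5))
  expect_equal(rr2$ranking$key, c("p", "q"))
  # ranks are a permutation and scores non-increasing
  set.seed(215)
  n <- 40L
  rr3 <- rank_report(sprintf("k%02d", 1:n), sample(0:1, n, replace = TRUE),
                     round(stats::runif(n), 2))
  expect_setequal(rr3$ranking$rank, 1:n)
  expect_true(all(diff(rr3$ranking$score) <= 0))
})

test_that("metric reports serialize in the benchmark column order", {
  m <- confusion_metrics(c(0L, 1L), c(0.2, 0.9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(list(transformer = m), path)
  df <- utils::read.csv(path)
  expect_equal(names(df), c("model", "AUC", "PR_AUC", "ACC", "Sp", "Sn",
                            "MCC"))
})
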