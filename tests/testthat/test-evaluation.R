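test_that("negative sampling is uniform over zero cells, disjoint and reproducible", {
  A <- matrix(0L, 6, 5, dimnames = list(sprintf("c%d", 1:6),
                                        sprintf("d%d", 1:5)))
  A[cbind(c(1, 2, 3), c(1, 2, 3))] <- 1L
  n1 <- sample_negatives(A, 3, seed = 42)
  n2 <- sample_negatives(A, 3, seed = 42)
  expect_identical(n1, n2)
  expect_true(all(A[cbind(n1$circ, n1$disease)] == 0))
  all_zero <- sample_negatives(A, sum(A == 0), seed = 1)
  expect_equal(nrow(all_zero), 27)
  expect_error(sample_negatives(A, 28, seed = 1), "only 27")
  expect_false(identical(sample_negatives(A, 3, seed = 43), n1))
})

test_that("metrics match hand evaluation and a brute-force implementation", {
  m <- metrics_from_counts(3, 4, 1, 2)
  expect_equal(m$Pre, 0.75)
  expect_equal(m$Sen, 0.6)
  expect_equal(m$Acc, 0.7)
  expect_equal(m$F1, 2 * 0.6 * 0.75 / 1.35, tolerance = 1e-12)
  expect_equal(m$MCC, 10 / sqrt(600), tolerance = 1e-12)

  perfect <- metrics_from_counts(5, 7, 0, 0)
  expect_equal(unlist(perfect[c("Pre", "Sen", "Acc", "F1", "MCC")]),
               c(Pre = 1, Sen = 1, Acc = 1, F1 = 1, MCC = 1))

  set.seed(99)
  for (rep in 1:200) {
    cts <- rmultinom(1, sample(10:200, 1), prob = runif(4, 0.05, 1))
    tp <- cts[1]; tn <- cts[2]; fp <- cts[3]; fn <- cts[4]
    got <- suppressWarnings(metrics_from_counts(tp, tn, fp, fn))
    ora <- oracle_metrics(tp, tn, fp, fn)
    for (k in names(ora)) {
      if (is.nan(got[[k]])) expect_true(!is.finite(ora[[k]]) || is.nan(ora[[k]]))
      else expect_equal(got[[k]], ora[[k]], tolerance = 1e-9, label = k)
    }
  }
  ws <- testthat::capture_warnings(metrics_from_counts(0, 5, 0, 0))
  expect_match(ws, "undefined", all = TRUE)
  expect_length(ws, 3)  # precision, sensitivity, MCC all undefined
  expect_error(compute_metrics(numeric(), integer()), "empty")
})

test_that("rank AUC matches all-pairs counting and is monotone-invariant", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    scores <- round(runif(n), 2)  # induce ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_score(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
    expect_equal(auc_score(plogis(5 * scores - 2), labels),
                 auc_score(scores, labels), tolerance = 1e-12)
  }
  scores <- runif(2000)
  labels <- rbinom(2000, 1, 0.5)
  expect_equal(auc_score(scores, labels), 0.5, tolerance = 0.05)
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  scores <- runif(150); labels <- rbinom(150, 1, 0.4)
  expect_equal(auc_score(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-9)
})

test_that("cross-validation partitions positives into disjoint exhaustive folds", {
  study <- tiny_study()
  prep <- suppressMessages(prepare_study(study, skf_config(), np = 4))
  cfg <- cnn_config(n_filters = 4, kernel1 = c(2, 8), kernel2 = c(1, 4),
                    epochs = 4)
  cv <- suppressWarnings(cross_validate_study(prep, config = cfg, folds = 5,
                                              repetitions = 2, seed = 3))
  expect_equal(nrow(cv$folds), 10)
  n_pos <- sum(study$network$A)
  # every positive tested exactly once per repetition
  per_rep <- tapply(cv$folds$TP + cv$folds$FN, cv$folds$repetition, sum)
  expect_equal(as.vector(per_rep), rep(n_pos, 2))
  per_rep_n <- tapply(cv$folds$TN + cv$folds$FP, cv$folds$repetition, sum)
  expect_equal(as.vector(per_rep_n), rep(n_pos, 2))
  # aggregate summary is recomputable from the fold rows
  expect_equal(cv$summary$mean[cv$summary$metric == "AUC"],
               mean(cv$folds$AUC))
  # determinism of the whole CV stage
  cv2 <- suppressWarnings(cross_validate_study(prep, config = cfg, folds = 5,
                                               repetitions = 2, seed = 3))
  expect_identical(cv$folds, cv2$folds)
})

test_that("candidate ranking averages model scores with deterministic ties", {
  ds <- separable_dataset(n = 30)
  cfg <- cnn_config(n_filters = 4, kernel1 = c(2, 8), kernel2 = c(1, 4),
                    epochs = 5, seed = 2)
  model <- train_cnn(ds, cfg)
  cand <- ds
  cand$pairs$label <- NA_integer_
  r1 <- rank_candidates(list(model), cand)
  expect_equal(r1$score, sort(score_pairs(model, cand), decreasing = TRUE))
  r10 <- rank_candidates(rep(list(model), 10), cand)
  expect_equal(r10$score, r1$score, tolerance = 1e-12)
  expect_equal(r1$rank, seq_len(30))
  # a dominant pair ranks first under any model set
  cand2 <- cand
  cand2$X[4, , ] <- cand2$X[4, , ] * 0 + 5
  top_scores <- vapply(list(model), function(m) score_pairs(m, cand2),
                       numeric(30))
  expect_equal(rank_candidates(list(model), cand2)$circ[1],
               cand2$pairs$circ[which.max(rowMeans(top_scores))])
  expect_error(rank_candidates(list(model), ds), "unlabeled")
})
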