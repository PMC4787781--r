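test_that("setting (i) balances positives with random negatives", {
  set.seed(1)
  sigs <- toy_dataset(n_pos = 12L, n_neg = 40L, seed = 2)
  ds <- make_dataset(sigs, "i", seed = 3)
  expect_equal(sum(ds$label == "m1A"), 12L)
  expect_equal(sum(ds$label == "non_m1A"), 12L)
  # 45 positives + 45 negatives -> 90 instances
  big <- toy_dataset(n_pos = 45L, n_neg = 100L, seed = 4)
  expect_equal(nrow(make_dataset(big, "i", seed = 1)), 90L)
})

test_that("setting (ii) requires confusable negatives and errors without them", {
  sigs <- toy_dataset(n_pos = 10L, n_neg = 50L, seed = 5)
  # the toy negatives are null signatures: no confusables available
  expect_error(make_dataset(sigs, "ii", seed = 1), "confusable")
  # make some negatives confusable (a >= 0.2)
  idx <- which(sigs$label == "non_m1A")[1:10]
  sigs$a[idx] <- 0.3
  ds <- make_dataset(sigs, "ii", seed = 1)
  expect_equal(nrow(ds), 20L)
  expect_true(all(sigs$a[idx] >= 0.2))
})

test_that("setting (iii) keeps train and test disjoint by RNA class", {
  sigs <- toy_dataset(n_pos = 25L, n_neg = 60L, seed = 6)
  sigs$ref_id <- paste0("s", seq_len(nrow(sigs)))
  sigs$rna_class <- "tRNA"
  pos_idx <- which(sigs$label == "m1A")
  neg_idx <- which(sigs$label == "non_m1A")
  sigs$rna_class[pos_idx[21:25]] <- "rRNA"
  sigs$rna_class[neg_idx[1:20]] <- "rRNA"
  ds <- make_dataset(sigs, "iii", seed = 1)
  expect_equal(sum(ds$train$label == "m1A"), 20L)
  expect_equal(sum(ds$test$label == "m1A"), 5L)
  expect_length(intersect(ds$train$ref_id, ds$test$ref_id), 0L)
  expect_true(all(ds$train$rna_class == "tRNA"))
  expect_true(all(ds$test$rna_class == "rRNA"))
})

test_that("perfectly separable features give perfect cross-validated scores", {
  ds <- toy_dataset(n_pos = 15L, n_neg = 15L, seed = 7)
  cv <- cross_validate(ds, folds = 5, repetitions = 2, n_trees = 100,
                       seed = 8)
  expect_equal(cv$mean_sensitivity, 1)
  expect_equal(cv$mean_specificity, 1)
  expect_equal(cv$auc, 1)
  expect_equal(nrow(cv$per_fold), 10L)
})

test_that("cross-validation is reproducible from its seed", {
  ds <- toy_dataset(n_pos = 10L, n_neg = 10L, noise = 0.4, seed = 9)
  cv1 <- cross_validate(ds, repetitions = 2, n_trees = 50, seed = 11)
  cv2 <- cross_validate(ds, repetitions = 2, n_trees = 50, seed = 11)
  expect_identical(cv1$per_fold, cv2$per_fold)
  expect_identical(cv1$auc, cv2$auc)
})

test_that("stratified fold assignment preserves the class ratio within one", {
  set.seed(13)
  labels <- rep(c("m1A", "non_m1A"), times = c(45, 45))
  for (i in 1:10) {
    fa <- rtsig:::.fold_assign(labels, 5L)
    tab <- table(fa, labels)
    expect_true(all(abs(tab[, "m1A"] - tab[, "non_m1A"]) <= 1))
    expect_equal(unname(rowSums(tab)), rep(18, 5))
  }
  # uneven class sizes still differ by at most one across folds
  fa <- rtsig:::.fold_assign(rep(c("m1A", "non_m1A"), times = c(23, 23)), 5L)
  expect_true(all(diff(range(table(fa))) <= 2))
  expect_error(rtsig:::.fold_assign(rep(c("m1A", "non_m1A"),
                                        times = c(3, 45)), 5L), "fewer")
})

test_that("leave-one-out runs min(n_pos, n_neg) rounds, each instance once", {
  ds <- toy_dataset(n_pos = 4L, n_neg = 4L, seed = 15)
  loo <- leave_one_out(ds, n_trees = 50, seed = 16)
  expect_equal(loo$rounds, 4L)
  expect_equal(nrow(loo$per_round), 4L)
  expect_equal(loo$pos_accuracy, 1)
  expect_equal(loo$neg_accuracy, 1)
  expect_error(leave_one_out(toy_dataset(n_pos = 4L, n_neg = 6L, seed = 1)),
               "balanced")
})

test_that("more training instances never hurt on the same distribution", {
  big <- simulate_signature_dataset(n_sites = 45L, depth = 600,
                                    p_arrest_range = c(0.3, 0.5),
                                    occupancy_range = c(0.15, 0.45),
                                    seed = 31)
  ds_big <- make_dataset(big$signatures, "i", seed = 1)
  small_sigs <- big$signatures[
    c(which(big$signatures$label == "m1A")[1:10],
      which(big$signatures$label == "non_m1A")), ]
  ds_small <- make_dataset(small_sigs, "i", seed = 1)
  cv_big <- cross_validate(ds_big, repetitions = 5, n_trees = 200, seed = 2)
  cv_small <- cross_validate(ds_small, repetitions = 5, n_trees = 200,
                             seed = 2)
  expect_gte(cv_big$mean_sensitivity, cv_small$mean_sensitivity - 0.02)
})

test_that("leave-feature-out emits the expected combinations", {
  ds <- toy_dataset(n_pos = 10L, n_neg = 10L, seed = 17)
  single <- leave_feature_out(ds, "single", repetitions = 1, n_trees = 50,
                              seed = 18)
  expect_equal(nrow(single), 7L)
  expect_setequal(single$feature_set,
                  paste0("drop_", c("a", "m", "m_over_a", "comp_G", "comp_T",
                                    "comp_C", "csa")))
  subs <- leave_feature_out(ds, "subsets", repetitions = 1, n_trees = 50,
                            seed = 18)
  expect_setequal(subs$feature_set, c("full", "arrest_only", "mismatch_only"))
  expect_equal(subs$n_features[subs$feature_set == "full"], 7L)
  expect_equal(subs$n_features[subs$feature_set == "arrest_only"], 2L)
})

test_that("dropping a constant feature leaves performance unchanged within SD", {
  ds <- toy_dataset(n_pos = 12L, n_neg = 12L, noise = 0.25, seed = 19)
  ds$comp_G <- 0  # constant, uninformative
  full <- cross_validate(ds, repetitions = 3, n_trees = 200, seed = 20)
  wo <- cross_validate(ds, repetitions = 3, n_trees = 200, seed = 20,
                       features = setdiff(rtsig:::.signature_features,
                                          "comp_G"))
  tol <- 3 * max(full$sd_sensitivity, wo$sd_sensitivity, 0.02)
  expect_lt(abs(full$mean_sensitivity - wo$mean_sensitivity), tol)
})

test_that("the kNN baseline shares the harness and rejects oversized k", {
  ds <- toy_dataset(n_pos = 10L, n_neg = 10L, seed = 21)
  knn <- knn_baseline(ds, k = 1, folds = 5, repetitions = 2, seed = 22)
  expect_equal(knn$mean_sensitivity, 1)
  expect_equal(knn$auc, 1)
  expect_error(knn_baseline(ds, k = 20, folds = 5, repetitions = 1,
                            seed = 1), "smaller")
})

test_that("trapezoid AUC matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:5) {
    score <- runif(60)
    truth <- runif(60) < plogis(4 * score - 2)
    if (!any(truth) || all(truth)) next
    ours <- attr(roc_points(score, truth), "auc")
    theirs <- as.numeric(pROC::auc(pROC::roc(response = truth,
                                             predictor = score,
                                             quiet = TRUE,
                                             direction = "<")))
    expect_equal(ours, theirs, tolerance = 1e-9)
  }
})

test_that("ROC endpoints and separable AUC behave canonically", {
  score <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  roc <- roc_points(score, truth)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_equal(attr(roc, "auc"), 1)
})

test_that("holdout evaluation scores a held-out set", {
  train <- toy_dataset(n_pos = 15L, n_neg = 15L, seed = 25)
  test <- toy_dataset(n_pos = 5L, n_neg = 5L, seed = 26)
  ev <- evaluate_holdout(train, test, n_trees = 100, seed = 27)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
})

test_that("random forest outperforms kNN on noisy overlapping data in most seeds", {
  sim <- simulate_signature_dataset(n_sites = 30L, depth = 400,
                                    p_arrest_range = c(0.2, 0.45),
                                    occupancy_range = c(0.1, 0.4),
                                    seed = 41)
  wins <- 0L
  for (s in 1:10) {
    ds <- make_dataset(sim$signatures, "i", seed = s)
    rf <- cross_validate(ds, repetitions = 1, n_trees = 200, seed = s)
    knn_aucs <- vapply(c(1, 3, 5), function(k) {
      knn_baseline(ds, k = k, repetitions = 1, seed = s)$auc
    }, 0)
    if (rf$auc >= max(knn_aucs)) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
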