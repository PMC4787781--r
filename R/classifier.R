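#' Assemble a labeled dataset under one of the three validation settings
#'
#' Setting (i): all positives are merged with an equal number of negatives
#' drawn uniformly at random from the non-m1A pool. Setting (ii): like (i)
#' but the negative pool is restricted to records with a minimum m1A
#' signature resemblance ([is_confusable_negative()]). Setting (iii): the
#' training set is built from tRNA-class instances (positives plus equal
#' random tRNA-class negatives) and the test set from rRNA-class instances
#' exclusively, so train and test are disjoint by RNA class.
#'
#' @param signatures labeled signature data.frame (`label` in
#'   `"m1A"`/`"non_m1A"`; setting (iii) additionally needs an `rna_class`
#'   column with values like `"tRNA"`/`"rRNA"`).
#' @param setting `"i"`, `"ii"` or `"iii"`.
#' @param seed seed for the negative sampling.
#' @return for settings (i)/(ii), a data.frame of class `rt_dataset`
#'   (balanced); for (iii), a list with `train` and `test` datasets.
#' @export
make_dataset <- function(signatures, setting = c("i", "ii", "iii"), seed = 1L) {
  setting <- match.arg(setting)
  stopifnot("label" %in% names(signatures))
  miss <- setdiff(.signature_features, names(signatures))
  if (length(miss)) {
    stop("signatures lack feature column(s): ", paste(miss, collapse = ", "))
  }
  set.seed(seed)

  balance <- function(pos, neg, what) {
    if (nrow(neg) < nrow(pos)) {
      stop("insufficient ", what, ": ", nrow(pos), " positives but only ",
           nrow(neg), " available negatives")
    }
    neg <- neg[sample.int(nrow(neg), nrow(pos)), , drop = FALSE]
    out <- rbind(pos, neg)
    rownames(out) <- NULL
    class(out) <- c("rt_dataset", "data.frame")
    out
  }

  pos <- signatures[signatures$label == "m1A", , drop = FALSE]
  neg <- signatures[signatures$label == "non_m1A", , drop = FALSE]
  if (!nrow(pos)) stop("no m1A instances in the signature table")

  if (setting == "i") {
    balance(pos, neg, "random negatives")
  } else if (setting == "ii") {
    balance(pos, neg[is_confusable_negative(neg), , drop = FALSE],
            "confusable negatives")
  } else {
    if (!"rna_class" %in% names(signatures)) {
      stop("setting (iii) requires an rna_class column")
    }
    train <- balance(pos[pos$rna_class == "tRNA", , drop = FALSE],
                     neg[neg$rna_class == "tRNA", , drop = FALSE],
                     "tRNA-class negatives")
    test <- balance(pos[pos$rna_class == "rRNA", , drop = FALSE],
                    neg[neg$rna_class == "rRNA", , drop = FALSE],
                    "rRNA-class negatives")
    list(train = train, test = test)
  }
}

.check_dataset <- function(dataset, features) {
  stopifnot(is.data.frame(dataset), "label" %in% names(dataset))
  miss <- setdiff(features, names(dataset))
  if (length(miss)) {
    stop("dataset lacks feature column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(dataset$label %in% c("m1A", "non_m1A"))) {
    stop("labels must be m1A / non_m1A")
  }
  if (any(!is.finite(as.matrix(dataset[, features])))) {
    stop("non-finite feature values; apply the epsilon guards upstream")
  }
}

.fit_predict <- function(train, test, features, model, n_trees, k) {
  y <- factor(train$label, levels = c("non_m1A", "m1A"))
  if (model == "rf") {
    fit <- randomForest::randomForest(x = train[, features, drop = FALSE],
                                      y = y, ntree = n_trees)
    score <- predict(fit, test[, features, drop = FALSE],
                     type = "prob")[, "m1A"]
    imp <- randomForest::importance(fit)[, 1L]
  } else {
    if (k >= nrow(train)) {
      stop("k (", k, ") must be smaller than the training-set size (",
           nrow(train), ")")
    }
    pr <- class::knn(scale_to(train, train, features),
                     scale_to(train, test, features),
                     cl = y, k = k, prob = TRUE)
    win <- attr(pr, "prob")
    score <- ifelse(pr == "m1A", win, 1 - win)
    imp <- NULL
  }
  # majority vote; exact ties called non_m1A (conservative)
  pred <- ifelse(score > 0.5, "m1A", "non_m1A")
  list(score = score, pred = pred, importance = imp)
}

# z-scale features on training statistics so the kNN euclidean metric is not
# dominated by the wide-range ratio features
scale_to <- function(train, x, features) {
  mu <- vapply(train[, features, drop = FALSE], mean, 0)
  sg <- vapply(train[, features, drop = FALSE], sd, 0)
  sg[sg == 0] <- 1
  scale(as.matrix(x[, features, drop = FALSE]), center = mu, scale = sg)
}

.fold_assign <- function(labels, folds) {
  f <- integer(length(labels))
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    if (length(i) < folds) {
      stop("class ", cl, " has fewer instances (", length(i),
           ") than folds (", folds, ")")
    }
    f[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  f
}

#' Repeated stratified cross-validation
#'
#' Ten repetitions of a five-fold stratified cross-validation of a 500-tree
#' random forest are the default evaluation harness. Folds preserve the class
#' ratio within one instance; in each repetition the model is trained on four
#' fifths and tested on the held-out fifth, rotating. Sensitivity is the
#' recall of the m1A class, specificity that of the non-m1A class. Ties in
#' the class vote are called non-m1A.
#'
#' @param dataset balanced `rt_dataset` (or any labeled data.frame).
#' @param folds number of folds (default 5).
#' @param repetitions number of repetitions (default 10).
#' @param n_trees random-forest size (default 500).
#' @param seed RNG seed; identical seeds give identical reports.
#' @param model `"rf"` or `"knn"`.
#' @param k neighbor count for `model = "knn"`.
#' @param features feature columns (default: the 7-feature signature set).
#' @return an `rt_cv_report`: list with `per_fold` (repetition, fold,
#'   sensitivity, specificity), `mean_sensitivity`, `sd_sensitivity`,
#'   `mean_specificity`, `sd_specificity`, pooled out-of-fold `roc` points,
#'   `auc`, mean random-forest `importance`, and the configuration echo.
#' @export
cross_validate <- function(dataset, folds = 5L, repetitions = 10L,
                           n_trees = 500L, seed = 1L,
                           model = c("rf", "knn"), k = 5L,
                           features = .signature_features) {
  model <- match.arg(model)
  .check_dataset(dataset, features)
  set.seed(seed)
  per_fold <- list()
  scores <- list()
  imps <- list()
  for (rep_i in seq_len(repetitions)) {
    fa <- .fold_assign(dataset$label, folds)
    for (fold_i in seq_len(folds)) {
      test_idx <- which(fa == fold_i)
      fit <- .fit_predict(dataset[-test_idx, , drop = FALSE],
                          dataset[test_idx, , drop = FALSE],
                          features, model, n_trees, k)
      truth <- dataset$label[test_idx]
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        repetition = rep_i, fold = fold_i,
        sensitivity = mean(fit$pred[truth == "m1A"] == "m1A"),
        specificity = mean(fit$pred[truth == "non_m1A"] == "non_m1A")
      )
      scores[[length(scores) + 1L]] <- data.frame(score = fit$score,
                                                  truth = truth)
      if (!is.null(fit$importance)) imps[[length(imps) + 1L]] <- fit$importance
    }
  }
  per_fold <- do.call(rbind, per_fold)
  pooled <- do.call(rbind, scores)
  roc <- roc_points(pooled$score, pooled$truth == "m1A")
  structure(list(
    per_fold = per_fold,
    mean_sensitivity = mean(per_fold$sensitivity),
    sd_sensitivity = sd(per_fold$sensitivity),
    mean_specificity = mean(per_fold$specificity),
    sd_specificity = sd(per_fold$specificity),
    roc = roc,
    auc = attr(roc, "auc"),
    importance = if (length(imps)) Reduce(`+`, imps) / length(imps),
    config = list(model = model, folds = folds, repetitions = repetitions,
                  n_trees = n_trees, k = if (model == "knn") k else NA,
                  seed = seed, features = features,
                  n_instances = nrow(dataset))
  ), class = "rt_cv_report")
}

#' @export
print.rt_cv_report <- function(x, ...) {
  cat(sprintf(
    "%s cross-validation: %d x %d-fold on %d instances\n",
    toupper(x$config$model), x$config$repetitions, x$config$folds,
    x$config$n_instances))
  cat(sprintf("  sensitivity %.3f (SD %.3f)\n  specificity %.3f (SD %.3f)\n",
              x$mean_sensitivity, x$sd_sensitivity,
              x$mean_specificity, x$sd_specificity))
  cat(sprintf("  AUC %.4f\n", x$auc))
  invisible(x)
}

#' Empirical ROC curve and trapezoid AUC
#'
#' Built by thresholding the out-of-fold positive-class vote fractions; the
#' area is the trapezoid integral over the empirical curve and equals the
#' probability that a random positive scores above a random negative (ties
#' counted half).
#'
#' @param score numeric scores, higher = more m1A-like.
#' @param is_pos logical truth.
#' @return data.frame with `threshold`, `fpr`, `tpr`, ordered from (0,0) to
#'   (1,1), with the AUC as attribute `"auc"`.
#' @export
roc_points <- function(score, is_pos) {
  stopifnot(length(score) == length(is_pos), any(is_pos), any(!is_pos))
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(score[is_pos] >= t), 0)
  fpr <- vapply(thr, function(t) mean(score[!is_pos] >= t), 0)
  out <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (out$fpr[nrow(out)] < 1 || out$tpr[nrow(out)] < 1) {
    out <- rbind(out, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(out$fpr) * (head(out$tpr, -1) + out$tpr[-1]) / 2)
  attr(out, "auc") <- auc
  out
}

#' Leave-one-out cross-validation over balanced pairs
#'
#' Each round holds out one positive and one negative instance (the
#' stratification concept with the fold count maximally increased); the
#' model is trained on the remainder and the pair is classified. There are
#' exactly `min(n_pos, n_neg)` rounds and every instance is tested once.
#'
#' @inheritParams cross_validate
#' @return list with `rounds`, `pos_accuracy`, `neg_accuracy` and the
#'   `per_round` data.frame.
#' @export
leave_one_out <- function(dataset, n_trees = 500L, seed = 1L,
                          features = .signature_features) {
  .check_dataset(dataset, features)
  n_pos <- sum(dataset$label == "m1A")
  n_neg <- sum(dataset$label == "non_m1A")
  if (n_pos != n_neg) {
    stop("leave-one-out expects a balanced dataset (", n_pos, " vs ",
         n_neg, ")")
  }
  set.seed(seed)
  pos_idx <- sample(which(dataset$label == "m1A"))
  neg_idx <- sample(which(dataset$label == "non_m1A"))
  rounds <- min(n_pos, n_neg)
  per_round <- do.call(rbind, lapply(seq_len(rounds), function(i) {
    test_idx <- c(pos_idx[i], neg_idx[i])
    fit <- .fit_predict(dataset[-test_idx, , drop = FALSE],
                        dataset[test_idx, , drop = FALSE],
                        features, "rf", n_trees, NA)
    data.frame(round = i,
               pos_correct = fit$pred[1L] == "m1A",
               neg_correct = fit$pred[2L] == "non_m1A")
  }))
  list(rounds = rounds,
       pos_accuracy = mean(per_round$pos_correct),
       neg_accuracy = mean(per_round$neg_correct),
       per_round = per_round)
}

#' Leave-feature-out analysis
#'
#' Mode `"single"` drops one feature at a time from the 7-feature set; mode
#' `"subsets"` evaluates the full set against the arrest-only features
#' (`a`, `csa`) and the mismatch-only features (`m`, `comp_G`, `comp_T`,
#' `comp_C`), quantifying how much each signature component contributes.
#' Each combination is scored with [cross_validate()].
#'
#' @inheritParams cross_validate
#' @param mode `"single"` or `"subsets"`.
#' @return data.frame with `feature_set`, `n_features`, `mean_sensitivity`,
#'   `mean_specificity`.
#' @export
leave_feature_out <- function(dataset, mode = c("single", "subsets"),
                              folds = 5L, repetitions = 10L, n_trees = 500L,
                              seed = 1L, features = .signature_features) {
  mode <- match.arg(mode)
  if (length(features) < 2L) stop("need at least two features")
  sets <- if (mode == "single") {
    out <- lapply(features, function(f) setdiff(features, f))
    names(out) <- paste0("drop_", features)
    out
  } else {
    list(full = features,
         arrest_only = intersect(c("a", "csa"), features),
         mismatch_only = intersect(c("m", "comp_G", "comp_T", "comp_C"),
                                   features))
  }
  do.call(rbind, lapply(names(sets), function(nm) {
    cv <- cross_validate(dataset, folds = folds, repetitions = repetitions,
                         n_trees = n_trees, seed = seed, features = sets[[nm]])
    data.frame(feature_set = nm, n_features = length(sets[[nm]]),
               mean_sensitivity = cv$mean_sensitivity,
               mean_specificity = cv$mean_specificity,
               stringsAsFactors = FALSE)
  }))
}

#' kNN baseline under the same cross-validation harness
#'
#' @inheritParams cross_validate
#' @return an `rt_cv_report` (see [cross_validate()]).
#' @export
knn_baseline <- function(dataset, k = 5L, folds = 5L, repetitions = 10L,
                         seed = 1L, features = .signature_features) {
  cross_validate(dataset, folds = folds, repetitions = repetitions,
                 seed = seed, model = "knn", k = k, features = features)
}

#' Train on one dataset, evaluate on a held-out one
#'
#' Used for validation setting (iii): train on tRNA-class instances, test on
#' the rRNA-class set.
#'
#' @param train,test labeled datasets (see [make_dataset()]).
#' @inheritParams cross_validate
#' @return list with `sensitivity`, `specificity`, `scores`.
#' @export
evaluate_holdout <- function(train, test, n_trees = 500L, seed = 1L,
                             features = .signature_features) {
  .check_dataset(train, features)
  .check_dataset(test, features)
  set.seed(seed)
  fit <- .fit_predict(train, test, features, "rf", n_trees, NA)
  truth <- test$label
  list(sensitivity = mean(fit$pred[truth == "m1A"] == "m1A"),
       specificity = mean(fit$pred[truth == "non_m1A"] == "non_m1A"),
       scores = data.frame(score = fit$score, truth = truth))
}
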