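#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen case
#' receives a higher score than a randomly chosen control, with ties counted
#' as 1/2. Computed from mid-ranks, so it is exact.
#'
#' @param scores Numeric prediction scores (higher = more case-like).
#' @param labels Character/factor labels, `"case"` / `"control"`; both must
#'   be present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_score(c(0.9, 0.4, 0.6, 0.1), c("case", "case", "control", "control"))
#' @export
auc_score <- function(scores, labels) {
  labels <- as.character(labels)
  assert_that(all(labels %in% c("case", "control")),
              "labels must be 'case' or 'control'")
  n1 <- sum(labels == "case")
  n0 <- sum(labels == "control")
  assert_that(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(scores)
  (sum(r[labels == "case"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold ids: within each class, samples are shuffled and dealt
# round-robin into folds, keeping per-fold class proportions within one
# sample of the global proportions.
stratified_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (lev in unique(labels)) {
    idx <- sample(which(labels == lev))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Repeated cross-validated random-forest AUC and feature ranking
#'
#' Trains a random forest (500 trees by default) under `n_repeats` repeats
#' of stratified `n_folds`-fold cross-validation. Each held-out fold is
#' scored by the out-of-fold predicted case probability and its AUC
#' recorded; permutation importance (mean decrease in accuracy, MDA) is
#' collected per fold and features are ranked by the average MDA over all
#' `n_repeats * n_folds` folds.
#'
#' @param features Numeric matrix samples x features (signature vOTU
#'   abundances), with rownames = sample ids.
#' @param labels Character vector `"case"` / `"control"` per sample.
#' @param n_repeats,n_folds Cross-validation design (default 5 x 5).
#' @param seed Integer seed; the whole procedure is reproducible given
#'   (data, seed).
#' @param ntree Number of trees (default 500).
#' @return An object of class `virosig_cv`: list with `mean_auc`,
#'   `fold_aucs` (tibble repeat/fold/auc), `feature_ranking` (tibble ordered
#'   by decreasing mean MDA) and the design parameters.
#' @export
cv_auc <- function(features, labels, n_repeats = 5, n_folds = 5, seed = 1,
                   ntree = 500) {
  labels <- as.character(labels)
  assert_that(all(labels %in% c("case", "control")),
              "labels must be 'case' or 'control'")
  assert_that(all(c("case", "control") %in% labels) &&
                min(table(labels)) >= n_folds,
              "each class needs at least n_folds samples for stratification")
  features <- as.matrix(features)
  y <- factor(labels, levels = c("control", "case"))

  fold_rows <- list()
  mda <- matrix(0, nrow = ncol(features),
                ncol = 0, dimnames = list(colnames(features), NULL))
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      folds <- stratified_folds(labels, n_folds)
      for (f in seq_len(n_folds)) {
        train <- folds != f
        fit <- randomForest::randomForest(
          x = features[train, , drop = FALSE], y = y[train],
          ntree = ntree, importance = TRUE
        )
        prob <- predict(fit, features[!train, , drop = FALSE],
                        type = "prob")[, "case"]
        fold_rows[[length(fold_rows) + 1]] <- tibble::tibble(
          repeat_id = r, fold_id = f,
          auc = auc_score(prob, labels[!train])
        )
        mda <- cbind(mda, randomForest::importance(fit, type = 1)[, 1])
      }
    }
  })
  fold_aucs <- dplyr::bind_rows(fold_rows)
  ranking <- tibble::tibble(
    feature = rownames(mda),
    mean_mda = rowMeans(mda)
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_mda), .data$feature)
  structure(list(mean_auc = mean(fold_aucs$auc),
                 fold_aucs = fold_aucs,
                 feature_ranking = ranking,
                 n_repeats = n_repeats, n_folds = n_folds,
                 seed = seed, ntree = ntree),
            class = "virosig_cv")
}

#' @export
print.virosig_cv <- function(x, ...) {
  cat(sprintf("Random-forest CV (%dx%d-fold, %d trees): mean AUC = %.3f\n",
              x$n_repeats, x$n_folds, x$ntree, x$mean_auc))
  cat("Top features:",
      paste(head(x$feature_ranking$feature, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.virosig_cv <- function(x, ...) x$feature_ranking

#' @export
glance.virosig_cv <- function(x, ...) {
  tibble::tibble(mean_auc = x$mean_auc,
                 sd_auc = sd(x$fold_aucs$auc),
                 n_folds_total = nrow(x$fold_aucs))
}

#' Union of per-dataset top-k features
#'
#' @param rankings A list of feature rankings (character vectors ordered by
#'   importance, or `virosig_cv` objects).
#' @param k Number of top features taken from each ranking (default 5).
#' @return Sorted character vector: the union of each dataset's top-k
#'   features.
#' @export
top_union <- function(rankings, k = 5) {
  assert_that(is_count(k) && k >= 1, "k must be a positive integer")
  tops <- purrr::map(rankings, function(r) {
    if (inherits(r, "virosig_cv")) r <- r$feature_ranking$feature
    assert_that(length(r) > 0, "empty feature ranking")
    head(r, k)
  })
  sort(unique(unlist(tops)))
}

rf_train_predict <- function(train_x, train_y, test_x, seed, ntree = 500) {
  with_seed(seed, {
    fit <- randomForest::randomForest(
      x = train_x, y = factor(train_y, levels = c("control", "case")),
      ntree = ntree
    )
    predict(fit, test_x, type = "prob")[, "case"]
  })
}

check_bundles <- function(bundles, features) {
  assert_that(length(bundles) >= 2, "need at least 2 dataset bundles")
  for (nm in names(bundles)) {
    b <- bundles[[nm]]
    missing <- setdiff(features, colnames(b$features))
    assert_that(length(missing) == 0,
                paste0("features missing in dataset ", nm, ": ",
                       paste(missing, collapse = ", ")))
    assert_that(all(c("case", "control") %in% b$labels),
                paste0("dataset ", nm, " must contain both classes"))
  }
  invisible(TRUE)
}

#' Cross-dataset AUC matrix
#'
#' Entry (i, j) with i != j is the AUC of a random forest trained on the
#' full dataset i and evaluated on dataset j; the diagonal holds each
#' dataset's repeated-CV mean AUC.
#'
#' @param bundles Named list of dataset bundles; each bundle is a list with
#'   `features` (samples x features matrix) and `labels`.
#' @param features Character vector of features to use (present in every
#'   bundle).
#' @param seed Integer seed.
#' @param ntree Number of trees.
#' @return Square numeric matrix with dataset ids as dimnames.
#' @export
cross_dataset_auc <- function(bundles, features, seed = 1, ntree = 500) {
  check_bundles(bundles, features)
  ids <- names(bundles)
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in ids) {
    bi <- bundles[[i]]
    for (j in ids) {
      if (i == j) {
        m[i, j] <- cv_auc(bi$features[, features, drop = FALSE], bi$labels,
                          seed = child_seed(seed, paste0("cv:", i)),
                          ntree = ntree)$mean_auc
      } else {
        bj <- bundles[[j]]
        prob <- rf_train_predict(bi$features[, features, drop = FALSE],
                                 bi$labels,
                                 bj$features[, features, drop = FALSE],
                                 seed = child_seed(seed, paste0(i, "->", j)),
                                 ntree = ntree)
        m[i, j] <- auc_score(prob, bj$labels)
      }
    }
  }
  m
}

#' Leave-one-dataset-out AUC
#'
#' For each dataset, trains a random forest on the concatenation of all
#' other datasets and evaluates the AUC on the held-out dataset.
#'
#' @inheritParams cross_dataset_auc
#' @return A tibble `dataset_id`, `auc`, one row per held-out dataset.
#' @export
lodo_auc <- function(bundles, features, seed = 1, ntree = 500) {
  assert_that(length(bundles) >= 3, "LODO needs at least 3 dataset bundles")
  check_bundles(bundles, features)
  rows <- purrr::map(names(bundles), function(held) {
    others <- bundles[setdiff(names(bundles), held)]
    train_x <- do.call(rbind, purrr::map(others, \(b)
      b$features[, features, drop = FALSE]))
    train_y <- unlist(purrr::map(others, "labels"), use.names = FALSE)
    test <- bundles[[held]]
    prob <- rf_train_predict(train_x, train_y,
                             test$features[, features, drop = FALSE],
                             seed = child_seed(seed, paste0("lodo:", held)),
                             ntree = ntree)
    tibble::tibble(dataset_id = held, auc = auc_score(prob, test$labels))
  })
  dplyr::bind_rows(rows)
}
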