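# End-to-end evaluation protocol: mean imputation, 3-sigma outlier-row
# removal, stratified 70/30 split, grid search with 5-fold CV (optionally
# OBL+ARA hyperparameter tuning), classification metrics, top-k precision,
# and the feature-ranking-vs-ground-truth effect report.

#' Preprocess a feature table: impute means, drop 3-sigma outlier rows
#'
#' Missing cells are imputed with their column mean first; then any row with
#' at least one cell beyond 3 SDs of its (post-imputation) column mean is
#' removed. Column statistics are computed once, not re-screened
#' iteratively. The label column, if provided, is carried through untouched.
#'
#' @param table Data frame of numeric feature columns, or a
#'   `"labeled_dataset"`.
#' @param labels Optional label vector (taken from the dataset if one is
#'   given).
#' @param z_cutoff Outlier threshold in column SDs (default 3).
#' @return A list of class `"preprocess_result"`: `features`, `labels`
#'   (filtered), and `report` with `imputed_per_column`, `removed_rows`
#'   (indices into the input), `column_mean`, `column_sd`.
#' @export
preprocess <- function(table, labels = NULL, z_cutoff = 3) {
  if (inherits(table, "labeled_dataset")) {
    labels <- table$labels
    table <- table$features
  }
  X <- as.matrix(table)
  if (!is.numeric(X)) stop("feature columns must be numeric", call. = FALSE)
  all_missing <- colSums(!is.na(X)) == 0
  if (any(all_missing)) {
    stop(sprintf("column(s) entirely missing: %s",
                 paste(colnames(X)[all_missing], collapse = ", ")),
         call. = FALSE)
  }
  imputed_per_column <- colSums(is.na(X))
  for (j in which(imputed_per_column > 0)) {
    m <- mean(X[, j], na.rm = TRUE)
    X[is.na(X[, j]), j] <- m
  }
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  z <- sweep(sweep(X, 2, mu), 2, ifelse(sdev > 0, sdev, 1), "/")
  bad_row <- rowSums(abs(z) > z_cutoff) > 0
  structure(
    list(features = as.data.frame(X[!bad_row, , drop = FALSE]),
         labels = if (!is.null(labels)) labels[!bad_row] else NULL,
         report = list(imputed_per_column = imputed_per_column,
                       removed_rows = which(bad_row),
                       n_removed = sum(bad_row),
                       column_mean = mu, column_sd = sdev)),
    class = "preprocess_result")
}

#' Stratified train/test split
#'
#' Splits rows into train and test, stratified by label: each class
#' contributes `round(ratio * n_class)` rows to the training side, so a
#' 70/30 split of 1500 balanced rows gives exactly 1050/450.
#'
#' @param n Number of rows, or a label vector (stratification requires the
#'   labels).
#' @param labels Label vector (required when `n` is a count).
#' @param ratio Training fraction, strictly inside (0, 1).
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `test` (disjoint,
#'   union = all rows).
#' @export
train_test_split <- function(labels, ratio = 0.7, seed = 0) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must be inside (0, 1)", call. = FALSE)
  labels <- factor(labels)
  n <- length(labels)
  with_local_seed(seed, {
    train <- integer(0)
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      n_tr <- round(ratio * length(idx))
      if (n_tr == 0 || n_tr == length(idx)) {
        warning(sprintf("class '%s' absent from one side of the split", lv))
      }
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

# Stratified k-fold assignment (1..k per row), seeded.
make_folds <- function(labels, k_folds, seed) {
  labels <- factor(labels)
  folds <- integer(length(labels))
  with_local_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      folds[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
    }
  })
  folds
}

# Mean held-out-fold accuracy of a forest config on (X, y).
cv_accuracy <- function(X, y, config, k_folds = 5, seed = 0,
                        folds = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  if (is.null(folds)) folds <- make_folds(y, k_folds, seed)
  accs <- numeric(max(folds))
  for (fo in seq_len(max(folds))) {
    tr <- folds != fo
    if (nlevels(droplevels(y[!tr])) < 2) {
      warning(sprintf("fold %d holds a single class", fo))
    }
    cfg <- config
    cfg$seed <- config$seed + 7919L * fo
    fit <- weighted_rf(X[tr, , drop = FALSE], y[tr], cfg)
    pred <- predict(fit, X[!tr, , drop = FALSE])
    accs[fo] <- mean(pred == y[!tr])
  }
  mean(accs)
}

#' Grid search over forest size and depth with k-fold cross-validation
#'
#' Evaluates every `(n_trees, max_depth)` cell of the grid by mean held-out
#' fold accuracy over stratified folds; the folds are built once and shared
#' by all cells, so cell comparisons are paired. The best cell attains the
#' maximum mean accuracy; ties prefer fewer trees, then shallower depth.
#'
#' @param data A `"labeled_dataset"` or feature matrix/data frame.
#' @param labels Labels when `data` is a matrix.
#' @param n_trees_grid,max_depth_grid Candidate values (defaults are the
#'   protocol grid 50/100/150/200 trees by depth 10/20/30/40).
#' @param k_folds Number of folds (default 5).
#' @param seed Integer seed for folds and forests.
#' @param config Base [forest_config()] supplying the non-grid parameters.
#' @return A list of class `"grid_search_result"`: `grid` (data frame of
#'   `n_trees`, `max_depth`, `cv_accuracy`), `best` (the winning row),
#'   `best_config` (a [forest_config()]).
#' @export
grid_search <- function(data, labels = NULL,
                        n_trees_grid = c(50, 100, 150, 200),
                        max_depth_grid = c(10, 20, 30, 40),
                        k_folds = 5, seed = 0, config = forest_config()) {
  if (k_folds < 2) stop("k_folds must be >= 2", call. = FALSE)
  xy <- resolve_xy(data, labels)
  folds <- make_folds(xy$y, k_folds, seed)
  grid <- expand.grid(n_trees = n_trees_grid, max_depth = max_depth_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$n_trees <- as.integer(grid$n_trees[i])
    cfg$max_depth <- as.integer(grid$max_depth[i])
    cfg$seed <- as.integer(seed)
    grid$cv_accuracy[i] <- cv_accuracy(xy$X, xy$y, cfg, folds = folds)
  }
  ord <- order(-grid$cv_accuracy, grid$n_trees, grid$max_depth)
  best <- grid[ord[1], ]
  best_config <- config
  best_config$n_trees <- as.integer(best$n_trees)
  best_config$max_depth <- as.integer(best$max_depth)
  best_config$seed <- as.integer(seed)
  structure(list(grid = grid, best = best, best_config = best_config),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat("Grid search (mean CV accuracy):\n")
  print(x$grid, row.names = FALSE)
  cat(sprintf("best: n_trees = %d, max_depth = %d (accuracy %.4f)\n",
              x$best$n_trees, x$best$max_depth, x$best$cv_accuracy))
  invisible(x)
}

#' Tune forest hyperparameters with the OBL+ARA optimizer
#'
#' Minimizes `1 - mean CV accuracy` over a continuous box covering
#' `(n_trees, max_depth, features_per_split)`; positions are rounded to
#' integers before each evaluation and repeated integer configurations are
#' memoized, so the optimizer's real evaluation count is the number of
#' distinct configurations visited.
#'
#' @param data A `"labeled_dataset"` or feature matrix.
#' @param labels Labels when `data` is a matrix.
#' @param lower,upper Bounds for `(n_trees, max_depth, features_per_split)`.
#' @param budget Total optimizer iterations; must allow at least one
#'   iteration for the configured population.
#' @param k_folds CV folds for the objective.
#' @param seed Integer seed (folds, forests and optimizer).
#' @param opt_config An [optimizer_config()]; its `iterations` and `seed`
#'   are overridden by `budget` and `seed`.
#' @return A list: `config` (best [forest_config()]), `cv_accuracy`,
#'   `trace` (the optimizer's convergence trace), `n_distinct_configs`.
#' @export
tune_with_ara <- function(data, labels = NULL,
                          lower = c(25, 4, 2), upper = c(200, 40, 10),
                          budget = 20, k_folds = 5, seed = 0,
                          opt_config = optimizer_config(population = 8,
                                                        pool_capacity = 6)) {
  xy <- resolve_xy(data, labels)
  if (budget < 1) stop("budget must allow at least one iteration", call. = FALSE)
  # degenerate box: bounds pin a single integer config, nothing to search
  if (all(round(lower) == round(upper))) {
    v <- round(lower)
    v[3] <- min(v[3], ncol(xy$X))
    cfg <- forest_config(n_trees = v[1], max_depth = v[2],
                         features_per_split = v[3], seed = seed)
    acc <- cv_accuracy(xy$X, xy$y, cfg, k_folds = k_folds, seed = seed)
    return(list(config = cfg, cv_accuracy = acc, trace = NULL,
                n_distinct_configs = 1L))
  }
  space <- search_space(lower, upper)
  upper_mtry <- min(upper[3], ncol(xy$X))
  folds <- make_folds(xy$y, k_folds, seed)
  cache <- new.env(parent = emptyenv())
  evaluate_config <- function(v) {
    v <- round(v)
    v[3] <- min(v[3], ncol(xy$X))
    key <- paste(v, collapse = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- forest_config(n_trees = v[1], max_depth = v[2],
                         features_per_split = v[3], seed = seed)
    acc <- cv_accuracy(xy$X, xy$y, cfg, folds = folds)
    cache[[key]] <- 1 - acc
    cache[[key]]
  }
  opt_config$iterations <- as.integer(budget)
  opt_config$seed <- as.integer(seed)
  trace <- ara_optimize(evaluate_config, space, opt_config)
  v <- round(trace$best_position)
  v[3] <- min(v[3], ncol(xy$X))
  best <- forest_config(n_trees = v[1], max_depth = v[2],
                        features_per_split = v[3], seed = seed)
  list(config = best, cv_accuracy = 1 - trace$final_fitness, trace = trace,
       n_distinct_configs = length(ls(cache)))
}

#' Binary classification metrics from true and predicted labels
#'
#' Accuracy, precision, recall and F1 for an explicit positive class,
#' computed from the confusion table. When a denominator is zero (for
#' example, nothing predicted positive), the affected metric is reported as
#' 0 and flagged in `degenerate`.
#'
#' @param truth,predicted Label vectors of equal length.
#' @param positive The positive class label (default: the second factor
#'   level, i.e. `"competition"` for generated data).
#' @return A list of class `"metrics_report"`: `accuracy`, `precision`,
#'   `recall`, `f1`, `confusion` (TP/FP/FN/TN), `positive`, `degenerate`.
#' @export
compute_metrics <- function(truth, predicted, positive = NULL) {
  truth <- factor(truth)
  if (is.null(positive)) positive <- levels(truth)[nlevels(truth)]
  predicted <- factor(predicted, levels = levels(truth))
  if (anyNA(predicted)) stop("predicted contains labels unseen in truth", call. = FALSE)
  if (length(truth) != length(predicted)) stop("length mismatch", call. = FALSE)
  tp <- sum(truth == positive & predicted == positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  tn <- sum(truth != positive & predicted != positive)
  degenerate <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    degenerate <- c(degenerate, "precision"); 0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    degenerate <- c(degenerate, "recall"); 0
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    degenerate <- c(degenerate, "f1"); 0
  }
  structure(
    list(accuracy = (tp + tn) / length(truth), precision = precision,
         recall = recall, f1 = f1,
         confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
         positive = positive, degenerate = degenerate),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f (positive = %s)\n",
              x$accuracy, x$precision, x$recall, x$f1, x$positive))
  if (length(x$degenerate) > 0) {
    cat("  degenerate (reported as 0):", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Top-k precision of a feature ranking against ground truth
#'
#' The fraction of the `k_cut` highest-ranked features that belong to the
#' ground-truth influential set: matches / selected.
#'
#' @param ranked Character vector of features, best first.
#' @param truth Character vector of truly influential features (non-empty).
#' @param k_cut Cut-off; at most `length(ranked)`.
#' @return Precision in `[0, 1]`.
#' @export
topk_precision <- function(ranked, truth, k_cut) {
  if (length(truth) == 0) stop("truth set is empty", call. = FALSE)
  if (k_cut < 1 || k_cut > length(ranked)) {
    stop("k_cut must be between 1 and the number of ranked features", call. = FALSE)
  }
  sum(ranked[seq_len(k_cut)] %in% truth) / k_cut
}

#' Full effect report: ranking, similarity, top-k precision, metrics
#'
#' Combines the forest's normalized importance ranking, pairwise Pearson
#' similarity among the top-ranked indicators, top@3/5/10 precision against
#' the planted ground truth (when available), and classification metrics on
#' a held-out test set (when given).
#'
#' @param forest A fitted [weighted_rf()].
#' @param data The data the forest was trained on (for similarity
#'   computations); a `"labeled_dataset"` or matrix.
#' @param labels Labels when `data` is a matrix.
#' @param truth Character vector of ground-truth influential features, or
#'   `NULL` for real data (the top-k section is then omitted).
#' @param test_data,test_labels Optional held-out data for metrics.
#' @param top_n Number of top features for the similarity block.
#' @return A list of class `"evaluation_report"`: `importance` (ranking data
#'   frame), `similarity` (correlation matrix of the top features),
#'   `topk` (named vector, or `NULL`), `metrics` (or `NULL`).
#' @export
effect_report <- function(forest, data, labels = NULL, truth = NULL,
                          test_data = NULL, test_labels = NULL, top_n = 5) {
  xy <- resolve_xy(data, labels)
  imp <- importance(forest)
  ranked <- imp$feature
  top <- ranked[seq_len(min(top_n, length(ranked)))]
  sim <- matrix(1, length(top), length(top), dimnames = list(top, top))
  for (i in seq_along(top)) {
    for (j in seq_along(top)) {
      if (i < j) {
        r <- pearson_correlation(xy$X[, top[i]], xy$X[, top[j]])$coefficient
        sim[i, j] <- sim[j, i] <- r
      }
    }
  }
  topk <- NULL
  if (!is.null(truth) && length(truth) > 0) {
    cuts <- c(3, 5, 10)
    cuts <- cuts[cuts <= length(ranked)]
    topk <- stats::setNames(
      vapply(cuts, function(k) topk_precision(ranked, truth, k), numeric(1)),
      sprintf("top@%d", cuts))
  }
  metrics <- NULL
  if (!is.null(test_data)) {
    ty <- if (inherits(test_data, "labeled_dataset")) test_data$labels
          else test_labels
    pred <- predict(forest, test_data)
    metrics <- compute_metrics(ty, pred)
  }
  structure(list(importance = imp, similarity = sim, topk = topk,
                 metrics = metrics, truth = truth),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Feature importance ranking (top 10):\n")
  print(utils::head(x$importance, 10), row.names = FALSE)
  if (!is.null(x$topk)) {
    cat("\nTop-k precision vs planted truth:\n")
    print(round(x$topk, 3))
  }
  if (!is.null(x$metrics)) {
    cat("\nHeld-out metrics:\n")
    print(x$metrics)
  }
  invisible(x)
}
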