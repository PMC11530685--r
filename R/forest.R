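# Weighted random forest: bootstrap-resampled information-gain trees over
# random feature subsets, OOB-accuracy tree weights, weighted voting,
# per-node Gini importance bookkeeping, permutation (noise) importance and
# iterative percentage-based feature elimination.

#' Forest configuration
#'
#' @param n_trees Number of trees.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param features_per_split Number of features sampled (without replacement)
#'   at each node; default `ceiling(sqrt(p))`, resolved at fit time when
#'   `NULL`.
#' @param min_samples_leaf Minimum samples in each child of a split.
#' @param removal_fraction Fraction of features removed per elimination round
#'   by [iterative_feature_elimination()].
#' @param seed Integer seed controlling bootstraps and feature subsampling.
#' @return A validated list of class `"forest_config"`.
#' @export
forest_config <- function(n_trees = 100, max_depth = 20,
                          features_per_split = NULL, min_samples_leaf = 1,
                          removal_fraction = 0.2, seed = 0) {
  cfg <- list(n_trees = as.integer(n_trees),
              max_depth = as.integer(max_depth),
              features_per_split = if (is.null(features_per_split)) NULL
                                   else as.integer(features_per_split),
              min_samples_leaf = as.integer(min_samples_leaf),
              removal_fraction = as.numeric(removal_fraction),
              seed = as.integer(seed))
  if (cfg$n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  if (cfg$max_depth < 1) stop("max_depth must be >= 1", call. = FALSE)
  if (!is.null(cfg$features_per_split) && cfg$features_per_split < 1) {
    stop("features_per_split must be >= 1", call. = FALSE)
  }
  if (cfg$min_samples_leaf < 1) stop("min_samples_leaf must be >= 1", call. = FALSE)
  if (cfg$removal_fraction <= 0 || cfg$removal_fraction >= 1) {
    stop("removal_fraction must be strictly inside (0, 1)", call. = FALSE)
  }
  class(cfg) <- "forest_config"
  cfg
}

# Coerce (features, labels) out of the objects the package passes around.
resolve_xy <- function(data, labels = NULL) {
  if (inherits(data, "labeled_dataset")) {
    X <- as.matrix(data$features)
    y <- data$labels
  } else {
    X <- as.matrix(data)
    y <- labels
  }
  if (is.null(y)) stop("labels required", call. = FALSE)
  if (anyNA(X)) stop("feature matrix contains missing values; preprocess first",
                     call. = FALSE)
  y <- factor(y)
  if (nrow(X) != length(y)) stop("features and labels differ in length", call. = FALSE)
  list(X = X, y = y)
}

#' Build a single information-gain decision tree
#'
#' Grows one tree on the given rows: at each node `features_per_split`
#' features are sampled without replacement, the split with the highest
#' information gain (midpoint thresholds between sorted unique values) is
#' taken, and recursion stops at purity, `max_depth`, `min_samples_leaf`, or
#' when no candidate split has positive gain. Leaves store class counts;
#' internal nodes record the before/after-branching Gini deltas used by
#' forest importance aggregation.
#'
#' @param data A `"labeled_dataset"` or feature matrix/data frame.
#' @param labels Class labels when `data` is a plain matrix.
#' @param config A [forest_config()]. `n_trees` is ignored here.
#' @param rows Integer row indices to train on (default all rows).
#' @return A list of class `"ig_tree"`: flat node table plus `classes`.
#' @export
build_tree <- function(data, labels = NULL, config = forest_config(),
                       rows = NULL) {
  xy <- resolve_xy(data, labels)
  if (nrow(xy$X) < 1 || ncol(xy$X) < 1) stop("empty data", call. = FALSE)
  if (is.null(rows)) rows <- seq_len(nrow(xy$X))
  mtry <- config$features_per_split
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(xy$X)))
  tr <- cpp_build_tree(xy$X, as.integer(xy$y) - 1L, nlevels(xy$y),
                       as.integer(rows), mtry, config$max_depth,
                       config$min_samples_leaf)
  tr$classes <- levels(xy$y)
  tr$feature_names <- colnames(xy$X)
  class(tr) <- "ig_tree"
  tr
}

#' @export
predict.ig_tree <- function(object, newdata, ...) {
  X <- as.matrix(if (inherits(newdata, "labeled_dataset")) newdata$features
                 else newdata)
  X <- X[, object$feature_names, drop = FALSE]
  factor(object$classes[cpp_predict_tree(object, X)], levels = object$classes)
}

#' Fit a weighted random forest
#'
#' Fits `n_trees` information-gain trees, each on an independent bootstrap
#' (n draws with replacement); the out-of-bag (OOB) rows of each tree give
#' its error rate, and tree voting weights are set proportional to OOB
#' accuracy, normalized to sum to 1. A tree whose bootstrap happens to leave
#' no OOB rows falls back to in-bag accuracy (with a warning). Prediction is
#' by weighted vote (see [predict.weighted_rf()]); variable importance by
#' per-node Gini deltas (see [importance.weighted_rf()]) or permutation
#' ([noise_importance()]).
#'
#' @inheritParams build_tree
#' @param config A [forest_config()].
#' @return A list of class `"weighted_rf"`: `trees`, `weights`, `oob_error`,
#'   `in_bag` (list of bootstrap index vectors), `classes`,
#'   `feature_names`, `config`, `oob_prediction` overall OOB error.
#' @examples
#' ds <- generate_dataset(generator_spec(n_participants = 120, seed = 1))
#' fit <- weighted_rf(ds, config = forest_config(n_trees = 25, seed = 1))
#' fit
#' @export
weighted_rf <- function(data, labels = NULL, config = forest_config()) {
  xy <- resolve_xy(data, labels)
  n <- nrow(xy$X)
  if (n < 2 * config$min_samples_leaf) {
    stop("dataset smaller than min_samples_leaf allows", call. = FALSE)
  }
  mtry <- config$features_per_split
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(xy$X)))
  with_local_seed(config$seed, {
    trees <- vector("list", config$n_trees)
    in_bag <- vector("list", config$n_trees)
    oob_err <- numeric(config$n_trees)
    raw_w <- numeric(config$n_trees)
    empty_oob <- 0L
    for (t in seq_len(config$n_trees)) {
      bag <- sample.int(n, n, replace = TRUE)
      in_bag[[t]] <- bag
      tr <- cpp_build_tree(xy$X, as.integer(xy$y) - 1L, nlevels(xy$y),
                           bag, mtry, config$max_depth,
                           config$min_samples_leaf)
      tr$classes <- levels(xy$y)
      tr$feature_names <- colnames(xy$X)
      class(tr) <- "ig_tree"
      trees[[t]] <- tr
      oob <- setdiff(seq_len(n), bag)
      if (length(oob) > 0) {
        pred <- cpp_predict_tree(tr, xy$X[oob, , drop = FALSE])
        oob_err[t] <- mean(pred != as.integer(xy$y)[oob])
        raw_w[t] <- 1 - oob_err[t]
      } else {
        empty_oob <- empty_oob + 1L
        pred <- cpp_predict_tree(tr, xy$X[bag, , drop = FALSE])
        oob_err[t] <- NA_real_
        raw_w[t] <- mean(pred == as.integer(xy$y)[bag])
      }
    }
    if (empty_oob > 0) {
      warning(sprintf("%d tree(s) had an empty OOB set; weighted by in-bag accuracy",
                      empty_oob))
    }
    w <- if (sum(raw_w) > 0) raw_w / sum(raw_w)
         else rep(1 / config$n_trees, config$n_trees)
    structure(
      list(trees = trees, weights = w, oob_error = oob_err, in_bag = in_bag,
           classes = levels(xy$y), feature_names = colnames(xy$X),
           n_train = n, config = config),
      class = "weighted_rf")
  })
}

#' @export
print.weighted_rf <- function(x, ...) {
  cat(sprintf("Weighted random forest: %d trees, %d features, %d classes\n",
              length(x$trees), length(x$feature_names), length(x$classes)))
  cat(sprintf("  mean per-tree OOB error: %.4f\n",
              mean(x$oob_error, na.rm = TRUE)))
  cat(sprintf("  tree weight range: [%.4f, %.4f] (sum 1)\n",
              min(x$weights), max(x$weights)))
  invisible(x)
}

# n x K matrix of weighted vote shares (rows sum to 1).
vote_shares <- function(object, X) {
  K <- length(object$classes)
  shares <- matrix(0, nrow(X), K, dimnames = list(NULL, object$classes))
  for (t in seq_along(object$trees)) {
    pred <- cpp_predict_tree(object$trees[[t]], X)
    shares[cbind(seq_len(nrow(X)), pred)] <-
      shares[cbind(seq_len(nrow(X)), pred)] + object$weights[t]
  }
  shares
}

#' Predict classes by weighted tree vote
#'
#' Each tree casts a one-hot class vote; votes are combined with the forest's
#' normalized per-tree weights (a weight row "convolved" with the tree vote
#' matrix) and the class with the largest weighted share wins. Ties are
#' broken by the lowest class index. With uniform weights this reduces to
#' majority vote.
#'
#' @param object A fitted [weighted_rf()].
#' @param newdata Feature matrix/data frame or `"labeled_dataset"`.
#' @param type `"class"` for labels, `"share"` for the n-by-K matrix of
#'   weighted vote shares (rows sum to 1).
#' @param ... Unused.
#' @return Factor of predicted labels, or the vote-share matrix.
#' @export
predict.weighted_rf <- function(object, newdata, type = c("class", "share"),
                                ...) {
  type <- match.arg(type)
  X <- as.matrix(if (inherits(newdata, "labeled_dataset")) newdata$features
                 else newdata)
  missing_cols <- setdiff(object$feature_names, colnames(X))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing feature column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  X <- X[, object$feature_names, drop = FALSE]
  shares <- vote_shares(object, X)
  if (type == "share") return(shares)
  # max.col with ties.method = "first" = lowest class index on ties
  factor(object$classes[max.col(shares, ties.method = "first")],
         levels = object$classes)
}

#' Gini variable importance of a weighted random forest
#'
#' Accumulates the before/after-branching Gini delta of every node that
#' splits on a feature, over every tree, then normalizes by the total over
#' features so scores sum to 1. The default `type = "gini"` is the field's
#' standard mean decrease in Gini: each node contributes its child-count-
#' weighted impurity decrease `Gini_m - (n_l/n_m) Gini_l - (n_r/n_m) Gini_r`
#' scaled by the node's share of training samples `n_m / n`. Both factors
#' are nonnegative (by concavity of the Gini index), so normalized scores
#' lie in `[0, 1]`. `type = "gini_unweighted"` instead takes the plain sum
#' of the raw unweighted deltas `Gini_m - Gini_l - Gini_r` exactly as
#' [node_importance_delta()] computes them; that form is negative for
#' uninformative splits, so its normalized scores still sum to 1 but are not
#' confined to `[0, 1]`. Either way features are ranked by raw score.
#'
#' @param object A fitted [weighted_rf()].
#' @param type `"gini"` (node-share- and child-count-weighted decrease,
#'   default) or `"gini_unweighted"` (plain sum of the deltas exactly as
#'   printed in the node records).
#' @param ... Unused.
#' @return A data frame with one row per feature: `feature`, `raw_score`,
#'   `normalized_score`, `rank` (1 = most important), ordered by rank.
#' @export
importance <- function(object, ...) UseMethod("importance")

#' @rdname importance
#' @export
importance.weighted_rf <- function(object,
                                   type = c("gini", "gini_unweighted"), ...) {
  type <- match.arg(type)
  p <- length(object$feature_names)
  raw <- numeric(p)
  n_splits <- 0L
  for (tr in object$trees) {
    internal <- !is.na(tr$feature)
    if (!any(internal)) next
    n_splits <- n_splits + sum(internal)
    deltas <- if (type == "gini") {
      tr$delta_weighted[internal] * tr$n_node[internal] / object$n_train
    } else {
      tr$delta_unweighted[internal]
    }
    feats <- tr$feature[internal]
    agg <- rowsum(deltas, feats)
    raw[as.integer(rownames(agg))] <- raw[as.integer(rownames(agg))] + agg[, 1]
  }
  if (n_splits == 0L) {
    warning("forest contains no splits; importance is uniform")
    norm <- rep(1 / p, p)
  } else {
    total <- sum(raw)
    norm <- if (abs(total) > 0) raw / total else rep(NA_real_, p)
  }
  ord <- order(-raw, seq_len(p)) # rank by raw score, ties by column order
  out <- data.frame(feature = object$feature_names, raw_score = raw,
                    normalized_score = norm,
                    stringsAsFactors = FALSE)
  out$rank <- integer(p)
  out$rank[ord] <- seq_len(p)
  out[ord, , drop = FALSE]
}

#' Noise-perturbation (permutation) feature importance
#'
#' For each tree, the feature's column is perturbed on that tree's OOB rows
#' and the increase in OOB error over baseline is recorded; the score is the
#' mean increase over trees. The default perturbation is a within-column
#' permutation, which destroys the feature-label association while
#' preserving the marginal distribution; `perturbation = "gaussian"` instead
#' adds N(0, sd(column)) noise.
#'
#' @param object A fitted [weighted_rf()].
#' @param data The training data (a `"labeled_dataset"` or matrix).
#' @param labels Labels when `data` is a matrix.
#' @param features Character vector of features to score (default: all).
#' @param perturbation `"permute"` or `"gaussian"`.
#' @param seed Integer seed for the perturbations.
#' @return Named numeric vector of mean OOB-error increases.
#' @export
noise_importance <- function(object, data, labels = NULL,
                             features = object$feature_names,
                             perturbation = c("permute", "gaussian"),
                             seed = object$config$seed + 1L) {
  perturbation <- match.arg(perturbation)
  xy <- resolve_xy(data, labels)
  bad <- setdiff(features, object$feature_names)
  if (length(bad) > 0) {
    stop(sprintf("feature(s) not in training set: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  X <- xy$X[, object$feature_names, drop = FALSE]
  yi <- as.integer(factor(xy$y, levels = object$classes))
  n <- nrow(X)
  with_local_seed(seed, {
    scores <- stats::setNames(numeric(length(features)), features)
    for (f in features) {
      j <- match(f, object$feature_names)
      incr <- numeric(0)
      for (t in seq_along(object$trees)) {
        oob <- setdiff(seq_len(n), object$in_bag[[t]])
        if (length(oob) == 0) next
        base_err <- object$oob_error[t]
        Xp <- X[oob, , drop = FALSE]
        Xp[, j] <- switch(perturbation,
          permute = Xp[sample.int(length(oob)), j],
          gaussian = Xp[, j] + stats::rnorm(length(oob), 0, stats::sd(X[, j])))
        perm_err <- mean(cpp_predict_tree(object$trees[[t]], Xp) != yi[oob])
        incr <- c(incr, perm_err - base_err)
      }
      scores[f] <- if (length(incr) > 0) mean(incr) else NA_real_
    }
    scores
  })
}

#' Iterative percentage-based feature elimination
#'
#' Repeatedly fits a forest, ranks features by normalized Gini importance,
#' and removes the bottom `ceiling(removal_fraction * p_current)` features,
#' recording the cross-validated accuracy of each round's feature set. Stops
#' after `rounds` rounds or when one feature remains.
#'
#' @inheritParams weighted_rf
#' @param rounds Maximum number of elimination rounds.
#' @param removal_fraction Overrides `config$removal_fraction` if given.
#' @param k_folds Folds for the per-round CV accuracy.
#' @param importance_type Passed to [importance.weighted_rf()].
#' @return A data frame trajectory with one row per round: `round`,
#'   `n_features`, `cv_accuracy`, and list columns `features` (the set used)
#'   and `removed` (features dropped after the round).
#' @export
iterative_feature_elimination <- function(data, labels = NULL,
                                          config = forest_config(),
                                          rounds = 10,
                                          removal_fraction = config$removal_fraction,
                                          k_folds = 5,
                                          importance_type = "gini") {
  if (removal_fraction <= 0 || removal_fraction >= 1) {
    stop("removal_fraction must be strictly inside (0, 1)", call. = FALSE)
  }
  xy <- resolve_xy(data, labels)
  current <- colnames(xy$X)
  traj <- list()
  for (r in seq_len(rounds)) {
    Xr <- xy$X[, current, drop = FALSE]
    cfg_r <- config
    cfg_r$seed <- config$seed + r
    fit <- weighted_rf(Xr, xy$y, cfg_r)
    imp <- importance(fit, type = importance_type)
    acc <- cv_accuracy(Xr, xy$y, cfg_r, k_folds = k_folds,
                       seed = config$seed + 1000L + r)
    n_drop <- min(ceiling(removal_fraction * length(current)),
                  length(current) - 1L)
    dropped <- imp$feature[imp$rank > length(current) - n_drop]
    traj[[r]] <- data.frame(round = r, n_features = length(current),
                            cv_accuracy = acc, stringsAsFactors = FALSE)
    traj[[r]]$features <- list(current)
    traj[[r]]$removed <- list(dropped)
    current <- setdiff(current, dropped)
    if (length(current) <= 1 || n_drop == 0) break
  }
  do.call(rbind, traj)
}
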