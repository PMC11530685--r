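test_that("degenerate inputs produce the expected trees", {
  # pure labels: a single leaf
  X <- matrix(stats::rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  tr <- build_tree(X, rep("one", 10))
  expect_length(tr$feature, 1)
  expect_true(is.na(tr$feature[1]))
  # one perfectly separating feature: a depth-1 stump
  y <- rep(c("lo", "hi"), each = 5)
  X <- cbind(sig = c(1:5, 11:15))
  tr <- build_tree(X, y, forest_config(features_per_split = 1))
  expect_equal(sum(!is.na(tr$feature)), 1)
  expect_equal(max(tr$depth), 1)
  expect_identical(as.character(predict(tr, X)), as.character(factor(y)))
})

test_that("trees reproduce the exhaustive-search oracle on small binary data", {
  # fixed 8 x 3 design, every possible labelling
  X <- as.matrix(expand.grid(f1 = 0:1, f2 = 0:1, f3 = 0:1))
  storage.mode(X) <- "double"
  cfg <- forest_config(features_per_split = 3, max_depth = 30)
  for (code in 0:255) {
    y <- as.integer(intToBits(code))[1:8]
    tr <- build_tree(X, factor(y, levels = 0:1), cfg)
    got <- as.integer(as.character(predict(tr, X)))
    expect_identical(got, oracle_tree_predict(X, y))
  }
  # random 8 x 4 binary designs
  set.seed(21)
  for (i in 1:100) {
    X <- matrix(sample(0:1, 32, replace = TRUE), 8, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    storage.mode(X) <- "double"
    y <- sample(0:1, 8, replace = TRUE)
    cfg4 <- forest_config(features_per_split = 4, max_depth = 30)
    tr <- build_tree(X, factor(y, levels = 0:1), cfg4)
    got <- as.integer(as.character(predict(tr, X)))
    expect_identical(got, oracle_tree_predict(X, y))
  }
})

test_that("forest OOB errors equal a direct recount of misclassified OOB rows", {
  d <- separable_dataset(n = 80, seed = 2)
  fit <- weighted_rf(d$X, d$y, forest_config(n_trees = 12, seed = 2))
  yi <- as.integer(d$y)
  for (t in seq_along(fit$trees)) {
    oob <- setdiff(seq_len(80), fit$in_bag[[t]])
    pred <- predict(fit$trees[[t]], d$X[oob, , drop = FALSE])
    expect_equal(fit$oob_error[t], mean(as.integer(pred) != yi[oob]))
  }
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$weights >= 0))
})

test_that("single-tree forests predict exactly as their tree", {
  d <- separable_dataset(n = 40, seed = 3)
  fit <- weighted_rf(d$X, d$y, forest_config(n_trees = 1, seed = 3))
  expect_identical(predict(fit, d$X),
                   predict(fit$trees[[1]], d$X))
})

test_that("weighted voting follows the weights; uniform weights = majority", {
  d <- separable_dataset(n = 50, seed = 4)
  fit <- weighted_rf(d$X, d$y, forest_config(n_trees = 5, seed = 4))
  # hand-computed weighted tally
  shares <- matrix(0, 50, 2)
  for (t in 1:5) {
    p <- as.integer(predict(fit$trees[[t]], d$X))
    shares[cbind(1:50, p)] <- shares[cbind(1:50, p)] + fit$weights[t]
  }
  expect_equal(unname(predict(fit, d$X, type = "share")), shares,
               tolerance = 1e-12)
  expect_equal(rowSums(predict(fit, d$X, type = "share")), rep(1, 50),
               tolerance = 1e-9)
  # a dominant weight forces the vote of its tree
  forced <- fit
  forced$weights <- c(0.9, 0.025, 0.025, 0.025, 0.025)
  t1 <- predict(fit$trees[[1]], d$X)
  expect_identical(predict(forced, d$X), t1)
  # uniform weights reduce to majority vote
  unif <- fit
  unif$weights <- rep(0.2, 5)
  votes <- sapply(fit$trees, function(tr)
    as.integer(predict(tr, d$X)))
  majority <- apply(votes, 1, function(v) which.max(tabulate(v, 2)))
  expect_identical(as.integer(predict(unif, d$X)), as.integer(majority))
})

test_that("forests are deterministic under a fixed seed", {
  d <- separable_dataset(n = 60, seed = 5)
  f1 <- weighted_rf(d$X, d$y, forest_config(n_trees = 10, seed = 9))
  f2 <- weighted_rf(d$X, d$y, forest_config(n_trees = 10, seed = 9))
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))
  expect_identical(importance(f1), importance(f2))
})

test_that("in-bag accuracy is perfect on separable data at full depth", {
  d <- separable_dataset(n = 60, seed = 6)
  fit <- weighted_rf(d$X, d$y,
                     forest_config(n_trees = 10, max_depth = 30, seed = 6))
  yi <- as.integer(d$y)
  for (t in seq_along(fit$trees)) {
    bag <- fit$in_bag[[t]]
    p <- predict(fit$trees[[t]], d$X[bag, , drop = FALSE])
    expect_equal(mean(as.integer(p) == yi[bag]), 1)
  }
})

test_that("gini importance: stump concentrates mass; scores normalize; scale-free", {
  y <- rep(c("lo", "hi"), each = 10)
  X <- cbind(sig = c(1:10, 21:30), noise = stats::rnorm(20))
  fit <- weighted_rf(X, y, forest_config(n_trees = 1, max_depth = 1,
                                         features_per_split = 2, seed = 1))
  imp <- importance(fit)
  expect_equal(imp$normalized_score[imp$feature == "sig"], 1, tolerance = 1e-12)
  expect_equal(imp$normalized_score[imp$feature == "noise"], 0, tolerance = 1e-12)
  d <- separable_dataset(n = 50, seed = 7)
  fit <- weighted_rf(d$X, d$y, forest_config(n_trees = 8, seed = 7))
  imp <- importance(fit)
  expect_equal(sum(imp$normalized_score), 1, tolerance = 1e-9)
  expect_true(all(imp$normalized_score >= -1e-12))
  impu <- importance(fit, type = "gini_unweighted")
  expect_equal(sum(impu$normalized_score), 1, tolerance = 1e-9)
  # duplicating every sample leaves normalized scores unchanged
  fit2 <- weighted_rf(d$X[rep(1:50, 2), ], d$y[rep(1:50, 2)],
                      forest_config(n_trees = 8, seed = 7))
  imp2 <- importance(fit2)
  m <- match(imp$feature, imp2$feature)
  expect_equal(imp$normalized_score, imp2$normalized_score[m],
               tolerance = 0.15)
})

test_that("importance aggregation equals a hand sum over node records", {
  d <- separable_dataset(n = 40, seed = 8)
  fit <- weighted_rf(d$X, d$y, forest_config(n_trees = 3, seed = 8))
  p <- length(fit$feature_names)
  raw <- numeric(p)
  for (tr in fit$trees) {
    for (m in seq_along(tr$feature)) {
      if (!is.na(tr$feature[m])) {
        j <- tr$feature[m]
        counts_m <- tr$counts[m, ]
        counts_l <- tr$counts[tr$left[m], ]
        counts_r <- tr$counts[tr$right[m], ]
        delta <- node_importance_delta(counts_m, counts_l, counts_r,
                                       weighted = TRUE)
        raw[j] <- raw[j] + delta * sum(counts_m) / fit$n_train
      }
    }
  }
  imp <- importance(fit)
  expect_equal(imp$raw_score[match(fit$feature_names, imp$feature)], raw,
               tolerance = 1e-9)
})

test_that("noise importance: unused features score ~0, the signal scores > 0", {
  d <- separable_dataset(n = 100, seed = 9)
  fit <- weighted_rf(d$X, d$y, forest_config(n_trees = 20, seed = 9))
  sc <- noise_importance(fit, d$X, d$y)
  expect_gt(sc["sig"], 0.1)
  expect_lt(abs(sc["noise1"]), 2 / sqrt(100))
  expect_lt(abs(sc["noise2"]), 2 / sqrt(100))
  expect_error(noise_importance(fit, d$X, d$y, features = "ghost"),
               "not in training set")
})

test_that("noise importance matches an independent recount at the same seed", {
  d <- separable_dataset(n = 60, seed = 10)
  fit <- weighted_rf(d$X, d$y, forest_config(n_trees = 6, seed = 10))
  seed <- 123
  got <- noise_importance(fit, d$X, d$y, features = "sig", seed = seed)
  # independent recount: replay the same RNG stream, rebuild the perturbed
  # OOB predictions per tree and recount the misclassifications
  yi <- as.integer(d$y)
  set.seed(seed)
  incr <- numeric(0)
  j <- match("sig", fit$feature_names)
  for (t in seq_along(fit$trees)) {
    oob <- setdiff(seq_len(60), fit$in_bag[[t]])
    Xp <- d$X[oob, , drop = FALSE]
    Xp[, j] <- Xp[sample.int(length(oob)), j]
    wrong <- sum(as.integer(predict(fit$trees[[t]], Xp)) != yi[oob])
    incr <- c(incr, wrong / length(oob) - fit$oob_error[t])
  }
  expect_equal(unname(got["sig"]), mean(incr), tolerance = 1e-12)
})

test_that("feature elimination removes the bottom of the same round's ranking", {
  set.seed(30)
  ds <- generate_dataset(generator_spec(n_participants = 300, n_informative = 3,
                                        n_noise = 7, seed = 30))
  traj <- iterative_feature_elimination(ds, config = forest_config(
    n_trees = 20, seed = 30), rounds = 4, removal_fraction = 0.05, k_folds = 3)
  # ceil(0.05 * p) = 1 per round: sizes 10, 9, 8, 7
  expect_equal(traj$n_features, c(10, 9, 8, 7))
  expect_true(all(vapply(traj$removed, length, integer(1)) == 1))
  for (r in seq_len(nrow(traj) - 1)) {
    expect_setequal(traj$features[[r + 1]],
                    setdiff(traj$features[[r]], traj$removed[[r]]))
  }
  expect_true(all(traj$cv_accuracy >= 0 & traj$cv_accuracy <= 1))
})

test_that("planted informative features survive elimination rounds", {
  ds <- generate_dataset(generator_spec(n_participants = 400, seed = 31))
  traj <- iterative_feature_elimination(ds, config = forest_config(
    n_trees = 30, seed = 31), rounds = 4, removal_fraction = 0.25, k_folds = 3)
  # 20 -> 15 -> 11 -> 8 features; the 5 planted ones must survive
  last <- traj$features[[nrow(traj)]]
  expect_true(all(ds$truth %in% last))
})

test_that("forests refuse missing values and missing columns", {
  d <- separable_dataset(n = 30, seed = 11)
  Xna <- d$X; Xna[1, 1] <- NA
  expect_error(weighted_rf(Xna, d$y), "missing values")
  fit <- weighted_rf(d$X, d$y, forest_config(n_trees = 2, seed = 1))
  expect_error(predict(fit, d$X[, 1:2]), "missing feature column")
})

test_that("accuracy is competitive with an established forest implementation", {
  skip_if_not_installed("randomForest")
  ds <- generate_dataset(generator_spec(n_participants = 600, seed = 12))
  X <- as.matrix(ds$features)
  idx <- train_test_split(ds$labels, 0.7, seed = 12)
  fit <- weighted_rf(X[idx$train, ], ds$labels[idx$train],
                     forest_config(n_trees = 100, seed = 12))
  ours <- mean(predict(fit, X[idx$test, ]) == ds$labels[idx$test])
  set.seed(12)
  rf <- randomForest::randomForest(X[idx$train, ], ds$labels[idx$train],
                                   ntree = 100)
  theirs <- mean(predict(rf, X[idx$test, ]) == ds$labels[idx$test])
  expect_gte(ours, theirs - 0.05)
  # and the importance rankings broadly agree on the planted truth
  rf_rank <- names(sort(rf$importance[, 1], decreasing = TRUE))
  our_rank <- importance(fit)$feature
  expect_gte(topk_precision(our_rank, ds$truth, 5), 0.8)
  expect_gte(topk_precision(rf_rank, ds$truth, 5), 0.6)
})
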