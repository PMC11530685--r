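test_that("entropy matches the defining formula and its fixed points", {
  expect_identical(entropy(c(0.5, 0.5)), 1)
  expect_identical(entropy(c(1, 0)), 0)
  # frozen 50-digit reference value for (0.25, 0.75)
  expect_equal(entropy(c(0.25, 0.75)), 0.811278124459132863909695792039,
               tolerance = 1e-15)
  set.seed(41)
  for (i in 1:200) {
    p <- random_proportions(sample(2:6, 1))
    expect_equal(entropy(p), oracle_entropy(p), tolerance = 1e-12)
  }
  expect_error(entropy(c(0.5, 0.4)), "sum to 1")
  expect_error(entropy(c(-0.1, 1.1)), "nonnegative")
})

test_that("gini index matches the defining formula; bounded by 1 - 1/K", {
  expect_identical(gini_index(c(1, 0)), 0)
  expect_identical(gini_index(c(0.5, 0.5)), 0.5)
  expect_equal(gini_index(c(0.2, 0.8)), 1 - (0.04 + 0.64), tolerance = 1e-15)
  set.seed(42)
  for (i in 1:200) {
    K <- sample(2:6, 1)
    p <- random_proportions(K)
    expect_equal(gini_index(p), oracle_gini(p), tolerance = 1e-12)
    expect_lte(gini_index(p), 1 - 1 / K + 1e-12)
  }
})

test_that("information gain: perfect split, constant feature, brute-force table", {
  y <- c(0, 0, 1, 1, 1, 0, 1, 0)
  perfect <- information_gain(y, as.character(y))
  expect_equal(perfect$gain, entropy(c(0.5, 0.5)), tolerance = 1e-12)
  expect_equal(information_gain(y, rep("x", 8))$gain, 0, tolerance = 1e-15)
  set.seed(43)
  for (i in 1:50) {
    y <- sample(0:1, 8, replace = TRUE)
    f <- sample(c("u", "v"), 8, replace = TRUE)
    got <- information_gain(y, f)
    expect_equal(got$gain, max(oracle_information_gain(y, f), 0),
                 tolerance = 1e-12)
    expect_equal(got$gain, got$parent_entropy - got$conditional_entropy,
                 tolerance = 1e-12)
    expect_gte(got$gain, -1e-12)
  }
  expect_error(information_gain(integer(0), integer(0)), "empty")
})

test_that("gain is zero exactly when the feature is empirically independent", {
  # balanced cross design: every feature value sees the same label mix
  y <- rep(c(0, 1), times = 4)
  f <- rep(c("a", "a", "b", "b"), times = 2)
  expect_equal(information_gain(y, f)$gain, 0, tolerance = 1e-12)
})

test_that("select_best_feature is the brute-force argmax with low-index ties", {
  y <- c(0, 0, 1, 1)
  expect_identical(select_best_feature(y, data.frame(only = c(1, 1, 2, 2))),
                   "only")
  feats <- data.frame(noise = c(1, 2, 1, 2), signal = c(0, 0, 1, 1))
  expect_identical(select_best_feature(y, feats), "signal")
  set.seed(44)
  for (i in 1:30) {
    y <- sample(0:1, 12, replace = TRUE)
    feats <- as.data.frame(matrix(sample(1:3, 60, replace = TRUE), 12, 5))
    gains <- vapply(feats, function(f) oracle_information_gain(y, f), numeric(1))
    expect_identical(select_best_feature(y, feats),
                     names(feats)[which.max(pmax(gains, 0))])
  }
})

test_that("node importance delta follows the before/after-branching formula", {
  # 50/50 parent split into two pure children
  expect_equal(node_importance_delta(c(5, 5), c(5, 0), c(0, 5)), 0.5,
               tolerance = 1e-15)
  # children with the parent's distribution: forced to -Gini_m
  expect_equal(node_importance_delta(c(6, 6), c(3, 3), c(3, 3)),
               -gini_index(c(0.5, 0.5)), tolerance = 1e-15)
  set.seed(45)
  for (i in 1:100) {
    l <- sample(0:5, 2, replace = TRUE)
    r <- sample(0:5, 2, replace = TRUE)
    if (sum(l) == 0 || sum(r) == 0) next
    parent <- l + r
    direct <- oracle_gini(parent / sum(parent)) -
      oracle_gini(l / sum(l)) - oracle_gini(r / sum(r))
    expect_equal(node_importance_delta(parent, l, r), direct,
                 tolerance = 1e-12)
    # child-count-weighted variant is nonnegative (Gini concavity)
    expect_gte(node_importance_delta(parent, l, r, weighted = TRUE), -1e-12)
  }
  expect_error(node_importance_delta(c(4, 4), c(1, 1), c(1, 1)), "partition")
})

test_that("pearson correlation matches direct computation and affine laws", {
  x <- c(1, 4, 2, 8, 5, 7, 3, 6, 9, 10)
  expect_equal(pearson_correlation(x, x)$coefficient, 1, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, -x)$coefficient, -1, tolerance = 1e-12)
  set.seed(46)
  for (i in 1:50) {
    a <- stats::rnorm(10); b <- stats::rnorm(10)
    got <- pearson_correlation(a, b)
    expect_equal(got$coefficient, stats::cor(a, b), tolerance = 1e-12)
    expect_equal(got$covariance, stats::cov(a, b), tolerance = 1e-12)
    # invariant under positive-slope affine maps; sign flip under negative
    expect_equal(pearson_correlation(2 * a + 3, b)$coefficient,
                 got$coefficient, tolerance = 1e-12)
    expect_equal(pearson_correlation(-2 * a + 1, b)$coefficient,
                 -got$coefficient, tolerance = 1e-12)
  }
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("penalized objectives evaluate exactly as defined", {
  expect_identical(penalized_objective(2, c(0, 0), 1, 1, "l1"), 2)
  expect_identical(penalized_objective(2, c(0, 0), 1, 1, "l2"), 2)
  expect_identical(penalized_objective(2, c(0, 0), 1, 1, "elastic"), 2)
  expect_identical(penalized_objective(3, c(1, -2), 0, 0, "elastic"), 3)
  # frozen worked example: J = 1, w = (3, -4), alpha = 0.5, lambda = 2
  # combined form: 1 + 0.5*2*7 + ((1-0.5)/2)*0.5*5 = 8.625
  expect_equal(penalized_objective(1, c(3, -4), 0.5, 2, "elastic"), 8.625,
               tolerance = 1e-15)
  set.seed(47)
  for (i in 1:100) {
    w <- stats::rnorm(4); J <- stats::runif(1); a <- stats::runif(1)
    l <- stats::runif(1)
    expect_equal(penalized_objective(J, w, a, l, "l1"),
                 J + l * sum(abs(w)), tolerance = 1e-12)
    expect_equal(penalized_objective(J, w, a, l, "l2"),
                 J + a * sqrt(sum(w^2)), tolerance = 1e-12)
    expect_equal(penalized_objective(J, w, a, l, "elastic"),
                 J + a * l * sum(abs(w)) + (1 - a) / 2 * a * sqrt(sum(w^2)),
                 tolerance = 1e-12)
    expect_equal(penalized_objective(J, w, a, l, "elastic_standard"),
                 J + l * (a * sum(abs(w)) + (1 - a) / 2 * sum(w^2)),
                 tolerance = 1e-12)
    # penalties never push below the bare risk
    expect_gte(penalized_objective(J, w, a, l, "elastic"), J)
  }
  expect_error(penalized_objective(1, 1, -1, 0, "l1"), "nonnegative")
  expect_error(penalized_objective(1, 1, 0, 0, "ridge"))
})
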