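# Shared test fixtures and independent oracles. Everything here is written
# directly from the defining formulas, independently of the package's
# implementation paths.

# Entropy in bits, straight from the defining sum.
oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p) / log(2))
}

oracle_gini <- function(p) 1 - sum(p^2)

# Information gain from the full contingency table of (labels, feature).
oracle_information_gain <- function(labels, feature) {
  n <- length(labels)
  tab <- table(feature, labels)
  parent <- oracle_entropy(table(labels) / n)
  cond <- 0
  for (v in rownames(tab)) {
    nv <- sum(tab[v, ])
    cond <- cond + (nv / n) * oracle_entropy(tab[v, ] / nv)
  }
  parent - cond
}

# Exhaustive-search decision tree on binary feature matrices: at each node
# every feature is evaluated by information gain (computed from the
# contingency table), argmax wins with ties to the lowest column index,
# stopping at purity or when no split has positive gain. Returns in-sample
# predictions (majority leaf, ties to the lowest class index).
oracle_tree_predict <- function(X, y) {
  pred <- integer(length(y))
  recurse <- function(idx) {
    ys <- y[idx]
    if (length(unique(ys)) == 1) { pred[idx] <<- ys[1]; return(invisible()) }
    gains <- vapply(seq_len(ncol(X)), function(j) {
      f <- X[idx, j]
      if (length(unique(f)) < 2) return(0)
      oracle_information_gain(ys, f)
    }, numeric(1))
    if (max(gains) <= 1e-12) {
      counts <- tabulate(ys + 1L)
      pred[idx] <<- which.max(counts) - 1L
      return(invisible())
    }
    j <- which.max(gains)
    recurse(idx[X[idx, j] == 0])
    recurse(idx[X[idx, j] == 1])
  }
  recurse(seq_along(y))
  pred
}

# A random proportion vector over K classes.
random_proportions <- function(K) {
  x <- stats::rexp(K)
  x / sum(x)
}

# Small well-separated two-class dataset for forest sanity checks.
separable_dataset <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- cbind(sig = ifelse(y == "b", 5, 0) + stats::rnorm(n, 0, 0.5),
             noise1 = stats::rnorm(n), noise2 = stats::rnorm(n))
  list(X = X, y = y)
}
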