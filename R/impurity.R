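#' Shannon entropy of a class distribution, in bits
#'
#' Measures the impurity of a sample set from its per-class proportions,
#' `-sum(p * log2(p))` with the convention `0 * log2(0) = 0`. Base 2 is used
#' throughout the package so that a uniform binary distribution has entropy
#' exactly 1 bit.
#'
#' @param p Numeric vector of class proportions. Must be nonnegative and sum
#'   to 1 (within `1e-8`).
#' @return Entropy in bits: 0 for a pure node, `log2(K)` for a uniform
#'   distribution over `K` classes.
#' @examples
#' entropy(c(0.5, 0.5)) # 1 bit
#' entropy(c(1, 0))     # pure node, 0 bits
#' @export
entropy <- function(p) {
  p <- validate_proportions(p)
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

#' Gini index of a class distribution
#'
#' Node impurity `1 - sum(p^2)`: 0 for a pure node, at most `1 - 1/K` for
#' `K` classes (0.5 for a uniform binary node).
#'
#' @inheritParams entropy
#' @return Gini impurity in `[0, 1 - 1/K]`.
#' @examples
#' gini_index(c(0.5, 0.5)) # 0.5
#' @export
gini_index <- function(p) {
  p <- validate_proportions(p)
  1 - sum(p^2)
}

validate_proportions <- function(p) {
  if (!is.numeric(p) || length(p) == 0) {
    stop("class proportions must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(p < -1e-12)) {
    stop("class proportions must be nonnegative", call. = FALSE)
  }
  s <- sum(p)
  if (abs(s - 1) > 1e-8) {
    stop(sprintf("class proportions must sum to 1 (got %.10g)", s),
         call. = FALSE)
  }
  pmax(p, 0)
}

class_proportions <- function(labels) {
  tab <- table(labels)
  as.numeric(tab) / sum(tab)
}

#' Information gain of a discrete feature for a label vector
#'
#' The reduction in label entropy from conditioning on a feature:
#' `Ent(labels) - sum_v (n_v / n) * Ent(labels | feature == v)`.
#' This is the split-selection and feature-ranking criterion used by the
#' forest. Always nonnegative; zero when the feature carries no information
#' about the labels in the empirical table.
#'
#' @param labels Class label vector.
#' @param feature Discrete feature vector of the same length.
#' @return A list of class `"split_evaluation"` with elements
#'   `parent_entropy`, `conditional_entropy` and `gain`, all in bits.
#' @examples
#' y <- c(0, 0, 1, 1)
#' information_gain(y, c("a", "a", "b", "b"))$gain # perfect split: Ent(y)
#' @export
information_gain <- function(labels, feature) {
  if (length(labels) == 0) stop("empty input", call. = FALSE)
  if (length(labels) != length(feature)) {
    stop("labels and feature must have equal length", call. = FALSE)
  }
  n <- length(labels)
  parent <- entropy(class_proportions(labels))
  cond <- 0
  for (v in unique(feature)) {
    idx <- feature == v
    cond <- cond + (sum(idx) / n) * entropy(class_proportions(labels[idx]))
  }
  structure(
    list(parent_entropy = parent, conditional_entropy = cond,
         gain = max(parent - cond, 0)),
    class = "split_evaluation"
  )
}

#' Select the feature with the highest information gain
#'
#' Argmax of [information_gain()] over candidate feature columns. Ties are
#' broken by the lowest column index, so selection is deterministic.
#'
#' @param labels Class label vector.
#' @param features A data frame or matrix of candidate (discrete) features,
#'   one column per candidate.
#' @return The name (or index, if unnamed) of the winning column.
#' @export
select_best_feature <- function(labels, features) {
  features <- as.data.frame(features)
  if (ncol(features) < 1) stop("at least one candidate feature required", call. = FALSE)
  gains <- vapply(features, function(f) information_gain(labels, f)$gain,
                  numeric(1))
  best <- which.max(gains)   # which.max takes the first maximum: lowest index
  if (is.null(colnames(features))) best else colnames(features)[best]
}

#' Node importance delta of a split, before/after branching
#'
#' The change in Gini index across one branching of node m into children
#' l and r: `Gini_m - Gini_l - Gini_r`, with the child terms *unweighted* by
#' child size. Because the children of an uninformative split are each about
#' as impure as the parent, this quantity is negative for useless splits and
#' positive only for strongly purifying ones. A child-count-weighted variant
#' `Gini_m - (n_l/n) Gini_l - (n_r/n) Gini_r` (always nonnegative, by
#' concavity of the Gini index) is available via `weighted = TRUE`; the
#' forest's default importance aggregation uses the weighted form (see
#' [importance.weighted_rf()]).
#'
#' @param parent,left,right Class *count* vectors for the parent node and its
#'   two children. Left and right counts must sum to the parent counts.
#' @param weighted If `TRUE`, weight each child Gini by its sample share.
#' @return The importance delta (a single number; may be negative when
#'   `weighted = FALSE`).
#' @export
node_importance_delta <- function(parent, left, right, weighted = FALSE) {
  if (!isTRUE(all.equal(as.numeric(parent), as.numeric(left + right)))) {
    stop("left and right counts must partition the parent counts", call. = FALSE)
  }
  g <- function(counts) {
    n <- sum(counts)
    if (n == 0) return(0)
    1 - sum((counts / n)^2)
  }
  if (weighted) {
    n <- sum(parent)
    g(parent) - (sum(left) / n) * g(left) - (sum(right) / n) * g(right)
  } else {
    g(parent) - g(left) - g(right)
  }
}

#' Pearson correlation between two numeric vectors
#'
#' `cov(x, y) / (sd(x) * sd(y))`, used to measure similarity between the
#' top-ranked fitness indicators in an effect report.
#'
#' @param x,y Numeric vectors of equal length (at least 2).
#' @return A list of class `"correlation_result"` with `covariance`, `sd_x`,
#'   `sd_y` and `coefficient` (in `[-1, 1]`).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must have equal length >= 2", call. = FALSE)
  }
  mx <- mean(x); my <- mean(y)
  n <- length(x)
  covxy <- sum((x - mx) * (y - my)) / (n - 1)
  sx <- sqrt(sum((x - mx)^2) / (n - 1))
  sy <- sqrt(sum((y - my)^2) / (n - 1))
  if (sx == 0 || sy == 0) {
    stop("correlation undefined: zero variance input", call. = FALSE)
  }
  structure(
    list(covariance = covxy, sd_x = sx, sd_y = sy,
         coefficient = max(-1, min(1, covxy / (sx * sy)))),
    class = "correlation_result"
  )
}

#' Penalized empirical-risk objective value
#'
#' Evaluates a regularized objective for a given empirical risk `J` and
#' weight vector `w`:
#' \describe{
#'   \item{`"l1"`}{`J + lambda * ||w||_1`}
#'   \item{`"l2"`}{`J + alpha * ||w||_2`}
#'   \item{`"elastic"`}{`J + alpha*lambda*||w||_1 + ((1-alpha)/2)*alpha*||w||_2`,
#'     the combined form as used by this package's objective bookkeeping. Note
#'     that it repeats `alpha` on the l1 term, unlike the textbook elastic
#'     net; the textbook form
#'     `J + lambda*(alpha*||w||_1 + ((1-alpha)/2)*||w||_2^2)` is available as
#'     `"elastic_standard"`.}
#' }
#' `||w||_2` here is the Euclidean norm (not its square) except in the
#' standard elastic variant, which uses the conventional squared norm.
#' These are objective *evaluators* only; no model fitting is attached.
#'
#' @param J Empirical risk (a single number).
#' @param w Numeric weight vector.
#' @param alpha,lambda Nonnegative penalty strengths.
#' @param variant One of `"l1"`, `"l2"`, `"elastic"`, `"elastic_standard"`.
#' @return The penalized objective value (never less than `J` for
#'   nonnegative strengths).
#' @export
penalized_objective <- function(J, w, alpha = 0, lambda = 0,
                                variant = c("l1", "l2", "elastic",
                                            "elastic_standard")) {
  variant <- match.arg(variant)
  if (alpha < 0 || lambda < 0) {
    stop("penalty strengths must be nonnegative", call. = FALSE)
  }
  l1 <- sum(abs(w))
  l2 <- sqrt(sum(w^2))
  switch(variant,
    l1 = J + lambda * l1,
    l2 = J + alpha * l2,
    elastic = J + alpha * lambda * l1 + ((1 - alpha) / 2) * alpha * l2,
    elastic_standard = J + lambda * (alpha * l1 + ((1 - alpha) / 2) * l2^2)
  )
}
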