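# CSV and configuration I/O. The CSV dialect is fixed: comma-separated,
# UTF-8, header row, empty field = missing; numeric feature columns plus one
# label column.

#' Read a feature CSV into a labelled table
#'
#' Reads a comma-separated file with a header row; every column except the
#' label column must parse as numeric (empty fields become `NA`). Errors
#' name the offending row and column, so malformed exports fail loudly
#' rather than silently coercing.
#'
#' @param path Path to the CSV file.
#' @param label_column Name of the class label column (default `"label"`);
#'   use `NULL` for a label-free table.
#' @return A list of class `"labeled_dataset"` (with `truth = NULL` unless a
#'   manifest written by [write_dataset()] sits next to the file, in which
#'   case the recorded truth set is restored).
#' @export
read_feature_csv <- function(path, label_column = "label") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (anyDuplicated(names(raw))) {
    stop(sprintf("duplicate header name(s): %s",
                 paste(unique(names(raw)[duplicated(names(raw))]),
                       collapse = ", ")), call. = FALSE)
  }
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(raw)) {
      stop(sprintf("label column '%s' not present", label_column), call. = FALSE)
    }
    labels <- factor(raw[[label_column]])
    raw[[label_column]] <- NULL
  }
  features <- raw
  for (col in names(features)) {
    v <- features[[col]]
    v[v == ""] <- NA_character_
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in column '%s', data row %d (file line %d)",
                   v[bad[1]], col, bad[1], bad[1] + 1L), call. = FALSE)
    }
    features[[col]] <- parsed
  }
  truth <- NULL
  spec <- NULL
  manifest_path <- paste0(path, ".manifest.json")
  if (file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    truth <- manifest$truth
    if (!is.null(manifest$spec)) {
      spec <- tryCatch(do.call(generator_spec, manifest$spec),
                       error = function(e) NULL)
    }
  }
  structure(list(features = features, labels = labels, truth = truth,
                 spec = spec),
            class = "labeled_dataset")
}

# ---- Run configuration -------------------------------------------------

config_schema <- function() {
  list(
    seed = 0L,
    generator = formals(generator_spec),
    forest = formals(forest_config),
    optimizer = formals(optimizer_config),
    pipeline = list(ratio = 0.7, k_folds = 5L,
                    n_trees_grid = c(50L, 100L, 150L, 200L),
                    max_depth_grid = c(10L, 20L, 30L, 40L)),
    output_dir = ".")
}

#' Default run configuration
#'
#' The full set of knobs for an end-to-end run: generator spec, forest
#' config, optimizer config, pipeline options (split ratio, folds, search
#' grid), output directory and a single top-level seed that feeds every
#' stage. Round-trips losslessly through [save_run_config()] /
#' [load_run_config()].
#'
#' @param seed Top-level integer seed.
#' @return A nested list of class `"run_config"`.
#' @export
default_run_config <- function(seed = 0) {
  schema <- config_schema()
  cfg <- list(
    seed = as.integer(seed),
    generator = lapply(schema$generator, eval),
    forest = lapply(schema$forest, function(x) if (is.null(x)) NULL else eval(x)),
    optimizer = lapply(schema$optimizer, eval),
    pipeline = schema$pipeline,
    output_dir = ".")
  cfg$generator$seed <- as.integer(seed)
  cfg$forest$seed <- as.integer(seed)
  cfg$optimizer$seed <- as.integer(seed)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  schema <- default_run_config()
  check_keys <- function(got, allowed, where) {
    unknown <- setdiff(got, allowed)
    if (length(unknown) > 0) {
      hint <- ""
      d <- utils::adist(unknown[1], allowed)
      if (min(d) <= 2) {
        hint <- sprintf(" (did you mean '%s'?)", allowed[which.min(d)])
      }
      stop(sprintf("unknown config key '%s' in %s%s", unknown[1], where, hint),
           call. = FALSE)
    }
  }
  check_keys(names(cfg), names(schema), "top level")
  for (section in c("generator", "forest", "optimizer", "pipeline")) {
    if (!is.null(cfg[[section]])) {
      check_keys(names(cfg[[section]]), names(schema[[section]]), section)
    }
  }
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file, rejects unknown keys (suggesting the nearest valid
#' key), fills omitted keys from [default_run_config()] (an omitted seed
#' defaults to 0), and propagates the top-level seed to any stage seed not
#' set explicitly.
#'
#' @param path YAML file path.
#' @return A `"run_config"`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_run_config(user)
  seed <- if (is.null(user$seed)) 0L else as.integer(user$seed)
  cfg <- default_run_config(seed)
  for (key in names(user)) {
    if (is.list(cfg[[key]]) && is.list(user[[key]])) {
      # [ <- list(...) ] keeps explicit-NULL entries instead of deleting them
      for (sub in names(user[[key]])) {
        cfg[[key]][sub] <- user[[key]][sub]
      }
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  cfg$seed <- seed
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration to YAML
#'
#' Writes every key explicitly (including defaults and the resolved seed),
#' so the saved file alone is sufficient to re-run identically.
#'
#' @param cfg A `"run_config"`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(cfg, path) {
  validate_run_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Export an importance ranking to CSV
#'
#' @param imp The data frame returned by [importance.weighted_rf()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_importance_csv <- function(imp, path) {
  utils::write.csv(imp[order(imp$rank),
                       c("feature", "raw_score", "normalized_score", "rank")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted forest to JSON
#'
#' Writes the complete forest (per-tree node tables, thresholds, weights,
#' classes, config and seed) to a documented JSON layout, from which
#' [read_forest_json()] reconstructs an identical predictor.
#'
#' @param forest A fitted [weighted_rf()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_forest_json <- function(forest, path) {
  trees <- lapply(forest$trees, function(tr) {
    list(feature = tr$feature, threshold = tr$threshold, left = tr$left,
         right = tr$right, depth = tr$depth, n_node = tr$n_node,
         counts = tr$counts, gini = tr$gini,
         delta_unweighted = tr$delta_unweighted,
         delta_weighted = tr$delta_weighted, leaf_class = tr$leaf_class)
  })
  obj <- list(format = "raindropRF-forest-v1", trees = trees,
              weights = forest$weights, oob_error = forest$oob_error,
              classes = forest$classes, feature_names = forest$feature_names,
              n_train = forest$n_train, config = unclass(forest$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a forest serialized by [write_forest_json()]
#'
#' @param path JSON file path.
#' @return A `"weighted_rf"` object (without the in-bag index lists, which
#'   are not needed for prediction or importance).
#' @export
read_forest_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "raindropRF-forest-v1")) {
    stop("not a raindropRF forest JSON file", call. = FALSE)
  }
  trees <- lapply(seq_len(nrow_or_len(obj$trees)), function(i) {
    tr <- if (is.data.frame(obj$trees)) lapply(obj$trees, `[[`, i)
          else obj$trees[[i]]
    tr$feature <- as.integer(tr$feature)
    tr$left <- as.integer(tr$left)
    tr$right <- as.integer(tr$right)
    tr$leaf_class <- as.integer(tr$leaf_class)
    tr$counts <- matrix(as.integer(tr$counts), ncol = length(obj$classes))
    tr$classes <- obj$classes
    tr$feature_names <- obj$feature_names
    class(tr) <- "ig_tree"
    tr
  })
  cfg <- obj$config
  fps <- cfg$features_per_split
  if (length(fps) == 0 || all(is.na(fps))) fps <- NULL
  cfg_obj <- forest_config(n_trees = cfg$n_trees, max_depth = cfg$max_depth,
                           features_per_split = fps,
                           min_samples_leaf = cfg$min_samples_leaf,
                           removal_fraction = cfg$removal_fraction,
                           seed = cfg$seed)
  structure(
    list(trees = trees, weights = obj$weights, oob_error = obj$oob_error,
         in_bag = NULL, classes = obj$classes,
         feature_names = obj$feature_names, n_train = obj$n_train,
         config = cfg_obj),
    class = "weighted_rf")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
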