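# Synthetic fitness-indicator data with planted class effects.
#
# The generator emulates the structure a two-group exercise-effect study
# assumes: one row per participant, numeric physical-fitness indicator
# columns, a binary label (competition vs non-competition), a small set of
# truly informative indicators whose class-conditional means differ by a
# configurable number of within-class SDs, and the rest pure noise.

# Cosmetic indicator vocabulary: plausible baseline mean/SD per indicator so
# generated CSVs read like fitness data. Purely presentational; the planted
# effects are defined in within-class SD units, not in these raw units.
.indicator_vocab <- data.frame(
  name = c("height", "weight", "resting_heart_rate", "vital_capacity",
           "sprint_time", "standing_long_jump", "sit_and_reach",
           "grip_strength", "vo2max", "body_fat_pct", "systolic_bp",
           "diastolic_bp", "reaction_time", "endurance_run_time",
           "pushup_count", "situp_count", "agility_score", "balance_score",
           "jump_height", "throw_distance", "step_test_score",
           "flexibility_score", "lean_mass", "stride_length"),
  mean = c(170, 65, 68, 3500, 8.2, 210, 12, 38, 42, 18, 118, 76, 0.28, 540,
           28, 35, 14, 60, 45, 18, 55, 50, 52, 1.2),
  sd = c(8, 10, 9, 500, 0.8, 20, 6, 7, 6, 5, 10, 8, 0.05, 60,
         8, 9, 2.5, 12, 7, 4, 10, 11, 6, 0.15),
  stringsAsFactors = FALSE
)

indicator_names <- function(p) {
  if (p <= nrow(.indicator_vocab)) return(.indicator_vocab$name[seq_len(p)])
  c(.indicator_vocab$name,
    sprintf("indicator_%02d", seq_len(p - nrow(.indicator_vocab)) +
              nrow(.indicator_vocab)))
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification for the synthetic fitness-data generator
#'
#' Collects and validates every knob of the generator. Defaults describe the
#' package's reference study conditions: 1500 participants, 5 informative
#' indicators shifted by 1.5 within-class SDs between the competition and
#' non-competition groups, 15 noise indicators, balanced classes.
#'
#' @param n_participants Number of rows to generate.
#' @param n_informative Number of indicators with a planted class effect.
#' @param n_noise Number of class-independent noise indicators.
#' @param effect_sizes Mean shift between classes for each informative
#'   indicator, in within-class SD units. A single value is recycled.
#' @param class_balance Fraction of participants in the positive
#'   ("competition") class.
#' @param missing_rate Fraction of feature cells blanked by
#'   [inject_missing_and_outliers()].
#' @param outlier_rate Fraction of feature cells replaced by values beyond
#'   3 column SDs by [inject_missing_and_outliers()].
#' @param n_categories Number of sport-category tasks produced by
#'   [generate_category_tasks()].
#' @param seed Integer RNG seed; the same seed yields byte-identical data.
#' @return A validated list of class `"generator_spec"`.
#' @examples
#' spec <- generator_spec(n_participants = 200, seed = 1)
#' @export
generator_spec <- function(n_participants = 1500,
                           n_informative = 5,
                           n_noise = 15,
                           effect_sizes = 1.5,
                           class_balance = 0.5,
                           missing_rate = 0.02,
                           outlier_rate = 0.005,
                           n_categories = 4,
                           seed = 0) {
  effect_sizes <- as.numeric(effect_sizes)
  n_inf <- max(as.integer(n_informative), 1L)
  if (!length(effect_sizes) %in% c(1L, n_inf)) {
    stop(sprintf(paste0("invalid generator spec: field 'effect_sizes' has ",
                        "length %d, expected 1 or %d"),
                 length(effect_sizes), n_inf), call. = FALSE)
  }
  spec <- list(n_participants = as.integer(n_participants),
               n_informative = as.integer(n_informative),
               n_noise = as.integer(n_noise),
               effect_sizes = rep_len(effect_sizes, n_inf),
               class_balance = as.numeric(class_balance),
               missing_rate = as.numeric(missing_rate),
               outlier_rate = as.numeric(outlier_rate),
               n_categories = as.integer(n_categories),
               seed = as.integer(seed))
  validate_generator_spec(spec)
  class(spec) <- "generator_spec"
  spec
}

validate_generator_spec <- function(spec) {
  check <- function(ok, field, why) {
    if (!ok) stop(sprintf("invalid generator spec: field '%s' %s", field, why),
                  call. = FALSE)
  }
  check(spec$n_participants >= 2, "n_participants", "must be >= 2")
  check(spec$n_informative >= 0, "n_informative", "must be >= 0")
  check(spec$n_noise >= 0, "n_noise", "must be >= 0")
  check(spec$n_informative + spec$n_noise >= 1, "n_informative",
        "+ n_noise must be >= 1")
  check(length(spec$effect_sizes) == max(spec$n_informative, 1L),
        "effect_sizes", "must have one entry per informative indicator")
  for (f in c("class_balance", "missing_rate", "outlier_rate")) {
    check(spec[[f]] >= 0 && spec[[f]] <= 1, f, "must be in [0, 1]")
  }
  check(spec$class_balance > 0 && spec$class_balance < 1, "class_balance",
        "must be strictly inside (0, 1)")
  check(spec$n_categories >= 1, "n_categories", "must be >= 1")
  invisible(spec)
}

#' Generate a labelled synthetic fitness dataset
#'
#' Draws a participant-by-indicator matrix under the class-conditional
#' Gaussian model: informative indicators have class means separated by
#' `effect_sizes` within-class SDs (half the shift applied to each class, so
#' the pooled column stays centred on the indicator's baseline); noise
#' indicators are independent of the class. Labels are drawn per
#' `class_balance`. The returned object records the ground-truth informative
#' column names, which downstream evaluation uses for top-k precision.
#'
#' Missing cells and outliers are *not* injected here; see
#' [inject_missing_and_outliers()].
#'
#' @param spec A [generator_spec()].
#' @return A list of class `"labeled_dataset"`: `features` (data frame),
#'   `labels` (factor, levels `non_competition`, `competition`), `truth`
#'   (character vector of informative column names), `spec`.
#' @export
generate_dataset <- function(spec) {
  if (!inherits(spec, "generator_spec")) spec <- do.call(generator_spec, spec)
  validate_generator_spec(spec)
  with_local_seed(spec$seed, {
    n <- spec$n_participants
    p <- spec$n_informative + spec$n_noise
    nms <- indicator_names(p)
    base <- merge(data.frame(name = nms, order = seq_len(p)),
                  .indicator_vocab, by = "name", all.x = TRUE)
    base <- base[order(base$order), ]
    base$mean[is.na(base$mean)] <- 50
    base$sd[is.na(base$sd)] <- 10
    labels <- factor(
      ifelse(stats::runif(n) < spec$class_balance,
             "competition", "non_competition"),
      levels = c("non_competition", "competition"))
    informative <- if (spec$n_informative > 0) {
      sort(sample.int(p, spec$n_informative))
    } else integer(0)
    X <- matrix(0, n, p, dimnames = list(NULL, nms))
    pos <- labels == "competition"
    eff <- numeric(p)
    eff[informative] <- spec$effect_sizes[seq_along(informative)]
    for (j in seq_len(p)) {
      mu <- rep(base$mean[j], n)
      # half the shift up for competition, half down, in within-class SDs
      mu <- mu + ifelse(pos, 0.5, -0.5) * eff[j] * base$sd[j]
      X[, j] <- stats::rnorm(n, mean = mu, sd = base$sd[j])
    }
    structure(
      list(features = as.data.frame(X), labels = labels,
           truth = nms[informative], spec = spec),
      class = "labeled_dataset")
  })
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("Synthetic fitness dataset: %d participants x %d indicators\n",
              nrow(x$features), ncol(x$features)))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  cat(sprintf("  informative (truth): %s\n", paste(x$truth, collapse = ", ")))
  invisible(x)
}

#' Inject missing cells and 3-sigma outliers into a dataset
#'
#' Blanks exactly `round(missing_rate * n_cells)` feature cells (as `NA`) and
#' replaces exactly `round(outlier_rate * n_cells)` *other* cells by values
#' 4-6 pre-injection column SDs away from the pre-injection column mean
#' (random sign), guaranteeing every injected outlier trips a 3-sigma filter.
#' The label column is never touched. Pre-injection column statistics and the
#' injected cell positions are recorded in the returned object's `injection`
#' element so tests can verify the injected cells directly.
#'
#' @param dataset A `"labeled_dataset"`.
#' @param missing_rate,outlier_rate Cell fractions in `[0, 1]`; default to
#'   the rates in the dataset's generator spec.
#' @param seed Integer seed for cell selection.
#' @return The dataset with cells modified and an `injection` record:
#'   `missing_cells`, `outlier_cells` (two-column row/col index matrices),
#'   `column_mean`, `column_sd` (pre-injection statistics).
#' @export
inject_missing_and_outliers <- function(dataset,
                                        missing_rate = dataset$spec$missing_rate,
                                        outlier_rate = dataset$spec$outlier_rate,
                                        seed = dataset$spec$seed + 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (missing_rate < 0 || missing_rate > 1 ||
      outlier_rate < 0 || outlier_rate > 1) {
    stop("missing_rate and outlier_rate must be in [0, 1]", call. = FALSE)
  }
  X <- as.matrix(dataset$features)
  n_cells <- length(X)
  n_miss <- round(missing_rate * n_cells)
  n_out <- round(outlier_rate * n_cells)
  if (n_miss + n_out > n_cells) {
    stop("missing_rate + outlier_rate exceed the number of cells", call. = FALSE)
  }
  col_mean <- colMeans(X)
  col_sd <- apply(X, 2, stats::sd)
  with_local_seed(seed, {
    cells <- sample.int(n_cells, n_miss + n_out)
    out_cells <- cells[seq_len(n_out)]
    miss_cells <- cells[n_out + seq_len(n_miss)]
    if (n_out > 0) {
      j <- ((out_cells - 1) %/% nrow(X)) + 1
      shift <- stats::runif(n_out, 4, 6) * sample(c(-1, 1), n_out, replace = TRUE)
      X[out_cells] <- col_mean[j] + shift * col_sd[j]
    }
    if (n_miss > 0) X[miss_cells] <- NA_real_
    as_ij <- function(cells) {
      cbind(row = ((cells - 1) %% nrow(X)) + 1,
            col = ((cells - 1) %/% nrow(X)) + 1)
    }
    dataset$features <- as.data.frame(X)
    dataset$injection <- list(
      missing_cells = as_ij(miss_cells), outlier_cells = as_ij(out_cells),
      column_mean = col_mean, column_sd = col_sd)
    dataset
  })
}

#' Generate one dataset per sport category with disjoint informative sets
#'
#' Stands in for a per-category evaluation (wrestling, racing, skills, ...):
#' each category gets its own dataset over the same indicator columns, but
#' with an informative subset sampled without replacement across categories,
#' so the truth sets are pairwise disjoint (requires
#' `n_categories * n_informative <=` total columns).
#'
#' @param spec A [generator_spec()].
#' @return A list of `n_categories` `"labeled_dataset"` objects, named
#'   `category_1`, `category_2`, ...
#' @export
generate_category_tasks <- function(spec) {
  if (!inherits(spec, "generator_spec")) spec <- do.call(generator_spec, spec)
  validate_generator_spec(spec)
  p <- spec$n_informative + spec$n_noise
  need <- spec$n_categories * spec$n_informative
  if (need > p) {
    stop(sprintf(paste0("cannot give %d categories disjoint informative sets:",
                        " %d columns needed, %d available"),
                 spec$n_categories, need, p), call. = FALSE)
  }
  nms <- indicator_names(p)
  with_local_seed(spec$seed, {
    slots <- sample.int(p, need)
    sub_seeds <- sample.int(.Machine$integer.max %/% 2, spec$n_categories)
    tasks <- vector("list", spec$n_categories)
    for (k in seq_len(spec$n_categories)) {
      informative <- sort(slots[(k - 1) * spec$n_informative +
                                  seq_len(spec$n_informative)])
      sub <- spec
      sub$seed <- sub_seeds[k]
      sub$n_categories <- 1L
      ds <- generate_dataset_at(sub, informative, nms)
      tasks[[k]] <- ds
    }
    names(tasks) <- sprintf("category_%d", seq_len(spec$n_categories))
    tasks
  })
}

# generate_dataset with the informative column positions imposed rather than
# sampled; shared by generate_category_tasks.
generate_dataset_at <- function(spec, informative, nms) {
  with_local_seed(spec$seed, {
    n <- spec$n_participants
    p <- length(nms)
    base <- merge(data.frame(name = nms, order = seq_len(p)),
                  .indicator_vocab, by = "name", all.x = TRUE)
    base <- base[order(base$order), ]
    base$mean[is.na(base$mean)] <- 50
    base$sd[is.na(base$sd)] <- 10
    labels <- factor(
      ifelse(stats::runif(n) < spec$class_balance,
             "competition", "non_competition"),
      levels = c("non_competition", "competition"))
    pos <- labels == "competition"
    eff <- numeric(p)
    eff[informative] <- spec$effect_sizes[seq_along(informative)]
    X <- matrix(0, n, p, dimnames = list(NULL, nms))
    for (j in seq_len(p)) {
      mu <- base$mean[j] + ifelse(pos, 0.5, -0.5) * eff[j] * base$sd[j]
      X[, j] <- stats::rnorm(n, mean = mu, sd = base$sd[j])
    }
    structure(
      list(features = as.data.frame(X), labels = labels,
           truth = nms[informative], spec = spec),
      class = "labeled_dataset")
  })
}

#' Write a labelled dataset to CSV with a JSON manifest
#'
#' The CSV has a header row, one participant per row, the label in a final
#' `label` column, and empty fields for missing cells. A sidecar
#' `<path>.manifest.json` records the generator spec, seed and ground-truth
#' informative columns, enough to regenerate the file exactly.
#'
#' @param dataset A `"labeled_dataset"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_feature_csv()]
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  out <- dataset$features
  out$label <- as.character(dataset$labels)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  manifest <- list(
    seed = dataset$spec$seed,
    spec = unclass(dataset$spec),
    truth = dataset$truth,
    label_column = "label")
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
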