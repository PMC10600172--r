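#' Random-forest hyperparameters
#'
#' One binary random forest is trained per behavior.  Trees are grown on
#' bootstrap-free column-subsampled data (`sqrt(p)` features per node,
#' gini-equivalent variance splitting on 0/1 labels), 100-1500 trees,
#' minimum leaf size 1 or 2, a 20% held-out test fraction and no sampling
#' adjustment (no class rebalancing).
#'
#' @param n_trees Number of trees, in `[100, 1500]` (default 500).
#' @param min_leaf Minimum observations per leaf, 1 or 2.
#' @param test_fraction Held-out test fraction (0.20).
#' @param seed Integer seed recorded in the bundle; all stochastic steps
#'   (split, tree column sampling) derive from it.
#' @param criterion,max_features,sampling_adjustment Fixed to `"gini"`,
#'   `"sqrt"`, `"none"`; recorded for provenance.
#'
#' @return An `rf_hyperparams` list.
#' @export
rf_hyperparams <- function(n_trees = 500, min_leaf = 1,
                           test_fraction = 0.20, seed = 1L,
                           criterion = "gini", max_features = "sqrt",
                           sampling_adjustment = "none") {
  if (n_trees < 100 || n_trees > 1500) {
    abort("`n_trees` must lie in [100, 1500].")
  }
  if (!min_leaf %in% c(1, 2)) abort("`min_leaf` must be 1 or 2.")
  stopifnot(identical(criterion, "gini"), identical(max_features, "sqrt"),
            identical(sampling_adjustment, "none"))
  structure(
    list(
      n_trees = as.integer(n_trees), min_leaf = as.integer(min_leaf),
      criterion = criterion, max_features = max_features,
      test_fraction = test_fraction,
      sampling_adjustment = sampling_adjustment, seed = as.integer(seed)
    ),
    class = "rf_hyperparams"
  )
}

#' Keep every other frame, per video
#'
#' Adjacent frames carry nearly identical features and labels; training
#' sets are thinned by keeping the even-indexed frames of each video
#' (indices 0, 2, 4, ... within each video, not a global stride).
#'
#' @param fm Feature matrix tibble with a `video_id` column.
#' @param labels Aligned label vector (or data frame of label columns).
#'
#' @return List with thinned `features` and `labels`.
#' @export
subsample_alternate_frames <- function(fm, labels) {
  n_lab <- if (is.data.frame(labels)) nrow(labels) else length(labels)
  if (nrow(fm) != n_lab) {
    abort("`fm` and `labels` have different lengths.",
          class = "nw_validation_error")
  }
  vid <- fm$video_id %||% rep("video", nrow(fm))
  keep <- unlist(lapply(split(seq_along(vid), vid), function(idx) {
    idx[seq(1, length(idx), by = 2)]
  }), use.names = FALSE)
  keep <- sort(keep)
  list(
    features = fm[keep, , drop = FALSE],
    labels = if (is.data.frame(labels)) labels[keep, , drop = FALSE]
             else labels[keep]
  )
}

# Fit the forest: single boosting round of n_trees parallel trees with
# unshrunken leaf means, so the prediction is the forest-average of leaf
# label means -- i.e. a random-forest probability.
fit_forest <- function(x, y, hp) {
  p <- ncol(x)
  params <- list(
    objective = "reg:squarederror",
    eta = 1, lambda = 0, alpha = 0,
    num_parallel_tree = hp$n_trees,
    colsample_bynode = max(sqrt(p) / p, 1 / p),
    subsample = 1,
    max_depth = 20,
    min_child_weight = hp$min_leaf,
    seed = substream_seed(hp$seed, "forest"),
    nthread = 1
  )
  xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(x, label = as.numeric(y)),
    nrounds = 1, verbose = 0
  )
}

forest_probs <- function(booster, x) {
  pmin(pmax(predict(booster, xgboost::xgb.DMatrix(x)), 0), 1)
}

#' Train one binary behavior classifier
#'
#' Performs a stratified, seeded 80/20 train/test split, fits the forest,
#' computes the precision-recall curve on the test split across a
#' threshold grid, selects the discrimination threshold (smallest
#' threshold attaining maximal F1, unless overridden), and records test
#' precision/recall/F1 at that threshold in the bundle.
#'
#' @param fm Feature matrix tibble (from [extract_features()], possibly
#'   row-bound over videos).
#' @param labels Logical (or 0/1) per-frame labels for one behavior.
#' @param behavior Behavior name recorded in the bundle.
#' @param hp [rf_hyperparams()].
#' @param threshold_grid Candidate discrimination thresholds.
#' @param threshold_override Optional manual threshold (the visual
#'   inspection step made explicit); recorded with provenance `"manual"`.
#' @param manifest Feature manifest used to select feature columns.
#'
#' @return A `behavior_classifier` bundle.
#' @export
train_classifier <- function(fm, labels, behavior = "behavior",
                             hp = rf_hyperparams(),
                             threshold_grid = seq(0, 1, by = 0.02),
                             threshold_override = NULL,
                             manifest = feature_manifest()) {
  y <- as.logical(labels)
  if (length(y) != nrow(fm)) {
    abort("`fm` and `labels` have different lengths.",
          class = "nw_validation_error")
  }
  if (length(unique(y)) < 2) {
    abort(sprintf("Labels for '%s' contain a single class.", behavior),
          class = "nw_validation_error")
  }
  cols <- feature_columns(fm, manifest)
  x <- as.matrix(fm[cols])
  storage.mode(x) <- "double"

  # stratified 80/20 split, seeded
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(substream_seed(hp$seed, paste0("split-", behavior)))
  idx_pos <- which(y); idx_neg <- which(!y)
  test_idx <- sort(c(
    sample(idx_pos, max(1L, round(hp$test_fraction * length(idx_pos)))),
    sample(idx_neg, max(1L, round(hp$test_fraction * length(idx_neg))))
  ))
  train_idx <- setdiff(seq_along(y), test_idx)
  if (length(unique(y[train_idx])) < 2) {
    abort(sprintf("Training split for '%s' has a single class.", behavior),
          class = "nw_validation_error")
  }

  booster <- fit_forest(x[train_idx, , drop = FALSE], y[train_idx], hp)
  test_probs <- forest_probs(booster, x[test_idx, , drop = FALSE])
  curve <- pr_curve_probs(test_probs, y[test_idx], threshold_grid)
  thr <- select_threshold(curve, override = threshold_override)
  ev <- evaluate(test_probs >= thr, y[test_idx])

  structure(
    list(
      behavior = behavior,
      booster = booster,
      feature_names = cols,
      threshold = as.numeric(thr),
      threshold_provenance = attr(thr, "provenance") %||% "pr_curve",
      hyperparams = hp,
      manifest_version = manifest_version(manifest),
      base_rate = mean(y[train_idx]),
      training_stats = list(
        n_frames = length(y), n_train = length(train_idx),
        n_test = length(test_idx), positive_fraction = mean(y),
        precision = ev$precision, recall = ev$recall, f1 = ev$f1
      ),
      pr = curve
    ),
    class = "behavior_classifier"
  )
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.behavior_classifier <- function(x, ...) {
  s <- x$training_stats
  cat(sprintf(
    paste0("<behavior_classifier %s: %d trees, threshold %.2f (%s),\n",
           "  test precision %.3f recall %.3f F1 %.3f, base rate %.3f>\n"),
    x$behavior, x$hyperparams$n_trees, x$threshold,
    x$threshold_provenance, s$precision, s$recall, s$f1, x$base_rate
  ))
  invisible(x)
}

#' Precision, recall and F1 of binary frame labels
#'
#' Precision is the fraction of true positives among frames scored
#' positive, recall the fraction of true positives retrieved out of all
#' positive frames, F1 their harmonic mean.  Zero-denominator cases
#' return 0 with a `zero_denominator` attribute flag.
#'
#' @param pred,truth Logical (or 0/1) vectors of equal length.
#' @return One-row tibble with `precision`, `recall`, `f1`.
#' @export
#' @examples
#' evaluate(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
evaluate <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (length(pred) != length(truth)) {
    abort("`pred` and `truth` have different lengths.",
          class = "nw_validation_error")
  }
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  flags <- c(precision = (tp + fp) == 0, recall = (tp + fn) == 0)
  precision <- if (flags["precision"]) 0 else tp / (tp + fp)
  recall <- if (flags["recall"]) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  out <- tibble::tibble(precision = precision, recall = recall, f1 = f1)
  attr(out, "zero_denominator") <- flags
  out
}

#' F1 from precision and recall
#'
#' @param precision,recall Scores in `[0, 1]`.
#' @return Harmonic mean (0 when both are 0).
#' @export
#' @examples
#' round(f1_score(0.71, 0.69), 2) # 0.70
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

pr_curve_probs <- function(probs, truth, grid = seq(0, 1, by = 0.02)) {
  truth <- as.logical(truth)
  if (any(grid < 0 | grid > 1)) abort("`grid` must lie within [0, 1].")
  if (!any(truth)) {
    abort("No positive labels: recall is undefined.",
          class = "nw_validation_error")
  }
  grid <- sort(unique(grid))
  rows <- purrr::map_dfr(grid, function(t) {
    evaluate(probs >= t, truth)
  })
  out <- dplyr::bind_cols(tibble::tibble(threshold = grid), rows)
  structure(out, class = c("pr_curve", class(out)))
}

#' Precision-recall curve of a classifier over a threshold grid
#'
#' @param bundle A `behavior_classifier`.
#' @param fm Feature matrix tibble.
#' @param labels True labels for the same frames.
#' @param grid Thresholds within `[0, 1]`.
#' @return A `pr_curve` tibble: `threshold`, `precision`, `recall`, `f1`.
#' @export
pr_curve <- function(bundle, fm, labels, grid = seq(0, 1, by = 0.02)) {
  pred <- predict(bundle, fm)
  pr_curve_probs(pred$probability, labels, grid)
}

#' Select the discrimination threshold from a precision-recall curve
#'
#' Default criterion: the smallest threshold attaining the maximal F1 on
#' the curve.  An explicit `override` (the visual-inspection adjustment
#' made configurable) is returned unchanged with provenance `"manual"`.
#'
#' @param curve A `pr_curve` tibble.
#' @param override Optional manual threshold.
#' @return Threshold with attribute `provenance`.
#' @export
select_threshold <- function(curve, override = NULL) {
  if (!is.null(override)) {
    stopifnot(override >= 0, override <= 1)
    return(structure(as.numeric(override), provenance = "manual"))
  }
  if (nrow(curve) == 0 || all(!is.finite(curve$f1))) {
    abort("Cannot select a threshold: F1 undefined everywhere.",
          class = "nw_validation_error")
  }
  best <- max(curve$f1)
  structure(min(curve$threshold[curve$f1 == best]),
            provenance = "pr_curve")
}

#' Predict behavior probabilities and labels for new frames
#'
#' A frame is labeled positive when its probability is at or above the
#' bundle's discrimination threshold (`>=` convention).  Behaviors are
#' predicted independently; frames may carry several.
#'
#' @param object A `behavior_classifier`.
#' @param fm Feature matrix tibble; its manifest version must match the
#'   bundle's.
#' @param ... Unused.
#' @return Tibble with `probability` and logical `label`.
#' @export
predict.behavior_classifier <- function(object, fm, ...) {
  fm_ver <- attr(fm, "manifest_version")
  if (!is.null(fm_ver) && !identical(fm_ver, object$manifest_version)) {
    abort(sprintf(
      "Manifest mismatch: features '%s' vs bundle '%s'.",
      fm_ver, object$manifest_version
    ), class = "nw_validation_error")
  }
  x <- as.matrix(fm[object$feature_names])
  storage.mode(x) <- "double"
  probs <- forest_probs(object$booster, x)
  tibble::tibble(probability = probs, label = probs >= object$threshold)
}

#' Merge two behaviors into one (element-wise OR)
#'
#' Used to score near-confusable behaviors (eating and drinking) as one.
#'
#' @param labels_a,labels_b Logical vectors of equal length.
#' @return Logical vector.
#' @export
merge_behaviors <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("Label vectors have different lengths.",
          class = "nw_validation_error")
  }
  as.logical(labels_a) | as.logical(labels_b)
}

#' Save / load a classifier bundle
#'
#' The bundle directory holds the serialized forest (`model.ubj`), and a
#' plain-text provenance sidecar (`bundle.yaml`) with behavior, threshold
#' and its provenance, hyperparameters, manifest version, base rate and
#' training statistics.
#'
#' @param bundle A `behavior_classifier`.
#' @param dir Bundle directory (created if needed).
#' @return `dir` (write) / a `behavior_classifier` (read).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(bundle$booster, file.path(dir, "model.ubj"))
  side <- bundle[setdiff(names(bundle), c("booster", "pr"))]
  side$hyperparams <- unclass(side$hyperparams)
  yaml::write_yaml(side, file.path(dir, "bundle.yaml"))
  utils::write.csv(as.data.frame(bundle$pr),
                   file.path(dir, "pr_curve.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  side <- yaml::read_yaml(file.path(dir, "bundle.yaml"))
  side$booster <- xgboost::xgb.load(file.path(dir, "model.ubj"))
  side$feature_names <- unlist(side$feature_names)
  side$hyperparams <- structure(side$hyperparams, class = "rf_hyperparams")
  pr <- tibble::as_tibble(utils::read.csv(file.path(dir, "pr_curve.csv")))
  side$pr <- structure(pr, class = c("pr_curve", class(pr)))
  structure(side[c("behavior", "booster", "feature_names", "threshold",
                   "threshold_provenance", "hyperparams",
                   "manifest_version", "base_rate", "training_stats",
                   "pr")],
            class = "behavior_classifier")
}
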