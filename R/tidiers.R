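#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted behavior classifier
#'
#' One row per feature with the forest's split-gain importance (share of
#' total gain), in manifest order.  For permutation-based importance use
#' [permutation_importance()].
#'
#' @param x A `behavior_classifier`.
#' @param ... Unused.
#' @return Tibble with `feature_name`, `gain`.
#' @export
tidy.behavior_classifier <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  gain <- stats::setNames(rep(0, length(x$feature_names)),
                          x$feature_names)
  gain[imp$Feature] <- imp$Gain
  tibble::tibble(feature_name = x$feature_names, gain = unname(gain))
}

#' One-row summary of a fitted behavior classifier
#'
#' @param x A `behavior_classifier`.
#' @param ... Unused.
#' @return One-row tibble: behavior, hyperparameters, threshold and
#'   held-out test precision/recall/F1.
#' @export
glance.behavior_classifier <- function(x, ...) {
  s <- x$training_stats
  tibble::tibble(
    behavior = x$behavior,
    n_trees = x$hyperparams$n_trees,
    min_leaf = x$hyperparams$min_leaf,
    seed = x$hyperparams$seed,
    threshold = x$threshold,
    threshold_provenance = x$threshold_provenance,
    base_rate = x$base_rate,
    n_frames = s$n_frames,
    positive_fraction = s$positive_fraction,
    precision = s$precision,
    recall = s$recall,
    f1 = s$f1
  )
}

#' @export
tidy.pr_curve <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.pr_curve <- function(x, ...) {
  best <- which.max(x$f1)
  tibble::tibble(
    n_thresholds = nrow(x),
    best_threshold = x$threshold[best],
    best_f1 = x$f1[best]
  )
}

#' @export
tidy.importance_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
tidy.attribution_sample <- function(x, ...) {
  m <- x$scores
  tibble::tibble(
    feature_name = rep(colnames(m), each = nrow(m)),
    row = rep(x$frames$row, ncol(m)),
    present = rep(x$frames$present, ncol(m)),
    attribution = as.vector(m)
  )
}

#' @export
glance.attribution_sample <- function(x, ...) {
  tibble::tibble(
    n_present = sum(x$frames$present),
    n_absent = sum(!x$frames$present),
    base_rate = x$base_rate,
    mean_probability = mean(x$probability)
  )
}
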