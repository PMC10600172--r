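#' Permutation feature importance
#'
#' Estimates the information each feature carries by measuring the loss in
#' classifier skill (F1 at the bundle's discrimination threshold) when
#' that feature column is replaced with a random shuffle of itself, mean
#' over `n_repeats` shuffles.  Features are ranked from most important
#' (rank 1) to least important (rank 218); exact ties are broken by
#' manifest order for determinism.
#'
#' @param bundle A `behavior_classifier`.
#' @param fm Feature matrix tibble.
#' @param labels True labels for the same frames (both classes present).
#' @param n_repeats Shuffles per feature (default 5).
#' @param seed Integer seed.
#' @return An `importance_table` tibble: `feature_name`,
#'   `importance_score`, `rank`.
#' @export
permutation_importance <- function(bundle, fm, labels, n_repeats = 5,
                                   seed = 1L) {
  y <- as.logical(labels)
  if (length(unique(y)) < 2) {
    abort("Labels contain a single class.", class = "nw_validation_error")
  }
  x <- as.matrix(fm[bundle$feature_names])
  storage.mode(x) <- "double"
  base_f1 <- evaluate(forest_probs(bundle$booster, x) >= bundle$threshold,
                      y)$f1
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(substream_seed(seed, "perm-importance"))
  n <- nrow(x)
  scores <- vapply(seq_len(ncol(x)), function(j) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      xp <- x
      xp[, j] <- x[sample.int(n), j]
      f1 <- evaluate(
        forest_probs(bundle$booster, xp) >= bundle$threshold, y
      )$f1
      base_f1 - f1
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  out <- tibble::tibble(
    feature_name = bundle$feature_names,
    importance_score = scores
  )
  # rank 1 = most important; ties broken by manifest (input) order
  ord <- order(-out$importance_score, seq_len(nrow(out)))
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  structure(out, class = c("importance_table", class(out)))
}

#' Mean importance rank per feature category
#'
#' @param table An `importance_table` from [permutation_importance()].
#' @param manifest Feature manifest.
#' @return Tibble with `category`, `mean_rank`, `n_features`, sorted by
#'   `mean_rank` (most important category first).
#' @export
category_mean_rank <- function(table, manifest = feature_manifest()) {
  missing <- setdiff(manifest$name, table$feature_name)
  if (length(missing) > 0) {
    abort(sprintf("Importance table lacks feature(s), e.g. '%s'.",
                  missing[1]), class = "nw_validation_error")
  }
  dplyr::inner_join(
    manifest[, c("name", "category")],
    table, by = c(name = "feature_name")
  ) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      mean_rank = mean(.data$rank),
      n_features = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$mean_rank)
}

#' Additive tree attributions on a 150 + 150 frame sample
#'
#' Draws (seeded) 150 random behavior-present and 150 random
#' behavior-absent frames (all available, with a warning, when fewer
#' exist) and computes per-frame per-feature additive attribution scores
#' with the forest's exact tree-path attribution backend.  For every
#' sampled frame, `base_rate + sum(attributions)` reconstructs the model
#' probability to numerical precision; the base rate is the training
#' positive fraction (the probability of the behavior before any feature
#' is consulted).
#'
#' @param bundle A `behavior_classifier`.
#' @param fm Feature matrix tibble.
#' @param labels True labels for the same frames.
#' @param n_each Frames per class (default 150).
#' @param seed Integer seed.
#' @return An `attribution_sample`: list with `frames` (tibble: `row`,
#'   `present`), `scores` (frames x features matrix), `base_rate`,
#'   `probability` (model probability of each sampled frame),
#'   `feature_names`.
#' @export
attribution_sample <- function(bundle, fm, labels, n_each = 150,
                               seed = 1L) {
  y <- as.logical(labels)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(substream_seed(seed, "attribution"))
  pick <- function(idx, what) {
    if (length(idx) < n_each) {
      warn(sprintf("Only %d behavior-%s frames available (wanted %d).",
                   length(idx), what, n_each))
      idx
    } else {
      sort(sample(idx, n_each))
    }
  }
  rows_pos <- pick(which(y), "present")
  rows_neg <- pick(which(!y), "absent")
  rows <- c(rows_pos, rows_neg)
  x <- as.matrix(fm[rows, bundle$feature_names, drop = FALSE])
  storage.mode(x) <- "double"
  contrib <- predict(bundle$booster, xgboost::xgb.DMatrix(x),
                     predcontrib = TRUE)
  k <- ncol(contrib)
  scores <- contrib[, -k, drop = FALSE]
  colnames(scores) <- bundle$feature_names
  structure(
    list(
      frames = tibble::tibble(
        row = rows,
        present = c(rep(TRUE, length(rows_pos)),
                    rep(FALSE, length(rows_neg)))
      ),
      scores = scores,
      base_rate = unname(contrib[1, k]),
      probability = forest_probs(bundle$booster, x),
      feature_names = bundle$feature_names
    ),
    class = "attribution_sample"
  )
}

#' @export
print.attribution_sample <- function(x, ...) {
  cat(sprintf(
    "<attribution_sample: %d present + %d absent frames, base rate %.3f>\n",
    sum(x$frames$present), sum(!x$frames$present), x$base_rate
  ))
  invisible(x)
}

#' Per-category attribution sums
#'
#' Per feature category, the sum over member features of the mean
#' attribution score, computed separately over behavior-present and
#' behavior-absent frames; signs are preserved (positive sums push
#' probability above the base rate).  Summed over all categories and
#' added to the base rate, each class's value reconstructs that class's
#' mean predicted probability.
#'
#' @param sample An [attribution_sample()].
#' @param manifest Feature manifest.
#' @return Tibble with `category`, `present_sum`, `absent_sum`.
#' @export
attribution_category_sums <- function(sample,
                                      manifest = feature_manifest()) {
  cat_of <- manifest$category[match(sample$feature_names, manifest$name)]
  cats <- unique(manifest$category)
  mean_rows <- function(mask) {
    if (!any(mask)) return(stats::setNames(rep(0, length(cats)), cats))
    m <- colMeans(sample$scores[mask, , drop = FALSE])
    vapply(cats, function(cc) sum(m[cat_of == cc]), numeric(1))
  }
  tibble::tibble(
    category = cats,
    present_sum = unname(mean_rows(sample$frames$present)),
    absent_sum = unname(mean_rows(!sample$frames$present))
  )
}
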