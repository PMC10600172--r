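test_that("alternate-frame subsampling is per video", {
  fm <- tibble::tibble(
    video_id = c(rep("a", 100), rep("b", 10), rep("c", 1)),
    frame = c(0:99, 0:9, 0),
    f = rnorm(111)
  )
  labs <- rep(c(TRUE, FALSE), length.out = 111)
  out <- subsample_alternate_frames(fm, labs)
  expect_equal(nrow(out$features), 50 + 5 + 1)
  kept_a <- out$features$frame[out$features$video_id == "a"]
  expect_equal(kept_a, seq(0, 98, by = 2))
  expect_equal(length(out$labels), nrow(out$features))
  expect_error(subsample_alternate_frames(fm, labs[-1]),
               class = "nw_validation_error")
})

test_that("well-separated synthetic classes reach perfect test F1", {
  set.seed(7)
  n <- 2000
  manifest <- feature_manifest()
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x <- matrix(rnorm(n * 218), n, 218,
              dimnames = list(NULL, manifest$name))
  # two Gaussian blobs separated by 10 sd along 5 features
  x[y, 1:5] <- x[y, 1:5] + 10
  fm <- dplyr::bind_cols(
    tibble::tibble(video_id = "blobs", frame = seq_len(n) - 1L),
    tibble::as_tibble(x)
  )
  b <- train_classifier(fm, y, "blob",
                        rf_hyperparams(n_trees = 100, seed = 7))
  expect_equal(b$training_stats$f1, 1)
  expect_equal(b$training_stats$precision, 1)
  expect_equal(b$training_stats$recall, 1)
})

test_that("shuffled labels score near the positive base rate", {
  set.seed(11)
  n <- 1200
  manifest <- feature_manifest()
  x <- matrix(rnorm(n * 218), n, 218,
              dimnames = list(NULL, manifest$name))
  fm <- dplyr::bind_cols(
    tibble::tibble(video_id = "null", frame = seq_len(n) - 1L),
    tibble::as_tibble(x)
  )
  y <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.3, 0.7))
  b <- train_classifier(fm, y, "null",
                        rf_hyperparams(n_trees = 100, seed = 11),
                        threshold_override = 0.3)
  # with threshold at the base rate, precision ~ base rate; F1 must sit
  # well below what any real signal would produce
  expect_lt(b$training_stats$f1, 0.55)
  expect_gt(b$training_stats$f1, 0.05)
})

test_that("degenerate label vectors are rejected", {
  fix <- toy_informative_features(100)
  expect_error(
    train_classifier(fix$fm, rep(TRUE, 100), "mono"),
    "mono", class = "nw_validation_error"
  )
})

test_that("training is deterministic given the seed", {
  fix <- toy_informative_features(400)
  hp <- rf_hyperparams(n_trees = 100, seed = 99)
  b1 <- train_classifier(fix$fm, fix$labels, "toy", hp)
  b2 <- train_classifier(fix$fm, fix$labels, "toy", hp)
  p1 <- predict(b1, fix$fm)
  p2 <- predict(b2, fix$fm)
  expect_identical(p1, p2)
  expect_identical(b1$threshold, b2$threshold)
  expect_identical(b1$training_stats, b2$training_stats)
})

test_that("evaluate matches a brute-force confusion matrix", {
  # worked example: precision 0.71, recall 0.69 -> F1 0.70 at 2 d.p.
  expect_equal(round(f1_score(0.71, 0.69), 2), 0.70)

  expect_equal(evaluate(c(TRUE, FALSE), c(TRUE, FALSE))$f1, 1)
  ev0 <- evaluate(c(FALSE, FALSE), c(TRUE, FALSE))
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$f1, 0)
  expect_error(evaluate(TRUE, c(TRUE, FALSE)),
               class = "nw_validation_error")

  set.seed(13)
  for (i in 1:10) {
    n <- sample(10:5000, 1)
    pred <- runif(n) < runif(1)
    truth <- runif(n) < runif(1)
    ev <- evaluate(pred, truth)
    bf <- brute_scores(pred, truth)
    expect_equal(unlist(ev), bf, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("PR curves follow the confusion matrix on a toy set", {
  probs <- c(0.9, 0.6, 0.4, 0.1)
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  curve <- nestwatch:::pr_curve_probs(probs, truth, c(0, 0.5, 1))
  at05 <- curve[curve$threshold == 0.5, ]
  expect_equal(at05$precision, 1)
  expect_equal(at05$recall, 1)
  # threshold 0: everything positive -> recall 1
  expect_equal(curve$recall[curve$threshold == 0], 1)
  # perfect probabilities: precision = recall = 1 inside (0, 1)
  perfect <- nestwatch:::pr_curve_probs(
    c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE), c(0.25, 0.5, 0.75)
  )
  expect_true(all(perfect$precision == 1 & perfect$recall == 1))
  expect_error(
    nestwatch:::pr_curve_probs(probs, rep(FALSE, 4), c(0.5)),
    class = "nw_validation_error"
  )
})

test_that("raising the threshold never increases recall", {
  set.seed(17)
  for (i in 1:5) {
    n <- 500
    probs <- runif(n)
    truth <- runif(n) < 0.4
    curve <- nestwatch:::pr_curve_probs(probs, truth, seq(0, 1, 0.05))
    expect_true(all(diff(curve$recall) <= 1e-12))
  }
})

test_that("threshold selection takes the smallest F1-maximal threshold", {
  curve <- structure(
    tibble::tibble(
      threshold = c(0.1, 0.3, 0.4, 0.5, 0.7),
      precision = 1, recall = 1,
      f1 = c(0.5, 0.8, 0.8, 0.8, 0.6)
    ),
    class = c("pr_curve", "tbl_df", "tbl", "data.frame")
  )
  thr <- select_threshold(curve)
  expect_equal(as.numeric(thr), 0.3)
  expect_equal(attr(thr, "provenance"), "pr_curve")
  manual <- select_threshold(curve, override = 0.45)
  expect_equal(as.numeric(manual), 0.45)
  expect_equal(attr(manual, "provenance"), "manual")
})

test_that("prediction uses the >= threshold convention and checks schema", {
  fix <- toy_informative_features(400)
  b <- train_classifier(fix$fm, fix$labels, "toy",
                        rf_hyperparams(n_trees = 100, seed = 1),
                        threshold_override = 0.5)
  pred <- predict(b, fix$fm)
  expect_type(pred$probability, "double")
  expect_identical(pred$label, pred$probability >= 0.5)
  # a probability exactly at the threshold is positive
  b2 <- b; b2$threshold <- pred$probability[1]
  expect_true(predict(b2, fix$fm[1, ])$label)

  fm_bad <- fix$fm
  attr(fm_bad, "manifest_version") <- "fm-9.9"
  expect_error(predict(b, fm_bad), "fm-9.9",
               class = "nw_validation_error")
})

test_that("behavior merging is element-wise OR", {
  a <- c(TRUE, FALSE, FALSE)
  b <- c(FALSE, TRUE, FALSE)
  expect_equal(merge_behaviors(a, b), c(TRUE, TRUE, FALSE))
  expect_equal(merge_behaviors(a, a), a)
  expect_equal(merge_behaviors(a, rep(FALSE, 3)), a)
  expect_error(merge_behaviors(a, b[-1]), class = "nw_validation_error")
})

test_that("bundles survive a save/load round trip", {
  fix <- toy_informative_features(300)
  b <- train_classifier(fix$fm, fix$labels, "toy",
                        rf_hyperparams(n_trees = 100, seed = 3))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "bundle.yaml")))
  back <- read_bundle(dir)
  expect_equal(back$threshold, b$threshold)
  expect_equal(back$behavior, b$behavior)
  expect_equal(predict(back, fix$fm), predict(b, fix$fm))
})

test_that("hyperparameter ranges are enforced", {
  expect_error(rf_hyperparams(n_trees = 50))
  expect_error(rf_hyperparams(n_trees = 2000))
  expect_error(rf_hyperparams(min_leaf = 3))
  hp <- rf_hyperparams(n_trees = 1500, min_leaf = 2, seed = 4)
  expect_equal(hp$criterion, "gini")
  expect_equal(hp$max_features, "sqrt")
  expect_equal(hp$test_fraction, 0.2)
})
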