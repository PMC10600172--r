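# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, fn(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A short simulated session plus its feature matrix.
small_session <- function() {
  cached("small_session", function() {
    simulate_session(sim_scenario(seed = 42, duration_s = 40))
  })
}

small_features <- function() {
  cached("small_features", function() {
    session_features(small_session())
  })
}

# Simulate several sessions and pool features + labels.
pool_sessions <- function(seeds, duration_s = 60, occlusion = NULL) {
  parts <- lapply(seeds, function(s) {
    args <- list(seed = s, duration_s = duration_s)
    if (!is.null(occlusion)) args$occlusion <- occlusion
    ses <- simulate_session(do.call(sim_scenario, args))
    list(fm = session_features(ses), labs = ses$truth$frame_labels)
  })
  list(
    fm = dplyr::bind_rows(lapply(parts, `[[`, "fm")),
    labs = dplyr::bind_rows(lapply(parts, `[[`, "labs"))
  )
}

# Two-feature toy fixture: one perfectly informative feature, one pure
# noise, padded out to the full manifest so bundles stay schema-valid.
toy_informative_features <- function(n = 600, seed = 7) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), length.out = n)
  manifest <- feature_manifest()
  x <- matrix(0, n, nrow(manifest), dimnames = list(NULL, manifest$name))
  x[, "dam_pup_centroid_dist"] <- ifelse(y, 10, 0) + rnorm(n, sd = 0.5)
  x[, "dam_hull_area"] <- rnorm(n) # pure noise
  fm <- dplyr::bind_cols(
    tibble::tibble(video_id = "toy", frame = seq_len(n) - 1L),
    tibble::as_tibble(x)
  )
  attr(fm, "manifest_version") <- manifest_version(manifest)
  list(fm = fm, labels = y)
}

meta30_f <- function(n) {
  video_meta("v", fps = 30, width_px = 1280, height_px = 780,
             px_per_mm = 2, n_frames = n)
}

make_pose_tbl <- function(n = 10, scheme = keypoint_scheme("dam")) {
  set.seed(1)
  tb <- tibble::tibble(frame = seq_len(n) - 1L)
  for (k in scheme$names) {
    tb[[paste0(k, "_x")]] <- runif(n, 0, 1280)
    tb[[paste0(k, "_y")]] <- runif(n, 0, 780)
    tb[[paste0(k, "_p")]] <- runif(n)
  }
  tb
}

# Brute-force confusion-matrix scores, kept independent of evaluate().
brute_scores <- function(pred, truth) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] && truth[i]) tp <- tp + 1
    if (pred[i] && !truth[i]) fp <- fp + 1
    if (!pred[i] && truth[i]) fn <- fn + 1
  }
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f1 = f1)
}
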