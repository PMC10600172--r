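test_that("weighted centroid follows the probability-weighting rule", {
  expect_equal(
    weighted_centroid(cbind(x = c(0, 2), y = c(0, 0), p = c(1, 1))),
    c(1, 0)
  )
  expect_equal(
    weighted_centroid(cbind(x = c(0, 10), y = c(0, 0), p = c(1, 0))),
    c(0, 0)
  )
  # hand evaluation: (0.5*0 + 1*4) / 1.5 = 2.6667
  expect_equal(
    weighted_centroid(cbind(x = c(0, 4), y = c(0, 0), p = c(0.5, 1))),
    c(8 / 3, 0),
    tolerance = 1e-12
  )
  expect_true(all(is.na(
    weighted_centroid(cbind(x = 1:2, y = 1:2, p = c(0, 0)))
  )))
})

test_that("convex hull area handles thresholds and degeneracy", {
  sq <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), p = 1)
  expect_equal(convex_hull_area(sq), 1)
  coll <- cbind(x = c(0, 1, 2), y = c(0, 0, 0), p = 1)
  expect_equal(convex_hull_area(coll), 0)
  # interior points do not change the hull: brute-force over point subsets
  sq5 <- rbind(sq, c(0.5, 0.5, 1))
  expect_equal(convex_hull_area(sq5), convex_hull_area(sq))
  # below-threshold points are excluded
  sq_occ <- sq; sq_occ[3, 3] <- 0.2
  expect_equal(convex_hull_area(sq_occ), 0.5)
  # px_per_mm scales area quadratically
  expect_equal(convex_hull_area(sq, px_per_mm = 2), 0.25)
  expect_equal(convex_hull_area(sq[1:2, ]), 0)
})

test_that("back-arch angle recovers analytic central angles", {
  on_circle <- function(deg, centre = c(0, 0), r = 5) {
    th <- deg * pi / 180
    cbind(x = centre[1] + r * cos(th), y = centre[2] + r * sin(th), p = 1)
  }
  expect_equal(back_arch_angle(on_circle(c(0, 45, 90))), 90,
               tolerance = 1e-8)
  expect_equal(back_arch_angle(on_circle(c(0, 45, 90, 135, 180))), 180,
               tolerance = 1e-8)
  expect_equal(
    back_arch_angle(cbind(x = 0:2, y = c(0, 0, 0), p = 1)), 0
  )
  low <- back_arch_angle(cbind(x = 0:2, y = c(0, 1, 0),
                               p = c(1, 0.2, 0.2)))
  expect_equal(as.numeric(low), 0)
  expect_true(attr(low, "low_confidence"))

  # property: noise-free points from random circles recover the angle
  set.seed(3)
  for (i in 1:25) {
    centre <- runif(2, -100, 100)
    r <- runif(1, 5, 60)
    start <- runif(1, 0, 360)
    span <- runif(1, 20, 300)
    degs <- start + seq(0, span, length.out = 6)
    got <- back_arch_angle(on_circle(degs, centre, r))
    expect_equal(as.numeric(got), span, tolerance = 1e-6)
  }
})

test_that("point movement is likelihood-weighted displacement in mm", {
  tb <- tibble::tibble(
    frame = 0:2,
    a_x = c(0, 3, 3), a_y = c(0, 4, 4), a_p = c(1, 1, 0.5)
  )
  mv <- nestwatch:::movement_series(tb$a_x, tb$a_y, tb$a_p, 1)
  expect_equal(mv, c(0, 5, 0))
  # halved prior likelihood halves the step
  mv2 <- nestwatch:::movement_series(c(0, 3), c(0, 4), c(0.5, 1), 1)
  expect_equal(mv2, c(0, 2.5))
  # px_per_mm division
  mv3 <- nestwatch:::movement_series(c(0, 3), c(0, 4), c(1, 1), 2)
  expect_equal(mv3, c(0, 2.5))
  expect_equal(nestwatch:::movement_series(rep(1, 10), rep(2, 10),
                                           rep(1, 10), 1), rep(0, 10))
})

test_that("rolling statistics match a brute-force window scan", {
  expect_equal(rolling_stat(c(1, 2, 3, 4), "mean", 2, 1),
               c(1, 1.5, 2.5, 3.5))
  expect_equal(rolling_stat(rep(7, 20), "std", 1, 30), rep(0, 20))
  # window of one frame is the identity for mean/sum
  x <- rnorm(50)
  expect_equal(rolling_stat(x, "mean", 1 / 30, 30), x)

  brute <- function(x, stat, w) {
    vapply(seq_along(x), function(i) {
      win <- x[max(1, i - w + 1):i]
      switch(stat,
        mean = mean(win), sum = sum(win),
        std = if (length(win) < 2) 0 else sd(win)
      )
    }, numeric(1))
  }
  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(sample(50:1000, 1), sd = 10)
    for (stat in c("mean", "sum", "std")) {
      span <- sample(c(0.1, 1, 2), 1)
      fps <- sample(c(10, 30), 1)
      w <- max(1, round(span * fps))
      expect_equal(rolling_stat(x, stat, span, fps), brute(x, stat, w),
                   tolerance = 1e-8)
    }
  }
})

test_that("long-window pup centroid holds through occlusion gaps", {
  ses <- small_session()
  pups <- detections_to_table(ses$pup_detections, 8)
  joined <- join_dam_pup(ses$dam, pups)
  ctr <- pup_centroid_longwindow(joined, span_min = 30)
  expect_false(anyNA(ctr))

  # hand-built: two frames of detections, then darkness; value must hold
  bp <- keypoint_scheme("pup")$names
  frames <- nestwatch:::empty_detection_frames(10, bp)
  frames[[1]]$nose <- cbind(c(0, 10), c(0, 0), c(1, 1))
  meta <- video_meta("v", fps = 1, width_px = 100, height_px = 50,
                     px_per_mm = 1, n_frames = 10)
  d <- raw_detections(frames, meta)
  j <- join_dam_pup(
    pose_series(make_pose_tbl(10), meta, keypoint_scheme("dam")),
    detections_to_table(d, 4), meta
  )
  # tiny window: only frame 0 sees pups; later frames hold that centroid
  ctr2 <- pup_centroid_longwindow(j, span_min = 1 / 60)
  expect_equal(ctr2$x, rep(5, 10))
  expect_equal(ctr2$y, rep(0, 10))

  # equal summed weights -> midpoint of the two clusters
  frames3 <- nestwatch:::empty_detection_frames(1, bp)
  frames3[[1]]$nose <- cbind(c(0, 20), c(0, 10), c(0.5, 0.5))
  j3 <- join_dam_pup(
    pose_series(make_pose_tbl(1), meta30_f(1), keypoint_scheme("dam")),
    detections_to_table(raw_detections(frames3, meta30_f(1)), 4),
    meta30_f(1)
  )
  ctr3 <- pup_centroid_longwindow(j3, span_min = 30)
  expect_equal(c(ctr3$x, ctr3$y), c(10, 5))

  # no detections at all -> cage centre, flagged
  frames4 <- nestwatch:::empty_detection_frames(5, bp)
  m4 <- video_meta("v", fps = 1, width_px = 100, height_px = 60,
                   px_per_mm = 1, n_frames = 5)
  j4 <- join_dam_pup(
    pose_series(make_pose_tbl(5), m4, keypoint_scheme("dam")),
    detections_to_table(raw_detections(frames4, m4), 4), m4
  )
  ctr4 <- pup_centroid_longwindow(j4, span_min = 30)
  expect_true(attr(ctr4, "low_confidence"))
  expect_equal(unique(ctr4$x), 50)
  expect_equal(unique(ctr4$y), 30)
})

test_that("the manifest has the documented shape", {
  m <- feature_manifest()
  expect_equal(nrow(m), 218)
  expect_equal(sum(m$source == "dam"), 172)
  expect_equal(sum(m$source == "pup"), 19)
  expect_equal(sum(m$source == "both"), 27)
  expect_equal(sort(unique(m$category)), sort(c(
    "dam_location", "dam_areas", "dam_angles", "dam_probabilities",
    "dam_movement", "pup_area", "pup_probabilities", "dam_pup_distances"
  )))
  expect_false(anyDuplicated(m$name) > 0)
  expect_true(all(stats::na.omit(m$span_s) %in% c(0.1, 1, 2)))
  expect_true(all(stats::na.omit(m$pup_centroid_span_min) %in% c(30, 60)))

  path <- withr::local_tempfile(fileext = ".yaml")
  write_manifest_yaml(m, path)
  back <- read_manifest_yaml(path)
  expect_equal(as.data.frame(back), as.data.frame(m))
  expect_equal(manifest_version(back), manifest_version(m))
})

test_that("extract_features emits the full matrix with no NaN", {
  fm <- small_features()
  m <- feature_manifest()
  expect_equal(ncol(fm), 2 + 218)
  expect_equal(names(fm)[-(1:2)], m$name)
  expect_equal(nrow(fm), small_session()$meta$n_frames)
  expect_false(anyNA(fm))
  expect_error(
    extract_features(
      structure(list(), class = "joined_pose"),
      meta = video_meta("v", fps = 30)
    ),
    "calibrate", class = "nw_validation_error"
  )
})

test_that("features are invariant to per-frame pup slot permutation", {
  ses <- small_session()
  pups <- detections_to_table(ses$pup_detections, 6)
  joined <- join_dam_pup(ses$dam, pups)
  fm1 <- extract_features(joined)

  # permute the slot blocks independently per frame
  set.seed(77)
  bp <- keypoint_scheme("pup")$names
  cols_of_slot <- lapply(1:6, function(s)
    nestwatch:::triple_names(bp, prefix = paste0("pup", s)))
  permuted <- joined
  for (i in seq_len(nrow(joined))) {
    perm <- sample(6)
    for (s in 1:6) {
      permuted[i, cols_of_slot[[s]]] <-
        joined[i, cols_of_slot[[perm[s]]]]
    }
  }
  fm2 <- extract_features(permuted, meta = attr(joined, "meta"))
  expect_equal(as.data.frame(fm2), as.data.frame(fm1), tolerance = 1e-10)
})

test_that("rigid translation shifts only location features", {
  ses <- small_session()
  pups <- detections_to_table(ses$pup_detections, 6)
  joined <- join_dam_pup(ses$dam, pups)
  fm1 <- extract_features(joined)
  tx <- 17; ty <- -23
  shifted <- joined
  xcols <- grep("_x$", names(joined), value = TRUE)
  ycols <- grep("_y$", names(joined), value = TRUE)
  shifted[xcols] <- shifted[xcols] + tx
  shifted[ycols] <- shifted[ycols] + ty
  fm2 <- extract_features(shifted, meta = attr(joined, "meta"))

  m <- feature_manifest()
  for (i in seq_len(nrow(m))) {
    nm <- m$name[i]
    is_loc <- m$category[i] == "dam_location"
    expected_shift <- 0
    if (is_loc && m$stat[i] %in% c("none", "mean")) {
      expected_shift <- if (grepl("_x", m$base[i])) tx else ty
    }
    expect_equal(fm2[[nm]], fm1[[nm]] + expected_shift,
                 tolerance = 1e-7, label = nm)
  }
})

test_that("doubling px_per_mm rescales mm features and leaves the rest", {
  ses <- small_session()
  pups <- detections_to_table(ses$pup_detections, 6)
  joined <- join_dam_pup(ses$dam, pups)
  meta1 <- attr(joined, "meta")
  meta2 <- meta1; meta2$px_per_mm <- 2 * meta1$px_per_mm
  fm1 <- extract_features(joined, meta = meta1)
  fm2 <- extract_features(joined, meta = meta2)
  m <- feature_manifest()
  for (i in seq_len(nrow(m))) {
    nm <- m$name[i]
    fac <- switch(sub("_sum$", "", m$units[i]),
                  mm = 0.5, mm2 = 0.25, 1)
    expect_equal(fm2[[nm]], fm1[[nm]] * fac, tolerance = 1e-9, label = nm)
  }
})

test_that("unit likelihoods make weighted centroids arithmetic ones", {
  ses <- small_session()
  pups <- detections_to_table(ses$pup_detections, 6)
  joined <- join_dam_pup(ses$dam, pups)
  saturated <- joined
  pcols <- grep("^(?!pup).*_p$", names(joined), value = TRUE, perl = TRUE)
  saturated[pcols] <- 1
  fm <- extract_features(saturated, meta = attr(joined, "meta"))
  kp <- keypoint_scheme("dam")$names
  xs <- as.matrix(saturated[paste0(kp, "_x")])
  ys <- as.matrix(saturated[paste0(kp, "_y")])
  expect_equal(fm$dam_centroid_x, rowMeans(xs), tolerance = 1e-10)
  expect_equal(fm$dam_centroid_y, rowMeans(ys), tolerance = 1e-10)
})
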