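meta30 <- function(n = 10) {
  video_meta("v1", fps = 30, width_px = 1280, height_px = 780,
             px_per_mm = 2, n_frames = n)
}

test_that("dam pose CSV round-trips through the three-row-header dialect", {
  pose <- pose_series(make_pose_tbl(10), meta30(), keypoint_scheme("dam"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dam_pose(pose, path)
  hdr <- readLines(path, n = 3)
  expect_match(hdr[1], "^scorer,")
  expect_match(hdr[2], "^bodyparts,")
  expect_match(hdr[3], "^coords,")
  back <- read_dam_pose(path, meta30())
  expect_equal(back$data, pose$data, tolerance = 1e-12)
  # 32 keypoints x 3 values
  expect_equal(ncol(back$data) - 1L, 96L)
})

test_that("a missing keypoint is a schema error naming the keypoint", {
  pose <- pose_series(make_pose_tbl(5), meta30(5), keypoint_scheme("dam"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dam_pose(pose, path)
  lines <- readLines(path)
  # drop the chin triple (columns 2 + 3*1 .. ) by name surgery on headers
  keep <- which(strsplit(lines[2], ",")[[1]] != "chin")
  lines <- vapply(lines, function(l) {
    paste(strsplit(l, ",")[[1]][keep], collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  writeLines(lines, path)
  expect_error(read_dam_pose(path, meta30(5)), "chin",
               class = "nw_schema_error")
})

test_that("non-numeric cells are parse errors; stray likelihoods clip", {
  tb <- make_pose_tbl(5)
  pose <- pose_series(tb, meta30(5), keypoint_scheme("dam"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dam_pose(pose, path)
  lines <- readLines(path)
  lines[7] <- sub("^([^,]*,)[^,]*", "\\1oops", lines[7])
  writeLines(lines, path)
  expect_error(read_dam_pose(path, meta30(5)), "frame",
               class = "nw_parse_error")

  tb$nose_p[4] <- 1.2
  expect_warning(
    clipped <- pose_series(tb, meta30(5), keypoint_scheme("dam")),
    "clipped"
  )
  expect_equal(clipped$data$nose_p[4], 1)
})

test_that("detections are slotted by descending confidence with surplus dropped", {
  bp <- keypoint_scheme("pup")$names
  frames <- nestwatch:::empty_detection_frames(2, bp)
  frames[[1]]$nose <- cbind(c(10, 20, 30), c(1, 2, 3), c(0.7, 0.9, 0.2))
  d <- raw_detections(frames, meta30(2))
  tab <- detections_to_table(d, max_pups = 8)
  expect_equal(tab$pup1_nose_x[1], 20) # conf 0.9
  expect_equal(tab$pup2_nose_x[1], 10) # conf 0.7
  expect_equal(tab$pup3_nose_x[1], 30) # conf 0.2
  expect_equal(tab$pup4_nose_p[1], 0)
  # empty frame: everything zero
  expect_true(all(tab[2, -1] == 0))
  expect_equal(ncol(tab) - 1L, 8 * 9 * 3)

  # surplus: 10 tail_base detections, 8 slots -> brute-force top-8 by conf
  set.seed(5)
  m <- cbind(runif(10, 0, 100), runif(10, 0, 100), runif(10))
  frames2 <- nestwatch:::empty_detection_frames(1, bp)
  frames2[[1]]$tail_base <- m
  tab2 <- detections_to_table(raw_detections(frames2, meta30(1)), 8)
  kept <- sort(m[, 3], decreasing = TRUE)[1:8]
  got <- vapply(1:8, function(s) tab2[[paste0("pup", s, "_tail_base_p")]],
                numeric(1))
  expect_equal(got, kept)
})

test_that("slot assignment is invariant to detection input order", {
  bp <- keypoint_scheme("pup")$names
  set.seed(11)
  m <- cbind(runif(6, 0, 100), runif(6, 0, 100),
             sample(c(0.8, 0.8, 0.5, 0.5, 0.3, 0.9))) # deliberate ties
  f1 <- nestwatch:::empty_detection_frames(1, bp)
  f2 <- f1
  f1[[1]]$spine_2 <- m
  f2[[1]]$spine_2 <- m[sample(6), ]
  t1 <- detections_to_table(raw_detections(f1, meta30(1)), 8)
  t2 <- detections_to_table(raw_detections(f2, meta30(1)), 8)
  expect_equal(t1, t2)
})

test_that("confidence outside [0,1] clips with a warning", {
  bp <- keypoint_scheme("pup")$names
  frames <- nestwatch:::empty_detection_frames(1, bp)
  frames[[1]]$nose <- cbind(1, 1, 1.4)
  expect_warning(
    tab <- detections_to_table(raw_detections(frames, meta30(1)), 2),
    "clipped"
  )
  expect_equal(tab$pup1_nose_p[1], 1)
})

test_that("joining gives the documented flat layout and truncates on mismatch", {
  dam <- pose_series(make_pose_tbl(100), meta30(100),
                     keypoint_scheme("dam"))
  d <- raw_detections(nestwatch:::empty_detection_frames(100,
                        keypoint_scheme("pup")$names), meta30(100))
  pups <- detections_to_table(d, max_pups = 8)
  joined <- join_dam_pup(dam, pups)
  expect_equal(nrow(joined), 100)
  expect_equal(ncol(joined) - 1L, (32 + 8 * 9) * 3)
  # dam block first
  expect_equal(names(joined)[2], "nose_x")

  expect_warning(
    j2 <- join_dam_pup(dam, pups[1:98, ]),
    "truncated"
  )
  expect_equal(nrow(j2), 98)

  meta_other <- video_meta("other", fps = 30, n_frames = 100)
  expect_error(join_dam_pup(dam, pups, meta_other),
               class = "nw_validation_error")
  expect_error(join_dam_pup(dam, pups[0, ]),
               class = "nw_validation_error")
})

test_that("joined tables round-trip bit-identically through CSV", {
  ses <- small_session()
  pups <- detections_to_table(ses$pup_detections, 6)
  joined <- join_dam_pup(ses$dam, pups)
  path <- withr::local_tempfile(fileext = ".csv")
  write_joined(joined, path)
  back <- read_joined(path, ses$meta)
  expect_identical(as.data.frame(back), as.data.frame(joined))
  expect_equal(attr(back, "max_pups"), 6L)
})

test_that("detections round-trip through both on-disk dialects", {
  ses <- small_session()
  d <- ses$pup_detections
  for (ext in c(".json", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_detections(d, path)
    back <- read_detections(path, ses$meta)
    t1 <- detections_to_table(d, 8)
    t2 <- detections_to_table(back, 8)
    expect_equal(t2, t1, tolerance = 1e-9)
  }
})

test_that("annotation rasterization follows the half-open frame rule", {
  meta <- meta30(120)
  ann <- annotation_set(
    tibble::tibble(behavior = "licking_grooming", start_s = 1, stop_s = 2),
    meta
  )
  pos <- which(ann$frame_labels$licking_grooming) - 1L
  expect_equal(pos, 30:59)
  expect_equal(length(pos), 30)

  # property: per-behavior positives equal a brute-force interval scan
  set.seed(9)
  iv <- tibble::tibble(
    behavior = sample(behavior_vocabulary(), 12, replace = TRUE),
    start_s = runif(12, 0, 3)
  )
  iv$stop_s <- iv$start_s + runif(12, 0.05, 1)
  ann2 <- annotation_set(iv, meta)
  for (b in behavior_vocabulary()) {
    brute <- vapply(seq_len(meta$n_frames) - 1L, function(f) {
      t <- f / meta$fps
      any(iv$behavior == b & iv$start_s <= t & t < iv$stop_s)
    }, logical(1))
    expect_equal(ann2$frame_labels[[b]], brute)
  }
})

test_that("annotation validation rejects bad rows and unknown behaviors", {
  meta <- meta30(10)
  expect_error(
    annotation_set(tibble::tibble(behavior = "retrieval",
                                  start_s = 0, stop_s = 1), meta),
    "retrieval", class = "nw_validation_error"
  )
  expect_error(
    annotation_set(tibble::tibble(behavior = "eating",
                                  start_s = 2, stop_s = 2), meta),
    "row 1", class = "nw_validation_error"
  )
  empty <- annotation_set(
    tibble::tibble(behavior = character(), start_s = numeric(),
                   stop_s = numeric()), meta
  )
  expect_false(any(as.matrix(empty$frame_labels)))
})

test_that("BORIS-style headers are accepted", {
  meta <- meta30(60)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Behavior,Start (s),Stop (s)",
    "eating,0.5,1.5"
  ), path)
  ann <- read_annotations(path, meta)
  expect_equal(sum(ann$frame_labels$eating), 30)
})

test_that("calibration and duration arithmetic behave", {
  expect_equal(calibrate_px_per_mm(580, 290), 2)
  expect_equal(calibrate_px_per_mm(290, 290), 1)
  expect_error(calibrate_px_per_mm(0, 290))
  expect_equal(frames_to_hours(108000, 30), 1)
  expect_equal(frames_to_hours(0, 30), 0)
  expect_equal(hours_completed(1.999), 1.9)
  expect_error(frames_to_hours(10, 0))
})
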