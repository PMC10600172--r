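#' @title Pose-series container
#'
#' @description A `pose_series` holds per-frame `(x, y, likelihood)` triples
#' for one animal under a fixed [keypoint_scheme()].  The tabular payload is
#' a tibble with a `frame` column (contiguous from 0) and one
#' `<keypoint>_{x,y,p}` triple per keypoint.
#'
#' @param data Tibble of coordinates as described above.
#' @param meta A [video_meta()].
#' @param scheme A [keypoint_scheme()].
#'
#' @return A `pose_series` object.
#' @export
pose_series <- function(data, meta, scheme) {
  data <- tibble::as_tibble(data)
  want <- triple_names(scheme$names)
  missing <- setdiff(want, names(data))
  if (length(missing) > 0) {
    abort(
      sprintf(
        "Pose table is missing keypoint column(s): %s",
        paste(missing, collapse = ", ")
      ),
      class = "nw_schema_error"
    )
  }
  if (!"frame" %in% names(data)) {
    data <- dplyr::mutate(data, frame = dplyr::row_number() - 1L)
  }
  data <- dplyr::select(data, "frame", dplyr::all_of(want))
  p_cols <- paste0(scheme$names, "_p")
  pm <- as.matrix(data[p_cols])
  if (anyNA(as.matrix(data[setdiff(want, "frame")]))) {
    abort("Pose table contains missing values.", class = "nw_parse_error")
  }
  if (any(pm < 0 | pm > 1)) {
    warn(sprintf(
      "%d likelihood value(s) outside [0, 1] clipped.",
      sum(pm < 0 | pm > 1)
    ))
    data[p_cols] <- pmin(pmax(pm, 0), 1)
  }
  structure(
    list(meta = meta, scheme = scheme, data = data),
    class = "pose_series"
  )
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf(
    "<pose_series %s/%s: %d frames x %d keypoints>\n",
    x$meta$video_id, x$scheme$animal, nrow(x$data), length(x$scheme$names)
  ))
  invisible(x)
}

triple_names <- function(kp_names, prefix = NULL) {
  base <- if (is.null(prefix)) kp_names else paste0(prefix, "_", kp_names)
  as.vector(t(outer(base, c("x", "y", "p"), paste, sep = "_")))
}

#' Read a single-animal pose-estimation CSV (three-row-header dialect)
#'
#' The dialect has three header rows (`scorer`, `bodyparts`, `coords`),
#' then one row per frame with an index column followed by
#' `x, y, likelihood` per keypoint.  Likelihoods outside `[0, 1]` are
#' clipped with a warning; a keypoint absent from the header is a schema
#' error; a non-numeric cell is a parse error naming the frame.
#'
#' @param path CSV file path.
#' @param meta A [video_meta()].
#' @param scheme Keypoint scheme to validate against (default dam, 32
#'   points).
#'
#' @return A [pose_series()].
#' @export
read_dam_pose <- function(path, meta, scheme = keypoint_scheme("dam")) {
  hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                         colClasses = "character")
  if (nrow(hdr) < 3 ||
      !identical(tolower(hdr[[1]][1:3]),
                 c("scorer", "bodyparts", "coords"))) {
    abort(
      "File does not use the scorer/bodyparts/coords three-row header dialect.",
      class = "nw_schema_error"
    )
  }
  bodyparts <- as.character(hdr[2, -1])
  coords <- tolower(as.character(hdr[3, -1]))
  missing <- setdiff(scheme$names, unique(bodyparts))
  if (length(missing) > 0) {
    abort(
      sprintf("Keypoint(s) absent from file: %s",
              paste(missing, collapse = ", ")),
      class = "nw_schema_error"
    )
  }
  raw <- utils::read.csv(path, header = FALSE, skip = 3,
                         colClasses = "character")
  frame_idx <- suppressWarnings(as.numeric(raw[[1]]))
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw[, -1, drop = FALSE])), nrow = nrow(raw))
  )
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1]
    abort(
      sprintf("Non-numeric cell at frame row %d.", bad),
      class = "nw_parse_error"
    )
  }
  colnames(vals) <- paste0(bodyparts, "_",
                           sub("likelihood", "p", coords))
  out <- tibble::as_tibble(vals, .name_repair = "minimal")
  out <- out[triple_names(scheme$names)]
  out$frame <- if (all(!is.na(frame_idx))) as.integer(frame_idx) else
    seq_len(nrow(out)) - 1L
  pose_series(out, meta, scheme)
}

#' Write a pose series in the three-row-header CSV dialect
#'
#' @param pose A [pose_series()].
#' @param path Output CSV path.
#' @param scorer Scorer tag written in the first header row.
#' @return `path`, invisibly.
#' @export
write_dam_pose <- function(pose, path, scorer = "nestwatch") {
  kp <- pose$scheme$names
  dat <- pose$data
  vals <- as.matrix(dat[triple_names(kp)])
  hdr1 <- c("scorer", rep(scorer, ncol(vals)))
  hdr2 <- c("bodyparts", rep(kp, each = 3))
  hdr3 <- c("coords", rep(c("x", "y", "likelihood"), length(kp)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr1, collapse = ","), con)
  writeLines(paste(hdr2, collapse = ","), con)
  writeLines(paste(hdr3, collapse = ","), con)
  body <- cbind(dat$frame, vals)
  utils::write.table(body, con, sep = ",", col.names = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @title Raw identity-free pup detections
#'
#' @description Per frame and per bodypart, a variable-length list of
#' `(x, y, confidence)` detections with no pup identity attached (the
#' multi-animal tracker's mid-workflow output, before any tracklet
#' assembly).  Stored as `frames`: a list (one element per frame) of named
#' lists (one per bodypart) of `k x 3` matrices; `k` may be 0.
#'
#' @param frames Nested detection list as described.
#' @param meta A [video_meta()].
#' @param bodyparts Pup keypoint labels (default pup scheme, 9 points).
#' @return A `raw_detections` object.
#' @export
raw_detections <- function(frames, meta,
                           bodyparts = keypoint_scheme("pup")$names) {
  structure(
    list(meta = meta, bodyparts = bodyparts, frames = frames),
    class = "raw_detections"
  )
}

#' @export
print.raw_detections <- function(x, ...) {
  n_det <- sum(vapply(x$frames, function(fr)
    sum(vapply(fr, NROW, 0L)), 0))
  cat(sprintf(
    "<raw_detections %s: %d frames, %d bodyparts, %d detections>\n",
    x$meta$video_id, length(x$frames), length(x$bodyparts), n_det
  ))
  invisible(x)
}

#' Read raw pup detections (portable JSON or long CSV dialect)
#'
#' Two interchangeable on-disk dialects are supported and detected from the
#' file extension: a JSON document
#' `{video_id, bodyparts, frames: [{frame, detections: {bp: [[x,y,conf],...]}}]}`
#' and a long-format CSV with columns `frame, bodypart, x, y, confidence`.
#'
#' @param path File path (`.json` or `.csv`).
#' @param meta A [video_meta()]; `n_frames` is used to size the frame axis
#'   when the tail of the video has no detections.
#' @return A [raw_detections()] object.
#' @export
read_detections <- function(path, meta) {
  ext <- tolower(tools::file_ext(path))
  bp <- keypoint_scheme("pup")$names
  n <- meta$n_frames
  if (ext == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    bp <- unlist(doc$bodyparts)
    if (is.na(n)) n <- length(doc$frames)
    frames <- empty_detection_frames(n, bp)
    for (fr in doc$frames) {
      i <- fr$frame + 1L
      if (i < 1L || i > n) next
      for (b in names(fr$detections)) {
        rows <- fr$detections[[b]]
        if (length(rows) == 0) next
        m <- do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
        frames[[i]][[b]] <- m
      }
    }
  } else if (ext == "csv") {
    tb <- utils::read.csv(path)
    need <- c("frame", "bodypart", "x", "y", "confidence")
    if (!all(need %in% names(tb))) {
      abort(sprintf("Detections CSV must have columns: %s",
                    paste(need, collapse = ", ")),
            class = "nw_schema_error")
    }
    if (is.na(n)) n <- if (nrow(tb)) max(tb$frame) + 1L else 0L
    frames <- empty_detection_frames(n, bp)
    if (nrow(tb)) {
      tb <- tb[tb$frame >= 0 & tb$frame < n, , drop = FALSE]
      key <- split(seq_len(nrow(tb)),
                   list(frame = tb$frame, bodypart = tb$bodypart),
                   drop = TRUE)
      for (k in names(key)) {
        idx <- key[[k]]
        i <- tb$frame[idx[1]] + 1L
        b <- as.character(tb$bodypart[idx[1]])
        frames[[i]][[b]] <- cbind(tb$x[idx], tb$y[idx], tb$confidence[idx])
      }
    }
  } else {
    abort("Unsupported detections file extension (use .json or .csv).",
          class = "nw_schema_error")
  }
  raw_detections(frames, meta, bodyparts = bp)
}

empty_detection_frames <- function(n, bodyparts) {
  empty <- stats::setNames(
    rep(list(matrix(numeric(0), ncol = 3)), length(bodyparts)), bodyparts
  )
  rep(list(empty), n)
}

#' Write raw pup detections
#'
#' @param d A [raw_detections()].
#' @param path Output path; format follows the extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_detections <- function(d, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    frames <- lapply(seq_along(d$frames), function(i) {
      dets <- d$frames[[i]]
      dets <- dets[vapply(dets, NROW, 0L) > 0]
      list(
        frame = i - 1L,
        detections = lapply(dets, function(m) {
          lapply(seq_len(nrow(m)), function(r) as.numeric(m[r, ]))
        })
      )
    })
    doc <- list(
      video_id = d$meta$video_id,
      bodyparts = as.list(d$bodyparts),
      frames = frames
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    rows <- purrr::imap(d$frames, function(dets, i) {
      keep <- vapply(dets, NROW, 0L) > 0
      if (!any(keep)) return(NULL)
      purrr::imap(dets[keep], function(m, b) {
        tibble::tibble(
          frame = i - 1L, bodypart = b,
          x = m[, 1], y = m[, 2], confidence = m[, 3]
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    if (nrow(rows) == 0) {
      rows <- tibble::tibble(frame = integer(), bodypart = character(),
                             x = numeric(), y = numeric(),
                             confidence = numeric())
    }
    utils::write.csv(rows, path, row.names = FALSE)
  } else {
    abort("Unsupported detections file extension (use .json or .csv).")
  }
  invisible(path)
}

#' Assign identity-free detections to fixed pup slots
#'
#' Per frame and per bodypart, detections are written into pup slots
#' `1..max_pups` in descending confidence order (ties broken by ascending
#' `x`, then `y`); surplus detections are dropped and unfilled slots get
#' `(0, 0, p = 0)`.  Slot assignment carries **no** cross-frame identity:
#' a point in slot 3 at frame t and frame t+1 need not belong to the same
#' pup.  Downstream features must therefore be invariant to per-frame slot
#' permutation, and are.
#'
#' @param d A [raw_detections()].
#' @param max_pups Number of slots (>= 1; default 12 covers typical
#'   Long-Evans litters).
#'
#' @return Tibble with `frame` plus `pup<i>_<bodypart>_{x,y,p}` columns,
#'   `max_pups * length(bodyparts) * 3` value columns in slot-major order.
#' @export
detections_to_table <- function(d, max_pups = 12) {
  stopifnot(inherits(d, "raw_detections"))
  if (max_pups < 1) abort("`max_pups` must be >= 1.")
  bp <- d$bodyparts
  n <- length(d$frames)
  ncol_out <- max_pups * length(bp) * 3L
  out <- matrix(0, nrow = n, ncol = ncol_out)
  # column index of the x coord for (slot s, bodypart j)
  col0 <- function(s, j) ((s - 1L) * length(bp) + (j - 1L)) * 3L + 1L
  n_clipped <- 0L
  for (i in seq_len(n)) {
    dets <- d$frames[[i]]
    for (j in seq_along(bp)) {
      m <- dets[[bp[j]]]
      k <- NROW(m)
      if (k == 0) next
      conf <- m[, 3]
      if (any(conf < 0 | conf > 1)) {
        n_clipped <- n_clipped + sum(conf < 0 | conf > 1)
        conf <- pmin(pmax(conf, 0), 1)
      }
      ord <- order(-conf, m[, 1], m[, 2])
      keep <- ord[seq_len(min(k, max_pups))]
      for (s in seq_along(keep)) {
        c0 <- col0(s, j)
        out[i, c0:(c0 + 2L)] <- c(m[keep[s], 1], m[keep[s], 2],
                                  conf[keep[s]])
      }
    }
  }
  if (n_clipped > 0) {
    warn(sprintf("%d detection confidence(s) outside [0, 1] clipped.",
                 n_clipped))
  }
  cols <- unlist(lapply(seq_len(max_pups), function(s)
    triple_names(bp, prefix = paste0("pup", s))))
  colnames(out) <- cols
  dplyr::bind_cols(
    tibble::tibble(frame = seq_len(n) - 1L),
    tibble::as_tibble(out)
  )
}

#' Join dam pose and pup slot table into one flat per-frame table
#'
#' Produces the single flat table the feature extractor consumes: dam
#' keypoint triples first, then pup slots in order, one `x/y/p` column
#' triple per keypoint.  If frame counts differ the longer input is
#' truncated to the shorter with a warning (padding would fabricate
#' detections).
#'
#' @param dam A dam [pose_series()].
#' @param pups Pup slot tibble from [detections_to_table()].
#' @param meta A [video_meta()]; must share `video_id` with `dam`.
#'
#' @return A `joined_pose` tibble (`frame` + `(32 + max_pups*9) * 3` value
#'   columns) with attributes `meta`, `max_pups`, `dam_scheme`,
#'   `pup_bodyparts`.
#' @export
join_dam_pup <- function(dam, pups, meta = dam$meta) {
  stopifnot(inherits(dam, "pose_series"))
  if (!identical(dam$meta$video_id, meta$video_id)) {
    abort("Dam pose and metadata come from different video_ids.",
          class = "nw_validation_error")
  }
  n_dam <- nrow(dam$data)
  n_pup <- nrow(pups)
  n <- min(n_dam, n_pup)
  if (n == 0) {
    abort("Zero overlapping frames between dam and pup tables.",
          class = "nw_validation_error")
  }
  if (n_dam != n_pup) {
    warn(sprintf(
      "Frame counts differ (dam %d, pups %d); truncated to %d.",
      n_dam, n_pup, n
    ))
  }
  pup_value_cols <- setdiff(names(pups), "frame")
  max_pups <- length(pup_value_cols) / 27L # 9 bodyparts x 3
  joined <- dplyr::bind_cols(
    dam$data[seq_len(n), , drop = FALSE],
    pups[seq_len(n), pup_value_cols, drop = FALSE]
  )
  meta$n_frames <- n
  structure(
    joined,
    meta = meta, max_pups = as.integer(max_pups),
    dam_scheme = dam$scheme,
    pup_bodyparts = keypoint_scheme("pup")$names,
    class = c("joined_pose", class(joined))
  )
}

#' Write / read the joined per-frame table
#'
#' The on-disk form is a plain single-header CSV in the documented column
#' order; reading it back reproduces the table bit-identically for finite
#' values.
#'
#' @param joined A `joined_pose` tibble from [join_dam_pup()].
#' @param path CSV path.
#' @return `path` (write) or a `joined_pose` tibble (read).
#' @export
write_joined <- function(joined, path) {
  dt <- data.table::as.data.table(joined)
  # serialize doubles with 17 significant digits so the on-disk table
  # round-trips bit-identically
  for (j in names(dt)) {
    if (is.double(dt[[j]])) {
      data.table::set(dt, j = j,
                      value = formatC(dt[[j]], digits = 17, format = "g"))
    }
  }
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_joined
#' @param meta A [video_meta()] for the recording being read.
#' @export
read_joined <- function(path, meta) {
  dt <- data.table::fread(path)
  tb <- tibble::as_tibble(dt)
  scheme <- keypoint_scheme("dam")
  pup_cols <- grep("^pup[0-9]+_", names(tb), value = TRUE)
  max_pups <- length(pup_cols) / 27L
  meta$n_frames <- nrow(tb)
  structure(
    tb,
    meta = meta, max_pups = as.integer(max_pups),
    dam_scheme = scheme, pup_bodyparts = keypoint_scheme("pup")$names,
    class = c("joined_pose", class(tb))
  )
}

#' @title Interval annotations and frame labels
#'
#' @description Ground-truth behavior annotations as `(behavior, start_s,
#' stop_s)` intervals plus their rasterization to per-frame booleans using
#' the half-open convention: frame `f` is positive iff
#' `start_s <= f / fps < stop_s` (no double counting at bout boundaries).
#' Overlapping intervals of different behaviors are permitted.
#'
#' @param intervals Tibble/data frame with columns `behavior`, `start_s`,
#'   `stop_s`.
#' @param meta A [video_meta()] with `fps` and `n_frames` set.
#' @return An `annotation_set`: list with `behaviors`, `intervals` (tibble)
#'   and `frame_labels` (tibble of logicals, one column per behavior,
#'   `n_frames` rows).
#' @export
annotation_set <- function(intervals, meta) {
  intervals <- tibble::as_tibble(intervals)
  vocab <- behavior_vocabulary()
  if (nrow(intervals) > 0) {
    bad <- which(!(intervals$behavior %in% vocab))
    if (length(bad) > 0) {
      abort(
        sprintf("Unknown behavior '%s' at row %d.",
                intervals$behavior[bad[1]], bad[1]),
        class = "nw_validation_error"
      )
    }
    rev_rows <- which(intervals$stop_s <= intervals$start_s)
    if (length(rev_rows) > 0) {
      abort(
        sprintf("stop_s <= start_s at row %d.", rev_rows[1]),
        class = "nw_validation_error"
      )
    }
  }
  n <- meta$n_frames
  if (is.na(n)) abort("`meta$n_frames` must be set to rasterize labels.")
  t_frame <- (seq_len(n) - 1L) / meta$fps
  labs <- matrix(FALSE, nrow = n, ncol = length(vocab),
                 dimnames = list(NULL, vocab))
  for (i in seq_len(nrow(intervals))) {
    b <- intervals$behavior[i]
    labs[, b] <- labs[, b] |
      (t_frame >= intervals$start_s[i] & t_frame < intervals$stop_s[i])
  }
  structure(
    list(
      behaviors = vocab,
      intervals = intervals,
      frame_labels = tibble::as_tibble(labs),
      meta = meta
    ),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set %s: %d intervals, %d frames, %d behaviors>\n",
    x$meta$video_id, nrow(x$intervals), nrow(x$frame_labels),
    length(x$behaviors)
  ))
  invisible(x)
}

#' Read a BORIS-style aggregated-events annotation CSV
#'
#' Accepts either portable column names (`behavior`, `start_s`, `stop_s`)
#' or the BORIS aggregated-events export headers (`Behavior`, `Start (s)`,
#' `Stop (s)`).
#'
#' @param path CSV path.
#' @param meta A [video_meta()] with `fps` and `n_frames`.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, meta) {
  tb <- utils::read.csv(path, check.names = FALSE)
  nm <- tolower(gsub("[^a-z]", "", tolower(names(tb))))
  pick <- function(keys) {
    i <- which(nm %in% keys)[1]
    if (is.na(i)) abort(
      sprintf("Annotation file lacks a column matching %s.",
              paste(keys, collapse = "/")),
      class = "nw_schema_error"
    )
    tb[[i]]
  }
  intervals <- tibble::tibble(
    behavior = as.character(pick(c("behavior"))),
    start_s = as.numeric(pick(c("starts", "start"))),
    stop_s = as.numeric(pick(c("stops", "stop")))
  )
  annotation_set(intervals, meta)
}

#' Write annotations as a portable interval CSV
#'
#' @param ann An [annotation_set()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(ann$intervals, path, row.names = FALSE)
  invisible(path)
}
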