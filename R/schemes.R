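#' Keypoint schemes for dam and pups
#'
#' The pipeline tracks 32 named anatomical landmarks on the dam and 9 on
#' each pup (nose through tail base).  The rosters are versioned package
#' constants: downstream features reference the named groups (back points
#' for the arch angle, ear points for grooming oscillation, ...), never
#' positional indices.
#'
#' @param animal `"dam"` or `"pup"`.
#'
#' @return A `keypoint_scheme` object: list with `animal`, `names` (ordered
#'   keypoint labels), `groups` (named list of label subsets) and `version`.
#' @export
#' @examples
#' length(keypoint_scheme("dam")$names) # 32
#' length(keypoint_scheme("pup")$names) # 9
keypoint_scheme <- function(animal = c("dam", "pup")) {
  animal <- match.arg(animal)
  if (animal == "dam") {
    head_points <- c(
      "nose", "chin", "left_eye", "right_eye",
      "left_ear", "right_ear", "top_head"
    )
    back_points <- paste0("back_", 1:6) # ordered neck -> rump
    ventrum_points <- c(
      "throat", "chest", "abdomen_mid", "abdomen_low", "groin", "pelvis"
    )
    limb_points <- c(
      "left_shoulder", "right_shoulder", "left_forepaw", "right_forepaw",
      "left_hip", "right_hip", "left_hindpaw", "right_hindpaw"
    )
    flank_points <- c("left_flank", "right_flank")
    tail_points <- c("tail_base", "tail_mid", "tail_tip")
    nms <- c(
      head_points, back_points, ventrum_points,
      limb_points, flank_points, tail_points
    )
    stopifnot(length(nms) == 32L, !anyDuplicated(nms))
    groups <- list(
      head_points = head_points,
      ear_points = c("left_ear", "right_ear"),
      back_points = back_points,
      ventrum_points = ventrum_points,
      limb_points = limb_points,
      flank_points = flank_points,
      tail_points = tail_points
    )
  } else {
    nms <- c(
      "nose", "left_ear", "right_ear", "neck",
      "spine_1", "spine_2", "spine_3", "rump", "tail_base"
    )
    stopifnot(length(nms) == 9L)
    groups <- list(axial_points = c("nose", "neck", "spine_1", "spine_2",
                                    "spine_3", "rump", "tail_base"))
  }
  structure(
    list(animal = animal, names = nms, groups = groups, version = "kp-1.0"),
    class = "keypoint_scheme"
  )
}

#' @export
print.keypoint_scheme <- function(x, ...) {
  cat(sprintf(
    "<keypoint_scheme %s: %d points, %d groups, version %s>\n",
    x$animal, length(x$names), length(x$groups), x$version
  ))
  invisible(x)
}

#' Per-video metadata
#'
#' @param video_id Character identifier of the recording.
#' @param fps Frames per second (> 0).
#' @param width_px,height_px Frame size in pixels.
#' @param px_per_mm Pixels per millimetre calibration (> 0); see
#'   [calibrate_px_per_mm()].
#' @param n_frames Number of frames (>= 0), if known.
#'
#' @return A `video_meta` object (named list).
#' @export
#' @examples
#' video_meta("v1", fps = 30, width_px = 1280, height_px = 780,
#'            px_per_mm = 2.28, n_frames = 1800)
video_meta <- function(video_id, fps, width_px = NA_real_,
                       height_px = NA_real_, px_per_mm = NA_real_,
                       n_frames = NA_integer_) {
  if (!is.numeric(fps) || length(fps) != 1L || is.na(fps) || fps <= 0) {
    abort("`fps` must be a single positive number.")
  }
  if (!is.na(px_per_mm) && px_per_mm <= 0) {
    abort("`px_per_mm` must be positive.")
  }
  if (!is.na(n_frames) && n_frames < 0) {
    abort("`n_frames` must be non-negative.")
  }
  structure(
    list(
      video_id = as.character(video_id), fps = as.numeric(fps),
      width_px = as.numeric(width_px), height_px = as.numeric(height_px),
      px_per_mm = as.numeric(px_per_mm),
      n_frames = if (is.na(n_frames)) NA_integer_ else as.integer(n_frames)
    ),
    class = "video_meta"
  )
}

#' @export
print.video_meta <- function(x, ...) {
  cat(sprintf(
    "<video_meta %s: %g fps, %gx%g px, %g px/mm, %s frames>\n",
    x$video_id, x$fps, x$width_px, x$height_px, x$px_per_mm,
    ifelse(is.na(x$n_frames), "?", format(x$n_frames))
  ))
  invisible(x)
}

#' Pixels-per-millimetre calibration from a known landmark
#'
#' Side-view recordings are calibrated against a structure of known physical
#' size; by convention the width of the wire cage top at its lowest point
#' (roughly half the cage depth), so that one scalar roughly compensates for
#' camera distance and frame resolution across recordings.
#'
#' @param measured_px Apparent landmark length in pixels (> 0).
#' @param known_mm True landmark length in millimetres (> 0).
#'
#' @return Pixels per millimetre (numeric scalar).
#' @export
#' @examples
#' calibrate_px_per_mm(580, 290) # 2
calibrate_px_per_mm <- function(measured_px, known_mm) {
  if (!is.numeric(measured_px) || !is.numeric(known_mm) ||
      measured_px <= 0 || known_mm <= 0) {
    abort("`measured_px` and `known_mm` must both be positive numbers.")
  }
  measured_px / known_mm
}

#' Convert a frame count to hours of recording
#'
#' @param n_frames Number of frames (>= 0).
#' @param fps Frames per second (> 0).
#'
#' @return Hours (numeric scalar).  Summaries print whole tenths of an
#'   hour completed, i.e. the value truncated (not rounded) to one
#'   decimal place; see [hours_completed()].
#' @export
#' @examples
#' hours_completed(frames_to_hours(3366254, 30)) # 31.1
frames_to_hours <- function(n_frames, fps) {
  if (!is.numeric(fps) || length(fps) != 1L || is.na(fps) || fps <= 0) {
    abort("`fps` must be a single positive number.")
  }
  if (any(n_frames < 0)) abort("`n_frames` must be non-negative.")
  n_frames / fps / 3600
}

#' Whole tenths of an hour completed
#'
#' The display convention for recording durations in summaries: hours are
#' truncated toward zero at one decimal place (31.169 h of annotated video
#' prints as 31.1 h -- tenths completed, not the nearest tenth).
#'
#' @param hours Duration in hours.
#' @return Hours truncated to one decimal place.
#' @export
#' @examples
#' hours_completed(31.169) # 31.1
hours_completed <- function(hours) {
  trunc(hours * 10) / 10
}
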