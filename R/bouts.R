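#' Convert per-frame labels to bouts
#'
#' A bout is a maximal run of consecutive behavior-positive frames; a
#' single positive frame is a bout.  Frame spans are inclusive on both
#' ends and `duration_s = (end - start + 1) / fps`, so label vectors and
#' bout tables are in bijection (see [bouts_to_labels()]).
#'
#' @param labels Logical per-frame vector.
#' @param fps Frames per second (> 0).
#' @param behavior Behavior name recorded in the table.
#'
#' @return A bout tibble: `behavior`, `start_frame`, `end_frame`
#'   (inclusive, 0-based), `duration_s`.
#' @export
#' @examples
#' labels_to_bouts(c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE), fps = 1)
labels_to_bouts <- function(labels, fps, behavior = "behavior") {
  if (fps <= 0) abort("`fps` must be positive.")
  labels <- as.logical(labels)
  if (length(labels) == 0 || !any(labels)) {
    return(tibble::tibble(
      behavior = character(), start_frame = integer(),
      end_frame = integer(), duration_s = numeric()
    ))
  }
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- which(r$values)
  tibble::tibble(
    behavior = behavior,
    start_frame = starts[pos] - 1L,
    end_frame = ends[pos] - 1L,
    duration_s = r$lengths[pos] / fps
  )
}

#' Rasterize a bout table back to per-frame labels
#'
#' Inverse of [labels_to_bouts()] for a single behavior.
#'
#' @param bouts Bout tibble.
#' @param n_frames Length of the output label vector.
#' @return Logical vector.
#' @export
bouts_to_labels <- function(bouts, n_frames) {
  out <- logical(n_frames)
  for (i in seq_len(nrow(bouts))) {
    out[(bouts$start_frame[i] + 1L):(bouts$end_frame[i] + 1L)] <- TRUE
  }
  out
}

#' Minimum-bout-duration smoothing
#'
#' Drops bouts shorter than `min_s` seconds.  Bouts are never merged
#' across gaps (gap merging is a separate, optional step,
#' [merge_bout_gaps()]), so smoothing never increases bout count or total
#' duration, and is idempotent.  The default elsewhere in the package is
#' no smoothing (`min_s = 0`).
#'
#' @param bouts Bout tibble.
#' @param min_s Minimum bout duration in seconds (>= 0).
#' @return Filtered bout tibble.
#' @export
smooth_min_bout <- function(bouts, min_s) {
  if (min_s < 0) abort("`min_s` must be >= 0.")
  bouts[bouts$duration_s >= min_s, , drop = FALSE]
}

#' Merge bouts separated by short gaps
#'
#' Joins consecutive bouts of the same behavior separated by fewer than
#' `max_gap_s` seconds of negative frames.  Off by default throughout the
#' package; provided for users who want coarser bouts.
#'
#' @param bouts Bout tibble (single behavior).
#' @param max_gap_s Maximum gap to bridge, in seconds.
#' @param fps Frames per second.
#' @return Merged bout tibble.
#' @export
merge_bout_gaps <- function(bouts, max_gap_s, fps) {
  if (nrow(bouts) < 2 || max_gap_s <= 0) return(bouts)
  bouts <- bouts[order(bouts$start_frame), , drop = FALSE]
  gap_frames <- (bouts$start_frame[-1] - bouts$end_frame[-nrow(bouts)] - 1L)
  grp <- cumsum(c(1L, as.integer(gap_frames / fps >= max_gap_s)))
  dplyr::group_by(bouts, grp = grp, .data$behavior) |>
    dplyr::summarise(
      start_frame = min(.data$start_frame),
      end_frame = max(.data$end_frame), .groups = "drop"
    ) |>
    dplyr::mutate(
      duration_s = (.data$end_frame - .data$start_frame + 1L) / fps
    ) |>
    dplyr::select("behavior", "start_frame", "end_frame", "duration_s")
}

#' Per-video behavior summary
#'
#' Total duration, percent time, bout count and mean bout duration per
#' behavior.  Behaviors with no bouts report zeros; percent time for a
#' single behavior never exceeds 100, but behaviors may jointly exceed 100
#' because co-occurrence is allowed (nursing implies nest attendance).
#'
#' @param bouts Bout tibble (any mix of behaviors).
#' @param meta A [video_meta()] with `fps` and `n_frames`.
#' @param behaviors Behaviors to report (default the canonical seven).
#' @return Tibble with one row per behavior: `video_id`, `behavior`,
#'   `total_duration_s`, `percent_time`, `bout_count`, `mean_bout_s`.
#' @export
summarize_video <- function(bouts, meta,
                            behaviors = behavior_vocabulary()) {
  if (nrow(bouts) > 0 && any(bouts$end_frame >= meta$n_frames)) {
    abort("Bout extends beyond the end of the video.",
          class = "nw_validation_error")
  }
  video_s <- meta$n_frames / meta$fps
  purrr::map_dfr(behaviors, function(b) {
    bb <- bouts[bouts$behavior == b, , drop = FALSE]
    total <- sum(bb$duration_s)
    n <- nrow(bb)
    tibble::tibble(
      video_id = meta$video_id, behavior = b,
      total_duration_s = total,
      percent_time = if (video_s > 0) 100 * total / video_s else 0,
      bout_count = n,
      mean_bout_s = if (n > 0) total / n else 0
    )
  })
}

#' Long-format cohort table across videos
#'
#' One row per video and behavior with the four summary measures plus
#' cohort metadata (litter, postnatal day), ready for export to external
#' statistics tooling (e.g. mixed-model packages).
#'
#' @param summaries Row-bound output of [summarize_video()] over videos.
#' @param metadata Optional tibble with `video_id` plus e.g. `litter_id`,
#'   `postnatal_day` columns, joined on `video_id`.
#' @return Long-format tibble.
#' @export
cohort_table <- function(summaries, metadata = NULL) {
  out <- tibble::as_tibble(summaries)
  if (!is.null(metadata)) {
    metadata <- tibble::as_tibble(metadata)
    if (anyDuplicated(metadata$video_id)) {
      warn("Duplicate video_id in `metadata`.")
    }
    out <- dplyr::left_join(out, metadata, by = "video_id",
                            relationship = "many-to-many")
  }
  if (anyDuplicated(unique(out[c("video_id", "behavior")])) > 0) {
    warn("Duplicate video_id/behavior rows in `summaries`.")
  }
  out
}
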