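#' Long-window rolling pup centroid
#'
#' Probability-weighted centroid over all pup slot points within a trailing
#' window of 30 or 60 minutes, used to anchor dam-pup distance features
#' through long stretches where the litter is occluded by bedding or the
#' dam.  Frames whose window contains no point with `p > 0` inherit the
#' nearest preceding defined centroid, leading gaps take the first defined
#' value, and a video with no pup detections at all falls back to the cage
#' centre (attribute `low_confidence`).
#'
#' @param joined A `joined_pose` tibble from [join_dam_pup()].
#' @param span_min Window span in minutes (30 or 60; any positive value is
#'   accepted).
#' @param meta A [video_meta()]; defaults to the `joined` attribute.
#'
#' @return Tibble with per-frame `x`, `y` (px).
#' @export
pup_centroid_longwindow <- function(joined, span_min = 30,
                                    meta = attr(joined, "meta")) {
  arr <- pup_arrays(joined)
  ctr <- longwindow_centroid(arr$X, arr$Y, arr$P, span_min * 60, meta)
  out <- tibble::tibble(x = ctr$x, y = ctr$y)
  attr(out, "low_confidence") <- isTRUE(attr(ctr, "low_confidence"))
  out
}

cage_centre <- function(meta) {
  cx <- meta$width_px; cy <- meta$height_px
  c(ifelse(is.na(cx), 0, cx / 2), ifelse(is.na(cy), 0, cy / 2))
}

# Trailing weighted centroid over span_s seconds, with last-valid hold.
longwindow_centroid <- function(X, Y, P, span_s, meta) {
  n <- nrow(X)
  w <- max(1L, as.integer(round(span_s * meta$fps)))
  wx <- rowSums(P * X); wy <- rowSums(P * Y); wp <- rowSums(P)
  cs <- function(v) cumsum(v)
  csx <- cs(wx); csy <- cs(wy); csp <- cs(wp)
  lag_i <- pmax(seq_len(n) - w, 0L)
  lagged <- function(csv) ifelse(lag_i == 0L, 0, csv[pmax(lag_i, 1L)])
  sx <- csx - lagged(csx); sy <- csy - lagged(csy); sp <- csp - lagged(csp)
  defined <- sp > 0
  x <- ifelse(defined, sx / pmax(sp, .Machine$double.eps), NA_real_)
  y <- ifelse(defined, sy / pmax(sp, .Machine$double.eps), NA_real_)
  hold_last_valid(x, y, defined, fallback = cage_centre(meta))
}

# Split a joined_pose into dam coordinate matrices (frames x 32).
dam_arrays <- function(joined, scheme = attr(joined, "dam_scheme")) {
  scheme <- scheme %||% keypoint_scheme("dam")
  kp <- scheme$names
  list(
    X = as.matrix(joined[paste0(kp, "_x")]),
    Y = as.matrix(joined[paste0(kp, "_y")]),
    P = as.matrix(joined[paste0(kp, "_p")]),
    kp = kp, scheme = scheme
  )
}

# Flatten pup slot columns into frames x (max_pups * 9) matrices.
pup_arrays <- function(joined) {
  cols <- names(joined)
  xc <- grep("^pup[0-9]+_.*_x$", cols, value = TRUE)
  yc <- sub("_x$", "_y", xc)
  pc <- sub("_x$", "_p", xc)
  list(
    X = as.matrix(joined[xc]),
    Y = as.matrix(joined[yc]),
    P = as.matrix(joined[pc])
  )
}

# Weighted centroid series over a keypoint subset, with last-valid hold.
centroid_series <- function(X, Y, P, idx, meta) {
  Xs <- X[, idx, drop = FALSE]
  Ys <- Y[, idx, drop = FALSE]
  Ps <- P[, idx, drop = FALSE]
  sp <- rowSums(Ps)
  defined <- sp > 0
  x <- ifelse(defined, rowSums(Ps * Xs) / pmax(sp, .Machine$double.eps),
              NA_real_)
  y <- ifelse(defined, rowSums(Ps * Ys) / pmax(sp, .Machine$double.eps),
              NA_real_)
  hold_last_valid(x, y, defined, fallback = cage_centre(meta))
}

# Single keypoint with threshold-excluded hold: below p_min the last
# admissible position is carried forward.
held_point <- function(X, Y, P, j, p_min, meta) {
  defined <- P[, j] >= p_min
  hold_last_valid(X[, j], Y[, j], defined, fallback = cage_centre(meta))
}

hull_series <- function(X, Y, P, idx, p_min, px_per_mm) {
  n <- nrow(X)
  out <- numeric(n)
  Xs <- X[, idx, drop = FALSE]; Ys <- Y[, idx, drop = FALSE]
  Ps <- P[, idx, drop = FALSE]
  for (i in seq_len(n)) {
    keep <- Ps[i, ] >= p_min
    if (sum(keep) >= 3) out[i] <- hull_area_px(Xs[i, keep], Ys[i, keep])
  }
  out / px_per_mm^2
}

arch_series <- function(X, Y, P, idx, p_min) {
  n <- nrow(X)
  out <- numeric(n)
  Xs <- X[, idx, drop = FALSE]; Ys <- Y[, idx, drop = FALSE]
  Ps <- P[, idx, drop = FALSE]
  for (i in seq_len(n)) {
    out[i] <- back_arch_angle(cbind(Xs[i, ], Ys[i, ], Ps[i, ]),
                              p_min = p_min)
  }
  out
}

#' Extract the 218-feature frame-level matrix
#'
#' Computes every feature in the manifest from a joined dam+pup pose table:
#' likelihood-weighted centroids and group centroids, convex hull areas,
#' circle-fit back-arch and head/body axis angles, likelihood summaries,
#' per-keypoint movement, pup collective features, dam-pup distances with
#' instantaneous and 30/60-min pup centroids, and trailing rolling-window
#' statistics.  Distances, areas and movement are mm-denominated via
#' `px_per_mm`; locations are in frame px; angles in degrees.  Degenerate
#' geometry never yields NaN (areas and angles fall back to 0, undefined
#' centroids to the last defined value).
#'
#' @param joined A `joined_pose` tibble from [join_dam_pup()] or
#'   [read_joined()].
#' @param meta A [video_meta()]; defaults to the `joined` attribute.
#'   `px_per_mm` must be set.
#' @param params [geometry_params()].
#' @param manifest Feature manifest (default [feature_manifest()]).
#'
#' @return A `feature_matrix` tibble: `video_id`, `frame`, then the 218
#'   feature columns in manifest order; attributes `manifest`, `meta`.
#' @export
extract_features <- function(joined, meta = attr(joined, "meta"),
                             params = geometry_params(),
                             manifest = feature_manifest()) {
  if (is.null(meta)) abort("`meta` is required (joined table lacks one).")
  if (is.na(meta$px_per_mm)) {
    abort(paste(
      "px_per_mm is unset; calibrate the recording first",
      "(see calibrate_px_per_mm())."
    ), class = "nw_validation_error")
  }
  p_min <- params$p_min
  ppm <- meta$px_per_mm
  fps <- meta$fps
  dam <- dam_arrays(joined)
  pup <- pup_arrays(joined)
  n <- nrow(dam$X)
  grp <- dam$scheme$groups
  gidx <- lapply(grp, function(g) match(g, dam$kp))

  base <- new.env(parent = emptyenv())
  put <- function(name, v) assign(name, v, envir = base)

  # centroids (px locations)
  dc <- centroid_series(dam$X, dam$Y, dam$P, seq_len(32), meta)
  put("dam_centroid_x", dc$x); put("dam_centroid_y", dc$y)
  nose <- held_point(dam$X, dam$Y, dam$P, match("nose", dam$kp), p_min, meta)
  put("dam_nose_x", nose$x); put("dam_nose_y", nose$y)
  for (g in names(grp)) {
    gc <- centroid_series(dam$X, dam$Y, dam$P, gidx[[g]], meta)
    put(paste0(g, "_centroid_x"), gc$x)
    put(paste0(g, "_centroid_y"), gc$y)
  }

  # areas (mm^2)
  put("dam_hull_area",
      hull_series(dam$X, dam$Y, dam$P, seq_len(32), p_min, ppm))
  put("dam_head_hull_area",
      hull_series(dam$X, dam$Y, dam$P, gidx$head_points, p_min, ppm))
  put("dam_dorsal_hull_area",
      hull_series(dam$X, dam$Y, dam$P,
                  c(gidx$back_points, gidx$tail_points), p_min, ppm))

  # angles (degrees)
  put("back_arch_angle",
      arch_series(dam$X, dam$Y, dam$P, gidx$back_points, p_min))
  top <- held_point(dam$X, dam$Y, dam$P, match("top_head", dam$kp),
                    p_min, meta)
  # pitch of the nose relative to the top of the head; y grows downward in
  # image coordinates, so a raised nose gives a positive angle
  put("head_direction_angle",
      atan2(top$y - nose$y, nose$x - top$x) * 180 / pi)
  b1 <- held_point(dam$X, dam$Y, dam$P, match("back_1", dam$kp),
                   p_min, meta)
  tb <- held_point(dam$X, dam$Y, dam$P, match("tail_base", dam$kp),
                   p_min, meta)
  put("body_axis_angle", atan2(b1$y - tb$y, b1$x - tb$x) * 180 / pi)

  # likelihood summaries
  pmean <- rowMeans(dam$P)
  put("dam_p_mean", pmean)
  put("dam_p_sum", rowSums(dam$P))
  k <- ncol(dam$P)
  v <- (rowSums(dam$P^2) - k * pmean^2) / (k - 1)
  put("dam_p_std", sqrt(pmax(v, 0)))
  put("dam_p_min", do.call(pmin, as.data.frame(dam$P)))
  put("dam_n_detected", rowSums(dam$P >= p_min))
  for (g in names(grp)) {
    put(paste0(g, "_p_mean"),
        rowMeans(dam$P[, gidx[[g]], drop = FALSE]))
  }

  # movement (mm)
  for (j in seq_along(dam$kp)) {
    put(paste0(dam$kp[j], "_movement"),
        movement_series(dam$X[, j], dam$Y[, j], dam$P[, j], ppm))
  }
  put("dam_centroid_movement",
      movement_series(dc$x, dc$y, rep(1, n), ppm))
  hc <- centroid_series(dam$X, dam$Y, dam$P, gidx$head_points, meta)
  put("dam_head_centroid_movement",
      movement_series(hc$x, hc$y, rep(1, n), ppm))

  # pup collective features (identity-free: symmetric in slots)
  put("pup_hull_area",
      hull_series(pup$X, pup$Y, pup$P, seq_len(ncol(pup$X)), p_min, ppm))
  put("pup_p_mean", rowMeans(pup$P))
  put("pup_p_sum", rowSums(pup$P))
  put("pup_n_detected", rowSums(pup$P > 0))

  # dam-pup distances (mm)
  pc <- longwindow_centroid(pup$X, pup$Y, pup$P, 1 / fps, meta)
  pc30 <- longwindow_centroid(pup$X, pup$Y, pup$P, 30 * 60, meta)
  pc60 <- longwindow_centroid(pup$X, pup$Y, pup$P, 60 * 60, meta)
  edist <- function(ax, ay, bx, by) sqrt((ax - bx)^2 + (ay - by)^2) / ppm
  put("dam_pup_centroid_dist", edist(dc$x, dc$y, pc$x, pc$y))
  put("dam_nose_pup_dist", edist(nose$x, nose$y, pc$x, pc$y))
  put("dam_tailbase_pup_dist", edist(tb$x, tb$y, pc$x, pc$y))
  put("dam_pup_dx", (pc$x - dc$x) / ppm)
  put("dam_pup_dy", (pc$y - dc$y) / ppm)
  put("dam_pup_centroid_dist_30m", edist(dc$x, dc$y, pc30$x, pc30$y))
  put("dam_pup_centroid_dist_60m", edist(dc$x, dc$y, pc60$x, pc60$y))
  put("dam_nose_pup_dist_30m", edist(nose$x, nose$y, pc30$x, pc30$y))
  put("dam_nose_pup_dist_60m", edist(nose$x, nose$y, pc60$x, pc60$y))

  # assemble in manifest order, expanding rolling windows
  out <- matrix(NA_real_, nrow = n, ncol = nrow(manifest),
                dimnames = list(NULL, manifest$name))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    series <- get(row$base, envir = base, inherits = FALSE)
    out[, i] <- if (row$stat == "none") series else
      rolling_stat(series, row$stat, row$span_s, fps)
  }
  if (anyNA(out)) {
    abort("Internal error: NaN/NA produced in feature matrix.")
  }
  fm <- dplyr::bind_cols(
    tibble::tibble(
      video_id = meta$video_id,
      frame = joined$frame %||% (seq_len(n) - 1L)
    ),
    tibble::as_tibble(out)
  )
  structure(fm, manifest = manifest, meta = meta,
            manifest_version = manifest_version(manifest),
            class = c("feature_matrix", class(fm)))
}

#' Feature column names of a feature matrix
#'
#' @param fm A `feature_matrix` (or any data frame containing the manifest
#'   columns).
#' @param manifest Manifest tibble.
#' @return Character vector of the 218 feature column names, in order.
#' @export
feature_columns <- function(fm, manifest = feature_manifest()) {
  missing <- setdiff(manifest$name, names(fm))
  if (length(missing) > 0) {
    abort(sprintf("Feature matrix lacks %d manifest column(s), e.g. %s.",
                  length(missing), missing[1]),
          class = "nw_schema_error")
  }
  manifest$name
}
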