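#' Geometry and weighting parameters for feature extraction
#'
#' Occluded keypoints are handled without any outlier-correction pass:
#' centroid-type calculations weight each point by its likelihood, while
#' hull/angle-type calculations exclude points below a minimum likelihood
#' (`p_min`).  `p_min = 0.5` matches the likelihood cutoff used when the
#' pose models were evaluated.
#'
#' @param p_min Minimum likelihood for threshold-excluded calculations,
#'   in `[0, 1]`.
#' @return A `geometry_params` list.
#' @export
geometry_params <- function(p_min = 0.5) {
  stopifnot(is.numeric(p_min), p_min >= 0, p_min <= 1)
  structure(list(p_min = p_min), class = "geometry_params")
}

#' Likelihood-weighted centroid
#'
#' @param points Matrix or data frame with columns `x`, `y`, `p` (or three
#'   unnamed columns in that order).
#'
#' @return `c(x, y)`: the probability-weighted centroid
#'   `(sum(p*x)/sum(p), sum(p*y)/sum(p))`.  If every `p` is 0 the location
#'   is undefined and `c(NA, NA)` is returned; series-level extraction
#'   propagates the last defined value instead (see the package vignette).
#' @export
#' @examples
#' weighted_centroid(cbind(x = c(0, 2), y = c(0, 0), p = c(1, 1))) # (1, 0)
weighted_centroid <- function(points) {
  m <- as.matrix(points)
  if (ncol(m) < 3) abort("`points` needs x, y, p columns.")
  x <- m[, 1]; y <- m[, 2]; p <- m[, 3]
  sp <- sum(p)
  if (sp <= 0) return(c(NA_real_, NA_real_))
  c(sum(p * x) / sp, sum(p * y) / sp)
}

#' Convex hull area of admissible keypoints
#'
#' @param points Matrix/data frame with `x`, `y`, `p` columns.
#' @param p_min Likelihood threshold; points with `p < p_min` are excluded.
#' @param px_per_mm Calibration; the pixel-squared area is divided by
#'   `px_per_mm^2` to give mm^2.
#'
#' @return Hull area in mm^2; 0 when fewer than 3 admissible points remain
#'   or when they are collinear.
#' @export
#' @examples
#' sq <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), p = 1)
#' convex_hull_area(sq) # 1
convex_hull_area <- function(points, p_min = 0.5, px_per_mm = 1) {
  m <- as.matrix(points)
  keep <- m[, 3] >= p_min
  hull_area_px(m[keep, 1], m[keep, 2]) / px_per_mm^2
}

# Shoelace area of the convex hull of (x, y); 0 for degenerate inputs.
hull_area_px <- function(x, y) {
  if (length(x) < 3) return(0)
  h <- grDevices::chull(x, y)
  if (length(h) < 3) return(0)
  hx <- x[h]; hy <- y[h]
  abs(sum(hx * (hy[c(2:length(h), 1)]) - hx[c(2:length(h), 1)] * hy)) / 2
}

# Algebraic least-squares (Kasa) circle fit.  Returns c(cx, cy, r) or NULL
# when the normal equations are numerically singular (collinear points).
fit_circle_kasa <- function(x, y) {
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  M <- crossprod(A)
  d <- det(M)
  scale <- prod(sqrt(pmax(diag(M), .Machine$double.eps)))
  if (!is.finite(d) || abs(d) < 1e-10 * scale) return(NULL)
  coef <- tryCatch(solve(M, crossprod(A, b)),
                   error = function(e) NULL)
  if (is.null(coef)) return(NULL)
  cx <- -coef[1] / 2
  cy <- -coef[2] / 2
  r2 <- cx^2 + cy^2 - coef[3]
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  c(cx, cy, sqrt(r2))
}

#' Back-arch angle from a circle fit through the back points
#'
#' Fits a circle (algebraic least squares, Kasa) through the admissible
#' back keypoints, then returns the central angle at the fitted centre
#' subtended between the first and last admissible back points, choosing
#' the arc that passes through the interior points.  A crouched, arched
#' back yields a large angle; a flat back is numerically collinear and
#' maps to the documented degenerate value 0.
#'
#' @param back_points Ordered (neck to rump) matrix/data frame with `x`,
#'   `y`, `p` columns.
#' @param p_min Likelihood threshold for admissibility.
#' @param radius_cap_factor The fit is treated as collinear when the
#'   fitted radius exceeds this multiple of the largest pairwise chord.
#'
#' @return Central angle in degrees, in `[0, 360)`; 0 for collinear or
#'   under-determined (< 3 admissible points) input, with attribute
#'   `low_confidence = TRUE` in the under-determined case.
#' @export
#' @examples
#' th <- c(0, 45, 90) * pi / 180
#' pts <- cbind(x = 5 * cos(th), y = 5 * sin(th), p = 1)
#' back_arch_angle(pts) # 90
back_arch_angle <- function(back_points, p_min = 0.5,
                            radius_cap_factor = 100) {
  m <- as.matrix(back_points)
  keep <- which(m[, 3] >= p_min)
  if (length(keep) < 3) {
    return(structure(0, low_confidence = TRUE))
  }
  x <- m[keep, 1]; y <- m[keep, 2]
  fit <- fit_circle_kasa(x, y)
  if (is.null(fit)) return(0)
  chord <- max(dist(cbind(x, y)))
  if (fit[3] > radius_cap_factor * chord) return(0)
  phi <- atan2(y - fit[2], x - fit[1]) * 180 / pi
  sweep <- (phi[length(phi)] - phi[1]) %% 360
  if (length(phi) > 2) {
    rel <- (phi[-c(1, length(phi))] - phi[1]) %% 360
    inside <- mean(rel <= sweep + 1e-9)
    if (inside < 0.5) sweep <- 360 - sweep
  }
  sweep %% 360
}

#' Per-frame keypoint displacement, likelihood-weighted
#'
#' Euclidean displacement of one keypoint between consecutive frames,
#' converted to mm and down-weighted by `min(p_t, p_{t-1})`, so that
#' displacement "seen" through an occlusion contributes little.  Frame 0
#' gets 0.
#'
#' @param pose A [pose_series()] (or a `joined_pose` tibble).
#' @param keypoint Keypoint name.
#' @param px_per_mm Calibration; defaults to the pose metadata.
#'
#' @return Numeric vector of per-frame displacements (mm).
#' @export
point_movement <- function(pose, keypoint, px_per_mm = NULL) {
  if (inherits(pose, "pose_series")) {
    dat <- pose$data
    px_per_mm <- px_per_mm %||% pose$meta$px_per_mm
  } else {
    dat <- pose
    px_per_mm <- px_per_mm %||% attr(pose, "meta")$px_per_mm
  }
  if (is.null(px_per_mm) || is.na(px_per_mm)) px_per_mm <- 1
  x <- dat[[paste0(keypoint, "_x")]]
  y <- dat[[paste0(keypoint, "_y")]]
  p <- dat[[paste0(keypoint, "_p")]]
  if (is.null(x)) abort(sprintf("Unknown keypoint '%s'.", keypoint))
  movement_series(x, y, p, px_per_mm)
}

movement_series <- function(x, y, p, px_per_mm) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  d <- sqrt(diff(x)^2 + diff(y)^2) * pmin(p[-1], p[-n]) / px_per_mm
  c(0, d)
}

#' Trailing rolling-window summary statistic
#'
#' Trailing (causal) window of `w = max(1, round(span_s * fps))` frames
#' ending at the current frame; windows at the start of the series shrink
#' to the frames available.  The standard deviation of a single-frame
#' window is 0.
#'
#' @param x Numeric series.
#' @param stat One of `"mean"`, `"sum"`, `"std"`.
#' @param span_s Window span in seconds (> 0).
#' @param fps Frames per second.
#'
#' @return Numeric series of the same length.
#' @export
#' @examples
#' rolling_stat(c(1, 2, 3, 4), "mean", span_s = 2, fps = 1) # 1 1.5 2.5 3.5
rolling_stat <- function(x, stat = c("mean", "sum", "std"), span_s, fps) {
  stat <- match.arg(stat)
  if (span_s <= 0) abort("`span_s` must be positive.")
  w <- max(1L, as.integer(round(span_s * fps)))
  n <- length(x)
  if (n == 0) return(numeric(0))
  k <- pmin(seq_len(n), w)
  s1 <- data.table::frollsum(x, n = k, adaptive = TRUE)
  if (stat == "sum") return(s1)
  if (stat == "mean") return(s1 / k)
  s2 <- data.table::frollsum(x^2, n = k, adaptive = TRUE)
  v <- (s2 - s1^2 / k) / pmax(k - 1, 1)
  v[k < 2] <- 0
  sqrt(pmax(v, 0))
}

# Forward-fill an (x, y) track: frames where `defined` is FALSE inherit the
# nearest preceding defined value, leading gaps take the first defined
# value, and a track with no defined frame at all falls back to `fallback`
# (cage centre) with attribute low_confidence.
hold_last_valid <- function(x, y, defined, fallback = c(0, 0)) {
  n <- length(x)
  if (!any(defined)) {
    return(structure(
      list(x = rep(fallback[1], n), y = rep(fallback[2], n)),
      low_confidence = TRUE
    ))
  }
  idx <- cummax(ifelse(defined, seq_len(n), 0L))
  first <- which(defined)[1]
  idx[idx == 0L] <- first
  list(x = x[idx], y = y[idx])
}
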