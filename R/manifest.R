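#' The versioned 218-feature manifest
#'
#' The feature roster is a package constant: 218 named frame-level
#' features in eight categories (dam location, dam areas, dam key point
#' angles, dam key point probabilities, dam movement, pup area, pup
#' probabilities, dam-pup distances), derived from pup data only (19),
#' dam data only (172) or both (27).  Rolling-window variants use
#' mean/sum/std over trailing 0.1 s, 1 s and 2 s windows; two dam-pup
#' distance families additionally use 30-min and 60-min rolling pup
#' centroids to bridge long pup occlusions.  Within the dam-location
#' category only mean/std windows are used (a trailing *sum* of a raw
#' coordinate scales with window length and would break the documented
#' translation behavior of location features).
#'
#' @return A tibble with one row per feature: `name`, `category`,
#'   `source` (`dam`/`pup`/`both`), `base` (underlying per-frame series),
#'   `stat` (`none`/`mean`/`sum`/`std`), `span_s` (window span, NA when
#'   unwindowed), `pup_centroid_span_min` (30/60 for long-window pup
#'   centroid variants, NA otherwise), `units`.
#' @export
#' @examples
#' m <- feature_manifest()
#' nrow(m)            # 218
#' table(m$source)    # dam 172, pup 19, both 27
feature_manifest <- function() {
  spans <- c(0.1, 1, 2)
  span_tag <- function(s) c("0.1" = "100ms", "1" = "1s", "2" = "2s")[
    as.character(s)]

  plain <- function(name, category, source, units) {
    tibble::tibble(
      name = name, category = category, source = source, base = name,
      stat = "none", span_s = NA_real_,
      pup_centroid_span_min = NA_real_, units = units
    )
  }
  windowed <- function(base, category, source, units,
                       stats = c("mean", "sum", "std")) {
    grid <- expand.grid(stat = stats, span_s = spans,
                        stringsAsFactors = FALSE)
    tibble::tibble(
      name = paste0(base, "_", grid$stat, "_", span_tag(grid$span_s)),
      category = category, source = source, base = base,
      stat = grid$stat, span_s = grid$span_s,
      pup_centroid_span_min = NA_real_,
      units = ifelse(grid$stat == "sum", paste0(units, "_sum"), units)
    )
  }

  dam_groups <- names(keypoint_scheme("dam")$groups)
  dam_kp <- keypoint_scheme("dam")$names

  rows <- dplyr::bind_rows(
    # --- dam_location (30): px coordinates of weighted centroids --------
    plain(c("dam_centroid_x", "dam_centroid_y", "dam_nose_x", "dam_nose_y"),
          "dam_location", "dam", "px"),
    plain(as.vector(t(outer(dam_groups, c("centroid_x", "centroid_y"),
                            paste, sep = "_"))),
          "dam_location", "dam", "px"),
    windowed("dam_centroid_x", "dam_location", "dam", "px",
             stats = c("mean", "std")),
    windowed("dam_centroid_y", "dam_location", "dam", "px",
             stats = c("mean", "std")),
    # --- dam_areas (30): convex hulls in mm^2 ---------------------------
    plain(c("dam_hull_area", "dam_head_hull_area", "dam_dorsal_hull_area"),
          "dam_areas", "dam", "mm2"),
    windowed("dam_hull_area", "dam_areas", "dam", "mm2"),
    windowed("dam_head_hull_area", "dam_areas", "dam", "mm2"),
    windowed("dam_dorsal_hull_area", "dam_areas", "dam", "mm2"),
    # --- dam_angles (30): degrees ---------------------------------------
    plain(c("back_arch_angle", "head_direction_angle", "body_axis_angle"),
          "dam_angles", "dam", "deg"),
    windowed("back_arch_angle", "dam_angles", "dam", "deg"),
    windowed("head_direction_angle", "dam_angles", "dam", "deg"),
    windowed("body_axis_angle", "dam_angles", "dam", "deg"),
    # --- dam_probabilities (30) -----------------------------------------
    plain(c("dam_p_mean", "dam_p_sum", "dam_p_std", "dam_p_min",
            "dam_n_detected"),
          "dam_probabilities", "dam",
          c("prob", "prob_sum", "prob", "prob", "count")),
    plain(paste0(dam_groups, "_p_mean"), "dam_probabilities", "dam", "prob"),
    windowed("dam_p_mean", "dam_probabilities", "dam", "prob"),
    windowed("dam_n_detected", "dam_probabilities", "dam", "count",
             stats = "mean"),
    windowed("dam_p_std", "dam_probabilities", "dam", "prob",
             stats = c("mean", "std")),
    # --- dam_movement (52): mm per frame --------------------------------
    plain(paste0(dam_kp, "_movement"), "dam_movement", "dam", "mm"),
    plain(c("dam_centroid_movement", "dam_head_centroid_movement"),
          "dam_movement", "dam", "mm"),
    windowed("dam_centroid_movement", "dam_movement", "dam", "mm"),
    windowed("dam_head_centroid_movement", "dam_movement", "dam", "mm"),
    # --- pup_area (10) ---------------------------------------------------
    plain("pup_hull_area", "pup_area", "pup", "mm2"),
    windowed("pup_hull_area", "pup_area", "pup", "mm2"),
    # --- pup_probabilities (9) ------------------------------------------
    plain(c("pup_p_mean", "pup_p_sum", "pup_n_detected"),
          "pup_probabilities", "pup", c("prob", "prob_sum", "count")),
    windowed("pup_p_mean", "pup_probabilities", "pup", "prob",
             stats = c("mean", "std")),
    # --- dam_pup_distances (27): mm -------------------------------------
    plain(c("dam_pup_centroid_dist", "dam_nose_pup_dist",
            "dam_tailbase_pup_dist", "dam_pup_dx", "dam_pup_dy"),
          "dam_pup_distances", "both", "mm"),
    tibble::tibble(
      name = c("dam_pup_centroid_dist_30m", "dam_pup_centroid_dist_60m",
               "dam_nose_pup_dist_30m", "dam_nose_pup_dist_60m"),
      category = "dam_pup_distances", source = "both",
      base = name, stat = "none", span_s = NA_real_,
      pup_centroid_span_min = c(30, 60, 30, 60), units = "mm"
    ),
    windowed("dam_pup_centroid_dist", "dam_pup_distances", "both", "mm"),
    windowed("dam_nose_pup_dist", "dam_pup_distances", "both", "mm")
  )

  stopifnot(
    nrow(rows) == 218L,
    !anyDuplicated(rows$name),
    sum(rows$source == "dam") == 172L,
    sum(rows$source == "pup") == 19L,
    sum(rows$source == "both") == 27L,
    length(unique(rows$category)) == 8L
  )
  attr(rows, "manifest_version") <- "fm-1.0-218"
  rows
}

#' Manifest version string
#'
#' @param manifest A manifest tibble from [feature_manifest()] (or one read
#'   back from YAML).
#' @return Character scalar.
#' @export
manifest_version <- function(manifest = feature_manifest()) {
  attr(manifest, "manifest_version") %||% "fm-unknown"
}

#' Serialize / read the feature manifest as YAML
#'
#' @param manifest Manifest tibble.
#' @param path YAML path.
#' @return `path` (write) or the manifest tibble (read).
#' @export
write_manifest_yaml <- function(manifest, path) {
  doc <- list(
    manifest_version = manifest_version(manifest),
    features = purrr::pmap(manifest, function(...) {
      row <- list(...)
      row[!vapply(row, function(v) is.na(v) %in% TRUE, logical(1))]
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_manifest_yaml
#' @export
read_manifest_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  rows <- purrr::map_dfr(doc$features, function(f) {
    tibble::tibble(
      name = f$name, category = f$category, source = f$source,
      base = f$base, stat = f$stat,
      span_s = f$span_s %||% NA_real_,
      pup_centroid_span_min = f$pup_centroid_span_min %||% NA_real_,
      units = f$units
    )
  })
  attr(rows, "manifest_version") <- doc$manifest_version
  rows
}
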