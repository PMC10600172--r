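#' Simulation scenario for an in-silico home-cage session
#'
#' Describes everything needed to generate a synthetic recording: cage
#' geometry and calibration, zones (nest, food hopper, water spout), litter
#' size, a scripted behavior timeline, an occlusion model and coordinate
#' noise.  Defaults mirror the recording conditions the pipeline targets:
#' 30 fps side-view video at 1280 x 780 px of a standard cage, calibrated
#' at ~2.28 px/mm from the known cage-top width, with a litter of 8 pups
#' clustered in the nest and heavy keypoint dropout for in-nest pups.
#'
#' The simulator is a test oracle, not a biomechanical model: behavior
#' templates are deliberately simple (zone occupancy, back-arch curvature,
#' nose/ear oscillation frequency, posture scaling) so that the feature
#' families the pipeline computes are exactly what separates the classes.
#'
#' @param seed Integer master seed; every random component draws from a
#'   named substream derived from it.
#' @param duration_s Session length in seconds.
#' @param fps Frames per second.
#' @param width_px,height_px Frame size.
#' @param px_per_mm Calibration.
#' @param n_pups Litter size (must not exceed `max_pups` downstream).
#' @param behavior_script Optional tibble `(state, start_s, stop_s)`;
#'   states are the seven behaviors plus `"off_nest"`.  Auto-generated
#'   when `NULL` (all behaviors represented, 1.5 s unlabeled transit gaps
#'   between segments).
#' @param occlusion Per-context keypoint dropout probabilities: `dam`,
#'   `pup_in_nest`, `pup_off_nest`.
#' @param noise_sd_px Gaussian coordinate jitter (px).
#' @param video_id Recording identifier.
#'
#' @return A `sim_scenario` list (zones included).
#' @export
sim_scenario <- function(seed = 1L, duration_s = 120, fps = 30,
                         width_px = 1280, height_px = 780,
                         px_per_mm = 2.28, n_pups = 8,
                         behavior_script = NULL,
                         occlusion = list(dam = 0.15, pup_in_nest = 0.5,
                                          pup_off_nest = 0.1),
                         noise_sd_px = 4,
                         video_id = sprintf("sim%06d", seed)) {
  zones <- list(
    nest = c(80, 460, 440, 740),
    food = c(520, 40, 760, 200),
    water = c(1000, 40, 1200, 200)
  )
  if (is.null(behavior_script)) {
    behavior_script <- random_behavior_script(duration_s, seed)
  }
  behavior_script <- validate_script(behavior_script, duration_s)
  structure(
    list(
      seed = as.integer(seed), duration_s = duration_s, fps = fps,
      width_px = width_px, height_px = height_px, px_per_mm = px_per_mm,
      n_pups = n_pups, zones = zones, behavior_script = behavior_script,
      occlusion = occlusion, noise_sd_px = noise_sd_px,
      video_id = video_id
    ),
    class = "sim_scenario"
  )
}

sim_states <- function() {
  c("off_nest", behavior_vocabulary())
}

# Which scripted states may overlap: nursing and licking/grooming happen
# on the nest, so they may overlap nest_attendance; everything else is
# mutually exclusive.
nest_states <- function() {
  c("nest_attendance", "active_nursing", "passive_nursing",
    "licking_grooming")
}

validate_script <- function(script, duration_s) {
  script <- tibble::as_tibble(script)
  stopifnot(all(c("state", "start_s", "stop_s") %in% names(script)))
  bad <- setdiff(unique(script$state), sim_states())
  if (length(bad) > 0) {
    abort(sprintf("Unknown script state '%s'.", bad[1]),
          class = "nw_validation_error")
  }
  if (any(script$stop_s <= script$start_s) ||
      any(script$start_s < 0) || any(script$stop_s > duration_s)) {
    abort("Script intervals must satisfy 0 <= start < stop <= duration.",
          class = "nw_validation_error")
  }
  s <- script[order(script$start_s), ]
  for (i in seq_len(nrow(s))) {
    for (j in seq_len(nrow(s))) {
      if (j <= i) next
      overlap <- s$start_s[j] < s$stop_s[i] & s$stop_s[j] > s$start_s[i]
      if (overlap) {
        both_nest <- all(c(s$state[i], s$state[j]) %in% nest_states())
        if (!both_nest) {
          abort(sprintf(
            "Contradictory overlapping script entries: %s and %s.",
            s$state[i], s$state[j]
          ), class = "nw_validation_error")
        }
      }
    }
  }
  s
}

#' Generate a random behavior script
#'
#' Seeded semi-Markov timeline: one shuffled pass through all eight states
#' (guaranteeing coverage), then random continuation until the session is
#' filled.  Consecutive segments are separated by 1.5 s unlabeled transit
#' gaps, as a human annotator would leave locomotion between behaviors
#' unscored.
#'
#' @param duration_s Session length (s).
#' @param seed Integer seed.
#' @return Tibble `(state, start_s, stop_s)`.
#' @export
random_behavior_script <- function(duration_s, seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(substream_seed(seed, "script"))
  dwell <- list(
    off_nest = c(3, 6), nest_attendance = c(6, 12),
    active_nursing = c(6, 12), passive_nursing = c(6, 12),
    licking_grooming = c(4, 8), self_grooming = c(4, 8),
    eating = c(5, 10), drinking = c(4, 8)
  )
  gap <- 1.5
  states <- sample(sim_states())
  rows <- list()
  t <- 0
  i <- 1
  while (t < duration_s - gap - 2) {
    st <- if (i <= length(states)) states[i] else sample(sim_states(), 1)
    d <- stats::runif(1, dwell[[st]][1], dwell[[st]][2])
    stop_t <- min(t + d, duration_s)
    if (stop_t - t > 1) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        state = st, start_s = t, stop_s = stop_t
      )
    }
    t <- stop_t + gap
    i <- i + 1
  }
  dplyr::bind_rows(rows)
}

# state -> posture/motion parameters
state_params <- function() {
  tibble::tribble(
    ~state,             ~scale_x, ~scale_y, ~dy, ~arch, ~osc, ~wander, ~target,
    "off_nest",         1.00,     1.00,      0,   60,    2,    2.0,    "idle",
    "nest_attendance",  1.00,     1.00,      0,   60,    2,    1.2,    "nest",
    "active_nursing",   0.80,     1.10,      0,  150,    2,    0.8,    "nest",
    "passive_nursing",  1.35,     0.75,     25,    6,    1,    0.3,    "nest",
    "licking_grooming", 1.00,     1.00,      0,   70,   16,    1.0,    "nest",
    "self_grooming",    1.00,     1.00,      0,   80,   16,    0.8,    "idle",
    "eating",           1.00,     1.00,      0,   55,    3,    1.0,    "food",
    "drinking",         1.00,     1.00,      0,   45,    3,    0.8,    "water"
  )
}

# Static keypoint template: side view, animal facing left, centroid near
# the origin, units px.  Back points are generated from the arch angle.
dam_template_offsets <- function() {
  tibble::tribble(
    ~kp,              ~x,    ~y,
    "nose",           -170,  -45,
    "chin",           -165,  -25,
    "left_eye",       -150,  -62,
    "right_eye",      -146,  -58,
    "left_ear",       -138,  -70,
    "right_ear",      -130,  -64,
    "top_head",       -125,  -75,
    "throat",         -140,  -10,
    "chest",           -90,   25,
    "abdomen_mid",     -20,   35,
    "abdomen_low",      40,   35,
    "groin",            85,   30,
    "pelvis",          105,   15,
    "left_shoulder",  -105,  -15,
    "right_shoulder",  -95,   -8,
    "left_forepaw",   -115,   45,
    "right_forepaw",  -100,   48,
    "left_hip",         75,   -5,
    "right_hip",        85,    2,
    "left_hindpaw",     70,   50,
    "right_hindpaw",    85,   52,
    "left_flank",      -10,  -15,
    "right_flank",       5,   -8,
    "tail_base",       115,  -20,
    "tail_mid",        160,    0,
    "tail_tip",        200,   15
  )
}

# Six back points on a circular arc: chord from (-90, -78) to (95, -78),
# bulging upward (negative y) with the given central angle.
arch_points <- function(arch_deg) {
  a <- c(-90, -78); b <- c(95, -78)
  theta <- max(arch_deg, 1) * pi / 180
  half <- sqrt(sum((b - a)^2)) / 2
  r <- half / sin(theta / 2)
  mid <- (a + b) / 2
  centre <- mid + c(0, r * cos(theta / 2)) # below the chord (y down)
  phi_a <- atan2(a[2] - centre[2], a[1] - centre[1])
  phi_b <- atan2(b[2] - centre[2], b[1] - centre[1])
  phi <- phi_a + seq(0, 1, length.out = 6) * (phi_b - phi_a)
  cbind(x = centre[1] + r * cos(phi), y = centre[2] + r * sin(phi))
}

# drinking: head tilted up toward the bottle in the wire top
drinking_head_override <- function() {
  tibble::tribble(
    ~kp,        ~x,    ~y,
    "nose",     -130, -130,
    "chin",     -128, -105,
    "left_eye", -132,  -95,
    "right_eye",-128,  -92,
    "left_ear", -126,  -85,
    "right_ear",-120,  -80,
    "top_head", -118,  -82
  )
}

zone_centre <- function(z) c((z[1] + z[3]) / 2, (z[2] + z[4]) / 2)

#' Simulate one home-cage session
#'
#' Generates a deterministic (given the scenario seed) session: a dam
#' [pose_series()] driven by per-state posture templates, identity-free
#' pup [raw_detections()] clustered in the nest with occlusion dropout,
#' ground-truth [annotation_set()] equal to the rasterized script, and
#' [video_meta()].
#'
#' Posture templates per behavior: nest attendance places the dam centroid
#' in the nest zone near the pup centroid; active nursing adds a strongly
#' arched back (circle-fit central angle ~150 deg); passive nursing a
#' laterally stretched, nearly flat-backed template; licking/grooming adds
#' 6 Hz nose/ear oscillation near the pup centroid; self-grooming the same
#' oscillation away from the pups; eating moves the dam to the food zone;
#' drinking to the water zone with an upward head angle.
#'
#' @param s A [sim_scenario()].
#' @return A `sim_session`: list with `dam`, `pup_detections`, `truth`,
#'   `meta`, `scenario`.
#' @export
simulate_session <- function(s) {
  stopifnot(inherits(s, "sim_scenario"))
  n <- round(s$duration_s * s$fps)
  fps <- s$fps
  meta <- video_meta(s$video_id, fps = fps, width_px = s$width_px,
                     height_px = s$height_px, px_per_mm = s$px_per_mm,
                     n_frames = n)
  sp <- state_params()
  targets <- list(
    idle = c(880, 600),
    nest = zone_centre(s$zones$nest) + c(110, -30),
    food = zone_centre(s$zones$food) + c(0, 160),
    water = zone_centre(s$zones$water) + c(0, 160)
  )

  # --- per-frame posture state and motion target ------------------------
  t_frame <- (seq_len(n) - 1) / fps
  script <- s$behavior_script
  prio <- c(
    off_nest = 0, nest_attendance = 1, eating = 2, drinking = 2,
    self_grooming = 2, passive_nursing = 3, active_nursing = 3,
    licking_grooming = 4
  )
  state <- rep("off_nest", n)
  best <- rep(-1, n)
  for (i in seq_len(nrow(script))) {
    in_seg <- t_frame >= script$start_s[i] & t_frame < script$stop_s[i]
    take <- in_seg & prio[script$state[i]] > best
    state[take] <- script$state[i]
    best[take] <- prio[script$state[i]]
  }
  # during unlabeled gaps the dam walks toward the next segment's target
  covered <- best >= 0
  seg_target <- sp$target[match(script$state, sp$state)]
  gap_target <- rep("idle", n)
  if (nrow(script) > 0) {
    nxt <- findInterval(t_frame, script$start_s) + 1L
    has_next <- nxt <= nrow(script)
    gap_target[has_next] <- seg_target[nxt[has_next]]
  }
  par_idx <- match(state, sp$state)
  target_name <- ifelse(covered, sp$target[par_idx], gap_target)

  # --- dam centroid trajectory (seeded substream) -----------------------
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(substream_seed(s$seed, "dam-motion"))
  rate <- 1 - exp(-1 / (0.3 * fps))
  wander <- sp$wander[par_idx]
  wn_x <- rnorm(n); wn_y <- rnorm(n)
  pos <- matrix(0, n, 2)
  tgt0 <- targets[[target_name[1]]]
  pos[1, ] <- tgt0
  for (i in 2:n) {
    tg <- targets[[target_name[i]]]
    pos[i, 1] <- pos[i - 1, 1] + rate * (tg[1] - pos[i - 1, 1]) +
      wander[i] * wn_x[i]
    pos[i, 2] <- pos[i - 1, 2] + rate * (tg[2] - pos[i - 1, 2]) +
      wander[i] * wn_y[i]
  }

  # --- dam keypoints ----------------------------------------------------
  set.seed(substream_seed(s$seed, "dam-pose"))
  scheme <- keypoint_scheme("dam")
  kp <- scheme$names
  tmpl <- dam_template_offsets()
  base_x <- stats::setNames(rep(NA_real_, 32), kp)
  base_y <- base_x
  base_x[tmpl$kp] <- tmpl$x
  base_y[tmpl$kp] <- tmpl$y
  drink <- drinking_head_override()

  arch_by_state <- lapply(stats::setNames(sp$state, sp$state), function(st) {
    arch_points(sp$arch[sp$state == st])
  })
  osc_kp <- c("nose", "chin", "left_ear", "right_ear", "left_eye",
              "right_eye")
  phase <- stats::setNames(seq(0, pi, length.out = length(osc_kp)), osc_kp)
  osc_amp <- sp$osc[par_idx]
  osc_t <- sin(2 * pi * 6 * t_frame)
  osc_t2 <- cos(2 * pi * 6 * t_frame)

  X <- matrix(0, n, 32, dimnames = list(NULL, kp))
  Y <- X
  sxv <- sp$scale_x[par_idx]; syv <- sp$scale_y[par_idx]
  dyv <- sp$dy[par_idx]
  for (j in seq_along(kp)) {
    k <- kp[j]
    if (startsWith(k, "back_")) {
      bi <- as.integer(sub("back_", "", k))
      off_x <- vapply(arch_by_state, function(m) m[bi, 1], numeric(1))
      off_y <- vapply(arch_by_state, function(m) m[bi, 2], numeric(1))
      ox <- off_x[state]; oy <- off_y[state]
    } else {
      ox <- rep(base_x[k], n); oy <- rep(base_y[k], n)
      if (k %in% drink$kp) {
        di <- match(k, drink$kp)
        is_drink <- state == "drinking"
        ox[is_drink] <- drink$x[di]; oy[is_drink] <- drink$y[di]
      }
      if (k %in% osc_kp) {
        ox <- ox + osc_amp * osc_t * cos(phase[k])
        oy <- oy + 0.6 * osc_amp * osc_t2 * sin(phase[k] + 0.5)
      }
    }
    X[, j] <- pos[, 1] + ox * sxv + rnorm(n, sd = s$noise_sd_px)
    Y[, j] <- pos[, 2] + oy * syv + dyv + rnorm(n, sd = s$noise_sd_px)
  }

  # --- dam occlusion / likelihoods --------------------------------------
  set.seed(substream_seed(s$seed, "dam-occlusion"))
  drop_mask <- matrix(runif(n * 32) < s$occlusion$dam, n, 32)
  P <- matrix(runif(n * 32, 0.75, 1), n, 32)
  P[drop_mask] <- 0
  # occluded points come back as garbage locations, as real pose
  # estimators produce; probability weighting must absorb them
  X[drop_mask] <- runif(sum(drop_mask), 0, s$width_px)
  Y[drop_mask] <- runif(sum(drop_mask), 0, s$height_px)

  dam_tb <- tibble::tibble(frame = seq_len(n) - 1L)
  for (j in seq_along(kp)) {
    dam_tb[[paste0(kp[j], "_x")]] <- X[, j]
    dam_tb[[paste0(kp[j], "_y")]] <- Y[, j]
    dam_tb[[paste0(kp[j], "_p")]] <- P[, j]
  }
  dam <- pose_series(dam_tb, meta, scheme)

  # --- pups -------------------------------------------------------------
  set.seed(substream_seed(s$seed, "pups"))
  pup_bp <- keypoint_scheme("pup")$names
  nest_c <- zone_centre(s$zones$nest)
  frames <- empty_detection_frames(n, pup_bp)
  if (s$n_pups > 0) {
    anchors <- cbind(rnorm(s$n_pups, nest_c[1], 45),
                     rnorm(s$n_pups, nest_c[2], 45))
    angles0 <- runif(s$n_pups, 0, 2 * pi)
    # axial offsets nose -> tail_base along a 60 px body
    axial <- stats::setNames(seq(30, -30, length.out = 9), pup_bp)
    perp <- stats::setNames(rep(0, 9), pup_bp)
    perp[c("left_ear", "right_ear")] <- c(-7, 7)
    axial[c("left_ear", "right_ear")] <- 22
    drift <- array(rnorm(n * s$n_pups * 2, sd = 0.35),
                   dim = c(n, s$n_pups, 2))
    rot_drift <- matrix(rnorm(n * s$n_pups, sd = 0.005), n, s$n_pups)
    keep_p <- 1 - s$occlusion$pup_in_nest
    det_mask <- array(runif(n * s$n_pups * 9) < keep_p,
                      dim = c(n, s$n_pups, 9))
    confs <- array(runif(n * s$n_pups * 9, 0.55, 0.95),
                   dim = c(n, s$n_pups, 9))
    noise <- array(rnorm(n * s$n_pups * 9 * 2, sd = s$noise_sd_px),
                   dim = c(n, s$n_pups, 9, 2))
    cx <- apply(matrix(drift[, , 1], n), 2, cumsum)
    cy <- apply(matrix(drift[, , 2], n), 2, cumsum)
    ang <- apply(rot_drift, 2, cumsum) + rep(angles0, each = n)
    for (i in seq_len(n)) {
      for (b in seq_along(pup_bp)) {
        vis <- which(det_mask[i, , b])
        if (length(vis) == 0) next
        a <- ang[i, vis]
        px <- anchors[vis, 1] + cx[i, vis] +
          axial[b] * cos(a) + perp[b] * -sin(a) + noise[i, vis, b, 1]
        py <- anchors[vis, 2] + cy[i, vis] +
          axial[b] * sin(a) + perp[b] * cos(a) + noise[i, vis, b, 2]
        frames[[i]][[pup_bp[b]]] <-
          cbind(px, py, confs[i, vis, b])
      }
    }
  }
  pups <- raw_detections(frames, meta, bodyparts = pup_bp)

  # --- ground truth -----------------------------------------------------
  truth_int <- script[script$state != "off_nest", ]
  truth_int <- tibble::tibble(
    behavior = truth_int$state,
    start_s = truth_int$start_s, stop_s = truth_int$stop_s
  )
  # nursing and licking/grooming imply nest attendance
  implied <- truth_int[truth_int$behavior %in%
                         setdiff(nest_states(), "nest_attendance"), ]
  if (nrow(implied) > 0) {
    implied$behavior <- "nest_attendance"
    truth_int <- dplyr::bind_rows(truth_int, implied)
  }
  truth <- annotation_set(truth_int, meta)

  structure(
    list(dam = dam, pup_detections = pups, truth = truth, meta = meta,
         scenario = s),
    class = "sim_session"
  )
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf(
    "<sim_session %s: %d frames at %g fps, %d pups, %d script segments>\n",
    x$meta$video_id, x$meta$n_frames, x$meta$fps, x$scenario$n_pups,
    nrow(x$scenario$behavior_script)
  ))
  invisible(x)
}

#' Run a simulated session through the joining + feature steps
#'
#' Convenience wrapper: slot assignment, dam-pup join and feature
#' extraction for one [simulate_session()] output.
#'
#' @param session A `sim_session`.
#' @param max_pups Slot count for [detections_to_table()].
#' @param params [geometry_params()].
#' @return A `feature_matrix` tibble.
#' @export
session_features <- function(session, max_pups = 12,
                             params = geometry_params()) {
  pup_tab <- detections_to_table(session$pup_detections, max_pups)
  joined <- join_dam_pup(session$dam, pup_tab, session$meta)
  extract_features(joined, params = params)
}

#' Write a session to disk in the formats the readers consume
#'
#' Emits five plain-text files: the dam pose CSV (three-row-header
#' dialect), pup detections in both interchangeable dialects (JSON and
#' long CSV), the annotation interval CSV and a metadata YAML.  Reading
#' them back through the I/O layer round-trips the session.
#'
#' @param session A `sim_session` (or a [sim_scenario()], which is
#'   simulated first).
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture_set <- function(session, dir) {
  if (inherits(session, "sim_scenario")) {
    session <- simulate_session(session)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    dam_pose = file.path(dir, "dam_pose.csv"),
    detections_json = file.path(dir, "pup_detections.json"),
    detections_csv = file.path(dir, "pup_detections.csv"),
    annotations = file.path(dir, "annotations.csv"),
    meta = file.path(dir, "meta.yaml")
  )
  write_dam_pose(session$dam, paths["dam_pose"])
  write_detections(session$pup_detections, paths["detections_json"])
  write_detections(session$pup_detections, paths["detections_csv"])
  write_annotations(session$truth, paths["annotations"])
  write_video_meta(session$meta, paths["meta"])
  invisible(paths)
}

#' Write / read video metadata as YAML
#'
#' @param meta A [video_meta()].
#' @param path YAML path.
#' @return `path` (write) or a [video_meta()] (read).
#' @export
write_video_meta <- function(meta, path) {
  yaml::write_yaml(unclass(meta), path)
  invisible(path)
}

#' @rdname write_video_meta
#' @export
read_video_meta <- function(path) {
  m <- yaml::read_yaml(path)
  video_meta(m$video_id, fps = m$fps, width_px = m$width_px,
             height_px = m$height_px, px_per_mm = m$px_per_mm,
             n_frames = m$n_frames %||% NA_integer_)
}
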