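# Gaze-target classification from 3D facial keypoints. Head direction is
# the gaze proxy: the forward axis is the outward unit normal of the plane
# through the two eyes and the blaze (the forehead marker), and a target is
# "looked at" when it falls inside a virtual cone of half-angle 15 degrees
# around that axis. The stated 15-degree "solid angle" is dimensionally a
# cone aperture; it is read here as the half-angle, with the apex-angle
# reading selectable.

#' Head pose from one frame of facial keypoints
#'
#' Fits the face plane through `left_eye`, `right_eye` and `blaze`, takes
#' the gaze origin at the eye midpoint and the forward axis as the plane's
#' unit normal, with its sign chosen to point out of the face: away from
#' the ear-tuft midpoint when at least one ear tuft is present, otherwise
#' toward the mouth side (the mouth sits slightly anterior to the face
#' plane). Degenerate geometry (missing keypoints, near-collinear eyes and
#' blaze) yields `valid = FALSE` with a reason, never an error.
#'
#' @param points Numeric 6 x 3 matrix of keypoint coordinates (cm) with
#'   rownames from the six canonical keypoint names; missing keypoints are
#'   `NA` rows.
#' @param min_triangle_cm2 Minimum area of the eye-eye-blaze triangle below
#'   which the plane is declared degenerate. Default 0.01 cm^2.
#' @return List (`origin`, `forward`, `valid`, `reason`): `forward` is a
#'   unit 3-vector when valid.
#' @examples
#' hp <- head_pose(marmopull:::canonical_head())
#' hp$forward  # (0, 0, 1)
#' @export
head_pose <- function(points, min_triangle_cm2 = 0.01) {
  need <- c("left_eye", "right_eye", "blaze")
  invalid <- function(reason) list(origin = rep(NA_real_, 3),
                                   forward = rep(NA_real_, 3),
                                   valid = FALSE, reason = reason)
  if (!all(need %in% rownames(points)))
    return(invalid("missing keypoint"))
  le <- points["left_eye", ]; re <- points["right_eye", ]
  bl <- points["blaze", ]
  if (anyNA(c(le, re, bl))) return(invalid("missing keypoint"))
  origin <- (le + re) / 2
  nrm <- cross3(re - le, bl - origin)
  area <- sqrt(sum(nrm^2)) / 2
  if (!is.finite(area) || area < min_triangle_cm2)
    return(invalid("degenerate plane"))
  forward <- nrm / sqrt(sum(nrm^2))
  # sign disambiguation: ears behind the face, mouth slightly in front
  ears <- points[c("left_ear_tuft", "right_ear_tuft"), , drop = FALSE]
  ears <- ears[stats::complete.cases(ears), , drop = FALSE]
  if (nrow(ears)) {
    ear_mid <- colMeans(ears)
    if (sum(forward * (origin - ear_mid)) < 0) forward <- -forward
  } else if (!anyNA(points["mouth", ])) {
    if (sum(forward * (points["mouth", ] - origin)) < 0) forward <- -forward
  } else {
    return(invalid("cannot disambiguate normal sign"))
  }
  list(origin = origin, forward = forward, valid = TRUE, reason = NA_character_)
}

# long keypoint df for one animal -> per-frame pose data.frame
#' Head poses for every frame of a keypoint table
#'
#' @param keypoints Long-format keypoint `data.frame` (one animal) as from
#'   [read_keypoints()] or [synthesize_keypoints()].
#' @param min_triangle_cm2 Passed to [head_pose()].
#' @return `data.frame` with one row per frame: `frame, t_ms, animal, ox,
#'   oy, oz, fx, fy, fz, valid, reason`.
#' @export
head_poses <- function(keypoints, min_triangle_cm2 = 0.01) {
  if (length(unique(keypoints$animal)) > 1L)
    validation_error("head_poses expects keypoints of a single animal")
  frames <- sort(unique(keypoints$frame))
  out <- lapply(frames, function(f) {
    kf <- keypoints[keypoints$frame == f, ]
    m <- matrix(NA_real_, 6, 3, dimnames = list(KEYPOINT_NAMES, c("x", "y", "z")))
    m[kf$keypoint, ] <- cbind(kf$x, kf$y, kf$z)
    hp <- head_pose(m, min_triangle_cm2)
    data.frame(frame = f, t_ms = kf$t_ms[1], animal = kf$animal[1],
               ox = hp$origin[1], oy = hp$origin[2], oz = hp$origin[3],
               fx = hp$forward[1], fy = hp$forward[2], fz = hp$forward[3],
               valid = hp$valid, reason = hp$reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Is a target inside the gaze cone?
#'
#' True iff the target lies in front of the face (positive projection on
#' the forward axis) and the angle between the forward axis and the
#' origin-to-target direction is at most the cone half-angle. The boundary
#' counts as a hit (closed cone), so enlarging the cone never turns a hit
#' into a miss.
#'
#' @param pose A valid pose from [head_pose()] (list with `origin`,
#'   `forward`, `valid`).
#' @param target_point 3-vector (cm); must differ from the gaze origin.
#' @param half_angle_deg Cone half-angle in degrees; default 15.
#' @param angle_interpretation `"half_angle"` (default: the quoted aperture
#'   is the half-angle) or `"apex_angle"` (the aperture is the full apex
#'   angle, i.e. half of it on each side of the axis).
#' @return `TRUE`/`FALSE`, or `NA` when the pose is invalid (the frame is
#'   excluded from counts).
#' @export
gaze_hit <- function(pose, target_point, half_angle_deg = 15,
                     angle_interpretation = c("half_angle", "apex_angle")) {
  angle_interpretation <- match.arg(angle_interpretation)
  if (!isTRUE(pose$valid)) return(NA)
  ang <- gaze_angle_rad(pose$forward, target_point - pose$origin)
  if (is.na(ang)) return(NA)
  theta <- half_angle_deg * pi / 180
  if (angle_interpretation == "apex_angle") theta <- theta / 2
  ang <= theta + 1e-9
}

# angle (radians) between forward and a direction; NA for zero direction,
# Inf-like misses (behind the head) simply give angles > pi/2
gaze_angle_rad <- function(forward, dir) {
  u <- unitize(dir)
  if (is.null(u)) return(NA_real_)
  d <- sum(forward * u)
  acos(max(-1, min(1, d)))
}

#' Classify the gaze target of every frame
#'
#' For each frame the candidate targets are the static scene targets
#' (lever, juice tube, ...) plus the partner's head — a dynamic target at
#' the partner's per-frame gaze origin when `partner_poses` is supplied
#' (frames where the partner pose is invalid drop the partner candidate).
#' The label is the hit target nearest in angle; `"none"` if no target is
#' inside the cone; `NA` for invalid frames.
#'
#' @param poses Pose `data.frame` from [head_poses()].
#' @param scene A [scene_geometry()].
#' @param partner_poses Optional pose `data.frame` of the partner, aligned
#'   on `frame` (same frame set).
#' @param half_angle_deg,angle_interpretation Passed to the cone test.
#' @return `data.frame` (`frame, t_ms, animal, target, angle_deg`):
#'   `target` is the winning label, `"none"`, or `NA`; `angle_deg` the
#'   winning angle.
#' @export
classify_frames <- function(poses, scene, partner_poses = NULL,
                            half_angle_deg = 15,
                            angle_interpretation = c("half_angle",
                                                     "apex_angle")) {
  angle_interpretation <- match.arg(angle_interpretation)
  if (!is.null(partner_poses) &&
      !identical(sort(poses$frame), sort(partner_poses$frame)))
    validation_error("poses and partner_poses frames are misaligned")
  theta <- half_angle_deg * pi / 180
  if (angle_interpretation == "apex_angle") theta <- theta / 2
  static <- scene$targets
  partner_idx <- if (!is.null(partner_poses))
    match(poses$frame, partner_poses$frame) else NULL
  n <- nrow(poses)
  target <- rep(NA_character_, n)
  angle_deg <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!poses$valid[i]) next
    fwd <- c(poses$fx[i], poses$fy[i], poses$fz[i])
    org <- c(poses$ox[i], poses$oy[i], poses$oz[i])
    names_i <- static$name
    pts <- cbind(static$x, static$y, static$z)
    if (!is.null(partner_idx) && !is.na(partner_idx[i]) &&
        partner_poses$valid[partner_idx[i]]) {
      j <- partner_idx[i]
      pts <- rbind(pts, c(partner_poses$ox[j], partner_poses$oy[j],
                          partner_poses$oz[j]))
      names_i <- c(names_i, "partner_head")
    }
    angs <- apply(pts, 1, function(p) gaze_angle_rad(fwd, p - org))
    hit <- !is.na(angs) & angs <= theta + 1e-9
    if (any(hit)) {
      k <- which(hit)[which.min(angs[hit])]
      target[i] <- names_i[k]
      angle_deg[i] <- angs[k] * 180 / pi
    } else {
      target[i] <- "none"
    }
  }
  data.frame(frame = poses$frame, t_ms = poses$t_ms, animal = poses$animal,
             target = target, angle_deg = angle_deg, stringsAsFactors = FALSE)
}

#' Segment per-frame gaze labels into bouts
#'
#' A bout is a maximal run of one non-`none` target label, allowed to
#' bridge interruptions of at most `max_gap_frames` consecutive
#' `none`/invalid frames, and kept only if its span (first to last frame of
#' the target label, bridged gaps included) is at least `min_bout_frames`.
#' A different target always terminates the bout. The defaults (minimum 3
#' frames, gap 1) are this package's own bout criteria — chosen so that a
#' bout at 30 fps lasts at least ~100 ms and a single dropped frame does
#' not split a fixation.
#'
#' @param labels Character vector of per-frame targets (`"none"` / `NA`
#'   allowed), time-ordered; or the `data.frame` from [classify_frames()].
#' @param frame_rate_hz Frame rate used to convert spans to ms.
#' @param min_bout_frames Minimum bout span in frames; default 3.
#' @param max_gap_frames Maximum bridged gap in frames; default 1.
#' @return `data.frame` (`target, start_frame, end_frame, n_frames,
#'   duration_ms`), non-overlapping and time-ordered. Frame indices are
#'   0-based positions in `labels` (or the `frame` column when a
#'   classification `data.frame` is given).
#' @examples
#' segment_bouts(c("lever", "lever", "lever", "none", "lever", "lever"),
#'               frame_rate_hz = 30)
#' @export
segment_bouts <- function(labels, frame_rate_hz, min_bout_frames = 3,
                          max_gap_frames = 1) {
  frames <- NULL
  animal <- NA_character_
  if (is.data.frame(labels)) {
    frames <- labels$frame
    if ("animal" %in% names(labels)) animal <- labels$animal[1]
    labels <- labels$target
  }
  if (is.null(frames)) frames <- seq_along(labels) - 1L
  n <- length(labels)
  is_gap <- is.na(labels) | labels == "none"
  bouts <- list()
  cur <- NULL      # list(target, start_i, last_i)
  gap_run <- 0L
  close_cur <- function() {
    if (is.null(cur)) return()
    span <- cur$last_i - cur$start_i + 1L
    if (span >= min_bout_frames)
      bouts[[length(bouts) + 1L]] <<- data.frame(
        animal = animal, target = cur$target,
        start_frame = frames[cur$start_i], end_frame = frames[cur$last_i],
        n_frames = span,
        duration_ms = span * 1000 / frame_rate_hz,
        stringsAsFactors = FALSE)
    cur <<- NULL
  }
  for (i in seq_len(n)) {
    if (is_gap[i]) {
      gap_run <- gap_run + 1L
      if (!is.null(cur) && gap_run > max_gap_frames) close_cur()
      next
    }
    if (!is.null(cur) && labels[i] == cur$target && gap_run <= max_gap_frames) {
      cur$last_i <- i
    } else {
      close_cur()
      cur <- list(target = labels[i], start_i = i, last_i = i)
    }
    gap_run <- 0L
  }
  close_cur()
  if (!length(bouts)) {
    return(data.frame(animal = character(), target = character(),
                      start_frame = integer(), end_frame = integer(),
                      n_frames = integer(), duration_ms = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, bouts)
  rownames(out) <- NULL
  out
}

#' Per-target gaze counts: bouts and frames
#'
#' Whether one should count discrete gaze bouts or the raw number of frames
#' on target is a judgment call; both are reported.
#'
#' @param classification Output of [classify_frames()].
#' @param frame_rate_hz Frame rate (Hz).
#' @param ... Passed to [segment_bouts()].
#' @return `data.frame` (`target, n_bouts, n_frames, total_duration_ms`).
#' @export
gaze_target_counts <- function(classification, frame_rate_hz, ...) {
  bouts <- segment_bouts(classification, frame_rate_hz, ...)
  targets <- sort(unique(stats::na.omit(
    classification$target[classification$target != "none"])))
  out <- lapply(targets, function(tg) {
    data.frame(target = tg,
               n_bouts = sum(bouts$target == tg),
               n_frames = sum(classification$target == tg, na.rm = TRUE),
               total_duration_ms = sum(bouts$duration_ms[bouts$target == tg]),
               stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(target = character(), n_bouts = integer(),
                      n_frames = integer(), total_duration_ms = numeric()))
  do.call(rbind, out)
}
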