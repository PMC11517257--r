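# On-disk interchange formats. All files are UTF-8 CSV with a mandatory
# header row and integer-millisecond timestamps counted from session start.
# The logging schema is defined by this package (the task literature states
# millisecond precision but no schema); writers emit a canonical formatting
# so that write/read round-trips are byte-identical.

ACTORS <- c("M1", "M2")
EVENT_ACTORS <- c("M1", "M2", "system")
EVENT_KINDS <- c("pull", "tone", "reward")
KEYPOINT_NAMES <- c("left_ear_tuft", "right_ear_tuft", "left_eye",
                    "right_eye", "blaze", "mouth")

read_csv_strict <- function(path, expected_cols) {
  if (!file.exists(path)) format_error("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE),
    error = function(e) format_error("cannot parse '", path, "': ",
                                     conditionMessage(e)))
  if (!identical(names(df), expected_cols)) {
    extra <- setdiff(names(df), expected_cols)
    miss <- setdiff(expected_cols, names(df))
    format_error("header of '", path, "' does not match (",
                 paste(expected_cols, collapse = ","), ")",
                 if (length(extra)) paste0("; unknown column(s): ",
                                           paste(extra, collapse = ",")),
                 if (length(miss)) paste0("; missing column(s): ",
                                          paste(miss, collapse = ",")))
  }
  df
}

parse_int_col <- function(x, path, col) {
  bad <- which(!grepl("^-?[0-9]+$", x))
  if (length(bad))
    format_error("'", path, "' line ", bad[1] + 1L, ", column '", col,
                 "': not an integer: '", x[bad[1]], "'")
  as.integer(x)
}

parse_num_col <- function(x, path, col, allow_missing = FALSE) {
  x2 <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(x2) & !(allow_missing & (is.na(x) | x == "")))
  if (length(bad))
    format_error("'", path, "' line ", bad[1] + 1L, ", column '", col,
                 "': not a number: '", x[bad[1]], "'")
  x2
}

check_enum_col <- function(x, allowed, path, col) {
  bad <- which(!x %in% allowed)
  if (length(bad))
    validation_error("'", path, "' line ", bad[1] + 1L, ", column '", col,
                     "': value '", x[bad[1]], "' not in {",
                     paste(allowed, collapse = ", "), "}")
  x
}

write_lines_utf8 <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# ---- events.csv ------------------------------------------------------------

#' Read and write task event records
#'
#' `events.csv` is the normative serialization of a session's typed event
#' stream (columns `t_ms, actor, kind, value, ref_id`). `kind` is one of
#' `pull`, `tone`, `reward`; `value` carries the reward volume in ml for
#' reward events and 0 otherwise; `ref_id` links a tone/reward back to the
#' pull (self-reward) or cooperation pair (mutual cooperation) that caused
#' it, and holds the pull's own identifier for pull events.
#'
#' @param path CSV file path.
#' @return `read_events` returns a validated `data.frame` with columns
#'   `t_ms` (integer), `actor`, `kind`, `value` (numeric), `ref_id`.
#' @export
read_events <- function(path) {
  df <- read_csv_strict(path, c("t_ms", "actor", "kind", "value", "ref_id"))
  out <- data.frame(
    t_ms = parse_int_col(df$t_ms, path, "t_ms"),
    actor = check_enum_col(df$actor, EVENT_ACTORS, path, "actor"),
    kind = check_enum_col(df$kind, EVENT_KINDS, path, "kind"),
    value = parse_num_col(df$value, path, "value"),
    ref_id = df$ref_id,
    stringsAsFactors = FALSE
  )
  if (any(out$t_ms < 0))
    validation_error("'", path, "': negative timestamps")
  if (any(out$value < 0))
    validation_error("'", path, "': negative reward volumes")
  out
}

#' @rdname read_events
#' @param events Event `data.frame` as returned by [read_events()] or
#'   produced by [run_session()].
#' @export
write_events <- function(events, path) {
  events <- canonicalize_events(events)
  lines <- c("t_ms,actor,kind,value,ref_id",
             paste(fmt_int(events$t_ms), events$actor, events$kind,
                   fmt_num(events$value), chr_or_empty(events$ref_id),
                   sep = ","))
  write_lines_utf8(lines, path)
}

# canonical order: time, then pull < tone < reward at equal times, then actor
canonicalize_events <- function(events) {
  if (!all(c("t_ms", "actor", "kind", "value", "ref_id") %in% names(events)))
    validation_error("events must have columns t_ms, actor, kind, value, ref_id")
  kind_rank <- match(events$kind, EVENT_KINDS)
  o <- order(events$t_ms, kind_rank, events$actor, events$ref_id)
  out <- events[o, c("t_ms", "actor", "kind", "value", "ref_id")]
  rownames(out) <- NULL
  out
}

# ---- lever.csv -------------------------------------------------------------

#' Read and write lever position traces
#'
#' `lever.csv` holds the potentiometer (position) and strain-gauge (force)
#' samples: columns `t_ms, actor, position, force_g`. Timestamps must be
#' strictly increasing within each actor; `force_g` may be empty (missing).
#'
#' @param path CSV file path.
#' @return `read_lever_trace` returns a `data.frame` with columns `t_ms`
#'   (integer), `actor`, `position` (numeric), `force_g` (numeric, `NA` when
#'   missing).
#' @export
read_lever_trace <- function(path) {
  df <- read_csv_strict(path, c("t_ms", "actor", "position", "force_g"))
  out <- data.frame(
    t_ms = parse_int_col(df$t_ms, path, "t_ms"),
    actor = check_enum_col(df$actor, ACTORS, path, "actor"),
    position = parse_num_col(df$position, path, "position"),
    force_g = parse_num_col(df$force_g, path, "force_g", allow_missing = TRUE),
    stringsAsFactors = FALSE
  )
  for (a in unique(out$actor)) {
    t <- out$t_ms[out$actor == a]
    if (any(diff(t) <= 0))
      validation_error("'", path, "': timestamps not strictly increasing for ",
                       a)
  }
  if (any(!is.na(out$force_g) & out$force_g < 0))
    validation_error("'", path, "': negative force")
  out
}

#' @rdname read_lever_trace
#' @param trace Lever trace `data.frame`.
#' @export
write_lever_trace <- function(trace, path) {
  o <- order(trace$t_ms, trace$actor)
  trace <- trace[o, ]
  lines <- c("t_ms,actor,position,force_g",
             paste(fmt_int(trace$t_ms), trace$actor, fmt_num(trace$position),
                   fmt_num(trace$force_g), sep = ","))
  write_lines_utf8(lines, path)
}

# ---- keypoints.csv ---------------------------------------------------------

#' Read and write 3D facial-keypoint trajectories
#'
#' Long-format CSV with columns `frame, t_ms, animal, keypoint, x, y, z,
#' confidence`: one row per (frame, animal, keypoint). The six keypoints per
#' head are the two ear tufts, two eyes, central blaze and mouth, in a
#' shared world frame in cm (right-handed axes assumed), as produced by
#' markerless 3D trackers. Keypoints whose tracker confidence falls below
#' `confidence_min` are marked missing (`NA` coordinates) — never silently
#' interpolated; the tracking literature filters by likelihood without
#' stating a cutoff, so the threshold is exposed as a reader parameter.
#'
#' @param path CSV file path.
#' @param confidence_min Confidence below which a keypoint is treated as
#'   missing. Default 0.6.
#' @return `read_keypoints` returns a `data.frame` with columns `frame`
#'   (integer), `t_ms` (integer), `animal`, `keypoint`, `x`, `y`, `z`,
#'   `confidence`; missing keypoints have `NA` coordinates.
#' @export
read_keypoints <- function(path, confidence_min = 0.6) {
  df <- read_csv_strict(path, c("frame", "t_ms", "animal", "keypoint",
                                "x", "y", "z", "confidence"))
  out <- data.frame(
    frame = parse_int_col(df$frame, path, "frame"),
    t_ms = parse_int_col(df$t_ms, path, "t_ms"),
    animal = check_enum_col(df$animal, ACTORS, path, "animal"),
    keypoint = check_enum_col(df$keypoint, KEYPOINT_NAMES, path, "keypoint"),
    x = parse_num_col(df$x, path, "x", allow_missing = TRUE),
    y = parse_num_col(df$y, path, "y", allow_missing = TRUE),
    z = parse_num_col(df$z, path, "z", allow_missing = TRUE),
    confidence = parse_num_col(df$confidence, path, "confidence"),
    stringsAsFactors = FALSE
  )
  if (any(out$confidence < 0 | out$confidence > 1))
    validation_error("'", path, "': confidence outside [0, 1]")
  key <- paste(out$frame, out$animal, out$keypoint)
  if (anyDuplicated(key))
    validation_error("'", path, "': duplicate (frame, animal, keypoint): ",
                     key[which(duplicated(key))[1]])
  low <- out$confidence < confidence_min
  out$x[low] <- NA_real_
  out$y[low] <- NA_real_
  out$z[low] <- NA_real_
  bad <- !is.na(out$x) & (!is.finite(out$x) | !is.finite(out$y) |
                            !is.finite(out$z))
  if (any(bad))
    validation_error("'", path, "': non-finite coordinates at frame ",
                     out$frame[which(bad)[1]])
  o <- order(out$animal, out$frame, match(out$keypoint, KEYPOINT_NAMES))
  out <- out[o, ]
  rownames(out) <- NULL
  out
}

#' @rdname read_keypoints
#' @param keypoints Keypoint `data.frame` (long format).
#' @export
write_keypoints <- function(keypoints, path) {
  o <- order(keypoints$animal, keypoints$frame,
             match(keypoints$keypoint, KEYPOINT_NAMES))
  kp <- keypoints[o, ]
  lines <- c("frame,t_ms,animal,keypoint,x,y,z,confidence",
             paste(fmt_int(kp$frame), fmt_int(kp$t_ms), kp$animal, kp$keypoint,
                   fmt_num(kp$x), fmt_num(kp$y), fmt_num(kp$z),
                   fmt_num(kp$confidence), sep = ","))
  write_lines_utf8(lines, path)
}

# ---- point_times.csv -------------------------------------------------------

#' Read and write labeled point-event times
#'
#' `point_times.csv` (columns `label, t_ms`) carries any labeled point
#' process: vocalization times by call type (chirp, trill, phee) or spike
#' times by unit id. Times must be strictly increasing within each label.
#'
#' @param path CSV file path.
#' @return `read_point_times` returns a `data.frame` with columns `label`,
#'   `t_ms` (integer), sorted by label then time.
#' @export
read_point_times <- function(path) {
  df <- read_csv_strict(path, c("label", "t_ms"))
  out <- data.frame(
    label = df$label,
    t_ms = parse_int_col(df$t_ms, path, "t_ms"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$label, out$t_ms), ]
  rownames(out) <- NULL
  for (l in unique(out$label)) {
    t <- out$t_ms[out$label == l]
    if (any(diff(t) <= 0))
      validation_error("'", path, "': times for label '", l,
                       "' not strictly increasing")
  }
  out
}

#' @rdname read_point_times
#' @param point_times `data.frame` with columns `label`, `t_ms`.
#' @export
write_point_times <- function(point_times, path) {
  pt <- point_times[order(point_times$label, point_times$t_ms), ]
  lines <- c("label,t_ms",
             paste(pt$label, fmt_int(pt$t_ms), sep = ","))
  write_lines_utf8(lines, path)
}
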