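#' Session log: the complete typed record of one session
#'
#' A `session_log` bundles the session configuration with the pull events,
#' cooperation pairs and the full event stream (pulls, tones, rewards) — the
#' interchange object between the task engine, the simulator and every
#' analysis. Pulls are rows of `pulls` (`pull_id, actor, t_ms,
#' peak_position, source`); pairs are rows of `pairs` (`pair_id, leader_id,
#' follower_id, t_leader_ms, t_follower_ms, latency_ms`).
#'
#' @param config A [session_config()].
#' @param pulls Pull-event `data.frame`.
#' @param pairs Cooperation-pair `data.frame` (may have zero rows).
#' @param events Event `data.frame` (`t_ms, actor, kind, value, ref_id`).
#' @param provenance Free-text origin note.
#' @return An object of class `session_log`.
#' @export
session_log <- function(config, pulls, pairs = empty_pairs(),
                        events = empty_events(), provenance = "") {
  log <- structure(list(
    config = validate_session_config(config),
    pulls = pulls,
    pairs = pairs,
    events = canonicalize_events(events),
    provenance = provenance
  ), class = "session_log")
  validate_session_log(log)
}

empty_pulls <- function() {
  data.frame(pull_id = character(), actor = character(), t_ms = integer(),
             peak_position = numeric(), source = character(),
             stringsAsFactors = FALSE)
}

empty_pairs <- function() {
  data.frame(pair_id = character(), leader_id = character(),
             follower_id = character(), t_leader_ms = integer(),
             t_follower_ms = integer(), latency_ms = integer(),
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(t_ms = integer(), actor = character(), kind = character(),
             value = numeric(), ref_id = character(), stringsAsFactors = FALSE)
}

#' Validate a session log
#'
#' Enforces the structural invariants: pull ids unique, timestamps within
#' the session, each pull in at most one pair, every reward's `ref_id`
#' resolving to a pull (self-reward) or a pair (mutual cooperation).
#'
#' @param log A `session_log`.
#' @return The validated log.
#' @export
validate_session_log <- function(log) {
  p <- log$pulls
  if (nrow(p)) {
    if (anyDuplicated(p$pull_id))
      validation_error("duplicate pull_id in session log")
    if (any(!p$actor %in% ACTORS))
      validation_error("pull actor outside {M1, M2}")
    if (any(p$t_ms < 0 | p$t_ms > log$config$session_duration_ms))
      validation_error("pull time outside [0, session_duration_ms]")
  }
  pr <- log$pairs
  if (nrow(pr)) {
    mem <- c(pr$leader_id, pr$follower_id)
    if (anyDuplicated(mem))
      validation_error("a pull belongs to more than one cooperation pair")
    if (!all(mem %in% p$pull_id))
      validation_error("pair references unknown pull_id")
    if (any(pr$latency_ms < 0))
      validation_error("negative pair latency")
  }
  ev <- log$events
  if (nrow(ev)) {
    if (any(!ev$kind %in% EVENT_KINDS))
      validation_error("event kind outside {pull, tone, reward}")
    rw <- ev[ev$kind == "reward", ]
    if (nrow(rw)) {
      ok <- rw$ref_id %in% c(p$pull_id, pr$pair_id)
      if (!all(ok))
        validation_error("reward ref_id '", rw$ref_id[which(!ok)[1]],
                         "' resolves to neither a pull nor a pair")
    }
  }
  log
}

#' Read / write a session log
#'
#' The event stream is the normative on-disk form (`events.csv`); pulls are
#' recovered from rows with `kind == "pull"` (whose `ref_id` carries the
#' pull id) and cooperation pairs from tone events (whose `ref_id` carries
#' the pair id `<leader_id>+<follower_id>`). Writing then re-reading a log
#' reproduces it exactly, and re-writing a read file is byte-identical to
#' the canonicalized original.
#'
#' @param events_path Path of `events.csv`.
#' @param config A [session_config()], or the path of its YAML file.
#' @return `read_session_log` returns a `session_log`.
#' @export
read_session_log <- function(events_path, config) {
  if (is.character(config)) config <- read_session_config(config)
  config <- validate_session_config(config)
  ev <- read_events(events_path)
  # rewards may legitimately land past session end (scheduled by the delay
  # and flagged truncated); all other events must lie within the session
  late <- ev$t_ms > config$session_duration_ms & ev$kind != "reward"
  if (any(late))
    validation_error("'", events_path, "': event time beyond session end")
  pu <- ev[ev$kind == "pull", ]
  pulls <- data.frame(
    pull_id = pu$ref_id, actor = pu$actor, t_ms = pu$t_ms,
    peak_position = rep(NA_real_, nrow(pu)),
    source = rep("given", nrow(pu)), stringsAsFactors = FALSE)
  pulls <- pulls[order(pulls$t_ms, pulls$actor), ]
  rownames(pulls) <- NULL
  for (a in ACTORS) {
    t <- pulls$t_ms[pulls$actor == a]
    if (any(diff(t) <= 0))
      validation_error("'", events_path,
                       "': pull times not strictly increasing for ", a)
  }
  pairs <- empty_pairs()
  tones <- ev[ev$kind == "tone", ]
  if (nrow(tones)) {
    ids <- strsplit(tones$ref_id, "+", fixed = TRUE)
    bad <- vapply(ids, length, integer(1)) != 2L
    if (any(bad))
      validation_error("'", events_path, "': malformed pair id '",
                       tones$ref_id[which(bad)[1]], "'")
    leader_id <- vapply(ids, `[`, character(1), 1L)
    follower_id <- vapply(ids, `[`, character(1), 2L)
    it_l <- match(leader_id, pulls$pull_id)
    it_f <- match(follower_id, pulls$pull_id)
    if (anyNA(it_l) || anyNA(it_f))
      validation_error("'", events_path, "': tone references unknown pull")
    pairs <- data.frame(
      pair_id = tones$ref_id, leader_id = leader_id,
      follower_id = follower_id,
      t_leader_ms = pulls$t_ms[it_l], t_follower_ms = pulls$t_ms[it_f],
      latency_ms = pulls$t_ms[it_f] - pulls$t_ms[it_l],
      stringsAsFactors = FALSE)
  }
  session_log(config, pulls, pairs, ev,
              provenance = paste0("read from ", basename(events_path)))
}

#' @rdname read_session_log
#' @param log A `session_log`.
#' @param path Output path for `events.csv`.
#' @export
write_session_log <- function(log, path) {
  validate_session_log(log)
  write_events(log$events, path)
}

#' @export
print.session_log <- function(x, ...) {
  cat("<session_log>", x$config$condition, "|",
      nrow(x$pulls), "pulls,", nrow(x$pairs), "pairs,",
      sum(x$events$kind == "reward"), "rewards\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}
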