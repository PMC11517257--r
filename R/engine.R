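# Task engine: the software equivalent of the apparatus control code.
# A pull registers when the lever position first passes the positional
# threshold (potentiometer reading); in the Mutual Cooperation condition a
# pair of pulls by the two animals within the cooperation window triggers
# the tone + delayed mutual reward.

#' Detect lever pulls from a position trace
#'
#' A pull registers at the first sample at or above `threshold` while the
#' lever is armed. After a pull the lever disarms and re-arms only once the
#' position falls to or below `rearm_fraction * threshold` (two-threshold
#' hysteresis, so noise oscillating about the threshold cannot register
#' chatter pulls). The lever starts armed if its first sample is below the
#' threshold. The pull timestamp is the first suprathreshold sample — the
#' observable a real-time controller reacts to — not the position peak.
#'
#' @param trace Lever trace `data.frame` with columns `t_ms`, `position`
#'   and optionally `actor` (`M1`/`M2`; traces are detected per actor).
#' @param threshold Position threshold (must exceed the resting position).
#' @param rearm_fraction Re-arm level as a fraction of `threshold`, in
#'   (0, 1). Default 0.5.
#' @return Pull-event `data.frame` (`pull_id, actor, t_ms, peak_position,
#'   source`), time-ordered; `source` is `"trace_detected"`.
#' @examples
#' tr <- data.frame(t_ms = 0:9 * 10L,
#'                  position = c(0, 0, .2, 1.2, 1.4, .8, .3, 0, 0, 0))
#' detect_pulls(tr, threshold = 1)
#' @export
detect_pulls <- function(trace, threshold, rearm_fraction = 0.5) {
  stopifnot_scalar_num(threshold, "threshold")
  stopifnot_scalar_num(rearm_fraction, "rearm_fraction", lower = 0, upper = 1,
                       open_lower = TRUE, open_upper = TRUE)
  if (is.null(trace$actor)) trace$actor <- "M1"
  out <- empty_pulls()
  for (a in sort(unique(trace$actor))) {
    tr <- trace[trace$actor == a, ]
    if (nrow(tr) == 0L) next
    if (any(diff(tr$t_ms) <= 0))
      validation_error("trace timestamps not strictly increasing for ", a)
    idx <- detect_crossings(tr$position, threshold,
                            rearm_fraction * threshold)
    if (length(idx)) {
      peaks <- vapply(seq_along(idx), function(i) {
        to <- if (i < length(idx)) idx[i + 1L] - 1L else nrow(tr)
        max(tr$position[idx[i]:to])
      }, numeric(1))
      out <- rbind(out, data.frame(
        pull_id = NA_character_, actor = a, t_ms = tr$t_ms[idx],
        peak_position = peaks, source = "trace_detected",
        stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$t_ms, out$actor), ]
  out$pull_id <- sprintf("p%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# Event-driven two-state scan: instead of walking every sample, walk only
# the upward threshold crossings and the downward re-arm crossings, keeping
# the armed/disarmed state. O(#crossings) after vectorized comparisons.
detect_crossings <- function(pos, threshold, rearm_level) {
  n <- length(pos)
  if (n == 0L) return(integer())
  above <- pos >= threshold
  low <- pos <= rearm_level
  up_idx <- which(above & !c(FALSE, above[-n]))      # first samples of runs >= thr
  dn_idx <- which(low & !c(FALSE, low[-n]))          # first samples of runs <= rearm
  ev_idx <- c(up_idx, dn_idx)
  ev_kind <- c(rep(1L, length(up_idx)), rep(2L, length(dn_idx)))
  o <- order(ev_idx, ev_kind)  # same-sample impossible (thr > rearm)
  ev_idx <- ev_idx[o]; ev_kind <- ev_kind[o]
  armed <- pos[1] < threshold
  pulls <- integer()
  for (k in seq_along(ev_idx)) {
    if (ev_kind[k] == 1L) {
      if (armed) { pulls <- c(pulls, ev_idx[k]); armed <- FALSE }
    } else {
      armed <- TRUE
    }
  }
  pulls
}

#' Pair cooperative pulls within the cooperation window
#'
#' Greedy chronological one-to-one matching, the policy a real-time
#' controller implements: scanning pulls in time order, a not-yet-matched
#' pull becomes the \emph{follower} of the earliest not-yet-matched pull by
#' the opposite actor whose time lies within `window_ms` before it (closed
#' interval, so a latency of exactly `window_ms` — or 0, for simultaneous
#' pulls — succeeds). Matched pulls are consumed: each pull belongs to at
#' most one pair. Simultaneous pulls are ordered M1-first, so the M1 pull is
#' designated leader at latency 0.
#'
#' @param pulls Pull-event `data.frame` (`pull_id, actor, t_ms, ...`).
#' @param window_ms Cooperation window in ms (> 0).
#' @param leader_preference `"earliest"` (default) or `"latest"` in-window
#'   unmatched leader.
#' @return A list with `pairs` (`pair_id, leader_id, follower_id,
#'   t_leader_ms, t_follower_ms, latency_ms`) and `unpaired` (the leftover
#'   pulls). The partition is exhaustive: `2 * nrow(pairs) + nrow(unpaired)
#'   == nrow(pulls)`.
#' @examples
#' p <- data.frame(pull_id = c("a", "b"), actor = c("M1", "M2"),
#'                 t_ms = c(2000L, 2800L))
#' pair_cooperative_pulls(p, window_ms = 1000)$pairs
#' @export
pair_cooperative_pulls <- function(pulls, window_ms,
                                   leader_preference = c("earliest", "latest")) {
  leader_preference <- match.arg(leader_preference)
  stopifnot_scalar_num(window_ms, "window_ms", lower = 0, open_lower = TRUE)
  if (anyDuplicated(pulls$pull_id))
    validation_error("duplicate pull_ids")
  if (any(!pulls$actor %in% ACTORS))
    validation_error("pull actor outside {M1, M2}")
  o <- order(pulls$t_ms, match(pulls$actor, ACTORS))
  pulls <- pulls[o, ]
  n <- nrow(pulls)
  matched <- logical(n)
  partner <- integer(n)  # follower i -> leader index
  t <- pulls$t_ms
  act <- pulls$actor
  for (i in seq_len(n)) {
    if (matched[i]) next
    cand <- which(!matched[seq_len(i - 1L)] &
                    act[seq_len(i - 1L)] != act[i] &
                    t[i] - t[seq_len(i - 1L)] <= window_ms)
    if (length(cand)) {
      j <- if (leader_preference == "earliest") cand[1L] else
        cand[length(cand)]
      matched[i] <- TRUE
      matched[j] <- TRUE
      partner[i] <- j
    }
  }
  fo <- which(partner > 0L)
  le <- partner[fo]
  pairs <- if (length(fo) == 0L) empty_pairs() else data.frame(
    pair_id = paste0(pulls$pull_id[le], "+", pulls$pull_id[fo]),
    leader_id = pulls$pull_id[le], follower_id = pulls$pull_id[fo],
    t_leader_ms = t[le], t_follower_ms = t[fo],
    latency_ms = t[fo] - t[le], stringsAsFactors = FALSE)
  unpaired <- pulls[!matched, ]
  rownames(pairs) <- NULL
  rownames(unpaired) <- NULL
  list(pairs = pairs, unpaired = unpaired)
}

#' Run a session: apply the reward contingency to pulls or a lever trace
#'
#' Converts the input into pull events (via [detect_pulls()] when a trace is
#' given) and applies the configured contingency:
#' \itemize{
#'   \item `self_reward`: every pull earns its actor one reward of
#'     `reward_volume_self_ml` at the pull time; the contingency is fully
#'     independent across the two animals.
#'   \item `mutual_cooperation`: pulls are paired with
#'     [pair_cooperative_pulls()]; each pair triggers a tone at the
#'     follower's pull time and one reward of `reward_volume_coop_ml` to
#'     each animal at follower time + `reward_delay_coop_ms`. Unpaired
#'     pulls generate nothing.
#' }
#' Rewards whose delivery time falls past the session end are still logged
#' (at their scheduled time) and counted in the `n_truncated_rewards`
#' attribute of the returned log.
#'
#' @param x Either a pull-event `data.frame` (`pull_id, actor, t_ms`, with
#'   ids generated when absent) or a lever trace (`t_ms, actor, position`).
#' @param config A [session_config()].
#' @return A [session_log()] with pulls, pairs (cooperation only) and the
#'   full event stream.
#' @examples
#' cfg <- session_config("mutual_cooperation", session_duration_ms = 10000)
#' pulls <- data.frame(actor = c("M1", "M2"), t_ms = c(4200L, 5000L))
#' log <- run_session(pulls, cfg)
#' subset(log$events, kind != "pull")
#' @export
run_session <- function(x, config) {
  config <- validate_session_config(config)
  if (!is.data.frame(x)) validation_error("input must be a data.frame")
  if ("position" %in% names(x)) {
    pulls <- detect_pulls(x, config$position_threshold, config$rearm_fraction)
  } else {
    pulls <- x
    if (!all(c("actor", "t_ms") %in% names(pulls)))
      validation_error("pulls need columns actor, t_ms")
    if (is.null(pulls$pull_id) || all(is.na(pulls$pull_id)))
      pulls$pull_id <- sprintf("p%04d", seq_len(nrow(pulls)))
    if (is.null(pulls$peak_position))
      pulls$peak_position <- rep(NA_real_, nrow(pulls))
    if (is.null(pulls$source)) pulls$source <- rep("given", nrow(pulls))
    pulls <- pulls[, c("pull_id", "actor", "t_ms", "peak_position", "source")]
  }
  if (any(pulls$t_ms < 0 | pulls$t_ms > config$session_duration_ms))
    validation_error("pull outside session duration")
  o <- order(pulls$t_ms, match(pulls$actor, ACTORS))
  pulls <- pulls[o, ]
  rownames(pulls) <- NULL

  if (config$lockout_ms > 0) pulls <- apply_lockout(pulls, config)

  np <- nrow(pulls)
  ev_pull <- data.frame(t_ms = pulls$t_ms, actor = pulls$actor,
                        kind = rep("pull", np), value = rep(0, np),
                        ref_id = pulls$pull_id, stringsAsFactors = FALSE)
  n_trunc <- 0L
  if (config$condition == "self_reward") {
    pairs <- empty_pairs()
    ev_rew <- data.frame(t_ms = pulls$t_ms, actor = pulls$actor,
                         kind = rep("reward", np),
                         value = rep(config$reward_volume_self_ml, np),
                         ref_id = pulls$pull_id, stringsAsFactors = FALSE)
    events <- rbind(ev_pull, ev_rew)
  } else {
    res <- pair_cooperative_pulls(pulls, config$coop_window_ms,
                                  config$leader_preference)
    pairs <- res$pairs
    t_rew <- pairs$t_follower_ms + config$reward_delay_coop_ms
    n_trunc <- sum(rep(t_rew, each = 2L) > config$session_duration_ms)
    npair <- nrow(pairs)
    ev_tone <- data.frame(t_ms = pairs$t_follower_ms,
                          actor = rep("system", npair),
                          kind = rep("tone", npair), value = rep(0, npair),
                          ref_id = pairs$pair_id, stringsAsFactors = FALSE)
    ev_rew <- data.frame(
      t_ms = rep(t_rew, each = 2L),
      actor = rep(ACTORS, times = npair),
      kind = rep("reward", 2L * npair),
      value = rep(config$reward_volume_coop_ml, 2L * npair),
      ref_id = rep(pairs$pair_id, each = 2L), stringsAsFactors = FALSE)
    events <- rbind(ev_pull, ev_tone, ev_rew)
  }
  log <- session_log(config, pulls, pairs, events,
                     provenance = "run_session")
  attr(log, "n_truncated_rewards") <- n_trunc
  log
}

# optional post-reward refractory: drop pulls within lockout_ms after a
# rewarded pull by the same actor
apply_lockout <- function(pulls, config) {
  keep <- rep(TRUE, nrow(pulls))
  for (a in ACTORS) {
    idx <- which(pulls$actor == a)
    last <- -Inf
    for (i in idx) {
      if (pulls$t_ms[i] - last < config$lockout_ms) keep[i] <- FALSE
      else last <- pulls$t_ms[i]
    }
  }
  pulls[keep, ]
}
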