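# Session-level performance metrics. Undefined values (no pulls, zero
# working time, a missing actor) are explicit NA, never 0, and serialize
# as JSON nulls.

#' Success rate of a session
#'
#' Number of successful lever pulls divided by the total number of lever
#' pulls in the session, pooling both animals. In the mutual-cooperation
#' condition both members of a cooperation pair count as successful, so the
#' rate is `2 * n_pairs / n_pulls`; dyads are conventionally called
#' proficient once this exceeds 0.5. In the self-reward condition every
#' registered pull is by definition successful (event-level logs), so the
#' rate is 1. Undefined (`NA`) when there are no pulls.
#'
#' @param log A [session_log()].
#' @return A single numeric in `[0, 1]`, or `NA` when no pulls occurred.
#' @examples
#' cfg <- session_config("mutual_cooperation", session_duration_ms = 20000)
#' pulls <- data.frame(actor = c("M1", "M2", "M1"),
#'                     t_ms = c(1000L, 1400L, 9000L))
#' success_rate(run_session(pulls, cfg))  # 2/3
#' @export
success_rate <- function(log) {
  n <- nrow(log$pulls)
  if (n == 0L) return(NA_real_)
  if (log$config$condition == "self_reward") return(1)
  2 * nrow(log$pairs) / n
}

#' Rewards earned per working minute
#'
#' The average number of rewards earned per 60 s of active task engagement.
#' Working time is the cumulative session time during which a lever pull
#' occurred within the trailing `activity_window_ms` (default 30 s): the
#' measure of the union of intervals `[t_pull, t_pull + window]`, clipped
#' to the session, pooling pulls from both animals. The rate is
#' `n_rewards * 60000 / working_time_ms`, counting all reward deliveries in
#' the log (dyadic count: a successful cooperation delivers two rewards).
#'
#' @param log A [session_log()].
#' @param activity_window_ms Trailing activity window in ms; default 30000.
#' @param window_side Where the window sits relative to each moment of
#'   working time: `"trailing"` (default; a time counts as working if a
#'   pull occurred within the previous 30 s), `"leading"`, or `"centered"`.
#' @param per_actor Optional actor (`"M1"`/`"M2"`): restrict both the pulls
#'   defining working time and the rewards counted to that animal.
#' @return List with `rate` (rewards/min; `NA` when working time is 0) and
#'   `working_time_ms`.
#' @export
rewards_per_working_minute <- function(log, activity_window_ms = 30000,
                                       window_side = c("trailing", "leading",
                                                       "centered"),
                                       per_actor = NULL) {
  window_side <- match.arg(window_side)
  pulls <- log$pulls
  rewards <- log$events[log$events$kind == "reward", ]
  if (!is.null(per_actor)) {
    pulls <- pulls[pulls$actor == per_actor, ]
    rewards <- rewards[rewards$actor == per_actor, ]
  }
  w <- activity_window_ms
  iv <- switch(window_side,
               trailing = cbind(pulls$t_ms, pulls$t_ms + w),
               leading = cbind(pulls$t_ms - w, pulls$t_ms),
               centered = cbind(pulls$t_ms - w / 2, pulls$t_ms + w / 2))
  wt <- interval_union_measure(iv, 0, log$config$session_duration_ms)
  rate <- if (wt > 0) nrow(rewards) * 60000 / wt else NA_real_
  list(rate = rate, working_time_ms = wt)
}

# total measure of the union of [lo_i, hi_i], clipped to [clip_lo, clip_hi]
interval_union_measure <- function(iv, clip_lo, clip_hi) {
  if (is.null(iv) || nrow(iv) == 0L) return(0)
  lo <- pmax(iv[, 1], clip_lo)
  hi <- pmin(iv[, 2], clip_hi)
  keep <- hi > lo
  if (!any(keep)) return(0)
  lo <- lo[keep]; hi <- hi[keep]
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  total <- 0
  cur_lo <- lo[1]; cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= cur_hi) {
      cur_hi <- max(cur_hi, hi[i])
    } else {
      total <- total + (cur_hi - cur_lo)
      cur_lo <- lo[i]; cur_hi <- hi[i]
    }
  }
  total + (cur_hi - cur_lo)
}

#' Mean inter-pull time between the two animals
#'
#' The average time separating one animal's pulls from the partner's pulls
#' in a session. Two definitions are available:
#' \describe{
#'   \item{`nearest_partner`}{(default) mean over \emph{all} pulls of the
#'     absolute time to the nearest opposite-actor pull — failed pulls
#'     included, and symmetric under swapping the actor labels.}
#'   \item{`paired_only`}{mean leader-to-follower latency over cooperation
#'     pairs only.}
#' }
#'
#' @param log A [session_log()].
#' @param mode `"nearest_partner"` or `"paired_only"`.
#' @return Mean inter-pull time in ms; `NA` when undefined (an actor with
#'   no pulls, or no pairs in `paired_only` mode).
#' @export
inter_pull_time <- function(log, mode = c("nearest_partner", "paired_only")) {
  mode <- match.arg(mode)
  if (mode == "paired_only") {
    if (nrow(log$pairs) == 0L) return(NA_real_)
    return(mean(log$pairs$latency_ms))
  }
  t1 <- log$pulls$t_ms[log$pulls$actor == "M1"]
  t2 <- log$pulls$t_ms[log$pulls$actor == "M2"]
  if (length(t1) == 0L || length(t2) == 0L) return(NA_real_)
  mean(c(nearest_dist(t1, t2), nearest_dist(t2, t1)))
}

# for each a: distance to the nearest element of sorted b
nearest_dist <- function(a, b) {
  b <- sort(b)
  i <- findInterval(a, b)
  lo <- ifelse(i >= 1L, abs(a - b[pmax(i, 1L)]), Inf)
  hi <- ifelse(i < length(b), abs(b[pmin(i + 1L, length(b))] - a), Inf)
  pmin(lo, hi)
}

#' All session metrics at once
#'
#' @param log A [session_log()].
#' @param activity_window_ms Passed to [rewards_per_working_minute()].
#' @return An object of class `session_metrics`: `n_pulls_total`,
#'   `n_pulls_successful`, `n_pulls_unsuccessful`, `success_rate`,
#'   `rewards_per_working_minute`, `working_time_ms`,
#'   `mean_inter_pull_time_ms`, `condition`.
#' @export
session_metrics <- function(log, activity_window_ms = 30000) {
  n <- nrow(log$pulls)
  n_succ <- if (log$config$condition == "self_reward") n else
    2L * nrow(log$pairs)
  rw <- rewards_per_working_minute(log, activity_window_ms)
  structure(list(
    condition = log$config$condition,
    n_pulls_total = n,
    n_pulls_successful = n_succ,
    n_pulls_unsuccessful = n - n_succ,
    success_rate = success_rate(log),
    rewards_per_working_minute = rw$rate,
    working_time_ms = rw$working_time_ms,
    mean_inter_pull_time_ms = inter_pull_time(log)
  ), class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat("<session_metrics>", x$condition, "\n")
  cat(sprintf("  pulls: %d (%d successful, %d unsuccessful)\n",
              x$n_pulls_total, x$n_pulls_successful, x$n_pulls_unsuccessful))
  cat(sprintf("  success rate: %s\n", format(x$success_rate, digits = 3)))
  cat(sprintf("  rewards/working min: %s (working time %.1f s)\n",
              format(x$rewards_per_working_minute, digits = 3),
              x$working_time_ms / 1000))
  cat(sprintf("  mean inter-pull time: %s ms\n",
              format(x$mean_inter_pull_time_ms, digits = 4)))
  invisible(x)
}

#' Write session metrics as JSON
#'
#' Undefined metrics are serialized as JSON `null`, never 0 or `"NaN"`.
#' @param metrics A `session_metrics`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  x <- unclass(metrics)
  x <- c(list(schema = "marmopull/metrics/v1"), x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}
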