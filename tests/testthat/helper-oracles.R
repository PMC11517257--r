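# Independent brute-force oracles. Each re-derives an operation's answer by
# the most literal method available (per-sample scans, O(n^2) loops, 1 ms
# grids, exhaustive permutations) with no code shared with the package
# implementation.

# per-sample two-state scan over a lever position vector
oracle_detect_idx <- function(pos, threshold, rearm_fraction = 0.5) {
  armed <- pos[1] < threshold
  hits <- integer()
  for (i in seq_along(pos)) {
    if (armed && pos[i] >= threshold) {
      hits <- c(hits, i)
      armed <- FALSE
    } else if (!armed && pos[i] <= rearm_fraction * threshold) {
      armed <- TRUE
    }
  }
  hits
}

# exhaustive greedy pairing: repeatedly find, among all remaining pulls in
# chronological order, the next follower and its preferred leader
oracle_pair_greedy <- function(pulls, window_ms,
                               leader_preference = "earliest") {
  o <- order(pulls$t_ms, match(pulls$actor, c("M1", "M2")))
  pulls <- pulls[o, ]
  n <- nrow(pulls)
  taken <- rep(FALSE, n)
  leaders <- integer(0); followers <- integer(0)
  for (i in seq_len(n)) {
    if (taken[i]) next
    best <- NA_integer_
    for (j in seq_len(n)) {
      if (j >= i) break
      if (taken[j]) next
      if (pulls$actor[j] == pulls$actor[i]) next
      lat <- pulls$t_ms[i] - pulls$t_ms[j]
      if (lat < 0 || lat > window_ms) next
      if (is.na(best)) best <- j
      else if (leader_preference == "earliest") {
        # j scanned in increasing order: keep the first
      } else best <- j
    }
    if (!is.na(best)) {
      taken[i] <- TRUE; taken[best] <- TRUE
      leaders <- c(leaders, best); followers <- c(followers, i)
    }
  }
  data.frame(leader_id = pulls$pull_id[leaders],
             follower_id = pulls$pull_id[followers],
             latency_ms = pulls$t_ms[followers] - pulls$t_ms[leaders],
             stringsAsFactors = FALSE)
}

# working time by 1 ms grid scan: a millisecond t counts if some pull
# occurred in [t - window, t]
oracle_working_time_grid <- function(pull_t, window_ms, duration_ms) {
  grid <- rep(FALSE, duration_ms)
  for (tp in pull_t) {
    lo <- max(tp, 0)
    hi <- min(tp + window_ms, duration_ms)
    if (hi > lo) grid[(lo + 1L):hi] <- TRUE  # grid[k] covers (k-1, k]
  }
  sum(grid)
}

oracle_nearest_partner_mean <- function(t1, t2) {
  d <- c(vapply(t1, function(a) min(abs(a - t2)), numeric(1)),
         vapply(t2, function(a) min(abs(a - t1)), numeric(1)))
  mean(d)
}

# exhaustive permutation distribution of the rank-sum statistic
oracle_permutation_ranksum <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); N <- n1 + length(y)
  mu <- n1 * (N + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  combos <- utils::combn(N, n1)
  perm <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(perm - mu) >= obs - 1e-9)
}

# per-trial loop over raw (unsorted) times with explicit interval tests
oracle_align_counts <- function(times_ms, events_ms, cfg) {
  centers <- seq(-cfg$window_pre_ms + cfg$bin_ms / 2,
                 cfg$window_post_ms - cfg$bin_ms / 2, by = cfg$step_ms)
  m <- matrix(0L, length(events_ms), length(centers))
  for (i in seq_along(events_ms)) {
    rel <- times_ms - events_ms[i]
    for (j in seq_along(centers)) {
      lo <- centers[j] - cfg$bin_ms / 2
      hi <- centers[j] + cfg$bin_ms / 2
      m[i, j] <- sum(rel >= lo & rel < hi)
    }
  }
  m
}

# regex bout oracle: encode the stream as one character per frame (gaps as
# '.') and, per target, match maximal runs of that character bridged by at
# most max_gap_frames dots
oracle_bouts <- function(labels, min_bout_frames = 3, max_gap_frames = 1) {
  labels[is.na(labels)] <- "none"
  targets <- setdiff(unique(labels), "none")
  codes <- LETTERS[seq_along(targets)]
  chars <- ifelse(labels == "none", ".", codes[match(labels, targets)])
  s <- paste(chars, collapse = "")
  out <- list()
  for (k in seq_along(targets)) {
    pat <- if (max_gap_frames > 0)
      sprintf("%s(?:[.]{1,%d}%s|%s)*", codes[k], max_gap_frames,
              codes[k], codes[k])
    else sprintf("%s+", codes[k])
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    keep <- len >= min_bout_frames
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        target = targets[k], start_frame = as.integer(m[keep]) - 1L,
        end_frame = as.integer(m[keep]) + len[keep] - 2L,
        stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(target = character(),
                                      start_frame = integer(),
                                      end_frame = integer()))
  out <- do.call(rbind, out)
  out[order(out$start_frame), ]
}

# random rigid transform (rotation + translation)
random_rigid_transform <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  list(R = R, t = stats::rnorm(3, 0, 20))
}

apply_rigid_points <- function(tf, pts) {
  t(tf$R %*% t(pts)) + rep(tf$t, each = nrow(pts))
}

# random pull set: n pulls, random actors and times on [0, t_max]
random_pull_set <- function(n, t_max = 60000) {
  t <- sort(sample.int(t_max, n, replace = TRUE))
  data.frame(pull_id = sprintf("r%03d", seq_len(n)),
             actor = sample(c("M1", "M2"), n, replace = TRUE),
             t_ms = as.integer(t), stringsAsFactors = FALSE)
}

# random event log for round-trip tests (self-reward style)
random_session_log <- function(seed, duration_ms = 120000L) {
  set.seed(seed)
  n <- sample(1:40, 1)
  pulls <- random_pull_set(n, duration_ms)
  pulls <- pulls[!duplicated(paste(pulls$actor, pulls$t_ms)), ]
  cond <- sample(c("self_reward", "mutual_cooperation"), 1)
  cfg <- session_config(cond, session_duration_ms = duration_ms,
                        rng_seed = seed)
  run_session(pulls, cfg)
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# one-row pose data.frame for a template head placed at (R, origin)
head_poses_from_template <- function(R, origin) {
  tmpl <- marmopull:::canonical_head()
  pts <- t(R %*% t(tmpl)) + rep(origin, each = nrow(tmpl))
  rownames(pts) <- rownames(tmpl)
  hp <- head_pose(pts)
  data.frame(frame = 0L, t_ms = 0L, animal = "M1",
             ox = hp$origin[1], oy = hp$origin[2], oz = hp$origin[3],
             fx = hp$forward[1], fy = hp$forward[2], fz = hp$forward[3],
             valid = hp$valid, reason = hp$reason, stringsAsFactors = FALSE)
}
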