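square_trace <- function(pos, dt = 10L) {
  data.frame(t_ms = seq_along(pos) * dt - dt,
             actor = rep("M1", length(pos)), position = pos)
}

test_that("a square pulse yields exactly one pull at the first suprathreshold sample", {
  tr <- square_trace(c(0, 0, 0, 1.3, 1.4, 1.2, 0.2, 0, 0))
  p <- detect_pulls(tr, threshold = 1)
  expect_equal(nrow(p), 1L)
  expect_equal(p$t_ms, 30L)
  expect_equal(p$peak_position, 1.4)
})

test_that("hysteresis: oscillation about the threshold without re-arming is one pull", {
  # wobbles around 1.0 but never drops to the 0.5 re-arm level
  tr <- square_trace(c(0, 0.2, 1.05, 0.95, 1.1, 0.9, 1.2, 0.6, 1.3, 0.2, 0))
  p <- detect_pulls(tr, threshold = 1, rearm_fraction = 0.5)
  expect_equal(nrow(p), 1L)
  expect_equal(p$t_ms, 20L)
  # dropping below re-arm in between gives two pulls
  tr2 <- square_trace(c(0, 1.2, 0.3, 1.2, 0))
  expect_equal(nrow(detect_pulls(tr2, 1)), 2L)
})

test_that("empty and invalid traces are handled", {
  expect_equal(nrow(detect_pulls(square_trace(numeric()), 1)), 0L)
  bad <- data.frame(t_ms = c(10L, 5L), actor = "M1", position = c(0, 1))
  expect_error(detect_pulls(bad, 1), class = "mp_validation_error")
})

test_that("pull detection matches the per-sample scan oracle on random traces", {
  set.seed(71)
  for (k in 1:200) {
    n <- sample(200:800, 1)
    # random smooth-ish walk clipped to a plausible lever range
    pos <- cumsum(rnorm(n, 0, 0.25))
    pos <- pmax(pmin(pos, 2), 0)
    tr <- square_trace(pos, dt = 4L)
    rf <- runif(1, 0.2, 0.8)
    got <- detect_pulls(tr, threshold = 1, rearm_fraction = rf)
    want <- oracle_detect_idx(pos, 1, rf)
    expect_identical(got$t_ms, tr$t_ms[want])
  }
})

test_that("cooperation pairing follows the 1 s rule and the greedy tie-break", {
  p2 <- function(t1, t2) data.frame(pull_id = c("a", "b"),
                                    actor = c("M1", "M2"),
                                    t_ms = as.integer(c(t1, t2)))
  r <- pair_cooperative_pulls(p2(2000, 2800), 1000)
  expect_equal(nrow(r$pairs), 1L)
  expect_equal(r$pairs$latency_ms, 800L)
  r <- pair_cooperative_pulls(p2(2000, 3500), 1000)
  expect_equal(nrow(r$pairs), 0L)
  expect_equal(nrow(r$unpaired), 2L)
  # latency exactly at the window boundary succeeds (closed interval)
  r <- pair_cooperative_pulls(p2(2000, 3000), 1000)
  expect_equal(r$pairs$latency_ms, 1000L)
  # greedy earliest-leader: M2@950 pairs with M1@0, not M1@900
  p3 <- data.frame(pull_id = c("a", "b", "c"), actor = c("M1", "M1", "M2"),
                   t_ms = c(0L, 900L, 950L))
  r <- pair_cooperative_pulls(p3, 1000)
  expect_equal(r$pairs$leader_id, "a")
  expect_equal(r$pairs$latency_ms, 950L)
  expect_equal(r$unpaired$pull_id, "b")
  # latest-leader alternative
  r <- pair_cooperative_pulls(p3, 1000, leader_preference = "latest")
  expect_equal(r$pairs$leader_id, "b")
  # simultaneous pulls: M1 is leader, latency 0 is a success
  r <- pair_cooperative_pulls(p2(500, 500), 1000)
  expect_equal(r$pairs$leader_id, "a")
  expect_equal(r$pairs$latency_ms, 0L)
  expect_error(pair_cooperative_pulls(
    data.frame(pull_id = c("a", "a"), actor = c("M1", "M2"),
               t_ms = c(1L, 2L)), 1000), class = "mp_validation_error")
})

test_that("pairing equals the exhaustive O(n^2) oracle and conserves pulls", {
  set.seed(72)
  for (k in 1:200) {
    pulls <- random_pull_set(sample(0:50, 1), t_max = 30000)
    pulls <- pulls[!duplicated(paste(pulls$actor, pulls$t_ms)), ]
    pref <- sample(c("earliest", "latest"), 1)
    got <- pair_cooperative_pulls(pulls, 1000, leader_preference = pref)
    want <- oracle_pair_greedy(pulls, 1000, pref)
    expect_equal(got$pairs$leader_id, want$leader_id)
    expect_equal(got$pairs$follower_id, want$follower_id)
    expect_equal(2L * nrow(got$pairs) + nrow(got$unpaired), nrow(pulls))
  }
})

test_that("enlarging the window never decreases the number of pairs", {
  set.seed(73)
  for (k in 1:50) {
    pulls <- random_pull_set(sample(2:40, 1), t_max = 20000)
    pulls <- pulls[!duplicated(paste(pulls$actor, pulls$t_ms)), ]
    n_prev <- -1L
    for (w in c(250, 500, 1000, 2000, 4000)) {
      n <- nrow(pair_cooperative_pulls(pulls, w)$pairs)
      expect_gte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("self-reward: one actor-matched reward per pull at pull time", {
  cfg <- session_config("self_reward", session_duration_ms = 60000)
  pulls <- data.frame(actor = c("M1", "M1", "M1", "M2", "M2"),
                      t_ms = c(1000L, 5000L, 9000L, 2000L, 7000L))
  log <- run_session(pulls, cfg)
  rw <- log$events[log$events$kind == "reward", ]
  expect_equal(nrow(rw), 5L)
  expect_equal(rw$value, rep(0.1, 5))
  expect_equal(rw$t_ms, sort(pulls$t_ms))
  # actor-matched: the reward goes to the puller
  m <- merge(rw, log$pulls, by.x = "ref_id", by.y = "pull_id")
  expect_equal(m$actor.x, m$actor.y)
  expect_equal(nrow(log$pairs), 0L)
  expect_equal(sum(log$events$kind == "tone"), 0L)
})

test_that("mutual cooperation: tone at follower time, two 0.2 ml rewards 1 s later", {
  cfg <- session_config("mutual_cooperation", session_duration_ms = 20000)
  pulls <- data.frame(actor = c("M1", "M2"), t_ms = c(4300L, 5000L))
  log <- run_session(pulls, cfg)
  tone <- log$events[log$events$kind == "tone", ]
  rw <- log$events[log$events$kind == "reward", ]
  expect_equal(tone$t_ms, 5000L)
  expect_equal(tone$actor, "system")
  expect_equal(rw$t_ms, c(6000L, 6000L))
  expect_setequal(rw$actor, c("M1", "M2"))
  expect_equal(rw$value, c(0.2, 0.2))
  expect_equal(unique(rw$ref_id), log$pairs$pair_id)
})

test_that("mutual cooperation with zero pairs produces zero tones and rewards", {
  cfg <- session_config("mutual_cooperation", session_duration_ms = 20000)
  pulls <- data.frame(actor = c("M1", "M2"), t_ms = c(1000L, 9000L))
  log <- run_session(pulls, cfg)
  expect_equal(sum(log$events$kind != "pull"), 0L)
  expect_equal(success_rate(log), 0)
})

test_that("rewards scheduled past session end are logged and flagged truncated", {
  cfg <- session_config("mutual_cooperation", session_duration_ms = 10000)
  pulls <- data.frame(actor = c("M1", "M2"), t_ms = c(9200L, 9800L))
  log <- run_session(pulls, cfg)
  rw <- log$events[log$events$kind == "reward", ]
  expect_equal(rw$t_ms, c(10800L, 10800L))
  expect_equal(attr(log, "n_truncated_rewards"), 2L)
})

test_that("identical inputs produce byte-identical session logs", {
  pulls <- simulate_pulls(dyad_preset()$m1, dyad_preset()$m2, 300000, seed = 5)
  cfg <- session_config("mutual_cooperation", session_duration_ms = 300000)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_session_log(run_session(pulls, cfg), f1)
  write_session_log(run_session(pulls, cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
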