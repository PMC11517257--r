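cfg_fig <- peri_event_config(window_pre_ms = 1000, window_post_ms = 1000,
                             bin_ms = 150, step_ms = 50)

test_that("a point at the event time lands in the three bins covering lag 0", {
  m <- align_events(times_ms = 5000L, events_ms = 5000L, cfg_fig)
  centers <- bin_centers(cfg_fig)
  hit <- which(m[1, ] == 1L)
  expect_equal(centers[hit], c(-25, 25, 75))  # [lo, hi) bins containing 0
  expect_true(all(m[1, -hit] == 0L))
  # boundary: a point at exactly lag +75 belongs to the bin starting there
  m2 <- align_events(5075L, 5000L, cfg_fig)
  expect_equal(centers[which(m2[1, ] == 1L)], c(25, 75, 125))
})

test_that("no points and no events degenerate gracefully", {
  m <- align_events(integer(), c(1000L, 2000L), cfg_fig)
  expect_true(all(m == 0L))
  expect_equal(dim(m), c(2L, length(bin_centers(cfg_fig))))
  m0 <- align_events(c(100L, 200L), integer(), cfg_fig)
  expect_equal(nrow(m0), 0L)
  expect_error(psth(m0), class = "mp_validation_error")
})

test_that("alignment equals the brute-force per-trial loop oracle", {
  set.seed(101)
  for (k in 1:20) {
    dur <- 60000
    pts <- synthesize_point_times(8, NULL, integer(), dur, seed = 2000 + k)
    ev <- sort(sample.int(dur, 15))
    cfg <- peri_event_config(window_pre_ms = sample(c(500, 1000), 1),
                             window_post_ms = 1000,
                             bin_ms = sample(c(100, 150), 1), step_ms = 50)
    got <- align_events(pts$t_ms, ev, cfg)
    want <- oracle_align_counts(pts$t_ms, ev, cfg)
    expect_equal(unname(unclass(got))[, ], want[, ],
                 ignore_attr = TRUE)
  }
})

test_that("at step = bin the row sums conserve the in-window point count", {
  cfg <- peri_event_config(window_pre_ms = 900, window_post_ms = 900,
                           bin_ms = 150, step_ms = 150)
  set.seed(102)
  pts <- sort(sample.int(50000, 400))
  ev <- seq(5000, 45000, by = 5000)
  m <- align_events(pts, ev, cfg)
  for (i in seq_along(ev)) {
    rel <- pts - ev[i]
    expect_equal(sum(m[i, ]), sum(rel >= -900 & rel < 900))
  }
})

test_that("results are equivariant under a common time shift", {
  set.seed(103)
  pts <- sort(sample.int(40000, 200))
  ev <- seq(3000, 37000, by = 4000)
  m1 <- align_events(pts, ev, cfg_fig)
  m2 <- align_events(pts + 12345L, ev + 12345L, cfg_fig)
  expect_equal(unname(m1[, ]), unname(m2[, ]))
})

test_that("psth converts counts to rates with s.e.m. across trials", {
  cfg <- peri_event_config(window_pre_ms = 300, window_post_ms = 300,
                           bin_ms = 150, step_ms = 150)
  m <- matrix(c(3L, 1L, 0L, 2L, 1L, 3L, 0L, 2L), 2, 4, byrow = TRUE)
  r <- psth(m, cfg)
  expect_equal(r$mean_rate, colMeans(m) / 0.15)
  expect_equal(r$sem, apply(m / 0.15, 2, sd) / sqrt(2))
  # single trial: s.e.m. 0 by convention
  r1 <- psth(m[1, , drop = FALSE], cfg)
  expect_equal(r1$sem, rep(0, 4))
  expect_equal(r1$n_trials, 1L)
})

test_that("homogeneous Poisson PSTH recovers the true rate within 3 sem", {
  ev <- seq(3000, by = 3000, length.out = 200)
  dur <- max(ev) + 3000
  pts <- synthesize_point_times(5, NULL, integer(), dur, seed = 104)
  m <- align_events(pts$t_ms, ev, cfg_fig, dur)
  r <- psth(m)
  covered <- abs(r$mean_rate - 5) <= 3 * pmax(r$sem, 1e-9)
  expect_gte(mean(covered), 0.99)
})

test_that("an injected rate step at +200 ms puts the PSTH peak within one step", {
  ev <- seq(5000, by = 4000, length.out = 150)
  dur <- max(ev) + 4000
  mod <- data.frame(lag_lo_ms = 200, lag_hi_ms = 700, rate_hz = 10)
  pts <- synthesize_point_times(1, mod, ev, dur, seed = 105)
  m <- align_events(pts$t_ms, ev, cfg_fig, dur)
  r <- psth(m)
  onset_bins <- r$bin_centers_ms[r$mean_rate > (1 + 10) / 2]
  # first elevated bin center should sit at the step onset + half a bin
  expect_lte(abs(min(onset_bins) - (200 + 75)), cfg_fig$step_ms)
})

test_that("rank-sum test: conventions, ties, and agreement with wilcox.test", {
  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2)), 1)
  # identical multisets: z = 0 exactly, p = 1
  expect_equal(rank_sum_test(c(0, 1, 1, 3), c(0, 1, 1, 3)), 1)
  # tie-corrected normal approximation matches wilcox.test without
  # continuity correction
  set.seed(106)
  for (k in 1:50) {
    x <- rpois(30, 2); y <- rpois(25, 3)
    got <- rank_sum_test(x, y, method = "normal")
    want <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = FALSE))$p.value
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("small-sample p-values equal the exhaustive permutation oracle", {
  set.seed(107)
  for (k in 1:100) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rpois(n1, 1.5); y <- rpois(n2, sample(c(1.5, 4), 1))
    if (max(c(x, y)) == min(c(x, y))) next
    got <- rank_sum_test(x, y)  # auto: exact path at these sizes
    want <- oracle_permutation_ranksum(x, y)
    expect_lt(abs(got - want), 0.01)
  }
})

test_that("identical count matrices yield no significant bins", {
  set.seed(108)
  m <- matrix(rpois(5 * 10, 2), 5, 10)
  cfg <- peri_event_config(window_pre_ms = 250, window_post_ms = 250,
                           bin_ms = 50, step_ms = 50)
  cc <- compare_conditions(m, m, cfg)
  expect_true(all(cc$p_value == 1))
  expect_false(any(cc$significant))
})

test_that("a localized 3x rate elevation is flagged in the right bins", {
  ev_a <- seq(5000, by = 4000, length.out = 100)
  ev_b <- seq(5000, by = 4000, length.out = 100)
  dur <- max(ev_a) + 4000
  mod <- data.frame(lag_lo_ms = 0, lag_hi_ms = 500, rate_hz = 6)
  inside <- outside <- numeric(0)
  for (s in 1:5) {
    a <- synthesize_point_times(2, mod, ev_a, dur, seed = 300 + s)
    b <- synthesize_point_times(2, NULL, integer(), dur, seed = 400 + s)
    ma <- align_events(a$t_ms, ev_a, cfg_fig, dur)
    mb <- align_events(b$t_ms, ev_b, cfg_fig, dur)
    cc <- compare_conditions(ma, mb, cfg_fig)
    in_bin <- cc$bin_center_ms - 75 >= 0 & cc$bin_center_ms + 75 <= 500
    inside <- c(inside, mean(cc$significant[in_bin]))
    outside <- c(outside, mean(cc$significant[cc$bin_center_ms < -200]))
  }
  expect_gte(mean(inside), 0.9)   # strong power inside the elevated window
  expect_lte(mean(outside), 0.15) # outside stays near the uncorrected alpha
})

test_that("Benjamini-Hochberg option only removes significance", {
  set.seed(109)
  ma <- matrix(rpois(30 * 20, 2), 30, 20)
  mb <- matrix(rpois(30 * 20, 3), 30, 20)
  cfg <- peri_event_config(window_pre_ms = 500, window_post_ms = 500,
                           bin_ms = 50, step_ms = 50)
  raw <- compare_conditions(ma, mb, cfg)
  bh <- compare_conditions(ma, mb, cfg, p_adjust = "BH")
  expect_true(all(bh$p_value >= raw$p_value - 1e-12))
  expect_true(all(which(bh$significant) %in% which(raw$significant)))
})

test_that("psth CSV output is tidy and stable", {
  cfg <- peri_event_config(window_pre_ms = 300, window_post_ms = 300,
                           bin_ms = 150, step_ms = 150)
  m <- matrix(rpois(8, 2), 2, 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_psth_csv(psth(m, cfg), f, compare_conditions(m, m + 1L, cfg))
  df <- read.csv(f)
  expect_equal(names(df), c("bin_center_ms", "mean_rate", "sem",
                            "p_value", "significant"))
  expect_equal(nrow(df), 4L)
})
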