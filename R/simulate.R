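# Dyadic behavior simulator. There is no behavioral model in the task
# literature; the leader-follower point process below is the minimal
# generative structure that can produce both chance-level and proficient
# cooperation: each agent pulls spontaneously as a (optionally decaying)
# Poisson process and, after each spontaneous partner pull, answers with
# one response pull with probability respond_prob after a random latency.
# Response pulls do not themselves trigger responses (no infinite echo).

#' Agent parameters for the dyadic pull simulator
#'
#' @param base_rate_hz Spontaneous pull intensity (Hz, >= 0).
#' @param respond_prob Probability of answering a spontaneous partner pull
#'   with a response pull, in `[0, 1]`.
#' @param latency Latency distribution of response pulls:
#'   `latency_uniform(lo_ms, hi_ms)` or `latency_exponential(mean_ms)`.
#' @param motivation_halflife_ms Half-life (ms) of an exponential decay of
#'   the spontaneous rate across the session; `Inf` (default) keeps the
#'   rate constant. Models waning motivation in long sessions.
#' @return An object of class `agent_params`.
#' @examples
#' agent_params(0.06, respond_prob = 0.8, latency = latency_uniform(100, 700))
#' @export
agent_params <- function(base_rate_hz = 0.05, respond_prob = 0,
                         latency = latency_uniform(100, 700),
                         motivation_halflife_ms = Inf) {
  stopifnot_scalar_num(base_rate_hz, "base_rate_hz", lower = 0)
  stopifnot_scalar_num(respond_prob, "respond_prob", lower = 0, upper = 1)
  if (!is.finite(motivation_halflife_ms) && motivation_halflife_ms != Inf)
    validation_error("motivation_halflife_ms must be > 0 or Inf")
  if (motivation_halflife_ms <= 0)
    validation_error("motivation_halflife_ms must be > 0 or Inf")
  if (!inherits(latency, "latency_dist"))
    validation_error("latency must be latency_uniform() or latency_exponential()")
  structure(list(base_rate_hz = base_rate_hz, respond_prob = respond_prob,
                 latency = latency,
                 motivation_halflife_ms = motivation_halflife_ms),
            class = "agent_params")
}

#' @rdname agent_params
#' @param lo_ms,hi_ms Uniform latency support in ms (`0 <= lo_ms <= hi_ms`).
#' @export
latency_uniform <- function(lo_ms, hi_ms) {
  if (lo_ms < 0 || hi_ms < lo_ms)
    validation_error("need 0 <= lo_ms <= hi_ms")
  structure(list(kind = "uniform", lo_ms = lo_ms, hi_ms = hi_ms),
            class = "latency_dist")
}

#' @rdname agent_params
#' @param mean_ms Mean of the exponential latency in ms (> 0).
#' @export
latency_exponential <- function(mean_ms) {
  if (mean_ms <= 0) validation_error("mean_ms must be > 0")
  structure(list(kind = "exponential", mean_ms = mean_ms),
            class = "latency_dist")
}

draw_latency <- function(dist, n) {
  switch(dist$kind,
         uniform = stats::runif(n, dist$lo_ms, dist$hi_ms),
         exponential = stats::rexp(n, rate = 1 / dist$mean_ms))
}

latency_mean_ms <- function(dist) {
  switch(dist$kind,
         uniform = (dist$lo_ms + dist$hi_ms) / 2,
         exponential = dist$mean_ms)
}

# homogeneous/decaying Poisson on [0, duration) by thinning; returns sorted
# continuous-time ms
sim_poisson_ms <- function(rate_hz, duration_ms, halflife_ms) {
  if (rate_hz <= 0) return(numeric())
  lam <- rate_hz / 1000  # per ms
  n <- stats::rpois(1, lam * duration_ms)
  t <- sort(stats::runif(n, 0, duration_ms))
  if (is.finite(halflife_ms) && n > 0) {
    keep <- stats::runif(n) < 2^(-t / halflife_ms)
    t <- t[keep]
  }
  t
}

#' Simulate a dyad's pull events
#'
#' Generates pull times for both animals from the leader-follower point
#' process: spontaneous pulls as independent Poisson processes (optionally
#' decaying with each agent's motivation half-life) plus, for each
#' spontaneous partner pull, a single response pull with probability
#' `respond_prob` at partner time + latency draw. Responses landing past
#' the session end are dropped. Fully reproducible from `seed`.
#'
#' The ground truth is attached as attribute `"truth"`: a `data.frame` with
#' one row per pull (`actor, t_ms, is_response, parent_t_ms`) so analyses
#' can be validated against known generative labels.
#'
#' @param params_m1,params_m2 [agent_params()] for the two animals.
#' @param duration_ms Session duration in ms (> 0).
#' @param seed Integer seed.
#' @return Pull-event `data.frame` (`pull_id, actor, t_ms, peak_position,
#'   source`), time-sorted, `source = "given"`.
#' @examples
#' p <- agent_params(0.06, respond_prob = 0.8)
#' pulls <- simulate_pulls(p, p, duration_ms = 120000, seed = 1)
#' nrow(pulls)
#' @export
simulate_pulls <- function(params_m1, params_m2, duration_ms, seed) {
  if (!is.numeric(duration_ms) || duration_ms <= 0)
    validation_error("duration_ms must be > 0")
  for (p in list(params_m1, params_m2))
    if (!inherits(p, "agent_params"))
      validation_error("params must be agent_params objects")
  with_seed(seed, {
    spont1 <- sim_poisson_ms(params_m1$base_rate_hz, duration_ms,
                             params_m1$motivation_halflife_ms)
    spont2 <- sim_poisson_ms(params_m2$base_rate_hz, duration_ms,
                             params_m2$motivation_halflife_ms)
    # M2 answers M1's spontaneous pulls; M1 answers M2's
    resp2 <- respond_to(spont1, params_m2, duration_ms)
    resp1 <- respond_to(spont2, params_m1, duration_ms)
    truth_block <- function(actor, t_cont, is_response, parent) {
      data.frame(actor = rep(actor, length(t_cont)), t_cont = t_cont,
                 is_response = rep(is_response, length(t_cont)),
                 parent_t_ms = round(parent), stringsAsFactors = FALSE)
    }
    truth <- rbind(
      truth_block("M1", spont1, FALSE, rep(NA_real_, length(spont1))),
      truth_block("M2", spont2, FALSE, rep(NA_real_, length(spont2))),
      truth_block("M2", resp2$t, TRUE, resp2$parent),
      truth_block("M1", resp1$t, TRUE, resp1$parent))
    truth$t_ms <- as.integer(round(truth$t_cont))
    truth$t_ms[truth$t_ms >= duration_ms] <- as.integer(duration_ms) - 1L
    truth <- truth[order(truth$t_ms, match(truth$actor, ACTORS)), ]
    # integer-ms resolution: drop same-ms duplicates within an actor
    dup <- duplicated(paste(truth$actor, truth$t_ms))
    truth <- truth[!dup, ]
    rownames(truth) <- NULL
    n <- nrow(truth)
    pulls <- data.frame(
      pull_id = sprintf("p%04d", seq_len(n)),
      actor = truth$actor, t_ms = truth$t_ms,
      peak_position = rep(NA_real_, n), source = rep("given", n),
      stringsAsFactors = FALSE)
    attr(pulls, "truth") <-
      truth[, c("actor", "t_ms", "is_response", "parent_t_ms")]
    pulls
  })
}

respond_to <- function(partner_t, params, duration_ms) {
  if (length(partner_t) == 0L || params$respond_prob == 0)
    return(list(t = numeric(), parent = numeric()))
  ans <- stats::runif(length(partner_t)) < params$respond_prob
  lat <- draw_latency(params$latency, sum(ans))
  t <- partner_t[ans] + lat
  keep <- t < duration_ms
  list(t = t[keep], parent = partner_t[ans][keep])
}

#' Render pull events as a synthetic lever position trace
#'
#' Each pull becomes a smooth excursion that first reaches `threshold` at
#' the first sample at or after the pull's `t_ms` (so
#' `detect_pulls(synthesize_lever_trace(P))` recovers `P`'s times within
#' one sample period), overshoots to `peak`, then decays back to rest —
#' below the re-arm level — before the next pull. Gaussian sensor noise is
#' added throughout. Pulls spaced closer than the excursion duration get a
#' compressed excursion, with a warning.
#'
#' @param pulls Pull-event `data.frame` (`actor, t_ms`).
#' @param sample_rate_hz Sampling rate of the trace (Hz).
#' @param threshold Position threshold the excursions must cross.
#' @param seed Integer seed for the sensor noise.
#' @param duration_ms Trace length; default covers the last pull + 1 s.
#' @param noise_sd Noise standard deviation in position units; default 1%%
#'   of `threshold`.
#' @param peak Excursion peak; default 1.6 * threshold.
#' @return Lever trace `data.frame` (`t_ms, actor, position, force_g`);
#'   `force_g` is a scaled copy of position, as from a strain gauge.
#' @export
synthesize_lever_trace <- function(pulls, sample_rate_hz, threshold, seed,
                                   duration_ms = NULL,
                                   noise_sd = 0.01 * threshold,
                                   peak = 1.6 * threshold) {
  stopifnot_scalar_num(sample_rate_hz, "sample_rate_hz", lower = 0,
                       open_lower = TRUE)
  if (is.null(duration_ms))
    duration_ms <- (if (nrow(pulls)) max(pulls$t_ms) else 0) + 1000
  dt <- 1000 / sample_rate_hz
  t_grid <- as.integer(round(seq(0, duration_ms, by = dt)))
  t_grid <- t_grid[!duplicated(t_grid)]
  actors <- if (nrow(pulls)) intersect(ACTORS, pulls$actor) else "M1"
  with_seed(seed, {
    out <- NULL
    for (a in actors) {
      tp <- sort(pulls$t_ms[pulls$actor == a])
      pos <- rep(0, length(t_grid))
      # sample index where each pull's excursion first reaches threshold
      s0 <- findInterval(tp - 1e-9, t_grid) + 1L
      s0[tp <= 0] <- 1L
      rise_n <- 3L; hold_n <- 2L; fall_n <- 5L
      for (i in seq_along(s0)) {
        a0 <- s0[i]
        if (a0 > length(t_grid)) next
        end_lim <- if (i < length(s0)) s0[i + 1L] - rise_n - 1L else
          length(t_grid)
        if (end_lim < a0 + 1L) {
          warning("pulls closer than the excursion duration; compressing")
          end_lim <- min(a0 + 1L, length(t_grid))
        }
        ramp <- a0 - (rise_n:1)            # sub-threshold approach
        ramp_v <- threshold * c(0.25, 0.5, 0.7)[seq_along(rise_n:1)]
        ok <- ramp >= 1L
        pos[ramp[ok]] <- pmax(pos[ramp[ok]], ramp_v[ok])
        top <- a0:min(a0 + hold_n - 1L, end_lim, length(t_grid))
        pos[top] <- peak
        f0 <- max(top) + 1L
        f1 <- min(f0 + fall_n - 1L, end_lim, length(t_grid))
        if (f1 >= f0) {
          k <- f1 - f0 + 1L
          pos[f0:f1] <- peak * (1 - seq_len(k) / k)
        }
      }
      pos <- pos + stats::rnorm(length(pos), 0, noise_sd)
      out <- rbind(out, data.frame(
        t_ms = t_grid, actor = a, position = pos,
        force_g = pmax(pos, 0) * 100, stringsAsFactors = FALSE))
    }
    out <- out[order(out$t_ms, out$actor), ]
    rownames(out) <- NULL
    out
  })
}

#' Scene geometry: enclosure origins and gaze targets
#'
#' Describes where each animal's head sits and where the gaze targets of
#' interest are: the partner's head (social gaze), the lever, and the juice
#' tube, each a labeled 3D point with a hit radius.
#'
#' @param origin_m1,origin_m2 3-vectors (cm): resting head position of each
#'   animal in the shared world frame.
#' @param targets `data.frame` with columns `name, x, y, z, radius_cm`;
#'   default places a lever and a juice tube near each animal's enclosure.
#' @return An object of class `scene_geometry`.
#' @export
scene_geometry <- function(origin_m1 = c(0, 0, 0),
                           origin_m2 = c(60, 0, 0),
                           targets = NULL) {
  if (is.null(targets)) {
    targets <- data.frame(
      name = c("lever", "juice_tube"),
      x = c(10, -5), y = c(-15, -8), z = c(25, 10),
      radius_cm = c(3, 2), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(targets$name))
    validation_error("target names must be distinct")
  if (any(targets$radius_cm <= 0))
    validation_error("target radii must be > 0")
  key <- paste(targets$x, targets$y, targets$z)
  if (anyDuplicated(key))
    validation_error("target points must be distinct")
  structure(list(origins = list(M1 = origin_m1, M2 = origin_m2),
                 targets = targets),
            class = "scene_geometry")
}

# Rigid canonical head template (cm), an invented geometry whose absolute
# size is irrelevant — only the relative configuration matters for the gaze
# math. Eyes on the x-axis 1.4 cm apart, blaze above the eye midpoint (the
# forehead marker), mouth below and slightly forward, ear tufts posterior-
# lateral (behind the face plane). Face plane = eyes + blaze, so the
# outward normal of the canonical head is +z.
canonical_head <- function() {
  m <- rbind(
    left_ear_tuft  = c(-1.6,  0.4, -1.2),
    right_ear_tuft = c( 1.6,  0.4, -1.2),
    left_eye       = c(-0.7,  0.0,  0.0),
    right_eye      = c( 0.7,  0.0,  0.0),
    blaze          = c( 0.0,  1.0,  0.0),
    mouth          = c( 0.0, -1.3,  0.4))
  m[KEYPOINT_NAMES, , drop = FALSE]
}

# rotation taking the +z axis onto unit vector d (Rodrigues)
rotation_from_z <- function(d) {
  z <- c(0, 0, 1)
  c_ <- sum(z * d)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))  # 180 deg about x
  v <- cross3(z, d)
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    u <- unitize(v)
    if (!is.null(u)) return(u)
  }
}

#' Synthesize 3D facial keypoints following a gaze script
#'
#' Places the six-keypoint rigid head template at the animal's enclosure
#' origin, oriented so the face-plane normal points at the scripted target
#' during each script interval (and in a random direction otherwise), with
#' isotropic Gaussian jitter on every keypoint. The generative gaze label
#' of every frame is attached as attribute `"truth"` so gaze classification
#' can be scored against ground truth.
#'
#' @param scene A [scene_geometry()].
#' @param gaze_script `data.frame` with columns `t_start_ms, t_end_ms,
#'   target` (a target name from the scene, `"partner_head"`, or `"none"`);
#'   intervals `[t_start, t_end)` must not overlap.
#' @param frame_rate_hz Video frame rate (Hz).
#' @param noise_sd_cm Keypoint jitter SD in cm.
#' @param seed Integer seed.
#' @param animal `"M1"` (default) or `"M2"`: whose head to synthesize.
#' @param duration_ms Clip length; default last script end.
#' @return Long-format keypoint `data.frame` as from [read_keypoints()],
#'   with attribute `"truth"` (`frame, t_ms, true_target`).
#' @export
synthesize_keypoints <- function(scene, gaze_script, frame_rate_hz,
                                 noise_sd_cm, seed, animal = "M1",
                                 duration_ms = NULL) {
  if (!inherits(scene, "scene_geometry"))
    validation_error("scene must be a scene_geometry")
  gs <- gaze_script[order(gaze_script$t_start_ms), ]
  if (nrow(gs) > 1 &&
      any(gs$t_start_ms[-1] < gs$t_end_ms[-nrow(gs)]))
    validation_error("gaze script intervals overlap")
  if (is.null(duration_ms)) duration_ms <- max(gs$t_end_ms)
  origin <- scene$origins[[animal]]
  partner <- setdiff(ACTORS, animal)
  target_point <- function(name) {
    if (name == "partner_head") return(scene$origins[[partner]])
    i <- match(name, scene$targets$name)
    if (is.na(i)) validation_error("unknown gaze target: ", name)
    c(scene$targets$x[i], scene$targets$y[i], scene$targets$z[i])
  }
  n_frames <- floor(duration_ms * frame_rate_hz / 1000)
  t_ms <- as.integer(round((seq_len(n_frames) - 1L) * 1000 / frame_rate_hz))
  tmpl <- canonical_head()
  with_seed(seed, {
    rows <- vector("list", n_frames)
    truth <- character(n_frames)
    for (f in seq_len(n_frames)) {
      k <- which(gs$t_start_ms <= t_ms[f] & t_ms[f] < gs$t_end_ms)
      tgt <- if (length(k)) gs$target[k[1]] else "none"
      truth[f] <- tgt
      d <- if (tgt == "none") random_unit_vector() else
        unitize(target_point(tgt) - origin)
      R <- rotation_from_z(d)
      pts <- t(R %*% t(tmpl)) + rep(origin, each = 6L)
      if (noise_sd_cm > 0)
        pts <- pts + matrix(stats::rnorm(18, 0, noise_sd_cm), 6, 3)
      rows[[f]] <- data.frame(
        frame = f - 1L, t_ms = t_ms[f], animal = animal,
        keypoint = KEYPOINT_NAMES,
        x = pts[, 1], y = pts[, 2], z = pts[, 3],
        confidence = 1, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- data.frame(frame = seq_len(n_frames) - 1L,
                                     t_ms = t_ms, true_target = truth,
                                     stringsAsFactors = FALSE)
    out
  })
}

#' Synthesize an event-modulated point process (calls or spikes)
#'
#' Draws an inhomogeneous Poisson process whose intensity is a baseline
#' rate plus a peri-event modulation: within each `(lag_lo_ms, lag_hi_ms)`
#' window after every event the rate is replaced by the window's rate.
#' Used to generate ground-truth vocalization times and spike trains with a
#' known peri-event structure.
#'
#' @param baseline_hz Baseline intensity (Hz, >= 0).
#' @param modulation `data.frame` with columns `lag_lo_ms, lag_hi_ms,
#'   rate_hz`: rate within each peri-event lag window (later rows win where
#'   windows overlap). `NULL` for a homogeneous process.
#' @param events Event times in ms (may be empty).
#' @param duration_ms Length of the generated train (> 0).
#' @param seed Integer seed.
#' @param label Label for the returned point-time set.
#' @return `data.frame` (`label, t_ms`) of strictly increasing integer
#'   times; the realized intensity is piecewise-constant.
#' @export
synthesize_point_times <- function(baseline_hz, modulation = NULL,
                                   events = integer(), duration_ms, seed,
                                   label = "unit") {
  stopifnot_scalar_num(baseline_hz, "baseline_hz", lower = 0)
  if (!is.null(modulation) && any(modulation$rate_hz < 0))
    validation_error("rates must be >= 0")
  if (duration_ms <= 0) validation_error("duration_ms must be > 0")
  rate_at <- function(t) {
    r <- rep(baseline_hz, length(t))
    if (!is.null(modulation) && length(events)) {
      for (i in seq_len(nrow(modulation))) {
        hit <- rep(FALSE, length(t))
        for (e in events)
          hit <- hit | (t - e >= modulation$lag_lo_ms[i] &
                          t - e < modulation$lag_hi_ms[i])
        r[hit] <- modulation$rate_hz[i]
      }
    }
    r
  }
  rmax <- baseline_hz
  if (!is.null(modulation)) rmax <- max(rmax, modulation$rate_hz)
  with_seed(seed, {
    if (rmax <= 0) {
      t <- integer()
    } else {
      n <- stats::rpois(1, rmax / 1000 * duration_ms)
      cand <- sort(stats::runif(n, 0, duration_ms))
      keep <- stats::runif(n) < rate_at(cand) / rmax
      t <- unique(as.integer(round(cand[keep])))
    }
    data.frame(label = rep(label, length(t)), t_ms = t,
               stringsAsFactors = FALSE)
  })
}

#' Dyad presets spanning naive to proficient cooperation
#'
#' Named parameter sets for [simulate_pulls()] chosen to cover the regimes
#' reported for real dyads: roughly 150 pulls per 20-minute session, with
#' success rates below 50% for a naive dyad and above 50% (the customary
#' proficiency bound) for a proficient one. Expected dyadic pull count is
#' `(1 + p) * (b1 + b2) * T`; with the preset base rates (0.06 and 0.0185
#' Hz) and the proficient response probability 0.55 this gives ~146 pulls
#' in 20 min.
#'
#' @param level `"naive"` or `"proficient"`.
#' @return List with elements `m1` and `m2` ([agent_params()]).
#' @export
dyad_preset <- function(level = c("proficient", "naive")) {
  level <- match.arg(level)
  p <- if (level == "proficient") 0.55 else 0.10
  list(
    m1 = agent_params(base_rate_hz = 0.06, respond_prob = p,
                      latency = latency_uniform(100, 700)),
    m2 = agent_params(base_rate_hz = 0.0185, respond_prob = p,
                      latency = latency_uniform(100, 700))
  )
}
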