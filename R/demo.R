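# End-to-end demo pipeline: simulate -> engine -> metrics / gaze / psth.
# Every artifact in the output tree is a pure function of (seed, config),
# so repeat runs with the same seed are byte-identical; the run manifest
# records everything needed to reproduce the tree (and deliberately no
# wall-clock timestamp, which would break reproducibility).

#' Regenerate the full synthetic demonstration suite
#'
#' Simulates sessions for both reward contingencies — a self-reward
#' session and two mutual-cooperation sessions, one with a naive dyad
#' preset (success rate below the 50% proficiency bound) and one with a
#' proficient dyad (above it) — then runs every analysis: session metrics,
#' gaze-target classification on a scripted keypoint clip, and the
#' peri-event comparison of call times between conditions. All outputs are
#' plain text (CSV/JSON/YAML) under `out_dir`, plus a `manifest.json`
#' sufficient to reproduce the tree exactly.
#'
#' @param out_dir Output directory (created; must be writable).
#' @param seed Integer master seed; every stage derives its own stream.
#' @param duration_ms Session length; default 20 minutes.
#' @return Invisibly, a list of the summary metrics per session.
#' @export
run_demo <- function(out_dir, seed, duration_ms = 1200000) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    mp_stop(paste0("output directory not writable: ", out_dir),
            "mp_io_error")
  seed <- as.integer(seed)
  summaries <- list()
  files <- character()

  sessions <- list(
    self_reward = list(condition = "self_reward", preset = "proficient",
                       respond_override = 0, seed_off = 101L),
    coop_naive = list(condition = "mutual_cooperation", preset = "naive",
                      respond_override = NULL, seed_off = 102L),
    coop_proficient = list(condition = "mutual_cooperation",
                           preset = "proficient", respond_override = NULL,
                           seed_off = 103L)
  )
  logs <- list()
  for (nm in names(sessions)) {
    s <- sessions[[nm]]
    preset <- dyad_preset(s$preset)
    if (!is.null(s$respond_override)) {
      # self-reward: pulling is fully independent across the animals
      preset$m1$respond_prob <- s$respond_override
      preset$m2$respond_prob <- s$respond_override
    }
    cfg <- session_config(s$condition, session_duration_ms = duration_ms,
                          rng_seed = seed + s$seed_off)
    pulls <- simulate_pulls(preset$m1, preset$m2, duration_ms,
                            seed = seed + s$seed_off)
    log <- run_session(pulls, cfg)
    logs[[nm]] <- log
    dir.create(file.path(out_dir, nm), showWarnings = FALSE)
    f_ev <- file.path(out_dir, nm, "events.csv")
    f_cfg <- file.path(out_dir, nm, "session_config.yaml")
    f_met <- file.path(out_dir, nm, "metrics.json")
    write_session_log(log, f_ev)
    write_session_config(cfg, f_cfg)
    m <- session_metrics(log)
    write_metrics_json(m, f_met)
    summaries[[nm]] <- m
    files <- c(files, f_ev, f_cfg, f_met)
  }

  # gaze: scripted keypoint clip with known labels
  scene <- scene_geometry()
  script <- data.frame(
    t_start_ms = c(0, 4000, 8000, 12000),
    t_end_ms = c(3000, 7000, 11000, 15000),
    target = c("lever", "partner_head", "juice_tube", "lever"),
    stringsAsFactors = FALSE)
  kp <- synthesize_keypoints(scene, script, frame_rate_hz = 30,
                             noise_sd_cm = 0.05, seed = seed + 201L,
                             duration_ms = 16000)
  f_kp <- file.path(out_dir, "keypoints.csv")
  write_keypoints(kp, f_kp)
  poses <- head_poses(read_keypoints(f_kp))
  cls <- classify_frames(poses, scene_with_partner(scene, "M1"))
  bouts <- segment_bouts(cls, frame_rate_hz = 30)
  f_bouts <- file.path(out_dir, "gaze_bouts.csv")
  write_gaze_bouts(bouts, f_bouts)
  files <- c(files, f_kp, f_bouts)

  # peri-event: chirp-like call times elevated after cooperation pulls
  coop <- logs$coop_proficient
  selfr <- logs$self_reward
  mod <- data.frame(lag_lo_ms = 0, lag_hi_ms = 500, rate_hz = 3)
  calls_coop <- synthesize_point_times(1, mod, coop$pulls$t_ms, duration_ms,
                                       seed = seed + 301L, label = "chirp")
  calls_self <- synthesize_point_times(1, NULL, integer(), duration_ms,
                                       seed = seed + 302L, label = "chirp")
  cfg_pe <- peri_event_config(window_pre_ms = 2000, window_post_ms = 2000)
  m_coop <- align_events(calls_coop$t_ms, coop$pulls$t_ms, cfg_pe,
                         duration_ms)
  m_self <- align_events(calls_self$t_ms, selfr$pulls$t_ms, cfg_pe,
                         duration_ms)
  res <- psth(m_coop)
  cmpr <- compare_conditions(m_coop, m_self, cfg_pe)
  f_psth <- file.path(out_dir, "psth_chirp.csv")
  write_psth_csv(res, f_psth, cmpr)
  f_calls <- file.path(out_dir, "point_times.csv")
  write_point_times(rbind(calls_coop, calls_self), f_calls)
  files <- c(files, f_psth, f_calls)

  manifest <- list(
    schema = "marmopull/manifest/v1",
    command = "demo",
    tool_version = as.character(utils::packageVersion("marmopull")),
    seed = seed,
    duration_ms = duration_ms,
    sessions = lapply(sessions, function(s)
      s[c("condition", "preset", "seed_off")]),
    outputs = sort(basename_rel(files, out_dir))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(summaries)
}

basename_rel <- function(paths, root) {
  root <- sub("/+$", "", root)
  pre <- paste0(root, "/")
  ifelse(startsWith(paths, pre), substring(paths, nchar(pre) + 1L), paths)
}

# a scene whose partner_head static target is the *other* animal's origin —
# used when only one animal's keypoints exist and the partner head is a
# fixed point
scene_with_partner <- function(scene, animal) {
  partner <- setdiff(ACTORS, animal)
  p <- scene$origins[[partner]]
  scene$targets <- rbind(scene$targets,
                         data.frame(name = "partner_head", x = p[1],
                                    y = p[2], z = p[3], radius_cm = 5,
                                    stringsAsFactors = FALSE))
  scene
}

#' Write gaze bouts as CSV
#' @param bouts Output of [segment_bouts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_bouts <- function(bouts, path) {
  lines <- c("animal,target,start_frame,end_frame,n_frames,duration_ms",
             paste(chr_or_empty(bouts$animal), bouts$target,
                   fmt_int(bouts$start_frame), fmt_int(bouts$end_frame),
                   fmt_int(bouts$n_frames), fmt_num(bouts$duration_ms),
                   sep = ","))
  write_lines_utf8(lines, path)
}
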