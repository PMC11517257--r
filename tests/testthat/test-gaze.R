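tmpl <- marmopull:::canonical_head()

test_that("head pose is equivariant under rigid rotation (1e-9)", {
  set.seed(91)
  for (k in 1:1000) {
    tf <- random_rigid_transform()
    pts <- apply_rigid_points(tf, tmpl)
    rownames(pts) <- rownames(tmpl)
    hp <- head_pose(pts)
    expect_true(hp$valid)
    expect_equal(hp$forward, as.numeric(tf$R %*% c(0, 0, 1)),
                 tolerance = 1e-9)
    expect_equal(hp$origin, as.numeric(tf$R %*% c(0, 0, 0) + tf$t),
                 tolerance = 1e-9)
  }
})

test_that("degenerate or incomplete keypoints invalidate the pose with a reason", {
  flat <- tmpl
  flat["blaze", ] <- c(0, 0, 0)  # collinear with the eyes
  hp <- head_pose(flat)
  expect_false(hp$valid)
  expect_equal(hp$reason, "degenerate plane")
  missing_eye <- tmpl
  missing_eye["left_eye", ] <- NA
  expect_equal(head_pose(missing_eye)$reason, "missing keypoint")
  # ears missing: the mouth still disambiguates the outward direction
  no_ears <- tmpl
  no_ears[c("left_ear_tuft", "right_ear_tuft"), ] <- NA
  hp2 <- head_pose(no_ears)
  expect_true(hp2$valid)
  expect_equal(hp2$forward, c(0, 0, 1))
  no_ears["mouth", ] <- NA
  expect_false(head_pose(no_ears)$valid)
})

test_that("gaze cone: on-axis hit, closed 15-degree boundary, behind-head miss", {
  hp <- head_pose(tmpl)
  expect_true(gaze_hit(hp, c(0, 0, 5)))
  expect_true(gaze_hit(hp, c(0, 0, 0.01)))
  th <- 15 * pi / 180
  boundary <- 10 * c(sin(th), 0, cos(th))
  expect_true(gaze_hit(hp, boundary))
  just_out <- 10 * c(sin(th + 1e-4), 0, cos(th + 1e-4))
  expect_false(gaze_hit(hp, just_out))
  expect_false(gaze_hit(hp, c(0, 0, -5)))
  expect_false(gaze_hit(hp, c(0, 10, -0.1)))  # > 90 degrees off-axis
  # invalid pose gives NA, not an error
  expect_true(is.na(gaze_hit(list(valid = FALSE), c(1, 1, 1))))
  # apex-angle reading halves the aperture
  expect_false(gaze_hit(hp, boundary, angle_interpretation = "apex_angle"))
})

test_that("cone hits agree with a cross-product/atan2 oracle on random poses", {
  set.seed(92)
  for (k in 1:10000) {
    f <- rnorm(3); f <- f / sqrt(sum(f^2))
    org <- rnorm(3, 0, 10)
    tgt <- rnorm(3, 0, 10)
    pose <- list(origin = org, forward = f, valid = TRUE)
    half <- runif(1, 1, 60)
    got <- gaze_hit(pose, tgt, half_angle_deg = half)
    d <- tgt - org
    ang <- atan2(sqrt(sum(crossprod_vec(f, d)^2)), sum(f * d)) * 180 / pi
    expect_identical(got, ang <= half + 1e-7)
  }
})

test_that("enlarging the cone never turns a hit into a miss", {
  set.seed(93)
  hp <- head_pose(tmpl)
  for (k in 1:200) {
    tgt <- rnorm(3, 0, 5)
    hits <- vapply(c(5, 10, 15, 30, 60, 90),
                   function(a) gaze_hit(hp, tgt, a), logical(1))
    expect_true(all(diff(hits) >= 0))
  }
})

test_that("classification picks the hit target nearest in angle", {
  hp_df <- head_poses_from_template(diag(3), c(0, 0, 0))
  th2 <- 2 * pi / 180; th10 <- 10 * pi / 180
  scene <- scene_geometry(targets = data.frame(
    name = c("near_axis", "off_axis"),
    x = 10 * c(sin(th2), sin(th10)), y = c(0, 0),
    z = 10 * c(cos(th2), cos(th10)), radius_cm = c(2, 2)))
  cls <- classify_frames(hp_df, scene)
  expect_equal(cls$target, "near_axis")
  # no candidate inside the cone: none
  far <- scene_geometry(targets = data.frame(name = "wall", x = 10, y = 0,
                                             z = 0, radius_cm = 2))
  expect_equal(classify_frames(hp_df, far)$target, "none")
})

test_that("invalid frames classify as NA and produce zero bouts", {
  kp <- data.frame(frame = rep(0:4, each = 6), t_ms = rep(0:4 * 33L, each = 6),
                   animal = "M1", keypoint = rep(rownames(tmpl), 5),
                   x = NA_real_, y = NA_real_, z = NA_real_, confidence = 0)
  poses <- head_poses(kp)
  expect_false(any(poses$valid))
  cls <- classify_frames(poses, scene_geometry())
  expect_true(all(is.na(cls$target)))
  expect_equal(nrow(segment_bouts(cls, 30)), 0L)
})

test_that("zero-noise scripted clips are recovered frame-perfectly end-to-end", {
  scene <- scene_geometry()
  script <- data.frame(
    t_start_ms = c(0, 3400, 6800),
    t_end_ms = c(3300, 6700, 10000),
    target = c("lever", "partner_head", "juice_tube"))
  kp <- synthesize_keypoints(scene, script, frame_rate_hz = 30,
                             noise_sd_cm = 0, seed = 94,
                             duration_ms = 10000)
  truth <- attr(kp, "truth")
  cls <- classify_frames(head_poses(kp),
                         marmopull:::scene_with_partner(scene, "M1"))
  scripted <- truth$true_target != "none"
  expect_true(all(cls$target[scripted] == truth$true_target[scripted]))
})

test_that("noisy scripted clips are recovered at >= 95% with the default cone", {
  scene <- scene_geometry()
  script <- data.frame(
    t_start_ms = c(0, 3400, 6800),
    t_end_ms = c(3300, 6700, 10000),
    target = c("lever", "partner_head", "juice_tube"))
  kp <- synthesize_keypoints(scene, script, frame_rate_hz = 30,
                             noise_sd_cm = 0.05, seed = 95,
                             duration_ms = 10000)
  truth <- attr(kp, "truth")
  cls <- classify_frames(head_poses(kp),
                         marmopull:::scene_with_partner(scene, "M1"))
  scripted <- truth$true_target != "none"
  acc <- mean(cls$target[scripted] == truth$true_target[scripted])
  expect_gte(acc, 0.95)
})

test_that("hits and labels are invariant under one rigid motion of the world", {
  scene <- scene_geometry()
  script <- data.frame(t_start_ms = c(0, 2000), t_end_ms = c(1800, 4000),
                       target = c("lever", "juice_tube"))
  kp <- synthesize_keypoints(scene, script, 30, noise_sd_cm = 0.1, seed = 96,
                             duration_ms = 4000)
  base_cls <- classify_frames(head_poses(kp),
                              marmopull:::scene_with_partner(scene, "M1"))
  set.seed(97)
  for (k in 1:25) {
    tf <- random_rigid_transform()
    kp2 <- kp
    pts <- apply_rigid_points(tf, cbind(kp$x, kp$y, kp$z))
    kp2$x <- pts[, 1]; kp2$y <- pts[, 2]; kp2$z <- pts[, 3]
    tpts <- apply_rigid_points(tf, cbind(scene$targets$x, scene$targets$y,
                                         scene$targets$z))
    scene2 <- scene
    scene2$targets$x <- tpts[, 1]; scene2$targets$y <- tpts[, 2]
    scene2$targets$z <- tpts[, 3]
    scene2$origins <- lapply(scene$origins, function(o)
      as.numeric(tf$R %*% o + tf$t))
    cls2 <- classify_frames(head_poses(kp2),
                            marmopull:::scene_with_partner(scene2, "M1"))
    expect_identical(cls2$target, base_cls$target)
    expect_equal(cls2$angle_deg, base_cls$angle_deg, tolerance = 1e-9)
  }
})

test_that("bout segmentation bridges short gaps and enforces minimum span", {
  b <- segment_bouts(c("L", "L", "L", "none", "L", "L"), 30)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_frames, 6L)
  expect_equal(b$duration_ms, 200)
  expect_equal(nrow(segment_bouts(c("L", "L"), 30)), 0L)
  # a different target always terminates the bout
  b2 <- segment_bouts(c("L", "L", "L", "J", "J", "J"), 30)
  expect_equal(b2$target, c("L", "J"))
  # a two-frame gap is not bridged at the default tolerance
  b3 <- segment_bouts(c("L", "L", "L", "none", "none", "L", "L", "L"), 30)
  expect_equal(nrow(b3), 2L)
})

test_that("bout partition equals the regex run-length oracle on random streams", {
  set.seed(98)
  for (k in 1:200) {
    n <- sample(5:60, 1)
    labels <- sample(c("partner", "lever", "juice", "none", NA), n,
                     replace = TRUE, prob = c(.2, .25, .15, .3, .1))
    gap <- sample(0:2, 1)
    minb <- sample(1:4, 1)
    got <- segment_bouts(labels, 30, min_bout_frames = minb,
                         max_gap_frames = gap)
    want <- oracle_bouts(labels, min_bout_frames = minb,
                         max_gap_frames = gap)
    expect_equal(got$target, want$target)
    expect_equal(got$start_frame, want$start_frame)
    expect_equal(got$end_frame, want$end_frame)
  }
})

test_that("bout counts ignore leading and trailing none-frames", {
  core <- c("L", "L", "L", "none", "J", "J", "J")
  a <- segment_bouts(core, 30)
  b <- segment_bouts(c(rep("none", 7), core, rep(NA, 5)), 30)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$target, b$target)
  expect_equal(a$n_frames, b$n_frames)
})

test_that("gaze target counts report both bouts and frames", {
  labels <- c("lever", "lever", "lever", "none", "partner_head",
              "partner_head", "partner_head", "lever", "lever", "lever")
  cls <- data.frame(frame = 0:9, t_ms = 0:9 * 33L, animal = "M1",
                    target = labels, angle_deg = 1)
  gc <- gaze_target_counts(cls, 30)
  expect_equal(gc$n_bouts[gc$target == "lever"], 2L)
  expect_equal(gc$n_frames[gc$target == "lever"], 6L)
  expect_equal(gc$n_bouts[gc$target == "partner_head"], 1L)
})
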