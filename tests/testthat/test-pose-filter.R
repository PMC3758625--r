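# Confidence gating, model-constrained pose estimation, validated
# interpolation and the stream filter.

conf_all <- function(v = 1) stats::setNames(rep(v, 8), KIN_JOINTS)

test_that("gating replaces only low-confidence joints, by role", {
  m <- test_model()
  truth <- generate_motion(m, 2, 30, "right_arm_reach", seed = 1)
  prev_frame <- tracker_frame(truth[[10]]$timestamp,
                              truth[[10]]$positions + 3, conf_all(1))
  prev_pose <- truth[[10]]
  cur <- truth[[11]]
  conf <- conf_all(1)
  conf["r_elbow"] <- 0.4  # outside the three tracker confidence levels
  expect_error(tracker_frame(cur$timestamp, cur$positions, conf),
               "confidence")
  conf["r_hand"] <- 0      # end effector: previous observation
  conf["r_elbow"] <- 0     # intermediate joint: previous model position
  conf["l_shoulder"] <- 0  # passthrough joint: held from the model
  frame <- tracker_frame(cur$timestamp, cur$positions, conf)
  gated <- gate_centroids(frame, prev_frame, prev_pose)
  expect_equal(gated$positions["r_hand", ], prev_frame$positions["r_hand", ])
  expect_equal(gated$positions["r_elbow", ], prev_pose$positions["r_elbow", ])
  expect_equal(gated$positions["l_shoulder", ],
               prev_pose$positions["l_shoulder", ])
  # all other joints untouched
  untouched <- setdiff(KIN_JOINTS, c("r_hand", "r_elbow", "l_shoulder"))
  expect_equal(gated$positions[untouched, ], frame$positions[untouched, ])
  expect_setequal(attr(gated, "gated_joints"),
                  c("r_hand", "r_elbow", "l_shoulder"))
})

test_that("a full-confidence frame passes the gate unchanged", {
  m <- test_model()
  truth <- generate_motion(m, 1, 30, "free_arms", seed = 2)
  f1 <- tracker_frame(truth[[1]]$timestamp, truth[[1]]$positions, conf_all())
  f2 <- tracker_frame(truth[[2]]$timestamp, truth[[2]]$positions, conf_all())
  gated <- gate_centroids(f2, f1, truth[[1]])
  expect_equal(gated$positions, f2$positions)
  expect_length(attr(gated, "gated_joints"), 0)
  # first frame: no history, passthrough
  g1 <- gate_centroids(f1, NULL, NULL)
  expect_equal(g1$positions, f1$positions)
})

test_that("noiseless frames are recovered within 1 mm", {
  m <- test_model()
  truth <- generate_motion(m, 3, 30, "free_arms", seed = 3)
  frames <- frames_from_truth(truth)
  prev <- truth[[1]]
  for (k in 2:length(frames)) {
    pose <- estimate_pose(frames[[k]], m, prev)
    expect_lt(max(abs(pose$positions - truth[[k]]$positions)), 1)
    prev <- pose
  }
})

test_that("an out-of-reach hand target fully extends the arm toward it", {
  m <- test_model()
  prev <- neutral_pose(m)
  S <- m$offsets$r_shoulder
  reach <- m$lengths[["r_upper_arm"]] + m$lengths[["r_forearm"]]
  dir <- c(-0.2, -0.5, 0.843); dir <- dir / sqrt(sum(dir^2))
  pos <- prev$positions
  pos["r_hand", ] <- S + 1.6 * reach * dir  # e.g. held object
  frame <- tracker_frame(1 / 30, pos, conf_all())
  pose <- estimate_pose(frame, m, prev)
  expect_equal(sqrt(sum((pose$positions["r_hand", ] - S)^2)), reach,
               tolerance = 1e-6)
  # hand lies on the shoulder-to-target ray
  v <- pose$positions["r_hand", ] - S
  expect_equal(as.numeric(v / sqrt(sum(v^2))), dir, tolerance = 1e-6)
  expect_equal(attr(pose, "clamped"), 1L)
})

test_that("a displaced elbow centroid is projected onto the valid locus", {
  m <- test_model()
  truth <- generate_motion(m, 2, 30, "right_arm_reach", seed = 6)
  k <- 30
  prev <- truth[[k - 1]]
  pos <- truth[[k]]$positions
  # displace the observed elbow 80 mm off its true position
  pos["r_elbow", ] <- pos["r_elbow", ] + c(50, -40, 45.8)
  frame <- tracker_frame(truth[[k]]$timestamp, pos, conf_all())
  pose <- estimate_pose(frame, m, prev)
  # law-of-cosines locus: model elbow at upper-arm length from the
  # shoulder and forearm length from the solved hand
  S <- m$offsets$r_shoulder
  E <- pose$positions["r_elbow", ]; W <- pose$positions["r_hand", ]
  expect_equal(sqrt(sum((E - S)^2)), m$lengths[["r_upper_arm"]],
               tolerance = 1e-6)
  expect_equal(sqrt(sum((W - E)^2)), m$lengths[["r_forearm"]],
               tolerance = 1e-6)
})

test_that("interpolation produces validated poses between key poses", {
  m <- test_model()
  truth <- generate_motion(m, 2, 30, "free_arms", seed = 8)
  p0 <- truth[[20]]; p1 <- truth[[21]]
  expect_length(interpolate_poses(p0, p1, 0, m), 0)
  sub <- interpolate_poses(p0, p1, 4, m, history = truth[19])
  expect_length(sub, 4)
  for (s in sub) {
    expect_true(check_pose_validity(m, s)$ok)
    expect_gt(s$timestamp, p0$timestamp)
    expect_lt(s$timestamp, p1$timestamp)
  }
  # identical consecutive poses: constant spline
  p1b <- new_pose(m, p0$angles, timestamp = p0$timestamp + 1 / 30)
  sub2 <- interpolate_poses(p0, p1b, 3, m)
  for (s in sub2)
    expect_equal(s$positions, p0$positions, tolerance = 1e-6)
})

test_that("substeps between arm-crossing poses remain collision free", {
  m <- test_model()
  np <- neutral_pose(m)
  # both hands far to opposite sides in front of the chest; the straight
  # blend to the mirrored pose would sweep the forearms through each other
  mk <- function(lx, rx, t) {
    pos <- np$positions
    pos["l_hand", ] <- c(lx, 150, 330)
    pos["r_hand", ] <- c(rx, 150, 330)
    estimate_pose(tracker_frame(t, pos, conf_all()), m,
                  new_pose(m, np$angles, t - 1 / 30))
  }
  pa <- mk(250, -250, 1)
  pb <- mk(-250, 250, 1 + 1 / 30)
  sub <- interpolate_poses(pa, pb, 6, m)
  for (s in sub) expect_true(check_pose_validity(m, s)$ok)
})

test_that("the stream filter rejects bad input and handles empties", {
  m <- test_model()
  expect_length(filter_stream(list(), m)$poses, 0)
  truth <- generate_motion(m, 1, 30, "free_arms", seed = 2)
  frames <- frames_from_truth(truth)
  frames[[3]]$t <- frames[[2]]$t
  expect_error(filter_stream(frames, m), "increasing")
})

test_that("filtering reduces the elbow error of a noisy stream", {
  m <- test_model()
  truth <- generate_motion(m, 10, 30, "right_arm_reach", seed = 12)
  spec <- corruption_spec(sigma = c(r_elbow = 30, l_elbow = 30,
                                    r_hand = 20, l_hand = 20),
                          default_sigma = 10,
                          elbow_extension_gain = 2, seed = 13)
  frames <- corrupt_stream(truth, spec, m)
  res <- filter_stream(frames, m, config = filter_config(substeps = 0))
  tr_true <- joint_trajectory(truth, "r_elbow")
  err_raw <- sqrt(rowSums((joint_trajectory(frames, "r_elbow") - tr_true)^2))
  err_fil <- sqrt(rowSums((joint_trajectory(res$key_poses, "r_elbow") -
                           tr_true)^2))
  expect_lt(mean(err_fil), mean(err_raw))
  # one output pose per input frame
  expect_length(res$poses, length(frames))
})

test_that("the cubic interpolator delays the output by two samples", {
  m <- test_model()
  truth <- generate_motion(m, 8, 30, "right_arm_reach", seed = 4)
  frames <- frames_from_truth(truth)
  res <- filter_stream(frames, m,
                       config = filter_config(substeps = 0, learn = FALSE))
  A <- list(hand = joint_trajectory(truth, "r_hand"),
            elbow = joint_trajectory(truth, "r_elbow"),
            shoulder = joint_trajectory(truth, "r_shoulder"))
  B <- list(hand = joint_trajectory(res$poses, "r_hand"),
            elbow = joint_trajectory(res$poses, "r_elbow"),
            shoulder = joint_trajectory(res$poses, "r_shoulder"))
  al <- temporal_align(A, B, max_lag = 8)
  expect_equal(al$lag, 2)
  # linear interpolator: one sample; interpolation off: no delay
  resL <- filter_stream(frames, m,
                        config = filter_config(substeps = 0,
                                               interpolator = "linear",
                                               learn = FALSE))
  expect_equal(temporal_align(A, list(
    hand = joint_trajectory(resL$poses, "r_hand"),
    elbow = joint_trajectory(resL$poses, "r_elbow"),
    shoulder = joint_trajectory(resL$poses, "r_shoulder")), 8)$lag, 1)
})

test_that("a 30-frame hand occlusion leaves the output continuous", {
  m <- test_model()
  truth <- generate_motion(m, 8, 30, "right_arm_reach", seed = 4)
  spec <- corruption_spec(default_sigma = 5,
                          occlusions = list(list(joint = "r_hand",
                                                 from = 100, to = 130,
                                                 confidence = 0)),
                          seed = 9)
  frames <- corrupt_stream(truth, spec, m)
  cfg <- filter_config(substeps = 0)
  res <- filter_stream(frames, m, config = cfg)
  jumps <- sqrt(rowSums(diff(joint_trajectory(res$key_poses, "r_hand"))^2))
  bound <- cfg$max_ee_speed / 30  # per-frame motion bound
  expect_lte(max(jumps), 2 * bound)
  expect_gt(res$log$gated, 25)
})

test_that("all emitted poses and substeps are valid on a hostile stream", {
  m <- test_model()
  truth <- generate_motion(m, 5, 30, "free_arms", seed = 21)
  spec <- corruption_spec(default_sigma = 25,
                          sigma = c(r_hand = 60, l_hand = 60),
                          occlusions = list(list(joint = "l_hand",
                                                 from = 40, to = 70,
                                                 confidence = 0.5)),
                          object_in_hand = list(list(hand = "r_hand",
                                                     from = 80, to = 120,
                                                     offset = 400)),
                          seed = 22)
  frames <- corrupt_stream(truth, spec, m)
  res <- filter_stream(frames, m, config = filter_config(substeps = 2))
  for (p in res$key_poses) expect_true(check_pose_validity(res$model, p)$ok)
  for (gap in res$substeps) for (p in gap)
    expect_true(check_pose_validity(res$model, p)$ok)
})
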