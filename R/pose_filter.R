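# Per-frame filtering of tracker streams: confidence gating,
# model-constrained pose estimation, and validated cubic interpolation
# between consecutive key poses.

#' Construct a tracker frame
#'
#' One timestamped set of eight 3D joint centroids with per-joint
#' confidence values, as emitted by an OpenNI-style skeleton tracker.
#' Confidences are restricted to 0 (unreliable), 0.5 (estimated for an
#' occluded centroid) and 1 (correctly perceived). Positions are in
#' millimetres, torso-referenced.
#'
#' @param t Timestamp, seconds.
#' @param positions 8 x 3 matrix with rows in [KIN_JOINTS] order.
#' @param confidence Named numeric vector over [KIN_JOINTS] with values
#'   in `{0, 0.5, 1}`.
#' @return An object of class `tracker_frame`.
#' @export
tracker_frame <- function(t, positions, confidence) {
  if (is.null(rownames(positions))) rownames(positions) <- KIN_JOINTS
  positions <- positions[KIN_JOINTS, , drop = FALSE]
  colnames(positions) <- c("x", "y", "z")
  if (is.null(names(confidence))) names(confidence) <- KIN_JOINTS
  confidence <- confidence[KIN_JOINTS]
  if (!all(confidence %in% c(0, 0.5, 1)))
    stop("tracker_frame: confidence values must be 0, 0.5 or 1",
         call. = FALSE)
  structure(list(t = t, positions = positions, confidence = confidence),
            class = "tracker_frame")
}

#' @export
print.tracker_frame <- function(x, ...) {
  cat(sprintf("<tracker_frame> t = %.3f s, %d/8 full-confidence joints\n",
              x$t, sum(x$confidence == 1)))
  invisible(x)
}

#' Filter configuration
#'
#' @param substeps Interpolation substeps inserted between consecutive
#'   key poses (0 disables interpolation output).
#' @param interpolator `"cubic"` (third-order, 2-sample latency),
#'   `"linear"` (1-sample latency) or `"off"`.
#' @param ee_gate_source Replacement source for low-confidence end
#'   effectors: `"observation"` holds the previous raw centroid (the
#'   literal gating rule) or `"model"` uses the previous model position.
#' @param check_collisions Enforce self-collision constraints in the IK.
#' @param n_swivel Swivel discretization of the IK solver.
#' @param max_ee_speed Smoothness bound on end-effector motion during
#'   occlusion recovery, mm/s: from the frame an end effector is gated
#'   until its model hand has caught up with the observation again, the
#'   hand target may move at most `max_ee_speed * dt` per frame from the
#'   previous model hand. This keeps the output continuous across
#'   re-acquisition snaps without slowing fully observed motion (an
#'   unreachable but observed target still stretches the arm instantly).
#'   Default 3600 mm/s; `Inf` disables the bound.
#' @param learn Run the limb-length learner alongside filtering.
#' @param learner_config See [learner_config()].
#' @return List of class `kin_filter_config`.
#' @export
filter_config <- function(substeps = 4,
                          interpolator = c("cubic", "linear", "off"),
                          ee_gate_source = c("observation", "model"),
                          check_collisions = TRUE,
                          n_swivel = 64,
                          max_ee_speed = 3600,
                          learn = TRUE,
                          learner_config = NULL) {
  if (is.null(learner_config)) learner_config <- kinfilt::learner_config()
  structure(list(substeps = substeps,
                 interpolator = match.arg(interpolator),
                 ee_gate_source = match.arg(ee_gate_source),
                 check_collisions = check_collisions,
                 n_swivel = n_swivel,
                 max_ee_speed = max_ee_speed,
                 learn = learn,
                 learner_config = learner_config),
            class = "kin_filter_config")
}

#' Gate unreliable centroids
#'
#' Joints with confidence below 0.5 are replaced: end effectors by their
#' position in the previous tracker frame (previous observation), and
#' intermediate joints by the model's position in the previous pose.
#' Shoulders, head and torso are passed through; at low confidence they
#' are held from the previous model pose. All other centroids are left
#' untouched.
#'
#' @param frame Current `tracker_frame`.
#' @param previous_frame Previous `tracker_frame` (may be `NULL` on the
#'   first frame, which then passes through unchanged).
#' @param previous_pose Previous `kin_pose` (model positions).
#' @param config A [filter_config()].
#' @return The gated `tracker_frame`; attribute `gated_joints` lists the
#'   joints that were replaced.
#' @export
gate_centroids <- function(frame, previous_frame = NULL,
                           previous_pose = NULL,
                           config = filter_config()) {
  if (is.null(previous_frame) || is.null(previous_pose)) {
    attr(frame, "gated_joints") <- character(0)
    return(frame)
  }
  gated <- character(0)
  pos <- frame$positions
  for (j in KIN_JOINTS) {
    if (frame$confidence[[j]] >= 0.5) next
    if (j %in% KIN_END_EFFECTORS) {
      pos[j, ] <- if (config$ee_gate_source == "observation")
        previous_frame$positions[j, ] else previous_pose$positions[j, ]
    } else {
      pos[j, ] <- previous_pose$positions[j, ]
    }
    gated <- c(gated, j)
  }
  out <- tracker_frame(frame$t, pos, frame$confidence)
  attr(out, "gated_joints") <- gated
  out
}

#' Estimate a valid pose from a gated frame
#'
#' For each arm the hand centroid is clamped into the reachable annulus
#' and solved by analytic IK, with the swivel angle drawn toward the
#' observed elbow centroid; if no constraint-satisfying solution exists
#' the pose is replaced by the closest valid alternative. Elbow (and
#' shoulder/head) positions are read back from the posed model, so the
#' returned pose is valid by construction.
#'
#' @param gated A gated `tracker_frame`.
#' @param model A `kin_model`.
#' @param previous_pose Previous `kin_pose` (continuity); defaults to the
#'   neutral pose.
#' @param config A [filter_config()].
#' @param recovering Named logical (`l`, `r`): sides currently
#'   recovering from an end-effector occlusion, whose hand targets are
#'   speed-limited (see `max_ee_speed`); managed by [filter_stream()].
#' @return A `kin_pose`; attributes `clamped` and `resolved` count the
#'   arms whose target was clamped / whose pose needed replacement.
#' @export
estimate_pose <- function(gated, model, previous_pose = NULL,
                          config = filter_config(),
                          recovering = c(l = FALSE, r = FALSE)) {
  if (is.null(previous_pose)) previous_pose <- neutral_pose(model)
  angles <- previous_pose$angles
  context <- previous_pose$positions
  context["head", ] <- model$offsets$head
  context["l_shoulder", ] <- model$offsets$l_shoulder
  context["r_shoulder", ] <- model$offsets$r_shoulder
  n_clamped <- 0L; n_resolved <- 0L
  capped <- c(l = FALSE, r = FALSE)
  for (side in c("l", "r")) {
    S <- model$offsets[[paste0(side, "_shoulder")]]
    hand_j <- paste0(side, "_hand"); elbow_j <- paste0(side, "_elbow")
    prev_hand <- previous_pose$positions[hand_j, ]
    fb <- prev_hand - S
    if (sqrt(sum(fb^2)) < 1e-9) fb <- c(0, -1, 0)
    raw_target <- gated$positions[hand_j, ]
    dt <- gated$t - previous_pose$timestamp
    if (isTRUE(recovering[[side]]) &&
        is.finite(config$max_ee_speed) && is.finite(dt) && dt > 0) {
      step <- raw_target - prev_hand
      len <- sqrt(sum(step^2))
      cap <- config$max_ee_speed * dt
      if (len > cap) {
        raw_target <- prev_hand + step * (cap / len)
        capped[[side]] <- TRUE
      }
    }
    target <- clamp_to_reachable(S, raw_target,
                                 model$lengths[[paste0(side, "_upper_arm")]],
                                 model$lengths[[paste0(side, "_forearm")]],
                                 fallback_dir = fb)
    if (isTRUE(attr(target, "clamped"))) n_clamped <- n_clamped + 1L
    res <- solve_arm_ik(model, side, S, target, previous_pose,
                        elbow_hint = gated$positions[elbow_j, ],
                        context_positions = context,
                        check_collisions = config$check_collisions,
                        n_swivel = config$n_swivel)
    if (!res$valid) {
      res <- resolve_invalid_pose(model, side, S, target, previous_pose,
                                  elbow_hint = gated$positions[elbow_j, ],
                                  context_positions = context,
                                  check_collisions = config$check_collisions,
                                  n_swivel = config$n_swivel,
                                  skip_direct = TRUE)
      n_resolved <- n_resolved + 1L
    }
    angles[arm_dof_names(side)] <- res$angles
    context[elbow_j, ] <- res$elbow
    context[hand_j, ] <- res$hand
  }
  pose <- new_pose(model, angles, timestamp = gated$t)
  attr(pose, "clamped") <- n_clamped
  attr(pose, "resolved") <- n_resolved
  attr(pose, "speed_capped") <- capped
  pose
}

# Cubic Hermite interpolation of a 3D point between (t0, p0, m0) and
# (t1, p1, m1); slopes in mm/s.
hermite_point <- function(tau, t0, t1, p0, p1, m0, m1) {
  h <- t1 - t0
  s <- (tau - t0) / h
  h00 <- 2 * s^3 - 3 * s^2 + 1
  h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2
  h11 <- s^3 - s^2
  h00 * p0 + h10 * h * m0 + h01 * p1 + h11 * h * m1
}

#' Interpolate validated poses between two key poses
#'
#' End-effector trajectories follow a third-order (cubic Hermite) spline
#' between the two key poses, with knot slopes estimated by finite
#' differences over the last three key points; every substep target is
#' re-solved through the IK pipeline so all emitted poses satisfy joint
#' limits, limb lengths and self-collision constraints. With fewer than
#' two history samples the slopes fall back to linear differences.
#'
#' @param previous_pose,new_pose Consecutive key `kin_pose`s.
#' @param substeps Number of interior samples to emit (0 gives an empty
#'   list).
#' @param model A `kin_model`.
#' @param history Optional list of earlier key poses (the pose before
#'   `previous_pose` last), for the finite-difference slopes.
#' @param config A [filter_config()].
#' @return List of validated `kin_pose`s at the interior times.
#' @export
interpolate_poses <- function(previous_pose, new_pose, substeps, model,
                              history = NULL, config = filter_config()) {
  if (substeps <= 0) return(list())
  t0 <- previous_pose$timestamp; t1 <- new_pose$timestamp
  if (!(t1 > t0)) stop("interpolate_poses: non-increasing timestamps",
                       call. = FALSE)
  linear <- config$interpolator != "cubic"
  p_before <- if (!is.null(history) && length(history))
    history[[length(history)]] else NULL

  slopes <- list()
  for (j in c(KIN_END_EFFECTORS, KIN_INTERMEDIATE)) {
    p0 <- previous_pose$positions[j, ]; p1 <- new_pose$positions[j, ]
    if (linear || is.null(p_before)) {
      m0 <- (p1 - p0) / (t1 - t0); m1 <- m0
    } else {
      tb <- p_before$timestamp
      m0 <- (p1 - p_before$positions[j, ]) / (t1 - tb)  # central at t0
      m1 <- (p1 - p0) / (t1 - t0)                        # backward at t1
    }
    slopes[[j]] <- list(p0 = p0, p1 = p1, m0 = m0, m1 = m1)
  }

  out <- vector("list", substeps)
  prev <- previous_pose
  taus <- t0 + (seq_len(substeps) / (substeps + 1)) * (t1 - t0)
  for (i in seq_along(taus)) {
    tau <- taus[i]
    pos <- prev$positions
    conf <- stats::setNames(rep(1, 8), KIN_JOINTS)
    for (j in names(slopes)) {
      s <- slopes[[j]]
      pos[j, ] <- if (linear)
        s$p0 + (tau - t0) / (t1 - t0) * (s$p1 - s$p0)
      else hermite_point(tau, t0, t1, s$p0, s$p1, s$m0, s$m1)
    }
    frame <- tracker_frame(tau, pos, conf)
    prev <- estimate_pose(frame, model, prev, config)
    out[[i]] <- prev
  }
  out
}

#' Filter a tracker stream into validated poses
#'
#' Runs the full per-frame pipeline over a time-ordered stream: the limb
#' learner consumes the raw centroids while the filter consumes the
#' current length estimates (a deterministic interleave of the two
#' parallel processes); each frame is gated, solved to a valid key pose,
#' and the emitted trajectory is the third-order-interpolated, re-validated
#' sequence. The cubic interpolator needs the slope at the previous knot,
#' so the emitted pose stream lags the input by two samples (one for the
#' linear interpolator, none when interpolation is off).
#'
#' @param frames List of `tracker_frame`s with non-decreasing timestamps.
#' @param model A `kin_model` (updated online when learning is enabled).
#' @param learner Optional list of per-limb [LimbLengthState][new_limb_state]
#'   objects; initialized from the model when `config$learn` is `TRUE`.
#' @param config A [filter_config()].
#' @return A list of class `kin_filter_result`:
#'   \describe{
#'     \item{poses}{emitted pose per input frame (content delayed by the
#'       interpolator latency),}
#'     \item{key_poses}{the undelayed per-frame solved poses,}
#'     \item{substeps}{list of interpolated validated poses per frame gap,}
#'     \item{learner, model}{final learner states and adapted model,}
#'     \item{log}{counts of gated centroids, clamped targets, resolved
#'       poses, learner resets.}
#'   }
#' @export
filter_stream <- function(frames, model, learner = NULL,
                          config = filter_config()) {
  if (length(frames) == 0)
    return(structure(list(poses = list(), key_poses = list(),
                          substeps = list(), learner = learner,
                          model = model,
                          log = list(n_frames = 0L, gated = 0L, clamped = 0L,
                                     resolved = 0L, resets = 0L)),
                     class = "kin_filter_result"))
  ts <- vapply(frames, function(f) f$t, numeric(1))
  if (any(diff(ts) <= 0))
    stop("filter_stream: timestamps must be strictly increasing",
         call. = FALSE)
  if (config$learn && is.null(learner))
    learner <- init_learner(model)

  n <- length(frames)
  key_poses <- vector("list", n)
  substeps <- vector("list", n)
  gated_n <- 0L; clamped_n <- 0L; resolved_n <- 0L; resets_n <- 0L
  prev_frame <- NULL; prev_pose <- NULL
  recovering <- c(l = FALSE, r = FALSE)

  for (k in seq_len(n)) {
    frame <- frames[[k]]
    if (config$learn) {
      st <- learner_step(learner, frame, config$learner_config, model)
      learner <- st$states; model <- st$model
      resets_n <- resets_n + st$resets
    }
    gated <- gate_centroids(frame, prev_frame, prev_pose, config)
    gated_n <- gated_n + length(attr(gated, "gated_joints"))
    for (side in c("l", "r"))
      if (frame$confidence[[paste0(side, "_hand")]] < 0.5)
        recovering[[side]] <- TRUE
    pose <- estimate_pose(gated, model, prev_pose, config, recovering)
    capped <- attr(pose, "speed_capped")
    for (side in c("l", "r"))
      if (recovering[[side]] &&
          frame$confidence[[paste0(side, "_hand")]] >= 0.5 &&
          !isTRUE(capped[[side]]))
        recovering[[side]] <- FALSE  # cap no longer binding: caught up
    clamped_n <- clamped_n + attr(pose, "clamped")
    resolved_n <- resolved_n + attr(pose, "resolved")
    key_poses[[k]] <- pose

    if (k > 1 && config$substeps > 0 && config$interpolator != "off") {
      hist <- if (k > 2) key_poses[k - 2] else NULL
      substeps[[k]] <- interpolate_poses(key_poses[[k - 1]], pose,
                                         config$substeps, model,
                                         history = hist, config = config)
    } else {
      substeps[[k]] <- list()
    }
    prev_frame <- frame
    prev_pose <- pose
  }

  delay <- switch(config$interpolator, cubic = 2L, linear = 1L, off = 0L)
  poses <- key_poses[pmax(seq_len(n) - delay, 1L)]

  structure(list(poses = poses, key_poses = key_poses, substeps = substeps,
                 learner = learner, model = model,
                 log = list(n_frames = n, gated = gated_n,
                            clamped = clamped_n, resolved = resolved_n,
                            resets = resets_n, delay = delay)),
            class = "kin_filter_result")
}

#' @export
print.kin_filter_result <- function(x, ...) {
  l <- x$log
  cat(sprintf(paste0("<kin_filter_result> %d frames (delay %d), ",
                     "%d gated centroids, %d clamped targets, ",
                     "%d resolved poses, %d learner resets\n"),
              l$n_frames, l$delay, l$gated, l$clamped, l$resolved, l$resets))
  invisible(x)
}
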