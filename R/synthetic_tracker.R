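# Synthetic tracker: generates ground-truth upper-body motion and
# corrupts it into OpenNI-style centroid streams exhibiting the
# documented depth-tracker failure modes (occlusions, depth hijacking,
# object-in-hand length inflation, extension-dependent elbow
# oscillation). Also labels and scores sequences by camera-distance
# region categories.

#' Corruption specification for the synthetic tracker
#'
#' @param sigma Named per-joint Gaussian noise SD (mm per axis); joints
#'   not named get `default_sigma`.
#' @param default_sigma Fallback noise SD, mm.
#' @param occlusions List of events `list(joint=, from=, to=,
#'   confidence=)` (frame interval, confidence 0 or 0.5). Occluded
#'   centroids freeze at the last visible observation; at confidence 0.5
#'   they additionally drift (the tracker's own estimate of an occluded
#'   centroid is emulated by a slow random walk).
#' @param depth_hijack List of events `list(hand=, from=, to=, donor=)`:
#'   within the interval the hand centroid keeps full confidence but its
#'   camera-axis coordinate is replaced by the donor joint's (the tracker
#'   does not consider the centroid lost and takes depth from the
#'   occluding part).
#' @param object_in_hand List of events `list(hand=, from=, to=,
#'   offset=)`: the hand centroid is displaced `offset` mm along the
#'   forearm axis (a held object inflating the apparent forearm).
#' @param elbow_extension_gain Gain g of the extension-dependent elbow
#'   noise: the elbow SD is multiplied by `1 + g * r` with
#'   `r = |hand - shoulder| / (l_upper + l_fore)` (oscillation grows as
#'   the arm stretches).
#' @param drift_sigma Random-walk step SD (mm) for confidence-0.5
#'   occlusions.
#' @param seed Integer seed; corruption is bitwise reproducible.
#' @return List of class `corruption_spec`.
#' @export
corruption_spec <- function(sigma = c(), default_sigma = 0,
                            occlusions = list(), depth_hijack = list(),
                            object_in_hand = list(),
                            elbow_extension_gain = 0,
                            drift_sigma = 5, seed = 1) {
  s <- stats::setNames(rep(default_sigma, 8), KIN_JOINTS)
  if (length(sigma)) s[names(sigma)] <- sigma
  if (any(s < 0)) stop("noise sigma must be >= 0", call. = FALSE)
  structure(list(sigma = s, occlusions = occlusions,
                 depth_hijack = depth_hijack,
                 object_in_hand = object_in_hand,
                 elbow_extension_gain = elbow_extension_gain,
                 drift_sigma = drift_sigma, seed = seed),
            class = "corruption_spec")
}

# Smooth scalar way-point interpolation helper: cubic spline through
# way values at way times, evaluated at t.
way_spline <- function(way_t, way_v, t)
  stats::spline(way_t, way_v, xout = t, method = "natural")$y

# Motion boxes (degrees) for angle-space presets; right-side abduction
# is mirrored in sign.
motion_angle_box <- function(dof, active) {
  if (!active) {
    lo <- c(abd = 2, sag = -8, rot = -10, flex = 10)
    hi <- c(abd = 12, sag = 8, rot = 10, flex = 30)
  } else {
    lo <- c(abd = -20, sag = -110, rot = -50, flex = 15)
    hi <- c(abd = 110, sag = 25, rot = 50, flex = 120)
  }
  kind <- sub(".*_(abd|sag|rot|flex)$", "\\1", dof)
  sgn <- if (startsWith(dof, "r_") && kind == "abd") -1 else 1
  sort(sgn * c(lo[[kind]], hi[[kind]]))
}

generate_angle_motion <- function(model, n, rate, active_sides,
                                  waypoint_dt = 1) {
  t <- (seq_len(n) - 1) / rate
  nway <- max(4, ceiling(t[n] / waypoint_dt) + 1)
  way_t <- seq(0, t[n], length.out = nway)
  boxes <- lapply(KIN_DOFS, function(dof)
    motion_angle_box(dof, substr(dof, 1, 1) %in% active_sides))
  names(boxes) <- KIN_DOFS
  # inflated proxies: margin for the interpolated path between way-poses
  mi <- model; mi$radii <- mi$radii * 1.25
  draw_way <- function() {
    for (try in 1:200) {
      w <- vapply(KIN_DOFS, function(dof)
        stats::runif(1, boxes[[dof]][1], boxes[[dof]][2]), numeric(1))
      if (nrow(detect_self_collisions(mi, forward_kinematics(model, w)))
          == 0) return(w)
    }
    stop("generate_motion: could not draw a collision-free way-pose",
         call. = FALSE)
  }
  for (attempt in 1:25) {
    ways <- t(vapply(seq_len(nway), function(i) draw_way(),
                     numeric(length(KIN_DOFS))))
    colnames(ways) <- KIN_DOFS
    ang <- sapply(KIN_DOFS, function(dof) way_spline(way_t, ways[, dof], t))
    ang <- pmin(pmax(ang, matrix(model$limits[KIN_DOFS, 1], n,
                                 length(KIN_DOFS), byrow = TRUE)),
                matrix(model$limits[KIN_DOFS, 2], n, length(KIN_DOFS),
                       byrow = TRUE))
    poses <- lapply(seq_len(n), function(i)
      new_pose(model, ang[i, ], timestamp = t[i]))
    valid <- all(vapply(poses, function(p)
      check_pose_validity(model, p)$ok, logical(1)))
    if (valid) return(poses)
  }
  stop("generate_motion: could not draw a collision-free sequence",
       call. = FALSE)
}

# Task-space preset: the right hand cycles front -> around the side ->
# behind the torso and back, the way a person actually hides a hand
# behind the back; truth poses are produced by the analytic IK (with
# collision avoidance) so every frame is valid by construction.
generate_torso_reach <- function(model, n, rate) {
  t <- (seq_len(n) - 1) / rate
  S <- model$offsets$r_shoulder
  a <- model$lengths[["r_upper_arm"]]; b <- model$lengths[["r_forearm"]]
  r_clear <- model$radii[["radius_torso"]] +
    model$radii[["radius_forearm"]] + 40
  front  <- c(S[1] + 60, S[2] - 260, 300)
  side   <- c(S[1] - 160, S[2] - 280, 40)   # lateral, outside the trunk
  behind <- c(S[1] + 110, S[2] - 230, -r_clear)
  period <- 8  # seconds for a full front -> behind -> front cycle
  phase <- stats::runif(1, 0, 2 * pi)
  prev <- neutral_pose(model)
  poses <- vector("list", n)
  for (i in seq_len(n)) {
    w <- (1 - cos(2 * pi * t[i] / period + phase)) / 2  # 0 front, 1 behind
    target <- if (w < 0.5) (1 - 2 * w) * front + 2 * w * side
              else (2 - 2 * w) * side + (2 * w - 1) * behind
    target <- clamp_to_reachable(S, target, a, b)
    res <- solve_arm_ik(model, "r", S, target, prev)
    if (!res$valid)
      res <- resolve_invalid_pose(model, "r", S, target, prev,
                                  skip_direct = TRUE)
    ang <- prev$angles
    ang[arm_dof_names("r")] <- res$angles
    poses[[i]] <- new_pose(model, ang, timestamp = t[i])
    prev <- poses[[i]]
  }
  poses
}

#' Generate ground-truth upper-body motion
#'
#' Draws smooth joint-angle trajectories (cubic splines through random
#' way-poses inside the joint limits, rejection-sampled for
#' collision-freeness) or, for the `torso_reach` preset, a task-space
#' reach cycle solved by the analytic IK. Deterministic under `seed`.
#'
#' @param model A `kin_model`.
#' @param duration Sequence duration, seconds.
#' @param rate Sampling rate, Hz.
#' @param motion_spec One of `"free_arms"` (both arms move),
#'   `"right_arm_reach"` (right arm moves, left near neutral; mirrors a
#'   free right-arm gesture protocol), `"torso_reach"` (right hand
#'   repeatedly hidden behind the torso).
#' @param seed Integer seed.
#' @return List of valid `kin_pose`s, one per frame.
#' @export
generate_motion <- function(model, duration, rate,
                            motion_spec = c("free_arms", "right_arm_reach",
                                            "torso_reach"),
                            seed = 1) {
  motion_spec <- match.arg(motion_spec)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  n <- round(duration * rate)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  switch(motion_spec,
         free_arms = generate_angle_motion(model, n, rate, c("l", "r")),
         right_arm_reach = generate_angle_motion(model, n, rate, "r"),
         torso_reach = generate_torso_reach(model, n, rate))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Corrupt a truth sequence into a tracker stream
#'
#' Adds per-joint Gaussian centroid noise (with the extension-dependent
#' elbow gain), then applies the configured failure events: occlusions
#' (confidence 0 or 0.5 with frozen/drifting stale positions), depth
#' hijacking (the hand's camera-axis coordinate replaced by a donor
#' joint's) and object-in-hand displacement along the forearm axis. The
#' truth sequence is not modified; re-running with the same spec is
#' bitwise identical.
#'
#' @param truth List of `kin_pose`s (see [generate_motion()]).
#' @param spec A [corruption_spec()].
#' @param model The `kin_model` used for the extension ratio (needed only
#'   when `elbow_extension_gain > 0`).
#' @return List of `tracker_frame`s.
#' @export
corrupt_stream <- function(truth, spec, model = NULL) {
  n <- length(truth)
  for (ev in c(spec$occlusions, spec$depth_hijack, spec$object_in_hand))
    if (ev$from < 1 || ev$to > n || ev$from > ev$to)
      stop("corrupt_stream: event interval outside the sequence",
           call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  frames <- vector("list", n)
  last_visible <- NULL
  drift <- stats::setNames(vector("list", 8), KIN_JOINTS)
  for (k in seq_len(n)) {
    tp <- truth[[k]]
    pos <- tp$positions
    conf <- stats::setNames(rep(1, 8), KIN_JOINTS)
    # Gaussian centroid noise, elbow SD scaled with arm extension
    for (j in KIN_JOINTS) {
      s <- spec$sigma[[j]]
      if (j %in% KIN_INTERMEDIATE && spec$elbow_extension_gain > 0 &&
          !is.null(model)) {
        side <- substr(j, 1, 1)
        reach <- model$lengths[[paste0(side, "_upper_arm")]] +
          model$lengths[[paste0(side, "_forearm")]]
        ext <- sqrt(sum((tp$positions[paste0(side, "_hand"), ] -
                         tp$positions[paste0(side, "_shoulder"), ])^2))
        s <- s * (1 + spec$elbow_extension_gain * min(ext / reach, 1))
      }
      if (s > 0) pos[j, ] <- pos[j, ] + stats::rnorm(3, 0, s)
    }
    # object in hand: displacement along the forearm axis
    for (ev in spec$object_in_hand) {
      if (k < ev$from || k > ev$to) next
      side <- substr(ev$hand, 1, 1)
      ax <- tp$positions[ev$hand, ] -
        tp$positions[paste0(side, "_elbow"), ]
      ax <- ax / sqrt(sum(ax^2))
      pos[ev$hand, ] <- pos[ev$hand, ] + ev$offset * ax
    }
    # depth hijack: camera-axis (z) coordinate taken from the donor
    for (ev in spec$depth_hijack) {
      if (k < ev$from || k > ev$to) next
      pos[ev$hand, "z"] <- pos[ev$donor, "z"]
    }
    # occlusions: stale positions, lowered confidence
    for (ev in spec$occlusions) {
      if (k < ev$from || k > ev$to) next
      j <- ev$joint
      conf[j] <- ev$confidence
      stale <- if (!is.null(last_visible)) last_visible[j, ] else pos[j, ]
      if (ev$confidence == 0.5) {
        if (is.null(drift[[j]])) drift[[j]] <- c(0, 0, 0)
        drift[[j]] <- drift[[j]] + stats::rnorm(3, 0, spec$drift_sigma)
        pos[j, ] <- stale + drift[[j]]
      } else {
        pos[j, ] <- stale
      }
    }
    for (j in KIN_JOINTS) if (conf[[j]] == 1) drift[[j]] <- NULL
    frames[[k]] <- tracker_frame(tp$timestamp, pos, conf)
    lv <- pos
    if (!is.null(last_visible))
      for (j in KIN_JOINTS) if (conf[[j]] < 1) lv[j, ] <- last_visible[j, ]
    last_visible <- lv
  }
  frames
}

#' Frames in which a joint is occluded by the trunk from the camera
#'
#' A hand is depth-hijacked by the torso exactly while it is hidden
#' behind the trunk as seen from the camera: laterally inside the trunk
#' silhouette and farther from the camera than the trunk front. This
#' helper derives those contiguous frame intervals from a truth sequence,
#' ready to be used as `depth_hijack` (or occlusion) events in a
#' [corruption_spec()].
#'
#' @param truth List of `kin_pose`s.
#' @param model The `kin_model` (trunk silhouette radius).
#' @param joint Joint to test (default `"r_hand"`).
#' @param donor Donor joint whose camera depth the tracker reports
#'   (default `"torso"`).
#' @return List of `list(hand=, from=, to=, donor=)` events (possibly
#'   empty).
#' @export
camera_occluded_intervals <- function(truth, model, joint = "r_hand",
                                      donor = "torso") {
  r_sil <- model$radii[["radius_torso"]]
  occ <- which(vapply(truth, function(p) {
    h <- p$positions[joint, ]
    abs(h[1]) < r_sil && h[3] < 0
  }, logical(1)))
  if (!length(occ)) return(list())
  runs <- split(occ, cumsum(c(1, diff(occ) != 1)))
  unname(lapply(runs, function(ix)
    list(hand = joint, from = min(ix), to = max(ix), donor = donor)))
}

# Extract an n x 3 position matrix list from poses / frames / matrices.
positions_of <- function(seq) {
  lapply(seq, function(e) {
    if (inherits(e, "kin_pose") || inherits(e, "tracker_frame")) e$positions
    else e
  })
}

#' Label joint regions relative to a reference joint
#'
#' For each frame, each labeled joint is categorized as `behind`,
#' `aligned` or `in_front` of the reference joint by thresholding the
#' difference of their Euclidean distances to the camera: farther than
#' the reference by more than `theta_d` mm is `behind`, closer by more
#' than `theta_d` is `in_front`, otherwise `aligned`.
#'
#' @param seq List of `kin_pose`s, `tracker_frame`s or 8 x 3 matrices.
#' @param joints Joints to label (e.g. `c("r_hand", "l_hand")`).
#' @param reference Reference joint (`"head"` or `"torso"`).
#' @param theta_d Threshold, mm.
#' @param camera Camera position in the torso frame (mm); default 1.7 m
#'   toward the sensor on +z.
#' @param farther_is_behind Sign convention: farther from the camera
#'   means behind (default).
#' @return Data frame: `frame`, `joint`, `category` (factor with levels
#'   behind/aligned/in_front).
#' @export
label_regions <- function(seq, joints, reference, theta_d,
                          camera = c(0, 0, 1700),
                          farther_is_behind = TRUE) {
  pos <- positions_of(seq)
  rows <- vector("list", length(pos) * length(joints))
  i <- 0
  for (k in seq_along(pos)) {
    P <- pos[[k]]
    dref <- sqrt(sum((P[reference, ] - camera)^2))
    for (j in joints) {
      d <- sqrt(sum((P[j, ] - camera)^2)) - dref
      if (!farther_is_behind) d <- -d
      cat_ <- if (d > theta_d) "behind"
              else if (d < -theta_d) "in_front" else "aligned"
      i <- i + 1
      rows[[i]] <- data.frame(frame = k, joint = j, category = cat_,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$category <- factor(out$category,
                         levels = c("behind", "aligned", "in_front"))
  out
}

#' Score estimated positions against region labels
#'
#' A joint is successfully estimated for a frame when the category of
#' its estimated position (computed by [label_regions()] with the same
#' reference, threshold and camera) matches the truth label.
#'
#' @param est_seq Estimated sequence (poses, frames or matrices), frame
#'   aligned with the labels.
#' @param labels Truth labels from [label_regions()].
#' @param reference,theta_d,camera,farther_is_behind As in
#'   [label_regions()].
#' @return List with `per_joint` (data frame: joint, n, correct, pct)
#'   and `overall` (percentage), plus `n_frames`.
#' @export
evaluate_categories <- function(est_seq, labels, reference, theta_d,
                                camera = c(0, 0, 1700),
                                farther_is_behind = TRUE) {
  joints <- unique(labels$joint)
  n_frames <- max(labels$frame)
  if (length(est_seq) != n_frames)
    stop("evaluate_categories: estimate/label length mismatch",
         call. = FALSE)
  est_lab <- label_regions(est_seq, joints, reference, theta_d, camera,
                           farther_is_behind)
  key <- paste(labels$frame, labels$joint)
  est_lab <- est_lab[match(key, paste(est_lab$frame, est_lab$joint)), ]
  hit <- as.character(est_lab$category) == as.character(labels$category)
  per <- do.call(rbind, lapply(joints, function(j) {
    sel <- labels$joint == j
    data.frame(joint = j, n = sum(sel), correct = sum(hit[sel]),
               pct = 100 * mean(hit[sel]), stringsAsFactors = FALSE)
  }))
  list(per_joint = per, overall = 100 * mean(hit), n_frames = n_frames)
}
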