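# Shared fixtures and independent oracles for the test suite.

test_model <- function(H = 1750) build_default_model(H)

arm_dofs <- function(side)
  paste0(side, c("_shoulder_abd", "_shoulder_sag", "_shoulder_rot",
                 "_elbow_flex"))

# FK of a single arm from its four angles, everything else neutral.
arm_fk <- function(model, side, angles4) {
  ang <- neutral_pose(model)$angles
  ang[arm_dofs(side)] <- angles4
  forward_kinematics(model, ang)
}

# Draw a random hand target in the reachable annulus of `side`.
random_reachable_target <- function(model, side) {
  S <- model$offsets[[paste0(side, "_shoulder")]]
  a <- model$lengths[[paste0(side, "_upper_arm")]]
  b <- model$lengths[[paste0(side, "_forearm")]]
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  d <- stats::runif(1, abs(a - b) + 2, a + b - 1e-6)
  S + d * dir
}

# Independent numerical IK oracle: box-constrained quasi-Newton
# minimisation of a heavily weighted hand-target error plus the
# elbow-hint distance that selects the swivel, from several starting
# points. The hand weight keeps the target binding while the elbow term
# retains O(1) gradients so the optimizer slides along the solution
# manifold to the swivel optimum.
numeric_ik <- function(model, side, target, hint, n_starts = 8,
                       w_hand = 1e6) {
  dofs <- arm_dofs(side)
  lo <- model$limits[dofs, 1]; hi <- model$limits[dofs, 2]
  obj <- function(th) {
    p <- arm_fk(model, side, th)
    w_hand * sum((p[paste0(side, "_hand"), ] - target)^2) +
      sum((p[paste0(side, "_elbow"), ] - hint)^2)
  }
  starts <- lapply(seq_len(n_starts), function(i)
    stats::runif(4, lo, hi))
  starts[[n_starts + 1]] <- pmin(pmax(rep(0, 4), lo), hi)
  best <- NULL
  for (s in starts) {
    r <- tryCatch(stats::optim(s, obj, method = "L-BFGS-B",
                               lower = lo, upper = hi,
                               control = list(maxit = 1000,
                                              factr = 1e2)),
                  error = function(e) NULL)
    if (!is.null(r) && (is.null(best) || r$value < best$value)) best <- r
  }
  best$par
}

# Geodesic angle (degrees) between two rotation matrices.
rotation_angle_deg <- function(R1, R2) {
  tr <- sum(diag(t(R1) %*% R2))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

shoulder_rotation <- function(angles4)
  rot_z(angles4[[1]]) %*% rot_x(angles4[[2]]) %*% rot_y(angles4[[3]])

# Brute-force minimum distance between two segments on a parameter grid
# (independent of the closed-form implementation).
brute_segment_distance <- function(p1, q1, p2, q2, n = 201) {
  s <- seq(0, 1, length.out = n)
  A <- outer(1 - s, p1) + outer(s, q1)   # n x 3
  B <- outer(1 - s, p2) + outer(s, q2)
  m <- Inf
  for (i in seq_len(n)) {
    d2 <- rowSums((B - matrix(A[i, ], n, 3, byrow = TRUE))^2)
    m <- min(m, min(d2))
  }
  sqrt(m)
}

# A clean tracker stream (confidence 1, no noise) from a truth sequence.
frames_from_truth <- function(truth) {
  lapply(truth, function(p)
    tracker_frame(p$timestamp, p$positions,
                  stats::setNames(rep(1, 8), KIN_JOINTS)))
}

joint_trajectory <- function(seq, joint) {
  t(vapply(seq, function(e) {
    pos <- if (inherits(e, "kin_pose") || inherits(e, "tracker_frame"))
      e$positions else e
    pos[joint, ]
  }, numeric(3)))
}

rms <- function(x) sqrt(mean(x^2))
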