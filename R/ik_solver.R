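# Analytic arm inverse kinematics with joint limits, reachability
# clamping, swivel redundancy and invalid-pose replacement.
#
# Each arm is a 4-DOF chain (3 shoulder rotations + elbow flexion). Given
# shoulder S and hand target W the elbow flexion follows from the law of
# cosines and the remaining freedom is the swivel angle psi of the elbow
# on its circle about the S-W axis. The solver picks the swivel closest
# to a hint (the observed elbow centroid, or the previous pose) and
# falls back to a discretized swivel search filtered by joint limits and
# self-collisions.

IK_INNER_EPS <- 1  # mm added to the inner reach boundary (singularity guard)

#' Clamp a hand target into the reachable annulus
#'
#' The reachable hand positions lie between `|l_upper - l_fore| + eps`
#' and `l_upper + l_fore` from the shoulder. Targets outside (e.g. an
#' object held in the hand inflating the apparent arm) are projected onto
#' the violated boundary along the shoulder-to-target ray, so the arm
#' stretches fully toward the target but stays kinematically coherent.
#'
#' @param shoulder_pos,target_pos 3-vectors, mm.
#' @param l_upper,l_fore Segment lengths, mm (positive).
#' @param fallback_dir Unit direction used when the target coincides with
#'   the shoulder (direction undefined); defaults to straight down.
#' @param eps Inner-boundary margin, mm.
#' @return Clamped 3-vector (attribute `clamped` records whether the
#'   target moved).
#' @export
clamp_to_reachable <- function(shoulder_pos, target_pos, l_upper, l_fore,
                               fallback_dir = c(0, -1, 0),
                               eps = IK_INNER_EPS) {
  stopifnot(l_upper > 0, l_fore > 0)
  v <- target_pos - shoulder_pos
  d <- sqrt(sum(v * v))
  outer <- l_upper + l_fore
  inner <- abs(l_upper - l_fore)
  inner <- if (inner > 0) inner + eps else 0
  if (d < 1e-9) {
    if (inner <= 0) return(structure(target_pos, clamped = FALSE))
    u <- fallback_dir / sqrt(sum(fallback_dir^2))
    return(structure(shoulder_pos + inner * u, clamped = TRUE))
  }
  u <- v / d
  if (d > outer)
    return(structure(shoulder_pos + outer * u, clamped = TRUE))
  if (d < inner)
    return(structure(shoulder_pos + inner * u, clamped = TRUE))
  structure(target_pos, clamped = FALSE)
}

# Elbow circle for shoulder S, hand W, lengths a (upper) and b (fore):
# centre C on the S->W axis, radius r, orthonormal in-plane basis
# (n1, n2) with n1 the projection of global down onto the plane.
elbow_circle <- function(S, W, a, b) {
  v <- W - S
  d <- sqrt(sum(v * v))
  u <- v / d
  along <- (a^2 - b^2 + d^2) / (2 * d)
  r2 <- a^2 - along^2
  r <- if (r2 > 0) sqrt(r2) else 0
  refs <- list(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  n1 <- NULL
  for (ref in refs) {
    w <- ref - sum(ref * u) * u
    nw <- sqrt(sum(w * w))
    if (nw > 1e-6) { n1 <- w / nw; break }
  }
  n2 <- c(u[2] * n1[3] - u[3] * n1[2],
          u[3] * n1[1] - u[1] * n1[3],
          u[1] * n1[2] - u[2] * n1[1])
  list(center = S + along * u, radius = r, u = u, n1 = n1, n2 = n2, d = d)
}

elbow_at_swivel <- function(circle, psi_deg) {
  p <- psi_deg * pi / 180
  circle$center + circle$radius * (cos(p) * circle$n1 + sin(p) * circle$n2)
}

swivel_of_point <- function(circle, point) {
  w <- point - circle$center
  atan2(sum(w * circle$n2), sum(w * circle$n1)) * 180 / pi
}

wrap180 <- function(a) ((a + 180) %% 360) - 180

# Shoulder + elbow angles from joint positions. Returns the Euler
# branches for the (abd, sag) decomposition of the upper-arm direction;
# the axial angle and elbow flexion are completed per branch.
arm_angles_from_positions <- function(S, E, W, prev_rot = 0) {
  u1 <- E - S; u1 <- u1 / sqrt(sum(u1 * u1))
  u2 <- W - E; n2 <- sqrt(sum(u2 * u2))
  u2 <- if (n2 > 1e-9) u2 / n2 else u1
  sag1 <- asin(max(-1, min(1, -u1[3]))) * 180 / pi
  abd1 <- atan2(u1[1], -u1[2]) * 180 / pi
  branches <- list(c(abd1, sag1),
                   c(wrap180(abd1 + 180),
                     if (sag1 >= 0) 180 - sag1 else -180 - sag1))
  out <- vector("list", 2)
  for (i in 1:2) {
    abd <- branches[[i]][1]; sag <- branches[[i]][2]
    Q <- rot_z(abd) %*% rot_x(sag)
    v <- drop(t(Q) %*% u2)
    flex <- atan2(sqrt(v[1]^2 + v[3]^2), -v[2]) * 180 / pi
    rot <- if (sqrt(v[1]^2 + v[3]^2) > 1e-7) atan2(v[1], v[3]) * 180 / pi
           else prev_rot
    if (flex < 0 && flex > -1e-9) flex <- 0
    out[[i]] <- c(abd = abd, sag = sag, rot = rot, flex = flex)
  }
  out
}

arm_dof_names <- function(side)
  paste0(side, c("_shoulder_abd", "_shoulder_sag", "_shoulder_rot",
                 "_elbow_flex"))

angles_within_limits <- function(angles4, limits4, tol = 1e-7) {
  all(angles4 >= limits4[, 1] - tol & angles4 <= limits4[, 2] + tol)
}

# Collision test for one arm candidate: this side's upper arm and
# forearm, posed at (S, E, W), against every non-adjacent body posed
# from base_positions. Lean inline version of the two-level test used in
# the IK hot path (same adjacency rule and capsule maths as
# detect_self_collisions, which remains the audit-grade entry point).
arm_collides <- function(model, side, S, E, W, base_positions) {
  other <- if (side == "l") "r" else "l"
  S2 <- base_positions[paste0(other, "_shoulder"), ]
  E2 <- base_positions[paste0(other, "_elbow"), ]
  W2 <- base_positions[paste0(other, "_hand"), ]
  head <- model$offsets$head
  r <- model$radii
  ru <- r[["radius_upper_arm"]]; rf <- r[["radius_forearm"]]
  rh <- r[["radius_head"]]; rt <- r[["radius_torso"]]
  # own upper arm vs head, other upper arm, other forearm
  if (segment_segment_distance(S, E, head, head) <= ru + rh) return(TRUE)
  if (segment_segment_distance(S, E, S2, E2) <= ru + ru) return(TRUE)
  if (segment_segment_distance(S, E, E2, W2) <= ru + rf) return(TRUE)
  # own forearm vs trunk, head, other upper arm, other forearm
  if (segment_segment_distance(E, W, model$trunk$lower,
                               model$trunk$upper) <= rf + rt) return(TRUE)
  if (segment_segment_distance(E, W, head, head) <= rf + rh) return(TRUE)
  if (segment_segment_distance(E, W, S2, E2) <= rf + ru) return(TRUE)
  if (segment_segment_distance(E, W, E2, W2) <= rf + rf) return(TRUE)
  FALSE
}

#' Solve the arm inverse kinematics analytically
#'
#' Places the hand of one arm at `hand_target` (which must already lie in
#' the reachable annulus, see [clamp_to_reachable()]). Elbow flexion
#' follows from the law of cosines; the redundant swivel angle is chosen
#' as close as possible to `elbow_hint` (e.g. the tracker's elbow
#' centroid) or, failing that, to the previous pose's elbow, and is
#' discretized (`n_swivel` samples) when the preferred swivel violates
#' joint limits or self-collision constraints.
#'
#' @param model A `kin_model`.
#' @param side `"l"` or `"r"`.
#' @param shoulder_pos Shoulder position (defaults to the model offset).
#' @param hand_target Desired hand position, mm, already clamped.
#' @param previous_pose Previous `kin_pose` (swivel continuity and angle
#'   fallbacks); defaults to the neutral pose.
#' @param elbow_hint Optional observed elbow position; the swivel is
#'   chosen to bring the model elbow as close as possible to it.
#' @param context_positions 8 x 3 positions used to pose the *other*
#'   bodies for collision checking; defaults to `previous_pose$positions`.
#' @param check_collisions Test candidate poses for self-collision.
#' @param n_swivel Number of discretized swivel candidates.
#' @return A list with `valid` (logical), `angles` (the four arm DOFs,
#'   degrees), `elbow`, `hand`, `swivel`. When no swivel satisfies the
#'   constraints, `valid` is `FALSE` and the caller should use
#'   [resolve_invalid_pose()].
#' @export
solve_arm_ik <- function(model, side, shoulder_pos = NULL, hand_target,
                         previous_pose = NULL, elbow_hint = NULL,
                         context_positions = NULL, check_collisions = TRUE,
                         n_swivel = 64) {
  stopifnot(side %in% c("l", "r"))
  if (is.null(previous_pose)) previous_pose <- neutral_pose(model)
  if (is.null(shoulder_pos))
    shoulder_pos <- model$offsets[[paste0(side, "_shoulder")]]
  if (is.null(context_positions)) context_positions <- previous_pose$positions
  a <- model$lengths[[paste0(side, "_upper_arm")]]
  b <- model$lengths[[paste0(side, "_forearm")]]
  dofs <- arm_dof_names(side)
  limits4 <- model$limits[dofs, , drop = FALSE]
  prev4 <- previous_pose$angles[dofs]

  circ <- elbow_circle(shoulder_pos, hand_target, a, b)

  # The elbow flexion is fixed by the shoulder-hand distance (law of
  # cosines); if it violates its limits no swivel can help.
  cosg <- (a^2 + b^2 - circ$d^2) / (2 * a * b)
  flex_req <- 180 - acos(max(-1, min(1, cosg))) * 180 / pi
  flim <- limits4[4, ]
  if (flex_req < flim[1] - 1e-7 || flex_req > flim[2] + 1e-7)
    return(list(valid = FALSE, reason = "elbow flexion out of limits"))

  # Straight (or fully folded) arm: the elbow is collinear, the swivel
  # has no positional effect.
  if (circ$radius < 1e-7) {
    E <- circ$center
    cands <- arm_angles_from_positions(shoulder_pos, E, hand_target,
                                       prev_rot = prev4[[3]])
    for (ang in cands) {
      if (!angles_within_limits(ang, limits4)) next
      if (check_collisions &&
          arm_collides(model, side, shoulder_pos, E, hand_target,
                       context_positions)) next
      return(list(valid = TRUE,
                  angles = stats::setNames(ang, dofs),
                  elbow = E, hand = hand_target, swivel = NA_real_))
    }
    return(list(valid = FALSE, reason = "no limit-satisfying solution"))
  }

  hint_point <- elbow_hint
  if (is.null(hint_point))
    hint_point <- previous_pose$positions[paste0(side, "_elbow"), ]
  psi_star <- swivel_of_point(circ, hint_point)
  if (!is.finite(psi_star)) psi_star <- 0

  step <- 360 / n_swivel
  k <- seq_len(n_swivel %/% 2)
  # candidates ordered by |swivel change|; ties: positive offset first
  offsets <- c(0, as.vector(rbind(k * step, -k * step)))
  offsets <- offsets[offsets > -180 - 1e-9 & offsets <= 180]

  for (off in offsets) {
    psi <- psi_star + off
    E <- elbow_at_swivel(circ, psi)
    cands <- arm_angles_from_positions(shoulder_pos, E, hand_target,
                                       prev_rot = prev4[[3]])
    for (ang in cands) {
      if (!angles_within_limits(ang, limits4)) next
      if (check_collisions &&
          arm_collides(model, side, shoulder_pos, E, hand_target,
                       context_positions)) next
      return(list(valid = TRUE,
                  angles = stats::setNames(ang, dofs),
                  elbow = E, hand = hand_target, swivel = wrap180(psi)))
    }
  }
  list(valid = FALSE, reason = "no limit-satisfying swivel")
}

#' Check the validity of a full pose
#'
#' A pose is valid iff every joint angle lies within its limit interval
#' and [detect_self_collisions()] reports no colliding pair.
#'
#' @param model A `kin_model`.
#' @param pose A `kin_pose`.
#' @return List with `limit_violations` (data frame: dof, angle, min,
#'   max), `collisions` (data frame of body pairs) and `ok` (logical).
#' @export
check_pose_validity <- function(model, pose) {
  ang <- pose$angles[KIN_DOFS]
  tol <- 1e-7
  bad <- which(ang < model$limits[, 1] - tol | ang > model$limits[, 2] + tol)
  lv <- data.frame(dof = KIN_DOFS[bad], angle = unname(ang[bad]),
                   min = unname(model$limits[bad, 1]),
                   max = unname(model$limits[bad, 2]),
                   stringsAsFactors = FALSE)
  col <- detect_self_collisions(model, pose)
  list(limit_violations = lv, collisions = col,
       ok = nrow(lv) == 0 && nrow(col) == 0)
}

# Feasible hand-shoulder distance range once the elbow flexion limit is
# honoured (flexion <= max shortens how close the hand may come).
feasible_reach <- function(model, side) {
  a <- model$lengths[[paste0(side, "_upper_arm")]]
  b <- model$lengths[[paste0(side, "_forearm")]]
  fmax <- model$limits[paste0(side, "_elbow_flex"), 2]
  gamma_min <- (180 - fmax) * pi / 180
  dmin <- sqrt(max(a^2 + b^2 - 2 * a * b * cos(gamma_min),
                   (abs(a - b) + IK_INNER_EPS)^2))
  c(dmin, a + b)
}

# 26 unit directions on the {-1,0,1}^3 grid, fixed order.
resolve_directions <- function() {
  g <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  g <- g[rowSums(abs(g)) > 0, ]
  m <- as.matrix(g)
  m / sqrt(rowSums(m^2))
}

#' Replace an invalid arm pose by the closest valid alternative
#'
#' When [solve_arm_ik()] finds no swivel satisfying joint limits and
#' collision constraints, the hand target is replaced deterministically.
#' Temporal coherence is tried first: the target is pulled back along the
#' straight path from the previous hand position (bisection), which stops
#' the hand at the obstacle surface it would otherwise pass through -- an
#' occluded hand held behind the head or torso therefore stays behind it
#' instead of teleporting to the geometrically nearest free spot. If no
#' point on that path is feasible the target is moved over an expanding
#' candidate grid (radial push-outs to the flexion-feasible range first,
#' then spherical offsets of growing radius) and the first candidate
#' admitting a valid solution -- the one closest to the desired position
#' among those evaluated, near-ties broken toward the previous hand --
#' is returned. The neutral arm configuration is the final fallback.
#'
#' @inheritParams solve_arm_ik
#' @param skip_direct Skip the initial attempt at the unmodified target
#'   (used by callers that just saw it fail).
#' @return Same shape as [solve_arm_ik()], always with `valid = TRUE`.
#' @export
resolve_invalid_pose <- function(model, side, shoulder_pos = NULL,
                                 hand_target, previous_pose = NULL,
                                 elbow_hint = NULL, context_positions = NULL,
                                 check_collisions = TRUE, n_swivel = 64,
                                 skip_direct = FALSE) {
  if (is.null(previous_pose)) previous_pose <- neutral_pose(model)
  if (is.null(shoulder_pos))
    shoulder_pos <- model$offsets[[paste0(side, "_shoulder")]]
  a <- model$lengths[[paste0(side, "_upper_arm")]]
  b <- model$lengths[[paste0(side, "_forearm")]]
  prev_hand <- previous_pose$positions[paste0(side, "_hand"), ]
  fr <- feasible_reach(model, side)

  # direct attempt first: an already-valid target is returned unchanged
  if (!skip_direct) {
    direct <- solve_arm_ik(model, side, shoulder_pos, hand_target,
                           previous_pose, elbow_hint, context_positions,
                           check_collisions, n_swivel)
    if (direct$valid) return(direct)
  }

  # clamp a point into the flexion-feasible radial range
  feas <- function(p) {
    w <- p - shoulder_pos
    dw <- sqrt(sum(w * w))
    uw <- if (dw > 1e-9) w / dw else c(0, -1, 0)
    shoulder_pos + min(max(dw, fr[1]), fr[2]) * uw
  }
  try_point <- function(p, n_sw = n_swivel)
    solve_arm_ik(model, side, shoulder_pos, p, previous_pose, elbow_hint,
                 context_positions, check_collisions, n_swivel = n_sw)

  # temporal-coherence path: bisect along previous hand -> target for the
  # feasible point closest to the target
  path_point <- function(f) feas(prev_hand + f * (hand_target - prev_hand))
  res0 <- try_point(path_point(0))
  if (res0$valid) {
    lo <- 0; hi <- 1; best <- res0
    for (it in 1:12) {
      mid <- (lo + hi) / 2
      r <- try_point(path_point(mid))
      if (r$valid) { lo <- mid; best <- r } else hi <- mid
    }
    # back the stop point a few millimetres off the constraint surface
    # so it stays robustly valid as the context changes frame to frame
    plen <- sqrt(sum((hand_target - prev_hand)^2))
    if (lo > 0 && plen > 1e-6) {
      fm <- max(0, lo - 4 / plen)
      r <- try_point(path_point(fm))
      if (r$valid) best <- r
    }
    return(best)
  }

  v <- hand_target - shoulder_pos
  d <- sqrt(sum(v * v))
  u <- if (d > 1e-9) v / d else c(0, -1, 0)

  cand <- list()
  # radial push-outs to flexion-feasible distances (common case: target
  # too close to the shoulder for the elbow flexion limit)
  for (dd in unique(pmax(pmin(c(fr[1] + 1, fr[1] + 10, fr[1] + 25,
                                seq(fr[1], fr[2], length.out = 8)),
                              fr[2]), fr[1])))
    cand[[length(cand) + 1]] <- shoulder_pos + dd * u
  # expanding spherical grid around the target
  dirs <- resolve_directions()
  radii <- c(5, 10, 20, 35, 50, 75, 100, 150, 200, 300, 450, 650)
  for (r in radii) for (i in seq_len(nrow(dirs)))
    cand[[length(cand) + 1]] <- hand_target + r * dirs[i, ]

  cmat <- do.call(rbind, cand)
  # clamp every candidate into the flexion-feasible radial range before
  # ranking (closer targets are unreachable at any swivel)
  for (i in seq_len(nrow(cmat))) {
    w <- cmat[i, ] - shoulder_pos
    dw <- sqrt(sum(w * w))
    uw <- if (dw > 1e-9) w / dw else u
    cmat[i, ] <- shoulder_pos + min(max(dw, fr[1]), fr[2]) * uw
  }
  dist_target <- sqrt(rowSums((cmat - matrix(hand_target, nrow(cmat), 3,
                                             byrow = TRUE))^2))
  dist_prev <- sqrt(rowSums((cmat - matrix(prev_hand, nrow(cmat), 3,
                                           byrow = TRUE))^2))
  # primary key: distance to the desired target (10 mm buckets so that
  # near-ties are broken by temporal coherence)
  ord <- order(round(dist_target / 10), dist_prev)
  cmat <- cmat[ord, , drop = FALSE]
  seen <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(nrow(cmat))) {
    p <- cmat[i, ]
    if (nrow(seen) &&
        any(rowSums((seen - matrix(p, nrow(seen), 3, byrow = TRUE))^2) < 1))
      next
    seen <- rbind(seen, p)
    res <- solve_arm_ik(model, side, shoulder_pos, p, previous_pose,
                        elbow_hint, context_positions, check_collisions,
                        n_swivel = 16)
    if (res$valid) return(res)
  }
  # guaranteed fallback: the neutral arm configuration
  dofs <- arm_dof_names(side)
  npose <- neutral_pose(model)
  list(valid = TRUE, angles = npose$angles[dofs],
       elbow = npose$positions[paste0(side, "_elbow"), ],
       hand = npose$positions[paste0(side, "_hand"), ],
       swivel = NA_real_, fallback = TRUE)
}
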