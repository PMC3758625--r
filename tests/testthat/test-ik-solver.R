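# Analytic arm IK: reachability clamping, solution accuracy against
# independent oracles, validity enforcement and invalid-pose replacement.

test_that("targets are clamped onto the reach annulus", {
  S <- c(0, 0, 0)
  expect_equal(as.numeric(clamp_to_reachable(S, c(900, 0, 0), 300, 300)),
               c(600, 0, 0))
  expect_equal(as.numeric(clamp_to_reachable(S, c(100, 0, 0), 300, 300)),
               c(100, 0, 0))
  expect_false(attr(clamp_to_reachable(S, c(100, 0, 0), 300, 300),
                    "clamped"))
  # inner boundary |350-250| (+1 mm margin)
  out <- clamp_to_reachable(S, c(0, 0, 10), 350, 250)
  expect_equal(as.numeric(out), c(0, 0, 101))
  expect_true(attr(out, "clamped"))
  # degenerate: target at the shoulder falls back to the supplied ray
  out <- clamp_to_reachable(S, S, 350, 250, fallback_dir = c(1, 0, 0))
  expect_equal(as.numeric(out), c(101, 0, 0))
})

test_that("full-extension target gives a collinear elbow, flexion 0", {
  m <- test_model()
  S <- m$offsets$r_shoulder
  a <- m$lengths[["r_upper_arm"]]; b <- m$lengths[["r_forearm"]]
  dir <- c(-0.3, -0.8, 0.52); dir <- dir / sqrt(sum(dir^2))
  tg <- S + (a + b) * dir
  res <- solve_arm_ik(m, "r", S, tg)
  expect_true(res$valid)
  expect_equal(unname(res$elbow), unname(S + a * dir), tolerance = 1e-9)
  expect_equal(unname(res$angles[["r_elbow_flex"]]), 0, tolerance = 1e-6)
})

test_that("FK of the IK solution reproduces random reachable targets", {
  m <- test_model()
  set.seed(101)
  prev <- neutral_pose(m)
  n_ok <- 0
  for (i in 1:300) {
    side <- sample(c("l", "r"), 1)
    tg <- random_reachable_target(m, side)
    res <- solve_arm_ik(m, side, NULL, tg, prev)
    if (!res$valid) next  # flexion-limit or collision-blocked targets
    n_ok <- n_ok + 1
    p <- arm_fk(m, side, res$angles)
    expect_lt(sqrt(sum((p[paste0(side, "_hand"), ] - tg)^2)), 0.1)
    expect_lt(sqrt(sum((p[paste0(side, "_elbow"), ] - res$elbow)^2)), 1e-6)
    # all returned angles within limits
    lim <- m$limits[arm_dofs(side), ]
    expect_true(all(res$angles >= lim[, 1] - 1e-7 &
                    res$angles <= lim[, 2] + 1e-7))
  }
  expect_gt(n_ok, 150)
})

test_that("analytic IK agrees with a numerical optimizer oracle", {
  m <- test_model()
  set.seed(202)
  checked <- 0
  for (i in 1:40) {
    tg <- random_reachable_target(m, "r")
    hint <- random_reachable_target(m, "r")
    res <- solve_arm_ik(m, "r", NULL, tg, elbow_hint = hint,
                        check_collisions = FALSE)
    if (!res$valid) next
    # only compare where the preferred (projected) swivel was accepted,
    # i.e. the analytic answer is the unconstrained nearest-to-hint one
    if (!is.na(res$swivel)) {
      ref <- swivel_of_point(elbow_circle(m$offsets$r_shoulder, tg,
                                          m$lengths[["r_upper_arm"]],
                                          m$lengths[["r_forearm"]]), hint)
      if (abs(wrap180(res$swivel - ref)) > 1e-6) next
    }
    th <- numeric_ik(m, "r", tg, hint)
    p_num <- arm_fk(m, "r", th)
    p_ana <- arm_fk(m, "r", res$angles)
    if (sqrt(sum((p_num["r_hand", ] - tg)^2)) > 0.5) next # optimizer stuck
    checked <- checked + 1
    expect_lt(rotation_angle_deg(shoulder_rotation(res$angles),
                                 shoulder_rotation(th)), 0.5)
    expect_lt(abs(res$angles[["r_elbow_flex"]] - th[[4]]), 0.5)
    expect_lt(sqrt(sum((p_num["r_elbow", ] - p_ana["r_elbow", ])^2)), 3)
  }
  expect_gt(checked, 10)
})

test_that("the swivel tracks the observed elbow centroid", {
  m <- test_model()
  S <- m$offsets$r_shoulder
  tg <- S + c(0, -150, 380)
  circ <- elbow_circle(S, tg, m$lengths[["r_upper_arm"]],
                       m$lengths[["r_forearm"]])
  # hint exactly on the circle at a known swivel: solution must hit it
  hint <- elbow_at_swivel(circ, 25)
  res <- solve_arm_ik(m, "r", S, tg, elbow_hint = hint,
                      check_collisions = FALSE)
  expect_true(res$valid)
  expect_equal(unname(res$elbow), unname(hint), tolerance = 1e-6)
  # hint off the circle: solution is its projection onto the circle
  hint2 <- hint + 80 * circ$u  # displaced along the shoulder-hand axis
  res2 <- solve_arm_ik(m, "r", S, tg, elbow_hint = hint2,
                       check_collisions = FALSE)
  expect_equal(unname(res2$elbow), unname(hint), tolerance = 1e-6)
})

test_that("pose validity reports limit violations and collisions", {
  m <- test_model()
  np <- neutral_pose(m)
  v <- check_pose_validity(m, np)
  expect_true(v$ok)
  expect_equal(nrow(v$limit_violations), 0)
  expect_equal(nrow(v$collisions), 0)
  ang <- np$angles
  ang["r_elbow_flex"] <- -20
  v2 <- check_pose_validity(m, new_pose(m, ang))
  expect_false(v2$ok)
  expect_equal(v2$limit_violations$dof, "r_elbow_flex")
  # arms wrapped across the body: forearms intersect
  ang3 <- np$angles
  ang3[1:8] <- c(128.7, -142.0, 88.0, 29.9, -139.1, -140.4, 15.7, 105.4)
  v3 <- check_pose_validity(m, new_pose(m, ang3))
  expect_true(any(v3$collisions$body_a == "l_forearm" &
                  v3$collisions$body_b == "r_forearm"))
})

test_that("resolving an already-valid pose returns it unchanged", {
  m <- test_model()
  tg <- m$offsets$r_shoulder + c(-50, -200, 350)
  a <- solve_arm_ik(m, "r", NULL, tg)
  b <- resolve_invalid_pose(m, "r", NULL, tg)
  expect_true(a$valid)
  expect_equal(a$angles, b$angles)
  expect_equal(a$elbow, b$elbow)
})

test_that("unreachable targets farther along a ray keep full extension", {
  m <- test_model()
  S <- m$offsets$r_shoulder
  a <- m$lengths[["r_upper_arm"]]; b <- m$lengths[["r_forearm"]]
  dir <- c(-0.5, -0.4, 0.768); dir <- dir / sqrt(sum(dir^2))
  hands <- sapply(c(700, 900, 1500, 3000), function(d) {
    tg <- clamp_to_reachable(S, S + d * dir, a, b)
    res <- solve_arm_ik(m, "r", S, tg)
    expect_true(res$valid)
    res$hand
  })
  for (j in 2:ncol(hands))
    expect_equal(hands[, j], hands[, 1], tolerance = 1e-9)
  expect_equal(sqrt(sum((hands[, 1] - S)^2)), a + b, tolerance = 1e-9)
})

test_that("a hand tracked behind the head stays there when its target
           collapses into the head", {
  m <- test_model()
  head <- m$offsets$head
  clearance <- m$radii[["radius_head"]] + m$radii[["radius_forearm"]]
  # previous pose: the hand validly held behind the head
  behind <- head + c(0, 0, -(clearance + 60))
  S <- m$offsets$r_shoulder
  r1 <- solve_arm_ik(m, "r", S,
                     clamp_to_reachable(S, behind,
                                        m$lengths[["r_upper_arm"]],
                                        m$lengths[["r_forearm"]]))
  expect_true(r1$valid)
  ang <- neutral_pose(m)$angles; ang[arm_dofs("r")] <- r1$angles
  prev <- new_pose(m, ang)
  # depth-hijacked target inside the head proxy
  res <- resolve_invalid_pose(m, "r", S, head, prev)
  expect_true(res$valid)
  ang[arm_dofs("r")] <- res$angles
  expect_true(check_pose_validity(m, new_pose(m, ang))$ok)
  # the hand rests on the head proxy surface and stays behind it
  d_head <- sqrt(sum((res$hand - head)^2))
  expect_equal(d_head, clearance, tolerance = 0.05)
  expect_lt(res$hand[3], head[3])
})

test_that("a hyperextension target resolves to the nearest feasible point", {
  m <- test_model()
  S <- m$offsets$r_shoulder
  # closer to the shoulder than the elbow-flexion limit allows
  tg <- S + c(0, -120, 0)
  direct <- solve_arm_ik(m, "r", S, tg)
  expect_false(direct$valid)
  res <- resolve_invalid_pose(m, "r", S, tg)
  expect_true(res$valid)
  # oracle: the closest feasible distance given max flexion
  a <- m$lengths[["r_upper_arm"]]; b <- m$lengths[["r_forearm"]]
  gmin <- (180 - m$limits["r_elbow_flex", 2]) * pi / 180
  dmin <- sqrt(a^2 + b^2 - 2 * a * b * cos(gmin))
  expect_equal(sqrt(sum((res$hand - S)^2)), dmin, tolerance = 0.01)
  expect_lt(sqrt(sum((res$hand - tg)^2)), dmin - 120 + 30)
  ang <- neutral_pose(m)$angles; ang[arm_dofs("r")] <- res$angles
  expect_true(check_pose_validity(m, new_pose(m, ang))$ok)
})

test_that("every emitted arm solution passes the validity check (fuzz)", {
  m <- test_model()
  set.seed(77)
  prev <- neutral_pose(m)
  for (i in 1:60) {
    side <- sample(c("l", "r"), 1)
    S <- m$offsets[[paste0(side, "_shoulder")]]
    raw <- S + stats::rnorm(3, 0, 400)
    tg <- clamp_to_reachable(S, raw,
                             m$lengths[[paste0(side, "_upper_arm")]],
                             m$lengths[[paste0(side, "_forearm")]])
    res <- solve_arm_ik(m, side, S, tg, prev)
    if (!res$valid) res <- resolve_invalid_pose(m, side, S, tg, prev)
    ang <- prev$angles; ang[arm_dofs(side)] <- res$angles
    pose <- new_pose(m, ang)
    expect_true(check_pose_validity(m, pose)$ok)
    prev <- pose
  }
})
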