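# Articulated upper-body model: topology, anthropometric dimensions,
# joint limits and forward kinematics.
#
# Coordinate convention (used by every module in the package):
# right-handed, millimetres, origin at the torso centroid, +x toward the
# performer's left, +y up, +z toward the camera. In the neutral
# (zero-angle) reference pose both arms hang along the body.

#' Upper-body joint names
#'
#' The eight tracked joints, in canonical order: torso (root), head, the
#' two shoulders, elbows and hands. Hands are the end effectors driven by
#' inverse kinematics; elbows are the intermediate joints read back from
#' the posed model.
#'
#' @export
KIN_JOINTS <- c("torso", "head", "l_shoulder", "r_shoulder",
                "l_elbow", "r_elbow", "l_hand", "r_hand")

#' @rdname KIN_JOINTS
#' @export
KIN_END_EFFECTORS <- c("l_hand", "r_hand")

#' @rdname KIN_JOINTS
#' @export
KIN_INTERMEDIATE <- c("l_elbow", "r_elbow")

# Degrees of freedom, one angle each (degrees):
#   *_shoulder_abd : rotation about +z; positive abducts the arm away from
#                    the torso (mirrored for the right side)
#   *_shoulder_sag : rotation about +x; positive moves the arm backwards
#   *_shoulder_rot : axial (swivel) rotation about the upper-arm axis
#   *_elbow_flex   : elbow flexion; positive brings the hand forward
#' @rdname KIN_JOINTS
#' @export
KIN_DOFS <- c("l_shoulder_abd", "l_shoulder_sag", "l_shoulder_rot",
              "l_elbow_flex",
              "r_shoulder_abd", "r_shoulder_sag", "r_shoulder_rot",
              "r_elbow_flex")

#' Default anthropometric proportion table
#'
#' Segment dimensions expressed as fractions of the stature H (floor to
#' crown). Limb fractions follow the published Drillis--Contini body
#' segment proportions (upper arm 0.186 H, forearm 0.146 H); the frame
#' offsets and collision-proxy radii are package defaults chosen so that
#' the neutral reference pose is collision free. All entries are
#' configuration, not hard-coded: pass an edited table to
#' [build_default_model()] to change the model.
#'
#' @return Named numeric vector of fractions of H.
#' @export
default_ratio_table <- function() {
  c(
    upper_arm         = 0.186,  # shoulder -> elbow
    forearm           = 0.146,  # elbow -> hand centroid
    shoulder_lateral  = 0.129,  # half biacromial width
    shoulder_vertical = 0.188,  # torso centroid -> shoulder line
    head_vertical     = 0.306,  # torso centroid -> face centroid
    trunk_lower       = 0.200,  # torso centroid -> lower end of trunk proxy
    torso_height      = 0.630,  # floor -> torso centroid (standing)
    radius_torso      = 0.080,  # trunk capsule radius
    radius_head       = 0.066,  # head sphere radius
    radius_upper_arm  = 0.022,
    radius_forearm    = 0.018
  )
}

#' Default joint-angle limit table
#'
#' Range-of-motion limits, in degrees, for the eight rotational degrees of
#' freedom. Values are package defaults taken from standard published
#' range-of-motion tables (e.g. elbow flexion 0--145 degrees, no
#' hyperextension); abduction limits are mirrored between sides because
#' the abduction angle is signed about the body-fixed +z axis.
#'
#' @return A two-column matrix (min, max) with one row per DOF, in
#'   [KIN_DOFS] order.
#' @export
default_joint_limits <- function() {
  lim <- rbind(
    l_shoulder_abd = c(-50, 180),
    l_shoulder_sag = c(-180, 60),
    l_shoulder_rot = c(-120, 120),
    l_elbow_flex   = c(0, 145),
    r_shoulder_abd = c(-180, 50),
    r_shoulder_sag = c(-180, 60),
    r_shoulder_rot = c(-120, 120),
    r_elbow_flex   = c(0, 145)
  )
  colnames(lim) <- c("min", "max")
  lim
}

# Collision proxy bodies: each body is attached to one or two joints and
# the exclusion of adjacent pairs is derived from the shared-joint rule.
kin_geometry_spec <- function() {
  list(
    torso       = list(joints = c("torso", "head", "l_shoulder", "r_shoulder"),
                       shape = "trunk", radius_key = "radius_torso"),
    head        = list(joints = "head", shape = "sphere",
                       radius_key = "radius_head"),
    l_upper_arm = list(joints = c("l_shoulder", "l_elbow"), shape = "capsule",
                       radius_key = "radius_upper_arm"),
    r_upper_arm = list(joints = c("r_shoulder", "r_elbow"), shape = "capsule",
                       radius_key = "radius_upper_arm"),
    l_forearm   = list(joints = c("l_elbow", "l_hand"), shape = "capsule",
                       radius_key = "radius_forearm"),
    r_forearm   = list(joints = c("r_elbow", "r_hand"), shape = "capsule",
                       radius_key = "radius_forearm")
  )
}

#' Build an upper-body kinematic model from stature
#'
#' Constructs the articulated model: 8-joint topology rooted at the torso,
#' limb lengths as anthropometric fractions of the stature `stature_H`,
#' joint-angle limits, and capsule collision proxies scaled to the segment
#' dimensions.
#'
#' @param stature_H Stature (floor to crown) in millimetres; must lie in
#'   `[1000, 2300]`.
#' @param ratio_table Named vector of segment fractions of H; see
#'   [default_ratio_table()] for the required entries.
#' @param joint_limits Two-column min/max matrix over [KIN_DOFS]; see
#'   [default_joint_limits()].
#' @return An object of class `kin_model`.
#' @examples
#' m <- build_default_model(1750)
#' m$lengths["l_forearm"]   # 0.146 * 1750 = 255.5 mm
#' @export
build_default_model <- function(stature_H,
                                ratio_table = default_ratio_table(),
                                joint_limits = default_joint_limits()) {
  if (!is.numeric(stature_H) || length(stature_H) != 1 || stature_H <= 0)
    stop("stature_H must be a single positive number (mm)", call. = FALSE)
  if (stature_H < 1000 || stature_H > 2300)
    stop("stature_H out of supported range [1000, 2300] mm", call. = FALSE)
  needed <- names(default_ratio_table())
  missing <- setdiff(needed, names(ratio_table))
  if (length(missing))
    stop("ratio_table is missing entries: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(ratio_table[needed] <= 0))
    stop("all ratio_table entries must be positive", call. = FALSE)
  if (!all(rownames(joint_limits) == KIN_DOFS))
    stop("joint_limits rows must match KIN_DOFS order", call. = FALSE)
  if (any(joint_limits[, 1] >= joint_limits[, 2]))
    stop("every joint limit must satisfy min < max", call. = FALSE)

  r <- ratio_table
  limbs <- data.frame(
    name   = c("neck", "l_clavicle", "r_clavicle",
               "l_upper_arm", "r_upper_arm", "l_forearm", "r_forearm"),
    parent = c("torso", "torso", "torso",
               "l_shoulder", "r_shoulder", "l_elbow", "r_elbow"),
    child  = c("head", "l_shoulder", "r_shoulder",
               "l_elbow", "r_elbow", "l_hand", "r_hand"),
    stringsAsFactors = FALSE
  )
  chains <- list(
    torso = "torso", head = c("torso", "head"),
    l_shoulder = c("torso", "l_shoulder"),
    r_shoulder = c("torso", "r_shoulder"),
    l_elbow = c("torso", "l_shoulder", "l_elbow"),
    r_elbow = c("torso", "r_shoulder", "r_elbow"),
    l_hand = c("torso", "l_shoulder", "l_elbow", "l_hand"),
    r_hand = c("torso", "r_shoulder", "r_elbow", "r_hand")
  )
  topology <- list(joints = KIN_JOINTS, limbs = limbs,
                   end_effectors = KIN_END_EFFECTORS,
                   intermediate = KIN_INTERMEDIATE,
                   chains = chains, root = "torso")

  H <- stature_H
  model <- structure(list(
    topology = topology,
    stature = H,
    ratio_table = r,
    lengths = c(l_upper_arm = unname(r["upper_arm"] * H),
                r_upper_arm = unname(r["upper_arm"] * H),
                l_forearm = unname(r["forearm"] * H),
                r_forearm = unname(r["forearm"] * H)),
    offsets = list(
      head       = c(0, r[["head_vertical"]] * H, 0),
      l_shoulder = c(r[["shoulder_lateral"]] * H,
                     r[["shoulder_vertical"]] * H, 0),
      r_shoulder = c(-r[["shoulder_lateral"]] * H,
                     r[["shoulder_vertical"]] * H, 0)),
    trunk = list(lower = c(0, -r[["trunk_lower"]] * H, 0),
                 upper = c(0, r[["shoulder_vertical"]] * H, 0)),
    dofs = KIN_DOFS,
    limits = joint_limits,
    geometry = kin_geometry_spec(),
    radii = c(radius_torso = unname(r["radius_torso"] * H),
              radius_head = unname(r["radius_head"] * H),
              radius_upper_arm = unname(r["radius_upper_arm"] * H),
              radius_forearm = unname(r["radius_forearm"] * H)),
    torso_height = unname(r["torso_height"] * H)
  ), class = "kin_model")
  model$collision_pairs <- collision_pairs(model)
  model
}

#' @export
print.kin_model <- function(x, ...) {
  cat("<kin_model> upper body, 8 joints, 8 DOF\n")
  cat(sprintf("  stature H = %.0f mm\n", x$stature))
  cat(sprintf("  upper arm %.1f mm, forearm %.1f mm\n",
              x$lengths[["l_upper_arm"]], x$lengths[["l_forearm"]]))
  invisible(x)
}

#' Estimate stature from face-centroid heights
#'
#' The stature H is recovered from the floor-to-eye distance He using the
#' anthropometric relation H = He / 0.936, with He estimated as the mean
#' floor height of the tracked face centroid while the performer stands
#' still.
#'
#' @param face_centroid_heights Numeric vector of floor-referenced face
#'   centroid heights in millimetres (full-confidence samples only).
#' @return Estimated stature in millimetres.
#' @examples
#' estimate_stature(936)  # 1000 mm
#' @export
estimate_stature <- function(face_centroid_heights) {
  h <- face_centroid_heights[is.finite(face_centroid_heights)]
  if (length(h) < 1)
    stop("estimate_stature: no usable face-centroid samples", call. = FALSE)
  mean(h) / 0.936
}

# --- rotations (degrees) ------------------------------------------------

rot_x <- function(a) {
  a <- a * pi / 180; c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  a <- a * pi / 180; c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  a <- a * pi / 180; c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# Rotation of the full arm chain for one side. Returns list(Q, Rfull)
# where Q orients the upper arm and Rfull additionally carries the axial
# swivel rotation that orients the elbow flexion plane.
arm_rotation <- function(abd, sag, rot) {
  Q <- rot_z(abd) %*% rot_x(sag)
  list(Q = Q, Rfull = Q %*% rot_y(rot))
}

#' Forward kinematics
#'
#' Maps a full vector of joint angles to 3D joint positions in the torso
#' frame. The torso sits at the origin; head and shoulders are fixed
#' offsets; each arm is posed by three shoulder rotations plus elbow
#' flexion. Angles outside their limits are still computed -- validity is
#' the concern of [check_pose_validity()].
#'
#' @param model A `kin_model`.
#' @param joint_angles Named numeric vector over [KIN_DOFS] (degrees).
#' @return An 8 x 3 matrix of positions (mm), rows named by [KIN_JOINTS].
#' @export
forward_kinematics <- function(model, joint_angles) {
  if (is.null(names(joint_angles))) names(joint_angles) <- KIN_DOFS
  if (!all(KIN_DOFS %in% names(joint_angles)))
    stop("forward_kinematics: need one angle per DOF (see KIN_DOFS)",
         call. = FALSE)
  a <- joint_angles[KIN_DOFS]
  pos <- matrix(0, nrow = 8, ncol = 3,
                dimnames = list(KIN_JOINTS, c("x", "y", "z")))
  pos["head", ] <- model$offsets$head
  pos["l_shoulder", ] <- model$offsets$l_shoulder
  pos["r_shoulder", ] <- model$offsets$r_shoulder
  d0 <- c(0, -1, 0)
  for (side in c("l", "r")) {
    S <- pos[paste0(side, "_shoulder"), ]
    ar <- arm_rotation(a[[paste0(side, "_shoulder_abd")]],
                       a[[paste0(side, "_shoulder_sag")]],
                       a[[paste0(side, "_shoulder_rot")]])
    ua <- model$lengths[[paste0(side, "_upper_arm")]]
    fa <- model$lengths[[paste0(side, "_forearm")]]
    E <- S + ua * drop(ar$Q %*% d0)
    Wd <- drop(ar$Rfull %*% rot_x(-a[[paste0(side, "_elbow_flex")]]) %*% d0)
    W <- E + fa * Wd
    pos[paste0(side, "_elbow"), ] <- E
    pos[paste0(side, "_hand"), ] <- W
  }
  pos
}

#' Construct a pose from joint angles
#'
#' A `kin_pose` couples a timestamp, the joint-angle vector and the joint
#' positions derived from it by forward kinematics, so positions are
#' always reproducible from angles.
#'
#' @param model A `kin_model`.
#' @param joint_angles Named numeric vector over [KIN_DOFS] (degrees).
#' @param timestamp Time in seconds.
#' @return An object of class `kin_pose` with elements `timestamp`,
#'   `angles`, `positions`.
#' @export
new_pose <- function(model, joint_angles, timestamp = 0) {
  if (is.null(names(joint_angles))) names(joint_angles) <- KIN_DOFS
  ang <- joint_angles[KIN_DOFS]
  structure(list(timestamp = timestamp, angles = ang,
                 positions = forward_kinematics(model, ang)),
            class = "kin_pose")
}

#' Neutral reference pose (arms hanging along the body)
#' @param model A `kin_model`.
#' @param timestamp Time in seconds.
#' @return A `kin_pose` with all angles zero.
#' @export
neutral_pose <- function(model, timestamp = 0) {
  ang <- stats::setNames(rep(0, length(KIN_DOFS)), KIN_DOFS)
  new_pose(model, ang, timestamp)
}

#' @export
print.kin_pose <- function(x, ...) {
  cat(sprintf("<kin_pose> t = %.3f s\n", x$timestamp))
  print(round(x$positions, 1))
  invisible(x)
}

# Serialize a model to a plain list suitable for YAML/JSON round-trip.
#' Model serialization
#'
#' `model_to_config()` reduces a model to its defining configuration
#' (stature, ratio table, joint limits); `model_from_config()` rebuilds
#' it. Learned limb lengths, which may deviate from the anthropometric
#' ratios, are carried explicitly.
#'
#' @param model A `kin_model`.
#' @return A plain named list (`model_to_config`) or a `kin_model`
#'   (`model_from_config`).
#' @export
model_to_config <- function(model) {
  list(stature = model$stature,
       ratio_table = as.list(model$ratio_table),
       joint_limits = apply(model$limits, 1, function(r)
         list(min = r[[1]], max = r[[2]]), simplify = FALSE),
       lengths = as.list(model$lengths))
}

#' @rdname model_to_config
#' @param config A list as produced by `model_to_config()`.
#' @export
model_from_config <- function(config) {
  lim <- t(vapply(config$joint_limits[KIN_DOFS],
                  function(e) c(e$min, e$max), numeric(2)))
  colnames(lim) <- c("min", "max")
  m <- build_default_model(config$stature,
                           ratio_table = unlist(config$ratio_table),
                           joint_limits = lim)
  if (!is.null(config$lengths))
    m$lengths[names(config$lengths)] <- unlist(config$lengths)
  m
}

# Replace the four arm-limb lengths (mm), e.g. with learned estimates.
#' Set arm limb lengths
#' @param model A `kin_model`.
#' @param lengths Named vector with any of `l_upper_arm`, `r_upper_arm`,
#'   `l_forearm`, `r_forearm` (mm, positive).
#' @return The updated model.
#' @export
set_limb_lengths <- function(model, lengths) {
  stopifnot(all(names(lengths) %in% names(model$lengths)))
  if (any(lengths <= 0)) stop("limb lengths must be positive", call. = FALSE)
  model$lengths[names(lengths)] <- lengths
  model
}
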