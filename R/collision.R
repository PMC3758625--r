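# Two-level self-collision detection.
#
# Broad phase: axis-aligned bounding boxes of the posed proxies.
# Narrow phase: exact capsule/capsule test (minimum distance between the
# two axis segments compared with the radius sum). Boundary contact
# counts as collision, so the filter errs toward separation.

#' Axis-aligned bounding-box overlap
#'
#' Conservative broad-phase test: boxes overlap iff their intervals
#' overlap on all three axes; touching faces count as overlap.
#'
#' @param a,b 2 x 3 matrices, row 1 = min corner, row 2 = max corner (mm).
#' @return Logical.
#' @export
aabb_overlap <- function(a, b) {
  if (any(a[1, ] > a[2, ]) || any(b[1, ] > b[2, ]))
    stop("aabb_overlap: malformed box (min > max)", call. = FALSE)
  all(a[1, ] <= b[2, ]) && all(b[1, ] <= a[2, ])
}

# Minimum distance between segments P1-Q1 and P2-Q2 (Ericson's clamped
# closed form, robust for degenerate/point segments).
segment_segment_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- 1e-12
  if (a <= eps && e <= eps) return(sqrt(sum(r * r)))
  if (a <= eps) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    c_ <- sum(d1 * r)
    if (e <= eps) {
      t <- 0; s <- min(max(-c_ / a, 0), 1)
    } else {
      b <- sum(d1 * d2)
      denom <- a * e - b * b
      s <- if (denom > eps) min(max((b * f - c_ * e) / denom, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) {
        t <- 0; s <- min(max(-c_ / a, 0), 1)
      } else if (t > 1) {
        t <- 1; s <- min(max((b - c_) / a, 0), 1)
      }
    }
  }
  v <- (p1 + s * d1) - (p2 + t * d2)
  sqrt(sum(v * v))
}

# Posed proxy geometry for every collision body: endpoints of the capsule
# axis (a sphere is a zero-length capsule), radius, and the AABB inflated
# by the radius so it always contains the proxy.
#' Posed collision geometry
#'
#' Computes, for each collision body of the model, the capsule axis
#' endpoints in the torso frame, the proxy radius, and its axis-aligned
#' bounding box for the given joint positions.
#'
#' @param model A `kin_model`.
#' @param positions 8 x 3 joint position matrix (as from
#'   [forward_kinematics()]).
#' @return Named list of bodies, each with `a`, `b` (axis endpoints),
#'   `radius`, `aabb`, `joints`.
#' @export
pose_geometry <- function(model, positions) {
  out <- vector("list", length(model$geometry))
  names(out) <- names(model$geometry)
  for (nm in names(model$geometry)) {
    g <- model$geometry[[nm]]
    radius <- model$radii[[g$radius_key]]
    if (g$shape == "trunk") {
      a <- model$trunk$lower; b <- model$trunk$upper
    } else if (g$shape == "sphere") {
      a <- positions[g$joints[1], ]; b <- a
    } else {
      a <- positions[g$joints[1], ]; b <- positions[g$joints[2], ]
    }
    aabb <- rbind(pmin(a, b) - radius, pmax(a, b) + radius)
    out[[nm]] <- list(name = nm, a = a, b = b, radius = radius,
                      aabb = aabb, joints = g$joints)
  }
  out
}

#' Narrow-phase collision test between two posed segments
#'
#' Runs the broad-phase [aabb_overlap()] first and the exact capsule test
#' only when the boxes overlap, mirroring the two-level architecture.
#'
#' @param geomA,geomB Posed bodies as returned by [pose_geometry()].
#' @return Logical; `TRUE` iff the convex proxies intersect (boundary
#'   contact included). The attribute `narrow_phase` records whether the
#'   capsule-level test was invoked.
#' @export
segment_collision <- function(geomA, geomB) {
  if (any(!is.finite(c(geomA$a, geomA$b, geomB$a, geomB$b))))
    stop("segment_collision: degenerate geometry (non-finite endpoint)",
         call. = FALSE)
  if (!aabb_overlap(geomA$aabb, geomB$aabb))
    return(structure(FALSE, narrow_phase = FALSE))
  d <- segment_segment_distance(geomA$a, geomA$b, geomB$a, geomB$b)
  structure(d <= geomA$radius + geomB$radius, narrow_phase = TRUE)
}

# Non-adjacent body pairs (bodies sharing a joint are excluded),
# precomputed once per model geometry spec.
collision_pairs <- function(model) {
  if (!is.null(model$collision_pairs)) return(model$collision_pairs)
  nms <- names(model$geometry)
  pairs <- utils::combn(nms, 2)
  keep <- apply(pairs, 2, function(p) {
    ja <- model$geometry[[p[1]]]$joints
    jb <- model$geometry[[p[2]]]$joints
    length(intersect(ja, jb)) == 0
  })
  pairs[, keep, drop = FALSE]
}

#' Detect self-collisions in a pose
#'
#' Tests every unordered pair of non-adjacent collision bodies (adjacency
#' = sharing a joint, derived from the topology) with the two-level test.
#'
#' @param model A `kin_model`.
#' @param pose A `kin_pose`, or an 8 x 3 position matrix.
#' @return Data frame of colliding pairs (`body_a`, `body_b`); zero rows
#'   when the pose is collision free. The attribute `narrow_tests` counts
#'   how many pairs reached the capsule-level test.
#' @export
detect_self_collisions <- function(model, pose) {
  positions <- if (inherits(pose, "kin_pose")) pose$positions else pose
  geom <- pose_geometry(model, positions)
  pairs <- collision_pairs(model)
  hits_a <- character(0); hits_b <- character(0)
  narrow <- 0L
  if (ncol(pairs) > 0) for (j in seq_len(ncol(pairs))) {
    res <- segment_collision(geom[[pairs[1, j]]], geom[[pairs[2, j]]])
    if (isTRUE(attr(res, "narrow_phase"))) narrow <- narrow + 1L
    if (res) {
      hits_a <- c(hits_a, pairs[1, j]); hits_b <- c(hits_b, pairs[2, j])
    }
  }
  structure(data.frame(body_a = hits_a, body_b = hits_b,
                       stringsAsFactors = FALSE),
            narrow_tests = narrow)
}
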