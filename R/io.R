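# Frame-stream and pose I/O.
#
# Frame stream (the tracker's raw output), two dialects:
#   JSONL: one object per line, {"t": s, "joints": {name: {x,y,z,c}}}
#   CSV:   long table with columns t, joint, x, y, z, c
# Units are millimetres, torso-referenced, axes: +x performer's left,
# +y up, +z toward the camera.

frame_dialect <- function(path, dialect = NULL) {
  if (!is.null(dialect)) return(match.arg(dialect, c("jsonl", "csv")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "json", "ndjson")) "jsonl"
  else if (ext == "csv") "csv"
  else stop("cannot infer stream dialect from extension '", ext,
            "'; pass dialect=", call. = FALSE)
}

#' Read a tracker frame stream
#'
#' @param path File path; dialect inferred from the extension (`.jsonl`
#'   or `.csv`) unless given.
#' @param dialect `"jsonl"` or `"csv"`, or `NULL` to infer.
#' @return List of [tracker_frame()]s.
#' @export
read_frames <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dialect <- frame_dialect(path, dialect)
  if (dialect == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    frames <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e)
                        stop("malformed JSONL record at line ", i, ": ",
                             conditionMessage(e), call. = FALSE))
      if (is.null(rec$t) || is.null(rec$joints))
        stop("malformed JSONL record at line ", i,
             ": need fields 't' and 'joints'", call. = FALSE)
      pos <- matrix(NA_real_, 8, 3, dimnames = list(KIN_JOINTS, c("x","y","z")))
      conf <- stats::setNames(rep(NA_real_, 8), KIN_JOINTS)
      for (j in KIN_JOINTS) {
        e <- rec$joints[[j]]
        if (is.null(e) || is.null(e$c))
          stop("malformed JSONL record at line ", i, ": joint '", j,
               "' missing or lacks confidence", call. = FALSE)
        pos[j, ] <- c(e$x, e$y, e$z); conf[j] <- e$c
      }
      frames[[i]] <- tracker_frame(rec$t, pos, conf)
    }
    frames
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("t", "joint", "x", "y", "z", "c")
    if (!all(need %in% names(df)))
      stop("frame CSV schema error: need columns ",
           paste(need, collapse = ", "), call. = FALSE)
    ts <- unique(df$t)
    lapply(ts, function(tt) {
      sub <- df[df$t == tt, ]
      if (!setequal(sub$joint, KIN_JOINTS))
        stop("frame at t=", tt, " does not contain exactly the 8 joints",
             call. = FALSE)
      rownames(sub) <- sub$joint
      tracker_frame(tt, as.matrix(sub[KIN_JOINTS, c("x", "y", "z")]),
                    stats::setNames(sub[KIN_JOINTS, "c"], KIN_JOINTS))
    })
  }
}

#' Write a tracker frame stream
#' @param frames List of `tracker_frame`s.
#' @param path Output path (`.jsonl` or `.csv`).
#' @param dialect `"jsonl"` or `"csv"`, or `NULL` to infer.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path, dialect = NULL) {
  dialect <- frame_dialect(path, dialect)
  if (dialect == "jsonl") {
    lines <- vapply(frames, function(f) {
      joints <- lapply(KIN_JOINTS, function(j)
        list(x = f$positions[j, 1], y = f$positions[j, 2],
             z = f$positions[j, 3], c = f$confidence[[j]]))
      names(joints) <- KIN_JOINTS
      jsonlite::toJSON(list(t = f$t, joints = joints),
                       auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path)
  } else {
    rows <- do.call(rbind, lapply(frames, function(f)
      data.frame(t = f$t, joint = KIN_JOINTS,
                 x = f$positions[, 1], y = f$positions[, 2],
                 z = f$positions[, 3], c = unname(f$confidence),
                 stringsAsFactors = FALSE)))
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

#' Write poses to JSONL or BVH
#'
#' JSONL mirrors the frame format with joint angles added. BVH encodes
#' the skeleton hierarchy (torso root with 3 translation + 3 rotation
#' channels; head, shoulders and elbows with 3 rotation channels each in
#' Z-X-Y order; hands as end sites) and one line of channel values per
#' key pose, at the stream rate.
#'
#' @param poses List of `kin_pose`s.
#' @param path Output path.
#' @param format `"jsonl"` or `"bvh"`; inferred from the extension when
#'   `NULL`.
#' @param model The `kin_model` (required for BVH offsets).
#' @return `path`, invisibly.
#' @export
write_poses <- function(poses, path, format = NULL, model = NULL) {
  if (is.null(format))
    format <- if (tolower(tools::file_ext(path)) == "bvh") "bvh" else "jsonl"
  format <- match.arg(format, c("jsonl", "bvh"))
  if (format == "jsonl") {
    lines <- vapply(poses, function(p) {
      joints <- lapply(KIN_JOINTS, function(j)
        list(x = p$positions[j, 1], y = p$positions[j, 2],
             z = p$positions[j, 3]))
      names(joints) <- KIN_JOINTS
      jsonlite::toJSON(list(t = p$timestamp,
                            angles = as.list(p$angles),
                            joints = joints),
                       auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path)
    return(invisible(path))
  }
  if (is.null(model)) stop("BVH export needs the model", call. = FALSE)
  off <- function(v) paste(sprintf("%.4f", v), collapse = " ")
  ua <- model$lengths[["l_upper_arm"]]; fa <- model$lengths[["l_forearm"]]
  uar <- model$lengths[["r_upper_arm"]]; far <- model$lengths[["r_forearm"]]
  hier <- c(
    "HIERARCHY",
    "ROOT torso",
    "{",
    "  OFFSET 0 0 0",
    paste("  CHANNELS 6 Xposition Yposition Zposition",
          "Zrotation Xrotation Yrotation"),
    "  JOINT head",
    "  {",
    paste0("    OFFSET ", off(model$offsets$head)),
    "    CHANNELS 3 Zrotation Xrotation Yrotation",
    "    End Site",
    "    {",
    paste0("      OFFSET 0 ",
           sprintf("%.4f", model$radii[["radius_head"]]), " 0"),
    "    }",
    "  }",
    "  JOINT l_shoulder",
    "  {",
    paste0("    OFFSET ", off(model$offsets$l_shoulder)),
    "    CHANNELS 3 Zrotation Xrotation Yrotation",
    "    JOINT l_elbow",
    "    {",
    paste0("      OFFSET 0 ", sprintf("%.4f", -ua), " 0"),
    "      CHANNELS 3 Zrotation Xrotation Yrotation",
    "      End Site",
    "      {",
    paste0("        OFFSET 0 ", sprintf("%.4f", -fa), " 0"),
    "      }",
    "    }",
    "  }",
    "  JOINT r_shoulder",
    "  {",
    paste0("    OFFSET ", off(model$offsets$r_shoulder)),
    "    CHANNELS 3 Zrotation Xrotation Yrotation",
    "    JOINT r_elbow",
    "    {",
    paste0("      OFFSET 0 ", sprintf("%.4f", -uar), " 0"),
    "      CHANNELS 3 Zrotation Xrotation Yrotation",
    "      End Site",
    "      {",
    paste0("        OFFSET 0 ", sprintf("%.4f", -far), " 0"),
    "      }",
    "    }",
    "  }",
    "}"
  )
  ts <- vapply(poses, function(p) p$timestamp, numeric(1))
  ft <- if (length(ts) > 1) stats::median(diff(ts)) else 1 / 30
  frame_line <- function(p) {
    a <- p$angles
    vals <- c(0, 0, 0, 0, 0, 0,          # root translation + rotation
              0, 0, 0,                   # head
              a[["l_shoulder_abd"]], a[["l_shoulder_sag"]],
              a[["l_shoulder_rot"]],
              0, -a[["l_elbow_flex"]], 0,
              a[["r_shoulder_abd"]], a[["r_shoulder_sag"]],
              a[["r_shoulder_rot"]],
              0, -a[["r_elbow_flex"]], 0)
    paste(sprintf("%.6f", vals), collapse = " ")
  }
  motion <- c("MOTION",
              paste0("Frames: ", length(poses)),
              paste0("Frame Time: ", sprintf("%.8f", ft)),
              vapply(poses, frame_line, character(1)))
  writeLines(c(hier, motion), path)
  invisible(path)
}

#' Read poses written by [write_poses()] (JSONL)
#' @param path JSONL pose file.
#' @param model The `kin_model` used to rebuild positions from angles.
#' @return List of `kin_pose`s.
#' @export
read_poses <- function(path, model) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e)
                      stop("malformed pose record at line ", i, call. = FALSE))
    new_pose(model, unlist(rec$angles)[KIN_DOFS], timestamp = rec$t)
  })
}

#' Write / read the model configuration document (YAML)
#' @param model A `kin_model`.
#' @param path Output path.
#' @param learner Optional learner states to include.
#' @return `path` invisibly; `read_model_config()` returns a list with
#'   `model` and (optionally) `learner`.
#' @export
write_model_config <- function(model, path, learner = NULL) {
  cfg <- model_to_config(model)
  if (!is.null(learner)) cfg$learner <- learner_to_config(learner)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  learner <- if (!is.null(cfg$learner)) learner_from_config(cfg$learner)
  cfg$learner <- NULL
  list(model = model_from_config(cfg), learner = learner)
}
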