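# Skeleton model: the 20-joint first-generation depth-sensor skeleton, its
# kinematic tree (19 edges) and the 14 documented joint-angle sites.

.JOINTS <- c(
  "hip_center", "spine", "shoulder_center", "head",
  "shoulder_left", "elbow_left", "wrist_left", "hand_left",
  "shoulder_right", "elbow_right", "wrist_right", "hand_right",
  "hip_left", "knee_left", "ankle_left", "foot_left",
  "hip_right", "knee_right", "ankle_right", "foot_right"
)

# 19 edges of the kinematic tree, parent -> child, rooted at hip_center.
# The order is topological (parents precede children) and fixed: it defines
# the layout of the segment block of the feature vector.
.EDGES <- matrix(c(
  "hip_center",      "spine",
  "spine",           "shoulder_center",
  "shoulder_center", "head",
  "shoulder_center", "shoulder_left",
  "shoulder_left",   "elbow_left",
  "elbow_left",      "wrist_left",
  "wrist_left",      "hand_left",
  "shoulder_center", "shoulder_right",
  "shoulder_right",  "elbow_right",
  "elbow_right",     "wrist_right",
  "wrist_right",     "hand_right",
  "hip_center",      "hip_left",
  "hip_left",        "knee_left",
  "knee_left",       "ankle_left",
  "ankle_left",      "foot_left",
  "hip_center",      "hip_right",
  "hip_right",       "knee_right",
  "knee_right",      "ankle_right",
  "ankle_right",     "foot_right"
), ncol = 2, byrow = TRUE, dimnames = list(NULL, c("parent", "child")))

# 14 angle sites: (site name, incoming edge index, outgoing edge index).
# The angle is between the two oriented segment unit vectors meeting at the
# site joint; a straight chain therefore has angle 0.
.ANGLE_SITES <- data.frame(
  site = c("trunk", "neck",
           "shoulder_left", "elbow_left", "wrist_left",
           "shoulder_right", "elbow_right", "wrist_right",
           "hip_left", "knee_left", "ankle_left",
           "hip_right", "knee_right", "ankle_right"),
  edge_in  = c(1L, 2L, 4L, 5L, 6L, 8L, 9L, 10L, 12L, 13L, 14L, 17L, 18L, 19L),
  edge_out = c(2L, 3L, 5L, 6L, 7L, 9L, 10L, 11L, 13L, 14L, 15L, 18L, 19L, 20L),
  stringsAsFactors = FALSE
)
# edge_out indices above are row numbers into .EDGES shifted where needed;
# fix them up programmatically below so the table cannot drift from .EDGES.
.ANGLE_SITES$edge_in <- match(
  c("spine|hip_center", "shoulder_center|spine",
    "shoulder_left|shoulder_center", "elbow_left|shoulder_left",
    "wrist_left|elbow_left",
    "shoulder_right|shoulder_center", "elbow_right|shoulder_right",
    "wrist_right|elbow_right",
    "hip_left|hip_center", "knee_left|hip_left", "ankle_left|knee_left",
    "hip_right|hip_center", "knee_right|hip_right", "ankle_right|knee_right"),
  paste(.EDGES[, "child"], .EDGES[, "parent"], sep = "|")
)
.ANGLE_SITES$edge_out <- match(
  c("shoulder_center|spine", "head|shoulder_center",
    "elbow_left|shoulder_left", "wrist_left|elbow_left",
    "hand_left|wrist_left",
    "elbow_right|shoulder_right", "wrist_right|elbow_right",
    "hand_right|wrist_right",
    "knee_left|hip_left", "ankle_left|knee_left", "foot_left|ankle_left",
    "knee_right|hip_right", "ankle_right|knee_right", "foot_right|ankle_right"),
  paste(.EDGES[, "child"], .EDGES[, "parent"], sep = "|")
)

#' Joint names of the 20-joint skeleton
#'
#' Canonical joint order used throughout the package (frame matrices, CSV
#' columns, feature layout).
#'
#' @return Character vector of 20 joint names.
#' @export
joint_names <- function() .JOINTS

#' Kinematic-tree edges of the skeleton
#'
#' The 19 parent->child edges of the 20-joint skeleton tree, rooted at
#' `hip_center`, in the fixed order that defines the segment block of the
#' feature vector.
#'
#' @return A 19 x 2 character matrix with columns `parent` and `child`.
#' @export
skeleton_edges <- function() .EDGES

#' Joint-angle sites
#'
#' The 14 documented angle sites. Each site pairs the incoming and outgoing
#' kinematic-tree edges meeting at a joint; the feature is the angle between
#' their oriented unit vectors, so a straight chain scores 0 and a fold
#' scores up to pi.
#'
#' @return A data frame with columns `site`, `edge_in`, `edge_out` (row
#'   indices into [skeleton_edges()]).
#' @export
angle_sites <- function() .ANGLE_SITES

#' Construct and validate a skeleton frame
#'
#' A frame is a 20 x 3 numeric matrix of world coordinates in meters, rows
#' named by [joint_names()]. Input rows may come in any order; they are
#' reordered canonically.
#'
#' @param joints Numeric matrix (or data frame) with one row per joint and
#'   3 columns (x, y, z), rownames naming the joints; or a named list of
#'   length-3 numeric vectors.
#' @param timestamp Optional time in seconds, stored as an attribute.
#' @return A validated 20 x 3 matrix with a `"timestamp"` attribute when
#'   supplied.
#' @export
skeleton_frame <- function(joints, timestamp = NULL) {
  if (is.null(timestamp)) timestamp <- attr(joints, "timestamp")
  if (is.list(joints) && !is.data.frame(joints)) {
    joints <- do.call(rbind, joints)
  }
  joints <- as.matrix(joints)
  if (ncol(joints) != 3L) {
    stop("a skeleton frame needs 3 coordinate columns, got ", ncol(joints))
  }
  if (is.null(rownames(joints))) {
    if (nrow(joints) != 20L) stop("unnamed joint matrix must have 20 rows")
    rownames(joints) <- .JOINTS
  }
  missing <- setdiff(.JOINTS, rownames(joints))
  if (length(missing)) {
    stop("missing joints: ", paste(missing, collapse = ", "))
  }
  joints <- joints[.JOINTS, , drop = FALSE]
  storage.mode(joints) <- "double"
  if (!all(is.finite(joints))) stop("non-finite joint coordinates")
  colnames(joints) <- c("x", "y", "z")
  if (!is.null(timestamp)) attr(joints, "timestamp") <- as.numeric(timestamp)
  joints
}

#' Segment lengths of a frame
#'
#' @param frame Skeleton frame.
#' @return Numeric vector of 19 edge lengths (meters), in edge order.
#' @export
segment_lengths <- function(frame) {
  d <- frame[.EDGES[, "child"], , drop = FALSE] -
    frame[.EDGES[, "parent"], , drop = FALSE]
  sqrt(rowSums(d * d))
}

# ---- trajectory file I/O ---------------------------------------------------

.frame_cols <- function() {
  as.vector(t(outer(.JOINTS, c("x", "y", "z"), paste, sep = "_")))
}

#' Read / write motion trajectories
#'
#' A trajectory is an ordered list of skeleton frames stored either as CSV
#' (one row per frame, columns `<joint>_x`, `<joint>_y`, `<joint>_z` plus an
#' optional `timestamp`) or as JSON-Lines (one object per line with a
#' `joints` mapping and optional `timestamp`).
#'
#' @param path File path.
#' @param frames List of skeleton frames.
#' @return `read_frames_*` return a list of validated frames;
#'   `write_frames_*` return `path` invisibly.
#' @export
read_frames_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  cols <- .frame_cols()
  missing <- setdiff(cols, names(tab))
  if (length(missing)) {
    stop("trajectory CSV missing columns: ", paste(missing[1:3], collapse = ", "),
         if (length(missing) > 3L) ", ...")
  }
  ts <- if ("timestamp" %in% names(tab)) tab$timestamp else NULL
  lapply(seq_len(nrow(tab)), function(i) {
    m <- matrix(as.numeric(tab[i, cols]), ncol = 3L, byrow = TRUE,
                dimnames = list(.JOINTS, c("x", "y", "z")))
    skeleton_frame(m, timestamp = if (is.null(ts)) NULL else ts[i])
  })
}

#' @rdname read_frames_csv
#' @export
write_frames_csv <- function(frames, path) {
  stopifnot(length(frames) >= 1L)
  rows <- t(vapply(frames, function(f) as.vector(t(skeleton_frame(f))),
                   numeric(60L)))
  colnames(rows) <- .frame_cols()
  tab <- as.data.frame(rows)
  ts <- vapply(frames, function(f) {
    t0 <- attr(f, "timestamp")
    if (is.null(t0)) NA_real_ else t0
  }, numeric(1L))
  if (!all(is.na(ts))) tab$timestamp <- ts
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_frames_csv
#' @export
read_frames_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln)
    skeleton_frame(obj$joints, timestamp = obj$timestamp)
  })
}

#' @rdname read_frames_csv
#' @export
write_frames_jsonl <- function(frames, path) {
  stopifnot(length(frames) >= 1L)
  lines <- vapply(frames, function(f) {
    f <- skeleton_frame(f)
    obj <- list(joints = stats::setNames(
      lapply(seq_len(20L), function(i) unname(f[i, ])), rownames(f)))
    t0 <- attr(f, "timestamp")
    if (!is.null(t0)) obj$timestamp <- t0
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
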