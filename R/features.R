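# Body-plane coordinate transform and the 71-D per-frame posture descriptor:
# 19 unit segment vectors (3 x 19 = 57 components) + 14 joint angles.

.unitize <- function(v, what = "vector", tol = 1e-10) {
  n <- sqrt(sum(v * v))
  if (!is.finite(n) || n < tol) stop("degenerate zero-length ", what)
  v / n
}

#' Body-plane basis of a skeleton frame
#'
#' Builds the subject-centered orthonormal frame at the spine: `u` points
#' from the spine to the shoulder center (body-vertical), `v` is the
#' Gram-Schmidt residual of spine->shoulder_left against `u` (body-lateral),
#' and `w = u x v` completes a right-handed system. The spanned X-Y plane is
#' the coronal plane, Y-Z the sagittal, X-Z the transverse.
#'
#' @param frame Skeleton frame (see [skeleton_frame()]).
#' @return List with `origin` (spine position) and unit vectors `u`, `v`,
#'   `w`, class `"body_basis"`.
#' @export
compute_body_basis <- function(frame) {
  frame <- skeleton_frame(frame)
  origin <- frame["spine", ]
  a <- frame["shoulder_center", ] - origin
  b <- frame["shoulder_left", ] - origin
  if (sqrt(sum(a * a)) < 1e-10 || sqrt(sum(b * b)) < 1e-10) {
    stop("degenerate frame: spine, shoulder_center, shoulder_left coincide")
  }
  u <- a / sqrt(sum(a * a))
  r <- b - sum(b * u) * u
  if (sqrt(sum(r * r)) < 1e-10) {
    stop("degenerate frame: spine, shoulder_center, shoulder_left collinear")
  }
  v <- r / sqrt(sum(r * r))
  w <- c(u[2L] * v[3L] - u[3L] * v[2L],
         u[3L] * v[1L] - u[1L] * v[3L],
         u[1L] * v[2L] - u[2L] * v[1L])
  structure(list(origin = origin, u = unname(u), v = unname(v), w = unname(w)),
            class = "body_basis")
}

#' Transform a frame into body-plane coordinates
#'
#' Maps every joint `p` to `((p - origin) . v, (p - origin) . u,
#' (p - origin) . w)`, so the spine lands at the origin, the new Y axis is
#' the body-vertical and the X-Y plane is the coronal plane. The transform
#' is invariant to translation and to any rigid rotation of the whole
#' skeleton (the basis co-rotates).
#'
#' @param frame Skeleton frame.
#' @param basis Body basis from [compute_body_basis()]; recomputed from
#'   `frame` when omitted.
#' @return Skeleton frame in body-plane coordinates.
#' @export
to_body_coordinates <- function(frame, basis = compute_body_basis(frame)) {
  frame <- skeleton_frame(frame)
  centered <- sweep(frame, 2L, basis$origin)
  out <- cbind(centered %*% basis$v, centered %*% basis$u, centered %*% basis$w)
  dimnames(out) <- list(rownames(frame), c("x", "y", "z"))
  ts <- attr(frame, "timestamp")
  if (!is.null(ts)) attr(out, "timestamp") <- ts
  out
}

#' Extract the 71-D posture descriptor of a frame
#'
#' The descriptor concatenates, in fixed order, the 19 unit vectors of the
#' kinematic-tree segments expressed in body-plane coordinates (57 values)
#' and the 14 joint angles in radians (angle between the oriented incoming
#' and outgoing segment unit vectors at each site of [angle_sites()], in
#' `[0, pi]`). Unit vectors and angles are invariant to global translation,
#' rigid rotation and uniform scaling of the skeleton.
#'
#' With `scale_angles = TRUE` angles are divided by pi so all 71 entries lie
#' in `[-1, 1]`; this is the scaling used for map training, where raw
#' radians would dominate the Euclidean metric.
#'
#' @param frame Skeleton frame (world coordinates).
#' @param scale_angles Divide angles by pi? Default `FALSE` (radians).
#' @return Named numeric vector of length 71.
#' @export
extract_features <- function(frame, scale_angles = FALSE) {
  body <- to_body_coordinates(frame)
  edges <- skeleton_edges()
  seg <- body[edges[, "child"], , drop = FALSE] -
    body[edges[, "parent"], , drop = FALSE]
  len <- sqrt(rowSums(seg * seg))
  zero <- which(len < 1e-10)
  if (length(zero)) {
    stop("zero-length segment: ", edges[zero[1L], "parent"], "->",
         edges[zero[1L], "child"])
  }
  seg <- seg / len
  sites <- angle_sites()
  cosang <- rowSums(seg[sites$edge_in, , drop = FALSE] *
                      seg[sites$edge_out, , drop = FALSE])
  ang <- acos(pmin(1, pmax(-1, cosang)))
  if (scale_angles) ang <- ang / pi
  out <- c(t(seg), ang)
  names(out) <- c(
    as.vector(t(outer(paste(edges[, "parent"], edges[, "child"], sep = "."),
                      c("x", "y", "z"), paste, sep = "_"))),
    paste0("angle_", sites$site))
  out
}

#' Feature matrix of a trajectory
#'
#' Applies [extract_features()] to every frame of a trajectory.
#'
#' @param frames List of skeleton frames.
#' @param scale_angles Passed to [extract_features()]; defaults to `TRUE`,
#'   the scaling used throughout the map pipeline.
#' @return Numeric matrix, one row per frame, 71 columns.
#' @export
trajectory_features <- function(frames, scale_angles = TRUE) {
  if (length(frames) == 0L) stop("empty trajectory")
  t(vapply(frames, extract_features, numeric(71L), scale_angles = scale_angles))
}
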