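# Synthetic multi-subject skeletal recordings of 12 coarse full-body
# exercises. Key poses are the package's own encodings of typical
# physiotherapy movements (arm raises, trunk bends/rotation, squat, knee
# raises, forward reach); trajectories are piecewise-linear interpolations
# between key poses with per-frame bone-length renormalization, then
# perturbed (speed, pause, facing rotation, sensor noise, height scaling).

#' Canonical neutral standing skeleton
#'
#' A 20-joint skeleton of a ~1.75 m subject standing upright facing the
#' sensor, arms at the sides. World axes: x lateral (subject's left at -x),
#' y up, z toward the sensor. Units: meters.
#'
#' @return A validated skeleton frame.
#' @export
canonical_skeleton <- function() {
  skeleton_frame(matrix(c(
    0.00, 1.00, 0.00,   # hip_center
    0.00, 1.12, 0.00,   # spine
    0.00, 1.45, 0.00,   # shoulder_center
    0.00, 1.66, 0.00,   # head
    -0.19, 1.42, 0.00,  # shoulder_left
    -0.24, 1.15, 0.00,  # elbow_left
    -0.27, 0.90, 0.00,  # wrist_left
    -0.28, 0.82, 0.00,  # hand_left
    0.19, 1.42, 0.00,   # shoulder_right
    0.24, 1.15, 0.00,   # elbow_right
    0.27, 0.90, 0.00,   # wrist_right
    0.28, 0.82, 0.00,   # hand_right
    -0.10, 0.96, 0.00,  # hip_left
    -0.12, 0.52, 0.00,  # knee_left
    -0.13, 0.08, 0.00,  # ankle_left
    -0.13, 0.02, 0.14,  # foot_left
    0.10, 0.96, 0.00,   # hip_right
    0.12, 0.52, 0.00,   # knee_right
    0.13, 0.08, 0.00,   # ankle_right
    0.13, 0.02, 0.14    # foot_right
  ), ncol = 3L, byrow = TRUE, dimnames = list(joint_names(), c("x", "y", "z"))))
}

# ---- pose construction helpers --------------------------------------------

# reposition an arm chain given unit directions shoulder->elbow and
# elbow->wrist (hand continues the forearm); lengths from the input frame
.pose_arm <- function(frame, side, d_upper, d_fore) {
  sh <- paste0("shoulder_", side); el <- paste0("elbow_", side)
  wr <- paste0("wrist_", side); ha <- paste0("hand_", side)
  l1 <- sqrt(sum((frame[el, ] - frame[sh, ])^2))
  l2 <- sqrt(sum((frame[wr, ] - frame[el, ])^2))
  l3 <- sqrt(sum((frame[ha, ] - frame[wr, ])^2))
  d_upper <- d_upper / sqrt(sum(d_upper^2))
  d_fore <- d_fore / sqrt(sum(d_fore^2))
  frame[el, ] <- frame[sh, ] + l1 * d_upper
  frame[wr, ] <- frame[el, ] + l2 * d_fore
  frame[ha, ] <- frame[wr, ] + l3 * d_fore
  frame
}

.pose_leg <- function(frame, side, d_thigh, d_shank, d_foot = NULL) {
  hp <- paste0("hip_", side); kn <- paste0("knee_", side)
  an <- paste0("ankle_", side); ft <- paste0("foot_", side)
  l1 <- sqrt(sum((frame[kn, ] - frame[hp, ])^2))
  l2 <- sqrt(sum((frame[an, ] - frame[kn, ])^2))
  l3 <- sqrt(sum((frame[ft, ] - frame[an, ])^2))
  d_thigh <- d_thigh / sqrt(sum(d_thigh^2))
  d_shank <- d_shank / sqrt(sum(d_shank^2))
  if (is.null(d_foot)) d_foot <- c(0, -0.2, 1)
  d_foot <- d_foot / sqrt(sum(d_foot^2))
  frame[kn, ] <- frame[hp, ] + l1 * d_thigh
  frame[an, ] <- frame[kn, ] + l2 * d_shank
  frame[ft, ] <- frame[an, ] + l3 * d_foot
  frame
}

.rot_y <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3L, 3L)
}
.rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
}
.rot_x <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3L, 3L)
}

.UPPER_JOINTS <- c("spine", "shoulder_center", "head",
                   "shoulder_left", "elbow_left", "wrist_left", "hand_left",
                   "shoulder_right", "elbow_right", "wrist_right", "hand_right")

# rotate the upper body (everything above the hip center) about an axis
# through the hip center
.pose_trunk <- function(frame, R) {
  pivot <- frame["hip_center", ]
  up <- .UPPER_JOINTS
  frame[up, ] <- sweep(sweep(frame[up, , drop = FALSE], 2L, pivot) %*% t(R),
                       2L, pivot, `+`)
  frame
}

#' Exercise specification
#'
#' @param label Exercise name.
#' @param key_poses Ordered list of >= 2 skeleton frames of the canonical
#'   subject.
#' @param dwell_fractions Per-pose positive fractions of the total duration
#'   (normalized to sum to 1); equal by default.
#' @return Object of class `"exercise_spec"`.
#' @export
exercise_spec <- function(label, key_poses, dwell_fractions = NULL) {
  stopifnot(length(key_poses) >= 2L)
  key_poses <- lapply(key_poses, skeleton_frame)
  if (is.null(dwell_fractions)) {
    dwell_fractions <- rep(1 / length(key_poses), length(key_poses))
  }
  stopifnot(length(dwell_fractions) == length(key_poses),
            all(dwell_fractions > 0))
  dwell_fractions <- dwell_fractions / sum(dwell_fractions)
  structure(list(label = as.character(label), key_poses = key_poses,
                 dwell_fractions = dwell_fractions,
                 canonical_lengths = segment_lengths(key_poses[[1L]])),
            class = "exercise_spec")
}

#' The 12 built-in coarse exercises
#'
#' Key-pose encodings of 12 full-body exercises of the kind assigned in
#' Parkinson's physiotherapy: bilateral arm raises (front, side, overhead),
#' single-arm overhead raises, lateral trunk bends, a trunk rotation, a
#' squat, knee raises, and a forward reach-and-bend. Each starts and ends at
#' the neutral stance. These are package fixtures, not measured data.
#'
#' @return Named list of 12 [exercise_spec()] objects.
#' @export
exercise_specs <- function() {
  neutral <- canonical_skeleton()
  # hold-dominated dwell: the target posture is held for most of a
  # repetition (typical physiotherapy prescription: hold several seconds,
  # transition in one or two)
  cyc <- function(label, peak, dwell = c(0.2, 0.6, 0.2)) {
    exercise_spec(label, list(neutral, peak, neutral), dwell)
  }

  arms_front <- .pose_arm(.pose_arm(neutral, "left", c(-0.1, 0, 1), c(0, 0, 1)),
                          "right", c(0.1, 0, 1), c(0, 0, 1))
  arms_side <- .pose_arm(.pose_arm(neutral, "left", c(-1, 0.05, 0), c(-1, 0, 0)),
                         "right", c(1, 0.05, 0), c(1, 0, 0))
  arms_up <- .pose_arm(.pose_arm(neutral, "left", c(-0.15, 1, 0), c(0, 1, 0)),
                       "right", c(0.15, 1, 0), c(0, 1, 0))
  left_up <- .pose_arm(neutral, "left", c(-0.15, 1, 0), c(0, 1, 0))
  right_up <- .pose_arm(neutral, "right", c(0.15, 1, 0), c(0, 1, 0))
  # standing side stretches: ~35 deg lateral trunk inclination with the
  # opposite arm reaching over the head toward the bend side (standard
  # form; the reach tilts well past vertical, unlike a plain arm raise)
  bend_left <- .pose_trunk(.pose_arm(neutral, "right", c(-0.5, 0.85, 0),
                                     c(-0.6, 0.8, 0)), .rot_z(-35))
  bend_right <- .pose_trunk(.pose_arm(neutral, "left", c(0.5, 0.85, 0),
                                      c(0.6, 0.8, 0)), .rot_z(35))
  # rotations at ~50 deg with the arms extended forward so the turn carries
  # a directional signature beyond the leg counter-rotation
  rot_base <- .pose_arm(.pose_arm(neutral, "left", c(-0.1, 0, 1), c(0, 0, 1)),
                        "right", c(0.1, 0, 1), c(0, 0, 1))
  rot_left <- .pose_trunk(rot_base, .rot_y(50))
  rot_right <- .pose_trunk(rot_base, .rot_y(-50))

  # squat: hips drop and sit back, knees travel forward, trunk leans
  # ~30 deg forward, hands brought together at the chest (standard form,
  # and distinct from the forward arm raise)
  squat <- neutral
  drop <- c(0, -0.25, -0.08)
  squat[c("hip_center", "hip_left", "hip_right", .UPPER_JOINTS), ] <-
    sweep(squat[c("hip_center", "hip_left", "hip_right", .UPPER_JOINTS), ,
                drop = FALSE], 2L, drop, `+`)
  squat <- .pose_trunk(squat, .rot_x(30))
  squat <- .pose_arm(squat, "left", c(-0.3, -0.6, 0.75), c(0.9, 0.45, 0.1))
  squat <- .pose_arm(squat, "right", c(0.3, -0.6, 0.75), c(-0.9, 0.45, 0.1))
  squat <- .pose_leg(squat, "left", c(-0.05, -0.45, 0.9), c(0, -1, -0.4))
  squat <- .pose_leg(squat, "right", c(0.05, -0.45, 0.9), c(0, -1, -0.4))

  # marching knee raises: thigh horizontal (90 deg hip flexion), shank
  # vertical, counter-arm swing forward
  knee_l <- .pose_leg(neutral, "left", c(-0.05, -0.1, 1), c(0, -1, 0.1))
  knee_l <- .pose_arm(knee_l, "right", c(0.1, -0.3, 0.95), c(0, 0.1, 1))
  knee_r <- .pose_leg(neutral, "right", c(0.05, -0.1, 1), c(0, -1, 0.1))
  knee_r <- .pose_arm(knee_r, "left", c(-0.1, -0.3, 0.95), c(0, 0.1, 1))

  # overhead reach then forward hinge ("reach and sweep"): arms overhead,
  # then a ~45 deg hip hinge with the arms following forward
  reach <- .pose_trunk(arms_up, .rot_x(45))

  specs <- list(
    cyc("arm_raise_front", arms_front),
    cyc("arm_raise_side", arms_side),
    # overhead raise travels through the lateral position (raise through
    # the side, the common prescribed form)
    exercise_spec("arm_raise_overhead",
                  list(neutral, arms_side, arms_up, arms_side, neutral),
                  c(0.1, 0.2, 0.4, 0.2, 0.1)),
    cyc("arm_raise_left", left_up),
    cyc("arm_raise_right", right_up),
    cyc("side_stretch_left", bend_left),
    cyc("side_stretch_right", bend_right),
    exercise_spec("trunk_rotation",
                  list(neutral, rot_left, neutral, rot_right, neutral),
                  c(0.1, 0.3, 0.2, 0.3, 0.1)),
    cyc("squat", squat),
    cyc("knee_raise_left", knee_l),
    cyc("knee_raise_right", knee_r),
    # overhead reach followed by a forward hinge and back
    exercise_spec("reach_forward",
                  list(neutral, arms_up, reach, arms_up, neutral),
                  c(0.1, 0.25, 0.3, 0.25, 0.1))
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1L), "label"))
}

# renormalize every segment of a frame to the canonical lengths, walking the
# tree root-down (edge order is topological)
.renormalize_bones <- function(frame, lengths) {
  edges <- skeleton_edges()
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, "parent"]; ch <- edges[i, "child"]
    d <- frame[ch, ] - frame[p, ]
    nd <- sqrt(sum(d * d))
    if (nd < 1e-12) stop("degenerate segment during renormalization")
    frame[ch, ] <- frame[p, ] + d / nd * lengths[i]
  }
  frame
}

#' Interpolate key poses into a frame sequence
#'
#' Models how exercises are actually performed: each key pose is *held* for
#' `hold` of its dwell fraction (a subject raising an arm pauses at the
#' raise), and the remaining time is spent in linear transitions between
#' consecutive poses (transition time proportional to the mean dwell of its
#' two endpoint poses). Frames are sampled at `n_frames` equally spaced
#' times, then every frame's bone lengths are renormalized to the canonical
#' skeleton's segment lengths (root-down), so interpolation never shrinks
#' limbs. With equal dwell and `n_frames` equal to the number of key poses,
#' the sampled frames are exactly the (renormalized) key poses.
#'
#' @param spec An [exercise_spec()].
#' @param n_frames Number of frames, at least the number of key poses.
#' @param hold Fraction of each pose's dwell spent stationary at the pose,
#'   in `[0, 1)`; default 0.7 (hold-dominated execution, with transitions
#'   taking the remaining ~30 percent of the cycle).
#' @return List of `n_frames` skeleton frames.
#' @export
interpolate_poses <- function(spec, n_frames, hold = 0.7) {
  stopifnot(inherits(spec, "exercise_spec"), hold >= 0, hold < 1)
  P <- length(spec$key_poses)
  if (n_frames < P) stop("n_frames (", n_frames, ") < number of key poses (",
                         P, ")")
  f <- spec$dwell_fractions
  # alternating segments: hold(1), trans(1->2), hold(2), ..., hold(P)
  dur <- numeric(2L * P - 1L)
  dur[seq(1L, 2L * P - 1L, by = 2L)] <- hold * f
  dur[seq(2L, 2L * P - 2L, by = 2L)] <- (1 - hold) * (f[-P] + f[-1L]) / 2
  dur <- dur / sum(dur)
  ends <- cumsum(dur)
  starts <- c(0, ends[-length(ends)])
  times <- seq(0, 1, length.out = n_frames)
  poses <- array(unlist(spec$key_poses), dim = c(20L, 3L, P))
  lapply(times, function(t0) {
    s <- findInterval(t0, starts, rightmost.closed = FALSE)
    s <- min(max(s, 1L), length(dur))
    if (s %% 2L == 1L) {           # hold segment
      fr <- poses[, , (s + 1L) %/% 2L]
    } else {                       # transition segment i -> i + 1
      i <- s %/% 2L
      a <- (t0 - starts[s]) / dur[s]
      fr <- (1 - a) * poses[, , i] + a * poses[, , i + 1L]
    }
    rownames(fr) <- joint_names()
    .renormalize_bones(skeleton_frame(fr), spec$canonical_lengths)
  })
}

#' Perturbation configuration
#'
#' Encodes the robustness conditions: `speed_factor` rescales execution
#' speed (0.5 = twice slower, doubling the frame count), `pause_spec` holds
#' the subject still mid-exercise, `rotation_deg` rotates the body about the
#' world vertical axis (45 degrees in the robustness condition),
#' `noise_sigma` is i.i.d. Gaussian sensor jitter per coordinate (default
#' 0.01 m, typical consumer depth-sensor joint noise), and `height_scale`
#' scales the skeleton uniformly about the hip center (anthropometry).
#'
#' @param n_frames Frames per generated trajectory before perturbation.
#' @param seed Integer seed.
#' @param speed_factor Positive speed multiplier.
#' @param pause_spec `NULL`, or `list(at = position fraction in [0,1],
#'   frames = number of repeated frames)`.
#' @param rotation_deg Facing rotation in degrees.
#' @param noise_sigma Noise standard deviation in meters (>= 0).
#' @param height_scale Positive uniform scale factor.
#' @return List of class `"generation_config"`.
#' @export
generation_config <- function(n_frames = 40L, seed = 1L, speed_factor = 1,
                              pause_spec = NULL, rotation_deg = 0,
                              noise_sigma = 0.01, height_scale = 1) {
  stopifnot(n_frames >= 2L, speed_factor > 0, noise_sigma >= 0,
            height_scale > 0)
  if (!is.null(pause_spec)) {
    stopifnot(pause_spec$at >= 0, pause_spec$at <= 1, pause_spec$frames >= 1)
  }
  structure(list(n_frames = as.integer(n_frames), seed = as.integer(seed),
                 speed_factor = speed_factor, pause_spec = pause_spec,
                 rotation_deg = rotation_deg, noise_sigma = noise_sigma,
                 height_scale = height_scale),
            class = "generation_config")
}

#' Apply perturbations to a frame sequence
#'
#' In order: temporal resampling by `1 / speed_factor` (linear interpolation
#' over the frame index), pause insertion (frame repetition at the pause
#' position), rigid rotation about the world vertical axis, i.i.d. Gaussian
#' positional noise, and uniform height scaling about each frame's hip
#' center. Deterministic given `config$seed`. An identity configuration
#' returns the frames unchanged.
#'
#' @param frames List of skeleton frames.
#' @param config A [generation_config()].
#' @return Perturbed list of skeleton frames.
#' @export
perturb_frames <- function(frames, config) {
  stopifnot(inherits(config, "generation_config"), length(frames) >= 1L)
  arr <- array(unlist(frames), dim = c(20L, 3L, length(frames)))

  if (config$speed_factor != 1) {
    n <- dim(arr)[3L]
    n2 <- max(2L, as.integer(round(n / config$speed_factor)))
    at <- seq(1, n, length.out = n2)
    lo <- pmin(floor(at), n - 1L); a <- at - lo
    arr2 <- array(0, dim = c(20L, 3L, n2))
    for (t in seq_len(n2)) {
      arr2[, , t] <- (1 - a[t]) * arr[, , lo[t]] + a[t] * arr[, , lo[t] + 1L]
    }
    arr <- arr2
  }
  if (!is.null(config$pause_spec)) {
    n <- dim(arr)[3L]
    pos <- min(max(1L, as.integer(round(1 + config$pause_spec$at * (n - 1L)))), n)
    idx <- c(seq_len(pos), rep(pos, config$pause_spec$frames),
             if (pos < n) (pos + 1L):n)
    arr <- arr[, , idx, drop = FALSE]
  }
  if (config$rotation_deg != 0) {
    R <- .rot_y(config$rotation_deg)
    for (t in seq_len(dim(arr)[3L])) arr[, , t] <- arr[, , t] %*% t(R)
  }
  .with_seed(config$seed, {
    if (config$noise_sigma > 0) {
      arr <- arr + array(stats::rnorm(length(arr), sd = config$noise_sigma),
                         dim = dim(arr))
    }
  })
  if (config$height_scale != 1) {
    for (t in seq_len(dim(arr)[3L])) {
      hip <- arr[1L, , t]  # hip_center is joint 1 in canonical order
      arr[, , t] <- sweep(config$height_scale * sweep(arr[, , t], 2L, hip),
                          2L, hip, `+`)
    }
  }
  lapply(seq_len(dim(arr)[3L]), function(t) {
    f <- arr[, , t]
    rownames(f) <- joint_names()
    skeleton_frame(f)
  })
}

#' Generate a labeled multi-subject dataset
#'
#' For each subject, draws a height scale (uniform in 0.92-1.08, spanning
#' the stature range of a mixed adult cohort) and a per-subject jitter of
#' every key pose (Gaussian, sd 0.015 m on non-root joints) from the seeded
#' generator, then emits `reps` trajectories per exercise and subject, each
#' with its own noise realization. Reproducible given `seed`.
#'
#' @param specs Named list of [exercise_spec()]s (default all 12 built-ins).
#' @param n_subjects Number of synthetic subjects.
#' @param reps Repetitions per subject and exercise.
#' @param base_config [generation_config()] shared by all trajectories
#'   (its `seed` and `height_scale` are overridden per trajectory/subject).
#' @param seed Master seed.
#' @param subject_offset Added to subject ids (to generate disjoint cohorts).
#' @return Object of class `"motion_dataset"`: list of trajectories, each
#'   with `label`, `subject`, `rep`, `frames` and the `config` used.
#' @export
generate_dataset <- function(specs = exercise_specs(), n_subjects = 5L,
                             reps = 1L, base_config = generation_config(),
                             seed = 1L, subject_offset = 0L) {
  stopifnot(length(specs) >= 1L)
  out <- .with_seed(seed, {
    trajs <- list()
    for (s in seq_len(n_subjects)) {
      height <- stats::runif(1L, 0.92, 1.08)
      # one jitter per subject per *unique* key pose: a subject's personal
      # stance (e.g. their neutral) is consistent across exercises and
      # repetitions of the same posture. Style variation is angular: each
      # body segment's direction is tilted by a small random rotation
      # (sd ~6 deg per axis) and positions are rebuilt down the tree, so
      # short segments are not disproportionately distorted.
      pose_jitter <- new.env(parent = emptyenv())
      edges <- skeleton_edges()
      jitter_pose <- function(f) {
        key <- paste(round(as.numeric(f), 6L), collapse = ",")
        if (is.null(pose_jitter[[key]])) {
          pose_jitter[[key]] <- lapply(seq_len(nrow(edges)), function(e) {
            ang <- stats::rnorm(3L, sd = 6)
            .rot_x(ang[1L]) %*% .rot_y(ang[2L]) %*% .rot_z(ang[3L])
          })
        }
        rots <- pose_jitter[[key]]
        out <- f
        for (e in seq_len(nrow(edges))) {
          p <- edges[e, "parent"]; ch <- edges[e, "child"]
          d <- f[ch, ] - f[p, ]
          out[ch, ] <- out[p, ] + as.numeric(rots[[e]] %*% d)
        }
        skeleton_frame(out)
      }
      subj_specs <- lapply(specs, function(sp) {
        exercise_spec(sp$label, lapply(sp$key_poses, jitter_pose),
                      sp$dwell_fractions)
      })
      for (sp in subj_specs) {
        for (r in seq_len(reps)) {
          cfg <- base_config
          cfg$seed <- sample.int(2147483646L, 1L)
          cfg$height_scale <- height
          frames <- perturb_frames(interpolate_poses(sp, cfg$n_frames), cfg)
          trajs[[length(trajs) + 1L]] <- list(
            label = sp$label, subject = s + subject_offset, rep = r,
            frames = frames, config = cfg)
        }
      }
    }
    trajs
  })
  structure(list(trajectories = out, seed = as.integer(seed)),
            class = "motion_dataset")
}

#' @export
print.motion_dataset <- function(x, ...) {
  labs <- vapply(x$trajectories, `[[`, character(1L), "label")
  cat(sprintf("motion_dataset: %d trajectories, %d exercises, %d subjects\n",
              length(x$trajectories), length(unique(labs)),
              length(unique(vapply(x$trajectories, `[[`, numeric(1L),
                                   "subject")))))
  invisible(x)
}
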