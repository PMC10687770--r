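# Per-frame series and the channel-by-frame behavior matrix.

#' Convert a rotation matrix to head-pose Euler angles
#'
#' Decomposes a rotation into intrinsic Z-Y-X (yaw about the vertical axis,
#' then pitch, then roll) Euler angles in degrees — the common head-pose
#' convention. The decomposition round-trips through [euler_to_rotation()]
#' away from gimbal lock. At gimbal lock (|pitch| within 1e-6 degrees of 90)
#' yaw and roll are not separately identifiable; roll is set to 0, the
#' remaining freedom is absorbed into yaw, and the result carries attribute
#' `gimbal_lock = TRUE`.
#'
#' @param rotation Numeric 3 x 3 rotation matrix (orthogonal, det +1,
#'   tolerance 1e-6).
#' @return Named numeric vector `c(yaw, pitch, roll)` in degrees; yaw and
#'   roll in (-180, 180], pitch in [-90, 90].
#' @export
rotation_to_euler <- function(rotation) {
  R <- as.matrix(rotation)
  if (!all(dim(R) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("rotation must be orthogonal with determinant +1")
  s <- -R[3, 1]
  s <- min(max(s, -1), 1)
  pitch <- asin(s)
  deg <- 180 / pi
  lock <- abs(abs(pitch) * deg - 90) < 1e-6
  if (lock) {
    yaw <- atan2(-R[1, 2], R[2, 2])
    roll <- 0
  } else {
    yaw <- atan2(R[2, 1], R[1, 1])
    roll <- atan2(R[3, 2], R[3, 3])
  }
  out <- c(yaw = yaw * deg, pitch = pitch * deg, roll = roll * deg)
  attr(out, "gimbal_lock") <- lock
  out
}

#' Compose a rotation matrix from head-pose Euler angles
#'
#' Inverse of [rotation_to_euler()]: intrinsic Z-Y-X composition
#' `Rz(yaw) %*% Ry(pitch) %*% Rx(roll)`, angles in degrees.
#'
#' @param yaw,pitch,roll Angles in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
euler_to_rotation <- function(yaw, pitch, roll) {
  a <- yaw * pi / 180; b <- pitch * pi / 180; c <- roll * pi / 180
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Construct an expression coefficient series
#'
#' @param values Numeric T x C matrix of per-frame expression coefficients
#'   (C = 53 with the default basis).
#' @param channel_names Character vector of C channel names; defaults to the
#'   expression part of [default_channel_descriptors()] when C = 53, else
#'   `expr_01`, ...
#' @return Object of class `expression_series`.
#' @export
expression_series <- function(values, channel_names = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (nrow(values) < 1L) stop("need at least one frame")
  C <- ncol(values)
  if (is.null(channel_names)) {
    channel_names <- if (C == 53L) default_channel_descriptors()[1:53]
                     else sprintf("expr_%02d", seq_len(C))
  }
  if (length(channel_names) != C)
    stop("channel_names must have one entry per column")
  structure(list(values = values, channel_names = channel_names),
            class = "expression_series")
}

#' Construct a head-pose angle series
#'
#' @param angles Numeric T x 3 matrix of yaw, pitch, roll in degrees (that
#'   fixed axis order). Each angle must lie in (-180, 180].
#' @return Object of class `pose_series`.
#' @export
pose_series <- function(angles) {
  angles <- as.matrix(angles)
  if (ncol(angles) != 3L) stop("angles must be T x 3 (yaw, pitch, roll)")
  if (!all(is.finite(angles))) stop("angles must be finite")
  if (any(angles <= -180 | angles > 180))
    stop("angles must lie in (-180, 180] degrees")
  colnames(angles) <- c("yaw", "pitch", "roll")
  structure(list(angles = angles), class = "pose_series")
}

#' Assemble the channel-by-frame behavior matrix
#'
#' Stacks the expression channels on top of the pose channels into a single
#' C+3 by T matrix: rows 1..C are the expression coefficients (the series
#' transposed), the last three rows are yaw, pitch and roll. With the default
#' basis this is the 56 x T representation of a recording.
#'
#' @param expr An [expression_series()].
#' @param pose A [pose_series()] over the same frames.
#' @param frame_rate Frames per second (default 30).
#' @return Object of class `behavior_matrix` with elements `values`
#'   (channels x T), `channel_descriptors`, `frame_rate`.
#' @export
assemble_behavior <- function(expr, pose, frame_rate = 30) {
  stopifnot(inherits(expr, "expression_series"), inherits(pose, "pose_series"))
  Te <- nrow(expr$values); Tp <- nrow(pose$angles)
  if (Te != Tp)
    stop("frame-count mismatch: expression has ", Te, " frames, pose has ", Tp)
  values <- rbind(t(expr$values), t(pose$angles))
  desc <- c(expr$channel_names, "pose_yaw", "pose_pitch", "pose_roll")
  rownames(values) <- desc
  behavior_matrix(values, desc, frame_rate)
}

#' Construct a behavior matrix directly
#'
#' Low-level constructor used by [assemble_behavior()] and the synthetic
#' cohort generator.
#'
#' @param values Numeric channels x T matrix.
#' @param channel_descriptors Character vector of channel names, one per row.
#' @param frame_rate Frames per second.
#' @return Object of class `behavior_matrix`.
#' @export
behavior_matrix <- function(values, channel_descriptors = rownames(values),
                            frame_rate = 30) {
  values <- as.matrix(values)
  if (is.null(channel_descriptors))
    channel_descriptors <- sprintf("ch_%02d", seq_len(nrow(values)))
  if (length(channel_descriptors) != nrow(values))
    stop("channel_descriptors must have one entry per row")
  if (!all(is.finite(values))) stop("behavior values must be finite")
  rownames(values) <- channel_descriptors
  structure(list(values = values,
                 channel_descriptors = channel_descriptors,
                 frame_rate = frame_rate),
            class = "behavior_matrix")
}

#' @export
print.behavior_matrix <- function(x, ...) {
  cat(sprintf("behavior_matrix: %d channels x %d frames at %g fps (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$frame_rate,
              ncol(x$values) / x$frame_rate))
  invisible(x)
}

#' Default channel descriptors for the 56-channel behavior matrix
#'
#' Channel order under the default region counts: 19 brow, 20 eye and
#' 14 mouth expression components, then yaw, pitch, roll.
#'
#' @return Character vector of length 56.
#' @export
default_channel_descriptors <- function() {
  c(sprintf("brow_%02d", 1:19), sprintf("eye_%02d", 1:20),
    sprintf("mouth_%02d", 1:14), "pose_yaw", "pose_pitch", "pose_roll")
}

#' Linearly interpolate gaps in a per-frame series
#'
#' Utility pre-step for recordings with dropped frames: fills runs of NA in
#' each column by linear interpolation between the neighbouring observed
#' frames (leading/trailing NAs are filled with the nearest observed value).
#' The analysis pipeline itself requires gap-free input; this helper is
#' deliberately not applied automatically.
#'
#' @param x Numeric matrix (frames in rows) possibly containing NA rows.
#' @return Matrix of the same shape with NAs filled.
#' @export
interpolate_gaps <- function(x) {
  x <- as.matrix(x)
  if (!anyNA(x)) return(x)
  tt <- seq_len(nrow(x))
  apply(x, 2L, function(col) {
    ok <- !is.na(col)
    if (!any(ok)) stop("a column is entirely NA; cannot interpolate")
    if (all(ok)) return(col)
    stats::approx(tt[ok], col[ok], xout = tt, rule = 2)$y
  })
}
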