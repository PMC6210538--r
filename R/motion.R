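#' Angle at a joint from three 2-D points
#'
#' For limb vectors `V1 = l_i - l_j` and `V2 = l_k - l_j` (e.g., ankle and
#' hip around the knee `l_j`), returns `acos(V1.V2 / |V1||V2|)` in degrees,
#' clamped into `[0, 180]`.  The angle is unsigned.  If either point
#' coincides with the vertex the angle is undefined and `NA` is returned so
#' the sample propagates as a gap.
#'
#' @param l_i,l_j,l_k Numeric `c(x, y)` points: distal joint, vertex joint,
#'   proximal joint.
#' @return Angle in degrees, or `NA_real_`.
#' @export
joint_angle <- function(l_i, l_j, l_k) {
  v1 <- c(l_i[1L] - l_j[1L], l_i[2L] - l_j[2L])
  v2 <- c(l_k[1L] - l_j[1L], l_k[2L] - l_j[2L])
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  cth <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, cth))) * 180 / pi
}

# Joints at which an angle is defined: a parent and exactly one child.
#' Parts at which joint angles are computed
#'
#' Angles are defined at every part that has both a parent and exactly one
#' child in the kinematic tree (shoulders, elbows, hips, knees for the
#' default infant tree); the vertex angle is taken between the child and the
#' parent limb vectors.
#'
#' @param tree A [kinematic_tree()].
#' @return Data frame with columns `joint`, `child`, `parent`.
#' @export
angle_joints <- function(tree) {
  js <- Filter(function(p) !is.na(tree$parent[[p]]) &&
                 length(tree$children[[p]]) == 1L, tree$parts)
  data.frame(joint = js,
             child = vapply(js, function(p) tree$children[[p]][1L], character(1L)),
             parent = vapply(js, function(p) tree$parent[[p]], character(1L)),
             stringsAsFactors = FALSE)
}

#' Encode motion as joint-angle time series
#'
#' Converts a joint trajectory into per-frame angles at every angle joint of
#' the tree.  Frames where any of the three defining joints is occluded (or
#' where the angle is undefined) yield `NA` gaps.
#'
#' @param trajectory Data frame with columns `frame`, `part`, `x`, `y`,
#'   `visible` (one row per joint per frame).
#' @param tree A [kinematic_tree()].
#' @param smooth_window Optional odd window for a moving-median smoother
#'   applied per joint (default `NULL`, no smoothing).
#' @return Data frame with columns `frame`, `joint`, `theta` (degrees in
#'   `[0, 180]` or `NA`).
#' @export
encode_motion <- function(trajectory, tree = infant_tree(),
                          smooth_window = NULL) {
  aj <- angle_joints(tree)
  frames <- sort(unique(trajectory$frame))
  key <- paste(trajectory$frame, trajectory$part)
  look <- function(f, p) {
    i <- match(paste(f, p), key)
    if (is.na(i) || !isTRUE(trajectory$visible[i])) return(NULL)
    c(trajectory$x[i], trajectory$y[i])
  }
  out <- do.call(rbind, lapply(seq_len(nrow(aj)), function(r) {
    th <- vapply(frames, function(f) {
      li <- look(f, aj$child[r]); lj <- look(f, aj$joint[r]); lk <- look(f, aj$parent[r])
      if (is.null(li) || is.null(lj) || is.null(lk)) return(NA_real_)
      joint_angle(li, lj, lk)
    }, numeric(1L))
    if (!is.null(smooth_window) && smooth_window > 1L)
      th <- stats::runmed(th, k = smooth_window, endrule = "median")
    data.frame(frame = frames, joint = aj$joint[r], theta = th,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Convert a list of pose estimates to a joint trajectory
#'
#' @param poses List of `pose_estimate` objects (possibly with `NULL`
#'   entries for undetected frames).
#' @param frames Frame indices (default `seq_along(poses)`).
#' @return Trajectory data frame (`frame`, `part`, `x`, `y`, `visible`).
#' @export
poses_to_trajectory <- function(poses, frames = seq_along(poses)) {
  out <- do.call(rbind, lapply(seq_along(poses), function(i) {
    p <- poses[[i]]
    if (is.null(p)) return(NULL)
    data.frame(frame = frames[i], part = p$parts$part,
               x = p$parts$x, y = p$parts$y, visible = p$parts$visible,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Join predicted and truth trajectories on (frame, part), keeping pairs
# visible on both sides.
match_trajectories <- function(predicted, truth) {
  m <- merge(predicted, truth, by = c("frame", "part"),
             suffixes = c("_pred", "_true"))
  m[m$visible_pred & m$visible_true, , drop = FALSE]
}

#' Average joint position error
#'
#' Mean Euclidean distance between predicted and ground-truth joint
#' locations, per part and averaged across parts, in millimeters
#' (`mm_per_px = 1` reports pixel units).
#'
#' @param predicted,truth Trajectory data frames (`frame`, `part`, `x`, `y`,
#'   `visible`).
#' @param mm_per_px Millimeters per pixel (> 0).
#' @return List with `per_part` (named means) and `mean` (average across
#'   parts).
#' @export
ajpe <- function(predicted, truth, mm_per_px = 1) {
  if (mm_per_px <= 0) stop("mm_per_px must be positive")
  if (mm_per_px == 1)
    message("ajpe: mm_per_px = 1, errors reported in pixel units")
  m <- match_trajectories(predicted, truth)
  if (!nrow(m)) stop("no matched visible frames between predicted and truth")
  d <- sqrt((m$x_pred - m$x_true)^2 + (m$y_pred - m$y_true)^2) * mm_per_px
  per <- tapply(d, m$part, mean)
  list(per_part = per, mean = mean(per))
}

#' Worst-case accuracy
#'
#' Percentage of frames in which every matched joint lies within
#' `omega_wca` of its ground truth; a frame with even one joint beyond the
#' threshold counts as a failure.  The published operating points are 5 cm
#' and 3 cm.
#'
#' @inheritParams ajpe
#' @param omega_wca Distance threshold, in the units implied by
#'   `mm_per_px`.
#' @return Percentage in `[0, 100]`.
#' @export
wca <- function(predicted, truth, omega_wca, mm_per_px = 1) {
  m <- match_trajectories(predicted, truth)
  if (!nrow(m)) stop("no matched visible frames between predicted and truth")
  d <- sqrt((m$x_pred - m$x_true)^2 + (m$y_pred - m$y_true)^2) * mm_per_px
  ok <- tapply(d <= omega_wca, m$frame, all)
  100 * mean(ok)
}

#' Mean absolute error between angle series
#'
#' @param predicted,truth Angle data frames (`frame`, `joint`, `theta`);
#'   `NA` samples (gaps) are excluded pairwise.
#' @return List with `per_joint` (named MAE, degrees) and `mean`.
#' @export
mae_angles <- function(predicted, truth) {
  m <- merge(predicted, truth, by = c("frame", "joint"),
             suffixes = c("_pred", "_true"))
  m <- m[!is.na(m$theta_pred) & !is.na(m$theta_true), , drop = FALSE]
  if (!nrow(m)) stop("no overlapping angle samples between predicted and truth")
  e <- abs(m$theta_pred - m$theta_true)
  per <- tapply(e, m$joint, mean)
  list(per_joint = per, mean = mean(per))
}
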