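# Discriminative-pose summaries of analysis windows.
#
# A window is reduced to three poses per 2-s sub-window: the mean pose
# (per-keypoint average), the maximum pose (the frame where the hand
# centroids are furthest apart) and the minimum pose (closest
# together). A 180-frame window therefore yields 9 poses; a 360-frame
# window yields 18.

# flatten one 46 x 3 hand+arm frame to the 92-coordinate pose vector
# (x1, y1, x2, y2, ...)
#' @keywords internal
hm_flatten_pose <- function(frame) {
  as.vector(t(frame[, 1:2, drop = FALSE]))
}

#' Mean pose of a frame sequence
#'
#' Per-keypoint arithmetic mean of the coordinates over the supplied
#' frames. Confidences are averaged as well so downstream weighting
#' stays meaningful.
#'
#' @param ha array `m x 46 x 3` of hand+arm frames.
#' @return a `46 x 3` matrix.
#' @export
mean_pose <- function(ha) {
  if (dim(ha)[1] < 1) stop("mean pose of an empty sequence")
  out <- apply(ha, c(2, 3), mean)
  out
}

#' Extremal poses of a frame sequence
#'
#' The maximum pose is the frame whose hand centroids are furthest
#' apart (Euclidean distance); the minimum pose the frame where they are
#' closest. Ties pick the earliest frame, so output is deterministic.
#'
#' @param ha array `m x 46 x 3` of hand+arm frames.
#' @param centroids `m x 2 x 2` centroid array aligned with `ha` (from
#'   [hand_centroids()]).
#' @return list with elements `maximum` and `minimum` (each `46 x 3`)
#'   and the frame indices `i_max`, `i_min` (1-based within `ha`).
#' @export
extremal_poses <- function(ha, centroids) {
  if (dim(ha)[1] != dim(centroids)[1])
    stop("centroids are not aligned with frames")
  d <- sqrt((centroids[, "r", "x"] - centroids[, "l", "x"])^2 +
            (centroids[, "r", "y"] - centroids[, "l", "y"])^2)
  i_max <- which.max(d)  # which.max/min return the earliest tie
  i_min <- which.min(d)
  list(maximum = ha[i_max, , ], minimum = ha[i_min, , ],
       i_max = i_max, i_min = i_min)
}

#' Summarise a window by discriminative poses
#'
#' The window is divided into consecutive complete sub-windows of
#' `subwindow_frames` frames (2 s at 30 fps, the smallest span that
#' always contains movement); each contributes a mean, a maximum and a
#' minimum pose, in that order. For 12-s windows the rule generalises to
#' 18 poses by default; `central_180 = TRUE` restricts to the central
#' 180 frames for strict 9-pose parity with 6-s windows.
#'
#' @param window an `hm_window` from [segment_windows()].
#' @param subwindow_frames sub-window length in frames.
#' @param central_180 use only the central 180 frames of longer windows.
#' @return an `hm_poseset`: list with `poses` (matrix, one 92-coordinate
#'   row per pose), `kind`, `subwindow` and `meta`.
#' @export
discriminative_poses <- function(window, subwindow_frames = 60,
                                 central_180 = FALSE) {
  ha <- window$kp
  cen <- window$centroids
  m <- dim(ha)[1]
  if (central_180 && m > 180L) {
    off <- (m - 180L) %/% 2L
    keep <- (off + 1L):(off + 180L)
    ha <- ha[keep, , , drop = FALSE]
    cen <- cen[keep, , , drop = FALSE]
    m <- 180L
  }
  ns <- m %/% subwindow_frames
  if (ns < 1)
    stop("window of ", m, " frames is shorter than one sub-window (",
         subwindow_frames, " frames)")
  poses <- matrix(NA_real_, nrow = 3L * ns, ncol = 92L)
  for (s in seq_len(ns)) {
    idx <- ((s - 1L) * subwindow_frames + 1L):(s * subwindow_frames)
    ext <- extremal_poses(ha[idx, , , drop = FALSE],
                          cen[idx, , , drop = FALSE])
    poses[3L * s - 2L, ] <- hm_flatten_pose(mean_pose(ha[idx, , , drop = FALSE]))
    poses[3L * s - 1L, ] <- hm_flatten_pose(ext$maximum)
    poses[3L * s, ]      <- hm_flatten_pose(ext$minimum)
  }
  structure(
    list(poses = poses,
         kind = rep(c("mean", "maximum", "minimum"), ns),
         subwindow = rep(seq_len(ns), each = 3L),
         meta = window$meta),
    class = "hm_poseset"
  )
}

#' @export
print.hm_poseset <- function(x, ...) {
  cat(sprintf("<hm_poseset> %d poses (%d sub-windows x 3 kinds)\n",
              nrow(x$poses), max(x$subwindow)))
  invisible(x)
}

#' Flatten a discriminative pose set to a single feature vector
#'
#' Poses are concatenated in (sub-window, kind) order; each contributes
#' 46 keypoints x 2 coordinates, so a 9-pose set yields the 828-length
#' vector used by vector-classifier baselines.
#'
#' @param set an `hm_poseset`.
#' @return numeric vector of length `92 * nrow(set$poses) / ... `
#'   (828 for 9 poses).
#' @export
vectorise_poses <- function(set) {
  stopifnot(inherits(set, "hm_poseset"))
  as.vector(t(set$poses))
}
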