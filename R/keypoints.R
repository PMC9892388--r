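# Keypoint layout shared by every module.
#
# A frame carries 50 keypoints: 8 upper-body points (nose, neck, both
# shoulders, elbows and wrists) and 21 points per hand in the standard
# OpenPose hand layout (wrist root plus 4 points per digit). Coordinates
# are image coordinates: x grows rightwards, y grows DOWNWARDS.

#' @keywords internal
hm_body_names <- function() {
  c("nose", "neck",
    "r_shoulder", "r_elbow", "r_wrist",
    "l_shoulder", "l_elbow", "l_wrist")
}

#' @keywords internal
hm_kp_names <- function() {
  c(hm_body_names(),
    paste0("l_hand_", 0:20),
    paste0("r_hand_", 0:20))
}

# 46-keypoint hand+arm layout used after re-centring on the wrist
# midpoint: elbows, wrists and both hands; other body points dropped.
#' @keywords internal
hm_ha_names <- function() {
  c("l_elbow", "l_wrist", "r_elbow", "r_wrist",
    paste0("l_hand_", 0:20),
    paste0("r_hand_", 0:20))
}

# left/right label swap used when reflecting a skeleton
#' @keywords internal
hm_swap_names <- function(nms) {
  out <- nms
  out <- sub("^l_", "TMP_", out)
  out <- sub("^r_", "l_", out)
  out <- sub("^TMP_", "r_", out)
  out
}

#' Construct a keypoint recording
#'
#' A recording is the container every other function consumes: an ordered
#' stack of frames, each holding 50 named keypoints with image
#' coordinates and a detector confidence in `[0, 1]`. A keypoint with
#' confidence 0 at position (0, 0) is treated as missing, matching the
#' OpenPose convention.
#'
#' @param kp numeric array `n_frames x 50 x 3`, third dimension named
#'   `c("x", "y", "c")`. Keypoint order must match [hm_kp_names()].
#' @param fps frames per second of the recording.
#' @param meta named list of metadata (subject id, movement label,
#'   commanded repetition rate, ...). Free-form; the pipeline reads
#'   `subject`, `class`, `rate` and `intensity` when present.
#' @param imputed optional logical `n_frames x 50` matrix flagging
#'   keypoints filled in by [impute_missing()].
#' @return an object of class `hm_recording`.
#' @export
hm_recording <- function(kp, fps, meta = list(), imputed = NULL) {
  stopifnot(is.array(kp), length(dim(kp)) == 3L)
  if (dim(kp)[2] != 50L)
    stop("a recording frame must have exactly 50 keypoints, got ", dim(kp)[2])
  if (dim(kp)[3] != 3L)
    stop("keypoint array must have x, y, c slices")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  dimnames(kp) <- list(NULL, hm_kp_names(), c("x", "y", "c"))
  cc <- kp[, , "c"]
  if (any(cc < 0 | cc > 1, na.rm = TRUE))
    stop("keypoint confidences must lie in [0, 1]")
  structure(
    list(kp = kp, fps = fps, meta = meta, imputed = imputed),
    class = "hm_recording"
  )
}

#' @export
print.hm_recording <- function(x, ...) {
  cat(sprintf("<hm_recording> %d frames @ %g fps (%.1f s)\n",
              n_frames(x), x$fps, n_frames(x) / x$fps))
  if (length(x$meta)) {
    keep <- intersect(c("subject", "class", "rate", "intensity"), names(x$meta))
    if (length(keep))
      cat("  ", paste(sprintf("%s=%s", keep, unlist(x$meta[keep])),
                      collapse = ", "), "\n", sep = "")
  }
  miss <- sum(missing_mask(x))
  if (miss > 0) cat(sprintf("  %d missing keypoint observations\n", miss))
  invisible(x)
}

#' Number of frames in a recording
#' @param rec an `hm_recording`.
#' @export
n_frames <- function(rec) dim(rec$kp)[1]

#' Logical mask of missing keypoints
#'
#' Missing means confidence 0 at (0, 0), the convention used by OpenPose
#' for undetected body parts.
#'
#' @param rec an `hm_recording`.
#' @return logical `n_frames x 50` matrix.
#' @export
missing_mask <- function(rec) {
  rec$kp[, , "c"] == 0 & rec$kp[, , "x"] == 0 & rec$kp[, , "y"] == 0
}

# internal validator used at module boundaries
#' @keywords internal
hm_assert_recording <- function(rec) {
  if (!inherits(rec, "hm_recording")) stop("expected an hm_recording")
  invisible(rec)
}
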