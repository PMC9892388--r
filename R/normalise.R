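# Scale normalisation, smoothing, dominant-hand orientation, wrist
# re-centring and windowing.
#
# Fixed processing order: impute -> resample -> scale_normalise ->
# smooth -> segment into windows, then per window orient the dominant
# hand to the right and re-centre on the wrist midpoint. Dominance is
# decided per analysis window because windows are the unit of
# classification.

#' Scale-normalise a recording to neck-origin, shoulder-width units
#'
#' Every keypoint in frame `f` is translated so the neck becomes the
#' origin and divided by the inter-shoulder distance `d_f`, making the
#' pose invariant to camera distance, image position and participant
#' size. Confidences are carried through untouched.
#'
#' @param rec an [hm_recording()] with neck and shoulders observed in
#'   every frame (run [impute_missing()] first).
#' @return an [hm_recording()] in normalised units (the `fps` and
#'   metadata are preserved; `meta$normalised` is set).
#' @export
scale_normalise <- function(rec) {
  hm_assert_recording(rec)
  miss <- missing_mask(rec)[, c("neck", "r_shoulder", "l_shoulder"), drop = FALSE]
  if (any(miss))
    stop("neck/shoulder keypoints missing in ", sum(rowSums(miss) > 0),
         " frame(s); impute before normalising")
  dx <- rec$kp[, "l_shoulder", "x"] - rec$kp[, "r_shoulder", "x"]
  dy <- rec$kp[, "l_shoulder", "y"] - rec$kp[, "r_shoulder", "y"]
  d <- sqrt(dx^2 + dy^2)
  if (any(d == 0))
    stop("degenerate pose: zero shoulder width in frame(s) ",
         paste(which(d == 0)[1:min(3, sum(d == 0))] - 1L, collapse = ", "))
  kp <- rec$kp
  kp[, , "x"] <- (kp[, , "x"] - kp[, "neck", "x"]) / d
  kp[, , "y"] <- (kp[, , "y"] - kp[, "neck", "y"]) / d
  meta <- rec$meta
  meta$normalised <- TRUE
  hm_recording(kp, fps = rec$fps, meta = meta, imputed = rec$imputed)
}

#' Savitzky-Golay smoothing of keypoint trajectories
#'
#' Applies a Savitzky-Golay filter independently to each keypoint's x
#' and y series. The default polynomial order 3 and window length 17
#' preserve the shape and height of waveform peaks that carry the
#' repetition structure, while suppressing detector jitter.
#'
#' @param rec an [hm_recording()] (normally scale-normalised).
#' @param order polynomial order of the filter.
#' @param window filter window length in frames (odd).
#' @return the smoothed [hm_recording()].
#' @export
smooth_recording <- function(rec, order = 3, window = 17) {
  hm_assert_recording(rec)
  n <- n_frames(rec)
  if (n < window)
    stop("recording has ", n, " frames but smoothing needs at least ",
         window, "; record at least ", sprintf("%.1f", window / rec$fps),
         " seconds")
  kp <- rec$kp
  for (k in seq_len(50L)) {
    kp[, k, 1] <- signal::sgolayfilt(kp[, k, 1], p = order, n = window)
    kp[, k, 2] <- signal::sgolayfilt(kp[, k, 2], p = order, n = window)
  }
  hm_recording(kp, fps = rec$fps, meta = rec$meta, imputed = rec$imputed)
}

#' Cumulative wrist path distance
#'
#' Sum over consecutive frame pairs of the Euclidean displacement of one
#' wrist; the wrist with the larger path distance over a window defines
#' the dominant hand.
#'
#' @param kp keypoint array of an [hm_recording()] (or the recording
#'   itself), at least 2 frames.
#' @param side `"left"` or `"right"`.
#' @return non-negative scalar.
#' @export
wrist_path_distance <- function(kp, side = c("left", "right")) {
  side <- match.arg(side)
  if (inherits(kp, "hm_recording")) kp <- kp$kp
  if (dim(kp)[1] < 2) stop("path distance needs at least 2 frames")
  wr <- paste0(substr(side, 1, 1), "_wrist")
  sum(sqrt(diff(kp[, wr, "x"])^2 + diff(kp[, wr, "y"])^2))
}

#' Reflect a sequence so the dominant hand is the right hand
#'
#' The dominant side is the wrist with the larger cumulative path
#' distance over the supplied frames. If the left wrist dominates, every
#' keypoint's x coordinate is negated and left/right labels are swapped
#' for shoulders, elbows, wrists and hands, which preserves anatomical
#' plausibility. An exact tie keeps the right hand dominant (with a
#' warning) so output is deterministic.
#'
#' @param kp keypoint array `n x 50 x 3` in neck-origin coordinates.
#' @return list with elements `kp` (oriented array), `dominant`
#'   (`"left"` or `"right"`, as measured before reflection) and
#'   `reflected` (logical).
#' @export
orient_dominant_right <- function(kp) {
  rp <- wrist_path_distance(kp, "right")
  lp <- wrist_path_distance(kp, "left")
  if (lp == rp && lp > 0)
    warning("wrist path distances tie exactly; keeping right hand dominant")
  if (lp > rp) {
    kp[, , "x"] <- -kp[, , "x"]
    kp <- kp[, hm_swap_names(colnames(kp)), , drop = FALSE]
    colnames(kp) <- hm_swap_names(colnames(kp))  # restore canonical names
    kp <- kp[, hm_kp_names(), , drop = FALSE]
    list(kp = kp, dominant = "left", reflected = TRUE)
  } else {
    list(kp = kp, dominant = "right", reflected = FALSE)
  }
}

#' Re-centre hand and arm keypoints on the wrist midpoint
#'
#' Keeps the 46 hand/wrist/elbow keypoints and translates them by minus
#' the midpoint of the two wrists, so inter-hand geometry is expressed
#' relative to where the action happens. Remaining body keypoints are
#' dropped; confidences are carried through.
#'
#' @param kp keypoint array `n x 50 x 3` in normalised units.
#' @return array `n x 46 x 3` with keypoints named per [hm_ha_names()].
#' @export
recenter_hand_arm <- function(kp) {
  midx <- (kp[, "r_wrist", "x"] + kp[, "l_wrist", "x"]) / 2
  midy <- (kp[, "r_wrist", "y"] + kp[, "l_wrist", "y"]) / 2
  ha <- kp[, hm_ha_names(), , drop = FALSE]
  ha[, , "x"] <- ha[, , "x"] - midx
  ha[, , "y"] <- ha[, , "y"] - midy
  ha
}

#' Confidence-weighted hand centroid
#'
#' The centroid of one hand is the mean of its 21 keypoint locations
#' weighted by detector confidence, which keeps erroneous low-confidence
#' finger predictions from dragging the estimate. If every confidence is
#' zero the unweighted mean is used, with a warning.
#'
#' @param hand `21 x 3` matrix of one hand's keypoints (columns x, y, c).
#' @return numeric length-2 vector (x, y).
#' @export
hand_centroid <- function(hand) {
  stopifnot(nrow(hand) == 21L)
  w <- hand[, 3]
  sw <- sum(w)
  if (sw <= 0) {
    warning("all hand keypoint confidences are zero; using unweighted mean")
    return(c(mean(hand[, 1]), mean(hand[, 2])))
  }
  c(sum(w * hand[, 1]) / sw, sum(w * hand[, 2]) / sw)
}

#' Per-frame hand centroids for a hand+arm sequence
#'
#' @param ha array `n x 46 x 3` from [recenter_hand_arm()] (any array
#'   with `l_hand_*`/`r_hand_*` keypoints works).
#' @return array `n x 2 x 2` with dimensions (frame, side `l`/`r`,
#'   coordinate x/y).
#' @export
hand_centroids <- function(ha) {
  n <- dim(ha)[1]
  out <- array(NA_real_, dim = c(n, 2, 2),
               dimnames = list(NULL, c("l", "r"), c("x", "y")))
  for (s in c("l", "r")) {
    idx <- paste0(s, "_hand_", 0:20)
    w <- ha[, idx, "c", drop = FALSE][, , 1, drop = FALSE]
    dim(w) <- c(n, 21L)
    sw <- rowSums(w)
    zero <- sw <= 0
    if (any(zero)) {
      warning(sum(zero), " frame(s) with all-zero ", s,
              " hand confidences; using unweighted mean")
      w[zero, ] <- 1
      sw[zero] <- 21
    }
    xs <- ha[, idx, "x", drop = FALSE]; dim(xs) <- c(n, 21L)
    ys <- ha[, idx, "y", drop = FALSE]; dim(ys) <- c(n, 21L)
    out[, s, "x"] <- rowSums(w * xs) / sw
    out[, s, "y"] <- rowSums(w * ys) / sw
  }
  out
}

#' Cut a processed recording into oriented hand+arm analysis windows
#'
#' After discarding `discard_s` seconds at each end (movement on-/offset
#' artefacts), maximal runs of windows of exactly `window_s` seconds are
#' taken with stride `window_s - overlap_s`. Each window is then
#' independently reflected so its dominant hand is on the right,
#' re-centred on the wrist midpoint, and annotated with per-frame hand
#' centroids.
#'
#' @param rec a scale-normalised, smoothed [hm_recording()] at 30 fps.
#' @param window_s window length in seconds.
#' @param overlap_s overlap between consecutive windows in seconds
#'   (strictly less than `window_s`).
#' @param discard_s seconds discarded at each end of the recording.
#' @return list of `hm_window` objects, each holding `kp` (oriented
#'   `m x 46 x 3` hand+arm array), `centroids`, `start`/`end` frame
#'   indices (half-open, 0-based, relative to the untrimmed recording),
#'   `dominant`, `reflected` and the recording's `meta`. Zero windows
#'   (with a warning) when the usable duration is shorter than one
#'   window.
#' @export
segment_windows <- function(rec, window_s, overlap_s = 0, discard_s = 0) {
  hm_assert_recording(rec)
  if (!(window_s > overlap_s && overlap_s >= 0 && discard_s >= 0))
    stop("need window_s > overlap_s >= 0 and discard_s >= 0")
  fps <- rec$fps
  wf <- as.integer(round(window_s * fps))
  stride <- as.integer(round((window_s - overlap_s) * fps))
  df <- as.integer(round(discard_s * fps))
  n <- n_frames(rec)
  last_start <- n - df - wf
  if (last_start < df) {
    warning("usable duration shorter than one window; returning 0 windows")
    return(list())
  }
  starts <- seq.int(df, last_start, by = stride)
  lapply(starts, function(s0) {
    sub <- rec$kp[(s0 + 1):(s0 + wf), , , drop = FALSE]
    ori <- orient_dominant_right(sub)
    ha <- recenter_hand_arm(ori$kp)
    structure(
      list(kp = ha, centroids = hand_centroids(ha),
           start = s0, end = s0 + wf, fps = fps,
           dominant = ori$dominant, reflected = ori$reflected,
           meta = rec$meta),
      class = "hm_window"
    )
  })
}

#' @export
print.hm_window <- function(x, ...) {
  cat(sprintf("<hm_window> frames [%d, %d) @ %g fps, dominant %s hand%s\n",
              x$start, x$end, x$fps, x$dominant,
              if (x$reflected) " (reflected)" else ""))
  invisible(x)
}

#' Preprocess a raw recording for analysis
#'
#' Convenience chain: impute missing keypoints, resample to 30 fps,
#' scale-normalise, smooth. The result is ready for
#' [segment_windows()].
#'
#' @param rec a raw [hm_recording()].
#' @param impute_half_window neighbourhood half-width for imputation.
#' @param savgol_order,savgol_window smoothing filter parameters.
#' @param target_fps frame rate the pipeline operates at.
#' @return a processed [hm_recording()].
#' @export
preprocess_recording <- function(rec, impute_half_window = 8,
                                 savgol_order = 3, savgol_window = 17,
                                 target_fps = 30) {
  rec <- impute_missing(rec, half_window = impute_half_window)
  rec <- resample_recording(rec, target_fps = target_fps)
  rec <- scale_normalise(rec)
  smooth_recording(rec, order = savgol_order, window = savgol_window)
}
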