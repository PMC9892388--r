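# Reading, validating, resampling, imputing and persisting keypoint
# recordings: the OpenPose per-frame JSON dialect on the way in, a
# diff-able delimiter-separated internal format on the way out.

# BODY_25 and COCO-18 share the 8 slots we need, in the same order:
# 0 nose, 1 neck, 2 RShoulder, 3 RElbow, 4 RWrist, 5 LShoulder,
# 6 LElbow, 7 LWrist.
#' @keywords internal
hm_body25_slots <- function() {
  c(nose = 0L, neck = 1L, r_shoulder = 2L, r_elbow = 3L, r_wrist = 4L,
    l_shoulder = 5L, l_elbow = 6L, l_wrist = 7L)
}

# flat (x, y, c) triples -> k x 3 matrix
#' @keywords internal
hm_triples <- function(v, k) {
  if (is.null(v) || length(v) == 0) return(matrix(0, k, 3))
  v <- as.numeric(v)
  if (length(v) < 3 * k) stop("keypoint vector too short: ", length(v))
  matrix(v[seq_len(3 * k)], ncol = 3, byrow = TRUE)
}

#' Read a recording from OpenPose per-frame JSON files
#'
#' Each file holds a `people` array whose entries carry flat
#' `pose_keypoints_2d`, `hand_left_keypoints_2d` and
#' `hand_right_keypoints_2d` triples of (x, y, confidence). BODY_25 and
#' COCO body dialects are both accepted; only the 8 upper-body slots are
#' kept and extra body keypoints are discarded.
#'
#' @param paths character vector of frame files in temporal order.
#' @param fps frames per second the files were captured at.
#' @param person_policy how to pick one person when a frame contains
#'   several: `"largest_shoulder"` (default) keeps the person with the
#'   largest inter-shoulder pixel distance, `"first"` keeps the first
#'   entry.
#' @param meta metadata list stored on the recording.
#' @return an [hm_recording()]. Frames whose `people` array is empty are
#'   kept, with all 50 keypoints marked missing.
#' @export
read_openpose_frames <- function(paths, fps = 30,
                                 person_policy = c("largest_shoulder", "first"),
                                 meta = list()) {
  person_policy <- match.arg(person_policy)
  if (length(paths) == 0) stop("no frame files supplied")
  slots <- hm_body25_slots()
  kp <- array(0, dim = c(length(paths), 50L, 3L),
              dimnames = list(NULL, hm_kp_names(), c("x", "y", "c")))
  for (f in seq_along(paths)) {
    js <- tryCatch(jsonlite::fromJSON(paths[f], simplifyVector = FALSE),
                   error = function(e)
                     stop("cannot parse OpenPose file '", paths[f], "': ",
                          conditionMessage(e), call. = FALSE))
    people <- js$people
    if (is.null(people) || length(people) == 0) next  # all-missing frame
    pick <- 1L
    if (person_policy == "largest_shoulder" && length(people) > 1L) {
      widths <- vapply(people, function(p) {
        body <- as.numeric(p$pose_keypoints_2d)
        rs <- body[slots[["r_shoulder"]] * 3 + 1:3]
        ls <- body[slots[["l_shoulder"]] * 3 + 1:3]
        if (length(rs) < 3 || length(ls) < 3 ||
            anyNA(rs) || anyNA(ls) || rs[3] == 0 || ls[3] == 0) return(-Inf)
        sqrt((rs[1] - ls[1])^2 + (rs[2] - ls[2])^2)
      }, numeric(1))
      if (any(is.finite(widths))) pick <- which.max(widths)
    }
    p <- people[[pick]]
    body <- as.numeric(p$pose_keypoints_2d)
    n_body <- length(body) / 3
    if (n_body < 8) stop("body keypoint vector in '", paths[f],
                         "' has fewer than 8 keypoints")
    for (nm in names(slots))
      kp[f, nm, ] <- body[slots[[nm]] * 3 + 1:3]
    kp[f, paste0("l_hand_", 0:20), ] <- hm_triples(p$hand_left_keypoints_2d, 21L)
    kp[f, paste0("r_hand_", 0:20), ] <- hm_triples(p$hand_right_keypoints_2d, 21L)
  }
  hm_recording(kp, fps = fps, meta = meta)
}

#' Write a recording as OpenPose per-frame JSON files
#'
#' Emits one file per frame containing a single person with BODY_25 pose
#' keypoints (slots beyond the 8 used are zero) and the two 21-point hand
#' arrays. Companion to [read_openpose_frames()]; used by the `simulate`
#' CLI subcommand.
#'
#' @param rec an [hm_recording()].
#' @param dir output directory, created if absent.
#' @param prefix file-name prefix; files are named
#'   `<prefix>_<frame>_keypoints.json`.
#' @return the written paths, invisibly.
#' @export
write_openpose_frames <- function(rec, dir, prefix = "frame") {
  hm_assert_recording(rec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  slots <- hm_body25_slots()
  paths <- character(n_frames(rec))
  for (f in seq_len(n_frames(rec))) {
    body <- numeric(25 * 3)
    for (nm in names(slots))
      body[slots[[nm]] * 3 + 1:3] <- rec$kp[f, nm, ]
    person <- list(
      pose_keypoints_2d = body,
      hand_left_keypoints_2d = as.numeric(t(rec$kp[f, paste0("l_hand_", 0:20), ])),
      hand_right_keypoints_2d = as.numeric(t(rec$kp[f, paste0("r_hand_", 0:20), ]))
    )
    paths[f] <- file.path(dir, sprintf("%s_%06d_keypoints.json", prefix, f - 1L))
    jsonlite::write_json(list(version = 1.3, people = list(person)),
                         paths[f], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' @keywords internal
hm_part_of <- function(nms) {
  ifelse(grepl("^l_hand_", nms), "left_hand",
         ifelse(grepl("^r_hand_", nms), "right_hand", "body"))
}

#' @keywords internal
hm_index_of <- function(nms) {
  idx <- match(nms, hm_kp_names()) - 1L
  hand <- grepl("hand", nms)
  idx[hand] <- as.integer(sub("^[lr]_hand_", "", nms[hand]))
  idx
}

#' Persist a recording in the internal tabular format
#'
#' One row per (frame, keypoint) with columns `frame, part, index, x, y,
#' c, imputed`, written with 17 significant digits so that a
#' write-then-read round trip reproduces every coordinate bit-exactly.
#' A JSON manifest alongside carries fps and metadata.
#'
#' @param rec an [hm_recording()].
#' @param prefix path prefix; `<prefix>.csv` and `<prefix>.json` are
#'   written.
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  hm_assert_recording(rec)
  nms <- hm_kp_names()
  n <- n_frames(rec)
  frame <- rep(0:(n - 1L), each = 50L)
  part <- rep(hm_part_of(nms), n)
  index <- rep(hm_index_of(nms), n)
  xs <- as.vector(t(rec$kp[, , "x"]))
  ys <- as.vector(t(rec$kp[, , "y"]))
  cs <- as.vector(t(rec$kp[, , "c"]))
  imp <- if (is.null(rec$imputed)) rep(0L, n * 50L)
         else as.integer(as.vector(t(rec$imputed)))
  lines <- c("frame,part,index,x,y,c,imputed",
             sprintf("%d,%s,%d,%.17g,%.17g,%.17g,%d",
                     frame, part, index, xs, ys, cs, imp))
  writeLines(lines, paste0(prefix, ".csv"))
  jsonlite::write_json(list(fps = rec$fps, n_frames = n, meta = rec$meta),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a recording from the internal tabular format
#'
#' @param prefix path prefix used by [write_recording()].
#' @return an [hm_recording()].
#' @export
read_recording <- function(prefix) {
  tab <- utils::read.csv(paste0(prefix, ".csv"), stringsAsFactors = FALSE)
  man <- jsonlite::fromJSON(paste0(prefix, ".json"), simplifyVector = TRUE)
  need <- c("frame", "part", "index", "x", "y", "c")
  if (!all(need %in% names(tab))) stop("malformed recording table")
  nms <- hm_kp_names()
  key <- paste(hm_part_of(nms), hm_index_of(nms))
  slot <- match(paste(tab$part, tab$index), key)
  if (anyNA(slot)) stop("unknown part/index combination in recording table")
  n <- max(tab$frame) + 1L
  kp <- array(0, dim = c(n, 50L, 3L))
  idx <- cbind(tab$frame + 1L, slot)
  kp[cbind(idx, 1L)] <- tab$x
  kp[cbind(idx, 2L)] <- tab$y
  kp[cbind(idx, 3L)] <- tab$c
  imputed <- NULL
  if ("imputed" %in% names(tab) && any(tab$imputed > 0)) {
    imputed <- matrix(FALSE, n, 50L, dimnames = list(NULL, nms))
    imputed[idx] <- tab$imputed > 0
  }
  meta <- if (is.null(man$meta)) list() else as.list(man$meta)
  hm_recording(kp, fps = man$fps, meta = meta, imputed = imputed)
}

#' Resample a recording to a uniform frame rate
#'
#' Coordinates are linearly interpolated per keypoint on a uniform grid
#' at `target_fps`; the confidence of an interpolated frame is the
#' minimum of the two bracketing confidences (an interpolated location
#' is no more trustworthy than its worse parent). A recording already at
#' the target rate is returned unchanged.
#'
#' @param rec an [hm_recording()] with no missing keypoints (impute
#'   first; see [impute_missing()]).
#' @param target_fps target frame rate, 30 by default.
#' @return a resampled [hm_recording()].
#' @export
resample_recording <- function(rec, target_fps = 30) {
  hm_assert_recording(rec)
  if (rec$fps == target_fps) return(rec)
  n <- n_frames(rec)
  if (n < 2) stop("resampling needs at least 2 frames")
  t_in <- (0:(n - 1)) / rec$fps
  t_out <- seq(0, t_in[n], by = 1 / target_fps)
  m <- length(t_out)
  kp <- array(0, dim = c(m, 50L, 3L))
  lo <- findInterval(t_out, t_in, rightmost.closed = TRUE)
  hi <- pmin(lo + 1L, n)
  near <- ifelse(abs(t_out - t_in[hi]) < abs(t_out - t_in[lo]), hi, lo)
  exact <- abs(t_out - t_in[near]) < 1e-9
  for (k in seq_len(50L)) {
    kp[, k, 1] <- stats::approx(t_in, rec$kp[, k, "x"], xout = t_out)$y
    kp[, k, 2] <- stats::approx(t_in, rec$kp[, k, "y"], xout = t_out)$y
    cin <- rec$kp[, k, "c"]
    kp[, k, 3] <- ifelse(exact, cin[near], pmin(cin[lo], cin[hi]))
  }
  hm_recording(kp, fps = target_fps, meta = rec$meta)
}

#' Impute missing keypoints from neighbouring frames
#'
#' Each missing keypoint (confidence 0 at (0, 0)) is replaced by the
#' coordinate-wise median of the non-missing observations of the same
#' keypoint within `half_window` frames on either side; its confidence
#' becomes the median confidence of the contributing frames. If a window
#' holds no observation it is doubled once; if the doubled window is
#' still empty, or a keypoint is missing in every frame, imputation
#' fails with an error naming the keypoint.
#'
#' @param rec an [hm_recording()].
#' @param half_window frames on either side to draw neighbours from
#'   (default 8, a 17-frame window matching the smoothing scale).
#' @return an [hm_recording()] with no missing keypoints and an
#'   `imputed` flag matrix recording what was filled in.
#' @export
impute_missing <- function(rec, half_window = 8) {
  hm_assert_recording(rec)
  miss <- missing_mask(rec)
  if (!any(miss)) {
    rec$imputed <- matrix(FALSE, n_frames(rec), 50L,
                          dimnames = list(NULL, hm_kp_names()))
    return(rec)
  }
  n <- n_frames(rec)
  kp <- rec$kp
  nms <- hm_kp_names()
  for (k in which(colSums(miss) > 0)) {
    obs <- which(!miss[, k])
    if (length(obs) == 0)
      stop("keypoint '", nms[k], "' is missing in every frame")
    for (f in which(miss[, k])) {
      w <- obs[obs >= f - half_window & obs <= f + half_window]
      if (length(w) == 0)
        w <- obs[obs >= f - 2 * half_window & obs <= f + 2 * half_window]
      if (length(w) == 0)
        stop("keypoint '", nms[k], "' has no observed neighbour within ",
             2 * half_window, " frames of frame ", f - 1L)
      kp[f, k, 1] <- stats::median(kp[w, k, 1])
      kp[f, k, 2] <- stats::median(kp[w, k, 2])
      kp[f, k, 3] <- stats::median(kp[w, k, 3])
    }
  }
  out <- hm_recording(kp, fps = rec$fps, meta = rec$meta,
                      imputed = miss)
  dimnames(out$imputed) <- list(NULL, nms)
  out
}
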