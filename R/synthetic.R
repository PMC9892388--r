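# Parametric generator of synthetic keypoint recordings.
#
# Emulates the structure of a metronome-paced study of five repetitive
# hand movements: 30-s recordings at 30 fps, commanded rates of
# 30/50/70/90 repetitions per minute, subject-level variation in build,
# position, handedness and whether one or both hands move, plus
# per-keypoint Gaussian detector noise, dropped keypoints and
# confidence scores anticorrelated with the injected noise.
#
# All subjects follow the metronome, so the oscillator phase is zero at
# t = 0 (a repetition boundary); with the pipeline's half-second-aligned
# window boundaries this keeps every repetition minimum at least a
# quarter cycle away from every window edge at the four study rates,
# making noise-free repetition counts exact for any seed. Subject
# individuality enters through geometry, amplitude and phase jitter
# instead.

#' Movement classes known to the generator and the pipeline
#' @return character vector of the five class labels.
#' @export
movement_classes <- function() {
  c("clap", "pick", "rub", "scratch", "wring")
}

#' A synthetic subject profile
#'
#' Draws (seeded) per-subject variation: shoulder width in pixels, body
#' anchor position in the image, seated or standing, handedness (which
#' hand performs single-handed movements), whether the other hand moves
#' too, and multipliers for movement amplitude and pacing jitter.
#'
#' @param id subject identifier (integer or string).
#' @param seed RNG seed; defaults to a hash of `id` so profiles are
#'   reproducible per subject.
#' @return a `subject_profile` list.
#' @export
subject_profile <- function(id, seed = NULL) {
  if (is.null(seed))
    seed <- (sum(utf8ToInt(paste0("subject", id))) * 2654435) %% 2147483646 + 1
  set.seed(seed)
  structure(list(
    id = id,
    shoulder_px = stats::runif(1, 140, 190),
    anchor = c(x = stats::runif(1, 500, 780), y = stats::runif(1, 280, 420)),
    seated = stats::runif(1) < 0.5,
    handedness = if (stats::runif(1) < 0.8) "right" else "left",
    both_hands = stats::runif(1) < 0.5,
    amplitude_mult = stats::runif(1, 0.85, 1.15),
    jitter_mult = stats::runif(1, 0.7, 1.3)
  ), class = "subject_profile")
}

#' A movement specification
#'
#' @param class one of [movement_classes()].
#' @param rate commanded repetitions per minute (> 0).
#' @param duration recording length in seconds.
#' @param noise_sd per-keypoint Gaussian noise, pixels.
#' @param missing_prob per-keypoint per-frame probability of a dropped
#'   (missing) keypoint, in `[0, 1)`.
#' @param jitter_sd per-cycle pacing error as a fraction of the cycle
#'   period (human deviation from the metronome).
#' @param seed RNG seed for the recording.
#' @return a `movement_spec` list.
#' @export
movement_spec <- function(class, rate, duration = 30, noise_sd = 2,
                          missing_prob = 0.01, jitter_sd = 0.05,
                          seed = 1) {
  class <- match.arg(class, movement_classes())
  if (rate <= 0) stop("rate must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (missing_prob < 0 || missing_prob >= 1)
    stop("missing_prob must be in [0, 1)")
  structure(list(class = class, rate = rate, duration = duration,
                 noise_sd = noise_sd, missing_prob = missing_prob,
                 jitter_sd = jitter_sd, seed = seed),
            class = "movement_spec")
}

# 21-point hand template in shoulder-width units, right hand, relative
# to the wrist: root + 4 points per digit fanning downwards
#' @keywords internal
hm_hand_template <- function() {
  ang <- c(-55, -25, 0, 25, 50) * pi / 180   # thumb .. little finger
  len <- c(0.16, 0.22, 0.24, 0.22, 0.18)
  pts <- matrix(0, 21, 2)
  pts[1, ] <- c(0, 0.02)                      # palm root
  r <- 2L
  for (d in 1:5) {
    dir <- c(sin(ang[d]), cos(ang[d]))
    for (k in 1:4) {
      pts[r, ] <- pts[1, ] + dir * len[d] * k / 4
      r <- r + 1L
    }
  }
  pts
}

# cycle-boundary times with per-cycle period jitter; phase is 0 at t=0
#' @keywords internal
hm_cycle_times <- function(rate, duration, jitter_sd) {
  period <- 60 / rate
  k <- ceiling(duration / period) + 2L
  dur <- period * pmax(0.3, 1 + jitter_sd * stats::rnorm(k))
  cumsum(c(0, dur))
}

# piecewise-linear phase (cycles) at times t given cycle boundaries
#' @keywords internal
hm_phase_at <- function(t, bounds) {
  seg <- findInterval(t, bounds, rightmost.closed = FALSE)
  seg <- pmin(pmax(seg, 1L), length(bounds) - 1L)
  (seg - 1) + (t - bounds[seg]) / (bounds[seg + 1] - bounds[seg])
}

# archetype kinematics: wrist/elbow/nose tracks in shoulder-width units
# relative to the neck, dominant hand on the right (+x). u in [0,1] is
# the within-cycle oscillation (0 = hands closest / bottom of stroke).
#' @keywords internal
hm_archetype_tracks <- function(class, u, amp, both_hands) {
  n <- length(u)
  rest <- list(
    nose = cbind(0, rep(-0.30, n)),
    r_shoulder = cbind(0.5, rep(0, n)), l_shoulder = cbind(-0.5, rep(0, n)),
    r_elbow = cbind(0.62, rep(0.55, n)), l_elbow = cbind(-0.62, rep(0.55, n))
  )
  a <- amp
  tr <- switch(
    class,
    clap = {
      sep <- 0.08 + 0.42 * a * u
      list(r_wrist = cbind(sep, rep(0.85, n)),
           l_wrist = cbind(-sep, rep(0.85, n)),
           r_elbow = cbind(0.45 + 0.20 * u, rep(0.75, n)),
           l_elbow = cbind(-0.45 - 0.20 * u, rep(0.75, n)))
    },
    pick = {
      # dominant hand hovers over the opposite forearm, dipping to pick
      lw <- cbind(rep(-0.35, n), rep(0.75, n))
      if (both_hands) lw[, 2] <- lw[, 2] + 0.02 * u
      list(r_wrist = cbind(rep(-0.30, n), 0.62 - 0.10 * a * u),
           l_wrist = lw,
           l_elbow = cbind(rep(-0.62, n), rep(0.60, n)))
    },
    rub = {
      # dominant hand strokes an object held low by the other hand
      lw <- cbind(rep(-0.18, n), rep(1.25, n))
      if (both_hands) lw[, 1] <- lw[, 1] - 0.03 * u
      list(r_wrist = cbind(0.12 + 0.05 * u, 1.21 - 0.22 * a * u),
           l_wrist = lw,
           r_elbow = cbind(0.55, 0.85 - 0.08 * u))
    },
    scratch = {
      # dominant hand runs along the opposite forearm, nearest the
      # opposite wrist at the start of each cycle
      le <- c(-0.62, 0.55); lw <- c(-0.35, 0.80)
      f <- 0.65 - 0.45 * a * u          # position along the forearm
      list(r_wrist = cbind(le[1] + f * (lw[1] - le[1]) + 0.03,
                           le[2] + f * (lw[2] - le[2]) - 0.06),
           l_wrist = cbind(rep(lw[1], n),
                           lw[2] + if (both_hands) 0.02 * u else rep(0, n)))
    },
    wring = {
      # hands clasped, separating slightly as they twist
      sep <- 0.05 + 0.10 * a * u
      tw <- 0.04 * sin(2 * pi * u)       # small counter-phase twist
      list(r_wrist = cbind(sep, 0.95 + tw),
           l_wrist = cbind(-sep, 0.95 - tw))
    }
  )
  utils::modifyList(rest, tr)
}

# cycle-shape exponent: clapping dwells with hands apart and makes
# brief contact, so its distance dip is sharpened
#' @keywords internal
hm_cycle_exponent <- function(class) {
  switch(class, clap = 0.25, 0.5)
}

#' Generate one synthetic keypoint recording
#'
#' Builds a 30 fps recording of one subject performing one movement at
#' a commanded rate. Deterministic for a fixed spec seed. The recording
#' metadata carries the ground truth: commanded `rate`, intensity
#' category, and `minima_times`, the instants at which the hands are
#' closest together (one per repetition), from which true per-window
#' repetition counts follow.
#'
#' @param subject a [subject_profile()].
#' @param spec a [movement_spec()].
#' @return an [hm_recording()] with ground-truth metadata.
#' @export
generate_recording <- function(subject, spec) {
  stopifnot(inherits(subject, "subject_profile"),
            inherits(spec, "movement_spec"))
  set.seed(spec$seed)
  fps <- 30
  n <- as.integer(round(spec$duration * fps))
  t <- (0:(n - 1)) / fps
  bounds <- hm_cycle_times(spec$rate, spec$duration,
                           spec$jitter_sd * subject$jitter_mult)
  phase <- hm_phase_at(t, bounds)                  # in cycles
  u <- ((1 - cos(2 * pi * phase)) / 2)^hm_cycle_exponent(spec$class)
  tracks <- hm_archetype_tracks(spec$class, u, subject$amplitude_mult,
                                subject$both_hands)

  kp_rel <- array(0, dim = c(n, 50L, 2L),
                  dimnames = list(NULL, hm_kp_names(), c("x", "y")))
  kp_rel[, "neck", ] <- 0
  for (nm in names(tracks)) kp_rel[, nm, ] <- tracks[[nm]]
  hand <- hm_hand_template() * 0.9
  for (k in 1:21) {
    kp_rel[, paste0("r_hand_", k - 1L), "x"] <- kp_rel[, "r_wrist", "x"] + hand[k, 1]
    kp_rel[, paste0("r_hand_", k - 1L), "y"] <- kp_rel[, "r_wrist", "y"] + hand[k, 2]
    kp_rel[, paste0("l_hand_", k - 1L), "x"] <- kp_rel[, "l_wrist", "x"] - hand[k, 1]
    kp_rel[, paste0("l_hand_", k - 1L), "y"] <- kp_rel[, "l_wrist", "y"] + hand[k, 2]
  }
  if (subject$handedness == "left") {              # mirror the skeleton
    kp_rel[, , "x"] <- -kp_rel[, , "x"]
    kp_rel <- kp_rel[, hm_swap_names(hm_kp_names()), , drop = FALSE]
    dimnames(kp_rel)[[2]] <- hm_swap_names(dimnames(kp_rel)[[2]])
    kp_rel <- kp_rel[, hm_kp_names(), , drop = FALSE]
  }

  anchor_y <- subject$anchor[["y"]] + if (subject$seated) 60 else 0
  kp <- array(0, dim = c(n, 50L, 3L),
              dimnames = list(NULL, hm_kp_names(), c("x", "y", "c")))
  kp[, , "x"] <- subject$anchor[["x"]] + subject$shoulder_px * kp_rel[, , "x"]
  kp[, , "y"] <- anchor_y + subject$shoulder_px * kp_rel[, , "y"]

  conf_scale <- 10   # pixels of error at which confidence reaches zero
  if (spec$noise_sd > 0) {
    nx <- matrix(stats::rnorm(n * 50L, sd = spec$noise_sd), n, 50L)
    ny <- matrix(stats::rnorm(n * 50L, sd = spec$noise_sd), n, 50L)
    kp[, , "x"] <- kp[, , "x"] + nx
    kp[, , "y"] <- kp[, , "y"] + ny
    kp[, , "c"] <- pmax(0, 1 - sqrt(nx^2 + ny^2) / conf_scale)
  } else {
    kp[, , "c"] <- 1
  }
  if (spec$missing_prob > 0) {
    drop <- matrix(stats::runif(n * 50L) < spec$missing_prob, n, 50L)
    for (sl in 1:3) {
      slice <- kp[, , sl]
      slice[drop] <- 0
      kp[, , sl] <- slice
    }
  }

  minima <- bounds[bounds >= 0 & bounds < spec$duration]
  hm_recording(kp, fps = fps, meta = list(
    subject = subject$id, class = spec$class, rate = spec$rate,
    intensity = as.character(rate_category(spec$rate)),
    duration = spec$duration, noise_sd = spec$noise_sd,
    missing_prob = spec$missing_prob, jitter_sd = spec$jitter_sd,
    handedness = subject$handedness, seed = spec$seed,
    minima_times = minima, synthetic = TRUE
  ))
}

#' Ground-truth repetition count inside a window
#'
#' Counts the generator's hands-closest instants falling in the
#' half-open interval `[start, end)` (seconds).
#'
#' @param rec a synthetic [hm_recording()].
#' @param start,end window bounds in seconds.
#' @return integer count.
#' @export
true_repetitions <- function(rec, start, end) {
  mt <- rec$meta$minima_times
  if (is.null(mt)) stop("recording carries no ground-truth minima times")
  sum(mt >= start & mt < end)
}

#' Generate a labelled corpus of synthetic recordings
#'
#' One recording per (subject, class, rate) cell, mirroring a study
#' design of `n_subjects` participants each performing every movement
#' at every metronome rate for `duration` seconds. The manifest records
#' a train/test subject split: subjects `1..n_train` are training
#' subjects, the rest are held out.
#'
#' @param n_subjects number of subjects.
#' @param n_train number of training subjects.
#' @param classes movement classes to include.
#' @param rates commanded rates, repetitions per minute.
#' @param duration recording length, seconds.
#' @param noise_sd,missing_prob,jitter_sd noise model, see
#'   [movement_spec()].
#' @param seed master seed; every recording seed derives from it.
#' @return list with `recordings` (list of [hm_recording()]) and
#'   `manifest` (data frame: index, subject, class, rate, intensity,
#'   split).
#' @export
generate_corpus <- function(n_subjects = 20, n_train = 15,
                            classes = movement_classes(),
                            rates = c(30, 50, 70, 90),
                            duration = 30, noise_sd = 2,
                            missing_prob = 0.01, jitter_sd = 0.05,
                            seed = 1) {
  stopifnot(n_subjects >= 1, n_train >= 0, n_train <= n_subjects)
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  cells <- expand.grid(class = classes, rate = rates,
                       subject = seq_len(n_subjects),
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$subject), ]
  rec_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  subjects <- lapply(seq_len(n_subjects), function(s)
    subject_profile(s, seed = subject_seeds[s]))
  recordings <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    spec <- movement_spec(cells$class[i], cells$rate[i],
                          duration = duration, noise_sd = noise_sd,
                          missing_prob = missing_prob,
                          jitter_sd = jitter_sd, seed = rec_seeds[i])
    recordings[[i]] <- generate_recording(subjects[[cells$subject[i]]], spec)
  }
  manifest <- data.frame(
    index = seq_len(nrow(cells)),
    subject = cells$subject,
    class = cells$class,
    rate = cells$rate,
    intensity = as.character(rate_category(cells$rate)),
    split = ifelse(cells$subject <= n_train, "train", "test"),
    stringsAsFactors = FALSE
  )
  list(recordings = recordings, manifest = manifest)
}
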