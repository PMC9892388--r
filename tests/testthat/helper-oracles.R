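# Fixture builders and independent brute-force oracles used across the
# suite. Oracles deliberately share no code with the implementation
# paths they check.

# --- fixture builders -------------------------------------------------

# a structurally valid recording with a static plausible skeleton; `mod`
# can rewrite the keypoint array (n x 50 x 3) before construction
make_recording <- function(n = 60, fps = 30, mod = NULL, meta = list()) {
  kp <- array(0, dim = c(n, 50L, 3L))
  dimnames(kp) <- list(NULL, handrep:::hm_kp_names(), c("x", "y", "c"))
  base <- list(nose = c(320, 160), neck = c(320, 200),
               r_shoulder = c(360, 200), r_elbow = c(380, 250),
               r_wrist = c(370, 300), l_shoulder = c(280, 200),
               l_elbow = c(260, 250), l_wrist = c(270, 300))
  for (nm in names(base)) {
    kp[, nm, "x"] <- base[[nm]][1]
    kp[, nm, "y"] <- base[[nm]][2]
  }
  for (k in 0:20) {
    kp[, paste0("r_hand_", k), "x"] <- 370 + (k %% 5) * 2
    kp[, paste0("r_hand_", k), "y"] <- 305 + (k %/% 5) * 3
    kp[, paste0("l_hand_", k), "x"] <- 270 - (k %% 5) * 2
    kp[, paste0("l_hand_", k), "y"] <- 305 + (k %/% 5) * 3
  }
  kp[, , "c"] <- 0.9
  if (!is.null(mod)) kp <- mod(kp)
  hm_recording(kp, fps = fps, meta = meta)
}

# a random valid pose set: ns sub-windows x 3 kinds, coordinates ~ N(0,1)
random_poseset <- function(ns = 1) {
  structure(list(
    poses = matrix(stats::rnorm(3 * ns * 92), nrow = 3 * ns),
    kind = rep(c("mean", "maximum", "minimum"), ns),
    subwindow = rep(seq_len(ns), each = 3),
    meta = list()
  ), class = "hm_poseset")
}

# quick noise-free single-recording window fetch
quiet_windows <- function(rec, window_s, overlap_s, discard_s) {
  suppressWarnings(segment_windows(preprocess_recording(rec),
                                   window_s, overlap_s, discard_s))
}

# --- independent oracles ----------------------------------------------

# NBNN by explicit double loop over poses and stored instances
oracle_nbnn_totals <- function(set, sets, labels) {
  classes <- sort(unique(labels))
  totals <- stats::setNames(numeric(length(classes)), classes)
  for (i in seq_len(nrow(set$poses))) {
    q <- set$poses[i, ]
    k <- set$kind[i]
    for (cl in classes) {
      best <- Inf
      for (j in which(labels == cl)) {
        s <- sets[[j]]
        for (r in which(s$kind == k)) {
          d <- sqrt(sum((q - s$poses[r, ])^2))
          if (d < best) best <- d
        }
      }
      totals[cl] <- totals[cl] + best
    }
  }
  totals
}

# strict local maxima by direct neighbour comparison (no plateaus)
oracle_maxima <- function(x) {
  which(vapply(seq_along(x), function(i)
    i > 1 && i < length(x) && x[i] > x[i - 1] && x[i] > x[i + 1],
    logical(1)))
}

# topographic prominence straight from the definition
oracle_prominence <- function(x, p) {
  higher_l <- which(x[seq_len(p - 1)] > x[p])
  lseg <- if (length(higher_l)) (max(higher_l)):p else 1:p
  higher_r <- which(x[(p + 1):length(x)] > x[p]) + p
  rseg <- if (length(higher_r)) p:(min(higher_r)) else p:length(x)
  x[p] - max(min(x[lseg]), min(x[rseg]))
}

# full filtered peak count, written as an independent second path
oracle_peak_count <- function(x, min_height, min_distance, min_prominence) {
  pk <- oracle_maxima(x)
  pk <- pk[x[pk] >= min_height]
  alive <- rep(TRUE, length(pk))
  for (o in order(-x[pk], pk)) {
    if (!alive[o]) next
    for (j in seq_along(pk)) {
      if (j != o && alive[j] && abs(pk[j] - pk[o]) < min_distance)
        alive[j] <- FALSE
    }
  }
  pk <- pk[alive]
  sum(vapply(pk, function(p) oracle_prominence(x, p), numeric(1)) >=
        min_prominence)
}
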