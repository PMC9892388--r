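# Intensity assessment: inter-hand distance signals, peak-detection
# repetition counting, range and personalised accuracy, and the grid
# search that tunes per-class peak hyperparameters.

#' Distance measures available for intensity assessment
#'
#' In order: Euclidean distance between wrists, vertical (|dy|) and
#' horizontal (|dx|) wrist distance, and Euclidean distance between
#' confidence-weighted hand centroids. The order is also the
#' tie-breaking order in [tune_intensity()].
#'
#' @return character vector of measure names.
#' @export
distance_measures <- function() {
  c("euclid_wrist", "vert_wrist", "horiz_wrist", "euclid_centroid")
}

#' Inter-hand distance signal of a window
#'
#' Computes the chosen per-frame distance and min-max normalises it to
#' `[0, 1]` within the window, so sequences from subjects with
#' different ranges of motion are comparable. A constant raw signal
#' cannot be normalised; it becomes all zeros with a warning.
#'
#' @param window an `hm_window` from [segment_windows()].
#' @param measure one of [distance_measures()].
#' @return an `hm_distance_signal`: list with `measure`, `values`
#'   (normalised series) and `raw`.
#' @export
compute_distance_signal <- function(window, measure = distance_measures()) {
  measure <- match.arg(measure)
  kp <- window$kp
  raw <- switch(
    measure,
    euclid_wrist = sqrt((kp[, "r_wrist", "x"] - kp[, "l_wrist", "x"])^2 +
                        (kp[, "r_wrist", "y"] - kp[, "l_wrist", "y"])^2),
    vert_wrist  = abs(kp[, "r_wrist", "y"] - kp[, "l_wrist", "y"]),
    horiz_wrist = abs(kp[, "r_wrist", "x"] - kp[, "l_wrist", "x"]),
    euclid_centroid = {
      cen <- window$centroids
      sqrt((cen[, "r", "x"] - cen[, "l", "x"])^2 +
           (cen[, "r", "y"] - cen[, "l", "y"])^2)
    }
  )
  rng <- max(raw) - min(raw)
  if (rng <= .Machine$double.eps * max(abs(raw), 1)) {
    warning("constant ", measure, " signal; normalisation degenerates ",
            "to an all-zero signal")
    values <- rep(0, length(raw))
  } else {
    values <- (raw - min(raw)) / rng
  }
  structure(list(measure = measure, values = values, raw = raw),
            class = "hm_distance_signal")
}

#' Peak-detection hyperparameters
#'
#' @param min_prominence minimum topographic prominence, in normalised
#'   distance units.
#' @param min_distance minimum separation between repetitions, frames.
#' @param min_height minimum peak height on the *negated* normalised
#'   signal, so values lie in `[-1, 0]` and realistic thresholds are
#'   negative.
#' @return a `peak_params` list.
#' @export
peak_params <- function(min_prominence, min_distance, min_height) {
  if (min_prominence < 0) stop("min_prominence must be >= 0")
  if (min_distance < 1) stop("min_distance must be >= 1")
  structure(list(min_prominence = min_prominence,
                 min_distance = min_distance,
                 min_height = min_height),
            class = "peak_params")
}

#' Count movement repetitions in a distance signal
#'
#' The normalised signal is negated so that the instant of each
#' repetition (hands closest together) becomes a wave peak; peaks are
#' then filtered by minimum prominence, height and separation and the
#' survivors counted.
#'
#' @param sig an `hm_distance_signal` (or bare numeric vector already
#'   normalised to `[0, 1]`).
#' @param params a [peak_params()] list.
#' @return integer repetition count.
#' @export
count_repetitions <- function(sig, params) {
  x <- if (inherits(sig, "hm_distance_signal")) sig$values else sig
  if (length(x) < 3) stop("signal too short to count repetitions")
  length(find_signal_peaks(-x,
                           min_height = params$min_height,
                           min_distance = params$min_distance,
                           min_prominence = params$min_prominence))
}

#' Intensity category from a repetition count
#'
#' Global range boundaries for a 12-s window: at most 8 repetitions is
#' `slow`, 9-12 `medium`, 13-16 `medfast`, 17 or more `fast`. The four
#' metronome rates 30/50/70/90 rpm correspond to 6/10/14/18 repetitions
#' per 12-s window, one per bin.
#'
#' @param reps integer vector of repetition counts.
#' @return factor with levels `slow`, `medium`, `medfast`, `fast`.
#' @export
range_category <- function(reps) {
  if (any(reps < 0)) stop("repetition counts must be non-negative")
  cut(reps, breaks = c(-Inf, 8, 12, 16, Inf),
      labels = c("slow", "medium", "medfast", "fast"))
}

#' Intensity category commanded by a metronome rate
#'
#' @param rate repetitions per minute (30, 50, 70 or 90 in the study
#'   design).
#' @return factor as [range_category()], via the expected count in a
#'   12-s window (`rate / 5`).
#' @export
rate_category <- function(rate) {
  range_category(rate * 12 / 60)
}

#' Range accuracy
#'
#' Percentage of windows whose predicted intensity category matches the
#' true category defined by the global range boundaries.
#'
#' @param predicted,truth factors/vectors of equal length.
#' @return percentage in `[0, 100]`.
#' @export
range_accuracy <- function(predicted, truth) {
  if (length(predicted) == 0) stop("no sequences to score")
  if (length(predicted) != length(truth)) stop("length mismatch")
  100 * mean(as.character(predicted) == as.character(truth))
}

#' Personalised intensity boundaries
#'
#' For each (subject, activity) pair the mean detected repetition count
#' at each of the four intensities defines personalised boundaries: a
#' window is correct when its count falls strictly between the mean
#' counts of the adjacent slower and faster intensities (one-sided for
#' `slow` and `fast`). Boundaries are reset for each activity and
#' participant.
#'
#' @param df data frame with columns `subject`, `activity`, `intensity`
#'   (slow/medium/medfast/fast) and `reps`.
#' @return data frame with one row per (subject, activity) and columns
#'   `mean_slow`, `mean_medium`, `mean_medfast`, `mean_fast`.
#' @export
personalised_boundaries <- function(df) {
  need <- c("subject", "activity", "intensity", "reps")
  if (!all(need %in% names(df))) stop("df needs columns ",
                                      paste(need, collapse = ", "))
  levels4 <- c("slow", "medium", "medfast", "fast")
  agg <- stats::aggregate(reps ~ subject + activity + intensity,
                          data = transform(df, intensity = as.character(intensity)),
                          FUN = mean)
  out <- NULL
  for (key in unique(paste(agg$subject, agg$activity, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- agg[agg$subject == parts[1] & agg$activity == parts[2], ]
    got <- levels4 %in% sub$intensity
    if (!all(got))
      stop("subject '", parts[1], "', activity '", parts[2],
           "' lacks intensity level(s): ",
           paste(levels4[!got], collapse = ", "))
    means <- sub$reps[match(levels4, sub$intensity)]
    out <- rbind(out, data.frame(
      subject = parts[1], activity = parts[2],
      mean_slow = means[1], mean_medium = means[2],
      mean_medfast = means[3], mean_fast = means[4],
      stringsAsFactors = FALSE))
  }
  out
}

# correctness of one window under personalised boundaries
#' @keywords internal
hm_personalised_ok <- function(reps, intensity, b) {
  switch(as.character(intensity),
         slow    = reps < b$mean_medium,
         medium  = reps > b$mean_slow   & reps < b$mean_medfast,
         medfast = reps > b$mean_medium & reps < b$mean_fast,
         fast    = reps > b$mean_medfast,
         stop("unknown intensity '", intensity, "'"))
}

#' Personalised accuracy
#'
#' Percentage of windows whose detected repetition count falls inside
#' that subject-and-activity's personalised boundaries (see
#' [personalised_boundaries()]). Less stringent than range accuracy but
#' sufficient to track changes in an individual's movement speed, which
#' is what matters for monitoring.
#'
#' @param df data frame with columns `subject`, `activity`, `intensity`
#'   and `reps`; boundaries are computed from `df` itself.
#' @return percentage in `[0, 100]`.
#' @export
personalised_accuracy <- function(df) {
  if (nrow(df) == 0) stop("no sequences to score")
  bounds <- personalised_boundaries(df)
  ok <- vapply(seq_len(nrow(df)), function(i) {
    b <- bounds[bounds$subject == as.character(df$subject[i]) &
                bounds$activity == as.character(df$activity[i]), ]
    hm_personalised_ok(df$reps[i], df$intensity[i], b)
  }, logical(1))
  100 * mean(ok)
}

#' Shipped per-class intensity configuration
#'
#' Distance measure and peak hyperparameters per movement class, as
#' tuned by grid search on the reference training corpus: clap and the
#' whole-hand movements scratch/wring track the Euclidean wrist
#' distance, pick and rub the vertical wrist distance. Note the clap
#' minimum height (-0.65) lies off the default tuning grid; it is
#' shipped as published. Retune on your own data with
#' [tune_intensity()].
#'
#' @return named list: per class a list with `measure` and `params`
#'   ([peak_params()]).
#' @export
default_intensity_config <- function() {
  list(
    clap    = list(measure = "euclid_wrist",
                   params = peak_params(0.8, 10, -0.65)),
    pick    = list(measure = "vert_wrist",
                   params = peak_params(0.5, 11, -0.2)),
    rub     = list(measure = "vert_wrist",
                   params = peak_params(0.6, 10, -0.5)),
    scratch = list(measure = "euclid_wrist",
                   params = peak_params(0.4, 10, -0.5)),
    wring   = list(measure = "euclid_wrist",
                   params = peak_params(0.4, 10, -0.4))
  )
}

#' Write / read an intensity configuration
#'
#' YAML keyed by class, each entry holding `measure`, `min_prominence`,
#' `min_distance`, `min_height`.
#'
#' @param cfg configuration list as from [default_intensity_config()]
#'   or [tune_intensity()].
#' @param path file path.
#' @return `path` (write) or the configuration list (read).
#' @export
write_intensity_config <- function(cfg, path) {
  flat <- lapply(cfg, function(e)
    list(measure = e$measure,
         min_prominence = e$params$min_prominence,
         min_distance = e$params$min_distance,
         min_height = e$params$min_height))
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_intensity_config
#' @export
read_intensity_config <- function(path) {
  flat <- yaml::read_yaml(path)
  lapply(flat, function(e)
    list(measure = e$measure,
         params = peak_params(e$min_prominence, e$min_distance,
                              e$min_height)))
}

#' Default hyperparameter tuning grid
#'
#' Prominence 0 to 2 in steps of 0.2, distance 10 to 20 frames,
#' height -0.5 to 0.5 in steps of 0.1 (on the negated normalised
#' signal); all endpoints inclusive.
#'
#' @return list with `prominence`, `distance`, `height` numeric grids.
#' @export
default_tuning_grid <- function() {
  list(prominence = seq(0, 2, by = 0.2),
       distance = 10:20,
       height = seq(-0.5, 0.5, by = 0.1))
}

# counts for every (height, distance, prominence) combination of one
# signal's cached peak candidates; returns an array [h, d, p]
#' @keywords internal
hm_grid_counts <- function(cand, grid) {
  nh <- length(grid$height); nd <- length(grid$distance)
  np <- length(grid$prominence)
  counts <- array(0L, dim = c(nh, nd, np))
  for (hi in seq_len(nh)) {
    sel <- cand$height >= grid$height[hi]
    idx <- cand$idx[sel]; h <- cand$height[sel]; pr <- cand$prominence[sel]
    for (di in seq_len(nd)) {
      keep <- hm_distance_suppress(idx, h, grid$distance[di])
      prk <- sort(pr[keep], decreasing = TRUE)
      # number of kept peaks with prominence >= each grid threshold
      counts[hi, di, ] <- vapply(grid$prominence, function(p)
        sum(prk >= p), integer(1))
    }
  }
  counts
}

#' Tune per-class intensity parameters by grid search
#'
#' For each movement class and each candidate distance measure, every
#' point of the (prominence, distance, height) grid is scored by range
#' accuracy over the supplied windows; the best-scoring combination is
#' kept. Ties are broken towards smaller prominence, then smaller
#' distance, then larger height, then the measure order of
#' [distance_measures()].
#'
#' @param windows list of `hm_window` objects (12-s intensity windows).
#' @param classes true movement class per window.
#' @param intensities true intensity category per window (factor or
#'   character: slow/medium/medfast/fast).
#' @param measures distance measures to scan.
#' @param grid tuning grid, see [default_tuning_grid()].
#' @return configuration list in the [default_intensity_config()]
#'   shape, each entry also carrying `accuracy` (the achieved range
#'   accuracy, percent).
#' @export
tune_intensity <- function(windows, classes, intensities,
                           measures = distance_measures(),
                           grid = default_tuning_grid()) {
  if (length(grid$prominence) == 0 || length(grid$distance) == 0 ||
      length(grid$height) == 0) stop("empty tuning grid")
  classes <- as.character(classes)
  intensities <- as.character(intensities)
  measures <- match.arg(measures, distance_measures(), several.ok = TRUE)
  # negated-signal height grid: thresholds are stated on the negated
  # signal, where peaks live
  out <- list()
  for (cl in sort(unique(classes))) {
    wsel <- which(classes == cl)
    best <- NULL
    for (mi in seq_along(measures)) {
      m <- measures[mi]
      counts <- vapply(wsel, function(w) {
        sig <- suppressWarnings(compute_distance_signal(windows[[w]], m))
        hm_grid_counts(hm_peak_candidates(-sig$values), grid)
      }, array(0L, dim = c(length(grid$height), length(grid$distance),
                           length(grid$prominence))))
      dim(counts) <- c(length(grid$height) * length(grid$distance) *
                         length(grid$prominence), length(wsel))
      cats <- as.character(range_category(as.vector(counts)))
      dim(cats) <- dim(counts)
      acc <- 100 * rowMeans(cats == rep(intensities[wsel],
                                        each = nrow(counts)))
      combos <- expand.grid(hi = seq_along(grid$height),
                            di = seq_along(grid$distance),
                            pi = seq_along(grid$prominence))
      ord <- order(-acc, grid$prominence[combos$pi],
                   grid$distance[combos$di], -grid$height[combos$hi])
      top <- ord[1]
      cand <- list(measure = m,
                   params = peak_params(grid$prominence[combos$pi[top]],
                                        grid$distance[combos$di[top]],
                                        grid$height[combos$hi[top]]),
                   accuracy = acc[top])
      if (is.null(best) || cand$accuracy > best$accuracy) best <- cand
    }
    out[[cl]] <- best
  }
  out
}

#' Tune a single generic intensity configuration
#'
#' The generic scenario skips classification and uses one Euclidean
#' wrist configuration for every movement, tuned on the entire training
#' set.
#'
#' @inheritParams tune_intensity
#' @return a single-entry configuration list named `generic`.
#' @export
tune_generic <- function(windows, intensities,
                         grid = default_tuning_grid()) {
  cfg <- tune_intensity(windows, rep("generic", length(windows)),
                        intensities, measures = "euclid_wrist",
                        grid = grid)
  cfg
}
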