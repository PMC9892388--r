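# One-dimensional peak detection with topographic prominence.
#
# Semantics follow the conventional signal-processing toolkit reading:
# a peak is a sample strictly greater than its neighbours (a flat
# plateau is represented by its midpoint sample); filters are applied
# in the order height, minimum distance (keeping the higher of two
# close peaks, the earlier on ties), then prominence. Prominence is a
# property of a peak in the whole signal, so it is unaffected by which
# other peaks survive filtering.

#' Local maxima of a numeric series
#'
#' Endpoints cannot be maxima. A plateau (run of equal values higher
#' than both neighbouring samples) is represented by its midpoint
#' sample (the earlier of the two central samples for even runs).
#'
#' @param x numeric vector.
#' @return integer vector of peak indices (1-based), increasing.
#' @export
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        peaks <- c(peaks, (i + j) %/% 2L)
        i <- j + 1L
      } else {
        i <- j + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  peaks
}

#' Topographic prominence of peaks
#'
#' For each peak, extend horizontally left and right until the signal
#' rises strictly above the peak height or the signal border is
#' reached; the base on each side is the minimum over that interval,
#' and the prominence is the peak height minus the higher of the two
#' bases.
#'
#' @param x numeric vector.
#' @param peaks integer vector of peak indices (from [local_maxima()]).
#' @return numeric vector of prominences, one per peak.
#' @export
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    i <- p - 1L; lb <- h
    while (i >= 1L && x[i] <= h) { if (x[i] < lb) lb <- x[i]; i <- i - 1L }
    i <- p + 1L; rb <- h
    while (i <= length(x) && x[i] <= h) { if (x[i] < rb) rb <- x[i]; i <- i + 1L }
    h - max(lb, rb)
  }, numeric(1))
}

# peak candidates with the per-peak quantities the filters need;
# computed once per signal and reused across a hyperparameter grid
#' @keywords internal
hm_peak_candidates <- function(x) {
  idx <- local_maxima(x)
  list(idx = idx, height = x[idx], prominence = peak_prominences(x, idx))
}

# minimum-distance suppression: visit peaks from highest (earlier index
# wins ties) and drop any unvisited peak closer than min_distance
#' @keywords internal
hm_distance_suppress <- function(idx, height, min_distance) {
  k <- length(idx)
  if (k <= 1L || min_distance <= 1) return(rep(TRUE, k))
  keep <- rep(TRUE, k)
  for (o in order(-height, idx)) {
    if (!keep[o]) next
    close <- keep & abs(idx - idx[o]) < min_distance
    close[o] <- FALSE
    keep[close] <- FALSE
  }
  keep
}

#' @keywords internal
hm_filter_candidates <- function(cand, min_height = -Inf, min_distance = 1,
                                 min_prominence = 0) {
  sel <- cand$height >= min_height
  idx <- cand$idx[sel]; h <- cand$height[sel]; pr <- cand$prominence[sel]
  keep <- hm_distance_suppress(idx, h, min_distance)
  idx <- idx[keep]; pr <- pr[keep]
  idx[pr >= min_prominence]
}

#' Detect peaks subject to height, distance and prominence thresholds
#'
#' @param x numeric vector.
#' @param min_height minimum peak value (applied to `x` as given).
#' @param min_distance minimum separation between retained peaks in
#'   samples; when two qualifying peaks are closer, the higher is kept
#'   (the earlier on an exact tie).
#' @param min_prominence minimum topographic prominence.
#' @return integer vector of retained peak indices, increasing.
#' @export
find_signal_peaks <- function(x, min_height = -Inf, min_distance = 1,
                              min_prominence = 0) {
  if (min_distance < 1) stop("min_distance must be >= 1")
  if (min_prominence < 0) stop("min_prominence must be >= 0")
  hm_filter_candidates(hm_peak_candidates(x), min_height, min_distance,
                       min_prominence)
}
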