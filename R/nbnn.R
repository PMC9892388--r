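# Naive Bayes Nearest Neighbour classification of movement type from
# discriminative pose sets, with the three cross-validation protocols
# used to evaluate it (stratified k-fold, cross-intensity,
# leave-one-subject-out).

# per query row, the Euclidean distance to its nearest row of X;
# computed from explicit differences (no expansion trick) so an exact
# self-match yields exactly zero
#' @keywords internal
hm_nearest_dists <- function(Q, X) {
  vapply(seq_len(nrow(Q)), function(i) {
    diff <- X - matrix(Q[i, ], nrow(X), ncol(X), byrow = TRUE)
    sqrt(min(rowSums(diff * diff)))
  }, numeric(1))
}

#' Build a pose library for NBNN classification
#'
#' NBNN is instance-based: fitting stores every training pose, grouped
#' by (class, pose kind), and estimates no parameters. Duplicate sets
#' are stored twice.
#'
#' @param sets list of `hm_poseset` objects.
#' @param labels character vector of class labels, one per set.
#' @return an `hm_pose_library` with elements `classes`, `kinds` and
#'   `store[[class]][[kind]]` pose matrices.
#' @export
nbnn_fit <- function(sets, labels) {
  if (length(sets) == 0) stop("empty training data")
  if (length(sets) != length(labels))
    stop("labels must match training sets")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  kinds <- sort(unique(unlist(lapply(sets, `[[`, "kind"))))
  store <- lapply(classes, function(cl) {
    rows <- do.call(rbind, lapply(sets[labels == cl], `[[`, "poses"))
    kind <- unlist(lapply(sets[labels == cl], `[[`, "kind"))
    by_kind <- lapply(kinds, function(k) rows[kind == k, , drop = FALSE])
    names(by_kind) <- kinds
    empty <- vapply(by_kind, nrow, integer(1)) == 0
    if (any(empty))
      stop("class '", cl, "' has no training pose of kind ",
           paste(kinds[empty], collapse = ", "))
    by_kind
  })
  names(store) <- classes
  structure(list(classes = classes, kinds = kinds, store = store),
            class = "hm_pose_library")
}

#' @export
print.hm_pose_library <- function(x, ...) {
  n <- vapply(x$store, function(s) sum(vapply(s, nrow, integer(1))),
              integer(1))
  cat("<hm_pose_library>", sum(n), "poses:",
      paste(sprintf("%s=%d", x$classes, n), collapse = ", "), "\n")
  invisible(x)
}

#' Classify a pose set with Naive Bayes Nearest Neighbour
#'
#' For each candidate class the total distance is the sum, over the
#' query's poses, of the Euclidean distance (on the 92-coordinate
#' flattened pose) to the nearest stored pose of the *same kind* in
#' that class. The predicted class minimises the total; an exact tie
#' picks the lexicographically smallest label with a warning.
#'
#' @param set an `hm_poseset` query.
#' @param lib an `hm_pose_library` from [nbnn_fit()].
#' @return list with `class` (predicted label), `totals` (named
#'   per-class total distances) and `margin` (runner-up total minus
#'   winner total).
#' @export
nbnn_classify <- function(set, lib) {
  stopifnot(inherits(set, "hm_poseset"), inherits(lib, "hm_pose_library"))
  qk <- unique(set$kind)
  if (!all(qk %in% lib$kinds))
    stop("library lacks pose kind(s): ",
         paste(setdiff(qk, lib$kinds), collapse = ", "))
  totals <- stats::setNames(numeric(length(lib$classes)), lib$classes)
  for (k in qk) {
    Q <- set$poses[set$kind == k, , drop = FALSE]
    for (cl in lib$classes) {
      totals[cl] <- totals[cl] +
        sum(hm_nearest_dists(Q, lib$store[[cl]][[k]]))
    }
  }
  best <- min(totals)
  winners <- names(totals)[totals == best]
  if (length(winners) > 1)
    warning("per-class totals tie exactly (",
            paste(winners, collapse = ", "),
            "); returning lexicographically first")
  pred <- sort(winners)[1]
  margin <- if (length(totals) > 1) sort(totals)[2] - best else Inf
  list(class = pred, totals = totals, margin = margin)
}

# fold assignment helpers ---------------------------------------------

#' @keywords internal
hm_stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Cross-validate NBNN classification of movement type
#'
#' Three protocols: `"kfold"` is a stratified random k-fold (default
#' four folds); `"cross_intensity"` holds out one intensity level
#' entirely per fold, testing generalisation across movement speeds;
#' `"cross_subject"` is leave-one-subject-out, testing generalisation
#' to new people.
#'
#' @param sets list of `hm_poseset` objects.
#' @param labels class label per set.
#' @param protocol validation protocol.
#' @param subjects subject id per set (required for `cross_subject`).
#' @param intensities intensity label per set (required for
#'   `cross_intensity`).
#' @param k number of folds for `kfold`.
#' @param seed RNG seed for the random fold assignment.
#' @return list with `fold_accuracy` (percentage per fold, named),
#'   `mean` and `sd`.
#' @export
nbnn_cross_validate <- function(sets, labels,
                                protocol = c("kfold", "cross_intensity",
                                             "cross_subject"),
                                subjects = NULL, intensities = NULL,
                                k = 4, seed = 1) {
  protocol <- match.arg(protocol)
  labels <- as.character(labels)
  fold <- switch(
    protocol,
    kfold = {
      set.seed(seed)
      hm_stratified_folds(labels, k)
    },
    cross_intensity = {
      if (is.null(intensities)) stop("cross_intensity needs intensity labels")
      as.integer(factor(intensities))
    },
    cross_subject = {
      if (is.null(subjects)) stop("cross_subject needs subject ids")
      as.integer(factor(subjects))
    }
  )
  fold_names <- switch(protocol,
                       kfold = paste0("fold", sort(unique(fold))),
                       cross_intensity = levels(factor(intensities)),
                       cross_subject = levels(factor(subjects)))
  acc <- vapply(sort(unique(fold)), function(f) {
    tr <- fold != f
    lib <- nbnn_fit(sets[tr], labels[tr])
    pred <- vapply(sets[!tr], function(s) nbnn_classify(s, lib)$class,
                   character(1))
    100 * mean(pred == labels[!tr])
  }, numeric(1))
  names(acc) <- fold_names
  list(fold_accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
       protocol = protocol)
}
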