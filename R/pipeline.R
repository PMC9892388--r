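# The end-to-end system: preprocess, classify the movement type with
# NBNN, pick that class's intensity configuration and count
# repetitions. Scenarios: "proposed" (the full pipeline), "known"
# (ground-truth labels select the intensity configuration) and
# "generic" (classification skipped, one Euclidean-wrist configuration
# for everything).

#' Default windowing parameters
#'
#' Classification trains on 6-s non-overlapping windows after
#' discarding 3 s at each end of a 30-s recording (4 windows);
#' intensity uses 12-s windows shifted by 5 s after discarding 1.5 s at
#' each end (4 windows, consecutive windows sharing 7 s).
#'
#' @return nested list with `classify` and `intensity` entries, each
#'   holding `window_s`, `overlap_s`, `discard_s`.
#' @export
default_window_params <- function() {
  list(classify = list(window_s = 6, overlap_s = 0, discard_s = 3),
       intensity = list(window_s = 12, overlap_s = 7, discard_s = 1.5))
}

# segment with a params entry
#' @keywords internal
hm_windows_for <- function(rec, wp) {
  segment_windows(rec, window_s = wp$window_s, overlap_s = wp$overlap_s,
                  discard_s = wp$discard_s)
}

#' Train the movement-type and intensity models
#'
#' Preprocesses every training recording, builds the NBNN pose library
#' from 6-s classification windows, and tunes per-class and generic
#' intensity hyperparameters by grid search on 12-s intensity windows
#' scored by range accuracy.
#'
#' @param recordings list of raw [hm_recording()] objects whose `meta`
#'   carries `class`, `rate` (or `intensity`) and `subject`.
#' @param window_params see [default_window_params()].
#' @param grid tuning grid for [tune_intensity()].
#' @param tune when `FALSE`, skip the grid search and ship
#'   [default_intensity_config()] (plus its Euclidean-wrist `generic`
#'   fallback tuned from the same windows).
#' @param preprocessed set to `TRUE` when `recordings` are already
#'   imputed/normalised/smoothed.
#' @return an `hm_model`: list with `library` (pose library), `config`
#'   (per-class intensity configuration), `generic` (single-entry
#'   configuration) and `window_params`.
#' @export
fit_pipeline <- function(recordings, window_params = default_window_params(),
                         grid = default_tuning_grid(), tune = TRUE,
                         preprocessed = FALSE) {
  if (length(recordings) == 0) stop("no training recordings")
  if (!preprocessed)
    recordings <- lapply(recordings, preprocess_recording)
  # classification windows -> pose sets
  sets <- list(); set_labels <- character(0)
  iwin <- list(); icls <- character(0); iint <- character(0)
  for (rec in recordings) {
    cl <- rec$meta$class
    if (is.null(cl)) stop("training recording lacks meta$class")
    intensity <- rec$meta$intensity
    if (is.null(intensity)) intensity <- as.character(rate_category(rec$meta$rate))
    cw <- hm_windows_for(rec, window_params$classify)
    for (w in cw) {
      sets[[length(sets) + 1L]] <- discriminative_poses(w)
      set_labels <- c(set_labels, cl)
    }
    for (w in hm_windows_for(rec, window_params$intensity)) {
      iwin[[length(iwin) + 1L]] <- w
      icls <- c(icls, cl)
      iint <- c(iint, intensity)
    }
  }
  lib <- nbnn_fit(sets, set_labels)
  if (tune) {
    config <- tune_intensity(iwin, icls, iint, grid = grid)
    generic <- tune_generic(iwin, iint, grid = grid)
  } else {
    config <- default_intensity_config()
    generic <- tune_generic(iwin, iint, grid = grid)
  }
  structure(list(library = lib, config = config, generic = generic,
                 window_params = window_params),
            class = "hm_model")
}

#' @export
print.hm_model <- function(x, ...) {
  cat("<hm_model>\n"); print(x$library)
  for (cl in names(x$config))
    cat(sprintf("  %-8s %s prom>=%.2g dist>=%g height>=%.3g\n", cl,
                x$config[[cl]]$measure,
                x$config[[cl]]$params$min_prominence,
                x$config[[cl]]$params$min_distance,
                x$config[[cl]]$params$min_height))
  invisible(x)
}

#' Run the pipeline on one recording
#'
#' Cuts the recording into 12-s intensity windows; per window,
#' classifies the movement type from its discriminative poses (scenario
#' `"proposed"`), or takes the ground-truth label (`"known"`), or skips
#' classification (`"generic"`), then selects the matching intensity
#' configuration and counts repetitions.
#'
#' @param rec a raw [hm_recording()].
#' @param model an `hm_model` from [fit_pipeline()].
#' @param scenario `"proposed"`, `"known"` or `"generic"`.
#' @param central_180 summarise 12-s windows by 9 poses from the
#'   central 6 s instead of the default 18.
#' @param preprocessed set `TRUE` when `rec` is already preprocessed.
#' @return data frame, one row per window: `window`, `start_s`,
#'   `end_s`, `predicted_class`, `measure`, `reps`, `range_cat`,
#'   `scenario`, plus true labels when the recording carries them.
#' @export
run_pipeline <- function(rec, model,
                         scenario = c("proposed", "known", "generic"),
                         central_180 = FALSE, preprocessed = FALSE) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(model, "hm_model"))
  if (!preprocessed) rec <- preprocess_recording(rec)
  wins <- hm_windows_for(rec, model$window_params$intensity)
  if (length(wins) == 0)
    stop("recording too short for one intensity window")
  if (scenario == "known" && is.null(rec$meta$class))
    stop("scenario 'known' needs a ground-truth class label")
  rows <- lapply(seq_along(wins), function(i) {
    w <- wins[[i]]
    pred <- switch(scenario,
      proposed = nbnn_classify(discriminative_poses(w, central_180 = central_180),
                               model$library)$class,
      known = rec$meta$class,
      generic = NA_character_)
    entry <- if (scenario == "generic") model$generic$generic
             else model$config[[pred]]
    if (is.null(entry))
      stop("no intensity configuration for class '", pred, "'")
    sig <- suppressWarnings(compute_distance_signal(w, entry$measure))
    reps <- count_repetitions(sig, entry$params)
    data.frame(window = i, start_s = w$start / w$fps, end_s = w$end / w$fps,
               predicted_class = pred, measure = entry$measure,
               reps = reps, range_cat = as.character(range_category(reps)),
               scenario = scenario, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(rec$meta$class)) out$true_class <- rec$meta$class
  if (!is.null(rec$meta$intensity)) out$true_intensity <- rec$meta$intensity
  if (!is.null(rec$meta$subject)) out$subject <- rec$meta$subject
  out
}

#' Evaluate the pipeline on a labelled corpus
#'
#' Runs [run_pipeline()] over every recording and reports type
#' accuracy, range accuracy, personalised intensity accuracy (with
#' boundaries reset per subject and activity) and the joint accuracy
#' (type correct AND personalised intensity correct), plus confusion
#' matrices for type and intensity.
#'
#' @param recordings list of labelled raw [hm_recording()] objects.
#' @param model an `hm_model`.
#' @param scenario see [run_pipeline()].
#' @param central_180 see [run_pipeline()].
#' @param preprocessed set `TRUE` when `recordings` are already
#'   preprocessed.
#' @return an `hm_report`: list with `windows` (per-window data frame),
#'   `type_accuracy`, `range_accuracy`, `personalised_accuracy`,
#'   `joint_accuracy` (percentages), `type_confusion` (true x
#'   predicted) and `intensity_confusion` (true x predicted range
#'   category).
#' @export
evaluate_pipeline <- function(recordings, model,
                              scenario = c("proposed", "known", "generic"),
                              central_180 = FALSE, preprocessed = FALSE) {
  scenario <- match.arg(scenario)
  if (length(recordings) == 0) stop("empty evaluation corpus")
  res <- do.call(rbind, lapply(recordings, function(rec) {
    if (is.null(rec$meta$class) || is.null(rec$meta$subject))
      stop("evaluation recordings need meta$class and meta$subject")
    run_pipeline(rec, model, scenario = scenario,
                 central_180 = central_180, preprocessed = preprocessed)
  }))
  type_ok <- if (scenario == "generic") rep(NA, nrow(res))
             else res$predicted_class == res$true_class
  df <- data.frame(subject = res$subject, activity = res$true_class,
                   intensity = res$true_intensity, reps = res$reps,
                   stringsAsFactors = FALSE)
  bounds <- personalised_boundaries(df)
  pers_ok <- vapply(seq_len(nrow(df)), function(i) {
    b <- bounds[bounds$subject == as.character(df$subject[i]) &
                bounds$activity == df$activity[i], ]
    hm_personalised_ok(df$reps[i], df$intensity[i], b)
  }, logical(1))
  res$type_correct <- type_ok
  res$personalised_correct <- pers_ok
  type_acc <- if (scenario == "generic") NA_real_ else 100 * mean(type_ok)
  joint <- if (scenario == "generic") NA_real_
           else 100 * mean(type_ok & pers_ok)
  structure(list(
    windows = res,
    scenario = scenario,
    type_accuracy = type_acc,
    range_accuracy = range_accuracy(res$range_cat, res$true_intensity),
    personalised_accuracy = 100 * mean(pers_ok),
    joint_accuracy = joint,
    type_confusion = if (scenario == "generic") NULL
                     else table(true = res$true_class,
                                predicted = res$predicted_class),
    intensity_confusion = table(true = res$true_intensity,
                                predicted = res$range_cat)
  ), class = "hm_report")
}

#' @export
print.hm_report <- function(x, ...) {
  cat(sprintf("<hm_report> scenario '%s' over %d windows\n",
              x$scenario, nrow(x$windows)))
  if (!is.na(x$type_accuracy))
    cat(sprintf("  type accuracy:         %6.2f %%\n", x$type_accuracy))
  cat(sprintf("  range accuracy:        %6.2f %%\n", x$range_accuracy))
  cat(sprintf("  personalised accuracy: %6.2f %%\n", x$personalised_accuracy))
  if (!is.na(x$joint_accuracy))
    cat(sprintf("  joint type+intensity:  %6.2f %%\n", x$joint_accuracy))
  if (!is.null(x$type_confusion)) {
    cat("  type confusion (rows = true class):\n")
    print(x$type_confusion)
  }
  cat("  intensity confusion (rows = true intensity):\n")
  print(x$intensity_confusion)
  invisible(x)
}

# model persistence ----------------------------------------------------

#' Save / load a trained model
#'
#' The pose library is written as a delimiter-separated table (class,
#' kind, 92 coordinate columns), the intensity configurations as YAML
#' and the windowing parameters as JSON, so a saved model is plain
#' text and diff-able.
#'
#' @param model an `hm_model`.
#' @param dir directory to hold the model files.
#' @return `dir` (save) / an `hm_model` (load).
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "hm_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list(); labs <- character(0); kinds <- character(0)
  for (cl in model$library$classes) {
    for (k in model$library$kinds) {
      m <- model$library$store[[cl]][[k]]
      rows[[length(rows) + 1L]] <- m
      labs <- c(labs, rep(cl, nrow(m)))
      kinds <- c(kinds, rep(k, nrow(m)))
    }
  }
  mat <- do.call(rbind, rows)
  lines <- c(paste(c("class", "kind", paste0("v", 1:92)), collapse = ","),
             vapply(seq_len(nrow(mat)), function(i)
               paste(c(labs[i], kinds[i], sprintf("%.17g", mat[i, ])),
                     collapse = ","), character(1)))
  writeLines(lines, file.path(dir, "pose_library.csv"))
  write_intensity_config(model$config, file.path(dir, "intensity_config.yaml"))
  write_intensity_config(model$generic, file.path(dir, "generic_config.yaml"))
  jsonlite::write_json(model$window_params,
                       file.path(dir, "window_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "pose_library.csv"),
                         stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, paste0("v", 1:92)])
  classes <- sort(unique(tab$class))
  kinds <- sort(unique(tab$kind))
  store <- lapply(classes, function(cl) {
    by_kind <- lapply(kinds, function(k)
      unname(mat[tab$class == cl & tab$kind == k, , drop = FALSE]))
    names(by_kind) <- kinds
    by_kind
  })
  names(store) <- classes
  lib <- structure(list(classes = classes, kinds = kinds, store = store),
                   class = "hm_pose_library")
  wp <- jsonlite::fromJSON(file.path(dir, "window_params.json"),
                           simplifyVector = TRUE)
  structure(list(
    library = lib,
    config = read_intensity_config(file.path(dir, "intensity_config.yaml")),
    generic = read_intensity_config(file.path(dir, "generic_config.yaml")),
    window_params = wp
  ), class = "hm_model")
}
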