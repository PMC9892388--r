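# Distance signals, repetition counting, intensity categories,
# accuracy measures and the tuning grid search.

# a window whose wrist separation follows `sep` (and everything else is
# rigid), for direct signal checks
sep_window <- function(sep_x, sep_y = rep(0, length(sep_x))) {
  n <- length(sep_x)
  ha <- array(0, dim = c(n, 46L, 3L),
              dimnames = list(NULL, handrep:::hm_ha_names(), c("x", "y", "c")))
  ha[, , "c"] <- 1
  ha[, "r_wrist", "x"] <- sep_x / 2;  ha[, "l_wrist", "x"] <- -sep_x / 2
  ha[, "r_wrist", "y"] <- sep_y / 2;  ha[, "l_wrist", "y"] <- -sep_y / 2
  for (k in 0:20) {
    ha[, paste0("r_hand_", k), "x"] <- ha[, "r_wrist", "x"] + 0.01 * k
    ha[, paste0("l_hand_", k), "x"] <- ha[, "l_wrist", "x"] - 0.01 * k
  }
  structure(list(kp = ha, centroids = hand_centroids(ha), start = 0,
                 end = n, fps = 30, dominant = "right", reflected = FALSE,
                 meta = list()), class = "hm_window")
}

test_that("distance measures compute the advertised geometry and normalise to [0, 1]", {
  # wrists separated by (3, 4): euclid 5, vertical 4, horizontal 3
  w <- sep_window(c(3, 3, 0), c(4, 4, 0))
  expect_equal(compute_distance_signal(w, "euclid_wrist")$raw[1], 5)
  expect_equal(compute_distance_signal(w, "vert_wrist")$raw[1], 4)
  expect_equal(compute_distance_signal(w, "horiz_wrist")$raw[1], 3)
  # constant signal degenerates to zeros with a warning
  const <- sep_window(rep(2, 10))
  expect_warning(sig <- compute_distance_signal(const, "euclid_wrist"),
                 "constant")
  expect_true(all(sig$values == 0))
  # random signals hit exactly 0 and 1 after normalisation
  set.seed(31)
  for (i in 1:10) {
    wr <- sep_window(runif(40, 1, 3))
    v <- compute_distance_signal(wr, "euclid_wrist")$values
    expect_equal(min(v), 0)
    expect_equal(max(v), 1)
  }
})

test_that("repetitions are counted as filtered peaks of the negated signal", {
  p <- peak_params(0.4, 10, -0.5)
  expect_equal(count_repetitions(rep(0.5, 50), p), 0)
  # 10 full cosine cycles over 360 frames: minima counted via the
  # analytic zero-derivative positions
  tt <- 0:359
  sig <- (1 + cos(2 * pi * 10 * tt / 360)) / 2
  analytic_minima <- sum(((2 * (0:100) + 1) * 18) %in% tt)  # t = (2k+1)*T/2
  expect_equal(count_repetitions(sig, p), analytic_minima)
  expect_equal(count_repetitions(sig, p), 10)
  # two minima 5 frames apart with min_distance 10: deeper one kept
  x <- rep(0.8, 40)
  x[10] <- 0.0; x[15] <- 0.2
  expect_equal(count_repetitions(x, peak_params(0.1, 10, -1)), 1)
  # invariant to adding a constant to the raw signal (pre-normalisation)
  raw <- 2 + cos(2 * pi * 7 * (0:299) / 300)
  norm <- function(v) (v - min(v)) / (max(v) - min(v))
  expect_equal(count_repetitions(norm(raw), p),
               count_repetitions(norm(raw + 11.3), p))
})

test_that("range categories partition counts at 8/12/16", {
  expect_equal(as.character(range_category(8)), "slow")
  expect_equal(as.character(range_category(9)), "medium")
  expect_equal(as.character(range_category(13)), "medfast")
  expect_equal(as.character(range_category(17)), "fast")
  # partition: every non-negative integer falls in exactly one bin
  cats <- range_category(0:40)
  expect_false(anyNA(cats))
  expect_equal(as.vector(table(cats)), c(9, 4, 4, 24))
  # metronome rates map one-per-bin
  expect_equal(as.character(rate_category(c(30, 50, 70, 90))),
               c("slow", "medium", "medfast", "fast"))
})

test_that("range accuracy is the plain percentage of matching categories", {
  expect_equal(range_accuracy(c("slow", "fast"), c("slow", "fast")), 100)
  expect_equal(range_accuracy(c("slow", "fast"), c("fast", "slow")), 0)
  expect_equal(range_accuracy(rep("slow", 4), c(rep("slow", 3), "fast")), 75)
  expect_error(range_accuracy(character(0), character(0)), "no sequences")
})

test_that("personalised boundaries follow the between-adjacent-means rules", {
  base <- expand.grid(subject = "s1", activity = "clap",
                      intensity = c("slow", "medium", "medfast", "fast"),
                      stringsAsFactors = FALSE)
  base$reps <- c(6, 10, 14, 18)
  b <- personalised_boundaries(base)
  expect_equal(b$mean_medium, 10)
  # means 6/10/14/18: 11 at true medium is correct (6 < 11 < 14)
  expect_true(handrep:::hm_personalised_ok(11, "medium", b))
  # 15 at true medium violates the upper boundary (15 >= 14)
  expect_false(handrep:::hm_personalised_ok(15, "medium", b))
  # fast is one-sided: 19 > mean(medfast) = 14
  expect_true(handrep:::hm_personalised_ok(19, "fast", b))
  expect_error(personalised_boundaries(base[base$intensity != "fast", ]),
               "fast")
})

test_that("personalised accuracy scores a hand-tallied 16-window fixture", {
  df <- expand.grid(rep_i = 1:4,
                    intensity = c("slow", "medium", "medfast", "fast"),
                    stringsAsFactors = FALSE)
  df$subject <- "s1"; df$activity <- "pick"
  # strictly increasing counts across intensities: all correct
  df$reps <- rep(c(5, 9, 13, 17), each = 4) + df$rep_i / 10
  expect_equal(personalised_accuracy(df), 100)
  # corrupt three windows outside their personal bounds and tally by hand:
  # means become slow 6.25, medium 9.15, medfast 14.2, fast 16.3
  df2 <- df
  df2$reps[1] <- 10    # slow >= mean(medium) -> wrong
  df2$reps[6] <- 6     # medium <= mean(slow) -> wrong
  df2$reps[16] <- 14   # fast <= mean(medfast) -> wrong
  m <- tapply(df2$reps, df2$intensity, mean)
  manual <- sum(
    vapply(seq_len(16), function(i) switch(df2$intensity[i],
      slow = df2$reps[i] < m[["medium"]],
      medium = df2$reps[i] > m[["slow"]] && df2$reps[i] < m[["medfast"]],
      medfast = df2$reps[i] > m[["medium"]] && df2$reps[i] < m[["fast"]],
      fast = df2$reps[i] > m[["medfast"]]), logical(1)))
  expect_equal(personalised_accuracy(df2), 100 * manual / 16)
})

test_that("the shipped configuration carries the published per-class parameters", {
  cfg <- default_intensity_config()
  expect_setequal(names(cfg), movement_classes())
  expect_equal(cfg$clap$measure, "euclid_wrist")
  expect_equal(cfg$clap$params$min_prominence, 0.8)
  expect_equal(cfg$pick$measure, "vert_wrist")
  expect_equal(cfg$pick$params$min_distance, 11)
  expect_equal(cfg$wring$params$min_height, -0.4)
  # YAML round trip
  path <- file.path(withr::local_tempdir(), "cfg.yaml")
  write_intensity_config(cfg, path)
  expect_equal(read_intensity_config(path), cfg)
})

test_that("grid search returns the optimum of the grid it scans", {
  set.seed(41)
  corp <- generate_corpus(n_subjects = 1, n_train = 1, classes = "clap",
                          seed = 17)
  wins <- list(); ints <- character(0)
  for (i in seq_along(corp$recordings)) {
    for (w in quiet_windows(corp$recordings[[i]], 12, 7, 1.5)) {
      wins[[length(wins) + 1L]] <- w
      ints <- c(ints, corp$manifest$intensity[i])
    }
  }
  # degenerate single-point grid returns that point
  g1 <- list(prominence = 0.3, distance = 12, height = -0.3)
  cfg1 <- tune_intensity(wins, rep("clap", length(wins)), ints,
                         measures = "euclid_wrist", grid = g1)
  expect_equal(cfg1$clap$params$min_prominence, 0.3)
  expect_equal(cfg1$clap$params$min_distance, 12)
  expect_equal(cfg1$clap$params$min_height, -0.3)
  expect_error(tune_intensity(wins, rep("clap", length(wins)), ints,
                              grid = list(prominence = numeric(0),
                                          distance = 10, height = 0)),
               "empty")
  # reduced grid: tuned accuracy >= every grid point, re-evaluated
  # independently through count_repetitions
  grid <- list(prominence = c(0, 0.4, 0.8), distance = c(10, 15, 20),
               height = c(-0.4, -0.2, 0))
  cfg <- tune_intensity(wins, rep("clap", length(wins)), ints,
                        measures = c("euclid_wrist", "vert_wrist"),
                        grid = grid)
  sigs <- lapply(c(euclid_wrist = "euclid_wrist", vert_wrist = "vert_wrist"),
                 function(m) lapply(wins, function(w)
                   suppressWarnings(compute_distance_signal(w, m))))
  for (m in names(sigs)) {
    for (pr in grid$prominence) for (d in grid$distance) for (h in grid$height) {
      reps <- vapply(sigs[[m]], count_repetitions,
                     integer(1), peak_params(pr, d, h))
      acc <- range_accuracy(range_category(reps), ints)
      expect_lte(acc, cfg$clap$accuracy)
    }
  }
  expect_gte(cfg$clap$accuracy, 75)
})
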