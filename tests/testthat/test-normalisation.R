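# Scale normalisation, smoothing, dominance orientation, re-centring,
# centroids and windowing.

test_that("scale normalisation maps the neck to the origin in shoulder-width units", {
  rec <- make_recording(3, mod = function(kp) {
    kp[, "neck", "x"] <- 100; kp[, "neck", "y"] <- 200
    kp[, "r_shoulder", "x"] <- 80;  kp[, "r_shoulder", "y"] <- 200
    kp[, "l_shoulder", "x"] <- 120; kp[, "l_shoulder", "y"] <- 200
    kp[, "nose", "x"] <- 120; kp[, "nose", "y"] <- 240
    kp
  })
  norm <- scale_normalise(rec)
  expect_equal(unname(norm$kp[1, "neck", c("x", "y")]), c(0, 0))
  # (120, 240) with d = 40: ((120-100)/40, (240-200)/40) = (0.5, 1.0)
  expect_equal(unname(norm$kp[1, "nose", c("x", "y")]), c(0.5, 1.0))
  # shoulder distance becomes exactly 1
  d <- sqrt(sum((norm$kp[1, "l_shoulder", 1:2] - norm$kp[1, "r_shoulder", 1:2])^2))
  expect_equal(d, 1)
})

test_that("normalised poses are invariant to image scaling and translation", {
  rec <- make_recording(10)
  moved <- rec
  moved$kp[, , "x"] <- rec$kp[, , "x"] * 3 + 7
  moved$kp[, , "y"] <- rec$kp[, , "y"] * 3 - 5
  a <- scale_normalise(rec)$kp[, , 1:2]
  b <- scale_normalise(moved)$kp[, , 1:2]
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("degenerate zero-width shoulders are refused", {
  rec <- make_recording(3, mod = function(kp) {
    kp[, "l_shoulder", c("x", "y")] <- kp[, "r_shoulder", c("x", "y")]; kp
  })
  expect_error(scale_normalise(rec), "shoulder width")
})

test_that("Savitzky-Golay smoothing is exact on cubics and gentle on 1 Hz motion", {
  # constants pass through untouched
  rec <- make_recording(40)
  expect_equal(smooth_recording(rec)$kp[, , 1:2], rec$kp[, , 1:2],
               tolerance = 1e-9)
  # an order-3 filter reproduces cubic trajectories everywhere
  tt <- seq(0, 1, length.out = 60)
  cubic <- 2 * tt^3 - tt^2 + 0.5 * tt - 0.2
  rec2 <- make_recording(60, mod = function(kp) {
    kp[, "r_wrist", "x"] <- kp[, "r_wrist", "x"] + cubic; kp
  })
  sm <- smooth_recording(rec2)
  expect_equal(unname(sm$kp[, "r_wrist", "x"]),
               unname(rec2$kp[, "r_wrist", "x"]), tolerance = 1e-9)
  # a 1 Hz sinusoid at 30 fps keeps its peak amplitude within 5 %
  t3 <- (0:119) / 30
  rec3 <- make_recording(120, mod = function(kp) {
    kp[, "r_wrist", "y"] <- 300 + 20 * sin(2 * pi * t3); kp
  })
  y <- smooth_recording(rec3)$kp[, "r_wrist", "y"]
  interior <- 20:100
  expect_lt(abs(max(y[interior]) - 320) / 20, 0.05)
  expect_lt(abs(min(y[interior]) - 280) / 20, 0.05)
  expect_error(smooth_recording(make_recording(10)), "at least")
})

test_that("wrist path distance sums frame-to-frame displacements", {
  still <- make_recording(10)
  expect_equal(wrist_path_distance(still, "left"), 0)
  # 1 unit per frame over 179 transitions
  rec <- make_recording(180, mod = function(kp) {
    kp[, "r_wrist", "x"] <- kp[, "r_wrist", "x"] + 0:179; kp
  })
  expect_equal(wrist_path_distance(rec, "right"), 179)
  # random walk equals an explicit loop oracle
  set.seed(99)
  rw <- make_recording(50, mod = function(kp) {
    kp[, "l_wrist", "x"] <- cumsum(rnorm(50))
    kp[, "l_wrist", "y"] <- cumsum(rnorm(50))
    kp
  })
  manual <- 0
  for (f in 1:49)
    manual <- manual + sqrt(sum((rw$kp[f + 1, "l_wrist", 1:2] -
                                 rw$kp[f, "l_wrist", 1:2])^2))
  expect_equal(wrist_path_distance(rw, "left"), manual)
})

test_that("dominant-hand orientation reflects once, idempotently, and matches mirrors", {
  move_wrist <- function(kp, nm, amp) {
    kp[, nm, "x"] <- kp[, nm, "x"] + amp * sin(seq_len(dim(kp)[1]) / 3); kp
  }
  right_dom <- scale_normalise(make_recording(60, mod = function(kp)
    move_wrist(kp, "r_wrist", 30)))$kp
  ori <- orient_dominant_right(right_dom)
  expect_false(ori$reflected)
  expect_equal(ori$kp, right_dom)
  left_dom <- scale_normalise(make_recording(60, mod = function(kp)
    move_wrist(kp, "l_wrist", 30)))$kp
  ori2 <- orient_dominant_right(left_dom)
  expect_true(ori2$reflected)
  expect_equal(ori2$dominant, "left")
  # idempotent: orienting an oriented sequence changes nothing
  ori3 <- orient_dominant_right(ori2$kp)
  expect_false(ori3$reflected)
  expect_equal(ori3$kp, ori2$kp)
  # a mirrored recording orients to the identical sequence
  mirror <- left_dom
  mirror[, , "x"] <- -mirror[, , "x"]
  mirror <- mirror[, handrep:::hm_swap_names(colnames(mirror)), ]
  dimnames(mirror)[[2]] <- handrep:::hm_swap_names(dimnames(mirror)[[2]])
  mirror <- mirror[, handrep:::hm_kp_names(), ]
  expect_equal(orient_dominant_right(mirror)$kp, ori2$kp)
})

test_that("re-centring puts the wrist midpoint at the origin and keeps 46 keypoints", {
  rec <- scale_normalise(make_recording(5, mod = function(kp) {
    kp[, "r_wrist", c("x", "y")] <- c(400, 320)
    kp[, "l_wrist", c("x", "y")] <- c(240, 280)
    kp
  }))
  ha <- recenter_hand_arm(rec$kp)
  expect_equal(dim(ha)[2], 46L)
  mid <- (ha[, "r_wrist", 1:2] + ha[, "l_wrist", 1:2]) / 2
  expect_equal(unname(mid), matrix(0, 5, 2), tolerance = 1e-12)
  # property over random frames
  set.seed(7)
  rnd <- make_recording(20, mod = function(kp) {
    kp[, , "x"] <- kp[, , "x"] + matrix(rnorm(20 * 50, sd = 5), 20)
    kp[, , "y"] <- kp[, , "y"] + matrix(rnorm(20 * 50, sd = 5), 20)
    kp
  })
  ha2 <- recenter_hand_arm(scale_normalise(rnd)$kp)
  mids <- (ha2[, "r_wrist", 1:2] + ha2[, "l_wrist", 1:2]) / 2
  expect_true(all(abs(mids) < 1e-12))
})

test_that("hand centroids are confidence-weighted means inside the keypoint hull", {
  hand <- cbind(x = runif(21, 0, 10), y = runif(21, 0, 10), c = rep(0.5, 21))
  expect_equal(hand_centroid(hand), c(mean(hand[, 1]), mean(hand[, 2])))
  hand2 <- hand; hand2[, "c"] <- 0; hand2[7, "c"] <- 1
  expect_equal(hand_centroid(hand2), unname(hand2[7, 1:2]))
  hand3 <- matrix(0, 21, 3); hand3[1, ] <- c(0, 0, 1); hand3[2, ] <- c(3, 3, 0.5)
  expect_equal(hand_centroid(hand3), c(1, 1))
  expect_warning(z <- hand_centroid(cbind(hand[, 1:2], c = 0)), "zero")
  expect_equal(z, c(mean(hand[, 1]), mean(hand[, 2])))
  # containment in the bounding box, per frame and hand
  rec <- generate_recording(subject_profile(4),
                            movement_spec("rub", 50, duration = 8, seed = 3))
  w <- quiet_windows(rec, 6, 0, 0.5)[[1]]
  cen <- w$centroids
  for (s in c("l", "r")) {
    xs <- w$kp[, paste0(s, "_hand_", 0:20), "x"]
    ys <- w$kp[, paste0(s, "_hand_", 0:20), "y"]
    expect_true(all(cen[, s, "x"] >= apply(xs, 1, min) - 1e-12 &
                    cen[, s, "x"] <= apply(xs, 1, max) + 1e-12))
    expect_true(all(cen[, s, "y"] >= apply(ys, 1, min) - 1e-12 &
                    cen[, s, "y"] <= apply(ys, 1, max) + 1e-12))
  }
})

test_that("windowing reproduces the study segmentations", {
  rec <- generate_recording(subject_profile(2),
                            movement_spec("clap", 50, duration = 30,
                                          noise_sd = 0, missing_prob = 0,
                                          jitter_sd = 0, seed = 5))
  proc <- preprocess_recording(rec)
  # 30 s, 6-s windows, no overlap, 3-s discards -> 4 windows of 180 frames
  w6 <- suppressWarnings(segment_windows(proc, 6, 0, 3))
  expect_length(w6, 4)
  expect_true(all(vapply(w6, function(w) w$end - w$start, numeric(1)) == 180))
  expect_equal(vapply(w6, `[[`, numeric(1), "start"), c(90, 270, 450, 630))
  # 30 s, 12-s windows shifted 5 s, 1.5-s discards -> 4 windows of 360
  w12 <- suppressWarnings(segment_windows(proc, 12, 7, 1.5))
  expect_length(w12, 4)
  expect_true(all(vapply(w12, function(w) w$end - w$start, numeric(1)) == 360))
  expect_equal(vapply(w12, `[[`, numeric(1), "start"), c(45, 195, 345, 495))
  # too-short recordings yield zero windows with a warning
  short <- preprocess_recording(
    generate_recording(subject_profile(2),
                       movement_spec("clap", 50, duration = 5, noise_sd = 0,
                                     missing_prob = 0, jitter_sd = 0, seed = 5)))
  expect_warning(w0 <- segment_windows(short, 6, 0, 0), "0 windows")
  expect_length(w0, 0)
})
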