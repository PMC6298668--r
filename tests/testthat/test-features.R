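test_that("summary statistics of 13-frame series follow their closed forms", {
  expect_equal(unname(summarize_series(rep(2.5, 13))), c(2.5, 0, 0, 2.5, 2.5))
  # arithmetic progression 12, 11, ..., 0
  expect_equal(unname(summarize_series(12:0)), c(0, -1, -1, 9, 3))
  # V shape symmetric about frame 7: rates mirror, means agree
  v <- c(6:0, 1:6)
  s <- summarize_series(v)
  expect_equal(s[["rate_pre"]], -s[["rate_post"]])
  expect_equal(s[["mean_pre"]], s[["mean_post"]])
  expect_error(summarize_series(1:10), "length 13")
})

test_that("reversing a series swaps the pre/post summaries", {
  set.seed(31)
  for (i in 1:20) {
    x <- runif(13, 0, 8)
    a <- summarize_series(x); b <- summarize_series(rev(x))
    expect_equal(a[["min"]], b[["min"]])
    expect_equal(a[["mean_pre"]], b[["mean_post"]])
    expect_equal(a[["mean_post"]], b[["mean_pre"]])
    expect_equal(a[["rate_pre"]], -b[["rate_post"]])
    expect_equal(a[["rate_post"]], -b[["rate_pre"]])
  }
})

test_that("distance series are Euclidean and accept goal and ball entities", {
  seq <- random_sequence(30, seed = 5, ball = TRUE)
  seq$pos[1, "o1", ] <- c(0, 0)
  seq$pos[1, "o2", ] <- c(3, 4)
  expect_equal(distance_series(seq, "o1", "o2", 1), 5)
  seq$pos[, "o3", ] <- seq$pos[, "o1", ]
  expect_equal(distance_series(seq, "o1", "o3", 1:30), rep(0, 30))
  g <- seq$court$goal
  seq$pos[2, "o1", ] <- g + c(0.6, 0.8)
  expect_equal(distance_series(seq, "o1", "goal", 2), 1)
  expect_error(distance_series(seq, "o1", "nobody", 1), "unknown")
})

test_that("three-player angles are interior angles at the screener vertex", {
  expect_equal(three_player_angle(c(1, 0), c(0, 0), c(0, 1)), 90)
  expect_equal(three_player_angle(c(1, 0), c(0, 0), c(-2, 0)), 180)
  expect_equal(three_player_angle(c(1, 0), c(0, 0), c(1, 1)), 45)
  expect_error(three_player_angle(c(0, 0), c(0, 0), c(1, 1)), "vertex")
})

test_that("screen areas form the configured 3x3 partition", {
  court <- court_spec()
  expect_equal(screen_area(c(0, 7), court), 5L)        # centre cell
  expect_equal(screen_area(c(-6.5, 0.5), court), 1L)   # baseline-left corner
  expect_equal(screen_area(c(6.5, 0.5), court), 3L)
  expect_equal(screen_area(c(0, 13), court), 8L)
  # two positions in the same cell share a code
  expect_equal(screen_area(c(3.1, 1.2), court), screen_area(c(6.9, 3.8), court))
  # positions outside the court map to the nearest area
  expect_equal(screen_area(c(-9, -2), court), 1L)
})

test_that("block and total dimensionalities are fixed", {
  seq <- random_sequence(80, seed = 6, ball = TRUE)
  a <- random_action(seq)
  expect_length(baseline_block(a, seq), 30L)
  expect_length(distance_block(a, seq), 45L)
  expect_length(moving_block(a, seq), 13L)
  expect_length(geometric_block(a, seq), 60L)
  full <- feature_vector(a, seq)
  expect_length(full, 148L)
  expect_false(anyNA(full))
  expect_false(anyDuplicated(names(full)) > 0)
  expect_length(feature_vector(a, seq, feature_config(baseline_only = TRUE)), 30L)
  expect_length(feature_vector(a, seq, feature_config(include_moving = FALSE)), 135L)
  expect_length(feature_vector(a, seq, feature_config(include_geometric = FALSE)), 88L)
})

test_that("stationary geometry produces zero distances and zero movement", {
  n <- 40
  roster <- data.frame(id = c(paste0("o", 1:5), paste0("d", 1:5)),
                       side = rep(c("offense", "defense"), each = 5))
  pos <- array(0, dim = c(n, 10, 2))
  spots <- rbind(c(0, 3), c(2, 3), c(-2, 3), c(5, 9), c(-5, 9),
                 c(0, 4.5), c(2, 4.5), c(-2, 4.5), c(5, 7), c(-5, 7))
  for (j in 1:10) pos[, j, ] <- matrix(spots[j, ], n, 2, byrow = TRUE)
  ball <- cbind(0, 3, 1)[rep(1, n), ]
  seq <- tracking_sequence((seq_len(n) - 1) / 25, roster, pos, ball = ball)
  a <- structure(data.frame(screener = "o1", user1 = "o2", user2 = "o3",
                            defender = "d1", min_frame = 20L, start = 7L,
                            end = 33L, onball = "on", label = NA, screen_type = NA,
                            stringsAsFactors = FALSE),
                 class = c("action_set", "data.frame"))
  bb <- baseline_block(a, seq)
  expect_true(all(bb[grep("change", names(bb))] == 0))
  expect_equal(unname(bb["base.scr_usr.min"]), unname(bb["base.scr_usr.mean_pre"]))
  expect_true(all(moving_block(a, seq) == 0))
  db <- distance_block(a, seq)
  expect_true(all(db[grep("rate", names(db))] == 0))
})

test_that("constant-speed motion yields the scripted path lengths", {
  n <- 40
  roster <- data.frame(id = c(paste0("o", 1:5), paste0("d", 1:5)),
                       side = rep(c("offense", "defense"), each = 5))
  pos <- array(0, dim = c(n, 10, 2))
  for (j in 1:10) pos[, j, 1] <- j - 5
  pos[, 1, 2] <- 0.1 * (seq_len(n) - 1)   # o1 moves 0.1 m/frame along y
  ball <- cbind(0, 5, 1)[rep(1, n), ]
  seq <- tracking_sequence((seq_len(n) - 1) / 25, roster, pos, ball = ball)
  a <- structure(data.frame(screener = "o1", user1 = "o2", user2 = "o3",
                            defender = "d1", min_frame = 14L, start = 1L,
                            end = 27L, onball = "off", label = NA, screen_type = NA,
                            stringsAsFactors = FALSE),
                 class = c("action_set", "data.frame"))
  mv <- moving_block(a, seq)
  expect_equal(unname(mv["mov.scr.total"]), 2.6)   # 26 intervals x 0.1 m
  expect_equal(unname(mv["mov.scr.pre"]), 1.3)
  expect_equal(unname(mv["mov.scr.post"]), 1.3)
  expect_equal(unname(mv["mov.ball.total"]), 0)
})

test_that("feature windows are edge-replicated at sequence boundaries", {
  seq <- random_sequence(30, seed = 8, ball = TRUE)
  a <- random_action(seq)
  a$min_frame <- 3L; a$start <- 1L; a$end <- 16L
  w <- feature_window(a, seq)
  expect_length(w, 13L)
  expect_equal(w[1:4], c(1L, 1L, 1L, 1L))   # replicated leading edge
  expect_length(distance_block(a, seq), 45L)
})

test_that("features match a naive per-frame recomputation on random actions", {
  for (s in 1:12) {
    seq <- random_sequence(70, seed = 700 + s, ball = TRUE)
    a <- random_action(seq)
    got <- feature_vector(a, seq)
    want <- brute_feature_vector(a, seq)
    expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("non-area features are invariant under rigid motions", {
  for (s in 1:6) {
    seq <- random_sequence(70, seed = 900 + s, ball = TRUE)
    a <- random_action(seq)
    moved <- rigid_transform(seq, theta = 0.35 + 0.3 * s, shift = c(2.5, -1.5))
    f1 <- feature_vector(a, seq)
    f2 <- feature_vector(a, moved)
    keep <- !grepl("^geo\\.area", names(f1))
    expect_equal(f1[keep], f2[keep], tolerance = 1e-9)
    # the area one-hot is court-anchored and stays a valid one-hot
    expect_equal(sum(f2[grepl("^geo\\.area", names(f2))]), 1)
  }
})

test_that("feature matrices round trip through delimited text with metadata", {
  seq <- random_sequence(60, seed = 44, ball = TRUE)
  acts <- do.call(rbind, list(random_action(seq), random_action(seq)))
  class(acts) <- c("action_set", "data.frame")
  x <- build_feature_matrix(acts, seq)
  expect_equal(dim(x), c(2L, 148L))
  path <- tempfile(fileext = ".csv")
  write_features(x, acts, path)
  back <- read_features(path)
  expect_equal(unname(back$features), unname(x), tolerance = 1e-6)
  expect_identical(back$actions$screener, acts$screener)
  unlink(path)
})
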