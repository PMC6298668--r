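# hand-built sequence: all players parked far apart, except a screener (o1)
# whose distance to defender d1 dips below 1.2 m for `dip_frames` frames,
# while d1 guards user o2 at 1.3 m (d1 stays the closest player to o2, and
# the o2-d1 pair itself stays above the contact threshold)
planted_approach <- function(n = 60, dip_frames = 5, dip_at = 30) {
  roster <- data.frame(id = c(paste0("o", 1:5), paste0("d", 1:5)),
                       side = rep(c("offense", "defense"), each = 5))
  pos <- array(0, dim = c(n, 10, 2))
  spots <- rbind(c(0, 8), c(1.3, 5), c(-6, 12), c(6, 12), c(0, 13),   # o1..o5
                 c(0, 5), c(-4, 9), c(4, 9), c(-6, 8), c(6, 8))       # d1..d5
  for (j in 1:10) pos[, j, ] <- matrix(spots[j, ], n, 2, byrow = TRUE)
  # o1 walks down the y axis toward d1 at (0,5); its distance is d_series
  d_series <- rep(3, n)
  if (dip_frames > 0) d_series[dip_at + seq_len(dip_frames) - 1] <- 1.0
  d_series[dip_at - 1] <- 1.3
  d_series[dip_at + max(dip_frames, 1)] <- 1.3
  pos[, 1, 2] <- 5 + d_series
  tracking_sequence((seq_len(n) - 1) / 25, roster, pos)
}

test_that("signals require both conditions and a minimum run length", {
  # condition (1) fails: never below 1.2 m
  expect_equal(nrow(find_signals(planted_approach(dip_frames = 0))), 0L)
  # 2-frame contact is excluded
  expect_equal(nrow(find_signals(planted_approach(dip_frames = 2))), 0L)
  # 5-frame contact yields one signal of length 5 for the planted triple
  sig <- find_signals(planted_approach(dip_frames = 5))
  expect_equal(nrow(sig), 1L)
  expect_identical(sig$screener, "o1")
  expect_identical(sig$user, "o2")
  expect_identical(sig$defender, "d1")
  expect_equal(sig$last - sig$first + 1L, 5L)
})

test_that("condition (2) gates on the defender being closest to the user", {
  seq <- planted_approach(dip_frames = 5)
  # park another offense player on top of the user: d1 no longer closest to o2
  seq$pos[, 3, 1] <- 1.5; seq$pos[, 3, 2] <- 5
  sig <- find_signals(seq)
  expect_false(any(sig$screener == "o1" & sig$user == "o2" & sig$defender == "d1"))
})

test_that("candidate enumeration picks nearest users and defenders deterministically", {
  seq <- planted_approach(dip_frames = 5)
  cand <- enumerate_candidates(seq, 30)
  expect_length(cand, 5L)
  expect_identical(names(cand), paste0("o", 1:5))
  # brute-force nearest neighbours for o1 at frame 30
  xy <- seq$pos[30, , ]
  rownames(xy) <- seq$players$id
  d1 <- sqrt(rowSums(sweep(xy, 2, xy["o1", ])^2))
  expect_identical(cand$o1$users, names(sort(d1[paste0("o", 2:5)]))[1:2])
  expect_true(all(cand$o1$defenders %in% paste0("d", 1:5)))
  expect_length(unique(cand$o1$defenders), 3L)
  # an exact tie between two offense players resolves to the lower id:
  # o3 and o4 coincide, so o3 must take the slot
  seq$pos[, 3, 1] <- 4; seq$pos[, 3, 2] <- 6
  seq$pos[, 4, ] <- seq$pos[, 3, ]          # o4 coincides with o3
  cand <- enumerate_candidates(seq, 30)
  expect_identical(cand$o2$users, c("o1", "o3"))
})

test_that("adjacent same-identity signals are joined; distant ones are not", {
  # second dip for the same (o1, d1) identity, 5 frames after the first ends
  seq2 <- planted_approach(n = 120, dip_frames = 5, dip_at = 30)
  seq2$pos[40:44, 1, 2] <- 6.0
  seq2$pos[39, 1, 2] <- 6.3; seq2$pos[45, 1, 2] <- 6.3
  acts <- segment_actions(seq2)
  expect_equal(nrow(acts), 1L)      # gap of 5 <= join_gap: merged
  expect_equal(acts$min_frame, 30L) # earliest frame of the tied minima
  # move the second dip 40 frames later: two separate actions
  seq3 <- planted_approach(n = 120, dip_frames = 5, dip_at = 20)
  seq3$pos[80:84, 1, 2] <- 6.0
  seq3$pos[79, 1, 2] <- 6.3; seq3$pos[85, 1, 2] <- 6.3
  acts <- segment_actions(seq3)
  expect_equal(nrow(acts), 2L)
})

test_that("action windows are clipped at sequence boundaries", {
  seq <- planted_approach(n = 40, dip_frames = 5, dip_at = 3)
  acts <- segment_actions(seq)
  expect_equal(acts$start[1], 1L)
  expect_true(acts$min_frame[1] - 13L < 1L)
  expect_equal(acts$end[1], acts$min_frame[1] + 13L)
})

test_that("empty signal sets build empty action sets", {
  seq <- planted_approach(dip_frames = 0)
  acts <- build_actions(find_signals(seq), seq)
  expect_s3_class(acts, "action_set")
  expect_equal(nrow(acts), 0L)
})

test_that("on/off-ball classification follows possession at the minimum frame", {
  seq <- planted_approach(dip_frames = 5)
  a <- segment_actions(seq)[1, ]
  mf <- a$min_frame
  with_ball_at <- function(id) {
    s <- seq
    s$ball <- matrix(NA_real_, n_frames(s), 3)
    s$ball[mf, ] <- c(s$pos[mf, id, ], 1)
    s
  }
  expect_identical(classify_onball(a, with_ball_at(a$screener)), "on")
  expect_identical(classify_onball(a, with_ball_at(a$user1)), "on")
  outsider <- setdiff(paste0("o", 1:5), c(a$screener, a$user1, a$user2))[1]
  expect_identical(classify_onball(a, with_ball_at(outsider)), "off")
  # nobody possesses: ball far from every player
  s <- seq
  s$ball <- matrix(NA_real_, n_frames(s), 3)
  s$ball[mf, ] <- c(-7, 0.5, 1)
  expect_identical(classify_onball(a, s), "off")
  # absent ball is an error
  s$ball[mf, ] <- NA_real_
  expect_error(classify_onball(a, s), "absent")
})

test_that("segmentation equals the brute-force oracle on random sequences", {
  for (s in 1:8)
    expect_segmentation_matches_oracle(random_sequence(80, seed = 400 + s))
})

test_that("segmentation is deterministic and invariant under rigid motions", {
  seq <- random_sequence(120, seed = 77)
  a1 <- segment_actions(seq)
  a2 <- segment_actions(seq)
  expect_identical(a1, a2)
  moved <- rigid_transform(seq, theta = 1.1, shift = c(-4, 6))
  a3 <- segment_actions(moved)
  cols <- c("screener", "user1", "user2", "defender", "min_frame", "start", "end")
  expect_identical(a1[, cols], a3[, cols])
})

test_that("action tables survive a write/read round trip", {
  seq <- planted_approach(dip_frames = 5)
  acts <- segment_actions(seq)
  path <- tempfile(fileext = ".csv")
  write_actions(acts, path)
  back <- read_actions(path)
  expect_equal(as.data.frame(back), as.data.frame(acts))
  unlink(path)
})
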