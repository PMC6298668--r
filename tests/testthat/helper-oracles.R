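# Independent brute-force oracles and fixture builders. These deliberately
# use plain per-frame loops and closed-form arithmetic, not the package's
# vectorized code paths.

# random 5v5 sequence: smooth clamped random walks, optional ball walk
random_sequence <- function(n = 120, seed = NULL, ball = FALSE,
                            court = court_spec()) {
  if (!is.null(seed)) set.seed(seed)
  roster <- data.frame(id = c(paste0("o", 1:5), paste0("d", 1:5)),
                       side = rep(c("offense", "defense"), each = 5),
                       stringsAsFactors = FALSE)
  pos <- array(NA_real_, dim = c(n, 10L, 2L))
  for (j in 1:10) {
    start <- c(runif(1, -6.5, 6.5), runif(1, 0.5, 13.5))
    steps <- matrix(rnorm(2 * n, 0, 0.12), ncol = 2)
    p <- sweep(apply(steps, 2, cumsum), 2, start, "+")
    p[, 1] <- pmin(pmax(p[, 1], -7.4), 7.4)
    p[, 2] <- pmin(pmax(p[, 2], 0.1), 13.9)
    pos[, j, ] <- p
  }
  bl <- NULL
  if (ball) {
    b <- cbind(cumsum(rnorm(n, 0, 0.2)) + runif(1, -4, 4),
               cumsum(rnorm(n, 0, 0.2)) + runif(1, 2, 11),
               pmax(0.1, 1 + cumsum(rnorm(n, 0, 0.05))))
    b[, 1] <- pmin(pmax(b[, 1], -7.4), 7.4)
    b[, 2] <- pmin(pmax(b[, 2], 0.1), 13.9)
    bl <- b
  }
  tracking_sequence(time = (seq_len(n) - 1) / court$fps, players = roster,
                    pos = pos, ball = bl, court = court)
}

# apply a rigid motion (rotation by theta then translation) to all player
# positions, the ball XY and the goal; bypasses the court validator on
# purpose (the transformed frame is no longer court-aligned)
rigid_transform <- function(seq, theta, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  tr <- function(m) sweep(m %*% t(R), 2, shift, "+")
  out <- seq
  for (j in seq_len(dim(seq$pos)[2]))
    out$pos[, j, ] <- tr(matrix(seq$pos[, j, ], ncol = 2))
  if (!is.null(seq$ball)) {
    pres <- !is.na(seq$ball[, 1])
    out$ball[pres, 1:2] <- tr(seq$ball[pres, 1:2, drop = FALSE])
  }
  out$court$goal <- as.numeric(tr(matrix(seq$court$goal, 1, 2)))
  out
}

# --- segmentation oracle: literal per-frame rule checking ----------------

brute_find_signals <- function(seq, cfg = segmentation_config()) {
  off <- sort(player_ids(seq, "offense"))
  def <- sort(player_ids(seq, "defense"))
  all_ids <- sort(seq$players$id)
  n <- n_frames(seq)
  d_at <- function(f, a, b) sqrt(sum((seq$pos[f, a, ] - seq$pos[f, b, ])^2))
  rows <- list()
  for (s in off) for (u in setdiff(off, s)) for (d in def) {
    run_start <- NA
    flush <- function(first, last) {
      if (!is.na(first) && last - first + 1L >= cfg$min_signal_frames)
        rows[[length(rows) + 1L]] <<- data.frame(
          screener = s, user = u, defender = d, first = first, last = last,
          stringsAsFactors = FALSE)
    }
    for (f in seq_len(n)) {
      cond1 <- d_at(f, s, d) < cfg$contact_threshold
      pool <- if (cfg$condition2_scope == "all") setdiff(all_ids, u) else def
      dd <- vapply(pool, function(p) d_at(f, u, p), numeric(1))
      cond2 <- pool[which.min(dd)] == d
      if (cond1 && cond2) {
        if (is.na(run_start)) run_start <- f
      } else if (!is.na(run_start)) {
        flush(run_start, f - 1L); run_start <- NA
      }
    }
    flush(run_start, n)
  }
  if (!length(rows))
    return(data.frame(screener = character(), user = character(),
                      defender = character(), first = integer(),
                      last = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$screener, out$user, out$defender, out$first), , drop = FALSE]
}

brute_build_actions <- function(signals, seq, cfg = segmentation_config()) {
  n <- n_frames(seq)
  out <- list()
  if (nrow(signals) == 0L) return(out)
  for (k in sort(unique(paste(signals$screener, signals$defender)))) {
    parts <- strsplit(k, " ")[[1]]
    s <- parts[1]; d <- parts[2]
    sub <- signals[signals$screener == s & signals$defender == d, , drop = FALSE]
    covered <- rep(FALSE, n)
    for (i in seq_len(nrow(sub))) covered[sub$first[i]:sub$last[i]] <- TRUE
    # join runs whose gap <= join_gap by scanning
    f <- 1L
    while (f <= n) {
      if (!covered[f]) { f <- f + 1L; next }
      last <- f
      g <- f + 1L
      while (g <= n) {
        if (covered[g]) { last <- g; g <- g + 1L }
        else {
          nxt <- g
          while (nxt <= n && !covered[nxt]) nxt <- nxt + 1L
          if (nxt <= n && (nxt - last - 1L) <= cfg$join_gap) { g <- nxt }
          else break
        }
      }
      span <- f:last
      dists <- vapply(span, function(ff)
        sqrt(sum((seq$pos[ff, s, ] - seq$pos[ff, d, ])^2)), numeric(1))
      mf <- span[which.min(dists)]
      out[[length(out) + 1L]] <- list(
        screener = s, defender = d, min_frame = mf,
        start = max(1L, mf - cfg$action_halfwindow),
        end = min(n, mf + cfg$action_halfwindow))
      f <- last + 1L
    }
  }
  out
}

# compare package segmentation to the brute-force oracle on one sequence
expect_segmentation_matches_oracle <- function(seq, cfg = segmentation_config()) {
  sig <- find_signals(seq, cfg)
  sig_o <- brute_find_signals(seq, cfg)
  rownames(sig) <- rownames(sig_o) <- NULL
  expect_equal(sig, sig_o)
  acts <- build_actions(sig, seq, cfg)
  acts_o <- brute_build_actions(sig_o, seq, cfg)
  expect_equal(nrow(acts), length(acts_o))
  if (nrow(acts) > 0L) {
    key <- function(s, d, m, a, b) paste(s, d, m, a, b)
    got <- sort(key(acts$screener, acts$defender, acts$min_frame,
                    acts$start, acts$end))
    want <- sort(vapply(acts_o, function(x)
      key(x$screener, x$defender, x$min_frame, x$start, x$end), character(1)))
    expect_identical(got, want)
  }
}

# --- AUC oracle: pairwise mid-rank statistic -----------------------------

rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)             # mid-ranks on ties
  np <- sum(labels); nn <- sum(!labels)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

# --- feature oracle: naive per-frame recomputation -----------------------

brute_feature_vector <- function(action, seq, partition = area_partition()) {
  d2 <- function(p, q) sqrt(sum((p - q)^2))
  at <- function(f, id) {
    if (identical(id, "goal")) seq$court$goal
    else if (identical(id, "ball")) seq$ball[f, 1:2]
    else seq$pos[f, id, ]
  }
  win <- action$start:action$end
  mf <- action$min_frame
  # primary user by minimum screener distance over the window
  m1 <- min(vapply(win, function(f) d2(at(f, action$screener), at(f, action$user1)), numeric(1)))
  m2 <- min(vapply(win, function(f) d2(at(f, action$screener), at(f, action$user2)), numeric(1)))
  pu <- if (m2 < m1) action$user2 else if (m1 < m2) action$user1 else
    sort(c(action$user1, action$user2))[1]
  ents <- c(action$screener, pu, action$defender, "goal")
  base <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    dd <- vapply(win, function(f) d2(at(f, ents[i]), at(f, ents[j])), numeric(1))
    pre <- 1:(mf - action$start + 1); post <- (mf - action$start + 1):length(win)
    base <- c(base, min(dd), mean(dd[pre]), dd[max(pre)] - dd[1],
              mean(dd[post]), dd[length(dd)] - dd[min(post)])
  }
  fw <- pmin(pmax(mf + (-6:6), 1), n_frames(seq))
  summ <- function(s) c(min(s), (s[7] - s[1]) / 6, (s[13] - s[7]) / 6,
                        mean(s[1:7]), mean(s[7:13]))
  series <- function(a, b) vapply(fw, function(f) d2(at(f, a), at(f, b)), numeric(1))
  pairs <- list(c(action$screener, action$defender),
                c(action$screener, action$user1),
                c(action$screener, action$user2),
                c(action$defender, action$user1),
                c(action$defender, action$user2),
                c("goal", action$screener), c("goal", action$user1),
                c("goal", action$user2), c("goal", action$defender))
  distb <- unlist(lapply(pairs, function(p) summ(series(p[1], p[2]))))
  path <- function(id, fr) {
    if (length(fr) < 2) return(0)
    sum(vapply(seq_len(length(fr) - 1), function(i)
      d2(at(fr[i], id), at(fr[i + 1], id)), numeric(1)))
  }
  four <- c(action$screener, action$defender, action$user1, action$user2)
  mov <- c(vapply(four, path, numeric(1), fr = win),
           vapply(four, path, numeric(1), fr = action$start:mf),
           vapply(four, path, numeric(1), fr = mf:action$end),
           path("ball", win))
  area <- screen_area(seq$pos[mf, action$screener, ], seq$court, partition)
  geo <- as.numeric(1:9 == area)
  for (id in four) geo <- c(geo, summ(series(id, "ball")))
  ang <- function(a, v, b, f) {
    v1 <- at(f, a) - at(f, v); v2 <- at(f, b) - at(f, v)
    acos(min(1, max(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  }
  for (u in c(action$user1, action$user2)) {
    geo <- c(geo, summ(vapply(fw, function(f) ang(u, action$screener, action$defender, f), numeric(1))))
    geo <- c(geo, summ(vapply(fw, function(f) ang(action$screener, u, action$defender, f), numeric(1))))
    geo <- c(geo, summ(vapply(fw, function(f) ang(action$screener, action$defender, u, f), numeric(1))))
  }
  geo <- c(geo, d2(at(mf, "ball"), seq$court$goal))
  c(base, distb, mov, geo)
}

# a random action over a random ball-carrying sequence
random_action <- function(seq) {
  n <- n_frames(seq)
  mf <- sample(14:(n - 14), 1)
  off <- sample(player_ids(seq, "offense"))
  structure(data.frame(screener = off[1], user1 = off[2], user2 = off[3],
                       defender = sample(player_ids(seq, "defense"), 1),
                       min_frame = mf, start = mf - 13L, end = mf + 13L,
                       onball = "off", label = NA_character_,
                       screen_type = NA_character_, stringsAsFactors = FALSE),
            class = c("action_set", "data.frame"))
}

# small separable two-cloud problem
two_clouds <- function(n = 60, d = 5, sep = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * d), n, d),
             matrix(rnorm(n * d, mean = sep), n, d))
  y <- rep(c("neg", "pos"), each = n)
  list(x = x, y = y)
}

fast_svm_config <- function() svm_config(cost_grid = 10, width_grid = 1, cv_folds = 2)
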