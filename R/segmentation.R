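#' Segmentation configuration
#'
#' Parameters of the rule-based candidate segmentation. All frame counts are
#' in frames at the sequence's own rate; the defaults correspond to a 25 fps
#' feed: a screener/user-defender contact is a frame where their distance
#' falls below 1.2 m, runs shorter than 3 frames are discarded, and the
#' action window spans 13 frames either side of the minimum-distance frame.
#'
#' @param contact_threshold screener to user-defender contact distance (m).
#' @param min_signal_frames minimum run length of a signal (frames).
#' @param action_halfwindow half-width of the action window (frames).
#' @param join_gap maximum gap for joining same-identity signals (frames).
#' @param feature_halfwindow half-width of the 13-frame feature window.
#' @param condition2_scope `"all"` (the user-defender must be the closest of
#'   all other players to the candidate user) or `"defense"` (closest
#'   defender only).
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(contact_threshold = 1.2, min_signal_frames = 3L,
                                action_halfwindow = 13L, join_gap = 13L,
                                feature_halfwindow = 6L,
                                condition2_scope = c("all", "defense")) {
  condition2_scope <- match.arg(condition2_scope)
  stopifnot(contact_threshold > 0, min_signal_frames >= 1,
            action_halfwindow >= 1, join_gap >= 0, feature_halfwindow >= 1,
            feature_halfwindow <= action_halfwindow)
  structure(list(contact_threshold = contact_threshold,
                 min_signal_frames = as.integer(min_signal_frames),
                 action_halfwindow = as.integer(action_halfwindow),
                 join_gap = as.integer(join_gap),
                 feature_halfwindow = as.integer(feature_halfwindow),
                 condition2_scope = condition2_scope),
            class = "segmentation_config")
}

#' Candidate screeners, users and defenders at a frame
#'
#' Every offense player is a candidate screener; for each, the two other
#' offense players nearest the screener are the candidate users, and three
#' defenders are attached: the nearest defender to the screener and to each
#' candidate user, de-duplicated in that order and topped up by proximity to
#' the screener. All ties break to the smaller player id.
#'
#' @param seq a `tracking_sequence`.
#' @param frame frame index.
#' @return a list with one element per offense player (named by screener id),
#'   each a list with `screener`, `users` (2 ids) and `defenders` (3 ids).
#' @export
enumerate_candidates <- function(seq, frame) {
  stopifnot(inherits(seq, "tracking_sequence"))
  if (frame < 1L || frame > n_frames(seq)) stop("frame out of range")
  off <- sort(player_ids(seq, "offense"))
  def <- sort(player_ids(seq, "defense"))
  if (length(off) < 3L || length(def) < 3L)
    stop("need at least 3 offense and 3 defense players")
  xy <- seq$pos[frame, , , drop = TRUE]  # players x 2
  dist2 <- function(a, b) sqrt(sum((xy[a, ] - xy[b, ])^2))
  nearest <- function(from, pool, k = 1L) {
    d <- vapply(pool, dist2, numeric(1), a = from)
    pool[order(d, pool)][seq_len(k)]
  }
  out <- lapply(off, function(s) {
    users <- nearest(s, setdiff(off, s), 2L)
    defs <- c(nearest(s, def), nearest(users[1], def), nearest(users[2], def))
    defs <- unique(defs)
    if (length(defs) < 3L)
      defs <- c(defs, nearest(s, setdiff(def, defs), 3L - length(defs)))
    list(screener = s, users = users, defenders = defs)
  })
  stats::setNames(out, off)
}

# distance matrix helpers over all frames ------------------------------

pair_dist_series <- function(seq, a, b) {
  sqrt((seq$pos[, a, 1] - seq$pos[, b, 1])^2 + (seq$pos[, a, 2] - seq$pos[, b, 2])^2)
}

# for each frame, the id of the player closest to `u` among `pool`
# (ties to the smaller id; pool must be sorted)
closest_to <- function(seq, u, pool) {
  d <- vapply(pool, function(p) pair_dist_series(seq, u, p), numeric(n_frames(seq)))
  d <- matrix(d, nrow = n_frames(seq))
  pool[max.col(-d, ties.method = "first")]
}

#' Find screen-play signals
#'
#' A signal frame for an ordered triple (screener, user, user-defender) is a
#' frame satisfying both segmentation conditions: (1) the screener to
#' user-defender distance is below `contact_threshold`, and (2) the
#' user-defender is the player closest to the candidate user. Contiguous runs
#' per triple become signals; runs shorter than `min_signal_frames` are
#' discarded.
#'
#' @param seq a `tracking_sequence` with full 5v5 rosters (at least 3 per side).
#' @param cfg a [segmentation_config()].
#' @return data.frame with columns `screener`, `user`, `defender`, `first`,
#'   `last` (frame indices), ordered by screener, user, defender, first.
#' @export
find_signals <- function(seq, cfg = segmentation_config()) {
  stopifnot(inherits(seq, "tracking_sequence"), inherits(cfg, "segmentation_config"))
  off <- sort(player_ids(seq, "offense"))
  def <- sort(player_ids(seq, "defense"))
  if (length(off) < 3L || length(def) < 3L)
    stop("need at least 3 offense and 3 defense players")
  n <- n_frames(seq)
  # condition (1): per (screener, defender) pair
  cond1 <- list()
  for (s in off) for (d in def)
    cond1[[paste(s, d)]] <- pair_dist_series(seq, s, d) < cfg$contact_threshold
  # condition (2): nearest player to each candidate user
  all_ids <- sort(seq$players$id)
  nearest_id <- lapply(stats::setNames(off, off), function(u) {
    pool <- if (cfg$condition2_scope == "all") setdiff(all_ids, u) else def
    closest_to(seq, u, pool)
  })
  rows <- list()
  for (s in off) for (u in setdiff(off, s)) {
    c2 <- nearest_id[[u]]
    for (d in def) {
      active <- cond1[[paste(s, d)]] & (c2 == d)
      if (!any(active)) next
      r <- rle(active)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= cfg$min_signal_frames
      if (any(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          screener = s, user = u, defender = d,
          first = starts[keep], last = ends[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(screener = character(), user = character(),
                      defender = character(), first = integer(),
                      last = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$screener, out$user, out$defender, out$first), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build candidate actions from signals
#'
#' Signals sharing a (screener, user-defender) identity are merged when the
#' gap between them is at most `join_gap` frames ("temporarily adjacent same
#' actions are joined"). Each merged span yields one action: `min_frame` is
#' the frame of minimum screener/defender distance over the span (earliest on
#' ties), the window is `min_frame` plus/minus `action_halfwindow` clipped to
#' the sequence, the two candidate users are attached from
#' [enumerate_candidates()] at `min_frame`, and the action is flagged on- or
#' off-ball from possession at `min_frame` (NA when the ball is absent
#' there).
#'
#' @param signals data.frame as returned by [find_signals()].
#' @param seq the originating `tracking_sequence`.
#' @param cfg a [segmentation_config()].
#' @return data.frame of class `action_set` with columns `screener`, `user1`,
#'   `user2`, `defender`, `min_frame`, `start`, `end`, `onball`, `label`,
#'   `screen_type`.
#' @export
build_actions <- function(signals, seq, cfg = segmentation_config()) {
  stopifnot(inherits(seq, "tracking_sequence"))
  empty <- data.frame(screener = character(), user1 = character(),
                      user2 = character(), defender = character(),
                      min_frame = integer(), start = integer(), end = integer(),
                      onball = character(), label = character(),
                      screen_type = character(), stringsAsFactors = FALSE)
  class(empty) <- c("action_set", "data.frame")
  if (is.null(signals) || nrow(signals) == 0L) return(empty)
  n <- n_frames(seq)
  key <- paste(signals$screener, signals$defender, sep = "\r")
  rows <- list()
  for (k in sort(unique(key))) {
    sub <- signals[key == k, , drop = FALSE]
    sub <- sub[order(sub$first, sub$last), , drop = FALSE]
    # merge intervals whose gap <= join_gap
    spans <- list(c(sub$first[1], sub$last[1]))
    for (i in seq_len(nrow(sub))[-1]) {
      cur <- spans[[length(spans)]]
      gap <- sub$first[i] - cur[2] - 1L
      if (gap <= cfg$join_gap) {
        spans[[length(spans)]][2] <- max(cur[2], sub$last[i])
      } else {
        spans[[length(spans) + 1L]] <- c(sub$first[i], sub$last[i])
      }
    }
    s <- sub$screener[1]; d <- sub$defender[1]
    dist_sd <- pair_dist_series(seq, s, d)
    for (sp in spans) {
      span_frames <- sp[1]:sp[2]
      mf <- span_frames[which.min(dist_sd[span_frames])]
      cand <- enumerate_candidates(seq, mf)[[s]]
      start <- max(1L, mf - cfg$action_halfwindow)
      end <- min(n, mf + cfg$action_halfwindow)
      rows[[length(rows) + 1L]] <- data.frame(
        screener = s, user1 = cand$users[1], user2 = cand$users[2],
        defender = d, min_frame = mf, start = start, end = end,
        onball = NA_character_, label = NA_character_,
        screen_type = NA_character_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$min_frame, out$screener, out$defender), , drop = FALSE]
  rownames(out) <- NULL
  ok <- ball_present(seq, out$min_frame)
  for (i in which(ok))
    out$onball[i] <- classify_onball(out[i, ], seq)
  class(out) <- c("action_set", "data.frame")
  out
}

#' On-ball / off-ball classification of an action
#'
#' An action is off-ball when neither the screener nor either candidate user
#' possesses the ball at the minimum-distance frame (including when nobody
#' does); otherwise it is on-ball.
#'
#' @param action a single-row action (from [build_actions()]).
#' @param seq the originating `tracking_sequence`.
#' @return `"on"` or `"off"`.
#' @export
classify_onball <- function(action, seq) {
  stopifnot(nrow(action) == 1L)
  p <- possessor(seq, action$min_frame)
  if (!is.na(p) && p %in% c(action$screener, action$user1, action$user2)) "on" else "off"
}

#' Run the full segmentation stage
#'
#' Convenience wrapper: [find_signals()] then [build_actions()].
#'
#' @inheritParams find_signals
#' @return an `action_set` data.frame.
#' @export
segment_actions <- function(seq, cfg = segmentation_config()) {
  build_actions(find_signals(seq, cfg), seq, cfg)
}

#' Write / read an action table
#'
#' Delimited-text export of an `action_set` (one row per action).
#' @param actions an `action_set`.
#' @param path file path.
#' @return `path` (write) or the `action_set` (read).
#' @export
write_actions <- function(actions, path) {
  utils::write.table(as.data.frame(actions), path, sep = ",",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_actions
#' @export
read_actions <- function(path) {
  if (!file.exists(path)) stop("actions file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = ",", na.strings = "",
                          colClasses = c(screener = "character", user1 = "character",
                                         user2 = "character", defender = "character",
                                         min_frame = "integer", start = "integer",
                                         end = "integer", onball = "character",
                                         label = "character", screen_type = "character"),
                          stringsAsFactors = FALSE)
  class(df) <- c("action_set", "data.frame")
  df
}
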