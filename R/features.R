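#' Feature configuration
#'
#' Controls the blocks assembled by [feature_vector()]: the full descriptor
#' concatenates the 30-dim conventional baseline block, the 45-dim expanded
#' distance block, the 13-dim moving-distance block and the 60-dim geometric
#' block (148 dims in total). The moving and geometric blocks can be ablated,
#' or the descriptor reduced to the baseline block alone, to reproduce the
#' with/without comparisons against the conventional method.
#'
#' @param include_moving include the 13-dim moving-distance block.
#' @param include_geometric include the 60-dim geometric block.
#' @param baseline_only emit only the 30-dim conventional block.
#' @param partition an [area_partition()] for the screen-area one-hot.
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(include_moving = TRUE, include_geometric = TRUE,
                           baseline_only = FALSE, partition = area_partition()) {
  structure(list(include_moving = isTRUE(include_moving),
                 include_geometric = isTRUE(include_geometric),
                 baseline_only = isTRUE(baseline_only),
                 partition = partition),
            class = "feature_config")
}

#' Court partition for the screen-area feature
#'
#' A 3x3 grid over the half court with a deliberately narrow middle column,
#' because screens cluster laterally near the lane: columns split at
#' `x = -2.5` and `x = +2.5` m, rows at `y = 4` and `y = 9` m. Area codes run
#' 1..9, row-major from the baseline-left cell.
#'
#' @param x_breaks two increasing lateral split points (m).
#' @param y_breaks two increasing depth split points (m).
#' @return an object of class `area_partition`.
#' @export
area_partition <- function(x_breaks = c(-2.5, 2.5), y_breaks = c(4, 9)) {
  stopifnot(length(x_breaks) == 2L, length(y_breaks) == 2L,
            diff(x_breaks) > 0, diff(y_breaks) > 0)
  structure(list(x_breaks = as.numeric(x_breaks), y_breaks = as.numeric(y_breaks)),
            class = "area_partition")
}

#' Screen-area code of a court position
#'
#' @param position numeric length-2 court XY (m); positions outside the court
#'   fall in the nearest area.
#' @param court a [court_spec()] (unused by the default grid but kept so
#'   custom partitions can be court-relative).
#' @param partition an [area_partition()].
#' @return integer area code in 1..9.
#' @export
screen_area <- function(position, court = court_spec(), partition = area_partition()) {
  stopifnot(is.numeric(position), length(position) == 2L)
  col <- findInterval(position[1], partition$x_breaks) + 1L
  row <- findInterval(position[2], partition$y_breaks) + 1L
  (row - 1L) * 3L + col
}

#' Interior angle at the screener (or any vertex)
#'
#' Angle in degrees, in `[0, 180]`, at `screener` between the rays to `user`
#' and `defender`.
#'
#' @param user,screener,defender numeric length-2 court XY points; the vertex
#'   must be distinct from both rays' endpoints.
#' @return angle in degrees.
#' @export
three_player_angle <- function(user, screener, defender) {
  v1 <- user - screener; v2 <- defender - screener
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("degenerate angle: a point coincides with the vertex")
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' The 13-frame feature window of an action
#'
#' Frame indices `min_frame - hw .. min_frame + hw` (hw = 6 by default),
#' clamped to the sequence bounds so boundary windows are edge-replicated and
#' every window has fixed length.
#'
#' @param action single-row action.
#' @param seq the `tracking_sequence`.
#' @param halfwindow feature half-window in frames.
#' @return integer vector of length `2 * halfwindow + 1`.
#' @export
feature_window <- function(action, seq, halfwindow = 6L) {
  pmin(pmax(action$min_frame + (-halfwindow:halfwindow), 1L), n_frames(seq))
}

#' Distance series between two entities
#'
#' Per-frame Euclidean distance in the court plane between two entities over
#' a window of frames. Entities are player ids, `"goal"` or `"ball"` (the
#' ball uses its XY projection).
#'
#' @param seq a `tracking_sequence`.
#' @param a,b entity identifiers.
#' @param window integer frame indices.
#' @return numeric vector of distances (m), one per window frame.
#' @export
distance_series <- function(seq, a, b, window) {
  pa <- entity_xy(seq, a, window)
  pb <- entity_xy(seq, b, window)
  sqrt(rowSums((pa - pb)^2))
}

#' Five summary statistics of a 13-frame distance series
#'
#' The former seven frames are 1..7 and the latter seven are 7..13 (frame 7,
#' the minimum-distance frame, is shared). Returns the minimum amplitude over
#' all 13 frames, the average rate of change over each half (endpoint
#' difference per frame, i.e. divided by the 6 intervals) and the mean
#' amplitude over each half.
#'
#' @param series numeric vector of length 13.
#' @return named numeric: `min`, `rate_pre`, `rate_post`, `mean_pre`,
#'   `mean_post`.
#' @export
summarize_series <- function(series) {
  if (length(series) != 13L) stop("series must have length 13")
  c(min = min(series),
    rate_pre = (series[7] - series[1]) / 6,
    rate_post = (series[13] - series[7]) / 6,
    mean_pre = mean(series[1:7]),
    mean_post = mean(series[7:13]))
}

# primary user = candidate user with the smaller minimum screener distance
# over the action window (ties to the smaller id)
primary_user <- function(action, seq) {
  w <- action$start:action$end
  m1 <- min(distance_series(seq, action$screener, action$user1, w))
  m2 <- min(distance_series(seq, action$screener, action$user2, w))
  if (m2 < m1) action$user2
  else if (m1 < m2) action$user1
  else sort(c(action$user1, action$user2))[1]
}

#' Conventional 30-dimensional baseline block
#'
#' The conventional on-ball descriptor: the six pairwise distances among the
#' screener, the primary user, the user-defender and the goal; for each, the
#' minimum over the whole action window, and the mean and endpoint change
#' over the start-to-minimum and minimum-to-end intervals (5 stats x 6
#' distances).
#'
#' @param action single-row action.
#' @param seq the `tracking_sequence`.
#' @return named numeric vector of length 30.
#' @export
baseline_block <- function(action, seq) {
  if (action$start >= action$end) stop("degenerate action window (start >= end)")
  u <- primary_user(action, seq)
  ents <- c(scr = action$screener, usr = u, def = action$defender, goal = "goal")
  pairs <- utils::combn(names(ents), 2)
  w <- action$start:action$end
  mf_at <- action$min_frame - action$start + 1L
  out <- numeric(0)
  for (j in seq_len(ncol(pairs))) {
    nm <- paste(pairs[1, j], pairs[2, j], sep = "_")
    d <- distance_series(seq, ents[[pairs[1, j]]], ents[[pairs[2, j]]], w)
    v <- c(min(d),
           mean(d[1:mf_at]), d[mf_at] - d[1],
           mean(d[mf_at:length(d)]), d[length(d)] - d[mf_at])
    names(v) <- paste0("base.", nm, c(".min", ".mean_pre", ".change_pre",
                                      ".mean_post", ".change_post"))
    out <- c(out, v)
  }
  out
}

#' Expanded 45-dimensional distance block
#'
#' Nine distances over the 13-frame feature window (screener to the
#' user-defender, screener to each candidate user, user-defender to each
#' candidate user, and the goal to each of the four players), each summarized
#' by [summarize_series()].
#'
#' @inheritParams baseline_block
#' @param halfwindow feature half-window (frames).
#' @return named numeric vector of length 45.
#' @export
distance_block <- function(action, seq, halfwindow = 6L) {
  w <- feature_window(action, seq, halfwindow)
  specs <- list(scr_def = c(action$screener, action$defender),
                scr_usr1 = c(action$screener, action$user1),
                scr_usr2 = c(action$screener, action$user2),
                def_usr1 = c(action$defender, action$user1),
                def_usr2 = c(action$defender, action$user2),
                goal_scr = c("goal", action$screener),
                goal_usr1 = c("goal", action$user1),
                goal_usr2 = c("goal", action$user2),
                goal_def = c("goal", action$defender))
  out <- numeric(0)
  for (nm in names(specs)) {
    s <- summarize_series(distance_series(seq, specs[[nm]][1], specs[[nm]][2], w))
    names(s) <- paste0("dist.", nm, ".", names(s))
    out <- c(out, s)
  }
  out
}

# path length of an entity over an inclusive frame range; the ball skips
# absent frames (errors if never present in the range)
path_length <- function(seq, entity, frames) {
  if (identical(entity, "ball")) {
    frames <- frames[ball_present(seq, frames)]
    if (length(frames) == 0L) stop("ball absent over the whole window")
  }
  if (length(frames) < 2L) return(0)
  xy <- entity_xy(seq, entity, frames)
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' 13-dimensional moving-distance block
#'
#' Path lengths of the four involved players (screener, user-defender, two
#' candidate users) over the full action window and over its pre- and
#' post-minimum halves, plus the ball's path length over the full window.
#'
#' @inheritParams baseline_block
#' @return named numeric vector of length 13.
#' @export
moving_block <- function(action, seq) {
  players <- c(scr = action$screener, def = action$defender,
               usr1 = action$user1, usr2 = action$user2)
  full <- action$start:action$end
  pre <- action$start:action$min_frame
  post <- action$min_frame:action$end
  out <- c(vapply(players, path_length, numeric(1), seq = seq, frames = full),
           vapply(players, path_length, numeric(1), seq = seq, frames = pre),
           vapply(players, path_length, numeric(1), seq = seq, frames = post),
           ball = path_length(seq, "ball", full))
  names(out) <- c(paste0("mov.", names(players), ".total"),
                  paste0("mov.", names(players), ".pre"),
                  paste0("mov.", names(players), ".post"),
                  "mov.ball.total")
  out
}

#' 60-dimensional geometric block
#'
#' Court-anchored and shape information at and around the minimum-distance
#' frame: a one-hot of the screener's screen area (9), the ball-distance
#' series of the four involved players over the 13-frame window summarized
#' (4 x 5), the six three-player angle series of the two user triangles
#' (angles at the screener, user and defender vertices for each candidate
#' user) summarized (6 x 5), and the ball-to-goal distance at the minimum
#' frame (1).
#'
#' @inheritParams distance_block
#' @param court a [court_spec()]; defaults to the sequence's own.
#' @param partition an [area_partition()].
#' @return named numeric vector of length 60.
#' @export
geometric_block <- function(action, seq, court = seq$court,
                            partition = area_partition(), halfwindow = 6L) {
  w <- feature_window(action, seq, halfwindow)
  if (!all(ball_present(seq, unique(c(w, action$min_frame)))))
    stop("ball absent in the feature window; geometric block undefined")
  area <- screen_area(seq$pos[action$min_frame, action$screener, ], court, partition)
  onehot <- as.numeric(seq_len(9L) == area)
  names(onehot) <- paste0("geo.area", 1:9)
  players <- c(scr = action$screener, def = action$defender,
               usr1 = action$user1, usr2 = action$user2)
  balls <- numeric(0)
  for (nm in names(players)) {
    s <- summarize_series(distance_series(seq, players[[nm]], "ball", w))
    names(s) <- paste0("geo.ball_", nm, ".", names(s))
    balls <- c(balls, s)
  }
  angs <- numeric(0)
  for (uu in c("usr1", "usr2")) {
    uid <- if (uu == "usr1") action$user1 else action$user2
    tri <- vapply(w, function(f) {
      pu <- seq$pos[f, uid, ]; ps <- seq$pos[f, action$screener, ]
      pd <- seq$pos[f, action$defender, ]
      c(scr = three_player_angle(pu, ps, pd),
        usr = three_player_angle(ps, pu, pd),
        def = three_player_angle(ps, pd, pu))
    }, numeric(3))
    for (vx in rownames(tri)) {
      s <- summarize_series(tri[vx, ])
      names(s) <- paste0("geo.ang_", uu, "_", vx, ".", names(s))
      angs <- c(angs, s)
    }
  }
  bg <- distance_series(seq, "ball", "goal", action$min_frame)
  c(onehot, balls, angs, geo.ball_goal = unname(bg))
}

#' Assemble the full feature vector of an action
#'
#' Concatenates the enabled blocks: baseline (30), expanded distances (45),
#' moving distances (13) and geometric information (60) — 148 dimensions when
#' all are on.
#'
#' @param action single-row action.
#' @param seq the `tracking_sequence`.
#' @param cfg a [feature_config()].
#' @return named numeric vector (length 148 by default).
#' @export
feature_vector <- function(action, seq, cfg = feature_config()) {
  out <- baseline_block(action, seq)
  if (cfg$baseline_only) return(out)
  out <- c(out, distance_block(action, seq))
  if (cfg$include_moving) out <- c(out, moving_block(action, seq))
  if (cfg$include_geometric)
    out <- c(out, geometric_block(action, seq, seq$court, cfg$partition))
  out
}

#' Feature matrix for a set of actions
#'
#' @param actions an `action_set`.
#' @param seq the `tracking_sequence`.
#' @param cfg a [feature_config()].
#' @return numeric matrix, one row per action, with named feature columns.
#' @export
build_feature_matrix <- function(actions, seq, cfg = feature_config()) {
  stopifnot(nrow(actions) >= 1L)
  rows <- lapply(seq_len(nrow(actions)), function(i)
    feature_vector(actions[i, ], seq, cfg))
  do.call(rbind, rows)
}

#' Write / read a feature matrix with action metadata
#'
#' Delimited text, one row per action: the action's metadata columns followed
#' by the named feature columns.
#'
#' @param x numeric feature matrix from [build_feature_matrix()].
#' @param actions the matching `action_set`.
#' @param path file path.
#' @return `path` (write); a list with `actions` and `features` (read).
#' @export
write_features <- function(x, actions, path) {
  stopifnot(nrow(x) == nrow(actions))
  df <- cbind(as.data.frame(actions), as.data.frame(x, optional = TRUE))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("features file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = ",", na.strings = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("screener", "user1", "user2", "defender", "min_frame",
                 "start", "end", "onball", "label", "screen_type")
  actions <- df[, intersect(meta_cols, names(df)), drop = FALSE]
  for (cc in c("screener", "user1", "user2", "defender", "onball", "label", "screen_type"))
    if (cc %in% names(actions)) actions[[cc]] <- as.character(actions[[cc]])
  class(actions) <- c("action_set", "data.frame")
  feats <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  list(actions = actions, features = feats)
}
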