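#' Half-court specification
#'
#' Describes the playing surface and sampling rate of a tracking feed. The
#' coordinate frame has its origin at the midpoint of the baseline under the
#' goal, with x running laterally in `[-width/2, +width/2]` and y running
#' up-court in `[0, depth]`. The goal (hoop centre) sits on the baseline axis,
#' 1.575 m into the court by default (FIBA hoop offset).
#'
#' @param depth court depth in metres, baseline to half-line (default 14).
#' @param width court width in metres (default 15).
#' @param goal numeric length-2, goal position in court coordinates.
#' @param fps frames per second of the feed (default 25).
#' @return an object of class `court_spec`.
#' @export
court_spec <- function(depth = 14, width = 15, goal = c(0, 1.575), fps = 25) {
  stopifnot(is.numeric(depth), length(depth) == 1L, depth > 0,
            is.numeric(width), length(width) == 1L, width > 0,
            is.numeric(fps), length(fps) == 1L, fps > 0,
            is.numeric(goal), length(goal) == 2L, all(is.finite(goal)))
  if (goal[1] < -width / 2 || goal[1] > width / 2 || goal[2] < 0 || goal[2] > depth)
    stop("goal position must lie inside or on the court boundary")
  structure(list(depth = depth, width = width, goal = as.numeric(goal), fps = fps),
            class = "court_spec")
}

#' @export
print.court_spec <- function(x, ...) {
  cat(sprintf("<court_spec> %g x %g m, goal at (%g, %g), %g fps\n",
              x$depth, x$width, x$goal[1], x$goal[2], x$fps))
  invisible(x)
}

#' Multi-agent tracking sequence
#'
#' Container for a uniformly sampled sequence of player and ball positions.
#' Positions are stored as an array `[frame, player, xy]`; the ball as an
#' `n x 3` matrix (XY on court plus height), with `NA` rows marking frames
#' where the ball is untracked. Ball-dependent operations raise explicit
#' errors on absent frames rather than imputing.
#'
#' @param time numeric vector of timestamps in seconds, strictly increasing
#'   with constant spacing `1/fps`.
#' @param players data.frame with columns `id` (character, unique) and `side`
#'   (`"offense"` or `"defense"`).
#' @param pos numeric array `n_frames x n_players x 2` of court XY positions
#'   in metres; second dimension named by player id.
#' @param ball optional `n_frames x 3` matrix of ball XYZ (metres); `NA` rows
#'   mark absence. `NULL` means the ball was never tracked.
#' @param court a [court_spec()].
#' @return an object of class `tracking_sequence`.
#' @export
tracking_sequence <- function(time, players, pos, ball = NULL, court = court_spec()) {
  stopifnot(inherits(court, "court_spec"))
  players <- as.data.frame(players, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "side") %in% names(players)))
  players$id <- as.character(players$id)
  players$side <- as.character(players$side)
  if (anyDuplicated(players$id)) stop("player ids must be unique")
  if (!all(players$side %in% c("offense", "defense")))
    stop("player side must be 'offense' or 'defense'")
  n <- length(time)
  if (n < 1L) stop("a tracking sequence needs at least one frame")
  if (!is.array(pos) || length(dim(pos)) != 3L ||
      dim(pos)[1] != n || dim(pos)[2] != nrow(players) || dim(pos)[3] != 2L)
    stop("pos must be an n_frames x n_players x 2 array matching time and players")
  dimnames(pos) <- list(NULL, players$id, c("x", "y"))
  if (any(!is.finite(pos))) stop("all player positions must be finite")
  if (n > 1L) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing")
    if (any(abs(dt - 1 / court$fps) > 1e-6))
      stop("timestamps must be uniformly spaced at 1/fps")
  }
  if (!is.null(ball)) {
    ball <- as.matrix(ball)
    if (nrow(ball) != n || ncol(ball) != 3L)
      stop("ball must be an n_frames x 3 matrix")
    colnames(ball) <- c("x", "y", "z")
    bad <- !is.na(ball) & !is.finite(ball)
    if (any(bad)) stop("ball positions must be finite or NA")
    # a frame's ball is all-present or all-absent
    pres <- rowSums(!is.na(ball))
    if (any(!pres %in% c(0L, 3L)))
      stop("ball coordinates must be jointly present or jointly absent per frame")
  }
  structure(list(court = court, players = players, time = as.numeric(time),
                 pos = pos, ball = ball),
            class = "tracking_sequence")
}

#' @export
print.tracking_sequence <- function(x, ...) {
  nb <- if (is.null(x$ball)) 0L else sum(!is.na(x$ball[, 1]))
  cat(sprintf("<tracking_sequence> %d frames @ %g fps, %d players (%d offense / %d defense), ball present in %d frames\n",
              n_frames(x), x$court$fps, nrow(x$players),
              sum(x$players$side == "offense"), sum(x$players$side == "defense"), nb))
  invisible(x)
}

#' Number of frames in a tracking sequence
#' @param seq a `tracking_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(seq) length(seq$time)

#' Player ids, optionally restricted to one side
#' @param seq a `tracking_sequence`.
#' @param side `NULL`, `"offense"` or `"defense"`.
#' @return character vector of ids, in roster order.
#' @export
player_ids <- function(seq, side = NULL) {
  if (is.null(side)) return(seq$players$id)
  seq$players$id[seq$players$side == side]
}

#' Positions of one player over (a subset of) frames
#' @param seq a `tracking_sequence`.
#' @param id player id.
#' @param frames integer frame indices (default all).
#' @return numeric matrix with columns x, y.
#' @export
player_pos <- function(seq, id, frames = seq_len(n_frames(seq))) {
  if (!id %in% seq$players$id) stop("unknown player id: ", id)
  m <- seq$pos[frames, id, , drop = FALSE]
  matrix(m, ncol = 2L, dimnames = list(NULL, c("x", "y")))
}

ball_present <- function(seq, frames = seq_len(n_frames(seq))) {
  if (is.null(seq$ball)) return(rep(FALSE, length(frames)))
  !is.na(seq$ball[frames, 1])
}

# ---- I/O ---------------------------------------------------------------

#' Write a tracking sequence to delimited text
#'
#' One row per frame, columns `t, <id>_x, <id>_y, ..., ball_x, ball_y,
#' ball_z`; empty ball cells mark absence. A YAML sidecar `<path>.yaml`
#' carries the court spec and roster sides so [read_tracking()] can restore
#' the sequence without extra arguments.
#'
#' @param seq a valid `tracking_sequence` with at least one frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(seq, path) {
  stopifnot(inherits(seq, "tracking_sequence"))
  if (n_frames(seq) < 1L) stop("refusing to write a zero-frame sequence")
  ids <- seq$players$id
  cols <- list(t = seq$time)
  for (id in ids) {
    cols[[paste0(id, "_x")]] <- seq$pos[, id, 1]
    cols[[paste0(id, "_y")]] <- seq$pos[, id, 2]
  }
  if (!is.null(seq$ball)) {
    cols$ball_x <- seq$ball[, 1]; cols$ball_y <- seq$ball[, 2]; cols$ball_z <- seq$ball[, 3]
  } else {
    n <- n_frames(seq)
    cols$ball_x <- rep(NA_real_, n); cols$ball_y <- rep(NA_real_, n); cols$ball_z <- rep(NA_real_, n)
  }
  df <- as.data.frame(cols, check.names = FALSE)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, quote = FALSE, na = "")
  sidecar <- list(
    court = list(depth = seq$court$depth, width = seq$court$width,
                 goal = as.numeric(seq$court$goal), fps = seq$court$fps),
    roster = stats::setNames(as.list(seq$players$side), seq$players$id))
  yaml::write_yaml(sidecar, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a tracking sequence from delimited text
#'
#' Reads the format written by [write_tracking()]. Court geometry and roster
#' sides come from the YAML sidecar `<path>.yaml` when present; explicit
#' `court` / `sides` arguments override it.
#'
#' @param path tracking file path.
#' @param court optional [court_spec()] overriding the sidecar.
#' @param sides optional named character vector mapping player id to
#'   `"offense"`/`"defense"`, overriding the sidecar.
#' @return a validated `tracking_sequence`.
#' @export
read_tracking <- function(path, court = NULL, sides = NULL) {
  if (!file.exists(path)) stop("tracking file not found: ", path)
  side_path <- paste0(path, ".yaml")
  if (file.exists(side_path)) {
    sc <- yaml::read_yaml(side_path)
    if (is.null(court) && !is.null(sc$court))
      court <- court_spec(depth = sc$court$depth, width = sc$court$width,
                          goal = as.numeric(sc$court$goal), fps = sc$court$fps)
    if (is.null(sides) && !is.null(sc$roster))
      sides <- unlist(sc$roster)
  }
  if (is.null(court)) court <- court_spec()
  if (is.null(sides)) stop("roster sides unavailable: no sidecar and no 'sides' argument")

  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  ncol_expect <- length(header)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = ",", colClasses = "numeric",
                      na.strings = "", check.names = FALSE),
    error = function(e) {
      # locate the offending line for the error message
      lines <- readLines(path)
      for (i in seq_along(lines)[-1]) {
        fields <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
        if (length(fields) > ncol_expect ||
            anyNA(suppressWarnings(as.numeric(fields[fields != ""]))))
          stop("malformed tracking row at line ", i, " of ", path)
      }
      stop("cannot parse tracking file ", path, ": ", conditionMessage(e))
    })
  if (!"t" %in% names(df)) stop("schema error: missing 't' column")
  xcols <- grep("_x$", names(df), value = TRUE)
  ids <- sub("_x$", "", setdiff(xcols, "ball_x"))
  for (id in ids)
    if (!paste0(id, "_y") %in% names(df))
      stop("schema error: column ", id, "_y missing for player ", id)
  if (length(ids) == 0L) stop("schema error: no player position columns found")
  miss <- setdiff(ids, names(sides))
  if (length(miss)) stop("schema error: no side given for player(s) ", paste(miss, collapse = ", "))
  tt <- df$t
  if (any(diff(tt) <= 0)) stop("validation error: timestamps not strictly increasing")
  n <- nrow(df)
  pos <- array(NA_real_, dim = c(n, length(ids), 2L))
  for (j in seq_along(ids)) {
    pos[, j, 1] <- df[[paste0(ids[j], "_x")]]
    pos[, j, 2] <- df[[paste0(ids[j], "_y")]]
  }
  ball <- NULL
  if (all(c("ball_x", "ball_y", "ball_z") %in% names(df)))
    ball <- cbind(df$ball_x, df$ball_y, df$ball_z)
  players <- data.frame(id = ids, side = unname(sides[ids]), stringsAsFactors = FALSE)
  tracking_sequence(time = tt, players = players, pos = pos, ball = ball, court = court)
}

# ---- resampling --------------------------------------------------------

#' Resample a tracking sequence to a new frame rate
#'
#' Linear interpolation of all positions at a uniform grid spanning the
#' original time range. Used to bring 100 Hz motion-capture feeds onto the
#' 25 fps grid on which the frame-count constants of the segmentation and
#' feature stages are defined. A resampled ball frame is present only when
#' both bracketing source frames carry the ball.
#'
#' @param seq a `tracking_sequence` with at least 2 frames.
#' @param target_fps new frame rate (> 0).
#' @return a `tracking_sequence` at `target_fps`.
#' @export
resample_tracking <- function(seq, target_fps) {
  stopifnot(inherits(seq, "tracking_sequence"), target_fps > 0)
  n <- n_frames(seq)
  if (n < 2L) stop("cannot resample a sequence shorter than 2 frames")
  t0 <- seq$time[1]; t1 <- seq$time[n]
  m <- floor((t1 - t0) * target_fps + 1e-9) + 1L
  new_t <- t0 + (seq_len(m) - 1L) / target_fps
  ids <- seq$players$id
  pos <- array(NA_real_, dim = c(m, length(ids), 2L))
  for (j in seq_along(ids)) for (k in 1:2)
    pos[, j, k] <- stats::approx(seq$time, seq$pos[, j, k], xout = new_t, rule = 2)$y
  ball <- NULL
  if (!is.null(seq$ball)) {
    pres <- !is.na(seq$ball[, 1])
    ball <- matrix(NA_real_, m, 3L)
    if (sum(pres) >= 2L) {
      for (k in 1:3)
        ball[, k] <- stats::approx(seq$time[pres], seq$ball[pres, k], xout = new_t)$y
      # keep only frames fully bracketed by present source frames
      ok <- vapply(new_t, function(tv) {
        lo <- max(which(seq$time <= tv + 1e-12)); hi <- min(which(seq$time >= tv - 1e-12))
        pres[lo] && pres[hi]
      }, logical(1))
      ball[!ok, ] <- NA_real_
    } else if (sum(pres) == 1L) {
      at <- which(pres)
      hit <- abs(new_t - seq$time[at]) < 1e-9
      ball[hit, ] <- matrix(seq$ball[at, ], sum(hit), 3L, byrow = TRUE)
    }
  }
  court <- seq$court; court$fps <- target_fps
  tracking_sequence(time = new_t, players = seq$players, pos = pos,
                    ball = ball, court = court)
}

# ---- possession --------------------------------------------------------

#' Nearest-player ball possession proxy
#'
#' Segmentation distinguishes on- from off-ball screens by who possesses
#' the ball at the closest approach, but possession is not observable from
#' positions alone; the proxy is the player nearest the ball in the court
#' plane,
#' provided that distance is within `radius` and the ball is no higher than
#' `max_height` (i.e. plausibly held or dribbled). Ties go to the smallest
#' player id.
#'
#' @param seq a `tracking_sequence`.
#' @param frame frame index; the ball must be present there.
#' @param radius horizontal possession radius in metres (default 1.0).
#' @param max_height maximum ball height in metres (default 2.2).
#' @return the possessing player id, or `NA_character_` when no player
#'   qualifies.
#' @export
possessor <- function(seq, frame, radius = 1.0, max_height = 2.2) {
  stopifnot(inherits(seq, "tracking_sequence"))
  if (frame < 1L || frame > n_frames(seq)) stop("frame out of range")
  if (is.null(seq$ball) || is.na(seq$ball[frame, 1]))
    stop("ball absent at frame ", frame, "; possession undefined")
  if (seq$ball[frame, 3] > max_height) return(NA_character_)
  bxy <- seq$ball[frame, 1:2]
  d <- sqrt((seq$pos[frame, , 1] - bxy[1])^2 + (seq$pos[frame, , 2] - bxy[2])^2)
  if (min(d) > radius) return(NA_character_)
  cand <- seq$players$id[d == min(d)]
  sort(cand)[1]
}

# pairwise 2D distance between two entities over given frames.
# entity: a player id, "ball" (court-plane XY), or "goal".
entity_xy <- function(seq, entity, frames) {
  if (identical(entity, "goal")) {
    g <- seq$court$goal
    return(cbind(rep(g[1], length(frames)), rep(g[2], length(frames))))
  }
  if (identical(entity, "ball")) {
    if (is.null(seq$ball)) stop("sequence has no ball track")
    return(seq$ball[frames, 1:2, drop = FALSE])
  }
  if (!entity %in% seq$players$id) stop("unknown entity: ", entity)
  player_pos(seq, entity, frames)
}
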