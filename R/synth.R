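#' Scenario configuration for the synthetic half-court simulator
#'
#' The simulator emulates the statistical structure of half-court tracking
#' feeds: a 14 x 15 m court sampled at 25 fps, scripted screen-play motifs of
#' the eight screen types, sustained screener/user-defender approaches below
#' 1.2 m, and per-frame positional jitter. The default `type_mix` mirrors the
#' real-game screen-type frequencies (down 104, flare 68, pin 23, back 31,
#' flex 8, cross 51, pick-and-roll 140, hand-off 42 of 467 screens), scaled
#' to 70% screen plays with 30% non-screen distractor plays.
#'
#' @param n_plays number of plays to simulate.
#' @param type_mix named probability vector over the eight screen types plus
#'   `distractor`; must sum to 1.
#' @param noise_sd per-frame, per-coordinate Gaussian jitter (m; default
#'   0.05).
#' @param duration frames per play (default 100, i.e. 4 s at 25 fps).
#' @param transition neutral frames between consecutive plays in a session.
#' @param fps frame rate (default 25).
#' @param seed integer RNG seed.
#' @param court a [court_spec()].
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(n_plays = 1000L, type_mix = default_type_mix(),
                            noise_sd = 0.05, duration = 100L, transition = 12L,
                            fps = 25, seed = 1L, court = court_spec(fps = fps)) {
  stopifnot(n_plays >= 1L, noise_sd >= 0, duration >= 60L, transition >= 2L)
  if (abs(sum(type_mix) - 1) > 1e-8) stop("type_mix must sum to 1")
  if (!all(names(type_mix) %in% c(screen_types(), "distractor")))
    stop("unknown play type in type_mix")
  structure(list(n_plays = as.integer(n_plays), type_mix = type_mix,
                 noise_sd = noise_sd, duration = as.integer(duration),
                 transition = as.integer(transition), fps = fps,
                 seed = as.integer(seed), court = court),
            class = "scenario_config")
}

#' The eight screen-play types
#' @return character vector of type names (six off-ball, then two on-ball).
#' @export
screen_types <- function() {
  c("down", "flare", "pin", "back", "flex", "cross", "pick_roll", "handoff")
}

#' @rdname scenario_config
#' @export
default_type_mix <- function() {
  counts <- c(down = 104, flare = 68, pin = 23, back = 31, flex = 8,
              cross = 51, pick_roll = 140, handoff = 42)
  c(counts / sum(counts) * 0.7, distractor = 0.3)
}

# ---- geometry helpers --------------------------------------------------

unitv <- function(v) v / sqrt(sum(v^2))
rot90v <- function(v) c(-v[2], v[1])

# linear interpolation of (frame, x, y) waypoints onto frames 1..n
interp_path <- function(wp, n) {
  wp <- wp[order(wp[, 1]), , drop = FALSE]
  cbind(stats::approx(wp[, 1], wp[, 2], xout = seq_len(n), rule = 2)$y,
        stats::approx(wp[, 1], wp[, 3], xout = seq_len(n), rule = 2)$y)
}

clamp_court_array <- function(pos, court, margin = 0.05) {
  pos[, , 1] <- pmin(pmax(pos[, , 1], -court$width / 2 + margin), court$width / 2 - margin)
  pos[, , 2] <- pmin(pmax(pos[, , 2], margin), court$depth - margin)
  pos
}

# base motif parameters per type, in right-side canonical coordinates:
# `site` is the user-defender's spot at contact, `u_dir` the unit offset of
# the user from the defender, `target` the user's cut destination, and
# s_start / s_end the screener's entry and exit points
motif_params <- function(type) {
  switch(type,
    down = list(site = c(2.0, 3.8), u_dir = c(0.15, -1), target = c(3.8, 9.0),
                s_start = c(1.6, 8.6), s_end = c(1.0, 2.6)),
    flare = list(site = c(2.6, 9.0), u_dir = c(-1, 0.15), target = c(6.2, 10.2),
                 s_start = c(6.9, 8.2), s_end = c(0.5, 10.5)),
    pin = list(site = c(3.0, 2.6), u_dir = c(-0.6, 0.8), target = c(6.4, 1.4),
               s_start = c(6.6, 0.9), s_end = c(1.5, 1.8)),
    back = list(site = c(3.0, 8.2), u_dir = c(0.1, 1), target = c(0.8, 2.8),
                s_start = c(2.5, 3.4), s_end = c(3.8, 10.2)),
    flex = list(site = c(3.2, 5.2), u_dir = c(1, 0.1), target = c(-4.8, 4.6),
                s_start = c(-1.6, 4.7), s_end = c(2.2, 3.4)),
    cross = list(site = c(2.0, 3.2), u_dir = c(1, 0.15), target = c(-3.3, 3.1),
                 s_start = c(-3.0, 3.4), s_end = c(1.4, 2.2)),
    pick_roll = list(site = c(1.4, 8.6), u_dir = c(0.15, 1), target = c(-3.2, 6.8),
                     s_start = c(0.4, 3.7), s_end = c(0.4, 3.0)),
    handoff = list(site = c(2.6, 8.0), u_dir = c(1, -0.1), target = c(-2.6, 8.6),
                   s_start = c(-1.8, 8.6), s_end = c(2.0, 5.6)),
    stop("unknown screen type: ", type))
}

# spread anchors for uninvolved players
formation_anchors <- function() {
  rbind(c(0, 9.8), c(4.5, 8.2), c(-4.5, 8.2), c(5.9, 2.0), c(-5.9, 2.0))
}

# the three anchors clearest of the scripted hot spots (site, cut arc and
# target, screener entry/exit), jittered; clearest one first. Both the
# anchor and its goal-side guard position must be clear.
far_anchors <- function(site, mirror, goal, avoid = NULL) {
  a <- formation_anchors()
  a[, 1] <- mirror * a[, 1]
  pts <- rbind(site, avoid)
  score <- apply(a, 1, function(p) {
    g <- p + 2.0 * unitv(goal - p)
    min(sqrt(colSums((t(pts) - p)^2)), sqrt(colSums((t(pts) - g)^2)))
  })
  a <- a[order(-score)[1:3], , drop = FALSE]
  a + matrix(stats::runif(6, -0.3, 0.3), 3, 2)
}

guard_path <- function(wp, goal, dist = 2.0) {
  for (i in seq_len(nrow(wp)))
    wp[i, 2:3] <- wp[i, 2:3] + dist * unitv(goal - wp[i, 2:3])
  wp
}

hold_path <- function(xy, n) {
  rbind(c(1, xy + stats::runif(2, -0.15, 0.15)),
        c(n, xy + stats::runif(2, -0.3, 0.3)))
}

#' Build a randomized screen-play script
#'
#' Transcribes the motif of one screen type into timed waypoints for the
#' involved players (screener, user, user-defender and the ball carrier),
#' places the remaining players on non-interfering paths (their defenders
#' 2 m goal-side), and records the planted contact frame, at which the
#' screener presses to 0.4-0.8 m from the user-defender and the distance
#' stays under 1.2 m for well over three frames. Randomness (court-side
#' mirroring, anchor jitter, contact depth and timing) comes from the
#' current RNG state.
#'
#' @param type one of [screen_types()].
#' @param cfg a [scenario_config()].
#' @return an object of class `screen_script`: waypoint list per role,
#'   ball-carrier timeline, `contact_frame`, `onball` flag.
#' @export
screen_script <- function(type, cfg = scenario_config()) {
  type <- match.arg(type, screen_types())
  p <- motif_params(type)
  n <- cfg$duration
  cf <- round(n * 0.5) + sample(-4:4, 1)
  mirror <- sample(c(1, -1), 1)
  jit <- function(v, s = 0.35) v + stats::runif(length(v), -s, s)
  mx <- function(v) c(mirror * v[1], v[2])

  site <- mx(jit(p$site))
  u_dir <- unitv(mx(p$u_dir) + stats::runif(2, -0.12, 0.12))
  target <- mx(jit(p$target, 0.5))
  s_start <- mx(jit(p$s_start, 0.5))
  s_end <- mx(jit(p$s_end, 0.5))
  s_dist <- stats::runif(1, 0.4, 0.8)
  u_start <- site + 1.5 * u_dir
  perp <- rot90v(u_dir)
  if (sum(perp * (target - site)) < 0) perp <- -perp
  # the cut swings around the screen, staying well clear of the defender
  w1 <- site + 1.0 * u_dir + 1.7 * perp
  w2 <- site - 0.4 * u_dir + 1.8 * perp
  w3 <- site - 1.5 * u_dir + 1.2 * perp

  wps <- list()
  # screener: approach, press to s_dist at contact, hold the screen, then
  # exit on the side opposite the cut (never re-approaching the defender)
  wps$S <- rbind(c(1, s_start),
                 c(cf - 6, site - (s_dist + 0.45) * u_dir),
                 c(cf, site - s_dist * u_dir),
                 c(cf + 6, site - (s_dist + 0.35) * u_dir),
                 c(cf + 12, site - (s_dist + 0.5) * u_dir),
                 c(cf + 24, site - 2.0 * u_dir - 1.5 * perp),
                 c(n, s_end))
  wps$U <- rbind(c(1, u_start + stats::runif(2, -0.15, 0.15)),
                 c(cf - 2, u_start),
                 c(cf + 3, w1), c(cf + 8, w2), c(cf + 13, w3),
                 c(n, target))
  # user-defender: held up at the site, then fights over the top along the
  # user's arc, trailing the cut without ever catching back up
  wps$D <- rbind(c(1, site + stats::runif(2, -0.1, 0.1)),
                 c(cf + 5, site),
                 c(cf + 14, w1), c(cf + 20, w2),
                 c(n, w3 + 0.25 * (target - w3)))
  wps$DS <- rbind(c(1, site - 2.3 * perp + stats::runif(2, -0.2, 0.2)),
                  c(n, site - 2.3 * perp))
  anchors <- far_anchors(site, mirror, cfg$court$goal,
                         avoid = rbind(target, s_start, s_end, u_start,
                                       w1, w2, w3,
                                       site - 2.0 * u_dir - 1.5 * perp))
  wps$P <- hold_path(anchors[1, ], n)   # passer: clearest of the screen
  wps$O2 <- hold_path(anchors[3, ], n)
  wps$O3 <- hold_path(anchors[2, ], n)
  goal <- cfg$court$goal
  wps$DP <- guard_path(wps$P, goal)
  wps$D2 <- guard_path(wps$O2, goal)
  wps$D3 <- guard_path(wps$O3, goal)

  onball <- type %in% c("pick_roll", "handoff")
  carrier <- if (!onball) rep("P", n)
             else if (type == "pick_roll") rep("U", n)
             else c(rep("S", cf), rep("U", n - cf))

  structure(list(type = type, onball = if (onball) "on" else "off",
                 duration = n, contact_frame = cf, waypoints = wps,
                 carrier = carrier, court = cfg$court),
            class = "screen_script")
}

#' @export
print.screen_script <- function(x, ...) {
  cat(sprintf("<screen_script> %s (%s-ball), %d frames, contact at %d\n",
              x$type, x$onball, x$duration, x$contact_frame))
  invisible(x)
}

# ---- frame assembly ----------------------------------------------------

roster_5v5 <- function() {
  data.frame(id = c(paste0("o", 1:5), paste0("d", 1:5)),
             side = rep(c("offense", "defense"), each = 5),
             stringsAsFactors = FALSE)
}

# map script roles to player ids; defender d<i> is paired with offense o<i>
role_ids <- function() {
  off <- stats::setNames(sample(paste0("o", 1:5)), c("S", "U", "P", "O2", "O3"))
  def <- stats::setNames(sub("^o", "d", off), c("DS", "D", "DP", "D2", "D3"))
  c(off, def)
}

# noiseless per-id positions and carrier ids for one play
script_frames <- function(script) {
  n <- script$duration
  ids <- role_ids()
  roster <- roster_5v5()
  pos <- array(NA_real_, dim = c(n, 10L, 2L),
               dimnames = list(NULL, roster$id, c("x", "y")))
  for (role in names(script$waypoints))
    pos[, ids[[role]], ] <- interp_path(script$waypoints[[role]], n)
  pos <- clamp_court_array(pos, script$court)
  truth <- if (script$type == "distractor") {
    empty_truth()
  } else {
    data.frame(screener = unname(ids[["S"]]), user = unname(ids[["U"]]),
               defender = unname(ids[["D"]]),
               contact_frame = script$contact_frame,
               onball = script$onball, screen_type = script$type,
               stringsAsFactors = FALSE)
  }
  list(pos = pos, carrier_id = unname(ids[script$carrier]), truth = truth)
}

empty_truth <- function() {
  data.frame(screener = character(), user = character(), defender = character(),
             contact_frame = integer(), onball = character(),
             screen_type = character(), stringsAsFactors = FALSE)
}

# jitter, ball attachment, tracking_sequence construction
assemble_sequence <- function(pos, carrier_id, cfg, t0 = 0) {
  n <- dim(pos)[1]
  if (cfg$noise_sd > 0)
    pos <- clamp_court_array(
      pos + array(stats::rnorm(length(pos), 0, cfg$noise_sd), dim = dim(pos)),
      cfg$court)
  ball <- matrix(NA_real_, n, 3L)
  for (f in seq_len(n)) {
    ball[f, 1:2] <- pos[f, carrier_id[f], ]
    ball[f, 3] <- 1.0
  }
  tracking_sequence(time = t0 + (seq_len(n) - 1) / cfg$fps,
                    players = roster_5v5(), pos = pos, ball = ball,
                    court = cfg$court)
}

#' Simulate one screen play
#'
#' Piecewise-linear interpolation of the script waypoints plus seeded
#' Gaussian jitter; the ball rides with the scripted carrier at 1 m height.
#' With `noise_sd = 0` the screener/user-defender distance attains its
#' minimum exactly at the scripted contact frame.
#'
#' @param script a [screen_script()].
#' @param cfg a [scenario_config()].
#' @param seed optional seed making the play reproducible on its own.
#' @return list with `seq` (a `tracking_sequence`) and `truth` (one-row
#'   ground-truth data.frame: screener, user, defender, contact_frame,
#'   onball, screen_type).
#' @export
simulate_play <- function(script, cfg = scenario_config(), seed = NULL) {
  stopifnot(inherits(script, "screen_script"))
  if (!is.null(seed)) set.seed(seed)
  fr <- script_frames(script)
  list(seq = assemble_sequence(fr$pos, fr$carrier_id, cfg), truth = fr$truth)
}

# distractor script builder (same waypoint machinery, no planted screen)
distractor_script <- function(cfg, variant = NULL) {
  if (is.null(variant))
    variant <- sample(c("brief", "wide", "linger"), 1, prob = c(0.25, 0.25, 0.5))
  variant <- match.arg(variant, c("brief", "wide", "linger"))
  n <- cfg$duration
  cf <- round(n * 0.5) + sample(-4:4, 1)
  mirror <- sample(c(1, -1), 1)
  goal <- cfg$court$goal
  # local pocket: offense V guarded at 1.35 m by defender K (so K is always
  # the closest player to V, satisfying condition 2 near the pocket)
  site <- c(mirror * stats::runif(1, 1.2, 2.6), stats::runif(1, 3.0, 6.0))
  v_dir <- unitv(stats::runif(2, -1, 1))
  v_off <- if (identical(variant, "wide")) 2.3 else 1.5
  v_pos <- site + v_off * v_dir

  wps <- list()
  # the would-be user holds tight beside the defender (no cut, little drift,
  # so the pair itself never crosses the contact threshold)
  wps$U <- rbind(c(1, v_pos + stats::runif(2, -0.1, 0.1)),
                 c(n, v_pos + stats::runif(2, -0.1, 0.1)))
  wps$D <- rbind(c(1, site + stats::runif(2, -0.05, 0.05)), c(n, site))
  if (variant == "brief") {
    # fly-by past K: perpendicular offset 1.05 m, fast (0.45 m/frame) only
    # through the closest approach, timed half a frame off it so exactly
    # 2 frames fall below 1.2 m; slow approach and exit along the chord
    # keep the whole footprint compact
    sdir <- rot90v(v_dir)
    if (sum(sdir * (c(0, 8) - site)) < 0) sdir <- -sdir
    p0 <- site - 1.05 * v_dir
    wps$S <- rbind(c(1, p0 - 3.0 * sdir),
                   c(cf - 2, p0 - 0.675 * sdir),
                   c(cf + 2, p0 + 1.125 * sdir),
                   c(cf + 8, p0 + 1.7 * sdir),
                   c(n, p0 + 2.6 * sdir))
  } else if (variant == "linger") {
    g <- stats::runif(1, 0.85, 1.1)
    stay <- site - g * v_dir
    appr <- unitv(c(0, 7) - site)
    hold_end <- cf + sample(4:8, 1)
    wps$S <- rbind(c(1, stay + 4.5 * appr),
                   c(cf - 8, stay + 1.0 * appr),
                   c(cf - 2, stay),
                   c(hold_end, stay),
                   c(n, stay + 2.8 * rot90v(v_dir)))
  } else {
    wps$S <- hold_path(site - 2.6 * v_dir, n)  # wide: never below 2 m
  }
  anchors <- far_anchors(site, mirror, goal,
                         avoid = rbind(v_pos, wps$S[, 2:3, drop = FALSE]))
  wps$P <- hold_path(anchors[1, ], n)
  wps$O2 <- hold_path(anchors[3, ], n)
  wps$O3 <- hold_path(anchors[2, ], n)
  # the mover's defender sags deep to the weak-side corner, clear of the
  # pocket, the mover's path and every anchor
  sag <- c(-mirror * 6.6, 12.8)
  wps$DS <- rbind(c(1, sag + stats::runif(2, -0.2, 0.2)), c(n, sag))
  wps$DP <- guard_path(wps$P, goal)
  wps$D2 <- guard_path(wps$O2, goal)
  wps$D3 <- guard_path(wps$O3, goal)
  structure(list(type = "distractor", onball = "off", duration = n,
                 contact_frame = cf, waypoints = wps,
                 carrier = rep("P", n), court = cfg$court,
                 variant = variant),
            class = "screen_script")
}

#' Simulate a non-screen distractor play
#'
#' Hard-negative motifs exercising the segmentation rules without a real
#' screen: `"brief"` sweeps an offense player past a defender so their
#' distance stays under 1.2 m for only 2 frames (excluded by the run-length
#' rule); `"wide"` keeps all cross-team distances above 2 m (no signal at
#' all); `"linger"` parks an offense player 0.85-1.1 m from a defender for
#' around ten frames with no user cut: a planted false alarm that
#' segmentation emits but that is labeled `not_screen`.
#'
#' @param cfg a [scenario_config()].
#' @param variant `"brief"`, `"wide"` or `"linger"` (default: sampled with
#'   probabilities 0.25 / 0.25 / 0.5).
#' @param seed optional seed.
#' @return list with `seq` and `truth` (a zero-row data.frame).
#' @export
distractor_play <- function(cfg = scenario_config(), variant = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  script <- distractor_script(cfg, variant)
  fr <- script_frames(script)
  list(seq = assemble_sequence(fr$pos, fr$carrier_id, cfg), truth = fr$truth)
}

#' Simulate a full session of plays
#'
#' Draws play types from `type_mix` (multinomially, seeded), simulates each
#' play, and concatenates them with short neutral transition segments
#' (linear motion from the end of one play to the start of the next).
#' Ground-truth contact frames are reported in session frame indices.
#'
#' @param cfg a [scenario_config()]; `cfg$seed` drives all randomness.
#' @return list with `seq` (the session `tracking_sequence`), `truth` (one
#'   row per planted screen) and `play_log` (type and frame range per play).
#' @export
simulate_session <- function(cfg = scenario_config()) {
  set.seed(cfg$seed)
  types <- sample(names(cfg$type_mix), cfg$n_plays, replace = TRUE,
                  prob = cfg$type_mix)
  pos_all <- list(); carrier_all <- list(); truth <- list(); log <- list()
  offset <- 0L; prev_last <- NULL
  for (i in seq_along(types)) {
    script <- if (types[i] == "distractor") distractor_script(cfg)
              else screen_script(types[i], cfg)
    fr <- script_frames(script)
    if (!is.null(prev_last)) {
      tn <- cfg$transition
      blend <- array(NA_real_, dim = c(tn, 10L, 2L), dimnames = dimnames(fr$pos))
      for (f in seq_len(tn)) {
        a <- f / (tn + 1)
        blend[f, , ] <- (1 - a) * prev_last + a * fr$pos[1, , ]
      }
      pos_all[[length(pos_all) + 1L]] <- blend
      carrier_all[[length(carrier_all) + 1L]] <- rep(fr$carrier_id[1], tn)
      offset <- offset + tn
    }
    pos_all[[length(pos_all) + 1L]] <- fr$pos
    carrier_all[[length(carrier_all) + 1L]] <- fr$carrier_id
    if (nrow(fr$truth)) {
      fr$truth$contact_frame <- fr$truth$contact_frame + offset
      truth[[length(truth) + 1L]] <- fr$truth
    }
    log[[length(log) + 1L]] <- data.frame(play = i, type = types[i],
                                          start = offset + 1L,
                                          end = offset + dim(fr$pos)[1],
                                          stringsAsFactors = FALSE)
    offset <- offset + dim(fr$pos)[1]
    prev_last <- fr$pos[dim(fr$pos)[1], , ]
  }
  n <- offset
  pos <- array(NA_real_, dim = c(n, 10L, 2L), dimnames = dimnames(pos_all[[1]]))
  at <- 0L
  for (a in pos_all) {
    pos[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  seq <- assemble_sequence(pos, unlist(carrier_all), cfg)
  truth <- if (length(truth)) do.call(rbind, truth) else empty_truth()
  rownames(truth) <- NULL
  list(seq = seq, truth = truth, play_log = do.call(rbind, log))
}

#' Label segmented actions against the planted ground truth
#'
#' An action is labeled `screen` when its window contains the contact frame
#' of a planted screen with the same screener and user-defender; it then
#' inherits the planted screen type. All other actions are `not_screen`.
#'
#' @param actions an `action_set` from [segment_actions()].
#' @param truth ground-truth data.frame from [simulate_session()].
#' @return the `action_set` with `label` and `screen_type` filled in.
#' @export
match_actions <- function(actions, truth) {
  if (nrow(actions) == 0L) return(actions)
  actions$label <- "not_screen"
  actions$screen_type <- NA_character_
  if (nrow(truth) == 0L) return(actions)
  for (i in seq_len(nrow(actions))) {
    hit <- truth$contact_frame >= actions$start[i] &
      truth$contact_frame <= actions$end[i] &
      truth$screener == actions$screener[i] &
      truth$defender == actions$defender[i]
    if (any(hit)) {
      actions$label[i] <- "screen"
      actions$screen_type[i] <- truth$screen_type[which(hit)[1]]
    }
  }
  actions
}

#' Segmentation recovery statistics against ground truth
#'
#' @param actions a labeled `action_set`.
#' @param truth ground-truth data.frame.
#' @return named numeric: `n_truth`, `n_actions`, `recovered` (planted
#'   screens whose contact frame falls inside at least one action window,
#'   any triple), `recovery_rate`, and `screen_action_rate` (fraction of
#'   actions labeled as true screens).
#' @export
recovery_stats <- function(actions, truth) {
  overl <- vapply(seq_len(nrow(truth)), function(i)
    any(actions$start <= truth$contact_frame[i] &
          actions$end >= truth$contact_frame[i]), logical(1))
  c(n_truth = nrow(truth), n_actions = nrow(actions),
    recovered = sum(overl),
    recovery_rate = if (nrow(truth)) mean(overl) else NA_real_,
    screen_action_rate = if (nrow(actions)) mean(actions$label == "screen",
                                                 na.rm = TRUE) else NA_real_)
}
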