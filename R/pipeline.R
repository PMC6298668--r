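#' Read and validate a run configuration
#'
#' A single YAML file configures every pipeline stage, with blocks `court`,
#' `segmentation`, `features`, `classifier`, `plan` and `scenario`; each
#' block is optional and missing keys take the package defaults. Unknown
#' keys raise a schema error naming the key.
#'
#' @param path YAML file path, or `NULL` for an all-defaults configuration.
#' @return a named list of validated stage configurations (class
#'   `run_config`).
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c("court", "segmentation", "features", "classifier", "plan", "scenario")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("config schema error: unknown block '", bad[1], "'")
  take <- function(block, fn, allowed) {
    args <- raw[[block]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), allowed)
    if (length(bad))
      stop("config schema error: unknown key '", bad[1], "' in block '", block, "'")
    list(fn = fn, args = args)
  }
  court_args <- if (is.null(raw$court)) list() else raw$court
  badc <- setdiff(names(court_args), c("depth", "width", "goal", "fps"))
  if (length(badc)) stop("config schema error: unknown key '", badc[1], "' in block 'court'")
  if (!is.null(court_args$goal)) court_args$goal <- as.numeric(court_args$goal)
  court <- do.call(court_spec, court_args)

  build <- function(block, fn, allowed, extra = list()) {
    spec <- take(block, fn, allowed)
    do.call(spec$fn, c(spec$args, extra))
  }
  seg <- build("segmentation", segmentation_config,
               c("contact_threshold", "min_signal_frames", "action_halfwindow",
                 "join_gap", "feature_halfwindow", "condition2_scope"))
  featl <- if (is.null(raw$features)) list() else raw$features
  badf <- setdiff(names(featl), c("include_moving", "include_geometric",
                                  "baseline_only", "partition"))
  if (length(badf)) stop("config schema error: unknown key '", badf[1], "' in block 'features'")
  part <- if (is.null(featl$partition)) area_partition()
          else area_partition(as.numeric(featl$partition$x_breaks),
                              as.numeric(featl$partition$y_breaks))
  feat <- feature_config(include_moving = featl$include_moving %||% TRUE,
                         include_geometric = featl$include_geometric %||% TRUE,
                         baseline_only = featl$baseline_only %||% FALSE,
                         partition = part)
  cls <- build("classifier", svm_config, c("cost_grid", "width_grid", "cv_folds"))
  plan <- build("plan", split_plan, c("test_fraction", "n_repeats", "seed"))
  scen_args <- if (is.null(raw$scenario)) list() else raw$scenario
  bads <- setdiff(names(scen_args), c("n_plays", "type_mix", "noise_sd",
                                      "duration", "transition", "fps", "seed"))
  if (length(bads)) stop("config schema error: unknown key '", bads[1], "' in block 'scenario'")
  if (!is.null(scen_args$type_mix)) scen_args$type_mix <- unlist(scen_args$type_mix)
  scen <- do.call(scenario_config, c(scen_args, list(court = court)))
  structure(list(court = court, segmentation = seg, features = feat,
                 classifier = cls, plan = plan, scenario = scen),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Pipeline stage: simulate a session to files
#'
#' Writes `tracking.csv` (+ YAML sidecar), `truth.csv` and `play_log.csv`
#' under `out_dir`.
#'
#' @param config a `run_config` (or path to one).
#' @param out_dir output directory (created if missing).
#' @param seed optional override of the scenario seed.
#' @return invisibly, the named vector of written paths.
#' @export
cmd_simulate <- function(config = read_run_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  ensure_dir(out_dir)
  scen <- config$scenario
  if (!is.null(seed)) scen$seed <- as.integer(seed)
  sess <- simulate_session(scen)
  paths <- c(tracking = file.path(out_dir, "tracking.csv"),
             truth = file.path(out_dir, "truth.csv"),
             play_log = file.path(out_dir, "play_log.csv"))
  write_tracking(sess$seq, paths["tracking"])
  utils::write.table(sess$truth, paths["truth"], sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  utils::write.table(sess$play_log, paths["play_log"], sep = ",",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(paths)
}

#' Pipeline stage: segment a tracking file into actions
#'
#' @param tracking_path tracking file written by [cmd_simulate()] or
#'   [write_tracking()].
#' @param config a `run_config` (or path).
#' @param out actions file path.
#' @return invisibly, `out`.
#' @export
cmd_segment <- function(tracking_path, config = read_run_config(), out) {
  if (is.character(config)) config <- read_run_config(config)
  seq <- read_tracking(tracking_path, court = config$court)
  actions <- segment_actions(seq, config$segmentation)
  write_actions(actions, out)
  invisible(out)
}

#' Pipeline stage: extract feature vectors for segmented actions
#'
#' @param tracking_path tracking file path.
#' @param actions_path actions file from [cmd_segment()].
#' @param config a `run_config` (or path).
#' @param out feature matrix file path.
#' @param truth_path optional ground-truth file; when given, action labels
#'   and screen types are attached before export.
#' @return invisibly, `out`.
#' @export
cmd_featurize <- function(tracking_path, actions_path, config = read_run_config(),
                          out, truth_path = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  seq <- read_tracking(tracking_path, court = config$court)
  actions <- read_actions(actions_path)
  if (!is.null(truth_path)) {
    truth <- utils::read.table(truth_path, header = TRUE, sep = ",",
                               stringsAsFactors = FALSE,
                               colClasses = c(screener = "character",
                                              user = "character",
                                              defender = "character"))
    actions <- match_actions(actions, truth)
  }
  if (nrow(actions) == 0L) {
    utils::write.table(actions, out, sep = ",", row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  x <- build_feature_matrix(actions, seq, config$features)
  write_features(x, actions, out)
  invisible(out)
}

#' Pipeline stage: train detectors and evaluate
#'
#' Runs the repeated-split detection protocol on a labeled feature file
#' (and, when enough labeled off-ball screens are present, the off-ball
#' typing protocol), writing JSON reports under `out_dir`.
#'
#' @param features_path labeled feature file from [cmd_featurize()].
#' @param config a `run_config` (or path).
#' @param out_dir output directory.
#' @param seed optional override of the split-plan seed.
#' @return invisibly, a list with the detection reports and typing summary.
#' @export
cmd_train_eval <- function(features_path, config = read_run_config(), out_dir,
                           seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  ensure_dir(out_dir)
  ff <- read_features(features_path)
  if (is.null(ff$actions$label) || length(unique(ff$actions$label)) < 2L)
    stop("train-eval needs labeled actions of both classes")
  plan <- config$plan
  if (!is.null(seed)) plan$seed <- as.integer(seed)
  reports <- run_protocol(ff$features, ff$actions$label,
                          onball = ff$actions$onball, plan = plan,
                          cfg = config$classifier, mode = "joint")
  med <- aggregate_reports(reports)
  det <- list(median = as.list(med),
              repeats = lapply(reports, function(r)
                list(auc = r$auc, f_score = r$f_score, recall = r$recall,
                     precision = r$precision, n_test = r$n_test,
                     subsets = r$subsets)))
  jsonlite::write_json(det, file.path(out_dir, "detection_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  typing <- NULL
  off <- ff$actions$label == "screen" & ff$actions$onball == "off" &
    !is.na(ff$actions$screen_type)
  if (sum(off) >= 40L && length(unique(ff$actions$screen_type[off])) >= 2L) {
    typing <- run_typing_protocol(ff$features[off, , drop = FALSE],
                                  ff$actions$screen_type[off], plan = plan,
                                  cfg = config$classifier)
    jsonlite::write_json(list(median = typing$median,
                              confusion = lapply(typing$repeats, `[[`, "confusion")),
                         file.path(out_dir, "typing_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(detection = det, typing = typing))
}
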