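#' SVM configuration
#'
#' Settings for the soft-margin Gaussian-kernel SVM. The constraint weight
#' (cost) and the kernel width are selected by stratified k-fold
#' cross-validation over the grids, maximizing validation AUC. The kernel
#' width grid is expressed as multipliers of the median-heuristic scale (the
#' median pairwise training distance), so the effective grid adapts to the
#' feature scaling of each problem.
#'
#' @param cost_grid candidate soft-margin costs.
#' @param width_grid candidate kernel-width multipliers of the median
#'   pairwise distance.
#' @param cv_folds number of cross-validation folds (default 10).
#' @return an object of class `svm_config`.
#' @export
svm_config <- function(cost_grid = c(0.1, 1, 10, 100),
                       width_grid = 2^(-4:2), cv_folds = 10L) {
  stopifnot(length(cost_grid) >= 1L, all(cost_grid > 0),
            length(width_grid) >= 1L, all(width_grid > 0), cv_folds >= 2L)
  structure(list(cost_grid = cost_grid, width_grid = width_grid,
                 cv_folds = as.integer(cv_folds)),
            class = "svm_config")
}

#' Repeated random-split plan
#'
#' The evaluation protocol holds out a random stratified test fraction
#' (default one third, mirroring a 2:1 train:test ratio), repeats the whole
#' train/tune/test cycle `n_repeats` times with fresh random splits, and
#' aggregates metrics as medians.
#'
#' @param test_fraction held-out fraction in (0, 1).
#' @param n_repeats number of repeated splits (default 5).
#' @param seed integer RNG seed for the split stream.
#' @return an object of class `split_plan`.
#' @export
split_plan <- function(test_fraction = 1 / 3, n_repeats = 5L, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, n_repeats >= 1L)
  structure(list(test_fraction = test_fraction, n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "split_plan")
}

# ---- internal helpers --------------------------------------------------

fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

median_heuristic <- function(x, max_n = 500L) {
  n <- nrow(x)
  idx <- if (n > max_n) round(seq(1, n, length.out = max_n)) else seq_len(n)
  d <- stats::dist(x[idx, , drop = FALSE])
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m == 0) 1 else m
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

svm_scores <- function(fit, x) {
  pr <- stats::predict(fit, x, decision.values = TRUE)
  as.numeric(attr(pr, "decision.values"))
}

# core binary fit on already-standardized features; y logical (TRUE = positive)
fit_binary_core <- function(x, y, cfg) {
  if (length(unique(y)) < 2L) stop("single-class input: cannot fit a binary SVM")
  if (min(table(y)) < 2L) stop("need at least 2 examples per class")
  sigma0 <- median_heuristic(x)
  grid <- expand.grid(cost = cfg$cost_grid, width = cfg$width_grid)
  k <- min(cfg$cv_folds, min(table(y)))
  cv_auc <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1L && k >= 2L) {
    fold <- stratified_folds(y, k)
    scores <- matrix(NA_real_, length(y), nrow(grid))
    for (f in seq_len(k)) {
      tr <- fold != f; te <- !tr
      if (length(unique(y[tr])) < 2L) next
      for (g in seq_len(nrow(grid))) {
        gamma <- 1 / (2 * (sigma0 * grid$width[g])^2)
        fit <- e1071::svm(x[tr, , drop = FALSE], factor(y[tr], levels = c(FALSE, TRUE)),
                          kernel = "radial", cost = grid$cost[g], gamma = gamma,
                          scale = FALSE)
        scores[te, g] <- svm_scores(fit, x[te, , drop = FALSE])
      }
    }
    for (g in seq_len(nrow(grid))) {
      ok <- !is.na(scores[, g])
      if (length(unique(y[ok])) == 2L) {
        a <- roc_auc(scores[ok, g], y[ok])$auc
        cv_auc[g] <- max(a, 1 - a)  # orientation-free ranking quality
      }
    }
  }
  best <- if (all(is.na(cv_auc))) 1L else which.max(cv_auc)
  gamma <- 1 / (2 * (sigma0 * grid$width[best])^2)
  fit <- e1071::svm(x, factor(y, levels = c(FALSE, TRUE)), kernel = "radial",
                    cost = grid$cost[best], gamma = gamma, scale = FALSE)
  # orient decision scores so higher = positive
  s_tr <- svm_scores(fit, x)
  flip <- roc_auc(s_tr, y)$auc < 0.5
  list(fit = fit, flip = flip, cost = grid$cost[best],
       width = grid$width[best], gamma = gamma, cv_auc = cv_auc[best])
}

core_scores <- function(core, x) {
  s <- svm_scores(core$fit, x)
  if (core$flip) -s else s
}

# ---- public fitting API ------------------------------------------------

#' Fit a two-class soft-margin Gaussian-kernel SVM
#'
#' Standardizes the features (training statistics only), selects cost and
#' kernel width by stratified cross-validated AUC over the configured grids,
#' and fits the final model on all training rows. Decision scores are
#' oriented so that higher means more positive.
#'
#' @param x numeric feature matrix (rows = examples).
#' @param y class labels; coerced to factor.
#' @param cfg an [svm_config()].
#' @param positive the label treated as positive (default: the second factor
#'   level).
#' @return an object of class `screen_svm`.
#' @export
fit_binary <- function(x, y, cfg = svm_config(), positive = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly 2 classes, got ", nlevels(y))
  if (is.null(positive)) positive <- levels(y)[2]
  stopifnot(positive %in% levels(y))
  scaler <- fit_scaler(x)
  core <- fit_binary_core(apply_scaler(x, scaler), y == positive, cfg)
  structure(list(core = core, scaler = scaler, positive = positive,
                 levels = levels(y), n_features = ncol(x)),
            class = "screen_svm")
}

#' @export
print.screen_svm <- function(x, ...) {
  cat(sprintf("<screen_svm> positive = '%s', cost = %g, width = %g x median scale\n",
              x$positive, x$core$cost, x$core$width))
  invisible(x)
}

#' Decision scores of a fitted model
#'
#' For a binary `screen_svm`, one real score per row (higher = positive).
#' For a `multiclass_svm`, an `n x k` matrix of per-class scores: the
#' one-against-all member scores, or the summed signed pairwise scores under
#' one-against-one.
#'
#' @param model a `screen_svm` or `multiclass_svm`.
#' @param x feature matrix with the training dimensionality.
#' @return numeric vector or matrix of scores.
#' @export
decision_scores <- function(model, x) UseMethod("decision_scores")

#' @export
decision_scores.screen_svm <- function(model, x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) return(numeric(0))
  if (ncol(x) != model$n_features)
    stop("feature dimension mismatch: model expects ", model$n_features)
  core_scores(model$core, apply_scaler(x, model$scaler))
}

#' Fit a multi-class SVM by binary decomposition
#'
#' One-against-all trains k members (one class positive, the rest negative);
#' one-against-one trains k(k-1)/2 members on each class pair, ignoring the
#' other classes. Classes with fewer than `min_class_size` examples are
#' dropped before fitting (with a warning naming them), mirroring the
#' exclusion of undersampled screen types. A single standardization, fit on
#' the full training set, is shared by all members.
#'
#' @param x numeric feature matrix.
#' @param y class labels (3 or more classes after exclusion).
#' @param strategy `"one_vs_all"` or `"one_vs_one"`.
#' @param cfg an [svm_config()].
#' @param min_class_size exclusion threshold (default 10; classes below it
#'   are dropped, and any kept class must still have at least 2 examples).
#' @return an object of class `multiclass_svm`.
#' @export
fit_multiclass <- function(x, y, strategy = c("one_vs_all", "one_vs_one"),
                           cfg = svm_config(), min_class_size = 10L) {
  strategy <- match.arg(strategy)
  x <- as.matrix(x); y <- as.character(y)
  tab <- table(y)
  drop <- names(tab)[tab < min_class_size]
  if (length(drop)) {
    warning("dropping undersampled class(es): ",
            paste(sprintf("%s (n=%d)", drop, tab[drop]), collapse = ", "))
    keep <- !(y %in% drop)
    x <- x[keep, , drop = FALSE]; y <- y[keep]
    tab <- table(y)
  }
  if (any(tab < 2L))
    stop("class with < 2 examples: ", paste(names(tab)[tab < 2L], collapse = ", "))
  classes <- sort(names(tab))
  if (length(classes) < 2L) stop("need at least 2 classes after exclusion")
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  members <- list()
  if (strategy == "one_vs_all") {
    for (cl in classes)
      members[[cl]] <- fit_binary_core(xs, y == cl, cfg)
  } else {
    for (i in seq_along(classes)) for (j in seq_along(classes)) {
      if (j <= i) next
      pair <- c(classes[i], classes[j])
      sel <- y %in% pair
      members[[paste(pair, collapse = "|")]] <-
        c(fit_binary_core(xs[sel, , drop = FALSE], y[sel] == pair[2], cfg),
          list(pair = pair))
    }
  }
  structure(list(strategy = strategy, classes = classes, members = members,
                 scaler = scaler, n_features = ncol(x)),
            class = "multiclass_svm")
}

#' @export
print.multiclass_svm <- function(x, ...) {
  cat(sprintf("<multiclass_svm> %s over %d classes (%d members)\n",
              x$strategy, length(x$classes), length(x$members)))
  invisible(x)
}

#' @export
decision_scores.multiclass_svm <- function(model, x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L)
    return(matrix(numeric(0), 0, length(model$classes),
                  dimnames = list(NULL, model$classes)))
  if (ncol(x) != model$n_features)
    stop("feature dimension mismatch: model expects ", model$n_features)
  xs <- apply_scaler(x, model$scaler)
  k <- length(model$classes)
  out <- matrix(0, nrow(x), k, dimnames = list(NULL, model$classes))
  if (model$strategy == "one_vs_all") {
    for (cl in model$classes) out[, cl] <- core_scores(model$members[[cl]], xs)
  } else {
    for (m in model$members) {
      s <- core_scores(m, xs)       # positive = m$pair[2]
      out[, m$pair[2]] <- out[, m$pair[2]] + s
      out[, m$pair[1]] <- out[, m$pair[1]] - s
    }
  }
  out
}

#' Predict classes from a multi-class SVM
#'
#' One-against-all predicts the argmax member score; one-against-one takes a
#' majority vote over the pairwise members, breaking ties by the highest
#' summed signed decision score.
#'
#' @param object a `multiclass_svm`.
#' @param x feature matrix.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.multiclass_svm <- function(object, x, ...) {
  x <- as.matrix(x)
  sc <- decision_scores(object, x)
  if (nrow(sc) == 0L) return(character(0))
  if (object$strategy == "one_vs_all")
    return(object$classes[max.col(sc, ties.method = "first")])
  xs <- apply_scaler(x, object$scaler)
  votes <- matrix(0L, nrow(x), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (m in object$members) {
    s <- core_scores(m, xs)
    win <- ifelse(s >= 0, m$pair[2], m$pair[1])
    for (cl in m$pair) votes[, cl] <- votes[, cl] + (win == cl)
  }
  vapply(seq_len(nrow(x)), function(i) {
    v <- votes[i, ]
    top <- names(v)[v == max(v)]
    if (length(top) == 1L) top else top[which.max(sc[i, top])]
  }, character(1))
}

# ---- repeated-split protocols -----------------------------------------

stratified_split <- function(strata, test_fraction) {
  test <- logical(length(strata))
  for (g in unique(strata)) {
    idx <- which(strata == g)
    n_test <- round(length(idx) * test_fraction)
    n_test <- min(max(n_test, 1L), length(idx) - 1L)
    test[sample(idx, n_test)] <- TRUE
  }
  test
}

#' Repeated-split detection protocol
#'
#' Runs the full evaluation protocol for the binary screen detector: per
#' repeat, a random stratified train/test split, cross-validated
#' hyperparameter selection on the training part only, and evaluation on the
#' held-out part. In `"joint"` mode the detector is trained on on- and
#' off-ball actions together and additionally evaluated on each subset of
#' the test set; the separate modes restrict the data to one subset before
#' splitting.
#'
#' @param x feature matrix.
#' @param labels binary labels (`"screen"` / `"not_screen"`, or any 2-level
#'   vector; `positive` names the positive one).
#' @param onball optional `"on"`/`"off"` flag per row; required unless
#'   `mode = "joint"` with no subset reporting desired.
#' @param plan a [split_plan()].
#' @param cfg an [svm_config()].
#' @param mode `"joint"`, `"onball_only"` or `"offball_only"`.
#' @param positive positive label (default `"screen"` when present).
#' @param threshold operating-point rule for [report_f()].
#' @return list of per-repeat `eval_report`s; in joint mode each report
#'   carries `subsets$onball` / `subsets$offball` metric vectors.
#' @export
run_protocol <- function(x, labels, onball = NULL, plan = split_plan(),
                         cfg = svm_config(),
                         mode = c("joint", "onball_only", "offball_only"),
                         positive = NULL, threshold = "max_f") {
  mode <- match.arg(mode)
  x <- as.matrix(x); labels <- as.character(labels)
  if (is.null(positive))
    positive <- if ("screen" %in% labels) "screen" else sort(unique(labels))[2]
  if (mode != "joint") {
    if (is.null(onball)) stop("mode '", mode, "' needs the onball flag")
    keep <- onball == (if (mode == "onball_only") "on" else "off")
    x <- x[keep, , drop = FALSE]; labels <- labels[keep]; onball <- onball[keep]
  }
  if (length(unique(labels)) < 2L) stop("both classes needed for the protocol")
  strata <- if (!is.null(onball)) paste(labels, onball) else labels
  set.seed(plan$seed)
  reports <- vector("list", plan$n_repeats)
  for (r in seq_len(plan$n_repeats)) {
    test <- stratified_split(strata, plan$test_fraction)
    model <- fit_binary(x[!test, , drop = FALSE], labels[!test], cfg,
                        positive = positive)
    sc <- decision_scores(model, x[test, , drop = FALSE])
    yy <- labels[test] == positive
    rep_r <- eval_report(sc, yy, threshold)
    if (mode == "joint" && !is.null(onball)) {
      subs <- list()
      for (flag in c("on", "off")) {
        sel <- onball[test] == flag
        subs[[if (flag == "on") "onball" else "offball"]] <-
          if (length(unique(yy[sel])) == 2L)
            c(auc = roc_auc(sc[sel], yy[sel])$auc,
              report_f(sc[sel], yy[sel], threshold)[c("recall", "precision", "f")])
          else c(auc = NA_real_, recall = NA_real_, precision = NA_real_, f = NA_real_)
      }
      rep_r$subsets <- subs
    }
    reports[[r]] <- rep_r
  }
  reports
}

#' Repeated-split typing protocol for off-ball screens
#'
#' Per repeat: stratified split, multi-class fit on the training rows, then
#' per-class one-vs-rest AUC from the class scores and per-class recall /
#' precision / F from the predicted labels, plus the confusion matrix.
#'
#' @param x feature matrix of off-ball screen actions.
#' @param types screen-type label per row.
#' @param plan a [split_plan()].
#' @param cfg an [svm_config()].
#' @param strategy `"one_vs_all"` or `"one_vs_one"`.
#' @param min_class_size exclusion threshold applied before splitting.
#' @return list with `repeats` (per-repeat list of `per_class` data.frame
#'   and `confusion`) and `median` (per-class medians of auc and f).
#' @export
run_typing_protocol <- function(x, types, plan = split_plan(), cfg = svm_config(),
                                strategy = "one_vs_all", min_class_size = 10L) {
  x <- as.matrix(x); types <- as.character(types)
  tab <- table(types)
  drop <- names(tab)[tab < min_class_size]
  if (length(drop)) {
    message("excluding undersampled type(s): ",
            paste(sprintf("%s (n=%d)", drop, tab[drop]), collapse = ", "))
    keep <- !(types %in% drop)
    x <- x[keep, , drop = FALSE]; types <- types[keep]
  }
  classes <- sort(unique(types))
  set.seed(plan$seed)
  repeats <- vector("list", plan$n_repeats)
  for (r in seq_len(plan$n_repeats)) {
    test <- stratified_split(types, plan$test_fraction)
    model <- fit_multiclass(x[!test, , drop = FALSE], types[!test],
                            strategy = strategy, cfg = cfg,
                            min_class_size = 2L)
    sc <- decision_scores(model, x[test, , drop = FALSE])
    pred <- predict(model, x[test, , drop = FALSE])
    per <- do.call(rbind, lapply(classes, function(cl) {
      yy <- types[test] == cl
      auc <- if (length(unique(yy)) == 2L) roc_auc(sc[, cl], yy)$auc else NA_real_
      tp <- sum(pred == cl & yy)
      rec <- tp / sum(yy)
      prec <- if (sum(pred == cl) == 0L) 1 else tp / sum(pred == cl)
      data.frame(class = cl, auc = auc, recall = rec, precision = prec,
                 f = f_score(rec, prec), stringsAsFactors = FALSE)
    }))
    repeats[[r]] <- list(per_class = per,
                         confusion = confusion_matrix(types[test], pred, classes))
  }
  med <- do.call(rbind, lapply(classes, function(cl) {
    vals <- function(f) vapply(repeats, function(r)
      r$per_class[r$per_class$class == cl, f], numeric(1))
    data.frame(class = cl, auc = stats::median(vals("auc")),
               f = stats::median(vals("f")), stringsAsFactors = FALSE)
  }))
  list(repeats = repeats, median = med, classes = classes)
}

#' Save / load a fitted model
#'
#' Self-describing single-file persistence (a version field plus the scaler
#' and member parameters) via R serialization.
#'
#' @param model a `screen_svm` or `multiclass_svm`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("screen_svm", "multiclass_svm")))
  saveRDS(list(format = "screendetect-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "screendetect-model"))
    stop("not a screendetect model archive: ", path)
  obj$model
}
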