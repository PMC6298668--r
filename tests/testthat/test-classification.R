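test_that("member counts follow the one-vs-all and one-vs-one formulas", {
  set.seed(21)
  for (k in 2:10) {
    n_per <- 6
    x <- do.call(rbind, lapply(1:k, function(i)
      matrix(rnorm(n_per * 2, mean = 6 * i), n_per, 2)))
    y <- rep(letters[1:k], each = n_per)
    m_all <- fit_multiclass(x, y, "one_vs_all", fast_svm_config(), min_class_size = 2)
    m_one <- fit_multiclass(x, y, "one_vs_one", fast_svm_config(), min_class_size = 2)
    expect_length(m_all$members, k)
    expect_length(m_one$members, k * (k - 1) / 2)
  }
})

test_that("well-separated clouds are ranked almost perfectly", {
  d <- two_clouds(n = 100, seed = 22)
  m <- fit_binary(d$x, d$y, svm_config(cost_grid = c(1, 10), width_grid = c(0.5, 1),
                                       cv_folds = 5), positive = "pos")
  sc <- decision_scores(m, d$x)
  expect_gte(roc_auc(sc, d$y == "pos")$auc, 0.99)
  # positives all score above negatives on the training set
  expect_gt(min(sc[d$y == "pos"]), max(sc[d$y == "neg"]))
})

test_that("shuffled labels give chance-level cross-validated performance", {
  set.seed(23)
  x <- matrix(rnorm(400 * 6), 400, 6)
  y <- sample(rep(c("neg", "pos"), each = 200))
  reports <- run_protocol(x, y, plan = split_plan(n_repeats = 5, seed = 23),
                          cfg = fast_svm_config(), positive = "pos")
  med <- stats::median(vapply(reports, `[[`, numeric(1), "auc"))
  expect_gte(med, 0.4); expect_lte(med, 0.6)
})

test_that("duplicating every training row leaves the decision function intact", {
  d <- two_clouds(n = 40, seed = 24)
  cfg <- fast_svm_config()
  m1 <- fit_binary(d$x, d$y, cfg, positive = "pos")
  m2 <- fit_binary(rbind(d$x, d$x), c(d$y, d$y), cfg, positive = "pos")
  probe <- matrix(rnorm(50 * 5, mean = 2), 50, 5)
  s1 <- decision_scores(m1, probe); s2 <- decision_scores(m2, probe)
  expect_equal(s1, s2, tolerance = 1e-4)
})

test_that("scores are deterministic, dimension-checked and empty-safe", {
  d <- two_clouds(n = 30, seed = 25)
  m <- fit_binary(d$x, d$y, fast_svm_config(), positive = "pos")
  s1 <- decision_scores(m, d$x); s2 <- decision_scores(m, d$x)
  expect_identical(s1, s2)
  expect_length(decision_scores(m, d$x[0, , drop = FALSE]), 0L)
  expect_error(decision_scores(m, d$x[, 1:3]), "dimension")
  expect_error(fit_binary(d$x, rep("pos", nrow(d$x)), fast_svm_config()), "2 classes")
})

test_that("standardization is fitted on training rows only", {
  d <- two_clouds(n = 50, seed = 26)
  m <- fit_binary(d$x, d$y, fast_svm_config(), positive = "pos")
  expect_equal(unname(m$scaler$center), unname(colMeans(d$x)))
  expect_equal(unname(m$scaler$scale), unname(apply(d$x, 2, sd)))
  # scoring extra rows does not mutate the stored scaler
  extreme <- matrix(1e3, 4, 5)
  invisible(decision_scores(m, extreme))
  expect_equal(unname(m$scaler$center), unname(colMeans(d$x)))
})

test_that("three separable clouds classify almost perfectly under both strategies", {
  set.seed(27)
  n_per <- 40
  x <- do.call(rbind, lapply(1:3, function(i) {
    ang <- 2 * pi * i / 3
    cbind(rnorm(n_per, 8 * cos(ang)), rnorm(n_per, 8 * sin(ang)))
  }))
  y <- rep(c("a", "b", "c"), each = n_per)
  test <- rep(c(rep(FALSE, 30), rep(TRUE, 10)), 3)
  for (strat in c("one_vs_all", "one_vs_one")) {
    m <- fit_multiclass(x[!test, ], y[!test], strat, fast_svm_config(),
                        min_class_size = 2)
    pred <- predict(m, x[test, ])
    expect_gte(mean(pred == y[test]), 0.95)
    sc <- decision_scores(m, x[test, ])
    expect_equal(dim(sc), c(sum(test), 3L))
  }
})

test_that("undersampled classes are dropped with a warning naming them", {
  set.seed(28)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2),
             matrix(rnorm(6, 16), 3, 2))
  y <- c(rep("a", 20), rep("b", 20), rep("tiny", 3))
  expect_warning(m <- fit_multiclass(x, y, "one_vs_all", fast_svm_config(),
                                     min_class_size = 10), "tiny")
  expect_identical(m$classes, c("a", "b"))
  expect_error(fit_multiclass(x[1:21, ], y[1:21], "one_vs_all",
                              fast_svm_config(), min_class_size = 1), "< 2")
})

test_that("the repeated-split protocol is reproducible and well-formed", {
  d <- two_clouds(n = 60, seed = 29)
  onball <- rep(c("on", "off"), 60)
  plan <- split_plan(n_repeats = 5, seed = 31)
  r1 <- run_protocol(d$x, d$y, onball, plan, fast_svm_config(), positive = "pos")
  r2 <- run_protocol(d$x, d$y, onball, plan, fast_svm_config(), positive = "pos")
  expect_length(r1, 5L)
  expect_identical(r1, r2)   # bit-identical under a fixed seed
  # joint mode reports subset metrics for both subsets
  expect_named(r1[[1]]$subsets, c("onball", "offball"))
  expect_false(anyNA(r1[[1]]$subsets$onball))
  # separate modes restrict to the requested subset
  ron <- run_protocol(d$x, d$y, onball, plan, fast_svm_config(),
                      mode = "onball_only", positive = "pos")
  expect_equal(ron[[1]]$n_test, sum(onball == "on") %/% 3)
  expect_error(run_protocol(d$x, d$y, NULL, plan, fast_svm_config(),
                            mode = "onball_only"), "onball")
})

test_that("typing protocol reports per-class medians and confusions", {
  set.seed(33)
  n_per <- 30
  x <- do.call(rbind, lapply(1:3, function(i)
    cbind(rnorm(n_per, 7 * i), rnorm(n_per, -4 * i))))
  y <- rep(c("down", "flare", "cross"), each = n_per)
  out <- run_typing_protocol(x, y, split_plan(n_repeats = 3, seed = 7),
                             fast_svm_config(), min_class_size = 2)
  expect_setequal(out$classes, c("down", "flare", "cross"))
  expect_equal(nrow(out$median), 3L)
  expect_true(all(out$median$auc > 0.95))
  cm <- out$repeats[[1]]$confusion
  expect_equal(dim(cm), c(3L, 3L))
  expect_equal(sum(cm), 30L)   # 3 classes x 30 each at 1/3 test fraction
})

test_that("models survive a save/load round trip", {
  d <- two_clouds(n = 30, seed = 35)
  m <- fit_binary(d$x, d$y, fast_svm_config(), positive = "pos")
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(decision_scores(m2, d$x), decision_scores(m, d$x))
  unlink(path)
})
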