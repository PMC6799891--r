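two_clouds <- function(n_per_class, sep = 4, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
               matrix(rnorm(2 * n_per_class, mean = sep), ncol = 2))
  })
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}

small_cfg <- function() svm_config(cost_grid = c(1, 10),
                                   gamma_grid = c(0.1, 1),
                                   n_folds = 3, min_events = 10)

test_that("well-separated clouds are classified perfectly", {
  d <- two_clouds(100, sep = 8)
  test <- two_clouds(50, sep = 8, seed = 2)
  model <- train_viability_svm(d$x, d$y, small_cfg(), seed = 1)
  expect_equal(accuracy(confusion_matrix(predict(model, test$x), test$y)), 1)
  # training points through their own model reproduce the labels
  expect_equal(predict(model, d$x), d$y)
})

test_that("shuffled labels give chance-level cross-validated accuracy", {
  d <- two_clouds(100)
  y_shuf <- withr::with_seed(7, sample(d$y))
  model <- suppressWarnings(
    train_viability_svm(d$x, y_shuf, small_cfg(), seed = 1))
  expect_gt(model$cv_accuracy, 0.4)
  expect_lt(model$cv_accuracy, 0.6)
})

test_that("training requires both classes and complete inputs", {
  d <- two_clouds(20)
  expect_error(train_viability_svm(d$x, rep(1L, nrow(d$x)), small_cfg()),
               "both live")
  expect_error(train_viability_svm(d$x, d$y[-1], small_cfg()), "one entry")
  expect_warning(train_viability_svm(d$x[c(1:5, 21:25), ],
                                     d$y[c(1:5, 21:25)],
                                     svm_config(cost_grid = 1,
                                                gamma_grid = 1,
                                                n_folds = 2,
                                                min_events = 100)),
                 "below the recommended")
})

test_that("prediction handles empty input, duplicates, and schema checks", {
  d <- two_clouds(50)
  model <- train_viability_svm(d$x, d$y, small_cfg(), seed = 1)
  expect_identical(predict(model, d$x[0, , drop = FALSE]), integer(0))
  rep_row <- d$x[rep(3, 7), , drop = FALSE]
  expect_length(unique(predict(model, rep_row)), 1)
  expect_error(predict(model, matrix(0, 2, 3)), "schema")
})

test_that("training is deterministic under a fixed seed", {
  d <- two_clouds(60, sep = 2)
  m1 <- train_viability_svm(d$x, d$y, small_cfg(), seed = 5)
  m2 <- train_viability_svm(d$x, d$y, small_cfg(), seed = 5)
  expect_identical(m1$cv, m2$cv)
  expect_identical(predict(m1, d$x), predict(m2, d$x))
})

test_that("an independent RBF-SVM implementation agrees on the decision rule", {
  skip_if_not_installed("kernlab")
  d <- two_clouds(100, sep = 2.5)
  test <- two_clouds(200, sep = 2.5, seed = 3)
  cfg <- svm_config(cost_grid = 10, gamma_grid = 0.5, n_folds = 2,
                    min_events = 10, normalize = FALSE)
  model <- train_viability_svm(d$x, d$y, cfg, seed = 1)
  ref <- kernlab::ksvm(x = d$x, y = factor(d$y), type = "C-svc",
                       kernel = "rbfdot",
                       kpar = list(sigma = 0.5), C = 10, scaled = FALSE)
  agree <- mean(predict(model, test$x) ==
                  as.integer(as.character(kernlab::predict(ref, test$x))))
  expect_gte(agree, 0.98)
})

test_that("confusion counts match brute-force enumeration", {
  cm <- confusion_matrix(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(cm[c("tp", "tn", "fp", "fn")]),
               c(tp = 2, tn = 2, fp = 0, fn = 0))

  cm2 <- confusion_matrix(1 - c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(cm2$tp + cm2$tn, 0)

  cm3 <- confusion_matrix(c(1, 0, 1, 0, 1), c(1, 1, 0, 0, 1))
  expect_equal(unlist(cm3[c("tp", "tn", "fp", "fn")]),
               c(tp = 2, tn = 1, fp = 1, fn = 1))

  expect_error(confusion_matrix(c(1, 0), c(1)), "equal length")
  expect_error(confusion_matrix(c(2, 0), c(1, 0)), "0 or 1")
})

test_that("accuracy and per-class rates follow their definitions", {
  cm <- structure(list(tp = 45, tn = 46, fp = 5, fn = 4),
                  class = "confusion_matrix")
  expect_equal(accuracy(cm), 0.91)
  cm_perfect <- structure(list(tp = 0, tn = 10, fp = 0, fn = 0),
                          class = "confusion_matrix")
  expect_equal(accuracy(cm_perfect), 1)
  cm_wrong <- structure(list(tp = 0, tn = 0, fp = 3, fn = 7),
                        class = "confusion_matrix")
  expect_equal(accuracy(cm_wrong), 0)

  r <- class_rates(structure(list(tp = 9, tn = 9, fp = 1, fn = 1),
                             class = "confusion_matrix"))
  expect_equal(unname(r), c(0.9, 0.9))
  r2 <- class_rates(structure(list(tp = 19, tn = 29, fp = 1, fn = 1),
                              class = "confusion_matrix"))
  expect_equal(unname(r2), c(0.95, 29 / 30))
  expect_error(class_rates(structure(list(tp = 0, tn = 3, fp = 1, fn = 0),
                                     class = "confusion_matrix")),
               "both classes")
})

test_that("accuracy identity holds on random confusion matrices", {
  set.seed(11)
  for (i in 1:50) {
    counts <- rmultinom(1, size = sample(20:500, 1), prob = runif(4))
    cm <- structure(list(tp = counts[1], tn = counts[2],
                         fp = counts[3], fn = counts[4]),
                    class = "confusion_matrix")
    if (cm$tp + cm$fn == 0 || cm$tn + cm$fp == 0) next
    r <- class_rates(cm)
    n_live <- cm$tp + cm$fn
    n_dead <- cm$tn + cm$fp
    expect_equal(accuracy(cm),
                 (r[["tp_rate"]] * n_live + r[["tn_rate"]] * n_dead) /
                   (n_live + n_dead))
  }
})

test_that("viability percentage is the fraction of predicted-live events", {
  expect_equal(viability_percent(rep(1, 4))$viability_percent, 100)
  expect_equal(viability_percent(rep(0, 4))$viability_percent, 0)
  est <- viability_percent(c(rep(1, 9), 0))
  expect_equal(est$viability_percent, 90)
  expect_equal(est$n_predicted_live, 9)
  expect_error(viability_percent(integer(0)), "no predictions")
})
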