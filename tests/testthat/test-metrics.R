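test_that("perfect predictions score 1 on every metric", {
  y <- c(1, 2, 3, 4, 1, 2)
  scores <- matrix(0.01, 6, 4)
  for (i in seq_along(y)) scores[i, y[i]] <- 0.97
  m <- classification_metrics(y, scores)
  expect_equal(m$accuracy, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$roc_auc, 1)
})

test_that("a hand-computed two-class case matches", {
  # y = (0,0,1,1), predictions (0,1,1,1) in 0-based terms
  y <- c(1, 1, 2, 2)
  scores <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.3, 0.7), c(0.1, 0.9))
  m <- classification_metrics(y, scores)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$recall, 0.75)  # weighted recall == accuracy
  # per-class: prec = (1, 2/3), rec = (1/2, 1); weighted 0.5 each
  expect_equal(m$precision, 0.5 * 1 + 0.5 * 2 / 3)
})

test_that("weighted recall equals accuracy on any input", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      n <- 50
      nc <- sample(2:5, 1)
      y <- sample(nc, n, replace = TRUE)
      raw <- matrix(rexp(n * nc), n, nc)
      scores <- raw / rowSums(raw)
      m <- suppressWarnings(classification_metrics(y, scores))
      expect_equal(m$recall, m$accuracy, tolerance = 1e-12)
      expect_true(all(unlist(m[, c("accuracy", "precision", "recall",
                                   "f1", "roc_auc")]) >= 0))
      expect_true(all(unlist(m[, c("accuracy", "precision", "recall",
                                   "f1", "roc_auc")]) <= 1))
    }
  })
})

test_that("score rows must be calibrated probabilities", {
  expect_error(classification_metrics(c(1, 2), rbind(c(0.9, 0.3), c(0.5, 0.5))),
               "sum to 1")
  expect_error(classification_metrics(c(1, 3), rbind(c(1, 0), c(0, 1))),
               "out of range")
})

test_that("absent classes trigger a warning, not a failure", {
  y <- c(1, 1, 2, 2)
  scores <- matrix(0.25, 4, 4)
  expect_warning(m <- classification_metrics(y, scores), "absent")
  expect_true(is.finite(m$roc_auc))
})

test_that("confusion matrix matches a brute-force tally", {
  withr::with_seed(31, {
    y_true <- sample(4, 1000, replace = TRUE)
    y_pred <- sample(4, 1000, replace = TRUE)
    cm <- confusion_matrix(y_true, y_pred, 4)
    manual <- matrix(0L, 4, 4)
    for (k in seq_along(y_true)) {
      manual[y_true[k], y_pred[k]] <- manual[y_true[k], y_pred[k]] + 1L
    }
    expect_equal(unname(unclass(cm)), manual)
    expect_equal(sum(cm), 1000)
    expect_equal(unname(rowSums(cm)), unname(tabulate(y_true, 4)))
  })
  perfect <- confusion_matrix(c(1, 2, 3), c(1, 2, 3), 3)
  expect_equal(unname(diag(perfect)), c(1L, 1L, 1L))
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)
  expect_error(confusion_matrix(c(1, 5), c(1, 1), 4), "out of range")
})

test_that("the centralized baseline trains, ranks and persists", {
  ds <- tiny_ds(10, image_size = c(16, 16), seed = 12)
  sp <- stratified_split(ds, 0.8, seed = 12)
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "centralized_models_comparison.csv")
  rows <- run_centralized_baseline("tiny_cnn", sp$train, sp$test,
                                   training_config(local_epochs = 1,
                                                   batch_size = 16),
                                   out_csv = csv)
  expect_equal(nrow(rows), 1)
  expect_true(rows$best[1])
  expect_true(file.exists(csv))
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(back$accuracy, rows$accuracy)
  expect_equal(back$f1, rows$f1)
  expect_error(run_centralized_baseline("resnet50", sp$train, sp$test,
                                        training_config(local_epochs = 1)),
               "stub|tiny_cnn")
})

test_that("best-F1 selection breaks ties by first occurrence", {
  rows <- tibble::tibble(label = c("a", "b", "c"),
                         accuracy = c(0.9, 0.95, 0.95),
                         f1 = c(0.9, 0.95, 0.95))
  rows$best <- seq_len(nrow(rows)) == which.max(rows$f1)
  expect_equal(rows$label[rows$best], "b")
})

test_that("comparison report computes accuracy drops", {
  cen <- tibble::tibble(label = "resnet50", accuracy = 0.9886, f1 = 0.9885)
  fed <- tibble::tibble(label = c("no_privacy", "dp_sa"),
                        accuracy = c(0.9589, 0.9300),
                        f1 = c(0.9590, 0.9304))
  rep <- compare_report(cen, fed)
  expect_equal(rep$comparison$drop[1], 0.0297, tolerance = 1e-12)
  expect_equal(nrow(rep$comparison), nrow(fed))
  expect_equal(rep$privacy_utility$leakage, c(1.0, 0.2))
  # identical accuracies give zero drop
  same <- compare_report(tibble::tibble(label = "m", accuracy = 0.9, f1 = 0.9),
                         tibble::tibble(label = "no_privacy", accuracy = 0.9,
                                        f1 = 0.9))
  expect_equal(same$comparison$drop, 0)
})

test_that("metrics survive a CSV round trip at full precision", {
  dir <- withr::local_tempdir()
  m <- classification_metrics(c(1, 1, 2, 2),
                              rbind(c(0.9, 0.1), c(0.2, 0.8),
                                    c(0.3, 0.7), c(0.1, 0.9)),
                              label = "roundtrip")
  path <- file.path(dir, "metrics.csv")
  readr::write_csv(m, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  for (col in c("accuracy", "precision", "recall", "f1", "roc_auc")) {
    expect_equal(back[[col]], m[[col]], tolerance = 1e-12)
  }
})
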