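#' Multi-class classification metrics
#'
#' Predictions are the argmax of the score rows. Precision, recall and F1
#' are support-weighted averages over classes, which makes weighted recall
#' algebraically equal to accuracy. ROC-AUC is the support-weighted average
#' of one-vs-rest rank-based (Mann-Whitney) AUCs over the classes present in
#' `y_true`; absent classes are skipped with a warning.
#'
#' @param y_true Integer labels (1-based class indices).
#' @param y_score Numeric matrix, one row per sample, one column per class;
#'   rows must sum to 1 (within 1e-6).
#' @param label Configuration name recorded in the output row.
#' @param training_time_s Optional wall-clock seconds to record.
#' @return A one-row tibble: `label`, `accuracy`, `precision`, `recall`,
#'   `f1`, `roc_auc`, `training_time_s`.
#' @examples
#' scores <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
#' classification_metrics(c(1, 2), scores)
#' @export
classification_metrics <- function(y_true, y_score, label = "model",
                                   training_time_s = NA_real_) {
  y_true <- as.integer(y_true)
  y_score <- as.matrix(y_score)
  assert_that(length(y_true) == nrow(y_score),
              "y_true and y_score lengths must match")
  assert_that(all(abs(rowSums(y_score) - 1) < 1e-6),
              "score rows must sum to 1")
  n_class <- ncol(y_score)
  assert_that(all(y_true >= 1 & y_true <= n_class), "labels out of range")
  y_pred <- max.col(y_score, ties.method = "first")

  cm <- confusion_matrix(y_true, y_pred, n_class)
  support <- rowSums(cm)
  present <- which(support > 0)
  tp <- diag(cm)
  prec_c <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec_c <- ifelse(support > 0, tp / support, 0)
  f1_c <- ifelse(prec_c + rec_c > 0, 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  w <- support[present] / sum(support)

  if (length(present) < n_class) {
    warn(sprintf("ROC-AUC computed over %d of %d classes (others absent from y_true)",
                 length(present), n_class))
  }
  aucs <- vapply(present, function(cl) binary_auc(y_true == cl, y_score[, cl]),
                 numeric(1))

  tibble(label = label,
         accuracy = sum(tp) / length(y_true),
         precision = sum(w * prec_c[present]),
         recall = sum(w * rec_c[present]),
         f1 = sum(w * f1_c[present]),
         roc_auc = sum(w * aucs),
         training_time_s = training_time_s)
}

# Rank-based AUC (Mann-Whitney); 0.5 when one side is empty.
binary_auc <- function(pos, score) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(0.5)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion matrix
#'
#' @param y_true,y_pred Integer labels (1-based).
#' @param n_classes Number of classes C.
#' @return A C x C integer matrix; entry (i, j) counts samples of true class
#'   i predicted as class j, so row sums are the class supports.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  assert_that(length(y_true) == length(y_pred), "label vectors must align")
  assert_that(all(c(y_true, y_pred) >= 1) && all(c(y_true, y_pred) <= n_classes),
              "labels out of range")
  cm <- matrix(0L, n_classes, n_classes)
  for (k in seq_along(y_true)) {
    cm[y_true[k], y_pred[k]] <- cm[y_true[k], y_pred[k]] + 1L
  }
  dimnames(cm) <- list(true = seq_len(n_classes), pred = seq_len(n_classes))
  cm
}

#' Evaluate a model on a dataset
#'
#' @param model A trainable `fed_model`.
#' @param dataset A [labeled_dataset()].
#' @param stats Optional standardization statistics (as used in training).
#' @param label Row label for the metrics.
#' @return A one-row metrics tibble (see [classification_metrics()]).
#' @export
evaluate_model <- function(model, dataset, stats = NULL, label = model$arch) {
  arr <- standardize_array(dataset_array(dataset), stats)
  probs <- forward_model(model, arr)$probs
  classification_metrics(dataset$labels, probs, label = label)
}

#' Centralized training baseline
#'
#' Trains each requested architecture centrally on the training split,
#' evaluates on the test split, and flags the best model by F1 (ties broken
#' by first occurrence). Only architectures with materialized weights
#' (tiny_cnn) can be trained in-process.
#'
#' @param arch_names Character vector of registry architectures.
#' @param train,test [labeled_dataset()]s.
#' @param cfg A [training_config()]; `local_epochs` is the epoch budget.
#' @param out_csv Optional path; when given, the comparison table is written
#'   as CSV (`centralized_models_comparison.csv` convention).
#' @return A tibble with one metrics row per architecture plus a logical
#'   `best` column.
#' @export
run_centralized_baseline <- function(arch_names, train, test,
                                     cfg = training_config(), out_csv = NULL) {
  assert_that(length(arch_names) > 0, "need at least one architecture")
  rows <- purrr::map(arch_names, function(a) {
    model <- build_model(a, length(train$class_names), seed = cfg$seed)
    if (is.null(model$state)) {
      abort(sprintf(
        "'%s' has no in-process trainer (accounting stub); use tiny_cnn for desk-scale baselines", a))
    }
    stats <- if (cfg$standardize) dataset_stats(train) else NULL
    t0 <- proc.time()[["elapsed"]]
    upd <- local_train(model, train, cfg, client_id = 0L, round = 0L, stats = stats)
    elapsed <- proc.time()[["elapsed"]] - t0
    trained <- set_state(model, upd$state)
    evaluate_model(trained, test, stats = stats, label = a) |>
      dplyr::mutate(training_time_s = elapsed)
  }) |> dplyr::bind_rows()
  rows$best <- seq_len(nrow(rows)) == which.max(rows$f1)
  if (!is.null(out_csv)) readr::write_csv(rows, out_csv)
  rows
}

#' Compare centralized and federated results
#'
#' @param centralized Metrics tibble from [run_centralized_baseline()] (the
#'   best row is used as reference when several are given).
#' @param federated Metrics tibble with one row per federated configuration;
#'   a `label` column naming the privacy mode is expected.
#' @return A list of two tibbles: `comparison` (per federated configuration:
#'   centralized reference accuracy, federated accuracy, `drop` =
#'   centralized - federated) and `privacy_utility` (configuration, leakage
#'   score, accuracy, F1).
#' @examples
#' cen <- tibble::tibble(label = "tiny_cnn", accuracy = 0.9886, f1 = 0.9885)
#' fed <- tibble::tibble(label = "no_privacy", accuracy = 0.9589, f1 = 0.9590)
#' compare_report(cen, fed)$comparison$drop  # 0.0297
#' @export
compare_report <- function(centralized, federated) {
  assert_that(nrow(centralized) > 0 && nrow(federated) > 0,
              "both result tables must be nonempty")
  ref <- if ("best" %in% names(centralized)) {
    centralized[which(centralized$best)[1], ]
  } else {
    centralized[which.max(centralized$f1)[1], ]
  }
  comparison <- federated |>
    dplyr::transmute(configuration = .data$label,
                     centralized_model = ref$label,
                     centralized_accuracy = ref$accuracy,
                     federated_accuracy = .data$accuracy,
                     drop = ref$accuracy - .data$accuracy)
  privacy_utility <- federated |>
    dplyr::transmute(configuration = .data$label,
                     leakage = purrr::map_dbl(.data$label, function(l) {
                       if (l %in% privacy_modes()) leakage_score(l) else NA_real_
                     }),
                     accuracy = .data$accuracy, f1 = .data$f1)
  list(comparison = comparison, privacy_utility = privacy_utility)
}
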