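#' Federated experiment configuration
#'
#' Bundles the federation layout (5 simulated hospitals, 8 rounds, Dirichlet
#' alpha 0.5 by default), the privacy mode, the layer-skip ratio and the
#' local training recipe.
#'
#' @param arch_name Registry architecture (default `"tiny_cnn"`, the only
#'   in-process trainable backbone).
#' @param n_clients Number of clients (default 5).
#' @param rounds Number of federated rounds (default 8).
#' @param alpha Dirichlet concentration for the non-IID partition (default 0.5).
#' @param privacy_mode One of [privacy_modes()] (default `"no_privacy"`).
#' @param skip_ratio Layer-skip ratio in \[0, 1) (default 0).
#' @param training A [training_config()].
#' @param dp A [dp_config()] (used by the dp modes).
#' @param sa An [sa_config()] (used by the sa modes).
#' @param proto_merge `"merge"` (count-weighted merge of the server's carried
#'   prototypes with the round's client prototypes) or `"replace"`.
#' @param proto_align_weight Weight of the optional prototype-alignment
#'   regularizer added to the local loss (default 0 = off, the literal
#'   aggregation-only flow).
#' @param seed Master seed (default 42).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(arch_name = "tiny_cnn", n_clients = 5, rounds = 8,
                              alpha = 0.5, privacy_mode = "no_privacy",
                              skip_ratio = 0, training = training_config(),
                              dp = dp_config(), sa = sa_config(),
                              proto_merge = c("merge", "replace"),
                              proto_align_weight = 0, seed = 42) {
  check_privacy_mode(privacy_mode)
  assert_that(n_clients >= 1, "n_clients must be positive")
  assert_that(rounds >= 1, "rounds must be at least 1")
  assert_that(skip_ratio >= 0 && skip_ratio < 1, "skip_ratio must be in [0, 1)")
  assert_that(proto_align_weight >= 0, "proto_align_weight must be nonnegative")
  structure(list(arch_name = arch_name, n_clients = as.integer(n_clients),
                 rounds = as.integer(rounds), alpha = alpha,
                 privacy_mode = privacy_mode, skip_ratio = skip_ratio,
                 training = training, dp = dp, sa = sa,
                 proto_merge = match.arg(proto_merge),
                 proto_align_weight = proto_align_weight,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Sample-count-weighted federated averaging (FedAvg)
#'
#' The aggregated parameter state is the convex combination of the client
#' states with weights `n_k / n`, applied group by group.
#'
#' @param updates List of `client_update` objects (from [local_train()]),
#'   all sharing one architecture.
#' @return Named list of aggregated flat parameter vectors (a model state).
#' @examples
#' # two scalar clients, n = 1 and 3: 0 * 1/4 + 1 * 3/4 = 0.75
#' @export
fedavg <- function(updates) {
  assert_that(is.list(updates) && length(updates) >= 1, "need at least one update")
  states <- lapply(updates, function(u) u$state)
  ns <- vapply(updates, function(u) as.numeric(u$n_samples), numeric(1))
  assert_that(sum(ns) > 0, "all client sample counts are zero")
  gnames <- names(states[[1]])
  for (s in states) {
    assert_that(identical(names(s), gnames) &&
                  identical(lengths(s), lengths(states[[1]])),
                "client states have mismatched parameter groups")
  }
  w <- ns / sum(ns)
  out <- setNames(vector("list", length(gnames)), gnames)
  for (g in gnames) {
    acc <- numeric(length(states[[1]][[g]]))
    for (k in seq_along(states)) acc <- acc + w[k] * states[[k]][[g]]
    out[[g]] <- acc
  }
  out
}

#' Count-weighted class-prototype aggregation
#'
#' For every class held by at least one client, the global prototype is the
#' support-weighted mean of the client prototypes,
#' `P(c) = sum_k n_k(c) p_k(c) / sum_k n_k(c)`, with global support
#' `sum_k n_k(c)`. Classes absent everywhere are absent from the result.
#'
#' @param proto_sets List of `prototype_set`s with equal feature widths.
#' @return A merged `prototype_set`.
#' @export
aggregate_prototypes <- function(proto_sets) {
  assert_that(is.list(proto_sets) && length(proto_sets) >= 1,
              "need at least one prototype set")
  proto_sets <- purrr::keep(proto_sets, function(p) !is.null(p) && nrow(p) > 0)
  assert_that(length(proto_sets) >= 1, "all prototype sets are empty")
  widths <- unique(unlist(lapply(proto_sets, function(p) lengths(p$prototype))))
  assert_that(length(widths) == 1, "prototype feature widths differ across sets")
  all_rows <- dplyr::bind_rows(lapply(proto_sets, function(p) {
    tibble(class = p$class, n = p$n, prototype = p$prototype)
  }))
  merged <- all_rows |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      prototype = list(Reduce(`+`, purrr::map2(.data$prototype, .data$n, `*`)) / sum(.data$n)),
      n = sum(.data$n), .groups = "drop") |>
    dplyr::arrange(.data$class)
  prototype_set(merged$class, merged$n, merged$prototype)
}

#' Execute one federated round
#'
#' Broadcast the global state, run [local_train()] on every client shard,
#' apply the configured privacy mechanisms (DP noising of trainable-group
#' deltas and prototypes; secure-aggregation masking of the weighted client
#' states), aggregate with [fedavg()] and [aggregate_prototypes()], and
#' evaluate the new global model on the held-out test set.
#'
#' @param model Global `fed_model` (skip plan already applied).
#' @param protos Carried global `prototype_set` or NULL.
#' @param config An [experiment_config()].
#' @param partition A `partition_plan` over `train`.
#' @param train,test [labeled_dataset()]s.
#' @param round Round index (1-based).
#' @param stats Shared standardization statistics.
#' @return List: `model` (updated global), `protos`, `metrics` (one-row
#'   tibble), `per_round_MB`.
#' @export
run_round <- function(model, protos, config, partition, train, test,
                      round = 1L, stats = NULL) {
  k <- config$n_clients
  assert_that(partition$n_clients == k, "partition does not cover the configured clients")
  mode <- config$privacy_mode
  use_dp <- mode %in% c("dp_only", "dp_sa")
  use_sa <- mode %in% c("sa_only", "dp_sa")
  trainable <- setdiff(model$inventory$group, model$frozen)

  bcast_protos <- if (config$proto_align_weight > 0) protos else NULL
  updates <- vector("list", k)
  for (cl in seq_len(k)) {
    shard <- tryCatch(dataset_subset(train, partition$assignments[[cl]]),
                      error = function(e) abort(sprintf(
                        "client %d failed: %s", cl, conditionMessage(e))))
    updates[[cl]] <- local_train(model, shard, config$training,
                                 client_id = cl, round = round, stats = stats,
                                 broadcast_protos = bcast_protos,
                                 proto_align_weight = config$proto_align_weight)
  }

  if (use_dp) {
    dp <- config$dp
    for (cl in seq_len(k)) {
      delta <- flatten_state(updates[[cl]]$state[trainable]) -
        flatten_state(model$state[trainable])
      noised <- clip_and_noise(delta, dp, stream = derive_seed(round, cl))
      new_flat <- flatten_state(model$state[trainable]) + noised
      updates[[cl]]$state[trainable] <-
        unflatten_state(new_flat, model$state[trainable])
      updates[[cl]]$prototypes <-
        noise_prototypes(updates[[cl]]$prototypes, dp,
                         stream = derive_seed(round, cl, 2L))
    }
  }

  if (use_sa && k >= 2) {
    # clients upload weighted, pairwise-masked states; the server only sums
    ns <- vapply(updates, function(u) u$n_samples, numeric(1))
    w <- ns / sum(ns)
    masked <- secure_mask(
      purrr::imap(updates, function(u, cl) w[cl] * flatten_state(u$state)),
      config$sa, round = round)
    agg_flat <- Reduce(`+`, masked)
    new_state <- unflatten_state(agg_flat, model$state)
  } else {
    new_state <- fedavg(updates)
  }
  # frozen groups never travel; keep the broadcast values exactly
  for (g in model$frozen) new_state[[g]] <- model$state[[g]]
  model <- set_state(model, new_state)

  client_protos <- lapply(updates, function(u) u$prototypes)
  round_protos <- aggregate_prototypes(client_protos)
  protos <- if (is.null(protos) || config$proto_merge == "replace") {
    round_protos
  } else {
    aggregate_prototypes(list(protos, round_protos))
  }

  metrics <- evaluate_model(model, test, stats = stats, label = mode)
  prc <- per_round_cost(total_params(model), config$skip_ratio,
                        sa_enabled = use_sa,
                        overhead_factor = config$sa$overhead_factor)
  list(model = model, protos = protos, metrics = metrics, per_round_MB = prc)
}

#' Run a full federated experiment
#'
#' From a labeled dataset: stratified 80/20 train/test split, Dirichlet
#' non-IID partition of the training part across clients, fresh model build,
#' skip-plan application, then `rounds` federated rounds via [run_round()].
#' Fully reproducible under the config seed.
#'
#' @param config An [experiment_config()].
#' @param data Either a [labeled_dataset()] (split and partitioned
#'   internally) or a list with `train`, `test` and optionally `partition`.
#' @param out_dir Optional directory; when given, per-round metrics and the
#'   summary row are written as CSV (`federated_learning_results.csv` and
#'   `federated_rounds_<mode>.csv`).
#' @param init_model Optional trained `fed_model` to start from (the
#'   warm-start flow of [run_federated_suite()], where the federated stage
#'   continues from the best centralized baseline); NULL builds a fresh
#'   model under the config seed.
#' @return A `fed_experiment` object: fields `rounds` (per-round metrics
#'   tibble with `round`, metrics columns, `per_round_MB`), `summary`
#'   (one-row tibble including leakage score and total communication),
#'   `model`, `protos`, `config`, `stats`.
#' @export
run_experiment <- function(config, data, out_dir = NULL, init_model = NULL) {
  assert_that(inherits(config, "experiment_config"), "config must be an experiment_config")
  t0 <- proc.time()[["elapsed"]]
  if (inherits(data, "labeled_dataset")) {
    sp <- stratified_split(data, 0.8, seed = config$seed)
    train <- sp$train; test <- sp$test
    partition <- dirichlet_partition(train, config$n_clients, config$alpha,
                                     seed = config$seed)
  } else {
    train <- data$train; test <- data$test
    partition <- data$partition %||%
      dirichlet_partition(train, config$n_clients, config$alpha,
                          seed = config$seed)
  }
  assert_that(inherits(train, "labeled_dataset") && inherits(test, "labeled_dataset"),
              "data must provide labeled train and test sets")

  stats <- if (config$training$standardize) dataset_stats(train) else NULL
  # shuffle streams follow the experiment seed so reruns with a new seed
  # re-randomize the data loaders, not only the partition and init
  config$training$seed <- derive_seed(config$seed, config$training$seed)
  model <- if (is.null(init_model)) {
    build_model(config$arch_name, length(train$class_names), seed = config$seed)
  } else {
    assert_that(inherits(init_model, "fed_model") && !is.null(init_model$state),
                "init_model must be a trained fed_model")
    assert_that(identical(init_model$arch, config$arch_name),
                "init_model architecture does not match the config")
    init_model
  }
  plan <- make_skip_plan(model$inventory, config$skip_ratio)
  model <- apply_skip_plan(model, plan)
  if (plan$trainable_params != round(plan$total_params * (1 - config$skip_ratio))) {
    message(sprintf(
      "skip plan: greedy freezing trains %s params; continuous cost accounting assumes %s",
      format(plan$trainable_params, big.mark = ","),
      format(round(plan$total_params * (1 - config$skip_ratio)), big.mark = ",")))
  }

  protos <- NULL
  round_rows <- vector("list", config$rounds)
  for (r in seq_len(config$rounds)) {
    res <- run_round(model, protos, config, partition, train, test,
                     round = r, stats = stats)
    model <- res$model; protos <- res$protos
    round_rows[[r]] <- dplyr::mutate(res$metrics, round = r,
                                     per_round_MB = res$per_round_MB,
                                     .before = 1)
  }
  rounds_tbl <- dplyr::bind_rows(round_rows)
  elapsed <- proc.time()[["elapsed"]] - t0

  final <- rounds_tbl[nrow(rounds_tbl), ]
  summary <- tibble(
    configuration = config$privacy_mode,
    accuracy = final$accuracy, precision = final$precision,
    recall = final$recall, f1 = final$f1, roc_auc = final$roc_auc,
    training_time_s = elapsed,
    leakage = leakage_score(config$privacy_mode),
    per_round_MB = final$per_round_MB,
    total_MB = total_cost(final$per_round_MB, config$n_clients, config$rounds))

  out <- structure(list(rounds = rounds_tbl, summary = summary, model = model,
                        protos = protos, config = config, stats = stats,
                        partition = partition),
                   class = "fed_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(rounds_tbl, file.path(
      out_dir, sprintf("federated_rounds_%s.csv", config$privacy_mode)))
    summary_path <- file.path(out_dir, "federated_learning_results.csv")
    if (file.exists(summary_path)) {
      old <- readr::read_csv(summary_path, show_col_types = FALSE)
      readr::write_csv(dplyr::bind_rows(old, summary), summary_path)
    } else {
      readr::write_csv(summary, summary_path)
    }
  }
  out
}

#' @export
print.fed_experiment <- function(x, ...) {
  cat(sprintf("<fed_experiment> %s, %d clients, %d rounds (%s)\n",
              x$config$arch_name, x$config$n_clients, x$config$rounds,
              x$config$privacy_mode))
  print(x$summary)
  invisible(x)
}

#' Per-round metrics of a federated experiment
#' @param x A `fed_experiment`.
#' @param ... Unused.
#' @return Tibble with one row per round.
#' @exportS3Method generics::tidy
tidy.fed_experiment <- function(x, ...) x$rounds

#' One-row summary of a federated experiment
#' @param x A `fed_experiment`.
#' @param ... Unused.
#' @return One-row tibble (configuration, metrics, leakage, communication).
#' @exportS3Method generics::glance
glance.fed_experiment <- function(x, ...) x$summary

#' Plot test accuracy over federated rounds
#' @param object A `fed_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fed_experiment <- function(object, ...) {
  ggplot2::ggplot(object$rounds, ggplot2::aes(x = .data$round, y = .data$accuracy)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(colour = "#2c7fb8") +
    ggplot2::labs(x = "federated round", y = "test accuracy",
                  title = sprintf("%s (%s)", object$config$arch_name,
                                  object$config$privacy_mode)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Nearest-prototype classification
#'
#' Optional evaluator that assigns each sample to the class of the nearest
#' aggregated prototype in feature space (Euclidean distance).
#'
#' @param model A trainable `fed_model`.
#' @param protos A `prototype_set`.
#' @param dataset A [labeled_dataset()].
#' @param stats Optional standardization statistics.
#' @return Integer vector of predicted class indices.
#' @export
predict_nearest_prototype <- function(model, protos, dataset, stats = NULL) {
  assert_that(nrow(protos) > 0, "prototype set is empty")
  arr <- standardize_array(dataset_array(dataset), stats)
  feats <- forward_model(model, arr)$features
  pm <- do.call(rbind, protos$prototype)
  d2 <- outer(rowSums(feats^2), rep(1, nrow(pm))) -
    2 * feats %*% t(pm) + outer(rep(1, nrow(feats)), rowSums(pm^2))
  protos$class[max.col(-d2, ties.method = "first")]
}

#' Run the full centralized-then-federated experiment pipeline
#'
#' The complete simulation flow: (1) split the data 80/20; (2) train the
#' centralized baseline for `baseline_epochs` and record its metrics; (3)
#' for each privacy configuration, run a federated experiment of `rounds`
#' rounds warm-started from the baseline model (the federated stage
#' continues from the best centrally trained model, the desk-scale analogue
#' of starting from a pretrained backbone), with layer skipping at
#' `skip_ratio`; (4) assemble the per-configuration summary and the
#' centralized-vs-federated comparison. One Dirichlet partition (under
#' `seed`) is shared by all configurations so they differ only in their
#' privacy mechanism.
#'
#' @param data A [labeled_dataset()].
#' @param modes Privacy configurations to run (default all four).
#' @param arch_name Trainable registry architecture (default `"tiny_cnn"`).
#' @param skip_ratio Layer-skip ratio for the federated stage (default 0.4,
#'   the setting behind the reported per-round communication costs).
#' @param n_clients,rounds,alpha Federation layout (defaults 5, 8, 0.5).
#' @param training A [training_config()] for the federated stage.
#' @param baseline_epochs Centralized baseline epoch budget (default 20,
#'   the desk-scale plateau).
#' @param dp,sa Privacy mechanism configurations.
#' @param seed Master seed (default 42).
#' @param out_dir Optional output directory for the CSV artifacts
#'   (`centralized_models_comparison.csv`, `federated_learning_results.csv`).
#' @return A `fed_suite`: list with `baseline` (metrics row), `experiments`
#'   (named list of `fed_experiment`), `summary` (one row per mode),
#'   `comparison` (see [compare_report()]).
#' @examples
#' \donttest{
#' ds <- generate_synthetic_dataset(40, image_size = c(32, 32), seed = 42)
#' suite <- run_federated_suite(ds, modes = "no_privacy", rounds = 2,
#'                              baseline_epochs = 5, seed = 42)
#' suite$summary
#' }
#' @export
run_federated_suite <- function(data, modes = privacy_modes(),
                                arch_name = "tiny_cnn", skip_ratio = 0.4,
                                n_clients = 5, rounds = 8, alpha = 0.5,
                                training = training_config(),
                                baseline_epochs = 20,
                                dp = dp_config(), sa = sa_config(),
                                seed = 42, out_dir = NULL) {
  assert_that(all(modes %in% privacy_modes()),
              sprintf("modes must be among: %s", paste(privacy_modes(), collapse = ", ")))
  sp <- stratified_split(data, 0.8, seed = seed)
  stats <- if (training$standardize) dataset_stats(sp$train) else NULL
  partition <- dirichlet_partition(sp$train, n_clients, alpha, seed = seed)

  base_cfg <- training
  base_cfg$local_epochs <- as.integer(baseline_epochs)
  base_cfg$seed <- derive_seed(seed, 271L)
  t0 <- proc.time()[["elapsed"]]
  model <- build_model(arch_name, length(data$class_names), seed = seed)
  assert_that(!is.null(model$state),
              sprintf("'%s' has no in-process trainer; use tiny_cnn", arch_name))
  base_upd <- local_train(model, sp$train, base_cfg, client_id = 0L,
                          round = 0L, stats = stats)
  baseline_model <- set_state(model, base_upd$state)
  baseline <- evaluate_model(baseline_model, sp$test, stats = stats,
                             label = arch_name) |>
    dplyr::mutate(training_time_s = proc.time()[["elapsed"]] - t0, best = TRUE)

  experiments <- list()
  for (mode in modes) {
    cfg <- experiment_config(arch_name = arch_name, n_clients = n_clients,
                             rounds = rounds, alpha = alpha,
                             privacy_mode = mode, skip_ratio = skip_ratio,
                             training = training, dp = dp, sa = sa, seed = seed)
    experiments[[mode]] <- run_experiment(
      cfg, list(train = sp$train, test = sp$test, partition = partition),
      out_dir = out_dir, init_model = baseline_model)
  }
  summary <- dplyr::bind_rows(lapply(experiments, function(e) e$summary))
  fed_rows <- summary |>
    dplyr::transmute(label = .data$configuration, accuracy = .data$accuracy,
                     f1 = .data$f1)
  comparison <- compare_report(baseline, fed_rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(baseline, file.path(out_dir, "centralized_models_comparison.csv"))
    readr::write_csv(comparison$privacy_utility,
                     file.path(out_dir, "privacy_utility.csv"))
    readr::write_csv(comparison$comparison,
                     file.path(out_dir, "centralized_vs_federated.csv"))
  }
  structure(list(baseline = baseline, experiments = experiments,
                 summary = summary, comparison = comparison,
                 seed = seed),
            class = "fed_suite")
}

#' @export
print.fed_suite <- function(x, ...) {
  cat(sprintf("<fed_suite> baseline acc %.4f; %d federated configurations\n",
              x$baseline$accuracy, nrow(x$summary)))
  print(x$summary)
  invisible(x)
}

#' Per-configuration summary of a pipeline run
#' @param x A `fed_suite`.
#' @param ... Unused.
#' @return The per-configuration summary tibble.
#' @exportS3Method generics::tidy
tidy.fed_suite <- function(x, ...) x$summary

#' Plot the privacy-utility trade-off of a pipeline run
#' @param object A `fed_suite`.
#' @param ... Unused.
#' @return A ggplot object (leakage score vs accuracy).
#' @exportS3Method ggplot2::autoplot
autoplot.fed_suite <- function(object, ...) {
  ggplot2::ggplot(object$comparison$privacy_utility,
                  ggplot2::aes(x = .data$leakage, y = .data$accuracy,
                               label = .data$configuration)) +
    ggplot2::geom_point(size = 2, colour = "#d95f02") +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "privacy leakage score", y = "test accuracy") +
    ggplot2::xlim(0, 1.05) +
    ggplot2::theme_minimal()
}
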