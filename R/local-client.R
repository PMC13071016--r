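#' Local training configuration
#'
#' Defaults follow the simulated-hospital training recipe: Adam with learning
#' rate 0.001 and weight decay 1e-4 (the L2 regularization of the local
#' objective), batch size 64, 5 local epochs per federated round,
#' cross-entropy loss. `standardize` rescales inputs with dataset mean/sd
#' before the backbone; `augment` enables random training-time transforms
#' (rotation up to 15 degrees, horizontal flip, zoom up to 10%).
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param weight_decay L2 coefficient added to gradients (default 1e-4).
#' @param batch_size Mini-batch size (default 64).
#' @param local_epochs Passes over the shard per round (default 5).
#' @param seed Integer seed controlling shuffling and augmentation (default 42).
#' @param augment Apply random training-time augmentation (default FALSE).
#' @param standardize Standardize inputs with dataset statistics (default TRUE).
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 0.001, weight_decay = 1e-4,
                            batch_size = 64, local_epochs = 5, seed = 42,
                            augment = FALSE, standardize = TRUE) {
  assert_that(learning_rate > 0, "learning_rate must be positive")
  assert_that(weight_decay >= 0, "weight_decay must be nonnegative")
  assert_that(batch_size >= 1, "batch_size must be at least 1")
  assert_that(local_epochs >= 0, "local_epochs must be nonnegative")
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 local_epochs = as.integer(local_epochs), loss = "cross_entropy",
                 seed = as.integer(seed), augment = isTRUE(augment),
                 standardize = isTRUE(standardize)),
            class = "training_config")
}

# Dataset intensity statistics used for standardization; computed once where
# a dataset enters an experiment and shared by trainer and evaluator.
dataset_stats <- function(dataset) {
  px <- unlist(lapply(dataset$images, as.numeric), use.names = FALSE)
  list(mean = mean(px), sd = max(stats::sd(px), 1e-8))
}

standardize_array <- function(arr, stats) {
  if (is.null(stats)) return(arr)
  (arr - stats$mean) / stats$sd
}

#' Train a model locally on a client shard
#'
#' Runs `cfg$local_epochs` epochs of mini-batch Adam on the shard, starting
#' from the model's current (global) parameter state. Groups frozen by an
#' applied [make_skip_plan()] receive no updates and are returned
#' bit-identical. After training, class prototypes are extracted from the
#' final local model. The whole procedure is a pure function of
#' (state, shard, cfg, client_id, round).
#'
#' @param model A trainable `fed_model` carrying the broadcast global state
#'   (freeze groups beforehand with [apply_skip_plan()]).
#' @param shard The client's [labeled_dataset()] (nonempty).
#' @param cfg A [training_config()].
#' @param client_id,round Integers identifying the client and federated
#'   round; they seed the data-loader shuffle so repeated rounds differ
#'   deterministically.
#' @param stats Optional dataset statistics (list with `mean`, `sd`) shared
#'   across the federation; defaults to the shard's own statistics when
#'   standardization is on.
#' @param broadcast_protos Optional broadcast `prototype_set`; with
#'   `proto_align_weight > 0` a squared-distance penalty pulling each
#'   sample's features towards its class prototype is added to the loss.
#' @param proto_align_weight Weight of that alignment penalty (default 0).
#' @return A `client_update`: list with `client_id`, `state` (post-training
#'   parameter state), `prototypes` (a prototype set, see
#'   [extract_prototypes()]), `n_samples`, and `loss` (mean loss per epoch).
#' @export
local_train <- function(model, shard, cfg = training_config(), client_id = 1L,
                        round = 1L, stats = NULL, broadcast_protos = NULL,
                        proto_align_weight = 0) {
  assert_that(inherits(shard, "labeled_dataset") && length(shard$labels) > 0,
              "shard must be a nonempty labeled_dataset")
  assert_that(inherits(cfg, "training_config"), "cfg must be a training_config")
  assert_that(!is.null(model$state), "model must have materialized weights")
  assert_that(max(shard$labels) <= model$num_classes,
              "shard labels exceed the model's class count")
  if (cfg$standardize && is.null(stats)) stats <- dataset_stats(shard)
  if (!cfg$standardize) stats <- NULL

  proto_mat <- NULL; proto_mask <- NULL
  if (!is.null(broadcast_protos) && proto_align_weight > 0 &&
      nrow(broadcast_protos) > 0) {
    proto_mat <- matrix(0, model$num_classes, model$feature_width)
    proto_mask <- numeric(model$num_classes)
    for (i in seq_len(nrow(broadcast_protos))) {
      cl <- broadcast_protos$class[i]
      proto_mat[cl, ] <- broadcast_protos$prototype[[i]]
      proto_mask[cl] <- 1
    }
  }

  state <- model$state
  trainable <- setdiff(names(state), model$frozen)
  n <- length(shard$labels)
  y0 <- shard$labels - 1L

  # Adam moments per trainable group
  m <- lapply(state[trainable], function(v) numeric(length(v)))
  v <- lapply(state[trainable], function(v) numeric(length(v)))
  t_step <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  epoch_loss <- numeric(cfg$local_epochs)

  if (cfg$local_epochs > 0 && length(trainable) > 0) {
    for (epoch in seq_len(cfg$local_epochs)) {
      ord <- with_seed(derive_seed(cfg$seed, client_id, round, epoch), sample.int(n))
      losses <- numeric(0)
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        arr <- dataset_array(shard, idx)
        if (cfg$augment) {
          arr <- with_seed(derive_seed(cfg$seed, client_id, round, epoch, start),
                           augment_array(arr))
        }
        arr <- standardize_array(arr, stats)
        bp <- cpp_tiny_grad(arr, y0[idx], state, model$num_classes,
                            proto = proto_mat, proto_mask = proto_mask,
                            proto_w = proto_align_weight)
        losses <- c(losses, bp$loss)
        t_step <- t_step + 1
        corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
        for (g in trainable) {
          grad <- bp$grads[[g]] + cfg$weight_decay * state[[g]]
          m[[g]] <- b1 * m[[g]] + (1 - b1) * grad
          v[[g]] <- b2 * v[[g]] + (1 - b2) * grad^2
          state[[g]] <- state[[g]] -
            cfg$learning_rate * (m[[g]] / corr1) / (sqrt(v[[g]] / corr2) + eps)
        }
      }
      epoch_loss[epoch] <- mean(losses)
    }
  }

  trained <- set_state(model, state)
  protos <- extract_prototypes(trained, shard, stats = stats)
  structure(list(client_id = as.integer(client_id), state = state,
                 prototypes = protos, n_samples = n, loss = epoch_loss),
            class = "client_update")
}

#' @export
print.client_update <- function(x, ...) {
  cat(sprintf("<client_update> client %d, n = %d, final loss %.4f\n",
              x$client_id, x$n_samples,
              if (length(x$loss)) x$loss[length(x$loss)] else NA_real_))
  invisible(x)
}

#' Extract class prototypes from a model
#'
#' The prototype of class c is the arithmetic mean of the penultimate feature
#' vectors of the shard's class-c samples; its support count is the class-c
#' sample count. Classes without samples in the shard are absent.
#'
#' @param model A trainable `fed_model`.
#' @param shard A nonempty [labeled_dataset()].
#' @param stats Optional standardization statistics (must match training).
#' @return A `prototype_set`: tibble with columns `class` (integer), `n`
#'   (support count) and `prototype` (list-column of feature vectors).
#' @export
extract_prototypes <- function(model, shard, stats = NULL) {
  assert_that(inherits(shard, "labeled_dataset") && length(shard$labels) > 0,
              "shard must be a nonempty labeled_dataset")
  arr <- standardize_array(dataset_array(shard), stats)
  feats <- forward_model(model, arr)$features
  classes <- sort(unique(shard$labels))
  prototype_set(
    class = classes,
    n = vapply(classes, function(cl) sum(shard$labels == cl), integer(1)),
    prototype = lapply(classes, function(cl) {
      colMeans(feats[shard$labels == cl, , drop = FALSE])
    }))
}

#' Construct a prototype set
#' @param class Integer class indices.
#' @param n Integer support counts (all at least 1).
#' @param prototype List of equal-length numeric feature vectors.
#' @return A `prototype_set` tibble.
#' @export
prototype_set <- function(class, n, prototype) {
  assert_that(length(class) == length(n) && length(n) == length(prototype),
              "class, n and prototype must align")
  assert_that(all(n >= 1), "support counts must be at least 1")
  widths <- lengths(prototype)
  assert_that(length(unique(widths)) <= 1, "prototype vectors must share one width")
  out <- tibble(class = as.integer(class), n = as.integer(n),
                prototype = prototype)
  class(out) <- c("prototype_set", class(out))
  out
}

# ---- training-time augmentation ------------------------------------------

# Random rotation (±15 deg), horizontal flip (p = 0.5), zoom (±10%), applied
# per image with nearest-neighbour resampling under the caller's RNG state.
augment_array <- function(arr) {
  d <- dim(arr)
  for (k in seq_len(d[3])) {
    ang <- runif(1, -15, 15) * pi / 180
    zoom <- runif(1, 0.9, 1.1)
    flip <- runif(1) < 0.5
    arr[, , k] <- affine_resample(arr[, , k], ang, zoom, flip)
  }
  arr
}

affine_resample <- function(img, angle, zoom, flip) {
  h <- nrow(img); w <- ncol(img)
  ci <- (h + 1) / 2; cj <- (w + 1) / 2
  ii <- matrix(seq_len(h) - ci, h, w)
  jj <- matrix(rep(seq_len(w) - cj, each = h), h, w)
  # inverse map: rotate by -angle, scale by 1/zoom
  si <- (cos(angle) * ii + sin(angle) * jj) / zoom + ci
  sj <- (-sin(angle) * ii + cos(angle) * jj) / zoom + cj
  if (flip) sj <- w + 1 - sj
  si <- pmin(pmax(round(si), 1), h)
  sj <- pmin(pmax(round(sj), 1), w)
  matrix(img[cbind(as.vector(si), as.vector(sj))], h, w)
}
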