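# Registry of classification backbones. `tiny_cnn` is fully trainable
# in-process (C++ backend); the large backbones are analytic entries that
# expose the layer inventory and parameter accounting needed by the skip
# planner and the communication-cost model. Their stage parameter counts
# follow the standard published topologies with the 1000-way classifier
# replaced by a `num_classes`-way linear layer.

tiny_cnn_channels <- c(8L, 16L, 32L)

arch_registry <- function() {
  tc <- tiny_cnn_channels
  list(
    tiny_cnn = list(
      trainable = TRUE, feature_width = tc[3],
      groups = function(nc) tibble(
        group = c("conv1", "conv2", "conv3", "head"),
        params = c(tc[1] * 9 + tc[1],
                   tc[2] * tc[1] * 9 + tc[2],
                   tc[3] * tc[2] * 9 + tc[3],
                   tc[3] * nc + nc),
        is_head = c(FALSE, FALSE, FALSE, TRUE))),
    resnet50 = list(
      trainable = FALSE, feature_width = 2048L,
      groups = function(nc) tibble(
        group = c("stem", "layer1", "layer2", "layer3", "layer4", "head"),
        params = c(9536, 215808, 1219584, 7098368, 14964736, 2048 * nc + nc),
        is_head = c(rep(FALSE, 5), TRUE))),
    efficientnet_b0 = list(
      trainable = FALSE, feature_width = 1280L,
      groups = function(nc) tibble(
        group = c("features", "head"),
        params = c(4007548, 1280 * nc + nc),
        is_head = c(FALSE, TRUE))),
    convnext = list(
      trainable = FALSE, feature_width = 768L,
      groups = function(nc) tibble(
        group = c("features", "head"),
        params = c(27820128, 768 * nc + nc),
        is_head = c(FALSE, TRUE))),
    swin = list(
      trainable = FALSE, feature_width = 768L,
      groups = function(nc) tibble(
        group = c("features", "head"),
        params = c(27519354, 768 * nc + nc),
        is_head = c(FALSE, TRUE)))
  )
}

#' Layer inventory of a registered architecture
#'
#' @param arch_name One of `"tiny_cnn"`, `"resnet50"`, `"efficientnet_b0"`,
#'   `"convnext"`, `"swin"`.
#' @param num_classes Number of output classes (sets the head size).
#' @return A tibble with columns `group`, `params`, `is_head`, ordered from
#'   input to classifier head; exactly the last group is the head.
#' @export
layer_inventory <- function(arch_name, num_classes = 4) {
  reg <- arch_registry()
  if (!arch_name %in% names(reg)) {
    abort(sprintf("unknown architecture '%s'; registry: %s",
                  arch_name, paste(names(reg), collapse = ", ")))
  }
  assert_that(num_classes >= 2, "num_classes must be at least 2")
  reg[[arch_name]]$groups(as.integer(num_classes))
}

#' Build a model from the registry
#'
#' `tiny_cnn` is returned with deterministically initialized weights (He
#' initialization for conv blocks, zero-initialized head) and can be trained,
#' evaluated and used for feature extraction. The large backbones are
#' returned as accounting stubs: their layer inventory, parameter counts and
#' feature width are exact, but weights are not materialized (no pretrained
#' checkpoints are bundled), so they serve the skip planner and cost model
#' rather than the in-process trainer.
#'
#' @param arch_name Registry architecture name.
#' @param num_classes Number of classes (at least 2).
#' @param seed Integer seed for weight initialization.
#' @return A `fed_model`: list with `arch`, `num_classes`, `inventory`,
#'   `feature_width`, `state` (named list of flat parameter vectors, or NULL
#'   for stubs) and `frozen` (character vector of frozen group names).
#' @examples
#' m <- build_model("tiny_cnn", num_classes = 4, seed = 42)
#' total_params(m)
#' @export
build_model <- function(arch_name, num_classes = 4, seed = 42) {
  inv <- layer_inventory(arch_name, num_classes)
  reg <- arch_registry()[[arch_name]]
  state <- NULL
  if (isTRUE(reg$trainable)) {
    state <- with_seed(derive_seed(seed, 11L), init_tiny_state(num_classes))
  }
  structure(list(arch = arch_name, num_classes = as.integer(num_classes),
                 inventory = inv, feature_width = reg$feature_width,
                 state = state, frozen = character(0)),
            class = "fed_model")
}

init_tiny_state <- function(nc) {
  tc <- tiny_cnn_channels
  he <- function(cout, cin) {
    w <- rnorm(cout * cin * 9, 0, sqrt(2 / (cin * 9)))
    c(w, rep(0, cout))
  }
  # zero-initialized head: uniform initial class probabilities, so the
  # first optimizer steps are not spent undoing a random saturated softmax
  list(conv1 = he(tc[1], 1L), conv2 = he(tc[2], tc[1]),
       conv3 = he(tc[3], tc[2]), head = rep(0, tc[3] * nc + nc))
}

#' @export
print.fed_model <- function(x, ...) {
  cat(sprintf("<fed_model> %s, %d classes, %s params (%s)\n",
              x$arch, x$num_classes, format(total_params(x), big.mark = ","),
              if (is.null(x$state)) "accounting stub" else "weights materialized"))
  print(x$inventory)
  if (length(x$frozen)) cat("frozen:", paste(x$frozen, collapse = ", "), "\n")
  invisible(x)
}

#' Total parameter count of a model or inventory
#' @param x A `fed_model` or an inventory tibble.
#' @return Integer-valued double: sum of all group parameter counts.
#' @export
total_params <- function(x) {
  inv <- if (inherits(x, "fed_model")) x$inventory else x
  sum(inv$params)
}

#' Plan which layer groups to freeze (layer skipping)
#'
#' Freezes parameter groups greedily in forward order (earliest layers first,
#' the transfer-learning convention) until the cumulative frozen parameter
#' count reaches `skip_ratio * total_params`. The classifier head is never
#' frozen, so the trainable count never drops below the head size.
#'
#' @param inventory An inventory tibble from [layer_inventory()] (or a
#'   `fed_model`, whose inventory is used).
#' @param skip_ratio Fraction of parameters to freeze, in \[0, 1).
#' @return A `skip_plan`: list with `skip_ratio`, `frozen_groups`,
#'   `total_params`, `frozen_params`, `trainable_params`.
#' @examples
#' make_skip_plan(layer_inventory("resnet50", 4), skip_ratio = 0.4)
#' @export
make_skip_plan <- function(inventory, skip_ratio) {
  if (inherits(inventory, "fed_model")) inventory <- inventory$inventory
  assert_that(skip_ratio >= 0 && skip_ratio < 1,
              "skip_ratio must be in [0, 1): the classifier head stays trainable")
  total <- sum(inventory$params)
  target <- skip_ratio * total
  frozen <- character(0)
  cum <- 0
  if (target > 0) {
    for (i in seq_len(nrow(inventory))) {
      if (inventory$is_head[i]) next
      frozen <- c(frozen, inventory$group[i])
      cum <- cum + inventory$params[i]
      if (cum >= target) break
    }
  }
  structure(list(skip_ratio = skip_ratio, frozen_groups = frozen,
                 total_params = total, frozen_params = cum,
                 trainable_params = total - cum),
            class = "skip_plan")
}

#' @export
print.skip_plan <- function(x, ...) {
  cat(sprintf("<skip_plan> ratio %.2f: frozen %s of %s params (%s); %s trainable\n",
              x$skip_ratio,
              format(x$frozen_params, big.mark = ","),
              format(x$total_params, big.mark = ","),
              if (length(x$frozen_groups)) paste(x$frozen_groups, collapse = ", ") else "no groups",
              format(x$trainable_params, big.mark = ",")))
  invisible(x)
}

#' Apply a skip plan to a model
#'
#' Marks the plan's groups as frozen on the model; frozen groups receive no
#' updates during [local_train()] and are returned bit-identical.
#'
#' @param model A `fed_model`.
#' @param plan A `skip_plan` built from the same architecture's inventory.
#' @return The model with its `frozen` field set.
#' @export
apply_skip_plan <- function(model, plan) {
  assert_that(inherits(model, "fed_model") && inherits(plan, "skip_plan"),
              "need a fed_model and a skip_plan")
  bad <- setdiff(plan$frozen_groups, model$inventory$group)
  if (length(bad) > 0) {
    abort(sprintf("skip plan groups not in this architecture: %s",
                  paste(bad, collapse = ", ")))
  }
  if (plan$total_params != total_params(model)) {
    abort("skip plan was built for a different architecture (parameter totals differ)")
  }
  model$frozen <- plan$frozen_groups
  model
}

#' Extract penultimate-layer features
#'
#' Runs the backbone in evaluation mode and returns the globally pooled
#' penultimate activations, one fixed-length vector per image.
#'
#' @param model A trainable `fed_model` (weights materialized).
#' @param images A [labeled_dataset()], a list of image matrices, or an
#'   H x W x N array.
#' @return A numeric matrix, one row per image, `model$feature_width` columns.
#' @export
extract_features <- function(model, images) {
  arr <- images_to_array(images)
  assert_that(dim(arr)[3] > 0, "empty batch")
  fw <- forward_model(model, arr)
  fw$features
}

images_to_array <- function(images) {
  if (inherits(images, "labeled_dataset")) return(dataset_array(images))
  if (is.list(images)) {
    assert_that(length(images) > 0, "empty batch")
    arr <- array(0, c(dim(images[[1]]), length(images)))
    for (k in seq_along(images)) arr[, , k] <- images[[k]]
    return(arr)
  }
  if (is.array(images) && length(dim(images)) == 2) {
    return(array(images, c(dim(images), 1)))
  }
  assert_that(is.array(images) && length(dim(images)) == 3,
              "images must be a dataset, list of matrices, or H x W x N array")
  images
}

forward_model <- function(model, arr) {
  assert_that(inherits(model, "fed_model"), "model must be a fed_model")
  if (is.null(model$state)) {
    abort(sprintf(
      "'%s' is an accounting stub (no weights materialized); only tiny_cnn supports in-process forward passes", model$arch))
  }
  cpp_tiny_eval(arr, model$state, model$num_classes)
}

# ---- model state plumbing -------------------------------------------------

set_state <- function(model, state) {
  assert_that(identical(sort(names(state)), sort(model$inventory$group)),
              "state group names must match the architecture inventory")
  model$state <- state[model$inventory$group]
  model
}

flatten_state <- function(state) unlist(state, use.names = FALSE)

unflatten_state <- function(flat, template) {
  out <- template
  pos <- 0L
  for (g in names(template)) {
    n <- length(template[[g]])
    out[[g]] <- flat[(pos + 1):(pos + n)]
    pos <- pos + n
  }
  assert_that(pos == length(flat), "flat state length mismatch")
  out
}

#' Save / load a model checkpoint
#'
#' Writes the parameter state as a raw little-endian double vector with a
#' JSON sidecar describing the architecture, class count and group table, so
#' checkpoints can be read outside R. Round-trips are bit-identical.
#'
#' @param model A trainable `fed_model`.
#' @param path Checkpoint path (the sidecar gets `.json` appended).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  assert_that(!is.null(model$state), "cannot checkpoint an accounting stub")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(flatten_state(model$state), con, size = 8, endian = "little")
  sidecar <- sprintf(
    '{"arch":"%s","num_classes":%d,"groups":[%s],"lengths":[%s]}',
    model$arch, model$num_classes,
    paste(sprintf('"%s"', names(model$state)), collapse = ","),
    paste(lengths(model$state), collapse = ","))
  writeLines(sidecar, paste0(path, ".json"))
  invisible(path)
}

#' @rdname save_model
#' @param num_classes,arch_name Used to rebuild the model skeleton.
#' @export
load_model <- function(path, arch_name = "tiny_cnn", num_classes = 4) {
  model <- build_model(arch_name, num_classes, seed = 0)
  n <- sum(lengths(model$state))
  con <- file(path, "rb")
  on.exit(close(con))
  flat <- readBin(con, "double", n = n, size = 8, endian = "little")
  set_state(model, unflatten_state(flat, model$state))
}
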