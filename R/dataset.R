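#' Labeled image dataset
#'
#' The in-memory container consumed by clients, trainers and evaluators: a
#' list of equally sized grayscale images with intensities in \[0, 1\], an
#' integer class label per image, and the ordered class names.
#'
#' @param images List of numeric H x W matrices with values in \[0, 1\].
#' @param labels Integer vector, one label per image, indexing `class_names`.
#' @param class_names Character vector of class names (length C).
#' @param source_ids Optional character vector of per-sample identifiers.
#'
#' @return An object of class `labeled_dataset` with fields `images`,
#'   `labels`, `class_names`, `image_size` and `source_ids`.
#' @export
labeled_dataset <- function(images, labels, class_names, source_ids = NULL) {
  assert_that(is.list(images) && length(images) > 0, "images must be a nonempty list")
  labels <- as.integer(labels)
  assert_that(length(labels) == length(images), "one label per image required")
  assert_that(all(labels >= 1L & labels <= length(class_names)),
              "every label must index class_names")
  sz <- dim(images[[1]])
  assert_that(all(vapply(images, function(m) identical(dim(m), sz), logical(1))),
              "all images must share the same size")
  rng <- range(vapply(images, function(m) range(m), numeric(2)))
  assert_that(rng[1] >= 0 && rng[2] <= 1, "pixel intensities must lie in [0, 1]")
  structure(
    list(images = images, labels = labels,
         class_names = as.character(class_names),
         image_size = as.integer(sz),
         source_ids = source_ids %||% sprintf("sample_%05d", seq_along(images))),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples, %d classes, %dx%d px\n",
              length(x$labels), length(x$class_names),
              x$image_size[1], x$image_size[2]))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names),
                      labels = x$class_names))
  print(tab)
  invisible(x)
}

#' @export
length.labeled_dataset <- function(x) length(x$labels)

#' Subset a dataset by sample indices
#' @param dataset A [labeled_dataset()].
#' @param idx Integer sample indices.
#' @return A `labeled_dataset` with the selected samples, classes unchanged.
#' @export
dataset_subset <- function(dataset, idx) {
  idx <- as.integer(idx)
  assert_that(length(idx) > 0 && all(idx >= 1 & idx <= length(dataset$labels)),
              "subset indices out of range")
  labeled_dataset(dataset$images[idx], dataset$labels[idx],
                  dataset$class_names, dataset$source_ids[idx])
}

#' Dataset manifest as a tibble
#' @param x A [labeled_dataset()].
#' @param ... Unused.
#' @return A tibble with one row per sample: `source_id`, `label`, `class`.
#' @exportS3Method tibble::as_tibble
as_tibble.labeled_dataset <- function(x, ...) {
  tibble(source_id = x$source_ids, label = x$labels,
         class = x$class_names[x$labels])
}

# Stack images into an H x W x N array for the C++ backbone.
dataset_array <- function(dataset, idx = seq_along(dataset$labels)) {
  sz <- dataset$image_size
  arr <- array(0, c(sz[1], sz[2], length(idx)))
  for (k in seq_along(idx)) arr[, , k] <- dataset$images[[idx[k]]]
  arr
}
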