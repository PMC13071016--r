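#' Generate a class-structured synthetic image dataset
#'
#' Produces grayscale images that emulate, at desk scale, a multi-class brain
#' MRI classification problem: every image carries a dark background and a
#' brighter "brain" disk; each class adds a distinct deterministic lesion
#' motif. Class 1 has no lesion; the remaining classes cycle through three
#' lesion families that differ in size, shape and intensity (large elongated
#' lesion, bright ring with dark core, small very bright focal spot). Motifs
#' deliberately differ in pooled-intensity statistics rather than in absolute
#' position, because the backbone ends in global average pooling.
#'
#' @param n_per_class Samples per class (positive integer).
#' @param n_classes Number of classes, at least 2 (default 4, mirroring
#'   glioma / meningioma / pituitary / no-tumor).
#' @param image_size Integer vector `c(H, W)`, both at least 16.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise;
#'   intensities are clipped back to \[0, 1\].
#' @param seed Integer seed; equal arguments give bit-identical datasets.
#'
#' @return A [labeled_dataset()] with `n_per_class * n_classes` samples.
#' @examples
#' ds <- generate_synthetic_dataset(10, n_classes = 4, image_size = c(32, 32),
#'                                  noise_sd = 0.05, seed = 42)
#' table(ds$labels)
#' @export
generate_synthetic_dataset <- function(n_per_class, n_classes = 4,
                                       image_size = c(64, 64),
                                       noise_sd = 0.05, seed = 42) {
  assert_that(is.numeric(n_per_class) && n_per_class >= 1,
              "n_per_class must be a positive integer")
  assert_that(n_classes >= 2, "n_classes must be at least 2")
  image_size <- as.integer(image_size)
  assert_that(length(image_size) == 2 && all(image_size >= 16),
              "image_size must be at least 16 x 16")
  assert_that(noise_sd >= 0, "noise_sd must be nonnegative")

  class_names <- if (n_classes == 4) {
    c("glioma", "meningioma", "no_tumor", "pituitary")
  } else {
    sprintf("class_%02d", seq_len(n_classes))
  }
  # lesion motif per class: class order is lexicographic like an image folder;
  # "no_tumor" (or class 3 in the 4-class default) carries no lesion.
  none_class <- if (n_classes == 4) 3L else 1L

  h <- image_size[1]; w <- image_size[2]
  yy <- matrix(seq_len(h) / h - 0.5, h, w)
  xx <- matrix(rep(seq_len(w) / w - 0.5, each = h), h, w)

  images <- vector("list", n_per_class * n_classes)
  labels <- integer(n_per_class * n_classes)
  k <- 0L
  for (cls in seq_len(n_classes)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      s <- derive_seed(seed, cls, i)
      images[[k]] <- with_seed(s, {
        render_motif(cls, none_class, xx, yy, noise_sd)
      })
      labels[k] <- cls
    }
  }
  labeled_dataset(images, labels, class_names)
}

# One image: brain disk + class lesion + texture + noise, all under the
# caller-established RNG state.
render_motif <- function(cls, none_class, xx, yy, noise_sd) {
  # jittered brain ellipse
  cx <- runif(1, -0.02, 0.02); cy <- runif(1, -0.02, 0.02)
  ax <- runif(1, 0.40, 0.44); ay <- runif(1, 0.36, 0.40)
  d2 <- ((xx - cx) / ax)^2 + ((yy - cy) / ay)^2
  img <- ifelse(d2 <= 1, 0.35 + 0.1 * (1 - d2), 0.02)
  # smooth low-frequency tissue texture
  fx <- runif(2, 2, 5); ph <- runif(2, 0, 2 * pi)
  img <- img + ifelse(d2 <= 1, 0.04 * sin(2 * pi * fx[1] * xx + ph[1]) *
                                 cos(2 * pi * fx[2] * yy + ph[2]), 0)

  if (cls != none_class) {
    lesion_rank <- cls - (cls > none_class)
    motif <- lesion_rank %% 3            # cycle lesion families
    sc <- 1 + 0.3 * ((lesion_rank - 1) %/% 3)  # grow sizes on later cycles (>4 classes)
    # lesion center well inside the brain
    lr <- runif(1, 0, 0.16); th <- runif(1, 0, 2 * pi)
    lx <- cx + lr * cos(th); ly <- cy + lr * sin(th)
    rot <- runif(1, 0, pi)
    u <- (xx - lx) * cos(rot) + (yy - ly) * sin(rot)
    v <- -(xx - lx) * sin(rot) + (yy - ly) * cos(rot)
    if (motif == 1) {          # large elongated lesion
      a <- sc * runif(1, 0.26, 0.32); b <- sc * runif(1, 0.11, 0.14)
      m2 <- (u / a)^2 + (v / b)^2
      img <- ifelse(m2 <= 1, pmax(img, 0.97 - 0.05 * m2), img)
    } else if (motif == 2) {   # bright ring, dark core
      ro <- sc * runif(1, 0.15, 0.19); ri <- ro * runif(1, 0.5, 0.6)
      m2 <- u^2 + v^2
      img <- ifelse(m2 <= ro^2 & m2 >= ri^2, pmax(img, 1.0), img)
      img <- ifelse(m2 < ri^2, pmin(img, 0.03), img)
    } else {                   # small very bright focal spot
      rs <- sc * runif(1, 0.05, 0.07)
      m2 <- (u^2 + v^2) / rs^2
      img <- ifelse(m2 <= 1, pmax(img, 1.0 - 0.05 * m2), img)
    }
  }
  if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
  matrix(pmin(pmax(img, 0), 1), nrow(xx), ncol(xx))
}

#' Stratified train/test split
#'
#' Splits a dataset so that each class contributes `round(train_frac * n_c)`
#' samples to the training part; the remainder forms the test part. No sample
#' appears in both parts.
#'
#' @param dataset A [labeled_dataset()].
#' @param train_frac Training fraction, strictly between 0 and 1 (default 0.8).
#' @param seed Integer seed controlling the within-class shuffle.
#'
#' @return A list with elements `train` and `test`, both [labeled_dataset()]s,
#'   plus `train_idx`/`test_idx` giving the original indices.
#' @export
stratified_split <- function(dataset, train_frac = 0.8, seed = 42) {
  assert_that(inherits(dataset, "labeled_dataset"), "dataset must be a labeled_dataset")
  assert_that(train_frac > 0 && train_frac < 1, "train_frac must be in (0, 1)")
  counts <- tabulate(dataset$labels, nbins = length(dataset$class_names))
  present <- which(counts > 0)
  assert_that(all(counts[present] >= 2),
              "every present class needs at least 2 samples to split")
  train_idx <- integer(0)
  with_seed(derive_seed(seed, 1303L), {
    for (cls in present) {
      idx <- sample(which(dataset$labels == cls))
      n_train <- round(train_frac * length(idx))
      n_train <- min(max(n_train, 1L), length(idx) - 1L)
      train_idx <- c(train_idx, idx[seq_len(n_train)])
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(dataset$labels), train_idx)
  list(train = dataset_subset(dataset, train_idx),
       test = dataset_subset(dataset, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Partition a dataset across simulated clients by Dirichlet sampling
#'
#' For every class, a proportion vector over the `n_clients` clients is drawn
#' from a symmetric Dirichlet(alpha) distribution and the class's samples are
#' divided according to those proportions (largest-remainder rounding, which
#' conserves totals exactly). Small `alpha` yields strongly non-IID shards;
#' large `alpha` approaches an IID split. The draw is repeated (up to
#' `max_retries`) until every client holds at least `min_per_client` samples.
#'
#' @param dataset A [labeled_dataset()].
#' @param n_clients Number of clients K (at least 2, unless exactly 1 in which
#'   case the single client receives everything).
#' @param alpha Dirichlet concentration parameter (default 0.5).
#' @param seed Integer seed.
#' @param min_per_client Minimum samples any client must receive (default 1).
#' @param max_retries Redraw budget before failing (default 100).
#'
#' @return A `partition_plan`: list with `n_clients`, `assignments` (list of
#'   index vectors), `class_counts` (K x C matrix of n_k(c)), `alpha`, `seed`.
#' @export
dirichlet_partition <- function(dataset, n_clients, alpha = 0.5, seed = 42,
                                min_per_client = 1, max_retries = 100) {
  assert_that(inherits(dataset, "labeled_dataset"), "dataset must be a labeled_dataset")
  n <- length(dataset$labels)
  assert_that(n > 0, "dataset must be nonempty")
  assert_that(n_clients >= 1, "n_clients must be positive")
  assert_that(alpha > 0, "alpha must be positive")
  assert_that(n_clients * min_per_client <= n,
              sprintf("infeasible: %d clients x min_per_client %d exceeds %d samples",
                      n_clients, min_per_client, n))
  n_class <- length(dataset$class_names)

  if (n_clients == 1) {
    cc <- matrix(tabulate(dataset$labels, n_class), 1, n_class)
    return(new_partition_plan(1L, list(seq_len(n)), cc, alpha, seed))
  }

  for (attempt in seq_len(max_retries)) {
    plan <- with_seed(derive_seed(seed, 7919L, attempt), {
      draw_partition(dataset$labels, n_class, n_clients, alpha)
    })
    if (all(lengths(plan$assignments) >= min_per_client)) {
      return(new_partition_plan(as.integer(n_clients), plan$assignments,
                                plan$class_counts, alpha, seed))
    }
  }
  abort(sprintf(
    "Dirichlet partition failed after %d redraws: could not give every one of %d clients >= %d samples (alpha = %g). Lower min_per_client or alpha constraints.",
    max_retries, n_clients, min_per_client, alpha))
}

draw_partition <- function(labels, n_class, k, alpha) {
  assignments <- vector("list", k)
  for (j in seq_len(k)) assignments[[j]] <- integer(0)
  class_counts <- matrix(0L, k, n_class)
  for (cls in seq_len(n_class)) {
    idx <- which(labels == cls)
    if (length(idx) == 0) next
    idx <- sample(idx)
    g <- rgamma(k, shape = alpha)
    if (sum(g) == 0) g <- rep(1, k)
    counts <- largest_remainder(g / sum(g), length(idx))
    stop_at <- cumsum(counts)
    start_at <- c(1L, head(stop_at, -1) + 1L)
    for (j in seq_len(k)) {
      if (counts[j] > 0) {
        take <- idx[start_at[j]:stop_at[j]]
        assignments[[j]] <- c(assignments[[j]], take)
        class_counts[j, cls] <- counts[j]
      }
    }
  }
  list(assignments = lapply(assignments, sort), class_counts = class_counts)
}

# Apportion n into integer counts proportional to p, conserving the total.
largest_remainder <- function(p, n) {
  raw <- p * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

new_partition_plan <- function(n_clients, assignments, class_counts, alpha, seed) {
  structure(list(n_clients = n_clients, assignments = assignments,
                 class_counts = class_counts, alpha = alpha, seed = seed),
            class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  cat(sprintf("<partition_plan> %d clients, alpha = %g\n", x$n_clients, x$alpha))
  print(tidy(x), n = 10)
  invisible(x)
}

#' Tidy a client partition plan
#' @param x A `partition_plan`.
#' @param ... Unused.
#' @return A tibble with one row per (client, class): columns `client`,
#'   `class`, `n` (the per-client per-class count n_k(c)).
#' @exportS3Method generics::tidy
tidy.partition_plan <- function(x, ...) {
  cc <- x$class_counts
  tibble(client = rep(seq_len(nrow(cc)), ncol(cc)),
         class = rep(seq_len(ncol(cc)), each = nrow(cc)),
         n = as.integer(cc)) |>
    dplyr::arrange(.data$client, .data$class)
}
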