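# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

# small default dataset: 4 classes, 16x16, cheap to train on
tiny_ds <- function(n_per_class = 10, image_size = c(16, 16), seed = 42,
                    n_classes = 4, noise_sd = 0.05) {
  key <- paste("ds", n_per_class, image_size[1], image_size[2], seed,
               n_classes, noise_sd, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_synthetic_dataset(
      n_per_class, n_classes = n_classes, image_size = image_size,
      noise_sd = noise_sd, seed = seed)
  }
  .fixture_env[[key]]
}

# a minimal client update usable by fedavg(): only $state and $n_samples
fake_update <- function(state, n) list(state = state, n_samples = n)

# independent brute-force weighted mean over concatenated parameters
oracle_fedavg <- function(states, ns) {
  flat <- sapply(states, function(s) unlist(s, use.names = FALSE))
  w <- ns / sum(ns)
  as.numeric(flat %*% w)
}

# O(n^2) double-loop Pareto oracle, written independently of pareto_filter
oracle_pareto <- function(pts) {
  n <- nrow(pts)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j == i) next
      if (all(pts[j, ] <= pts[i, ]) && any(pts[j, ] < pts[i, ])) {
        dominated <- TRUE
        break
      }
    }
    keep[i] <- !dominated
  }
  which(keep)
}
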