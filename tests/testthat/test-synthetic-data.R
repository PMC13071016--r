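test_that("generator produces the requested class structure deterministically", {
  ds <- generate_synthetic_dataset(10, n_classes = 4, image_size = c(32, 32),
                                   noise_sd = 0.05, seed = 42)
  expect_s3_class(ds, "labeled_dataset")
  expect_length(ds$labels, 40)
  expect_equal(unname(tabulate(ds$labels, 4)), rep(10L, 4))
  expect_equal(ds$image_size, c(32L, 32L))
  px <- range(vapply(ds$images, range, numeric(2)))
  expect_true(px[1] >= 0 && px[2] <= 1)

  ds2 <- generate_synthetic_dataset(10, n_classes = 4, image_size = c(32, 32),
                                    noise_sd = 0.05, seed = 42)
  expect_identical(ds$images, ds2$images)

  a <- generate_synthetic_dataset(3, image_size = c(16, 16), noise_sd = 0, seed = 7)
  b <- generate_synthetic_dataset(3, image_size = c(16, 16), noise_sd = 0, seed = 7)
  expect_identical(a$images, b$images)

  expect_error(generate_synthetic_dataset(0), "positive")
  expect_error(generate_synthetic_dataset(5, n_classes = 1), "at least 2")
  expect_error(generate_synthetic_dataset(5, image_size = c(8, 8)), "16")
})

test_that("class motifs are distinct enough for a rapid learner", {
  # separability oracle: the module's own trainer, 5 epochs, 80/20 split
  ds <- generate_synthetic_dataset(200, n_classes = 4, image_size = c(64, 64),
                                   noise_sd = 0.05, seed = 42)
  sp <- stratified_split(ds, 0.8, seed = 42)
  model <- build_model("tiny_cnn", 4, seed = 42)
  stats <- fedprosim:::dataset_stats(sp$train)
  upd <- local_train(model, sp$train, training_config(local_epochs = 5),
                     stats = stats)
  trained <- fedprosim:::set_state(model, upd$state)
  metrics <- evaluate_model(trained, sp$test, stats = stats)
  expect_gte(metrics$accuracy, 0.90)
})

test_that("stratified split is exact per class and deterministic", {
  ds <- tiny_ds(10)
  sp <- stratified_split(ds, 0.8, seed = 1)
  expect_length(sp$train$labels, 32)
  expect_length(sp$test$labels, 8)
  expect_equal(unname(tabulate(sp$train$labels, 4)), rep(8L, 4))
  expect_equal(unname(tabulate(sp$test$labels, 4)), rep(2L, 4))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)

  sp5 <- stratified_split(ds, 0.5, seed = 1)
  expect_equal(unname(tabulate(sp5$train$labels, 4)), rep(5L, 4))

  sp2 <- stratified_split(ds, 0.8, seed = 1)
  expect_identical(sp$train_idx, sp2$train_idx)

  one <- labeled_dataset(ds$images[c(1, 2, 11)], c(1, 1, 2),
                         ds$class_names[1:2])
  expect_error(stratified_split(one, 0.8), "at least 2")
  expect_error(stratified_split(ds, 1.0), "in \\(0, 1\\)")
})

test_that("Dirichlet partition conserves samples for all seeds and alphas", {
  ds <- tiny_ds(25)
  for (alpha in c(0.1, 0.5, 5)) {
    for (seed in 1:4) {
      plan <- dirichlet_partition(ds, 5, alpha = alpha, seed = seed)
      all_idx <- sort(unlist(plan$assignments))
      expect_identical(all_idx, seq_along(ds$labels))
      expect_equal(sum(plan$class_counts), length(ds$labels))
      expect_equal(unname(colSums(plan$class_counts)),
                   unname(tabulate(ds$labels, 4)))
      expect_equal(unname(rowSums(plan$class_counts)),
                   unname(lengths(plan$assignments)))
      expect_true(all(lengths(plan$assignments) >= 1))
    }
  }
})

test_that("near-IID alpha recovers global class proportions", {
  ds <- tiny_ds(500, seed = 3)  # 2000 samples, 4 classes
  global <- tabulate(ds$labels, 4) / length(ds$labels)
  for (seed in 1:10) {
    plan <- dirichlet_partition(ds, 5, alpha = 1e6, seed = seed)
    props <- plan$class_counts / rowSums(plan$class_counts)
    expect_true(max(abs(sweep(props, 2, global))) < 0.05)
  }
})

test_that("heterogeneity grows as alpha shrinks", {
  ds <- tiny_ds(100, seed = 5)
  spread <- function(alpha) {
    mean(sapply(1:10, function(seed) {
      plan <- dirichlet_partition(ds, 5, alpha = alpha, seed = seed)
      props <- plan$class_counts / rowSums(plan$class_counts)
      mean(apply(props, 2, stats::var))
    }))
  }
  expect_gt(spread(0.1), spread(100))
})

test_that("partition edge cases behave per contract", {
  ds <- tiny_ds(10)
  one <- dirichlet_partition(ds, 1, alpha = 0.5, seed = 42)
  expect_identical(one$assignments[[1]], seq_along(ds$labels))
  expect_error(dirichlet_partition(ds, 5, min_per_client = 100), "infeasible")
  expect_error(dirichlet_partition(ds, 40, alpha = 0.01, seed = 1,
                                   min_per_client = 1, max_retries = 3),
               "redraws")
  tt <- tidy(dirichlet_partition(ds, 3, seed = 9))
  expect_named(tt, c("client", "class", "n"))
  expect_equal(sum(tt$n), length(ds$labels))
})

test_that("image folder round trip preserves labels and class order", {
  dir <- withr::local_tempdir()
  ds <- tiny_ds(3)
  write_image_folder(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_image_folder(dir)
  expect_equal(back$class_names, sort(ds$class_names))
  expect_equal(unname(table(back$class_names[back$labels])),
               unname(table(ds$class_names[ds$labels])))
  # lexicographic order independent of write order
  expect_equal(back$class_names, sort(back$class_names))
  # pixel content survives 8-bit quantization
  expect_lt(max(abs(back$images[[1]] - ds$images[[1]])), 1 / 255)
})

test_that("image folder error contract", {
  dir <- withr::local_tempdir()
  expect_error(read_image_folder(file.path(dir, "missing")), "not found")
  expect_error(read_image_folder(dir), "no class subdirectories")
  dir.create(file.path(dir, "empty_class"))
  dir.create(file.path(dir, "full_class"))
  png::writePNG(matrix(0.5, 16, 16), file.path(dir, "full_class", "a.png"))
  expect_warning(got <- read_image_folder(dir), "empty class")
  expect_equal(got$class_names, "full_class")
})
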