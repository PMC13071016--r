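test_that("fedavg is the sample-weighted convex combination", {
  # scalar hand example: w1 = 1/4, w2 = 3/4 -> 0.75
  u1 <- fake_update(list(w = 0), 1)
  u2 <- fake_update(list(w = 1), 3)
  expect_equal(fedavg(list(u1, u2))$w, 0.75)

  # identical states are a fixed point for any counts
  st <- build_model("tiny_cnn", 4, seed = 3)$state
  same <- fedavg(list(fake_update(st, 2), fake_update(st, 17)))
  expect_equal(same, st, tolerance = 1e-15)

  expect_error(fedavg(list(fake_update(list(a = 1), 0),
                           fake_update(list(a = 2), 0))), "zero")
  expect_error(fedavg(list(fake_update(list(a = 1), 1),
                           fake_update(list(b = 2), 1))), "mismatch")
})

test_that("fedavg matches a brute-force concatenated weighted mean", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      k <- sample(2:5, 1)
      states <- lapply(seq_len(k), function(i) {
        list(g1 = rnorm(13), g2 = rnorm(31), g3 = rnorm(5))
      })
      ns <- sample(1:50, k)
      got <- fedavg(purrr::map2(states, ns, fake_update))
      want <- oracle_fedavg(states, ns)
      expect_lt(max(abs(unlist(got) - want)), 1e-7)
      # convexity: every coordinate within the clients' range
      flat <- sapply(states, unlist)
      expect_true(all(unlist(got) >= apply(flat, 1, min) - 1e-12))
      expect_true(all(unlist(got) <= apply(flat, 1, max) + 1e-12))
    }
  })
})

test_that("prototype aggregation is count-weighted per class", {
  a <- prototype_set(1L, 2L, list(1.0))
  b <- prototype_set(1L, 3L, list(0.5))
  got <- aggregate_prototypes(list(a, b))
  expect_equal(got$prototype[[1]], 0.7)  # (2*1.0 + 3*0.5) / 5
  expect_equal(got$n, 5L)

  # a class held by one client passes through
  c2 <- prototype_set(2L, 4L, list(-1.5))
  merged <- aggregate_prototypes(list(a, c2))
  expect_equal(merged$class, c(1L, 2L))
  expect_equal(merged$prototype[[2]], -1.5)

  # identical prototypes are invariant to counts
  same <- aggregate_prototypes(list(prototype_set(1L, 1L, list(c(2, 3))),
                                    prototype_set(1L, 99L, list(c(2, 3)))))
  expect_equal(same$prototype[[1]], c(2, 3))

  expect_error(aggregate_prototypes(list(a, prototype_set(1L, 1L, list(c(1, 2))))),
               "width")
})

test_that("prototype aggregation conserves support counts", {
  m <- build_model("tiny_cnn", 4, seed = 42)
  ds <- tiny_ds(6)
  plan <- dirichlet_partition(ds, 3, alpha = 0.5, seed = 1)
  sets <- lapply(plan$assignments, function(idx) {
    extract_prototypes(m, dataset_subset(ds, idx))
  })
  merged <- aggregate_prototypes(sets)
  expect_equal(sum(merged$n), length(ds$labels))
  expect_equal(merged$n, unname(colSums(plan$class_counts))[merged$class])
})

test_that("secure aggregation is transparent to the aggregated model", {
  ds <- tiny_ds(12, image_size = c(16, 16), seed = 2)
  sp <- stratified_split(ds, 0.75, seed = 2)
  part <- dirichlet_partition(sp$train, 3, alpha = 1, seed = 2)
  base <- list(train = sp$train, test = sp$test, partition = part)
  tc <- training_config(local_epochs = 1, batch_size = 16)
  run_mode <- function(mode) {
    cfg <- experiment_config(privacy_mode = mode, n_clients = 3, rounds = 2,
                             training = tc, seed = 2)
    run_experiment(cfg, base)
  }
  plain <- run_mode("no_privacy")
  sa <- run_mode("sa_only")
  rel <- max(abs(fedprosim:::flatten_state(sa$model$state) -
                 fedprosim:::flatten_state(plain$model$state))) /
    max(abs(fedprosim:::flatten_state(plain$model$state)))
  expect_lt(rel, 1e-6)
  expect_equal(sa$summary$accuracy, plain$summary$accuracy)
})

test_that("DP with zero noise and a loose clip is a no-op pipeline", {
  ds <- tiny_ds(12, image_size = c(16, 16), seed = 4)
  sp <- stratified_split(ds, 0.75, seed = 4)
  part <- dirichlet_partition(sp$train, 3, alpha = 1, seed = 4)
  base <- list(train = sp$train, test = sp$test, partition = part)
  tc <- training_config(local_epochs = 1, batch_size = 16)
  loose_dp <- dp_config(clip_norm = 1e9, noise_multiplier = 0)
  plain <- run_experiment(experiment_config(privacy_mode = "no_privacy",
                                            n_clients = 3, rounds = 2,
                                            training = tc, seed = 4), base)
  dp <- run_experiment(experiment_config(privacy_mode = "dp_only",
                                         n_clients = 3, rounds = 2,
                                         training = tc, dp = loose_dp,
                                         seed = 4), base)
  expect_equal(fedprosim:::flatten_state(dp$model$state),
               fedprosim:::flatten_state(plain$model$state),
               tolerance = 1e-10)
})

test_that("a one-client one-round experiment equals centralized training", {
  ds <- tiny_ds(10, image_size = c(16, 16), seed = 6)
  cfg <- experiment_config(privacy_mode = "no_privacy", n_clients = 1,
                           rounds = 1, seed = 6,
                           training = training_config(local_epochs = 5,
                                                      batch_size = 16))
  ex <- run_experiment(cfg, ds)

  sp <- stratified_split(ds, 0.8, seed = 6)
  stats <- fedprosim:::dataset_stats(sp$train)
  m <- build_model("tiny_cnn", 4, seed = 6)
  central_cfg <- cfg$training
  central_cfg$seed <- fedprosim:::derive_seed(6L, central_cfg$seed)
  upd <- local_train(m, sp$train, central_cfg, client_id = 1L, round = 1L,
                     stats = stats)
  central <- evaluate_model(fedprosim:::set_state(m, upd$state), sp$test,
                            stats = stats)
  expect_equal(ex$summary$accuracy, central$accuracy)
})

test_that("experiment results expose tidy/glance/autoplot interfaces", {
  ds <- tiny_ds(10, image_size = c(16, 16), seed = 8)
  cfg <- experiment_config(privacy_mode = "dp_sa", n_clients = 2, rounds = 2,
                           training = training_config(local_epochs = 1,
                                                      batch_size = 16),
                           seed = 8)
  dir <- withr::local_tempdir()
  ex <- run_experiment(cfg, ds, out_dir = dir)
  rounds <- tidy(ex)
  expect_equal(nrow(rounds), 2)
  expect_true(all(c("round", "accuracy", "f1", "per_round_MB") %in% names(rounds)))
  expect_true(all(rounds$accuracy >= 0 & rounds$accuracy <= 1))
  g <- glance(ex)
  expect_equal(nrow(g), 1)
  expect_equal(g$configuration, "dp_sa")
  expect_equal(g$leakage, 0.2)
  expect_equal(g$total_MB, g$per_round_MB * 2 * 2)
  expect_s3_class(autoplot(ex), "ggplot")
  expect_true(file.exists(file.path(dir, "federated_learning_results.csv")))
  # round index increments by one
  expect_equal(rounds$round, 1:2)
})

test_that("the two-stage pipeline warm-starts and orders configurations", {
  ds <- tiny_ds(25, image_size = c(32, 32), seed = 10)
  suite <- suppressMessages(run_federated_suite(
    ds, modes = c("no_privacy", "dp_only"), rounds = 2, baseline_epochs = 5,
    n_clients = 3, training = training_config(batch_size = 32,
                                              local_epochs = 2),
    seed = 10))
  expect_s3_class(suite, "fed_suite")
  expect_equal(nrow(suite$summary), 2)
  expect_gte(suite$summary$accuracy[suite$summary$configuration == "no_privacy"],
             suite$summary$accuracy[suite$summary$configuration == "dp_only"])
  expect_equal(nrow(suite$comparison$comparison), 2)
  expect_equal(suite$comparison$privacy_utility$leakage, c(1.0, 0.4))
  expect_s3_class(autoplot(suite), "ggplot")
})

test_that("nearest-prototype classification matches features", {
  m <- build_model("tiny_cnn", 4, seed = 42)
  ds <- tiny_ds(6)
  protos <- extract_prototypes(m, ds)
  pred <- predict_nearest_prototype(m, protos, ds)
  expect_length(pred, length(ds$labels))
  expect_true(all(pred %in% 1:4))
  # with one prototype, everything maps to it
  one <- protos[1, ]
  class(one) <- class(protos)
  expect_true(all(predict_nearest_prototype(m, one, ds) == one$class))
})
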