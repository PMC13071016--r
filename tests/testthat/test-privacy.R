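test_that("clipping follows the max(1, |g|/C) rule exactly", {
  dp0 <- dp_config(clip_norm = 1, noise_multiplier = 0, seed = 1)
  g_in <- c(0.3, -0.4)  # norm 0.5 <= C
  expect_identical(clip_and_noise(g_in, dp0), g_in)
  g2 <- c(1.2, -1.6)    # norm 2 = 2C
  expect_equal(clip_and_noise(g2, dp0), g2 / 2, tolerance = 1e-15)
  expect_error(clip_and_noise(c(1, NaN), dp0), "finite")
  dp5 <- dp_config(clip_norm = 5, noise_multiplier = 0)
  expect_identical(clip_and_noise(g2, dp5), g2)
})

test_that("noise calibration matches sigma * C empirically", {
  dp <- dp_config(clip_norm = 1.0, noise_multiplier = 0.5, seed = 42)
  z <- clip_and_noise(numeric(1e5), dp)
  expect_equal(stats::sd(z), 0.5, tolerance = 0.01)
  expect_equal(mean(z), 0, tolerance = 0.01)
  # scaling: sd tracks sigma * C for another configuration
  dp2 <- dp_config(clip_norm = 2.0, noise_multiplier = 0.25, seed = 7)
  z2 <- clip_and_noise(numeric(1e5), dp2)
  expect_equal(stats::sd(z2), 0.5, tolerance = 0.01)
  # deterministic under the config seed and stream
  expect_identical(clip_and_noise(numeric(10), dp, stream = 3),
                   clip_and_noise(numeric(10), dp, stream = 3))
  expect_false(identical(clip_and_noise(numeric(10), dp, stream = 3),
                         clip_and_noise(numeric(10), dp, stream = 4)))
})

test_that("prototype noising perturbs vectors but never counts", {
  protos <- prototype_set(class = 1:2, n = c(3L, 5L),
                          prototype = list(c(0.1, 0.2), c(-0.3, 0.1)))
  dp0 <- dp_config(clip_norm = 1, noise_multiplier = 0)
  same <- noise_prototypes(protos, dp0)
  expect_equal(same$prototype, protos$prototype, tolerance = 1e-15)
  dp <- dp_config(clip_norm = 1, noise_multiplier = 0.5, seed = 3)
  noised <- noise_prototypes(protos, dp)
  expect_identical(noised$n, protos$n)
  expect_identical(noised$class, protos$class)
  expect_false(identical(noised$prototype, protos$prototype))
})

test_that("prototype noise variance matches sigma^2 C^2", {
  width <- 1e4
  protos <- prototype_set(class = 1:100, n = rep(1L, 100),
                          prototype = replicate(100, numeric(width),
                                                simplify = FALSE))
  dp <- dp_config(clip_norm = 1.0, noise_multiplier = 0.5, seed = 11)
  noised <- noise_prototypes(protos, dp)
  draws <- unlist(noised$prototype)  # 1e6 zero-centred noise samples
  expect_equal(stats::var(draws), 0.25, tolerance = 0.01 * 0.25)
})

test_that("pairwise masks cancel in the sum for any federation", {
  sa <- sa_config(mask_scale = 10, seed = 5)
  for (k in c(2, 3, 5)) {
    for (len in c(10, 1000)) {
      raw <- lapply(seq_len(k), function(i) rnorm(len, mean = i))
      masked <- secure_mask(raw, sa, round = k)
      expect_equal(Reduce(`+`, masked), Reduce(`+`, raw),
                   tolerance = 1e-6)
      expect_false(isTRUE(all.equal(masked[[1]], raw[[1]])))
    }
  }
  expect_error(secure_mask(list(rnorm(4)), sa), "at least 2")
  expect_error(secure_mask(list(rnorm(4), rnorm(5)), sa), "equal length")
})

test_that("mask streams are symmetric per pair and fresh per round", {
  sa <- sa_config(mask_scale = 1, seed = 9)
  raw <- list(numeric(50), numeric(50), numeric(50))
  m1 <- secure_mask(raw, sa, round = 1)
  m2 <- secure_mask(raw, sa, round = 2)
  expect_false(identical(m1, m2))
  expect_identical(secure_mask(raw, sa, round = 1), m1)
  # antisymmetry for two clients: masks are exact negatives
  two <- secure_mask(list(numeric(20), numeric(20)), sa, round = 1)
  expect_equal(two[[1]], -two[[2]], tolerance = 1e-15)
})

test_that("leakage scores reproduce the protection ranking", {
  expect_equal(leakage_score("no_privacy"), 1.0)
  expect_equal(leakage_score("dp_only"), 0.4)
  expect_equal(leakage_score("sa_only"), 0.6)
  expect_equal(leakage_score("dp_sa"), 0.2)
  expect_true(leakage_score("dp_sa") < leakage_score("dp_only"))
  expect_true(leakage_score("dp_only") < leakage_score("sa_only"))
  expect_true(leakage_score("sa_only") < leakage_score("no_privacy"))
  expect_error(leakage_score("tls_only"), "privacy mode")
})

test_that("budget-based leakage and Gaussian accounting follow closed forms", {
  expect_equal(leakage_from_budget(1), 1)
  expect_equal(leakage_from_budget(10), 0.1)
  eps <- leakage_from_budget(c(1, 2, 5, 10))
  expect_true(all(diff(eps) < 0))
  expect_error(leakage_from_budget(0), "positive")

  expect_equal(gaussian_budget(1, 1e-5, 1), sqrt(2 * log(1.25e5)))
  expect_equal(gaussian_budget(1, 1e-5, 8), 8 * sqrt(2 * log(1.25e5)))
  expect_lt(gaussian_budget(100, 1e-5, 1), gaussian_budget(0.5, 1e-5, 1))
  expect_lt(gaussian_budget(1e6, 1e-5, 1), 1e-2)
  expect_error(gaussian_budget(0, 1e-5, 1), "positive")
  expect_error(gaussian_budget(1, 2, 1), "\\(0, 1\\)")
})
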