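#' Differential-privacy configuration
#'
#' Parameters of the Gaussian mechanism applied to client update vectors and
#' class prototypes: the vector is clipped to L2 norm `clip_norm` (C) and
#' perturbed with i.i.d. Gaussian noise of standard deviation
#' `noise_multiplier * clip_norm` (sigma * C) per coordinate.
#'
#' @param clip_norm Clipping norm C (default 1.0).
#' @param noise_multiplier Noise multiplier sigma, the ratio of noise sd to
#'   clip norm (default 0.5).
#' @param delta DP delta parameter, in (0, 1); only used by the privacy
#'   accountant (default 1e-5, an artifact choice).
#' @param seed Integer seed for the noise stream.
#' @return A `dp_config` list.
#' @export
dp_config <- function(clip_norm = 1.0, noise_multiplier = 0.5,
                      delta = 1e-5, seed = 42) {
  assert_that(clip_norm > 0, "clip_norm must be positive")
  assert_that(noise_multiplier >= 0, "noise_multiplier must be nonnegative")
  assert_that(delta > 0 && delta < 1, "delta must be in (0, 1)")
  structure(list(clip_norm = clip_norm, noise_multiplier = noise_multiplier,
                 delta = delta, seed = as.integer(seed)),
            class = "dp_config")
}

#' Secure-aggregation configuration
#'
#' Secure aggregation is simulated by pairwise antisymmetric additive
#' masking: clients i < j share a pseudorandom mask m_ij; client i adds it,
#' client j subtracts it, so masks cancel exactly in the sum while each
#' individual masked vector reveals nothing about its raw vector without the
#' pair seeds. `overhead_factor` models the extra bytes of the masking
#' protocol in the communication-cost accounting (1.15 reproduces the
#' reported per-round costs).
#'
#' @param mask_scale Standard deviation of mask entries (default 1.0).
#' @param overhead_factor Communication overhead multiplier, at least 1
#'   (default 1.15).
#' @param seed Base seed from which the per-pair mask seeds are derived
#'   (symmetric in the pair).
#' @return An `sa_config` list.
#' @export
sa_config <- function(mask_scale = 1.0, overhead_factor = 1.15, seed = 42) {
  assert_that(mask_scale > 0, "mask_scale must be positive")
  assert_that(overhead_factor >= 1, "overhead_factor must be at least 1")
  structure(list(mask_scale = mask_scale, overhead_factor = overhead_factor,
                 seed = as.integer(seed)),
            class = "sa_config")
}

#' Privacy modes
#'
#' The four protection configurations compared by the simulator.
#' @return Character vector of the valid modes.
#' @export
privacy_modes <- function() c("no_privacy", "dp_only", "sa_only", "dp_sa")

check_privacy_mode <- function(mode) {
  assert_that(is.character(mode) && length(mode) == 1 && mode %in% privacy_modes(),
              sprintf("privacy mode must be one of: %s",
                      paste(privacy_modes(), collapse = ", ")))
  mode
}

#' Clip an update vector and add Gaussian noise
#'
#' The Gaussian mechanism: the input g is scaled to `g / max(1, |g|_2 / C)`
#' so its L2 norm is at most C, then perturbed with z ~ N(0, (sigma C)^2 I).
#' With `noise_multiplier = 0` this is pure clipping; inputs already inside
#' the clip ball are returned unchanged.
#'
#' @param update Finite numeric vector.
#' @param dp A [dp_config()].
#' @param stream Integer offsetting the noise stream (so successive calls
#'   under one config draw independent noise deterministically).
#' @return Numeric vector of the same length.
#' @examples
#' clip_and_noise(c(3, 4), dp_config(clip_norm = 1, noise_multiplier = 0))
#' @export
clip_and_noise <- function(update, dp = dp_config(), stream = 0L) {
  assert_that(is.numeric(update) && all(is.finite(update)),
              "update must be a finite numeric vector")
  assert_that(inherits(dp, "dp_config"), "dp must be a dp_config")
  nrm <- sqrt(sum(update^2))
  clipped <- update / max(1, nrm / dp$clip_norm)
  if (dp$noise_multiplier == 0) return(clipped)
  z <- with_seed(derive_seed(dp$seed, 52711L, stream), {
    rnorm(length(update), 0, dp$noise_multiplier * dp$clip_norm)
  })
  clipped + z
}

#' Apply differential privacy to a prototype set
#'
#' Each prototype vector is clipped and noised as in [clip_and_noise()];
#' support counts are left untouched.
#'
#' @param protos A `prototype_set` (see [extract_prototypes()]).
#' @param dp A [dp_config()].
#' @param stream Integer noise-stream offset.
#' @return A `prototype_set` with perturbed vectors and identical counts.
#' @export
noise_prototypes <- function(protos, dp = dp_config(), stream = 0L) {
  assert_that(inherits(protos, "prototype_set"), "protos must be a prototype_set")
  protos$prototype <- lapply(seq_len(nrow(protos)), function(i) {
    clip_and_noise(protos$prototype[[i]], dp,
                   stream = derive_seed(stream, protos$class[i]))
  })
  protos
}

#' Mask client update vectors for secure aggregation
#'
#' For every unordered client pair (i, j), i < j, a pseudorandom mask vector
#' is drawn from the pair's shared seed; client i's vector receives +m_ij and
#' client j's receives -m_ij. Individual masked vectors are uninformative
#' without the seeds, while the sum over clients equals the raw sum exactly
#' up to floating-point tolerance.
#'
#' @param updates List of equal-length numeric vectors, one per client
#'   (at least 2 clients).
#' @param sa An [sa_config()].
#' @param round Integer mixed into the pair seeds so each round uses fresh
#'   masks.
#' @return List of masked vectors, same names and lengths as `updates`.
#' @export
secure_mask <- function(updates, sa = sa_config(), round = 1L) {
  assert_that(is.list(updates) && length(updates) >= 2,
              "secure aggregation needs at least 2 clients")
  len <- unique(lengths(updates))
  assert_that(length(len) == 1, "all update vectors must have equal length")
  assert_that(inherits(sa, "sa_config"), "sa must be an sa_config")
  k <- length(updates)
  masked <- updates
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m <- with_seed(derive_seed(sa$seed, 104729L, round, i, j), {
        rnorm(len, 0, sa$mask_scale)
      })
      masked[[i]] <- masked[[i]] + m
      masked[[j]] <- masked[[j]] - m
    }
  }
  masked
}

#' Privacy-leakage score of a protection configuration
#'
#' Returns the assigned relative leakage ranking used throughout the
#' reporting: 1.0 for no protection, 0.4 for DP only, 0.6 for SA only and
#' 0.2 for the DP + SA hybrid. These are fixed comparative scores, not
#' measured attack-success rates.
#'
#' @param mode One of [privacy_modes()].
#' @return Leakage score in (0, 1\].
#' @examples
#' leakage_score("dp_sa")
#' @export
leakage_score <- function(mode) {
  check_privacy_mode(mode)
  c(no_privacy = 1.0, dp_only = 0.4, sa_only = 0.6, dp_sa = 0.2)[[mode]]
}

#' Leakage surrogate from a privacy budget
#'
#' The multi-objective optimizer scores a configuration's privacy exposure
#' as the reciprocal of its privacy budget epsilon.
#'
#' @param epsilon Privacy budget, strictly positive.
#' @return `1 / epsilon`.
#' @export
leakage_from_budget <- function(epsilon) {
  assert_that(is.numeric(epsilon) && all(epsilon > 0), "epsilon must be positive")
  1 / epsilon
}

#' Conservative (epsilon, delta) accounting for the Gaussian mechanism
#'
#' Per release, the classic Gaussian-mechanism bound gives
#' `epsilon_0 = sqrt(2 * log(1.25 / delta)) / sigma` for sensitivity C and
#' noise sd sigma * C; releases over `rounds` rounds are composed by basic
#' composition (`epsilon = rounds * epsilon_0`). This is a deliberately
#' conservative stand-in for a moments-accountant analysis.
#'
#' @param sigma Noise multiplier, strictly positive.
#' @param delta DP delta in (0, 1).
#' @param rounds Number of composed releases (at least 1).
#' @return The composed epsilon.
#' @export
gaussian_budget <- function(sigma, delta = 1e-5, rounds = 1) {
  assert_that(sigma > 0, "sigma must be positive")
  assert_that(delta > 0 && delta < 1, "delta must be in (0, 1)")
  assert_that(rounds >= 1, "rounds must be at least 1")
  rounds * sqrt(2 * log(1.25 / delta)) / sigma
}
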