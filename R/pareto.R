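#' Surrogate objective vector for a (skip_ratio, privacy_budget) configuration
#'
#' The cheap analytic objectives used by the multi-objective optimizer, all
#' to be minimized: f1 is the negated accuracy surrogate
#' `-(base_acc - penalty_coef * skip_ratio)` (linear accuracy penalty for
#' layer skipping; the default coefficient is calibrated so a 0.6 skip ratio
#' costs about 2 accuracy points, matching the reported 1-2% loss at the
#' headline 60% communication saving); f2 is the per-round communication
#' cost in MB; f3 is the privacy-leakage surrogate `1 / privacy_budget`.
#'
#' @param skip_ratio Layer-skip ratio in \[0, 1).
#' @param privacy_budget Privacy budget epsilon, strictly positive.
#' @param base_acc Baseline accuracy in \[0, 1\] (default 0.96).
#' @param total_params Model parameter count for the cost term (default:
#'   ResNet50 with a 4-class head).
#' @param penalty_coef Accuracy penalty per unit skip ratio (default
#'   `0.02 / 0.6`).
#' @param penalty Penalty shape: `"linear"` (default) or `"quadratic"`
#'   (`penalty_coef * skip_ratio^2`).
#' @return A named numeric vector `c(f1, f2, f3)`; `accuracy_surrogate` is
#'   attached as an attribute.
#' @examples
#' surrogate_objectives(0.4, 5)
#' @export
surrogate_objectives <- function(skip_ratio, privacy_budget, base_acc = 0.96,
                                 total_params = 23516228,
                                 penalty_coef = 0.02 / 0.6,
                                 penalty = c("linear", "quadratic")) {
  assert_that(skip_ratio >= 0 && skip_ratio < 1, "skip_ratio must be in [0, 1)")
  assert_that(privacy_budget > 0, "privacy_budget must be positive")
  assert_that(base_acc >= 0 && base_acc <= 1, "base_acc must be in [0, 1]")
  penalty <- match.arg(penalty)
  pen <- if (penalty == "linear") penalty_coef * skip_ratio
         else penalty_coef * skip_ratio^2
  acc <- base_acc - pen
  out <- c(f1 = -acc,
           f2 = per_round_cost(total_params, skip_ratio, sa_enabled = FALSE),
           f3 = leakage_from_budget(privacy_budget))
  attr(out, "accuracy_surrogate") <- acc
  out
}

#' Exact non-dominated (Pareto) filtering
#'
#' A point is dominated when some other point is no worse in every objective
#' and strictly better in at least one; the result is the index set of
#' non-dominated points (all objectives minimized).
#'
#' @param points Numeric matrix, one row per point, one column per objective
#'   (a data frame is accepted and coerced).
#' @return Integer vector of row indices of the non-dominated set.
#' @export
pareto_filter <- function(points) {
  pts <- as.matrix(points)
  assert_that(nrow(pts) >= 1, "need at least one point")
  n <- nrow(pts)
  dominated <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (dominated[i]) next
    leq <- sweep(pts, 2, pts[i, ], `>=`)       # rows dominated-or-equal by i
    lt <- sweep(pts, 2, pts[i, ], `>`)
    dom_by_i <- rowSums(leq) == ncol(pts) & rowSums(lt) > 0
    dominated <- dominated | dom_by_i
  }
  which(!dominated)
}

# ---- NSGA-II --------------------------------------------------------------

# Fast non-dominated sorting; returns integer rank per row (1 = best front).
nds_rank <- function(F) {
  n <- nrow(F)
  rank <- integer(n)
  dom_count <- integer(n)
  dominates <- vector("list", n)
  for (i in seq_len(n)) {
    leq <- sweep(F, 2, F[i, ], `<=`)
    lt <- sweep(F, 2, F[i, ], `<`)
    d <- rowSums(leq) == ncol(F) & rowSums(lt) > 0   # rows dominating i
    dom_count[i] <- sum(d)
    geq <- sweep(F, 2, F[i, ], `>=`)
    gt <- sweep(F, 2, F[i, ], `>`)
    dominates[[i]] <- which(rowSums(geq) == ncol(F) & rowSums(gt) > 0)
  }
  current <- which(dom_count == 0)
  r <- 1L
  while (length(current) > 0) {
    rank[current] <- r
    nxt <- integer(0)
    for (i in current) {
      for (j in dominates[[i]]) {
        dom_count[j] <- dom_count[j] - 1L
        if (dom_count[j] == 0) nxt <- c(nxt, j)
      }
    }
    current <- unique(nxt)
    r <- r + 1L
  }
  rank
}

# Crowding distance within one front; boundary points get Inf.
crowding_distance <- function(F) {
  n <- nrow(F)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (m in seq_len(ncol(F))) {
    ord <- order(F[, m])
    d[ord[1]] <- Inf
    d[ord[n]] <- Inf
    span <- F[ord[n], m] - F[ord[1], m]
    if (span > 0) {
      for (k in 2:(n - 1)) {
        d[ord[k]] <- d[ord[k]] + (F[ord[k + 1], m] - F[ord[k - 1], m]) / span
      }
    }
  }
  d
}

sbx_crossover <- function(p1, p2, lower, upper, eta = 15, pc = 0.9) {
  c1 <- p1; c2 <- p2
  if (runif(1) < pc) {
    for (j in seq_along(p1)) {
      if (runif(1) < 0.5 && abs(p1[j] - p2[j]) > 1e-14) {
        u <- runif(1)
        beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1)) else
          (1 / (2 * (1 - u)))^(1 / (eta + 1))
        c1[j] <- 0.5 * ((1 + beta) * p1[j] + (1 - beta) * p2[j])
        c2[j] <- 0.5 * ((1 - beta) * p1[j] + (1 + beta) * p2[j])
      }
    }
  }
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

poly_mutation <- function(x, lower, upper, eta = 20, pm = NULL) {
  if (is.null(pm)) pm <- 1 / length(x)
  for (j in seq_along(x)) {
    if (runif(1) < pm) {
      u <- runif(1)
      span <- upper[j] - lower[j]
      delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1 else
        1 - (2 * (1 - u))^(1 / (eta + 1))
      x[j] <- min(max(x[j] + delta * span, lower[j]), upper[j])
    }
  }
  x
}

#' NSGA-II multi-objective optimizer
#'
#' Standard elitist NSGA-II over a real-valued box: fast non-dominated
#' sorting into ranks, crowding-distance diversity, binary tournament
#' selection (rank, then crowding), simulated-binary crossover and
#' polynomial mutation, and environmental selection keeping the best
#' `pop_size` of parents plus offspring. Deterministic under `seed`.
#'
#' @param objective_fn Function mapping a parameter vector to a numeric
#'   vector of objectives (all minimized).
#' @param lower,upper Numeric bounds of equal length (the search box).
#' @param pop_size Even population size, at least 4 (default 40).
#' @param generations Number of generations (default 60).
#' @param seed Integer seed (default 42).
#' @param eta_cross,eta_mut SBX and polynomial-mutation distribution indices
#'   (defaults 15 and 20).
#' @return An `nsga2_result`: list with `front` (tibble of rank-0 parameters
#'   and objectives), `population` (tibble of the final population with
#'   `rank` and `crowding`), and the call parameters.
#' @examples
#' res <- nsga2(function(x) c(x^2, (x - 1)^2), 0, 2,
#'              pop_size = 20, generations = 20, seed = 1)
#' range(res$front$x1)   # within the [0, 1] Pareto set
#' @export
nsga2 <- function(objective_fn, lower, upper, pop_size = 40, generations = 60,
                  seed = 42, eta_cross = 15, eta_mut = 20) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  assert_that(length(lower) == length(upper) && all(upper > lower),
              "invalid bounds: need upper > lower elementwise")
  assert_that(pop_size >= 4 && pop_size %% 2 == 0,
              "pop_size must be even and at least 4")
  assert_that(generations >= 1, "generations must be at least 1")
  nvar <- length(lower)

  with_seed(derive_seed(seed, 31337L), {
    X <- matrix(runif(pop_size * nvar, rep(lower, each = pop_size),
                      rep(upper, each = pop_size)), pop_size, nvar)
    F <- t(apply(X, 1, objective_fn))
    if (is.null(dim(F))) F <- matrix(F, ncol = 1)
    rank <- nds_rank(F)
    crowd <- numeric(pop_size)
    for (r in unique(rank)) {
      idx <- which(rank == r)
      crowd[idx] <- crowding_distance(F[idx, , drop = FALSE])
    }

    tournament <- function() {
      a <- sample.int(nrow(X), 1); b <- sample.int(nrow(X), 1)
      if (rank[a] < rank[b]) a
      else if (rank[b] < rank[a]) b
      else if (crowd[a] >= crowd[b]) a else b
    }

    for (gen in seq_len(generations)) {
      offspring <- matrix(0, pop_size, nvar)
      for (k in seq(1, pop_size, by = 2)) {
        p1 <- X[tournament(), ]; p2 <- X[tournament(), ]
        ch <- sbx_crossover(p1, p2, lower, upper, eta = eta_cross)
        offspring[k, ] <- poly_mutation(ch[[1]], lower, upper, eta = eta_mut)
        offspring[k + 1, ] <- poly_mutation(ch[[2]], lower, upper, eta = eta_mut)
      }
      Fo <- t(apply(offspring, 1, objective_fn))
      if (is.null(dim(Fo))) Fo <- matrix(Fo, ncol = 1)
      Xall <- rbind(X, offspring)
      Fall <- rbind(F, Fo)
      rall <- nds_rank(Fall)
      call_crowd <- numeric(nrow(Xall))
      keep <- integer(0)
      for (r in sort(unique(rall))) {
        idx <- which(rall == r)
        call_crowd[idx] <- crowding_distance(Fall[idx, , drop = FALSE])
        if (length(keep) + length(idx) <= pop_size) {
          keep <- c(keep, idx)
        } else {
          slots <- pop_size - length(keep)
          keep <- c(keep, idx[order(call_crowd[idx], decreasing = TRUE)[seq_len(slots)]])
          break
        }
      }
      X <- Xall[keep, , drop = FALSE]
      F <- Fall[keep, , drop = FALSE]
      rank <- rall[keep]
      crowd <- call_crowd[keep]
      # re-rank within the survivors (ranks are relative to the new population)
      rank <- nds_rank(F)
      for (r in unique(rank)) {
        idx <- which(rank == r)
        crowd[idx] <- crowding_distance(F[idx, , drop = FALSE])
      }
    }

    pop_tbl <- dplyr::bind_cols(
      as_tibble(setNames(as.data.frame(X), paste0("x", seq_len(nvar)))),
      as_tibble(setNames(as.data.frame(F), paste0("f", seq_len(ncol(F))))),
      tibble(rank = rank, crowding = crowd))
    structure(list(front = pop_tbl[pop_tbl$rank == 1, ],
                   population = pop_tbl,
                   pop_size = pop_size, generations = generations, seed = seed),
              class = "nsga2_result")
  })
}

#' @export
print.nsga2_result <- function(x, ...) {
  cat(sprintf("<nsga2_result> pop %d, %d generations, front size %d\n",
              x$pop_size, x$generations, nrow(x$front)))
  print(x$front, n = 8)
  invisible(x)
}

#' Tidy the Pareto front of an NSGA-II run
#' @param x An `nsga2_result`.
#' @param ... Unused.
#' @return Tibble of rank-0 points (parameters and objectives).
#' @exportS3Method generics::tidy
tidy.nsga2_result <- function(x, ...) x$front

#' @param x An `nsga2_result`.
#' @param ... Unused.
#' @return One-row tibble: front size, population size, generations.
#' @rdname tidy.nsga2_result
#' @exportS3Method generics::glance
glance.nsga2_result <- function(x, ...) {
  tibble(front_size = nrow(x$front), pop_size = x$pop_size,
         generations = x$generations)
}

#' Plot the first two objectives of a Pareto front
#' @param object An `nsga2_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.nsga2_result <- function(object, ...) {
  ggplot2::ggplot(object$population,
                  ggplot2::aes(x = .data$f1, y = .data$f2,
                               colour = .data$rank == 1)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d95f02", `FALSE` = "grey60"),
                                 name = "Pareto front") +
    ggplot2::labs(x = "objective 1", y = "objective 2") +
    ggplot2::theme_minimal()
}

#' Optimize (skip_ratio, privacy_budget) trade-offs
#'
#' Runs [nsga2()] on the [surrogate_objectives()] with the decision variables
#' `skip_ratio` in \[0, 0.95\] and `privacy_budget` in \[0.1, 10\].
#'
#' @param base_acc Baseline accuracy for the surrogate (default 0.96).
#' @param total_params Parameter count for the cost objective (default:
#'   ResNet50, 4 classes).
#' @param pop_size,generations,seed Passed to [nsga2()].
#' @param penalty_coef Accuracy penalty coefficient.
#' @return A tibble: `skip_ratio`, `privacy_budget`, `accuracy_surrogate`,
#'   `cost_MB`, `leakage` for each front point.
#' @export
optimize_tradeoffs <- function(base_acc = 0.96, total_params = 23516228,
                               pop_size = 40, generations = 60, seed = 42,
                               penalty_coef = 0.02 / 0.6) {
  res <- nsga2(function(x) {
    as.numeric(surrogate_objectives(x[1], x[2], base_acc = base_acc,
                                    total_params = total_params,
                                    penalty_coef = penalty_coef))
  }, lower = c(0, 0.1), upper = c(0.95, 10),
  pop_size = pop_size, generations = generations, seed = seed)
  res$front |>
    dplyr::transmute(skip_ratio = .data$x1, privacy_budget = .data$x2,
                     accuracy_surrogate = -.data$f1, cost_MB = .data$f2,
                     leakage = .data$f3)
}
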