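#' Analytic per-round communication cost
#'
#' Each client uploads `total_params * (1 - skip_ratio)` trainable parameters
#' at 4 bytes (32-bit floats) per parameter, so the per-client per-round cost
#' is `total_params * (1 - skip_ratio) * 4 / 1024^2` MB. When secure
#' aggregation is enabled the cost is multiplied by `overhead_factor`
#' (default 1.15), modelling the masking protocol's extra payload. The
#' continuous `(1 - skip_ratio)` accounting is used here even though the
#' training-time skip planner freezes whole groups; the two counts are
#' reported side by side by [cost_report()].
#'
#' @param total_params Total model parameter count (positive).
#' @param skip_ratio Fraction of parameters skipped, in \[0, 1).
#' @param sa_enabled Apply the secure-aggregation overhead factor?
#' @param overhead_factor Multiplier used when `sa_enabled` (default 1.15).
#' @return Per-client per-round cost in MB.
#' @examples
#' per_round_cost(1024^2, 0)              # 4 MB
#' per_round_cost(23516228, 0.4)          # 53.82 MB
#' @export
per_round_cost <- function(total_params, skip_ratio = 0, sa_enabled = FALSE,
                           overhead_factor = 1.15) {
  assert_that(total_params > 0, "total_params must be positive")
  assert_that(skip_ratio >= 0 && skip_ratio < 1, "skip_ratio must be in [0, 1)")
  assert_that(overhead_factor >= 1, "overhead_factor must be at least 1")
  mb <- total_params * (1 - skip_ratio) * 4 / 1024^2
  if (isTRUE(sa_enabled)) mb <- mb * overhead_factor
  mb
}

#' Total communication cost of an experiment
#'
#' @param per_round_MB Per-client per-round cost in MB.
#' @param n_clients Number of clients.
#' @param rounds Number of federated rounds.
#' @return `per_round_MB * n_clients * rounds`.
#' @export
total_cost <- function(per_round_MB, n_clients, rounds) {
  assert_that(per_round_MB > 0 && n_clients > 0 && rounds > 0,
              "all cost arguments must be positive")
  per_round_MB * n_clients * rounds
}

#' Communication-cost report for a configuration
#'
#' @param arch_name Registry architecture (sets `total_params`).
#' @param num_classes Number of classes.
#' @param skip_ratio Layer-skip ratio in \[0, 1).
#' @param n_clients,rounds Federation size and length.
#' @param privacy_mode One of [privacy_modes()]; SA overhead applies for
#'   `sa_only` and `dp_sa`.
#' @param overhead_factor SA overhead multiplier (default 1.15).
#' @return A one-row tibble: `arch`, `privacy_mode`, `total_params`,
#'   `skip_ratio`, `trainable_params_continuous` (the accounting count),
#'   `trainable_params_plan` (the discrete greedy skip plan's count),
#'   `sa_enabled`, `per_round_MB`, `n_clients`, `rounds`, `total_MB`.
#' @examples
#' cost_report("resnet50", 4, skip_ratio = 0.4, privacy_mode = "sa_only")
#' @export
cost_report <- function(arch_name, num_classes = 4, skip_ratio = 0,
                        n_clients = 5, rounds = 8,
                        privacy_mode = "no_privacy", overhead_factor = 1.15) {
  check_privacy_mode(privacy_mode)
  inv <- layer_inventory(arch_name, num_classes)
  total <- total_params(inv)
  sa <- privacy_mode %in% c("sa_only", "dp_sa")
  prc <- per_round_cost(total, skip_ratio, sa, overhead_factor)
  plan <- make_skip_plan(inv, skip_ratio)
  tibble(arch = arch_name, privacy_mode = privacy_mode,
         total_params = total, skip_ratio = skip_ratio,
         trainable_params_continuous = total * (1 - skip_ratio),
         trainable_params_plan = plan$trainable_params,
         sa_enabled = sa, per_round_MB = prc,
         n_clients = as.integer(n_clients), rounds = as.integer(rounds),
         total_MB = total_cost(prc, n_clients, rounds))
}
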