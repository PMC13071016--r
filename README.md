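# fedprosim

Privacy-aware federated learning, simulated end-to-end on one machine.

Hospitals cannot pool MRI scans, so a shared tumor classifier must be
trained federatedly: each site fits the model on its own images and uploads
only parameter updates, which a server averages into a new global model.
That setting brings three coupled problems — non-IID data across sites,
per-round communication cost, and privacy leakage from the updates
themselves — and `fedprosim` simulates all three, at desk scale, in R.

The package provides:

* a **synthetic image generator** (4 classes of lesion motif on a "brain"
  disk) plus PNG image-folder I/O, stratified splitting, and **non-IID
  Dirichlet partitioning** across simulated clients;
* a **model registry**: a small trainable CNN (RcppArmadillo backend with
  its own Adam optimizer) and exact layer inventories / parameter counts
  for ResNet50-class backbones, with greedy **layer-skip (freeze) plans**;
* **federated orchestration**: sample-count-weighted FedAvg
  $\omega^{t+1} = \sum_k \frac{n_k}{n}\,\omega_k^{t+1}$ and count-weighted
  class-prototype aggregation
  $P(c) = \sum_k n_k(c)\,p_k(c) \,/\, \sum_k n_k(c)$;
* **privacy mechanisms**: differential privacy (clip to $L_2$ norm
  $C = 1$, add $\mathcal N(0,\sigma^2C^2 I)$ noise, $\sigma = 0.5$),
  simulated secure aggregation (pairwise antisymmetric masks that cancel
  in the sum), conservative $(\varepsilon,\delta)$ accounting, and the
  comparative leakage scores 1.0 / 0.6 / 0.4 / 0.2 for
  none / SA / DP / DP+SA;
* an **analytic communication-cost model**
  (`MB = params × (1 − skip) × 4 / 1024²`, ×1.15 under SA);
* **NSGA-II** multi-objective optimization over (skip ratio, privacy
  budget) against accuracy / cost / leakage surrogates;
* classification **metrics and reports** (weighted precision/recall/F1,
  one-vs-rest ROC-AUC, confusion matrices, centralized-vs-federated
  comparison CSVs).

Results come back as tibbles with `tidy()` / `glance()` / `autoplot()`
methods.

## Worked example

```r
library(fedprosim)

ds <- generate_synthetic_dataset(200, n_classes = 4, image_size = c(64, 64),
                                 noise_sd = 0.05, seed = 42)
suite <- run_federated_suite(ds, seed = 42)  # baseline + 4 federated configs
tidy(suite)
```

```
  configuration accuracy    f1 roc_auc leakage per_round_MB total_MB
1 no_privacy       1     1       1         1         0.0138    0.551
2 dp_only          0.356 0.258   0.647     0.4       0.0138    0.551
3 sa_only          1     1       1         0.6       0.0158    0.634
4 dp_sa            0.356 0.258   0.647     0.2       0.0158    0.634
```

Reading this: a centralized baseline (here accuracy 1.00 on the easy
synthetic classes) is trained on the pooled 80% split, then each privacy
configuration runs 8 federated rounds over 5 Dirichlet-partitioned
(α = 0.5) clients, warm-started from that baseline with layer skipping at
0.4. Secure aggregation is *transparent* — its masks cancel in the sum, so
`sa_only` matches `no_privacy` to floating-point tolerance while lowering
the leakage score to 0.6 at a 15% communication surcharge. The DP
configurations pay for their stronger protection (leakage 0.4 / 0.2) with
real accuracy loss: at desk scale the calibrated noise (σC = 0.5 per
coordinate) swamps the small updates. The qualitative ordering
none ≥ SA ≥ DP is the reproducible finding; absolute DP accuracies are
scale-dependent.

The cost model reproduces the large-backbone accounting analytically:

```r
cost_report("resnet50", 4, skip_ratio = 0.4, privacy_mode = "sa_only")
#   per_round_MB total_MB
#       61.898   2475.921        (53.824 and 2152.97 without SA)
```

and the trade-off optimizer returns a Pareto front over
(skip ratio, privacy budget):

```r
optimize_tradeoffs(seed = 42)
# A tibble: 40 × 5 — e.g. skip 0.95, ε = 10: accuracy surrogate 0.928,
# cost 4.49 MB/round, leakage 0.1 — versus skip 0, ε = 10: 0.96, 89.7 MB, 0.1
```

A command-line front end with the same operations ships in
`inst/cli/fedprosim` (`generate-data`, `partition`, `inspect-model`,
`train-federated`, `analyze-costs`, `optimize`, `report`).

## Acceptance script

`scripts/acceptance.R` recomputes, by running the installed package, the
privacy-leakage scores of the DP+SA and DP-only configurations and the
empirical standard deviation of the DP mechanism's noise (clip norm 1.0,
noise multiplier 0.5, 100,000 coordinates), and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/federated-simulation.Rmd`) describes the
model and aggregation rules, the privacy mechanisms and their accounting,
the synthetic world and what a green test does and does not establish,
and the numerical design decisions (including why the federated stage
warm-starts from the centralized baseline).
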