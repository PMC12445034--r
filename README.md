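# svgbench

Benchmarking toolkit for spatially variable gene (SVG) detection in spatial
transcriptomics and spatial ATAC-seq.

Spatial assays measure gene expression (or chromatin accessibility) at spots
with known 2-D tissue coordinates, and a central analysis step is finding
the genes whose expression depends on location — spatially variable genes.
Real tissue provides no ground truth for this task, so detectors must be
benchmarked on simulations with *known* spatial variability. svgbench is
for method developers and benchmarkers: it generates such data, ships a
strong Moran's I baseline, and scores any detector's output.

## What it provides

* **Reference-based simulator.** Per gene, a negative binomial model with a
  Gaussian-process-smoothed spatial mean μ_s(s) is fitted to a reference
  dataset. Counts are then synthesized from the convex mixture

      μ(s) = α·μ_s(s) + (1 − α)·μ_ns(s),

  where μ_ns is μ_s reordered by a random spot permutation and
  α ∈ [0, 1] is the known fraction of spatial variability (default: 21
  evenly spaced levels assigned round-robin across genes). α = 0 is a
  constructed null with the reference's marginals; α = 1 reproduces the
  reference-level spatial signal.

* **Multi-kernel scalability simulator.** Per gene, a squared-exponential
  mixture covariance K(a,b) = Σ_n β_n·exp(−‖x(a)−x(b)‖²/(2 l_n²)) with
  Dirichlet(1/N,…,1/N) weights, MVN log-intensities log λ ~ MVN(μ, K),
  per-spot normalization and Poisson counts y ~ Poisson(s·λ′) at library
  size s = 10,000 — arbitrary spot counts (a low-rank random-Fourier
  sampler takes over beyond 5,000 spots).

* **Moran's I detector.** I = (n/ΣW)·(Σ w_ij z_i z_j)/(Σ z_i²) on a KNN
  spatial graph, with analytic, permutation (default, n_perms = 100) and
  permutation-z p-values, BH adjustment and deterministic ranking; top-k
  feature selection (2,000 genes / 20,000 peaks by convention).

* **Evaluation suite.** Kendall τ (tau-a/tau-b) against true α, auPRC for
  SVG/non-SVG classification, K–S distance of null p-values from
  uniformity, adjusted Rand index, the CHAOS spatial continuity score, and
  cross-dataset rank aggregation. External detectors and clusterings enter
  through plain CSV schemas.

* **I/O.** Matrix Market + TSV sidecars, h5ad (interchangeable with the
  Python single-cell ecosystem), and CSV; log1p-CPM and TF-IDF
  normalization; gene filtering.

## Worked example

Simulate from a fitted reference with known α per gene, detect SVGs with
Moran's I, and score the detector:

```r
library(svgbench)

ref   <- generate_fixture("hotspot", n_spots = 400, n_genes = 63,
                          alpha_grid = 1, base_mean = 8, seed = 1)$dataset
model <- fit_reference(ref, smoother_settings(k = 48))
sim   <- simulate_from_reference(model, seed = 2)

tab <- detect_svg(sim$dataset, mode = "permutation", n_perms = 100, seed = 3)
head(tab[order(tab$rank), ], 5)
#>   gene_id     score    p_value p_adjusted rank
#>  gene0020 0.5152023 0.00990099 0.02012137    1
#>  gene0021 0.4418878 0.00990099 0.02012137    2
#>  gene0062 0.3995784 0.00990099 0.02012137    3
#>  gene0061 0.3152528 0.00990099 0.02012137    4
#>  gene0040 0.2425867 0.00990099 0.02012137    5

run_accuracy_benchmark(sim$truth, tab)
#> $kendall
#> [1] 0.6026731
#> $auprc
#> [1] 0.9912584
#> $n_genes
#> [1] 63
```

`score` is each gene's Moran's I on log1p-CPM expression and `rank = 1` is
the most spatially variable gene; `p_value` is the one-sided add-one
permutation p (1/101 when a gene beats all 100 permutations, as the top
genes here do). The Kendall τ of 0.60 says the detector recovers most of
the true α ordering across the 21 levels; the auPRC of 0.99 says genes with
any spatial signal (α > 0) separate almost perfectly from the constructed
α = 0 nulls.

The calibration audit permutes spots to destroy spatial signal and checks
that the detector's null p-values are uniform:

```r
run_calibration_audit(sim$dataset, min_expressed_spots = 300, seed = 4)
#> calibration_report: 63 genes, mode = permutation, K-S distance = 0.0558
```

A K–S distance near zero means well-calibrated p-values; miscalibrated
detectors show distances several times larger.

A thin command-line wrapper over the same functions is included at
`inst/cli/svgbench.R` (subcommands `simulate-kernel`, `fixture`, `detect`,
`evaluate`, `calibrate`).

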