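# semibench

Order-aware semi-synthetic null benchmarks for RNA-seq differential
expression.

## The problem

Semi-synthetic benchmarks for differential-expression (DE) methods force
most genes under the null hypothesis by randomly swapping their values
between samples, while a retained subset of truly DE genes serves as
gold-standard positives. Discoveries outside the gold standard are counted
as false positives and the empirical false discovery rate (FDR) is compared
with the nominal Benjamini–Hochberg (BH) level.

Whether that comparison means anything depends on *when* the swapping
happens. Sequencing depth (library size) varies several-fold across
samples. If raw counts are permuted and the permuted matrix is then
normalized, a high count swapped from a deeply sequenced donor into a
shallow sample becomes an artificially large log2-CPM value: the "null"
genes are no longer null on the analyzed scale, every test (Wilcoxon
included) appears to exceed its nominal FDR, and the excess "false
positives" are really detections of library-size differences. Permuting the
*normalized* values instead makes the group assignment independent of the
analyzed data by construction, and the benchmark's nominal FDR becomes
interpretable.

`semibench` is for methodologists who build or audit such benchmarks. It
provides:

- a seeded negative-binomial simulator of two-group count matrices with
  known truth, heavy-tailed gene means and heterogeneous library sizes
  (`sim_config()`, `simulate_counts()`, `gtex_like_config()`);
- edgeR-style preprocessing: low-count filtering, log2-CPM
  (`v = log2((y + c) 10^6 / (L f + 2c))`), and TMM factors
  (`filter_low_counts()`, `log2_cpm()`, `tmm_factors()`);
- the three permutation/normalization orderings — permute-then-normalize,
  raw, normalize-then-permute — with full donor bookkeeping
  (`select_gold_standard()`, `build_plan()`, `make_semisynthetic()`);
- per-gene two-group tests: Wilcoxon rank-sum, an asymptotic score test
  (statistic `n·r²` against chi-square(1)), and its permutation counterpart
  with the add-one p-value `(1 + #{T_b ≥ T_obs})/(B + 1)` and its explicit
  floor `1/(B + 1)` (`wilcoxon_test()`, `score_test_asymptotic()`,
  `score_test_permutation()`, `bh_adjust()`);
- a replicate benchmark of empirical FDR and power against nominal levels
  (`run_benchmark()`, `evaluate_replicate()`, `power_vs_n_curve()`), and a
  diagnostic that correlates each null gene's donor/recipient library-size
  imbalance with its apparent expression shift
  (`confounding_diagnostic()`).

Results are tibbles with `tidy()`/`glance()`/`autoplot()` methods, so
everything chains with the pipe.

## Worked example

Average over 25 replicate semi-synthetic datasets (2000 genes, 10% truly
DE, half retained as gold standard, 100 samples per group, library-size
factors with log-sd 0.7):

```r
library(semibench)
library(dplyr)

sim <- sim_config(n_genes = 2000, n_per_group = c(100, 100),
                  de_fraction = 0.1, seed = 1)
ev <- eval_config(n_replicates = 25,
                  schemes = c("permute_then_normalize",
                              "normalize_then_permute"),
                  root_seed = 20240)
report <- run_benchmark(sim, ev)
report |> tidy() |> filter(level == 0.05) |>
  select(scheme, method, fdr, fdr_se, power)
#> # A tibble: 6 × 5
#>   scheme                 method               fdr  fdr_se power
#>   <chr>                  <chr>              <dbl>   <dbl> <dbl>
#> 1 normalize_then_permute score_asymptotic  0.0443 0.00533 0.888
#> 2 normalize_then_permute score_permutation 0.0380 0.00477 0.886
#> 3 normalize_then_permute wilcoxon          0.0459 0.00537 0.888
#> 4 permute_then_normalize score_asymptotic  0.0767 0.0249  0.821
#> 5 permute_then_normalize score_permutation 0.0646 0.0254  0.816
#> 6 permute_then_normalize wilcoxon          0.0763 0.0235  0.82
```

At a nominal 5% FDR, the normalize-then-permute benchmark stays at or below
5% for all three tests (0.038–0.046), while the permute-then-normalize
construction pushes every test above its nominal level (0.065–0.077) and
also costs power, because gold-standard genes are normalized against
library sizes recomputed from a permuted matrix.

The diagnostic shows what those extra discoveries are detecting. On a
single permute-then-normalize dataset versus its normalize-then-permute
twin (same permutations):

```r
truth <- select_gold_standard(simulate_counts(sim)$truth, 0.5, seed = 2)
plan  <- build_plan(truth, 200, scheme = "permute_then_normalize", seed = 3)
ds    <- make_semisynthetic(simulate_counts(sim)$counts, plan, truth)
confounding_diagnostic(ds, seed = 5)
#> <confounding_report> Spearman rho(d, s) = 0.822 over 1710 null genes (permutation p = 0.001)
```

Under normalize-then-permute the same correlation is 0.003 (p = 0.92):
apparent DE of null genes tracks the donor/recipient library-size imbalance
`d` only when raw counts are permuted before normalization.

`autoplot(report)` draws empirical-vs-nominal FDR panels per scheme;
`plot_power_curve()` draws power against sample size, where the
permutation test's power collapses at a 1% nominal FDR because its p-values
cannot go below `1/(B + 1)`.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "semibench.R", package = "semibench"))') \
    benchmark --config bench.yaml --out-dir out/
```

Subcommands: `simulate`, `nullgen`, `test`, `benchmark`, `report`; schemes
are abbreviated `A` (permute-then-normalize), `raw`, `C`
(normalize-then-permute). All outputs are plain CSV/TSV with JSON sidecars,
and a rerun with the same config and seed is byte-identical.

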